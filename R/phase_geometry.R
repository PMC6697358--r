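# Closed-form V-nullcline and its analytic V-derivative.
#
# h enters dV/dt linearly, so dV/dt = 0 solves in closed form:
#   h_null(V) = -(I_K + I_L + I_synI + I_synE) / (g_NaP m_inf(V) (V - E_Na))
# For inhibitory units the adaptation gate is taken at its quasi-steady
# value p = d_adapt f_out(V) (the V-h projection of their dynamics).

nullcline_funs <- function(unit, shared, exc_sum, inh_sum) {
  if (unit$g_NaP <= 0)
    stop("V-nullcline undefined for g_NaP = 0 (h does not enter dV/dt)")
  s <- shared
  lg <- function(V, th, sg) 1 / (1 + exp((V - th) / sg))
  dlg <- function(V, th, sg) {
    f <- lg(V, th, sg)
    -f * (1 - f) / sg
  }
  N <- function(V) {
    IK <- if (unit$excitatory) {
      unit$g_K * lg(V, s$theta_n, s$sigma_n)^4 * (V - s$E_K)
    } else {
      unit$g_K * unit$d_adapt * lg(V, unit$theta_out, unit$sigma_out) *
        (V - s$E_K)
    }
    -(IK + unit$g_L * (V - unit$E_L) +
        s$g_synI * (V - s$E_synI) * inh_sum +
        s$g_synE * (V - s$E_synE) * exc_sum)
  }
  dN <- function(V) {
    dIK <- if (unit$excitatory) {
      n <- lg(V, s$theta_n, s$sigma_n)
      unit$g_K * (4 * n^3 * dlg(V, s$theta_n, s$sigma_n) * (V - s$E_K) + n^4)
    } else {
      fo <- lg(V, unit$theta_out, unit$sigma_out)
      unit$g_K * unit$d_adapt *
        (dlg(V, unit$theta_out, unit$sigma_out) * (V - s$E_K) + fo)
    }
    -(dIK + unit$g_L + s$g_synI * inh_sum + s$g_synE * exc_sum)
  }
  D <- function(V) unit$g_NaP * lg(V, s$theta_m, s$sigma_m) * (V - s$E_Na)
  dD <- function(V) {
    m <- lg(V, s$theta_m, s$sigma_m)
    unit$g_NaP * (dlg(V, s$theta_m, s$sigma_m) * (V - s$E_Na) + m)
  }
  list(h = function(V) N(V) / D(V),
       dh = function(V) (dN(V) * D(V) - N(V) * dD(V)) / D(V)^2)
}

#' V-nullcline of a unit under frozen synaptic input
#'
#' The set of (V, h) with dV/dt = 0, with the synaptic sums held fixed
#' as parameters. Since h enters the voltage equation linearly the
#' curve is obtained in closed form as h(V). The shape is `"cubic"`
#' when the curve has two interior folds (knees) in the sampled range
#' and `"monotone"` otherwise.
#'
#' @param unit a [unit_params()] object
#' @param shared a [shared_params()] object
#' @param exc_sum,inh_sum frozen synaptic sums (dimensionless)
#' @param V voltage grid (mV); must exclude E_Na
#' @return data frame of class `cpg_nullcline` with columns `V`, `h`,
#'   `clipped` (TRUE where h falls outside [-0.2, 1.2]); attributes
#'   `shape`, `exc_sum`, `inh_sum`, `unit`
#' @export
v_nullcline <- function(unit, shared = shared_params(), exc_sum = 0,
                        inh_sum = 0, V = seq(-100, 20, by = 0.1)) {
  if (any(V == shared$E_Na)) stop("V grid must exclude E_Na")
  fns <- nullcline_funs(unit, shared, exc_sum, inh_sum)
  h <- fns$h(V)
  folds <- fold_points(fns, range(V))
  out <- data.frame(V = V, h = pmin(pmax(h, -0.2), 1.2),
                    clipped = h < -0.2 | h > 1.2)
  structure(out, class = c("cpg_nullcline", "data.frame"),
            shape = if (nrow(folds) >= 2) "cubic" else "monotone",
            folds = folds, exc_sum = exc_sum, inh_sum = inh_sum,
            unit = unit$name)
}

# roots of dh_null/dV on a V interval (the knees/folds), by dense sign
# scan plus uniroot refinement
fold_points <- function(fns, Vlim, n_scan = 2000) {
  V <- seq(Vlim[1], Vlim[2], length.out = n_scan)
  d <- fns$dh(V)
  k <- which(d[-length(d)] * d[-1] < 0)
  if (!length(k)) return(data.frame(V = numeric(0), h = numeric(0)))
  Vf <- vapply(k, function(j)
    stats::uniroot(fns$dh, c(V[j], V[j + 1]), tol = 1e-12)$root, numeric(1))
  data.frame(V = Vf, h = fns$h(Vf))
}

#' h-nullcline
#'
#' The steady-state inactivation curve h = h_inf(V), independent of
#' synaptic input.
#' @inheritParams v_nullcline
#' @return data frame with columns `V`, `h`
#' @export
h_nullcline <- function(shared = shared_params(),
                        V = seq(-100, 20, by = 0.1)) {
  data.frame(V = V, h = gating("h_inf", V, shared))
}

#' Curve of knees versus inhibition
#'
#' Tracks a fold (knee) of the V-nullcline as the frozen inhibition
#' level varies. The left knee is the lower-voltage fold; crossing it
#' from below triggers the jump to the active phase ("escape"). Where
#' the nullcline turns monotone the fold ceases to exist and the curve
#' terminates; the termination inhibition level is refined by
#' bisection and recorded.
#'
#' @inheritParams v_nullcline
#' @param inh numeric grid of inhibition levels (non-negative,
#'   increasing)
#' @param side `"left"` or `"right"` knee
#' @param Vlim voltage interval searched for folds (mV)
#' @return data frame of class `cpg_knee_curve` with columns
#'   `inh_sum`, `V`, `h`; attributes `side` and `termination` (NA when
#'   the fold exists over the whole range)
#' @export
knee_curve <- function(unit, shared = shared_params(), exc_sum = 0,
                       inh = seq(0, 0.15, by = 0.001),
                       side = c("left", "right"), Vlim = c(-100, 20)) {
  side <- match.arg(side)
  stopifnot(all(inh >= 0), !is.unsorted(inh))
  pick <- function(level) {
    fns <- nullcline_funs(unit, shared, exc_sum, level)
    f <- fold_points(fns, Vlim)
    if (nrow(f) < 2) return(NULL)
    if (side == "left") f[which.min(f$V), ] else f[which.max(f$V), ]
  }
  rows <- lapply(inh, pick)
  have <- !vapply(rows, is.null, logical(1))
  term <- NA_real_
  if (!all(have) && any(have)) {
    # fold exists at high inhibition; refine where it is lost
    lo <- max(inh[!have & inh < min(inh[have])], -Inf)
    if (is.finite(lo)) {
      hi <- min(inh[have])
      while (hi - lo > 1e-6) {
        mid <- (lo + hi) / 2
        if (is.null(pick(mid))) lo <- mid else hi <- mid
      }
      term <- hi
    }
  }
  out <- do.call(rbind, c(list(data.frame(inh_sum = numeric(0), V = numeric(0),
                                          h = numeric(0))),
                          Map(function(i, r) if (is.null(r)) NULL else
                                data.frame(inh_sum = i, V = r$V, h = r$h),
                              inh, rows)))
  rownames(out) <- NULL
  structure(out, class = c("cpg_knee_curve", "data.frame"),
            side = side, termination = term,
            exc_sum = exc_sum, unit = unit$name)
}

#' Curve of fixed points versus inhibition
#'
#' Tracks the fixed point(s) of the isolated (V, h) subsystem over a
#' grid of frozen inhibition levels, with branch continuity (at each
#' level the fixed point nearest the previous one is reported first).
#'
#' @inheritParams knee_curve
#' @return data frame with columns `inh_sum`, `V`, `h`, `stable`
#' @export
fp_curve <- function(unit, shared = shared_params(), exc_sum = 0,
                     inh = seq(0, 0.15, by = 0.001)) {
  prev <- NULL
  rows <- lapply(inh, function(level) {
    fp <- find_fixed_points(unit, shared, exc_sum = exc_sum,
                            inh_sum = level)
    if (!nrow(fp)) return(NULL)
    if (!is.null(prev)) fp <- fp[order(abs(fp$V - prev)), ]
    prev <<- fp$V[1]
    data.frame(inh_sum = level, V = fp$V, h = fp$h, stable = fp$stable)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Escape event: trajectory crossing of the knee curve
#'
#' Projects a unit's trajectory into the (inhibition, h) plane and
#' finds, per cycle, the first crossing of the curve of left knees:
#' the moment when slow persistent-sodium deinactivation plus the
#' decay of inhibition carry the unit across the fold of its
#' V-nullcline, releasing the jump to the active phase. Crossings are
#' detected on the sign of h(t) - h_LK(inh(t)) with the knee curve
#' interpolated linearly in inhibition; the event is refined to
#' sub-sample accuracy.
#'
#' @param trace a rhythmic `cpg_trace`
#' @param unit unit index or name (default pre-I)
#' @param knees a [knee_curve()] for the same unit and frozen
#'   excitation
#' @param fps optional [fp_curve()] output (returned alongside for
#'   plotting; not used in detection)
#' @return list with `events` (data frame: cycle, t, inh_sum, h) and
#'   `path` (data frame: t, inh_sum, h); `events` has zero rows when
#'   no crossing exists
#' @export
project_escape <- function(trace, unit = 1, knees, fps = NULL) {
  i <- unit_index(trace$config, unit)
  if (classify_regime(trace, i) != "rhythmic")
    stop("escape projection requires a rhythmic trace")
  if (!nrow(knees)) {
    return(list(events = data.frame(cycle = integer(0), t = numeric(0),
                                    inh_sum = numeric(0), h = numeric(0)),
                path = data.frame(t = trace$t, inh_sum = trace$inh_sum[, i],
                                  h = trace$h[, i])))
  }
  hk <- stats::approxfun(knees$inh_sum, knees$h)
  inh <- trace$inh_sum[, i]
  h <- trace$h[, i]
  d <- h - hk(inh)      # NA where the knee curve does not exist
  # cycles bounded by inspiratory onsets of the reference unit
  lev <- mean(range(trace$f_out[, i]))
  cyc <- threshold_crossings(trace, unit, "f_out", lev, "up")
  events <- list()
  if (length(cyc) >= 2) {
    for (k in seq_len(length(cyc) - 1)) {
      j <- which(trace$t >= cyc[k] & trace$t < cyc[k + 1])
      jj <- j[-length(j)]
      cross <- jj[!is.na(d[jj]) & !is.na(d[jj + 1]) &
                    d[jj] < 0 & d[jj + 1] >= 0]
      if (length(cross)) {
        j0 <- cross[1]
        w <- (0 - d[j0]) / (d[j0 + 1] - d[j0])
        events[[length(events) + 1]] <- data.frame(
          cycle = k,
          t = trace$t[j0] + w * (trace$t[j0 + 1] - trace$t[j0]),
          inh_sum = inh[j0] + w * (inh[j0 + 1] - inh[j0]),
          h = h[j0] + w * (h[j0 + 1] - h[j0]))
      }
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(cycle = integer(0), t = numeric(0), inh_sum = numeric(0),
               h = numeric(0))
  list(events = events,
       path = data.frame(t = trace$t, inh_sum = inh, h = h))
}
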