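# Isolated-unit analysis: the planar (V, h) subsystem of an excitatory
# unit with frozen synaptic input, its fixed points and stability, the
# one-parameter bifurcation structure in the tunable drive c11, and
# the two-parameter oscillatory/tonic transition curve in
# (g_NaP, c11).

# planar vector field and analytic Jacobian at (V, h)
planar_field <- function(unit, shared, exc_sum, inh_sum) {
  s <- shared
  lg <- function(V, th, sg) 1 / (1 + exp((V - th) / sg))
  dlg <- function(V, th, sg) {
    f <- lg(V, th, sg)
    -f * (1 - f) / sg
  }
  F <- function(V, h) {
    IK <- if (unit$excitatory) {
      unit$g_K * lg(V, s$theta_n, s$sigma_n)^4 * (V - s$E_K)
    } else {
      unit$g_K * unit$d_adapt * lg(V, unit$theta_out, unit$sigma_out) *
        (V - s$E_K)
    }
    -(unit$g_NaP * lg(V, s$theta_m, s$sigma_m) * h * (V - s$E_Na) + IK +
        unit$g_L * (V - unit$E_L) +
        s$g_synI * (V - s$E_synI) * inh_sum +
        s$g_synE * (V - s$E_synE) * exc_sum) / s$C
  }
  G <- function(V, h) (lg(V, s$theta_h, s$sigma_h) - h) /
    (s$epsilon / cosh((V - s$theta_h) / (2 * s$sigma_h)))
  jac <- function(V, h) {
    m <- lg(V, s$theta_m, s$sigma_m)
    dm <- dlg(V, s$theta_m, s$sigma_m)
    dIK <- if (unit$excitatory) {
      n <- lg(V, s$theta_n, s$sigma_n)
      unit$g_K * (4 * n^3 * dlg(V, s$theta_n, s$sigma_n) * (V - s$E_K) + n^4)
    } else {
      fo <- lg(V, unit$theta_out, unit$sigma_out)
      unit$g_K * unit$d_adapt *
        (dlg(V, unit$theta_out, unit$sigma_out) * (V - s$E_K) + fo)
    }
    FV <- -(unit$g_NaP * h * (dm * (V - s$E_Na) + m) + dIK + unit$g_L +
              s$g_synI * inh_sum + s$g_synE * exc_sum) / s$C
    Fh <- -unit$g_NaP * m * (V - s$E_Na) / s$C
    u <- (V - s$theta_h) / (2 * s$sigma_h)
    tauh <- s$epsilon / cosh(u)
    dtauh <- -s$epsilon * sinh(u) / cosh(u)^2 / (2 * s$sigma_h)
    hinf <- lg(V, s$theta_h, s$sigma_h)
    GV <- dlg(V, s$theta_h, s$sigma_h) / tauh -
      (hinf - h) * dtauh / tauh^2
    Gh <- -1 / tauh
    matrix(c(FV, GV, Fh, Gh), 2, 2,
           dimnames = list(c("V", "h"), c("V", "h")))
  }
  list(F = F, G = G, jac = jac)
}

#' Fixed points of the isolated planar subsystem
#'
#' Finds all equilibria of the (V, h) subsystem of an excitatory unit
#' with the synaptic sums frozen as parameters: roots of dV/dt = 0
#' along h = h_inf(V), located by a dense 2000-point sign scan over V
#' in [-100, 20] mV with root refinement, each with the eigenvalues of
#' the analytic 2x2 Jacobian. The branch label places the fixed point
#' relative to the folds of the V-nullcline (`left` / `middle` /
#' `right`); when the nullcline is monotone the single branch is
#' labeled by the sign of its slope continuation (`left` below the h
#' midpoint voltage, `right` above).
#'
#' @param unit a [unit_params()] object
#' @param shared a [shared_params()] object
#' @param exc_sum,inh_sum frozen synaptic sums (dimensionless)
#' @param Vlim scan interval (mV)
#' @return data frame with columns `V`, `h`, `stable`, `re1`, `im1`,
#'   `re2`, `im2` (eigenvalues, 1/ms), `branch`
#' @export
find_fixed_points <- function(unit, shared = shared_params(),
                              exc_sum = 0, inh_sum = 0,
                              Vlim = c(-100, 20)) {
  pf <- planar_field(unit, shared, exc_sum, inh_sum)
  g <- function(V) pf$F(V, gating("h_inf", V, shared))
  V <- seq(Vlim[1], Vlim[2], length.out = 2000)
  y <- g(V)
  k <- which(y[-length(y)] * y[-1] < 0)
  k <- k[!is.na(k)]
  if (!length(k))
    stop("no fixed point found in the scan range; widen Vlim")
  roots <- vapply(k, function(j)
    stats::uniroot(g, c(V[j], V[j + 1]), tol = 1e-13)$root, numeric(1))
  folds <- tryCatch(
    fold_points(nullcline_funs(unit, shared, exc_sum, inh_sum), Vlim),
    error = function(e) data.frame(V = numeric(0), h = numeric(0)))
  rows <- lapply(roots, function(Vfp) {
    hfp <- gating("h_inf", Vfp, shared)
    ev <- eigen(pf$jac(Vfp, hfp), only.values = TRUE)$values
    ev <- ev[order(-Re(ev))]
    branch <- if (nrow(folds) >= 2) {
      if (Vfp < min(folds$V)) "left"
      else if (Vfp > max(folds$V)) "right" else "middle"
    } else if (Vfp < shared$theta_h) "left" else "right"
    data.frame(V = Vfp, h = hfp, stable = all(Re(ev) < 0),
               re1 = Re(ev[1]), im1 = Im(ev[1]),
               re2 = Re(ev[2]), im2 = Im(ev[2]), branch = branch)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# trace of the Jacobian at the drive-tracked fixed point, as a
# function of the tunable drive; used for Hopf detection.  When
# several fixed points coexist the one with positive determinant
# nearest `near` is tracked.
tracked_trace <- function(unit, shared, inh_sum, exc_offset) {
  pf_at <- function(c11, near = NULL) {
    fp <- find_fixed_points(unit, shared, exc_sum = c11 + exc_offset,
                            inh_sum = inh_sum)
    pf <- planar_field(unit, shared, c11 + exc_offset, inh_sum)
    J <- lapply(seq_len(nrow(fp)), function(r) pf$jac(fp$V[r], fp$h[r]))
    det_ok <- vapply(J, det, numeric(1)) > 0
    idx <- which(det_ok)
    if (!length(idx)) idx <- seq_len(nrow(fp))
    if (!is.null(near)) idx <- idx[order(abs(fp$V[idx] - near))]
    list(fp = fp[idx[1], ], J = J[[idx[1]]])
  }
  function(c11, near = NULL) {
    x <- pf_at(c11, near)
    list(tr = sum(diag(x$J)), det = det(x$J), V = x$fp$V)
  }
}

#' Hopf point of the isolated unit in the tunable drive
#'
#' Locates the drive value where the tracked fixed point's Jacobian
#' trace vanishes with positive determinant (an Andronov-Hopf point;
#' in this slow-fast system it is accompanied by a canard explosion,
#' so it nearly coincides with the onset of large-amplitude
#' oscillation).
#'
#' @inheritParams find_fixed_points
#' @param bracket c11 interval over which trace(J) changes sign
#' @param exc_offset fixed part of the excitatory drive added to c11
#'   (the second, fixed drive; 0.095 for the pre-I unit)
#' @return c11 value; attributes `trace` and `det` hold the defining
#'   quantities at the returned point
#' @export
hopf_point <- function(unit, shared = shared_params(), inh_sum = 0,
                       bracket, exc_offset = 0.095) {
  tt <- tracked_trace(unit, shared, inh_sum, exc_offset)
  f <- function(c11) tt(c11)$tr
  if (f(bracket[1]) * f(bracket[2]) > 0)
    stop("trace(J) does not change sign over the bracket")
  c11 <- stats::uniroot(f, bracket, tol = 1e-13)$root
  x <- tt(c11)
  if (x$det <= 0)
    stop("det(J) <= 0 at trace zero: saddle-node, not Hopf")
  structure(c11, trace = x$tr, det = x$det)
}

# classify the isolated unit's long-run regime at one drive value
isolated_regime <- function(unit, shared, c11, exc_offset = 0.095,
                            inh_sum = 0, opts = NULL) {
  if (is.null(opts)) opts <- solver_options(window = 60e3)
  cfg <- isolated_config(unit, shared, exc_sum = c11 + exc_offset,
                         inh_sum = inh_sum)
  tr <- find_attractor(cfg, opts)
  classify_regime(tr, 1)
}

#' Oscillatory interval of the isolated unit
#'
#' Boundaries of the drive interval over which the isolated unit's
#' attractor is a large-amplitude oscillation, located by simulation
#' classification and bisection to |dc11| < 1e-4. Returns NA
#' boundaries (with a reason attribute) when no oscillatory interval
#' exists, e.g. for g_NaP = 0 where h decouples from the voltage
#' dynamics and the planar system has no limit cycle.
#'
#' @inheritParams hopf_point
#' @param g_NaP optional persistent sodium conductance override (nS)
#' @param scan initial classification grid over c11
#' @param tol bisection tolerance on c11
#' @return numeric `c(c11_low, c11_high)`; attribute `regimes` holds
#'   the scan classifications
#' @export
oscillation_boundaries <- function(unit, shared = shared_params(),
                                   g_NaP = NULL, exc_offset = 0.095,
                                   inh_sum = 0,
                                   scan = seq(-0.1, 0.03, by = 0.005),
                                   tol = 1e-4) {
  if (!is.null(g_NaP)) unit$g_NaP <- g_NaP
  cls <- vapply(scan, function(c11)
    isolated_regime(unit, shared, c11, exc_offset, inh_sum), character(1))
  rhy <- cls == "rhythmic"
  if (!any(rhy)) {
    return(structure(c(NA_real_, NA_real_), reason = "no oscillatory interval",
                     regimes = stats::setNames(cls, scan)))
  }
  bisect <- function(lo, hi, rhythmic_at_hi) {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      r <- isolated_regime(unit, shared, mid, exc_offset, inh_sum) ==
        "rhythmic"
      if (r == rhythmic_at_hi) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  i1 <- which(rhy)[1]; i2 <- which(rhy)[length(which(rhy))]
  low <- if (i1 == 1) scan[1] else bisect(scan[i1 - 1], scan[i1], TRUE)
  high <- if (i2 == length(scan)) scan[length(scan)] else
    bisect(scan[i2], scan[i2 + 1], FALSE)
  structure(c(low, high), regimes = stats::setNames(cls, scan))
}

#' One-parameter bifurcation diagram of the isolated unit
#'
#' For each drive value: all fixed points with stability, plus (from
#' simulation) the orbit envelope (min and max voltage) and period
#' where the attractor is a large-amplitude oscillation.
#'
#' @inheritParams oscillation_boundaries
#' @param c11 drive grid
#' @return list of class `cpg_bifurcation` with `fixed_points` (long
#'   data frame: c11, V, h, stable, branch), `orbits` (c11, Vmin,
#'   Vmax, period_s), and `oscillatory_interval` from
#'   [oscillation_boundaries()]
#' @export
bifurcation_diagram <- function(unit, shared = shared_params(),
                                c11 = seq(-0.1, 0.02, by = 0.002),
                                exc_offset = 0.095, inh_sum = 0) {
  fps <- do.call(rbind, lapply(c11, function(cc) {
    fp <- find_fixed_points(unit, shared, cc + exc_offset, inh_sum)
    cbind(c11 = cc, fp[, c("V", "h", "stable", "branch")])
  }))
  opts <- solver_options(window = 60e3)
  orbits <- do.call(rbind, lapply(c11, function(cc) {
    cfg <- isolated_config(unit, shared, exc_sum = cc + exc_offset,
                           inh_sum = inh_sum)
    tr <- find_attractor(cfg, opts)
    if (classify_regime(tr, 1) != "rhythmic")
      return(data.frame(c11 = cc, Vmin = NA_real_, Vmax = NA_real_,
                        period_s = NA_real_))
    m <- compute_metrics(tr)
    data.frame(c11 = cc, Vmin = min(tr$V[, 1]), Vmax = max(tr$V[, 1]),
               period_s = m$T)
  }))
  interval <- oscillation_boundaries(unit, shared, exc_offset = exc_offset,
                                     inh_sum = inh_sum,
                                     scan = pretty(range(c11), 26))
  structure(list(fixed_points = fps, orbits = orbits,
                 oscillatory_interval = interval),
            class = "cpg_bifurcation")
}

#' Two-parameter transition curve in (g_NaP, c11)
#'
#' Follows the oscillatory-to-tonic boundary of the isolated unit
#' through the (g_NaP, c11) plane: for each conductance on the grid,
#' the upper drive boundary is re-located, warm-started from the
#' previous point (stepwise continuation). Two methods are available:
#' `"simulation-onset"` (bisection on the simulated large-amplitude
#' oscillation, the observable quantity) and `"linear-hopf"`
#' (trace(J) = 0 with det(J) > 0 at the tracked fixed point); the
#' canard explosion makes them nearly coincide.
#'
#' @inheritParams oscillation_boundaries
#' @param g_NaP decreasing or increasing grid of conductances (nS)
#' @param kind which boundary to follow
#' @param method boundary definition
#' @return data frame of class `cpg_transition_curve` with columns
#'   `g_NaP`, `c11`; rows are dropped (with attribute `truncated`)
#'   where the boundary ceases to exist
#' @export
continue_transition_curve <- function(unit, shared = shared_params(),
                                      g_NaP = seq(5, 0.5, by = -0.25),
                                      kind = c("oscillatory-to-tonic",
                                               "quiescent-to-oscillatory"),
                                      method = c("simulation-onset",
                                                 "linear-hopf"),
                                      exc_offset = 0.095, inh_sum = 0,
                                      tol = 1e-4) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  upper <- kind == "oscillatory-to-tonic"
  guess <- NULL
  truncated <- NULL
  rows <- list()
  for (g in g_NaP) {
    u <- unit; u$g_NaP <- g
    c11 <- NA_real_
    if (method == "linear-hopf") {
      tt <- tracked_trace(u, shared, inh_sum, exc_offset)
      f <- function(cc) tt(cc)$tr
      br <- if (!is.null(guess)) guess + c(-0.01, 0.01) else
        if (upper) c(-0.04, 0.01) else c(-0.09, -0.03)
      ok <- tryCatch(f(br[1]) * f(br[2]) < 0, error = function(e) FALSE)
      if (!ok) {   # widen once before giving up
        br <- if (upper) c(-0.06, 0.02) else c(-0.12, -0.02)
        ok <- tryCatch(f(br[1]) * f(br[2]) < 0, error = function(e) FALSE)
      }
      if (ok) c11 <- stats::uniroot(f, br, tol = 1e-10)$root
    } else {
      w <- if (!is.null(guess)) 0.01 else 0.05
      ctr <- if (!is.null(guess)) guess else if (upper) -0.015 else -0.06
      lo <- ctr - w; hi <- ctr + w
      rl <- isolated_regime(u, shared, lo, exc_offset, inh_sum)
      rh <- isolated_regime(u, shared, hi, exc_offset, inh_sum)
      want_lo <- if (upper) "rhythmic" else "quiescent"
      if ((rl == want_lo) != (rh == want_lo)) {
        while (hi - lo > tol) {
          mid <- (lo + hi) / 2
          if (isolated_regime(u, shared, mid, exc_offset, inh_sum) ==
              want_lo) lo <- mid else hi <- mid
        }
        c11 <- (lo + hi) / 2
      } else {
        # window does not bracket the boundary (cold start or a jump
        # in the curve); fall back to a full rescan
        b <- oscillation_boundaries(u, shared, exc_offset = exc_offset,
                                    inh_sum = inh_sum, tol = tol)
        c11 <- if (upper) b[2] else b[1]
      }
    }
    if (is.na(c11)) {
      truncated <- g
      break
    }
    guess <- c11
    rows[[length(rows) + 1]] <- data.frame(g_NaP = g, c11 = c11)
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("cpg_transition_curve", "data.frame"),
            kind = kind, method = method, truncated = truncated)
}
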