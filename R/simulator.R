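#' Solver options
#'
#' @param rel_tol,abs_tol integrator tolerances. Defaults suit the
#'   stiff relaxation dynamics (fast V jumps on a few-ms scale against
#'   the slow h with epsilon = 4000 ms).
#' @param max_step maximal integrator step (ms)
#' @param transient simulated time discarded before recording (ms)
#' @param record_dt output sampling interval (ms)
#' @param window length of the recorded analysis window (ms)
#' @param max_extend cap on total additional transient simulated while
#'   searching for an attractor (ms)
#' @param method deSolve integration method
#' @param seed integer seed for randomized initial conditions
#' @return list of class `cpg_solver_options`
#' @export
solver_options <- function(rel_tol = 1e-8, abs_tol = 1e-10, max_step = 10,
                           transient = 60e3, record_dt = 1, window = 40e3,
                           max_extend = 400e3, method = "lsoda",
                           seed = NULL) {
  stopifnot(rel_tol > 0, abs_tol > 0, transient >= 0, record_dt > 0,
            window > 0)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol, max_step = max_step,
                 transient = transient, record_dt = record_dt,
                 window = window, max_extend = max_extend, method = method,
                 seed = seed),
            class = "cpg_solver_options")
}

ode_raw <- function(config, y0, times, opts) {
  n <- length(config$units)
  out <- deSolve::ode(
    y = as.numeric(y0), times = times, func = "respcpg_derivs",
    parms = pack_parms(config), dllname = "respcpg",
    initfunc = "respcpg_initmod", nout = 3 * n,
    outnames = c(paste0("fout", seq_len(n)), paste0("inh", seq_len(n)),
                 paste0("exc", seq_len(n))),
    method = opts$method, rtol = opts$rel_tol, atol = opts$abs_tol,
    hmax = opts$max_step, maxsteps = 1e6)
  if (attr(out, "istate")[1] < 0)
    stop("integration failure (solver did not complete); last state at t = ",
         max(out[, 1]), " ms")
  out
}

trace_from_ode <- function(config, out, opts) {
  lay <- state_layout(config)
  nm <- unit_names(config)
  n <- length(nm)
  t <- out[, 1] - out[1, 1]
  y <- out[, 1 + seq_len(lay$n), drop = FALSE]
  V <- y[, lay$V, drop = FALSE]; colnames(V) <- nm
  h <- gating("h_inf", V, config$shared)
  h[, names(lay$h)] <- y[, lay$h, drop = FALSE]
  colnames(h) <- nm
  p <- matrix(NA_real_, nrow(y), n, dimnames = list(NULL, nm))
  p[, names(lay$p)] <- y[, lay$p, drop = FALSE]
  fo <- out[, 1 + lay$n + seq_len(n), drop = FALSE]; colnames(fo) <- nm
  is <- out[, 1 + lay$n + n + seq_len(n), drop = FALSE]; colnames(is) <- nm
  es <- out[, 1 + lay$n + 2 * n + seq_len(n), drop = FALSE]; colnames(es) <- nm
  yf <- y[nrow(y), ]
  names(yf) <- names(pack_state(config, V = rep(-60, n)))
  structure(list(t = t, V = V, h = h, p = p, f_out = fo, inh_sum = is,
                 exc_sum = es, config = config, opts = opts,
                 state_final = yf),
            class = "cpg_trace")
}

#' Integrate the network ODEs
#'
#' Integrates the model from `state0`, discards `opts$transient` ms and
#' returns a densely sampled trace over the following `duration` ms
#' with the derived per-unit outputs and synaptic sums.
#'
#' @param config a [network_config()]
#' @param state0 packed initial state (see [pack_state()]); default
#'   [default_initial_state()]
#' @param duration length of the recorded trace (ms)
#' @param opts a [solver_options()] object
#' @return a `cpg_trace` object: time grid `t` (starting at 0 after the
#'   transient), matrices `V`, `h`, `p`, `f_out`, `inh_sum`, `exc_sum`
#'   (rows = samples, columns = units), the config snapshot and the
#'   final packed state
#' @export
cpg_integrate <- function(config, state0 = NULL, duration = 40e3,
                          opts = solver_options()) {
  if (is.null(state0)) state0 <- default_initial_state(config)
  lay <- state_layout(config)
  if (length(state0) != lay$n)
    stop("state0 has length ", length(state0), ", expected ", lay$n)
  V0 <- state0[lay$V]
  if (any(V0 < -100 | V0 > 60)) stop("initial V outside [-100, 60] mV")
  if (any(state0[lay$h] < 0 | state0[lay$h] > 1))
    stop("initial h outside [0, 1]")
  if (any(state0[lay$p] < 0)) stop("initial p < 0")
  y <- as.numeric(state0)
  if (opts$transient > 0) {
    pre <- ode_raw(config, y, c(0, opts$transient), opts)
    y <- pre[nrow(pre), 1 + seq_len(lay$n)]
  }
  times <- seq(0, duration, by = opts$record_dt)
  trace_from_ode(config, ode_raw(config, y, times, opts), opts)
}

#' @export
print.cpg_trace <- function(x, ...) {
  cat("<cpg_trace> ", length(x$t), " samples over ",
      diff(range(x$t)) / 1000, " s, units: ",
      paste(colnames(x$V), collapse = ", "), sep = "")
  if (!is.null(attr(x, "attractor")))
    cat(", attractor: ", attr(x, "attractor"), sep = "")
  cat("\n")
  invisible(x)
}

#' Flatten a trace to a data frame
#'
#' One row per sample: t plus V, h, p, f_out and inh_sum per unit, with
#' columns named by unit. Suitable for delimited-text export via
#' [utils::write.table()].
#' @param x a `cpg_trace`
#' @param row.names,optional,... ignored (S3 signature)
#' @export
as.data.frame.cpg_trace <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  cols <- list(t = x$t)
  for (w in c("V", "h", "p", "f_out", "inh_sum")) {
    m <- x[[w]]
    for (u in colnames(m)) cols[[paste0(w, "_", u)]] <- m[, u]
  }
  as.data.frame(cols, check.names = FALSE)
}

periodicity_check <- function(trace, unit = 1, level = NULL,
                              min_cycles = 4, cv_tol = 1e-3) {
  # adaptive level: small oscillations need not reach any fixed voltage
  if (is.null(level)) {
    r <- range(trace$V[, unit_index(trace$config, unit)])
    if (diff(r) < 0.5) return(list(ok = FALSE, periods = NULL))
    level <- mean(r)
  }
  up <- threshold_crossings(trace, unit, "V", level, "up")
  if (length(up) < min_cycles + 1) return(list(ok = FALSE, periods = NULL))
  per <- diff(up)
  per <- per[max(1, length(per) - 7):length(per)]   # last cycles only
  cv <- stats::sd(per) / mean(per)
  list(ok = is.finite(cv) && cv < cv_tol && length(per) >= min_cycles,
       periods = per, cv = cv)
}

steady_check <- function(trace, tail_ms = 5000, tol = 1e-5) {
  keep <- trace$t >= max(trace$t) - tail_ms
  idx <- which(keep)
  idx <- idx[seq(1, length(idx), length.out = min(50, length(idx)))]
  lay <- state_layout(trace$config)
  mx <- 0
  for (k in idx) {
    y <- numeric(lay$n)
    y[lay$V] <- trace$V[k, ]
    y[lay$h] <- trace$h[k, names(lay$h)]
    y[lay$p] <- trace$p[k, names(lay$p)]
    d <- cpg_rhs_compiled(trace$config, y)$ydot
    mx <- max(mx, max(abs(d[lay$V])))
  }
  mx < tol
}

#' Integrate to an attractor
#'
#' Runs the model past its transient and keeps extending the
#' integration until the recorded window is judged to be on an
#' attractor: periodic (at least 4 complete cycles of the pre-I
#' voltage through -35 mV with cycle-to-cycle period coefficient of
#' variation below 0.1%) or steady (max |dV/dt| below tolerance over
#' the final 5 s). If neither criterion is met within the extension
#' cap, the trace is labeled `"undetermined"` rather than silently
#' classified.
#'
#' @inheritParams cpg_integrate
#' @param state0 optional initial state
#' @return a `cpg_trace` with attribute `attractor` in
#'   `c("periodic", "steady", "undetermined")`
#' @export
find_attractor <- function(config, opts = solver_options(), state0 = NULL) {
  tr <- cpg_integrate(config, state0, duration = opts$window, opts = opts)
  extended <- 0
  repeat {
    pc <- periodicity_check(tr)
    if (pc$ok) {
      attr(tr, "attractor") <- "periodic"
      return(tr)
    }
    if (steady_check(tr)) {
      attr(tr, "attractor") <- "steady"
      return(tr)
    }
    if (extended >= opts$max_extend) {
      attr(tr, "attractor") <- "undetermined"
      return(tr)
    }
    extended <- extended + opts$window
    opts2 <- opts
    opts2$transient <- 0
    tr <- cpg_integrate(config, tr$state_final, duration = opts$window,
                        opts = opts2)
  }
}

#' Locate threshold crossings in a trace
#'
#' Crossing times of a recorded variable through a level, refined by
#' monotone cubic interpolation on the samples bracketing each sign
#' change (sub-sample accuracy without event-based solving).
#'
#' @param trace a `cpg_trace`
#' @param unit unit index or name
#' @param variable `"V"` (mV) or `"f_out"` (dimensionless)
#' @param level threshold
#' @param direction `"up"` or `"down"`
#' @return sorted numeric vector of crossing times (ms); empty when no
#'   transversal crossing exists
#' @export
threshold_crossings <- function(trace, unit = 1, variable = c("V", "f_out"),
                                level, direction = c("up", "down")) {
  variable <- match.arg(variable)
  direction <- match.arg(direction)
  i <- unit_index(trace$config, unit)
  y <- trace[[variable]][, i] - level
  t <- trace$t
  if (direction == "up") k <- which(y[-length(y)] < 0 & y[-1] >= 0)
  else k <- which(y[-length(y)] > 0 & y[-1] <= 0)
  vapply(k, function(j) {
    if (y[j] == 0) return(t[j])
    if (y[j + 1] == 0) return(t[j + 1])
    w <- max(1, j - 2):min(length(t), j + 3)
    f <- stats::splinefun(t[w], y[w], method = "monoH.FC")
    if (f(t[j]) * f(t[j + 1]) < 0)
      stats::uniroot(f, c(t[j], t[j + 1]), tol = 1e-9)$root
    else (t[j] + t[j + 1]) / 2
  }, numeric(1))
}
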