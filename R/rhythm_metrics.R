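#' Rhythm metrics of an attractor trace
#'
#' Extracts the standard respiratory observables from an attractor
#' trace: period `T` (mean interval between successive up-crossings of
#' the pre-I voltage through -35 mV), inspiratory duration `T_I` (mean
#' up-to-down interval through the same threshold), expiratory
#' duration `T_E = T - T_I`, and amplitude (max minus min of the pre-I
#' output over the analyzed cycles). Averages use at least
#' `min_cycles` complete cycles. When the oscillation never reaches
#' -35 mV (small-amplitude rhythms at low g_NaP or near the soft upper
#' Hopf), `T` falls back to mid-range voltage crossings and `T_I`,
#' `T_E` are flagged `NA`.
#'
#' @param trace a `cpg_trace`, ideally from [find_attractor()]
#' @param unit unit whose voltage defines the phase convention
#'   (default pre-I, unit 1)
#' @param level threshold voltage (mV)
#' @param min_cycles minimum number of complete cycles to average over
#' @return object of class `cpg_metrics`: list with `T`, `T_I`, `T_E`
#'   (seconds), `amplitude`, `regime`, `three_phase_valid` (NA unless
#'   filled by [validate_three_phase()]), `n_cycles_used`
#' @export
compute_metrics <- function(trace, unit = 1, level = -35, min_cycles = 4) {
  regime <- classify_regime(trace, unit)
  out <- structure(list(T = NA_real_, T_I = NA_real_, T_E = NA_real_,
                        amplitude = NA_real_, regime = regime,
                        three_phase_valid = NA, n_cycles_used = 0L),
                   class = "cpg_metrics")
  if (regime != "rhythmic") return(out)
  i <- unit_index(trace$config, unit)
  up <- threshold_crossings(trace, unit, "V", level, "up")
  dn <- threshold_crossings(trace, unit, "V", level, "down")
  if (length(up) >= 2) {
    Tms <- mean(diff(up))
    # pair each up-crossing with the next down-crossing
    ti <- vapply(up[-length(up)], function(u) {
      d <- dn[dn > u]
      if (length(d)) d[1] - u else NA_real_
    }, numeric(1))
    out$T <- Tms / 1000
    out$T_I <- mean(ti, na.rm = TRUE) / 1000
    out$T_E <- out$T - out$T_I
    out$n_cycles_used <- length(up) - 1L
  } else {
    mid <- mean(range(trace$V[, i]))
    upm <- threshold_crossings(trace, unit, "V", mid, "up")
    if (length(upm) >= 2) {
      out$T <- mean(diff(upm)) / 1000
      out$n_cycles_used <- length(upm) - 1L
    }
  }
  if (out$n_cycles_used >= 1) {
    lo <- if (length(up) >= 2) up[1] else 0
    keep <- trace$t >= lo
    out$amplitude <- max(trace$f_out[keep, i]) - min(trace$f_out[keep, i])
  }
  if (out$n_cycles_used < min_cycles)
    warning("only ", out$n_cycles_used, " complete cycles in window")
  out
}

#' @export
print.cpg_metrics <- function(x, ...) {
  cat("<cpg_metrics> regime:", x$regime)
  if (x$regime == "rhythmic")
    cat(sprintf("; T = %.3f s (T_I = %.3f, T_E = %.3f), amplitude = %.3f, %d cycles",
                x$T, x$T_I, x$T_E, x$amplitude, x$n_cycles_used))
  cat("\n")
  invisible(x)
}

#' Classify the dynamic regime of a trace
#'
#' A trace is `rhythmic` when it is on a periodic attractor and the
#' output excursion of the reference unit exceeds 0.05 (large-
#' amplitude oscillation; sub-threshold ripple near a Hopf point does
#' not count). A steady trace is `tonic` when the steady voltage
#' exceeds `theta_h` (equivalently `h_inf(V) < 0.5`: drive keeps the
#' unit depolarized enough that persistent-sodium deinactivation is
#' limited) and `quiescent` otherwise. For `unit = "network"` the
#' trace is tonic when any unit's steady voltage exceeds `theta_h`
#' (e.g. the non-rhythmic network state in which post-I holds a steady
#' elevated activation). Traces whose attractor search did not
#' converge stay `undetermined`.
#'
#' @param trace a `cpg_trace` from [find_attractor()]
#' @param unit unit index/name, or `"network"`
#' @param excursion_min minimal output excursion for rhythmicity
#' @return one of `"rhythmic"`, `"tonic"`, `"quiescent"`,
#'   `"undetermined"`
#' @export
classify_regime <- function(trace, unit = 1, excursion_min = 0.05) {
  att <- attr(trace, "attractor")
  if (is.null(att)) {
    att <- if (periodicity_check(trace)$ok) "periodic"
           else if (steady_check(trace)) "steady" else "undetermined"
  }
  if (att == "undetermined") return("undetermined")
  network <- identical(unit, "network")
  i <- if (network) 1L else unit_index(trace$config, unit)
  if (att == "periodic") {
    exc <- max(trace$f_out[, i]) - min(trace$f_out[, i])
    if (exc > excursion_min) return("rhythmic")
  }
  th <- trace$config$shared$theta_h
  Vss <- trace$V[nrow(trace$V), ]
  dep <- if (network) any(Vss > th) else Vss[i] > th
  if (dep) "tonic" else "quiescent"
}

#' Validate the three-phase activation order
#'
#' Checks, cycle by cycle, that the network produces a functional
#' three-phase rhythm: pre-I activates before or together with
#' early-I, followed by post-I and then aug-E (each unit's onset is
#' the up-crossing of its own output through the midpoint of its cycle
#' range), and that aug-E output exceeds post-I output at the end of
#' expiration (the sample immediately preceding the inspiratory
#' onset).
#'
#' When a unit crosses its onset level more than once per cycle, the
#' crossing followed by the longest continuous time above the level
#' is taken as the activation onset. This rejects the brief transient
#' spike of the aug-E unit at the inspiratory-to-expiratory
#' transition (when post-I and aug-E compete and post-I wins) in
#' favor of its sustained late-expiratory surge.
#'
#' @param trace a rhythmic network `cpg_trace`
#' @param tol onset-time slack (ms) for the "before or together"
#'   comparison between pre-I and early-I
#' @return list with `valid` (logical), `onsets` (matrix of per-cycle
#'   onset times, ms), and `augE_gt_postI` (per-cycle logical)
#' @export
validate_three_phase <- function(trace, tol = 50) {
  cfg <- trace$config
  nm <- unit_names(cfg)
  need <- c("pre-I", "early-I", "post-I", "aug-E")
  if (!all(need %in% nm)) stop("trace lacks the four core units")
  if (classify_regime(trace, 1) != "rhythmic")
    stop("three-phase validation requires a rhythmic network trace")
  # cycle boundaries: pre-I onset (own half-range output crossing)
  onset_level <- function(i) mean(range(trace$f_out[, i]))
  cyc <- threshold_crossings(trace, "pre-I", "f_out",
                             onset_level(unit_index(cfg, "pre-I")), "up")
  if (length(cyc) < 3) stop("too few cycles for validation")
  ncyc <- length(cyc) - 1L
  onsets <- matrix(NA_real_, ncyc, length(need),
                   dimnames = list(NULL, need))
  augE_gt <- logical(ncyc)
  for (k in seq_len(ncyc)) {
    lo <- cyc[k]; hi <- cyc[k + 1]
    onsets[k, "pre-I"] <- lo
    for (u in c("early-I", "post-I", "aug-E")) {
      i <- unit_index(cfg, u)
      lev <- onset_level(i)
      cr <- threshold_crossings(trace, u, "f_out", lev, "up")
      dnn <- threshold_crossings(trace, u, "f_out", lev, "down")
      # early-I may activate together with (numerically just before)
      # pre-I; the window is shifted by tol at both ends so the next
      # cycle's near-simultaneous onset is not captured
      cr <- cr[cr >= lo - tol & cr < hi - tol]
      if (length(cr) > 1) {
        dwell <- vapply(cr, function(tc) {
          d <- dnn[dnn > tc]
          if (length(d)) d[1] - tc else max(trace$t) - tc
        }, numeric(1))
        cr <- cr[which.max(dwell)]
      }
      if (length(cr)) onsets[k, u] <- cr[1]
    }
    j <- max(which(trace$t < hi))   # last sample before next inspiration
    augE_gt[k] <- trace$f_out[j, unit_index(cfg, "aug-E")] >
      trace$f_out[j, unit_index(cfg, "post-I")]
  }
  ord_ok <- apply(onsets, 1, function(o) {
    !anyNA(o) && o["pre-I"] <= o["early-I"] + tol &&
      o["early-I"] < o["post-I"] && o["post-I"] < o["aug-E"]
  })
  list(valid = all(ord_ok) && all(augE_gt), onsets = onsets,
       augE_gt_postI = augE_gt)
}

#' Metrics for one configuration, end to end
#'
#' Convenience wrapper: find the attractor, compute metrics, and (for
#' rhythmic 4/5-unit networks) validate the three-phase order.
#' @param config a [network_config()]
#' @param opts a [solver_options()]
#' @param state0 optional initial state (warm start)
#' @return a `cpg_metrics` object; attribute `trace` holds the
#'   attractor trace
#' @export
network_metrics <- function(config, opts = solver_options(), state0 = NULL) {
  tr <- find_attractor(config, opts, state0)
  m <- compute_metrics(tr)
  if (m$regime == "rhythmic" &&
      all(c("pre-I", "early-I", "post-I", "aug-E") %in% unit_names(config)))
    m$three_phase_valid <- validate_three_phase(tr)$valid
  attr(m, "trace") <- tr
  m
}

#' Flatten metrics to a one-row data frame
#' @param x a `cpg_metrics`
#' @param row.names,optional,... ignored (S3 signature)
#' @export
as.data.frame.cpg_metrics <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  data.frame(T = x$T, T_I = x$T_I, T_E = x$T_E, amplitude = x$amplitude,
             regime = x$regime, three_phase_valid = x$three_phase_valid,
             n_cycles_used = x$n_cycles_used)
}
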