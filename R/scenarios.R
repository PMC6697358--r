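#' Named model presets
#'
#' Fully populated network configurations used throughout the analyses.
#' `baseline4` is the canonical 4-unit network (pre-I, early-I, post-I,
#' aug-E) at the baseline parameter set with the intrinsically
#' oscillatory pre-I drive tuning c11 = -0.03; `oscillatory` is an
#' alias for it. `tonic` retunes the pre-I drive to c11 = 0.01, for
#' which the isolated pre-I unit is tonically active. `strong_b31` /
#' `weak_b31` raise/lower the post-I -> pre-I inhibitory weight to
#' 0.175 / 0.105. `baseline5_pico` adds the excitatory PiCo unit
#' (a15 = 0.2, a53 = 0.1, b25 = 0.2, b45 = 0.3, c15 = 0.045) and
#' weakens aug-E -> post-I inhibition to b43 = 0.02.
#'
#' Every non-default value carries a provenance note in the preset's
#' `provenance` attribute, so deviations from the baseline lists are
#' explicit.
#'
#' @param name preset name
#' @param c11 optional override of the pre-I tunable drive
#' @return a [network_config()] with attributes `preset` and
#'   `provenance`
#' @export
preset <- function(name = c("baseline4", "oscillatory", "tonic",
                            "strong_b31", "weak_b31", "baseline5_pico"),
                   c11 = NULL) {
  if (!is.character(name) || !(name[1] %in% c(
    "baseline4", "oscillatory", "tonic", "strong_b31", "weak_b31",
    "baseline5_pico")))
    stop("unknown preset '", name[1], "'; available: baseline4, ",
         "oscillatory, tonic, strong_b31, weak_b31, baseline5_pico")
  name <- match.arg(name)

  exc_unit <- function(nm, theta_out, sigma_out)
    unit_params(nm, TRUE, g_NaP = 4.5, g_K = 1.0, g_L = 3, E_L = -65,
                theta_out = theta_out, sigma_out = sigma_out)
  inh_unit <- function(nm, tau_p)
    unit_params(nm, FALSE, g_NaP = 0.25, g_K = 10.0, g_L = 3.25,
                E_L = -60, theta_out = -30, sigma_out = -4,
                tau_p = tau_p, d_adapt = 1)

  units <- list(exc_unit("pre-I", -32, -8),
                inh_unit("early-I", 2000),
                inh_unit("post-I", 1500),
                inh_unit("aug-E", 2000))
  pico <- name == "baseline5_pico"
  if (pico) units <- c(units, list(exc_unit("PiCo", -20, -12)))
  n <- length(units)

  a <- matrix(0, n, n); b <- matrix(0, n, n)
  a[1, 2] <- 0.6                       # pre-I -> early-I
  b[3, 1] <- 0.125; b[4, 1] <- 0.015   # onto pre-I
  b[3, 2] <- 0.27;  b[4, 2] <- 0.3     # onto early-I
  b[2, 3] <- 0.6;   b[4, 3] <- 0.05    # onto post-I
  b[2, 4] <- 0.3;   b[3, 4] <- 0.45    # onto aug-E
  c1 <- c(-0.03, 0.19, 0.58, 0.2)
  c2 <- c(0.095, 0.3, 0, 0.4)
  if (pico) {
    a[1, 5] <- 0.2   # pre-I -> PiCo
    a[5, 3] <- 0.1   # PiCo -> post-I
    b[2, 5] <- 0.2; b[4, 5] <- 0.3
    b[4, 3] <- 0.02  # aug-E -> post-I weakened when PiCo present
    c1 <- c(c1, 0.045)
    c2 <- c(c2, 0)   # PiCo second drive not listed; taken as 0
  }
  if (name == "tonic") c1[1] <- 0.01
  if (name == "strong_b31") b[3, 1] <- 0.175
  if (name == "weak_b31") b[3, 1] <- 0.105
  if (!is.null(c11)) c1[1] <- c11

  cfg <- network_config(units, shared_params(), a, b, c1, c2)
  attr(cfg, "preset") <- name
  attr(cfg, "provenance") <- c(
    "unit and shared values: baseline parameter lists",
    switch(name,
           oscillatory = , baseline4 = "c11 = -0.03: oscillatory pre-I tuning",
           tonic = "c11 = 0.01: tonic pre-I tuning",
           strong_b31 = "b31 = 0.175: raised post-I -> pre-I inhibition",
           weak_b31 = "b31 = 0.105: lowered post-I -> pre-I inhibition",
           baseline5_pico = "PiCo unit with a53 = 0.1, b43 = 0.02, c15 = 0.045"))
  cfg
}

#' Isolated single-unit configuration
#'
#' A 1-unit network holding a copy of the given unit with all phasic
#' synaptic input removed: the excitatory sum is the frozen
#' `exc_sum` and the inhibitory sum the frozen `inh_sum`. For the
#' pre-I unit this is the planar (V, h) subsystem studied in the
#' bifurcation and phase-plane analyses.
#'
#' @param unit a [unit_params()] object (or a unit name resolved in
#'   `from`)
#' @param shared a [shared_params()] object
#' @param exc_sum frozen total excitatory drive (dimensionless); for
#'   the isolated pre-I unit this is c11 + c21
#' @param inh_sum frozen total inhibition (dimensionless)
#' @param from optional [network_config()] to take the unit and shared
#'   parameters from
#' @return a 1-unit [network_config()]
#' @export
isolated_config <- function(unit = "pre-I", shared = shared_params(),
                            exc_sum = 0.065, inh_sum = 0, from = NULL) {
  if (is.character(unit) && is.null(from))
    from <- preset(if (unit == "PiCo") "baseline5_pico" else "baseline4")
  if (!is.null(from)) {
    i <- unit_index(from, unit)
    unit <- from$units[[i]]
    shared <- from$shared
  }
  stopifnot(inherits(unit, "cpg_unit"))
  unit$inh0 <- inh_sum
  network_config(list(unit), shared,
                 a = matrix(0, 1, 1), b = matrix(0, 1, 1),
                 c1 = exc_sum, c2 = 0)
}

#' Random initial state
#'
#' Draws V uniformly from [-70, -20] mV, h from [0.2, 0.9] and p from
#' [0, 0.5], reproducibly for a given seed. The seed is applied via a
#' local RNG scope, leaving the caller's RNG state untouched.
#'
#' @param config a [network_config()]
#' @param seed integer seed
#' @return packed state vector
#' @export
random_initial_state <- function(config, seed) {
  lay <- state_layout(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pack_state(config,
             V = stats::runif(length(lay$V), -70, -20),
             h = stats::runif(length(lay$h), 0.2, 0.9),
             p = stats::runif(length(lay$p), 0, 0.5))
}

#' Default initial state
#'
#' Post-I-active start: V = -60 mV everywhere except post-I at -30 mV,
#' h = 0.6, p = 0.1.
#' @param config a [network_config()]
#' @return packed state vector
#' @export
default_initial_state <- function(config) {
  nm <- unit_names(config)
  V <- ifelse(nm == "post-I", -30, -60)
  pack_state(config, V = V, h = 0.6, p = 0.1)
}
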