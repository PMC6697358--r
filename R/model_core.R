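#' Gating functions
#'
#' Voltage-dependent steady-state activation/inactivation sigmoids and
#' the inactivation time constant of the persistent sodium current:
#' `h_inf(V) = 1/(1 + exp((V - theta_h)/sigma_h))`,
#' `tau_h(V) = epsilon / cosh((V - theta_h)/(2 sigma_h))`,
#' `m_inf(V) = 1/(1 + exp((V - theta_m)/sigma_m))`,
#' `n_inf(V) = 1/(1 + exp((V - theta_n)/sigma_n))`.
#'
#' @param kind one of `"h_inf"`, `"tau_h"`, `"m_inf"`, `"n_inf"`
#' @param V membrane potential (mV), vectorized
#' @param shared a [shared_params()] object
#' @return dimensionless value in (0,1), or ms for `"tau_h"`
#' @export
gating <- function(kind = c("h_inf", "tau_h", "m_inf", "n_inf"), V,
                   shared = shared_params()) {
  kind <- match.arg(kind)
  switch(kind,
    h_inf = 1 / (1 + exp((V - shared$theta_h) / shared$sigma_h)),
    tau_h = shared$epsilon / cosh((V - shared$theta_h) / (2 * shared$sigma_h)),
    m_inf = 1 / (1 + exp((V - shared$theta_m) / shared$sigma_m)),
    n_inf = 1 / (1 + exp((V - shared$theta_n) / shared$sigma_n)))
}

#' Unit output sigmoid
#'
#' Nonlinear filtering of a unit's voltage into its (synaptic) output,
#' `f_out(V) = 1/(1 + exp((V - theta_out)/sigma_out))`; `sigma_out < 0`
#' for every unit, so output increases with V and is 0.5 at
#' `theta_out`.
#'
#' @param unit a [unit_params()] object
#' @param V membrane potential (mV), vectorized
#' @return dimensionless output in (0,1)
#' @export
f_out <- function(unit, V) {
  1 / (1 + exp((V - unit$theta_out) / unit$sigma_out))
}

#' Intrinsic membrane currents of one unit
#'
#' Persistent sodium `I_NaP = g_NaP m_inf(V) h (V - E_Na)`; potassium
#' `I_K = g_K n_inf(V)^4 (V - E_K)` for excitatory units (weak delayed
#' rectifier, no extra state) or `I_K = g_K p (V - E_K)` for inhibitory
#' units (adaptation current); leak `I_L = g_L (V - E_L)`.
#'
#' @param unit a [unit_params()] object
#' @param V membrane potential (mV)
#' @param h persistent sodium inactivation (dimensionless)
#' @param p adaptation gating (dimensionless; ignored for excitatory
#'   units)
#' @param shared a [shared_params()] object
#' @return named numeric vector `c(I_NaP, I_K, I_L)` in pA
#' @export
intrinsic_currents <- function(unit, V, h, p = NA_real_,
                               shared = shared_params()) {
  I_NaP <- unit$g_NaP * gating("m_inf", V, shared) * h * (V - shared$E_Na)
  I_K <- if (unit$excitatory) {
    unit$g_K * gating("n_inf", V, shared)^4 * (V - shared$E_K)
  } else {
    unit$g_K * p * (V - shared$E_K)
  }
  I_L <- unit$g_L * (V - unit$E_L)
  c(I_NaP = I_NaP, I_K = I_K, I_L = I_L)
}

#' Synaptic input sums and currents for one unit
#'
#' The total weighted inhibition `inh_sum = inh0_i + sum_j b[j,i]
#' f_out(V_j)` over inhibitory presynaptic units (this dimensionless
#' sum is the "level of inhibition" used throughout the phase-plane
#' analysis), the excitatory sum `exc_sum = sum_j a[j,i] f_out(V_j) +
#' c1_i + c2_i`, and the corresponding currents
#' `I_synI = g_synI (V_i - E_synI) inh_sum`,
#' `I_synE = g_synE (V_i - E_synE) exc_sum`.
#'
#' @param config a [network_config()]
#' @param state packed state vector (see [pack_state()])
#' @param i unit index or name
#' @return list with `inh_sum`, `exc_sum` (dimensionless) and `I_synI`,
#'   `I_synE` (pA)
#' @export
synaptic_inputs <- function(config, state, i) {
  i <- unit_index(config, i)
  st <- unpack_state(config, state)
  exc <- unit_is_exc(config)
  fo <- vapply(seq_along(config$units),
               function(j) f_out(config$units[[j]], st$V[j]), numeric(1))
  inh_sum <- config$units[[i]]$inh0 +
    sum(config$b[!exc, i] * fo[!exc])
  exc_sum <- sum(config$a[exc, i] * fo[exc]) + config$c1[i] + config$c2[i]
  s <- config$shared
  list(inh_sum = unname(inh_sum), exc_sum = unname(exc_sum),
       I_synI = unname(s$g_synI * (st$V[i] - s$E_synI) * inh_sum),
       I_synE = unname(s$g_synE * (st$V[i] - s$E_synE) * exc_sum))
}

#' Right-hand side of the network ODE system
#'
#' Reference R implementation of the model vector field:
#' `dV_i/dt = -(I_NaP + I_K + I_L + I_synI + I_synE)/C`,
#' `dh_i/dt = (h_inf(V_i) - h_i)/tau_h(V_i)` for h-carrying units,
#' `dp_i/dt = (d_i f_out(V_i) - p_i)/tau_p_i` for inhibitory units. In
#' quasi-steady h mode the inhibitory-unit h inside `I_NaP` is
#' `h_inf(V_i)`. The system is autonomous; `t` is accepted for solver
#' compatibility only. The compiled equivalent used by the integrator
#' is [cpg_rhs_compiled()].
#'
#' @param config a [network_config()]
#' @param state packed state vector
#' @param t time (ms, unused)
#' @return named derivative vector in the packed layout
#' @export
cpg_rhs <- function(config, state, t = 0) {
  lay <- state_layout(config)
  if (length(state) != lay$n)
    stop("state has length ", length(state), ", expected ", lay$n)
  st <- unpack_state(config, state)
  s <- config$shared
  n <- length(config$units)
  dy <- numeric(lay$n)
  for (i in seq_len(n)) {
    u <- config$units[[i]]
    ic <- intrinsic_currents(u, st$V[i], st$h[i], st$p[i], s)
    sy <- synaptic_inputs(config, state, i)
    dy[lay$V[i]] <- -(sum(ic) + sy$I_synI + sy$I_synE) / s$C
  }
  for (nm in names(lay$h)) {
    i <- unit_index(config, nm)
    dy[lay$h[nm]] <- (gating("h_inf", st$V[i], s) - st$h[i]) /
      gating("tau_h", st$V[i], s)
  }
  for (nm in names(lay$p)) {
    i <- unit_index(config, nm)
    u <- config$units[[i]]
    dy[lay$p[nm]] <- (u$d_adapt * f_out(u, st$V[i]) - st$p[i]) / u$tau_p
  }
  names(dy) <- names(state)
  dy
}

#' Compiled right-hand side evaluation
#'
#' Evaluates the C implementation of the vector field (the one used by
#' [cpg_integrate()]) at a single state, returning the derivative plus
#' the per-unit outputs and synaptic sums.
#'
#' @inheritParams cpg_rhs
#' @return list with `ydot` (derivative in the packed layout), `f_out`,
#'   `inh_sum`, `exc_sum` (per-unit numeric vectors)
#' @export
cpg_rhs_compiled <- function(config, state, t = 0) {
  n <- length(config$units)
  res <- .Call(respcpg_eval, pack_parms(config), as.numeric(state))
  nm <- unit_names(config)
  ydot <- res$ydot
  names(ydot) <- names(state)
  list(ydot = ydot,
       f_out = stats::setNames(res$extra[seq_len(n)], nm),
       inh_sum = stats::setNames(res$extra[n + seq_len(n)], nm),
       exc_sum = stats::setNames(res$extra[2 * n + seq_len(n)], nm))
}
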