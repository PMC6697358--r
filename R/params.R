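#' Shared biophysical parameters
#'
#' Parameters common to all units of the network: membrane capacitance,
#' reversal potentials, the half-activation voltages and slopes of the
#' gating sigmoids, the slow-inactivation time-constant scale `epsilon`,
#' and the synaptic conductance scales. Defaults are the baseline set.
#'
#' Units convention throughout the package: mV, ms, nS, pF, pA
#' (nS * mV = pA and pA / pF = mV/ms).
#'
#' @param C membrane capacitance (pF)
#' @param E_Na,E_K,E_synE,E_synI reversal potentials (mV)
#' @param theta_h,sigma_h half-inactivation and slope of the persistent
#'   sodium inactivation sigmoid `h_inf` (mV); `sigma_h > 0` so `h_inf`
#'   decreases with V
#' @param theta_m,sigma_m persistent sodium activation `m_inf` (mV);
#'   `sigma_m < 0` so `m_inf` increases with V
#' @param theta_n,sigma_n delayed-rectifier activation `n_inf` (mV)
#' @param epsilon time-constant scale of h (ms); `tau_h` peaks at
#'   `epsilon` at `V = theta_h`
#' @param g_synE,g_synI synaptic conductance scales (nS)
#' @return an object of class `cpg_shared`
#' @export
shared_params <- function(C = 20, E_Na = 50, E_K = -85,
                          E_synE = 0, E_synI = -75,
                          theta_h = -48, sigma_h = 8,
                          theta_m = -37, sigma_m = -6,
                          theta_n = -29, sigma_n = -4,
                          epsilon = 4000, g_synE = 10, g_synI = 60) {
  x <- list(C = C, E_Na = E_Na, E_K = E_K, E_synE = E_synE, E_synI = E_synI,
            theta_h = theta_h, sigma_h = sigma_h,
            theta_m = theta_m, sigma_m = sigma_m,
            theta_n = theta_n, sigma_n = sigma_n,
            epsilon = epsilon, g_synE = g_synE, g_synI = g_synI)
  stopifnot(C > 0, epsilon > 0, g_synE >= 0, g_synI >= 0,
            sigma_h > 0, sigma_m < 0, sigma_n < 0)
  structure(x, class = "cpg_shared")
}

#' Per-unit parameters
#'
#' @param name unit name, one of `"pre-I"`, `"early-I"`, `"post-I"`,
#'   `"aug-E"`, `"PiCo"`
#' @param excitatory logical; excitatory units carry a dynamic h state
#'   and a weak delayed-rectifier potassium current, inhibitory units a
#'   strong adaptation current with gating state p
#' @param g_NaP,g_K,g_L maximal conductances (nS)
#' @param E_L leak reversal potential (mV)
#' @param theta_out,sigma_out output sigmoid half-activation and slope
#'   (mV); all `sigma_out < 0` so output increases with V
#' @param tau_p adaptation time constant (ms; inhibitory units only)
#' @param d_adapt adaptation drive coefficient (dimensionless;
#'   inhibitory units only). Not pinned by the baseline list; the
#'   package default is 1 so that p saturates at the output range.
#' @param inh0 constant (frozen) inhibitory input added to the unit's
#'   weighted inhibition sum; 0 in the full network, nonzero only when
#'   treating the inhibition level as a parameter in isolated-unit
#'   analysis
#' @return an object of class `cpg_unit`
#' @export
unit_params <- function(name, excitatory,
                        g_NaP, g_K, g_L, E_L, theta_out, sigma_out,
                        tau_p = NA_real_, d_adapt = NA_real_, inh0 = 0) {
  stopifnot(g_NaP >= 0, g_K >= 0, g_L >= 0, sigma_out < 0)
  if (excitatory) {
    tau_p <- NA_real_; d_adapt <- NA_real_
  } else {
    if (is.na(tau_p)) stop("inhibitory units need tau_p")
    if (is.na(d_adapt)) d_adapt <- 1
    stopifnot(tau_p > 0, d_adapt >= 0)
  }
  structure(list(name = name, excitatory = excitatory,
                 g_NaP = g_NaP, g_K = g_K, g_L = g_L, E_L = E_L,
                 theta_out = theta_out, sigma_out = sigma_out,
                 tau_p = tau_p, d_adapt = d_adapt, inh0 = inh0),
            class = "cpg_unit")
}

#' Network configuration
#'
#' Assembles units, shared parameters, synaptic weight matrices and
#' tonic drives into a complete, validated model configuration.
#'
#' Weight convention: `a[j, i]` (`b[j, i]`) is the excitatory
#' (inhibitory) strength from presynaptic unit j onto postsynaptic unit
#' i; rows of `a` may be nonzero only for excitatory units, rows of `b`
#' only for inhibitory units. Drives `c1 + c2` enter the excitatory sum
#' of each unit; `c1` entries may be negative (arbitrary drive units).
#'
#' @param units list of [unit_params()] objects, in index order
#' @param shared a [shared_params()] object
#' @param a,b n x n weight matrices (presynaptic row, postsynaptic
#'   column)
#' @param c1,c2 numeric drive vectors of length n
#' @param h_mode `"dynamic"` (default; every unit's h is integrated,
#'   as the model equations state) or `"quasi-steady"` (inhibitory h
#'   slaved to `h_inf(V)`, giving the reduced 8-dimensional 4-unit
#'   network; a sensitivity option since g_NaP is small for inhibitory
#'   units)
#' @return an object of class `cpg_config`
#' @export
network_config <- function(units, shared = shared_params(),
                           a, b, c1, c2,
                           h_mode = c("dynamic", "quasi-steady")) {
  h_mode <- match.arg(h_mode)
  n <- length(units)
  stopifnot(n >= 1, n <= 5,
            is.matrix(a), all(dim(a) == n),
            is.matrix(b), all(dim(b) == n),
            length(c1) == n, length(c2) == n)
  exc <- vapply(units, function(u) u$excitatory, logical(1))
  nm <- vapply(units, function(u) u$name, character(1))
  if (any(a[!exc, , drop = FALSE] != 0))
    stop("rows of 'a' must be zero for inhibitory units")
  if (any(b[exc, , drop = FALSE] != 0))
    stop("rows of 'b' must be zero for excitatory units")
  if (any(a < 0) || any(b < 0)) stop("synaptic weights must be >= 0")
  dimnames(a) <- dimnames(b) <- list(nm, nm)
  names(c1) <- names(c2) <- nm
  structure(list(units = units, shared = shared, a = a, b = b,
                 c1 = c1, c2 = c2, h_mode = h_mode),
            class = "cpg_config")
}

#' @export
print.cpg_config <- function(x, ...) {
  nm <- unit_names(x)
  cat("<cpg_config> ", length(nm), " units (", paste(nm, collapse = ", "),
      "), h_mode = ", x$h_mode, ", ", n_states(x), " state variables\n",
      sep = "")
  invisible(x)
}

unit_names <- function(config) {
  vapply(config$units, function(u) u$name, character(1))
}

unit_is_exc <- function(config) {
  vapply(config$units, function(u) u$excitatory, logical(1))
}

#' Resolve a unit index or name
#' @noRd
unit_index <- function(config, unit) {
  nm <- unit_names(config)
  if (is.character(unit)) {
    i <- match(unit, nm)
    if (is.na(i)) stop("unknown unit '", unit, "'; available: ",
                       paste(nm, collapse = ", "))
    return(i)
  }
  unit <- as.integer(unit)
  if (unit < 1L || unit > length(nm))
    stop("unit index out of range 1..", length(nm))
  unit
}

# --- state vector layout -----------------------------------------------

#' State layout of a configuration
#'
#' Returns which state slots hold V, h and p. The state vector is
#' ordered V for all units, then h for every h-carrying unit (all
#' excitatory units; inhibitory units too in dynamic h mode), then p
#' for inhibitory units.
#' @param config a [network_config()]
#' @return list with integer index vectors `V`, `h`, `p` (named by
#'   unit) and `n` total state dimension
#' @export
state_layout <- function(config) {
  n <- length(config$units)
  exc <- unit_is_exc(config)
  has_h <- exc | (config$h_mode == "dynamic")
  nm <- unit_names(config)
  iV <- seq_len(n); names(iV) <- nm
  ih <- n + seq_len(sum(has_h)); names(ih) <- nm[has_h]
  ip <- n + sum(has_h) + seq_len(sum(!exc)); names(ip) <- nm[!exc]
  list(V = iV, h = ih, p = ip, n = n + sum(has_h) + sum(!exc))
}

n_states <- function(config) state_layout(config)$n

#' Build a packed state vector
#'
#' @param config a [network_config()]
#' @param V numeric vector of membrane potentials (mV), length n
#' @param h persistent-sodium inactivation for h-carrying units; a
#'   scalar is recycled
#' @param p adaptation gating for inhibitory units; a scalar is recycled
#' @return named numeric state vector in the packed layout
#' @export
pack_state <- function(config, V, h = 0.6, p = 0.1) {
  lay <- state_layout(config)
  y <- numeric(lay$n)
  stopifnot(length(V) == length(lay$V))
  y[lay$V] <- V
  y[lay$h] <- rep_len(h, length(lay$h))
  y[lay$p] <- rep_len(p, length(lay$p))
  pre <- function(w, idx) if (length(idx)) paste0(w, names(idx)) else character(0)
  names(y) <- c(pre("V_", lay$V), pre("h_", lay$h), pre("p_", lay$p))
  y
}

#' Unpack a state vector into per-unit V, h, p
#'
#' Quasi-steady inhibitory h values are filled in as `h_inf(V)`.
#' @param config a [network_config()]
#' @param y packed state vector
#' @return list with numeric vectors `V`, `h`, `p` (p is NA for
#'   excitatory units)
#' @export
unpack_state <- function(config, y) {
  lay <- state_layout(config)
  if (length(y) != lay$n)
    stop("state has length ", length(y), ", expected ", lay$n)
  nm <- unit_names(config)
  V <- y[lay$V]; names(V) <- nm
  h <- gating("h_inf", V, config$shared)
  h[names(lay$h)] <- y[lay$h]
  p <- rep(NA_real_, length(nm)); names(p) <- nm
  p[names(lay$p)] <- y[lay$p]
  list(V = V, h = h, p = p)
}

# --- packed parameter vector (kept in sync with src/respcpg.c) ---------

#' Pack a configuration into the flat parameter vector used by the
#' compiled right-hand side
#' @param config a [network_config()]
#' @return numeric vector of length 126
#' @export
pack_parms <- function(config) {
  s <- config$shared
  n <- length(config$units)
  p <- numeric(126)
  p[1] <- n
  p[2] <- as.integer(config$h_mode == "dynamic")
  p[3:16] <- c(s$C, s$E_Na, s$E_K, s$E_synE, s$E_synI,
               s$theta_h, s$sigma_h, s$theta_m, s$sigma_m,
               s$theta_n, s$sigma_n, s$epsilon, s$g_synE, s$g_synI)
  for (u in seq_len(n)) {
    up <- config$units[[u]]
    o <- 16 + 10 * (u - 1)
    p[o + 1:10] <- c(as.integer(up$excitatory), up$g_NaP, up$g_K, up$g_L,
                     up$E_L, up$theta_out, up$sigma_out,
                     ifelse(is.na(up$tau_p), 1, up$tau_p),
                     ifelse(is.na(up$d_adapt), 0, up$d_adapt),
                     up$inh0)
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    p[66 + 5 * (i - 1) + j] <- config$a[j, i]
    p[91 + 5 * (i - 1) + j] <- config$b[j, i]
  }
  p[116 + seq_len(n)] <- config$c1
  p[121 + seq_len(n)] <- config$c2
  p
}
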