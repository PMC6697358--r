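# Network-level analysis pipelines: isolated-vs-embedded comparison,
# the (g_NaP, c11) grid sweep with transition-curve overlay, drive and
# inhibition-weight sweeps, inhibition-block protocols, and the PiCo
# suite.  Sweeps warm-start each point from the previous point's final
# state to stay on the same attractor branch.

set_param <- function(config, param, value) {
  nm <- unit_names(config)
  idx <- function(u) unit_index(config, u)
  switch(param,
    c11 = { config$c1[idx("pre-I")] <- value },
    c12 = { config$c1[idx("early-I")] <- value },
    c13 = { config$c1[idx("post-I")] <- value },
    c14 = { config$c1[idx("aug-E")] <- value },
    c15 = { config$c1[idx("PiCo")] <- value },
    b31 = { config$b[idx("post-I"), idx("pre-I")] <- value },
    a53 = { config$a[idx("PiCo"), idx("post-I")] <- value },
    g_NaP_exc = { config$units[[idx("pre-I")]]$g_NaP <- value },
    stop("unknown parameter '", param, "'"))
  config
}

get_param <- function(config, param) {
  idx <- function(u) unit_index(config, u)
  switch(param,
    c11 = config$c1[[idx("pre-I")]],
    c12 = config$c1[[idx("early-I")]],
    c13 = config$c1[[idx("post-I")]],
    c14 = config$c1[[idx("aug-E")]],
    c15 = config$c1[[idx("PiCo")]],
    b31 = config$b[idx("post-I"), idx("pre-I")],
    a53 = config$a[idx("PiCo"), idx("post-I")],
    g_NaP_exc = config$units[[idx("pre-I")]]$g_NaP,
    stop("unknown parameter '", param, "'"))
}

# run one configuration, warm-started; returns metrics + final state
run_point <- function(config, opts, state0) {
  m <- network_metrics(config, opts, state0)
  tr <- attr(m, "trace")
  list(metrics = m, state = tr$state_final, trace = tr)
}

#' Isolated versus embedded pre-I oscillation properties
#'
#' For each tunable pre-I drive value: period and amplitude of the
#' isolated planar pre-I subsystem, and of the pre-I unit embedded in
#' the full network. Non-rhythmic points carry NA metrics and their
#' regime label. The two columns differ in both their oscillatory
#' ranges and their period/amplitude values — the masking phenomenon.
#'
#' @param c11 drive grid
#' @param config base network (default the baseline 4-unit net)
#' @param opts solver options
#' @return data frame: c11, isolated_regime, isolated_T, isolated_amp,
#'   embedded_regime, embedded_T, embedded_amp
#' @export
compare_isolated_embedded <- function(c11 = seq(-0.065, 0.015, by = 0.005),
                                      config = preset("baseline4"),
                                      opts = solver_options()) {
  iso_opts <- solver_options(window = 60e3)
  state <- NULL
  rows <- lapply(c11, function(cc) {
    icfg <- isolated_config("pre-I", from = config,
                            exc_sum = cc + config$c2[[1]])
    itr <- find_attractor(icfg, iso_opts)
    im <- compute_metrics(itr)
    ecfg <- set_param(config, "c11", cc)
    r <- run_point(ecfg, opts, state)
    state <<- r$state
    em <- r$metrics
    data.frame(c11 = cc,
               isolated_regime = im$regime, isolated_T = im$T,
               isolated_amp = im$amplitude,
               embedded_regime = em$regime, embedded_T = em$T,
               embedded_amp = em$amplitude)
  })
  do.call(rbind, rows)
}

#' Grid sweep over (g_NaP, c11)
#'
#' Computes rhythm metrics of the full network over a rectangular
#' (g_NaP,exc, c11) grid, together with each point's isolated pre-I
#' regime label, and (optionally) the oscillatory-to-tonic transition
#' curve overlay. For each drive column the conductance is swept
#' downward with warm starts, so the rhythmic branch is followed into
#' the region where it coexists with a non-rhythmic steady state.
#'
#' @param g_NaP conductance grid (nS); swept in decreasing order
#' @param c11 drive grid
#' @param config base network
#' @param opts solver options
#' @param isolated_labels also classify the isolated pre-I unit at
#'   every grid point
#' @param transition_curve also compute the transition-curve overlay
#' @return list of class `cpg_sweep`: `grid` (data frame: g_NaP, c11,
#'   T, T_I, T_E, amplitude, regime, three_phase_valid,
#'   isolated_regime), `transition` (or NULL)
#' @export
grid_sweep <- function(g_NaP = seq(4.1, 1.7, by = -0.1),
                       c11 = seq(-0.006, 0.004, by = 0.002),
                       config = preset("baseline4"),
                       opts = solver_options(),
                       isolated_labels = TRUE,
                       transition_curve = FALSE) {
  g_NaP <- sort(g_NaP, decreasing = TRUE)
  rows <- list()
  for (cc in c11) {
    state <- NULL
    for (g in g_NaP) {
      cfg <- set_param(set_param(config, "c11", cc), "g_NaP_exc", g)
      r <- run_point(cfg, opts, state)
      state <- r$state
      m <- r$metrics
      iso <- if (isolated_labels) {
        u <- cfg$units[[unit_index(cfg, "pre-I")]]
        isolated_regime(u, cfg$shared, cc,
                        exc_offset = cfg$c2[[unit_index(cfg, "pre-I")]])
      } else NA_character_
      rows[[length(rows) + 1]] <- data.frame(
        g_NaP = g, c11 = cc, T = m$T, T_I = m$T_I, T_E = m$T_E,
        amplitude = m$amplitude, regime = m$regime,
        three_phase_valid = m$three_phase_valid, isolated_regime = iso)
    }
  }
  grid <- do.call(rbind, rows)
  tc <- if (transition_curve) {
    u <- config$units[[unit_index(config, "pre-I")]]
    continue_transition_curve(u, config$shared,
                              g_NaP = sort(unique(g_NaP), decreasing = TRUE),
                              exc_offset = config$c2[[1]])
  } else NULL
  structure(list(grid = grid, transition = tc), class = "cpg_sweep")
}

#' One-parameter drive / weight sweep
#'
#' Rhythm metrics as one drive or synaptic parameter varies, all
#' others at baseline, warm-starting along the sweep. The
#' rhythm-preserving range endpoints are located by bisection when
#' `find_range = TRUE`.
#'
#' @param param one of `"c11"`, `"c12"`, `"c13"`, `"c14"`, `"c15"`,
#'   `"b31"`, `"a53"`
#' @param values parameter grid (absolute values)
#' @param config base network
#' @param opts solver options
#' @param find_range locate the rhythm-preserving endpoints by
#'   bisection (to `range_tol`)
#' @param range_tol bisection tolerance on the parameter
#' @return data frame of per-value metrics (attribute
#'   `rhythmic_range` when requested)
#' @export
drive_sweep <- function(param, values, config = preset("baseline4"),
                        opts = solver_options(), find_range = FALSE,
                        range_tol = NULL) {
  state <- NULL
  rows <- lapply(values, function(v) {
    cfg <- set_param(config, param, v)
    r <- run_point(cfg, opts, state)
    state <<- r$state
    m <- r$metrics
    data.frame(value = v, T = m$T, T_I = m$T_I, T_E = m$T_E,
               amplitude = m$amplitude, regime = m$regime,
               three_phase_valid = m$three_phase_valid)
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- param
  if (find_range) {
    if (is.null(range_tol)) range_tol <- diff(range(values)) / 1000
    ok <- out$regime == "rhythmic" & !is.na(out$three_phase_valid) &
      out$three_phase_valid
    rng <- c(NA_real_, NA_real_)
    if (any(ok)) {
      i1 <- which(ok)[1]; i2 <- rev(which(ok))[1]
      is_rhy <- function(v, st) {
        cfg <- set_param(config, param, v)
        m <- run_point(cfg, opts, st)$metrics
        m$regime == "rhythmic" && isTRUE(m$three_phase_valid)
      }
      bisect <- function(lo, hi, st) {
        # lo rhythmic XOR hi rhythmic assumed
        lo_r <- is_rhy(lo, st)
        while (abs(hi - lo) > range_tol) {
          mid <- (lo + hi) / 2
          if (is_rhy(mid, st) == lo_r) lo <- mid else hi <- mid
        }
        (lo + hi) / 2
      }
      rng[1] <- if (i1 == 1) values[1] else
        bisect(values[i1], values[i1 - 1], NULL)
      rng[2] <- if (i2 == length(values)) values[length(values)] else
        bisect(values[i2], values[i2 + 1], NULL)
    }
    attr(out, "rhythmic_range") <- sort(rng)
  }
  out
}

#' Inhibition-block protocol
#'
#' Scales the inhibitory weights onto a target group by a common
#' factor kappa, emulating postsynaptic blockade of inhibition:
#' `"preBotC"` scales all inhibitory inputs onto the pre-I and early-I
#' units (b31, b41, b32, b42), `"BotC"` those onto the post-I and
#' aug-E units (b23, b43, b24, b34). Tonic drives are never scaled.
#' kappa = 1 reproduces the baseline exactly.
#'
#' @param config base network
#' @param target `"preBotC"` or `"BotC"`
#' @param kappa scale factor in (0, 1]
#' @return modified [network_config()]
#' @export
apply_block <- function(config, target = c("preBotC", "BotC"), kappa) {
  target <- match.arg(target)
  stopifnot(kappa > 0, kappa <= 1)
  post <- if (target == "preBotC") c("pre-I", "early-I") else
    c("post-I", "aug-E")
  for (u in post) {
    i <- unit_index(config, u)
    config$b[, i] <- config$b[, i] * kappa
  }
  config
}

#' Inhibition-block sweep and loss-of-rhythm boundary
#'
#' Sweeps the block factor kappa downward from 1 with warm starts,
#' reporting per-kappa metrics (period and amplitude also relative to
#' baseline), and locates the smallest rhythm-preserving kappa by
#' bisection to 0.5% precision.
#'
#' @param config base network
#' @param target `"preBotC"` or `"BotC"`
#' @param kappa decreasing grid in (0, 1]
#' @param opts solver options
#' @param tol bisection precision on kappa
#' @return list of class `cpg_block`: `sweep` (data frame with kappa,
#'   metrics, T_rel, amp_rel), `kappa_star` (loss boundary), and
#'   `at_boundary` (metrics at the smallest rhythm-preserving kappa)
#' @export
inhibition_block <- function(config = preset("baseline4"),
                             target = c("preBotC", "BotC"),
                             kappa = seq(1, 0.3, by = -0.05),
                             opts = solver_options(), tol = 0.005) {
  target <- match.arg(target)
  kappa <- sort(kappa, decreasing = TRUE)
  stopifnot(kappa[1] == 1)
  state <- NULL
  states <- list()
  rows <- lapply(kappa, function(k) {
    cfg <- apply_block(config, target, k)
    r <- run_point(cfg, opts, state)
    state <<- r$state
    states[[as.character(k)]] <<- r$state
    m <- r$metrics
    data.frame(kappa = k, T = m$T, T_I = m$T_I, T_E = m$T_E,
               amplitude = m$amplitude, regime = m$regime,
               three_phase_valid = m$three_phase_valid)
  })
  sweep <- do.call(rbind, rows)
  base <- sweep[1, ]
  sweep$T_rel <- sweep$T / base$T
  sweep$amp_rel <- sweep$amplitude / base$amplitude
  # "oscillation is lost" is literal loss of the oscillation (the
  # network settles to a steady state), not an order violation; the
  # three-phase flag is still reported per kappa
  rhy <- sweep$regime == "rhythmic"
  kappa_star <- NA_real_
  if (all(rhy)) {
    kappa_star <- min(kappa)   # rhythm persists over the whole grid
  } else if (any(rhy)) {
    i <- which(!rhy)[1]        # first loss along the downward sweep
    lo <- sweep$kappa[i]; hi <- sweep$kappa[i - 1]
    st <- states[[as.character(hi)]]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      cfg <- apply_block(config, target, mid)
      r <- run_point(cfg, opts, st)
      if (r$metrics$regime == "rhythmic") {
        hi <- mid
        st <- r$state
      } else lo <- mid
    }
    kappa_star <- hi
  }
  at_boundary <- if (!is.na(kappa_star)) {
    cfg <- apply_block(config, target, kappa_star)
    r <- run_point(cfg, opts, states[[as.character(
      sweep$kappa[max(which(rhy))])]])
    m <- r$metrics
    data.frame(kappa = kappa_star, T = m$T, amplitude = m$amplitude,
               T_rel = m$T / base$T, amp_rel = m$amplitude / base$amplitude)
  } else NULL
  structure(list(sweep = sweep, kappa_star = kappa_star,
                 at_boundary = at_boundary, target = target),
            class = "cpg_block")
}

#' PiCo suite
#'
#' The analyses around the optional excitatory post-inspiratory
#' complex unit: the PiCo-to-post-I drive (a53) sweep, the PiCo tonic
#' drive (c15) sweep with the PiCo's intrinsic regime interval, the
#' post-I drive (c13) sweep with and without PiCo, and slow-plane
#' (inhibition, h) projections of the pre-I trajectory at a53 = 0
#' versus 0.4.
#'
#' @param config 5-unit base network (default `preset("baseline5_pico")`)
#' @param a53,c15,c13 sweep grids (absolute values); any may be NULL
#'   to skip
#' @param opts solver options
#' @param projections compute the (inh, h) projections at a53 = 0 and
#'   0.4
#' @return list with elements `a53`, `c15` (+ attribute
#'   `pico_interval`), `c13_with_pico`, `c13_without_pico`,
#'   `projections`
#' @export
pico_suite <- function(config = preset("baseline5_pico"),
                       a53 = seq(0, 0.4, by = 0.05),
                       c15 = seq(0, 0.12, by = 0.01),
                       c13 = seq(0.38, 0.68, by = 0.02),
                       opts = solver_options(), projections = FALSE) {
  stopifnot("PiCo" %in% unit_names(config))
  out <- list()
  if (!is.null(a53))
    out$a53 <- drive_sweep("a53", a53, config, opts)
  if (!is.null(c15)) {
    out$c15 <- drive_sweep("c15", c15, config, opts)
    u <- config$units[[unit_index(config, "PiCo")]]
    attr(out$c15, "pico_interval") <- oscillation_boundaries(
      u, config$shared, exc_offset = config$c2[[unit_index(config, "PiCo")]],
      scan = seq(-0.02, 0.12, by = 0.01))
  }
  if (!is.null(c13)) {
    out$c13_with_pico <- drive_sweep("c13", c13, config, opts,
                                     find_range = TRUE)
    cfg4 <- preset("baseline4", c11 = get_param(config, "c11"))
    out$c13_without_pico <- drive_sweep("c13", c13, cfg4, opts,
                                        find_range = TRUE)
  }
  if (projections) {
    u1 <- config$units[[unit_index(config, "pre-I")]]
    kn <- knee_curve(u1, config$shared,
                     exc_sum = get_param(config, "c11") + config$c2[[1]])
    out$projections <- lapply(c(0, 0.4), function(v) {
      cfg <- set_param(config, "a53", v)
      tr <- find_attractor(cfg, opts)
      project_escape(tr, "pre-I", kn)
    })
    names(out$projections) <- c("a53_0", "a53_0.4")
  }
  out
}
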