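# Heavy shared computations (attractor traces, boundary bisections)
# are computed once per test run and reused across files.

.respcpg_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .respcpg_cache))
    assign(key, expr, envir = .respcpg_cache)
  get(key, envir = .respcpg_cache)
}

osc_attractor <- function() cached("osc", find_attractor(preset("oscillatory")))
tonic_attractor <- function() cached("tonic", find_attractor(preset("tonic")))

pre_I_unit <- function() preset("baseline4")$units[[1]]

osc_boundaries <- function()
  cached("bounds", oscillation_boundaries(pre_I_unit()))

# knee curves at the two standard pre-I tunings (frozen excitation
# c11 + c21)
osc_knees <- function()
  cached("knees_osc", knee_curve(pre_I_unit(), shared_params(),
                                 exc_sum = -0.03 + 0.095))
tonic_knees <- function()
  cached("knees_tonic", knee_curve(pre_I_unit(), shared_params(),
                                   exc_sum = 0.01 + 0.095))

# a small synthetic trace built by hand (no integration)
fake_trace <- function(t, V1, config = isolated_config("pre-I"),
                       attractor = "periodic") {
  V <- matrix(V1, ncol = 1, dimnames = list(NULL, "pre-I"))
  fo <- matrix(f_out(config$units[[1]], V1), ncol = 1,
               dimnames = list(NULL, "pre-I"))
  h <- matrix(0.5, length(t), 1, dimnames = list(NULL, "pre-I"))
  structure(list(t = t, V = V, h = h,
                 p = matrix(NA_real_, length(t), 1,
                            dimnames = list(NULL, "pre-I")),
                 f_out = fo, inh_sum = fo * 0, exc_sum = fo * 0,
                 config = config, opts = solver_options()),
            class = "cpg_trace", attractor = attractor)
}
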