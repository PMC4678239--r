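# Shared fixtures, built in code.

demo_steady <- build_demo_steady()
demo_osc <- build_demo_oscillator()

# Minimal 3-reaction cascade used for brute-force oracle checks:
# stimulus converts A to B, B converts to C, C decays.
toy_model <- function() {
  kinetic_model(
    "toy",
    initial_state = c(A = 10, B = 0, C = 0),
    reactions = list(
      list(id = "r1", k = 1e-3, reactants = c(A = 1),
           stoich = c(A = -1, B = 1), stim = 1),
      list(id = "r2", k = 2e-3, reactants = c(B = 1),
           stoich = c(B = -1, C = 1)),
      list(id = "r3", k = 1e-3, reactants = c(C = 1),
           stoich = c(C = -1))
    ),
    stimulus = 1, stimulus_name = "u",
    output_names = c("B", "C"), default_horizon_h = 2
  )
}

# Trajectory holding an arbitrary matrix of values (for noise statistics
# and analytic-series tests).
make_traj <- function(times, values, outputs = "y") {
  kinfault:::new_trajectory(times, as.matrix(values), outputs)
}

# Analytic sinusoid c + a*sin(2*pi*t/period_h) sampled on [0, horizon].
sinusoid_traj <- function(c0 = 10, a = 3, period_h = 2, horizon_h = 15,
                          density = 600) {
  t <- sample_times(sampling_spec(horizon_h, density))
  make_traj(t, c0 + a * sin(2 * pi * t / period_h))
}

# Moiety totals: transcription-factor conservation sums for the demos.
stat_moiety <- function(vals)
  vals[, "STAT3c"] + vals[, "STAT3p"] + 2 * vals[, "DimC"] + 2 * vals[, "DimN"]
nfkb_moiety <- function(vals)
  vals[, "NIc"] + vals[, "NFkBc"] + vals[, "NFkBn"]
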