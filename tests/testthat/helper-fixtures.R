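# Shared helpers for the test suite.

# Final premalignant count of a trajectory.
final_m <- function(traj) traj$m[nrow(traj)]

# A cheap custom parameter set for structural tests.
tiny_params <- function(...) {
  organ_params("custom", lam = 0.4, r = 0.8, N = 1e6, alpha_R = 0.2,
               gamma_R = 1e-6, alpha_C = 0.2, gamma_C = 1e-7,
               alpha_d = 0.1333, g = 1, ...)
}
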