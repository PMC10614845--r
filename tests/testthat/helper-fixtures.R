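# Shared fixture builders: everything is generated in code at test time.

uniform_atlas <- function(nr = 8, nc = nr, glucose = 2.0, oxygen = 0.2,
                          stiffness = 2000) {
  synthetic_atlases(c(nr, nc), seed = 1, preset = "uniform",
                    config = list(glucose = glucose, oxygen = oxygen,
                                  stiffness = stiffness))
}

single_clone <- function(label = "c", gamma_i = NULL) {
  clone_params(label, ploidy = 2, beta_d_i = 1.0, beta_g_i = 2.9,
               a_mig = 0.53, b_mig = 0.57, gamma_i = gamma_i)
}

center_seed_map <- function(nr, nc, cells) {
  m <- matrix(0, nr, nc)
  m[ceiling(nr / 2), ceiling(nc / 2)] <- cells
  m
}

# Single-voxel unlimited-resource configuration: saturating kinetics are
# switched off so growth is pure logistic.
logistic_cfg <- function(n0 = 100, duration = 100, dt = 0.05) {
  p <- sim_params(alpha_g = 0, alpha_d = 0, iota_o = 0, iota_g = 0,
                  iota_g2 = 0, p0 = 0, dt = dt)
  atl <- uniform_atlas(1, 1)
  run_config(p, list(single_clone()), atl, list(c = matrix(n0, 1, 1)),
             duration = duration, dt = dt, seed = 1)
}

premalignant_clone_pair <- function() {
  fitted <- fitted_patient_clones()
  list(extrapolate_clone_params(fitted$low, fitted$high, 2, label = "2N"),
       extrapolate_clone_params(fitted$low, fitted$high, 4, label = "4N"))
}
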