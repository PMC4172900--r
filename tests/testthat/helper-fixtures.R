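# Shared fixtures, built in code.

# Exponential two-group survival data with a planted hazard ratio.
make_two_group <- function(n_per_group, hr, base_hazard = 0.5,
                           censor_max = Inf, seed = 1) {
  set.seed(seed)
  z <- rep(c(0L, 1L), each = n_per_group)
  t_ev <- rexp(2 * n_per_group, base_hazard * ifelse(z == 1, hr, 1))
  if (is.finite(censor_max)) {
    t_c <- runif(2 * n_per_group, 0, censor_max)
    data.frame(time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c),
               z = z)
  } else {
    data.frame(time = t_ev, event = 1L, z = z)
  }
}

# A small cohort with survival columns for tree tests.
make_test_cohort <- function(n = 60, seed = 1) {
  cfg <- sim_config(n_patients = n, seed = seed)
  make_cohort(cfg)
}
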