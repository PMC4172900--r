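test_that("endpoint construction converts dates at 365.25 days/year", {
  r <- build_endpoint("2010-01-01", "2010-01-01", "2012-01-01", "OS")
  expect_equal(r$time, 0)
  expect_equal(r$event, 1L)
  r <- build_endpoint("2010-01-01", "2011-01-01", NA, "OS")
  expect_equal(r$time, 365 / 365.25)
  expect_equal(r$event, 1L)
  r <- build_endpoint("2010-01-01", NA, "2012-01-01", "PFS")
  expect_equal(r$time, 730 / 365.25)
  expect_equal(r$event, 0L)
  expect_error(build_endpoint("2010-06-01", "2010-01-01", NA, "OS"),
               "precedes baseline")
})

test_that("incidence rates use the truncating display convention", {
  r <- incidence_rate(events = 16, person_years = 45)
  expect_equal(r$rate_display, 35)
  expect_equal(r$rate_per_100py, 100 * 16 / 45)
  r <- incidence_rate(events = 17, person_years = 29)
  expect_equal(r$rate_display, 58)
  r <- incidence_rate(events = c(0, 0, 0), times = c(1, 2, 3))
  expect_equal(r$rate_per_100py, 0)
  expect_error(incidence_rate(events = 1, person_years = 0), "positive")
  # scale covariance: times scaled by c divide the rate by c
  ev <- c(1, 0, 1, 1)
  tm <- c(2, 3, 1, 4)
  r1 <- incidence_rate(ev, tm)
  r2 <- incidence_rate(ev, 2 * tm)
  expect_equal(r2$rate_per_100py, r1$rate_per_100py / 2)
})

test_that("Cox fit is symmetric, invariant, and matches coxph", {
  # identical event patterns in the two groups: beta = 0 by symmetry
  t0 <- c(1, 2, 3, 1, 2, 3)
  e0 <- c(1, 1, 0, 1, 1, 0)
  z0 <- c(0, 0, 0, 1, 1, 1)
  f <- fit_cox(t0, e0, cbind(z = z0))
  expect_lt(abs(f$coefficients), 1e-6)
  expect_equal(unname(f$hr), 1, tolerance = 1e-5)
  # translation and scaling invariances of the coefficient
  set.seed(8)
  n <- 50
  x <- rnorm(n)
  tt <- rexp(n, exp(0.5 * x))
  ee <- rbinom(n, 1, 0.8)
  b0 <- fit_cox(tt, ee, cbind(x = x))$coefficients
  b_shift <- fit_cox(tt, ee, cbind(x = x + 10))$coefficients
  b_scale <- fit_cox(tt, ee, cbind(x = 3 * x))$coefficients
  expect_lt(abs(b0 - b_shift), 1e-8)
  expect_lt(abs(b0 - 3 * b_scale), 1e-8)
  skip_if_not_installed("survival")
  # dual route: independent reference fit, with ties present
  set.seed(9)
  for (i in 1:10) {
    m <- 40
    X <- cbind(a = rnorm(m), b = rbinom(m, 1, 0.5))
    t2 <- ceiling(rexp(m, exp(0.4 * X[, 1])) * 4) / 4 # tied times
    e2 <- rbinom(m, 1, 0.8)
    if (sum(e2) < 3) next
    mine <- fit_cox(t2, e2, X)
    ref <- survival::coxph(survival::Surv(t2, e2) ~ X,
                           ties = "breslow")
    expect_equal(unname(mine$coefficients), unname(coef(ref)),
                 tolerance = 1e-6)
    expect_equal(unname(mine$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-6)
    expect_equal(mine$loglik, ref$loglik[2], tolerance = 1e-8)
  }
})

test_that("six-subject fit matches a brute-force grid search", {
  tt <- 1:6
  ee <- rep(1L, 6)
  grid <- seq(-5, 5, by = 1e-4)
  grid_max <- function(zz) {
    ll <- vapply(grid, function(b) {
      s <- 0
      for (k in 1:6) {
        rs <- k:6
        s <- s + b * zz[k] - log(sum(exp(b * zz[rs])))
      }
      s
    }, numeric(1))
    grid[which.max(ll)]
  }
  zz <- c(0, 1, 0, 1, 1, 0) # interleaved groups: finite maximum
  f <- fit_cox(tt, ee, cbind(z = zz))
  expect_true(f$converged)
  expect_lt(abs(unname(f$coefficients) - grid_max(zz)), 1e-3)
  # perfectly ordered groups separate the risk sets: the partial
  # likelihood is monotone and the fit must say so rather than agree
  # with a clamped grid
  f2 <- fit_cox(tt, ee, cbind(z = c(0, 0, 0, 1, 1, 1)))
  expect_false(f2$converged)
  expect_true(f2$monotone)
})

test_that("Cox fitter matches grid-search oracle on random small data", {
  oc <- run_cox_oracle_check(n_datasets = 50, seed = 5)
  expect_lt(oc$max_abs_error, 1e-3)
})

test_that("a planted hazard ratio of 3 is recovered at n = 2000", {
  d <- make_two_group(1000, hr = 3, base_hazard = 0.5, censor_max = 6.5,
                      seed = 10)
  expect_gt(mean(1 - d$event), 0.1) # some censoring present
  f <- fit_cox(d$time, d$event, cbind(z = d$z))
  expect_gt(unname(f$hr), 2.7)
  expect_lt(unname(f$hr), 3.3)
})

test_that("monotone likelihood is flagged, not reported as a huge HR", {
  tt <- c(1, 2, 3, 4, 5, 6)
  ee <- rep(1L, 6)
  zz <- -tt # later failure times have smaller covariate: perfect ordering
  f <- fit_cox(tt, ee, cbind(z = zz))
  expect_false(f$converged)
  expect_true(f$monotone)
})

test_that("class survivor functions start at 1, decrease, and order by
           hazard", {
  d <- make_two_group(400, hr = 5, base_hazard = 0.4, seed = 11)
  curves <- class_survival_curves(d$time, d$event,
                                  factor(d$z, labels = c("ref", "high")),
                                  reference = "ref")
  for (cl in unique(curves$class)) {
    s <- curves$survival[curves$class == cl]
    expect_equal(s[1], 1)
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
  wide <- split(curves$survival, curves$class)
  expect_true(all(wide$high <= wide$ref + 1e-12))
  # single class: Breslow baseline exp(-sum d/n_at_risk)
  one <- class_survival_curves(d$time[1:50], d$event[1:50],
                               rep("all", 50))
  ts <- sort(d$time[1:50])
  es <- d$event[1:50][order(d$time[1:50])]
  ev_t <- unique(ts[es == 1])
  km_breslow <- exp(-cumsum(vapply(ev_t, function(u) {
    sum(ts == u & es == 1) / sum(ts >= u)
  }, numeric(1))))
  expect_equal(one$survival, c(1, km_breslow), tolerance = 1e-10)
})
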