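test_that("candidate enumeration respects admissibility", {
  ev6 <- rep(1L, 6)
  # constant covariate: nothing to split
  expect_equal(nrow(candidate_splits(rep(2, 6), ev6)), 0)
  # only the 3|3 cut passes the >=3-per-side constraint
  cs <- candidate_splits(c(0.1, 0.2, 0.4, 0.8, 1.0, 1.2), ev6)
  expect_equal(nrow(cs), 1)
  expect_equal(cs$threshold, 0.6)
  expect_equal(cs$left_n, 3)
  expect_equal(cs$right_n, 3)
  # binary covariate: at most one candidate
  expect_lte(nrow(candidate_splits(rep(c(0, 1), 5), rep(1L, 10))), 1)
  # categorical: 3 levels admit at most 3 two-set partitions
  x <- factor(rep(c("a", "b", "c"), each = 4))
  cs3 <- candidate_splits(x, rep(1L, 12))
  expect_lte(nrow(cs3), 3)
  expect_true(all(cs3$left_n + cs3$right_n == 12))
})

test_that("split statistic is zero for identical groups and chi-square
           calibrated under the null", {
  # two groups with identical event patterns
  tt <- rep(c(1, 2, 3, 4), 2)
  ee <- rep(c(1, 1, 1, 0), 2)
  xx <- rep(c(0, 1), each = 4)
  r <- evaluate_split(tt, ee, xx, threshold = 0.5)
  expect_lt(abs(r$statistic), 1e-8)
  expect_equal(r$hr, 1, tolerance = 1e-4)
  # null calibration: LR statistic of a fixed admissible split ~ chi2(1)
  set.seed(20)
  stats <- vapply(1:1000, function(i) {
    n <- 40
    t2 <- rexp(n, 0.5)
    e2 <- rbinom(n, 1, 0.8)
    x2 <- rnorm(n)
    if (sum(e2[x2 <= 0]) < 1 || sum(e2[x2 > 0]) < 1) return(NA_real_)
    evaluate_split(t2, e2, x2, threshold = 0)$statistic
  }, numeric(1))
  m <- mean(stats, na.rm = TRUE)
  expect_gt(m, 0.85)
  expect_lt(m, 1.15)
})

test_that("a planted strong split is detected with high power", {
  d <- make_two_group(100, hr = 5, base_hazard = 0.5, seed = 30)
  r <- evaluate_split(d$time, d$event, d$z, threshold = 0.5)
  expect_gt(r$statistic, qchisq(0.999, 1))
})

test_that("variable selection returns the only candidate, is
           deterministic, and prefers the planted signal", {
  d <- make_two_group(30, hr = 4, base_hazard = 0.5, seed = 40)
  one <- select_split_variable(d$time, d$event,
                               data.frame(g = d$z + rnorm(60, 0, 1e-6)),
                               n_permutations = 99, seed = 3)
  expect_equal(one$covariate, "g")
  again <- select_split_variable(d$time, d$event,
                                 data.frame(g = d$z + rnorm(60, 0, 1e-6)),
                                 n_permutations = 99, seed = 3)
  expect_identical(one[c("covariate", "perm_p", "global_p")],
                   again[c("covariate", "perm_p", "global_p")])
  # planted threshold effect against three noise covariates
  set.seed(41)
  picks <- vapply(1:200, function(i) {
    n <- 200
    X <- data.frame(sig = exp(rnorm(n)), n1 = exp(rnorm(n)),
                    n2 = exp(rnorm(n)), n3 = exp(rnorm(n)))
    hz <- ifelse(X$sig > 1, 5, 1) * 0.3
    t2 <- rexp(n, hz)
    e2 <- rep(1L, n)
    sel <- select_split_variable(t2, e2, X, n_permutations = 199,
                                 seed = 1000 + i)
    sel$covariate
  }, character(1))
  expect_gte(mean(picks == "sig"), 0.95)
})

test_that("tree growth obeys the gate, stopping rules and partitioning", {
  co <- make_test_cohort(n = 80, seed = 50)
  # closed gate: root leaf only
  t0 <- grow_tree(co, "os", c("hENT1", "CHOP", "MRP1", "DCK"),
                  alpha = 0, seed = 1)
  expect_equal(t0$leaves, 1L)
  # 5 subjects cannot satisfy a 3+3 partition
  tiny <- co[1:5, ]
  tiny$os_event <- c(1, 0, 0, 0, 0)
  t5 <- grow_tree(tiny, "os", c("hENT1", "DCK"), seed = 1)
  expect_equal(t5$leaves, 1L)
  # no events: refuse to model
  z <- co
  z$os_event <- 0
  expect_error(grow_tree(z, "os", c("hENT1")), "no events")
  # grown tree: every leaf meets the floor, siblings partition the parent
  cfg <- gemtree:::recovery_config(n = 300, seed = 60)
  expr <- simulate_expression(cfg, seed = 60)
  sv <- simulate_survival(expr, cfg$planted_tree, cfg$leaf_hazards,
                          cfg$censor_time_max, seed = 60,
                          genes = cfg$genes)
  co2 <- cbind(data.frame(patient_id = 1:300), expr, os_time = sv$time,
               os_event = sv$event)
  tr <- grow_tree(co2, "os", cfg$genes, seed = 61)
  expect_gt(length(tr$leaves), 1)
  for (id in tr$leaves) {
    nd <- tr$nodes[[as.character(id)]]
    expect_gte(nd$n_events, 1)
    expect_gte(length(nd$members), 3)
  }
  for (nd in tr$nodes) {
    if (!is.null(nd$children)) {
      l <- tr$nodes[[as.character(nd$children[1])]]
      r <- tr$nodes[[as.character(nd$children[2])]]
      expect_length(intersect(l$members, r$members), 0)
      expect_setequal(c(l$members, r$members), nd$members)
      expect_equal(l$n_events + r$n_events, nd$n_events)
    }
  }
  # leaf assignment covers every subject exactly once
  la <- leaf_assignment(tr)
  expect_false(anyNA(la))
  expect_equal(length(la), 300)
})

test_that("amalgamation merges indistinguishable leaves and ranks
           classes by hazard", {
  set.seed(70)
  n <- 200
  lab <- rep(c("a", "b", "c"), each = n)
  hz <- c(a = 0.3, b = 0.3, c = 2.4)[lab]
  tt <- rexp(3 * n, hz)
  ee <- rep(1L, 3 * n)
  # merging on: the two HR~1 leaves collapse
  rc <- risk_classes(tt, ee, lab, amalgamation_alpha = 0.05)
  expect_equal(nrow(rc$classes), 2)
  expect_true("a+b" %in% rc$classes$leaves)
  # merging off: leaves are the classes
  rc1 <- risk_classes(tt, ee, lab, amalgamation_alpha = 1)
  expect_equal(nrow(rc1$classes), 3)
  expect_true(all(diff(rc1$classes$hr) <= 1e-12)) # decreasing HR order
  ref <- rc1$classes[rc1$classes$class_id == rc1$reference_class_id, ]
  expect_equal(ref$hr, 1)
  expect_equal(min(rc1$classes$rate_per_100py), ref$rate_per_100py)
  # single label: one reference class
  rc2 <- risk_classes(tt[1:50], ee[1:50], rep("only", 50))
  expect_equal(nrow(rc2$classes), 1)
  expect_equal(rc2$classes$hr, 1)
})

test_that("class profiles use Fisher for categorical and Kruskal-Wallis
           for continuous covariates", {
  cohort <- data.frame(flag = c(1, 1, 0, 0), score = c(1, 2, 3, 6))
  cls <- structure(list(assignment = c(1, 1, 2, 2)))
  prof <- class_profiles(cohort, cls, c("flag", "score"))
  # 2x2 diagonal table [[2,0],[0,2]]: two-sided Fisher p = 1/3
  expect_equal(prof$p_value[prof$covariate == "flag"], 1 / 3,
               tolerance = 1e-12)
  expect_equal(prof$test, c("fisher", "kruskal-wallis"))
  # Kruskal-Wallis against the direct rank formula, no ties
  cohort2 <- data.frame(v = c(1, 2, 3, 4, 5, 6) + 0.5)
  cls2 <- structure(list(assignment = rep(1:2, each = 3)))
  p2 <- class_profiles(cohort2, cls2, "v")
  h_direct <- 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7
  expect_equal(p2$statistic, h_direct, tolerance = 1e-10)
  # identical distributions: H = 0
  cohort3 <- data.frame(v = rep(c(1.5, 2.5, 3.5), 2))
  cls3 <- structure(list(assignment = rep(1:2, each = 3)))
  expect_equal(class_profiles(cohort3, cls3, "v")$statistic, 0,
               tolerance = 1e-10)
  # entirely-missing covariate dropped with a warning
  cohort$gone <- NA_real_
  expect_warning(class_profiles(cohort, cls, c("flag", "gone")),
                 "entirely missing")
})

test_that("tree reports serialize losslessly and name the splits", {
  cfg <- gemtree:::recovery_config(n = 300, seed = 80)
  expr <- simulate_expression(cfg, seed = 80)
  sv <- simulate_survival(expr, cfg$planted_tree, cfg$leaf_hazards,
                          cfg$censor_time_max, seed = 80,
                          genes = cfg$genes)
  co <- cbind(data.frame(patient_id = sprintf("P%03d", 1:300)), expr,
              os_time = sv$time, os_event = sv$event)
  tr <- grow_tree(co, "os", cfg$genes, seed = 81)
  cls <- amalgamate(tr)
  rep1 <- report_tree(tr, cls)
  parsed <- jsonlite::fromJSON(rep1$json, simplifyVector = FALSE)
  expect_setequal(names(parsed$nodes), names(tr$nodes))
  for (id in names(tr$nodes)) {
    nd <- tr$nodes[[id]]
    pj <- parsed$nodes[[id]]
    expect_equal(unlist(pj$member_ids), nd$patient_ids)
    expect_equal(pj$n_events, nd$n_events)
    if (!is.null(nd$split)) {
      expect_equal(pj$split$covariate, nd$split$covariate)
      expect_equal(pj$split$threshold, nd$split$threshold,
                   tolerance = 1e-9)
    }
  }
  # the planted splitting genes are named in the human-readable report
  split_covs <- vapply(Filter(function(n) !is.null(n$split), tr$nodes),
                       function(n) n$split$covariate, character(1))
  for (cv in unique(split_covs)) {
    expect_match(rep1$text, cv, fixed = TRUE)
  }
  # single-leaf tree reports exactly one class
  t1 <- grow_tree(co, "os", cfg$genes, alpha = 0, seed = 1)
  r1 <- report_tree(t1, amalgamate(t1))
  expect_equal(nrow(r1$classes), 1)
})
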