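test_that("zero log-sd collapses fold changes to the configured medians", {
  cfg <- sim_config(gene_log_sds = c(hENT1 = 0, CHOP = 0, MRP1 = 0,
                                     DCK = 0), seed = 4)
  fc <- simulate_expression(cfg, n = 10)
  for (g in cfg$genes) {
    expect_equal(fc[[paste0(g, "_fc")]],
                 rep(exp(cfg$gene_log_medians[[g]]), 10))
  }
})

test_that("marginal medians and the log-scale copula are recovered", {
  cfg <- sim_config(n_patients = 5000, seed = 11)
  fc <- simulate_expression(cfg)
  expect_gt(median(fc$hENT1_fc), 0.50)
  expect_lt(median(fc$hENT1_fc), 0.56)
  # all four log-medians within 3 standard errors of the configuration
  for (g in cfg$genes) {
    lx <- log(fc[[paste0(g, "_fc")]])
    se_med <- 1.2533 * sd(lx) / sqrt(5000)
    expect_lt(abs(median(lx) - cfg$gene_log_medians[[g]]), 3 * se_med)
  }
  r <- cor(log(fc$MRP1_fc), log(fc$hENT1_fc))
  expect_gt(r, 0.48)
  expect_lt(r, 0.58)
})

test_that("identity correlation yields near-zero pairwise correlations", {
  cfg <- sim_config(n_patients = 5000, gene_corr = diag(4), seed = 12)
  dimnames(cfg$gene_corr) <- list(cfg$genes, cfg$genes)
  fc <- simulate_expression(cfg)
  cm <- cor(log(as.matrix(fc)))
  off <- cm[upper.tri(cm)]
  expect_true(all(abs(off) < 0.05))
})

test_that("a non-PSD correlation matrix is rejected with an explanation", {
  m <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  genes <- c("hENT1", "CHOP", "MRP1")
  dimnames(m) <- list(genes, genes)
  expect_error(
    sim_config(genes = genes,
               gene_log_medians = c(hENT1 = 0, CHOP = 0, MRP1 = 0),
               gene_log_sds = c(hENT1 = 1, CHOP = 1, MRP1 = 1),
               gene_corr = m),
    "positive semi-definite")
})

test_that("survival simulator honours leaf hazards and censoring", {
  one_leaf <- list(list(name = "all",
                        rules = list(list(var = "x", op = "gt",
                                          threshold = -Inf))))
  dat <- data.frame(x = rnorm(5000))
  # heavy censoring off: mean observed time approximates 1/hazard
  sv <- simulate_survival(dat, one_leaf, c(all = 0.5), 1e6, seed = 3)
  expect_gt(mean(sv$time), 1.9)
  expect_lt(mean(sv$time), 2.1)
  expect_true(all(sv$event == 1 | sv$time < 1e6))
  # vanishing censoring horizon: no events observed
  sv0 <- simulate_survival(dat, one_leaf, c(all = 0.5), 1e-9, seed = 3)
  expect_true(all(sv0$event == 0))
})

test_that("planted two-leaf hazard ratio shows up in crude event rates", {
  two_leaf <- list(
    list(name = "a", rules = list(list(var = "x", op = "le",
                                       threshold = 0))),
    list(name = "b", rules = list(list(var = "x", op = "gt",
                                       threshold = 0))))
  dat <- data.frame(x = rep(c(-1, 1), each = 2000))
  sv <- simulate_survival(dat, two_leaf, c(a = 1.0, b = 0.2), 1e9,
                          seed = 5)
  rate <- tapply(sv$event, sv$leaf, sum) / tapply(sv$time, sv$leaf, sum)
  ratio <- rate[["a"]] / rate[["b"]]
  expect_gt(ratio, 4.0)
  expect_lt(ratio, 6.25)
})

test_that("crude per-leaf event rates recover planted hazards within 10%", {
  cfg <- sim_config(n_patients = 5000, seed = 21)
  expr <- simulate_expression(cfg)
  sv <- simulate_survival(expr, cfg$planted_tree, cfg$leaf_hazards, 1e9,
                          seed = 21, genes = cfg$genes)
  for (leaf in names(cfg$leaf_hazards)) {
    sel <- sv$leaf == leaf
    crude <- sum(sv$event[sel]) / sum(sv$time[sel])
    expect_lt(abs(crude - cfg$leaf_hazards[[leaf]]),
              0.1 * cfg$leaf_hazards[[leaf]])
  }
})

test_that("rows not covered by the planted tree are reported", {
  gap_tree <- list(list(name = "only",
                        rules = list(list(var = "x", op = "le",
                                          threshold = 0))))
  expect_error(
    simulate_survival(data.frame(x = c(-1, 1)), gap_tree, c(only = 1), 5,
                      seed = 1),
    "row 2")
})

test_that("clinical simulator matches prevalences and range contracts", {
  cfg <- sim_config(n_patients = 5000, seed = 31)
  clin <- simulate_clinical(cfg)
  expect_gt(mean(clin$jaundice), 0.56)
  expect_lt(mean(clin$jaundice), 0.60)
  expect_true(all(clin$lymph_node_ratio >= 0 &
                    clin$lymph_node_ratio <= 1))
  cfg1 <- sim_config(clinical_prevalences = c(jaundice = 1), seed = 1)
  expect_true(all(simulate_clinical(cfg1)$jaundice == 1))
  expect_error(
    sim_config(clinical_prevalences = c(not_a_covariate = 0.5)),
    "unknown clinical covariate")
})

test_that("make_cohort is deterministic, sized and valid, and the CSV
           dialect round-trips losslessly", {
  cfg <- sim_config(seed = 7)
  c1 <- make_cohort(cfg)
  c2 <- make_cohort(cfg)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 26)
  expect_length(validate_cohort(c1), 0)
  expect_true(all(c1$pfs_time <= c1$os_time))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(c1, path)
  back <- read_cohort(path)
  expect_identical(names(back), names(c1))
  for (nm in names(c1)) {
    if (is.numeric(c1[[nm]])) {
      expect_true(all(back[[nm]] == c1[[nm]]), info = nm)
    } else {
      expect_identical(as.character(back[[nm]]), as.character(c1[[nm]]))
    }
  }
})
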