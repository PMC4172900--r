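# Simulation experiments validating the engine. These are package-level so
# the analysis drivers, the test suite and scripts/acceptance.R all run the
# same code.

# Brute-force Breslow log partial likelihood, written naively (explicit
# loops over event times and risk sets) and independently of cox_loglik();
# serves as the oracle in grid-search comparisons.
breslow_loglik_naive <- function(beta, x, time, event) {
  ll <- numeric(length(beta))
  for (tt in unique(time[event == 1])) {
    at_risk <- which(time >= tt)
    ev <- which(time == tt & event == 1)
    denom <- colSums(exp(outer(x[at_risk], beta)))
    ll <- ll + beta * sum(x[ev]) - length(ev) * log(denom)
  }
  ll
}

#' Cox fitter versus brute-force grid search
#'
#' Draws random single-covariate censored datasets (n <= 12), fits each
#' with [fit_cox()], and compares the coefficient against an exhaustive
#' grid maximization (step 1e-4 over `[-5, 5]`) of a naive, independently
#' coded Breslow partial likelihood.
#'
#' @param n_datasets number of random datasets (default 50).
#' @param seed RNG seed.
#' @return list with `max_abs_error` and the per-dataset comparison frame.
#' @export
run_cox_oracle_check <- function(n_datasets = 50, seed = 1) {
  set.seed(substream_seed(seed, 21))
  grid <- seq(-5, 5, by = 1e-4)
  rows <- list()
  made <- 0
  while (made < n_datasets) {
    n <- sample(6:12, 1)
    x <- rnorm(n)
    b_true <- runif(1, -1, 1)
    time <- rexp(n, exp(b_true * x))
    event <- rbinom(n, 1, 0.8)
    if (sum(event) < 2 || length(unique(x)) < 2) next
    fit <- fit_cox(time, event, cbind(x = x))
    if (!fit$converged || abs(fit$coefficients) > 4.5) next
    ll <- breslow_loglik_naive(grid, x, time, event)
    b_grid <- grid[which.max(ll)]
    made <- made + 1
    rows[[made]] <- data.frame(n = n, beta_fit = unname(fit$coefficients),
                               beta_grid = b_grid,
                               abs_error = abs(unname(fit$coefficients) -
                                                 b_grid))
  }
  out <- do.call(rbind, rows)
  list(max_abs_error = max(out$abs_error), datasets = out)
}

#' Type-I error of the node permutation gate
#'
#' Simulates cohorts under a global null (independent log-normal noise
#' covariates, exponential survival unrelated to them, uniform censoring)
#' and measures how often the root node splits at the given gate level.
#'
#' @param n_reps replicates (default 500).
#' @param n cohort size per replicate (default 26, the study scale).
#' @param n_covariates number of noise covariates (default 4).
#' @param B permutations per covariate (default 199).
#' @param alpha gate level (default 0.05).
#' @param hazard,censor_time_max survival-generation settings.
#' @param seed RNG seed.
#' @return list with `split_rate`, `n_reps`, and the per-replicate gate
#'   p-values.
#' @export
run_gate_calibration <- function(n_reps = 500, n = 26, n_covariates = 4,
                                 B = 199, alpha = 0.05, hazard = 0.35,
                                 censor_time_max = 5, seed = 1) {
  pvals <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(substream_seed(seed, 31) + r)
    X <- as.data.frame(matrix(exp(rnorm(n * n_covariates, 0, 1.3)), n,
                              n_covariates))
    names(X) <- paste0("g", seq_len(n_covariates))
    t_ev <- rexp(n, hazard)
    t_c <- runif(n, 0, censor_time_max)
    time <- pmin(t_ev, t_c)
    event <- as.integer(t_ev <= t_c)
    if (sum(event) < 2) next
    sel <- select_split_variable(time, event, X, n_permutations = B,
                                 seed = seed + r, node_id = 1)
    pvals[r] <- if (is.null(sel)) 1 else sel$global_p
  }
  ok <- !is.na(pvals)
  list(split_rate = mean(pvals[ok] <= alpha), n_reps = sum(ok),
       gate_p = pvals[ok])
}

# Planted depth-2 configuration used by the recovery experiment: gene A
# (DCK-like marginal) cut at 0.27, then gene B (CHOP-like marginal) cut at
# 0.25 among A-high patients; leaf hazards in ratio 1 : 3 : 9. Censoring is
# effectively off (every subject's event is observed) so the experiment
# isolates split localization from censoring noise.
recovery_config <- function(n = 400, base_hazard = 0.23, seed = 1) {
  sim_config(
    n_patients = n,
    leaf_hazards = c(low = base_hazard, mid = 3 * base_hazard,
                     high = 9 * base_hazard),
    censor_time_max = 1e6,
    seed = seed)
}

#' Planted-tree recovery experiment
#'
#' Simulates cohorts from a depth-2 planted tree (gene thresholds 0.27 and
#' 0.25, leaf hazard ratios 1 : 3 : 9 against the reference leaf), grows a
#' tree on each with all four genes as candidates, and scores recovery: the
#' root must split on the first planted gene and the high-expression child
#' on the second, both thresholds within `tol` of the planted cuts. Class
#' hazard ratios are averaged over recovered replicates with exactly three
#' leaves and compared with the planted 3 and 9.
#'
#' @param n_reps replicates (default 100).
#' @param n patients per cohort (default 400).
#' @param B permutations per covariate (default 199).
#' @param alpha gate level (default 0.05).
#' @param tol threshold tolerance (default 0.05).
#' @param seed RNG seed.
#' @return list with `recovery_rate`, `hr_mid`, `hr_high` (mean recovered),
#'   `hr_max_rel_error` versus the planted (3, 9), and the per-replicate
#'   frame.
#' @export
run_recovery_experiment <- function(n_reps = 100, n = 400, B = 199,
                                    alpha = 0.05, tol = 0.05, seed = 1) {
  rows <- list()
  for (r in seq_len(n_reps)) {
    rep_seed <- substream_seed(seed, 41) + 101 * r
    cfg <- recovery_config(n = n, seed = rep_seed)
    expr <- simulate_expression(cfg, seed = rep_seed)
    sv <- simulate_survival(expr, cfg$planted_tree, cfg$leaf_hazards,
                            cfg$censor_time_max, seed = rep_seed,
                            genes = cfg$genes)
    cohort <- cbind(data.frame(patient_id = seq_len(n)), expr,
                    os_time = sv$time, os_event = sv$event)
    tree <- grow_tree(cohort, "os", cfg$genes, n_permutations = B,
                      alpha = alpha, seed = rep_seed)
    root <- tree$nodes[["1"]]
    root_ok <- !is.null(root$split) && root$split$covariate == "DCK" &&
      is.finite(root$split$threshold) &&
      abs(root$split$threshold - 0.27) <= tol
    child_ok <- FALSE
    if (root_ok) {
      right <- tree$nodes[[as.character(root$children[2])]]
      child_ok <- !is.null(right$split) &&
        right$split$covariate == "CHOP" &&
        is.finite(right$split$threshold) &&
        abs(right$split$threshold - 0.25) <= tol
    }
    recovered <- root_ok && child_ok
    hr_mid <- hr_high <- NA_real_
    if (recovered && length(tree$leaves) == 3) {
      cls <- amalgamate(tree)
      hrs <- sort(cls$classes$hr)
      if (length(hrs) == 3) {
        hr_mid <- hrs[2]
        hr_high <- hrs[3]
      }
    }
    rows[[r]] <- data.frame(
      rep = r, recovered = recovered, n_leaves = length(tree$leaves),
      root_threshold = if (!is.null(root$split)) root$split$threshold
                       else NA_real_,
      hr_mid = hr_mid, hr_high = hr_high)
  }
  out <- do.call(rbind, rows)
  hr_mid <- mean(out$hr_mid, na.rm = TRUE)
  hr_high <- mean(out$hr_high, na.rm = TRUE)
  list(recovery_rate = mean(out$recovered),
       hr_mid = hr_mid, hr_high = hr_high,
       hr_max_rel_error = max(abs(hr_mid - 3) / 3, abs(hr_high - 9) / 9),
       replicates = out)
}
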