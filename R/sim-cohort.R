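#' Simulation configuration for a synthetic PDAC-like cohort
#'
#' Builds the configuration object consumed by [make_cohort()] and the
#' individual simulators. Defaults emulate the statistical structure of a
#' resected pancreatic ductal adenocarcinoma cohort treated with adjuvant
#' gemcitabine: four gemcitabine-pathway genes (hENT1, CHOP, MRP1, DCK) with
#' log-normal tumor-vs-normal fold changes (hENT1 median 0.53, CHOP 1.02,
#' MRP1 0.58, DCK 1.15; spreads matched to the reported interquartile
#' ranges), a Gaussian copula on the log scale carrying the reported
#' inter-gene correlations (MRP1--hENT1 r = 0.53, MRP1--CHOP r = 0.42),
#' threshold-defined hazard subgroups (reference leaf DCK <= 0.27; high-risk
#' leaf DCK > 0.27 & CHOP <= 0.25; intermediate leaf otherwise, with
#' mortality hazards 0.23 / 0.63 / 0.35 events per person-year taken from
#' the per-class crude rates), uniform administrative censoring, and binary
#' clinical covariates at the cohort's prevalences (e.g. jaundice 58%).
#'
#' @param n_patients number of patients (default 26).
#' @param genes character vector of gene names.
#' @param gene_log_medians named numeric, natural log of the median fold
#'   change per gene.
#' @param gene_log_sds named numeric, log-scale standard deviations.
#' @param gene_corr correlation matrix over genes on the log scale; must
#'   have unit diagonal and eigenvalues >= -1e-10.
#' @param planted_tree list of leaves; each leaf is a list with `name` and
#'   `rules`, a list of `(var, op, threshold)` with `op` in `"le"`/`"gt"`.
#'   Leaves must partition the covariate space.
#' @param leaf_hazards named positive numeric, mortality hazard (events per
#'   person-year) per leaf, names matching the planted leaves.
#' @param pfs_hazard_scale progression hazard = `pfs_hazard_scale` times the
#'   leaf mortality hazard (default 58/35, the ratio of the cohort-level
#'   progression and mortality rates).
#' @param censor_time_max upper bound (years) of the uniform administrative
#'   censoring time.
#' @param clinical_prevalences named probabilities for the binary clinical
#'   flags.
#' @param seed integer base seed; all simulator substreams derive from it.
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 26,
                       genes = c("hENT1", "CHOP", "MRP1", "DCK"),
                       gene_log_medians = log(c(hENT1 = 0.53, CHOP = 1.02,
                                                MRP1 = 0.58, DCK = 1.15)),
                       gene_log_sds = c(hENT1 = 1.044, CHOP = 1.880,
                                        MRP1 = 1.264, DCK = 1.580),
                       gene_corr = default_gene_corr(genes),
                       planted_tree = default_planted_tree(),
                       leaf_hazards = c(low = 0.23, mid = 0.35, high = 0.63),
                       pfs_hazard_scale = 58 / 35,
                       censor_time_max = 5,
                       clinical_prevalences = default_clinical_prevalences(),
                       seed = 1L) {
  cfg <- structure(list(
    n_patients = as.integer(n_patients),
    genes = genes,
    gene_log_medians = gene_log_medians[genes],
    gene_log_sds = gene_log_sds[genes],
    gene_corr = gene_corr,
    planted_tree = planted_tree,
    leaf_hazards = leaf_hazards,
    pfs_hazard_scale = pfs_hazard_scale,
    censor_time_max = censor_time_max,
    clinical_prevalences = clinical_prevalences,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
default_gene_corr <- function(genes = c("hENT1", "CHOP", "MRP1", "DCK")) {
  p <- length(genes)
  m <- diag(p)
  dimnames(m) <- list(genes, genes)
  if (all(c("MRP1", "hENT1") %in% genes)) {
    m["MRP1", "hENT1"] <- m["hENT1", "MRP1"] <- 0.53
  }
  if (all(c("MRP1", "CHOP") %in% genes)) {
    m["MRP1", "CHOP"] <- m["CHOP", "MRP1"] <- 0.42
  }
  m
}

#' @rdname sim_config
#' @export
default_planted_tree <- function() {
  list(
    list(name = "low",
         rules = list(list(var = "DCK", op = "le", threshold = 0.27))),
    list(name = "high",
         rules = list(list(var = "DCK", op = "gt", threshold = 0.27),
                      list(var = "CHOP", op = "le", threshold = 0.25))),
    list(name = "mid",
         rules = list(list(var = "DCK", op = "gt", threshold = 0.27),
                      list(var = "CHOP", op = "gt", threshold = 0.25)))
  )
}

#' @rdname sim_config
#' @export
default_clinical_prevalences <- function() {
  c(jaundice = 0.58, diabetes = 0.35, family_history = 0.19,
    previous_neoplasia = 0.08, margins_r1 = 0.31, stage_iib = 0.88,
    mucinous = 0.15, vascular_invasion = 0.12, perineural_invasion = 0.54,
    gem_cycles_lt6 = 0.39)
}

# Binary flags the clinical simulator knows how to draw.
known_binary_covariates <- function() {
  names(default_clinical_prevalences())
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1)
  p <- length(cfg$genes)
  if (!is.matrix(cfg$gene_corr) || nrow(cfg$gene_corr) != p ||
      ncol(cfg$gene_corr) != p) {
    stop("gene_corr must be a ", p, "x", p, " matrix over the genes")
  }
  if (any(abs(diag(cfg$gene_corr) - 1) > 1e-12)) {
    stop("gene_corr must have unit diagonal")
  }
  if (any(abs(cfg$gene_corr - t(cfg$gene_corr)) > 1e-12)) {
    stop("gene_corr must be symmetric")
  }
  ev <- eigen(cfg$gene_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("gene_corr is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")")
  }
  if (any(cfg$gene_log_sds < 0) || anyNA(cfg$gene_log_sds)) {
    stop("gene_log_sds must be non-negative")
  }
  if (any(cfg$leaf_hazards <= 0)) stop("leaf_hazards must be positive")
  leaf_names <- vapply(cfg$planted_tree, `[[`, character(1), "name")
  if (!setequal(leaf_names, names(cfg$leaf_hazards))) {
    stop("leaf_hazards names must match the planted tree leaves")
  }
  if (any(cfg$clinical_prevalences < 0 | cfg$clinical_prevalences > 1)) {
    stop("clinical prevalences must lie in [0, 1]")
  }
  unknown <- setdiff(names(cfg$clinical_prevalences),
                     known_binary_covariates())
  if (length(unknown) > 0) {
    stop("unknown clinical covariate(s): ", paste(unknown, collapse = ", "))
  }
  if (cfg$censor_time_max <= 0) stop("censor_time_max must be positive")
  invisible(cfg)
}

#' Simulate correlated fold changes on the log scale
#'
#' Draws per-patient, per-gene tumor-vs-normal fold changes as exponentials
#' of a multivariate Gaussian with the configured log medians, log standard
#' deviations and correlation matrix (log-normal marginals, Gaussian
#' copula). Deterministic given the seed.
#'
#' @param config a [sim_config()] object.
#' @param n number of patients; defaults to `config$n_patients`.
#' @param seed base seed; defaults to `config$seed`.
#' @return data frame with one `<gene>_fc` column per gene.
#' @export
simulate_expression <- function(config, n = config$n_patients,
                                seed = config$seed) {
  validate_sim_config(config)
  p <- length(config$genes)
  d <- config$gene_log_sds
  sigma <- diag(d, p) %*% config$gene_corr %*% diag(d, p)
  e <- eigen(sigma, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  root <- e$vectors %*% diag(sqrt(lam), p)
  z <- with_substream(seed, 11, matrix(rnorm(n * p), n, p))
  logx <- sweep(z %*% t(root), 2, config$gene_log_medians, `+`)
  fc <- exp(logx)
  colnames(fc) <- paste0(config$genes, "_fc")
  as.data.frame(fc)
}

# Map each row of `data` to exactly one planted leaf. Rule variables name
# either a gene (resolved to its `<gene>_fc` column) or a clinical column.
assign_leaf <- function(data, planted_tree, genes = NULL) {
  resolve <- function(var) {
    if (!is.null(genes) && var %in% genes && paste0(var, "_fc") %in%
        names(data)) {
      return(paste0(var, "_fc"))
    }
    if (var %in% names(data)) return(var)
    stop("planted tree rule refers to unknown variable '", var, "'")
  }
  n <- nrow(data)
  hits <- matrix(TRUE, n, length(planted_tree))
  for (k in seq_along(planted_tree)) {
    for (rule in planted_tree[[k]]$rules) {
      v <- data[[resolve(rule$var)]]
      hits[, k] <- hits[, k] & switch(rule$op,
        le = v <= rule$threshold,
        gt = v > rule$threshold,
        stop("unknown rule op '", rule$op, "'")
      )
    }
  }
  nmatch <- rowSums(hits)
  if (any(nmatch != 1)) {
    bad <- which(nmatch != 1)[1]
    stop("row ", bad, " maps to ", nmatch[bad],
         " leaves; planted tree rules must partition the covariate space")
  }
  leaf_names <- vapply(planted_tree, `[[`, character(1), "name")
  factor(leaf_names[max.col(hits)], levels = leaf_names)
}

#' Simulate censored event times from planted leaf hazards
#'
#' Event times are exponential at the hazard of the leaf each patient falls
#' into; censoring times are uniform on (0, `censor_time_max`]; the recorded
#' time is the smaller of the two with the event indicator set accordingly.
#'
#' @param data covariate rows (genes and/or clinical columns).
#' @param planted_tree leaf definitions as in [sim_config()].
#' @param leaf_hazards named positive hazards (events per person-year).
#' @param censor_time_max censoring upper bound in years.
#' @param seed integer seed.
#' @param genes gene names used to resolve rule variables to `_fc` columns.
#' @return data frame with columns `time`, `event`, `leaf`.
#' @export
simulate_survival <- function(data, planted_tree, leaf_hazards,
                              censor_time_max, seed, genes = NULL) {
  leaf <- assign_leaf(data, planted_tree, genes)
  n <- nrow(data)
  hz <- leaf_hazards[as.character(leaf)]
  with_substream(seed, 13, {
    t_event <- rexp(n, rate = hz)
    t_cens <- runif(n, 0, censor_time_max)
    data.frame(time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens),
               leaf = leaf)
  })
}

#' Simulate clinical covariates
#'
#' Binary flags are independent Bernoulli draws at the configured
#' prevalences. Continuous covariates use fixed cohort-calibrated
#' distributions: age (truncated normal, median 64.5), lymph-node ratio
#' (beta, bounded in `[0, 1]`, median about 0.25), pre-operative CEA and
#' CA19-9 (log-normal, medians 3.2 and 200.4), gemcitabine cycles
#' (shifted Poisson, median 5).
#'
#' @inheritParams simulate_expression
#' @return data frame of clinical columns.
#' @export
simulate_clinical <- function(config, n = config$n_patients,
                              seed = config$seed) {
  prev <- config$clinical_prevalences
  unknown <- setdiff(names(prev), known_binary_covariates())
  if (length(unknown) > 0) {
    stop("unknown clinical covariate(s): ", paste(unknown, collapse = ", "))
  }
  with_substream(seed, 12, {
    out <- lapply(prev, function(p) rbinom(n, 1, p))
    out <- as.data.frame(out)
    age <- rnorm(n, 64.5, 16.3)
    out$age <- pmin(pmax(age, 35), 90)
    out$lymph_node_ratio <- rbeta(n, 1.3, 3.5)
    out$cea_preop <- exp(rnorm(n, log(3.2), 0.814))
    out$ca19_9_preop <- exp(rnorm(n, log(200.4), 1.362))
    out$gem_cycles <- 1L + rpois(n, 4)
    out
  })
}

#' Generate a full synthetic cohort
#'
#' Composes the expression, clinical and survival simulators into one
#' cohort table with both endpoints. Progression and death are nested:
#' progression time is exponential at `pfs_hazard_scale` times the leaf
#' mortality hazard, death follows progression after a further exponential
#' residual at the leaf mortality hazard, and both endpoints share one
#' uniform administrative censoring time, so `pfs_time <= os_time` holds
#' for every patient.
#'
#' @inheritParams simulate_expression
#' @return a cohort data frame: `patient_id`, one `<gene>_fc` column per
#'   gene, clinical columns, `os_time`, `os_event`, `pfs_time`, `pfs_event`.
#' @export
make_cohort <- function(config = sim_config(), n = config$n_patients,
                        seed = config$seed) {
  validate_sim_config(config)
  expr <- simulate_expression(config, n = n, seed = seed)
  clin <- simulate_clinical(config, n = n, seed = seed)
  covars <- cbind(expr, clin)
  leaf <- assign_leaf(covars, config$planted_tree, genes = config$genes)
  hz_os <- config$leaf_hazards[as.character(leaf)]
  hz_pfs <- hz_os * config$pfs_hazard_scale
  surv <- with_substream(seed, 13, {
    t_prog <- rexp(n, rate = hz_pfs)
    t_death <- t_prog + rexp(n, rate = hz_os)
    t_cens <- runif(n, 0, config$censor_time_max)
    data.frame(os_time = pmin(t_death, t_cens),
               os_event = as.integer(t_death <= t_cens),
               pfs_time = pmin(t_prog, t_cens),
               pfs_event = as.integer(t_prog <= t_cens))
  })
  cohort <- cbind(data.frame(patient_id = sprintf("P%03d", seq_len(n))),
                  covars, surv)
  rownames(cohort) <- NULL
  cohort
}

#' Write / read a cohort table as CSV
#'
#' One header row, one row per patient, decimal point, UTF-8, newline
#' terminated. Numeric columns are written with round-trip precision so the
#' table survives a write/read cycle losslessly.
#'
#' @param cohort a cohort data frame.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  # base read.csv parses doubles with correctly-rounded strtod, so the
  # shortest-round-trip digits written by write_cohort come back bit-exact
  utils::read.csv(path, stringsAsFactors = FALSE)
}
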