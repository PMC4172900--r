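#' Comparative relative quantification (2^-ddCt)
#'
#' Converts paired cycle-threshold measurements into a tumor-vs-normal fold
#' change, normalizing each sample's target-gene Ct by a housekeeping gene:
#' ddCt = (Ct_target,tumor - Ct_ref,tumor) - (Ct_target,normal -
#' Ct_ref,normal) and fold change = 2^-ddCt. Vectorized over patients.
#'
#' @param ct_target_tumor,ct_ref_tumor,ct_target_normal,ct_ref_normal
#'   cycle-threshold values (cycles). Must be finite; values outside the
#'   usual (0, 45) instrument range trigger a warning, not an error.
#' @return positive fold change(s).
#' @examples
#' relative_expression(25, 20, 24, 20) # 0.5
#' @export
relative_expression <- function(ct_target_tumor, ct_ref_tumor,
                                ct_target_normal, ct_ref_normal) {
  args <- list(ct_target_tumor = ct_target_tumor,
               ct_ref_tumor = ct_ref_tumor,
               ct_target_normal = ct_target_normal,
               ct_ref_normal = ct_ref_normal)
  for (nm in names(args)) {
    if (any(!is.finite(args[[nm]]))) {
      stop("non-finite Ct value in '", nm, "'")
    }
    if (any(args[[nm]] <= 0 | args[[nm]] >= 45)) {
      warning("Ct values in '", nm, "' outside the typical (0, 45) range")
    }
  }
  ddct <- (ct_target_tumor - ct_ref_tumor) -
    (ct_target_normal - ct_ref_normal)
  2^(-ddct)
}

#' Fold changes from a table of Ct records
#'
#' @param ct_table data frame with columns `patient_id`, `gene`,
#'   `ct_target_tumor`, `ct_ref_tumor`, `ct_target_normal`,
#'   `ct_ref_normal`.
#' @return the table with a `fold_change` column appended.
#' @export
fold_changes_from_ct <- function(ct_table) {
  need <- c("patient_id", "gene", "ct_target_tumor", "ct_ref_tumor",
            "ct_target_normal", "ct_ref_normal")
  missing <- setdiff(need, names(ct_table))
  if (length(missing) > 0) {
    stop("ct table lacks column(s): ", paste(missing, collapse = ", "))
  }
  ct_table$fold_change <- relative_expression(
    ct_table$ct_target_tumor, ct_table$ct_ref_tumor,
    ct_table$ct_target_normal, ct_table$ct_ref_normal)
  ct_table
}

#' One-sample test of differential expression on log fold changes
#'
#' Two-sided one-sample t-test of the mean log fold change against zero
#' (i.e. against no tumor-vs-normal difference), reported together with the
#' median and quartiles on the original fold-change scale. The t statistic
#' and p-value are invariant to the logarithm base; the natural log is used
#' internally. Quartiles use linear interpolation between order statistics.
#'
#' @param fold_changes positive fold changes, n >= 2.
#' @param gene optional gene label carried into the result.
#' @return list with `gene`, `n`, `median_fc`, `q1_fc`, `q3_fc`,
#'   `t_statistic`, `df`, `p_value`, `degenerate`.
#' @export
fold_change_test <- function(fold_changes, gene = NA_character_) {
  if (length(fold_changes) < 2) stop("need at least 2 fold changes")
  if (any(fold_changes <= 0)) stop("fold changes must be positive")
  lx <- log(fold_changes)
  n <- length(lx)
  q <- quantile(fold_changes, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  s <- sd(lx)
  if (s == 0) {
    return(list(gene = gene, n = n, median_fc = q[2], q1_fc = q[1],
                q3_fc = q[3], t_statistic = NA_real_, df = n - 1,
                p_value = NA_real_, degenerate = TRUE))
  }
  t_stat <- mean(lx) / (s / sqrt(n))
  p <- 2 * pt(-abs(t_stat), df = n - 1)
  list(gene = gene, n = n, median_fc = q[2], q1_fc = q[1], q3_fc = q[3],
       t_statistic = t_stat, df = n - 1, p_value = p, degenerate = FALSE)
}

#' Pearson correlation between two genes' log expression
#'
#' Pearson r on log-transformed values with the two-sided p-value from the
#' t transform, t = r sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom.
#'
#' @param x,y positive expression values of equal length, n >= 3.
#' @param log_input set TRUE when `x`, `y` are already log scale.
#' @param gene_a,gene_b optional labels.
#' @return list with `gene_a`, `gene_b`, `n`, `r`, `p_value`, `degenerate`.
#' @export
correlate_expression <- function(x, y, log_input = FALSE,
                                 gene_a = NA_character_,
                                 gene_b = NA_character_) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  lx <- if (log_input) x else log(x)
  ly <- if (log_input) y else log(y)
  dx <- lx - mean(lx)
  dy <- ly - mean(ly)
  sxx <- sum(dx^2)
  syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) {
    return(list(gene_a = gene_a, gene_b = gene_b, n = n, r = NA_real_,
                p_value = NA_real_, degenerate = TRUE))
  }
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t_stat), df = n - 2)
  }
  list(gene_a = gene_a, gene_b = gene_b, n = n, r = r, p_value = p,
       degenerate = FALSE)
}

#' Association between log expression and a clinical phenotype
#'
#' Two groups: classical two-sample t-test with pooled variance. More than
#' two groups: one-way ANOVA F-test. Both act on the supplied (log)
#' values. A zero pooled within-group variance is flagged as degenerate
#' rather than reported as p = 0.
#'
#' @param log_values numeric values (log expression).
#' @param groups group labels, >= 2 groups with >= 2 observations each.
#' @return list with `test` ("t" or "anova"), `statistic`, `df`,
#'   `p_value`, `degenerate`.
#' @export
phenotype_association <- function(log_values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  counts <- table(groups)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    stop("group(s) with fewer than 2 observations: ",
         paste(small, collapse = ", "))
  }
  n <- length(log_values)
  k <- nlevels(groups)
  gm <- tapply(log_values, groups, mean)
  gn <- as.numeric(counts)
  ssw <- sum(tapply(log_values, groups, function(v) sum((v - mean(v))^2)))
  if (k == 2) {
    df <- n - 2
    sp2 <- ssw / df
    if (sp2 == 0) {
      return(list(test = "t", statistic = NA_real_, df = df,
                  p_value = NA_real_, degenerate = TRUE))
    }
    t_stat <- (gm[1] - gm[2]) / sqrt(sp2 * (1 / gn[1] + 1 / gn[2]))
    return(list(test = "t", statistic = unname(t_stat), df = df,
                p_value = 2 * pt(-abs(unname(t_stat)), df = df),
                degenerate = FALSE))
  }
  ssb <- sum(gn * (gm - mean(log_values))^2)
  df1 <- k - 1
  df2 <- n - k
  if (ssw == 0) {
    return(list(test = "anova", statistic = NA_real_, df = c(df1, df2),
                p_value = NA_real_, degenerate = TRUE))
  }
  f_stat <- (ssb / df1) / (ssw / df2)
  list(test = "anova", statistic = f_stat, df = c(df1, df2),
       p_value = pf(f_stat, df1, df2, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Per-gene expression statistics over a cohort table
#'
#' Runs [fold_change_test()] for every gene and
#' [correlate_expression()] for every gene pair of a cohort table.
#'
#' @param cohort a cohort data frame with `<gene>_fc` columns.
#' @param genes gene names.
#' @return list with data frames `fold_changes` and `correlations`. P-values
#'   are raw (no multiplicity adjustment); adjustment is left to the caller.
#' @export
expression_stats <- function(cohort, genes = c("hENT1", "CHOP", "MRP1",
                                               "DCK")) {
  cols <- paste0(genes, "_fc")
  missing <- setdiff(cols, names(cohort))
  if (length(missing) > 0) {
    stop("cohort lacks expression column(s): ",
         paste(missing, collapse = ", "))
  }
  fc <- do.call(rbind, lapply(seq_along(genes), function(i) {
    r <- fold_change_test(cohort[[cols[i]]], gene = genes[i])
    data.frame(gene = r$gene, n = r$n, median_fc = r$median_fc,
               q1_fc = r$q1_fc, q3_fc = r$q3_fc,
               t_statistic = r$t_statistic, p_value = r$p_value,
               degenerate = r$degenerate)
  }))
  pairs <- utils::combn(seq_along(genes), 2)
  cors <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]
    i2 <- pairs[2, j]
    r <- correlate_expression(cohort[[cols[i1]]], cohort[[cols[i2]]],
                              gene_a = genes[i1], gene_b = genes[i2])
    data.frame(gene_a = r$gene_a, gene_b = r$gene_b, n = r$n, r = r$r,
               p_value = r$p_value, degenerate = r$degenerate)
  }))
  list(fold_changes = fc, correlations = cors)
}
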