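#' Amalgamate group labels into risk classes
#'
#' Starting from one class per label, iteratively merges the pair of
#' current classes whose two-class Cox Wald p-value is largest, as long as
#' that p-value exceeds `amalgamation_alpha`; with `amalgamation_alpha = 1`
#' no merging occurs and classes are exactly the input labels. The
#' reference class is the one with the lowest crude event rate
#' (events / person-years); hazard ratios and Wald 95% CIs come from one
#' Cox fit on class indicators against the reference. Classes are numbered
#' 1, 2, ... in decreasing hazard-ratio order.
#'
#' @param time,event survival data.
#' @param labels initial group labels (e.g. tree leaves), one per subject.
#' @param amalgamation_alpha merging threshold in `[0, 1]` (default 1: off).
#' @return object of class `risk_class_table`: data frame `classes` with
#'   `class_id`, `leaves`, `n`, `n_events`, `hr`, `ci95_low`, `ci95_high`,
#'   `rate_per_100py`, `rate_display`, `median_followup_months`; plus
#'   `reference_class_id` and the per-subject `assignment`.
#' @export
risk_classes <- function(time, event, labels, amalgamation_alpha = 1) {
  labels <- factor(labels)
  if (any(table(labels) == 0)) labels <- droplevels(labels)
  groups <- lapply(levels(labels), function(l) l) # class -> member labels
  assign_class <- function() {
    cl <- integer(length(labels))
    for (k in seq_along(groups)) {
      cl[as.character(labels) %in% groups[[k]]] <- k
    }
    cl
  }
  pair_p <- function(ia, ib) {
    cl <- assign_class()
    sel <- cl %in% c(ia, ib)
    z <- as.integer(cl[sel] == ib)
    if (length(unique(z)) < 2) return(NA_real_)
    ord <- order(time[sel])
    r <- cox1_indicator_cpp(time[sel][ord], as.integer(event[sel][ord]),
                            z[ord])
    if (!r$converged || !is.finite(r$se) || r$se == 0) return(0)
    2 * pnorm(-abs(r$beta / r$se))
  }
  while (length(groups) > 1 && amalgamation_alpha < 1) {
    best <- NULL
    for (a in seq_along(groups)) {
      for (b in seq_along(groups)) {
        if (b <= a) next
        p <- pair_p(a, b)
        if (!is.na(p) && (is.null(best) || p > best$p)) {
          best <- list(a = a, b = b, p = p)
        }
      }
    }
    if (is.null(best) || best$p <= amalgamation_alpha) break
    groups[[best$a]] <- c(groups[[best$a]], groups[[best$b]])
    groups[[best$b]] <- NULL
  }
  k <- length(groups)
  cl <- assign_class()
  rates <- vapply(seq_len(k), function(i) {
    sum(event[cl == i]) / sum(time[cl == i])
  }, numeric(1))
  ref <- which.min(rates)
  hrs <- rep(1, k)
  ci_lo <- rep(NA_real_, k)
  ci_hi <- rep(NA_real_, k)
  fit <- NULL
  if (k > 1) {
    f <- factor(cl, levels = c(ref, setdiff(seq_len(k), ref)))
    mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(mm) <- paste0("class", setdiff(seq_len(k), ref))
    fit <- fit_cox(time, event, mm)
    non_ref <- setdiff(seq_len(k), ref)
    hrs[non_ref] <- unname(fit$hr)
    ci_lo[non_ref] <- unname(fit$ci95_low)
    ci_hi[non_ref] <- unname(fit$ci95_high)
    ci_lo[ref] <- ci_hi[ref] <- 1
  } else {
    ci_lo[1] <- ci_hi[1] <- 1
  }
  ord <- order(-hrs, rates * -1)
  class_id <- integer(k)
  class_id[ord] <- seq_len(k)
  classes <- do.call(rbind, lapply(seq_len(k), function(i) {
    sel <- cl == i
    rate <- incidence_rate(event[sel], time[sel])
    data.frame(class_id = class_id[i],
               leaves = paste(sort(unlist(groups[[i]])), collapse = "+"),
               n = sum(sel), n_events = sum(event[sel]), hr = hrs[i],
               ci95_low = ci_lo[i], ci95_high = ci_hi[i],
               rate_per_100py = rate$rate_per_100py,
               rate_display = rate$rate_display,
               median_followup_months = median(time[sel]) * 12)
  }))
  classes <- classes[order(classes$class_id), , drop = FALSE]
  rownames(classes) <- NULL
  structure(list(classes = classes,
                 reference_class_id = class_id[ref],
                 assignment = class_id[cl], fit = fit),
            class = "risk_class_table")
}

#' Amalgamate tree leaves into final risk classes
#'
#' @param tree a [grow_tree()] result.
#' @param amalgamation_alpha merging threshold (default 1: leaves are the
#'   classes, matching trees whose terminal nodes are reported directly as
#'   classes).
#' @return a `risk_class_table` (see [risk_classes()]).
#' @export
amalgamate <- function(tree, amalgamation_alpha = 1) {
  risk_classes(tree$time, tree$event, leaf_assignment(tree),
               amalgamation_alpha = amalgamation_alpha)
}

#' @export
print.risk_class_table <- function(x, ...) {
  cat("Risk classes (reference = class", x$reference_class_id, ")\n")
  print(x$classes, ...)
  invisible(x)
}

#' Clinical profiles of the final risk classes
#'
#' Compares each clinical covariate across classes: Kruskal-Wallis for
#' continuous covariates, Fisher's exact test for categorical ones
#' (factors, characters, logicals, and binary 0/1 numerics). Covariates
#' entirely missing are dropped with a warning.
#'
#' @param cohort the cohort data frame.
#' @param classes a `risk_class_table` (its `assignment` is used).
#' @param clinical_covariates column names to compare.
#' @return data frame with `covariate`, `test`, `statistic`, `p_value`.
#' @export
class_profiles <- function(cohort, classes, clinical_covariates) {
  cl <- factor(classes$assignment)
  if (nlevels(cl) < 2) stop("need at least 2 classes")
  rows <- list()
  for (nm in clinical_covariates) {
    if (!nm %in% names(cohort)) stop("covariate '", nm, "' not in cohort")
    v <- cohort[[nm]]
    if (all(is.na(v))) {
      warning("covariate '", nm, "' entirely missing; dropped")
      next
    }
    categorical <- is.factor(v) || is.character(v) || is.logical(v) ||
      (is.numeric(v) && length(unique(v[!is.na(v)])) <= 2)
    if (categorical) {
      ok <- !is.na(v)
      tab <- table(factor(v[ok]), cl[ok])
      ft <- fisher.test(tab)
      rows[[nm]] <- data.frame(covariate = nm, test = "fisher",
                               statistic = NA_real_, p_value = ft$p.value)
    } else {
      kw <- kruskal.test(v ~ cl)
      rows[[nm]] <- data.frame(covariate = nm, test = "kruskal-wallis",
                               statistic = unname(kw$statistic),
                               p_value = kw$p.value)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize a tree and its risk classes
#'
#' Produces a machine-readable JSON document (nodes keyed by id with
#' depth, member ids, event/non-event counts, split condition with HR and
#' CI, gate p-value and children) and an indented human-readable report
#' with per-class HR (95% CI), incidence rate per 100 person-years and
#' median follow-up in months.
#'
#' @param tree a `recpam_tree`.
#' @param classes a `risk_class_table` for the tree.
#' @param out_prefix optional path prefix; when given, writes
#'   `<prefix>tree.json`, `<prefix>classes.tsv` and `<prefix>report.txt`.
#' @return list with `json` (string), `text` (string), `classes`
#'   (data frame).
#' @export
report_tree <- function(tree, classes, out_prefix = NULL) {
  nodes <- lapply(tree$nodes, function(nd) {
    out <- list(depth = nd$depth, member_ids = nd$patient_ids,
                n_events = nd$n_events, n_nonevents = nd$n_nonevents,
                permutation_p = nd$permutation_p)
    if (!is.null(nd$split)) {
      out$split <- list(
        covariate = nd$split$covariate,
        threshold = nd$split$threshold,
        left_levels = nd$split$left_levels,
        statistic = nd$split$statistic,
        hr = nd$split$hr,
        ci95 = c(nd$split$ci95_low, nd$split$ci95_high))
      out$children <- nd$children
    }
    out
  })
  doc <- list(endpoint = toupper(tree$endpoint), n = tree$n,
              n_events = tree$n_events,
              stopping = as.list(tree$stopping),
              n_permutations = tree$n_permutations, alpha = tree$alpha,
              seed = tree$seed, nodes = nodes,
              reference_class_id = classes$reference_class_id,
              classes = classes$classes)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, na = "null")
  txt <- c(
    sprintf("RECPAM analysis, endpoint %s", toupper(tree$endpoint)),
    sprintf("n = %d patients, %d events; stopping: >= %d event(s) and >= %d subjects per leaf",
            tree$n, tree$n_events, tree$stopping[["min_events_per_leaf"]],
            tree$stopping[["min_subjects_per_leaf"]]),
    "", capture.output(print(tree)), "",
    sprintf("Final classes (reference = class %d):",
            classes$reference_class_id))
  cc <- classes$classes
  for (i in seq_len(nrow(cc))) {
    txt <- c(txt, sprintf(
      "  class %d [%s]: n = %d, events = %d, HR = %.2f (95%% CI %.2f-%.2f), rate = %d/100 py, median follow-up = %.1f months",
      cc$class_id[i], cc$leaves[i], cc$n[i], cc$n_events[i], cc$hr[i],
      cc$ci95_low[i], cc$ci95_high[i], cc$rate_display[i],
      cc$median_followup_months[i]))
  }
  text <- paste(txt, collapse = "\n")
  if (!is.null(out_prefix)) {
    writeLines(json, paste0(out_prefix, "tree.json"))
    readr::write_tsv(cc, paste0(out_prefix, "classes.tsv"))
    writeLines(text, paste0(out_prefix, "report.txt"))
  }
  list(json = as.character(json), text = text, classes = cc)
}
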