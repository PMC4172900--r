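#' Admissible binary splits of one covariate
#'
#' Continuous covariates: candidate thresholds are the midpoints between
#' consecutive distinct sorted values. Categorical covariates (at most 4
#' levels): every unordered two-set partition of the observed levels. A
#' candidate is admissible when both children have at least `min_subjects`
#' subjects and `min_events` events.
#'
#' @param x covariate values (numeric, or factor/character for categorical).
#' @param event 0/1 event indicators aligned with `x`.
#' @param min_subjects,min_events admissibility floor per child.
#' @return data frame of admissible candidates with columns `threshold`
#'   (numeric; NA for categorical), `left_levels` (comma-joined; NA for
#'   continuous), `left_n`, `right_n`, `left_events`, `right_events`. Empty
#'   data frame when no split is admissible.
#' @export
candidate_splits <- function(x, event, min_subjects = 3, min_events = 1) {
  keep <- !is.na(x)
  x <- x[keep]
  event <- event[keep]
  empty <- data.frame(threshold = numeric(0), left_levels = character(0),
                      left_n = integer(0), right_n = integer(0),
                      left_events = integer(0), right_events = integer(0))
  n <- length(x)
  if (n == 0) return(empty)
  admissible <- function(ln, rn, le, re) {
    ln >= min_subjects && rn >= min_subjects && le >= min_events &&
      re >= min_events
  }
  if (is.numeric(x)) {
    u <- sort(unique(x))
    if (length(u) < 2) return(empty)
    thr <- (u[-1] + u[-length(u)]) / 2
    rows <- lapply(thr, function(tt) {
      l <- x <= tt
      if (!admissible(sum(l), sum(!l), sum(event[l]), sum(event[!l]))) {
        return(NULL)
      }
      data.frame(threshold = tt, left_levels = NA_character_,
                 left_n = sum(l), right_n = sum(!l),
                 left_events = sum(event[l]), right_events = sum(event[!l]))
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) empty else out
  } else {
    lev <- sort(unique(as.character(x)))
    if (length(lev) < 2) return(empty)
    if (length(lev) > 4) {
      stop("categorical covariates are limited to 4 levels")
    }
    # each partition once: subsets containing the first level
    others <- lev[-1]
    subs <- list()
    for (k in 0:(length(others) - 1)) {
      if (k == 0) {
        subs <- c(subs, list(lev[1]))
      } else {
        cm <- utils::combn(others, k, simplify = FALSE)
        subs <- c(subs, lapply(cm, function(s) c(lev[1], s)))
      }
    }
    subs <- subs[vapply(subs, length, 1L) < length(lev)]
    rows <- lapply(subs, function(s) {
      l <- as.character(x) %in% s
      if (!admissible(sum(l), sum(!l), sum(event[l]), sum(event[!l]))) {
        return(NULL)
      }
      data.frame(threshold = NA_real_,
                 left_levels = paste(s, collapse = ","),
                 left_n = sum(l), right_n = sum(!l),
                 left_events = sum(event[l]), right_events = sum(event[!l]))
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) empty else out
  }
}

#' Evaluate one binary split by a Cox likelihood-ratio statistic
#'
#' Fits a single-covariate Cox model on the indicator I(x > threshold)
#' (or I(x not in left levels) for categorical splits) and returns the
#' likelihood-ratio chi-square 2(logPL(beta_hat) - logPL(0)) together with
#' the indicator's hazard ratio and Wald 95% CI for reporting.
#'
#' @param time,event survival data for the node's members.
#' @param x covariate values; missing values are excluded from the
#'   evaluation (never from the node).
#' @param threshold numeric cut for continuous covariates.
#' @param left_levels character vector (or comma-joined string) of levels
#'   sent left, for categorical covariates.
#' @return list with `statistic`, `beta`, `se`, `hr`, `ci95_low`,
#'   `ci95_high`, `converged`.
#' @export
evaluate_split <- function(time, event, x, threshold = NULL,
                           left_levels = NULL) {
  keep <- !is.na(x)
  time <- time[keep]
  event <- event[keep]
  x <- x[keep]
  if (!is.null(threshold)) {
    z <- as.integer(x > threshold)
  } else if (!is.null(left_levels)) {
    if (length(left_levels) == 1 && grepl(",", left_levels)) {
      left_levels <- strsplit(left_levels, ",")[[1]]
    }
    z <- as.integer(!(as.character(x) %in% left_levels))
  } else {
    stop("give either a threshold or left_levels")
  }
  ord <- order(time)
  r <- cox1_indicator_cpp(time[ord], as.integer(event[ord]),
                          as.integer(z[ord]))
  if (!r$converged) {
    return(list(statistic = NA_real_, beta = r$beta, se = r$se,
                hr = NA_real_, ci95_low = NA_real_, ci95_high = NA_real_,
                converged = FALSE))
  }
  list(statistic = r$lr, beta = r$beta, se = r$se, hr = exp(r$beta),
       ci95_low = exp(r$beta - 1.96 * r$se),
       ci95_high = exp(r$beta + 1.96 * r$se), converged = TRUE)
}

# Best split of one covariate: observed T_max and the best candidate.
# Returns NULL when nothing is admissible (or nothing converged).
best_split_one <- function(time, event, x, min_subjects, min_events) {
  keep <- !is.na(x)
  time <- time[keep]
  event <- event[keep]
  x <- x[keep]
  if (length(x) == 0) return(NULL)
  ord <- order(time)
  ts <- time[ord]
  es <- as.integer(event[ord])
  if (is.numeric(x)) {
    r <- cox1_scan_cpp(ts, es, x[ord], min_subjects, min_events)
    if (!r$found) return(NULL)
    l <- x <= r$threshold
    list(threshold = r$threshold, left_levels = NA_character_,
         statistic = r$stat, beta = r$beta, se = r$se,
         left_n = sum(l), right_n = sum(!l),
         left_events = sum(event[l]), right_events = sum(event[!l]))
  } else {
    cands <- candidate_splits(x, event, min_subjects, min_events)
    if (nrow(cands) == 0) return(NULL)
    best <- NULL
    for (i in seq_len(nrow(cands))) {
      lv <- strsplit(cands$left_levels[i], ",")[[1]]
      z <- as.integer(!(as.character(x) %in% lv))
      r <- cox1_indicator_cpp(ts, es, z[ord])
      if (!r$converged) next
      if (is.null(best) || r$lr > best$statistic + 1e-12) {
        best <- list(threshold = NA_real_,
                     left_levels = cands$left_levels[i], statistic = r$lr,
                     beta = r$beta, se = r$se, left_n = cands$left_n[i],
                     right_n = cands$right_n[i],
                     left_events = cands$left_events[i],
                     right_events = cands$right_events[i])
      }
    }
    best
  }
}

# Permutation null draws of one covariate's T_max (B values, -1 when a
# permuted dataset has no admissible converged split). Consumes R's RNG.
perm_tmax_one <- function(time, event, x, B, min_subjects, min_events) {
  keep <- !is.na(x)
  time <- time[keep]
  event <- event[keep]
  x <- x[keep]
  ord <- order(time)
  ts <- time[ord]
  es <- as.integer(event[ord])
  if (is.numeric(x)) {
    return(cox1_perm_tmax_cpp(ts, es, x[ord], as.integer(B),
                              as.integer(min_subjects),
                              as.integer(min_events)))
  }
  xs <- as.character(x)[ord]
  vapply(seq_len(B), function(b) {
    xp <- sample(xs)
    bs <- best_split_one(ts, es, xp, min_subjects, min_events)
    if (is.null(bs)) -1 else bs$statistic
  }, numeric(1))
}

#' Choose the splitting variable by permutation
#'
#' For every candidate covariate, the observed T_max is the largest
#' likelihood-ratio statistic over its admissible splits. The covariate's
#' permutation p-value compares T_max with its null distribution obtained
#' by shuffling that covariate's values among the node's members with the
#' outcomes fixed (add-one estimator, (1 + #{permuted >= observed}) /
#' (1 + B)). The chosen covariate has the smallest permutation p, ties
#' broken by larger observed T_max, then lexicographic name. The node-level
#' gate p-value (`global_p`) compares the best observed T_max with the
#' permutation distribution of the maximum over all covariates, which keeps
#' the probability of a spurious split at a node near the nominal level
#' regardless of how many covariates compete.
#'
#' @param time,event survival data for the node members.
#' @param covariates data frame of candidate covariates (node members only).
#' @param n_permutations number of permutations B (default 199).
#' @param seed,node_id define the RNG substream so trees are reproducible
#'   regardless of traversal order.
#' @param min_subjects,min_events admissibility floor per child.
#' @return `NULL` when no covariate has an admissible split; otherwise a
#'   list with `covariate`, `split` (threshold or left levels, statistic,
#'   HR, CI, child counts), `perm_p` (winner's per-covariate p),
#'   `global_p`, and `per_covariate` (observed T_max and p per covariate).
#' @export
select_split_variable <- function(time, event, covariates,
                                  n_permutations = 199, seed = 1,
                                  node_id = 1, min_subjects = 3,
                                  min_events = 1) {
  nms <- sort(names(covariates))
  B <- n_permutations
  obs <- list()
  perms <- list()
  set.seed(substream_seed(seed, node_id))
  for (nm in nms) {
    x <- covariates[[nm]]
    bs <- best_split_one(time, event, x, min_subjects, min_events)
    if (is.null(bs)) next
    obs[[nm]] <- bs
    perms[[nm]] <- perm_tmax_one(time, event, x, B, min_subjects,
                                 min_events)
  }
  if (length(obs) == 0) return(NULL)
  active <- names(obs)
  pvals <- vapply(active, function(nm) {
    (1 + sum(perms[[nm]] >= obs[[nm]]$statistic - 1e-12)) / (1 + B)
  }, numeric(1))
  tmax <- vapply(active, function(nm) obs[[nm]]$statistic, numeric(1))
  pick <- active[order(pvals, -tmax, active)][1]
  g_obs <- max(tmax)
  g_perm <- do.call(pmax, perms[active])
  global_p <- (1 + sum(g_perm >= g_obs - 1e-12)) / (1 + B)
  list(covariate = pick, split = obs[[pick]],
       perm_p = unname(pvals[pick]), global_p = global_p,
       per_covariate = data.frame(covariate = active, t_max = tmax,
                                  perm_p = pvals, row.names = NULL))
}

# Resolve requested covariate names against a cohort table: a gene name
# maps to its `<gene>_fc` column but keeps the bare name for reporting.
resolve_covariates <- function(cohort, covariates) {
  out <- list()
  for (nm in covariates) {
    col <- if (nm %in% names(cohort)) {
      nm
    } else if (paste0(nm, "_fc") %in% names(cohort)) {
      paste0(nm, "_fc")
    } else {
      stop("covariate '", nm, "' not found in the cohort")
    }
    v <- cohort[[col]]
    if (is.character(v) || is.logical(v)) v <- factor(v)
    out[[nm]] <- v
  }
  as.data.frame(out, optional = TRUE)
}

#' Grow a RECPAM-style survival tree
#'
#' Recursive binary partitioning of a censored cohort. At each node the
#' splitting variable is chosen by [select_split_variable()]; the node is
#' split only when the node-level permutation gate passes (`global_p <=
#' alpha`) and both children satisfy the stopping floor (at least
#' `min_events` event and `min_subjects` subjects per leaf); otherwise it
#' becomes a leaf. Patients with a missing value of the chosen covariate
#' are sent to the child with more complete-case members. Deterministic
#' given the seed.
#'
#' @param cohort cohort data frame (`<gene>_fc`, clinical, endpoint
#'   columns).
#' @param endpoint `"os"` or `"pfs"`; uses `<endpoint>_time` /
#'   `<endpoint>_event`.
#' @param covariates names of candidate splitting variables; gene names are
#'   resolved to their `_fc` columns.
#' @param min_subjects,min_events stopping floor per leaf (default 3 and 1).
#' @param n_permutations permutations per node (default 199).
#' @param alpha permutation gate level (default 0.05); `alpha = 0` closes
#'   the gate and returns the root leaf.
#' @param max_depth safety bound on the depth (default 5).
#' @param seed base seed for the per-node permutation substreams.
#' @return object of class `recpam_tree`.
#' @export
grow_tree <- function(cohort, endpoint = c("os", "pfs"), covariates,
                      min_subjects = 3, min_events = 1,
                      n_permutations = 199, alpha = 0.05, max_depth = 5,
                      seed = 1) {
  endpoint <- match.arg(endpoint)
  time <- cohort[[paste0(endpoint, "_time")]]
  event <- cohort[[paste0(endpoint, "_event")]]
  if (is.null(time) || is.null(event)) {
    stop("cohort lacks ", endpoint, "_time / ", endpoint, "_event columns")
  }
  if (sum(event) == 0) stop("no events to model")
  X <- resolve_covariates(cohort, covariates)
  pid <- if ("patient_id" %in% names(cohort)) {
    as.character(cohort$patient_id)
  } else {
    as.character(seq_len(nrow(cohort)))
  }
  nodes <- list()
  build <- function(members, depth, id) {
    node <- list(id = id, depth = depth, members = members,
                 patient_ids = pid[members],
                 n_events = sum(event[members]),
                 n_nonevents = sum(1 - event[members]),
                 split = NULL, permutation_p = NA_real_, children = NULL)
    can_try <- depth < max_depth &&
      length(members) >= 2 * min_subjects &&
      sum(event[members]) >= 2 * min_events && alpha > 0
    if (can_try) {
      sel <- select_split_variable(time[members], event[members],
                                   X[members, , drop = FALSE],
                                   n_permutations = n_permutations,
                                   seed = seed, node_id = id,
                                   min_subjects = min_subjects,
                                   min_events = min_events)
      if (!is.null(sel) && sel$global_p <= alpha) {
        x <- X[[sel$covariate]][members]
        if (!is.na(sel$split$threshold)) {
          right <- x > sel$split$threshold
        } else {
          lv <- strsplit(sel$split$left_levels, ",")[[1]]
          right <- !(as.character(x) %in% lv)
        }
        if (anyNA(right)) { # majority rule for missing values
          right[is.na(right)] <-
            sum(right, na.rm = TRUE) > sum(!right, na.rm = TRUE)
        }
        ev <- evaluate_split(time[members], event[members], x,
                             threshold = if (!is.na(sel$split$threshold))
                               sel$split$threshold else NULL,
                             left_levels = if (is.na(sel$split$threshold))
                               sel$split$left_levels else NULL)
        node$split <- list(covariate = sel$covariate,
                           threshold = sel$split$threshold,
                           left_levels = sel$split$left_levels,
                           statistic = sel$split$statistic,
                           hr = ev$hr, ci95_low = ev$ci95_low,
                           ci95_high = ev$ci95_high,
                           perm_p = sel$perm_p)
        node$permutation_p <- sel$global_p
        node$children <- c(2 * id, 2 * id + 1)
        nodes[[as.character(id)]] <<- node
        build(members[!right], depth + 1, 2 * id)
        build(members[right], depth + 1, 2 * id + 1)
        return(invisible(NULL))
      }
      if (!is.null(sel)) node$permutation_p <- sel$global_p
    }
    nodes[[as.character(id)]] <<- node
    invisible(NULL)
  }
  build(seq_len(nrow(cohort)), 0, 1)
  ids <- as.integer(names(nodes))
  leaves <- sort(ids[vapply(nodes, function(nd) is.null(nd$children),
                            logical(1))])
  structure(list(
    endpoint = endpoint, nodes = nodes[order(ids)], leaves = leaves,
    stopping = c(min_events_per_leaf = min_events,
                 min_subjects_per_leaf = min_subjects),
    n_permutations = n_permutations, alpha = alpha, max_depth = max_depth,
    seed = seed, covariates = covariates, n = nrow(cohort),
    n_events = sum(event), time = time, event = event,
    patient_ids = pid
  ), class = "recpam_tree")
}

#' Leaf membership of every patient
#'
#' @param tree a `recpam_tree`.
#' @return factor of leaf node ids, one entry per cohort row.
#' @export
leaf_assignment <- function(tree) {
  out <- integer(tree$n)
  for (id in tree$leaves) {
    nd <- tree$nodes[[as.character(id)]]
    out[nd$members] <- id
  }
  factor(out, levels = tree$leaves)
}

#' @export
print.recpam_tree <- function(x, ...) {
  cat(sprintf("RECPAM survival tree (%s): n = %d, events = %d, %d leaves\n",
              toupper(x$endpoint), x$n, x$n_events, length(x$leaves)))
  print_node <- function(id, indent) {
    nd <- x$nodes[[as.character(id)]]
    pad <- strrep("  ", indent)
    cat(sprintf("%snode %d [%d events / %d non-events]", pad, nd$id,
                nd$n_events, nd$n_nonevents))
    if (!is.null(nd$split)) {
      cond <- if (!is.na(nd$split$threshold)) {
        sprintf("%s <= %.4g", nd$split$covariate, nd$split$threshold)
      } else {
        sprintf("%s in {%s}", nd$split$covariate, nd$split$left_levels)
      }
      cat(sprintf(" split: %s (LR = %.2f, gate p = %.4f)\n", cond,
                  nd$split$statistic, nd$permutation_p))
      print_node(nd$children[1], indent + 1)
      print_node(nd$children[2], indent + 1)
    } else {
      cat(" (leaf)\n")
    }
  }
  print_node(1, 0)
  invisible(x)
}
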