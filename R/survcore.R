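#' Build a survival record from dates
#'
#' Time to event is measured from the baseline (surgery) date to the event
#' date when the event occurred, otherwise to the last available clinical
#' follow-up, in years (days / 365.25).
#'
#' @param baseline_date,event_date,last_followup_date `Date`s or strings
#'   coercible via [as.Date()]; `event_date = NA` means no event.
#' @param endpoint `"OS"` or `"PFS"`.
#' @param patient_id identifier carried into the record.
#' @return list with `patient_id`, `time` (years), `event` (0/1),
#'   `endpoint`.
#' @export
build_endpoint <- function(baseline_date, event_date = NA,
                           last_followup_date, endpoint = c("OS", "PFS"),
                           patient_id = NA_character_) {
  endpoint <- match.arg(endpoint)
  baseline <- as.Date(baseline_date)
  if (!is.na(event_date)) {
    ev <- as.Date(event_date)
    if (ev < baseline) stop("event date precedes baseline")
    return(list(patient_id = patient_id,
                time = as.numeric(ev - baseline) / 365.25,
                event = 1L, endpoint = endpoint))
  }
  fu <- as.Date(last_followup_date)
  if (fu < baseline) stop("follow-up date precedes baseline")
  list(patient_id = patient_id,
       time = as.numeric(fu - baseline) / 365.25,
       event = 0L, endpoint = endpoint)
}

#' Person-years incidence rate
#'
#' Number of events divided by the summed person-years of follow-up,
#' multiplied by 100. The exact rate is returned together with the integer
#' display value truncated toward zero (the convention under which 17
#' events over 29 person-years prints as 58).
#'
#' @param events event indicators (0/1) or, with `person_years` given, the
#'   total event count.
#' @param times follow-up times in years (ignored when `person_years` is
#'   given).
#' @param person_years optional total person-years, for use with aggregate
#'   counts.
#' @return list with `n_events`, `person_years`, `rate_per_100py` (exact)
#'   and `rate_display` (truncated integer).
#' @export
incidence_rate <- function(events, times = NULL, person_years = NULL) {
  if (is.null(person_years)) {
    if (is.null(times) || length(times) != length(events)) {
      stop("need per-subject times matching events, or total person_years")
    }
    n_events <- sum(events)
    person_years <- sum(times)
  } else {
    n_events <- sum(events)
  }
  if (person_years <= 0) stop("total person-years must be positive")
  rate <- 100 * n_events / person_years
  list(n_events = as.integer(n_events), person_years = person_years,
       rate_per_100py = rate, rate_display = trunc(rate))
}

# Breslow log partial likelihood with gradient and hessian.
# X: n x p matrix sorted by ascending time together with event.
cox_loglik <- function(beta, X, time, event, want_deriv = TRUE) {
  n <- nrow(X)
  p <- ncol(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  # reverse cumulative sums over the risk sets (time ascending)
  s0 <- rev(cumsum(rev(w)))                       # sum w over risk set i..n
  s1 <- apply(X * w, 2, function(col) rev(cumsum(rev(col))))
  s1 <- matrix(s1, nrow = n)
  ll <- 0
  grad <- numeric(p)
  hess <- matrix(0, p, p)
  i <- 1
  while (i <= n) {
    j <- i
    d <- 0
    sx <- numeric(p)
    while (j <= n && time[j] == time[i]) {
      if (event[j] == 1) {
        d <- d + 1
        sx <- sx + X[j, ]
        ll <- ll + eta[j]
      }
      j <- j + 1
    }
    if (d > 0) {
      ll <- ll - d * log(s0[i])
      if (want_deriv) {
        mu <- s1[i, ] / s0[i]
        grad <- grad + sx - d * mu
        # second moment of X over the risk set
        rs <- i:n
        s2 <- crossprod(X[rs, , drop = FALSE] * w[rs],
                        X[rs, , drop = FALSE])
        hess <- hess - d * (s2 / s0[i] - tcrossprod(mu))
      }
    }
    i <- j
  }
  list(loglik = ll, grad = grad, hess = hess)
}

#' Cox proportional-hazards fit (Breslow ties)
#'
#' Maximizes the Cox partial likelihood with the Breslow approximation for
#' tied event times by Newton-Raphson with step-halving; convergence when
#' the log partial likelihood changes by less than 1e-9 (at most 100
#' iterations). Wald 95% confidence intervals, exp(beta +/- 1.96 SE).
#' Monotone likelihood (risk perfectly separated, beta diverging) is
#' flagged via `converged = FALSE` and a `monotone` flag instead of
#' returning a silently huge hazard ratio.
#'
#' @param time follow-up times (years).
#' @param event 0/1 event indicators; at least one event required.
#' @param covariates numeric matrix or data frame of covariates (finite; no
#'   covariate may be constant).
#' @return object of class `cox_fit`: `coefficients`, `se`, `hr`,
#'   `ci95_low`, `ci95_high`, `loglik`, `loglik_null`, `lr_statistic`,
#'   `n`, `n_events`, `iter`, `converged`, `monotone`.
#' @export
fit_cox <- function(time, event, covariates) {
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("covariates must be finite")
  if (length(time) != nrow(X) || length(event) != nrow(X)) {
    stop("time, event and covariates must have matching lengths")
  }
  if (sum(event) < 1) stop("need at least one event")
  if (any(apply(X, 2, function(c) length(unique(c)) == 1))) {
    stop("constant covariate")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  ord <- order(time)
  X <- X[ord, , drop = FALSE]
  time <- time[ord]
  event <- event[ord]
  # center for numerical stability; beta is translation-invariant
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  p <- ncol(Xc)
  beta <- numeric(p)
  l0 <- cox_loglik(beta, Xc, time, event)
  ll_null <- l0$loglik
  ll_old <- ll_null
  cur <- l0
  converged <- FALSE
  monotone <- FALSE
  iter <- 0
  for (it in seq_len(100)) {
    iter <- it
    step <- tryCatch(solve(-cur$hess, cur$grad), error = function(e) NULL)
    if (is.null(step)) break
    bnew <- beta + step
    lnew <- cox_loglik(bnew, Xc, time, event)
    halv <- 0
    while (lnew$loglik < ll_old && halv < 30) {
      step <- step / 2
      bnew <- beta + step
      lnew <- cox_loglik(bnew, Xc, time, event)
      halv <- halv + 1
    }
    beta <- bnew
    cur <- lnew
    if (max(abs(beta)) > 15) {
      monotone <- TRUE
      break
    }
    if (abs(lnew$loglik - ll_old) < 1e-9) {
      ll_old <- lnew$loglik
      converged <- TRUE
      break
    }
    ll_old <- lnew$loglik
  }
  vcov <- tryCatch(solve(-cur$hess), error = function(e) {
    matrix(NA_real_, p, p)
  })
  se <- sqrt(pmax(diag(vcov), 0))
  hr <- exp(beta)
  names(beta) <- names(se) <- names(hr) <- colnames(X)
  structure(list(
    coefficients = beta, se = se, hr = hr,
    ci95_low = exp(beta - 1.96 * se), ci95_high = exp(beta + 1.96 * se),
    loglik = cur$loglik, loglik_null = ll_null,
    lr_statistic = 2 * (cur$loglik - ll_null),
    n = length(time), n_events = sum(event), iter = iter,
    converged = converged, monotone = monotone
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional hazards fit (Breslow ties)\n")
  cat(sprintf("n = %d, events = %d, logPL = %.4f (null %.4f)\n", x$n,
              x$n_events, x$loglik, x$loglik_null))
  if (!x$converged) {
    cat(if (x$monotone) "NOT CONVERGED: monotone likelihood\n"
        else "NOT CONVERGED\n")
  }
  tab <- data.frame(coef = x$coefficients, se = x$se, HR = x$hr,
                    ci_low = x$ci95_low, ci_high = x$ci95_high)
  print(tab, ...)
  invisible(x)
}

#' Per-class survivor functions from a Cox model
#'
#' Fits a Cox model on class-indicator covariates (relative to a reference
#' class) and returns each class's survivor function through the Breslow
#' baseline cumulative hazard: S_k(t) = S_0(t)^{HR_k}. With a single class
#' the curve is the baseline (Breslow) estimator itself.
#'
#' @param time,event survival data.
#' @param class_labels factor of class memberships, each class non-empty.
#' @param reference reference class label; defaults to the first level.
#' @return data frame with columns `time`, `class`, `survival`; one row per
#'   class at t = 0 and at every distinct event time.
#' @export
class_survival_curves <- function(time, event, class_labels,
                                  reference = NULL) {
  cls <- factor(class_labels)
  if (any(table(cls) == 0)) stop("every class must have at least one subject")
  if (is.null(reference)) reference <- levels(cls)[1]
  cls <- stats::relevel(cls, ref = as.character(reference))
  k <- nlevels(cls)
  if (k > 1) {
    mm <- stats::model.matrix(~cls)[, -1, drop = FALSE]
    colnames(mm) <- levels(cls)[-1]
    fit <- fit_cox(time, event, mm)
    eta <- drop(mm %*% fit$coefficients)
    hrs <- c(1, exp(fit$coefficients))
  } else {
    eta <- rep(0, length(time))
    hrs <- 1
  }
  names(hrs) <- levels(cls)
  ord <- order(time)
  t_s <- time[ord]
  e_s <- event[ord]
  w <- exp(eta)[ord]
  s0 <- rev(cumsum(rev(w)))
  # Breslow baseline cumulative hazard increments at distinct event times
  ev_times <- unique(t_s[e_s == 1])
  h0 <- vapply(ev_times, function(tt) {
    i <- match(tt, t_s) # first row with this time (risk set start)
    sum(e_s[t_s == tt]) / s0[i]
  }, numeric(1))
  H0 <- cumsum(h0)
  S0 <- exp(-H0)
  grid <- c(0, ev_times)
  S0 <- c(1, S0)
  out <- do.call(rbind, lapply(levels(cls), function(cl) {
    data.frame(time = grid, class = cl, survival = S0^hrs[[cl]])
  }))
  rownames(out) <- NULL
  out
}
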