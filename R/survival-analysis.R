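#' Validate a survival record table
#'
#' Records carry `sample_id`, `time` (>= 0), `event` (0/1) and an optional
#' `endpoint` label (OS, DFS, RFS, DMFS, FP, PFS, relapse). Endpoints are
#' metadata: estimators are endpoint-agnostic, but mixing endpoints within
#' one test is refused.
#' @param records data frame with at least `time` and `event` columns.
#' @return the validated data frame (endpoint column added if absent).
#' @keywords internal
check_records <- function(records) {
  records <- as.data.frame(records)
  stopifnot(all(c("time", "event") %in% names(records)))
  if (nrow(records) < 1L) stop("no survival records", call. = FALSE)
  if (any(records$time < 0)) stop("negative follow-up time", call. = FALSE)
  if (!all(records$event %in% c(0, 1))) {
    stop("event indicator must be 0/1", call. = FALSE)
  }
  if (!"endpoint" %in% names(records)) records$endpoint <- "OS"
  if (length(unique(records$endpoint)) > 1L) {
    stop("records mix endpoints: ",
         paste(unique(records$endpoint), collapse = ", "), call. = FALSE)
  }
  records
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function; censored subjects leave
#' the risk set after their censoring time, and S(0) = 1.
#'
#' @param records data frame with `time`, `event` (and optionally
#'   `sample_id`, `endpoint`).
#' @return list (class `KMEstimate`) with `time`, `surv`, `n_risk`,
#'   `n_event`, `n_censor`, `n`, `events`, plus `survfn`, a right-continuous
#'   step function S(t).
#' @export
km_estimate <- function(records) {
  records <- check_records(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  sf <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 n = nrow(records), events = sum(records$event),
                 survfn = sf),
            class = "KMEstimate")
}

#' @export
print.KMEstimate <- function(x, ...) {
  cat(sprintf("KMEstimate: n = %d, events = %d\n", x$n, x$events))
  print(utils::head(data.frame(time = x$time, n_risk = x$n_risk,
                               n_event = x$n_event, surv = x$surv), 10))
  invisible(x)
}

#' Log-rank test across groups
#'
#' Observed-versus-expected log-rank test over pooled event times; any
#' number of groups (k-1 degrees of freedom).
#'
#' @param groups named list of record data frames, or a single data frame
#'   with a `group` column.
#' @return list with `statistic`, `df`, `p`, `n`, `events`, `observed`,
#'   `expected` (per group).
#' @export
logrank_test <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot("group" %in% names(groups))
    df <- check_records(groups)
    df$group <- factor(df$group)
  } else {
    stopifnot(is.list(groups), length(groups) >= 2L)
    if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
    df <- do.call(rbind, lapply(names(groups), function(nm) {
      g <- check_records(groups[[nm]])
      g$group <- nm
      g[, c("time", "event", "group")]
    }))
    df$group <- factor(df$group)
  }
  if (nlevels(df$group) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (sum(df$event) == 0L) {
    stop("log-rank undefined: zero events in all groups", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  k <- nlevels(df$group)
  list(statistic = sd$chisq, df = k - 1L,
       p = stats::pchisq(sd$chisq, df = k - 1L, lower.tail = FALSE),
       n = as.vector(sd$n), events = sum(df$event),
       observed = as.vector(sd$obs), expected = as.vector(sd$exp))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling. Categorical
#' covariates are expanded against their first (lowest-coded) level unless
#' releveled by the caller. Hazard ratios, Wald 95% confidence intervals
#' and p-values are reported per covariate.
#'
#' @param records data frame with `time`, `event`.
#' @param covariates data frame of covariates aligned with `records` rows,
#'   or a character vector naming columns of `records`.
#' @return data frame (class `CoxResult`) with one row per coefficient:
#'   `term`, `coef`, `hr`, `ci_low`, `ci_high`, `p`; attributes `loglik`,
#'   `n`, `events`, `ties`.
#' @export
cox_fit <- function(records, covariates) {
  records <- check_records(records)
  if (is.character(covariates)) {
    covariates <- records[, covariates, drop = FALSE]
  }
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(records)) {
    stop("covariates and records differ in rows", call. = FALSE)
  }
  const <- vapply(covariates, function(c) length(unique(c)) == 1L, TRUE)
  if (any(const)) {
    stop("constant covariate(s): ",
         paste(names(covariates)[const], collapse = ", "), call. = FALSE)
  }
  dat <- cbind(records[, c("time", "event")], covariates)
  form <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                  paste(names(covariates), collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(form, data = dat, ties = "efron"),
    error = function(e) stop("Cox fit failed: ", conditionMessage(e),
                             call. = FALSE),
    warning = function(w) {
      if (grepl("infinite|did not converge|Loglik converged", conditionMessage(w))) {
        stop("Cox fit unstable (possible separation): ",
             conditionMessage(w), call. = FALSE)
      }
      suppressWarnings(survival::coxph(form, data = dat, ties = "efron"))
    })
  if (sum(records$event) < length(stats::coef(fit))) {
    stop(sprintf("too few events (%d) for %d parameters",
                 sum(records$event), length(stats::coef(fit))),
         call. = FALSE)
  }
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(!is.finite(beta)) || any(!is.finite(se))) {
    stop("Cox fit failed: non-finite coefficients (separation?)",
         call. = FALSE)
  }
  z <- stats::qnorm(0.975)
  res <- data.frame(term = names(beta), coef = unname(beta),
                    hr = exp(unname(beta)),
                    ci_low = exp(unname(beta) - z * se),
                    ci_high = exp(unname(beta) + z * se),
                    se = unname(se),
                    p = 2 * stats::pnorm(-abs(unname(beta) / se)),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("CoxResult", "data.frame")
  attr(res, "loglik") <- fit$loglik[2]
  attr(res, "n") <- nrow(records)
  attr(res, "events") <- sum(records$event)
  attr(res, "ties") <- "efron"
  res
}

#' Five-year survival comparison by chi-square
#'
#' Classifies each subject at `horizon` time units: event before the horizon
#' means not surviving; event-free follow-up past the horizon means
#' surviving; subjects censored before the horizon are excluded (counts
#' reported). Groups are then compared with a 2x2 chi-square (no continuity
#' correction).
#'
#' @param group_a,group_b record data frames (`time`, `event`).
#' @param horizon classification horizon (default 5).
#' @return list with `proportions` (surviving fraction per group), `counts`
#'   (2x2 table), `excluded` (censored-early counts per group),
#'   `statistic`, `p`.
#' @export
five_year_survival_test <- function(group_a, group_b, horizon = 5) {
  classify <- function(records) {
    records <- check_records(records)
    # an event at/after the horizon still counts as surviving to it
    died <- records$event == 1 & records$time < horizon
    alive <- records$time >= horizon
    excluded <- records$event == 0 & records$time < horizon
    list(surviving = sum(alive), not = sum(died), excluded = sum(excluded))
  }
  a <- classify(group_a)
  b <- classify(group_b)
  if (a$surviving + a$not == 0L || b$surviving + b$not == 0L) {
    stop("a group has zero classifiable subjects at the horizon",
         call. = FALSE)
  }
  counts <- matrix(c(a$surviving, a$not, b$surviving, b$not), nrow = 2,
                   byrow = TRUE,
                   dimnames = list(group = c("A", "B"),
                                   status = c("surviving", "not_surviving")))
  prop <- counts[, 1] / rowSums(counts)
  if (all(counts[, 2] == 0) || all(counts[, 1] == 0)) {
    stat <- 0
    p <- 1
  } else {
    ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  list(proportions = prop, counts = counts,
       excluded = c(A = a$excluded, B = b$excluded),
       statistic = stat, p = p, horizon = horizon)
}

#' Treatment-stratified hazard analysis (forest table)
#'
#' For a cohort with a binary CES stratum (high = top tertile vs low = rest)
#' and a binary treatment flag, runs the four analyses behind a
#' treated-vs-untreated forest plot: hazard of treatment within the high
#' stratum, within the low stratum, and hazard of high-vs-low CES within the
#' treated and the untreated arms. Each row reports the Cox HR with 95% CI
#' and Wald p plus the two-group log-rank p. Analyses whose subcohort falls
#' below `min_n` subjects are dropped with a note.
#'
#' @param cohort data frame with `sample_id`, `time`, `event`, `treated`
#'   (0/1).
#' @param strata a `StrataAssignment` with levels `low`/`high` (mode
#'   `top_tertile_vs_rest`) or a named factor with those levels.
#' @param min_n subcohort floor (default 30).
#' @return data frame (class `ForestTable`) with columns `analysis`,
#'   `subcohort`, `contrast`, `hr`, `ci_low`, `ci_high`, `p_wald`,
#'   `p_logrank`, `n`, `events`; attribute `dropped` lists analyses below
#'   the floor.
#' @export
stratified_treatment_analysis <- function(cohort, strata, min_n = 30L) {
  cohort <- as.data.frame(cohort)
  stopifnot(all(c("sample_id", "time", "event", "treated") %in%
                names(cohort)))
  st <- if (inherits(strata, "StrataAssignment")) strata$strata else strata
  ids <- intersect(as.character(cohort$sample_id), names(st))
  cohort <- cohort[match(ids, as.character(cohort$sample_id)), ]
  cohort$stratum <- factor(as.character(st[ids]), levels = c("low", "high"))
  if (anyNA(cohort$stratum)) {
    stop("strata must use labels 'low' and 'high'", call. = FALSE)
  }
  analyses <- list(
    list(analysis = "treatment_within_high",
         sub = cohort[cohort$stratum == "high", ], var = "treated",
         subcohort = "high CES", contrast = "treated vs untreated"),
    list(analysis = "treatment_within_low",
         sub = cohort[cohort$stratum == "low", ], var = "treated",
         subcohort = "low CES", contrast = "treated vs untreated"),
    list(analysis = "high_vs_low_within_treated",
         sub = cohort[cohort$treated == 1, ], var = "stratum",
         subcohort = "treated arm", contrast = "high vs low CES"),
    list(analysis = "high_vs_low_within_untreated",
         sub = cohort[cohort$treated == 0, ], var = "stratum",
         subcohort = "untreated arm", contrast = "high vs low CES")
  )
  rows <- list()
  dropped <- character(0)
  for (a in analyses) {
    sub <- a$sub
    grp <- sub[[a$var]]
    if (nrow(sub) < min_n || length(unique(grp)) < 2L ||
        min(table(grp)) < 1L) {
      dropped <- c(dropped, sprintf("%s (n=%d < %d or a cell is empty)",
                                    a$analysis, nrow(sub), min_n))
      next
    }
    cx <- tryCatch(
      cox_fit(sub, stats::setNames(data.frame(x = if (a$var == "stratum")
        as.integer(sub$stratum == "high") else sub$treated), a$var)),
      error = function(e) NULL)
    if (is.null(cx)) {
      dropped <- c(dropped, sprintf("%s (Cox fit failed)", a$analysis))
      next
    }
    lr <- tryCatch(
      logrank_test(data.frame(time = sub$time, event = sub$event,
                              group = grp)),
      error = function(e) list(p = NA_real_))
    rows[[a$analysis]] <- data.frame(
      analysis = a$analysis, subcohort = a$subcohort, contrast = a$contrast,
      hr = cx$hr[1], ci_low = cx$ci_low[1], ci_high = cx$ci_high[1],
      p_wald = cx$p[1], p_logrank = lr$p,
      n = nrow(sub), events = sum(sub$event), stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    stop("every stratified analysis fell below the n >= ", min_n, " floor",
         call. = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("ForestTable", "data.frame")
  attr(res, "dropped") <- dropped
  res
}
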