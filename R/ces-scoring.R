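#' Compute the centromere/kinetochore expression score (CES)
#'
#' The CES of a sample is the unweighted sum of log2 expression over a fixed
#' gene panel. Linear-scale input is converted with `log2(x + 1)` first.
#' No gene weighting or z-scoring is applied: the score is deliberately a
#' plain sum so that it is comparable across stratification modes.
#'
#' @param x an `ExpressionMatrix`.
#' @param panel a `GenePanel` (see [load_gene_panel()]).
#' @param allow_missing if `TRUE`, panel genes absent from `x` are tolerated
#'   and the score is rescaled by `panel_size / n_available` to stay on the
#'   full-panel scale; a warning is issued and the result is flagged.
#' @return A `CESResult`: list with `scores` (named numeric per sample),
#'   `panel`, `n_genes` (genes actually used), `panel_size`, `rescaled`.
#' @export
compute_ces <- function(x, panel, allow_missing = FALSE) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(panel, "GenePanel"))
  x <- as_log2(x)
  present <- panel$genes[panel$genes %in% gene_ids(x)]
  missing <- setdiff(panel$genes, present)
  if (length(missing) > 0L && !allow_missing) {
    stop("panel genes missing from matrix: ",
         paste(missing, collapse = ", "),
         " (set allow_missing = TRUE to rescale over available genes)",
         call. = FALSE)
  }
  if (length(present) == 0L) stop("no panel genes present in matrix",
                                  call. = FALSE)
  scores <- colSums(x$values[present, , drop = FALSE])
  rescaled <- length(missing) > 0L
  if (rescaled) {
    scores <- scores * length(panel$genes) / length(present)
    warning(sprintf("%d/%d panel genes missing; scores rescaled by %d/%d",
                    length(missing), length(panel$genes),
                    length(panel$genes), length(present)), call. = FALSE)
  }
  structure(
    list(scores = scores, panel = panel$name, n_genes = length(present),
         panel_size = length(panel$genes), rescaled = rescaled,
         missing_genes = missing),
    class = "CESResult"
  )
}

#' @export
print.CESResult <- function(x, ...) {
  cat(sprintf("CESResult: %d samples, panel '%s' (%d/%d genes%s)\n",
              length(x$scores), x$panel, x$n_genes, x$panel_size,
              if (x$rescaled) ", rescaled" else ""))
  print(summary(x$scores))
  invisible(x)
}

ces_scores <- function(scores) {
  if (inherits(scores, "CESResult")) scores$scores
  else if (is.numeric(scores) && !is.null(names(scores))) scores
  else stop("need a CESResult or a named numeric vector of scores",
            call. = FALSE)
}

#' Stratify samples by CES
#'
#' Supported modes:
#' \describe{
#'   \item{quantile_tertile}{empirical 1/3 and 2/3 quantile boundaries;
#'     labels `low`/`intermediate`/`high`.}
#'   \item{range_tertile}{equal-width thirds of the observed `[min, max]`
#'     score range.}
#'   \item{top_tertile_vs_rest}{binary: `high` = top quantile tertile,
#'     `low` = the remaining two tertiles.}
#'   \item{quartile}{four empirical quartile bins `Q1`..`Q4`.}
#'   \item{fixed_cutpoint}{user-supplied boundaries via `cutpoints`.}
#' }
#' Boundary ties always go to the lower stratum (bins are closed on the
#' right): a score exactly at a boundary belongs to the stratum below it.
#'
#' @param scores a `CESResult` or named numeric vector.
#' @param mode stratification mode (see Details).
#' @param cutpoints strictly increasing numeric boundaries, only for
#'   `fixed_cutpoint`.
#' @return A `StrataAssignment`: list with `strata` (named factor), `mode`,
#'   `boundaries`.
#' @export
stratify <- function(scores,
                     mode = c("quantile_tertile", "range_tertile",
                              "top_tertile_vs_rest", "quartile",
                              "fixed_cutpoint"),
                     cutpoints = NULL) {
  mode <- match.arg(mode)
  s <- ces_scores(scores)
  if (any(!is.finite(s))) stop("scores must be finite", call. = FALSE)
  ndist <- length(unique(s))
  if (ndist == 1L) {
    stop("degenerate stratification: all scores are equal", call. = FALSE)
  }
  need <- switch(mode, quartile = 4L, fixed_cutpoint = 2L, 3L)
  if (ndist < need) {
    stop(sprintf("mode '%s' needs >= %d distinct scores, got %d",
                 mode, need, ndist), call. = FALSE)
  }
  assign_bins <- function(bounds, labels) {
    # right-closed bins: score <= bounds[1] -> labels[1], etc.
    idx <- rowSums(outer(s, bounds, `>`)) + 1L
    factor(labels[idx], levels = labels)
  }
  res <- switch(mode,
    quantile_tertile = {
      b <- unname(stats::quantile(s, c(1, 2) / 3))
      list(strata = assign_bins(b, c("low", "intermediate", "high")),
           boundaries = b)
    },
    range_tertile = {
      b <- min(s) + diff(range(s)) * c(1, 2) / 3
      list(strata = assign_bins(b, c("low", "intermediate", "high")),
           boundaries = b)
    },
    top_tertile_vs_rest = {
      b <- unname(stats::quantile(s, 2 / 3))
      list(strata = assign_bins(b, c("low", "high")), boundaries = b)
    },
    quartile = {
      b <- unname(stats::quantile(s, c(1, 2, 3) / 4))
      list(strata = assign_bins(b, c("Q1", "Q2", "Q3", "Q4")),
           boundaries = b)
    },
    fixed_cutpoint = {
      if (is.null(cutpoints) || any(diff(cutpoints) <= 0)) {
        stop("fixed_cutpoint needs strictly increasing `cutpoints`",
             call. = FALSE)
      }
      labels <- paste0("bin", seq_len(length(cutpoints) + 1L))
      list(strata = assign_bins(cutpoints, labels), boundaries = cutpoints)
    }
  )
  names(res$strata) <- names(s)
  structure(list(strata = res$strata, mode = mode,
                 boundaries = res$boundaries),
            class = "StrataAssignment")
}

#' @export
print.StrataAssignment <- function(x, ...) {
  cat(sprintf("StrataAssignment [%s], boundaries: %s\n", x$mode,
              paste(signif(x$boundaries, 5), collapse = ", ")))
  print(table(x$strata))
  invisible(x)
}

#' Minimal-p cutpoint scan for a survival split
#'
#' Scans candidate CES cutoffs over the unique observed scores clipped to
#' the 10th-90th percentile interval and returns the cutoff whose two-group
#' (score > cutoff vs score <= cutoff) log-rank p-value is smallest. The
#' returned p-value is a minimal p over the scan and is NOT corrected for
#' the selection; treat it as exploratory.
#'
#' @param scores `CESResult` or named numeric vector.
#' @param cohort data frame with columns `sample_id`, `time`, `event`.
#' @param min_n cohort-size floor; cohorts smaller than this are refused
#'   (default 30).
#' @return list with `cutoff`, `p` (uncorrected minimal p), `statistic`,
#'   `assignment` (named factor low/high), `grid` (data frame of all
#'   candidate cutoffs and p-values), `minimal_p = TRUE`.
#' @export
best_cutpoint <- function(scores, cohort, min_n = 30L) {
  s <- ces_scores(scores)
  cohort <- as.data.frame(cohort)
  stopifnot(all(c("sample_id", "time", "event") %in% names(cohort)))
  ids <- intersect(names(s), as.character(cohort$sample_id))
  if (length(ids) < min_n) {
    stop(sprintf("cohort too small: %d matched subjects < floor of %d",
                 length(ids), min_n), call. = FALSE)
  }
  cohort <- cohort[match(ids, as.character(cohort$sample_id)), ]
  s <- s[ids]
  lim <- stats::quantile(s, c(0.1, 0.9))
  cand <- sort(unique(s))
  cand <- cand[cand >= lim[1] & cand <= lim[2]]
  cand <- cand[cand < max(s)]  # must leave a non-empty high group
  scan <- lapply(cand, function(cut) {
    grp <- factor(ifelse(s > cut, "high", "low"), levels = c("low", "high"))
    if (sum(cohort$event[grp == "high"]) < 1 ||
        sum(cohort$event[grp == "low"]) < 1) return(NULL)
    sd <- survival::survdiff(survival::Surv(cohort$time, cohort$event) ~ grp)
    p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
    data.frame(cutoff = cut, statistic = sd$chisq, p = p)
  })
  scan <- do.call(rbind, scan)
  if (is.null(scan) || nrow(scan) == 0L) {
    stop("no admissible cutoff: every candidate split leaves a group ",
         "without events", call. = FALSE)
  }
  best <- scan[which.min(scan$p), ]
  assignment <- factor(ifelse(s > best$cutoff, "high", "low"),
                       levels = c("low", "high"))
  names(assignment) <- ids
  list(cutoff = best$cutoff, p = best$p, statistic = best$statistic,
       assignment = assignment, grid = scan, minimal_p = TRUE)
}

#' Export CES scores and strata as a table
#' @param scores a `CESResult`.
#' @param strata optional `StrataAssignment` on the same samples.
#' @param path optional file; when given, written tab-delimited.
#' @return data frame with `sample_id`, `score` and (optionally) `stratum`.
#' @export
ces_table <- function(scores, strata = NULL, path = NULL) {
  stopifnot(inherits(scores, "CESResult"))
  df <- data.frame(sample_id = names(scores$scores),
                   score = unname(scores$scores),
                   stringsAsFactors = FALSE)
  if (!is.null(strata)) {
    stopifnot(inherits(strata, "StrataAssignment"))
    df$stratum <- as.character(strata$strata[df$sample_id])
  }
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
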