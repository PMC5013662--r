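#' Spearman correlations with a joint FDR family
#'
#' Computes Spearman's rank correlation (average ranks for ties, two-tailed
#' p via the t approximation) for each group x metric row and adjusts all
#' rows jointly with Benjamini-Hochberg, matching a single-FDR-column table
#' layout. Rows with a constant vector are reported with `NA` and a note and
#' are excluded from the FDR family.
#'
#' @param tables data frame with columns `group`, `metric`, `score`, `value`
#'   (one row per paired observation), or a named list of
#'   `list(score =, value =)` pairs (then `metric` is the list name and
#'   `group` is `"all"`).
#' @return data frame (class `AssociationResult`) with `group`, `metric`,
#'   `r_s`, `p`, `q`, `n`, `note`.
#' @export
spearman_with_fdr <- function(tables) {
  if (is.list(tables) && !is.data.frame(tables)) {
    tables <- do.call(rbind, lapply(names(tables), function(nm) {
      data.frame(group = "all", metric = nm,
                 score = tables[[nm]]$score, value = tables[[nm]]$value,
                 stringsAsFactors = FALSE)
    }))
  }
  tables <- as.data.frame(tables)
  stopifnot(all(c("group", "metric", "score", "value") %in% names(tables)))
  keys <- unique(tables[, c("group", "metric")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- tables[tables$group == keys$group[i] &
                  tables$metric == keys$metric[i], ]
    n <- nrow(sub)
    if (n < 3L) {
      return(data.frame(group = keys$group[i], metric = keys$metric[i],
                        r_s = NA_real_, p = NA_real_, n = n,
                        note = "n < 3", stringsAsFactors = FALSE))
    }
    if (length(unique(sub$score)) == 1L || length(unique(sub$value)) == 1L) {
      return(data.frame(group = keys$group[i], metric = keys$metric[i],
                        r_s = NA_real_, p = NA_real_, n = n,
                        note = "degenerate: constant vector",
                        stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(
      stats::cor.test(sub$score, sub$value, method = "spearman",
                      exact = FALSE))
    data.frame(group = keys$group[i], metric = keys$metric[i],
               r_s = unname(ct$estimate), p = ct$p.value, n = n,
               note = "", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  ok <- !is.na(res$p)
  res$q[ok] <- stats::p.adjust(res$p[ok], method = "BH")
  res <- res[, c("group", "metric", "r_s", "p", "q", "n", "note")]
  class(res) <- c("AssociationResult", "data.frame")
  res
}

#' Rank-based group comparison of scores
#'
#' Two groups: Wilcoxon rank-sum with normal approximation and tie
#' correction. Three or more groups: Kruskal-Wallis.
#'
#' @param scores numeric vector.
#' @param groups factor/character of the same length.
#' @param mode `"auto"` (default; picks by group count), `"two_group"`, or
#'   `"k_group"`.
#' @return list with `statistic`, `p`, `test`, `n_per_group`.
#' @export
rank_test <- function(scores, groups, mode = c("auto", "two_group",
                                               "k_group")) {
  mode <- match.arg(mode)
  groups <- factor(groups)
  if (length(scores) != length(groups)) {
    stop("scores and groups differ in length", call. = FALSE)
  }
  tab <- table(groups)
  if (length(tab) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(tab < 2L)) {
    stop("each group needs >= 2 observations; smallest has ", min(tab),
         call. = FALSE)
  }
  if (mode == "auto") mode <- if (length(tab) == 2L) "two_group" else "k_group"
  if (mode == "two_group") {
    if (length(tab) != 2L) stop("two_group mode requires exactly 2 groups",
                                call. = FALSE)
    # plain normal approximation (tie-corrected variance, no continuity
    # correction), as documented
    ht <- suppressWarnings(
      stats::wilcox.test(scores ~ groups, exact = FALSE, correct = FALSE))
    test <- "wilcoxon_rank_sum"
  } else {
    ht <- stats::kruskal.test(scores ~ groups)
    test <- "kruskal_wallis"
  }
  list(statistic = unname(ht$statistic), p = ht$p.value, test = test,
       n_per_group = as.vector(tab))
}

#' Enrichment of a categorical factor across CES strata
#'
#' Builds the factor-levels x strata contingency table and tests
#' independence. Policy: chi-square without continuity correction by
#' default; Fisher's exact test when the table is 2x2 and any expected cell
#' count is below 5. The test actually used is recorded.
#'
#' @param strata a `StrataAssignment` or named factor.
#' @param factor_values named categorical covariate (names = sample ids).
#' @param test_policy `"auto"` (default), `"chisq"`, or `"fisher"`.
#' @return list (class `ContingencyResult`) with `table`, `test`, `p`,
#'   `statistic` (chi-square only), `percent` (column percentages).
#' @export
categorical_enrichment <- function(strata, factor_values,
                                   test_policy = c("auto", "chisq",
                                                   "fisher")) {
  test_policy <- match.arg(test_policy)
  st <- if (inherits(strata, "StrataAssignment")) strata$strata else strata
  if (is.null(names(st)) || is.null(names(factor_values))) {
    stop("strata and factor must be named by sample id", call. = FALSE)
  }
  ids <- intersect(names(st), names(factor_values))
  if (!length(ids)) stop("no shared sample ids between strata and factor",
                         call. = FALSE)
  tab <- table(factor = factor(factor_values[ids]),
               stratum = factor(st[ids]))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (any(dim(tab) < 2L)) {
    stop("contingency table degenerate after dropping empty levels",
         call. = FALSE)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use_fisher <- switch(test_policy,
    fisher = TRUE,
    chisq = FALSE,
    auto = all(dim(tab) == 2L) && any(expected < 5))
  if (use_fisher) {
    ht <- stats::fisher.test(tab)
    stat <- NA_real_
    test <- "fisher_exact"
  } else {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    stat <- unname(ht$statistic)
    test <- "chi_square"
  }
  structure(list(table = tab, test = test, p = ht$p.value, statistic = stat,
                 percent = prop.table(tab, margin = 1L) * 100),
            class = "ContingencyResult")
}

#' @export
print.ContingencyResult <- function(x, ...) {
  cat(sprintf("ContingencyResult [%s], p = %.4g\n", x$test, x$p))
  print(x$table)
  invisible(x)
}

#' Co-expression network by correlation thresholding
#'
#' Pearson correlations over samples between all gene pairs; pairs with
#' `r >= threshold` become undirected edges. Constant genes are excluded
#' with a note.
#'
#' @param x an `ExpressionMatrix` (log2 scale recommended; converted if
#'   linear).
#' @param threshold minimum correlation for an edge (default 0.4).
#' @return list with `edges` (data frame `gene1`, `gene2`, `r`), `degrees`
#'   (named integer, all retained genes), `excluded` (constant genes).
#' @export
coexpression_network <- function(x, threshold = 0.4) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (ncol(x$values) < 3L) stop("need >= 3 samples", call. = FALSE)
  x <- as_log2(x)
  sds <- apply(x$values, 1L, stats::sd)
  excluded <- gene_ids(x)[sds == 0]
  v <- x$values[sds > 0, , drop = FALSE]
  if (nrow(v) < 2L) stop("fewer than 2 non-constant genes", call. = FALSE)
  cm <- stats::cor(t(v))
  idx <- which(upper.tri(cm) & cm >= threshold, arr.ind = TRUE)
  edges <- data.frame(gene1 = rownames(cm)[idx[, 1]],
                      gene2 = colnames(cm)[idx[, 2]],
                      r = cm[idx], stringsAsFactors = FALSE)
  edges <- edges[order(-edges$r), , drop = FALSE]
  rownames(edges) <- NULL
  degrees <- stats::setNames(integer(nrow(v)), rownames(v))
  if (nrow(edges)) {
    dt <- table(c(edges$gene1, edges$gene2))
    degrees[names(dt)] <- as.integer(dt)
  }
  list(edges = edges, degrees = degrees, excluded = excluded,
       threshold = threshold)
}

#' Qn robust scale estimate
#'
#' Location-free scale estimator based on pairwise differences: the raw
#' kernel is the k-th order statistic of `{|x_i - x_j| : i < j}` with
#' `h = floor(n/2) + 1` and `k = choose(h, 2)`. The returned estimate is
#' `2.2219 * d_n * kernel`, where 2.2219 is the Gaussian consistency
#' constant and `d_n` a finite-sample correction. More efficient than the
#' MAD under normality and resistant to a large outlier fraction.
#'
#' For `n <= 500` the kernel is found by enumerating all pairs; for larger
#' `n` by exact selection (binary search on the value combined with
#' two-pointer pair counting), avoiding the O(n^2) memory.
#'
#' @param x numeric vector, `n >= 2`, finite.
#' @return list with `kernel` (raw order statistic), `estimate`
#'   (consistency-scaled), `n`, `constant`, `dn`.
#' @export
qn_scale <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("qn_scale needs n >= 2", call. = FALSE)
  if (any(!is.finite(x))) stop("values must be finite", call. = FALSE)
  h <- n %/% 2L + 1L
  k <- h * (h - 1L) / 2
  xs <- sort(x)
  kernel <- if (n <= 500L) {
    sort(as.vector(stats::dist(xs)))[k]
  } else {
    qn_select_kth(xs, k)
  }
  dn <- qn_dn(n)
  list(kernel = kernel, estimate = 2.2219 * dn * kernel, n = n,
       constant = 2.2219, dn = dn)
}

# finite-sample correction factors (Rousseeuw & Croux style)
qn_dn <- function(n) {
  small <- c(NA, 0.399, 0.994, 0.512, 0.844, 0.611, 0.857, 0.669, 0.872)
  if (n <= 9L) return(small[n])
  if (n %% 2L == 0L) n / (n + 3.8) else n / (n + 1.4)
}

# number of pairs i<j with xs[j] - xs[i] <= t, xs sorted; O(n)
qn_count_le <- function(xs, t) {
  n <- length(xs)
  i <- 1L
  cnt <- 0
  for (j in seq_len(n)) {
    while (xs[j] - xs[i] > t) i <- i + 1L
    cnt <- cnt + (j - i)
  }
  cnt
}

# exact k-th smallest pairwise difference via bisection on the value
qn_select_kth <- function(xs, k) {
  lo <- 0
  hi <- xs[length(xs)] - xs[1]
  if (qn_count_le(xs, 0) >= k) return(0)
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    if (mid == lo || mid == hi) break
    if (qn_count_le(xs, mid) >= k) hi <- mid else lo <- mid
  }
  hi
}

#' CES-vs-drug-sensitivity analysis
#'
#' (i) Optionally excludes cell lines with extreme IC50, defined as
#' `log(IC50) > median + 3 * Qn` of the log-IC50 distribution (one-sided,
#' above the median only; IC50s span orders of magnitude and are log-normal
#' to first order, so the rule is applied on the scale on which they are
#' analysed); (ii) bins the remaining lines into CES quartiles and
#' compares IC50 between top and bottom quartiles by Wilcoxon rank-sum;
#' (iii) reports Spearman correlation between CES and IC50 overall and per
#' tissue group (IC50 analysed on log scale; rank statistics are unaffected
#' by the log).
#'
#' @param ces a `CESResult` or named numeric scores for the cell lines.
#' @param drugs data frame with columns `cell_line`, `ic50` (> 0), and
#'   optionally `tissue`.
#' @param exclude_extremes apply the Qn exclusion rule (default `TRUE`).
#' @param min_group smallest tissue group analysed (default 3; smaller
#'   groups are skipped with a note).
#' @return list with `excluded` (flagged cell-line ids), `quartile_test`
#'   (Wilcoxon top-vs-bottom quartile), `spearman` (`AssociationResult`
#'   across tissues + pooled), `strata`, `n_used`, `skipped_tissues`.
#' @export
drug_sensitivity_analysis <- function(ces, drugs, exclude_extremes = TRUE,
                                      min_group = 3L) {
  s <- ces_scores(ces)
  drugs <- as.data.frame(drugs)
  stopifnot(all(c("cell_line", "ic50") %in% names(drugs)))
  if (any(drugs$ic50 <= 0)) stop("IC50 values must be positive",
                                 call. = FALSE)
  drugs$cell_line <- as.character(drugs$cell_line)
  ids <- intersect(names(s), drugs$cell_line)
  if (length(ids) < 8L) {
    stop("need >= 8 matched cell lines, got ", length(ids), call. = FALSE)
  }
  drugs <- drugs[match(ids, drugs$cell_line), ]
  s <- s[ids]
  excluded <- character(0)
  if (exclude_extremes) {
    lg <- log(drugs$ic50)
    cut <- stats::median(lg) + 3 * qn_scale(lg)$estimate
    flag <- lg > cut
    excluded <- drugs$cell_line[flag]
    drugs <- drugs[!flag, ]
    s <- s[drugs$cell_line]
  }
  strata <- stratify(s, mode = "quartile")
  top <- names(strata$strata)[strata$strata == "Q4"]
  bottom <- names(strata$strata)[strata$strata == "Q1"]
  ic50 <- stats::setNames(drugs$ic50, drugs$cell_line)
  wt <- suppressWarnings(stats::wilcox.test(ic50[top], ic50[bottom],
                                            exact = FALSE))
  tissue <- if ("tissue" %in% names(drugs)) as.character(drugs$tissue)
            else rep("all", nrow(drugs))
  tabs <- data.frame(group = c(tissue, rep("pooled", nrow(drugs))),
                     metric = "ic50",
                     score = c(s, s),
                     value = log(c(drugs$ic50, drugs$ic50)),
                     stringsAsFactors = FALSE)
  sizes <- table(tissue)
  skipped <- names(sizes)[sizes < min_group]
  tabs <- tabs[!tabs$group %in% skipped, ]
  sp <- spearman_with_fdr(tabs)
  list(excluded = excluded,
       quartile_test = list(statistic = unname(wt$statistic), p = wt$p.value,
                            n_top = length(top), n_bottom = length(bottom),
                            median_top = stats::median(ic50[top]),
                            median_bottom = stats::median(ic50[bottom])),
       spearman = sp, strata = strata, n_used = nrow(drugs),
       skipped_tissues = skipped)
}
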