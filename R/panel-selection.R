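#' Tumour-vs-normal differential expression for one dataset
#'
#' Per-gene comparison of tumour against normal samples on log2 scale.
#' The fold change is the difference of log2 means (i.e. the log2 ratio of
#' geometric means). Two engines:
#' \describe{
#'   \item{welch_log2}{Welch two-sample t-test on log2 values (default).}
#'   \item{moderated}{SAM-style d-statistic `d = (m_T - m_N) / (s + s0)` with
#'     the variance-stabilising offset `s0` set to the median per-gene
#'     standard error; p-values from a label-permutation null pooled across
#'     genes.}
#' }
#' q-values are Benjamini-Hochberg within the dataset.
#'
#' @param x an `ExpressionMatrix` with `normal` and `tumour` sample roles.
#' @param method `"welch_log2"` or `"moderated"`.
#' @param B permutations for the moderated engine (default 200).
#' @param seed RNG seed for the moderated engine's permutations.
#' @return data frame (class `DEResult`) with columns `gene`, `log2fc`,
#'   `p`, `q`, `direction` (`"up"`/`"down"`/`"none"`).
#' @export
differential_expression <- function(x, method = c("welch_log2", "moderated"),
                                    B = 200L, seed = 1L) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  method <- match.arg(method)
  x <- as_log2(x)
  ni <- which(x$sample_roles == "normal")
  ti <- which(x$sample_roles == "tumour")
  if (length(ni) < 2L || length(ti) < 2L) {
    stop(sprintf("need >= 2 samples per class, got %d normal / %d tumour",
                 length(ni), length(ti)), call. = FALSE)
  }
  v <- x$values
  mn <- rowMeans(v[, ni, drop = FALSE])
  mt <- rowMeans(v[, ti, drop = FALSE])
  vn <- apply(v[, ni, drop = FALSE], 1L, stats::var)
  vt <- apply(v[, ti, drop = FALSE], 1L, stats::var)
  log2fc <- mt - mn
  if (method == "welch_log2") {
    se2n <- vn / length(ni)
    se2t <- vt / length(ti)
    se <- sqrt(se2n + se2t)
    tstat <- ifelse(se > 0, log2fc / se, 0)
    df <- (se2n + se2t)^2 /
      (se2n^2 / (length(ni) - 1L) + se2t^2 / (length(ti) - 1L))
    df[!is.finite(df)] <- length(ni) + length(ti) - 2L
    p <- 2 * stats::pt(-abs(tstat), df)
    p[se == 0] <- 1
  } else {
    s <- sqrt(vn / length(ni) + vt / length(ti))
    s0 <- stats::median(s)
    d <- log2fc / (s + s0)
    set.seed(seed)
    n <- ncol(v)
    null_d <- matrix(NA_real_, nrow(v), B)
    for (b in seq_len(B)) {
      perm <- sample.int(n)
      pni <- perm[seq_along(ni)]
      pti <- perm[length(ni) + seq_along(ti)]
      pmn <- rowMeans(v[, pni, drop = FALSE])
      pmt <- rowMeans(v[, pti, drop = FALSE])
      ps <- sqrt(apply(v[, pni, drop = FALSE], 1L, stats::var) / length(ni) +
                 apply(v[, pti, drop = FALSE], 1L, stats::var) / length(ti))
      null_d[, b] <- (pmt - pmn) / (ps + s0)
    }
    pool <- abs(as.vector(null_d))
    # pooled permutation null across genes, add-one estimator
    p <- (1 + vapply(abs(d), function(di) sum(pool >= di), 0L)) /
      (1 + length(pool))
  }
  q <- stats::p.adjust(p, method = "BH")
  res <- data.frame(gene = rownames(v), log2fc = log2fc, p = p, q = q,
                    direction = ifelse(log2fc > 0, "up",
                                       ifelse(log2fc < 0, "down", "none")),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("DEResult", "data.frame")
  attr(res, "method") <- method
  res
}

#' Cross-dataset prevalence filter for overexpressed genes
#'
#' A gene passes a dataset when its FDR-adjusted q is at most `q_max`, its
#' (linear) fold change is at least `min_fold` and its direction is up.
#' The returned set contains genes that pass in at least
#' `ceiling(prevalence * n_datasets)` datasets: "at least 50 percent" is
#' resolved with a ceiling, so an odd dataset count requires a strict
#' majority.
#'
#' @param results list of `DEResult` data frames, one per dataset.
#' @param q_max FDR ceiling (default 0.05).
#' @param min_fold minimum linear fold change (default 2).
#' @param prevalence required fraction of datasets (default 0.5).
#' @return character vector of gene ids, with a `pass_counts` attribute
#'   (named integer vector over all genes seen).
#' @export
cross_dataset_filter <- function(results, q_max = 0.05, min_fold = 2,
                                 prevalence = 0.5) {
  if (!length(results)) stop("need at least one DEResult", call. = FALSE)
  counts <- list()
  for (res in results) {
    res <- as.data.frame(res)
    pass <- res$q <= q_max & res$log2fc >= log2(min_fold) &
      res$direction == "up"
    for (g in res$gene) counts[[g]] <- (counts[[g]] %||% 0L)
    for (g in res$gene[pass]) counts[[g]] <- counts[[g]] + 1L
  }
  counts <- unlist(counts)
  need <- ceiling(prevalence * length(results))
  out <- names(counts)[counts >= need]
  attr(out, "pass_counts") <- counts
  attr(out, "required_datasets") <- need
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permutation test for overexpression of one gene
#'
#' Tests whether the observed tumour-minus-normal log2 fold change is larger
#' than expected after randomizing the sample labels. The p-value uses the
#' add-one estimator `p = (1 + #{permuted fc >= observed}) / (B + 1)`, so it
#' can never be zero.
#'
#' @param x an `ExpressionMatrix` with `normal` and `tumour` roles.
#' @param gene gene id.
#' @param B number of permutations (>= 99; default 999).
#' @param seed RNG seed.
#' @return list (class `PermutationResult`) with `gene`, `observed_log2fc`,
#'   `B`, `p_perm`, `degenerate`.
#' @export
permutation_overexpression_test <- function(x, gene, B = 999L, seed = 1L) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (B < 99L) stop("B must be >= 99", call. = FALSE)
  x <- as_log2(x)
  if (!gene %in% gene_ids(x)) stop("gene not in matrix: ", gene,
                                   call. = FALSE)
  ni <- which(x$sample_roles == "normal")
  ti <- which(x$sample_roles == "tumour")
  if (!length(ni) || !length(ti)) {
    stop("both normal and tumour samples are required", call. = FALSE)
  }
  vals <- x$values[gene, c(ni, ti)]
  is_t <- c(rep(FALSE, length(ni)), rep(TRUE, length(ti)))
  obs <- mean(vals[is_t]) - mean(vals[!is_t])
  degenerate <- stats::var(vals) == 0
  if (degenerate) {
    warning("gene '", gene, "' is constant; p_perm set to 1", call. = FALSE)
    p <- 1
  } else {
    set.seed(seed)
    n <- length(vals)
    perm_fc <- vapply(seq_len(B), function(b) {
      pv <- vals[sample.int(n)]
      mean(pv[is_t]) - mean(pv[!is_t])
    }, 0)
    p <- (1 + sum(perm_fc >= obs)) / (B + 1)
  }
  structure(list(gene = gene, observed_log2fc = obs, B = as.integer(B),
                 p_perm = p, degenerate = degenerate),
            class = "PermutationResult")
}

#' Derive the core panel from upregulation and prognostic evidence
#'
#' Implements the Venn intersection: a gene enters the panel when it is in
#' the consistently-upregulated set and appears in at least one prognostic
#' evidence set. A gene supported by any single evidence source is kept
#' (platform-limited sources may lack probes for genes that other sources
#' cover).
#'
#' @param upregulated character vector of consistently upregulated genes.
#' @param prognostic_evidence named list of character vectors, one per
#'   evidence source.
#' @param name panel name for the result (default `"derived"`).
#' @return A `GenePanel` with a `provenance` attribute (data frame mapping
#'   each member to the evidence sources supporting it).
#' @export
derive_panel <- function(upregulated, prognostic_evidence, name = "derived") {
  upregulated <- as.character(upregulated)
  if (!length(upregulated)) stop("upregulated set is empty", call. = FALSE)
  if (!is.list(prognostic_evidence) || is.null(names(prognostic_evidence))) {
    stop("prognostic_evidence must be a named list of gene sets",
         call. = FALSE)
  }
  support <- lapply(upregulated, function(g) {
    names(prognostic_evidence)[vapply(prognostic_evidence,
                                      function(s) g %in% s, TRUE)]
  })
  keep <- lengths(support) > 0L
  if (!any(keep)) {
    stop("empty panel: no upregulated gene has prognostic evidence",
         call. = FALSE)
  }
  panel <- gene_panel(name, upregulated[keep])
  attr(panel, "provenance") <- data.frame(
    gene = upregulated[keep],
    evidence = vapply(support[keep], paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  panel
}
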