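#' Construct an expression matrix
#'
#' The package's central container: a numeric genes x samples matrix with a
#' declared scale (`"linear"` or `"log2"`) and a per-sample role label.
#' Microarray series-matrix exports are typically already on log2 scale;
#' RNA-seq normalized counts are linear and are converted with `log2(x + 1)`
#' where a log2 scale is required.
#'
#' @param values numeric matrix, genes in rows, samples in columns; must have
#'   unique, non-empty row and column names.
#' @param scale `"linear"` or `"log2"`.
#' @param sample_roles character vector, one of `"normal"`, `"tumour"`,
#'   `"cell_line"`, `"unknown"` per sample. Recycled if length 1.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, scale = c("log2", "linear"),
                              sample_roles = "unknown") {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene (row) and sample (column) names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate gene ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    stop("duplicate sample ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("expression values must all be finite", call. = FALSE)
  }
  if (scale == "linear" && any(values < 0)) {
    stop("linear-scale expression values must be non-negative", call. = FALSE)
  }
  roles <- rep_len(as.character(sample_roles), ncol(values))
  ok <- roles %in% c("normal", "tumour", "cell_line", "unknown")
  if (!all(ok)) {
    stop("invalid sample roles: ", paste(unique(roles[!ok]), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(values = values, scale = scale,
         sample_roles = stats::setNames(roles, colnames(values))),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat("roles:", paste(sprintf("%s=%d", names(table(x$sample_roles)),
                              table(x$sample_roles)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Subset an ExpressionMatrix by samples
#' @param x an `ExpressionMatrix`.
#' @param samples sample ids or logical/integer index.
#' @return An `ExpressionMatrix` restricted to the selected samples.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- x$values[, samples, drop = FALSE]
  expression_matrix(v, scale = x$scale,
                    sample_roles = x$sample_roles[colnames(v)])
}

#' Convert an ExpressionMatrix to log2 scale
#'
#' Linear values are transformed with `log2(x + 1)`; the pseudocount keeps
#' zeros finite. A matrix already on log2 scale is returned unchanged.
#' @param x an `ExpressionMatrix`.
#' @return An `ExpressionMatrix` on log2 scale.
#' @export
as_log2 <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale == "log2") return(x)
  expression_matrix(log2(x$values + 1), scale = "log2",
                    sample_roles = x$sample_roles)
}

#' Read a tab-delimited expression table
#'
#' Reads the series-matrix-like dialect: optional `#scale:` and `#roles:`
#' comment lines, then a header row and a first column of feature ids.
#' Tables may be oriented either way; `dialect` declares which.
#'
#' @param path file path.
#' @param dialect `"genes_by_samples"` (default) or `"samples_by_genes"`.
#' @param scale declared scale; if `NULL`, taken from the `#scale:` header
#'   (defaulting to `"log2"` when absent).
#' @param sample_roles optional roles; if `NULL`, taken from the `#roles:`
#'   header when present, else `"unknown"`.
#' @return An `ExpressionMatrix` oriented genes x samples.
#' @export
read_expression_table <- function(path,
                                  dialect = c("genes_by_samples",
                                              "samples_by_genes"),
                                  scale = NULL, sample_roles = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) < 2L) stop("expression table has no data rows: ", path,
                              call. = FALSE)
  if (is.null(scale)) {
    m <- grep("^#\\s*scale\\s*:", hdr, value = TRUE)
    scale <- if (length(m)) trimws(sub("^#\\s*scale\\s*:", "", m[1])) else "log2"
  }
  if (is.null(sample_roles)) {
    m <- grep("^#\\s*roles\\s*:", hdr, value = TRUE)
    if (length(m)) {
      sample_roles <- trimws(strsplit(sub("^#\\s*roles\\s*:", "", m[1]),
                                      ",")[[1]])
    } else {
      sample_roles <- "unknown"
    }
  }
  cells <- strsplit(body, "\t", fixed = TRUE)
  ncell <- lengths(cells)
  if (length(unique(ncell)) != 1L) {
    bad <- which(ncell != ncell[1])[1]
    stop(sprintf("ragged table: row %d has %d fields, expected %d",
                 bad, ncell[bad], ncell[1]), call. = FALSE)
  }
  header <- cells[[1]][-1]
  ids <- vapply(cells[-1], `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate row ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(header)) {
    stop("duplicate column ids: ",
         paste(unique(header[duplicated(header)]), collapse = ", "),
         call. = FALSE)
  }
  raw <- vapply(cells[-1], function(r) r[-1], character(length(header)))
  raw <- if (length(header) == 1L) matrix(raw, nrow = 1L) else raw
  # raw is columns-of-file x rows-of-file; transpose back
  num <- suppressWarnings(as.numeric(raw))
  if (anyNA(num)) {
    bad <- which(is.na(num))[1]
    col_i <- (bad - 1L) %% length(header) + 1L
    row_i <- (bad - 1L) %/% length(header) + 1L
    stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                 ids[row_i], header[col_i], raw[bad]), call. = FALSE)
  }
  m <- matrix(num, nrow = length(ids), ncol = length(header), byrow = TRUE,
              dimnames = list(ids, header))
  if (dialect == "samples_by_genes") m <- t(m)
  expression_matrix(m, scale = scale, sample_roles = sample_roles)
}

#' Write an ExpressionMatrix as a tab-delimited table
#'
#' Emits `#scale:` and `#roles:` comment lines followed by a genes x samples
#' table; `read_expression_table()` on the result is a fixed point.
#' @param x an `ExpressionMatrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#scale: ", x$scale),
               paste0("#roles: ", paste(x$sample_roles, collapse = ","))),
             con)
  writeLines(paste(c("feature_id", colnames(x$values)), collapse = "\t"), con)
  body <- apply(x$values, 1L, function(r)
    paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(x$values), body, sep = "\t"), con)
  invisible(path)
}

#' Collapse a probe-level matrix to gene level
#'
#' @param x probe-level `ExpressionMatrix`.
#' @param probe_map data frame with columns `probe_id`, `gene_id`
#'   (many probes to one gene).
#' @param method `"mean_log2"` (default): average probes on log2 scale;
#'   `"max_mean_probe"`: keep the probe with the highest across-sample mean.
#' @return A gene-level `ExpressionMatrix` on log2 scale. Genes in the map
#'   with no probe present in `x` are reported in the `missing_genes`
#'   attribute rather than silently dropped.
#' @export
collapse_probes <- function(x, probe_map,
                            method = c("mean_log2", "max_mean_probe")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  method <- match.arg(method)
  pm <- as.data.frame(probe_map)
  if (!all(c("probe_id", "gene_id") %in% names(pm))) {
    stop("probe_map needs columns probe_id, gene_id", call. = FALSE)
  }
  if (anyDuplicated(pm$probe_id)) {
    stop("probe_map assigns some probe to more than one gene", call. = FALSE)
  }
  x <- as_log2(x)
  pm <- pm[pm$probe_id %in% gene_ids(x), , drop = FALSE]
  missing <- setdiff(unique(as.character(probe_map$gene_id)),
                     unique(as.character(pm$gene_id)))
  if (nrow(pm) == 0L) stop("no mapped probes present in matrix", call. = FALSE)
  genes <- unique(as.character(pm$gene_id))
  out <- matrix(NA_real_, length(genes), ncol(x$values),
                dimnames = list(genes, colnames(x$values)))
  for (g in genes) {
    probes <- pm$probe_id[pm$gene_id == g]
    sub <- x$values[probes, , drop = FALSE]
    out[g, ] <- if (method == "mean_log2") {
      colMeans(sub)
    } else {
      sub[which.max(rowMeans(sub)), ]
    }
  }
  res <- expression_matrix(out, scale = "log2", sample_roles = x$sample_roles)
  attr(res, "missing_genes") <- missing
  attr(res, "collapse_method") <- method
  res
}

#' Construct a gene panel
#' @param name panel name.
#' @param genes character vector of unique gene ids.
#' @return A `GenePanel` object.
#' @export
gene_panel <- function(name, genes) {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("panel '", name, "' is empty", call. = FALSE)
  if (anyDuplicated(genes)) {
    stop("panel '", name, "' has duplicate genes: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(name = name, genes = genes), class = "GenePanel")
}

#' @export
print.GenePanel <- function(x, ...) {
  cat(sprintf("GenePanel '%s' (%d genes): %s\n", x$name, length(x$genes),
              paste(x$genes, collapse = ", ")))
  invisible(x)
}

#' Load a gene panel
#'
#' `source` is either a built-in name — `"cenkt31"` (the 31 structural and
#' assembly centromere/kinetochore genes), `"ces14"` (the 14-gene core CES
#' panel) or `"ces9"` (the simplified panel for HG-U133A-restricted
#' meta-analyses, equal to ces14 minus CENPW, CENPL, CENPK, SPC24, NUF2) —
#' or a path to a one-gene-per-line file (`#` comments allowed).
#'
#' @param source built-in panel name or file path.
#' @return A `GenePanel`.
#' @export
load_gene_panel <- function(source) {
  builtin <- c("cenkt31", "ces14", "ces9")
  if (source %in% builtin) {
    path <- system.file("extdata", "panels", paste0(source, ".txt"),
                        package = "cescore", mustWork = TRUE)
    name <- source
  } else if (file.exists(source)) {
    path <- source
    name <- sub("\\.[^.]*$", "", basename(source))
  } else {
    stop("unknown panel '", source, "': not a built-in (",
         paste(builtin, collapse = ", "), ") and not an existing file",
         call. = FALSE)
  }
  lines <- trimws(readLines(path))
  genes <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (length(genes) == 0L) stop("panel file '", path, "' lists no genes",
                                call. = FALSE)
  gene_panel(name, genes)
}
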