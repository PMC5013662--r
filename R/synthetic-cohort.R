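#' Simulation configuration
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults describe a
#' microarray-like multi-dataset design: 4 tumour/normal datasets of 30+30
#' samples, a 14-gene panel planted at log2 fold change 1.5 over 200
#' background genes with per-gene log2 noise SD 0.5; an exponential
#' proportional-hazards survival process (log hazard 0.7 per standardized
#' CES unit, treatment x high-stratum interaction -0.9, baseline hazard 0.1
#' events per time unit, uniform censoring over 10 time units); a Gaussian
#' copula instability link with target Spearman 0.45; and a cell-line drug
#' response with log-IC50 slope -0.5 per standardized CES unit and 3
#' injected extreme outliers.
#'
#' One global `seed` is expanded into independent per-stream substreams
#' (expression / cohort / instability / drug), so each generator can be
#' rerun independently and reproducibly.
#'
#' @param n_datasets number of expression datasets.
#' @param n_normal,n_tumour samples per class per dataset.
#' @param n_genes_background background (unplanted) genes.
#' @param panel_genes character vector of planted gene ids (default: the
#'   ces14 built-in panel).
#' @param planted_log2fc per-gene tumour-vs-normal log2 fold change (scalar
#'   recycled over `panel_genes`).
#' @param gene_sd per-gene log2-scale noise SD.
#' @param hazard_beta log hazard per unit standardized CES.
#' @param treat_beta additional log hazard for treated subjects in the high
#'   CES stratum (interaction; negative = treatment benefit).
#' @param baseline_hazard events per time unit at CES z = 0, untreated.
#' @param censor_horizon censoring times are uniform on (0, horizon].
#' @param assoc_slope target Spearman correlation between CES and each
#'   instability metric (0 = independence).
#' @param covariate_links list of logit slopes for grade / ER / histology
#'   shifts per standardized CES unit.
#' @param ic50_slope drop in log IC50 per standardized CES unit (> 0 means
#'   higher CES = more sensitive).
#' @param ic50_noise_sd SD of log IC50 noise.
#' @param n_outliers cell lines injected with extreme IC50 (100x the bulk
#'   median).
#' @param n_cell_lines cell lines simulated.
#' @param seed integer global seed.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(n_datasets = 4L, n_normal = 30L, n_tumour = 30L,
                       n_genes_background = 200L, panel_genes = NULL,
                       planted_log2fc = 1.5, gene_sd = 0.5,
                       hazard_beta = 0.7, treat_beta = -0.9,
                       baseline_hazard = 0.1, censor_horizon = 10,
                       assoc_slope = 0.45,
                       covariate_links = list(grade = 0.8, er = 0.8,
                                              histology = 0.8),
                       ic50_slope = 0.5, ic50_noise_sd = 1, n_outliers = 3L,
                       n_cell_lines = 300L, seed = 1L) {
  if (is.null(panel_genes)) panel_genes <- load_gene_panel("ces14")$genes
  counts <- c(n_datasets = n_datasets, n_normal = n_normal,
              n_tumour = n_tumour, n_genes_background = n_genes_background,
              n_cell_lines = n_cell_lines)
  if (any(counts < 1L)) {
    stop("non-positive dimension(s): ",
         paste(names(counts)[counts < 1L], collapse = ", "), call. = FALSE)
  }
  if (gene_sd <= 0 && gene_sd != 0) stop("gene_sd must be >= 0", call. = FALSE)
  if (baseline_hazard < 0) stop("baseline_hazard must be >= 0", call. = FALSE)
  if (censor_horizon <= 0) stop("censor_horizon must be > 0", call. = FALSE)
  if (assoc_slope < 0 || assoc_slope >= 1) {
    stop("assoc_slope must be in [0, 1)", call. = FALSE)
  }
  if (n_outliers < 0 || n_outliers >= n_cell_lines) {
    stop("n_outliers must be in [0, n_cell_lines)", call. = FALSE)
  }
  fc <- rep_len(planted_log2fc, length(panel_genes))
  names(fc) <- panel_genes
  structure(list(
    n_datasets = as.integer(n_datasets), n_normal = as.integer(n_normal),
    n_tumour = as.integer(n_tumour),
    n_genes_background = as.integer(n_genes_background),
    panel_genes = panel_genes, planted_log2fc = fc, gene_sd = gene_sd,
    hazard_beta = hazard_beta, treat_beta = treat_beta,
    baseline_hazard = baseline_hazard, censor_horizon = censor_horizon,
    assoc_slope = assoc_slope, covariate_links = covariate_links,
    ic50_slope = ic50_slope, ic50_noise_sd = ic50_noise_sd,
    n_outliers = as.integer(n_outliers),
    n_cell_lines = as.integer(n_cell_lines), seed = as.integer(seed)),
    class = "SimConfig")
}

# independent substream seeds from the global seed (kept below 2^31)
stream_seed <- function(config, stream) {
  offset <- c(expression = 1L, cohort = 2L, instability = 3L, drug = 4L)
  (as.integer(config$seed) %% 500000000L) * 4L + offset[[stream]]
}

#' Simulate multi-dataset tumour/normal expression matrices
#'
#' Per dataset, each gene gets a baseline log2 mean (uniform on 5-9); normal
#' samples draw `N(mu, gene_sd)` and tumour samples
#' `N(mu + planted_log2fc, gene_sd)`, with the planted shift zero for
#' background genes. Independent normal noise on log2 scale makes planted
#' fold changes exact in expectation.
#'
#' @param config a `SimConfig`.
#' @return list with `datasets` (list of log2 `ExpressionMatrix`) and
#'   `truth` (planted genes, per-dataset realized mean shifts).
#' @export
simulate_expression_datasets <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(stream_seed(config, "expression"))
  bg <- sprintf("BG%04d", seq_len(config$n_genes_background))
  genes <- c(config$panel_genes, bg)
  fc <- c(config$planted_log2fc,
          stats::setNames(rep(0, length(bg)), bg))
  datasets <- vector("list", config$n_datasets)
  realized <- matrix(NA_real_, length(config$panel_genes), config$n_datasets,
                     dimnames = list(config$panel_genes,
                                     paste0("D", seq_len(config$n_datasets))))
  for (d in seq_len(config$n_datasets)) {
    mu <- stats::runif(length(genes), 5, 9)
    nN <- config$n_normal
    nT <- config$n_tumour
    vals <- matrix(stats::rnorm(length(genes) * (nN + nT), sd = config$gene_sd),
                   length(genes), nN + nT)
    vals <- vals + mu + outer(fc, c(rep(0, nN), rep(1, nT)))
    dimnames(vals) <- list(genes,
                           c(sprintf("D%d_N%03d", d, seq_len(nN)),
                             sprintf("D%d_T%03d", d, seq_len(nT))))
    em <- expression_matrix(vals, scale = "log2",
                            sample_roles = c(rep("normal", nN),
                                             rep("tumour", nT)))
    datasets[[d]] <- em
    realized[, d] <-
      rowMeans(vals[config$panel_genes, nN + seq_len(nT), drop = FALSE]) -
      rowMeans(vals[config$panel_genes, seq_len(nN), drop = FALSE])
  }
  names(datasets) <- paste0("D", seq_len(config$n_datasets))
  list(datasets = datasets,
       truth = list(planted_up_genes = config$panel_genes,
                    planted_log2fc = config$planted_log2fc,
                    realized_shift = realized))
}

#' Simulate a clinical cohort keyed to CES
#'
#' Survival times follow an exponential proportional-hazards process with
#' `h = baseline_hazard * exp(hazard_beta * z + treat_beta * treated *
#' 1[high stratum])`, where `z` is the standardized CES and the high stratum
#' is the top quantile tertile. Censoring is independent uniform on
#' (0, censor_horizon]. Grade (ordinal 1-3), ER status and histology are
#' drawn from latent-logistic links whose location shifts with `z` by the
#' `covariate_links` slopes; the treatment flag is randomized 1:1.
#'
#' @param config a `SimConfig`.
#' @param ces named numeric vector, one CES value per subject.
#' @return data frame (CohortTable) with `sample_id`, `time`, `event`,
#'   `endpoint`, `treated`, `stratum`, `grade`, `er_status`, `histology`,
#'   `ces`.
#' @export
simulate_cohort <- function(config, ces) {
  stopifnot(inherits(config, "SimConfig"))
  if (is.null(names(ces))) stop("ces must be named by sample id",
                                call. = FALSE)
  n <- length(ces)
  if (n < 2L) stop("need >= 2 subjects", call. = FALSE)
  set.seed(stream_seed(config, "cohort"))
  z <- if (stats::sd(ces) > 0) as.vector(scale(ces)) else rep(0, n)
  high <- if (stats::sd(ces) > 0) {
    as.integer(stratify(ces, "top_tertile_vs_rest")$strata == "high")
  } else rep(0L, n)
  treated <- stats::rbinom(n, 1L, 0.5)
  rate <- config$baseline_hazard *
    exp(config$hazard_beta * z + config$treat_beta * treated * high)
  t_event <- ifelse(rate > 0, stats::rexp(n) / rate, Inf)
  censor <- stats::runif(n, 0, config$censor_horizon)
  time <- pmin(t_event, censor)
  event <- as.integer(t_event <= censor)
  links <- config$covariate_links
  g_lat <- links$grade * z + stats::rlogis(n)
  grade <- cut(g_lat, c(-Inf, 0, 1.5, Inf), labels = c("1", "2", "3"))
  er_negative <- stats::rbinom(n, 1L,
                               stats::plogis(-0.5 + links$er * z))
  histology <- ifelse(
    stats::rbinom(n, 1L, stats::plogis(-0.5 + links$histology * z)) == 1L,
    "SCC", "ADC")
  data.frame(sample_id = names(ces), time = time, event = event,
             endpoint = "OS", treated = treated,
             stratum = ifelse(high == 1L, "high", "low"),
             grade = as.character(grade),
             er_status = ifelse(er_negative == 1L, "negative", "positive"),
             histology = histology, ces = unname(ces),
             stringsAsFactors = FALSE)
}

#' Simulate per-sample genomic-instability metrics
#'
#' Gaussian-copula monotone link: the normal scores of the CES are mixed
#' with independent noise at the Pearson correlation `2 sin(pi r_s / 6)`
#' that yields the target Spearman `r_s = assoc_slope`; the CNA latent is
#' squashed through a logistic into [0, 1], the mutation latent is
#' exponentiated (both monotone, so the Spearman target is preserved).
#'
#' @param ces named numeric vector of CES values.
#' @param config a `SimConfig` (uses `assoc_slope` and the instability
#'   substream seed).
#' @return data frame with `sample_id`, `cna_fraction` (in [0, 1]),
#'   `mutation_freq` (>= 0).
#' @export
simulate_instability <- function(ces, config) {
  stopifnot(inherits(config, "SimConfig"))
  if (any(!is.finite(ces))) stop("ces must be finite", call. = FALSE)
  n <- length(ces)
  set.seed(stream_seed(config, "instability"))
  u <- if (length(unique(ces)) > 1L) {
    stats::qnorm((rank(ces, ties.method = "average") - 0.5) / n)
  } else rep(0, n)
  rho <- 2 * sin(pi * config$assoc_slope / 6)
  lat_cna <- rho * u + sqrt(1 - rho^2) * stats::rnorm(n)
  lat_mut <- rho * u + sqrt(1 - rho^2) * stats::rnorm(n)
  data.frame(
    sample_id = if (is.null(names(ces))) paste0("S", seq_len(n))
                else names(ces),
    cna_fraction = stats::plogis(1.2 * lat_cna - 1),
    mutation_freq = exp(0.8 * lat_mut + log(30)),
    stringsAsFactors = FALSE)
}

#' Simulate a cell-line panel with drug response
#'
#' Cell lines get a latent proliferation/misregulation activity `a ~ N(0,1)`
#' loaded onto every panel gene (loading 0.8), so the computed CES varies
#' across lines; background genes are pure noise. Log IC50 is
#' `2 - ic50_slope * z(CES) + N(0, ic50_noise_sd)`; `n_outliers` randomly
#' chosen lines then have their IC50 replaced by 100x the bulk median
#' (recorded in the truth).
#'
#' @param config a `SimConfig`.
#' @return list with `expression` (log2 `ExpressionMatrix`, role
#'   `cell_line`), `drugs` (data frame `cell_line`, `ic50`, `tissue`),
#'   `truth` (outlier ids, slope, per-line latent activity).
#' @export
simulate_celllines <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(stream_seed(config, "drug"))
  n <- config$n_cell_lines
  ids <- sprintf("CL%04d", seq_len(n))
  bg <- sprintf("BG%04d", seq_len(config$n_genes_background))
  genes <- c(config$panel_genes, bg)
  a <- stats::rnorm(n)
  mu <- stats::runif(length(genes), 5, 9)
  loading <- c(rep(0.8, length(config$panel_genes)), rep(0, length(bg)))
  vals <- matrix(stats::rnorm(length(genes) * n, sd = config$gene_sd),
                 length(genes), n) + mu + outer(loading, a)
  dimnames(vals) <- list(genes, ids)
  em <- expression_matrix(vals, scale = "log2", sample_roles = "cell_line")
  ces <- colSums(vals[config$panel_genes, , drop = FALSE])
  z <- if (stats::sd(ces) > 0) as.vector(scale(ces)) else rep(0, n)
  log_ic50 <- 2 - config$ic50_slope * z +
    stats::rnorm(n, sd = config$ic50_noise_sd)
  ic50 <- exp(log_ic50)
  outlier_ids <- character(0)
  if (config$n_outliers > 0L) {
    outlier_ids <- sample(ids, config$n_outliers)
    bulk_median <- stats::median(ic50[!ids %in% outlier_ids])
    ic50[ids %in% outlier_ids] <- bulk_median * 100
  }
  tissue <- sample(c("breast", "lung", "ovary", "skin", "cns"), n,
                   replace = TRUE)
  list(expression = em,
       drugs = data.frame(cell_line = ids, ic50 = ic50, tissue = tissue,
                          stringsAsFactors = FALSE),
       truth = list(outlier_ids = sort(outlier_ids),
                    ic50_slope = config$ic50_slope, activity = a))
}
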