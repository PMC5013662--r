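#' Build a pipeline run configuration
#'
#' @param mode `"simulate"` (generate data via [sim_config()]) or `"ingest"`
#'   (read files from `paths`).
#' @param sim a `SimConfig`; required in simulate mode, forbidden in ingest
#'   mode.
#' @param paths named list of input files (`expression`, optionally
#'   `cohort`, `drugs`); required in ingest mode.
#' @param panel panel name or file for scoring (default `"ces14"`).
#' @param strata_mode stratification mode for the main survival analysis.
#' @param stages named logical list of analysis toggles: `de`,
#'   `associations`, `drugs`, `survival`, `treatment`.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed; in simulate mode overrides `sim$seed`.
#' @return A `RunConfig` list.
#' @export
run_config <- function(mode = c("simulate", "ingest"), sim = NULL,
                       paths = NULL, panel = "ces14",
                       strata_mode = "quantile_tertile",
                       stages = list(), out_dir = tempfile("cescore_run_"),
                       seed = 1L) {
  mode <- match.arg(mode)
  defaults <- list(de = TRUE, associations = TRUE, drugs = TRUE,
                   survival = TRUE, treatment = TRUE)
  defaults[names(stages)] <- stages
  if (mode == "simulate" && is.null(sim)) sim <- sim_config(seed = seed)
  if (mode == "simulate" && !is.null(sim)) sim$seed <- as.integer(seed)
  structure(list(mode = mode, sim = sim, paths = paths, panel = panel,
                 strata_mode = strata_mode, stages = defaults,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Validate a pipeline configuration
#'
#' Never throws: returns a character vector of issues, empty when
#' [run_pipeline()] preconditions hold.
#' @param config a `RunConfig`.
#' @return character vector of issues (possibly empty).
#' @export
validate_config <- function(config) {
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)
  if (!inherits(config, "RunConfig")) {
    return("config is not a RunConfig (use run_config())")
  }
  if (!config$mode %in% c("simulate", "ingest")) {
    add("mode: must be 'simulate' or 'ingest'")
  }
  if (config$mode == "simulate") {
    if (is.null(config$sim)) add("sim: simulate mode requires a SimConfig")
    if (!is.null(config$paths)) {
      add("paths: must be absent in simulate mode (exactly one of sim/paths)")
    }
  } else {
    if (!is.null(config$sim)) {
      add("sim: must be absent in ingest mode (exactly one of sim/paths)")
    }
    if (is.null(config$paths$expression)) {
      add("paths$expression: ingest mode requires an expression table")
    } else if (!file.exists(config$paths$expression)) {
      add(paste0("paths$expression: file not found: ",
                 config$paths$expression))
    }
    if (isTRUE(config$stages$survival) && is.null(config$paths$cohort)) {
      add("stages$survival: enabled in ingest mode without paths$cohort")
    }
    if (isTRUE(config$stages$treatment) && is.null(config$paths$cohort)) {
      add("stages$treatment: enabled in ingest mode without paths$cohort")
    }
    if (isTRUE(config$stages$drugs) && is.null(config$paths$drugs)) {
      add("stages$drugs: enabled in ingest mode without paths$drugs")
    }
    if (isTRUE(config$stages$de)) {
      add("stages$de: differential expression needs multi-dataset input; ingest mode supports scoring/associations/survival only")
    }
  }
  if (!config$strata_mode %in% c("quantile_tertile", "range_tertile")) {
    add("strata_mode: main survival stratification must be quantile_tertile or range_tertile")
  }
  issues
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  basename(path)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order (simulate/ingest ->
#' differential expression + prevalence filter -> CES scoring and
#' stratification -> associations -> drug sensitivity -> survival ->
#' treatment-stratified hazards), writing every result as a tab-delimited
#' table under `config$out_dir`. A failure in one optional stage is recorded
#' in the run log and does not abort the others. The run log carries no
#' timestamps, so a rerun under the same configuration reproduces every
#' output file byte-identically.
#'
#' @param config a `RunConfig` (see [run_config()]).
#' @return A `ReportBundle`: list with `manifest` (data frame `file`,
#'   `stage`), `out_dir`, `errors` (named character), `log`.
#' @export
run_pipeline <- function(config) {
  issues <- validate_config(config)
  if (length(issues)) {
    stop("invalid configuration:\n  - ", paste(issues, collapse = "\n  - "),
         call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  errors <- character(0)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  emit <- function(df, name, stage) {
    f <- write_tsv(df, file.path(config$out_dir, name))
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = f, stage = stage, stringsAsFactors = FALSE)
    say("[%s] wrote %s", stage, f)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      say("[%s] ERROR: %s", name, conditionMessage(e))
      NULL
    })
  }
  say("pipeline start: mode=%s seed=%d panel=%s strata=%s",
      config$mode, config$seed, config$panel, config$strata_mode)

  panel <- load_gene_panel(config$panel)

  # --- data stage -----------------------------------------------------
  if (config$mode == "simulate") {
    sim <- config$sim
    expr_sets <- simulate_expression_datasets(sim)
    for (d in names(expr_sets$datasets)) {
      write_expression_table(expr_sets$datasets[[d]],
                             file.path(config$out_dir,
                                       paste0("expression_", d, ".tsv")))
      manifest[[length(manifest) + 1L]] <- data.frame(
        file = paste0("expression_", d, ".tsv"), stage = "simulate",
        stringsAsFactors = FALSE)
    }
    say("[simulate] %d datasets, %d planted genes",
        sim$n_datasets, length(sim$panel_genes))
    score_matrix <- subset_samples(
      expr_sets$datasets[[1]],
      expr_sets$datasets[[1]]$sample_roles == "tumour")
  } else {
    score_matrix <- read_expression_table(config$paths$expression)
    expr_sets <- NULL
    sim <- NULL
    say("[ingest] expression: %d genes x %d samples",
        nrow(score_matrix$values), ncol(score_matrix$values))
  }

  # --- differential expression ---------------------------------------
  if (isTRUE(config$stages$de) && !is.null(expr_sets)) {
    stage("de", {
      de <- lapply(expr_sets$datasets, differential_expression)
      for (d in names(de)) emit(de[[d]], paste0("de_", d, ".tsv"), "de")
      sel <- cross_dataset_filter(de)
      emit(data.frame(gene = sel, stringsAsFactors = FALSE),
           "selected_genes.tsv", "de")
      say("[de] prevalence filter kept %d genes", length(sel))
    })
  }

  # --- scoring --------------------------------------------------------
  ces <- compute_ces(score_matrix, panel)
  strata <- stratify(ces, config$strata_mode)
  emit(ces_table(ces, strata), "ces_scores.tsv", "score")

  # --- cohort ---------------------------------------------------------
  cohort <- NULL
  if (config$mode == "simulate") {
    cohort <- simulate_cohort(sim, ces$scores)
  } else if (!is.null(config$paths$cohort)) {
    cohort <- utils::read.delim(config$paths$cohort,
                                stringsAsFactors = FALSE)
  }
  if (!is.null(cohort)) emit(cohort, "cohort.tsv", "cohort")

  # --- associations ---------------------------------------------------
  if (isTRUE(config$stages$associations)) {
    stage("associations", {
      if (config$mode == "simulate") {
        inst <- simulate_instability(ces$scores, sim)
        emit(inst, "instability.tsv", "associations")
        tabs <- rbind(
          data.frame(group = "simulated", metric = "cna_fraction",
                     score = ces$scores[inst$sample_id],
                     value = inst$cna_fraction),
          data.frame(group = "simulated", metric = "mutation_freq",
                     score = ces$scores[inst$sample_id],
                     value = inst$mutation_freq))
        emit(spearman_with_fdr(tabs), "instability_correlation.tsv",
             "associations")
      }
      if (!is.null(cohort)) {
        enr <- categorical_enrichment(
          strata, stats::setNames(cohort$grade, cohort$sample_id))
        emit(as.data.frame.matrix(enr$table), "grade_by_stratum.tsv",
             "associations")
        say("[associations] grade enrichment: %s p=%.3g", enr$test, enr$p)
      }
      pg <- intersect(panel$genes, rownames(score_matrix$values))
      net <- coexpression_network(
        expression_matrix(score_matrix$values[pg, , drop = FALSE],
                          scale = score_matrix$scale,
                          sample_roles = score_matrix$sample_roles),
        threshold = 0.4)
      emit(net$edges, "network_edges.tsv", "associations")
      emit(data.frame(gene = names(net$degrees),
                      degree = unname(net$degrees)),
           "network_degrees.tsv", "associations")
    })
  }

  # --- drug sensitivity ----------------------------------------------
  if (isTRUE(config$stages$drugs)) {
    stage("drugs", {
      if (config$mode == "simulate") {
        cl <- simulate_celllines(sim)
        drug_tab <- cl$drugs
        cl_ces <- compute_ces(cl$expression, panel)
      } else {
        drug_tab <- utils::read.delim(config$paths$drugs,
                                      stringsAsFactors = FALSE)
        cl_ces <- ces
      }
      dsa <- drug_sensitivity_analysis(cl_ces, drug_tab)
      emit(drug_tab, "drug_response.tsv", "drugs")
      emit(dsa$spearman, "drug_spearman.tsv", "drugs")
      emit(data.frame(statistic = dsa$quartile_test$statistic,
                      p = dsa$quartile_test$p,
                      n_top = dsa$quartile_test$n_top,
                      n_bottom = dsa$quartile_test$n_bottom,
                      n_excluded = length(dsa$excluded)),
           "drug_quartile_test.tsv", "drugs")
      say("[drugs] excluded %d extreme lines; top-vs-bottom quartile p=%.3g",
          length(dsa$excluded), dsa$quartile_test$p)
    })
  }

  # --- survival -------------------------------------------------------
  if (isTRUE(config$stages$survival) && !is.null(cohort)) {
    stage("survival", {
      km_rows <- do.call(rbind, lapply(levels(strata$strata), function(lv) {
        ids <- names(strata$strata)[strata$strata == lv]
        sub <- cohort[cohort$sample_id %in% ids, ]
        if (!nrow(sub)) return(NULL)
        km <- km_estimate(sub)
        data.frame(stratum = lv, time = km$time, surv = km$surv,
                   n_risk = km$n_risk, n_event = km$n_event)
      }))
      emit(km_rows, "km_curves.tsv", "survival")
      grp <- data.frame(time = cohort$time, event = cohort$event,
                        group = as.character(
                          strata$strata[cohort$sample_id]))
      lr <- logrank_test(grp)
      emit(data.frame(statistic = lr$statistic, df = lr$df, p = lr$p,
                      events = lr$events),
           "logrank.tsv", "survival")
      covs <- data.frame(ces_z = as.vector(scale(cohort$ces)),
                         grade = factor(cohort$grade))
      cx <- cox_fit(cohort, covs)
      emit(as.data.frame(cx), "cox.tsv", "survival")
      say("[survival] log-rank p=%.3g; CES HR=%.3f",
          lr$p, cx$hr[cx$term == "ces_z"])
    })
  }

  # --- treatment-stratified hazards ----------------------------------
  if (isTRUE(config$stages$treatment) && !is.null(cohort) &&
      "treated" %in% names(cohort)) {
    stage("treatment", {
      st2 <- stratify(ces, "top_tertile_vs_rest")
      forest <- stratified_treatment_analysis(cohort, st2)
      emit(as.data.frame(forest), "forest.tsv", "treatment")
      say("[treatment] %d forest rows (%d dropped)",
          nrow(forest), length(attr(forest, "dropped")))
    })
  }

  # --- bundle ---------------------------------------------------------
  manifest <- do.call(rbind, manifest)
  write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
  writeLines(log, file.path(config$out_dir, "run_log.txt"))
  echo <- config
  echo$out_dir <- NULL  # location metadata, not part of the run identity
  echo$sim$planted_log2fc <- as.list(echo$sim$planted_log2fc)
  jsonlite::write_json(unclass(echo),
                       file.path(config$out_dir, "config_echo.json"),
                       auto_unbox = TRUE, null = "null", digits = NA,
                       force = TRUE)
  structure(list(manifest = manifest, out_dir = config$out_dir,
                 errors = errors, log = log),
            class = "ReportBundle")
}

#' @export
print.ReportBundle <- function(x, ...) {
  cat(sprintf("ReportBundle: %d files in %s\n", nrow(x$manifest), x$out_dir))
  if (length(x$errors)) {
    cat("stage errors:\n")
    for (nm in names(x$errors)) cat("  ", nm, ": ", x$errors[[nm]], "\n")
  }
  invisible(x)
}
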