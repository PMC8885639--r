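# End-to-end orchestration: simulate -> quantify -> compare -> enrich ->
# localize -> report, with a machine-readable run manifest.

#' Pipeline run configuration
#'
#' Collects every analysis default in one declarative object so each choice
#' the analysis depends on (universe policy, CI estimator, pseudocount,
#' thresholds, seed) is explicit and echoed into the run manifest.
#'
#' @param sim a [sim_config()] describing the synthetic inputs, or `NULL`
#'   when all inputs are supplied as files.
#' @param outdir output directory.
#' @param inputs optional named list of existing input paths
#'   (`spc_counts`, `frag_counts`, `gmt`, `evidence`, `detection` — a vector
#'   of detection TSVs) that replace the corresponding simulated inputs;
#'   validated before any stage runs.
#' @param ci_levels confidence levels for [compare_abundance()].
#' @param fc_threshold fold-change selection threshold.
#' @param estimator `"robust"` or `"parametric"` CI estimator.
#' @param universe_policy hypergeometric universe policy (see
#'   [test_collection()]).
#' @param p_floor p-value floor for significance matrices.
#' @param top_k rows in the ranked depletion/enrichment tables.
#' @param heatmap also render PNG heatmaps next to their TSV twins.
#' @param stages stages to execute, in pipeline order.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), outdir = tempfile("systeomics_run_"),
                       inputs = list(),
                       ci_levels = c(0.90, 0.95), fc_threshold = 1.8,
                       estimator = c("robust", "parametric"),
                       universe_policy = c("annotation", "detected_union"),
                       p_floor = 1e-16, top_k = 15L, heatmap = FALSE,
                       stages = c("simulate", "quantify", "compare",
                                  "enrich", "localize", "report")) {
  estimator <- match.arg(estimator)
  universe_policy <- match.arg(universe_policy)
  stages <- match.arg(stages, several.ok = TRUE)
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  for (nm in names(inputs)) {
    for (p in inputs[[nm]])
      if (!file.exists(p))
        .stop_val("input path for '%s' does not exist: %s", nm, p)
  }
  structure(list(sim = sim, outdir = outdir, inputs = inputs,
                 ci_levels = ci_levels, fc_threshold = fc_threshold,
                 estimator = estimator, universe_policy = universe_policy,
                 p_floor = p_floor, top_k = as.integer(top_k),
                 heatmap = heatmap, stages = stages),
            class = "run_config")
}

.run_stage <- function(name, outdir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               file.path(outdir, "FAILED"))
    .stop_val("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order — simulate, quantify (NSAF, FPKM,
#' size factors), compare (detection overlap and CI/fold-change flags),
#' enrich (hypergeometric enrichment/depletion per detection profile with
#' significance matrices and ranked tables), localize (consensus
#' membrane/secreted calls) and report (run manifest) — writing every table
#' as a deterministic TSV under `config$outdir`. Identical configuration and
#' seed give byte-identical data outputs; only the manifest carries a
#' wall-clock timestamp.
#'
#' @param config a [run_config()].
#' @return named character vector of all written paths, invisibly; the run
#'   manifest is `run_manifest.json`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(config$outdir, "FAILED"))
  outdir <- config$outdir
  paths <- character(0)
  counts <- list()
  sim <- NULL; spc <- NULL; frag <- NULL; sets <- NULL
  detection <- NULL; evidence <- NULL; nsaf <- NULL; fpkm <- NULL

  if ("simulate" %in% config$stages && !is.null(config$sim)) {
    .run_stage("simulate", outdir, {
      sim <- simulate_omics(config$sim)
      paths <- c(paths, write_simulation(sim, outdir))
      counts$simulate <- list(n_genes = nrow(sim$universe$genes),
                               n_terms = length(sim$universe$sets$sets),
                               n_datasets = length(sim$detection))
    })
  }

  # resolve inputs: explicit file inputs win over the simulation
  inp <- config$inputs
  spc <- if (!is.null(inp$spc_counts)) read_tsv(inp$spc_counts)
         else sim$abundance$spc_counts
  frag <- if (!is.null(inp$frag_counts)) read_tsv(inp$frag_counts)
          else sim$abundance$frag_counts
  sets <- if (!is.null(inp$gmt)) read_gmt(inp$gmt) else sim$universe$sets
  evidence <- if (!is.null(inp$evidence)) read_tsv(inp$evidence)
              else sim$predictors$evidence
  detection <- if (!is.null(inp$detection)) {
    lapply(seq_along(inp$detection), function(i)
      detection_profile(read_tsv(inp$detection[[i]])[[1]],
                        label = sprintf("D%02d", i), namespace = "gene_id"))
  } else sim$detection
  if (is.null(spc) || is.null(detection))
    .stop_val("no inputs: supply a sim_config or explicit input paths")

  if ("quantify" %in% config$stages) {
    .run_stage("quantify", outdir, {
      nsaf <- compute_nsaf(spc)
      fpkm <- compute_fpkm(frag)
      sf <- size_factors(frag)
      p <- c(nsaf = file.path(outdir, "nsaf.tsv"),
             fpkm = file.path(outdir, "fpkm.tsv"),
             size_factors = file.path(outdir, "size_factors.tsv"))
      write_tsv(nsaf, p["nsaf"]); write_tsv(fpkm, p["fpkm"])
      write_tsv(data.frame(sample = names(sf), size_factor = unname(sf),
                           stringsAsFactors = FALSE), p["size_factors"])
      paths <- c(paths, p)
      counts$quantify <- list(n_features = nrow(nsaf))
    })
  }

  if ("compare" %in% config$stages) {
    .run_stage("compare", outdir, {
      cols <- setdiff(names(nsaf), "feature_id")
      cmp <- compare_abundance(
        stats::setNames(nsaf[[cols[1]]], nsaf$feature_id),
        stats::setNames(nsaf[[cols[2]]], nsaf$feature_id),
        ci_levels = config$ci_levels, fc_threshold = config$fc_threshold,
        estimator = config$estimator)
      ov <- overlap_profiles(detection[[1]],
                             detection[[min(2, length(detection))]])
      p <- c(comparison = file.path(outdir, "comparison.tsv"),
             overlap = file.path(outdir, "overlap_summary.tsv"))
      write_tsv(cmp, p["comparison"])
      write_tsv(data.frame(partition = names(ov$counts),
                           n = unname(ov$counts), stringsAsFactors = FALSE),
                p["overlap"])
      paths <- c(paths, p)
      counts$compare <- list(n_shared = nrow(cmp),
                              n_fc_selected = sum(cmp$fc_selected))
    })
  }

  if ("enrich" %in% config$stages) {
    .run_stage("enrich", outdir, {
      recs <- lapply(detection, test_collection, sets = sets,
                     universe = config$universe_policy)
      names(recs) <- vapply(detection, function(d) d$label, "")
      for (nm in names(recs)) {
        f <- file.path(outdir, sprintf("enrichment_%s.tsv", nm))
        write_tsv(recs[[nm]], f)
        paths[paste0("enrichment_", nm)] <- f
      }
      for (dir in c("enrich", "deplete")) {
        m <- significance_matrix(recs, direction = dir,
                                 p_floor = config$p_floor)
        f <- file.path(outdir, sprintf("significance_%s.tsv", dir))
        render_heatmap(m, tsv = f,
                       png = if (config$heatmap)
                         file.path(outdir, sprintf("significance_%s.png", dir)))
        paths[paste0("significance_", dir)] <- f
      }
      top <- rank_terms(recs[[1]], "deplete", top_k = config$top_k)
      f <- file.path(outdir, "top_depleted.tsv")
      write_tsv(top, f)
      paths["top_depleted"] <- f
      counts$enrich <- list(n_terms = nrow(recs[[1]]),
                             n_datasets = length(recs))
    })
  }

  if ("localize" %in% config$stages) {
    .run_stage("localize", outdir, {
      calls <- classify_localization(evidence)
      f <- file.path(outdir, "localization_calls.tsv")
      write_tsv(calls, f)
      paths["localization"] <- f
      counts$localize <- list(n_proteins = nrow(calls),
                               n_membrane = sum(calls$membrane),
                               n_secreted = sum(calls$secreted))
    })
  }

  if ("report" %in% config$stages) {
    .run_stage("report", outdir, {
      data_files <- sort(setdiff(list.files(outdir, full.names = TRUE),
                                 file.path(outdir, "run_manifest.json")))
      manifest <- list(
        tool = "systeomics",
        version = as.character(utils::packageVersion("systeomics")),
        config = list(
          seed = if (!is.null(config$sim)) config$sim$seed else NA,
          ci_levels = config$ci_levels, fc_threshold = config$fc_threshold,
          estimator = config$estimator,
          universe_policy = config$universe_policy,
          p_floor = config$p_floor, top_k = config$top_k,
          stages = config$stages),
        checksums = as.list(tools::md5sum(data_files)),
        row_counts = counts,
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
      f <- file.path(outdir, "run_manifest.json")
      jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
      paths["manifest"] <- f
    })
  }
  invisible(paths)
}

#' Render a significance matrix as TSV (and optionally PNG)
#'
#' The TSV twin carries exactly the values the heatmap displays and is the
#' testable artifact; the PNG (drawn with \pkg{pheatmap}, clustering off so
#' rendering follows the recorded order) is cosmetic.
#'
#' @param matrix a [significance_matrix()] result.
#' @param tsv path of the TSV twin.
#' @param png optional PNG path; `NULL` skips rendering.
#' @param ordering `"row_max"` (rows sorted by their maximum, descending,
#'   ties by term key) or `"none"`.
#' @param ceiling clip values above this ceiling (default: no clipping).
#' @return the row-ordered matrix, invisibly.
#' @export
render_heatmap <- function(matrix, tsv, png = NULL,
                           ordering = c("row_max", "none"), ceiling = Inf) {
  ordering <- match.arg(ordering)
  if (is.null(dim(matrix)) || nrow(matrix) == 0L)
    .stop_val("significance matrix is empty")
  m <- pmin(matrix, ceiling)
  if (ordering == "row_max") {
    mx <- apply(m, 1, max, na.rm = TRUE)
    m <- m[order(-mx, rownames(m)), , drop = FALSE]
  }
  df <- data.frame(term_key = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, tsv)
  if (!is.null(png)) {
    grDevices::png(png, width = 900, height = 200 + 18 * nrow(m), res = 110)
    on.exit(grDevices::dev.off())
    pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                       main = sprintf("-log10 p (%s)",
                                      attr(matrix, "direction")))
  }
  invisible(m)
}
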