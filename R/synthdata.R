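# Synthetic multi-omics data with known ground truth: a gene universe with
# term annotations, per-dataset detection with term-specific detection
# probabilities (planted depleted/enriched terms), log-normal abundance with
# planted fold-changes, and localization-predictor tables with known
# membrane/secreted labels.

#' Planted term specification
#'
#' @param term term index (1-based) within the simulated collection.
#' @param direction `"depleted"` or `"enriched"`.
#' @param detect_prob detection probability overriding the baseline for the
#'   term's genes.
#' @return list usable inside `planted_terms` of [sim_config()].
#' @export
planted_term <- function(term, direction = c("depleted", "enriched"),
                         detect_prob) {
  direction <- match.arg(direction)
  .check_prob(detect_prob, "detect_prob")
  list(term = as.integer(term), direction = direction,
       detect_prob = detect_prob)
}

#' Planted fold-change specification
#'
#' @param gene gene index (1-based).
#' @param log2fc true log2 fold change of condition B relative to A.
#' @return list usable inside `planted_fc_genes` of [sim_config()].
#' @export
planted_fc <- function(gene, log2fc) {
  list(gene = as.integer(gene), log2fc = as.numeric(log2fc))
}

#' Simulation configuration
#'
#' Defines the study conditions emulated by the generator: universe and
#' annotation sizes, per-dataset detection probabilities with planted
#' depleted/enriched terms, log-normal abundance with planted log2
#' fold-changes, Poisson count emission proportional to abundance x length,
#' and membrane/secreted label frequencies for the predictor tables.
#'
#' @param n_genes number of genes in the universe.
#' @param n_terms number of annotation terms.
#' @param term_size_range integer (min, max); term sizes are drawn uniformly
#'   from this range.
#' @param baseline_detect_prob per-dataset detection probability of a gene
#'   not covered by a planted term.
#' @param planted_terms list of [planted_term()] specifications.
#' @param n_datasets number of detection profiles to draw.
#' @param abundance_log_mean,abundance_log_sd natural-log mean and sd of the
#'   per-gene base abundance (log-normal); `abundance_log_sd = 0` gives a
#'   degenerate (noise-free) abundance useful as a null configuration.
#' @param planted_fc_genes list of [planted_fc()] specifications applied to
#'   condition B.
#' @param protein_length_range,gene_length_range integer (min, max) lengths
#'   in amino acids / nucleotides.
#' @param depth_factor sequencing/spectral depth multiplier: expected counts
#'   are `abundance * (length / 1000) * depth_factor`.
#' @param frac_membrane,frac_secreted fractions of proteins truly membrane /
#'   truly secreted; `frac_both` (<= both fractions) is the fraction that is
#'   both, so the marginal fractions are exactly `frac_membrane` and
#'   `frac_secreted`.
#' @param frac_both fraction of proteins both membrane and secreted.
#' @param predictor_error independent per-predictor error rate (miss or
#'   false call) in the evidence tables.
#' @param seed global integer seed; every stage derives its own named
#'   substream from it, so the same seed gives byte-identical outputs and
#'   adding a stage never perturbs earlier draws.
#' @return validated object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L, n_terms = 50L,
                       term_size_range = c(10L, 100L),
                       baseline_detect_prob = 0.8,
                       planted_terms = list(),
                       n_datasets = 2L,
                       abundance_log_mean = 2, abundance_log_sd = 1,
                       planted_fc_genes = list(),
                       protein_length_range = c(100L, 3000L),
                       gene_length_range = c(300L, 10000L),
                       depth_factor = 5,
                       frac_membrane = 0.2, frac_secreted = 0.2,
                       frac_both = 0.05,
                       predictor_error = 0,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_terms = as.integer(n_terms),
    term_size_range = .check_range(term_size_range, "term_size_range"),
    baseline_detect_prob = baseline_detect_prob,
    planted_terms = planted_terms,
    n_datasets = as.integer(n_datasets),
    abundance_log_mean = abundance_log_mean,
    abundance_log_sd = abundance_log_sd,
    planted_fc_genes = planted_fc_genes,
    protein_length_range = .check_range(protein_length_range,
                                        "protein_length_range"),
    gene_length_range = .check_range(gene_length_range, "gene_length_range"),
    depth_factor = depth_factor,
    frac_membrane = frac_membrane, frac_secreted = frac_secreted,
    frac_both = frac_both,
    predictor_error = predictor_error,
    seed = as.integer(seed))
  if (cfg$n_genes < 1L || cfg$n_terms < 1L || cfg$n_datasets < 1L)
    .stop_val("n_genes, n_terms and n_datasets must be positive")
  if (cfg$term_size_range[2] > cfg$n_genes)
    .stop_val("term sizes (up to %d) cannot exceed n_genes = %d",
              cfg$term_size_range[2], cfg$n_genes)
  .check_prob(cfg$baseline_detect_prob, "baseline_detect_prob")
  .check_prob(cfg$frac_membrane, "frac_membrane")
  .check_prob(cfg$frac_secreted, "frac_secreted")
  .check_prob(cfg$frac_both, "frac_both")
  .check_prob(cfg$predictor_error, "predictor_error")
  if (cfg$frac_both > min(cfg$frac_membrane, cfg$frac_secreted))
    .stop_val("frac_both cannot exceed frac_membrane or frac_secreted")
  if (cfg$frac_membrane + cfg$frac_secreted - cfg$frac_both > 1)
    .stop_val("membrane/secreted fractions exceed 1")
  if (cfg$abundance_log_sd < 0)
    .stop_val("abundance_log_sd must be >= 0")
  if (cfg$depth_factor <= 0) .stop_val("depth_factor must be positive")
  for (pt in cfg$planted_terms) {
    if (is.null(pt$term) || pt$term < 1L || pt$term > cfg$n_terms)
      .stop_val("planted term index out of range 1..%d", cfg$n_terms)
    .check_prob(pt$detect_prob, "planted detect_prob")
  }
  for (pf in cfg$planted_fc_genes)
    if (is.null(pf$gene) || pf$gene < 1L || pf$gene > cfg$n_genes)
      .stop_val("planted fold-change gene index out of range 1..%d", cfg$n_genes)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate the gene universe, annotation and ground truth
#'
#' Draws a gene catalog with protein and gene lengths, a term collection
#' with uniformly drawn term sizes and uniformly sampled member genes, and
#' the ground-truth labels (per-term direction, per-gene true log2
#' fold-change, per-protein membrane/secreted status).
#'
#' @param config a [sim_config()].
#' @return list of class `sim_universe`: `genes` (data frame `gene_id`,
#'   `symbol`, `protein_length_aa`, `gene_length_nt`), `sets` (a
#'   [gene_set_collection()]), `truth` (list `term_direction`,
#'   `gene_log2fc`, `membrane`, `secreted`, all named), and the `config`.
#' @export
generate_universe <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.substream_seed(config$seed, "universe"))
  n <- config$n_genes
  gene_id <- sprintf("G%05d", seq_len(n))
  genes <- data.frame(
    gene_id = gene_id,
    symbol = sprintf("SYN%05d", seq_len(n)),
    protein_length_aa = .resample(config$protein_length_range[1]:
                                  config$protein_length_range[2], n, replace = TRUE),
    gene_length_nt = .resample(config$gene_length_range[1]:
                               config$gene_length_range[2], n, replace = TRUE),
    stringsAsFactors = FALSE)

  term_id <- sprintf("T%03d", seq_len(config$n_terms))
  sizes <- .resample(config$term_size_range[1]:config$term_size_range[2],
                     config$n_terms, replace = TRUE)
  sets <- stats::setNames(lapply(sizes, function(s) .resample(gene_id, s)),
                          term_id)
  collection <- gene_set_collection(
    sets, namespace = "custom", species = "synthetic",
    term_names = stats::setNames(sprintf("synthetic term %s", term_id), term_id))

  term_direction <- stats::setNames(rep("baseline", config$n_terms), term_id)
  for (pt in config$planted_terms)
    term_direction[pt$term] <- pt$direction
  gene_log2fc <- stats::setNames(numeric(n), gene_id)
  for (pf in config$planted_fc_genes)
    gene_log2fc[pf$gene] <- pf$log2fc

  set.seed(.substream_seed(config$seed, "labels"))
  u <- stats::runif(n)
  p_both <- config$frac_both
  p_mem_only <- config$frac_membrane - p_both
  p_sec_only <- config$frac_secreted - p_both
  membrane <- u < p_both + p_mem_only
  secreted <- u < p_both | (u >= p_both + p_mem_only &
                            u < p_both + p_mem_only + p_sec_only)
  truth <- list(term_direction = term_direction,
                gene_log2fc = gene_log2fc,
                membrane = stats::setNames(membrane, gene_id),
                secreted = stats::setNames(secreted, gene_id))
  structure(list(genes = genes, sets = collection, truth = truth,
                 config = config),
            class = "sim_universe")
}

# Per-gene detection probability: a planted term's override applies to its
# member genes; the first planted term listing a gene wins; everyone else
# gets the baseline.
.detect_probs <- function(universe) {
  cfg <- universe$config
  p <- stats::setNames(rep(cfg$baseline_detect_prob, cfg$n_genes),
                       universe$genes$gene_id)
  assigned <- rep(FALSE, cfg$n_genes)
  names(assigned) <- universe$genes$gene_id
  for (pt in cfg$planted_terms) {
    members <- universe$sets$sets[[pt$term]]
    take <- members[!assigned[members]]
    p[take] <- pt$detect_prob
    assigned[take] <- TRUE
  }
  p
}

#' Draw per-dataset detection profiles
#'
#' Each gene is detected in each dataset independently with its per-gene
#' probability: the override of its planted term when it has one, the
#' baseline otherwise.
#'
#' @param universe a [generate_universe()] result.
#' @param config optional [sim_config()]; defaults to the universe's own.
#' @return list of [detection_profile()] objects labeled `D01`, `D02`, ...
#' @export
generate_detection <- function(universe, config = universe$config) {
  stopifnot(inherits(universe, "sim_universe"))
  set.seed(.substream_seed(config$seed, "detection"))
  p <- .detect_probs(universe)
  lapply(seq_len(config$n_datasets), function(d) {
    hit <- stats::runif(length(p)) < p
    detection_profile(names(p)[hit], label = sprintf("D%02d", d),
                      layer = "protein", namespace = "gene_id")
  })
}

#' Generate abundances and raw count tables for two conditions
#'
#' Per-gene base abundance is log-normal(`abundance_log_mean`,
#' `abundance_log_sd`); condition B multiplies it by `2^log2fc` for planted
#' fold-change genes. Spectral counts (proteomics) and fragment counts
#' (RNA-seq) are drawn Poisson with mean `abundance * (length / 1000) *
#' depth_factor`, so expected counts are proportional to abundance times
#' length — the structure NSAF and FPKM divide back out.
#'
#' @inheritParams generate_detection
#' @return list: `abundance` (data frame `feature_id`, `A`, `B` of true
#'   abundances), `spc_counts` and `frag_counts` (count tables with
#'   `feature_id`, `length`, samples `A`, `B`), `nsaf` and `fpkm` (the
#'   quantified pair).
#' @export
generate_abundance <- function(universe, config = universe$config) {
  stopifnot(inherits(universe, "sim_universe"))
  set.seed(.substream_seed(config$seed, "abundance"))
  n <- config$n_genes
  base <- stats::rlnorm(n, meanlog = config$abundance_log_mean,
                        sdlog = config$abundance_log_sd)
  ab_a <- base
  ab_b <- base * 2^unname(universe$truth$gene_log2fc)
  draw <- function(ab, len) stats::rpois(n, ab * (len / 1000) * config$depth_factor)
  spc <- data.frame(feature_id = universe$genes$gene_id,
                    length = universe$genes$protein_length_aa,
                    A = draw(ab_a, universe$genes$protein_length_aa),
                    B = draw(ab_b, universe$genes$protein_length_aa),
                    stringsAsFactors = FALSE)
  frag <- data.frame(feature_id = universe$genes$gene_id,
                     length = universe$genes$gene_length_nt,
                     A = draw(ab_a, universe$genes$gene_length_nt),
                     B = draw(ab_b, universe$genes$gene_length_nt),
                     stringsAsFactors = FALSE)
  list(abundance = data.frame(feature_id = universe$genes$gene_id,
                              A = ab_a, B = ab_b, stringsAsFactors = FALSE),
       spc_counts = spc, frag_counts = frag,
       nsaf = compute_nsaf(spc), fpkm = compute_fpkm(frag))
}

#' Generate localization-predictor evidence with known labels
#'
#' Emulates normalized outputs of TM-helix predictors (TMHMM, Phobius),
#' signal-peptide predictors (SignalP, Phobius) and compartment predictors
#' (TargetP, WoLF PSORT). Each predictor independently errs (misses a true
#' positive or fires on a true negative) with probability
#' `config$predictor_error` (overridable).
#'
#' @inheritParams generate_detection
#' @param error_rate per-predictor error probability; defaults to
#'   `config$predictor_error`.
#' @return list: `evidence` (the normalized predictor table consumed by
#'   [classify_localization()]) and `labels` (data frame `protein_id`,
#'   `membrane`, `secreted` ground truth).
#' @export
generate_predictor_tables <- function(universe, config = universe$config,
                                      error_rate = config$predictor_error) {
  stopifnot(inherits(universe, "sim_universe"))
  .check_prob(error_rate, "error_rate")
  set.seed(.substream_seed(config$seed, "predictors"))
  id <- universe$genes$gene_id
  n <- length(id)
  mem <- unname(universe$truth$membrane)
  sec <- unname(universe$truth$secreted)
  err <- function() stats::runif(n) < error_rate
  tm_count <- function() {
    e <- err()
    pos <- (mem & !e) | (!mem & e)
    ifelse(pos, .resample(1:12, n, replace = TRUE), 0L)
  }
  sp_call <- function() {
    e <- err()
    (sec & !e) | (!sec & e)
  }
  e_tp <- err()
  targetp <- ifelse(e_tp, "other", ifelse(sec, "S", ifelse(mem, "M", "other")))
  e_wp <- err()
  wolf <- ifelse(e_wp, "other",
                 ifelse(mem, "plasma_membrane",
                        ifelse(sec, "extracellular", "other")))
  evidence <- data.frame(
    protein_id = id,
    tmhmm_tm_count = tm_count(),
    phobius_tm_count = tm_count(),
    phobius_sp = sp_call(),
    signalp_sp = sp_call(),
    targetp_loc = targetp,
    wolfpsort_loc = wolf,
    stringsAsFactors = FALSE)
  list(evidence = evidence,
       labels = data.frame(protein_id = id, membrane = mem, secreted = sec,
                           stringsAsFactors = FALSE))
}

#' Run every generator stage of a simulation
#'
#' @param config a [sim_config()].
#' @return list of class `simulation`: `universe`, `detection`, `abundance`,
#'   `predictors`.
#' @export
simulate_omics <- function(config = sim_config()) {
  universe <- generate_universe(config)
  structure(list(universe = universe,
                 detection = generate_detection(universe),
                 abundance = generate_abundance(universe),
                 predictors = generate_predictor_tables(universe)),
            class = "simulation")
}

#' Write a simulation to disk
#'
#' Emits the gene catalog, GMT annotation, per-dataset detection lists, raw
#' count tables, predictor evidence and ground-truth labels as deterministic
#' TSV/GMT files.
#'
#' @param sim a [simulate_omics()] result.
#' @param outdir output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  stopifnot(inherits(sim, "simulation"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  u <- sim$universe
  paths <- c(catalog = file.path(outdir, "gene_catalog.tsv"),
             gmt = file.path(outdir, "annotation.gmt"),
             spc = file.path(outdir, "spc_counts.tsv"),
             frag = file.path(outdir, "fragment_counts.tsv"),
             predictors = file.path(outdir, "predictor_evidence.tsv"),
             truth = file.path(outdir, "ground_truth.tsv"))
  write_tsv(u$genes, paths["catalog"])
  write_gmt(u$sets, paths["gmt"])
  write_tsv(sim$abundance$spc_counts, paths["spc"])
  write_tsv(sim$abundance$frag_counts, paths["frag"])
  write_tsv(sim$predictors$evidence, paths["predictors"])
  truth <- data.frame(gene_id = u$genes$gene_id,
                      log2fc = unname(u$truth$gene_log2fc),
                      membrane = unname(u$truth$membrane),
                      secreted = unname(u$truth$secreted),
                      stringsAsFactors = FALSE)
  write_tsv(truth, paths["truth"])
  for (prof in sim$detection) {
    f <- file.path(outdir, sprintf("detection_%s.tsv", prof$label))
    write_tsv(data.frame(gene_id = sort(prof$ids), stringsAsFactors = FALSE), f)
    paths[paste0("detection_", prof$label)] <- f
  }
  invisible(paths)
}
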