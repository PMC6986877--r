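#' Pipeline configuration
#'
#' Bundles the thresholds, seed and output directory for [run_pipeline()].
#' A configuration can also be read from a JSON file; explicit arguments win
#' over values in the file.
#'
#' @param outdir output directory; every stage writes only below it.
#' @param seed mandatory seed driving the simulation and permutation stages.
#' @param fdr FDR threshold for differential significance (in (0, 1]).
#' @param motif_threshold motif hit threshold in bits.
#' @param n_perm permutations for the enrichment stage (>= 1).
#' @param window peak-caller window size in bp.
#' @param sim a [simulation_config()]; defaults to the standard bundle at
#'   this seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed, fdr = 0.05, motif_threshold = 12,
                            n_perm = 1000, window = 200, sim = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (fdr <= 0 || fdr > 1) stop("fdr must lie in (0, 1]")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (window < 1) stop("window must be >= 1")
  if (is.null(sim)) sim <- simulation_config(seed = seed)
  structure(list(outdir = outdir, seed = seed, fdr = fdr,
                 motif_threshold = motif_threshold, n_perm = n_perm,
                 window = window, sim = sim),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with any subset of the [pipeline_config()] fields
#'   (plus an optional `sim` object of [simulation_config()] fields).
#' @param ... overrides, passed to [pipeline_config()]; these win over the
#'   file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  overrides <- list(...)
  for (f in names(overrides)) raw[[f]] <- overrides[[f]]
  simargs <- raw$sim
  raw$sim <- NULL
  if (is.null(raw$seed)) stop("config must supply a seed")
  if (!is.null(simargs)) {
    if (is.null(simargs$seed)) simargs$seed <- raw$seed
    for (f in c("chrom_sizes", "n_gbr", "promoter_bias", "motif_prob",
                "atac_mut_extra_drop", "comark_prob"))
      if (!is.null(simargs[[f]])) simargs[[f]] <- unlist(simargs[[f]])
    raw$sim <- do.call(simulation_config, simargs)
  }
  do.call(pipeline_config, raw)
}

pipeline_log <- function(...) message("[gliEnhancers] ", sprintf(...))

#' Run the enhancer-classification pipeline
#'
#' Orchestrates the stages end-to-end on a synthetic bundle: `simulate`
#' generates the dataset; `diffpeaks` calls per-condition peaks, merges them
#' and computes differential acetylation; `classify` labels the GBRs and
#' annotates promoters/co-marks; `enrich` runs the TSS permutation test for
#' responsive and stable GBRs against the target genes; `motifs` scans GBR
#' sequences and compares per-class motif statistics; `report` adds the
#' accessibility comparison and writes a combined summary. `all` runs every
#' stage in order. Outputs are confined to `config$outdir`; inputs are never
#' mutated; a manifest records the seed and thresholds used. Identical
#' config + seed gives byte-identical outputs.
#'
#' @param step one of `"all"`, `"simulate"`, `"diffpeaks"`, `"classify"`,
#'   `"enrich"`, `"motifs"`, `"report"`. Later stages expect earlier ones to
#'   have run in the same `outdir`.
#' @param config a [pipeline_config()] or path to a JSON config.
#' @return Invisibly, a named list of the paths written by the stage(s).
#' @export
run_pipeline <- function(step = c("all", "simulate", "diffpeaks", "classify",
                                  "enrich", "motifs", "report"),
                         config) {
  step <- match.arg(step)
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  steps <- if (step == "all")
    c("simulate", "diffpeaks", "classify", "enrich", "motifs", "report")
  else step
  written <- list()
  for (s in steps) {
    pipeline_log("stage %s (seed %s, fdr %g, motif threshold %g bits, n_perm %d)",
                 s, format(config$seed), config$fdr, config$motif_threshold,
                 config$n_perm)
    written[[s]] <- switch(s,
      simulate = stage_simulate(config),
      diffpeaks = stage_diffpeaks(config),
      classify = stage_classify(config),
      enrich = stage_enrich(config),
      motifs = stage_motifs(config),
      report = stage_report(config))
  }
  manifest <- list(seed = config$seed, fdr = config$fdr,
                   motif_threshold = config$motif_threshold,
                   n_perm = config$n_perm, window = config$window,
                   steps = steps,
                   outputs = lapply(written, function(x)
                     lapply(x, basename)))
  jsonlite::write_json(manifest, file.path(config$outdir,
                                           "pipeline_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(written)
}

sim_dir <- function(config) file.path(config$outdir, "sim")

require_file <- function(path) {
  if (!file.exists(path))
    stop("missing input: ", path, " (run the earlier pipeline stages first)")
  path
}

load_bundle <- function(config) {
  sd <- sim_dir(config)
  manifest <- jsonlite::read_json(require_file(file.path(sd,
                                                         "manifest.json")),
                                  simplifyVector = TRUE)
  samples <- utils::read.delim(file.path(sd, "samples.tsv"),
                               stringsAsFactors = FALSE)
  list(dir = sd, manifest = manifest, samples = samples,
       chrom_sizes = unlist(manifest$config$chrom_sizes),
       gbrs = read_bed(file.path(sd, "gbrs.bed")),
       genes = read_genes(file.path(sd, "genes.tsv")),
       targets = readLines(file.path(sd, "target_genes.txt")),
       cpg = read_bed(file.path(sd, "cpg_islands.bed")),
       truth = utils::read.delim(file.path(sd, "truth.tsv"),
                                 stringsAsFactors = FALSE))
}

read_sample_reads <- function(bundle, assay) {
  reads <- lapply(bundle$samples$sample_id, function(sid)
    read_positions(require_file(
      file.path(bundle$dir, "reads", paste0(assay, "_", sid, ".tsv")))))
  stats::setNames(reads, bundle$samples$sample_id)
}

stage_simulate <- function(config) {
  res <- generate_dataset(config$sim, sim_dir(config))
  list(dir = sim_dir(config))
}

stage_diffpeaks <- function(config) {
  bundle <- load_bundle(config)
  reads <- read_sample_reads(bundle, "acet")
  conds <- bundle$samples$condition
  pooled_a <- do.call(rbind, reads[conds == "condition_a"])
  pooled_b <- do.call(rbind, reads[conds == "condition_b"])
  peaks_a <- call_peaks_fixed_windows(pooled_a, bundle$chrom_sizes,
                                      config$window, config$fdr, "peakA")
  peaks_b <- call_peaks_fixed_windows(pooled_b, bundle$chrom_sizes,
                                      config$window, config$fdr, "peakB")
  merged <- merge_overlapping(
    region_set(c(peaks_a$chrom, peaks_b$chrom),
               c(peaks_a$start, peaks_b$start),
               c(peaks_a$end, peaks_b$end),
               id = c(paste0("a_", peaks_a$id), paste0("b_", peaks_b$id))),
    id_prefix = "acet")
  cm <- count_reads_in_regions(reads, merged, conds)
  diff <- differential_regions(cm, peaks_a, peaks_b, fdr = config$fdr)
  paths <- list(
    peaks_a = file.path(config$outdir, "peaks_condition_a.bed"),
    peaks_b = file.path(config$outdir, "peaks_condition_b.bed"),
    diff = file.path(config$outdir, "differential_acetylation.tsv"))
  write_bed(peaks_a, paths$peaks_a)
  write_bed(peaks_b, paths$peaks_b)
  write_diff_tsv(diff, paths$diff)
  pipeline_log("called %d + %d peaks, %d merged regions, %d significant at q < %g",
               nrow(peaks_a), nrow(peaks_b), nrow(diff),
               sum(diff$q < config$fdr), config$fdr)
  paths
}

stage_classify <- function(config) {
  bundle <- load_bundle(config)
  diff <- read_diff_tsv(require_file(
    file.path(config$outdir, "differential_acetylation.tsv")))
  comarks <- list(h3k4me1 = read_bed(file.path(bundle$dir, "h3k4me1.bed")))
  classes <- classify_gbrs(bundle$gbrs, diff, fdr = config$fdr,
                           comarks = comarks, genes = bundle$genes,
                           cpg_islands = bundle$cpg)
  paths <- list(
    classes = file.path(config$outdir, "gbr_classification.tsv"),
    summary = file.path(config$outdir, "classification_summary.json"))
  write_tsv(as.data.frame(classes), paths$classes)
  s <- summary(classes)
  jsonlite::write_json(
    list(n = s$n, counts = as.list(s$counts), n_acetylated = s$n_acetylated,
         fraction_stable = s$fraction_stable,
         n_responsive = s$n_responsive),
    paths$summary, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  pipeline_log("classified %d GBRs (%d stable / %d sensitive / %d dependent / %d non-acetylated)",
               s$n, sum(classes$label == "stable"),
               sum(classes$label == "hh_sensitive"),
               sum(classes$label == "hh_dependent"),
               sum(classes$label == "non_acetylated"))
  paths
}

read_classes <- function(config) {
  out <- utils::read.delim(require_file(
    file.path(config$outdir, "gbr_classification.tsv")),
    stringsAsFactors = FALSE)
  class(out) <- c("gbr_class", "data.frame")
  out
}

stage_enrich <- function(config) {
  bundle <- load_bundle(config)
  classes <- read_classes(config)
  pick <- function(lbls) {
    k <- classes$label %in% lbls
    region_set(classes$chrom[k], classes$start[k], classes$end[k],
               id = classes$gbr_id[k])
  }
  groups <- list(responsive = c("hh_sensitive", "hh_dependent"),
                 hh_dependent = "hh_dependent", stable = "stable")
  res <- lapply(seq_along(groups), function(gi) {
    rs <- pick(groups[[gi]])
    if (!nrow(rs)) return(NULL)
    er <- tss_enrichment_test(rs, bundle$targets, bundle$genes,
                              n_perm = config$n_perm,
                              seed = config$seed + gi)
    list(group = names(groups)[gi], n_regions = nrow(rs),
         observed = er$observed,
         null_mean = mean(er$null),
         null_q95 = unname(stats::quantile(er$null, 0.95)),
         p_plain = er$p_plain, p_plus_one = er$p_plus_one,
         n_perm = er$n_perm, seed = er$seed)
  })
  res <- res[!vapply(res, is.null, TRUE)]
  path <- file.path(config$outdir, "tss_enrichment.json")
  jsonlite::write_json(res, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  for (r in res)
    pipeline_log("TSS enrichment %s: observed %d vs null mean %.1f (p_plus_one = %.3g)",
                 r$group, r$observed, r$null_mean, r$p_plus_one)
  list(enrichment = path)
}

stage_motifs <- function(config) {
  bundle <- load_bundle(config)
  classes <- read_classes(config)
  pwm <- gli_pwm()
  genome <- Biostrings::readDNAStringSet(file.path(bundle$dir, "genome.fa"))
  by_class <- list()
  for (cl in c("stable", "hh_sensitive", "hh_dependent")) {
    k <- classes$label == cl
    if (!any(k)) next
    rs <- region_set(classes$chrom[k], classes$start[k], classes$end[k],
                     id = classes$gbr_id[k])
    hits <- scan_regions(pwm, rs, genome, config$motif_threshold)
    by_class[[cl]] <- region_motif_stats(hits, rs$id)
  }
  cmp <- compare_motif_stats(by_class, reference = "stable")
  paths <- list(stats = file.path(config$outdir, "motif_stats.tsv"),
                report = file.path(config$outdir, "motif_report.json"))
  all_stats <- do.call(rbind, lapply(names(by_class), function(cl)
    data.frame(class = cl, by_class[[cl]], stringsAsFactors = FALSE)))
  write_tsv(all_stats, paths$stats)
  jsonlite::write_json(list(report = cmp$report, tests = cmp$tests),
                       paths$report, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  for (i in seq_len(nrow(cmp$report)))
    pipeline_log("motifs %s: %.1f%% with motif (n = %d)",
                 cmp$report$class[i], 100 * cmp$report$presence_fraction[i],
                 cmp$report$n[i])
  paths
}

stage_report <- function(config) {
  bundle <- load_bundle(config)
  classes <- read_classes(config)
  atac <- read_sample_reads(bundle, "atac")
  cm <- count_reads_in_regions(atac, bundle$gbrs, bundle$samples$condition)
  norm <- normalize_log2(cm)
  ia <- bundle$samples$condition == "condition_a"
  signal <- data.frame(gbr_id = rownames(norm),
                       signal_a = rowMeans(norm[, ia, drop = FALSE]),
                       signal_b = rowMeans(norm[, !ia, drop = FALSE]),
                       stringsAsFactors = FALSE)
  acc <- accessibility_compare(signal, classes)
  paths <- list(accessibility = file.path(config$outdir,
                                          "accessibility_tests.tsv"),
                summary = file.path(config$outdir, "report.json"))
  write_tsv(acc, paths$accessibility)
  summary_obj <- list(
    classification = jsonlite::read_json(require_file(
      file.path(config$outdir, "classification_summary.json"))),
    tss_enrichment = jsonlite::read_json(require_file(
      file.path(config$outdir, "tss_enrichment.json"))),
    motifs = jsonlite::read_json(require_file(
      file.path(config$outdir, "motif_report.json"))),
    accessibility = acc)
  jsonlite::write_json(summary_obj, paths$summary, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  pipeline_log("report written to %s", paths$summary)
  paths
}
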