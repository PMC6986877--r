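#' Configuration for the synthetic-data generator
#'
#' Defines a toy two-chromosome genome with annotated genes, CpG islands and
#' planted GLI binding regions (GBRs) of three response classes, plus
#' negative-binomial acetylation and accessibility read counts for two
#' conditions (A = wild type with active Hedgehog signalling, B = mutant
#' without it). Class structure mirrors the biology being emulated:
#' `stable` GBRs keep their acetylation in both conditions, `hh_sensitive`
#' GBRs drop by `sensitive_drop` log2 units in condition B, and
#' `hh_dependent` GBRs lose their signal entirely (background only) in
#' condition B.
#'
#' @param seed mandatory RNG seed; the full bundle is reproducible from it.
#' @param chrom_sizes named chromosome lengths in bp.
#' @param n_genes number of genes, spread across chromosomes by length.
#' @param fraction_target_genes fraction of genes designated Hedgehog
#'   targets.
#' @param n_gbr named counts of planted GBRs per class.
#' @param n_nongbr named counts of acetylated regions not bound by GLI:
#'   `stable` regions keep their signal in both conditions (the bulk of any
#'   real acetylation landscape, which keeps library-size normalisation
#'   honest), `responsive` regions lose `sensitive_drop` log2 units in
#'   condition B and are planted near responsive GBRs.
#' @param nongbr_near_distance maximum distance (bp) of a responsive non-GBR
#'   region from its anchoring responsive GBR.
#' @param promoter_bias per-class probability that a planted GBR lands inside
#'   a gene's 2 kb / 1 kb promoter window. Promoter-placed responsive GBRs
#'   use target-gene promoters; stable ones use any gene.
#' @param gbr_width width of each planted GBR in bp.
#' @param baseline_mean expected acetylation reads per GBR per replicate at
#'   library factor 1 (condition A).
#' @param sensitive_drop log2 reduction of `hh_sensitive` signal in
#'   condition B.
#' @param nb_dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param n_replicates replicates per condition.
#' @param library_factors per-sample depth multipliers, condition A
#'   replicates first (length `2 * n_replicates`).
#' @param background_reads expected scattered background reads per sample at
#'   library factor 1.
#' @param motif_prob per-class probability that a GBR carries a planted GLI
#'   motif instance.
#' @param motif_strength minimum log-odds score (bits) of planted instances.
#' @param cpg_gene_fraction fraction of genes with a CpG island near the TSS.
#' @param atac_mean expected accessibility reads per stable GBR.
#' @param atac_wt_drop log2 accessibility deficit of responsive GBRs in
#'   condition A.
#' @param atac_mut_extra_drop named additional log2 drop of responsive
#'   classes in condition B.
#' @param comark_prob per-class probability of an H3K4me1 co-mark interval.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed,
    chrom_sizes = c(chr1 = 3e6, chr2 = 3e6),
    n_genes = 240,
    fraction_target_genes = 0.15,
    n_gbr = c(stable = 200, hh_sensitive = 60, hh_dependent = 60),
    n_nongbr = c(stable = 600, responsive = 30),
    nongbr_near_distance = 50000,
    promoter_bias = c(stable = 0.62, hh_sensitive = 0.26,
                      hh_dependent = 0.26),
    gbr_width = 400,
    baseline_mean = 150,
    sensitive_drop = 1.5,
    nb_dispersion = 0.025,
    n_replicates = 2,
    library_factors = NULL,
    background_reads = 20000,
    motif_prob = c(stable = 0.40, hh_sensitive = 0.57, hh_dependent = 0.70),
    motif_strength = 12,
    cpg_gene_fraction = 0.6,
    atac_mean = 120,
    atac_wt_drop = 1.5,
    atac_mut_extra_drop = c(hh_sensitive = 0.5, hh_dependent = 1.5),
    comark_prob = c(stable = 0.90, hh_sensitive = 0.82,
                    hh_dependent = 0.82)) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(library_factors))
    library_factors <- rep(c(1, 1.15, 0.9, 1.05), length.out =
                             2 * n_replicates)
  classes <- c("stable", "hh_sensitive", "hh_dependent")
  stopifnot(all(classes %in% names(n_gbr)), all(n_gbr >= 0),
            all(classes %in% names(promoter_bias)),
            all(promoter_bias >= 0 & promoter_bias <= 1),
            all(classes %in% names(motif_prob)),
            all(motif_prob >= 0 & motif_prob <= 1),
            all(chrom_sizes > 0), n_genes > 0,
            fraction_target_genes > 0, fraction_target_genes <= 1,
            baseline_mean >= 0, nb_dispersion >= 0, n_replicates >= 2,
            length(library_factors) == 2 * n_replicates,
            all(library_factors > 0))
  cfg <- as.list(environment())
  cfg$classes <- NULL
  structure(cfg, class = "simulation_config")
}

rnb <- function(n, mu, dispersion) {
  if (mu <= 0) return(integer(n))
  if (dispersion <= 0) return(stats::rpois(n, mu))
  as.integer(stats::rnbinom(n, mu = mu, size = 1 / dispersion))
}

sample_motif_instance <- function(pwm, min_score) {
  for (try in 1:50) {
    idx <- apply(pwm$prob, 1, function(p) sample.int(4, 1, prob = p))
    score <- sum(pwm$log_odds[cbind(seq_len(pwm$L), idx)])
    if (score >= min_score)
      return(paste(DNA_BASES[idx], collapse = ""))
  }
  paste(DNA_BASES[apply(pwm$prob, 1, which.max)], collapse = "")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_read_positions <- function(df, path) {
  ord <- order(df$chrom, df$pos)
  writeLines(sprintf("%s\t%d", df$chrom[ord], as.integer(df$pos[ord])), path)
  invisible(path)
}

#' Generate a complete synthetic dataset with planted ground truth
#'
#' Writes a file bundle into `outdir`: genome FASTA, gene and target-gene
#' tables, CpG-island and GBR BED files, per-sample acetylation and
#' accessibility read-position files, a per-GBR count table with sample
#' metadata, an H3K4me1 co-mark BED, a ground-truth table, and a manifest.
#' Identical `config` (including seed) produces a byte-identical bundle.
#'
#' @param config a [simulation_config()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with the bundle paths and the in-memory objects
#'   (`genes`, `gbrs`, `truth`, `counts`).
#' @export
generate_dataset <- function(config, outdir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "reads"), showWarnings = FALSE)
  withr::with_seed(config$seed, generate_dataset_impl(config, outdir))
}

generate_dataset_impl <- function(cfg, outdir) {
  cls_names <- c("stable", "hh_sensitive", "hh_dependent")
  chroms <- names(cfg$chrom_sizes)

  ## genes: evenly spaced TSSs with jitter, strand random
  n_per_chrom <- round(cfg$n_genes * cfg$chrom_sizes / sum(cfg$chrom_sizes))
  n_per_chrom[length(n_per_chrom)] <- cfg$n_genes - sum(n_per_chrom[-length(n_per_chrom)])
  genes <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    k <- n_per_chrom[ci]
    if (!k) return(NULL)
    spacing <- cfg$chrom_sizes[ci] / (k + 1)
    tss <- round(seq_len(k) * spacing +
                   stats::runif(k, -0.15, 0.15) * spacing)
    tss <- pmin(pmax(tss, 6000), cfg$chrom_sizes[ci] - 6000)
    data.frame(chrom = chroms[ci], strand = sample(c("+", "-"), k, TRUE),
               tss = tss, stringsAsFactors = FALSE)
  }))
  genes <- data.frame(gene_id = paste0("gene_", seq_len(nrow(genes))), genes,
                      stringsAsFactors = FALSE)
  n_targets <- max(1, round(cfg$n_genes * cfg$fraction_target_genes))
  target_ids <- sort(sample(genes$gene_id, n_targets))

  ## CpG islands near a fraction of TSSs
  has_cpg <- stats::runif(nrow(genes)) < cfg$cpg_gene_fraction
  cpg <- genes[has_cpg, , drop = FALSE]
  cpg_start <- pmax(0, cpg$tss + round(stats::runif(nrow(cpg), -1000, 500)))
  cpg_rs <- if (nrow(cpg))
    region_set(cpg$chrom, cpg_start, cpg_start + 300,
               id = paste0("cpg_", seq_len(nrow(cpg))), name = "cpg") else
    region_set(character(0), numeric(0), numeric(0), name = "cpg")

  ## promoter windows used for placement decisions
  prom <- promoter_windows(genes, 2000, 1000)

  ## GBR placement with a minimum 1 kb gap so neighbouring acetylation peaks
  ## stay separate after window-quantised peak calling
  total_gbr <- sum(cfg$n_gbr[cls_names])
  placed <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), class = character(0),
                       promoter = logical(0), stringsAsFactors = FALSE)
  occupied_gr <- NULL
  gap <- 1000
  w <- cfg$gbr_width
  too_close <- function(chrom, start, end) {
    if (!nrow(placed)) return(FALSE)
    same <- placed$chrom == chrom
    any(same & placed$start < end + gap & start < placed$end + gap)
  }
  for (cl in cls_names) {
    n_cl <- cfg$n_gbr[[cl]]
    if (!n_cl) next
    gene_pool <- if (cl == "stable") genes else
      genes[genes$gene_id %in% target_ids, , drop = FALSE]
    for (i in seq_len(n_cl)) {
      in_prom <- stats::runif(1) < cfg$promoter_bias[[cl]]
      ok <- FALSE
      for (try in 1:1000) {
        if (in_prom) {
          g <- gene_pool[sample.int(nrow(gene_pool), 1), ]
          pw <- promoter_windows(g, 2000, 1000)
          if (pw$end - pw$start < w) next
          s <- pw$start + floor(stats::runif(1) * (pw$end - pw$start - w + 1))
          chrom <- g$chrom
        } else {
          chrom <- sample(chroms, 1, prob = cfg$chrom_sizes)
          s <- floor(stats::runif(1) * (cfg$chrom_sizes[[chrom]] - w))
          cand <- region_set(chrom, s, s + w, id = "cand")
          if (any(lengths(intersect_any(cand, prom)) > 0)) next
        }
        if (too_close(chrom, s, s + w)) next
        placed <- rbind(placed, data.frame(
          chrom = chrom, start = s, end = s + w, class = cl,
          promoter = in_prom, stringsAsFactors = FALSE))
        ok <- TRUE
        break
      }
      if (!ok)
        stop("could not place all GBRs without overlap; ",
             "increase chromosome sizes or reduce n_gbr")
    }
  }
  gbrs <- region_set(placed$chrom, placed$start, placed$end,
                     id = paste0("gbr_", seq_len(nrow(placed))),
                     name = "gbrs")

  ## non-GBR acetylated regions: a large stable bulk (so that the changing
  ## regions are a minority of the landscape, as in real data, and
  ## library-size normalisation stays honest) plus a small responsive set
  ## clustered near responsive GBRs
  extra <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), class = character(0),
                      stringsAsFactors = FALSE)
  occupied <- function(chrom, start, end) {
    hit <- function(df) nrow(df) > 0 &&
      any(df$chrom == chrom & df$start < end + gap & start < df$end + gap)
    hit(placed) || hit(extra)
  }
  resp_rows <- which(placed$class %in% c("hh_sensitive", "hh_dependent"))
  for (kind in c("stable", "responsive")) {
    n_k <- cfg$n_nongbr[[kind]]
    if (!n_k || (kind == "responsive" && !length(resp_rows))) next
    for (i in seq_len(n_k)) {
      ok <- FALSE
      for (try in 1:1000) {
        if (kind == "responsive") {
          a <- placed[sample(resp_rows, 1), ]
          s <- a$start + sample(c(-1, 1), 1) *
            floor(stats::runif(1, gap, cfg$nongbr_near_distance))
          chrom <- a$chrom
          if (s < 0 || s + w > cfg$chrom_sizes[[chrom]]) next
        } else {
          chrom <- sample(chroms, 1, prob = cfg$chrom_sizes)
          s <- floor(stats::runif(1) * (cfg$chrom_sizes[[chrom]] - w))
        }
        if (occupied(chrom, s, s + w)) next
        extra <- rbind(extra, data.frame(
          chrom = chrom, start = s, end = s + w,
          class = paste0("nongbr_", kind), stringsAsFactors = FALSE))
        ok <- TRUE
        break
      }
      if (!ok)
        stop("could not place all non-GBR regions; ",
             "increase chromosome sizes or reduce n_nongbr")
    }
  }
  nongbr_rs <- if (nrow(extra))
    region_set(extra$chrom, extra$start, extra$end,
               id = paste0(extra$class, "_",
                           unlist(lapply(table(extra$class)[unique(extra$class)],
                                         seq_len))),
               name = "nongbr") else
    region_set(character(0), numeric(0), numeric(0), name = "nongbr")
  signal_regions <- rbind(placed[c("chrom", "start", "end", "class")], extra)

  ## genome sequence with planted motif instances inside GBRs
  seqs <- lapply(cfg$chrom_sizes, function(L)
    sample(DNA_BASES, L, replace = TRUE))
  pwm <- gli_pwm()
  motif_planted <- integer(nrow(placed))
  for (i in seq_len(nrow(placed))) {
    if (stats::runif(1) < cfg$motif_prob[[placed$class[i]]]) {
      inst <- sample_motif_instance(pwm, cfg$motif_strength)
      if (stats::runif(1) < 0.5) inst <- revcomp(inst)
      pos <- placed$start[i] +
        floor(stats::runif(1) * (w - nchar(inst) + 1))
      seqs[[placed$chrom[i]]][(pos + 1):(pos + nchar(inst))] <-
        strsplit(inst, "")[[1]]
      motif_planted[i] <- 1L
    }
  }

  ## per-class expected means (library factor 1)
  acet_mean <- function(class, cond) {
    base <- cfg$baseline_mean
    if (cond == "condition_a") return(base)
    switch(class,
           stable = base,
           nongbr_stable = base,
           hh_sensitive = base / 2^cfg$sensitive_drop,
           nongbr_responsive = base / 2^cfg$sensitive_drop,
           hh_dependent = 0)
  }
  atac_mean_fun <- function(class, cond) {
    if (grepl("^nongbr", class)) return(0)
    if (class == "stable") return(cfg$atac_mean)
    wt <- cfg$atac_mean / 2^cfg$atac_wt_drop
    if (cond == "condition_a") wt else
      wt / 2^cfg$atac_mut_extra_drop[[class]]
  }

  samples <- data.frame(
    sample_id = c(paste0("wt_rep", seq_len(cfg$n_replicates)),
                  paste0("mut_rep", seq_len(cfg$n_replicates))),
    condition = rep(c("condition_a", "condition_b"),
                    each = cfg$n_replicates),
    factor = cfg$library_factors, stringsAsFactors = FALSE)

  draw_reads <- function(mean_fun, bg_reads) {
    lapply(seq_len(nrow(samples)), function(si) {
      f <- samples$factor[si]
      cond <- samples$condition[si]
      counts <- vapply(seq_len(nrow(signal_regions)), function(i)
        rnb(1, f * mean_fun(signal_regions$class[i], cond),
            cfg$nb_dispersion), integer(1))
      pos <- unlist(lapply(seq_len(nrow(signal_regions)), function(i)
        signal_regions$start[i] + floor(stats::runif(counts[i]) * w)),
        use.names = FALSE)
      sig <- data.frame(chrom = rep(signal_regions$chrom, counts),
                        pos = if (is.null(pos)) numeric(0) else pos)
      nbg <- stats::rpois(1, f * bg_reads)
      bgc <- sample(chroms, nbg, TRUE, prob = cfg$chrom_sizes)
      bg <- data.frame(chrom = bgc,
                       pos = floor(stats::runif(nbg) *
                                     cfg$chrom_sizes[bgc]))
      out <- rbind(sig, bg)
      if (!nrow(out)) out <- data.frame(chrom = character(0),
                                        pos = numeric(0))
      out
    })
  }
  acet_reads <- stats::setNames(draw_reads(acet_mean, cfg$background_reads),
                                samples$sample_id)
  atac_reads <- stats::setNames(draw_reads(atac_mean_fun,
                                           cfg$background_reads),
                                samples$sample_id)

  ## H3K4me1 co-mark intervals over a per-class fraction of GBRs
  has_mark <- stats::runif(nrow(placed)) <
    unlist(cfg$comark_prob[placed$class])
  mark_rs <- if (any(has_mark))
    region_set(placed$chrom[has_mark], pmax(0, placed$start[has_mark] - 100),
               placed$end[has_mark] + 100,
               id = paste0("k4me1_", seq_len(sum(has_mark)))) else
    region_set(character(0), numeric(0), numeric(0))

  ## file bundle
  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    genes = file.path(outdir, "genes.tsv"),
    targets = file.path(outdir, "target_genes.txt"),
    cpg = file.path(outdir, "cpg_islands.bed"),
    gbrs = file.path(outdir, "gbrs.bed"),
    nongbr = file.path(outdir, "nongbr_acetylated.bed"),
    h3k4me1 = file.path(outdir, "h3k4me1.bed"),
    counts = file.path(outdir, "counts_acetylation.tsv"),
    samples = file.path(outdir, "samples.tsv"),
    truth = file.path(outdir, "truth.tsv"),
    manifest = file.path(outdir, "manifest.json"))

  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))
  names(genome) <- chroms
  Biostrings::writeXStringSet(genome, paths$genome, width = 80)
  write_tsv(genes, paths$genes)
  writeLines(target_ids, paths$targets)
  write_bed(cpg_rs, paths$cpg)
  write_bed(gbrs, paths$gbrs)
  write_bed(nongbr_rs, paths$nongbr)
  write_bed(mark_rs, paths$h3k4me1)

  read_paths <- list()
  for (si in seq_len(nrow(samples))) {
    pa <- file.path(outdir, "reads",
                    paste0("acet_", samples$sample_id[si], ".tsv"))
    pt <- file.path(outdir, "reads",
                    paste0("atac_", samples$sample_id[si], ".tsv"))
    write_read_positions(acet_reads[[si]], pa)
    write_read_positions(atac_reads[[si]], pt)
    read_paths[[samples$sample_id[si]]] <- list(acet = pa, atac = pt)
  }

  cm <- count_reads_in_regions(acet_reads, gbrs, samples$condition)
  counts_df <- data.frame(region_id = rownames(cm$counts), cm$counts,
                          stringsAsFactors = FALSE, row.names = NULL)
  write_tsv(counts_df, paths$counts)
  write_tsv(data.frame(sample_id = samples$sample_id,
                       condition = samples$condition,
                       library_size = cm$samples$library_size,
                       library_factor = samples$factor), paths$samples)

  truth <- data.frame(
    gbr_id = gbrs$id, chrom = placed$chrom, start = placed$start,
    end = placed$end, class = placed$class,
    motif_planted = motif_planted, promoter_proximal = placed$promoter,
    mean_a = vapply(placed$class, acet_mean, 0, cond = "condition_a"),
    mean_b = vapply(placed$class, acet_mean, 0, cond = "condition_b"),
    atac_mean_a = vapply(placed$class, atac_mean_fun, 0,
                         cond = "condition_a"),
    atac_mean_b = vapply(placed$class, atac_mean_fun, 0,
                         cond = "condition_b"),
    stringsAsFactors = FALSE)
  write_tsv(truth, paths$truth)

  cfg_list <- lapply(unclass(cfg), function(x)
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x)
  cfg_json <- jsonlite::toJSON(cfg_list, auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  writeLines(as.character(cfg_json), tf)
  manifest <- list(
    seed = cfg$seed,
    config = jsonlite::fromJSON(cfg_json),
    config_md5 = unname(tools::md5sum(tf)),
    files = lapply(paths[names(paths) != "manifest"], function(p)
      basename(p)),
    read_files = lapply(read_paths, function(x)
      lapply(x, function(p) file.path("reads", basename(p)))))
  unlink(tf)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(paths = paths, read_paths = read_paths, genes = genes,
                 targets = target_ids, gbrs = gbrs, nongbr = nongbr_rs,
                 truth = truth, counts = cm, config = cfg))
}

#' Redraw counts for an existing synthetic bundle
#'
#' Keeps the geometry (regions, genes, motifs) of a bundle produced by
#' [generate_dataset()] and draws a fresh negative-binomial count table for
#' the planted GBRs, enabling calibration and power sweeps without
#' re-planting. Background contribution to each region is approximated by
#' its Poisson expectation under the genome-wide background rate.
#'
#' @param bundle_dir directory written by [generate_dataset()].
#' @param seed_override seed for the fresh draws.
#' @param null_counts if `TRUE`, every class is drawn at its condition-A mean
#'   in both conditions (a pure-null dataset on fixed geometry).
#' @return A [count_matrix()] over the bundle's GBRs.
#' @export
regenerate_counts <- function(bundle_dir, seed_override,
                              null_counts = FALSE) {
  manifest_path <- file.path(bundle_dir, "manifest.json")
  if (!file.exists(manifest_path))
    stop("bundle manifest not found in ", bundle_dir)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- manifest$config
  truth <- utils::read.delim(file.path(bundle_dir, "truth.tsv"),
                             stringsAsFactors = FALSE)
  gbrs <- read_bed(file.path(bundle_dir, "gbrs.bed"))
  samples <- utils::read.delim(file.path(bundle_dir, "samples.tsv"),
                               stringsAsFactors = FALSE)
  w <- truth$end - truth$start
  bg_per_region <- w / sum(unlist(cfg$chrom_sizes)) * cfg$background_reads
  withr::with_seed(seed_override, {
    counts <- vapply(seq_len(nrow(samples)), function(si) {
      f <- samples$library_factor[si]
      mu <- if (samples$condition[si] == "condition_a" || null_counts)
        truth$mean_a else truth$mean_b
      vapply(seq_along(mu), function(i)
        rnb(1, f * mu[i], cfg$nb_dispersion) +
          stats::rpois(1, f * bg_per_region[i]), integer(1))
    }, integer(nrow(truth)))
    dimnames(counts) <- list(truth$gbr_id, samples$sample_id)
    count_matrix(counts, samples$condition,
                 library_size = colSums(counts) +
                   round(samples$library_factor * cfg$background_reads),
                 regions = gbrs)
  })
}
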