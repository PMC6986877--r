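enrichment_result <- function(observed, null, n_perm, seed) {
  structure(list(
    observed = observed,
    null = null,
    p_plain = sum(null >= observed) / n_perm,
    p_plus_one = (1 + sum(null >= observed)) / (1 + n_perm),
    n_perm = n_perm,
    seed = seed),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("permutation enrichment: observed = %d, n_perm = %d, seed = %s\n",
              x$observed, x$n_perm, format(x$seed)))
  cat(sprintf("  null mean %.2f [%.0f, %.0f];  p_plain = %.4g, p_plus_one = %.4g\n",
              mean(x$null), min(x$null), max(x$null), x$p_plain,
              x$p_plus_one))
  invisible(x)
}

#' Permutation test for region enrichment near target-gene TSSs
#'
#' The statistic is the number of regions overlapping at least one promoter
#' window (default 2 kb upstream / 1 kb downstream of the TSS) of the target
#' gene set. The null distribution repeats the count for `n_perm` gene sets
#' of the same size drawn uniformly without replacement from all genes.
#' Both the plain permutation p-value `#{null >= obs} / n_perm` (which can be
#' 0) and the bias-corrected `(1 + #{null >= obs}) / (1 + n_perm)`
#' (recommended) are reported.
#'
#' @param regions [region_set()] under test.
#' @param target_genes character vector of target gene ids (subset of
#'   `all_genes$gene_id`).
#' @param all_genes gene table (see [read_genes()]).
#' @param upstream,downstream promoter window extents in bp.
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed (mandatory, for reproducibility).
#' @param count `"regions"` counts regions hitting the gene set (default);
#'   `"genes"` counts genes of the set hit by any region.
#' @return An `enrichment_result` with the observed statistic, the null
#'   vector, `p_plain`, `p_plus_one`, `n_perm` and `seed`.
#' @export
tss_enrichment_test <- function(regions, target_genes, all_genes,
                                upstream = 2000, downstream = 1000,
                                n_perm = 1000, seed,
                                count = c("regions", "genes")) {
  count <- match.arg(count)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!all(target_genes %in% all_genes$gene_id))
    stop("target_genes must be a subset of all_genes")
  k <- length(target_genes)
  if (k > nrow(all_genes)) stop("more target genes than genes")
  prom <- promoter_windows(all_genes, upstream, downstream)
  ov <- intersect_any(regions, prom)           # region id -> gene ids
  pairs <- data.frame(
    region = rep(seq_along(ov), lengths(ov)),
    gene = unlist(ov, use.names = FALSE), stringsAsFactors = FALSE)
  stat <- function(gene_set) {
    hit <- pairs$gene %in% gene_set
    if (count == "regions") length(unique(pairs$region[hit]))
    else length(unique(pairs$gene[hit]))
  }
  observed <- stat(target_genes)
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      stat(sample(all_genes$gene_id, k)), 0L)
  })
  enrichment_result(observed, null, n_perm, seed)
}

#' Permutation test for clustering of regions around anchor regions
#'
#' The statistic is the number of query regions whose nearest anchor on the
#' same chromosome lies within `max_distance` bp (0 = overlap). The null
#' repositions each query region uniformly at random on its own chromosome
#' (length preserved), `n_perm` times.
#'
#' @param query,anchors [region_set()] objects.
#' @param chrom_sizes named numeric vector of chromosome lengths covering all
#'   query regions.
#' @param max_distance proximity threshold in bp (default 100 kb).
#' @param n_perm number of permutations.
#' @param seed RNG seed (mandatory).
#' @return An `enrichment_result`.
#' @export
neighbor_enrichment <- function(query, anchors, chrom_sizes,
                                max_distance = 1e5, n_perm = 1000, seed) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!all(query$chrom %in% names(chrom_sizes)))
    stop("chrom_sizes must cover all query chromosomes")
  w <- query$end - query$start
  if (any(w > chrom_sizes[query$chrom]))
    stop("query region longer than its chromosome")
  count_near <- function(rs) {
    d <- nearest_distance(rs, anchors)
    sum(!is.na(d) & d <= max_distance)
  }
  observed <- count_near(query)
  maxstart <- chrom_sizes[query$chrom] - w      # uniform start in [0, L - w]
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      s <- floor(stats::runif(nrow(query)) * (maxstart + 1))
      count_near(region_set(query$chrom, s, s + w, id = query$id))
    }, 0L)
  })
  enrichment_result(observed, null, n_perm, seed)
}
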