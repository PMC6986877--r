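# Shared fixtures, built in code at test time.

# Reduced-size simulation for pipeline mechanics tests (the full default
# bundle is exercised in the acceptance suite).
mini_sim_config <- function(seed) {
  simulation_config(
    seed = seed,
    chrom_sizes = c(chrA = 1.2e6, chrB = 1.2e6),
    n_genes = 80,
    n_gbr = c(stable = 40, hh_sensitive = 15, hh_dependent = 15),
    n_nongbr = c(stable = 120, responsive = 8),
    background_reads = 6000)
}

# The default synthetic bundle, generated once per test session.
.bundle_cache <- new.env(parent = emptyenv())
default_bundle <- function(seed = 20240101) {
  key <- paste0("b", seed)
  if (is.null(.bundle_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("bundle_", seed))
    cfg <- simulation_config(seed = seed)
    .bundle_cache[[key]] <- generate_dataset(cfg, dir)
  }
  .bundle_cache[[key]]
}

# A toy differential table for classification rule tests: one acetylation
# region per GBR position, with chosen peak_type/q/log2fc.
toy_diff <- function(chrom, start, end, q, log2fc, peak_type) {
  presence_a <- peak_type %in% c("shared", "a_only")
  presence_b <- peak_type %in% c("shared", "b_only")
  out <- data.frame(
    region_id = paste0("acet_", seq_along(start)),
    chrom = rep_len(chrom, length(start)), start = start, end = end,
    mean_a = 5, mean_b = 5 - log2fc, log2fc = log2fc,
    t = 0, df = 4, p = q, q = q,
    presence_a = presence_a, presence_b = presence_b,
    peak_type = peak_type, stringsAsFactors = FALSE)
  class(out) <- c("gbr_diff", "data.frame")
  out
}

write_bed_lines <- function(lines) {
  path <- tempfile(fileext = ".bed")
  writeLines(lines, path)
  path
}
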