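#' Construct a per-region, per-sample count matrix
#'
#' @param counts non-negative integer matrix, regions in rows (rownames =
#'   region ids), samples in columns (colnames = sample ids).
#' @param condition condition label per sample (e.g. `"condition_a"`,
#'   `"condition_b"`).
#' @param library_size total mapped reads per sample; must be at least the
#'   column sum.
#' @param regions optional [region_set()] describing the rows.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, condition, library_size, regions = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(condition) != ncol(counts))
    stop("every sample needs a condition label")
  library_size <- as.numeric(library_size)
  if (length(library_size) != ncol(counts) || any(library_size <= 0))
    stop("library_size must be a positive value per sample")
  if (any(library_size < colSums(counts)))
    stop("library_size cannot be smaller than the per-sample column sum")
  if (is.null(colnames(counts)) && ncol(counts))
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  if (is.null(rownames(counts)) && nrow(counts))
    rownames(counts) <- paste0("region_", seq_len(nrow(counts)))
  if (!is.null(regions) && nrow(counts) > 0 &&
      !identical(regions$id, rownames(counts)))
    stop("region ids must match count matrix rownames")
  structure(list(
    counts = counts,
    samples = data.frame(sample_id = colnames(counts),
                         condition = as.character(condition),
                         library_size = library_size,
                         stringsAsFactors = FALSE),
    regions = regions),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d regions x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(x$samples)
  invisible(x)
}

#' Read simplified read positions from a 2-column TSV
#'
#' Each line is `chrom<TAB>position`, one read per line, positions 0-based.
#'
#' @param path input path.
#' @return data.frame with columns `chrom`, `pos`.
#' @export
read_positions <- function(path) {
  df <- utils::read.delim(path, header = FALSE, col.names = c("chrom", "pos"),
                          colClasses = c("character", "numeric"))
  if (any(df$pos < 0)) stop("read positions must be non-negative")
  df
}

#' Count reads overlapping each region
#'
#' A read (a single 5' position) is counted for a region when its position
#' lies in `[start, end)`; a read may count toward several overlapping
#' regions. The library size of each sample is its total read count. Reads on
#' chromosomes absent from the region set contribute to the library size but
#' to no region; a warning reports them.
#'
#' @param reads_by_sample named list of data.frames with columns `chrom`,
#'   `pos` (one element per sample).
#' @param regions a [region_set()].
#' @param condition condition label per sample, recycled if length 1.
#' @return A [count_matrix()].
#' @export
count_reads_in_regions <- function(reads_by_sample, regions, condition) {
  if (is.null(names(reads_by_sample)))
    names(reads_by_sample) <- paste0("sample_", seq_along(reads_by_sample))
  condition <- rep_len(condition, length(reads_by_sample))
  rgr <- as_granges(regions)
  counts <- vapply(reads_by_sample, function(rd) {
    if (!nrow(rd)) return(integer(nrow(regions)))
    unknown <- !rd$chrom %in% unique(regions$chrom)
    if (any(unknown) && nrow(regions))
      warning(sprintf("%d read(s) on chromosomes without regions (e.g. %s)",
                      sum(unknown), rd$chrom[which(unknown)[1]]))
    pts <- GenomicRanges::GRanges(rd$chrom,
                                  IRanges::IRanges(rd$pos + 1, width = 1))
    GenomicRanges::countOverlaps(rgr, pts)
  }, integer(nrow(regions)))
  counts <- matrix(as.integer(counts), nrow = nrow(regions),
                   ncol = length(reads_by_sample),
                   dimnames = list(regions$id, names(reads_by_sample)))
  count_matrix(counts, condition,
               library_size = pmax(1, vapply(reads_by_sample, nrow, 0L)),
               regions = regions)
}

#' Library-size-adjusted log2 counts
#'
#' `log2(count * reference_depth / library_size + 1)`: counts are scaled to a
#' common sequencing depth and log2 transformed after adding a pseudo-count
#' of 1, so a zero count maps to 0.
#'
#' @param cm a [count_matrix()].
#' @param reference_depth scaling target; defaults to the median library
#'   size.
#' @return Numeric matrix, same shape as the counts.
#' @export
normalize_log2 <- function(cm, reference_depth = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(reference_depth))
    reference_depth <- stats::median(cm$samples$library_size)
  if (reference_depth <= 0) stop("reference_depth must be positive")
  sf <- reference_depth / cm$samples$library_size
  log2(sweep(cm$counts, 2, sf, `*`) + 1)
}

#' Fixed-window Poisson peak caller
#'
#' A deliberately simplified stand-in for a full peak caller (MACS2-style
#' callers model local background, fragment length and duplicates; this does
#' not). The genome is tiled with non-overlapping windows of fixed width;
#' each window's read count is tested against the genome-wide background rate
#' with an upper-tail Poisson test, p-values are BH-adjusted across all
#' windows, and runs of consecutive significant windows are merged into
#' peaks. A merged peak carries the minimum q of its windows and the
#' length-weighted mean log2 enrichment over background. Externally produced
#' peak calls can always be supplied as BED and this caller bypassed.
#'
#' @param reads data.frame with columns `chrom`, `pos` (0-based), typically
#'   the pooled replicates of one condition.
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param window window width in bp (default 200).
#' @param q_cutoff BH-adjusted significance cutoff (default 0.05).
#' @param id_prefix prefix for peak ids.
#' @return A [region_set()] of peaks with extra columns `enrichment`
#'   (log2 over background) and `q`.
#' @export
call_peaks_fixed_windows <- function(reads, chrom_sizes, window = 200,
                                     q_cutoff = 0.05, id_prefix = "peak") {
  if (any(chrom_sizes <= 0)) stop("chromosome sizes must be positive")
  if (!nrow(reads)) {
    warning("no reads supplied; returning no peaks")
    return(region_set(character(0), numeric(0), numeric(0)))
  }
  bad <- setdiff(unique(reads$chrom), names(chrom_sizes))
  if (length(bad))
    stop("reads on chromosome absent from chrom_sizes: ", bad[1])
  over <- reads$pos >= chrom_sizes[reads$chrom]
  if (any(over))
    stop("read position beyond chromosome end on ",
         reads$chrom[which(over)[1]])
  n_win <- ceiling(chrom_sizes / window)
  total_windows <- sum(n_win)
  lambda <- nrow(reads) * window / sum(chrom_sizes)
  # per-window counts, genome-wide
  win_chrom <- rep(names(chrom_sizes), n_win)
  win_idx <- unlist(lapply(n_win, seq_len), use.names = FALSE)
  key <- paste0(win_chrom, ":", win_idx)
  cnt <- stats::setNames(integer(total_windows), key)
  rk <- paste0(reads$chrom, ":", floor(reads$pos / window) + 1)
  tab <- table(rk)
  cnt[names(tab)] <- as.integer(tab)
  p <- stats::ppois(cnt - 1, lambda, lower.tail = FALSE)
  q <- bh_fdr(p)
  sig <- which(q < q_cutoff)
  if (!length(sig))
    return(region_set(character(0), numeric(0), numeric(0)))
  sc <- win_chrom[sig]
  si <- win_idx[sig]
  # merge runs of consecutive significant windows per chromosome
  ord <- order(sc, si)
  sc <- sc[ord]; si <- si[ord]
  newrun <- c(TRUE, sc[-1] != sc[-length(sc)] | diff(si) != 1)
  runid <- factor(cumsum(newrun), levels = unique(cumsum(newrun)))
  enr <- log2(pmax(cnt[sig][ord], 1) / lambda)
  starts <- tapply((si - 1) * window, runid, min)
  chroms <- tapply(sc, runid, `[`, 1)
  ends <- pmin(tapply(si * window, runid, max),
               chrom_sizes[as.character(chroms)])
  qmin <- tapply(q[sig][ord], runid, min)
  enrich <- tapply(enr, runid, mean)
  rs <- region_set(as.character(chroms), as.numeric(starts), as.numeric(ends),
                   id = paste0(id_prefix, "_", seq_along(starts)),
                   name = "peaks")
  rs$enrichment <- as.numeric(enrich)
  rs$q <- as.numeric(qmin)
  rs
}

#' Differential enrichment between two conditions over merged peak regions
#'
#' Normalises counts by library size ([normalize_log2()]), tests condition A
#' against condition B with the empirical-Bayes moderated t
#' ([moderated_t()]), adjusts p-values by Benjamini-Hochberg, and annotates
#' each region with per-condition peak presence (any overlap with the
#' condition's called peaks) and the derived `peak_type`
#' (`shared` / `a_only` / `b_only` / `neither`).
#'
#' @param cm [count_matrix()] whose regions are the merged union of the two
#'   conditions' peaks and whose samples carry conditions `condition_a` and
#'   `condition_b` (at least 2 replicates each).
#' @param peaks_a,peaks_b [region_set()] of peaks called in each condition;
#'   when `NULL` presence flags default to `TRUE` (useful for pure count
#'   comparisons).
#' @param fdr significance threshold recorded in the result (default 0.05).
#' @param reference_depth passed to [normalize_log2()].
#' @return A data.frame of class `gbr_diff`: per region the coordinates,
#'   normalized log2 means per condition, `log2fc` (A - B), `t`, `df`, `p`,
#'   `q`, presence flags and `peak_type`.
#' @export
differential_regions <- function(cm, peaks_a = NULL, peaks_b = NULL,
                                 fdr = 0.05, reference_depth = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  ia <- cm$samples$condition == "condition_a"
  ib <- cm$samples$condition == "condition_b"
  if (sum(ia) < 2 || sum(ib) < 2)
    stop("need >= 2 replicates per condition")
  norm <- normalize_log2(cm, reference_depth)
  res <- moderated_t(norm[, ia, drop = FALSE], norm[, ib, drop = FALSE])
  q <- bh_fdr(res$p)
  regions <- cm$regions
  if (is.null(regions))
    regions <- region_set("chrUnknown", seq_len(nrow(norm)) * 10 - 10,
                          seq_len(nrow(norm)) * 10,
                          id = rownames(cm$counts))
  pres_a <- if (is.null(peaks_a)) rep(TRUE, nrow(regions)) else
    lengths(intersect_any(regions, peaks_a)) > 0
  pres_b <- if (is.null(peaks_b)) rep(TRUE, nrow(regions)) else
    lengths(intersect_any(regions, peaks_b)) > 0
  if (!is.null(peaks_a) && !any(pres_a) && !any(pres_b))
    warning("no region overlaps any supplied peak")
  peak_type <- ifelse(pres_a & pres_b, "shared",
               ifelse(pres_a, "a_only",
               ifelse(pres_b, "b_only", "neither")))
  out <- data.frame(
    region_id = rownames(cm$counts),
    chrom = regions$chrom, start = regions$start, end = regions$end,
    mean_a = res$mean1, mean_b = res$mean2, log2fc = res$diff,
    t = res$t, df = res$df, p = res$p, q = q,
    presence_a = pres_a, presence_b = pres_b, peak_type = peak_type,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "fdr") <- fdr
  class(out) <- c("gbr_diff", "data.frame")
  out
}

#' @export
print.gbr_diff <- function(x, ...) {
  fdr <- attr(x, "fdr") %||% 0.05
  cat(sprintf("differential enrichment over %d regions (FDR threshold %g)\n",
              nrow(x), fdr))
  cat(sprintf("  significant (q < %g): %d  [A>B: %d, B>A: %d]\n", fdr,
              sum(x$q < fdr), sum(x$q < fdr & x$log2fc > 0),
              sum(x$q < fdr & x$log2fc < 0)))
  tt <- table(x$peak_type)
  cat("  peak types:", paste(names(tt), tt, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.gbr_diff <- function(object, ...) {
  fdr <- attr(object, "fdr") %||% 0.05
  list(n = nrow(object),
       n_significant = sum(object$q < fdr),
       n_up_a = sum(object$q < fdr & object$log2fc > 0),
       n_up_b = sum(object$q < fdr & object$log2fc < 0),
       peak_types = table(object$peak_type))
}

#' Write / read a differential result table as TSV
#'
#' @param diff a `gbr_diff` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diff_tsv <- function(diff, path) {
  utils::write.table(as.data.frame(diff), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_diff_tsv
#' @export
read_diff_tsv <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("gbr_diff", "data.frame")
  out
}
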