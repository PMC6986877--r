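DNA_BASES <- c("A", "C", "G", "T")

#' Load a position weight matrix from a JASPAR-style text file
#'
#' Accepts the JASPAR layout (optional `>` header line, then four rows
#' `A [ 1 2 ... ]` ... `T [ ... ]`) or a bare 4-row whitespace-separated
#' matrix in ACGT row order. Counts (or frequencies) are converted to
#' per-position probabilities with a pseudocount:
#' `p = (count + pseudocount) / (column_total + 4 * pseudocount)`.
#'
#' @param path input path.
#' @param pseudocount added to every cell (default 0.25).
#' @param background background base frequencies over ACGT (default
#'   uniform).
#' @return A `pwm` object: list with `L` (motif width), `prob` (L x 4
#'   probability matrix), `log_odds` (L x 4, bits, `log2(p / background)`),
#'   `background`, `pseudocount`.
#' @export
load_pwm <- function(path, pseudocount = 0.25,
                     background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^>", lines) & nzchar(trimws(lines))]
  if (length(lines) != 4)
    stop("PWM parse error: expected 4 matrix rows (ACGT), got ",
         length(lines))
  rows <- lapply(lines, function(l) {
    l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
    l <- gsub("\\[|\\]", " ", l)
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    if (any(is.na(v))) stop("PWM parse error: non-numeric entry in row: ", l)
    v
  })
  if (length(unique(lengths(rows))) != 1)
    stop("PWM parse error: ragged rows")
  counts <- do.call(cbind, rows)          # L x 4
  if (any(counts < 0)) stop("PWM parse error: negative entries")
  pwm_from_counts(counts, pseudocount, background)
}

#' Build a PWM from an L x 4 count (or frequency) matrix
#'
#' @param counts numeric matrix, positions in rows, columns in ACGT order.
#' @inheritParams load_pwm
#' @return A `pwm` object.
#' @export
pwm_from_counts <- function(counts, pseudocount = 0.25,
                            background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4) stop("count matrix must have 4 columns (ACGT)")
  if (nrow(counts) < 2) stop("motif width must be at least 2")
  if (abs(sum(background) - 1) > 1e-6)
    stop("background frequencies must sum to 1")
  prob <- (counts + pseudocount) /
    (rowSums(counts) + 4 * pseudocount)
  colnames(prob) <- DNA_BASES
  structure(list(L = nrow(prob), prob = prob,
                 log_odds = log2(sweep(prob, 2, background, `/`)),
                 background = background, pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cons <- paste(DNA_BASES[apply(x$prob, 1, which.max)], collapse = "")
  cat(sprintf("pwm: width %d, consensus %s, max score %.2f bits\n",
              x$L, cons, sum(apply(x$log_odds, 1, max))))
  invisible(x)
}

#' The bundled GLI-like position weight matrix
#'
#' A synthetic matrix constructed from the canonical GACCACCCA GLI-repressor
#' consensus (count 10 for the consensus base at each position, 0 elsewhere,
#' before pseudocounts). It is a documented stand-in for scanning synthetic
#' data; supply an experimentally derived matrix for real analyses.
#'
#' @inheritParams load_pwm
#' @return A `pwm` object.
#' @export
gli_pwm <- function(pseudocount = 0.25, background = rep(0.25, 4)) {
  load_pwm(system.file("extdata", "gli_motif_synthetic.jaspar",
                       package = "gliEnhancers"),
           pseudocount = pseudocount, background = background)
}

revcomp <- function(seq) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         vapply(seq, function(s)
           paste(rev(strsplit(s, "")[[1]]), collapse = ""), ""))
}

scan_one_strand <- function(lo, idx, L) {
  S <- length(idx) - L + 1
  if (S < 1) return(list(score = numeric(0), ok = logical(0)))
  sc <- numeric(S)
  ok <- rep(TRUE, S)
  for (j in seq_len(L)) {
    b <- idx[j:(j + S - 1)]
    ok <- ok & !is.na(b)
    v <- lo[j, ]
    vv <- v[b]
    vv[is.na(vv)] <- 0
    sc <- sc + vv
  }
  list(score = sc, ok = ok)
}

#' Scan a sequence for motif hits on both strands
#'
#' Every window of the motif width is scored as the sum of per-position
#' log2-odds (bits) on the forward strand and on the reverse complement;
#' windows containing `N` are skipped. Reverse-strand hits report the offset
#' of the window in forward-strand coordinates.
#'
#' @param pwm a `pwm` object.
#' @param sequence DNA string over ACGTN (case-insensitive).
#' @param threshold minimum score in bits for a hit (default 7).
#' @param region_id label recorded with each hit.
#' @return data.frame with columns `region_id`, `offset` (0-based), `strand`,
#'   `score`; empty when the sequence is shorter than the motif.
#' @export
scan_region <- function(pwm, sequence, threshold = 7, region_id = "region") {
  stopifnot(inherits(pwm, "pwm"), is.finite(threshold))
  seq <- toupper(sequence)
  n <- nchar(seq)
  empty <- data.frame(region_id = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (n < pwm$L) return(empty)
  chars <- strsplit(seq, "")[[1]]
  if (!all(chars %in% c(DNA_BASES, "N")))
    stop("sequence must be over ACGTN")
  idx_f <- match(chars, DNA_BASES)
  idx_r <- match(strsplit(revcomp(seq), "")[[1]], DNA_BASES)
  fwd <- scan_one_strand(pwm$log_odds, idx_f, pwm$L)
  rev <- scan_one_strand(pwm$log_odds, idx_r, pwm$L)
  hf <- which(fwd$ok & fwd$score >= threshold)
  hr <- which(rev$ok & rev$score >= threshold)
  out <- rbind(
    if (length(hf)) data.frame(region_id = region_id, offset = hf - 1L,
                               strand = "+", score = fwd$score[hf],
                               stringsAsFactors = FALSE),
    if (length(hr)) data.frame(region_id = region_id,
                               offset = n - pwm$L - (hr - 1L),
                               strand = "-", score = rev$score[hr],
                               stringsAsFactors = FALSE))
  if (is.null(out)) empty else out[order(out$offset, out$strand), ,
                                   drop = FALSE]
}

#' Scan many regions against a genome FASTA
#'
#' Extracts each region's sequence from the genome and applies
#' [scan_region()].
#'
#' @param pwm a `pwm` object.
#' @param regions a [region_set()].
#' @param genome a `Biostrings::DNAStringSet` or path to a FASTA file.
#' @param threshold minimum hit score in bits.
#' @return data.frame of hits over all regions (possibly empty).
#' @export
scan_regions <- function(pwm, regions, genome, threshold = 7) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  nm <- sub("\\s.*", "", names(genome))
  missing <- setdiff(unique(regions$chrom), nm)
  if (length(missing))
    stop("chromosome missing from genome FASTA: ", missing[1])
  hits <- lapply(seq_len(nrow(regions)), function(i) {
    s <- as.character(Biostrings::subseq(genome[[match(regions$chrom[i], nm)]],
                                         regions$start[i] + 1,
                                         regions$end[i]))
    scan_region(pwm, s, threshold, region_id = regions$id[i])
  })
  do.call(rbind, hits)
}

#' Per-region motif presence, quantity and quality
#'
#' @param hits hit data.frame from [scan_regions()].
#' @param region_ids all region ids scanned (regions without hits get
#'   `has_motif = FALSE`).
#' @param quality `"mean"` (default) or `"max"` hit score per region.
#' @return data.frame with columns `region_id`, `has_motif`, `quantity`
#'   (hit count) and `quality` (bits; `NA` without hits).
#' @export
region_motif_stats <- function(hits, region_ids,
                               quality = c("mean", "max")) {
  quality <- match.arg(quality)
  qfun <- if (quality == "mean") mean else max
  cnt <- stats::setNames(integer(length(region_ids)), region_ids)
  qual <- stats::setNames(rep(NA_real_, length(region_ids)), region_ids)
  if (!is.null(hits) && nrow(hits)) {
    tb <- table(hits$region_id)
    cnt[names(tb)] <- as.integer(tb)
    qq <- tapply(hits$score, hits$region_id, qfun)
    qual[names(qq)] <- as.numeric(qq)
  }
  data.frame(region_id = region_ids, has_motif = cnt >= 1,
             quantity = as.integer(cnt), quality = qual,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare motif statistics between GBR classes
#'
#' For each class: number of regions, fraction containing at least one motif,
#' and mean quantity and mean quality restricted to motif-containing regions.
#' Each non-reference class is tested against the reference (default
#' `stable`): presence by a one-sided two-proportion test with continuity
#' correction, quantity and quality by one-sided Wilcoxon rank-sum tests over
#' motif-containing regions (alternative: class exceeds reference). Tests are
#' `NA` when a class has no motif-containing regions.
#'
#' @param stats_by_class named list of [region_motif_stats()] data.frames.
#' @param reference name of the reference class.
#' @return List with `report` (per-class summaries) and `tests` (pairwise
#'   p-values), of class `motif_comparison`.
#' @export
compare_motif_stats <- function(stats_by_class, reference = "stable") {
  if (length(stats_by_class) < 2) stop("need at least 2 classes")
  if (!reference %in% names(stats_by_class))
    stop("reference class '", reference, "' not supplied")
  if (any(!vapply(stats_by_class, nrow, 0L)))
    stop("every class must be non-empty")
  report <- do.call(rbind, lapply(names(stats_by_class), function(cl) {
    s <- stats_by_class[[cl]]
    withm <- s[s$has_motif, , drop = FALSE]
    data.frame(class = cl, n = nrow(s),
               n_with_motif = nrow(withm),
               presence_fraction = mean(s$has_motif),
               mean_quantity = if (nrow(withm)) mean(withm$quantity) else NA,
               mean_quality = if (nrow(withm)) mean(withm$quality) else NA,
               stringsAsFactors = FALSE)
  }))
  ref <- stats_by_class[[reference]]
  refm <- ref[ref$has_motif, , drop = FALSE]
  tests <- do.call(rbind, lapply(setdiff(names(stats_by_class), reference),
                                 function(cl) {
    s <- stats_by_class[[cl]]
    sm <- s[s$has_motif, , drop = FALSE]
    p_presence <- two_proportion_test(sum(s$has_motif), nrow(s),
                                      sum(ref$has_motif), nrow(ref),
                                      "greater")
    p_quantity <- if (nrow(sm) && nrow(refm))
      wilcoxon_rank_sum(sm$quantity, refm$quantity, "greater") else NA
    p_quality <- if (nrow(sm) && nrow(refm))
      wilcoxon_rank_sum(sm$quality, refm$quality, "greater") else NA
    data.frame(class = cl, reference = reference, p_presence = p_presence,
               p_quantity = p_quantity, p_quality = p_quality,
               stringsAsFactors = FALSE)
  }))
  structure(list(report = report, tests = tests), class = "motif_comparison")
}

#' @export
print.motif_comparison <- function(x, ...) {
  cat("motif statistics by class:\n")
  print(x$report, row.names = FALSE, digits = 3)
  cat("one-sided tests vs reference:\n")
  print(x$tests, row.names = FALSE, digits = 3)
  invisible(x)
}
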