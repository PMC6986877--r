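#' Construct a region set
#'
#' A region set is the universal currency of the pipeline: an ordered
#' collection of genomic intervals in 0-based half-open (BED) coordinates,
#' each carrying a unique id. Internally it is a plain `data.frame` with
#' columns `chrom`, `start`, `end`, `strand`, `id` and class `region_set`.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start integer vector, 0-based inclusive start coordinates.
#' @param end integer vector, exclusive end coordinates (`start < end`).
#' @param strand character vector in `"+"`, `"-"`, `"*"` (unstranded).
#' @param id unique labels; auto-generated (`region_1`, ...) when `NULL`.
#'   Duplicated ids are de-duplicated with numeric suffixes, with a warning.
#' @param name label for the set.
#' @return A `region_set` data.frame.
#' @export
region_set <- function(chrom, start, end, strand = "*", id = NULL,
                       name = "regions") {
  n <- max(length(chrom), length(start), length(end))
  if (!length(chrom) || !length(start) || !length(end)) n <- 0L
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  strand <- rep_len(as.character(strand), n)
  if (any(is.na(chrom)) || any(!nzchar(chrom)))
    stop("chrom must be non-empty strings")
  if (any(is.na(start)) || any(is.na(end)))
    stop("start/end must be numeric")
  if (any(start < 0))
    stop("start must be >= 0")
  if (any(start >= end))
    stop("start must be < end for every interval")
  if (!all(strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  if (is.null(id)) {
    id <- if (n) paste0("region_", seq_len(n)) else character(0)
  } else {
    id <- as.character(id)
    if (n == 0) id <- character(0)   # paste0 maps empty input to ""
    if (length(id) != n) stop("ids must match the number of intervals")
    if (anyDuplicated(id)) {
      warning("duplicate region ids de-duplicated with suffixes")
      id <- make.unique(id, sep = "_dup")
    }
  }
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    strand = strand, id = id, stringsAsFactors = FALSE)
  attr(out, "set_name") <- name
  class(out) <- c("region_set", "data.frame")
  out
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set '%s': %d intervals on %d chromosome(s)\n",
              attr(x, "set_name") %||% "regions", nrow(x),
              length(unique(x$chrom))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# GRanges bridge: region_set stores 0-based half-open, GRanges is 1-based
# closed, so start+1 on the way in and start-1 on the way out.
as_granges <- function(rs) {
  GenomicRanges::GRanges(
    seqnames = rs$chrom,
    ranges = IRanges::IRanges(start = rs$start + 1, end = rs$end),
    strand = ifelse(rs$strand == "*", "*", rs$strand))
}

#' Read a BED3/BED6 file into a region set
#'
#' Coordinates follow the BED convention (0-based half-open). Column 4, when
#' present, supplies ids (missing/`.` names get sequential ids); column 6, when
#' present, supplies strand. Malformed lines raise an error naming the line.
#'
#' @param path path to a tab-separated BED file.
#' @param name label for the resulting set (defaults to the file name).
#' @return A [region_set()].
#' @export
read_bed <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx))
    return(region_set(character(0), numeric(0), numeric(0), name = name))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop(sprintf("BED parse error at line %d: fewer than 3 fields",
                 idx[which(nf < 3)[1]]))
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("BED parse error at line %d: non-integer coordinates",
                 idx[bad[1]]))
  bad <- which(start >= end | start < 0)
  if (length(bad))
    stop(sprintf("BED parse error at line %d: invalid interval [%s, %s)",
                 idx[bad[1]], start[bad[1]], end[bad[1]]))
  ids <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4, length(f))], ""),
                NA_character_)
  miss <- is.na(ids) | ids == "." | !nzchar(ids)
  ids[miss] <- paste0("region_", which(miss))
  strand <- ifelse(nf >= 6,
                   vapply(fields, function(f) f[min(6, length(f))], ""), "*")
  strand[!strand %in% c("+", "-")] <- "*"
  region_set(chrom, start, end, strand, id = ids, name = name)
}

#' Write a region set as BED6
#'
#' Emits chrom, start, end, id, score 0 and strand (`.` for unstranded), so
#' that `read_bed(write_bed(x))` round-trips exactly.
#'
#' @param rs a [region_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(rs, path) {
  strand <- ifelse(rs$strand == "*", ".", rs$strand)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", rs$chrom, as.integer(rs$start),
                   as.integer(rs$end), rs$id, strand)
  writeLines(lines, path)
  invisible(path)
}

#' Map query regions to overlapping subject regions
#'
#' Overlap means at least one shared base under half-open arithmetic; adjacent
#' intervals (`end == start`) do not overlap. Every query id is present in the
#' result, possibly with an empty hit vector.
#'
#' @param query,subject [region_set()] objects.
#' @return Named list: for each query id, the character vector of overlapping
#'   subject ids.
#' @export
intersect_any <- function(query, subject) {
  out <- stats::setNames(rep(list(character(0)), nrow(query)), query$id)
  if (!nrow(query) || !nrow(subject)) return(out)
  # disjoint chromosome sets legitimately share no sequence levels
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(query), as_granges(subject),
                                ignore.strand = TRUE))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (length(qh)) {
    byq <- split(subject$id[sh], qh)
    out[as.integer(names(byq))] <- byq
    names(out) <- query$id
  }
  out
}

#' Merge overlapping intervals
#'
#' Returns disjoint, sorted intervals whose union equals the input union.
#' Adjacent intervals (`end == start`) are kept separate, consistent with
#' half-open semantics. Strand is ignored; merged intervals are unstranded and
#' get fresh sequential ids.
#'
#' @param rs a [region_set()].
#' @param id_prefix prefix for the new ids.
#' @return A [region_set()] of merged intervals.
#' @export
merge_overlapping <- function(rs, id_prefix = "merged") {
  if (!nrow(rs)) return(rs)
  gr <- GenomicRanges::reduce(as_granges(rs), min.gapwidth = 0L,
                              ignore.strand = TRUE)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  region_set(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr) - 1, GenomicRanges::end(gr),
             id = paste0(id_prefix, "_", seq_along(gr)),
             name = attr(rs, "set_name") %||% "regions")
}

#' Strand-aware promoter windows around gene TSSs
#'
#' For a plus-strand gene the window is `[tss - upstream, tss + downstream)`;
#' for a minus-strand gene it is the coordinate mirror
#' `[tss - downstream, tss + upstream)`. Coordinates are clipped at 0.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`, `tss`
#'   (0-based coordinate of the first transcribed base).
#' @param upstream,downstream window extents in bp (both `>= 0`, not both 0).
#' @param stranded if `FALSE`, all genes are treated as plus-strand
#'   (strand-ignorant mode).
#' @return A [region_set()] with one window per gene, ids = gene ids.
#' @export
promoter_windows <- function(genes, upstream = 2000, downstream = 1000,
                             stranded = TRUE) {
  stopifnot(all(c("gene_id", "chrom", "strand", "tss") %in% names(genes)))
  if (upstream < 0 || downstream < 0 || (upstream == 0 && downstream == 0))
    stop("upstream and downstream must be >= 0 and not both 0")
  strand <- if (stranded) genes$strand else rep("+", nrow(genes))
  if (stranded && !all(strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-' (strand required for promoter windows)")
  plus <- strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  start <- pmax(start, 0)
  region_set(genes$chrom, start, end, strand, id = genes$gene_id,
             name = "promoters")
}

#' Flag genes whose promoter lies near a CpG island
#'
#' A gene is flagged when any CpG island overlaps the window 5 kb upstream to
#' 2.5 kb downstream of its TSS, the conventional definition of a CpG-island
#' promoter.
#'
#' @param genes data.frame as in [promoter_windows()].
#' @param cpg_islands [region_set()] of CpG islands.
#' @param upstream,downstream window extents in bp.
#' @return Named logical vector over `gene_id`.
#' @export
assign_cpg_promoters <- function(genes, cpg_islands,
                                 upstream = 5000, downstream = 2500) {
  win <- promoter_windows(genes, upstream, downstream)
  hits <- intersect_any(win, cpg_islands)
  stats::setNames(lengths(hits) > 0, genes$gene_id)
}

#' Distance from each query interval to the nearest subject interval
#'
#' Distance is the gap in bp between closest ends (0 for overlapping or
#' adjacent intervals), computed on the same chromosome only. Queries with no
#' same-chromosome subject get `NA`.
#'
#' @param query,subjects [region_set()] objects.
#' @return Numeric vector named by query id.
#' @export
nearest_distance <- function(query, subjects) {
  out <- stats::setNames(rep(NA_real_, nrow(query)), query$id)
  if (!nrow(query) || !nrow(subjects)) return(out)
  hits <- suppressWarnings(
    GenomicRanges::distanceToNearest(as_granges(query), as_granges(subjects),
                                     ignore.strand = TRUE))
  out[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  names(out) <- query$id
  out
}

#' Read a gene annotation table
#'
#' Accepts either a 4-column TSV with header `gene_id`, `chrom`, `strand`,
#' `tss` (0-based), or a BED6 file where the TSS is taken as `start` for
#' plus-strand genes and `end - 1` for minus-strand genes.
#'
#' @param path input path.
#' @param format `"auto"` detects BED by extension.
#' @return data.frame with columns `gene_id`, `chrom`, `strand`, `tss`.
#' @export
read_genes <- function(path, format = c("auto", "tsv", "bed")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  if (format == "bed") {
    rs <- read_bed(path)
    if (!all(rs$strand %in% c("+", "-")))
      stop("gene BED must carry strand in column 6")
    tss <- ifelse(rs$strand == "+", rs$start, rs$end - 1)
    return(data.frame(gene_id = rs$id, chrom = rs$chrom, strand = rs$strand,
                      tss = tss, stringsAsFactors = FALSE))
  }
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss")
  if (!all(need %in% names(g)))
    stop("gene TSV must have columns: ", paste(need, collapse = ", "))
  g[need]
}
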