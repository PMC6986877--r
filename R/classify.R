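#' Classify GLI binding regions by their acetylation response
#'
#' Each GLI binding region (GBR) is labelled from the differential-enrichment
#' results of the acetylation regions overlapping it, applying rules in
#' precedence order:
#'
#' 1. no overlapping region with acetylation in condition A (wild type) ->
#'    `non_acetylated`;
#' 2. every overlapping A-present region has `peak_type == "a_only"`
#'    (acetylation completely absent in condition B) -> `hh_dependent`;
#' 3. otherwise, any overlapping region significantly reduced in B
#'    (`q < fdr` and `log2fc > 0`) -> `hh_sensitive`;
#' 4. otherwise -> `stable`.
#'
#' The `hh_dependent` rule requires *all* overlapping wild-type acetylation to
#' vanish (a conservative reading of "complete absence"); any retained but
#' significantly reduced region yields `hh_sensitive`. "HH-responsive" denotes
#' the union of `hh_sensitive` and `hh_dependent`.
#'
#' @param gbrs [region_set()] of GLI binding regions.
#' @param diff `gbr_diff` result from [differential_regions()] over the
#'   merged acetylation regions.
#' @param fdr significance threshold for rule 3 (default 0.05).
#' @param comarks optional named list of [region_set()]s (e.g. `H3K4me1`,
#'   `ATAC`); each contributes an any-overlap logical column.
#' @param genes optional gene table (see [read_genes()]); adds
#'   `promoter_proximal` (overlap with any 2 kb upstream / 1 kb downstream
#'   TSS window) and, together with `cpg_islands`, `cpg_promoter` (overlap
#'   with the promoter window of a CpG-island gene).
#' @param cpg_islands optional [region_set()] of CpG islands.
#' @return data.frame of class `gbr_class`: per GBR the coordinates, `label`,
#'   supporting evidence (`n_overlap`, `min_q`, `log2fc` of the minimum-q
#'   overlapping region), co-mark flags and promoter annotations.
#' @export
classify_gbrs <- function(gbrs, diff, fdr = 0.05, comarks = NULL,
                          genes = NULL, cpg_islands = NULL) {
  if (!nrow(gbrs)) stop("GBR set is empty")
  stopifnot(inherits(diff, "gbr_diff"))
  if (anyDuplicated(diff$region_id))
    stop("differential region ids must be unique")
  diff_rs <- region_set(diff$chrom, diff$start, diff$end, id = diff$region_id,
                        name = "acetylation")
  ov <- intersect_any(gbrs, diff_rs)
  lab <- character(nrow(gbrs))
  min_q <- rep(NA_real_, nrow(gbrs))
  lfc <- rep(NA_real_, nrow(gbrs))
  n_overlap <- integer(nrow(gbrs))
  for (i in seq_len(nrow(gbrs))) {
    rows <- match(ov[[i]], diff$region_id)
    rows <- rows[diff$presence_a[rows]]        # only WT-acetylated regions
    n_overlap[i] <- length(rows)
    if (!length(rows)) {
      lab[i] <- "non_acetylated"
      next
    }
    j <- rows[which.min(diff$q[rows])]
    min_q[i] <- diff$q[j]
    lfc[i] <- diff$log2fc[j]
    if (all(diff$peak_type[rows] == "a_only")) {
      lab[i] <- "hh_dependent"
    } else if (any(diff$q[rows] < fdr & diff$log2fc[rows] > 0)) {
      lab[i] <- "hh_sensitive"
    } else {
      lab[i] <- "stable"
    }
  }
  out <- data.frame(gbr_id = gbrs$id, chrom = gbrs$chrom, start = gbrs$start,
                    end = gbrs$end, label = lab, n_overlap = n_overlap,
                    min_q = min_q, log2fc = lfc, stringsAsFactors = FALSE)
  for (mark in names(comarks)) {
    out[[mark]] <- lengths(intersect_any(gbrs, comarks[[mark]])) > 0
  }
  if (!is.null(genes)) {
    prom <- promoter_windows(genes, 2000, 1000)
    out$promoter_proximal <- lengths(intersect_any(gbrs, prom)) > 0
    if (!is.null(cpg_islands)) {
      cpg_gene <- assign_cpg_promoters(genes, cpg_islands)
      cpg_prom <- prom[prom$id %in% names(cpg_gene)[cpg_gene], , drop = FALSE]
      out$cpg_promoter <- if (nrow(cpg_prom))
        lengths(intersect_any(gbrs, cpg_prom)) > 0 else FALSE
    }
  }
  attr(out, "fdr") <- fdr
  class(out) <- c("gbr_class", "data.frame")
  out
}

#' @export
print.gbr_class <- function(x, ...) {
  tt <- table(factor(x$label, levels = c("stable", "hh_sensitive",
                                         "hh_dependent", "non_acetylated")))
  acet <- sum(tt[c("stable", "hh_sensitive", "hh_dependent")])
  cat(sprintf("GBR classification: %d regions (%d acetylated)\n",
              nrow(x), acet))
  for (l in names(tt)) {
    pct <- if (acet && l != "non_acetylated")
      sprintf("  (%.1f%% of acetylated)", 100 * tt[[l]] / acet) else ""
    cat(sprintf("  %-15s %5d%s\n", l, tt[[l]], pct))
  }
  invisible(x)
}

#' @export
summary.gbr_class <- function(object, ...) {
  tt <- table(object$label)
  n_acet <- sum(object$label != "non_acetylated")
  list(n = nrow(object), counts = tt, n_acetylated = n_acet,
       fraction_stable = if (n_acet) sum(object$label == "stable") / n_acet
                         else NA,
       n_responsive = sum(object$label %in% c("hh_sensitive",
                                              "hh_dependent")))
}

#' Test the TSS-proximity distribution of stable vs responsive GBRs
#'
#' Builds the 2x2 table (stable vs HH-responsive) x (promoter-proximal vs
#' distal), where proximal means overlap with any 2 kb upstream / 1 kb
#' downstream promoter window, and tests association with a two-sided
#' Fisher's exact test.
#'
#' @param classes `gbr_class` result from [classify_gbrs()].
#' @param genes gene table (see [read_genes()]).
#' @param upstream,downstream promoter window extents in bp.
#' @return List with `table` (2x2 matrix, rows stable/responsive, columns
#'   proximal/distal) and `p`.
#' @export
tss_distribution_test <- function(classes, genes, upstream = 2000,
                                  downstream = 1000) {
  stable <- classes$label == "stable"
  resp <- classes$label %in% c("hh_sensitive", "hh_dependent")
  if (!any(stable)) stop("no GBR labelled stable")
  if (!any(resp)) stop("no GBR labelled hh_sensitive or hh_dependent")
  keep <- stable | resp
  rs <- region_set(classes$chrom[keep], classes$start[keep],
                   classes$end[keep], id = classes$gbr_id[keep])
  prox <- lengths(intersect_any(rs, promoter_windows(genes, upstream,
                                                     downstream))) > 0
  grp <- stable[keep]
  tab <- matrix(c(sum(grp & prox), sum(grp & !prox),
                  sum(!grp & prox), sum(!grp & !prox)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("stable", "responsive"),
                                c("proximal", "distal")))
  p <- fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  list(table = tab, p = p)
}

#' Compare chromatin accessibility between GBR classes
#'
#' One-sided Wilcoxon rank-sum tests on two measures: (a) the condition-A
#' (wild-type) normalized signal, alternative "stable more accessible than
#' the other class"; and (b) the per-GBR log2 condition ratio (A - B),
#' alternative "the other class loses more accessibility than stable in
#' condition B" (a larger ratio). Responsive classes are compared both
#' separately (`hh_sensitive`, `hh_dependent`) and pooled (`responsive`).
#'
#' @param signal data.frame with columns `gbr_id`, `signal_a`, `signal_b`
#'   (normalized log2 accessibility per condition). GBRs present in
#'   `classes` but missing here are dropped with a warning.
#' @param classes `gbr_class` result from [classify_gbrs()].
#' @return data.frame with one row per (comparison, measure): group sizes and
#'   the one-sided p-value (`NA` when a group is empty).
#' @export
accessibility_compare <- function(signal, classes) {
  stopifnot(all(c("gbr_id", "signal_a", "signal_b") %in% names(signal)))
  classified <- classes$gbr_id[classes$label != "non_acetylated"]
  missing <- setdiff(classified, signal$gbr_id)
  if (length(missing))
    warning(sprintf("%d classified GBR(s) missing from accessibility table",
                    length(missing)))
  m <- merge(signal, as.data.frame(classes)[c("gbr_id", "label")],
             by = "gbr_id")
  m$ratio <- m$signal_a - m$signal_b
  pick <- function(lbl) m[m$label %in% lbl, , drop = FALSE]
  st <- pick("stable")
  rows <- list()
  for (other in list(c(name = "hh_sensitive"), c(name = "hh_dependent"),
                     c(name = "responsive"))) {
    lbls <- if (other[["name"]] == "responsive")
      c("hh_sensitive", "hh_dependent") else other[["name"]]
    ot <- pick(lbls)
    for (measure in c("signal_a", "ratio")) {
      side <- if (measure == "signal_a") "greater" else "less"
      p <- if (nrow(st) && nrow(ot))
        wilcoxon_rank_sum(st[[measure]], ot[[measure]], side) else NA
      rows[[length(rows) + 1]] <- data.frame(
        comparison = paste0("stable_vs_", other[["name"]]),
        measure = measure, n_stable = nrow(st), n_other = nrow(ot), p = p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Mean annotated tissues per enhancer by GBR class
#'
#' Summarises a transgenic-reporter annotation table (VISTA-style): for each
#' GBR class, the number of enhancers tested and the mean number of tissues
#' in which each enhancer drives expression.
#'
#' @param tab data.frame with columns `class` (e.g. `stable`, `responsive`)
#'   and `n_tissues` (non-negative integer per enhancer).
#' @return data.frame with columns `class`, `n`, `mean_tissues`.
#' @export
enhancer_tissue_summary <- function(tab) {
  stopifnot(all(c("class", "n_tissues") %in% names(tab)))
  if (any(tab$n_tissues < 0)) stop("tissue counts must be non-negative")
  agg <- stats::aggregate(n_tissues ~ class, data = tab,
                          FUN = function(v) c(n = length(v), mean = mean(v)))
  data.frame(class = agg$class, n = agg$n_tissues[, "n"],
             mean_tissues = agg$n_tissues[, "mean"],
             stringsAsFactors = FALSE)
}
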