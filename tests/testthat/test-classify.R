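test_that("classification rules follow the documented precedence", {
  gbrs <- region_set(rep("chr1", 5), c(0, 1000, 2000, 3000, 4000),
                     c(400, 1400, 2400, 3400, 4400),
                     id = paste0("g", 1:5))
  diff <- toy_diff(
    chrom = rep("chr1", 5),
    start = c(1000, 2000, 3000, 4000, 4100),
    end = c(1400, 2400, 3400, 4100, 4400),
    q = c(0.5, 0.01, 0.5, 0.001, 0.5),
    log2fc = c(0.1, 1.2, 0.1, 2, 0),
    peak_type = c("a_only", "shared", "shared", "a_only", "shared"))
  cls <- classify_gbrs(gbrs, diff)
  # g1 overlaps nothing -> non_acetylated
  expect_equal(cls$label[cls$gbr_id == "g1"], "non_acetylated")
  # g2 overlaps only an a_only region -> hh_dependent
  expect_equal(cls$label[cls$gbr_id == "g2"], "hh_dependent")
  # g3: shared region with q = 0.01 and positive fold change -> hh_sensitive
  expect_equal(cls$label[cls$gbr_id == "g3"], "hh_sensitive")
  # g4: shared, not significant -> stable
  expect_equal(cls$label[cls$gbr_id == "g4"], "stable")
  # g5: one vanished region but another retained -> not dependent;
  # the vanished one is significant with positive fold change -> sensitive
  expect_equal(cls$label[cls$gbr_id == "g5"], "hh_sensitive")
  expect_error(classify_gbrs(gbrs[0, ], diff), "empty")
})

test_that("labels always partition the GBR set", {
  set.seed(19)
  for (rep in 1:3) {
    n <- 40
    gstart <- sample.int(50000, n)
    gbrs <- region_set("chr1", gstart, gstart + 200)
    m <- 30
    dstart <- sample.int(50000, m)
    diff <- toy_diff("chr1", dstart, dstart + 300,
                     q = runif(m), log2fc = rnorm(m),
                     peak_type = sample(c("shared", "a_only", "b_only",
                                          "neither"), m, TRUE))
    cls <- classify_gbrs(gbrs, diff)
    expect_equal(nrow(cls), n)
    expect_true(all(cls$label %in% c("stable", "hh_sensitive",
                                     "hh_dependent", "non_acetylated")))
    # a label other than non_acetylated implies an overlapping WT region
    expect_true(all(cls$n_overlap[cls$label != "non_acetylated"] >= 1))
  }
})

test_that("equal conditions force zero responsive labels", {
  set.seed(29)
  regions <- region_set("chr1", (0:49) * 2000, (0:49) * 2000 + 400,
                        id = sprintf("acet_%d", 1:50))
  counts <- matrix(rnbinom(200, mu = 120, size = 30), 50, 4,
                   dimnames = list(regions$id, NULL))
  cm <- count_matrix(cbind(counts[, 1:2], counts[, 1:2]),
                     rep(c("condition_a", "condition_b"), each = 2),
                     library_size = rep(max(colSums(counts)) * 2, 4),
                     regions = regions)
  peaks <- region_set("chr1", (0:49) * 2000, (0:49) * 2000 + 400)
  diff <- differential_regions(cm, peaks, peaks)
  cls <- classify_gbrs(regions, diff)
  expect_equal(sum(cls$label %in% c("hh_sensitive", "hh_dependent")), 0)
})

test_that("TSS distribution test recovers the planted table and margins", {
  genes <- data.frame(gene_id = paste0("g", 1:4), chrom = "chr1",
                      strand = "+", tss = c(10000, 30000, 50000, 70000))
  # 2 stable at promoters, 1 stable distal; 1 responsive at promoter,
  # 2 responsive distal
  cls <- data.frame(
    gbr_id = paste0("r", 1:6), chrom = "chr1",
    start = c(9000, 29500, 90000, 49000, 95000, 99000),
    end = c(9400, 29900, 90400, 49400, 95400, 99400),
    label = c("stable", "stable", "stable", "hh_sensitive", "hh_dependent",
              "hh_sensitive"), stringsAsFactors = FALSE)
  class(cls) <- c("gbr_class", "data.frame")
  res <- tss_distribution_test(cls, genes)
  expect_equal(unname(res$table["stable", ]), c(2, 1))
  expect_equal(unname(res$table["responsive", ]), c(1, 2))
  expect_equal(unname(rowSums(res$table)), c(3, 3))
  expect_equal(res$p,
               fisher_exact_2x2(2, 1, 1, 2), tolerance = 1e-12)
  cls$label <- "stable"
  class(cls) <- c("gbr_class", "data.frame")
  expect_error(tss_distribution_test(cls, genes), "hh_")
})

test_that("accessibility comparisons behave at symmetry and separation extremes", {
  mk <- function(labels) {
    d <- data.frame(gbr_id = paste0("r", seq_along(labels)), chrom = "chr1",
                    start = seq_along(labels) * 1000,
                    end = seq_along(labels) * 1000 + 400,
                    label = labels, stringsAsFactors = FALSE)
    class(d) <- c("gbr_class", "data.frame")
    d
  }
  # identical distributions: one-sided p about 1/2 for the signal measure
  set.seed(43)
  vals <- rnorm(40)
  cls <- mk(rep(c("stable", "hh_dependent"), each = 20))
  sig <- data.frame(gbr_id = cls$gbr_id, signal_a = vals,
                    signal_b = vals - 0)
  res <- accessibility_compare(sig, cls)
  p_sig <- res$p[res$comparison == "stable_vs_hh_dependent" &
                   res$measure == "signal_a"]
  expect_gt(p_sig, 0.3)
  # complete separation: exact one-sided p = 1 / choose(20, 10)
  cls2 <- mk(rep(c("stable", "hh_dependent"), each = 10))
  sig2 <- data.frame(gbr_id = cls2$gbr_id,
                     signal_a = rep(c(10, 1), each = 10) + (1:20) * 1e-3,
                     signal_b = rep(0, 20))
  res2 <- accessibility_compare(sig2, cls2)
  expect_equal(res2$p[res2$comparison == "stable_vs_hh_dependent" &
                        res2$measure == "signal_a"],
               1 / choose(20, 10), tolerance = 1e-9)
  # planted 1.5-log2 shift with realistic n is detected decisively
  set.seed(47)
  cls3 <- mk(rep(c("stable", "hh_sensitive"), times = c(200, 50)))
  sig3 <- data.frame(gbr_id = cls3$gbr_id,
                     signal_a = c(rnorm(200, 6, 0.5), rnorm(50, 4.5, 0.5)),
                     signal_b = c(rnorm(200, 6, 0.5), rnorm(50, 4.0, 0.5)))
  res3 <- accessibility_compare(sig3, cls3)
  expect_lt(res3$p[res3$comparison == "stable_vs_hh_sensitive" &
                     res3$measure == "signal_a"], 1e-6)
  # missing GBRs are dropped with a warning
  expect_warning(accessibility_compare(sig3[-1, ], cls3), "missing")
})

test_that("enhancer tissue summary computes per-class means", {
  # synthetic stand-in for a transgenic-reporter annotation table
  tab <- data.frame(class = rep(c("responsive", "stable"), c(4, 5)),
                    n_tissues = c(1, 2, 2, 3, 2, 3, 3, 4, 3))
  s <- enhancer_tissue_summary(tab)
  expect_equal(s$mean_tissues[s$class == "responsive"], 2)
  expect_equal(s$mean_tissues[s$class == "stable"], 3)
  expect_equal(s$n, c(4, 5))
  expect_error(enhancer_tissue_summary(data.frame(class = "a",
                                                  n_tissues = -1)),
               "non-negative")
})
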