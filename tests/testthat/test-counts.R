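test_that("read counting uses the half-open rule and per-sample library sizes", {
  regions <- region_set(c("chr1", "chr1"), c(0, 100), c(100, 200),
                        id = c("left", "right"))
  reads <- list(s1 = data.frame(chrom = "chr1", pos = c(100, 99, 150)),
                s2 = data.frame(chrom = character(0), pos = numeric(0)))
  cm <- count_reads_in_regions(reads, regions, c("condition_a",
                                                 "condition_b"))
  expect_equal(cm$counts["left", "s1"], 1)     # pos 99 only
  expect_equal(cm$counts["right", "s1"], 2)    # pos 100 and 150
  expect_equal(unname(cm$counts[, "s2"]), c(0, 0))
  expect_equal(cm$samples$library_size[1], 3)
  # unknown chromosome: counted nowhere, with a warning
  expect_warning(
    cm2 <- count_reads_in_regions(
      list(s = data.frame(chrom = c("chr1", "chrM"), pos = c(5, 5))),
      regions, "condition_a"),
    "chromosomes without regions")
  expect_equal(sum(cm2$counts), 1)
})

test_that("uniform reads land in a region at the expected binomial rate", {
  set.seed(9)
  n <- 2000
  reads <- list(s = data.frame(chrom = "chr1",
                               pos = floor(runif(n) * 10000)))
  regions <- region_set("chr1", 0, 1000, id = "tenth")
  cm <- count_reads_in_regions(reads, regions, "condition_a")
  ci <- qbinom(c(0.0005, 0.9995), n, 0.1)
  expect_gte(cm$counts[1, 1], ci[1])
  expect_lte(cm$counts[1, 1], ci[2])
})

test_that("normalize_log2 scales by library size with a pseudo-count of 1", {
  cm <- count_matrix(matrix(c(0, 3, 10, 0), 2,
                            dimnames = list(c("r1", "r2"), c("a", "b"))),
                     condition = c("condition_a", "condition_b"),
                     library_size = c(1000, 2000))
  norm <- normalize_log2(cm, reference_depth = 1000)
  expect_equal(norm["r1", "a"], 0)
  expect_equal(norm["r2", "a"], 2)              # log2(3 + 1)
  expect_equal(norm["r1", "b"], log2(6))        # 10 * 1000/2000 + 1
  # monotone in counts for fixed library size
  cm2 <- count_matrix(matrix(0:5, 6, 1, dimnames = list(NULL, "s")),
                      "condition_a", 100)
  expect_true(all(diff(normalize_log2(cm2, 100)[, 1]) > 0))
})

test_that("count_matrix validates its invariants", {
  expect_error(count_matrix(matrix(-1), "condition_a", 10), "non-negative")
  expect_error(count_matrix(matrix(5), "condition_a", 4), "column sum")
  expect_error(count_matrix(matrix(5), c("a", "b"), 10), "condition")
})

test_that("the fixed-window caller finds a planted spike and nothing under the null", {
  # null: perfectly uniform reads, one per window
  sizes <- c(chrU = 10000)
  uniform <- data.frame(chrom = "chrU", pos = seq(0, 9999, by = 200) + 100)
  expect_equal(nrow(call_peaks_fixed_windows(uniform, sizes)), 0)
  # spike: one window holding 50x the background
  set.seed(13)
  bg <- data.frame(chrom = "chrU", pos = floor(runif(2000) * 10000))
  spike <- data.frame(chrom = "chrU", pos = 400 + floor(runif(500) * 200))
  peaks <- call_peaks_fixed_windows(rbind(bg, spike), sizes)
  expect_gte(nrow(peaks), 1)
  expect_true(any(peaks$start <= 400 & peaks$end >= 600))
  expect_true(all(peaks$q < 0.05))
  # contract errors
  expect_error(call_peaks_fixed_windows(
    data.frame(chrom = "chrM", pos = 1), sizes), "chrM")
  expect_warning(res <- call_peaks_fixed_windows(
    data.frame(chrom = character(0), pos = numeric(0)), sizes), "no reads")
  expect_equal(nrow(res), 0)
})

test_that("peak caller recovers planted enrichment with high precision and recall", {
  set.seed(31)
  sizes <- c(chrU = 200000)
  centers <- seq(5000, 195000, by = 10000)   # 20 planted sites
  signal <- data.frame(
    chrom = "chrU",
    pos = rep(centers, each = 60) + floor(runif(60 * length(centers)) * 400) - 200)
  bg <- data.frame(chrom = "chrU", pos = floor(runif(4000) * 200000))
  peaks <- call_peaks_fixed_windows(rbind(signal, bg), sizes)
  planted <- region_set("chrU", centers - 200, centers + 200,
                        id = paste0("site", seq_along(centers)))
  hit <- lengths(intersect_any(planted, peaks)) > 0
  recall <- mean(hit)
  called_true <- lengths(intersect_any(peaks, planted)) > 0
  precision <- mean(called_true)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})

test_that("differential testing is null-faithful and label-symmetric", {
  set.seed(17)
  counts <- matrix(rnbinom(400, mu = 100, size = 20), 100, 4,
                   dimnames = list(paste0("r", 1:100), c("a1", "a2", "b1", "b2")))
  regions <- region_set("chr1", (0:99) * 1000, (0:99) * 1000 + 500,
                        id = paste0("r", 1:100))
  # exact null: identical columns across conditions
  cmx <- count_matrix(cbind(a1 = counts[, 1], a2 = counts[, 2],
                            b1 = counts[, 1], b2 = counts[, 2]),
                      rep(c("condition_a", "condition_b"), each = 2),
                      library_size = rep(max(colSums(counts)), 4),
                      regions = regions)
  res <- differential_regions(cmx)
  expect_true(all(res$log2fc == 0))
  expect_equal(sum(res$q < 0.05), 0)
  # label symmetry: swapping conditions negates log2fc, keeps p
  cm1 <- count_matrix(counts, c("condition_a", "condition_a",
                                "condition_b", "condition_b"),
                      library_size = rep(max(colSums(counts)), 4),
                      regions = regions)
  cm2 <- count_matrix(counts[, c(3, 4, 1, 2)],
                      c("condition_a", "condition_a",
                        "condition_b", "condition_b"),
                      library_size = rep(max(colSums(counts)), 4),
                      regions = regions)
  r1 <- differential_regions(cm1)
  r2 <- differential_regions(cm2)
  expect_equal(r1$log2fc, -r2$log2fc, tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
})

test_that("differential testing recovers planted 8-fold drops", {
  set.seed(23)
  n_null <- 100; n_sig <- 20
  mu_a <- rep(200, n_null + n_sig)
  mu_b <- c(rep(200, n_null), rep(25, n_sig))
  draw <- function(mu) rnbinom(length(mu), mu = mu, size = 10)
  counts <- cbind(a1 = draw(mu_a), a2 = draw(mu_a),
                  b1 = draw(mu_b), b2 = draw(mu_b))
  rownames(counts) <- paste0("r", seq_len(nrow(counts)))
  cm <- count_matrix(counts, rep(c("condition_a", "condition_b"), each = 2),
                     library_size = rep(max(colSums(counts)), 4))
  res <- differential_regions(cm)
  planted <- seq(n_null + 1, n_null + n_sig)
  expect_gte(sum(res$q[planted] < 0.05 & res$log2fc[planted] > 0), 18)
  expect_lte(sum(res$q[-planted] < 0.05), 2)
})

test_that("peak presence flags derive the documented peak types", {
  regions <- region_set(c("chr1", "chr1", "chr1", "chr1"),
                        c(0, 1000, 2000, 3000), c(500, 1500, 2500, 3500),
                        id = paste0("r", 1:4))
  counts <- matrix(rep(c(50, 53, 47, 51), each = 4), 4, 4,
                   dimnames = list(regions$id, NULL))
  cm <- count_matrix(counts, rep(c("condition_a", "condition_b"), each = 2),
                     library_size = rep(300, 4), regions = regions)
  peaks_a <- region_set("chr1", c(0, 1000), c(500, 1500))
  peaks_b <- region_set("chr1", c(0, 2000), c(500, 2500))
  res <- differential_regions(cm, peaks_a, peaks_b)
  expect_equal(res$peak_type, c("shared", "a_only", "b_only", "neither"))
})
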