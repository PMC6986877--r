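write_pwm_file <- function(rows, header = ">toy") {
  path <- tempfile(fileext = ".jaspar")
  writeLines(c(header, rows), path)
  path
}

test_that("PWM loading normalises counts with pseudocounts", {
  path <- write_pwm_file(c("A [ 10  0  0  0 ]",
                           "C [  0 10  0 10 ]",
                           "G [  0  0 10  0 ]",
                           "T [  0  0  0  0 ]"))
  pwm <- load_pwm(path)           # pseudocount 0.25
  expect_equal(pwm$L, 4)
  expect_equal(unname(pwm$prob[1, "A"]), 10.25 / 11, tolerance = 1e-12)
  expect_equal(sum(pwm$prob[1, ]), 1, tolerance = 1e-9)
  # uniform matrix: all log-odds zero
  upath <- write_pwm_file(c("A [ 1 1 1 1 ]", "C [ 1 1 1 1 ]",
                            "G [ 1 1 1 1 ]", "T [ 1 1 1 1 ]"))
  up <- load_pwm(upath)
  expect_true(all(abs(up$log_odds) < 1e-12))
  # parse errors
  expect_error(load_pwm(write_pwm_file(c("A [ 1 2 ]", "C [ 1 ]",
                                         "G [ 1 2 ]", "T [ 1 2 ]"))),
               "ragged")
  expect_error(load_pwm(write_pwm_file(c("A [ 1 -2 ]", "C [ 1 2 ]",
                                         "G [ 1 2 ]", "T [ 1 2 ]"))),
               "negative")
})

test_that("scanning scores the consensus at the summed maxima on both strands", {
  pwm <- gli_pwm()
  cons <- "GACCACCCA"
  maxscore <- sum(apply(pwm$log_odds, 1, max))
  hits <- scan_region(pwm, cons, threshold = 7)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "+")
  expect_equal(hits$score, maxscore, tolerance = 1e-10)
  # the reverse complement is found on the minus strand at the same score
  rc_hits <- scan_region(pwm, "TGGGTGGTC", threshold = 7)
  expect_equal(rc_hits$strand, "-")
  expect_equal(rc_hits$score, maxscore, tolerance = 1e-10)
  # shorter than the motif: empty result
  expect_equal(nrow(scan_region(pwm, "ACGT")), 0)
  # windows containing N are skipped
  expect_equal(nrow(scan_region(pwm, "GACCANCCA", threshold = 0)), 0)
})

test_that("a palindromic PWM hits both strands at equal scores", {
  counts <- matrix(0, 4, 4, dimnames = list(NULL, NULL))
  counts[1, 1] <- 10; counts[2, 2] <- 10   # AC..
  counts[3, 3] <- 10; counts[4, 4] <- 10   # ..GT -> ACGT, its own revcomp
  pwm <- pwm_from_counts(counts)
  hits <- scan_region(pwm, "ACGT", threshold = 1)
  expect_equal(nrow(hits), 2)
  expect_equal(sort(hits$strand), c("+", "-"))
  expect_equal(hits$score[1], hits$score[2], tolerance = 1e-10)
  expect_equal(hits$offset, c(0L, 0L))
})

test_that("scanning matches brute-force enumeration for a width-4 PWM", {
  counts <- rbind(c(8, 1, 1, 0), c(0, 6, 2, 2), c(5, 0, 5, 0),
                  c(1, 1, 1, 7))
  pwm <- pwm_from_counts(counts)
  bases <- c("A", "C", "G", "T")
  tetramers <- apply(expand.grid(bases, bases, bases, bases), 1, paste,
                     collapse = "")
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  brute_score <- function(s) {
    idx <- match(strsplit(s, "")[[1]], bases)
    sum(pwm$log_odds[cbind(1:4, idx)])
  }
  for (thr in c(-5, 0, 2, 4)) {
    for (s in tetramers) {
      hits <- scan_region(pwm, s, threshold = thr)
      expected_fwd <- brute_score(s) >= thr
      expected_rev <- brute_score(rc(s)) >= thr
      expect_equal(any(hits$strand == "+"), expected_fwd, info = s)
      expect_equal(any(hits$strand == "-"), expected_rev, info = s)
    }
  }
})

test_that("reverse-complementing a sequence mirrors the hit set exactly", {
  pwm <- gli_pwm()
  set.seed(53)
  seq <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  rcseq <- chartr("ACGT", "TGCA",
                  paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
  h1 <- scan_region(pwm, seq, threshold = 5)
  h2 <- scan_region(pwm, rcseq, threshold = 5)
  expect_equal(nrow(h1), nrow(h2))
  if (nrow(h1)) {
    mirrored <- sort(300 - pwm$L - h1$offset)
    expect_equal(sort(h2$offset), mirrored)
    expect_equal(sort(h1$score), sort(h2$score), tolerance = 1e-10)
  }
})

test_that("raising the threshold never increases per-region quantity", {
  pwm <- gli_pwm()
  set.seed(59)
  seqs <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = ""), "")
  for (i in c(1, 7, 20)) {
    q <- vapply(c(0, 3, 6, 9, 12), function(thr)
      nrow(scan_region(pwm, seqs[i], thr)), 0L)
    expect_true(all(diff(q) <= 0))
  }
})

test_that("region stats and class comparison summarise presence/quantity/quality", {
  hits <- data.frame(region_id = c("r1", "r1", "r3"),
                     offset = c(0L, 10L, 3L), strand = "+",
                     score = c(10, 14, 8), stringsAsFactors = FALSE)
  st <- region_motif_stats(hits, c("r1", "r2", "r3"))
  expect_equal(st$has_motif, c(TRUE, FALSE, TRUE))
  expect_equal(st$quantity, c(2L, 0L, 1L))
  expect_equal(st$quality, c(12, NA, 8))
  stmax <- region_motif_stats(hits, c("r1", "r2", "r3"), quality = "max")
  expect_equal(stmax$quality[1], 14)
  # identical classes: no significance in either direction
  cmp <- compare_motif_stats(list(stable = st, other = st),
                             reference = "stable")
  expect_gte(cmp$tests$p_presence, 0.5)
  expect_gte(cmp$tests$p_quantity, 0.4)
  # class without motifs: quality/quantity tests undefined
  none <- region_motif_stats(hits[0, ], c("x1", "x2"))
  cmp2 <- compare_motif_stats(list(stable = st, bare = none),
                              reference = "stable")
  expect_true(is.na(cmp2$tests$p_quality))
})

test_that("presence testing on reconstructed class counts reproduces the printed value", {
  # 57.4% of 148 vs 39.5% of 5715, one-sided with continuity correction
  p <- two_proportion_test(85, 148, 2257, 5715, "greater")
  expect_equal(p, 8.0e-6, tolerance = 0.01)
})

test_that("planted presence rates are recovered on synthetic classes", {
  set.seed(61)
  pwm <- gli_pwm()
  plant <- function(n, rate) {
    present <- runif(n) < rate
    seqs <- vapply(seq_len(n), function(i) {
      s <- sample(c("A", "C", "G", "T"), 200, TRUE)
      if (present[i]) s[50:58] <- strsplit("GACCACCCA", "")[[1]]
      paste(s, collapse = "")
    }, "")
    list(seqs = seqs, present = present)
  }
  a <- plant(200, 0.70)
  b <- plant(200, 0.40)
  stats_for <- function(x) {
    hits <- do.call(rbind, lapply(seq_along(x$seqs), function(i)
      scan_region(pwm, x$seqs[i], threshold = 12,
                  region_id = paste0("r", i))))
    region_motif_stats(hits, paste0("r", seq_along(x$seqs)))
  }
  sa <- stats_for(a); sb <- stats_for(b)
  # estimated fractions sit inside the exact binomial 99% CI of the rates
  for (pair in list(list(sa, 0.70), list(sb, 0.40))) {
    x <- sum(pair[[1]]$has_motif)
    ci <- qbinom(c(0.005, 0.995), 200, pair[[2]])
    expect_gte(x, ci[1]); expect_lte(x, ci[2])
  }
  cmp <- compare_motif_stats(list(stable = sb, responsive = sa),
                             reference = "stable")
  expect_lt(cmp$tests$p_presence, 1e-6)
})
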