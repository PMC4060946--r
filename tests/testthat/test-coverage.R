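conv_s <- library_convention("short")

manual_track <- function(depth_vec, chrom = "chrS") {
  structure(list(depth = setNames(list(as.integer(depth_vec)), chrom),
                 mean_depth = mean(depth_vec),
                 genome_length = setNames(list(length(depth_vec)), chrom)),
            class = "depth_track")
}

test_that("depth counts the aligned bases of proper mates only", {
  p <- make_pair()
  tr <- depth_from_alignments(p, conv_s, list(chr1 = 1000L))
  d <- tr$depth$chr1
  expect_equal(sum(d), 200)
  expect_true(all(d[101:200] == 1) && all(d[401:500] == 1))
  expect_true(all(d[c(1:100, 201:400, 501:1000)] == 0))
  # two identical pairs without duplicate flags double the depth
  p2 <- rbind_pairs(make_pair(), make_pair())
  d2 <- depth_from_alignments(p2, conv_s, list(chr1 = 1000L))$depth$chr1
  expect_equal(max(d2), 2L)
  # flagged duplicates are excluded
  p3 <- mark_duplicates(p2)
  d3 <- depth_from_alignments(p3, conv_s, list(chr1 = 1000L))$depth$chr1
  expect_equal(max(d3), 1L)
  # improper pairs contribute nothing
  expect_error(depth_from_alignments(make_pair(strand2 = "+"), conv_s,
                                     list(chr1 = 1000L)), "no pairs")
})

test_that("mean depth matches the counting identity on an unbiased run", {
  g <- test_genome(100000, seed = 50)
  fr <- simulate_fragments(g, NULL, n = 2000, seed = 51)
  n_pairs <- 10000L
  lib <- simulate_short_library(fr, g, library_params("short", n_pairs = n_pairs,
                                                      dup_rate = 0, error_rate = 0,
                                                      seed = 52))
  pairs <- mark_duplicates(pairs_from_truth(lib))
  tr <- depth_from_alignments(pairs, conv_s, list(chrS = g$length))
  expected <- 2 * n_pairs * lib$read_length / g$length
  expect_lt(abs(tr$mean_depth - expected) / expected, 0.05)
})

test_that("evenness curve has the closed-form values on constant and two-level tracks", {
  ev <- evenness_curve(manual_track(rep(5L, 1000)))
  expect_equal(ev$deviation, 0)
  expect_true(all(ev$normalized_depth == 1))
  ev2 <- evenness_curve(manual_track(c(rep(0L, 500), rep(2L, 500))))
  expect_equal(ev2$deviation, 1)
  expect_equal(ev2$normalized_depth, c(0, 2))
  expect_equal(ev2$genome_fraction, c(0.5, 1))
  # curve is non-decreasing and mean-normalised
  g <- test_genome(30000, seed = 53)
  fr <- simulate_fragments(g, NULL, n = 500, seed = 54)
  lib <- simulate_short_library(fr, g, library_params("short", n_pairs = 2000,
                                                      dup_rate = 0, seed = 55))
  tr <- depth_from_alignments(mark_duplicates(pairs_from_truth(lib)), conv_s,
                              list(chrS = g$length))
  ev3 <- evenness_curve(tr)
  expect_true(all(diff(ev3$normalized_depth) >= 0))
  expect_error(evenness_curve(manual_track(rep(0L, 100))), "zero")
})

test_that("window statistics have exact values on constructed inputs", {
  # constant depth: all normalised medians are 1
  tr <- manual_track(rep(7L, 5000))
  g <- structure(list(name = "chrS",
                      sequence = paste(rep("ACGT", 1250), collapse = ""),
                      length = 5000L,
                      repeat_features = data.frame(start = 500L, end = 1000L,
                                                   kind = "tandem")),
                 class = "synthetic_genome")
  wt <- window_stats(tr, g, window = 1000L)
  expect_equal(nrow(wt), 5L)
  expect_true(all(wt$norm_depth == 1))
  expect_equal(wt$gc, rep(0.5, 5))
  # half of window 1 is covered by the tandem feature
  expect_equal(wt$tandem, c(0.5, 0, 0, 0, 0))
  expect_false(any(wt$partial))
  # trailing partial window is retained and flagged
  tr2 <- manual_track(rep(3L, 5500))
  g2 <- g; g2$length <- 5500L
  g2$sequence <- paste(rep("ACGT", 1375), collapse = "")
  wt2 <- window_stats(tr2, g2, window = 1000L)
  expect_equal(nrow(wt2), 6L)
  expect_equal(wt2$partial, c(rep(FALSE, 5), TRUE))
  expect_equal(wt2$end[6] - wt2$start[6], 500L)
})

test_that("window medians match a naive per-base recomputation", {
  g <- test_genome(100000, seed = 56, tandem_repeats = list(c(40, 5, 20)))
  fr <- simulate_fragments(g, NULL, n = 1500, seed = 57)
  lib <- simulate_short_library(fr, g, library_params("short", n_pairs = 5000,
                                                      dup_rate = 0, seed = 58))
  pairs <- mark_duplicates(pairs_from_truth(lib))
  tr <- depth_from_alignments(pairs, conv_s, list(chrS = g$length))
  wt <- window_stats(tr, g, window = 10000L)
  # naive oracle: rebuild depth by incrementing bases one pair at a time
  depth <- numeric(g$length)
  k <- classify_pairs(pairs, conv_s)
  for (i in which(k == "PROPER" & !pairs$duplicate)) {
    depth[(pairs$start1[i] + 1):pairs$end1[i]] <-
      depth[(pairs$start1[i] + 1):pairs$end1[i]] + 1
    depth[(pairs$start2[i] + 1):pairs$end2[i]] <-
      depth[(pairs$start2[i] + 1):pairs$end2[i]] + 1
  }
  naive_med <- vapply(seq_len(10), function(w) {
    median(depth[((w - 1) * 10000 + 1):(w * 10000)])
  }, 0)
  expect_equal(wt$median_depth, naive_med)
})

test_that("repeat correlations recover exact ranks and respect the null", {
  # exact anti-rank relation
  wt <- data.frame(chrom = "c", start = 0, end = 1,
                   norm_depth = 1 - (1:50) / 50, tandem = (1:50) / 50,
                   inverted = runif(50), partial = FALSE)
  class(wt) <- c("window_table", "data.frame")
  cc <- repeat_coverage_correlation(wt)
  expect_equal(cc$rho_tandem, -1)
  expect_lt(cc$p_tandem, 1e-6)
  # independent noise: p rarely small
  withr::with_seed(99, {
    ps <- replicate(20, {
      w <- data.frame(chrom = "c", start = 0, end = 1,
                      norm_depth = runif(500), tandem = runif(500),
                      inverted = runif(500), partial = FALSE)
      class(w) <- c("window_table", "data.frame")
      repeat_coverage_correlation(w)$p_tandem
    })
    expect_gte(mean(ps > 0.01), 0.9)
  })
  # constant variable: correlation undefined, reported as NA
  wt$tandem <- 0
  cc2 <- repeat_coverage_correlation(wt)
  expect_true(is.na(cc2$rho_tandem))
})

test_that("GC distribution is a point mass on a uniform-composition genome", {
  g <- structure(list(name = "chrS",
                      sequence = strrep("ACGT", 2500), length = 10000L,
                      repeat_features = data.frame()),
                 class = "synthetic_genome")
  pairs <- rbind_pairs(make_pair(start1 = 100, end1 = 200, start2 = 400, end2 = 500),
                       make_pair(start1 = 1000, end1 = 1100, start2 = 1400, end2 = 1500))
  gcp <- read_gc_distribution(pairs, g, read_length = 100)
  expect_equal(gcp$shift, 0)
  expect_equal(sum(gcp$observed$density), 1)
  expect_equal(sum(gcp$theoretical$density), 1)
  expect_equal(sum(gcp$observed$density > 0), 1L)
  expect_equal(gcp$observed$gc[gcp$observed$density > 0], 0.5)
})

test_that("library GC difference is antisymmetric and zero on identical tracks", {
  g <- test_genome(50000, seed = 60)
  fr <- simulate_fragments(g, NULL, n = 800, seed = 61)
  lib <- simulate_short_library(fr, g, library_params("short", n_pairs = 4000,
                                                      dup_rate = 0, seed = 62))
  tr <- depth_from_alignments(mark_duplicates(pairs_from_truth(lib)), conv_s,
                              list(chrS = g$length))
  wt <- window_stats(tr, g, window = 1000L)
  same <- library_gc_difference(wt, wt)
  expect_true(all(same$windows$diff == 0))
  lib2 <- simulate_short_library(fr, g, library_params("short", n_pairs = 4000,
                                                       dup_rate = 0, seed = 63))
  tr2 <- depth_from_alignments(mark_duplicates(pairs_from_truth(lib2)), conv_s,
                               list(chrS = g$length))
  wt2 <- window_stats(tr2, g, window = 1000L)
  ab <- library_gc_difference(wt, wt2)
  ba <- library_gc_difference(wt2, wt)
  expect_equal(ab$windows$diff, -ba$windows$diff)
  expect_equal(ab$rho, -ba$rho)
  # mismatched grids are rejected
  expect_error(library_gc_difference(wt, wt2[-1, ]), "grids")
})
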