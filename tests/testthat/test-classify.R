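conv_s <- library_convention("short")
conv_l <- library_convention("long")

test_that("conventions carry the standard thresholds", {
  expect_equal(conv_s$max_insert, 600L)
  expect_equal(conv_l$max_insert, 100000L)
  expect_equal(conv_s$min_aligned_fraction, 0.8)
  expect_equal(conv_l$min_aligned_fraction, 0.5)
  expect_equal(conv_s$proper_facing, "inward")
  expect_equal(conv_l$proper_facing, "outward")
})

test_that("compute_insert uses outer span for opposite strands and start distance for same strand", {
  p <- make_pair(start1 = 100, end1 = 200, strand1 = "+",
                 start2 = 400, end2 = 500, strand2 = "-")
  expect_equal(compute_insert(p), 400)
  p2 <- make_pair(start1 = 100, end1 = 200, strand1 = "+",
                  start2 = 100, end2 = 200, strand2 = "+")
  expect_equal(compute_insert(p2), 0)
  p3 <- make_pair(chrom2 = "chr9")
  expect_true(is.na(compute_insert(p3)))
  p4 <- make_pair(mapped2 = FALSE)
  expect_true(is.na(compute_insert(p4)))
})

test_that("single-pair classification matches the taxonomy definitions", {
  expect_equal(as.character(classify_pairs(make_pair(), conv_s)), "PROPER")
  # inward-facing short insert in a long library: an innie
  expect_equal(as.character(classify_pairs(
    make_pair(start1 = 100, end1 = 200, strand1 = "+",
              start2 = 300, end2 = 400, strand2 = "-"), conv_l)),
    "WRONG_FACING")
  # outward-facing in a short library: an outie
  expect_equal(as.character(classify_pairs(
    make_pair(strand1 = "-", strand2 = "+"), conv_s)),
    "WRONG_FACING")
  expect_equal(as.character(classify_pairs(
    make_pair(chrom2 = "chr2"), conv_s)), "INTERCHROMOSOMAL")
  expect_equal(as.character(classify_pairs(
    make_pair(start2 = 5000, end2 = 5100), conv_s)), "INCORRECT_INSERT")
  expect_equal(as.character(classify_pairs(
    make_pair(strand2 = "+"), conv_s)), "SAME_ORIENTATION")
  expect_equal(as.character(classify_pairs(
    make_pair(mapped2 = FALSE), conv_s)), "SINGLETON")
  expect_equal(as.character(classify_pairs(
    make_pair(mapped1 = FALSE, mapped2 = FALSE), conv_s)), "BOTH_UNMAPPED")
  # low aligned fraction turns a mate into a singleton under the short-library
  # 0.8 threshold but keeps it usable under the long-library 0.5 threshold
  expect_equal(as.character(classify_pairs(
    make_pair(af2 = 0.5), conv_s)), "SINGLETON")
  expect_false(as.character(classify_pairs(
    make_pair(af2 = 0.5), conv_l)) %in% c("SINGLETON", "BOTH_UNMAPPED"))
})

test_that("precedence: duplicates out-rank orientation classes, interchromosomal out-ranks orientation", {
  expect_equal(as.character(classify_pairs(
    make_pair(strand2 = "+", duplicate = TRUE), conv_s)), "DUPLICATE")
  expect_equal(as.character(classify_pairs(
    make_pair(chrom2 = "chr2", strand2 = "+"), conv_s)), "INTERCHROMOSOMAL")
  # but unmapped mates out-rank the duplicate flag
  expect_equal(as.character(classify_pairs(
    make_pair(mapped2 = FALSE, duplicate = TRUE), conv_s)), "SINGLETON")
})

test_that("classification is invariant under swapping mate order", {
  pairs <- random_pairs(400, seed = 21)
  swapped <- pairs
  for (col in c("mapped", "chrom", "start", "end", "strand", "af")) {
    swapped[[paste0(col, "1")]] <- pairs[[paste0(col, "2")]]
    swapped[[paste0(col, "2")]] <- pairs[[paste0(col, "1")]]
  }
  for (conv in list(conv_s, conv_l)) {
    expect_identical(classify_pairs(pairs, conv), classify_pairs(swapped, conv))
  }
})

test_that("classification matches the brute-force rule evaluator on randomized pairs", {
  pairs <- random_pairs(1000, seed = 77)
  for (conv in list(conv_s, conv_l)) {
    expect_identical(as.character(classify_pairs(pairs, conv)),
                     brute_classify(pairs, conv))
  }
})

test_that("mark_duplicates flags all but the first of coordinate-identical pairs", {
  a <- make_pair(read_id = "a")
  b <- make_pair(read_id = "b")
  c <- make_pair(read_id = "c", start1 = 150)
  p <- rbind_pairs(a, b, c)
  out <- mark_duplicates(p)
  expect_equal(out$duplicate, c(FALSE, TRUE, FALSE))
  # idempotent
  expect_equal(mark_duplicates(out)$duplicate, out$duplicate)
  # swapping mates of the copy still counts as a duplicate
  b_sw <- make_pair(read_id = "b",
                    chrom1 = "chr1", start1 = 400, end1 = 500, strand1 = "-",
                    chrom2 = "chr1", start2 = 100, end2 = 200, strand2 = "+")
  out2 <- mark_duplicates(rbind_pairs(a, b_sw))
  expect_equal(out2$duplicate, c(FALSE, TRUE))
  # unmapped pairs are never flagged
  u <- make_pair(read_id = "u", mapped1 = FALSE, mapped2 = FALSE)
  expect_equal(mark_duplicates(rbind_pairs(u, u))$duplicate, c(FALSE, FALSE))
})

test_that("duplicate marking recovers the simulated duplicate rate", {
  g <- test_genome(1000000, seed = 30)
  fr <- simulate_fragments(g, NULL, n = 2000, seed = 31)
  lib <- simulate_short_library(fr, g, library_params("short", n_pairs = 5000,
                                                      dup_rate = 0.2, error_rate = 0,
                                                      seed = 32))
  pairs <- mark_duplicates(pairs_from_truth(lib))
  truth_rate <- mean(lib$truth$artifact_class == "pcr_duplicate")
  ci <- binom.test(sum(pairs$duplicate), nrow(pairs))$conf.int
  expect_true(ci[1] <= truth_rate && truth_rate <= ci[2])
})

test_that("category counts partition the pair table", {
  pairs <- mark_duplicates(random_pairs(800, seed = 5))
  k <- classify_pairs(pairs, conv_s)
  expect_equal(sum(table(k)), nrow(pairs))
  expect_false(any(is.na(k)))
})

test_that("summarize_library reproduces simple closed-form summaries", {
  ten <- do.call(rbind_pairs, replicate(10, make_pair(), simplify = FALSE))
  s <- summarize_library(ten, conv_s)
  expect_equal(s$proper_pct, 100)
  expect_equal(s$median_insert, 400)
  four <- rbind_pairs(make_pair(), make_pair(), make_pair(),
                      make_pair(mapped2 = FALSE))
  s4 <- summarize_library(four, conv_s)
  expect_equal(s4$mapped_pct, 100 * 7 / 8)
  expect_equal(s4$proper_pct, 75)
  expect_equal(s4$singleton_pct, 25)
  expect_error(summarize_library(make_pair()[0, ], conv_s), "empty")
})

test_that("summary percentages agree with simulated artifact rates", {
  g <- test_genome(200000, seed = 33)
  fr <- simulate_fragments(g, NULL, n = 1500, seed = 34)
  lib <- simulate_long_library(fr, g, library_params("long", n_pairs = 6000,
                                                     dup_rate = 0,
                                                     nonjunction_rate = 0.1,
                                                     circular_contaminant_rate = 0,
                                                     error_rate = 0, seed = 35))
  pairs <- mark_duplicates(pairs_from_truth(lib))
  s <- summarize_library(pairs, conv_l)
  # nonjunction pairs surface as innies (wrong facing)
  truth_rate <- mean(lib$truth$artifact_class == "nonjunction")
  ci <- binom.test(round(s$wrong_facing_pct / 100 * 6000), 6000)$conf.int
  expect_true(ci[1] <= truth_rate && truth_rate <= ci[2])
})
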