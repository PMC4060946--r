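# Shared fixtures and independent oracles used across the test files.

# A single read pair in the classifier's wide layout, with overridable fields.
make_pair <- function(read_id = "p1",
                      chrom1 = "chr1", start1 = 100L, end1 = 200L, strand1 = "+",
                      mapped1 = TRUE, af1 = 1,
                      chrom2 = "chr1", start2 = 400L, end2 = 500L, strand2 = "-",
                      mapped2 = TRUE, af2 = 1,
                      duplicate = FALSE) {
  out <- data.frame(read_id = read_id,
                    mapped1 = mapped1, chrom1 = chrom1, start1 = start1,
                    end1 = end1, strand1 = strand1, af1 = af1,
                    mapped2 = mapped2, chrom2 = chrom2, start2 = start2,
                    end2 = end2, strand2 = strand2, af2 = af2,
                    duplicate = duplicate, stringsAsFactors = FALSE)
  class(out) <- c("read_pairs", "data.frame")
  out
}

rbind_pairs <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  out$read_id <- sprintf("p%04d", seq_len(nrow(out)))
  class(out) <- c("read_pairs", "data.frame")
  out
}

# Random pair table exercising every category.
random_pairs <- function(n, seed = 1) {
  withr::with_seed(seed, {
    start1 <- sample.int(100000L, n)
    start2 <- sample.int(100000L, n)
    len1 <- sample(50:150, n, replace = TRUE)
    len2 <- sample(50:150, n, replace = TRUE)
    out <- data.frame(
      read_id = sprintf("r%05d", seq_len(n)),
      mapped1 = runif(n) < 0.9, chrom1 = sample(c("c1", "c2"), n, TRUE),
      start1 = start1, end1 = start1 + len1,
      strand1 = sample(c("+", "-"), n, TRUE),
      af1 = sample(c(1, 0.9, 0.7, 0.4), n, TRUE),
      mapped2 = runif(n) < 0.9, chrom2 = sample(c("c1", "c2"), n, TRUE),
      start2 = start2, end2 = start2 + len2,
      strand2 = sample(c("+", "-"), n, TRUE),
      af2 = sample(c(1, 0.9, 0.7, 0.4), n, TRUE),
      duplicate = runif(n) < 0.1, stringsAsFactors = FALSE)
    # a slice of near-proper pairs so PROPER/INCORRECT_INSERT are well covered
    k <- seq_len(n %/% 3)
    out$chrom2[k] <- out$chrom1[k]
    out$start2[k] <- out$start1[k] + sample(c(100L, 300L, 700L, 5000L), length(k), TRUE)
    out$end2[k] <- out$start2[k] + len2[k]
    out$strand1[k] <- "+"
    out$strand2[k] <- "-"
    class(out) <- c("read_pairs", "data.frame")
    out
  })
}

# Brute-force scalar re-implementation of the classification rules, written
# directly from their definition; the vectorised classifier must agree with
# it exactly.
brute_classify <- function(pairs, conv) {
  one <- function(i) {
    p <- pairs[i, ]
    ok1 <- p$mapped1 && !is.na(p$af1) && p$af1 >= conv$min_aligned_fraction
    ok2 <- p$mapped2 && !is.na(p$af2) && p$af2 >= conv$min_aligned_fraction
    if (!ok1 && !ok2) return("BOTH_UNMAPPED")
    if (xor(ok1, ok2)) return("SINGLETON")
    if (p$duplicate) return("DUPLICATE")
    if (p$chrom1 != p$chrom2) return("INTERCHROMOSOMAL")
    if (p$strand1 == p$strand2) return("SAME_ORIENTATION")
    if (p$start1 == p$start2 && p$end1 == p$end2) {
      facing <- "inward"
    } else {
      if (p$start1 < p$start2 || (p$start1 == p$start2 && p$end1 < p$end2)) {
        left_strand <- p$strand1
      } else {
        left_strand <- p$strand2
      }
      facing <- if (left_strand == "+") "inward" else "outward"
    }
    if (facing != conv$proper_facing) return("WRONG_FACING")
    insert <- max(p$end1, p$end2) - min(p$start1, p$start2)
    if (insert > conv$max_insert) return("INCORRECT_INSERT")
    "PROPER"
  }
  vapply(seq_len(nrow(pairs)), one, "")
}

# Small default genome used by simulator-level tests.
test_genome <- function(length = 120000L, seed = 5L, ...) {
  generate_genome(genome_spec(length, gc_target = 0.36, seed = seed, ...))
}

# Random synthetic call sets over shared sites, for set-logic oracles.
random_callset <- function(n_sites = 120, p_called = 0.7, seed = 1,
                           chrom = "chrS", sample = "s") {
  withr::with_seed(seed, {
    pos <- seq(10L, by = 13L, length.out = n_sites)
    called <- runif(n_sites) < p_called
    calls <- data.frame(chrom = chrom, pos = pos[called], ref = "A",
                        alt = sample(c("C", "G", "T"), sum(called), TRUE),
                        genotype = sample(c("hom_alt", "het"), sum(called), TRUE),
                        depth = sample(1:40, sum(called), TRUE),
                        stringsAsFactors = FALSE)
    depth <- setNames(list(sample(0:40, max(pos) + 10L, TRUE)), chrom)
    call_set(calls, sample = sample, depth = depth)
  })
}

# Brute-force fate classification straight from the category definitions.
brute_fates <- function(ref_df, amps, min_depth = 5L) {
  fate <- character(nrow(ref_df))
  for (i in seq_len(nrow(ref_df))) {
    r <- ref_df[i, ]
    calls <- lapply(amps, function(a) {
      m <- a$calls[a$calls$chrom == r$chrom & a$calls$pos == r$pos, ]
      if (nrow(m) == 0) NULL else m
    })
    deps <- vapply(amps, function(a) site_depth(a, r$chrom, r$pos), 0)
    called <- !vapply(calls, is.null, TRUE)
    matches <- vapply(seq_along(calls), function(j) {
      called[j] && calls[[j]]$alt == r$alt && calls[[j]]$genotype == r$genotype
    }, TRUE)
    fate[i] <- if (!any(called) && all(deps < min_depth)) {
      "no_low_coverage"
    } else if (any(called & !matches) || !any(called)) {
      "not_called_same"
    } else if (length(amps) == 2 && all(matches)) {
      "called_in_both_replicates"
    } else {
      "called_in_one_replicate"
    }
  }
  table(factor(fate, levels = c("no_low_coverage", "not_called_same",
                                "called_in_one_replicate",
                                "called_in_both_replicates")))
}
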