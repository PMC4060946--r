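mk_calls <- function(...) {
  rows <- list(...)
  if (length(rows) == 0) {
    return(data.frame(chrom = character(0), pos = numeric(0), ref = character(0),
                      alt = character(0), genotype = character(0),
                      depth = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom = "c", pos = r[[1]], ref = "A", alt = r[[2]],
               genotype = r[[3]], depth = if (length(r) > 3) r[[4]] else 20,
               stringsAsFactors = FALSE)
  }))
}
flat_depth <- function(d, n = 1000) setNames(list(rep(d, n)), "c")

test_that("reference set keeps only sites called identically in both replicates", {
  u1 <- call_set(mk_calls(list(10, "T", "het"), list(20, "G", "hom_alt"),
                          list(30, "C", "het"), list(40, "T", "het")), "u1")
  u2 <- call_set(mk_calls(list(10, "T", "het"),          # identical -> in
                          list(20, "G", "het"),          # zygosity differs -> out
                          list(30, "G", "het"),          # allele differs -> out
                          list(50, "T", "hom_alt")),     # only in u2 -> out
                 "u2")
  ref <- build_reference_set(u1, u2)
  expect_equal(nrow(ref$het), 1L)
  expect_equal(ref$het$pos, 10)
  expect_equal(nrow(ref$hom), 0L)
  # symmetric in its arguments
  ref_sw <- build_reference_set(u2, u1)
  expect_equal(ref$het[c("chrom", "pos", "alt")], ref_sw$het[c("chrom", "pos", "alt")])
})

test_that("reference set equals a brute-force intersection on random call sets", {
  u1 <- random_callset(seed = 1, sample = "u1")
  u2 <- random_callset(seed = 2, sample = "u2")
  ref <- build_reference_set(u1, u2)
  got <- rbind(ref$hom, ref$het)
  brute <- merge(u1$calls, u2$calls, by = c("chrom", "pos", "alt", "genotype"))
  expect_equal(nrow(got), nrow(brute))
  expect_setequal(paste(got$pos, got$alt, got$genotype),
                  paste(brute$pos, brute$alt, brute$genotype))
})

test_that("fate rules follow the stated precedence", {
  ref <- list(hom = mk_calls(list(100, "T", "hom_alt")),
              het = mk_calls(list(10, "T", "het"), list(20, "T", "het"),
                             list(30, "T", "het")))
  ref$hom$genotype <- "hom_alt"
  # amp1: site 10 uncalled at depth 1; site 20 miscalled hom; site 30 called het
  amp1 <- call_set(mk_calls(list(20, "T", "hom_alt"), list(30, "T", "het"),
                            list(100, "T", "hom_alt")),
                   "a1", depth = flat_depth(1))
  # amp2: site 10 uncalled at depth 2; site 20 uncalled; site 30 called het
  amp2 <- call_set(mk_calls(list(30, "T", "het"), list(100, "T", "hom_alt")),
                   "a2", depth = flat_depth(2))
  f <- classify_fates(ref, amp1, amp2, min_depth = 5)
  expect_equal(unname(f$het["no_low_coverage"]), 1L)          # site 10
  expect_equal(unname(f$het["not_called_same"]), 1L)          # site 20 (het -> hom)
  expect_equal(unname(f$het["called_in_both_replicates"]), 1L) # site 30
  expect_equal(unname(f$hom["called_in_both_replicates"]), 1L) # site 100
  # uncalled everywhere but with adequate depth counts as not_called_same
  amp_hi1 <- call_set(mk_calls(list(999, "T", "het")), "h1", depth = flat_depth(30))
  amp_hi2 <- call_set(mk_calls(list(999, "T", "het")), "h2", depth = flat_depth(30))
  f2 <- classify_fates(list(hom = ref$hom, het = ref$het), amp_hi1, amp_hi2)
  expect_equal(unname(f2$het["not_called_same"]), 3L)
})

test_that("a single amplified replicate reports called_in_both as NA", {
  ref <- list(hom = mk_calls(list(100, "T", "hom_alt")), het = mk_calls()[0, ])
  ref$hom$genotype <- "hom_alt"
  amp1 <- call_set(mk_calls(list(100, "T", "hom_alt")), "a1", depth = flat_depth(10))
  f <- classify_fates(ref, amp1)
  expect_true(is.na(f$hom["called_in_both_replicates"]))
  expect_equal(unname(f$hom["called_in_one_replicate"]), 1L)
})

test_that("fate counts partition the reference set and match brute-force enumeration", {
  u1 <- random_callset(seed = 11, sample = "u1")
  u2 <- random_callset(seed = 12, sample = "u2")
  a1 <- random_callset(seed = 13, sample = "a1")
  a2 <- random_callset(seed = 14, sample = "a2")
  ref <- build_reference_set(u1, u2)
  f <- classify_fates(ref, a1, a2, min_depth = 5)
  expect_equal(sum(f$hom), nrow(ref$hom))
  expect_equal(sum(f$het), nrow(ref$het))
  for (z in c("hom", "het")) {
    brute <- brute_fates(ref[[z]], list(a1, a2), min_depth = 5)
    expect_equal(unname(f[[z]]), as.vector(brute), info = z)
  }
})

test_that("missing depth accessor and out-of-range sites are input errors", {
  cs <- call_set(mk_calls(list(10, "T", "het")), "x")
  expect_error(site_depth(cs, "c", 10), "no depth accessor")
  cs2 <- call_set(mk_calls(list(10, "T", "het")), "x", depth = flat_depth(5, n = 20))
  expect_error(site_depth(cs2, "c", 100), "outside")
  ref <- list(hom = mk_calls(list(500, "T", "hom_alt")), het = mk_calls()[0, ])
  ref$hom$genotype <- "hom_alt"
  expect_error(classify_fates(ref, cs2), "outside")
})

test_that("extra-call fates follow their definitions and a brute-force oracle", {
  u1 <- call_set(mk_calls(list(10, "T", "hom_alt"), list(20, "T", "het")), "u1")
  u2 <- call_set(mk_calls(list(10, "T", "hom_alt"), list(30, "G", "het")), "u2")
  ref <- build_reference_set(u1, u2)   # site 10 only
  amp <- call_set(mk_calls(list(10, "T", "het"),    # differs from both unamp
                           list(20, "T", "het"),    # carried by exactly one
                           list(40, "C", "het")),   # novel: neither category
                  "a", depth = flat_depth(10))
  ex <- extra_call_fates(ref, list(amp), u1, u2)
  expect_equal(unname(ex$het["called_differently_in_both_unamplified"]), 1L)
  expect_equal(unname(ex$het["called_in_one_replicate"]), 1L)
  expect_equal(ex$n_extra_calls, 3L)

  # randomized oracle
  u1r <- random_callset(seed = 21, sample = "u1")
  u2r <- random_callset(seed = 22, sample = "u2")
  a1r <- random_callset(seed = 23, sample = "a1")
  refr <- build_reference_set(u1r, u2r)
  exr <- extra_call_fates(refr, list(a1r), u1r, u2r)
  ref_keys <- with(rbind(refr$hom, refr$het), paste(chrom, pos, alt, genotype))
  brute <- c(diff_both = 0L, in_one = 0L)
  for (i in seq_len(nrow(a1r$calls))) {
    r <- a1r$calls[i, ]
    if (paste(r$chrom, r$pos, r$alt, r$genotype) %in% ref_keys) next
    pick <- function(cs) cs$calls[cs$calls$pos == r$pos, ]
    c1 <- pick(u1r); c2 <- pick(u2r)
    s1 <- nrow(c1) == 1 && c1$alt == r$alt && c1$genotype == r$genotype
    s2 <- nrow(c2) == 1 && c2$alt == r$alt && c2$genotype == r$genotype
    if (nrow(c1) == 1 && nrow(c2) == 1 && !s1 && !s2) brute["diff_both"] <- brute["diff_both"] + 1L
    if (s1 + s2 == 1) brute["in_one"] <- brute["in_one"] + 1L
  }
  expect_equal(unname(ex_sum <- exr$hom + exr$het), unname(brute))
})

test_that("the toy threshold caller applies its thresholds", {
  got <- threshold_caller(alt_depth = c(10, 5, 1, 3, 9),
                          depth = c(10, 10, 10, 4, 10))
  expect_equal(got, c("hom_alt", "het", NA, NA, "hom_alt"))
})

test_that("depth thinning monotonically increases heterozygous miscalls", {
  withr::with_seed(88, {
    n_sites <- 1500L
    base_depth <- rpois(n_sites, 30)
    miscall_rate <- sapply(c(1, 0.5, 0.25), function(keep) {
      dep <- rbinom(n_sites, base_depth, keep)
      alt <- rbinom(n_sites, dep, 0.5)
      called <- threshold_caller(alt, dep)
      # het reference truth: anything not called het at adequate depth
      mean(dep >= 5 & (is.na(called) | called != "het"))
    })
    expect_true(all(diff(miscall_rate) > 0))
  })
})

test_that("VCF call sets are parsed into the internal layout", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=c,length=1000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "c\t10\t.\tA\tT\t50\tPASS\t.\tGT:DP\t0/1:12",
    "c\t20\t.\tG\tC\t50\tPASS\t.\tGT:DP\t1/1:30",
    "c\t30\t.\tT\tTA\t50\tPASS\t.\tGT:DP\t0/1:9",    # indel: dropped
    "c\t40\t.\tC\tG,A\t50\tPASS\t.\tGT:DP\t1/2:9"),  # multi-allelic: dropped
    vcf)
  cs <- read_callset(vcf, sample = "s1")
  expect_equal(nrow(cs$calls), 2L)
  expect_equal(cs$calls$pos, c(10, 20))
  expect_equal(cs$calls$genotype, c("het", "hom_alt"))
  expect_equal(cs$calls$depth, c(12, 30))
})
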