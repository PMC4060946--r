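#' A genotyped SNP call set
#'
#' Container for biallelic SNP calls from one sample plus a depth accessor
#' for sites without a call (needed to distinguish "missed for lack of
#' coverage" from "missed despite coverage").
#'
#' @param calls data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `genotype` (`"hom_alt"` or `"het"`), `depth`.
#' @param sample sample label.
#' @param depth a `depth_track`, or a named list of per-base depth vectors
#'   (1-based indexing by position), or `NULL`.
#' @return object of class `call_set`.
#' @export
call_set <- function(calls, sample = "sample", depth = NULL) {
  need <- c("chrom", "pos", "ref", "alt", "genotype")
  if (!all(need %in% names(calls))) {
    stopf("calls must have columns %s", paste(need, collapse = ", "))
  }
  if (!"depth" %in% names(calls)) calls$depth <- NA_real_
  if (any(calls$ref == calls$alt)) stopf("ref and alt alleles must differ")
  bad <- !calls$genotype %in% c("hom_alt", "het")
  if (any(bad)) stopf("genotype must be 'hom_alt' or 'het'")
  key <- paste(calls$chrom, calls$pos)
  if (anyDuplicated(key)) {
    warning("multi-allelic / duplicated sites dropped from call set")
    calls <- calls[!key %in% key[duplicated(key)], , drop = FALSE]
  }
  if (inherits(depth, "depth_track")) depth <- depth$depth
  structure(list(sample = sample, calls = calls, depth = depth),
            class = "call_set")
}

#' Depth at arbitrary sites of a call set's sample
#'
#' @param cs a [call_set()].
#' @param chrom,pos site coordinates (`pos` 1-based).
#' @return numeric depths; errors if the accessor cannot resolve a site.
#' @export
site_depth <- function(cs, chrom, pos) {
  if (is.null(cs$depth)) stopf("call set '%s' has no depth accessor", cs$sample)
  out <- numeric(length(pos))
  for (ch in unique(chrom)) {
    v <- cs$depth[[ch]]
    i <- which(chrom == ch)
    if (is.null(v) || any(pos[i] > length(v)) || any(pos[i] < 1L)) {
      stopf("site outside the depth accessor of call set '%s'", cs$sample)
    }
    out[i] <- v[pos[i]]
  }
  out
}

#' Read a call set from VCF or TSV
#'
#' VCF input (via VariantAnnotation) keeps biallelic SNVs only and maps
#' genotypes `1/1` (or `1|1`) to `hom_alt` and `0/1`, `1/0`, `0|1`, `1|0`
#' to `het`; per-sample `DP` is used as the site depth. TSV input expects
#' the [call_set()] column layout.
#'
#' @param path `.vcf` (or `.vcf.gz`) or `.tsv` file.
#' @param sample sample label (defaults to the file name).
#' @param depth optional depth accessor passed to [call_set()].
#' @return a `call_set`.
#' @export
read_callset <- function(path, sample = NULL, depth = NULL) {
  if (is.null(sample)) sample <- tools::file_path_sans_ext(basename(path))
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
      stopf("reading VCF requires the VariantAnnotation package")
    }
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    rrd <- as.data.frame(rr)
    ref <- as.character(rr$REF)
    altl <- rr$ALT
    n_alt <- S4Vectors::elementNROWS(altl)
    alt <- rep(NA_character_, length(ref))
    alt[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
    gt <- VariantAnnotation::geno(vcf)$GT[, 1]
    dp <- if ("DP" %in% names(VariantAnnotation::geno(vcf))) {
      as.numeric(VariantAnnotation::geno(vcf)$DP[, 1])
    } else rep(NA_real_, length(ref))
    genotype <- rep(NA_character_, length(gt))
    genotype[gt %in% c("1/1", "1|1")] <- "hom_alt"
    genotype[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- "het"
    keep <- n_alt == 1L & nchar(ref) == 1L & nchar(alt) == 1L & !is.na(genotype)
    calls <- data.frame(chrom = as.character(rrd$seqnames)[keep],
                        pos = rrd$start[keep],
                        ref = ref[keep], alt = alt[keep],
                        genotype = genotype[keep], depth = dp[keep],
                        stringsAsFactors = FALSE)
  } else {
    calls <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }
  call_set(calls, sample = sample, depth = depth)
}

call_key <- function(calls) paste(calls$chrom, calls$pos)
full_key <- function(calls) paste(calls$chrom, calls$pos, calls$alt, calls$genotype)

#' Build the reference SNP set from two unamplified replicates
#'
#' A site enters the reference set iff it is called in both unamplified
#' replicates with identical alternate allele and identical zygosity. The
#' result is partitioned into homozygous and heterozygous reference SNPs.
#' The operation is symmetric in its two arguments.
#'
#' @param unamp1,unamp2 [call_set()]s of the two unamplified replicates.
#' @return list with data.frames `hom` and `het` (columns `chrom`, `pos`,
#'   `ref`, `alt`, `genotype`).
#' @export
build_reference_set <- function(unamp1, unamp2) {
  c1 <- unamp1$calls; c2 <- unamp2$calls
  m <- match(full_key(c1), full_key(c2))
  both <- c1[!is.na(m), c("chrom", "pos", "ref", "alt", "genotype"), drop = FALSE]
  rownames(both) <- NULL
  list(hom = both[both$genotype == "hom_alt", , drop = FALSE],
       het = both[both$genotype == "het", , drop = FALSE])
}

FATE_LEVELS <- c("no_low_coverage", "not_called_same",
                 "called_in_one_replicate", "called_in_both_replicates")

classify_fates_one <- function(ref, amps, min_depth) {
  n <- if (is.null(ref)) 0L else nrow(ref)
  if (n == 0L) {
    return(setNames(rep(0L, length(FATE_LEVELS)), FATE_LEVELS))
  }
  rkey <- call_key(ref)
  called <- matrix(FALSE, n, length(amps))
  matched <- matrix(FALSE, n, length(amps))
  lowdep <- matrix(FALSE, n, length(amps))
  for (j in seq_along(amps)) {
    a <- amps[[j]]$calls
    m <- match(rkey, call_key(a))
    called[, j] <- !is.na(m)
    matched[, j] <- called[, j] &
      a$alt[m] == ref$alt & a$genotype[m] == ref$genotype
    matched[is.na(matched[, j]), j] <- FALSE
    dep <- site_depth(amps[[j]], ref$chrom, ref$pos)
    lowdep[, j] <- dep < min_depth
  }
  uncalled_all <- rowSums(called) == 0L
  mismatch_any <- rowSums(called & !matched) > 0L
  low_all <- rowSums(lowdep) == ncol(lowdep)
  fate <- rep("called_in_one_replicate", n)
  fate[length(amps) == 2L & rowSums(matched) == 2L] <- "called_in_both_replicates"
  fate[mismatch_any | (uncalled_all & !low_all)] <- "not_called_same"
  fate[uncalled_all & low_all] <- "no_low_coverage"
  counts <- table(factor(fate, levels = FATE_LEVELS))
  setNames(as.integer(counts), FATE_LEVELS)
}

#' Classify the fate of reference SNPs in amplified replicates
#'
#' For every reference SNP, the first matching rule decides its fate:
#'
#' 1. `no_low_coverage` — uncalled in every available amplified replicate
#'    and depth below `min_depth` in every available replicate.
#' 2. `not_called_same` — called in at least one replicate with a different
#'    allele or zygosity (e.g. a heterozygous reference SNP called
#'    homozygous), or uncalled everywhere despite adequate depth.
#' 3. `called_in_both_replicates` — identically called in both replicates.
#' 4. `called_in_one_replicate` — otherwise.
#'
#' With a single amplified replicate (some protocols yield only one usable
#' library), `called_in_both_replicates` is reported as `NA` and matching
#' calls fall into `called_in_one_replicate`.
#'
#' @param ref reference set from [build_reference_set()].
#' @param amp1,amp2 amplified-replicate [call_set()]s (`amp2` optional).
#' @param min_depth depth threshold separating "no/low coverage" from
#'   "missed despite coverage" (default 5, the conventional minimum calling
#'   depth).
#' @return object of class `fate_counts`: list with integer vectors `hom`
#'   and `het` over the four fate categories, plus metadata.
#' @export
classify_fates <- function(ref, amp1, amp2 = NULL, min_depth = 5L) {
  amps <- if (is.null(amp2)) list(amp1) else list(amp1, amp2)
  hom <- classify_fates_one(ref$hom, amps, min_depth)
  het <- classify_fates_one(ref$het, amps, min_depth)
  if (is.null(amp2)) {
    hom[["called_in_both_replicates"]] <- NA_integer_
    het[["called_in_both_replicates"]] <- NA_integer_
  }
  structure(list(hom = hom, het = het, min_depth = min_depth,
                 n_replicates = length(amps),
                 n_reference = c(hom = nrow(ref$hom), het = nrow(ref$het))),
            class = "fate_counts")
}

#' @export
print.fate_counts <- function(x, ...) {
  cat(sprintf("SNP fates (%d amplified replicate%s, min depth %d):\n",
              x$n_replicates, if (x$n_replicates > 1) "s" else "", x$min_depth))
  print(rbind(hom = x$hom, het = x$het))
  invisible(x)
}

#' Fate of additional SNP calls made only in amplified replicates
#'
#' Considers distinct calls `(chrom, pos, alt, genotype)` present in any
#' amplified replicate but absent from the reference set, and counts per
#' zygosity: `called_differently_in_both_unamplified` — both unamplified
#' replicates carry a call at the site that differs from the amplified
#' call (this is where heterozygous reference SNPs miscalled homozygous
#' surface); and `called_in_one_replicate` — exactly one unamplified
#' replicate carries the identical call.
#'
#' @param ref reference set from [build_reference_set()].
#' @param amps list of amplified [call_set()]s.
#' @param unamp1,unamp2 the unamplified [call_set()]s.
#' @return list with integer vectors `hom` and `het` over the two extra-call
#'   categories, plus `n_extra_calls`.
#' @export
extra_call_fates <- function(ref, amps, unamp1, unamp2) {
  if (inherits(amps, "call_set")) amps <- list(amps)
  all_amp <- do.call(rbind, lapply(amps, function(a)
    a$calls[, c("chrom", "pos", "ref", "alt", "genotype"), drop = FALSE]))
  all_amp <- all_amp[!duplicated(full_key(all_amp)), , drop = FALSE]
  ref_all <- rbind(ref$hom, ref$het)
  extra <- all_amp[!full_key(all_amp) %in% full_key(ref_all), , drop = FALSE]

  u1 <- unamp1$calls; u2 <- unamp2$calls
  m1 <- match(call_key(extra), call_key(u1))
  m2 <- match(call_key(extra), call_key(u2))
  same1 <- !is.na(m1) & u1$alt[m1] == extra$alt & u1$genotype[m1] == extra$genotype
  same2 <- !is.na(m2) & u2$alt[m2] == extra$alt & u2$genotype[m2] == extra$genotype
  diff_both <- !is.na(m1) & !is.na(m2) & !same1 & !same2
  in_one <- (same1 + same2) == 1L
  count <- function(gt) c(
    called_differently_in_both_unamplified = sum(diff_both & extra$genotype == gt),
    called_in_one_replicate = sum(in_one & extra$genotype == gt))
  list(hom = count("hom_alt"), het = count("het"),
       n_extra_calls = nrow(extra))
}

#' Toy threshold genotype caller
#'
#' A deliberately simple caller used to study how depth thinning turns
#' heterozygous sites into homozygous miscalls: with `depth >= min_depth`,
#' an alternate-allele fraction at or above `hom_threshold` is called
#' `hom_alt`, at or above `het_threshold` is called `het`, and below that
#' no variant is called. It is not part of the analysis path and is no
#' substitute for a real genotype-likelihood caller.
#'
#' @param alt_depth,depth alternate-allele and total read counts per site.
#' @param min_depth minimum depth to attempt a call.
#' @param het_threshold,hom_threshold alternate-allele fraction thresholds.
#' @return character vector: `"hom_alt"`, `"het"` or `NA` (no call).
#' @export
threshold_caller <- function(alt_depth, depth, min_depth = 5L,
                             het_threshold = 0.2, hom_threshold = 0.8) {
  frac <- ifelse(depth > 0, alt_depth / depth, 0)
  out <- rep(NA_character_, length(depth))
  callable <- depth >= min_depth
  out[callable & frac >= het_threshold] <- "het"
  out[callable & frac >= hom_threshold] <- "hom_alt"
  out
}

#' Write a Table-3-shaped TSV of fate counts
#'
#' @param fates a `fate_counts` from [classify_fates()].
#' @param extra optional result of [extra_call_fates()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_fate_table <- function(fates, path, extra = NULL) {
  a <- data.frame(block = "A", zygosity = rep(c("hom", "het"), each = 4L),
                  category = rep(FATE_LEVELS, 2L),
                  count = c(fates$hom, fates$het))
  if (!is.null(extra)) {
    b <- data.frame(block = "B", zygosity = rep(c("hom", "het"), each = 2L),
                    category = rep(names(extra$hom), 2L),
                    count = c(extra$hom, extra$het))
    a <- rbind(a, b)
  }
  write.table(a, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
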