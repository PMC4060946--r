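#' Library mapping conventions
#'
#' The facing and insert-size conventions used to classify read pairs:
#' short-insert paired-end libraries expect inward-facing mates with inserts
#' up to 600 bp and require at least 80% of a read aligned; long-insert
#' (mate-pair) libraries expect outward-facing mates with inserts up to
#' 100 kb and require at least 50% aligned.
#'
#' @param library_type `"short"` or `"long"`.
#' @param max_insert maximum insert size considered for a paired mapping.
#' @param min_aligned_fraction minimum fraction of a read that must be
#'   aligned for the mate to count as mapped.
#' @return an object of class `library_convention`.
#' @export
library_convention <- function(library_type = c("short", "long"),
                               max_insert = NULL, min_aligned_fraction = NULL) {
  library_type <- match.arg(library_type)
  short <- library_type == "short"
  if (is.null(max_insert)) max_insert <- if (short) 600L else 100000L
  if (is.null(min_aligned_fraction)) min_aligned_fraction <- if (short) 0.8 else 0.5
  if (max_insert <= 0) stopf("max_insert must be positive")
  structure(list(library_type = library_type,
                 proper_facing = if (short) "inward" else "outward",
                 max_insert = max_insert,
                 min_aligned_fraction = min_aligned_fraction),
            class = "library_convention")
}

#' Pair categories
#'
#' The exhaustive, mutually exclusive read-pair taxonomy, in classification
#' precedence order.
#' @export
PAIR_CATEGORIES <- c("BOTH_UNMAPPED", "SINGLETON", "DUPLICATE",
                     "INTERCHROMOSOMAL", "SAME_ORIENTATION", "WRONG_FACING",
                     "INCORRECT_INSERT", "PROPER")

#' Flag PCR duplicate pairs by mapped coordinates
#'
#' Pairs whose two mates have identical `(chrom, start, end, strand)` tuples
#' are duplicates of each other; all but the first pair in input order are
#' flagged. Mate order within a pair is canonicalised before comparison, so
#' swapping mates does not affect duplicate detection. Pairs with an
#' unmapped mate are never flagged. The operation is idempotent.
#'
#' @param pairs a `read_pairs` data.frame.
#' @return the same data.frame with its `duplicate` column set.
#' @export
mark_duplicates <- function(pairs) {
  k1 <- paste(pairs$chrom1, pairs$start1, pairs$end1, pairs$strand1)
  k2 <- paste(pairs$chrom2, pairs$start2, pairs$end2, pairs$strand2)
  lo <- pmin(k1, k2)
  hi <- pmax(k1, k2)
  key <- paste(lo, hi, sep = "|")
  both <- pairs$mapped1 & pairs$mapped2
  dup <- rep(FALSE, nrow(pairs))
  dup[both] <- duplicated(key[both])
  pairs$duplicate <- dup
  pairs
}

pair_geometry <- function(pairs, conv) {
  eff1 <- pairs$mapped1 & pairs$af1 >= conv$min_aligned_fraction
  eff2 <- pairs$mapped2 & pairs$af2 >= conv$min_aligned_fraction
  same_chrom <- eff1 & eff2 & pairs$chrom1 == pairs$chrom2
  same_strand <- same_chrom & pairs$strand1 == pairs$strand2
  ## leftmost mate: smaller start, ties by smaller end
  left1 <- pairs$start1 < pairs$start2 |
    (pairs$start1 == pairs$start2 & pairs$end1 < pairs$end2)
  equal_iv <- pairs$start1 == pairs$start2 & pairs$end1 == pairs$end2
  left_strand <- ifelse(left1, pairs$strand1, pairs$strand2)
  facing <- ifelse(equal_iv, "inward",
                   ifelse(left_strand == "+", "inward", "outward"))
  insert <- ifelse(same_strand, abs(pairs$start1 - pairs$start2),
                   pmax(pairs$end1, pairs$end2) - pmin(pairs$start1, pairs$start2))
  list(eff1 = eff1, eff2 = eff2, same_chrom = same_chrom,
       same_strand = same_strand, facing = facing, insert = insert)
}

#' Insert size of read pairs
#'
#' The reference distance spanned by a pair, mates included. For
#' opposite-strand pairs this is the outer span
#' `max(end) - min(start)`; for same-strand pairs, whose outer span is not
#' meaningful, the start-to-start distance `|start1 - start2|` is used —
#' the statistic under which pairs with inverted-duplicated insert ends
#' (whose two reads map on top of each other) peak near 0.
#'
#' @param pairs a `read_pairs` data.frame.
#' @return numeric vector; `NA` where mates are unmapped or on different
#'   chromosomes.
#' @export
compute_insert <- function(pairs) {
  ok <- pairs$mapped1 & pairs$mapped2 &
    !is.na(pairs$chrom1) & !is.na(pairs$chrom2) & pairs$chrom1 == pairs$chrom2
  same_strand <- pairs$strand1 == pairs$strand2
  out <- ifelse(same_strand, abs(pairs$start1 - pairs$start2),
                pmax(pairs$end1, pairs$end2) - pmin(pairs$start1, pairs$start2))
  out[!ok] <- NA_real_
  as.numeric(out)
}

#' Classify read pairs into the mapping QC taxonomy
#'
#' Applies the category precedence (first match wins):
#' `BOTH_UNMAPPED` (no usable mate) -> `SINGLETON` (exactly one usable
#' mate) -> `DUPLICATE` (duplicate flag set) -> `INTERCHROMOSOMAL` ->
#' `SAME_ORIENTATION` (both mates on the same strand — the chimera
#' signature) -> `WRONG_FACING` (opposite strands but facing against the
#' library convention: outies in short libraries, innies in long ones) ->
#' `INCORRECT_INSERT` (correct facing but insert above `max_insert`) ->
#' `PROPER`. Mates aligned below `min_aligned_fraction` are treated as
#' unmapped. Classification is invariant under swapping mate order.
#'
#' @param pairs a `read_pairs` data.frame (run [mark_duplicates()] first if
#'   duplicate flags are not already set).
#' @param conv a [library_convention()].
#' @return factor of categories, levels [PAIR_CATEGORIES].
#' @export
classify_pairs <- function(pairs, conv) {
  stopifnot(inherits(conv, "library_convention"))
  g <- pair_geometry(pairs, conv)
  n_eff <- as.integer(g$eff1) + as.integer(g$eff2)
  cat <- rep("PROPER", nrow(pairs))
  cat[n_eff == 0L] <- "BOTH_UNMAPPED"
  cat[n_eff == 1L] <- "SINGLETON"
  both <- n_eff == 2L
  cat[both & pairs$duplicate] <- "DUPLICATE"
  rest <- both & !pairs$duplicate
  cat[rest & pairs$chrom1 != pairs$chrom2] <- "INTERCHROMOSOMAL"
  rest <- rest & pairs$chrom1 == pairs$chrom2
  cat[rest & g$same_strand] <- "SAME_ORIENTATION"
  rest <- rest & !g$same_strand
  wrong <- rest & g$facing != conv$proper_facing
  cat[wrong] <- "WRONG_FACING"
  rest <- rest & g$facing == conv$proper_facing
  cat[rest & g$insert > conv$max_insert] <- "INCORRECT_INSERT"
  factor(cat, levels = PAIR_CATEGORIES)
}

#' Summarise a library's mapping statistics
#'
#' Produces the per-library mapping summary: totals, mapped and duplicate
#' percentages, the proper-pair percentage, per-category percentages of the
#' improper classes, the median insert size of proper pairs and the median
#' per-base depth. All percentages are relative to the total number of
#' reads (two per pair). Duplicate pairs are excluded from the improper
#' category percentages.
#'
#' @param pairs a `read_pairs` data.frame with duplicate flags set.
#' @param conv a [library_convention()].
#' @param depth_track optional `depth_track` (see
#'   [depth_from_alignments()]) used for the median-depth column.
#' @return a one-row data.frame of class `pair_summary`.
#' @export
summarize_library <- function(pairs, conv, depth_track = NULL) {
  if (nrow(pairs) == 0L) stopf("empty pair table")
  cat <- classify_pairs(pairs, conv)
  g <- pair_geometry(pairs, conv)
  total_reads <- 2L * nrow(pairs)
  n_mapped <- sum(as.integer(g$eff1) + as.integer(g$eff2))
  pct <- function(n_pairs) 100 * 2 * n_pairs / total_reads
  n <- table(cat)
  proper_insert <- compute_insert(pairs[cat == "PROPER", , drop = FALSE])
  out <- data.frame(
    library_type = conv$library_type,
    total_reads = total_reads,
    mapped_pct = 100 * n_mapped / total_reads,
    duplicates_pct = pct(n[["DUPLICATE"]]),
    proper_pct = pct(n[["PROPER"]]),
    both_mapped_pct = pct(sum(g$eff1 & g$eff2)),
    singleton_pct = pct(n[["SINGLETON"]]),
    interchromosomal_pct = pct(n[["INTERCHROMOSOMAL"]]),
    wrong_facing_pct = pct(n[["WRONG_FACING"]]),
    same_orientation_pct = pct(n[["SAME_ORIENTATION"]]),
    incorrect_insert_pct = pct(n[["INCORRECT_INSERT"]]),
    median_insert = as.numeric(median(proper_insert, na.rm = TRUE)),
    median_depth = if (is.null(depth_track)) NA_real_ else median_depth(depth_track))
  class(out) <- c("pair_summary", "data.frame")
  out
}
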