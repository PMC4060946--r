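#' Chimera signature of a library
#'
#' Quantifies the same-orientation (both mates on the same strand) read
#' pairs that are the hallmark of WGA chimeras, and the features that
#' separate the two chimera mechanisms: fold-back products give mate pairs
#' that lie on top of each other (start-to-start distance near 0), while
#' re-priming chimeras give a broad distance distribution governed by the
#' deletion length.
#'
#' @param pairs a `read_pairs` data.frame with duplicate flags set.
#' @param conv a [library_convention()].
#' @param read_length read length in bases; sets the first histogram bin
#'   `[0, read_length]` within which the two mates of a pair overlap.
#' @param n_genome_bins number of equal genomic bins per chromosome for the
#'   positional uniformity test.
#' @param genome_length named vector of chromosome lengths (optional; when
#'   missing, the maximum mapped coordinate is used).
#' @return list of class `chimera_signature` with elements
#'   `same_orientation_fraction` (of total reads), `n_same_orientation`,
#'   `insert_histogram` (data.frame of log-spaced bins plus the
#'   `[0, read_length]` bin), `mate_overlap_fraction`, and `uniformity`
#'   (per-bin counts with a chi-square statistic and p-value).
#' @export
chimera_signature <- function(pairs, conv, read_length = NULL,
                              n_genome_bins = 20L, genome_length = NULL) {
  cat <- classify_pairs(pairs, conv)
  so <- pairs[cat == "SAME_ORIENTATION", , drop = FALSE]
  n_so <- nrow(so)
  frac <- 2 * n_so / (2 * nrow(pairs))
  if (is.null(read_length)) {
    read_length <- max(c(pairs$end1 - pairs$start1, pairs$end2 - pairs$start2),
                       na.rm = TRUE)
  }
  if (n_so == 0L) {
    return(structure(list(same_orientation_fraction = 0,
                          n_same_orientation = 0L,
                          insert_histogram = data.frame(lower = numeric(0),
                                                        upper = numeric(0),
                                                        count = integer(0)),
                          mate_overlap_fraction = 0,
                          uniformity = NULL),
                     class = "chimera_signature"))
  }
  ins <- compute_insert(so)
  hi <- max(ins, read_length + 1)
  breaks <- unique(c(0, read_length,
                     exp(seq(log(read_length + 1), log(hi + 1), length.out = 12L))))
  breaks[length(breaks)] <- hi + 1
  cut_idx <- findInterval(ins, breaks, rightmost.closed = TRUE)
  counts <- tabulate(cut_idx, nbins = length(breaks) - 1L)
  hist_df <- data.frame(lower = breaks[-length(breaks)],
                        upper = breaks[-1], count = counts)
  overlap <- so$start1 < so$end2 & so$start2 < so$end1
  mate_overlap_fraction <- mean(overlap)

  mid <- (pmin(so$start1, so$start2) + pmax(so$end1, so$end2)) / 2
  if (is.null(genome_length)) {
    genome_length <- tapply(pmax(so$end1, so$end2), so$chrom1, max)
  }
  bins <- lapply(names(genome_length), function(ch) {
    m <- mid[so$chrom1 == ch]
    b <- pmin(n_genome_bins, 1L + floor(m / (genome_length[[ch]] / n_genome_bins)))
    tabulate(b, nbins = n_genome_bins)
  })
  counts_bins <- unlist(bins)
  uniformity <- if (n_so >= 2L) {
    cs <- suppressWarnings(chisq.test(counts_bins))
    list(bin_counts = counts_bins, statistic = unname(cs$statistic),
         df = unname(cs$parameter), p_value = unname(cs$p.value))
  } else NULL

  structure(list(same_orientation_fraction = frac,
                 n_same_orientation = n_so,
                 insert_histogram = hist_df,
                 mate_overlap_fraction = mate_overlap_fraction,
                 uniformity = uniformity),
            class = "chimera_signature")
}

#' @export
print.chimera_signature <- function(x, ...) {
  cat(sprintf("chimera signature: %d same-orientation pairs (%.3f%% of reads), mate overlap %.2f\n",
              x$n_same_orientation, 100 * x$same_orientation_fraction,
              x$mate_overlap_fraction))
  invisible(x)
}
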