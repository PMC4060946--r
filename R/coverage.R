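#' Per-base depth from properly paired reads
#'
#' Builds the per-base depth track used for evenness and window profiling:
#' every base covered by the aligned interval of a mate belonging to a
#' PROPER pair increments depth by one; duplicate pairs are excluded.
#'
#' @param pairs a `read_pairs` data.frame with duplicate flags set.
#' @param conv a [library_convention()].
#' @param genome_length named list/vector of chromosome lengths.
#' @param categories pair categories contributing to depth (default
#'   `"PROPER"`).
#' @return object of class `depth_track`: list with `depth` (named list of
#'   integer vectors), `mean_depth`, and `genome_length`.
#' @export
depth_from_alignments <- function(pairs, conv, genome_length,
                                  categories = "PROPER") {
  cat <- classify_pairs(pairs, conv)
  keep <- cat %in% categories & !pairs$duplicate
  if (!any(keep)) stopf("no pairs in the requested categories")
  p <- pairs[keep, , drop = FALSE]
  if (is.null(names(genome_length))) stopf("genome_length must be named by chromosome")
  depth <- lapply(names(genome_length), function(ch) {
    L <- genome_length[[ch]]
    s <- c(p$start1[p$chrom1 == ch], p$start2[p$chrom2 == ch])
    e <- c(p$end1[p$chrom1 == ch], p$end2[p$chrom2 == ch])
    e <- pmin(e, L)
    as.integer(IRanges::coverage(IRanges::IRanges(start = s + 1L, end = e), width = L))
  })
  names(depth) <- names(genome_length)
  total <- sum(vapply(depth, function(d) sum(as.numeric(d)), 0))
  len <- sum(unlist(genome_length))
  structure(list(depth = depth, mean_depth = total / len,
                 genome_length = genome_length),
            class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("depth_track: %d chromosome(s), %.0f bp, mean depth %.2f\n",
              length(x$depth), sum(unlist(x$genome_length)), x$mean_depth))
  invisible(x)
}

#' Median per-base depth
#' @param track a `depth_track`.
#' @return median depth over all genome positions.
#' @export
median_depth <- function(track) {
  median(unlist(track$depth, use.names = FALSE))
}

#' Coverage evenness curve
#'
#' The empirical quantile function of mean-normalised per-base depth:
#' sorting all genome positions by depth, the curve maps the cumulative
#' genome fraction to the normalised depth quantile. Perfectly uniform
#' coverage gives the constant line at 1; the deviation score is the area
#' between the curve and that line, `mean(|normalized depth - 1|)`, and is 0
#' iff depth is constant. Note that even unbiased shotgun sampling has a
#' stochastic floor: per-base depth is approximately Poisson, so at mean
#' depth `d` the deviation cannot fall below about `sqrt(2 / (pi * d))`.
#'
#' @param track a `depth_track`.
#' @return list of class `evenness_curve`: `genome_fraction`,
#'   `normalized_depth` (non-decreasing), `deviation`, `mean_depth`.
#' @export
evenness_curve <- function(track) {
  mu <- track$mean_depth
  if (mu <= 0) stopf("all-zero depth track")
  d <- unlist(track$depth, use.names = FALSE)
  L <- length(d)
  tab <- tabulate(d + 1L)            # counts of depth 0, 1, 2, ...
  depths <- seq_along(tab) - 1L
  keep <- tab > 0L
  depths <- depths[keep]; counts <- tab[keep]
  q <- depths / mu
  cumfrac <- cumsum(counts) / L
  deviation <- sum(counts * abs(q - 1)) / L
  structure(list(genome_fraction = cumfrac, normalized_depth = q,
                 deviation = deviation, mean_depth = mu),
            class = "evenness_curve")
}

#' @export
print.evenness_curve <- function(x, ...) {
  cat(sprintf("evenness curve: mean depth %.2f, deviation score %.4f\n",
              x$mean_depth, x$deviation))
  invisible(x)
}

window_fractions <- function(starts, ends, L, win_start, win_end) {
  if (length(starts) == 0L) return(numeric(length(win_start)))
  cov <- IRanges::coverage(IRanges::IRanges(start = starts + 1L, end = ends), width = L)
  v <- IRanges::Views(cov > 0L, start = win_start + 1L, end = win_end)
  as.numeric(IRanges::viewSums(v)) / (win_end - win_start)
}

#' Windowed coverage, GC and repeat-content table
#'
#' Tiles each chromosome with non-overlapping windows and reports per-window
#' median depth, median depth normalised by the genome-wide mean of window
#' medians (full windows only), GC fraction, and the fraction of the window
#' covered by tandem and inverted repeat annotations. A trailing partial
#' window is retained with its true length and flagged; correlations should
#' be computed on full windows.
#'
#' @param track a `depth_track`.
#' @param genome a `synthetic_genome`, or a named character vector of
#'   chromosome sequences.
#' @param repeats repeat annotation data.frame (`chrom` optional, `start`,
#'   `end`, `kind`), e.g. `genome$repeat_features` or [read_repeat_bed()].
#' @param window window size in bases (default 10 kb).
#' @return data.frame of class `window_table`: `chrom`, `start`, `end`,
#'   `median_depth`, `norm_depth`, `gc`, `tandem`, `inverted`, `partial`.
#' @export
window_stats <- function(track, genome, repeats = NULL, window = 10000L) {
  seqs <- if (inherits(genome, "synthetic_genome")) {
    setNames(list(genome$sequence), genome$name)
  } else as.list(genome)
  if (is.null(repeats) && inherits(genome, "synthetic_genome")) {
    repeats <- genome$repeat_features
  }
  rows <- lapply(names(track$depth), function(ch) {
    L <- track$genome_length[[ch]]
    ws <- seq(0L, L - 1L, by = window)
    we <- pmin(ws + window, L)
    d <- track$depth[[ch]]
    n_full <- L %/% window
    med <- numeric(length(ws))
    if (n_full > 0L) {
      m <- matrix(d[seq_len(n_full * window)], nrow = window)
      med[seq_len(n_full)] <- apply(m, 2L, median)
    }
    if (length(ws) > n_full) {
      med[length(ws)] <- median(d[(n_full * window + 1L):L])
    }
    dna <- Biostrings::DNAString(seqs[[ch]])
    gc <- as.numeric(Biostrings::letterFrequency(
      Biostrings::Views(dna, start = ws + 1L, end = we), "GC", as.prob = TRUE))
    rp <- repeats
    if (!is.null(rp) && "chrom" %in% names(rp)) rp <- rp[rp$chrom == ch, , drop = FALSE]
    tand <- if (is.null(rp)) numeric(length(ws)) else
      window_fractions(rp$start[rp$kind == "tandem"], rp$end[rp$kind == "tandem"], L, ws, we)
    inv <- if (is.null(rp)) numeric(length(ws)) else
      window_fractions(rp$start[rp$kind == "inverted"], rp$end[rp$kind == "inverted"], L, ws, we)
    data.frame(chrom = ch, start = ws, end = we, median_depth = med,
               gc = gc, tandem = tand, inverted = inv,
               partial = (we - ws) < window, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  norm_const <- mean(out$median_depth[!out$partial])
  out$norm_depth <- out$median_depth / norm_const
  attr(out, "normalization_mean_of_medians") <- norm_const
  attr(out, "mean_depth") <- track$mean_depth
  class(out) <- c("window_table", "data.frame")
  out[, c("chrom", "start", "end", "median_depth", "norm_depth", "gc",
          "tandem", "inverted", "partial")]
}

spearman_test <- function(x, y, n_perm = 10000L, perm_seed = 1L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  if (n > 30L) {
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    p <- ct$p.value
  } else {
    ## exact-style permutation p-value for small n, seeded for determinism
    p <- withr::with_seed(perm_seed, {
      perm <- replicate(n_perm, suppressWarnings(
        stats::cor(x, sample(y), method = "spearman")))
      (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
    })
  }
  list(rho = unname(rho), p = unname(p), n = n)
}

#' Correlation of window coverage with repeat content
#'
#' Spearman rank correlations (midranks for ties) of normalised window
#' coverage against the tandem and inverted repeat fractions, with
#' two-sided p-values (t approximation for n > 30, seeded permutation test
#' otherwise). Partial windows are excluded. If either variable is
#' constant, the correlation is reported as `NA`.
#'
#' @param table a `window_table`.
#' @return list with `rho_tandem`, `p_tandem`, `rho_inverted`,
#'   `p_inverted`, `n_windows`.
#' @export
repeat_coverage_correlation <- function(table) {
  full <- table[!table$partial, , drop = FALSE]
  if (nrow(full) < 10L) stopf("need at least 10 full windows")
  t_res <- spearman_test(full$norm_depth, full$tandem)
  i_res <- spearman_test(full$norm_depth, full$inverted)
  list(rho_tandem = t_res$rho, p_tandem = t_res$p,
       rho_inverted = i_res$rho, p_inverted = i_res$p,
       n_windows = nrow(full))
}

#' GC distribution of mapped reads versus the genome-wide expectation
#'
#' Computes the GC fraction of the reference span of every usable mapped
#' read and compares its distribution with the theoretical one obtained
#' from read-length windows at every genome position. GC is measured on the
#' reference, not the read sequence, so the statistic is independent of the
#' sequencing error model. The shift statistic is
#' `mean(observed GC) - mean(theoretical GC)`: positive values indicate
#' enrichment of reads from GC-rich sequence.
#'
#' @param pairs a `read_pairs` data.frame.
#' @param genome a `synthetic_genome`.
#' @param read_length window width for the theoretical distribution;
#'   defaults to the modal mapped-read span.
#' @param exclude_duplicates drop duplicate-flagged pairs (default TRUE).
#' @param bin_width histogram bin width on the GC axis (default 0.01).
#' @return list of class `gc_profile`: `observed` and `theoretical`
#'   histogram data.frames (`gc`, `density`, both summing to 1),
#'   `shift` (observed mean GC - theoretical mean GC), `n_reads`.
#' @export
read_gc_distribution <- function(pairs, genome, read_length = NULL,
                                 exclude_duplicates = TRUE, bin_width = 0.01) {
  p <- pairs
  if (exclude_duplicates) p <- p[!p$duplicate, , drop = FALSE]
  starts <- c(p$start1[p$mapped1], p$start2[p$mapped2])
  ends <- c(p$end1[p$mapped1], p$end2[p$mapped2])
  if (length(starts) == 0L) stopf("no mapped reads")
  if (is.null(read_length)) {
    w <- ends - starts
    read_length <- as.integer(names(sort(table(w), decreasing = TRUE))[1])
  }
  dna <- Biostrings::DNAString(genome$sequence)
  obs_gc <- as.numeric(Biostrings::letterFrequency(
    Biostrings::Views(dna, start = starts + 1L, end = pmin(ends, genome$length)),
    "GC", as.prob = TRUE))
  theo_gc <- as.numeric(Biostrings::letterFrequencyInSlidingView(
    dna, read_length, "GC", as.prob = TRUE))
  brk <- seq(0, 1 + bin_width, by = bin_width)
  hist_of <- function(x) {
    idx <- pmin(length(brk) - 1L, 1L + floor(x / bin_width))
    cnt <- tabulate(idx, nbins = length(brk) - 1L)
    data.frame(gc = brk[-length(brk)], density = cnt / sum(cnt))
  }
  structure(list(observed = hist_of(obs_gc), theoretical = hist_of(theo_gc),
                 shift = mean(obs_gc) - mean(theo_gc),
                 n_reads = length(obs_gc)),
            class = "gc_profile")
}

#' Per-window coverage difference between two libraries versus GC
#'
#' For two window tables on the same grid (typically a long- and a
#' short-insert library over the same genome), computes the per-window
#' difference of normalised coverage (`table_long - table_short`) and its
#' Spearman correlation with window GC. A positive correlation means the
#' long-insert library preferentially covers GC-rich windows.
#'
#' @param table_short,table_long `window_table`s on identical grids.
#' @return list with the per-window data.frame (`chrom`, `start`, `end`,
#'   `gc`, `diff`) and `rho`, `p`.
#' @export
library_gc_difference <- function(table_short, table_long) {
  if (nrow(table_short) != nrow(table_long) ||
      any(table_short$chrom != table_long$chrom) ||
      any(table_short$start != table_long$start) ||
      any(table_short$end != table_long$end)) {
    stopf("window grids differ between the two tables")
  }
  full <- !table_short$partial
  d <- data.frame(chrom = table_short$chrom[full],
                  start = table_short$start[full],
                  end = table_short$end[full],
                  gc = table_short$gc[full],
                  diff = table_long$norm_depth[full] - table_short$norm_depth[full])
  res <- spearman_test(d$diff, d$gc)
  list(windows = d, rho = res$rho, p = res$p)
}
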