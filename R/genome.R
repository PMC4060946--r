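#' Specification of a synthetic genome
#'
#' Describes a single-chromosome synthetic genome used to emulate a compact
#' eukaryote reference: target GC content, planted tandem and inverted
#' repeats, and how strongly repeats cluster towards the chromosome ends
#' (mimicking the repeat-rich autosome arms of nematode chromosomes).
#'
#' @param length genome length in bases (> 0).
#' @param gc_target target GC fraction in \[0, 1\].
#' @param tandem_repeats list of `c(unit_length, copy_number, count)` triples;
#'   each planted tandem feature spans `unit_length * copy_number` bases.
#' @param inverted_repeats list of `c(arm_length, spacer_length, count)`
#'   triples; each feature spans `2 * arm_length + spacer_length` bases and
#'   consists of an arm, a spacer, and the reverse complement of the arm.
#' @param arm_cluster_fraction fraction of repeat features placed in the
#'   terminal thirds of the chromosome (the "arms"); the rest go to the
#'   middle third.
#' @param gc_block_sd,gc_block_size regional base-composition heterogeneity:
#'   the background GC drifts between blocks of `gc_block_size` bases with
#'   standard deviation `gc_block_sd` around `gc_target` (block deviations
#'   are centred, so the genome-wide GC hits the target exactly in
#'   expectation regardless of block count). Set `gc_block_sd = 0` for a
#'   homogeneous background.
#' @param name chromosome name used in all outputs.
#' @param seed integer seed; the same spec always yields the same genome.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(length, gc_target = 0.36, tandem_repeats = list(),
                        inverted_repeats = list(), arm_cluster_fraction = 0.8,
                        gc_block_sd = 0.03, gc_block_size = 10000L,
                        name = "chrS", seed = 1L) {
  if (!is_count(length) || length <= 0) stopf("`length` must be a positive integer")
  if (!is_fraction(gc_target)) stopf("`gc_target` must be in [0, 1]")
  if (!is_fraction(arm_cluster_fraction)) stopf("`arm_cluster_fraction` must be in [0, 1]")
  norm_triples <- function(x, what, n_fields) {
    lapply(x, function(tr) {
      tr <- as.numeric(tr)
      if (length(tr) != n_fields || any(tr < 0)) stopf("malformed %s entry", what)
      tr
    })
  }
  tandem_repeats <- norm_triples(tandem_repeats, "tandem_repeats", 3L)
  inverted_repeats <- norm_triples(inverted_repeats, "inverted_repeats", 3L)
  span_t <- sum(vapply(tandem_repeats, function(tr) tr[1] * tr[2] * tr[3], 0))
  span_i <- sum(vapply(inverted_repeats, function(tr) (2 * tr[1] + tr[2]) * tr[3], 0))
  if (span_t + span_i >= length) {
    stopf("total repeat span (%d) must be smaller than genome length (%d)",
          span_t + span_i, length)
  }
  if (gc_block_sd < 0 || !is_count(gc_block_size) || gc_block_size < 1) {
    stopf("invalid GC block parameters")
  }
  structure(list(length = as.integer(length), gc_target = gc_target,
                 tandem_repeats = tandem_repeats,
                 inverted_repeats = inverted_repeats,
                 arm_cluster_fraction = arm_cluster_fraction,
                 gc_block_sd = gc_block_sd,
                 gc_block_size = as.integer(gc_block_size),
                 name = name, seed = as.integer(seed)),
            class = "genome_spec")
}

random_bases <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(DNA_BASES, n, replace = TRUE, prob = p)
}

## Place `widths` non-overlapping intervals on [0, L), a fraction of them in
## the terminal thirds. Rejection sampling with bounded retries.
place_features <- function(widths, L, cluster_fraction, max_tries = 2000L) {
  n <- length(widths)
  if (n == 0L) return(integer(0))
  placed_start <- integer(0)
  placed_end <- integer(0)
  starts <- integer(n)
  third <- L %/% 3L
  ## widest first: easier packing
  ord <- order(widths, decreasing = TRUE)
  for (i in ord) {
    w <- widths[i]
    if (w > L) stopf("repeat feature of width %d exceeds genome length %d", w, L)
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      in_arms <- runif(1) < cluster_fraction
      if (in_arms) {
        left <- runif(1) < 0.5
        lo <- if (left) 0L else 2L * third
        hi <- if (left) third else L
      } else {
        lo <- third; hi <- 2L * third
      }
      if (hi - lo < w) { lo <- 0L; hi <- L }
      s <- lo + floor(runif(1) * (hi - lo - w + 1))
      e <- s + w
      if (!any(s < placed_end & e > placed_start)) {
        placed_start <- c(placed_start, s)
        placed_end <- c(placed_end, e)
        starts[i] <- as.integer(s)
        ok <- TRUE
        break
      }
    }
    if (!ok) stopf("could not place repeat features without overlap; reduce repeat load")
  }
  starts
}

#' Generate a synthetic genome with planted repeats
#'
#' Builds a random background sequence at the target GC and overwrites it
#' with the planted tandem and inverted repeat features described by the
#' spec. Repeat units are drawn at the same base composition, so the planted
#' repeats do not perturb the genome-wide GC fraction. Features of all kinds
#' are mutually non-overlapping and recorded exactly in the truth annotation.
#'
#' @param spec a [genome_spec()].
#' @return an object of class `synthetic_genome`: a list with elements
#'   `name`, `sequence` (single character string), `length`, and
#'   `repeat_features` (data.frame with 0-based half-open `start`, `end` and
#'   `kind` in `{"tandem", "inverted"}`).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  withr::with_seed(spec$seed, {
    L <- spec$length
    sd <- if (is.null(spec$gc_block_sd)) 0 else spec$gc_block_sd
    if (sd > 0) {
      bs <- spec$gc_block_size
      nb <- as.integer(ceiling(L / bs))
      w <- pmin(seq_len(nb) * bs, L) - (seq_len(nb) - 1L) * bs
      dev <- rnorm(nb, 0, sd)
      dev <- dev - sum(dev * w) / L          # centre: genome GC == target
      block_gc <- pmin(0.95, pmax(0.05, spec$gc_target + dev))
      bases <- unlist(lapply(seq_len(nb), function(b) random_bases(w[b], block_gc[b])),
                      use.names = FALSE)
    } else {
      bases <- random_bases(L, spec$gc_target)
    }

    widths <- integer(0); kinds <- character(0); makers <- list()
    for (tr in spec$tandem_repeats) {
      unit_len <- as.integer(tr[1]); copies <- as.integer(tr[2]); count <- as.integer(tr[3])
      for (k in seq_len(count)) {
        widths <- c(widths, unit_len * copies); kinds <- c(kinds, "tandem")
        makers[[length(makers) + 1L]] <- local({
          ul <- unit_len; cp <- copies
          function() rep(random_bases(ul, spec$gc_target), cp)
        })
      }
    }
    for (ir in spec$inverted_repeats) {
      arm <- as.integer(ir[1]); spacer <- as.integer(ir[2]); count <- as.integer(ir[3])
      for (k in seq_len(count)) {
        widths <- c(widths, 2L * arm + spacer); kinds <- c(kinds, "inverted")
        makers[[length(makers) + 1L]] <- local({
          a <- arm; sp <- spacer
          function() {
            arm_seq <- random_bases(a, spec$gc_target)
            spacer_seq <- if (sp > 0) random_bases(sp, spec$gc_target) else character(0)
            c(arm_seq, spacer_seq,
              rev(chartr("ACGT", "TGCA", arm_seq)))
          }
        })
      }
    }

    starts <- place_features(widths, L, spec$arm_cluster_fraction)
    for (i in seq_along(starts)) {
      seqv <- makers[[i]]()
      bases[(starts[i] + 1L):(starts[i] + widths[i])] <- seqv
    }

    feats <- data.frame(start = starts, end = starts + widths, kind = kinds,
                        stringsAsFactors = FALSE)
    feats <- feats[order(feats$start), , drop = FALSE]
    rownames(feats) <- NULL
    structure(list(name = spec$name,
                   sequence = paste(bases, collapse = ""),
                   length = L,
                   gc = mean(bases %in% c("G", "C")),
                   repeat_features = feats,
                   spec = spec),
              class = "synthetic_genome")
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic_genome '%s': %d bp, GC %.3f, %d repeat features (%d tandem, %d inverted)\n",
              x$name, x$length, x$gc, nrow(x$repeat_features),
              sum(x$repeat_features$kind == "tandem"),
              sum(x$repeat_features$kind == "inverted")))
  invisible(x)
}

#' Write genome outputs
#'
#' `write_genome_fasta()` writes the sequence as FASTA;
#' `write_repeat_bed()` writes the truth repeat annotation as a 0-based
#' half-open BED file with the repeat kind in the name column.
#'
#' @param genome a `synthetic_genome`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  dna <- Biostrings::DNAStringSet(setNames(genome$sequence, genome$name))
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
write_repeat_bed <- function(genome, path) {
  f <- genome$repeat_features
  bed <- data.frame(chrom = genome$name, start = f$start, end = f$end, name = f$kind)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a repeat annotation BED file
#'
#' Reads the first four BED columns (0-based half-open) into the
#' `repeat_features` data.frame layout used across the package. The name
#' column must be `tandem` or `inverted`.
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end`, `kind`.
#' @export
read_repeat_bed <- function(path) {
  bed <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) stopf("repeat BED needs at least 4 columns (chrom, start, end, kind)")
  data.frame(chrom = bed[[1]], start = as.integer(bed[[2]]),
             end = as.integer(bed[[3]]), kind = bed[[4]],
             stringsAsFactors = FALSE)
}
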