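#' Library construction parameters
#'
#' Parameters of a simulated Illumina library built from a WGA fragment
#' pool. Defaults follow typical practice: 450 bp short-insert paired-end
#' libraries and 3 kb long-insert (mate-pair) libraries, 100 bp reads,
#' about 1% PCR duplicates in short libraries and a higher rate in
#' long-insert libraries, plus the two artifact classes specific to
#' mate-pair construction (non-junction pairs from segments lacking the
#' biotinylated junction adaptor, and short circularised templates that
#' escape size selection).
#'
#' @param library_type `"short"` or `"long"`.
#' @param insert_mean,insert_sd target insert size in bases (defaults
#'   450/45 short, 3000/300 long).
#' @param read_length read length in bases.
#' @param n_pairs number of read pairs to emit.
#' @param dup_rate fraction of emitted pairs that are PCR duplicates
#'   (re-emissions of an earlier pair); default 0.01 short, 0.05 long.
#' @param nonjunction_rate long-only: fraction of pairs drawn as short,
#'   inward-facing pairs from a random interior segment of the circularised
#'   template (no junction adaptor).
#' @param circular_contaminant_rate long-only: fraction of pairs from short
#'   (< 1.5 kb) templates that escaped size selection and were circularised;
#'   these keep the correct outward facing but have short inserts.
#' @param error_rate per-base substitution probability in read sequences.
#' @param seed integer seed.
#' @return an object of class `library_params`.
#' @export
library_params <- function(library_type = c("short", "long"),
                           insert_mean = NULL, insert_sd = NULL,
                           read_length = 100L, n_pairs = 10000L,
                           dup_rate = NULL, nonjunction_rate = NULL,
                           circular_contaminant_rate = NULL,
                           error_rate = 0, seed = 1L) {
  library_type <- match.arg(library_type)
  short <- library_type == "short"
  if (is.null(insert_mean)) insert_mean <- if (short) 450L else 3000L
  if (is.null(insert_sd)) insert_sd <- if (short) 45 else 300
  if (is.null(dup_rate)) dup_rate <- if (short) 0.01 else 0.05
  if (is.null(nonjunction_rate)) nonjunction_rate <- if (short) 0 else 0.02
  if (is.null(circular_contaminant_rate)) circular_contaminant_rate <- if (short) 0 else 0.02
  for (r in list(dup_rate, nonjunction_rate, circular_contaminant_rate, error_rate)) {
    if (!is_fraction(r)) stopf("rates must be fractions in [0, 1]")
  }
  if (short && (nonjunction_rate > 0 || circular_contaminant_rate > 0)) {
    stopf("nonjunction_rate and circular_contaminant_rate apply to long libraries only")
  }
  if (read_length > insert_mean) stopf("read_length must not exceed insert_mean")
  if (!is_count(n_pairs) || n_pairs < 1) stopf("n_pairs must be a positive integer")
  structure(list(library_type = library_type, insert_mean = insert_mean,
                 insert_sd = insert_sd, read_length = as.integer(read_length),
                 n_pairs = as.integer(n_pairs), dup_rate = dup_rate,
                 nonjunction_rate = nonjunction_rate,
                 circular_contaminant_rate = circular_contaminant_rate,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "library_params")
}

inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  rl <- nchar(seqs)
  k <- rbinom(length(seqs), rl, rate)
  for (i in which(k > 0)) {
    pos <- sample.int(rl[i], k[i])
    ch <- strsplit(seqs[i], "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b) sample(DNA_BASES[DNA_BASES != b], 1L), "")
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

## Fold-back fragments travel through shearing as physical hairpins: a shear
## cut severs both strands of the folded molecule at one point, so any
## sheared piece containing the fold linearises to u + loop + revcomp(u) --
## its two ends are inverted copies of each other. We model this by snapping
## inserts that cover the fold midpoint so that they are centred on the fold
## (with a few bases of end-repair jitter).
snap_foldback <- function(frags_sel, i0, S) {
  inv <- which(frags_sel$mechanism == "inverted_dup")
  if (!length(inv)) return(i0)
  fold <- frags_sel$arm_len[inv] + frags_sel$loop_len[inv] / 2
  covers <- i0[inv] < fold & (i0[inv] + S[inv]) > fold &
    S[inv] >= frags_sel$loop_len[inv] + 20L
  if (!any(covers)) return(i0)
  j <- inv[covers]
  jitter <- sample(-5:5, length(j), replace = TRUE)
  newi <- as.integer(round(fold[covers] - S[j] / 2)) + jitter
  i0[j] <- pmax(0L, pmin(frags_sel$length[j] - S[j], newi))
  i0
}

## Emit read pairs from fragment rows; `facing` "inward" (mate1 reads the
## insert start forward, mate2 the insert end reverse-complemented) or
## "outward" (both flipped, as produced by circularisation in mate-pair
## protocols).
emit_pairs <- function(genome, frags, frag_idx, S, facing, read_length, error_rate) {
  fr <- frags[frag_idx, , drop = FALSE]
  n <- length(frag_idx)
  rl <- read_length
  i0 <- as.integer(floor(runif(n) * (fr$length - S + 1)))
  i0 <- snap_foldback(fr, i0, S)
  o1s <- i0; o1e <- i0 + rl
  o2s <- i0 + S - rl; o2e <- i0 + S
  rev1 <- facing == "outward"
  rev2 <- facing == "inward"
  m1 <- map_read_to_genome(fr, o1s, o1e, rev1)
  m2 <- map_read_to_genome(fr, o2s, o2e, rev2)
  seq1 <- fragment_subseq(genome, fr, o1s, o1e)
  seq2 <- fragment_subseq(genome, fr, o2s, o2e)
  seq1[rev1] <- revcomp(seq1[rev1])
  seq2[rev2] <- revcomp(seq2[rev2])
  seq1 <- inject_errors(seq1, error_rate)
  seq2 <- inject_errors(seq2, error_rate)
  list(
    reads = data.frame(seq1 = seq1, seq2 = seq2, stringsAsFactors = FALSE),
    truth = data.frame(
      frag_id = fr$id, mechanism = fr$mechanism,
      insert_len = as.integer(S),
      chrom = rep(genome$name, n),
      start1 = m1$gstart, end1 = m1$gend,
      strand1 = ifelse(m1$strand == 1L, "+", "-"), af1 = m1$af,
      clipL1 = ifelse(m1$seg_strand == 1L, m1$clip_low, m1$clip_high),
      clipR1 = ifelse(m1$seg_strand == 1L, m1$clip_high, m1$clip_low),
      start2 = m2$gstart, end2 = m2$gend,
      strand2 = ifelse(m2$strand == 1L, "+", "-"), af2 = m2$af,
      clipL2 = ifelse(m2$seg_strand == 1L, m2$clip_low, m2$clip_high),
      clipR2 = ifelse(m2$seg_strand == 1L, m2$clip_high, m2$clip_low),
      stringsAsFactors = FALSE)
  )
}

swap_mates <- function(res, swap) {
  if (!any(swap)) return(res)
  r <- res$reads; t <- res$truth
  tmp <- r$seq1[swap]; r$seq1[swap] <- r$seq2[swap]; r$seq2[swap] <- tmp
  for (col in c("start", "end", "strand", "af", "clipL", "clipR")) {
    c1 <- paste0(col, "1"); c2 <- paste0(col, "2")
    tmp <- t[[c1]][swap]; t[[c1]][swap] <- t[[c2]][swap]; t[[c2]][swap] <- tmp
  }
  list(reads = r, truth = t)
}

finish_library <- function(res, artifact_class, params, genome, n_dup) {
  n_orig <- nrow(res$reads)
  res$truth$artifact_class <- artifact_class
  if (n_dup > 0) {
    src <- sample.int(n_orig, n_dup, replace = TRUE)
    res$reads <- rbind(res$reads, res$reads[src, , drop = FALSE])
    dup_truth <- res$truth[src, , drop = FALSE]
    dup_truth$artifact_class <- "pcr_duplicate"
    res$truth <- rbind(res$truth, dup_truth)
  }
  n <- nrow(res$reads)
  ids <- sprintf("%s%07d", if (params$library_type == "short") "ps" else "pl", seq_len(n))
  reads <- cbind(data.frame(pair_id = ids, stringsAsFactors = FALSE), res$reads)
  truth <- cbind(data.frame(pair_id = ids, stringsAsFactors = FALSE), res$truth)
  rownames(reads) <- rownames(truth) <- NULL
  structure(list(reads = reads, truth = truth, params = params,
                 genome_name = genome$name, genome_length = genome$length,
                 read_length = params$read_length),
            class = "wga_library")
}

#' @export
print.wga_library <- function(x, ...) {
  cat(sprintf("wga_library (%s): %d pairs, read length %d, genome %s (%d bp)\n",
              x$params$library_type, nrow(x$reads), x$read_length,
              x$genome_name, x$genome_length))
  print(table(x$truth$artifact_class))
  invisible(x)
}

#' Simulate a short-insert paired-end library
#'
#' Shears the amplified fragment pool into inserts of approximately
#' `insert_mean` bases (normal, truncated at `read_length` below and the
#' fragment length above) and sequences `read_length` bases inward from
#' both insert ends. Fragments are selected proportionally to their length
#' (longer amplification products yield more shear pieces); amplification
#' bias itself is carried by the gain-weighted fragment start positions.
#' PCR duplicates are injected by re-emitting previously emitted pairs.
#' Fold-back (inverted duplication) fragments shear as hairpins, so inserts
#' covering the fold carry inverted-duplicated ends and yield
#' same-orientation read pairs with near-zero start-to-start distance.
#'
#' @param frags a `wga_fragments` pool from [simulate_fragments()].
#' @param genome the `synthetic_genome` the pool was drawn from.
#' @param params a [library_params()] with `library_type = "short"`.
#' @return an object of class `wga_library`: `reads` (pair id and the two
#'   read sequences), `truth` (one row per pair: source fragment, mechanism,
#'   artifact class, and each mate's true mapping chrom/start/end/strand and
#'   aligned fraction), plus the parameters.
#' @export
simulate_short_library <- function(frags, genome, params) {
  stopifnot(inherits(params, "library_params"))
  if (params$library_type != "short") stopf("params$library_type must be 'short'")
  if (nrow(frags) == 0L) stopf("empty fragment pool")
  withr::with_seed(params$seed, {
    n <- params$n_pairs
    n_dup <- rbinom(1L, n, params$dup_rate)
    n_orig <- max(1L, n - n_dup)
    n_dup <- n - n_orig
    frag_idx <- sample.int(nrow(frags), n_orig, replace = TRUE, prob = frags$length)
    Fl <- frags$length[frag_idx]
    S <- as.integer(round(rnorm(n_orig, params$insert_mean, params$insert_sd)))
    for (r in 1:5) {
      bad <- S < params$read_length | S > Fl
      if (!any(bad)) break
      S[bad] <- as.integer(round(rnorm(sum(bad), params$insert_mean, params$insert_sd)))
    }
    S <- pmax(params$read_length, pmin(S, Fl))
    res <- emit_pairs(genome, frags, frag_idx, S, "inward",
                      params$read_length, params$error_rate)
    res <- swap_mates(res, runif(n_orig) < 0.5)
    finish_library(res, "clean", params, genome, n_dup)
  })
}

#' Simulate a long-insert (mate-pair) library
#'
#' Clean pairs read the two ends of an approximately `insert_mean` (3 kb)
#' span of a fragment and are emitted outward-facing, as produced by the
#' circularisation step of mate-pair protocols. Two construction artifacts
#' are mixed in at the configured rates: non-junction pairs (inward-facing,
#' short inserts drawn from a random interior segment of the template, which
#' lacks the biotinylated junction) and circularised short templates that
#' escaped size selection (outward-facing with inserts below 1.5 kb).
#' Chimeric source fragments propagate their same-orientation signature
#' exactly as in the short library. Fragments shorter than the requested
#' span are resampled from eligible fragments.
#'
#' @inheritParams simulate_short_library
#' @param params a [library_params()] with `library_type = "long"`.
#' @return a `wga_library`; see [simulate_short_library()].
#' @export
simulate_long_library <- function(frags, genome, params) {
  stopifnot(inherits(params, "library_params"))
  if (params$library_type != "long") stopf("params$library_type must be 'long'")
  if (nrow(frags) == 0L) stopf("empty fragment pool")
  rl <- params$read_length
  if (max(frags$length) < 2L * rl) stopf("no fragment long enough for a read pair")
  withr::with_seed(params$seed, {
    n <- params$n_pairs
    n_dup <- rbinom(1L, n, params$dup_rate)
    n_orig <- max(1L, n - n_dup)
    n_dup <- n - n_orig
    u <- runif(n_orig)
    aclass <- ifelse(u < params$nonjunction_rate, "nonjunction",
                     ifelse(u < params$nonjunction_rate + params$circular_contaminant_rate,
                            "circular_contaminant", "clean"))
    draw_span <- function(cls, m) {
      switch(cls,
        clean = as.integer(round(rnorm(m, params$insert_mean, params$insert_sd))),
        nonjunction = as.integer(round(rnorm(m, 450, 45))),
        circular_contaminant = as.integer(2L * rl + floor(runif(m) * (1500 - 2L * rl))))
    }
    S <- integer(n_orig)
    for (cls in unique(aclass)) {
      k <- aclass == cls
      S[k] <- draw_span(cls, sum(k))
    }
    frag_idx <- sample.int(nrow(frags), n_orig, replace = TRUE, prob = frags$length)
    ## resample fragment (and span) where the fragment cannot hold the span
    for (r in 1:30) {
      bad <- which(S > frags$length[frag_idx] | S < 2L * rl)
      if (!length(bad)) break
      frag_idx[bad] <- sample.int(nrow(frags), length(bad), replace = TRUE,
                                  prob = frags$length)
      for (cls in unique(aclass[bad])) {
        k <- bad[aclass[bad] == cls]
        S[k] <- draw_span(cls, length(k))
      }
    }
    S <- pmax(2L * rl, pmin(S, frags$length[frag_idx]))
    facing <- ifelse(aclass == "nonjunction", "inward", "outward")
    res <- emit_pairs(genome, frags, frag_idx, S, facing, rl, params$error_rate)
    res <- swap_mates(res, runif(n_orig) < 0.5)
    finish_library(res, aclass, params, genome, n_dup)
  })
}
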