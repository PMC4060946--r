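#' Simulate a WGA fragment population
#'
#' Draws `n` amplified fragments from the genome with start positions sampled
#' proportionally to the amplification gain track. Each fragment is one of
#' three mechanisms:
#'
#' * `normal` — an exact contiguous substring of the genome.
#' * `priming_chimera` — re-priming from a displaced 3' terminus: segment `a`
#'   is copied, a downstream stretch `b` is skipped (deleted), and segment `c`
#'   is copied in reverse complement, so the product is
#'   `genome[a] + revcomp(genome[c])` with `c` downstream of the deletion.
#' * `inverted_dup` — a fold-back product whose two ends are identical but
#'   inverted copies of the same arm: `s + loop + revcomp(s)`, where the
#'   short loop is the contiguous genomic sequence immediately downstream of
#'   the arm, so reads internal to the product map normally and only pairs
#'   bridging the fold are aberrant.
#'
#' Internally a fragment is stored as up to three ordered genome segments
#' (0-based half-open `start`, `len`, strand +1/-1); sequences are
#' materialised lazily from the genome.
#'
#' @param genome a `synthetic_genome`.
#' @param gain a `gain_track` from [amplification_gain()], or `NULL` for a
#'   uniform (unbiased) track.
#' @param n number of fragments.
#' @param frag_len_dist sampling function `f(n)` for fragment lengths in
#'   bases; default log-uniform on 1-20 kb, the size range of sheared
#'   Phi29 amplification products entering library construction.
#' @param p_priming,p_inverted_dup per-fragment chimera probabilities
#'   (`p_priming + p_inverted_dup <= 1`).
#' @param deletion_len_dist sampling function for the priming-chimera
#'   deletion length; default log-uniform 100 bp - 20 kb.
#' @param dup_arm_dist sampling function for the fold-back arm length, or
#'   `NULL` (default) to place the fold at the fragment midpoint, i.e.
#'   `arm = (fragment_length - loop) / 2`.
#' @param loop_len_dist sampling function for the short unknown loop between
#'   the two arm copies; default uniform 20-80 bp.
#' @param seed integer seed.
#' @param max_retries rounds of resampling for fragments that do not fit in
#'   the genome before erroring.
#' @return data.frame of class `wga_fragments`; one row per fragment with
#'   segment columns `s{1,2,3}_{start,len,strand}`, `mechanism`, `length`,
#'   `arm_len`, `loop_len`, `del_len`.
#' @export
simulate_fragments <- function(genome, gain = NULL, n = 5000L,
                               frag_len_dist = dist_loguniform(1000, 20000),
                               p_priming = 0, p_inverted_dup = 0,
                               deletion_len_dist = dist_loguniform(100, 20000),
                               dup_arm_dist = NULL,
                               loop_len_dist = function(n) as.integer(20 + floor(runif(n) * 61)),
                               seed = 1L, max_retries = 60L) {
  if (p_priming + p_inverted_dup > 1 + 1e-12) stopf("p_priming + p_inverted_dup must be <= 1")
  L <- genome$length
  if (is.null(gain)) {
    gain <- data.frame(start = 0L, end = L, gain = 1)
    attr(gain, "bin_size") <- L
  }
  withr::with_seed(seed, {
    u <- runif(n)
    mech <- ifelse(u < p_priming, "priming_chimera",
                   ifelse(u < p_priming + p_inverted_dup, "inverted_dup", "normal"))

    len <- pmax(50L, frag_len_dist(n))
    loop_len <- ifelse(mech == "inverted_dup", loop_len_dist(n), NA_integer_)
    if (is.null(dup_arm_dist)) {
      arm_len <- ifelse(mech == "inverted_dup",
                        pmax(50L, as.integer((len - loop_len) %/% 2L)), NA_integer_)
    } else {
      arm_len <- ifelse(mech == "inverted_dup", pmax(50L, dup_arm_dist(n)), NA_integer_)
    }
    ## fold-back products: total length follows from arm + loop
    idx_inv <- mech == "inverted_dup"
    len[idx_inv] <- 2L * arm_len[idx_inv] + loop_len[idx_inv]

    del_len <- ifelse(mech == "priming_chimera", deletion_len_dist(n), NA_integer_)
    a_len <- ifelse(mech == "priming_chimera",
                    pmax(25L, as.integer(round(runif(n, 0.3, 0.7) * len))), NA_integer_)
    a_len <- pmin(a_len, len - 25L)

    ## genomic footprint needed downstream of the start position
    footprint <- ifelse(mech == "priming_chimera", len + del_len,
                        ifelse(mech == "inverted_dup", arm_len + loop_len, len))
    if (any(footprint > L & mech == "normal")) {
      if (all(len > L)) stopf("fragments longer than the genome")
    }

    bin_w <- gain$end - gain$start
    prob <- gain$gain * bin_w
    start <- integer(n)
    todo <- rep(TRUE, n)
    for (r in seq_len(max_retries)) {
      m <- sum(todo)
      if (m == 0L) break
      b <- sample.int(nrow(gain), m, replace = TRUE, prob = prob)
      pos <- gain$start[b] + floor(runif(m) * bin_w[b])
      cand_ok <- pos + footprint[todo] <= L
      start[todo][cand_ok] <- as.integer(pos[cand_ok])
      still <- which(todo)[!cand_ok]
      todo[] <- FALSE
      todo[still] <- TRUE
      ## pending priming chimeras redraw their deletion length too
      k <- which(todo & mech == "priming_chimera")
      if (length(k)) {
        del_len[k] <- deletion_len_dist(length(k))
        footprint[k] <- len[k] + del_len[k]
      }
    }
    if (any(todo)) stopf("%d fragments could not be placed after %d retries (fragment longer than genome?)",
                         sum(todo), max_retries)

    ## segment tables (fragment order)
    s1_start <- start
    s1_len <- ifelse(mech == "priming_chimera", a_len,
                     ifelse(mech == "inverted_dup", arm_len, len))
    s1_strand <- rep(1L, n)
    s2_start <- ifelse(mech == "priming_chimera", start + a_len + del_len,
                       ifelse(mech == "inverted_dup", start + arm_len, NA_integer_))
    s2_len <- ifelse(mech == "priming_chimera", len - a_len,
                     ifelse(mech == "inverted_dup", loop_len, NA_integer_))
    s2_strand <- ifelse(mech == "priming_chimera", -1L,
                        ifelse(mech == "inverted_dup", 1L, NA_integer_))
    s3_start <- ifelse(mech == "inverted_dup", start, NA_integer_)
    s3_len <- ifelse(mech == "inverted_dup", arm_len, NA_integer_)
    s3_strand <- ifelse(mech == "inverted_dup", -1L, NA_integer_)

    out <- data.frame(id = seq_len(n), mechanism = mech, length = as.integer(len),
                      s1_start = as.integer(s1_start), s1_len = as.integer(s1_len), s1_strand = s1_strand,
                      s2_start = as.integer(s2_start), s2_len = as.integer(s2_len), s2_strand = as.integer(s2_strand),
                      s3_start = as.integer(s3_start), s3_len = as.integer(s3_len), s3_strand = as.integer(s3_strand),
                      arm_len = as.integer(arm_len), loop_len = as.integer(loop_len),
                      del_len = as.integer(del_len),
                      stringsAsFactors = FALSE)
    attr(out, "genome_name") <- genome$name
    class(out) <- c("wga_fragments", "data.frame")
    out
  })
}

seg_cum <- function(frags) {
  l1 <- frags$s1_len
  l2 <- ifelse(is.na(frags$s2_len), 0L, frags$s2_len)
  l3 <- ifelse(is.na(frags$s3_len), 0L, frags$s3_len)
  cbind(0L, l1, l1 + l2, l1 + l2 + l3)
}

## Extract the sequence of fragment rows over fragment offsets
## [off_start, off_end) (0-based half-open). Vectorised; `frags` rows are
## aligned 1:1 with the offset vectors.
fragment_subseq <- function(genome, frags, off_start, off_end) {
  cum <- seg_cum(frags)
  pieces <- matrix("", nrow = nrow(frags), ncol = 3L)
  for (k in 1:3) {
    s_start <- frags[[paste0("s", k, "_start")]]
    s_len <- frags[[paste0("s", k, "_len")]]
    s_strand <- frags[[paste0("s", k, "_strand")]]
    has <- !is.na(s_start)
    os <- pmax(off_start, cum[, k])
    oe <- pmin(off_end, cum[, k + 1L])
    ov <- has & oe > os
    if (!any(ov)) next
    ls <- os[ov] - cum[ov, k]
    le <- oe[ov] - cum[ov, k]
    fwd <- s_strand[ov] == 1L
    piece <- character(sum(ov))
    if (any(fwd)) {
      piece[fwd] <- subseq0(genome$sequence, s_start[ov][fwd] + ls[fwd],
                            s_start[ov][fwd] + le[fwd])
    }
    if (any(!fwd)) {
      piece[!fwd] <- revcomp(subseq0(genome$sequence,
                                     s_start[ov][!fwd] + s_len[ov][!fwd] - le[!fwd],
                                     s_start[ov][!fwd] + s_len[ov][!fwd] - ls[!fwd]))
    }
    pieces[ov, k] <- piece
  }
  paste0(pieces[, 1], pieces[, 2], pieces[, 3])
}

#' Materialise full fragment sequences
#'
#' @param frags a `wga_fragments` data.frame.
#' @param genome the `synthetic_genome` the fragments were drawn from.
#' @return character vector of fragment sequences.
#' @export
fragment_sequences <- function(frags, genome) {
  fragment_subseq(genome, frags, rep(0L, nrow(frags)), frags$length)
}

## Map a read occupying fragment offsets [off_start, off_end), read either in
## fragment orientation (read_reverse = FALSE) or reverse-complemented, to
## its genomic origin: the segment holding the majority of the read (ties ->
## earlier segment), mimicking an aligner that maps each read independently
## and soft-clips the minority overhang.
map_read_to_genome <- function(frags, off_start, off_end, read_reverse) {
  n <- nrow(frags)
  cum <- seg_cum(frags)
  ov <- matrix(0L, n, 3L)
  for (k in 1:3) {
    ov[, k] <- pmax(0L, pmin(off_end, cum[, k + 1L]) - pmax(off_start, cum[, k]))
    ov[is.na(ov[, k]), k] <- 0L
  }
  best <- max.col(ov, ties.method = "first")
  idx <- cbind(seq_len(n), best)
  s_start <- cbind(frags$s1_start, frags$s2_start, frags$s3_start)[idx]
  s_len <- cbind(frags$s1_len, frags$s2_len, frags$s3_len)[idx]
  s_strand <- cbind(frags$s1_strand, frags$s2_strand, frags$s3_strand)[idx]
  ls <- pmax(off_start, cum[idx]) - cum[idx]
  le <- pmin(off_end, cum[cbind(seq_len(n), best + 1L)]) - cum[idx]
  gstart <- ifelse(s_strand == 1L, s_start + ls, s_start + s_len - le)
  gend <- ifelse(s_strand == 1L, s_start + le, s_start + s_len - ls)
  strand <- s_strand * ifelse(read_reverse, -1L, 1L)
  block_s <- pmax(off_start, cum[idx])
  block_e <- pmin(off_end, cum[cbind(seq_len(n), best + 1L)])
  ## unaligned read overhangs, in fragment coordinates (low/high side); the
  ## SAM writer converts them to reference-orientation soft clips
  data.frame(gstart = as.integer(gstart), gend = as.integer(gend),
             strand = as.integer(strand),
             af = ov[idx] / (off_end - off_start),
             clip_low = as.integer(block_s - off_start),
             clip_high = as.integer(off_end - block_e),
             seg_strand = as.integer(s_strand))
}
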