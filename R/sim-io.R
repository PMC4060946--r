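#' Write library outputs to disk
#'
#' `write_library()` writes the two FASTQ mate files, a truth SAM (each
#' mate's true origin as an independent primary alignment, with custom tags
#' `XM` for the source-fragment mechanism and `XA` for the artifact class),
#' a truth TSV table, and a JSON manifest echoing all parameters and the
#' seed.
#'
#' @param lib a `wga_library`.
#' @param prefix output path prefix; files are written as
#'   `<prefix>_1.fastq`, `<prefix>_2.fastq`, `<prefix>_truth.sam`,
#'   `<prefix>_truth.tsv`, `<prefix>_manifest.json`.
#' @return named list of file paths, invisibly.
#' @export
write_library <- function(lib, prefix) {
  paths <- list(fastq1 = paste0(prefix, "_1.fastq"),
                fastq2 = paste0(prefix, "_2.fastq"),
                sam = paste0(prefix, "_truth.sam"),
                tsv = paste0(prefix, "_truth.tsv"),
                manifest = paste0(prefix, "_manifest.json"))
  write_fastq(lib$reads$pair_id, lib$reads$seq1, paths$fastq1, mate = 1L)
  write_fastq(lib$reads$pair_id, lib$reads$seq2, paths$fastq2, mate = 2L)
  write_truth_sam(lib, paths$sam)
  write.table(lib$truth, paths$tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- c(lib$params,
                list(genome_name = lib$genome_name,
                     genome_length = lib$genome_length,
                     n_pairs_emitted = nrow(lib$reads),
                     files = lapply(paths, basename)))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' @rdname write_library
#' @param ids,seqs read names and sequences.
#' @param path output file.
#' @param mate mate index appended to read names (`/1`, `/2`).
#' @export
write_fastq <- function(ids, seqs, path, mate = 1L) {
  qual <- strrep("I", nchar(seqs))
  rec <- paste0("@", ids, "/", mate, "\n", seqs, "\n+\n", qual)
  writeLines(rec, path)
  invisible(path)
}

sam_flag <- function(first, self_rev, mate_rev) {
  1L + ifelse(first, 64L, 128L) + ifelse(self_rev, 16L, 0L) + ifelse(mate_rev, 32L, 0L)
}

sam_cigar <- function(rl, clipL, clipR) {
  m <- rl - clipL - clipR
  paste0(ifelse(clipL > 0, paste0(clipL, "S"), ""),
         m, "M",
         ifelse(clipR > 0, paste0(clipR, "S"), ""))
}

#' @rdname write_library
#' @export
write_truth_sam <- function(lib, path) {
  t <- lib$truth
  rl <- lib$read_length
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", lib$genome_name, lib$genome_length),
              "@PG\tID:wgaprofiler\tPN:wgaprofiler")
  rev1 <- t$strand1 == "-"; rev2 <- t$strand2 == "-"
  span <- pmax(t$end1, t$end2) - pmin(t$start1, t$start2)
  tlen1 <- ifelse(t$start1 <= t$start2, span, -span)
  seq1 <- ifelse(rev1, revcomp(lib$reads$seq1), lib$reads$seq1)
  seq2 <- ifelse(rev2, revcomp(lib$reads$seq2), lib$reads$seq2)
  tags <- paste0("XM:Z:", t$mechanism, "\tXA:Z:", t$artifact_class)
  qual <- strrep("I", rl)
  line1 <- paste(t$pair_id, sam_flag(TRUE, rev1, rev2), t$chrom, t$start1 + 1L, 60L,
                 sam_cigar(rl, t$clipL1, t$clipR1), "=", t$start2 + 1L, tlen1,
                 seq1, qual, tags, sep = "\t")
  line2 <- paste(t$pair_id, sam_flag(FALSE, rev2, rev1), t$chrom, t$start2 + 1L, 60L,
                 sam_cigar(rl, t$clipL2, t$clipR2), "=", t$start1 + 1L, -tlen1,
                 seq2, qual, tags, sep = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(as.vector(rbind(line1, line2)), con)
  invisible(path)
}

#' Read paired alignments from SAM/BAM
#'
#' Loads primary alignments from a SAM or BAM file into the flat alignment
#' table used by the classifier. Each record keeps its mapped interval
#' (0-based half-open), strand, the fraction of the read aligned (after
#' soft clipping), the duplicate flag, and, when present, the simulator's
#' truth tags `XM` (mechanism) and `XA` (artifact class).
#'
#' @param path SAM or BAM file.
#' @return data.frame with one row per read: `read_id`, `mate`, `mapped`,
#'   `chrom`, `start`, `end`, `strand`, `aligned_fraction`, `duplicate`,
#'   `mechanism`, `artifact_class`.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth", "cigar", "strand"),
    tag = c("XM", "XA"),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  flag <- b$flag
  mapped <- bitwAnd(flag, 4L) == 0L
  cig <- b$cigar
  ref_w <- rep(NA_integer_, length(cig))
  q_al <- rep(NA_integer_, length(cig))
  ok <- !is.na(cig)
  if (any(ok)) {
    ref_w[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig[ok])
    q_al[ok] <- GenomicAlignments::cigarWidthAlongQuerySpace(cig[ok], after.soft.clipping = TRUE)
  }
  mech <- b$tag$XM
  if (is.null(mech)) mech <- rep(NA_character_, length(flag))
  acl <- b$tag$XA
  if (is.null(acl)) acl <- rep(NA_character_, length(flag))
  data.frame(
    read_id = b$qname,
    mate = ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L),
    mapped = mapped,
    chrom = as.character(b$rname),
    start = ifelse(mapped, b$pos - 1L, NA_integer_),
    end = ifelse(mapped, b$pos - 1L + ref_w, NA_integer_),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    aligned_fraction = ifelse(mapped, q_al / b$qwidth, 0),
    duplicate = bitwAnd(flag, 1024L) > 0L,
    mechanism = mech,
    artifact_class = acl,
    stringsAsFactors = FALSE)
}

#' Assemble read pairs from an alignment table
#'
#' Joins mates 1 and 2 by read name into the wide one-row-per-pair layout
#' consumed by [classify_pairs()]. Reads without a partner get an unmapped
#' placeholder mate.
#'
#' @param aln alignment data.frame from [read_alignments()].
#' @return data.frame of class `read_pairs`, one row per pair.
#' @export
pairs_from_alignments <- function(aln) {
  a1 <- aln[aln$mate == 1L, , drop = FALSE]
  a2 <- aln[aln$mate == 2L, , drop = FALSE]
  if (anyDuplicated(a1$read_id) || anyDuplicated(a2$read_id)) {
    stopf("duplicate mate records for the same read name (malformed pair)")
  }
  ids <- union(a1$read_id, a2$read_id)
  i1 <- match(ids, a1$read_id)
  i2 <- match(ids, a2$read_id)
  grab <- function(a, i, col, default) {
    v <- a[[col]][i]
    v[is.na(i)] <- default
    v
  }
  out <- data.frame(
    read_id = ids,
    mapped1 = grab(a1, i1, "mapped", FALSE),
    chrom1 = grab(a1, i1, "chrom", NA_character_),
    start1 = grab(a1, i1, "start", NA_integer_),
    end1 = grab(a1, i1, "end", NA_integer_),
    strand1 = grab(a1, i1, "strand", NA_character_),
    af1 = grab(a1, i1, "aligned_fraction", 0),
    mapped2 = grab(a2, i2, "mapped", FALSE),
    chrom2 = grab(a2, i2, "chrom", NA_character_),
    start2 = grab(a2, i2, "start", NA_integer_),
    end2 = grab(a2, i2, "end", NA_integer_),
    strand2 = grab(a2, i2, "strand", NA_character_),
    af2 = grab(a2, i2, "aligned_fraction", 0),
    duplicate = grab(a1, i1, "duplicate", FALSE) | grab(a2, i2, "duplicate", FALSE),
    mechanism = grab(a1, i1, "mechanism", NA_character_),
    stringsAsFactors = FALSE)
  class(out) <- c("read_pairs", "data.frame")
  out
}

#' Build the pair table directly from a simulated library's truth records
#'
#' Equivalent to writing the truth SAM and reading it back, without the
#' round trip: each mate's truth origin becomes its alignment.
#'
#' @param lib a `wga_library`.
#' @return a `read_pairs` data.frame (see [pairs_from_alignments()]).
#' @export
pairs_from_truth <- function(lib) {
  t <- lib$truth
  out <- data.frame(
    read_id = t$pair_id,
    mapped1 = TRUE, chrom1 = t$chrom, start1 = t$start1, end1 = t$end1,
    strand1 = t$strand1, af1 = t$af1,
    mapped2 = TRUE, chrom2 = t$chrom, start2 = t$start2, end2 = t$end2,
    strand2 = t$strand2, af2 = t$af2,
    duplicate = FALSE,
    mechanism = t$mechanism,
    artifact_class = t$artifact_class,
    stringsAsFactors = FALSE)
  class(out) <- c("read_pairs", "data.frame")
  out
}
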