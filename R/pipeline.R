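#' Configuration for an end-to-end synthetic run
#'
#' Bundles every knob of the simulate -> classify -> profile -> (optional)
#' SNP-fate pipeline. All randomness flows from the single `seed`: the
#' genome, the fragment pool and each library derive their own seeds from
#' it, so one config always reproduces one report.
#'
#' @param out_dir output directory (created if missing).
#' @param genome a [genome_spec()] (its own seed is overridden by the
#'   derived stage seed).
#' @param bias a [bias_model()].
#' @param n_fragments WGA fragment pool size.
#' @param p_priming,p_inverted_dup per-fragment chimera probabilities.
#' @param frag_len_dist,deletion_len_dist,dup_arm_dist distributions passed
#'   to [simulate_fragments()].
#' @param short,long [library_params()] for the two libraries; set either to
#'   `NULL` to skip it.
#' @param window window size for [window_stats()].
#' @param seed master seed.
#' @param stages character subset of
#'   `c("simulate", "classify", "coverage", "variants")`; later stages
#'   require earlier ones.
#' @param callsets optional named list for the variants stage:
#'   `unamp1`, `unamp2`, `amp1` (paths or `call_set`s), optionally `amp2`
#'   and `min_depth`.
#' @param write_files write FASTQ/SAM/BED/TSV stage outputs (default TRUE;
#'   the JSON report is always written).
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       genome = genome_spec(200000,
                                            tandem_repeats = list(c(50, 10, 40)),
                                            inverted_repeats = list(c(300, 50, 30))),
                       bias = bias_model(),
                       n_fragments = 5000L,
                       p_priming = 0.03, p_inverted_dup = 0.05,
                       frag_len_dist = dist_loguniform(1000, 20000),
                       deletion_len_dist = dist_loguniform(100, 20000),
                       dup_arm_dist = NULL,
                       short = library_params("short"),
                       long = library_params("long"),
                       window = 10000L, seed = 1L,
                       stages = c("simulate", "classify", "coverage"),
                       callsets = NULL, write_files = TRUE) {
  stages <- match.arg(stages, c("simulate", "classify", "coverage", "variants"),
                      several.ok = TRUE)
  structure(list(out_dir = out_dir, genome = genome, bias = bias,
                 n_fragments = as.integer(n_fragments),
                 p_priming = p_priming, p_inverted_dup = p_inverted_dup,
                 frag_len_dist = frag_len_dist,
                 deletion_len_dist = deletion_len_dist,
                 dup_arm_dist = dup_arm_dist,
                 short = short, long = long, window = as.integer(window),
                 seed = as.integer(seed), stages = stages,
                 callsets = callsets, write_files = write_files),
            class = "run_config")
}

classify_one_library <- function(lib) {
  conv <- library_convention(lib$params$library_type)
  pairs <- mark_duplicates(pairs_from_truth(lib))
  list(conv = conv, pairs = pairs,
       summary = summarize_library(pairs, conv),
       signature = chimera_signature(
         pairs, conv, read_length = lib$read_length,
         genome_length = setNames(lib$genome_length, lib$genome_name)))
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in order on a single synthetic genome:
#' simulation of the WGA fragment pool and libraries, read-pair
#' classification and chimera signatures, coverage/GC/repeat profiling,
#' and optional SNP-fate classification from supplied call sets. Writes
#' each stage's outputs under `config$out_dir` plus a consolidated JSON
#' report (`report.json`) whose numeric sections are reproducible
#' byte-for-byte for a fixed config.
#'
#' @param config a [run_config()].
#' @return the report, invisibly (a nested list mirroring `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = list(seed = config$seed,
                               stages = config$stages,
                               n_fragments = config$n_fragments,
                               p_priming = config$p_priming,
                               p_inverted_dup = config$p_inverted_dup,
                               window = config$window))
  files <- character(0)

  gspec <- config$genome
  gspec$seed <- derive_seed(config$seed, 1L)
  genome <- generate_genome(gspec)
  gain <- amplification_gain(genome, config$bias)
  frags <- simulate_fragments(genome, gain, n = config$n_fragments,
                              frag_len_dist = config$frag_len_dist,
                              p_priming = config$p_priming,
                              p_inverted_dup = config$p_inverted_dup,
                              deletion_len_dist = config$deletion_len_dist,
                              dup_arm_dist = config$dup_arm_dist,
                              seed = derive_seed(config$seed, 2L))
  libs <- list()
  if (!is.null(config$short)) {
    p <- config$short; p$seed <- derive_seed(config$seed, 3L)
    libs$short <- simulate_short_library(frags, genome, p)
  }
  if (!is.null(config$long)) {
    p <- config$long; p$seed <- derive_seed(config$seed, 4L)
    libs$long <- simulate_long_library(frags, genome, p)
  }
  if (config$write_files) {
    files <- c(files,
               fasta = write_genome_fasta(genome, file.path(config$out_dir, "genome.fasta")),
               repeats = write_repeat_bed(genome, file.path(config$out_dir, "repeats.bed")))
    for (nm in names(libs)) {
      files <- c(files, unlist(write_library(libs[[nm]], file.path(config$out_dir, nm))))
    }
  }
  report$simulate <- list(genome_length = genome$length, genome_gc = genome$gc,
                          n_repeat_features = nrow(genome$repeat_features),
                          mechanism_counts = as.list(table(frags$mechanism)))
  if (!length(intersect(config$stages, c("classify", "coverage", "variants")))) {
    return(finish_report(report, files, config))
  }

  cls <- lapply(libs, classify_one_library)
  report$classify <- lapply(cls, function(x) {
    list(summary = as.list(x$summary),
         same_orientation_fraction = x$signature$same_orientation_fraction,
         mate_overlap_fraction = x$signature$mate_overlap_fraction)
  })
  if (config$write_files) {
    for (nm in names(cls)) {
      f <- file.path(config$out_dir, paste0(nm, "_summary.tsv"))
      write.table(cls[[nm]]$summary, f, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, f)
    }
  }

  if ("coverage" %in% config$stages) {
    glen <- setNames(list(genome$length), genome$name)
    cov <- lapply(names(libs), function(nm) {
      track <- depth_from_alignments(cls[[nm]]$pairs, cls[[nm]]$conv, glen)
      wt <- window_stats(track, genome, window = config$window)
      list(track = track, windows = wt,
           evenness = evenness_curve(track),
           correlations = repeat_coverage_correlation(wt),
           gc = read_gc_distribution(cls[[nm]]$pairs, genome,
                                     read_length = libs[[nm]]$read_length))
    })
    names(cov) <- names(libs)
    report$coverage <- lapply(cov, function(x) {
      list(mean_depth = x$track$mean_depth,
           evenness_deviation = x$evenness$deviation,
           correlations = x$correlations,
           gc_shift = x$gc$shift)
    })
    if (all(c("short", "long") %in% names(cov))) {
      d <- library_gc_difference(cov$short$windows, cov$long$windows)
      report$coverage$long_minus_short_gc_rho <- d$rho
    }
    if (config$write_files) {
      for (nm in names(cov)) {
        f <- file.path(config$out_dir, paste0(nm, "_windows.tsv"))
        write.table(cov[[nm]]$windows, f, sep = "\t", quote = FALSE, row.names = FALSE)
        files <- c(files, f)
      }
    }
  }

  if ("variants" %in% config$stages && !is.null(config$callsets)) {
    cs <- lapply(config$callsets[c("unamp1", "unamp2", "amp1", "amp2")],
                 function(x) {
                   if (is.null(x) || inherits(x, "call_set")) x else read_callset(x)
                 })
    refset <- build_reference_set(cs$unamp1, cs$unamp2)
    md <- config$callsets$min_depth
    if (is.null(md)) md <- 5L
    fates <- classify_fates(refset, cs$amp1, cs$amp2, min_depth = md)
    amps <- Filter(Negate(is.null), cs[c("amp1", "amp2")])
    extra <- extra_call_fates(refset, amps, cs$unamp1, cs$unamp2)
    report$variants <- list(n_reference = as.list(fates$n_reference),
                            hom = as.list(fates$hom), het = as.list(fates$het),
                            extra_hom = as.list(extra$hom),
                            extra_het = as.list(extra$het))
    if (config$write_files) {
      f <- file.path(config$out_dir, "snp_fates.tsv")
      write_fate_table(fates, f, extra)
      files <- c(files, f)
    }
  }
  finish_report(report, files, config)
}

finish_report <- function(report, files, config) {
  path <- file.path(config$out_dir, "report.json")
  report$manifest <- list(files = sort(basename(unname(files))))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(report)
}
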