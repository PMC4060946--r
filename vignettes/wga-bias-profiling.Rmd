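---
title: "Profiling WGA biases in Illumina libraries: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling WGA biases in Illumina libraries: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Whole-genome amplification (WGA), and in particular multiple displacement
amplification (MDA) with the strand-displacing Phi29 polymerase, makes it
possible to sequence genomes from nanograms or less of input DNA. The price
is a set of characteristic artifacts in the resulting Illumina libraries:

* **chimeric amplification products**, visible after alignment as read pairs
  whose two mates map on the same strand ("wrong orientation", `→→`/`←←`);
* **uneven coverage** correlated with local tandem- and inverted-repeat
  content;
* **GC-dependent representation**, most pronounced in long-insert
  (mate-pair) libraries;
* library-construction artifacts specific to mate-pair protocols
  (non-junction pairs, circularised short templates) and PCR duplicates.

`wgaprofiler` provides (i) a truth-tracked simulator of these artifacts,
(ii) a read-pair classifier and chimera-signature report, (iii) coverage,
repeat and GC profilers, and (iv) replicate-based SNP fate classification.
Because every simulated read pair carries its true origin, every downstream
statistic can be validated against known truth without any real sequencing
data.

# Chimera mechanisms

## Re-priming chimeras

Displaced 3' termini can re-prime nearby single-stranded template. The
modelled product copies a segment *a*, skips (deletes) a downstream stretch
*b*, and continues with the reverse complement of a further segment *c*:

```
product = genome[a] + revcomp(genome[c]),   c downstream of the deletion
```

Read pairs straddling the junction map with both mates on the same strand,
separated by roughly the deletion length. The deletion length is a free
parameter (`deletion_len_dist`); the default is log-uniform between 100 bp
and 20 kb, spanning the "sometimes > 10 kb" regime, so same-orientation
pairs from this mechanism show a broad insert-size distribution.

## Inverted end-duplication (fold-back) products

The dominant chimera class in amplified libraries consists of fragments
whose two ends are identical but inverted copies of one sequence. We model
the product as

```
product = s + loop + revcomp(s)
```

where `s` is a genomic arm and the short `loop` (default 20–80 bp) is the
contiguous genomic sequence immediately downstream of the arm — so reads
internal to the product map normally and only end-bridging pairs are
aberrant.

A subtle but load-bearing modelling choice concerns shearing. A fold-back
product is physically a *hairpin*: the two arms are base-paired, with the
loop at one end. A shear cut severs both strands of the folded molecule at
one physical point, so every sheared piece that contains the loop
linearises to `u + loop + revcomp(u)` — its ends are *always* inverted
copies of each other, whatever the insert size. The simulator therefore
centres loop-covering inserts on the fold (with a few bases of end-repair
jitter, ±5 bp). The two end reads of such an insert are then identical
inverted copies, map to the same locus on the same strand, and their
start-to-start distance is ≈ 0. A naive linear-shear model cannot produce
this concentration near zero: bridging inserts would spread their mate
offsets uniformly over the insert slack. The hairpin model is what makes
the same-orientation insert distribution "peak near 0 bp" and makes the
mate-overlap fraction high, and it naturally produces the positive
relationship between insert size and chimera yield: a 3 kb span covers the
fold of a given product far more often than a 450 bp span, so the same
fragment pool yields a higher wrong-orientation fraction when read as a
mate-pair library.

# The amplification bias model

Amplification gain is modelled as a log-linear function of local sequence
features, evaluated on non-overlapping bins (`bin_size`, default 1 kb):

$$\mathrm{gain}(b) \propto \exp\{\beta_t\,t_b + \beta_i\,i_b + \beta_g\,(g_b - \bar g)\}$$

with $t_b$, $i_b$ the fraction of bin $b$ covered by tandem and inverted
repeat annotations, $g_b$ its GC fraction and $\bar g$ the genome mean. The
track is normalised to mean 1 and used as the sampling weight for fragment
start positions. The model form is deliberately simple: the observations it
must reproduce are *sign and significance* of rank correlations between
coverage and repeat/GC content, not a mechanistic MDA kinetics model.
Negative $\beta_t$, $\beta_i$ emulate Phi29-style repeat depletion; a
positive $\beta_i$ emulates the inverted-repeat *enrichment* seen with
primase-based amplification; positive $\beta_g$ emulates the GC preference
of long-insert library construction.

Because fragments are 1–20 kb while gain varies bin to bin, coverage is a
backward moving average of the gain over roughly a fragment length. Window
profiling should therefore use windows comparable to (or larger than) the
fragment scale; the bundled studies use 5 kb bins and windows against
1–20 kb fragments. Sub-fragment windows dilute, but do not invert, the
correlations.

# The synthetic genome

`generate_genome()` builds a single chromosome with:

* iid background bases at a target GC (default 0.36, a nematode-like
  composition);
* **regional GC heterogeneity**: block-wise drift of the background GC
  (default sd 0.03 per 10 kb block, centred so that the genome-wide GC hits
  the target exactly). Real genomes are not composition-white-noise; without
  regional structure, GC-bias effects on read GC would be statistically
  invisible at desk scale because a 100 bp read shares almost no composition
  signal with its 1 kb bin.
* planted **tandem repeats** (a unit repeated `copy_number` times) and
  **inverted repeats** (arm + spacer + revcomp(arm)), both drawn at the
  background composition so they do not perturb genome GC;
* **arm clustering**: a configurable fraction (default 0.8) of repeat
  features is placed in the terminal thirds of the chromosome, mimicking
  the repeat-dense autosome arms of nematode chromosomes. Clustering is
  also statistically important: it makes gain vary on regional scales that
  survive the fragment-length smearing described above.

All truth (sequence, repeat BED, fragment mechanisms, per-mate origins and
artifact classes) is retained and written alongside FASTQ/SAM outputs.

# Library simulation

Short-insert libraries shear gain-weighted fragments into ~N(450, 45) bp
inserts (truncated at the read length below and the fragment length above)
and read 100 bp inward from both ends. Long-insert libraries read outward
from the two ends of a ~N(3000, 300) bp span, as produced by
circularisation; two artifact classes are mixed in:

* **non-junction pairs** (default 2%): inward-facing, ~450 bp inserts from a
  random interior segment of the template (no biotinylated junction). These
  surface as the "innies" class of long-library QC tables.
* **circularised short templates** (default 2%): templates below the 1.5 kb
  size cut that still circularise; they keep the *correct outward* facing
  but have short inserts, so they distort the insert-size distribution
  rather than the facing statistics.

PCR duplicates (default 1% short / 5% long) are injected by re-emitting an
already-emitted pair; injection happens after artifact-class assignment and
copies the original's truth with class `pcr_duplicate`. Base-call errors
are uniform substitutions (default 0); there is no quality model, indel
model or adaptor contamination — trimming is out of scope, and truth
alignments are exact by construction.

Mate order within each pair is randomised; all classification operations
are invariant under mate swapping.

# Read-pair classification

The taxonomy (precedence order, first match wins):
`BOTH_UNMAPPED → SINGLETON → DUPLICATE → INTERCHROMOSOMAL →
SAME_ORIENTATION → WRONG_FACING → INCORRECT_INSERT → PROPER`.

Decisions worth stating explicitly:

* **Insert size.** For opposite-strand pairs, the outer span
  `max(end) − min(start)` (mates included). For same-strand pairs the outer
  span is floored at the read length and cannot represent mates that map on
  top of each other, so the **start-to-start distance** `|start1 − start2|`
  is used instead. This is the statistic under which fold-back pairs peak
  near zero; it is the single most divergence-sensitive choice in the
  classifier.
* **Aligned-fraction filter.** Mates aligned below `min_aligned_fraction`
  (0.8 short / 0.5 long, matching common alignment filtering for these
  library types) are treated as unmapped. Junction-spanning reads from
  chimeric inserts are the main casualties, becoming singletons.
* **Facing.** The leftmost mate (smaller start; ties by smaller end) on the
  `+` strand means inward; on `-`, outward. Identical intervals on opposite
  strands count as inward. Inward is proper for short libraries, outward for
  long ones; insert sizes above `max_insert` (600 bp / 100 kb) with correct
  facing are `INCORRECT_INSERT`.
* **Duplicates.** Pairs whose canonicalised mate coordinate tuples
  `(chrom, start, end, strand)` coincide are duplicates; the first pair in
  input order is retained (deterministic without quality information).
  Duplicate marking precedes the orientation classes, and duplicates are
  excluded from downstream category percentages; all percentages are
  reported relative to total reads (two per pair).

A consequence of coordinate-based duplicate marking worth knowing:
fold-centred chimera pairs from the *same* fold-back product map to nearly
identical coordinates, so at high sampling depth of a finite fragment pool
some true chimera pairs are flagged as duplicates. The recovered chimera
fraction therefore sits slightly below the truth fraction, well within
binomial uncertainty at the bundled study sizes.

# Coverage, evenness, GC

Depth counts the aligned reference bases of each mate of non-duplicate
PROPER pairs ("correctly paired read coverage"); per-base depth is
normalised by its mean, window medians by the mean of window medians (both
constants are reported). Trailing partial windows are kept and flagged;
correlations use full windows only.

The **evenness curve** is read as the empirical quantile function of
normalised per-base depth against cumulative genome fraction — constant 1
under perfectly uniform coverage — and the **deviation score** is
`mean(|normalised depth − 1|)`, zero iff depth is constant. Note the
stochastic floor: unbiased shotgun placement gives approximately Poisson
per-base depth, so at mean depth $d$ the deviation cannot fall below about
$\sqrt{2/(\pi d)}$ (≈ 0.15 at 30×; reaching 0.05 would require ≈ 255×).
Finite fragment pools add within-fragment clustering on top of that floor.
Comparative statements (biased vs unbiased at equal depth) are therefore
the meaningful use of the score; its absolute value reflects sampling as
much as amplification.

**GC profiling** measures the GC of every mapped read's *reference span*
(independent of the error model) and compares it against the theoretical
distribution of read-length windows at every genome position; the shift
statistic is the difference of means. Spearman correlations use midranks
for ties, the t-approximation for n > 30 and a seeded permutation test
otherwise.

# SNP fates

The reference SNP set is the intersection of two unamplified replicates
(identical alternate allele and zygosity), split by zygosity. Each
reference SNP's fate in the amplified replicates is, in order:
`no_low_coverage` (uncalled everywhere, depth < `min_depth` in *both*
replicates — the configurable both-replicates rule), `not_called_same`
(any discordant call, e.g. het reference called hom, or uncalled despite
adequate depth), `called_in_both_replicates`, `called_in_one_replicate`.
`min_depth` defaults to 5, the conventional minimum calling depth; with a
single amplified replicate the "both" category is `NA`. Additional calls
absent from the reference set are classified against the unamplified
replicates (`called_differently_in_both_unamplified`,
`called_in_one_replicate`).

A bundled toy threshold caller (alt fraction ≥ 0.2 → het, ≥ 0.8 → hom,
min depth 5) exists solely to demonstrate the dropout mechanism: thinning
read depth at heterozygous sites binomially pushes observed allele
fractions away from 0.5, converting het calls into hom miscalls and
uncalled-at-depth sites — the `not_called_same` rate rises monotonically
with thinning. It is not part of the analysis path.

# Study sizes and reproducibility

The bundled tests and the acceptance script run entirely on synthetic data
at desk scale, chosen so each effect is detectable with comfortable power:
200 kb genomes with 50,000 pairs for chimera-rate recovery; 20 replicate
pools of 8,000 pairs for the short/long monotonicity; 200 kb repeat-dense
genomes at 30× for evenness; 2.5 Mb genomes with 500 × 5 kb windows and 75,000 pairs for
repeat-coverage correlations; 200 kb genomes with 50,000 reads for GC
shifts; 2,000 sites for the dropout study. All randomness flows from one
master seed through `derive_seed()`, and identical configurations produce
byte-identical outputs.

```{r example}
library(wgaprofiler)
g <- generate_genome(genome_spec(200000,
                                 tandem_repeats = list(c(50, 10, 40)),
                                 inverted_repeats = list(c(300, 50, 30)),
                                 seed = 1))
gain <- amplification_gain(g, bias_model(beta_tandem = -2))
frags <- simulate_fragments(g, gain, n = 4000,
                            p_priming = 0.03, p_inverted_dup = 0.05, seed = 2)
lib <- simulate_short_library(frags, g,
                              library_params("short", n_pairs = 50000, seed = 3))
pairs <- mark_duplicates(pairs_from_truth(lib))
conv <- library_convention("short")
summarize_library(pairs, conv)
chimera_signature(pairs, conv, read_length = 100)
```

# What passing the synthetic studies does and does not show

The simulator emulates the *geometry* of WGA artifacts: chimera junction
structure, facing and insert conventions, artifact classes, repeat/GC
coupled gain. It does not emulate base-quality profiles, indels, adaptor
read-through, alignment ambiguity in repeats (truth alignments are exact),
multi-chromosome genomes, or the practically unlimited molecular diversity
of a real amplification reaction — a finite fragment pool means chimera
loci recur, so positional-uniformity statistics of same-orientation pairs
are conservative relative to real data. Passing the bundled studies shows
the statistics recover planted signals under these idealised conditions; on
real alignments the same code paths consume SAM/BAM via
`read_alignments()`, where aligner noise will loosen, but not redefine, the
signatures.

# Known limitations

* Single-chromosome synthetic genomes (the analysis code handles multiple
  chromosomes; the generator does not plant them).
* No amplicon-length decay or branching model of MDA; fragment lengths are
  a free distribution.
* Coordinate-based duplicate marking cannot distinguish genuine PCR
  duplicates from coincidentally co-mapping chimera pairs.
* The evenness deviation score has the sampling floor discussed above.
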