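---
title: "Methods: exact sequence variants from long-read amplicon sequencing"
author: "longasv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact sequence variants from long-read amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longasv)
```

## The problem

PacBio circular-consensus (CCS) sequencing reads the full ~1.5 kb 16S rRNA
gene in a single pass, with per-base error rates of a few parts in 10^4 —
low enough that roughly half of all full-length reads are entirely
error-free. At that accuracy, the statistical machinery developed for
short-read amplicon denoising can resolve *exact* amplicon sequence
variants (ASVs): the true biological sequences, to single-nucleotide
resolution, rather than 97%-identity OTU clusters. Single-nucleotide
resolution over the whole gene exposes *intragenomic* variation — bacterial
genomes carry 1–15 copies of the rrn operon, and copies may differ — which
is both a nuisance (one strain yields several ASVs) and an opportunity
(the full complement of a strain's alleles, with their integral copy-number
ratios, supports classification below the species level).

`longasv` implements this pipeline end to end: primer handling and
filtering for mixed-orientation CCS reads, a quality-conditioned error
model, divisive-partitioning denoising, chimera removal tuned for
multi-copy genes, mock-community evaluation analytics, strain-level allele
binning with consensus classification, and a closed-loop synthetic read
generator.

## The error model

The model is a transition-rate array \(p(\mathrm{observed\ base} \mid
\mathrm{true\ base}, q)\) over the 4×4 base pairs and quality scores
\(q \in [0, 93]\). Two assumptions carry the inference:

* the relationship between quality score and error likelihood is the same
  at every position in a read (so all positions can be pooled), and
* errors are independent between reads once quality and composition are
  accounted for.

Estimation (`estimateRates`) proceeds per error transition. For \(q \le
92\), the raw rates (error count plus a pseudocount of 1, over total
observations at that quality) are smoothed on the log10 scale by a
tricube-weighted local linear regression in \(q\), with weights further
multiplied by the number of observations at each quality and a window
spanning half the observed quality range. A pool-adjacent-violators
(isotonic) pass then enforces that modeled error rates never *increase*
with quality, and rates are floored at 10^-7 (so that long error-free
alignments keep finite log-likelihoods) and capped at 0.25. The maximum
quality score is treated separately: CCS instruments emit a large point
mass at \(q = 93\) whose empirical error rate does not extrapolate from
the rest of the distribution, so the \(q = 93\) entry is the plain
pseudocounted ratio computed from \(q = 93\) observations only. Rows are
normalized to sum to one over observed bases. Insertions and deletions
have no usable quality structure (deletions carry no quality score at
all), so a single quality-independent indel rate — total indel columns
over total aligned bases, pseudocounted — accompanies the matrix.

Because the true sequences are unknown, `learnErrors` alternates: denoise
with the current model, re-align every dereplicated sequence to its
inferred partition center, re-tally transitions over all member reads with
their own per-base qualities, re-estimate. The loop starts from a
maximally pessimistic quality-independent model (2.5×10^-3 per transition)
and stops when the largest absolute change in log10 rate drops below 0.05
(or after 10 rounds); on simulated data two to three rounds suffice. Reads
that no inferred variant can explain are excluded from the tallies — such
reads are dominated by chimeras, and training on them would inflate the
rates.

## Denoising by divisive partitioning

Reads are dereplicated into unique sequences with abundances and
position-wise mean quality profiles. All uniques start in one partition
centered on the most abundant sequence. For a member \(m\) of a partition
with center \(c\), \(\lambda_{m}\) is the probability under the error
model of reading \(c\) as exactly \(m\): the product over alignment
columns of \(p(m_i \mid c_i, q_i)\), with indel columns contributing the
indel rate. With \(\mu = n_c \lambda\) (where \(n_c\) is the partition's
read total), the abundance p-value
\[
p_A = P(X \ge a \mid X \ge 1), \qquad X \sim \mathrm{Poisson}(\mu)
\]
asks whether a sequence seen \(a\) times is observed too often to be an
error mosaic of its center. The smallest Bonferroni-corrected \(p_A\)
across all partitions is compared against `omegaA` (default 10^-40);
significant members are promoted to new partition centers, everything is
reassigned to its maximum-\(\lambda\) center, and the loop repeats until
no member is significant. ASVs are the partition centers — verbatim
observed sequences — with partition read totals as abundances.

Pairwise comparison over thousands of 1.5 kb uniques is the hot path, so
it is staged: a kmer prefilter (k = 8) computes the kmer distance from
sorted kmer arrays and skips pairs above `kdistCutoff` (0.42); when the
in-sequence-order kmer overlap equals the multiset overlap, the ungapped
positional alignment is provably consistent and used directly; otherwise a
banded Needleman–Wunsch alignment (band 32, match +5 / mismatch −4 /
gap −8, end gaps penalized, deterministic diagonal-up-left tie-breaking)
is computed in C++.

Three behaviors are worth stating precisely:

* **Singletons are never promoted**: \(p_A = 1\) when \(a = 1\) by
  construction, so an ASV always has independent read support.
* **Unexplainable uniques**: when \(\lambda = 0\) against every center
  (beyond the kmer screen for all of them), the Poisson conditional limit
  gives \(p_A \to 0\) for \(a \ge 2\), so repeated far sequences are
  promoted — this is how genuinely novel variants and abundant chimeras
  surface. Unexplainable *singletons*, however, are set aside and reported
  as `unassigned` rather than silently attributed to the most abundant
  partition. This is a deliberate departure from the usual convention:
  arbitrary attribution of unexplainable reads (mostly one-off chimeras)
  inflates the largest ASV's abundance and corrupts the integral
  copy-ratio structure on which downstream accuracy assessment rests.
  Conservation therefore reads: assigned + unassigned = input reads.
* **Sensitivity floor**: a true variant is detected only when its
  abundance makes \(p_A\) significant; a variant seen twice that is a few
  substitutions from a large partition cannot reach 10^-40. This matches
  the expected behavior of this class of method (rare strains in a staggered community
  are missed, not mis-reported).

## Chimera removal for multi-copy genes

A candidate is a *bimera* if some ordered pair of sufficiently abundant
pool members reconstructs it exactly as a one-crossover mosaic: an
error-free candidate prefix with respect to parent A and an error-free
suffix with respect to parent B that together cover it, while neither
parent matches it exactly. Prefix/suffix extents are computed from plain
longest-common-prefix/suffix (mosaic segments are anchored at the read
ends) with banded-alignment extents (band 16) as a fallback for shifted
segments. The crucial parameter is `minFold = 3.5`: only pool members at
least 3.5× more abundant than the candidate qualify as parents.
Intragenomic alleles appear at small integral abundance ratios (1:1 to
~3:1) to their same-genome siblings, so a smaller fold would explain
genuine minor alleles away as chimeras of their more abundant siblings;
3.5 sits above the common 3:1 allele ratio yet far below the
parent/chimera abundance gap of real PCR chimeras. Across samples, an ASV
is removed only when flagged in a strict majority of the samples in which
it occurs.

## Strain binning and full-complement classification

Within a taxonomic group, `binStrains` searches candidate genome units
\(g\) (each ASV abundance divided by 1..copy number) for a partition of
the ASVs into bins in which every member's abundance/\(g\) lies within
±0.2 of an integer copy number and the bin's copies sum to the known copy
number. In practice such binning has been done by hand; automating it requires
an explicit objective, and the obvious one — minimize total deviation —
is degenerate on noisy data (any ASV alone, assigned the full copy
number, has deviation 0). `longasv` therefore uses lexicographic
parsimony: fewest unbinned ASVs, then fewest bins, then smallest total
deviation. Distinct strains separate naturally when their abundance scales
differ by more than the tolerance, because no single genome unit can
satisfy both; two strains at the *same* scale merge, which is a stated
limitation (hand analyses disambiguate such cases by taxonomy
first).

`consensusClassify` implements full-complement classification over
precomputed best-hit tables: tabulate how often each database accession is
a best hit across the strain's ASVs, keep the accessions with the maximal
count, and read the metadata field of interest across them, ignoring
missing entries — unanimity classifies, conflict is reported as
ambiguous. Executing the database search itself is out of scope (results
against a live nt change daily and are irreproducible); the hit table is
ingested as TSV. `extractSubregion` extracts V3V4/V4V5 sub-regions with
the standard Illumina (341F/805R) and JGI (515F/926R) primer pairs for
comparison against short-read resolution.

## The synthetic community generator

`simulateReads` emulates the data-generating process the pipeline is built
for, with every deviation from reality stated:

* **Templates**: per strain, allele 1 is a random backbone
  (1400–1500 nt) and each further allele carries 4 substitutions at
  positions disjoint from its siblings' (within-strain alleles differ by
  4–8 substitutions; real rrn alleles differ by 1 to tens). Backbones are
  independent across strains (~25% identity), so the generator does not
  reproduce the near-identical inter-species pairs (e.g. congeneric
  staphylococci) of real communities — passing tests show single-strain
  allele resolution, not discrimination of 99%-identical species.
* **Abundances**: allele sampling weight = genome proportion × copy
  number. The bundled `zymoLikeSpec` has 8 strains with copy numbers
  4, 7, 7, 5, 4, 6, 6, 10 (29 alleles; the E. coli analogue at copies
  3:1:1:1:1, the B. subtilis analogue one allele × 10) in equimolar genome
  proportions; `hmpLikeSpec` has 20 strains with the staggered design's
  copy numbers and genome proportions log-spaced over three orders of
  magnitude.
* **Errors**: substitutions 1.1×10^-4, insertions 2.2×10^-4, deletions
  1.0×10^-4 per base — the rates measured for CCS full-length 16S reads.
  90% of bases draw quality 93, the rest uniform 30–92; the per-base
  substitution probability scales as \(10^{-q/30}\), normalized so the
  marginal rate equals the configured value (the real joint distribution
  of quality and error is only partially characterized; this choice makes
  quality-conditional rates monotone, which is all the denoiser assumes).
  Inserted bases carry their own drawn quality; deletions carry none.
  Homopolymer-targeted error enrichment is not modeled: the 16S gene is
  nearly devoid of long homopolymers.
* **Artifacts**: 2% of reads are one-crossover mosaics of two
  abundance-weighted templates (crossover uniform in the 20–80% span);
  half of all reads are emitted reverse-complemented; concrete
  realizations of the degenerate 27F/1492R primers are attached.

Everything is driven by one integer seed; the same seed yields
byte-identical FASTQ.

## Numerical and scale choices

* Alignment scoring (+5/−4/−8, no gap extension) keeps the banded DP
  exact and integer-valued; tie-breaking (diagonal, then gap-in-member,
  then gap-in-center) makes inference byte-deterministic.
* The abundance p-value is computed as
  `ppois(a - 1, mu, lower.tail = FALSE) / -expm1(-mu)`, stable in the
  \(\mu \ll 1\) regime where promotions are decided.
* `omegaA = 1e-40` with Bonferroni correction by the number of uniques is
  deliberately extreme: promotions should be driven by overwhelming
  abundance evidence, and every promotion is irreversible within a run.
* Validation runs use 10,000 reads (even community) and 20,000 reads
  (staggered community); at 10,000 reads each Zymo-like allele receives
  ~204 reads per copy, so allele copy-ratio estimates carry multinomial
  noise with deviation sd ≈ 0.07–0.1 per multi-copy allele. The maximum
  deviation across 29 ASVs therefore sits near the 0.2 integral-ratio
  tolerance at this depth; at the ~69,000-read depth of a full sequencing
  cell the same noise is ~√7 smaller.
* Degenerate inputs: empty FASTQ files yield empty read sets; empty
  chimera pools yield a non-chimera verdict; `omegaA = 0` disables all
  promotions (one partition); rarefaction refuses depths above the total.

## Known limitations

* Per-sample inference only: no pooling or prior sharing across samples.
* The error model is global per run, not position- or context-dependent
  (by assumption), and quality re-calibration is out of scope.
* Strain bins at identical abundance scales merge; cross-sample joint
  binning is not implemented.
* The chimera stage models single-crossover bimeras only, mirroring the
  standard de novo per-sequence test; multimeras pass undetected.
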