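---
title: "Calling productive translation from ribosome profiling"
author: "ribocall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling productive translation from ribosome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribocall)
```

## The problem

Ribosome profiling (Ribo-Seq) sequences the ~26–36 nt mRNA fragments that
ribosomes protect from nuclease digestion. Ribosomal occupancy alone,
however, does not prove that an ORF is productively translated: scanning
subunits, overlapping frames and regulatory stalling all leave footprints.
The hallmark of productive elongation is *framing* — a 3-nucleotide
periodicity of footprint 5′ ends locked to the codon register of the ORF
being decoded. `ribocall` implements a complete calling pipeline around
that signal for developmental (multi-stage, replicated) experiments, with
three ORF classes in view: canonical ORFs (annotated CDS > 100 codons),
short CDSs (≤ 100 codons from independent loci), and AUG-start uORFs in 5′
leaders.

## The model

**Framing as a coin toss.** Each footprint is the product of an
independent mRNA–ribosome interaction, so under the null of no
periodicity its 5′ end falls in any of the three frame classes with
probability 1/3. For an ORF with $n$ mapped footprints of the dominant
length, of which $x$ match the dominant frame, the translation evidence is
the binomial upper tail

$$p = P(X \ge x), \quad X \sim \mathrm{Binomial}(n, 1/3),$$

evaluated as `pbinom(x - 1, n, 1/3, lower.tail = FALSE)`. With every read
in frame, $p = (1/3)^n$: five reads suffice for $p < 0.01$, and with one
read out of frame seven are needed. No P-site offset is applied: the
dominant frame is learned empirically per sample from the metagene
profile (the most abundant read length, then its most overrepresented
frame class), so any constant offset between the 5′ end and the decoded
codon cancels.

**The decision ladder.** Per ORF and per stage:

1. *transcribed*: RNA-Seq RPKM > 1 in at least one of the replicates;
2. *ribosome-bound*: footprint RPKM > 1 in **every** replicate
   (reproducible binding), given 1;
3. *translated*: binomial framing $p < 0.01$ on the replicate-merged
   footprints, given 2.

RPKM is reads per kilobase of ORF per million genome-aligned reads of the
library; footprint counting takes 26–36 nt reads overlapping the ORF by at
least 1 nt (a read overlapping two ORFs counts for both — the framing
test, computed against each ORF's own register, attributes translation to
the right one). Thresholds are strict inequalities. ORFs translated at
every stage are *constitutive*, at some but not all *stage-specific*.

**Translational regulation.** TE = RPKM^FP^ / RPKM^RNA^ per ORF and
stage (undefined where the RNA density is zero). Between contiguous
stages, TE values are standardized per sample
($Z = (\mathrm{TE} - \overline{\mathrm{TE}})/\mathrm{SD}$) over the ORFs
with defined TE in both stages, separately per ORF class so the very
different TE scales of uORFs and canonical ORFs are not mixed; the
per-ORF change is standardized again over all compared ORFs
($Z\text{-ratio} = (Z_B - Z_A)/\mathrm{SD}(Z_B - Z_A)$), and
$|Z\text{-ratio}| \ge 1.5$ (both bounds inclusive) flags regulation.
This is a relative outlier test: what is flagged is a TE change that
stands out against the distribution of all changes, not an absolute
effect size.

**Sequence features.** Start-codon context is scored with a
position-specific log-odds table over positions −5…−1 and +4…+6 (the AUG
itself is excluded; there is no position 0): per position,
$\log_2(\text{observed}/\text{background})$ with a pseudocount of 1 per
cell, summed over the observed nucleotides of a query context. The table
is trained on canonical start contexts — the bona fide initiation sites —
and the background defaults to the pooled nucleotide composition of the
training windows (uniform 0.25 is available); pooled was chosen so that a
position's score measures *positional* enrichment rather than overall
base composition. Peptide-level features are the pooled amino-acid
composition and an in-silico digest cleaving after every K and R
(no proline exception by default; a `skip_proline` flag exists), counting
fragments of 7–24 AA as detectable by mass spectrometry.

## The ORF catalog

Annotated CDSs longer than 303 nt (100 codons plus the stop, following
the CDS-includes-stop convention) are canonical; CDSs of at most 303 nt
are short CDSs only when no isoform of their gene is canonical — short
isoforms of canonical loci are discarded. uORF candidates are AUG-start
ORFs in annotated 5′ leaders whose first in-frame stop lies fully inside
the leader and which encode more than 10 AA beyond the initiator
methionine (strictly more; an AUG followed by exactly 10 sense codons is
rejected). Filters, in order: class-wise deduplication on the exact
genome-space CDS coordinates (deterministic survivor: smallest
identifier); removal of uORFs overlapping any annotated CDS in genome
space; removal of uORFs fully included in frame within a longer uORF
(out-of-frame overlaps are kept, each tested against its own register);
finally, annotated CDSs fully contained within another isoform's leader —
dicistronic arrangements — are added to the uORF set. Internally all
coordinates are 0-based half-open; GFF3 I/O is 1-based inclusive. The
genome-space frame comparison uses the 5′-most genomic base as anchor,
which is exact for single-exon transcripts and for multi-exon pairs whose
overlap is intron-free.

## The synthetic data generator

`simulate_ribodata()` emulates the statistical structure the pipeline
assumes, not raw sequencing: three stages × two replicates; footprint
lengths on 26–36 nt with the mode at 32 nt and 3% of reads just outside
the window (so ~97% fall in range); RNA-Seq reads placed uniformly along
transcribed transcripts; footprints placed on codon slots of bound or
translated ORFs with expected counts proportional to
TE × abundance × length; and 5′-end frame classes drawn with probability
0.6 for the dominant frame in translated ORFs (matching the ~56–64%
in-frame fraction observed for 32-nt footprints in real libraries) versus
exactly 1/3 — no periodicity — in bound-only ORFs. Transcript abundances
are lognormal (σ~log~ = 0.75), baseline TE lognormal (σ~log~ = 0.4), and
per-stage expression states are drawn from configurable probabilities
with the ladder (translated ⇒ bound ⇒ transcribed) enforced by
construction; uORF states are conditioned on host-transcript
transcription.

Leader sequences use a deliberate trick: outside the designed uORF
motifs, leaders are drawn from the {A, C, G} alphabet. Without T, no AUG
and no stop codon can arise by chance, so the designed uORFs are
*provably* the complete uORF content of every leader and catalog
round-trip tests can demand exact recovery — including the adversarial
cases the generator plants (in-frame nested uORFs, out-of-frame
overlapping pairs, dicistronic second CDSs, short in-frame isoforms).
The price is an unrealistic leader base composition; consequences are
discussed under limitations. Reads are placed only within ORFs (RNA-Seq:
within transcripts); there is no intergenic noise, no sequencing error,
no rRNA contamination, and no splice-aware read placement (read records
live in transcript space). The one-frame shift of terminating ribosomes
at stop codons seen in real metagene profiles is not simulated. All
randomness is seeded; identical configurations reproduce byte-identical
fixtures.

## Numerical and design choices

* Binomial tails come from `pbinom`, which is exact for these sample
  sizes; the test suite cross-checks every (x, n) with n ≤ 12 against
  direct enumeration of the pmf at 10^−12^ tolerance.
* Dominant length/frame ties break toward the smaller length and frame
  index, with a warning; per-ORF framing counts use only dominant-length
  reads whose 5′ end lies inside the ORF body, while the metagene window
  (−18/+15 nt, both multiples of 3, so frame classes are preserved) is
  used only to learn the global pattern.
* An ORF with zero dominant-length reads has an undefined framing p and
  can never be called translated; it can still be bound.
* Framing p-values are not multiplicity-corrected; the fixed 0.01 cutoff
  is part of the method's definition and is configurable.
* Z-scores use the sample SD; classes or stage pairs with fewer than two
  ORFs with defined TE in both stages are skipped, and a zero SD
  (constant TE, or identical Z-vectors) is an error rather than a silent
  NaN.
* RPKM-based TE is defined only up to a per-stage scale: expected counts
  are shares of a library total, so a strong TE shift in one ORF slightly
  deflates every other ORF's share. Tests therefore check TE recovery on
  scale-normalized ratios, and the Z-ratio (being standardized twice) is
  unaffected.
* With more than two replicates, transcription generalizes to "any
  replicate passes" and binding to "all replicates pass", the
  conservative extension of the printed two-replicate rule.
* Missing replicates are an error, not an imputation: the
  reproducibility filter is undefined without them.

## Problem sizes used in the tests

The suite runs entirely on generated data: a shared simulation of 23
genes (~0.7 M reads across 12 libraries), calibration cohorts of 2,000
ORFs at fidelity 1/3 and 400 at 0.6 with 2 × 50 dominant-length reads per
ORF (replicates merged, so each binomial test sees n = 100), a catalog
round-trip over a 14-gene composition carrying every filter case, and a
200-ORF two-stage TE cohort with 10% of ORFs shifted by 3–5 sample-SDs.
Down-shifted ORFs are drawn from those with enough baseline TE to lose
3 SDs — TE is non-negative, so a low-TE ORF cannot be shifted down that
far; biologically these are the strongly translated messages that
repression acts on.

## What passing tests do and do not show

The generator reproduces the *statistical* structure the method relies
on (frame fidelities, length distribution, state ladder, TE scales), so
the tests demonstrate internal correctness and calibration: the type-I
rate of the framing test at its analytic value, ≥ 95% power at the
in-frame fraction real libraries show with adequate coverage, exact catalog
recovery, and directionally correct Z-ratio calls for large TE shifts.
They do not demonstrate robustness to what real libraries add: mapping
ambiguity, nuclease bias, leader annotation errors, rRNA contamination,
stop-codon frame shifts, or non-AUG initiation (out of scope throughout:
only AUG-start ORFs are considered). Percentages reported for real
embryonic data in the literature depend on those factors and on the full
genome annotation, and are not expected from synthetic runs.

## Known limitations

* Multi-exon support is complete for sequence assembly and coordinate
  mapping, but the in-frame-nesting and frame-anchor comparisons are
  exact only when the compared ORFs' overlap contains no intron.
* T-free leader backgrounds make synthetic leaders compositionally
  unrealistic; Kozak-score distributions from synthetic data should not
  be compared with real ones.
* The RPKM normalizer is the library's genome-aligned total, as the
  method defines; no TPM-style or bias-corrected variant is provided.
* lncRNA ORFs and ORFs overlapping annotated CDSs are outside the
  catalog by design.
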