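---
title: "Detecting ribosome stalling on plastid ORFs with ribostall"
author: "ribostall authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ribosome stalling on plastid ORFs with ribostall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribostall)
```

## The model

Ribosome profiling sequences the ~28–36 nt mRNA fragments protected by
translating ribosomes. Each footprint is evidence that a ribosome
occupied one codon; the genomic position of the footprint's 5′ end,
plus a fixed P-site offset, localizes that codon. `ribostall` treats a
chloroplast Ribo-seq experiment as a collection of such intervals per
sample and asks two questions:

1. **How much is each plastid ORF translated?** Counts are summarized
   as cpRPKM — reads per kilobase of ORF per million reads mapped to
   all chloroplast ORFs. Restricting the per-million denominator to
   chloroplast ORFs makes the measure insensitive to the (large,
   variable) fraction of reads from elsewhere. The statistic for
   genotype comparisons is the per-replicate log2 ratio of mutant
   cpRPKM to the WT reference, reported as mean ± sample SD
   (n − 1 denominator; three biological replicates is the expected
   design).

2. **Where along an ORF do ribosomes pause, and does a mutant pause
   more?** Per-gene coverage profiles are normalized by total gene
   reads, so each sample contributes a *density* over the ORF summing
   to 1. Pauses appear as peaks in this density. The mutant/WT
   relative peak height then measures redistribution of ribosomes
   along the message, independent of how many ribosomes the message
   carries — a gene can be twice as ribosome-loaded overall and still
   show a 1.3-fold *relative* increase only at one pause.

### Assumptions

* Footprint 5′ ends are assigned to exactly one ORF (same strand,
  half-open containment). Where plastid operons overlap, the ORF whose
  start codon is nearest upstream wins, with lexicographic gene order
  as the final tie-break; ambiguous assignments are counted and
  reported. Reads whose 5′ end falls outside every ORF are counted as
  unassigned and excluded from the cpRPKM denominator — the
  "per million" is per million *ORF-assigned* reads.
* ORFs are single intervals on a linear sequence. Spliced ORFs must be
  supplied pre-spliced; ORFs wrapping a circular origin are rejected.
* Codon-level operations (periodicity, peak calling) require triplet
  ORF lengths; non-triplet records are kept but flagged, and refused by
  those operations.

## Peak calling

Normalized density is aggregated to codons (sum of the 3 nt) before
peak detection — footprint 5′ ends have a strong 3-nt periodicity, so
nucleotide-level maxima would be frame artifacts. The codon density is
smoothed by a centered moving average (window `smooth_codons`, default
3, truncated at the edges); candidate peaks are plateau-aware local
maxima whose topographic prominence is at least `min_prominence_frac`
(default 0.25) of the smoothed global maximum; candidates closer than
`min_sep_codons` (default 9) are merged keeping the higher (ties: the
5′-most); at most `top_k` (default 6) peaks survive, and survivors are
labelled with roman numerals in 5′→3′ order. A flat profile has no
peaks (not an error). The defaults were chosen so the simulator's
psbB-like fixture with five pause regions yields exactly five major
peaks; all four values are configuration keys and are stamped into
output metadata.

Peaks are *defined* on the pooled-WT density and *measured* per sample:
each replicate's height is the maximum smoothed codon density within
`match_window` (default ±1 codon) of the peak codon. A common peak
definition is what makes "the fifth peak" comparable across genotypes;
the window absorbs sub-codon jitter between samples. The WT reference
is the mean height over WT replicates (`ratio_mode = "mean_ref"`;
`"paired"` divides replicate by replicate instead — the mean reference
is the default because the experimental design implies no pairing).

### Numerical choices

* The moving average uses direct window sums, not cumulative-sum
  differences, so exact ties in the input remain exact ties — plateau
  handling (the 5′-most codon of a flat top is the peak) depends on
  this.
* Prominence follows the standard topographic definition: on each side
  of a candidate, walk to the nearest strictly higher point (or the
  profile edge); the side's base is the minimum in between; prominence
  is the height above the higher base.
* A gene with zero assigned reads in a sample cannot be normalized;
  `normalize_profile()` errors, and the genome-wide scan excludes such
  genes with a recorded reason rather than silently dropping them (the
  default `min_reads = 200` filter removes them earlier anyway — the
  same raw-count threshold used for cpRPKM ratio exclusions).

## The synthetic generator

The generator emulates the structure of a three-genotype × three-
replicate chloroplast experiment so that every stage of the pipeline
can be tested against known ground truth:

* **Layout** — genes on alternating strands separated by 50-nt
  spacers; the default annotation has a 508-codon psbB-like gene (the
  scale of CP47) flanked by 100- and 80-codon genes.
* **Counts** — per gene and sample, Poisson with mean `depth_per_gene`
  (default 50 000, giving per-codon baselines of ~100 counts on the
  psbB-like gene — deep enough that peak calling is limited by biology,
  not shot noise, while the full suite runs in seconds).
* **Pauses** — multiplicative stall factors on codon sampling weights,
  applied *before* per-gene normalization. A stall therefore slightly
  depresses density everywhere else, exactly as real per-gene
  normalization does: an injected multiplier *m* at a window holding a
  baseline density share *d₀* is recovered not as *m* but as
  *m*/(1 + (*m* − 1)·*d₀*). The recovery tests check against this
  corrected truth, which keeps them honest about the normalization
  artifact. The default psbB-like architecture uses five 3-codon pause
  regions (centres 8, 120, 210, 265, 480; multipliers 6, 4, 4, 4, 5) —
  an initiation pause plus pauses at TMD-emergence positions — with
  mutant-specific extra factors 1.31 (*fpb1*) and 1.42 (*pam68*) on
  the fifth region. Pause regions span three codons so that
  region-level stalling survives the default 3-codon smoothing.
* **Replicate noise** — each multiplier is perturbed once per
  replicate by mean-1 lognormal noise with CV `replicate_noise_cv`
  (default 0.05). Multiplicative noise on multipliers, rather than
  additive noise on counts, is what produces the replicate-to-replicate
  ratio spread that the mean ± SD statistic summarizes.
* **Geometry** — the 5′ end sits `psite_offset` (default 12) nt
  upstream of the sampled codon, the conventional offset for ~31-nt
  plant footprints; with probability `1 − frame_fidelity` (default
  fidelity 0.9) it is shifted ±1 nt equiprobably. Lengths are drawn
  from a distribution over 28–36 nt with mode 0.25 at 32 nt, matching
  the 31–33 nt peak of real libraries. Seeding is a deterministic
  integer function of (seed, genotype, replicate), so any sample can
  be regenerated independently.

What the generator does **not** emulate: sequence-dependent biases
(ligation, nuclease), rRNA contamination, UTR and non-coding coverage,
inter-gene depth differences, and codon-specific dwell times. Passing
tests therefore demonstrate the pipeline's correctness and calibration
under idealized coverage, not robustness to every artifact of real
libraries.

## Measuring a known stall

When the stall position is known exactly (as in simulation recovery
tests), heights are measured at that codon with `match_window = 0` and
`smooth_codons = 1`: the ±1-codon window exists to absorb positional
jitter when peaks are *estimated*, and taking a windowed maximum over
noisy WT profiles would bias the reference upward; likewise smoothing
would dilute a single-codon spike three-fold relative to the
renormalization-corrected truth above. For peaks found by the caller
on pooled WT — the real use case — the defaults apply.

With the default P-site offset, raw 5′-end profiles place peaks four
codons upstream of the paused P-site (a 12-nt shift); the scan reports
codons in whichever space `profile_offset` selects (0 = raw 5′ ends,
12 = P-site codons). Tunnel mapping (`map_peak_to_tunnel`) subtracts
`tunnel_len_codons` (default 33, configurable 30–40; structural
estimates of the exit tunnel span roughly 30–40 residues) from the
P-site codon and, given a TMD table, labels the emerging feature. The
shipped `cp47_tmd_synthetic.tsv` is a synthetic topology (six TMDs, a
192-residue lumenal loop between TMD V and VI) at the documented scale
of CP47, not measured coordinates.

## Problem sizes used by the test suite

Simulation-backed checks run at depths of 10⁴–10⁵ footprints per gene:
large enough that binomial noise on frame fractions (±0.1%) and on
peak heights (~3%) sits well inside the asserted tolerances, small
enough that the whole suite completes in about two minutes. Stall
recovery uses 20 seeds × (3 WT + 3 mutant) replicates at depth
5 × 10⁴ for multipliers 1.5, 2 and 3; null calibration relabels three
of six WT replicates as a pseudo-mutant and requires every scan ratio
to stay within [0.7, 1.4] in ≥95% of seeds. Oracle checks (assignment,
peak calling) compare against brute-force reimplementations on 200
randomized instances each.

## Known limitations

* No significance testing of pause differences — the statistic is a
  replicate mean ± SD, matching how such comparisons are usually
  reported; formal inference would need a variance model for
  normalized peak heights.
* The ratio is undefined where WT lacks the peak (zero reference);
  such cases error rather than report infinity.
* cpRPKM compares the same gene across samples; cross-gene comparisons
  inherit RPKM's usual length and composition caveats.
* Peak labels are per-dataset: removing a 5′ peak renumbers the ones
  downstream, so labels should be compared only between runs with
  identical parameters.
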