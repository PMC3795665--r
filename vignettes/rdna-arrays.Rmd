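---
title: "Copy number and intragenomic variation in rDNA repeat arrays"
author: "rdnarray authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy number and intragenomic variation in rDNA repeat arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnarray)
```

## The problem

Eukaryotic ribosomal RNA genes sit in tandem repeat arrays: each unit
carries the conserved 18S, 5.8S and 26S/28S genes plus rapidly evolving
transcribed and intergenic spacers (ITS, ETS, IGS). Concerted evolution
homogenizes copies within a genome, so a species typically has one dominant
repeat variant plus many low-frequency site variants. Both the number of
copies and the amount of within-genome variation matter directly for
rRNA-based biodiversity surveys (a species' read count scales with its copy
number) and for understanding how selection acts on the locus.

`rdnarray` analyses these arrays from ordinary whole-genome shotgun data
mapped to a single repeat unit. Its five analysis stages are: copy-number
estimation, consensus construction, intragenomic polymorphism calling,
interspecific divergence classification, and a mutational-variance test for
purifying selection. A truth-tracked simulator generates arrays, read sets
and mutation-accumulation (MA) series so every stage can be validated
end-to-end without any external download.

## Copy-number estimation

The estimator is a coverage quotient. With $D$ the genome-wide fold
coverage (total sequenced bases / genome size) and $\bar{c}$ the mean fold
coverage of the repeat unit (total bases aligned to the unit / unit length
$L$), the array copy number is

$$\hat{C} = \bar{c} / D.$$

Coverage certainly varies across individual repeat units, so $\hat{C}$ is
an average over the whole array; no per-unit deconvolution is attempted.
Two reporting conventions matter in practice:

* `estimate_copies()` keeps the **unrounded** mean coverage internally.
  Rounding the intermediate can shift a final integer estimate by one unit,
  so displayed coverages are rounded only for reporting.
* Per-generation expansion rates for MA lines
  (`expansion_rate()`) are by default computed from the **rounded**
  reported estimates — integer precision for low-depth long-read datasets,
  one decimal for high-depth short-read datasets — which makes reported
  rate tables exactly reproducible. Pass unrounded estimates for the
  alternative convention.

`coverage_uniformity()` checks whether each annotated gene region's mean
depth lies within one standard deviation of the whole-repeat mean (the SD
is the population SD over per-position depths; the granularity of the SD
was a free choice and is documented here). A region outside that band
suggests a sub-repeat duplication or deletion rather than whole-unit
copy-number change.

`bootstrap_copy_number()` attaches a percentile interval by resampling
reads (mapped and unmapped alike) with replacement, capturing the binomial
sampling of reads into the array. Resampling only the mapped reads would
produce a spuriously tight interval, since every mapped read contributes a
nearly constant number of aligned bases.

## Alignment ingestion and the internal mapper

The analyses are downstream of alignment, so alignment itself is
deliberately commodity. Two routes produce the per-position base tallies
(`rdna_pileup`):

* `pileup_from_sam()` ingests plain-text SAM (mandatory fields; CIGAR
  `M/=/X/I/D/N/S/H/P`). Read identity is matches / aligned columns, where
  deletion columns count as aligned and insertions do not. Reads below the
  identity threshold are excluded. `pileup_dual()` mirrors the two-pass
  protocol (stringent 95% pass, then a permissive 85% pass over the
  residue). For a fixed ingested alignment the residual-first merge is
  mathematically identical to a single 85% pass — each read's identity is
  fixed — so the two modes differ only in per-pass bookkeeping; both are
  provided because the protocol is usually described as two passes.
* `naive_map()` is an internal ungapped mapper (compiled sliding Hamming
  comparison, both strands) sufficient for simulated data. Candidate
  offsets span one unit of a tiled reference, so reads crossing the
  junction between adjacent tandem copies still place correctly, and any
  placement is reported in canonical coordinates modulo $L$ — the natural
  convention when every analysis is per-unit. Ties go to the forward
  strand, then the smallest offset.

Deletions in reads are tallied as a fifth allele. Insertions are kept in a
side table keyed by the preceding reference position and never contribute
to column depth or polymorphism calling: the per-position 4+1-allele model
has no insertion slot. Base qualities are ignored throughout — the
polymorphism filter below works on raw call counts.

The permissive identity level matters more than it may appear: reads drawn
from variant-rich repeat copies can carry several true mismatches per 100
bases against the unit reference, and a stringent-only pass would silently
drop exactly the variant carriers, biasing diversity downward.

## Consensus construction

`build_consensus()` emits the most frequent allele at each position. Ties
are broken alphabetically (A < C < G < T < del) and recorded; zero-depth
positions emit `N` with winning fraction 0; positions whose majority call
is the deletion allele are dropped from the collapsed sequence (it must
remain a valid nucleotide string) but kept as `del` in the per-position
vector so downstream coordinates are stable — whether such positions
belong in a consensus at all is a genuinely open convention, and this one
is explicit and reversible. `gap_report()` lists the `N` runs an external
gap-filling step (homology search plus multiple alignment against outside
databases, out of scope here) would need to patch.

## Polymorphism calling

A non-consensus allele at a covered position is called a polymorphism when
its count reaches

$$t = \max(2,\ \lceil 0.5\,D \rceil),$$

half the genome-wide 1x coverage depth (at 10x, at least five identical
calls). The logic: a real variant carried by a single repeat copy is
expected in about $D$ reads, because every copy is sequenced to depth $D$;
requiring half a copy-equivalent of identical support is far above what
per-base sequencing error (~4% for 454-class long reads, ~1% for
Illumina-class short reads) produces for any one allele at one position at
single-copy depths. The floor of 2 keeps 1x datasets from calling
polymorphisms out of single reads. The threshold is applied to the
**variant allele's own count** (the any-allele reading is vacuous — the
consensus allele nearly always satisfies it); a per-site-depth variant
`ceiling(0.5 * site depth)` sits behind the `per_site` flag for users who
prefer a depth-local filter.

Note the scale on which the error bound is meaningful: at a single-copy
locus the site depth equals $D$ and the per-allele false-positive rate is
bounded by $P[\mathrm{Binom}(D, e) \ge t]$. Inside a $C$-copy array the
site depth is about $C \cdot D$, so the fixed threshold acts as a
*per-copy-equivalent* filter: a variant present in a fraction $f$ of
copies appears in about $f \cdot C \cdot D$ reads and is detected with
power approaching 1 for $f \ge 0.5$ at $D \ge 10$. The validation suite
tests the false-positive bound at single-copy depth and the power property
in a multi-copy array, matching the two regimes.

`window_profile()` summarizes passed calls as the fraction of polymorphic
positions per 50 bp sliding window (step 1; a position counts once no
matter how many alleles passed). `region_summary()` tabulates per-region
densities plus a coding-vs-noncoding aggregate, where noncoding is every
unit position outside the coding regions (the spacers).

## Interspecific divergence

`align_pair()` globally aligns two consensus units by affine-gap
Needleman–Wunsch (Gotoh), compiled, with declared scoring — match +1,
mismatch −1, gap open −2, gap extend −0.5 (a length-$g$ run costs
$2 + 0.5g$) — and a deterministic trace-back (diagonal, then gap-in-second,
then gap-in-first). All parameters are overridable. The test suite checks
the scores against an exhaustive enumeration of all alignments of short
pairs and against an independent library implementation.

`classify_events()` partitions divergent sites into:

* **transition** — A↔G or C↔T substitution column;
* **transversion** — purine↔pyrimidine substitution column;
* **complex** — one event per maximal gap run (an indel of any length is
  one event, not one per base); gap runs separated by fewer than 3 matched
  columns merge into one event, since micro-fragmented gaps are usually
  one mutational event mis-split by the aligner; a gapless mismatch run of
  length ≥ 4 whose reverse complement equals the partner's run is
  re-labelled one complex (inversion) event.

The merge distance (3) and minimum inversion length (4) are pragmatic
constants with no canonical value; both are recorded in the output and
configurable. A known limitation: an inverted segment that shares
substrings with its reverse complement is often absorbed into gap events
by the optimal alignment before the inversion rule can see it, so the
inversion count is a lower bound.

## The Vg/Vm selection test

Under neutrality in diploids, the ratio of standing per-site variation in
a natural isolate ($V_g$) to the per-site-per-generation mutational
variation accumulated in repeatedly bottlenecked MA lines ($V_m$) equals
$4 N_e$. An implied $N_e = (V_g/V_m)/4$ falling orders of magnitude below
an independent estimate of the species' $N_e$ indicates purifying
selection on the locus.

The per-site estimator behind both quantities is declared and isolated in
one operation so it can be substituted: `per_site_diversity()` computes
Gini–Simpson diversity $h_i = 1 - \sum_b (n_{ib}/d_i)^2$ over the five
pileup alleles, with mean $V_g$ and site-level SEM. `vm_per_generation()`
divides an MA line's accumulated diversity by its generations. In
`vg_vm_test()` the joint $V_m$ is the unweighted arithmetic mean over
lines, rounded to 3 significant figures before the ratio so reported
ratios are reproducible from reported inputs (configurable).
`selection_verdict()` flags purifying selection when the implied $N_e$ is
at least two orders of magnitude below the reference — an intentionally
conservative cutoff, given that $V_g/V_m$ ratios carry large sampling
uncertainty.

## The simulator

`simulate_genome()` builds background flank + $C$ concatenated unit copies
+ background flank. Each copy carries each declared variant independently
at its frequency (frequencies strictly inside (0, 1): a fixed "variant" is
just the reference). The background is i.i.d. uniform nucleotides with a
guard that no 20-mer of the unit (either strand) occurs in it, so
single-copy depth is unambiguous. `simulate_reads()` places reads
uniformly to the target depth, on either strand, with i.i.d. substitution
errors at the platform rate; defaults model the two platform classes
(0.04 long-read-like, 0.01 short-read-like). Indel sequencing errors are
off — the downstream model is substitution-centric — and there is no
fragment-length or GC model because only depth enters the analyses.
`simulate_ma_series()` drifts each line's copy number by
`round(rate * generations)` plus integer noise
(`round(rnorm(0, sd = sqrt(|rate| * t)/2))`, variance growing with the
number of accumulated events; a zero rate reproduces the progenitor
exactly). All generators take seeds and restore the caller's RNG state.

What passing simulation tests does **not** show about real data: real
shotgun libraries have non-uniform coverage (GC, mappability), structured
error profiles (homopolymer errors, quality gradients), chimeric reads,
and arrays with internal structure (sub-repeat duplication, gene
conversion tracts). The simulator emulates none of these; it validates
the estimators' arithmetic and sampling behaviour, not robustness to
platform artefacts.

## Validation problem sizes and numerical choices

The validation suite scales the simulations down so they are exact but
quick: repeat units of 400–500 bp (analyses are per-position, so unit
length only scales runtime), copy numbers spanning the observed 56–323
range at 10x depth with 100 bp reads and 20 kb background, a 10 kb
single-copy locus (≥ 10<sup>4</sup> sites) for the false-positive bound,
and exhaustive alignment enumeration up to 8-mers (265 k alignments). The
copy-number recovery check uses a 99% read-resampling bootstrap interval
and additionally requires relative error below 5%; observed errors are
well under 1–2%.

Degenerate inputs are defined rather than left to chance: empty read sets
map to empty alignments (not an error); zero-depth positions become `N`
and emit no polymorphism calls; an all-`N` consensus yields a single
full-length gap interval; empty regions and non-positive depths,
generation counts or genome sizes are errors naming the offending
quantity.

## Known limitations

* The ungapped internal mapper is for simulation-backed validation, not a
  general aligner; real data should arrive as SAM from a real aligner.
* Reads overlapping the array/background boundary are dropped by the
  identity filter, shaving a fraction of order read-length / array-length
  off the aligned-base total — negligible for realistic arrays, visible
  only as a sub-percent bias in the smallest simulated ones.
* The default gene-region table follows the published unit coordinates
  verbatim, including an 18S interval (2694–3157) far shorter than a
  typical ~1.7 kb 18S gene; it is user-overridable and carries no silent
  correction.
* No haplotype phasing across the unit, no paired-end awareness, no
  GC/mappability correction, no per-unit copy deconvolution.
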