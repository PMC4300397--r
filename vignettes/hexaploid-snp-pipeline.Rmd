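---
title: "Methods: polyploid-aware SNP marker development, mapping and diversity analysis"
author: "camsnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polyploid-aware SNP marker development, mapping and diversity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model of the problem

`camsnp` implements, end to end and on fully synthetic data with known
truth, the marker-development strategy used for undifferentiated hexaploid
oilseed genomes such as camelina: three homeologous subgenomes so similar
that any hybridisation- or alignment-based assay risks interrogating all
three copies at once. Inter-subgenome (homeologous) variation then
masquerades as allelic polymorphism, and markers designed on it fail or
segregate bizarrely. The package's central object of study is the
*zero-variance* (100%-representation) screen: a candidate SNP between two
inbred parental lines is kept only if every sequencing read of line A at
that position carries the reference base and every read of line B carries
the alternate base. True allelic SNPs in locus-specific territory satisfy
this; collapsed homeologous columns, which mix subgenome alleles *within*
a line, do not.

Because the original reads and array intensities for the motivating study
were never deposited, every stage is driven by the `simdata` generators,
and the package's claims are properties measured against the generators'
truth tables, not reproductions of real-data counts.

# The synthetic hexaploid and its study conditions

`make_hexaploid()` builds, per pseudo-chromosome, an ancestral sequence
and three subgenome copies mutated independently at half the requested
divergence, so the *pairwise* subgenome divergence matches the target
(two independent substitution processes at rate d/2 differ at ~d of
positions, less a small coincidence correction). True allelic SNPs are
injected into parent B on exactly one subgenome copy each, only at
positions where all three subgenomes agree — allelic and homeologous
variant sets are disjoint by construction, which is what makes the
filter's confusion matrix measurable.

The default conditions, used by the discovery experiment and stated here
once as the package's reference configuration: 2 chromosomes x 50 kb x 3
subgenomes, pairwise divergence 0.03 (an undifferentiated hexaploid),
300 true SNPs, EcoRI (`G^AATTC`) complete digest with 2–4 kb size
selection, 300 bp inserts sequenced as 101 bp paired ends at 20x mean
fragment coverage, substitution error 0.001. Fragment size selection
keeps roughly a third of the genome, so of the 300 genome-wide SNPs a few
dozen land in assayable (selected, covered) territory — the denominator
the retention property uses.

Design choices worth recording:

* **Size selection** is plain inclusive length filtering of all digest
  fragments, terminal fragments included; the digest's full tiling is kept
  alongside so the reconstruction invariant (`concatenate(fragments) ==
  input`) is testable.
* **Reads**: mate 1 reads the insert's 5' end forward, mate 2 the 3' end
  reverse-complemented; the pair is strand-flipped with probability 1/2 so
  orientation carries no information. Errors are i.i.d. substitutions; no
  quality model, homopolymer chemistry or indels (indels were never
  carried into assay design, so they are out of scope).
* **cDNA arm**: 3'-biased libraries are emulated as single-end reads from
  the terminal 500 bp of designated transcript sequences, with no
  expression model — downstream the cDNA arm differs from the genomic arm
  only in its calling thresholds (depth ≥ 3, variant fraction ≥ 0.30
  versus ≥ 8 and ≥ 0.35).

# Discovery: mapping, calling, and the two experimental arms

The mapper is deliberately simple and fully specified: an exact k-mer
index (k = 21, three seed offsets per read, both orientations) followed by
ungapped full-length verification with a mismatch cap. Under
`unique_only`, a read whose best mismatch count is achieved at more than
one locus is discarded — equal-score ties are non-unique, so reads from
locally identical homeologous windows drop out rather than vote.
K-mers above a multiplicity cap (default 8) are excluded from seeding
only; their loci remain reachable through neighbouring seeds.

Variant calling applies the profile thresholds inclusively (a variant
fraction of exactly 0.35 passes; the vendor semantics of the original
caller are unverifiable, so the inclusive rule is the documented choice)
and requires exactly one alternate base at or above the fraction; columns
where two alternates qualify are rejected as multi-allelic. The assumed
ploidy is recorded in the profile as provenance.

The discovery experiment has two arms sharing all code paths:

* **Marker-development arm** — reference = parent A's selected fragments
  from *all three* subgenomes; unique-only mapping, ≤ 3 mismatches. This
  is the intended workflow: divergence separates the subgenome contigs,
  and true SNPs in covered unique territory are recovered and pass the
  zero-variance screen unless a sequencing error lands on their column
  (at error 0.001 and ~40 reads per column, a ~4% sensitivity tax —
  the screen trades sensitivity for specificity by design, evaluated on
  raw counts with no error correction).
* **Collapsed arm** — reference = subgenome-1 fragments only, ties kept,
  mismatch cap raised to 10 so reads from the other subgenomes cross-map
  (at 3% divergence a 101 bp read carries ~3 mismatches). Homeologous
  variation now surfaces as mixed columns in *both* lines; roughly
  `P(Binom(depth, 1/3) >= 0.35 depth)` of single-subgenome variants clear
  the 35% fraction and become candidates — and the zero-variance filter
  rejects essentially all of them, because passing would require one
  line's ~60 reads to miss two subgenomes entirely.

The acceptance suite pins the two headline rates under the reference
configuration: ≥ 90% retention of assayable true SNPs, ≥ 95% rejection of
homeologous candidates.

# Panel design

Post-discovery screens mirror assay-design practice: the clean-flank rule
(100 bp of contig on both sides, no other variant within ±100 bp —
*inclusive*, a variant exactly 100 bp away fails, the conservative reading
of "no additional SNPs") and a designability surrogate. The surrogate's
penalty table (0.3 per secondary variant within ±60 bp, 0.2 for GC outside
0.30–0.70 in the ±60 bp window, 0.2 per ambiguous base, 0.2 for a ≥ 6 bp
homopolymer within ±20 bp; pass at score ≥ 0.6, threshold inclusive) is a
set of declared constants of this package, not a model of any vendor's
scoring tool; only the 0.6 acceptance threshold is taken from practice.

Synteny-spread selection works from a user-supplied homology table (the
package computes no alignments to real genomes): per model-genome
chromosome it selects up to a quota of candidates maximizing the minimum
pairwise gene-position gap. Points on a line admit an exact solution —
binary search over achievable gaps with a greedy left-to-right feasibility
scan — so the implementation is the optimum, with the lowest-position
construction as the deterministic tie-break. Candidates with no homology
entry form the "intergenic" tranche, drawn with a seeded random sample.
`assemble_panel()` concatenates the provenance-labelled tranches and
refuses duplicate assay positions.

# Array genotyping

Intensities live in GoldenGate polar convention: `theta = (2/pi)
atan(y/x)`, `R = x + y`; `x = y = 0` is a missing record. Per locus:

* if no sample reaches `R = 0.2` the locus is *failed* and yields no
  calls;
* theta is clustered for k = 1..3 with a deterministic quantile-initialised
  Lloyd routine (a stochastic-restart k-means would make QC
  irreproducible); k is chosen by mean silhouette with ties to smaller k,
  **among eligible k only** — a clustering is eligible when every adjacent
  cluster-mean gap exceeds 3x the largest within-cluster standard
  deviation. The guard is what separates a genuinely monomorphic locus
  (one Gaussian, which a silhouette alone will happily split) from a
  polymorphic locus with poor separation;
* patterns: *monomorphic* (k = 1); *dominant* (one cluster's mean R below
  0.2 while the others are clearly fluorescing — heterozygotes are
  indistinguishable from the signalling homozygote, so such loci are
  excluded from mapping by default); *low_separation* (min gap < 0.15);
  *diffuse_allele* (one cluster's spread above 2x the median cluster
  spread — the generator draws the diffuse cluster at 3x the nominal
  noise, and the detector sits at 2x so that sampling noise in the spread
  estimate does not flip the verdict); else *standard*.

Calls label clusters by theta order (low → AA, mid → AB, high → BB),
re-anchor so a supplied parent A sits in the AA cluster (parents sharing a
cluster flag the locus inconsistent), and blank samples farther than 3
cluster standard deviations from every mean. Matrix QC excludes samples
above 20% missingness first, then loci above 20% missingness over the
*retained* samples (the post-exclusion denominator — the order in which
the original study applied its exclusions).

# Linkage mapping

Two-point analysis treats residual heterozygous calls as missing (RILs
are modelled fully inbred: the generation count of the motivating
population is unstated, and "recombinant inbred" is read as F-infinity).
The observed recombinant fraction `R` converts to a per-meiosis estimate
through the RIL-by-selfing identity `r = R/(2(1-R))`; the LOD is the
binomial likelihood ratio at `R̂` against 0.5. Grouping takes connected
components of {LOD ≥ 3.0 and r ≤ rmax}.

The `rmax` guard deserves its arithmetic. With 180 lines and ~600 markers
there are ~1.7x10^5 unlinked pairs; an unlinked pair reaches LOD 3 when
`R̂ ≲ 0.36`, an event of probability ~1.3x10^-4 — over twenty expected
spurious links, each able to fuse two chromosomes through transitive
closure. A guard at r ≤ 0.35 binds at `R̂ = 0.41` and blocks none of them.
The default here is **rmax = 0.20** (binding at `R̂ = 0.286`,
~5x10^-9 per pair, ~10^-3 expected false joins panel-wide) which still
links any gap up to ~22 Kosambi cM. Sparser maps with larger gaps should
relax it; the parameter is exposed.

Ordering is two-point seriation: nearest-neighbour chaining seeded from
several end-like loci (largest summed r — chains started mid-group fold
back on themselves), improved by 2-opt reversals, minimising the sum of
adjacent r. This is a documented heuristic, not a multipoint likelihood
order; its acceptance is rank correlation ≥ 0.95 against the generating
order on simulations, not identity with any specific mapper. Distances
are Kosambi, `d = 25 ln((1+2r)/(1-2r))` cM. The crossover generator is
no-interference (Haldane) while estimation uses Kosambi, so estimated map
lengths run a few percent short of truth; the ±15% acceptance band
absorbs this deliberate mismatch. Segregation distortion is a 1-df
chi-square on AA:BB counts flagged at p < 0.01, with runs of ≥ 3 flagged
adjacent loci reported as distorted regions. The summary table follows
the published convention of dividing group length by the locus count
(not the interval count) for "average distance between loci".

# Diversity and structure

Per-locus statistics are textbook: gene diversity `He = 1 - Σp²`, `PIC =
He - Σ_{i<j} 2 p_i² p_j²`, observed heterozygosity, major-allele
frequency. `F_IS` pools as a ratio of sums (`1 - ΣHo/ΣHe`), robust to
near-monomorphic loci; `F_ST` is Weir–Cockerham 1984, with AMOVA's
`Phi_ST` reported alongside since the two estimands differ slightly.
AMOVA distances are squared dosage differences summed over loci (squared
Euclidean), decomposed by the standard distance formulae and tested by
label permutation with plus-one correction; a permutation that happens to
reproduce the original partition counts as extreme, so with very small
balanced groups the attainable p floor is slightly above 1/(n_perm+1).

The NJ tree uses allele-sharing dissimilarity with pairwise deletion
(each pair over its co-called loci; a pair with none is an error), ape's
Saitou–Nei agglomeration, and locus bootstrap (resampling columns) for
split support.

Admixture inference is the maximum-likelihood EM of the standard
admixture model — each allele copy draws its cluster from `q_i`, then its
state from `p_k` — not a Bayesian sampler with a correlated-frequency
prior. The original study's burn-in/iteration settings map onto `max_iter`
and random restarts; replicates are restarts, and label switching across
replicates or against truth is repaired by greedy column matching. The
log-likelihood omits the constant genotype binomial coefficient. Evanno's
ΔK is computed from replicate means and standard deviations, undefined at
the K-range endpoints and wherever the replicate sd is exactly zero (with
finite tolerance and random restarts the converged log-likelihoods differ
in their last digits, which is enough to keep ΔK defined; a clean peak at
the generating K relies on |L''| collapsing above it). Population
assignment uses the strict rule: an accession joins its majority cluster
only if that ancestry *exceeds* 0.70.

The panel generator's defaults are the diversity-collection conditions:
178 accessions, 493 biallelic loci, K = 2 ancestral populations at
Balding–Nichols differentiation 0.276, selfing 0.96 (so `F_IS` equals the
selfing rate and observed heterozygosity is 4% of outbred expectation),
13% of accessions with Dirichlet-drawn admixed ancestry.

# What the synthetic data does and does not show

The generators emulate structure — subgenome divergence, digest
geometry, cluster patterns, selfed-RIL recombination, drift and admixture
— but not the pathologies of real instruments: no base-quality gradients,
PCR duplicates, mapping reference bias, assay batch effects, or
expression-level variation in the cDNA arm. Passing tests therefore
certify the *logic* of the filters and estimators under controlled
violation of their assumptions (collapsed homeologs, failed probes,
distorted segregation), not their field performance. Problem sizes in the
test and acceptance runs (2x50 kb chromosomes, 20x30-marker maps with 180
lines, 80–178 accession panels, K scans to 4–5 with 5 replicates) were
chosen once as desk-scale configurations that leave the measured
properties' margins comfortably wide; the analysis scripts under
`analysis/` state the same choices.

# Known limitations

* No gapped alignment and no indel handling anywhere.
* Partial-panel marker merging (loci scored on a subset of lines) is not
  implemented; marker-class labels in the map report are the supported
  hook.
* `spread_select` optimises gene positions on a line per chromosome; it
  does not balance quotas across chromosomes when candidates run short.
* The EM fits biallelic loci only and excludes others with a warning.
* Dominant loci can optionally enter diversity statistics as
  presence/absence calls, but the default keeps them out of every
  downstream stage.
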