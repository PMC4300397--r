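# camsnp

SNP marker development for an undifferentiated hexaploid oilseed genome,
rebuilt as a tested, simulation-driven R pipeline. The three homeologous
subgenomes of a crop like camelina are so similar that sequence variants
*between* subgenomes masquerade as allelic SNPs: an assay designed on such
a position interrogates all three copies at once and fails. The package
implements the polyploid-aware answer — reduced-representation
sequencing of two inbred parents, unique-match read mapping, and a
**zero-variance screen** that keeps a candidate SNP only if 100% of each
parent's reads carry a single allele — plus everything downstream of it:
GoldenGate-style two-channel genotype calling with cluster-pattern QC,
recombinant-inbred-line linkage mapping, and diversity / population
structure analysis of a germplasm panel.

No real reads or intensities are required (none were ever deposited for
the motivating study): a first-class synthetic-data module generates a
hexaploid genome with a known truth table of allelic and homeologous
variants, EcoRI-digested size-selected paired-end libraries, selfed RIL
populations, admixed diversity panels and per-locus two-channel
intensities for every cluster pathology seen on real arrays.

## The statistics at the core

* **Zero-variance filter** — candidate (ref, alt) passes iff line A reads
  are 100% ref *and* line B reads are 100% alt; any within-line mixture
  (the collapsed-homeolog signature) fails.
* **Two-point RIL mapping** — observed recombinant fraction R, per-meiosis
  r = R/(2(1−R)), LOD = n_R log₁₀(R̂/0.5) + n_NR log₁₀((1−R̂)/0.5),
  grouping at LOD ≥ 3.0, Kosambi distances d = 25 ln((1+2r)/(1−2r)) cM,
  1-df chi-square distortion audit at p < 0.01.
* **Genotype calling** — theta = (2/π) atan(y/x), R = x + y; loci with all
  R < 0.2 fail; deterministic 1-D clustering with silhouette k-selection
  classifies standard / diffuse / low-separation / dominant / failed /
  monomorphic patterns; 20% missingness exclusions (samples first).
* **Diversity** — He = 1 − Σp², PIC = He − Σᵢ<ⱼ 2pᵢ²pⱼ², F_IS = 1 − ΣHo/ΣHe,
  Weir–Cockerham F_ST, distance-based AMOVA with permutation p,
  allele-sharing NJ trees with locus bootstrap, admixture by EM with
  Evanno ΔK and the strict qK > 0.70 assignment rule.

## Worked example

```r
library(camsnp)

truth <- make_hexaploid(n_chromosomes = 2, chrom_length = 50000,
                        homeolog_divergence = 0.03, n_true_snps = 300, seed = 1)

# marker-development arm: per-subgenome reference, unique-only mapping
run <- snp_discovery_run(truth, depth = 20, error_rate = 0.001, seed = 1)
ev  <- evaluate_discovery(run, truth)
cat(sprintf("retention: %d/%d true SNPs kept\n",
            ev$snp$n_retained, ev$snp$n_assayable))

# collapsed-homeolog contrast: one-copy reference, ties kept
coll <- snp_discovery_run(truth, depth = 20, error_rate = 0.001,
                          collapsed = TRUE, seed = 1)
evc <- evaluate_discovery(coll, truth)
cat(sprintf("homeolog rejection: %d/%d artifact candidates removed\n",
            evc$homeolog$n_rejected, evc$homeolog$n_candidates))

# 180 RILs over 20 chromosomes, mapped back at LOD 3.0
geno <- simulate_ril(regular_map(20, 30, 5), n_lines = 180, seed = 1)
map  <- build_map(geno, lod_min = 3.0)
tail(map_report(map), 3)
```

prints

```
retention: 40/41 true SNPs kept
homeolog rejection: 362/362 artifact candidates removed
 group n_loci length_cM avg_spacing_cM
  LG19     30     130.8           4.36
  LG20     30     139.5           4.65
 Total    600    2795.2           4.66
```

Read: of the 300 planted parent-A/parent-B SNPs, 41 landed in digest-
selected, uniquely mappable territory covered at calling depth in both
lines, and the zero-variance screen kept 40 of them (one lost to a
sequencing-error read on its column). On the collapsed reference every
one of the 362 homeologous artifact candidates shows a within-line
mixture and is rejected. The RIL map recovers all 20 chromosomes with 30
loci each; the 2795 cM total sits a few percent under the generating
2900 cM because crossovers are simulated without interference while
distances are estimated with Kosambi.

## The analysis workflow

Numbered drivers under `analysis/` run the full narrative and write their
tables to `results/`:

1. `01_simulate_genome.R` — hexaploid truth, digests, fragment FASTA.
2. `02_discover_snps.R` — both discovery arms, candidate tables,
   retention/rejection summary.
3. `03_design_panel.R` — flank filter, designability surrogate, synteny
   spread + intergenic + cDNA tranches, assembled assay panel.
4. `04_genotype_and_map.R` — RIL intensities with mixed cluster
   pathologies, genotype calls + QC, linkage map and distortion report.
5. `05_diversity.R` — 178-accession panel: per-locus stats, F-statistics,
   AMOVA, NJ tree, admixture scan with ΔK and 70% assignment.

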