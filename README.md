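# SRNaseEvol

Molecular-evolution analyses for **S-RNase** alleles under RNase-based
gametophytic self-incompatibility (GSI). In GSI, the pistil-expressed
S-RNase determines the pistil recognition specificity; balancing selection
maintains many allelic specificities over tens of millions of years, so
allelic lineages are shared across species and even genera. This package
bundles, as tested reusable functions, the analyses this system calls for:

* **Divergence** — pairwise Ka/Ks by Nei–Gojobori (1986) counting with the
  Jukes–Cantor correction `d = -(3/4) ln(1 - (4/3) p)`; amino-acid
  p-distances; a clock-like (UPGMA) tree.
* **Positive selection** — two desk-scale per-codon detectors (parsimony
  counting on a tree; close-pair counting) plus the dual-method calling
  rule: an ungapped codon is positively selected iff one method gives
  posterior probability > 0.95 and the other > 0.50; a gapped codon iff
  the population-genetics method alone gives > 0.95. External per-site
  probability tracks plug in via TSV.
* **Recombination** — a MaxChi-style permutation scan for gene-conversion
  tracts, consolidation of signals into independent events, parsimony
  counting of synonymous mutations, and the events-per-synonymous-mutation
  ratio.
* **Specificities** — single-linkage clustering at 5% amino-acid
  divergence, per-genus counts, trans-generic (ancestral) lineage sharing,
  lineage ages at 1% divergence per My, the new-specificity rate
  (`100 * sum(Ks) / sum(PSS differences)`), and the Poisson no-hit bound
  `exp(-Ka / 0.0192)`.
* **Replacement changes** — parsimony networks (minimum spanning forests
  over close sequences), enumeration of independent replacement mutations
  at selected sites, conservative/non-conservative classification on the
  groups {RHK, DE, NQ, C, AGPST, ILMV, FWY}.
* **Population genetics** — `theta = 4 Ne mu` arithmetic: theta from SNP
  density, mu from theta and Ne, divergence projections over time and
  generation time, and the inverse generation-time solver.
* **Structure** — PDB parsing, Shrake–Rupley accessible surface area with
  a deterministic point set, alignment-to-structure mapping, Mann–Whitney
  comparison of selected vs other sites, lysine conservation profiles.
* **Simulator** — a Gillespie codon simulator with omega site classes,
  clock-like specificity clades spanning genera, and gene-conversion
  tracts calibrated per synonymous substitution, with a full truth channel
  for parameter-recovery testing.

## Worked example

```r
library(SRNaseEvol)

sim <- simulate_dataset(sim_config(seed = 1))   # 60 seqs x 200 codons
aln <- sim$alignment
D   <- aa_distance_matrix(aln)

partition <- cluster_specificities(D)           # 5% single linkage
genus_counts(partition)$per_genus
shared_lineages(partition)$formatted
profile <- selection_profile(aln)               # dual-method PSS calls
recovery_metrics(sim$truth, pss = profile, partition = partition)
```

This prints (abridged):

```
specificity partition: 6 specificities among 60 sequences (threshold 0.05)
Crataegus     Malus     Pyrus    Sorbus
        6         6         6         6
          Crataegus    Malus        Pyrus        Sorbus
Crataegus "-"          "6/6 (100%)" "6/6 (100%)" "6/6 (100%)"
Malus     "6/6 (100%)" "-"          "6/6 (100%)" "6/6 (100%)"
...
site selection profile: 200 codons; 13 ungapped + 0 gapped positively selected sites
PSS recall: 0.65  precision: 1  FPR: 0
```

The six planted specificity lineages are recovered exactly, every lineage
is shared by all four genera (the simulator assigns genera round-robin
within lineages, mimicking trans-generic polymorphism), and 13 of the 20
planted positively selected sites are called with no false positives.

The closed-form arithmetic works on published inputs directly:

```r
theta_from_snp_density(1/149)          # 0.0201  (one SNP per 149 bp, x3)
mu_from_theta(0.02, ne = 1e4)          # 5e-07   per site per generation
project_divergence(1.2e-7, 5e6, 50)    # 0.012   silent divergence, 5 My
recomb_per_synmut(17, 571.1)           # 0.030   events per syn mutation
poisson_no_hit(0.058, 0.0192)          # 0.0488  (< 5%)
```

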