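---
title: "Methods: evolutionary analysis of S-RNase alleles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolutionary analysis of S-RNase alleles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological problem

In RNase-based gametophytic self-incompatibility (GSI), the pistil-expressed
S-RNase encodes the pistil recognition specificity at the S-locus. Balancing
(negative frequency-dependent) selection keeps many allelic specificities
segregating for very long times, so allelic lineages routinely predate
speciation and even genus splits. `SRNaseEvol` implements the quantitative
analyses this situation calls for: how fast sequences diverge at synonymous
and non-synonymous sites, which codons are under positive selection, how much
gene conversion occurs relative to point mutation, how many distinct
specificities a sample implies and how they are shared across genera, how
fast new specificities arise, and where the selected sites sit on the
protein surface.

```{r, eval = FALSE}
library(SRNaseEvol)
sim <- simulate_dataset(sim_config(seed = 1))
aln <- sim$alignment
D <- aa_distance_matrix(aln)
profile <- selection_profile(aln)
partition <- cluster_specificities(D)
```

## Divergence: Nei–Gojobori counting with Jukes–Cantor correction

`kaks_pair()` counts synonymous (S) and non-synonymous (N) *sites* per codon
as the fraction of possible single-nucleotide changes that preserve the
amino acid, averaged over the two sequences; changes into stop codons are
excluded from the denominators. *Differences* at codons hit more than once
are resolved by averaging over all minimal mutational pathways with equal
weight, discarding pathways that pass through a stop codon. The proportions
`pS = Sd/S` and `pN = Nd/N` are corrected for multiple hits with the
Jukes–Cantor transform `d = -(3/4) log(1 - (4/3) p)`, which is undefined at
`p >= 0.75`; such pairs are flagged saturated. Codons containing gaps, `N`,
or stops in either sequence are skipped pairwise (not list-wise), which
maximizes the number of comparable sites per pair.

Amino-acid distances (`aa_distance_matrix()`) are plain p-distances over
pairwise-ungapped columns of the translated alignment. Whether corrected or
uncorrected amino-acid distances should feed the 5% specificity rule is an
open choice; the p-distance is used because at the divergences where the
rule bites (<= 5–10%) the correction is negligible, and the threshold itself
was defined operationally.

`linearized_tree()` produces the clock-like tree used for lineage ages and
as the default topology for the parsimony detector. It is UPGMA
(average linkage), a deliberate stand-in for a linearized Minimum Evolution
tree: both are clock-like, and all quantities derived from the tree in this
package (ages, parsimony change counts) either come directly from pairwise
distances or are robust to the difference. Rows are sorted by identifier
before clustering so ties break deterministically.

## Positively selected sites: two counting detectors and a combination rule

The package's PSS machinery has two layers. The *combination rule*
(`call_pss()`) is the part with scientific content: an ungapped codon is
called positively selected when one method supports it with posterior
probability above 0.95 and the other above 0.50 (strict inequalities); a
gapped codon, which phylogenetic codon models cannot analyse, is called on
the population-genetics probability alone exceeding 0.95. The rule is
monotone and pure: externally produced per-site probability tracks (e.g.
from codon-model or population-genetics MCMC software) can be supplied via
`read_probability_track()` and passed straight to `call_pss()`.

The two built-in detectors are desk-scale counting stand-ins so the whole
pipeline runs with no external tools:

* `detector_phylo()` reconstructs ancestral nucleotides per column by Fitch
  parsimony on the clock tree (ties resolved toward the alphabetically
  first nucleotide, for reproducibility), classifies each inferred change
  in its reconstructed codon context, and scores each codon with a
  one-sided binomial tail `P(X >= n | n + s, pN)`, where `pN = N/(N + S)`
  comes from the codon's own site fractions. The reported probability is
  one minus the tail.
* `detector_popgen()` aggregates synonymous/non-synonymous differences per
  codon over all sequence pairs closer than 5% amino-acid divergence
  (minimizing multiple hits) and applies the same binomial score. Close
  pairs share mutations, so the aggregated counts are not independent; the
  score is an approximation and is documented as such.

These are detectors of *counting excess*, not codon-model likelihoods; they
have no model of transition/transversion bias or codon frequencies. On
synthetic data they rank planted high-omega sites far above background
(recall 0.65–0.8 at false-positive rate <= 1% under the default study
conditions), which is what the downstream analyses need.

## Recombination: MaxChi scan, event consolidation, and the ratio

`maxchi_scan()` is a maximum chi-square scan: for each sequence pair,
pairwise-ungapped columns that are polymorphic in the alignment are
classified match/mismatch; for each candidate breakpoint a 2x2 chi-square
(no continuity correction) compares mismatch counts left/right within
windows of the 20 nearest polymorphic sites per side (truncated at the
ends). Significance of the maximum is assessed by permuting column order;
the permutation loop is seeded and stops early once a pair can no longer
reach the 0.05 threshold. One detector is provided rather than a suite; the
union-over-detectors rule then degenerates to this single method, and
externally produced event tables can be fed to `consolidate_events()` for
parity with multi-method suites.

`consolidate_events()` merges signals whose breakpoints lie within 30 nt
and whose sequence sets overlap (transitively) into independent events —
the same conversion tract detected in several descendant pairs should count
once. `count_syn_mutations()` totals synonymous changes implied by Fitch
parsimony over the tree (a stand-in for model-based counting; at the low
synonymous divergences of allele pairs the two agree well — on shallow
synthetic data the parsimony count is within ~1% of the simulated truth).
`recomb_per_synmut()` is the headline ratio, reported to three decimals,
and deliberately decoupled so published event and mutation counts can be
fed directly. The percentage of recombinant sequences is a lower bound:
only sequences carrying a detected signal are counted.

Note one caveat discovered during validation: strong per-site rate
heterogeneity (a handful of high-omega codons) can create spatially
clustered mismatches that MaxChi reads as weak recombination signals. The
permutation null is exchangeable columns, so this is a property of the
statistic itself, shared with its classical implementations.

## Specificities: clustering, sharing, ages, and the new-specificity rate

`cluster_specificities()` applies single linkage at 5% amino-acid
divergence: sequences more than 5% diverged represent different
specificities unless connected through intermediates; boundary pairs
(exactly 5%) are the same specificity. Counting is genus-aware
(`genus_counts()`): a cluster containing several genera counts once per
genus and once in the total — such trans-generic clusters are the
operational definition of ancestral lineages. `shared_lineages()` reports,
for each ordered genus pair (A, B), the fraction of A's lineages also
containing B; the numerator is symmetric, the denominator is the row
genus's lineage count, so the matrix is asymmetric by design. Lineage ages
use a linear clock of 1% amino-acid divergence per million years
(`lineage_ages()`, calibration exposed).

`new_specificity_rate()` assumes a single amino-acid change at a positively
selected site suffices to create a new specificity. Over close pairs
(<5% amino-acid divergence, `close_pairs()`), the default estimator is the
ratio of sums `100 * sum(Ks) / sum(PSS differences)` — robust to pairs with
zero PSS differences — with a mean-of-ratios alternative exposed because
the choice is not canonical. The companion Poisson argument
(`poisson_no_hit()`, `threshold_ka()`): if PSS changes accrue at one per
1.92% non-synonymous divergence, a pair with more than 5.8% non-synonymous
divergence has probability `exp(-0.058/0.0192) = 4.9% < 5%` of showing no
PSS change, which is what justifies the 5% clustering rule.

## Replacement changes and conservativeness

`build_network()` connects sequences differing at no more than 15
nucleotides (configurable) and takes a minimum spanning forest per
component (Kruskal, ties broken lexicographically), so each mutation is
counted once — a deliberate simplification of statistical-parsimony
networks, whose exact probability-of-parsimony connection limit is not
recomputed; the downstream statistic only requires that connected sequences
be closely related. `enumerate_replacements()` walks the forest edges,
decomposes multi-hit codons along a deterministic minimal stop-avoiding
pathway, and records each amino-acid-changing step. Changes are
conservative when both residues share a group of
`{RHK, DE, NQ, C, AGPST, ILMV, FWY}` (charge/volume/polarity classes).
`conservative_summary()` compares the conservative fraction at positively
selected sites against the 35% baseline expected from large protein
surveys, with an exact binomial test whose two-sided p-value doubles the
smaller tail (capped at 1).

## Population-genetic arithmetic

`theta_from_snp_density()` converts a SNP density (e.g. one SNP per 149 bp
of EST sequence) to a per-silent-site diversity by multiplying by 3,
assuming most SNPs are neutral and third positions nearly neutral.
`mu_from_theta()` inverts `theta = 4 Ne mu` (default `Ne = 1e4`, an upper
bound consistent with S-allele numbers in natural populations).
`project_divergence()` computes `mu * years / generation_time`. The
single-lineage convention (no factor 2) is the default because it
reproduces the published bounding values (0.012 at `mu = 1.2e-7`, 50-year
generations, 5 My; 0.10 at `mu = 5e-7`, 25-year generations); a
`two_lineage` flag adds the conventional doubling and the discrepancy is
deliberately surfaced rather than hidden. `generation_time_for()` is the
exact inverse, giving e.g. ~500-year generations if fossil-record ages are
forced onto the molecular rates.

## Structure: accessible surface and lysines

`parse_structure()` reads PDB ATOM records (first model, heavy atoms,
waters excluded) with Chothia-style radii (C 1.70, N 1.55, O 1.52, S 1.80
Angstrom). `shrake_rupley_asa()` samples each atom's solvent-expanded
sphere at 960 deterministic golden-spiral points (probe 1.4 Angstrom); the
deterministic point set makes results bit-reproducible and
rotation-invariant to well under 1%. An isolated atom recovers the
closed-form `4*pi*(r+p)^2` within 1%. Published reference values obtained
with analytic surface programs are expected to differ at the few-percent
level from any sampled estimator, so they serve as documentation
comparisons, not acceptance targets; the molecular (reduced) surface is
out of scope. `map_alignment_to_structure()` aligns the reference protein
to the structure sequence (BLOSUM62, affine gaps) and
`category_surface_stats()` compares per-residue ASA of positively selected
vs other sites with a two-sided Mann–Whitney test — exact when the smaller
group has at most 8 residues and no ties, otherwise the normal
approximation with tie-corrected variance. `lysine_profile()` reports, for
each lysine of a reference sequence, the column frequency of lysine with
gaps excluded from the denominator, binned at 50% and 75% — the
conservation classes used to flag candidate ubiquitylation sites.

## The synthetic-data generator

`simulate_dataset()` generates the structure the analyses assume, with a
complete truth channel:

* **Tree.** A clock-like tree with `n_clades` long internal lineages
  (root-to-leaf height `crown_depth`, default 0.2 expected substitutions
  per neutral site) each subtending a shallow caterpillar clade (height
  `clade_depth`, default 0.01) — long-lived specificity lineages with
  recent within-lineage diversification. Genera are assigned round-robin
  within clades, so every lineage spans several genera (trans-generic
  sharing).
* **Substitutions.** Codons evolve by an exact event-by-event (Gillespie)
  process: per-position moves at relative rate `kappa/(kappa+2)` for
  transitions and `1/(kappa+2)` for transversions (default `kappa = 2`),
  multiplied by the site's omega for non-synonymous changes (default 20
  planted sites at omega 5 on a background of 0.1), with changes into stop
  codons forbidden. Rates are normalized so one unit of branch length is
  one expected substitution per neutral nucleotide site; under neutrality
  the realized per-branch counts match branch lengths to within the small
  stop-exclusion loss, and measured mean Ka/Ks is 0.96 on the seeded
  neutral check. Event-by-event simulation (rather than matrix
  exponentiation) is what makes exact truth recording possible.
* **Gene conversion.** After the substitution phase, a Poisson number of
  conversion events with mean `conversion_rate` x (realized synonymous
  substitutions) is superimposed (default rate 0.02, the midpoint of the
  0.012–0.030 range reported for S-RNase data). Each event copies a
  geometric-length, codon-aligned tract (mean 90 nt) from a contemporaneous
  donor lineage into a recipient branch; donors are reconstructed at the
  event time including earlier conversions. Substitutions replayed after a
  conversion that would create a stop codon in the new context are skipped
  (a rare-event guard). Tract boundaries are codon-aligned to avoid
  chimeric codons.
* **Truth.** Planted PSS positions, per-branch synonymous/non-synonymous
  counts, clade and genus assignments, and per-conversion records
  including the number of diagnostic sites at event time and the residual
  *leaf deficit* — the mismatch shortfall inside the tract for a
  recipient/donor leaf pair relative to the flank mismatch density, i.e.
  the signal actually available to a pairwise scan at sampling time.

What the generator does *not* emulate: indels (gaps only enter via
masking), codon-frequency bias, rate variation beyond the two omega
classes, intra-locus recombination other than conversion, and population
processes (it draws a fixed genealogy, not a coalescent). Passing recovery
tests therefore demonstrates correctness of the inference machinery under
the stated model, not robustness to all features of real S-RNase data.

## Recovery experiments and problem sizes

The seeded checks in the test suite use these study conditions:

* **Specificity clustering and PSS recovery:** one simulation at the
  default conditions (60 sequences x 200 codons, 6 clades, 20 planted
  sites at omega 5, background 0.1, seed 1). Clustering must recover
  exactly 6 clusters; PSS calling must reach recall >= 0.5 at
  false-positive rate <= 0.05.
* **Conversion recovery:** eight simulations (30 sequences, conversion
  rate 0.1, mean tract 180 nt, seeds 201–208), pooled. A planted event
  enters the recall denominator only if its residual leaf deficit is at
  least 16 sites (eight diagnostic sites per flank): conversions between
  lineages that had barely diverged at event time, or whose tract signal
  has since decayed, carry no pairwise signal in principle — no
  two-sequence method can see a tract that erased no differences. The
  elevated conversion rate relative to the default exists purely to plant
  enough qualifying events for a recall estimate; the detector and its
  thresholds are identical to the defaults. Pooled recall must reach 0.7
  with breakpoints within 60 nt (measured: 0.82 with ~5 nt mean error).
* **Neutral calibration:** 20 sequences x 300 codons at omega 1
  everywhere; mean pairwise Ka/Ks must fall in [0.9, 1.1].
* **Synonymous-count oracle:** 20 sequences x 300 codons at tree height
  0.05, where parsimony counting must land within 15% of the recorded
  truth.

These sizes keep the full suite to a few minutes while leaving each
stochastic check a comfortable margin.

## Numerical and degenerate-input conventions

All coordinates are 1-based; intervals are closed. Ambiguity codes other
than `N` are rejected at construction. Fitch ties, UPGMA ties, spanning-tree
ties and multi-hit pathway choices all break deterministically
(alphabetical / lexicographic), so every analysis is bit-reproducible given
a seed. Saturated pairs propagate `NA` rates rather than clamping. Empty
masks, all-gap codon columns, missing probability-track rows, empty event
lists, single-genus partitions and reference sequences without lysines all
produce defined results or informative errors, covered by tests.
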