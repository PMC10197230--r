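---
title: "Designing and validating a multi-species SNP array"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating a multi-species SNP array}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Blue mussels (*Mytilus edulis*, *M. galloprovincialis*, *M. trossulus*,
*M. chilensis*) hybridize wherever their ranges overlap, and the genus is
farmed at a scale where genomic selection, parentage assignment and
provenance tracing all need a common, reproducible marker set.  A
medium-density (60 K class) SNP array serving four species at once has to
solve several coupled problems:

* variants are discovered from low-coverage whole-genome sequencing
  (lcWGS, ~4x), so genotypes are patchy (60–77% missing per individual)
  and error-prone;
* array probes are 71-mers — 35 bp of reference flank either side of the
  variant — and any *other* polymorphism inside those flanks disrupts
  hybridization, so candidate markers must have monomorphic flanks;
* the panel must serve each species: markers are selected by the number
  of species in which they segregate (sharing tiers), with per-species
  quotas for species-exclusive markers and a reserved slice for
  previously published diagnostic markers (species identification,
  phenotypic sex, transmissible cancer, population structure);
* once manufactured, the array is validated by call-rate (CR)
  scenarios, within-species polymorphism accounting, and concordance
  between array and sequencing genotypes.

`snpanel` implements this workflow end to end as composable functions
plus a small command-line front-end, and ships a synthetic hybrid-zone
generator so that every stage can be exercised and tested without any
external data.

# Data model

The common currency is a markers x samples dosage matrix
(`genotype_matrix`) with entries 0/1/2 (alt-allele count) and `NA` as an
explicit missing sentinel, aligned to a `variant_table` of coordinates,
alleles and caller annotations (QD, FS, MQ, HaplotypeScore, MQRankSum,
mean depth) and to a `sample_sheet` (sample, population, optional
species, platform).  Marker identity is the key `contig:pos:ref:alt`
throughout, which also resolves allele orientation when two genotype
datasets are compared.  Coordinates are 1-based in VCF and panel files
and 0-based half-open in BED sidecars.

# The filtering ladder

`filter_thresholds()` centralizes the defaults:

| filter | default | note |
|---|---|---|
| QD | fail `< 2.0` | hard filter, strict inequality |
| FS | fail `> 60.0` | |
| MQ | fail `< 40.0` | |
| HaplotypeScore | fail `> 13` | |
| MQRankSum | fail `< -13` | see below |
| site mean depth | keep `[4, 10]` | inclusive bounds |
| contig | `> 10 kb`, coverage `< 20x` | eligibility |
| global MAF | `>= 0.01` | called genotypes only |
| within-species MAF | `>= 0.02` | panel stage |
| population missingness | fail `> 50%` in any population | strict |
| LD pruning | 50 kb window, 10 kb step, `r^2 > 0.1` | greedy keep-first |

Two conventions deserve a note.  Hard-filter write-ups sometimes print
the rank-sum bound without its sign; a positive bound would fail
essentially every site, so the default is −13 (the usual convention) and
the value is configurable.  A missing required annotation fails the site
(tag `missing_annot`): that is the conservative reading when a caller
does not emit a statistic.  All per-marker filters are pure predicates,
so masks compose by AND in any order (`combine_masks()`); only LD
pruning is order-sensitive, and it is deterministic (markers are scanned
in position order and a later marker is removed when its r² with a
retained earlier marker in the same window exceeds the threshold).
MAF uses called genotypes only — under 60–77% missingness anything else
would conflate missingness with frequency.

# Species assignment: PCA and admixture

`run_pca()` mean-imputes missing genotypes per marker, centers, and
takes scores from the SVD.  Mean imputation shrinks missing samples
toward the centroid, which is acceptable for visual clustering but is
why assignment is *not* done by eye: `admixture_em()` fits the standard
binomial admixture likelihood

$$\log L(Q, F) = \sum_{ij\ \mathrm{called}} \log\Big[\binom{2}{g_{ij}}
\pi_{ij}^{g_{ij}} (1-\pi_{ij})^{2-g_{ij}}\Big], \qquad
\pi_{ij} = \sum_k Q_{ik} F_{kj},$$

by EM, skipping missing entries.  The log-likelihood is non-decreasing
at every iteration (asserted in the tests).  By default EM starts from
k-means clusters on the leading principal components, with cluster
allele frequencies taken from the implied groups; this starts the chain
close to the dominant structure and typically saves an order of
magnitude in iterations relative to a random start (which remains
available as `init = "random"`).  Convergence is declared when the
log-likelihood gain drops below `tol` (default 1e-4).

Structure analyses are best run on the markers genotyped in every
population (`markers_called_in_all_pops()`, the intersection-set idiom
of variant-calling toolkits).  Under depth-driven missingness this
subset is strongly enriched for well-covered sites — its per-entry
missingness is a fraction of the dataset average — and K selection on it
is markedly more stable than on the full callset, where the
cross-validation contrast between adjacent K values can drown in
missingness noise.

`select_k()` chooses K by masked-genotype cross-validation: called
genotypes are partitioned into folds (default 3), each fold is masked in
turn, and the CV error is the mean squared difference between the
masked dosages and their expectation $2\hat\pi$.  Under-converged fits
systematically penalize larger K — the extra clusters are the slowest
part of the solution to form — so the fold fits should be given enough
iterations (the package uses 200 at its default problem sizes).

`assign_species()` replaces irreproducible visual cluster assignment
with an explicit rule: a sample takes the label of its majority cluster
when `max_k Q_ik >= q_min` (default 0.8) and is otherwise `unassigned`
(hybrids land here by design).  The cluster-to-species label mapping
must be anchored by the user (e.g. from reference samples); label
switching is otherwise undetermined, as in any mixture model.

# Probe candidacy

`flanking_monomorphic_mask()` passes a marker only if no other variant
lies within 35 bp on the same contig; the boundary is inclusive (two
variants exactly 35 bp apart disqualify each other) and the relation is
symmetric.  The screen is run against the *full* called variant list,
not the post-filter survivors — a flanking polymorphism disrupts the
probe whether or not it passed the quality ladder.  `probe_candidates()`
extracts the 71-mer from the reference (erroring on contig edges and on
reference-allele mismatches) and scores each flank.  The vendor's
proprietary per-flank design score is replaced by an openly documented
heuristic with the same four classes (NotPossible for non-ACGT,
NotRecommended for GC outside [0.25, 0.75] or homopolymers of 8+,
Neutral for homopolymers of 6–7, else Recommended); vendor scores can be
substituted from a file (`apply_vendor_scores()`), and downstream
selection keeps only markers Recommended on both flanks.

# Panel assembly

Within each assigned species group, markers need MAF >= 0.02
(`species_pass_masks()`).  `classify_sharing_tiers()` counts, per
marker, the species whose pass set contains it: all four (`shared_all`),
three, two, or exactly one (`exclusive:<species>`).  All shared markers
enter the panel; each species-exclusive pool is thinned uniformly at
random to a quota (default 2,500) over sorted marker ids under a stated
seed, so assembly is a pure function of (pass sets, quotas, priors,
seed).  `merge_prior_markers()` screens previously published markers
exactly like discovery candidates (probe extraction + double-Recommended)
and appends the survivors with `prior:<category>` tiers; a prior
duplicating a discovery marker keeps the prior provenance.  Rejections
are returned with reasons, which is how attrition of a prior pool (810
supplied, fewer designable) stays visible.  `panel_composition()` emits
the design table whose per-tier counts sum to the panel size by
construction — the structural identity of a published 60 K design
(3,268 + 13,185 + 37,554 shared, four exclusive classes, 691 priors,
total 60,142) that the acceptance suite re-checks through
`read_panel_composition()`.

# Validation

`marker_call_rate()` / `cr_scenario_table()` reproduce the
retained-marker scenario tables (CR thresholds 0.90–0.96) for all
samples combined versus per-species runs.  `polymorphism_report()`
classifies each marker with CR >= 0.95 within a group as monomorphic iff
exactly one allele is observed among called genotypes (any heterozygote
shows both), polymorphic otherwise; monomorphic + polymorphic = total
holds for every grouping by construction.  (The published summary table
bundled with the package violates this additivity on one of its four
rows — a transcription inconsistency in the source; the package enforces
the identity rather than reproducing it, and the bundled fixture carries
the printed cells untouched.)  `genotype_concordance()` compares two
datasets individual by individual over the markers called in both,
reporting percent identical dosage with group mean ± SE over
individuals; under the symmetric error model, concordance converges to
100·(1 − err) as markers grow, which the tests verify.

# The synthetic generator

`simulate_dataset()` emulates the study conditions rather than any real
genome: K = 4 species at Balding–Nichols divergence
F = (0.20, 0.20, 0.25, 0.30) around ancestral frequencies uniform on
[0.1, 0.9]; 23 populations of 6 individuals (n = 138), three of them
admixed with 50:50 hybrids; 60 random contigs of 12 kb with markers
placed at a configurable minimum spacing (200 bp by default, so
flanking-monomorphism outcomes are controllable by construction);
lcWGS-style per-species missingness drawn in [0.60, 0.77] with genotype
error 0.05, and array-style missingness in [0, 0.02] with error 0.005.
Genotypes are binomial draws from `pi = Q f`, so Hardy–Weinberg holds
within clusters by construction.

Missingness is genotype-independent (MCAR) by default.  That choice has
one important consequence: at 60–77% MCAR missingness, a
`>50%-missing-in-any-population` filter removes essentially *every*
marker, at any sample size — real low-coverage callsets survive that
filter only because missingness is depth-driven and strongly
site-heterogeneous (well-covered sites are called almost everywhere).
The generator therefore offers a depth-linked mode
(`miss_site_sd > 0`): a per-site logit-normal effect shared across
samples, which concentrates missingness on poorly covered sites.  The
design-funnel fixtures use `miss_site_sd = 2.5` for exactly this reason.
The generator does not simulate reads, recombination, linkage beyond
spacing, or the hemizygosity/presence–absence variation that drives
het-to-hom miscalls on real mussel arrays (a biased error mode,
`het_hom_bias`, gives a first-order emulation).  Passing tests on this
generator therefore demonstrate correctness of the *procedures*, not
performance claims about any real dataset.

# Problem sizes and numerical choices

The package's own test and acceptance runs use deliberately desk-scale
problems: 400–3,000 markers, 46–138 samples, K in 2–6, EM capped at
200–600 iterations with tolerance 1e-3–1e-4, 3-fold CV for K selection.
At these sizes the full suite runs in a few minutes on one core.
Degenerate inputs are handled explicitly: all-missing markers are
dropped from PCA with a message; markers with zero called genotypes
fail frequency filters with tag `no_calls`; zero-variance dosage vectors
yield undefined r² and are never pruned for it; empty exclusive pools
are logged shortfalls, not errors; an individual with no co-called
markers is reported with n = 0 and excluded from concordance means.
Ties in LD pruning are broken deterministically (keep-first in position
order); random thinning draws over *sorted* marker ids so panel
assembly is bit-reproducible across platforms.

# Known limitations

* The heuristic probe scorer is a stand-in with the vendor's *classes*
  but not its model; real designability rates will differ.
* The admixture EM is the classical per-entry update — adequate at desk
  scale, slower than block-relaxation solvers on millions of markers.
* Assignment thresholds (`q_min`) trade hybrid sensitivity against
  species recall; 0.8 is a reasonable default for deeply diverged
  clusters and should be revisited for shallow structure.
* CV-based K selection inherits the usual caveats: it is a model-fit
  criterion, and under-converged fold fits bias it downward.
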