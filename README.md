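# snpanel

Design and validation toolkit for medium-density SNP genotyping arrays
that span several closely related, hybridizing species — the workflow
behind 60 K class multi-species arrays such as the blue mussel
(*Mytilus*) platform, generalized and made fully reproducible.

Blue mussels are farmed at ~2 million tonnes/year, and the four main
cultured species (*M. edulis*, *M. galloprovincialis*, *M. trossulus*,
*M. chilensis*) hybridize wherever they meet.  Building one array that
genotypes all of them requires: filtering millions of variants called
from low-coverage sequencing, assigning samples to species without
relying on morphology, screening probe flanks for hidden polymorphism,
balancing the panel across species, and validating the manufactured
array against the sequencing data it came from.  `snpanel` implements
each stage as composable R functions, with a bundled synthetic
hybrid-zone generator so the entire pipeline runs and is tested without
any external download.

## The models at the core

**Admixture.**  Sample ancestries Q (n x K) and cluster allele
frequencies F (K x m) are estimated by EM on the binomial likelihood

    log L = sum_{ij called} log[ C(2, g_ij) pi_ij^g_ij (1 - pi_ij)^(2 - g_ij) ],
    pi_ij = sum_k Q_ik F_kj,

with missing genotypes skipped, k-means-on-PCA initialization, and K
chosen by masked-genotype cross-validation.  Species labels come from
the majority ancestry with a threshold (default 0.8); admixed samples
stay unassigned.

**Simulation.**  Species allele frequencies follow the Balding–Nichols
model, `f_kj ~ Beta(p(1-F)/F, (1-p)(1-F)/F)`, genotypes are
`Binomial(2, Q f)`, and platform effects (missingness, genotype error,
optional depth-linked site heterogeneity and het-to-hom bias) are
applied on top, with the full truth serialized for testing.

**Probe design.**  Candidates need monomorphic 35 bp flanks against the
full called variant list, a 71-mer extractable from the reference, and a
"Recommended" design class on both flanks (open heuristic, or imported
vendor scores).  Panels are assembled by sharing tier — markers
segregating in all, three, or two species are all kept; species-exclusive
pools are randomly thinned to per-species quotas — then merged with
prior published markers under provenance-preserving deduplication.

## Worked example

```r
library(snpanel)

# a synthetic four-species hybrid zone: 23 populations x 6 samples,
# 3,000 markers, lcWGS-style missingness
d <- simulate_dataset(sim_config(), seed = 11, out_dir = "bundle")

mean(is.na(d$g_lcwgs))          # lcWGS missingness
#> [1] 0.6872899

fit <- admixture_em(d$g_lcwgs, K = 4, seed = 2)
lab <- assign_species(fit, paste0("cluster", 1:4))
table(lab)
#> lab
#>   cluster1   cluster2   cluster3   cluster4 unassigned
#>         36         36         36         12         18
```

The 18 unassigned samples are exactly the three admixed populations of
50:50 hybrids (6 samples each); each cluster maps one-to-one onto a
simulated species (36 = 6 pure populations x 6 samples; 12 = the two
pure *trossulus*-like populations), with zero cross-species confusion
against the generator's truth labels.

Design and validation run the same way from the shell:

```sh
exec/snpanel design   --config design.yaml   --out design_out
exec/snpanel validate --config validate.yaml --out validate_out
```

`design` writes the panel file (71-mers with bracketed alleles), a BED
sidecar of probe footprints, the composition report whose tier counts
sum to the panel size, and a machine-readable funnel log of marker
counts surviving each stage.  `validate` writes call-rate scenario
tables (thresholds 0.90–0.96, all samples combined vs per species),
within-species polymorphism partitions, and per-individual / per-species
array-vs-sequencing concordance (mean ± SE).

## Package layout

| path | contents |
|---|---|
| `R/datamodel.R`, `R/io.R` | typed containers; VCF/FASTA/panel/BED/table IO |
| `R/simulate.R` | Balding–Nichols + admixture generator, platform degradation |
| `R/filters.R` | hard filters, depth/contig, MAF, missingness, LD pruning |
| `R/structure.R` | PCA, admixture EM, K selection, species assignment |
| `R/probes.R` | flank screening, 71-mer extraction, design scoring |
| `R/panel.R` | sharing tiers, quota thinning, prior merge, composition |
| `R/validate.R` | call rates, polymorphism, concordance |
| `R/pipeline.R`, `exec/snpanel` | simulate / design / validate drivers |
| `vignettes/array-design.Rmd` | methods: models, defaults, limitations |
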