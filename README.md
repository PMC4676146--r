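# popclust

Population-structure clustering from multi-sample VCF genotypes.

`popclust` answers a routine question in cohort genomics — *do the
individuals in this VCF fall into their ancestral populations?* — with a
deliberately simple, memory-bounded pipeline:

1. **Stream** one or more VCF files record by record (plain or gzip), keeping
   only the GT subfield of each sample column. Peak memory is independent of
   file length.
2. **Encode** each genotype as its Hamming distance to the reference
   genotype, i.e. the count of non-reference alleles: `0|1 → 1` (heterozygous
   variant), `1|1 → 2` (homozygous variant), `0|0 → 0` (no variant). Zero
   dosages are never stored, giving a sample-major **sparse dosage matrix**.
3. Optionally **drop singleton variants** (sites carried by exactly one
   individual — in the sparse representation, columns of length one) and/or
   **subsample a fraction of variants genome-wide** with a seeded,
   chunk-independent decision per variant.
4. **Cluster** individuals with a from-scratch Lloyd's k-means over the
   sparse rows (dense centroids, k-means++ seeding, cached-norm distance
   expansion ‖x−c‖² = ‖x‖² − 2x·c + ‖c‖²), minimising the within-cluster sum
   of squares (WCSS).
5. **Score** the clustering against annotated population labels (e.g. a
   1000 Genomes panel file) with the adjusted Rand index (Hubert–Arabie
   form),

   ARI = (Σᵢⱼ C(nᵢⱼ,2) − E) / (½[Σᵢ C(aᵢ,2) + Σⱼ C(bⱼ,2)] − E),
   E = Σᵢ C(aᵢ,2) Σⱼ C(bⱼ,2) / C(n,2),

   which is 1 for a perfect match, near 0 for independent labelings, and
   bounded below by −1.
6. **Export** the clustering as a Gephi-loadable GEXF graph: one node per
   individual (annotated with predicted cluster and true label), one hub
   node per cluster, and sample→hub edges weighted by 1/(1+distance to
   centroid).

A bundled **Balding–Nichols simulator** generates structured diploid
cohorts with ground-truth labels, so the whole pipeline is testable without
downloading reference data: per variant an ancestral frequency p is drawn,
each population drifts to its own Beta(p(1−F)/F, (1−p)(1−F)/F) frequency,
and genotypes are Binomial(2, ·).

## Worked example

```r
library(popclust)

dir <- tempfile(); dir.create(dir)
sim <- simulate_cohort(n_pops = 4, samples_per_pop = 100, n_variants = 2000,
                       fst = 0.2, seed = 11,
                       out_vcf = file.path(dir, "cohort.vcf.gz"),
                       out_panel = file.path(dir, "cohort.panel"))

gm <- vcf_to_genotype_matrix(sim$vcf, drop_singletons = TRUE)
gm
#> genotype_matrix: 400 samples x 2000 variants, 529274 stored dosages (66.16% dense)

fit <- kmeans_fit(gm, k = 4, seed = 11, n_restarts = 5)
fit
#> k-means genotype clustering: k = 4, 400 samples, 2000 variants
#>   WCSS 251622.2500 after 2 iterations
#>   cluster sizes: 100 100 100 100

truth  <- read_panel(sim$panel)
labels <- truth_for_samples(truth, gm$sample_ids)
adjusted_rand_index(fit$assignments, labels)
#> [1] 1
contingency_table(fit$assignments, labels)
#> cluster x label contingency table (n = 400 ):
#>        label
#> cluster POP1 POP2 POP3 POP4
#>       1    0    0  100    0
#>       2    0  100    0    0
#>       3  100    0    0    0
#>       4    0    0    0  100

export_gexf(fit, gm, truth, file.path(dir, "cohort.gexf"))
#> 404 nodes, 400 edges
```

At F = 0.2 the four simulated populations are perfectly recovered (ARI 1);
the contingency table shows each cluster capturing exactly one population.
Lowering `fst` toward 0.01 makes the populations merge and the ARI degrade —
the expected behaviour for closely related groups.

The same pipeline is available from a shell via the bundled script
(`inst/exec/popclust` after installation):

```sh
popclust simulate   --pops 4 --samples 100 --variants 2000 --fst 0.2 \
                    --seed 11 --out-vcf cohort.vcf.gz --out-panel cohort.panel
popclust preprocess --vcf cohort.vcf.gz --drop-singletons --out cohort.matrix
popclust cluster    --matrix cohort.matrix --k 4 --restarts 5 --seed 11 --out cohort.model.json
popclust evaluate   --model cohort.model.json --panel cohort.panel --out cohort.metrics.json
popclust export     --model cohort.model.json --matrix cohort.matrix \
                    --panel cohort.panel --out cohort.gexf
```

For real data, point `preprocess` at per-chromosome VCFs (in order) and
`evaluate` at the cohort's panel file (`--label-column super_pop`,
optionally `--exclude AMR` to drop an admixed group before scoring).

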