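---
title: "Clustering population structure from VCF genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering population structure from VCF genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popclust)
```

## The problem and the model

Cohort-scale VCF files record, for every variant site, each individual's
genotype as allele indices (`0|1`, `1|1`, ...). `popclust` asks whether the
individuals cluster into their ancestral populations when each genotype is
reduced to a single number: its *Hamming distance to the reference
genotype*, i.e. the count of non-reference alleles. A heterozygote is 1, a
homozygous variant 2, a homozygous-reference genotype 0. Two deliberate
simplifications follow from this encoding:

* **Allele identity is discarded.** Any non-zero allele index counts as one
  mismatch, so the multi-allelic `1|2` encodes to 2. The pipeline never uses
  which alternate allele an individual carries, only that it differs from
  the reference.
* **Zeros are never stored.** Because most genotypes at most sites are
  homozygous reference, dropping the zeros yields a sparse matrix whose
  memory footprint scales with the number of *variant* genotypes, not with
  samples × sites. Every downstream step (k-means distances included) is
  written against this sparse representation.

Individuals — sparse rows of dosages — are then clustered with Lloyd's
k-means under squared Euclidean distance, with k set to the number of
annotated populations, and the clustering is scored against the annotation
with the adjusted Rand index (ARI). The method makes no attempt to model
linkage disequilibrium, admixture proportions, or allele-frequency
standardisation; it is a direct geometric clustering of raw dosages.

## Preprocessing contracts

`vcf_to_genotype_matrix()` composes the whole chain in a single pass with
peak memory bounded by the retained entries plus one record:

1. *Streaming parse.* Only the GT subfield of each sample column is kept;
   its position is read from the FORMAT column (whole column used when no
   GT is declared). Meta lines are skipped unvalidated — the method uses no
   meta information. Multiple files are concatenated in caller order, and
   record order always follows file order, so variant indices preserve the
   genome loci order. Missing allele tokens (`.`) count as reference: this
   keeps sparsity and matches fully imputed reference panels, but means
   heavy missingness deflates dosages rather than being flagged.
2. *Variant subsampling* (optional). Each variant is retained with
   probability `sample_fraction`. The decision is a deterministic function
   of `(seed, original variant index)`, so the same variants are kept no
   matter how the stream is chunked, and a rerun is bit-identical.
   `sample_fraction = 1` is an exact pass-through.
3. *Singleton filtering* (optional). Variants carried by exactly one
   individual are dropped — in the sparse representation these are simply
   the columns of length one. Columns with *no* carriers are dropped by the
   same switch: they hold no signal. When both toggles are on, sampling runs
   first, so the filter describes the dataset actually clustered. Survivors
   are re-indexed sequentially, preserving order.

Without the filter switch, zero-carrier variants are retained as empty
columns (they still occupy a variant index). They contribute nothing to any
distance, so clustering results are unaffected either way; the choice only
moves the column count.

## k-means: numerical choices

The fitter is a from-scratch Lloyd iteration over sparse rows with dense
centroids (cluster means of sparse rows are generically dense):

* **Distances** use the expansion ‖x−c‖² = ‖x‖² − 2x·c + ‖c‖² with cached
  row norms, so each iteration costs O(stored entries × k) rather than
  O(n·p·k). Cancellation can produce tiny negative values; they are clamped
  at zero.
* **Initialisation** defaults to sequential k-means++ seeding; a plain
  random partition is available, and a fixed k×p centroid matrix is
  accepted for reproducible comparisons against other implementations.
* **Ties** in the assignment step go to the lowest centroid index, always.
* **Empty clusters** are reseeded to the sample currently farthest from its
  own centroid (repeatedly, for multiple empties), after which means are
  recomputed.
* **Convergence**: stop when the largest centroid displacement (Euclidean)
  falls below `tol` (default 1e-4) or after `max_iter` (default 100)
  iterations. The recorded `objective_trace` is the WCSS after each
  assignment-update pair and is non-increasing by construction; a final
  assignment pass makes the stored assignments nearest-centroid consistent
  with the final centroids.
* **Restarts**: `n_restarts` seeded restarts (default 1), lowest WCSS wins.
  For production-style runs on cohort data we use 5 restarts; k-means on
  well-separated populations almost always lands in the same optimum, but
  restarts cheaply insure against an unlucky seeding.

All randomness flows from the `seed` argument through a save/restore
wrapper, so fits are reproducible and never disturb the caller's RNG.

## Scoring

The ARI is computed from the cluster-by-label contingency table in the
Hubert–Arabie form. Two conventions are worth stating because the adjusted
denominator can vanish: when both partitions are degenerate (both a single
cluster, or both all singletons) the index is defined as 1 if they are
identical as set partitions and 0 otherwise — the dominant convention, and
the one that keeps the index inside [−1, 1] with 1 meaning a perfect match.
Samples present in the clustering but absent from the panel raise an error
rather than being silently dropped; silent drops would corrupt any reported
accuracy.

## The simulator: what it emulates and what it does not

`simulate_cohort()` is a Balding–Nichols generator: per variant an ancestral
frequency p is drawn uniformly (default range 0.1–0.9, keeping most sites
informative while still letting drift fix some of them); each population
draws its frequency from Beta(p(1−F)/F, (1−p)(1−F)/F) — mean p, variance
p(1−p)F — and each individual's alternate-allele count is Binomial(2, ·).
Heterozygotes are always written `0|1`: the dosage encoding is phase-blind,
so emitting arbitrary phase would change nothing downstream. Sites that
drift to fixation everywhere are retained on purpose: they exercise the
empty-column path of the encoder.

The defaults (4 populations × 100 individuals × 2,000 unlinked variants,
F = 0.2) are the package's standard validation cohort: large enough that
population structure at continental-scale divergence is unambiguous, small
enough to run end-to-end in seconds. The package's own calibration, run by
the test suite, is that at F = 0.2 the full pipeline recovers the four
populations with ARI ≥ 0.95 in at least 9 of 10 seeds, while at F = 0.01
the median ARI falls below 0.5 as the weakly diverged populations merge —
qualitatively the same behaviour seen on real cohorts, where closely
related groups (e.g. an admixed population and its major source) fuse into
one cluster.

What the simulator does **not** emulate — and therefore what passing tests
do not establish about real data: linkage disequilibrium (sites are
independent, so effective information per variant is higher than in real
genomes), admixed individuals (each sample belongs wholly to one
population), relatedness within populations, genotyping error and
missingness structure, and realistic site-frequency spectra. A real-data
run should treat the simulated calibration as a correctness check of the
machinery, not as a promised accuracy.

## Graph export

`export_gexf()` writes GEXF 1.2 with a bipartite star topology: every
individual connects to its cluster's hub node with weight 1/(1+d), d the
distance to the centroid. All-pairs similarity edges would be quadratic in
cohort size and add nothing a force-directed layout needs; the star gives
Gephi exactly the hub-shaped clusters one wants to recolour by true label.
Output is deterministic — samples in matrix order, hubs last, no
timestamps — so identical inputs give byte-identical files.

## Problem sizes and verification

The test suite verifies each stage against an independent oracle computed a
different way: the dosage encoder against per-token counting over every
diploid allele combination, the streamed sparse pipeline against a dense
in-memory reimplementation on random cohorts, the sparse k-means against a
naive dense Lloyd implementation started from identical centroids (50
random 100 × 1,000 instances), the contingency-table ARI against
brute-force pair counting (200 random label pairs, n ≤ 50) plus an
exhaustive enumeration of all partitions of 6 items into ≤ 3 groups, and
the simulator's drift parameter against a Hudson-style F\_ST estimator.
End-to-end recovery uses 10 seeds at each of F = 0.2 and F = 0.01 on the
default cohort. These sizes were chosen so the whole suite runs in well
under a minute while leaving each comparison statistically meaningful.

## Known limitations

* k is fixed by the user; there is no model selection.
* Raw dosages are clustered without frequency standardisation or PCA, so
  very rare structure signals that projection methods can amplify may be
  missed — mitigated in practice by genome-scale variant counts.
* The streaming reader handles the genotype-bearing subset of VCF 4.x; BCF,
  tabix indexing and INFO/QUAL/FILTER semantics are out of scope.
* Haploid calls are accepted (dosage in [0, 1]) but sex-chromosome ploidy
  is otherwise ignored.
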