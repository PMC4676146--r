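# Independent oracles and fixture builders. Everything here works on dense
# matrices with plain loops, deliberately sharing no code with the package's
# sparse streaming paths.

# Write a small VCF from a dense dosage-free genotype-string matrix
# (variants x samples).
write_fixture_vcf <- function(gt, sample_ids, path,
                              meta = "##fileformat=VCFv4.2") {
  stopifnot(ncol(gt) == length(sample_ids))
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", sample_ids), collapse = "\t")
  body <- vapply(seq_len(nrow(gt)), function(v) {
    paste(c("1", v, ".", "A", "T", ".", ".", ".", "GT", gt[v, ]),
          collapse = "\t")
  }, character(1L))
  writeLines(c(meta, header, body), path)
  path
}

# Dense reference for the dosage encoding, one genotype at a time.
dense_dosage <- function(g) {
  tok <- strsplit(g, "[|/]")[[1L]]
  sum(tok != "." & tok != "0")
}

# Dense reference for the whole preprocessing chain: genotype-string matrix
# (variants x samples) -> dense sample-major dosage matrix, applying the
# same singleton rule.
dense_pipeline <- function(gt, drop_singletons = FALSE) {
  D <- apply(gt, c(1L, 2L), dense_dosage)  # variants x samples
  if (drop_singletons) {
    carriers <- rowSums(D > 0)
    D <- D[carriers >= 2L, , drop = FALSE]
  }
  t(D)
}

# Brute-force pair-counting adjusted Rand index: walk every pair of items,
# count co-clustered agreements, then apply the chance correction.
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (sa && !sb) n10 <- n10 + 1
      else if (!sa && sb) n01 <- n01 + 1
      else n00 <- n00 + 1
    }
  }
  total <- choose(n, 2)
  expected <- (n11 + n10) * (n11 + n01) / total
  max_index <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_index == expected) {
    return(if (n10 == 0 && n01 == 0) 1 else 0)
  }
  (n11 - expected) / (max_index - expected)
}

# Plain dense Lloyd's k-means from given starting centroids, mirroring the
# package's iteration rule (assign with ties to the lowest index, mean
# update, farthest-point reseeding of empty clusters, stop on max centroid
# movement < tol, final reassignment) but computed with naive dense loops.
dense_lloyd <- function(X, C, max_iter = 100L, tol = 1e-4) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- nrow(C)
  dist2 <- function(C) {
    d <- matrix(0, n, k)
    for (i in seq_len(n)) {
      for (c in seq_len(k)) d[i, c] <- sum((X[i, ] - C[c, ])^2)
    }
    d
  }
  for (iter in seq_len(max_iter)) {
    d <- dist2(C)
    assign <- apply(d, 1L, which.min)
    newC <- C
    for (c in seq_len(k)) {
      members <- which(assign == c)
      if (length(members)) newC[c, ] <- colMeans(X[members, , drop = FALSE])
    }
    empties <- which(tabulate(assign, k) == 0L)
    if (length(empties)) {
      per_sample <- d[cbind(seq_len(n), assign)]
      for (e in empties) {
        far <- which.max(per_sample)
        newC[e, ] <- X[far, ]
        per_sample[far] <- -Inf
        assign[far] <- e
      }
      for (c in seq_len(k)) {
        members <- which(assign == c)
        if (length(members)) newC[c, ] <- colMeans(X[members, , drop = FALSE])
      }
    }
    moved <- sqrt(max(rowSums((newC - C)^2)))
    C <- newC
    if (moved < tol) break
  }
  d <- dist2(C)
  assign <- apply(d, 1L, which.min)
  list(centroids = C, assignments = assign,
       objective = sum(d[cbind(seq_len(n), assign)]))
}

# Random sparse variant-column fixtures.
random_columns <- function(n_variants, n_samples, density = 0.2, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n_variants) - 1L, function(idx) {
    carriers <- which(runif(n_samples) < density)
    list(variant_index = idx,
         sample_index = carriers - 1L,
         dosage = sample(1:2, length(carriers), replace = TRUE))
  })
}

# All set partitions of n items into at most k_max blocks, in canonical
# first-occurrence labeling.
enumerate_partitions <- function(n, k_max) {
  grids <- expand.grid(rep(list(seq_len(k_max)), n))
  canon <- apply(grids, 1L, function(v) paste(match(v, unique(v)), collapse = ","))
  lapply(strsplit(unique(canon), ",", fixed = TRUE), as.integer)
}

# Hudson-style Fst estimator from population allele frequencies: ratio of
# averages of between-population variance to total heterozygosity, averaged
# over loci and population pairs.
hudson_fst <- function(freqs, sizes) {
  # freqs: loci x pops sample allele frequencies; sizes: chromosomes per pop
  pairs <- utils::combn(ncol(freqs), 2L)
  num <- den <- 0
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1L, q]; j <- pairs[2L, q]
    p1 <- freqs[, i]; p2 <- freqs[, j]
    n1 <- sizes[i]; n2 <- sizes[j]
    num <- num + sum((p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
                       p2 * (1 - p2) / (n2 - 1))
    den <- den + sum(p1 * (1 - p2) + p2 * (1 - p1))
  }
  num / den
}
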