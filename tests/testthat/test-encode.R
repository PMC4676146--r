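test_that("dosage is the Hamming distance to the reference genotype", {
  # the canonical diploid table: het 1, hom-alt 2, hom-ref 0
  expect_identical(hamming_dosage("0|1"), 1L)
  expect_identical(hamming_dosage("1|1"), 2L)
  expect_identical(hamming_dosage("0|0"), 0L)
  # phasing carries no dosage information
  expect_identical(hamming_dosage("0/1"), hamming_dosage("0|1"))
  # any non-reference allele index is one mismatch
  expect_identical(hamming_dosage(c("1|2", "0|2", "2/2")), c(2L, 1L, 2L))
  # missing tokens count as reference
  expect_identical(hamming_dosage(c("./.", ".|1", ".")), c(0L, 1L, 0L))
  # haploid calls stay within [0, 1]
  expect_identical(hamming_dosage(c("0", "1")), c(0L, 1L))
  expect_identical(hamming_dosage(character(0L)), integer(0L))
  expect_error(hamming_dosage("0|x"), class = "popclust_format_error")
  # agrees with the token-level oracle on every diploid combination
  alleles <- c("0", "1", "2", ".")
  combos <- as.vector(outer(alleles, alleles, paste, sep = "|"))
  expect_identical(hamming_dosage(combos),
                   vapply(combos, dense_dosage, 0L, USE.NAMES = FALSE))
})

test_that("records become sequentially indexed sparse columns", {
  records <- list(
    list(gt_strings = c("0|1", "0|0", "1|1")),
    list(gt_strings = c("0|0", "0|0", "0|0")),
    list(gt_strings = c("0|1", "0|1", "0|0"))
  )
  cols <- records_to_columns(records)
  expect_identical(vapply(cols, `[[`, 0L, "variant_index"), 0:2)
  expect_identical(cols[[1L]]$sample_index, c(0L, 2L))
  expect_identical(cols[[1L]]$dosage, c(1L, 2L))
  # an all-reference site keeps its index but stores nothing
  expect_length(cols[[2L]]$sample_index, 0L)
})

test_that("singleton filter drops length-one and empty columns, re-indexing", {
  cols <- list(
    list(variant_index = 0L, sample_index = 0L, dosage = 2L),           # singleton
    list(variant_index = 1L, sample_index = c(0L, 3L), dosage = c(1L, 1L)),
    list(variant_index = 2L, sample_index = 2L, dosage = 1L),           # singleton
    list(variant_index = 3L, sample_index = integer(0L), dosage = integer(0L)),
    list(variant_index = 4L, sample_index = 0:2, dosage = c(1L, 2L, 1L))
  )
  out <- filter_singletons(cols)
  expect_length(out, 2L)
  expect_identical(vapply(out, `[[`, 0L, "variant_index"), 0:1)
  expect_identical(out[[1L]]$sample_index, c(0L, 3L))
  expect_identical(out[[2L]]$dosage, c(1L, 2L, 1L))
  # idempotent, and a no-singleton input passes through unchanged
  expect_identical(filter_singletons(out), out)
  expect_identical(filter_singletons(list()), list())
})

test_that("variant sampling is seeded, chunk-independent and binomial", {
  cols <- random_columns(10000L, 20L, density = 0.3, seed = 42L)
  expect_identical(sample_columns(cols, 1.0, seed = 5L), cols)
  expect_identical(sample_columns(cols, 0.0, seed = 5L), list())
  expect_error(sample_columns(cols, 1.2), class = "popclust_param_error")
  expect_error(sample_columns(cols, -0.1), class = "popclust_param_error")

  kept <- sample_columns(cols, 0.2, seed = 9L)
  # 3-sigma binomial band around the expectation
  expect_lt(abs(length(kept) - 2000L), 3 * sqrt(10000 * 0.2 * 0.8))
  # reproducible bit-for-bit under the same seed
  expect_identical(sample_columns(cols, 0.2, seed = 9L), kept)
  # a different seed draws a different subset
  expect_false(identical(sample_columns(cols, 0.2, seed = 10L), kept))
})

test_that("sampling keeps the same original variants under any chunking", {
  cols <- random_columns(500L, 5L, density = 0.5, seed = 3L)
  whole <- sample_columns(cols, 0.4, seed = 11L)
  pieces <- list(cols[1:100], cols[101:341], cols[342:500])
  kept_pieces <- unlist(lapply(pieces, function(piece) {
    vapply(Filter(function(col)
      popclust:::variant_uniform(11L, col$variant_index) < 0.4, piece),
      `[[`, 0L, "variant_index")
  }))
  # whole-stream result was re-indexed; compare the per-column payloads
  expect_identical(lapply(whole, `[[`, "sample_index"),
                   lapply(cols[kept_pieces + 1L], `[[`, "sample_index"))
})

test_that("transpose to sample-major rows conserves every entry", {
  cols <- list(
    list(variant_index = 0L, sample_index = c(0L, 2L), dosage = c(1L, 2L)),
    list(variant_index = 1L, sample_index = 0L, dosage = 2L)
  )
  gm <- columns_to_matrix(cols, c("s1", "s2", "s3"))
  expect_identical(dim(gm), c(3L, 2L))
  expect_identical(as.vector(gm$dosage["s1", ]), c(1, 2))
  expect_identical(as.vector(gm$dosage["s2", ]), c(0, 0))
  expect_identical(as.vector(gm$dosage["s3", ]), c(2, 0))

  empty <- columns_to_matrix(list(), c("a", "b"))
  expect_identical(dim(empty), c(2L, 0L))

  expect_error(columns_to_matrix(list(list(variant_index = 0L,
                                           sample_index = 5L, dosage = 1L)),
                                 c("a", "b")),
               class = "popclust_param_error")
})

test_that("double transpose returns the original sparse columns", {
  cols <- random_columns(200L, 50L, density = 0.15, seed = 8L)
  gm <- columns_to_matrix(cols, sprintf("s%02d", 1:50))
  tm <- methods::as(gm$dosage, "TsparseMatrix")
  back <- lapply(seq_len(200L) - 1L, function(idx) {
    sel <- which(tm@j == idx)
    ord <- order(tm@i[sel])
    list(variant_index = idx,
         sample_index = tm@i[sel][ord],
         dosage = as.integer(tm@x[sel][ord]))
  })
  expect_identical(back, cols)
})

test_that("streamed pipeline matches the dense oracle on random cohorts", {
  set.seed(101)
  for (case in 1:4) {
    n_s <- sample(5:40, 1L)
    n_v <- sample(20:200, 1L)
    gt <- matrix(sample(c("0|0", "0|1", "1|1", "0/1", "./."), n_s * n_v,
                        replace = TRUE, prob = c(0.55, 0.2, 0.15, 0.05, 0.05)),
                 nrow = n_v)
    ids <- sprintf("s%03d", seq_len(n_s))
    path <- write_fixture_vcf(gt, ids, tempfile(fileext = ".vcf"))
    for (drop in c(FALSE, TRUE)) {
      gm <- vcf_to_genotype_matrix(path, drop_singletons = drop)
      dense <- dense_pipeline(gt, drop_singletons = drop)
      expect_identical(unname(as.matrix(gm$dosage)),
                       matrix(as.double(dense), nrow = n_s))
      # dosage mass conservation against per-genotype encoding
      expect_equal(sum(gm$dosage), sum(dense))
    }
  }
})

test_that("streamed pipeline equals the list-based composition", {
  set.seed(77)
  gt <- matrix(sample(c("0|0", "0|1", "1|1"), 60L * 30L, replace = TRUE,
                      prob = c(0.6, 0.25, 0.15)), nrow = 60L)
  ids <- sprintf("i%02d", 1:30)
  path <- write_fixture_vcf(gt, ids, tempfile(fileext = ".vcf"))
  streamed <- vcf_to_genotype_matrix(path, sample_fraction = 0.5,
                                     drop_singletons = TRUE, seed = 4L)
  listed <- read_vcf(path)
  cols <- filter_singletons(sample_columns(records_to_columns(listed$records),
                                           0.5, seed = 4L))
  composed <- columns_to_matrix(cols, listed$sample_ids)
  expect_identical(as.matrix(streamed$dosage), as.matrix(composed$dosage))
  expect_identical(attr(streamed, "n_seen"), 60L)
})

test_that("triplet serialisation round-trips bit-exactly", {
  cols <- random_columns(120L, 25L, density = 0.2, seed = 13L)
  gm <- columns_to_matrix(cols, sprintf("id%02d", 1:25))
  path <- tempfile(fileext = ".tsv")
  write_genotype_matrix(gm, path, meta = c(seed = "13"))
  back <- read_genotype_matrix(path)
  expect_identical(back$sample_ids, gm$sample_ids)
  expect_identical(as.matrix(back$dosage), as.matrix(gm$dosage))
  expect_true(any(grepl("^#seed: 13$", readLines(path))))
  # an empty matrix survives too
  empty <- columns_to_matrix(list(), c("a", "b"))
  p2 <- tempfile()
  write_genotype_matrix(empty, p2)
  expect_identical(dim(read_genotype_matrix(p2)), c(2L, 0L))
})
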