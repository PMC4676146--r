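#' Genotype dosage as Hamming distance to the reference genotype
#'
#' Converts GT genotype strings (allele indices separated by `|` or `/`)
#' to the count of non-reference alleles they carry: `"0|1"` is 1 (one
#' heterozygous variant allele), `"1|1"` is 2 (homozygous variant), `"0|0"`
#' is 0 (no variant). Any non-zero allele index counts as one mismatch, so
#' the multi-allelic `"1|2"` is 2 — the identity of the alternate allele is
#' deliberately discarded. Missing allele tokens (`.`) count as reference,
#' and phasing carries no information (`"0/1"` equals `"0|1"`).
#'
#' @param gt character vector of GT subfields.
#' @return integer vector of dosages in `[0, ploidy]`.
#' @examples
#' hamming_dosage(c("0|1", "1|1", "0|0", "0/1", "1|2", "./."))
#' @export
hamming_dosage <- function(gt) {
  if (length(gt) == 0L) return(integer(0L))
  # genotype strings repeat heavily within a site; encode uniques only
  ug <- unique(gt)
  tokens <- strsplit(ug, "[|/]")
  ud <- vapply(tokens, function(tok) {
    bad <- !grepl("^([0-9]+|\\.)$", tok)
    if (any(bad) || length(tok) == 0L) {
      stop_format("malformed GT field '", paste(tok, collapse = "|"), "'")
    }
    sum(tok != "." & tok != "0")
  }, integer(1L))
  ud[match(gt, ug)]
}

# One sparse variant column from a record's genotype strings: only nonzero
# dosages are stored, with 0-based sample indices.
record_to_column <- function(gt_strings, variant_index) {
  d <- hamming_dosage(gt_strings)
  keep <- which(d > 0L)
  list(
    variant_index = as.integer(variant_index),
    sample_index = keep - 1L,
    dosage = d[keep]
  )
}

#' Encode variant records as sparse dosage columns
#'
#' One column per record, in input order, carrying only the nonzero dosages
#' as (0-based sample index, dosage) pairs. Variant indices are assigned
#' sequentially from 0 in stream order, preserving the genome loci order;
#' columns in which no individual carries a variant still receive an index
#' but hold no entries.
#'
#' @param records list of variant records (see [read_vcf()]).
#' @return list of variant columns, each with `variant_index`,
#'   `sample_index` and `dosage`.
#' @export
records_to_columns <- function(records) {
  lapply(seq_along(records), function(i) {
    record_to_column(records[[i]]$gt_strings, i - 1L)
  })
}

#' Drop singleton (and empty) variant columns
#'
#' Removes variants carried by exactly one individual — in the sparse
#' representation these are simply the columns of length one — together
#' with columns that hold no variant at all. Survivors are re-indexed
#' sequentially from 0, preserving order. The operation is idempotent.
#'
#' @param columns list of variant columns.
#' @return filtered, re-indexed list of variant columns.
#' @export
filter_singletons <- function(columns) {
  kept <- Filter(function(col) length(col$sample_index) >= 2L, columns)
  reindex_columns(kept)
}

reindex_columns <- function(columns) {
  for (i in seq_along(columns)) {
    columns[[i]]$variant_index <- i - 1L
  }
  columns
}

#' Subsample variant columns genome-wide
#'
#' Retains each column independently with probability `fraction`, using a
#' deterministic pseudo-random stream derived from `(seed, variant_index)`,
#' so the decision for a given variant does not depend on how the stream
#' was chunked. Retained columns are re-indexed sequentially. `fraction = 1`
#' is an exact pass-through and `fraction = 0` yields nothing.
#'
#' @param columns list of variant columns.
#' @param fraction retention probability in `[0, 1]`.
#' @param seed integer seed for the sampling stream.
#' @return filtered, re-indexed list of variant columns.
#' @export
sample_columns <- function(columns, fraction, seed = 1L) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      is.na(fraction) || fraction < 0 || fraction > 1) {
    stop_param("fraction must be a single number in [0, 1]")
  }
  if (fraction == 1) return(columns)
  if (fraction == 0) return(list())
  kept <- Filter(function(col) {
    variant_uniform(seed, col$variant_index) < fraction
  }, columns)
  reindex_columns(kept)
}

#' Transpose variant columns into a sample-major sparse dosage matrix
#'
#' Groups the per-variant entries by individual, producing one sparse row
#' per sample. Entry count is conserved by the transpose, and the dosage
#' values are untouched.
#'
#' @param columns list of re-indexed variant columns.
#' @param sample_ids ordered character vector of sample identifiers.
#' @param n_variants total variant count; defaults to the number of
#'   columns supplied.
#' @return a [genotype_matrix] object.
#' @export
columns_to_matrix <- function(columns, sample_ids,
                              n_variants = length(columns)) {
  n_samples <- length(sample_ids)
  i <- unlist(lapply(columns, `[[`, "sample_index"), use.names = FALSE)
  j <- unlist(lapply(columns, function(col) {
    rep.int(col$variant_index, length(col$sample_index))
  }), use.names = FALSE)
  x <- unlist(lapply(columns, `[[`, "dosage"), use.names = FALSE)
  if (is.null(i)) i <- integer(0L)
  if (is.null(j)) j <- integer(0L)
  if (is.null(x)) x <- integer(0L)
  if (length(i) && (min(i) < 0L || max(i) >= n_samples)) {
    stop_param("sample index out of range for ", n_samples, " samples")
  }
  if (length(j) && max(j) >= n_variants) {
    stop_param("variant index out of range for ", n_variants, " variants")
  }
  genotype_matrix(
    Matrix::sparseMatrix(i = i + 1L, j = j + 1L, x = as.double(x),
                         dims = c(n_samples, as.integer(n_variants))),
    sample_ids
  )
}

#' Sample-major sparse genotype dosage matrix
#'
#' A light container pairing a `Matrix::dgCMatrix` of dosages (samples in
#' rows, variants in columns) with the sample identifiers.
#'
#' @param dosage a sparse dosage matrix (samples x variants).
#' @param sample_ids character vector, one per row.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, sample_ids) {
  dosage <- methods::as(methods::as(dosage, "CsparseMatrix"), "generalMatrix")
  if (nrow(dosage) != length(sample_ids)) {
    stop_param("dosage matrix has ", nrow(dosage), " rows but ",
               length(sample_ids), " sample IDs were given")
  }
  rownames(dosage) <- sample_ids
  structure(list(dosage = dosage, sample_ids = as.character(sample_ids)),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' @export
print.genotype_matrix <- function(x, ...) {
  nnz <- length(x$dosage@x)
  cat(sprintf(
    "genotype_matrix: %d samples x %d variants, %d stored dosages (%.2f%% dense)\n",
    nrow(x$dosage), ncol(x$dosage), nnz,
    if (prod(dim(x$dosage)) > 0) 100 * nnz / prod(dim(x$dosage)) else 0))
  invisible(x)
}

#' Stream one or more VCF files into a genotype matrix
#'
#' Single-pass composition of the preprocessing chain: read records in file
#' order, encode each as a sparse dosage column, optionally subsample
#' variants (decided per original variant index, so reproducible under any
#' chunking), optionally drop singleton variants, and transpose into a
#' sample-major sparse matrix. Sampling is applied before the singleton
#' filter, so filtering acts on the dataset actually clustered. Peak memory
#' is bounded by the retained entries plus one record.
#'
#' @param paths one or more VCF paths, concatenated in the order given;
#'   all must declare the same samples.
#' @param sample_fraction fraction of variants to retain (default 1).
#' @param drop_singletons drop variants carried by exactly one individual
#'   (zero-carrier variants are dropped too).
#' @param seed seed for the variant-sampling stream.
#' @return a [genotype_matrix]; attributes `n_seen`, `n_sampled_out` and
#'   `n_singletons_dropped` record the stream accounting.
#' @export
vcf_to_genotype_matrix <- function(paths, sample_fraction = 1,
                                   drop_singletons = FALSE, seed = 1L) {
  if (!is.numeric(sample_fraction) || length(sample_fraction) != 1L ||
      is.na(sample_fraction) || sample_fraction < 0 || sample_fraction > 1) {
    stop_param("sample_fraction must be a single number in [0, 1]")
  }
  cap <- 4096L
  ti <- integer(cap); tj <- integer(cap); tx <- integer(cap)
  n_entries <- 0L
  sample_ids <- NULL
  seen <- 0L          # original sequential variant index counter
  kept <- 0L          # retained (re-indexed) variant counter
  sampled_out <- 0L
  singletons <- 0L
  for (path in paths) {
    rdr <- open_vcf(path)
    if (is.null(sample_ids)) {
      sample_ids <- rdr$sample_ids
    } else if (!identical(sample_ids, rdr$sample_ids)) {
      rdr$close()
      stop_format("sample columns of ", path,
                  " do not match the first input file")
    }
    repeat {
      rec <- rdr$next_record()
      if (is.null(rec)) break
      idx <- seen
      seen <- seen + 1L
      if (sample_fraction < 1) {
        if (sample_fraction == 0 ||
            variant_uniform(seed, idx) >= sample_fraction) {
          sampled_out <- sampled_out + 1L
          next
        }
      }
      col <- record_to_column(rec$gt_strings, idx)
      nnz <- length(col$sample_index)
      if (drop_singletons && nnz < 2L) {
        singletons <- singletons + 1L
        next
      }
      if (nnz > 0L) {
        while (n_entries + nnz > cap) {
          cap <- cap * 2L
          length(ti) <- cap; length(tj) <- cap; length(tx) <- cap
        }
        slot <- (n_entries + 1L):(n_entries + nnz)
        ti[slot] <- col$sample_index
        tj[slot] <- kept
        tx[slot] <- col$dosage
        n_entries <- n_entries + nnz
      }
      kept <- kept + 1L
    }
  }
  if (is.null(sample_ids)) stop_param("no input files given")
  gm <- genotype_matrix(
    Matrix::sparseMatrix(i = ti[seq_len(n_entries)] + 1L,
                         j = tj[seq_len(n_entries)] + 1L,
                         x = as.double(tx[seq_len(n_entries)]),
                         dims = c(length(sample_ids), kept)),
    sample_ids
  )
  attr(gm, "n_seen") <- seen
  attr(gm, "n_sampled_out") <- sampled_out
  attr(gm, "n_singletons_dropped") <- singletons
  gm
}

#' Write a genotype matrix as a plain-text sparse triplet file
#'
#' Documented on-disk format: two comment lines carrying the sample IDs and
#' the variant count, a column header, then one `sample_index`,
#' `variant_index`, `dosage` triplet per stored entry (0-based indices,
#' sorted by sample then variant). Round-trips bit-exactly through
#' [read_genotype_matrix()].
#'
#' @param gm a [genotype_matrix].
#' @param dest output path.
#' @param meta optional named character vector written as extra `#key: value`
#'   comment lines (e.g. the seed that produced the matrix).
#' @return `dest`, invisibly.
#' @export
write_genotype_matrix <- function(gm, dest, meta = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  tm <- methods::as(gm$dosage, "TsparseMatrix")
  ord <- order(tm@i, tm@j)  # sample-major order
  lines <- c(
    paste0("#samples: ", paste(gm$sample_ids, collapse = "\t")),
    paste0("#n_variants: ", ncol(gm$dosage)),
    if (!is.null(meta)) paste0("#", names(meta), ": ", meta),
    "sample_index\tvariant_index\tdosage",
    if (length(ord)) {
      paste(tm@i[ord], tm@j[ord], format(tm@x[ord], trim = TRUE,
                                         scientific = FALSE), sep = "\t")
    }
  )
  status <- tryCatch(writeLines(lines, dest),
                     error = function(e) stop_io("cannot write ", dest),
                     warning = function(w) stop_io("cannot write ", dest))
  invisible(dest)
}

#' Read a genotype matrix written by [write_genotype_matrix()]
#'
#' @param path triplet file path.
#' @return a [genotype_matrix].
#' @export
read_genotype_matrix <- function(path) {
  if (!file.exists(path)) stop_io("cannot open matrix file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  samp_line <- grep("^#samples: ", hdr, value = TRUE)
  nvar_line <- grep("^#n_variants: ", hdr, value = TRUE)
  if (length(samp_line) != 1L || length(nvar_line) != 1L) {
    stop_format("not a genotype matrix file: ", path)
  }
  sample_ids <- strsplit(sub("^#samples: ", "", samp_line), "\t",
                         fixed = TRUE)[[1L]]
  n_variants <- as.integer(sub("^#n_variants: ", "", nvar_line))
  body <- lines[!grepl("^#", lines)][-1L]  # drop the column header
  if (length(body)) {
    parts <- matrix(as.numeric(unlist(strsplit(body, "\t", fixed = TRUE),
                                      use.names = FALSE)),
                    ncol = 3L, byrow = TRUE)
  } else {
    parts <- matrix(numeric(0L), ncol = 3L)
  }
  genotype_matrix(
    Matrix::sparseMatrix(i = parts[, 1L] + 1L, j = parts[, 2L] + 1L,
                         x = parts[, 3L],
                         dims = c(length(sample_ids), n_variants)),
    sample_ids
  )
}
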