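#' Cluster-by-label contingency table
#'
#' Co-occurrence counts between a predicted clustering and annotated labels;
#' the pair-counting quantities behind the adjusted Rand index.
#'
#' @param pred vector of predicted cluster assignments.
#' @param truth vector of annotated labels, same length.
#' @return object of class `popclust_contingency`: list with `counts`
#'   (clusters x labels matrix), `row_sums`, `col_sums` and `n`.
#' @export
contingency_table <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop_param("pred and truth have different lengths (",
               length(pred), " vs ", length(truth), ")")
  }
  if (length(pred) == 0L) stop_param("empty labelings")
  counts <- unclass(table(cluster = as.character(pred),
                          label = as.character(truth)))
  structure(
    list(counts = counts, row_sums = rowSums(counts),
         col_sums = colSums(counts), n = length(pred)),
    class = "popclust_contingency"
  )
}

#' @export
print.popclust_contingency <- function(x, ...) {
  cat("cluster x label contingency table (n =", x$n, "):\n")
  print(x$counts)
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between a predicted clustering and a reference
#' labeling (Hubert-Arabie form), computed from the contingency table:
#' \deqn{ARI = \frac{\sum_{ij} \binom{n_{ij}}{2} - E}{\tfrac12\left[\sum_i
#'   \binom{a_i}{2} + \sum_j \binom{b_j}{2}\right] - E}, \quad
#'   E = \sum_i \binom{a_i}{2} \sum_j \binom{b_j}{2} / \binom{n}{2}.}
#' Returns 1 for identical partitions, values near 0 for independent
#' labelings, and is bounded below by -1. Label names are immaterial: the
#' index is invariant under relabeling of either argument and symmetric in
#' the two. For degenerate partition pairs where the adjustment denominator
#' vanishes (both one-cluster, or both all-singletons) the index is 1 if the
#' two are identical as set partitions and 0 otherwise.
#'
#' @param pred,truth equal-length label vectors (length >= 2).
#' @return a number in `[-1, 1]`.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))  # 1
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))          # -0.5
#' @export
adjusted_rand_index <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop_param("pred and truth have different lengths (",
               length(pred), " vs ", length(truth), ")")
  }
  n <- length(pred)
  if (n < 2L) stop_param("need at least two samples to score a clustering")
  ct <- contingency_table(pred, truth)
  sum_ij <- sum(choose(ct$counts, 2))
  sum_a <- sum(choose(ct$row_sums, 2))
  sum_b <- sum(choose(ct$col_sums, 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    same <- identical(partition_canonical(pred), partition_canonical(truth))
    return(if (same) 1 else 0)
  }
  (sum_ij - expected) / (max_index - expected)
}

# First-occurrence canonical form of a partition, so set-partition identity
# ignores label names.
partition_canonical <- function(labels) {
  match(labels, unique(labels))
}

#' Read a population panel file
#'
#' Reads a tab-separated sample-to-population annotation table in the
#' dialect distributed with the 1000 Genomes Project: a header line naming
#' the columns (`sample`, `pop`, `super_pop`, optionally `gender`, in any
#' order), one row per sample.
#'
#' @param path panel file path.
#' @param column label column to use, e.g. `"super_pop"` (default) for the
#'   coarse ancestry grouping or `"pop"` for fine-grained populations.
#' @return named character vector mapping sample ID to population label.
#' @export
read_panel <- function(path, column = "super_pop") {
  if (!file.exists(path)) stop_io("cannot open panel file: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (!"sample" %in% names(tab)) {
    stop_format("panel file ", path, " has no 'sample' column")
  }
  if (!column %in% names(tab)) {
    stop_format("panel file ", path, " has no '", column, "' column")
  }
  if (anyDuplicated(tab$sample)) {
    dup <- tab$sample[duplicated(tab$sample)][1L]
    stop_format("duplicate sample '", dup, "' in panel file ", path)
  }
  stats::setNames(tab[[column]], tab$sample)
}

#' Align annotated labels with a set of samples
#'
#' Looks up each sample's label, failing loudly on any sample missing from
#' the panel — silently dropping unlabeled samples would corrupt any
#' accuracy claim made downstream.
#'
#' @param truth named character vector from [read_panel()].
#' @param sample_ids sample IDs to score, in order.
#' @return character vector of labels aligned with `sample_ids`.
#' @export
truth_for_samples <- function(truth, sample_ids) {
  missing <- setdiff(sample_ids, names(truth))
  if (length(missing)) {
    stop_param("sample(s) absent from the panel: ",
               paste(utils::head(missing, 5L), collapse = ", "),
               if (length(missing) > 5L) ", ...")
  }
  unname(truth[sample_ids])
}

#' Drop samples with excluded population labels
#'
#' Removes from the matrix (and the truth mapping) every sample whose
#' annotated label is in `exclude_labels` — e.g. dropping the admixed AMR
#' super-population before clustering. Variant indices are unchanged.
#'
#' @param gm a [genotype_matrix].
#' @param truth named character vector mapping sample ID to label.
#' @param exclude_labels character vector of labels to drop; a label not
#'   present among the annotations raises a warning, not an error.
#' @return list with the subset `matrix` and `truth`.
#' @export
subset_samples <- function(gm, truth, exclude_labels = character(0L)) {
  stopifnot(inherits(gm, "genotype_matrix"))
  labels <- truth_for_samples(truth, gm$sample_ids)
  unknown <- setdiff(exclude_labels, unique(labels))
  if (length(unknown)) {
    warning("exclude label(s) not present among annotations: ",
            paste(unknown, collapse = ", "))
  }
  keep <- !(labels %in% exclude_labels)
  sub <- genotype_matrix(gm$dosage[keep, , drop = FALSE],
                         gm$sample_ids[keep])
  list(matrix = sub, truth = truth[names(truth) %in% sub$sample_ids])
}
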