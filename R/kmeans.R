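#' Lloyd's k-means over sparse sample rows
#'
#' From-scratch k-means for genotype dosage matrices: samples are sparse
#' rows, centroids are dense (cluster means of sparse rows are generically
#' dense). Distances use the expansion \eqn{\|x-c\|^2 = \|x\|^2 - 2 x \cdot c
#' + \|c\|^2} with cached norms, so the cost of an iteration scales with the
#' number of stored dosages rather than the full sample-by-variant product —
#' the same memory argument that motivates the sparse encoding in the first
#' place. Absent entries are zeros (homozygous reference).
#'
#' Each iteration assigns every sample to its nearest centroid (ties to the
#' lowest centroid index) and recomputes centroids as cluster means; a
#' cluster left empty is reseeded to the sample currently farthest from its
#' assigned centroid. Iteration stops when the largest centroid displacement
#' falls below `tol` or after `max_iter` iterations. Among `n_restarts`
#' seeded restarts the fit with the lowest within-cluster sum of squares
#' (WCSS) is returned. Fully reproducible given `seed`.
#'
#' @param x a [genotype_matrix], or any matrix coercible to a sparse matrix
#'   with samples in rows.
#' @param k number of clusters, `1 <= k <=` number of samples.
#' @param max_iter maximum Lloyd iterations per restart.
#' @param tol convergence threshold on the maximum centroid movement
#'   (Euclidean norm).
#' @param seed integer seed governing initialisation.
#' @param init `"plusplus"` for k-means++ seeding (default), `"random-partition"`
#'   for a random initial partition, or a numeric `k x n_variants` matrix of
#'   starting centroids.
#' @param n_restarts number of seeded restarts; the lowest-WCSS fit wins.
#' @return object of class `popclust_km` with elements `k`, `centroids`
#'   (`k x n_variants` dense matrix), `assignments` (1-based cluster index
#'   per sample), `objective` (final WCSS), `n_iter`, `objective_trace`
#'   (WCSS after each iteration), `sample_ids` and `seed`.
#' @examples
#' gm <- columns_to_matrix(
#'   list(list(variant_index = 0L, sample_index = c(0L, 1L), dosage = c(2L, 2L)),
#'        list(variant_index = 1L, sample_index = 2L, dosage = 2L)),
#'   c("a", "b", "c"))
#' fit <- kmeans_fit(gm, k = 2, seed = 1)
#' fit$assignments
#' @export
kmeans_fit <- function(x, k, max_iter = 100L, tol = 1e-4, seed = 1L,
                       init = c("plusplus", "random-partition"),
                       n_restarts = 1L) {
  X <- as_dosage_sparse(x)
  sample_ids <- if (inherits(x, "genotype_matrix")) x$sample_ids else rownames(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n == 0L || p == 0L) stop_param("cannot cluster an empty matrix")
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k != round(k)) {
    stop_param("k must be a positive integer")
  }
  k <- as.integer(k)
  if (k > n) stop_param("k (", k, ") exceeds the number of samples (", n, ")")
  if (max_iter < 1L) stop_param("max_iter must be >= 1")
  if (tol < 0) stop_param("tol must be >= 0")
  fixed_init <- is.numeric(init) && is.matrix(init)
  if (!fixed_init) init <- match.arg(init)

  rn2 <- Matrix::rowSums(X^2)  # cached squared row norms
  best <- NULL
  for (r in seq_len(n_restarts)) {
    C0 <- if (fixed_init) {
      if (!all(dim(init) == c(k, p))) {
        stop_param("init centroid matrix must be ", k, " x ", p)
      }
      init
    } else {
      init_centroids(X, rn2, k, init, seed = seed + (r - 1L))
    }
    fit <- lloyd_iterate(X, rn2, C0, max_iter, tol)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }

  structure(
    list(k = k, centroids = best$centroids, assignments = best$assignments,
         objective = best$objective, n_iter = best$n_iter,
         objective_trace = best$trace, sample_ids = sample_ids, seed = seed),
    class = "popclust_km"
  )
}

as_dosage_sparse <- function(x) {
  if (inherits(x, "genotype_matrix")) return(x$dosage)
  methods::as(methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix"),
              "dMatrix")
}

# Squared Euclidean distances from every row of X to every centroid,
# n x k, clamped at zero against cancellation.
sq_dist_to_centroids <- function(X, rn2, C) {
  cross <- as.matrix(X %*% t(C))
  d2 <- sweep(-2 * cross, 2L, rowSums(C^2), `+`) + rn2
  d2[d2 < 0] <- 0
  d2
}

init_centroids <- function(X, rn2, k, method, seed) {
  n <- nrow(X)
  with_seed(seed, {
    if (method == "plusplus") {
      idx <- integer(k)
      idx[1L] <- sample.int(n, 1L)
      d2 <- sq_dist_to_centroids(X, rn2, as_dense_rows(X, idx[1L]))[, 1L]
      if (k > 1L) {
        for (j in 2:k) {
          if (sum(d2) <= 0) {
            idx[j] <- sample.int(n, 1L)
          } else {
            idx[j] <- sample.int(n, 1L, prob = d2 / sum(d2))
          }
          d2 <- pmin(d2, sq_dist_to_centroids(X, rn2,
                                              as_dense_rows(X, idx[j]))[, 1L])
        }
      }
      as_dense_rows(X, idx)
    } else {
      part <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))[sample.int(n)]
      centroid_means(X, part, k)
    }
  })
}

as_dense_rows <- function(X, idx) {
  matrix(as.matrix(X[idx, , drop = FALSE]), nrow = length(idx))
}

# Cluster mean matrix (k x p) via sparse aggregation; clusters may be empty
# (rows of zeros), flagged by the caller through the size vector.
centroid_means <- function(X, assign, k) {
  M <- Matrix::sparseMatrix(i = assign, j = seq_along(assign), x = 1,
                            dims = c(k, length(assign)))
  sizes <- tabulate(assign, nbins = k)
  C <- as.matrix(M %*% X)
  nz <- sizes > 0L
  C[nz, ] <- C[nz, , drop = FALSE] / sizes[nz]
  C
}

lloyd_iterate <- function(X, rn2, C, max_iter, tol) {
  n <- nrow(X)
  k <- nrow(C)
  trace <- numeric(0L)
  assign <- integer(n)
  for (iter in seq_len(max_iter)) {
    d2 <- sq_dist_to_centroids(X, rn2, C)
    assign <- max.col(-d2, ties.method = "first")
    newC <- centroid_means(X, assign, k)
    sizes <- tabulate(assign, nbins = k)
    empties <- which(sizes == 0L)
    if (length(empties)) {
      # reseed each empty centroid to the sample farthest from its own
      # current centroid, removing it from its donor cluster
      per_sample <- d2[cbind(seq_len(n), assign)]
      for (e in empties) {
        far <- which.max(per_sample)
        newC[e, ] <- as_dense_rows(X, far)
        per_sample[far] <- -Inf
        assign[far] <- e
      }
      newC <- centroid_means(X, assign, k)
    }
    moved <- sqrt(max(rowSums((newC - C)^2)))
    C <- newC
    d2 <- sq_dist_to_centroids(X, rn2, C)
    trace <- c(trace, sum(d2[cbind(seq_len(n), assign)]))
    if (moved < tol) break
  }
  # final assignment pass so assignments are nearest-centroid consistent
  d2 <- sq_dist_to_centroids(X, rn2, C)
  assign <- max.col(-d2, ties.method = "first")
  list(centroids = C, assignments = assign,
       objective = sum(d2[cbind(seq_len(n), assign)]),
       n_iter = iter, trace = trace)
}

#' Assign samples to the nearest centroid of a fitted model
#'
#' @param object a fitted `popclust_km` model.
#' @param newdata a [genotype_matrix] (or matrix) with the same number of
#'   variants the model was fitted on.
#' @param ... unused.
#' @return integer vector of 1-based cluster assignments; ties go to the
#'   lowest centroid index.
#' @export
predict.popclust_km <- function(object, newdata, ...) {
  X <- as_dosage_sparse(newdata)
  if (ncol(X) != ncol(object$centroids)) {
    stop_param("matrix has ", ncol(X), " variants but model expects ",
               ncol(object$centroids))
  }
  d2 <- sq_dist_to_centroids(X, Matrix::rowSums(X^2), object$centroids)
  max.col(-d2, ties.method = "first")
}

#' @export
print.popclust_km <- function(x, ...) {
  cat(sprintf("k-means genotype clustering: k = %d, %d samples, %d variants\n",
              x$k, length(x$assignments), ncol(x$centroids)))
  cat(sprintf("  WCSS %.4f after %d iterations\n", x$objective, x$n_iter))
  cat("  cluster sizes:", tabulate(x$assignments, nbins = x$k), "\n")
  invisible(x)
}

#' @export
summary.popclust_km <- function(object, ...) {
  out <- list(k = object$k, n = length(object$assignments),
              sizes = tabulate(object$assignments, nbins = object$k),
              objective = object$objective, n_iter = object$n_iter,
              trace = object$objective_trace)
  class(out) <- "summary.popclust_km"
  out
}

#' @export
print.summary.popclust_km <- function(x, ...) {
  cat(sprintf("k = %d over %d samples; WCSS %.4f in %d iterations\n",
              x$k, x$n, x$objective, x$n_iter))
  cat("cluster sizes:", x$sizes, "\n")
  cat("WCSS trace:", format(x$trace, digits = 6), "\n")
  invisible(x)
}

#' Save a fitted k-means model as JSON
#'
#' Serialises centroids, assignments, objective and provenance (seed) to a
#' plain-text JSON file that [read_kmeans_model()] restores exactly.
#'
#' @param model a `popclust_km` fit.
#' @param dest output path.
#' @return `dest`, invisibly.
#' @export
write_kmeans_model <- function(model, dest) {
  stopifnot(inherits(model, "popclust_km"))
  payload <- list(
    format = "popclust-kmeans-v1",
    k = model$k,
    n_variants = ncol(model$centroids),
    centroids = apply(model$centroids, 1L, identity, simplify = FALSE),
    assignments = model$assignments,
    objective = model$objective,
    n_iter = model$n_iter,
    objective_trace = model$objective_trace,
    sample_ids = model$sample_ids,
    seed = model$seed
  )
  tryCatch(
    jsonlite::write_json(payload, dest, auto_unbox = TRUE, digits = NA),
    error = function(e) stop_io("cannot write model to ", dest),
    warning = function(w) stop_io("cannot write model to ", dest)
  )
  invisible(dest)
}

#' Load a k-means model saved by [write_kmeans_model()]
#'
#' @param path model file path.
#' @return a `popclust_km` object.
#' @export
read_kmeans_model <- function(path) {
  if (!file.exists(path)) stop_io("cannot open model file: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "popclust-kmeans-v1")) {
    stop_format("not a popclust k-means model file: ", path)
  }
  centroids <- if (payload$k == 1L && is.numeric(payload$centroids)) {
    matrix(payload$centroids, nrow = 1L)
  } else if (is.list(payload$centroids)) {
    do.call(rbind, payload$centroids)
  } else {
    as.matrix(payload$centroids)
  }
  structure(
    list(k = as.integer(payload$k), centroids = unname(centroids),
         assignments = as.integer(payload$assignments),
         objective = payload$objective, n_iter = as.integer(payload$n_iter),
         objective_trace = as.numeric(payload$objective_trace),
         sample_ids = as.character(payload$sample_ids),
         seed = payload$seed),
    class = "popclust_km"
  )
}
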