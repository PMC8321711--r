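#' Build a bag-of-visual-words codebook by k-means
#'
#' Pools the descriptors of the training images and clusters them with
#' k-means: seeded k-means++ initialization followed by at most
#' `iterations` full Lloyd passes (the method's "Iter" budget; one pass
#' already yields a usable vocabulary). Assignment ties go to the
#' lowest centroid index and a centroid whose cluster empties keeps its
#' previous position. Fully deterministic given `(descriptors, k,
#' iterations, seed)`.
#'
#' @param training_sets a list of `keypoint_descriptor_set` objects (or a
#'   single one), all with the same descriptor length.
#' @param k vocabulary size (>= 1); the pooled descriptor count must be at
#'   least `k`.
#' @param iterations Lloyd pass budget (>= 0; 0 returns the k-means++
#'   initialization).
#' @param seed integer seed.
#' @param max_descriptors optional cap: when the pool is larger, cluster a
#'   seeded subsample of this size (at least `k`).
#' @return A `bow_codebook`: list with `centroids` (k x d matrix), `k`,
#'   `iterations`, `seed`.
#' @export
build_codebook <- function(training_sets, k, iterations = 1L, seed = 1L,
                           max_descriptors = Inf) {
  if (inherits(training_sets, "keypoint_descriptor_set")) training_sets <- list(training_sets)
  mats <- lapply(training_sets, function(s) s$descriptors)
  X <- do.call(rbind, mats)
  k <- as.integer(k); iterations <- as.integer(iterations)
  if (k < 1L) stop_param("k must be >= 1", field = "k")
  if (iterations < 0L) stop_param("iterations must be >= 0", field = "iterations")
  if (is.null(X) || nrow(X) < k) {
    stop_data(sprintf("need at least k = %d pooled descriptors, got %d", k, if (is.null(X)) 0L else nrow(X)))
  }
  if (anyNA(X) || any(!is.finite(X))) stop_data("descriptors contain non-finite values")
  if (is.finite(max_descriptors) && nrow(X) > max(max_descriptors, k)) {
    X <- with_seed(derive_seed(seed, "pool"),
                   X[sort(sample.int(nrow(X), max(max_descriptors, k))), , drop = FALSE])
  }
  cent <- with_seed(seed, {
    C <- kmeanspp_init(X, k)
    lloyd(X, C, iterations)
  })
  structure(list(centroids = cent, k = k, iterations = iterations,
                 seed = as.integer(seed)),
            class = "bow_codebook")
}

# Squared Euclidean distances between rows of X (n x d) and C (k x d).
pairwise_sqdist <- function(X, C) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
  pmax(d2, 0)
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- pairwise_sqdist(X, X[idx[1L], , drop = FALSE])[, 1L]
  if (k > 1L) {
    for (j in 2:k) {
      tot <- sum(d2)
      idx[j] <- if (tot <= 0) sample.int(n, 1L) else sample.int(n, 1L, prob = d2 / tot)
      d2 <- pmin(d2, pairwise_sqdist(X, X[idx[j], , drop = FALSE])[, 1L])
    }
  }
  X[idx, , drop = FALSE]
}

lloyd <- function(X, C, iterations) {
  for (it in seq_len(iterations)) {
    assign <- max.col(-pairwise_sqdist(X, C), ties.method = "first")
    for (j in seq_len(nrow(C))) {
      members <- assign == j
      if (any(members)) C[j, ] <- colMeans(X[members, , drop = FALSE])
    }
  }
  C
}

#' Encode a descriptor set against a codebook
#'
#' Assigns each descriptor to its nearest centroid (Euclidean distance,
#' ties to the lowest index) and returns the k-length occurrence histogram.
#' An empty descriptor set encodes to the all-zero vector, also under
#' normalization.
#'
#' @param descriptors a `keypoint_descriptor_set`.
#' @param codebook a [build_codebook()] result.
#' @param normalize L1-normalize the histogram (sums to 1 unless empty).
#' @return A numeric vector of length `codebook$k`.
#' @export
bow_encode <- function(descriptors, codebook, normalize = TRUE) {
  stopifnot(inherits(codebook, "bow_codebook"))
  X <- descriptors$descriptors
  if (!is.null(X) && nrow(X) > 0L && ncol(X) != ncol(codebook$centroids)) {
    stop_dim(sprintf("descriptor length %d does not match codebook length %d",
                     ncol(X), ncol(codebook$centroids)))
  }
  h <- numeric(codebook$k)
  if (!is.null(X) && nrow(X) > 0L) {
    assign <- max.col(-pairwise_sqdist(X, codebook$centroids), ties.method = "first")
    h <- tabulate(assign, nbins = codebook$k)
  }
  if (normalize && sum(h) > 0) h <- h / sum(h)
  as.numeric(h)
}

#' Serialize / restore a codebook as JSON
#'
#' @param codebook a `bow_codebook`.
#' @param path file path.
#' @return `write_codebook()` the path invisibly; `read_codebook()` the
#'   restored `bow_codebook`.
#' @export
write_codebook <- function(codebook, path) {
  stopifnot(inherits(codebook, "bow_codebook"))
  jsonlite::write_json(
    list(k = codebook$k, iterations = codebook$iterations, seed = codebook$seed,
         centroids = codebook$centroids),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor"
  )
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(centroids = as.matrix(x$centroids), k = as.integer(x$k),
                 iterations = as.integer(x$iterations), seed = as.integer(x$seed)),
            class = "bow_codebook")
}
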