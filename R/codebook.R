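#' Fit a posture codebook by k-means vector quantization
#'
#' Clusters posture feature vectors into `k` codewords with Lloyd's algorithm
#' under Euclidean distance, seeded k-means++ initialisation and `nstart`
#' restarts keeping the lowest within-cluster sum of squares. Iteration stops
#' when the largest centroid displacement falls below `tol`. An empty cluster
#' is reseeded at the point currently farthest from its assigned centroid.
#' The fit is deterministic for fixed `(x, k, seed)`.
#'
#' No feature scaling is applied: all features are angles in radians on
#' comparable scales.
#'
#' @param x Numeric matrix or data frame of feature vectors (one row per
#'   posture). A `frame` column is ignored; columns that are entirely `NA`
#'   (masked features) are dropped.
#' @param k Number of codewords (default 43, the model size that performed
#'   best in the reference experiments).
#' @param seed Integer seed controlling initialisation.
#' @param nstart Number of seeded restarts (default 10).
#' @param max_iter Lloyd iteration cap per restart (default 100).
#' @param tol Convergence tolerance on centroid motion (default 1e-6).
#' @return An object of class `gait_codebook`: centroids (`k x d` matrix),
#'   `k`, `feature_dim`, feature names, `seed` and `inertia`.
#' @export
fit_codebook <- function(x, k = 43, seed = 1, nstart = 10,
                         max_iter = 100, tol = 1e-6) {
  x <- as_feature_matrix(x)
  if (!is_count(k, min = 2L)) abort("k must be an integer >= 2")
  n_distinct <- nrow(unique(x))
  if (n_distinct < k) {
    abort(paste0("k = ", k, " exceeds the number of distinct feature vectors (",
                 n_distinct, ")"))
  }

  best <- NULL
  for (r in seq_len(nstart)) {
    init <- with_seed(derive_seed(seed, r), kmeanspp_init(x, k))
    fit <- lloyd(x, init, max_iter = max_iter, tol = tol)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }

  colnames(best$centroids) <- colnames(x)
  structure(
    list(
      centroids = best$centroids, k = as.integer(k),
      feature_dim = ncol(x), features = colnames(x),
      seed = as.integer(seed), inertia = best$inertia, iter = best$iter
    ),
    class = "gait_codebook"
  )
}

# coerce feature input (matrix / tibble, possibly with frame column and
# masked all-NA columns) to a complete numeric matrix
as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    x <- x[, setdiff(names(x), "frame"), drop = FALSE]
    x <- x[, vapply(x, function(col) !all(is.na(col)), logical(1)), drop = FALSE]
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || !is.numeric(x)) abort("x must be a numeric matrix or data frame")
  if (anyNA(x)) abort("feature vectors contain NA; drop masked features consistently")
  if (nrow(x) < 1L) abort("x must have at least one row")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  x
}

# squared Euclidean distances between rows of x and rows of c (n x k)
dist2 <- function(x, centers) {
  outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) -
    2 * x %*% t(centers)
}

# k-means++ seeding (uses the current RNG state)
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- dist2(x, centers[1L, , drop = FALSE])[, 1L]
  for (j in seq_len(k)[-1L]) {
    d2 <- pmax(d2, 0)
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1L, prob = probs), ]
    d2 <- pmin(d2, dist2(x, centers[j, , drop = FALSE])[, 1L])
  }
  centers
}

# Lloyd iterations with empty-cluster reseeding at the farthest point
lloyd <- function(x, centers, max_iter = 100, tol = 1e-6) {
  k <- nrow(centers)
  for (iter in seq_len(max_iter)) {
    d2 <- dist2(x, centers)
    assign <- max.col(-d2, ties.method = "first")
    new_centers <- centers
    for (j in seq_len(k)) {
      members <- assign == j
      if (any(members)) {
        new_centers[j, ] <- colMeans(x[members, , drop = FALSE])
      } else {
        # reseed an empty cluster at the point farthest from its centroid
        farthest <- which.max(d2[cbind(seq_len(nrow(x)), assign)])
        new_centers[j, ] <- x[farthest, ]
        assign[farthest] <- j
      }
    }
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) break
  }
  d2 <- dist2(x, centers)
  assign <- max.col(-d2, ties.method = "first")
  inertia <- sum(pmax(d2[cbind(seq_len(nrow(x)), assign)], 0))
  list(centroids = centers, assign = assign, inertia = inertia, iter = iter)
}

#' Encode feature vectors as codewords
#'
#' Maps each posture feature vector to the index (1-based, in `1..k`) of its
#' nearest codebook centroid under Euclidean distance; exact ties go to the
#' lowest index. Encoding is deterministic and idempotent.
#'
#' @param x A numeric vector (one posture), matrix or feature tibble.
#' @param codebook A [fit_codebook()] object.
#' @return Integer vector of codewords.
#' @export
encode <- function(x, codebook) {
  stopifnot(inherits(codebook, "gait_codebook"))
  if (is.numeric(x) && is.null(dim(x)) && !is.data.frame(x)) x <- rbind(x)
  x <- as_feature_matrix(x)
  if (ncol(x) != codebook$feature_dim) {
    abort(paste0("feature dimension mismatch: got ", ncol(x),
                 ", codebook expects ", codebook$feature_dim))
  }
  d2 <- dist2(x, codebook$centroids)
  as.integer(max.col(-d2, ties.method = "first"))
}

#' Encode each gait cycle as a codeword sequence
#'
#' Adds a `codewords` list-column to a cycle tibble: the per-frame codeword
#' sequence of each cycle, preserving frame order and length.
#'
#' @param cycles A cycle tibble from [extract_cycles()] / [segment_cycles()].
#' @param features The per-frame feature tibble for the same skeleton.
#' @param codebook A [fit_codebook()] object.
#' @return `cycles` with an added integer list-column `codewords`.
#' @export
encode_cycles <- function(cycles, features, codebook) {
  mats <- cycle_feature_matrices(cycles, features)
  cycles$codewords <- purrr::map(mats, encode, codebook = codebook)
  cycles
}

#' @export
print.gait_codebook <- function(x, ...) {
  cat("<gait_codebook>", x$k, "codewords over", x$feature_dim,
      "features (", paste(x$features, collapse = ", "), ")\n")
  cat("  seed:", x$seed, " inertia:", format(x$inertia, digits = 6), "\n")
  invisible(x)
}

#' Serialize a codebook to JSON
#'
#' @param codebook A [fit_codebook()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_codebook_json <- function(codebook, path) {
  obj <- list(
    version = 1L, k = codebook$k, feature_dim = codebook$feature_dim,
    features = as.list(codebook$features), seed = codebook$seed,
    centroids = apply(codebook$centroids, 1L, as.list, simplify = FALSE)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a codebook from JSON
#'
#' @param path Path written by [write_codebook_json()].
#' @return A `gait_codebook` object.
#' @export
read_codebook_json <- function(path) {
  obj <- jsonlite::read_json(path)
  centroids <- do.call(rbind, lapply(obj$centroids, function(r) unlist(r)))
  colnames(centroids) <- unlist(obj$features)
  structure(
    list(
      centroids = centroids, k = as.integer(obj$k),
      feature_dim = as.integer(obj$feature_dim),
      features = unlist(obj$features), seed = as.integer(obj$seed),
      inertia = NA_real_, iter = NA_integer_
    ),
    class = "gait_codebook"
  )
}
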