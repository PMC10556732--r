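#' Euclidean distance between two points
#'
#' @param a,b Numeric vectors of equal length with finite coordinates.
#' @return Non-negative scalar.
#' @export
pairwise_distance <- function(a, b) {
    if (length(a) != length(b)) stop("points must have the same dimension")
    if (!all(is.finite(a)) || !all(is.finite(b)))
        stop("coordinates must be finite")
    sqrt(sum((a - b)^2))
}

.dist_to_others <- function(x_index, points) {
    d <- sqrt(colSums((t(points) - points[x_index, ])^2))
    d[x_index] <- NA_real_
    d
}

.check_k <- function(k, n) {
    if (k >= n) stop("k must be < number of objects")
    if (k < 1L) stop("k must be a positive integer")
}

#' Distance from an object to its k-th nearest neighbour
#'
#' Distances to all other objects are sorted in ascending order and the
#' k-th is returned. Ties are broken by object index (lowest first), which
#' keeps [k_neighborhood()] at exactly `k` members.
#'
#' @param x_index Row index of the query object in `points`.
#' @param points Numeric matrix, one object per row.
#' @param k Neighbour count, `1 <= k <= nrow(points) - 1`.
#' @return Scalar k-distance.
#' @export
k_distance <- function(x_index, points, k) {
    .check_k(k, nrow(points))
    d <- .dist_to_others(x_index, points)
    sort(d[-x_index])[k]
}

#' Indices of the k nearest neighbours of an object
#'
#' Returns exactly `k` indices even when several objects are tied at the
#' k-distance: the lowest-index candidates win, so the neighbourhood size
#' always matches the `1/k` and `1/(k(k-1))` normalisations used downstream.
#'
#' @inheritParams k_distance
#' @return Integer vector of length `k`; never contains `x_index`.
#' @export
k_neighborhood <- function(x_index, points, k) {
    .check_k(k, nrow(points))
    d <- .dist_to_others(x_index, points)
    others <- seq_len(nrow(points))[-x_index]
    others[order(d[-x_index])][seq_len(k)]   # order() is stable: index ties
}

#' Mean distance from an object to its neighbourhood
#'
#' @param x_index Row index of the query object.
#' @param neighborhood Integer vector of neighbour indices.
#' @param points Numeric matrix of objects.
#' @return Scalar mean distance.
#' @export
knn_distance <- function(x_index, neighborhood, points) {
    if (length(neighborhood) == 0L) stop("neighborhood must be non-empty")
    d <- sqrt(colSums((t(points[neighborhood, , drop = FALSE]) -
                           points[x_index, ])^2))
    mean(d)
}

#' Mean pairwise distance within a neighbourhood
#'
#' Computed as the ordered-pair sum divided by `k * (k - 1)`, which equals
#' the mean over unordered pairs. This measures the internal spread of the
#' neighbour cluster, against which the query's own remoteness is judged.
#'
#' @param neighborhood Integer vector of at least 2 neighbour indices.
#' @param points Numeric matrix of objects.
#' @return Scalar mean internal distance.
#' @export
knn_internal_distance <- function(neighborhood, points) {
    k <- length(neighborhood)
    if (k < 2L) stop("internal distance needs k >= 2")
    d <- dist(points[neighborhood, , drop = FALSE])
    2 * sum(d) / (k * (k - 1))
}

#' Local distance score
#'
#' The ratio of an object's mean neighbour distance to its neighbourhood's
#' internal spread. Values well above 1 mark objects isolated from their
#' own neighbourhood (CNV candidates); values below 1 mark objects nestled
#' inside it. Degenerate cases: a query coincident with its neighbours
#' (`knn_dist == 0`) scores 0; a query at positive distance from a fully
#' coincident neighbour cluster (`knn_indist == 0`) is scored against
#' `1e-12 * dist_scale` so such extreme outliers still rank highest.
#'
#' @param knn_dist Mean distance to the k neighbours (>= 0).
#' @param knn_indist Mean pairwise distance among the neighbours (>= 0).
#' @param dist_scale Typical distance used to size the zero-denominator
#'   guard; [score_all()] passes the global mean pairwise distance.
#' @return Non-negative scalar score (vectorised over its first two
#'   arguments).
#' @export
lds_score <- function(knn_dist, knn_indist, dist_scale = 1) {
    stopifnot(all(knn_dist >= 0), all(knn_indist >= 0))
    eps <- 1e-12 * dist_scale
    ifelse(knn_dist == 0, 0,
           knn_dist / pmax(knn_indist, eps))
}

#' Score every object in a feature matrix
#'
#' Runs the full local-distance computation for each row of `points`:
#' k-distance, k-nearest-neighbour set (index-stable under distance ties),
#' mean neighbour distance, neighbourhood internal distance, and their
#' ratio, the local distance score. Equivalent by construction to looping
#' the per-object operations.
#'
#' @param points Numeric matrix (objects in rows, typically the 2-D output
#'   of [to_features()]).
#' @param k Neighbour count, `2 <= k <= nrow(points) - 1`.
#' @return An `lds_result` list with elements `k`, `kdist`, `neighbors`
#'   (n x k integer matrix), `knn_dist`, `knn_indist`, `lds`.
#' @export
score_all <- function(points, k = 100) {
    points <- as.matrix(points)
    n <- nrow(points)
    if (!all(is.finite(points))) stop("coordinates must be finite")
    if (k < 2L) stop("k must be >= 2")
    if (n < k + 1L) stop("k must be < number of objects")
    D <- as.matrix(dist(points))
    dist_scale <- mean(D[upper.tri(D)])
    kdist <- numeric(n)
    knn_d <- numeric(n)
    knn_i <- numeric(n)
    nbrs <- matrix(NA_integer_, n, k)
    for (i in seq_len(n)) {
        others <- seq_len(n)[-i]
        o <- others[order(D[i, -i])][seq_len(k)]
        nbrs[i, ] <- o
        kdist[i] <- D[i, o[k]]
        knn_d[i] <- mean(D[i, o])
        knn_i[i] <- sum(D[o, o]) / (k * (k - 1))
    }
    structure(list(k = k, kdist = kdist, neighbors = nbrs,
                   knn_dist = knn_d, knn_indist = knn_i,
                   lds = lds_score(knn_d, knn_i, dist_scale)),
              class = "lds_result")
}

#' @export
print.lds_result <- function(x, ...) {
    cat(sprintf("lds_result: %d objects, k = %d\n", length(x$lds), x$k))
    cat(sprintf("  LDS range [%.4g, %.4g], median %.4g\n",
                min(x$lds), max(x$lds), stats::median(x$lds)))
    invisible(x)
}
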