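# Independent reference implementations used to cross-check the package.
# These deliberately share no code with R/: distances are recomputed from
# coordinates, the local-distance definitions are transcribed literally,
# and the total-variation oracle solves the dual problem instead of the
# primal sweep.

# Literal per-definition local distance computation, O(n^2 k^2)-ish.
brute_lds <- function(points, k) {
    points <- as.matrix(points)
    n <- nrow(points)
    edist <- function(i, j) sqrt(sum((points[i, ] - points[j, ])^2))
    all_d <- outer(seq_len(n), seq_len(n),
                   Vectorize(function(i, j) edist(i, j)))
    mean_pair <- mean(all_d[upper.tri(all_d)])
    kdist <- numeric(n); knn_d <- numeric(n); knn_i <- numeric(n)
    lds <- numeric(n)
    nbrs <- matrix(NA_integer_, n, k)
    for (i in seq_len(n)) {
        others <- setdiff(seq_len(n), i)
        d <- vapply(others, function(j) edist(i, j), numeric(1))
        # ascending by distance, ties by index (others is index-sorted)
        ord <- others[order(d)]
        nb <- ord[seq_len(k)]
        nbrs[i, ] <- nb
        kdist[i] <- sort(d)[k]
        knn_d[i] <- sum(vapply(nb, function(j) edist(i, j),
                               numeric(1))) / k
        s <- 0
        for (a in nb) for (b in nb) if (a != b) s <- s + edist(a, b)
        knn_i[i] <- s / (k * (k - 1))
        lds[i] <- if (knn_d[i] == 0) 0 else
            knn_d[i] / max(knn_i[i], 1e-12 * mean_pair)
    }
    list(kdist = kdist, neighbors = nbrs, knn_dist = knn_d,
         knn_indist = knn_i, lds = lds)
}

# Exact-to-tolerance fused-lasso solution via FISTA on the box-constrained
# dual QP: min_u 1/2 ||y - D'u||^2 s.t. |u| <= lambda, x = y - D'u.
# Stops on the primal-dual gap, so the answer is certified.
tv_dual_oracle <- function(y, lambda, tol = 1e-11, max_iter = 5e5) {
    n <- length(y)
    if (n == 1L || lambda == 0) return(y)
    DT <- function(u) c(-u, 0) + c(0, u)        # D' u
    u <- rep(0, n - 1); v <- u; t <- 1
    for (it in seq_len(max_iter)) {
        g <- -diff(y - DT(v))                   # grad of dual objective
        u_new <- pmin(lambda, pmax(-lambda, v - g / 4))
        t_new <- (1 + sqrt(1 + 4 * t^2)) / 2
        v <- u_new + (t - 1) / t_new * (u_new - u)
        u <- u_new; t <- t_new
        if (it %% 200 == 0) {
            x <- y - DT(u)
            primal <- 0.5 * sum((y - x)^2) + lambda * sum(abs(diff(x)))
            dual <- 0.5 * sum(y^2) - 0.5 * sum(x^2)
            if (primal - dual < tol * max(1, primal)) break
        }
    }
    y - DT(u)
}

# Tiny depth profile with hand-controllable bins.
toy_profile <- function(rd, gc = rep(0.5, length(rd)),
                        has_n = rep(FALSE, length(rd)),
                        bin_size = 10, contig = "toy") {
    rd_profile(contig = contig, bin_size = bin_size,
               bin_start = (seq_along(rd) - 1) * bin_size,
               rc_mean = rd, gc_frac = gc, has_n = has_n)
}

# Hand-built segment profile (bypasses tv_denoise) for feature tests.
toy_segments <- function(values, lengths = rep(1L, length(values))) {
    ends <- cumsum(lengths)
    out <- data.frame(start_bin = ends - lengths + 1L, end_bin = ends,
                      value = values, n_bins = lengths)
    class(out) <- c("segment_profile", "data.frame")
    out
}
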