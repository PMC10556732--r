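#' Denoise a read-depth vector with a 1-D total-variation model
#'
#' Solves the fused-lasso signal approximator
#' \deqn{\min_s \tfrac12 \sum_i (rd_i - s_i)^2 +
#'       \lambda \sum_i |s_{i+1} - s_i|}
#' exactly with a direct O(n) sweep, then collapses maximal runs of equal
#' fitted value into read-depth segments. With `penalty = 0` the fit
#' reproduces the input; as the penalty grows the fit becomes coarser and
#' jump heights shrink.
#'
#' @param rd Numeric vector of (corrected) per-bin read depths; finite,
#'   non-empty.
#' @param penalty Non-negative total-variation penalty \eqn{\lambda}. The
#'   data-driven default [default_tv_penalty()] is used by the pipeline.
#' @return A `segment_profile`: a data frame with one row per segment and
#'   columns `start_bin`, `end_bin` (1-based, inclusive, indices into `rd`),
#'   `value` (fitted level) and `n_bins`. The full fitted vector is kept in
#'   attribute `fitted`.
#' @export
tv_denoise <- function(rd, penalty) {
    if (length(rd) == 0L) stop("rd must be non-empty")
    if (!all(is.finite(rd))) stop("rd must be finite")
    stopifnot(is.numeric(penalty), length(penalty) == 1L)
    if (penalty < 0) stop("penalty must be non-negative")
    fit <- tv1d_prox(as.numeric(rd), penalty)
    r <- rle(fit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    out <- data.frame(start_bin = starts, end_bin = ends,
                      value = r$values, n_bins = r$lengths)
    attr(out, "fitted") <- fit
    class(out) <- c("segment_profile", "data.frame")
    out
}

#' Data-driven total-variation penalty
#'
#' Estimates the per-bin noise standard deviation from the median absolute
#' deviation of first differences (which are free of the piecewise-constant
#' signal except at the few change points): `sigma = mad(diff(rd)) / sqrt(2)`.
#' Returns `3 * sigma`, a penalty large enough to suppress noise-only jumps
#' while leaving CNV-scale level shifts intact across coverages.
#'
#' @param rd Numeric depth vector (length >= 2).
#' @return Non-negative scalar penalty.
#' @export
default_tv_penalty <- function(rd) {
    if (length(rd) < 2L) stop("need at least 2 bins to estimate a penalty")
    3 * stats::mad(diff(rd)) / sqrt(2)
}

#' @export
print.segment_profile <- function(x, ...) {
    cat(sprintf("segment_profile: %d segments over %d bins\n",
                nrow(x), sum(x$n_bins)))
    invisible(x)
}

#' Map read-depth segments into the 2-D feature space
#'
#' Each segment `i` becomes a point `(ratio_i, diff_ratio_i)` where
#' `ratio_i` is the segment level divided by the bin-weighted mean level
#' (global magnitude: a diploid segment sits near 1) and `diff_ratio_i =
#' ratio_i - ratio_{i-1}` (local contrast with the left neighbour; the
#' first segment, having none, gets 0). Both dimensions are ratios, so the
#' representation is invariant to global depth rescaling.
#'
#' @param segments A `segment_profile` from [tv_denoise()] with at least
#'   two segments.
#' @return Numeric matrix with `nrow(segments)` rows and columns
#'   `ratio`, `diff_ratio`.
#' @export
to_features <- function(segments) {
    stopifnot(inherits(segments, "segment_profile"))
    if (nrow(segments) < 2L)
        stop("need at least 2 segments to build features")
    baseline <- weighted.mean(segments$value, segments$n_bins)
    if (baseline == 0) stop("empty coverage: mean segment level is zero")
    ratio <- segments$value / baseline
    feat <- cbind(ratio = ratio, diff_ratio = c(0, diff(ratio)))
    rownames(feat) <- NULL
    feat
}
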