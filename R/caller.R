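#' Fit a normal distribution to local distance scores
#'
#' Under the null hypothesis of a CNV-free genome the scores are modelled
#' as \eqn{N(\mu, \sigma^2)}; `mu` is the sample mean and `sigma` the
#' population (ddof = 0) standard deviation, i.e. the distribution
#' parameters of the fitted normal rather than an unbiased sample
#' estimate.
#'
#' @param lds Numeric vector of at least 2 finite scores.
#' @return Named numeric vector `c(mu = , sigma = )`.
#' @export
fit_normal <- function(lds) {
    lds <- as.numeric(lds)
    if (length(lds) < 2L || !all(is.finite(lds)))
        stop("need at least 2 finite scores")
    mu <- mean(lds)
    sigma <- sqrt(mean((lds - mu)^2))
    if (sigma == 0) stop("degenerate score distribution: zero variance")
    c(mu = mu, sigma = sigma)
}

#' Right-tail normal p-value of a score
#'
#' `P(X > x)` for `X ~ N(mu, sigma^2)`: the probability of a score at
#' least this extreme under the CNV-free null. Strictly decreasing in `x`;
#' `right_tail_p(mu, mu, sigma)` is exactly 0.5.
#'
#' @param x Score(s).
#' @param mu,sigma Normal parameters, `sigma > 0`.
#' @return p-value(s) in `[0, 1]`.
#' @export
right_tail_p <- function(x, mu, sigma) {
    stopifnot(sigma > 0)
    pnorm(x, mean = mu, sd = sigma, lower.tail = FALSE)
}

#' Flag candidate CNV segments at a significance level
#'
#' @param p Vector of right-tail p-values.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return Logical vector: `p < alpha`.
#' @export
declare <- function(p, alpha = 0.05) {
    stopifnot(length(alpha) == 1L, alpha > 0, alpha < 1)
    p < alpha
}

#' Type flagged segments as gain or loss against the diploid baseline
#'
#' The baseline is the mean corrected read depth of the *unflagged*
#' (normal) segments, weighted by segment length in bins; a flagged
#' segment above it is a gain (duplication), otherwise a loss (deletion).
#'
#' @param flags Logical vector from [declare()].
#' @param seg_mean_rd Mean corrected read depth per segment.
#' @param weights Per-segment weights for the baseline (bin counts);
#'   defaults to equal weights.
#' @return List with `labels` (character, `"gain"`/`"loss"` for flagged
#'   segments, `NA` otherwise) and `baseline` (the normal depth level).
#' @export
classify_type <- function(flags, seg_mean_rd, weights = NULL) {
    stopifnot(length(flags) == length(seg_mean_rd))
    if (is.null(weights)) weights <- rep(1, length(flags))
    if (!any(!flags))
        stop("cannot establish normal baseline: every segment is flagged")
    baseline <- weighted.mean(seg_mean_rd[!flags], weights[!flags])
    labels <- rep(NA_character_, length(flags))
    labels[flags] <- ifelse(seg_mean_rd[flags] > baseline, "gain", "loss")
    list(labels = labels, baseline = baseline)
}

#' Merge flagged segments into genomic CNV calls
#'
#' Flagged segments are expanded to their bins; maximal runs of bins that
#' are genomically adjacent (no gap left by N-bin filtering) and share a
#' gain/loss label become one call. Coordinates are 0-based half-open bp.
#'
#' @param flags Logical per-segment flags.
#' @param labels Character per-segment labels (from [classify_type()]).
#' @param segments A `segment_profile` aligned with `flags`.
#' @param profile The filtered, GC-corrected [rd_profile()] the segments
#'   index into.
#' @param lds_result Optional `lds_result` supplying per-segment scores;
#'   p-values are taken from its attribute `p_value` when present.
#' @param p_values Optional per-segment p-value vector.
#' @return A `cnv_calls` data frame: `contig`, `start`, `end`, `type`,
#'   `mean_rd`, `lds`, `p_value`.
#' @export
merge_calls <- function(flags, labels, segments, profile,
                        lds_result = NULL, p_values = NULL) {
    stopifnot(inherits(segments, "segment_profile"),
              inherits(profile, "rd_profile"),
              length(flags) == nrow(segments))
    bs <- attr(profile, "bin_size")
    contig <- attr(profile, "contig")
    seg_lds <- if (!is.null(lds_result)) lds_result$lds else
        rep(NA_real_, nrow(segments))
    if (is.null(p_values)) p_values <- rep(NA_real_, nrow(segments))
    empty <- data.frame(contig = character(), start = numeric(),
                        end = numeric(), type = character(),
                        mean_rd = numeric(), lds = numeric(),
                        p_value = numeric())
    class(empty) <- c("cnv_calls", "data.frame")
    if (!any(flags)) return(empty)
    # expand flagged segments to bins
    segi <- which(flags)
    bin_idx <- unlist(lapply(segi, function(s)
        segments$start_bin[s]:segments$end_bin[s]))
    bin_seg <- rep(segi, segments$n_bins[segi])
    bin_lab <- labels[bin_seg]
    ord <- order(bin_idx)
    bin_idx <- bin_idx[ord]; bin_seg <- bin_seg[ord]; bin_lab <- bin_lab[ord]
    starts <- profile$bin_start[bin_idx]
    # break runs at label changes or genomic gaps (filtered N-bins)
    new_run <- c(TRUE, diff(starts) != bs |
                     bin_lab[-1] != bin_lab[-length(bin_lab)])
    run <- cumsum(new_run)
    calls <- do.call(rbind, lapply(split(seq_along(run), run), function(ii) {
        segs <- unique(bin_seg[ii])
        data.frame(contig = contig,
                   start = starts[ii[1L]],
                   end = starts[ii[length(ii)]] + bs,
                   type = bin_lab[ii[1L]],
                   mean_rd = mean(profile$rd_corrected[bin_idx[ii]]),
                   lds = if (all(is.na(seg_lds[segs]))) NA_real_ else
                       max(seg_lds[segs], na.rm = TRUE),
                   p_value = if (all(is.na(p_values[segs]))) NA_real_ else
                       min(p_values[segs], na.rm = TRUE))
    }))
    rownames(calls) <- NULL
    class(calls) <- c("cnv_calls", "data.frame")
    calls
}

#' Call CNVs from scored segments
#'
#' Convenience wrapper running the whole inference stage: fit the normal
#' null to the scores, compute right-tail p-values, flag segments at
#' `alpha` (optionally Bonferroni-adjusted), type them against the normal
#' read-depth baseline, and merge into genomic calls.
#'
#' @param profile Filtered, GC-corrected [rd_profile()].
#' @param segments `segment_profile` over `profile`'s bins.
#' @param lds_result `lds_result` from [score_all()] for those segments.
#' @param alpha Significance level (default 0.05).
#' @param bonferroni If `TRUE`, test at `alpha / n_segments`.
#' @return List: `calls` (a `cnv_calls` data frame), `diagnostics`
#'   (per-segment table), `mu`, `sigma`, `baseline`.
#' @export
call_cnvs <- function(profile, segments, lds_result, alpha = 0.05,
                      bonferroni = FALSE) {
    stopifnot(length(lds_result$lds) == nrow(segments))
    fit <- fit_normal(lds_result$lds)
    p <- right_tail_p(lds_result$lds, fit["mu"], fit["sigma"])
    eff_alpha <- if (bonferroni) alpha / nrow(segments) else alpha
    flags <- declare(p, eff_alpha)
    seg_mean_rd <- vapply(seq_len(nrow(segments)), function(s)
        mean(profile$rd_corrected[segments$start_bin[s]:segments$end_bin[s]]),
        numeric(1))
    typed <- classify_type(flags, seg_mean_rd, weights = segments$n_bins)
    calls <- merge_calls(flags, typed$labels, segments, profile,
                         lds_result = lds_result, p_values = p)
    bs <- attr(profile, "bin_size")
    diagnostics <- data.frame(
        seg_index = seq_len(nrow(segments)),
        start = profile$bin_start[segments$start_bin],
        end = profile$bin_start[segments$end_bin] + bs,
        feat_h = NA_real_, feat_l = NA_real_,
        knn_dist = lds_result$knn_dist,
        knn_indist = lds_result$knn_indist,
        lds = lds_result$lds, pvalue = p,
        flagged = flags, type = typed$labels)
    list(calls = calls, diagnostics = diagnostics,
         mu = unname(fit["mu"]), sigma = unname(fit["sigma"]),
         baseline = typed$baseline)
}
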