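#' Score CNV calls against a simulated truth set
#'
#' A truth CNV counts as detected when at least one call of the same type
#' overlaps it (by at least 1 bp, or by the given reciprocal-overlap
#' fraction); a call is correct when it overlaps at least one same-type
#' truth interval. Recall is detected truths over all truths, precision is
#' correct calls over all calls, F1 their harmonic mean, and FDR the
#' false-call fraction. TPR is additionally reported per CNV length class
#' (short < 20 kb, medium 20–35 kb, long >= 35 kb).
#'
#' @param calls A `cnv_calls` data frame (0-based half-open coordinates).
#' @param truth A `sim_truth` data frame on the same coordinate system.
#' @param reciprocal Minimum reciprocal overlap fraction in `[0, 1)`;
#'   0 (default) requires any overlap.
#' @return A list of class `cnv_eval`: `recall`, `precision`, `f1`, `fdr`,
#'   `n_truth`, `n_calls`, `n_detected`, `n_correct`, `tpr_by_length`.
#' @export
evaluate_calls <- function(calls, truth, reciprocal = 0) {
    stopifnot(reciprocal >= 0, reciprocal < 1)
    n_truth <- nrow(truth)
    n_calls <- nrow(calls)
    len_class <- cut(truth$end - truth$start,
                     breaks = c(0, 20e3, 35e3, Inf),
                     labels = c("short", "medium", "long"))
    detected <- rep(FALSE, n_truth)
    correct <- rep(FALSE, n_calls)
    if (n_calls > 0 && n_truth > 0) {
        gr_t <- GenomicRanges::GRanges(
            "g", IRanges::IRanges(truth$start + 1L, truth$end))
        gr_c <- GenomicRanges::GRanges(
            "g", IRanges::IRanges(calls$start + 1L, calls$end))
        hits <- GenomicRanges::findOverlaps(gr_c, gr_t)
        qi <- S4Vectors::queryHits(hits)
        si <- S4Vectors::subjectHits(hits)
        ok <- calls$type[qi] == truth$type[si]
        if (reciprocal > 0) {
            ov <- IRanges::width(IRanges::pintersect(
                IRanges::ranges(gr_c)[qi], IRanges::ranges(gr_t)[si]))
            ok <- ok & ov >= reciprocal * IRanges::width(gr_c)[qi] &
                ov >= reciprocal * IRanges::width(gr_t)[si]
        }
        detected[unique(si[ok])] <- TRUE
        correct[unique(qi[ok])] <- TRUE
    }
    recall <- if (n_truth > 0) sum(detected) / n_truth else NA_real_
    if (n_calls == 0) {
        warning("no calls: precision defined as 0")
        precision <- 0
    } else precision <- sum(correct) / n_calls
    f1 <- if (recall + precision > 0)
        2 * recall * precision / (recall + precision) else 0
    tpr <- vapply(levels(len_class), function(cl) {
        idx <- len_class == cl
        if (!any(idx)) return(NA_real_)
        sum(detected[idx]) / sum(idx)
    }, numeric(1))
    structure(list(recall = recall, precision = precision, f1 = f1,
                   fdr = if (n_calls > 0) 1 - precision else NA_real_,
                   n_truth = n_truth, n_calls = n_calls,
                   n_detected = sum(detected), n_correct = sum(correct),
                   tpr_by_length = tpr),
              class = "cnv_eval")
}

#' @export
print.cnv_eval <- function(x, ...) {
    cat(sprintf(
        "cnv_eval: recall %.3f  precision %.3f  F1 %.3f  FDR %s\n",
        x$recall, x$precision, x$f1,
        ifelse(is.na(x$fdr), "NA", sprintf("%.3f", x$fdr))))
    cat(sprintf("  %d/%d truth CNVs detected; %d/%d calls correct\n",
                x$n_detected, x$n_truth, x$n_correct, x$n_calls))
    invisible(x)
}
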