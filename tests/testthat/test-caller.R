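test_that("the normal fit uses the population standard deviation", {
    f <- fit_normal(c(1, 1, 3, 3))
    expect_equal(unname(f), c(2, 1))
    base <- fit_normal(c(0.4, 1.1, 2.3, 0.9))
    shifted <- fit_normal(c(0.4, 1.1, 2.3, 0.9) + 7)
    scaled <- fit_normal(c(0.4, 1.1, 2.3, 0.9) * 3)
    expect_equal(shifted["mu"], base["mu"] + 7)
    expect_equal(shifted["sigma"], base["sigma"])
    expect_equal(unname(scaled), unname(base) * 3)
    expect_error(fit_normal(rep(2, 5)), "degenerate")
    expect_error(fit_normal(1), "at least 2")
})

test_that("right-tail p-values are calibrated and monotone", {
    expect_equal(right_tail_p(2, 2, 1.3), 0.5)
    expect_equal(right_tail_p(2 + 1.6448536 * 1.3, 2, 1.3), 0.05,
                 tolerance = 1e-6)
    grid <- right_tail_p(seq(-4, 8, by = 0.25), 2, 1.3)
    expect_true(all(diff(grid) < 0))
    expect_lt(right_tail_p(1e6, 0, 1), 1e-12)
})

test_that("declaration thresholds p-values and is monotone in alpha", {
    expect_equal(declare(c(0.001, 0.2), 0.05), c(TRUE, FALSE))
    expect_false(any(declare(rep(0.5, 10), 0.05)))
    set.seed(1)
    p <- runif(200)
    loose <- declare(p, 0.2)
    strict <- declare(p, 0.01)
    expect_true(all(loose[strict]))          # strict flags subset of loose
    expect_error(declare(p, 1.2))
})

test_that("null scores are flagged at close to the nominal rate", {
    set.seed(42)
    frac <- vapply(1:10, function(s) {
        scores <- rnorm(2000)
        f <- fit_normal(scores)
        mean(declare(right_tail_p(scores, f["mu"], f["sigma"]), 0.05))
    }, numeric(1))
    expect_true(abs(mean(frac) - 0.05) < 0.02)
})

test_that("gain/loss typing uses the weighted normal baseline", {
    flags <- c(FALSE, FALSE, TRUE, TRUE)
    rd <- c(5, 5, 10, 0)
    t1 <- classify_type(flags, rd)
    expect_equal(t1$baseline, 5)
    expect_equal(t1$labels, c(NA, NA, "gain", "loss"))
    # bin-length weighting moves the baseline
    t2 <- classify_type(c(FALSE, FALSE, TRUE), c(4, 8, 6), weights = c(9, 1, 5))
    expect_equal(t2$baseline, 4.4)
    expect_equal(t2$labels[3], "gain")
    expect_error(classify_type(c(TRUE, TRUE), c(1, 2)), "baseline")
})

test_that("adjacent same-type segments merge; boundaries and N-gaps split calls", {
    prof <- toy_profile(c(9, 9, 1, 5, 5), bin_size = 10)
    prof$rd_corrected <- prof$rc_mean
    segs <- toy_segments(c(9, 9, 1, 5, 5))   # one segment per bin
    flags <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
    labels <- c("gain", "gain", "loss", NA, NA)
    calls <- merge_calls(flags, labels, segs, prof)
    expect_equal(nrow(calls), 2L)
    expect_equal(calls$start, c(0, 20))
    expect_equal(calls$end, c(20, 30))
    expect_equal(calls$type, c("gain", "loss"))
    expect_equal(calls$mean_rd, c(9, 1))
    # same two flagged gains, but an N-bin was filtered between them
    prof_gap <- prof[-2, , drop = FALSE]
    attr(prof_gap, "contig") <- "toy"; attr(prof_gap, "bin_size") <- 10
    class(prof_gap) <- class(prof)
    segs_gap <- toy_segments(c(9, 1, 5, 5))
    calls_gap <- merge_calls(c(TRUE, TRUE, FALSE, FALSE),
                             c("gain", "gain", NA, NA), segs_gap, prof_gap)
    expect_equal(nrow(calls_gap), 2L)        # gap forbids merging
    expect_equal(calls_gap$start, c(0, 20))
    # no flags -> empty call set
    expect_equal(nrow(merge_calls(rep(FALSE, 4), rep(NA, 4), segs_gap,
                                  prof_gap)), 0L)
})

test_that("calls cover exactly the flagged bins", {
    set.seed(7)
    run <- run_pipeline("simulate", config = sim_config(
        genome_length = 4e6, seed = 7))
    d <- run$diagnostics
    bs <- run$params$bin_size
    flagged_bins <- sort(unlist(lapply(which(d$flagged), function(s)
        seq(run$segments$start_bin[s], run$segments$end_bin[s]))))
    call_bins <- sort(unlist(lapply(seq_len(nrow(run$calls)), function(i)
        which(run$profile$bin_start >= run$calls$start[i] &
              run$profile$bin_start < run$calls$end[i]))))
    expect_identical(flagged_bins, call_bins)
})

test_that("call_cnvs wires fit, test, typing and merging together", {
    set.seed(5)
    prof <- toy_profile(c(rnorm(60, 5, 0.1), rep(10, 3), rnorm(60, 5, 0.1)))
    prof$rd_corrected <- prof$rc_mean
    segs <- tv_denoise(prof$rd_corrected, 0.5)
    feats <- to_features(segs)
    lds <- score_all(feats, k = min(10, nrow(segs) - 1))
    res <- call_cnvs(prof, segs, lds, alpha = 0.05)
    expect_true(nrow(res$calls) >= 1)
    gain <- res$calls[res$calls$type == "gain", ]
    expect_equal(gain$start[1], 600)
    expect_equal(gain$end[1], 630)
    expect_true(all(res$calls$mean_rd[res$calls$type == "gain"] >
                        res$baseline))
    expect_equal(nrow(res$diagnostics), nrow(segs))
})
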