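test_that("the default design implants 14 non-overlapping CNVs of 6 gains and 8 losses", {
    sim <- simulate_profile(sim_config(seed = 3))
    tr <- sim$truth
    expect_equal(nrow(tr), 14L)
    expect_equal(sum(tr$type == "gain"), 6L)
    expect_equal(sum(tr$type == "loss"), 8L)
    len <- tr$end - tr$start
    expect_true(all(len >= 10000 & len <= 50000))
    o <- order(tr$start)
    expect_true(all(tr$start[o][-1] >= tr$end[o][-14]))
    expect_true(all(tr$cn[tr$type == "gain"] >= 3))
    expect_true(all(tr$cn[tr$type == "loss"] %in% c(0, 1)))
})

test_that("expected depth follows the purity mixture", {
    # no CNV signal: depth = coverage everywhere
    flat <- simulate_profile(sim_config(n_gains = 0, n_losses = 0,
                                        genome_length = 5e6, gc_bias = 0,
                                        seed = 8))
    expect_equal(mean(flat$profile$rc_mean), 5, tolerance = 0.02)
    # purity 0.8, cn = 4 gain: expected in-CNV depth = coverage * 1.8
    cfg <- sim_config(tumor_purity = 0.8, n_gains = 6, n_losses = 0,
                      gain_cn = 4L, gc_bias = 0, seed = 9)
    sim <- simulate_profile(cfg)
    tr <- sim$truth; p <- sim$profile
    inside <- rep(FALSE, nrow(p))
    for (j in seq_len(nrow(tr)))
        inside <- inside | (p$bin_start >= tr$start[j] &
                            p$bin_start + 1000 <= tr$end[j])
    expect_equal(mean(p$rc_mean[inside]), 5 * 1.8, tolerance = 0.03)
    expect_equal(mean(p$rc_mean[!inside]), 5, tolerance = 0.02)
})

test_that("simulation is deterministic in the seed", {
    a <- simulate_profile(sim_config(seed = 21, genome_length = 3e6))
    b <- simulate_profile(sim_config(seed = 21, genome_length = 3e6))
    c <- simulate_profile(sim_config(seed = 22, genome_length = 3e6))
    expect_identical(a$profile, b$profile)
    expect_identical(a$truth, b$truth)
    expect_false(identical(a$profile$rc_mean, c$profile$rc_mean))
})

test_that("evaluation metrics follow their definitions", {
    truth <- data.frame(start = seq(0, 13) * 1e5,
                        end = seq(0, 13) * 1e5 + 2e4,
                        type = rep(c("gain", "loss"), 7),
                        cn = rep(c(4, 1), 7))
    # perfect caller
    calls <- data.frame(contig = "c", start = truth$start, end = truth$end,
                        type = truth$type)
    ev <- evaluate_calls(calls, truth)
    expect_equal(ev$recall, 1)
    expect_equal(ev$precision, 1)
    expect_equal(ev$f1, 1)
    expect_equal(ev$fdr, 0)
    # no calls
    expect_warning(ev0 <- evaluate_calls(calls[0, ], truth), "no calls")
    expect_equal(ev0$recall, 0)
    expect_equal(ev0$precision, 0)
    # 7 of 14 truths hit plus 3 false calls: recall 0.5, precision 0.7
    calls7 <- rbind(calls[1:7, ],
                    data.frame(contig = "c", start = c(50, 52, 54) * 1e5,
                               end = c(50, 52, 54) * 1e5 + 1000,
                               type = "gain"))
    ev7 <- evaluate_calls(calls7, truth)
    expect_equal(ev7$recall, 0.5)
    expect_equal(ev7$precision, 0.7)
    expect_equal(ev7$f1, 7 / 12)
    # type must match for an overlap to count
    wrong <- calls; wrong$type <- ifelse(calls$type == "gain", "loss", "gain")
    expect_equal(evaluate_calls(wrong, truth)$recall, 0)
    # reciprocal-overlap option discards sliver overlaps
    sliver <- data.frame(contig = "c", start = truth$end[1] - 100,
                         end = truth$end[1] + 2e4, type = "gain")
    expect_equal(evaluate_calls(sliver, truth)$recall, 1 / 14)
    expect_equal(evaluate_calls(sliver, truth, reciprocal = 0.5)$recall, 0)
})

test_that("the BAM fixture realizes the depth model", {
    dir <- withr::local_tempdir()
    cfg <- sim_config(genome_length = 3e5, n_gains = 1, n_losses = 0,
                      gain_cn = 4L, tumor_purity = 1, seed = 12)
    sim <- simulate_profile(cfg)
    fx <- write_fixture_bam(sim$truth, cfg, dir)
    rc <- extract_read_counts(fx$bam, "sim1")
    expect_length(rc, 3e5)
    tr <- sim$truth
    inside <- seq(tr$start[1] + 200, tr$end[1] - 200)
    outside <- setdiff(seq(1000, 2.9e5), seq(tr$start[1] - 200,
                                             tr$end[1] + 200))
    expect_equal(mean(rc[inside]), 10, tolerance = 0.1)
    expect_equal(mean(rc[outside]), 5, tolerance = 0.05)
    # N-runs propagate into flagged bins
    fx2 <- write_fixture_bam(sim$truth[0, ], cfg, dir,
                             n_runs = data.frame(start = 5001, width = 1500))
    prof <- bin_profile(extract_read_counts(fx2$bam, "sim1"), 1000,
                        fx2$reference, contig = "sim1")
    expect_true(all(prof$has_n[6:7]))
    expect_false(any(prof$has_n[-(6:7)]))
})

test_that("a zero-coverage fixture produces an empty, readable BAM", {
    dir <- withr::local_tempdir()
    cfg <- sim_config(genome_length = 5e4, n_gains = 0, n_losses = 0,
                      coverage = 1e-9, seed = 2)
    sim <- simulate_profile(cfg)
    fx <- write_fixture_bam(sim$truth, cfg, dir)
    rc <- extract_read_counts(fx$bam, "sim1")
    expect_true(all(rc == 0))
})
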