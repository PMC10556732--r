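#' Configuration for the read-depth simulator
#'
#' Defaults reproduce the evaluation design the package is tested under: a
#' 5x mean-coverage tumour sample carrying 14 CNVs — 6 gains and 8 losses —
#' of 10–50 kb on a 20 Mb synthetic contig, with tumour purity chosen from
#' {0.2, 0.4, 0.6, 0.8} (0.8 by default). Purity dilutes the CNV depth
#' signal toward the diploid baseline: the expected depth inside a CNV of
#' copy number `cn` is `coverage * (purity * cn/2 + (1 - purity))`.
#'
#' @param tumor_purity Tumour cell fraction in (0, 1].
#' @param coverage Mean per-base sequencing depth.
#' @param n_gains,n_losses Number of implanted gains / losses.
#' @param length_range Min/max CNV length in bp.
#' @param gain_cn Candidate gain copy numbers (integers >= 3).
#' @param loss_cn Candidate loss copy numbers (0 and/or 1).
#' @param genome_length Synthetic contig length in bp.
#' @param bin_size Bin width in bp.
#' @param noise Per-base negative-binomial dispersion (`size` parameter);
#'   binned counts have `size = noise * bin_size`. Smaller is noisier;
#'   counts approach Poisson as `noise` grows.
#' @param gc_bias Amplitude of a mild quadratic GC bias on expected depth
#'   (0 disables it).
#' @param n_frac Fraction of bins flagged as containing reference "N".
#' @param seed RNG seed; identical configs reproduce byte-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(tumor_purity = 0.8, coverage = 5,
                       n_gains = 6, n_losses = 8,
                       length_range = c(10000, 50000),
                       gain_cn = c(3L, 4L), loss_cn = c(0L, 1L),
                       genome_length = 2e7, bin_size = 1000,
                       noise = 0.5, gc_bias = 0.2, n_frac = 0,
                       seed = 1L) {
    stopifnot(tumor_purity > 0, tumor_purity <= 1, coverage > 0,
              n_gains >= 0, n_losses >= 0,
              length(length_range) == 2L,
              length_range[1] > 0, length_range[1] <= length_range[2],
              all(gain_cn >= 3), all(loss_cn %in% c(0L, 1L)),
              bin_size >= 1, noise > 0, gc_bias >= 0,
              n_frac >= 0, n_frac < 1)
    n_cnv <- n_gains + n_losses
    if (genome_length < 4 * n_cnv * length_range[2])
        stop("genome_length too small to place non-overlapping CNVs")
    structure(list(tumor_purity = tumor_purity, coverage = coverage,
                   n_gains = n_gains, n_losses = n_losses,
                   length_range = length_range, gain_cn = gain_cn,
                   loss_cn = loss_cn, genome_length = genome_length,
                   bin_size = bin_size, noise = noise, gc_bias = gc_bias,
                   n_frac = n_frac, seed = as.integer(seed)),
              class = "sim_config")
}

# place n non-overlapping intervals of the configured lengths
.place_intervals <- function(config) {
    n <- config$n_gains + config$n_losses
    if (n == 0L) return(data.frame(start = numeric(), end = numeric()))
    lens <- round(runif(n, config$length_range[1], config$length_range[2]))
    for (attempt in seq_len(1000L)) {
        starts <- sort(round(runif(n, 0, config$genome_length - max(lens))))
        ends <- starts + lens
        if (all(diff(starts) > lens[-n]) &&
            all(ends <= config$genome_length))
            return(data.frame(start = starts, end = ends))
    }
    stop("could not place non-overlapping CNV intervals; enlarge the genome")
}

#' Simulate a binned read-depth profile with implanted CNVs
#'
#' Per-bin expected depth follows the purity mixture
#' `coverage * (purity * cn/2 + (1 - purity))` inside implanted CNVs and
#' `coverage` outside (bins partially overlapped by a CNV get the
#' overlap-weighted mixture). GC fractions are drawn uniformly on
#' [0.3, 0.6] and, when `gc_bias > 0`, modulate expected depth by the
#' unimodal factor `1 - gc_bias * ((gc - 0.45) / 0.15)^2`, which
#' [correct_gc()] is designed to undo. Observed binned counts are negative
#' binomial; by additivity this matches drawing per-base counts with
#' dispersion `noise` and summing over the bin.
#'
#' @param config A [sim_config()].
#' @return List with `profile` (an [rd_profile()]) and `truth` (a
#'   `sim_truth`: data frame of implanted intervals with 0-based half-open
#'   coordinates, `type`, and `cn`, plus purity/coverage attributes).
#' @export
simulate_profile <- function(config) {
    stopifnot(inherits(config, "sim_config"))
    set.seed(config$seed)
    iv <- .place_intervals(config)
    n <- nrow(iv)
    type <- rep(c("gain", "loss"), c(config$n_gains, config$n_losses))
    type <- sample(type)                    # interleave gains and losses
    cn <- integer(n)
    # index-based draw: sample(x, ...) on a length-1 x would sample 1:x
    pick <- function(pool, m) pool[sample.int(length(pool), m, replace = TRUE)]
    cn[type == "gain"] <- pick(config$gain_cn, sum(type == "gain"))
    cn[type == "loss"] <- pick(config$loss_cn, sum(type == "loss"))
    truth <- data.frame(start = iv$start, end = iv$end, type = type, cn = cn)
    bs <- config$bin_size
    n_bins <- config$genome_length %/% bs
    starts <- (seq_len(n_bins) - 1) * bs
    # overlap-weighted expected depth multiplier per bin
    mult <- rep(1, n_bins)
    for (j in seq_len(n)) {
        f <- pmax(0, pmin(starts + bs, truth$end[j]) -
                      pmax(starts, truth$start[j])) / bs
        m_j <- config$tumor_purity * truth$cn[j] / 2 +
            (1 - config$tumor_purity)
        mult <- mult + f * (m_j - 1)
    }
    gc <- runif(n_bins, 0.3, 0.6)
    bias <- if (config$gc_bias > 0)
        1 - config$gc_bias * ((gc - 0.45) / 0.15)^2 else rep(1, n_bins)
    mu_bin <- config$coverage * mult * bias * bs
    counts <- rnbinom(n_bins, mu = mu_bin, size = config$noise * bs)
    has_n <- rep(FALSE, n_bins)
    if (config$n_frac > 0)
        has_n[sample.int(n_bins, round(config$n_frac * n_bins))] <- TRUE
    profile <- rd_profile(contig = "sim1", bin_size = bs,
                          bin_start = starts, rc_mean = counts / bs,
                          gc_frac = gc, has_n = has_n)
    attr(truth, "purity") <- config$tumor_purity
    attr(truth, "coverage") <- config$coverage
    class(truth) <- c("sim_truth", "data.frame")
    list(profile = profile, truth = truth)
}

#' Write a synthetic BAM + FASTA fixture realizing a simulated sample
#'
#' Emits a random reference FASTA (optionally with "N" runs) and a
#' coordinate-sorted, indexed BAM of single-end 100 bp reads whose start
#' positions are Poisson-placed so that expected coverage follows the same
#' purity mixture as [simulate_profile()]. Intended for small genomes
#' (<= 2 Mb) so the alignment-input path can be exercised end to end.
#'
#' @param truth A `sim_truth` (may have zero rows).
#' @param config The [sim_config()] that produced it; `genome_length`
#'   must be <= 2 Mb.
#' @param dir Output directory (created if needed).
#' @param n_runs Optional data frame `start`,`width` (1-based) of "N" runs
#'   to write into the reference.
#' @param read_len Read length in bp.
#' @return List with paths `bam`, `fasta` and the reference `DNAString`.
#' @export
write_fixture_bam <- function(truth, config, dir, n_runs = NULL,
                              read_len = 100L) {
    stopifnot(inherits(config, "sim_config"))
    if (config$genome_length > 2e6)
        stop("fixture genomes are limited to 2 Mb")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    set.seed(config$seed + 1L)
    L <- as.integer(config$genome_length)
    ref <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    if (!is.null(n_runs))
        for (j in seq_len(nrow(n_runs)))
            ref[n_runs$start[j] + seq_len(n_runs$width[j]) - 1L] <- "N"
    ref_str <- Biostrings::DNAString(paste(ref, collapse = ""))
    fasta <- file.path(dir, "ref.fa")
    seqs <- Biostrings::DNAStringSet(ref_str)
    names(seqs) <- "sim1"
    Biostrings::writeXStringSet(seqs, fasta)
    # expected depth per start position -> Poisson read starts
    pos <- seq_len(L - read_len + 1L)
    mult <- rep(1, length(pos))
    if (nrow(truth) > 0)
        for (j in seq_len(nrow(truth))) {
            inside <- pos > truth$start[j] & pos <= truth$end[j]
            m_j <- config$tumor_purity * truth$cn[j] / 2 +
                (1 - config$tumor_purity)
            mult[inside] <- mult[inside] + (m_j - 1)
        }
    lambda <- config$coverage * mult / read_len
    n_reads <- rpois(length(pos), lambda)
    starts <- rep(pos, n_reads)
    sam <- file.path(dir, "reads.sam")
    con <- file(sam, "w")
    writeLines(c("@HD\tVN:1.6\tSO:unsorted",
                 sprintf("@SQ\tSN:sim1\tLN:%d", L)), con)
    if (length(starts) > 0) {
        seq_txt <- as.character(Biostrings::Views(ref_str, start = starts,
                                                  width = read_len))
        writeLines(sprintf("r%d\t0\tsim1\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                           seq_along(starts), starts, read_len, seq_txt),
                   con)
    }
    close(con)
    bam <- Rsamtools::asBam(sam, file.path(dir, "reads"),
                            overwrite = TRUE, indexDestination = TRUE)
    unlink(sam)
    list(bam = bam, fasta = fasta, reference = ref_str)
}
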