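#' Run the CNV-calling pipeline end to end
#'
#' Orchestrates extract -> bin -> filter N -> GC-correct -> TV-denoise ->
#' 2-D features -> local distance score -> normal-tail test -> merge, from
#' one of three entry points: a BAM + reference FASTA, a per-bin depth
#' table, or the built-in simulator.
#'
#' @param mode `"bam"`, `"table"` or `"simulate"`.
#' @param bam,ref BAM and reference FASTA paths (`mode = "bam"`).
#' @param table Depth-table TSV path (`mode = "table"`).
#' @param config A [sim_config()] (`mode = "simulate"`).
#' @param contig Contig to process (`mode = "bam"`; defaults to the first
#'   contig of the reference).
#' @param bin_size Bin width in bp (`mode = "bam"`).
#' @param k Neighbour count for the local distance score (default 100;
#'   clamped to `n_segments - 1` with a warning on short profiles).
#' @param alpha Significance level for the normal-tail test.
#' @param tv_penalty Total-variation penalty; `NULL` (default) uses
#'   [default_tv_penalty()].
#' @param bonferroni Test at `alpha / n_segments` instead of `alpha`.
#' @param out_dir If non-`NULL`, write `calls.bed`, `segments.tsv`,
#'   `rd_profile.tsv` and `run.log` there.
#' @return List of class `ldcnv_run`: `calls`, `diagnostics`, `profile`
#'   (filtered + corrected), `segments`, `features`, `lds`, `params`, and
#'   `truth` in simulate mode.
#' @export
run_pipeline <- function(mode = c("table", "bam", "simulate"),
                         bam = NULL, ref = NULL, table = NULL,
                         config = NULL, contig = NULL, bin_size = 1000,
                         k = 100, alpha = 0.05, tv_penalty = NULL,
                         bonferroni = FALSE, out_dir = NULL) {
    mode <- match.arg(mode)
    truth <- NULL
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
    }
    if (mode == "bam") {
        if (is.null(bam) || is.null(ref))
            stop("mode 'bam' needs `bam` and `ref`")
        seqs <- stage("reference", Biostrings::readDNAStringSet(ref))
        if (is.null(contig)) contig <- sub("\\s.*", "", names(seqs)[1L])
        names(seqs) <- sub("\\s.*", "", names(seqs))
        if (!contig %in% names(seqs))
            stop("contig '", contig, "' not in reference")
        rc <- stage("extract", extract_read_counts(bam, contig))
        profile <- stage("bin", bin_profile(rc, bin_size, seqs[[contig]],
                                            contig = contig))
    } else if (mode == "table") {
        if (is.null(table)) stop("mode 'table' needs `table`")
        profile <- stage("read-table", read_rd_table(table))
    } else {
        if (is.null(config)) config <- sim_config()
        sim <- stage("simulate", simulate_profile(config))
        profile <- sim$profile
        truth <- sim$truth
    }
    profile <- stage("filter-N", filter_n_bins(profile))
    profile <- stage("gc-correct", correct_gc(profile))
    if (is.null(tv_penalty))
        tv_penalty <- default_tv_penalty(profile$rd_corrected)
    segments <- stage("tv-denoise",
                      tv_denoise(profile$rd_corrected, tv_penalty))
    feats <- stage("features", to_features(segments))
    k_used <- k
    if (k_used >= nrow(segments)) {
        k_used <- nrow(segments) - 1L
        warning("k = ", k, " >= number of segments (", nrow(segments),
                "); clamped to ", k_used)
    }
    lds <- stage("score", score_all(feats, k = k_used))
    res <- stage("call", call_cnvs(profile, segments, lds, alpha = alpha,
                                   bonferroni = bonferroni))
    res$diagnostics$feat_h <- feats[, "ratio"]
    res$diagnostics$feat_l <- feats[, "diff_ratio"]
    params <- list(mode = mode, bin_size = attr(profile, "bin_size"),
                   k = k_used, k_requested = k, alpha = alpha,
                   tv_penalty = tv_penalty, bonferroni = bonferroni,
                   contig = attr(profile, "contig"),
                   seed = if (!is.null(config)) config$seed else NA)
    out <- structure(list(calls = res$calls, diagnostics = res$diagnostics,
                          profile = profile, segments = segments,
                          features = feats, lds = lds, params = params,
                          mu = res$mu, sigma = res$sigma,
                          baseline = res$baseline, truth = truth),
                     class = "ldcnv_run")
    if (!is.null(out_dir)) write_run(out, out_dir)
    out
}

#' @export
print.ldcnv_run <- function(x, ...) {
    cat(sprintf("ldcnv_run (%s mode): %d bins -> %d segments -> %d calls\n",
                x$params$mode, nrow(x$profile), nrow(x$segments),
                nrow(x$calls)))
    cat(sprintf("  k = %d, alpha = %g, tv_penalty = %.4g, baseline RD %.3f\n",
                x$params$k, x$params$alpha, x$params$tv_penalty,
                x$baseline))
    if (nrow(x$calls) > 0) {
        cat(sprintf("  %d gain(s), %d loss(es)\n",
                    sum(x$calls$type == "gain"),
                    sum(x$calls$type == "loss")))
    }
    invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Emits `calls.bed` (BED-like TSV: contig, start, end, type, mean_rd,
#' lds, pvalue; 0-based half-open), `segments.tsv` (per-segment
#' diagnostics), `rd_profile.tsv` (the corrected depth table) and
#' `run.log` (every parameter of the run).
#'
#' @param run An `ldcnv_run` from [run_pipeline()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
    stopifnot(inherits(run, "ldcnv_run"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_calls_bed(run$calls, file.path(dir, "calls.bed"))
    write.table(run$diagnostics, file.path(dir, "segments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_rd_table(run$profile, file.path(dir, "rd_profile.tsv"))
    p <- run$params
    writeLines(c(sprintf("ldcnv run %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                 sprintf("mode\t%s", p$mode),
                 sprintf("contig\t%s", p$contig),
                 sprintf("bin_size\t%g", p$bin_size),
                 sprintf("k\t%d (requested %d)", p$k, p$k_requested),
                 sprintf("alpha\t%g", p$alpha),
                 sprintf("tv_penalty\t%.10g", p$tv_penalty),
                 sprintf("bonferroni\t%s", p$bonferroni),
                 sprintf("seed\t%s", p$seed),
                 sprintf("n_bins\t%d", nrow(run$profile)),
                 sprintf("n_segments\t%d", nrow(run$segments)),
                 sprintf("n_calls\t%d", nrow(run$calls))),
               file.path(dir, "run.log"))
    invisible(dir)
}

#' Write CNV calls as a BED-like TSV
#'
#' @param calls A `cnv_calls` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path) {
    write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read CNV calls written by [write_calls_bed()]
#'
#' @param path Path to the BED-like TSV.
#' @return A `cnv_calls` data frame.
#' @export
read_calls_bed <- function(path) {
    calls <- read.delim(path, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    class(calls) <- c("cnv_calls", "data.frame")
    calls
}

#' Write CNV calls as minimal VCF 4.2
#'
#' Gains become `SVTYPE=DUP`, losses `SVTYPE=DEL`; the interval end is
#' carried in `INFO/END` (1-based inclusive, per VCF convention).
#'
#' @param calls A `cnv_calls` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path) {
    hdr <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
             "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
             "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the variant\">",
             "##ALT=<ID=DUP,Description=\"Duplication\">",
             "##ALT=<ID=DEL,Description=\"Deletion\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    rows <- character(0)
    if (nrow(calls) > 0) {
        svtype <- ifelse(calls$type == "gain", "DUP", "DEL")
        svlen <- (calls$end - calls$start) *
            ifelse(calls$type == "gain", 1L, -1L)
        rows <- sprintf("%s\t%d\t%s\tN\t<%s>\t.\tPASS\tEND=%d;SVTYPE=%s;SVLEN=%d",
                        calls$contig, calls$start + 1L,
                        sprintf("cnv%d", seq_len(nrow(calls))),
                        svtype, calls$end, svtype, svlen)
    }
    writeLines(c(hdr, rows), path)
    invisible(path)
}
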