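#' Construct a binned read-depth profile
#'
#' An `rd_profile` is a data frame with one row per fixed-width genomic bin
#' and columns `bin_start` (0-based bp), `rc_mean` (mean per-base read count
#' in the bin), `gc_frac` (G+C fraction of the bin's reference sequence,
#' computed over non-N bases), `has_n` (does the bin contain at least one
#' reference "N"?) and `rd_corrected` (GC-calibrated depth; `NA` until
#' [correct_gc()] has run). The contig name and bin size are carried as
#' attributes so that genomic coordinates survive filtering.
#'
#' @param contig Chromosome/contig name.
#' @param bin_size Bin width in bp.
#' @param bin_start Integer vector of 0-based bin start positions, strictly
#'   increasing, each a multiple of `bin_size`.
#' @param rc_mean Numeric vector of non-negative mean per-base read counts.
#' @param gc_frac Numeric vector in `[0, 1]`.
#' @param has_n Logical vector.
#' @param rd_corrected Optional numeric vector of GC-corrected depths.
#' @return An object of class `rd_profile` (a data frame).
#' @seealso [bin_profile()], [filter_n_bins()], [correct_gc()]
#' @export
rd_profile <- function(contig, bin_size, bin_start, rc_mean, gc_frac, has_n,
                       rd_corrected = NULL) {
    n <- length(bin_start)
    stopifnot(is.character(contig), length(contig) == 1L,
              is.numeric(bin_size), length(bin_size) == 1L, bin_size >= 1)
    if (length(rc_mean) != n || length(gc_frac) != n || length(has_n) != n)
        stop("all per-bin vectors must have the same length")
    if (n > 1L && any(diff(bin_start) <= 0))
        stop("bin_start must be strictly increasing")
    if (any(rc_mean < 0)) stop("rc_mean must be non-negative")
    if (any(gc_frac < 0 | gc_frac > 1)) stop("gc_frac must lie in [0, 1]")
    if (is.null(rd_corrected)) rd_corrected <- rep(NA_real_, n)
    out <- data.frame(bin_start = as.numeric(bin_start),
                      rc_mean = as.numeric(rc_mean),
                      gc_frac = as.numeric(gc_frac),
                      has_n = as.logical(has_n),
                      rd_corrected = as.numeric(rd_corrected))
    attr(out, "contig") <- contig
    attr(out, "bin_size") <- as.numeric(bin_size)
    class(out) <- c("rd_profile", "data.frame")
    out
}

#' @export
print.rd_profile <- function(x, ...) {
    cat(sprintf("rd_profile: %d bins of %g bp on %s\n",
                nrow(x), attr(x, "bin_size"), attr(x, "contig")))
    cat(sprintf("  mean raw depth %.3f; %d N-flagged bins; GC corrected: %s\n",
                mean(x$rc_mean), sum(x$has_n),
                if (all(is.na(x$rd_corrected))) "no" else "yes"))
    invisible(x)
}

#' Read/write a per-bin read-depth table
#'
#' The on-disk format is a TSV with header
#' `contig start end rd_raw gc rd_corrected` using 0-based half-open
#' coordinates. Bins in a table are assumed usable (N-containing bins are
#' removed before a profile is serialized).
#'
#' @param path File path.
#' @return `read_rd_table()` returns an `rd_profile`;
#'   `write_rd_table()` returns `path` invisibly.
#' @export
read_rd_table <- function(path) {
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    need <- c("contig", "start", "end", "rd_raw", "gc", "rd_corrected")
    if (!all(need %in% names(tab)))
        stop("depth table must have columns: ", paste(need, collapse = " "))
    if (nrow(tab) == 0L) stop("empty depth table")
    if (length(unique(tab$contig)) > 1L)
        stop("depth table must contain a single contig")
    widths <- tab$end - tab$start
    if (length(unique(widths)) != 1L)
        stop("all bins in a depth table must have equal width")
    rd_profile(contig = tab$contig[1L], bin_size = widths[1L],
               bin_start = tab$start, rc_mean = tab$rd_raw,
               gc_frac = tab$gc, has_n = rep(FALSE, nrow(tab)),
               rd_corrected = tab$rd_corrected)
}

#' @param profile An `rd_profile`.
#' @rdname read_rd_table
#' @export
write_rd_table <- function(profile, path) {
    stopifnot(inherits(profile, "rd_profile"))
    bs <- attr(profile, "bin_size")
    out <- data.frame(contig = attr(profile, "contig"),
                      start = profile$bin_start,
                      end = profile$bin_start + bs,
                      rd_raw = profile$rc_mean,
                      gc = profile$gc_frac,
                      rd_corrected = profile$rd_corrected)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
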