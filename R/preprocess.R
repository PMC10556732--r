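#' Extract per-base read counts from an indexed BAM file
#'
#' Counts, for every position of one contig, the number of aligned reads
#' covering it (coverage of the aligned bases, CIGAR-aware).
#'
#' @param bam_file Path to a coordinate-sorted BAM file with a `.bai` index.
#' @param contig Contig to extract; must be present in the BAM header.
#' @return Integer vector of length equal to the contig length; element `i`
#'   is the read coverage of reference position `i` (1-based).
#' @export
extract_read_counts <- function(bam_file, contig) {
    if (!file.exists(bam_file)) stop("BAM file not found: ", bam_file)
    idx <- c(paste0(bam_file, ".bai"), sub("\\.bam$", ".bai", bam_file))
    if (!any(file.exists(idx)))
        stop("no index found for ", bam_file,
             "; create one with `samtools index` or Rsamtools::indexBam()")
    hdr <- Rsamtools::scanBamHeader(bam_file)[[1L]]$targets
    if (!contig %in% names(hdr))
        stop("contig '", contig, "' not in BAM header; available: ",
             paste(names(hdr), collapse = ", "))
    len <- unname(hdr[[contig]])
    which <- GenomicRanges::GRanges(contig, IRanges::IRanges(1L, len))
    aln <- GenomicAlignments::readGAlignments(
        bam_file, param = Rsamtools::ScanBamParam(which = which))
    cov <- GenomicAlignments::coverage(aln)[[contig]]
    rc <- as.integer(cov)
    length(rc) <- len          # pad in case coverage Rle is shorter
    rc[is.na(rc)] <- 0L
    rc
}

#' Bin a per-base read-count vector into a read-depth profile
#'
#' The contig is divided into consecutive, non-overlapping bins of
#' `bin_size` bp; each bin's depth is the arithmetic mean of the per-base
#' read counts it spans. A trailing partial bin is dropped so every bin has
#' exactly `bin_size` positions and bin means stay comparable. GC fraction
#' is computed from the reference over non-N bases; bins containing any "N"
#' are flagged for removal by [filter_n_bins()].
#'
#' @param rc Per-base read-count vector (from [extract_read_counts()]).
#' @param bin_size Bin width in bp (default 1000).
#' @param reference_seq Reference sequence for the same contig: a
#'   [Biostrings::DNAString] or a single character string, of length
#'   `length(rc)`.
#' @param contig Contig name stored in the profile.
#' @return An [rd_profile()].
#' @export
bin_profile <- function(rc, bin_size = 1000, reference_seq,
                        contig = "chr1") {
    stopifnot(bin_size >= 1)
    if (is.character(reference_seq))
        reference_seq <- Biostrings::DNAString(reference_seq)
    if (length(reference_seq) != length(rc))
        stop("reference length (", length(reference_seq),
             ") != read-count vector length (", length(rc), ")")
    n_bins <- length(rc) %/% bin_size
    if (n_bins < 1L) stop("contig shorter than one bin")
    used <- n_bins * bin_size
    rc_mean <- colMeans(matrix(as.numeric(rc[seq_len(used)]),
                               nrow = bin_size))
    starts <- (seq_len(n_bins) - 1L) * bin_size
    v <- Biostrings::Views(reference_seq, start = starts + 1L,
                           width = bin_size)
    cg <- as.vector(Biostrings::letterFrequency(v, "CG"))
    nn <- as.vector(Biostrings::letterFrequency(v, "N"))
    non_n <- bin_size - nn
    gc <- ifelse(non_n > 0, cg / non_n, 0)
    rd_profile(contig = contig, bin_size = bin_size, bin_start = starts,
               rc_mean = rc_mean, gc_frac = gc, has_n = nn > 0L)
}

#' Remove bins overlapping reference "N" runs
#'
#' Reads cannot align over uncalled reference bases, so bins containing "N"
#' would masquerade as copy-number losses; they are discarded. Original
#' `bin_start` coordinates are retained, so the genomic position of every
#' surviving bin is unchanged (the profile simply acquires gaps).
#'
#' @param profile An [rd_profile()] with `has_n` populated.
#' @return The profile restricted to usable bins.
#' @export
filter_n_bins <- function(profile) {
    stopifnot(inherits(profile, "rd_profile"))
    keep <- !profile$has_n
    if (!any(keep)) stop("no usable bins: every bin contains an 'N' position")
    out <- profile[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "contig") <- attr(profile, "contig")
    attr(out, "bin_size") <- attr(profile, "bin_size")
    class(out) <- class(profile)
    out
}

#' Calibrate GC-content bias by a mean-ratio correction
#'
#' Bins are grouped into GC classes (GC fraction rounded onto
#' `n_gc_bins` equally spaced levels; the default 101 corresponds to whole
#' percentage points). Each bin's depth is rescaled by the ratio of the
#' global mean depth to the mean depth of its GC class:
#' `rd_corrected = rc_mean * mean(rc_mean) / mean(rc_mean[same GC class])`.
#' After correction every occupied GC class has the same mean depth, while
#' the ordering of depths within a class is preserved. A class whose mean
#' depth is zero cannot be rescaled; its bins are left uncorrected with a
#' warning.
#'
#' @param profile An [rd_profile()] (usually after [filter_n_bins()]).
#' @param n_gc_bins Number of GC classes (default 101, i.e. integer percent).
#' @return The profile with `rd_corrected` filled in.
#' @export
correct_gc <- function(profile, n_gc_bins = 101) {
    stopifnot(inherits(profile, "rd_profile"), n_gc_bins >= 2)
    if (nrow(profile) < 1L) stop("profile has no bins")
    cls <- round(profile$gc_frac * (n_gc_bins - 1))
    global_mean <- mean(profile$rc_mean)
    class_mean <- stats::ave(profile$rc_mean, cls)
    corrected <- profile$rc_mean * global_mean / class_mean
    zero <- class_mean == 0
    if (any(zero)) {
        warning(sum(zero), " bin(s) in zero-mean GC classes left uncorrected")
        corrected[zero] <- profile$rc_mean[zero]
    }
    profile$rd_corrected <- corrected
    profile
}
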