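#' Otsu threshold of an intensity sample
#'
#' Bins the intensities into `bins` equal-width bins over their range and
#' returns the bin edge that maximizes the between-class variance
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2} of the split at that edge.
#' Binning is right-closed, so a value exactly equal to the returned
#' threshold falls in the lower class — consistent with the
#' `value <= threshold` labelling rule used by [partition_shell()]. Ties are
#' broken toward the lowest qualifying threshold, making the result
#' deterministic.
#'
#' @param values nonempty numeric vector with at least two distinct values.
#' @param bins number of histogram bins (default 256).
#' @return The threshold (a bin edge), with attribute `between_var` giving
#'   the attained between-class variance.
#' @export
otsu_threshold <- function(values, bins = 256L) {
    values <- as.numeric(values)
    if (length(values) == 0L) empty_region_error("no intensities to threshold")
    if (!all(is.finite(values))) sc_stop("value_error", "intensities must be finite")
    bins <- as.integer(bins)
    if (bins < 2L) config_error("bins must be >= 2")
    lo <- min(values); hi <- max(values)
    if (lo == hi)
        degenerate_histogram_error("all intensities identical; no threshold exists")

    width <- (hi - lo) / bins
    # right-closed bins (lo, lo+w], ..., first bin closed on the left
    idx <- pmin(pmax(ceiling((values - lo) / width), 1L), bins)
    counts <- tabulate(idx, nbins = bins)
    centers <- lo + (seq_len(bins) - 0.5) * width
    edges <- lo + seq_len(bins - 1L) * width

    n <- length(values)
    w0 <- cumsum(counts)[-bins] / n
    w1 <- 1 - w0
    csum <- cumsum(counts * centers)[-bins]
    total <- sum(counts * centers)
    mu0 <- ifelse(w0 > 0, csum / (w0 * n), 0)
    mu1 <- ifelse(w1 > 0, (total - csum) / (w1 * n), 0)
    bcv <- w0 * w1 * (mu0 - mu1)^2

    k <- which.max(bcv)   # first maximum -> lowest qualifying threshold
    structure(edges[k], between_var = bcv[k])
}

#' Partition a boundary shell into adipose and fibroglandular tissue
#'
#' Applies [otsu_threshold()] to the shell's intensities and labels voxels
#' `<= threshold` adipose and `> threshold` fibroglandular. On
#' fat-suppressed contrast-enhanced T1 imaging adipose is the dark class and
#' enhancing fibroglandular tissue the bright one, which fixes the side of
#' the split. If every shell voxel has the same intensity no threshold
#' exists; the whole shell is then assigned to one tissue by comparing the
#' shell mean against the tumor mean (darker than tumor reads as adipose)
#' and the result is flagged `degenerate_partition`.
#'
#' @param volume [image_volume()] the shell was drawn on.
#' @param shell a `boundary_shell` from [build_boundary_shell()].
#' @param bins histogram bins passed to [otsu_threshold()].
#' @return An object of class `boundary_partition`: `adipose` and
#'   `fibroglandular` ([region_mask()]s), `threshold`, `histogram_bins`,
#'   `fibro_fraction` (fibroglandular shell volume over total shell volume),
#'   `degenerate`, `flags`.
#' @export
partition_shell <- function(volume, shell, bins = 256L) {
    stopifnot(inherits(volume, "image_volume"), inherits(shell, "boundary_shell"))
    shell_arr <- shell$mask$mask
    if (!any(shell_arr)) empty_region_error("boundary shell is empty")
    vals <- volume$data[shell_arr]

    degenerate <- FALSE
    thr <- tryCatch(otsu_threshold(vals, bins = bins),
                    degenerate_histogram_error = function(e) NULL)
    if (is.null(thr)) {
        degenerate <- TRUE
        tumor_mean <- mean(volume$data[shell$tumor$mask])
        all_adipose <- mean(vals) < tumor_mean
        fib_arr <- shell_arr & !all_adipose
        adi_arr <- shell_arr & all_adipose
        thr <- NA_real_
    } else {
        adi_arr <- shell_arr & (volume$data <= as.numeric(thr))
        fib_arr <- shell_arr & (volume$data > as.numeric(thr))
    }

    sp <- shell$mask$spacing
    v_fib <- sum(fib_arr) * voxel_volume(sp)
    v_adi <- sum(adi_arr) * voxel_volume(sp)
    flags <- character(0)
    if (degenerate) flags <- c(flags, "degenerate_partition")
    if (v_adi == 0) flags <- c(flags, "no_adipose")
    if (v_fib == 0) flags <- c(flags, "no_fibro")

    structure(list(
        adipose = region_mask(adi_arr, sp),
        fibroglandular = region_mask(fib_arr, sp),
        threshold = as.numeric(thr),
        histogram_bins = as.integer(bins),
        fibro_fraction = v_fib / (v_fib + v_adi),
        degenerate = degenerate,
        flags = flags
    ), class = "boundary_partition")
}

#' @export
print.boundary_partition <- function(x, ...) {
    cat(sprintf("<boundary_partition> threshold %.4g, fibro fraction %.3f%s\n",
                x$threshold, x$fibro_fraction,
                if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
                else ""))
    invisible(x)
}
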