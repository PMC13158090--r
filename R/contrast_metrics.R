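#' Michelson contrast between two region means
#'
#' \eqn{(\bar{I}_a - \bar{I}_b) / (\bar{I}_a + \bar{I}_b)}, the normalized
#' contrast between two nonnegative mean signal intensities. Bounded in
#' \[-1, 1\] and invariant to global intensity scaling, which is what makes
#' it comparable across scanners and sequences.
#'
#' @param mean_a,mean_b region mean intensities.
#' @return The contrast, in \[-1, 1\].
#' @export
michelson_contrast <- function(mean_a, mean_b) {
    if (!is.finite(mean_a) || !is.finite(mean_b))
        sc_stop("value_error", "region means must be finite")
    s <- mean_a + mean_b
    if (s == 0)
        undefined_contrast_error("contrast undefined: region means sum to zero")
    (mean_a - mean_b) / s
}

#' Rank-based ROC AUC between two intensity samples
#'
#' Probability that a randomly drawn positive-score exceeds a randomly drawn
#' negative-score, ties counted 1/2 — identical to the Mann-Whitney
#' \eqn{U/(n_1 n_2)} statistic. Midranks implement the tie rule without
#' enumerating pairs.
#'
#' @param positives,negatives numeric score vectors (here voxel intensities,
#'   tumor voxels as positives).
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(positives, negatives) {
    n1 <- length(positives); n2 <- length(negatives)
    if (n1 == 0L || n2 == 0L)
        empty_region_error("AUC needs at least one score in each group")
    r <- rank(c(positives, negatives))
    (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# robust noise-sigma estimate from the darkest decile of the shell, used when
# no air background is available
estimate_noise_sigma <- function(shell_vals) {
    q10 <- stats::quantile(shell_vals, 0.1, names = FALSE, type = 7)
    low <- shell_vals[shell_vals <= q10]
    stats::mad(low)
}

#' Per-case contrast report
#'
#' Computes every per-case metric from the volume, tumor mask, boundary
#' shell and tissue partition: mean intensities of tumor, whole shell,
#' adipose and fibroglandular compartments; the three Michelson contrasts
#' (tumor-to-boundary, tumor-to-adipose, tumor-to-fibroglandular);
#' fibroglandular boundary composition; SNR (= mean/sigma) per region and
#' CNR (= mean difference/sigma) per tissue pair; voxelwise ROC AUC of tumor
#' versus each tissue; and tumor size/shape metrics.
#'
#' The noise scale sigma comes from, in order of preference: the
#' `noise_sigma` argument; the standard deviation inside `air` (a background
#' region outside the body); or a robust estimate (MAD) over the darkest
#' decile of shell intensities. If none yields a positive sigma, SNR/CNR are
#' reported as `NA` with the `noise_estimation_failed` flag — contrasts and
#' AUCs are still computed. Metrics whose tissue compartment is empty are
#' `NA` with a `no_adipose`/`no_fibro` flag, never silently zero.
#'
#' @param volume [image_volume()].
#' @param tumor tumor [region_mask()].
#' @param shell `boundary_shell` from [build_boundary_shell()].
#' @param partition `boundary_partition` from [partition_shell()].
#' @param noise_sigma optional known noise standard deviation.
#' @param air optional [region_mask()] of background air for noise
#'   estimation.
#' @param case_id,cohort_label identifiers carried into the report.
#' @return An object of class `case_report` (a named list; see
#'   [report_as_row()] for the flat form).
#' @export
case_report <- function(volume, tumor, shell, partition,
                        noise_sigma = NULL, air = NULL,
                        case_id = NA_character_, cohort_label = NA_character_) {
    stopifnot(inherits(volume, "image_volume"), inherits(tumor, "region_mask"),
              inherits(shell, "boundary_shell"),
              inherits(partition, "boundary_partition"))
    if (!any(tumor$mask)) empty_region_error("tumor mask contains no voxels")

    tum_vals <- volume$data[tumor$mask]
    shell_vals <- volume$data[shell$mask$mask]
    adi_vals <- volume$data[partition$adipose$mask]
    fib_vals <- volume$data[partition$fibroglandular$mask]

    flags <- union(shell$flags, partition$flags)

    mean_tum <- mean(tum_vals)
    mean_shell <- mean(shell_vals)
    mean_adi <- if (length(adi_vals)) mean(adi_vals) else NA_real_
    mean_fib <- if (length(fib_vals)) mean(fib_vals) else NA_real_

    safe_contrast <- function(a, b) {
        if (is.na(a) || is.na(b)) return(NA_real_)
        tryCatch(michelson_contrast(a, b),
                 undefined_contrast_error = function(e) NA_real_)
    }

    sigma <- if (!is.null(noise_sigma)) {
        as.numeric(noise_sigma)
    } else if (!is.null(air)) {
        stats::sd(volume$data[air$mask])
    } else {
        estimate_noise_sigma(shell_vals)
    }
    if (!is.finite(sigma) || sigma <= 0) {
        sigma <- NA_real_
        flags <- union(flags, "noise_estimation_failed")
    }

    rep <- list(
        case_id = case_id,
        cohort_label = cohort_label,
        mean_tumor = mean_tum,
        mean_boundary = mean_shell,
        mean_adipose = mean_adi,
        mean_fibro = mean_fib,
        contrast_tumor_boundary = safe_contrast(mean_tum, mean_shell),
        contrast_tumor_adipose = safe_contrast(mean_tum, mean_adi),
        contrast_tumor_fibro = safe_contrast(mean_tum, mean_fib),
        fibro_fraction = partition$fibro_fraction,
        otsu_threshold = partition$threshold,
        noise_sigma = sigma,
        snr_tumor = mean_tum / sigma,
        snr_adipose = mean_adi / sigma,
        snr_fibro = mean_fib / sigma,
        cnr_tumor_adipose = (mean_tum - mean_adi) / sigma,
        cnr_tumor_fibro = (mean_tum - mean_fib) / sigma,
        auc_tumor_adipose = if (length(adi_vals)) rank_auc(tum_vals, adi_vals)
                            else NA_real_,
        auc_tumor_fibro = if (length(fib_vals)) rank_auc(tum_vals, fib_vals)
                          else NA_real_,
        shape = shape_metrics(tumor),
        shell_volume_mm3 = shell$shell_volume_mm3,
        shell_thickness_mm = shell$thickness_mm,
        flags = flags
    )
    class(rep) <- "case_report"
    rep
}

#' @export
print.case_report <- function(x, ...) {
    cat(sprintf("<case_report> %s (%s)\n", x$case_id, x$cohort_label))
    cat(sprintf("  contrast  t-boundary %.3f | t-adipose %s | t-fibro %s\n",
                x$contrast_tumor_boundary,
                formatC(x$contrast_tumor_adipose, format = "f", digits = 3),
                formatC(x$contrast_tumor_fibro, format = "f", digits = 3)))
    cat(sprintf("  fibro fraction %.3f, AUC t-fibro %s, CNR t-fibro %s\n",
                x$fibro_fraction,
                formatC(x$auc_tumor_fibro, format = "f", digits = 3),
                formatC(x$cnr_tumor_fibro, format = "f", digits = 2)))
    if (length(x$flags))
        cat("  flags:", paste(x$flags, collapse = ", "), "\n")
    invisible(x)
}

#' Flatten a case report to a one-row data frame
#'
#' Column order is stable so cohort CSVs from different runs align.
#'
#' @param rep a `case_report`.
#' @return A one-row data.frame; `flags` are joined with `;`.
#' @export
report_as_row <- function(rep) {
    stopifnot(inherits(rep, "case_report"))
    data.frame(
        case_id = rep$case_id,
        cohort_label = rep$cohort_label,
        contrast_tumor_boundary = rep$contrast_tumor_boundary,
        contrast_tumor_adipose = rep$contrast_tumor_adipose,
        contrast_tumor_fibro = rep$contrast_tumor_fibro,
        fibro_fraction = rep$fibro_fraction,
        otsu_threshold = rep$otsu_threshold,
        noise_sigma = rep$noise_sigma,
        snr_tumor = rep$snr_tumor,
        snr_adipose = rep$snr_adipose,
        snr_fibro = rep$snr_fibro,
        cnr_tumor_adipose = rep$cnr_tumor_adipose,
        cnr_tumor_fibro = rep$cnr_tumor_fibro,
        auc_tumor_adipose = rep$auc_tumor_adipose,
        auc_tumor_fibro = rep$auc_tumor_fibro,
        volume_mm3 = rep$shape$volume_mm3,
        max_extent_mm = rep$shape$max_extent_mm,
        surface_area_mm2 = rep$shape$surface_area_mm2,
        sphericity = rep$shape$sphericity,
        shell_volume_mm3 = rep$shell_volume_mm3,
        shell_thickness_mm = rep$shell_thickness_mm,
        flags = paste(rep$flags, collapse = ";"),
        stringsAsFactors = FALSE
    )
}
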