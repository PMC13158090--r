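#' Run configuration for the analysis pipeline
#'
#' @param manifest_path per-case manifest CSV (see [read_manifest()]).
#' @param out_dir output directory for CSV/JSON reports; `NULL` keeps
#'   results in memory only.
#' @param otsu_bins histogram bins for tissue classification.
#' @param noise_mode `"air_background"` (noise SD from outside the body
#'   mask), `"shell_decile"` (robust SD of the darkest shell decile), or
#'   `"provided"` with `noise_sigma` set.
#' @param noise_sigma known noise SD when `noise_mode = "provided"`.
#' @param margin non-inferiority margin on the contrast difference
#'   (default -0.1, i.e. a 0.1 drop in normalized contrast units).
#' @param alpha_two_sided,alpha_noninf significance levels (0.05 / 0.025).
#' @param reference_cohort cohort label serving as the non-inferiority
#'   reference (the standard-of-care arm); must be named, never inferred.
#' @param write_label_maps write per-case tumor/adipose/fibro label maps.
#' @return An object of class `run_config`.
#' @export
run_config <- function(manifest_path = NULL, out_dir = NULL,
                       otsu_bins = 256L,
                       noise_mode = c("air_background", "shell_decile",
                                      "provided"),
                       noise_sigma = NULL, margin = -0.1,
                       alpha_two_sided = 0.05, alpha_noninf = 0.025,
                       reference_cohort = NULL, write_label_maps = FALSE) {
    noise_mode <- match.arg(noise_mode)
    if (!is.finite(margin) || margin >= 0)
        config_error("margin must be a negative difference")
    for (a in c(alpha_two_sided, alpha_noninf))
        if (a <= 0 || a >= 1) config_error("alpha levels must lie in (0, 1)")
    if (noise_mode == "provided" && is.null(noise_sigma))
        config_error("noise_mode 'provided' requires noise_sigma")
    structure(list(manifest_path = manifest_path, out_dir = out_dir,
                   otsu_bins = as.integer(otsu_bins), noise_mode = noise_mode,
                   noise_sigma = noise_sigma, margin = margin,
                   alpha_two_sided = alpha_two_sided,
                   alpha_noninf = alpha_noninf,
                   reference_cohort = reference_cohort,
                   write_label_maps = write_label_maps),
              class = "run_config")
}

# shell -> partition -> metrics on already-loaded objects
analyze_loaded_case <- function(config, volume, tumor, body = NULL,
                                case_id = NA_character_,
                                cohort_label = NA_character_) {
    shell <- build_boundary_shell(tumor, volume, body = body)
    partition <- partition_shell(volume, shell, bins = config$otsu_bins)
    air <- NULL
    noise_sigma <- NULL
    if (config$noise_mode == "provided") {
        noise_sigma <- config$noise_sigma
    } else if (config$noise_mode == "air_background" && !is.null(body)) {
        air <- region_mask(!body$mask, body$spacing)
    }
    rep <- case_report(volume, tumor, shell, partition,
                       noise_sigma = noise_sigma, air = air,
                       case_id = case_id, cohort_label = cohort_label)
    if (isTRUE(config$write_label_maps) && !is.null(config$out_dir)) {
        dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
        write_label_map(tumor, shell, partition,
                        file.path(config$out_dir,
                                  paste0(case_id, "_labels.nii.gz")))
    }
    rep
}

#' Analyze one manifest case
#'
#' Loads the case files and composes the per-case stages in order: boundary
#' shell growth, Otsu tissue partition, contrast/SNR/CNR/AUC metrics.
#'
#' @param config a [run_config()].
#' @param row one manifest row (list or 1-row data.frame) with `case_id`,
#'   `cohort_label`, `volume_path`, `tumor_mask_path`, optional
#'   `body_mask_path`.
#' @return A `case_report`.
#' @export
run_case <- function(config, row) {
    bmp <- row$body_mask_path
    if (!is.null(bmp) && (is.na(bmp) || bmp == "")) bmp <- NULL
    case <- load_case(row$volume_path, row$tumor_mask_path, bmp)
    analyze_loaded_case(config, case$volume, case$tumor, case$body,
                        case_id = row$case_id,
                        cohort_label = row$cohort_label)
}

#' Analyze every case in a manifest
#'
#' Failed cases are logged and skipped; the batch continues and the failures
#' are listed in the returned summary.
#'
#' @param config a [run_config()] with `manifest_path` set (or `manifest`
#'   given directly).
#' @param manifest optional manifest data.frame overriding
#'   `config$manifest_path`.
#' @return List with `reports` (data.frame, one row per successful case, in
#'   [report_as_row()] column order) and `failures` (data.frame of case_id
#'   + error message). When `config$out_dir` is set, `case_reports.csv` is
#'   written there.
#' @export
analyze_manifest <- function(config, manifest = NULL) {
    stopifnot(inherits(config, "run_config"))
    if (is.null(manifest)) {
        if (is.null(config$manifest_path))
            config_error("no manifest given")
        manifest <- read_manifest(config$manifest_path)
    }
    rows <- list(); fails <- list()
    for (i in seq_len(nrow(manifest))) {
        row <- manifest[i, ]
        res <- tryCatch(report_as_row(run_case(config, row)),
                        error = function(e) e)
        if (inherits(res, "error")) {
            message(sprintf("case %s failed: %s", row$case_id,
                            conditionMessage(res)))
            fails[[length(fails) + 1L]] <-
                data.frame(case_id = row$case_id,
                           error = conditionMessage(res),
                           stringsAsFactors = FALSE)
        } else {
            rows[[length(rows) + 1L]] <- res
        }
    }
    reports <- if (length(rows)) do.call(rbind, rows) else NULL
    failures <- if (length(fails)) do.call(rbind, fails) else
        data.frame(case_id = character(0), error = character(0))
    if (!is.null(config$out_dir) && !is.null(reports)) {
        dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(reports,
                         file.path(config$out_dir, "case_reports.csv"),
                         row.names = FALSE)
    }
    list(reports = reports, failures = failures)
}

metrics_for_comparison <- function() {
    c("contrast_tumor_fibro", "contrast_tumor_adipose", "fibro_fraction",
      "snr_tumor", "cnr_tumor_fibro", "cnr_tumor_adipose",
      "auc_tumor_fibro", "auc_tumor_adipose")
}

#' Cohort-level statistical comparison
#'
#' For every metric and every pair of cohort labels: Welch two-sample test
#' (two-sided, alpha 0.05), Mann-Whitney U test, per-group KS normality p,
#' and post-hoc power at the observed effect. For the two normalized
#' contrast metrics, cohorts are additionally tested for non-inferiority
#' against the designated reference cohort (margin -0.1, one-sided alpha
#' 0.025), emitted as a forest-plot table (difference, 95% CI, margin,
#' verdict). Within each cohort, tumor-to-boundary contrast is correlated
#' (Pearson + Fisher-z 95% CI) with fibroglandular boundary composition and
#' with tumor volume, maximum extent and sphericity. Tumor-to-boundary
#' contrast itself is never compared across cohorts: it depends on the
#' per-case tissue composition, which is exactly what the correlation
#' analysis quantifies. Flagged/missing metric values are excluded listwise
#' per metric.
#'
#' @param reports case-report data.frame from [analyze_manifest()] (or any
#'   table with the same columns).
#' @param config a [run_config()]; `reference_cohort` must be one of the
#'   cohort labels present.
#' @return An object of class `cohort_comparison`: `summaries`,
#'   `comparisons`, `noninferiority` (list of `comparison_result`),
#'   `forest`, `correlations`. CSVs are written to `config$out_dir` if set.
#' @export
run_cohort_comparison <- function(reports, config = run_config()) {
    labs <- unique(reports$cohort_label)
    if (length(labs) < 2L)
        config_error("cohort comparison needs >= 2 cohorts")
    ref <- config$reference_cohort
    if (!is.null(ref) && !(ref %in% labs))
        config_error(sprintf("unknown reference cohort '%s'", ref))

    metrics <- intersect(metrics_for_comparison(), names(reports))
    vals <- function(lab, metric) {
        v <- reports[[metric]][reports$cohort_label == lab]
        v[is.finite(v)]
    }

    summaries <- do.call(rbind, lapply(labs, function(lab) {
        do.call(rbind, lapply(metrics, function(m) {
            v <- vals(lab, m)
            data.frame(cohort_label = lab, metric = m, n = length(v),
                       mean = if (length(v)) mean(v) else NA_real_,
                       sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                       median = if (length(v)) stats::median(v) else NA_real_,
                       stringsAsFactors = FALSE)
        }))
    }))

    pairs <- utils::combn(labs, 2, simplify = FALSE)
    comp_rows <- list()
    for (m in metrics) {
        for (pr in pairs) {
            va <- vals(pr[1], m); vb <- vals(pr[2], m)
            if (length(va) < 2L || length(vb) < 2L) {
                comp_rows[[length(comp_rows) + 1L]] <- data.frame(
                    metric = m, cohort_a = pr[1], cohort_b = pr[2],
                    n_a = length(va), n_b = length(vb),
                    mean_diff = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                    p_welch = NA_real_, p_mwu = NA_real_,
                    power_posthoc = NA_real_,
                    normality_p_a = NA_real_, normality_p_b = NA_real_,
                    skipped = "insufficient_n", stringsAsFactors = FALSE)
                next
            }
            w <- welch_test(va, vb)
            mw <- mwu_test(va, vb)
            pow <- if (w$degenerate) NA_real_ else posthoc_power(
                list(mean = mean(va), sd = stats::sd(va), n = length(va)),
                list(mean = mean(vb), sd = stats::sd(vb), n = length(vb)),
                alpha = config$alpha_two_sided, sided = 2)
            ka <- if (length(va) >= 5) ks_normality(va)$p else NA_real_
            kb <- if (length(vb) >= 5) ks_normality(vb)$p else NA_real_
            comp_rows[[length(comp_rows) + 1L]] <- data.frame(
                metric = m, cohort_a = pr[1], cohort_b = pr[2],
                n_a = length(va), n_b = length(vb),
                mean_diff = w$mean_diff, ci_lo = w$ci95[1], ci_hi = w$ci95[2],
                p_welch = w$p_two_sided, p_mwu = mw$p, power_posthoc = pow,
                normality_p_a = ka, normality_p_b = kb,
                skipped = "", stringsAsFactors = FALSE)
        }
    }
    comparisons <- do.call(rbind, comp_rows)

    noninf <- list(); forest_rows <- list()
    if (!is.null(ref)) {
        contrast_metrics_ni <- intersect(
            c("contrast_tumor_fibro", "contrast_tumor_adipose"), metrics)
        for (m in contrast_metrics_ni) {
            vref <- vals(ref, m)
            for (lab in setdiff(labs, ref)) {
                vnew <- vals(lab, m)
                if (length(vnew) < 2L || length(vref) < 2L) next
                ni <- noninferiority_test(vnew, vref,
                                          margin = config$margin,
                                          alpha = config$alpha_noninf,
                                          metric = m)
                key <- paste(m, lab, sep = ".")
                noninf[[key]] <- ni
                forest_rows[[key]] <- data.frame(
                    metric = m, cohort = lab, reference = ref,
                    mean_diff = ni$mean_diff,
                    ci_lo = ni$ci95[1], ci_hi = ni$ci95[2],
                    margin = ni$noninferiority_margin,
                    p_noninferiority = ni$p_noninferiority,
                    power_posthoc = ni$power_posthoc,
                    verdict = ni$verdict, stringsAsFactors = FALSE)
            }
        }
    }
    forest <- if (length(forest_rows)) do.call(rbind, unname(forest_rows))
              else NULL

    cor_rows <- list()
    cor_targets <- intersect(c("fibro_fraction", "volume_mm3",
                               "max_extent_mm", "sphericity"),
                             names(reports))
    for (lab in labs) {
        sub <- reports[reports$cohort_label == lab, ]
        for (tgt in cor_targets) {
            keep <- is.finite(sub$contrast_tumor_boundary) &
                    is.finite(sub[[tgt]])
            if (sum(keep) < 4L || stats::var(sub[[tgt]][keep]) == 0) next
            pc <- tryCatch(
                pearson_with_ci(sub[[tgt]][keep],
                                sub$contrast_tumor_boundary[keep]),
                shellcontrast_error = function(e) NULL)
            if (is.null(pc)) next
            cor_rows[[paste(lab, tgt)]] <- data.frame(
                cohort = lab, x = tgt, y = "contrast_tumor_boundary",
                n = pc$n, r = pc$r, ci_lo = pc$ci95[1], ci_hi = pc$ci95[2],
                stringsAsFactors = FALSE)
        }
    }
    correlations <- if (length(cor_rows)) do.call(rbind, unname(cor_rows))
                    else NULL

    out <- structure(list(summaries = summaries, comparisons = comparisons,
                          noninferiority = noninf, forest = forest,
                          correlations = correlations,
                          reference_cohort = ref, config = config),
                     class = "cohort_comparison")
    if (!is.null(config$out_dir)) {
        dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(comparisons,
                         file.path(config$out_dir, "comparisons.csv"),
                         row.names = FALSE)
        if (!is.null(forest))
            utils::write.csv(forest,
                             file.path(config$out_dir, "forest.csv"),
                             row.names = FALSE)
        if (!is.null(correlations))
            utils::write.csv(correlations,
                             file.path(config$out_dir, "correlations.csv"),
                             row.names = FALSE)
    }
    out
}

#' @export
print.cohort_comparison <- function(x, ...) {
    cat("<cohort_comparison>\n")
    cat(sprintf("  cohorts: %s\n",
                paste(unique(x$summaries$cohort_label), collapse = ", ")))
    if (!is.null(x$forest)) {
        cat(sprintf("  non-inferiority vs '%s' (margin %.2f):\n",
                    x$reference_cohort, x$config$margin))
        for (i in seq_len(nrow(x$forest)))
            cat(sprintf("    %-24s %-12s diff %+.3f [%+.3f, %+.3f] -> %s\n",
                        x$forest$metric[i], x$forest$cohort[i],
                        x$forest$mean_diff[i], x$forest$ci_lo[i],
                        x$forest$ci_hi[i], x$forest$verdict[i]))
    }
    if (!is.null(x$correlations)) {
        cat("  tumor-to-boundary contrast correlations:\n")
        for (i in seq_len(nrow(x$correlations)))
            cat(sprintf("    %-12s vs %-14s r = %+.2f [%+.2f, %+.2f] (n=%d)\n",
                        x$correlations$cohort[i], x$correlations$x[i],
                        x$correlations$r[i], x$correlations$ci_lo[i],
                        x$correlations$ci_hi[i], x$correlations$n[i]))
    }
    invisible(x)
}
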