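# evaluate expr under a fixed RNG seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}

# separable Gaussian smoothing with replicate-padding at the edges;
# sigma_vox per axis in voxels, 0 skips the axis
smooth_gaussian3d <- function(arr, sigma_vox) {
    d <- dim(arr)
    for (ax in 1:3) {
        s <- sigma_vox[ax]
        if (s <= 0) next
        half <- max(1L, ceiling(3 * s))
        w <- stats::dnorm(-half:half, sd = s)
        w <- w / sum(w)
        n <- d[ax]
        acc <- array(0, d)
        for (k in -half:half) {
            idx <- pmin(pmax(seq_len(n) + k, 1L), n)
            sl <- switch(ax,
                         arr[idx, , , drop = FALSE],
                         arr[, idx, , drop = FALSE],
                         arr[, , idx, drop = FALSE])
            acc <- acc + w[k + half + 1L] * sl
        }
        arr <- acc
    }
    arr
}

#' Specify a synthetic breast MRI phantom
#'
#' Describes one phantom case: a compact ellipsoidal tumor of elevated mean
#' intensity inside a body (breast) region whose remaining tissue is a
#' mixture of dark adipose and brighter fibroglandular voxels, surrounded by
#' near-zero air. The fibro/adipose arrangement is a smoothed random field
#' thresholded to hit `fibro_fraction`, which reproduces the bimodal shell
#' histograms of fat-suppressed contrast-enhanced imaging while keeping the
#' ground-truth labels exact. Intensity defaults follow the ordering tumor >
#' fibroglandular > adipose > air of fat-suppressed post-contrast T1.
#'
#' @param shape grid dimensions (voxels), default `c(48, 48, 32)`.
#' @param spacing voxel spacing in mm, default `c(1, 1, 2)` (typical axial
#'   in-plane resolution with 2 mm slices).
#' @param semi_axes tumor ellipsoid semi-axes in mm, default `c(8, 8, 8)`
#'   (~16 mm lesion).
#' @param center tumor centre in mm; default the grid centre.
#' @param means named intensities `c(tumor=, fibro=, adipose=, air=)`;
#'   the defaults put adipose near the noise floor, as fat suppression
#'   does, with enhancing fibroglandular tissue well above it and the
#'   early-phase tumor brightest.
#' @param noise_sigma additive noise SD (scanner units).
#' @param noise_model `"gaussian"` (default; magnitude MRI at moderate SNR)
#'   or `"rician"`.
#' @param fibro_fraction target fibroglandular fraction of the peritumoral
#'   body tissue, in \[0, 1\].
#' @param texture_length correlation length of the tissue texture in mm
#'   (0 = voxelwise white noise labels).
#' @param seed RNG seed; the phantom is deterministic given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(48L, 48L, 32L), spacing = c(1, 1, 2),
                         semi_axes = c(8, 8, 8), center = NULL,
                         means = c(tumor = 400, fibro = 100,
                                   adipose = 20, air = 2),
                         noise_sigma = 10, noise_model = c("gaussian", "rician"),
                         fibro_fraction = 0.3, texture_length = 4, seed = 1L) {
    noise_model <- match.arg(noise_model)
    shape <- as.integer(shape)
    if (length(shape) != 3L || any(shape < 4L))
        spec_error("phantom grid must be 3D with every axis >= 4 voxels")
    extent <- shape * spacing
    if (is.null(center)) center <- extent / 2
    if (any(center - semi_axes < 0) || any(center + semi_axes > extent))
        spec_error("tumor ellipsoid extends outside the grid")
    if (fibro_fraction < 0 || fibro_fraction > 1)
        spec_error("fibro_fraction must lie in [0, 1]")
    if (noise_sigma < 0) spec_error("noise_sigma must be >= 0")
    structure(list(shape = shape, spacing = spacing, semi_axes = semi_axes,
                   center = center, means = means, noise_sigma = noise_sigma,
                   noise_model = noise_model, fibro_fraction = fibro_fraction,
                   texture_length = texture_length, seed = as.integer(seed)),
              class = "phantom_spec")
}

#' Generate a phantom case
#'
#' Deterministic given the spec (including its seed). Returns the noisy
#' volume plus exact ground truth: the tumor mask, the body mask, and the
#' full tissue label field (0 air, 1 tumor, 2 adipose, 3 fibroglandular).
#' The fibro/adipose split thresholds a smoothed standard-normal field at
#' an empirical quantile, taken over the equal-volume peritumoral
#' neighborhood (the same deterministic layer [build_boundary_shell()]
#' grows), so the realized fibroglandular fraction of that neighborhood
#' matches the target to within one voxel; the same threshold labels the
#' rest of the body tissue. `truth$fibro_fraction_realized` reports the
#' realized neighborhood fraction.
#'
#' @param spec a [phantom_spec()].
#' @return List with `volume` ([image_volume()]), `tumor`, `body`
#'   ([region_mask()]s), `labels` (integer array), `spec`, and
#'   `truth` (realized means/fractions and analytic expected contrasts).
#' @export
make_phantom <- function(spec) {
    stopifnot(inherits(spec, "phantom_spec"))
    d <- spec$shape; sp <- spec$spacing
    xs <- (seq_len(d[1]) - 1) * sp[1]
    ys <- (seq_len(d[2]) - 1) * sp[2]
    zs <- (seq_len(d[3]) - 1) * sp[3]

    # squared normalized ellipsoid coordinate, separable outer sum
    quad <- function(c0, ax) {
        ex <- outer(((xs - c0[1]) / ax[1])^2,
                    ((ys - c0[2]) / ax[2])^2, `+`)
        outer(ex, ((zs - c0[3]) / ax[3])^2, `+`)
    }
    tumor_arr <- quad(spec$center, spec$semi_axes) <= 1
    extent <- d * sp
    body_arr <- quad(extent / 2, 0.45 * extent) <= 1
    tumor_arr <- tumor_arr & body_arr
    if (!any(tumor_arr)) spec_error("tumor ellipsoid contains no voxels")

    # the fraction target governs the peritumoral neighborhood: the same
    # equal-volume layer the analysis will measure, built with the identical
    # deterministic construction
    tumor_rm <- region_mask(tumor_arr, sp)
    body_rm <- region_mask(body_arr, sp)
    nbhd <- build_boundary_shell(tumor_rm, image_volume(array(0, d), sp),
                                 body = body_rm)$mask$mask

    with_seed(spec$seed, {
        field <- array(stats::rnorm(prod(d)), d)
        if (spec$texture_length > 0)
            field <- smooth_gaussian3d(field, spec$texture_length / sp)
        peri <- body_arr & !tumor_arr
        thr <- stats::quantile(field[nbhd], 1 - spec$fibro_fraction,
                               names = FALSE)
        fibro_arr <- peri & (field > thr)
        adipose_arr <- peri & !fibro_arr

        labels <- array(0L, d)
        labels[tumor_arr] <- 1L
        labels[adipose_arr] <- 2L
        labels[fibro_arr] <- 3L

        m <- spec$means
        signal <- array(m[["air"]], d)
        signal[tumor_arr] <- m[["tumor"]]
        signal[adipose_arr] <- m[["adipose"]]
        signal[fibro_arr] <- m[["fibro"]]

        s <- spec$noise_sigma
        data <- if (s == 0) {
            signal
        } else if (spec$noise_model == "gaussian") {
            signal + array(stats::rnorm(prod(d), sd = s), d)
        } else {
            sqrt((signal + array(stats::rnorm(prod(d), sd = s), d))^2 +
                 array(stats::rnorm(prod(d), sd = s), d)^2)
        }
    })

    exp_contrast <- function(a, b) (a - b) / (a + b)
    m <- spec$means
    truth <- list(
        fibro_fraction_realized = sum(fibro_arr & nbhd) / sum(nbhd),
        expected_contrast_tumor_fibro = exp_contrast(m[["tumor"]], m[["fibro"]]),
        expected_contrast_tumor_adipose = exp_contrast(m[["tumor"]], m[["adipose"]]),
        means = m
    )

    list(volume = image_volume(data, sp),
         tumor = region_mask(tumor_arr, sp),
         body = region_mask(body_arr, sp),
         labels = labels, spec = spec, truth = truth)
}

#' Specify a synthetic cohort
#'
#' A cohort is n cases drawn from a base [phantom_spec()] with per-case
#' jitter on intensity means and tumor size and a per-case fibroglandular
#' fraction drawn uniformly from `fibro_fraction_range`. The
#' delayed-acquisition regime is parameterized by the washout factor
#' `w` in \[0, 1\]: the tumor mean decays toward the fibroglandular mean,
#' `tumor -> fibro + (tumor - fibro) * (1 - w)`, while the fibroglandular
#' mean is multiplied by `persistence` (>= 1 models persistent parenchymal
#' enhancement at the later timepoint). Per-case randomness is derived from
#' `seed` and the case index only, so two cohorts sharing a seed share case
#' geometry and noise and differ solely through the washout transform;
#' `w = 0, persistence = 1` reproduces the early-phase cohort exactly.
#'
#' @param n_cases number of cases (>= 2).
#' @param label cohort label used in manifests and reports.
#' @param base base [phantom_spec()].
#' @param washout washout factor w in \[0, 1\].
#' @param persistence fibroglandular persistence factor (>= 0).
#' @param mean_jitter_frac SD of the lognormal-free relative jitter applied
#'   to tumor/fibro/adipose means per case (truncated at +/- 3 SD).
#' @param fibro_fraction_range per-case fibro fraction range.
#' @param size_jitter_frac relative jitter SD on tumor semi-axes.
#' @param seed cohort seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases, label, base = phantom_spec(),
                        washout = 0, persistence = 1,
                        mean_jitter_frac = 0.05,
                        fibro_fraction_range = c(0.15, 0.6),
                        size_jitter_frac = 0.15, seed = 1L) {
    if (n_cases < 2L) spec_error("a cohort needs n_cases >= 2")
    if (washout < 0 || washout > 1) spec_error("washout must lie in [0, 1]")
    if (persistence < 0) spec_error("persistence must be >= 0")
    structure(list(n_cases = as.integer(n_cases), label = label, base = base,
                   washout = washout, persistence = persistence,
                   mean_jitter_frac = mean_jitter_frac,
                   fibro_fraction_range = fibro_fraction_range,
                   size_jitter_frac = size_jitter_frac,
                   seed = as.integer(seed)),
              class = "cohort_spec")
}

rtrunc_jitter <- function(n, frac) {
    z <- stats::rnorm(n)
    1 + frac * pmax(pmin(z, 3), -3)
}

case_specs_for_cohort <- function(cs) {
    lapply(seq_len(cs$n_cases), function(i) {
        case_seed <- (cs$seed + 7919L * i) %% .Machine$integer.max
        with_seed(case_seed, {
            jit <- rtrunc_jitter(3, cs$mean_jitter_frac)
            ff <- stats::runif(1, cs$fibro_fraction_range[1],
                               cs$fibro_fraction_range[2])
            size <- rtrunc_jitter(3, cs$size_jitter_frac)
        })
        m <- cs$base$means
        tumor_m <- m[["tumor"]] * jit[1]
        fibro_m <- m[["fibro"]] * jit[2]
        adipose_m <- m[["adipose"]] * jit[3]
        # delayed-acquisition transform: tumor washes out toward fibro,
        # fibro enhancement persists/rises
        tumor_m <- fibro_m + (tumor_m - fibro_m) * (1 - cs$washout)
        fibro_m <- fibro_m * cs$persistence
        phantom_spec(
            shape = cs$base$shape, spacing = cs$base$spacing,
            semi_axes = pmax(cs$base$semi_axes * size, 2 * max(cs$base$spacing)),
            center = cs$base$center,
            means = c(tumor = tumor_m, fibro = fibro_m,
                      adipose = adipose_m, air = m[["air"]]),
            noise_sigma = cs$base$noise_sigma,
            noise_model = cs$base$noise_model,
            fibro_fraction = ff,
            texture_length = cs$base$texture_length,
            seed = case_seed)
    })
}

#' Generate an in-memory cohort of phantom cases
#'
#' @param cs a [cohort_spec()].
#' @return List with `cases` (list of [make_phantom()] outputs) and `truth`
#'   (data.frame of per-case true means, fractions and analytic expected
#'   contrasts).
#' @export
make_cohort_cases <- function(cs) {
    stopifnot(inherits(cs, "cohort_spec"))
    specs <- case_specs_for_cohort(cs)
    cases <- lapply(specs, make_phantom)
    truth <- do.call(rbind, lapply(seq_along(cases), function(i) {
        tr <- cases[[i]]$truth
        data.frame(case_id = sprintf("%s_%03d", cs$label, i),
                   cohort_label = cs$label,
                   washout = cs$washout,
                   true_tumor_mean = tr$means[["tumor"]],
                   true_fibro_mean = tr$means[["fibro"]],
                   true_adipose_mean = tr$means[["adipose"]],
                   fibro_fraction_target = specs[[i]]$fibro_fraction,
                   fibro_fraction_realized = tr$fibro_fraction_realized,
                   expected_contrast_tumor_fibro = tr$expected_contrast_tumor_fibro,
                   expected_contrast_tumor_adipose = tr$expected_contrast_tumor_adipose,
                   stringsAsFactors = FALSE)
    }))
    list(cases = cases, truth = truth)
}

#' Write phantom cohorts to disk as NIfTI + manifest
#'
#' Emits, for every case of every cohort, the volume / tumor mask / body
#' mask as NIfTI files, plus a combined `manifest.csv` in the contract
#' consumed by [read_manifest()] and a `ground_truth.csv` with true means,
#' fractions and analytic expected contrasts.
#'
#' @param cohorts list of [cohort_spec()]s (e.g. early and delayed).
#' @param dir output directory (created if needed).
#' @return List with `manifest_path`, `truth_path`, `manifest`, `truth`.
#' @export
make_cohorts <- function(cohorts, dir) {
    if (inherits(cohorts, "cohort_spec")) cohorts <- list(cohorts)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    man <- list(); tru <- list()
    for (cs in cohorts) {
        gen <- make_cohort_cases(cs)
        for (i in seq_along(gen$cases)) {
            case <- gen$cases[[i]]
            cid <- gen$truth$case_id[i]
            vp <- file.path(dir, paste0(cid, "_vol.nii.gz"))
            tp <- file.path(dir, paste0(cid, "_tumor.nii.gz"))
            bp <- file.path(dir, paste0(cid, "_body.nii.gz"))
            ok <- tryCatch({
                write_nifti_volume(case$volume, vp)
                write_nifti_volume(case$tumor, tp)
                write_nifti_volume(case$body, bp)
                TRUE
            }, error = function(e)
                sc_stop("io_error", sprintf("failed writing %s: %s",
                                            vp, conditionMessage(e))))
            man[[cid]] <- data.frame(case_id = cid, cohort_label = cs$label,
                                     volume_path = vp, tumor_mask_path = tp,
                                     body_mask_path = bp,
                                     stringsAsFactors = FALSE)
        }
        tru[[cs$label]] <- gen$truth
    }
    manifest <- do.call(rbind, unname(man))
    truth <- do.call(rbind, unname(tru))
    manifest_path <- file.path(dir, "manifest.csv")
    truth_path <- file.path(dir, "ground_truth.csv")
    utils::write.csv(manifest, manifest_path, row.names = FALSE)
    utils::write.csv(truth, truth_path, row.names = FALSE)
    list(manifest_path = manifest_path, truth_path = truth_path,
         manifest = manifest, truth = truth)
}
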