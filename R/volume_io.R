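#' Construct an image volume
#'
#' A 3D scalar intensity grid (arbitrary scanner units) with per-axis voxel
#' spacing in mm. All downstream geometry (shell growth, volumes, extents) is
#' spacing-aware; the array itself is used in voxel space and never resampled.
#'
#' @param data 3D numeric array of finite intensities.
#' @param spacing numeric length-3 vector of voxel edge lengths in mm,
#'   strictly positive, ordered (x, y, z) to match the array axes.
#' @return An object of class `image_volume` with elements `data` and
#'   `spacing`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1)) {
    if (!is.array(data) || length(dim(data)) != 3L)
        geometry_error("image volume must be a 3D array")
    if (any(dim(data) < 1L))
        geometry_error("every image axis must have length >= 1")
    storage.mode(data) <- "double"
    if (!all(is.finite(data)))
        sc_stop("value_error", "image intensities must all be finite")
    spacing <- as.numeric(spacing)
    if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
        geometry_error("spacing must be 3 strictly positive voxel edge lengths (mm)")
    structure(list(data = data, spacing = spacing), class = "image_volume")
}

#' Construct a binary region mask
#'
#' A voxel-aligned boolean mask on the same grid as its paired
#' [image_volume()]. Membership is whole-voxel; there is no sub-voxel
#' weighting.
#'
#' @param mask 3D logical (or 0/1 numeric) array.
#' @param spacing voxel spacing in mm, as in [image_volume()].
#' @return An object of class `region_mask` with elements `mask` and
#'   `spacing`.
#' @export
region_mask <- function(mask, spacing = c(1, 1, 1)) {
    if (!is.array(mask) || length(dim(mask)) != 3L)
        geometry_error("region mask must be a 3D array")
    vals <- unique(as.vector(mask))
    if (length(vals) > 2L)
        mask_encoding_error(sprintf(
            "mask is not binary: %d distinct values found", length(vals)))
    if (!is.logical(mask)) {
        m <- array(as.vector(mask) != 0, dim = dim(mask))
        mask <- m
    }
    spacing <- as.numeric(spacing)
    if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
        geometry_error("spacing must be 3 strictly positive voxel edge lengths (mm)")
    structure(list(mask = mask, spacing = spacing), class = "region_mask")
}

#' @export
print.image_volume <- function(x, ...) {
    cat(sprintf("<image_volume> %s voxels, spacing %s mm, intensity [%.4g, %.4g]\n",
                paste(dim(x$data), collapse = "x"),
                paste(format(x$spacing), collapse = "x"),
                min(x$data), max(x$data)))
    invisible(x)
}

#' @export
print.region_mask <- function(x, ...) {
    cat(sprintf("<region_mask> %s voxels, %d in region (%.4g mm^3)\n",
                paste(dim(x$mask), collapse = "x"), sum(x$mask), volume_of(x)))
    invisible(x)
}

#' Physical volume of a mask
#'
#' @param mask a [region_mask()].
#' @return Volume in mm^3: voxel count times the product of the voxel edge
#'   lengths.
#' @export
volume_of <- function(mask) {
    stopifnot(inherits(mask, "region_mask"))
    sum(mask$mask) * prod(mask$spacing)
}

voxel_volume <- function(spacing) prod(spacing)

#' Write a volume or mask to NIfTI
#'
#' @param x an [image_volume()] or [region_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
    arr <- if (inherits(x, "image_volume")) x$data else x$mask * 1L
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- x$spacing
    RNifti::writeNifti(img, path)
    invisible(path)
}

read_nifti_array <- function(path) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)[seq_len(3)]
    arr <- as.array(img)
    if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
        arr <- arr[, , , 1L, drop = TRUE]
    arr <- array(as.double(arr), dim(arr))   # drop NIfTI header attributes
    if (length(dim(arr)) != 3L)
        geometry_error(sprintf("'%s' is not a 3D volume (dims %s)",
                               path, paste(dim(arr), collapse = "x")))
    list(data = arr, spacing = as.numeric(sp))
}

#' Load a per-case volume/mask pair from NIfTI files
#'
#' Reads the intensity volume and the tumor segmentation (plus an optional
#' breast/body mask), verifies that all grids are identical in shape and that
#' header spacings agree within 1e-3 mm per axis, and coerces masks to
#' logical. Spacing disagreement is an error rather than a warning because a
#' silent geometric mismatch corrupts every mm^3 quantity downstream.
#'
#' @param volume_path path to the intensity volume.
#' @param tumor_mask_path path to the binary tumor mask on the same grid.
#' @param body_mask_path optional path to a binary breast/body mask.
#' @return A list with elements `volume` ([image_volume()]), `tumor`
#'   ([region_mask()]), and `body` (`region_mask` or `NULL`).
#' @export
load_case <- function(volume_path, tumor_mask_path, body_mask_path = NULL) {
    for (p in c(volume_path, tumor_mask_path, body_mask_path))
        if (!file.exists(p)) sc_stop("io_error", sprintf("file not found: %s", p))
    vol <- read_nifti_array(volume_path)

    read_mask <- function(path, what) {
        m <- read_nifti_array(path)
        if (!identical(dim(m$data), dim(vol$data)))
            geometry_error(sprintf(
                "%s grid %s does not match volume grid %s", what,
                paste(dim(m$data), collapse = "x"),
                paste(dim(vol$data), collapse = "x")))
        if (any(abs(m$spacing - vol$spacing) > 1e-3))
            geometry_error(sprintf(
                "%s spacing (%s) disagrees with volume spacing (%s) beyond 1e-3 mm",
                what, paste(format(m$spacing), collapse = ", "),
                paste(format(vol$spacing), collapse = ", ")))
        vals <- unique(as.vector(m$data))
        if (length(vals) > 2L)
            mask_encoding_error(sprintf(
                "%s mask has %d distinct values; expected a binary mask",
                what, length(vals)))
        region_mask(m$data != 0, spacing = vol$spacing)
    }

    tumor <- read_mask(tumor_mask_path, "tumor")
    if (sum(tumor$mask) < 1L)
        empty_region_error("tumor mask contains no voxels")
    body <- if (!is.null(body_mask_path)) read_mask(body_mask_path, "body") else NULL

    list(volume = image_volume(vol$data, vol$spacing), tumor = tumor, body = body)
}

#' Read a per-case manifest
#'
#' The manifest is a CSV with columns `case_id`, `cohort_label`,
#' `volume_path`, `tumor_mask_path` and optionally `body_mask_path`.
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path manifest CSV path.
#' @return A data.frame, one row per case.
#' @export
read_manifest <- function(path) {
    if (!file.exists(path)) sc_stop("io_error", sprintf("file not found: %s", path))
    man <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("case_id", "cohort_label", "volume_path", "tumor_mask_path")
    missing_cols <- setdiff(need, names(man))
    if (length(missing_cols))
        config_error(sprintf("manifest lacks columns: %s",
                             paste(missing_cols, collapse = ", ")))
    root <- dirname(normalizePath(path))
    fix <- function(p) ifelse(is.na(p) | p == "" | grepl("^/", p), p,
                              file.path(root, p))
    man$volume_path <- fix(man$volume_path)
    man$tumor_mask_path <- fix(man$tumor_mask_path)
    if ("body_mask_path" %in% names(man))
        man$body_mask_path <- fix(man$body_mask_path)
    man
}
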