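#' Spacing-aware Euclidean distance to a voxel region
#'
#' Exact Euclidean distance (mm) from every voxel centre to the nearest voxel
#' centre of `mask`, honouring anisotropic spacing (axial breast MRI is
#' typically ~1x1 mm in-plane with 2 mm slices, so an isotropic voxel-step
#' dilation would bias any margin toward the slice axis).
#'
#' @param mask a [region_mask()] with at least one voxel set.
#' @return 3D numeric array of distances in mm (0 inside the region).
#' @export
distance_to_region <- function(mask) {
    stopifnot(inherits(mask, "region_mask"))
    if (!any(mask$mask)) empty_region_error("distance to an empty region is undefined")
    d2 <- edt3d_sq(as.vector(mask$mask), dim(mask$mask), mask$spacing)
    sqrt(array(d2, dim = dim(mask$mask)))
}

#' Grow the equal-volume boundary shell around a tumor
#'
#' Builds the layer of non-tumor voxels immediately surrounding the tumor,
#' grown outward in distance strata until the shell's physical volume first
#' reaches the tumor's physical volume — the margin thickness that makes
#' tumor and boundary volumetrically equivalent. Growth follows the
#' spacing-aware Euclidean distance from the tumor; a stratum is the set of
#' voxels sharing one distance value, and the final stratum is always
#' included whole, so the construction is deterministic. If a body mask is
#' given, the shell is restricted to it (e.g. to exclude air); if the
#' eligible region runs out before the tumor volume is matched the full
#' eligible shell is returned with the `volume_deficit` flag.
#'
#' @param tumor nonempty tumor [region_mask()].
#' @param volume an [image_volume()] on the same grid (grid/spacing guard).
#' @param body optional [region_mask()] restricting eligible shell voxels.
#' @return An object of class `boundary_shell`: `mask` (the shell
#'   `region_mask`), `tumor` (the tumor mask), `thickness_mm`,
#'   `tumor_volume_mm3`, `shell_volume_mm3`, and `flags`.
#' @export
build_boundary_shell <- function(tumor, volume, body = NULL) {
    stopifnot(inherits(tumor, "region_mask"), inherits(volume, "image_volume"))
    if (!identical(dim(tumor$mask), dim(volume$data)))
        geometry_error("tumor mask and volume are on different grids")
    if (!any(tumor$mask)) empty_region_error("tumor mask contains no voxels")

    eligible <- !tumor$mask
    if (!is.null(body)) {
        stopifnot(inherits(body, "region_mask"))
        if (!identical(dim(body$mask), dim(tumor$mask)))
            geometry_error("body mask and tumor mask are on different grids")
        eligible <- eligible & body$mask
    }
    if (!any(eligible))
        no_boundary_error("tumor fills the entire grid/body; no boundary voxels exist")

    dist <- distance_to_region(tumor)
    vvol <- voxel_volume(tumor$spacing)
    tumor_vol <- sum(tumor$mask) * vvol

    d_elig <- dist[eligible]
    # group voxels into distance strata; signif() guards against last-bit
    # differences in equal distances computed along different transform paths
    strata <- sort(unique(signif(d_elig, 10)))
    counts <- tabulate(match(signif(d_elig, 10), strata), nbins = length(strata))
    cum_vol <- cumsum(counts) * vvol

    k <- which(cum_vol >= tumor_vol)[1]
    flags <- character(0)
    if (is.na(k)) {
        k <- length(strata)
        flags <- "volume_deficit"
    }
    t_star <- strata[k]
    shell_arr <- eligible & (signif(dist, 10) <= t_star)

    structure(list(
        mask = region_mask(shell_arr, tumor$spacing),
        tumor = tumor,
        thickness_mm = t_star,
        tumor_volume_mm3 = tumor_vol,
        shell_volume_mm3 = sum(shell_arr) * vvol,
        flags = flags
    ), class = "boundary_shell")
}

#' @export
print.boundary_shell <- function(x, ...) {
    cat(sprintf(
        "<boundary_shell> thickness %.3f mm, shell %.4g mm^3 vs tumor %.4g mm^3%s\n",
        x$thickness_mm, x$shell_volume_mm3, x$tumor_volume_mm3,
        if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
        else ""))
    invisible(x)
}

surface_voxels <- function(mask_arr) {
    # tumor voxels with at least one of the 6 face neighbours outside the
    # region (out-of-grid counts as outside)
    d <- dim(mask_arr)
    pad <- array(FALSE, d + 2L)
    pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask_arr
    core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
    nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
          pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
          pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
          pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
          pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
          pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
    core & !nb
}

exposed_face_area <- function(mask_arr, spacing) {
    d <- dim(mask_arr)
    pad <- array(FALSE, d + 2L)
    pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask_arr
    core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
    shift <- function(dx, dy, dz)
        pad[(2 + dx):(d[1] + 1 + dx), (2 + dy):(d[2] + 1 + dy),
            (2 + dz):(d[3] + 1 + dz)]
    # a face normal to axis k has area = product of the other two spacings
    ax <- spacing[2] * spacing[3]
    ay <- spacing[1] * spacing[3]
    az <- spacing[1] * spacing[2]
    sum(core & !shift(-1, 0, 0)) * ax + sum(core & !shift(1, 0, 0)) * ax +
    sum(core & !shift(0, -1, 0)) * ay + sum(core & !shift(0, 1, 0)) * ay +
    sum(core & !shift(0, 0, -1)) * az + sum(core & !shift(0, 0, 1)) * az
}

max_pairwise_extent <- function(coords) {
    # exact max pairwise distance; chunked so memory stays bounded for large
    # surfaces
    n <- nrow(coords)
    if (n < 2L) return(0)
    best <- 0
    step <- 2000L
    sq <- rowSums(coords^2)
    for (i0 in seq(1L, n, by = step)) {
        i1 <- min(i0 + step - 1L, n)
        cross <- coords[i0:i1, , drop = FALSE] %*% t(coords)
        d2 <- outer(sq[i0:i1], rep(1, n)) + outer(rep(1, i1 - i0 + 1L), sq) -
              2 * cross
        best <- max(best, max(d2))
    }
    sqrt(max(best, 0))
}

#' Tumor size and shape metrics
#'
#' Volume (mm^3), maximum extent (largest pairwise spacing-aware distance
#' between surface voxel centres, floored at the largest voxel edge so a
#' single-voxel mask still reports a physical extent), surface area by
#' exposed-face counting, and sphericity
#' \eqn{\pi^{1/3} (6V)^{2/3} / A}. Face-counted surface area overestimates a
#' smooth surface's area, so sphericity of a digitised ball converges to a
#' constant slightly below 1 rather than to 1 exactly.
#'
#' @param tumor nonempty [region_mask()].
#' @return An object of class `shape_metrics`: `volume_mm3`,
#'   `max_extent_mm`, `surface_area_mm2`, `sphericity`.
#' @export
shape_metrics <- function(tumor) {
    stopifnot(inherits(tumor, "region_mask"))
    if (!any(tumor$mask)) empty_region_error("shape metrics of an empty mask")
    sp <- tumor$spacing
    V <- volume_of(tumor)
    A <- exposed_face_area(tumor$mask, sp)
    surf <- which(surface_voxels(tumor$mask), arr.ind = TRUE)
    coords <- sweep(surf - 1, 2, sp, `*`)
    extent <- max(max_pairwise_extent(coords), max(sp))
    structure(list(
        volume_mm3 = V,
        max_extent_mm = extent,
        surface_area_mm2 = A,
        sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / A
    ), class = "shape_metrics")
}

#' @export
print.shape_metrics <- function(x, ...) {
    cat(sprintf("<shape_metrics> V=%.4g mm^3, extent=%.3f mm, A=%.4g mm^2, sphericity=%.3f\n",
                x$volume_mm3, x$max_extent_mm, x$surface_area_mm2, x$sphericity))
    invisible(x)
}

#' Export tumor/shell (or tumor/adipose/fibroglandular) label map
#'
#' @param tumor tumor [region_mask()].
#' @param shell a `boundary_shell`.
#' @param partition optional `boundary_partition`; when given, shell labels
#'   split into adipose (2) and fibroglandular (3), else the whole shell is 2.
#' @param path output NIfTI path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(tumor, shell, partition = NULL, path) {
    lab <- array(0L, dim(tumor$mask))
    lab[tumor$mask] <- 1L
    if (is.null(partition)) {
        lab[shell$mask$mask] <- 2L
    } else {
        lab[partition$adipose$mask] <- 2L
        lab[partition$fibroglandular$mask] <- 3L
    }
    img <- RNifti::asNifti(lab)
    RNifti::pixdim(img) <- tumor$spacing
    RNifti::writeNifti(img, path)
    invisible(path)
}
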