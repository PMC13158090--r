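# Independent oracles used across tests. These deliberately take the dumb,
# enumerate-everything route so they share no code path with the package.

# exact distance from every voxel centre to the nearest mask voxel centre
brute_edt <- function(mask_arr, spacing) {
    d <- dim(mask_arr)
    idx <- which(mask_arr, arr.ind = TRUE)
    pts <- sweep(idx - 1, 2, spacing, `*`)
    out <- array(NA_real_, d)
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
        p <- c((x - 1) * spacing[1], (y - 1) * spacing[2], (z - 1) * spacing[3])
        out[x, y, z] <- sqrt(min(colSums((t(pts) - p)^2)))
    }
    out
}

# equal-volume shell by sorting all eligible voxels by brute-force distance
# and absorbing whole distance strata until tumor volume is reached
brute_shell <- function(tumor_arr, spacing, body_arr = NULL) {
    dist <- brute_edt(tumor_arr, spacing)
    eligible <- !tumor_arr
    if (!is.null(body_arr)) eligible <- eligible & body_arr
    vv <- prod(spacing)
    tumor_vol <- sum(tumor_arr) * vv
    dvals <- sort(unique(signif(dist[eligible], 10)))
    shell <- array(FALSE, dim(tumor_arr))
    vol <- 0
    t_star <- NA_real_
    for (dv in dvals) {
        stratum <- eligible & (signif(dist, 10) == dv)
        shell <- shell | stratum
        vol <- vol + sum(stratum) * vv
        if (vol >= tumor_vol) { t_star <- dv; break }
    }
    list(shell = shell, thickness = if (is.na(t_star)) max(dvals) else t_star,
         volume = vol, deficit = is.na(t_star))
}

# between-class variance scan over every candidate bin edge, computed from
# the histogram by explicit summation
brute_otsu <- function(values, bins = 256L) {
    lo <- min(values); hi <- max(values)
    width <- (hi - lo) / bins
    idx <- pmin(pmax(ceiling((values - lo) / width), 1L), bins)
    counts <- tabulate(idx, nbins = bins)
    centers <- lo + (seq_len(bins) - 0.5) * width
    n <- length(values)
    best <- -1; best_edge <- NA_real_
    for (k in seq_len(bins - 1L)) {
        n0 <- 0; s0 <- 0; n1 <- 0; s1 <- 0
        for (j in seq_len(bins)) {
            if (j <= k) { n0 <- n0 + counts[j]; s0 <- s0 + counts[j] * centers[j] }
            else        { n1 <- n1 + counts[j]; s1 <- s1 + counts[j] * centers[j] }
        }
        w0 <- n0 / n; w1 <- n1 / n
        mu0 <- if (n0 > 0) s0 / n0 else 0
        mu1 <- if (n1 > 0) s1 / n1 else 0
        bcv <- w0 * w1 * (mu0 - mu1)^2
        if (bcv > best + 1e-15 * max(1, abs(best))) {
            best <- bcv
            best_edge <- lo + k * width
        }
    }
    best_edge
}

# all-pairs AUC with ties counted one half
brute_auc <- function(pos, neg) {
    gt <- outer(pos, neg, `>`)
    eq <- outer(pos, neg, `==`)
    (sum(gt) + 0.5 * sum(eq)) / (length(pos) * length(neg))
}

# noncentral t CDF through its mixture representation
# P(T <= t) = E_V[ pnorm(t * sqrt(V/df) - ncp) ], V ~ chi^2_df,
# sharing nothing with stats::pt(ncp = ...)
nct_cdf <- function(t, df, ncp) {
    stats::integrate(function(v)
        stats::pnorm(t * sqrt(v / df) - ncp) * stats::dchisq(v, df),
        0, Inf, rel.tol = 1e-10)$value
}

# small solid cuboid tumor centred in a grid
cuboid_mask <- function(dims, lo, hi) {
    m <- array(FALSE, dims)
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    m
}

# random blobby tumor mask: an ellipsoid with random centre/axes
random_tumor <- function(dims, spacing, seed) {
    set.seed(seed)
    ext <- dims * spacing
    ax <- runif(3, 0.08, 0.2) * ext
    ctr <- runif(3, 0.35, 0.65) * ext
    xs <- (seq_len(dims[1]) - 1) * spacing[1]
    ys <- (seq_len(dims[2]) - 1) * spacing[2]
    zs <- (seq_len(dims[3]) - 1) * spacing[3]
    q <- outer(outer(((xs - ctr[1]) / ax[1])^2, ((ys - ctr[2]) / ax[2])^2, `+`),
               ((zs - ctr[3]) / ax[3])^2, `+`)
    q <= 1
}

expect_error_class <- function(expr, class) {
    expect_error(expr, class = class)
}
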