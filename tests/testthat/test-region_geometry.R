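test_that("distance transform matches brute force on anisotropic random masks", {
    for (seed in 1:4) {
        set.seed(seed)
        d <- c(sample(5:9, 1), sample(5:9, 1), sample(4:7, 1))
        sp <- c(runif(1, 0.5, 1.5), runif(1, 0.5, 1.5), runif(1, 1, 2.5))
        m <- array(runif(prod(d)) < 0.15, d)
        if (!any(m)) m[1, 1, 1] <- TRUE
        got <- distance_to_region(region_mask(m, sp))
        expect_equal(got, brute_edt(m, sp), tolerance = 1e-10)
    }
})

test_that("single-voxel tumor shell matches the brute-force stratum oracle", {
    d <- c(9L, 9L, 9L)
    tum <- array(FALSE, d); tum[5, 5, 5] <- TRUE
    vol <- image_volume(array(0, d), c(1, 1, 1))
    sh <- build_boundary_shell(region_mask(tum), vol)
    oracle <- brute_shell(tum, c(1, 1, 1))
    expect_identical(sh$mask$mask, oracle$shell)
    expect_equal(sh$thickness_mm, oracle$thickness)
    # first stratum: the 6 face-adjacent voxels at distance 1, already >= 1
    expect_identical(sum(sh$mask$mask), 6L)
    expect_equal(sh$thickness_mm, 1)
    expect_false(any(sh$mask$mask & tum))
})

test_that("cube tumor shell reaches equal volume in the second stratum", {
    d <- c(24L, 24L, 24L)
    tum <- cuboid_mask(d, c(8, 8, 8), c(17, 17, 17))   # 10^3 cube
    vol <- image_volume(array(0, d), c(1, 1, 1))
    sh <- build_boundary_shell(region_mask(tum), vol)
    oracle <- brute_shell(tum, c(1, 1, 1))
    expect_identical(sh$mask$mask, oracle$shell)
    expect_equal(sh$shell_volume_mm3, oracle$volume)
    # 6 faces x 100 voxels = 600 < 1000, so the shell must pass distance 1
    expect_gt(sh$thickness_mm, 1)
    expect_gte(sh$shell_volume_mm3, 1000)
})

test_that("shell minimality, disjointness and flags hold on random phantoms", {
    for (seed in 1:6) {
        sp <- c(1, 1, 2)
        d <- c(20L, 20L, 14L)
        tum <- random_tumor(d, sp, seed)
        vol <- image_volume(array(0, d), sp)
        sh <- build_boundary_shell(region_mask(tum, sp), vol)
        expect_false(any(sh$mask$mask & tum))
        expect_gte(sh$shell_volume_mm3, sh$tumor_volume_mm3)
        # dropping the outermost stratum must break volume equivalence
        dist <- distance_to_region(region_mask(tum, sp))
        inner <- sh$mask$mask & (signif(dist, 10) < signif(sh$thickness_mm, 10))
        expect_lt(sum(inner) * prod(sp), sh$tumor_volume_mm3)
        # every shell voxel within realized thickness of the tumor
        expect_lte(max(dist[sh$mask$mask]), sh$thickness_mm + 1e-9)
    }
})

test_that("tumor filling the grid or body leaves no boundary", {
    d <- c(4L, 4L, 4L)
    full <- region_mask(array(TRUE, d))
    vol <- image_volume(array(0, d))
    expect_error_class(build_boundary_shell(full, vol), "no_boundary_error")
    expect_error_class(
        build_boundary_shell(region_mask(array(FALSE, d)), vol),
        "empty_region_error")

    # eligible region exhausted before tumor volume is matched -> volume_deficit
    d2 <- c(10L, 10L, 10L)
    tum <- cuboid_mask(d2, c(2, 2, 2), c(9, 9, 9))   # 512 voxels, 488 left
    sh <- build_boundary_shell(region_mask(tum), image_volume(array(0, d2)))
    expect_true("volume_deficit" %in% sh$flags)
    expect_lt(sh$shell_volume_mm3, sh$tumor_volume_mm3)
})

test_that("shape metrics match closed forms for canonical solids", {
    d <- c(12L, 12L, 12L)
    one <- array(FALSE, d); one[6, 6, 6] <- TRUE
    sm <- shape_metrics(region_mask(one))
    expect_equal(sm$volume_mm3, 1)
    expect_equal(sm$surface_area_mm2, 6)
    expect_equal(sm$sphericity, pi^(1 / 3) * 6^(2 / 3) / 6, tolerance = 1e-12)
    expect_equal(sm$max_extent_mm, 1)   # floored at the voxel edge

    rod <- cuboid_mask(d, c(6, 6, 2), c(6, 6, 11))   # 1x1x10
    sr <- shape_metrics(region_mask(rod))
    expect_equal(sr$volume_mm3, 10)
    expect_equal(sr$surface_area_mm2, 42)
    expect_equal(sr$max_extent_mm, 9)
    expect_equal(sr$sphericity, pi^(1 / 3) * 60^(2 / 3) / 42, tolerance = 1e-12)

    pair <- cuboid_mask(d, c(5, 6, 6), c(6, 6, 6))   # 2x1x1
    expect_equal(shape_metrics(region_mask(pair))$max_extent_mm, 1)

    expect_error_class(shape_metrics(region_mask(array(FALSE, d))),
                       "empty_region_error")
})

test_that("shape metrics are scale-equivariant in the spacing", {
    d <- c(16L, 16L, 16L)
    tum <- random_tumor(d, c(1, 1, 1), 11)
    s1 <- shape_metrics(region_mask(tum, c(1, 1, 1)))
    s2 <- shape_metrics(region_mask(tum, c(2, 2, 2)))
    expect_equal(s2$volume_mm3, 8 * s1$volume_mm3)
    expect_equal(s2$max_extent_mm, 2 * s1$max_extent_mm)
    expect_equal(s2$surface_area_mm2, 4 * s1$surface_area_mm2)
    expect_equal(s2$sphericity, s1$sphericity)
})

test_that("digital ball sphericity settles near the face-counting constant", {
    sph <- sapply(c(5, 8, 11), function(r) {
        n <- as.integer(2 * r + 5)
        ctr <- (n + 1) / 2
        g <- seq_len(n) - ctr
        q <- outer(outer(g^2, g^2, `+`), g^2, `+`)
        shape_metrics(region_mask(q <= r^2, c(1, 1, 1)))$sphericity
    })
    # face counting overestimates a sphere's area by 3/2, so the limit is 2/3
    expect_true(all(sph > 0.6 & sph < 0.75))
    expect_lt(abs(sph[3] - sph[2]), 0.03)
    expect_true(all(sph > 0 & sph <= 1.1))
})
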