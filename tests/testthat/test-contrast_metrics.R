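test_that("Michelson contrast reproduces closed forms and its symmetries", {
    expect_equal(michelson_contrast(300, 100), 0.5)
    expect_equal(michelson_contrast(7, 7), 0)
    expect_equal(michelson_contrast(42.5, 42.5), 0)
    expect_equal(michelson_contrast(100, 300), -0.5)
    for (ab in list(c(1, 2), c(250, 75), c(0.3, 0.9)))
        expect_equal(michelson_contrast(ab[1], ab[2]),
                     -michelson_contrast(ab[2], ab[1]))
    expect_error_class(michelson_contrast(0, 0), "undefined_contrast_error")
})

test_that("rank AUC equals all-pairs counting and handles ties at one half", {
    expect_equal(rank_auc(c(3, 4), c(1, 2)), 1)
    expect_equal(rank_auc(c(1, 2), c(1, 2)), 0.5)
    set.seed(77)
    pos <- rnorm(200, 300, 20)
    neg <- rnorm(200, 250, 20)
    expect_lt(abs(rank_auc(pos, neg) - brute_auc(pos, neg)), 1e-12)
    # heavy ties
    a <- sample(1:5, 60, replace = TRUE)
    b <- sample(2:6, 40, replace = TRUE)
    expect_lt(abs(rank_auc(a, b) - brute_auc(a, b)), 1e-12)
})

test_that("AUC equals Mann-Whitney U over n1*n2 on shared samples", {
    set.seed(31)
    for (i in 1:5) {
        a <- rnorm(40, 1); b <- rnorm(55)
        expect_equal(rank_auc(a, b), mwu_test(a, b)$auc, tolerance = 1e-12)
    }
})

test_that("constant-region case report matches hand arithmetic", {
    d <- c(20L, 20L, 12L)
    tum <- cuboid_mask(d, c(8, 8, 5), c(13, 13, 8))
    vol_arr <- array(50, d)
    vol_arr[tum] <- 400
    vol <- image_volume(vol_arr)
    sh <- build_boundary_shell(region_mask(tum), vol)
    shell_idx <- which(sh$mask$mask)
    n_f <- round(0.4 * length(shell_idx))
    vol_arr[shell_idx[seq_len(n_f)]] <- 100
    vol <- image_volume(vol_arr)
    pt <- partition_shell(vol, sh)
    rep <- case_report(vol, region_mask(tum), sh, pt, noise_sigma = 10)

    expect_equal(rep$contrast_tumor_fibro, 0.6)
    expect_equal(rep$contrast_tumor_adipose, (400 - 50) / 450)
    expect_equal(rep$cnr_tumor_fibro, 30)
    expect_equal(rep$cnr_tumor_adipose, 35)
    expect_equal(rep$snr_tumor, 40)
    expect_equal(rep$auc_tumor_fibro, 1)
    expect_equal(rep$auc_tumor_adipose, 1)
    mean_shell <- (n_f * 100 + (length(shell_idx) - n_f) * 50) /
        length(shell_idx)
    expect_equal(rep$contrast_tumor_boundary,
                 (400 - mean_shell) / (400 + mean_shell))
})

test_that("contrasts and AUC are invariant to global intensity scaling", {
    ph <- make_phantom(phantom_spec(shape = c(28L, 28L, 18L),
                                    semi_axes = c(5, 5, 5), seed = 9))
    analyze <- function(vol, sigma) {
        sh <- build_boundary_shell(ph$tumor, vol, body = ph$body)
        pt <- partition_shell(vol, sh)
        case_report(vol, ph$tumor, sh, pt, noise_sigma = sigma)
    }
    r1 <- analyze(ph$volume, 10)
    k <- 4.25
    r2 <- analyze(image_volume(k * ph$volume$data, ph$volume$spacing), k * 10)
    for (f in c("contrast_tumor_boundary", "contrast_tumor_adipose",
                "contrast_tumor_fibro", "fibro_fraction",
                "auc_tumor_fibro", "auc_tumor_adipose",
                "snr_tumor", "cnr_tumor_fibro", "cnr_tumor_adipose"))
        expect_equal(r2[[f]], r1[[f]], tolerance = 1e-9, label = f)
})

test_that("tissue contrasts are ordered when adipose is darker than fibro", {
    ph <- make_phantom(phantom_spec(shape = c(28L, 28L, 18L),
                                    semi_axes = c(5, 5, 5),
                                    noise_sigma = 0, seed = 3))
    sh <- build_boundary_shell(ph$tumor, ph$volume, body = ph$body)
    pt <- partition_shell(ph$volume, sh)
    rep <- case_report(ph$volume, ph$tumor, sh, pt, noise_sigma = 10)
    expect_gt(rep$contrast_tumor_fibro, 0)
    expect_gt(rep$contrast_tumor_adipose, rep$contrast_tumor_fibro)
    for (f in c("contrast_tumor_boundary", "contrast_tumor_adipose",
                "contrast_tumor_fibro"))
        expect_true(rep[[f]] >= -1 && rep[[f]] <= 1)
})

test_that("an all-adipose shell flags no_fibro and leaves fibro metrics NA", {
    d <- c(18L, 18L, 12L)
    tum <- cuboid_mask(d, c(8, 8, 5), c(11, 11, 8))
    vol_arr <- array(50, d); vol_arr[tum] <- 400
    vol <- image_volume(vol_arr)
    sh <- build_boundary_shell(region_mask(tum), vol)
    pt <- partition_shell(vol, sh)
    rep <- case_report(vol, region_mask(tum), sh, pt, noise_sigma = 10)
    expect_true("no_fibro" %in% rep$flags)
    expect_true(is.na(rep$contrast_tumor_fibro))
    expect_true(is.na(rep$cnr_tumor_fibro))
    expect_true(is.na(rep$auc_tumor_fibro))
    expect_false(is.na(rep$contrast_tumor_adipose))
})

test_that("noise sigma falls back from air region to shell decile with flags", {
    ph <- make_phantom(phantom_spec(shape = c(28L, 28L, 18L),
                                    semi_axes = c(5, 5, 5),
                                    noise_sigma = 10, seed = 12))
    sh <- build_boundary_shell(ph$tumor, ph$volume, body = ph$body)
    pt <- partition_shell(ph$volume, sh)
    air <- region_mask(!ph$body$mask, ph$body$spacing)
    r_air <- case_report(ph$volume, ph$tumor, sh, pt, air = air)
    expect_equal(r_air$noise_sigma, 10, tolerance = 0.15 * 10)
    r_dec <- case_report(ph$volume, ph$tumor, sh, pt)
    expect_true(is.finite(r_dec$noise_sigma) && r_dec$noise_sigma > 0)

    # constant image: no estimable noise anywhere
    d <- c(16L, 16L, 10L)
    tum <- cuboid_mask(d, c(7, 7, 4), c(10, 10, 7))
    varr <- array(50, d); varr[tum] <- 400
    v <- image_volume(varr)
    sh2 <- build_boundary_shell(region_mask(tum), v)
    pt2 <- partition_shell(v, sh2)
    r2 <- case_report(v, region_mask(tum), sh2, pt2)
    expect_true("noise_estimation_failed" %in% r2$flags)
    expect_true(is.na(r2$snr_tumor))
    expect_false(is.na(r2$contrast_tumor_adipose))
})

test_that("report rows have a stable column layout", {
    ph <- make_phantom(phantom_spec(shape = c(24L, 24L, 16L),
                                    semi_axes = c(4, 4, 4), seed = 2))
    sh <- build_boundary_shell(ph$tumor, ph$volume, body = ph$body)
    pt <- partition_shell(ph$volume, sh)
    rep <- case_report(ph$volume, ph$tumor, sh, pt, noise_sigma = 10,
                       case_id = "x", cohort_label = "early")
    row <- report_as_row(rep)
    expect_identical(nrow(row), 1L)
    expect_identical(names(row)[1:2], c("case_id", "cohort_label"))
    expect_true(all(c("contrast_tumor_fibro", "fibro_fraction", "sphericity",
                      "auc_tumor_adipose", "flags") %in% names(row)))
})
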