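small_spec <- function(...) {
    phantom_spec(shape = c(28L, 28L, 18L), semi_axes = c(5, 5, 5), ...)
}

test_that("phantoms are byte-identical under a fixed seed", {
    s <- small_spec(seed = 21)
    p1 <- make_phantom(s)
    p2 <- make_phantom(s)
    expect_identical(p1$volume$data, p2$volume$data)
    expect_identical(p1$labels, p2$labels)
    expect_identical(p1$tumor$mask, p2$tumor$mask)
    # and the caller's RNG stream is left untouched
    set.seed(1); before <- rnorm(1)
    set.seed(1); invisible(make_phantom(s)); after <- rnorm(1)
    expect_identical(before, after)
})

test_that("realized fibro fraction hits the target in the peritumoral layer", {
    for (ff in c(0.1, 0.3, 0.5, 0.8)) {
        ph <- make_phantom(small_spec(fibro_fraction = ff, seed = 31))
        expect_lt(abs(ph$truth$fibro_fraction_realized - ff), 0.02)
    }
})

test_that("noiseless phantom recovers analytic contrasts exactly", {
    ph <- make_phantom(small_spec(
        means = c(tumor = 400, fibro = 100, adipose = 50, air = 5),
        noise_sigma = 0, seed = 41))
    sh <- build_boundary_shell(ph$tumor, ph$volume, body = ph$body)
    pt <- partition_shell(ph$volume, sh)
    rep <- case_report(ph$volume, ph$tumor, sh, pt, noise_sigma = 10)
    expect_equal(rep$contrast_tumor_fibro, 0.6, tolerance = 1e-12)
    expect_equal(rep$contrast_tumor_adipose, 0.7 + 7 / 90, tolerance = 1e-12)
    # Otsu labels coincide with the true tissue labels inside the shell
    expect_identical(pt$fibroglandular$mask,
                     sh$mask$mask & (ph$labels == 3L))
})

test_that("noisy recovery stays close to the noiseless values over seeds", {
    devs <- sapply(1:8, function(seed) {
        spec0 <- small_spec(
            means = c(tumor = 400, fibro = 100, adipose = 50, air = 5),
            noise_sigma = 10, fibro_fraction = 0.4, seed = seed)
        ph <- make_phantom(spec0)
        sh <- build_boundary_shell(ph$tumor, ph$volume, body = ph$body)
        pt <- partition_shell(ph$volume, sh)
        rep <- case_report(ph$volume, ph$tumor, sh, pt, noise_sigma = 10)
        c(rep$contrast_tumor_fibro - 0.6,
          rep$fibro_fraction - ph$truth$fibro_fraction_realized)
    })
    expect_true(all(abs(devs[1, ]) <= 0.02))
    expect_true(all(abs(devs[2, ]) <= 0.05))
})

test_that("rician noise and spec validation behave", {
    ph <- make_phantom(small_spec(noise_model = "rician", seed = 3))
    expect_true(all(ph$volume$data >= 0))
    expect_error_class(
        phantom_spec(shape = c(20L, 20L, 10L), semi_axes = c(30, 5, 5)),
        "spec_error")
    expect_error_class(phantom_spec(fibro_fraction = 1.5), "spec_error")
    expect_error_class(cohort_spec(1, "x"), "spec_error")
})

test_that("washout lowers tumor-to-fibro contrast monotonically, case by case", {
    base <- small_spec()
    truth_contrast <- function(w) {
        cs <- cohort_spec(4, "c", base = base, washout = w, seed = 17)
        make_cohort_cases(cs)$truth$expected_contrast_tumor_fibro
    }
    c0 <- truth_contrast(0); c25 <- truth_contrast(0.25)
    c5 <- truth_contrast(0.5); c75 <- truth_contrast(0.75)
    expect_true(all(c25 < c0))
    expect_true(all(c5 < c25))
    expect_true(all(c75 < c5))
})

test_that("washout zero reproduces the early cohort exactly under shared seeds", {
    base <- small_spec()
    early <- make_cohort_cases(cohort_spec(3, "early", base = base,
                                           washout = 0, seed = 23))
    again <- make_cohort_cases(cohort_spec(3, "later", base = base,
                                           washout = 0, seed = 23))
    for (i in 1:3)
        expect_identical(early$cases[[i]]$volume$data,
                         again$cases[[i]]$volume$data)
    # with washout, geometry and noise stay shared; contrast drops per case
    washed <- make_cohort_cases(cohort_spec(3, "delayed", base = base,
                                            washout = 0.5, seed = 23))
    for (i in 1:3) {
        expect_identical(early$cases[[i]]$tumor$mask,
                         washed$cases[[i]]$tumor$mask)
        expect_lt(washed$truth$expected_contrast_tumor_fibro[i],
                  early$truth$expected_contrast_tumor_fibro[i])
    }
})

test_that("cohorts written to disk round-trip through the manifest contract", {
    dir <- tempfile()
    base <- small_spec()
    out <- make_cohorts(list(
        cohort_spec(2, "early", base = base, seed = 11),
        cohort_spec(2, "delayed", base = base, washout = 0.5, seed = 11)), dir)
    expect_true(file.exists(out$manifest_path))
    expect_true(file.exists(out$truth_path))
    man <- read_manifest(out$manifest_path)
    expect_identical(nrow(man), 4L)
    case <- load_case(man$volume_path[1], man$tumor_mask_path[1],
                      man$body_mask_path[1])
    gen <- make_cohort_cases(cohort_spec(2, "early", base = base, seed = 11))
    expect_equal(case$volume$data, gen$cases[[1]]$volume$data,
                 tolerance = 1e-6)
    expect_identical(case$tumor$mask, gen$cases[[1]]$tumor$mask)
})
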