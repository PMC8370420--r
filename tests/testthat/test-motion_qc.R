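dvars_of <- function(values) {
    structure(list(values = values, mask_used = "all voxels"),
              class = "dvars_series")
}

test_that("DVARS matches hand-computed RMS successive differences", {
    # 2 voxels, 3 volumes: (0,0) -> (1,1) -> (1,3)
    a <- array(c(0, 0, 1, 1, 1, 3), c(2, 1, 1, 3))
    d <- compute_dvars(bold4d(a, subject_id = "toy"))
    expect_equal(d$values, c(0, 1, sqrt(2)))

    # temporally constant data
    cst <- bold4d(array(7, c(3, 3, 2, 6)))
    expect_equal(compute_dvars(cst)$values, rep(0, 6))

    # homogeneity: scaling intensities by c scales DVARS by |c|
    b <- withr::with_seed(2, bold4d(array(rnorm(4 * 4 * 2 * 8), c(4, 4, 2, 8))))
    b3 <- bold4d(-3 * b$data)
    expect_equal(compute_dvars(b3)$values, 3 * compute_dvars(b)$values,
                 tolerance = 1e-12)

    # empty mask rejected
    expect_error(compute_dvars(b, array(FALSE, c(4, 4, 2))), "empty mask")
})

test_that("outlier flagging applies the Q3 + 1.5 IQR rule over t >= 2", {
    d <- dvars_of(c(0, 1, 1, 1, 1, 1, 1, 1, 1, 1, 10))
    o <- flag_outliers(d)
    expect_equal(o$threshold, 1)            # Q1 = Q3 = 1, IQR = 0
    expect_equal(which(o$flags), 11L)
    expect_false(o$flags[1])

    # all-identical series: threshold equals the value, zero outliers
    o2 <- flag_outliers(dvars_of(c(0, rep(2, 9))))
    expect_equal(o2$threshold, 2)
    expect_false(any(o2$flags))

    # values at the threshold are not flagged (strict >)
    expect_false(any(flag_outliers(dvars_of(c(0, rep(1, 8), 1)))$flags))
})

test_that("the quartile estimator agrees with a sort-and-interpolate oracle", {
    withr::with_seed(99, {
        for (rep in 1:200) {
            v <- c(0, rexp(sample(5:60, 1)))
            o <- flag_outliers(dvars_of(v))
            q1 <- quartile_oracle(v[-1], 0.25)
            q3 <- quartile_oracle(v[-1], 0.75)
            expect_equal(o$threshold, q3 + 1.5 * (q3 - q1), tolerance = 1e-12)
        }
    })
})

test_that("window selection is optimal, brute-force-equal and first-start on ties", {
    # worked toy: T = 10, window 7, outliers at volumes 1, 9, 10
    flags <- as.logical(c(1, 0, 0, 0, 0, 0, 0, 0, 1, 1))
    o <- structure(list(flags = flags, threshold = 1), class = "outlier_mask")
    cr <- select_window(o, window_len = 7)
    expect_equal(cr$start, 2L)
    expect_equal(cr$outlier_count, 0L)

    # no outliers anywhere: first window wins the tie
    o0 <- structure(list(flags = rep(FALSE, 30), threshold = 1),
                    class = "outlier_mask")
    cr0 <- select_window(o0, window_len = 10)
    expect_equal(cr0$start, 1L)
    expect_equal(cr0$outlier_count, 0L)
    expect_false(cr0$excluded)

    expect_error(select_window(o0, window_len = 31), "exceeds")

    # brute-force equality on random instances with T <= 200
    withr::with_seed(7, {
        for (rep in 1:200) {
            T <- sample(10:200, 1)
            wl <- sample(5:T, 1)
            fl <- runif(T) < runif(1, 0.05, 0.4)
            fl[1] <- FALSE
            om <- structure(list(flags = fl, threshold = 1),
                            class = "outlier_mask")
            got <- select_window(om, window_len = wl)
            want <- window_oracle(fl, wl)
            expect_equal(got$outlier_count, want$outlier_count)
            expect_equal(got$start, want$start)
        }
    })
})

test_that("outliers outside every optimal window never change the selected count", {
    withr::with_seed(11, {
        for (rep in 1:50) {
            T <- sample(30:120, 1)
            wl <- sample(10:(T %/% 2), 1)
            fl <- runif(T) < 0.15
            fl[1] <- FALSE
            om <- structure(list(flags = fl, threshold = 1),
                            class = "outlier_mask")
            base <- select_window(om, window_len = wl)
            opt <- window_oracle(fl, wl)$all_optimal
            covered <- unique(unlist(lapply(opt, function(s) s:(s + wl - 1))))
            outside <- setdiff(which(!fl), covered)
            outside <- setdiff(outside, 1L)
            if (!length(outside)) next
            fl2 <- fl
            fl2[outside[1]] <- TRUE
            om2 <- structure(list(flags = fl2, threshold = 1),
                             class = "outlier_mask")
            expect_equal(select_window(om2, window_len = wl)$outlier_count,
                         base$outlier_count)
        }
    })
})

test_that("default window is the ~70% crop: 1600 volumes of 2300", {
    o <- structure(list(flags = rep(FALSE, 2300), threshold = 1),
                   class = "outlier_mask")
    expect_equal(select_window(o)$length, 1600L)
    # generalisation to other T
    o2 <- structure(list(flags = rep(FALSE, 1000), threshold = 1),
                    class = "outlier_mask")
    expect_equal(select_window(o2)$length, as.integer(round(1600 / 2300 * 1000)))
})

test_that("the exclusion boundary is strict: 160 of 1600 retained, 161 excluded", {
    mk <- function(k) {
        fl <- rep(FALSE, 1600)
        fl[seq_len(k) + 1] <- TRUE
        structure(list(flags = fl, threshold = 1), class = "outlier_mask")
    }
    expect_false(select_window(mk(160), window_len = 1600)$excluded)
    expect_true(select_window(mk(161), window_len = 1600)$excluded)
})

test_that("applying QC crops exactly and records the motion covariate", {
    b <- withr::with_seed(3, bold4d(array(rnorm(4 * 4 * 2 * 50), c(4, 4, 2, 50))))
    meta <- make_metas(1)
    qc <- run_subject_qc(b, meta)
    expect_false(qc$excluded)
    expect_equal(dim(qc$bold$data)[4], as.integer(round(1600 / 2300 * 50)))
    expect_equal(qc$meta$motion_outliers, qc$crop$outlier_count)

    # excluded subjects yield no cropped data
    fl <- rep(TRUE, 50); fl[1] <- FALSE
    om <- structure(list(flags = fl, threshold = 0), class = "outlier_mask")
    cr <- select_window(om, window_len = 40)
    expect_true(cr$excluded)
    res <- apply_qc(b, cr, meta)
    expect_null(res$bold)
    expect_true(res$excluded)
    expect_equal(res$meta$motion_outliers, cr$outlier_count)
})

test_that("simulated motion spikes are detected by the DVARS rule", {
    cfg <- synth_config(grid = c(8, 8, 4), T = 120, K_signal = 2,
                        K_artifact = 0, n_term = 1, n_preterm = 0,
                        spike_rate = 0.06, noise_sd = 0.5, seed = 13)
    maps <- make_ground_truth_maps(cfg)
    sim <- simulate_subject(cfg, make_metas(1), maps, seed = 21)
    spiked <- setdiff(sim$truth$spiked_volumes, 1L)
    expect_gt(length(spiked), 0)
    o <- flag_outliers(compute_dvars(sim$bold))
    expect_true(all(o$flags[spiked]))
})
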