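test_that("design matrices carry the study's covariate sets and codings", {
    metas <- make_metas(8)
    d <- build_design(metas, "age")
    expect_equal(d$column_names, c("intercept", "pma_scan", "sex", "motion"))
    expect_equal(d$contrast, c(0, 1, 0, 0))
    expect_equal(d$nuisance_columns, c(1L, 3L, 4L))
    # continuous covariates are mean-centred
    expect_lt(abs(mean(d$matrix[, "pma_scan"])), 1e-12)
    expect_lt(abs(mean(d$matrix[, "motion"])), 1e-12)

    d2 <- build_design(metas, "sex")
    expect_equal(d2$column_names,
                 c("intercept", "sex", "pma_scan", "ga_birth", "motion"))
    expect_equal(which(d2$contrast == 1), 2L)

    metas_mix <- make_metas(10, groups = c("term", "preterm"))
    d3 <- build_design(metas_mix, "preterm_group")
    expect_equal(d3$column_names,
                 c("intercept", "group", "pma_scan", "sex", "motion"))
    expect_equal(d3$matrix[, "group"],
                 as.numeric(metas_mix$group == "preterm"))

    d4 <- build_design(metas_mix, "ga_continuous")
    expect_equal(which(d4$contrast == 1), 2L)
    expect_equal(d4$column_names[2], "ga_birth")

    d5 <- build_design(metas, "group_mean")
    expect_equal(d5$column_names, c("intercept", "sex", "motion"))
    expect_equal(d5$contrast, c(1, 0, 0))
})

test_that("degenerate designs are rejected", {
    metas <- make_metas(8)
    metas_mix <- make_metas(10, groups = c("term", "preterm"))
    expect_error(build_design(metas_mix, "age"), "term-born")
    expect_error(build_design(metas, "preterm_group"), "degenerate group")
    same_sex <- metas; same_sex$sex <- "female"
    expect_error(build_design(same_sex, "age"), "constant column")
    no_qc <- metas; no_qc$motion_outliers <- NA_real_
    expect_error(build_design(no_qc, "age"), "motion QC")
})

test_that("voxelwise t-statistics match a scalar regression oracle", {
    metas <- make_metas(6)
    d <- build_design(metas, "age")
    withr::with_seed(12, {
        Y <- matrix(rnorm(6 * 4), 6, 4)
        tv <- fit_glm_voxelwise(Y, d)
        for (v in 1:4) {
            fit <- lm(Y[, v] ~ 0 + d$matrix)
            want <- summary(fit)$coefficients["d$matrixpma_scan", "t value"]
            expect_equal(tv[v], want, tolerance = 1e-10)
        }
        expect_equal(attr(tv, "df"), 2L)

        # equivariance: permuting subjects and design rows together
        p <- sample(6)
        dp <- d; dp$matrix <- d$matrix[p, ]
        expect_equal(as.vector(fit_glm_voxelwise(Y[p, ], dp)), as.vector(tv),
                     tolerance = 1e-10)
    })

    # perfect noiseless signal: |t| enormous with the sign of the slope
    Yp <- matrix(-2 * d$matrix[, "pma_scan"], 6, 1) +
          matrix(d$matrix[, "sex"], 6, 1)
    tvp <- fit_glm_voxelwise(Yp, d)
    expect_lt(tvp[1], -1e6)
})

test_that("TFCE handles trivial supports and matches the closed-form single-voxel sum", {
    z <- array(0, c(6, 6, 6))
    expect_equal(tfce_enhance(z), z)

    one <- array(0, c(7, 7, 7)); one[4, 4, 4] <- 1
    got <- tfce_enhance(one, tfce_params(E = 0.5, H = 2, n_steps = 100))
    # extent is always 1: sum_i (i/100)^2 * (1/100), a Riemann sum for 1/3
    want <- sum((seq_len(100) / 100)^2) / 100
    expect_equal(got[4, 4, 4], want, tolerance = 1e-12)
    expect_equal(want, 1 / 3, tolerance = 0.02)
    expect_equal(sum(got > 0), 1)

    # negative and zero voxels never receive mass
    mix <- array(-1, c(5, 5, 5)); mix[2, 2, 2] <- 2
    gm <- tfce_enhance(mix)
    expect_equal(sum(gm > 0), 1)
})

test_that("TFCE agrees with the per-threshold connected-component oracle", {
    withr::with_seed(21, {
        for (conn in c(6, 18, 26)) {
            stat <- array(rnorm(6 * 6 * 6), c(6, 6, 6))
            p <- tfce_params(n_steps = 40, connectivity = conn)
            got <- tfce_enhance(stat, p)
            want <- tfce_oracle(stat, E = 0.5, H = 2, n_steps = 40,
                                connectivity = conn)
            expect_lt(max(abs(got - want)), 1e-6)
        }
    })
})

test_that("TFCE is monotone under pointwise domination (matched step size)", {
    withr::with_seed(22, {
        a <- array(abs(rnorm(6 * 6 * 4)), c(6, 6, 4))
        a[1, 1, 1] <- 5            # shared maximum fixes dh for both maps
        b <- a + 0.3 * abs(rnorm(length(a)))
        b[1, 1, 1] <- 5
        ta <- tfce_enhance(a); tb <- tfce_enhance(b)
        expect_true(all(tb - ta >= -1e-12))
    })
})

test_that("exhaustive enumeration yields exact p-values as multiples of 1/n!", {
    n <- 5
    grid <- c(4, 4, 2)
    metas <- make_metas(n, groups = c("term", "term", "term", "preterm", "preterm"))
    metas$sex <- c("female", "male", "female", "male", "female")
    # minimal two-group design: intercept + group indicator
    d <- structure(list(matrix = cbind(intercept = 1,
                                       group = as.numeric(metas$group == "preterm")),
                        column_names = c("intercept", "group"),
                        contrast = c(0, 1), nuisance_columns = 1L,
                        model = "two_group"), class = "glm_design")
    Y <- withr::with_seed(31, matrix(rnorm(n * prod(grid)), n))
    attr(Y, "grid") <- grid
    r <- permutation_fwe(Y, d, tfce_params(n_steps = 20), n_perm = 500, seed = 1)
    expect_true(r$exhaustive)
    expect_equal(r$n_perm, 120L)
    expect_true(all(abs(r$p_fwe_pos * 120 - round(r$p_fwe_pos * 120)) < 1e-9))
    expect_true(all(r$p_fwe_pos >= 1 / 120 & r$p_fwe_pos <= 1))
})

test_that("sampled permutation p-values respect the 1/(n_perm+1) floor", {
    n <- 20
    grid <- c(4, 4, 2)
    metas <- make_metas(n)
    d <- build_design(metas, "age")
    # strong age effect in a corner block
    eff <- matrix(0, n, prod(grid))
    eff[, 1:4] <- outer(d$matrix[, "pma_scan"], rep(4, 4))
    Y <- withr::with_seed(32, eff + 0.1 * matrix(rnorm(n * prod(grid)), n))
    attr(Y, "grid") <- grid
    r <- permutation_fwe(Y, d, tfce_params(n_steps = 20), n_perm = 50, seed = 2)
    expect_false(r$exhaustive)
    expect_equal(min(r$p_fwe_pos), 1 / 51)
    expect_true(all(r$p_fwe_neg >= 1 / 51))
    expect_length(r$null_max_pos, 50)
})

test_that("Freedman-Lane with no nuisance reduces to plain row permutation", {
    n <- 5
    grid <- c(4, 4, 2)
    V <- prod(grid)
    x <- c(-1, -0.5, 0, 0.5, 1)
    d <- structure(list(matrix = cbind(x = x), column_names = "x",
                        contrast = 1, nuisance_columns = integer(0),
                        model = "bare"), class = "glm_design")
    Y <- withr::with_seed(33, matrix(rnorm(n * V), n))
    attr(Y, "grid") <- grid
    p <- tfce_params(n_steps = 25)
    r <- permutation_fwe(Y, d, p, n_perm = 500, seed = 3)
    expect_true(r$exhaustive)
    # independent reconstruction: permute raw rows, refit, TFCE, take maxima
    gen <- function(v) if (length(v) == 1) list(v) else {
        out <- list()
        for (i in seq_along(v))
            out <- c(out, lapply(gen(v[-i]), function(p) c(v[i], p)))
        out
    }
    want <- vapply(gen(1:5), function(pp) {
        Yp <- Y[pp, , drop = FALSE]
        bb <- solve(crossprod(cbind(x)), crossprod(cbind(x), Yp))
        res <- Yp - cbind(x) %*% bb
        s2 <- colSums(res^2) / (n - 1)
        tv <- bb[1, ] / sqrt(s2 * solve(crossprod(cbind(x)))[1, 1])
        max(tfce_enhance(array(tv, grid), p))
    }, numeric(1))
    expect_equal(sort(r$null_max_pos), sort(want), tolerance = 1e-10)
})

test_that("significance thresholds are strict and Bonferroni-scaled", {
    r <- structure(list(p_fwe_pos = array(c(0.025, 0.0249, 0.3, 1e-4), c(4, 1, 1)),
                        p_fwe_neg = array(rep(0.4, 4), c(4, 1, 1))),
                   class = "stat_result")
    th <- threshold_results(r, alpha = 0.025)
    expect_equal(as.vector(th$pos), c(FALSE, TRUE, FALSE, TRUE))
    thb <- threshold_results(r, alpha = 0.025, n_networks = 11,
                             bonferroni = TRUE)
    expect_equal(thb$cutoff, 0.025 / 11)
    expect_equal(as.vector(thb$pos), c(FALSE, FALSE, FALSE, TRUE))
    th5 <- threshold_results(r, alpha = 0.5)
    expect_true(all(th5$pos))
})

test_that("weekly bins use half-open intervals and lowest postnatal days", {
    grid <- c(5, 5, 2)
    V <- prod(grid)
    n <- 30
    metas <- make_metas(n)
    metas$pma_scan <- c(rep(38.0, 12), 38.5, rep(39.0, 12), rep(43, 5))
    metas$postnatal_days <- seq_len(n)
    metas$sex <- rep(c("female", "male"), 15)
    Y <- withr::with_seed(41, matrix(rnorm(n * V, mean = 2), n))
    attr(Y, "grid") <- grid
    res <- weekly_bin_maps(metas, Y, bin_edges = c(37.5, 38.5, 39.5),
                           n_per_bin = 10, params = tfce_params(n_steps = 20),
                           n_perm = 60, seed = 4, alpha = 0.05)
    expect_named(res, c("[37.5,38.5)", "[38.5,39.5)"))
    # the 38.5-week subject falls in the second bin (half-open convention)
    expect_false(metas$subject_id[13] %in% res[["[37.5,38.5)"]]$subjects)
    expect_true(metas$subject_id[13] %in% res[["[38.5,39.5)"]]$subjects)
    # within bin 1 the 10 lowest-postnatal-day subjects of 12 are kept
    expect_setequal(res[["[37.5,38.5)"]]$subjects, metas$subject_id[1:10])
    # strong positive mean: significant voxels found at p < 0.05
    expect_true(any(res[["[37.5,38.5)"]]$mask))

    expect_error(weekly_bin_maps(metas, Y, bin_edges = c(41.5, 42.5),
                                 n_per_bin = 10), "bin \\[41.5,42.5\\)")
})
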