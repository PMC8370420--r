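test_that("whitening yields identity covariance and respects rank limits", {
    subs <- withr::with_seed(4, lapply(1:2, function(s)
        bold4d(array(rnorm(5 * 5 * 4 * 50), c(5, 5, 4, 50)),
               subject_id = paste0("s", s))))
    w <- concat_and_whiten(subs, K = 3)
    expect_equal(dim(w$whitened), c(3, 100))
    expect_lt(max(abs(tcrossprod(w$whitened) / w$nvox - diag(3))), 1e-8)

    # K above the data rank is rejected
    src <- make_plateau_sources(c(8, 8, 6), 1)
    rank1 <- make_mixture_subjects(src, 2, 30, seed = 1)
    expect_error(concat_and_whiten(rank1, K = 2), "rank")
    # rank-1 noise-free data at K = 1 captures all variance
    w1 <- concat_and_whiten(rank1, K = 1)
    expect_equal(w1$var_explained[1], 1, tolerance = 1e-8)

    # mismatched grids are rejected
    bad <- bold4d(array(rnorm(4 * 4 * 4 * 10), c(4, 4, 4, 10)))
    expect_error(concat_and_whiten(list(subs[[1]], bad), K = 2), "grid mismatch")
})

test_that("the whitened subspace is invariant to subject order", {
    src <- make_plateau_sources(c(12, 12, 8), 3)
    subs <- make_mixture_subjects(src, 3, 40, seed = 2)
    w1 <- concat_and_whiten(subs, K = 3)
    w2 <- concat_and_whiten(rev(subs), K = 3)
    # principal angles between the two spanned spatial subspaces are 0
    q1 <- qr.Q(qr(t(w1$whitened)))
    q2 <- qr.Q(qr(t(w2$whitened)))
    expect_equal(svd(crossprod(q1, q2))$d, rep(1, 3), tolerance = 1e-8)
})

test_that("ICA recovers disjoint super-Gaussian sources and is seed-deterministic", {
    grid <- c(15, 15, 10)
    src <- make_plateau_sources(grid, 2)
    subs <- make_mixture_subjects(src, 3, 50, seed = 3)
    w <- concat_and_whiten(subs, K = 2)
    g <- fit_group_ica(w, seed = 1)
    m <- match_maps(g$maps, array(unlist(src), c(grid, 2)))
    expect_true(all(m$cor >= 0.99))
    # positive-skewness sign convention
    for (k in 1:2) {
        mk <- g$maps[, , , k]
        expect_gt(mean((mk - mean(mk))^3), 0)
    }
    # same seed reproduces the maps to high precision
    g2 <- fit_group_ica(w, seed = 1)
    expect_lt(max(abs(g$maps - g2$maps)), 1e-10)
})

test_that("sources up to k = 6 are recovered across seeds after optimal matching", {
    grid <- c(17, 17, 11)
    for (k in c(4, 6)) {
        src <- make_plateau_sources(grid, k)
        for (s in 1:3) {
            subs <- make_mixture_subjects(src, 3, 60, seed = 10 + s)
            g <- fit_group_ica(concat_and_whiten(subs, K = k), seed = s)
            m <- match_maps(g$maps, array(unlist(src), c(grid, k)))
            expect_true(all(m$cor >= 0.95))
        }
    }
})

test_that("Z-maps of pure-noise data are calibrated (about 1% above |Z| = 3)", {
    subs <- withr::with_seed(8, lapply(1:3, function(s)
        bold4d(array(rnorm(12 * 12 * 8 * 40), c(12, 12, 8, 40)),
               subject_id = paste0("n", s))))
    w <- concat_and_whiten(subs, K = 5)
    g <- suppressWarnings(fit_group_ica(w, seed = 2,
                                        on_nonconvergence = "warn"))
    frac <- mean(abs(g$maps) > 3)
    expect_lte(frac, 0.01)
})

test_that("requesting K components returns exactly K, ordered by explained variance", {
    grid <- c(15, 15, 10)
    src <- make_plateau_sources(grid, 4)
    subs <- make_mixture_subjects(src, 2, 50, seed = 5)
    g <- fit_group_ica(concat_and_whiten(subs, K = 4), seed = 3)
    expect_equal(g$K, 4L)
    expect_equal(dim(g$maps)[4], 4L)
    expect_equal(order(g$mixing_info$var_explained, decreasing = TRUE), 1:4)
})

test_that("labelling validates tokens and counts and filters downstream networks", {
    grid <- c(15, 15, 10)
    src <- make_plateau_sources(grid, 3)
    subs <- make_mixture_subjects(src, 2, 40, seed = 6)
    g <- fit_group_ica(concat_and_whiten(subs, K = 3), seed = 1)

    expect_error(label_components(g, c("signal", "noise")), "3 components")
    expect_error(label_components(g, c("signal", "noise", "rsn")),
                 "unknown label token")

    g2 <- suppressMessages(label_components(g, c("signal", "noise", "signal")))
    expect_equal(signal_components(g2), c(1L, 3L))
    # all signal: no filtering
    g3 <- suppressMessages(label_components(g, rep("signal", 3)))
    expect_length(signal_components(g3), 3)

    # file-based labelling with a missing row is located
    tmp <- withr::local_tempdir()
    lp <- file.path(tmp, "labels.tsv")
    write.table(data.frame(name = g$names[1:2], label = "signal"), lp,
                sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(label_components(g, lp), "IC03")
    write.table(data.frame(name = g$names, label = c("signal", "noise", "signal")),
                lp, sep = "\t", quote = FALSE, row.names = FALSE)
    g4 <- suppressMessages(label_components(g, lp))
    expect_equal(g4$labels, c("signal", "noise", "signal"))
})

test_that("degenerate near-constant components are pruned, well-conditioned sets kept", {
    grid <- c(10, 10, 6)
    V <- prod(grid)
    src <- make_plateau_sources(grid, 3, radius = 1)
    withr::with_seed(71, {
        # three blobs plus a near-constant global map whose tiny demeaned
        # remainder lies in the span of the blob maps (as happens when all
        # maps come from one low-rank decomposition): the classic
        # degenerate-regressor case
        glob <- array(5 + 0.05 * src[[1]] - 0.03 * src[[2]] +
                      0.001 * rnorm(V), grid)
        maps <- c(lapply(src, function(m) 6 * m + 0.05 * array(rnorm(V), grid)),
                  list(glob))
    })
    g <- structure(list(maps = array(unlist(maps), c(grid, 4)),
                        raw_maps = array(unlist(maps), c(grid, 4)),
                        labels = c("signal", "signal", "signal", "noise"),
                        names = sprintf("IC%02d", 1:4), K = 4, grid = grid,
                        mask = rep(TRUE, V), voxel_size = c(1, 1, 1),
                        tr = 0.392,
                        mixing_info = list(timecourses = matrix(0, 5, 4),
                                           var_explained = rep(0.25, 4))),
                   class = "group_map_set")
    pruned <- prune_components(g)
    expect_equal(pruned$K, 3L)
    expect_equal(pruned$names, c("IC01", "IC02", "IC03"))
    expect_equal(ncol(pruned$mixing_info$timecourses), 3L)

    # a well-conditioned set is returned unchanged
    g3 <- g
    g3$maps <- g$maps[, , , 1:3, drop = FALSE]
    g3$raw_maps <- g3$maps; g3$K <- 3L
    g3$labels <- g$labels[1:3]; g3$names <- g$names[1:3]
    g3$mixing_info <- list(timecourses = matrix(0, 5, 3),
                           var_explained = rep(1/3, 3))
    expect_identical(prune_components(g3), g3)
})

test_that("the heuristic pre-labeller flags edge-dominated components as noise", {
    grid <- c(14, 14, 8)
    src <- make_plateau_sources(grid, 2)
    # an edge ring as a genuine negative
    ring <- array(0, grid)
    ring[c(1, grid[1]), , ] <- 1
    ring[, c(1, grid[2]), ] <- 1
    subs <- make_mixture_subjects(c(src, list(ring)), 3, 60, seed = 9)
    g <- fit_group_ica(concat_and_whiten(subs, K = 3), seed = 4)
    sugg <- suggest_labels(g)
    m <- match_maps(g$maps, array(ring, c(grid, 1)))
    expect_equal(sugg$suggested[m$perm[1]], "noise")
})
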