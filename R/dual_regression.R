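# Dual regression: stage 1 regresses the group spatial maps (all components,
# signal and noise alike, so artifact components absorb confound variance)
# into the subject's 4D data as spatial regressors, giving one time course
# per component; stage 2 regresses those time courses back into the same 4D
# data as temporal regressors, giving one subject-specific beta map per
# component.

#' Stage 1: spatial regression of group maps into a subject's data
#'
#' For each volume, an ordinary-least-squares multiple regression of the
#' demeaned group maps (demeaned over in-mask voxels) against the demeaned
#' voxel vector. All K components enter jointly.
#'
#' @param b the subject's cropped [bold4d()].
#' @param g a `group_map_set` (or a voxels x K numeric matrix of maps).
#' @param mask optional 3D logical array; defaults to the map set's mask.
#' @return T x K matrix of component time courses.
#' @export
stage1_spatial_regression <- function(b, g, mask = NULL) {
    stopifnot(inherits(b, "bold4d"))
    d <- dim(b$data)
    if (inherits(g, "group_map_set")) {
        if (!identical(g$grid, d[1:3])) stop("grid mismatch between maps and data")
        vox <- g$mask
        M <- matrix(g$maps, prod(g$grid), g$K)[vox, , drop = FALSE]
        cn <- g$names
    } else {
        M <- as.matrix(g)
        vox <- if (is.null(mask)) rep(TRUE, prod(d[1:3])) else as.vector(mask)
        M <- M[vox, , drop = FALSE]
        cn <- colnames(M)
    }
    K <- ncol(M)
    if (K >= sum(vox)) stop("K must be smaller than the number of in-mask voxels")
    Mc <- sweep(M, 2, colMeans(M))
    qrM <- qr(Mc)
    if (qrM$rank < K)
        stop("rank-deficient map matrix; collinear components: ",
             paste(if (!is.null(cn)) cn[-seq_len(qrM$rank)] else
                   (qrM$rank + 1):K, collapse = ", "))
    Y <- matrix(b$data, prod(d[1:3]), d[4])[vox, , drop = FALSE]
    Y <- sweep(Y, 2, colMeans(Y))        # demean each volume over voxels
    tcs <- t(qr.coef(qrM, Y))            # T x K
    colnames(tcs) <- cn
    tcs
}

#' Stage 2: temporal regression of stage-1 time courses into the data
#'
#' Per voxel, OLS of the demeaned (and, with `variance_normalise`,
#' unit-variance-scaled) component time courses onto the voxel's demeaned
#' time series. With variance normalisation the betas are in units of
#' response per unit time-course standard deviation.
#'
#' @param b the subject's cropped [bold4d()].
#' @param tcs T x K matrix from [stage1_spatial_regression()].
#' @param variance_normalise scale each time course to unit variance first.
#' @return 4D array of beta maps (component along the 4th axis).
#' @export
stage2_temporal_regression <- function(b, tcs, variance_normalise = FALSE) {
    stopifnot(inherits(b, "bold4d"))
    d <- dim(b$data)
    tcs <- as.matrix(tcs)
    if (nrow(tcs) != d[4])
        stop("time-course length ", nrow(tcs), " does not match T = ", d[4])
    D <- sweep(tcs, 2, colMeans(tcs))
    if (variance_normalise) {
        sds <- apply(D, 2, sd)
        if (any(sds == 0)) stop("constant time course cannot be variance-normalised")
        D <- sweep(D, 2, sds, "/")
    }
    qrD <- qr(D)
    if (qrD$rank < ncol(D)) stop("rank-deficient time-course matrix")
    Y <- matrix(b$data, prod(d[1:3]), d[4])
    Y <- Y - rowMeans(Y)                 # demean each voxel over time
    B <- t(qr.coef(qrD, t(Y)))           # voxels x K
    array(B, c(d[1:3], ncol(D)))
}

#' Run both dual-regression stages for one subject
#'
#' @inheritParams stage1_spatial_regression
#' @inheritParams stage2_temporal_regression
#' @return A `subject_dr`: list with `timecourses` (T x K), `beta_maps`
#'   (4D, component along the 4th axis, all K components including noise),
#'   `subject_id`, `variance_normalised`.
#' @export
dual_regress <- function(b, g, variance_normalise = FALSE) {
    tcs <- stage1_spatial_regression(b, g)
    betas <- stage2_temporal_regression(b, tcs, variance_normalise)
    structure(list(timecourses = tcs, beta_maps = betas,
                   subject_id = b$subject_id,
                   variance_normalised = variance_normalise),
              class = "subject_dr")
}

#' Stack one network's beta maps across subjects
#'
#' Analysis outputs use signal components only; noise components were
#' carried through both stages purely as confound regressors and are
#' discarded here by selecting a signal component index.
#'
#' @param drs list of `subject_dr` objects.
#' @param component component index into the map set.
#' @return n_subjects x V matrix with attribute `grid`.
#' @export
stack_betas <- function(drs, component) {
    grid <- dim(drs[[1]]$beta_maps)[1:3]
    out <- t(vapply(drs, function(dr) as.vector(dr$beta_maps[, , , component]),
                    numeric(prod(grid))))
    rownames(out) <- vapply(drs, `[[`, "", "subject_id")
    attr(out, "grid") <- grid
    out
}
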