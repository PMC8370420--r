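# Group-level network definition: temporal concatenation across subjects,
# PCA whitening to the requested dimensionality, and spatial ICA by
# fixed-point negentropy maximisation (tanh contrast, symmetric
# decorrelation). Raw maps are converted to Z-maps by robust background
# normalisation and ordered by explained variance.

#' Concatenate subjects in time and whiten to K dimensions
#'
#' Each subject's voxel time series is demeaned and variance-normalised over
#' time, the subjects are stacked along the time axis, and the stack is
#' reduced to `K` spatial dimensions by singular-value decomposition with
#' unit-variance whitening: the returned `K x V` matrix `Y` satisfies
#' `Y %*% t(Y) / V = I`.
#'
#' @param subjects list of (cropped) [bold4d()] objects on a shared grid.
#' @param K target dimensionality.
#' @param mask optional 3D logical array; defaults to all voxels.
#' @return A `whitened_data` list: `whitened` (K x V), `concat` (total-T x V,
#'   retained for variance accounting), `var_explained` (per retained
#'   dimension), `grid`, `mask`, `voxel_size`, `tr`, `subject_ids`.
#' @export
concat_and_whiten <- function(subjects, K, mask = NULL) {
    stopifnot(length(subjects) >= 1)
    grid <- dim(subjects[[1]]$data)[1:3]
    for (s in subjects)
        if (!identical(dim(s$data)[1:3], grid))
            stop("grid mismatch across subjects (", s$subject_id, ")")
    vox <- if (is.null(mask)) rep(TRUE, prod(grid)) else {
        stopifnot(identical(dim(mask), grid)); as.vector(mask)
    }
    V <- sum(vox)
    X <- do.call(rbind, lapply(subjects, function(s) {
        d <- dim(s$data)
        m <- matrix(s$data, prod(d[1:3]), d[4])[vox, , drop = FALSE]
        m <- m - rowMeans(m)
        sds <- sqrt(rowSums(m^2) / (d[4] - 1))
        m[sds > 0, ] <- m[sds > 0, ] / sds[sds > 0]
        t(m)
    }))
    if (nrow(X) <= K)
        stop("total time points (", nrow(X), ") must exceed K = ", K)
    ev <- eigen(tcrossprod(X), symmetric = TRUE)
    lambda <- pmax(ev$values, 0)
    if (lambda[K] <= max(lambda) * 1e-12)
        stop("K = ", K, " exceeds the rank of the concatenated data")
    d <- sqrt(lambda[1:K])
    # right singular vectors scaled to unit variance over voxels
    Y <- sqrt(V) * t(crossprod(X, ev$vectors[, 1:K, drop = FALSE]) %*%
                     diag(1 / d, K))
    structure(list(whitened = Y, concat = X,
                   var_explained = lambda[1:K] / sum(lambda),
                   grid = grid, mask = vox, nvox = V,
                   voxel_size = subjects[[1]]$voxel_size,
                   tr = subjects[[1]]$tr,
                   subject_ids = vapply(subjects, `[[`, "", "subject_id")),
              class = "whitened_data")
}

# Symmetric decorrelation: W <- (W W^T)^{-1/2} W.
sym_decorrelate <- function(W) {
    e <- eigen(tcrossprod(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)),
                       nrow(W)) %*% t(e$vectors) %*% W
}

#' Estimate spatially independent components from whitened data
#'
#' Fixed-point (FastICA-style) estimation with the hyperbolic-tangent
#' contrast and symmetric decorrelation, run on the spatial dimension so the
#' sources are spatial maps. Each raw map is converted to a Z-map by robust
#' background normalisation (centred on its median, divided by 1.4826 x MAD,
#' which estimates the residual-noise standard deviation of the component
#' map); map sign is fixed so that skewness is positive (networks are
#' positive activations) and components are ordered by explained variance.
#'
#' When the data hold fewer genuinely non-Gaussian sources than `K`, the
#' surplus components span a (near-)Gaussian subspace in which the
#' fixed-point update has no stable direction, and the iteration cannot
#' reach a tight tolerance; by default this is an error (restart with
#' another seed, or lower `K`). `on_nonconvergence = "warn"` instead
#' returns the iterate with the smallest update step, which is the useful
#' behaviour when weak-contrast components are expected (for example
#' noise-calibration runs).
#'
#' @param w a `whitened_data` from [concat_and_whiten()].
#' @param K number of components; defaults to the whitening dimensionality.
#' @param seed RNG seed for the random orthogonal initialisation.
#' @param max_iter,tol fixed-point iteration cap and convergence tolerance.
#' @param on_nonconvergence `"error"` (default) or `"warn"` (return the best
#'   iterate).
#' @return A `group_map_set`: list with `maps` (4D array, component along the
#'   4th axis, Z units), `raw_maps`, `labels` (all `"unlabelled"`), `names`,
#'   `K`, `mixing_info` (per-component time courses and variance explained),
#'   `grid`, `mask`, `voxel_size`, `tr`.
#' @export
fit_group_ica <- function(w, K = NULL, seed = 1, max_iter = 1000, tol = 1e-6,
                          on_nonconvergence = c("error", "warn")) {
    stopifnot(inherits(w, "whitened_data"))
    on_nonconvergence <- match.arg(on_nonconvergence)
    Y <- w$whitened
    if (is.null(K)) K <- nrow(Y)
    if (K != nrow(Y)) stop("K must match the whitening dimensionality")
    V <- ncol(Y)
    W <- with_seed(seed, matrix(rnorm(K * K), K, K))
    W <- sym_decorrelate(W)
    converged <- FALSE
    best_delta <- Inf
    W_best <- W
    for (it in seq_len(max_iter)) {
        S <- W %*% Y
        G <- tanh(S)
        W1 <- tcrossprod(G, Y) / V - diag(rowMeans(1 - G^2), K) %*% W
        W1 <- sym_decorrelate(W1)
        delta <- max(abs(abs(diag(tcrossprod(W1, W))) - 1))
        W <- W1
        if (delta < best_delta) { best_delta <- delta; W_best <- W1 }
        if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged) {
        if (on_nonconvergence == "error")
            stop("ICA did not converge in ", max_iter,
                 " iterations (best step ", signif(best_delta, 3),
                 "); restart with a different seed or reduce K")
        warning("ICA did not converge in ", max_iter,
                " iterations; returning the best iterate (step ",
                signif(best_delta, 3), ")")
        W <- W_best
    }
    S <- W %*% Y
    flip <- sign(rowMeans(S^3))          # positive-skewness sign convention
    flip[flip == 0] <- 1
    S <- S * flip
    W <- W * flip
    A <- w$concat %*% t(S) / V           # associated time courses (mixing)
    varexp <- colSums(A^2) * V
    ord <- order(varexp, decreasing = TRUE)
    S <- S[ord, , drop = FALSE]
    A <- A[, ord, drop = FALSE]
    varexp <- varexp[ord] / sum(rowSums(w$concat^2))
    zmaps <- t(apply(S, 1, function(s) {
        sigma <- mad(s)
        if (sigma == 0) sigma <- sd(s)   # sparse map: majority of voxels identical
        (s - median(s)) / sigma
    }))
    full <- function(M) {
        out <- matrix(0, length(w$mask), nrow(M))
        out[w$mask, ] <- t(M)
        array(out, c(w$grid, nrow(M)))
    }
    structure(list(maps = full(zmaps), raw_maps = full(S),
                   labels = rep("unlabelled", K),
                   names = sprintf("IC%02d", seq_len(K)), K = K,
                   mixing_info = list(timecourses = A, var_explained = varexp),
                   grid = w$grid, mask = w$mask,
                   voxel_size = w$voxel_size, tr = w$tr),
              class = "group_map_set")
}

#' @export
print.group_map_set <- function(x, ...) {
    cat(sprintf("<group_map_set> %d components on %dx%dx%d grid (%d signal, %d noise, %d unlabelled)\n",
                x$K, x$grid[1], x$grid[2], x$grid[3],
                sum(x$labels == "signal"), sum(x$labels == "noise"),
                sum(x$labels == "unlabelled")))
    invisible(x)
}

#' Attach signal/noise labels to a component set
#'
#' Labelling mirrors the manual RSN-versus-noise classification of group-ICA
#' output: labels come from the analyst, either as a character vector or as
#' a two-column TSV (`name`, `label`). Downstream stages treat signal
#' components as networks and keep noise components only as confound
#' regressors.
#'
#' @param g a `group_map_set`.
#' @param labels character vector of `"signal"`/`"noise"`, length `K`, or a
#'   TSV path with columns `name` and `label`.
#' @return The labelled `group_map_set`.
#' @export
label_components <- function(g, labels) {
    stopifnot(inherits(g, "group_map_set"))
    if (is.character(labels) && length(labels) == 1 && file.exists(labels)) {
        tab <- read.delim(labels, stringsAsFactors = FALSE)
        if (!all(c("name", "label") %in% names(tab)))
            stop("label file needs columns 'name' and 'label'")
        miss <- setdiff(g$names, tab$name)
        if (length(miss))
            stop("missing label row for component ", miss[1])
        labels <- tab$label[match(g$names, tab$name)]
    }
    if (length(labels) != g$K)
        stop("got ", length(labels), " labels for ", g$K, " components")
    bad <- setdiff(unique(labels), c("signal", "noise"))
    if (length(bad)) stop("unknown label token: ", bad[1])
    g$labels <- labels
    nr_log("labelled components: %d signal, %d noise",
           sum(labels == "signal"), sum(labels == "noise"))
    g
}

#' Remove components that are degenerate as spatial regressors
#'
#' Spatial regression demeans each component map over voxels, so a
#' (near-)constant map — typically a global component driven by
#' whole-volume intensity shifts — collapses to a tiny-norm regressor that
#' the remaining maps can jointly reconstruct, inflating the variance of
#' every stage-1 time course by orders of magnitude. This screens the
#' demeaned maps by variance inflation factor and removes the worst
#' offender until all remaining components are well conditioned.
#'
#' @param g a `group_map_set`.
#' @param vif_max largest acceptable variance inflation factor.
#' @return The pruned `group_map_set` (possibly unchanged); removed
#'   component names are reported via [nr_log()].
#' @export
prune_components <- function(g, vif_max = 10) {
    stopifnot(inherits(g, "group_map_set"), vif_max >= 1)
    keep <- seq_len(g$K)
    M <- matrix(g$maps, length(g$mask), g$K)[g$mask, , drop = FALSE]
    repeat {
        if (length(keep) < 2) break
        Mc <- sweep(M[, keep, drop = FALSE], 2,
                    colMeans(M[, keep, drop = FALSE]))
        G <- crossprod(Mc)
        Gi <- tryCatch(solve(G), error = function(e) NULL)
        if (is.null(Gi)) {
            # singular: drop the component with the smallest demeaned norm
            drop <- keep[which.min(diag(G))]
            nr_log("pruning component %s (degenerate demeaned map)",
                   g$names[drop])
        } else {
            vif <- diag(Gi) * diag(G)
            if (max(vif) <= vif_max) break
            drop <- keep[which.max(vif)]
            nr_log("pruning component %s (VIF %.3g)", g$names[drop], max(vif))
        }
        keep <- setdiff(keep, drop)
    }
    if (length(keep) == g$K) return(g)
    g$maps <- g$maps[, , , keep, drop = FALSE]
    g$raw_maps <- g$raw_maps[, , , keep, drop = FALSE]
    g$labels <- g$labels[keep]
    g$names <- g$names[keep]
    g$K <- length(keep)
    if (!is.null(g$mixing_info$timecourses))
        g$mixing_info$timecourses <-
            g$mixing_info$timecourses[, keep, drop = FALSE]
    if (!is.null(g$mixing_info$var_explained))
        g$mixing_info$var_explained <- g$mixing_info$var_explained[keep]
    g
}

#' Indices of signal (network) components
#' @param g a labelled `group_map_set`.
#' @return Integer vector of component indices labelled `"signal"`.
#' @export
signal_components <- function(g) {
    stopifnot(inherits(g, "group_map_set"))
    which(g$labels == "signal")
}

#' Heuristic label suggestions for ICA components
#'
#' Suggests `"noise"` for components whose suprathreshold voxels sit mostly
#' on the volume boundary (edge fraction) or whose associated time course
#' carries most of its spectral power above the resting-state band
#' (> 0.1 Hz). A screening aid only: labels are the analyst's decision and
#' must be attached with [label_components()].
#'
#' @param g a `group_map_set`.
#' @param z_thr voxel threshold for the edge-fraction computation.
#' @param edge_frac_max suggest noise above this edge fraction.
#' @param hf_power_max suggest noise above this high-frequency power fraction.
#' @return Data frame: component name, edge fraction, high-frequency power
#'   fraction, suggested label.
#' @export
suggest_labels <- function(g, z_thr = 3, edge_frac_max = 0.5,
                           hf_power_max = 0.6) {
    stopifnot(inherits(g, "group_map_set"))
    grid <- g$grid
    on_edge <- array(FALSE, grid)
    on_edge[c(1, grid[1]), , ] <- TRUE
    on_edge[, c(1, grid[2]), ] <- TRUE
    on_edge[, , c(1, grid[3])] <- TRUE
    res <- lapply(seq_len(g$K), function(k) {
        m <- abs(g$maps[, , , k]) > z_thr
        ef <- if (any(m)) sum(m & on_edge) / sum(m) else 0
        tc <- g$mixing_info$timecourses[, k]
        sp <- Mod(stats::fft(tc - mean(tc)))^2
        Tt <- length(tc)
        freq <- (seq_len(Tt) - 1) / (Tt * g$tr)
        freq <- pmin(freq, 1 / g$tr - freq)
        hf <- sum(sp[freq > 0.1]) / sum(sp)
        data.frame(name = g$names[k], edge_fraction = ef, hf_power = hf,
                   suggested = if (ef > edge_frac_max || hf > hf_power_max)
                       "noise" else "signal",
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}

#' Write group maps and labels to disk
#' @param g a `group_map_set`.
#' @param maps_path output 4D NIfTI path (component along the 4th axis).
#' @param labels_path output TSV path (`name`, `label`).
#' @return Invisibly, the two paths.
#' @export
write_group_maps <- function(g, maps_path, labels_path) {
    write_volume(g$maps, maps_path, voxel_size = g$voxel_size)
    write.table(data.frame(name = g$names, label = g$labels),
                labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(maps_path, labels_path))
}
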