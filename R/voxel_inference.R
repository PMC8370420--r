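# Cross-subject voxelwise inference on dual-regression beta maps: GLM
# designs with the study's covariate sets, contrast t-maps, threshold-free
# cluster enhancement, and family-wise error control by the permutation
# max-statistic method with Freedman-Lane residual permutation. Contrasts
# are two-tailed: each direction is tested against its own max-TFCE null.

#' Build a cross-subject GLM design
#'
#' Covariate sets per model:
#' \describe{
#'   \item{age}{effect of PMA at scan, term-born subjects only; covariates
#'     sex and motion. Columns intercept, pma_scan, sex, motion.}
#'   \item{sex}{effect of sex; covariates PMA at scan, GA at birth and
#'     motion. Columns intercept, sex, pma_scan, ga_birth, motion.}
#'   \item{preterm_group}{term vs preterm birth; covariates PMA at scan, sex
#'     and motion. Columns intercept, group, pma_scan, sex, motion.}
#'   \item{ga_continuous}{effect of GA at birth; covariates PMA at scan, sex
#'     and motion. Columns intercept, ga_birth, pma_scan, sex, motion.}
#'   \item{group_mean}{group-average map controlling for sex and motion.
#'     Columns intercept, sex, motion; contrast on the intercept.}
#' }
#' Continuous covariates are mean-centred; sex is coded female = 1, male = 0
#' and group preterm = 1, term = 0, so positive contrasts read female > male
#' and preterm > term.
#'
#' @param metas covariate data frame with `motion_outliers` filled by QC.
#' @param model one of `"age"`, `"sex"`, `"preterm_group"`,
#'   `"ga_continuous"`, `"group_mean"`.
#' @return A `glm_design`: list with `matrix` (n x p), `column_names`,
#'   `contrast`, `nuisance_columns`, `model`.
#' @export
build_design <- function(metas, model = c("age", "sex", "preterm_group",
                                          "ga_continuous", "group_mean")) {
    model <- match.arg(model)
    stopifnot(nrow(metas) > 0)
    if (any(is.na(metas$motion_outliers)))
        stop("motion_outliers not filled; run motion QC first")
    if (model == "age" && any(metas$group != "term"))
        stop("the age model is restricted to term-born subjects")
    centre <- function(x) x - mean(x)
    sex <- as.numeric(metas$sex == "female")
    grp <- as.numeric(metas$group == "preterm")
    pma <- centre(metas$pma_scan)
    ga <- centre(metas$ga_birth)
    mot <- centre(metas$motion_outliers)
    spec <- switch(model,
        age = list(cols = cbind(intercept = 1, pma_scan = pma, sex = sex,
                                motion = mot), contrast_on = "pma_scan"),
        sex = list(cols = cbind(intercept = 1, sex = sex, pma_scan = pma,
                                ga_birth = ga, motion = mot),
                   contrast_on = "sex"),
        preterm_group = list(cols = cbind(intercept = 1, group = grp,
                                          pma_scan = pma, sex = sex,
                                          motion = mot),
                             contrast_on = "group"),
        ga_continuous = list(cols = cbind(intercept = 1, ga_birth = ga,
                                          pma_scan = pma, sex = sex,
                                          motion = mot),
                             contrast_on = "ga_birth"),
        group_mean = list(cols = cbind(intercept = 1, sex = sex, motion = mot),
                          contrast_on = "intercept"))
    X <- spec$cols
    const <- which(apply(X, 2, function(v) var(v) == 0))
    const <- setdiff(colnames(X)[const], "intercept")
    if (length(const))
        stop("constant column other than intercept: ", paste(const, collapse = ", "),
             if ("group" %in% const) " (degenerate group indicator)" else "")
    if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
    contrast <- as.numeric(colnames(X) == spec$contrast_on)
    structure(list(matrix = X, column_names = colnames(X),
                   contrast = contrast,
                   nuisance_columns = which(contrast == 0), model = model),
              class = "glm_design")
}

# Vectorised contrast t-statistics over voxels. Returns a closure so the
# permutation loop pays the design decompositions only once.
make_t_fun <- function(X, contrast) {
    n <- nrow(X); p <- ncol(X)
    if (n <= p) stop("need more subjects (", n, ") than design columns (", p, ")")
    XtXinv <- solve(crossprod(X))
    pinv <- XtXinv %*% t(X)
    cc <- as.numeric(t(contrast) %*% XtXinv %*% contrast)
    df <- n - p
    function(Y) {
        B <- pinv %*% Y
        res <- Y - X %*% B
        s2 <- colSums(res^2) / df
        num <- as.vector(crossprod(contrast, B))
        se <- sqrt(s2 * cc)
        ifelse(se > 0, num / se, 0)
    }
}

#' Voxelwise GLM contrast t-map
#'
#' Per voxel, ordinary least squares and the contrast t-statistic with
#' n - p degrees of freedom.
#'
#' @param betas n_subjects x V matrix (one network's beta maps, as from
#'   [stack_betas()]).
#' @param design a `glm_design`.
#' @return t-statistic map: 3D array if `betas` carries a `grid` attribute,
#'   else a numeric vector. Degrees of freedom in attribute `df`.
#' @export
fit_glm_voxelwise <- function(betas, design) {
    stopifnot(inherits(design, "glm_design"),
              nrow(betas) == nrow(design$matrix))
    tv <- make_t_fun(design$matrix, design$contrast)(betas)
    grid <- attr(betas, "grid")
    out <- if (!is.null(grid)) array(tv, grid) else tv
    attr(out, "df") <- nrow(betas) - ncol(design$matrix)
    out
}

#' TFCE parameters
#' @param E extent exponent.
#' @param H height exponent.
#' @param n_steps number of integration steps (>= 10).
#' @param connectivity voxel neighbourhood: 6, 18 or 26.
#' @return A validated `tfce_params` list.
#' @export
tfce_params <- function(E = 0.5, H = 2.0, n_steps = 100, connectivity = 26) {
    stopifnot(E > 0, H >= 0, n_steps >= 10, connectivity %in% c(6, 18, 26))
    structure(list(E = E, H = H, n_steps = as.integer(n_steps),
                   connectivity = as.integer(connectivity)),
              class = "tfce_params")
}

#' Threshold-free cluster enhancement
#'
#' `TFCE(v) = sum over h = dh, 2dh, ..., max of extent(v, h)^E * h^H * dh`
#' with `dh = max / n_steps`, where `extent(v, h)` is the size of the
#' connected component containing `v` after thresholding the map at `h`.
#' Only positive values are enhanced; apply to the negated map for the
#' opposite direction. An all-non-positive map returns zeros.
#'
#' @param stat 3D statistic map (numeric array).
#' @param params a [tfce_params()].
#' @return 3D non-negative array of TFCE scores.
#' @export
tfce_enhance <- function(stat, params = tfce_params()) {
    stopifnot(length(dim(stat)) == 3, all(is.finite(stat)))
    out <- tfce_cpp(as.numeric(stat), dim(stat), params$E, params$H,
                    params$n_steps, params$connectivity)
    array(out, dim(stat))
}

# Sample n_perm distinct non-identity row permutations, seeded.
sample_permutations <- function(n, n_perm, seed) {
    with_seed(seed, {
        seen <- new.env(hash = TRUE)
        assign(paste(seq_len(n), collapse = ","), TRUE, envir = seen)  # identity
        out <- vector("list", n_perm)
        got <- 0L
        while (got < n_perm) {
            p <- sample.int(n)
            key <- paste(p, collapse = ",")
            if (!exists(key, envir = seen, inherits = FALSE)) {
                assign(key, TRUE, envir = seen)
                got <- got + 1L
                out[[got]] <- p
            }
        }
        out
    })
}

#' Permutation inference with TFCE and max-statistic FWE correction
#'
#' The observed contrast t-map is TFCE-enhanced in both directions. Null
#' data are generated by Freedman-Lane permutation: the data are
#' residualised against the nuisance columns, the residual rows are
#' permuted, the nuisance fit is added back, and the full model is refit.
#' The null distribution per direction is the spatial maximum of the TFCE
#' map under each permutation, and
#' `p_fwe(v) = (1 + #\{null maxima >= observed(v)\}) / (1 + n_perm)`.
#' When the requested permutations exceed the number of distinct row
#' permutations, all `n!` permutations (identity included) are enumerated
#' and p-values become exact multiples of `1 / n!`.
#'
#' @param betas n_subjects x V matrix with a `grid` attribute.
#' @param design a `glm_design`.
#' @param params a [tfce_params()].
#' @param n_perm number of permutations (the identity is accounted for by
#'   the +1 in the p-value; sampled permutations are distinct and
#'   non-identity).
#' @param seed RNG seed for permutation sampling.
#' @return A `stat_result`: list with `t_map`, `tfce_pos`, `tfce_neg`,
#'   `p_fwe_pos`, `p_fwe_neg` (3D arrays), `null_max_pos`, `null_max_neg`,
#'   `n_perm` (permutations actually used), `exhaustive`, `df`.
#' @export
permutation_fwe <- function(betas, design, params = tfce_params(),
                            n_perm = 5000, seed = 1) {
    stopifnot(inherits(design, "glm_design"))
    grid <- attr(betas, "grid")
    if (is.null(grid)) stop("betas must carry a 'grid' attribute (see stack_betas)")
    X <- design$matrix
    n <- nrow(X)
    stopifnot(nrow(betas) == n)
    t_fun <- make_t_fun(X, design$contrast)
    Z <- X[, design$nuisance_columns, drop = FALSE]
    if (ncol(Z) > 0) {
        Hz <- Z %*% solve(crossprod(Z), t(Z))
        Yhat <- Hz %*% betas
        Yr <- betas - Yhat
    } else {
        Yhat <- matrix(0, n, ncol(betas))
        Yr <- betas
    }
    tfce_of <- function(tv) {
        arr <- array(tv, grid)
        list(pos = tfce_enhance(arr, params), neg = tfce_enhance(-arr, params))
    }
    t_obs <- t_fun(betas)
    obs <- tfce_of(t_obs)
    n_distinct <- if (n <= 10) factorial(n) else Inf
    exhaustive <- n_distinct <= n_perm
    perms <- if (exhaustive) all_permutations(n)
             else sample_permutations(n, n_perm, seed)
    null_pos <- null_neg <- numeric(length(perms))
    for (i in seq_along(perms)) {
        tf <- tfce_of(t_fun(Yr[perms[[i]], , drop = FALSE] + Yhat))
        null_pos[i] <- max(tf$pos)
        null_neg[i] <- max(tf$neg)
    }
    pval <- function(obs_map, null_max) {
        srt <- sort(null_max)
        # count of null maxima >= v, via #{null < v}
        cnt <- length(srt) - findInterval(as.vector(obs_map), srt,
                                          left.open = TRUE)
        p <- if (exhaustive) cnt / length(null_max)
             else (1 + cnt) / (1 + length(null_max))
        array(p, grid)
    }
    structure(list(t_map = array(t_obs, grid),
                   tfce_pos = obs$pos, tfce_neg = obs$neg,
                   p_fwe_pos = pval(obs$pos, null_pos),
                   p_fwe_neg = pval(obs$neg, null_neg),
                   null_max_pos = null_pos, null_max_neg = null_neg,
                   n_perm = length(perms), exhaustive = exhaustive,
                   df = n - ncol(X)),
              class = "stat_result")
}

#' Significance masks from a permutation result
#'
#' Voxels are significant when their FWE-corrected p-value is strictly below
#' `alpha` (0.025 per direction for two-tailed contrasts), or strictly below
#' `alpha / n_networks` with Bonferroni correction across networks.
#'
#' @param r a `stat_result`.
#' @param alpha per-direction significance level, in (0, 0.5].
#' @param n_networks number of networks tested (Bonferroni denominator).
#' @param bonferroni apply the across-network correction.
#' @return List with logical arrays `pos` and `neg` and the `cutoff` used.
#' @export
threshold_results <- function(r, alpha = 0.025, n_networks = 1,
                              bonferroni = FALSE) {
    stopifnot(inherits(r, "stat_result"), alpha > 0, alpha <= 0.5)
    cutoff <- if (bonferroni) alpha / n_networks else alpha
    list(pos = r$p_fwe_pos < cutoff, neg = r$p_fwe_neg < cutoff,
         cutoff = cutoff)
}

#' Weekly-bin group-average network maps
#'
#' Term-born subjects are split into half-open weekly bins of PMA at scan
#' (`[lo, hi)`); within each bin the `n_per_bin` subjects with the lowest
#' postnatal age (ties broken by subject id) are entered into a group-mean
#' GLM controlling for sex and motion, with permutation FWE inference
#' thresholded at `alpha` (0.05 for these qualitative maps).
#'
#' @param metas cohort covariate data frame (rows aligned with `betas`).
#' @param betas n_subjects x V matrix with a `grid` attribute.
#' @param bin_edges increasing numeric vector of bin edges in weeks.
#' @param n_per_bin subjects entered per bin.
#' @param params,n_perm,seed passed to [permutation_fwe()].
#' @param alpha FWE threshold for the per-bin masks.
#' @return Named list (one element per bin) of lists with `result`
#'   (`stat_result`), `mask` (positive-direction significance mask),
#'   `subjects` (ids entered).
#' @export
weekly_bin_maps <- function(metas, betas, bin_edges = seq(37.5, 42.5, by = 1),
                            n_per_bin = 20, params = tfce_params(),
                            n_perm = 5000, seed = 1, alpha = 0.05) {
    stopifnot(nrow(metas) == nrow(betas), length(bin_edges) >= 2)
    out <- list()
    for (i in seq_len(length(bin_edges) - 1)) {
        lo <- bin_edges[i]; hi <- bin_edges[i + 1]
        lab <- sprintf("[%g,%g)", lo, hi)
        idx <- which(metas$group == "term" &
                     metas$pma_scan >= lo & metas$pma_scan < hi)
        if (length(idx) < n_per_bin)
            stop("bin ", lab, " contains ", length(idx),
                 " term subjects, need ", n_per_bin)
        ord <- idx[order(metas$postnatal_days[idx], metas$subject_id[idx])]
        sel <- ord[seq_len(n_per_bin)]
        sub_b <- betas[sel, , drop = FALSE]
        attr(sub_b, "grid") <- attr(betas, "grid")
        design <- build_design(metas[sel, ], "group_mean")
        res <- permutation_fwe(sub_b, design, params, n_perm,
                               seed = derive_seed(seed, i))
        out[[lab]] <- list(result = res,
                           mask = threshold_results(res, alpha = alpha)$pos,
                           subjects = metas$subject_id[sel])
    }
    out
}
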