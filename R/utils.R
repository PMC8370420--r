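# Internal helpers shared across stages: seeded RNG scoping, seed derivation,
# logging, config files, run manifests, Gaussian smoothing.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the prior
#' RNG state so package functions do not perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(seed)
    code
}

#' Derive a stage- or subject-level seed from a master seed
#'
#' All randomness in the package flows from one master seed; per-stage and
#' per-subject seeds are derived deterministically so that stages are
#' individually reproducible. Results stay below 2^31.
#'
#' @param seed master integer seed.
#' @param offset non-negative integer offset (stage or subject index).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, offset = 0) {
    s <- (as.numeric(seed) %% 2147483629) * 48271 + as.numeric(offset) * 9973 + 1
    as.integer(s %% 2147483629)
}

#' Log a message to stderr with a timestamp
#' @param fmt sprintf-style format string.
#' @param ... values for `fmt`.
#' @return Invisibly, the formatted message.
#' @export
nr_log <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message(sprintf("[neorsn %s] %s", format(Sys.time(), "%H:%M:%S"), msg))
    invisible(msg)
}

#' Read / write a pipeline configuration file
#'
#' A single YAML file holds every tunable parameter of a run (synthetic-cohort
#' settings, QC fractions, ICA dimensionality, permutation counts, the master
#' seed). Stages read what they need from it.
#'
#' @param path file path.
#' @return `read_config`: a named list. `write_config`: `path`, invisibly.
#' @export
read_config <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config named list of settings.
#' @export
write_config <- function(config, path) {
    yaml::write_yaml(config, path)
    invisible(path)
}

#' Run manifest: record config, seeds and per-stage input/output hashes
#'
#' A manifest is an accumulating record of a pipeline run. Each stage appends
#' its name, the seed it used, and MD5 hashes of the files it read and wrote,
#' so a run can be audited and reproduced.
#'
#' @param config named list (as from [read_config()]).
#' @param seed master seed of the run.
#' @return A manifest object (named list).
#' @export
manifest_start <- function(config = list(), seed = NA_integer_) {
    list(created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
         seed = seed, config = config, stages = list())
}

#' @rdname manifest_start
#' @param manifest an existing manifest.
#' @param stage stage name.
#' @param inputs,outputs character vectors of file paths (hashed if they exist).
#' @export
manifest_add_stage <- function(manifest, stage, seed = NA_integer_,
                               inputs = character(), outputs = character()) {
    hash <- function(paths) {
        paths <- paths[file.exists(paths)]
        if (!length(paths)) return(list())
        as.list(tools::md5sum(paths))
    }
    manifest$stages[[stage]] <- list(seed = seed, inputs = hash(inputs),
                                     outputs = hash(outputs))
    manifest
}

#' @rdname manifest_start
#' @export
manifest_write <- function(manifest, path) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
    invisible(path)
}

# 1D Gaussian convolution matrix with edge renormalisation (kernel truncated
# at the volume boundary and re-normalised to sum 1).
gauss_conv_matrix <- function(n, sigma_vox) {
    if (sigma_vox <= 0) return(diag(n))
    r <- max(1L, as.integer(ceiling(3 * sigma_vox)))
    k <- dnorm(seq(-r, r), sd = sigma_vox)
    A <- matrix(0, n, n)
    for (i in seq_len(n)) {
        idx <- (i - r):(i + r)
        ok <- idx >= 1 & idx <= n
        w <- k[ok]
        A[i, idx[ok]] <- w / sum(w)
    }
    A
}

#' Gaussian smoothing of a 3D volume
#'
#' Separable Gaussian filter specified by its full width at half maximum in
#' millimetres; the kernel is truncated at 3 sigma and re-normalised at the
#' volume edges.
#'
#' @param vol 3D numeric array.
#' @param fwhm_mm kernel FWHM in mm (0 returns `vol` unchanged).
#' @param voxel_size mm triple giving the voxel dimensions.
#' @return Smoothed 3D array of the same dimension.
#' @export
smooth_gaussian <- function(vol, fwhm_mm, voxel_size = c(1, 1, 1)) {
    stopifnot(length(dim(vol)) == 3, fwhm_mm >= 0, length(voxel_size) == 3)
    if (fwhm_mm == 0) return(vol)
    sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / voxel_size
    d <- dim(vol)
    for (axis in 1:3) {
        A <- gauss_conv_matrix(d[axis], sigma_vox[axis])
        perm <- c(axis, setdiff(1:3, axis))
        a <- aperm(vol, perm)
        a <- array(A %*% matrix(a, d[axis]), dim(a))
        vol <- aperm(a, order(perm))
    }
    vol
}

# All permutations of 1..n as a list (n small; used for exhaustive inference).
all_permutations <- function(n) {
    if (n == 1) return(list(1L))
    sub <- all_permutations(n - 1L)
    out <- vector("list", n * length(sub))
    i <- 0L
    for (p in sub) {
        for (pos in 0:(n - 1L)) {
            i <- i + 1L
            out[[i]] <- append(p, n, after = pos)
        }
    }
    out
}

#' Match estimated component maps to reference maps
#'
#' Finds the component-to-reference assignment maximising the total absolute
#' spatial correlation (optimal assignment by enumeration for up to 8
#' components, greedy beyond), and reports the matched correlations.
#'
#' @param est matrix (voxels x K_est) or 4D array of estimated maps.
#' @param ref matrix (voxels x K_ref) or 4D array of reference maps;
#'   `K_est >= K_ref`.
#' @return List with `perm` (index into `est` columns for each reference
#'   column) and `cor` (absolute matched correlations, one per reference map).
#' @export
match_maps <- function(est, ref) {
    as_mat <- function(x) if (is.matrix(x)) x else
        matrix(x, prod(dim(x)[1:3]), dim(x)[4])
    est <- as_mat(est); ref <- as_mat(ref)
    K <- ncol(ref)
    stopifnot(ncol(est) >= K)
    C <- abs(cor(est, ref))          # K_est x K_ref
    if (ncol(est) == K && K <= 8) {
        best <- NULL; best_val <- -Inf
        for (p in all_permutations(K)) {
            v <- sum(C[cbind(p, seq_len(K))])
            if (v > best_val) { best_val <- v; best <- p }
        }
        perm <- unlist(best)
    } else {
        perm <- integer(K); taken <- rep(FALSE, ncol(est))
        for (j in order(apply(C, 2, max), decreasing = TRUE)) {
            i <- order(C[, j], decreasing = TRUE)
            i <- i[!taken[i]][1]
            perm[j] <- i; taken[i] <- TRUE
        }
    }
    list(perm = perm, cor = C[cbind(perm, seq_len(K))])
}
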