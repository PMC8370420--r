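# Synthetic multi-subject BOLD cohorts with known ground truth. The
# generator emulates the statistical structure the downstream stages assume:
# K spatially fixed, smooth, midline-symmetric network maps shared across
# subjects; per-subject band-limited (< 0.1 Hz) network time courses;
# covariate-linked network amplitudes (linear age-at-scan effect,
# multiplicative preterm attenuation, a region-specific sex effect);
# edge-localised broadband artifact components; iid Gaussian sensor noise;
# and additive whole-volume intensity spikes detectable via DVARS.

#' Configuration for a synthetic cohort
#'
#' Defaults reflect the acquisition the pipeline targets (2300 volumes at TR
#' 0.392 s) and study-condition effect sizes: a 30% multiplicative preterm
#' attenuation and a linear age slope on every network. Amplitudes are in
#' arbitrary BOLD units; the base network amplitude is 1.
#'
#' @param grid integer triple (X, Y, Z) of voxels.
#' @param T number of volumes.
#' @param tr repetition time, seconds.
#' @param K_signal number of true networks (>= 1).
#' @param K_artifact number of structured artifact components.
#' @param n_term,n_preterm subject counts per group.
#' @param base_amplitude per-network base amplitude (recycled to `K_signal`).
#' @param age_slope amplitude units per week of PMA at scan, centred at 40
#'   weeks (recycled to `K_signal`; may be 0).
#' @param preterm_attenuation fraction in \[0, 1) applied multiplicatively to
#'   every network amplitude of preterm subjects.
#' @param sex_effect list with `network` (index), `delta` (additive amplitude
#'   on the designated subregion for female subjects). The subregion is the
#'   right-of-midline half of that network's support.
#' @param spike_rate expected fraction of motion-spiked volumes, in \[0, 0.3).
#' @param spike_amplitude intensity jump added to spiked volumes; `NULL`
#'   sizes it automatically to dominate the DVARS outlier threshold.
#' @param artifact_amplitude amplitude of artifact components.
#' @param noise_sd sensor-noise standard deviation.
#' @param seed master seed for the cohort.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(grid = c(20, 20, 12), T = 2300, tr = 0.392,
                         K_signal = 4, K_artifact = 2,
                         n_term = 60, n_preterm = 40,
                         base_amplitude = 1, age_slope = 0.12,
                         preterm_attenuation = 0.30,
                         sex_effect = list(network = 1, delta = 0.2),
                         spike_rate = 0.05, spike_amplitude = NULL,
                         artifact_amplitude = 1, noise_sd = 1, seed = 1) {
    stopifnot(length(grid) == 3, all(grid >= 1), T >= 2, tr > 0,
              K_signal >= 1, K_artifact >= 0, n_term >= 1, n_preterm >= 0,
              preterm_attenuation >= 0, preterm_attenuation < 1,
              spike_rate >= 0, spike_rate < 0.3, noise_sd >= 0)
    cfg <- list(grid = as.integer(grid), T = as.integer(T), tr = tr,
                K_signal = as.integer(K_signal),
                K_artifact = as.integer(K_artifact),
                n_term = as.integer(n_term), n_preterm = as.integer(n_preterm),
                base_amplitude = rep_len(base_amplitude, K_signal),
                age_slope = rep_len(age_slope, K_signal),
                preterm_attenuation = preterm_attenuation,
                sex_effect = sex_effect, spike_rate = spike_rate,
                spike_amplitude = spike_amplitude,
                artifact_amplitude = artifact_amplitude,
                noise_sd = noise_sd, seed = as.integer(seed))
    class(cfg) <- "synth_config"
    cfg
}

# Smooth mirrored-pair Gaussian blob centred at (cx, cy, cz) and its
# reflection across the x midline; max-normalised to 1.
blob_pair <- function(grid, cx, cy, cz, sigma) {
    x <- seq_len(grid[1]); y <- seq_len(grid[2]); z <- seq_len(grid[3])
    mid <- (grid[1] + 1) / 2
    cx2 <- 2 * mid - cx
    g <- function(c0) outer(outer(exp(-(x - c0[1])^2 / (2 * sigma^2)),
                                  exp(-(y - c0[2])^2 / (2 * sigma^2))),
                            exp(-(z - c0[3])^2 / (2 * sigma^2)))
    m <- g(c(cx, cy, cz)) + g(c(cx2, cy, cz))
    m / max(m)
}

#' Generate ground-truth network maps
#'
#' Places `K_signal` smooth, non-negative blob pairs mirrored across the x
#' midline (emulating the symmetric, modular organisation of neonatal
#' resting-state networks), max-normalised to 1, and rejects-and-resamples
#' whole sets until all pairwise spatial correlations are below 0.2.
#'
#' @param cfg a [synth_config()].
#' @return List of `K_signal` 3D arrays.
#' @export
make_ground_truth_maps <- function(cfg) {
    grid <- cfg$grid
    K <- cfg$K_signal
    sigma <- max(1.2, min(grid) / 7)
    # per-axis placement margins, clamped so small grids stay feasible
    mx <- min(ceiling(sigma), floor(0.4 * grid[1]))
    my <- min(ceiling(sigma), floor((grid[2] - 1) / 2))
    mz <- min(ceiling(sigma), floor((grid[3] - 1) / 2))
    if (grid[1] < 4 || grid[1] * 0.55 >= grid[1] - mx + 1e-9 ||
        1 + my > grid[2] - my || 1 + mz > grid[3] - mz)
        stop("grid too small to place ", K, " network blobs")
    with_seed(derive_seed(cfg$seed, 1e6), {
        maps <- vector("list", K)
        M <- matrix(numeric(0), prod(grid), 0)
        for (k in seq_len(K)) {
            placed <- FALSE
            for (attempt in seq_len(500)) {
                cx <- runif(1, grid[1] * 0.55, grid[1] - mx)
                cy <- runif(1, 1 + my, grid[2] - my)
                cz <- runif(1, 1 + mz, grid[3] - mz)
                m <- blob_pair(grid, cx, cy, cz, sigma)
                if (k == 1 || max(abs(cor(as.vector(m), M))) < 0.2) {
                    maps[[k]] <- m
                    M <- cbind(M, as.vector(m))
                    placed <- TRUE
                    break
                }
            }
            if (!placed)
                stop("grid too small to place ", K,
                     " networks with pairwise correlation < 0.2")
        }
        maps
    })
}

#' Generate edge-localised artifact maps
#'
#' Rectangular rings hugging the x-y boundary (alternating 1- and 2-voxel
#' widths, one z-slab per component), max-normalised. Paired with broadband
#' time courses these give component labelling genuine negatives.
#'
#' @param cfg a [synth_config()].
#' @return List of `K_artifact` 3D arrays (empty list when `K_artifact = 0`).
#' @export
make_artifact_maps <- function(cfg) {
    grid <- cfg$grid
    if (cfg$K_artifact == 0) return(list())
    lapply(seq_len(cfg$K_artifact), function(j) {
        m <- array(0, grid)
        zi <- unique(pmin(grid[3], pmax(1, round(seq(1, grid[3],
                     length.out = cfg$K_artifact + 2))[j + (0:2)])))
        edge <- outer(seq_len(grid[1]), seq_len(grid[2]), function(x, y) {
            d <- pmin(x - 1, grid[1] - x, y - 1, grid[2] - y)
            as.numeric(d <= (j - 1) %% 2)   # alternate 1- and 2-voxel rings
        })
        for (z in zi) m[, , z] <- edge
        m / max(m)
    })
}

# Band-limited (< cutoff Hz) unit-variance, zero-mean time course: white
# noise restricted to low-frequency Fourier bins. At very short T at least
# two non-DC bins are kept so that the course is non-degenerate.
lowfreq_timecourse <- function(T, tr, cutoff = 0.1) {
    w <- rnorm(T)
    f <- stats::fft(w)
    freq <- (seq_len(T) - 1) / (T * tr)
    freq <- pmin(freq, 1 / tr - freq)    # two-sided frequency axis
    kmax <- max(2, floor(cutoff * T * tr))
    keep <- freq <= kmax / (T * tr)
    f[!keep] <- 0
    s <- Re(stats::fft(f, inverse = TRUE)) / T
    s <- s - mean(s)
    s / sd(s)
}

# Deterministic amplitude law: a_k(meta) = (base_k + slope_k * (pma - 40)),
# multiplied by (1 - attenuation) iff preterm.
true_amplitudes <- function(cfg, meta) {
    a <- cfg$base_amplitude + cfg$age_slope * (meta$pma_scan - 40)
    if (meta$group == "preterm") a <- a * (1 - cfg$preterm_attenuation)
    a
}

# Right-of-midline half of a network's support; the subregion carrying the
# sex effect.
sex_subregion <- function(map, grid) {
    half <- array(rep(seq_len(grid[1]) > ceiling(grid[1] / 2),
                      times = grid[2] * grid[3]), grid)
    (map > 0.3) & half
}

#' Simulate one subject's 4D BOLD run
#'
#' Data are the closed-form mixture
#' `sum_k a_k(meta) map_k s_k(t) + sex-delta term + sum_j artifact_j u_j(t) +
#' noise`, with whole-volume intensity jumps added on spiked volumes. The
#' emitted truth record contains the amplitudes, time courses and spiked
#' volume indices actually used.
#'
#' @param cfg a [synth_config()].
#' @param meta single-row data frame of subject covariates.
#' @param true_maps list from [make_ground_truth_maps()].
#' @param artifact_maps list from the generator (may be empty).
#' @param seed integer seed for this subject.
#' @return List with elements `bold` ([bold4d()]) and `truth` (list:
#'   `amplitudes`, `spiked_volumes`, `timecourses` (T x K_signal),
#'   `artifact_timecourses`).
#' @export
simulate_subject <- function(cfg, meta, true_maps,
                             artifact_maps = list(), seed = cfg$seed) {
    grid <- cfg$grid; T <- cfg$T
    V <- prod(grid)
    a <- true_amplitudes(cfg, meta)
    with_seed(seed, {
        S <- vapply(seq_len(cfg$K_signal),
                    function(k) lowfreq_timecourse(T, cfg$tr), numeric(T))
        M <- vapply(true_maps, as.vector, numeric(V))
        dat <- M %*% (t(S) * a)                       # V x T signal mixture
        se <- cfg$sex_effect
        if (!is.null(se) && se$delta != 0 && meta$sex == "female") {
            sub <- sex_subregion(true_maps[[se$network]], grid)
            dat <- dat + se$delta *
                as.vector(true_maps[[se$network]] * sub) %*% t(S[, se$network])
        }
        nart <- length(artifact_maps)
        U <- NULL
        if (nart > 0) {
            U <- matrix(rnorm(T * nart), T, nart)     # broadband artifacts
            Am <- vapply(artifact_maps, as.vector, numeric(V))
            dat <- dat + cfg$artifact_amplitude * (Am %*% t(U))
        }
        if (cfg$noise_sd > 0)
            dat <- dat + rnorm(V * T, sd = cfg$noise_sd)
        spiked <- integer(0)
        if (cfg$spike_rate > 0) {
            spiked <- which(runif(T) < cfg$spike_rate)
            amp <- cfg$spike_amplitude
            # auto size: a clear multiple of the DVARS noise floor
            # (~ sqrt(2) * noise_sd), the quantity that sets detectability
            if (is.null(amp))
                amp <- 4 * cfg$noise_sd + 0.5 * max(abs(a))
            if (length(spiked)) dat[, spiked] <- dat[, spiked] + amp
        }
        b <- bold4d(array(dat, c(grid, T)), tr = cfg$tr,
                    subject_id = meta$subject_id)
        list(bold = b,
             truth = list(subject_id = meta$subject_id, amplitudes = a,
                          spiked_volumes = spiked, timecourses = S,
                          artifact_timecourses = U))
    })
}

# Draw the cohort covariate table. PMA at scan uniform on [37, 43.5] weeks;
# GA at birth uniform on [37, min(42.3, pma)] for term (scan cannot precede
# birth) and [24.3, 36.9] for preterm.
draw_metas <- function(cfg) {
    n <- cfg$n_term + cfg$n_preterm
    group <- rep(c("term", "preterm"), c(cfg$n_term, cfg$n_preterm))
    pma <- runif(n, 37, 43.5)
    ga <- ifelse(group == "term",
                 runif(n, 37, pmin(42.3, pma)),
                 runif(n, 24.3, 36.9))
    data.frame(subject_id = sprintf("sub-%03d", seq_len(n)),
               ga_birth = round(ga, 2), pma_scan = round(pma, 2),
               sex = sample(c("female", "male"), n, replace = TRUE),
               group = group,
               postnatal_days = round((pma - ga) * 7),
               motion_outliers = NA_real_,
               stringsAsFactors = FALSE)
}

#' Simulate a full cohort
#'
#' Draws covariates, generates ground-truth network and artifact maps, and
#' simulates every subject with a seed derived from the master seed. With
#' `dir` set, subject volumes are written as NIfTI, covariates as TSV, true
#' maps as a 4D NIfTI and the truth record as JSON; otherwise everything is
#' returned in memory.
#'
#' @param cfg a [synth_config()].
#' @param dir optional output directory (created if needed).
#' @return A `cohort_truth` list: `metas`, `true_maps`, `artifact_maps`,
#'   `true_amplitudes` (n x K_signal), `spiked_volumes`, `timecourses`,
#'   `subjects` (list of [bold4d()], or file paths when `dir` is given),
#'   `config`, and `paths` when written to disk.
#' @export
simulate_cohort <- function(cfg, dir = NULL) {
    metas <- with_seed(cfg$seed, draw_metas(cfg))
    maps <- make_ground_truth_maps(cfg)
    arts <- make_artifact_maps(cfg)
    n <- nrow(metas)
    subjects <- vector("list", n)
    amps <- matrix(NA_real_, n, cfg$K_signal,
                   dimnames = list(metas$subject_id, NULL))
    spiked <- vector("list", n)
    tcs <- vector("list", n)
    names(spiked) <- names(tcs) <- metas$subject_id
    write_out <- !is.null(dir)
    if (write_out) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
        sim <- simulate_subject(cfg, metas[i, ], maps, arts,
                                seed = derive_seed(cfg$seed, i))
        amps[i, ] <- sim$truth$amplitudes
        spiked[[i]] <- sim$truth$spiked_volumes
        tcs[[i]] <- sim$truth$timecourses
        if (write_out) {
            p <- file.path(dir, paste0(metas$subject_id[i], "_bold.nii.gz"))
            write_bold(sim$bold, p)
            subjects[[i]] <- p
        } else subjects[[i]] <- sim$bold
    }
    out <- list(metas = metas, true_maps = maps, artifact_maps = arts,
                true_amplitudes = amps, spiked_volumes = spiked,
                timecourses = tcs, subjects = subjects, config = cfg)
    class(out) <- "cohort_truth"
    if (write_out) {
        cov_path <- file.path(dir, "covariates.tsv")
        write_covariates(metas, cov_path)
        maps_path <- file.path(dir, "true_maps.nii.gz")
        write_volume(array(unlist(maps), c(cfg$grid, cfg$K_signal)), maps_path)
        truth_path <- file.path(dir, "truth.json")
        jsonlite::write_json(
            list(config = unclass(cfg), metas = metas,
                 true_amplitudes = amps, spiked_volumes = spiked),
            truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
            null = "null")
        out$paths <- list(dir = dir, covariates = cov_path,
                          true_maps = maps_path, truth = truth_path,
                          subjects = unlist(subjects))
    }
    out
}
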