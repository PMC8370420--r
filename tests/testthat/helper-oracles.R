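# Independent oracles and fixture builders. Everything here is written
# against the definitions directly (sorting, enumeration, flood fill,
# normal equations) and never calls the package code paths it checks.

# Disjoint plateau (indicator-ball) sources on a lattice: the canonical
# super-Gaussian spatial sources for ICA recovery checks. Disjointness makes
# recovery exact even after per-voxel variance normalisation.
make_plateau_sources <- function(grid, k, radius = 2) {
    ctrs <- expand.grid(x = seq(radius + 1, grid[1] - radius, by = 2 * radius + 1),
                        y = seq(radius + 1, grid[2] - radius, by = 2 * radius + 1),
                        z = seq(radius + 1, grid[3] - radius, by = 2 * radius + 1))
    stopifnot(nrow(ctrs) >= k)
    lapply(seq_len(k), function(i) {
        m <- array(0, grid)
        c0 <- as.numeric(ctrs[i, ])
        for (dx in -radius:radius) for (dy in -radius:radius)
            for (dz in -radius:radius)
                if (dx^2 + dy^2 + dz^2 <= radius^2)
                    m[c0[1] + dx, c0[2] + dy, c0[3] + dz] <- 1
        m
    })
}

# Noise-free multi-subject mixtures of given spatial sources with random
# Gaussian time courses (one independent set per subject).
make_mixture_subjects <- function(sources, n_subjects, T, seed = 1) {
    grid <- dim(sources[[1]])
    k <- length(sources)
    M <- vapply(sources, as.vector, numeric(prod(grid)))
    withr::with_seed(seed, lapply(seq_len(n_subjects), function(s) {
        S <- matrix(rnorm(T * k), T, k)
        neorsn::bold4d(array(M %*% t(S), c(grid, T)),
                       subject_id = sprintf("mix-%02d", s))
    }))
}

# Quartile oracle: sorted-data linear interpolation (type 7), written out.
quartile_oracle <- function(x, p) {
    s <- sort(x)
    n <- length(s)
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Exhaustive window-selection oracle: try every start position.
window_oracle <- function(flags, window_len) {
    T <- length(flags)
    counts <- vapply(seq_len(T - window_len + 1), function(s)
        sum(flags[s:(s + window_len - 1)]), numeric(1))
    best <- which(counts == min(counts))
    list(start = best[1], outlier_count = min(counts), all_optimal = best)
}

# Per-threshold connected-component TFCE oracle: explicit flood fill at
# every integration step.
neighbour_offsets_oracle <- function(connectivity) {
    max_l1 <- switch(as.character(connectivity), "6" = 1, "18" = 2, "26" = 3)
    off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    l1 <- abs(off$dx) + abs(off$dy) + abs(off$dz)
    off[l1 > 0 & l1 <= max_l1, ]
}

tfce_oracle <- function(stat, E = 0.5, H = 2, n_steps = 100,
                        connectivity = 26) {
    d <- dim(stat)
    hmax <- max(stat)
    out <- array(0, d)
    if (hmax <= 0) return(out)
    dh <- hmax / n_steps
    off <- neighbour_offsets_oracle(connectivity)
    # precompute neighbour index lists once
    V <- prod(d)
    coords <- arrayInd(seq_len(V), d)
    nbrs <- lapply(seq_len(V), function(i) {
        xx <- coords[i, 1] + off$dx; yy <- coords[i, 2] + off$dy
        zz <- coords[i, 3] + off$dz
        ok <- xx >= 1 & xx <= d[1] & yy >= 1 & yy <= d[2] & zz >= 1 & zz <= d[3]
        (zz[ok] - 1) * d[1] * d[2] + (yy[ok] - 1) * d[1] + xx[ok]
    })
    sv <- as.vector(stat)
    for (step in seq_len(n_steps)) {
        h <- if (step == n_steps) hmax else step * dh
        in_mask <- sv >= h
        lab <- integer(V)
        cur <- 0L
        for (i in seq_len(V)) {
            if (!in_mask[i] || lab[i] != 0L) next
            cur <- cur + 1L
            queue <- i
            lab[i] <- cur
            while (length(queue)) {
                v <- queue[[1]]
                queue <- queue[-1]
                nb <- nbrs[[v]]
                nb <- nb[in_mask[nb] & lab[nb] == 0L]
                lab[nb] <- cur
                queue <- c(queue, nb)
            }
        }
        if (cur == 0L) next
        sizes <- tabulate(lab, cur)
        add <- numeric(V)
        add[in_mask] <- sizes[lab[in_mask]]^E * h^H * dh
        out <- out + array(add, d)
    }
    out
}

# Partial Spearman oracle: explicit ranks, explicit residualisation via
# solve() on the normal equations, explicit Pearson correlation.
partial_spearman_oracle <- function(x, y, covariates = NULL) {
    rx <- rank(x); ry <- rank(y)
    n <- length(x)
    if (!is.null(covariates)) {
        RC <- apply(as.matrix(covariates), 2, rank)
        Z <- cbind(1, RC)
        resid <- function(v) v - Z %*% solve(t(Z) %*% Z, t(Z) %*% v)
        rx <- resid(rx); ry <- resid(ry)
        c_n <- ncol(RC)
    } else {
        rx <- rx - mean(rx); ry <- ry - mean(ry)
        c_n <- 0
    }
    rho <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
    df <- n - c_n - 2
    tt <- rho * sqrt(df / (1 - rho^2))
    list(rho = rho, p = 2 * stats::pt(-abs(tt), df))
}

# Winner-takes-all oracle: per-voxel loop with explicit argmax + threshold.
wta_oracle <- function(smoothed_list, z_thr) {
    grid <- dim(smoothed_list[[1]])
    out <- array(0L, grid)
    for (i in seq_len(prod(grid))) {
        vals <- vapply(smoothed_list, function(m) m[i], numeric(1))
        ok <- which(vals > z_thr)
        if (length(ok))
            out[i] <- ok[which.max(vals[ok])]
    }
    out
}

# Tiny covariate table for design/metric tests.
make_metas <- function(n, groups = "term", seed = 1) {
    withr::with_seed(seed, {
        grp <- rep_len(groups, n)
        pma <- round(runif(n, 37.2, 43.4), 2)
        ga <- ifelse(grp == "term", pmin(pma, round(runif(n, 37, 42.3), 2)),
                     round(runif(n, 24.3, 36.9), 2))
        data.frame(subject_id = sprintf("s%03d", seq_len(n)),
                   ga_birth = ga, pma_scan = pma,
                   sex = sample(rep_len(c("female", "male"), n)), group = grp,
                   postnatal_days = round((pma - ga) * 7),
                   motion_outliers = rpois(n, 40),
                   stringsAsFactors = FALSE)
    })
}
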