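# Core network strength and its inferential analyses. Core network strength
# is the mean dual-regression beta within the group network template
# thresholded at Z > 3: a single per-subject, per-network summary of
# within-network functional connectivity.

#' Core network strength for one subject and network
#'
#' The subject's stage-2 beta map for a network, masked by the corresponding
#' group template thresholded at `Z > z_thr` (strict), averaged over the
#' mask. Linear in the beta map.
#'
#' @param dr a `subject_dr` from [dual_regress()].
#' @param g the labelled `group_map_set`.
#' @param network component index (must be labelled signal).
#' @param z_thr template threshold in Z units.
#' @return A one-row data frame: `subject_id`, `network`, `strength`.
#' @export
core_network_strength <- function(dr, g, network, z_thr = 3.0) {
    stopifnot(inherits(dr, "subject_dr"), inherits(g, "group_map_set"))
    if (g$labels[network] != "signal")
        stop("component ", g$names[network], " is not labelled signal")
    mask <- g$maps[, , , network] > z_thr
    if (!any(mask))
        stop("empty core mask for ", g$names[network], " at Z > ", z_thr)
    data.frame(subject_id = dr$subject_id, network = g$names[network],
               strength = mean(dr$beta_maps[, , , network][mask]),
               stringsAsFactors = FALSE)
}

#' Core-strength table for a cohort
#' @param drs list of `subject_dr` objects.
#' @param g the labelled `group_map_set`.
#' @param z_thr template threshold in Z units.
#' @return Long data frame of [core_network_strength()] rows, all subjects
#'   by all signal networks.
#' @export
strength_table <- function(drs, g, z_thr = 3.0) {
    sig <- signal_components(g)
    if (!length(sig)) stop("no components labelled signal")
    do.call(rbind, lapply(drs, function(dr)
        do.call(rbind, lapply(sig, function(k)
            core_network_strength(dr, g, k, z_thr)))))
}

#' Partial Spearman correlation
#'
#' Rank-transforms `x`, `y` and each covariate (average ranks for ties),
#' residualises the ranked `x` and `y` on the ranked covariates plus an
#' intercept by OLS, and correlates the residuals. The p-value uses the
#' t-approximation with `n - ncol(covariates) - 2` degrees of freedom. With
#' no covariates this is ordinary Spearman correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric matrix or data frame (n x c).
#' @return List with `rho`, `p`, `n`, `df`, `covariates` (names).
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
    n <- length(x)
    stopifnot(length(y) == n)
    C <- if (is.null(covariates)) matrix(numeric(0), n, 0)
         else as.matrix(covariates)
    stopifnot(nrow(C) == n)
    nc <- ncol(C)
    if (n <= nc + 2) stop("need n > number of covariates + 2")
    if (var(x) == 0 || var(y) == 0) stop("constant input vector")
    rx <- rank(x); ry <- rank(y)
    if (nc > 0) {
        RC <- apply(C, 2, rank)
        fit <- lm.fit(cbind(1, RC), cbind(rx, ry))
        rx <- fit$residuals[, 1]; ry <- fit$residuals[, 2]
    } else {
        rx <- rx - mean(rx); ry <- ry - mean(ry)
    }
    # fully-explained input (residuals ~ 0 on the rank scale, which grows
    # like n^3): no remaining association
    tol2 <- (1e-10 * n^1.5)^2
    rho <- if (sum(rx^2) < tol2 || sum(ry^2) < tol2) 0
           else sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
    df <- n - nc - 2
    tstat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
    list(rho = rho, p = 2 * pt(-abs(tstat), df), n = n, df = df,
         covariates = colnames(C))
}

#' Association of core network strength with age at scan
#'
#' Per network, the partial Spearman correlation between strength and PMA at
#' scan in term-born subjects, controlling for sex and motion.
#'
#' @param records strength table from [strength_table()].
#' @param metas cohort covariate data frame.
#' @return Data frame: network, rho, p, n.
#' @export
strength_age_association <- function(records, metas) {
    term <- metas[metas$group == "term", ]
    if (!all(term$subject_id %in% records$subject_id))
        stop("strength records missing for subject ",
             setdiff(term$subject_id, records$subject_id)[1])
    do.call(rbind, lapply(split(records, records$network), function(r) {
        r <- r[match(term$subject_id, r$subject_id), ]
        res <- partial_spearman(r$strength, term$pma_scan,
                                cbind(sex = as.numeric(term$sex == "female"),
                                      motion = term$motion_outliers))
        data.frame(network = r$network[1], rho = res$rho, p = res$p,
                   n = res$n, stringsAsFactors = FALSE)
    }))
}

#' Term-versus-preterm GLM on core network strength
#'
#' Per network, OLS of strength on group (preterm = 1), PMA at scan, sex and
#' motion. Also emits covariate-adjusted strengths (residuals from the
#' nuisance-only fit, plus the grand mean) for boxplot display.
#'
#' @param records strength table from [strength_table()].
#' @param metas cohort covariate data frame (both groups present).
#' @return List with `tests` (data frame: network, group coefficient, t,
#'   two-sided p, df) and `adjusted` (data frame: subject_id, network, group,
#'   adjusted strength).
#' @export
strength_group_glm <- function(records, metas) {
    if (length(unique(metas$group)) < 2)
        stop("both term and preterm subjects are required")
    tests <- list(); adjusted <- list()
    for (nw in unique(records$network)) {
        r <- records[records$network == nw, ]
        m <- metas[match(r$subject_id, metas$subject_id), ]
        if (anyNA(m$subject_id))
            stop("no covariate row for subject ",
                 r$subject_id[which(is.na(m$subject_id))[1]])
        dat <- data.frame(strength = r$strength,
                          group = as.numeric(m$group == "preterm"),
                          pma = m$pma_scan,
                          sex = as.numeric(m$sex == "female"),
                          motion = m$motion_outliers)
        fit <- lm(strength ~ group + pma + sex + motion, data = dat)
        sm <- summary(fit)$coefficients
        tests[[nw]] <- data.frame(network = nw,
                                  coefficient = sm["group", 1],
                                  t = sm["group", 3], p = sm["group", 4],
                                  df = fit$df.residual,
                                  stringsAsFactors = FALSE)
        nuis <- lm(strength ~ pma + sex + motion, data = dat)
        adjusted[[nw]] <- data.frame(subject_id = r$subject_id, network = nw,
                                     group = m$group,
                                     adjusted = stats::residuals(nuis) +
                                         mean(dat$strength),
                                     stringsAsFactors = FALSE)
    }
    list(tests = do.call(rbind, tests), adjusted = do.call(rbind, adjusted))
}

#' Percent reduction of core network strength in the preterm group
#'
#' Per network, `100 * (mean_term - mean_preterm) / mean_term` on raw
#' (covariate-unadjusted) strengths, with an unpaired two-sample t-test. A
#' non-positive term-group mean is reported with a warning flag rather than
#' an error.
#'
#' @param records strength table from [strength_table()].
#' @param metas cohort covariate data frame.
#' @return Data frame: network, mean_term, mean_preterm, percent_reduction,
#'   t, p, warning flag.
#' @export
percent_reduction <- function(records, metas) {
    grp <- metas$group[match(records$subject_id, metas$subject_id)]
    if (anyNA(grp))
        stop("no covariate row for subject ",
             records$subject_id[which(is.na(grp))[1]])
    do.call(rbind, lapply(split(seq_len(nrow(records)), records$network),
                          function(idx) {
        s <- records$strength[idx]; g <- grp[idx]
        mt <- mean(s[g == "term"]); mp <- mean(s[g == "preterm"])
        tt <- tryCatch(t.test(s[g == "term"], s[g == "preterm"],
                              var.equal = FALSE),
                       error = function(e)
                           list(statistic = NA_real_, p.value = NA_real_))
        warn <- mt <= 0
        if (warn) warning("non-positive term-group mean for network ",
                          records$network[idx[1]])
        data.frame(network = records$network[idx[1]], mean_term = mt,
                   mean_preterm = mp,
                   percent_reduction = 100 * (mt - mp) / mt,
                   t = unname(tt$statistic), p = tt$p.value,
                   warning = warn, stringsAsFactors = FALSE)
    }))
}
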