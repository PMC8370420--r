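# Motion quality control. DVARS (root-mean-square intensity difference
# between successive volumes) indexes per-volume motion; volumes above
# Q3 + 1.5*IQR of the subject's own DVARS distribution are motion outliers.
# The continuous window of ~70% of the acquisition with fewest outliers is
# retained (1600 of 2300 volumes at the target acquisition), and subjects
# with more than 10% outliers inside the window are excluded.

# Fraction of the acquisition retained by the default crop: 1600/2300.
WINDOW_FRAC <- 1600 / 2300

#' Compute the DVARS series of a 4D run
#'
#' `values[t] = sqrt(mean over in-mask voxels of (data[,t] - data[,t-1])^2)`
#' for `t >= 2`; the first volume has no predecessor and its DVARS is 0 by
#' convention.
#'
#' @param b a [bold4d()].
#' @param mask optional 3D logical array restricting the voxel set.
#' @return A `dvars_series`: list with `values` (length T, `values[1] = 0`)
#'   and `mask_used`.
#' @export
compute_dvars <- function(b, mask = NULL) {
    stopifnot(inherits(b, "bold4d"))
    d <- dim(b$data)
    m <- matrix(b$data, prod(d[1:3]), d[4])
    used <- "all voxels"
    if (!is.null(mask)) {
        stopifnot(identical(dim(mask), d[1:3]))
        if (!any(mask)) stop("empty mask")
        m <- m[as.vector(mask), , drop = FALSE]
        used <- mask
    }
    diffs <- m[, -1, drop = FALSE] - m[, -d[4], drop = FALSE]
    v <- c(0, sqrt(colMeans(diffs^2)))
    structure(list(values = v, mask_used = used), class = "dvars_series")
}

#' Flag motion-outlier volumes
#'
#' The threshold is Q3 + 1.5 * IQR of the DVARS values excluding the first
#' volume (whose DVARS is undefined); quartiles use the common
#' linear-interpolation estimator (type 7). Volumes strictly above the
#' threshold are flagged; the first volume is never flagged. A constant
#' series yields zero outliers.
#'
#' @param d a `dvars_series` from [compute_dvars()].
#' @return An `outlier_mask`: list with `flags` (length-T logical,
#'   `flags[1] = FALSE`) and `threshold`.
#' @export
flag_outliers <- function(d) {
    stopifnot(inherits(d, "dvars_series"))
    v <- d$values
    if (length(v) < 5) stop("need at least 5 volumes for quartiles")
    q <- quantile(v[-1], c(0.25, 0.75), names = FALSE, type = 7)
    thr <- q[2] + 1.5 * (q[2] - q[1])
    flags <- v > thr
    flags[1] <- FALSE
    structure(list(flags = flags, threshold = thr), class = "outlier_mask")
}

#' Select the continuous low-motion window
#'
#' Finds the contiguous window of exactly `window_len` volumes with the
#' minimum in-window outlier count; ties are broken by the smallest start
#' index. The exclusion rule marks the subject excluded when the in-window
#' count strictly exceeds `floor(exclude_frac * window_len)` (so a count
#' equal to the 10% boundary is retained).
#'
#' @param o an `outlier_mask` from [flag_outliers()].
#' @param window_len window length in volumes; defaults to
#'   `round(1600/2300 * T)`, which is exactly 1600 when T = 2300.
#' @param exclude_frac exclusion boundary as a fraction of the window.
#' @return A `crop_result`: list with `start` (1-based index of the first
#'   retained volume), `length`, `outlier_count`, `threshold_count` and
#'   `excluded`.
#' @export
select_window <- function(o, window_len = NULL, exclude_frac = 0.10) {
    stopifnot(inherits(o, "outlier_mask"))
    T <- length(o$flags)
    if (is.null(window_len)) window_len <- round(WINDOW_FRAC * T)
    window_len <- as.integer(window_len)
    if (window_len > T) stop("window length ", window_len, " exceeds T = ", T)
    cs <- cumsum(c(0L, as.integer(o$flags)))
    counts <- cs[(window_len + 1):(T + 1)] - cs[1:(T - window_len + 1)]
    start <- which.min(counts)   # which.min takes the first minimum: tie-break
    cnt <- counts[start]
    limit <- floor(exclude_frac * window_len)
    structure(list(start = as.integer(start), length = window_len,
                   outlier_count = as.integer(cnt),
                   threshold_count = as.integer(limit),
                   excluded = cnt > limit),
              class = "crop_result")
}

#' Apply the crop / exclusion decision to a subject
#'
#' Retained subjects are cropped to the selected window and their in-window
#' outlier count is written into `meta$motion_outliers` (it enters every
#' downstream regression as a covariate). Excluded subjects yield no cropped
#' data and are dropped from all downstream stages.
#'
#' @param b the subject's [bold4d()].
#' @param crop a `crop_result` derived from `b`.
#' @param meta single-row covariate data frame for the subject.
#' @return A `qc_result`: list with `bold` (cropped [bold4d()], or `NULL` if
#'   excluded), `meta` (with `motion_outliers` filled), `crop`, `excluded`.
#' @export
apply_qc <- function(b, crop, meta) {
    stopifnot(inherits(b, "bold4d"), inherits(crop, "crop_result"))
    if (dim(b$data)[4] < crop$start + crop$length - 1)
        stop("crop window exceeds the run length; was it derived from this subject?")
    meta$motion_outliers <- crop$outlier_count
    cropped <- NULL
    if (!crop$excluded) {
        idx <- crop$start:(crop$start + crop$length - 1)
        cropped <- bold4d(b$data[, , , idx, drop = FALSE],
                          voxel_size = b$voxel_size, tr = b$tr,
                          subject_id = b$subject_id)
    }
    structure(list(bold = cropped, meta = meta, crop = crop,
                   excluded = crop$excluded), class = "qc_result")
}

#' Run the full motion-QC chain for one subject
#'
#' DVARS, outlier flagging, window selection and cropping in one call.
#'
#' @inheritParams compute_dvars
#' @inheritParams select_window
#' @param meta single-row covariate data frame.
#' @param window_frac fraction of the run retained (default 1600/2300).
#' @return A `qc_result` (see [apply_qc()]) with the `dvars_series` and
#'   `outlier_mask` attached as `dvars` and `outliers`.
#' @export
run_subject_qc <- function(b, meta, mask = NULL, window_frac = WINDOW_FRAC,
                           exclude_frac = 0.10) {
    d <- compute_dvars(b, mask)
    o <- flag_outliers(d)
    cr <- select_window(o, window_len = round(window_frac * length(o$flags)),
                        exclude_frac = exclude_frac)
    res <- apply_qc(b, cr, meta)
    res$dvars <- d
    res$outliers <- o
    res
}

#' Summarise QC across a cohort
#' @param qc_results list of `qc_result` objects.
#' @return Data frame with one row per subject: DVARS threshold, window
#'   start, outlier count, exclusion flag.
#' @export
qc_report <- function(qc_results) {
    do.call(rbind, lapply(qc_results, function(r) {
        data.frame(subject_id = r$meta$subject_id,
                   threshold = if (!is.null(r$outliers)) r$outliers$threshold else NA_real_,
                   start = r$crop$start, length = r$crop$length,
                   outlier_count = r$crop$outlier_count,
                   excluded = r$excluded, stringsAsFactors = FALSE)
    }))
}
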