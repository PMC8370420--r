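# Volume and covariate I/O. All cross-subject operations in the package
# assume volumes already share a voxel grid (data registered to a common
# template upstream); affines are carried but not acted on.

#' Construct a 4D BOLD object
#'
#' A `bold4d` couples a subject's 4D space-time grid with its voxel sizes,
#' repetition time and identifier. The time axis must have at least two
#' volumes and the data must be entirely finite.
#'
#' @param data 4D numeric array (X x Y x Z x T).
#' @param voxel_size mm triple.
#' @param tr repetition time in seconds.
#' @param subject_id subject identifier string.
#' @return An object of class `bold4d`.
#' @export
bold4d <- function(data, voxel_size = c(2.15, 2.15, 2.15), tr = 0.392,
                   subject_id = "subject") {
    d <- dim(data)
    if (length(d) != 4) stop("expected 4D volume, got ", length(d), " dimensions")
    if (any(d < 1)) stop("all dimensions must be >= 1")
    if (d[4] < 2) stop("need at least 2 volumes, got ", d[4])
    if (!all(is.finite(data))) stop("data contains non-finite values")
    stopifnot(length(voxel_size) == 3, all(voxel_size > 0), tr > 0)
    structure(list(data = data, voxel_size = as.numeric(voxel_size),
                   tr = as.numeric(tr), subject_id = as.character(subject_id)),
              class = "bold4d")
}

#' @export
print.bold4d <- function(x, ...) {
    d <- dim(x$data)
    cat(sprintf("<bold4d> %s: %dx%dx%d voxels x %d volumes, voxel %.4gx%.4gx%.4g mm, TR %.4g s\n",
                x$subject_id, d[1], d[2], d[3], d[4],
                x$voxel_size[1], x$voxel_size[2], x$voxel_size[3], x$tr))
    invisible(x)
}

#' Read a 4D BOLD NIfTI-1 file
#'
#' The grid shape and voxel sizes are taken from the header; the repetition
#' time is the header time-step (pixdim slot 5). Files with fewer than four
#' dimensions or any non-finite voxel are rejected.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param subject_id identifier; defaults to the file name without extension.
#' @return A [bold4d()] object.
#' @export
read_bold <- function(path, subject_id = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) < 4)
        stop("expected 4D volume in ", path, ", got ", length(d), " dimensions")
    if (length(d) > 4) {
        if (any(d[-(1:4)] != 1)) stop("more than 4 non-singleton dimensions in ", path)
        dim(img) <- d[1:4]
    }
    arr <- as.array(img)
    attributes(arr) <- list(dim = dim(arr))   # drop NIfTI header attributes
    if (!all(is.finite(arr)))
        stop("non-finite voxel values in ", path)
    pd <- RNifti::pixdim(img)
    tr <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
    if (is.null(subject_id))
        subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
    bold4d(arr, voxel_size = pd[1:3], tr = tr, subject_id = subject_id)
}

#' Write a 4D BOLD object as NIfTI-1
#'
#' Voxel sizes and repetition time are stored in the header pixdim field so
#' that [read_bold()] round-trips the object exactly. Overwrites silently.
#'
#' @param b a [bold4d()] object.
#' @param path output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_bold <- function(b, path) {
    stopifnot(inherits(b, "bold4d"))
    if (!dir.exists(dirname(path)))
        stop("parent directory does not exist: ", dirname(path))
    img <- RNifti::asNifti(b$data)
    RNifti::pixdim(img) <- c(b$voxel_size, b$tr)
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Write a 3D volume (or stack of 3D maps) as NIfTI-1
#' @param vol 3D array, or 4D array with maps along the 4th axis.
#' @param path output path.
#' @param voxel_size mm triple.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, voxel_size = c(2.15, 2.15, 2.15)) {
    img <- RNifti::asNifti(vol)
    RNifti::pixdim(img) <- if (length(dim(vol)) == 4) c(voxel_size, 1) else voxel_size
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Read an optional brain-mask volume
#' @param path NIfTI path; the volume is binarised at > 0.
#' @return 3D logical array with at least one `TRUE` voxel.
#' @export
read_mask <- function(path) {
    arr <- as.array(RNifti::readNifti(path))
    attributes(arr) <- list(dim = dim(arr))
    if (length(dim(arr)) != 3) stop("mask must be 3D: ", path)
    m <- arr > 0
    if (!any(m)) stop("mask has no voxels: ", path)
    m
}

# Scan-age window (weeks PMA) of the study population.
PMA_WINDOW <- c(37, 44.5)

#' Read the per-subject covariate table
#'
#' Tab-separated with header; required columns `subject_id`, `ga_birth`,
#' `pma_scan`, `sex`, `postnatal_days`; optional `group` (derived from
#' `ga_birth >= 37` when absent, validated against it when present). Row
#' order is preserved and every defect is reported with its row number.
#'
#' @param path TSV file path.
#' @return A data frame with one row per subject, columns as above plus
#'   `motion_outliers` (NA until motion QC fills it).
#' @export
read_covariates <- function(path) {
    if (!file.exists(path)) stop("covariate file not found: ", path)
    df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                     check.names = FALSE)
    required <- c("subject_id", "ga_birth", "pma_scan", "sex", "postnatal_days")
    missing <- setdiff(required, names(df))
    if (length(missing))
        stop("missing required column(s): ", paste(missing, collapse = ", "))
    num <- function(col) {
        v <- suppressWarnings(as.numeric(df[[col]]))
        bad <- which(is.na(v) & !is.na(df[[col]]) | is.na(df[[col]]))
        if (length(bad))
            stop("unparseable numeric in column '", col, "' at row ", bad[1])
        v
    }
    df$ga_birth <- num("ga_birth")
    df$pma_scan <- num("pma_scan")
    df$postnatal_days <- num("postnatal_days")
    bad_sex <- which(!df$sex %in% c("female", "male"))
    if (length(bad_sex))
        stop("sex must be 'female' or 'male' at row ", bad_sex[1])
    bad <- which(df$ga_birth > df$pma_scan)
    if (length(bad))
        stop("ga_birth exceeds pma_scan at row ", bad[1],
             " (subject ", df$subject_id[bad[1]], ")")
    bad <- which(df$pma_scan < PMA_WINDOW[1] | df$pma_scan > PMA_WINDOW[2])
    if (length(bad))
        stop("pma_scan outside study window [", PMA_WINDOW[1], ", ",
             PMA_WINDOW[2], "] weeks at row ", bad[1])
    derived <- ifelse(df$ga_birth >= 37, "term", "preterm")
    if (is.null(df$group)) {
        df$group <- derived
    } else {
        bad <- which(df$group != derived)
        if (length(bad))
            stop("group label inconsistent with ga_birth at row ", bad[1],
                 " (ga_birth ", df$ga_birth[bad[1]], " implies ",
                 derived[bad[1]], ")")
    }
    if (is.null(df$motion_outliers)) df$motion_outliers <- NA_real_
    df[c(required[1:3], "sex", "group", "postnatal_days", "motion_outliers")]
}

#' Write a covariate table as TSV
#' @param metas data frame as returned by [read_covariates()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(metas, path) {
    write.table(metas, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
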