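# Winner-takes-all functional parcellation: each voxel is assigned to the
# network whose smoothed Z value is highest, provided it exceeds the
# threshold; voxels where no network survives stay unassigned.

#' Winner-takes-all parcellation of the group network maps
#'
#' Each signal component's Z-map is Gaussian-smoothed, then every voxel is
#' labelled with the signal component attaining the largest smoothed Z among
#' those strictly exceeding `z_thr` (0 when none does). Ties go to the
#' lowest component index.
#'
#' @param g a labelled `group_map_set` with at least one signal component.
#' @param smoothing_fwhm smoothing kernel FWHM in mm.
#' @param z_thr inclusion threshold on the smoothed Z value.
#' @return A `parcel_map`: list with `labels` (3D integer array; 0 =
#'   unassigned, k = k-th signal component), `legend` (label to network
#'   name), `smoothing_fwhm`, `z_thr`.
#' @export
winner_takes_all <- function(g, smoothing_fwhm = 3, z_thr = 1.0) {
    stopifnot(inherits(g, "group_map_set"))
    sig <- signal_components(g)
    if (!length(sig)) stop("no components labelled signal")
    sm <- vapply(sig, function(k)
        as.vector(smooth_gaussian(g$maps[, , , k], smoothing_fwhm,
                                  g$voxel_size)),
        numeric(prod(g$grid)))
    winner <- max.col(sm, ties.method = "first")
    best <- sm[cbind(seq_len(nrow(sm)), winner)]
    labels <- ifelse(best > z_thr, winner, 0L)
    structure(list(labels = array(as.integer(labels), g$grid),
                   legend = data.frame(label = seq_along(sig),
                                       name = g$names[sig],
                                       stringsAsFactors = FALSE),
                   smoothing_fwhm = smoothing_fwhm, z_thr = z_thr),
              class = "parcel_map")
}

#' Write a parcellation to disk
#' @param p a `parcel_map`.
#' @param labels_path integer-label NIfTI output path.
#' @param legend_path legend TSV output path.
#' @param voxel_size mm triple for the NIfTI header.
#' @return Invisibly, the two paths.
#' @export
write_parcellation <- function(p, labels_path, legend_path,
                               voxel_size = c(2.15, 2.15, 2.15)) {
    write_volume(p$labels, labels_path, voxel_size = voxel_size)
    write.table(p$legend, legend_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(c(labels_path, legend_path))
}
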