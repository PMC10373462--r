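#' Optimal rigid-body (Kabsch) superposition
#'
#' Least-squares optimal proper rotation + translation mapping `mobile`
#' onto `reference` over the atoms in `fit_idx`, computed by singular
#' value decomposition of the covariance of the centered fit sets. The
#' returned rotation always has determinant +1 (no reflections).
#'
#' @param mobile n x 3 coordinate matrix to transform.
#' @param reference n x 3 coordinate matrix held fixed.
#' @param fit_idx row indices used to determine the transform
#'   (default: all rows). At least 3 non-collinear points required.
#' @return list with `coords` (all of `mobile` transformed), `rotation`
#'   (3 x 3, det +1) and `translation` (length 3), so that
#'   `coords = mobile %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, reference, fit_idx = seq_len(nrow(mobile))) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (length(fit_idx) < 3) stop("fit set must contain at least 3 atoms")
  mo <- mobile[fit_idx, , drop = FALSE]
  re <- reference[fit_idx, , drop = FALSE]
  if (nrow(mo) != nrow(re)) stop("fit sets differ in size")
  cm <- colMeans(mo); cr <- colMeans(re)
  moc <- sweep(mo, 2, cm); rec <- sweep(re, 2, cr)
  s <- svd(t(moc) %*% rec)
  # smallest singular value ~ 0 with ambiguous axis => degenerate fit set
  if (s$d[2] < 1e-8 * max(s$d[1], 1e-30))
    stop("degenerate (collinear or coincident) fit set")
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- cr - drop(rot %*% cm)
  list(coords = sweep(mobile %*% t(rot), 2, trans, "+"),
       rotation = rot, translation = trans)
}

#' Root-mean-square deviation between two frames
#'
#' sqrt of the mean squared per-atom displacement over the selection; no
#' superposition is applied here (see [rmsd_series()] for the aligned
#' variant).
#'
#' @param frame,reference n x 3 coordinate matrices.
#' @param sel row indices of the atoms entering the average
#'   (default: all rows).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(frame, reference, sel = seq_len(nrow(frame))) {
  if (length(sel) == 0) stop("empty selection")
  d <- as.matrix(frame)[sel, , drop = FALSE] -
    as.matrix(reference)[sel, , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}

#' RMSD time series of a trajectory against a reference frame
#'
#' One RMSD value per frame over the chosen selection (whole-protein
#' backbone by default, the conventional stability measure). With
#' `align = TRUE` (default) every frame is first Kabsch-superposed onto
#' the reference over the same selection, so diffusive rigid-body motion
#' does not inflate the series; `align = FALSE` gives the literal
#' fixed-axes deviation.
#'
#' @param traj a `trajectory`.
#' @param sel integer atom indices (default [backbone_indices()]).
#' @param reference_frame 1-based reference frame (default 1, the start
#'   of the production run).
#' @param align superpose each frame on the reference first.
#' @return object of class `rmsd_series`: data.frame with columns
#'   `frame`, `time_ns`, `rmsd` plus attributes recording the settings.
#' @export
rmsd_series <- function(traj, sel = backbone_indices(traj),
                        reference_frame = 1, align = TRUE) {
  if (length(sel) == 0) stop("empty selection")
  ref <- frame_coords(traj, reference_frame)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    crd <- frame_coords(traj, f)
    if (align) crd <- kabsch_superpose(crd, ref, fit_idx = sel)$coords
    rmsd(crd, ref, sel = sel)
  }, numeric(1))
  out <- data.frame(
    frame = seq_len(n_frames(traj)),
    time_ns = traj$origin_time + (seq_len(n_frames(traj)) - 1) *
      traj$frame_spacing,
    rmsd = vals)
  structure(out, class = c("rmsd_series", "data.frame"),
            reference_frame = reference_frame, aligned = align,
            n_sel = length(sel))
}

#' Write an RMSD series as TSV
#' @param series result of [rmsd_series()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rmsd_tsv <- function(series, path) {
  utils::write.table(as.data.frame(series), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
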