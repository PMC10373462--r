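#' Define a pair of sites for distance analysis
#'
#' @param label pair label (conventionally d1..d6 for the
#'   electron-transfer chain distances).
#' @param site_a,site_b `site_definition`s for the two endpoints; the
#'   per-frame distance is taken between their centers of mass.
#' @return object of class `site_pair`.
#' @export
site_pair <- function(label, site_a, site_b) {
  stopifnot(inherits(site_a, "site_definition"),
            inherits(site_b, "site_definition"))
  structure(list(label = as.character(label), site_a = site_a,
                 site_b = site_b),
            class = "site_pair")
}

#' Default electron-transfer chain distance pairs
#'
#' The conventional six distances: the tetrad chain FAD-W395-W372-W318-
#' W369 walked pairwise (d1-d4), plus the back-transfer pairs W318-Y319
#' (d5) and FAD-W369 (d6). Endpoint centers of mass use side-chain heavy
#' atoms (the electron-transfer relevant moieties); all definitions are
#' overridable by passing an own list to the geometry functions, and
#' reports print the pair definitions used.
#'
#' @param fad_resno author residue number of the FAD cofactor in the
#'   topology (it is selected by residue name FAD when `NULL`).
#' @return named list of `site_pair` objects.
#' @export
default_distance_pairs <- function(fad_resno = NULL) {
  site <- function(lab, rs, cof = FALSE)
    site_definition(lab, rs, selection_mode = "side_chain",
                    include_cofactor = cof)
  fad <- if (is.null(fad_resno)) {
    site_definition("FAD", 1L, selection_mode = "all_atoms",
                    include_cofactor = TRUE)
  } else {
    site_definition("FAD", fad_resno, selection_mode = "all_atoms")
  }
  w <- function(rs) site(paste0("W", rs), rs)
  list(
    d1 = site_pair("d1", fad, w(395)),
    d2 = site_pair("d2", w(395), w(372)),
    d3 = site_pair("d3", w(372), w(318)),
    d4 = site_pair("d4", w(318), w(369)),
    d5 = site_pair("d5", w(318), site("Y319", 319)),
    d6 = site_pair("d6", fad, w(369)))
}

.site_com_series <- function(traj, site) {
  idx <- select_site(traj, site)
  .com_series(traj, idx)
}

#' Per-frame distance between the centers of mass of two sites
#'
#' @param traj a `trajectory`.
#' @param pair a `site_pair`.
#' @return a `scalar_series` of Euclidean distances (Angstrom).
#' @export
distance_series <- function(traj, pair) {
  stopifnot(inherits(pair, "site_pair"))
  ca <- .site_com_series(traj, pair$site_a)
  cb <- .site_com_series(traj, pair$site_b)
  scalar_series(sqrt(rowSums((ca - cb)^2)), spacing = traj$frame_spacing)
}

#' Block statistics and Gaussian fit of a distance series
#'
#' The series is split into `n_blocks` contiguous blocks; the reported
#' mean is the grand mean and the error is the standard deviation of the
#' per-block means. A Gaussian is fitted to the pooled distance density.
#'
#' @param series a `scalar_series`.
#' @param n_blocks number of blocks (default 20).
#' @return list with `mean`, `block_sd`, `block_means`, `n_blocks`, and
#'   `fit` (a `gaussian_fit`, `NULL` if the series is degenerate).
#' @export
distance_stats <- function(series, n_blocks = 20) {
  x <- series$values
  if (length(x) < n_blocks)
    stop("series shorter (", length(x), ") than n_blocks (", n_blocks, ")")
  fpb <- length(x) %/% n_blocks
  used <- fpb * n_blocks
  block_means <- tapply(x[seq_len(used)],
                        rep(seq_len(n_blocks), each = fpb), mean)
  fit <- tryCatch(fit_gaussian(x, 1), error = function(e) NULL)
  list(mean = mean(x), block_sd = sd(block_means),
       block_means = as.numeric(block_means),
       n_blocks = as.integer(n_blocks), fit = fit)
}

#' Count water molecules near a site
#'
#' A water molecule counts in a frame when any of its atoms lies within
#' `radius` of any site atom; each water is counted at most once per
#' frame. Waters are recognized by residue name ([is_water()]).
#'
#' @param traj a `trajectory`.
#' @param site a `site_definition` (all its atoms are used).
#' @param radius Angstrom (default 5).
#' @return list with `counts` (per frame), `mean`, `radius`.
#' @export
count_waters <- function(traj, site, radius = 5.0) {
  site_idx <- select_site(traj, site, mode = "all_atoms")
  wat <- which(is_water(traj$atoms$resname))
  if (length(wat) == 0) {
    warning("no water molecules in topology")
    return(list(counts = rep(0L, n_frames(traj)), mean = 0,
                radius = radius))
  }
  wkeys <- .residue_keys(traj)[wat]
  counts <- vapply(seq_len(n_frames(traj)), function(f) {
    crd <- frame_coords(traj, f)
    d2 <- .min_cross_dist2(crd[wat, , drop = FALSE],
                           crd[site_idx, , drop = FALSE])
    length(unique(wkeys[d2 <= radius^2]))
  }, integer(1))
  list(counts = counts, mean = mean(counts), radius = radius)
}

#' Specify three atoms defining an aromatic plane
#'
#' Conventional defaults for the residues of interest: Trp CG/CD2/CE2,
#' Phe CG/CE1/CE2, Tyr CG/CE1/CE2, FAD N5/N10/C4A (isoalloxazine).
#'
#' @param residue_seq author residue number.
#' @param atoms character vector of exactly three distinct atom names;
#'   when `NULL` the default triplet for `resname` is used.
#' @param resname residue name used to pick the default triplet.
#' @param chain optional chain restriction.
#' @return object of class `plane_spec`.
#' @export
plane_spec <- function(residue_seq, atoms = NULL, resname = NULL,
                       chain = NULL) {
  if (is.null(atoms)) {
    defaults <- list(TRP = c("CG", "CD2", "CE2"),
                     PHE = c("CG", "CE1", "CE2"),
                     TYR = c("CG", "CE1", "CE2"),
                     FAD = c("N5", "N10", "C4A"))
    if (is.null(resname) || !toupper(resname) %in% names(defaults))
      stop("no default plane triplet for residue name '",
           resname %||% "?", "'; give `atoms` explicitly")
    atoms <- defaults[[toupper(resname)]]
  }
  if (length(unique(atoms)) != 3) stop("need three distinct atom names")
  structure(list(residue_seq = as.integer(residue_seq), atoms = atoms,
                 chain = chain),
            class = "plane_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.plane_normal <- function(crd, idx) {
  v1 <- crd[idx[2], ] - crd[idx[1], ]
  v2 <- crd[idx[3], ] - crd[idx[1], ]
  n <- c(v1[2] * v2[3] - v1[3] * v2[2],
         v1[3] * v2[1] - v1[1] * v2[3],
         v1[1] * v2[2] - v1[2] * v2[1])
  len <- sqrt(sum(n^2))
  scale <- max(sqrt(sum(v1^2)), sqrt(sum(v2^2)))
  if (len < 1e-8 * max(scale^2, 1e-12)) return(NULL)  # collinear triplet
  n / len
}

.plane_atom_idx <- function(traj, spec) {
  a <- traj$atoms
  idx <- vapply(spec$atoms, function(nm) {
    ok <- a$resno == spec$residue_seq & a$name == nm
    if (!is.null(spec$chain)) ok <- ok & a$chain %in% spec$chain
    hit <- which(ok)
    if (length(hit) == 0)
      stop("plane atom ", nm, " of residue ", spec$residue_seq,
           " not in topology")
    hit[1]
  }, integer(1))
  unname(idx)
}

#' Angle between two aromatic planes per frame
#'
#' The angle between the plane normals, folded into [0, 90] degrees (a
#' plane has no orientation, so angle and 180 minus angle are
#' equivalent). Frames with a collinear triplet are excluded and counted.
#'
#' @param traj a `trajectory`.
#' @param spec_a,spec_b `plane_spec`s.
#' @return list with `series` (a `scalar_series` in degrees over the
#'   retained frames), `mean`, `sd`, `n_excluded`.
#' @export
plane_angle_series <- function(traj, spec_a, spec_b) {
  ia <- .plane_atom_idx(traj, spec_a)
  ib <- .plane_atom_idx(traj, spec_b)
  ang <- rep(NA_real_, n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    crd <- frame_coords(traj, f)
    na_ <- .plane_normal(crd, ia); nb_ <- .plane_normal(crd, ib)
    if (is.null(na_) || is.null(nb_)) next
    cosang <- abs(sum(na_ * nb_))
    ang[f] <- acos(min(1, cosang)) * 180 / pi
  }
  excl <- sum(is.na(ang))
  if (excl > 0)
    warning(excl, " frame(s) with a collinear plane triplet excluded")
  vals <- ang[!is.na(ang)]
  list(series = scalar_series(vals, spacing = traj$frame_spacing),
       mean = mean(vals), sd = sd(vals), n_excluded = excl)
}
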