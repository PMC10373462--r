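#' Load a donor/acceptor chemistry table
#'
#' The table is shipped as an editable TSV resource so cofactor atoms can
#' be added without code changes. `resname = "*"` rows apply to every
#' standard amino-acid residue (backbone N/H donor and carbonyl O
#' acceptor). Each donor row names the heavy atom and its attached
#' hydrogen candidates; of those, the ones actually present in a given
#' residue are used.
#'
#' @param path TSV with columns `role`, `resname`, `atom`, `hydrogens`
#'   (space-separated H names; donors only). Default: the built-in table.
#' @return data.frame of class `donor_acceptor_table`.
#' @export
load_donor_acceptor_table <- function(path = system.file(
    "extdata", "donor_acceptor_table.tsv", package = "crytraj")) {
  tab <- read.delim(path, stringsAsFactors = FALSE, fill = TRUE)
  tab$hydrogens[is.na(tab$hydrogens)] <- ""
  if (any(tab$role == "donor" & !nzchar(tab$hydrogens)))
    stop("donor rows must list at least one attached hydrogen name")
  class(tab) <- c("donor_acceptor_table", "data.frame")
  tab
}

# Resolve the table against a topology: returns list(donors, acceptors).
# donors: data.frame(atom, h_atom) of 1-based atom indices (one row per
# donor-H combination actually present); acceptors: integer indices.
.resolve_da <- function(traj, table) {
  a <- traj$atoms
  keys <- .residue_keys(traj)
  std <- a$resname %in% .standard_aa

  match_rows <- function(role) {
    rows <- table[table$role == role, , drop = FALSE]
    idx <- integer(0); h_of <- list()
    for (r in seq_len(nrow(rows))) {
      hit <- if (rows$resname[r] == "*") {
        std & a$name == rows$atom[r]
      } else {
        a$resname == rows$resname[r] & a$name == rows$atom[r]
      }
      w <- which(hit)
      if (role == "donor")
        h_of[w] <- rep(list(strsplit(rows$hydrogens[r], "\\s+")[[1]]),
                       length(w))
      idx <- c(idx, w)
    }
    list(idx = idx, h_of = h_of)
  }

  don <- match_rows("donor")
  acc_idx <- unique(match_rows("acceptor")$idx)
  # water-water scope control happens at the pair level, so water donor
  # and acceptor atoms are always resolved here

  # expand donors to (heavy, H) pairs with hydrogens present in the same
  # residue
  dh <- list()
  for (d in unique(don$idx)) {
    hn <- don$h_of[[d]]
    hs <- which(keys == keys[d] & a$name %in% hn & a$element == "H")
    if (length(hs) == 0) next
    dh[[length(dh) + 1]] <- data.frame(atom = d, h_atom = hs)
  }
  donors <- if (length(dh)) do.call(rbind, dh) else
    data.frame(atom = integer(0), h_atom = integer(0))
  list(donors = donors, acceptors = acc_idx)
}

#' Detect hydrogen bonds in a single frame
#'
#' Geometric criterion: donor-heavy-atom to acceptor distance at most
#' `dist_cutoff` (default 3 Angstrom) and a donor-H...acceptor angle
#' within `max_angle_dev` (default 20 degrees) of linearity, the angle
#' measured at the hydrogen. Intra-residue pairs and covalently bonded
#' pairs (heavy atoms closer than 1.8 Angstrom) are excluded. The
#' distance convention can be switched to H...acceptor and the angle
#' vertex to the donor heavy atom to match other scripts' conventions.
#'
#' @param traj a `trajectory`.
#' @param frame 1-based frame index.
#' @param table a `donor_acceptor_table`
#'   (default [load_donor_acceptor_table()]).
#' @param dist_cutoff Angstrom.
#' @param max_angle_dev degrees of allowed deviation from linear.
#' @param distance_mode `"heavy"` (donor heavy atom to acceptor, default)
#'   or `"hydrogen"` (H to acceptor).
#' @param angle_vertex `"hydrogen"` (D-H...A angle, deviation from 180
#'   degrees; default) or `"donor"` (H-D...A angle, deviation from 0).
#' @param include_water_water also report water-water bonds
#'   (default FALSE: protein/cofactor plus protein-water only).
#' @return data.frame with columns `donor`, `h`, `acceptor` (atom
#'   indices) and `distance`, `angle_dev`.
#' @export
detect_frame_hbonds <- function(traj, frame,
                                table = load_donor_acceptor_table(),
                                dist_cutoff = 3.0, max_angle_dev = 20,
                                distance_mode = c("heavy", "hydrogen"),
                                angle_vertex = c("hydrogen", "donor"),
                                include_water_water = FALSE) {
  distance_mode <- match.arg(distance_mode)
  angle_vertex <- match.arg(angle_vertex)
  da <- .resolve_da(traj, table)
  .detect_hbonds_resolved(traj, frame, da, dist_cutoff, max_angle_dev,
                          distance_mode, angle_vertex, include_water_water)
}

.detect_hbonds_resolved <- function(traj, frame, da, dist_cutoff,
                                    max_angle_dev, distance_mode,
                                    angle_vertex, include_water_water) {
  crd <- frame_coords(traj, frame)
  keys <- .residue_keys(traj)
  water <- is_water(traj$atoms$resname)
  donors <- da$donors; acceptors <- da$acceptors
  empty <- data.frame(donor = integer(0), h = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle_dev = numeric(0))
  if (nrow(donors) == 0 || length(acceptors) == 0) return(empty)

  ref_atom <- if (distance_mode == "heavy") donors$atom else donors$h_atom
  dmat <- sqrt(pmax(outer(rowSums(crd[ref_atom, , drop = FALSE]^2),
                          rowSums(crd[acceptors, , drop = FALSE]^2), "+") -
                      2 * crd[ref_atom, , drop = FALSE] %*%
                      t(crd[acceptors, , drop = FALSE]), 0))
  cand <- which(dmat <= dist_cutoff, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  di <- donors$atom[cand[, 1]]; hi <- donors$h_atom[cand[, 1]]
  ai <- acceptors[cand[, 2]]
  keep <- keys[di] != keys[ai]
  if (!include_water_water) keep <- keep & !(water[di] & water[ai])
  # covalently bonded heavy-atom pairs (and the donor's own H) excluded
  dd <- sqrt(rowSums((crd[di, , drop = FALSE] - crd[ai, , drop = FALSE])^2))
  keep <- keep & dd > 1.8 & ai != hi
  di <- di[keep]; hi <- hi[keep]; ai <- ai[keep]
  if (length(di) == 0) return(empty)

  if (angle_vertex == "hydrogen") {
    v1 <- crd[di, , drop = FALSE] - crd[hi, , drop = FALSE]
    v2 <- crd[ai, , drop = FALSE] - crd[hi, , drop = FALSE]
  } else {
    v1 <- crd[hi, , drop = FALSE] - crd[di, , drop = FALSE]
    v2 <- crd[ai, , drop = FALSE] - crd[di, , drop = FALSE]
  }
  cosang <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  # at the H the ideal D-H...A angle is 180; at the donor the ideal
  # H-D...A angle is 0, so the deviation is the angle itself
  dev <- if (angle_vertex == "hydrogen") 180 - ang else ang
  ok <- dev <= max_angle_dev
  dist_out <- sqrt(rowSums((crd[if (distance_mode == "heavy") di else hi,
                                , drop = FALSE] -
                              crd[ai, , drop = FALSE])^2))
  out <- data.frame(donor = di[ok], h = hi[ok], acceptor = ai[ok],
                    distance = dist_out[ok], angle_dev = dev[ok])
  # one record per donor-heavy/acceptor pair: keep the best hydrogen
  ord <- order(out$donor, out$acceptor, out$angle_dev)
  out <- out[ord, , drop = FALSE]
  out[!duplicated(out[, c("donor", "acceptor")]), , drop = FALSE]
}

.atom_label <- function(traj, idx) {
  a <- traj$atoms
  sprintf("%s%d (%s)", substr(a$resname[idx], 1, 3), a$resno[idx],
          a$name[idx])
}

#' Hydrogen-bond occupancy table over a trajectory
#'
#' For every donor-atom/acceptor-atom pair observed in at least one
#' frame, the percentage of frames in which the geometric criterion
#' holds. Pairs never satisfied are absent from the table rather than
#' listed at 0%.
#'
#' @inheritParams detect_frame_hbonds
#' @param donor_resnos optional integer vector: restrict to donors in
#'   these residues (e.g. the tetrad tryptophans `c(318, 369, 372, 395)`).
#' @return data.frame with columns `donor`, `acceptor` (labels like
#'   `"TRP318 (NE1)"`), `donor_atom`, `acceptor_atom` (indices),
#'   `occupancy` (percent) and `n_frames`, sorted by occupancy.
#' @export
occupancy_table <- function(traj, table = load_donor_acceptor_table(),
                            dist_cutoff = 3.0, max_angle_dev = 20,
                            distance_mode = "heavy",
                            angle_vertex = "hydrogen",
                            donor_resnos = NULL,
                            include_water_water = FALSE) {
  stopifnot(n_frames(traj) >= 1)
  da <- .resolve_da(traj, table)
  counts <- new.env(parent = emptyenv())
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    hb <- .detect_hbonds_resolved(traj, f, da, dist_cutoff, max_angle_dev,
                                  distance_mode, angle_vertex,
                                  include_water_water)
    if (nrow(hb) == 0) next
    ids <- paste(hb$donor, hb$acceptor)
    for (id in ids)
      assign(id, (if (exists(id, counts)) get(id, counts) else 0L) + 1L,
             counts)
  }
  ids <- ls(counts)
  if (length(ids) == 0)
    return(data.frame(donor = character(0), acceptor = character(0),
                      donor_atom = integer(0), acceptor_atom = integer(0),
                      occupancy = numeric(0), n_frames = integer(0)))
  parts <- do.call(rbind, strsplit(ids, " "))
  di <- as.integer(parts[, 1]); ai <- as.integer(parts[, 2])
  n <- vapply(ids, function(id) get(id, counts), integer(1))
  out <- data.frame(
    donor = .atom_label(traj, di), acceptor = .atom_label(traj, ai),
    donor_atom = di, acceptor_atom = ai,
    occupancy = 100 * n / nf, n_frames = nf,
    stringsAsFactors = FALSE)
  if (!is.null(donor_resnos))
    out <- out[traj$atoms$resno[out$donor_atom] %in% donor_resnos, ,
               drop = FALSE]
  out <- out[order(-out$occupancy), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean hydrogen-bond count per residue
#'
#' For each residue, the number of hydrogen bonds in which it
#' participates — as donor or acceptor — averaged over frames.
#'
#' @inheritParams occupancy_table
#' @return data.frame with columns `key`, `chain`, `resno`, `resname`,
#'   `mean_hbonds`.
#' @export
per_residue_average <- function(traj, table = load_donor_acceptor_table(),
                                dist_cutoff = 3.0, max_angle_dev = 20,
                                distance_mode = "heavy",
                                angle_vertex = "hydrogen") {
  stopifnot(n_frames(traj) >= 1)
  da <- .resolve_da(traj, table)
  rt <- residue_table(traj)
  keys <- .residue_keys(traj)
  acc <- setNames(numeric(nrow(rt)), rt$key)
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    hb <- .detect_hbonds_resolved(traj, f, da, dist_cutoff, max_angle_dev,
                                  distance_mode, angle_vertex, FALSE)
    if (nrow(hb) == 0) next
    for (k in c(keys[hb$donor], keys[hb$acceptor]))
      acc[k] <- acc[k] + 1
  }
  cbind(rt, mean_hbonds = unname(acc[rt$key]) / nf)
}
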