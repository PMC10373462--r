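#' @importFrom stats acf coef complete.cases dist dnorm median quantile rnorm
#'   runif sd setNames var
#' @importFrom utils head read.delim tail
NULL

# Atomic masses (Da) for elements commonly found in hydrogenated protein +
# cofactor + water systems. Unknown elements raise an error rather than
# silently contributing zero mass.
.element_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305,
  CA = 40.078, "NA" = 22.990, K = 39.098, CL = 35.45, MN = 54.938
)

.water_resnames <- c("HOH", "WAT", "TIP3", "SOL")
.backbone_names <- c("N", "CA", "C", "O")
.standard_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "HSD",
  "HSE", "HSP", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR",
  "TRP", "TYR", "VAL"
)

#' Look up atomic masses by element symbol
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in daltons.
#' @export
element_mass <- function(element) {
  key <- toupper(trimws(element))
  m <- .element_masses[key]
  if (anyNA(m)) {
    bad <- unique(key[is.na(m)])
    stop("unknown element(s): ", paste(bad, collapse = ", "),
         "; extend the element mass table or fix the input", call. = FALSE)
  }
  unname(m)
}

#' Is a residue name a water?
#'
#' Residue names HOH, WAT, TIP3 and SOL are treated as water; everything
#' else is polymer or cofactor.
#'
#' @param resname character vector of residue names.
#' @return logical vector.
#' @export
is_water <- function(resname) toupper(trimws(resname)) %in% .water_resnames

# Guess the element from a PDB atom name when the element column is blank.
.guess_element <- function(name) {
  nm <- toupper(trimws(name))
  first <- substr(nm, 1, 1)
  ifelse(grepl("^[0-9]", nm) | first == "H", "H",
    ifelse(substr(nm, 1, 2) %in% c("FE", "ZN", "MG", "CL", "SE", "MN"),
           substr(nm, 1, 2), first))
}

#' Construct a trajectory object
#'
#' The container every analysis stage consumes: an atom table (the static
#' topology) plus an `n_frames x 3*n_atoms` coordinate matrix in Angstrom
#' (bio3d xyz layout: frame rows, `x1,y1,z1,x2,...` columns) and a frame
#' spacing in nanoseconds.
#'
#' @param atoms data.frame with columns `name`, `element`, `resno`
#'   (author residue numbering, kept verbatim), `resname`, `chain`.
#'   A `mass` column is derived from `element` when absent.
#' @param xyz numeric matrix, one row per frame, `3 * nrow(atoms)` columns.
#' @param frame_spacing time between frames in ns (default 1).
#' @param origin_time time of the first frame in ns.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(atoms, xyz, frame_spacing = 1, origin_time = 0) {
  stopifnot(is.data.frame(atoms), frame_spacing > 0)
  req <- c("name", "element", "resno", "resname", "chain")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    stop("atoms table lacks column(s): ", paste(miss, collapse = ", "))
  xyz <- rbind(xyz)
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("coordinate matrix has ", ncol(xyz), " columns; expected ",
         3L * nrow(atoms), " for ", nrow(atoms), " atoms")
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  if (any(atoms$mass <= 0)) stop("all atomic masses must be positive")
  atoms$name <- trimws(atoms$name)
  atoms$resname <- toupper(trimws(atoms$resname))
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms, xyz = xyz,
         frame_spacing = frame_spacing, origin_time = origin_time),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "trajectory: %d atoms, %d residues, %d frames, %.4g ns/frame\n",
    n_atoms(x), nrow(residue_table(x)), n_frames(x), x$frame_spacing))
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj a `trajectory`.
#' @return integer count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' @rdname n_frames
#' @export
n_atoms <- function(traj) nrow(traj$atoms)

#' Coordinates of one frame as an n_atoms x 3 matrix
#' @param traj a `trajectory`.
#' @param frame 1-based frame index.
#' @return numeric matrix with columns x, y, z (Angstrom).
#' @export
frame_coords <- function(traj, frame) {
  if (frame < 1 || frame > n_frames(traj))
    stop("frame index ", frame, " out of range 1..", n_frames(traj))
  matrix(traj$xyz[frame, ], ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Derived residue table of a trajectory
#'
#' One row per residue in atom order: chain, author residue number,
#' residue name, plus a unique `key` string.
#'
#' @param traj a `trajectory`.
#' @return data.frame with columns chain, resno, resname, key.
#' @export
residue_table <- function(traj) {
  a <- traj$atoms
  key <- paste(a$chain, a$resno, sep = ":")
  keep <- !duplicated(key)
  data.frame(chain = a$chain[keep], resno = a$resno[keep],
             resname = a$resname[keep], key = key[keep],
             stringsAsFactors = FALSE)
}

.residue_keys <- function(traj) paste(traj$atoms$chain, traj$atoms$resno, sep = ":")

#' Read a multi-model PDB file as a trajectory
#'
#' Fixed-column PDB parsing is delegated to bio3d; one frame per MODEL
#' block (a single coordinate block yields a one-frame trajectory). PDB
#' carries no time axis, so the frame spacing is supplied by the caller.
#'
#' @param path PDB file path.
#' @param frame_spacing ns between MODELs (default 1 frame-unit).
#' @param origin_time ns of the first frame.
#' @return a `trajectory`.
#' @export
read_multimodel_pdb <- function(path, frame_spacing = 1, origin_time = 0) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("malformed PDB '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  elem <- at$elesy
  blank <- is.na(elem) | trimws(elem) == ""
  elem[blank] <- .guess_element(at$elety[blank])
  atoms <- data.frame(
    name = trimws(at$elety), element = toupper(trimws(elem)),
    resno = at$resno, resname = at$resid,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    stringsAsFactors = FALSE)
  xyz <- rbind(unclass(pdb$xyz))
  if (any(is.na(xyz)))
    stop("inconsistent PDB '", path,
         "': MODEL blocks differ in atom count or order")
  trajectory(atoms, xyz, frame_spacing = frame_spacing,
             origin_time = origin_time)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Coordinates are written at the PDB fixed-column precision (3 decimals).
#'
#' @param traj a `trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  a <- traj$atoms
  bio3d::write.pdb(
    file = path, xyz = traj$xyz, type = rep("ATOM", nrow(a)),
    resno = a$resno, resid = a$resname, eleno = seq_len(nrow(a)),
    elety = a$name, chain = a$chain, elesy = a$element)
  invisible(path)
}

#' Read a PDB topology plus DCD coordinate file as a trajectory
#'
#' @param pdb_path PDB file providing the topology (first frame discarded).
#' @param dcd_path binary DCD coordinate file.
#' @inheritParams read_multimodel_pdb
#' @return a `trajectory`.
#' @export
read_dcd_trajectory <- function(pdb_path, dcd_path, frame_spacing = 1,
                                origin_time = 0) {
  top <- read_multimodel_pdb(pdb_path, frame_spacing = frame_spacing)
  # bio3d warns about header flavors some writers emit; the atom-count
  # check below is the real consistency guard
  xyz <- suppressWarnings(bio3d::read.dcd(dcd_path, verbose = FALSE))
  if (ncol(xyz) != 3L * n_atoms(top))
    stop("DCD atom count (", ncol(xyz) / 3, ") does not match topology (",
         n_atoms(top), ")")
  trajectory(top$atoms, rbind(unclass(xyz)), frame_spacing = frame_spacing,
             origin_time = origin_time)
}

#' Define a site of interest
#'
#' A named residue or residue set (e.g. the tetrad tryptophans 318, 369,
#' 372, 395, or the FAD cofactor) together with its selection rule.
#'
#' @param label site label used in reports and error messages.
#' @param residue_seqs integer vector of author residue numbers.
#' @param selection_mode one of `"backbone"`, `"side_chain"`, `"all_atoms"`.
#' @param include_cofactor also select residues named FAD.
#' @param neighborhood_radius optional radius in Angstrom used when the
#'   site is expanded to its spatial neighborhood.
#' @param chain optional chain restriction.
#' @return an object of class `site_definition`.
#' @export
site_definition <- function(label, residue_seqs,
                            selection_mode = c("backbone", "side_chain",
                                               "all_atoms"),
                            include_cofactor = FALSE,
                            neighborhood_radius = NULL, chain = NULL) {
  selection_mode <- match.arg(selection_mode)
  if (length(residue_seqs) < 1) stop("residue_seqs must be non-empty")
  if (!is.null(neighborhood_radius) && neighborhood_radius <= 0)
    stop("neighborhood_radius must be > 0")
  structure(
    list(label = as.character(label),
         residue_seqs = as.integer(residue_seqs),
         selection_mode = selection_mode,
         include_cofactor = isTRUE(include_cofactor),
         neighborhood_radius = neighborhood_radius, chain = chain),
    class = "site_definition")
}

#' Select atom indices for a site
#'
#' `backbone` returns atoms named N, CA, C, O of the listed residues;
#' `side_chain` the remaining non-hydrogen atoms of those residues;
#' `all_atoms` every atom of the residues.
#'
#' @param traj a `trajectory` (the topology is used).
#' @param site a `site_definition`.
#' @param mode override the site's selection mode.
#' @return integer vector of 1-based atom indices.
#' @export
select_site <- function(traj, site, mode = site$selection_mode) {
  a <- traj$atoms
  in_res <- a$resno %in% site$residue_seqs
  if (!is.null(site$chain)) in_res <- in_res & a$chain %in% site$chain
  if (site$include_cofactor) in_res <- in_res | a$resname == "FAD"
  if (!any(in_res))
    stop("site '", site$label, "': residue number(s) ",
         paste(site$residue_seqs, collapse = ","), " not in topology")
  idx <- switch(mode,
    backbone   = which(in_res & a$name %in% .backbone_names),
    side_chain = which(in_res & !(a$name %in% .backbone_names) &
                         a$element != "H"),
    all_atoms  = which(in_res),
    stop("unknown selection mode: ", mode))
  if (length(idx) == 0)
    stop("site '", site$label, "': selection mode '", mode,
         "' matches no atoms")
  idx
}

#' Residues within a radius of a site at a reference frame
#'
#' Returns the amino-acid residues having at least one atom within
#' `radius` of at least one site atom at the reference frame. Membership
#' is evaluated once at that frame and intended to be frozen for the whole
#' trajectory, so downstream center-of-mass series are functions of a
#' fixed atom set. Waters, the cofactor and the site's own residues are
#' excluded.
#'
#' @param traj a `trajectory`.
#' @param site a `site_definition`.
#' @param radius Angstrom (default 10).
#' @param reference_frame 1-based frame at which membership is evaluated.
#' @return character vector of residue keys (`chain:resno`).
#' @export
neighborhood <- function(traj, site, radius = 10, reference_frame = 1) {
  stopifnot(radius > 0)
  crd <- frame_coords(traj, reference_frame)
  site_idx <- select_site(traj, site, mode = "all_atoms")
  a <- traj$atoms
  keys <- .residue_keys(traj)
  candidate <- which(!(keys %in% keys[site_idx]) &
                       !is_water(a$resname) & a$resname %in% .standard_aa)
  if (length(candidate) == 0) return(character(0))
  d2 <- .min_cross_dist2(crd[candidate, , drop = FALSE],
                         crd[site_idx, , drop = FALSE])
  hit <- candidate[d2 <= radius^2]
  unique(keys[hit])
}

# Squared distance from each row of a to the nearest row of b.
.min_cross_dist2 <- function(a, b) {
  cross <- a %*% t(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * cross
  apply(d2, 1, min)
}

#' Mass-weighted center of mass of an atom set at one frame
#'
#' @param traj a `trajectory`.
#' @param atom_idx integer atom indices.
#' @param frame 1-based frame index.
#' @return numeric length-3 vector (Angstrom).
#' @export
center_of_mass <- function(traj, atom_idx, frame) {
  if (length(atom_idx) == 0) stop("empty atom set")
  crd <- frame_coords(traj, frame)[atom_idx, , drop = FALSE]
  m <- traj$atoms$mass[atom_idx]
  tot <- sum(m)
  if (tot <= 0) stop("zero total mass")
  unname(drop(t(crd) %*% m)) / tot
}

# Vectorized CoM over all frames: returns n_frames x 3 matrix.
.com_series <- function(traj, atom_idx) {
  m <- traj$atoms$mass[atom_idx]
  tot <- sum(m)
  if (tot <= 0) stop("zero total mass")
  xs <- traj$xyz[, 3 * (atom_idx - 1) + 1, drop = FALSE]
  ys <- traj$xyz[, 3 * (atom_idx - 1) + 2, drop = FALSE]
  zs <- traj$xyz[, 3 * (atom_idx - 1) + 3, drop = FALSE]
  cbind(x = drop(xs %*% m), y = drop(ys %*% m), z = drop(zs %*% m)) / tot
}

#' Atom indices of whole-protein backbone
#' @param traj a `trajectory`.
#' @return integer vector of 1-based atom indices.
#' @export
backbone_indices <- function(traj) {
  a <- traj$atoms
  which(a$name %in% .backbone_names & !is_water(a$resname) &
          a$resname %in% .standard_aa)
}
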