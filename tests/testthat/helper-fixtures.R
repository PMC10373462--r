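# Fixture builders and independent brute-force oracles used across tests.

# A minimal trajectory from an atoms spec and a list of n_atoms x 3 frames.
make_traj <- function(atoms, frames, frame_spacing = 0.1) {
  xyz <- do.call(rbind, lapply(frames, function(fr) as.numeric(t(fr))))
  trajectory(atoms, xyz, frame_spacing = frame_spacing)
}

simple_atoms <- function(n, resname = "GLY", name = "CA", element = "C",
                         resno = seq_len(n), chain = "A") {
  data.frame(name = name, element = element, resno = resno,
             resname = resname, chain = chain, stringsAsFactors = FALSE)
}

# Fully hydrogenated tryptophan atom names (CHARMM): 24 atoms.
trp_atom_names <- c(
  "N", "HN", "CA", "HA", "CB", "HB1", "HB2", "CG", "CD1", "HD1", "NE1",
  "HE1", "CE2", "CD2", "CE3", "HE3", "CZ3", "HZ3", "CZ2", "HZ2", "CH2",
  "HH2", "C", "O")

trp_atoms <- function(resno = 1, chain = "A") {
  data.frame(
    name = trp_atom_names,
    element = ifelse(substr(trp_atom_names, 1, 1) == "H", "H",
                     substr(trp_atom_names, 1, 1)),
    resno = resno, resname = "TRP", chain = chain,
    stringsAsFactors = FALSE)
}

random_coords <- function(n, scale = 10) {
  matrix(runif(3 * n, -scale, scale), ncol = 3)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# O(n^2) RMSD oracle: explicit double loop over atoms and coordinates.
brute_rmsd <- function(a, b, sel = seq_len(nrow(a))) {
  total <- 0
  for (i in sel) {
    s <- 0
    for (k in 1:3) s <- s + (a[i, k] - b[i, k])^2
    total <- total + s
  }
  sqrt(total / length(sel))
}

# O(T^2) direct-sum autocorrelation oracle (unbiased 1/(T-h) lag
# normalization over the mean-centered series).
brute_acf <- function(x, max_lag) {
  xm <- mean(x); T <- length(x)
  c0 <- sum((x - xm)^2) / T
  vapply(0:max_lag, function(h) {
    s <- 0
    for (t in seq_len(T - h)) s <- s + (x[t] - xm) * (x[t + h] - xm)
    (s / (T - h)) / c0
  }, numeric(1))
}

# All-pairs neighborhood oracle.
brute_neighborhood <- function(traj, site, radius, frame = 1) {
  crd <- frame_coords(traj, frame)
  site_idx <- select_site(traj, site, mode = "all_atoms")
  keys <- paste(traj$atoms$chain, traj$atoms$resno, sep = ":")
  std <- traj$atoms$resname %in% c(
    "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "HSD",
    "HSE", "HSP", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR",
    "TRP", "TYR", "VAL")
  hits <- character(0)
  for (i in seq_len(nrow(traj$atoms))) {
    if (keys[i] %in% keys[site_idx] || !std[i]) next
    for (j in site_idx) {
      if (sqrt(sum((crd[i, ] - crd[j, ])^2)) <= radius) {
        hits <- c(hits, keys[i]); break
      }
    }
  }
  unique(hits)
}

# Brute-force hydrogen-bond oracle over explicit donor/H/acceptor loops.
brute_hbonds <- function(traj, frame, donors, acceptors, dist_cutoff = 3,
                         max_angle_dev = 20) {
  crd <- frame_coords(traj, frame)
  keys <- paste(traj$atoms$chain, traj$atoms$resno, sep = ":")
  out <- NULL
  for (r in seq_len(nrow(donors))) {
    d <- donors$atom[r]; hh <- donors$h_atom[r]
    for (a in acceptors) {
      if (keys[d] == keys[a] || a == hh) next
      dd <- sqrt(sum((crd[d, ] - crd[a, ])^2))
      if (dd > dist_cutoff || dd <= 1.8) next
      v1 <- crd[d, ] - crd[hh, ]; v2 <- crd[a, ] - crd[hh, ]
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (180 - ang <= max_angle_dev)
        out <- rbind(out, data.frame(donor = d, acceptor = a))
    }
  }
  out
}
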