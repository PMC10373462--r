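# Seeded generators with ground-truth manifests. Each generator is a pure
# function of its arguments including the seed (RNG state is scoped with
# withr), and each manifest suffices to recompute the expected analysis
# output without rerunning the generator.

.bb_offsets <- matrix(c(
  0.00, 0.00, 0.00,    # N
  1.46, 0.00, 0.00,    # CA
  2.00, 1.00, 0.30,    # C
  2.00, 2.23, 0.30),   # O
  ncol = 3, byrow = TRUE,
  dimnames = list(c("N", "CA", "C", "O"), NULL))

.residue_atoms <- function(resno, chain = "A", resname = "GLY") {
  data.frame(name = rownames(.bb_offsets),
             element = c("N", "C", "C", "O"),
             resno = resno, resname = resname, chain = chain,
             stringsAsFactors = FALSE)
}

# Exact-discretization stationary OU path: n values, autocorrelation
# exp(-spacing/tau), stationary sd sigma.
.ou_path <- function(n, tau, sigma, spacing) {
  phi <- exp(-spacing / tau)
  d0 <- rnorm(1, sd = sigma)
  if (n == 1) return(d0)
  innov <- rnorm(n - 1, sd = sigma * sqrt(1 - phi^2))
  c(d0, stats::filter(innov, phi, method = "recursive", init = d0))
}

#' Generate a trajectory of rigid residues with Ornstein-Uhlenbeck motion
#'
#' Each residue is a rigid 4-atom backbone unit (N, CA, C, O) whose
#' displacement from its equilibrium position follows an independent
#' 3-dimensional stationary Ornstein-Uhlenbeck process with per-coordinate
#' stationary standard deviation `sigma` and autocorrelation
#' `exp(-dt/tau)`. The exact discretization is used, so the target
#' autocorrelation holds at any frame spacing. Residues sit 6 Angstrom
#' apart along x, emulating the stationary site fluctuations (correlation
#' times of order 1-10 ns at 0.1 ns frame spacing) whose statistics the
#' correlation and RMSF stages estimate.
#'
#' @param n_residues number of residues.
#' @param n_frames number of frames.
#' @param frame_spacing ns between frames (default 0.1).
#' @param tau correlation time(s) in ns, recycled over residues; must
#'   exceed `frame_spacing`.
#' @param sigma stationary per-coordinate fluctuation(s) in Angstrom,
#'   recycled over residues.
#' @param seed integer RNG seed.
#' @return list with `trajectory` and `manifest`. The manifest records
#'   the parameters, the equilibrium coordinates and the per-residue
#'   displacement series (`n_frames x 3` matrices).
#' @export
generate_ou_trajectory <- function(n_residues, n_frames, frame_spacing = 0.1,
                                   tau = 2, sigma = 0.5, seed = 1) {
  tau <- rep_len(tau, n_residues)
  sigma <- rep_len(sigma, n_residues)
  if (any(tau <= frame_spacing))
    stop("tau must exceed the frame spacing for a resolvable process")
  if (any(sigma <= 0)) stop("sigma must be positive")
  atoms <- do.call(rbind, lapply(seq_len(n_residues), .residue_atoms))
  equil <- do.call(rbind, lapply(seq_len(n_residues), function(r)
    sweep(.bb_offsets, 2, c(6 * (r - 1), 0, 0), "+")))
  disp <- withr::with_seed(seed, lapply(seq_len(n_residues), function(r)
    cbind(.ou_path(n_frames, tau[r], sigma[r], frame_spacing),
          .ou_path(n_frames, tau[r], sigma[r], frame_spacing),
          .ou_path(n_frames, tau[r], sigma[r], frame_spacing))))
  xyz <- matrix(0, n_frames, 3 * nrow(atoms))
  for (r in seq_len(n_residues)) {
    rows <- (r - 1) * 4 + 1:4
    for (k in 1:3) {
      cols <- 3 * (rows - 1) + k
      xyz[, cols] <- matrix(rep(equil[rows, k], each = n_frames),
                            n_frames) + disp[[r]][, k]
    }
  }
  list(
    trajectory = trajectory(atoms, xyz, frame_spacing = frame_spacing),
    manifest = list(generator = "ou", seed = seed,
                    n_residues = n_residues, n_frames = n_frames,
                    frame_spacing = frame_spacing, tau = tau,
                    sigma = sigma, equilibrium = equil,
                    displacement = disp))
}

#' Generate a donor/H/acceptor scene toggled at a target occupancy
#'
#' A backbone amide donor (residue 1) and a carbonyl acceptor (residue 3)
#' whose geometry satisfies the 3 Angstrom / 20 degree criterion in a
#' Bernoulli(`occupancy_target`) subset of frames: satisfying frames use
#' a 2.9 Angstrom donor-acceptor distance at 5 degrees deviation,
#' violating frames 3.4 Angstrom. The manifest records the exact
#' satisfying frame set.
#'
#' @param occupancy_target fraction in [0, 1].
#' @param n_frames number of frames.
#' @param seed integer RNG seed.
#' @param frame_spacing ns between frames.
#' @return list with `trajectory` and `manifest` (fields
#'   `satisfied_frames`, `realized_fraction`).
#' @export
generate_hbond_scene <- function(occupancy_target, n_frames, seed = 1,
                                 frame_spacing = 0.1) {
  stopifnot(occupancy_target >= 0, occupancy_target <= 1)
  atoms <- data.frame(
    name = c("N", "H", "CA", "C", "O", "CA"),
    element = c("N", "H", "C", "C", "O", "C"),
    resno = c(1, 1, 1, 3, 3, 3),
    resname = "GLY", chain = "A", stringsAsFactors = FALSE)
  # donor N at origin, H along +x; acceptor O placed either at 2.9 A with
  # 5 degree deviation from linearity (bond) or at 3.4 A (no bond)
  c5 <- cos(5 * pi / 180); s5 <- sin(5 * pi / 180)
  t_on <- -c5 + sqrt(c5^2 - 1 + 2.9^2)
  o_on <- c(1 + t_on * c5, t_on * s5, 0)
  o_off <- c(3.4, 0, 0)
  base <- rbind(N = c(0, 0, 0), H = c(1, 0, 0), CA1 = c(-0.8, -1.2, 0),
                C3 = c(0, 0, 0), O3 = c(0, 0, 0), CA3 = c(0, 0, 0))
  on <- withr::with_seed(seed, runif(n_frames) < occupancy_target)
  xyz <- matrix(0, n_frames, 18)
  for (f in seq_len(n_frames)) {
    crd <- base
    o <- if (on[f]) o_on else o_off
    crd["O3", ] <- o
    crd["C3", ] <- o + c(1.23, 0, 0)
    crd["CA3", ] <- o + c(1.9, 1.1, 0)
    xyz[f, ] <- as.numeric(t(crd))
  }
  list(
    trajectory = trajectory(atoms, xyz, frame_spacing = frame_spacing),
    manifest = list(generator = "hbond_scene", seed = seed,
                    occupancy_target = occupancy_target,
                    n_frames = n_frames,
                    satisfied_frames = which(on),
                    realized_fraction = mean(on)))
}

#' Generate a water shell around a single-atom site
#'
#' `k_inside` waters are placed with every atom inside `radius` of the
#' site and `k_outside` waters with every atom beyond `radius + 1`
#' Angstrom; positions are re-jittered each frame without crossing the
#' boundary, so the per-frame count within `radius` is exactly
#' `k_inside`.
#'
#' @param k_inside,k_outside water counts.
#' @param radius shell radius in Angstrom (default 5).
#' @param n_frames number of frames.
#' @param seed integer RNG seed.
#' @param frame_spacing ns between frames.
#' @return list with `trajectory` and `manifest` (field `counts`:
#'   per-frame expected count).
#' @export
generate_water_shell <- function(k_inside, k_outside, radius = 5.0,
                                 n_frames = 10, seed = 1,
                                 frame_spacing = 0.1) {
  stopifnot(k_inside >= 0, k_outside >= 0, radius > 2)
  site <- data.frame(name = "CA", element = "C", resno = 1,
                     resname = "GLY", chain = "A",
                     stringsAsFactors = FALSE)
  nw <- k_inside + k_outside
  waters <- if (nw > 0) do.call(rbind, lapply(seq_len(nw), function(i)
    data.frame(name = c("OH2", "H1", "H2"), element = c("O", "H", "H"),
               resno = 100 + i, resname = "HOH", chain = "W",
               stringsAsFactors = FALSE))) else NULL
  atoms <- rbind(site, waters)
  h_off <- rbind(c(0.6, 0.6, 0), c(-0.6, 0.6, 0))
  place <- function(r_o) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    o <- r_o * u
    rbind(o, o + h_off[1, ], o + h_off[2, ])
  }
  xyz <- withr::with_seed(seed, {
    m <- matrix(0, n_frames, 3 * nrow(atoms))
    for (f in seq_len(n_frames)) {
      crd <- matrix(0, nrow(atoms), 3)
      row <- 2
      for (i in seq_len(k_inside)) {
        # O no farther than radius - 0.9 so the H atoms stay inside too
        crd[row + 0:2, ] <- place(runif(1, 1.2, radius - 0.9))
        row <- row + 3
      }
      for (i in seq_len(k_outside)) {
        crd[row + 0:2, ] <- place(radius + 1 + 0.9 + runif(1, 0, 3))
        row <- row + 3
      }
      m[f, ] <- as.numeric(t(crd))
    }
    m
  })
  list(
    trajectory = trajectory(atoms, xyz, frame_spacing = frame_spacing),
    manifest = list(generator = "water_shell", seed = seed,
                    k_inside = k_inside, k_outside = k_outside,
                    radius = radius,
                    counts = rep(k_inside, n_frames)))
}

#' Generate a pair of aromatic-plane triplets at a controlled angle
#'
#' Two three-atom planar triplets (named like a Trp ring: CG, CD2, CE2);
#' the second is the first rotated about x by the requested angle plus a
#' Gaussian jitter, then translated 5 Angstrom away. The manifest stores
#' the per-frame true inter-plane angle folded into [0, 90] degrees.
#'
#' @param angle_deg target angle in degrees, in [0, 90].
#' @param n_frames number of frames.
#' @param jitter_deg standard deviation of the per-frame angular jitter.
#' @param seed integer RNG seed.
#' @param frame_spacing ns between frames.
#' @return list with `trajectory`, `manifest` (field `angles`: per-frame
#'   folded angle), and the two `plane_spec`s under `specs`.
#' @export
generate_ring_pair <- function(angle_deg, n_frames = 100, jitter_deg = 0,
                               seed = 1, frame_spacing = 0.1) {
  stopifnot(angle_deg >= 0, angle_deg <= 90)
  tri <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(0.7, 1.2, 0))
  atoms <- data.frame(
    name = rep(c("CG", "CD2", "CE2"), 2), element = "C",
    resno = rep(c(1, 2), each = 3), resname = "TRP", chain = "A",
    stringsAsFactors = FALSE)
  theta <- withr::with_seed(seed,
    angle_deg + rnorm(n_frames, sd = jitter_deg))
  fold <- function(a) {
    a <- abs(a) %% 180
    ifelse(a > 90, 180 - a, a)
  }
  xyz <- matrix(0, n_frames, 18)
  for (f in seq_len(n_frames)) {
    th <- theta[f] * pi / 180
    rot <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
    b <- sweep(tri %*% t(rot), 2, c(5, 0, 0), "+")
    xyz[f, ] <- as.numeric(t(rbind(tri, b)))
  }
  list(
    trajectory = trajectory(atoms, xyz, frame_spacing = frame_spacing),
    manifest = list(generator = "ring_pair", seed = seed,
                    angle_deg = angle_deg, jitter_deg = jitter_deg,
                    angles = fold(theta)),
    specs = list(plane_spec(1, resname = "TRP"),
                 plane_spec(2, resname = "TRP")))
}

# deterministic codon for each amino acid: first codon in lexicographic
# order of the standard genetic code
.aa_to_codon <- function() {
  tab <- .codon_table()
  split_codons <- split(names(tab), tab)
  vapply(split_codons, function(x) sort(x)[1], character(1))
}

#' Generate a toy codon alignment with designated conserved and variable
#' columns
#'
#' Every column not listed in `variable_column_spec` is fully conserved:
#' one amino acid (from `conserved_columns` when given there, otherwise
#' drawn once from the seed) encoded by the same codon in every species.
#' Variable columns draw each species' state from the given categorical
#' distribution. This emulates the composition structure of a
#' cross-species site survey: one dominant state with minority states.
#'
#' @param n_species number of sequences.
#' @param n_sites number of codon columns.
#' @param conserved_columns named character vector: column index ->
#'   amino-acid letter forced at that column.
#' @param variable_column_spec named list: column index -> named
#'   probability vector over amino-acid letters.
#' @param seed integer RNG seed.
#' @return list with `alignment` (an `msa`, kind codon) and `manifest`
#'   (per-column truth: state or distribution).
#' @export
generate_toy_alignment <- function(n_species, n_sites,
                                   conserved_columns = c(),
                                   variable_column_spec = list(),
                                   seed = 1) {
  codon_of <- .aa_to_codon()
  aa_pool <- setdiff(names(codon_of), "*")
  var_cols <- as.integer(names(variable_column_spec))
  stopifnot(all(var_cols >= 1), all(var_cols <= n_sites))
  withr::with_seed(seed, {
    col_aa <- sample(aa_pool, n_sites, replace = TRUE)
    if (length(conserved_columns) > 0)
      col_aa[as.integer(names(conserved_columns))] <-
        unname(conserved_columns)
    states <- matrix(rep(col_aa, each = n_species), n_species, n_sites)
    for (j in var_cols) {
      p <- variable_column_spec[[as.character(j)]]
      states[, j] <- sample(names(p), n_species, replace = TRUE,
                            prob = as.numeric(p))
    }
    seqs <- apply(states, 1, function(row)
      paste(codon_of[row], collapse = ""))
    names(seqs) <- sprintf("species_%03d", seq_len(n_species))
    list(alignment = msa(seqs, kind = "codon"),
         manifest = list(generator = "toy_alignment", seed = seed,
                         n_species = n_species, n_sites = n_sites,
                         column_aa = col_aa,
                         variable_columns = variable_column_spec,
                         states = states))
  })
}
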