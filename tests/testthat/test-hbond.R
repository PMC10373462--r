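# A 5-atom scene: donor amide (N,H) in residue 1, acceptor carbonyl O in
# residue 3, placed by explicit geometry.
hb_scene <- function(no_dist, dev_deg) {
  atoms <- data.frame(
    name = c("N", "H", "CA", "O", "C"),
    element = c("N", "H", "C", "O", "C"),
    resno = c(1, 1, 1, 3, 3), resname = "GLY", chain = "A",
    stringsAsFactors = FALSE)
  th <- dev_deg * pi / 180
  # H at (1,0,0); acceptor along a ray at `dev_deg` off linearity with
  # donor-acceptor distance no_dist
  tt <- -cos(th) + sqrt(cos(th)^2 - 1 + no_dist^2)
  o <- c(1 + tt * cos(th), tt * sin(th), 0)
  crd <- rbind(c(0, 0, 0), c(1, 0, 0), c(-0.8, -1.1, 0), o,
               o + c(1.2, 0.4, 0))
  make_traj(atoms, list(crd))
}

test_that("the 3 A / 20 degree criterion admits and rejects as specified", {
  hit <- detect_frame_hbonds(hb_scene(2.9, 0), 1)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$distance, 2.9, tolerance = 1e-9)
  expect_equal(nrow(detect_frame_hbonds(hb_scene(3.1, 0), 1)), 0)
  expect_equal(nrow(detect_frame_hbonds(hb_scene(2.8, 25), 1)), 0)
  edge <- detect_frame_hbonds(hb_scene(2.8, 19), 1)
  expect_equal(nrow(edge), 1)
  expect_equal(edge$angle_dev, 19, tolerance = 1e-6)
})

test_that("tightening either cutoff never grows the detected set", {
  g <- generate_hbond_scene(0.7, 40, seed = 12)
  tr <- g$trajectory
  for (f in c(1, 7, 20)) {
    base <- detect_frame_hbonds(tr, f)
    tight_d <- detect_frame_hbonds(tr, f, dist_cutoff = 2.5)
    tight_a <- detect_frame_hbonds(tr, f, max_angle_dev = 3)
    expect_lte(nrow(tight_d), nrow(base))
    expect_lte(nrow(tight_a), nrow(base))
  }
})

test_that("detection matches the brute-force oracle on a crowded random scene", {
  set.seed(13)
  n_res <- 12
  atoms <- do.call(rbind, lapply(seq_len(n_res), function(r)
    data.frame(name = c("N", "H", "CA", "C", "O"),
               element = c("N", "H", "C", "C", "O"),
               resno = r, resname = "ALA", chain = "A",
               stringsAsFactors = FALSE)))
  for (rep in 1:3) {
    centers <- random_coords(n_res, scale = 6)
    crd <- do.call(rbind, lapply(seq_len(n_res), function(r) {
      sweep(rbind(c(0, 0, 0), c(1, 0, 0), c(-0.7, -1.2, 0),
                  c(1.2, 1.6, 0.4), c(2.2, 2.2, 0.4)),
            2, centers[r, ], "+")
    }))
    tr <- make_traj(atoms, list(crd))
    ours <- detect_frame_hbonds(tr, 1)
    donors <- data.frame(atom = which(atoms$name == "N"),
                         h_atom = which(atoms$name == "H"))
    oracle <- brute_hbonds(tr, 1, donors, which(atoms$name == "O"))
    key <- function(d) if (is.null(d) || nrow(d) == 0) character(0) else
      paste(d$donor, d$acceptor)
    expect_setequal(key(ours), key(oracle))
  }
})

test_that("occupancy counts frames and honors the sparsity convention", {
  # bond present in 3 of 10 frames
  on <- hb_scene(2.9, 0); off <- hb_scene(3.4, 0)
  xyz <- rbind(on$xyz, on$xyz, on$xyz, off$xyz[rep(1, 7), ])
  tr <- trajectory(on$atoms, xyz, frame_spacing = 0.1)
  tab <- occupancy_table(tr)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$occupancy, 30)
  # a never-satisfied pair is absent, not 0%
  tab0 <- occupancy_table(trajectory(off$atoms, off$xyz[rep(1, 5), ],
                                     frame_spacing = 0.1))
  expect_equal(nrow(tab0), 0)
})

test_that("occupancy equals the generator's realized toggle fraction", {
  g <- generate_hbond_scene(0.4, 1000, seed = 3)
  tab <- occupancy_table(g$trajectory)
  expect_equal(tab$occupancy, 100 * g$manifest$realized_fraction)
  # and the realized fraction is within 3 binomial sd of the target
  expect_lt(abs(g$manifest$realized_fraction - 0.4),
            3 * sqrt(0.4 * 0.6 / 1000))
})

test_that("occupancy is invariant to frame order", {
  g <- generate_hbond_scene(0.5, 60, seed = 14)
  tr <- g$trajectory
  perm <- withr::with_seed(15, sample(n_frames(tr)))
  tr2 <- trajectory(tr$atoms, tr$xyz[perm, ], frame_spacing = 0.1)
  expect_equal(occupancy_table(tr2)$occupancy,
               occupancy_table(tr)$occupancy)
})

test_that("per-residue averages count both donor and acceptor roles", {
  tr <- hb_scene(2.9, 0)
  tr5 <- trajectory(tr$atoms, tr$xyz[rep(1, 5), ], frame_spacing = 0.1)
  avg <- per_residue_average(tr5)
  expect_equal(avg$mean_hbonds[avg$resno == 1], 1)
  expect_equal(avg$mean_hbonds[avg$resno == 3], 1)
  # half the frames bonded -> 0.5 for each partner
  g <- generate_hbond_scene(1, 4, seed = 16)
  off <- generate_hbond_scene(0, 4, seed = 16)
  tr2 <- trajectory(g$trajectory$atoms,
                    rbind(g$trajectory$xyz, off$trajectory$xyz),
                    frame_spacing = 0.1)
  avg2 <- per_residue_average(tr2)
  expect_equal(sort(avg2$mean_hbonds), c(0.5, 0.5))
})

test_that("alternate distance/angle conventions are exposed", {
  tr <- hb_scene(3.2, 0)   # heavy-atom distance fails, H...A = 2.2 passes
  expect_equal(nrow(detect_frame_hbonds(tr, 1)), 0)
  expect_equal(nrow(detect_frame_hbonds(tr, 1, distance_mode = "hydrogen")), 1)
  # 25 degrees off-linear at the H is only ~16 degrees seen from the
  # donor, so the donor-vertex convention admits what the default rejects
  bent <- hb_scene(2.8, 25)
  expect_equal(nrow(detect_frame_hbonds(bent, 1)), 0)
  expect_equal(nrow(detect_frame_hbonds(bent, 1, angle_vertex = "donor")), 1)
})

test_that("the chemistry table resource loads and validates", {
  tab <- load_donor_acceptor_table()
  expect_true(all(c("role", "resname", "atom") %in% names(tab)))
  expect_true(any(tab$role == "donor" & tab$resname == "TRP" &
                    tab$atom == "NE1"))
  expect_true(any(tab$role == "acceptor" & tab$resname == "*" &
                    tab$atom == "O"))
})
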