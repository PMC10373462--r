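two_site_traj <- function(frames_a, frames_b) {
  atoms <- simple_atoms(2, name = "CB", resno = c(1, 2))
  frames <- Map(function(a, b) rbind(a, b), frames_a, frames_b)
  make_traj(atoms, frames)
}

sdef <- function(r) site_definition(paste0("s", r), r,
                                    selection_mode = "side_chain")

test_that("distance series reproduces fixed and scripted separations", {
  tr <- two_site_traj(list(c(0, 0, 0)), list(c(0, 3, 4)))
  pr <- site_pair("d", sdef(1), sdef(2))
  expect_equal(distance_series(tr, pr)$values, 5)
  # identical sites -> 0
  tr0 <- two_site_traj(list(c(1, 2, 3)), list(c(1, 2, 3)))
  expect_equal(distance_series(tr0, pr)$values, 0)
  # scripted sinusoidal separation matches the script
  d_t <- 10 + 2 * sin(seq(0, 4 * pi, length.out = 50))
  tr2 <- two_site_traj(lapply(d_t, function(d) c(0, 0, 0)),
                       lapply(d_t, function(d) c(d, 0, 0)))
  expect_equal(distance_series(tr2, pr)$values, d_t, tolerance = 1e-9)
})

test_that("distance stats recover i.i.d. normal parameters", {
  x <- withr::with_seed(11, rnorm(10000, mean = 10, sd = 0.3))
  st <- distance_stats(scalar_series(x, 0.1), n_blocks = 20)
  expect_equal(st$fit$means, 10, tolerance = 0.01 * 10)
  expect_equal(st$fit$sds, 0.3, tolerance = 0.1 * 0.3)
  expect_equal(mean(st$block_means), st$mean, tolerance = 1e-12)
  # constant series: zero block sd, no density fit
  st0 <- distance_stats(scalar_series(rep(4, 100), 0.1), n_blocks = 20)
  expect_equal(st0$block_sd, 0)
})

test_that("water counting follows the any-atom rule and the shell manifest", {
  g <- generate_water_shell(2, 5, radius = 5, n_frames = 6, seed = 17)
  cw <- count_waters(g$trajectory,
                     site_definition("s", 1, selection_mode = "all_atoms"),
                     radius = 5)
  expect_equal(cw$counts, g$manifest$counts)
  expect_equal(cw$mean, 2)
  # a water whose only inside atom is an H still counts once
  atoms <- rbind(simple_atoms(1),
                 data.frame(name = c("OH2", "H1", "H2"),
                            element = c("O", "H", "H"), resno = 101,
                            resname = "HOH", chain = "W",
                            stringsAsFactors = FALSE))
  crd <- rbind(c(0, 0, 0), c(5.5, 0, 0), c(4.9, 0.3, 0), c(6.1, 0.3, 0))
  tr <- make_traj(atoms, list(crd))
  cw2 <- count_waters(tr, site_definition("s", 1,
                                          selection_mode = "all_atoms"),
                      radius = 5)
  expect_equal(cw2$counts, 1L)
})

test_that("water counts are monotone in radius and the shell margin holds", {
  g <- generate_water_shell(3, 4, radius = 5, n_frames = 5, seed = 18)
  site <- site_definition("s", 1, selection_mode = "all_atoms")
  counts <- vapply(c(3, 5, 6.5, 12),
                   function(r) count_waters(g$trajectory, site, r)$mean,
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
  # post-hoc boundary scan: inside atoms < radius < outside atoms
  wat <- which(is_water(g$trajectory$atoms$resname))
  for (f in seq_len(n_frames(g$trajectory))) {
    d <- sqrt(rowSums(frame_coords(g$trajectory, f)[wat, ]^2))
    inside <- d[d < 5]; outside <- d[d >= 5]
    expect_length(inside, 9)    # 3 waters x 3 atoms
    expect_gt(min(outside), 5)
  }
  # topology without waters warns and returns zeros
  dry <- make_traj(simple_atoms(1), list(rbind(c(0, 0, 0))))
  expect_warning(cw <- count_waters(dry, site), "no water")
  expect_equal(cw$counts, 0L)
})

test_that("plane angles hit constructed 0/30/60/90 degree scenes", {
  for (ang in c(0, 30, 90)) {
    g <- generate_ring_pair(ang, n_frames = 3, jitter_deg = 0, seed = 19)
    pa <- plane_angle_series(g$trajectory, g$specs[[1]], g$specs[[2]])
    expect_equal(pa$series$values, rep(ang, 3), tolerance = 1e-9)
  }
  # normals constructed at 120 degrees fold to 60
  g <- generate_ring_pair(60, n_frames = 1, jitter_deg = 0, seed = 20)
  tri <- frame_coords(g$trajectory, 1)[1:3, ]
  th <- 120 * pi / 180
  rot <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  crd <- rbind(tri, sweep(tri %*% t(rot), 2, c(5, 0, 0), "+"))
  tr <- make_traj(g$trajectory$atoms, list(crd))
  pa <- plane_angle_series(tr, g$specs[[1]], g$specs[[2]])
  expect_equal(pa$series$values, 60, tolerance = 1e-9)
})

test_that("plane angles stay in [0,90], are symmetric, and jitter averages out", {
  g <- generate_ring_pair(30, n_frames = 1000, jitter_deg = 2, seed = 21)
  pa <- plane_angle_series(g$trajectory, g$specs[[1]], g$specs[[2]])
  expect_true(all(pa$series$values >= 0 & pa$series$values <= 90))
  expect_equal(pa$series$values, g$manifest$angles, tolerance = 1e-9)
  expect_equal(pa$mean, 30, tolerance = 0.5)
  pa_rev <- plane_angle_series(g$trajectory, g$specs[[2]], g$specs[[1]])
  expect_equal(pa_rev$series$values, pa$series$values)
})

test_that("collinear plane triplets are excluded with a warning", {
  atoms <- data.frame(name = rep(c("CG", "CD2", "CE2"), 2), element = "C",
                      resno = rep(1:2, each = 3), resname = "TRP",
                      chain = "A", stringsAsFactors = FALSE)
  good <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(0.7, 1.2, 0))
  flat <- rbind(c(5, 0, 0), c(6, 0, 0), c(7, 0, 0))
  tr <- make_traj(atoms, list(rbind(good, sweep(good, 2, c(5, 0, 0), "+")),
                              rbind(good, flat)))
  expect_warning(
    pa <- plane_angle_series(tr, plane_spec(1, resname = "TRP"),
                             plane_spec(2, resname = "TRP")),
    "collinear")
  expect_equal(pa$n_excluded, 1)
  expect_length(pa$series$values, 1)
})

test_that("geometric outputs are invariant under a global rigid transform", {
  set.seed(22)
  g <- generate_ring_pair(40, n_frames = 20, jitter_deg = 3, seed = 23)
  tr <- g$trajectory
  r <- random_rotation(); t <- c(3, -7, 2)
  xyz2 <- t(apply(tr$xyz, 1, function(row) {
    crd <- matrix(row, ncol = 3, byrow = TRUE)
    as.numeric(t(sweep(crd %*% t(r), 2, t, "+")))
  }))
  tr2 <- trajectory(tr$atoms, xyz2, frame_spacing = 0.1)
  pa1 <- plane_angle_series(tr, g$specs[[1]], g$specs[[2]])
  pa2 <- plane_angle_series(tr2, g$specs[[1]], g$specs[[2]])
  expect_equal(pa2$series$values, pa1$series$values, tolerance = 1e-9)

  gw <- generate_water_shell(2, 3, n_frames = 4, seed = 24)
  trw <- gw$trajectory
  xyzw <- t(apply(trw$xyz, 1, function(row) {
    crd <- matrix(row, ncol = 3, byrow = TRUE)
    as.numeric(t(sweep(crd %*% t(r), 2, t, "+")))
  }))
  trw2 <- trajectory(trw$atoms, xyzw, frame_spacing = 0.1)
  site <- site_definition("s", 1, selection_mode = "all_atoms")
  expect_equal(count_waters(trw2, site)$counts,
               count_waters(trw, site)$counts)
})

test_that("default distance pairs cover the transfer chain and print their definitions", {
  pairs <- default_distance_pairs(fad_resno = 500)
  expect_named(pairs, paste0("d", 1:6))
  expect_equal(pairs$d2$site_a$residue_seqs, 395L)
  expect_equal(pairs$d5$site_b$residue_seqs, 319L)
})
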