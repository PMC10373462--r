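test_that("identical-to-reference trajectories give zero RMSF", {
  g <- generate_ou_trajectory(3, 1, tau = 1, sigma = 0.1, seed = 1)
  crd <- frame_coords(g$trajectory, 1)
  tr <- make_traj(g$trajectory$atoms, replicate(8, crd, simplify = FALSE))
  prof <- rmsf_blocks(tr, n_blocks = 4)
  expect_equal(prof$residues$rmsf_mean, rep(0, 3))
  expect_equal(prof$residues$rmsf_sd, rep(0, 3))
})

test_that("duplicated blocks have zero across-block sd", {
  set.seed(2)
  g <- generate_ou_trajectory(2, 10, tau = 1, sigma = 0.3, seed = 3)
  xyz <- rbind(g$trajectory$xyz, g$trajectory$xyz)
  tr <- trajectory(g$trajectory$atoms, xyz, frame_spacing = 0.1)
  prof <- rmsf_blocks(tr, n_blocks = 2, align = FALSE)
  expect_equal(prof$residues$rmsf_sd, rep(0, 2), tolerance = 1e-12)
})

test_that("isotropic jitter of sd sigma gives RMSF mean near sigma*sqrt(3)", {
  sigma <- 0.2
  # stationary marginal of the OU generator is exactly N(0, sigma^2)
  # about the equilibrium coordinates, which serve as the reference
  g <- generate_ou_trajectory(4, 4000, frame_spacing = 0.1, tau = 0.2,
                              sigma = sigma, seed = 4)
  prof <- rmsf_blocks(g$trajectory, n_blocks = 8, align = FALSE,
                      reference_coords = g$manifest$equilibrium)
  expect_equal(prof$residues$rmsf_mean, rep(sigma * sqrt(3), 4),
               tolerance = 0.05)
})

test_that("pooled RMSF equals the block-mean-square identity and scales linearly", {
  g <- generate_ou_trajectory(3, 400, tau = 1, sigma = 0.5, seed = 5)
  tr <- g$trajectory
  prof <- rmsf_blocks(tr, n_blocks = 4, align = FALSE)
  expect_equal(prof$residues$rmsf_pooled,
               sqrt(rowMeans(prof$block_values^2)), tolerance = 1e-12)
  # scaling all fluctuations by c scales every RMSF mean by c
  ref <- tr$xyz[rep(1, n_frames(tr)), ]
  tr_scaled <- trajectory(tr$atoms, ref + 2 * (tr$xyz - ref),
                          frame_spacing = 0.1)
  prof2 <- rmsf_blocks(tr_scaled, n_blocks = 4, align = FALSE)
  expect_equal(prof2$residues$rmsf_mean, 2 * prof$residues$rmsf_mean,
               tolerance = 1e-9)
})

test_that("aligned RMSF is invariant under a global rigid transform", {
  set.seed(6)
  g <- generate_ou_trajectory(4, 60, tau = 1, sigma = 0.4, seed = 7)
  tr <- g$trajectory
  prof <- rmsf_blocks(tr, n_blocks = 3, align = TRUE)
  r <- random_rotation(); t <- c(4, -2, 9)
  xyz2 <- t(apply(tr$xyz, 1, function(row) {
    crd <- matrix(row, ncol = 3, byrow = TRUE)
    as.numeric(t(sweep(crd %*% t(r), 2, t, "+")))
  }))
  tr2 <- trajectory(tr$atoms, xyz2, frame_spacing = 0.1)
  prof2 <- rmsf_blocks(tr2, n_blocks = 3, align = TRUE)
  expect_equal(prof2$residues$rmsf_mean, prof$residues$rmsf_mean,
               tolerance = 1e-9)
})

test_that("trailing frames are dropped with a warning; too many blocks error", {
  g <- generate_ou_trajectory(2, 11, tau = 1, sigma = 0.3, seed = 8)
  expect_warning(rmsf_blocks(g$trajectory, n_blocks = 2), "trailing")
  expect_error(rmsf_blocks(g$trajectory, n_blocks = 50), "exceeds")
})

test_that("sequence window picks the 10 sequence neighbors, clipped sensibly", {
  g <- generate_ou_trajectory(12, 20, tau = 1, sigma = 0.3, seed = 9)
  prof <- rmsf_blocks(g$trajectory, n_blocks = 2, align = FALSE)
  vals <- site_rmsf_distribution(prof, g$trajectory,
                                 site_definition("s6", 6),
                                 mode = "sequence_10")
  res <- attr(vals, "residues")
  expect_length(res, 10)
  expect_false("A:6" %in% res)
  expect_setequal(res, paste0("A:", c(1:5, 7:11)))
  expect_length(vals, 10 * prof$n_blocks)
  # site at the chain end: window extends inward to keep 10 residues
  vals2 <- site_rmsf_distribution(prof, g$trajectory,
                                  site_definition("s1", 1),
                                  mode = "sequence_10")
  expect_setequal(attr(vals2, "residues"), paste0("A:", 2:11))
})

test_that("radius mode matches the frozen spatial neighborhood", {
  g <- generate_ou_trajectory(8, 20, tau = 1, sigma = 0.1, seed = 10)
  prof <- rmsf_blocks(g$trajectory, n_blocks = 2, align = FALSE)
  site <- site_definition("s4", 4)
  vals <- site_rmsf_distribution(prof, g$trajectory, site,
                                 mode = "radius_10A", radius = 10)
  expect_setequal(attr(vals, "residues"),
                  neighborhood(g$trajectory, site, radius = 10))
})

test_that("gaussian fit recovers parameters and clears the r2 quality bar", {
  x <- withr::with_seed(7, rnorm(10000, mean = 1.0, sd = 0.1))
  f <- fit_gaussian(x, 1)
  expect_equal(f$means, 1.0, tolerance = 0.05)
  expect_equal(f$sds, 0.1, tolerance = 0.1 * 0.1 + 0.01)
  expect_gt(f$r2, 0.8)
})

test_that("two-component gaussian fit resolves a constructed mixture", {
  x <- withr::with_seed(8, c(rnorm(5000, 0.5, 0.05), rnorm(5000, 1.0, 0.05)))
  f2 <- fit_gaussian(x, 2)
  expect_equal(f2$means, c(0.5, 1.0), tolerance = 0.1)
  expect_equal(sum(f2$weights), 1, tolerance = 1e-12)
  f1 <- fit_gaussian(x, 1)
  expect_gt(f2$r2, f1$r2)
  expect_identical(fit_gaussian_auto(x)$n_components, 2L)
  # unimodal data keeps the single component
  y <- withr::with_seed(9, rnorm(5000, 1, 0.1))
  expect_identical(fit_gaussian_auto(y)$n_components, 1L)
})

test_that("degenerate samples are rejected by the gaussian fit", {
  expect_error(fit_gaussian(rep(1, 100)), "degenerate")
  expect_error(fit_gaussian(rnorm(5)), "at least 10")
})

test_that("two fluctuation populations yield a bimodal pooled distribution", {
  g <- generate_ou_trajectory(10, 2000, frame_spacing = 0.1, tau = 0.2,
                              sigma = rep(c(0.1, 0.45), each = 5),
                              seed = 11)
  prof <- rmsf_blocks(g$trajectory, n_blocks = 20, align = FALSE)
  vals <- site_rmsf_distribution(prof, g$trajectory,
                                 site_definition("mid", 5),
                                 mode = "sequence_10")
  f1 <- fit_gaussian(vals, 1)
  f2 <- fit_gaussian(vals, 2)
  expect_gt(f2$r2, f1$r2)
  expect_gt(diff(f2$means), 0.2)
})
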