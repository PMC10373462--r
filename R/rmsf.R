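#' Block-subsampled per-residue RMSF
#'
#' The trajectory is split into `n_blocks` contiguous blocks of equal
#' length (a trailing remainder is dropped with a warning). Within each
#' block, the RMSF of a residue is the root of the mean — over block
#' frames and the residue's backbone atoms — squared displacement from
#' the reference frame. The profile reports the mean and standard
#' deviation of the per-block values across blocks, plus the pooled
#' all-frame RMSF.
#'
#' With `align = TRUE` (default) each frame is Kabsch-superposed onto the
#' reference over the whole-protein backbone before displacements are
#' taken, so the profile is invariant under per-frame rigid motion.
#'
#' @param traj a `trajectory`.
#' @param sel atom indices whose residues are profiled
#'   (default [backbone_indices()]).
#' @param n_blocks number of blocks (default 20).
#' @param reference_frame 1-based frame used as the displacement
#'   reference (default 1: the configuration at the start of the run).
#' @param reference_coords optional explicit `n_atoms x 3` reference
#'   coordinate matrix (e.g. the minimized structure prior to
#'   production), overriding `reference_frame`.
#' @param align superpose frames on the reference first.
#' @return object of class `rmsf_profile`: list with `residues`
#'   (data.frame: key, chain, resno, resname, rmsf_mean, rmsf_sd,
#'   rmsf_pooled), `block_values` (residues x blocks matrix),
#'   `n_blocks`, `frames_per_block`, `reference_frame`, `aligned`.
#' @export
rmsf_blocks <- function(traj, sel = backbone_indices(traj), n_blocks = 20,
                        reference_frame = 1, reference_coords = NULL,
                        align = TRUE) {
  nf <- n_frames(traj)
  if (n_blocks > nf) stop("n_blocks (", n_blocks,
                          ") exceeds number of frames (", nf, ")")
  fpb <- nf %/% n_blocks
  used <- fpb * n_blocks
  if (used < nf)
    warning("dropping trailing ", nf - used,
            " frame(s) not filling a block")
  ref <- if (is.null(reference_coords)) {
    frame_coords(traj, reference_frame)
  } else {
    stopifnot(nrow(reference_coords) == n_atoms(traj))
    as.matrix(reference_coords)
  }
  keys <- .residue_keys(traj)[sel]
  res_of <- factor(keys, levels = unique(keys))

  # per-frame, per-residue mean squared displacement of the selected atoms
  msd <- matrix(0, used, nlevels(res_of))
  fit_idx <- sel
  for (f in seq_len(used)) {
    crd <- frame_coords(traj, f)
    if (align) crd <- kabsch_superpose(crd, ref, fit_idx = fit_idx)$coords
    d2 <- rowSums((crd[sel, , drop = FALSE] - ref[sel, , drop = FALSE])^2)
    msd[f, ] <- tapply(d2, res_of, mean)
  }
  block_of <- rep(seq_len(n_blocks), each = fpb)
  block_ms <- apply(msd, 2, function(col) tapply(col, block_of, mean))
  block_rmsf <- t(sqrt(block_ms))          # residues x blocks
  rt <- residue_table(traj)
  rt <- rt[match(levels(res_of), rt$key), ]
  residues <- data.frame(
    key = rt$key, chain = rt$chain, resno = rt$resno, resname = rt$resname,
    rmsf_mean = rowMeans(block_rmsf),
    rmsf_sd = apply(block_rmsf, 1, sd),
    rmsf_pooled = sqrt(colMeans(msd)),
    stringsAsFactors = FALSE)
  rownames(residues) <- NULL
  structure(list(residues = residues, block_values = block_rmsf,
                 n_blocks = as.integer(n_blocks),
                 frames_per_block = as.integer(fpb),
                 reference_frame = reference_frame, aligned = align),
            class = "rmsf_profile")
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat(sprintf("RMSF profile: %d residues, %d blocks x %d frames\n",
              nrow(x$residues), x$n_blocks, x$frames_per_block))
  invisible(x)
}

#' Pooled per-block RMSF sample around a site
#'
#' Collects the per-block, per-residue RMSF values of the residues around
#' a site, either the 10 sequence neighbors (`sequence_10`: the +-5
#' window minus the site, extended at chain ends so 10 residues are kept
#' where possible) or the frozen spatial neighborhood within 10 Angstrom
#' (`radius_10A`).
#'
#' @param profile an `rmsf_profile`.
#' @param traj the `trajectory` the profile came from.
#' @param site a `site_definition` (single residue sites are typical).
#' @param mode `"sequence_10"` or `"radius_10A"`.
#' @param radius radius for `radius_10A` mode (Angstrom).
#' @return numeric vector of pooled per-block RMSF values, with
#'   attributes `residues` (keys used) and `mode`.
#' @export
site_rmsf_distribution <- function(profile, traj, site,
                                   mode = c("sequence_10", "radius_10A"),
                                   radius = 10) {
  mode <- match.arg(mode)
  rt <- profile$residues
  if (mode == "sequence_10") {
    keep <- character(0)
    for (rs in site$residue_seqs) {
      i <- which(rt$resno == rs)
      if (length(i) == 0) stop("site '", site$label, "': residue ", rs,
                               " not in profile")
      i <- i[1]
      cand <- setdiff(order(abs(seq_len(nrow(rt)) - i)), i)
      keep <- union(keep, rt$key[head(cand[abs(cand - i) >= 1], 10)])
    }
    # prefer the symmetric +-5 window; order() above already ranks by
    # sequence distance so clipped ends are topped up from the other side
    keys <- keep
  } else {
    keys <- neighborhood(traj, site, radius = radius,
                         reference_frame = profile$reference_frame)
  }
  rows <- which(rt$key %in% keys)
  if (length(rows) == 0) stop("site '", site$label,
                              "': no surrounding residues in profile")
  vals <- as.numeric(profile$block_values[rows, , drop = FALSE])
  attr(vals, "residues") <- rt$key[rows]
  attr(vals, "mode") <- mode
  vals
}

#' Least-squares Gaussian fit of a sample's density
#'
#' Bins the sample (Freedman-Diaconis rule, falling back to 30 bins when
#' the IQR degenerates) and fits a 1- or 2-component Gaussian mixture
#' density by Levenberg-Marquardt least squares on the bin densities.
#' Initialization is deterministic: moments for one component, the
#' lower/upper halves split at the median for two.
#'
#' @param sample numeric vector (>= 10 values).
#' @param n_components 1 or 2.
#' @return object of class `gaussian_fit`: list with `means`, `sds`,
#'   `weights` (sum to 1), `r2`, `n_components`, `breaks`.
#' @export
fit_gaussian <- function(sample, n_components = 1) {
  sample <- as.numeric(sample)
  if (length(sample) < 10) stop("need at least 10 values")
  if (sd(sample) == 0) stop("degenerate sample: all values identical")
  k <- as.integer(n_components)
  stopifnot(k %in% c(1L, 2L))
  nb <- tryCatch(grDevices::nclass.FD(sample), error = function(e) 30L)
  if (!is.finite(nb) || nb < 5) nb <- 30L
  hh <- graphics::hist(sample, breaks = nb, plot = FALSE)
  x <- hh$mids; y <- hh$density
  sd_floor <- max(diff(range(sample)) * 1e-3, .Machine$double.eps)

  if (k == 1) {
    par0 <- c(mean(sample), log(max(sd(sample), sd_floor)))
    fn <- function(p) dnorm(x, p[1], max(exp(p[2]), sd_floor)) - y
  } else {
    med <- median(sample)
    lo <- sample[sample <= med]; hi <- sample[sample > med]
    par0 <- c(0,                       # logit weight
              mean(lo), log(max(sd(lo), sd_floor)),
              mean(hi), log(max(sd(hi), sd_floor)))
    fn <- function(p) {
      w <- stats::plogis(p[1])
      w * dnorm(x, p[2], max(exp(p[3]), sd_floor)) +
        (1 - w) * dnorm(x, p[4], max(exp(p[5]), sd_floor)) - y
    }
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = fn,
                            control = minpack.lm::nls.lm.control(maxiter = 300))
  p <- fit$par
  if (k == 1) {
    means <- p[1]; sds <- max(exp(p[2]), sd_floor); weights <- 1
  } else {
    w <- stats::plogis(p[1])
    means <- c(p[2], p[4]); sds <- pmax(exp(c(p[3], p[5])), sd_floor)
    weights <- c(w, 1 - w)
    ord <- order(means)
    means <- means[ord]; sds <- sds[ord]; weights <- weights[ord]
  }
  rss <- sum(fit$fvec^2); tss <- sum((y - mean(y))^2)
  structure(list(means = means, sds = sds, weights = weights,
                 r2 = if (tss > 0) 1 - rss / tss else NA_real_,
                 n_components = k, breaks = hh$breaks),
            class = "gaussian_fit")
}

#' Fit 1- and 2-component Gaussians and keep the better-supported model
#'
#' The 2-component fit is retained only when its coefficient of
#' determination exceeds the 1-component one by at least `delta_r2`
#' (default 0.05), mirroring the sparing use of double Gaussians for
#' distributions with a visible second mode.
#'
#' @inheritParams fit_gaussian
#' @param delta_r2 improvement required to prefer two components.
#' @return a `gaussian_fit`.
#' @export
fit_gaussian_auto <- function(sample, delta_r2 = 0.05) {
  f1 <- fit_gaussian(sample, 1)
  f2 <- tryCatch(fit_gaussian(sample, 2), error = function(e) NULL)
  if (!is.null(f2) && isTRUE(f2$r2 > f1$r2 + delta_r2)) f2 else f1
}
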