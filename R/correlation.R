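#' Center-of-mass length series of a site and its frozen neighborhood
#'
#' For every frame, the mass-weighted center of mass of the site's
#' backbone atoms together with the backbone atoms of all amino-acid
#' residues within `radius` of the site (membership evaluated once at
#' `reference_frame` and frozen — see [neighborhood()]), reduced to the
#' length of the CoM vector. By default coordinates are first expressed
#' relative to the whole-protein backbone CoM of the same frame, which
#' removes rigid-body drift; `origin = "raw"` uses box coordinates.
#'
#' @param traj a `trajectory`.
#' @param site a `site_definition`.
#' @param radius neighborhood radius in Angstrom (default 10).
#' @param reference_frame frame at which the neighborhood is frozen.
#' @param origin `"protein_com"` (default) or `"raw"`.
#' @return object of class `scalar_series`: list with `values` (one per
#'   frame) and `spacing` (ns).
#' @export
com_length_series <- function(traj, site, radius = 10, reference_frame = 1,
                              origin = c("protein_com", "raw")) {
  origin <- match.arg(origin)
  site_bb <- select_site(traj, site, mode = "backbone")
  nb_keys <- neighborhood(traj, site, radius = radius,
                          reference_frame = reference_frame)
  keys <- .residue_keys(traj)
  a <- traj$atoms
  nb_bb <- which(keys %in% nb_keys & a$name %in% .backbone_names)
  if (length(nb_keys) == 0)
    warning("site '", site$label,
            "': empty neighborhood; using site backbone only")
  idx <- sort(unique(c(site_bb, nb_bb)))
  com <- .com_series(traj, idx)
  if (origin == "protein_com") com <- com - .com_series(traj, backbone_indices(traj))
  scalar_series(sqrt(rowSums(com^2)), spacing = traj$frame_spacing)
}

#' Construct a scalar per-frame series
#' @param values numeric vector, one value per frame.
#' @param spacing frame spacing in ns.
#' @return object of class `scalar_series`.
#' @export
scalar_series <- function(values, spacing) {
  stopifnot(is.numeric(values), spacing > 0)
  structure(list(values = as.numeric(values), spacing = spacing),
            class = "scalar_series")
}

#' Normalized autocorrelation of a scalar series
#'
#' The autocovariance of the mean-centered series, with the unbiased
#' `1/(T - h)` lag normalization, divided by the lag-0 value, so the
#' curve equals 1 at lag 0 by construction (and an alternating series
#' has exactly -1 at lag 1). A constant series has no defined
#' autocorrelation and raises an error.
#'
#' @param series a `scalar_series` (or plain numeric vector with
#'   `spacing` given).
#' @param max_lag largest lag in ns; default 10% of the series length
#'   (longer lags are noise-dominated).
#' @param spacing frame spacing in ns, required when `series` is a bare
#'   numeric vector.
#' @return object of class `acf_curve`: list with `lags` (ns) and
#'   `values` (dimensionless), lag 0 first.
#' @export
autocorrelation <- function(series, max_lag = NULL, spacing = NULL) {
  if (inherits(series, "scalar_series")) {
    x <- series$values; spacing <- series$spacing
  } else {
    x <- as.numeric(series)
    if (is.null(spacing)) stop("spacing required for a bare numeric series")
  }
  if (length(x) < 2) stop("series too short for autocorrelation")
  if (var(x) == 0) stop("undefined autocorrelation: series is constant")
  max_lag_frames <- if (is.null(max_lag)) {
    max(1L, floor(length(x) * 0.1))
  } else {
    max(1L, min(length(x) - 1L, floor(max_lag / spacing)))
  }
  ac <- drop(acf(x, lag.max = max_lag_frames, plot = FALSE,
                 demean = TRUE)$acf)
  T_ <- length(x)
  hs <- seq_along(ac) - 1
  ac <- ac * T_ / (T_ - hs)   # biased-to-unbiased lag normalization
  ac[1] <- 1
  structure(list(lags = hs * spacing, values = ac),
            class = "acf_curve")
}

# Stick-breaking map from 2 free parameters to 3 non-negative weights
# summing to 1 exactly.
.weights_from_par <- function(b) {
  s1 <- stats::plogis(b[1]); s2 <- stats::plogis(b[2])
  w1 <- s1; w2 <- (1 - s1) * s2
  c(w1, w2, 1 - w1 - w2)
}

#' Fit a constrained mixture of exponential decays to an autocorrelation
#' curve
#'
#' Least-squares fit of `sum_i A_i * exp(-h / tau_i)` with the hard
#' constraints `A_i >= 0`, `sum A_i = 1` (enforced exactly by a
#' stick-breaking parameterization) and `tau_i > 0` (bounded logistic
#' parameterization). Initialization is a deterministic multi-start grid
#' with decay times log-spaced over the fitted lag window, so repeated
#' fits are identical. Three components by default, following the usual
#' practice of resolving fast librational, intermediate and slow
#' collective decay.
#'
#' Two numerical guards keep the estimate away from long-lag noise:
#' with `fit_window = "adaptive"` (default) the curve is truncated at 10
#' times the lag where it first drops below 1/e (estimation beyond a few
#' decay times only adds noise), and decay times are constrained to the
#' fitted window, since slower decays are not resolvable from it.
#'
#' @param curve an `acf_curve` (>= 10 lags).
#' @param n_components number of exponentials (default 3).
#' @param fit_window `"adaptive"` (default) or `"full"`.
#' @return object of class `exp_mixture_fit`: list with `weights`,
#'   `times` (ns, ascending), `r2` (coefficient of determination over
#'   the fitted lags), `tau_c` (weighted mean time, ns), `rss`,
#'   `window` (last fitted lag, ns).
#' @export
fit_exponential_mixture <- function(curve, n_components = 3,
                                    fit_window = c("adaptive", "full")) {
  stopifnot(inherits(curve, "acf_curve"))
  fit_window <- match.arg(fit_window)
  h <- curve$lags; y <- curve$values
  if (length(h) < 10) stop("need at least 10 lags to fit")
  k <- as.integer(n_components)
  stopifnot(k >= 1, k <= 3)
  spacing <- if (length(h) > 1) h[2] - h[1] else 1
  if (fit_window == "adaptive") {
    below <- which(y < exp(-1))
    if (length(below) > 0) {
      cut <- min(length(h), max(10, ceiling(10 * below[1])))
      h <- h[seq_len(cut)]; y <- y[seq_len(cut)]
    }
  }
  t_lo <- max(spacing, 1e-6)
  W <- max(h[length(h)], t_lo * 10)   # decay times constrained to (0, W]
  grid <- exp(seq(log(t_lo), log(W * 0.99), length.out = 4))
  tau_of <- function(l) W * stats::plogis(l)
  l_of <- function(tau) stats::qlogis(pmin(tau / W, 0.99))

  model <- function(par) {
    w <- if (k == 3) .weights_from_par(par[1:2])
         else if (k == 2) { s <- stats::plogis(par[1]); c(s, 1 - s) }
         else 1
    tau <- tau_of(par[(k - 1 + 1):(k - 1 + k)])
    drop(exp(-outer(h, 1 / tau)) %*% w)
  }
  resid_fun <- function(par) model(par) - y

  starts <- list()
  if (k == 3) {
    for (i in 1:3) for (j in (i + 1):4) {
      mid <- sqrt(grid[i] * grid[j])
      starts[[length(starts) + 1]] <-
        c(0, 0, l_of(c(grid[i], mid, grid[j])))
    }
  } else if (k == 2) {
    for (i in 1:3) for (j in (i + 1):4)
      starts[[length(starts) + 1]] <- c(0, l_of(c(grid[i], grid[j])))
  } else {
    for (g in grid) starts[[length(starts) + 1]] <- l_of(g)
  }

  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ptol = 1e-12, ftol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15)
      best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best))
    stop("exponential mixture fit failed to converge from any start")

  w <- if (k == 3) .weights_from_par(best$par[1:2])
       else if (k == 2) { s <- stats::plogis(best$par[1]); c(s, 1 - s) }
       else 1
  tau <- tau_of(best$par[(k - 1 + 1):(k - 1 + k)])
  ord <- order(tau)
  w <- w[ord]; tau <- tau[ord]
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - best$rss / tss else NA_real_
  structure(list(weights = w, times = tau, r2 = r2,
                 tau_c = sum(w * tau), rss = best$rss,
                 n_components = k, window = h[length(h)]),
            class = "exp_mixture_fit")
}

#' @export
print.exp_mixture_fit <- function(x, ...) {
  cat(sprintf("%d-exponential fit: tau_c = %.4g ns, r2 = %.4f\n",
              x$n_components, x$tau_c, x$r2))
  cat(sprintf("  A = (%s), tau = (%s) ns\n",
              paste(sprintf("%.3f", x$weights), collapse = ", "),
              paste(sprintf("%.3g", x$times), collapse = ", ")))
  invisible(x)
}

#' Cumulative correlation time of an exponential-mixture fit
#'
#' The weight-averaged decay time `sum_i A_i * tau_i`, the standard
#' cumulative correlation time of a multi-exponential relaxation.
#'
#' @param fit an `exp_mixture_fit`.
#' @return correlation time in ns.
#' @export
cumulative_correlation_time <- function(fit) {
  stopifnot(inherits(fit, "exp_mixture_fit"))
  sum(fit$weights * fit$times)
}

#' Suggest a block-subsampling scheme
#'
#' Splits a trajectory of `total_length` ns into `n_blocks` contiguous
#' blocks and warns when the block length is shorter than twice the
#' correlation time, i.e. when the blocks cannot plausibly be treated as
#' statistically independent samples.
#'
#' @param total_length trajectory length in ns.
#' @param tau_c correlation time in ns.
#' @param n_blocks number of blocks (default 20).
#' @return list with `n_blocks`, `block_length` (ns) and `independent`
#'   (logical).
#' @export
suggest_block_scheme <- function(total_length, tau_c, n_blocks = 20) {
  stopifnot(total_length > 0, n_blocks >= 2)
  if (tau_c >= total_length)
    stop("correlation time (", tau_c,
         " ns) is not shorter than the trajectory (", total_length, " ns)")
  block_length <- total_length / n_blocks
  ok <- block_length >= 2 * tau_c
  if (!ok)
    warning(sprintf(
      "block length %.3g ns < 2 * tau_c = %.3g ns: blocks are not plausibly independent",
      block_length, 2 * tau_c))
  list(n_blocks = as.integer(n_blocks), block_length = block_length,
       independent = ok)
}
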