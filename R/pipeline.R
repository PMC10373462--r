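#' Build an analysis configuration
#'
#' Collects everything a full per-variant analysis needs: trajectories
#' (paths to multi-model PDBs, or in-memory `trajectory` objects), site
#' definitions, distance pairs, cutoffs and the block scheme. Defaults
#' follow the usual choices for a cryptochrome tetrad study: 3 Angstrom /
#' 20 degree hydrogen-bond criterion, 5 Angstrom water shell, 10 Angstrom
#' site neighborhood, 20 blocks.
#'
#' @param trajectories named list (variant label -> path or `trajectory`).
#' @param sites list of `site_definition`s analysed per variant.
#' @param pairs named list of `site_pair`s (default
#'   [default_distance_pairs()] when the topology carries a FAD, else
#'   empty).
#' @param hbond_cutoff,hbond_angle_dev,water_radius,neighborhood_radius
#'   cutoffs (Angstrom / degrees).
#' @param n_blocks block count for all block statistics.
#' @param frame_spacing ns per frame, used when trajectories are read
#'   from disk.
#' @param align superpose frames for RMSD/RMSF.
#' @param seed seed recorded in the report (analyses are deterministic;
#'   the seed matters only when callers generate inputs from it).
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(trajectories, sites, pairs = NULL,
                            hbond_cutoff = 3.0, hbond_angle_dev = 20,
                            water_radius = 5.0, neighborhood_radius = 10,
                            n_blocks = 20, frame_spacing = 0.1,
                            align = TRUE, seed = 1) {
  stopifnot(length(trajectories) >= 1, !is.null(names(trajectories)),
            !anyDuplicated(names(trajectories)),
            hbond_cutoff > 0, hbond_angle_dev > 0, water_radius > 0,
            neighborhood_radius > 0)
  structure(
    list(trajectories = trajectories, sites = sites, pairs = pairs,
         hbond_cutoff = hbond_cutoff, hbond_angle_dev = hbond_angle_dev,
         water_radius = water_radius,
         neighborhood_radius = neighborhood_radius,
         n_blocks = n_blocks, frame_spacing = frame_spacing,
         align = align, seed = seed),
    class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Keys mirror the [analysis_config()] arguments; `trajectories` maps
#' variant labels to PDB paths (relative paths resolved against the
#' config file), `sites` is a list of `{label, residues, mode}` entries.
#'
#' @param path YAML file.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  trajs <- lapply(y$trajectories, function(p)
    if (file.exists(p)) p else file.path(base, p))
  sites <- lapply(y$sites, function(s)
    site_definition(s$label, unlist(s$residues),
                    selection_mode = s$mode %||% "backbone"))
  analysis_config(
    trajectories = trajs, sites = sites,
    hbond_cutoff = y$hbond_cutoff %||% 3.0,
    hbond_angle_dev = y$hbond_angle_dev %||% 20,
    water_radius = y$water_radius %||% 5.0,
    neighborhood_radius = y$neighborhood_radius %||% 10,
    n_blocks = y$n_blocks %||% 20,
    frame_spacing = y$frame_spacing %||% 0.1,
    align = y$align %||% TRUE, seed = y$seed %||% 1)
}

.stage <- function(report, name, expr) {
  res <- tryCatch(list(ok = TRUE, value = expr),
                  error = function(e) list(ok = FALSE,
                                           error = conditionMessage(e)))
  report$stages[[name]] <- res
  report
}

#' Run the full analysis pipeline over all variants
#'
#' Per variant, the stages run in dependency order: RMSD series, site
#' correlation times (which feed the block-scheme check), block RMSF,
#' hydrogen-bond occupancy, inter-site distances, water counts and plane
#' angles where the inputs allow. A failing stage is recorded and the
#' remaining stages still run. The result also carries a WT-vs-variant
#' comparison table of the headline per-site metrics (first variant
#' taken as reference): per metric the two values and a z-like
#' difference scaled by the pooled block sd — mirroring error-bar
#' overlap rather than a hypothesis test.
#'
#' @param config an `analysis_config`.
#' @return object of class `variant_reports`: list with `variants` (per
#'   label: list of stage results), `comparison` (data.frame), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  variants <- list()
  for (label in names(config$trajectories)) {
    tr <- config$trajectories[[label]]
    report <- list(stages = list())
    traj <- tryCatch(
      if (inherits(tr, "trajectory")) tr else
        read_multimodel_pdb(tr, frame_spacing = config$frame_spacing),
      error = function(e) NULL)
    if (is.null(traj)) {
      report$failed <- paste("unreadable trajectory:", tr)
      variants[[label]] <- report
      next
    }
    total_ns <- n_frames(traj) * traj$frame_spacing
    nb <- min(config$n_blocks, n_frames(traj))

    report <- .stage(report, "rmsd", {
      s <- rmsd_series(traj, align = config$align)
      list(mean = mean(s$rmsd), final = tail(s$rmsd, 1), series = s)
    })
    report <- .stage(report, "correlation", {
      out <- lapply(config$sites, function(site) {
        cs <- com_length_series(traj, site,
                                radius = config$neighborhood_radius)
        fit <- fit_exponential_mixture(autocorrelation(cs))
        list(site = site$label, tau_c = fit$tau_c, r2 = fit$r2, fit = fit)
      })
      names(out) <- vapply(config$sites, `[[`, "", "label")
      out
    })
    report <- .stage(report, "block_scheme", {
      taus <- vapply(report$stages$correlation$value, `[[`, 0, "tau_c")
      suppressWarnings(
        suggest_block_scheme(total_ns, max(taus), n_blocks = nb))
    })
    report <- .stage(report, "rmsf", {
      prof <- rmsf_blocks(traj, n_blocks = nb, align = config$align)
      site_bars <- lapply(config$sites, function(site) {
        vals <- tryCatch(
          site_rmsf_distribution(prof, traj, site, mode = "sequence_10"),
          error = function(e) NULL)
        list(site = site$label,
             site_rmsf = mean(prof$block_values[
               prof$residues$resno %in% site$residue_seqs, ]),
             surround_sd = if (is.null(vals)) NA_real_ else sd(vals))
      })
      list(profile = prof, site_bars = site_bars)
    })
    report <- .stage(report, "hbonds", {
      occupancy_table(traj, dist_cutoff = config$hbond_cutoff,
                      max_angle_dev = config$hbond_angle_dev)
    })
    report <- .stage(report, "distances", {
      if (is.null(config$pairs)) list() else
        lapply(config$pairs, function(p) {
          ds <- distance_series(traj, p)
          c(list(label = p$label),
            distance_stats(ds, n_blocks = min(nb, length(ds$values))))
        })
    })
    report <- .stage(report, "waters", {
      out <- lapply(config$sites, function(site)
        count_waters(traj, site, radius = config$water_radius))
      names(out) <- vapply(config$sites, `[[`, "", "label")
      out
    })
    report$n_frames <- n_frames(traj)
    report$total_ns <- total_ns
    variants[[label]] <- report
  }
  ok <- vapply(variants, function(v) is.null(v$failed), TRUE)
  if (!any(ok)) stop("all variants failed")

  comparison <- .comparison_table(variants[ok])
  structure(list(variants = variants, comparison = comparison,
                 config = config),
            class = "variant_reports")
}

.comparison_table <- function(variants) {
  if (length(variants) < 1) return(NULL)
  ref_label <- names(variants)[1]
  rows <- list()
  pull <- function(v) {
    out <- c()
    if (isTRUE(v$stages$rmsd$ok))
      out <- c(out, rmsd_mean = v$stages$rmsd$value$mean)
    if (isTRUE(v$stages$correlation$ok))
      for (s in v$stages$correlation$value)
        out <- c(out, setNames(s$tau_c, paste0("tau_c_", s$site)))
    if (isTRUE(v$stages$waters$ok))
      for (nm in names(v$stages$waters$value))
        out <- c(out, setNames(v$stages$waters$value[[nm]]$mean,
                               paste0("waters_", nm)))
    if (isTRUE(v$stages$distances$ok))
      for (d in v$stages$distances$value)
        out <- c(out, setNames(d$mean, paste0("dist_", d$label)))
    out
  }
  ref <- pull(variants[[ref_label]])
  for (label in names(variants)) {
    cur <- pull(variants[[label]])
    common <- intersect(names(ref), names(cur))
    if (length(common) == 0) next
    rows[[label]] <- data.frame(
      variant = label, metric = common,
      reference = unname(ref[common]), value = unname(cur[common]),
      delta = unname(cur[common] - ref[common]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.variant_reports <- function(x, ...) {
  cat("variant reports:", paste(names(x$variants), collapse = ", "), "\n")
  for (label in names(x$variants)) {
    v <- x$variants[[label]]
    if (!is.null(v$failed)) {
      cat(sprintf("  %s: FAILED (%s)\n", label, v$failed)); next
    }
    oks <- vapply(v$stages, function(s) isTRUE(s$ok), TRUE)
    cat(sprintf("  %s: %d/%d stages ok (%s)\n", label, sum(oks),
                length(oks),
                paste(names(oks)[!oks], collapse = ", ")))
  }
  invisible(x)
}
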