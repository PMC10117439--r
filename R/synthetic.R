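#' Construct a phantom brain atlas
#'
#' A phantom atlas stands in for an anatomical parcellation (e.g. a 90-ROI or
#' 246-ROI scheme): it fixes the number of regions of interest (ROIs) and gives
#' every ROI the same small voxel lattice, on which regional features such as
#' ReHo are computed.
#'
#' @param n_rois Number of ROIs; at least 10 (graph-level pooling degenerates
#'   below that).
#' @param block_shape Integer vector of length 3, the voxel lattice of each
#'   ROI. Every dimension must be at least 2 so each voxel has neighbours.
#'
#' @return An object of class `atlas_phantom` with fields `n_rois`,
#'   `roi_names` (zero-padded `ROI_001`, ...), `block_shape`, `n_voxels`,
#'   `voxel_coords` (n_voxels x 3 integer matrix) and `neighbor_offsets`
#'   (the 26-connected offsets, excluding the zero offset).
#' @export
#' @examples
#' atlas <- make_atlas_phantom(90)
#' atlas$n_rois
make_atlas_phantom <- function(n_rois, block_shape = c(3L, 3L, 3L)) {
  n_rois <- as.integer(n_rois)
  block_shape <- as.integer(block_shape)
  if (length(n_rois) != 1L || is.na(n_rois) || n_rois < 10L)
    stop("n_rois must be a single integer >= 10 (pooling needs enough nodes)")
  if (length(block_shape) != 3L || any(block_shape < 2L))
    stop("block_shape must have 3 dimensions, each >= 2")
  width <- max(3L, nchar(as.character(n_rois)))
  coords <- as.matrix(expand.grid(
    x = seq_len(block_shape[1]),
    y = seq_len(block_shape[2]),
    z = seq_len(block_shape[3])
  ))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  structure(list(
    n_rois = n_rois,
    roi_names = sprintf(paste0("ROI_%0", width, "d"), seq_len(n_rois)),
    block_shape = block_shape,
    n_voxels = prod(block_shape),
    voxel_coords = coords,
    neighbor_offsets = offs
  ), class = "atlas_phantom")
}

#' Configuration of a synthetic two-group multimodal cohort
#'
#' Encodes the generative conditions of a phantom patient/control cohort:
#' group sizes, fMRI sampling (number of timepoints and repetition time),
#' community structure of the functional signal, and the planted group
#' effects — a regional mean gray-matter-volume decrement (`gmv_shift`, in
#' units of the voxel SD) and a reduction of community coupling
#' (`coupling_drop`, a fraction of the loading) in a configurable subset of
#' affected ROIs.
#'
#' @param n_control,n_patient Group sizes (positive).
#' @param seed Master seed; every random quantity in the cohort derives from it.
#' @param n_timepoints Number of fMRI timepoints (default 200).
#' @param tr_seconds Repetition time in seconds (default 2).
#' @param n_communities Number of functional communities (default 5). ROIs are
#'   assigned round-robin (ROI i -> community ((i - 1) mod C) + 1).
#' @param affected_rois 1-based ROI indices carrying the planted effects.
#' @param gmv_shift Patient mean gray-matter decrement in affected ROIs, in SD
#'   units of the voxel distribution.
#' @param coupling_drop Fraction in \[0, 1\] by which the community loading of
#'   affected ROIs is reduced in patients (0 = no effect, 1 = decoupled).
#' @param voxel_noise_sd SD of i.i.d. voxel-level noise added to the ROI time
#'   series (default 1).
#' @param temporal_noise_sd SD of the ROI-level noise term on top of the
#'   community signal (default 0.5).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_control, n_patient, seed = 1L,
                          n_timepoints = 200L, tr_seconds = 2,
                          n_communities = 5L, affected_rois = integer(0),
                          gmv_shift = 0, coupling_drop = 0,
                          voxel_noise_sd = 1, temporal_noise_sd = 0.5) {
  stopifnot(n_control >= 1, n_patient >= 1, n_timepoints >= 2,
            tr_seconds > 0, n_communities >= 1,
            voxel_noise_sd > 0, temporal_noise_sd > 0)
  if (coupling_drop < 0 || coupling_drop > 1)
    stop("coupling_drop must lie in [0, 1]")
  cfg <- list(
    n_control = as.integer(n_control), n_patient = as.integer(n_patient),
    seed = as.integer(seed), n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds, n_communities = as.integer(n_communities),
    affected_rois = as.integer(sort(unique(affected_rois))),
    gmv_shift = gmv_shift, coupling_drop = coupling_drop,
    voxel_noise_sd = voxel_noise_sd, temporal_noise_sd = temporal_noise_sd
  )
  class(cfg) <- "cohort_config"
  cfg
}

check_config_atlas <- function(config, atlas) {
  if (length(config$affected_rois) &&
      (min(config$affected_rois) < 1L || max(config$affected_rois) > atlas$n_rois))
    stop("affected_rois must be 1-based indices within the atlas")
  invisible(TRUE)
}

# Cohort-level latent parameters shared by both groups: per-ROI baseline mean
# volume mu_r ~ U(0.4, 0.8) with fixed sigma_r = 0.1, and the round-robin
# community assignment.  Drawn once from the master seed so ROI identity is
# stable across subjects (KL similarity between subjects' ROI densities is
# then structured rather than pure noise).
cohort_hyperparams <- function(atlas, config) {
  set.seed(config$seed)
  mu <- stats::runif(atlas$n_rois, 0.4, 0.8)
  mu_wm <- stats::runif(atlas$n_rois, 0.4, 0.8)
  list(
    mu_gm = mu,
    mu_wm = mu_wm,
    sigma = rep(0.1, atlas$n_rois),
    community = ((seq_len(atlas$n_rois) - 1L) %% config$n_communities) + 1L,
    subject_seeds = sample.int(.Machine$integer.max - 1L,
                               config$n_control + config$n_patient)
  )
}

# Band-limited community signal: moving average (window 5) of white noise,
# rescaled to unit SD.  At TR = 2 s this places most power inside the
# 0.01-0.08 Hz ALFF band.
smooth_signal <- function(n_timepoints, window = 5L) {
  x <- stats::rnorm(n_timepoints + window - 1L)
  s <- stats::filter(x, rep(1 / window, window), sides = 1L)
  s <- as.numeric(s[window:(n_timepoints + window - 1L)])
  s / stats::sd(s)
}

#' Simulate one phantom subject
#'
#' Draws one subject under the cohort's generative model. Each ROI r belongs
#' round-robin to a community c(r); a latent smoothed-Gaussian community
#' signal s_c(t) is drawn per subject; the ROI mean series is
#' `lambda_r * s_c(t) + eps_r(t)` with loading `lambda_r = 1` for controls and
#' `1 - coupling_drop` for patients in affected ROIs; each voxel's series is
#' the ROI series plus voxel noise. Gray-matter voxel values are
#' `Normal(mu_r - delta_r, sigma_r)` with `delta_r = gmv_shift * sigma_r` for
#' patients in affected ROIs (0 otherwise); white-matter values are analogous
#' with no shift.
#'
#' @param atlas An `atlas_phantom`.
#' @param group `"control"` or `"patient"`.
#' @param config A [cohort_config()].
#' @param subject_seed Integer seed for this subject's random stream.
#' @param hyper Cohort hyperparameters; computed from `config$seed` when NULL.
#' @param subject_id Label; auto-generated when NULL.
#' @return A list of class `subject_raw` with `subject_id`, `group`,
#'   `gm_values` and `wm_values` (n_rois x n_voxels matrices) and `timeseries`
#'   (list of n_voxels x n_timepoints matrices, one per ROI).
#' @export
simulate_subject <- function(atlas, group = c("control", "patient"), config,
                             subject_seed, hyper = NULL, subject_id = NULL) {
  group <- match.arg(group)
  check_config_atlas(config, atlas)
  if (is.null(hyper)) hyper <- cohort_hyperparams(atlas, config)
  set.seed(as.integer(subject_seed))
  n <- atlas$n_rois
  v <- atlas$n_voxels
  tt <- config$n_timepoints

  comm_sig <- matrix(0, config$n_communities, tt)
  for (c_i in seq_len(config$n_communities))
    comm_sig[c_i, ] <- smooth_signal(tt)

  affected <- logical(n)
  affected[config$affected_rois] <- TRUE

  gm <- matrix(0, n, v)
  wm <- matrix(0, n, v)
  ts <- vector("list", n)
  for (r in seq_len(n)) {
    delta <- if (group == "patient" && affected[r])
      config$gmv_shift * hyper$sigma[r] else 0
    gm[r, ] <- stats::rnorm(v, hyper$mu_gm[r] - delta, hyper$sigma[r])
    wm[r, ] <- stats::rnorm(v, hyper$mu_wm[r], hyper$sigma[r])
    lambda <- if (group == "patient" && affected[r])
      1 - config$coupling_drop else 1
    roi_series <- lambda * comm_sig[hyper$community[r], ] +
      stats::rnorm(tt, 0, config$temporal_noise_sd)
    noise <- matrix(stats::rnorm(v * tt, 0, config$voxel_noise_sd), v, tt)
    ts[[r]] <- sweep(noise, 2L, roi_series, `+`)
  }
  names(ts) <- atlas$roi_names
  rownames(gm) <- rownames(wm) <- atlas$roi_names
  structure(list(
    subject_id = if (is.null(subject_id)) paste0(group, "_", subject_seed)
                 else subject_id,
    group = group, gm_values = gm, wm_values = wm, timeseries = ts
  ), class = "subject_raw")
}

#' Simulate a full two-group cohort
#'
#' Generates `n_control + n_patient` subjects under [simulate_subject()]'s
#' generative model. Per-subject seeds are derived deterministically from the
#' master seed; the manifest records the configuration, the labels and every
#' per-subject seed, so the cohort is a pure function of `(atlas, config)`.
#'
#' @param atlas An `atlas_phantom`.
#' @param config A [cohort_config()].
#' @return A list of class `cohort` with `subjects` (list of `subject_raw`),
#'   `labels` (0 = control, 1 = patient), `atlas`, `config` and `manifest`.
#' @export
simulate_cohort <- function(atlas, config) {
  check_config_atlas(config, atlas)
  hyper <- cohort_hyperparams(atlas, config)
  groups <- c(rep("control", config$n_control), rep("patient", config$n_patient))
  ids <- sprintf("sub_%03d_%s", seq_along(groups), groups)
  subjects <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    subjects[[i]] <- simulate_subject(
      atlas, groups[i], config,
      subject_seed = hyper$subject_seeds[i], hyper = hyper, subject_id = ids[i]
    )
  }
  manifest <- list(
    config = unclass(config),
    n_rois = atlas$n_rois,
    hyperprior = list(mu = "Uniform(0.4, 0.8) per ROI (synthetic invention)",
                      sigma = 0.1),
    subject_ids = ids,
    groups = groups,
    subject_seeds = hyper$subject_seeds
  )
  structure(list(
    subjects = subjects,
    labels = as.integer(groups == "patient"),
    atlas = atlas, config = config, hyper = hyper, manifest = manifest
  ), class = "cohort")
}

#' Write a cohort to a plain-text directory layout
#'
#' One directory per subject holding `gm.tsv` and `wm.tsv` (ROI x voxel) and
#' `ts_ROI_<k>.tsv` (voxel x time), plus a cohort-level `manifest.json`.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    sd <- file.path(dir, s$subject_id)
    dir.create(sd, showWarnings = FALSE)
    utils::write.table(s$gm_values, file.path(sd, "gm.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(s$wm_values, file.path(sd, "wm.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    for (k in seq_along(s$timeseries))
      utils::write.table(s$timeseries[[k]],
                         file.path(sd, sprintf("ts_ROI_%d.tsv", k)),
                         sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
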