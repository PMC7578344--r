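# Synthetic two-arm cohort generator. Every downstream stage of the pipeline
# (motion QC, rsFC metrics, FA extraction, Rasch measurement, mixed-model
# change indices, permutation inference, discovery) consumes the objects
# produced here, so the generator is first-class, tested code rather than a
# fixture.

#' Simulate one preprocessed-BOLD acquisition with coupled motion spikes
#'
#' Draws a volumes-by-ROI matrix from a zero-mean multivariate normal with
#' the block covariance implied by the configuration, rescales it to the
#' configured marginal mean/SD, adds a small linear drift, and injects
#' single-volume spikes at which the realignment parameters and the signal
#' jump simultaneously, so that framewise displacement and DVARS censoring
#' both flag the same volumes.
#'
#' @param subject A list with at least `subject_id`; its id seeds the
#'   subject-specific random substream.
#' @param config A [cohort_config()] object.
#' @param timepoint `"BL"` or `"EP"`.
#' @return A list of class `roi_timeseries` with elements `data` (volumes x
#'   ROI matrix, ROI labels as column names), `tr_seconds`, `missing_rois`
#'   (character, empty here), `motion` (volumes x 6 matrix: 3 translations in
#'   mm, 3 rotations in radians), `spike_volumes` (integer), `subject_id`
#'   and `timepoint`.
#' @export
simulate_bold <- function(subject, config, timepoint = c("BL", "EP")) {
  timepoint <- match.arg(timepoint)
  set.seed(subject_seed(config$seed, subject$subject_id,
                        paste0("bold-", timepoint)))
  sig <- block_correlation_matrix(config, timepoint)
  ch <- chol(sig)
  n <- config$n_volumes
  p <- length(config$rois)
  z <- matrix(rnorm(n * p), n, p) %*% ch
  series <- config$bold_mean + config$roi_sd * z
  colnames(series) <- config$rois
  # linear drift, amplitude a fixed fraction of the marginal SD, random
  # direction per ROI
  ramp <- seq(-0.5, 0.5, length.out = n)
  dir <- sample(c(-1, 1), p, replace = TRUE)
  series <- series + outer(ramp, dir * config$drift_sd_frac * config$roi_sd)

  motion <- motion_walk(n, config)
  spikes <- integer(0)
  if (config$motion_spike_rate > 0 && n >= 2) {
    spikes <- which(runif(n) < config$motion_spike_rate)
    spikes <- spikes[spikes >= 2]
  }
  if (length(spikes)) {
    series[spikes, ] <- series[spikes, ] + config$spike_signal
    motion[spikes, 1] <- motion[spikes, 1] + config$spike_translation_mm
  }
  structure(list(data = series, tr_seconds = config$tr_seconds,
                 missing_rois = character(0), motion = motion,
                 spike_volumes = spikes, subject_id = subject$subject_id,
                 timepoint = timepoint),
            class = "roi_timeseries")
}

# Smooth random-walk realignment parameters (3 translations mm, 3 rotations
# radians); increments small enough that a clean series never crosses the
# FD censoring threshold.
motion_walk <- function(n, config) {
  inc <- cbind(matrix(rnorm(n * 3, sd = config$motion_walk_sd_mm), n, 3),
               matrix(rnorm(n * 3, sd = config$motion_walk_sd_rad), n, 3))
  apply(inc, 2, cumsum)
}

# Axis-aligned box geometry for the 19 tracts plus the brain mask.
# Convention: the anterior-posterior axis is config$ap_axis (default the
# second grid axis), anterior at low index, posterior at high index; every
# tract shares a common posterior pole so that posterior-anchored
# adjustment retains a segment shared across subjects.
tract_geometry <- function(config, coupled_length) {
  dims <- config$grid_dim
  tracts <- config$tracts
  pole <- dims[config$ap_axis] - 16L
  xs <- 2L + ((seq_along(tracts) - 1L) %% 8L) * 4L
  zs <- 4L + ((seq_along(tracts) - 1L) %/% 8L) * 10L
  masks <- vector("list", length(tracts))
  names(masks) <- tracts
  for (t in seq_along(tracts)) {
    len <- if (tracts[t] == config$fa_coupled_tract) coupled_length else 20L
    y <- (pole - len + 1L):pole
    masks[[t]] <- as.matrix(expand.grid(x = xs[t] + 0:2, y = y, z = zs[t] + 0:2))
  }
  list(masks = masks, pole = pole)
}

#' Simulate FA volumes and tract masks for one subject
#'
#' Voxel FA inside each tract equals the tract mean plus spatial noise; the
#' endpoint tract mean equals the baseline mean plus the configured
#' group-by-time effect (plus, for the coupled tract in the FAST group, the
#' subject's latent recovery contribution). Voxels outside every tract are
#' zero. `shared_length` is the cohort-minimum anterior-posterior length of
#' the coupled tract; when `config$fa_effect_region` is `"posterior"` or
#' `"anterior"` the coupled tract's change is confined to the corresponding
#' segment relative to that shared posterior length.
#'
#' @param subject A subject list with `subject_id`, `group`, `u` (latent
#'   recovery factor) and `coupled_tract_length`.
#' @param config A [cohort_config()] object.
#' @param shared_length Cohort-minimum coupled-tract length in voxels.
#' @return List with `fa` (list of BL/EP 3-d arrays), `tract_masks` (named
#'   list of voxel index matrices), `brain_mask` (3-d logical array),
#'   `skull_scale` and `skull_length_mm`.
#' @export
simulate_fa <- function(subject, config, shared_length = NULL) {
  set.seed(subject_seed(config$seed, subject$subject_id, "fa"))
  dims <- config$grid_dim
  geo <- tract_geometry(config, subject$coupled_tract_length)
  if (is.null(shared_length)) shared_length <- subject$coupled_tract_length

  eff <- config$fa_group_time_effect[[subject$group]]
  coupling <- if (subject$group == "FAST") config$fa_coupling_sd * subject$u else 0

  base_dev <- rnorm(length(config$tracts), sd = config$fa_subject_sd)
  names(base_dev) <- config$tracts

  fa <- list()
  for (tp in c("BL", "EP")) {
    vol <- array(0, dims)
    for (tr in config$tracts) {
      m <- geo$masks[[tr]]
      mu <- config$fa_baseline[[tr]] + base_dev[[tr]]
      delta <- eff[[tr]] + if (tr == config$fa_coupled_tract) coupling else 0
      vals <- rep(mu, nrow(m))
      if (tp == "EP") {
        in_post <- m[, config$ap_axis] > geo$pole - shared_length
        keep <- switch(config$fa_effect_region,
                       whole = rep(TRUE, nrow(m)),
                       posterior = in_post,
                       anterior = !in_post)
        vals[keep] <- vals[keep] + delta
      }
      vals <- vals + rnorm(nrow(m), sd = config$fa_noise_sd)
      vol[m] <- pmin(1, pmax(0, vals))
    }
    fa[[tp]] <- vol
  }

  skull_scale <- max(0.8, 1 + rnorm(1, sd = config$skull_scale_sd))
  skull_len_vox <- round(skull_scale * config$mni_length_mm / config$voxel_mm)
  brain <- array(FALSE, dims)
  brain[4:(dims[1] - 3), 3:min(dims[2], 2 + skull_len_vox), 4:(dims[3] - 3)] <- TRUE

  list(fa = fa, tract_masks = geo$masks, brain_mask = brain,
       skull_scale = skull_scale,
       skull_length_mm = skull_len_vox * config$voxel_mm)
}

# Item banks for the two instruments. Difficulties are spread evenly over
# the configured range; category thresholds are centered offsets within each
# item. Returned step parameters delta[i, j] = difficulty_i + tau_j.
item_bank <- function(config, instrument = c("DOCS", "CNC")) {
  instrument <- match.arg(instrument)
  if (instrument == "DOCS") {
    n_items <- config$docs_n_items
    n_steps <- rep(config$docs_n_categories - 1L, n_items)
  } else {
    n_items <- config$cnc_n_items
    n_steps <- config$cnc_categories - 1L
  }
  if (!is.null(config$rasch_item_difficulties[[instrument]])) {
    diffs <- config$rasch_item_difficulties[[instrument]]
  } else {
    diffs <- seq(config$difficulty_range[1], config$difficulty_range[2],
                 length.out = n_items)
  }
  steps <- lapply(seq_len(n_items), function(i) {
    k <- n_steps[i]
    tau <- if (k == 1) 0 else seq(-config$threshold_spread,
                                  config$threshold_spread, length.out = k)
    diffs[i] + (tau - mean(tau))
  })
  list(difficulties = diffs, steps = steps, n_steps = n_steps)
}

# Adjacent-category (partial credit / facets) category probabilities for a
# single linear predictor theta' = ability - rater severity and one item's
# step parameters. Returns a vector over categories 0..m.
pcm_probs <- function(theta, steps) {
  cum <- c(0, cumsum(steps))
  k <- seq_along(cum) - 1
  num <- k * theta - cum
  num <- num - max(num)
  e <- exp(num)
  e / sum(e)
}

#' Simulate polytomous item responses for one subject
#'
#' Draws category scores from the adjacent-category model with probabilities
#' determined by (ability - item difficulty - rater severity - category
#' thresholds). The DOCS-like instrument is observed at `length(docs_weeks)`
#' weekly occasions with raters cycling across subjects and occasions (a
#' linked rater network); the CNC-like instrument at `cnc_timepoints`
#' occasions with a single rater.
#'
#' @param subject Subject list with `subject_id`, `subject_index`, `group`,
#'   `u` (latent recovery factor).
#' @param config A [cohort_config()] object.
#' @return Data frame with columns `instrument`, `occasion` (0-based index),
#'   `item`, `rater`, `score`.
#' @export
simulate_neurobehavioral <- function(subject, config) {
  set.seed(subject_seed(config$seed, subject$subject_id, "behavior"))
  g <- subject$group
  docs_base <- config$docs_baseline_mean[[g]] +
    rnorm(1, sd = config$docs_baseline_sd)
  docs_slope <- config$docs_slope[[g]] + config$docs_slope_sd * subject$u
  cnc_base <- config$cnc_baseline_mean[[g]]
  cnc_slope <- config$cnc_slope[[g]] + config$cnc_slope_sd * subject$u

  out <- list()
  banks <- list(DOCS = item_bank(config, "DOCS"), CNC = item_bank(config, "CNC"))
  n_raters <- length(config$rater_severities)

  occasions <- list(DOCS = config$docs_weeks,
                    CNC = seq_len(config$cnc_timepoints) - 1)
  for (inst in c("DOCS", "CNC")) {
    bank <- banks[[inst]]
    for (oi in seq_along(occasions[[inst]])) {
      occ <- occasions[[inst]][oi]
      theta <- if (inst == "DOCS") docs_base + docs_slope * occ
               else cnc_base + cnc_slope * occ
      # DOCS-like occasions are double-scored by every rater (a fully
      # linked design, so severities are identified); CNC-like occasions
      # have a single rater and no facet.
      raters <- if (inst == "DOCS") seq_len(n_raters) else 0L
      for (rater in raters) {
        sev <- if (inst == "DOCS") config$rater_severities[rater] else 0
        scores <- vapply(seq_along(bank$steps), function(i) {
          pr <- pcm_probs(theta - sev, bank$steps[[i]])
          sample.int(length(pr), 1, prob = pr) - 1L
        }, integer(1))
        out[[length(out) + 1L]] <- data.frame(
          instrument = inst, occasion = occ, item = seq_along(bank$steps),
          rater = paste0("R", rater),
          score = scores, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Apply structured missingness to a cohort
#'
#' Marks ROIs and tracts as not discernible per subject with the configured
#' rate; missing ROI time series are set to `NA` (never imputed at the
#' metric stage) and missing tract voxels are removed from the FA maps and
#' mask list. When the guarantee is enabled every imaging subject has at
#' least one missing region or tract. A realized pattern that removes an
#' entire network, or a tract, for every subject of a group is rejected,
#' since group-nested imputation would be undefined.
#'
#' @param cohort A `synthetic_cohort` object.
#' @param config The generating [cohort_config()].
#' @return The cohort with `missing_regions` populated per subject.
#' @export
apply_missingness <- function(cohort, config) {
  rate <- config$missing_region_rate
  regions <- setdiff(c(config$rois, config$tracts), config$missing_exclude)
  img_idx <- which(vapply(cohort$subjects, function(s) s$has_imaging, logical(1)))
  miss_sets <- list()
  for (i in img_idx) {
    s <- cohort$subjects[[i]]
    set.seed(subject_seed(config$seed, s$subject_id, "missing"))
    miss <- regions[runif(length(regions)) < rate]
    if (config$missing_guarantee && length(miss) == 0) {
      miss <- sample(regions, 1)
    }
    miss_sets[[s$subject_id]] <- miss
  }
  # group-nested imputation needs >= 2 observed subjects per (group, region):
  # where sampling collides, restore the region for the subjects with the
  # largest missing sets until 2 observers remain
  grp_of <- vapply(cohort$subjects[img_idx], `[[`, "", "group")
  ids_of <- vapply(cohort$subjects[img_idx], `[[`, "", "subject_id")
  for (g in unique(grp_of)) {
    gids <- ids_of[grp_of == g]
    for (r in regions) {
      repeat {
        missing_here <- gids[vapply(gids, function(id)
          r %in% miss_sets[[id]], logical(1))]
        if (length(gids) - length(missing_here) >= 2 ||
            length(missing_here) == 0) break
        sizes <- vapply(missing_here, function(id)
          length(miss_sets[[id]]), numeric(1))
        victim <- missing_here[which.max(sizes)]
        miss_sets[[victim]] <- setdiff(miss_sets[[victim]], r)
      }
    }
  }
  if (config$missing_guarantee) {
    for (id in names(miss_sets)) {
      if (!length(miss_sets[[id]])) {
        # re-grant one region that still leaves 2 observers in the group
        g <- grp_of[match(id, ids_of)]
        gids <- ids_of[grp_of == g]
        for (r in regions) {
          n_missing <- sum(vapply(gids, function(j)
            r %in% miss_sets[[j]], logical(1)))
          if (length(gids) - n_missing >= 3) {
            miss_sets[[id]] <- r
            break
          }
        }
      }
    }
  }
  for (i in img_idx) {
    s <- cohort$subjects[[i]]
    s$missing_regions <- miss_sets[[s$subject_id]]
    miss <- s$missing_regions
    for (r in intersect(miss, config$rois)) {
      for (tp in c("BL", "EP")) {
        s$bold[[tp]]$data[, r] <- NA_real_
        s$bold[[tp]]$missing_rois <- union(s$bold[[tp]]$missing_rois, r)
      }
    }
    for (r in intersect(miss, config$tracts)) {
      m <- s$tract_masks[[r]]
      for (tp in c("BL", "EP")) s$fa[[tp]][m] <- 0
      s$tract_masks[[r]] <- NULL
    }
    cohort$subjects[[i]] <- s
  }
  # reject patterns that empty a whole network or tract for a whole group
  img <- Filter(function(s) s$has_imaging, cohort$subjects)
  for (g in c("FAST", "placebo")) {
    gs <- Filter(function(s) s$group == g, img)
    if (!length(gs)) next
    for (nl in names(config$networks)) {
      gone <- vapply(gs, function(s)
        all(config$networks[[nl]] %in% s$missing_regions), logical(1))
      if (all(gone)) stop(sprintf(
        "missingness removed network %s for every %s subject; imputation undefined",
        nl, g))
    }
    for (tr in config$tracts) {
      gone <- vapply(gs, function(s) tr %in% s$missing_regions, logical(1))
      if (all(gone)) stop(sprintf(
        "missingness removed tract %s for every %s subject; imputation undefined",
        tr, g))
    }
  }
  cohort
}

#' Generate a complete synthetic two-arm cohort
#'
#' Produces imaging subjects (`n_per_group` per arm, groups `FAST` and
#' `placebo`) with BOLD time series and realignment parameters at BL and EP,
#' FA volumes with tract and brain masks, item-level neurobehavioral
#' responses, and structured missingness, plus behavioral-only subjects that
#' stand in for the rest of the trial sample. Deterministic given the
#' configuration seed; per-subject substreams are derived by a stable hash
#' of the subject id, so individual subjects are reproducible in isolation.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `synthetic_cohort`: a list with `subjects` (a
#'   list of subject records) and `config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_per_group = 2, n_behavioral_extra = 0,
#'                      n_volumes = 40, grid_dim = c(16L, 48L, 16L), seed = 7)
#' coh <- generate_cohort(cfg)
#' length(coh$subjects)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n_img <- 2L * config$n_per_group
  n_all <- n_img + config$n_behavioral_extra
  groups <- c(rep("FAST", config$n_per_group),
              rep("placebo", config$n_per_group),
              rep(c("FAST", "placebo"), length.out = config$n_behavioral_extra))
  ids <- sprintf("sub%02d", seq_len(n_all))

  set.seed(subject_seed(config$seed, "cohort", "lengths"))
  if (!is.null(config$coupled_tract_lengths)) {
    lens <- rep(as.integer(config$coupled_tract_lengths), length.out = n_img)
  } else {
    lens <- sample(14:24, n_img, replace = TRUE)
    lens[which.min(lens)] <- 14L
  }
  shared_len <- min(lens)

  subjects <- vector("list", n_all)
  for (i in seq_len(n_all)) {
    s <- list(subject_id = ids[i], subject_index = i, group = groups[i],
              has_imaging = i <= n_img)
    set.seed(subject_seed(config$seed, ids[i], "latent"))
    s$u <- rnorm(1)
    dpi_range <- if (groups[i] == "FAST") c(59, 187) else c(52, 136)
    s$days_post_injury <- round(runif(1, dpi_range[1], dpi_range[2]))
    if (s$has_imaging) {
      s$coupled_tract_length <- lens[i]
      s$bold <- list(BL = simulate_bold(s, config, "BL"),
                     EP = simulate_bold(s, config, "EP"))
      fa <- simulate_fa(s, config, shared_length = shared_len)
      s$fa <- fa$fa
      s$tract_masks <- fa$tract_masks
      s$brain_mask <- fa$brain_mask
      s$skull_scale <- fa$skull_scale
      s$skull_length_mm <- fa$skull_length_mm
    }
    s$item_responses <- simulate_neurobehavioral(s, config)
    s$missing_regions <- character(0)
    subjects[[i]] <- s
  }
  cohort <- structure(list(subjects = subjects, config = config),
                      class = "synthetic_cohort")
  if (config$missing_region_rate > 0 || config$missing_guarantee) {
    cohort <- apply_missingness(cohort, config)
  }
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  img <- vapply(x$subjects, function(s) s$has_imaging, logical(1))
  grp <- vapply(x$subjects, function(s) s$group, character(1))
  cat(sprintf("synthetic cohort: %d subjects (%d imaging; FAST %d / placebo %d)\n",
              length(x$subjects), sum(img), sum(grp == "FAST"),
              sum(grp == "placebo")))
  invisible(x)
}
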