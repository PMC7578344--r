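# Configuration for the synthetic two-arm cohort generator. Defaults encode
# the study conditions the rest of the pipeline assumes: 205 BOLD volumes at
# TR = 3 s over 26 regions in 4 networks, 19 white-matter tracts, two raters,
# 6 weekly timepoints for the DOCS-like instrument and 12 for the CNC-like
# one, and n = 4 imaging subjects per arm.

#' Default resting-state network membership
#'
#' Returns the default assignment of the 26 regions of interest to the four
#' resting-state networks: default mode (DMN), language (LN), salience (SN),
#' and attention (AN). Membership is configuration, not code: any named list
#' of disjoint ROI label vectors may be supplied to [cohort_config()].
#'
#' @return Named list with elements `DMN` (6 ROIs), `LN` (6), `SN` (7) and
#'   `AN` (7); 26 unique ROI labels in total.
#' @export
#' @examples
#' lengths(default_networks())
default_networks <- function() {
  list(
    DMN = c("mPFC", "PCC", "L_parahippocampal", "R_parahippocampal",
            "L_TPJ", "R_TPJ"),
    LN  = c("L_Broca", "R_Broca", "L_Heschl", "R_Heschl",
            "L_Wernicke", "R_Wernicke"),
    SN  = c("ACC", "L_amygdala", "R_amygdala", "L_ant_insula",
            "R_ant_insula", "L_striatum", "R_striatum"),
    AN  = c("L_DLPFC", "R_DLPFC", "L_FEF", "R_FEF",
            "L_IPS", "R_IPS", "R_VLPFC")
  )
}

#' Default white-matter tract labels
#'
#' The 19 association and commissural tracts tracked by the generator and the
#' FA extraction stage: eight bilateral pairs (inferior and superior
#' longitudinal fasciculus, arcuate, uncinate, inferior and superior
#' fronto-occipital fasciculus, cingulum, corticospinal tract) plus the genu,
#' body and splenium of the corpus callosum.
#'
#' @return Character vector of 19 tract labels.
#' @export
default_tracts <- function() {
  c("left_ILF", "right_ILF", "left_SLF", "right_SLF",
    "left_AF", "right_AF", "left_UF", "right_UF",
    "left_IFOF", "right_IFOF", "left_SFOF", "right_SFOF",
    "left_cingulum", "right_cingulum", "left_CST", "right_CST",
    "genu_CC", "body_CC", "splenium_CC")
}

#' Synthetic cohort configuration
#'
#' Builds and validates the configuration object consumed by
#' [generate_cohort()]. Defaults encode the acquisition and design constants
#' of the study the generator emulates (205 volumes at TR = 3 s, 26 ROIs in 4
#' networks, 19 tracts, 4 imaging subjects per arm plus 7 behavioral-only
#' subjects, weekly DOCS-like and twice-weekly CNC-like schedules) together
#' with effect sizes chosen so the downstream discovery stage has signal to
#' find: a FAST-specific left-ILF FA increase coupled, through a per-subject
#' latent recovery factor, to the auditory-language ability slope, and no
#' rsFC-behavior coupling.
#'
#' The block correlation structure of the BOLD signal is validated on
#' construction: the implied 26 x 26 correlation matrix must be positive
#' semi-definite, otherwise the offending network block pair is named.
#'
#' @param n_per_group Imaging subjects per arm (default 4).
#' @param n_behavioral_extra Additional behavioral-only subjects split
#'   across arms (default 7, giving a 15-subject trial analog).
#' @param networks Named list mapping network label to ROI labels; see
#'   [default_networks()].
#' @param n_volumes,tr_seconds,n_dummy BOLD acquisition length, repetition
#'   time in seconds, and number of initial dummy volumes discarded.
#' @param within_r Named list with elements `BL` and `EP`, each a named
#'   numeric vector of ROI-ROI correlations within each network.
#' @param between_r Named list with elements `BL` and `EP`, each a symmetric
#'   4 x 4 matrix (dimnames = network labels) of ROI-level between-network
#'   correlations.
#' @param bold_mean,roi_sd Marginal BOLD mean and SD per ROI; the mean sets
#'   the raw scale on which DVARS is later median-normalized to 1000.
#' @param drift_sd_frac Linear drift amplitude as a fraction of `roi_sd`.
#' @param motion_spike_rate Per-volume probability of a coupled motion/signal
#'   spike; spikes displace the realignment parameters and inject a
#'   broadband signal jump so FD and DVARS censoring both fire.
#' @param motion_walk_sd_mm,motion_walk_sd_rad Random-walk increment SDs for
#'   clean translation (mm) and rotation (radians) parameters.
#' @param spike_translation_mm,spike_signal Magnitude of the translation jump
#'   and of the uniform signal jump at spike volumes.
#' @param tracts Character vector of tract labels.
#' @param fa_baseline Named numeric vector of mean baseline FA per tract.
#' @param fa_group_time_effect List with elements `FAST` and `placebo`, each
#'   a named numeric vector of additive EP-BL FA change per tract (tracts
#'   not named get 0).
#' @param fa_coupled_tract,fa_coupling_sd Tract whose FAST-group FA change is
#'   coupled to the latent recovery factor, and the SD of that coupling in
#'   FA units (set `fa_coupling_sd = 0` for a null-coupling cohort).
#' @param fa_noise_sd Voxelwise spatial FA noise SD.
#' @param fa_subject_sd Between-subject SD of baseline tract-mean FA.
#' @param grid_dim,voxel_mm,ap_axis FA volume grid dimensions, voxel size in
#'   mm, and the index of the anterior-posterior axis.
#' @param mni_length_mm Reference (template) skull length along the
#'   anterior-posterior axis, in mm, used for the tract-length adjustment.
#' @param skull_scale_sd Between-subject SD of the skull-length scale ratio.
#' @param coupled_tract_lengths Optional integer vector of per-subject
#'   anterior-posterior lengths (voxels) for the coupled tract; by default
#'   lengths are drawn from 14..24 with the cohort minimum forced to 14.
#' @param fa_effect_region Where the EP-BL FA change is applied within each
#'   tract: `"whole"` (default), `"posterior"` (only the posterior segment
#'   shared across subjects after adjustment) or `"anterior"`.
#' @param docs_n_items,docs_n_categories,docs_aud_lang_items DOCS-like
#'   instrument structure: item count, response categories per item (scores
#'   `0..docs_n_categories-1`), and the indices of the auditory-language
#'   subscale items (spread across the difficulty ladder by default, so the
#'   subscale measures over the same ability range as the full scale).
#' @param cnc_n_items,cnc_categories CNC-like instrument structure; each item
#'   has its own rating scale, given as a vector of category counts.
#' @param rasch_item_difficulties Optional list with elements `DOCS` and
#'   `CNC` giving explicit item difficulties (logits); by default spread
#'   evenly over `difficulty_range`.
#' @param difficulty_range Range (logits) over which default item
#'   difficulties are spread.
#' @param threshold_spread Half-range (logits) of the centered category
#'   threshold offsets within each item.
#' @param rater_severities Numeric vector of rater severities (logits); must
#'   sum to zero. Every rater scores every DOCS-like occasion (a fully
#'   linked design, so severities are identified).
#' @param docs_weeks,cnc_timepoints Measurement schedules: DOCS-like weekly
#'   occasions (default `0:5`) and number of CNC-like occasions (default 12,
#'   indexed `0..11`).
#' @param docs_baseline_mean,docs_baseline_sd,docs_slope,docs_slope_sd
#'   DOCS-like ability trajectory parameters (logits): per-group baseline
#'   means, between-subject baseline SD, per-group weekly slope, and the SD
#'   of the subject slope deviation carried by the latent recovery factor.
#' @param cnc_baseline_mean,cnc_slope,cnc_slope_sd CNC-like analogues (per
#'   occasion-index slope); the CNC slope deviation shares the same latent
#'   recovery factor, so the behavioral outcomes are mutually correlated.
#' @param missing_region_rate Per-region probability that an ROI or tract is
#'   not discernible for a subject (removed from that subject's data).
#' @param missing_exclude Regions or tracts never marked missing (e.g. a
#'   tract whose planted effect a simulation study wants observed for every
#'   subject).
#' @param missing_guarantee Logical; when `TRUE` every imaging subject is
#'   guaranteed at least one missing region or tract.
#' @param seed Master integer seed; per-subject substreams are derived by a
#'   stable hash of the subject identifier.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @export
#' @examples
#' cfg <- cohort_config(n_per_group = 2, n_behavioral_extra = 0, seed = 1)
#' cfg$n_volumes
cohort_config <- function(n_per_group = 4,
                          n_behavioral_extra = 7,
                          networks = default_networks(),
                          n_volumes = 205,
                          tr_seconds = 3,
                          n_dummy = 3,
                          within_r = NULL,
                          between_r = NULL,
                          bold_mean = 1000,
                          roi_sd = 20,
                          drift_sd_frac = 0.02,
                          motion_spike_rate = 0.05,
                          motion_walk_sd_mm = 0.02,
                          motion_walk_sd_rad = 2e-4,
                          spike_translation_mm = 1.5,
                          spike_signal = 80,
                          tracts = default_tracts(),
                          fa_baseline = NULL,
                          fa_group_time_effect = NULL,
                          fa_coupled_tract = "left_ILF",
                          fa_coupling_sd = 0.02,
                          fa_noise_sd = 0.01,
                          fa_subject_sd = 0.015,
                          grid_dim = c(40L, 72L, 40L),
                          voxel_mm = 1,
                          ap_axis = 2L,
                          mni_length_mm = 60,
                          skull_scale_sd = 0.05,
                          coupled_tract_lengths = NULL,
                          fa_effect_region = c("whole", "posterior", "anterior"),
                          docs_n_items = 25,
                          docs_n_categories = 5,
                          docs_aud_lang_items = c(2, 6, 10, 14, 18, 22),
                          cnc_n_items = 11,
                          cnc_categories = NULL,
                          rasch_item_difficulties = NULL,
                          difficulty_range = c(-6, 6),
                          threshold_spread = 1.5,
                          rater_severities = c(-0.4, 0.4),
                          docs_weeks = 0:5,
                          cnc_timepoints = 12,
                          docs_baseline_mean = c(FAST = -2, placebo = -2),
                          docs_baseline_sd = 0.7,
                          docs_slope = c(FAST = 0.5, placebo = 0.35),
                          docs_slope_sd = 0.4,
                          cnc_baseline_mean = c(FAST = 1, placebo = 1),
                          cnc_slope = c(FAST = -0.2, placebo = -0.15),
                          cnc_slope_sd = 0.15,
                          missing_region_rate = 0.06,
                          missing_exclude = character(0),
                          missing_guarantee = TRUE,
                          seed = 1L) {
  fa_effect_region <- match.arg(fa_effect_region)
  stopifnot(n_per_group >= 1, n_volumes > n_dummy, tr_seconds > 0)

  net_labels <- names(networks)
  rois <- unlist(networks, use.names = FALSE)
  if (anyDuplicated(rois)) {
    stop("ROI labels must be unique across networks")
  }

  if (is.null(within_r)) {
    base_w <- c(DMN = 0.30, LN = 0.42, SN = 0.40, AN = 0.29)
    base_w <- base_w[net_labels]
    if (anyNA(base_w)) base_w <- setNames(rep(0.3, length(net_labels)), net_labels)
    within_r <- list(BL = base_w, EP = base_w)
  }
  if (is.null(between_r)) {
    k <- length(net_labels)
    m <- matrix(0.12, k, k, dimnames = list(net_labels, net_labels))
    diag(m) <- 1
    between_r <- list(BL = m, EP = m)
  }

  if (is.null(fa_baseline)) {
    fa_baseline <- setNames(
      rep(c(0.40, 0.42, 0.38, 0.44, 0.36), length.out = length(tracts)), tracts)
  }
  if (is.null(fa_group_time_effect)) {
    fast_eff <- c(left_ILF = 0.03, right_SLF = 0.02, right_AF = 0.02,
                  right_UF = 0.02, right_SFOF = 0.025)
    plac_eff <- c(right_AF = -0.02, splenium_CC = -0.02, body_CC = -0.02,
                  left_ILF = -0.015, right_SFOF = 0.01)
    fa_group_time_effect <- list(
      FAST = fast_eff[names(fast_eff) %in% tracts],
      placebo = plac_eff[names(plac_eff) %in% tracts])
  }
  full_eff <- lapply(fa_group_time_effect, function(e) {
    out <- setNames(rep(0, length(tracts)), tracts)
    out[names(e)] <- e
    out
  })
  rng <- range(unlist(lapply(full_eff, function(e) fa_baseline[tracts] + e)))
  if (rng[1] < 0 || rng[2] > 1) {
    stop("fa_baseline plus group-time effects must stay within [0, 1]")
  }

  if (is.null(cnc_categories)) {
    cnc_categories <- rep(c(3L, 4L, 5L), length.out = cnc_n_items)
  }
  if (abs(sum(rater_severities)) > 1e-8) {
    stop("rater_severities must sum to zero")
  }

  cfg <- list(
    n_per_group = as.integer(n_per_group),
    n_behavioral_extra = as.integer(n_behavioral_extra),
    networks = networks, rois = rois,
    n_volumes = as.integer(n_volumes), tr_seconds = tr_seconds,
    n_dummy = as.integer(n_dummy),
    within_r = within_r, between_r = between_r,
    bold_mean = bold_mean, roi_sd = roi_sd, drift_sd_frac = drift_sd_frac,
    motion_spike_rate = motion_spike_rate,
    motion_walk_sd_mm = motion_walk_sd_mm,
    motion_walk_sd_rad = motion_walk_sd_rad,
    spike_translation_mm = spike_translation_mm, spike_signal = spike_signal,
    tracts = tracts, fa_baseline = fa_baseline[tracts],
    fa_group_time_effect = full_eff,
    fa_coupled_tract = fa_coupled_tract, fa_coupling_sd = fa_coupling_sd,
    fa_noise_sd = fa_noise_sd, fa_subject_sd = fa_subject_sd,
    grid_dim = as.integer(grid_dim), voxel_mm = voxel_mm,
    ap_axis = as.integer(ap_axis), mni_length_mm = mni_length_mm,
    skull_scale_sd = skull_scale_sd,
    coupled_tract_lengths = coupled_tract_lengths,
    fa_effect_region = fa_effect_region,
    docs_n_items = as.integer(docs_n_items),
    docs_n_categories = as.integer(docs_n_categories),
    docs_aud_lang_items = as.integer(docs_aud_lang_items),
    cnc_n_items = as.integer(cnc_n_items),
    cnc_categories = as.integer(cnc_categories),
    rasch_item_difficulties = rasch_item_difficulties,
    difficulty_range = difficulty_range, threshold_spread = threshold_spread,
    rater_severities = rater_severities,
    docs_weeks = docs_weeks, cnc_timepoints = as.integer(cnc_timepoints),
    docs_baseline_mean = docs_baseline_mean, docs_baseline_sd = docs_baseline_sd,
    docs_slope = docs_slope, docs_slope_sd = docs_slope_sd,
    cnc_baseline_mean = cnc_baseline_mean, cnc_slope = cnc_slope,
    cnc_slope_sd = cnc_slope_sd,
    missing_region_rate = missing_region_rate,
    missing_exclude = missing_exclude,
    missing_guarantee = missing_guarantee,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  # validate the block covariance at both timepoints up front
  for (tp in c("BL", "EP")) invisible(block_correlation_matrix(cfg, tp))
  cfg
}

#' Block ROI-ROI correlation matrix implied by a cohort configuration
#'
#' Assembles the full ROI-ROI correlation matrix from the per-network
#' within-network correlations and the between-network correlation matrix,
#' and verifies positive semi-definiteness. Non-PSD configurations are
#' rejected with a diagnostic naming the offending network block pair.
#'
#' @param config A [cohort_config()] object.
#' @param timepoint `"BL"` or `"EP"`.
#' @return The ROI-ROI correlation matrix (dimnames = ROI labels).
#' @export
block_correlation_matrix <- function(config, timepoint = c("BL", "EP")) {
  timepoint <- match.arg(timepoint)
  nets <- config$networks
  rois <- config$rois
  w <- config$within_r[[timepoint]]
  b <- config$between_r[[timepoint]]
  p <- length(rois)
  sig <- matrix(0, p, p, dimnames = list(rois, rois))
  net_of <- rep(names(nets), lengths(nets))
  names(net_of) <- rois
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      ni <- net_of[rois[i]]; nj <- net_of[rois[j]]
      sig[i, j] <- if (i == j) 1 else if (ni == nj) w[[ni]] else b[ni, nj]
    }
  }
  ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    # locate a 2-network sub-block that already fails, if any
    labs <- names(nets)
    for (a in seq_along(labs)) {
      for (bb in seq_len(a)) {
        idx <- rois[net_of %in% labs[c(a, bb)]]
        sub <- sig[idx, idx]
        if (min(eigen(sub, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
          stop(sprintf(
            "correlation structure at %s is not positive semi-definite (block %s-%s)",
            timepoint, labs[bb], labs[a]))
        }
      }
    }
    stop(sprintf(
      "correlation structure at %s is not positive semi-definite (min eigenvalue %.3g)",
      timepoint, min(ev)))
  }
  sig
}

# Stable 31-adic string hash reduced modulo 2^31 - 1; used to derive
# per-subject substream seeds from the master seed so that cohorts are
# reproducible subject-by-subject regardless of generation order.
stable_hash <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

subject_seed <- function(master, subject_id, purpose = "") {
  as.integer((as.numeric(master) * 48271 +
                stable_hash(paste0(subject_id, ":", purpose))) %% 2147483647)
}
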