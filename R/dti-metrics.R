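# Structural connectivity metrics: tract-mean FA within common-voxel masks,
# plus the tract-length standardization used to verify positive FA-outcome
# correlations (fixed cohort-minimum tract length, scaled by each subject's
# skull length relative to the template, anchored at the posterior pole).

#' Common-voxel mask across timepoints
#'
#' A voxel enters the mask iff its FA reaches the threshold at both
#' timepoints; 0.2 is inclusive so partial-volume edges are kept.
#'
#' @param fa_bl_map,fa_ep_map FA arrays on identical grids.
#' @param fa_threshold Inclusion threshold (default 0.2).
#' @return Logical array: voxels present at both timepoints.
#' @export
common_voxel_mask <- function(fa_bl_map, fa_ep_map, fa_threshold = 0.2) {
  if (!identical(dim(fa_bl_map), dim(fa_ep_map))) {
    stop("FA maps must be on identical grids")
  }
  (fa_bl_map >= fa_threshold) & (fa_ep_map >= fa_threshold)
}

#' Tract-mean FA within a common-voxel mask
#'
#' Mean and SD of FA over the intersection of the tract mask with the
#' common-voxel mask. An empty intersection yields a missing-metric marker
#' (`NA` mean) handed to mixed-model imputation.
#'
#' @param fa_map FA array.
#' @param tract_mask Voxel index matrix (n x 3) or logical array for the
#'   tract.
#' @param common_mask Optional logical array from [common_voxel_mask()].
#' @param tract,timepoint Optional labels carried through.
#' @param adjusted Logical flag marking length-adjusted extractions.
#' @return Data frame row: `tract`, `timepoint`, `mean_fa`, `sd_fa`,
#'   `n_voxels`, `adjusted`.
#' @export
tract_mean_fa <- function(fa_map, tract_mask, common_mask = NULL,
                          tract = NA_character_, timepoint = NA_character_,
                          adjusted = FALSE) {
  sel <- array(FALSE, dim(fa_map))
  if (is.matrix(tract_mask)) sel[tract_mask] <- TRUE else sel <- sel | tract_mask
  if (!is.null(common_mask)) sel <- sel & common_mask
  n <- sum(sel)
  vals <- fa_map[sel]
  data.frame(tract = tract, timepoint = timepoint,
             mean_fa = if (n) mean(vals) else NA_real_,
             sd_fa = if (n > 1) sd(vals) else if (n == 1) 0 else NA_real_,
             n_voxels = n, adjusted = adjusted, stringsAsFactors = FALSE)
}

#' Anterior-posterior skull length of a mask
#'
#' Inclusive voxel extent of the mask along the anterior-posterior axis,
#' times the voxel size: `(max index - min index + 1) * voxel_mm`.
#'
#' @param brain_mask Logical (or 0/1) array.
#' @param voxel_mm Voxel size along the a-p axis in mm.
#' @param ap_axis Index of the a-p axis in the grid (default 2).
#' @return Extent in mm.
#' @export
skull_length_ap <- function(brain_mask, voxel_mm = 1, ap_axis = 2L) {
  idx <- which(brain_mask != 0, arr.ind = TRUE)
  if (!nrow(idx)) stop("brain mask is empty")
  rng <- range(idx[, ap_axis])
  (rng[2] - rng[1] + 1) * voxel_mm
}

# round-half-away-from-zero (base round() is round-half-even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Length-standardized tract masks across subjects
#'
#' Implements the verification adjustment for a tract: the cohort-minimum
#' anterior-posterior tract extent defines a fixed length, each subject's
#' adjusted length is that minimum scaled by the ratio of their skull length
#' to the template skull length (rounded half away from zero), and the
#' adjusted mask keeps the voxels within the adjusted length of the tract's
#' posterior pole along the a-p axis.
#'
#' @param tract_masks Named (by subject) list of voxel index matrices for
#'   the tract; subjects missing the tract should be omitted (they are
#'   recorded by the caller and handled by imputation).
#' @param skull_lengths Named numeric vector of subject a-p skull lengths
#'   (mm), aligned with `tract_masks`.
#' @param mni_length Template a-p skull length in mm.
#' @param ap_axis A-p axis index (default 2); posterior = larger index.
#' @param voxel_mm Voxel size along the a-p axis.
#' @return List with `min_length_voxels`, and per subject `scale`,
#'   `adjusted_length_voxels` and `masks` (adjusted voxel index matrices).
#' @export
#' @examples
#' m <- cbind(1, 10:23, 1)  # 14 voxels along a-p
#' adjusted_tract_mask(list(g = m), c(g = 60), mni_length = 60)$adjusted_length_voxels
adjusted_tract_mask <- function(tract_masks, skull_lengths, mni_length,
                                ap_axis = 2L, voxel_mm = 1) {
  stopifnot(length(tract_masks) >= 1,
            length(skull_lengths) == length(tract_masks))
  extents <- vapply(tract_masks, function(m) {
    rng <- range(m[, ap_axis])
    rng[2] - rng[1] + 1
  }, numeric(1))
  min_len <- min(extents)
  scale <- skull_lengths / mni_length
  adj_len <- round_half_away(scale * min_len)
  if (any(adj_len < 1)) {
    stop("adjusted tract length below 1 voxel for subject ",
         names(tract_masks)[which(adj_len < 1)[1]])
  }
  masks <- vector("list", length(tract_masks))
  names(masks) <- names(tract_masks)
  for (i in seq_along(tract_masks)) {
    m <- tract_masks[[i]]
    pole <- max(m[, ap_axis])
    keep <- m[, ap_axis] > pole - adj_len[i]
    masks[[i]] <- m[keep, , drop = FALSE]
  }
  list(min_length_voxels = as.integer(min_len), scale = scale,
       adjusted_length_voxels = setNames(as.integer(adj_len),
                                         names(tract_masks)),
       masks = masks)
}

#' Subject-level tract FA table
#'
#' Extracts mean FA for every tract at both timepoints within the subject's
#' common-voxel mask, in long format for mixed-model change estimation.
#' Tracts absent from `tract_masks` (not discernible) appear with `NA`.
#'
#' @param fa_bl,fa_ep FA arrays at BL and EP.
#' @param tract_masks Named list of voxel index matrices.
#' @param all_tracts Character vector of the full tract set (absent ones are
#'   reported missing).
#' @param fa_threshold Common-mask threshold.
#' @return Data frame: `tract`, `timepoint`, `mean_fa`, `sd_fa`,
#'   `n_voxels`, `adjusted`.
#' @export
tract_fa_table <- function(fa_bl, fa_ep, tract_masks,
                           all_tracts = names(tract_masks),
                           fa_threshold = 0.2) {
  common <- common_voxel_mask(fa_bl, fa_ep, fa_threshold)
  maps <- list(BL = fa_bl, EP = fa_ep)
  rows <- list()
  for (tr in all_tracts) {
    for (tp in c("BL", "EP")) {
      if (is.null(tract_masks[[tr]])) {
        rows[[length(rows) + 1L]] <- data.frame(
          tract = tr, timepoint = tp, mean_fa = NA_real_, sd_fa = NA_real_,
          n_voxels = 0L, adjusted = FALSE, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- tract_mean_fa(
          maps[[tp]], tract_masks[[tr]], common, tract = tr, timepoint = tp)
      }
    }
  }
  do.call(rbind, rows)
}
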