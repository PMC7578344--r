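# Disk layout for cohorts: per-subject TSV BOLD and motion-parameter files,
# NIfTI FA / mask volumes, a single item-response TSV, a JSON manifest, and
# a YAML copy of the generating configuration.

#' Write a cohort to a directory layout
#'
#' Layout: `manifest.json` (subjects, groups, missingness, analysis
#' constants), `config.yaml` (generator configuration), `item_responses.tsv`
#' (all subjects), and per imaging subject
#' `<id>_<TP>_bold.tsv` (volumes x ROI, header = ROI labels),
#' `<id>_<TP>_motion.tsv` (6 columns), `<id>_<TP>_fa.nii.gz`,
#' `<id>_tracts.nii.gz` (integer tract labels) and
#' `<id>_brain_mask.nii.gz`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Target directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort$config
  subj_meta <- lapply(cohort$subjects, function(s) {
    list(subject_id = s$subject_id, group = s$group,
         has_imaging = s$has_imaging, days_post_injury = s$days_post_injury,
         skull_length_mm = s$skull_length_mm %||% NA,
         missing_regions = as.list(s$missing_regions))
  })
  manifest <- list(
    subjects = subj_meta,
    networks = cfg$networks, tracts = as.list(cfg$tracts),
    n_volumes = cfg$n_volumes, tr_seconds = cfg$tr_seconds,
    n_dummy = cfg$n_dummy, voxel_mm = cfg$voxel_mm, ap_axis = cfg$ap_axis,
    mni_length_mm = cfg$mni_length_mm,
    docs_n_items = cfg$docs_n_items,
    docs_aud_lang_items = cfg$docs_aud_lang_items,
    docs_n_categories = cfg$docs_n_categories,
    cnc_n_items = cfg$cnc_n_items, cnc_timepoints = cfg$cnc_timepoints,
    docs_weeks = cfg$docs_weeks, seed = cfg$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(config_to_list(cfg), file.path(dir, "config.yaml"))

  resp <- do.call(rbind, lapply(cohort$subjects, function(s) {
    df <- s$item_responses
    df$subject <- s$subject_id
    df
  }))
  write.table(resp, file.path(dir, "item_responses.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  for (s in cohort$subjects) {
    if (!s$has_imaging) next
    for (tp in c("BL", "EP")) {
      b <- s$bold[[tp]]
      write.table(as.data.frame(b$data),
                  file.path(dir, sprintf("%s_%s_bold.tsv", s$subject_id, tp)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      mo <- as.data.frame(b$motion)
      colnames(mo) <- c("tx_mm", "ty_mm", "tz_mm", "rx_rad", "ry_rad", "rz_rad")
      write.table(mo,
                  file.path(dir, sprintf("%s_%s_motion.tsv", s$subject_id, tp)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      RNifti::writeNifti(s$fa[[tp]],
                         file.path(dir, sprintf("%s_%s_fa.nii.gz", s$subject_id, tp)))
    }
    lab <- array(0L, dim(s$fa$BL))
    for (tr in names(s$tract_masks)) {
      lab[s$tract_masks[[tr]]] <- match(tr, cfg$tracts)
    }
    RNifti::writeNifti(lab, file.path(dir, sprintf("%s_tracts.nii.gz",
                                                   s$subject_id)))
    RNifti::writeNifti(s$brain_mask + 0L,
                       file.path(dir, sprintf("%s_brain_mask.nii.gz",
                                              s$subject_id)))
  }
  invisible(dir)
}

#' Read a cohort from its directory layout
#'
#' Rebuilds a cohort object (subjects with BOLD series, motion parameters,
#' FA maps, tract masks, item responses, missingness) from the layout
#' written by [write_cohort()], sufficient to drive
#' [run_full_pipeline()].
#'
#' @param dir Cohort directory.
#' @return A `synthetic_cohort`-shaped list.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- read_cohort_config(file.path(dir, "config.yaml"))
  resp <- read.delim(file.path(dir, "item_responses.tsv"),
                     stringsAsFactors = FALSE)
  subjects <- vector("list", nrow(manifest$subjects))
  for (i in seq_len(nrow(manifest$subjects))) {
    m <- manifest$subjects[i, ]
    s <- list(subject_id = m$subject_id, group = m$group,
              subject_index = i, has_imaging = m$has_imaging,
              days_post_injury = m$days_post_injury,
              skull_length_mm = m$skull_length_mm,
              missing_regions = unlist(m$missing_regions) %||% character(0))
    s$item_responses <- resp[resp$subject == s$subject_id,
                             setdiff(names(resp), "subject")]
    if (isTRUE(s$has_imaging)) {
      s$bold <- list()
      for (tp in c("BL", "EP")) {
        dat <- as.matrix(read.delim(
          file.path(dir, sprintf("%s_%s_bold.tsv", s$subject_id, tp))))
        mo <- as.matrix(read.delim(
          file.path(dir, sprintf("%s_%s_motion.tsv", s$subject_id, tp))))
        s$bold[[tp]] <- structure(
          list(data = dat, tr_seconds = manifest$tr_seconds,
               missing_rois = intersect(colnames(dat), s$missing_regions),
               motion = unname(mo), subject_id = s$subject_id,
               timepoint = tp),
          class = "roi_timeseries")
      }
      s$fa <- list(
        BL = as.array(RNifti::readNifti(
          file.path(dir, sprintf("%s_BL_fa.nii.gz", s$subject_id)))),
        EP = as.array(RNifti::readNifti(
          file.path(dir, sprintf("%s_EP_fa.nii.gz", s$subject_id)))))
      lab <- as.array(RNifti::readNifti(
        file.path(dir, sprintf("%s_tracts.nii.gz", s$subject_id))))
      tracts <- unlist(manifest$tracts)
      s$tract_masks <- list()
      for (t_i in sort(unique(lab[lab > 0]))) {
        s$tract_masks[[tracts[t_i]]] <- which(lab == t_i, arr.ind = TRUE)
      }
      s$brain_mask <- as.array(RNifti::readNifti(
        file.path(dir, sprintf("%s_brain_mask.nii.gz", s$subject_id)))) > 0
    }
    subjects[[i]] <- s
  }
  structure(list(subjects = subjects, config = cfg),
            class = "synthetic_cohort")
}

# flatten a cohort_config for YAML (matrices and named vectors become
# nested lists, so names survive the round trip)
config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$between_r <- lapply(cfg$between_r, function(m)
    list(labels = rownames(m), values = apply(m, 1, as.list)))
  out$within_r <- lapply(cfg$within_r, as.list)
  for (nm in c("fa_baseline", "docs_baseline_mean", "docs_slope",
               "cnc_baseline_mean", "cnc_slope")) {
    out[[nm]] <- as.list(cfg[[nm]])
  }
  out$fa_group_time_effect <- lapply(cfg$fa_group_time_effect, as.list)
  out
}

#' Read a cohort configuration from YAML
#'
#' Rebuilds a validated [cohort_config()] from the `config.yaml` written by
#' [write_cohort()] (or hand-written with the same field names).
#'
#' @param path YAML file path.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$between_r)) {
    raw$between_r <- lapply(raw$between_r, function(b) {
      labs <- unlist(b$labels)
      m <- do.call(rbind, lapply(b$values, unlist))
      dimnames(m) <- list(labs, labs)
      m[labs, labs]
    })
  }
  if (!is.null(raw$within_r)) {
    raw$within_r <- lapply(raw$within_r, unlist)
  }
  for (nm in c("fa_baseline", "docs_baseline_mean", "docs_slope",
               "cnc_baseline_mean", "cnc_slope", "rater_severities")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  if (!is.null(raw$fa_group_time_effect)) {
    raw$fa_group_time_effect <- lapply(raw$fa_group_time_effect, unlist)
  }
  if (!is.null(raw$networks)) raw$networks <- lapply(raw$networks, unlist)
  keep <- intersect(names(raw), names(formals(cohort_config)))
  do.call(cohort_config, raw[keep])
}
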