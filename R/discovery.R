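# Discovery stage: correlations between model-derived connectivity change
# and neurobehavioral change, significance filtering, and the adjusted-FA
# verification that labels a positive finding robust. run_full_pipeline()
# chains every stage of the analysis over a cohort.

#' Correlate connectivity change with neurobehavioral change
#'
#' Pearson correlations between per-subject connectivity change indices and
#' neurobehavioral change indices, computed within group by default (the
#' per-arm analysis the discovery design implies) over features that
#' survived baseline screening. Significance uses the t transform
#' `t = r sqrt((n-2)/(1-r^2))`; the FDR flag applies the Benjamini-Hochberg
#' step-up rule over the whole discovery family at `q`. Zero-variance
#' inputs yield an undefined correlation, flagged rather than dropped.
#'
#' @param change_table Data frame: `subject`, `group`, `measure`,
#'   `feature_class` (`"rsfc"` or `"fa"`), `change`.
#' @param outcomes_table Data frame: `subject`, `group`, `outcome`,
#'   `change`.
#' @param screened_out Features excluded by [baseline_screen()].
#' @param per_group Correlate within each arm (default) or pooled.
#' @param q FDR level over the discovery family.
#' @param alpha Raw two-sided significance level.
#' @return Data frame of class `correlation_findings`: one row per (group,
#'   feature, outcome) with `n`, `r`, `p`, `raw_significant`,
#'   `fdr_significant`.
#' @export
change_correlations <- function(change_table, outcomes_table,
                                screened_out = character(),
                                per_group = TRUE, q = 0.20, alpha = 0.05) {
  feats <- setdiff(unique(change_table$measure), screened_out)
  outs <- unique(outcomes_table$outcome)
  groups <- if (per_group) sort(unique(as.character(change_table$group)))
            else "pooled"
  rows <- list()
  for (g in groups) {
    for (f in feats) {
      ch <- change_table[change_table$measure == f, ]
      if (per_group) ch <- ch[ch$group == g, ]
      for (o in outs) {
        oc <- outcomes_table[outcomes_table$outcome == o, ]
        if (per_group) oc <- oc[oc$group == g, ]
        m <- merge(ch[, c("subject", "change")],
                   oc[, c("subject", "change")], by = "subject",
                   suffixes = c("_feat", "_out"))
        m <- m[complete.cases(m), ]
        n <- nrow(m)
        fc <- ch$feature_class[1]
        if (n < 3 || sd(m$change_feat) == 0 || sd(m$change_out) == 0) {
          rows[[length(rows) + 1L]] <- data.frame(
            group = g, measure = f, feature_class = fc, outcome = o, n = n,
            r = NA_real_, t = NA_real_, p = NA_real_,
            raw_significant = FALSE, fdr_significant = FALSE,
            undefined = TRUE, stringsAsFactors = FALSE)
          next
        }
        r <- cor(m$change_feat, m$change_out)
        tv <- r * sqrt((n - 2) / max(1 - r^2, 1e-12))
        p <- 2 * pt(-abs(tv), df = n - 2)
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, measure = f, feature_class = fc, outcome = o, n = n,
          r = r, t = tv, p = p, raw_significant = p < alpha,
          fdr_significant = FALSE, undefined = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(group = character(0), measure = character(0),
                      feature_class = character(0), outcome = character(0),
                      n = integer(0), r = numeric(0), t = numeric(0),
                      p = numeric(0), raw_significant = logical(0),
                      fdr_significant = logical(0), undefined = logical(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    ok <- !is.na(out$p)
    out$fdr_significant[ok] <- bh_fdr(out$p[ok], q)
  }
  class(out) <- c("correlation_findings", class(out))
  out
}

#' Fisher-z comparison of two correlations
#'
#' Two-sided test of the difference between two independent correlations
#' via the Fisher z transform, used when comparing network-network
#' correlation strengths between arms.
#'
#' @param r1,r2 Correlations; `n1`, `n2` their sample sizes (> 3).
#' @return List with `z` and `p.value`.
#' @export
compare_correlations_z <- function(r1, n1, r2, n2) {
  stopifnot(n1 > 3, n2 > 3)
  z <- (fisher_z(r1) - fisher_z(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p.value = 2 * stats::pnorm(-abs(z)))
}

#' Verify a positive FA-outcome correlation with length-adjusted tracts
#'
#' Rebuilds the tract's FA change indices with the tract-length
#' standardization ([adjusted_tract_mask()] anchored at the posterior pole,
#' cohort-minimum length scaled by relative skull length), refits the mixed
#' model, recomputes the correlation with the same outcome in each arm, and
#' flags the finding robust iff the verified correlation in the finding's
#' arm remains positive (significance is not required). Subjects missing
#' the tract are imputed from the group prediction and flagged.
#'
#' @param finding One row of a `correlation_findings` table (positive FA
#'   finding).
#' @param cohort The `synthetic_cohort` (or any cohort with `fa`,
#'   `tract_masks`, `brain_mask` per imaging subject).
#' @param outcomes_table As in [change_correlations()].
#' @param fa_threshold Common-voxel-mask threshold.
#' @return The finding row augmented with `verified_r`, `robust`, and an
#'   attribute `"verification"` carrying per-arm verified correlations and
#'   the adjusted change indices.
#' @export
verify_positive_finding <- function(finding, cohort, outcomes_table,
                                    fa_threshold = 0.2) {
  stopifnot(nrow(finding) == 1)
  if (!identical(finding$feature_class, "fa") ||
      is.na(finding$r) || finding$r <= 0) {
    stop("verification applies to positive FA-outcome correlations only")
  }
  tract <- finding$measure
  cfg <- cohort$config
  img <- Filter(function(s) s$has_imaging, cohort$subjects)
  have <- Filter(function(s) !is.null(s$tract_masks[[tract]]), img)
  if (length(have) < 2) stop("too few subjects with tract ", tract)
  masks <- lapply(have, function(s) s$tract_masks[[tract]])
  names(masks) <- vapply(have, `[[`, "", "subject_id")
  skull <- vapply(have, function(s)
    skull_length_ap(s$brain_mask, cfg$voxel_mm, cfg$ap_axis), numeric(1))
  names(skull) <- names(masks)
  adj <- adjusted_tract_mask(masks, skull, cfg$mni_length_mm,
                             ap_axis = cfg$ap_axis, voxel_mm = cfg$voxel_mm)
  rows <- list()
  for (s in have) {
    common <- common_voxel_mask(s$fa$BL, s$fa$EP, fa_threshold)
    for (tp in c("BL", "EP")) {
      r <- tract_mean_fa(s$fa[[tp]], adj$masks[[s$subject_id]], common,
                         tract = tract, timepoint = tp, adjusted = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s$subject_id, group = s$group,
        time = if (tp == "BL") 0 else 1, value = r$mean_fa,
        stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, rows)
  fit <- fit_mlm(long, measure = paste0(tract, "_adjusted"), time_ep = 1)
  idx <- derive_indices(fit)
  miss <- setdiff(vapply(img, `[[`, "", "subject_id"), idx$subject)
  if (length(miss)) {
    grp <- setNames(vapply(img, `[[`, "", "group"),
                    vapply(img, `[[`, "", "subject_id"))
    idx <- rbind(idx, impute_missing(fit, miss, grp))
  }
  oc <- outcomes_table[outcomes_table$outcome == finding$outcome, ]
  per_group <- lapply(sort(unique(idx$group)), function(g) {
    m <- merge(idx[idx$group == g, c("subject", "change")],
               oc[oc$group == g, c("subject", "change")], by = "subject",
               suffixes = c("_feat", "_out"))
    m <- m[complete.cases(m), ]
    r <- if (nrow(m) >= 3 && sd(m$change_feat) > 0 && sd(m$change_out) > 0)
      cor(m$change_feat, m$change_out) else NA_real_
    data.frame(group = g, verified_r = r, n = nrow(m),
               stringsAsFactors = FALSE)
  })
  per_group <- do.call(rbind, per_group)
  vr <- per_group$verified_r[per_group$group == finding$group]
  finding$verified_r <- vr
  finding$robust <- isTRUE(vr > 0)
  attr(finding, "verification") <- list(
    per_group = per_group, adjusted_indices = idx,
    min_length_voxels = adj$min_length_voxels,
    adjusted_lengths = adj$adjusted_length_voxels,
    imputed_subjects = miss)
  finding
}

# assemble behavioral long tables and Rasch fits for a cohort
behavioral_measures <- function(cohort) {
  cfg <- cohort$config
  resp <- do.call(rbind, lapply(cohort$subjects, function(s) {
    df <- s$item_responses
    df$subject <- s$subject_id
    df$group <- s$group
    df
  }))
  resp$person <- paste(resp$subject, resp$occasion, sep = "@")
  out <- list()
  specs <- list(
    DOCS_total = list(inst = "DOCS", items = seq_len(cfg$docs_n_items),
                      facet = TRUE, t_ep = max(cfg$docs_weeks)),
    DOCS_auditory_language = list(inst = "DOCS",
                                  items = cfg$docs_aud_lang_items,
                                  facet = TRUE, t_ep = max(cfg$docs_weeks)),
    CNC = list(inst = "CNC", items = seq_len(cfg$cnc_n_items),
               facet = FALSE, t_ep = cfg$cnc_timepoints - 1))
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    sub <- resp[resp$instrument == sp$inst & resp$item %in% sp$items, ]
    # items observed in a single category (among non-extreme persons) carry
    # no information for joint estimation; drop them from the fit
    sub <- filter_informative_items(sub)
    fit <- if (sp$facet) fit_mfrm(sub) else fit_partial_credit(sub)
    mm <- fit$measures
    parts <- strsplit(mm$person, "@", fixed = TRUE)
    mm$subject <- vapply(parts, `[[`, "", 1)
    mm$time <- as.numeric(vapply(parts, `[[`, "", 2))
    mm$group <- resp$group[match(mm$subject, resp$subject)]
    out[[nm]] <- list(fit = fit, measures = mm, t_ep = sp$t_ep)
  }
  out
}

#' Run the full discovery pipeline on a cohort
#'
#' Chains every stage: motion QC and truncation, within/between-network
#' rsFC metrics, tract-mean FA extraction, Rasch person measurement and
#' conditional-MDC gain flags, per-measure mixed-model change indices with
#' group-nested imputation and MAE/MARE validation, exact permutation tests
#' with FDR filtering (network and tract families), baseline screening,
#' change-change correlation discovery, and adjusted-FA verification of
#' positive FAST-arm FA findings. Fully deterministic given the cohort.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()] or
#'   [read_cohort()].
#' @param fd_max,dvars_max Censoring thresholds.
#' @param target_length Common retained length; `NULL` uses the cohort
#'   minimum.
#' @param q FDR level for all families.
#' @param alpha Raw significance level for discovery correlations.
#' @param verify_group Arm whose positive FA findings trigger verification
#'   (default `"FAST"`).
#' @return Object of class `doc_pipeline_report`; see the elements
#'   `qc`, `motion_tests`, `metrics`, `change_indices`, `validation`,
#'   `perm_tests`, `screen`, `findings`, `verification`, `meaningful_gains`.
#' @export
run_full_pipeline <- function(cohort, fd_max = 0.5, dvars_max = 50,
                              target_length = NULL, q = 0.20, alpha = 0.05,
                              verify_group = "FAST") {
  cfg <- cohort$config
  img <- Filter(function(s) s$has_imaging, cohort$subjects)
  sub_ids <- vapply(img, `[[`, "", "subject_id")
  groups <- setNames(vapply(img, `[[`, "", "group"), sub_ids)

  # --- stage 1: motion QC --------------------------------------------------
  qc <- list()
  masks <- list()
  for (s in img) {
    for (tp in c("BL", "EP")) {
      key <- paste(s$subject_id, tp, sep = ":")
      qc[[key]] <- qc_acquisition(s$bold[[tp]], n_dummy = cfg$n_dummy,
                                  fd_max = fd_max, dvars_max = dvars_max)
      masks[[key]] <- qc[[key]]$trace$retained
    }
  }
  kept <- truncate_to_common_length(masks, target_length)
  qc_summary <- do.call(rbind, lapply(names(qc), function(k) {
    parts <- strsplit(k, ":", fixed = TRUE)[[1]]
    tr <- qc[[k]]$trace
    data.frame(subject = parts[1], timepoint = parts[2],
               mean_fd = mean(tr$fd), mean_dvars = mean(tr$dvars),
               n_retained = sum(tr$retained), n_used = length(kept[[k]]),
               stringsAsFactors = FALSE)
  }))

  motion_tests <- list()
  for (g in unique(groups)) {
    ids <- names(groups)[groups == g]
    for (met in c("mean_fd", "mean_dvars")) {
      bl <- qc_summary[[met]][match(paste(ids, "BL"),
                                    paste(qc_summary$subject, qc_summary$timepoint))]
      ep <- qc_summary[[met]][match(paste(ids, "EP"),
                                    paste(qc_summary$subject, qc_summary$timepoint))]
      motion_tests[[paste(g, met, sep = ":")]] <- compare_motion_paired(bl, ep)
    }
  }

  # --- stage 2: connectivity metrics --------------------------------------
  metric_rows <- list()
  for (s in img) {
    for (tp in c("BL", "EP")) {
      key <- paste(s$subject_id, tp, sep = ":")
      ts <- list(data = qc[[key]]$filtered,
                 missing_rois = s$bold[[tp]]$missing_rois)
      cm <- connectivity_metrics(ts, cfg$networks, volumes = kept[[key]])
      metric_rows[[length(metric_rows) + 1L]] <- data.frame(
        subject = s$subject_id, group = s$group,
        time = if (tp == "BL") 0 else 1, measure = cm$measure,
        feature_class = "rsfc", value = cm$value, stringsAsFactors = FALSE)
    }
    fa_tab <- tract_fa_table(s$fa$BL, s$fa$EP, s$tract_masks,
                             all_tracts = cfg$tracts)
    metric_rows[[length(metric_rows) + 1L]] <- data.frame(
      subject = s$subject_id, group = s$group,
      time = ifelse(fa_tab$timepoint == "BL", 0, 1), measure = fa_tab$tract,
      feature_class = "fa", value = fa_tab$mean_fa, stringsAsFactors = FALSE)
  }
  metrics <- do.call(rbind, metric_rows)

  # --- stage 3: Rasch measurement and behavioral change --------------------
  beh <- behavioral_measures(cohort)
  outcome_rows <- list()
  mdc_rows <- list()
  for (nm in names(beh)) {
    mm <- beh[[nm]]$measures
    long <- data.frame(subject = mm$subject, group = mm$group,
                       time = mm$time, value = mm$measure,
                       stringsAsFactors = FALSE)
    bfit <- fit_mlm(long, measure = nm, time_ep = beh[[nm]]$t_ep)
    idx <- derive_indices(bfit)
    outcome_rows[[nm]] <- data.frame(subject = idx$subject, group = idx$group,
                                     outcome = nm, bl = idx$bl, ep = idx$ep,
                                     change = idx$change,
                                     stringsAsFactors = FALSE)
    t0 <- min(mm$time)
    te <- beh[[nm]]$t_ep
    for (sid in unique(mm$subject)) {
      mb <- mm[mm$subject == sid & mm$time == t0, ]
      me <- mm[mm$subject == sid & mm$time == te, ]
      if (nrow(mb) && nrow(me)) {
        md <- conditional_mdc(mb$measure, me$measure, mb$sem, me$sem)
        mdc_rows[[length(mdc_rows) + 1L]] <- data.frame(
          subject = sid, outcome = nm, gain = md$gain, mdc = md$mdc,
          meaningful = md$meaningful, stringsAsFactors = FALSE)
      }
    }
  }
  outcomes <- do.call(rbind, outcome_rows)
  rownames(outcomes) <- NULL
  outcomes_img <- outcomes[outcomes$subject %in% sub_ids, ]
  meaningful_gains <- do.call(rbind, mdc_rows)

  # --- stage 4: mixed-model change indices for imaging features ------------
  features <- unique(metrics$measure)
  change_rows <- list()
  validation_rows <- list()
  fits <- list()
  for (f in features) {
    sub <- metrics[metrics$measure == f, ]
    observed <- unique(sub$subject[!is.na(sub$value)])
    long <- data.frame(subject = sub$subject, group = sub$group,
                       time = sub$time, value = sub$value,
                       stringsAsFactors = FALSE)
    fit <- fit_mlm(long, measure = f, time_ep = 1)
    fits[[f]] <- fit
    idx <- derive_indices(fit)
    missing_sub <- setdiff(sub_ids, observed)
    if (length(missing_sub)) {
      idx <- rbind(idx, impute_missing(fit, missing_sub, groups))
    }
    idx$feature_class <- sub$feature_class[1]
    change_rows[[f]] <- idx
    v <- validate_fit(fit)
    v$measure <- f
    validation_rows[[f]] <- v
  }
  change_indices <- do.call(rbind, change_rows)
  rownames(change_indices) <- NULL
  validation <- do.call(rbind, validation_rows)
  rownames(validation) <- NULL

  # --- stage 5: permutation tests with FDR families ------------------------
  fc <- setNames(
    metrics$feature_class[match(features, metrics$measure)], features)
  perm_rows <- list()
  for (f in features) {
    ci <- change_indices[change_indices$measure == f, ]
    ga <- ci[ci$group == "FAST", ]
    gb <- ci[ci$group == "placebo", ]
    # two-sided counting for the summary-table tests: the within/between
    # summary prints ordered p values above 0.5, which only a two-sided
    # count produces
    tests <- list(
      change_FAST = signflip_perm_test(ga$change, alternative = "two.sided"),
      change_placebo = signflip_perm_test(gb$change,
                                          alternative = "two.sided"),
      BL = group_perm_test(ga$bl, gb$bl, alternative = "two.sided"),
      EP = group_perm_test(ga$ep, gb$ep, alternative = "two.sided"))
    for (ct in names(tests)) {
      perm_rows[[length(perm_rows) + 1L]] <- data.frame(
        measure = f, feature_class = fc[[f]], contrast = ct,
        t1 = tests[[ct]]$t1, n_perms = tests[[ct]]$n_perms,
        ordered_p = tests[[ct]]$ordered_p, stringsAsFactors = FALSE)
    }
  }
  perm_tests <- do.call(rbind, perm_rows)
  rownames(perm_tests) <- NULL
  perm_tests$fdr_significant <- FALSE
  for (cls in unique(perm_tests$feature_class)) {
    for (ct in unique(perm_tests$contrast)) {
      sel <- perm_tests$feature_class == cls & perm_tests$contrast == ct
      perm_tests$fdr_significant[sel] <- bh_fdr(perm_tests$ordered_p[sel], q)
    }
  }

  # --- stage 6: baseline screening -----------------------------------------
  screen_rows <- list()
  for (cls in unique(change_indices$feature_class)) {
    bl_tab <- change_indices[change_indices$feature_class == cls,
                             c("measure", "group", "bl")]
    screen_rows[[cls]] <- baseline_screen(bl_tab, q = q)
  }
  screen <- do.call(rbind, screen_rows)
  rownames(screen) <- NULL
  screened_out <- screen$measure[screen$excluded]

  # --- stage 7: discovery correlations -------------------------------------
  findings <- change_correlations(
    change_indices[, c("subject", "group", "measure", "feature_class",
                       "change")],
    outcomes_img[, c("subject", "group", "outcome", "change")],
    screened_out = screened_out, q = q, alpha = alpha)

  # --- stage 8: verification of positive FA findings -----------------------
  to_verify <- which(findings$feature_class == "fa" &
                       findings$raw_significant &
                       !is.na(findings$r) & findings$r > 0 &
                       findings$group %in% verify_group)
  verification <- list()
  findings$verified_r <- NA_real_
  findings$robust <- NA
  for (i in to_verify) {
    vf <- verify_positive_finding(findings[i, ], cohort, outcomes_img)
    findings$verified_r[i] <- vf$verified_r
    findings$robust[i] <- vf$robust
    verification[[paste(vf$group, vf$measure, vf$outcome, sep = ":")]] <-
      attr(vf, "verification")
  }

  structure(list(
    qc = qc_summary, motion_tests = motion_tests, metrics = metrics,
    outcomes = outcomes, meaningful_gains = meaningful_gains,
    change_indices = change_indices, validation = validation,
    perm_tests = perm_tests, screen = screen, screened_out = screened_out,
    findings = findings, verification = verification,
    settings = list(fd_max = fd_max, dvars_max = dvars_max, q = q,
                    alpha = alpha, target_length = attr(kept, "target"))),
    class = "doc_pipeline_report")
}

#' @export
print.doc_pipeline_report <- function(x, ...) {
  cat("discovery pipeline report\n")
  cat(sprintf("  subjects: %d acquisitions, common length %d volumes\n",
              nrow(x$qc), x$settings$target_length))
  cat(sprintf("  features: %d (%d screened out at baseline)\n",
              length(unique(x$metrics$measure)), length(x$screened_out)))
  nf <- sum(x$findings$raw_significant, na.rm = TRUE)
  cat(sprintf("  findings: %d raw-significant, %d FDR-filtered, %d verified robust\n",
              nf, sum(x$findings$fdr_significant, na.rm = TRUE),
              sum(x$findings$robust %in% TRUE)))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits a machine-readable `results.json` plus TSV tables (network and
#' tract permutation tables shaped like the within/between-arm summary, the
#' change-index table, and the findings table) under `dir`.
#'
#' @param report A `doc_pipeline_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tdir <- file.path(dir, "tables")
  dir.create(tdir, showWarnings = FALSE)
  paths <- character(0)
  j <- file.path(dir, "results.json")
  jsonlite::write_json(list(
    qc = report$qc, motion_tests = lapply(report$motion_tests, function(m)
      m[c("statistic", "p.value", "n_used", "exact")]),
    perm_tests = report$perm_tests, screen = report$screen,
    findings = report$findings, validation = report$validation,
    meaningful_gains = report$meaningful_gains,
    settings = report$settings),
    j, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, j)
  for (nm in c("perm_tests", "change_indices", "findings", "screen",
               "validation", "meaningful_gains", "outcomes")) {
    p <- file.path(tdir, paste0(nm, ".tsv"))
    write.table(report[[nm]], p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
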