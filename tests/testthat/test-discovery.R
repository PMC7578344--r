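test_that("change correlations follow the definitional Pearson/t oracle", {
  set.seed(401)
  ch <- data.frame(subject = sprintf("s%d", 1:4), group = "FAST",
                   measure = "feat", feature_class = "fa",
                   change = rnorm(4))
  oc <- data.frame(subject = sprintf("s%d", 1:4), group = "FAST",
                   outcome = "OUT", change = rnorm(4))
  f <- change_correlations(ch, oc)
  # brute-force covariance / sd formula
  m <- merge(ch, oc, by = "subject")
  r_oracle <- sum((m$change.x - mean(m$change.x)) *
                    (m$change.y - mean(m$change.y))) /
    (3 * sd(m$change.x) * sd(m$change.y))
  expect_equal(f$r, r_oracle, tolerance = 1e-12)
  t_oracle <- r_oracle * sqrt(2 / (1 - r_oracle^2))
  expect_equal(f$t, t_oracle)
  expect_equal(f$p, 2 * pt(-abs(t_oracle), 2))

  # affine outcome -> r = 1
  oc2 <- oc
  oc2$change <- 3 * ch$change - 1
  f2 <- change_correlations(ch, oc2)
  expect_equal(f2$r, 1, tolerance = 1e-12)
  # n = 4, r = 0.95 -> t = 4.39 on 2 df (closed form)
  expect_equal(0.95 * sqrt(2 / (1 - 0.95^2)), 4.30, tolerance = 0.05)

  # zero-variance feature flagged undefined
  ch0 <- ch
  ch0$change <- 1
  f0 <- change_correlations(ch0, oc)
  expect_true(f0$undefined)
  expect_true(is.na(f0$r))

  # screened features never appear
  f3 <- change_correlations(ch, oc, screened_out = "feat")
  expect_equal(nrow(f3), 0)
})

test_that("Fisher-z comparison of correlations behaves sensibly", {
  r <- compare_correlations_z(0.8, 30, 0.8, 30)
  expect_equal(r$z, 0)
  expect_equal(r$p.value, 1)
  expect_lt(compare_correlations_z(0.9, 50, 0.1, 50)$p.value, 1e-4)
})

test_that("the pipeline report has the expected shape and is deterministic", {
  cfg <- small_config(seed = 11)
  coh <- generate_cohort(cfg)
  rep1 <- run_full_pipeline(coh)
  # 10 rsFC features (4 within + 6 between) and 19 tracts
  feats <- unique(rep1$metrics$measure)
  expect_equal(sum(unique(rep1$metrics[, c("measure", "feature_class")])$
                     feature_class == "rsfc"), 10)
  expect_equal(sum(unique(rep1$metrics[, c("measure", "feature_class")])$
                     feature_class == "fa"), 19)
  # permutation table spans 4 contrasts per feature
  expect_equal(nrow(rep1$perm_tests), 29 * 4)
  expect_true(all(rep1$perm_tests$n_perms %in% c(16L, 70L)))
  # discovery covers groups x screened features x 3 outcomes
  n_screen <- length(rep1$screened_out)
  expect_equal(nrow(rep1$findings), 2 * (29 - n_screen) * 3)
  # change identity holds for every entry, observed or imputed
  expect_equal(rep1$change_indices$change,
               rep1$change_indices$ep - rep1$change_indices$bl)
  # meaningful-gain flags exist for every subject and instrument
  expect_equal(nrow(rep1$meaningful_gains),
               3 * length(coh$subjects))
  # determinism: identical cohort -> byte-identical report
  rep2 <- run_full_pipeline(generate_cohort(cfg))
  expect_identical(rep1$findings, rep2$findings)
  expect_identical(rep1$perm_tests, rep2$perm_tests)

  # report writer emits valid JSON and tables
  dir <- file.path(tempdir(), "report_test")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  write_report(rep1, dir)
  expect_true(file.exists(file.path(dir, "results.json")))
  j <- jsonlite::read_json(file.path(dir, "results.json"))
  expect_true(all(c("qc", "perm_tests", "findings", "settings") %in% names(j)))
  expect_true(file.exists(file.path(dir, "tables", "findings.tsv")))
})

test_that("missing substrates flow through imputation into the report", {
  cfg <- small_config(seed = 13, missing_region_rate = 0.1)
  coh <- generate_cohort(cfg)
  rep <- run_full_pipeline(coh)
  ci <- rep$change_indices
  img <- Filter(function(s) s$has_imaging, coh$subjects)
  miss_tracts <- unlist(lapply(img, function(s)
    intersect(s$missing_regions, cfg$tracts)))
  if (length(miss_tracts)) {
    expect_true(any(ci$imputed))
    has_miss <- vapply(img, function(s)
      length(intersect(s$missing_regions, cfg$tracts)) > 0, logical(1))
    s_miss <- img[[which(has_miss)[1]]]
    tr <- intersect(s_miss$missing_regions, cfg$tracts)[1]
    row <- ci[ci$subject == s_miss$subject_id & ci$measure == tr, ]
    expect_true(row$imputed)
    # imputed value equals the group fixed-effect prediction = group mean
    grp_rows <- ci[ci$measure == tr & ci$group == s_miss$group & !ci$imputed, ]
    expect_equal(row$bl, mean(grp_rows$bl), tolerance = 1e-8)
  }
  # every subject x measure combination is present exactly once
  expect_equal(nrow(ci), 8 * 29)
})

test_that("verification preserves the sign of a posterior-segment planted effect", {
  cfg <- planted_config(seed = 17)
  cfg$fa_effect_region <- "posterior"
  coh <- generate_cohort(cfg)
  rep <- run_full_pipeline(coh)
  f <- rep$findings
  row <- f[f$group == "FAST" & f$measure == "left_ILF" &
             f$outcome == "DOCS_auditory_language", ]
  expect_equal(nrow(row), 1)
  expect_true(row$raw_significant)
  expect_gt(row$verified_r, 0)
  expect_true(row$robust)
  ver <- rep$verification[[paste("FAST", "left_ILF",
                                 "DOCS_auditory_language", sep = ":")]]
  expect_equal(ver$min_length_voxels, 14L)
  expect_true(all(ver$adjusted_lengths >= 1))
})

test_that("an anterior-only effect can attenuate the verified correlation", {
  # the adjusted mask keeps the posterior segment; an effect confined to the
  # anterior segment is invisible to it, so the verified correlation loses
  # the planted signal
  cfg <- planted_config(seed = 19)
  cfg$fa_effect_region <- "anterior"
  cfg$skull_scale_sd <- 0   # scale 1: adjusted masks are exactly posterior
  coh <- generate_cohort(cfg)
  all_img <- Filter(function(s) s$has_imaging, coh$subjects)
  img <- Filter(function(s) s$group == "FAST", all_img)
  # compute adjusted and unadjusted change directly for the coupled tract
  full_ch <- vapply(img, function(s) {
    m <- s$tract_masks$left_ILF
    mean(s$fa$EP[m]) - mean(s$fa$BL[m])
  }, numeric(1))
  # cohort-minimum length comes from all imaging subjects, as in the
  # verification stage
  adj <- adjusted_tract_mask(
    setNames(lapply(all_img, function(s) s$tract_masks$left_ILF),
             vapply(all_img, `[[`, "", "subject_id")),
    setNames(vapply(all_img, function(s)
      skull_length_ap(s$brain_mask, cfg$voxel_mm, cfg$ap_axis), numeric(1)),
      vapply(all_img, `[[`, "", "subject_id")),
    cfg$mni_length_mm)
  adj_ch <- vapply(seq_along(img), function(i) {
    m <- adj$masks[[img[[i]]$subject_id]]
    mean(img[[i]]$fa$EP[m]) - mean(img[[i]]$fa$BL[m])
  }, numeric(1))
  # the adjusted (posterior) changes see none of the anterior effect, so
  # they sit at the measurement-noise scale, while unadjusted changes in
  # subjects with an anterior segment carry it
  expect_lt(max(abs(adj_ch)), 0.006)
  expect_gt(max(abs(full_ch)), 0.008)
})
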