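test_that("configuration validates block covariance and bounds", {
  expect_s3_class(cohort_config(seed = 1), "cohort_config")
  # a wildly negative between-network correlation cannot be PSD
  bad_b <- matrix(-0.9, 4, 4)
  diag(bad_b) <- 1
  dimnames(bad_b) <- list(names(default_networks()), names(default_networks()))
  expect_error(cohort_config(between_r = list(BL = bad_b, EP = bad_b)),
               "positive semi-definite")
  expect_error(cohort_config(fa_baseline = setNames(rep(0.99, 19),
                                                    default_tracts())),
               "within \\[0, 1\\]")
  expect_error(cohort_config(rater_severities = c(0.2, 0.3)), "sum to zero")
})

test_that("cohorts have the configured arm sizes and are seed-deterministic", {
  cfg <- cohort_config(n_per_group = 4, n_behavioral_extra = 0,
                       n_volumes = 40, seed = 21)
  coh <- generate_cohort(cfg)
  expect_equal(length(coh$subjects), 8)
  grp <- vapply(coh$subjects, `[[`, "", "group")
  expect_equal(sum(grp == "FAST"), 4)
  expect_equal(sum(grp == "placebo"), 4)
  coh2 <- generate_cohort(cfg)
  expect_identical(coh, coh2)   # bit-identical regeneration
  coh3 <- generate_cohort(cohort_config(n_per_group = 4,
                                        n_behavioral_extra = 0,
                                        n_volumes = 40, seed = 22))
  expect_false(identical(coh$subjects[[1]]$bold$BL$data,
                         coh3$subjects[[1]]$bold$BL$data))
})

test_that("simulated BOLD converges to the configured correlation structure", {
  nets <- default_networks()
  w <- c(DMN = 0.5, LN = 0.3, SN = 0.3, AN = 0.3)
  b0 <- matrix(0, 4, 4, dimnames = list(names(nets), names(nets)))
  diag(b0) <- 1
  cfg <- cohort_config(n_per_group = 1, n_behavioral_extra = 0,
                       n_volumes = 10000, motion_spike_rate = 0,
                       within_r = list(BL = w, EP = w),
                       between_r = list(BL = b0, EP = b0), seed = 31)
  ts <- simulate_bold(list(subject_id = "s1"), cfg, "BL")
  cm <- cor(ts$data)
  dmn <- nets$DMN
  pair_r <- cm[dmn, dmn][upper.tri(diag(length(dmn)))]
  expect_equal(mean(pair_r), 0.5, tolerance = 0.02)
  # between-network correlations configured to 0: mean |r| small
  cross <- abs(cm[nets$DMN, nets$LN])
  expect_lte(mean(cross), 0.05)
})

test_that("neurobehavioral schedules have 6 DOCS-like and 12 CNC-like occasions", {
  cfg <- cohort_config(n_per_group = 1, n_behavioral_extra = 0,
                       n_volumes = 40, seed = 41)
  s <- list(subject_id = "s1", subject_index = 1, group = "FAST", u = 0.3)
  resp <- simulate_neurobehavioral(s, cfg)
  expect_equal(length(unique(resp$occasion[resp$instrument == "DOCS"])), 6)
  expect_equal(length(unique(resp$occasion[resp$instrument == "CNC"])), 12)
  # scores stay within each item's category range
  expect_true(all(resp$score[resp$instrument == "DOCS"] >= 0))
  expect_true(all(resp$score[resp$instrument == "DOCS"] <=
                    cfg$docs_n_categories - 1))
  cnc <- resp[resp$instrument == "CNC", ]
  for (i in unique(cnc$item)) {
    expect_true(all(cnc$score[cnc$item == i] <= cfg$cnc_categories[i] - 1))
  }
})

test_that("high ability drives responses to the top category", {
  steps <- c(-1, 0, 1)
  pr <- connrecov:::pcm_probs(30, steps)
  expect_equal(pr[length(pr)], 1, tolerance = 1e-8)
})

test_that("simulated response frequencies match the analytic category probabilities", {
  steps <- c(-0.5, 0.2, 0.9)
  theta <- 0.4
  pr <- connrecov:::pcm_probs(theta, steps)
  set.seed(51)
  n <- 10000
  draws <- sample.int(length(pr), n, replace = TRUE, prob = pr)
  freq <- tabulate(draws, nbins = length(pr)) / n
  se <- sqrt(pr * (1 - pr) / n)
  expect_true(all(abs(freq - pr) <= 3 * se + 1e-9))
})

test_that("missingness guarantees, constraints and propagation hold", {
  cfg <- cohort_config(n_per_group = 4, n_behavioral_extra = 0,
                       n_volumes = 40, missing_region_rate = 0.08, seed = 61)
  coh <- generate_cohort(cfg)
  img <- Filter(function(s) s$has_imaging, coh$subjects)
  n_miss <- vapply(img, function(s) length(s$missing_regions), numeric(1))
  expect_true(all(n_miss >= 1))   # guarantee
  # every (group, region) keeps at least 2 observed subjects
  for (g in c("FAST", "placebo")) {
    gs <- Filter(function(s) s$group == g, img)
    for (r in c(cfg$rois, cfg$tracts)) {
      n_obs <- sum(!vapply(gs, function(s) r %in% s$missing_regions,
                           logical(1)))
      expect_gte(n_obs, 2)
    }
  }
  # missing ROI series are NA; missing tracts dropped from the mask list
  s1 <- img[[which(n_miss > 0)[1]]]
  for (r in s1$missing_regions) {
    if (r %in% cfg$rois) {
      expect_true(all(is.na(s1$bold$BL$data[, r])))
      expect_true(r %in% s1$bold$BL$missing_rois)
    } else {
      expect_null(s1$tract_masks[[r]])
    }
  }
  # rate 0 with the guarantee off: nothing missing
  cfg0 <- cohort_config(n_per_group = 2, n_behavioral_extra = 0,
                        n_volumes = 40, missing_region_rate = 0,
                        missing_guarantee = FALSE, seed = 62)
  coh0 <- generate_cohort(cfg0)
  expect_true(all(vapply(coh0$subjects, function(s)
    length(s$missing_regions) == 0, logical(1))))
})

test_that("cohort round-trips through the directory layout", {
  cfg <- cohort_config(n_per_group = 2, n_behavioral_extra = 1,
                       n_volumes = 40, seed = 71)
  coh <- generate_cohort(cfg)
  dir <- file.path(tempdir(), "cohort_io_test")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  back <- read_cohort(dir)
  expect_equal(length(back$subjects), length(coh$subjects))
  s0 <- coh$subjects[[1]]
  s1 <- back$subjects[[1]]
  expect_equal(unname(s1$bold$BL$data), unname(s0$bold$BL$data),
               tolerance = 1e-6)
  expect_equal(s1$bold$EP$motion, unname(s0$bold$EP$motion),
               tolerance = 1e-6)
  expect_equal(as.vector(s1$fa$BL), as.vector(s0$fa$BL), tolerance = 1e-6)
  expect_setequal(names(s1$tract_masks), names(s0$tract_masks))
  m0 <- s0$tract_masks$right_UF
  m1 <- s1$tract_masks$right_UF
  expect_setequal(apply(m1, 1, paste, collapse = ","),
                  apply(m0, 1, paste, collapse = ","))
  expect_equal(sort(s1$missing_regions), sort(s0$missing_regions))
  expect_equal(nrow(s1$item_responses), nrow(s0$item_responses))
  # the reconstructed cohort drives the pipeline the same way
  cfg2 <- read_cohort_config(file.path(dir, "config.yaml"))
  expect_equal(cfg2$n_volumes, cfg$n_volumes)
  expect_equal(cfg2$networks, cfg$networks)
})
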