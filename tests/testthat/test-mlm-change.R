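test_that("noiseless common-slope data is fit exactly", {
  tab <- expand.grid(subject = sprintf("s%d", 1:6), time = 0:3)
  tab$group <- ifelse(as.integer(sub("s", "", tab$subject)) <= 3,
                      "FAST", "placebo")
  tab$value <- 2 + 0.7 * tab$time
  fit <- fit_mlm(tab, measure = "toy")
  expect_equal(fit$beta$slope, c(0.7, 0.7), tolerance = 1e-6)
  expect_equal(fit$beta$intercept, c(2, 2), tolerance = 1e-6)
  expect_lt(fit$var_components$sigma2_eps, 1e-6)
  idx <- derive_indices(fit)
  expect_equal(idx$change, rep(0.7 * 3, 6), tolerance = 1e-5)
})

test_that("two-timepoint fits reproduce observed values (boundary representative)", {
  set.seed(201)
  tab <- expand.grid(subject = sprintf("s%d", 1:8), time = 0:1)
  tab$group <- ifelse(as.integer(sub("s", "", tab$subject)) <= 4,
                      "FAST", "placebo")
  tab$value <- rnorm(nrow(tab))
  fit <- fit_mlm(tab, measure = "img")
  expect_equal(fit$model_type, "saturated_boundary")
  idx <- derive_indices(fit)
  key <- paste(tab$subject, tab$time)
  obs_bl <- tab$value[match(paste(idx$subject, 0), key)]
  obs_ep <- tab$value[match(paste(idx$subject, 1), key)]
  expect_equal(idx$bl, obs_bl, tolerance = 1e-10)
  expect_equal(idx$ep, obs_ep, tolerance = 1e-10)
  expect_equal(idx$change, obs_ep - obs_bl, tolerance = 1e-10)
  # validation: MAE and MARE are zero for the saturated representative
  v <- validate_fit(fit)
  expect_true(all(v$mae < 1e-10))
  expect_true(all(v$mare < 1e-10))
  # random effects sum to ~0 within each group under balance
  for (g in c("FAST", "placebo")) {
    subj <- idx$subject[idx$group == g]
    expect_equal(sum(fit$ranef$b0[fit$ranef$subject %in% subj]), 0,
                 tolerance = 1e-6)
    expect_equal(sum(fit$ranef$b1[fit$ranef$subject %in% subj]), 0,
                 tolerance = 1e-6)
  }
})

test_that("derived indices equal the model prediction at t = 0 and t_EP", {
  set.seed(202)
  tab <- simulate_mlm_table()
  fit <- fit_mlm(tab, measure = "beh")
  idx <- derive_indices(fit)
  # prediction-function oracle via the underlying lmer fit
  nd <- data.frame(subject = idx$subject, group = idx$group, time = 0)
  pr0 <- predict(fit$fit, newdata = nd)
  nd$time <- fit$time_ep
  pr1 <- predict(fit$fit, newdata = nd)
  expect_equal(idx$bl, unname(pr0), tolerance = 1e-8)
  expect_equal(idx$ep, unname(pr1), tolerance = 1e-8)
  expect_equal(idx$change, idx$ep - idx$bl)   # identity holds exactly
  # zero random effects: change = fixed slope * t_EP
  fit0 <- fit
  fit0$ranef$b0[] <- 0
  fit0$ranef$b1[] <- 0
  idx0 <- derive_indices(fit0)
  sl <- fit$beta$slope[match(idx0$group, fit$beta$group)]
  expect_equal(idx0$change, sl * fit$time_ep)
})

test_that("fixed effects are recovered without bias over 500 simulated cohorts", {
  set.seed(203)
  est <- matrix(NA_real_, 500, 2)
  for (i in 1:500) {
    tab <- simulate_mlm_table(n_per_group = 5, times = 0:3,
                              beta = list(FAST = c(1, 0.5),
                                          placebo = c(1, 0.2)),
                              sd_b0 = 0.4, sd_b1 = 0.15, sd_eps = 0.25)
    fit <- fit_mlm(tab, measure = "sim")
    est[i, ] <- fit$beta$slope
  }
  mc_se <- apply(est, 2, sd) / sqrt(500)
  expect_equal(mean(est[, 1]), 0.5, tolerance = 4 * mc_se[1])
  expect_equal(mean(est[, 2]), 0.2, tolerance = 4 * mc_se[2])
})

test_that("BLUP shrinkage reduces change-index variance relative to raw changes", {
  set.seed(204)
  ratios <- replicate(30, {
    tab <- simulate_mlm_table(n_per_group = 6, times = 0:3, sd_b1 = 0.1,
                              sd_eps = 0.6)
    fit <- fit_mlm(tab, measure = "shrink")
    idx <- derive_indices(fit)
    raw_change <- with(tab, tapply(value, subject, function(v) v[4] - v[1]))
    var(idx$change) / var(raw_change[idx$subject])
  })
  expect_lt(mean(ratios), 1)
})

test_that("imputation uses the group fixed-effect prediction and is flagged", {
  tab <- expand.grid(subject = sprintf("s%d", 1:6), time = 0:1)
  tab$group <- ifelse(as.integer(sub("s", "", tab$subject)) <= 3,
                      "FAST", "placebo")
  # all FAST subjects share value 1 at BL and 2 at EP; placebo 5 then 7
  tab$value <- ifelse(tab$group == "FAST", ifelse(tab$time == 0, 1, 2),
                      ifelse(tab$time == 0, 5, 7))
  fit <- fit_mlm(tab, measure = "const")
  imp <- impute_missing(fit, "s_new", c(s_new = "FAST"))
  expect_true(imp$imputed)
  expect_equal(imp$bl, 1)
  expect_equal(imp$ep, 2)
  expect_equal(imp$change, 1)
  # balanced group: imputed BL equals the mean of members' predicted BLs
  set.seed(205)
  tab2 <- expand.grid(subject = sprintf("s%d", 1:8), time = 0:1)
  tab2$group <- ifelse(as.integer(sub("s", "", tab2$subject)) <= 4,
                       "FAST", "placebo")
  tab2$value <- rnorm(nrow(tab2))
  fit2 <- fit_mlm(tab2, measure = "img")
  idx2 <- derive_indices(fit2)
  imp2 <- impute_missing(fit2, "sX", c(sX = "placebo"))
  expect_equal(imp2$bl, mean(idx2$bl[idx2$group == "placebo"]),
               tolerance = 1e-10)
  expect_error(impute_missing(fit2, "sY", c(sY = "ghost")),
               "no observed subjects")
})

test_that("MAE and MARE follow their definitions on a hand-built example", {
  # estimates {1.1, 0.9} against observed {1.0, 1.0}: MAE = MARE = 0.1
  est <- c(1.1, 0.9)
  obs <- c(1, 1)
  expect_equal(mean(abs(est - obs)), 0.1)
  expect_equal(mean(abs(est - obs) / abs(obs)), 0.1)
  # and validate_fit computes exactly that structure on random tables
  set.seed(206)
  tab <- simulate_mlm_table(n_per_group = 4, times = 0:2)
  fit <- fit_mlm(tab, measure = "v")
  v <- validate_fit(fit)
  idx <- derive_indices(fit)
  key <- paste(tab$subject, tab$time)
  obs_bl <- tab$value[match(paste(idx$subject, 0), key)]
  expect_equal(v$mae[v$index == "BL"], mean(abs(idx$bl - obs_bl)))
  expect_equal(v$mare[v$index == "BL"],
               mean(abs(idx$bl - obs_bl) / abs(obs_bl)))
})

test_that("chi-square imputation validation is exact on a hand computation and degenerate case", {
  # imputation equal to held-out values -> statistic 0, p = 1
  tab <- expand.grid(subject = sprintf("s%d", 1:6), time = 0:1)
  tab$group <- "FAST"
  tab$value <- ifelse(tab$time == 0, 1, 2)
  tab$value <- tab$value + rep(c(0.01, -0.01, 0.02, -0.02, 0, 0), 2)
  hold <- "s5"   # s5 sits exactly on the group prediction
  r <- validate_imputation(tab, hold, measure = "c")
  expect_lt(r$statistic, 0.2)
  expect_gt(r$p.value, 0.6)
  expect_gte(r$df, 1L)   # the zero-change direction is degenerate here
  # 3-entry holdout equals the manual quadratic-form summation
  set.seed(207)
  tab2 <- simulate_mlm_table(n_per_group = 8, times = 0:2)
  r2 <- validate_imputation(tab2, "s01", measure = "m")
  fit <- r2$fit
  rows <- tab2[tab2$subject == "s01", ]
  b <- fit$beta[fit$beta$group == "FAST", ]
  pred <- b$intercept + b$slope * rows$time
  e <- rows$value - pred
  D <- fit$var_components$vcov_re
  Zt <- cbind(1, rows$time)
  X <- matrix(0, 3, nrow(fit$fixed_vcov),
              dimnames = list(NULL, colnames(fit$fixed_vcov)))
  X[, "groupFAST"] <- 1
  X[, "groupFAST:time"] <- rows$time
  Cov <- Zt %*% D %*% t(Zt) + diag(fit$var_components$sigma2_eps, 3) +
    X %*% fit$fixed_vcov %*% t(X)
  expect_equal(r2$statistic, drop(t(e) %*% solve(Cov, e)), tolerance = 1e-8)
  expect_equal(r2$df, 3L)
})

test_that("chi-square validation p-values are calibrated under the correct model", {
  set.seed(208)
  ps <- replicate(150, {
    tab <- simulate_mlm_table(n_per_group = 30, times = 0:3,
                              sd_b0 = 0.5, sd_b1 = 0.15, sd_eps = 0.4)
    validate_imputation(tab, c("s01", "s31"), measure = "cal")$p.value
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  # roughly uniform coverage in the tails too
  expect_equal(mean(ps < 0.5), 0.5, tolerance = 0.12)
})
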