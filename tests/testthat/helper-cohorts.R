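# Shared fixtures: small, fast cohort configurations built in code.

# compact cohort for structural/pipeline tests: short scan, few extras
small_config <- function(seed = 1, ...) {
  cohort_config(n_per_group = 4, n_behavioral_extra = 3, n_volumes = 80,
                seed = seed, ...)
}

# the strong-coupling configuration used by the planted-effect recovery
# studies: a FAST-specific left-ILF FA change carried by the same latent
# recovery factor as the auditory-language ability slope, measured by a
# widened, triple-scored instrument so measurement error stays small
# relative to the planted between-subject spread
planted_config <- function(seed, coupled = TRUE) {
  cohort_config(
    fa_coupling_sd = if (coupled) 0.05 else 0,
    docs_slope_sd = 0.7, docs_n_categories = 7, threshold_spread = 2.5,
    difficulty_range = c(-8, 8), docs_aud_lang_items = seq(2, 23, by = 3),
    rater_severities = c(-0.4, 0, 0.4), missing_exclude = "left_ILF",
    seed = seed)
}

# long table from a known mixed model: group-specific fixed effects plus
# subject random intercept/slope and iid noise
simulate_mlm_table <- function(n_per_group = 6, times = 0:3,
                               beta = list(FAST = c(1, 0.5),
                                           placebo = c(1, 0.2)),
                               sd_b0 = 0.5, sd_b1 = 0.2, sd_eps = 0.3) {
  rows <- list()
  sid <- 0
  for (g in names(beta)) {
    for (i in seq_len(n_per_group)) {
      sid <- sid + 1
      b0 <- rnorm(1, sd = sd_b0)
      b1 <- rnorm(1, sd = sd_b1)
      y <- beta[[g]][1] + b0 + (beta[[g]][2] + b1) * times +
        rnorm(length(times), sd = sd_eps)
      rows[[sid]] <- data.frame(subject = sprintf("s%02d", sid), group = g,
                                time = times, value = y)
    }
  }
  do.call(rbind, rows)
}

# polytomous responses from the generating adjacent-category model
simulate_pcm_responses <- function(n_persons, difficulties, n_steps = 3,
                                   theta_sd = 1.5, severities = NULL,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  steps <- lapply(difficulties, function(d) {
    tau <- seq(-0.8, 0.8, length.out = n_steps)
    d + tau - mean(tau)
  })
  theta <- rnorm(n_persons, sd = theta_sd)
  raters <- if (is.null(severities)) "R0" else names(severities)
  rows <- list()
  for (p in seq_len(n_persons)) {
    for (rt in raters) {  # every rater scores every person: linked design
      sev <- if (is.null(severities)) 0 else severities[[rt]]
      for (i in seq_along(steps)) {
        pr <- connrecov:::pcm_probs(theta[p] - sev, steps[[i]])
        rows[[length(rows) + 1L]] <- data.frame(
          person = sprintf("p%03d", p), item = sprintf("i%02d", i),
          rater = rt, score = sample.int(length(pr), 1, prob = pr) - 1L)
      }
    }
  }
  list(responses = do.call(rbind, rows), theta = theta,
       difficulties = difficulties)
}
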