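# Rasch person measurement: partial-credit model (PCM) and its many-facet
# extension with an additive rater-severity facet, both fit by joint maximum
# likelihood (JMLE) with alternating damped Newton updates. Person-timepoint
# combinations are treated as separate measurement occasions. Extreme
# (zero/perfect) response patterns are measured via the conventional
# 0.3-score-point adjustment; step parameters for unobserved categories are
# pinned at a cap so floor-heavy response patterns cannot destabilize the
# fit.

# -- internal JMLE engine ----------------------------------------------------

rasch_jmle <- function(responses, facet = FALSE, max_iter = 500L,
                       tol = 1e-4, extreme_adjust = 0.3, delta_cap = 12,
                       trace = FALSE) {
  stopifnot(all(c("person", "item", "score") %in% names(responses)))
  df <- responses
  df$person <- as.character(df$person)
  df$item <- as.character(df$item)
  if (facet) {
    if (is.null(df$rater)) stop("facet model requires a 'rater' column")
    df$rater <- as.character(df$rater)
  } else {
    df$rater <- "R"
  }
  persons <- sort(unique(df$person))
  items <- sort(unique(df$item))
  raters <- sort(unique(df$rater))
  p_idx <- match(df$person, persons)
  i_idx <- match(df$item, items)
  r_idx <- match(df$rater, raters)
  x <- as.integer(df$score)
  if (any(x < 0)) stop("scores must be non-negative integers")

  # extreme persons (zero or perfect total raw score, relative to observed
  # per-item maxima) carry no information about item/rater parameters and
  # are excluded from estimation
  m_obs <- vapply(seq_along(items), function(i) max(x[i_idx == i]), integer(1))
  raw0 <- rowsum(x, p_idx)[, 1]
  maxraw0 <- rowsum(m_obs[i_idx], p_idx)[, 1]
  extreme_lo <- raw0 == 0
  extreme_hi <- raw0 == maxraw0
  extreme <- extreme_lo | extreme_hi
  est_obs <- !extreme[p_idx]

  # collapse each item's scale to the categories observed among non-extreme
  # persons: null categories have no finite step estimate and would send
  # the joint Newton updates on an unbounded drift, so estimation runs on
  # dense-recoded scores (the mapping is recorded in the fit)
  category_maps <- lapply(seq_along(items), function(i)
    sort(unique(x[i_idx == i & est_obs])))
  n_cat_obs <- lengths(category_maps)
  if (any(n_cat_obs < 2)) {
    stop("item(s) observed in fewer than 2 categories: ",
         paste(items[n_cat_obs < 2], collapse = ", "))
  }
  x <- vapply(seq_along(x), function(o) {
    map <- category_maps[[i_idx[o]]]
    max(findInterval(x[o], map), 1L) - 1L
  }, integer(1))
  m_i <- n_cat_obs - 1L
  names(m_i) <- items
  if (facet && length(raters) > 1) {
    check_rater_connectivity(df)
  }
  max_m <- max(m_i)
  K <- 0:max_m

  raw <- rowsum(x, p_idx)[, 1]
  maxraw <- rowsum(m_i[i_idx], p_idx)[, 1]

  theta <- log((raw + 0.5) / (maxraw - raw + 0.5))
  delta <- matrix(NA_real_, length(items), max_m)
  for (i in seq_along(items)) delta[i, seq_len(m_i[i])] <- 0
  sev <- setNames(rep(0, length(raters)), raters)

  valid <- outer(m_i, K[-1], `>=`)            # items x steps
  kmat_valid <- cbind(TRUE, valid)            # items x (0..max_m)

  cum_steps <- function(delta) {
    cumd <- matrix(0, nrow(delta), max_m + 1)
    for (k in seq_len(max_m)) {
      dk <- delta[, k]
      dk[is.na(dk)] <- 0
      cumd[, k + 1] <- cumd[, k] + dk
    }
    cumd
  }
  invalid_rows <- !kmat_valid[i_idx, , drop = FALSE]
  probs_for <- function(theta, delta, sev) {
    cumd <- cum_steps(delta)
    th <- theta[p_idx] - sev[r_idx]
    num <- outer(th, K) - cumd[i_idx, , drop = FALSE]
    num[invalid_rows] <- -Inf
    num <- num - num[cbind(seq_len(nrow(num)), max.col(num))]
    pr <- exp(num)
    pr / rowSums(pr)
  }

  iter <- 0L
  max_change <- Inf
  # adaptive under-relaxation: undamped alternating Newton can enter a small
  # limit cycle near the optimum; halve the step factor whenever the sweep
  # change has not decreased for a while
  omega <- 1
  best_change <- Inf
  best_iter <- 0L
  while (iter < max_iter && max_change > tol) {
    iter <- iter + 1L
    max_change <- 0

    # person abilities (non-extreme only): inner Newton loop, profiling the
    # abilities out at the current item/rater parameters
    for (inner in 1:10) {
      pr <- probs_for(theta, delta, sev)
      ex <- as.vector(pr %*% K)
      vx <- as.vector(pr %*% K^2) - ex^2
      sc <- rowsum((x - ex) * est_obs, p_idx)[, 1]
      inf <- rowsum(vx * est_obs, p_idx)[, 1]
      upd <- ifelse(inf > 1e-10, sc / inf, 0)
      upd <- omega * pmax(-1, pmin(1, upd))
      upd[extreme] <- 0
      theta <- theta + upd
      if (inner == 1) max_change <- max(max_change, max(abs(upd)))
      if (max(abs(upd)) < tol / 4) break
    }

    # item step parameters: per-item multivariate Newton (steps within an
    # item are coupled through the category probabilities)
    pr <- probs_for(theta, delta, sev)
    pge_all <- pr
    for (k in rev(seq_len(max_m))) {
      pge_all[, k] <- pge_all[, k] + pge_all[, k + 1]
    }
    pge_all <- pge_all[, -1, drop = FALSE]
    for (i in seq_along(items)) {
      m <- m_i[i]
      rows <- which(i_idx == i & est_obs)
      if (!length(rows)) next
      pg <- pge_all[rows, seq_len(m), drop = FALSE]
      g <- colSums(pg - outer(x[rows], seq_len(m), `>=`))
      H <- matrix(0, m, m)
      for (j in seq_len(m)) {
        for (k in j:m) {
          H[j, k] <- H[k, j] <- sum(pg[, k] - pg[, j] * pg[, k])
        }
      }
      st <- tryCatch(solve(H + diag(1e-8, m), g), error = function(e) g / (diag(H) + 1e-8))
      st <- omega * pmax(-1, pmin(1, st))
      newd <- delta[i, seq_len(m)] + st
      capped <- abs(newd) >= delta_cap
      newd[capped] <- sign(newd[capped]) * delta_cap
      moved <- abs(newd - delta[i, seq_len(m)])
      moved[capped] <- 0   # pinned (null-category) params don't block convergence
      max_change <- max(max_change, max(moved))
      delta[i, seq_len(m)] <- newd
    }

    # rater severities
    if (facet && length(raters) > 1) {
      pr <- probs_for(theta, delta, sev)
      ex <- as.vector(pr %*% K)
      vx <- as.vector(pr %*% K^2) - ex^2
      gr <- rowsum((ex - x) * est_obs, r_idx)[, 1]
      hi <- rowsum(vx * est_obs, r_idx)[, 1]
      st <- omega * pmax(-1, pmin(1, ifelse(hi > 1e-10, gr / hi, 0)))
      sev <- sev + st
      max_change <- max(max_change, max(abs(st)))
      d <- mean(sev)
      sev <- sev - d
      theta <- theta - d
    }

    # identification: mean-centered item difficulties
    diffs <- rowMeans(delta, na.rm = TRUE)
    cc <- mean(diffs)
    delta <- delta - cc
    theta <- theta - cc
    if (max_change < best_change * 0.98) {
      best_change <- max_change
      best_iter <- iter
    } else if (iter - best_iter > 25 && omega > 0.1) {
      omega <- omega / 2
      best_iter <- iter
    }
    if (trace && (iter %% 10 == 0 || iter <= 3)) {
      message(sprintf("  jmle iter %d: max change %.2e (omega %.2f)",
                      iter, max_change, omega))
    }
  }
  if (max_change > tol) {
    stop(sprintf(paste0("Rasch JMLE did not converge in %d iterations ",
                        "(last max parameter change %.3g)"), max_iter, max_change))
  }

  # extreme-score measures via adjusted raw scores
  for (pp in which(extreme)) {
    rows <- p_idx == pp
    target <- if (extreme_lo[pp]) extreme_adjust else maxraw[pp] - extreme_adjust
    theta[pp] <- solve_theta_for_score(
      target, i_idx[rows], r_idx[rows], delta, sev, m_i, K, kmat_valid)
  }

  # conditional SEM: inverse sqrt of test information at the measure
  pr <- probs_for(theta, delta, sev)
  vx <- as.vector(pr %*% K^2) - as.vector(pr %*% K)^2
  info_p <- rowsum(vx, p_idx)[, 1]
  sem <- 1 / sqrt(pmax(info_p, 1e-10))

  diffs <- rowMeans(delta, na.rm = TRUE)
  thresholds <- delta - diffs   # centered category thresholds per item
  measures <- data.frame(person = persons, measure = theta[seq_along(persons)],
                         sem = sem, raw_score = raw, max_score = maxraw,
                         extreme = extreme, stringsAsFactors = FALSE)
  structure(list(
    items = items, difficulties = setNames(diffs, items),
    steps = delta, thresholds = thresholds, m_i = m_i,
    category_maps = setNames(category_maps, items),
    severities = if (facet) sev else setNames(0, raters),
    measures = measures,
    convergence = list(iterations = iter, max_change = max_change,
                       converged = TRUE)),
    class = "rasch_fit")
}

# Newton solve of expected total score = target for one person's observed
# item/rater pattern.
solve_theta_for_score <- function(target, i_rows, r_rows, delta, sev, m_i,
                                  K, kmat_valid) {
  cumd <- matrix(0, nrow(delta), ncol(delta) + 1)
  for (k in seq_len(ncol(delta))) {
    dk <- delta[, k]
    dk[is.na(dk)] <- 0
    cumd[, k + 1] <- cumd[, k] + dk
  }
  th <- 0
  for (it in 1:100) {
    num <- outer(th - sev[r_rows], K) - cumd[i_rows, , drop = FALSE]
    num[!kmat_valid[i_rows, , drop = FALSE]] <- -Inf
    num <- num - apply(num, 1, max)
    pr <- exp(num); pr <- pr / rowSums(pr)
    ex <- sum(pr %*% K)
    vx <- sum(pr %*% K^2) - sum((pr %*% K)^2)
    step <- (target - ex) / max(vx, 1e-8)
    step <- max(-2, min(2, step))
    th <- th + step
    if (abs(step) < 1e-6) break
  }
  th
}

# Drop items that are uninformative for joint estimation: observed in fewer
# than 2 categories among non-extreme persons. Iterates because dropping an
# item changes which persons are extreme.
filter_informative_items <- function(responses) {
  df <- responses
  repeat {
    m_obs <- tapply(df$score, df$item, max)
    raw <- tapply(df$score, df$person, sum)
    maxr <- tapply(m_obs[as.character(df$item)], df$person, sum)
    extreme <- names(raw)[raw == 0 | raw == maxr[names(raw)]]
    keep_rows <- !(df$person %in% extreme)
    n_cat <- tapply(df$score[keep_rows], df$item[keep_rows],
                    function(s) length(unique(s)))
    bad <- names(n_cat)[is.na(n_cat) | n_cat < 2]
    bad <- union(bad, setdiff(unique(as.character(df$item)), names(n_cat)))
    if (!length(bad)) return(df)
    df <- df[!(as.character(df$item) %in% bad), , drop = FALSE]
    if (!nrow(df)) stop("no informative items left")
  }
}

check_rater_connectivity <- function(df) {
  raters <- sort(unique(df$rater))
  comp <- seq_along(raters)
  for (p in unique(df$person)) {
    rs <- match(unique(df$rater[df$person == p]), raters)
    if (length(rs) > 1) comp[comp %in% comp[rs]] <- min(comp[rs])
  }
  # raters are also linked when distinct persons... rely on shared persons
  # only is too strict: raters sharing an item across linked persons connect
  # through the person facet. Merge components connected via any person that
  # appears (raters rating the same person), then via chains of persons is
  # already covered by iterating to a fixed point.
  repeat {
    changed <- FALSE
    for (p in unique(df$person)) {
      rs <- match(unique(df$rater[df$person == p]), raters)
      m <- min(comp[rs])
      if (any(comp[rs] != m)) { comp[comp %in% comp[rs]] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  if (length(unique(comp)) > 1) {
    groups <- split(raters, comp)
    stop("disconnected rater network: ",
         paste(vapply(groups, paste, "", collapse = ","), collapse = " | "))
  }
  invisible(TRUE)
}

# -- exported model fits -----------------------------------------------------

#' Fit a partial-credit Rasch model
#'
#' Joint maximum likelihood estimation of person measures and item-specific
#' category step parameters for polytomous responses; each item may have its
#' own rating scale. Person-timepoints are treated as separate measurement
#' occasions. Identification: item difficulties (step means) are centered at
#' zero and abilities are free. Convergence requires the largest parameter
#' change in a sweep to fall below `tol`.
#'
#' Extreme (zero or perfect) response patterns carry no finite maximum
#' likelihood measure; they are measured by solving the expected raw score
#' equal to the observed score adjusted inward by 0.3 score points. The
#' conditional standard error of measurement is the inverse square root of
#' the test information at the person's measure.
#'
#' @param responses Data frame with columns `person`, `item`, `score`
#'   (integer categories starting at 0).
#' @param max_iter,tol Convergence controls (default 200 sweeps, 1e-4
#'   logits).
#' @param extreme_adjust Score-point adjustment for extreme patterns.
#' @return Object of class `rasch_fit`: item `difficulties`, step matrix
#'   `steps`, centered `thresholds`, person `measures` (measure, conditional
#'   `sem`, raw score, extreme flag) and `convergence` diagnostics.
#' @export
fit_partial_credit <- function(responses, max_iter = 500L, tol = 1e-4,
                               extreme_adjust = 0.3) {
  rasch_jmle(responses, facet = FALSE, max_iter = max_iter, tol = tol,
             extreme_adjust = extreme_adjust)
}

#' Fit a many-facet Rasch model with a rater facet
#'
#' Extends the partial-credit model with an additive rater-severity term in
#' the linear predictor (ability minus item step minus rater severity),
#' neutralizing between-rater differences. Severities are constrained to sum
#' to zero; a disconnected rater network (no chain of shared persons linking
#' all raters) is rejected with the disconnected subsets named. With a
#' single rater the fit reduces to [fit_partial_credit()].
#'
#' @param responses Data frame with columns `person`, `item`, `rater`,
#'   `score`.
#' @inheritParams fit_partial_credit
#' @return A `rasch_fit` with estimated `severities`.
#' @export
fit_mfrm <- function(responses, max_iter = 500L, tol = 1e-4,
                     extreme_adjust = 0.3) {
  rasch_jmle(responses, facet = TRUE, max_iter = max_iter, tol = tol,
             extreme_adjust = extreme_adjust)
}

#' @export
print.rasch_fit <- function(x, ...) {
  cat(sprintf("Rasch fit: %d items, %d persons (%d extreme), %d iterations\n",
              length(x$items), nrow(x$measures), sum(x$measures$extreme),
              x$convergence$iterations))
  invisible(x)
}

#' Conditional minimal detectable change
#'
#' The measurement-error threshold a gain must exceed to count as
#' meaningful: `mdc = z * sqrt(sem_bl^2 + sem_ep^2)` at the requested
#' confidence level, with the gain compared by strict inequality.
#'
#' @param measure_bl,measure_ep Person measures (logits) at BL and EP.
#' @param sem_bl,sem_ep Conditional standard errors of measurement.
#' @param confidence Two-sided confidence level (default 0.95).
#' @return List with `mdc` (logits), `gain` and logical `meaningful`.
#' @export
#' @examples
#' conditional_mdc(0, 2, 0.5, 0.5)$mdc  # 1.96 * sqrt(0.5)
conditional_mdc <- function(measure_bl, measure_ep, sem_bl, sem_ep,
                            confidence = 0.95) {
  if (any(is.na(c(sem_bl, sem_ep)))) stop("missing SEM")
  z <- qnorm((1 + confidence) / 2)
  mdc <- z * sqrt(sem_bl^2 + sem_ep^2)
  gain <- measure_ep - measure_bl
  list(mdc = mdc, gain = gain, meaningful = gain > mdc)
}
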