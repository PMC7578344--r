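# Resting-state functional connectivity metrics. Two deliberately distinct
# approaches: within-network strength preserves ROI-ROI correlation
# structure (including anticorrelations); between-network strength averages
# raw member time series into a network mask series first, preserving the
# contribution of dominant (high-amplitude) nodes.

#' Fisher z transform of a correlation
#'
#' `z = atanh(r)`, with `|r| = 1` clipped to `1 - 1e-7` before transforming
#' so that z stays finite without materially moving any realistic value.
#'
#' @param r Correlation(s) in `[-1, 1]`; values outside error.
#' @return Fisher z value(s); `NA` propagates.
#' @export
#' @examples
#' round(fisher_z(0.4621), 4)
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| > 1")
  r <- pmin(1 - 1e-7, pmax(-1 + 1e-7, r))
  atanh(r)
}

#' Pairwise ROI-ROI correlation matrix
#'
#' Pearson correlations over retained volumes for every discernible ROI
#' pair, with Fisher z values alongside. Missing ROIs (all-`NA` columns or
#' labels in `missing_rois`) propagate to a pairwise missing mask and are
#' never imputed here. Constant-signal ROIs are flagged missing as their
#' correlations are undefined.
#'
#' @param ts An acquisition (list with `data`, optionally `missing_rois`),
#'   or a plain volumes x ROI matrix.
#' @param volumes Optional integer vector of retained volume indices.
#' @return Object of class `connectivity_matrix`: list with `labels`,
#'   `r_values`, `z_values` and logical `missing_mask`, all p x p.
#' @export
roi_correlation_matrix <- function(ts, volumes = NULL) {
  x <- if (is.list(ts)) ts$data else ts
  if (!is.null(volumes)) x <- x[volumes, , drop = FALSE]
  if (nrow(x) < 3) stop("need at least 3 retained volumes")
  labels <- colnames(x) %||% paste0("ROI", seq_len(ncol(x)))
  missing_cols <- apply(x, 2, function(col) {
    all(is.na(col)) || isTRUE(sd(col, na.rm = TRUE) == 0)
  })
  if (is.list(ts) && length(ts$missing_rois)) {
    missing_cols <- missing_cols | labels %in% ts$missing_rois
  }
  r <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  dimnames(r) <- list(labels, labels)
  miss <- outer(missing_cols, missing_cols, `|`) | !is.finite(r)
  diag(miss) <- missing_cols
  r[miss] <- NA_real_
  diag(r)[!missing_cols] <- 1
  z <- r
  off <- !miss
  z[off] <- fisher_z(r[off])
  structure(list(labels = labels, r_values = r, z_values = z,
                 missing_mask = miss),
            class = "connectivity_matrix")
}

#' Within-network connectivity strength
#'
#' Mean Fisher z over all unordered distinct ROI pairs inside a network,
#' excluding pairs touching a missing ROI; signed values are kept so
#' anticorrelations count as such. With fewer than two usable ROIs the
#' metric is a missing marker (`NA`) handed to mixed-model imputation.
#'
#' @param cm A `connectivity_matrix` from [roi_correlation_matrix()].
#' @param networks Named list of ROI label vectors (see
#'   [default_networks()]).
#' @param network_label Which network to summarize.
#' @return Mean z (scalar), or `NA` when fewer than 2 ROIs are usable.
#' @export
within_network_strength <- function(cm, networks, network_label) {
  rois <- intersect(networks[[network_label]], cm$labels)
  usable <- rois[!cm$missing_mask[cbind(rois, rois)]]
  if (length(usable) < 2) return(NA_real_)
  sub <- cm$z_values[usable, usable, drop = FALSE]
  vals <- sub[upper.tri(sub)]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Network mask time series
#'
#' Per-volume arithmetic mean of the raw (filtered but unstandardized)
#' member ROI series, over non-missing members only. No per-ROI
#' standardization is applied: a dominant high-amplitude node keeps its
#' weight, which is the point of the masking approach.
#'
#' @param ts Acquisition or volumes x ROI matrix (see
#'   [roi_correlation_matrix()]).
#' @param networks Named list of ROI label vectors.
#' @param network_label Which network to average.
#' @param volumes Optional retained volume indices.
#' @return Numeric per-volume series, or `NULL` when every member is
#'   missing.
#' @export
network_mask_series <- function(ts, networks, network_label, volumes = NULL) {
  x <- if (is.list(ts)) ts$data else ts
  if (!is.null(volumes)) x <- x[volumes, , drop = FALSE]
  labels <- colnames(x) %||% paste0("ROI", seq_len(ncol(x)))
  members <- intersect(networks[[network_label]], labels)
  if (is.list(ts) && length(ts$missing_rois)) {
    members <- setdiff(members, ts$missing_rois)
  }
  sub <- x[, members, drop = FALSE]
  ok <- colSums(is.na(sub)) == 0
  if (!any(ok)) return(NULL)
  rowMeans(sub[, ok, drop = FALSE])
}

#' Between-network connectivity matrix
#'
#' Builds the four network mask series and returns their pairwise Pearson
#' correlations, Fisher transformed: a symmetric network-by-network matrix
#' with six unique off-diagonal entries for four networks. Networks whose
#' mask series is undefined propagate missingness to their pairs.
#'
#' @inheritParams network_mask_series
#' @return A `connectivity_matrix` over network labels.
#' @export
between_network_matrix <- function(ts, networks, volumes = NULL) {
  labs <- names(networks)
  series <- lapply(labs, function(nl)
    network_mask_series(ts, networks, nl, volumes))
  names(series) <- labs
  n_vol <- max(c(0, vapply(series, length, numeric(1))))
  mat <- matrix(NA_real_, n_vol, length(labs), dimnames = list(NULL, labs))
  for (nl in labs) if (!is.null(series[[nl]])) mat[, nl] <- series[[nl]]
  roi_correlation_matrix(mat)
}

#' Subject-level connectivity metric table
#'
#' Computes the 4 within-network and 6 between-network Fisher-z metrics for
#' one acquisition, in long format ready for mixed-model change estimation.
#'
#' @inheritParams network_mask_series
#' @return Data frame with columns `measure`, `class` (`"within"` or
#'   `"between"`), `value` (Fisher z, `NA` when missing).
#' @export
connectivity_metrics <- function(ts, networks, volumes = NULL) {
  cm <- roi_correlation_matrix(ts, volumes)
  labs <- names(networks)
  within <- vapply(labs, function(nl)
    within_network_strength(cm, networks, nl), numeric(1))
  bm <- between_network_matrix(ts, networks, volumes)
  pairs <- combn(labs, 2)
  between <- apply(pairs, 2, function(pr) bm$z_values[pr[1], pr[2]])
  data.frame(
    measure = c(labs, apply(pairs, 2, paste, collapse = "-")),
    class = rep(c("within", "between"), c(length(labs), ncol(pairs))),
    value = c(within, between),
    row.names = NULL, stringsAsFactors = FALSE)
}
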