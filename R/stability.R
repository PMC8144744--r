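# Feature-stability classification across respiratory phases.
#
# Agreement of a feature across phases is measured with the two-way
# mixed-effects, absolute-agreement, single-measurement intraclass
# correlation ICC(A,1) (McGraw & Wong). A feature is stable when the lower
# bound of the 95% confidence interval is >= 0.85 (good-to-excellent
# agreement). "Stability (10)" uses all phases as raters; "stability (3)"
# uses each patient's centre phase and its two cyclic neighbours, with rater
# identity given by relative position (-1 / 0 / +1).

#' ICC(A,1): two-way absolute-agreement single-measurement ICC
#'
#' Point estimate `(MS_R - MS_E) / (MS_R + (k-1) MS_E + k (MS_C - MS_E) / n)`
#' from the two-way ANOVA mean squares (subjects x raters), with the
#' McGraw-Wong F-based 95% confidence interval.
#'
#' @param m numeric matrix, subjects in rows, raters in columns
#'   (>= 5 subjects, >= 2 raters, finite values).
#' @param conf confidence level (default 0.95).
#' @return List with `icc`, `ci_low`, `ci_high` (all `NA` when the total
#'   variance is zero, in which case the feature is classed unstable).
#' @export
icc_a1 <- function(m, conf = 0.95) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 5) stop("ICC requires at least 5 subjects")
  if (k < 2) stop("ICC requires at least 2 raters")
  if (any(!is.finite(m))) stop("non-finite values in ICC input")
  mu <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_r <- k * sum((row_m - mu)^2)
  ss_c <- n * sum((col_m - mu)^2)
  ss_e <- sum((m - outer(row_m, col_m, "+") + mu)^2)
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  denom <- ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n
  if (denom <= 0 || sum((m - mu)^2) == 0)
    return(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  icc <- (ms_r - ms_e) / denom
  if (icc >= 1 - 1e-12) {
    # zero residual and zero rater variance: observed agreement is exact
    return(list(icc = 1, ci_low = 1, ci_high = 1))
  }
  alpha <- 1 - conf
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * ms_c + b * ms_e)^2 /
    ((a * ms_c)^2 / (k - 1) + (b * ms_e)^2 / ((n - 1) * (k - 1)))
  ci <- if (!is.finite(v) || v <= 0) {
    c(NA_real_, NA_real_)
  } else {
    f_l <- qf(1 - alpha / 2, n - 1, v)
    f_u <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (ms_r - f_l * ms_e) /
      (f_l * (k * ms_c + (k * n - k - n) * ms_e) + n * ms_r)
    hi <- n * (f_u * ms_r - ms_e) /
      (k * ms_c + (k * n - k - n) * ms_e + n * f_u * ms_r)
    c(lo, hi)
  }
  list(icc = icc, ci_low = ci[1], ci_high = ci[2])
}

#' Classify per-feature stability across phases
#'
#' For every (feature, ROI) pair, builds the subjects-by-raters matrix —
#' patients by all phases (`all_phases`) or patients by their own three
#' neighbour phases (`neighbours`, raters = relative position) — and flags
#' the feature stable when the ICC(A,1) CI lower bound reaches `threshold`.
#' Patients with missing cells or non-finite values in the required phases
#' are dropped from that feature's matrix; features whose matrix degenerates
#' (fewer than 5 complete patients, or zero variance) are classed unstable
#' with a logged reason.
#'
#' @param table a [phase_feature_table].
#' @param subset `"all_phases"` or `"neighbours"`.
#' @param center per-patient 1-based centre phase indices (or a
#'   `stable_phase_result`); required for `subset = "neighbours"`.
#' @param threshold CI-lower-bound stability cut (default 0.85).
#' @return data.frame (one row per feature x ROI): `feature`, `roi`, `icc`,
#'   `ci_low`, `ci_high`, `phase_subset`, `stable`.
#' @export
classify_stability <- function(table, subset = c("all_phases", "neighbours"),
                               center = NULL, threshold = 0.85) {
  stopifnot(inherits(table, "phase_feature_table"))
  subset <- match.arg(subset)
  P <- length(table$phases)
  if (subset == "neighbours") {
    if (inherits(center, "stable_phase_result")) center <- center$selected
    if (is.null(center)) stop("neighbours subset requires per-patient centre phases")
    if (!is.null(names(center))) center <- center[table$patients]
    stopifnot(length(center) == length(table$patients), !anyNA(center))
  }
  rows <- list()
  for (roi in table$rois) {
    for (f in table$features) {
      if (subset == "all_phases") {
        m <- matrix(table$values[f, , , roi], ncol = P,
                    dimnames = list(table$patients, table$phases))
      } else {
        m <- t(vapply(seq_along(table$patients), function(p) {
          c0 <- center[p]
          tri <- c((c0 - 2) %% P + 1, c0, c0 %% P + 1)
          table$values[f, p, tri, roi]
        }, numeric(3)))
        colnames(m) <- c("-1", "0", "+1")
      }
      keep <- apply(m, 1, function(r) all(is.finite(r)))
      res <- if (sum(keep) < 5) {
        list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
      } else {
        icc_a1(m[keep, , drop = FALSE])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, roi = roi, icc = res$icc,
        ci_low = res$ci_low, ci_high = res$ci_high,
        phase_subset = if (subset == "all_phases") "all_phases" else "neighbours",
        stable = isTRUE(res$ci_low >= threshold))
    }
  }
  do.call(rbind, rows)
}

#' Apply a stability-assessment method to a feature matrix
#'
#' The four regimes: `none` keeps the matrix; `stability10` and `stability3`
#' drop features classed unstable across all ten phases or across the three
#' neighbour phases; `averaging3` replaces values by the mean over the three
#' neighbour phases. The two neighbour-phase regimes are only valid for the
#' single-phase feature sets (50% phase and personalised).
#'
#' @param matrix a [feature_matrix] (columns `roi|feature`).
#' @param table the [phase_feature_table] the matrix was built from.
#' @param method assessment method.
#' @param stable_phases `stable_phase_result`, required when the matrix
#'   provenance is `personalised` and `method` involves neighbour phases.
#' @param threshold ICC CI-lower-bound stability cut (default 0.85).
#' @return A [feature_matrix] with updated provenance; for the stability
#'   regimes the dropped columns are recorded in attribute `"removed"`.
#' @export
apply_assessment <- function(matrix, table,
                             method = c("none", "stability10", "stability3", "averaging3"),
                             stable_phases = NULL, threshold = 0.85) {
  stopifnot(inherits(matrix, "feature_matrix"), inherits(table, "phase_feature_table"))
  method <- match.arg(method)
  prov <- attr(matrix, "provenance")
  validate_provenance(prov$set_method, method)
  if (method == "none") return(matrix)
  centre_for <- function() {
    if (prov$set_method == "phase50") {
      idx <- match("50%", table$phases)
      if (is.na(idx)) stop("configuration error: no phase labelled '50%'")
      rep(idx, length(table$patients))
    } else {
      if (is.null(stable_phases)) stop("personalised assessment requires stable_phases")
      sel <- if (inherits(stable_phases, "stable_phase_result")) stable_phases$selected else stable_phases
      sel[table$patients]
    }
  }
  if (method == "averaging3") {
    out <- neighbour_average(table, centre_for(), set_method = prov$set_method)
    return(out)
  }
  stab <- if (method == "stability10") {
    classify_stability(table, "all_phases", threshold = threshold)
  } else {
    classify_stability(table, "neighbours", center = centre_for(), threshold = threshold)
  }
  stable_cols <- paste(stab$roi, stab$feature, sep = "|")[stab$stable]
  keep <- colnames(matrix) %in% stable_cols
  if (!any(keep)) warning("no features remain after ", method, " assessment")
  out <- feature_matrix(matrix[, keep, drop = FALSE],
                        set_method = prov$set_method, assessment = method)
  attr(out, "removed") <- colnames(matrix)[!keep]
  out
}
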