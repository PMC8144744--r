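# Unsupervised feature selection: tumour-volume decorrelation (Spearman),
# within-ROI redundancy elimination (Pearson), and z-standardisation.
# Pipeline order is fixed: stability assessment -> volume -> redundancy,
# giving nested feature subsets.

#' Remove features correlated with tumour volume
#'
#' Features whose absolute Spearman rank correlation with tumour volume
#' exceeds `rho_max` are removed, to avoid rediscovering volume as a
#' surrogate prognostic factor.
#'
#' @param matrix a [feature_matrix].
#' @param volume numeric tumour volume (cm^3) per patient, named or in row
#'   order.
#' @param rho_max removal threshold on |rho| (default 0.5; strictly-above
#'   removes).
#' @return Filtered [feature_matrix]; removal audit in attribute
#'   `"removed"` (data.frame feature, rho).
#' @export
volume_filter <- function(matrix, volume, rho_max = 0.5) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (!is.null(names(volume))) volume <- volume[rownames(matrix)]
  stopifnot(length(volume) == nrow(matrix), !anyNA(volume))
  rho <- apply(matrix, 2, function(f) {
    if (sd(f) == 0) NA_real_ else suppressWarnings(cor(f, volume, method = "spearman"))
  })
  if (any(is.na(rho)))
    warning("constant feature(s), volume correlation undefined, retained: ",
            paste(names(rho)[is.na(rho)], collapse = ", "))
  drop <- !is.na(rho) & abs(rho) > rho_max
  prov <- attr(matrix, "provenance")
  out <- feature_matrix(matrix[, !drop, drop = FALSE],
                        set_method = prov$set_method, assessment = prov$assessment)
  attr(out, "removed") <- data.frame(feature = colnames(matrix)[drop],
                                     rho = unname(rho[drop]))
  out
}

#' Remove redundant (inter-correlated) features
#'
#' Within each ROI scope independently (tumour and peritumour features are
#' screened separately), iteratively finds pairs with absolute Pearson
#' correlation above `r_max`; among all features involved in such a pair,
#' the one with the largest mean absolute correlation to all other remaining
#' features in scope is removed; correlations are recomputed and the loop
#' repeats until the maximum pairwise |r| is at most `r_max`. Ties on the
#' mean correlation remove the lexicographically later feature name.
#'
#' @param matrix a [feature_matrix] with `roi|feature` column names.
#' @param r_max pairwise |Pearson r| ceiling (default 0.5).
#' @param scope_split function mapping column names to scope labels;
#'   defaults to the ROI prefix before the first `|`.
#' @return Filtered [feature_matrix]; removal audit in attribute `"removed"`.
#' @export
redundancy_filter <- function(matrix, r_max = 0.5,
                              scope_split = function(nm) sub("\\|.*$", "", nm)) {
  stopifnot(inherits(matrix, "feature_matrix"))
  scopes <- scope_split(colnames(matrix))
  removed <- character(0)
  keep_all <- character(0)
  for (sc in unique(scopes)) {
    cols <- colnames(matrix)[scopes == sc]
    if (length(cols) < 2) { keep_all <- c(keep_all, cols); next }
    current <- cols
    repeat {
      if (length(current) < 2) break
      cm <- abs(suppressWarnings(cor(matrix[, current, drop = FALSE])))
      diag(cm) <- 0
      cm[is.na(cm)] <- 0
      if (max(cm) <= r_max) break
      in_pair <- unique(c(row(cm)[cm > r_max], col(cm)[cm > r_max]))
      mean_r <- rowMeans(cm[in_pair, , drop = FALSE] * length(current) / (length(current) - 1))
      ord <- order(-mean_r, current[in_pair], decreasing = c(FALSE, TRUE), method = "radix")
      worst <- current[in_pair][ord[1]]
      removed <- c(removed, worst)
      current <- setdiff(current, worst)
    }
    keep_all <- c(keep_all, current)
  }
  keep <- colnames(matrix)[colnames(matrix) %in% keep_all]
  prov <- attr(matrix, "provenance")
  out <- feature_matrix(matrix[, keep, drop = FALSE],
                        set_method = prov$set_method, assessment = prov$assessment)
  attr(out, "removed") <- removed
  out
}

#' Standardise features to zero mean and unit variance
#'
#' Sample standard deviation; the transform parameters are stored so held-out
#' data can be mapped onto the same scale. Constant features are dropped
#' with a warning.
#'
#' @param matrix a [feature_matrix].
#' @return Standardised [feature_matrix] with attributes `"center"` and
#'   `"scale"`.
#' @export
standardise <- function(matrix) {
  stopifnot(inherits(matrix, "feature_matrix"), nrow(matrix) >= 2)
  mu <- colMeans(matrix)
  sdev <- apply(matrix, 2, sd)
  if (any(sdev == 0)) {
    warning("dropping constant feature(s): ",
            paste(colnames(matrix)[sdev == 0], collapse = ", "))
    keep <- sdev > 0
    matrix <- feature_matrix(matrix[, keep, drop = FALSE],
                             set_method = attr(matrix, "provenance")$set_method,
                             assessment = attr(matrix, "provenance")$assessment)
    mu <- mu[keep]; sdev <- sdev[keep]
  }
  z <- sweep(sweep(unclass(matrix), 2, mu), 2, sdev, "/")
  prov <- attr(matrix, "provenance")
  out <- feature_matrix(z, set_method = prov$set_method, assessment = prov$assessment)
  attr(out, "center") <- mu
  attr(out, "scale") <- sdev
  out
}
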