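# Construction of the four single-feature-set variants:
#   A mean across phases, B median across phases, C 50% phase,
#   D personalised (per-patient most stable phase),
# plus neighbour-phase averaging (mean of the three cyclic phases centred on
# a per-patient phase), used by the "averaging (3)" assessment.

#' Collapse the phase axis into a single feature set
#'
#' @param table a [phase_feature_table].
#' @param method `"mean"`, `"median"`, `"phase50"` or `"personalised"`.
#' @param stable a `stable_phase_result`, required for `personalised`.
#' @return A [feature_matrix] (patients x `roi|feature` columns) with
#'   provenance recording the construction method.
#' @export
build_feature_set <- function(table, method = c("mean", "median", "phase50", "personalised"),
                              stable = NULL) {
  stopifnot(inherits(table, "phase_feature_table"))
  method <- match.arg(method)
  if (method == "personalised") {
    if (is.null(stable)) stop("personalised feature set requires a stable_phase_result")
    return(personalised_values(table, stable))
  }
  if (method == "phase50") {
    idx <- match("50%", table$phases)
    if (is.na(idx)) stop("configuration error: no phase labelled '50%' in table")
    return(gather_phase_values(table, rep(idx, length(table$patients)),
                               set_method = "phase50"))
  }
  fun <- if (method == "mean") mean else median
  patients <- table$patients
  cols <- as.vector(outer(table$features, table$rois,
                          function(f, r) paste(r, f, sep = "|")))
  out <- matrix(NA_real_, length(patients), length(cols),
                dimnames = list(patients, cols))
  for (p in seq_along(patients)) {
    # values[, p, , ]: feature x phase x roi; collapse phases per feature-roi
    v <- table$values[, p, , , drop = FALSE]
    collapsed <- apply(v, c(1, 4), fun)   # feature x roi
    out[p, ] <- as.vector(collapsed)
  }
  feature_matrix(out, set_method = method, assessment = "none")
}

#' Average each value over its three neighbouring phases
#'
#' For every patient, replaces each feature value by the mean over the three
#' cyclic phases centred on that patient's centre phase (e.g. centre 70%
#' averages 60%, 70% and 80%; centre 0% averages 90%, 0% and 10%).
#'
#' @param table a [phase_feature_table] with at least 3 phases.
#' @param center integer vector of 1-based centre phase indices, one per
#'   patient (named or in table patient order), or a `stable_phase_result`.
#' @param set_method provenance set method recorded on the result (default
#'   `"personalised"`; `apply_assessment()` passes the matrix's own method).
#' @return A [feature_matrix] with assessment provenance `"averaging3"`.
#' @export
neighbour_average <- function(table, center, set_method = "personalised") {
  stopifnot(inherits(table, "phase_feature_table"))
  P <- length(table$phases)
  if (P < 3) stop("neighbour averaging requires at least 3 phases")
  if (inherits(center, "stable_phase_result")) center <- center$selected
  if (!is.null(names(center))) center <- center[table$patients]
  stopifnot(length(center) == length(table$patients), !anyNA(center))
  patients <- table$patients
  cols <- as.vector(outer(table$features, table$rois,
                          function(f, r) paste(r, f, sep = "|")))
  out <- matrix(NA_real_, length(patients), length(cols),
                dimnames = list(patients, cols))
  for (p in seq_along(patients)) {
    c0 <- center[p]
    tri <- c((c0 - 2) %% P + 1, c0, c0 %% P + 1)
    v <- table$values[, p, tri, , drop = FALSE]   # feature x 3 x roi
    if (anyNA(v))
      stop("missing neighbour-phase cell for patient ", patients[p])
    out[p, ] <- as.vector(apply(v, c(1, 4), mean))
  }
  feature_matrix(out, set_method = set_method, assessment = "averaging3")
}
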