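# Personalised most-stable-phase selection.
#
# For each patient and feature, each phase is scored by the summed absolute
# difference to its two cyclic neighbour phases (phase 0% neighbours 90% and
# 10%). The phase minimising this score is the most stable for that
# patient-feature pair; the per-patient phase is the mode over all voting
# features. Ties prefer the phase closest (cyclically) to the 50% label,
# then the lower phase index — encoding the expectation that stable phases
# sit near exhale, without randomness.

#' Cyclic neighbour-phase difference series
#'
#' For a per-phase value series `x` of length `P`, returns
#' `|x[p] - x[p-1]| + |x[p] - x[p+1]|` with cyclic indexing.
#'
#' @param x numeric per-phase values, length >= 3, all finite.
#' @return Non-negative numeric vector of the same length.
#' @export
neighbour_difference <- function(x) {
  P <- length(x)
  if (P < 3) stop("need at least 3 phases for neighbour differences")
  if (any(!is.finite(x)))
    stop("non-finite feature value at phase index ", which(!is.finite(x))[1])
  prev <- x[c(P, seq_len(P - 1))]
  nxt <- x[c(seq_len(P - 1) + 1, 1)]
  abs(x - prev) + abs(x - nxt)
}

# cyclic distance between phase indices (1-based) on a P-cycle
cyclic_distance <- function(i, j, P) {
  d <- abs(i - j) %% P
  pmin(d, P - d)
}

# deterministic tie-break: smallest cyclic distance to the reference phase
# (50% when present), then lowest phase index
break_phase_tie <- function(candidates, P, ref_idx) {
  d <- cyclic_distance(candidates, ref_idx, P)
  candidates[order(d, candidates)][1]
}

ref_phase_index <- function(phases) {
  idx <- match("50%", phases)
  if (is.na(idx)) idx <- floor(length(phases) / 2) + 1L
  idx
}

#' Most stable phase for one feature series
#'
#' @param dx neighbour-difference series from [neighbour_difference()].
#' @param ref_idx tie-break reference phase index (1-based).
#' @return 1-based phase index of the minimum, ties broken deterministically.
#' @export
stable_phase_per_feature <- function(dx, ref_idx = floor(length(dx) / 2) + 1L) {
  cand <- which(dx == min(dx))
  if (length(cand) == 1L) return(cand)
  break_phase_tie(cand, length(dx), ref_idx)
}

#' Most common phase over per-feature winners
#'
#' @param winners integer vector of per-feature winning phase indices.
#' @param P number of phases.
#' @param ref_idx tie-break reference phase index.
#' @return List with `phase` (modal index) and `tally` (votes per phase).
#' @export
stable_phase_per_patient <- function(winners, P, ref_idx = floor(P / 2) + 1L) {
  if (!length(winners)) stop("no voting features")
  tally <- tabulate(winners, nbins = P)
  cand <- which(tally == max(tally))
  phase <- if (length(cand) == 1L) cand else break_phase_tie(cand, P, ref_idx)
  list(phase = phase, tally = tally)
}

#' Personalised phase selection for a cohort
#'
#' Runs the per-feature neighbour-difference argmin and per-patient majority
#' vote over all (feature, ROI) pairs in the table, or a named subset.
#' Patients with any missing cell are excluded with a logged count.
#'
#' @param table a [phase_feature_table] with at least 3 phases.
#' @param features optional character subset of voting feature names.
#' @param rois optional character subset of voting ROIs.
#' @param exclude_constant drop features with zero neighbour difference at
#'   every phase from the vote instead of letting them vote via the
#'   tie-break phase (default `FALSE`: all features vote).
#' @return A `stable_phase_result`: list with `selected` (named integer phase
#'   index per patient), `selected_label`, `votes` (patient x phase tally
#'   matrix) and `winners` (patient x voting-column matrix of phase indices).
#' @export
select_stable_phase <- function(table, features = NULL, rois = NULL,
                                exclude_constant = FALSE) {
  stopifnot(inherits(table, "phase_feature_table"))
  P <- length(table$phases)
  if (P < 3) stop("phase selection requires at least 3 phases")
  features <- features %||% table$features
  rois <- rois %||% table$rois
  ref <- ref_phase_index(table$phases)
  patients <- table$patients
  votes <- matrix(0L, length(patients), P,
                  dimnames = list(patients, table$phases))
  n_cols <- length(features) * length(rois)
  winners <- matrix(NA_integer_, length(patients), n_cols,
                    dimnames = list(patients, as.vector(outer(features, rois, paste, sep = "@"))))
  selected <- setNames(integer(length(patients)), patients)
  excluded <- character(0)
  for (pat in patients) {
    w <- integer(0)
    k <- 0L
    bad <- FALSE
    for (roi in rois) {
      block <- table$values[features, pat, , roi, drop = FALSE]
      m <- matrix(block, nrow = length(features), ncol = P)
      if (anyNA(m)) { bad <- TRUE; break }
      for (f in seq_len(nrow(m))) {
        k <- k + 1L
        dx <- neighbour_difference(m[f, ])
        if (exclude_constant && all(dx == 0)) next
        win <- stable_phase_per_feature(dx, ref)
        winners[pat, k] <- win
        w <- c(w, win)
      }
    }
    if (bad) {
      excluded <- c(excluded, pat)
      selected[pat] <- NA_integer_
      next
    }
    res <- stable_phase_per_patient(w, P, ref)
    selected[pat] <- res$phase
    votes[pat, ] <- res$tally
  }
  if (length(excluded))
    message(length(excluded), " patient(s) excluded from phase selection (missing cells): ",
            paste(excluded, collapse = ", "))
  structure(list(selected = selected,
                 selected_label = table$phases[selected],
                 votes = votes, winners = winners,
                 phases = table$phases, excluded = excluded),
            class = "stable_phase_result")
}

#' @export
print.stable_phase_result <- function(x, ...) {
  cat("stable_phase_result:", length(x$selected), "patients\n")
  tab <- table(factor(x$selected_label, levels = x$phases))
  print(tab)
  invisible(x)
}

#' Gather per-patient values at the selected phase
#'
#' Builds the personalised feature matrix: every feature value for a patient
#' is read from that patient's single selected phase (not from per-feature
#' winning phases).
#'
#' @param table a [phase_feature_table].
#' @param result a `stable_phase_result` covering all patients in `table`.
#' @return A [feature_matrix] with provenance `personalised` / `none`;
#'   feature columns are named `roi|feature`.
#' @export
personalised_values <- function(table, result) {
  stopifnot(inherits(table, "phase_feature_table"),
            inherits(result, "stable_phase_result"))
  missing_pat <- setdiff(table$patients, names(result$selected))
  if (length(missing_pat))
    stop("stable-phase result does not cover patient(s): ",
         paste(missing_pat, collapse = ", "))
  gather_phase_values(table, result$selected[table$patients],
                      set_method = "personalised")
}

# shared row-gather: per-patient phase index -> patients x (roi|feature) matrix
gather_phase_values <- function(table, phase_idx, set_method) {
  patients <- table$patients
  cols <- as.vector(outer(table$features, table$rois,
                          function(f, r) paste(r, f, sep = "|")))
  out <- matrix(NA_real_, length(patients), length(cols),
                dimnames = list(patients, cols))
  for (p in seq_along(patients)) {
    ph <- phase_idx[p]
    if (is.na(ph)) stop("no selected phase for patient ", patients[p])
    vals <- as.vector(table$values[, p, ph, ])
    if (anyNA(vals))
      stop("selected-phase cell missing for patient ", patients[p])
    out[p, ] <- vals
  }
  feature_matrix(out, set_method = set_method, assessment = "none")
}
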