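# End-to-end comparison harness: builds each valid feature-set x assessment
# combination, runs unsupervised filtering, supervised selection in
# cross-validation, signature construction and final model evaluation, and
# returns one row per model plus the clinical baseline (13 rows).

#' Run the full radiomic model comparison
#'
#' For every valid combination of feature-set construction (mean, median,
#' 50% phase, personalised) and stability assessment (none, stability over
#' ten phases, stability over three neighbour phases, neighbour averaging)
#' — twelve in total — this applies the fixed pipeline: set construction,
#' assessment, volume decorrelation, redundancy elimination,
#' standardisation, supervised selection inside event-matched stratified
#' cross-validation, signature construction, and clinical-radiomics Cox
#' evaluation (bootstrap c-index, fraction of new information). A clinical
#' baseline row is included.
#'
#' @param table a [phase_feature_table].
#' @param clinical clinical data.frame (will be category-merged).
#' @param outcomes data.frame `patient`, `time`, `event`.
#' @param stable optional precomputed `stable_phase_result`; computed from
#'   `table` when any personalised combination is requested.
#' @param selector `"univariable"`, `"multivariable"`, `"mrmr"`, or
#'   `"auto"` to pick per-combination by the performance ranking.
#' @param combos data.frame of combinations (default [model_combinations()]).
#' @param repeats,folds cross-validation shape (defaults 40 and 5).
#' @param B bootstrap resamples (default 500).
#' @param seed integer seed driving partitioning and bootstrap.
#' @param threshold ICC stability threshold (default 0.85).
#' @param rho_max,r_max unsupervised filter thresholds (defaults 0.5).
#' @return data.frame with one row per model (combination label, selector
#'   used, signature size, LR statistics, adequacy, fraction of new
#'   information, bootstrap c-index median and 95% CI) plus the `clinical`
#'   baseline row; per-model signatures in attribute `"signatures"`.
#' @export
run_model_comparison <- function(table, clinical, outcomes, stable = NULL,
                                 selector = "univariable",
                                 combos = model_combinations(),
                                 repeats = 40, folds = 5, B = 500, seed = 1,
                                 threshold = 0.85, rho_max = 0.5, r_max = 0.5) {
  stopifnot(inherits(table, "phase_feature_table"))
  clinical <- merge_categories(clinical)
  clinical <- clinical[match(outcomes$patient, clinical$patient), ]
  cdesign <- clinical_design_matrix(clinical)
  volume <- setNames(clinical$tumour_volume, clinical$patient)
  need_stable <- any(combos$set_method == "personalised")
  if (need_stable && is.null(stable)) stable <- select_stable_phase(table)
  runs <- scv_partition(outcomes, repeats = repeats, folds = folds, seed = seed)

  fit_c <- fit_cox(cdesign, outcomes)
  bs_c <- bootstrap_cindex(cdesign, outcomes, B = B, seed = seed)
  rows <- list(data.frame(model = "clinical", set_method = NA, assessment = NA,
                          selector = NA, n_signature = 0L,
                          lr_clinical = fit_c$lr_chisq, lr_cr = NA,
                          adequacy = NA, fraction_new = NA,
                          cindex_median = bs_c$median,
                          cindex_lo = bs_c$ci[1], cindex_hi = bs_c$ci[2]))
  signatures <- list()
  for (i in seq_len(nrow(combos))) {
    sm <- combos$set_method[i]; am <- combos$assessment[i]
    label <- paste(sm, am, sep = "+")
    m <- build_feature_set(table, sm, stable = stable)
    m <- apply_assessment(m, table, am, stable_phases = stable, threshold = threshold)
    m <- volume_filter(m, volume, rho_max = rho_max)
    m <- redundancy_filter(m, r_max = r_max)
    m <- suppressWarnings(standardise(m))
    m <- m[outcomes$patient, , drop = FALSE]
    if (selector == "auto") {
      cs <- compare_selectors(m, cdesign, outcomes, runs)
      used <- cs$best
      cv <- cs$cv[[used]]
    } else {
      used <- selector
      cv <- run_selector_cv(m, cdesign, outcomes, runs, selector)
    }
    sig <- build_signature(cv)
    signatures[[label]] <- sig
    if (!length(sig$features)) {
      rows[[length(rows) + 1L]] <- data.frame(
        model = label, set_method = sm, assessment = am, selector = used,
        n_signature = 0L, lr_clinical = fit_c$lr_chisq, lr_cr = NA,
        adequacy = NA, fraction_new = NA, cindex_median = NA,
        cindex_lo = NA, cindex_hi = NA)
      next
    }
    ev <- evaluate_cr_model(sig$features, m, cdesign, outcomes, B = B, seed = seed)
    rows[[length(rows) + 1L]] <- data.frame(
      model = label, set_method = sm, assessment = am, selector = used,
      n_signature = ev$n_signature, lr_clinical = ev$lr_clinical,
      lr_cr = ev$lr_cr, adequacy = ev$adequacy,
      fraction_new = ev$fraction_new, cindex_median = ev$cindex_median,
      cindex_lo = ev$cindex_lo, cindex_hi = ev$cindex_hi)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "signatures") <- signatures
  out
}
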