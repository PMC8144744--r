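# Supervised feature selection inside repeated event-matched stratified
# cross-validation (default 40 repeats x 5 folds = 200 train/test runs).
# Three selectors are compared: univariable Cox significance, likelihood-
# ratio improvement over the clinical base model, and greedy survival MRMR.
# Selector performance is ranked by C_test - |C_test - C_train| on the
# median concordances over runs; the signature is the occurrence-ranked
# feature list truncated to the rounded median per-run selection size.

#' Event-matched stratified cross-validation partitions
#'
#' Events and non-events are shuffled separately and dealt round-robin into
#' folds, so every fold's event proportion is within one patient of the
#' cohort proportion. Reproducible under `seed`.
#'
#' @param outcomes data.frame with columns `patient`, `time`, `event`.
#' @param repeats,folds repeat and fold counts (defaults 40 and 5).
#' @param seed integer RNG seed.
#' @return List of `repeats * folds` runs, each with `repeat_idx`,
#'   `fold_idx`, `train` and `test` patient id vectors.
#' @export
scv_partition <- function(outcomes, repeats = 40, folds = 5, seed = 1) {
  stopifnot(all(c("patient", "time", "event") %in% names(outcomes)))
  ev <- outcomes$patient[outcomes$event == 1]
  ne <- outcomes$patient[outcomes$event == 0]
  if (length(ev) < folds || length(ne) < folds)
    stop("need at least ", folds, " events and ", folds, " non-events")
  runs <- list()
  old <- .Random.seed_safe()
  on.exit(restore_seed(old))
  set.seed(seed)
  for (r in seq_len(repeats)) {
    fold_of <- c(setNames(rep_len(seq_len(folds), length(ev)), sample(ev)),
                 setNames(rep_len(seq_len(folds), length(ne)), sample(ne)))
    for (k in seq_len(folds)) {
      test <- names(fold_of)[fold_of == k]
      runs[[length(runs) + 1L]] <- list(
        repeat_idx = r, fold_idx = k,
        train = setdiff(outcomes$patient, test), test = test)
    }
  }
  runs
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

surv_obj <- function(outcomes) survival::Surv(outcomes$time, outcomes$event)

#' Univariable Cox selector
#'
#' Features significantly associated with outcome in a univariable Cox
#' regression (Wald p below `alpha`). Non-convergent fits are skipped.
#'
#' @param x standardised feature matrix (patients x features).
#' @param outcomes data.frame `patient`, `time`, `event` matching rows of `x`.
#' @param alpha significance level (default 0.05).
#' @return Character vector of selected feature names, in p-value order.
#' @export
select_univariable <- function(x, outcomes, alpha = 0.05) {
  if (!ncol(x)) return(character(0))
  y <- surv_obj(outcomes)
  pvals <- vapply(seq_len(ncol(x)), function(j) {
    fit <- tryCatch(survival::coxph(y ~ x[, j]), error = function(e) NULL,
                    warning = function(w) NULL)
    if (is.null(fit)) return(NA_real_)
    z <- coef(fit)[1] / sqrt(fit$var[1, 1])
    2 * stats::pnorm(-abs(z))
  }, numeric(1))
  sel <- which(!is.na(pvals) & pvals < alpha)
  colnames(x)[sel[order(pvals[sel])]]
}

#' Likelihood-ratio selector over a clinical base model
#'
#' Features that significantly improve a multivariable Cox model of the
#' clinical covariates in a likelihood-ratio test (each feature tested
#' one at a time against the fixed clinical base model).
#'
#' @param x standardised feature matrix.
#' @param clinical_design numeric design matrix of clinical covariates
#'   (same rows as `x`).
#' @param outcomes data.frame `patient`, `time`, `event`.
#' @param alpha significance level (default 0.05).
#' @return Character vector of selected feature names, in p-value order.
#' @export
select_multivariable <- function(x, clinical_design, outcomes, alpha = 0.05) {
  if (!ncol(x)) return(character(0))
  y <- surv_obj(outcomes)
  base <- tryCatch(survival::coxph(y ~ clinical_design), error = function(e) NULL)
  if (is.null(base)) stop("clinical base model failed to fit")
  ll0 <- base$loglik[2]
  pvals <- vapply(seq_len(ncol(x)), function(j) {
    fit <- tryCatch(survival::coxph(y ~ clinical_design + x[, j]),
                    error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) return(NA_real_)
    lr <- 2 * (fit$loglik[2] - ll0)
    pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
  }, numeric(1))
  sel <- which(!is.na(pvals) & pvals < alpha)
  colnames(x)[sel[order(pvals[sel])]]
}

#' Greedy survival MRMR selector
#'
#' Relevance of a feature is its sign-aligned concordance with outcome
#' rescaled to `[0, 1]`: `2 * (max(C, 1 - C) - 0.5)`. Redundancy is the mean
#' absolute Pearson correlation with already-selected features. Features are
#' added greedily by maximum (relevance - redundancy) while that score is
#' positive.
#'
#' @param x standardised feature matrix.
#' @param outcomes data.frame `patient`, `time`, `event`.
#' @return Character vector of selected features in selection order.
#' @export
select_mrmr <- function(x, outcomes) {
  if (!ncol(x)) return(character(0))
  y <- surv_obj(outcomes)
  relevance <- vapply(seq_len(ncol(x)), function(j) {
    cc <- tryCatch(concordance_index(x[, j], outcomes), error = function(e) NA_real_)
    if (is.na(cc)) return(NA_real_)
    2 * (max(cc, 1 - cc) - 0.5)
  }, numeric(1))
  names(relevance) <- colnames(x)
  relevance[is.na(relevance)] <- 0
  selected <- character(0)
  remaining <- colnames(x)
  repeat {
    if (!length(remaining)) break
    red <- if (!length(selected)) {
      setNames(rep(0, length(remaining)), remaining)
    } else {
      cm <- abs(suppressWarnings(cor(x[, remaining, drop = FALSE],
                                     x[, selected, drop = FALSE])))
      cm[is.na(cm)] <- 1
      rowMeans(cm)
    }
    score <- relevance[remaining] - red
    best <- which.max(score)
    if (score[best] <= 0) break
    selected <- c(selected, remaining[best])
    remaining <- remaining[-best]
  }
  selected
}

#' Cross-validation performance ranking
#'
#' `C_test - |C_test - C_train|`: rewards test concordance while penalising
#' the train/test gap; commonly used for hyper-parameter choice.
#'
#' @param c_test,c_train concordance indices in `[0, 1]`.
#' @return Scalar ranking value (always `<= c_test`).
#' @export
performance_ranking <- function(c_test, c_train) {
  stopifnot(c_test >= 0, c_test <= 1, c_train >= 0, c_train <= 1)
  c_test - abs(c_test - c_train)
}

#' Run one selector over all cross-validation runs
#'
#' In each training run the selector is applied, the selected features are
#' combined with the clinical covariates in a Cox model, and the model is
#' applied without change to the test fold; train and test concordances are
#' recorded.
#'
#' @param x standardised feature matrix (patients x features).
#' @param clinical_design numeric clinical design matrix (same rows).
#' @param outcomes data.frame `patient`, `time`, `event` (rows match `x`).
#' @param runs partitions from [scv_partition()].
#' @param selector `"univariable"`, `"multivariable"` or `"mrmr"`.
#' @param alpha significance level for the testing selectors.
#' @return data.frame with one row per run: repeat/fold indices, number
#'   selected, semicolon-joined selected features, `c_train`, `c_test`.
#' @export
run_selector_cv <- function(x, clinical_design, outcomes, runs,
                            selector = c("univariable", "multivariable", "mrmr"),
                            alpha = 0.05) {
  selector <- match.arg(selector)
  stopifnot(identical(rownames(x), outcomes$patient))
  res <- lapply(runs, function(run) {
    tr <- match(run$train, outcomes$patient)
    te <- match(run$test, outcomes$patient)
    xtr <- x[tr, , drop = FALSE]
    otr <- outcomes[tr, ]
    sel <- switch(selector,
                  univariable = select_univariable(xtr, otr, alpha),
                  multivariable = select_multivariable(xtr, clinical_design[tr, , drop = FALSE], otr, alpha),
                  mrmr = select_mrmr(xtr, otr))
    design_tr <- cbind(clinical_design[tr, , drop = FALSE],
                       x[tr, sel, drop = FALSE])
    design_te <- cbind(clinical_design[te, , drop = FALSE],
                       x[te, sel, drop = FALSE])
    fit <- tryCatch(survival::coxph(surv_obj(otr) ~ design_tr),
                    error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) {
      c_tr <- c_te <- NA_real_
    } else {
      beta <- coef(fit)
      beta[is.na(beta)] <- 0
      c_tr <- concordance_index(as.vector(design_tr %*% beta), otr)
      c_te <- tryCatch(concordance_index(as.vector(design_te %*% beta), outcomes[te, ]),
                       error = function(e) NA_real_)
    }
    data.frame(repeat_idx = run$repeat_idx, fold_idx = run$fold_idx,
               n_selected = length(sel),
               selected = paste(sel, collapse = ";"),
               c_train = c_tr, c_test = c_te)
  })
  do.call(rbind, res)
}

#' Build the radiomics signature from cross-validation runs
#'
#' Features are ranked by occurrence over all training runs; the signature
#' length is the rounded (half-up) median of per-run selected-set sizes.
#' Ties at the cut are broken by smaller mean within-run selection position,
#' then by name.
#'
#' @param cv data.frame from [run_selector_cv()].
#' @return List with `features` (the signature), `occurrence` (named counts
#'   over all candidates) and `size`.
#' @export
build_signature <- function(cv) {
  sel_lists <- strsplit(cv$selected, ";", fixed = TRUE)
  sel_lists <- lapply(sel_lists, function(s) s[nzchar(s)])
  if (!any(lengths(sel_lists) > 0)) {
    warning("no features selected in any run; empty signature")
    return(list(features = character(0), occurrence = integer(0), size = 0L))
  }
  occ <- table(unlist(sel_lists))
  pos <- tapply(unlist(lapply(sel_lists, seq_along)), unlist(sel_lists), mean)
  size <- floor(median(lengths(sel_lists)) + 0.5)
  nm <- names(occ)
  ord <- order(-as.vector(occ), pos[nm], nm, method = "radix")
  ranked <- nm[ord]
  list(features = head(ranked, size),
       occurrence = sort(setNames(as.vector(occ), nm), decreasing = TRUE),
       size = size)
}

#' Compare the three selectors and pick the best by Eq.-style ranking
#'
#' Runs all three selectors over the same partitions, computes the median
#' train/test concordances, the performance ranking, and returns the argmax.
#'
#' @inheritParams run_selector_cv
#' @return List with `summary` (data.frame selector, median_c_train,
#'   median_c_test, ranking), `best` (selector name), and `cv` (per-selector
#'   run tables).
#' @export
compare_selectors <- function(x, clinical_design, outcomes, runs, alpha = 0.05) {
  selectors <- c("univariable", "multivariable", "mrmr")
  cvs <- lapply(selectors, function(s)
    run_selector_cv(x, clinical_design, outcomes, runs, s, alpha))
  names(cvs) <- selectors
  summ <- do.call(rbind, lapply(selectors, function(s) {
    cv <- cvs[[s]]
    ctr <- median(cv$c_train, na.rm = TRUE)
    cte <- median(cv$c_test, na.rm = TRUE)
    data.frame(selector = s, median_c_train = ctr, median_c_test = cte,
               ranking = performance_ranking(cte, ctr))
  }))
  list(summary = summ, best = summ$selector[which.max(summ$ranking)], cv = cvs)
}
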