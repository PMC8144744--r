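# Final model building and comparison: clinical and clinical-radiomics Cox
# models, Harrell's concordance, 500-resample bootstrap c-index, and the
# fraction of new information 1 - LR_C / LR_CR (adequacy index) for nested
# models.

#' Fit a Cox proportional hazards model
#'
#' Thin wrapper around maximum partial likelihood returning the quantities
#' the comparison needs: coefficients, log-likelihoods, and the
#' likelihood-ratio chi-squared against the null model.
#'
#' @param design numeric covariate matrix (patients x covariates), no
#'   missing values.
#' @param outcomes data.frame with `time` and `event` (+ optional `patient`).
#' @return List with `fit` (the `coxph` object), `coef`, `loglik_null`,
#'   `loglik`, `lr_chisq` and `risk` (linear predictor on the input data).
#' @export
fit_cox <- function(design, outcomes) {
  design <- as.matrix(design)
  stopifnot(nrow(design) == nrow(outcomes), !anyNA(design))
  if (nrow(design) <= ncol(design))
    stop("more covariates than patients")
  y <- survival::Surv(outcomes$time, outcomes$event)
  fit <- survival::coxph(y ~ design)
  if (!is.null(fit$info) && any(grepl("did not converge", fit$info)))
    stop("Cox model did not converge")
  beta <- coef(fit)
  beta[is.na(beta)] <- 0
  lr <- 2 * (fit$loglik[2] - fit$loglik[1])
  list(fit = fit, coef = setNames(beta, colnames(design)),
       loglik_null = fit$loglik[1], loglik = fit$loglik[2],
       lr_chisq = max(lr, 0),
       risk = as.vector(design %*% beta))
}

#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs whose risk ordering agrees with
#' their event ordering; tied risks count one half. A pair is comparable
#' when the shorter time ends in an event.
#'
#' @param risk numeric risk scores (higher = shorter expected survival).
#' @param outcomes data.frame with `time` and `event`.
#' @return Concordance in `[0, 1]`.
#' @export
concordance_index <- function(risk, outcomes) {
  stopifnot(all(is.finite(risk)), length(risk) == nrow(outcomes))
  cf <- survival::concordancefit(survival::Surv(outcomes$time, outcomes$event),
                                 x = -risk)
  num <- cf$count
  comparable <- num["concordant"] + num["discordant"] + num["tied.x"]
  if (comparable == 0) stop("no comparable pairs; concordance undefined")
  unname((num["concordant"] + 0.5 * num["tied.x"]) / comparable)
}

#' Bootstrap distribution of the c-index
#'
#' For each of `B` resamples (with replacement, original size) the model is
#' refit on the resample and applied without change to the original data;
#' the c-index on the original data is recorded. Resamples with zero events
#' are redrawn (logged). Returns the median and percentile 95% interval.
#'
#' @param design covariate matrix.
#' @param outcomes data.frame `time`, `event`.
#' @param B number of resamples (default 500).
#' @param seed integer RNG seed.
#' @return List with `median`, `ci` (2.5% and 97.5%), and `values` (length
#'   `B`).
#' @export
bootstrap_cindex <- function(design, outcomes, B = 500, seed = 1) {
  stopifnot(B >= 2)
  design <- as.matrix(design)
  n <- nrow(design)
  old <- .Random.seed_safe()
  on.exit(restore_seed(old))
  set.seed(seed)
  redrawn <- 0L
  vals <- vapply(seq_len(B), function(b) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (sum(outcomes$event[idx]) > 0) break
      redrawn <<- redrawn + 1L
    }
    fit <- tryCatch(fit_cox(design[idx, , drop = FALSE], outcomes[idx, ]),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    risk <- as.vector(design %*% fit$coef)
    concordance_index(risk, outcomes)
  }, numeric(1))
  if (redrawn > 0) message(redrawn, " zero-event resample(s) redrawn")
  list(median = median(vals, na.rm = TRUE),
       ci = unname(quantile(vals, c(0.025, 0.975), na.rm = TRUE)),
       values = vals)
}

#' Fraction of new information from a radiomics signature
#'
#' For the nested pair of a clinical model C and a clinical-radiomics model
#' CR fit to the same patients, the adequacy index is `LR_C / LR_CR` (ratio
#' of likelihood-ratio chi-squared statistics) and the fraction of new
#' information is its complement: the proportion of the explainable
#' variation in outcome provided by the radiomic features.
#'
#' @param clinical_fit,cr_fit results of [fit_cox()] on nested designs over
#'   the same patients.
#' @return List with `lr_clinical`, `lr_cr`, `adequacy`, `fraction_new`.
#' @export
fraction_new_information <- function(clinical_fit, cr_fit) {
  lr_c <- clinical_fit$lr_chisq
  lr_cr <- cr_fit$lr_chisq
  if (lr_cr == 0) stop("clinical-radiomics model has zero LR chi-squared; fraction undefined")
  adequacy <- lr_c / lr_cr
  list(lr_clinical = lr_c, lr_cr = lr_cr, adequacy = adequacy,
       fraction_new = 1 - adequacy)
}

#' Build the clinical design matrix
#'
#' Covariates: tumour volume (cm^3), merged lobe, sex, age, T stage and
#' merged ECOG, dummy-coded.
#'
#' @param clinical data.frame after [merge_categories()], one row per
#'   patient with columns `tumour_volume`, `lobe`, `sex`, `age`, `t_stage`,
#'   `ecog`.
#' @return Numeric design matrix (no intercept column).
#' @export
clinical_design_matrix <- function(clinical) {
  needed <- c("tumour_volume", "lobe", "sex", "age", "t_stage", "ecog")
  stopifnot(all(needed %in% names(clinical)))
  mm <- stats::model.matrix(~ tumour_volume + lobe + sex + age + t_stage + ecog,
                            data = clinical)
  mm <- mm[, -1, drop = FALSE]
  rownames(mm) <- clinical$patient
  mm
}

#' Fit and compare one clinical-radiomics model against the clinical base
#'
#' @param signature character vector of signature feature names (columns of
#'   `x`).
#' @param x standardised feature matrix.
#' @param clinical_design clinical design matrix.
#' @param outcomes data.frame `time`, `event` (rows match).
#' @param B bootstrap resamples for the c-index (default 500).
#' @param seed RNG seed for the bootstrap.
#' @return One-row data.frame: LR statistics, adequacy, fraction_new,
#'   bootstrap c-index median and CI; per-feature hazard ratios in
#'   attribute `"hazard_ratios"`.
#' @export
evaluate_cr_model <- function(signature, x, clinical_design, outcomes,
                              B = 500, seed = 1) {
  fit_c <- fit_cox(clinical_design, outcomes)
  design_cr <- cbind(clinical_design, x[, signature, drop = FALSE])
  fit_cr <- fit_cox(design_cr, outcomes)
  fni <- fraction_new_information(fit_c, fit_cr)
  bs <- bootstrap_cindex(design_cr, outcomes, B = B, seed = seed)
  out <- data.frame(lr_clinical = fni$lr_clinical, lr_cr = fni$lr_cr,
                    adequacy = fni$adequacy, fraction_new = fni$fraction_new,
                    cindex_median = bs$median,
                    cindex_lo = bs$ci[1], cindex_hi = bs$ci[2],
                    n_signature = length(signature))
  hr <- exp(fit_cr$coef[signature])
  attr(out, "hazard_ratios") <- hr
  out
}
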