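# Data model and I/O: phase-feature tables, clinical covariates, outcomes.
#
# The central container is the phase-feature table: one value per
# (feature, patient, phase, roi). Internally a 4-D numeric array with NA
# marking missing cells; the interchange format is long CSV with columns
# patient, phase, roi, feature, value.

#' Construct a phase-feature table
#'
#' The canonical container for per-phase radiomic feature values: a dense
#' 4-D array indexed by feature, patient, respiratory phase and region of
#' interest. Phases form a fixed cyclic order (default `"0%"` ... `"90%"`,
#' 0% = peak inhale). Missing cells are `NA` and are never imputed.
#'
#' @param values numeric array `[feature, patient, phase, roi]`, or `NULL` to
#'   create an all-missing table.
#' @param features,patients,phases,rois character vectors of axis labels.
#' @return An object of class `phase_feature_table`.
#' @export
phase_feature_table <- function(values = NULL, features, patients,
                                phases = default_phase_labels(), rois = c("tumour", "peritumour")) {
  features <- as.character(features); patients <- as.character(patients)
  phases <- as.character(phases); rois <- as.character(rois)
  if (anyDuplicated(features)) stop("feature names must be unique")
  if (anyDuplicated(phases)) stop("phase labels must be unique")
  dims <- c(length(features), length(patients), length(phases), length(rois))
  if (is.null(values)) {
    values <- array(NA_real_, dim = dims)
  } else {
    values <- array(as.numeric(values), dim = dims)
  }
  dimnames(values) <- list(feature = features, patient = patients,
                           phase = phases, roi = rois)
  structure(list(values = values, features = features, patients = patients,
                 phases = phases, rois = rois),
            class = "phase_feature_table")
}

#' @export
print.phase_feature_table <- function(x, ...) {
  n_missing <- sum(is.na(x$values))
  cat(sprintf("phase_feature_table: %d features x %d patients x %d phases x %d ROIs\n",
              length(x$features), length(x$patients), length(x$phases), length(x$rois)))
  cat(sprintf("  phases: %s\n", paste(x$phases, collapse = " ")))
  cat(sprintf("  missing cells: %d / %d\n", n_missing, length(x$values)))
  invisible(x)
}

#' @export
dim.phase_feature_table <- function(x) dim(x$values)

#' Load a long-format phase-feature CSV
#'
#' Reads one row per (patient, phase, roi, feature) with a numeric value.
#' Column names are resolved through `schema`; phases are ordered cyclically
#' following `phase_order` (default: sorted numerically by the leading
#' percentage). Cells absent from the file are flagged missing (`NA`).
#'
#' @param path path to a UTF-8 CSV with a header row.
#' @param schema named character vector mapping canonical column names
#'   (`patient`, `phase`, `roi`, `feature`, `value`) to the file's columns.
#' @param phase_order optional character vector giving the full cyclic phase
#'   order; defaults to the phases present, sorted by numeric prefix.
#' @return A [phase_feature_table].
#' @export
load_phase_features <- function(path,
                                schema = c(patient = "patient", phase = "phase",
                                           roi = "roi", feature = "feature", value = "value"),
                                phase_order = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path)
  needed <- unname(schema[c("patient", "phase", "roi", "feature", "value")])
  missing_cols <- setdiff(needed, names(dt))
  if (length(missing_cols))
    stop("schema error: column(s) not found in file: ", paste(missing_cols, collapse = ", "))
  dt <- dt[, needed, with = FALSE]
  data.table::setnames(dt, needed, c("patient", "phase", "roi", "feature", "value"))
  for (col in c("patient", "phase", "roi", "feature"))
    data.table::set(dt, j = col, value = as.character(dt[[col]]))
  if (anyDuplicated(dt, by = c("patient", "phase", "roi", "feature")))
    stop("integrity error: duplicated (patient, phase, roi, feature) rows")
  phases <- phase_order %||% {
    ph <- unique(dt$phase)
    ph[order(suppressWarnings(as.numeric(sub("%$", "", ph))))]
  }
  if (!all(dt$phase %in% phases))
    stop("phase labels in file not covered by phase_order")
  tab <- phase_feature_table(NULL, features = sort(unique(dt$feature)),
                             patients = unique(dt$patient), phases = phases,
                             rois = unique(dt$roi))
  idx <- cbind(match(dt$feature, tab$features), match(dt$patient, tab$patients),
               match(dt$phase, tab$phases), match(dt$roi, tab$rois))
  tab$values[idx] <- dt$value
  tab
}

#' Write a phase-feature table as long CSV
#'
#' Inverse of [load_phase_features()]; missing cells are not written, so a
#' write/load round trip reproduces every stored value exactly.
#'
#' @param table a [phase_feature_table].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_phase_features <- function(table, path) {
  stopifnot(inherits(table, "phase_feature_table"))
  dt <- data.table::as.data.table(table$values, value.name = "value")
  dt <- dt[!is.na(dt$value)]
  # 17 significant digits guarantee a bit-exact double round trip
  dt$value <- sprintf("%.17g", dt$value)
  data.table::fwrite(dt[, c("patient", "phase", "roi", "feature", "value"), with = FALSE], path)
  invisible(path)
}

#' Keep only complete clinical cases
#'
#' Retains records with no missing value in any of the required variables,
#' preserving order. Mirrors restricting outcome analysis to patients with
#' complete clinical data collection.
#'
#' @param clinical data.frame of clinical records, one row per patient.
#' @param required character vector of column names that must be non-missing.
#' @return Filtered data.frame.
#' @export
complete_case_filter <- function(clinical, required) {
  stopifnot(is.data.frame(clinical))
  bad <- setdiff(required, names(clinical))
  if (length(bad)) stop("required variable(s) absent: ", paste(bad, collapse = ", "))
  if (!length(required)) return(clinical)
  keep <- complete.cases(clinical[, required, drop = FALSE])
  out <- clinical[keep, , drop = FALSE]
  if (!nrow(out)) warning("no complete cases remain")
  out
}

#' Merge sparse clinical categories
#'
#' Applies the fixed category merges used before modelling: middle-lobe
#' tumours are pooled with upper ("upper+middle") and ECOG performance
#' status 0 with 1 ("0+1"), both because of sparse groups. Idempotent.
#'
#' @param clinical data.frame with columns `lobe` (levels lower/middle/upper)
#'   and/or `ecog` (levels 0/1/2/3); already-merged labels pass through.
#' @return data.frame with merged factor levels.
#' @export
merge_categories <- function(clinical) {
  stopifnot(is.data.frame(clinical))
  if ("lobe" %in% names(clinical)) {
    lobe <- as.character(clinical$lobe)
    known <- c("lower", "middle", "upper", "upper+middle", NA)
    if (!all(lobe %in% known)) stop("unknown lobe category: ",
                                    paste(setdiff(unique(lobe), known), collapse = ", "))
    lobe[lobe %in% c("middle", "upper")] <- "upper+middle"
    clinical$lobe <- factor(lobe, levels = c("lower", "upper+middle"))
  }
  if ("ecog" %in% names(clinical)) {
    ecog <- as.character(clinical$ecog)
    known <- c("0", "1", "2", "3", "0+1", NA)
    if (!all(ecog %in% known)) stop("unknown ecog category: ",
                                    paste(setdiff(unique(ecog), known), collapse = ", "))
    ecog[ecog %in% c("0", "1")] <- "0+1"
    clinical$ecog <- factor(ecog, levels = c("0+1", "2", "3"))
  }
  clinical
}

#' Construct a patient-by-feature matrix with provenance
#'
#' The per-patient feature container after the phase axis has been collapsed
#' by one of the four set-construction methods. Provenance records the
#' (set method, assessment method) pair and must stay within the twelve
#' valid combinations.
#'
#' @param values numeric matrix, patients in rows, features in columns.
#' @param set_method one of `"mean"`, `"median"`, `"phase50"`, `"personalised"`.
#' @param assessment one of `"none"`, `"stability10"`, `"stability3"`,
#'   `"averaging3"`.
#' @return A `feature_matrix` (numeric matrix with provenance attribute).
#' @export
feature_matrix <- function(values, set_method, assessment = "none") {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            ncol(values) == 0 || !is.null(colnames(values)))
  validate_provenance(set_method, assessment)
  structure(values, class = c("feature_matrix", "matrix", "array"),
            provenance = list(set_method = set_method, assessment = assessment))
}

#' @export
print.feature_matrix <- function(x, ...) {
  pv <- attr(x, "provenance")
  cat(sprintf("feature_matrix: %d patients x %d features [set=%s, assessment=%s]\n",
              nrow(x), ncol(x), pv$set_method, pv$assessment))
  invisible(x)
}

# The twelve valid set-method x assessment combinations: neighbour-phase
# assessments only make sense for single-phase feature sets.
#' Enumerate the valid model combinations
#'
#' Returns the twelve valid pairings of feature-set construction method and
#' stability-assessment method: all four assessments for the two single-phase
#' sets (50% phase and personalised), but only `none` and `stability10` for
#' the mean and median sets.
#'
#' @return data.frame with columns `set_method` and `assessment` (12 rows).
#' @export
model_combinations <- function() {
  rbind(
    expand.grid(set_method = c("personalised", "phase50"),
                assessment = c("none", "stability10", "stability3", "averaging3"),
                stringsAsFactors = FALSE),
    expand.grid(set_method = c("mean", "median"),
                assessment = c("none", "stability10"),
                stringsAsFactors = FALSE)
  )
}

validate_provenance <- function(set_method, assessment) {
  set_method <- match.arg(set_method, c("mean", "median", "phase50", "personalised"))
  assessment <- match.arg(assessment, c("none", "stability10", "stability3", "averaging3"))
  if (assessment %in% c("stability3", "averaging3") &&
      !set_method %in% c("phase50", "personalised"))
    stop("configuration error: neighbour-phase assessment '", assessment,
         "' is only valid for single-phase feature sets (phase50, personalised)")
  list(set_method = set_method, assessment = assessment)
}
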