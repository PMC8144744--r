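# Synthetic cohorts with known ground truth.
#
# The generator emulates the structure of a 4D-CT radiomics cohort: smooth
# cyclic per-phase feature variation whose flattest point sits at a
# per-patient designed stable phase, sporadic single-phase artifact spikes,
# correlated feature blocks, volume-coupled features, and survival times
# from an exponential-baseline Cox model on planted features with
# independent uniform censoring. Defaults follow the study cohort shape:
# 258 patients, 10 phases, 186 features per ROI, event fraction 44/258,
# exhale-biased designed phases (about a third at 50%).

#' Simulation design
#'
#' @param n_patients cohort size (default 258).
#' @param n_phases respiratory bins (default 10, labels 0%..90%).
#' @param n_features features per ROI (default 186: 93 per image type).
#' @param rois ROI labels.
#' @param noise_sd white-noise SD in standardised feature units (default
#'   0.05).
#' @param artifact_prob probability a patient has one artifact phase
#'   (default 0.3).
#' @param artifact_magnitude spike size in standardised units (default 0.5,
#'   ten times the noise SD).
#' @param block_size correlated-feature block size (default 10).
#' @param n_volume_coupled volume-coupled features per ROI (default 20).
#' @param planted_features number of prognostic features (default 3).
#' @param planted_loghr log hazard ratio per SD of each plant (default 1).
#' @param event_fraction target event fraction (default 44/258).
#' @param exhale_bias rate of the exponential decay of designed-phase
#'   probability with cyclic distance from 50% (default 1.5, putting about
#'   a third of patients at 50%).
#' @param seed mandatory integer seed.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_patients = 258, n_phases = 10, n_features = 186,
                              rois = c("tumour", "peritumour"),
                              noise_sd = 0.05, artifact_prob = 0.3,
                              artifact_magnitude = 0.5, block_size = 10,
                              n_volume_coupled = 20, planted_features = 3,
                              planted_loghr = 1, event_fraction = 44 / 258,
                              exhale_bias = 1.5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_phases >= 3, event_fraction >= 0, event_fraction < 1)
  structure(list(n_patients = n_patients, n_phases = n_phases,
                 n_features = n_features, rois = rois, noise_sd = noise_sd,
                 artifact_prob = artifact_prob,
                 artifact_magnitude = artifact_magnitude,
                 block_size = block_size, n_volume_coupled = n_volume_coupled,
                 planted_features = planted_features,
                 planted_loghr = planted_loghr,
                 event_fraction = event_fraction, exhale_bias = exhale_bias,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

# cyclic trajectory with its unique flattest point at theta = 0:
# cos(theta) - 0.25 cos(2 theta) (a plain cosine would tie peak and trough)
cyclic_trajectory <- function(theta) cos(theta) - 0.25 * cos(2 * theta)

draw_designed_phases <- function(n, P, phases, exhale_bias) {
  ref <- match("50%", phases)
  if (is.na(ref)) ref <- floor(P / 2) + 1L
  d <- cyclic_distance(seq_len(P), ref, P)
  w <- exp(-d / exhale_bias)
  sample.int(P, n, replace = TRUE, prob = w / sum(w))
}

#' Generate a synthetic phase-feature table with known truth
#'
#' @param design a [simulation_design].
#' @return List with `table` (a [phase_feature_table]) and `truth`: designed
#'   phase per patient, artifact phases, feature scales, block ids,
#'   volume-coupled and planted feature names, per-patient tumour volume
#'   (cm^3) and the patient-level base values used for outcome generation.
#' @export
gen_phase_features <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed)
  n <- design$n_patients; P <- design$n_phases; Fn <- design$n_features
  phases <- default_phase_labels(P)
  patients <- sprintf("P%03d", seq_len(n))
  designed <- draw_designed_phases(n, P, phases, design$exhale_bias)
  artifact <- rep(NA_integer_, n)
  has_art <- runif(n) < design$artifact_prob
  for (i in which(has_art)) {
    # an artifact adjacent to the designed phase would inflate that phase's
    # own neighbour difference, making the designed label false by
    # construction; keep spikes off the designed phase and its neighbours
    cand <- which(cyclic_distance(seq_len(P), designed[i], P) > 1)
    artifact[i] <- cand[sample.int(length(cand), 1)]
  }
  volume <- exp(rnorm(n, log(4.02), 0.85))
  zv <- as.vector(scale(log(volume)))
  tab <- phase_feature_table(NULL, features = sprintf("f%03d", seq_len(Fn)),
                             patients = patients, phases = phases,
                             rois = design$rois)
  truth <- list(designed_phase = setNames(designed, patients),
                artifact_phase = setNames(artifact, patients),
                volume = setNames(volume, patients),
                planted = character(0), volume_coupled = list(),
                base = list())
  theta <- function(phi) 2 * pi * (seq_len(P) - phi) / P
  n_blocks <- ceiling(Fn / design$block_size)
  for (roi in design$rois) {
    block_of <- rep(seq_len(n_blocks), each = design$block_size)[seq_len(Fn)]
    scale_f <- exp(rnorm(Fn, 0, 1))
    # cyclic amplitude comparable to the between-patient SD, so that phase
    # variation dominates the white noise for most features: the designed
    # phase is then the strict per-feature argmin for >= 80% of features
    amp_f <- exp(rnorm(Fn, 0, 0.5))
    vol_idx <- seq_len(min(design$n_volume_coupled, Fn))
    # planted prognostic features: singleton effects, kept off the volume-
    # coupled set so downstream filters cannot remove them for confounding
    plant_idx <- integer(0)
    if (roi == design$rois[1] && design$planted_features > 0) {
      plant_idx <- (Fn - design$planted_features + 1L):Fn
    }
    z_block <- matrix(rnorm(n * n_blocks), n, n_blocks)
    eta <- matrix(rnorm(n * Fn, 0, 0.5), n, Fn)
    base <- z_block[, block_of] + eta
    base[, vol_idx] <- base[, vol_idx] + 1.5 * zv
    if (length(plant_idx)) base[, plant_idx] <- matrix(rnorm(n * length(plant_idx)), n)
    for (i in seq_len(n)) {
      th <- theta(designed[i])
      traj <- cyclic_trajectory(th)   # length P, flattest at designed phase
      eps <- matrix(rnorm(Fn * P, 0, design$noise_sd), Fn, P)
      xv <- (base[i, ] + outer(amp_f, traj) + eps)
      if (!is.na(artifact[i])) {
        spike <- design$artifact_magnitude * sample(c(-1, 1), Fn, replace = TRUE)
        xv[, artifact[i]] <- xv[, artifact[i]] + spike
      }
      tab$values[, i, , roi] <- xv * scale_f
    }
    truth$base[[roi]] <- base
    truth$volume_coupled[[roi]] <- tab$features[vol_idx]
    if (length(plant_idx))
      truth$planted <- paste(roi, tab$features[plant_idx], sep = "|")
  }
  list(table = tab, truth = truth)
}

#' Generate survival outcomes and clinical covariates
#'
#' Survival times come from an exponential-baseline Cox model with linear
#' predictor `sum(beta_j * z(feature_j)) + 0.3 * z(log volume)`; independent
#' uniform censoring is calibrated so the expected event fraction matches
#' the design. Clinical covariate frequencies loosely follow the study
#' demographics (sex about 52/48, median age 76, T stage and ECOG category
#' frequencies, lognormal volume and motion amplitude).
#'
#' @param matrix a [feature_matrix] containing the planted feature columns.
#' @param design a [simulation_design].
#' @param planted character vector of planted column names (default taken
#'   from `attr(matrix, "planted")` or none).
#' @param volume named per-patient tumour volume; defaults to a fresh
#'   lognormal draw if not supplied.
#' @return List with `outcomes` (patient, time in months, event) and
#'   `clinical` (patient, sex, age, t_stage, ecog, lobe, tumour_volume,
#'   motion_amplitude) and `truth` (linear predictor, censor bound).
#' @export
gen_outcomes <- function(matrix, design, planted = NULL, volume = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed + 1L)
  patients <- rownames(matrix)
  n <- length(patients)
  planted <- planted %||% attr(matrix, "planted") %||% character(0)
  stopifnot(all(planted %in% colnames(matrix)))
  if (is.null(volume)) volume <- setNames(exp(rnorm(n, log(4.02), 0.85)), patients)
  volume <- volume[patients]
  lp <- rep(0, n)
  for (f in planted) lp <- lp + design$planted_loghr * as.vector(scale(matrix[, f]))
  lp <- lp + 0.3 * as.vector(scale(log(volume)))
  h0 <- log(2) / 30   # 30-month baseline median, matching observed follow-up scale
  T <- rexp(n, rate = h0 * exp(lp))
  target <- design$event_fraction
  if (target > 0) {
    frac <- function(cmax) mean(pmax(0, 1 - T / cmax)) - target
    cmax <- uniroot(frac, c(1e-3, 1e6))$root
    C <- runif(n, 0, cmax)
  } else {
    cmax <- 0
    C <- rep(0, n)
    warning("event_fraction 0: all observations censored at time ~0")
  }
  event <- as.integer(T <= C)
  time <- pmax(pmin(T, C), 1e-6)
  outcomes <- data.frame(patient = patients, time = time, event = event,
                         stringsAsFactors = FALSE)
  clinical <- data.frame(
    patient = patients,
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(133, 125)),
    age = round(pmin(93, pmax(45, rnorm(n, 75, 9)))),
    t_stage = sample(c("T1", "T2", "T3"), n, replace = TRUE, prob = c(152, 77, 1)),
    ecog = sample(c("0", "1", "2", "3"), n, replace = TRUE, prob = c(3, 78, 117, 27)),
    lobe = sample(c("lower", "middle", "upper"), n, replace = TRUE, prob = c(84, 13, 155)),
    tumour_volume = unname(volume),
    motion_amplitude = exp(rnorm(n, log(5.48), 0.7)),
    stringsAsFactors = FALSE)
  list(outcomes = outcomes, clinical = clinical,
       truth = list(linear_predictor = lp, censor_bound = cmax, latent_time = T))
}

# numeric-array shift with NA fill (integer voxel offsets)
shift_num_real <- function(arr, off, fill = NA_real_) {
  dims <- dim(arr)
  out <- array(fill, dims)
  src <- lapply(1:3, function(a) {
    i <- seq_len(dims[a]) - off[a]
    i[i >= 1 & i <= dims[a]]
  })
  if (any(!lengths(src))) return(out)
  dst <- lapply(1:3, function(a) src[[a]] + off[a])
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

#' Generate a 4D moving-sphere CT phantom
#'
#' A lung-density background (about -750 HU) with a soft-tissue sphere
#' (about 20 HU) translating sinusoidally in z (plus a small x component),
#' an optional high-density "chest wall" slab (about +300 HU), and an
#' optional duplicated-slice artifact at one phase. Background texture is a
#' fixed world-frame noise field; tumour texture is a fixed field moving
#' rigidly with the sphere, so tumour-mask contents are identical across
#' phases (no deformation). Translations are reported relative to the 50%
#' phase.
#'
#' @param n_phases number of phases (default 10).
#' @param dims grid size (default `c(32, 32, 32)`).
#' @param spacing voxel spacing mm (default `c(1.17, 1.17, 3)`).
#' @param radius sphere radius in mm (default 8).
#' @param amp_z,amp_x peak-to-peak motion amplitude in mm (defaults 5, 1).
#' @param slab include the chest-wall slab (default TRUE; placed at the
#'   high-x edge, `slab_margin` voxels thick).
#' @param slab_margin slab thickness in voxels (default 4).
#' @param artifact_phase 1-based phase index receiving a duplicated-slice
#'   artifact, or `NULL`.
#' @param seed integer seed.
#' @return List with `images` (per-phase [image_volume]), `gtv` and
#'   `peritumour` (per-phase [binary_mask]), `translations` (phase x 3
#'   matrix, mm, zero row at the reference phase) and `phases` labels.
#' @export
gen_phantom_4d <- function(n_phases = 10, dims = c(32, 32, 32),
                           spacing = c(1.17, 1.17, 3), radius = 8,
                           amp_z = 5, amp_x = 1, slab = TRUE, slab_margin = 4,
                           artifact_phase = NULL, seed = 1) {
  stopifnot(radius >= 2 * min(spacing))
  set.seed(seed)
  phases <- default_phase_labels(n_phases)
  ref <- match("50%", phases); if (is.na(ref)) ref <- 1L
  centre <- (dims / 2) * spacing
  coord <- list(x = (seq_len(dims[1]) - 0.5) * spacing[1],
                y = (seq_len(dims[2]) - 0.5) * spacing[2],
                z = (seq_len(dims[3]) - 0.5) * spacing[3])
  dist2 <- function(c0) {
    outer(outer((coord$x - c0[1])^2, (coord$y - c0[2])^2, "+"),
          (coord$z - c0[3])^2, "+")
  }
  background <- array(rnorm(prod(dims), -750, 40), dims)
  tumour_tex <- array(rnorm(prod(dims), 20, 30), dims)
  ref_mask <- dist2(centre) <= radius^2
  traj <- function(p) {
    th <- 2 * pi * (p - 1) / n_phases
    c(amp_x / 2 * cos(th), 0, amp_z / 2 * cos(th))
  }
  t_ref <- traj(ref)
  translations <- t(vapply(seq_len(n_phases), function(p) traj(p) - t_ref, numeric(3)))
  dimnames(translations) <- list(phases, c("tx", "ty", "tz"))
  images <- list(); gtvs <- list(); bands <- list()
  for (p in seq_len(n_phases)) {
    shift_vox <- round(translations[p, ] / spacing)
    gtv_arr <- shift_arr_logical(ref_mask, shift_vox)
    img <- background
    tex_p <- shift_num_real(tumour_tex, shift_vox, fill = 20)
    img[gtv_arr] <- tex_p[gtv_arr]
    if (slab) {
      xs <- (dims[1] - slab_margin + 1):dims[1]
      img[xs, , ] <- rnorm(length(xs) * dims[2] * dims[3], 300, 20)
    }
    if (!is.null(artifact_phase) && p == artifact_phase && dims[3] >= 2) {
      k <- floor(dims[3] / 2)
      img[, , k] <- img[, , k + 1]
    }
    img <- pmin(pmax(img, -1050), 3000)
    images[[phases[p]]] <- image_volume(img, spacing)
    gtv <- binary_mask(gtv_arr, spacing)
    band <- peritumour_band(gtv)
    band <- suppressWarnings(correct_high_density(band, gtv, images[[phases[p]]]))
    gtvs[[phases[p]]] <- gtv
    bands[[phases[p]]] <- band
  }
  list(images = images, gtv = gtvs, peritumour = bands,
       translations = translations, phases = phases, reference = phases[ref])
}

shift_arr_logical <- function(mask, off) {
  dims <- dim(mask)
  out <- array(FALSE, dims)
  src <- lapply(1:3, function(a) {
    i <- seq_len(dims[a]) - off[a]
    i[i >= 1 & i <= dims[a]]
  })
  if (any(!lengths(src))) return(out)
  dst <- lapply(1:3, function(a) src[[a]] + off[a])
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}
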