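# cohort generator for selector tests: planted features with known log-HR
# among independent noise features
sim_cohort <- function(n = 200, n_noise = 50, n_plant = 3, beta = 1,
                       event_frac = 0.4, seed = 1) {
  set.seed(seed)
  p <- n_noise + n_plant
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("p%d", 1:n),
                              c(sprintf("noise%02d", seq_len(n_noise)),
                                sprintf("plant%d", seq_len(n_plant)))))
  lp <- x[, grep("plant", colnames(x)), drop = FALSE] %*% rep(beta, n_plant)
  T <- rexp(n, rate = 0.03 * exp(lp))
  cmax <- uniroot(function(cm) mean(pmax(0, 1 - T / cm)) - event_frac,
                  c(1e-3, 1e7))$root
  C <- runif(n, 0, cmax)
  list(x = x,
       outcomes = data.frame(patient = rownames(x),
                             time = pmin(T, C), event = as.integer(T <= C)),
       clinical_design = matrix(rnorm(n * 2), n, 2,
                                dimnames = list(rownames(x), c("c1", "c2"))))
}

test_that("event-matched partitions balance events within one patient per fold", {
  # cohort shaped like 203 patients / 37 events
  set.seed(28)
  oc <- data.frame(patient = sprintf("p%d", 1:203),
                   time = runif(203, 1, 60),
                   event = sample(rep(c(1, 0), c(37, 166))))
  runs <- scv_partition(oc, repeats = 40, folds = 5, seed = 3)
  expect_length(runs, 200)
  for (r in runs[1:25]) {
    ev_test <- sum(oc$event[oc$patient %in% r$test])
    expect_true(ev_test %in% c(7, 8))
    expect_setequal(c(r$train, r$test), oc$patient)
  }
  # per repeat: test folds partition the cohort
  rep1 <- runs[vapply(runs, `[[`, 1, "repeat_idx") == 1]
  tests <- unlist(lapply(rep1, `[[`, "test"))
  expect_setequal(tests, oc$patient)
  expect_equal(anyDuplicated(tests), 0)
  # reproducible under seed
  runs2 <- scv_partition(oc, repeats = 40, folds = 5, seed = 3)
  expect_identical(runs, runs2)
  expect_error(scv_partition(oc[oc$event == 1, ][1:3, ], folds = 5), "at least")
})

test_that("univariable selector has nominal type-I error and high power on plants", {
  co <- sim_cohort(n = 200, n_noise = 200, n_plant = 0, seed = 29)
  sel <- select_univariable(co$x, co$outcomes)
  expect_gt(length(sel) / 200, 0.01)
  expect_lt(length(sel) / 200, 0.10)

  co2 <- sim_cohort(n = 200, n_noise = 5, n_plant = 3, beta = 1, seed = 30)
  sel2 <- select_univariable(co2$x, co2$outcomes)
  expect_true(all(sprintf("plant%d", 1:3) %in% sel2))

  expect_identical(select_univariable(co$x[, 0, drop = FALSE], co$outcomes),
                   character(0))
})

test_that("likelihood-ratio selector ignores features duplicating clinical covariates", {
  co <- sim_cohort(n = 150, n_noise = 3, n_plant = 2, seed = 31)
  # a radiomic feature identical to a clinical covariate adds no likelihood
  x <- cbind(co$x, dupclin = co$clinical_design[, 1])
  sel <- select_multivariable(x, co$clinical_design, co$outcomes)
  expect_false("dupclin" %in% sel)
  expect_true(all(sprintf("plant%d", 1:2) %in% sel))
})

test_that("MRMR ranks the relevant feature first and rejects duplicates", {
  co <- sim_cohort(n = 150, n_noise = 10, n_plant = 1, beta = 1.5, seed = 32)
  sel <- select_mrmr(co$x, co$outcomes)
  expect_equal(sel[1], "plant1")

  # a duplicated relevant feature has redundancy 1 >= relevance immediately
  # after the first copy is selected, so with those two candidates only one
  # copy can ever enter (the score bound is forced by the definition)
  x2 <- co$x[, c("plant1", "plant1"), drop = FALSE]
  colnames(x2) <- c("plant1", "plantcopy")
  sel2 <- select_mrmr(x2, co$outcomes)
  expect_equal(sum(c("plant1", "plantcopy") %in% sel2), 1)

  # all-noise: the positive-score stopping rule keeps the set small
  co3 <- sim_cohort(n = 200, n_noise = 30, n_plant = 0, seed = 33)
  sel3 <- select_mrmr(co3$x, co3$outcomes)
  expect_lt(length(sel3), 15)
})

test_that("the performance ranking follows its defining identity", {
  expect_equal(performance_ranking(0.7, 0.8), 0.6)
  expect_equal(performance_ranking(0.65, 0.65), 0.65)
  set.seed(34)
  for (k in 1:20) {
    ct <- runif(1); cr <- runif(1)
    expect_lte(performance_ranking(ct, cr), ct)
  }
})

test_that("signatures are occurrence-ranked with rounded-median length", {
  cv <- data.frame(repeat_idx = 1, fold_idx = 1:5,
                   n_selected = c(2, 2, 2, 2, 2),
                   selected = c("a;b", "a;b", "a;c", "a;b", "b;a"),
                   c_train = 0.7, c_test = 0.6)
  sig <- build_signature(cv)
  expect_equal(sig$size, 2)
  expect_equal(sig$features, c("a", "b"))

  # fractional median rounds half up
  cv2 <- cv
  cv2$selected <- c("a;b;c", "a;b", "a;b;c", "a;b", "a;b;c;d")
  sig2 <- build_signature(cv2)
  expect_equal(sig2$size, 3)
  expect_equal(sig2$features, c("a", "b", "c"))

  cv3 <- cv; cv3$selected <- ""
  expect_warning(sig3 <- build_signature(cv3), "empty signature")
  expect_length(sig3$features, 0)
})

test_that("cross-validated selection recovers a planted signature end to end", {
  co <- sim_cohort(n = 150, n_noise = 20, n_plant = 3, beta = 1, seed = 35)
  runs <- scv_partition(co$outcomes, repeats = 4, folds = 5, seed = 5)
  cv <- run_selector_cv(co$x, co$clinical_design, co$outcomes, runs, "univariable")
  expect_equal(nrow(cv), 20)
  sig <- build_signature(cv)
  expect_true(all(sprintf("plant%d", 1:3) %in% sig$features))
  expect_gt(median(cv$c_test, na.rm = TRUE), 0.6)

  cmp <- compare_selectors(co$x, co$clinical_design, co$outcomes,
                           scv_partition(co$outcomes, repeats = 2, folds = 5, seed = 6))
  expect_setequal(cmp$summary$selector, c("univariable", "multivariable", "mrmr"))
  expect_true(cmp$best %in% cmp$summary$selector)
  expect_true(all(cmp$summary$ranking <= cmp$summary$median_c_test, na.rm = TRUE))
})
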