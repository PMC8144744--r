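test_that("ICC(A,1) matches an explicit two-way ANOVA oracle to 1e-10", {
  # oracle: mean squares by explicit summation, McGraw-Wong point estimate
  icc_oracle <- function(m) {
    n <- nrow(m); k <- ncol(m); mu <- mean(m)
    ssr <- ssc <- sse <- 0
    for (i in 1:n) ssr <- ssr + k * (mean(m[i, ]) - mu)^2
    for (j in 1:k) ssc <- ssc + n * (mean(m[, j]) - mu)^2
    for (i in 1:n) for (j in 1:k)
      sse <- sse + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + mu)^2
    msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
  set.seed(15)
  for (rep in 1:100) {
    m <- matrix(rnorm(18), 6, 3)
    expect_equal(icc_a1(m)$icc, icc_oracle(m), tolerance = 1e-10)
  }
})

test_that("ICC(A,1) point estimate and CI reproduce an independent reference", {
  # expected values computed once with pingouin.intraclass_corr (ICC(A,1))
  set.seed(42)
  m1 <- matrix(round(rnorm(18, 10, 2), 4), 6, 3)
  r1 <- icc_a1(m1)
  expect_equal(r1$icc, -0.132199250494, tolerance = 1e-9)
  expect_lt(abs(r1$ci_low - (-0.26)), 0.005)   # reference rounded to 2 dp
  expect_lt(abs(r1$ci_high - 0.36), 0.005)

  set.seed(7)
  subj <- rnorm(8, 50, 10)
  m2 <- round(outer(subj, rep(1, 4)) + matrix(rnorm(32, 0, 2), 8, 4), 4)
  r2 <- icc_a1(m2)
  expect_equal(r2$icc, 0.966613432991, tolerance = 1e-9)
  expect_lt(abs(r2$ci_low - 0.90), 0.005)
  expect_lt(abs(r2$ci_high - 0.99), 0.005)
})

test_that("ICC limits: perfect agreement gives 1, dominant noise gives about 0", {
  subj <- seq(1, 12)
  m <- cbind(subj, subj, subj)
  expect_equal(icc_a1(m)$icc, 1)
  set.seed(16)
  mm <- matrix(rep(rnorm(200), 3) + rnorm(600, 0, 50), 200, 3)
  expect_lt(abs(icc_a1(mm)$icc), 0.1)
  # degenerate: zero total variance
  z <- icc_a1(matrix(5, 6, 3))
  expect_true(is.na(z$icc))
})

test_that("ICC is invariant to common shifts and positive scaling", {
  set.seed(17)
  m <- matrix(rnorm(30), 10, 3)
  base <- icc_a1(m)
  expect_equal(icc_a1(m + 100)$icc, base$icc, tolerance = 1e-12)
  expect_equal(icc_a1(m * 7)$icc, base$icc, tolerance = 1e-12)
  expect_equal(icc_a1(m + 100)$ci_low, base$ci_low, tolerance = 1e-12)
})

test_that("agreement-structured generators drive the stability classification", {
  # phase-constant features (patient variation only) are stable
  tab <- make_small_table(n_feat = 2, n_pat = 12, seed = 18)
  for (p in 1:12) for (r in 1:2) tab$values[, p, , r] <- tab$values[, p, 1, r]
  st <- classify_stability(tab, "all_phases")
  expect_true(all(st$icc == 1))
  expect_true(all(st$stable))

  # single-phase artifact spikes in 30% of patients break absolute agreement
  set.seed(19)
  n <- 30
  tab2 <- phase_feature_table(NULL, features = "f1",
                              patients = sprintf("p%d", 1:n))
  for (p in 1:n) {
    v <- rnorm(1)
    x <- rep(v, 10)
    if (p <= 9) x[sample(10, 1)] <- v + 8
    tab2$values[1, p, , ] <- cbind(x, x)
  }
  st2 <- classify_stability(tab2, "all_phases")
  expect_false(any(st2$stable))

  # estimated ICC tracks the designed variance ratio sigma2_s/(sigma2_s+sigma2_e)
  set.seed(20)
  ratio <- 0.8
  iccs <- replicate(300, {
    s <- rnorm(20, 0, sqrt(ratio))
    m <- outer(s, rep(1, 3)) + matrix(rnorm(60, 0, sqrt(1 - ratio)), 20, 3)
    icc_a1(m)$icc
  })
  expect_lt(abs(mean(iccs) - ratio), 0.02)
})

test_that("stable-feature count is non-increasing in the threshold", {
  d <- simulation_design(n_patients = 40, n_features = 30, seed = 21)
  gen <- gen_phase_features(d)
  counts <- vapply(seq(0.5, 0.99, by = 0.07), function(th)
    sum(classify_stability(gen$table, "all_phases", threshold = th)$stable),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("assessment regimes validate Table-1 combinations and transform correctly", {
  d <- simulation_design(n_patients = 30, n_features = 20, seed = 22)
  gen <- gen_phase_features(d)
  sp <- select_stable_phase(gen$table)
  m <- build_feature_set(gen$table, "personalised", stable = sp)

  expect_identical(apply_assessment(m, gen$table, "none"), m)

  mm <- build_feature_set(gen$table, "mean")
  expect_error(apply_assessment(mm, gen$table, "stability3"), "configuration error")
  expect_error(apply_assessment(mm, gen$table, "averaging3"), "configuration error")

  s10 <- apply_assessment(m, gen$table, "stability10", stable_phases = sp)
  expect_true(all(colnames(s10) %in% colnames(m)))
  expect_identical(attr(s10, "provenance")$assessment, "stability10")

  s3 <- apply_assessment(m, gen$table, "stability3", stable_phases = sp)
  st3r <- classify_stability(gen$table, "neighbours", center = sp)
  expect_setequal(colnames(s3), paste(st3r$roi, st3r$feature, sep = "|")[st3r$stable])

  av <- apply_assessment(m, gen$table, "averaging3", stable_phases = sp)
  expect_equal(unclass(av), unclass(neighbour_average(gen$table, sp)),
               ignore_attr = TRUE)

  # personalised stability3 pools patient-specific phase triples as raters
  st3 <- classify_stability(gen$table, "neighbours", center = sp)
  expect_equal(nrow(st3), 20 * 2)
})
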