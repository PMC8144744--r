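test_that("Cox coefficients match a Newton-Raphson partial-likelihood oracle", {
  set.seed(36)
  for (rep in 1:3) {
    n <- 10
    x <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
    oc <- data.frame(time = sample(seq(1, 100, length.out = n)),
                     event = rbinom(n, 1, 0.8))
    if (sum(oc$event) < 3) oc$event[1:3] <- 1
    fit <- fit_cox(x, oc)
    oracle <- cox_nr_oracle(x, oc$time, oc$event)
    expect_equal(unname(fit$coef), unname(oracle), tolerance = 1e-6)
    expect_gte(fit$lr_chisq, 0)
  }
})

test_that("an exchangeable binary covariate carries no information", {
  # two identical groups: same event-time pattern in each
  times <- c(1:6, 1:6) + 0.001 * (0:11)  # distinct but symmetric-ish
  oc <- data.frame(time = c(1:6, 1:6), event = rep(1, 12))
  x <- matrix(rep(c(0, 1), each = 6), ncol = 1, dimnames = list(NULL, "g"))
  fit <- fit_cox(x, oc)
  expect_equal(unname(fit$coef), 0, tolerance = 1e-8)
  expect_lt(fit$lr_chisq, 1e-8)
})

test_that("parameter recovery: planted log-HR 1 lies in the Wald CI almost always", {
  set.seed(37)
  hit <- replicate(40, {
    n <- 500
    x <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "f"))
    T <- rexp(n, 0.05 * exp(x[, 1]))
    C <- runif(n, 0, quantile(T, 0.9) * 2)
    oc <- data.frame(time = pmin(T, C), event = as.integer(T <= C))
    fit <- fit_cox(x, oc)
    se <- sqrt(fit$fit$var[1, 1])
    abs(fit$coef - 1) <= 1.96 * se
  })
  expect_gte(mean(hit), 0.90)
})

test_that("concordance matches exhaustive pair enumeration", {
  set.seed(38)
  for (rep in 1:20) {
    n <- 6
    risk <- round(rnorm(n), 1)  # rounding forces occasional risk ties
    oc <- data.frame(time = sample(n) + runif(n, 0, 0.1),
                     event = rbinom(n, 1, 0.7))
    if (!any(oc$event)) oc$event[1] <- 1
    expect_equal(concordance_index(risk, oc),
                 cindex_oracle(risk, oc$time, oc$event))
  }
  # perfect ordering and all-ties limits
  oc <- data.frame(time = 1:8, event = rep(1, 8))
  expect_equal(concordance_index(8:1, oc), 1)
  expect_equal(concordance_index(rep(0, 8), oc), 0.5)
  expect_error(concordance_index(rnorm(4), data.frame(time = 1:4, event = rep(0, 4))),
               "no comparable")
})

test_that("bootstrap c-index is seed-reproducible and honest about noise", {
  set.seed(39)
  n <- 80
  x <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "f"))
  T <- rexp(n, 0.05 * exp(1.5 * x[, 1]))
  oc <- data.frame(time = T, event = rep(1, n))
  b1 <- bootstrap_cindex(x, oc, B = 60, seed = 11)
  b2 <- bootstrap_cindex(x, oc, B = 60, seed = 11)
  expect_identical(b1, b2)
  expect_gt(b1$median, 0.65)
  expect_true(b1$ci[1] <= b1$median && b1$median <= b1$ci[2])

  # pure noise covariate: median near one half
  xn <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "noise"))
  bn <- bootstrap_cindex(xn, oc, B = 60, seed = 12)
  expect_lt(abs(bn$median - 0.5), 0.12)
})

test_that("fraction of new information follows its defining identities", {
  set.seed(40)
  n <- 60
  clin <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "c1"))
  feat <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "f1"))
  T <- rexp(n, 0.05 * exp(0.8 * clin[, 1] + 1.2 * feat[, 1]))
  oc <- data.frame(time = T, event = rep(1, n))

  fit_c <- fit_cox(clin, oc)
  fit_cr <- fit_cox(cbind(clin, feat), oc)
  fni <- fraction_new_information(fit_c, fit_cr)
  expect_equal(fni$adequacy + fni$fraction_new, 1)
  expect_equal(fni$fraction_new, 1 - fit_c$lr_chisq / fit_cr$lr_chisq)
  expect_gte(fit_cr$lr_chisq, fit_c$lr_chisq)  # nesting monotonicity
  expect_true(fni$fraction_new >= 0 && fni$fraction_new <= 1)

  # CR identical to C -> zero new information
  fni0 <- fraction_new_information(fit_c, fit_c)
  expect_equal(fni0$fraction_new, 0)

  # direct arithmetic: LR 10 vs 20 -> one half
  mock <- function(lr) list(lr_chisq = lr)
  expect_equal(fraction_new_information(mock(10), mock(20))$fraction_new, 0.5)
  expect_error(fraction_new_information(mock(0), mock(0)), "zero LR")

  # radiomic effect dwarfing the clinical one pushes the fraction toward 1
  T2 <- rexp(n, 0.05 * exp(0.1 * clin[, 1] + 2.5 * feat[, 1]))
  oc2 <- data.frame(time = T2, event = rep(1, n))
  fni2 <- fraction_new_information(fit_cox(clin, oc2), fit_cox(cbind(clin, feat), oc2))
  expect_gt(fni2$fraction_new, 0.8)
})

test_that("adding a covariate never decreases the LR statistic", {
  set.seed(41)
  n <- 50
  x <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  oc <- data.frame(time = rexp(n, 0.05 * exp(0.5 * x[, 1])), event = rep(1, n))
  lrs <- vapply(1:3, function(k) fit_cox(x[, 1:k, drop = FALSE], oc)$lr_chisq,
                numeric(1))
  expect_true(all(diff(lrs) >= -1e-8))
})
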