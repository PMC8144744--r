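# Shared fixtures, built in code.

# small complete phase-feature table with known values
make_small_table <- function(n_feat = 3, n_pat = 2, n_phase = 10, seed = 1) {
  set.seed(seed)
  phase_feature_table(
    array(rnorm(n_feat * n_pat * n_phase * 2), c(n_feat, n_pat, n_phase, 2)),
    features = sprintf("f%d", seq_len(n_feat)),
    patients = sprintf("p%d", seq_len(n_pat)),
    phases = phase4d:::default_phase_labels(n_phase))
}

# long-format CSV for a table (writes to a tempfile)
table_to_csv <- function(tab) {
  path <- tempfile(fileext = ".csv")
  write_phase_features(tab, path)
  path
}

# tiny survival data with distinct times (no ties)
toy_outcomes <- function(n = 10, seed = 1, event_p = 0.7) {
  set.seed(seed)
  data.frame(patient = sprintf("p%d", seq_len(n)),
             time = sort(runif(n, 1, 100)) * exp(rnorm(n, 0, 1e-3)),
             event = rbinom(n, 1, event_p))
}

# independent Newton-Raphson maximiser of the Cox partial likelihood
# (Breslow; valid oracle when event times are distinct)
cox_nr_oracle <- function(x, time, event, iter = 50) {
  x <- as.matrix(x)
  beta <- rep(0, ncol(x))
  for (it in seq_len(iter)) {
    eta <- as.vector(x %*% beta)
    w <- exp(eta)
    grad <- rep(0, ncol(x)); hess <- matrix(0, ncol(x), ncol(x))
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      sw <- sum(w[risk])
      xbar <- colSums(x[risk, , drop = FALSE] * w[risk]) / sw
      grad <- grad + x[i, ] - xbar
      xc <- sweep(x[risk, , drop = FALSE], 2, xbar)
      hess <- hess + t(xc * w[risk]) %*% xc / sw
    }
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < 1e-12) break
  }
  beta
}

# exhaustive-pair Harrell concordance oracle
cindex_oracle <- function(risk, time, event) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ti <- time[i]; tj <- time[j]
    if (ti == tj) next
    shorter <- if (ti < tj) i else j
    longer <- if (ti < tj) j else i
    if (event[shorter] == 0) next
    den <- den + 1
    if (risk[shorter] > risk[longer]) num <- num + 1
    else if (risk[shorter] == risk[longer]) num <- num + 0.5
  }
  num / den
}
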