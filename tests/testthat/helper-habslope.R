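# small configurations used across tests

quiet_cfg <- function(...) {
  sim_config(n_control = 4, n_patient = 4, outlier_rate = 0, ...)
}

noiseless_cfg <- function(...) {
  sim_config(noise_sd = 0, novelty_sd = 0, slope_sd = 0, outlier_rate = 0,
             ...)
}

default_window <- function(tr = 2) habituation_window(8, 18, tr)

# brute-force OLS slope via the normal equations, independent of the package
oracle_slope <- function(t, y) {
  X <- cbind(1, t)
  solve(t(X) %*% X, t(X) %*% y)[2]
}

# brute-force least-squares residual via the normal equations
oracle_residual <- function(y, X) {
  as.numeric(y - X %*% solve(t(X) %*% X, t(X) %*% y))
}

# brute-force Pearson chi-square
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# brute-force Spearman rho: rank then Pearson
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))
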