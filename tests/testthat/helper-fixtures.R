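# Shared fixtures and independent oracles for the test suite.

dim_values <- function() {
  p <- emt_parameters()
  stats::setNames(p$value, p$name)
}

# Random valid dimensional parameter table: each varied parameter perturbed
# multiplicatively around its baseline.
random_params <- function(spread = 0.4) {
  p <- emt_parameters()
  p$value[p$varied] <- p$value[p$varied] *
    stats::runif(sum(p$varied), 1 - spread, 1 + spread)
  p
}

# Independent PRCC oracle: partial correlation from the inverse of the
# Pearson correlation matrix of the rank-transformed columns of cbind(X, y):
# rho_jy = -Omega_jy / sqrt(Omega_jj * Omega_yy).
prcc_oracle <- function(X, y) {
  R <- apply(cbind(as.matrix(X), y = y), 2, rank)
  Omega <- solve(stats::cor(R))
  k <- ncol(R) - 1
  vapply(seq_len(k), function(j) {
    -Omega[j, k + 1] / sqrt(Omega[j, j] * Omega[k + 1, k + 1])
  }, numeric(1))
}

# Same construction for the partial correlation of columns i, j of X given
# the remaining columns.
interparameter_oracle <- function(X, i, j) {
  R <- apply(as.matrix(X), 2, rank)
  Omega <- solve(stats::cor(R))
  -Omega[i, j] / sqrt(Omega[i, i] * Omega[j, j])
}

# Significant-parameter set for one cell of a study grid.
sig_set <- function(grid, frame, contact, tgfb, output) {
  s <- grid[grid$frame == frame & grid$contact == contact &
              grid$tgfb == tgfb & grid$output == output, ]
  sort(s$parameter[s$significant])
}

rho_of <- function(grid, frame, contact, tgfb, output, parameter) {
  grid$rho[grid$frame == frame & grid$contact == contact &
             grid$tgfb == tgfb & grid$output == output &
             grid$parameter == parameter]
}
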