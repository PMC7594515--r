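# small topologies and data generators shared across tests

chain_topology <- function(p) {
  nodes <- paste0("N", seq_len(p))
  network_topology(data.frame(from = nodes[-p], to = nodes[-1]))
}

# p-node chain plus one chord, so node/edge counts differ from p - 1
small_topology <- function() {
  network_topology(data.frame(
    from = c("N1", "N2", "N3", "N4", "N1"),
    to   = c("N2", "N3", "N4", "N5", "N4")
  ))
}

# bivariate normal sample with correlation rho
rbvn <- function(n, rho) {
  MASS::mvrnorm(n, c(0, 0), matrix(c(1, rho, rho, 1), 2))
}

# closed-form PMI of the standard bivariate normal with correlation rho
bvn_pmi <- function(x, y, rho) {
  -0.5 * log(1 - rho^2) -
    (rho^2 * x^2 + rho^2 * y^2 - 2 * rho * x * y) / (2 * (1 - rho^2))
}

# independent Newton-Raphson logistic solver used as the fitting oracle
newton_logistic <- function(x, y, iter = 50) {
  beta <- rep(0, ncol(x))
  for (k in seq_len(iter)) {
    mu <- plogis(drop(x %*% beta))
    w <- mu * (1 - mu)
    beta <- beta + solve(crossprod(x * w, x), crossprod(x, y - mu))
  }
  unname(drop(beta))
}
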