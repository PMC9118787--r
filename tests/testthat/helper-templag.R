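# Shared builders for the test suite. All fixtures are generated in code.

# Small abundance matrix with controllable values (features x samples).
toy_table <- function(values, mode = "auto") {
  values <- as.matrix(values)
  rownames(values) <- paste0("s__sp", seq_len(nrow(values)))
  colnames(values) <- paste0("S", seq_len(ncol(values)))
  abundance_table(values, mode = mode)
}

# Designated mediator species id used by the synthetic generator.
mediator_id <- function(cohort) {
  grep("Lachnospiraceae_bacterium_3_1", cohort$feature_ids, value = TRUE)[1]
}

# Standardized two-wave dataset drawn from the implied cross-lag correlation.
draw_crosslag_data <- function(n, rho1, rho2, r1, r2, r3) {
  Sig <- implied_crosslag_corr(rho1, rho2, r1, r2, r3)
  MASS::mvrnorm(n, rep(0, 4), Sig)
}

# Independent ML-SEM oracle: numeric minimization of the discrepancy over the
# nine free parameters (exogenous covariance, four paths, two disturbance
# variances) with the follow-up disturbance covariance fixed at zero.
sem_discrepancy <- function(th, S) {
  v1 <- th[1]; v2 <- th[2]; cc <- th[3]
  B <- rbind(c(th[4], th[5]), c(th[6], th[7]))
  psi <- th[8:9]
  if (any(c(v1, v2, psi) <= 0)) return(1e10)
  Sxx <- matrix(c(v1, cc, cc, v2), 2)
  Syx <- B %*% Sxx
  Syy <- B %*% Sxx %*% t(B) + diag(psi)
  Sig <- rbind(cbind(Sxx, t(Syx)), cbind(Syx, Syy))
  if (min(eigen(Sig, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    return(1e10)
  as.numeric(determinant(Sig)$modulus - determinant(S)$modulus +
               sum(diag(S %*% solve(Sig))) - 4)
}

sem_oracle_T <- function(S, n, start) {
  op <- stats::optim(start * (1 + stats::runif(9, -0.05, 0.05)),
                     sem_discrepancy, S = S, method = "BFGS",
                     control = list(maxit = 2000, reltol = 1e-16))
  (n - 1) * op$value
}

# Closed-form start for the oracle, built only from S (not from the package).
sem_oracle_start <- function(S) {
  bxx <- solve(S[1:2, 1:2], S[1:2, 3:4])
  c(S[1, 1], S[2, 2], S[1, 2], bxx[1, 1], bxx[2, 1], bxx[1, 2], bxx[2, 2],
    S[3, 3] - crossprod(bxx[, 1], S[1:2, 1:2] %*% bxx[, 1]),
    S[4, 4] - crossprod(bxx[, 2], S[1:2, 1:2] %*% bxx[, 2]))
}
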