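# Independent restricted-Hartree-Fock reference: a plain Roothaan fixed-point
# iteration (symmetric orthogonalization, no DIIS, optional density mixing),
# sharing only the integral matrices with the package -- the SCF code path is
# entirely separate from run_neo_scf.

rhf_oracle <- function(system, basis_e, conv = 1e-12, max_iter = 500,
                       mix = 0.3) {
  ints <- neoadapt:::build_integrals(system, basis_e, NULL)
  S <- ints$e$S
  h <- ints$e$h
  n <- nrow(S)
  nocc <- n_electrons(system) %/% 2L
  es <- eigen(S, symmetric = TRUE)
  Shalf <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
  D <- matrix(0, n, n)
  E_old <- Inf
  for (it in seq_len(max_iter)) {
    J <- matrix(ints$ee %*% as.vector(D), n, n)
    K <- matrix(ints$ee_K %*% as.vector(D), n, n)
    F0 <- h + J - 0.5 * K
    E <- sum(D * h) + 0.5 * sum(D * (J - 0.5 * K)) + ints$e_classical
    Fp <- Shalf %*% F0 %*% Shalf
    ev <- eigen((Fp + t(Fp)) / 2, symmetric = TRUE)
    C <- Shalf %*% ev$vectors[, order(ev$values), drop = FALSE]
    D_new <- 2 * C[, seq_len(nocc), drop = FALSE] %*%
      t(C[, seq_len(nocc), drop = FALSE])
    D <- (1 - mix) * D_new + mix * D
    if (abs(E - E_old) < conv && it > 3) break
    E_old <- E
  }
  E
}

# shared fixture-calculation cache so expensive runs are computed once per
# test session
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- force(expr)
  }
  .fixture_cache[[key]]
}

water_system <- function() {
  ang <- 1.8897259886
  molecular_system(
    c("O", "H", "H"),
    rbind(c(0, 0, 0.1173), c(0, 0.7572, -0.4692),
          c(0, -0.7572, -0.4692)) * ang)
}
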