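# Assembly of normalized one- and two-particle integral matrices over the
# spherical contracted basis, for the current center positions.  The compiled
# McMurchie-Davidson kernels work in raw Cartesian functions; here we apply
# the solid-harmonic transform and scale every function to unit self-overlap.
# Everything is rebuilt from scratch after any center move.

#' Closed-form overlap of two normalized s-type primitives
#'
#' `(2 sqrt(a b)/(a+b))^(3/2) exp(-a b R^2 / (a+b))` -- the unit-test anchor
#' of the integral backend contract.
#' @param alpha,beta positive exponents, Bohr^-2.
#' @param R center separation, Bohr.
#' @export
overlap_pair <- function(alpha, beta, R) {
  stopifnot(alpha > 0, beta > 0)
  (2 * sqrt(alpha * beta) / (alpha + beta))^1.5 *
    exp(-alpha * beta * R^2 / (alpha + beta))
}

# Normalized spherical transform for a basis at current positions:
# returns list(Tn = folded transform incl. normalization, raw = cpp matrices)
normalized_transform <- function(basis, system, charge_pos, charges) {
  tab <- shell_table(basis, system)
  raw <- .cpp_one_particle(tab, charge_pos, charges)
  B <- basis_sph_transform(basis)
  S_sph <- B %*% raw$S %*% t(B)
  n <- 1 / sqrt(diag(S_sph))
  Tn <- n * B  # diag(n) %*% B
  list(Tn = Tn, raw = raw)
}

#' One-particle matrices for one species
#'
#' Overlap, kinetic (divided by twice the particle mass, i.e. the electron
#' convention scaled by 1/mass), signed point-charge interaction with the
#' classical nuclei (attractive for electrons, repulsive for protons), and
#' the three Cartesian position-operator matrices.
#'
#' @param basis a [basis_set()].
#' @param system the `neo_system` the basis is attached to.
#' @return list with symmetric matrices `S`, `T`, `V`, `X`, `Y`, `Z` and the
#'   core Hamiltonian `h = T + V`.
#' @export
one_particle <- function(basis, system) {
  cl <- classical_charges(system)
  nt <- normalized_transform(basis, system, cl$positions, cl$charges)
  Tn <- nt$Tn
  tr <- function(M) Tn %*% M %*% t(Tn)
  S <- tr(nt$raw$S)
  K <- tr(nt$raw$T) / basis$mass
  # raw V is the positive kernel sum_A Z_A <1/|r - R_A|>; the species charge
  # signs it: attractive (-) for electrons, repulsive (+) for protons
  V <- if (nrow(cl$positions)) basis$charge * tr(nt$raw$V) else
    matrix(0, nrow(S), ncol(S))
  out <- list(S = S, T = K, V = V,
              X = tr(nt$raw$X), Y = tr(nt$raw$Y), Z = tr(nt$raw$Z))
  out$h <- out$T + out$V
  out
}

# exchange-permuted copy: Kmat[(mu,nu),(la,si)] = (mu la | nu si)
exchange_permute <- function(G, n) {
  A <- array(G, c(n, n, n, n))
  matrix(aperm(A, c(1, 3, 2, 4)), n * n, n * n)
}

# contract index d of a 4-d array with a (m x n_d) matrix
contract_dim <- function(A, T, d) {
  dm <- dim(A)
  perm <- c(d, setdiff(1:4, d))
  M <- matrix(aperm(A, perm), dm[d], prod(dm[-d]))
  out <- array(T %*% M, c(nrow(T), dm[perm[-1]]))
  aperm(out, order(perm))
}

# transform a flattened Cartesian 4-index tensor (n1c^2 x n2c^2) to the
# normalized spherical basis, one index at a time (memory-lean)
eri_transform <- function(G, T1, T2) {
  n1c <- ncol(T1); n2c <- ncol(T2)
  A <- array(G, c(n1c, n1c, n2c, n2c))
  A <- contract_dim(A, T1, 1)
  A <- contract_dim(A, T1, 2)
  A <- contract_dim(A, T2, 3)
  A <- contract_dim(A, T2, 4)
  matrix(A, nrow(T1)^2, nrow(T2)^2)
}

#' Two-particle Coulomb tensors
#'
#' Electron-repulsion tensor `ee`, proton-proton Coulomb tensor `pp` (only
#' when two or more quantum centers are present), and the electron-proton
#' cross tensor `ep`.  All are stored as positive Coulomb kernels in
#' chemists' notation, flattened to `(n1^2 x n2^2)` matrices with
#' column-major pair indices; attraction signs are applied in the Fock
#' builds.
#'
#' @param basis_e electronic [basis_set()].
#' @param basis_p protonic [basis_set()] (may be empty).
#' @param system the shared `neo_system`.
#' @param memory_cap maximum tensor storage in bytes (default 2 GB).
#' @return list `ee`, `pp` (or NULL), `ep` (or NULL).
#' @export
two_particle <- function(basis_e, basis_p = NULL, system,
                         memory_cap = 2e9) {
  cl <- classical_charges(system)
  nte <- normalized_transform(basis_e, system, cl$positions, cl$charges)
  ne <- basis_dim(basis_e)
  np <- if (!is.null(basis_p)) basis_dim(basis_p) else 0L
  nq <- n_quantum(system)
  need <- 8 * ((as.numeric(ne)^4) + (as.numeric(ne) * np)^2 +
                 if (nq >= 2) as.numeric(np)^4 else 0)
  if (need > memory_cap) {
    stop("two-particle tensors need ", format(need, big.mark = ","),
         " bytes, above the configured cap; use a smaller basis or an ",
         "integral-direct mode")
  }
  tab_e <- shell_table(basis_e, system)
  ee <- eri_transform(.cpp_eri(tab_e, tab_e), nte$Tn, nte$Tn)
  out <- list(ee = ee, pp = NULL, ep = NULL)
  if (np > 0) {
    ntp <- normalized_transform(basis_p, system, cl$positions, cl$charges)
    tab_p <- shell_table(basis_p, system)
    out$ep <- eri_transform(.cpp_eri(tab_e, tab_p), nte$Tn, ntp$Tn)
    if (nq >= 2) {
      out$pp <- eri_transform(.cpp_eri(tab_p, tab_p), ntp$Tn, ntp$Tn)
    }
  }
  out
}

# Classical nuclear repulsion over the classical point charges only.
classical_repulsion <- function(system) {
  cl <- classical_charges(system)
  n <- length(cl$charges)
  if (n < 2) return(0)
  e <- 0
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      r <- sqrt(sum((cl$positions[a, ] - cl$positions[b, ])^2))
      e <- e + cl$charges[a] * cl$charges[b] / r
    }
  }
  e
}

# Full integral workspace used by the SCF: one-particle blocks per species,
# flattened two-particle tensors, the exchange-permuted ee copy, and the
# classical repulsion energy.
build_integrals <- function(system, basis_e, basis_p = NULL,
                            memory_cap = 2e9) {
  e1 <- one_particle(basis_e, system)
  p1 <- if (!is.null(basis_p) && basis_dim(basis_p) > 0) {
    one_particle(basis_p, system)
  } else NULL
  t2 <- two_particle(basis_e,
                     if (!is.null(p1)) basis_p else NULL,
                     system, memory_cap = memory_cap)
  ne <- basis_dim(basis_e)
  list(e = e1, p = p1,
       ee = t2$ee, ee_K = exchange_permute(t2$ee, ne),
       ep = t2$ep, pp = t2$pp,
       e_classical = classical_repulsion(system))
}
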