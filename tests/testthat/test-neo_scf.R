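test_that("solve_roothaan handles trivial, 2x2 and degenerate problems", {
  # identity overlap, diagonal Fock: lowest eigenvector occupied
  sol <- solve_roothaan(diag(c(-1, 0, 1)), diag(3), n_occ = 1, occupation = 1)
  expect_equal(sum(diag(sol$density)), 1, tolerance = 1e-12)
  expect_equal(abs(sol$mo_coeffs[, 1]), c(1, 0, 0), tolerance = 1e-12)

  # 2x2 generalized problem against the quadratic closed form:
  # det(F - e S) = 0 with F = [[-1, -0.4], [-0.4, -0.5]], S = [[1, .3], [.3, 1]]
  F2 <- matrix(c(-1, -0.4, -0.4, -0.5), 2, 2)
  S2 <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  a <- 1 - 0.3^2
  b <- -(-1 - 0.5 - 2 * 0.3 * -0.4)
  cc <- (-1) * (-0.5) - 0.4^2
  roots <- sort((-b + c(-1, 1) * sqrt(b^2 - 4 * a * cc)) / (2 * a))
  sol2 <- solve_roothaan(F2, S2, n_occ = 1, occupation = 2)
  expect_equal(sol2$orbital_energies, roots, tolerance = 1e-12)
  expect_equal(sum(sol2$density * S2), 2, tolerance = 1e-12)

  # duplicated basis function: linear dependence projected out, no crash
  F3 <- matrix(c(-1, -1, -1, -1), 2, 2)
  S3 <- matrix(c(1, 1, 1, 1), 2, 2)
  sol3 <- solve_roothaan(F3, S3, n_occ = 1, occupation = 1)
  expect_equal(length(sol3$orbital_energies), 1L)
  expect_error(solve_roothaan(diag(2), matrix(0, 2, 2), 1), "singular basis")
})

test_that("DIIS extrapolation degenerates gracefully", {
  F1 <- matrix(c(1, 2, 2, 3), 2, 2)
  e0 <- matrix(0, 2, 2)
  expect_equal(diis_extrapolate(list(list(fock = F1, error = e0))), F1)
  # two identical entries: no division by zero, same Fock back
  two <- list(list(fock = F1, error = e0 + 0.1),
              list(fock = F1, error = e0 + 0.1))
  expect_equal(suppressWarnings(diis_extrapolate(two)), F1)
  # converged history (errors ~ 0) returns the input Fock
  conv <- list(list(fock = F1, error = e0 + 1e-15),
               list(fock = F1, error = e0))
  expect_equal(suppressWarnings(diis_extrapolate(conv)), F1,
               tolerance = 1e-12)
  # a genuine 2-entry history solves the Pulay system exactly when errors
  # are opposite: equal weights
  Fa <- diag(2); Fb <- 2 * diag(2)
  hist <- list(list(fock = Fa, error = e0 + 1), list(fock = Fb, error = e0 - 1))
  expect_equal(diis_extrapolate(hist), 1.5 * diag(2), tolerance = 1e-12)
  expect_error(diis_extrapolate(list()), "history")
})

test_that("with no protonic density the electronic Fock is conventional RHF", {
  sys <- water_system()
  be <- load_basis("sto-3g", "electron", sys)
  ints <- neoadapt:::build_integrals(sys, be, NULL)
  n <- nrow(ints$e$S)
  set.seed(7)
  Cr <- matrix(rnorm(n * 5), n, 5)
  D <- 2 * Cr %*% t(Cr)
  state <- list(density_e = D, density_p = NULL, n_e = 10L)
  Fpkg <- build_electronic_fock(state, ints)
  J <- matrix(ints$ee %*% as.vector(D), n, n)
  K <- matrix(ints$ee_K %*% as.vector(D), n, n)
  expect_equal(Fpkg, ints$e$h + J - 0.5 * K, tolerance = 1e-12)
})

test_that("nuclear Fock limits: free proton, coupling sign, no J_pp", {
  sysq <- molecular_system("H", matrix(0, 1, 3), quantum = 1L)
  be <- load_basis("et-8s-0.02-3", "electron", sysq)
  bp <- load_basis("pb-et", "proton", sysq)
  ints <- neoadapt:::build_integrals(sysq, be, bp)
  expect_null(ints$pp)  # single quantum proton: no same-species Coulomb
  st0 <- list(density_e = NULL, density_p = NULL, n_e = 1L, n_q = 1L)
  Fp <- build_nuclear_fock(st0, ints)
  expect_equal(Fp, ints$p$h, tolerance = 1e-14)  # pure kinetic, no charges
  eps0 <- solve_roothaan(Fp, ints$p$S, 1, 1)$orbital_energies[1]
  expect_gt(eps0, 0)  # free quantum proton in a finite basis

  # an electron density lowers the lowest protonic level
  sole <- solve_roothaan(ints$e$h, ints$e$S, 1, 1)
  st1 <- list(density_e = sole$density, density_p = NULL, n_e = 1L, n_q = 1L)
  Fp1 <- build_nuclear_fock(st1, ints)
  eps1 <- solve_roothaan(Fp1, ints$p$S, 1, 1)$orbital_energies[1]
  expect_lt(eps1, eps0)

  # removing the proton attraction raises the lowest electronic level
  solp <- solve_roothaan(ints$p$h, ints$p$S, 1, 1)
  st2 <- list(density_e = NULL, density_p = solp$density, n_e = 1L, n_q = 1L)
  Fe <- build_electronic_fock(st2, ints)
  e_with <- solve_roothaan(Fe, ints$e$S, 1, 1)$orbital_energies[1]
  e_without <- solve_roothaan(ints$e$h, ints$e$S, 1, 1)$orbital_energies[1]
  expect_lt(e_with, e_without)
})

test_that("decoupled limit reproduces an independent RHF reference", {
  sys <- water_system()
  be <- load_basis("sto-3g", "electron", sys)
  st <- run_neo_scf(sys, be)
  E_ref <- rhf_oracle(sys, be)
  expect_equal(st$energy_components$E_total, E_ref, tolerance = 1e-8)
  expect_equal(st$energy_components$E_nuclear_quantum, 0)
  expect_equal(st$energy_components$E_coupling, 0)
  # particle-number invariant
  expect_equal(sum(st$density_e * st$integrals$e$S), 10, tolerance = 1e-8)

  # H2/STO-3G at 1.4 Bohr against the textbook restricted-HF value
  h2 <- molecular_system(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.4)))
  b2 <- load_basis("sto-3g", "electron", h2)
  e2 <- run_neo_scf(h2, b2)$energy_components$E_total
  expect_equal(e2, -1.1167, tolerance = 2e-4)
})

test_that("energy decomposition sums and degenerate systems behave", {
  # two classical protons at 2 Bohr, no electrons: pure classical repulsion
  pp <- molecular_system(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 2)),
                         total_charge = 2L)
  be <- load_basis("sto-3g", "electron", pp)
  st <- run_neo_scf(pp, be)
  expect_equal(st$energy_components$E_total, 0.5, tolerance = 1e-12)
  expect_equal(st$energy_components$E_classical_repulsion, 0.5)

  # components sum to the total; coupling equals its brute-force contraction
  fx <- cached("h2_1q", {
    f <- fixture_calculation("h2_1q")
    f$state <- run_neo_scf(f$system, f$basis_e, f$basis_p)
    f
  })
  comp <- fx$state$energy_components
  expect_equal(comp$E_total,
               comp$E_electronic + comp$E_nuclear_quantum + comp$E_coupling +
                 comp$E_classical_repulsion, tolerance = 1e-10)
  ints <- fx$state$integrals
  brute <- -sum(outer(as.vector(fx$state$density_e),
                      as.vector(fx$state$density_p)) * ints$ep)
  expect_equal(comp$E_coupling, brute, tolerance = 1e-10)
  # protonic particle number
  expect_equal(sum(fx$state$density_p * ints$p$S), 1, tolerance = 1e-8)
})

test_that("the H-atom energy obeys the finite-mass variational bound", {
  fa <- fixture_calculation("h_atom")
  st <- cached("h_atom_state", run_neo_scf(fa$system, fa$basis_e, fa$basis_p))
  mu <- 1836.15267343 / 1837.15267343
  expect_gt(st$energy_components$E_total, -mu / 2)
  # enlarging both bases lowers the energy but keeps the bound
  be_small <- load_basis("et-6s-0.05-3", "electron", fa$system)
  bp_small <- basis_set("proton", even_tempered(1, 0, 4, 4, 2), fa$system)
  e_small <- run_neo_scf(fa$system, be_small,
                         bp_small)$energy_components$E_total
  expect_gt(e_small, st$energy_components$E_total)
  expect_gt(e_small, -mu / 2)
})

test_that("warm starts from different guesses converge to one energy", {
  fx <- fixture_calculation("h2_1q")
  st1 <- run_neo_scf(fx$system, fx$basis_e, fx$basis_p)
  # a deliberately different starting density: zero matrices
  ne <- basis_dim(fx$basis_e); np <- basis_dim(fx$basis_p)
  # a zero guess makes the first DIIS histories degenerate; the documented
  # fallback warning is expected
  st2 <- suppressWarnings(
    run_neo_scf(fx$system, fx$basis_e, fx$basis_p,
                init = list(density_e = matrix(0, ne, ne),
                            density_p = matrix(0, np, np))))
  expect_equal(st1$energy_components$E_total, st2$energy_components$E_total,
               tolerance = 1e-8)
})

test_that("zeroing the coupling splits the problem into independent parts", {
  fx <- fixture_calculation("h2_1q")
  ints <- neoadapt:::build_integrals(fx$system, fx$basis_e, fx$basis_p)
  ints$ep <- NULL  # decouple the species
  # independent electronic RHF of the H2 frame with one proton removed from
  # the point-charge list, and a free proton in the same protonic basis
  state <- list(density_e = NULL, density_p = NULL, n_e = 2L, n_q = 1L)
  for (i in 1:60) {
    Fe <- build_electronic_fock(state, ints)
    state$density_e <- solve_roothaan(Fe, ints$e$S, 1, 2)$density
    Fp <- build_nuclear_fock(state, ints)
    state$density_p <- solve_roothaan(Fp, ints$p$S, 1, 1)$density
  }
  comp <- total_energy(state, ints)
  # electronic part: standalone RHF with the same h_e (quantum proton absent
  # from the charge list)
  E_e_alone <- {
    D <- NULL; stt <- list(density_e = NULL, density_p = NULL, n_e = 2L)
    i2 <- ints; i2$ep <- NULL; i2$p <- NULL; i2$pp <- NULL
    for (i in 1:60) {
      Fe <- build_electronic_fock(stt, i2)
      stt$density_e <- solve_roothaan(Fe, i2$e$S, 1, 2)$density
    }
    total_energy(stt, i2)$E_electronic
  }
  expect_equal(comp$E_electronic, E_e_alone, tolerance = 1e-10)
  # protonic part: lowest level of the one-particle problem T_p + V_p
  solp <- solve_roothaan(ints$p$h, ints$p$S, 1, 1)
  expect_equal(comp$E_nuclear_quantum, solp$orbital_energies[1],
               tolerance = 1e-10)
  expect_equal(comp$E_coupling, 0)
})

test_that("total energy is invariant under rigid rotation and translation", {
  fx <- fixture_calculation("h2_1q")
  E0 <- cached("h2_1q", {
    f <- fixture_calculation("h2_1q")
    f$state <- run_neo_scf(f$system, f$basis_e, f$basis_p)
    f
  })$state$energy_components$E_total
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  sys2 <- transform_system(fx$system, rotation = Rz,
                           translation = c(0.3, -0.8, 1.2))
  E1 <- run_neo_scf(sys2, fx$basis_e, fx$basis_p)$energy_components$E_total
  expect_equal(E1, E0, tolerance = 1e-8)
})

test_that("a symmetric system yields a symmetry-commuting Fock matrix", {
  fx <- fixture_calculation("hehhe_cation")
  st <- cached("hehhe_state", run_neo_scf(fx$system, fx$basis_e, fx$basis_p))
  # STO-3G puts one s function per atom; the mirror swaps the two heliums
  P <- diag(3)[, c(3, 2, 1)]
  Fe <- build_electronic_fock(st, st$integrals)
  expect_lt(max(abs(P %*% Fe %*% P - Fe)), 1e-10)
})

test_that("non-convergence raises a condition carrying the iteration trace", {
  fx <- fixture_calculation("h2_1q")
  err <- tryCatch(
    run_neo_scf(fx$system, fx$basis_e, fx$basis_p,
                scf_settings(max_macro = 1L, max_nuclear = 1L,
                             max_electronic = 1L)),
    neo_nonconvergence = function(e) e)
  expect_s3_class(err, "neo_nonconvergence")
  expect_true(is.data.frame(err$trace))
  expect_true(nrow(err$trace) >= 2)
})
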