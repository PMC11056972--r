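# Stepwise coupled multicomponent SCF.  Each macrocycle first converges the
# nuclear Roothaan-Hall problem at fixed electronic density, then runs the
# electronic cycles at fixed protonic density; macrocycles repeat until the
# inter-macrocycle energy change and the per-species energy/density/gradient
# criteria are all met.  DIIS acceleration is applied separately per species.

#' Convergence settings for the coupled SCF
#'
#' Defaults follow tight SCF practice: 1e-8 au on the energy change, RMS
#' density change and orbital-gradient norm within the nuclear and electronic
#' subcycles, 1e-6 hartree on the macrocycle (inter-NEO-iteration) energy
#' change, and DIIS over 10 Fock matrices starting after the first iteration.
#'
#' @param e_conv energy-change threshold within subcycles, hartree.
#' @param d_conv RMS density-change threshold.
#' @param g_conv Frobenius norm threshold on the orbital gradient `FDS - SDF`.
#' @param neo_e_conv macrocycle energy-change threshold, hartree.
#' @param diis_depth number of Fock matrices kept for extrapolation.
#' @param max_nuclear,max_electronic,max_macro cycle caps per level.
#' @param lindep overlap-eigenvalue threshold for canonical orthogonalization.
#' @return a `neo_settings` list.
#' @export
scf_settings <- function(e_conv = 1e-8, d_conv = 1e-8, g_conv = 1e-8,
                         neo_e_conv = 1e-6, diis_depth = 10L,
                         max_nuclear = 50L, max_electronic = 100L,
                         max_macro = 200L, lindep = 1e-10) {
  s <- list(e_conv = e_conv, d_conv = d_conv, g_conv = g_conv,
            neo_e_conv = neo_e_conv, diis_depth = as.integer(diis_depth),
            max_nuclear = as.integer(max_nuclear),
            max_electronic = as.integer(max_electronic),
            max_macro = as.integer(max_macro), lindep = lindep)
  if (any(unlist(s[1:4]) <= 0)) stop("convergence thresholds must be positive")
  structure(s, class = "neo_settings")
}

#' Solve one generalized Roothaan-Hall eigenproblem
#'
#' Canonical orthogonalization: overlap eigenvectors with eigenvalues below
#' the linear-dependence threshold are projected out, the Fock matrix is
#' diagonalized in the surviving orthonormal space, and the density is built
#' from the `n_occ` lowest orbitals.
#'
#' @param fock symmetric Fock matrix.
#' @param overlap symmetric positive-semidefinite overlap matrix.
#' @param n_occ number of occupied orbitals.
#' @param occupation occupation per orbital: 2 for closed-shell electrons,
#'   1 for protons (and for a single electron).
#' @param lindep eigenvalue threshold for projecting out linear dependence.
#' @return list `mo_coeffs` (AO x MO), `orbital_energies`, `density`.
#' @export
solve_roothaan <- function(fock, overlap, n_occ, occupation = 1,
                           lindep = 1e-10) {
  es <- eigen(overlap, symmetric = TRUE)
  keep <- es$values > lindep
  if (!any(keep)) stop("singular basis: all overlap eigenvalues below ",
                       lindep)
  X <- es$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(es$values[keep]), sum(keep))
  Fp <- t(X) %*% fock %*% X
  ef <- eigen((Fp + t(Fp)) / 2, symmetric = TRUE)
  ord <- order(ef$values)
  C <- X %*% ef$vectors[, ord, drop = FALSE]
  eps <- ef$values[ord]
  if (n_occ > length(eps)) stop("not enough orbitals (", length(eps),
                                ") for ", n_occ, " occupied")
  Cocc <- C[, seq_len(n_occ), drop = FALSE]
  D <- occupation * Cocc %*% t(Cocc)
  list(mo_coeffs = C, orbital_energies = eps, density = D)
}

#' Pulay DIIS extrapolation
#'
#' Standard direct inversion in the iterative subspace over a history of
#' (Fock, error) pairs, error being the AO-basis orbital gradient
#' `FDS - SDF`.  Entries beyond `depth` are evicted (oldest first).  A
#' singular DIIS system falls back to the latest Fock matrix with a warning.
#'
#' @param history list of `list(fock = , error = )`, oldest first.
#' @param depth maximum history length used.
#' @return the extrapolated Fock matrix.
#' @export
diis_extrapolate <- function(history, depth = 10L) {
  if (!length(history)) stop("DIIS requires at least one history entry")
  if (length(history) > depth) {
    history <- history[(length(history) - depth + 1L):length(history)]
  }
  if (length(history) == 1L) return(history[[1]]$fock)
  latest <- history[[length(history)]]
  if (sqrt(sum(latest$error^2)) < 1e-12) {
    # numerically converged: extrapolation is ill-posed and unnecessary
    return(latest$fock)
  }
  solve_sub <- function(hist) {
    m <- length(hist)
    B <- matrix(0, m + 1, m + 1)
    for (i in seq_len(m)) {
      for (j in i:m) {
        B[i, j] <- B[j, i] <- sum(hist[[i]]$error * hist[[j]]$error)
      }
    }
    B[m + 1, seq_len(m)] <- B[seq_len(m), m + 1] <- -1
    # scaling the error-overlap block only rescales the Lagrange multiplier,
    # not the extrapolation weights
    sc <- max(abs(B[seq_len(m), seq_len(m)]), 1e-300)
    B[seq_len(m), seq_len(m)] <- B[seq_len(m), seq_len(m)] / sc
    rhs <- c(rep(0, m), -1)
    coef <- tryCatch(solve(B, rhs), error = function(e) NULL)
    if (is.null(coef) || any(!is.finite(coef)) ||
        kappa(B, exact = FALSE) > 1e14) return(NULL)
    coef
  }
  # near-converged histories are linearly dependent: drop oldest entries
  # until the DIIS system is solvable
  while (length(history) > 1L) {
    coef <- solve_sub(history)
    if (!is.null(coef)) {
      F_new <- 0
      m <- length(history)
      for (i in seq_len(m)) F_new <- F_new + coef[i] * history[[i]]$fock
      return(F_new)
    }
    history <- history[-1L]
  }
  warning("singular DIIS system; using latest Fock matrix")
  history[[length(history)]]$fock
}

# --- Fock builds -----------------------------------------------------------

vecD <- function(D) as.vector(D)
unflat <- function(v, n) matrix(v, n, n)

#' Electronic Fock matrix
#'
#' `F_e = h_e + J_ee(D_e) - 1/2 K_ee(D_e) - J_ep(D_p)` in the closed-shell
#' convention (total density `D_e`).  For a one-electron system the
#' same-species Coulomb and exchange terms are absent.  The electron-proton
#' Coulomb enters attractively.
#'
#' @param state a list carrying `density_e`, `density_p`, `n_e`.
#' @param integrals integral workspace from the SCF driver.
#' @return the Fock matrix.
#' @export
build_electronic_fock <- function(state, integrals) {
  ne <- nrow(integrals$e$S)
  if (!is.null(state$density_e) &&
      !identical(dim(state$density_e), dim(integrals$e$S))) {
    stop("electronic density dimension does not match the integral workspace")
  }
  F_e <- integrals$e$h
  if (state$n_e > 1 && !is.null(state$density_e)) {
    J <- unflat(integrals$ee %*% vecD(state$density_e), ne)
    K <- unflat(integrals$ee_K %*% vecD(state$density_e), ne)
    F_e <- F_e + J - 0.5 * K
  }
  if (!is.null(integrals$ep) && !is.null(state$density_p)) {
    F_e <- F_e - unflat(integrals$ep %*% vecD(state$density_p), ne)
  }
  F_e
}

#' Nuclear (protonic) Fock matrix
#'
#' `F_p = T_p/m + V_p(classical nuclei, repulsive) + J_pp(D_p) - J_pe(D_e)`.
#' The proton-proton Coulomb term is present only with two or more quantum
#' protons (a single particle has no same-species interaction); no
#' proton-proton exchange is included.
#'
#' @inheritParams build_electronic_fock
#' @export
build_nuclear_fock <- function(state, integrals) {
  np <- nrow(integrals$p$S)
  F_p <- integrals$p$h
  if (!is.null(integrals$pp) && !is.null(state$density_p)) {
    F_p <- F_p + unflat(integrals$pp %*% vecD(state$density_p), np)
  }
  if (!is.null(integrals$ep) && !is.null(state$density_e)) {
    F_p <- F_p - unflat(crossprod(integrals$ep, vecD(state$density_e)), np)
  }
  F_p
}

#' Energy decomposition of a multicomponent state
#'
#' `E_electronic = Tr(D_e h_e) + 1/2 Tr(D_e (J_ee - 1/2 K_ee))` (same-species
#' terms absent for one electron), `E_nuclear_quantum = Tr(D_p h_p) +
#' 1/2 Tr(D_p J_pp)`, `E_coupling = -Tr(D_e J_ep(D_p))` counted once, and
#' `E_classical_repulsion` over classical nuclei only.
#'
#' @param state list with `density_e`, `density_p`, `n_e`.
#' @param integrals integral workspace.
#' @param system the `neo_system` (unused beyond interface symmetry; the
#'   classical repulsion is cached in the workspace).
#' @return named list of components in hartree, including `E_total`.
#' @export
total_energy <- function(state, integrals, system = NULL) {
  E_e <- 0
  if (!is.null(state$density_e) && state$n_e > 0) {
    De <- state$density_e
    E_e <- sum(De * integrals$e$h)
    if (state$n_e > 1) {
      ne <- nrow(De)
      J <- unflat(integrals$ee %*% vecD(De), ne)
      K <- unflat(integrals$ee_K %*% vecD(De), ne)
      E_e <- E_e + 0.5 * sum(De * (J - 0.5 * K))
    }
  }
  E_p <- 0
  if (!is.null(state$density_p) && !is.null(integrals$p)) {
    Dp <- state$density_p
    E_p <- sum(Dp * integrals$p$h)
    if (!is.null(integrals$pp)) {
      np <- nrow(Dp)
      Jpp <- unflat(integrals$pp %*% vecD(Dp), np)
      E_p <- E_p + 0.5 * sum(Dp * Jpp)
    }
  }
  E_c <- 0
  if (!is.null(state$density_e) && !is.null(state$density_p) &&
      !is.null(integrals$ep)) {
    E_c <- -sum(vecD(state$density_e) *
                  (integrals$ep %*% vecD(state$density_p)))
  }
  E_cl <- integrals$e_classical
  list(E_electronic = E_e, E_nuclear_quantum = E_p, E_coupling = E_c,
       E_classical_repulsion = E_cl, E_total = E_e + E_p + E_c + E_cl)
}

# --- stage driver ----------------------------------------------------------

orbital_gradient <- function(F, D, S) F %*% D %*% S - S %*% D %*% F

# Converge one species' Roothaan-Hall problem at fixed partner density.
# The cross-species Coulomb matrix and the partner's energy contribution are
# constant within the stage and are computed once; the stage energy is
# evaluated from the density used to build each Fock matrix.
converge_stage <- function(species, state, integrals, settings, macro) {
  if (species == "p") {
    S <- integrals$p$S; n_occ <- state$n_q; occ <- 1
    D <- state$density_p
    max_iter <- settings$max_nuclear
    np <- nrow(S)
    J_cross <- if (!is.null(integrals$ep) && !is.null(state$density_e)) {
      unflat(crossprod(integrals$ep, vecD(state$density_e)), np)
    } else NULL
    # electronic energy is frozen during the nuclear stage
    E_fixed <- integrals$e_classical
    if (!is.null(state$density_e) && state$n_e > 0) {
      De <- state$density_e
      E_fixed <- E_fixed + sum(De * integrals$e$h)
      if (state$n_e > 1) {
        ne <- nrow(De)
        J <- unflat(integrals$ee %*% vecD(De), ne)
        K <- unflat(integrals$ee_K %*% vecD(De), ne)
        E_fixed <- E_fixed + 0.5 * sum(De * (J - 0.5 * K))
      }
    }
    energy_at <- function(Dcur, Jpp) {
      E <- E_fixed + sum(Dcur * integrals$p$h)
      if (!is.null(Jpp)) E <- E + 0.5 * sum(Dcur * Jpp)
      if (!is.null(J_cross)) E <- E - sum(Dcur * J_cross)
      E
    }
    fock_at <- function(Dcur) {
      Jpp <- if (!is.null(integrals$pp)) {
        unflat(integrals$pp %*% vecD(Dcur), np)
      } else NULL
      F0 <- integrals$p$h
      if (!is.null(Jpp)) F0 <- F0 + Jpp
      if (!is.null(J_cross)) F0 <- F0 - J_cross
      list(fock = F0, E = energy_at(Dcur, Jpp))
    }
  } else {
    S <- integrals$e$S
    occ <- if (state$n_e == 1) 1 else 2
    n_occ <- if (state$n_e == 1) 1L else state$n_e %/% 2L
    D <- state$density_e
    max_iter <- settings$max_electronic
    ne <- nrow(S)
    J_cross <- if (!is.null(integrals$ep) && !is.null(state$density_p)) {
      unflat(integrals$ep %*% vecD(state$density_p), ne)
    } else NULL
    # protonic energy is frozen during the electronic stage
    E_fixed <- integrals$e_classical
    if (!is.null(state$density_p) && !is.null(integrals$p)) {
      Dp <- state$density_p
      E_fixed <- E_fixed + sum(Dp * integrals$p$h)
      if (!is.null(integrals$pp)) {
        np <- nrow(Dp)
        Jpp <- unflat(integrals$pp %*% vecD(Dp), np)
        E_fixed <- E_fixed + 0.5 * sum(Dp * Jpp)
      }
    }
    fock_at <- function(Dcur) {
      F0 <- integrals$e$h
      E <- E_fixed + sum(Dcur * integrals$e$h)
      if (state$n_e > 1) {
        J <- unflat(integrals$ee %*% vecD(Dcur), ne)
        K <- unflat(integrals$ee_K %*% vecD(Dcur), ne)
        F0 <- F0 + J - 0.5 * K
        E <- E + 0.5 * sum(Dcur * (J - 0.5 * K))
      }
      if (!is.null(J_cross)) {
        F0 <- F0 - J_cross
        E <- E - sum(Dcur * J_cross)
      }
      list(fock = F0, E = E)
    }
  }
  history <- list()
  log <- list()
  E_prev <- NA_real_
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    fb <- fock_at(D)
    F0 <- fb$fock
    err <- orbital_gradient(F0, D, S)
    history[[length(history) + 1L]] <- list(fock = F0, error = err)
    # DIIS starts after the first iteration; at a numerically exact fixed
    # point the error matrices vanish and extrapolation is skipped
    F_use <- if (it > 1 && sqrt(sum(err^2)) > 1e-11) {
      diis_extrapolate(history, settings$diis_depth)
    } else F0
    sol <- solve_roothaan(F_use, S, n_occ, occ, settings$lindep)
    D_new <- sol$density
    if (species == "p") {
      state$density_p <- D_new
      state$mo_coeffs_p <- sol$mo_coeffs
      state$orbital_energies_p <- sol$orbital_energies
      state$fock_p <- F_use
    } else {
      state$density_e <- D_new
      state$mo_coeffs_e <- sol$mo_coeffs
      state$orbital_energies_e <- sol$orbital_energies
      state$fock_e <- F_use
    }
    E <- fb$E
    dE <- if (is.na(E_prev)) NA_real_ else E - E_prev
    rmsd <- sqrt(mean((D_new - D)^2))
    gn <- sqrt(sum(err^2))
    log[[length(log) + 1L]] <- data.frame(
      level = if (species == "p") "nuclear" else "electronic",
      macro = macro, cycle = it, E_total = E, dE = dE,
      d_rms = rmsd, grad_norm = gn)
    D <- D_new
    E_prev <- E
    if (!is.na(dE) && abs(dE) < settings$e_conv && rmsd < settings$d_conv &&
        gn < settings$g_conv) {
      converged <- TRUE
      break
    }
  }
  list(state = state, converged = converged,
       log = do.call(rbind, log))
}

nonconvergence <- function(msg, trace) {
  stop(structure(class = c("neo_nonconvergence", "error", "condition"),
                 list(message = msg, call = sys.call(-1), trace = trace)))
}

init_state <- function(system, integrals, settings) {
  n_e <- n_electrons(system)
  n_q <- n_quantum(system)
  state <- list(n_e = n_e, n_q = n_q,
                density_e = NULL, density_p = NULL)
  if (n_e > 0) {
    occ <- if (n_e == 1) 1 else 2
    n_occ <- if (n_e == 1) 1L else n_e %/% 2L
    sol <- solve_roothaan(integrals$e$h, integrals$e$S, n_occ, occ,
                          settings$lindep)
    state$density_e <- sol$density
    state$mo_coeffs_e <- sol$mo_coeffs
    state$orbital_energies_e <- sol$orbital_energies
  }
  if (n_q > 0 && !is.null(integrals$p)) {
    sol <- solve_roothaan(integrals$p$h, integrals$p$S, n_q, 1,
                          settings$lindep)
    state$density_p <- sol$density
    state$mo_coeffs_p <- sol$mo_coeffs
    state$orbital_energies_p <- sol$orbital_energies
  }
  state
}

# Internal engine shared by run_neo_scf (adaptive = NULL) and
# run_adaptive_neo (adaptive = neo_adaptive_settings()).  `init` may carry
# warm-start densities (density_e / density_p).
neo_engine <- function(system, basis_e, basis_p = NULL,
                       settings = scf_settings(), adaptive = NULL,
                       init = NULL) {
  have_p <- n_quantum(system) > 0 && !is.null(basis_p) &&
    basis_dim(basis_p) > 0
  ints <- build_integrals(system, basis_e, if (have_p) basis_p else NULL)
  state <- init_state(system, ints, settings)
  if (!is.null(init$density_e)) state$density_e <- init$density_e
  if (!is.null(init$density_p) && have_p) state$density_p <- init$density_p
  logs <- list()
  trace <- list()
  E_prev <- NA_real_
  converged <- FALSE
  final_disp <- 0
  for (macro in seq_len(settings$max_macro)) {
    nuc_conv <- TRUE
    if (have_p) {
      st <- converge_stage("p", state, ints, settings, macro)
      state <- st$state
      logs[[length(logs) + 1L]] <- st$log
      nuc_conv <- st$converged
    }
    max_disp <- 0
    if (!is.null(adaptive) && have_p && nuc_conv) {
      up <- adaptive_step(state, system, basis_p, ints, adaptive,
                          basis_e = basis_e)
      system <- up$system
      max_disp <- up$max_disp
      ints <- up$integrals
      comp <- total_energy(state, ints)
      trace[[length(trace) + 1L]] <- cbind(
        data.frame(macro = macro), up$rows,
        data.frame(E_total = comp$E_total,
                   E_electronic = comp$E_electronic,
                   E_nuclear_quantum = comp$E_nuclear_quantum,
                   E_coupling = comp$E_coupling,
                   E_classical_repulsion = comp$E_classical_repulsion))
    }
    elec_conv <- TRUE
    if (state$n_e > 0) {
      st <- converge_stage("e", state, ints, settings, macro)
      state <- st$state
      logs[[length(logs) + 1L]] <- st$log
      elec_conv <- st$converged
    }
    comp <- total_energy(state, ints)
    E <- comp$E_total
    dE <- if (is.na(E_prev)) NA_real_ else E - E_prev
    logs[[length(logs) + 1L]] <- data.frame(
      level = "macro", macro = macro, cycle = macro, E_total = E, dE = dE,
      d_rms = NA_real_, grad_norm = NA_real_)
    pos_ok <- is.null(adaptive) || max_disp < adaptive$position_threshold
    if (!is.na(dE) && abs(dE) < settings$neo_e_conv && nuc_conv &&
        elec_conv && pos_ok) {
      converged <- TRUE
      final_disp <- max_disp
      break
    }
    E_prev <- E
    if (!have_p && state$n_e > 0 && elec_conv && is.null(adaptive)) {
      # purely electronic problem: the electronic stage is already converged
      # to the subcycle thresholds; one extra macrocycle only confirms dE = 0
      next
    }
  }
  log_df <- do.call(rbind, logs)
  if (!converged) {
    msg <- "NEO SCF did not converge within the macrocycle cap"
    if (!is.null(adaptive)) {
      msg <- paste0(msg, "; if the centroid positions oscillate, retry with ",
                    "a damping factor below 1")
    }
    nonconvergence(msg, log_df)
  }
  comp <- total_energy(state, ints)
  state$energy_components <- comp
  state$converged <- TRUE
  state$log <- log_df
  state$system <- system
  state$integrals <- ints
  state$max_centroid_disp <- final_disp
  state$trace <- if (length(trace)) do.call(rbind, trace) else NULL
  class(state) <- "neo_scf_state"
  state
}

#' Run the coupled multicomponent SCF at fixed centers
#'
#' Converges the stepwise nuclear/electronic macrocycles at fixed center
#' positions, i.e. a point on the extended NEO potential-energy surface.
#' With no quantum atoms this reduces exactly to conventional restricted
#' Hartree-Fock.
#'
#' @param system a `neo_system`.
#' @param basis_e electronic [basis_set()].
#' @param basis_p protonic [basis_set()] (NULL or empty for RHF).
#' @param settings a [scf_settings()].
#' @param init optional list with warm-start `density_e` / `density_p`.
#' @return a `neo_scf_state` with densities, MO coefficients, orbital
#'   energies, the energy decomposition, and the iteration log.
#' @export
run_neo_scf <- function(system, basis_e, basis_p = NULL,
                        settings = scf_settings(), init = NULL) {
  neo_engine(system, basis_e, basis_p, settings, adaptive = NULL,
             init = init)
}

#' @export
print.neo_scf_state <- function(x, ...) {
  cat("<neo_scf_state>\n")
  comp <- x$energy_components
  for (nm in names(comp)) {
    cat(sprintf("  %-22s %18.10f hartree\n", nm, comp[[nm]]))
  }
  invisible(x)
}
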