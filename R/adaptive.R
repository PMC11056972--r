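# Adaptive relocation of quantum-center positions: after each converged
# nuclear subcycle the center carrying a quantum proton's basis functions
# (protonic and that atom's electronic shells alike -- they share one center
# object) is moved to the charge centroid of its assigned occupied nuclear
# orbital.  Iterated to co-convergence with the SCF, this lands on the
# proton-position-optimized (standard NEO) surface without gradients.

#' Settings for the adaptive centroid update
#'
#' @param position_threshold convergence threshold on the largest centroid
#'   displacement, Bohr (default 1e-5).
#' @param damping_factor step scaling in (0, 1]; 1 applies the full centroid
#'   shift (no damping, the default), smaller values damp oscillations.
#' @param max_step runaway guard: a single displacement above this many Bohr
#'   aborts with a diagnostic.
#' @return a `neo_adaptive_settings` list.
#' @export
adaptive_settings <- function(position_threshold = 1e-5, damping_factor = 1,
                              max_step = 1) {
  if (position_threshold <= 0) stop("position threshold must be positive")
  if (damping_factor <= 0 || damping_factor > 1) {
    stop("damping factor must lie in (0, 1]")
  }
  structure(list(position_threshold = position_threshold,
                 damping_factor = damping_factor, max_step = max_step),
            class = "neo_adaptive_settings")
}

#' Charge centroids of the occupied nuclear orbitals
#'
#' The centroid of orbital i is the expectation value of the Cartesian
#' position operator, `(c_i' X c_i, c_i' Y c_i, c_i' Z c_i)`, with `c_i` the
#' AO coefficients of the occupied nuclear orbital assigned to quantum
#' center i.
#'
#' @param state a state carrying `mo_coeffs_p`.
#' @param position_matrices list with protonic `X`, `Y`, `Z` matrices.
#' @param assignment integer vector: for each quantum center (in order), the
#'   index of its occupied nuclear orbital.
#' @return matrix with one row per quantum center, columns x, y, z (Bohr).
#' @export
compute_centroids <- function(state, position_matrices, assignment) {
  out <- matrix(NA_real_, length(assignment), 3,
                dimnames = list(NULL, c("x", "y", "z")))
  for (k in seq_along(assignment)) {
    ci <- state$mo_coeffs_p[, assignment[k]]
    out[k, ] <- c(drop(ci %*% position_matrices$X %*% ci),
                  drop(ci %*% position_matrices$Y %*% ci),
                  drop(ci %*% position_matrices$Z %*% ci))
  }
  out
}

#' Map occupied nuclear orbitals to quantum centers
#'
#' Mulliken populations of each occupied nuclear orbital are accumulated per
#' quantum center; the one-to-one assignment maximizing the summed
#' populations is chosen (exhaustively for small counts), with ties broken
#' deterministically by center index.  An orbital whose largest population
#' falls below 0.5 triggers an ambiguity warning.
#'
#' @param state a state with `mo_coeffs_p` and `n_q`.
#' @param basis_p the protonic [basis_set()].
#' @param overlap protonic overlap matrix.
#' @param quantum_centers indices of the quantum centers, in system order.
#' @return integer vector: for each quantum center, the assigned occupied
#'   orbital index.
#' @export
assign_orbitals <- function(state, basis_p, overlap, quantum_centers) {
  nq <- state$n_q
  fc <- basis_function_centers(basis_p)
  P <- matrix(0, nq, nq)  # orbitals x centers
  for (i in seq_len(nq)) {
    ci <- state$mo_coeffs_p[, i]
    contrib <- ci * drop(overlap %*% ci)  # Mulliken per function
    for (k in seq_len(nq)) {
      P[i, k] <- sum(contrib[fc == quantum_centers[k]])
    }
  }
  for (i in seq_len(nq)) {
    if (max(P[i, ]) < 0.5) {
      warning("nuclear orbital ", i, " has no dominant center (max Mulliken ",
              "population ", signif(max(P[i, ]), 3), "); assignment may be ",
              "ambiguous for centers ",
              paste(quantum_centers, collapse = ", "))
    }
  }
  if (nq == 1L) return(1L)
  if (nq <= 7L) {
    perms <- permutations_of(nq)
    best <- -Inf; best_perm <- NULL
    for (p in perms) {
      s <- sum(P[cbind(p, seq_len(nq))])
      if (s > best + 1e-12) { best <- s; best_perm <- p }
    }
    assignment <- best_perm
  } else {
    # greedy fallback for many protons
    assignment <- integer(nq)
    taken <- logical(nq)
    for (k in seq_len(nq)) {
      ord <- order(P[, k], decreasing = TRUE)
      ord <- ord[!taken[ord]]
      assignment[k] <- ord[1]
      taken[ord[1]] <- TRUE
    }
  }
  assignment
}

permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in permutations_of(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    }
  }
  out
}

#' One adaptive centroid update
#'
#' Moves every quantum center toward its orbital's charge centroid,
#' `r_q <- r_q + damping * (centroid - r_q)`; classical centers never move.
#' Both the protonic shells and the moved atom's electronic shells follow,
#' because they reference the same center.  Position-dependent integrals
#' must be (and, when `basis_e` is supplied, are) rebuilt afterwards.
#'
#' @param state converged-nuclear-stage state.
#' @param system current `neo_system`.
#' @param basis_p protonic basis.
#' @param integrals current integral workspace (for position matrices).
#' @param settings an [adaptive_settings()].
#' @param basis_e electronic basis; when given and a move occurred, the
#'   returned workspace is rebuilt at the new positions.
#' @return list with `system`, `integrals` (rebuilt or unchanged),
#'   `max_disp` (Bohr), `moved` flag, `centroids`, and per-center `rows`
#'   (a data frame for the adaptive trace).
#' @export
adaptive_step <- function(state, system, basis_p, integrals, settings,
                          basis_e = NULL) {
  qc <- which(system$is_quantum)
  assignment <- assign_orbitals(state, basis_p, integrals$p$S, qc)
  cent <- compute_centroids(state,
                            list(X = integrals$p$X, Y = integrals$p$Y,
                                 Z = integrals$p$Z),
                            assignment)
  disp <- cent - system$positions[qc, , drop = FALSE]
  dn <- sqrt(rowSums(disp^2))
  if (any(dn > settings$max_step)) {
    bad <- qc[which.max(dn)]
    stop("adaptive step of ", signif(max(dn), 4), " Bohr at center ", bad,
         " exceeds the ", settings$max_step,
         " Bohr runaway guard; check the starting geometry or basis")
  }
  step <- settings$damping_factor * disp
  moved <- max(dn) * settings$damping_factor > 0
  for (k in seq_along(qc)) {
    system$positions[qc[k], ] <- system$positions[qc[k], ] + step[k, ]
  }
  rows <- data.frame(center = qc, x = cent[, 1], y = cent[, 2],
                     z = cent[, 3], disp_norm = dn)
  if (moved && !is.null(basis_e)) {
    integrals <- build_integrals(system, basis_e, basis_p)
  }
  list(system = system, integrals = integrals,
       max_disp = max(dn), moved = moved, centroids = cent, rows = rows)
}

#' Adaptive NEO calculation
#'
#' Runs the stepwise multicomponent SCF with the centroid update applied
#' after each converged nuclear subcycle.  Convergence requires the energy,
#' density and gradient criteria of [scf_settings()] *and* a largest centroid
#' displacement below the position threshold.  The returned state carries the
#' final (standard-NEO-surface) energy, the updated system, and the adaptive
#' trace (`$trace`): one row per macrocycle and quantum center with the
#' centroid position, displacement norm and energy components.
#'
#' @param system a `neo_system` with at least one quantum center.
#' @param basis_e,basis_p attached [basis_set()] objects.
#' @param settings a [scf_settings()].
#' @param adaptive an [adaptive_settings()].
#' @param init optional warm-start densities.
#' @return a `neo_scf_state`; `$system` holds the converged quantum-center
#'   positions, `$trace` the adaptive trajectory.
#' @export
run_adaptive_neo <- function(system, basis_e, basis_p,
                             settings = scf_settings(),
                             adaptive = adaptive_settings(),
                             init = NULL) {
  if (n_quantum(system) == 0) {
    stop("adaptive NEO requires at least one quantum center")
  }
  neo_engine(system, basis_e, basis_p, settings, adaptive = adaptive,
             init = init)
}

#' Write an adaptive trace as CSV
#'
#' @param state a converged `neo_scf_state` from [run_adaptive_neo()].
#' @param path output CSV path.
#' @export
write_trace_csv <- function(state, path) {
  if (is.null(state$trace)) stop("state carries no adaptive trace")
  utils::write.csv(state$trace, path, row.names = FALSE)
  invisible(path)
}
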