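# Numerical-gradient optimization of quantum-center positions on the
# extended NEO surface.  This is the validation oracle for the adaptive
# centroid procedure: both must land on the same standard-NEO-surface
# minimum.  Gradients are central finite differences of fully converged
# NEO-SCF energies; displaced points are warm-started from the reference
# densities.

# Tight settings used inside gradient evaluations so finite-difference noise
# stays well below the differencing step.
tight_settings <- function() {
  scf_settings(e_conv = 1e-10, d_conv = 1e-10, g_conv = 1e-8,
               neo_e_conv = 1e-9)
}

# Extended-NEO energy at given quantum-center coordinates (flattened vector,
# Bohr), with optional warm-start densities.
extended_neo_energy <- function(rq, system, basis_e, basis_p, settings,
                                init = NULL) {
  qc <- which(system$is_quantum)
  pos <- matrix(rq, ncol = 3)
  for (k in seq_along(qc)) system$positions[qc[k], ] <- pos[k, ]
  st <- run_neo_scf(system, basis_e, basis_p, settings, init = init)
  st
}

#' Numerical gradient of the extended NEO energy over quantum centers
#'
#' Central differences `(E(r+h) - E(r-h)) / (2h)` per Cartesian component of
#' every quantum center, each displaced energy from a fully converged
#' NEO-SCF at tightened thresholds.
#'
#' @param system a `neo_system` (current quantum-center positions are the
#'   expansion point).
#' @param basis_e,basis_p attached bases.
#' @param step finite-difference step, Bohr (default 1e-3).
#' @param settings SCF settings; defaults to tightened thresholds.
#' @param energy_fn optional replacement energy callback `function(rq_vec)`
#'   (used to validate the differencing itself); when supplied no SCF runs.
#' @param init optional warm-start densities applied to every displaced point.
#' @return gradient vector, hartree/Bohr, ordered (x1, y1, z1, x2, ...).
#' @export
numerical_gradient <- function(system, basis_e, basis_p, step = 1e-3,
                               settings = tight_settings(),
                               energy_fn = NULL, init = NULL) {
  stopifnot(step > 0)
  qc <- which(system$is_quantum)
  if (!length(qc)) stop("no quantum centers to differentiate")
  r0 <- as.vector(system$positions[qc, , drop = FALSE])
  if (is.null(energy_fn)) {
    energy_fn <- function(rq) {
      st <- tryCatch(
        extended_neo_energy(rq, system, basis_e, basis_p, settings, init),
        neo_nonconvergence = function(e) {
          stop("SCF failed to converge at displaced point (",
               paste(signif(rq, 8), collapse = ", "), "): ",
               conditionMessage(e))
        })
      st$energy_components$E_total
    }
  }
  g <- numeric(length(r0))
  for (i in seq_along(r0)) {
    rp <- r0; rp[i] <- rp[i] + step
    rm <- r0; rm[i] <- rm[i] - step
    g[i] <- (energy_fn(rp) - energy_fn(rm)) / (2 * step)
  }
  g
}

#' Optimize quantum-center positions with numerical gradients
#'
#' Quasi-Newton (BFGS) minimization of the extended NEO energy over the
#' quantum-center coordinates, classical centers frozen.  Convergence is
#' declared when the gradient norm falls below `grad_tol` and the last
#' position update below `step_tol`.
#'
#' @param system starting `neo_system`.
#' @param basis_e,basis_p attached bases.
#' @param settings SCF settings (tightened defaults).
#' @param grad_tol gradient-norm threshold, hartree/Bohr.
#' @param step_tol step-norm threshold, Bohr.
#' @param fd_step finite-difference step, Bohr.
#' @param max_eval cap on energy evaluations.
#' @return list `optimal_rq` (n_quantum x 3 matrix, Bohr), `E_min` (hartree),
#'   `n_energy_evaluations`, `converged`, `grad_norm`, `n_iterations`.
#' @export
optimize_rq <- function(system, basis_e, basis_p,
                        settings = tight_settings(),
                        grad_tol = 1e-5, step_tol = 1e-4, fd_step = 1e-3,
                        max_eval = 500) {
  qc <- which(system$is_quantum)
  if (!length(qc)) stop("no quantum centers to optimize")
  r0 <- as.vector(system$positions[qc, , drop = FALSE])
  n_eval <- 0L
  warm <- new.env(parent = emptyenv())
  efun <- function(rq) {
    n_eval <<- n_eval + 1L
    init <- if (!is.null(warm$de)) list(density_e = warm$de,
                                        density_p = warm$dp) else NULL
    st <- extended_neo_energy(rq, system, basis_e, basis_p, settings, init)
    warm$de <- st$density_e; warm$dp <- st$density_p
    st$energy_components$E_total
  }
  n_grad <- 0L
  gfun <- function(rq) {
    sys_at <- system
    pos <- matrix(rq, ncol = 3)
    for (k in seq_along(qc)) sys_at$positions[qc[k], ] <- pos[k, ]
    init <- if (!is.null(warm$de)) list(density_e = warm$de,
                                        density_p = warm$dp) else NULL
    n_eval <<- n_eval + 2L * length(rq)
    n_grad <<- n_grad + 1L
    numerical_gradient(sys_at, basis_e, basis_p, step = fd_step,
                       settings = settings, init = init)
  }
  r <- r0
  converged <- FALSE
  gnorm <- Inf
  iters <- 0L
  for (round in 1:5) {
    res <- stats::optim(r, efun, gfun, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 100))
    step_len <- sqrt(sum((res$par - r)^2))
    r <- res$par
    iters <- iters + res$counts[["function"]]
    gnorm <- sqrt(sum(gfun(r)^2))
    if (gnorm < grad_tol && step_len < step_tol) {
      converged <- TRUE
      break
    }
    if (n_eval > max_eval) break
  }
  list(optimal_rq = matrix(r, ncol = 3), E_min = efun(r),
       n_energy_evaluations = n_eval + 1L,
       n_gradient_evaluations = n_grad, converged = converged,
       grad_norm = gnorm, n_iterations = iters)
}

#' One-dimensional scan of the extended NEO surface
#'
#' Displaces one quantum center along a fixed axis and converges a full
#' NEO-SCF at every grid point (the extended NEO curve).  Optionally the
#' conventional restricted-HF curve is computed alongside, with the scanned
#' atom treated as a classical point-charge nucleus at the same grid point.
#' A per-point SCF failure is recorded as NA and the scan continues.
#'
#' @param system a `neo_system`.
#' @param basis_e electronic basis (a classical-variant basis is rebuilt
#'   internally for the RHF curve).
#' @param basis_p protonic basis.
#' @param center_index index of the scanned quantum center.
#' @param axis direction (length-3, normalized internally).
#' @param grid strictly increasing displacements along the axis, Angstrom,
#'   relative to the center's current position; must lie within +-1 A.
#' @param rhf also compute the conventional-HF curve (default TRUE).
#' @param settings SCF settings.
#' @param basis_e_source basis name/path used to rebuild the electronic basis
#'   for the classical-proton RHF curve (default "sto-3g").
#' @return a `neo_pes_scan`: data frame with `displacement` (Angstrom),
#'   `E_neo`, `E_rhf` (hartree), `centroid` (projection of the nuclear
#'   charge centroid on the axis, Angstrom, same origin as the grid).
#' @export
scan_1d <- function(system, basis_e, basis_p, center_index, axis, grid,
                    rhf = TRUE, settings = scf_settings(),
                    basis_e_source = "sto-3g") {
  axis <- as.numeric(axis); axis <- axis / sqrt(sum(axis^2))
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid displacements must be strictly increasing")
  }
  if (any(abs(grid) > 1)) stop("grid outside the +-1 Angstrom sanity window")
  if (!system$is_quantum[center_index]) {
    stop("center ", center_index, " is not a quantum center")
  }
  base <- system$positions[center_index, ]
  qc <- which(system$is_quantum)
  E_neo <- E_rhf <- centroid <- rep(NA_real_, length(grid))
  warm <- NULL
  for (i in seq_along(grid)) {
    sys_i <- system
    sys_i$positions[center_index, ] <- base + grid[i] * ANGSTROM_TO_BOHR * axis
    st <- tryCatch(run_neo_scf(sys_i, basis_e, basis_p, settings,
                               init = warm),
                   neo_nonconvergence = function(e) NULL)
    if (!is.null(st)) {
      E_neo[i] <- st$energy_components$E_total
      warm <- list(density_e = st$density_e, density_p = st$density_p)
      a <- assign_orbitals(st, basis_p, st$integrals$p$S, qc)
      cen <- compute_centroids(st, list(X = st$integrals$p$X,
                                        Y = st$integrals$p$Y,
                                        Z = st$integrals$p$Z), a)
      k <- match(center_index, qc)
      centroid[i] <- sum((cen[k, ] - base) * axis) * BOHR_TO_ANGSTROM
    }
  }
  if (rhf) {
    cls <- system
    cls$is_quantum[center_index] <- FALSE
    basis_e_cls <- load_basis(basis_e_source, "electron", cls)
    basis_p_cls <- if (n_quantum(cls) > 0) {
      keep <- Filter(function(s) s$center != center_index, basis_p$shells)
      basis_set("proton", keep, cls)
    } else NULL
    for (i in seq_along(grid)) {
      sys_i <- cls
      sys_i$positions[center_index, ] <-
        base + grid[i] * ANGSTROM_TO_BOHR * axis
      st <- tryCatch(run_neo_scf(sys_i, basis_e_cls, basis_p_cls, settings),
                     neo_nonconvergence = function(e) NULL)
      if (!is.null(st)) E_rhf[i] <- st$energy_components$E_total
    }
  }
  out <- data.frame(displacement = grid, E_neo = E_neo, E_rhf = E_rhf,
                    centroid = centroid)
  attr(out, "axis") <- axis
  attr(out, "center_index") <- center_index
  class(out) <- c("neo_pes_scan", class(out))
  out
}

#' Write a scan as CSV
#' @param scan a `neo_pes_scan`.
#' @param path output path.
#' @export
write_scan_csv <- function(scan, path) {
  utils::write.csv(as.data.frame(scan), path, row.names = FALSE)
  invisible(path)
}
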