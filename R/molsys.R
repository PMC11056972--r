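#' @useDynLib neoadapt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Conversion factors and constants used throughout the package (atomic units
# internally; file I/O in Angstrom).
ANGSTROM_TO_BOHR <- 1.8897259886
BOHR_TO_ANGSTROM <- 1 / ANGSTROM_TO_BOHR
PROTON_MASS_AMU <- 1836.15267343  # CODATA, electron-mass units
HARTREE_TO_KCAL <- 627.509474

ELEMENT_Z <- c(
  H = 1L, He = 2L, Li = 3L, Be = 4L, B = 5L, C = 6L, N = 7L, O = 8L,
  F = 9L, Ne = 10L, Na = 11L, Mg = 12L, Al = 13L, Si = 14L, P = 15L,
  S = 16L, Cl = 17L, Ar = 18L
)

#' Construct a molecular system with a classical/quantum center partition
#'
#' A molecular system holds an ordered set of atomic centers.  Each center is
#' either a classical nucleus (a point charge in the Hamiltonian) or a quantum
#' center: a placeholder coordinate carrying basis functions for a quantum
#' proton (and that atom's electronic functions).  A quantum center is *not* a
#' point charge; the proton's charge enters through its one-particle density.
#'
#' @param elements character vector of element symbols.
#' @param positions numeric 3-column matrix of positions, Bohr.
#' @param quantum integer vector of 1-based indices of quantum atoms (must be
#'   hydrogens), or a logical vector over atoms.
#' @param total_charge integer total molecular charge (e).
#' @return an object of class `neo_system` with fields `elements`, `positions`
#'   (n x 3, Bohr), `charges`, `is_quantum`, `total_charge`.
#' @export
molecular_system <- function(elements, positions, quantum = integer(),
                             total_charge = 0L) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  n <- length(elements)
  stopifnot(nrow(positions) == n)
  if (!all(is.finite(positions))) {
    stop("non-finite atomic position")
  }
  unknown <- setdiff(elements, names(ELEMENT_Z))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  charges <- unname(ELEMENT_Z[elements])
  if (is.logical(quantum)) quantum <- which(quantum)
  quantum <- as.integer(quantum)
  if (length(quantum) && (min(quantum) < 1L || max(quantum) > n)) {
    stop("quantum atom index out of range 1..", n)
  }
  if (any(charges[quantum] != 1L)) {
    stop("quantum centers must be hydrogen atoms (indices: ",
         paste(quantum[charges[quantum] != 1L], collapse = ", "), ")")
  }
  is_quantum <- rep(FALSE, n)
  is_quantum[quantum] <- TRUE
  sys <- structure(
    list(elements = elements, positions = positions, charges = charges,
         is_quantum = is_quantum, total_charge = as.integer(total_charge)),
    class = "neo_system")
  ne <- n_electrons(sys)
  if (ne < 0 || (ne != 1L && ne %% 2L != 0L)) {
    stop("electron count ", ne, " is not supported: the electronic problem ",
         "is restricted closed-shell (even count) or a single electron")
  }
  sys
}

#' Number of electrons of a system
#'
#' All nuclear charges (classical and quantum) count toward the molecular
#' formula; flagging an atom as quantum does not change the electron count.
#' @param system a `neo_system`.
#' @return integer electron count.
#' @export
n_electrons <- function(system) {
  as.integer(sum(system$charges) - system$total_charge)
}

#' Number of quantum centers
#' @param system a `neo_system`.
#' @export
n_quantum <- function(system) as.integer(sum(system$is_quantum))

# Positions and charges of the classical point-charge list only.  Quantum
# centers are excluded: they are represented by the protonic density.
classical_charges <- function(system) {
  keep <- !system$is_quantum
  list(positions = system$positions[keep, , drop = FALSE],
       charges = as.numeric(system$charges[keep]))
}

#' @export
print.neo_system <- function(x, ...) {
  cat(sprintf("<neo_system: %d atoms, %d quantum, charge %+d, %d electrons>\n",
              length(x$elements), n_quantum(x), x$total_charge,
              n_electrons(x)))
  ang <- x$positions * BOHR_TO_ANGSTROM
  for (i in seq_along(x$elements)) {
    cat(sprintf("  %-2s %12.6f %12.6f %12.6f %s\n", x$elements[i],
                ang[i, 1], ang[i, 2], ang[i, 3],
                if (x$is_quantum[i]) "[quantum]" else ""))
  }
  invisible(x)
}

#' Read a molecular system from an XYZ file
#'
#' Standard XYZ layout: atom count, comment line, then one `element x y z`
#' row per atom in Angstrom.  Positions are converted to Bohr internally.
#'
#' @param path path to an XYZ file.
#' @param quantum 1-based indices of atoms to treat as quantum protons; all
#'   must be hydrogen.
#' @param total_charge integer total charge.
#' @return a [molecular_system()].
#' @export
read_xyz <- function(path, quantum = integer(), total_charge = 0L) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("malformed XYZ (line 1): file too short")
  nat <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(nat)) stop("malformed XYZ (line 1): atom count expected")
  if (length(lines) < nat + 2) {
    stop("malformed XYZ (line ", length(lines) + 1, "): expected ", nat,
         " atom lines")
  }
  elements <- character(nat)
  pos <- matrix(NA_real_, nat, 3)
  for (i in seq_len(nat)) {
    ln <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4) stop("malformed XYZ (line ", ln, "): ", lines[ln])
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(xyz))) stop("malformed XYZ (line ", ln, "): bad coordinate")
    elements[i] <- tok[1]
    pos[i, ] <- xyz
  }
  molecular_system(elements, pos * ANGSTROM_TO_BOHR, quantum = quantum,
                   total_charge = total_charge)
}

#' Write a system to an XYZ file (Angstrom)
#'
#' @param system a `neo_system`.
#' @param path output path.
#' @param comment comment line content.
#' @export
write_xyz <- function(system, path, comment = "") {
  ang <- system$positions * BOHR_TO_ANGSTROM
  lines <- c(as.character(length(system$elements)), comment,
             sprintf("%-2s %16.10f %16.10f %16.10f", system$elements,
                     ang[, 1], ang[, 2], ang[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Rigidly transform a system
#'
#' Maps every center position r to `rotation %*% r + translation`.  Quantum
#' flags, charges and the total charge are preserved, so the electron count is
#' invariant.
#'
#' @param system a `neo_system`.
#' @param rotation 3x3 orthogonal matrix (checked to 1e-10).
#' @param translation length-3 numeric vector, Bohr.
#' @return the transformed `neo_system`.
#' @export
transform_system <- function(system, rotation = diag(3),
                             translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-10) {
    stop("rotation matrix is not orthogonal within 1e-10")
  }
  system$positions <- t(rotation %*% t(system$positions) +
                          as.numeric(translation))
  system
}

# Replace the position of one center (used by the adaptive update).
set_center_position <- function(system, index, position) {
  system$positions[index, ] <- as.numeric(position)
  system
}
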