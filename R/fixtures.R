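# Built-in fixtures: small systems with known symmetry points and bounds,
# runnable end-to-end with the bundled bases.  Geometries are constructed in
# Bohr.

FIXTURE_REGISTRY <- c("h_atom", "h2_1q", "hehhe_cation", "hbond_toy")

#' Construct a bundled fixture
#'
#' Available fixtures:
#' \describe{
#'   \item{h_atom}{One quantum hydrogen at the origin: one electron, one
#'     quantum proton, no classical nuclei.  The exact nonrelativistic
#'     ground-state energy with a clamped center of mass is `-mu/2` with
#'     `mu = m_p/(m_p + 1)`, a strict lower bound for the mean-field energy.}
#'   \item{h2_1q}{H2 with one classical H at the origin and one quantum H at
#'     1.4 Bohr on z (the standard equilibrium separation).}
#'   \item{hehhe_cation}{Linear [He-H-He]+ with helium atoms at +-2.0 Bohr on
#'     z and the quantum proton at the origin: the midpoint is a symmetry
#'     fixed point of the adaptive update.}
#'   \item{hbond_toy}{A linear donor-H-acceptor toy: a stretched low-barrier
#'     hydrogen bond [He-H-He]+ (helium atoms at 0 and 3.85 Bohr) weakly
#'     asymmetrized by a third helium at 11.05 Bohr, with the quantum proton
#'     starting at 1.80 Bohr, displaced from its single-well minimum near
#'     1.93 Bohr.  The classical-proton (RHF) curve is double-well with an
#'     off-center minimum, so the quantum treatment shifts the minimum
#'     visibly; used for minimum-shift and oracle-equivalence tests with the
#'     polarized bundled bases (neo-svp electrons, pb-et-d protons).}
#' }
#'
#' @param name fixture name.
#' @return list with `name`, `system` (a `neo_system`), recommended
#'   `basis_e` and `basis_p` source names, and `notes`.
#' @export
make_fixture <- function(name) {
  if (!name %in% FIXTURE_REGISTRY) {
    stop("unknown fixture '", name, "'; available: ",
         paste(FIXTURE_REGISTRY, collapse = ", "))
  }
  switch(name,
    h_atom = list(
      name = "h_atom",
      system = molecular_system("H", matrix(c(0, 0, 0), 1), quantum = 1L),
      basis_e = "et-12s-0.01-2.5",
      basis_p = "pb-et",
      notes = "fully quantum one-proton system; E_total > -0.49972784 Eh"),
    h2_1q = list(
      name = "h2_1q",
      system = molecular_system(c("H", "H"),
                                rbind(c(0, 0, 0), c(0, 0, 1.4)),
                                quantum = 2L),
      basis_e = "sto-3g",
      basis_p = "pb-et",
      notes = "H2 with one quantum proton at the standard 1.4 Bohr"),
    hehhe_cation = list(
      name = "hehhe_cation",
      system = molecular_system(c("He", "H", "He"),
                                rbind(c(0, 0, -2), c(0, 0, 0), c(0, 0, 2)),
                                quantum = 2L, total_charge = 1L),
      basis_e = "sto-3g",
      basis_p = "pb-et",
      notes = "symmetric proton well; midpoint is the adaptive fixed point"),
    hbond_toy = list(
      name = "hbond_toy",
      system = molecular_system(c("He", "H", "He", "He"),
                                rbind(c(0, 0, 0), c(0, 0, 1.80),
                                      c(0, 0, 3.85), c(0, 0, 11.05)),
                                quantum = 2L, total_charge = 1L),
      basis_e = "neo-svp",
      basis_p = "pb-et-d",
      notes = "asymmetric single-well donor-H-acceptor toy")
  )
}

#' Fixture with attached bases
#'
#' Convenience wrapper returning the system together with instantiated
#' electronic and protonic basis sets.
#' @param name fixture name (see [make_fixture()]).
#' @return list `system`, `basis_e`, `basis_p`, `name`, `notes`.
#' @export
fixture_calculation <- function(name) {
  fx <- make_fixture(name)
  basis_e <- load_basis(fx$basis_e, "electron", fx$system)
  basis_p <- if (n_quantum(fx$system) > 0) {
    load_basis(fx$basis_p, "proton", fx$system)
  } else NULL
  list(name = fx$name, system = fx$system, basis_e = basis_e,
       basis_p = basis_p, notes = fx$notes)
}
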