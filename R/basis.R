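# Contracted Gaussian basis sets for electrons and quantum protons, attached
# to movable centers.  Functions are solid-harmonic (spherical) for l >= 2.
# Contraction coefficients are stored as published (assuming normalized
# primitives); absolute normalization of every contracted function is fixed
# when integrals are assembled, by scaling to unit self-overlap.

SHELL_LETTERS <- c(S = 0L, P = 1L, D = 2L, F = 3L, G = 4L, H = 5L)

#' Construct a Gaussian shell
#'
#' @param center 1-based index of the atomic center carrying the shell.
#' @param l angular momentum (0 = s, 1 = p, ...).
#' @param exponents positive primitive exponents, Bohr^-2.
#' @param coefs contraction coefficients (same length), in the usual
#'   normalized-primitive convention.
#' @return a `neo_shell` list.
#' @export
gaussian_shell <- function(center, l, exponents, coefs) {
  exponents <- as.numeric(exponents)
  coefs <- as.numeric(coefs)
  if (length(exponents) != length(coefs)) {
    stop("exponent and coefficient lists differ in length")
  }
  if (any(exponents <= 0)) stop("primitive exponents must be positive")
  o <- order(exponents, decreasing = TRUE)
  structure(list(center = as.integer(center), l = as.integer(l),
                 exponents = exponents[o], coefs = coefs[o]),
            class = "neo_shell")
}

#' Construct a basis set for one particle species
#'
#' @param species `"electron"` or `"proton"`.
#' @param shells list of [gaussian_shell()] objects.
#' @param system the `neo_system` the shells attach to (validates center
#'   references; proton shells may sit only on quantum centers).
#' @return a `neo_basis` object with fields `species`, `shells`, `mass`
#'   (particle mass in electron-mass units), `charge` (signed, e).
#' @export
basis_set <- function(species = c("electron", "proton"), shells, system) {
  species <- match.arg(species)
  nctr <- length(system$elements)
  for (sh in shells) {
    if (sh$center < 1L || sh$center > nctr) {
      stop("shell references center ", sh$center, " outside 1..", nctr)
    }
    if (species == "proton" && !system$is_quantum[sh$center]) {
      stop("proton shells may attach only to quantum centers (center ",
           sh$center, " is classical)")
    }
  }
  structure(list(
    species = species,
    shells = shells,
    mass = if (species == "electron") 1 else PROTON_MASS_AMU,
    charge = if (species == "electron") -1 else +1
  ), class = "neo_basis")
}

#' Number of (spherical) basis functions
#' @param basis a `neo_basis`.
#' @export
basis_dim <- function(basis) {
  sum(vapply(basis$shells, function(s) 2L * s$l + 1L, integer(1)))
}

#' @export
print.neo_basis <- function(x, ...) {
  cat(sprintf("<neo_basis: %s, %d shells, %d functions, mass %.6f m_e>\n",
              x$species, length(x$shells), basis_dim(x), x$mass))
  invisible(x)
}

#' Even-tempered shell generator
#'
#' Produces uncontracted shells with exponents `alpha0 * beta^k`,
#' `k = 0..n_per_l-1`, replicated for every angular momentum `0..l_max`.
#'
#' @param center_index center the shells attach to.
#' @param l_max highest angular momentum.
#' @param n_per_l exponents per angular momentum.
#' @param alpha0 smallest exponent (> 0), Bohr^-2.
#' @param beta geometric ratio (> 1).
#' @return list of [gaussian_shell()], one per (l, exponent).
#' @export
even_tempered <- function(center_index, l_max, n_per_l, alpha0, beta) {
  if (alpha0 <= 0) stop("alpha0 must be positive")
  if (beta <= 1) stop("even-tempered ratio beta must exceed 1")
  if (n_per_l < 1) stop("n_per_l must be at least 1")
  exps <- alpha0 * beta^(seq_len(n_per_l) - 1)
  shells <- list()
  for (l in 0:l_max) {
    for (e in exps) {
      shells[[length(shells) + 1L]] <- gaussian_shell(center_index, l, e, 1)
    }
  }
  shells
}

# Bundled even-tempered protonic fallbacks spanning exponents 2..64:
# "pb-et" is 8s8p, "pb-et-d" 6s6p6d.  (The published protonic sets
# PB4-D/PB4-F2/PB5-G are loadable from user-supplied files; these generated
# sets keep the package self-contained.)
PROTON_ET_SETS <- list(
  `pb-et` = list(n = 8L, l_max = 1L),
  `pb-et-d` = list(n = 6L, l_max = 2L)
)
PROTON_ET_ALPHA0 <- 2
PROTON_ET_ALPHAMAX <- 64

#' Load a basis set and attach it to a system
#'
#' `source` may be: a path to a basis file in the common repository block
#' format (element header, shell letter with primitive count, rows of
#' exponent/coefficient pairs, `****` terminator) or in a JSON dialect with
#' the same content; the name of a bundled set (`"sto-3g"`, or the
#' package-defined polarized `"neo-svp"` for H/He); or for protons a
#' generated even-tempered fallback, `"pb-et"` (8s8p) or `"pb-et-d"`
#' (6s6p6d), both with exponents spanning 2 to 64.
#' An even-tempered electronic set can be requested with a name of the form
#' `"et-<n>s<...>-<alpha0>-<beta>"`, e.g. `"et-10s-0.02-3"`.
#'
#' Electronic shells are instantiated on every center, including quantum
#' centers (their electronic functions move with the center).  Protonic
#' shells are instantiated only on quantum centers.
#'
#' @param source basis name or file path.
#' @param species `"electron"` or `"proton"`.
#' @param system a `neo_system`.
#' @return a [basis_set()].
#' @export
load_basis <- function(source, species = c("electron", "proton"), system) {
  species <- match.arg(species)
  if (species == "proton") {
    idx <- which(system$is_quantum)
    if (!length(idx)) {
      warning("proton basis requested but the system has no quantum centers;",
              " returning an empty basis")
      return(basis_set("proton", list(), system))
    }
    if (tolower(source) %in% names(PROTON_ET_SETS)) {
      spec <- PROTON_ET_SETS[[tolower(source)]]
      beta <- (PROTON_ET_ALPHAMAX / PROTON_ET_ALPHA0)^(1 / (spec$n - 1))
      shells <- unlist(lapply(idx, function(i) {
        even_tempered(i, l_max = spec$l_max, n_per_l = spec$n,
                      alpha0 = PROTON_ET_ALPHA0, beta = beta)
      }), recursive = FALSE)
      return(basis_set("proton", shells, system))
    }
    tmpl <- read_basis_source(source)
    shells <- instantiate_shells(tmpl, system, idx)
    return(basis_set("proton", shells, system))
  }
  et <- parse_even_tempered_name(source)
  if (!is.null(et)) {
    shells <- unlist(lapply(seq_along(system$elements), function(i) {
      even_tempered(i, l_max = et$l_max, n_per_l = et$n,
                    alpha0 = et$alpha0, beta = et$beta)
    }), recursive = FALSE)
    return(basis_set("electron", shells, system))
  }
  tmpl <- read_basis_source(source)
  shells <- instantiate_shells(tmpl, system, seq_along(system$elements))
  basis_set("electron", shells, system)
}

parse_even_tempered_name <- function(source) {
  m <- regmatches(source,
                  regexec("^et-(\\d+)([spdfg])-([0-9.eE+-]+)-([0-9.eE+-]+)$",
                          source))[[1]]
  if (!length(m)) return(NULL)
  list(n = as.integer(m[2]),
       l_max = unname(SHELL_LETTERS[toupper(m[3])]),
       alpha0 = as.numeric(m[4]), beta = as.numeric(m[5]))
}

# Resolve a basis source to per-element shell templates:
# list(H = list(list(l=, exponents=, coefs=), ...), ...)
read_basis_source <- function(source) {
  path <- source
  if (!file.exists(path)) {
    bundled <- system.file("extdata", paste0(tolower(source), ".txt"),
                           package = "neoadapt")
    if (nzchar(bundled)) path <- bundled
  }
  if (!file.exists(path)) {
    stop("basis source not found: ", source)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    parse_basis_json(path)
  } else {
    parse_basis_text(path)
  }
}

instantiate_shells <- function(templates, system, center_indices) {
  shells <- list()
  for (i in center_indices) {
    el <- system$elements[i]
    if (is.null(templates[[el]])) {
      stop("element ", el, " missing from basis source")
    }
    for (t in templates[[el]]) {
      shells[[length(shells) + 1L]] <-
        gaussian_shell(i, t$l, t$exponents, t$coefs)
    }
  }
  shells
}

# Block text format: per element, a header line "<Symbol> 0", shell blocks
# "<LETTER> <nprim> <scale>", nprim rows of exponent + coefficient(s)
# ("SP" rows carry s and p coefficients), blocks closed by "****".
parse_basis_text <- function(path) {
  lines <- readLines(path)
  lines <- sub("!.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  templates <- list()
  i <- 1L
  nl <- length(lines)
  num <- function(x) as.numeric(gsub("[dD]", "e", x))
  while (i <= nl) {
    head <- strsplit(lines[i], "\\s+")[[1]]
    el <- head[1]
    if (!el %in% names(ELEMENT_Z)) {
      stop("basis parse error at line '", lines[i],
           "': element header expected")
    }
    i <- i + 1L
    shells <- list()
    while (i <= nl && lines[i] != "****") {
      hdr <- strsplit(lines[i], "\\s+")[[1]]
      letter <- toupper(hdr[1])
      nprim <- suppressWarnings(as.integer(hdr[2]))
      if (is.na(nprim) ||
          !(letter %in% c(names(SHELL_LETTERS), "SP"))) {
        stop("basis parse error at line '", lines[i],
             "': shell header expected")
      }
      rows <- lines[i + seq_len(nprim)]
      vals <- lapply(strsplit(rows, "\\s+"), num)
      if (any(vapply(vals, function(v) any(is.na(v)), logical(1)))) {
        stop("basis parse error in primitive rows after '", lines[i], "'")
      }
      exps <- vapply(vals, `[`, numeric(1), 1)
      if (letter == "SP") {
        cs <- vapply(vals, `[`, numeric(1), 2)
        cp <- vapply(vals, `[`, numeric(1), 3)
        shells <- c(shells, list(list(l = 0L, exponents = exps, coefs = cs),
                                 list(l = 1L, exponents = exps, coefs = cp)))
      } else {
        cf <- vapply(vals, `[`, numeric(1), 2)
        shells <- c(shells,
                    list(list(l = SHELL_LETTERS[[letter]],
                              exponents = exps, coefs = cf)))
      }
      i <- i + nprim + 1L
    }
    if (i > nl) stop("basis parse error: missing **** terminator for ", el)
    templates[[el]] <- shells
    i <- i + 1L
  }
  templates
}

# JSON dialect mirroring the block format:
# {"elements": {"H": [{"shell": "S", "exponents": [...],
#                      "coefficients": [...]}, ...]}}
parse_basis_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$elements)) stop("basis JSON lacks an 'elements' object")
  templates <- list()
  for (el in names(obj$elements)) {
    shells <- lapply(obj$elements[[el]], function(s) {
      l <- if (!is.null(s$l)) as.integer(s$l) else SHELL_LETTERS[[toupper(s$shell)]]
      list(l = l, exponents = as.numeric(unlist(s$exponents)),
           coefs = as.numeric(unlist(s$coefficients)))
    })
    templates[[el]] <- shells
  }
  templates
}

# --------------------------------------------------------------------------
# Real solid harmonics: homogeneous polynomial coefficient rows over the
# Cartesian monomials of the same degree, generated by recurrence.  Overall
# scale per row is irrelevant (functions are renormalized against their
# self-overlap); relative coefficients are exact rationals from the
# recurrences.

cart_components <- function(l) {
  out <- list()
  for (lx in l:0) for (ly in (l - lx):0) {
    out[[length(out) + 1L]] <- c(lx, ly, l - lx - ly)
  }
  out
}

n_cart <- function(l) ((l + 1L) * (l + 2L)) %/% 2L

# polynomial = named numeric vector, names "lx.ly.lz"
mono_name <- function(m) paste(m, collapse = ".")
poly_shift <- function(p, dx, dy, dz) {
  if (!length(p)) return(p)
  parts <- do.call(rbind, lapply(strsplit(names(p), "\\."), as.integer))
  parts <- sweep(parts, 2, c(dx, dy, dz), "+")
  stats::setNames(as.numeric(p), apply(parts, 1, paste, collapse = "."))
}
poly_add <- function(...) {
  ps <- list(...)
  all <- unlist(ps)
  if (!length(all)) return(numeric())
  tapply(as.numeric(all), names(all), sum)
}
poly_scale <- function(p, s) stats::setNames(as.numeric(p) * s, names(p))
poly_r2 <- function(p) {
  poly_add(poly_shift(p, 2, 0, 0), poly_shift(p, 0, 2, 0),
           poly_shift(p, 0, 0, 2))
}

solid_harmonics_upto <- function(lmax) {
  Rc <- list(list(stats::setNames(1, "0.0.0")))   # Rc[[l+1]][[m+1]]
  Rs <- list(list(numeric()))
  for (l in seq_len(lmax)) {
    Rc_l <- vector("list", l + 1)
    Rs_l <- vector("list", l + 1)
    for (m in 0:(l - 1)) {
      upper <- poly_shift(poly_add(Rc[[l]][[m + 1]]), 0, 0, 1)
      term <- poly_scale(upper, 2 * l - 1)
      if (l >= 2 && m <= l - 2) {
        term <- poly_add(term, poly_scale(poly_r2(Rc[[l - 1]][[m + 1]]),
                                          -(l - 1 + m)))
      }
      Rc_l[[m + 1]] <- poly_scale(term, 1 / (l - m))
      upper_s <- if (length(Rs[[l]][[m + 1]])) {
        poly_shift(Rs[[l]][[m + 1]], 0, 0, 1)
      } else numeric()
      term_s <- poly_scale(upper_s, 2 * l - 1)
      if (l >= 2 && m <= l - 2 && length(Rs[[l - 1]][[m + 1]])) {
        term_s <- poly_add(term_s, poly_scale(poly_r2(Rs[[l - 1]][[m + 1]]),
                                              -(l - 1 + m)))
      }
      Rs_l[[m + 1]] <- if (length(term_s)) poly_scale(term_s, 1 / (l - m)) else numeric()
    }
    prevC <- Rc[[l]][[l]]
    prevS <- Rs[[l]][[l]]
    xC <- poly_shift(prevC, 1, 0, 0)
    yS <- if (length(prevS)) poly_shift(prevS, 0, 1, 0) else numeric()
    Rc_l[[l + 1]] <- poly_add(xC, poly_scale(yS, -1))
    xS <- if (length(prevS)) poly_shift(prevS, 1, 0, 0) else numeric()
    yC <- poly_shift(prevC, 0, 1, 0)
    Rs_l[[l + 1]] <- poly_add(xS, yC)
    Rc[[l + 1]] <- Rc_l
    Rs[[l + 1]] <- Rs_l
  }
  list(Rc = Rc, Rs = Rs)
}

.sph_cache <- new.env(parent = emptyenv())

#' Cartesian-to-spherical transformation rows for one shell
#'
#' Returns the `(2l+1) x ncart(l)` matrix of real solid-harmonic expansion
#' coefficients over the Cartesian monomials `x^i y^j z^k`, `i+j+k = l`.
#' Row order: for p shells `x, y, z`; for `l >= 2` the order is
#' `m = 0, +1, -1, +2, -2, ...` (cosine before sine).  Rows are not
#' normalized; normalization is applied downstream against self-overlaps.
#' @param l angular momentum.
#' @export
sph_transform <- function(l) {
  key <- as.character(l)
  if (!is.null(.sph_cache[[key]])) return(.sph_cache[[key]])
  if (l == 0L) return(matrix(1, 1, 1))
  if (l == 1L) return(diag(3))  # Cartesian order x, y, z
  sh <- solid_harmonics_upto(l)
  comp <- cart_components(l)
  keys <- vapply(comp, mono_name, character(1))
  rows <- list(sh$Rc[[l + 1]][[1]])
  for (m in seq_len(l)) {
    rows <- c(rows, list(sh$Rc[[l + 1]][[m + 1]], sh$Rs[[l + 1]][[m + 1]]))
  }
  M <- matrix(0, 2 * l + 1, length(keys))
  for (r in seq_along(rows)) {
    p <- rows[[r]]
    idx <- match(names(p), keys)
    if (any(is.na(idx))) stop("internal: solid harmonic monomial mismatch")
    M[r, idx] <- as.numeric(p)
  }
  .sph_cache[[key]] <- M
  M
}

# Block-diagonal Cartesian -> spherical transform for a whole basis.
basis_sph_transform <- function(basis) {
  ncart_tot <- sum(vapply(basis$shells, function(s) n_cart(s$l), integer(1)))
  nsph_tot <- basis_dim(basis)
  M <- matrix(0, nsph_tot, ncart_tot)
  ro <- 0L; co <- 0L
  for (s in basis$shells) {
    B <- sph_transform(s$l)
    M[ro + seq_len(nrow(B)), co + seq_len(ncol(B))] <- B
    ro <- ro + nrow(B); co <- co + ncol(B)
  }
  M
}

# Map each spherical basis function to its center index.
basis_function_centers <- function(basis) {
  unlist(lapply(basis$shells, function(s) rep(s$center, 2L * s$l + 1L)))
}

# Shell list in the layout the compiled integral kernels expect; primitive
# coefficients are weighted by alpha^((2l+3)/4) so that published
# normalized-primitive contraction coefficients combine correctly (absolute
# normalization is applied later from the raw overlap diagonal).
shell_table <- function(basis, system) {
  lapply(basis$shells, function(s) {
    list(center = as.numeric(system$positions[s$center, ]),
         l = s$l,
         exponents = s$exponents,
         coefs = s$coefs * s$exponents^((2 * s$l + 3) / 4))
  })
}
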