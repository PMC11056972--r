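# Independent numerical oracles for the Gaussian integral classes.  Nothing
# here shares code with the package's McMurchie-Davidson/Boys engine: 1-D
# integrals use Gauss-Hermite quadrature (exact for polynomial-times-Gaussian
# integrands), and the Coulomb kernel is handled through the identity
# 1/r = 2/sqrt(pi) * Integral_0^inf exp(-t^2 r^2) dt with an outer mapped
# Gauss-Legendre rule.

# Golub-Welsch nodes/weights -------------------------------------------------

gauss_hermite <- function(n) {
  k <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- J[cbind(k + 1, k)] <- sqrt(k / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

gauss_legendre <- function(n) {
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}

GH64 <- gauss_hermite(64)
GL160 <- gauss_legendre(160)

# A primitive Cartesian Gaussian: list(l = c(lx,ly,lz), A = center, a = exp).
prim <- function(lx, ly, lz, A, a) list(l = c(lx, ly, lz), A = A, a = a)

# normalization of a primitive Cartesian Gaussian (closed form)
prim_norm <- function(p) {
  dfact <- function(n) if (n <= 1) 1 else prod(seq(n, 1, by = -2))
  l <- p$l
  sqrt((2 * p$a / pi)^1.5 * (4 * p$a)^sum(l) /
         (dfact(2 * l[1] - 1) * dfact(2 * l[2] - 1) * dfact(2 * l[3] - 1)))
}

# 1-D quadrature of f(x) * exp(-p (x - mu)^2) with f polynomial
int_gauss_1d <- function(f, p, mu) {
  x <- mu + GH64$nodes / sqrt(p)
  sum(GH64$weights * f(x)) / sqrt(p)
}

# ---------------------------------------------------------------------------
# overlap / kinetic / dipole oracles over two primitives (normalized)

overlap_oracle <- function(pa, pb) {
  val <- 1
  for (d in 1:3) {
    a <- pa$a; b <- pb$a
    p <- a + b
    mu <- (a * pa$A[d] + b * pb$A[d]) / p
    pref <- exp(-a * b / p * (pa$A[d] - pb$A[d])^2)
    f <- function(x) (x - pa$A[d])^pa$l[d] * (x - pb$A[d])^pb$l[d]
    val <- val * pref * int_gauss_1d(f, p, mu)
  }
  prim_norm(pa) * prim_norm(pb) * val
}

# d/dx of (x-A)^l exp(-a (x-A)^2) as polynomial terms on the same Gaussian
dpoly <- function(l, A, a) {
  function(x) {
    res <- -2 * a * (x - A)^(l + 1)
    if (l > 0) res <- res + l * (x - A)^(l - 1)
    res
  }
}

kinetic_oracle <- function(pa, pb) {
  # 1/2 Integral grad(a) . grad(b), each term a product of three 1-D pieces
  a <- pa$a; b <- pb$a
  total <- 0
  for (gd in 1:3) {
    val <- 1
    for (d in 1:3) {
      p <- a + b
      mu <- (a * pa$A[d] + b * pb$A[d]) / p
      pref <- exp(-a * b / p * (pa$A[d] - pb$A[d])^2)
      fa <- if (d == gd) dpoly(pa$l[d], pa$A[d], a) else
        function(x) (x - pa$A[d])^pa$l[d]
      fb <- if (d == gd) dpoly(pb$l[d], pb$A[d], b) else
        function(x) (x - pb$A[d])^pb$l[d]
      val <- val * pref * int_gauss_1d(function(x) fa(x) * fb(x), p, mu)
    }
    total <- total + val
  }
  0.5 * prim_norm(pa) * prim_norm(pb) * total
}

dipole_oracle <- function(pa, pb, dim) {
  val <- 1
  for (d in 1:3) {
    a <- pa$a; b <- pb$a
    p <- a + b
    mu <- (a * pa$A[d] + b * pb$A[d]) / p
    pref <- exp(-a * b / p * (pa$A[d] - pb$A[d])^2)
    f <- function(x) {
      base <- (x - pa$A[d])^pa$l[d] * (x - pb$A[d])^pb$l[d]
      if (d == dim) base * x else base
    }
    val <- val * pref * int_gauss_1d(f, p, mu)
  }
  prim_norm(pa) * prim_norm(pb) * val
}

# ---------------------------------------------------------------------------
# point-charge attraction oracle: outer t-quadrature over the Gaussian
# kernel transform of 1/|r - C|, inner dims by Gauss-Hermite

attraction_oracle <- function(pa, pb, C) {
  a <- pa$a; b <- pb$a
  p <- a + b
  inner <- function(t2) {
    val <- 1
    for (d in 1:3) {
      q <- p + t2
      mu <- (a * pa$A[d] + b * pb$A[d] + t2 * C[d]) / q
      # complete the square over the three Gaussians
      cst <- a * pa$A[d]^2 + b * pb$A[d]^2 + t2 * C[d]^2 - q * mu^2
      f <- function(x) (x - pa$A[d])^pa$l[d] * (x - pb$A[d])^pb$l[d]
      val <- val * exp(-cst) * int_gauss_1d(f, q, mu)
    }
    val
  }
  # t = u/(1-u), dt = du/(1-u)^2
  u <- (GL160$nodes + 1) / 2
  w <- GL160$weights / 2
  t <- u / (1 - u)
  s <- sum(w * vapply(t, function(tt) inner(tt^2), numeric(1)) / (1 - u)^2)
  2 / sqrt(pi) * prim_norm(pa) * prim_norm(pb) * s
}

# ---------------------------------------------------------------------------
# two-particle Coulomb oracle: per Cartesian dimension a correlated 2-D
# Gaussian integral, evaluated exactly by rotating to the principal axes of
# the quadratic form and applying a Gauss-Hermite product rule

int_gauss_2d <- function(f, M, mu) {
  e <- eigen(M, symmetric = TRUE)
  n <- length(GH64$nodes)
  val <- 0
  for (i in seq_len(n)) {
    u1 <- GH64$nodes[i]
    xy <- mu + outer(e$vectors[, 1] / sqrt(e$values[1]), rep(u1, n)) +
      e$vectors[, 2] %o% (GH64$nodes / sqrt(e$values[2]))
    val <- val + GH64$weights[i] * sum(GH64$weights * f(xy[1, ], xy[2, ]))
  }
  val / sqrt(e$values[1] * e$values[2])
}

eri_oracle <- function(pa, pb, pc, pd) {
  a <- pa$a; b <- pb$a; c <- pc$a; d0 <- pd$a
  p <- a + b; q <- c + d0
  inner <- function(t2) {
    val <- 1
    for (d in 1:3) {
      A <- pa$A[d]; B <- pb$A[d]; C <- pc$A[d]; D <- pd$A[d]
      M <- matrix(c(p + t2, -t2, -t2, q + t2), 2, 2)
      lin <- c(a * A + b * B, c * C + d0 * D)
      mu <- solve(M, lin)
      cst <- a * A^2 + b * B^2 + c * C^2 + d0 * D^2 - sum(mu * (M %*% mu))
      f <- function(x1, x2) {
        (x1 - A)^pa$l[d] * (x1 - B)^pb$l[d] *
          (x2 - C)^pc$l[d] * (x2 - D)^pd$l[d]
      }
      val <- val * exp(-cst) * int_gauss_2d(f, M, mu)
    }
    val
  }
  u <- (GL160$nodes + 1) / 2
  w <- GL160$weights / 2
  t <- u / (1 - u)
  s <- sum(w * vapply(t, function(tt) inner(tt^2), numeric(1)) / (1 - u)^2)
  2 / sqrt(pi) * prim_norm(pa) * prim_norm(pb) * prim_norm(pc) *
    prim_norm(pd) * s
}
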