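# Shared fixtures and independent oracles for the test suite.

# Random complex points avoiding the plate cut [-c, c] on the real axis.
random_offcut_points <- function(n, c = 1, seed = 101) {
  withr::with_seed(seed, {
    re <- stats::runif(n, -4 * c, 4 * c)
    im <- stats::runif(n, -4 * c, 4 * c)
    on_cut <- abs(im) < 1e-3 & abs(re) <= c * (1 + 1e-3)
    im[on_cut] <- im[on_cut] + ifelse(im[on_cut] >= 0, 0.1, -0.1)
    complex(real = re, imaginary = im)
  })
}

# Elliptical-coordinate branch from the two polar factors, the independent
# definition the product-of-principal-roots construction must reproduce.
sqrt_zc_elliptic <- function(z, c) {
  r1 <- Mod(z - c); th1 <- Arg(z - c)
  r2 <- Mod(z + c); th2 <- Arg(z + c)
  sqrt(r1 * r2) * exp(1i * (th1 + th2) / 2)
}

# Finite-difference velocity oracle from the complex potential.
fd_velocity <- function(z, plate, h = 1e-6 * plate$c) {
  dphidx <- (Re(complex_potential(z + h, plate)) -
               Re(complex_potential(z - h, plate))) / (2 * h)
  dphidy <- (Re(complex_potential(z + 1i * h, plate)) -
               Re(complex_potential(z - 1i * h, plate))) / (2 * h)
  list(u = dphidx, v = dphidy)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}
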