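test_that("branch of (z^2 - c^2)^(1/2) matches the elliptic-coordinate definition", {
  plate <- plate_kinematics(c = 1.3, V = -2)
  z <- random_offcut_points(1e4, c = plate$c)
  via_product <- complex_potential(z, plate)
  via_elliptic <- -1i * plate$V * z +
    1i * plate$V * sqrt_zc_elliptic(z, plate$c)
  expect_lt(max(Mod(via_product - via_elliptic) / Mod(via_elliptic)), 1e-12)
})

test_that("kinematic boundary condition holds on both faces", {
  plate <- plate_kinematics(c = 2, V = -1.7)
  x <- seq(-plate$c, plate$c, length.out = 102)[2:101]
  for (side in c("top", "bottom")) {
    v <- face_velocity(x, side, plate)$v
    expect_lt(max(abs(v - plate$V)), 1e-10)
  }
})

test_that("face slip velocity and potential follow the on-plate closed forms", {
  plate <- plate_kinematics(c = 1, V = 1)
  # u = +Vx/sqrt(c^2 - x^2) on the top face; x = 0.6 gives 0.75
  expect_equal(face_velocity(0.6, "top", plate)$u, 0.75)
  expect_equal(face_velocity(0.6, "bottom", plate)$u, -0.75)
  expect_equal(face_velocity(0, "top", plate)$u, 0)
  # phi_+ at plate centre is -Vc
  expect_equal(face_potential(0, "top", plate), -1)
  # jump 2Vc at centre, antisymmetry, vanishing at the tips
  plate2 <- plate_kinematics(c = 1, V = 2)
  expect_equal(face_potential(0, "bottom", plate2) -
                 face_potential(0, "top", plate2), 4)
  x <- seq(-0.99, 0.99, length.out = 51)
  expect_equal(face_potential(x, "bottom", plate2),
               -face_potential(x, "top", plate2))
  expect_equal(face_potential(c(-1, 1), "top", plate2), c(0, 0))
  expect_error(face_potential(1.2, "top", plate2), "out of plate")
})

test_that("the horizon y = 0, |x| > c is an equipotential with no horizontal flow", {
  plate <- plate_kinematics(c = 1, V = 3)
  x <- c(seq(1.0001, 5, length.out = 50), -seq(1.0001, 5, length.out = 50))
  z <- complex(real = x, imaginary = 0)
  expect_lt(max(abs(Re(complex_potential(z, plate)))), 1e-10)
  expect_lt(max(abs(complex_velocity(z, plate)$u)), 1e-10)
})

test_that("the far field is undisturbed", {
  plate <- plate_kinematics(c = 1, V = 2)
  z <- 1e6 * exp(1i * seq(0.1, 2 * pi, length.out = 8))
  w <- complex_velocity(z, plate)
  expect_lt(max(sqrt(w$u^2 + (w$v)^2)), 1e-9 * abs(plate$V))
})

test_that("velocities agree with finite differences of the potential", {
  plate <- plate_kinematics(c = 1.5, V = -0.8)
  z <- random_offcut_points(200, c = plate$c, seed = 7)
  vel <- complex_velocity(z, plate)
  fd <- fd_velocity(z, plate)
  expect_lt(max(abs(vel$u - fd$u) / pmax(abs(fd$u), 1e-6)), 1e-5)
  expect_lt(max(abs(vel$v - fd$v) / pmax(abs(fd$v), 1e-6)), 1e-5)
})

test_that("the velocity potential is harmonic away from the cut", {
  plate <- plate_kinematics(c = 1, V = 1)
  h <- 1e-3
  pts <- expand.grid(x = seq(-2, 2, length.out = 9),
                     y = c(-1.5, -0.6, 0.6, 1.5))
  z0 <- complex(real = pts$x, imaginary = pts$y)
  phi <- function(z) Re(complex_potential(z, plate))
  lap <- (phi(z0 + h) + phi(z0 - h) + phi(z0 + 1i * h) + phi(z0 - 1i * h) -
            4 * phi(z0)) / h^2
  expect_lt(max(abs(lap)), 1e-4)
})

test_that("edge circulation: closed form, quadrature and Kelvin's theorem", {
  plate <- plate_kinematics(c = 1, V = 1)
  expect_equal(edge_circulation(plate, "right"), -2)
  expect_equal(edge_circulation(plate, "left"), 2)
  gq <- edge_circulation(plate, "right", method = "quadrature")
  expect_lt(abs(gq - (-2)) / 2, 1e-6)
  expect_identical(edge_circulation(plate, "right") +
                     edge_circulation(plate, "left"), 0)
  expect_lt(abs(edge_circulation(plate, "right", method = "quadrature") +
                  edge_circulation(plate, "left", method = "quadrature")), 1e-8)
  # linear in V and c
  plate3 <- plate_kinematics(c = 0.5, V = -3)
  expect_equal(edge_circulation(plate3, "right"), 3)
  g3 <- edge_circulation(plate3, "right", method = "quadrature")
  expect_lt(abs(g3 - 3) / 3, 1e-6)
})

test_that("submerged pressure jump carries only the unsteady term", {
  med <- fluid_medium(rho = 1, nu = 1e-6)
  steady <- plate_kinematics(c = 1, V = 5)
  x <- seq(-0.9, 0.9, length.out = 21)
  expect_equal(pressure_jump_submerged(x, steady, med), rep(0, 21))
  accel <- plate_kinematics(c = 1, V = 0, dV_dt = 1)
  expect_equal(pressure_jump_submerged(0, accel, med), -2)
  # integral over the plate with dc_dt = 0 is -rho pi c^2 dV/dt
  med1000 <- medium_freshwater()
  pl <- plate_kinematics(c = 0.7, V = 2, dV_dt = 3.1)
  q <- integrate(function(x) pressure_jump_submerged(x, pl, med1000),
                 -pl$c, pl$c, rel.tol = 1e-10)
  expect_equal(q$value, -med1000$rho * pi * pl$c^2 * pl$dV_dt,
               tolerance = 1e-8)
  expect_error(pressure_jump_submerged(1.5, pl, med1000), "out of plate")
})

test_that("water-entry pressure omits or includes the singular steady term", {
  med <- fluid_medium(rho = 1, nu = 1e-6)
  pl <- plate_kinematics(c = 1, V = 1, dc_dt = 1)
  expect_equal(pressure_water_entry(0, pl, med), -1)
  expect_equal(pressure_water_entry(0, pl, med, include_singular_term = TRUE),
               -1 - 0.5)
  # even in x
  x <- seq(0.05, 0.9, length.out = 10)
  expect_equal(pressure_water_entry(x, pl, med),
               pressure_water_entry(-x, pl, med))
  # singular term overflows to -Inf at the tips rather than erroring
  expect_identical(pressure_water_entry(1, pl, med,
                                        include_singular_term = TRUE), -Inf)
})

test_that("on-cut and on-edge points are rejected with explicit guidance", {
  plate <- plate_kinematics(c = 1, V = 1)
  expect_error(complex_potential(0.5 + 0i, plate), "side")
  expect_error(complex_velocity(1 + 0i, plate), "singularity")
  expect_error(plate_kinematics(c = -1, V = 1), "invalid geometry")
})

test_that("field and profile tables have consistent shapes and values", {
  plate <- plate_kinematics(c = 1, V = -1)
  fld <- plate_field(plate, x = seq(-2, 2, 0.5), y = seq(-1, 1, 0.5))
  expect_s3_class(fld, "tbl_df")
  expect_named(fld, c("x", "y", "phi", "psi", "u", "v"))
  # on-cut rows are NA, off-cut rows finite
  cut_rows <- fld$y == 0 & abs(fld$x) <= 1
  expect_true(all(is.na(fld$phi[cut_rows])))
  expect_true(all(is.finite(fld$phi[!cut_rows])))
  prof <- plate_face_profile(plate, n = 21)
  expect_equal(prof$u_plus, -prof$u_minus)
})
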