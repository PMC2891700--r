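kT300 <- mscg::KB * 300

test_that("bond inversion: Jacobian cancellation and single-bin edge cases", {
  # p(r) ~ r^2 -> flat potential
  set.seed(1)
  r <- sample_bonded("bond", function(x) rep(0, length(x)), 300, 5e5,
                     seed = 3, support = c(0.3, 0.5))
  h <- coordinate_histogram(r, "bond", 300, range = c(0.3, 0.5))
  v <- invert_bond(h)
  sup <- v$supported & v$counts > 1000
  expect_lt(max(v$values[sup]) - min(v$values[sup]), 0.3)  # ~6 sigma Poisson
  # single occupied bin: V = 0 there, unsupported elsewhere
  h1 <- h
  h1$counts <- rep(0, length(h1$counts))
  h1$counts[5] <- 100
  v1 <- invert_bond(h1)
  expect_equal(v1$values[5], 0)
  expect_equal(sum(v1$supported), 1L)
  h0 <- h
  h0$counts <- rep(0, length(h0$counts))
  expect_error(invert_bond(h0), "all-zero")
})

test_that("harmonic bond generate-and-recover: k within 5%, r0 within 0.002 nm", {
  k_true <- 1000; r0_true <- 0.38
  V <- function(r) 0.5 * k_true * (r - r0_true)^2
  r <- sample_bonded("bond", V, 300, 1e6, seed = 11, support = c(0.25, 0.55))
  h <- coordinate_histogram(r, "bond", 300)
  fit <- fit_polynomial(invert_bond(h), order = 2L, table_threshold = Inf)
  k_hat <- 2 * fit$coefficients[3]
  r0_hat <- fit$x0 - fit$coefficients[2] / (2 * fit$coefficients[3])
  expect_lt(abs(k_hat - k_true) / k_true, 0.05)
  expect_lt(abs(r0_hat - r0_true), 0.002)
})

test_that("angle inversion handles the sin(theta) Jacobian", {
  # p ~ sin(theta) -> flat
  th <- sample_bonded("angle", function(x) rep(0, length(x)), 300, 5e5,
                      seed = 5)
  v <- invert_angle(coordinate_histogram(th, "angle", 300))
  sup <- v$supported & v$counts > 2000  # ignore sparsely sampled edge bins
  expect_lt(max(v$values[sup]) - min(v$values[sup]), 0.2)
  # harmonic recovery of theta0 within 1 degree
  V <- function(x) 0.5 * 0.05 * (x - 100)^2  # kJ/mol per deg^2
  th2 <- sample_bonded("angle", V, 300, 5e5, seed = 6)
  fit <- fit_polynomial(invert_angle(coordinate_histogram(th2, "angle", 300)),
                        order = 2L, table_threshold = Inf)
  th0_hat <- fit$x0 - fit$coefficients[2] / (2 * fit$coefficients[3])
  expect_lt(abs(th0_hat - 100), 1)
  # uniform p -> V = +kT ln sin(theta) + c: symmetric about 90 degrees,
  # where it attains its maximum (the Jacobian-corrected density is lowest
  # there); compare shapes over the well-sampled interior
  set.seed(41)
  thu <- runif(1e6, 1e-3, 180 - 1e-3)
  vu <- invert_angle(coordinate_histogram(thu, "angle", 300))
  sup <- which(vu$grid > 15 & vu$grid < 165)
  m <- vu$grid[sup][which.max(vu$values[sup])]
  expect_lt(abs(m - 90), 10)
  expected <- kT300 * log(sin(vu$grid[sup] * pi / 180))
  anchor <- which.min(abs(vu$grid[sup] - 90))
  expect_lt(max(abs((vu$values[sup] - vu$values[sup][anchor]) -
                      (expected - expected[anchor]))), 0.12)
})

test_that("torsion inversion: uniform, cosine closed form, two wells", {
  set.seed(42)
  phi <- runif(5e5, -180, 180)
  v <- invert_torsion(coordinate_histogram(phi, "torsion", 300))
  expect_lt(max(v$values[v$supported]), 0.2)
  # p ~ exp(cos phi) at kT = 1 -> V = -cos(phi) + c, range 2 kJ/mol
  Tstar <- 1 / mscg::KB
  phic <- sample_bonded("torsion", function(x) -cos(x * pi / 180), Tstar,
                        1e6, seed = 8)
  vc <- invert_torsion(coordinate_histogram(phic, "torsion", Tstar))
  expect_equal(max(vc$values[vc$supported]), 2, tolerance = 0.05)
  expect_lt(abs(vc$grid[which.min(vc$values)]), 5)
  # two-well sampler recovers both well centers
  V2 <- function(x) 6 * sin(x * pi / 90)^2  # wells at 0 and +-90... period 180
  phi2 <- sample_bonded("torsion", V2, 300, 5e5, seed = 9)
  v2 <- invert_torsion(coordinate_histogram(phi2, "torsion", 300, binwidth = 5))
  low <- v2$grid[v2$values < 0.3]
  expect_true(any(abs(low) < 10))
  expect_true(any(abs(abs(low) - 90) < 10))
})

test_that("inversion is invariant to count rescaling and torsions are periodic", {
  set.seed(2)
  phi <- sample_bonded("torsion", function(x) 2 - 2 * cos(x * pi / 180),
                       300, 2e5, seed = 12)
  h <- coordinate_histogram(phi, "torsion", 300)
  v1 <- invert_torsion(h)
  h2 <- h
  h2$counts <- h$counts * 7
  expect_equal(invert_torsion(h2)$values, v1$values, tolerance = 1e-12)
  # series fitted to it is periodic by construction
  s <- fit_cosine_series(v1)
  expect_equal(eval_cosine_series(s, -180), eval_cosine_series(s, 180),
               tolerance = 1e-12)
})

test_that("fit_polynomial recovers exact quartics and flags bad fits", {
  x <- seq(0.3, 0.5, by = 0.002)
  coefs <- c(1.2, -3, 40, 10, 2000)
  y <- drop(outer(x - 0.4, 0:4, `^`) %*% coefs)
  pot <- synthetic_inverted(x, y, "bond")
  fit <- fit_polynomial(pot, order = 4L)
  shift <- min(y)
  expect_equal(fit$rms_residual, 0, tolerance = 1e-8)
  expect_equal(eval_polynomial(fit, x), y - shift, tolerance = 1e-8)
  expect_false(fit$use_table)
  # bimodal input at order 2: large residual flags the table fallback
  yb <- 5 * sin((x - 0.3) / 0.2 * 2 * pi)^2
  fitb <- fit_polynomial(synthetic_inverted(x, yb, "bond"), order = 2L,
                         table_threshold = 1.0)
  expect_true(fitb$use_table)
  expect_gt(fitb$rms_residual, 1.0)
  expect_error(fit_polynomial(synthetic_inverted(x[1:3], y[1:3], "bond"),
                              order = 4L), "underdetermined")
})

test_that("fit_cosine_series recovers known series", {
  phi <- seq(-177.5, 177.5, by = 5)
  s1 <- fit_cosine_series(synthetic_inverted(phi, cos(phi * pi / 180) + 1,
                                             "torsion"))
  expect_equal(s1$a[2], 1, tolerance = 1e-8)
  expect_lt(max(abs(s1$a[c(3, 4, 5)])), 1e-8)
  v <- 0.5 + 0.25 * cos(3 * phi * pi / 180)
  s2 <- fit_cosine_series(synthetic_inverted(phi, v, "torsion"))
  expect_equal(s2$a[1] + min(v) - min(v), s2$a[1])  # a0 absorbs the min shift
  expect_equal(s2$a[4], 0.25, tolerance = 1e-8)
  # sine extension captures asymmetry the pure-cosine basis cannot
  va <- cos(phi * pi / 180) + 0.4 * sin(2 * phi * pi / 180)
  sc <- fit_cosine_series(synthetic_inverted(phi, va, "torsion"))
  ss <- fit_cosine_series(synthetic_inverted(phi, va, "torsion"), sine = TRUE)
  expect_gt(sc$rms_residual, 0.1)
  expect_lt(ss$rms_residual, 1e-8)
  expect_equal(ss$b[2], 0.4, tolerance = 1e-8)
})

test_that("torsion library: 400 entries, scaling semantics, fallback logging", {
  res <- unname(mscg:::.AA3)
  input <- data.frame(res1 = rep(res, each = 20), res2 = rep(res, 20),
                      a0 = 0.2, a1 = 1, a2 = 0.5, a3 = 0.1, a4 = 0.02)
  lib <- build_torsion_library(input, scale = 0.54)
  expect_length(lib, 400L)
  expect_equal(lib[["ALA GLY"]]$a[2], 0.54)
  # scale multiplies (V - min V) by exactly s
  phi <- seq(-180, 175, by = 5)
  v1 <- eval_cosine_series(build_torsion_library(input, 1)[["ALA GLY"]], phi)
  vs <- eval_cosine_series(lib[["ALA GLY"]], phi)
  expect_equal(vs - min(vs), 0.54 * (v1 - min(v1)), tolerance = 1e-10)
  # scale = 1 is the identity
  expect_equal(build_torsion_library(input, 1)[["TRP TRP"]]$a,
               unlist(input[input$res1 == "TRP" & input$res2 == "TRP",
                            3:7], use.names = FALSE))
  expect_error(build_torsion_library(input, scale = 0))
  # missing pairs fall back when a fallback entry is designated
  part <- input[input$res1 != "TRP", ]
  expect_error(build_torsion_library(part, 0.54), "missing")
  fb <- structure(list(a = c(0, 1, 0, 0, 0), b = NULL,
                       rms_residual = NA_real_), class = "cosine_series")
  lib2 <- build_torsion_library(part, 0.54, fallback = fb)
  expect_length(attr(lib2, "fallback_pairs"), 20L)
  expect_equal(lib2[["TRP ALA"]]$a[2], 0.54)
  # file round trip
  p <- withr::local_tempfile()
  write_torsion_library(lib, p)
  lib3 <- build_torsion_library(read_torsion_coefficients(p), scale = 1)
  expect_equal(lib3[["ALA GLY"]]$a, lib[["ALA GLY"]]$a, tolerance = 1e-9)
})

test_that("backbone angle potential pools histograms into one quartic", {
  # bimodal pool with wells at 90 and 120 degrees
  V <- function(x) 8 * ((x - 90) / 30)^2 * ((x - 120) / 30)^2
  th1 <- sample_bonded("angle", V, 300, 3e5, seed = 21)
  th2 <- sample_bonded("angle", V, 300, 3e5, seed = 22)
  h1 <- coordinate_histogram(th1, "angle", 300)
  h2 <- coordinate_histogram(th2, "angle", 300)
  fit <- backbone_angle_potential(list(h1, h2))
  expect_equal(fit$order, 4L)
  xs <- seq(70, 140, by = 0.1)
  vf <- eval_polynomial(fit, xs)
  lm_idx <- which(diff(sign(diff(vf))) == 2) + 1
  minima <- xs[lm_idx]
  expect_length(minima, 2L)
  expect_true(min(minima) > 80 && min(minima) < 100)
  expect_true(max(minima) > 110 && max(minima) < 130)
  # identical pools give identical coefficients
  fit2 <- backbone_angle_potential(list(h1, h2))
  expect_identical(fit$coefficients, fit2$coefficients)
  # single harmonic well: quartic reduces to near-harmonic
  Vh <- function(x) 0.05 * (x - 105)^2
  h3 <- coordinate_histogram(sample_bonded("angle", Vh, 300, 3e5, seed = 23),
                             "angle", 300)
  fh <- backbone_angle_potential(h3)
  scale_q <- abs(fh$coefficients[3]) * 15^2  # quadratic term at 15 deg
  expect_lt(abs(fh$coefficients[4]) * 15^3, 0.2 * scale_q)
  expect_lt(abs(fh$coefficients[5]) * 15^4, 0.2 * scale_q)
})

test_that("re-Boltzmannization closes the loop", {
  # invert a sampled torsion, then sample the recovered potential and
  # re-invert: the two potentials agree within statistical tolerance
  Vtrue <- function(x) 3 - 3 * cos(2 * x * pi / 180)
  s1 <- sample_bonded("torsion", Vtrue, 300, 4e5, seed = 31)
  v1 <- invert_torsion(coordinate_histogram(s1, "torsion", 300))
  ser <- fit_cosine_series(v1)
  s2 <- sample_bonded("torsion", function(x) eval_cosine_series(ser, x),
                      300, 4e5, seed = 32)
  v2 <- invert_torsion(coordinate_histogram(s2, "torsion", 300))
  expect_lt(max(abs(v1$values - v2$values)), 0.25)
})
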