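test_that("stress tables convert and re-centre correctly", {
  # stress-volume convention: P = -S / V_slab
  f <- tempfile()
  writeLines(c("# slab_volume: 10",
               "z Sxx Syy Szz",
               paste(seq(-3, 3, by = 0.5), -1000, -1000, 0)), f)
  p <- load_stress_table(f, convention = "stress-volume", recenter = FALSE,
                         tension_tol = Inf)
  expect_equal(unique(p$P_T), 100)
  expect_equal(unique(p$P_N), 0)
  expect_equal(unique(p$pi), 100)
  # pressure convention with P_T = P_N everywhere: pi identically 0
  f2 <- tempfile()
  writeLines(c("z Pxx Pyy Pzz",
               paste(seq(-3, 3, by = 0.5), 50, 50, 50)), f2)
  p2 <- load_stress_table(f2, recenter = FALSE)
  expect_true(all(p2$pi == 0))
  # missing slab volume under stress-volume is a configuration error
  f3 <- tempfile()
  writeLines(c("z Sxx Syy Szz", "0 -1 -1 0"), f3)
  expect_error(load_stress_table(f3, convention = "stress-volume"),
               "slab_volume")
  # non-monotone z is a format error
  f4 <- tempfile()
  writeLines(c("z Pxx Pyy Pzz", "0 1 1 1", "-1 1 1 1"), f4)
  expect_error(load_stress_table(f4), "increasing")
})

test_that("a shifted symmetric profile is re-centred about 0", {
  gen <- gen_stress_profile(dz = 0.005)
  f <- tempfile()
  zoff <- gen$z + 2                       # midplane displaced to +2 nm
  writeLines(c("z Pxx Pyy Pzz",
               paste(zoff, gen$pi, gen$pi, 0)), f)
  p <- load_stress_table(f, recenter = TRUE)
  m <- chain_pressure(p)$minima
  expect_equal(m[2], -m[1], tolerance = 0.05)
  expect_equal(m[2], 2.45, tolerance = 0.05)
})

test_that("pi_CH matches the analytic Gaussian oracle to 1e-6", {
  # single Gaussian lobe, A = 100 bar, sigma = 0.5 nm, window +/- 2 nm
  z <- seq(-3.5, 3.5, by = 0.01)
  A <- 100; s <- 0.5
  prof <- pressure_profile(z, P_N = rep(0, length(z)),
                           P_T = A * exp(-z^2 / (2 * s^2)),
                           tension_tol = Inf)
  got <- chain_pressure(prof, minima = c(-2, 2))$pi_ch
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  truth <- 0.1 * A * s * sqrt(2 * pi) * erf(2 / (s * sqrt(2)))
  expect_equal(got, truth, tolerance = 1e-6)
  # generator closed forms at the 0.01 angstrom bin convention
  gen <- gen_stress_profile()
  tru <- attr(gen, "truth")
  got2 <- chain_pressure(gen, minima = tru$minima)$pi_ch
  expect_lt(abs(got2 - tru$pi_ch_mN_m) / tru$pi_ch_mN_m, 1e-6)
  # zero profile integrates to zero
  p0 <- pressure_profile(z, rep(0, length(z)), rep(0, length(z)))
  expect_equal(chain_pressure(p0, minima = c(-2, 2))$pi_ch, 0)
})

test_that("pi_CH only counts the positive region inside the minima", {
  # positive lobes strictly outside the window contribute nothing
  z <- seq(-4, 4, by = 0.01)
  pi_z <- 100 * (exp(-(z - 3)^2 / 0.02) + exp(-(z + 3)^2 / 0.02)) -
    5 * exp(-z^2 / 2)
  prof <- pressure_profile(z, rep(0, length(z)), pi_z, tension_tol = Inf)
  expect_equal(chain_pressure(prof, minima = c(-1.5, 1.5))$pi_ch, 0,
               tolerance = 1e-12)
})

test_that("glycerol minima are auto-detected at the deepest local minima", {
  gen <- gen_stress_profile()
  tru <- attr(gen, "truth")
  expect_equal(chain_pressure(gen)$minima, tru$auto_minima,
               tolerance = 0.01)
  # a profile with no minima prompts for manual input
  z <- seq(-3, 3, by = 0.01)
  flat <- pressure_profile(z, rep(0, length(z)), rep(1, length(z)),
                           tension_tol = Inf)
  expect_error(chain_pressure(flat), "minima")
})

test_that("first moment matches closed forms and conventions", {
  # constant 100 bar on [0, 2]: -int z pi dz = -200 bar nm^2 = -20 mN/m nm
  z <- seq(-3, 3, by = 0.001)
  pi_z <- ifelse(z >= 0 & z <= 2, 100, 0)
  prof <- pressure_profile(z, rep(0, length(z)), pi_z, L_z = 6,
                           tension_tol = Inf)
  fm <- first_moment_curvature(prof)
  expect_equal(unname(fm$kb_c0_leaflets["upper"]), -20, tolerance = 2e-3)
  # lobe pair weighted to zero the moment: amp2 = -amp1 * c1/c2 makes
  # amp1*area*c1 + amp2*area*c2 = 0 (compact symmetric bumps)
  bump <- function(u, c0, w) {
    s <- (u - c0) / w
    ifelse(abs(s) < 1, (1 - s^2)^2, 0)
  }
  pi_z0 <- 50 * (bump(abs(z), 0.75, 0.3) -
                   (0.75 / 2.25) * bump(abs(z), 2.25, 0.3))
  prof2 <- pressure_profile(z, rep(0, length(z)), pi_z0, L_z = 6,
                            tension_tol = Inf)
  fm2 <- first_moment_curvature(prof2)
  expect_equal(fm2$kb_c0, 0, tolerance = 1e-8)
  # mirror-symmetric profiles give equal leaflet values
  gen <- gen_stress_profile()
  fm3 <- first_moment_curvature(gen, kappa_b = 10)
  expect_equal(unname(fm3$kb_c0_leaflets["upper"]),
               unname(fm3$kb_c0_leaflets["lower"]), tolerance = 1e-9)
  tru <- attr(gen, "truth")
  expect_equal(fm3$kb_c0, (tru$kb_c0_upper + tru$kb_c0_lower) / 2,
               tolerance = 1e-6)
  # asymmetric generator reports a nonzero leaflet asymmetry
  gena <- gen_stress_profile(asymmetry = 1.3)
  fma <- first_moment_curvature(gena)
  expect_gt(abs(fma$asymmetry), 0.1)
  trua <- attr(gena, "truth")
  expect_equal(fma$kb_c0_leaflets[["upper"]], trua$kb_c0_upper,
               tolerance = 1e-6)
  expect_equal(fma$kb_c0_leaflets[["lower"]], trua$kb_c0_lower,
               tolerance = 1e-6)
  # identical replica columns give SD 0
  gen2 <- gen_stress_profile(n_replicas = 2)
  expect_equal(first_moment_curvature(gen2)$sd, 0)
})

test_that("the first-moment operator is linear", {
  set.seed(5)
  z <- seq(-3, 3, by = 0.01)
  mk <- function(y) pressure_profile(z, rep(0, length(z)), y, L_z = 6,
                                     tension_tol = Inf)
  y1 <- rnorm(length(z)); y2 <- rnorm(length(z))
  a <- 2.5; b <- -1.3
  m <- function(p) first_moment_curvature(p)$kb_c0
  expect_equal(m(mk(a * y1 + b * y2)), a * m(mk(y1)) + b * m(mk(y2)),
               tolerance = 1e-9)
})

test_that("generated tensionless profiles carry no net tension", {
  for (amp in c(50, 100, 200)) {
    gen <- gen_stress_profile(amplitude = amp)
    expect_lt(abs(gen$tension_mN_m), 0.1)
  }
  # a profile with real tension triggers the warning
  z <- seq(-3, 3, by = 0.01)
  expect_warning(pressure_profile(z, rep(0, length(z)),
                                  rep(10, length(z))), "tension")
})

test_that("curvature stress combines modulus and curvature with errors", {
  expect_equal(curvature_stress(10, 0)$stress, 0)
  expect_equal(curvature_stress(10, 0.1)$stress, 0.1)
  # doubling c0 quadruples the stress
  expect_equal(curvature_stress(10, 0.2)$stress,
               4 * curvature_stress(10, 0.1)$stress)
  expect_error(curvature_stress(-1, 0.1), "kappa_b")
  cs <- curvature_stress(10, 0.1, kappa_sd = 1, c0_sd = 0.01)
  expect_equal(cs$sd, sqrt((0.1^2 * 1)^2 + (2 * 10 * 0.1 * 0.01)^2))
})

test_that("height fields are extracted from bead configurations", {
  fr <- gen_bilayer_frame(c(DOPC = 1800), seed = 2, jitter = 0.05)
  hf <- extract_height_field(fr, grid = c(8, 8))
  # flat bilayer: midplane field is flat to within bead jitter
  expect_lt(diff(range(hf$mid)), 0.2)
  # a single cell averages everything
  hf1 <- extract_height_field(fr, grid = c(1, 1))
  glyc <- fr$role == "glycerol"
  expect_equal(as.numeric(hf1$mid), mean(fr$coords[glyc, 3]),
               tolerance = 1e-9)
  # imposed single-mode sinusoid is recovered
  fr2 <- fr
  amp <- 0.5
  fr2$coords[, 3] <- fr2$coords[, 3] +
    amp * sin(2 * pi * fr2$coords[, 1] / fr2$box[1])
  hf2 <- extract_height_field(fr2, grid = c(16, 16))
  xc <- (seq_len(16) - 0.5) / 16 * fr2$box[1]
  target <- mean(fr$coords[glyc, 3]) + amp * sin(2 * pi * xc / fr2$box[1])
  expect_lt(max(abs(rowMeans(hf2$mid) - target)), 0.12)
  # too fine a grid is a resolution error
  expect_error(extract_height_field(fr, grid = c(128, 128)), "too fine")
})

test_that("Fourier analysis recovers the generator bending modulus", {
  f <- gen_helfrich_fields(10, L = 50, grid = 64, n_frames = 256, seed = 1)
  fit <- kappa_fourier(f, box = 50)
  expect_equal(fit$kappa, 10, tolerance = 0.1)
  expect_equal(fit$kappa_b, fit$kappa / 2)
  expect_equal(fit$slope, -4, tolerance = 0.35)
  # amplitudes scale as 1/kappa: same seed, 4x stiffer, 4x smaller Sq
  f40 <- gen_helfrich_fields(40, L = 50, grid = 64, n_frames = 64, seed = 2)
  f10 <- gen_helfrich_fields(10, L = 50, grid = 64, n_frames = 64, seed = 2)
  s40 <- kappa_fourier(f40, box = 50)
  s10 <- kappa_fourier(f10, box = 50)
  expect_equal(s10$Sq / s40$Sq, rep(4, length(s10$Sq)), tolerance = 1e-9)
  # flat fields: divergent modulus flagged, not silently returned
  flat <- lapply(1:8, function(i) matrix(0, 32, 32))
  expect_warning(ff <- kappa_fourier(flat, box = 50), "no measurable")
  expect_true(ff$no_undulation)
  expect_true(is.infinite(ff$kappa))
})

test_that("real-space patch variances agree with the Fourier estimate", {
  f <- gen_helfrich_fields(10, L = 50, grid = 64, n_frames = 256, seed = 3)
  kf <- kappa_fourier(f, box = 50)$kappa
  kr <- kappa_realspace(f, box = 50)$kappa
  expect_equal(kr, 10, tolerance = 0.2)
  expect_lt(abs(kr - kf) / kf, 0.2)
  # stiffness ordering is preserved
  k5 <- kappa_realspace(gen_helfrich_fields(5, 50, 32, 64, seed = 4),
                        box = 50)$kappa
  k20 <- kappa_realspace(gen_helfrich_fields(20, 50, 32, 64, seed = 4),
                         box = 50)$kappa
  expect_lt(k5, k20)
  # flat fields decline to fit
  flat <- lapply(1:4, function(i) matrix(1, 32, 32))
  expect_error(kappa_realspace(flat, box = 50), "flat")
})
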