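test_that("classification handles edge cases per the protocol", {
  # single TG 1 nm from a PL: no lens (PL contact), counted as diluted
  fr <- bead_frame(rbind(c(10, 10, 6), c(11, 10, 6), c(3, 3, 6)),
                   c(30, 30, 12), 1:3, c("TG", "DOPC", "DOPC"))
  cl <- classify_tg(fr)
  expect_length(cl$lens, 0)
  expect_equal(cl$diluted, 1L)
  expect_length(cl$boundary, 0)
  # zero TG: empty sets, 0%
  fr0 <- bead_frame(matrix(runif(9, 0, 20), 3, 3), c(20, 20, 12), 1:3,
                    rep("DOPC", 3))
  cl0 <- classify_tg(fr0)
  expect_length(cl0$lens, 0)
  expect_equal(cl0$percent, 0)
  # no PLs is a contract violation
  frx <- bead_frame(matrix(runif(9, 0, 20), 3, 3), c(20, 20, 12), 1:3,
                    rep("TG", 3))
  expect_error(classify_tg(frx), "no phospholipid")
})

test_that("constructed coexistence frames classify exactly", {
  fr <- gen_coexistence_frame(100, 10, 1000, seed = 42)
  cl <- classify_tg(fr)
  expect_setequal(cl$lens, attr(fr, "lens_members"))
  expect_setequal(cl$diluted, attr(fr, "free_members"))
  expect_length(cl$lens_free_pl, 1000)
  expect_equal(cl$percent, 1.0)
})

test_that("classification equals the brute-force oracle", {
  for (seed in 1:4) {
    fr <- gen_coexistence_frame(60, 8, 300, seed = seed)
    a <- classify_tg(fr)
    b <- oracle_classify(fr)
    expect_setequal(a$lens, b$lens)
    expect_setequal(a$diluted, b$diluted)
    expect_setequal(a$boundary, b$boundary)
    expect_setequal(a$lens_free_pl, b$lens_free_pl)
  }
  # a frame dense enough to have a genuine boundary class
  set.seed(77)
  fr2 <- implant_lens(gen_bilayer_frame(c(DOPC = 800), Lz = 16, seed = 3),
                      150, radius = 6, seed = 4)
  a <- classify_tg(fr2)
  b <- oracle_classify(fr2)
  expect_setequal(a$lens, b$lens)
  expect_setequal(a$diluted, b$diluted)
  expect_setequal(a$boundary, b$boundary)
})

test_that("lens, diluted and boundary sets always partition the TG", {
  for (seed in 1:5) {
    set.seed(seed)
    fr <- random_tg_frame(80, box = c(25, 25, 12))
    # add a PL scaffold so the protocol applies
    n <- nrow(fr$coords)
    pos <- rbind(fr$coords,
                 cbind(runif(150, 0, 25), runif(150, 0, 25),
                       runif(150, 0, 12)))
    fr2 <- bead_frame(pos, fr$box, seq_len(n + 150),
                      c(rep("TG", n), rep("DOPC", 150)))
    cl <- classify_tg(fr2)
    tg <- molecules_of_class(fr2, "tg")
    expect_setequal(c(cl$lens, cl$diluted, cl$boundary), tg)
    expect_length(intersect(cl$lens, cl$diluted), 0)
    expect_length(intersect(cl$lens, cl$boundary), 0)
    expect_length(intersect(cl$diluted, cl$boundary), 0)
  }
})

test_that("diluted percentage is stable against the margin choice", {
  # protocol convergence: varying the lens-free margin 2.0-3.0 nm moves
  # the diluted percentage by < 5% on a well-separated fixture
  fr <- gen_coexistence_frame(150, 12, 800, seed = 6)
  pcts <- vapply(c(2.0, 2.5, 3.0), function(m)
    classify_tg(fr, margin = m)$percent, 0)
  expect_lt(max(abs(pcts - pcts[2])) / pcts[2], 0.05)
})

test_that("diluted series tracks constructed dynamics", {
  fr <- gen_coexistence_frame(80, 5, 400, seed = 8)
  frames <- lapply(0:3, function(t) {
    f <- fr; f$time <- t; f
  })
  s <- diluted_series(trajectory(frames))
  expect_equal(nrow(s), 4)
  expect_equal(unique(s$percent), 100 * 5 / 400)
  # strictly increasing series when TG leave the lens frame by frame
  s2 <- gen_relaxation_series(2.0, tau = 100, duration_us = 0.2, dt_ns = 20)
  expect_true(all(diff(s2$percent) > 0))
})

test_that("plateau statistics average the trailing window across replicas", {
  mk <- function(pct) {
    data.frame(time = seq(0, 3000, by = 10), percent = pct)
  }
  ps <- plateau_stats(list(mk(1.0), mk(1.2)), window = 1.5)
  expect_equal(ps$mean, 1.1)
  expect_equal(ps$sd, sd(c(1.0, 1.2)))
  ps1 <- plateau_stats(mk(2.0), window = 1.5)
  expect_equal(ps1$mean, 2.0)
  expect_equal(ps1$sd, 0)
  expect_error(plateau_stats(mk(1), window = 10), "window")
  # explicit (from, to) windows support pre/post-injection comparison
  inj <- gen_relaxation_series(1.1, tau = 200, noise_sd = 0.05,
                               duration_us = 6, injection_time_us = 3,
                               injection_amplitude = 1.5, seed = 5)
  pre <- plateau_stats(inj, window = c(1500, 3000))$mean
  post <- plateau_stats(inj, window = c(4500, 6000))$mean
  expect_equal(post, pre, tolerance = 0.1)
})

test_that("relaxation series recover the generated plateau", {
  s <- lapply(1:2, function(r)
    gen_relaxation_series(1.1, tau = 300, noise_sd = 0.1, seed = 40 + r))
  ps <- plateau_stats(s, window = 1.5)
  expect_equal(ps$mean, 1.1, tolerance = 0.1)
})

test_that("plateau means are independent of lens size", {
  # implanted lenses of different sizes with the same true diluted
  # fraction must report the same concentration
  pcts <- vapply(c(400, 900, 1500), function(n_lens) {
    fr <- gen_coexistence_frame(n_lens, 11, 1000, seed = n_lens)
    classify_tg(fr)$percent
  }, 0)
  expect_equal(pcts, rep(1.1, 3))
})

test_that("dissolution requires permanent disappearance", {
  # dispersed TG sit on a sparse far-from-centre lattice so they can
  # never chain onto the shrinking blob or each other
  far_sites <- local({
    g <- expand.grid(x = seq(2, 28, by = 4.3), y = seq(2, 28, by = 4.3),
                     z = c(2, 10))
    g <- as.matrix(g)
    g[sqrt((g[, 1] - 15)^2 + (g[, 2] - 15)^2) > 9.5, ]
  })
  mk_traj <- function(sizes) {
    frames <- lapply(seq_along(sizes), function(i) {
      n <- sizes[i]
      blob <- sweep(matrix(rnorm(3 * n, 0, 0.8), ncol = 3), 2,
                    c(15, 15, 6), "+")
      rest <- far_sites[seq_len(60 - n), , drop = FALSE]
      pl <- rbind(c(1, 1, 2), c(2, 2, 2))
      pos <- rbind(blob, rest, pl)
      bead_frame(pos, c(30, 30, 12), seq_len(nrow(pos)),
                 c(rep("TG", 60), rep("DOPC", 2)), time = i - 1)
    })
    trajectory(frames)
  }
  set.seed(3)
  # monotone shrinkage below 25: dissolution at the first frame of the
  # final sub-threshold stretch
  tr <- mk_traj(c(50, 40, 30, 24, 10, 5, 5))
  expect_equal(detect_dissolution(tr), 3)
  # stable lens: no dissolution
  expect_true(is.na(detect_dissolution(mk_traj(rep(50, 6)))))
  # dip, re-formation, then final dissolution: the later time counts
  tr2 <- mk_traj(c(50, 20, 40, 40, 20, 10, 5))
  expect_equal(detect_dissolution(tr2), 4)
  # no lens in the first frame is a precondition error
  expect_error(detect_dissolution(mk_traj(c(10, 5, 5))), "first frame")
})

test_that("lens extent spans the min-max coordinates per axis", {
  set.seed(12)
  n <- 400
  pos <- cbind(runif(n, 10, 35), runif(n, 12, 37), runif(n, 4, 9))
  # pin the corners so the extent is exact
  pos[1, ] <- c(10, 12, 4); pos[2, ] <- c(35, 37, 9)
  fr <- bead_frame(pos, c(50, 50, 12), seq_len(n), rep("TG", n))
  ex <- lens_extent(fr, seq_len(n))
  expect_equal(unname(ex), c(25, 25, 5), tolerance = 1e-9)
  # single-molecule lens has (0,0,0) extent at the molecule level
  fr1 <- bead_frame(matrix(c(5, 5, 5), 1, 3), c(20, 20, 12), 1L, "TG")
  expect_equal(unname(lens_extent(fr1, 1L)), c(0, 0, 0))
  expect_error(lens_extent(fr1, integer(0)), "empty")
  # extent is correct across the periodic boundary
  pos2 <- rbind(c(48, 5, 5), c(1, 5, 5), c(49.5, 5, 5))
  fr2 <- bead_frame(pos2, c(50, 50, 12), 1:3, rep("TG", 3))
  expect_equal(unname(lens_extent(fr2, 1:3)[1]), 3, tolerance = 1e-9)
})

test_that("implanted lens diameters are recovered by the extent", {
  for (r in c(12.5, 25)) {
    fr <- gen_bilayer_frame(c(DOPC = 8000), Lz = 20, seed = 1)
    fr2 <- implant_lens(fr, 800, radius = r, seed = 2)
    ex <- lens_extent(fr2, attr(fr2, "lens_members"))
    expect_equal(unname(ex[1]), 2 * r, tolerance = 0.12)
    expect_equal(unname(ex[2]), 2 * r, tolerance = 0.12)
  }
})

test_that("excess TG is the nominal minus equilibrium concentration", {
  expect_equal(excess_tg(6, 1.1), 4.9)
  expect_equal(excess_tg(6, 6), 0)
  expect_equal(excess_tg(6, 0.5), 5.5)
  expect_error(excess_tg(6, -1))
})
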