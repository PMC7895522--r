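test_that("single-linkage clustering matches the brute-force oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(c(10, 50, 200, 400), 1)
    fr <- random_tg_frame(n)
    cl <- cluster_tg(fr, 3.5)
    expect_identical(canonical_partition(cl$members),
                     oracle_partition(molecule_positions(fr), fr$box, 3.5))
  }
})

test_that("clustering handles degenerate inputs", {
  # no TG at all
  fr <- bead_frame(matrix(runif(9, 0, 20), 3, 3), c(20, 20, 20), 1:3,
                   rep("DOPC", 3))
  expect_length(cluster_tg(fr)$members, 0)
  # three TG at mutual ~1 nm: one component
  fr3 <- bead_frame(rbind(c(5, 5, 5), c(6, 5, 5), c(5.5, 5.9, 5)),
                    c(20, 20, 20), 1:3, rep("TG", 3))
  expect_equal(cluster_tg(fr3, 3.5)$sizes, 3L)
  # cutoff >= half box is ambiguous
  expect_error(cluster_tg(fr3, 10), "half the smallest box edge")
})

test_that("two implanted blobs and singletons cluster to known sizes", {
  set.seed(21)
  box <- c(60, 60, 14)
  blob <- function(n, cen, r = 2.5) {
    sweep(matrix(rnorm(3 * n, 0, r / 2.5), ncol = 3), 2, cen, "+")
  }
  pos <- rbind(blob(150, c(15, 30, 7)), blob(145, c(45, 30, 7)),
               rbind(c(2, 2, 2), c(30, 58, 3), c(58, 2, 11),
                     c(30, 6, 11), c(5, 55, 7)))
  fr <- bead_frame(pos, box, seq_len(nrow(pos)), rep("TG", nrow(pos)))
  cl <- cluster_tg(fr, 3.5)
  oracle <- oracle_partition(molecule_positions(fr), box, 3.5)
  expect_identical(canonical_partition(cl$members), oracle)
  expect_equal(cl$sizes[1:2], c(150L, 145L))
  expect_equal(sum(cl$sizes == 1L), 5)
})

test_that("clustering is invariant under rigid translation with wrap", {
  set.seed(9)
  fr <- random_tg_frame(120)
  cl0 <- canonical_partition(cluster_tg(fr, 3.5)$members)
  for (shift in list(c(7.3, -2.1, 5.5), c(15, 15, 6))) {
    pos2 <- sweep(fr$coords, 2, shift, "+")
    fr2 <- bead_frame(pos2, fr$box, fr$molecule, fr$species)
    expect_identical(canonical_partition(cluster_tg(fr2, 3.5)$members), cl0)
  }
})

test_that("bead-mode clustering links molecules by minimum bead distance", {
  # two 2-bead molecules whose means are 4 nm apart but closest beads 3 nm
  pos <- rbind(c(5, 5, 5), c(7, 5, 5),     # molecule 1, mean x = 6
               c(10, 5, 5), c(12, 5, 5))   # molecule 2, mean x = 11
  fr <- bead_frame(pos, c(30, 30, 12), c(1L, 1L, 2L, 2L), c("TG", "TG"))
  expect_equal(cluster_tg(fr, 3.5, mode = "molecule")$sizes, c(1L, 1L))
  expect_equal(cluster_tg(fr, 3.5, mode = "beads")$sizes, 2L)
})

test_that("lens formation is recovered at the implanted time", {
  tr <- gen_lens_trajectory(42.7, total_ns = 80, dt_ns = 1, seed = 13)
  lt <- detect_lens_formation(tr)
  expect_false(lt$censored)
  expect_equal(lt$formation_time, attr(tr, "formation_ns"))
  truth <- attr(tr, "lens_members")
  jac <- length(intersect(lt$lens_members, truth)) /
    length(union(lt$lens_members, truth))
  expect_gte(jac, 0.99)
})

test_that("aggregates below 25 molecules never count as a lens", {
  tr <- gen_lens_trajectory(10, total_ns = 40, dt_ns = 1, n_blob = 24,
                            seed = 17)
  lt <- detect_lens_formation(tr, min_size = 25)
  expect_true(lt$censored)
  expect_true(is.na(lt$formation_time))
})

test_that("transient aggregates violating persistence are censored", {
  # blob exists for 4 ns then disperses for good: persistence 5 fails
  mk_frame <- function(t, formed) {
    if (formed) {
      blob <- sweep(matrix(rnorm(90, 0, 1), ncol = 3), 2, c(15, 15, 6), "+")
    } else {
      blob <- .lattice <- cbind(runif(30, 0, 30), runif(30, 0, 30),
                                runif(30, 0, 12))
    }
    bead_frame(blob, c(30, 30, 12), 1:30, rep("TG", 30), time = t)
  }
  set.seed(31)
  frames <- lapply(0:20, function(t) mk_frame(t, formed = t >= 5 & t <= 8))
  lt <- detect_lens_formation(trajectory(frames), min_size = 25,
                              persistence = 5)
  expect_true(lt$censored)
  expect_gte(nrow(lt$candidates), 1)  # the transient is still recorded
  # frame spacing coarser than persistence is a configuration error
  sparse <- trajectory(lapply(c(0, 10, 20), function(t) mk_frame(t, FALSE)))
  expect_error(detect_lens_formation(sparse, persistence = 5),
               "frame spacing")
})

test_that("nucleation rate follows the replica-average convention", {
  # identical times: zero error
  est <- nucleation_rate(c(1, 1, 1))
  expect_equal(est$rate, 1)
  expect_equal(est$rate_error, 0)
  # spread times: rate = 1/mean, error = sd/mean^2
  est2 <- nucleation_rate(c(0.5, 1.0, 1.5))
  expect_equal(est2$rate, 1)
  expect_equal(est2$rate_error, 0.5)
  # all censored: rate 0, error = 1/total time
  est3 <- nucleation_rate(c(1.5, 1.5, 1.5), total_time = 1.5,
                          censored = rep(TRUE, 3))
  expect_equal(est3$rate, 0)
  expect_equal(est3$rate_error, 1 / 1.5)
  # mixed censoring imputes at the horizon and flags the lower bound
  est4 <- nucleation_rate(c(0.5, 1.5, 1.5), total_time = 1.5,
                          censored = c(FALSE, TRUE, TRUE))
  expect_true(est4$mixed_censoring)
  expect_equal(est4$rate, 1 / mean(c(0.5, 1.5, 1.5)))
  # inverse-averaging alternative
  est5 <- nucleation_rate(c(0.5, 1.0), average = "rate")
  expect_equal(est5$rate, mean(c(2, 1)))
  expect_error(nucleation_rate(numeric(0)), "replica")
})

test_that("the 1/mean(t) estimator carries the known small-n bias", {
  # for n = 3 exponential times at rate lambda, E[1/mean(t)] = 1.5 lambda
  set.seed(123)
  lambda <- 1
  t <- matrix(rexp(3 * 20000, lambda), nrow = 3)
  est <- vapply(seq_len(ncol(t)), function(j)
    nucleation_rate(t[, j], total_time = Inf)$rate, 0)
  expect_equal(mean(est), 1.5 * lambda, tolerance = 0.02)
})

test_that("relative nucleation energy follows -log(rate tau0) ratios", {
  mk <- function(rate) structure(list(rate = rate, rate_error = 0.1 * rate),
                                 class = "nucleation_estimate")
  # identity
  en <- relative_nucleation_energy(mk(1e-3 * 1000), mk(1e-3 * 1000))
  expect_equal(en$ratio, 1)
  # rate 10x reference, tau0 = 1 ns: ln(1e-2)/ln(1e-3) = 2/3
  en2 <- relative_nucleation_energy(mk(1e-2 * 1000), mk(1e-3 * 1000),
                                    tau0 = 1)
  expect_equal(en2$ratio, 2 / 3)
  # faster nucleation means lower barrier whenever rate tau0 < 1
  for (f in c(2, 5, 50)) {
    en3 <- relative_nucleation_energy(mk(f * 1e-3 * 1000), mk(1e-3 * 1000))
    expect_lt(en3$ratio, 1)
  }
  expect_error(relative_nucleation_energy(mk(0), mk(1)), "rate must be > 0")
  # tau0 sensitivity is reported because the normalisation is a convention
  expect_named(en2$tau0_sensitivity, c("tau0_x0.1", "tau0_x10"))
})

test_that("detected rate is non-increasing in the minimum lens size", {
  tr <- gen_lens_trajectory(20, total_ns = 60, dt_ns = 1, n_blob = 30,
                            seed = 23)
  rates <- vapply(c(20, 25, 30, 31), function(ms) {
    lt <- detect_lens_formation(tr, min_size = ms)
    nucleation_rate(list(lt), total_time = tr$total_time)$rate
  }, 0)
  expect_true(all(diff(rates) <= 1e-9))
})
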