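test_that("H-bond closure follows the geometric criterion exactly", {
  # constructed single-donor geometries
  mk <- function(d, angle_deg) {
    # acceptor O at distance d from H, with O...H-N angle as given
    at <- data.frame(
      residue_index = c(1, 1, 2, 2, 2),
      residue_number = c(10, 10, 14, 14, 14),
      residue = "A", atom = c("C", "O", "N", "H", "CA"),
      element = c("C", "O", "N", "H", "C"))
    h <- c(0, 0, 0)
    n <- c(0, 0.1, 0)           # N-H bond along -y from N
    th <- (180 - angle_deg) * pi / 180
    o <- d * c(sin(th), -cos(th), 0)
    xyz <- rbind(c(0.1, -0.3, 0), o, n, h, c(0.05, 0.2, 0))
    coords <- array(NA_real_, c(1, 5, 3)); coords[1, , ] <- xyz
    helix_trajectory(at, coords, 10)
  }
  expect_true(hbond_closed(mk(0.20, 180), 14, 4L))
  # boundary: exactly 0.26 nm is open (strict inequality)
  expect_false(hbond_closed(mk(0.26, 180), 14, 4L))
  expect_false(hbond_closed(mk(0.2599999, 119.9), 14, 4L))
  expect_true(hbond_closed(mk(0.2599, 120.1), 14, 4L))
  # missing amide H -> NULL (skipped position)
  tj <- make_ideal_traj(1)
  expect_null(hbond_closed(tj, 26, 4L))
})

test_that("ideal helix closes all alpha bonds and no 3-10 bonds", {
  tj <- make_ideal_traj(2)
  op <- suppressWarnings(occupancy_profile(tj))
  with_partner <- op$residue_number >= 30   # donors with an i-4 acceptor
  expect_true(all(op$occ_alpha[with_partner] == 1))
  expect_true(all(op$occ_310 == 0, na.rm = TRUE))
  expect_true(all(op$occ_helix[with_partner] == 1))
  # helix occupancy bounds: >= max of the two, <= their sum
  both <- !is.na(op$occ_alpha) & !is.na(op$occ_310)
  expect_true(all(op$occ_helix[both] >=
                    pmax(op$occ_alpha, op$occ_310)[both]))
  expect_true(all(op$occ_helix[both] <=
                    (op$occ_alpha + op$occ_310)[both]))
})

test_that("extended chain has zero occupancies everywhere", {
  tj <- make_extended_traj(1)
  op <- suppressWarnings(occupancy_profile(tj))
  expect_true(all(op$occ_helix == 0, na.rm = TRUE))
})

test_that("planted open probabilities are recovered within binomial error", {
  p_open <- c("38" = 0.5, "44" = 0.2)
  nf <- 2000
  tj <- gen_helix_trajectory(
    trajectory_truth(wt26, n_frames = nf, open_prob = p_open, seed = 9))
  op <- occupancy_profile(tj)
  for (r in c(38, 44)) {
    occ <- op$occ_helix[op$residue_number == r]
    p <- 1 - p_open[[as.character(r)]]
    expect_lt(abs(occ - p), 4 * sqrt(p * (1 - p) / nf))
  }
})

test_that("occupancy error shrinks like 1/sqrt(n_frames)", {
  err_at <- function(nf, seeds) {
    mean(sapply(seeds, function(s) {
      tj <- gen_helix_trajectory(
        trajectory_truth(wt26, n_frames = nf,
                         open_prob = c("40" = 0.3), seed = s))
      op <- occupancy_profile(tj)
      abs(op$occ_helix[op$residue_number == 40] - 0.7)
    }))
  }
  e500 <- err_at(500, 1:4)
  e5000 <- err_at(5000, 1:4)
  # expect roughly sqrt(10) ~ 3.2x shrinkage; accept a loose band
  expect_lt(e5000, e500 / 1.5)
})

test_that("closure agrees with the brute-force all-pairs checker", {
  tj <- gen_helix_trajectory(
    trajectory_truth(wt26, n_frames = 100, open_prob = 0.3,
                     hinge = 38, bend_mean_deg = 20, bend_sd_deg = 10,
                     seed = 4))
  frames <- seq_len(100)
  for (f in sample(frames, 10)) {
    ora <- oracle_hbond_matrix(tj, f)
    for (off in c(3L, 4L)) {
      sub <- ora[ora$donor - ora$acceptor == off, ]
      got <- vapply(sub$donor, function(d) {
        hbond_closed(tj, d, off, frames = f)
      }, logical(1))
      expect_identical(unname(got), sub$closed)
    }
  }
})

test_that("hydroxyl back-bonding occupancy matches the planted state", {
  tj <- gen_helix_trajectory(
    trajectory_truth(wt26, n_frames = 400, backbond_prob = 0.98, seed = 2))
  bb <- backbonding_occupancy(tj, c(43, 48))
  expect_equal(bb$occ_i4, c(0.98, 0.98), tolerance = 0.05)
  tj0 <- gen_helix_trajectory(
    trajectory_truth(wt26, n_frames = 50, backbond_prob = 0, seed = 2))
  bb0 <- backbonding_occupancy(tj0, c(43, 48))
  expect_equal(bb0$occ_i4, c(0, 0))
  tj1 <- gen_helix_trajectory(
    trajectory_truth(wt26, n_frames = 50, backbond_prob = 1, seed = 2))
  expect_equal(backbonding_occupancy(tj1, 43)$occ_i4, 1)
  expect_error(backbonding_occupancy(tj1, 41), "hydroxyl")
})

test_that("packing scores respond to contacts and planted back-bonds", {
  # isolated carbonyl: nothing within range -> 0; permanent close contact -> 1
  at <- data.frame(residue_index = c(1, 2), residue_number = c(10, 20),
                   residue = c("A", "T"), atom = c("O", "CB"),
                   element = c("O", "C"))
  mk <- function(d) {
    coords <- array(NA_real_, c(1, 2, 3))
    coords[1, , ] <- rbind(c(0, 0, 0), c(d, 0, 0))
    helix_trajectory(at, coords, 10)
  }
  expect_equal(packing_scores(mk(0.60))$packing[1], 0)
  expect_equal(packing_scores(mk(0.30))$packing[1], 1)
  # planted Thr back-bond increases packing at the acceptor carbonyl
  # relative to the same construction without the hydroxyl contact
  with_bb <- gen_helix_trajectory(
    trajectory_truth(wt26, n_frames = 5, backbond_prob = 1, seed = 3))
  no_bb <- gen_helix_trajectory(
    trajectory_truth(wt26, n_frames = 5, backbond_prob = NULL, seed = 3))
  s1 <- packing_scores(with_bb); s0 <- packing_scores(no_bb)
  # acceptors of the T43/T48 hydroxyls are V39 and V44
  for (acc in c(39, 44)) {
    expect_gt(s1$packing[s1$residue_number == acc],
              s0$packing[s0$residue_number == acc])
  }
})

test_that("MSF profiles are superposition-invariant and rank fluctuations", {
  # rigid-body motion only: MSF vanishes after superposition
  tj <- make_ideal_traj(40)
  set.seed(1)
  for (f in seq_len(40)) {
    R <- rotation_matrix(stats::rnorm(3), stats::runif(1, 0, 180))
    shift <- stats::rnorm(3, 0, 0.5)
    tj$coords[f, , ] <- sweep(tj$coords[f, , ] %*% t(R), 2, shift, "+")
  }
  prof <- msf_profile(tj, block_ns = 0.1)   # 10 frames per block
  expect_lt(max(prof$msf), 1e-10)
  expect_true(all(is.na(prof$msf_norm)))    # zero variance -> undefined

  # one jittered residue dominates the normalized profile
  tj2 <- gen_helix_trajectory(
    trajectory_truth(wt26, n_frames = 200, jitter = c("40" = 0.05),
                     seed = 6))
  prof2 <- msf_profile(tj2, block_ns = 0.5)
  expect_equal(prof2$residue_number[which.max(prof2$msf_norm)], 40)
  # z-score normalization
  expect_lt(abs(mean(prof2$msf_norm)), 1e-9)
  expect_lt(abs(stats::sd(prof2$msf_norm) - 1), 1e-9)
  expect_error(msf_profile(make_ideal_traj(3), block_ns = 1), "2 blocks")
})

test_that("MD-derived exchange prediction is self-consistent", {
  p_open <- stats::setNames(rep(0.2, 10), 38:47)
  tj <- gen_helix_trajectory(
    trajectory_truth(wt26, n_frames = 600, open_prob = p_open, seed = 8))
  occ <- occupancy_profile(tj)
  chem <- compute_intrinsic_rates(wt26, cond_dhx5)
  k <- chem$k_ch[match(occ$residue_number, chem$residue_number)] *
    (1 - occ$occ_helix)
  times <- default_exchange_times()
  experiment <- reconstruct_overall(k[is.finite(k)], times)
  fit <- md_to_dhx(occ, chem, experiment)
  expect_identical(fit$flag, "ok")
  expect_equal(fit$f, 1, tolerance = 0.02)
  expect_lt(abs(fit$t0), 0.5)
  expect_lt(fit$chi2, 1e-6)
  # open-state limit: zero occupancy reproduces the chemical-rate curve
  occ0 <- occ; occ0$occ_alpha <- occ0$occ_310 <- occ0$occ_helix <- 0
  k_ch <- chem$k_ch[match(occ0$residue_number, chem$residue_number)]
  chem_curve <- reconstruct_overall(k_ch[is.finite(k_ch)], times)
  fit0 <- md_to_dhx(occ0, chem, chem_curve)
  expect_equal(fit0$f, 1, tolerance = 1e-3)
  expect_lt(fit0$chi2, 1e-8)
  # scale degeneracy: doubling k_ch and halving f leaves the curve
  pred_a <- predict(fit, times)$mean_D
  chem2 <- chem; chem2$k_ch <- chem$k_ch * 2
  fit2 <- md_to_dhx(occ, chem2, experiment)
  expect_equal(fit2$f, fit$f / 2, tolerance = 0.02)
  expect_equal(predict(fit2, times)$mean_D, pred_a, tolerance = 1e-4)
})
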