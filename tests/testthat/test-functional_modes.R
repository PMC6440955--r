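# helper: trajectory with a planted linear mode on TM-C backbone atoms
make_mode_traj <- function(n_frames = 2000, seed = 3, scale = 0.05,
                           two_modes = FALSE, rho = 0.5) {
  base <- ideal_helix(wt26$residues, wt26$numbering, hydroxyls = FALSE)
  na <- nrow(base$atoms)
  set.seed(seed + 100)
  sel <- base$atoms$residue_number >= 44 &
    base$atoms$atom %in% c("N", "CA", "C", "O")
  v1 <- matrix(0, na, 3)
  v1[sel, ] <- matrix(stats::rnorm(sum(sel) * 3), ncol = 3)
  v1 <- v1 / sqrt(sum(v1^2))
  s1 <- as.numeric(scale(stats::arima.sim(list(ar = rho), n_frames)))
  if (!two_modes) {
    mode <- v1 * scale; series <- s1
    truth2 <- NULL; s2 <- NULL
  } else {
    v2 <- matrix(0, na, 3)
    v2[sel, ] <- matrix(stats::rnorm(sum(sel) * 3), ncol = 3)
    v2 <- v2 - v1 * sum(v2 * v1)          # orthogonalize
    v2 <- v2 / sqrt(sum(v2^2))
    s2 <- as.numeric(scale(stats::arima.sim(list(ar = rho), n_frames)))
    # two independent motions; the generator takes one matrix, so fold
    # the second in by frame-wise addition afterwards
    mode <- v1 * scale; series <- s1
    truth2 <- v2 * scale
  }
  tj <- gen_helix_trajectory(
    trajectory_truth(wt26, n_frames = n_frames, mode_vector = mode,
                     mode_series = series, seed = seed))
  if (two_modes) {
    for (f in seq_len(n_frames)) {
      tj$coords[f, , ] <- tj$coords[f, , ] + s2[f] * truth2
    }
  }
  list(traj = tj, v1 = v1, v2 = if (two_modes) truth2 / scale else NULL,
       s1 = s1, s2 = s2)
}

model_atom_rows <- function(traj) {
  which(traj$atoms$residue_number %in% 29:52 &
          traj$atoms$atom %in% c("N", "CA", "C", "O"))
}

test_that("order parameter counts closed helix H-bonds in the window", {
  tj <- make_ideal_traj(3)
  s <- build_order_parameter(tj, 44:47)
  expect_equal(as.numeric(s), rep(4, 3))
  ext <- make_extended_traj(2)
  expect_equal(as.numeric(build_order_parameter(ext, 44:47)), c(0, 0))
  # independent openings: mean of the sum ~ n * p
  tj2 <- gen_helix_trajectory(
    trajectory_truth(wt26, n_frames = 3000,
                     open_prob = stats::setNames(rep(0.5, 4), 44:47),
                     seed = 12))
  s2 <- build_order_parameter(tj2, 44:47)
  expect_lt(abs(mean(s2) - 2), 0.1)
  expect_error(build_order_parameter(tj, integer(0)), "empty")
})

test_that("planted functional mode is recovered with high validation", {
  mt <- make_mode_traj()
  m <- fit_pls_fma(mt$traj, order = mt$s1, n_components = 4)
  rows <- model_atom_rows(mt$traj)
  expect_gt(mode_overlap(m$ewmcm, mt$v1[rows, ]), 0.95)
  expect_gt(m$r_valid[m$n_components], 0.95)
  # validation never markedly exceeds training
  expect_lt(m$r_valid[m$n_components] - m$r_train[m$n_components], 0.05)
})

test_that("permuted order parameter gives a null model", {
  mt <- make_mode_traj(n_frames = 5000, seed = 21)
  set.seed(99)
  m0 <- fit_pls_fma(mt$traj, order = sample(mt$s1), n_components = 3)
  expect_lt(abs(m0$r_valid[m0$n_components]), 0.2)
})

test_that("uncorrelated second mode stays out of the ewMCM", {
  mt <- make_mode_traj(two_modes = TRUE, seed = 31)
  m <- fit_pls_fma(mt$traj, order = mt$s1, n_components = 4)
  rows <- model_atom_rows(mt$traj)
  expect_gt(mode_overlap(m$ewmcm, mt$v1[rows, ]), 0.9)
  expect_lt(mode_overlap(m$ewmcm, mt$v2[rows, ]), 0.2)
})

test_that("mode overlap is a sign-invariant inner product", {
  v <- stats::rnorm(30); v <- v / sqrt(sum(v^2))
  w <- stats::rnorm(30); w <- w - v * sum(w * v); w <- w / sqrt(sum(w^2))
  expect_equal(mode_overlap(v, v), 1)
  expect_equal(mode_overlap(v, -v), 1)
  expect_lt(mode_overlap(v, w), 1e-12)
  expect_error(mode_overlap(v, w[-1]), "dimension")
})

test_that("ewMCM is stable under frame duplication and extra components", {
  mt <- make_mode_traj(n_frames = 1200, seed = 41)
  m1 <- fit_pls_fma(mt$traj, order = mt$s1, n_components = 4)
  dup <- mt$traj
  dup$coords <- dup$coords[rep(seq_len(1200), each = 2), , , drop = FALSE]
  m2 <- fit_pls_fma(dup, order = rep(mt$s1, each = 2), n_components = 4)
  expect_gt(mode_overlap(m1$ewmcm, m2$ewmcm), 0.99)
  # beyond the planted dimensionality, validation gains stay < 0.02
  k <- m1$n_components
  if (length(m1$r_valid) > k) {
    expect_lt(max(diff(m1$r_valid[k:length(m1$r_valid)])), 0.02)
  }
})

test_that("interpolation along the mode is linear and feeds the classifier", {
  mt <- make_mode_traj(seed = 51)
  m <- fit_pls_fma(mt$traj, order = mt$s1, n_components = 3)
  # single step at amplitude zero returns the reference
  ref <- interpolate_along_mode(m, n_steps = 1, amplitude_range = c(0, 0))
  expect_equal(frame_coords(ref, 1), m$mean_structure, tolerance = 1e-12)
  # endpoints differ by (a_max - a_min) * ewMCM
  path <- interpolate_along_mode(m, n_steps = 7)
  a <- range(m$projection)
  expect_equal(frame_coords(path, 7) - frame_coords(path, 1),
               (a[2] - a[1]) * m$ewmcm, tolerance = 1e-9)
})

test_that("a planted bending mode classifies as type B end to end", {
  # order parameter drives a hinge bend; the extreme conformations along
  # the fitted mode must classify as bending
  nf <- 800
  bend_series <- abs(as.numeric(stats::arima.sim(list(ar = 0.6), nf))) * 8
  tj <- gen_helix_trajectory(
    trajectory_truth(wt26, n_frames = nf, hinge = 38,
                     bend_mean_deg = 15, bend_sd_deg = 6, bend_rho = 0.6,
                     seed = 61))
  s <- attr(tj, "truth")$bend_deg
  m <- fit_pls_fma(tj, order = s, n_components = 3)
  path <- interpolate_along_mode(m, n_steps = 2)
  cls <- classify_hinge_motion(
    frame_coords(path, 1)[path$atoms$atom == "CA", ],
    frame_coords(path, 2)[path$atoms$atom == "CA", ],
    residues = path$atoms$residue_number[path$atoms$atom == "CA"])
  expect_identical(cls$type, "B")
})

test_that("a constant order parameter is rejected", {
  tj <- make_ideal_traj(20)
  expect_error(fit_pls_fma(tj, order = rep(1, 20), n_components = 2),
               "constant")
})

test_that("the NIPALS PLS core agrees with an independent PLS implementation", {
  set.seed(81)
  n <- 300; p <- 40
  X <- matrix(stats::rnorm(n * p), n, p)
  colnames(X) <- paste0("v", seq_len(p))
  y <- drop(X %*% stats::rnorm(p, 0, 0.3)) + stats::rnorm(n)
  Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
  betas <- helixdx:::.pls1_nipals(Xc, yc, 3)
  ref <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = FALSE)
  pred_ref <- predict(ref, newdata = X)$predict
  for (k in 1:3) {
    pred_own <- drop(Xc %*% betas[[k]]) + mean(y)
    expect_equal(pred_own, unname(pred_ref[, 1, k]), tolerance = 1e-6)
  }
})
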