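test_that("segment axis fits are accurate, equivariant and oriented", {
  tj <- make_ideal_traj(1)
  ca_all <- frame_coords(tj, 1)[which(tj$atoms$atom == "CA"), ]
  # reference axis: difference of means over full helical turns lies on
  # the axis up to residual phase (independent of the fitted estimator)
  ax_ref <- colMeans(ca_all[13:30, ]) - colMeans(ca_all[1:18, ])
  fit <- fit_segment_axis(ca_all[6:10, ])
  expect_lt(vec_angle(fit$axis, ax_ref), 0.5)
  # equivariance under rotation
  R <- rotation_matrix(c(1, 2, 3), 37)
  fit_rot <- fit_segment_axis(ca_all[6:10, ] %*% t(R))
  expect_lt(vec_angle(fit_rot$axis, as.numeric(R %*% fit$axis)), 1e-6)
  # reversing the residue order flips the sign
  fit_rev <- fit_segment_axis(ca_all[10:6, ])
  expect_lt(vec_angle(fit_rev$axis, -fit$axis), 1e-6)
  # degenerate collinear input is rejected
  line <- cbind(seq(0, 1, length.out = 5), 0, 0)
  expect_error(fit_segment_axis(line), "degenerate|axis")
})

test_that("bend and swivel angles recover planted hinge geometry", {
  straight <- make_ideal_traj(3)
  bs0 <- bend_swivel(straight)
  expect_lt(max(bs0$theta), 1)

  bent <- gen_helix_trajectory(
    trajectory_truth(wt26, n_frames = 10, hinge = 38, bend_mean_deg = 30,
                     bend_sd_deg = 0, seed = 2))
  bs1 <- bend_swivel(bent)
  expect_lt(abs(mean(bs1$theta) - 30), 2)

  # rotating the kink direction by +90 deg shifts Phi by 90, theta fixed
  bent90 <- gen_helix_trajectory(
    trajectory_truth(wt26, n_frames = 10, hinge = 38, bend_mean_deg = 30,
                     bend_sd_deg = 0, bend_direction_deg = 90, seed = 2))
  bs2 <- bend_swivel(bent90)
  expect_lt(abs(mean(bs2$theta) - mean(bs1$theta)), 1)
  dphi <- (mean(bs2$phi) - mean(bs1$phi)) %% 360
  expect_lt(min(abs(dphi - 90), abs(dphi - 270)), 3)
})

test_that("bend/swivel is invariant under global rigid motion", {
  bent <- gen_helix_trajectory(
    trajectory_truth(wt26, n_frames = 5, hinge = 38, bend_mean_deg = 25,
                     bend_sd_deg = 5, seed = 3))
  bs_a <- bend_swivel(bent)
  set.seed(11)
  for (f in seq_len(5)) {
    R <- rotation_matrix(stats::rnorm(3), stats::runif(1, 0, 180))
    bent$coords[f, , ] <- sweep(bent$coords[f, , ] %*% t(R), 2,
                                stats::rnorm(3), "+")
  }
  bs_b <- bend_swivel(bent)
  expect_equal(bs_b$theta, bs_a$theta, tolerance = 1e-6)
  expect_equal(bs_b$phi, bs_a$phi, tolerance = 1e-4)
})

test_that("rise per residue separates helical from extended geometry", {
  helix <- make_ideal_traj(1)
  r <- rise_per_residue(helix, 40)
  expect_gt(mean(r), 0.14); expect_lt(mean(r), 0.16)
  ext <- make_extended_traj(1)
  r_ext <- rise_per_residue(ext, 40)
  expect_equal(mean(r_ext), 0.35, tolerance = 0.02)
})

test_that("angle clustering respects periodicity and recovers modes", {
  # two planted modes, well separated
  set.seed(5)
  s1 <- data.frame(theta = stats::rnorm(300, 30, 1),
                   phi = stats::rnorm(300, 170, 2))
  s2 <- data.frame(theta = stats::rnorm(300, 10, 1),
                   phi = stats::rnorm(300, -60, 2))
  series <- structure(
    data.frame(frame = 1:600, theta = c(s1$theta, s2$theta),
               phi = c(s1$phi, s2$phi)),
    class = c("bend_swivel_series", "data.frame"))
  cl <- cluster_angles(series, k = 2, seed = 1)
  cen <- cl$centers[order(cl$centers$theta), ]
  expect_lt(abs(cen$theta[1] - 10), 2)
  expect_lt(abs(cen$theta[2] - 30), 2)
  expect_lt(abs(cen$phi[1] - (-60)), 5)
  expect_lt(abs(cen$phi[2] - 170), 5)
  expect_equal(sum(cl$centers$size), 600)
  # all frames identical: one effective cluster at the point
  one <- structure(data.frame(frame = 1:10, theta = 20, phi = 45),
                   class = c("bend_swivel_series", "data.frame"))
  c1 <- cluster_angles(one, k = 1, seed = 1)
  expect_equal(c1$centers$theta, 20, tolerance = 1e-9)
  expect_equal(c1$centers$phi, 45, tolerance = 1e-9)
  expect_error(cluster_angles(one, k = 50), "exceeds")
})

test_that("free-energy surfaces follow Boltzmann inversion", {
  # uniform distribution -> flat surface at zero
  set.seed(2)
  series <- structure(
    data.frame(frame = 1:8000,
               theta = stats::runif(8000, 0, 90),
               phi = stats::runif(8000, -180, 180)),
    class = c("bend_swivel_series", "data.frame"))
  fe <- angle_free_energy(series, temperature = 293,
                          theta_breaks = seq(0, 90, by = 30),
                          phi_breaks = seq(-180, 180, by = 90))
  expect_lt(max(fe$G, na.rm = TRUE), 0.1)
  # two-state occupancy 10:1 -> RT log 10 between minima
  two <- structure(
    data.frame(frame = 1:1100,
               theta = c(rep(15, 1000), rep(75, 100)),
               phi = 0),
    class = c("bend_swivel_series", "data.frame"))
  fe2 <- angle_free_energy(two, temperature = 293,
                           theta_breaks = c(0, 30, 60, 90),
                           phi_breaks = c(-180, 180))
  vals <- sort(fe2$G[is.finite(fe2$G)])
  expect_equal(vals[2] - vals[1], 1.987204e-3 * 293 * log(10),
               tolerance = 1e-9)
  # single occupied bin: zero there, undefined elsewhere
  single <- structure(data.frame(frame = 1:5, theta = 15, phi = 0),
                      class = c("bend_swivel_series", "data.frame"))
  fe3 <- angle_free_energy(single, theta_breaks = c(0, 30, 60),
                           phi_breaks = c(-180, 180))
  expect_equal(sum(is.finite(fe3$G)), 1)
  expect_equal(min(fe3$G, na.rm = TRUE), 0)
})

test_that("hinge classification separates bending from twisting", {
  straight <- make_ideal_traj(1)
  bent <- gen_helix_trajectory(
    trajectory_truth(wt26, n_frames = 1, hinge = 38, bend_mean_deg = 30,
                     bend_sd_deg = 0, seed = 2))
  cls_b <- classify_hinge_motion(straight, bent)
  expect_identical(cls_b$type, "B")
  expect_true(any(cls_b$hinge_residues %in% c(37, 38)))
  # rotation angle agrees with the bend/swivel theta
  th <- mean(bend_swivel(bent)$theta)
  expect_lt(abs(cls_b$angle - th), 3)

  # pure twist: rotate downstream residues about the helix axis
  twist <- straight
  ax <- attr(straight, "truth")$axis
  ca_idx <- which(straight$atoms$atom == "CA")
  hinge_at <- match(44, straight$atoms$residue_number[ca_idx])
  pivot <- frame_coords(straight, 1)[ca_idx[hinge_at], ]
  R <- rotation_matrix(ax, 40)
  move <- straight$atoms$residue_number > 44
  for (f in 1:1) {
    xyz <- twist$coords[f, , ]
    xyz[move, ] <- sweep(sweep(xyz[move, , drop = FALSE], 2, pivot) %*%
                           t(R), 2, pivot, "+")
    twist$coords[f, , ] <- xyz
  }
  cls_t <- classify_hinge_motion(straight, twist)
  expect_identical(cls_t$type, "T")
  expect_true(all(cls_t$hinge_residues >= 43 & cls_t$hinge_residues <= 46))

  # identical conformations: no significant motion
  cls_0 <- classify_hinge_motion(straight, straight)
  expect_identical(cls_0$type, "none")
})
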