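test_that("centroid arithmetic recovers deuteron counts", {
  times <- c(1, 10, 100)
  # all-H centroids give zero content
  curve0 <- overall_curve_from_centroids(times, rep(1000, 3), 1000,
                                         n_amides = 10)
  expect_equal(curve0$mean_D, rep(0, 3))
  # known content round-trips through the mass scale
  D_true <- c(9.5, 5.2, 0.8)
  shift <- 1.00628
  curve <- overall_curve_from_centroids(times, 1000 + D_true * shift, 1000,
                                        per_deuteron_shift = shift,
                                        n_amides = 10)
  expect_equal(curve$mean_D, D_true, tolerance = 1e-9)
  # plateau anchoring maps t -> Inf onto the 5% residual floor
  anchored <- overall_curve_from_centroids(
    times, 1000 + c(9.5, 5.2, 1.0) * shift, 1000,
    per_deuteron_shift = shift, n_amides = 10, plateau_observed = 1.0)
  expect_equal(anchored$mean_D[3], 0.05 * 10, tolerance = 1e-9)
  expect_error(
    overall_curve_from_centroids(times, c(999, 1000, 1000), 1000,
                                 n_amides = 10),
    "negative")
})

test_that("fragment differencing localizes single amides", {
  # constant ladder increment: every resolvable residue shows content d
  d <- 0.37
  n <- length(wt28$residues)
  frag <- do.call(rbind, lapply(c("c", "z"), function(ion) {
    do.call(rbind, lapply(seq_len(n - 1), function(len) {
      span <- helixdx:::etd_amide_span(ion, len, n)
      data.frame(ion_type = ion, fragment_length = len, replicate = 1L,
                 time_min = 1, deuterons = d * length(span))
    }))
  }))
  cont <- residue_content_from_fragments(frag, wt28)
  expect_true(all(abs(cont$content - d) < 1e-12))
  # resolvable positions are residues 3..N in peptide numbering
  expect_equal(range(cont$residue_number),
               c(wt28$numbering[3], max(wt28$numbering)))
})

test_that("noiseless generator output is inverted exactly", {
  tr <- exchange_truth(delta_g = tm_helix_truth_profile(wt28), sigma = 0,
                       n_replicates = 1, seed = 11)
  ds <- gen_exchange_dataset(tr, wt28)
  cont <- residue_content_from_fragments(ds$fragments, wt28)
  for (r in unique(cont$residue_number)) {
    i <- match(r, ds$truth_rates$residue_number)
    k <- ds$truth_rates$k_true[i]
    y_true <- 0.95 * exp(-k * tr$times) + 0.05
    y_rec <- cont$content[cont$residue_number == r][order(
      cont$time_min[cont$residue_number == r])]
    expect_equal(y_rec, y_true[order(tr$times)], tolerance = 1e-9)
  }
})

test_that("pH-time mapping follows first-order hydroxide kinetics", {
  expect_equal(map_ph_time(10, 4.0, 5.0), 1.0)
  expect_equal(map_ph_time(7 * 1440, 6.45, 5.0), 7 * 1440 * 10^1.45)
  expect_equal(map_ph_time(123, 5.0, 5.0), 123)
  # precondition: base catalysis must dominate at both pH values
  expect_error(map_ph_time(10, 2.5, 5.0, peptide = wt26), "95")
})

test_that("site-rate fits recover known rates and flag degenerate data", {
  times <- default_exchange_times()
  k_true <- 0.01
  y <- 0.95 * exp(-k_true * times) + 0.05
  f <- fit_site_rate(times, y)
  expect_equal(f$k, k_true, tolerance = 1e-6)
  expect_identical(f$flag, "ok")
  # model value at t = 0 is 1 by construction
  expect_equal(0.95 * exp(-f$k * 0) + 0.05, 1.0)
  # data at the floor: no confident finite estimate
  f0 <- fit_site_rate(times, rep(0.05, length(times)))
  expect_identical(f0$flag, "at_floor")
  expect_true(is.na(f0$k))
  expect_error(fit_site_rate(c(1, 2, 3), c(1, 0.9, 0.8)), "4 time points")
})

test_that("free energies follow the EX2 relation and its domain", {
  rates <- structure(
    data.frame(residue_number = c(30, 31, 32),
               k_exp = c(0.5, 1 / 1001, 2), se = c(0.01, 1e-5, 0.1),
               flag = "ok"),
    class = c("residue_rate_profile", "data.frame"))
  chem <- compute_intrinsic_rates(wt26, cond_dhx5)
  chem$k_ch[] <- 1; chem$k_acid[] <- 0; chem$k_water[] <- 0
  chem$k_base[] <- 1
  dg <- delta_g(rates, chem, temperature = 293.15, n_mc = 500)
  # k_exp = k_ch/2 -> exactly zero
  expect_equal(dg$delta_g[1], 0, tolerance = 1e-12)
  # k_exp = k_ch/1001 -> RT log(1000) ~ 4.02 kcal/mol, against the
  # independent arithmetic oracle
  expect_equal(dg$delta_g[2], oracle_delta_g(1 / 1001, 1), tolerance = 1e-9)
  expect_equal(dg$delta_g[2], 4.02, tolerance = 0.01)
  # k_exp >= k_ch is flagged undefined
  expect_identical(dg$flag[3], "undefined")
  expect_true(is.na(dg$delta_g[3]))
  # CI brackets the estimate
  expect_true(dg$ci_lo[1] <= dg$delta_g[1] && dg$ci_hi[1] >= dg$delta_g[1])
})

test_that("free energy is strictly decreasing in the observed rate", {
  ks <- seq(0.01, 0.99, by = 0.01)
  dgs <- oracle_delta_g(ks, 1)
  expect_true(all(diff(dgs) < 0))
})

test_that("overall kinetics reconstruct from site rates", {
  k <- rep(0.02, 12)
  times <- default_exchange_times()
  rec <- reconstruct_overall(k, times)
  expect_equal(rec$mean_D, 12 * (0.95 * exp(-0.02 * times) + 0.05),
               tolerance = 1e-12)
  expect_equal(reconstruct_overall(k, c(1e-12, 1))$mean_D[1], 12,
               tolerance = 1e-9)
})

test_that("time-scaling superposition finds the planted factor", {
  tr <- exchange_truth(delta_g = tm_helix_truth_profile(wt28), sigma = 0,
                       n_replicates = 1, seed = 5)
  ds <- gen_exchange_dataset(tr, wt28)
  k <- ds$truth_rates$k_true[ds$truth_rates$measurable]
  grid <- exp(seq(log(0.1), log(10080), length.out = 60))
  a <- reconstruct_overall(k, grid)
  expect_equal(superpose_scale(a, a)$s, 1.0, tolerance = 1e-3)
  b <- reconstruct_overall(k * 0.2, grid)
  expect_equal(superpose_scale(a, b)$s, 0.2, tolerance = 0.01)
})

test_that("HDX/DHX generated under equal protection shows the chemical ratio", {
  dgp <- tm_helix_truth_profile(wt26)
  ds_d <- gen_exchange_dataset(
    exchange_truth(delta_g = dgp, sigma = 0, n_replicates = 1,
                   conditions = exchange_conditions(5, 293.15, "DHX")),
    wt26)
  ds_h <- gen_exchange_dataset(
    exchange_truth(delta_g = dgp, sigma = 0, n_replicates = 1,
                   conditions = exchange_conditions(5, 293.15, "HDX")),
    wt26)
  grid <- exp(seq(log(0.1), log(10080), length.out = 60))
  curve_d <- reconstruct_overall(
    ds_d$truth_rates$k_true[ds_d$truth_rates$measurable], grid)
  curve_h <- reconstruct_overall(
    ds_h$truth_rates$k_true[ds_h$truth_rates$measurable], grid)
  s <- superpose_scale(curve_d, curve_h)$s
  expect_gt(s, 0.15); expect_lt(s, 0.25)

  # per-residue observed-rate ratios reproduce the chemical ratio
  mk_prof <- function(ds) {
    structure(data.frame(
      residue_number = ds$truth_rates$residue_number,
      k_exp = ds$truth_rates$k_true,
      se = 0.01 * ds$truth_rates$k_true, flag = "ok"),
      class = c("residue_rate_profile", "data.frame"))
  }
  ir <- isotope_ratio_profile(mk_prof(ds_d), mk_prof(ds_h), n_mc = 200)
  expect_equal(mean(ir$ratio, na.rm = TRUE), 0.2, tolerance = 0.05)
  # equal profiles give unit ratio; undefined rates are flagged
  ir1 <- isotope_ratio_profile(mk_prof(ds_d), mk_prof(ds_d), n_mc = 200)
  expect_true(all(abs(ir1$ratio - 1) < 1e-12, na.rm = TRUE))
  expect_true(all(ir1$flag[is.na(ir1$ratio)] == "undefined"))
})

test_that("noisy round trip recovers the free-energy landscape", {
  tr <- exchange_truth(delta_g = tm_helix_truth_profile(wt28),
                       sigma = 0.05, n_replicates = 3, seed = 42)
  ds <- gen_exchange_dataset(tr, wt28)
  cont <- suppressWarnings(residue_content_from_fragments(ds$fragments, wt28))
  prof <- fit_rate_profile(cont)
  dg <- delta_g(prof, ds$chem, n_mc = 200)
  m <- merge(dg, ds$truth_rates, by = "residue_number")
  ok <- is.finite(m$delta_g.x) & is.finite(m$delta_g.y) & m$identifiable &
    m$flag == "ok"
  expect_gt(sum(ok), 20)
  expect_lt(mean(abs(m$delta_g.x - m$delta_g.y)[ok]), 0.15)
  # the recovered profile preserves the flexible-to-rigid step shape
  tmn <- ok & m$residue_number %in% 34:40
  tmc <- ok & m$residue_number %in% 41:51
  expect_gt(mean(m$delta_g.x[tmc]) - mean(m$delta_g.x[tmn]), 2)

  # reconstruction from fitted rates tracks the generated curve; the two
  # terminal amides never singly resolved contribute via the fast bound
  all_meas <- ds$truth_rates$residue_number[ds$truth_rates$measurable]
  k_full <- prof$k_exp[match(all_meas, prof$residue_number)]
  rec <- reconstruct_overall(k_full, tr$times, undefined = "fast")
  truth_curve <- reconstruct_overall(
    ds$truth_rates$k_true[ds$truth_rates$measurable], tr$times)
  late <- tr$times > 1
  expect_lt(max(abs(rec$mean_D - truth_curve$mean_D)[late]), 1)
})
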