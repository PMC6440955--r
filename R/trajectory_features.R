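# Per-residue dynamical features of a helix trajectory: intrahelical
# H-bond occupancies (alpha i->i-4 and 3-10 i->i-3), side-chain
# back-bonding, carbonyl packing scores, block-averaged normalized
# fluctuations, and the EX2 bridge predicting overall exchange kinetics
# from H-bond occupancies.

.HB_DIST_NM <- 0.26
.HB_ANGLE_DEG <- 60     # tolerance around linear O...H-N

# geometric closure test for one donor/acceptor/hydrogen triple,
# vectorized over frames.  o, h, n: matrices frames x 3.
.hb_closed_geom <- function(o, h, n,
                            dist_cut = .HB_DIST_NM,
                            angle_tol = .HB_ANGLE_DEG) {
  oh <- o - h
  d <- sqrt(rowSums(oh^2))
  hn <- n - h
  cosang <- rowSums(oh * hn) / (d * sqrt(rowSums(hn^2)))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  # O...H-N linear means the O-H and N-H bond vectors are antiparallel
  d < dist_cut & ang >= (180 - angle_tol)
}

#' Is an intrahelical H-bond closed?
#'
#' Closure criterion: O...H distance strictly below 0.26 nm and the
#' O...H-N angle within 60 degrees of linear.  The acceptor is the
#' carbonyl oxygen \code{offset} residues upstream of the donor amide
#' (offset 4 = alpha, offset 3 = 3-10).
#'
#' @param traj \code{helix_trajectory}.
#' @param donor_residue Donor residue number.
#' @param offset 3 or 4.
#' @param frames Frames to evaluate (default all).
#' @return Logical vector over frames, or NULL (with a message attribute)
#'   when donor H or acceptor O is missing.
#' @export
hbond_closed <- function(traj, donor_residue, offset = c(4L, 3L),
                         frames = seq_len(n_frames(traj))) {
  offset <- as.integer(offset[1])
  stopifnot(offset %in% c(3L, 4L))
  h <- atom_xyz(traj, donor_residue, "H")
  n <- atom_xyz(traj, donor_residue, "N")
  o <- atom_xyz(traj, donor_residue - offset, "O")
  if (is.null(h) || is.null(n) || is.null(o)) return(NULL)
  .hb_closed_geom(o[frames, , drop = FALSE], h[frames, , drop = FALSE],
                  n[frames, , drop = FALSE])
}

#' Intrahelical H-bond occupancy profile
#'
#' Per-residue fraction of frames in which the amide donates a closed
#' alpha (i -> i-4) or 3-10 (i -> i-3) H-bond, plus the combined "helix"
#' occupancy (either closed; frames closed as both count once).
#' Confidence intervals come from a BCa bootstrap over block averages;
#' the block length should exceed twice the occupancy autocorrelation
#' time.
#'
#' @param traj \code{helix_trajectory}.
#' @param block_frames Frames per bootstrap block (NULL = no intervals).
#' @param n_boot Bootstrap resamples.
#' @param seed Bootstrap seed.
#' @return data.frame of class \code{hbond_occupancy_profile}: columns
#'   \code{residue_number}, \code{occ_alpha}, \code{occ_310},
#'   \code{occ_helix} and, with intervals, \code{helix_lo},
#'   \code{helix_hi}; attribute \code{coverage} lists skipped donors.
#' @export
occupancy_profile <- function(traj, block_frames = NULL, n_boot = 2000,
                              seed = 1L) {
  if (n_frames(traj) < 100) {
    warning("fewer than 100 frames: occupancies will be noisy")
  }
  res <- traj_residues(traj)
  skipped <- integer(0)
  closed_a <- closed_3 <- list()
  for (r in res) {
    a <- hbond_closed(traj, r, 4L)
    t3 <- hbond_closed(traj, r, 3L)
    if (is.null(a) && is.null(t3)) { skipped <- c(skipped, r); next }
    closed_a[as.character(r)] <- list(a)
    closed_3[as.character(r)] <- list(t3)
  }
  keep <- as.integer(names(closed_a))
  occ <- function(x) if (is.null(x)) NA_real_ else mean(x)
  out <- data.frame(
    residue_number = keep,
    occ_alpha = vapply(closed_a, occ, numeric(1)),
    occ_310 = vapply(closed_3, occ, numeric(1)))
  helix_closed <- mapply(function(a, t3) {
    if (is.null(a)) t3 else if (is.null(t3)) a else (a | t3)
  }, closed_a, closed_3, SIMPLIFY = FALSE)
  out$occ_helix <- vapply(helix_closed, occ, numeric(1))
  if (!is.null(block_frames)) {
    hmat <- do.call(cbind, lapply(helix_closed, as.numeric))
    blocks <- block_averages(hmat, block_frames)
    if (nrow(blocks) >= 3) {
      bt <- bca_bootstrap(blocks, n = n_boot, seed = seed)
      out$helix_lo <- bt$lower
      out$helix_hi <- bt$upper
    } else {
      warning("fewer than 3 blocks: no bootstrap intervals")
    }
  }
  rownames(out) <- NULL
  structure(out, coverage_skipped = skipped,
            class = c("hbond_occupancy_profile", "data.frame"))
}

#' Side-chain hydroxyl back-bonding occupancy
#'
#' Occupancy of H-bonds donated by Thr/Ser hydroxyl groups to the
#' backbone carbonyl oxygens four and three residues upstream, using the
#' same geometric criterion as the amide bonds with the hydroxyl
#' hydrogen as donor.
#'
#' @param traj \code{helix_trajectory}.
#' @param positions Residue numbers carrying a hydroxyl.
#' @return data.frame: \code{residue_number}, \code{occ_i4},
#'   \code{occ_i3}.
#' @export
backbonding_occupancy <- function(traj, positions) {
  rows <- lapply(positions, function(r) {
    at <- traj$atoms
    letter <- at$residue[match(r, at$residue_number)]
    if (is.na(letter) || !letter %in% c("T", "S")) {
      stop("residue ", r, " carries no side-chain hydroxyl")
    }
    nm <- if (letter == "T") c("OG1", "HG1") else c("OG", "HG")
    og <- atom_xyz(traj, r, nm[1]); hg <- atom_xyz(traj, r, nm[2])
    if (is.null(og) || is.null(hg)) {
      stop("residue ", r, " lacks hydroxyl atoms in this trajectory")
    }
    one <- function(off) {
      o <- atom_xyz(traj, r - off, "O")
      if (is.null(o)) return(NA_real_)
      mean(.hb_closed_geom(o, hg, og))
    }
    data.frame(residue_number = r, occ_i4 = one(4L), occ_i3 = one(3L))
  })
  do.call(rbind, rows)
}

# smooth switching function: 1 below r1, cosine ramp to 0 at r2
.switch_fun <- function(d, r1 = 0.35, r2 = 0.50) {
  w <- 0.5 * (1 + cos(pi * (d - r1) / (r2 - r1)))
  w[d <= r1] <- 1
  w[d >= r2] <- 0
  w
}

#' Carbonyl packing scores
#'
#' For each residue i, the frame-averaged sum of a smooth switching
#' function over the distances from the carbonyl oxygen of i to all
#' side-chain heavy atoms of other residues: contacts closer than
#' \code{r_on} count fully, contacts beyond \code{r_off} not at all.
#'
#' @param traj \code{helix_trajectory}.
#' @param r_on,r_off Switching bounds in nm (defaults 0.35 / 0.50).
#' @return data.frame of class \code{packing_profile}: columns
#'   \code{residue_number}, \code{packing}.
#' @export
packing_scores <- function(traj, r_on = 0.35, r_off = 0.50) {
  at <- traj$atoms
  side <- which(!(at$atom %in% c("N", "CA", "C", "O")) & at$element != "H")
  res <- traj_residues(traj)
  nf <- n_frames(traj)
  rows <- lapply(res, function(r) {
    oi <- atom_index(traj, r, "O")
    if (is.na(oi)) return(NULL)
    j <- side[at$residue_number[side] != r]
    if (!length(j)) {
      return(data.frame(residue_number = r, packing = 0))
    }
    o <- traj$coords[, oi, , drop = FALSE][, 1, ]
    if (nf == 1L) o <- matrix(o, nrow = 1)
    s_tot <- numeric(nf)
    for (jj in j) {
      x <- traj$coords[, jj, , drop = FALSE][, 1, ]
      if (nf == 1L) x <- matrix(x, nrow = 1)
      d <- sqrt(rowSums((o - x)^2))
      s_tot <- s_tot + .switch_fun(d, r_on, r_off)
    }
    data.frame(residue_number = r, packing = mean(s_tot))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, r_on = r_on, r_off = r_off,
            class = c("packing_profile", "data.frame"))
}

# iterative superposition of frames onto their mean structure
# (coords: frames x atoms x 3; fit_idx: atoms used for the fit)
.iterative_mean_fit <- function(coords, fit_idx, tol = 1e-6, max_iter = 50) {
  nf <- dim(coords)[1]
  mean_xyz <- coords[1, , , drop = FALSE][1, , ]
  for (it in seq_len(max_iter)) {
    fitted <- coords
    for (f in seq_len(nf)) {
      fr <- coords[f, , , drop = FALSE][1, , ]
      ft <- kabsch_fit(fr[fit_idx, , drop = FALSE],
                       mean_xyz[fit_idx, , drop = FALSE])
      fitted[f, , ] <- apply_fit(fr, ft)
    }
    new_mean <- apply(fitted, c(2, 3), mean)
    delta <- max(abs(new_mean - mean_xyz))
    mean_xyz <- new_mean
    coords <- fitted
    if (delta < tol) break
  }
  list(coords = coords, mean = mean_xyz, iterations = it)
}

#' Block-averaged mean-squared fluctuation profile
#'
#' Splits the trajectory into non-overlapping blocks, iteratively
#' superposes each block's frames onto the block mean structure (fit on
#' the C-alpha atoms of the profiled range, repeated until the mean
#' changes by less than \code{tol} nm), computes per-residue mean squared
#' C-alpha deviations, averages the blocks, and standardizes the profile
#' to zero mean and unit variance over the profiled residues.
#'
#' @param traj \code{helix_trajectory}.
#' @param block_ns Block length in nanoseconds (with 10 ps frames the
#'   conventional 30 ns block holds 3000 frames; short synthetic
#'   trajectories use proportionally smaller blocks).
#' @param residues Residue-number range to profile (default all).
#' @param tol Convergence tolerance of the iterative mean (nm).
#' @return data.frame of class \code{fluctuation_profile}: columns
#'   \code{residue_number}, \code{msf} (nm^2), \code{msf_norm}.
#' @export
msf_profile <- function(traj, block_ns, residues = traj_residues(traj),
                        tol = 1e-6) {
  block_frames <- round(block_ns * 1000 / traj$frame_interval_ps)
  nf <- n_frames(traj)
  n_blocks <- nf %/% block_frames
  if (n_blocks < 2) stop("trajectory shorter than 2 blocks")
  ca_idx <- vapply(residues, function(r) atom_index(traj, r, "CA"),
                   integer(1))
  ok <- !is.na(ca_idx)
  residues <- residues[ok]; ca_idx <- ca_idx[ok]
  msf_blocks <- matrix(NA_real_, n_blocks, length(residues))
  for (b in seq_len(n_blocks)) {
    fr <- seq.int((b - 1) * block_frames + 1L, b * block_frames)
    sub <- traj$coords[fr, ca_idx, , drop = FALSE]
    fit <- .iterative_mean_fit(sub, seq_along(ca_idx), tol = tol)
    dev2 <- sweep(fit$coords, c(2, 3), fit$mean)^2
    msf_blocks[b, ] <- colMeans(apply(dev2, c(1, 2), sum))
  }
  msf <- colMeans(msf_blocks)
  s <- stats::sd(msf)
  norm <- if (is.finite(s) && s > 1e-12) (msf - mean(msf)) / s else
    rep(NA_real_, length(msf))
  out <- data.frame(residue_number = residues, msf = msf, msf_norm = norm)
  structure(out, block_ns = block_ns, n_blocks = n_blocks,
            normalization = if (anyNA(norm)) "undefined (zero variance)"
                            else "z-score",
            class = c("fluctuation_profile", "data.frame"))
}

#' Predict overall exchange kinetics from MD H-bond occupancies
#'
#' EX2 bridge between simulation and experiment: each amide exchanges at
#' \code{k_i = k_ch,i * (1 - occ_helix,i)} (intrinsic rate times open-
#' state fraction), the overall curve is
#' \code{D(t) = sum_i [0.95 exp(-k_i f (t + t0)) + 0.05]}, and the
#' scaling \code{f} and time offset \code{t0} are fitted to the
#' experimental curve by least squares.  Model quality is the normalized
#' mean-squared deviation of the predicted from the measured curve.
#' Note the scale degeneracy: doubling all chemical rates and halving
#' \code{f} leaves the prediction unchanged.
#'
#' @param occupancies \code{hbond_occupancy_profile}.
#' @param chem \code{intrinsic_rate_profile} on the same residues.
#' @param experiment \code{overall_exchange_curve}.
#' @param rate_model Function \code{(k_ch, occ) -> k} (default the EX2
#'   open-fraction form).
#' @return Object of class \code{md_dhx_fit}: list with \code{f},
#'   \code{t0}, \code{chi2}, \code{rates}, \code{predicted} (curve at the
#'   experimental times), \code{flag}.
#' @export
md_to_dhx <- function(occupancies, chem, experiment,
                      rate_model = function(k_ch, occ) k_ch * (1 - occ)) {
  idx <- match(occupancies$residue_number, chem$residue_number)
  if (anyNA(idx)) stop("occupancy and chemical profiles are not aligned")
  k <- rate_model(chem$k_ch[idx], occupancies$occ_helix)
  ok <- is.finite(k)
  k <- k[ok]
  tt <- experiment$time_min
  DD <- experiment$mean_D
  pred_fun <- function(f, t0) {
    vapply(tt, function(t) {
      sum(.EX2_AMPLITUDE * exp(-k * f * (t + t0)) + .EX2_BASELINE)
    }, numeric(1))
  }
  out <- list(f = NA_real_, t0 = NA_real_, chi2 = NA_real_, rates = k,
              predicted = NULL, flag = "ok")
  class(out) <- "md_dhx_fit"
  if (all(k <= 0) && stats::sd(DD) > 0) {
    out$flag <- "no_convergence"   # fully closed H-bond network cannot decay
    return(out)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(DD ~ pred_fun(f, t0),
                      start = list(f = 1, t0 = 0),
                      lower = c(f = 1e-6, t0 = -min(tt[tt > 0])),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) { out$flag <- "no_convergence"; return(out) }
  cf <- stats::coef(fit)
  out$f <- cf[["f"]]; out$t0 <- cf[["t0"]]
  pred <- pred_fun(out$f, out$t0)
  out$predicted <- overall_exchange_curve(tt, pred, n_amides = length(k))
  out$chi2 <- chi2_norm(pred, DD)
  out$experiment <- experiment
  out
}

#' @export
print.md_dhx_fit <- function(x, ...) {
  if (x$flag != "ok") {
    cat("MD->DHX fit:", x$flag, "\n"); return(invisible(x))
  }
  cat(sprintf(
    "MD->DHX fit over %d amides: f = %.4g, t0 = %.4g min, chi2 = %.4g\n",
    length(x$rates), x$f, x$t0, x$chi2))
  invisible(x)
}

#' @export
coef.md_dhx_fit <- function(object, ...) {
  c(f = object$f, t0 = object$t0)
}

#' @export
predict.md_dhx_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) return(object$predicted)
  k <- object$rates
  D <- vapply(times, function(t) {
    sum(.EX2_AMPLITUDE * exp(-k * object$f * (t + object$t0)) +
          .EX2_BASELINE)
  }, numeric(1))
  overall_exchange_curve(times, D, n_amides = length(k))
}

#' @export
plot.md_dhx_fit <- function(x, ...) {
  ex <- x$experiment
  plot(ex$time_min, ex$mean_D, log = "x", xlab = "time [min]",
       ylab = "remaining deuterons", pch = 16, ...)
  if (!is.null(x$predicted)) {
    graphics::lines(x$predicted$time_min, x$predicted$mean_D, col = 2)
  }
  invisible(x)
}
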