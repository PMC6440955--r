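# Synthetic helix trajectories with planted ground truth.  Geometry is
# constructive: an ideal alpha-helix backbone built from canonical
# internal coordinates, a hinge bend with sampled amplitude/direction, H-
# bond opening realized by displacing acceptor carbonyls past the
# geometric criterion with AR(1)-correlated open/close states, optional
# threonine/serine back-bonding, per-residue positional jitter, and an
# optional planted linear mode with a recorded scalar series.

.BB_GEOM <- list(
  b_NCA = 0.1458, b_CAC = 0.1525, b_CN = 0.1329,   # nm
  b_CO = 0.1231, b_NH = 0.1010, b_CACB = 0.1530,
  a_NCAC = 111.2, a_CACN = 116.2, a_CNCA = 121.7,
  a_CACO = 120.8, a_CNH = 119.0,
  phi = -57, psi = -47, omega = 180)

#' Ideal alpha-helix backbone coordinates
#'
#' Builds N, H, CA, C, O (and CB for non-Gly residues; OG1/HG1 for Thr,
#' OG/HG for Ser when \code{hydroxyls = TRUE}) for a straight ideal
#' alpha helix (phi = -57, psi = -47) from canonical bond lengths and
#' angles.  The first residue carries no amide hydrogen (cap junction).
#'
#' @param residues Character vector of one-letter residue codes.
#' @param numbering Integer residue numbers (same length).
#' @param hydroxyls Build Thr/Ser side-chain hydroxyl donors.
#' @return List with \code{atoms} (data.frame) and \code{xyz}
#'   (matrix n_atoms x 3, nm).
#' @export
ideal_helix <- function(residues, numbering = seq_along(residues),
                        hydroxyls = TRUE) {
  g <- .BB_GEOM
  n <- length(residues)
  stopifnot(n >= 2, length(numbering) == n)
  pos <- list()   # per residue: named list of atom coordinates
  # seed the first residue in a local frame
  N1 <- c(0, 0, 0)
  CA1 <- c(g$b_NCA, 0, 0)
  C1 <- place_atom(c(-1, 1, 0), N1, CA1, g$b_CAC, g$a_NCAC, g$phi + 120)
  pos[[1]] <- list(N = N1, CA = CA1, C = C1)
  for (i in 2:n) {
    p <- pos[[i - 1]]
    Ni <- place_atom(p$N, p$CA, p$C, g$b_CN, g$a_CACN, g$psi)
    CAi <- place_atom(p$CA, p$C, Ni, g$b_NCA, g$a_CNCA, g$omega)
    Ci <- place_atom(p$C, Ni, CAi, g$b_CAC, g$a_NCAC, g$phi)
    pos[[i]] <- list(N = Ni, CA = CAi, C = Ci)
  }
  # carbonyl O anti to the next amide nitrogen; last O trans to N
  for (i in seq_len(n)) {
    p <- pos[[i]]
    if (i < n) {
      # O in the peptide plane, opposite N(i+1)
      Nn <- pos[[i + 1]]$N
      d <- unit(unit(p$C - p$CA) + unit(p$C - Nn))
      pos[[i]]$O <- p$C + g$b_CO * d
    } else {
      d <- unit(unit(p$C - p$CA) + unit(p$C - pos[[i]]$N))
      pos[[i]]$O <- p$C + g$b_CO * d
    }
    # amide H anti to the preceding carbonyl O
    if (i > 1) {
      Cp <- pos[[i - 1]]$C; Op <- pos[[i - 1]]$O
      pos[[i]]$H <- place_atom(Op, Cp, p$N, g$b_NH, g$a_CNH, 180)
    }
    # beta carbon: tetrahedral off CA, away from N and C
    if (residues[i] != "G") {
      d <- -unit(unit(p$N - p$CA) + unit(pos[[i]]$C - p$CA))
      pos[[i]]$CB <- p$CA + g$b_CACB * d
    }
    if (hydroxyls && residues[i] %in% c("T", "S")) {
      on <- if (residues[i] == "T") c("OG1", "HG1") else c("OG", "HG")
      # hydroxyl oxygen off CB, roughly radially outward
      cb <- pos[[i]]$CB
      d <- unit(cb - p$CA)
      pos[[i]][[on[1]]] <- cb + 0.143 * d
      pos[[i]][[on[2]]] <- cb + (0.143 + 0.096) * d
    }
  }
  atoms <- list(); xyz <- list()
  for (i in seq_len(n)) {
    for (an in names(pos[[i]])) {
      atoms[[length(atoms) + 1L]] <- data.frame(
        residue_index = i, residue_number = numbering[i],
        residue = residues[i], atom = an, element = .element_of(an),
        stringsAsFactors = FALSE)
      xyz[[length(xyz) + 1L]] <- pos[[i]][[an]]
    }
  }
  list(atoms = do.call(rbind, atoms), xyz = do.call(rbind, xyz))
}

#' Ground truth for a synthetic helix trajectory
#'
#' @param peptide \code{\link{peptide_spec}} providing sequence and
#'   numbering (defaults to the 26-55 TMD model peptide).
#' @param n_frames Number of frames.
#' @param frame_interval_ps Frame spacing (ps), default 10.
#' @param hinge Residue number at which the helix bends (NULL = straight).
#' @param bend_mean_deg,bend_sd_deg Bend-amplitude distribution.
#' @param bend_direction_deg Bend direction (swivel) about the helix axis.
#' @param bend_rho AR(1) coefficient of the bend-amplitude series.
#' @param open_prob Per-residue amide H-bond open probability: scalar or
#'   vector named by residue number (donors).
#' @param open_rho AR(1) (lag-1) correlation of the open/close state.
#' @param open_shift Carbonyl displacement realizing an open bond (nm).
#' @param backbond_prob Closed probability of Thr/Ser hydroxyl
#'   back-bonds (NULL disables hydroxyl construction).
#' @param jitter Per-residue Gaussian positional noise SD (nm): scalar or
#'   vector named by residue number.
#' @param mode_vector Optional planted linear mode: matrix n_atoms x 3
#'   (or 3N vector) added as \code{s(t) * mode_vector}.
#' @param mode_series Optional scalar series s(t) (default standard
#'   Gaussian AR(1) with \code{bend_rho}).
#' @param seed Integer seed.
#' @return Object of class \code{trajectory_truth}.
#' @export
trajectory_truth <- function(peptide = app_peptide("A26-55_WT"),
                             n_frames = 500, frame_interval_ps = 10,
                             hinge = NULL, bend_mean_deg = 0,
                             bend_sd_deg = 0, bend_direction_deg = 0,
                             bend_rho = 0,
                             open_prob = 0, open_rho = 0,
                             open_shift = 0.12,
                             backbond_prob = NULL,
                             jitter = 0,
                             mode_vector = NULL, mode_series = NULL,
                             seed = 1L) {
  stopifnot(abs(bend_rho) < 1, abs(open_rho) < 1,
            all(open_prob >= 0), all(open_prob <= 1))
  structure(as.list(environment()), class = "trajectory_truth")
}

# stationary two-state Markov chain with P(open) = p and lag-1
# autocorrelation rho
.markov_binary <- function(n, p, rho) {
  if (p <= 0) return(rep(FALSE, n))
  if (p >= 1) return(rep(TRUE, n))
  rho <- max(rho, -min(p / (1 - p), (1 - p) / p) + 1e-9)
  p11 <- p + (1 - p) * rho      # open -> open
  p01 <- p * (1 - rho)          # closed -> open
  s <- logical(n)
  s[1] <- stats::runif(1) < p
  u <- stats::runif(n)
  for (t in 2:n) s[t] <- u[t] < (if (s[t - 1]) p11 else p01)
  s
}

.ar1 <- function(n, mean, sd, rho) {
  if (sd == 0) return(rep(mean, n))
  e <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  for (t in 2:n) x[t] <- rho * x[t - 1] + e[t]
  x + mean
}

#' Generate a synthetic helix trajectory
#'
#' Realizes the ground truth of \code{\link{trajectory_truth}} frame by
#' frame: ideal helix, hinge bend (rotation of all downstream atoms about
#' an axis through the hinge C-alpha, perpendicular to the helix axis,
#' oriented by the bend direction), H-bond opening (acceptor carbonyl
#' displaced along the O-H direction past the closure criterion when the
#' donor's Markov state is open), hydroxyl back-bond geometry, jitter and
#' planted mode.  The realized per-frame bend amplitudes, open states and
#' mode series are recorded in the returned truth attribute.
#'
#' @param truth \code{\link{trajectory_truth}}.
#' @param out_dir Optional directory: writes \code{trajectory.pdb}
#'   (multi-model) and \code{truth.csv}.
#' @return \code{helix_trajectory} with attribute \code{truth}.
#' @export
gen_helix_trajectory <- function(truth, out_dir = NULL) {
  stopifnot(inherits(truth, "trajectory_truth"))
  pep <- truth$peptide
  base <- ideal_helix(pep$residues, pep$numbering,
                      hydroxyls = !is.null(truth$backbond_prob))
  atoms <- base$atoms
  na <- nrow(atoms)
  nf <- truth$n_frames
  nres <- length(pep$residues)
  num <- pep$numbering

  set.seed(truth$seed)

  # helix axis of the straight construction (principal direction of CAs)
  ca_idx <- which(atoms$atom == "CA")
  ca <- base$xyz[ca_idx, , drop = FALSE]
  ax <- svd(sweep(ca, 2, colMeans(ca)))$v[, 1]
  if (sum((ca[nres, ] - ca[1, ]) * ax) < 0) ax <- -ax
  # two directions perpendicular to the axis
  u1 <- unit(cross3(ax, if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
  u2 <- cross3(ax, u1)

  # per-residue open probabilities for amide donors
  p_open <- rep(0, nres)
  if (length(truth$open_prob) == 1L && is.null(names(truth$open_prob))) {
    p_open[] <- truth$open_prob
  } else {
    p_open[match(as.integer(names(truth$open_prob)), num)] <- truth$open_prob
  }
  open_states <- vapply(seq_len(nres), function(i) {
    .markov_binary(nf, p_open[i], truth$open_rho)
  }, logical(nf))
  open_states <- matrix(open_states, nrow = nf)  # nf x nres

  bend <- .ar1(nf, truth$bend_mean_deg, truth$bend_sd_deg, truth$bend_rho)
  bend <- pmax(bend, 0)

  backbond_states <- NULL
  oh_res <- integer(0)
  if (!is.null(truth$backbond_prob)) {
    oh_res <- which(pep$residues %in% c("T", "S"))
    backbond_states <- sapply(oh_res, function(i) {
      .markov_binary(nf, truth$backbond_prob, truth$open_rho)
    })
    if (length(oh_res)) backbond_states <- matrix(backbond_states, nrow = nf)
  }

  jit <- rep(0, nres)
  if (length(truth$jitter) == 1L && is.null(names(truth$jitter))) {
    jit[] <- truth$jitter
  } else {
    jit[match(as.integer(names(truth$jitter)), num)] <- truth$jitter
  }

  mode_mat <- NULL; mode_s <- NULL
  if (!is.null(truth$mode_vector)) {
    mode_mat <- truth$mode_vector
    if (is.null(dim(mode_mat))) mode_mat <- matrix(mode_mat, ncol = 3,
                                                   byrow = TRUE)
    stopifnot(nrow(mode_mat) == na)
    mode_s <- if (is.null(truth$mode_series)) {
      .ar1(nf, 0, 1, truth$bend_rho)
    } else truth$mode_series
    stopifnot(length(mode_s) == nf)
  }

  hinge_idx <- if (is.null(truth$hinge)) NA_integer_ else
    match(truth$hinge, num)
  if (!is.null(truth$hinge) && is.na(hinge_idx)) {
    stop("hinge residue not in the peptide")
  }

  # atom bookkeeping for fast per-frame edits
  res_of_atom <- atoms$residue_index
  o_idx <- vapply(seq_len(nres), function(i) {
    j <- which(res_of_atom == i & atoms$atom == "O"); if (length(j)) j else NA_integer_
  }, integer(1))
  h_idx <- vapply(seq_len(nres), function(i) {
    j <- which(res_of_atom == i & atoms$atom == "H"); if (length(j)) j else NA_integer_
  }, integer(1))

  coords <- array(NA_real_, c(nf, na, 3))
  for (f in seq_len(nf)) {
    xyz <- base$xyz
    if (!is.na(hinge_idx) && bend[f] > 0) {
      dir <- truth$bend_direction_deg * pi / 180
      axis_f <- cos(dir) * u1 + sin(dir) * u2
      R <- rotation_matrix(axis_f, bend[f])
      pivot <- base$xyz[ca_idx[hinge_idx], ]
      move <- res_of_atom > hinge_idx
      xyz[move, ] <- sweep(sweep(xyz[move, , drop = FALSE], 2, pivot) %*%
                             t(R), 2, pivot, "+")
    }
    if (!is.null(mode_mat)) xyz <- xyz + mode_s[f] * mode_mat
    # H-bond opening: displace the alpha acceptor O(i-4) away from H(i)
    for (i in which(open_states[f, ])) {
      if (i <= 4) next
      oi <- o_idx[i - 4L]; hi <- h_idx[i]
      if (is.na(oi) || is.na(hi)) next
      d <- unit(xyz[oi, ] - xyz[hi, ])
      xyz[oi, ] <- xyz[oi, ] + truth$open_shift * d
    }
    # hydroxyl back-bonds to O(i-4): closed = H on the line to the
    # acceptor at 0.19 nm; open = rotated away
    if (length(oh_res)) {
      for (j in seq_along(oh_res)) {
        i <- oh_res[j]
        if (i <= 4 || is.na(o_idx[i - 4L])) next
        on <- if (pep$residues[i] == "T") c("OG1", "HG1") else c("OG", "HG")
        og <- which(res_of_atom == i & atoms$atom == on[1])
        hg <- which(res_of_atom == i & atoms$atom == on[2])
        acc <- xyz[o_idx[i - 4L], ]
        ca_i <- xyz[which(res_of_atom == i & atoms$atom == "CA"), ]
        d <- unit(acc - ca_i)
        xyz[og, ] <- acc - 0.29 * d
        xyz[hg, ] <- if (backbond_states[f, j]) acc - 0.19 * d
                     else xyz[og, ] - 0.096 * d
      }
    }
    if (any(jit > 0)) {
      for (i in which(jit > 0)) {
        ai <- which(res_of_atom == i)
        xyz[ai, ] <- xyz[ai, ] +
          matrix(stats::rnorm(3, 0, jit[i]), nrow = length(ai),
                 ncol = 3, byrow = TRUE)
      }
    }
    coords[f, , ] <- xyz
  }

  traj <- helix_trajectory(atoms, coords, truth$frame_interval_ps)
  attr(traj, "truth") <- list(spec = truth, bend_deg = bend,
                              open_states = open_states,
                              p_open = stats::setNames(p_open, num),
                              mode_series = mode_s,
                              axis = ax, u1 = u1, u2 = u2)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trajectory_pdb(traj, file.path(out_dir, "trajectory.pdb"))
    utils::write.csv(
      data.frame(frame = seq_len(nf), bend_deg = bend,
                 mode_s = if (is.null(mode_s)) NA_real_ else mode_s),
      file.path(out_dir, "truth.csv"), row.names = FALSE)
  }
  traj
}
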