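# Partial-least-squares functional mode analysis: the collective
# backbone motion maximally correlated with a scalar order parameter
# (here: the summed closed-H-bond count of a residue window).  The PLS1
# regression is solved by NIPALS; the ensemble-weighted maximally
# correlated motion (ewMCM) is the covariance-weighted regression
# coefficient vector, unit-normalized.  Training uses the chronological
# first half of the trajectory, validation the second half.

#' Collective H-bond order parameter
#'
#' Per frame, the number of residues in the window whose amide donates a
#' closed alpha or 3-10 H-bond.  The default window V44-I47 spans the
#' amides whose stability differs between wild type and the I45T mutant.
#'
#' @param traj \code{helix_trajectory}.
#' @param window Residue numbers (default 44:47).
#' @return Numeric vector over frames (values in [0, window size]),
#'   attribute \code{window}.
#' @export
build_order_parameter <- function(traj, window = 44:47) {
  if (!length(window)) stop("empty residue window")
  closed <- lapply(window, function(r) {
    a <- hbond_closed(traj, r, 4L)
    t3 <- hbond_closed(traj, r, 3L)
    if (is.null(a) && is.null(t3)) {
      stop("residue ", r, " has no H-bond partners in this trajectory")
    }
    if (is.null(a)) t3 else if (is.null(t3)) a else (a | t3)
  })
  s <- Reduce(`+`, lapply(closed, as.numeric))
  attr(s, "window") <- window
  s
}

# NIPALS PLS1: X (n x p, centered), y (n, centered).  Returns the
# regression coefficient vectors for 1..ncomp components.
.pls1_nipals <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  W <- P <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  Xd <- X; yd <- y
  for (k in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- k - 1L; break }
    w <- w / nw
    t_ <- drop(Xd %*% w)
    tt <- sum(t_^2)
    p_ <- drop(crossprod(Xd, t_)) / tt
    q_ <- sum(yd * t_) / tt
    W[, k] <- w; P[, k] <- p_; Q[k] <- q_
    Xd <- Xd - tcrossprod(t_, p_)
    yd <- yd - q_ * t_
  }
  if (ncomp == 0L) stop("order parameter is constant: nothing to correlate")
  betas <- vector("list", ncomp)
  for (k in seq_len(ncomp)) {
    Wk <- W[, seq_len(k), drop = FALSE]
    Pk <- P[, seq_len(k), drop = FALSE]
    Rk <- Wk %*% solve(crossprod(Pk, Wk))
    betas[[k]] <- drop(Rk %*% Q[seq_len(k)])
  }
  betas
}

#' Fit a PLS functional mode model
#'
#' Regresses the order parameter on the centered backbone heavy-atom
#' coordinates of the training half (chronological split), evaluates the
#' Pearson correlation between model and data on both halves for 1 ..
#' \code{n_components} components, and extracts the ewMCM: the
#' displacement direction whose excitation maximally co-varies with the
#' order parameter, computed as the coordinate covariance applied to the
#' regression coefficients and unit-normalized.
#'
#' Frames are superposed on the mean structure of the training half
#' (backbone of \code{fit_residues}) before the regression unless
#' \code{superpose = FALSE}.
#'
#' @param traj \code{helix_trajectory}.
#' @param order Numeric order-parameter series (one value per frame).
#' @param n_components Maximum number of PLS components.
#' @param atom_residues Residues whose backbone heavy atoms (N, CA, C, O)
#'   enter the regression (default 29:52).
#' @param fit_residues Residues used for the superposition fit
#'   (default 31:35).
#' @param superpose Superpose frames before the regression.
#' @param plateau_tol Validation-correlation gain below which adding a
#'   component is considered a plateau.
#' @return Object of class \code{fma_model}: list with \code{ewmcm}
#'   (matrix n_atoms x 3, unit Frobenius norm), \code{beta},
#'   \code{r_train}, \code{r_valid} (per component count),
#'   \code{n_components} (selected), \code{atoms} (data.frame),
#'   \code{mean_structure}, \code{projection} (per-frame scalar),
#'   \code{order}.
#' @export
fit_pls_fma <- function(traj, order, n_components = 6,
                        atom_residues = 29:52, fit_residues = 31:35,
                        superpose = TRUE, plateau_tol = 0.02) {
  nf <- n_frames(traj)
  stopifnot(length(order) == nf, nf >= 10)
  if (stats::sd(order) == 0) {
    stop("order parameter is constant: nothing to correlate")
  }
  at <- traj$atoms
  sel <- which(at$residue_number %in% atom_residues &
                 at$atom %in% c("N", "CA", "C", "O"))
  fit_sel_local <- which(at$residue_number[sel] %in% fit_residues &
                           at$atom[sel] %in% c("N", "CA", "C", "O"))
  train <- seq_len(nf %/% 2)
  valid <- setdiff(seq_len(nf), train)

  coords <- traj$coords[, sel, , drop = FALSE]
  if (superpose) {
    mfit <- .iterative_mean_fit(coords[train, , , drop = FALSE],
                                fit_sel_local)
    ref <- mfit$mean
    for (f in seq_len(nf)) {
      fr <- coords[f, , , drop = FALSE][1, , ]
      ft <- kabsch_fit(fr[fit_sel_local, , drop = FALSE],
                       ref[fit_sel_local, , drop = FALSE])
      coords[f, , ] <- apply_fit(fr, ft)
    }
  }
  p <- length(sel) * 3L
  X <- matrix(coords, nrow = nf)     # frame-major flattening: [x.., y.., z..]
  mu <- colMeans(X[train, , drop = FALSE])
  Xc <- sweep(X, 2, mu)
  y_mu <- mean(order[train])
  yc <- order - y_mu

  betas <- .pls1_nipals(Xc[train, , drop = FALSE], yc[train],
                        min(n_components, length(train) - 1L))
  r_train <- r_valid <- numeric(length(betas))
  for (k in seq_along(betas)) {
    pred <- drop(Xc %*% betas[[k]])
    r_train[k] <- stats::cor(pred[train], order[train])
    r_valid[k] <- stats::cor(pred[valid], order[valid])
  }
  gain <- c(Inf, diff(r_valid))
  sel_k <- which(gain < plateau_tol)[1]
  if (is.na(sel_k)) sel_k <- length(betas) else sel_k <- max(sel_k - 1L, 1L)

  beta <- betas[[sel_k]]
  # ewMCM: ensemble (covariance) weighting of the coefficient direction
  Xt <- Xc[train, , drop = FALSE]
  ew <- drop(crossprod(Xt, Xt %*% beta)) / (length(train) - 1L)
  ew <- ew / sqrt(sum(ew^2))
  ewmcm <- matrix(ew, ncol = 3)      # rows = atoms (same flattening as X)

  mean_structure <- matrix(mu, ncol = 3)
  proj <- drop(sweep(X, 2, mu) %*% ew)

  out <- list(ewmcm = ewmcm, beta = beta,
              r_train = r_train, r_valid = r_valid,
              n_components = sel_k,
              atoms = at[sel, , drop = FALSE],
              mean_structure = mean_structure,
              projection = proj, order = order,
              train = train, valid = valid,
              centering = mu, y_center = y_mu)
  class(out) <- "fma_model"
  out
}

#' @export
print.fma_model <- function(x, ...) {
  cat(sprintf(
    "PLS functional mode model: %d component(s), %d atoms\n",
    x$n_components, nrow(x$atoms)))
  cat(sprintf("  R_m training %.3f / validation %.3f\n",
              x$r_train[x$n_components], x$r_valid[x$n_components]))
  invisible(x)
}

#' @export
coef.fma_model <- function(object, ...) object$ewmcm

#' @export
predict.fma_model <- function(object, traj = NULL, ...) {
  if (is.null(traj)) {
    drop(object$projection)
  } else {
    sel <- match(paste(object$atoms$residue_number, object$atoms$atom),
                 paste(traj$atoms$residue_number, traj$atoms$atom))
    X <- matrix(traj$coords[, sel, , drop = FALSE], nrow = n_frames(traj))
    object$y_center + drop(sweep(X, 2, object$centering) %*% object$beta)
  }
}

#' @export
plot.fma_model <- function(x, ...) {
  plot(seq_along(x$r_valid), x$r_valid, type = "b", ylim = range(0, 1),
       xlab = "PLS components", ylab = "R_m", ...)
  graphics::lines(seq_along(x$r_train), x$r_train, type = "b", col = 2)
  graphics::legend("bottomright", c("validation", "training"),
                   col = c(1, 2), lty = 1, bty = "n")
  invisible(x)
}

#' Overlap between two mode vectors
#'
#' Absolute inner product of two unit-normalized collective modes; 1 for
#' identical (or sign-flipped) motions, 0 for orthogonal ones.
#'
#' @param v1,v2 Mode vectors (matrices or flattened; same dimension).
#' @return Scalar in [0, 1].
#' @export
mode_overlap <- function(v1, v2) {
  a <- as.numeric(v1); b <- as.numeric(v2)
  if (length(a) != length(b)) stop("mode vectors have different dimensions")
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  abs(sum(a * b))
}

#' Conformations interpolated along a functional mode
#'
#' Generates structures \code{mean + a * ewMCM} for amplitudes \code{a}
#' on a linear grid between the observed projection extremes (or a given
#' range).  The two endpoints visualize the motion and can be fed to
#' \code{\link{classify_hinge_motion}}.
#'
#' @param model \code{fma_model}.
#' @param n_steps Number of conformations.
#' @param amplitude_range Numeric length-2; defaults to the observed
#'   projection range.
#' @return \code{helix_trajectory} whose frames are ordered from low to
#'   high amplitude.
#' @export
interpolate_along_mode <- function(model, n_steps = 10,
                                   amplitude_range = NULL) {
  if (is.null(amplitude_range)) amplitude_range <- range(model$projection)
  a <- if (n_steps == 1L) mean(amplitude_range) else
    seq(amplitude_range[1], amplitude_range[2], length.out = n_steps)
  na <- nrow(model$atoms)
  coords <- array(NA_real_, c(length(a), na, 3))
  for (i in seq_along(a)) {
    coords[i, , ] <- model$mean_structure + a[i] * model$ewmcm
  }
  helix_trajectory(model$atoms, coords, frame_interval_ps = NA_real_)
}
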