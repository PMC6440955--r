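# Segment-axis geometry of a helix trajectory: bending and swivel angles
# between an N-terminal and a C-terminal reference segment, local
# rise-per-residue, clustering of the angle space, free-energy surfaces
# from angle probabilities, and a simplified rotation-axis decomposition
# classifying hinge motions as bending or twisting.

#' Segment definition for bend/swivel analysis
#'
#' Defaults follow the reference segments of the substrate TM helix:
#' I31-M35 in the N-terminal half and I47-M51 (carrying the epsilon
#' cleavage sites) in the C-terminal half.
#'
#' @param tm_n_range,tm_c_range Integer residue-number vectors (>= 4
#'   residues each, disjoint).
#' @return Object of class \code{segment_definition}.
#' @export
segment_definition <- function(tm_n_range = 31:35, tm_c_range = 47:51) {
  stopifnot(length(tm_n_range) >= 4, length(tm_c_range) >= 4,
            !length(intersect(tm_n_range, tm_c_range)))
  structure(list(tm_n = tm_n_range, tm_c = tm_c_range),
            class = "segment_definition")
}

#' Fit the axis of a helical segment
#'
#' Default strategy (\code{"kahn"}): local axis directions from the cross
#' products of successive differences of C-alpha bond vectors (the
#' curvature vectors of the helix point at the axis, and their cross
#' product is axis-parallel), averaged along the segment.  This is exact
#' for an ideal helix at any segment length >= 4 and therefore suited to
#' the short 5-residue reference segments.  \code{"midpoint_pca"} fits
#' the principal direction of sliding-window C-alpha midpoints and is
#' useful for long segments.  The axis is sign-oriented from the
#' N-terminal to the C-terminal end of the segment.
#'
#' @param ca Matrix n x 3 of C-alpha coordinates (sequence order).
#' @param strategy \code{"kahn"} or \code{"midpoint_pca"}.
#' @return List with unit \code{axis} and \code{centroid}.
#' @export
fit_segment_axis <- function(ca, strategy = c("kahn", "midpoint_pca")) {
  strategy <- match.arg(strategy)
  n <- nrow(ca)
  if (n < 4) stop("axis fit needs at least 4 C-alpha positions")
  if (strategy == "kahn") {
    v <- diff(ca)                       # bond vectors
    a <- diff(v)                        # curvature vectors, point at axis
    if (nrow(a) < 2) stop("degenerate segment")
    axes <- vapply(seq_len(nrow(a) - 1L), function(i) {
      cr <- cross3(a[i, ], a[i + 1L, ])
      if (vnorm(cr) < 1e-10) return(c(NA_real_, NA_real_, NA_real_))
      unit(cr)
    }, numeric(3))
    axes <- t(axes)
    axes <- axes[stats::complete.cases(axes), , drop = FALSE]
    if (nrow(axes)) {
      ref <- axes[1, ]
      flip <- (axes %*% ref)[, 1] < 0
      axes[flip, ] <- -axes[flip, ]
      axis <- unit(colMeans(axes))
    } else {
      # near-planar (e.g. extended) chain: curvature cross products vanish;
      # fall back to the principal direction of the positions themselves
      sv <- svd(sweep(ca, 2, colMeans(ca)))
      if (sv$d[2] / sv$d[1] < 1e-8) {
        stop("collinear/degenerate segment: no axis")
      }
      axis <- sv$v[, 1]
    }
  } else {
    w <- 4L
    if (n < w + 1L) stop("midpoint_pca needs at least 5 C-alpha positions")
    mids <- t(vapply(seq_len(n - w + 1L), function(i) {
      colMeans(ca[i:(i + w - 1L), , drop = FALSE])
    }, numeric(3)))
    if (nrow(mids) < 2) stop("degenerate segment")
    axis <- svd(sweep(mids, 2, colMeans(mids)))$v[, 1]
  }
  if (sum((ca[n, ] - ca[1, ]) * axis) < 0) axis <- -axis
  list(axis = unit(axis), centroid = colMeans(ca))
}

.segment_ca <- function(traj, residues, frame) {
  idx <- vapply(residues, function(r) atom_index(traj, r, "CA"), integer(1))
  if (anyNA(idx)) stop("segment residue(s) missing C-alpha atoms")
  traj$coords[frame, idx, , drop = FALSE][1, , ]
}

#' Bending and swivel angles between two helix segments
#'
#' Per frame, fits both segment axes and reports the bending angle theta
#' (angle between the axes, degrees in [0, 180]) and the swivel angle
#' Phi: the azimuth of the C-terminal axis about the N-terminal axis,
#' measured from a reference direction anchored at a fixed C-alpha
#' (default G33) projected perpendicular to the N-terminal axis.  The
#' zero of Phi is an arbitrary but fixed convention; consumers must
#' treat Phi on the circle.
#'
#' @param traj \code{helix_trajectory}.
#' @param segments \code{\link{segment_definition}}.
#' @param phi_anchor Residue number anchoring the Phi = 0 direction.
#' @param strategy Axis strategy, see \code{\link{fit_segment_axis}}.
#' @return data.frame of class \code{bend_swivel_series}: columns
#'   \code{frame}, \code{theta}, \code{phi}; frames whose axis fit failed
#'   are excluded and counted in attribute \code{n_excluded}.
#' @export
bend_swivel <- function(traj, segments = segment_definition(),
                        phi_anchor = 33, strategy = "kahn") {
  nf <- n_frames(traj)
  theta <- phi <- rep(NA_real_, nf)
  anchor_idx <- atom_index(traj, phi_anchor, "CA")
  if (is.na(anchor_idx)) stop("Phi anchor residue has no C-alpha")
  for (f in seq_len(nf)) {
    fitN <- tryCatch(
      fit_segment_axis(.segment_ca(traj, segments$tm_n, f), strategy),
      error = function(e) NULL)
    fitC <- tryCatch(
      fit_segment_axis(.segment_ca(traj, segments$tm_c, f), strategy),
      error = function(e) NULL)
    if (is.null(fitN) || is.null(fitC)) next
    theta[f] <- vec_angle(fitN$axis, fitC$axis)
    anchor <- traj$coords[f, anchor_idx, ]
    ref <- anchor - fitN$centroid
    ref_perp <- ref - sum(ref * fitN$axis) * fitN$axis
    if (vnorm(ref_perp) < 1e-9) next
    phi[f] <- signed_angle_about(ref_perp, fitC$axis, fitN$axis)
  }
  keep <- is.finite(theta) & is.finite(phi)
  out <- data.frame(frame = which(keep), theta = theta[keep],
                    phi = phi[keep])
  structure(out, n_excluded = sum(!keep),
            class = c("bend_swivel_series", "data.frame"))
}

#' Local rise per residue
#'
#' Projection of the C-alpha(i) to C-alpha(i+1) vector onto the local
#' helix axis fitted over the window i-2 .. i+3.  The canonical alpha
#' helix rises ~0.15 nm per residue; an extended chain ~0.35 nm.
#'
#' @param traj \code{helix_trajectory}.
#' @param position Residue number i.
#' @return Numeric vector (one rise per frame, nm); attribute
#'   \code{truncated} marks a window cut at the termini.
#' @export
rise_per_residue <- function(traj, position) {
  res <- traj_residues(traj)
  lo <- max(min(res), position - 2)
  hi <- min(max(res), position + 3)
  truncated <- (lo > position - 2) || (hi < position + 3)
  win <- lo:hi
  if (length(win) < 4 || !(position + 1) %in% res) {
    stop("window too short at position ", position)
  }
  nf <- n_frames(traj)
  i0 <- atom_index(traj, position, "CA")
  i1 <- atom_index(traj, position + 1, "CA")
  rise <- vapply(seq_len(nf), function(f) {
    ax <- fit_segment_axis(.segment_ca(traj, win, f))$axis
    sum((traj$coords[f, i1, ] - traj$coords[f, i0, ]) * ax)
  }, numeric(1))
  attr(rise, "truncated") <- truncated
  rise
}

#' K-means clustering of bend/swivel angles
#'
#' Clusters frames on the planar embedding (theta cos Phi, theta sin Phi)
#' so that the swivel periodicity is respected, then maps centroids back
#' to (theta, Phi) and reports member counts and the frame nearest each
#' centroid as the cluster representative.
#'
#' @param series \code{bend_swivel_series}.
#' @param k Number of clusters.
#' @param seed Seed for the k-means initialization.
#' @param nstart Restarts.
#' @return List with \code{centers} (data.frame theta/phi/size/
#'   representative_frame) and the \code{stats::kmeans} fit.
#' @export
cluster_angles <- function(series, k, seed = 1L, nstart = 10L) {
  stopifnot(nrow(series) >= 1, k >= 1)
  if (k > nrow(series)) stop("k exceeds the number of frames")
  th <- series$theta; ph <- series$phi * pi / 180
  X <- cbind(x = th * cos(ph), y = th * sin(ph))
  set.seed(seed)
  km <- stats::kmeans(X, centers = min(k, nrow(unique(X))),
                      nstart = nstart)
  cen <- km$centers
  theta_c <- sqrt(rowSums(cen^2))
  phi_c <- atan2(cen[, 2], cen[, 1]) * 180 / pi
  rep_frame <- vapply(seq_len(nrow(cen)), function(j) {
    d2 <- rowSums(sweep(X, 2, cen[j, ])^2)
    series$frame[which.min(replace(d2, km$cluster != j, Inf))]
  }, numeric(1))
  list(centers = data.frame(theta = theta_c, phi = phi_c,
                            size = km$size,
                            representative_frame = rep_frame),
       kmeans = km)
}

#' Free-energy surface over bend/swivel angles
#'
#' Bins the angle series, converts bin probabilities to free energies
#' \code{G = -RT log p} (kcal/mol) and shifts the minimum to zero.
#' Empty bins are NA (undefined), not infinite.
#'
#' @param series \code{bend_swivel_series}.
#' @param temperature Kelvin.
#' @param theta_breaks,phi_breaks Bin edges (degrees).
#' @return List with \code{G} (matrix theta x phi), bin mid-points and
#'   the probability matrix.
#' @export
angle_free_energy <- function(series, temperature = 293,
                              theta_breaks = seq(0, 90, by = 5),
                              phi_breaks = seq(-180, 180, by = 20)) {
  th <- cut(series$theta, theta_breaks, include.lowest = TRUE)
  ph <- cut(series$phi, phi_breaks, include.lowest = TRUE)
  counts <- table(th, ph)
  p <- counts / sum(counts)
  RT <- .R_kcal * temperature
  G <- -RT * log(p)
  G[counts == 0] <- NA
  G <- G - min(G, na.rm = TRUE)
  mids <- function(b) (b[-1] + b[-length(b)]) / 2
  list(G = unclass(G), theta_mid = mids(theta_breaks),
       phi_mid = mids(phi_breaks), p = unclass(p),
       temperature = temperature)
}

# local deformation profile between two conformations: residual RMSD of
# a 5-residue window of A fitted onto the same window of B
.local_deformation <- function(ca_a, ca_b, half = 2L) {
  n <- nrow(ca_a)
  vapply(seq_len(n), function(i) {
    w <- max(1, i - half):min(n, i + half)
    if (length(w) < 3) return(NA_real_)
    ft <- kabsch_fit(ca_a[w, , drop = FALSE], ca_b[w, , drop = FALSE])
    sqrt(mean(rowSums((apply_fit(ca_a[w, , drop = FALSE], ft) -
                         ca_b[w, , drop = FALSE])^2)))
  }, numeric(1))
}

#' Classify a conformational change as hinge bending or twisting
#'
#' Simplified rotation-axis decomposition between quasi-rigid segments:
#' conformation B is superposed on conformation A over the N-terminal
#' segment, the residual rotation of the C-terminal segment is extracted
#' (Kabsch), and its axis is decomposed against the inter-segment
#' direction.  A rotation axis perpendicular to the inter-segment axis
#' closes/opens the structure (bending, type B); an axis parallel to it
#' twists (type T).  Percent closure = 100 sin^2(angle between rotation
#' axis and inter-segment axis); type B if closure > 50.  Hinge residues
#' are the contiguous positions between the rigid segments whose local
#' deformation exceeds the rigid-segment baseline.  When two disjoint
#' deformation regions are found the motion is split at the middle block
#' and each hinge is classified separately (double-hinge types BB, BT,
#' TB, TT).
#'
#' @param conf_a,conf_b Matrices n_res x 3 of C-alpha coordinates (same
#'   topology), or single-frame \code{helix_trajectory} objects.
#' @param segments \code{\link{segment_definition}}.
#' @param residues Residue numbers corresponding to the C-alpha rows
#'   (required when matrices are supplied without names).
#' @param min_angle Rotations below this angle (degrees) are reported as
#'   "no significant motion".
#' @return Object of class \code{hinge_classification}: list with
#'   \code{type} ("B", "T", "BB", ..., or "none"), \code{angle},
#'   \code{closure_pct}, \code{hinge_residues}, \code{deformation}.
#' @export
classify_hinge_motion <- function(conf_a, conf_b,
                                  segments = segment_definition(),
                                  residues = NULL, min_angle = 2) {
  get_ca <- function(x) {
    if (inherits(x, "helix_trajectory")) {
      idx <- which(x$atoms$atom == "CA")
      list(ca = frame_coords(x, 1)[idx, ],
           res = x$atoms$residue_number[idx])
    } else list(ca = x, res = residues)
  }
  A <- get_ca(conf_a); B <- get_ca(conf_b)
  if (is.null(A$res)) stop("supply residue numbers for coordinate matrices")
  stopifnot(nrow(A$ca) == nrow(B$ca))
  res <- A$res
  segN <- match(segments$tm_n, res); segC <- match(segments$tm_c, res)
  if (anyNA(segN) || anyNA(segC)) stop("segments not contained in residues")

  # superpose B on A over segment N
  ftN <- kabsch_fit(B$ca[segN, , drop = FALSE], A$ca[segN, , drop = FALSE])
  Bfit <- apply_fit(B$ca, ftN)

  classify_pair <- function(idx_fixed, idx_moving) {
    ft <- kabsch_fit(Bfit[idx_moving, , drop = FALSE],
                     A$ca[idx_moving, , drop = FALSE])
    ra <- rotation_angle_axis(t(ft$R))   # rotation taking A-seg onto B-seg
    inter <- unit(colMeans(A$ca[idx_moving, , drop = FALSE]) -
                    colMeans(A$ca[idx_fixed, , drop = FALSE]))
    psi <- vec_angle(ra$axis, inter)
    closure <- 100 * sin(psi * pi / 180)^2
    list(angle = ra$angle, axis = ra$axis, closure_pct = closure,
         type = if (closure > 50) "B" else "T")
  }

  deform <- .local_deformation(A$ca, Bfit)
  between <- seq(max(segN) + 1L, min(segC) - 1L)
  baseline <- max(deform[c(segN, segC)], na.rm = TRUE)
  hot <- between[deform[between] > baseline * 1.5 + 1e-4]
  runs <- if (length(hot)) split(hot, cumsum(c(1, diff(hot) > 1))) else list()

  main <- classify_pair(segN, segC)
  out <- list(angle = main$angle, closure_pct = main$closure_pct,
              deformation = stats::setNames(deform, res),
              hinge_residues = res[hot])
  class(out) <- "hinge_classification"
  if (main$angle < min_angle) {
    out$type <- "none"
    return(out)
  }
  if (length(runs) >= 2L) {
    # double hinge: classify each rotation against the middle rigid block
    mid <- seq(max(runs[[1]]) + 1L, min(runs[[2]]) - 1L)
    if (length(mid) >= 4L) {
      c1 <- classify_pair(segN, mid)
      ftM <- kabsch_fit(Bfit[mid, , drop = FALSE],
                        A$ca[mid, , drop = FALSE])
      Bfit2 <- apply_fit(Bfit, ftM)
      ft2 <- kabsch_fit(Bfit2[segC, , drop = FALSE],
                        A$ca[segC, , drop = FALSE])
      ra2 <- rotation_angle_axis(t(ft2$R))
      inter2 <- unit(colMeans(A$ca[segC, , drop = FALSE]) -
                       colMeans(A$ca[mid, , drop = FALSE]))
      psi2 <- vec_angle(ra2$axis, inter2)
      t2 <- if (100 * sin(psi2 * pi / 180)^2 > 50) "B" else "T"
      out$type <- paste0(c1$type, t2)
      out$hinges <- list(res[runs[[1]]], res[runs[[2]]])
      return(out)
    }
  }
  out$type <- main$type
  out
}

#' @export
print.hinge_classification <- function(x, ...) {
  cat(sprintf("hinge motion type %s: rotation %.1f deg, closure %.0f%%\n",
              x$type, x$angle, x$closure_pct))
  if (length(x$hinge_residues)) {
    cat("  hinge residues:", paste(x$hinge_residues, collapse = ", "), "\n")
  }
  invisible(x)
}
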