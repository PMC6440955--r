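# Residue-resolved amide exchange kinetics under the EX2 regime:
# overall remaining-deuteron curves, ETD fragment-ladder localization,
# single-exponential site fits with a residual-label baseline, and
# Linderstroem-Lang hydrogen-bond opening free energies.

.EX2_AMPLITUDE <- 0.95
.EX2_BASELINE  <- 0.05

#' Overall exchange curve from centroid masses
#'
#' Converts a time series of isotope-envelope centroid masses into the
#' number of remaining deuterons,
#' \code{D(t) = (centroid(t) - all_H_mass) / per_deuteron_shift}.  When an
#' observed long-time plateau is supplied the curve is rescaled linearly
#' so that the plateau maps onto the theoretical residual level
#' \code{residual_label_fraction * n_amides} (the back-exchange floor left
#' by the labelling-solvent carry-over after dilution).
#'
#' @param times Incubation times (minutes).
#' @param centroid_masses Centroid masses (Da), charge-reduced.
#' @param all_H_mass Centroid of the fully protonated species (Da).
#' @param per_deuteron_shift Mass shift per deuteron (Da), default 1.00628.
#' @param conditions \code{\link{exchange_conditions}}.
#' @param n_amides Number of exchanging backbone amides.
#' @param plateau_observed Optional observed t -> Inf deuteron count used
#'   to anchor the dilution correction.
#' @return data.frame of class \code{overall_exchange_curve} with columns
#'   \code{time_min}, \code{mean_D}, \code{sem}, \code{n}.
#' @export
overall_curve_from_centroids <- function(times, centroid_masses, all_H_mass,
                                         per_deuteron_shift = 1.00628,
                                         conditions = exchange_conditions(),
                                         n_amides,
                                         plateau_observed = NULL) {
  stopifnot(length(times) == length(centroid_masses),
            !is.unsorted(times, strictly = TRUE))
  D <- (centroid_masses - all_H_mass) / per_deuteron_shift
  if (any(D < -1e-6 * n_amides)) {
    stop("centroid below the all-H reference: negative deuteron content")
  }
  D[D < 0] <- 0
  if (!is.null(plateau_observed)) {
    target <- conditions$residual_label_fraction * n_amides
    if (plateau_observed <= 0) stop("plateau_observed must be positive")
    D <- D * target / plateau_observed
  }
  overall_exchange_curve(times, D, n_amides = n_amides)
}

#' Construct an overall exchange curve object
#'
#' @param time_min Times in minutes (strictly increasing).
#' @param mean_D Mean remaining deuterons.
#' @param sem Standard error of the mean (optional).
#' @param n Replicates per point.
#' @param n_amides Number of exchanging amides (attribute).
#' @return data.frame of class \code{overall_exchange_curve}.
#' @export
overall_exchange_curve <- function(time_min, mean_D, sem = NA_real_, n = 1L,
                                   n_amides = NULL) {
  stopifnot(!is.unsorted(time_min, strictly = TRUE), all(mean_D >= 0))
  if (is.null(n_amides)) n_amides <- ceiling(max(mean_D))
  if (any(mean_D > n_amides + 1e-6)) {
    stop("remaining deuterons exceed the number of labile amides")
  }
  structure(data.frame(time_min = time_min, mean_D = mean_D,
                       sem = sem, n = n),
            n_amides = n_amides,
            class = c("overall_exchange_curve", "data.frame"))
}

# ETD amide bookkeeping.  ETD cleaves the N-Calpha bond of residue n+1 to
# give c_n / z_(N-n); the amide hydrogen of the cleaved residue travels
# with the c fragment.  Hence a c_n fragment carries the backbone amide
# deuterons of residues 1..n+1 and a z_m fragment those of residues
# N-m+2..N, and adjacent-fragment differences localize single amides:
# c_n - c_(n-1) -> residue n+1;  z_m - z_(m-1) -> residue N-m+2.
# This convention is centralized here and used identically by the
# synthetic generator and the analysis path.
etd_amide_span <- function(ion_type, fragment_length, n_residues) {
  if (ion_type == "c") return(seq_len(min(fragment_length + 1L, n_residues)))
  start <- max(n_residues - fragment_length + 2L, 1L)
  if (start > n_residues) return(integer(0))
  seq.int(start, n_residues)
}

etd_difference_residue <- function(ion_type, fragment_length, n_residues) {
  if (ion_type == "c") fragment_length + 1L
  else n_residues - fragment_length + 2L
}

#' Residue-level deuteron content from ETD fragment ladders
#'
#' Differences adjacent c fragments (and, independently, adjacent z
#' fragments) to localize deuterons to single backbone amides, averages
#' replicates, and combines the two ladders by inverse-variance weighting
#' where both cover a residue.  Residues covered by only one ladder are
#' reported from that ladder; the two terminal amides are never singly
#' resolved by either ladder.
#'
#' @param fragments data.frame with columns \code{ion_type} ("c"/"z"),
#'   \code{fragment_length}, \code{replicate}, \code{time_min},
#'   \code{deuterons}.
#' @param peptide \code{\link{peptide_spec}}.
#' @param tolerance Absolute c-vs-z disagreement (deuterons) above which a
#'   warning is emitted; both values are retained in the output.
#' @return data.frame of class \code{residue_content} with columns
#'   \code{residue_number}, \code{time_min}, \code{content}, \code{se},
#'   \code{n_obs}, \code{source} plus per-ladder columns \code{content_c},
#'   \code{content_z}.
#' @export
residue_content_from_fragments <- function(fragments, peptide,
                                           tolerance = 0.2) {
  need <- c("ion_type", "fragment_length", "replicate", "time_min",
            "deuterons")
  stopifnot(all(need %in% names(fragments)),
            inherits(peptide, "peptide_spec"))
  n_res <- length(peptide$residues)

  ladder_estimates <- function(ion) {
    fr <- fragments[fragments$ion_type == ion, ]
    if (!nrow(fr)) return(NULL)
    out <- list()
    for (rep_id in unique(fr$replicate)) {
      for (tm in unique(fr$time_min)) {
        sub <- fr[fr$replicate == rep_id & fr$time_min == tm, ]
        sub <- sub[order(sub$fragment_length), ]
        len <- sub$fragment_length
        adj <- which(diff(len) == 1L)
        if (!length(adj)) next
        resi <- vapply(len[adj + 1L], etd_difference_residue,
                       integer(1), ion_type = ion, n_residues = n_res)
        out[[length(out) + 1L]] <- data.frame(
          residue = resi, time_min = tm, replicate = rep_id,
          d = sub$deuterons[adj + 1L] - sub$deuterons[adj])
      }
    }
    if (!length(out)) return(NULL)
    do.call(rbind, out)
  }

  summarize <- function(est) {
    if (is.null(est)) return(NULL)
    agg <- stats::aggregate(d ~ residue + time_min, est, function(v) {
      c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)), n = length(v))
    })
    data.frame(residue_number = peptide$numbering[agg$residue],
               time_min = agg$time_min,
               content = agg$d[, "mean"], se = agg$d[, "se"],
               n_obs = agg$d[, "n"])
  }

  cs <- summarize(ladder_estimates("c"))
  zs <- summarize(ladder_estimates("z"))
  if (is.null(cs) && is.null(zs)) stop("no adjacent fragment pairs found")

  key <- function(d) paste(d$residue_number, d$time_min)
  all_keys <- union(if (is.null(cs)) character() else key(cs),
                    if (is.null(zs)) character() else key(zs))
  rows <- lapply(all_keys, function(k) {
    ci <- if (!is.null(cs)) match(k, key(cs)) else NA_integer_
    zi <- if (!is.null(zs)) match(k, key(zs)) else NA_integer_
    cc <- if (!is.na(ci)) cs[ci, ] else NULL
    zz <- if (!is.na(zi)) zs[zi, ] else NULL
    ref <- if (!is.null(cc)) cc else zz
    if (!is.null(cc) && !is.null(zz)) {
      if (is.finite(cc$content - zz$content) &&
          abs(cc$content - zz$content) > tolerance) {
        warning(sprintf(
          "c/z disagreement at residue %d, t=%g min: c=%.3f z=%.3f",
          ref$residue_number, ref$time_min, cc$content, zz$content))
      }
      wc <- if (is.finite(cc$se) && cc$se > 0) 1 / cc$se^2 else NA
      wz <- if (is.finite(zz$se) && zz$se > 0) 1 / zz$se^2 else NA
      if (is.na(wc) || is.na(wz)) { wc <- wz <- 1 }
      est <- (wc * cc$content + wz * zz$content) / (wc + wz)
      se <- sqrt(1 / (wc + wz))
      if (!is.finite(se)) se <- NA_real_
      data.frame(residue_number = ref$residue_number, time_min = ref$time_min,
                 content = est, se = se, n_obs = cc$n_obs + zz$n_obs,
                 source = "cz", content_c = cc$content, content_z = zz$content)
    } else {
      data.frame(residue_number = ref$residue_number, time_min = ref$time_min,
                 content = ref$content, se = ref$se, n_obs = ref$n_obs,
                 source = if (!is.null(cc)) "c" else "z",
                 content_c = if (!is.null(cc)) cc$content else NA_real_,
                 content_z = if (!is.null(zz)) zz$content else NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$residue_number, out$time_min), ]
  rownames(out) <- NULL
  structure(out, peptide = peptide$name,
            class = c("residue_content", "data.frame"))
}

#' Map incubation time across pH (base-catalysed regime)
#'
#' In the base-catalysed regime the intrinsic rate is first order in
#' hydroxide, so incubating for \code{t} at \code{ph_actual} is
#' equivalent to \code{t * 10^(ph_actual - ph_reference)} at the
#' reference pH.  If an intrinsic-rate profile is supplied the
#' precondition that base catalysis carries at least 95 percent of the
#' exchange is checked at both pH values.
#'
#' @param t Time (minutes).
#' @param ph_actual,ph_reference Operational pH values.
#' @param peptide Optional \code{\link{peptide_spec}} used to verify base
#'   dominance at both pH values.
#' @param direction Exchange direction for the check.
#' @return Equivalent time at \code{ph_reference}, in minutes.
#' @export
map_ph_time <- function(t, ph_actual, ph_reference, peptide = NULL,
                        direction = "DHX") {
  if (!is.null(peptide)) {
    for (ph in c(ph_actual, ph_reference)) {
      prof <- compute_intrinsic_rates(
        peptide, exchange_conditions(ph, direction = direction))
      frac <- base_catalysis_fraction(prof)
      if (min(frac, na.rm = TRUE) < 0.95) {
        stop("base catalysis below 95% at pH ", ph,
             "; map acid/base/water components separately")
      }
    }
  }
  t * 10^(ph_actual - ph_reference)
}

#' Fit a single-site exchange rate
#'
#' Weighted least-squares fit of the EX2 single-amide model
#' \code{y(t) = 0.95 exp(-k t) + 0.05}: full amplitude minus the 5 percent
#' residual-label floor.  Weights are inverse variances when standard
#' errors are available for at least two points, otherwise the fit is
#' unweighted.
#'
#' @param time_min Times (minutes), at least 4 points spanning a decade.
#' @param y Deuteron fraction remaining at each time.
#' @param se Optional standard errors of \code{y}.
#' @param amplitude,baseline Model constants (defaults 0.95 / 0.05).
#' @return Object of class \code{site_rate_fit}: list with \code{k},
#'   \code{k_se}, \code{flag} ("ok", "at_floor", "no_convergence"),
#'   \code{residual_norm}, \code{fitted}.
#' @export
fit_site_rate <- function(time_min, y, se = NULL,
                          amplitude = .EX2_AMPLITUDE,
                          baseline = .EX2_BASELINE) {
  ok <- is.finite(time_min) & is.finite(y)
  time_min <- time_min[ok]; y <- y[ok]
  if (!is.null(se)) se <- se[ok]
  if (length(y) < 4L) stop("need at least 4 time points")
  pos <- time_min[time_min > 0]
  if (length(pos) < 2L || max(pos) / min(pos) < 10) {
    stop("time points must span at least one decade")
  }
  out <- list(k = NA_real_, k_se = NA_real_, flag = "ok",
              residual_norm = NA_real_, fitted = NULL,
              time_min = time_min, y = y)
  class(out) <- "site_rate_fit"
  # unidentifiable: signal never rises meaningfully above the floor
  noise <- if (!is.null(se) && any(is.finite(se) & se > 0)) {
    stats::median(se[is.finite(se)])
  } else 0.02
  if (max(y) < baseline + 3 * noise + 0.01) {
    out$flag <- "at_floor"
    out$k_lower_bound <- log(amplitude / max(noise, 0.01)) / min(pos)
    return(out)
  }
  usable <- y > baseline + 1e-3 & time_min > 0
  k0 <- if (sum(usable) >= 2) {
    sl <- stats::coef(stats::lm(log((y[usable] - baseline) / amplitude)
                                ~ 0 + time_min[usable]))[[1]]
    max(-sl, 1e-8)
  } else 1 / max(pos)
  w <- if (!is.null(se) && sum(is.finite(se) & se > 0) >= 2) {
    wv <- 1 / se^2; wv[!is.finite(wv)] <- max(wv[is.finite(wv)]); wv
  } else rep(1, length(y))
  df <- data.frame(t = time_min, y = y, w = w)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ amplitude * exp(-k * t) + baseline, data = df,
                      start = list(k = k0), weights = w,
                      lower = c(k = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) { out$flag <- "no_convergence"; return(out) }
  sm <- summary(fit)
  out$k <- sm$coefficients["k", "Estimate"]
  out$k_se <- sm$coefficients["k", "Std. Error"]
  out$fitted <- stats::fitted(fit)
  out$residual_norm <- sqrt(sum((stats::residuals(fit))^2))
  out
}

#' @export
print.site_rate_fit <- function(x, ...) {
  if (x$flag == "ok") {
    cat(sprintf("site rate fit: k = %.4g +/- %.2g /min (residual %.3g)\n",
                x$k, x$k_se, x$residual_norm))
  } else {
    cat("site rate fit:", x$flag, "\n")
    if (!is.null(x$k_lower_bound)) {
      cat(sprintf("  k bounded below ~%.3g /min is unresolvable here\n",
                  x$k_lower_bound))
    }
  }
  invisible(x)
}

#' @export
coef.site_rate_fit <- function(object, ...) c(k = object$k)

#' Fit exchange rates for every covered residue
#'
#' Applies \code{\link{fit_site_rate}} to each residue of a
#' \code{residue_content} table.
#'
#' @param content Output of \code{\link{residue_content_from_fragments}}
#'   (or the generator's noiseless equivalent).
#' @param direction Exchange direction recorded on the result.
#' @return data.frame of class \code{residue_rate_profile}: columns
#'   \code{residue_number}, \code{k_exp}, \code{se}, \code{flag}.
#' @export
fit_rate_profile <- function(content, direction = "DHX") {
  res <- sort(unique(content$residue_number))
  rows <- lapply(res, function(r) {
    sub <- content[content$residue_number == r, ]
    f <- tryCatch(fit_site_rate(sub$time_min, sub$content, sub$se),
                  error = function(e) NULL)
    if (is.null(f)) {
      data.frame(residue_number = r, k_exp = NA_real_, se = NA_real_,
                 flag = "fit_error")
    } else {
      data.frame(residue_number = r, k_exp = f$k, se = f$k_se, flag = f$flag)
    }
  })
  out <- do.call(rbind, rows)
  structure(out, direction = direction,
            class = c("residue_rate_profile", "data.frame"))
}

#' EX2 hydrogen-bond opening free energies
#'
#' Linderstroem-Lang free energy of the amide hydrogen-bond opening
#' equilibrium under EX2 exchange,
#' \code{DeltaG = -RT log(k_exp / (k_ch - k_exp))}, defined only where the
#' observed rate is below the intrinsic rate.  Positions with
#' \code{k_exp >= k_ch} are flagged \code{undefined}; positions within two
#' standard errors of \code{k_ch} are flagged \code{lower_bound} (the
#' point estimate there is a lower bound on the true stability).
#' Confidence intervals are propagated from the rate standard errors by
#' Monte-Carlo sampling; draws violating \code{k_exp < k_ch} are rejected
#' and counted.
#'
#' @param rates \code{residue_rate_profile}.
#' @param chem \code{intrinsic_rate_profile} for the same peptide and
#'   conditions.
#' @param temperature Kelvin.
#' @param n_mc Monte-Carlo draws for the interval.
#' @param seed Seed for the propagation.
#' @return data.frame of class \code{delta_g_profile}: columns
#'   \code{residue_number}, \code{residue}, \code{delta_g} (kcal/mol),
#'   \code{ci_lo}, \code{ci_hi}, \code{flag}.
#' @export
delta_g <- function(rates, chem, temperature = 293.15, n_mc = 2000,
                    seed = 1L) {
  stopifnot(inherits(rates, "residue_rate_profile"),
            inherits(chem, "intrinsic_rate_profile"))
  idx <- match(rates$residue_number, chem$residue_number)
  if (any(is.na(idx))) stop("rate profile has residues absent from the ",
                            "intrinsic profile: mismatched sequences?")
  RT <- .R_kcal * temperature
  n <- nrow(rates)
  dg <- lo <- hi <- rep(NA_real_, n)
  flag <- rep("ok", n)
  for (i in seq_len(n)) {
    ke <- rates$k_exp[i]; se <- rates$se[i]; kc <- chem$k_ch[idx[i]]
    if (!is.finite(ke) || !is.finite(kc)) { flag[i] <- "no_rate"; next }
    if (ke >= kc) { flag[i] <- "undefined"; next }
    dg[i] <- -RT * log(ke / (kc - ke))
    if (is.finite(se) && ke + 2 * se >= kc) flag[i] <- "lower_bound"
    if (is.finite(se) && se > 0) {
      mc <- mc_propagate(function(x) {
        if (x[1] <= 0 || x[1] >= kc) return(NA_real_)
        -RT * log(x[1] / (kc - x[1]))
      }, mean = ke, se = se, n = n_mc, seed = seed + i)
      lo[i] <- mc$lower; hi[i] <- mc$upper
      if (attr(mc, "rejected_fraction") > 0.5) flag[i] <- "lower_bound"
    }
  }
  out <- data.frame(residue_number = rates$residue_number,
                    residue = chem$residue[idx],
                    delta_g = dg, ci_lo = lo, ci_hi = hi, flag = flag,
                    stringsAsFactors = FALSE)
  structure(out, temperature = temperature, R = .R_kcal,
            class = c("delta_g_profile", "data.frame"))
}

#' Reconstruct overall kinetics from site rates
#'
#' \code{D(t) = sum_i [0.95 exp(-k_i t) + 0.05]} over all amides.
#' Residues without a fitted rate contribute through a configurable
#' bound: \code{"slow"} (rate 0, deuteron retained), \code{"fast"}
#' (instant loss to the floor) or a numeric rate.
#'
#' @param rates \code{residue_rate_profile} (or numeric vector of rates).
#' @param times Evaluation times (minutes).
#' @param undefined How undefined positions contribute (see above).
#' @param amplitude,baseline Model constants.
#' @return \code{overall_exchange_curve}.
#' @export
reconstruct_overall <- function(rates, times, undefined = "slow",
                                amplitude = .EX2_AMPLITUDE,
                                baseline = .EX2_BASELINE) {
  k <- if (is.data.frame(rates)) rates$k_exp else as.numeric(rates)
  if (anyNA(k)) {
    k[is.na(k)] <- if (identical(undefined, "slow")) 0
      else if (identical(undefined, "fast")) Inf
      else as.numeric(undefined)
  }
  D <- vapply(times, function(t) {
    e <- exp(-k * t)
    e[k == Inf] <- if (t > 0) 0 else 1   # instant loss, but D(0) stays full
    sum(amplitude * e + baseline)
  }, numeric(1))
  overall_exchange_curve(times, D, n_amides = length(k))
}

#' Time-scale factor superposing two exchange curves
#'
#' Finds the factor \code{s} minimizing the squared discrepancy between
#' \code{D_a(t)} and \code{D_b(t / s)} over a logarithmic time grid
#' restricted to the overlap of the two curves.  Two kinetics that differ
#' only by a uniform rate factor \code{s} (e.g. HDX vs DHX with a common
#' chemical-rate ratio) superpose at that \code{s}.
#'
#' @param curve_a,curve_b \code{overall_exchange_curve} objects.
#' @param n_grid Points of the evaluation grid.
#' @param s_range Log10 search interval for \code{s}.
#' @return List with \code{s}, \code{residual} (mean squared discrepancy)
#'   and the grid used.
#' @export
superpose_scale <- function(curve_a, curve_b, n_grid = 200,
                            s_range = c(-2, 2)) {
  ta <- curve_a$time_min; tb <- curve_b$time_min
  pa <- ta > 0; pb <- tb > 0
  if (sum(pa) < 2 || sum(pb) < 2) stop("need positive time points")
  interp <- function(tt, t, v) {
    stats::approx(log(t), v, xout = log(tt), rule = 1)$y
  }
  objective <- function(log10s) {
    s <- 10^log10s
    lo <- max(min(ta[pa]), min(tb[pb]) * s)
    hi <- min(max(ta[pa]), max(tb[pb]) * s)
    if (!(hi > lo)) return(NA_real_)
    grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
    da <- interp(grid, ta[pa], curve_a$mean_D[pa])
    db <- interp(grid / s, tb[pb], curve_b$mean_D[pb])
    mean((da - db)^2)
  }
  probe <- seq(s_range[1], s_range[2], by = 0.05)
  vals <- vapply(probe, objective, numeric(1))
  if (all(is.na(vals))) stop("curves have no overlapping dynamic range")
  i0 <- which.min(vals)
  lo <- probe[max(1, i0 - 2)]; hi <- probe[min(length(probe), i0 + 2)]
  opt <- stats::optimize(objective, c(lo, hi))
  list(s = 10^opt$minimum, residual = opt$objective,
       grid_points = n_grid)
}

#' Per-residue HDX/DHX observed-rate ratio
#'
#' Ratio \code{k_exp,HDX / k_exp,DHX} per residue, with Monte-Carlo
#' propagated intervals.  Positions where either rate is undefined are
#' flagged rather than propagated as NaN.
#'
#' @param dhx,hdx \code{residue_rate_profile} objects on the same residue
#'   numbering.
#' @param n_mc,seed Monte-Carlo settings.
#' @return data.frame of class \code{isotope_ratio_profile} with columns
#'   \code{residue_number}, \code{ratio}, \code{ci_lo}, \code{ci_hi},
#'   \code{flag}.
#' @export
isotope_ratio_profile <- function(dhx, hdx, n_mc = 2000, seed = 1L) {
  common <- intersect(dhx$residue_number, hdx$residue_number)
  rows <- lapply(common, function(r) {
    d <- dhx[dhx$residue_number == r, ][1, ]
    h <- hdx[hdx$residue_number == r, ][1, ]
    if (!is.finite(d$k_exp) || !is.finite(h$k_exp) ||
        d$k_exp <= 0) {
      return(data.frame(residue_number = r, ratio = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_,
                        flag = "undefined"))
    }
    se <- c(h$se, d$se); se[!is.finite(se)] <- 0
    mc <- mc_propagate(function(x) {
      if (x[2] <= 0 || x[1] <= 0) return(NA_real_)
      x[1] / x[2]
    }, mean = c(h$k_exp, d$k_exp), se = se, n = n_mc, seed = seed)
    data.frame(residue_number = r, ratio = h$k_exp / d$k_exp,
               ci_lo = mc$lower, ci_hi = mc$upper, flag = "ok")
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("isotope_ratio_profile", "data.frame"))
}
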