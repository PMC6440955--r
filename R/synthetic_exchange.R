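# Synthetic exchange datasets with known ground truth.  The generator
# inverts the EX2 free-energy relation to obtain per-residue rates,
# builds overall curves and cumulative ETD fragment ladders with the
# same amide bookkeeping as the analysis path, and adds replicate
# Gaussian noise emulating the measurement design: 13 incubation periods
# from 0.1 min to 7 days and at least three replicates.

#' Default incubation-time design
#'
#' Thirteen log-spaced incubation periods from 0.1 minutes to 7 days,
#' mirroring the residue-resolved measurement design (short and long
#' periods realized experimentally by pH-matched incubations).
#'
#' @return Times in minutes.
#' @export
default_exchange_times <- function() {
  c(0.1, 0.5, 1, 5, 10, 30, 120, 480, 1440, 2880, 4320, 7200, 10080)
}

#' Ground truth for a synthetic exchange experiment
#'
#' @param delta_g Named numeric vector of hydrogen-bond opening free
#'   energies (kcal/mol), names = residue numbers.  Alternatively supply
#'   \code{k_exp} directly.
#' @param k_exp Optional named per-residue observed rates (1/min),
#'   overriding \code{delta_g}.
#' @param conditions \code{\link{exchange_conditions}}.
#' @param sigma Gaussian noise SD on fragment deuteron contents.
#' @param times Incubation times (minutes).
#' @param n_replicates Replicates per time point.
#' @param seed Integer seed.
#' @return Object of class \code{exchange_truth}.
#' @export
exchange_truth <- function(delta_g = NULL, k_exp = NULL,
                           conditions = exchange_conditions(),
                           sigma = 0.05,
                           times = default_exchange_times(),
                           n_replicates = 3L, seed = 1L) {
  if (is.null(delta_g) && is.null(k_exp)) {
    stop("supply delta_g or k_exp")
  }
  stopifnot(n_replicates >= 1L, sigma >= 0)
  structure(list(delta_g = delta_g, k_exp = k_exp,
                 conditions = conditions, sigma = sigma, times = times,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "exchange_truth")
}

#' A TM-helix-shaped free-energy truth profile
#'
#' A step profile emulating the archetypal substrate helix: a flexible,
#' Gly-rich N-terminal half (DeltaG below 2 kcal/mol) joined to a rigid
#' C-terminal half (about 5 kcal/mol) that carries the cleavage sites,
#' with soft termini.
#'
#' @param peptide \code{\link{peptide_spec}}.
#' @return Named numeric vector of DeltaG (kcal/mol) per residue number.
#' @export
tm_helix_truth_profile <- function(peptide = app_peptide("A28-55_WT")) {
  num <- peptide$numbering
  dg <- numeric(length(num))
  dg[num <= 28] <- 0.3
  dg[num >= 29 & num <= 33] <- 1.0
  dg[num >= 34 & num <= 40] <- 1.8
  dg[num >= 41 & num <= 51] <- 5.0
  dg[num >= 52] <- 2.5
  stats::setNames(dg, num)
}

#' Generate a synthetic exchange dataset
#'
#' Converts the truth profile into per-residue rates via the EX2
#' inversion \code{k_i = k_ch,i / (1 + exp(DeltaG_i / RT))}, evaluates
#' per-residue retentions \code{y_i(t) = 0.95 exp(-k_i t) + 0.05}, sums
#' them into the overall curve, accumulates them into full c and z
#' fragment ladders using the shared ETD amide bookkeeping, and adds
#' independent Gaussian noise per fragment, time and replicate.  Rates
#' too slow to decay within the observation window are flagged
#' unidentifiable-by-design in the returned truth record.
#'
#' @param truth \code{\link{exchange_truth}}.
#' @param peptide \code{\link{peptide_spec}}.
#' @param out_dir Optional directory; when given, fragments, the overall
#'   curve and the truth record are written as CSV.
#' @return List with \code{fragments} (data.frame), \code{overall}
#'   (\code{overall_exchange_curve}), \code{truth_rates} (data.frame with
#'   per-residue \code{k_true}, \code{delta_g}, \code{identifiable}),
#'   \code{chem} (the intrinsic profile used).
#' @export
gen_exchange_dataset <- function(truth, peptide, out_dir = NULL) {
  stopifnot(inherits(truth, "exchange_truth"),
            inherits(peptide, "peptide_spec"))
  cond <- truth$conditions
  chem <- compute_intrinsic_rates(peptide, cond)
  RT <- .R_kcal * cond$temperature
  num <- peptide$numbering
  n_res <- length(num)

  if (!is.null(truth$k_exp)) {
    k <- rep(NA_real_, n_res)
    k[match(as.integer(names(truth$k_exp)), num)] <- truth$k_exp
    dg_vec <- -RT * log(k / (chem$k_ch - k))
  } else {
    dg_vec <- rep(NA_real_, n_res)
    dg_vec[match(as.integer(names(truth$delta_g)), num)] <- truth$delta_g
    k <- chem$k_ch / (1 + exp(dg_vec / RT))
  }
  measurable <- !is.na(chem$k_ch)
  k[!measurable] <- NA_real_
  identifiable <- is.finite(k) & k >= 1 / (10 * max(truth$times))

  # per-residue retention matrix: rows residues, cols times
  y <- outer(k, truth$times,
             function(kk, tt) .EX2_AMPLITUDE * exp(-kk * tt) + .EX2_BASELINE)
  y[!measurable, ] <- 0

  set.seed(truth$seed)
  # overall curve: replicate means of the summed retention + noise
  overall_reps <- replicate(truth$n_replicates,
    colSums(y, na.rm = TRUE) +
      stats::rnorm(length(truth$times), 0, truth$sigma))
  overall_reps <- pmax(overall_reps, 0)
  overall <- overall_exchange_curve(
    truth$times, rowMeans(overall_reps),
    sem = apply(overall_reps, 1, stats::sd) / sqrt(truth$n_replicates),
    n = truth$n_replicates, n_amides = sum(measurable))

  # fragment ladders
  frag_rows <- list()
  for (ion in c("c", "z")) {
    for (len in seq_len(n_res - 1L)) {
      span <- etd_amide_span(ion, len, n_res)
      content <- colSums(y[span, , drop = FALSE], na.rm = TRUE)
      for (rep_id in seq_len(truth$n_replicates)) {
        noisy <- content + stats::rnorm(length(content), 0, truth$sigma)
        frag_rows[[length(frag_rows) + 1L]] <- data.frame(
          ion_type = ion, fragment_length = len, replicate = rep_id,
          time_min = truth$times, deuterons = noisy)
      }
    }
  }
  fragments <- do.call(rbind, frag_rows)

  truth_rates <- data.frame(residue_number = num,
                            residue = peptide$residues,
                            k_true = k, delta_g = dg_vec,
                            measurable = measurable,
                            identifiable = identifiable)

  out <- list(fragments = fragments, overall = overall,
              truth_rates = truth_rates, chem = chem, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(fragments, file.path(out_dir, "fragments.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(overall),
                     file.path(out_dir, "overall.csv"), row.names = FALSE)
    utils::write.csv(truth_rates, file.path(out_dir, "truth_rates.csv"),
                     row.names = FALSE)
  }
  out
}
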