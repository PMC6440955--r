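# Sequence-specific intrinsic (chemical) amide exchange rates.
#
# Model: k_ch = k_acid + k_base + k_water per backbone amide, with
# acid-, hydroxide- and water-catalysed terms.  Reference rates are for
# poly-DL-alanine with multiplicative side-chain corrections from the
# nearest neighbours on either side of the amide (Bai, Milne, Mayne &
# Englander 1993, Proteins 17:75, as curated in the SPHERE server lineage
# and the updated reference set of Nguyen, Mayne & Englander 2018,
# J. Am. Soc. Mass Spectrom. 29:1936).  Transcription used here
# (log10, rate units min^-1, acid/base second order in M^-1 min^-1,
# 293.15 K reference temperature):
#
#   direction      log kA   log kB   log kW   solvent ion product pK (20 C)
#   H -> D (HDX)    1.62    10.18    -1.50    15.05  (D2O)
#   D -> H (DHX)    1.40    10.00    -1.60    14.17  (H2O)
#   D -> D          1.60    10.36    -1.18    15.05  (D2O)
#
# Arrhenius activation energies: 14 (acid), 17 (base), 19 (water)
# kcal/mol; solvent autoionization enthalpies 13.34 (H2O) / 14.30 (D2O)
# kcal/mol drive the temperature dependence of the ion product.

.hx_ref <- list(
  HDX = list(logkA = 1.62, logkB = 10.18, logkW = -1.50,
             pK_ion = 15.05, dH_ion = 14.30),
  DHX = list(logkA = 1.40, logkB = 10.00, logkW = -1.60,
             pK_ion = 14.17, dH_ion = 13.34),
  DDX = list(logkA = 1.60, logkB = 10.36, logkW = -1.18,
             pK_ion = 15.05, dH_ion = 14.30))

.hx_Ea <- c(acid = 14, base = 17, water = 19)   # kcal/mol
.hx_Tref <- 293.15
.R_kcal <- 1.987204e-3                          # kcal / (mol K)

# Side-chain correction factors, log10 scale.  "lambda" is the effect of a
# residue's side chain on its own backbone NH; "rho" its effect on the NH
# of the following residue.  Charged-form values; acidic side chains and
# His are blended by their protonation state at run time.
.hx_side <- local({
  m <- rbind(
    #        A_lam   A_rho   B_lam   B_rho
    A   = c(  0.00,   0.00,   0.00,   0.00),
    R   = c( -0.59,  -0.32,   0.08,   0.22),
    N   = c( -0.58,  -0.13,   0.49,   0.32),
    D0  = c( -0.90,  -0.12,   0.69,   0.60),   # Asp-COOH
    D   = c(  0.90,   0.58,  -0.30,  -0.18),   # Asp-COO-
    C   = c( -0.54,  -0.46,   0.62,   0.55),   # reduced Cys
    Q   = c( -0.47,  -0.27,   0.06,   0.20),
    E0  = c( -0.60,  -0.27,   0.24,   0.39),   # Glu-COOH
    E   = c( -0.90,   0.31,  -0.11,  -0.15),   # Glu-COO-
    G   = c( -0.22,   0.22,   0.27,   0.17),
    H0  = c( -0.80,  -0.51,   0.80,   0.83),   # His+
    H   = c(  0.00,   0.00,  -0.10,   0.14),   # His neutral
    I   = c( -0.91,  -0.59,  -0.73,  -0.23),
    L   = c( -0.57,  -0.13,  -0.58,  -0.21),
    K   = c( -0.56,  -0.29,  -0.04,   0.12),
    M   = c( -0.64,  -0.28,  -0.01,   0.11),
    F   = c( -0.52,  -0.43,  -0.24,   0.06),
    P   = c(  0.00,  -0.19,   0.00,  -0.24),   # trans Pro (no own NH)
    S   = c( -0.44,  -0.39,   0.37,   0.30),
    T   = c( -0.79,  -0.47,  -0.07,   0.20),
    W   = c( -0.40,  -0.44,  -0.41,  -0.11),
    Y   = c( -0.41,  -0.37,  -0.27,   0.05),
    V   = c( -0.74,  -0.30,  -0.70,  -0.14),
    Ac  = c(  0.00,   0.00,   0.00,   0.00),   # acetyl N-cap: amide neighbour,
                                               # modelled Ala-like (no table entry
                                               # exists for the acetyl group)
    NT  = c( -1.32,  -1.32,   1.62,   1.62),   # free N-terminal NH3+ (rho only used)
    CT  = c(  0.96,   0.96,  -1.80,  -1.80))   # free C-terminal COO- (lambda only used)
  colnames(m) <- c("A_lam", "A_rho", "B_lam", "B_rho")
  m
})

# Side-chain pKa values (model-peptide scale) used to blend protonated /
# deprotonated factor sets for Asp, Glu and His.
.hx_pka <- c(D = 4.48, E = 4.93, H = 7.42)

.arrh <- function(Ea, temperature) {
  exp(-(Ea / .R_kcal) * (1 / temperature - 1 / .hx_Tref))
}

# log10 factor pair (acid, base) for one residue letter on one side,
# blending ionizable side chains by protonation state.
.side_factor <- function(letter, side = c("lam", "rho"), pH) {
  side <- match.arg(side)
  cols <- paste0(c("A_", "B_"), side)
  grab <- function(key) .hx_side[key, cols]
  if (letter %in% c("D", "E", "H")) {
    f_dep <- 1 / (1 + 10^(.hx_pka[[letter]] - pH))   # deprotonated fraction
    lin <- f_dep * 10^grab(letter) + (1 - f_dep) * 10^grab(paste0(letter, "0"))
    return(log10(lin))
  }
  grab(letter)
}

#' Intrinsic (chemical) amide exchange rate constants
#'
#' Computes per-residue intrinsic exchange rate constants for a fully
#' solvent-exposed backbone amide, decomposed into acid-, base- and
#' water-catalysed terms, with nearest-neighbour side-chain corrections,
#' pH dependence and Arrhenius temperature scaling.  The poly-DL-alanine
#' reference parameters and correction factors follow the Bai/Englander
#' lineage (see source for the exact transcription); separate parameter
#' sets are used for deuterium-to-hydrogen (DHX) and hydrogen-to-deuterium
#' (HDX) exchange, whose base-catalysed terms differ both in rate constant
#' and solvent ion product.
#'
#' The first residue of an N-acetylated peptide carries a measurable amide
#' and is treated with an alanine-like amide neighbour correction for the
#' acetyl cap; a free N-terminal residue has no backbone amide and the
#' second residue receives the protonated-amine neighbour correction.
#' Proline positions are reported as \code{NA}.
#'
#' @param peptide A \code{\link{peptide_spec}}.
#' @param conditions An \code{\link{exchange_conditions}} (pH must lie in
#'   [2, 9], inside the validated range of the neighbour-factor model).
#' @return A data.frame of class \code{intrinsic_rate_profile} with
#'   columns \code{residue_number}, \code{residue}, \code{k_acid},
#'   \code{k_base}, \code{k_water}, \code{k_ch} (all rates in 1/min), and
#'   attributes \code{direction}, \code{pH}, \code{temperature}.
#' @export
compute_intrinsic_rates <- function(peptide, conditions) {
  stopifnot(inherits(peptide, "peptide_spec"),
            inherits(conditions, "exchange_conditions"))
  pH <- conditions$pH + conditions$ph_offset
  if (pH < 2 || pH > 9) {
    stop("pH ", pH, " outside the validated range [2, 9]")
  }
  temperature <- conditions$temperature
  ref <- .hx_ref[[conditions$direction]]
  res <- peptide$residues
  n <- length(res)

  pK_T <- ref$pK_ion +
    (ref$dH_ion / (.R_kcal * log(10))) * (1 / temperature - 1 / .hx_Tref)
  conc_H  <- 10^(-pH)
  conc_OH <- 10^(pH - pK_T)
  aA <- .arrh(.hx_Ea[["acid"]], temperature)
  aB <- .arrh(.hx_Ea[["base"]], temperature)
  aW <- .arrh(.hx_Ea[["water"]], temperature)

  k_acid <- k_base <- k_water <- rep(NA_real_, n)
  flag <- rep("ok", n)
  for (i in seq_len(n)) {
    if (res[i] == "P") { flag[i] <- "proline"; next }
    if (i == 1L && peptide$n_terminal == "free") { flag[i] <- "n_term_amine"; next }
    lam <- .side_factor(res[i], "lam", pH)
    left <- if (i == 1L) "Ac" else res[i - 1L]
    rho <- .side_factor(left, "rho", pH)
    logFA <- lam[1] + rho[1]
    logFB <- lam[2] + rho[2]
    if (i == 2L && peptide$n_terminal == "free") {
      nt <- .hx_side["NT", c("A_rho", "B_rho")]
      logFA <- logFA + nt[1]; logFB <- logFB + nt[2]
    }
    if (i == n && peptide$c_terminal == "free") {
      ct <- .hx_side["CT", c("A_lam", "B_lam")]
      logFA <- logFA + ct[1]; logFB <- logFB + ct[2]
    }
    k_acid[i]  <- 10^(ref$logkA + logFA) * conc_H * aA
    k_base[i]  <- 10^(ref$logkB + logFB) * conc_OH * aB
    k_water[i] <- 10^(ref$logkW + logFB) * aW
  }
  out <- data.frame(
    residue_number = peptide$numbering,
    residue = res,
    k_acid = k_acid, k_base = k_base, k_water = k_water,
    k_ch = k_acid + k_base + k_water,
    flag = flag,
    stringsAsFactors = FALSE)
  structure(out,
            direction = conditions$direction,
            pH = pH, temperature = temperature,
            peptide = peptide$name,
            class = c("intrinsic_rate_profile", "data.frame"))
}

#' Fraction of exchange carried by base catalysis
#'
#' Returns the per-residue ratio of the hydroxide-catalysed term to the
#' total intrinsic rate, \code{k_base / k_ch}, each in [0, 1].  Above
#' roughly pH 4 base catalysis dominates amide exchange.
#'
#' @param profile An \code{intrinsic_rate_profile}.
#' @return Named numeric vector (names = residue numbers); \code{NA} for
#'   positions without an amide.
#' @export
base_catalysis_fraction <- function(profile) {
  stopifnot(inherits(profile, "intrinsic_rate_profile"))
  tot <- profile$k_ch
  if (any(!is.na(tot) & tot <= 0)) stop("zero total intrinsic rate")
  stats::setNames(profile$k_base / tot, profile$residue_number)
}

#' Chemical HDX/DHX isotope-rate ratio
#'
#' Evaluates the intrinsic rate profiles for both exchange directions at
#' the same operational pH and temperature and returns their per-residue
#' ratio \code{k_ch,HDX / k_ch,DHX}.  For these peptides the sequence
#' average is close to 0.2, i.e. intrinsic deuteron loss into protonated
#' solvent is about five-fold faster than proton loss into deuterated
#' solvent at the same meter reading.
#'
#' @param peptide A \code{\link{peptide_spec}}.
#' @param pH Operational pH (applied to both directions).
#' @param temperature Kelvin.
#' @param ph_offset_hdx Optional electrode offset applied only to the HDX
#'   (deuterated solvent) direction.
#' @return List with elements \code{ratio} (per-residue, named by residue
#'   number), \code{mean_ratio}, \code{mean_inverse} and the two profiles.
#' @export
hdx_dhx_chemical_ratio <- function(peptide, pH = 5.0, temperature = 293.15,
                                   ph_offset_hdx = 0) {
  dhx <- compute_intrinsic_rates(
    peptide, exchange_conditions(pH, temperature, "DHX"))
  hdx <- compute_intrinsic_rates(
    peptide, exchange_conditions(pH, temperature, "HDX",
                                 ph_offset = ph_offset_hdx))
  ratio <- hdx$k_ch / dhx$k_ch
  names(ratio) <- dhx$residue_number
  list(ratio = ratio,
       mean_ratio = mean(ratio, na.rm = TRUE),
       mean_inverse = mean(1 / ratio, na.rm = TRUE),
       dhx = dhx, hdx = hdx)
}

#' @export
print.intrinsic_rate_profile <- function(x, ...) {
  cat(sprintf("Intrinsic %s rates, pH %.2f, %.2f K (%s)\n",
              attr(x, "direction"), attr(x, "pH"), attr(x, "temperature"),
              attr(x, "peptide")))
  ok <- !is.na(x$k_ch)
  cat(sprintf("  %d amides, k_ch range %.3g - %.3g /min\n",
              sum(ok), min(x$k_ch[ok]), max(x$k_ch[ok])))
  NextMethod()
}
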