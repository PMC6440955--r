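#' Peptide specification
#'
#' Describes a peptide in the C99 numbering frame used throughout the
#' package: a one-letter sequence, the C99 position of its first residue,
#' terminal blocking chemistry and any point mutations relative to the
#' parent sequence.
#'
#' @param name Identifier, e.g. \code{"A26-55_WT"}.
#' @param sequence One-letter amino-acid string (canonical residues only).
#' @param first_residue C99 number of the first residue (e.g. 26).
#' @param n_terminal \code{"acetylated"} or \code{"free"}.
#' @param c_terminal \code{"amidated"} or \code{"free"}.
#' @param mutations Optional data.frame with columns \code{position}
#'   (C99 numbering), \code{original}, \code{replacement} describing point
#'   substitutions already present in \code{sequence}.
#'
#' @return An object of class \code{peptide_spec}.
#' @export
peptide_spec <- function(name, sequence, first_residue,
                         n_terminal = c("acetylated", "free"),
                         c_terminal = c("amidated", "free"),
                         mutations = NULL) {
  n_terminal <- match.arg(n_terminal)
  c_terminal <- match.arg(c_terminal)
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) >= 2L)
  sequence <- toupper(sequence)
  letters1 <- strsplit(sequence, "")[[1]]
  bad <- setdiff(letters1, names(AA3))
  if (length(bad)) {
    stop("non-canonical residue letter(s): ", paste(unique(bad), collapse = ", "))
  }
  first_residue <- as.integer(first_residue)
  numbering <- seq(first_residue, length.out = nchar(sequence))
  if (!is.null(mutations)) {
    stopifnot(all(c("position", "original", "replacement") %in% names(mutations)))
    if (!all(mutations$position %in% numbering)) {
      stop("mutation position outside the numbering span")
    }
    idx <- match(mutations$position, numbering)
    if (!all(letters1[idx] == mutations$replacement)) {
      stop("sequence does not carry the stated replacement residue(s)")
    }
  }
  structure(
    list(name = name, sequence = sequence, residues = letters1,
         first_residue = first_residue, numbering = numbering,
         n_terminal = n_terminal, c_terminal = c_terminal,
         mutations = mutations),
    class = "peptide_spec")
}

#' @export
print.peptide_spec <- function(x, ...) {
  nt <- if (x$n_terminal == "acetylated") "Ac-" else "H-"
  ct <- if (x$c_terminal == "amidated") "-NH2" else "-OH"
  cat("Peptide", x$name, "\n")
  cat(" ", nt, x$sequence, ct, "\n", sep = "")
  cat("  residues ", x$first_residue, "-", max(x$numbering),
      " (C99 numbering), ", length(x$residues), " aa\n", sep = "")
  if (!is.null(x$mutations)) {
    cat("  mutations:",
        paste0(x$mutations$original, x$mutations$position,
               x$mutations$replacement, collapse = ", "), "\n")
  }
  invisible(x)
}

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

C99_WT_26_55 <- "SNKGAIIGLMVGGVVIATVIVITLVMLKKK"

#' Built-in APP C99 transmembrane-domain peptides
#'
#' Returns one of the four model peptides spanning the C99 transmembrane
#' domain used for exchange measurements and simulations: residues 26-55
#' (\code{A26-55}) or the ETD-friendly variant with S26/N27 replaced by
#' lysines (\code{A28-55}), each as wild type or as the I45T familial
#' Alzheimer's disease mutant.  All four are N-terminally acetylated and
#' C-terminally amidated.
#'
#' @param name One of \code{"A26-55_WT"}, \code{"A26-55_I45T"},
#'   \code{"A28-55_WT"}, \code{"A28-55_I45T"}.
#' @return A \code{\link{peptide_spec}}.
#' @export
app_peptide <- function(name = c("A26-55_WT", "A26-55_I45T",
                                 "A28-55_WT", "A28-55_I45T")) {
  name <- match.arg(name)
  wt <- C99_WT_26_55
  seq26 <- wt
  seq28 <- paste0("KK", substring(wt, 3L))      # S26K, N27K tag
  mut45 <- function(s) {
    r <- strsplit(s, "")[[1]]; r[45 - 26 + 1] <- "T"; paste(r, collapse = "")
  }
  i45t <- data.frame(position = 45L, original = "I", replacement = "T")
  switch(name,
    "A26-55_WT"   = peptide_spec(name, seq26, 26L),
    "A26-55_I45T" = peptide_spec(name, mut45(seq26), 26L, mutations = i45t),
    "A28-55_WT"   = peptide_spec(name, seq28, 26L),
    "A28-55_I45T" = peptide_spec(name, mut45(seq28), 26L, mutations = i45t))
}

#' Exchange conditions
#'
#' Conditions under which amide exchange proceeds.  \code{direction}
#' distinguishes deuterium-to-hydrogen exchange (\code{"DHX"}, deuterated
#' amides in protonated solvent) from hydrogen-to-deuterium exchange
#' (\code{"HDX"}).  \code{pH} is the operational instrument reading; no
#' glass-electrode correction is applied unless \code{ph_offset} is set
#' (e.g. +0.4 for the conventional pD correction).
#'
#' @param pH Operational pH reading.
#' @param temperature Kelvin.
#' @param direction \code{"DHX"} or \code{"HDX"}.
#' @param residual_label_fraction Fraction of labelling solvent remaining
#'   after dilution (default 0.05, i.e. a 1:20 dilution).
#' @param dilution_factor Dilution applied at the start of exchange.
#' @param ph_offset Offset added to \code{pH} before rate evaluation.
#' @return An object of class \code{exchange_conditions}.
#' @export
exchange_conditions <- function(pH = 5.0, temperature = 293.15,
                                direction = c("DHX", "HDX"),
                                residual_label_fraction = 0.05,
                                dilution_factor = 20,
                                ph_offset = 0) {
  direction <- match.arg(direction)
  stopifnot(temperature > 0,
            residual_label_fraction >= 0, residual_label_fraction < 1)
  structure(
    list(pH = pH, temperature = temperature, direction = direction,
         residual_label_fraction = residual_label_fraction,
         dilution_factor = dilution_factor, ph_offset = ph_offset),
    class = "exchange_conditions")
}

#' @export
print.exchange_conditions <- function(x, ...) {
  cat(sprintf("%s at pH %.2f (offset %+.2f), %.2f K, residual label %.0f%%\n",
              x$direction, x$pH, x$ph_offset, x$temperature,
              100 * x$residual_label_fraction))
  invisible(x)
}

#' Read peptide definitions from a CSV table
#'
#' Expects columns \code{name}, \code{sequence}, \code{first_residue},
#' \code{n_terminal}, \code{c_terminal}.
#'
#' @param path CSV file path.
#' @return Named list of \code{\link{peptide_spec}} objects.
#' @export
read_peptides <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "sequence", "first_residue", "n_terminal", "c_terminal")
  missing <- setdiff(need, names(tab))
  if (length(missing)) stop("peptide table lacks column(s): ",
                            paste(missing, collapse = ", "))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    peptide_spec(tab$name[i], tab$sequence[i], tab$first_residue[i],
                 tab$n_terminal[i], tab$c_terminal[i])
  })
  names(out) <- tab$name
  out
}
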