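# Independent oracles, deliberately written as plain brute-force
# arithmetic separate from the package's code paths.

# --- intrinsic-rate oracle ------------------------------------------------
# Independent re-transcription of the poly-DL-alanine reference rates and
# nearest-neighbour factors (Bai et al. lineage), evaluated by direct
# term-by-term summation.

oracle_side_table <- function() {
  # residue: acid_lambda acid_rho base_lambda base_rho (log10)
  txt <- "
A  0.00  0.00  0.00  0.00
R -0.59 -0.32  0.08  0.22
N -0.58 -0.13  0.49  0.32
D  0.90  0.58 -0.30 -0.18
C -0.54 -0.46  0.62  0.55
Q -0.47 -0.27  0.06  0.20
E -0.90  0.31 -0.11 -0.15
G -0.22  0.22  0.27  0.17
H  0.00  0.00 -0.10  0.14
I -0.91 -0.59 -0.73 -0.23
L -0.57 -0.13 -0.58 -0.21
K -0.56 -0.29 -0.04  0.12
M -0.64 -0.28 -0.01  0.11
F -0.52 -0.43 -0.24  0.06
P  0.00 -0.19  0.00 -0.24
S -0.44 -0.39  0.37  0.30
T -0.79 -0.47 -0.07  0.20
W -0.40 -0.44 -0.41 -0.11
Y -0.41 -0.37 -0.27  0.05
V -0.74 -0.30 -0.70 -0.14"
  tab <- read.table(text = txt, col.names = c("res", "aL", "aR", "bL", "bR"),
                    stringsAsFactors = FALSE)
  rownames(tab) <- tab$res
  tab
}

# direct evaluation for an N-acetylated, C-amidated peptide at the
# reference temperature 293.15 K (no Arrhenius factor needed)
oracle_intrinsic_rates <- function(sequence, pH, direction) {
  par <- switch(direction,
    DHX = c(lkA = 1.40, lkB = 10.00, lkW = -1.60, pK = 14.17),
    HDX = c(lkA = 1.62, lkB = 10.18, lkW = -1.50, pK = 15.05))
  tab <- oracle_side_table()
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  k <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (res[i] == "P") next
    la <- tab[res[i], "aL"]; lb <- tab[res[i], "bL"]
    ra <- if (i == 1) 0 else tab[res[i - 1], "aR"]
    rb <- if (i == 1) 0 else tab[res[i - 1], "bR"]
    kA <- 10^(par[["lkA"]] + la + ra) * 10^(-pH)
    kB <- 10^(par[["lkB"]] + lb + rb) * 10^(pH - par[["pK"]])
    kW <- 10^(par[["lkW"]] + lb + rb)
    k[i] <- kA + kB + kW
  }
  k
}

# --- brute-force H-bond checker -------------------------------------------
# all donor/acceptor pairs, scalar arithmetic, no shared helpers
oracle_hbond_matrix <- function(traj, frame) {
  at <- traj$atoms
  xyz <- helixdx::frame_coords(traj, frame)
  donors <- sort(unique(at$residue_number[at$atom == "H"]))
  acceptors <- sort(unique(at$residue_number[at$atom == "O"]))
  out <- list()
  for (d in donors) {
    hi <- which(at$residue_number == d & at$atom == "H")
    ni <- which(at$residue_number == d & at$atom == "N")
    for (a in acceptors) {
      oi <- which(at$residue_number == a & at$atom == "O")
      v_oh <- xyz[oi, ] - xyz[hi, ]
      dist <- sqrt(sum(v_oh^2))
      v_nh <- xyz[ni, ] - xyz[hi, ]
      cosang <- sum(v_oh * v_nh) /
        (dist * sqrt(sum(v_nh^2)))
      ang <- acos(max(-1, min(1, cosang))) * 180 / pi
      out[[paste(d, a)]] <- data.frame(
        donor = d, acceptor = a,
        closed = (dist < 0.26) && (ang >= 120))
    }
  }
  do.call(rbind, out)
}

# --- exact free-energy arithmetic -----------------------------------------
oracle_delta_g <- function(k_exp, k_ch, temperature = 293.15) {
  -1.987204e-3 * temperature * log(k_exp / (k_ch - k_exp))
}
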