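# Shared small fixtures, built in code.

wt26 <- app_peptide("A26-55_WT")
wt28 <- app_peptide("A28-55_WT")

cond_dhx5 <- exchange_conditions(5.0, 293.15, "DHX")

# a small static ideal-helix trajectory reused across tests
make_ideal_traj <- function(n_frames = 3, ...) {
  gen_helix_trajectory(trajectory_truth(wt26, n_frames = n_frames, ...))
}

# fully extended chain, built directly: residues spaced 0.35 nm along x,
# carbonyl O and amide H pointing away from any partner
make_extended_traj <- function(n_frames = 1) {
  res <- wt26$residues
  n <- length(res)
  atoms <- list(); xyz <- list()
  for (i in seq_len(n)) {
    x0 <- 0.35 * (i - 1)
    coords <- list(
      N = c(x0, 0, 0),
      CA = c(x0 + 0.12, 0.08 * (-1)^i, 0),
      C = c(x0 + 0.24, 0, 0),
      O = c(x0 + 0.24, -0.12, 0))
    if (i > 1) coords$H <- c(x0, 0.10, 0)
    for (an in names(coords)) {
      atoms[[length(atoms) + 1]] <- data.frame(
        residue_index = i, residue_number = wt26$numbering[i],
        residue = res[i], atom = an,
        element = substring(an, 1, 1), stringsAsFactors = FALSE)
      xyz[[length(xyz) + 1]] <- coords[[an]]
    }
  }
  at <- do.call(rbind, atoms)
  xy <- do.call(rbind, xyz)
  coords <- array(NA_real_, c(n_frames, nrow(at), 3))
  for (f in seq_len(n_frames)) coords[f, , ] <- xy
  helix_trajectory(at, coords, 10)
}
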