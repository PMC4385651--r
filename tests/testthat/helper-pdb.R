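# Multi-model PDB fixture writer: `atoms` is a data frame with chain,
# resno, resname, elety, elesy; `models` a list of n_atoms x 3 coordinate
# matrices.

write_multimodel_pdb <- function(atoms, models, path = tempfile(fileext = ".pdb")) {
  lines <- character(0)
  for (m in seq_along(models)) {
    xyz <- models[[m]]
    lines <- c(lines, sprintf("MODEL     %4d", m))
    for (i in seq_len(nrow(atoms))) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        i, atoms$elety[i], atoms$resname[i], atoms$chain[i], atoms$resno[i],
        xyz[i, 1], xyz[i, 2], xyz[i, 3], 1.00, 0.00, atoms$elesy[i]
      ))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# one GLY + one ALA residue on chain A: 8 backbone atoms, 9 heavy atoms
two_residue_atoms <- function(with_hydrogens = FALSE) {
  atoms <- data.frame(
    chain = "A",
    resno = c(rep(10L, 4), rep(11L, 5)),
    resname = c(rep("GLY", 4), rep("ALA", 5)),
    elety = c("N", "CA", "C", "O", "N", "CA", "C", "O", "CB"),
    elesy = c("N", "C", "C", "O", "N", "C", "C", "O", "C"),
    stringsAsFactors = FALSE
  )
  if (with_hydrogens) {
    atoms <- rbind(atoms, data.frame(
      chain = "A", resno = c(10L, 11L), resname = c("GLY", "ALA"),
      elety = c("HA2", "HB1"), elesy = c("H", "H"),
      stringsAsFactors = FALSE
    ))
  }
  atoms
}

two_residue_coords <- function(n_atoms = 9) {
  withr::with_seed(42, matrix(rnorm(n_atoms * 3, sd = 2), ncol = 3))
}

random_rigid_transform <- function(xyz) {
  # QR of a random matrix gives a uniform-ish rotation; force det +1
  M <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  shift <- rnorm(3, sd = 5)
  sweep(xyz %*% Q, 2, shift, "+")
}
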