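#' Define a substrate-binding cavity by its residues
#'
#' A cavity is a non-empty set of (chain, residue number) selectors using PDB
#' author numbering. The RMSD feature is computed over the backbone atoms
#' (N, CA, C, O) of these residues; the heavy-atom feature counts all
#' non-hydrogen atoms in them. Chain ids are required to avoid cross-chain
#' ambiguity.
#'
#' @param residues Data frame with columns `chain` (character) and `resno`
#'   (integer residue numbers).
#' @return An object of class `rffr_cavity_spec`.
#' @export
#' @examples
#' cav <- cavity_spec(data.frame(chain = "A", resno = c(96, 121, 149)))
cavity_spec <- function(residues) {
  residues <- as.data.frame(residues)
  if (!all(c("chain", "resno") %in% names(residues))) {
    stop_rffr("`residues` must have columns `chain` and `resno`.", "rffr_invalid_spec")
  }
  if (nrow(residues) == 0) {
    stop_rffr("cavity residue list must be non-empty.", "rffr_invalid_spec")
  }
  residues$chain <- as.character(residues$chain)
  residues$resno <- as.integer(residues$resno)
  if (anyDuplicated(residues[, c("chain", "resno")])) {
    stop_rffr("duplicate (chain, resno) selectors in cavity residue list.",
              "rffr_invalid_spec")
  }
  structure(
    list(residues = tibble::as_tibble(residues[, c("chain", "resno")]),
         backbone_atoms = c("N", "CA", "C", "O")),
    class = "rffr_cavity_spec"
  )
}

#' Read a cavity residue list from YAML or CSV
#'
#' YAML files must contain a `residues` list of `{chain, resno}` entries (or
#' a top-level list of such entries); CSV files must have `chain,resno`
#' columns.
#'
#' @param path Path to the YAML (`.yml`/`.yaml`) or CSV file.
#' @return An [cavity_spec()] object.
#' @export
read_cavity_spec <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    entries <- y$residues %||% y
    residues <- dplyr::bind_rows(lapply(entries, tibble::as_tibble))
  } else {
    residues <- readr::read_csv(path, show_col_types = FALSE)
  }
  cavity_spec(residues)
}

#' @export
print.rffr_cavity_spec <- function(x, ...) {
  cat(sprintf("<rffr_cavity_spec> %d residues over chain(s) %s; backbone atoms %s\n",
              nrow(x$residues), paste(unique(x$residues$chain), collapse = ","),
              paste(x$backbone_atoms, collapse = ",")))
  invisible(x)
}

read_trajectory_pdb <- function(pdb) {
  if (is.character(pdb)) {
    pdb <- bio3d::read.pdb(pdb, multi = TRUE, verbose = FALSE)
  }
  if (!inherits(pdb, "pdb")) {
    stop_rffr("`pdb` must be a file path or a bio3d `pdb` object.", "rffr_type_error")
  }
  pdb
}

# Atom-table indices of the cavity backbone atoms, in (residue, N/CA/C/O)
# order; errors name the first residue/atom missing from the model.
cavity_backbone_indices <- function(pdb, cavity) {
  atom <- pdb$atom
  idx <- integer(0)
  for (i in seq_len(nrow(cavity$residues))) {
    ch <- cavity$residues$chain[i]
    rn <- cavity$residues$resno[i]
    in_res <- which(atom$chain == ch & atom$resno == rn)
    if (!length(in_res)) {
      stop_rffr(sprintf("cavity residue %s:%d absent from structure.", ch, rn),
                "rffr_structure_error")
    }
    for (nm in cavity$backbone_atoms) {
      j <- in_res[atom$elety[in_res] == nm]
      if (length(j) != 1) {
        stop_rffr(
          sprintf("backbone atom %s missing (or duplicated) in cavity residue %s:%d.",
                  nm, ch, rn),
          "rffr_structure_error"
        )
      }
      idx <- c(idx, j)
    }
  }
  idx
}

#' Backbone RMSD of the binding cavity along a trajectory
#'
#' Computes, for every model of a multi-model PDB trajectory, the root mean
#' square deviation of the cavity backbone atoms (N, CA, C, O of the cavity
#' residues) from the first model. With `superpose = TRUE` (default) an
#' optimal least-squares rigid-body superposition onto the reference is
#' applied before the deviation is measured, so global rotation/translation
#' of a frame does not register as cavity motion; a no-fit mode is kept for
#' trajectories already aligned upstream.
#'
#' @param pdb Path to a multi-model PDB file, or a `bio3d` pdb object read
#'   with `multi = TRUE`.
#' @param cavity An [cavity_spec()] object.
#' @param superpose Apply least-squares superposition before measuring.
#' @return Numeric vector of per-model RMSD (\eqn{\mbox{\AA}}); the first
#'   entry is 0 by construction.
#' @export
compute_cavity_rmsd <- function(pdb, cavity, superpose = TRUE) {
  stopifnot(inherits(cavity, "rffr_cavity_spec"))
  pdb <- read_trajectory_pdb(pdb)
  idx <- cavity_backbone_indices(pdb, cavity)
  xinds <- bio3d::atom2xyz(idx)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  coords <- xyz[, xinds, drop = FALSE]
  if (superpose && nrow(xyz) > 1) {
    coords <- bio3d::fit.xyz(fixed = xyz[1, ], mobile = xyz,
                             fixed.inds = xinds, mobile.inds = xinds)[, xinds,
                                                                      drop = FALSE]
  }
  m <- length(xinds) / 3
  delta <- sweep(coords, 2, coords[1, ])
  r <- sqrt(rowSums(delta^2) / m)
  r[1] <- 0
  unname(r)
}

#' Count heavy atoms in the binding cavity of one model
#'
#' Counts the atoms of the cavity residues whose element is not hydrogen.
#' Elements are taken from the PDB element column when present, otherwise
#' inferred from atom names, so structures with or without explicit
#' hydrogens give consistent counts.
#'
#' @param pdb Path to a PDB file or a `bio3d` pdb object.
#' @param cavity An [cavity_spec()] object.
#' @return Non-negative integer heavy-atom count.
#' @export
count_cavity_heavy_atoms <- function(pdb, cavity) {
  stopifnot(inherits(cavity, "rffr_cavity_spec"))
  pdb <- read_trajectory_pdb(pdb)
  atom <- pdb$atom
  sel <- rep(FALSE, nrow(atom))
  for (i in seq_len(nrow(cavity$residues))) {
    ch <- cavity$residues$chain[i]
    rn <- cavity$residues$resno[i]
    in_res <- atom$chain == ch & atom$resno == rn
    if (!any(in_res)) {
      stop_rffr(sprintf("cavity residue %s:%d absent from structure.", ch, rn),
                "rffr_structure_error")
    }
    sel <- sel | in_res
  }
  ele <- atom$elesy
  blank <- is.na(ele) | ele == ""
  if (any(blank)) {
    ele[blank] <- suppressWarnings(bio3d::atom2ele(atom$elety[blank]))
  }
  sum(sel & toupper(ele) != "H")
}

#' Extract cavity features from a multi-model PDB trajectory
#'
#' Convenience wrapper producing the RMSD and heavy-atom columns of the
#' feature table from a trajectory. Area and volume are pocket-geometry
#' quantities computed by external cavity software and must be merged in
#' separately; they are returned as `NA` here.
#'
#' @inheritParams compute_cavity_rmsd
#' @param interval_ps Sampling interval used to fill the time column.
#' @return A feature-schema tibble with `area_A2`/`volume_A3` set to `NA`.
#' @export
extract_cavity_features <- function(pdb, cavity, superpose = TRUE, interval_ps = 1) {
  pdb <- read_trajectory_pdb(pdb)
  r <- compute_cavity_rmsd(pdb, cavity, superpose = superpose)
  n <- length(r)
  # heavy-atom membership is per-residue, identical across models of one
  # multi-model file, so count once
  heavy <- count_cavity_heavy_atoms(pdb, cavity)
  tibble::tibble(
    snapshot_id = sprintf("snap_%06d", seq_len(n)),
    time_ps = seq_len(n) * interval_ps,
    area_A2 = NA_real_,
    volume_A3 = NA_real_,
    heavy_atoms = rep(as.integer(heavy), n),
    rmsd_A = r
  )
}
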