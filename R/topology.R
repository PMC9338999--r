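## Idealized heavy-atom side-chain topologies.
##
## Each side-chain atom beyond CB is defined by internal coordinates relative
## to three previously placed atoms: torsion path a1-a2-a3-atom, bond length r
## (Angstrom), bond angle a2-a3-atom theta (degrees), and a torsion that is
## either tied to a chi angle (chi index + offset) or fixed (chi = NA,
## offset = absolute torsion; used for planar ring/terminal atoms).
##
## Bond lengths and angles are standard idealized values; rings are built
## planar. Only heavy atoms are modeled (the force field is hydrogen-free).

sidechain_row <- function(name, a1, a2, a3, r, theta, chi, offset) {
  data.frame(name = name, a1 = a1, a2 = a2, a3 = a3, r = r, theta = theta,
             chi = chi, offset = offset, stringsAsFactors = FALSE)
}

.SIDECHAIN_TOPOLOGY <- local({
  rows <- function(...) do.call(rbind, list(...))
  list(
    GLY = NULL,
    ALA = NULL,
    SER = rows(sidechain_row("OG", "N", "CA", "CB", 1.417, 110.8, 1L, 0)),
    CYS = rows(sidechain_row("SG", "N", "CA", "CB", 1.808, 113.8, 1L, 0)),
    THR = rows(
      sidechain_row("OG1", "N", "CA", "CB", 1.433, 109.6, 1L, 0),
      sidechain_row("CG2", "N", "CA", "CB", 1.521, 110.5, 1L, -120)),
    VAL = rows(
      sidechain_row("CG1", "N", "CA", "CB", 1.527, 110.5, 1L, 0),
      sidechain_row("CG2", "N", "CA", "CB", 1.527, 110.5, 1L, 122)),
    LEU = rows(
      sidechain_row("CG", "N", "CA", "CB", 1.530, 116.3, 1L, 0),
      sidechain_row("CD1", "CA", "CB", "CG", 1.521, 110.5, 2L, 0),
      sidechain_row("CD2", "CA", "CB", "CG", 1.521, 110.5, 2L, 122)),
    ILE = rows(
      sidechain_row("CG1", "N", "CA", "CB", 1.530, 110.4, 1L, 0),
      sidechain_row("CG2", "N", "CA", "CB", 1.521, 110.5, 1L, -122),
      sidechain_row("CD1", "CA", "CB", "CG1", 1.513, 113.8, 2L, 0)),
    MET = rows(
      sidechain_row("CG", "N", "CA", "CB", 1.520, 114.1, 1L, 0),
      sidechain_row("SD", "CA", "CB", "CG", 1.803, 112.7, 2L, 0),
      sidechain_row("CE", "CB", "CG", "SD", 1.791, 100.9, 3L, 0)),
    PRO = rows(
      sidechain_row("CG", "N", "CA", "CB", 1.495, 104.5, 1L, 0),
      sidechain_row("CD", "CA", "CB", "CG", 1.507, 106.1, 2L, 0)),
    PHE = rows(
      sidechain_row("CG", "N", "CA", "CB", 1.502, 113.8, 1L, 0),
      sidechain_row("CD1", "CA", "CB", "CG", 1.384, 120.8, 2L, 0),
      sidechain_row("CD2", "CA", "CB", "CG", 1.384, 120.8, 2L, 180),
      sidechain_row("CE1", "CB", "CG", "CD1", 1.382, 120.8, NA, 180),
      sidechain_row("CE2", "CB", "CG", "CD2", 1.382, 120.8, NA, 180),
      sidechain_row("CZ", "CG", "CD1", "CE1", 1.370, 120.0, NA, 0)),
    TYR = rows(
      sidechain_row("CG", "N", "CA", "CB", 1.512, 113.8, 1L, 0),
      sidechain_row("CD1", "CA", "CB", "CG", 1.389, 120.8, 2L, 0),
      sidechain_row("CD2", "CA", "CB", "CG", 1.389, 120.8, 2L, 180),
      sidechain_row("CE1", "CB", "CG", "CD1", 1.382, 121.1, NA, 180),
      sidechain_row("CE2", "CB", "CG", "CD2", 1.382, 121.1, NA, 180),
      sidechain_row("CZ", "CG", "CD1", "CE1", 1.378, 119.5, NA, 0),
      sidechain_row("OH", "CD1", "CE1", "CZ", 1.376, 119.9, NA, 180)),
    TRP = rows(
      sidechain_row("CG", "N", "CA", "CB", 1.498, 114.1, 1L, 0),
      sidechain_row("CD1", "CA", "CB", "CG", 1.365, 126.9, 2L, 0),
      sidechain_row("CD2", "CA", "CB", "CG", 1.433, 126.6, 2L, 180),
      sidechain_row("NE1", "CB", "CG", "CD1", 1.374, 110.1, NA, 180),
      sidechain_row("CE2", "CB", "CG", "CD2", 1.409, 107.2, NA, 180),
      sidechain_row("CE3", "CB", "CG", "CD2", 1.398, 133.9, NA, 0),
      sidechain_row("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, NA, 180),
      sidechain_row("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, NA, 180),
      sidechain_row("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, NA, 0)),
    ASP = rows(
      sidechain_row("CG", "N", "CA", "CB", 1.516, 112.6, 1L, 0),
      sidechain_row("OD1", "CA", "CB", "CG", 1.249, 118.4, 2L, 0),
      sidechain_row("OD2", "CA", "CB", "CG", 1.249, 118.4, 2L, 180)),
    ASN = rows(
      sidechain_row("CG", "N", "CA", "CB", 1.516, 112.6, 1L, 0),
      sidechain_row("OD1", "CA", "CB", "CG", 1.231, 120.8, 2L, 0),
      sidechain_row("ND2", "CA", "CB", "CG", 1.328, 116.4, 2L, 180)),
    GLU = rows(
      sidechain_row("CG", "N", "CA", "CB", 1.520, 114.1, 1L, 0),
      sidechain_row("CD", "CA", "CB", "CG", 1.516, 112.6, 2L, 0),
      sidechain_row("OE1", "CB", "CG", "CD", 1.249, 118.4, 3L, 0),
      sidechain_row("OE2", "CB", "CG", "CD", 1.249, 118.4, 3L, 180)),
    GLN = rows(
      sidechain_row("CG", "N", "CA", "CB", 1.520, 114.1, 1L, 0),
      sidechain_row("CD", "CA", "CB", "CG", 1.516, 112.6, 2L, 0),
      sidechain_row("OE1", "CB", "CG", "CD", 1.231, 120.8, 3L, 0),
      sidechain_row("NE2", "CB", "CG", "CD", 1.328, 116.4, 3L, 180)),
    LYS = rows(
      sidechain_row("CG", "N", "CA", "CB", 1.520, 114.1, 1L, 0),
      sidechain_row("CD", "CA", "CB", "CG", 1.520, 111.3, 2L, 0),
      sidechain_row("CE", "CB", "CG", "CD", 1.520, 111.3, 3L, 0),
      sidechain_row("NZ", "CG", "CD", "CE", 1.489, 111.9, 4L, 0)),
    ARG = rows(
      sidechain_row("CG", "N", "CA", "CB", 1.520, 114.1, 1L, 0),
      sidechain_row("CD", "CA", "CB", "CG", 1.520, 111.3, 2L, 0),
      sidechain_row("NE", "CB", "CG", "CD", 1.461, 112.0, 3L, 0),
      sidechain_row("CZ", "CG", "CD", "NE", 1.329, 124.2, 4L, 0),
      sidechain_row("NH1", "CD", "NE", "CZ", 1.326, 120.0, NA, 0),
      sidechain_row("NH2", "CD", "NE", "CZ", 1.326, 120.0, NA, 180)),
    HIS = rows(
      sidechain_row("CG", "N", "CA", "CB", 1.497, 113.8, 1L, 0),
      sidechain_row("ND1", "CA", "CB", "CG", 1.378, 122.7, 2L, 0),
      sidechain_row("CD2", "CA", "CB", "CG", 1.356, 131.0, 2L, 180),
      sidechain_row("CE1", "CB", "CG", "ND1", 1.320, 109.3, NA, 180),
      sidechain_row("NE2", "CB", "CG", "CD2", 1.374, 107.2, NA, 180))
  )
})

#' Number of chi angles of an amino acid
#' @param aa3 three-letter code.
#' @return integer count of rotatable chi angles (0 for Gly/Ala/Pro).
#' @export
n_chi <- function(aa3) {
  aa3 <- aa_three(aa3)
  if (aa3 %in% AA_INFLEXIBLE) return(0L)
  topo <- .SIDECHAIN_TOPOLOGY[[aa3]]
  if (is.null(topo)) return(0L)
  max(c(0L, topo$chi), na.rm = TRUE)
}

## Build side-chain heavy-atom coordinates (beyond CB) for residue `aa3`
## given backbone coordinates (named list/matrix with N, CA, CB rows) and a
## chi-angle vector (degrees). Returns a matrix with rownames = atom names.
build_sidechain_coords <- function(aa3, anchor, chis) {
  topo <- .SIDECHAIN_TOPOLOGY[[aa3]]
  if (is.null(topo)) return(NULL)
  coords <- anchor  # named list of 3-vectors, must contain N, CA, CB
  out <- matrix(NA_real_, nrow = nrow(topo), ncol = 3,
                dimnames = list(topo$name, NULL))
  for (i in seq_len(nrow(topo))) {
    row <- topo[i, ]
    tor <- if (is.na(row$chi)) row$offset else {
      if (length(chis) < row$chi || is.na(chis[row$chi]))
        stop("missing chi", row$chi, " for ", aa3)
      chis[row$chi] + row$offset
    }
    pos <- place_atom(coords[[row$a1]], coords[[row$a2]], coords[[row$a3]],
                      row$r, row$theta, tor)
    coords[[row$name]] <- pos
    out[i, ] <- pos
  }
  out
}

## Measure the chi angles of a residue from its atom coordinates (named list
## of 3-vectors). Returns numeric vector (degrees), possibly length 0.
measure_chis <- function(aa3, coords) {
  topo <- .SIDECHAIN_TOPOLOGY[[aa3]]
  nch <- n_chi(aa3)
  if (nch == 0L || is.null(topo)) return(numeric(0))
  chis <- rep(NA_real_, nch)
  for (i in seq_len(nrow(topo))) {
    row <- topo[i, ]
    if (!is.na(row$chi) && row$offset == 0 && is.na(chis[row$chi])) {
      need <- c(row$a1, row$a2, row$a3, row$name)
      if (!all(need %in% names(coords))) next
      chis[row$chi] <- dihedral_angle(coords[[row$a1]], coords[[row$a2]],
                                      coords[[row$a3]], coords[[row$name]])
    }
  }
  chis
}

## Side-chain atom names beyond CB for an amino acid (NULL for Gly/Ala).
sidechain_atom_names <- function(aa3) {
  topo <- .SIDECHAIN_TOPOLOGY[[aa3]]
  if (is.null(topo)) character(0) else topo$name
}
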