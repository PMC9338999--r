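## Amino-acid naming tables shared across the package.

#' The 20 standard amino acids
#'
#' Three-letter codes of the 20 standard amino acids, ordered alphabetically
#' by one-letter code (the order used by saturation panels).
#'
#' @format Character vector of length 20.
#' @export
AA_STANDARD <- c(
  A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
  G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
  M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
  S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR"
)

#' Convert between one- and three-letter amino-acid codes
#'
#' @param x character vector of codes.
#' @return character vector of converted codes.
#' @export
aa_three <- function(x) {
  x <- toupper(x)
  out <- ifelse(nchar(x) == 3L, x, unname(AA_STANDARD[x]))
  if (any(is.na(out)) || !all(out %in% AA_STANDARD))
    stop("unknown amino-acid code(s): ", paste(x[is.na(out) | !(out %in% AA_STANDARD)], collapse = ", "))
  out
}

#' @rdname aa_three
#' @export
aa_one <- function(x) {
  x <- toupper(x)
  rev_map <- stats::setNames(names(AA_STANDARD), AA_STANDARD)
  out <- ifelse(nchar(x) == 1L, x, unname(rev_map[x]))
  if (any(is.na(out))) stop("unknown amino-acid code(s)")
  out
}

## Residues with no rotatable side-chain chi angles: excluded from rotamer
## search (GLY has no side chain, ALA only CB, PRO's ring is kept rigid).
AA_INFLEXIBLE <- c("GLY", "ALA", "PRO")

## Element inferred from a PDB atom name: first alphabetic character of the
## name with leading digits stripped (heavy atoms only: C, N, O, S).
element_from_name <- function(name) {
  stripped <- sub("^[0-9']+", "", toupper(name))
  el <- substr(stripped, 1L, 1L)
  el[!el %in% c("C", "N", "O", "S", "H")] <- NA_character_
  el
}
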