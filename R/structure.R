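## Atomic data model: a ComplexStructure is a flat atom table (one row per
## heavy atom) carrying the chain/residue hierarchy in its columns, plus
## provenance attributes. Residues are addressed by raw author numbering via
## the key "chain:resnum:icode".

ATOM_COLUMNS <- c("serial", "name", "element", "x", "y", "z",
                  "occupancy", "bfactor", "chain", "resnum", "icode", "aa3")

#' Construct a ComplexStructure from an atom table
#'
#' @param atoms data.frame with columns serial, name, element, x, y, z,
#'   occupancy, bfactor, chain, resnum, icode, aa3.
#' @param source provenance string.
#' @param hetero_stripped,hydrogens_stripped logical flags recording what was
#'   removed on read.
#' @return object of class `ComplexStructure`.
#' @export
complex_structure <- function(atoms, source = "in-memory",
                              hetero_stripped = TRUE,
                              hydrogens_stripped = TRUE) {
  stopifnot(is.data.frame(atoms))
  missing_cols <- setdiff(ATOM_COLUMNS, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty structure")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  if (any(is.na(atoms$element) | atoms$element == ""))
    stop("atoms with missing element symbol")
  atoms <- atoms[, ATOM_COLUMNS]
  atoms$icode[is.na(atoms$icode)] <- ""
  atoms$reskey <- paste(atoms$chain, atoms$resnum, atoms$icode, sep = ":")
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms, source = source,
         hetero_stripped = hetero_stripped,
         hydrogens_stripped = hydrogens_stripped),
    class = "ComplexStructure")
}

#' @export
print.ComplexStructure <- function(x, ...) {
  rt <- residue_table(x)
  cat("ComplexStructure:", nrow(x$atoms), "atoms,", nrow(rt), "residues,",
      "chains:", paste(unique(rt$chain), collapse = " "), "\n")
  cat("  source:", x$source,
      "| hetero_stripped:", x$hetero_stripped,
      "| hydrogens_stripped:", x$hydrogens_stripped, "\n")
  invisible(x)
}

#' Residue-level summary of a structure
#'
#' @param structure a `ComplexStructure`.
#' @return data.frame with one row per residue (reskey, chain, resnum, icode,
#'   aa3, n_atoms), in order of first appearance.
#' @export
residue_table <- function(structure) {
  a <- structure$atoms
  first <- !duplicated(a$reskey)
  rt <- a[first, c("reskey", "chain", "resnum", "icode", "aa3")]
  rt$n_atoms <- as.integer(table(factor(a$reskey, levels = rt$reskey)))
  rownames(rt) <- NULL
  rt
}

#' @rdname residue_table
#' @export
residue_keys <- function(structure) unique(structure$atoms$reskey)

#' Extract one residue's atoms
#'
#' @param structure a `ComplexStructure`.
#' @param key residue key "chain:resnum:icode".
#' @return data.frame of the residue's atoms.
#' @export
get_residue <- function(structure, key) {
  sel <- structure$atoms$reskey == key
  if (!any(sel)) stop("residue not found: ", key)
  structure$atoms[sel, , drop = FALSE]
}

## Coordinates of an atom table as an n x 3 matrix.
xyz_matrix <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

## Named list of 3-vectors (atom name -> coords) for one residue.
residue_coord_list <- function(res_atoms) {
  out <- lapply(seq_len(nrow(res_atoms)), function(i)
    c(res_atoms$x[i], res_atoms$y[i], res_atoms$z[i]))
  names(out) <- res_atoms$name
  out
}

#' Partner partition of a complex
#'
#' Assigns the structure's chains to the two sides of the interface.
#'
#' @param antibody_chains,antigen_chains character vectors of chain ids;
#'   must be disjoint and non-empty.
#' @return object of class `PartnerPartition`.
#' @export
partner_partition <- function(antibody_chains, antigen_chains) {
  antibody_chains <- unique(as.character(antibody_chains))
  antigen_chains <- unique(as.character(antigen_chains))
  if (!length(antibody_chains) || !length(antigen_chains))
    stop("both sides of the partition must be non-empty")
  if (length(intersect(antibody_chains, antigen_chains)))
    stop("partition sides overlap: ",
         paste(intersect(antibody_chains, antigen_chains), collapse = ", "))
  structure(list(antibody_chains = antibody_chains,
                 antigen_chains = antigen_chains),
            class = "PartnerPartition")
}

partition_side_chains <- function(partition, side) {
  side <- match.arg(side, c("antibody", "antigen"))
  if (side == "antibody") partition$antibody_chains else partition$antigen_chains
}

#' Read an antibody-antigen complex from a PDB file
#'
#' Parses ATOM records (via bio3d), drops HETATM records and waters when
#' `strip_hetero` is set, drops hydrogens when `strip_hydrogens` is set, and
#' resolves alternate locations to the highest-occupancy conformer (ties
#' broken by first occurrence).
#'
#' @param path PDB file path.
#' @param model_index 1-based MODEL index (default first model).
#' @param strip_hetero drop HETATM and water (HOH/WAT) records (default TRUE).
#' @param strip_hydrogens drop hydrogen atoms (default TRUE; the force field
#'   is heavy-atom only).
#' @return a `ComplexStructure`.
#' @export
read_pdb <- function(path, model_index = 1L, strip_hetero = TRUE,
                     strip_hydrogens = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  badline <- .find_bad_coord_line(path)
  if (!is.na(badline))
    stop("malformed coordinate fields in ", path, " at line ", badline)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("PDB parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  nmodels <- nrow(pdb$xyz)
  if (is.null(nmodels)) nmodels <- 1L
  if (model_index < 1L || model_index > nmodels)
    stop("model_index ", model_index, " not present (file has ",
         nmodels, " model(s))")
  at <- pdb$atom
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]

  bad <- which(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))
  if (length(bad))
    stop("malformed coordinate fields in ", path,
         " (atom serial ", at$eleno[bad[1]], ")")

  n_removed <- 0L
  if (strip_hetero) {
    drop <- at$type == "HETATM" | at$resid %in% c("HOH", "WAT")
    n_removed <- sum(drop)
    at <- at[!drop, , drop = FALSE]
  }
  if (nrow(at) == 0L) stop("empty structure")

  element <- at$elesy
  miss <- is.na(element) | element == ""
  element[miss] <- element_from_name(at$elety[miss])
  element <- toupper(trimws(element))

  if (strip_hydrogens) {
    keep <- !(element %in% c("H", "D"))
    at <- at[keep, , drop = FALSE]
    element <- element[keep]
  }
  if (nrow(at) == 0L) stop("empty structure")

  atoms <- data.frame(
    serial = as.integer(at$eleno), name = trimws(at$elety),
    element = element, x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    bfactor = ifelse(is.na(at$b), 0, at$b),
    chain = as.character(at$chain),
    resnum = as.integer(at$resno),
    icode = ifelse(is.na(at$insert), "", as.character(at$insert)),
    aa3 = as.character(at$resid),
    alt = ifelse(is.na(at$alt), "", as.character(at$alt)),
    stringsAsFactors = FALSE)

  atoms <- .resolve_altloc(atoms)
  atoms$alt <- NULL
  if (n_removed > 0L)
    message("read_pdb: removed ", n_removed, " HETATM/water atom records")
  complex_structure(atoms, source = path,
                    hetero_stripped = strip_hetero,
                    hydrogens_stripped = strip_hydrogens)
}

## Scan raw ATOM/HETATM lines for unparseable coordinate fields; returns the
## 1-based line number of the first offender, or NA.
.find_bad_coord_line <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    fields <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                substr(lines[i], 47, 54))
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals))) return(i)
  }
  NA_integer_
}

## Keep, within each (residue, atom name) group, the alternate location with
## the highest occupancy; ties broken by first occurrence.
.resolve_altloc <- function(atoms) {
  grp <- paste(atoms$chain, atoms$resnum, atoms$icode, atoms$name, sep = "\r")
  ord <- order(factor(grp, levels = unique(grp)), -atoms$occupancy,
               seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  grp <- grp[ord]
  atoms <- atoms[!duplicated(grp), , drop = FALSE]
  atoms[order(atoms$serial), , drop = FALSE]
}

#' Write a ComplexStructure to a PDB file
#'
#' Emits standard ATOM records with coordinates to 3 decimals; chain ids,
#' residue numbers and insertion codes are preserved. Atom serials beyond
#' 99999 wrap around (PDB fixed-width convention).
#'
#' @param structure a `ComplexStructure`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "ComplexStructure"))
  a <- structure$atoms
  if (nrow(a) == 0L) stop("empty structure")
  ok <- tryCatch({
    bio3d::write.pdb(
      file = path,
      xyz = as.vector(t(xyz_matrix(a))),
      type = rep("ATOM", nrow(a)),
      resno = a$resnum,
      resid = a$aa3,
      eleno = ((a$serial - 1L) %% 99999L) + 1L,
      elety = a$name,
      chain = a$chain,
      insert = ifelse(a$icode == "", NA, a$icode),
      o = a$occupancy,
      b = a$bfactor,
      elesy = a$element)
    TRUE
  }, error = function(e) stop("cannot write PDB to ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Select one side of the partner partition
#'
#' @param structure a `ComplexStructure`.
#' @param partition a `PartnerPartition`.
#' @param side `"antibody"` or `"antigen"`.
#' @return a `ComplexStructure` containing exactly the requested chains, in
#'   the original order.
#' @export
select_partner <- function(structure, partition, side) {
  side <- match.arg(side, c("antibody", "antigen"))
  chains <- partition_side_chains(partition, side)
  have <- unique(structure$atoms$chain)
  missing_ch <- setdiff(chains, have)
  if (length(missing_ch))
    stop("chain(s) not found: ", paste(missing_ch, collapse = ", "),
         "; available chains: ", paste(have, collapse = ", "))
  sel <- structure$atoms$chain %in% chains
  complex_structure(structure$atoms[sel, ATOM_COLUMNS, drop = FALSE],
                    source = paste0(structure$source, " [", side, "]"),
                    hetero_stripped = structure$hetero_stripped,
                    hydrogens_stripped = structure$hydrogens_stripped)
}

#' Minimum heavy-atom distance between two residues
#'
#' @param resA,resB residue atom tables (from [get_residue()]).
#' @return minimum pairwise Euclidean distance in Angstrom.
#' @export
min_heavy_atom_distance <- function(resA, resB) {
  if (nrow(resA) == 0L || nrow(resB) == 0L)
    stop("residue with zero atoms")
  min(cross_distances(xyz_matrix(resA), xyz_matrix(resB)))
}

## All pairwise Euclidean distances between two coordinate matrices
## (nA x 3, nB x 3) -> nA x nB matrix.
cross_distances <- function(xa, xb) {
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  sqrt(pmax(d2, 0))
}
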