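## Self-contained pairwise force field (package energy units, "eu"):
##   - Lennard-Jones 6-12 on heavy atoms, Lorentz combining (r_min = r_i+r_j),
##     geometric-mean well depth, repulsive branch clamped per pair;
##   - Coulomb on formal charges with a distance-dependent dielectric
##     eps(r) = k*r, i.e. E = CC * q_i q_j / (k r^2), CC = 332 eu A / e^2;
##   - distance-window hydrogen bond (no angles: hydrogens are absent);
##   - buried-surface-area solvation (interaction_energy only).
## This function is package-defined; it reproduces qualitative interface
## mechanisms (steric clash penalty, salt-bridge reward), not any particular
## molecular-mechanics energy scale.

COULOMB_CONSTANT <- 332  # eu * Angstrom / e^2

## Formal-charge templates: charge per (aa3, atom name), net +/-1 per group.
.CHARGE_TEMPLATES <- data.frame(
  aa3  = c("ASP", "ASP", "GLU", "GLU", "LYS", "ARG", "ARG", "ARG"),
  name = c("OD1", "OD2", "OE1", "OE2", "NZ", "NE", "NH1", "NH2"),
  charge = c(-0.5, -0.5, -0.5, -0.5, 1.0, 0.2, 0.4, 0.4),
  stringsAsFactors = FALSE)

## Hydrogen-bond atom typing by (aa3, atom name); backbone N is a donor and
## backbone O an acceptor for every residue. Hydroxyls are both.
.HB_DONORS <- data.frame(
  aa3  = c("SER", "THR", "TYR", "ASN", "GLN", "LYS", "ARG", "ARG", "ARG",
           "TRP", "HIS", "HIS"),
  name = c("OG", "OG1", "OH", "ND2", "NE2", "NZ", "NE", "NH1", "NH2",
           "NE1", "ND1", "NE2"),
  stringsAsFactors = FALSE)
.HB_ACCEPTORS <- data.frame(
  aa3  = c("ASP", "ASP", "GLU", "GLU", "ASN", "GLN", "SER", "THR", "TYR",
           "HIS", "HIS"),
  name = c("OD1", "OD2", "OE1", "OE2", "OD1", "OE1", "OG", "OG1", "OH",
           "ND1", "NE2"),
  stringsAsFactors = FALSE)

#' Default force-field parameters
#'
#' @param weights named numeric vector of term weights
#'   (`w_lj`, `w_elec`, `w_hb`, `w_solv`).
#' @param cutoff pairwise interaction cutoff (Angstrom).
#' @param clamp repulsion clamp: maximum LJ energy per atom pair (eu).
#' @param dielectric_k coefficient of the distance-dependent dielectric
#'   eps(r) = k r (default 4).
#' @param hbond hydrogen-bond window: `r_min`, `r_opt`, `r_max` (Angstrom)
#'   and `depth` (eu).
#' @param probe solvent probe radius for buried-area solvation (Angstrom).
#' @return a `ForceFieldParams` list with per-element tables loaded from the
#'   packaged plain-text parameter file.
#' @export
default_forcefield <- function(weights = c(w_lj = 1, w_elec = 1, w_hb = 1,
                                           w_solv = 0.5),
                               cutoff = 8.0, clamp = 10.0, dielectric_k = 4.0,
                               hbond = c(r_min = 2.4, r_opt = 2.9,
                                         r_max = 3.4, depth = 2.0),
                               probe = 1.4) {
  path <- system.file("extdata", "ff_elements.tsv", package = "abrescue",
                      mustWork = TRUE)
  elems <- utils::read.table(path, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(elems$radius > 0), all(elems$well_depth > 0))
  if (cutoff < hbond[["r_max"]]) stop("cutoff must be >= hbond r_max")
  if (clamp <= 0) stop("repulsion clamp must be positive")
  if (!all(is.finite(weights)) || length(weights) != 4L)
    stop("weights must be 4 finite values")
  params <- list(
    elements = elems,
    radius = stats::setNames(elems$radius, elems$element),
    well_depth = stats::setNames(elems$well_depth, elems$element),
    sigma_solv = stats::setNames(elems$sigma_solv, elems$element),
    charges = .CHARGE_TEMPLATES,
    hb_donors = .HB_DONORS,
    hb_acceptors = .HB_ACCEPTORS,
    weights = weights, cutoff = cutoff, clamp = clamp,
    dielectric_k = dielectric_k, hbond = hbond, probe = probe)
  class(params) <- "ForceFieldParams"
  params
}

## Per-atom force-field annotation: radius, well depth, charge, donor and
## acceptor flags, solvation sigma. Input: atom table; output: list of
## vectors aligned with its rows.
atom_ff_annotation <- function(atoms, params) {
  el <- atoms$element
  unknown <- setdiff(unique(el), names(params$radius))
  if (length(unknown))
    stop("unknown element(s) for force field: ",
         paste(unknown, collapse = ", "))
  key <- paste(atoms$aa3, atoms$name)
  chg <- stats::setNames(params$charges$charge,
                         paste(params$charges$aa3, params$charges$name))
  charge <- unname(chg[key])
  charge[is.na(charge)] <- 0
  donor <- key %in% paste(params$hb_donors$aa3, params$hb_donors$name) |
    atoms$name == "N"
  acceptor <- key %in% paste(params$hb_acceptors$aa3, params$hb_acceptors$name) |
    atoms$name == "O"
  list(radius = unname(params$radius[el]),
       well_depth = unname(params$well_depth[el]),
       sigma_solv = unname(params$sigma_solv[el]),
       charge = charge, donor = donor, acceptor = acceptor)
}

## Vectorized pair terms. All arguments are equal-length vectors describing
## atom pairs; returns a list of per-pair lj / coulomb / hbond energies.
## Pairs beyond the cutoff contribute exactly 0.
pair_terms <- function(r, rad_i, rad_j, eps_i, eps_j, q_i, q_j,
                       don_i, acc_i, don_j, acc_j, params) {
  lj <- coul <- hb <- numeric(length(r))
  within <- r <= params$cutoff
  if (any(within)) {
    rr <- pmax(r[within], 1e-6)  # coincident atoms hit the clamp, not Inf
    rm <- rad_i[within] + rad_j[within]
    eps <- sqrt(eps_i[within] * eps_j[within])
    x6 <- (rm / rr)^6
    lj_raw <- eps * (x6^2 - 2 * x6)
    lj[within] <- pmin(lj_raw, params$clamp)
    qq <- q_i[within] * q_j[within]
    coul[within] <- COULOMB_CONSTANT * qq / (params$dielectric_k * rr^2)
    hb_pair <- (don_i[within] & acc_j[within]) |
      (don_j[within] & acc_i[within])
    hw <- params$hbond
    in_window <- hb_pair & rr >= hw[["r_min"]] & rr <= hw[["r_max"]]
    if (any(in_window)) {
      z <- (rr[in_window] - hw[["r_opt"]]) / (hw[["r_max"]] - hw[["r_opt"]])
      hb[in_window] <- -hw[["depth"]] * pmax(0, 1 - z^2)
    }
  }
  list(lj = lj, coulomb = coul, hbond = hb)
}

#' Assemble an EnergyBreakdown
#'
#' @param lj,coulomb,hbond,solvation unweighted term sums (eu).
#' @param params force-field parameters (for the term weights).
#' @return `EnergyBreakdown` list; `total` is the weighted sum of terms
#'   (exact arithmetic identity).
#' @export
energy_breakdown <- function(lj = 0, coulomb = 0, hbond = 0, solvation = 0,
                             params = default_forcefield()) {
  w <- params$weights
  out <- list(lj = lj, coulomb = coulomb, hbond = hbond,
              solvation = solvation,
              total = w[["w_lj"]] * lj + w[["w_elec"]] * coulomb +
                w[["w_hb"]] * hbond + w[["w_solv"]] * solvation)
  class(out) <- "EnergyBreakdown"
  out
}

#' @export
print.EnergyBreakdown <- function(x, ...) {
  cat(sprintf(
    "EnergyBreakdown (eu): lj=%.4f coulomb=%.4f hbond=%.4f solv=%.4f total=%.4f\n",
    x$lj, x$coulomb, x$hbond, x$solvation, x$total))
  invisible(x)
}

#' Pairwise energy of two atoms
#'
#' Scalar convenience wrapper around the vectorized force-field kernel.
#' Atoms are rows of a structure's atom table (or any data.frame with
#' `name`, `element`, `aa3` and coordinates). Solvation is a many-body term
#' and is always 0 here.
#'
#' @param atom_i,atom_j single-row atom data.frames.
#' @param params `ForceFieldParams`.
#' @return an `EnergyBreakdown`.
#' @export
pair_energy <- function(atom_i, atom_j, params = default_forcefield()) {
  both <- rbind(atom_i[, ATOM_COLUMNS], atom_j[, ATOM_COLUMNS])
  ann <- atom_ff_annotation(both, params)
  r <- vnorm(c(atom_i$x - atom_j$x, atom_i$y - atom_j$y,
               atom_i$z - atom_j$z))
  terms <- pair_terms(r, ann$radius[1], ann$radius[2],
                      ann$well_depth[1], ann$well_depth[2],
                      ann$charge[1], ann$charge[2],
                      ann$donor[1], ann$acceptor[1],
                      ann$donor[2], ann$acceptor[2], params)
  energy_breakdown(lj = terms$lj, coulomb = terms$coulomb,
                   hbond = terms$hbond, solvation = 0, params = params)
}
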