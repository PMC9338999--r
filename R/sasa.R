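## Shrake-Rupley solvent-accessible surface area with a deterministic
## golden-spiral point set. Hand-rolled: the quadrature feeds the solvation
## term and must be reproducible bit-for-bit for a fixed point count.

## Deterministic quasi-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' @param structure a `ComplexStructure` (or atom data.frame).
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sphere quadrature points per atom (default 92);
#'   deterministic for a fixed count.
#' @param params force-field parameters supplying per-element vdW radii.
#' @param subset optional integer vector of atom row indices to report
#'   (neighbors are always taken from the full structure).
#' @return numeric vector of per-atom SASA (Angstrom^2), one value per
#'   (selected) atom.
#' @export
sasa <- function(structure, probe = 1.4, n_points = 92L,
                 params = default_forcefield(), subset = NULL) {
  atoms <- if (inherits(structure, "ComplexStructure")) structure$atoms
           else structure
  if (nrow(atoms) == 0L) stop("empty structure")
  if (n_points < 12L) stop("n_points must be >= 12")
  xyz <- xyz_matrix(atoms)
  el <- atoms$element
  unknown <- setdiff(unique(el), names(params$radius))
  if (length(unknown)) stop("unknown element(s): ",
                            paste(unknown, collapse = ", "))
  rad <- unname(params$radius[el]) + probe
  pts <- sphere_points(n_points)
  idx <- if (is.null(subset)) seq_len(nrow(atoms)) else subset
  out <- numeric(length(idx))
  maxrad <- max(rad)
  for (k in seq_along(idx)) {
    i <- idx[k]
    ri <- rad[i]
    d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(d < ri + maxrad & seq_len(nrow(atoms)) != i)
    nb <- nb[d[nb] < ri + rad[nb]]
    if (!length(nb)) {
      out[k] <- 4 * pi * ri^2
      next
    }
    surf <- pts * ri + rep(xyz[i, ], each = n_points)
    ## point accessible iff outside every neighbor's expanded sphere
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
        (surf[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > rad[j]^2
      if (!any(acc)) break
    }
    out[k] <- 4 * pi * ri^2 * sum(acc) / n_points
  }
  out
}
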