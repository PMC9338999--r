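## Interaction/binding energies, rotamer-based mutation, greedy shell
## repacking and ensemble generation.

## Evaluate seeded expressions without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Interaction energy between two atom groups
#'
#' Sum of pairwise force-field terms over all cross-group atom pairs within
#' the cutoff, plus the buried-surface solvation term
#' `w_solv * sum(sigma_a * dSASA_a)` where `dSASA` is the per-atom burial
#' caused by complexation (SASA separate minus SASA bound). Symmetric in its
#' arguments.
#'
#' @param groupA,groupB `ComplexStructure` objects with disjoint atoms.
#' @param params `ForceFieldParams`.
#' @return an `EnergyBreakdown` (unweighted term sums; `total` weighted).
#' @export
interaction_energy <- function(groupA, groupB, params = default_forcefield()) {
  a <- groupA$atoms; b <- groupB$atoms
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty group")
  shared <- intersect(paste(a$reskey, a$name), paste(b$reskey, b$name))
  if (length(shared)) stop("groups share atoms: ", shared[1])
  annA <- atom_ff_annotation(a, params)
  annB <- atom_ff_annotation(b, params)
  d <- cross_distances(xyz_matrix(a), xyz_matrix(b))
  idx <- which(d <= params$cutoff, arr.ind = TRUE)
  lj <- coul <- hb <- 0
  if (nrow(idx)) {
    i <- idx[, 1]; j <- idx[, 2]
    terms <- pair_terms(d[idx], annA$radius[i], annB$radius[j],
                        annA$well_depth[i], annB$well_depth[j],
                        annA$charge[i], annB$charge[j],
                        annA$donor[i], annA$acceptor[i],
                        annB$donor[j], annB$acceptor[j], params)
    lj <- sum(terms$lj); coul <- sum(terms$coulomb); hb <- sum(terms$hbond)
  }

  ## solvation: only atoms whose SASA can change on complexation, i.e. with
  ## a cross-group atom within r_i + r_j + 2*probe (bounded by the max radii)
  reach <- 2 * max(params$radius) + 2 * params$probe
  solv <- 0
  affA <- which(apply(d, 1, min) <= reach)
  affB <- which(apply(d, 2, min) <= reach)
  if (length(affA) || length(affB)) {
    bound <- rbind(a[, ATOM_COLUMNS], b[, ATOM_COLUMNS])
    nA <- nrow(a)
    sasa_bound <- sasa(bound, probe = params$probe, params = params,
                       subset = c(affA, nA + affB))
    sasa_sepA <- if (length(affA))
      sasa(a, probe = params$probe, params = params, subset = affA) else numeric(0)
    sasa_sepB <- if (length(affB))
      sasa(b, probe = params$probe, params = params, subset = affB) else numeric(0)
    dsasa <- c(sasa_sepA, sasa_sepB) - sasa_bound
    sig <- c(annA$sigma_solv[affA], annB$sigma_solv[affB])
    solv <- sum(sig * dsasa)
  }
  energy_breakdown(lj = lj, coulomb = coul, hbond = hb, solvation = solv,
                   params = params)
}

#' Binding energy of a partitioned complex
#'
#' `dG_bind`: interaction energy between the antibody side and the antigen
#' side under rigid separation (the separated partners are not repacked).
#' More negative is more favorable.
#'
#' @param complex a `ComplexStructure`.
#' @param partition a `PartnerPartition`.
#' @param params `ForceFieldParams`.
#' @return scalar binding energy (eu), with the term breakdown attached as
#'   attribute `"breakdown"`.
#' @export
binding_energy <- function(complex, partition, params = default_forcefield()) {
  ab <- select_partner(complex, partition, "antibody")
  ag <- select_partner(complex, partition, "antigen")
  e <- interaction_energy(ab, ag, params)
  structure(e$total, breakdown = e)
}

## ---- mutation and repacking ------------------------------------------------

## Rebuild one residue with amino acid `aa3` and chi angles `chis`; backbone
## N/CA/C/O and CB are preserved (CB built from ideal geometry if absent,
## dropped for Gly). Returns the structure with the residue replaced in
## place; atom serials are renumbered sequentially.
set_residue_conformation <- function(structure, key, aa3, chis) {
  a <- structure$atoms
  rows <- which(a$reskey == key)
  if (!length(rows)) stop("residue not found: ", key)
  res <- a[rows, , drop = FALSE]
  bb_names <- c("N", "CA", "C", "O")
  if (!all(bb_names %in% res$name))
    stop("residue ", key, " lacks backbone atoms")
  coords <- residue_coord_list(res)
  keep <- res[res$name %in% bb_names, , drop = FALSE]
  keep <- keep[match(bb_names, keep$name), , drop = FALSE]

  new_atoms <- keep
  if (aa3 != "GLY") {
    if ("CB" %in% res$name) {
      cb <- res[res$name == "CB", , drop = FALSE][1, , drop = FALSE]
    } else {
      pos <- place_atom(coords[["C"]], coords[["N"]], coords[["CA"]],
                        1.53, 110.5, -122.5)
      cb <- keep[1, , drop = FALSE]
      cb$name <- "CB"; cb$element <- "C"
      cb$x <- pos[1]; cb$y <- pos[2]; cb$z <- pos[3]
      cb$occupancy <- 1; cb$bfactor <- 0
    }
    new_atoms <- rbind(new_atoms, cb)
    anchor <- residue_coord_list(new_atoms)
    sc <- build_sidechain_coords(aa3, anchor, chis)
    if (!is.null(sc)) {
      scdf <- new_atoms[rep(1L, nrow(sc)), , drop = FALSE]
      scdf$name <- rownames(sc)
      scdf$element <- element_from_name(rownames(sc))
      scdf$x <- sc[, 1]; scdf$y <- sc[, 2]; scdf$z <- sc[, 3]
      scdf$occupancy <- 1; scdf$bfactor <- 0
      new_atoms <- rbind(new_atoms, scdf)
    }
  }
  new_atoms$aa3 <- aa3
  before <- a[seq_len(nrow(a)) < rows[1], , drop = FALSE]
  after <- a[seq_len(nrow(a)) > rows[length(rows)], , drop = FALSE]
  out <- rbind(before, new_atoms, after)
  out$serial <- seq_len(nrow(out))
  complex_structure(out[, ATOM_COLUMNS],
                    source = structure$source,
                    hetero_stripped = structure$hetero_stripped,
                    hydrogens_stripped = structure$hydrogens_stripped)
}

## Score one residue against its environment: weighted lj+coulomb+hbond of
## the residue's atoms versus all other atoms within the cutoff (solvation
## excluded: it is a complexation term, not a packing score).
score_residue_env <- function(structure, key, params) {
  a <- structure$atoms
  rows <- a$reskey == key
  res <- a[rows, , drop = FALSE]
  env <- a[!rows, , drop = FALSE]
  annR <- atom_ff_annotation(res, params)
  annE <- atom_ff_annotation(env, params)
  d <- cross_distances(xyz_matrix(res), xyz_matrix(env))
  idx <- which(d <= params$cutoff, arr.ind = TRUE)
  if (!nrow(idx)) return(0)
  i <- idx[, 1]; j <- idx[, 2]
  terms <- pair_terms(d[idx], annR$radius[i], annE$radius[j],
                      annR$well_depth[i], annE$well_depth[j],
                      annR$charge[i], annE$charge[j],
                      annR$donor[i], annR$acceptor[i],
                      annE$donor[j], annE$acceptor[j], params)
  w <- params$weights
  w[["w_lj"]] * sum(terms$lj) + w[["w_elec"]] * sum(terms$coulomb) +
    w[["w_hb"]] * sum(terms$hbond)
}

## Pairwise (no solvation) energy of all atom pairs between different
## residues of `keys` plus pairs (keys x rest): the shell packing score.
score_shell <- function(structure, keys, params) {
  a <- structure$atoms
  in_shell <- a$reskey %in% keys
  shell <- a[in_shell, , drop = FALSE]
  rest <- a[!in_shell, , drop = FALSE]
  annS <- atom_ff_annotation(shell, params)
  total <- 0
  ## shell-shell (exclude same-residue pairs, count each pair once)
  d <- cross_distances(xyz_matrix(shell), xyz_matrix(shell))
  idx <- which(upper.tri(d) & d <= params$cutoff, arr.ind = TRUE)
  if (nrow(idx)) {
    same <- shell$reskey[idx[, 1]] == shell$reskey[idx[, 2]]
    idx <- idx[!same, , drop = FALSE]
  }
  w <- params$weights
  if (nrow(idx)) {
    i <- idx[, 1]; j <- idx[, 2]
    terms <- pair_terms(d[idx], annS$radius[i], annS$radius[j],
                        annS$well_depth[i], annS$well_depth[j],
                        annS$charge[i], annS$charge[j],
                        annS$donor[i], annS$acceptor[i],
                        annS$donor[j], annS$acceptor[j], params)
    total <- total + w[["w_lj"]] * sum(terms$lj) +
      w[["w_elec"]] * sum(terms$coulomb) + w[["w_hb"]] * sum(terms$hbond)
  }
  if (nrow(rest)) {
    annR <- atom_ff_annotation(rest, params)
    d2 <- cross_distances(xyz_matrix(shell), xyz_matrix(rest))
    idx2 <- which(d2 <= params$cutoff, arr.ind = TRUE)
    if (nrow(idx2)) {
      i <- idx2[, 1]; j <- idx2[, 2]
      terms <- pair_terms(d2[idx2], annS$radius[i], annR$radius[j],
                          annS$well_depth[i], annR$well_depth[j],
                          annS$charge[i], annR$charge[j],
                          annS$donor[i], annS$acceptor[i],
                          annR$donor[j], annR$acceptor[j], params)
      total <- total + w[["w_lj"]] * sum(terms$lj) +
        w[["w_elec"]] * sum(terms$coulomb) + w[["w_hb"]] * sum(terms$hbond)
    }
  }
  total
}

#' Point-mutate a residue with rotamer placement
#'
#' Backbone atoms (N, CA, C, O and the CB stub) are preserved; the side chain
#' is rebuilt from the best-scoring rotamer of the packaged library (ties
#' broken by library order). An identity substitution returns the input
#' unchanged, guaranteeing an identically zero ddG.
#'
#' @param structure a `ComplexStructure`.
#' @param key residue key "chain:resnum:icode".
#' @param target_aa target amino acid (1- or 3-letter code).
#' @param rotlib a `RotamerLibrary`.
#' @param params `ForceFieldParams`.
#' @param seed accepted for interface stability; the placement is a
#'   deterministic argmin and does not consume randomness.
#' @return mutated `ComplexStructure`.
#' @export
mutate_residue <- function(structure, key, target_aa,
                           rotlib = default_rotlib(),
                           params = default_forcefield(), seed = 1729L) {
  target_aa <- aa_three(target_aa)
  res <- get_residue(structure, key)
  native <- res$aa3[1]
  if (!native %in% AA_STANDARD)
    stop("cannot mutate nonstandard residue ", native, " at ", key)
  if (native == target_aa) return(structure)
  chis_list <- rotamer_chis(rotlib, target_aa)
  best <- NULL; best_score <- Inf
  for (chis in chis_list) {
    cand <- set_residue_conformation(structure, key, target_aa, chis)
    s <- score_residue_env(cand, key, params)
    if (s < best_score) { best_score <- s; best <- cand }
  }
  best
}

#' Packing shell around a residue
#'
#' @param structure a `ComplexStructure`.
#' @param center residue key.
#' @param radius shell radius in Angstrom (default 6): members are residues
#'   with any heavy atom within `radius` of the center residue.
#' @return a `PackingShell` (center, radius, member keys).
#' @export
packing_shell <- function(structure, center, radius = 6.0) {
  cres <- get_residue(structure, center)
  keys <- residue_keys(structure)
  members <- vapply(keys, function(k) {
    min_heavy_atom_distance(cres, get_residue(structure, k)) <= radius
  }, logical(1))
  structure(list(center = center, radius = radius,
                 members = keys[members]),
            class = "PackingShell")
}

#' Greedy rotamer repacking of a residue shell
#'
#' One-residue-at-a-time greedy rotamer descent over `sweeps` passes.
#' Gly/Ala/Pro are skipped. The scored shell energy (internal plus
#' to-environment pair terms) is non-increasing across accepted moves; the
#' per-sweep energies are attached as attribute `"sweep_energies"`.
#'
#' @param structure a `ComplexStructure`.
#' @param shell a `PackingShell` (or any list with a `members` element).
#' @param rotlib a `RotamerLibrary`.
#' @param params `ForceFieldParams`.
#' @param seed accepted for interface stability; the descent is deterministic.
#' @param sweeps number of passes (default 3).
#' @return repacked `ComplexStructure`.
#' @export
repack_shell <- function(structure, shell, rotlib = default_rotlib(),
                         params = default_forcefield(), seed = 1729L,
                         sweeps = 3L) {
  members <- intersect(residue_keys(structure), shell$members)
  rt <- residue_table(structure)
  flex <- members[!(rt$aa3[match(members, rt$reskey)] %in% AA_INFLEXIBLE) &
                    rt$aa3[match(members, rt$reskey)] %in% AA_STANDARD]
  cur <- structure
  energies <- numeric(0)
  e_prev <- score_shell(cur, members, params)
  for (sweep in seq_len(sweeps)) {
    for (key in flex) {
      aa3 <- cur$atoms$aa3[cur$atoms$reskey == key][1]
      cur_score <- score_residue_env(cur, key, params)
      best <- NULL; best_score <- cur_score
      for (chis in rotamer_chis(rotlib, aa3)) {
        cand <- set_residue_conformation(cur, key, aa3, chis)
        s <- score_residue_env(cand, key, params)
        if (s < best_score - 1e-9) { best_score <- s; best <- cand }
      }
      if (!is.null(best)) cur <- best
    }
    e_sweep <- score_shell(cur, members, params)
    if (e_sweep > e_prev + 1e-6)
      stop("internal error: shell energy increased during repack")
    energies <- c(energies, e_sweep)
    e_prev <- e_sweep
  }
  attr(cur, "sweep_energies") <- energies
  cur
}

#' Generate a structural ensemble by side-chain perturbation
#'
#' Model 1 is the repacked input; each further model applies Gaussian chi
#' jitter to the flexible interface side chains followed by a greedy shell
#' repack. Per-model total energies (binding energy plus interface packing
#' energy) are attached as attribute `"energies"`.
#'
#' @param structure a `ComplexStructure`.
#' @param partition a `PartnerPartition`.
#' @param M ensemble size (>= 1); the reference campaign uses M = 100.
#' @param jitter_sigma chi jitter standard deviation in degrees (default 10).
#' @param seed RNG seed (default 1729).
#' @param cutoff interface cutoff in Angstrom (default 5).
#' @param rotlib,params force-field inputs.
#' @return list of `ComplexStructure` models with attribute `"energies"`.
#' @export
generate_ensemble <- function(structure, partition, M = 100L,
                              jitter_sigma = 10, seed = 1729L, cutoff = 5.0,
                              rotlib = default_rotlib(),
                              params = default_forcefield()) {
  if (M < 1L) stop("M must be >= 1")
  fpa <- find_interface_residues(structure, partition, cutoff, "antibody")
  fpg <- find_interface_residues(structure, partition, cutoff, "antigen")
  iface <- c(fpa$residues, fpg$residues)
  shell <- list(center = NULL, radius = NA_real_, members = iface)
  rt <- residue_table(structure)
  flex <- iface[!(rt$aa3[match(iface, rt$reskey)] %in% AA_INFLEXIBLE)]

  base <- repack_shell(structure, shell, rotlib, params)
  models <- vector("list", M)
  models[[1]] <- base
  if (M > 1L) {
    with_seed(seed, {
      for (m in 2:M) {
        jit <- structure
        for (key in flex) {
          res <- get_residue(jit, key)
          aa3 <- res$aa3[1]
          nch <- n_chi(aa3)
          if (nch == 0L) next
          chis <- measure_chis(aa3, residue_coord_list(res))
          chis <- chis + stats::rnorm(nch, 0, jitter_sigma)
          jit <- set_residue_conformation(jit, key, aa3, chis)
        }
        models[[m]] <- repack_shell(jit, shell, rotlib, params)
      }
    })
  }
  energies <- vapply(models, function(s) {
    as.numeric(binding_energy(s, partition, params)) +
      score_shell(s, iface, params)
  }, numeric(1))
  attr(models, "energies") <- energies
  attr(models, "interface_keys") <- iface
  models
}
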