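## Interface detection, point-mutation ddG (antigen and antibody sides),
## ensemble clustering by interface fingerprint, saturation scanning and
## cross-cluster hotspot intersection.

#' Interface residues of one side of a complex
#'
#' A residue on `side` belongs to the interface iff its minimum heavy-atom
#' distance to some residue of the other side is within `cutoff` (default
#' 5 Angstrom, the scan radius used throughout the package).
#'
#' @param complex a `ComplexStructure`.
#' @param partition a `PartnerPartition`.
#' @param cutoff contact cutoff in Angstrom (> 0).
#' @param side `"antibody"` or `"antigen"`.
#' @return an `InterfaceFingerprint`: list with `side`, `residues`
#'   (character vector of residue keys) and `cutoff`.
#' @export
find_interface_residues <- function(complex, partition, cutoff = 5.0,
                                    side = c("antibody", "antigen")) {
  side <- match.arg(side)
  if (cutoff <= 0) stop("cutoff must be > 0")
  mine <- select_partner(complex, partition, side)
  other <- select_partner(complex, partition,
                          if (side == "antibody") "antigen" else "antibody")
  d <- cross_distances(xyz_matrix(mine$atoms), xyz_matrix(other$atoms))
  per_atom_min <- apply(d, 1, min)
  keys <- unique(mine$atoms$reskey[per_atom_min <= cutoff])
  structure(list(side = side, residues = keys, cutoff = cutoff),
            class = "InterfaceFingerprint")
}

resolve_mut <- function(mut) {
  if (is.list(mut)) list(key = mut$key %||% mut[[1]],
                         aa3 = aa_three(mut$aa3 %||% mut[[2]]))
  else list(key = mut[[1]], aa3 = aa_three(mut[[2]]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_side <- function(complex, partition, key, side) {
  chain <- strsplit(key, ":", fixed = TRUE)[[1]][1]
  want <- partition_side_chains(partition, side)
  if (!chain %in% want)
    stop("residue ", key, " is not on the ", side, " side (chains ",
         paste(want, collapse = ","), ")")
}

#' ddG of an antigen point mutation
#'
#' Change in binding energy caused by a point mutation on the antigen side:
#' `dG_bind(mutant-antigen complex) - dG_bind(wild-type complex)`. The mutant
#' is built by rotamer placement followed by a greedy repack of the packing
#' shell around the mutated residue. Positive values mean the antigen
#' mutation weakens antibody binding.
#'
#' @param complex wild-type `ComplexStructure`.
#' @param partition a `PartnerPartition`.
#' @param mut mutation spec: list/vector `(key, aa3)`.
#' @param params,rotlib force-field inputs.
#' @param seed passed to the (deterministic) mutation/repack steps.
#' @param shell_radius repack shell radius (Angstrom).
#' @return scalar ddG (eu) with attributes `dG_variant` and `dG_reference`.
#' @export
ddg_antigen_mutation <- function(complex, partition, mut,
                                 params = default_forcefield(),
                                 rotlib = default_rotlib(), seed = 1729L,
                                 shell_radius = 6.0) {
  m <- resolve_mut(mut)
  .check_side(complex, partition, m$key, "antigen")
  .ddg_point_mutation(complex, partition, m, params, rotlib, seed,
                      shell_radius)
}

#' ddG of an antibody point mutation against a (mutant) antigen
#'
#' `dG_bind(variant antibody vs antigen) - dG_bind(parental antibody vs
#' antigen)`; the input complex normally already carries the antigen
#' resistance mutation. Negative values flag candidate rescues.
#'
#' @param mut_antigen_complex `ComplexStructure` (typically antigen-mutant).
#' @param partition a `PartnerPartition`.
#' @param ab_mut mutation spec `(key, aa3)` on the antibody side.
#' @inheritParams ddg_antigen_mutation
#' @return scalar ddG (eu) with attributes `dG_variant` and `dG_reference`.
#' @export
ddg_antibody_mutation <- function(mut_antigen_complex, partition, ab_mut,
                                  params = default_forcefield(),
                                  rotlib = default_rotlib(), seed = 1729L,
                                  shell_radius = 6.0) {
  m <- resolve_mut(ab_mut)
  .check_side(mut_antigen_complex, partition, m$key, "antibody")
  .ddg_point_mutation(mut_antigen_complex, partition, m, params, rotlib,
                      seed, shell_radius)
}

.ddg_point_mutation <- function(complex, partition, m, params, rotlib, seed,
                                shell_radius) {
  native <- get_residue(complex, m$key)$aa3[1]
  dg_ref <- as.numeric(binding_energy(complex, partition, params))
  if (native == m$aa3) {
    ## identity substitution: exact short-circuit, ddG == 0 by construction
    return(structure(0, dG_variant = dg_ref, dG_reference = dg_ref))
  }
  mutant <- mutate_residue(complex, m$key, m$aa3, rotlib, params, seed)
  shell <- packing_shell(mutant, m$key, shell_radius)
  mutant <- repack_shell(mutant, shell, rotlib, params, seed)
  dg_var <- as.numeric(binding_energy(mutant, partition, params))
  structure(dg_var - dg_ref, dG_variant = dg_var, dG_reference = dg_ref,
            mutant = mutant)
}

#' Per-model ddG of a mutation over an ensemble
#'
#' Applies [ddg_antigen_mutation()] or [ddg_antibody_mutation()] to every
#' model of an ensemble and returns the vector of ddG values (one per
#' model). The reference campaign summarizes 100 models by their median.
#'
#' @param models list of `ComplexStructure` models (see
#'   [generate_ensemble()]).
#' @param partition a `PartnerPartition`.
#' @param mut mutation spec `(key, aa3)`.
#' @param side `"antigen"` or `"antibody"`: which side the mutation is on.
#' @inheritParams ddg_antigen_mutation
#' @return numeric vector of per-model ddG values (eu).
#' @export
ddg_over_ensemble <- function(models, partition, mut,
                              side = c("antigen", "antibody"),
                              params = default_forcefield(),
                              rotlib = default_rotlib(), seed = 1729L) {
  side <- match.arg(side)
  f <- if (side == "antigen") ddg_antigen_mutation else ddg_antibody_mutation
  vapply(models, function(s)
    as.numeric(f(s, partition, mut, params, rotlib, seed)), numeric(1))
}

## ---- clustering ------------------------------------------------------------

jaccard_distance <- function(sets) {
  n <- length(sets)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    u <- length(union(sets[[i]], sets[[j]]))
    d[i, j] <- d[j, i] <- if (u == 0) 0 else
      1 - length(intersect(sets[[i]], sets[[j]])) / u
  }
  d
}

#' Cluster an ensemble by interface fingerprint
#'
#' Average-linkage hierarchical clustering on the Jaccard distance between
#' antibody-side interface fingerprints, cut at `k` clusters. If the
#' ensemble has fewer distinct fingerprints than `k`, the largest clusters
#' are split by model index until `k` is reached (logged). The
#' representative of each cluster is its lowest-total-energy member (ties
#' by lowest model index).
#'
#' @param models ensemble list (with attribute `"energies"`, as produced by
#'   [generate_ensemble()]; energies are recomputed if absent).
#' @param partition a `PartnerPartition`.
#' @param k number of clusters (default 3).
#' @param cutoff interface cutoff (Angstrom).
#' @param seed accepted for interface stability (the procedure is
#'   deterministic given input order).
#' @param params force-field parameters (only needed when energies must be
#'   recomputed).
#' @return list of `ClusterReport` objects (cluster_id,
#'   member_model_indices, representative_index, fingerprint,
#'   n_scannable_positions, n_predictions).
#' @export
cluster_ensemble <- function(models, partition, k = 3L, cutoff = 5.0,
                             seed = 1729L, params = default_forcefield()) {
  if (!length(models)) stop("empty ensemble")
  fps <- lapply(models, function(s)
    find_interface_residues(s, partition, cutoff, "antibody")$residues)
  energies <- attr(models, "energies")
  if (is.null(energies))
    energies <- vapply(models, function(s)
      as.numeric(binding_energy(s, partition, params)), numeric(1))

  sig <- vapply(fps, function(x) paste(sort(x), collapse = "|"), character(1))
  n_distinct <- length(unique(sig))
  if (n_distinct >= k && length(models) > 1L) {
    d <- jaccard_distance(fps)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    assign <- stats::cutree(hc, k = k)
  } else {
    assign <- as.integer(factor(sig, levels = unique(sig)))
    while (max(assign) < k) {
      ## pad by splitting the largest cluster at its median model index
      sizes <- table(assign)
      big <- as.integer(names(sizes)[which.max(sizes)])
      idx <- which(assign == big)
      if (length(idx) < 2L)
        stop("cannot form ", k, " clusters from ", length(models), " model(s)")
      half <- idx[seq_len(ceiling(length(idx) / 2))]
      assign[setdiff(idx, half)] <- max(assign) + 1L
      message("cluster_ensemble: fewer than k distinct fingerprints; ",
              "split cluster ", big, " by model index")
    }
  }

  lapply(sort(unique(assign)), function(cl) {
    members <- which(assign == cl)
    rep_idx <- members[order(energies[members], members)][1]
    fp <- fps[[rep_idx]]
    structure(list(cluster_id = cl,
                   member_model_indices = members,
                   representative_index = rep_idx,
                   fingerprint = fp,
                   n_scannable_positions = length(fp),
                   n_predictions = 19L * length(fp)),
              class = "ClusterReport")
  })
}

## ---- saturation scanning ---------------------------------------------------

#' Saturation mutation scan of interface positions
#'
#' For each position, evaluates all 19 non-native substitutions
#' ([ddg_antibody_mutation()] with repack) against the given representative
#' structure. Record count is exactly `19 * length(positions)`.
#'
#' Bookkeeping-only mode: when `representative` is `NULL` (or `positions` is
#' a roster from [build_interface_roster()]), records are emitted with `NA`
#' energies so the scan arithmetic can be audited without a force field.
#'
#' @param representative a `ComplexStructure`, or `NULL` for roster mode.
#' @param partition a `PartnerPartition` (ignored in roster mode).
#' @param positions character vector of residue keys, or a roster
#'   data.frame with columns `key` and `native_aa`.
#' @param params,rotlib,seed force-field inputs.
#' @param cluster_id integer tag copied into the records.
#' @param warn_outside warn (but proceed) when a position is outside the
#'   antibody-side interface fingerprint.
#' @return data.frame of scan records: cluster_id, position, chain, resnum,
#'   icode, native_aa, substitution_aa, dG_variant, dG_reference, ddG.
#' @export
saturation_scan <- function(representative, partition, positions,
                            params = default_forcefield(),
                            rotlib = default_rotlib(), seed = 1729L,
                            cluster_id = 1L, warn_outside = TRUE) {
  roster_mode <- is.null(representative) || is.data.frame(positions)
  if (is.data.frame(positions)) {
    keys <- positions$key
    natives <- positions$native_aa
  } else {
    keys <- positions
    natives <- NULL
  }
  if (!length(keys)) stop("empty positions")

  if (!roster_mode) {
    rt <- residue_table(representative)
    natives <- rt$aa3[match(keys, rt$reskey)]
    if (any(is.na(natives)))
      stop("position(s) not in structure: ",
           paste(keys[is.na(natives)], collapse = ", "))
    fp <- find_interface_residues(representative, partition, side = "antibody")
    outside <- setdiff(keys, fp$residues)
    if (length(outside) && warn_outside)
      warning("position(s) outside the antibody interface fingerprint: ",
              paste(outside, collapse = ", "), "; scanning anyway")
    dg_ref <- as.numeric(binding_energy(representative, partition, params))
  }
  if (is.null(natives)) natives <- rep("ALA", length(keys))

  records <- vector("list", length(keys))
  for (p in seq_along(keys)) {
    key <- keys[p]
    native <- natives[p]
    subs <- setdiff(unname(AA_STANDARD), native)
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    if (roster_mode) {
      recs <- data.frame(
        cluster_id = cluster_id, position = key,
        chain = parts[1], resnum = suppressWarnings(as.integer(parts[2])),
        icode = ifelse(is.na(parts[3]), "", parts[3]),
        native_aa = native, substitution_aa = subs,
        dG_variant = NA_real_, dG_reference = NA_real_, ddG = NA_real_,
        stringsAsFactors = FALSE)
    } else {
      vals <- lapply(subs, function(aa)
        ddg_antibody_mutation(representative, partition, list(key, aa),
                              params, rotlib, seed))
      recs <- data.frame(
        cluster_id = cluster_id, position = key,
        chain = parts[1], resnum = as.integer(parts[2]),
        icode = ifelse(is.na(parts[3]), "", parts[3]),
        native_aa = native, substitution_aa = subs,
        dG_variant = vapply(vals, function(v) attr(v, "dG_variant"),
                            numeric(1)),
        dG_reference = dg_ref,
        ddG = vapply(vals, as.numeric, numeric(1)),
        stringsAsFactors = FALSE)
    }
    records[[p]] <- recs
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}

#' Cross-cluster hotspot selection
#'
#' Per cluster, a position is a candidate when its best (minimum over
#' substitutions) ddG is at most `threshold`; the hotspot set is the exact
#' intersection of the per-cluster candidate sets. The reported
#' per-position best ddG is the maximum over clusters of the per-cluster
#' minimum (a worst-case guarantee across the ensemble).
#'
#' @param cluster_scans list of scan-record data.frames (one per cluster).
#' @param threshold candidate threshold tau in eu (default 0: some
#'   substitution is predicted to improve binding).
#' @param campaign label copied into the report.
#' @return a `HotspotSet`: campaign, threshold, per_cluster_candidates,
#'   hotspots, per_position_best_ddG.
#' @export
select_hotspots <- function(cluster_scans, threshold = 0.0,
                            campaign = "campaign") {
  if (!length(cluster_scans)) stop("need at least one cluster scan")
  per_cluster <- lapply(cluster_scans, function(sc) {
    best <- tapply(sc$ddG, sc$position, min)
    names(best)[!is.na(best) & best <= threshold]
  })
  hotspots <- Reduce(intersect, per_cluster)
  best_map <- numeric(0)
  if (length(hotspots)) {
    per_pos <- vapply(hotspots, function(p) {
      max(vapply(cluster_scans, function(sc)
        min(sc$ddG[sc$position == p]), numeric(1)))
    }, numeric(1))
    best_map <- per_pos
  }
  structure(list(campaign = campaign, threshold = threshold,
                 per_cluster_candidates = per_cluster,
                 hotspots = hotspots,
                 per_position_best_ddG = best_map),
            class = "HotspotSet")
}
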