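## Deterministic synthetic fixtures: a desk-scale antibody-antigen toy
## complex with engineered steric-clash / salt-bridge-rescue ground truth
## (a synthetic stand-in for a real receptor/Fab interface), abstract
## interface rosters for scan bookkeeping, and panning truth sets.
##
## The toy complex is built from ideal internal coordinates, never from a
## downloaded structure, so the clash geometry is provable: every packaged
## rotamer of the clash amino acid at the antigen cavity position overlaps
## opposing heavy atoms, while one rotamer pair of (clash aa, rescue aa)
## forms a carboxylate-guanidinium contact at salt-bridge distance once the
## bulky antibody residue is replaced.

## Build one residue's atoms at an arbitrary rigid placement: CA at `ca`,
## CB direction `cb_dir`, secondary reference direction `ref_dir` (fixes the
## rotation about the CA-CB axis), side-chain chi angles `chis`.
make_residue_atoms <- function(chain, resnum, aa3, ca, cb_dir, ref_dir,
                               chis = numeric(0)) {
  aa3 <- aa_three(aa3)
  deg <- pi / 180
  ## canonical backbone in a local frame (CA at origin)
  N0 <- 1.458 * c(cos(55.5 * deg), sin(55.5 * deg), 0)
  C0 <- 1.525 * c(cos(55.5 * deg), -sin(55.5 * deg), 0)
  CA0 <- c(0, 0, 0)
  CB0 <- place_atom(C0, N0, CA0, 1.53, 110.5, -122.5)
  O0 <- place_atom(N0, CA0, C0, 1.231, 120.5, 180)

  e1 <- vunit(CB0 - CA0)
  e2 <- vunit((N0 - CA0) - sum((N0 - CA0) * e1) * e1)
  e3 <- vcross(e1, e2)
  f1 <- vunit(cb_dir)
  rproj <- ref_dir - sum(ref_dir * f1) * f1
  if (vnorm(rproj) < 1e-8) stop("ref_dir parallel to cb_dir")
  f2 <- vunit(rproj)
  f3 <- vcross(f1, f2)
  R <- cbind(f1, f2, f3) %*% t(cbind(e1, e2, e3))
  tx <- function(v) as.numeric(ca + R %*% (v - CA0))

  names <- c("N", "CA", "C", "O")
  pos <- rbind(tx(N0), tx(CA0), tx(C0), tx(O0))
  if (aa3 != "GLY") {
    names <- c(names, "CB")
    pos <- rbind(pos, tx(CB0))
    anchor <- list(N = pos[1, ], CA = pos[2, ], CB = pos[5, ])
    sc <- build_sidechain_coords(aa3, anchor, chis)
    if (!is.null(sc)) {
      names <- c(names, rownames(sc))
      pos <- rbind(pos, sc)
    }
  }
  data.frame(serial = seq_along(names), name = names,
             element = element_from_name(names),
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             occupancy = 1, bfactor = 0,
             chain = chain, resnum = resnum, icode = "", aa3 = aa3,
             stringsAsFactors = FALSE)
}

.assemble <- function(res_list, source = "toy-complex") {
  atoms <- do.call(rbind, res_list)
  atoms$serial <- seq_len(nrow(atoms))
  complex_structure(atoms, source = source)
}

## Max overlap (sum of vdW radii minus distance) over cross pairs of two
## atom tables; > 0 means interpenetration.
.max_overlap <- function(a, b, radii) {
  d <- cross_distances(xyz_matrix(a), xyz_matrix(b))
  rm <- outer(unname(radii[a$element]), unname(radii[b$element]), "+")
  max(rm - d)
}

## Repulsive LJ penalty (clamped, weighted as scored) between two atom
## tables: the currency in which blockers must outbid the corridor clash.
.clash_penalty <- function(a, b, params) {
  d <- cross_distances(xyz_matrix(a), xyz_matrix(b))
  rm <- outer(unname(params$radius[a$element]),
              unname(params$radius[b$element]), "+")
  eps <- sqrt(outer(unname(params$well_depth[a$element]),
                    unname(params$well_depth[b$element])))
  x6 <- (rm / pmax(d, 1e-6))^6
  lj <- pmin(eps * (x6^2 - 2 * x6), params$clamp)
  lj[d > params$cutoff] <- 0
  params$weights[["w_lj"]] * sum(lj[lj > 0])
}

## Side-chain conformers of `aa3` built on a residue's backbone, one atom
## table per packaged rotamer.
.conformers <- function(res_atoms, aa3, rotlib) {
  lapply(rotamer_chis(rotlib, aa3), function(chis) {
    tmp <- .assemble(list(res_atoms), source = "tmp")
    out <- set_residue_conformation(tmp, res_atoms$reskey[1] %||%
                                      paste(res_atoms$chain[1],
                                            res_atoms$resnum[1], "",
                                            sep = ":"),
                                    aa3, chis)
    out$atoms[, ATOM_COLUMNS]
  })
}

#' Build the synthetic clash/rescue toy complex
#'
#' Constructs a two-chain complex (antigen chain "A": Gly-cavity-Gly;
#' antibody chain "H": a bulky residue facing the cavity plus Ala/Gly cage
#' residues) such that
#' (i) the wild-type complex binds favorably,
#' (ii) every packaged rotamer of `clash_aa` at the cavity position overlaps
#' at least one opposing heavy atom by >= 0.4 Angstrom, and
#' (iii) substituting `rescue_to` for `rescue_from` on the antibody opens a
#' clash-free corridor for one `clash_aa` rotamer and places an acceptor
#' oxygen 2.7-3.2 Angstrom from a side-chain nitrogen of `clash_aa`.
#' All three properties are verified numerically at build time; the builder
#' errors if the requested amino-acid combination cannot satisfy them.
#'
#' @param seed recorded in the manifest; the construction itself is
#'   deterministic.
#' @param cavity_aa native antigen residue at the cavity position
#'   (default "SER").
#' @param clash_aa resistance substitution expected to clash
#'   (default "ARG").
#' @param rescue_from native bulky antibody residue (default "TRP").
#' @param rescue_to rescuing antibody substitution (default "ASP").
#' @param params,rotlib force-field inputs used for the build-time checks.
#' @return list with elements `structure` (a repacked `ComplexStructure`),
#'   `partition`, and `manifest` (a `FixtureManifest` list: counts, contact
#'   pairs, clash/rescue keys, per-rotamer overlaps, salt-bridge geometry,
#'   expected ddG signs).
#' @export
build_toy_complex <- function(seed = 1729L, cavity_aa = "SER",
                              clash_aa = "ARG", rescue_from = "TRP",
                              rescue_to = "ASP",
                              params = default_forcefield(),
                              rotlib = default_rotlib()) {
  cavity_aa <- aa_three(cavity_aa); clash_aa <- aa_three(clash_aa)
  rescue_from <- aa_three(rescue_from); rescue_to <- aa_three(rescue_to)
  if (cavity_aa == clash_aa)
    stop("cavity_aa equals clash_aa: no mutation to test")
  radii <- params$radius

  yhat <- c(0, 1, 0); xhat <- c(1, 0, 0)
  ## antigen chain A: Gly - cavity - Gly along x, side chains toward +y
  ag <- list(
    make_residue_atoms("A", 1L, "GLY", c(-3.8, 0, 0), yhat, xhat),
    make_residue_atoms("A", 2L, cavity_aa, c(0, 0, 0), yhat, xhat,
                       rotamer_chis(rotlib, cavity_aa)[[1]]),
    make_residue_atoms("A", 3L, "GLY", c(3.8, 0, 0), yhat, xhat))
  cavity_key <- "A:2:"
  cb_row <- ag[[2]][ag[[2]]$name == "CB", ]
  cb_pos <- c(cb_row$x, cb_row$y, cb_row$z)

  ## clash-residue conformers on the cavity backbone
  arg_confs <- .conformers(ag[[2]], clash_aa, rotlib)
  arg_tip <- lapply(arg_confs, function(at) {
    sc <- at[!at$name %in% c("N", "CA", "C", "O", "CB"), , drop = FALSE]
    if (!nrow(sc)) stop("clash_aa has no side chain beyond CB")
    d <- sqrt((sc$x - cb_pos[1])^2 + (sc$y - cb_pos[2])^2 +
                (sc$z - cb_pos[3])^2)
    sc[which.max(d), , drop = FALSE]
  })
  reach <- vapply(arg_tip, function(t)
    vnorm(c(t$x, t$y, t$z) - cb_pos), numeric(1))
  rescue_rot <- which.max(reach)  # corridor rotamer: the longest reach

  ## place the bulky antibody residue so that (a) one of its rotamers
  ## blocks the corridor rotamer and (b) the rescue substitution can form
  ## an O...N contact at 2.7-3.2 A with that same rotamer
  don_names <- params$hb_donors$name[params$hb_donors$aa3 == clash_aa]
  acc_names <- params$hb_acceptors$name[params$hb_acceptors$aa3 == rescue_to]
  acc_names <- acc_names[grepl("^O", acc_names)]
  if (!length(don_names) || !length(acc_names))
    stop("geometric assertions unsatisfiable: ", clash_aa, "/", rescue_to,
         " cannot form a donor-oxygen salt bridge")

  ## antibody placement axis: from the cavity CB through the corridor
  ## rotamer's distal atom, so the bulky residue faces the incoming clash
  tip0 <- arg_tip[[rescue_rot]]
  u_ax <- vunit(c(tip0$x, tip0$y, tip0$z) - cb_pos)
  u_ref <- vunit(vcross(u_ax, if (abs(u_ax[3]) < 0.9) c(0, 0, 1) else xhat))
  tip_pos <- c(tip0$x, tip0$y, tip0$z)

  found <- NULL
  for (d_ca in seq(2.5, 9, by = 0.25)) {
    trp_res <- make_residue_atoms("H", 1L, rescue_from,
                                  tip_pos + d_ca * u_ax, -u_ax, u_ref,
                                  rotamer_chis(rotlib, rescue_from)[[1]])
    trp_confs <- .conformers(trp_res, rescue_from, rotlib)
    asp_confs <- .conformers(trp_res, rescue_to, rotlib)
    corridor <- arg_confs[[rescue_rot]]
    ## (a) some bulky-residue rotamer overlaps the corridor rotamer deeply
    ov_trp <- vapply(trp_confs, function(tc)
      .max_overlap(corridor, tc, radii), numeric(1))
    axial <- which.max(ov_trp)
    if (ov_trp[axial] < 1.0) next
    ## (b) salt bridge: an acceptor O of some rescue rotamer sits at
    ## 2.7-3.2 A from a donor N of the corridor rotamer, with no deep
    ## cross overlap elsewhere
    best <- NULL
    for (ai in seq_along(asp_confs)) {
      ac <- asp_confs[[ai]]
      o_at <- ac[ac$name %in% acc_names, , drop = FALSE]
      n_at <- corridor[corridor$name %in% don_names, , drop = FALSE]
      dd <- cross_distances(xyz_matrix(o_at), xyz_matrix(n_at))
      if (any(dd >= 2.7 & dd <= 3.2) &&
          .max_overlap(corridor, ac, radii) < 0.4) {
        best <- list(asp_rot = ai, sb_dist = min(dd[dd >= 2.7 & dd <= 3.2]))
        break
      }
    }
    if (is.null(best)) next
    found <- c(list(d_ca = d_ca, axial = axial, trp_res = trp_res,
                    trp_confs = trp_confs, asp_confs = asp_confs), best)
    break
  }
  if (is.null(found))
    stop("geometric assertions unsatisfiable for ", cavity_aa, "/",
         clash_aa, "/", rescue_from, "/", rescue_to)

  trp_res <- set_residue_conformation(
    .assemble(list(found$trp_res)), "H:1:", rescue_from,
    rotamer_chis(rotlib, rescue_from)[[found$axial]])$atoms[, ATOM_COLUMNS]

  ## protected atoms: nothing placed later may interpenetrate these
  cav_confs <- .conformers(ag[[2]], cavity_aa, rotlib)
  protected <- rbind(
    do.call(rbind, ag),
    do.call(rbind, cav_confs),
    arg_confs[[rescue_rot]],
    found$asp_confs[[found$asp_rot]],
    trp_res)

  place_blocker <- function(target_atoms, chain, resnum, protected,
                            clash_with, min_overlap = 1.2) {
    ## put an Ala CB near `target_atoms` so it deeply overlaps `clash_with`
    ## but keeps clear of `protected`
    ctr <- colMeans(xyz_matrix(target_atoms))
    u <- vunit(ctr - cb_pos)
    for (off in c(0, 0.4, 0.8, 1.2, 1.6)) {
      for (ref in list(xhat, c(0, 0, 1), -xhat, c(0, 0, -1))) {
        cbp <- ctr + off * u
        cap <- cbp + 1.53 * u
        cand <- tryCatch(
          make_residue_atoms(chain, resnum, "ALA", cap, -u, ref),
          error = function(e) NULL)
        if (is.null(cand)) next
        if (.max_overlap(cand, clash_with, radii) < min_overlap) next
        ## soft-contact tolerance: <= 0.6 A interpenetration of protected
        ## atoms costs < 0.5 eu per pair, far below one clamped clash
        if (.max_overlap(cand, protected, radii) > 0.6) next
        return(cand)
      }
    }
    NULL
  }

  ab <- list(trp_res)
  next_resnum <- 2L
  corridor_sc <- local({
    rc <- arg_confs[[rescue_rot]]
    rc[!rc$name %in% c("N", "CA", "C", "O", "CB"), , drop = FALSE]
  })
  axial_pen <- .clash_penalty(corridor_sc, trp_res, params)

  ## add Ala blockers near `target` atoms until the clamped repulsion they
  ## inflict on `target` reaches `budget`, staying clear of protected atoms
  add_blockers <- function(target, budget, max_new = 5L) {
    added <- 0L
    repeat {
      others <- if (length(ab) > 1L) do.call(rbind, ab[-1]) else NULL
      pen <- if (is.null(others)) 0 else .clash_penalty(target, others, params)
      if (pen >= budget) return(TRUE)
      if (added >= max_new) return(FALSE)
      prot <- rbind(protected, do.call(rbind, ab))
      clearance <- apply(cross_distances(xyz_matrix(target),
                                         xyz_matrix(prot)), 1, min)
      open <- rep(TRUE, nrow(target))
      if (!is.null(others)) {
        dmin <- apply(cross_distances(xyz_matrix(target),
                                      xyz_matrix(others)), 1, min)
        open <- dmin > 2.6   # skip atoms a blocker already covers
      }
      cand_atoms <- target[open, , drop = FALSE]
      if (!nrow(cand_atoms)) return(FALSE)
      cand_atoms <- cand_atoms[order(-clearance[open]), , drop = FALSE]
      bl <- NULL
      for (kk in c(3L, 2L, 1L)) {
        bl <- place_blocker(utils::head(cand_atoms, kk), "H", next_resnum,
                            prot, target)
        if (!is.null(bl)) break
      }
      if (is.null(bl)) return(FALSE)
      ab[[length(ab) + 1L]] <<- bl
      next_resnum <<- next_resnum + 1L
      added <- added + 1L
    }
  }

  ## braces: intra-side blockers that punish every non-axial rotamer of the
  ## bulky residue (more than the corridor clash punishes the axial one) so
  ## greedy repacking keeps it blocking the corridor
  for (ti in seq_along(found$trp_confs)) {
    if (ti == found$axial) next
    tc <- found$trp_confs[[ti]]
    ring <- tc[!tc$name %in% c("N", "CA", "C", "O", "CB", "CG"), , drop = FALSE]
    if (!nrow(ring)) next
    if (!add_blockers(ring, axial_pen + 20))
      stop("geometric assertions unsatisfiable: cannot brace rotamer ", ti,
           " of ", rescue_from)
  }

  ## cage: cross-side blockers so every non-corridor rotamer of the clash
  ## residue is strongly penalized across the interface
  for (ri in seq_along(arg_confs)) {
    if (ri == rescue_rot) next
    rc <- arg_confs[[ri]]
    sc <- rc[!rc$name %in% c("N", "CA", "C", "O", "CB"), , drop = FALSE]
    ## target the distal half of the side chain
    dist_cb <- sqrt((sc$x - cb_pos[1])^2 + (sc$y - cb_pos[2])^2 +
                      (sc$z - cb_pos[3])^2)
    tip <- sc[dist_cb >= stats::median(dist_cb), , drop = FALSE]
    if (!add_blockers(tip, 25))
      stop("geometric assertions unsatisfiable: cannot cage rotamer ", ri,
           " of ", clash_aa)
  }

  complex0 <- .assemble(c(ag, ab), source = "synthetic-toy-complex")
  partition <- partner_partition(antibody_chains = "H", antigen_chains = "A")

  ## settle the starting conformation: greedy repack of the interface
  fpa <- find_interface_residues(complex0, partition, 5, "antibody")
  fpg <- find_interface_residues(complex0, partition, 5, "antigen")
  shell <- list(members = c(fpa$residues, fpg$residues))
  complex0 <- repack_shell(complex0, shell, rotlib, params)
  attr(complex0, "sweep_energies") <- NULL

  ## ---- build-time verification --------------------------------------------
  ab_atoms <- complex0$atoms[complex0$atoms$chain == "H", , drop = FALSE]
  overlaps <- vapply(seq_along(arg_confs), function(ri) {
    sc <- arg_confs[[ri]]
    .max_overlap(sc[!sc$name %in% c("N", "CA", "C", "O"), , drop = FALSE],
                 ab_atoms, radii)
  }, numeric(1))
  if (any(overlaps < 0.4))
    stop("geometric assertions unsatisfiable: rotamer(s) ",
         paste(which(overlaps < 0.4), collapse = ","), " of ", clash_aa,
         " do not clash (max overlap ",
         paste(round(overlaps[overlaps < 0.4], 2), collapse = ","), ")")
  ## the bulky residue must have settled into the corridor-blocking rotamer
  trp_now <- get_residue(complex0, "H:1:")
  if (.max_overlap(arg_confs[[rescue_rot]], trp_now, radii) < 1.0)
    stop("geometric assertions unsatisfiable: repack moved ", rescue_from,
         " out of the corridor")
  dg_wt <- as.numeric(binding_energy(complex0, partition, params))
  if (dg_wt >= 0)
    stop("toy complex is not favorable: dG_bind = ", round(dg_wt, 3))

  ## ground-truth residue contact pairs (min heavy-atom distance <= 5 A)
  contacts <- local({
    rt <- residue_table(complex0)
    agk <- rt$reskey[rt$chain == "A"]
    abk <- rt$reskey[rt$chain == "H"]
    grid <- expand.grid(antigen = agk, antibody = abk,
                        stringsAsFactors = FALSE)
    dmin <- mapply(function(p, q)
      min_heavy_atom_distance(get_residue(complex0, p),
                              get_residue(complex0, q)),
      grid$antigen, grid$antibody)
    cbind(grid[dmin <= 5, , drop = FALSE], distance = dmin[dmin <= 5])
  })

  manifest <- structure(list(
    seed = seed,
    n_atoms = nrow(complex0$atoms),
    n_residues = nrow(residue_table(complex0)),
    cavity_aa = cavity_aa, clash_aa = clash_aa,
    rescue_from = rescue_from, rescue_to = rescue_to,
    clash_position = cavity_key, rescue_position = "H:1:",
    rotamer_overlaps = overlaps,
    corridor_rotamer = rescue_rot,
    salt_bridge_distance = found$sb_dist,
    dG_wildtype = dg_wt,
    contact_pairs = contacts,
    expected_sign_antigen_mutation = "positive",
    expected_sign_antibody_rescue = "negative"),
    class = "FixtureManifest")

  list(structure = complex0, partition = partition, manifest = manifest)
}

#' Abstract interface roster for scan bookkeeping
#'
#' Synthetic position lists of requested sizes, consumable by
#' [saturation_scan()] in bookkeeping-only mode (energies skipped), so the
#' scan-count arithmetic (19 substitutions per position) can be audited
#' independently of any force field.
#'
#' @param cluster_position_counts integer vector: number of scannable
#'   positions per cluster (e.g. `c(36, 35, 35)` gives per-cluster
#'   prediction counts 684/665/665).
#' @return list of roster data.frames (columns `key`, `native_aa`), one per
#'   cluster.
#' @export
build_interface_roster <- function(cluster_position_counts) {
  counts <- as.integer(cluster_position_counts)
  if (!length(counts) || any(counts < 1L))
    stop("cluster position counts must be positive integers")
  lapply(seq_along(counts), function(cl) {
    n <- counts[cl]
    data.frame(key = sprintf("H:%d:", seq_len(n)),
               native_aa = rep("ALA", n),
               stringsAsFactors = FALSE)
  })
}

#' Panning truth set: one engineered dual binder among decoys
#'
#' Builds per-target ddG tables and a starting pool in which exactly one
#' genotype ("dual") has at least an `dual_binder_advantage`-fold Kd edge on
#' both targets, while every decoy binds at most one target.
#'
#' @param seed RNG seed for decoy ddG draws.
#' @param n_decoys number of decoy variants (default 8).
#' @param dual_binder_advantage fold Kd advantage of the dual binder
#'   (> 1).
#' @param kd_ref reference Kd (nM).
#' @param beta energy-to-affinity slope (1/eu).
#' @return list: `ddg_tables` (per target), `pool` (a `VariantPool`),
#'   `winner` (the dual binder's id), `targets`.
#' @export
build_panning_truth <- function(seed = 1729L, n_decoys = 8L,
                                dual_binder_advantage = 10,
                                kd_ref = 100, beta = 1.0) {
  if (dual_binder_advantage <= 1)
    stop("dual_binder_advantage must be > 1")
  targets <- c("mutant", "wildtype")
  adv_ddg <- -log(dual_binder_advantage) / beta

  positions <- c("H:104:", "H:50:")
  aas <- c("ASP", "GLN")
  genotypes <- list(dual = stats::setNames(aas, positions))
  ddg_mut <- data.frame(position = positions, aa = aas,
                        ddg = c(adv_ddg, 0), stringsAsFactors = FALSE)
  ddg_wt <- data.frame(position = positions, aa = aas,
                       ddg = c(adv_ddg, 0), stringsAsFactors = FALSE)

  decoy_rows_mut <- decoy_rows_wt <- list()
  with_seed(seed, {
    for (i in seq_len(n_decoys)) {
      id <- sprintf("decoy%02d", i)
      pos <- sprintf("H:%d:", 200 + i)
      aa <- sample(setdiff(unname(AA_STANDARD), "ALA"), 1)
      genotypes[[id]] <- stats::setNames(aa, pos)
      ## decoys bind at most one target: parental-or-worse on one target
      ## (so the dual binder keeps its full fold advantage), hopeless on
      ## the other
      good_on_mutant <- (i %% 2L == 0L)
      good <- stats::runif(1, 0, 1)
      badv <- stats::runif(1, 8, 12)            # effectively non-binding
      decoy_rows_mut[[i]] <- data.frame(
        position = pos, aa = aa,
        ddg = if (good_on_mutant) good else badv, stringsAsFactors = FALSE)
      decoy_rows_wt[[i]] <- data.frame(
        position = pos, aa = aa,
        ddg = if (good_on_mutant) badv else good, stringsAsFactors = FALSE)
    }
  })
  ddg_mut <- rbind(ddg_mut, do.call(rbind, decoy_rows_mut))
  ddg_wt <- rbind(ddg_wt, do.call(rbind, decoy_rows_wt))
  tables <- list(mutant = ddg_mut, wildtype = ddg_wt)

  ids <- names(genotypes)
  kd <- matrix(NA_real_, nrow = length(ids), ncol = length(targets),
               dimnames = list(ids, targets))
  for (id in ids) for (tg in targets)
    kd[id, tg] <- affinity_from_ddg(tables[[tg]], genotypes[[id]],
                                    beta = beta, kd_ref = kd_ref)
  ## affinities 1e4-fold above the reference are below any detectable
  ## binding: encoded as Inf, which the simulator treats as zero capture
  kd[kd > 1e4 * kd_ref] <- Inf
  pool <- variant_pool(genotypes, kd)
  list(ddg_tables = tables, pool = pool, winner = "dual", targets = targets)
}
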