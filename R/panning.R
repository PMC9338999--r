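## Stochastic simulator of a coselection phage-display panning campaign:
## prepan depletion of nonspecific binders, equilibrium-occupancy capture,
## wash attrition, amplification to a fixed pool size, and an optional
## dual-target screen after the final round.
##
## Kinetics are equilibrium based: each variant carries one Kd (nM) per
## target; wash survival is a Kd-monotone proxy for off-rate. The default
## mode is deterministic expected-value propagation; `stochastic = TRUE`
## samples binomial survival and multinomial amplification from a seeded
## generator.

#' Construct a variant pool
#'
#' @param genotypes named list of genotypes (each a named character vector
#'   position -> amino acid); names are the variant ids.
#' @param kd numeric matrix of dissociation constants in nM, rows = variants
#'   (rownames = ids), columns = targets (colnames = target labels); `Inf`
#'   encodes no measurable binding.
#' @param counts named numeric vector of particle counts (default: 1000 per
#'   variant).
#' @param nonspecific named logical: prepan-removable cross-reactors
#'   (default all FALSE).
#' @param growth_factor named numeric amplification weights (default 1).
#' @return a `VariantPool`.
#' @export
variant_pool <- function(genotypes, kd, counts = NULL, nonspecific = NULL,
                         growth_factor = NULL) {
  ids <- names(genotypes)
  if (is.null(ids) || any(ids == "")) stop("genotypes must be named")
  stopifnot(is.matrix(kd), nrow(kd) == length(ids))
  if (is.null(rownames(kd))) rownames(kd) <- ids
  if (any(kd <= 0, na.rm = TRUE)) stop("Kd must be > 0")
  if (is.null(counts)) counts <- stats::setNames(rep(1000, length(ids)), ids)
  if (is.null(nonspecific))
    nonspecific <- stats::setNames(rep(FALSE, length(ids)), ids)
  if (is.null(growth_factor))
    growth_factor <- stats::setNames(rep(1, length(ids)), ids)
  stopifnot(all(counts >= 0), all(is.finite(counts)))
  structure(list(genotypes = genotypes, kd = kd,
                 counts = counts[ids],
                 nonspecific = nonspecific[ids],
                 growth_factor = growth_factor[ids],
                 round_index = 0L),
            class = "VariantPool")
}

#' @export
print.VariantPool <- function(x, ...) {
  cat("VariantPool:", length(x$counts), "variants, total",
      format(sum(x$counts), big.mark = ","), "particles, round",
      x$round_index, "\n")
  invisible(x)
}

#' Panning round configuration
#'
#' @param target target label (must match a column of the pool's Kd matrix).
#' @param target_concentration free target concentration in nM.
#' @param prepan_depletion probability that a nonspecific binder is removed
#'   in the prepan step.
#' @param capture_max maximum capture probability at saturating affinity.
#' @param washes number of washes W (default 10, as in the reference
#'   campaign).
#' @param wash_halfpoint Kd (nM) at which one wash removes half of the bound
#'   phage.
#' @param amplify_to pool size after amplification.
#' @return a `RoundConfig`.
#' @export
round_config <- function(target, target_concentration = 10,
                         prepan_depletion = 0.9, capture_max = 0.9,
                         washes = 10L, wash_halfpoint = 100,
                         amplify_to = 1e6) {
  stopifnot(prepan_depletion >= 0, prepan_depletion <= 1,
            capture_max >= 0, capture_max <= 1,
            washes >= 0, target_concentration >= 0, wash_halfpoint > 0)
  if (amplify_to <= 0) stop("amplify_to must be positive")
  structure(list(target = target,
                 target_concentration = target_concentration,
                 prepan_depletion = prepan_depletion,
                 capture_max = capture_max, washes = as.integer(washes),
                 wash_halfpoint = wash_halfpoint, amplify_to = amplify_to),
            class = "RoundConfig")
}

#' Selection schedule
#'
#' @param rounds list of `RoundConfig` (>= 1); the reference campaign runs
#'   three rounds with ten washes each.
#' @param dual_screen_target optional second target label: after the final
#'   round the pool is filtered by capture on this target, retaining dual
#'   binders only.
#' @return a `SelectionSchedule`.
#' @export
selection_schedule <- function(rounds, dual_screen_target = NULL) {
  if (!length(rounds)) stop("schedule needs at least one round")
  stopifnot(all(vapply(rounds, inherits, logical(1), "RoundConfig")))
  structure(list(rounds = rounds, dual_screen_target = dual_screen_target),
            class = "SelectionSchedule")
}

#' Map additive ddG to per-target dissociation constants
#'
#' Additive model `Kd = kd_ref * exp(beta * sum(ddG) + eps)` with
#' `eps ~ Normal(0, noise_sd)`: a genotype whose substitutions sum to zero
#' ddG (in particular the all-native genotype) has `Kd == kd_ref` exactly
#' when `noise_sd = 0`, and lower total ddG gives strictly lower Kd.
#'
#' @param ddg_table data.frame with columns `position`, `aa`, `ddg` (eu).
#' @param genotype named character vector position -> amino acid; positions
#'   absent from the genotype are wild-type (contribute 0).
#' @param beta energy-to-affinity slope (1/eu, > 0).
#' @param kd_ref reference (parental) Kd in nM.
#' @param noise_sd lognormal noise on the energy scale (eu; 0 = none).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return Kd in nM.
#' @export
affinity_from_ddg <- function(ddg_table, genotype, beta = 1.0, kd_ref = 1.0,
                              noise_sd = 0, seed = 1729L) {
  if (beta <= 0) stop("beta must be > 0")
  total <- 0
  for (i in seq_along(genotype)) {
    pos <- names(genotype)[i]
    aa <- genotype[[i]]
    hit <- ddg_table$position == pos & ddg_table$aa == aa
    if (!any(hit))
      stop("ddg table has no entry for (", pos, ", ", aa, ")")
    total <- total + ddg_table$ddg[which(hit)[1]]
  }
  eps <- if (noise_sd > 0) with_seed(seed, stats::rnorm(1, 0, noise_sd)) else 0
  kd_ref * exp(beta * total + eps)
}

## Per-variant survival probability through one round (before amplification).
.round_survival <- function(pool, config) {
  kd <- pool$kd[, config$target]
  prepan <- 1 - config$prepan_depletion * as.numeric(pool$nonspecific)
  capture <- ifelse(is.finite(kd),
                    config$capture_max * config$target_concentration /
                      (config$target_concentration + kd),
                    0)
  if (config$target_concentration == 0) capture <- rep(0, length(kd))
  wash <- ifelse(is.finite(kd),
                 (1 - kd / (kd + config$wash_halfpoint))^config$washes,
                 0)
  prepan * capture * wash
}

#' Run one panning round
#'
#' Prepan depletion, affinity capture, wash attrition, then amplification of
#' the survivors to `amplify_to` particles with growth-factor weights. In
#' expected-value mode every step propagates expectations; in stochastic
#' mode survival is binomial and amplification multinomial.
#'
#' @param pool a `VariantPool`.
#' @param config a `RoundConfig`.
#' @param seed RNG seed (stochastic mode).
#' @param stochastic sample instead of propagating expectations
#'   (default FALSE).
#' @return the post-round `VariantPool`.
#' @export
run_round <- function(pool, config, seed = 1729L, stochastic = FALSE) {
  if (sum(pool$counts) <= 0) stop("empty pool")
  surv_p <- .round_survival(pool, config)
  if (stochastic) {
    survivors <- with_seed(seed, stats::rbinom(length(pool$counts),
                                               size = round(pool$counts),
                                               prob = surv_p))
    survivors <- as.numeric(survivors)
  } else {
    survivors <- pool$counts * surv_p
  }
  total <- sum(survivors)
  if (total <= 0) {
    pool$counts[] <- 0
    pool$round_index <- pool$round_index + 1L
    return(pool)
  }
  wts <- survivors * pool$growth_factor
  if (stochastic) {
    amplified <- with_seed(seed + 1L, as.numeric(
      stats::rmultinom(1, size = config$amplify_to, prob = wts)))
  } else {
    amplified <- config$amplify_to * wts / sum(wts)
  }
  pool$counts <- stats::setNames(amplified, names(pool$counts))
  pool$round_index <- pool$round_index + 1L
  pool
}

#' Run a full selection schedule
#'
#' Applies the rounds in order; when the schedule carries a
#' `dual_screen_target`, the final pool is additionally filtered by capture
#' on that target (removing variants that bind only the panning target).
#'
#' @param pool starting `VariantPool`.
#' @param schedule a `SelectionSchedule`.
#' @param seed RNG seed; round r uses `seed + 1000 * r`.
#' @param stochastic sampling mode (default FALSE = expected value).
#' @return a `PanningTrajectory`: list with `pools` (per-round pools,
#'   including round 0), `frequencies` (matrix variants x rounds) and the
#'   schedule.
#' @export
run_schedule <- function(pool, schedule, seed = 1729L, stochastic = FALSE) {
  stopifnot(inherits(schedule, "SelectionSchedule"))
  pools <- list(pool)
  cur <- pool
  for (r in seq_along(schedule$rounds)) {
    cur <- run_round(cur, schedule$rounds[[r]], seed = seed + 1000L * r,
                     stochastic = stochastic)
    if (sum(cur$counts) <= 0)
      stop("library collapsed at round ", r, ": no phage survived selection")
    pools[[r + 1L]] <- cur
  }
  if (!is.null(schedule$dual_screen_target)) {
    cfg <- schedule$rounds[[length(schedule$rounds)]]
    kd2 <- cur$kd[, schedule$dual_screen_target]
    capture2 <- ifelse(is.finite(kd2),
                       cfg$capture_max * cfg$target_concentration /
                         (cfg$target_concentration + kd2),
                       0)
    if (stochastic) {
      cur$counts <- with_seed(seed + 999999L, as.numeric(
        stats::rbinom(length(cur$counts), size = round(cur$counts),
                      prob = capture2)))
      names(cur$counts) <- rownames(cur$kd)
    } else {
      cur$counts <- cur$counts * capture2
    }
    if (sum(cur$counts) <= 0)
      stop("library collapsed at the dual screen: no dual binder present")
    pools[[length(pools) + 1L]] <- cur
  }
  freq <- vapply(pools, function(p) {
    tot <- sum(p$counts)
    if (tot > 0) p$counts / tot else p$counts
  }, numeric(length(pool$counts)))
  rownames(freq) <- names(pool$counts)
  colnames(freq) <- c("round0", paste0("round", seq_len(ncol(freq) - 1L)))
  if (!is.null(schedule$dual_screen_target))
    colnames(freq)[ncol(freq)] <- "dual_screen"
  structure(list(pools = pools, frequencies = freq, schedule = schedule,
                 seed = seed, stochastic = stochastic),
            class = "PanningTrajectory")
}

#' Per-variant enrichment report of a panning trajectory
#'
#' @param trajectory a `PanningTrajectory` (>= 2 recorded stages).
#' @return data.frame: variant, per-stage frequency columns, cumulative
#'   enrichment (final frequency / initial frequency; variants absent from
#'   the initial pool get `Inf` when enriched), and final-frequency rank.
#' @export
enrichment_report <- function(trajectory) {
  freq <- trajectory$frequencies
  if (ncol(freq) < 2L) stop("trajectory needs at least 2 stages")
  f0 <- freq[, 1]
  ff <- freq[, ncol(freq)]
  enr <- ifelse(f0 > 0, ff / f0, ifelse(ff > 0, Inf, NA_real_))
  out <- data.frame(variant = rownames(freq), freq,
                    enrichment = enr,
                    rank = rank(-ff, ties.method = "min"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$rank), ]
}
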