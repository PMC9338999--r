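## Configuration, report assembly and the two pipeline commands driven by
## the command-line entry point (inst/cli/abrescue.R).

## Deterministic polynomial string hash (hex), used to stamp reports with a
## config fingerprint.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261 %% 2147483647
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

report_stamp <- function(config) {
  ## the hash fingerprints the scientific parameters; the output location
  ## must not change it (reruns into a fresh directory stay byte-identical)
  fingerprint <- config[setdiff(names(config), "outdir")]
  list(package_version = as.character(utils::packageVersion("abrescue")),
       seed = config$seed,
       config_hash = fnv1a_hash(fingerprint))
}

#' Validated run configuration
#'
#' @param pdb path to the complex PDB file (`NULL` to use the built-in
#'   synthetic toy complex).
#' @param antibody_chains,antigen_chains chain-id partition.
#' @param ensemble_M ensemble size (default 100).
#' @param cluster_k number of fingerprint clusters (default 3).
#' @param scan_tau hotspot candidate threshold in eu (default 0).
#' @param interface_cutoff contact cutoff in Angstrom (default 5).
#' @param library_scheme degenerate codon (default "NNS").
#' @param library_size intended transformant count (default 1e6).
#' @param seed global RNG seed (default 1729).
#' @param outdir output directory.
#' @param ... rejected: unknown keys error out.
#' @return a validated `RunConfig` list.
#' @export
run_config <- function(pdb = NULL, antibody_chains = "H",
                       antigen_chains = "A", ensemble_M = 100L,
                       cluster_k = 3L, scan_tau = 0.0,
                       interface_cutoff = 5.0, library_scheme = "NNS",
                       library_size = 1e6, seed = 1729L, outdir = ".",
                       ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown config key(s): ", paste(names(extra), collapse = ", "))
  stopifnot(ensemble_M >= 1, cluster_k >= 1, interface_cutoff > 0,
            library_size >= 0)
  cfg <- list(pdb = pdb, antibody_chains = antibody_chains,
              antigen_chains = antigen_chains,
              ensemble_M = as.integer(ensemble_M),
              cluster_k = as.integer(cluster_k), scan_tau = scan_tau,
              interface_cutoff = interface_cutoff,
              library_scheme = library_scheme, library_size = library_size,
              seed = as.integer(seed), outdir = outdir)
  class(cfg) <- "RunConfig"
  cfg
}

load_config_complex <- function(config) {
  if (is.null(config$pdb)) {
    toy <- build_toy_complex(seed = config$seed)
    list(structure = toy$structure, partition = toy$partition)
  } else {
    list(structure = read_pdb(config$pdb),
         partition = partner_partition(config$antibody_chains,
                                       config$antigen_chains))
  }
}

#' Write scan records to TSV
#'
#' @param records scan-record data.frame (see [saturation_scan()]).
#' @param path output file.
#' @param config optional `RunConfig` for the reproducibility stamp
#'   (written as `#`-prefixed header lines).
#' @return invisibly, the path.
#' @export
write_scan_tsv <- function(records, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    st <- report_stamp(config)
    writeLines(sprintf("# abrescue %s seed=%s config=%s",
                       st$package_version, st$seed, st$config_hash), con)
  }
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a hotspot report to JSON
#'
#' @param hotspots a `HotspotSet`.
#' @param path output file.
#' @param config optional `RunConfig` for the reproducibility stamp.
#' @return invisibly, the path.
#' @export
write_hotspot_json <- function(hotspots, path, config = NULL) {
  payload <- list(
    campaign = hotspots$campaign,
    threshold = hotspots$threshold,
    per_cluster_candidates = hotspots$per_cluster_candidates,
    hotspots = hotspots$hotspots,
    per_position_best_ddG = as.list(hotspots$per_position_best_ddG))
  if (!is.null(config)) payload$stamp <- report_stamp(config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Ensemble-scan command: ensemble, clusters, per-cluster saturation scans
#'
#' Runs the in-silico core end to end: structural ensemble, fingerprint
#' clustering, and a saturation scan of the antibody-side interface of each
#' cluster representative. Writes one scan TSV per cluster plus a cluster
#' report JSON into `config$outdir`.
#'
#' @param config a `RunConfig`.
#' @return invisibly, a list with `clusters`, `scans` (list of record
#'   data.frames) and the output paths.
#' @export
cmd_scan <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  cc <- load_config_complex(config)
  params <- default_forcefield()
  rotlib <- default_rotlib()
  models <- generate_ensemble(cc$structure, cc$partition,
                              M = config$ensemble_M, seed = config$seed,
                              cutoff = config$interface_cutoff,
                              rotlib = rotlib, params = params)
  clusters <- cluster_ensemble(models, cc$partition, k = config$cluster_k,
                               cutoff = config$interface_cutoff,
                               params = params)
  scans <- vector("list", length(clusters))
  paths <- character(0)
  for (cl in clusters) {
    rep_model <- models[[cl$representative_index]]
    sc <- saturation_scan(rep_model, cc$partition, cl$fingerprint,
                          params = params, rotlib = rotlib,
                          seed = config$seed, cluster_id = cl$cluster_id)
    scans[[cl$cluster_id]] <- sc
    p <- file.path(config$outdir,
                   sprintf("scan_cluster%d.tsv", cl$cluster_id))
    write_scan_tsv(sc, p, config)
    paths <- c(paths, p)
    message(sprintf("cluster %d: %d positions, %d predictions",
                    cl$cluster_id, cl$n_scannable_positions,
                    cl$n_predictions))
  }
  creport <- lapply(clusters, function(cl)
    list(cluster_id = cl$cluster_id,
         members = cl$member_model_indices,
         representative = cl$representative_index,
         n_scannable_positions = cl$n_scannable_positions,
         n_predictions = cl$n_predictions,
         fingerprint = cl$fingerprint))
  cpath <- file.path(config$outdir, "cluster_report.json")
  jsonlite::write_json(list(stamp = report_stamp(config),
                            clusters = creport),
                       cpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(clusters = clusters, scans = scans,
                 paths = c(paths, cpath)))
}

#' Design-and-pan command: hotspots, focused library, simulated panning
#'
#' Intersects per-cluster scan candidates into hotspots, designs the
#' degenerate-codon library over them, and simulates a default 3-round /
#' 10-wash coselection campaign on the packaged panning truth set. Writes
#' hotspot JSON, a library report and the panning trajectory TSV.
#'
#' @param config a `RunConfig`.
#' @param scans list of per-cluster scan-record data.frames (e.g. from
#'   [cmd_scan()]).
#' @return invisibly, a list with `hotspots`, `library`, `trajectory`,
#'   `report` and output paths.
#' @export
cmd_design_and_pan <- function(config, scans) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  hotspots <- select_hotspots(scans, threshold = config$scan_tau)
  hpath <- file.path(config$outdir, "hotspots.json")
  write_hotspot_json(hotspots, hpath, config)
  if (!length(hotspots$hotspots))
    stop("no hotspot positions at tau = ", config$scan_tau,
         ": library design aborted")
  lib <- design_library(hotspots$hotspots, scheme = config$library_scheme,
                        target_size = config$library_size)
  lpath <- file.path(config$outdir, "library_report.json")
  jsonlite::write_json(
    list(stamp = report_stamp(config),
         positions = lib$positions,
         scheme = lib$codon$letters,
         dna_diversity = lib$dna_diversity,
         protein_diversity = lib$protein_diversity,
         stop_free_dna_fraction = lib$stop_free_dna_fraction,
         target_library_size = lib$target_library_size,
         coverage = as.list(lib$coverage)),
    lpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  truth <- build_panning_truth(seed = config$seed)
  rounds <- lapply(1:3, function(i) round_config(target = "mutant"))
  schedule <- selection_schedule(rounds, dual_screen_target = "wildtype")
  traj <- run_schedule(truth$pool, schedule, seed = config$seed)
  report <- enrichment_report(traj)
  tpath <- file.path(config$outdir, "panning_trajectory.tsv")
  write_scan_tsv(report, tpath, config)
  invisible(list(hotspots = hotspots, library = lib, trajectory = traj,
                 report = report, paths = c(hpath, lpath, tpath)))
}
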