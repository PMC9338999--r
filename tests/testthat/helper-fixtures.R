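## Shared, lazily built fixtures. The toy complex and the 100-model
## ensembles are expensive enough to build once per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

toy_fixture <- function() memo("toy", function() build_toy_complex())

## wild-type ensemble at the reference size (M = 100)
wt_ensemble <- function() memo("wt_ens", function() {
  toy <- toy_fixture()
  generate_ensemble(toy$structure, toy$partition, M = 100L, seed = 20260927L)
})

## per-model ddG of the cavity Ser -> Arg antigen substitution
antigen_ddgs <- function() memo("ag_ddg", function() {
  toy <- toy_fixture()
  ddg_over_ensemble(wt_ensemble(), toy$partition,
                    list(toy$manifest$clash_position, toy$manifest$clash_aa),
                    side = "antigen")
})

## antigen-mutant complex (carries the clash substitution)
mutant_complex <- function() memo("mut_cplx", function() {
  toy <- toy_fixture()
  dd <- ddg_antigen_mutation(toy$structure, toy$partition,
                             list(toy$manifest$clash_position,
                                  toy$manifest$clash_aa))
  attr(dd, "mutant")
})

## per-model ddG of the antibody rescue substitution against the mutant
rescue_ddgs <- function() memo("rs_ddg", function() {
  toy <- toy_fixture()
  ens <- generate_ensemble(mutant_complex(), toy$partition, M = 100L,
                           seed = 20260928L)
  ddg_over_ensemble(ens, toy$partition,
                    list(toy$manifest$rescue_position,
                         toy$manifest$rescue_to),
                    side = "antibody")
})

## independent brute-force interface oracle: O(n^2) over residue pairs
brute_force_interface <- function(structure, partition, cutoff, side) {
  rt <- residue_table(structure)
  mine_ch <- if (side == "antibody") partition$antibody_chains else
    partition$antigen_chains
  mine <- rt$reskey[rt$chain %in% mine_ch]
  other <- rt$reskey[!rt$chain %in% mine_ch]
  hits <- character(0)
  for (p in mine) {
    pa <- structure$atoms[structure$atoms$reskey == p, ]
    for (q in other) {
      qa <- structure$atoms[structure$atoms$reskey == q, ]
      dmin <- Inf
      for (i in seq_len(nrow(pa))) {
        d <- sqrt((qa$x - pa$x[i])^2 + (qa$y - pa$y[i])^2 +
                    (qa$z - pa$z[i])^2)
        dmin <- min(dmin, d)
      }
      if (dmin <= cutoff) { hits <- c(hits, p); break }
    }
  }
  hits
}

## a minimal two-residue synthetic structure at a given separation
two_residue_structure <- function(offset, aa1 = "ALA", aa2 = "ALA") {
  r1 <- abrescue:::make_residue_atoms("A", 1L, aa1, c(0, 0, 0),
                                      c(0, 1, 0), c(1, 0, 0),
                                      rep(180, n_chi(aa1)))
  r2 <- abrescue:::make_residue_atoms("B", 1L, aa2, offset,
                                      c(0, -1, 0), c(1, 0, 0),
                                      rep(180, n_chi(aa2)))
  abrescue:::.assemble(list(r1, r2), source = "two-residue")
}
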