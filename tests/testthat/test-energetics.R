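test_that("interaction energy is symmetric on random two-residue fixtures", {
  params <- default_forcefield()
  set.seed(99)
  aas <- c("SER", "ASP", "ARG", "LEU", "TYR")
  for (i in 1:10) {
    s <- two_residue_structure(c(stats::rnorm(1, 0, 1),
                                 stats::runif(1, 4, 7),
                                 stats::rnorm(1, 0, 1)),
                               aa1 = sample(aas, 1), aa2 = sample(aas, 1))
    part <- partner_partition("B", "A")
    ga <- select_partner(s, part, "antigen")
    gb <- select_partner(s, part, "antibody")
    e1 <- interaction_energy(ga, gb, params)
    e2 <- interaction_energy(gb, ga, params)
    expect_equal(e1$total, e2$total, tolerance = 1e-12)
    expect_equal(e1$lj, e2$lj, tolerance = 1e-12)
    expect_equal(e1$solvation, e2$solvation, tolerance = 1e-9)
  }
})

test_that("binding energy vanishes at full separation", {
  toy <- toy_fixture()
  far <- toy$structure
  sel <- far$atoms$chain %in% toy$partition$antigen_chains
  far$atoms$x[sel] <- far$atoms$x[sel] + 500
  expect_equal(as.numeric(binding_energy(far, toy$partition)), 0,
               tolerance = 1e-6)
})

test_that("the toy complex binds favorably and a clash overwhelms it", {
  toy <- toy_fixture()
  expect_lt(as.numeric(binding_energy(toy$structure, toy$partition)), 0)
  mut <- mutate_residue(toy$structure, toy$manifest$clash_position,
                        toy$manifest$clash_aa)
  expect_gt(as.numeric(binding_energy(mut, toy$partition)), 0)
})

test_that("identity mutation returns the input bitwise-unchanged", {
  toy <- toy_fixture()
  for (key in residue_keys(toy$structure)) {
    aa <- get_residue(toy$structure, key)$aa3[1]
    expect_identical(mutate_residue(toy$structure, key, aa), toy$structure)
  }
})

test_that("every packaged Arg rotamer clashes across the toy interface", {
  toy <- toy_fixture()
  params <- default_forcefield()
  ab_atoms <- toy$structure$atoms[
    toy$structure$atoms$chain %in% toy$partition$antibody_chains, ]
  key <- toy$manifest$clash_position
  for (chis in abrescue:::rotamer_chis(default_rotlib(), "ARG")) {
    conf <- abrescue:::set_residue_conformation(toy$structure, key, "ARG",
                                                chis)
    sc <- get_residue(conf, key)
    sc <- sc[!sc$name %in% c("N", "CA", "C", "O"), ]
    ## independent distance check of the engineered overlap
    worst <- -Inf
    for (i in seq_len(nrow(sc))) {
      d <- sqrt((ab_atoms$x - sc$x[i])^2 + (ab_atoms$y - sc$y[i])^2 +
                  (ab_atoms$z - sc$z[i])^2)
      rsum <- params$radius[sc$element[i]] + params$radius[ab_atoms$element]
      worst <- max(worst, max(rsum - d))
    }
    expect_gte(worst, 0.4)
  }
})

test_that("Trp to Asp drops the side chain from 10 to 4 heavy atoms", {
  toy <- toy_fixture()
  key <- toy$manifest$rescue_position
  n_side <- function(s) {
    r <- get_residue(s, key)
    sum(!r$name %in% c("N", "CA", "C", "O"))
  }
  expect_equal(n_side(toy$structure), 10L)
  expect_equal(n_side(mutate_residue(toy$structure, key, "ASP")), 4L)
})

test_that("greedy repack never increases shell energy and is deterministic", {
  toy <- toy_fixture()
  params <- default_forcefield()
  rotlib <- default_rotlib()
  ## randomize chis of flexible interface residues, then repack
  s <- toy$structure
  set.seed(4)
  rt <- residue_table(s)
  flex <- rt$reskey[!rt$aa3 %in% c("GLY", "ALA", "PRO")]
  for (key in flex) {
    aa <- rt$aa3[rt$reskey == key]
    chis <- stats::runif(n_chi(aa), -180, 180)
    s <- abrescue:::set_residue_conformation(s, key, aa, chis)
  }
  shell <- list(members = residue_keys(s))
  e_before <- abrescue:::score_shell(s, shell$members, params)
  rep1 <- repack_shell(s, shell, rotlib, params, seed = 7L)
  sweeps <- attr(rep1, "sweep_energies")
  expect_true(all(diff(c(e_before, sweeps)) <= 1e-6))
  ## determinism: identical seed, identical coordinates
  rep2 <- repack_shell(s, shell, rotlib, params, seed = 7L)
  expect_identical(rep1$atoms, rep2$atoms)
  ## fixed point: repacking the repacked structure changes nothing
  rep3 <- repack_shell(rep1, shell, rotlib, params)
  expect_identical(rep3$atoms, rep1$atoms)
})

test_that("ensembles are reproducible and sized correctly", {
  toy <- toy_fixture()
  e1 <- generate_ensemble(toy$structure, toy$partition, M = 5L, seed = 31L)
  e2 <- generate_ensemble(toy$structure, toy$partition, M = 5L, seed = 31L)
  expect_equal(length(e1), 5L)
  expect_identical(attr(e1, "energies"), attr(e2, "energies"))
  expect_identical(e1[[3]]$atoms, e2[[3]]$atoms)
  ## M = 1 is the repacked input
  e3 <- generate_ensemble(toy$structure, toy$partition, M = 1L)
  expect_equal(length(e3), 1L)
  expect_error(generate_ensemble(toy$structure, toy$partition, M = 0L),
               "M must be >= 1")
})
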