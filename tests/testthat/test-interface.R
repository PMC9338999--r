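test_that("interface detection equals the brute-force oracle", {
  toy <- toy_fixture()
  for (side in c("antibody", "antigen")) {
    fp <- find_interface_residues(toy$structure, toy$partition, 5, side)
    oracle <- brute_force_interface(toy$structure, toy$partition, 5, side)
    expect_setequal(fp$residues, oracle)
  }
})

test_that("interface sets are monotone in the cutoff and empty at tiny cutoff", {
  toy <- toy_fixture()
  f5 <- find_interface_residues(toy$structure, toy$partition, 5, "antibody")
  f8 <- find_interface_residues(toy$structure, toy$partition, 8, "antibody")
  expect_true(all(f5$residues %in% f8$residues))
  f0 <- find_interface_residues(toy$structure, toy$partition, 0.01,
                                "antibody")
  expect_length(f0$residues, 0)
  expect_error(find_interface_residues(toy$structure, toy$partition, -1),
               "cutoff")
})

test_that("ddG of identity substitutions is exactly zero", {
  toy <- toy_fixture()
  expect_identical(
    as.numeric(ddg_antigen_mutation(toy$structure, toy$partition,
                                    list("A:2:", "SER"))), 0)
  expect_identical(
    as.numeric(ddg_antibody_mutation(toy$structure, toy$partition,
                                     list("H:1:", "TRP"))), 0)
})

test_that("mutations are validated against the partition side", {
  toy <- toy_fixture()
  expect_error(ddg_antigen_mutation(toy$structure, toy$partition,
                                    list("H:1:", "ASP")), "antigen side")
  expect_error(ddg_antibody_mutation(toy$structure, toy$partition,
                                     list("A:2:", "ARG")), "antibody side")
})

test_that("engineered clash and rescue have the designed ddG signs", {
  toy <- toy_fixture()
  dd_ag <- ddg_antigen_mutation(toy$structure, toy$partition,
                                list(toy$manifest$clash_position,
                                     toy$manifest$clash_aa))
  expect_gt(as.numeric(dd_ag), 0)
  dd_ab <- ddg_antibody_mutation(attr(dd_ag, "mutant"), toy$partition,
                                 list(toy$manifest$rescue_position,
                                      toy$manifest$rescue_to))
  expect_lt(as.numeric(dd_ab), 0)
  expect_true(is.finite(as.numeric(dd_ab)))
  ## exact arithmetic identity ddG = dG_variant - dG_reference
  expect_identical(as.numeric(dd_ag),
                   attr(dd_ag, "dG_variant") - attr(dd_ag, "dG_reference"))
})

test_that("clustering recovers constructed fingerprint groups exactly", {
  toy <- toy_fixture()
  ## group 2: displace one antibody contact residue far away so the
  ## antibody-side fingerprint genuinely differs
  fp_a <- find_interface_residues(toy$structure, toy$partition, 5,
                                  "antibody")$residues
  altered <- toy$structure
  sel <- altered$atoms$reskey == fp_a[1]
  altered$atoms$z[sel] <- altered$atoms$z[sel] + 40
  models <- c(rep(list(toy$structure), 4), rep(list(altered), 3))
  attr(models, "energies") <- c(4, 3, 2, 1, 6, 5, 7)
  fp_b <- find_interface_residues(altered, toy$partition, 5,
                                  "antibody")$residues
  expect_false(setequal(fp_a, fp_b))
  cl <- cluster_ensemble(models, toy$partition, k = 2L)
  groups <- lapply(cl, `[[`, "member_model_indices")
  expect_setequal(vapply(groups, paste, character(1), collapse = ","),
                  c("1,2,3,4", "5,6,7"))
  ## representative = lowest energy member
  reps <- vapply(cl, `[[`, integer(1), "representative_index")
  expect_setequal(reps, c(4L, 6L))
})

test_that("identical fingerprints collapse to one cluster at k = 1", {
  toy <- toy_fixture()
  models <- rep(list(toy$structure), 4)
  attr(models, "energies") <- c(2, 1, 3, 4)
  cl <- cluster_ensemble(models, toy$partition, k = 1L)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$member_model_indices, 1:4)
  expect_equal(cl[[1]]$representative_index, 2L)
  expect_error(cluster_ensemble(list(), toy$partition), "empty ensemble")
})

test_that("cluster reports partition the ensemble with exact bookkeeping", {
  toy <- toy_fixture()
  ens <- generate_ensemble(toy$structure, toy$partition, M = 6L, seed = 13L)
  cl <- cluster_ensemble(ens, toy$partition, k = 3L)
  members <- sort(unlist(lapply(cl, `[[`, "member_model_indices")))
  expect_equal(members, 1:6)
  for (x in cl) {
    expect_true(x$representative_index %in% x$member_model_indices)
    expect_identical(x$n_predictions, 19L * x$n_scannable_positions)
  }
})
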