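test_that("toy complex builds deterministically: same seed, same PDB bytes", {
  t1 <- build_toy_complex(seed = 1729L)
  t2 <- build_toy_complex(seed = 1729L)
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  write_pdb(t1$structure, f1)
  write_pdb(t2$structure, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(t1$manifest$rotamer_overlaps, t2$manifest$rotamer_overlaps)
})

test_that("degenerate amino-acid combinations are rejected", {
  expect_error(build_toy_complex(cavity_aa = "ARG", clash_aa = "ARG"),
               "no mutation to test")
})

test_that("manifest contact pairs match an independent O(n^2) distance scan", {
  toy <- toy_fixture()
  s <- toy$structure
  rt <- residue_table(s)
  agk <- rt$reskey[rt$chain == "A"]
  abk <- rt$reskey[rt$chain == "H"]
  found <- character(0)
  for (p in agk) for (q in abk) {
    pa <- s$atoms[s$atoms$reskey == p, ]
    qa <- s$atoms[s$atoms$reskey == q, ]
    dmin <- Inf
    for (i in seq_len(nrow(pa)))
      dmin <- min(dmin, sqrt((qa$x - pa$x[i])^2 + (qa$y - pa$y[i])^2 +
                               (qa$z - pa$z[i])^2))
    if (dmin <= 5) found <- c(found, paste(p, q))
  }
  expect_setequal(paste(toy$manifest$contact_pairs$antigen,
                        toy$manifest$contact_pairs$antibody), found)
})

test_that("manifest salt-bridge distance is re-verified from raw geometry", {
  toy <- toy_fixture()
  expect_gte(toy$manifest$salt_bridge_distance, 2.7)
  expect_lte(toy$manifest$salt_bridge_distance, 3.2)
  ## rebuild the rescue pair and measure the O...N distance directly
  rotlib <- default_rotlib()
  key_ag <- toy$manifest$clash_position
  key_ab <- toy$manifest$rescue_position
  best <- Inf
  for (ch_arg in abrescue:::rotamer_chis(rotlib, toy$manifest$clash_aa)) {
    arg <- abrescue:::set_residue_conformation(
      toy$structure, key_ag, toy$manifest$clash_aa, ch_arg)
    n_at <- get_residue(arg, key_ag)
    n_at <- n_at[n_at$element == "N" & n_at$name != "N", ]
    for (ch_asp in abrescue:::rotamer_chis(rotlib, toy$manifest$rescue_to)) {
      asp <- abrescue:::set_residue_conformation(
        arg, key_ab, toy$manifest$rescue_to, ch_asp)
      o_at <- get_residue(asp, key_ab)
      o_at <- o_at[o_at$element == "O" & o_at$name != "O", ]
      for (i in seq_len(nrow(o_at))) {
        d <- sqrt((n_at$x - o_at$x[i])^2 + (n_at$y - o_at$y[i])^2 +
                    (n_at$z - o_at$z[i])^2)
        cand <- d[d >= 2.7]
        if (length(cand)) best <- min(best, min(cand))
      }
    }
  }
  expect_lte(best, 3.2)
})

test_that("fixture generation is fast and its PDB is parseable", {
  t0 <- Sys.time()
  toy <- build_toy_complex(seed = 7L)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 5)
  f <- tempfile(fileext = ".pdb")
  write_pdb(toy$structure, f)
  back <- read_pdb(f)
  expect_equal(nrow(back$atoms), toy$manifest$n_atoms)
  expect_equal(nrow(residue_table(back)), toy$manifest$n_residues)
})

test_that("interface rosters validate their inputs", {
  expect_equal(nrow(build_interface_roster(1)[[1]]) * 19L, 19L)
  expect_error(build_interface_roster(c(3, 0)), "positive")
  expect_error(build_interface_roster(integer(0)), "positive")
})

test_that("panning truth sets are reproducible and honor the advantage", {
  t1 <- build_panning_truth(seed = 9, dual_binder_advantage = 10)
  t2 <- build_panning_truth(seed = 9, dual_binder_advantage = 10)
  expect_identical(t1$ddg_tables, t2$ddg_tables)
  expect_identical(t1$pool$kd, t2$pool$kd)
  expect_error(build_panning_truth(dual_binder_advantage = 1), "> 1")
  ## the winner holds at least the stated fold advantage on both targets
  kd <- t1$pool$kd
  for (tg in colnames(kd)) {
    others <- kd[rownames(kd) != t1$winner, tg]
    expect_true(all(others / kd[t1$winner, tg] >= 10 - 1e-9))
  }
})
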