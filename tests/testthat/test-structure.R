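test_that("PDB round-trip preserves coordinates and residue keys", {
  toy <- toy_fixture()
  p1 <- tempfile(fileext = ".pdb")
  p2 <- tempfile(fileext = ".pdb")
  write_pdb(toy$structure, p1)
  s1 <- read_pdb(p1)
  expect_equal(residue_table(s1)[, c("reskey", "chain", "resnum", "aa3")],
               residue_table(toy$structure)[, c("reskey", "chain", "resnum",
                                                "aa3")])
  expect_equal(abrescue:::xyz_matrix(s1$atoms),
               round(abrescue:::xyz_matrix(toy$structure$atoms), 3),
               tolerance = 1e-9, ignore_attr = TRUE)
  ## second round trip is exact (coordinates already at 3 decimals)
  write_pdb(s1, p2)
  s2 <- read_pdb(p2)
  expect_identical(abrescue:::xyz_matrix(s2$atoms),
                   abrescue:::xyz_matrix(s1$atoms))
})

test_that("hetero stripping removes waters and a water-only file errors", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("HETATM%5d  O   HOH A%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
            1:3, 1:3, 1:3 * 2, 0, 0),
    "END"), f)
  expect_error(read_pdb(f), "empty structure")
})

test_that("alternate locations resolve to highest occupancy, ties first", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BALA A   1       9.000   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA AALA A   1       1.000   1.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BALA A   1       8.000   1.000   0.000  0.50  0.00           C",
    "ATOM      5  C   ALA A   1       2.000   1.500   0.000  1.00  0.00           C",
    "ATOM      6  O   ALA A   1       3.000   1.200   0.000  1.00  0.00           O",
    "END"), f)
  s <- read_pdb(f)
  a <- s$atoms
  expect_equal(nrow(a), 4L)
  expect_equal(a$x[a$name == "N"], 9)    # higher occupancy wins
  expect_equal(a$x[a$name == "CA"], 1)   # tie -> first occurrence
})

test_that("malformed coordinate fields raise a parse error naming the line", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.xyz   0.000   0.000  1.00  0.00           C",
    "END"), f)
  expect_error(read_pdb(f), "line 2")
})

test_that("partner selection returns exactly the requested chains", {
  toy <- toy_fixture()
  ab <- select_partner(toy$structure, toy$partition, "antibody")
  ag <- select_partner(toy$structure, toy$partition, "antigen")
  expect_setequal(unique(ab$atoms$chain), toy$partition$antibody_chains)
  expect_setequal(unique(ag$atoms$chain), toy$partition$antigen_chains)
  ## union of the two sides is the whole partitioned structure
  expect_equal(sort(c(residue_keys(ab), residue_keys(ag))),
               sort(residue_keys(toy$structure)))
  bad <- partner_partition("Z", "A")
  expect_error(select_partner(toy$structure, bad, "antibody"),
               "available chains")
})

test_that("partition validation rejects overlap and empty sides", {
  expect_error(partner_partition(c("A", "B"), "B"), "overlap")
  expect_error(partner_partition(character(0), "A"), "non-empty")
})

test_that("min heavy-atom distance is symmetric and matches brute force", {
  toy <- toy_fixture()
  keys <- residue_keys(toy$structure)
  set.seed(11)
  pairs <- replicate(10, sample(keys, 2), simplify = FALSE)
  for (pr in pairs) {
    ra <- get_residue(toy$structure, pr[1])
    rb <- get_residue(toy$structure, pr[2])
    d1 <- min_heavy_atom_distance(ra, rb)
    d2 <- min_heavy_atom_distance(rb, ra)
    expect_identical(d1, d2)
    ## brute force all-pairs oracle
    dmin <- Inf
    for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(rb)))
      dmin <- min(dmin, sqrt(sum((c(ra$x[i], ra$y[i], ra$z[i]) -
                                    c(rb$x[j], rb$y[j], rb$z[j]))^2)))
    expect_equal(d1, dmin)
  }
  ## 3-4-5 triangle with single-atom tables
  a1 <- data.frame(serial = 1L, name = "CA", element = "C", x = 0, y = 0,
                   z = 0, occupancy = 1, bfactor = 0, chain = "A",
                   resnum = 1L, icode = "", aa3 = "GLY", reskey = "A:1:")
  a2 <- a1; a2$x <- 3; a2$y <- 4
  expect_equal(min_heavy_atom_distance(a1, a2), 5)
  expect_equal(min_heavy_atom_distance(a1, a1), 0)
})

test_that("mutation preserves backbone coordinates through a write/read cycle", {
  toy <- toy_fixture()
  key <- toy$manifest$rescue_position
  mut <- mutate_residue(toy$structure, key, "ASP")
  f <- tempfile(fileext = ".pdb")
  write_pdb(mut, f)
  back <- read_pdb(f)
  expect_equal(get_residue(back, key)$aa3[1], "ASP")
  bb <- c("N", "CA", "C", "O", "CB")
  orig <- get_residue(toy$structure, key)
  new <- get_residue(back, key)
  for (nm in bb) {
    expect_equal(unlist(new[new$name == nm, c("x", "y", "z")]),
                 round(unlist(orig[orig$name == nm, c("x", "y", "z")]), 3),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})
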