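test_that("parse_pdb reads a minimal single-atom record", {
  s <- parse_pdb(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C"
  ))
  expect_s3_class(s, "btb_structure")
  expect_equal(nrow(s), 1)
  expect_equal(unique(s$chain), "A")
  expect_equal(s$resname, "ALA")
  expect_equal(unname(unlist(s[1, c("x", "y", "z")])), c(1, 2, 3))
})

test_that("parse_pdb agrees with an independent line scanner on a 2-chain fixture", {
  lines <- fixture_pdb_lines()
  truth <- fixture_pdb_counts(lines)
  s <- parse_pdb(lines)
  expect_equal(nrow(s), truth$n_atoms)
  expect_equal(sort(unique(s$chain)), truth$chains)
  expect_equal(nrow(structure_residues(s)), truth$n_residues)
  # water and altloc-B records are dropped
  expect_false(any(s$resname == "HOH"))
  expect_equal(sum(s$chain == "B" & s$resno == 1 & s$atom == "CA"), 1)
  # adding another water leaves the structure unchanged
  with_water <- append(lines, "HETATM    9  O   HOH B 102       8.0     8.0     8.0   1.00  0.00           O", after = 7)
  expect_equal(as.data.frame(parse_pdb(with_water)), as.data.frame(s))
})

test_that("parse_pdb rejects malformed and empty input with informative errors", {
  expect_error(parse_pdb("REMARK nothing here"), "no ATOM records")
  bad <- c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       xxx     2.000   3.000  1.00  0.00           C"
  )
  expect_error(parse_pdb(bad), "line 2")
})

test_that("structure round-trips through PDB within format precision", {
  d <- make_toy_dimer(8, 2, seed = 11)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(d, path)
  d2 <- parse_pdb(path)
  expect_equal(nrow(d2), nrow(d))
  expect_lt(max(abs(atom_coords(d2, NULL) - atom_coords(d, NULL))), 1e-3)
})

test_that("trajectory round-trips exactly via coord-tsv and within 1e-3 via multi-model PDB", {
  d <- make_toy_dimer(6, 1, seed = 2)
  sim <- simulate_trajectory(d, 0.5, n_frames = 10, seed = 3)
  traj <- sim$trajectory

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory_tsv(traj, tsv)
  t2 <- parse_trajectory(tsv, "coord-tsv", topology = d)
  expect_equal(n_frames(t2), 10)
  expect_equal(t2$times, traj$times)
  for (f in c(1, 5, 10)) expect_equal(t2$coords[[f]], traj$coords[[f]], tolerance = 1e-12)

  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(traj, pdb)
  t3 <- parse_trajectory(pdb, "multi-model-pdb")
  expect_equal(n_frames(t3), 10)
  for (f in c(1, 5, 10)) {
    expect_lt(max(abs(t3$coords[[f]] - traj$coords[[f]])), 1e-3)
  }
})

test_that("trajectory parsing reports atom-count mismatches by model index", {
  d <- make_toy_dimer(4, 0, seed = 1)
  sim <- simulate_trajectory(d, n_frames = 3, seed = 1)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sim$trajectory, pdb)
  lines <- readLines(pdb)
  # drop one atom from model 2
  starts <- grep("^MODEL", lines)
  lines <- lines[-(starts[2] + 1)]
  expect_error(parse_trajectory(lines, "multi-model-pdb"), "model 2")
})

test_that("single-model PDB parses as a one-frame trajectory equal to parse_pdb", {
  d <- make_toy_dimer(5, 1, seed = 4)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(d, path)
  traj <- parse_trajectory(path, "multi-model-pdb")
  expect_equal(n_frames(traj), 1)
  expect_equal(traj$coords[[1]], atom_coords(parse_pdb(path), NULL))
})

test_that("energy TSV parsing is column-name driven and round-trips", {
  el <- simulate_energy_logs(n_frames = 4, seed = 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_energy_tsv(el$complex, path)
  es <- parse_energy_log(path, "tsv")
  expect_equal(nrow(es), 4)
  expect_equal(es$elec, el$complex$elec)

  # permuting columns leaves the parse unchanged
  df <- tibble::as_tibble(el$complex)
  perm <- df[, rev(names(df))]
  p2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(perm, p2)
  es2 <- parse_energy_log(p2, "tsv")
  expect_equal(as.data.frame(es2), as.data.frame(es))
})

test_that("namd-log dialect maps ETITLE columns by name", {
  log <- c(
    "Info: some preamble",
    "ETITLE:      TS        BOND       ANGLE       DIHED       IMPRP        ELECT         VDW          GB        SASA_ENERGY",
    "ENERGY:       0      10.5         20.0         5.0         1.0      -418.0      -194.3       437.1        0.0",
    "ENERGY:       1      11.5         21.0         6.0         2.0      -417.0      -195.3       436.1        0.5",
    "ENERGY:       2      12.5         22.0         7.0         3.0      -416.0      -196.3       435.1        1.0"
  )
  es <- parse_energy_log(log, "namd-log")
  expect_equal(nrow(es), 3)
  expect_equal(es$elec, c(-418, -417, -416))
  expect_equal(es$vdw, c(-194.3, -195.3, -196.3))
  expect_equal(es$gb_polar, c(437.1, 436.1, 435.1))
  expect_equal(es$nonpolar_sa, c(0, 0.5, 1))
})

test_that("degenerate energy logs raise dialect-appropriate errors", {
  expect_error(parse_energy_log(c("# only", "# comments"), "tsv"), "empty")
  expect_error(parse_energy_log("Info: no data", "namd-log"), "no ENERGY")
  expect_error(
    parse_energy_log(c("ENERGY: 0 1 2"), "namd-log"),
    "ETITLE"
  )
  # missing required column names the found columns
  expect_error(
    parse_energy_log(c(
      "ETITLE: TS BOND ANGLE",
      "ENERGY: 0 1 2"
    ), "namd-log"),
    "lacks required columns"
  )
})

test_that("newick parsing handles simple trees and reports imbalance offsets", {
  t1 <- parse_newick("(A,B);")
  expect_equal(sort(t1$tip.label), c("A", "B"))
  t2 <- parse_newick("((A:1,B:2):0.5,C:3);")
  expect_equal(ape::Ntip(t2), 3)
  expect_true(0.5 %in% t2$edge.length)
  expect_error(parse_newick("((A,B);"), "unbalanced")
  expect_error(parse_newick("(A,B));"), "character 6")
})

test_that("newick round-trip preserves the leaf bipartition set", {
  rt <- random_tree_with_clade(50, 5, seed = 21)
  nwk <- ape::write.tree(rt$tree)
  t2 <- parse_newick(nwk)
  bp1 <- ape::prop.part(rt$tree)
  bp2 <- ape::prop.part(t2)
  as_sets <- function(bp, tr) {
    lapply(bp, function(i) sort(tr$tip.label[i]))
  }
  expect_setequal(as_sets(bp1, rt$tree), as_sets(bp2, t2))
})
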