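test_that("a minimal single-atom PDB reads as one model, one chain, one atom", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END"), p)
  x <- read_pdb(p)
  expect_equal(n_models(x), 1)
  expect_equal(unique(x$atom$chain), "A")
  expect_equal(nrow(x$atom), 1)
  expect_equal(as.vector(model_coords(x, 1)), c(1, 2, 3))
})

test_that("write/read round-trip preserves topology and coordinates to 3 decimals", {
  b <- gen_overlap_bundle(theta = 15, omega = 8)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(b$structure, p)
  x <- read_pdb(p)
  expect_equal(nrow(x$atom), nrow(b$structure$atom))
  expect_equal(x$atom$resno, b$structure$atom$resno)
  expect_equal(x$atom$chain, b$structure$atom$chain)
  expect_lt(max(abs(x$xyz - b$structure$xyz)), 5e-4 + 1e-9)
})

test_that("multi-model files round-trip as trajectories with identical topology", {
  tr <- gen_trajectory(seed = 2, n_frames = 3, n_res = 12)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(tr$structure, p)
  x <- read_pdb(p)
  expect_equal(n_models(x), 3)
  expect_lt(max(abs(x$xyz - tr$structure$xyz)), 5e-4 + 1e-9)
  lines <- readLines(p)
  expect_equal(sum(grepl("^MODEL", lines)), 3)
  expect_equal(sum(grepl("^ENDMDL", lines)), 3)
})

test_that("single-model output has no MODEL records and TER-delimited chains", {
  b <- gen_overlap_bundle(n_res = 8)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(b$structure, p)
  lines <- readLines(p)
  expect_equal(sum(grepl("^MODEL", lines)), 0)
  expect_equal(sum(grepl("^TER", lines)), 4)  # chains A, B, C, D
})

test_that("unreadable inputs raise format or empty-input errors", {
  empty <- withr::local_tempfile(fileext = ".pdb")
  file.create(empty)
  expect_error(read_pdb(empty), "empty")
  garbage <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("this is not", "a pdb file"), garbage)
  expect_error(read_pdb(garbage), "parse|no ATOM")
  expect_error(read_pdb(file.path(tempdir(), "nope-missing.pdb")), "not found")
})

test_that("insertion codes are rejected; altlocs reduce to highest occupancy", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1A      1.000   2.000   3.000  1.00  0.00           C",
    "END"), p)
  expect_error(read_pdb(p), "insertion")

  q <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA  ALA A   2       2.000   0.000   0.000  1.00  0.00           C",
    "END"), q)
  x <- read_pdb(q)
  expect_equal(nrow(x$atom), 2)
  expect_equal(model_coords(x, 1)[1, 1], 9)  # occupancy 0.60 wins
})

test_that("coordinates wider than the PDB field refuse to write", {
  b <- gen_overlap_bundle(n_res = 8)
  big <- set_model_coords(b$structure,
                          model_coords(b$structure, 1) + c(99999, 0, 0))
  expect_error(write_pdb(big, withr::local_tempfile(fileext = ".pdb")),
               "fixed-column")
})

test_that("selection counts follow residue-range arithmetic", {
  x <- make_backbone_structure(80)
  ca <- select_coords(x, coord_selection("A", c(12, 35), "CA"))
  expect_equal(nrow(ca), 24)
  bb <- select_coords(x, coord_selection("A", c(12, 74), "backbone"))
  expect_equal(nrow(bb), 63 * 4)
  expect_equal(unique(attr(bb, "elety")[1:4]), c("N", "CA", "C", "O"))
})

test_that("selections are deterministic and canonically ordered", {
  x <- make_backbone_structure(20)
  a <- select_coords(x, coord_selection("A", c(3, 15), "backbone"))
  b <- select_coords(x, coord_selection("A", c(3, 15), "backbone"))
  expect_identical(a, b)
  expect_equal(attr(a, "resno"), rep(3:15, each = 4))
})

test_that("unresolvable selections fail with the offending range named", {
  x <- make_backbone_structure(20)
  expect_error(select_coords(x, coord_selection("Z", c(1, 5), "CA")),
               "chain 'Z'")
  expect_error(select_coords(x, coord_selection("A", c(100, 120), "CA")),
               "100-120")
})

test_that("residues missing requested atoms error by default but can be skipped", {
  x <- make_backbone_structure(20)
  drop <- !(x$atom$resno == 10 & x$atom$elety == "O")
  x2 <- cc_structure(x$atom[drop, ],
                     x$xyz[, rep(drop, each = 3), drop = FALSE])
  sel <- coord_selection("A", c(5, 15), "backbone")
  expect_error(select_coords(x2, sel), "lack requested atoms")
  skipped <- select_coords(x2, sel, on_missing = "skip")
  expect_equal(nrow(skipped), 10 * 4)  # residue 10 dropped entirely
  expect_false(10 %in% attr(skipped, "resno"))
})

test_that("trajectory stacking refuses mismatched topologies", {
  a <- make_backbone_structure(10)
  b <- make_backbone_structure(11)
  expect_error(structures_to_trajectory(list(a, b)), "topology")
  tr <- structures_to_trajectory(list(a, a))
  expect_equal(n_models(tr), 2)
})
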