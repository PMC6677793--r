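test_that("zero superhelical radius gives a straight ideal alpha-helix", {
  h <- build_ideal_coiled_coil(crick_parameters(r0 = 0, n_chains = 1), 100)
  co <- model_coords(h, 1)
  # axial extent follows the closed form rise * (n - 1)
  expect_equal(diff(range(co[, 3])), 1.495 * 99, tolerance = 1e-9)
  # minor-helix radius everywhere
  expect_equal(sqrt(co[, 1]^2 + co[, 2]^2), rep(2.26, 100), tolerance = 1e-9)
})

test_that("consecutive CA spacing stays in the physical alpha-helical band", {
  for (r0 in c(0, 3, 4.9, 6)) {
    x <- build_ideal_coiled_coil(crick_parameters(r0 = r0), 50)
    for (ch in c("A", "B")) {
      ca <- select_coords(x, coord_selection(ch, c(1, 50), "CA"))
      sp <- sqrt(rowSums(diff(ca)^2))
      expect_true(all(sp > 3.74 & sp < 3.85))
    }
  }
  expect_error(build_ideal_coiled_coil(crick_parameters(r1 = 0.5, rise = 1),
                                       20), "geometry error")
})

test_that("a 0/180 dimer has exact C2 symmetry about the superhelical axis", {
  d <- build_ideal_coiled_coil(crick_parameters(), 30)
  a <- select_coords(d, coord_selection("A", c(1, 30), "CA"))
  b <- select_coords(d, coord_selection("B", c(1, 30), "CA"))
  rot_a <- a %*% t(rotation_about(c(0, 0, 1), 180))
  expect_lt(sqrt(mean(rowSums((rot_a - b)^2))), 1e-6)
})

test_that("build then measure recovers the imposed Crick parameters", {
  for (r0 in c(3, 4.9, 6)) {
    d <- build_ideal_coiled_coil(crick_parameters(r0 = r0), 40)
    m <- measure_coiled_coil(d, c("A", "B"), c(1, 40))
    expect_equal(m$r0, r0, tolerance = 0.1)
    expect_equal(m$rise, 1.495, tolerance = 0.01)
  }
})

test_that("overlap assembly splices a superposed fragment into the scaffold", {
  scaf <- gen_overlap_bundle(theta = 10, omega = 5)$structure
  frag <- build_ideal_coiled_coil(crick_parameters(), 35,
                                  chain_ids = c("P", "Q"), start_resno = 6)
  R <- random_rotation(seed = 3)
  frag <- set_model_coords(frag, sweep(model_coords(frag, 1) %*% t(R), 2,
                                       c(25, -10, 4), `+`))
  asm <- assemble_overlap(scaf, frag, scaffold_window = c(1, 29),
                          fragment_window = c(6, 34),
                          chain_map = c(P = "A", Q = "B"))
  # the 4-helix junction survives the splice
  expect_setequal(unique(asm$atom$chain), c("A", "B", "C", "D"))
  expect_lt(asm$metadata$window_rmsd, 1e-6)
  # fragment numbering lands in scaffold numbering (6-34 -> 1-29)
  expect_equal(range(asm$atom$resno[asm$atom$chain == "A"]), c(1, 30))
  # untouched chains keep their coordinates
  keep <- asm$atom$chain %in% c("C", "D")
  orig <- scaf$atom$chain %in% c("C", "D")
  expect_equal(model_coords(asm, 1)[keep, ], model_coords(scaf, 1)[orig, ],
               tolerance = 1e-9)
})

test_that("assembly is idempotent for a fragment already in the scaffold frame", {
  scaf <- gen_overlap_bundle()$structure
  # fragment = the scaffold's own N-terminal dimer, relabelled
  rows <- scaf$atom$chain %in% c("A", "B")
  frag_atom <- scaf$atom[rows, ]
  frag_atom$chain <- ifelse(frag_atom$chain == "A", "P", "Q")
  frag <- cc_structure(frag_atom, scaf$xyz[, rep(rows, each = 3), drop = FALSE])
  asm <- assemble_overlap(scaf, frag, scaffold_window = c(1, 30),
                          fragment_window = c(1, 30),
                          chain_map = c(P = "A", Q = "B"))
  expect_lt(asm$metadata$window_rmsd, 1e-9)
  expect_equal(model_coords(asm, 1), model_coords(scaf, 1), tolerance = 1e-9)
})

test_that("mismatched mapping windows are refused", {
  scaf <- gen_overlap_bundle()$structure
  frag <- build_ideal_coiled_coil(crick_parameters(), 35,
                                  chain_ids = c("P", "Q"), start_resno = 6)
  expect_error(assemble_overlap(scaf, frag, scaffold_window = c(1, 29),
                                fragment_window = c(6, 35),
                                chain_map = c(P = "A", Q = "B")),
               "length mismatch")
})

test_that("threading renames residues without moving a single atom", {
  bb <- build_ideal_coiled_coil(crick_parameters(), 12)
  seq12 <- "MELDRAQKSLIV"
  th <- thread_sequence(bb, seq12)
  expect_identical(th$xyz, bb$xyz)
  expect_equal(th$atom$resid[th$atom$chain == "A"],
               unname(c(M = "MET", E = "GLU", L = "LEU", D = "ASP", R = "ARG",
                        A = "ALA", Q = "GLN", K = "LYS", S = "SER", L = "LEU",
                        I = "ILE", V = "VAL")))
  # threading the sequence already present changes nothing but metadata
  same <- thread_sequence(bb, paste(rep("A", 12), collapse = ""))
  expect_identical(same$xyz, bb$xyz)
  expect_equal(same$atom$resid, bb$atom$resid)
})

test_that("threading validates sequence length and alphabet", {
  bb <- build_ideal_coiled_coil(crick_parameters(), 85)
  expect_error(thread_sequence(bb, paste(rep("A", 80), collapse = "")),
               "length error")
  expect_error(thread_sequence(build_ideal_coiled_coil(crick_parameters(), 5),
                               "AXAAA"), "alphabet")
})

test_that("terminal extension continues numbering and matches body geometry", {
  d <- build_ideal_coiled_coil(crick_parameters(), 30)
  expect_identical(extend_termini(d, crick_parameters(), 0), d)
  e <- extend_termini(d, crick_parameters(), 12)
  expect_equal(max(e$atom$resno), 42)
  expect_equal(sum(e$atom$chain == "A"), 42)
  body <- measure_coiled_coil(d, c("A", "B"), c(1, 30))
  ext <- measure_coiled_coil(e, c("A", "B"), c(28, 42))
  expect_equal(ext$r0, body$r0, tolerance = 0.1)
})
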