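test_that("caps are added exactly at free extendable termini", {
  lib <- toy_lib()
  sc <- toy_chain_scene(c("H4", "H4", "H4_j1_K4", "K4"))
  capped <- add_caps(sc)
  caps <- grep("cap", names(capped$modules), value = TRUE)
  expect_setequal(caps, c("Ncap_H4.001", "Ccap_K4.001"))
  # brute-force occupancy scan: no free extendable terminus stays uncapped
  expect_length(modcad:::free_extendable_termini(capped), 0)
  # scene untouched (pure operation)
  expect_length(sc$modules, 4)

  # toy Cn hub with extended arms: n C-caps, 0 N-caps (N sides sealed)
  sc4 <- design_scene(lib)
  hid <- place_module(sc4, "H4_C4")
  extrude(sc4, hid, ":A(C)->(N)A:H4")
  capped4 <- add_caps(sc4)
  caps4 <- grep("cap", names(capped4$modules), value = TRUE)
  expect_length(grep("^Ccap_H4", caps4), 4)
  expect_length(grep("^Ncap", caps4), 0)
})

test_that("chain assignment is one id per maximal N->C path", {
  lib <- toy_lib()
  sc <- toy_chain_scene(c("H4", "H4", "H4"))
  chains <- assign_chains(add_caps(sc))
  expect_identical(names(chains), "A")
  expect_length(chains$A, 5)  # Ncap + 3 modules + Ccap

  sc4 <- design_scene(lib)
  hid <- place_module(sc4, "H4_C4")
  extrude(sc4, hid, ":A(C)->(N)A:H4")
  chains4 <- assign_chains(add_caps(sc4))
  expect_identical(names(chains4), c("A", "B", "C", "D"))
  # two disjoint networks: ordered by network name
  sc2 <- design_scene(lib)
  place_module(sc2, "K4")
  place_module(sc2, "H4", rt(diag(3), c(50, 0, 0)))
  chains2 <- assign_chains(add_caps(sc2))
  expect_identical(chains2$A[[1]]$instance, "Ncap_H4.001")
  expect_length(chains2, 2)
})

test_that("stitched atoms equal an independent reprojection", {
  lib <- toy_lib()
  sc <- toy_chain_scene(c("H4", "H4", "H4_j1_K4"))
  cif <- tempfile(fileext = ".cif")
  model <- stitch(sc, cif)
  capped <- add_caps(sc)
  # oracle: reproject every fragment from disk through the stored world pose
  expect_identical(nrow(model$atoms), nrow(model$provenance))
  for (id in unique(model$provenance$instance)) {
    inst <- capped$modules[[id]]
    frag <- read_pdb_fragment(file.path(
      toy_dir(), "fragments", paste0(inst$proto, ".pdb")))
    sel <- model$provenance$instance == id
    got <- cbind(model$atoms$x[sel], model$atoms$y[sel], model$atoms$z[sel])
    want <- apply_rt_oracle(inst$world$rot, inst$world$tran,
                            cbind(frag$x, frag$y, frag$z))
    expect_lt(max(abs(got - want)), 1e-6)
  }
  # residues renumbered 1..n without gaps
  expect_identical(sort(unique(model$atoms$resi)),
                   seq_len(max(model$atoms$resi)))
  # peptide continuity holds by construction in the toy library
  expect_silent(modcad:::check_peptide_continuity(model))

  # identity and pure-translation placements reproduce fragment atoms
  sc1 <- design_scene(lib)
  place_module(sc1, "K4")
  m1 <- stitch(sc1, NULL)
  frag <- read_pdb_fragment(file.path(toy_dir(), "fragments", "K4.pdb"))
  core <- m1$provenance$instance == "K4.001"
  expect_equal(cbind(m1$atoms$x[core], m1$atoms$y[core], m1$atoms$z[core]),
               cbind(frag$x, frag$y, frag$z), tolerance = 1e-9,
               ignore_attr = TRUE)
  sc2 <- design_scene(lib)
  place_module(sc2, "K4", rt(diag(3), c(10, 0, 0)))
  m2 <- stitch(sc2, NULL)
  core2 <- m2$provenance$instance == "K4.001"
  expect_equal(m2$atoms$x[core2], frag$x + 10, tolerance = 1e-9)
})

test_that("drop_b residue ranges are omitted at junctions", {
  lib <- toy_lib()
  # clone the library with a drop range on the H4->H4 pair
  lib2 <- lib
  idx <- which(vapply(lib2$pairs, function(p) {
    p$a == "H4" && p$b == "H4"
  }, logical(1)))
  lib2$pairs[[idx]]$drop_b <- 1L
  sc <- design_scene(lib2)
  id <- place_module(sc, "H4")
  extrude(sc, id, ":A(C)->(N)A:H4")
  # the dropped repeat leaves a gap; the continuity *warning* is by design
  model <- suppressWarnings(stitch(sc, NULL))
  second <- model$provenance$instance == "H4.002"
  expect_false(1L %in% model$provenance$src_resi[second])
  expect_identical(sum(second), 12L)  # 3 of 4 residues kept
})

test_that("mmCIF output round-trips and PDB limits are refused", {
  lib <- toy_lib()
  sc <- toy_chain_scene(c("H4", "H4"))
  cif <- tempfile(fileext = ".cif")
  model <- stitch(sc, cif)
  back <- read_mmcif(cif)
  expect_identical(nrow(back), nrow(model$atoms))
  expect_equal(cbind(back$x, back$y, back$z),
               round(cbind(model$atoms$x, model$atoms$y, model$atoms$z), 3),
               ignore_attr = TRUE)
  expect_identical(back$chain, model$atoms$chain)
  expect_identical(back$resi, model$atoms$resi)
  expect_error(write_mmcif(modcad:::empty_atom_table(), tempfile()),
               class = "modcad_empty_model")
  # > 26 chains are fine in mmCIF (two-letter ids), refused for PDB
  atoms <- model$atoms
  atoms$chain <- "AB"
  f <- tempfile(fileext = ".cif")
  write_mmcif(atoms, f)
  expect_identical(unique(read_mmcif(f)$chain), "AB")
  expect_error(write_pdb_fragment(atoms, tempfile()),
               class = "modcad_format_limit")
})

test_that("pdb reader infers elements and reports malformed lines", {
  d <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00",
    "ATOM      2  N   ALA A   2       2.000   3.000   4.000  1.00  0.00"),
    d)
  atoms <- read_pdb_fragment(d)
  expect_identical(atoms$element, c("C", "N"))
  writeLines("ATOM      1  CA  ALA A   1       xxx.000   2.000   3.000", d)
  expect_error(read_pdb_fragment(d), class = "modcad_parse")
  expect_error(read_pdb_fragment(tempfile()), class = "modcad_io")
  writeLines("REMARK nothing here", d)
  expect_error(read_pdb_fragment(d), class = "modcad_parse")
})

test_that("stitching refuses colliding or empty designs", {
  lib <- toy_lib()
  expect_error(stitch(design_scene(lib), NULL), class = "modcad_empty_model")
  sc <- design_scene(lib, auto_collision = FALSE)
  place_module(sc, "H4")
  place_module(sc, "H4", rt(diag(3), c(0.5, 0, 0)))
  expect_error(stitch(sc, NULL), class = "modcad_validation")
})
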