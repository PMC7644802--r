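test_that("placement numbering, networks, caps and collisions", {
  lib <- toy_lib()
  sc <- design_scene(lib)
  expect_identical(place_module(sc, "H4"), "H4.001")
  expect_identical(place_module(sc, "H4", rt(diag(3), c(50, 0, 0))),
                   "H4.002")
  expect_length(sc$networks, 2)
  expect_error(place_module(sc, "H4"), class = "modcad_collision")
  expect_error(place_module(sc, "Ccap_H4"), class = "modcad_cap_placement")
  expect_error(place_module(sc, "missing"), class = "modcad_unknown_module")
  # freed numbers are reused (lowest available)
  delete_instance(sc, "H4.001")
  expect_identical(place_module(sc, "H4", rt(diag(3), c(-50, 0, 0))),
                   "H4.001")
})

test_that("extrusion follows pair transforms and bookkeeping", {
  lib <- toy_lib()
  sc <- toy_chain_scene(c("H4", "H4", "H4", "H4_j1_K4", "K4"))
  expect_length(sc$networks, 1)
  expect_length(sc$links, 4)
  # child k world equals pair transforms composed k-1 times (oracle:
  # explicit repeated composition from the serialized pair list)
  pairs <- lib$pairs
  find <- function(a, b) {
    for (p in pairs) if (p$a == a && p$b == b) return(p$t)
  }
  w <- rt_identity()
  for (step in list(c("H4", "H4"), c("H4", "H4"), c("H4", "H4_j1_K4"),
                    c("H4_j1_K4", "K4"))) {
    w <- rt_compose(w, find(step[1], step[2]))
  }
  expect_rt_equal(sc$modules[["K4.001"]]$world, w, 1e-9)
  # occupancy bookkeeping: 2 occupied termini per link
  occ <- sum(vapply(sc$modules, function(m) {
    sum(grepl("^link\\.", unlist(m$occupancy)))
  }, numeric(1)))
  expect_identical(occ, 2 * length(sc$links))
  # extruding an occupied terminus fails
  expect_error(extrude(sc, "H4.001", ":A(C)->(N)A:H4"),
               class = "modcad_occupied_terminus")
  expect_error(extrude(sc, "K4.001", ":A(C)->(N)A:H4"),
               class = "modcad_incompatible_descriptor")
  # N-terminal extrusion places the predecessor
  nid <- extrude(sc, "H4.001", ":A(N)->(C)A:H4")
  expect_rt_equal(sc$modules[[nid]]$world,
                  rt(diag(3), c(0, 0, -6)), 1e-9)
})

test_that("descriptor strings round-trip the documented grammar", {
  d <- desc_from_string(":A(N)->(C)A:D49_aC2_24")
  expect_identical(d$from_chain, "A")
  expect_identical(d$from_term, "N")
  expect_identical(d$to_term, "C")
  expect_identical(d$to_proto, "D49_aC2_24")
  expect_identical(desc_to_string(d), ":A(N)->(C)A:D49_aC2_24")
  expect_error(desc_from_string("A(N)->C"), class = "modcad_invalid_descriptor")
})

test_that("sphere collision verdicts behave at the documented examples", {
  lib <- toy_lib()
  sc <- design_scene(lib)
  place_module(sc, "H4")
  r <- lib$modules$H4$radius
  # far apart: no collision even at f = 1
  far <- check_collision(sc, "H4", rt(diag(3), c(4 * r, 0, 0)), factor = 1)
  expect_false(far$collision)
  dup <- check_collision(sc, "H4", rt_identity())
  expect_true(dup$collision)
  expect_identical(dup$with, "H4.001")
  # exemption suppresses the verdict
  ex <- check_collision(sc, "H4", rt_identity(), exempt = "H4.001")
  expect_false(ex$collision)
})

test_that("mirror linking groups, extrudes atomically, and unlinks", {
  lib <- toy_lib()
  sc <- design_scene(lib)
  a <- place_module(sc, "H4")
  b <- place_module(sc, "H4", rt(rot_z(180), c(60, 0, 0)))
  k <- place_module(sc, "K4", rt(diag(3), c(0, 60, 0)))
  expect_error(link_by_mirror(sc, c(a, k)),
               class = "modcad_mirror_type_mismatch")
  expect_error(link_by_mirror(sc, a), class = "modcad_mirror_singleton")
  gid <- link_by_mirror(sc, c(a, b))
  kids <- extrude(sc, a, ":A(C)->(N)A:H4")
  expect_length(kids, 2)
  # children are mirror-linked in turn: extruding one extrudes both
  kids2 <- extrude(sc, kids[1], ":A(C)->(N)A:H4")
  expect_length(kids2, 2)
  expect_length(sc$modules, 7)
  unlink_mirror(sc, gid)
  expect_error(unlink_mirror(sc, gid), class = "modcad_unknown_mirror_group")
  # after unlinking, extrusion is independent again
  solo <- extrude(sc, a, ":A(N)->(C)A:H4")
  expect_length(solo, 1)
})

test_that("mirror extrusion is all-or-nothing", {
  lib <- toy_lib()
  sc <- design_scene(lib)
  a <- place_module(sc, "H4")
  b <- place_module(sc, "H4", rt(diag(3), c(60, 0, 0)))
  link_by_mirror(sc, c(a, b))
  # occupy b's C-terminus so the mirrored copy must fail
  grp <- sc$mirror_groups
  sc$mirror_groups <- list()
  extrude(sc, b, ":A(C)->(N)A:H4")
  sc$mirror_groups <- grp
  before <- length(sc$modules)
  expect_error(extrude(sc, a, ":A(C)->(N)A:H4"),
               class = "modcad_occupied_terminus")
  expect_length(sc$modules, before)
})

test_that("symmetric hubs are automatically mirror-linked", {
  lib <- toy_lib()
  sc <- design_scene(lib)
  hid <- place_module(sc, "H4_C4")
  expect_length(sc$mirror_groups, 1)
  expect_length(sc$mirror_groups[[1]], 4)
  arms <- extrude(sc, hid, ":A(C)->(N)A:H4")
  expect_length(arms, 4)
  expect_length(sc$networks, 1)
})

test_that("join_networks reproduces the extruded-equivalent geometry", {
  lib <- toy_lib()
  sc <- design_scene(lib)
  a <- place_module(sc, "H4")
  b <- place_module(sc, "H4", rt(rot_z(33), c(40, 10, -5)))
  nid <- join_networks(sc,
                       list(instance = a, chain = "A", term = "C"),
                       list(instance = b, chain = "A", term = "N"))
  expect_length(sc$networks, 1)
  expect_length(sc$links, 1)
  # oracle: the same chain built by extrusion
  sc2 <- toy_chain_scene(c("H4", "H4"))
  expect_rt_equal(sc$modules[[b]]$world, sc2$modules[["H4.002"]]$world, 1e-9)

  # incompatible or occupied termini refuse
  c1 <- place_module(sc, "K4", rt(diag(3), c(80, 0, 0)))
  expect_error(join_networks(sc,
                             list(instance = a, chain = "A", term = "C"),
                             list(instance = c1, chain = "A", term = "N")),
               class = "modcad_occupied_terminus")
  expect_error(join_networks(sc,
                             list(instance = c1, chain = "A", term = "N"),
                             list(instance = b, chain = "A", term = "C")),
               class = "modcad_incompatible_pair")
})

test_that("deletion splits networks into link-graph components", {
  sc <- toy_chain_scene(c("H4", "H4", "H4"))
  delete_instance(sc, "H4.002")
  expect_length(sc$networks, 2)
  comps <- lapply(sc$networks, sort)
  expect_setequal(unlist(lapply(comps, paste, collapse = ",")),
                  c("H4.001", "H4.003"))
  sc2 <- toy_chain_scene(c("H4", "H4", "H4"))
  delete_instance(sc2, "H4.003")
  expect_length(sc2$networks, 1)
  expect_error(delete_instance(sc2, "H4.099"),
               class = "modcad_unknown_instance")
})

test_that("transform_network moves members rigidly", {
  sc <- toy_chain_scene(c("H4", "H4"))
  nid <- names(sc$networks)[1]
  before <- lapply(sc$modules, function(m) m$world)
  transform_network(sc, nid, rt_identity())
  for (id in names(before)) {
    expect_rt_equal(sc$modules[[id]]$world, before[[id]], 1e-12)
  }
  tr <- rt(rot_y(65), c(5, -4, 12))
  transform_network(sc, nid, tr)
  d_before <- sqrt(sum((inst_com(sc, "H4.001") - inst_com(sc, "H4.002"))^2))
  expect_equal(d_before, 6, tolerance = 1e-9)
  for (id in names(before)) {
    expect_rt_equal(sc$modules[[id]]$world,
                    rt_compose(tr, before[[id]]), 1e-9)
  }
  expect_error(transform_network(sc, "net:nope", rt_identity()),
               class = "modcad_unknown_network")
})

test_that("design JSON round-trips scenes (modules + guide + mirrors)", {
  lib <- toy_lib()
  sc <- toy_chain_scene(c("H4", "H4", "H4_j1_K4"))
  j1 <- add_joint(sc, c(10, 0, 0))
  j2 <- extrude_joint(sc, j1, c(20, 5, 0))
  f1 <- tempfile(fileext = ".json")
  export_design(sc, f1)
  sc2 <- import_design(f1, lib)
  expect_identical(sort(names(sc2$modules)), sort(names(sc$modules)))
  for (id in names(sc$modules)) {
    expect_identical(sc2$modules[[id]]$proto, sc$modules[[id]]$proto)
    expect_rt_equal(sc2$modules[[id]]$world, sc$modules[[id]]$world, 1e-9)
  }
  expect_length(sc2$links, length(sc$links))
  expect_identical(sort(names(sc2$guide$joints)),
                   sort(names(sc$guide$joints)))
  # empty scene round-trip
  f0 <- tempfile(fileext = ".json")
  export_design(design_scene(lib), f0)
  sc0 <- import_design(f0, lib)
  expect_length(sc0$modules, 0)
  # schema violations carry field context
  obj <- jsonlite::fromJSON(f1, simplifyVector = FALSE)
  obj$units <- NULL
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(obj, f2, auto_unbox = TRUE)
  expect_error(import_design(f2, lib), class = "modcad_schema")
})

test_that("validate_scene reports collisions when auto-check is off", {
  lib <- toy_lib()
  sc <- design_scene(lib, auto_collision = FALSE)
  place_module(sc, "H4")
  place_module(sc, "H4", rt(diag(3), c(0.5, 0, 0)))
  findings <- validate_scene(sc)
  expect_true(any(vapply(findings, function(f) f$kind == "collision",
                         logical(1))))
  set_auto_collision(sc, TRUE)
  expect_error(place_module(sc, "H4", rt(diag(3), c(1, 0, 0))),
               class = "modcad_collision")
})
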