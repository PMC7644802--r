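test_that("module name grammar classifies the documented name forms", {
  j <- parse_module_name("D14_j1_D79")
  expect_identical(j$cls, "junction")
  expect_identical(j$n_iface, "D14")
  expect_identical(j$c_iface, "D79")
  expect_identical(j$junction_index, 1L)

  h <- parse_module_name("D4_C4")
  expect_identical(h$cls, "hub")
  expect_identical(h$hub_base, "D4")
  expect_identical(h$symmetry, "C4")
  # extended hub tags keep their cyclic order, suffix treated as opaque
  h2 <- parse_module_name("D49_aC2_24")
  expect_identical(h2$cls, "hub")
  expect_identical(h2$hub_base, "D49")
  expect_identical(h2$symmetry, "C2")

  cc <- parse_module_name("Ccap_D14")
  expect_identical(cc$cls, "cap")
  expect_identical(cc$n_iface, "D14")
  expect_true(is.na(cc$c_iface))
  nc <- parse_module_name("Ncap_D14")
  expect_identical(nc$c_iface, "D14")

  core <- parse_module_name("proA")
  expect_identical(core$cls, "core")
  expect_identical(core$n_iface, "proA")

  expect_error(parse_module_name(""), class = "modcad_invalid_name")
  expect_error(parse_module_name("D4.001"), class = "modcad_invalid_name")
})

test_that("com/radius equal brute-force values", {
  expect_equal(compute_com_radius(rbind(c(0, 0, 0))),
               list(com = c(0, 0, 0), radius = 0))
  expect_equal(compute_com_radius(rbind(c(1, 0, 0), c(-1, 0, 0))),
               list(com = c(0, 0, 0), radius = 1))
  set.seed(5)
  cloud <- matrix(rnorm(300), 100, 3)
  got <- compute_com_radius(cloud)
  ctr <- apply(cloud, 2, mean)
  brute <- max(apply(cloud, 1, function(p) sqrt(sum((p - ctr)^2))))
  expect_equal(got$com, as.numeric(ctr))
  expect_equal(got$radius, brute)
  expect_error(compute_com_radius(cloud[0, ]), class = "modcad_bad_points")
})

test_that("pair transforms are recovered from constructed pair structures", {
  lib <- toy_lib()
  frag <- read_pdb_fragment(file.path(toy_dir(), "fragments", "H4.pdb"))
  known <- rt(rot_y(40), c(2, -3, 7))
  moved <- frag
  xyz <- rt_apply(known, cbind(frag$x, frag$y, frag$z))
  moved$x <- xyz[, 1]; moved$y <- xyz[, 2]; moved$z <- xyz[, 3]
  moved$chain <- "B"
  pair <- rbind(frag, moved)
  fit <- compute_pair_transform(pair, frag, frag, c(A = "A"), c(A = "B"))
  expect_rt_equal(fit$t, known, 1e-7)
  expect_lt(fit$rmsd, 1e-9)

  ident <- compute_pair_transform(frag, frag, frag, c(A = "A"), c(A = "A"))
  expect_rt_equal(ident$t, rt_identity(), 1e-7)

  mislabeled <- frag
  mislabeled$atom[1] <- "XX"
  expect_error(
    compute_pair_transform(mislabeled, frag, frag, c(A = "A"), c(A = "A")),
    class = "modcad_unmatched_labels")
  far <- pair
  far$x[far$chain == "B"] <- far$x[far$chain == "B"] + rnorm(16, sd = 2)
  expect_error(
    compute_pair_transform(far, frag, frag, c(A = "A"), c(A = "B")),
    class = "modcad_incompatible_pair")
})

test_that("compatible_successors equals exhaustive pair-list filtering", {
  lib <- toy_lib()
  for (proto in names(lib$modules)) {
    m <- lib$modules[[proto]]
    for (ch in names(m$chains)) {
      for (term in c("N", "C")) {
        got <- sapply(compatible_successors(lib, proto, ch, term),
                      desc_to_string)
        # oracle: direct scan over the serialized pair list
        cd <- m$chains[[ch]]
        ext <- if (term == "N") isTRUE(cd$n_extendable)
               else isTRUE(cd$c_extendable)
        want <- character(0)
        if (ext) {
          for (p in lib$pairs) {
            if (term == "C" && p$a == proto && p$a_chain == ch &&
                lib$modules[[p$b]]$cls != "cap") {
              want <- c(want, sprintf(":%s(C)->(N)%s:%s", ch, p$b_chain, p$b))
            }
            if (term == "N" && p$b == proto && p$b_chain == ch &&
                lib$modules[[p$a]]$cls != "cap") {
              want <- c(want, sprintf(":%s(N)->(C)%s:%s", ch, p$a_chain, p$a))
            }
          }
        }
        expect_identical(as.character(got), sort(want),
                         info = paste(proto, ch, term))
      }
    }
  }
  # the paper's headline cases: self-compatibility and matching junctions
  cs <- sapply(compatible_successors(lib, "H4", "A", "C"), desc_to_string)
  expect_true(":A(C)->(N)A:H4" %in% cs)
  expect_true(":A(C)->(N)A:H4_j1_K4" %in% cs)
  # sealed hub N-terminus yields nothing
  expect_length(compatible_successors(lib, "H4_C2", "A", "N"), 0)
  expect_error(compatible_successors(lib, "nope", "A", "C"),
               class = "modcad_unknown_module")
})

test_that("library JSON round-trips exactly and rejects bad files", {
  lib <- toy_lib()
  path <- tempfile(fileext = ".json")
  save_library(lib, path)
  lib2 <- load_library(path)
  # numeric fields agree to full serialized precision (last-ulp wobble
  # from shortest-round-trip decimal output is allowed)
  expect_equal(lib2$modules, lib$modules, tolerance = 1e-12)
  expect_identical(names(lib2$modules), names(lib$modules))
  expect_equal(length(lib2$pairs), length(lib$pairs))
  for (i in seq_along(lib$pairs)) {
    expect_identical(lib2$pairs[[i]][c("a", "a_chain", "b", "b_chain")],
                     lib$pairs[[i]][c("a", "a_chain", "b", "b_chain")])
    expect_rt_equal(lib2$pairs[[i]]$t, lib$pairs[[i]]$t, 1e-12)
  }
  expect_identical(lib2$token_set, lib$token_set)

  bad <- tempfile(fileext = ".json")
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  obj$version <- "who-knows/9"
  jsonlite::write_json(obj, bad, auto_unbox = TRUE)
  expect_error(load_library(bad), class = "modcad_schema_version")
  writeLines(substr(paste(readLines(path), collapse = "\n"), 1, 100),
             bad)
  expect_error(load_library(bad), class = "modcad_parse")
})

test_that("build_library validates capping closure and input sanity", {
  expect_error(build_library(tempfile(), tempfile(), list()),
               class = "modcad_empty_library")
  # removing a cap from the manifest must break capping closure
  manifest <- jsonlite::fromJSON(file.path(toy_dir(), "manifest.json"),
                                 simplifyVector = FALSE)
  keep <- Filter(function(m) m$name != "Ccap_K4", manifest$modules)
  manifest$modules <- keep
  manifest$pairs <- Filter(function(p) {
    p$a != "Ccap_K4" && p$b != "Ccap_K4"
  }, manifest$pairs)
  expect_error(
    build_library(file.path(toy_dir(), "fragments"),
                  file.path(toy_dir(), "pairs"), manifest),
    class = "modcad_missing_cap")
})
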