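test_that("score_fit matches the stated chamfer formula", {
  g <- path_guide()
  j1 <- add_joint(g, c(0, 0, 0))
  j2 <- extrude_joint(g, j1, c(10, 0, 0))
  # coms exactly on the joints: 0
  expect_equal(score_fit(rbind(c(0, 0, 0), c(10, 0, 0)), g), 0)
  # single com at distance d from a single joint: d
  g1 <- path_guide()
  add_joint(g1, c(0, 0, 0))
  expect_equal(score_fit(rbind(c(3, 4, 0)), g1), 5, tolerance = 1e-12)
  # random configurations against a brute-force evaluation of the formula
  set.seed(23)
  for (rep in 1:20) {
    coms <- matrix(runif(9, -5, 15), 3, 3)
    jpos <- rbind(c(0, 0, 0), c(10, 0, 0))
    seg_d <- function(p) {
      t <- min(1, max(0, sum((p - jpos[1, ]) * c(10, 0, 0)) / 100))
      sqrt(sum((p - (jpos[1, ] + t * c(10, 0, 0)))^2))
    }
    d_com <- apply(coms, 1, seg_d)
    d_joint <- apply(jpos, 1, function(jp) {
      min(sqrt(rowSums(sweep(coms, 2, jp)^2)))
    })
    expect_equal(score_fit(coms, g),
                 sqrt(mean(c(d_com, d_joint)^2)), tolerance = 1e-12)
  }
  expect_error(score_fit(matrix(0, 0, 3), g), class = "modcad_bad_points")
})

test_that("solver recovers generating chains and handles tiny guides", {
  lib <- toy_lib()
  chain <- c("H4", "H4", "H4_j1_K4", "K4")
  g <- generate_guide_from_chain(lib, chain, 0)
  sol <- solve_spec(g, lib, max_len = 5, beam = 8, seed = 3)
  net <- sol$networks[[1]]
  gen_score <- score_fit(modcad:::chain_com_path(lib, chain), g)
  expect_lte(net$score, gen_score + 1e-9)
  expect_identical(vapply(net$chain, function(e) e$proto, character(1)),
                   chain)
  # single-joint guide: one module centered on the joint
  g1 <- path_guide()
  add_joint(g1, c(5, 5, 5))
  s1 <- solve_spec(g1, lib, max_len = 3, beam = 4)
  expect_lt(s1$networks[[1]]$score, 1e-9)
  expect_length(s1$networks[[1]]$chain, 1)
})

test_that("an unreachable guide yields an honest positive score", {
  lib <- toy_lib()
  # a sharp left turn the toy library cannot make
  g <- path_guide()
  j <- add_joint(g, c(0, 0, 0))
  j <- extrude_joint(g, j, c(0, 0, 12))
  j <- extrude_joint(g, j, c(40, 0, 12))
  sol <- solve_spec(g, lib, max_len = 4, beam = Inf, seed = 1)
  expect_gt(sol$networks[[1]]$score, 1)
  # exhaustive search over the same budget cannot do better (oracle:
  # enumerate all compatible sequences up to length 4 explicitly)
  seqs <- list(character(0))
  all_seqs <- list()
  grow <- function(s) {
    last <- s[length(s)]
    succ <- if (length(s) == 0) c("H4", "H4_j1_K4", "K4") else {
      vapply(compatible_successors(lib, last, "A", "C"),
             function(d) d$to_proto, character(1))
    }
    succ
  }
  frontier <- lapply(c("H4", "H4_j1_K4", "K4"), identity)
  best <- Inf
  score_seq <- function(s) {
    coms <- modcad:::chain_com_path(lib, s)
    tr <- modcad:::fit_chain_to_polyline(
      coms, rbind(c(0, 0, 0), c(0, 0, 12), c(40, 0, 12)))
    score_fit(rt_apply(tr, coms), g)
  }
  while (length(frontier)) {
    s <- frontier[[1]]
    frontier <- frontier[-1]
    best <- min(best, score_seq(s))
    if (length(s) < 4) {
      for (nxt in grow(s)) frontier <- c(frontier, list(c(s, nxt)))
    }
  }
  expect_equal(sol$networks[[1]]$score, best, tolerance = 1e-9)
})

test_that("solutions are deterministic and survive save/load/import", {
  lib <- toy_lib()
  g <- generate_guide_from_chain(lib, c("H4", "H4", "H4"), 0)
  s1 <- solve_spec(g, lib, max_len = 4, beam = 8, seed = 5)
  s2 <- solve_spec(g, lib, max_len = 4, beam = 8, seed = 5)
  f1 <- tempfile(); f2 <- tempfile()
  save_solution(s1, f1)
  save_solution(s2, f2)
  expect_identical(readLines(f1), readLines(f2))

  sc <- design_scene(lib)
  nets <- import_solution(sc, f1)
  expect_length(nets, 1)
  expect_length(sc$modules, length(s1$networks[[1]]$chain))
  expect_length(validate_scene(sc), 0)
  # chain links present and world poses match the solution file
  expect_length(sc$links, length(sc$modules) - 1)

  # tampered transforms are an integrity error
  obj <- jsonlite::fromJSON(f1, simplifyVector = FALSE)
  obj$networks[[1]]$chain[[2]]$tran[[1]] <-
    obj$networks[[1]]$chain[[2]]$tran[[1]] + 0.5
  jsonlite::write_json(obj, f2, auto_unbox = TRUE, digits = NA)
  sc2 <- design_scene(lib)
  expect_error(import_solution(sc2, f2), class = "modcad_integrity")

  # empty solution imports nothing without error
  empty <- list(version = modcad:::SOLUTION_SCHEMA_VERSION,
                networks = list(), meta = list(seed = 1))
  save_solution(empty, f2)
  sc3 <- design_scene(lib)
  expect_length(import_solution(sc3, f2), 0)
  expect_length(sc3$modules, 0)
})

test_that("fixed-module constraints anchor the search", {
  lib <- toy_lib()
  sc <- design_scene(lib)
  id <- place_module(sc, "H4", rt(rot_z(45), c(10, 0, 0)))
  j1 <- add_joint(sc, c(0, 0, 0))
  move_joint_to_module(sc, j1, id, chain = "A", term = "C")
  # guide continues along the module's growth direction
  w <- sc$modules[[id]]$world
  nxt <- rt_apply(w, lib$modules$H4$com + c(0, 0, 6))
  j2 <- extrude_joint(sc, j1, nxt)
  spec_path <- tempfile(fileext = ".json")
  export_solver_spec(sc, spec_path)
  sol <- solve_spec(read_solver_spec(spec_path), lib, max_len = 2, beam = 4)
  net <- sol$networks[[1]]
  expect_identical(net$chain[[1]]$proto, "H4")
  # fixed pose unchanged in the emitted solution
  first <- net$chain[[1]]
  expect_lt(max(abs(do.call(rbind, lapply(first$rot, unlist)) - w$rot)),
            1e-9)
  expect_equal(unlist(first$tran) * 10, w$tran, tolerance = 1e-9)
  expect_lt(net$score, 1e-6)
  expect_length(net$chain, 2)
})
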