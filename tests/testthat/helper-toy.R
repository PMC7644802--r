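# Shared fixtures: one toy library per test run, plus independent
# geometry helpers deliberately written without package internals so they
# can serve as oracles.

.toy_env <- new.env()

toy_dir <- function() {
  if (is.null(.toy_env$dir)) {
    .toy_env$dir <- file.path(tempdir(), "modcad-toy-library")
    .toy_env$lib <- generate_toy_library(toy_config(), .toy_env$dir)
  }
  .toy_env$dir
}

toy_lib <- function() {
  toy_dir()
  .toy_env$lib
}

# independent uniform random rotation (QR of a Gaussian matrix)
rand_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rand_rt <- function(scale = 10) {
  rt(rand_rotation(), runif(3, -scale, scale))
}

# independent application of a rigid transform to points (oracle path)
apply_rt_oracle <- function(rot, tran, pts) {
  t(apply(pts, 1L, function(p) as.numeric(rot %*% p + tran)))
}

# world-space center of mass of a placed instance, from first principles
inst_com <- function(scene, id) {
  m <- scene$modules[[id]]
  proto <- scene$lib$modules[[m$proto]]
  as.numeric(m$world$rot %*% proto$com + m$world$tran)
}

expect_rt_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a$rot - b$rot)), tol)
  expect_lt(max(abs(a$tran - b$tran)), tol)
}

# straight 3-module chain scene used by several suites
toy_chain_scene <- function(protos = c("H4", "H4", "H4")) {
  lib <- toy_lib()
  sc <- design_scene(lib)
  id <- place_module(sc, protos[1])
  for (p in protos[-1]) {
    ds <- sprintf(":A(C)->(N)A:%s", p)
    id <- extrude(sc, id, ds)
  }
  sc
}
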