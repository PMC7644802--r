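# Reference automated designer.
#
# Given a solver spec (pg-networks of joints/bridges, optionally with
# fixed-module constraints), searches single-chain module sequences whose
# center-of-mass path best fits the guide and emits an importable
# Solution.  The optimizer is a deterministic seeded beam search with an
# exhaustive mode (beam = Inf); it deliberately substitutes for the
# genetic algorithm of the original automated designer, behind the same
# spec/solution contract.  Guides are soft targets: there may be no
# zero-score solution, in which case the best effort and its honest score
# are returned.

SOLUTION_SCHEMA_VERSION <- "modcad-solution/1"

# distance from each point (rows of p) to segment [a, b]
point_segment_dist <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(rowSums(sweep(p, 2L, a)^2)))
  t <- pmin(1, pmax(0, (sweep(p, 2L, a) %*% ab) / len2))
  proj <- outer(as.numeric(t), ab) + matrix(a, nrow(p), 3L, byrow = TRUE)
  sqrt(rowSums((p - proj)^2))
}

#' Chamfer-style shape-fit score
#'
#' Root-mean-square of the combined residuals: for each module center the
#' distance to the nearest point of the guide polyline (bridges as
#' segments; isolated joints as points), and for each joint the distance
#' to the nearest module center.  Zero iff every center lies on the
#' polyline and every joint is met.  Units: Angstrom.
#'
#' @param coms ordered n x 3 matrix of module centers of mass (Angstrom).
#' @param guide a `path_guide` (one component).
#' @return the score (Angstrom, lower is better).
#' @export
score_fit <- function(coms, guide) {
  g <- as_guide(guide)
  coms <- as.matrix(coms)
  if (is.null(dim(coms))) coms <- matrix(coms, ncol = 3L)
  if (nrow(coms) == 0L || length(g$joints) == 0L) {
    stop_modcad("score_fit needs at least one center and one joint",
                "bad_points")
  }
  jpos <- do.call(rbind, lapply(g$joints, function(j) j$pos))
  d_com <- rep(Inf, nrow(coms))
  if (length(g$bridges)) {
    for (br in g$bridges) {
      d_com <- pmin(d_com, point_segment_dist(
        coms, g$joints[[br[1L]]]$pos, g$joints[[br[2L]]]$pos))
    }
  }
  bridged <- unique(unlist(g$bridges))
  lone <- setdiff(names(g$joints), bridged)
  for (jid in lone) {
    d_com <- pmin(d_com, sqrt(rowSums(sweep(coms, 2L,
                                            g$joints[[jid]]$pos)^2)))
  }
  d_joint <- apply(jpos, 1L, function(jp) {
    min(sqrt(rowSums(sweep(coms, 2L, jp)^2)))
  })
  sqrt(mean(c(d_com, d_joint)^2))
}

# deterministic traversal order of one pg-network's joints: start at the
# fixed joint of lowest id if any, else the lowest-id endpoint (degree <=
# 1), else the lowest-id joint; neighbors visited in id order.
spec_joint_order <- function(net) {
  ids <- sort(names(net$joints))
  deg <- stats::setNames(integer(length(ids)), ids)
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (br in net$bridges) {
    deg[br] <- deg[br] + 1L
    adj[[br[1L]]] <- c(adj[[br[1L]]], br[2L])
    adj[[br[2L]]] <- c(adj[[br[2L]]], br[1L])
  }
  fixed <- ids[vapply(ids, function(i) !is.null(net$joints[[i]]$fixed),
                      logical(1))]
  start <- if (length(fixed)) fixed[1L]
           else if (any(deg <= 1L)) ids[deg <= 1L][1L]
           else ids[1L]
  order <- character(0)
  stack <- start
  while (length(stack)) {
    cur <- stack[[1L]]
    stack <- stack[-1L]
    if (cur %in% order) next
    order <- c(order, cur)
    nxt <- sort(setdiff(adj[[cur]], order))
    stack <- c(nxt, stack)
  }
  c(order, setdiff(ids, order))
}

# resample a polyline (rows = vertices) to k points by arc length
resample_polyline <- function(pts, k) {
  if (nrow(pts) == 1L) return(pts[rep(1L, k), , drop = FALSE])
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  at <- if (k == 1L) total / 2 else seq(0, total, length.out = k)
  out <- matrix(0, k, 3L)
  for (i in seq_len(k)) {
    s <- at[i]
    j <- max(which(cum <= s + 1e-12))
    if (j >= nrow(pts)) {
      out[i, ] <- pts[nrow(pts), ]
    } else {
      f <- if (seg[j] == 0) 0 else (s - cum[j]) / seg[j]
      out[i, ] <- pts[j, ] * (1 - f) + pts[j + 1L, ] * f
    }
  }
  out
}

# optimal rigid placement of a local com path onto the ordered joints:
# exact pairing when lengths match, else arc-length resampling
fit_chain_to_polyline <- function(coms, joints) {
  target <- if (nrow(coms) == nrow(joints)) joints
            else resample_polyline(joints, nrow(coms))
  kabsch(coms, target)$transform
}

solver_start_protos <- function(lib) {
  sort(Filter(function(nm) {
    m <- lib$modules[[nm]]
    m$cls %in% c("core", "junction")
  }, names(lib$modules)))
}

# successors of the (single-chain) prototype's C-terminus, caps excluded
solver_successors <- function(lib, proto) {
  chain <- names(lib_module(lib, proto)$chains)[1L]
  compatible_successors(lib, proto, chain, "C")
}

# sphere feasibility of a local com path at overlap factor f
chain_feasible <- function(lib, protos, coms, f = 0.75) {
  n <- length(protos)
  if (n < 3L) return(TRUE)
  radii <- vapply_num(protos, function(p) lib_module(lib, p)$radius)
  for (i in seq_len(n - 2L)) {
    for (j in seq((i + 2L), n)) {
      if (sqrt(sum((coms[i, ] - coms[j, ])^2)) < f * (radii[i] + radii[j])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Solve a path-guide spec by deterministic beam search
#'
#' For every pg-network, grows compatible single-chain module sequences
#' C-terminal-wards (hubs enter designs only via manual placement), fits
#' each candidate rigidly onto the ordered guide polyline (exact
#' com-to-joint pairing when the lengths match, arc-length resampling
#' otherwise), scores with [score_fit()], and keeps the `beam` best
#' partial sequences per depth.  A network with a fixed-module constraint
#' is anchored: the fixed module is the mandatory start, its pose is never
#' altered, and no global refit is applied.  Ties are broken
#' lexicographically by descriptor sequence, so results are deterministic
#' for identical `(spec, seed)`.
#'
#' @param spec parsed solver spec ([read_solver_spec()]), or a
#'   `path_guide` (treated as one unconstrained spec).
#' @param lib a `module_library`.
#' @param max_len maximum chain length (search budget).
#' @param beam beam width (`Inf` = exhaustive).
#' @param seed integer, recorded in the solution metadata (the reference
#'   search is deterministic and uses no randomness).
#' @param collision_factor sphere overlap factor for feasibility.
#' @return a solution list (see [save_solution()]).
#' @export
solve_spec <- function(spec, lib, max_len = 6L, beam = 8L, seed = 1L,
                       collision_factor = 0.75) {
  if (inherits(spec, "path_guide")) {
    g <- spec
    nets <- lapply(pg_components(g), function(members) {
      joints <- lapply(members, function(jid) {
        list(id = jid, pos = g$joints[[jid]]$pos, fixed = NULL)
      })
      names(joints) <- members
      bridges <- Filter(function(br) br[1L] %in% members, g$bridges)
      list(name = paste0("pg:", members[1L]), joints = joints,
           bridges = bridges)
    })
    spec <- list(version = SPEC_SCHEMA_VERSION, pg_networks = nets)
  }
  if (length(spec$pg_networks) == 0L) {
    stop_modcad("spec has no pg-networks", "no_solution")
  }
  if (max_len < 1L || (!is.infinite(beam) && beam < 1L)) {
    stop_modcad("search budget must be positive", "invalid_config")
  }
  networks <- lapply(spec$pg_networks, function(net) {
    solve_network(net, lib, max_len, beam, collision_factor)
  })
  list(version = SOLUTION_SCHEMA_VERSION,
       networks = networks,
       meta = list(seed = as.integer(seed),
                   beam = if (is.infinite(beam)) -1L else as.integer(beam),
                   max_len = as.integer(max_len),
                   algorithm = "beam"))
}

solve_network <- function(net, lib, max_len, beam, f) {
  order <- spec_joint_order(net)
  joints <- do.call(rbind, lapply(order, function(jid) {
    net$joints[[jid]]$pos
  }))
  guide <- spec_net_guide(net)
  fixed <- Filter(function(jid) !is.null(net$joints[[jid]]$fixed), order)
  anchor <- if (length(fixed)) net$joints[[fixed[1L]]]$fixed

  score_state <- function(st) {
    coms <- do.call(rbind, st$coms)
    placed <- if (is.null(anchor)) {
      tr <- fit_chain_to_polyline(coms, joints)
      rt_apply(tr, coms)
    } else {
      coms
    }
    list(score = score_fit(placed, guide), placed = placed)
  }

  # initial states
  states <- list()
  if (!is.null(anchor)) {
    w <- anchor$world
    states[[1L]] <- list(
      protos = anchor$proto, worlds = list(w),
      coms = list(world_com(lib, anchor$proto, w)), descs = character(0))
  } else {
    for (proto in solver_start_protos(lib)) {
      states[[length(states) + 1L]] <- list(
        protos = proto, worlds = list(rt_identity()),
        coms = list(lib_module(lib, proto)$com), descs = character(0))
    }
  }
  if (length(states) == 0L) {
    stop_modcad("no compatible start module for the search", "no_solution")
  }

  best <- NULL
  consider <- function(st) {
    sc <- score_state(st)
    key <- paste(st$descs, collapse = " ")
    if (is.null(best) || sc$score < best$score - 1e-12 ||
        (abs(sc$score - best$score) <= 1e-12 && key < best$key)) {
      best <<- list(score = sc$score, state = st, key = key,
                    placed = sc$placed)
    }
    sc$score
  }

  depth <- 1L
  repeat {
    scored <- vapply_num(states, consider)
    if (depth >= max_len) break
    keep <- order(scored,
                  vapply_chr(states, function(s)
                    paste(s$descs, collapse = " ")))
    if (!is.infinite(beam)) keep <- utils::head(keep, beam)
    states <- states[keep]
    nxt <- list()
    for (st in states) {
      last <- st$protos[length(st$protos)]
      for (d in solver_successors(lib, last)) {
        p <- find_pair(lib, last, d)
        w <- rt_compose(st$worlds[[length(st$worlds)]], p$t)
        com <- world_com(lib, d$to_proto, w)
        protos <- c(st$protos, d$to_proto)
        coms <- c(st$coms, list(com))
        if (!chain_feasible(lib, protos, do.call(rbind, coms), f)) next
        nxt[[length(nxt) + 1L]] <- list(
          protos = protos, worlds = c(st$worlds, list(w)), coms = coms,
          descs = c(st$descs, desc_to_string(d)))
      }
    }
    if (length(nxt) == 0L) break
    states <- nxt
    depth <- depth + 1L
  }

  st <- best$state
  worlds <- st$worlds
  if (is.null(anchor)) {
    tr <- fit_chain_to_polyline(do.call(rbind, st$coms), joints)
    worlds <- lapply(worlds, function(w) rt_compose(tr, w))
  }
  chain <- lapply(seq_along(st$protos), function(i) {
    proto <- st$protos[i]
    entry <- list(proto = proto,
                  chain = names(lib_module(lib, proto)$chains)[1L],
                  term = if (i == 1L) NULL else "N",
                  rot = rt_to_json(worlds[[i]])$rot,
                  tran = tran_to_nm(worlds[[i]]$tran))
    entry
  })
  list(name = net$name, chain = chain, score = best$score)
}

#' Save / load a solution JSON
#'
#' Schema: `{"version", "units": "nm", "networks": [{"name", "chain":
#' [{"proto","chain","term","rot","tran"}], "score"}], "meta"}`.
#'
#' @param solution a solution list from [solve_spec()].
#' @param path file path.
#' @export
save_solution <- function(solution, path) {
  write_canonical_json(c(list(version = solution$version, units = "nm"),
                         solution[c("networks", "meta")]), path)
}

#' @rdname save_solution
#' @export
load_solution <- function(path) {
  obj <- read_json_file(path, "solution JSON")
  ver <- require_field(obj, "version", "solution JSON")
  if (!identical(ver, SOLUTION_SCHEMA_VERSION)) {
    stop_modcad(sprintf("unsupported solution schema version '%s'", ver),
                "schema_version")
  }
  # canonicalize numeric shapes so a reloaded solution re-serializes
  # byte-identically
  obj$networks <- lapply(obj$networks, function(net) {
    net$chain <- lapply(net$chain, function(e) {
      e$rot <- lapply(e$rot, function(r) as.numeric(unlist(r)))
      e$tran <- as.numeric(unlist(e$tran))
      e
    })
    net
  })
  obj
}

#' Import a solver solution into a design scene
#'
#' Places and links the solution's module chains as new networks.  Every
#' consecutive pose is verified against the library pair transform; a
#' mismatch above 1e-6 A is an integrity error (tampered or stale file).
#'
#' @param scene a `design_scene`.
#' @param path solution JSON path.
#' @return character vector of new network ids (empty solution imports
#'   nothing without error).
#' @export
import_solution <- function(scene, path) {
  sol <- load_solution(path)
  new_nets <- character(0)
  for (net in sol$networks) {
    prev_id <- NULL
    prev <- NULL
    for (entry in net$chain) {
      proto <- require_field(entry, "proto", "solution entry")
      lib_module(scene$lib, proto)
      world <- rt(do.call(rbind, lapply(entry$rot, function(r)
                    as.numeric(unlist(r)))),
                  tran_to_ang(require_field(entry, "tran",
                                            "solution entry")))
      if (!is.null(prev)) {
        p <- find_pair(scene$lib, prev$proto,
                       desc(prev$chain, "C", "N", entry$chain, proto))
        if (is.null(p)) {
          stop_modcad(sprintf("solution step %s -> %s has no library pair",
                              prev$proto, proto), "integrity")
        }
        expected <- rt_compose(prev$world, p$t)
        if (max(abs(expected$rot - world$rot)) > 1e-6 ||
            max(abs(expected$tran - world$tran)) > 1e-6) {
          stop_modcad(sprintf(
            "solution transform for '%s' disagrees with pair transform",
            proto), "integrity")
        }
        if (scene$config$auto_collision) {
          v <- check_collision(scene, proto, world, exempt = prev_id)
          if (v$collision) {
            stop_modcad(sprintf("imported module '%s' collides with '%s'",
                                proto, v$with), "collision")
          }
        }
        auto <- scene$config$auto_collision
        scene$config$auto_collision <- FALSE
        id <- place_module(scene, proto, world)
        scene$config$auto_collision <- auto
        record_link(scene,
                    list(instance = prev_id, chain = prev$chain,
                         term = "C"),
                    list(instance = id, chain = entry$chain, term = "N"),
                    p$index)
        merge_networks(scene, module_network_id(scene, prev_id),
                       paste0("net:", id))
      } else {
        id <- place_module(scene, proto, world)
      }
      prev <- list(proto = proto, chain = entry$chain, world = world)
      prev_id <- id
    }
    if (!is.null(prev_id)) {
      new_nets <- c(new_nets, module_network_id(scene, prev_id))
    }
  }
  new_nets
}
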