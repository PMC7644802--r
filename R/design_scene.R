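# The editable design scene.
#
# A scene is a mutable container (environment-backed, so operations update
# it in place like a structure editor) holding placed module instances,
# links between termini, mirror groups, network bookkeeping and an
# embedded path guide.  Placed modules are immutable in pose once linked;
# only whole networks move, which preserves every precomputed interface.
#
# Networks are maintained incrementally (created on placement, merged on
# linking, recomputed on deletion) and must always equal the connected
# components of the link graph -- tests enforce this against a
# from-scratch recomputation.

#' Create an empty design scene
#'
#' @param lib a `module_library`.
#' @param collision_factor overlap factor `f` of the sphere clash test:
#'   two modules collide when their center distance is below
#'   `f * (r1 + r2)`.  Default 0.75, so the necessarily-overlapping
#'   bounding spheres of bonded neighbors do not trip the check;
#'   must lie in (0, 1.5].
#' @param auto_collision check for clashes on every placement (default
#'   `TRUE`); when off, violations are only reported by
#'   [validate_scene()].
#' @return an object of class `design_scene`.
#' @export
design_scene <- function(lib, collision_factor = 0.75,
                         auto_collision = TRUE) {
  if (!inherits(lib, "module_library")) {
    stop_modcad("design_scene needs a module_library", "invalid_library")
  }
  if (collision_factor <= 0 || collision_factor > 1.5) {
    stop_modcad("collision_factor must be in (0, 1.5]", "invalid_config")
  }
  sc <- new.env(parent = emptyenv())
  sc$lib <- lib
  sc$modules <- list()        # id -> instance record
  sc$links <- list()          # link id -> link record
  sc$networks <- list()       # network id -> character vector of instances
  sc$mirror_groups <- list()  # group id -> list of (instance, chain)
  sc$guide <- path_guide()
  sc$counters <- list(link = 0L, mirror = 0L)
  sc$config <- list(collision_factor = collision_factor,
                    auto_collision = auto_collision)
  class(sc) <- "design_scene"
  sc
}

#' @export
print.design_scene <- function(x, ...) {
  cat(sprintf(paste0("<design_scene> %d modules, %d links, %d networks, ",
                     "%d mirror groups, %d joints\n"),
              length(x$modules), length(x$links), length(x$networks),
              length(x$mirror_groups), length(x$guide$joints)))
  invisible(x)
}

#' Toggle automatic collision checking
#' @param scene a `design_scene`.
#' @param on logical.
#' @export
set_auto_collision <- function(scene, on) {
  scene$config$auto_collision <- isTRUE(on)
  invisible(scene)
}

scene_module <- function(scene, id) {
  m <- scene$modules[[id]]
  if (is.null(m)) {
    stop_modcad(sprintf("unknown instance '%s'", id), "unknown_instance")
  }
  m
}

occ_key <- function(chain, term) paste0(chain, "|", term)

# lowest unused NNN suffix for a prototype, starting at 001
next_instance_id <- function(scene, proto) {
  used <- grep(paste0("^", proto, "\\.[0-9]{3}$"), names(scene$modules),
               value = TRUE)
  nums <- as.integer(sub(".*\\.", "", used))
  n <- 1L
  while (n %in% nums) n <- n + 1L
  sprintf("%s.%03d", proto, n)
}

module_network_id <- function(scene, id) {
  for (nid in names(scene$networks)) {
    if (id %in% scene$networks[[nid]]) return(nid)
  }
  stop_modcad(sprintf("instance '%s' belongs to no network", id),
              "internal")
}

# world-space center of mass of a placed or candidate module
world_com <- function(lib, proto, world) {
  rt_apply(world, lib_module(lib, proto)$com)
}

#' Sphere-based collision check
#'
#' Pure predicate: a candidate pose collides when some non-exempt placed
#' module's center lies closer than `f * (r_candidate + r_other)`.
#' Directly linked neighbors of the exempt instances are not implied --
#' pass every instance that should be ignored via `exempt`.
#'
#' @param scene a `design_scene`.
#' @param proto candidate prototype name.
#' @param world candidate pose (`rigid_transform`).
#' @param exempt character vector of instance ids to ignore.
#' @param factor overlap factor; defaults to the scene's configured value.
#' @return list with `collision` (logical) and `with` (offending instance
#'   id, or `NULL`).
#' @export
check_collision <- function(scene, proto, world, exempt = character(0),
                            factor = scene$config$collision_factor) {
  cand <- lib_module(scene$lib, proto)
  com <- rt_apply(world, cand$com)
  for (id in names(scene$modules)) {
    if (id %in% exempt) next
    other <- scene$modules[[id]]
    om <- lib_module(scene$lib, other$proto)
    ocom <- rt_apply(other$world, om$com)
    if (sqrt(sum((com - ocom)^2)) < factor * (cand$radius + om$radius)) {
      return(list(collision = TRUE, with = id))
    }
  }
  list(collision = FALSE, with = NULL)
}

#' Place a module instance in the scene
#'
#' @param scene a `design_scene`.
#' @param proto prototype name (caps cannot be placed interactively).
#' @param world pose of the instance (`rigid_transform`).
#' @param color optional display tag.
#' @return the new instance id, `"<proto>.NNN"` with the lowest unused
#'   3-digit suffix.  Placing a symmetric hub automatically mirror-links
#'   its chains.
#' @export
place_module <- function(scene, proto, world = rt_identity(),
                         color = NULL) {
  m <- lib_module(scene$lib, proto)
  if (m$cls == "cap") {
    stop_modcad(sprintf(
      "cap '%s' cannot be placed interactively; caps are added at stitch time",
      proto), "cap_placement")
  }
  assert_rotation(world$rot)
  if (scene$config$auto_collision) {
    v <- check_collision(scene, proto, world)
    if (v$collision) {
      stop_modcad(sprintf("placing '%s' collides with '%s'", proto, v$with),
                  "collision", candidate = proto, with = v$with)
    }
  }
  id <- next_instance_id(scene, proto)
  occ <- list()
  for (ch in m$chains) {
    occ[[occ_key(ch$chain_id, "N")]] <-
      if (isTRUE(ch$n_extendable)) "free" else "sealed"
    occ[[occ_key(ch$chain_id, "C")]] <-
      if (isTRUE(ch$c_extendable)) "free" else "sealed"
  }
  scene$modules[[id]] <- list(id = id, proto = proto, world = world,
                              occupancy = occ, color = color)
  scene$networks[[paste0("net:", id)]] <- id
  if (m$cls == "hub" && !is.null(m$symmetry) && length(m$chains) >= 2L) {
    add_mirror_group(scene, lapply(names(m$chains), function(ch) {
      list(instance = id, chain = ch)
    }))
  }
  id
}

add_mirror_group <- function(scene, members) {
  scene$counters$mirror <- scene$counters$mirror + 1L
  gid <- sprintf("mirror.%03d", scene$counters$mirror)
  scene$mirror_groups[[gid]] <- members
  gid
}

# mirror group id containing the exact member (instance, chain), or NULL
find_mirror_group <- function(scene, instance, chain) {
  for (gid in names(scene$mirror_groups)) {
    for (mb in scene$mirror_groups[[gid]]) {
      if (mb$instance == instance && mb$chain == chain) return(gid)
    }
  }
  NULL
}

#' Mirror-link identical module instances
#'
#' Groups two or more instances of the same prototype so that an extrusion
#' from one is applied to all members, enabling symmetric growth.
#'
#' @param scene a `design_scene`.
#' @param instance_ids character vector, length >= 2, all same prototype.
#' @return the new mirror group id.
#' @export
link_by_mirror <- function(scene, instance_ids) {
  if (length(instance_ids) < 2L) {
    stop_modcad("mirror linking needs at least 2 instances",
                "mirror_singleton")
  }
  protos <- vapply_chr(instance_ids,
                       function(id) scene_module(scene, id)$proto)
  if (length(unique(protos)) != 1L) {
    stop_modcad("mirror-linked modules must be of the same prototype",
                "mirror_type_mismatch")
  }
  chains <- names(lib_module(scene$lib, protos[1L])$chains)
  members <- list()
  for (id in instance_ids) {
    for (ch in chains) {
      if (!is.null(find_mirror_group(scene, id, ch))) {
        stop_modcad(sprintf("instance '%s' is already mirror-linked", id),
                    "mirror_conflict")
      }
      members[[length(members) + 1L]] <- list(instance = id, chain = ch)
    }
  }
  add_mirror_group(scene, members)
}

#' Remove a mirror linkage
#'
#' Members keep their poses; only the group membership is dropped.
#'
#' @param scene a `design_scene`.
#' @param group_id mirror group id.
#' @export
unlink_mirror <- function(scene, group_id) {
  if (is.null(scene$mirror_groups[[group_id]])) {
    stop_modcad(sprintf("unknown mirror group '%s'", group_id),
                "unknown_mirror_group")
  }
  scene$mirror_groups[[group_id]] <- NULL
  invisible(scene)
}

# occupancy state of one terminus; errors if the terminus does not exist
term_state <- function(scene, instance, chain, term) {
  m <- scene_module(scene, instance)
  lib_chain(scene$lib, m$proto, chain)
  if (!term %in% c("N", "C")) {
    stop_modcad(sprintf("unknown terminus '%s'", term), "unknown_terminus")
  }
  m$occupancy[[occ_key(chain, term)]]
}

record_link <- function(scene, a, b, pair_index) {
  scene$counters$link <- scene$counters$link + 1L
  lid <- sprintf("link.%05d", scene$counters$link)
  scene$links[[lid]] <- list(a = a, b = b, pair_index = pair_index)
  for (end in list(a, b)) {
    scene$modules[[end$instance]]$occupancy[[
      occ_key(end$chain, end$term)]] <- lid
  }
  lid
}

merge_networks <- function(scene, keep_id, drop_id) {
  if (keep_id == drop_id) return(keep_id)
  scene$networks[[keep_id]] <- sort(unique(c(scene$networks[[keep_id]],
                                             scene$networks[[drop_id]])))
  scene$networks[[drop_id]] <- NULL
  keep_id
}

#' Extrude a compatible module from a free terminus
#'
#' Places a new module bonded to `from_instance` at the pose dictated by
#' the library pair transform, records the link, and merges networks.  If
#' the source terminus belongs to a mirror group, the same extrusion is
#' applied to every member and the children form a new mirror group; the
#' operation is atomic -- if any copy fails (occupied terminus or clash),
#' nothing changes.
#'
#' @param scene a `design_scene`.
#' @param from_instance source instance id.
#' @param descriptor an extrusion descriptor (list or string, see
#'   [desc_to_string()]); must be one of the source terminus'
#'   [compatible_successors()].
#' @return character vector of new instance ids (one per mirror member).
#' @export
extrude <- function(scene, from_instance, descriptor) {
  d <- if (is.character(descriptor)) desc_from_string(descriptor)
       else descriptor
  src <- scene_module(scene, from_instance)
  gid <- find_mirror_group(scene, from_instance, d$from_chain)
  members <- if (is.null(gid)) {
    list(list(instance = from_instance, chain = d$from_chain))
  } else {
    scene$mirror_groups[[gid]]
  }

  # plan all placements before touching state (atomic mirror extrusion)
  plans <- lapply(members, function(mb) {
    inst <- scene_module(scene, mb$instance)
    md <- desc(mb$chain, d$from_term, d$to_term, d$to_chain, d$to_proto)
    state <- term_state(scene, mb$instance, mb$chain, md$from_term)
    if (!identical(state, "free")) {
      stop_modcad(sprintf("terminus %s:%s(%s) is not free (%s)",
                          mb$instance, mb$chain, md$from_term, state),
                  "occupied_terminus")
    }
    ok <- any(vapply(
      compatible_successors(scene$lib, inst$proto, mb$chain, md$from_term),
      function(s) identical(desc_to_string(s), desc_to_string(md)),
      logical(1)))
    p <- find_pair(scene$lib, inst$proto, md)
    if (!ok || is.null(p)) {
      stop_modcad(sprintf("descriptor '%s' is not compatible with %s:%s(%s)",
                          desc_to_string(md), mb$instance, mb$chain,
                          md$from_term), "incompatible_descriptor")
    }
    world <- if (md$from_term == "C") rt_compose(inst$world, p$t)
             else rt_compose(inst$world, rt_invert(p$t))
    list(member = mb, d = md, pair = p, world = world)
  })

  if (scene$config$auto_collision) {
    for (i in seq_along(plans)) {
      pl <- plans[[i]]
      v <- check_collision(scene, pl$d$to_proto, pl$world,
                           exempt = pl$member$instance)
      if (v$collision) {
        stop_modcad(sprintf("extrusion of '%s' collides with '%s'",
                            pl$d$to_proto, v$with), "collision")
      }
      for (j in seq_along(plans)) {      # pending siblings clash check
        if (j == i) next
        sib <- plans[[j]]
        c1 <- world_com(scene$lib, pl$d$to_proto, pl$world)
        c2 <- world_com(scene$lib, sib$d$to_proto, sib$world)
        r1 <- lib_module(scene$lib, pl$d$to_proto)$radius
        r2 <- lib_module(scene$lib, sib$d$to_proto)$radius
        if (sqrt(sum((c1 - c2)^2)) <
            scene$config$collision_factor * (r1 + r2)) {
          stop_modcad("mirror extrusion children collide with each other",
                      "collision")
        }
      }
    }
  }

  new_ids <- character(length(plans))
  for (i in seq_along(plans)) {
    pl <- plans[[i]]
    id <- next_instance_id(scene, pl$d$to_proto)
    new_ids[i] <- id
    m <- lib_module(scene$lib, pl$d$to_proto)
    occ <- list()
    for (ch in m$chains) {
      occ[[occ_key(ch$chain_id, "N")]] <-
        if (isTRUE(ch$n_extendable)) "free" else "sealed"
      occ[[occ_key(ch$chain_id, "C")]] <-
        if (isTRUE(ch$c_extendable)) "free" else "sealed"
    }
    scene$modules[[id]] <- list(id = id, proto = pl$d$to_proto,
                                world = pl$world, occupancy = occ,
                                color = NULL)
    scene$networks[[paste0("net:", id)]] <- id
    record_link(scene,
                list(instance = pl$member$instance, chain = pl$member$chain,
                     term = pl$d$from_term),
                list(instance = id, chain = pl$d$to_chain,
                     term = pl$d$to_term),
                pl$pair$index)
    merge_networks(scene, module_network_id(scene, pl$member$instance),
                   paste0("net:", id))
  }
  if (length(new_ids) > 1L) {
    chains0 <- names(lib_module(scene$lib, plans[[1L]]$d$to_proto)$chains)
    add_mirror_group(scene, unlist(lapply(new_ids, function(id) {
      lapply(chains0, function(ch) list(instance = id, chain = ch))
    }), recursive = FALSE))
  }
  new_ids
}

#' Join two networks through a compatible pair of free termini
#'
#' Rigidly moves the whole network of `b` so that the library pair
#' transform between the two termini is satisfied, then links them and
#' merges the networks.  The first-selected network (`a`'s) stays put.
#'
#' @param scene a `design_scene`.
#' @param a,b lists with fields `instance`, `chain`, `term`; the two
#'   termini must be free, in different networks, and compatible (one
#'   `"C"`, one `"N"` with a matching pair transform).
#' @return the merged network id.
#' @export
join_networks <- function(scene, a, b) {
  for (end in list(a, b)) {
    st <- term_state(scene, end$instance, end$chain, end$term)
    if (!identical(st, "free")) {
      stop_modcad(sprintf("terminus %s:%s(%s) is not free",
                          end$instance, end$chain, end$term),
                  "occupied_terminus")
    }
  }
  net_a <- module_network_id(scene, a$instance)
  net_b <- module_network_id(scene, b$instance)
  if (net_a == net_b) {
    stop_modcad("termini are already in the same network", "same_network")
  }
  ma <- scene_module(scene, a$instance)
  mb <- scene_module(scene, b$instance)
  if (a$term == b$term) {
    stop_modcad("cannot join two termini of the same kind",
                "incompatible_pair")
  }
  cend <- if (a$term == "C") a else b
  nend <- if (a$term == "C") b else a
  cmod <- scene_module(scene, cend$instance)
  nmod <- scene_module(scene, nend$instance)
  p <- find_pair(scene$lib, cmod$proto,
                 desc(cend$chain, "C", "N", nend$chain, nmod$proto))
  if (is.null(p)) {
    stop_modcad(sprintf("no pair transform bonds %s:%s(C) to %s:%s(N)",
                        cmod$proto, cend$chain, nmod$proto, nend$chain),
                "incompatible_pair")
  }
  # desired pose of the bonded module on b's side, keeping a's network fixed
  target <- if (identical(cend$instance, a$instance)) {
    rt_compose(ma$world, p$t)                      # b holds the N side
  } else {
    rt_compose(ma$world, rt_invert(p$t))           # b holds the C side
  }
  mover <- rt_compose(target, rt_invert(mb$world))
  moved <- lapply(scene$networks[[net_b]], function(id) {
    rt_compose(mover, scene$modules[[id]]$world)
  })
  names(moved) <- scene$networks[[net_b]]
  if (scene$config$auto_collision) {
    for (id in names(moved)) {
      exempt <- c(scene$networks[[net_b]],
                  if (id == b$instance) a$instance)
      v <- check_collision(scene, scene$modules[[id]]$proto, moved[[id]],
                           exempt = exempt)
      if (v$collision) {
        stop_modcad(sprintf("joining networks would collide '%s' with '%s'",
                            id, v$with), "collision")
      }
    }
  }
  for (id in names(moved)) scene$modules[[id]]$world <- moved[[id]]
  guide_follow_instances(scene, names(moved))
  record_link(scene,
              list(instance = cend$instance, chain = cend$chain, term = "C"),
              list(instance = nend$instance, chain = nend$chain, term = "N"),
              p$index)
  merge_networks(scene, net_a, net_b)
}

#' Delete a module instance
#'
#' Removes the instance, its links and mirror memberships, frees partner
#' termini, and splits its network into the remaining connected
#' components.
#'
#' @param scene a `design_scene`.
#' @param instance_id instance to delete.
#' @export
delete_instance <- function(scene, instance_id) {
  scene_module(scene, instance_id)
  nid <- module_network_id(scene, instance_id)
  for (lid in names(scene$links)) {
    l <- scene$links[[lid]]
    hit <- l$a$instance == instance_id || l$b$instance == instance_id
    if (!hit) next
    for (end in list(l$a, l$b)) {
      if (end$instance == instance_id) next
      scene$modules[[end$instance]]$occupancy[[
        occ_key(end$chain, end$term)]] <- "free"
    }
    scene$links[[lid]] <- NULL
  }
  for (gid in names(scene$mirror_groups)) {
    mem <- Filter(function(mb) mb$instance != instance_id,
                  scene$mirror_groups[[gid]])
    if (length(mem) < 2L) scene$mirror_groups[[gid]] <- NULL
    else scene$mirror_groups[[gid]] <- mem
  }
  for (jid in names(scene$guide$joints)) {
    att <- scene$guide$joints[[jid]]$attached
    if (!is.null(att) && att$instance == instance_id) {
      scene$guide$joints[[jid]]$attached <- NULL
    }
  }
  scene$modules[[instance_id]] <- NULL
  remaining <- setdiff(scene$networks[[nid]], instance_id)
  scene$networks[[nid]] <- NULL
  for (comp in link_components(remaining, scene$links)) {
    scene$networks[[paste0("net:", min(comp))]] <- sort(comp)
  }
  invisible(scene)
}

# connected components of the link graph restricted to `ids`
link_components <- function(ids, links) {
  if (length(ids) == 0L) return(list())
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (l in links) {
    ia <- l$a$instance
    ib <- l$b$instance
    if (ia %in% ids && ib %in% ids) {
      adj[[ia]] <- c(adj[[ia]], ib)
      adj[[ib]] <- c(adj[[ib]], ia)
    }
  }
  seen <- character(0)
  comps <- list()
  for (id in sort(ids)) {
    if (id %in% seen) next
    stack <- id
    comp <- character(0)
    while (length(stack)) {
      cur <- stack[[1L]]
      stack <- stack[-1L]
      if (cur %in% comp) next
      comp <- c(comp, cur)
      stack <- c(stack, setdiff(adj[[cur]], comp))
    }
    comp <- sort(comp)
    seen <- c(seen, comp)
    comps[[length(comps) + 1L]] <- comp
  }
  comps
}

#' Rigidly transform a whole network
#'
#' Pre-multiplies every member pose by `t`; relative transforms inside the
#' network are unchanged.  Attached guide joints follow their modules.
#'
#' @param scene a `design_scene`.
#' @param network_id network id.
#' @param t a `rigid_transform`.
#' @export
transform_network <- function(scene, network_id, t) {
  members <- scene$networks[[network_id]]
  if (is.null(members)) {
    stop_modcad(sprintf("unknown network '%s'", network_id),
                "unknown_network")
  }
  assert_rotation(t$rot)
  moved <- lapply(members, function(id) {
    rt_compose(t, scene$modules[[id]]$world)
  })
  names(moved) <- members
  if (scene$config$auto_collision) {
    for (id in members) {
      v <- check_collision(scene, scene$modules[[id]]$proto, moved[[id]],
                           exempt = members)
      if (v$collision) {
        stop_modcad(sprintf("transforming network would collide '%s' with '%s'",
                            id, v$with), "collision")
      }
    }
  }
  for (id in members) scene$modules[[id]]$world <- moved[[id]]
  guide_follow_instances(scene, members)
  invisible(scene)
}

#' Validate a scene's structural invariants
#'
#' Recomputes networks from scratch, scans all module pairs for sphere
#' collisions (directly linked neighbors exempt) and checks occupancy
#' bookkeeping.  Returns a list of findings; empty means valid.
#'
#' @param scene a `design_scene`.
#' @return list of findings, each a list with a `kind` field.
#' @export
validate_scene <- function(scene) {
  findings <- list()
  note <- function(...) findings[[length(findings) + 1L]] <<- list(...)
  comps <- link_components(names(scene$modules), scene$links)
  held <- lapply(scene$networks, sort)
  if (!setequal(vapply_chr(comps, function(x) paste(x, collapse = ",")),
                vapply_chr(held, function(x) paste(x, collapse = ",")))) {
    note(kind = "network_partition",
         message = "networks do not match link-graph components")
  }
  linked <- linked_instance_pairs(scene)
  ids <- names(scene$modules)
  f <- scene$config$collision_factor
  if (length(ids) > 1L) {
    for (i in seq_along(ids)[-length(ids)]) {
      for (j in seq((i + 1L), length(ids))) {
        if (paste(sort(c(ids[i], ids[j])), collapse = "|") %in% linked) next
        a <- scene$modules[[ids[i]]]
        b <- scene$modules[[ids[j]]]
        ra <- lib_module(scene$lib, a$proto)$radius
        rb <- lib_module(scene$lib, b$proto)$radius
        d <- sqrt(sum((world_com(scene$lib, a$proto, a$world) -
                         world_com(scene$lib, b$proto, b$world))^2))
        if (d < f * (ra + rb)) {
          note(kind = "collision", a = ids[i], b = ids[j], distance = d)
        }
      }
    }
  }
  n_occ <- 0L
  for (m in scene$modules) {
    for (st in m$occupancy) if (grepl("^link\\.", st)) n_occ <- n_occ + 1L
  }
  if (n_occ != 2L * length(scene$links)) {
    note(kind = "occupancy",
         message = sprintf("%d occupied termini != 2 x %d links",
                           n_occ, length(scene$links)))
  }
  findings
}

linked_instance_pairs <- function(scene) {
  vapply_chr(scene$links, function(l) {
    paste(sort(c(l$a$instance, l$b$instance)), collapse = "|")
  })
}
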