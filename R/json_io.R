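# Design / guide / solver-spec JSON.
#
# File-boundary unit convention: guide and design JSON store coordinates
# in nm (the design-space convention, 1 grid square = 1 nm); everything
# internal and every atomic file is Angstrom.  Conversion factor 10 is
# applied on read/write, and every file declares its units.

DESIGN_SCHEMA_VERSION <- "modcad-design/1"
SPEC_SCHEMA_VERSION <- "modcad-spec/1"

tran_to_nm <- function(v) as.numeric(v) * NM_PER_ANGSTROM
tran_to_ang <- function(v) as.numeric(unlist(v)) / NM_PER_ANGSTROM

joint_json <- function(g, jid, fixed_info = NULL) {
  j <- g$joints[[jid]]
  out <- list(id = jid, xyz = tran_to_nm(j$pos))
  if (!is.null(fixed_info)) out$fixed <- fixed_info
  out
}

pg_networks_json <- function(g, fixed_fn = function(jid) NULL) {
  comps <- pg_components(g)
  lapply(names(comps), function(nid) {
    members <- comps[[nid]]
    bridges <- Filter(function(br) br[1L] %in% members, g$bridges)
    bridges <- bridges[order(vapply_chr(bridges, function(br)
      paste(br, collapse = "|")))]
    list(name = nid,
         joints = lapply(members, function(jid)
           joint_json(g, jid, fixed_fn(jid))),
         bridges = lapply(bridges, as.list))
  })
}

#' Export a design scene as JSON
#'
#' Writes networks of placed modules (poses in nm, links, colors), the
#' embedded path guide (`pg_networks`) and mirror groups.  Field order and
#' element order are canonical, so export -> import -> export is
#' byte-identical.
#'
#' @param scene a `design_scene`.
#' @param path output path.
#' @export
export_design <- function(scene, path) {
  g <- scene$guide
  # canonical network naming (lowest member id) so re-exports are stable
  comps <- link_components(names(scene$modules), scene$links)
  comps <- stats::setNames(comps, vapply_chr(comps, function(cc)
    paste0("net:", min(cc))))
  nets <- lapply(sort(names(comps)), function(nid) {
    members <- sort(comps[[nid]])
    list(name = nid, modules = lapply(members, function(id) {
      m <- scene$modules[[id]]
      links <- list()
      for (lid in sort(names(scene$links))) {
        l <- scene$links[[lid]]
        ends <- if (l$a$instance == id) list(l$a, l$b)
                else if (l$b$instance == id) list(l$b, l$a)
                else NULL
        if (is.null(ends)) next
        links[[length(links) + 1L]] <- list(
          chain = ends[[1L]]$chain, term = ends[[1L]]$term,
          to_id = ends[[2L]]$instance, to_chain = ends[[2L]]$chain,
          to_term = ends[[2L]]$term)
      }
      keyf <- vapply_chr(links, function(l) paste(l$chain, l$term))
      out <- list(id = id, proto = m$proto,
                  rot = rt_to_json(m$world)$rot,
                  tran = tran_to_nm(m$world$tran),
                  links = links[order(keyf)])
      if (!is.null(m$color)) out$color <- m$color
      out
    }))
  })
  att_json <- function(jid) NULL
  pg <- pg_networks_json(g)
  # attachments ride on joints in the design file
  pg <- lapply(pg, function(net) {
    net$joints <- lapply(net$joints, function(j) {
      att <- g$joints[[j$id]]$attached
      j$attached <- if (is.null(att)) NULL else {
        a <- list(instance = att$instance)
        if (!is.null(att$chain)) a$chain <- att$chain
        if (!is.null(att$term)) a$term <- att$term
        a
      }
      j
    })
    net
  })
  mirrors <- lapply(sort(names(scene$mirror_groups)), function(gid) {
    mem <- scene$mirror_groups[[gid]]
    key <- vapply_chr(mem, function(mb) paste(mb$instance, mb$chain))
    list(id = gid, members = lapply(mem[order(key)], function(mb) {
      list(instance = mb$instance, chain = mb$chain)
    }))
  })
  write_canonical_json(list(
    version = DESIGN_SCHEMA_VERSION, units = "nm",
    networks = nets, pg_networks = pg, mirror_groups = mirrors), path)
}

#' Import a design scene from JSON
#'
#' Rebuilds the scene written by [export_design()]; collision checking is
#' left to [validate_scene()] so that imports never silently mutate data.
#'
#' @param path design JSON path.
#' @param lib the `module_library` the design references.
#' @param collision_factor,auto_collision see [design_scene()].
#' @return a `design_scene`.
#' @export
import_design <- function(path, lib, collision_factor = 0.75,
                          auto_collision = TRUE) {
  obj <- read_json_file(path, "design JSON")
  ver <- require_field(obj, "version", "design JSON")
  if (!identical(ver, DESIGN_SCHEMA_VERSION)) {
    stop_modcad(sprintf("unsupported design schema version '%s'", ver),
                "schema_version")
  }
  if (!identical(obj$units, "nm")) {
    stop_modcad("design JSON must declare units 'nm' (field 'units')",
                "schema")
  }
  scene <- design_scene(lib, collision_factor = collision_factor,
                        auto_collision = FALSE)
  links_seen <- character(0)
  pending <- list()
  for (net in obj$networks) {
    for (mj in net$modules) {
      id <- require_field(mj, "id", "design module")
      proto <- require_field(mj, "proto", "design module")
      m <- lib_module(lib, proto)
      world <- rt(do.call(rbind, lapply(mj$rot, function(r)
                    as.numeric(unlist(r)))),
                  tran_to_ang(require_field(mj, "tran", "design module")))
      occ <- list()
      for (ch in m$chains) {
        occ[[occ_key(ch$chain_id, "N")]] <-
          if (isTRUE(ch$n_extendable)) "free" else "sealed"
        occ[[occ_key(ch$chain_id, "C")]] <-
          if (isTRUE(ch$c_extendable)) "free" else "sealed"
      }
      scene$modules[[id]] <- list(id = id, proto = proto, world = world,
                                  occupancy = occ, color = mj$color)
      for (lj in mj$links) {
        a <- list(instance = id, chain = lj$chain, term = lj$term)
        b <- list(instance = lj$to_id, chain = lj$to_chain,
                  term = lj$to_term)
        key <- paste(sort(c(paste(a$instance, a$chain, a$term),
                            paste(b$instance, b$chain, b$term))),
                     collapse = "<->")
        if (key %in% links_seen) next
        links_seen <- c(links_seen, key)
        pending[[length(pending) + 1L]] <- list(a = a, b = b)
      }
    }
  }
  for (pl in pending) {
    cend <- if (pl$a$term == "C") pl$a else pl$b
    nend <- if (pl$a$term == "C") pl$b else pl$a
    cmod <- scene_module(scene, cend$instance)
    nmod <- scene_module(scene, nend$instance)
    p <- find_pair(lib, cmod$proto,
                   desc(cend$chain, "C", "N", nend$chain, nmod$proto))
    if (is.null(p)) {
      stop_modcad(sprintf(
        "design link %s:%s(C) -> %s:%s(N) has no library pair",
        cmod$proto, cend$chain, nmod$proto, nend$chain), "schema")
    }
    record_link(scene, cend, nend, p$index)
  }
  scene$networks <- list()
  for (comp in link_components(names(scene$modules), scene$links)) {
    scene$networks[[paste0("net:", min(comp))]] <- sort(comp)
  }
  for (net in obj$pg_networks) {
    for (jj in net$joints) {
      jid <- require_field(jj, "id", "design joint")
      att <- jj$attached
      scene$guide$joints[[jid]] <- list(
        pos = tran_to_ang(require_field(jj, "xyz", "design joint")),
        attached = if (is.null(att)) NULL else
          list(instance = require_field(att, "instance", "joint attachment"),
               chain = att$chain, term = att$term))
    }
    for (br in net$bridges) {
      scene$guide$bridges[[length(scene$guide$bridges) + 1L]] <-
        sort(as.character(unlist(br)))
    }
  }
  for (mg in obj$mirror_groups) {
    scene$mirror_groups[[require_field(mg, "id", "mirror group")]] <-
      lapply(mg$members, function(mb) {
        list(instance = mb$instance, chain = mb$chain)
      })
    n <- suppressWarnings(as.integer(sub("^mirror\\.", "", mg$id)))
    if (!is.na(n)) {
      scene$counters$mirror <- max(scene$counters$mirror, n)
    }
  }
  scene$config$auto_collision <- auto_collision
  scene
}

#' Export a solver spec from a scene's path guide
#'
#' Refuses to export when [validate_partial()] reports findings.  The spec
#' holds the pg-networks (joint coordinates in nm, bridges) and, for
#' joints pinned to placed modules, fixed-module constraints with the full
#' module pose.
#'
#' @param scene a `design_scene`.
#' @param path output path.
#' @export
export_solver_spec <- function(scene, path) {
  findings <- validate_partial(scene)
  if (length(findings)) {
    stop_modcad(sprintf(
      "refusing to export solver spec: %d validation finding(s), first: %s",
      length(findings), findings[[1L]]$kind), "validation",
      findings = findings)
  }
  g <- scene$guide
  fixed_fn <- function(jid) {
    att <- g$joints[[jid]]$attached
    if (is.null(att)) return(NULL)
    m <- scene_module(scene, att$instance)
    out <- list(proto = m$proto, rot = rt_to_json(m$world)$rot,
                tran = tran_to_nm(m$world$tran))
    if (!is.null(att$chain)) out$chain <- att$chain
    if (!is.null(att$term)) out$term <- att$term
    out
  }
  write_canonical_json(list(
    version = SPEC_SCHEMA_VERSION, units = "nm",
    pg_networks = pg_networks_json(g, fixed_fn)), path)
}

#' Read a solver spec
#'
#' @param path spec JSON path.
#' @return parsed spec: list of pg-networks with joints (positions in
#'   Angstrom), bridges, and fixed constraints.
#' @export
read_solver_spec <- function(path) {
  obj <- read_json_file(path, "solver spec")
  ver <- require_field(obj, "version", "solver spec")
  if (!identical(ver, SPEC_SCHEMA_VERSION)) {
    stop_modcad(sprintf("unsupported spec schema version '%s'", ver),
                "schema_version")
  }
  if (!identical(obj$units, "nm")) {
    stop_modcad("solver spec must declare units 'nm'", "schema")
  }
  nets <- lapply(obj$pg_networks, function(net) {
    joints <- lapply(net$joints, function(jj) {
      fixed <- jj$fixed
      list(id = require_field(jj, "id", "spec joint"),
           pos = tran_to_ang(require_field(jj, "xyz", "spec joint")),
           fixed = if (is.null(fixed)) NULL else list(
             proto = require_field(fixed, "proto", "fixed constraint"),
             world = rt(do.call(rbind, lapply(fixed$rot, function(r)
                          as.numeric(unlist(r)))),
                        tran_to_ang(fixed$tran)),
             chain = fixed$chain, term = fixed$term))
    })
    names(joints) <- vapply_chr(joints, function(j) j$id)
    list(name = net$name,
         joints = joints,
         bridges = lapply(net$bridges,
                          function(br) sort(as.character(unlist(br)))))
  })
  list(version = ver, pg_networks = nets)
}

# guide object from a parsed spec network (for scoring)
spec_net_guide <- function(net) {
  g <- path_guide()
  for (jid in names(net$joints)) {
    g$joints[[jid]] <- list(pos = net$joints[[jid]]$pos, attached = NULL)
  }
  g$bridges <- net$bridges
  g
}
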