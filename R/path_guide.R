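# Path guides: geometry-only graphs of joints (nodes) and bridges (edges)
# that describe a target shape for the automated solver.  Joints are freely
# movable, unlike modules; a joint may be pinned to a placed module
# ("hybrid design"), in which case the bridges at that joint become
# extrusion intents and the module contributes a full pose constraint.

#' Create an empty path guide
#'
#' Guides are mutable (environment-backed) like scenes; a `design_scene`
#' embeds one as `scene$guide`, and every guide operation accepts either a
#' guide or a scene.  All positions are Angstrom internally (files use nm).
#'
#' @return an object of class `path_guide`.
#' @export
path_guide <- function() {
  g <- new.env(parent = emptyenv())
  g$joints <- list()    # id -> list(pos, attached)
  g$bridges <- list()   # list of sorted id pairs
  class(g) <- "path_guide"
  g
}

#' @export
print.path_guide <- function(x, ...) {
  cat(sprintf("<path_guide> %d joints, %d bridges, %d components\n",
              length(x$joints), length(x$bridges),
              length(pg_components(x))))
  invisible(x)
}

as_guide <- function(x) {
  if (inherits(x, "design_scene")) x$guide
  else if (inherits(x, "path_guide")) x
  else stop_modcad("expected a path_guide or design_scene", "invalid_guide")
}

guide_joint <- function(g, id) {
  j <- g$joints[[id]]
  if (is.null(j)) {
    stop_modcad(sprintf("unknown joint '%s'", id), "unknown_joint")
  }
  j
}

next_joint_id <- function(g) {
  nums <- as.integer(sub("^joint\\.", "",
                         grep("^joint\\.[0-9]+$", names(g$joints),
                              value = TRUE)))
  n <- 1L
  while (n %in% nums) n <- n + 1L
  sprintf("joint.%03d", n)
}

check_position <- function(pos) {
  pos <- as.numeric(pos)
  if (length(pos) != 3L || any(!is.finite(pos))) {
    stop_modcad("joint position must be a finite 3-vector", "bad_position")
  }
  pos
}

#' Add an isolated joint
#'
#' @param guide a `path_guide` or `design_scene`.
#' @param position 3-vector, Angstrom.
#' @return the new joint id.
#' @export
add_joint <- function(guide, position) {
  g <- as_guide(guide)
  pos <- check_position(position)
  id <- next_joint_id(g)
  g$joints[[id]] <- list(pos = pos, attached = NULL)
  id
}

#' Extrude a joint: new joint bridged to an existing one
#'
#' @param guide a `path_guide` or `design_scene`.
#' @param from_joint existing joint id.
#' @param position position of the new joint (Angstrom).
#' @return the new joint id.
#' @export
extrude_joint <- function(guide, from_joint, position) {
  g <- as_guide(guide)
  guide_joint(g, from_joint)
  id <- add_joint(g, position)
  bridge_two_joints(g, from_joint, id)
  id
}

#' Bridge two existing joints
#'
#' @param guide a `path_guide` or `design_scene`.
#' @param a,b distinct joint ids, not already bridged.
#' @export
bridge_two_joints <- function(guide, a, b) {
  g <- as_guide(guide)
  guide_joint(g, a)
  guide_joint(g, b)
  if (identical(a, b)) {
    stop_modcad("cannot bridge a joint to itself", "self_bridge")
  }
  key <- sort(c(a, b))
  for (br in g$bridges) {
    if (identical(br, key)) {
      stop_modcad(sprintf("joints '%s' and '%s' are already bridged", a, b),
                  "duplicate_bridge")
    }
  }
  g$bridges[[length(g$bridges) + 1L]] <- key
  invisible(g)
}

#' Move a joint
#'
#' Joints, unlike placed modules, are freely movable.
#'
#' @param guide a `path_guide` or `design_scene`.
#' @param joint_id joint to move.
#' @param position new position (Angstrom).
#' @export
move_joint <- function(guide, joint_id, position) {
  g <- as_guide(guide)
  guide_joint(g, joint_id)
  g$joints[[joint_id]]$pos <- check_position(position)
  invisible(g)
}

# pg-networks: connected components of the joint graph, one name per
# component ("pg:" + lowest joint id)
pg_components <- function(g) {
  ids <- names(g$joints)
  if (length(ids) == 0L) return(list())
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (br in g$bridges) {
    adj[[br[1L]]] <- c(adj[[br[1L]]], br[2L])
    adj[[br[2L]]] <- c(adj[[br[2L]]], br[1L])
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
    comps[[paste0("pg:", comp[1L])]] <- comp
  }
  comps
}

#' Pin a joint onto a placed module (hybrid design)
#'
#' Moves the joint to the module's world center of mass and records the
#' attachment; bridges at that joint are then read as extrusion intents
#' from the module.  Re-running with the same pair is idempotent.
#'
#' @param scene a `design_scene`.
#' @param joint_id joint to pin.
#' @param instance_id placed module instance.
#' @param chain,term optional terminus hints for the intended extrusion.
#' @export
move_joint_to_module <- function(scene, joint_id, instance_id,
                                 chain = NULL, term = NULL) {
  g <- as_guide(scene)
  guide_joint(g, joint_id)
  m <- scene_module(scene, instance_id)
  att <- g$joints[[joint_id]]$attached
  if (!is.null(att) && !identical(att$instance, instance_id)) {
    stop_modcad(sprintf("joint '%s' is already attached to '%s'",
                        joint_id, att$instance), "joint_attached")
  }
  g$joints[[joint_id]]$pos <-
    world_com(scene$lib, m$proto, m$world)
  g$joints[[joint_id]]$attached <-
    list(instance = instance_id, chain = chain, term = term)
  invisible(scene)
}

# keep attached joints on their modules when whole networks move
guide_follow_instances <- function(scene, instance_ids) {
  g <- scene$guide
  for (jid in names(g$joints)) {
    att <- g$joints[[jid]]$attached
    if (!is.null(att) && att$instance %in% instance_ids) {
      m <- scene$modules[[att$instance]]
      g$joints[[jid]]$pos <- world_com(scene$lib, m$proto, m$world)
    }
  }
  invisible(scene)
}

#' Sanity-check a partial (hybrid) design
#'
#' Reports, without erroring:
#' * `overlap_intention` -- a joint lying within 1 Angstrom of a module's
#'   center of mass without a declared attachment (ambiguous intent);
#' * `link_unavailable` -- an attachment whose hinted terminus is occupied
#'   or sealed, or whose module has no free extendable terminus at all;
#' * `dangling_bridge` -- a bridge referencing a missing joint (possible
#'   only in hand-edited files).
#'
#' @param scene a `design_scene`.
#' @return list of findings; empty means the partial design is clean.
#' @export
validate_partial <- function(scene) {
  g <- scene$guide
  findings <- list()
  note <- function(...) findings[[length(findings) + 1L]] <<- list(...)
  for (jid in names(g$joints)) {
    j <- g$joints[[jid]]
    if (is.null(j$attached)) {
      for (id in names(scene$modules)) {
        m <- scene$modules[[id]]
        d <- sqrt(sum((j$pos - world_com(scene$lib, m$proto, m$world))^2))
        if (d < 1.0) {
          note(kind = "overlap_intention", joint = jid, instance = id,
               distance = d)
        }
      }
    } else {
      att <- j$attached
      if (is.null(scene$modules[[att$instance]])) {
        note(kind = "link_unavailable", joint = jid,
             instance = att$instance, reason = "instance missing")
        next
      }
      m <- scene$modules[[att$instance]]
      if (!is.null(att$chain) && !is.null(att$term)) {
        st <- term_state(scene, att$instance, att$chain, att$term)
        if (!identical(st, "free")) {
          note(kind = "link_unavailable", joint = jid,
               instance = att$instance, chain = att$chain, term = att$term,
               reason = st)
        }
      } else {
        any_free <- any(vapply(m$occupancy, identical, logical(1), "free"))
        if (!any_free) {
          note(kind = "link_unavailable", joint = jid,
               instance = att$instance, reason = "no free terminus")
        }
      }
    }
  }
  for (br in g$bridges) {
    missing <- br[!br %in% names(g$joints)]
    if (length(missing)) {
      note(kind = "dangling_bridge", bridge = br, missing = missing[1L])
    }
  }
  findings
}
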