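# Stitching: coarse-grained design -> all-atom model.
#
# Fragment atoms are projected through each instance's world transform;
# caps are added at every free extendable terminus (only at this final
# stage -- the editable scene never contains caps); chains are assigned
# one id per maximal N->C linked path; residues renumbered 1..n per
# chain; output is mmCIF.  Small discrepancies at junctions are the
# business of downstream minimization, so the 2 A peptide-continuity
# check is a warning for real libraries (the toy library satisfies it by
# construction).

#' Add capping modules to every free extendable terminus
#'
#' Pure: returns a capped snapshot of the design (modules + links + cap
#' placements) without mutating the scene.  A free C-terminus with
#' interface token `X` receives `Ccap_X` (appended via the cap pair
#' transform); a free N-terminus receives `Ncap_X` (prepended); sealed
#' and occupied termini receive nothing.
#'
#' @param scene a `design_scene`.
#' @return a `capped_design` list with `modules`, `links`, `lib`.
#' @export
add_caps <- function(scene) {
  lib <- scene$lib
  modules <- scene$modules
  links <- scene$links
  link_n <- length(links)
  cap_counter <- list()
  for (id in sort(names(scene$modules))) {
    m <- scene$modules[[id]]
    proto <- lib_module(lib, m$proto)
    for (ch in proto$chains) {
      for (term in c("N", "C")) {
        if (!identical(m$occupancy[[occ_key(ch$chain_id, term)]], "free")) {
          next
        }
        token <- term_iface(ch, term)
        cap_name <- paste0(if (term == "N") "Ncap_" else "Ccap_", token)
        if (is.null(lib$modules[[cap_name]])) {
          stop_modcad(sprintf(
            "no cap prototype '%s' for interface token '%s'",
            cap_name, token), "missing_cap")
        }
        cap_chain <- names(lib_module(lib, cap_name)$chains)[1L]
        p <- if (term == "C") {
          find_pair(lib, m$proto, desc(ch$chain_id, "C", "N", cap_chain,
                                       cap_name))
        } else {
          find_pair(lib, m$proto, desc(ch$chain_id, "N", "C", cap_chain,
                                       cap_name))
        }
        if (is.null(p)) {
          stop_modcad(sprintf(
            "library has no pair transform attaching '%s' to %s:%s(%s)",
            cap_name, m$proto, ch$chain_id, term), "missing_cap")
        }
        cap_world <- if (term == "C") rt_compose(m$world, p$t)
                     else rt_compose(m$world, rt_invert(p$t))
        k <- (cap_counter[[cap_name]] %||% 0L) + 1L
        cap_counter[[cap_name]] <- k
        cap_id <- sprintf("%s.%03d", cap_name, k)
        modules[[cap_id]] <- list(id = cap_id, proto = cap_name,
                                  world = cap_world,
                                  occupancy = list(), color = NULL)
        link_n <- link_n + 1L
        ends <- if (term == "C") {
          list(a = list(instance = id, chain = ch$chain_id, term = "C"),
               b = list(instance = cap_id, chain = cap_chain, term = "N"))
        } else {
          list(a = list(instance = cap_id, chain = cap_chain, term = "C"),
               b = list(instance = id, chain = ch$chain_id, term = "N"))
        }
        links[[sprintf("caplink.%05d", link_n)]] <-
          list(a = ends$a, b = ends$b, pair_index = p$index)
      }
    }
  }
  structure(list(modules = modules, links = links, lib = lib),
            class = "capped_design")
}

# free extendable termini of a capped (or raw) design, by brute-force
# occupancy scan over the link list; empty after correct capping
free_extendable_termini <- function(capped) {
  occupied <- character(0)
  for (l in capped$links) {
    for (end in list(l$a, l$b)) {
      occupied <- c(occupied,
                    paste(end$instance, end$chain, end$term))
    }
  }
  out <- list()
  for (id in names(capped$modules)) {
    m <- capped$modules[[id]]
    for (ch in lib_module(capped$lib, m$proto)$chains) {
      for (term in c("N", "C")) {
        if (!term_extendable(ch, term)) next
        if (paste(id, ch$chain_id, term) %in% occupied) next
        out[[length(out) + 1L]] <- list(instance = id, chain = ch$chain_id,
                                        term = term)
      }
    }
  }
  out
}

# per-(instance, chain) segment records of a capped design
design_segments <- function(capped) {
  segs <- list()
  for (id in names(capped$modules)) {
    m <- capped$modules[[id]]
    for (ch in names(lib_module(capped$lib, m$proto)$chains)) {
      segs[[paste0(id, ":", ch)]] <- list(
        instance = id, chain = ch, n_link = NULL, c_link = NULL)
    }
  }
  for (lid in names(capped$links)) {
    l <- capped$links[[lid]]
    cend <- if (l$a$term == "C") l$a else l$b
    nend <- if (l$a$term == "C") l$b else l$a
    segs[[paste0(cend$instance, ":", cend$chain)]]$c_link <-
      c(list(lid = lid), nend)
    segs[[paste0(nend$instance, ":", nend$chain)]]$n_link <-
      c(list(lid = lid), cend)
  }
  segs
}

#' Assign output chain ids to the maximal N->C paths of a capped design
#'
#' One chain id per maximal linked path.  Ids run `A`, `B`, ... `Z`,
#' `AA`, ... in order of (network name, then lowest instance id in the
#' path, then the starting segment), so the assignment is deterministic.
#'
#' @param capped a `capped_design` from [add_caps()].
#' @return named list mapping chain id to the ordered list of segments
#'   (`instance`, `chain`).
#' @export
assign_chains <- function(capped) {
  segs <- design_segments(capped)
  comps <- link_components(names(capped$modules), capped$links)
  net_of <- list()
  for (comp in comps) {
    for (id in comp) net_of[[id]] <- paste0("net:", min(comp))
  }
  starts <- Filter(function(k) is.null(segs[[k]]$n_link), names(segs))
  paths <- lapply(starts, function(k) {
    path <- list()
    cur <- segs[[k]]
    repeat {
      path[[length(path) + 1L]] <- list(instance = cur$instance,
                                        chain = cur$chain)
      if (is.null(cur$c_link)) break
      cur <- segs[[paste0(cur$c_link$instance, ":", cur$c_link$chain)]]
    }
    path
  })
  keys <- vapply_chr(paths, function(path) {
    insts <- vapply_chr(path, function(s) s$instance)
    paste(net_of[[insts[1L]]], min(insts), insts[1L], path[[1L]]$chain,
          sep = "\r")
  })
  paths <- paths[order(keys)]
  stats::setNames(paths, chain_id_seq(length(paths)))
}

# atoms of one fragment chain under an instance's world transform
segment_atoms <- function(lib, proto, chain, world, drop_resi = NULL) {
  frag <- lib_fragment(lib, proto)
  atoms <- frag[frag$chain == chain, , drop = FALSE]
  if (length(drop_resi)) {
    atoms <- atoms[!atoms$resi %in% drop_resi, , drop = FALSE]
  }
  set_atom_coords(atoms, rt_apply(world, atom_coords(atoms)))
}

#' Stitch a design into an all-atom model
#'
#' Validates the scene, adds caps, assigns chains, projects every
#' fragment atom through its instance's world transform, renumbers
#' residues 1..n per chain, and writes mmCIF.  Residue ranges declared as
#' `drop_b` on a pair transform are omitted from the downstream (b-side)
#' module at its junction.
#'
#' @param scene a `design_scene`.
#' @param out_path output mmCIF path (`NULL` to skip writing).
#' @param validate refuse to stitch scenes with validation findings
#'   (default `TRUE`).
#' @return (invisibly) a `stitched_model`: list with `atoms` (atom table,
#'   chain ids as assigned), `provenance` (source instance and original
#'   residue index per atom), `chains` (the [assign_chains()] map).
#' @export
stitch <- function(scene, out_path = NULL, validate = TRUE) {
  if (length(scene$modules) == 0L) {
    stop_modcad("refusing to stitch an empty design", "empty_model")
  }
  if (validate) {
    findings <- validate_scene(scene)
    if (length(findings)) {
      f1 <- findings[[1L]]
      detail <- if (identical(f1$kind, "collision")) {
        sprintf("collision between '%s' and '%s'", f1$a, f1$b)
      } else {
        f1$kind
      }
      stop_modcad(sprintf("design fails validation (%d finding(s)): %s",
                          length(findings), detail), "validation",
                  findings = findings)
    }
  }
  capped <- add_caps(scene)
  chains <- assign_chains(capped)
  segs <- design_segments(capped)
  all_atoms <- list()
  prov <- list()
  for (cid in names(chains)) {
    resi_offset <- 0L
    for (seg in chains[[cid]]) {
      inst <- capped$modules[[seg$instance]]
      drop_resi <- NULL
      segrec <- segs[[paste0(seg$instance, ":", seg$chain)]]
      if (!is.null(segrec$n_link)) {
        pair <- capped$lib$pairs[[capped$links[[segrec$n_link$lid]]$pair_index]]
        drop_resi <- pair$drop_b
      }
      atoms <- segment_atoms(capped$lib, inst$proto, seg$chain, inst$world,
                             drop_resi)
      if (nrow(atoms) == 0L) next
      prov[[length(prov) + 1L]] <- data.frame(
        instance = seg$instance, src_chain = seg$chain,
        src_resi = atoms$resi, stringsAsFactors = FALSE)
      new_resi <- match(atoms$resi, sort(unique(atoms$resi))) + resi_offset
      resi_offset <- max(new_resi)
      atoms$resi <- new_resi
      atoms$chain <- cid
      all_atoms[[length(all_atoms) + 1L]] <- atoms
    }
  }
  model <- structure(
    list(atoms = do.call(rbind, all_atoms),
         provenance = do.call(rbind, prov),
         chains = chains),
    class = "stitched_model")
  check_peptide_continuity(model)
  if (!is.null(out_path)) write_mmcif(model$atoms, out_path)
  invisible(model)
}

#' @export
print.stitched_model <- function(x, ...) {
  cat(sprintf("<stitched_model> %d atoms, %d chains (%s)\n",
              nrow(x$atoms), length(x$chains),
              paste(names(x$chains), collapse = ", ")))
  invisible(x)
}

# warn when consecutive residues' C-N distance exceeds 2 A (ideal peptide
# bond ~1.33 A); junction discrepancies are deferred to minimization
check_peptide_continuity <- function(model, threshold = 2.0) {
  atoms <- model$atoms
  for (cid in unique(atoms$chain)) {
    ch <- atoms[atoms$chain == cid, , drop = FALSE]
    resis <- sort(unique(ch$resi))
    cpos <- ch[ch$atom == "C", , drop = FALSE]
    npos <- ch[ch$atom == "N", , drop = FALSE]
    for (r in resis[-length(resis)]) {
      a <- cpos[cpos$resi == r, , drop = FALSE]
      b <- npos[npos$resi == r + 1L, , drop = FALSE]
      if (nrow(a) != 1L || nrow(b) != 1L) next
      d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
      if (d > threshold) {
        warning(sprintf(
          "chain %s: C(%d)-N(%d) distance %.2f A exceeds %.1f A", cid, r,
          r + 1L, d, threshold), call. = FALSE)
      }
    }
  }
  invisible(model)
}
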