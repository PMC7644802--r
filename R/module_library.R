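# The module database.
#
# A library holds one prototype per building block (core / junction / hub /
# cap), its fragment coordinates, center of mass and collision radius, and
# an explicit list of pairwise interface transforms.  Every pair bonds a
# C-terminus of module `a` to an N-terminus of module `b`; extruding from
# `a` places `b` at compose(a_world, pair$t), and extruding backwards from
# `b`'s N-terminus places `a` at compose(b_world, invert(pair$t)).
#
# Compatibility is *stored* as the pair list; the naming grammar below is a
# validation and classification convenience only, because extended hub
# names in real databases carry suffixes the grammar cannot fully predict.

LIBRARY_SCHEMA_VERSION <- "modcad-library/1"

#' Parse a module prototype name
#'
#' Classifies a prototype name by the field's naming convention:
#' * caps: `Ncap_X` / `Ccap_X` seal an interface of type `X`;
#' * junctions: `A_j<k>_B` bridges core types `A` (N side) and `B` (C side);
#' * hubs: `BASE_<symtag>` where the symmetry tag contains `C<n>`
#'   (e.g. `D4_C4`, `D49_aC2_24`); unrecognized suffix text is kept opaque;
#' * anything else is a core module, self-compatible at both termini.
#'
#' @param name prototype name.
#' @return a list with `cls` (`core`/`junction`/`hub`/`cap`), `n_iface`,
#'   `c_iface` (interface tokens or `NA` for sealed cap ends),
#'   `bridged_cores`, `junction_index`, `hub_base`, `symmetry`.
#' @examples
#' parse_module_name("D14_j1_D79")
#' parse_module_name("D4_C4")
#' parse_module_name("Ccap_D14")
#' @export
parse_module_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_modcad("module name must be a non-empty string", "invalid_name")
  }
  if (grepl(".", name, fixed = TRUE)) {
    stop_modcad(sprintf("module name '%s' contains reserved '.' separator",
                        name), "invalid_name")
  }
  info <- list(cls = "core", n_iface = name, c_iface = name,
               bridged_cores = NULL, junction_index = NULL,
               hub_base = NULL, symmetry = NULL)
  cap <- regmatches(name, regexec("^(Ncap|Ccap)_(.+)$", name))[[1]]
  if (length(cap)) {
    info$cls <- "cap"
    if (cap[2] == "Ncap") {
      info$n_iface <- NA_character_   # sealed outer end
      info$c_iface <- cap[3]
    } else {
      info$n_iface <- cap[3]
      info$c_iface <- NA_character_
    }
    return(info)
  }
  jn <- regmatches(name, regexec("^([A-Za-z0-9]+)_j([0-9]+)_([A-Za-z0-9]+)$",
                                 name))[[1]]
  if (length(jn)) {
    info$cls <- "junction"
    info$n_iface <- jn[2]
    info$c_iface <- jn[4]
    info$bridged_cores <- c(jn[2], jn[4])
    info$junction_index <- as.integer(jn[3])
    return(info)
  }
  hub <- regmatches(name,
                    regexec("^([A-Za-z0-9]+)_([a-z0-9]*C([0-9]+)(?:_[0-9]+)?)$",
                            name))[[1]]
  if (length(hub)) {
    info$cls <- "hub"
    info$hub_base <- hub[2]
    info$symmetry <- paste0("C", hub[4])
    info$n_iface <- hub[2]
    info$c_iface <- hub[2]
    return(info)
  }
  info
}

#' Center of mass and collision radius of a point cloud
#'
#' The center is the unweighted mean of the coordinates; the radius is the
#' exact maximum center-to-point distance (no padding -- padding is applied
#' at collision-check time through the overlap factor).
#'
#' @param pts n x 3 coordinate matrix (Angstrom), n >= 1.
#' @return list with `com` (3-vector) and `radius` (Angstrom).
#' @export
compute_com_radius <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) == 0L) stop_modcad("empty point set", "bad_points")
  com <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2L, com)^2))
  list(com = as.numeric(com), radius = max(d))
}

# --- extrusion descriptors ---------------------------------------------------

# internal structured form of ":<chain1>(<term1>)->(<term2>)<chain2>:<name2>"
desc <- function(from_chain, from_term, to_term, to_chain, to_proto) {
  list(from_chain = from_chain, from_term = from_term,
       to_term = to_term, to_chain = to_chain, to_proto = to_proto)
}

#' Serialize / parse extrusion descriptors
#'
#' An extrusion descriptor names a legal chain-growth step:
#' `":A(C)->(N)A:H4"` reads "from chain A's C-terminus of the selected
#' module, bond the N-terminus of chain A of a new H4".
#'
#' @param d descriptor list (fields `from_chain`, `from_term`, `to_term`,
#'   `to_chain`, `to_proto`).
#' @param s descriptor string.
#' @return `desc_to_string()` a string; `desc_from_string()` the list form.
#' @export
desc_to_string <- function(d) {
  sprintf(":%s(%s)->(%s)%s:%s", d$from_chain, d$from_term,
          d$to_term, d$to_chain, d$to_proto)
}

#' @rdname desc_to_string
#' @export
desc_from_string <- function(s) {
  m <- regmatches(s, regexec(
    "^:([A-Za-z0-9]+)\\((N|C)\\)->\\((N|C)\\)([A-Za-z0-9]+):(.+)$", s))[[1]]
  if (length(m) == 0L) {
    stop_modcad(sprintf("malformed extrusion descriptor '%s'", s),
                "invalid_descriptor")
  }
  desc(m[2], m[3], m[4], m[5], m[6])
}

# --- pair transforms ---------------------------------------------------------

new_pair <- function(a, a_chain, b, b_chain, t, rmsd = 0, drop_b = NULL) {
  list(a = a, a_chain = a_chain, a_term = "C",
       b = b, b_chain = b_chain, b_term = "N",
       t = t, rmsd = rmsd, drop_b = drop_b)
}

# match fragment atoms inside a pair structure by (mapped chain, resi, atom)
match_pair_region <- function(pair_atoms, frag_atoms, chain_map, what) {
  mapped <- chain_map[frag_atoms$chain]
  if (anyNA(mapped)) {
    stop_modcad(sprintf("pair structure: no chain mapping for %s chain '%s'",
                        what, frag_atoms$chain[which(is.na(mapped))[1]]),
                "unmatched_labels")
  }
  key_f <- paste(mapped, frag_atoms$resi, frag_atoms$atom)
  key_p <- paste(pair_atoms$chain, pair_atoms$resi, pair_atoms$atom)
  idx <- match(key_f, key_p)
  if (anyNA(idx) || anyDuplicated(idx)) {
    stop_modcad(sprintf("pair structure does not match %s fragment labels",
                        what), "unmatched_labels")
  }
  atom_coords(pair_atoms)[idx, , drop = FALSE]
}

#' Compute the interface transform of a module pair from a pair structure
#'
#' Superposes each module's canonical fragment onto its copy inside the
#' pair structure (label-matched Kabsch fits `T_a`, `T_b`) and returns the
#' transform `t = invert(T_a) %then% T_b` that places `b`'s canonical frame
#' relative to `a`'s.  The recorded rmsd is the worse of the two fits.
#'
#' @param pair_atoms atom table of the two-module pair structure.
#' @param a_atoms,b_atoms canonical fragment atom tables.
#' @param a_chain_map,b_chain_map named character vectors mapping fragment
#'   chain ids to the chain ids used in the pair structure.
#' @param tol superposition rmsd tolerance (Angstrom, default 0.5).
#' @return list with `t` (a `rigid_transform`) and `rmsd`.
#' @export
compute_pair_transform <- function(pair_atoms, a_atoms, b_atoms,
                                   a_chain_map, b_chain_map, tol = 0.5) {
  fit <- function(frag, map, what) {
    target <- match_pair_region(pair_atoms, frag, map, what)
    kabsch(atom_coords(frag), target)
  }
  fa <- fit(a_atoms, a_chain_map, "module a")
  fb <- fit(b_atoms, b_chain_map, "module b")
  rmsd <- max(fa$rmsd, fb$rmsd)
  if (rmsd > tol) {
    stop_modcad(sprintf(
      "pair superposition rmsd %.3f A exceeds tolerance %.3f A",
      rmsd, tol), "incompatible_pair")
  }
  list(t = rt_compose(rt_invert(fa$transform), fb$transform), rmsd = rmsd)
}

# --- library object ----------------------------------------------------------

new_library <- function(modules, pairs, base_dir) {
  modules <- modules[order(names(modules))]
  pairs <- pairs[order(vapply_chr(pairs, pair_key))]
  tokens <- sort(unique(stats::na.omit(unlist(lapply(modules, function(m) {
    unlist(lapply(m$chains, function(ch) c(ch$n_iface, ch$c_iface)))
  })))))
  lib <- structure(
    list(version = LIBRARY_SCHEMA_VERSION, units = "angstrom",
         modules = modules, pairs = pairs, token_set = tokens,
         base_dir = base_dir, fragment_cache = new.env(parent = emptyenv())),
    class = "module_library")
  validate_library(lib)
  lib
}

pair_key <- function(p) {
  paste(p$a, p$a_chain, p$a_term, p$b, p$b_chain, p$b_term, sep = "|")
}

#' @export
print.module_library <- function(x, ...) {
  cls <- table(vapply_chr(x$modules, function(m) m$cls))
  cat(sprintf("<module_library> %d prototypes (%s), %d pair transforms\n",
              length(x$modules),
              paste(sprintf("%d %s", cls, names(cls)), collapse = ", "),
              length(x$pairs)))
  invisible(x)
}

lib_module <- function(lib, name) {
  m <- lib$modules[[name]]
  if (is.null(m)) {
    stop_modcad(sprintf("unknown module prototype '%s'", name),
                "unknown_module")
  }
  m
}

lib_chain <- function(lib, name, chain_id) {
  m <- lib_module(lib, name)
  ch <- m$chains[[chain_id]]
  if (is.null(ch)) {
    stop_modcad(sprintf("module '%s' has no chain '%s'", name, chain_id),
                "unknown_chain")
  }
  ch
}

# fragment atoms for a prototype, cached per library object
lib_fragment <- function(lib, name) {
  cached <- lib$fragment_cache[[name]]
  if (!is.null(cached)) return(cached)
  m <- lib_module(lib, name)
  path <- file.path(lib$base_dir, m$fragment)
  atoms <- read_pdb_fragment(path)
  assign(name, atoms, envir = lib$fragment_cache)
  atoms
}

term_extendable <- function(ch, term) {
  if (term == "N") isTRUE(ch$n_extendable) else isTRUE(ch$c_extendable)
}

term_iface <- function(ch, term) {
  if (term == "N") ch$n_iface else ch$c_iface
}

#' Compatible extrusion successors of a terminus
#'
#' Lists every legal extrusion from the given prototype terminus, one
#' descriptor per matching pair transform.  Caps are never offered; sealed
#' (non-extendable) termini yield an empty list.  Ordering is lexicographic
#' by descriptor string, so the result is deterministic.
#'
#' @param lib a `module_library`.
#' @param proto prototype name.
#' @param chain_id chain within the prototype.
#' @param term `"N"` or `"C"`.
#' @return list of descriptor lists (see [desc_to_string()]).
#' @export
compatible_successors <- function(lib, proto, chain_id, term) {
  if (!term %in% c("N", "C")) {
    stop_modcad(sprintf("unknown terminus '%s'", term), "unknown_terminus")
  }
  ch <- lib_chain(lib, proto, chain_id)
  if (!term_extendable(ch, term)) return(list())
  out <- list()
  for (p in lib$pairs) {
    if (term == "C" && p$a == proto && p$a_chain == chain_id) {
      if (lib_module(lib, p$b)$cls == "cap") next
      out[[length(out) + 1L]] <- desc(chain_id, "C", "N", p$b_chain, p$b)
    } else if (term == "N" && p$b == proto && p$b_chain == chain_id) {
      if (lib_module(lib, p$a)$cls == "cap") next
      out[[length(out) + 1L]] <- desc(chain_id, "N", "C", p$a_chain, p$a)
    }
  }
  out[order(vapply_chr(out, desc_to_string))]
}

# find the pair record realizing a descriptor from `proto`; NULL if none
find_pair <- function(lib, proto, d) {
  for (i in seq_along(lib$pairs)) {
    p <- lib$pairs[[i]]
    hit <- if (d$from_term == "C") {
      p$a == proto && p$a_chain == d$from_chain &&
        p$b == d$to_proto && p$b_chain == d$to_chain && d$to_term == "N"
    } else {
      p$b == proto && p$b_chain == d$from_chain &&
        p$a == d$to_proto && p$a_chain == d$to_chain && d$to_term == "C"
    }
    if (hit) return(c(p, list(index = i)))
  }
  NULL
}

validate_library <- function(lib) {
  if (length(lib$modules) == 0L) {
    stop_modcad("library has no modules", "empty_library")
  }
  for (m in lib$modules) {
    nch <- length(m$chains)
    if (m$cls %in% c("core", "junction", "cap") && nch != 1L) {
      stop_modcad(sprintf("%s module '%s' must have exactly one chain",
                          m$cls, m$name), "invalid_library")
    }
    if (m$cls == "hub" && nch < 2L) {
      stop_modcad(sprintf("hub '%s' must have >= 2 chains", m$name),
                  "invalid_library")
    }
  }
  for (p in lib$pairs) {
    if (p$a_term == p$b_term) {
      stop_modcad(sprintf("pair %s bonds identical termini", pair_key(p)),
                  "invalid_library")
    }
    lib_chain(lib, p$a, p$a_chain)
    lib_chain(lib, p$b, p$b_chain)
  }
  # every extendable terminus is reachable, and its interface token capped
  for (m in lib$modules) {
    if (m$cls == "cap") next
    for (ch in m$chains) {
      for (term in c("N", "C")) {
        if (!term_extendable(ch, term)) next
        in_pair <- any(vapply(lib$pairs, function(p) {
          (p$a == m$name && p$a_chain == ch$chain_id && term == "C") ||
            (p$b == m$name && p$b_chain == ch$chain_id && term == "N")
        }, logical(1)))
        if (!in_pair) {
          stop_modcad(sprintf(
            "extendable terminus %s:%s(%s) appears in no pair transform",
            m$name, ch$chain_id, term), "invalid_library")
        }
        token <- term_iface(ch, term)
        for (cap in paste0(c("Ncap_", "Ccap_"), token)) {
          if (is.null(lib$modules[[cap]])) {
            stop_modcad(sprintf(
              "missing cap '%s' for interface token '%s'", cap, token),
              "missing_cap")
          }
        }
      }
    }
  }
  invisible(lib)
}

# --- building from fragment + pair structure files ---------------------------

#' Build a module library from fragment and pair structures
#'
#' Reads the manifest (JSON) that names every module fragment, its chain
#' extendability, and every pair structure together with the two fragments
#' it joins, then computes centers of mass, collision radii and pair
#' transforms.  Output is deterministic: modules and pairs are sorted, so
#' two builds from the same inputs serialize to identical bytes.
#'
#' @param fragments_dir directory holding module fragment PDB files.
#' @param pairs_dir directory holding pair structure PDB files.
#' @param manifest path to the manifest JSON, or the parsed manifest list.
#' @return a `module_library`.
#' @export
build_library <- function(fragments_dir, pairs_dir, manifest) {
  if (!dir.exists(fragments_dir) ||
      length(list.files(fragments_dir, pattern = "\\.pdb$")) == 0L) {
    stop_modcad(sprintf("no PDB fragments found in '%s'", fragments_dir),
                "empty_library")
  }
  if (is.character(manifest)) manifest <- read_json_file(manifest, "manifest")
  tol <- if (is.null(manifest$pair_rmsd_tol)) 0.5 else manifest$pair_rmsd_tol

  modules <- list()
  for (mm in manifest$modules) {
    name <- require_field(mm, "name", "manifest module")
    if (!is.null(modules[[name]])) {
      stop_modcad(sprintf("duplicate prototype name '%s'", name),
                  "duplicate_module")
    }
    info <- parse_module_name(name)
    frag_file <- require_field(mm, "fragment", sprintf("module '%s'", name))
    atoms <- read_pdb_fragment(file.path(fragments_dir, frag_file))
    cr <- compute_com_radius(atom_coords(atoms))
    chain_ids <- sort(unique(atoms$chain))
    cfg_chain <- function(id) {
      for (c0 in mm$chains %||% list()) if (identical(c0$chain_id, id)) return(c0)
      NULL
    }
    chains <- lapply(chain_ids, function(id) {
      c0 <- cfg_chain(id)
      ext_default <- info$cls %in% c("core", "junction")
      list(chain_id = id,
           n_extendable =
             if (!is.null(c0$n_extendable)) isTRUE(c0$n_extendable)
             else ext_default && !is.na(info$n_iface),
           c_extendable =
             if (!is.null(c0$c_extendable)) isTRUE(c0$c_extendable)
             else ext_default && !is.na(info$c_iface),
           n_iface = info$n_iface, c_iface = info$c_iface,
           residue_count = length(unique(atoms$resi[atoms$chain == id])))
    })
    names(chains) <- chain_ids
    modules[[name]] <- list(
      name = name, cls = info$cls, chains = chains,
      com = cr$com, radius = cr$radius, fragment = frag_file,
      symmetry = info$symmetry)
  }

  pairs <- list()
  for (pp in manifest$pairs) {
    a <- require_field(pp, "a", "manifest pair")
    b <- require_field(pp, "b", "manifest pair")
    for (nm in c(a, b)) {
      if (is.null(modules[[nm]])) {
        stop_modcad(sprintf("pair references unknown module '%s'", nm),
                    "unknown_module")
      }
    }
    pair_atoms <- read_pdb_fragment(
      file.path(pairs_dir, require_field(pp, "file", "manifest pair")))
    a_atoms <- read_pdb_fragment(file.path(fragments_dir,
                                           modules[[a]]$fragment))
    b_atoms <- read_pdb_fragment(file.path(fragments_dir,
                                           modules[[b]]$fragment))
    amap <- unlist(pp$a_chains)
    bmap <- unlist(pp$b_chains)
    fit <- compute_pair_transform(pair_atoms, a_atoms, b_atoms, amap, bmap,
                                  tol = tol)
    pairs[[length(pairs) + 1L]] <- new_pair(
      a, require_field(pp, "a_chain", "manifest pair"),
      b, require_field(pp, "b_chain", "manifest pair"),
      fit$t, fit$rmsd,
      drop_b = if (!is.null(pp$drop_b)) as.integer(unlist(pp$drop_b)))
  }

  new_library(modules, pairs, base_dir = normalizePath(fragments_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- serialization -----------------------------------------------------------

#' Save / load a module library as JSON
#'
#' `load_library(save_library(lib, path))` reproduces the library exactly
#' (numeric fields at full serialized precision).  Files carry a schema
#' version; an unknown version is an explicit error.
#'
#' @param lib a `module_library`.
#' @param path file path.  The JSON records where the fragment files live
#'   (`fragment_dir`, relative to the JSON when nested under it).
#' @param fragment_dir override for the fragment directory on load
#'   (default: the location recorded in the file).
#' @export
save_library <- function(lib, path) {
  mods <- lapply(lib$modules, function(m) {
    list(cls = m$cls,
         chains = lapply(unname(m$chains), function(ch) list(
           chain_id = ch$chain_id,
           n_extendable = ch$n_extendable, c_extendable = ch$c_extendable,
           n_iface = if (is.na(ch$n_iface)) NULL else ch$n_iface,
           c_iface = if (is.na(ch$c_iface)) NULL else ch$c_iface,
           residue_count = ch$residue_count)),
         com = as.numeric(m$com), radius = m$radius,
         fragment = m$fragment,
         symmetry = m$symmetry)
  })
  prs <- lapply(lib$pairs, function(p) {
    list(a = p$a, a_chain = p$a_chain, a_term = p$a_term,
         b = p$b, b_chain = p$b_chain, b_term = p$b_term,
         rot = rt_to_json(p$t)$rot, tran = rt_to_json(p$t)$tran,
         rmsd = p$rmsd,
         drop_b = if (is.null(p$drop_b)) NULL else as.integer(p$drop_b))
  })
  write_canonical_json(list(version = lib$version, units = lib$units,
                            fragment_dir = rel_dir(lib$base_dir,
                                                   dirname(path)),
                            modules = mods, pairs = prs), path)
}

# express `target` relative to `base` when nested, else keep it absolute
rel_dir <- function(target, base) {
  t <- normalizePath(target, winslash = "/", mustWork = FALSE)
  b <- normalizePath(base, winslash = "/", mustWork = FALSE)
  if (identical(t, b)) return(".")
  if (startsWith(t, paste0(b, "/"))) return(substring(t, nchar(b) + 2L))
  t
}

#' @rdname save_library
#' @export
load_library <- function(path, fragment_dir = NULL) {
  obj <- read_json_file(path, "library JSON")
  if (is.null(fragment_dir)) {
    fragment_dir <- file.path(dirname(path), obj$fragment_dir %||% ".")
  }
  ver <- require_field(obj, "version", "library JSON")
  if (!identical(ver, LIBRARY_SCHEMA_VERSION)) {
    stop_modcad(sprintf("unsupported library schema version '%s'", ver),
                "schema_version")
  }
  if (!identical(obj$units, "angstrom")) {
    stop_modcad("library JSON must declare units 'angstrom'", "schema")
  }
  modules <- lapply(names(obj$modules), function(name) {
    m <- obj$modules[[name]]
    chains <- lapply(m$chains, function(ch) list(
      chain_id = require_field(ch, "chain_id", "library chain"),
      n_extendable = isTRUE(ch$n_extendable),
      c_extendable = isTRUE(ch$c_extendable),
      n_iface = ch$n_iface %||% NA_character_,
      c_iface = ch$c_iface %||% NA_character_,
      residue_count = ch$residue_count))
    names(chains) <- vapply_chr(chains, function(ch) ch$chain_id)
    list(name = name, cls = require_field(m, "cls", "library module"),
         chains = chains,
         com = as.numeric(unlist(require_field(m, "com", "library module"))),
         radius = require_field(m, "radius", "library module"),
         fragment = require_field(m, "fragment", "library module"),
         symmetry = m$symmetry)
  })
  names(modules) <- names(obj$modules)
  pairs <- lapply(obj$pairs, function(p) {
    new_pair(require_field(p, "a", "library pair"), p$a_chain,
             require_field(p, "b", "library pair"), p$b_chain,
             rt_from_json(p, "library pair"), p$rmsd %||% 0,
             drop_b = if (is.null(p$drop_b)) NULL
                      else as.integer(unlist(p$drop_b)))
  })
  new_library(modules, pairs, base_dir = normalizePath(fragment_dir))
}
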