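# Synthetic toy module library.
#
# Stands in for the real repeat-protein-derived databases: single-chain
# core modules with a pure-translation N->C growth transform, a bent
# junction bridging the two core types, cyclic multi-chain hubs with
# sealed N-termini, and capping repeats for every interface token.  All
# pair transforms are analytic and recorded in a sidecar file, so every
# downstream computation (superposition, library building, extrusion,
# stitching, solving) can be checked against closed-form ground truth.
#
# Toy "atoms" sit on an ideal helix (1.5 A rise and 100 deg twist per
# residue, backbone names N/CA/C/O) so the fragments parse as plausible
# protein backbones while staying fully analytic.  With 4 residues per
# module the helix turns 400 deg per module, so a module boundary placed
# by a pure rise translation meets the previous C atom within ~0.9 A --
# comfortably under the 2 A peptide-continuity threshold.

#' Toy library configuration
#'
#' @param rise_per_module translation per core module along its growth
#'   axis (Angstrom).  The default, 6 A, equals
#'   `residues_per_module * 1.5` so modules continue the ideal helix.
#' @param junction_bend bend angle of the junction module in degrees
#'   (rotation about x between the bridged core types); `0 <= bend < 180`.
#' @param hub_symmetries integer vector of cyclic orders `n >= 2`; one hub
#'   `H4_C<n>` is generated per entry.
#' @param atoms_per_residue 3 (`N`,`CA`,`C`) or 4 (adds `O`).
#' @param residues_per_module residues per core/junction/cap fragment.
#' @param hub_arm_radius distance of each hub chain from the symmetry
#'   axis (Angstrom).
#' @param seed integer seed (used by [generate_guide_from_chain()]).
#' @return validated config list.
#' @export
toy_config <- function(rise_per_module = 6, junction_bend = 15,
                       hub_symmetries = c(2L, 4L), atoms_per_residue = 4L,
                       residues_per_module = 4L, hub_arm_radius = 8,
                       seed = 1L) {
  cfg <- list(rise_per_module = rise_per_module,
              junction_bend = junction_bend,
              hub_symmetries = as.integer(hub_symmetries),
              atoms_per_residue = as.integer(atoms_per_residue),
              residues_per_module = as.integer(residues_per_module),
              hub_arm_radius = hub_arm_radius,
              seed = as.integer(seed))
  if (!is.numeric(cfg$rise_per_module) || cfg$rise_per_module <= 0) {
    stop_modcad("rise_per_module must be > 0", "invalid_config")
  }
  if (cfg$junction_bend < 0 || cfg$junction_bend >= 180) {
    stop_modcad("junction_bend must be in [0, 180)", "invalid_config")
  }
  if (length(cfg$hub_symmetries) == 0L || any(cfg$hub_symmetries < 2L)) {
    stop_modcad("hub symmetries must all be >= 2", "invalid_config")
  }
  if (!cfg$atoms_per_residue %in% c(3L, 4L)) {
    stop_modcad("atoms_per_residue must be 3 or 4", "invalid_config")
  }
  if (cfg$residues_per_module < 2L) {
    stop_modcad("residues_per_module must be >= 2", "invalid_config")
  }
  cfg
}

HELIX_RADIUS <- 1.9      # A, backbone distance from helix axis
HELIX_RISE <- 1.5        # A per residue
HELIX_TWIST <- 100       # degrees per residue
O_RADIUS_EXTRA <- 0.6    # carbonyl O pushed radially outward

helix_point <- function(s, radius = HELIX_RADIUS) {
  a <- HELIX_TWIST * pi / 180 * s
  cbind(radius * cos(a), radius * sin(a), HELIX_RISE * s)
}

# one ideal-helix chain fragment; resn recycled over residues
toy_chain_atoms <- function(n_res, resn, chain = "A", atoms_per_residue = 4L) {
  names4 <- c("N", "CA", "C", "O")[seq_len(atoms_per_residue)]
  offs <- c(N = 0, CA = 0.25, C = 0.5, O = 0.5)
  rads <- c(N = HELIX_RADIUS, CA = HELIX_RADIUS, C = HELIX_RADIUS,
            O = HELIX_RADIUS + O_RADIUS_EXTRA)
  resn <- rep_len(resn, n_res)
  rows <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    xyz <- helix_point((i - 1) + offs[names4], rads[names4])
    atom_table(chain = chain, resi = i, resn = resn[i], atom = names4,
               element = substr(names4, 1L, 1L),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }))
  rows
}

# transform the coordinates of an atom table
transform_atoms <- function(atoms, t) {
  set_atom_coords(atoms, rt_apply(t, atom_coords(atoms)))
}

# analytic module fragments + pair transforms for a config
toy_blueprint <- function(cfg) {
  nres <- cfg$residues_per_module
  apr <- cfg$atoms_per_residue
  rise <- rt(diag(3), c(0, 0, cfg$rise_per_module), check = FALSE)
  bendt <- rt(rot_x(cfg$junction_bend), c(0, 0, cfg$rise_per_module))

  frags <- list(
    H4 = toy_chain_atoms(nres, "HIS", "A", apr),
    K4 = toy_chain_atoms(nres, "LYS", "A", apr),
    H4_j1_K4 = toy_chain_atoms(nres, c("HIS", "LYS"), "A", apr),
    Ncap_H4 = toy_chain_atoms(nres, "GLY", "A", apr),
    Ccap_H4 = toy_chain_atoms(nres, "GLY", "A", apr),
    Ncap_K4 = toy_chain_atoms(nres, "ALA", "A", apr),
    Ccap_K4 = toy_chain_atoms(nres, "ALA", "A", apr))

  hubs <- list()
  for (n in cfg$hub_symmetries) {
    name <- sprintf("H4_C%d", n)
    chains <- chain_id_seq(n)
    placements <- lapply(seq_len(n) - 1L, function(i) {
      rt(rot_z(360 * i / n),
         as.numeric(rot_z(360 * i / n) %*% c(cfg$hub_arm_radius, 0, 0)),
         check = FALSE)
    })
    atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
      arm <- toy_chain_atoms(nres, "HIS", chains[i], apr)
      transform_atoms(arm, placements[[i]])
    }))
    frags[[name]] <- atoms
    hubs[[name]] <- list(n = n, chains = chains, placements = placements)
  }

  pairs <- list(
    list(a = "H4", a_chain = "A", b = "H4", b_chain = "A", t = rise),
    list(a = "K4", a_chain = "A", b = "K4", b_chain = "A", t = rise),
    list(a = "H4", a_chain = "A", b = "H4_j1_K4", b_chain = "A", t = bendt),
    list(a = "H4_j1_K4", a_chain = "A", b = "K4", b_chain = "A", t = rise),
    list(a = "H4", a_chain = "A", b = "Ccap_H4", b_chain = "A", t = rise),
    list(a = "Ncap_H4", a_chain = "A", b = "H4", b_chain = "A", t = rise),
    list(a = "Ncap_H4", a_chain = "A", b = "H4_j1_K4", b_chain = "A",
         t = rise),
    list(a = "K4", a_chain = "A", b = "Ccap_K4", b_chain = "A", t = rise),
    list(a = "H4_j1_K4", a_chain = "A", b = "Ccap_K4", b_chain = "A",
         t = rise),
    list(a = "Ncap_K4", a_chain = "A", b = "K4", b_chain = "A", t = rise))
  for (hname in names(hubs)) {
    h <- hubs[[hname]]
    for (i in seq_len(h$n)) {
      arm_t <- rt_compose(h$placements[[i]],
                          rt(diag(3), c(0, 0, cfg$rise_per_module),
                             check = FALSE))
      pairs[[length(pairs) + 1L]] <- list(
        a = hname, a_chain = h$chains[i], b = "H4", b_chain = "A", t = arm_t)
      pairs[[length(pairs) + 1L]] <- list(
        a = hname, a_chain = h$chains[i], b = "Ccap_H4", b_chain = "A",
        t = arm_t)
    }
  }
  list(frags = frags, pairs = pairs, hubs = hubs)
}

#' Generate the synthetic toy module library
#'
#' Writes module fragment PDBs, pair-structure PDBs, the manifest, a
#' sidecar ground-truth JSON with the analytic pair transforms, then runs
#' [build_library()] on those files and saves the resulting library JSON.
#' Output is byte-deterministic for a fixed config.
#'
#' @param cfg a [toy_config()].
#' @param out_dir output directory (created if missing); fragments go to
#'   `<out_dir>/fragments`, pair structures to `<out_dir>/pairs`.
#' @return the built `module_library` (also saved as
#'   `<out_dir>/library.json`).
#' @export
generate_toy_library <- function(cfg = toy_config(), out_dir) {
  bp <- toy_blueprint(cfg)
  frag_dir <- file.path(out_dir, "fragments")
  pair_dir <- file.path(out_dir, "pairs")
  for (d in c(frag_dir, pair_dir)) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(d)) stop_modcad(sprintf("cannot create '%s'", d), "io")
  }

  for (name in names(bp$frags)) {
    write_pdb_fragment(bp$frags[[name]], file.path(frag_dir,
                                                   paste0(name, ".pdb")))
  }

  manifest_pairs <- list()
  gt_pairs <- list()
  for (p in bp$pairs) {
    a_atoms <- bp$frags[[p$a]]
    b_atoms <- bp$frags[[p$b]]
    a_chains <- sort(unique(a_atoms$chain))
    b_chains <- sort(unique(b_atoms$chain))
    free <- setdiff(chain_id_seq(26L), a_chains)
    bmap <- stats::setNames(free[seq_along(b_chains)], b_chains)
    amap <- stats::setNames(a_chains, a_chains)
    b_placed <- transform_atoms(b_atoms, p$t)
    b_placed$chain <- unname(bmap[b_placed$chain])
    pair_file <- sprintf("pair_%s_%s__%s_%s.pdb", p$a, p$a_chain, p$b,
                         p$b_chain)
    write_pdb_fragment(rbind(a_atoms, b_placed),
                       file.path(pair_dir, pair_file))
    manifest_pairs[[length(manifest_pairs) + 1L]] <- list(
      file = pair_file, a = p$a, a_chain = p$a_chain,
      b = p$b, b_chain = p$b_chain,
      a_chains = as.list(amap), b_chains = as.list(bmap))
    gt_pairs[[length(gt_pairs) + 1L]] <- list(
      a = p$a, a_chain = p$a_chain, b = p$b, b_chain = p$b_chain,
      rot = rt_to_json(p$t)$rot, tran = rt_to_json(p$t)$tran)
  }

  manifest_modules <- lapply(names(bp$frags), function(name) {
    hub <- bp$hubs[[name]]
    if (is.null(hub)) {
      list(name = name, fragment = paste0(name, ".pdb"))
    } else {
      list(name = name, fragment = paste0(name, ".pdb"),
           chains = lapply(hub$chains, function(ch) {
             list(chain_id = ch, n_extendable = FALSE, c_extendable = TRUE)
           }))
    }
  })

  manifest <- list(version = "modcad-manifest/1", pair_rmsd_tol = 0.5,
                   modules = manifest_modules, pairs = manifest_pairs)
  write_canonical_json(manifest, file.path(out_dir, "manifest.json"))
  write_canonical_json(
    list(version = "modcad-ground-truth/1", config = cfg, pairs = gt_pairs),
    file.path(out_dir, "ground_truth.json"))

  lib <- build_library(frag_dir, pair_dir, manifest)
  save_library(lib, file.path(out_dir, "library.json"))
  lib
}

#' Generate a path guide from a known module chain
#'
#' Places joints at the centers of mass of a compatible single-chain
#' module sequence (first module at the identity pose), optionally with
#' seeded Gaussian perturbation, and bridges them along the path.  Used as
#' a feasible oracle in solver-recovery tests: with zero noise the
#' generating chain scores 0 against the returned guide.
#'
#' @param lib a `module_library`.
#' @param chain_spec character vector of single-chain prototype names,
#'   consecutive elements library-compatible.
#' @param noise_sd standard deviation of the joint perturbation (Angstrom).
#' @param seed integer seed for the perturbation.
#' @return a `path_guide` (see [path_guide()]).
#' @export
generate_guide_from_chain <- function(lib, chain_spec, noise_sd = 0,
                                      seed = 1L) {
  coms <- chain_com_path(lib, chain_spec)
  if (noise_sd > 0) {
    coms <- coms + with_seed(seed, matrix(
      stats::rnorm(length(coms), sd = noise_sd), ncol = 3L))
  }
  g <- path_guide()
  ids <- character(nrow(coms))
  for (i in seq_len(nrow(coms))) {
    ids[i] <- if (i == 1L) add_joint(g, coms[i, ])
              else extrude_joint(g, ids[i - 1L], coms[i, ])
  }
  g
}

# world transforms of each module along a compatible single-chain sequence,
# first module at the identity
chain_worlds <- function(lib, chain_spec) {
  worlds <- vector("list", length(chain_spec))
  worlds[[1L]] <- rt_identity()
  for (i in seq_along(chain_spec)[-1L]) {
    prev <- chain_spec[i - 1L]
    cur <- chain_spec[i]
    prev_chain <- names(lib_module(lib, prev)$chains)[1L]
    cur_chain <- names(lib_module(lib, cur)$chains)[1L]
    p <- find_pair(lib, prev, desc(prev_chain, "C", "N", cur_chain, cur))
    if (is.null(p)) {
      stop_modcad(sprintf("chain spec not library-compatible: %s -> %s",
                          prev, cur), "incompatible_pair")
    }
    worlds[[i]] <- rt_compose(worlds[[i - 1L]], p$t)
  }
  worlds
}

# centers of mass along a compatible module sequence
chain_com_path <- function(lib, chain_spec) {
  worlds <- chain_worlds(lib, chain_spec)
  do.call(rbind, lapply(seq_along(chain_spec), function(i) {
    rt_apply(worlds[[i]], lib_module(lib, chain_spec[i])$com)
  }))
}
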