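# Structure file I/O.
#
# Module fragments live in PDB format (small, single-module files); the
# assembled atomic models are written as mmCIF, which has no limit on atom
# count or chain-id length.  Atom tables are plain data.frames with columns
# chain, resi, resn, atom, element, x, y, z (Angstrom).

atom_table <- function(chain, resi, resn, atom, element, x, y, z) {
  data.frame(chain = as.character(chain), resi = as.integer(resi),
             resn = as.character(resn), atom = as.character(atom),
             element = as.character(element),
             x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
             stringsAsFactors = FALSE)
}

empty_atom_table <- function() {
  atom_table(character(0), integer(0), character(0), character(0),
             character(0), numeric(0), numeric(0), numeric(0))
}

#' Read a PDB fragment file
#'
#' Parses `ATOM`/`HETATM` records (fixed-column format).  A missing element
#' column is tolerated: the element is then inferred from the atom name.
#'
#' @param path path to a PDB file.
#' @return a data.frame with columns `chain`, `resi`, `resn`, `atom`,
#'   `element`, `x`, `y`, `z` (coordinates in Angstrom).
#' @export
read_pdb_fragment <- function(path) {
  if (!file.exists(path)) {
    stop_modcad(sprintf("PDB file not found: %s", path), "io")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- grepl("^(ATOM  |HETATM)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    stop_modcad(sprintf("no ATOM records in PDB file: %s", path), "parse")
  }
  fld <- function(from, to) trimws(substring(lines, from, to))
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(fld(from, to)))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop_modcad(sprintf("malformed %s in %s line %d", what, path,
                          lineno[bad[1]]), "parse")
    }
    v
  }
  name <- fld(13, 16)
  element <- fld(77, 78)
  infer <- element == ""
  element[infer] <- vapply(name[infer], function(nm) {
    ch <- regmatches(nm, regexpr("[A-Za-z]", nm))
    if (length(ch) == 0L) "C" else toupper(ch)
  }, character(1))
  atom_table(chain = fld(22, 22), resi = as.integer(num(23, 26, "residue number")),
             resn = fld(18, 20), atom = name, element = element,
             x = num(31, 38, "x coordinate"),
             y = num(39, 46, "y coordinate"),
             z = num(47, 54, "z coordinate"))
}

#' Write an atom table as a PDB file
#'
#' Used by the toy-library generator for module fragments.  Refuses atom
#' tables that exceed PDB fixed-column limits (serials, residue numbers,
#' multi-character chains) with a clear message.
#'
#' @param atoms atom table (see [read_pdb_fragment()]).
#' @param path output path.
#' @export
write_pdb_fragment <- function(atoms, path) {
  if (nrow(atoms) == 0L) stop_modcad("refusing to write empty model", "empty_model")
  if (nrow(atoms) > 99999L) {
    stop_modcad("too many atoms for PDB format; write mmCIF instead", "format_limit")
  }
  if (any(nchar(atoms$chain) != 1L)) {
    stop_modcad("PDB chain ids must be single characters; write mmCIF instead",
                "format_limit")
  }
  if (any(atoms$resi > 9999L)) {
    stop_modcad("residue number exceeds PDB format; write mmCIF instead",
                "format_limit")
  }
  pad_name <- function(a, el) {
    # atom name starts in column 14 for 1-letter elements, 13 otherwise
    ifelse(nchar(el) == 1L & nchar(a) < 4L,
           formatC(paste0(" ", a), width = -4L),
           formatC(a, width = -4L))
  }
  recs <- sprintf(
    "ATOM  %5d %s%s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)), pad_name(atoms$atom, atoms$element), " ",
    atoms$resn, atoms$chain, atoms$resi, atoms$x, atoms$y, atoms$z,
    1, 0, atoms$element)
  writeLines(c(recs, "END"), path, useBytes = TRUE)
  invisible(path)
}

#' Write an atomic model as mmCIF
#'
#' Emits a minimal `atom_site` loop (coordinates to 3 decimals, serials
#' restarting at 1, sequential across chains) that mainstream parsers read
#' back.  Chain ids longer than one character are allowed: mmCIF has no
#' chain or atom-count limit.
#'
#' @param atoms atom table (see [read_pdb_fragment()]).
#' @param path output path.
#' @param name data block name.
#' @export
write_mmcif <- function(atoms, path, name = "modcad_model") {
  if (is.null(atoms) || nrow(atoms) == 0L) {
    stop_modcad("refusing to write empty model", "empty_model")
  }
  hdr <- c(paste0("data_", name),
           "#",
           "loop_",
           "_atom_site.group_PDB",
           "_atom_site.id",
           "_atom_site.type_symbol",
           "_atom_site.label_atom_id",
           "_atom_site.label_comp_id",
           "_atom_site.label_asym_id",
           "_atom_site.label_seq_id",
           "_atom_site.Cartn_x",
           "_atom_site.Cartn_y",
           "_atom_site.Cartn_z",
           "_atom_site.occupancy",
           "_atom_site.auth_asym_id")
  recs <- sprintf("ATOM %d %s %s %s %s %d %.3f %.3f %.3f 1.00 %s",
                  seq_len(nrow(atoms)), atoms$element, atoms$atom,
                  atoms$resn, atoms$chain, atoms$resi,
                  atoms$x, atoms$y, atoms$z, atoms$chain)
  writeLines(c(hdr, recs, "#"), path, useBytes = TRUE)
  invisible(path)
}

#' Read an `atom_site` loop from an mmCIF file
#'
#' Minimal reader for files produced by [write_mmcif()] and for round-trip
#' checks; handles whitespace-separated loop rows with the columns this
#' package writes (plus any extras, located by tag name).
#'
#' @param path mmCIF file path.
#' @return atom table (see [read_pdb_fragment()]).
#' @export
read_mmcif <- function(path) {
  if (!file.exists(path)) {
    stop_modcad(sprintf("mmCIF file not found: %s", path), "io")
  }
  lines <- readLines(path, warn = FALSE)
  tags <- grep("^_atom_site\\.", lines)
  if (length(tags) == 0L) {
    stop_modcad(sprintf("no _atom_site loop in %s", path), "parse")
  }
  cols <- sub("^_atom_site\\.", "", trimws(lines[tags]))
  body <- lines[(max(tags) + 1L):length(lines)]
  body <- body[!grepl("^\\s*(#.*)?$", body) & !grepl("^(data_|loop_|_)", body)]
  rows <- strsplit(trimws(body), "\\s+")
  n_bad <- which(lengths(rows) != length(cols))
  if (length(n_bad)) {
    stop_modcad(sprintf("malformed atom_site row at %s line %d", path,
                        max(tags) + n_bad[1]), "parse")
  }
  m <- do.call(rbind, rows)
  colnames(m) <- cols
  pick <- function(tag) {
    if (!tag %in% cols) {
      stop_modcad(sprintf("mmCIF %s lacks _atom_site.%s", path, tag), "parse")
    }
    m[, tag]
  }
  atom_table(chain = pick("label_asym_id"),
             resi = as.integer(pick("label_seq_id")),
             resn = pick("label_comp_id"), atom = pick("label_atom_id"),
             element = pick("type_symbol"),
             x = as.numeric(pick("Cartn_x")), y = as.numeric(pick("Cartn_y")),
             z = as.numeric(pick("Cartn_z")))
}

# coordinates of an atom table as an n x 3 matrix
atom_coords <- function(atoms) {
  cbind(x = atoms$x, y = atoms$y, z = atoms$z)
}

# replace coordinates of an atom table
set_atom_coords <- function(atoms, xyz) {
  atoms$x <- xyz[, 1]
  atoms$y <- xyz[, 2]
  atoms$z <- xyz[, 3]
  atoms
}
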