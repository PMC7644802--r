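# Shared internals: classed conditions, canonical JSON I/O, id helpers.

stop_modcad <- function(msg, class, ...) {
  stop(errorCondition(msg,
                      class = c(paste0("modcad_", class), "modcad_error"),
                      ...))
}

#' @keywords internal
NM_PER_ANGSTROM <- 0.1

# Canonical JSON writer used for every file the package emits.  Identical
# R structures serialize to identical bytes (full numeric precision,
# stable field order comes from how callers build the lists).
write_canonical_json <- function(x, path) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                          null = "null", pretty = TRUE)
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

read_json_file <- function(path, what = "JSON file") {
  if (!file.exists(path)) {
    stop_modcad(sprintf("%s not found: %s", what, path), "io")
  }
  out <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop_modcad(sprintf("failed to parse %s '%s': %s",
                          what, path, conditionMessage(e)), "parse")
    })
  out
}

require_field <- function(obj, field, where) {
  if (is.null(obj[[field]])) {
    stop_modcad(sprintf("missing field '%s' in %s", field, where), "schema")
  }
  obj[[field]]
}

# serialize / deserialize a rigid transform as {"rot": [[..]], "tran": [..]}
rt_to_json <- function(t) {
  list(rot = lapply(seq_len(3), function(i) as.numeric(t$rot[i, ])),
       tran = as.numeric(t$tran))
}

rt_from_json <- function(obj, where = "transform") {
  rotl <- require_field(obj, "rot", where)
  tran <- as.numeric(unlist(require_field(obj, "tran", where)))
  rot <- do.call(rbind, lapply(rotl, function(r) as.numeric(unlist(r))))
  rt(rot, tran)
}

# evaluate `expr` under a given seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

vapply_chr <- function(x, f) vapply(x, f, character(1))
vapply_num <- function(x, f) vapply(x, f, numeric(1))

# chain ids A..Z, then two-letter AA, AB, ... for arbitrarily many chains
chain_id_seq <- function(n) {
  ids <- LETTERS
  k <- 1L
  while (length(ids) < n) {
    k <- k + 1L
    grid <- do.call(expand.grid,
                    c(rep(list(LETTERS), k), stringsAsFactors = FALSE))
    ids <- c(ids, sort(do.call(paste0, grid)))
  }
  ids[seq_len(n)]
}
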