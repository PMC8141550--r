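# Topology data model, readers (GRO, PDB) and the residue:atom selection
# grammar.

#' Construct a Topology
#'
#' A Topology is the static atom table shared by all replicas: atom ids
#' (contiguous from 0), atom names, residue names and numbers, elements and
#' masses.  Coordinates live in [Frame]/[Trajectory] objects, never here.
#'
#' @param atoms data.frame with columns `atom_id` (integer, contiguous from
#'   0), `atom_name`, `residue_name` (character), `residue_number` (integer),
#'   `element` (character), `mass` (amu, > 0)
#' @return object of class `Topology`
#' @export
topology <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  need <- c("atom_id", "atom_name", "residue_name", "residue_number",
            "element", "mass")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stopf("topology: missing atom columns: %s", paste(miss, collapse = ", "))
  atoms <- atoms[need]
  n <- nrow(atoms)
  if (n == 0L) stopf("topology: empty atom table")
  if (anyDuplicated(atoms$atom_id))
    stopf("topology integrity error: duplicate atom ids")
  if (!identical(as.integer(atoms$atom_id), seq_len(n) - 1L))
    stopf("topology integrity error: atom ids must be contiguous from 0")
  if (any(!nzchar(atoms$atom_name)))
    stopf("topology integrity error: empty atom name")
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stopf("topology integrity error: non-positive mass")
  structure(list(atoms = atoms, n_atoms = n), class = "Topology")
}

#' @export
print.Topology <- function(x, ...) {
  cat(sprintf("Topology: %d atoms, %d residues\n", x$n_atoms,
              length(unique(paste(x$atoms$residue_name,
                                  x$atoms$residue_number)))))
  invisible(x)
}

#' Read a molecular topology from disk
#'
#' Parses the atom records of a PDB or GRO file into a [topology()].  GRO
#' files carry no element column, and PDB files may leave it blank; in both
#' cases the element is inferred from the atom name (ion names `NA`/`SOD`,
#' `CL`/`CLA` are recognised, otherwise the leading letter).  Masses are
#' standard atomic masses for the inferred element.
#'
#' @param path file path
#' @param format `"GRO"` or `"PDB"`; defaults to the file extension
#' @return a `Topology`
#' @export
read_topology <- function(path, format = NULL) {
  if (!file.exists(path)) stopf("read_topology: file not found: %s", path)
  format <- toupper(format %||% tools::file_ext(path))
  if (!format %in% c("GRO", "PDB"))
    stopf("read_topology: unsupported format '%s' (supported: GRO, PDB)",
          format)
  if (format == "GRO") {
    blk <- parse_gro_block(readLines(path), 1L, path)
    atoms_from_gro(blk)
  } else {
    pdb <- bio3d::read.pdb(path)
    a <- pdb$atom
    elem <- a$elesy
    blank <- is.na(elem) | !nzchar(trimws(elem))
    elem[blank] <- infer_element(a$elety[blank])
    elem <- ifelse(nchar(elem) > 1,
                   paste0(toupper(substr(elem, 1, 1)),
                          tolower(substr(elem, 2, nchar(elem)))),
                   toupper(elem))
    topology(data.frame(
      atom_id = seq_len(nrow(a)) - 1L,
      atom_name = trimws(a$elety),
      residue_name = trimws(a$resid),
      residue_number = as.integer(a$resno),
      element = elem,
      mass = mass_of_element(elem),
      stringsAsFactors = FALSE))
  }
}

## Parse one GRO frame block starting at line `i`; returns fields plus the
## index one past the block.  Errors name the offending line.
parse_gro_block <- function(lines, i, path) {
  if (length(lines) < i + 1L)
    stopf("GRO format error in %s: truncated file at line %d", path, i)
  nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
  if (is.na(nat) || nat < 1L)
    stopf("GRO format error in %s, line %d: expected atom count, got '%s'",
          path, i + 1L, lines[i + 1L])
  last <- i + 1L + nat + 1L
  if (length(lines) < last)
    stopf("GRO format error in %s: truncated file (expected %d atom lines after line %d)",
          path, nat, i + 1L)
  al <- lines[(i + 2L):(i + 1L + nat)]
  bad <- which(nchar(al) < 44L)
  if (length(bad))
    stopf("GRO format error in %s, line %d: atom line too short", path,
          i + 1L + bad[1L])
  resno <- suppressWarnings(as.integer(substr(al, 1L, 5L)))
  resnm <- trimws(substr(al, 6L, 10L))
  atnm <- trimws(substr(al, 11L, 15L))
  atid <- suppressWarnings(as.integer(substr(al, 16L, 20L)))
  x <- suppressWarnings(as.numeric(substr(al, 21L, 28L)))
  y <- suppressWarnings(as.numeric(substr(al, 29L, 36L)))
  z <- suppressWarnings(as.numeric(substr(al, 37L, 44L)))
  if (anyNA(resno) || anyNA(x) || anyNA(y) || anyNA(z))
    stopf("GRO format error in %s near line %d: unparseable atom record",
          path, i + 1L + which(is.na(x + y + z + resno))[1L])
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[last]),
                                              "[[:space:]]+")[[1L]]))
  if (length(box) < 3L || anyNA(box[1:3]))
    stopf("GRO format error in %s, line %d: unparseable box line", path, last)
  t_ns <- NA_real_
  m <- regmatches(lines[i], regexec("t= *(-?[0-9.eE+-]+)", lines[i]))[[1L]]
  if (length(m) == 2L) t_ns <- as.numeric(m[2L]) / 1000  # GRO titles carry ps
  list(title = lines[i], n_atoms = nat, residue_number = resno,
       residue_name = resnm, atom_name = atnm, atom_id = atid,
       positions = cbind(x, y, z), box = box[1:3], time = t_ns,
       next_line = last + 1L)
}

atoms_from_gro <- function(blk) {
  elem <- infer_element(blk$atom_name)
  topology(data.frame(
    atom_id = seq_len(blk$n_atoms) - 1L,
    atom_name = blk$atom_name,
    residue_name = blk$residue_name,
    residue_number = blk$residue_number,
    element = elem,
    mass = mass_of_element(elem),
    stringsAsFactors = FALSE))
}

#' Select atoms by residue-number:atom-name pairs
#'
#' The selection grammar is deliberately minimal: a comma-separated list of
#' `residue_number:atom_name` pairs (e.g. `"94:O, 97:O, 434:O"` for the NA2
#' coordinating atoms), or the single token `"CA"` selecting every atom named
#' CA (the alpha-carbon fit set).  Each pair must resolve to exactly one
#' atom; ambiguity or no match is an error naming the pair.
#'
#' @param top a `Topology`
#' @param expression selection string
#' @return object of class `AtomSelection` with 1-based `indices` into the
#'   atom table, 0-based `atom_ids`, and the original `expression`
#' @export
select_atoms <- function(top, expression) {
  stopifnot(inherits(top, "Topology"), is.character(expression),
            length(expression) == 1L)
  expr <- trimws(expression)
  if (!nzchar(expr)) stopf("selection error: empty expression")
  a <- top$atoms
  if (identical(toupper(expr), "CA")) {
    idx <- which(a$atom_name == "CA")
    if (!length(idx)) stopf("selection error: no CA atoms in topology")
  } else {
    parts <- trimws(strsplit(expr, ",")[[1L]])
    parts <- parts[nzchar(parts)]
    if (!length(parts)) stopf("selection error: empty expression")
    idx <- integer(length(parts))
    for (k in seq_along(parts)) {
      pr <- strsplit(parts[k], ":")[[1L]]
      if (length(pr) != 2L)
        stopf("selection error: malformed pair '%s' (expected residue:atom)",
              parts[k])
      rn <- suppressWarnings(as.integer(trimws(pr[1L])))
      an <- trimws(pr[2L])
      if (is.na(rn) || !nzchar(an))
        stopf("selection error: malformed pair '%s'", parts[k])
      hit <- which(a$residue_number == rn & a$atom_name == an)
      if (length(hit) == 0L)
        stopf("selection error: no atom matches pair '%s'", parts[k])
      if (length(hit) > 1L)
        stopf("selection error: pair '%s' is ambiguous (%d atoms match)",
              parts[k], length(hit))
      idx[k] <- hit
    }
  }
  structure(list(expression = expression, indices = idx,
                 atom_ids = a$atom_id[idx]),
            class = "AtomSelection")
}

#' @export
print.AtomSelection <- function(x, ...) {
  cat(sprintf("AtomSelection '%s': %d atoms\n", x$expression,
              length(x$indices)))
  invisible(x)
}

#' Default coordinating-atom selections for the two sodium sites
#'
#' NA1 is coordinated by A96-O, D98-CG, N101-OD, S336-O, S336-OG and
#' N368-OD; NA2 by G94-O, V97-O and L434-O.  Note the serine hydroxyl
#' oxygen: it is conventionally named OG in topologies, and that name is
#' used here; confirm your topology's naming before relying on the default.
#' The D98 carboxylate carbon (CG) is used verbatim as a coordination proxy.
#'
#' @return selection expression string
#' @export
na1_selection_expr <- function() "96:O, 98:CG, 101:OD, 336:O, 336:OG, 368:OD"

#' @rdname na1_selection_expr
#' @export
na2_selection_expr <- function() "94:O, 97:O, 434:O"
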