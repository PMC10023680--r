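## Structure containers and PDB text I/O.
##
## Atoms are held as plain data frames with a fixed column set; a
## `chain_model` is one polypeptide chain, a `complex_model` groups chains
## into named roles (ligand = nanobody, receptor = antigen, competitor =
## native binder, scaffold = flanking domain). Multi-model PDB files map to
## lists of complex models, which is also how trajectories are represented.

ATOM_COLS <- c("serial", "atom_name", "element", "res_name", "res_seq",
               "chain_id", "x", "y", "z")

AA_321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

AA_123 <- stats::setNames(names(AA_321), unname(AA_321))

#' Build an atom table
#'
#' Constructs and validates the canonical atom data frame used throughout
#' the package. Coordinates are in Angstrom.
#'
#' @param serial integer atom serial numbers.
#' @param atom_name PDB atom names (e.g. `"CA"`).
#' @param element element symbols (`"C"`, `"N"`, ...); must be nonempty.
#' @param res_name three-letter residue names.
#' @param res_seq integer residue numbers (author numbering, kept as-is).
#' @param chain_id single-character chain identifiers.
#' @param x,y,z coordinates in Angstrom; must be finite.
#' @return a data frame with columns
#'   `serial, atom_name, element, res_name, res_seq, chain_id, x, y, z`.
#' @export
atom_table <- function(serial, atom_name, element, res_name, res_seq,
                       chain_id, x, y, z) {
  df <- data.frame(serial = as.integer(serial),
                   atom_name = as.character(atom_name),
                   element = toupper(as.character(element)),
                   res_name = toupper(as.character(res_name)),
                   res_seq = as.integer(res_seq),
                   chain_id = as.character(chain_id),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   stringsAsFactors = FALSE)
  validate_atoms(df)
  df
}

validate_atoms <- function(atoms) {
  if (!all(ATOM_COLS %in% names(atoms)))
    stop("atom table lacks columns: ",
         paste(setdiff(ATOM_COLS, names(atoms)), collapse = ", "))
  if (nrow(atoms) > 0L) {
    if (any(!nzchar(atoms$element)))
      stop("atom table contains empty element symbols")
    if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
      stop("atom table contains non-finite coordinates")
  }
  invisible(atoms)
}

#' Extract the coordinate matrix from an atom table
#' @param atoms atom data frame (see [atom_table()]).
#' @return numeric matrix with one `(x, y, z)` row per atom.
#' @export
coords <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

#' One-letter sequence of a chain's residues
#'
#' Residues are taken in order of increasing `res_seq`; non-standard residue
#' names map to `"X"`.
#' @param atoms atom data frame for a single chain.
#' @return one-letter amino-acid string.
#' @export
chain_sequence <- function(atoms) {
  res <- atoms[!duplicated(atoms$res_seq), , drop = FALSE]
  res <- res[order(res$res_seq), , drop = FALSE]
  letters1 <- AA_321[res$res_name]
  letters1[is.na(letters1)] <- "X"
  paste(letters1, collapse = "")
}

#' Single-chain model
#'
#' @param atoms atom data frame for one chain (one `chain_id`);
#'   `res_seq` must be strictly increasing along the residue order.
#' @return an object of class `chain_model` with elements `chain_id`,
#'   `atoms` and derived one-letter `sequence`.
#' @export
chain_model <- function(atoms) {
  validate_atoms(atoms)
  ids <- unique(atoms$chain_id)
  if (length(ids) != 1L)
    stop("chain_model expects exactly one chain, got: ",
         paste(ids, collapse = ", "))
  rs <- atoms$res_seq[!duplicated(atoms$res_seq)]
  if (is.unsorted(rs, strictly = TRUE))
    stop("res_seq is not strictly increasing within chain ", ids)
  structure(list(chain_id = ids, atoms = atoms,
                 sequence = chain_sequence(atoms)),
            class = "chain_model")
}

#' Grouped multi-chain model
#'
#' @param atoms atom data frame carrying an extra `group` column with values
#'   such as `"ligand"`, `"receptor"`, `"competitor"`, `"scaffold"`.
#' @param model_no model number (1-based; PDB MODEL index).
#' @return an object of class `complex_model`.
#' @export
complex_model <- function(atoms, model_no = 1L) {
  validate_atoms(atoms)
  if (is.null(atoms$group))
    stop("complex_model atoms need a 'group' column")
  structure(list(atoms = atoms, model_no = as.integer(model_no)),
            class = "complex_model")
}

#' Atoms of one group of a complex model
#' @param model a `complex_model`.
#' @param group group name, or `NULL` for all atoms.
#' @return atom data frame.
#' @export
model_atoms <- function(model, group = NULL) {
  atoms <- model$atoms
  if (is.null(group)) return(atoms)
  atoms[atoms$group %in% group, , drop = FALSE]
}

#' @export
print.complex_model <- function(x, ...) {
  cat("complex_model (model", x$model_no, "):",
      nrow(x$atoms), "atoms;",
      paste(sprintf("%s=%d", names(table(x$atoms$group)),
                    as.integer(table(x$atoms$group))), collapse = ", "),
      "\n")
  invisible(x)
}

guess_element <- function(atom_name) {
  # ATOM records of proteins: strip digits/primes, first letter is the element
  el <- sub("^[0-9' ]*", "", atom_name)
  substr(el, 1L, 1L)
}

#' Read a (multi-model) PDB file into grouped complex models
#'
#' Parses `ATOM`/`HETATM`/`MODEL`/`ENDMDL` records. Every chain named in
#' `group_spec` must be present in each model; chains not named are dropped.
#'
#' @param path PDB file.
#' @param group_spec named character vector mapping chain id to group, e.g.
#'   `c(A = "ligand", B = "receptor")`.
#' @return list of `complex_model`, one per MODEL (a single-model file gives
#'   a length-1 list).
#' @export
read_pdb <- function(path, group_spec) {
  if (!file.exists(path)) stop("no such PDB file: ", path)
  if (is.null(names(group_spec)) || any(!nzchar(names(group_spec))))
    stop("group_spec must be a named character vector (chain id -> group)")
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(lines, "MODEL")

  model_of <- cumsum(is_model)
  model_of[model_of == 0L] <- 1L  # files without MODEL records
  n_models <- max(model_of[is_atom], 1L)

  parse_block <- function(idx, model_no) {
    ln <- lines[idx]
    num <- function(a, b, what) {
      v <- suppressWarnings(as.numeric(substr(ln, a, b)))
      bad <- which(!is.finite(v))
      if (length(bad))
        stop(sprintf("malformed %s field at line %d of %s",
                     what, idx[bad[1L]], path))
      v
    }
    alt <- substr(ln, 17, 17)
    keep <- alt %in% c(" ", "", "A")
    ln <- ln[keep]; idx <- idx[keep]
    element <- trimws(substr(ln, 77, 78))
    nm <- trimws(substr(ln, 13, 16))
    element[!nzchar(element)] <- guess_element(nm[!nzchar(element)])
    atoms <- data.frame(
      serial = as.integer(num(7, 11, "serial")),
      atom_name = nm,
      element = toupper(element),
      res_name = toupper(trimws(substr(ln, 18, 20))),
      res_seq = as.integer(num(23, 26, "residue number")),
      chain_id = substr(ln, 22, 22),
      x = num(31, 38, "x coordinate"),
      y = num(39, 46, "y coordinate"),
      z = num(47, 54, "z coordinate"),
      stringsAsFactors = FALSE)
    missing <- setdiff(names(group_spec), atoms$chain_id)
    if (length(missing))
      stop("chain(s) absent from ", path, " model ", model_no, ": ",
           paste(missing, collapse = ", "))
    atoms <- atoms[atoms$chain_id %in% names(group_spec), , drop = FALSE]
    atoms$group <- unname(group_spec[atoms$chain_id])
    rownames(atoms) <- NULL
    complex_model(atoms, model_no)
  }

  lapply(seq_len(n_models), function(m) {
    idx <- which(is_atom & model_of == m)
    if (!length(idx)) stop("MODEL ", m, " of ", path, " contains no atoms")
    parse_block(idx, m)
  })
}

#' Write complex models to a PDB file
#'
#' Multi-model lists are written with `MODEL`/`ENDMDL` records, suitable as
#' toy trajectories.
#'
#' @param models a `complex_model` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(models, path) {
  if (inherits(models, "complex_model")) models <- list(models)
  multi <- length(models) > 1L
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(models)) {
    atoms <- models[[i]]$atoms
    if (multi) writeLines(sprintf("MODEL     %4d", i), con)
    nm <- ifelse(nchar(atoms$atom_name) < 4L,
                 sprintf(" %-3s", atoms$atom_name),
                 atoms$atom_name)
    writeLines(sprintf(
      "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      atoms$serial %% 100000L, nm, atoms$res_name, atoms$chain_id,
      atoms$res_seq, atoms$x, atoms$y, atoms$z, 1, 0, atoms$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Resolve a residue-range / atom-name selection to atom rows
#'
#' Residue ranges are inclusive on both ends and use author numbering.
#' Returned rows are ordered by `(chain_id, res_seq, atom_name)` so that two
#' structures with identical topology resolve to paired lists.
#'
#' @param atoms atom data frame.
#' @param residues `NULL` (all), an integer vector of residue numbers, or a
#'   list of `c(lo, hi)` inclusive ranges.
#' @param atom_names `NULL` (all) or a character vector, e.g. `"CA"`.
#' @param chains `NULL` (all) or chain ids.
#' @return atom data frame subset, deterministically ordered.
#' @export
resolve_selection <- function(atoms, residues = NULL, atom_names = NULL,
                              chains = NULL) {
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(chains)) keep <- keep & atoms$chain_id %in% chains
  if (!is.null(residues)) {
    if (is.list(residues))
      residues <- unlist(lapply(residues, function(r) seq(r[1L], r[2L])))
    keep <- keep & atoms$res_seq %in% residues
  }
  if (!is.null(atom_names)) keep <- keep & atoms$atom_name %in% atom_names
  out <- atoms[keep, , drop = FALSE]
  out[order(out$chain_id, out$res_seq, out$atom_name), , drop = FALSE]
}
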