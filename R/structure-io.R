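#' Read a protein structure from PDB or mmCIF
#'
#' Parsing is delegated to bio3d. Heteroatoms and waters are excluded from the
#' residue list by default, since downstream distance checks are Calpha-based.
#'
#' @param path Path to the structure file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param keep_hetero Re-include HETATM records (waters are always dropped).
#' @return An object of class `pep_structure`: list with `atoms` (data.frame:
#'   `chain`, `resno`, `resid`, `elety`, `x`, `y`, `z`) and `annotations`
#'   (named list of per-residue attribute data.frames).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           keep_hetero = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  pdb <- if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
         else suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$resid != "HOH", , drop = FALSE]
  if (!keep_hetero) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("empty model: no (non-water) atoms in ", path)
  atoms <- data.frame(chain = as.character(at$chain),
                      resno = as.integer(at$resno),
                      resid = as.character(at$resid),
                      elety = as.character(at$elety),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  atoms <- atoms[order(atoms$chain, atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  new_structure(atoms)
}

#' Construct a structure model from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`.
#' @return A `pep_structure`.
#' @export
new_structure <- function(atoms) {
  needed <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  stopifnot(all(needed %in% names(atoms)))
  structure(list(atoms = atoms, annotations = list()), class = "pep_structure")
}

#' @export
print.pep_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat("Structure model:", nrow(rt), "residues,", nrow(x$atoms), "atoms, chains:",
      paste(unique(rt$chain), collapse = " "), "\n")
  if (length(x$annotations) > 0L)
    cat("  annotations:", paste(names(x$annotations), collapse = ", "), "\n")
  invisible(x)
}

#' Residue-level view of a structure
#'
#' @param model A `pep_structure`.
#' @return data.frame: `chain`, `resno`, `resid`, `has_ca` (whether a CA atom
#'   is present; residues without one are unusable for distance checks).
#' @export
residue_table <- function(model) {
  a <- model$atoms
  key <- paste(a$chain, a$resno)
  first <- !duplicated(key)
  rt <- data.frame(chain = a$chain[first], resno = a$resno[first],
                   resid = a$resid[first], stringsAsFactors = FALSE)
  ca <- unique(key[a$elety == "CA"])
  rt$has_ca <- paste(rt$chain, rt$resno) %in% ca
  rt
}

# Calpha coordinate lookup: returns c(x,y,z) or NULL
ca_coords <- function(model, chain, resno) {
  a <- model$atoms
  i <- which(a$chain == chain & a$resno == resno & a$elety == "CA")
  if (length(i) == 0L) return(NULL)
  unlist(a[i[1L], c("x", "y", "z")], use.names = FALSE)
}

#' Attach a per-residue annotation to a structure
#'
#' @param model A `pep_structure`.
#' @param name Attribute name.
#' @param chain,resno Parallel vectors identifying residues (must exist in the
#'   model).
#' @param value Parallel vector of values (numeric or categorical).
#' @return The annotated model.
#' @export
set_residue_annotation <- function(model, name, chain, resno, value) {
  rt <- residue_table(model)
  have <- paste(rt$chain, rt$resno)
  want <- paste(chain, resno)
  missing <- setdiff(want, have)
  if (length(missing) > 0L)
    stop("annotation references residues absent from the model: ",
         paste(missing, collapse = ", "))
  model$annotations[[name]] <- data.frame(chain = chain, resno = resno,
                                          value = value,
                                          stringsAsFactors = FALSE)
  model
}

#' Write a per-residue attribute file (and optional B-factor PDB)
#'
#' Writes a plain-text attribute file (chain, residue number, value) for use
#' in molecular viewers. When the attribute is numeric (or categorical, via a
#' numeric encoding documented in the header), a PDB copy with the value in
#' the B-factor column is written alongside.
#'
#' @param model A `pep_structure` carrying the annotation.
#' @param attribute_name Name of an annotation set with
#'   [set_residue_annotation()].
#' @param path Output text path.
#' @param pdb_path Output PDB path, or `NULL` to skip the PDB copy.
#' @return `path`, invisibly.
#' @export
write_residue_attributes <- function(model, attribute_name, path,
                                     pdb_path = paste0(path, ".pdb")) {
  ann <- model$annotations[[attribute_name]]
  if (is.null(ann)) stop("no annotation named ", attribute_name)
  header <- paste0("# per-residue attribute: ", attribute_name)
  values <- ann$value
  if (!is.numeric(values)) {
    levels <- sort(unique(as.character(values)))
    coded <- match(as.character(values), levels)
    header <- c(header,
                paste0("# categorical encoding: ",
                       paste(sprintf("%s=%d", levels, seq_along(levels)),
                             collapse = ", ")))
    numeric_values <- coded
  } else {
    numeric_values <- values
  }
  lines <- c(header, "chain\tresno\tvalue",
             sprintf("%s\t%d\t%s", ann$chain, ann$resno, as.character(values)))
  writeLines(lines, path)
  if (!is.null(pdb_path)) {
    b <- setNames(numeric_values, paste(ann$chain, ann$resno))
    write_structure_pdb(model, pdb_path,
                        bfactor = b[paste(model$atoms$chain, model$atoms$resno)])
  }
  invisible(path)
}

#' Write a structure model as mmCIF
#'
#' Emits a minimal `atom_site` loop sufficient for round-tripping
#' coordinates, residue numbering and names.
#'
#' @param model A `pep_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_cif <- function(model, path) {
  a <- model$atoms
  elem <- toupper(substr(trimws(a$elety), 1L, 1L))
  fields <- c("group_PDB", "id", "type_symbol", "label_atom_id",
              "label_alt_id", "label_comp_id", "label_asym_id",
              "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
              "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
              "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
              "auth_comp_id", "auth_asym_id", "auth_atom_id",
              "pdbx_PDB_model_num")
  rows <- sprintf("ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
                  seq_len(nrow(a)), elem, a$elety, a$resid, a$chain, a$resno,
                  a$x, a$y, a$z, a$resno, a$resid, a$chain, a$elety)
  writeLines(c("data_pepmap", "#", "loop_",
               paste0("_atom_site.", fields), rows, "#"), path)
  invisible(path)
}

#' Write a structure model as PDB
#'
#' @param model A `pep_structure`.
#' @param path Output path.
#' @param bfactor Optional per-atom numeric vector for the B-factor column
#'   (`NA` entries become 0).
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path, bfactor = NULL) {
  a <- model$atoms
  b <- if (is.null(bfactor)) rep(0, nrow(a)) else {
    bf <- as.numeric(bfactor); bf[is.na(bf)] <- 0; bf
  }
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   elety = a$elety, b = b)
  invisible(path)
}
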