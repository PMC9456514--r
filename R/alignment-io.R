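AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' Construct a multiple alignment object
#'
#' @param sequences Named character vector of aligned sequences (names are
#'   taxon ids) over the 20 amino acids plus the gap character "-".
#' @param clades Character vector of clade labels, one per taxon (recycled
#'   named vector also accepted: names are taxon ids).
#' @return An object of class `pep_msa`: a list with `mat` (taxa x columns
#'   character matrix, rownames = taxon ids), `clade` (named character) and
#'   `n_columns`.
#' @export
new_msa <- function(sequences, clades) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("sequences must be named by taxon id")
  if (anyDuplicated(names(sequences)))
    stop("duplicate taxon ids: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]), collapse = ", "))
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment: sequence lengths ", paste(sort(unique(widths)), collapse = ", "))
  if (widths[1] < 1L) stop("alignment has zero columns")
  seqs <- toupper(sequences)
  bad <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "")[[1]]), c(AA20, "-"))
  if (length(bad) > 0L)
    stop("illegal characters in alignment: ", paste(bad, collapse = ", "))
  if (!is.null(names(clades))) {
    missing <- setdiff(names(sequences), names(clades))
    if (length(missing) > 0L)
      stop("taxa missing from clade map: ", paste(missing, collapse = ", "))
    clades <- clades[names(sequences)]
  } else {
    if (length(clades) != length(sequences))
      stop("clades must be named or match the number of sequences")
    names(clades) <- names(sequences)
  }
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(sequences)
  structure(list(mat = mat, clade = clades, n_columns = ncol(mat)),
            class = "pep_msa")
}

#' Read a multiple sequence alignment with clade labels
#'
#' Reads an aligned FASTA or Clustal file (via Biostrings) and attaches a
#' clade label to every taxon. Validation enforces a rectangular alignment,
#' the 20-amino-acid + gap alphabet, unique taxon ids and a total clade map.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @param clade_map Named character vector: taxon id -> clade label. Every
#'   taxon in the file must be assigned.
#' @return A [new_msa()] object.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal"), clade_map) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  seqs <- if (format == "fasta") {
    x <- Biostrings::readBStringSet(path)
    setNames(as.character(x), names(x))
  } else {
    x <- Biostrings::unmasked(
      Biostrings::readAAMultipleAlignment(path, format = "clustal"))
    setNames(as.character(x), names(x))
  }
  # FASTA headers may carry descriptions after the id
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  new_msa(seqs, clade_map)
}

#' Write an alignment as FASTA
#'
#' @param msa A `pep_msa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(msa, path) {
  seqs <- apply(msa$mat, 1, paste, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}

#' @export
print.pep_msa <- function(x, ...) {
  cat("Multiple alignment:", nrow(x$mat), "taxa x", x$n_columns, "columns; clades:",
      paste(sprintf("%s(%d)", names(table(x$clade)), table(x$clade)), collapse = " "),
      "\n")
  invisible(x)
}

# taxon ids belonging to a subset spec: NULL = all taxa, a clade label, or an
# explicit vector of taxon ids
msa_subset_taxa <- function(msa, subset = NULL) {
  taxa <- rownames(msa$mat)
  if (is.null(subset)) return(taxa)
  if (length(subset) == 1L && subset %in% msa$clade && !(subset %in% taxa))
    return(taxa[msa$clade == subset])
  unknown <- setdiff(subset, taxa)
  if (length(unknown) > 0L)
    stop("unknown taxa or clade: ", paste(unknown, collapse = ", "))
  subset
}
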