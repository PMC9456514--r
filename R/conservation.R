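#' Per-column identity percentage
#'
#' Identity at a column is the frequency of the modal (most common) non-gap
#' residue among the selected taxa, as a percentage of the subset size. Gaps
#' stay in the denominator but can never be the mode; an all-gap column scores
#' 0. This is the per-column statistic behind BOXSHADE-style shading, not a
#' mean pairwise identity.
#'
#' @param msa A `pep_msa`.
#' @param column 1-based column index.
#' @param subset `NULL` (all taxa), a clade label, or a vector of taxon ids.
#' @return Percentage in \[0, 100\].
#' @export
column_identity <- function(msa, column, subset = NULL) {
  taxa <- msa_subset_taxa(msa, subset)
  if (length(taxa) == 0L) stop("empty subset")
  if (column < 1L || column > msa$n_columns) stop("column out of range: ", column)
  col <- msa$mat[taxa, column]
  res <- col[col != "-"]
  if (length(res) == 0L) return(0)
  100 * max(table(res)) / length(col)
}

#' Per-column homology percentage
#'
#' Like [column_identity()] but counts membership in the modal non-gap
#' functional group (see [functional_groups()]), so conservative substitutions
#' within a group still count. Homology is therefore never below identity.
#'
#' @inheritParams column_identity
#' @param groups Functional-group partition.
#' @return Percentage in \[0, 100\].
#' @export
column_homology <- function(msa, column, subset = NULL,
                            groups = functional_groups()) {
  taxa <- msa_subset_taxa(msa, subset)
  if (length(taxa) == 0L) stop("empty subset")
  if (column < 1L || column > msa$n_columns) stop("column out of range: ", column)
  col <- msa$mat[taxa, column]
  grp <- group_of(col, groups)
  grp_res <- grp[grp != "gap"]
  if (length(grp_res) == 0L) return(0)
  100 * max(table(grp_res)) / length(col)
}

# vectorized per-column profiles over all columns
profile_columns <- function(msa, subset = NULL, groups = functional_groups()) {
  taxa <- msa_subset_taxa(msa, subset)
  if (length(taxa) == 0L) stop("empty subset")
  sub <- msa$mat[taxa, , drop = FALSE]
  n <- length(taxa)
  lut <- setNames(rep(names(groups), lengths(groups)), unlist(groups))
  lut["-"] <- "gap"
  ident <- numeric(ncol(sub)); homol <- numeric(ncol(sub))
  for (j in seq_len(ncol(sub))) {
    col <- sub[, j]
    res <- col[col != "-"]
    ident[j] <- if (length(res) == 0L) 0 else 100 * max(table(res)) / n
    grp <- unname(lut[col]); grp <- grp[grp != "gap"]
    homol[j] <- if (length(grp) == 0L) 0 else 100 * max(table(grp)) / n
  }
  list(identity = ident, homology = homol)
}

#' Centered rolling mean with shrinking end windows
#'
#' Windows are truncated (shrunk) at both ends so the output has the same
#' length as the input, which keeps profile columns alignable to structure
#' coordinates. The window must be odd so it is centered.
#'
#' @param values Numeric vector.
#' @param window_size Odd integer window width (default 11).
#' @return Numeric vector, same length as `values`.
#' @export
rolling_profile <- function(values, window_size = 11L) {
  n <- length(values)
  if (window_size %% 2L == 0L) stop("window_size must be odd")
  if (window_size < 1L) stop("window_size must be >= 1")
  if (window_size > n) stop("window_size larger than profile length")
  half <- (window_size - 1L) %/% 2L
  cs <- c(0, cumsum(values))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Conservation profiles for clade subsets
#'
#' Computes one conservation profile (per-column and rolling identity and
#' homology) for all taxa and one per requested clade, the analysis behind
#' comparing all-taxa conservation against the conservation within plants
#' carrying detected PAPs.
#'
#' @param msa A `pep_msa`.
#' @param clade_labels Clade labels to profile (default: all clades present).
#'   Every requested clade must have at least 2 members.
#' @param window_size Odd rolling-window width (default 11 residues).
#' @param groups Functional-group partition.
#' @return Named list of `conservation_profile` objects, `"all"` first, then
#'   clades in sorted order. Each has fields `subset_label`, `column_identity`,
#'   `column_homology`, `window_size`, `rolling_identity`, `rolling_homology`.
#' @export
clade_profiles <- function(msa, clade_labels = NULL, window_size = 11L,
                           groups = functional_groups()) {
  present <- sort(unique(msa$clade))
  if (is.null(clade_labels)) clade_labels <- present
  unknown <- setdiff(clade_labels, present)
  if (length(unknown) > 0L)
    stop("unknown clade label: ", paste(unknown, collapse = ", "))
  for (cl in clade_labels)
    if (sum(msa$clade == cl) < 2L) stop("singleton clade: ", cl)
  make_profile <- function(label, subset) {
    p <- profile_columns(msa, subset, groups)
    structure(list(subset_label = label,
                   column_identity = p$identity,
                   column_homology = p$homology,
                   window_size = as.integer(window_size),
                   rolling_identity = rolling_profile(p$identity, window_size),
                   rolling_homology = rolling_profile(p$homology, window_size)),
              class = "conservation_profile")
  }
  out <- c(list(all = make_profile("all", NULL)),
           setNames(lapply(sort(clade_labels),
                           function(cl) make_profile(cl, cl)),
                    sort(clade_labels)))
  out
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("Conservation profile [%s]: %d columns, window %d; mean identity %.1f%%, mean homology %.1f%%\n",
              x$subset_label, length(x$column_identity), x$window_size,
              mean(x$column_identity), mean(x$column_homology)))
  invisible(x)
}

#' Map alignment columns to reference residue numbers
#'
#' The k-th non-gap column of the reference taxon maps to reference residue k;
#' columns where the reference is gapped are unmapped. Needed to place profile
#' features on a structure numbered in reference coordinates.
#'
#' @param msa A `pep_msa`.
#' @param reference_taxon Taxon id present in the alignment.
#' @return Object of class `column_reference_map`: list with `reference_taxon`
#'   and `residue` (integer vector of length `n_columns`, `NA` at reference
#'   gap columns).
#' @export
map_columns_to_reference <- function(msa, reference_taxon) {
  if (!reference_taxon %in% rownames(msa$mat))
    stop("unknown taxon: ", reference_taxon)
  ref <- msa$mat[reference_taxon, ]
  residue <- rep(NA_integer_, length(ref))
  residue[ref != "-"] <- seq_len(sum(ref != "-"))
  structure(list(reference_taxon = reference_taxon, residue = residue),
            class = "column_reference_map")
}

#' Tabulate a profile set against reference numbering
#'
#' @param profiles Result of [clade_profiles()].
#' @param ref_map Optional [map_columns_to_reference()] result.
#' @return A data.frame with one row per alignment column: `column`,
#'   `reference_residue` (if a map is given) and, per subset,
#'   `identity_<subset>`, `homology_<subset>`, `rolling_identity_<subset>`,
#'   `rolling_homology_<subset>`.
#' @export
profile_table <- function(profiles, ref_map = NULL) {
  n <- length(profiles[[1]]$column_identity)
  out <- data.frame(column = seq_len(n))
  if (!is.null(ref_map)) out$reference_residue <- ref_map$residue
  for (p in profiles) {
    lab <- p$subset_label
    out[[paste0("identity_", lab)]] <- p$column_identity
    out[[paste0("homology_", lab)]] <- p$column_homology
    out[[paste0("rolling_identity_", lab)]] <- p$rolling_identity
    out[[paste0("rolling_homology_", lab)]] <- p$rolling_homology
  }
  out
}
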