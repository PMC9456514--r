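#' Classify alignment columns between two clades
#'
#' Each column is compared between clade A (e.g. the PEP/chloroplast clade)
#' and clade B (e.g. bacterial references): `gap` when either clade is
#' majority-gap (> 50%), `homologous` when the modal residues of the two
#' clades share a functional group, `nonhomologous` otherwise. Modal-residue
#' ties break alphabetically for determinism.
#'
#' @param msa A `pep_msa`.
#' @param clade_A,clade_B Clade labels or taxon-id vectors; non-empty and
#'   disjoint.
#' @param groups Functional-group partition.
#' @return data.frame, one row per column: `column`, `class`, `modal_A`,
#'   `modal_B`, `group_A`, `group_B`.
#' @export
classify_columns <- function(msa, clade_A, clade_B,
                             groups = functional_groups()) {
  taxa_A <- msa_subset_taxa(msa, clade_A)
  taxa_B <- msa_subset_taxa(msa, clade_B)
  if (length(taxa_A) == 0L || length(taxa_B) == 0L) stop("empty clade")
  if (length(intersect(taxa_A, taxa_B)) > 0L)
    stop("overlapping clades: ", paste(intersect(taxa_A, taxa_B), collapse = ", "))
  modal_info <- function(col) {
    res <- col[col != "-"]
    gap_frac <- 1 - length(res) / length(col)
    if (length(res) == 0L) return(list(gap_frac = gap_frac, modal = NA_character_))
    tab <- table(res)
    modal <- sort(names(tab)[tab == max(tab)])[1L]
    list(gap_frac = gap_frac, modal = modal)
  }
  n <- msa$n_columns
  out <- data.frame(column = seq_len(n), class = NA_character_,
                    modal_A = NA_character_, modal_B = NA_character_,
                    group_A = NA_character_, group_B = NA_character_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(n)) {
    A <- modal_info(msa$mat[taxa_A, j]); B <- modal_info(msa$mat[taxa_B, j])
    if (A$gap_frac > 0.5 || B$gap_frac > 0.5 || is.na(A$modal) || is.na(B$modal)) {
      out$class[j] <- "gap"
    } else {
      gA <- group_of(A$modal, groups); gB <- group_of(B$modal, groups)
      out$class[j] <- if (gA == gB) "homologous" else "nonhomologous"
      out$group_A[j] <- gA; out$group_B[j] <- gB
    }
    out$modal_A[j] <- A$modal; out$modal_B[j] <- B$modal
  }
  out
}

#' Find runs of strong functional-group change
#'
#' A column shows a strong functional-group change when it is nonhomologous
#' between the two clades (the modal functional groups differ and neither
#' clade is majority-gap). Maximal runs of such columns, consecutive in
#' reference-residue numbering (reference gap columns break runs), are
#' reported when at least `min_run` residues long — the "at least 3
#' consecutive amino acids" rule.
#'
#' @param classes Result of [classify_columns()].
#' @param ref_map A [map_columns_to_reference()] result.
#' @param min_run Minimum run length in residues (default 3).
#' @return data.frame: `run_id`, `start_residue`, `end_residue`, `length`.
#' @export
find_strong_change_runs <- function(classes, ref_map, min_run = 3L) {
  strong <- classes$class == "nonhomologous" &
    !is.na(classes$group_A) & !is.na(classes$group_B) &
    classes$group_A != classes$group_B
  res <- ref_map$residue
  flagged <- sort(res[strong & !is.na(res)])
  if (length(flagged) == 0L)
    return(data.frame(run_id = integer(0), start_residue = integer(0),
                      end_residue = integer(0), length = integer(0)))
  breaks <- c(0L, which(diff(flagged) > 1L), length(flagged))
  runs <- do.call(rbind, lapply(seq_len(length(breaks) - 1L), function(k) {
    seg <- flagged[(breaks[k] + 1L):breaks[k + 1L]]
    data.frame(start_residue = seg[1L], end_residue = seg[length(seg)],
               length = length(seg))
  }))
  runs <- runs[runs$length >= min_run, , drop = FALSE]
  if (nrow(runs) == 0L)
    return(data.frame(run_id = integer(0), start_residue = integer(0),
                      end_residue = integer(0), length = integer(0)))
  runs <- runs[order(runs$start_residue), , drop = FALSE]
  data.frame(run_id = seq_len(nrow(runs)), runs, row.names = NULL)
}

#' Per-reference-residue divergence annotation
#'
#' Combines [classify_columns()], [map_columns_to_reference()] and
#' [find_strong_change_runs()] into one table in reference coordinates.
#'
#' @inheritParams classify_columns
#' @param reference_taxon Taxon whose residue numbering anchors the output.
#' @param min_run Minimum strong-change run length.
#' @return data.frame: `residue`, `class`, `strong_change`, `run_id` (`NA`
#'   outside runs).
#' @export
divergence_annotation <- function(msa, clade_A, clade_B, reference_taxon,
                                  min_run = 3L, groups = functional_groups()) {
  classes <- classify_columns(msa, clade_A, clade_B, groups)
  ref_map <- map_columns_to_reference(msa, reference_taxon)
  keep <- !is.na(ref_map$residue)
  ann <- data.frame(residue = ref_map$residue[keep],
                    class = classes$class[keep],
                    strong_change = FALSE, run_id = NA_integer_,
                    stringsAsFactors = FALSE)
  runs <- find_strong_change_runs(classes, ref_map, min_run)
  for (k in seq_len(nrow(runs))) {
    in_run <- ann$residue >= runs$start_residue[k] &
      ann$residue <= runs$end_residue[k]
    ann$strong_change[in_run] <- TRUE
    ann$run_id[in_run] <- runs$run_id[k]
  }
  attr(ann, "runs") <- runs
  ann
}

#' Map a divergence annotation onto a structure
#'
#' @param annotation A [divergence_annotation()] data.frame (or any data.frame
#'   with `residue`, `class`, `strong_change`).
#' @param model A `pep_structure`.
#' @param chain The chain carrying the annotated subunit.
#' @return list: `model` (with `class` and `strong_change` residue
#'   annotations), `n_mapped`, `n_unmapped`.
#' @export
map_annotations_to_structure <- function(annotation, model, chain) {
  rt <- residue_table(model)
  if (!chain %in% rt$chain) stop("chain absent from model: ", chain)
  present <- rt$resno[rt$chain == chain]
  hit <- annotation$residue %in% present
  n_mapped <- sum(hit); n_unmapped <- sum(!hit)
  if (n_mapped > 0L) {
    mapped <- annotation[hit, , drop = FALSE]
    model <- set_residue_annotation(model, "class",
                                    rep(chain, n_mapped), mapped$residue,
                                    mapped$class)
    model <- set_residue_annotation(model, "strong_change",
                                    rep(chain, n_mapped), mapped$residue,
                                    mapped$strong_change)
  }
  list(model = model, n_mapped = n_mapped, n_unmapped = n_unmapped)
}

#' Surface enrichment of variable sites
#'
#' Tests whether variable (nonhomologous, optionally gap) residues sit at the
#' protein surface more often than conserved (homologous) residues: a 2x2
#' contingency table of variable/conserved x exposed/buried, with the sample
#' odds ratio and a two-sided exact (Fisher) test. The claim "variable sites
#' lie at the surface" corresponds to `fraction_variable_exposed >
#' fraction_conserved_exposed` (odds ratio > 1).
#'
#' @param model A `pep_structure` carrying a `class` annotation.
#' @param accessibility An `accessibility_result` from [compute_sasa()].
#' @param variable_classes Classes counted as variable (default
#'   `c("nonhomologous", "gap")`; pass `"nonhomologous"` to exclude gap
#'   columns).
#' @return list: `table` (2x2), `fraction_variable_exposed`,
#'   `fraction_conserved_exposed`, `odds_ratio` (sample OR; `NA` with
#'   `degenerate = TRUE` when a margin is zero), `p_value`, `degenerate`.
#' @export
surface_enrichment <- function(model, accessibility,
                               variable_classes = c("nonhomologous", "gap")) {
  ann <- model$annotations[["class"]]
  if (is.null(ann)) stop("model has no 'class' annotation")
  key <- paste(ann$chain, ann$resno)
  akey <- paste(accessibility$chain, accessibility$resno)
  exposed <- setNames(accessibility$exposed, akey)[key]
  keep <- !is.na(exposed)
  variable <- ann$value[keep] %in% variable_classes
  conserved <- ann$value[keep] == "homologous"
  use <- variable | conserved
  variable <- variable[use]; exp_use <- exposed[keep][use]
  if (sum(variable) == 0L || sum(!variable) == 0L)
    stop("need at least one variable and one conserved residue with accessibility")
  tab <- matrix(c(sum(variable & exp_use), sum(variable & !exp_use),
                  sum(!variable & exp_use), sum(!variable & !exp_use)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("variable", "conserved"),
                                c("exposed", "buried")))
  degenerate <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)
  odds_ratio <- if (degenerate || tab[1, 2] * tab[2, 1] == 0L) NA_real_
                else (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  p <- fisher.test(tab)$p.value
  list(table = tab,
       fraction_variable_exposed = tab[1, 1] / sum(tab[1, ]),
       fraction_conserved_exposed = tab[2, 1] / sum(tab[2, ]),
       odds_ratio = odds_ratio, p_value = p, degenerate = degenerate)
}
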