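#' Simulate a multiple sequence alignment with known ground truth
#'
#' Emulates the conservation architecture of RNAP core-subunit alignments:
#' conserved catalytic blocks identical across all taxa, variable surface
#' patches where each clade has its own consensus mutated per taxon at a
#' given rate, and a clade-specific insertion that appears as gaps outside
#' its clade. Deterministic per seed.
#'
#' @param spec List: `clades` (data.frame `label`, `n_taxa`, each >= 2),
#'   `length` (columns), `conserved_blocks` (list of `c(start, end)`),
#'   `variable_patches` (list of `c(start, end)`), `clade_insertion`
#'   (optional list `label`, `range = c(start, end)`),
#'   `substitution_rate` (per-taxon mutation probability in variable patches,
#'   default 0.5), `seed`.
#' @return List: `msa` (a `pep_msa`), `truth` (list with `column_class`,
#'   a per-column factor in \{conserved, variable, insertion, background\},
#'   and the expanded `spec`).
#' @export
simulate_msa <- function(spec) {
  stopifnot(!is.null(spec$clades), !is.null(spec$length), !is.null(spec$seed))
  if (any(spec$clades$n_taxa < 2L)) stop("each clade needs >= 2 taxa")
  L <- spec$length
  rate <- if (is.null(spec$substitution_rate)) 0.5 else spec$substitution_rate
  ranges <- c(spec$conserved_blocks, spec$variable_patches,
              if (!is.null(spec$clade_insertion)) list(spec$clade_insertion$range))
  cols_used <- integer(0)
  for (r in ranges) {
    if (r[1] < 1L || r[2] > L || r[1] > r[2]) stop("invalid range: ",
                                                   paste(r, collapse = "-"))
    if (any(seq(r[1], r[2]) %in% cols_used)) stop("overlapping ranges")
    cols_used <- c(cols_used, seq(r[1], r[2]))
  }
  set.seed(spec$seed)
  taxa <- unlist(lapply(seq_len(nrow(spec$clades)), function(i)
    sprintf("%s_t%02d", spec$clades$label[i], seq_len(spec$clades$n_taxa[i]))))
  clades <- rep(spec$clades$label, spec$clades$n_taxa)
  names(clades) <- taxa
  ancestral <- sample(AA20, L, replace = TRUE)
  mat <- matrix(rep(ancestral, each = length(taxa)), nrow = length(taxa),
                dimnames = list(taxa, NULL))
  column_class <- rep("background", L)
  for (r in spec$conserved_blocks) column_class[seq(r[1], r[2])] <- "conserved"
  for (r in spec$variable_patches) {
    for (j in seq(r[1], r[2])) {
      column_class[j] <- "variable"
      consensus <- setNames(sample(AA20, nrow(spec$clades), replace = TRUE),
                            spec$clades$label)
      for (t in seq_along(taxa)) {
        base <- consensus[[clades[t]]]
        mat[t, j] <- if (runif(1) < rate) sample(AA20, 1L) else base
      }
    }
  }
  if (!is.null(spec$clade_insertion)) {
    r <- spec$clade_insertion$range
    outside <- clades != spec$clade_insertion$label
    column_class[seq(r[1], r[2])] <- "insertion"
    mat[outside, seq(r[1], r[2])] <- "-"
  }
  msa <- new_msa(setNames(apply(mat, 1, paste, collapse = ""), taxa), clades)
  list(msa = msa,
       truth = list(column_class = column_class, spec = spec))
}

#' Simulate a toy protein structure with known exposure
#'
#' Two folds: `helix`, an ideal alpha-helix Calpha trace (rise 1.5 Angstrom,
#' 100 degrees per residue, radius 2.3 Angstrom, giving the canonical ~3.8
#' Angstrom consecutive Calpha spacing); and `two_shell`, an inner Calpha
#' cluster (ground-truth buried) enclosed by a dense outer spherical shell
#' (ground-truth exposed). Purely deterministic.
#'
#' @param n_residues Number of residues (>= 2; `two_shell` needs >= 10).
#' @param fold `"helix"` or `"two_shell"`.
#' @param chain Chain id (default "A").
#' @param path Optional output path; when given, a PDB file is written.
#' @return List: `model` (a `pep_structure`), `exposed_truth` (logical per
#'   residue; all `NA` for helix, where no exposure truth is defined),
#'   `path`.
#' @export
simulate_structure <- function(n_residues, fold = c("helix", "two_shell"),
                               chain = "A", path = NULL) {
  fold <- match.arg(fold)
  if (n_residues < 2L) stop("n_residues must be >= 2")
  if (fold == "helix") {
    i <- seq_len(n_residues) - 1L
    theta <- i * 100 * pi / 180
    xyz <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
    exposed <- rep(NA, n_residues)
  } else {
    if (n_residues < 10L) stop("two_shell needs n_residues >= 10")
    n_inner <- max(4L, n_residues %/% 5L)
    n_outer <- n_residues - n_inner
    xyz <- rbind(sphere_points(n_inner) * 1.2, sphere_points(n_outer) * 8.0)
    exposed <- c(rep(FALSE, n_inner), rep(TRUE, n_outer))
  }
  atoms <- data.frame(chain = chain, resno = seq_len(n_residues),
                      resid = "ALA", elety = "CA",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  model <- new_structure(atoms)
  if (!is.null(path)) write_structure_pdb(model, path)
  list(model = model, exposed_truth = exposed, path = path)
}

# 9-residue tryptic block: eight non-K/R residues then K, so a protein of
# b blocks has exactly b fully cleaved peptides, all of length 9 (observable)
TRYPTIC_BLOCK <- "ADGFESTLK"

#' Simulate MS1 intensity tables from known subunit copy numbers
#'
#' Protein sequences are built from 9-residue tryptic blocks so the
#' theoretical observable peptide count is analytically known (one per
#' block). Per replicate, each protein's summed MS1 intensity is
#' `copy_number x peptide_count x lognormal(0, sigma) x replicate_scale`,
#' emulating multiplicative MS1 intensity noise; iBAQ then recovers copy
#' numbers up to noise. Deterministic per seed.
#'
#' @param spec List: `subunits` (data.frame `name`, `length` (residues,
#'   rounded to whole blocks), `copy_number` >= 1), `noise_sigma` (log-scale
#'   lognormal sigma, default 0.3), `n_replicates` (default 3),
#'   `replicate_scales` (optional numeric, default all 1e6), `seed`.
#' @return List: `intensities` (data.frame `protein_id`, `replicate_id`,
#'   `intensity`), `sequences` (named character), `truth` (list
#'   `copy_number`, `peptide_count`, named by protein).
#' @export
simulate_intensities <- function(spec) {
  stopifnot(!is.null(spec$subunits), !is.null(spec$seed))
  su <- spec$subunits
  if (any(su$copy_number < 1)) stop("copy numbers must be >= 1")
  sigma <- if (is.null(spec$noise_sigma)) 0.3 else spec$noise_sigma
  n_rep <- if (is.null(spec$n_replicates)) 3L else spec$n_replicates
  scales <- if (is.null(spec$replicate_scales)) rep(1e6, n_rep)
            else spec$replicate_scales
  stopifnot(length(scales) == n_rep)
  n_blocks <- pmax(1L, round(su$length / nchar(TRYPTIC_BLOCK)))
  sequences <- setNames(strrep(TRYPTIC_BLOCK, n_blocks), su$name)
  set.seed(spec$seed)
  rows <- expand.grid(protein = seq_len(nrow(su)), rep = seq_len(n_rep))
  intensities <- data.frame(
    protein_id = su$name[rows$protein],
    replicate_id = sprintf("rep%d", rows$rep),
    intensity = su$copy_number[rows$protein] * n_blocks[rows$protein] *
      exp(rnorm(nrow(rows), 0, sigma)) * scales[rows$rep],
    stringsAsFactors = FALSE)
  list(intensities = intensities, sequences = sequences,
       truth = list(copy_number = setNames(su$copy_number, su$name),
                    peptide_count = setNames(n_blocks, su$name)))
}

#' Simulate a crosslink dipeptide table with planted clusters
#'
#' Emits a table in the printed-dipeptide dialect (bracketed peptides,
#' From/To spans, relative site codes) containing planted intra-cluster
#' links with scores above the identification cutoff (uniform on
#' \[40, 130\]) and decoy links to non-member partners with scores spanning
#' the cutoff (uniform on \[0, 60\]), so score filtering is exercised on
#' both sides of 30. True cluster labels ship alongside. Deterministic per
#' seed.
#'
#' @param spec List: `clusters` (list of character vectors of protein
#'   names; consecutive members of each cluster are linked), `n_decoys`
#'   (default 0), `seed`, optional `planted` (data.frame `protein_1`,
#'   `protein_2`, `pos_1`, `pos_2` overriding the link positions).
#' @return List: `table` (data.frame with the dipeptide-table columns),
#'   `truth` (list `clusters`, `decoy_rows`).
#' @export
simulate_crosslinks <- function(spec) {
  stopifnot(!is.null(spec$clusters), !is.null(spec$seed))
  set.seed(spec$seed)
  n_decoys <- if (is.null(spec$n_decoys)) 0L else spec$n_decoys
  links <- if (!is.null(spec$planted)) spec$planted else {
    do.call(rbind, lapply(spec$clusters, function(cl) {
      if (length(cl) < 2L) return(NULL)
      data.frame(protein_1 = cl[-length(cl)], protein_2 = cl[-1L],
                 pos_1 = sample(10:200, length(cl) - 1L, replace = TRUE),
                 pos_2 = sample(10:200, length(cl) - 1L, replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
  }
  n_planted <- nrow(links)
  scores <- round(runif(n_planted, 40, 130), 2)
  if (n_decoys > 0L) {
    donors <- unlist(spec$clusters)
    links <- rbind(links, data.frame(
      protein_1 = sample(donors, n_decoys, replace = TRUE),
      protein_2 = sprintf("DECOY%d", seq_len(n_decoys)),
      pos_1 = sample(10:200, n_decoys, replace = TRUE),
      pos_2 = sample(10:200, n_decoys, replace = TRUE),
      stringsAsFactors = FALSE))
    scores <- c(scores, round(runif(n_decoys, 0, 60), 2))
  }
  # link peptide: 7-mer with the crosslinked K at relative position 4
  peptide <- "GSAKLVR"
  tab <- data.frame(row = seq_len(nrow(links)),
                    protein_1 = links$protein_1, protein_2 = links$protein_2,
                    score = scores,
                    peptide_1 = paste0("[", peptide, "]"),
                    from_1 = links$pos_1 - 3L, to_1 = links$pos_1 + 3L,
                    aa_1 = "K4",
                    peptide_2 = paste0("[", peptide, "]"),
                    from_2 = links$pos_2 - 3L, to_2 = links$pos_2 + 3L,
                    aa_2 = "K4",
                    stringsAsFactors = FALSE)
  list(table = tab,
       truth = list(clusters = spec$clusters,
                    decoy_rows = if (n_decoys > 0L)
                      seq.int(n_planted + 1L, n_planted + n_decoys)
                    else integer(0)))
}

#' Write a simulated dipeptide table to disk
#'
#' @param table The `table` element of [simulate_crosslinks()].
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_crosslink_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
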