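#' In-silico tryptic digestion (Trypsin/P)
#'
#' Cleaves after every Lys or Arg, including before proline (the Trypsin/P
#' rule), and enumerates peptides containing up to `missed_cleavages` internal
#' cleavage sites, with 1-based inclusive spans.
#'
#' @param sequence Protein sequence over the 20 amino acids.
#' @param missed_cleavages Maximum internal missed cleavage sites (default 0).
#' @return data.frame: `peptide`, `start`, `end`, `missed`.
#' @export
tryptic_digest <- function(sequence, missed_cleavages = 0L) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(chars), AA20)
  if (length(bad) > 0L)
    stop("illegal characters in sequence: ", paste(bad, collapse = ", "))
  n <- length(chars)
  cut_after <- which(chars %in% c("K", "R"))
  bounds <- unique(c(0L, cut_after[cut_after < n], n))
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  nfrag <- length(starts)
  out <- list()
  for (i in seq_len(nfrag)) {
    for (m in 0:missed_cleavages) {
      j <- i + m
      if (j > nfrag) break
      out[[length(out) + 1L]] <- data.frame(
        peptide = paste(chars[starts[i]:ends[j]], collapse = ""),
        start = starts[i], end = ends[j], missed = m,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Number of theoretically observable tryptic peptides
#'
#' The iBAQ denominator: fully cleaved (zero missed cleavage) tryptic
#' peptides whose length falls in the observable range, 6-30 residues by
#' convention.
#'
#' @param sequence Protein sequence.
#' @param len_range Observable length range, inclusive (default `c(6, 30)`).
#' @return Integer count.
#' @export
theoretical_peptide_count <- function(sequence, len_range = c(6L, 30L)) {
  stopifnot(length(len_range) == 2L, len_range[1] <= len_range[2])
  pep <- tryptic_digest(sequence, missed_cleavages = 0L)
  len <- nchar(pep$peptide)
  sum(len >= len_range[1] & len <= len_range[2])
}

#' iBAQ quantification with per-sample normalization
#'
#' For every protein and replicate, the raw iBAQ value is the summed MS1
#' intensity divided by the protein's theoretical observable peptide count.
#' Within each replicate, iBAQ values are normalized by the replicate total
#' (so each replicate's normalized values sum to 1) before being combined
#' across replicates — by summation (default) or by the mean — into the final
#' iBAQ. iBAQr expresses final iBAQ relative to the alpha subunit. Proteins
#' absent from a replicate contribute 0 for that replicate; proteins with no
#' observable peptide are excluded with a warning.
#'
#' @param intensities data.frame: `protein_id`, `replicate_id`, `intensity`
#'   (summed MS1 intensity, >= 0).
#' @param sequences Named character vector of protein sequences (one per
#'   quantified protein).
#' @param alpha_id Protein id of the alpha subunit used as the iBAQr
#'   reference (default `"rpoA"`).
#' @param len_range Observable peptide length range for the denominator.
#' @param combine `"sum"` (default) or `"mean"` across replicates.
#' @param peptides Optional data.frame `protein_id`, `start`, `end` of
#'   observed peptides for sequence coverage.
#' @return Object of class `ibaq_result`: list with `table` (data.frame:
#'   `protein_id`, `n_theoretical`, `final_ibaq`, `ibaqr`, `coverage`),
#'   `normalized` (protein x replicate matrix of per-replicate normalized
#'   iBAQ), `replicates`, `alpha_id`, `alpha_found`.
#' @export
compute_ibaq <- function(intensities, sequences, alpha_id = "rpoA",
                         len_range = c(6L, 30L), combine = c("sum", "mean"),
                         peptides = NULL) {
  combine <- match.arg(combine)
  stopifnot(all(c("protein_id", "replicate_id", "intensity") %in%
                  names(intensities)))
  if (any(intensities$intensity < 0)) stop("negative intensity")
  prots <- sort(unique(intensities$protein_id))
  missing_seq <- setdiff(prots, names(sequences))
  if (length(missing_seq) > 0L)
    stop("no sequence for: ", paste(missing_seq, collapse = ", "))
  counts <- vapply(sequences[prots], theoretical_peptide_count, integer(1),
                   len_range = len_range)
  zero <- counts == 0L
  if (any(zero)) {
    warning("excluded (no observable tryptic peptide): ",
            paste(prots[zero], collapse = ", "))
    prots <- prots[!zero]; counts <- counts[!zero]
  }
  if (length(prots) == 0L) stop("no quantifiable protein")
  reps <- sort(unique(intensities$replicate_id))
  raw <- matrix(0, nrow = length(prots), ncol = length(reps),
                dimnames = list(prots, reps))
  keep <- intensities$protein_id %in% prots
  idx <- cbind(match(intensities$protein_id[keep], prots),
               match(intensities$replicate_id[keep], reps))
  raw[idx] <- raw[idx] + intensities$intensity[keep] /
    counts[match(intensities$protein_id[keep], prots)]
  totals <- colSums(raw)
  if (any(totals == 0)) stop("replicate with zero total intensity: ",
                             paste(reps[totals == 0], collapse = ", "))
  normalized <- sweep(raw, 2L, totals, "/")
  final <- if (combine == "sum") rowSums(normalized) else rowMeans(normalized)
  alpha_found <- alpha_id %in% prots
  if (!alpha_found)
    warning("alpha subunit '", alpha_id, "' not quantified; iBAQr unavailable")
  ibaqr <- if (alpha_found) final / final[alpha_id] else rep(NA_real_, length(final))
  coverage <- rep(NA_real_, length(prots))
  if (!is.null(peptides)) {
    for (i in seq_along(prots)) {
      sp <- peptides[peptides$protein_id == prots[i], , drop = FALSE]
      coverage[i] <- sequence_coverage(sp, nchar(sequences[[prots[i]]]))
    }
  }
  tab <- data.frame(protein_id = prots, n_theoretical = unname(counts),
                    final_ibaq = unname(final), ibaqr = unname(ibaqr),
                    coverage = coverage, stringsAsFactors = FALSE)
  structure(list(table = tab, normalized = normalized, replicates = reps,
                 alpha_id = alpha_id, alpha_found = alpha_found),
            class = "ibaq_result")
}

#' @export
print.ibaq_result <- function(x, ...) {
  cat("iBAQ result:", nrow(x$table), "proteins,", length(x$replicates),
      "replicates; reference:", x$alpha_id,
      if (!x$alpha_found) "(not found)" else "", "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Protein sequence coverage from peptide spans
#'
#' @param spans data.frame with `start`, `end` (1-based inclusive).
#' @param protein_length Protein length in residues.
#' @return Percentage of residues covered by at least one peptide
#'   (overlaps counted once).
#' @export
sequence_coverage <- function(spans, protein_length) {
  if (nrow(spans) == 0L) return(0)
  if (any(spans$start < 1L) || any(spans$end > protein_length) ||
      any(spans$start > spans$end))
    stop("peptide span outside protein [1, ", protein_length, "]")
  covered <- logical(protein_length)
  for (i in seq_len(nrow(spans)))
    covered[spans$start[i]:spans$end[i]] <- TRUE
  100 * sum(covered) / protein_length
}

#' Subunit stoichiometry from final iBAQ values
#'
#' Ratios of final iBAQ values for requested subunit pairs — e.g. the
#' alpha:beta ratio, expected near 2 for an RNAP core with two alpha copies
#' per beta — with a bootstrap percentile interval obtained by resampling
#' replicates (requires >= 2 replicates; degenerate otherwise).
#'
#' @param ibaq An `ibaq_result`.
#' @param pairs List of `c(numerator, denominator)` protein-id pairs.
#' @param n_boot Bootstrap draws (default 1000).
#' @param conf Interval coverage (default 0.95).
#' @return data.frame: `numerator`, `denominator`, `ratio`, `ci_lower`,
#'   `ci_upper`.
#' @export
estimate_stoichiometry <- function(ibaq, pairs, n_boot = 1000L, conf = 0.95) {
  if (is.character(pairs)) pairs <- list(pairs)
  norm <- ibaq$normalized
  out <- do.call(rbind, lapply(pairs, function(p) {
    stopifnot(length(p) == 2L)
    if (!all(p %in% rownames(norm)))
      stop("pair member not quantified: ",
           paste(setdiff(p, rownames(norm)), collapse = ", "))
    fa <- sum(norm[p[1], ]); fb <- sum(norm[p[2], ])
    if (fb == 0) stop("zero denominator for ", p[2])
    ci <- c(NA_real_, NA_real_)
    nrep <- ncol(norm)
    if (nrep >= 2L) {
      ratios <- vapply(seq_len(n_boot), function(b) {
        cols <- sample.int(nrep, nrep, replace = TRUE)
        den <- sum(norm[p[2], cols])
        if (den == 0) return(NA_real_)
        sum(norm[p[1], cols]) / den
      }, numeric(1))
      ci <- unname(quantile(ratios, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                            na.rm = TRUE))
    }
    data.frame(numerator = p[1], denominator = p[2], ratio = fa / fb,
               ci_lower = ci[1], ci_upper = ci[2], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
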