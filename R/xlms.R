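# Header synonyms for crosslink tables: the printed-table dialect
# ("Protein 1 Names", "xLinkScore", duplicated From/To columns) and a
# MeroX-style export with the same semantic columns both normalize onto the
# canonical column set.
normalize_xl_headers <- function(nms) {
  norm <- gsub("[^a-z0-9]", "", tolower(nms))
  syn <- c(row = "row", x = "row", number = "row", id = "row",
           protein1names = "protein_1", protein1 = "protein_1",
           protein2names = "protein_2", protein2 = "protein_2",
           xlinkscore = "score", score = "score",
           peptide1 = "peptide_1", peptide2 = "peptide_2",
           from = "from_1", from1 = "from_1", to = "to_1", to1 = "to_1",
           from2 = "from_2", to2 = "to_2",
           aa1 = "site_1", aa2 = "site_2",
           replicate = "replicate_id", replicateid = "replicate_id")
  out <- unname(syn[norm])
  # duplicated positional From/To/aa pairs (printed-table layout): the second
  # occurrence belongs to peptide 2
  for (col in c("from_1", "to_1", "site_1")) {
    idx <- which(out == col)
    if (length(idx) == 2L) out[idx[2L]] <- sub("_1$", "_2", col)
  }
  out
}

strip_brackets <- function(x) gsub("[][(){}<>]", "", trimws(x))

#' Parse a crosslink dipeptide table
#'
#' Reads a delimited (tab or comma) hetero-dipeptide table in the printed
#' Table-1 dialect or a MeroX-style export with the same semantic columns:
#' partner protein names, crosslink score, both peptide sequences with their
#' 1-based inclusive protein spans (From/To), and the crosslinked amino acid
#' with its 1-based position relative to the peptide (e.g. "K5"). Bracket
#' characters around peptides are stripped. Absolute crosslink positions are
#' computed as `from + relative - 1`. Rows whose span length disagrees with
#' the peptide length are kept but flagged (`span_mismatch_1/2`), never
#' silently fixed.
#'
#' @param path Path to the table.
#' @param replicate_id Replicate label attached to every record lacking one.
#' @return data.frame of class `xlms_records`: `row`, `protein_1`,
#'   `protein_2`, `score`, `peptide_1`, `from_1`, `to_1`, `site_res_1`,
#'   `site_pos_1`, `absolute_1`, the peptide-2 counterparts, `replicate_id`,
#'   `span_mismatch_1`, `span_mismatch_2`.
#' @export
parse_crosslink_table <- function(path, replicate_id = "r1") {
  if (!file.exists(path)) stop("crosslink table not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE, quote = "",
                    check.names = TRUE)
  canon <- normalize_xl_headers(names(raw))
  keep <- !is.na(canon)
  raw <- raw[, keep, drop = FALSE]
  names(raw) <- canon[keep]
  needed <- c("protein_1", "protein_2", "score", "peptide_1", "from_1", "to_1",
              "site_1", "peptide_2", "from_2", "to_2", "site_2")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0L)
    stop("crosslink table lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(raw) == 0L) {
    warning("empty crosslink table: ", path)
    return(empty_xlms_records())
  }
  parse_site <- function(x, which) {
    m <- regmatches(x, regexec("^\\s*([A-Za-z])\\s*([0-9]+)\\s*$", x))
    bad <- vapply(m, length, integer(1)) != 3L
    if (any(bad))
      stop("unparsable crosslink site (", which, "): ",
           paste(x[bad], collapse = ", "))
    list(res = toupper(vapply(m, `[`, character(1), 2L)),
         pos = as.integer(vapply(m, `[`, character(1), 3L)))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (any(is.na(v))) stop("non-numeric values in column ", col)
    v
  }
  s1 <- parse_site(raw$site_1, "aa 1"); s2 <- parse_site(raw$site_2, "aa 2")
  rec <- data.frame(
    row = if ("row" %in% names(raw)) as.integer(raw$row) else seq_len(nrow(raw)),
    protein_1 = trimws(raw$protein_1), protein_2 = trimws(raw$protein_2),
    score = num("score"),
    peptide_1 = strip_brackets(raw$peptide_1),
    from_1 = as.integer(num("from_1")), to_1 = as.integer(num("to_1")),
    site_res_1 = s1$res, site_pos_1 = s1$pos,
    peptide_2 = strip_brackets(raw$peptide_2),
    from_2 = as.integer(num("from_2")), to_2 = as.integer(num("to_2")),
    site_res_2 = s2$res, site_pos_2 = s2$pos,
    replicate_id = if ("replicate_id" %in% names(raw))
      as.character(raw$replicate_id) else replicate_id,
    stringsAsFactors = FALSE)
  if (any(rec$score < 0)) stop("negative crosslink score")
  if (any(rec$from_1 > rec$to_1) || any(rec$from_2 > rec$to_2))
    stop("span with from > to")
  over1 <- rec$site_pos_1 > nchar(rec$peptide_1)
  over2 <- rec$site_pos_2 > nchar(rec$peptide_2)
  if (any(over1 | over2))
    stop("relative crosslink site exceeds peptide length in rows: ",
         paste(rec$row[over1 | over2], collapse = ", "))
  rec$absolute_1 <- absolute_position(rec$from_1, rec$site_pos_1)
  rec$absolute_2 <- absolute_position(rec$from_2, rec$site_pos_2)
  rec$span_mismatch_1 <- (rec$to_1 - rec$from_1 + 1L) != nchar(rec$peptide_1)
  rec$span_mismatch_2 <- (rec$to_2 - rec$from_2 + 1L) != nchar(rec$peptide_2)
  class(rec) <- c("xlms_records", "data.frame")
  rec
}

empty_xlms_records <- function() {
  rec <- data.frame(row = integer(0), protein_1 = character(0),
                    protein_2 = character(0), score = numeric(0),
                    peptide_1 = character(0), from_1 = integer(0),
                    to_1 = integer(0), site_res_1 = character(0),
                    site_pos_1 = integer(0), peptide_2 = character(0),
                    from_2 = integer(0), to_2 = integer(0),
                    site_res_2 = character(0), site_pos_2 = integer(0),
                    replicate_id = character(0), absolute_1 = integer(0),
                    absolute_2 = integer(0), span_mismatch_1 = logical(0),
                    span_mismatch_2 = logical(0), stringsAsFactors = FALSE)
  class(rec) <- c("xlms_records", "data.frame")
  rec
}

#' Absolute protein position of a crosslinked residue
#'
#' A crosslink site is reported relative to its peptide; with the peptide's
#' 1-based inclusive start `from`, the absolute protein position is
#' `from + relative - 1` (e.g. peptide starting at 156 with site at relative
#' position 2 -> residue 157).
#'
#' @param from 1-based peptide start position(s) in the protein.
#' @param relative_site 1-based site position(s) within the peptide.
#' @return Integer vector of 1-based protein positions.
#' @export
absolute_position <- function(from, relative_site) {
  if (any(from < 1L) || any(relative_site < 1L))
    stop("positions are 1-based: from and relative_site must be >= 1")
  as.integer(from + relative_site - 1L)
}

#' Filter crosslink records by score and crosslinker site specificity
#'
#' Retains records with score at or above `min_score` (identification score
#' cutoff, default 30) and, when site specificity is required, whose linked
#' residues match the amine-reactive crosslinker chemistry (DSBU: Lys, Ser,
#' Thr, Tyr or the protein N-terminus).
#'
#' @param records An `xlms_records` data.frame.
#' @param min_score Minimum score (default 30).
#' @param require_site_specificity Enforce the residue-chemistry filter.
#' @param specific_residues Allowed link residues (default K, S, T, Y).
#' @return Filtered records; dropped rows and reasons are attached as
#'   attribute `"dropped"`.
#' @export
filter_records <- function(records, min_score = 30,
                           require_site_specificity = TRUE,
                           specific_residues = c("K", "S", "T", "Y")) {
  ok_score <- records$score >= min_score
  site_ok <- function(res, abs_pos)
    res %in% specific_residues | abs_pos == 1L
  ok_site <- if (require_site_specificity)
    site_ok(records$site_res_1, records$absolute_1) &
    site_ok(records$site_res_2, records$absolute_2)
  else rep(TRUE, nrow(records))
  keep <- ok_score & ok_site
  reason <- ifelse(!ok_score, "score below cutoff",
                   ifelse(!ok_site, "link residue outside crosslinker specificity", NA))
  out <- records[keep, , drop = FALSE]
  attr(out, "dropped") <- data.frame(row = records$row[!keep],
                                     reason = reason[!keep],
                                     stringsAsFactors = FALSE)
  class(out) <- c("xlms_records", "data.frame")
  out
}

# replicate-invariant identity key of a record: unordered (protein, absolute
# position) pairs, alias-resolved when a registry is supplied
link_key <- function(records, registry = NULL) {
  lab1 <- records$protein_1; lab2 <- records$protein_2
  if (!is.null(registry)) {
    lab1 <- resolve_proteins(lab1, registry)$label
    lab2 <- resolve_proteins(lab2, registry)$label
  }
  a <- paste0(lab1, ":", records$absolute_1)
  b <- paste0(lab2, ":", records$absolute_2)
  ifelse(a < b, paste(a, b, sep = "--"), paste(b, a, sep = "--"))
}

#' Combine crosslink records across replicates
#'
#' Takes the union of records keyed by the unordered pair of (protein,
#' absolute position) sites; duplicate links collapse to a single record
#' keeping the maximum score and accumulating replicate ids (";"-separated).
#' The operation is idempotent and commutative.
#'
#' @param ... Two or more `xlms_records` data.frames (or a single list).
#' @param registry Optional `pep_registry` so that alias spellings of the same
#'   protein merge.
#' @return Merged `xlms_records`.
#' @export
merge_replicates <- function(..., registry = NULL) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is.data.frame(sets[[1]]))
    sets <- sets[[1]]
  if (length(sets) == 0L) stop("need at least one record set")
  all <- do.call(rbind, lapply(sets, as.data.frame))
  if (nrow(all) == 0L) return(empty_xlms_records())
  key <- link_key(all, registry)
  out <- do.call(rbind, lapply(split(seq_len(nrow(all)), key), function(idx) {
    grp <- all[idx, , drop = FALSE]
    best <- grp[which.max(grp$score), , drop = FALSE]
    best$replicate_id <- paste(sort(unique(grp$replicate_id)), collapse = ";")
    best
  }))
  out <- out[order(out$row, -out$score), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("xlms_records", "data.frame")
  out
}
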