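#' Load the PEP subunit membership registry
#'
#' The PEP-A complex comprises 16 established subunits: the four plastid-encoded
#' core subunits (alpha, beta, beta', beta'', encoded by rpoA/rpoB/rpoC1/rpoC2)
#' and twelve nuclear-encoded PEP-associated proteins (PAP1-PAP12). Two further
#' proteins, FLN2 and pTAC18, are recurrently co-purified candidates. The
#' registry ships with the package as a versioned delimited text resource and
#' records, for every member, its canonical name, its role and the alias names
#' under which it appears in the literature (pTAC numbering, functional names
#' such as HEMERA or MurE, and species-prefixed forms such as "SaRpoA").
#'
#' @return An object of class `pep_registry`: a list with element `members`,
#'   a data.frame with columns `canonical`, `role` (one of `core`, `pap`,
#'   `candidate`) and `aliases` (";"-separated).
#' @export
#' @examples
#' reg <- load_registry()
#' table(reg$members$role)
#' registry_lookup(reg, "pTAC12")  # "PAP5"
load_registry <- function() {
  path <- system.file("extdata", "pep_registry.tsv", package = "pepmap",
                      mustWork = TRUE)
  raw <- read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, quote = "")
  members <- data.frame(canonical = raw$canonical,
                        role = raw$role,
                        aliases = ifelse(is.na(raw$aliases), "", raw$aliases),
                        stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(members$canonical),
            sum(members$role == "core") == 4L,
            sum(members$role == "pap") == 12L,
            all(members$role %in% c("core", "pap", "candidate")))
  structure(list(members = members), class = "pep_registry")
}

#' @export
print.pep_registry <- function(x, ...) {
  cat("PEP subunit registry:", nrow(x$members), "members (",
      sum(x$members$role == "core"), "core,",
      sum(x$members$role == "pap"), "PAP,",
      sum(x$members$role == "candidate"), "candidate )\n")
  invisible(x)
}

# Normalise a single name for alias matching: strip whitespace and bracket
# characters, lowercase. Matching additionally tries the form with a leading
# species prefix "sa" removed (Table-1 style "SaRpoA" etc.).
normalize_alias <- function(x) {
  x <- gsub("[][(){}<>]", "", x)
  tolower(gsub("\\s+", "", x))
}

# Full alias -> canonical map (canonical names are their own aliases).
alias_map <- function(registry) {
  m <- registry$members
  alias_lists <- strsplit(m$aliases, ";", fixed = TRUE)
  keys <- character(0); vals <- character(0)
  for (i in seq_len(nrow(m))) {
    al <- c(m$canonical[i], alias_lists[[i]])
    al <- al[nzchar(al)]
    keys <- c(keys, normalize_alias(al))
    vals <- c(vals, rep(m$canonical[i], length(al)))
  }
  pairs <- unique(data.frame(keys, vals, stringsAsFactors = FALSE))
  if (anyDuplicated(pairs$keys)) {
    dup <- unique(pairs$keys[duplicated(pairs$keys)])
    stop("alias(es) resolve to more than one member: ",
         paste(dup, collapse = ", "))
  }
  setNames(pairs$vals, pairs$keys)
}

#' Look up a protein name against the registry
#'
#' Matching is case-insensitive, whitespace-stripped and tolerant of a leading
#' species prefix ("SaRpoA" resolves like "RpoA"). Compound literature labels
#' of the form "PAP1/pTac3" are tried whole and then part by part.
#'
#' @param registry A `pep_registry` from [load_registry()].
#' @param name A single protein name or alias.
#' @return The canonical member name, or `NA_character_` if the name does not
#'   resolve to any registry member.
#' @export
registry_lookup <- function(registry, name) {
  am <- alias_map(registry)
  lookup_one(name, am)
}

lookup_one <- function(name, am) {
  candidates <- normalize_alias(c(name, strsplit(name, "/", fixed = TRUE)[[1]]))
  candidates <- unique(c(candidates, sub("^sa", "", candidates)))
  hit <- candidates[candidates %in% names(am)]
  if (length(hit) == 0L) return(NA_character_)
  canon <- unique(unname(am[hit]))
  if (length(canon) > 1L) {
    # a compound like "PAP6/FLN1" whose parts agree is fine; disagreeing parts
    # (never the case for literature labels) resolve to the whole-string match
    whole <- normalize_alias(name)
    if (whole %in% names(am)) return(unname(am[whole]))
    return(canon[1L])
  }
  canon
}

#' Resolve crosslink partner labels to registry nodes
#'
#' Crosslink tables name partners by shared peptides, so a label may denote an
#' ambiguity group that one peptide cannot distinguish (e.g. "PAP6/FLN1; FLN2"
#' for the near-identical fructokinase-like paralogs, or "RPS2A; RPS2B").
#' Such groups become a single node carrying the ambiguity rather than
#' duplicated nodes. A node is a registry member if at least one group
#' component resolves to a member.
#'
#' @param names Character vector of protein labels as printed in a dipeptide
#'   table.
#' @param registry A `pep_registry`.
#' @return A data.frame with one row per input: `input`, `label` (deterministic
#'   node label: resolved canonical names, joined with "/"), `member` (logical)
#'   and `role` (role of the first member component, or `NA`).
#' @export
resolve_proteins <- function(names, registry) {
  am <- alias_map(registry)
  roles <- setNames(registry$members$role, registry$members$canonical)
  res <- lapply(names, function(nm) {
    parts <- trimws(strsplit(nm, ";", fixed = TRUE)[[1]])
    canon <- vapply(parts, lookup_one, character(1), am = am)
    comp <- ifelse(is.na(canon), parts, canon)
    comp <- unique(comp)
    label <- paste(sort(comp), collapse = "/")
    member <- any(!is.na(canon))
    role <- if (member) unname(roles[canon[!is.na(canon)][1L]]) else NA_character_
    data.frame(input = nm, label = label, member = member, role = role,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
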