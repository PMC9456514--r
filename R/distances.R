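#' Assess crosslink compatibility against a structure
#'
#' Computes the Calpha-Calpha Euclidean distance for each crosslink whose two
#' residues can be located in the model, and classifies it as compatible when
#' the distance does not exceed `max_distance`. The default 30 Angstrom
#' reflects the common restraint convention for a ~12.5 Angstrom-spacer
#' amine-reactive crosslinker once side-chain and backbone flexibility are
#' allowed for. Links whose protein has no chain mapping or whose residue is
#' absent from the model are reported `unmapped` and never counted as
#' compatible or incompatible.
#'
#' @param records An `xlms_records` data.frame.
#' @param model A `pep_structure`.
#' @param chain_map Named character vector: protein name (raw or canonical,
#'   resolved through `registry` when given) -> chain id. Every chain named
#'   here must exist in the model.
#' @param max_distance Maximum compatible Calpha-Calpha distance (Angstrom).
#' @param registry Optional `pep_registry` for alias resolution.
#' @return Object of class `distance_assessment`: data.frame per record with
#'   `row`, `protein_1`, `protein_2`, `chain_1`, `chain_2`, `distance`,
#'   `status` (`compatible`, `incompatible`, `unmapped`); `max_distance` as an
#'   attribute.
#' @export
assess_distances <- function(records, model, chain_map, max_distance = 30,
                             registry = NULL) {
  rt <- residue_table(model)
  absent <- setdiff(unname(chain_map), unique(rt$chain))
  if (length(absent) > 0L)
    stop("chain(s) named in chain_map absent from model: ",
         paste(absent, collapse = ", "))
  map_names <- names(chain_map)
  if (!is.null(registry)) {
    canon <- resolve_proteins(map_names, registry)$label
    chain_map <- setNames(unname(chain_map), canon)
    map_names <- canon
  }
  chain_for <- function(protein) {
    key <- if (is.null(registry)) protein
           else resolve_proteins(protein, registry)$label
    if (key %in% map_names) unname(chain_map[key]) else NA_character_
  }
  n <- nrow(records)
  out <- data.frame(row = records$row,
                    protein_1 = records$protein_1,
                    protein_2 = records$protein_2,
                    chain_1 = NA_character_, chain_2 = NA_character_,
                    distance = NA_real_, status = "unmapped",
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    c1 <- chain_for(records$protein_1[i]); c2 <- chain_for(records$protein_2[i])
    out$chain_1[i] <- c1; out$chain_2[i] <- c2
    if (is.na(c1) || is.na(c2)) next
    p1 <- ca_coords(model, c1, records$absolute_1[i])
    p2 <- ca_coords(model, c2, records$absolute_2[i])
    if (is.null(p1) || is.null(p2)) next
    d <- sqrt(sum((p1 - p2)^2))
    out$distance[i] <- d
    out$status[i] <- if (d <= max_distance) "compatible" else "incompatible"
  }
  structure(out, class = c("distance_assessment", "data.frame"),
            max_distance = max_distance)
}

#' Write a distance-restraint list
#'
#' Plain-text restraints (chain, residue, chain, residue, max distance) for
#' mapped crosslinks, usable as modelling input.
#'
#' @param assessment A [assess_distances()] result.
#' @param records The corresponding records (for absolute positions).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_restraints <- function(assessment, records, path) {
  mapped <- assessment$status != "unmapped"
  lines <- c("chain_1\tresidue_1\tchain_2\tresidue_2\tmax_distance",
             sprintf("%s\t%d\t%s\t%d\t%g",
                     assessment$chain_1[mapped], records$absolute_1[mapped],
                     assessment$chain_2[mapped], records$absolute_2[mapped],
                     attr(assessment, "max_distance")))
  writeLines(lines, path)
  invisible(path)
}
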