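#' Physicochemical functional groups of the amino acids
#'
#' A fixed six-class partition used to decide whether two residues are
#' homologous (same functional group) even when not identical: positive
#' \{K,R,H\}, negative \{D,E\}, polar \{S,T,N,Q\}, aromatic \{F,W,Y\},
#' aliphatic \{A,V,L,I,M,C\} and special \{G,P\}. The gap character is its
#' own class.
#'
#' @return Named list of character vectors partitioning the 20 amino acids.
#' @export
functional_groups <- function() {
  list(positive  = c("K", "R", "H"),
       negative  = c("D", "E"),
       polar     = c("S", "T", "N", "Q"),
       aromatic  = c("F", "W", "Y"),
       aliphatic = c("A", "V", "L", "I", "M", "C"),
       special   = c("G", "P"))
}

#' Map residues to their functional group
#'
#' @param residues Character vector of one-letter residue codes (gap "-"
#'   allowed).
#' @param groups A partition as returned by [functional_groups()].
#' @return Character vector of group names; "-" maps to `"gap"`.
#' @export
group_of <- function(residues, groups = functional_groups()) {
  lut <- setNames(rep(names(groups), lengths(groups)), unlist(groups))
  lut["-"] <- "gap"
  unknown <- setdiff(unique(residues), names(lut))
  if (length(unknown) > 0L)
    stop("residues outside the functional-group table: ",
         paste(unknown, collapse = ", "))
  unname(lut[residues])
}
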