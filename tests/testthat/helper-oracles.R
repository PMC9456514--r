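# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written as explicit loops, separate from the
# package's vectorized code paths.

# modal-residue identity: explicit counting
brute_identity <- function(column_chars) {
  n <- length(column_chars)
  best <- 0
  for (aa in unique(column_chars[column_chars != "-"])) {
    cnt <- 0
    for (x in column_chars) if (x == aa) cnt <- cnt + 1
    if (cnt > best) best <- cnt
  }
  100 * best / n
}

brute_homology <- function(column_chars, groups = functional_groups()) {
  n <- length(column_chars)
  grp <- character(length(column_chars))
  for (i in seq_along(column_chars)) {
    grp[i] <- "gap"
    for (g in names(groups))
      if (column_chars[i] %in% groups[[g]]) grp[i] <- g
  }
  best <- 0
  for (g in unique(grp[grp != "gap"])) {
    cnt <- 0
    for (x in grp) if (x == g) cnt <- cnt + 1
    if (cnt > best) best <- cnt
  }
  100 * best / n
}

# connected components by transitive closure over an adjacency matrix
brute_components <- function(nodes, edge_a, edge_b) {
  n <- length(nodes)
  adj <- diag(TRUE, n)
  for (k in seq_along(edge_a)) {
    i <- match(edge_a[k], nodes); j <- match(edge_b[k], nodes)
    adj[i, j] <- TRUE; adj[j, i] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj > 0)) break
    adj <- nxt
  }
  comp_id <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (comp_id[i] == 0L) {
      next_id <- next_id + 1L
      comp_id[adj[i, ] > 0] <- next_id
    }
  }
  comps <- lapply(split(nodes, comp_id), function(x) sort(unname(x)))
  unname(comps[order(-vapply(comps, length, integer(1)),
                     vapply(comps, `[`, character(1), 1L))])
}

# position-by-position tryptic cleavage enumeration (Trypsin/P)
brute_digest <- function(sequence, missed = 0L) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  # candidate start: position 1 or preceded by K/R; candidate end: n or K/R
  peptides <- character(0); starts <- integer(0); ends <- integer(0)
  for (s in seq_len(n)) {
    if (!(s == 1L || chars[s - 1L] %in% c("K", "R"))) next
    for (e in s:n) {
      if (!(e == n || chars[e] %in% c("K", "R"))) next
      internal <- 0L
      if (e > s) for (p in s:(e - 1L))
        if (chars[p] %in% c("K", "R")) internal <- internal + 1L
      if (internal <= missed) {
        peptides <- c(peptides, paste(chars[s:e], collapse = ""))
        starts <- c(starts, s); ends <- c(ends, e)
      }
    }
  }
  data.frame(peptide = peptides, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

# hypergeometric two-sided exact test by full enumeration over one margin
brute_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  prob <- function(x) choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  p_obs <- prob(a)
  xs <- max(0, c1 - r2):min(r1, c1)
  sum(vapply(xs, prob, numeric(1))[vapply(xs, prob, numeric(1)) <= p_obs * (1 + 1e-7)])
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "pepmap", mustWork = TRUE)
}
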