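base_msa_spec <- function(...) {
  spec <- list(
    clades = data.frame(label = c("pap", "bact"), n_taxa = c(3, 3)),
    length = 50, conserved_blocks = list(), variable_patches = list(),
    substitution_rate = 0.5, seed = 5)
  args <- list(...)
  spec[names(args)] <- args
  spec
}

test_that("alignment generator honours its ground-truth architecture", {
  sim <- simulate_msa(base_msa_spec())
  prof <- clade_profiles(sim$msa, window_size = 1)
  expect_equal(prof$all$column_identity, rep(100, 50))  # no features: conserved

  sim2 <- simulate_msa(base_msa_spec(
    conserved_blocks = list(c(1, 10)), variable_patches = list(c(21, 30)),
    clade_insertion = list(label = "pap", range = c(41, 45))))
  expect_equal(sim2$truth$column_class[c(1, 21, 41, 50)],
               c("conserved", "variable", "insertion", "background"))
  # insertion region gapped outside its clade only
  ins <- sim2$msa$mat[, 41:45]
  pap_rows <- sim2$msa$clade == "pap"
  expect_true(all(ins[!pap_rows, ] == "-"))
  expect_true(all(ins[pap_rows, ] != "-"))
  expect_error(simulate_msa(base_msa_spec(conserved_blocks = list(c(0, 5)))),
               "invalid range")
  expect_error(simulate_msa(base_msa_spec(conserved_blocks = list(c(1, 10)),
                                          variable_patches = list(c(5, 12)))),
               "overlapping")
})

test_that("generators are deterministic per seed", {
  s1 <- simulate_msa(base_msa_spec(variable_patches = list(c(10, 30))))
  s2 <- simulate_msa(base_msa_spec(variable_patches = list(c(10, 30))))
  expect_identical(s1$msa$mat, s2$msa$mat)
  s3 <- simulate_msa(base_msa_spec(variable_patches = list(c(10, 30)), seed = 6))
  expect_false(identical(s1$msa$mat, s3$msa$mat))

  i1 <- simulate_intensities(list(subunits = data.frame(
    name = "rpoA", length = 300, copy_number = 2), seed = 3))
  i2 <- simulate_intensities(list(subunits = data.frame(
    name = "rpoA", length = 300, copy_number = 2), seed = 3))
  expect_identical(i1$intensities, i2$intensities)

  x1 <- simulate_crosslinks(list(clusters = list(c("A", "B", "C")),
                                 n_decoys = 2, seed = 9))
  x2 <- simulate_crosslinks(list(clusters = list(c("A", "B", "C")),
                                 n_decoys = 2, seed = 9))
  expect_identical(x1$table, x2$table)
})

test_that("fully random variable columns match the multinomial modal-frequency oracle", {
  # at substitution rate 1, each taxon draws uniformly from the 20 letters;
  # expected column identity is E[max multinomial count] / n, estimated here
  # by direct Monte-Carlo draws independent of the generator
  n_taxa <- 6L
  sim <- simulate_msa(list(
    clades = data.frame(label = c("a", "b"), n_taxa = c(3, 3)),
    length = 400, conserved_blocks = list(),
    variable_patches = list(c(1, 400)), substitution_rate = 1, seed = 17))
  ident <- vapply(seq_len(400), function(j) column_identity(sim$msa, j),
                  numeric(1))
  set.seed(18)
  mc <- replicate(2000, {
    draw <- sample(20L, n_taxa, replace = TRUE)
    100 * max(tabulate(draw)) / n_taxa
  })
  expect_lt(abs(mean(ident) - mean(mc)), 3)
})

test_that("helix geometry gives the canonical Calpha spacing", {
  h <- simulate_structure(20, "helix")
  xyz <- as.matrix(h$model$atoms[, c("x", "y", "z")])
  d <- sqrt(rowSums((xyz[-1, ] - xyz[-20, ])^2))
  expect_true(all(abs(d - 3.83) < 0.01))
  h2 <- simulate_structure(2, "helix", path = tempfile(fileext = ".pdb"))
  expect_equal(nrow(h2$model$atoms), 2L)
  expect_true(file.exists(h2$path))
  expect_equal(nrow(residue_table(read_structure(h2$path))), 2L)
})

test_that("two-shell structures separate buried from exposed ground truth", {
  ts <- simulate_structure(50, "two_shell")
  sasa <- compute_sasa(ts$model)
  expect_lt(max(sasa$rel_sasa[!ts$exposed_truth]),
            min(sasa$rel_sasa[ts$exposed_truth]))
  expect_true(all(sasa$exposed[ts$exposed_truth]))
  expect_false(any(sasa$exposed[!ts$exposed_truth]))
  expect_error(simulate_structure(5, "two_shell"), ">= 10")
})

test_that("simulated crosslink tables feed the full network pipeline", {
  sim <- simulate_crosslinks(list(clusters = list(c("A", "B", "C"), c("D", "E")),
                                  seed = 12))
  f <- tempfile(fileext = ".tsv")
  write_crosslink_table(sim$table, f)
  rec <- parse_crosslink_table(f)
  expect_equal(nrow(rec), 3L)  # 2 + 1 chain links
  g <- build_graph(filter_records(rec), load_registry())
  expect_equal(length(g$clusters), 2L)
  expect_setequal(g$clusters[[1]], c("A", "B", "C"))
  expect_setequal(g$clusters[[2]], c("D", "E"))

  # decoys below the score cutoff are removed by filtering
  sim2 <- simulate_crosslinks(list(clusters = list(c("A", "B")), n_decoys = 30,
                                   seed = 14))
  f2 <- tempfile(fileext = ".tsv")
  write_crosslink_table(sim2$table, f2)
  rec2 <- parse_crosslink_table(f2)
  kept <- filter_records(rec2, min_score = 30)
  dropped <- attr(kept, "dropped")
  expect_true(all(rec2$score[rec2$row %in% dropped$row] < 30))
  expect_true(all(kept$score >= 30))
  expect_gt(nrow(dropped), 0L)   # uniform [0,60] decoys straddle the cutoff
  expect_lt(nrow(kept), nrow(rec2))
})

test_that("planted crosslinks assess correctly against a structure", {
  ts <- simulate_structure(30, "helix")
  # residues 1 and 3 are ~5.4 A apart; residues 1 and 25 are far in z
  rec <- data.frame(row = 1:3, protein_1 = "TOY", protein_2 = "TOY2",
                    score = 90, peptide_1 = "GSAKLVR", from_1 = c(1L, 1L, 1L),
                    to_1 = 7L, site_res_1 = "K",
                    site_pos_1 = c(1L, 1L, 1L), peptide_2 = "GSAKLVR",
                    from_2 = c(3L, 25L, 999L), to_2 = 31L, site_res_2 = "K",
                    site_pos_2 = 1L, replicate_id = "r1",
                    absolute_1 = c(1L, 1L, 1L), absolute_2 = c(3L, 25L, 999L),
                    span_mismatch_1 = FALSE, span_mismatch_2 = FALSE,
                    stringsAsFactors = FALSE)
  da <- assess_distances(rec, ts$model, c(TOY = "A", TOY2 = "A"),
                         max_distance = 30)
  expect_equal(da$status, c("compatible", "incompatible", "unmapped"))
  expect_lt(da$distance[1], 30)
  expect_gt(da$distance[2], 30)
  expect_true(is.na(da$distance[3]))
  expect_error(assess_distances(rec, ts$model, c(TOY = "Z")), "absent")
})
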