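two_clade_msa <- function(seq_A, seq_B, n_each = 2) {
  seqs <- c(setNames(rep(seq_A, n_each), paste0("a", seq_len(n_each))),
            setNames(rep(seq_B, n_each), paste0("b", seq_len(n_each))))
  clades <- setNames(rep(c("A", "B"), each = n_each), names(seqs))
  new_msa(seqs, clades)
}

test_that("column classification follows modal functional groups and gap majority", {
  msa <- two_clade_msa("K", "R")
  expect_equal(classify_columns(msa, "A", "B")$class, "homologous")
  msa <- two_clade_msa("K", "D")
  expect_equal(classify_columns(msa, "A", "B")$class, "nonhomologous")
  # clade B 3 of 4 gaps -> gap class
  seqs <- c(a1 = "K", a2 = "K", b1 = "K", b2 = "-", b3 = "-", b4 = "-")
  clades <- setNames(c("A", "A", "B", "B", "B", "B"), names(seqs))
  expect_equal(classify_columns(new_msa(seqs, clades), "A", "B")$class, "gap")
  expect_error(classify_columns(msa, "A", c("a1", "b1")), "overlapping")
})

test_that("class labels partition the columns", {
  set.seed(3)
  alphabet <- c("A", "K", "R", "D", "E", "G", "-")
  mat <- matrix(sample(alphabet, 6 * 30, replace = TRUE), nrow = 6)
  seqs <- setNames(apply(mat, 1, paste, collapse = ""), paste0("t", 1:6))
  clades <- setNames(rep(c("A", "B"), each = 3), names(seqs))
  cc <- classify_columns(new_msa(seqs, clades), "A", "B")
  expect_equal(sum(cc$class == "homologous") + sum(cc$class == "nonhomologous") +
                 sum(cc$class == "gap"), 30L)
})

test_that("strong-change runs require >= 3 consecutive reference residues", {
  # columns: K vs D (positive vs negative) = strong; K vs R = homologous
  msa <- two_clade_msa("KKKK", "DDDR")   # flags T,T,T,F
  cc <- classify_columns(msa, "A", "B")
  rm <- map_columns_to_reference(msa, "a1")
  runs <- find_strong_change_runs(cc, rm, min_run = 3)
  expect_equal(nrow(runs), 1L)
  expect_equal(c(runs$start_residue, runs$end_residue), c(1L, 3L))

  msa <- two_clade_msa("KKKKK", "DDRDD")  # flags T,T,F,T,T -> no run of 3
  runs <- find_strong_change_runs(classify_columns(msa, "A", "B"),
                                  map_columns_to_reference(msa, "a1"))
  expect_equal(nrow(runs), 0L)

  msa <- two_clade_msa("KKKKK", "DDDDD")  # five consecutive
  runs <- find_strong_change_runs(classify_columns(msa, "A", "B"),
                                  map_columns_to_reference(msa, "a1"))
  expect_equal(runs$length, 5L)
})

test_that("run detection is idempotent and total flagged = sum of run lengths", {
  msa <- two_clade_msa("KKKKAKKK", "DDDDADDD")
  cc <- classify_columns(msa, "A", "B")
  rm <- map_columns_to_reference(msa, "a1")
  r1 <- find_strong_change_runs(cc, rm)
  r2 <- find_strong_change_runs(cc, rm)
  expect_identical(r1, r2)
  ann <- divergence_annotation(msa, "A", "B", "a1")
  expect_equal(sum(ann$strong_change), sum(r1$length))
})

test_that("runs follow reference-residue numbering across reference gap columns", {
  # reference gapped in the middle of a divergent stretch: the gap column
  # drops out, but the flanking residues stay consecutive in reference
  # numbering, so the run continues
  seqs <- c(a1 = "KK-KK", a2 = "KKKKK", b1 = "DDDDD", b2 = "DDDDD")
  clades <- setNames(c("A", "A", "B", "B"), names(seqs))
  msa <- new_msa(seqs, clades)
  cc <- classify_columns(msa, "A", "B")
  rm <- map_columns_to_reference(msa, "a1")
  runs <- find_strong_change_runs(cc, rm, min_run = 2)
  # a1 has 4 residues; columns 1,2 -> residues 1,2; columns 4,5 -> 3,4:
  # residues 1,2,3,4 are consecutive in reference numbering, single run
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$length, 4L)
})

test_that("annotations map onto structures with unmapped counts", {
  toy <- simulate_structure(3, "helix")
  ann <- data.frame(residue = 1:3, class = c("homologous", "nonhomologous", "gap"),
                    strong_change = c(FALSE, TRUE, FALSE))
  res <- map_annotations_to_structure(ann, toy$model, "A")
  expect_equal(res$n_mapped, 3L)
  expect_equal(res$n_unmapped, 0L)
  expect_equal(res$model$annotations$class$value,
               c("homologous", "nonhomologous", "gap"))

  ann99 <- data.frame(residue = 99, class = "gap", strong_change = FALSE)
  res2 <- map_annotations_to_structure(ann99, toy$model, "A")
  expect_equal(res2$n_unmapped, 1L)

  res3 <- map_annotations_to_structure(ann[0, ], toy$model, "A")
  expect_equal(res3$n_mapped, 0L)
  expect_identical(res3$model$annotations, toy$model$annotations)

  expect_error(map_annotations_to_structure(ann, toy$model, "Z"),
               "chain absent")
})

test_that("surface enrichment fractions, odds ratio and exact p-value", {
  ts <- simulate_structure(50, "two_shell")
  sasa <- compute_sasa(ts$model)
  n <- nrow(ts$model$atoms)
  # plant variable sites exactly on the exposed shell
  classes <- ifelse(ts$exposed_truth, "nonhomologous", "homologous")
  model <- set_residue_annotation(ts$model, "class", rep("A", n), 1:n, classes)
  enr <- surface_enrichment(model, sasa)
  expect_equal(enr$fraction_variable_exposed, 1.0)
  expect_equal(enr$fraction_conserved_exposed, 0.0)
  expect_true(enr$degenerate || enr$odds_ratio > 1 || is.na(enr$odds_ratio))
  expect_lt(enr$p_value, 0.001)

  # exact p-value against the hand-enumerated hypergeometric oracle
  tab <- matrix(c(10, 0, 0, 10), nrow = 2, byrow = TRUE)
  expect_equal(brute_fisher_p(tab), 2 / choose(20, 10))
  expect_equal(fisher.test(tab)$p.value, brute_fisher_p(tab), tolerance = 1e-12)
})

test_that("mixed exposure gives a finite odds ratio matching the 2x2 table", {
  ts <- simulate_structure(50, "two_shell")
  sasa <- compute_sasa(ts$model)
  n <- length(ts$exposed_truth)
  set.seed(5)
  # variable sites enriched on the shell but present in both compartments
  classes <- ifelse(ts$exposed_truth,
                    sample(c("nonhomologous", "homologous"), n, TRUE, c(0.8, 0.2)),
                    sample(c("nonhomologous", "homologous"), n, TRUE, c(0.2, 0.8)))
  model <- set_residue_annotation(ts$model, "class", rep("A", n), 1:n, classes)
  enr <- surface_enrichment(model, sasa, variable_classes = "nonhomologous")
  tab <- enr$table
  expect_equal(enr$odds_ratio,
               (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]))
  expect_gt(enr$odds_ratio, 1)
  expect_equal(fisher.test(tab)$p.value, enr$p_value)
})
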