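toy_msa <- function(seqs, clades = NULL) {
  if (is.null(clades)) clades <- setNames(rep("x", length(seqs)), names(seqs))
  new_msa(seqs, clades)
}

test_that("column identity counts the modal non-gap residue over the subset", {
  msa <- toy_msa(c(a = "A", b = "A", c = "A", d = "A"))
  expect_equal(column_identity(msa, 1), 100)
  msa <- toy_msa(c(a = "A", b = "A", c = "A", d = "G"))
  expect_equal(column_identity(msa, 1), 75)
  msa <- toy_msa(c(a = "A", b = "-", c = "-", d = "-"))
  expect_equal(column_identity(msa, 1), 25)  # gaps stay in the denominator
  msa <- toy_msa(c(a = "-", b = "-"))
  expect_equal(column_identity(msa, 1), 0)   # all-gap column
  expect_error(column_identity(msa, 3), "out of range")
})

test_that("column homology counts the modal functional group", {
  msa <- toy_msa(c(a = "K", b = "R", c = "K", d = "K"))
  expect_equal(column_homology(msa, 1), 100)  # K and R both positive
  msa <- toy_msa(c(a = "K", b = "D", c = "K", d = "K"))
  expect_equal(column_homology(msa, 1), 75)
})

test_that("vectorized profiles match a brute-force counting oracle exactly", {
  set.seed(42)
  alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")
  for (trial in 1:10) {
    n_taxa <- sample(2:6, 1)
    n_col <- sample(5:20, 1)
    mat <- matrix(sample(alphabet, n_taxa * n_col, replace = TRUE),
                  nrow = n_taxa)
    seqs <- setNames(apply(mat, 1, paste, collapse = ""),
                     paste0("t", seq_len(n_taxa)))
    msa <- toy_msa(seqs)
    for (j in seq_len(n_col)) {
      expect_equal(column_identity(msa, j), brute_identity(mat[, j]))
      expect_equal(column_homology(msa, j), brute_homology(mat[, j]))
      expect_gte(column_homology(msa, j), column_identity(msa, j))
    }
  }
})

test_that("profiles are invariant under sequence-order permutation", {
  set.seed(7)
  mat <- matrix(sample(c("A", "K", "R", "D", "-"), 60, replace = TRUE), nrow = 4)
  seqs <- setNames(apply(mat, 1, paste, collapse = ""), paste0("t", 1:4))
  msa1 <- toy_msa(seqs)
  msa2 <- toy_msa(seqs[c(3, 1, 4, 2)])
  for (j in 1:15) {
    expect_equal(column_identity(msa1, j), column_identity(msa2, j))
    expect_equal(column_homology(msa1, j), column_homology(msa2, j))
  }
})

test_that("rolling profile uses centered shrinking windows", {
  expect_equal(rolling_profile(rep(100, 30), 11), rep(100, 30))
  v <- c(rep(100, 15), 0, rep(100, 15))
  r <- rolling_profile(v, 11)
  expect_equal(min(r), 1000 / 11)
  expect_equal(sum(r < 100 - 1e-9), 11)  # exactly 11 windows cover the 0
  expect_equal(rolling_profile(v, 1), v)
  expect_equal(length(r), length(v))
  expect_error(rolling_profile(v, 10), "odd")
  expect_error(rolling_profile(1:5, 7), "larger")
})

test_that("rolling profile preserves the mean up to end effects", {
  set.seed(11)
  v <- runif(200, 0, 100)
  r <- rolling_profile(v, 11)
  expect_lt(abs(mean(r) - mean(v)), 2)
  expect_equal(mean(rolling_profile(rep(42, 50), 11)), 42)
})

test_that("clade profiles expose clade-specific conservation", {
  # two clades with disjoint consensus in a region
  seqs <- c(p1 = "KKKK", p2 = "KKKK", p3 = "KKKK",
            b1 = "DDDD", b2 = "DDDD", b3 = "DDDD")
  clades <- setNames(c(rep("plant", 3), rep("bact", 3)), names(seqs))
  msa <- new_msa(seqs, clades)
  prof <- clade_profiles(msa, window_size = 1)
  expect_equal(names(prof), c("all", "bact", "plant"))
  expect_equal(prof$plant$column_identity, rep(100, 4))
  expect_equal(prof$bact$column_identity, rep(100, 4))
  expect_true(all(prof$all$column_identity <= 50 + 1e-9))

  # subset = all taxa reproduces the "all" profile
  one <- clade_profiles(new_msa(seqs, setNames(rep("only", 6), names(seqs))),
                        window_size = 1)
  expect_equal(one$only$column_identity, one$all$column_identity)

  expect_error(clade_profiles(msa, "unknown"), "unknown clade")
  bad <- new_msa(seqs, setNames(c("s", rep("p", 5)), names(seqs)))
  expect_error(clade_profiles(bad), "singleton")
})

test_that("PAP-clade-conserved blocks rise above the all-taxa profile", {
  sim <- simulate_msa(list(
    clades = data.frame(label = c("pap", "bact"), n_taxa = c(5, 5)),
    length = 60,
    conserved_blocks = list(c(1, 20)),
    variable_patches = list(c(21, 40)),
    substitution_rate = 0.15,
    seed = 99))
  prof <- clade_profiles(sim$msa, window_size = 11)
  inside <- 26:35
  expect_gt(mean(prof$pap$rolling_identity[inside]),
            mean(prof$all$rolling_identity[inside]))
})

test_that("column-to-reference mapping skips reference gaps and is monotonic", {
  msa <- toy_msa(c(r = "A-CD", o = "AACD"))
  m <- map_columns_to_reference(msa, "r")
  expect_equal(m$residue, c(1L, NA, 2L, 3L))
  mapped <- m$residue[!is.na(m$residue)]
  expect_true(all(diff(mapped) > 0))
  msa2 <- toy_msa(c(r = "ACDE", o = "ACDE"))
  expect_equal(map_columns_to_reference(msa2, "r")$residue, 1:4)
  expect_error(map_columns_to_reference(msa, "zz"), "unknown taxon")
})
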