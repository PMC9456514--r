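test_that("the bundled dipeptide fixture parses into 12 flagged records", {
  rec <- parse_crosslink_table(fixture_path("table1_crosslinks.tsv"))
  expect_equal(nrow(rec), 12L)
  # bracket characters (including the stray closing brace) are stripped
  expect_false(any(grepl("[][}{]", rec$peptide_1)))
  # row 9: printed span 602-617 (16) disagrees with its 15-letter peptide;
  # the row is kept with the mismatch flagged, not silently fixed
  r9 <- rec[rec$row == 9, ]
  expect_true(r9$span_mismatch_1)
  expect_equal(nchar(r9$peptide_1), 15L)
  expect_equal(r9$to_1 - r9$from_1 + 1L, 16L)
  expect_equal(sum(rec$span_mismatch_1 | rec$span_mismatch_2), 1L)
  # scores parsed as numeric
  expect_equal(rec$score[rec$row == 2], 194.61)
})

test_that("absolute positions reproduce the narrated crosslinked residues", {
  rec <- parse_crosslink_table(fixture_path("table1_crosslinks.tsv"))
  # alpha-subunit peptide GYSLKMSNNFEDR starting at 156: Y at relative 2
  # is Y157 (PAP5 partner, row 5); K at relative 5 is K160 (FLN partner,
  # row 10, where the alpha peptide is peptide 2)
  expect_equal(rec$absolute_1[rec$row == 5], 157L)
  expect_equal(rec$absolute_2[rec$row == 10], 160L)
  expect_equal(absolute_position(156, 2), 157L)
  expect_equal(absolute_position(156, 5), 160L)
  expect_equal(absolute_position(683, 1), 683L)
  expect_error(absolute_position(0, 1), "1-based")
})

test_that("empty and malformed tables are handled", {
  f <- tempfile(fileext = ".tsv")
  writeLines(paste(c("row", "protein_1", "protein_2", "score", "peptide_1",
                     "from_1", "to_1", "aa_1", "peptide_2", "from_2", "to_2",
                     "aa_2"), collapse = "\t"), f)
  expect_warning(rec <- parse_crosslink_table(f), "empty")
  expect_equal(nrow(rec), 0L)

  writeLines(c(paste(c("row", "protein_1", "protein_2", "score", "peptide_1",
                       "from_1", "to_1", "aa_1", "peptide_2", "from_2", "to_2",
                       "aa_2"), collapse = "\t"),
               "1\tA\tB\t50\t[GSAK]\t10\t13\tK9\t[GSAK]\t20\t23\tK1"), f)
  expect_error(parse_crosslink_table(f), "exceeds peptide length")

  writeLines(c(paste(c("row", "protein_1", "protein_2", "score", "peptide_1",
                       "from_1", "to_1", "aa_1", "peptide_2", "from_2", "to_2",
                       "aa_2"), collapse = "\t"),
               "1\tA\tB\t50\t[GSAK]\tten\t13\tK1\t[GSAK]\t20\t23\tK1"), f)
  expect_error(parse_crosslink_table(f), "non-numeric")
})

test_that("score and site-specificity filtering", {
  rec <- parse_crosslink_table(fixture_path("table1_crosslinks.tsv"))
  expect_equal(nrow(filter_records(rec, min_score = 30)), 12L)
  expect_equal(nrow(filter_records(rec, min_score = 1000)), 0L)
  # a non-K/S/T/Y link residue is dropped with a reason, unless N-terminal
  toy <- rec[1, ]
  toy$site_res_1 <- "G"; toy$absolute_1 <- 50L
  out <- filter_records(toy)
  expect_equal(nrow(out), 0L)
  expect_match(attr(out, "dropped")$reason, "specificity")
  toy$absolute_1 <- 1L  # protein N-terminus is a valid DSBU site
  expect_equal(nrow(filter_records(toy)), 1L)
})

test_that("replicate merging is a score-maximizing, id-accumulating union", {
  rec <- parse_crosslink_table(fixture_path("table1_crosslinks.tsv"),
                               replicate_id = "r1")
  L1 <- rec[1, ]; L2 <- rec[5, ]; L3 <- rec[7, ]
  s1 <- rbind(L1, L2)
  s2 <- rbind(L2, L3); s2$replicate_id <- "r2"
  m <- merge_replicates(s1, s2)
  expect_equal(nrow(m), 3L)
  dup <- m[m$row == 5, ]
  expect_equal(dup$replicate_id, "r1;r2")

  # idempotence and commutativity
  expect_equal(nrow(merge_replicates(s1, s1)), nrow(s1))
  m_ab <- merge_replicates(s1, s2)
  m_ba <- merge_replicates(s2, s1)
  expect_equal(m_ab[order(m_ab$row), c("row", "score", "replicate_id")],
               m_ba[order(m_ba$row), c("row", "score", "replicate_id")])

  # max-score rule
  hi <- L1; hi$score <- 500; hi$replicate_id <- "r2"
  mm <- merge_replicates(rbind(L1), rbind(hi))
  expect_equal(nrow(mm), 1L)
  expect_equal(mm$score, 500)
})

test_that("alias spellings of one protein merge under a registry", {
  reg <- load_registry()
  rec <- parse_crosslink_table(fixture_path("table1_crosslinks.tsv"))
  a <- rec[5, ]                 # SaRpoA -- PAP5/PTAC12
  b <- a; b$protein_1 <- "alpha"; b$protein_2 <- "HEMERA"; b$replicate_id <- "r2"
  m <- merge_replicates(rbind(a), rbind(b), registry = reg)
  expect_equal(nrow(m), 1L)
  m2 <- merge_replicates(rbind(a), rbind(b))  # no registry: distinct keys
  expect_equal(nrow(m2), 2L)
})
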