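#!/usr/bin/env Rscript
# Generate the ground-truthed synthetic inputs every later stage consumes:
# a clade-structured core-subunit-like alignment, toy structures with known
# exposure, an intensity table at 2:1 alpha:beta copy numbers, and a
# crosslink table with planted clusters and decoys.

suppressMessages(library(pepmap))
dir.create("results/synthetic", showWarnings = FALSE, recursive = TRUE)

msa_sim <- simulate_msa(list(
  clades = data.frame(label = c("pap_plants", "bacteria"), n_taxa = c(8, 6)),
  length = 400,
  conserved_blocks = list(c(40, 120), c(200, 260)),   # catalytic-like blocks
  variable_patches = list(c(130, 190), c(270, 330)),  # surface-like patches
  clade_insertion = list(label = "pap_plants", range = c(340, 380)),
  substitution_rate = 0.35, seed = 20220831))
write_alignment(msa_sim$msa, "results/synthetic/alignment.fasta")
write.table(data.frame(taxon = rownames(msa_sim$msa$mat),
                       clade = msa_sim$msa$clade),
            "results/synthetic/clades.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(column = seq_along(msa_sim$truth$column_class),
                       class = msa_sim$truth$column_class),
            "results/synthetic/alignment_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("alignment:", nrow(msa_sim$msa$mat), "taxa x", msa_sim$msa$n_columns,
    "columns;", sum(msa_sim$truth$column_class == "variable"),
    "variable columns\n")

shell <- simulate_structure(60, "two_shell",
                            path = "results/synthetic/two_shell.pdb")
write.table(data.frame(resno = seq_along(shell$exposed_truth),
                       exposed = shell$exposed_truth),
            "results/synthetic/two_shell_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
helix <- simulate_structure(120, "helix", path = "results/synthetic/helix.pdb")
cat("structures: two_shell (60 residues,", sum(!shell$exposed_truth),
    "buried) and helix (120 residues)\n")

int_sim <- simulate_intensities(list(
  subunits = data.frame(
    name = c("rpoA", "rpoB", "rpoC1", "rpoC2", "PAP1", "PAP5"),
    length = c(340, 1070, 680, 1400, 1000, 530),
    copy_number = c(2, 1, 1, 1, 1, 1)),
  noise_sigma = 0.3, n_replicates = 3, seed = 20220831))
write.table(int_sim$intensities, "results/synthetic/intensities.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(paste0(">", names(int_sim$sequences), "\n", int_sim$sequences),
           "results/synthetic/sequences.fasta")
cat("intensities: 6 subunits x 3 replicates, alpha at copy number 2\n")

xl_sim <- simulate_crosslinks(list(
  clusters = list(c("PAP5", "FLN2", "SaRpoA", "SaRpoB", "SaRpoC1"),
                  c("PAP1", "PAP2", "MurE")),
  n_decoys = 10, seed = 20220831))
write_crosslink_table(xl_sim$table, "results/synthetic/crosslinks.tsv")
cat("crosslinks:", nrow(xl_sim$table), "rows (",
    length(xl_sim$truth$decoy_rows), "decoys )\n")
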