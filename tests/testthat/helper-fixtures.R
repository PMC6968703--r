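# Small programmatic fixtures for IO and curation tests.

write_bioactivity_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  path
}

# a minimal, fully valid three-row table
tiny_bioactivity_rows <- function() {
  data.frame(
    cid = c("C1", "C2", "C3"),
    smiles = c("NS(=O)(=O)c1ccccc1", "NS(=O)(=O)c1ccc(F)cc1",
               "NS(=O)(=O)c1ccc(Cl)cc1"),
    target = "hCA IX", metric = "Ki", value_nM = c(10, 20, 30),
    aid = c("A1", "A2", "A3"), pmid = "P1", stringsAsFactors = FALSE)
}

# a ligand table with two isoform columns, handy for selectivity tests
tiny_ligand_table <- function() {
  selprof::ligand_table(
    cid = c("C1", "C2", "C3"),
    smiles = c("NS(=O)(=O)c1ccccc1", "NS(=O)(=O)c1ccc(F)cc1",
               "NS(=O)(=O)c1ccc(Cl)cc1"),
    ki = data.frame(`hCA IX` = c(2, 58, 10), `hCA II` = c(546, 51, 10),
                    check.names = FALSE))
}
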