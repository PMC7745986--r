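# small fixtures built in code at test time

# minimal panel: 3 endogenous, 2 housekeeping, 2 negative
tiny_panel <- function() {
  probe_panel(
    probe = c("E1", "E2", "E3", "H1", "H2", "N1", "N2"),
    class = c(rep("endogenous", 3), rep("housekeeping", 2),
              rep("negative", 2)),
    subtype_node = c("basal", "luminal", "none", rep("none", 4)))
}

tiny_counts <- function(panel = tiny_panel(), samples = c("a", "b")) {
  m <- matrix(c(50L, 200L, 2L, 120L, 90L, 4L, 4L,
                10L, 400L, 0L, 150L, 60L, 2L, 8L),
              nrow = 7, dimnames = list(panel$probe, c("a", "b")))
  m[, samples, drop = FALSE]
}

# text of a small RCC file
rcc_text <- function(rows = c("Endogenous,GENE_A,NM_1,5",
                              "Endogenous,GENE_B,NM_2,100",
                              "Negative,NEG_A,NA,0"),
                     header = "CodeClass,Name,Accession,Count",
                     sample_id = "SAMP1", eol = "\n") {
  paste(c("<Header>", "FileVersion,1.7", "</Header>",
          "<Sample_Attributes>", paste0("ID,", sample_id),
          "</Sample_Attributes>",
          "<Lane_Attributes>", "ID,1", "BindingDensity,0.61",
          "</Lane_Attributes>",
          "<Code_Summary>", header, rows, "</Code_Summary>", ""),
        collapse = eol)
}

write_rcc_text <- function(..., file = tempfile(fileext = ".RCC")) {
  writeLines(rcc_text(...), file, sep = "")
  file
}

# normalized log expression + truth for a simulated cohort
sim_logexpr <- function(config) {
  sim <- simulate_cohort(config)
  nm <- normalize_counts(sim$counts, sim$panel)
  list(x = nm$logexpr, truth = sim$truth[colnames(nm$logexpr)],
       sim = sim, nm = nm)
}
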