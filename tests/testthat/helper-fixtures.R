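# Fixtures built in code and shared across test files.

# A minimal valid phosphopeptide data.frame with constant abundances.
make_peptide_table <- function(sites, accessions = NULL, species = "ath",
                               abundance = 100) {
  n <- length(sites)
  if (is.null(accessions)) accessions <- sprintf("prot%02d", seq_len(n))
  tbl <- data.frame(peptide_id = sprintf("pep%03d", seq_len(n)),
                    bare_sequence = strrep("A", 10L),
                    protein_accession = accessions,
                    sites = sites, species = species,
                    stringsAsFactors = FALSE)
  for (cc in abundance_columns()) tbl[[cc]] <- abundance
  tbl
}

# Set the replicate abundances of one timepoint for one row.
set_condition <- function(tbl, row, timepoint, values) {
  tbl[row, sprintf("t%d_r%d", timepoint, quant_replicates())] <- values
  tbl
}

# Small shared synthetic bundle, generated once per test session.
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(seed = 7L, n_families = 30L, n_decoys = 8L,
                              n_peptides = 300L, n_site_families = 9L)
      cache <<- generate_bundle(cfg)
    }
    cache
  }
})
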