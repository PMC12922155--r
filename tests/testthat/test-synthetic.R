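# The synthetic generator: determinism, degenerate configs, divergence
# calibration and truth consistency.

test_that("zero divergence gives identical sequences across species", {
  cfg <- generator_config(seed = 2, n_families = 5, n_decoys = 0,
                          n_peptides = 10, n_site_families = 0,
                          divergence = list(
                            ath = list(p_sub = 0, indel_rate = 0),
                            osa = list(p_sub = 0, indel_rate = 0),
                            gma = list(p_sub = 0, indel_rate = 0)))
  fams <- generate_families(cfg)
  expect_identical(unname(fams$proteomes$ath), unname(fams$proteomes$osa))
  expect_identical(unname(fams$proteomes$ath), unname(fams$proteomes$gma))
})

test_that("identical seeds give byte-identical bundles", {
  cfg <- generator_config(seed = 99, n_families = 12, n_decoys = 3,
                          n_peptides = 80, n_site_families = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_fixture_bundle(cfg, d1, overwrite = TRUE)
  m2 <- write_fixture_bundle(cfg, d2, overwrite = TRUE)
  for (f in names(m1$files)) {
    expect_identical(m1$files[[f]]$md5, m2$files[[f]]$md5)
  }
  expect_setequal(names(m1$files),
                  c(sprintf("proteome_%s.fasta", cfg$species),
                    sprintf("phosphopeptides_%s.tsv", cfg$species),
                    "groups.txt", "truth.json"))
  # overwrite guard
  expect_error(write_fixture_bundle(cfg, d1), "overwrite")
})

test_that("pairwise divergence tracks the substitution probability", {
  cfg <- generator_config(seed = 31, n_families = 100, n_decoys = 0,
                          n_peptides = 10, n_site_families = 0,
                          divergence = list(
                            ath = list(p_sub = 0, indel_rate = 0),
                            osa = list(p_sub = 0.15, indel_rate = 0),
                            gma = list(p_sub = 0.15, indel_rate = 0)))
  fams <- generate_families(cfg)
  ident <- mapply(function(a, b) {
    x <- strsplit(a, "")[[1]]
    y <- strsplit(b, "")[[1]]
    mean(x == y)
  }, fams$proteomes$ath, fams$proteomes$osa)
  expect_lt(abs(mean(ident) - 0.85), 0.03)
})

test_that("residue and multiplicity mixes converge at n = 5000", {
  cfg <- generator_config(seed = 13, n_families = 550, n_decoys = 0,
                          n_peptides = 5000, n_site_families = 0)
  b <- generate_bundle(cfg)
  rd <- residue_distribution(b$peptides$ath)
  expect_lt(abs(rd[["pS"]] - 88.0), 1.5)
  expect_lt(abs(rd[["pT"]] - 11.7), 1.5)
  expect_lt(abs(rd[["pY"]] - 0.3), 1.5)
  md <- multiplicity_distribution(b$peptides$ath)
  expect_lt(abs(md[["1"]] - 78.7), 1.5)
  expect_lt(abs(md[["2"]] - 17.3), 1.5)
  expect_lt(abs(md[["3+"]] - 4.0), 1.5)
})

test_that("degenerate effect configurations plant no signal", {
  cfg0 <- generator_config(seed = 4, n_families = 20, n_decoys = 0,
                           n_peptides = 100, n_site_families = 0,
                           fraction_responsive = 0)
  b0 <- generate_bundle(cfg0)
  expect_identical(length(b0$truth$responsive_peptides$ath), 0L)

  cfg1 <- generator_config(seed = 4, n_families = 20, n_decoys = 0,
                           n_peptides = 200, n_site_families = 0,
                           effect_size = 1)
  b1 <- generate_bundle(cfg1)
  calls <- call_responsive(b1$peptides$ath)
  # "responders" carry no planted effect: nothing should pass both gates
  expect_lt(mean(calls$responsive), 0.01)
})

test_that("bundle truth is consistent with the emitted tables", {
  b <- small_bundle()
  cfg <- b$config
  for (s in cfg$species) {
    expect_identical(nrow(b$peptides[[s]]), cfg$n_peptides)
    # every truth responsive peptide exists in the table
    expect_true(all(b$truth$responsive_peptides[[s]] %in%
                    b$peptides[[s]]$peptide_id))
  }
  # planted motif residue is present at the recorded position
  ms <- b$truth$motif_sites$ath
  if (nrow(ms)) {
    res <- substring(b$proteomes$ath[ms$accession], ms$motif_position,
                     ms$motif_position)
    expect_true(all(res == cfg$motif_residue))
  }
  # planted site pairs carry the advertised residues
  sp <- b$truth$site_pairs
  if (nrow(sp)) {
    ref_res <- substring(b$proteomes$ath[sp$ref_accession], sp$ref_position,
                         sp$ref_position)
    expect_true(all(ref_res == "S"))
    tgt_res <- substring(b$proteomes$osa[sp$target_accession],
                         sp$target_position, sp$target_position)
    expect_true(all(tgt_res[sp$category == "position-not-conserved"] == "A"))
    expect_true(all(tgt_res[sp$category != "position-not-conserved"] == "S"))
  }
  # site residues in the tables match the proteome (no rejects on re-read)
  f <- withr::local_tempfile(fileext = ".tsv")
  fp <- withr::local_tempfile(fileext = ".fasta")
  write_phosphopeptide_table(b$peptides$osa, f)
  write_proteome(b$proteomes$osa, fp)
  pep <- read_phosphopeptide_table(f, "osa", read_proteome(fp))
  expect_identical(nrow(attr(pep, "rejects")), 0L)
})
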