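# Groups parsing, the internal aligner, E-value statistics and best-hit
# assignment.

test_that("read_groups parses the OrthoMCL dialect and enforces invariants", {
  f <- withr::local_tempfile()
  writeLines(c("OG7_0000009: ath|SRK2D osa|SAPK8", "",
               "OG7_0000396: ath|MPK2 osa|LOC_Os02g05480 gma|Q5K6N6"), f)
  g <- read_groups(f)
  expect_identical(nrow(g$table), 5L)
  expect_identical(unname(g$index[["SRK2D"]]), "OG7_0000009")
  expect_identical(g$table$species[g$table$accession == "SAPK8"], "osa")

  writeLines(c("OG7_1: ath|A", "not a group line"), f)
  expect_error(read_groups(f), "line 2")
  writeLines(c("OG7_1: ath|A", "OG7_2: osa|A"), f)
  expect_error(read_groups(f), "more than one group")
  writeLines(c("OG7_1: ath|A", "OG7_1: osa|B"), f)
  expect_error(read_groups(f), "duplicate group id")

  # write/read round trip
  write_groups(g, f)
  expect_identical(read_groups(f)$table, g$table)
})

test_that("Smith-Waterman scores equal the brute-force DP oracle", {
  expect_identical(smith_waterman_score("KRRS", "KRRS"), 19)  # 5+5+5+4
  set.seed(23)
  for (i in 1:60) {
    a <- random_aa_string(sample(5:30, 1))
    b <- random_aa_string(sample(5:30, 1))
    expect_identical(smith_waterman_score(a, b), oracle_sw_score(a, b))
    expect_identical(smith_waterman_score(a, b), smith_waterman_score(b, a))
  }
  # self-alignment dominates any other pairing of the same sequence
  a <- random_aa_string(25)
  expect_gte(smith_waterman_score(a, a),
             smith_waterman_score(a, random_aa_string(25)))
})

test_that("Karlin-Altschul statistics follow the closed form", {
  ka <- karlin_altschul_evalue(100, 300, 400)
  # frozen values from an independent evaluation of
  # bits = (0.267*100 - ln 0.041)/ln 2, E = 300*400*2^-bits
  expect_equal(ka$bit_score, 43.1281898718, tolerance = 1e-9)
  expect_equal(ka$e_value, 1.24825247533e-08, tolerance = 1e-9)
  # lambda*S = ln(K*m*n)  =>  E = 1
  p <- similarity_params()
  S <- log(p$K * 200 * 300) / p$lambda
  expect_equal(karlin_altschul_evalue(S, 200, 300)$e_value, 1,
               tolerance = 1e-12)
  # doubling the subject length doubles E at fixed score
  expect_equal(karlin_altschul_evalue(80, 100, 400)$e_value,
               2 * karlin_altschul_evalue(80, 100, 200)$e_value,
               tolerance = 1e-12)
})

make_groups <- function(...) {
  tbl <- do.call(rbind, lapply(list(...), function(x) {
    data.frame(group_id = x[1], species = x[2], accession = x[3],
               stringsAsFactors = FALSE)
  }))
  structure(list(table = tbl,
                 index = stats::setNames(tbl$group_id, tbl$accession)),
            class = "ortholog_groups")
}

test_that("tabular best-hit assignment applies the lowest-E rule strictly", {
  groups <- make_groups(c("G1", "ath", "A1"), c("G2", "ath", "A2"))
  hits <- data.frame(qseqid = c("q1", "q1", "q2", "q3"),
                     sseqid = c("A1", "A2", "A1", "A2"),
                     pident = 0, length = 0, mismatch = 0, gapopen = 0,
                     qstart = 0, qend = 0, sstart = 0, send = 0,
                     evalue = c(1e-8, 1e-6, 1e-5, 2e-3),
                     bitscore = c(50, 40, 30, 20))
  asg <- assign_best_hit(c("q1", "q2", "q3"), groups = groups, hits = hits)
  expect_identical(asg$group_id, c("G1", NA, NA))   # E = 1e-5 exactly fails
  expect_identical(asg$backend, rep("tabular", 3))

  # ties on E broken by bit score, then subject accession
  hits2 <- data.frame(qseqid = "q1", sseqid = c("A2", "A1"),
                      pident = 0, length = 0, mismatch = 0, gapopen = 0,
                      qstart = 0, qend = 0, sstart = 0, send = 0,
                      evalue = 1e-9, bitscore = c(60, 60))
  asg2 <- assign_best_hit("q1", groups = groups, hits = hits2)
  expect_identical(asg2$subject, "A1")

  # unknown accessions dropped with a warning
  hits3 <- rbind(hits, data.frame(qseqid = "q9", sseqid = "A1", pident = 0,
                                  length = 0, mismatch = 0, gapopen = 0,
                                  qstart = 0, qend = 0, sstart = 0, send = 0,
                                  evalue = 1e-9, bitscore = 10))
  expect_warning(assign_best_hit(c("q1", "q2", "q3"), groups = groups,
                                 hits = hits3), "unknown")

  # shuffling hit order does not change the result
  set.seed(2)
  asg3 <- assign_best_hit(c("q1", "q2", "q3"), groups = groups,
                          hits = hits[sample(nrow(hits)), ])
  expect_identical(asg3, asg)

  # threshold monotonicity: shrinking e_threshold never adds assignments
  a_inf <- assign_best_hit(c("q1", "q2", "q3"), groups = groups, hits = hits,
                           e_threshold = Inf)
  expect_true(all(!is.na(a_inf$group_id)))   # every query with a hit
  a_mid <- assign_best_hit(c("q1", "q2", "q3"), groups = groups, hits = hits,
                           e_threshold = 1e-4)
  expect_true(all(which(!is.na(a_mid$group_id)) %in%
                  which(!is.na(a_inf$group_id))))
})

test_that("internal backend assigns diverged members and rejects decoys", {
  set.seed(29)
  fam1 <- random_aa_string(150)
  fam2 <- random_aa_string(150)
  mutate <- function(s, p) {
    ch <- strsplit(s, "")[[1]]
    idx <- which(runif(length(ch)) < p)
    ch[idx] <- vapply(ch[idx], function(x)
      sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], x), 1), "")
    paste(ch, collapse = "")
  }
  refs <- c(A1 = fam1, A2 = fam2)
  groups <- make_groups(c("G1", "ath", "A1"), c("G2", "ath", "A2"))
  queries <- c(q1 = mutate(fam1, 0.15), q2 = mutate(fam2, 0.15),
               decoy = random_aa_string(150))
  asg <- assign_best_hit(queries, refs, groups)
  expect_identical(asg$group_id[asg$query == "q1"], "G1")
  expect_identical(asg$group_id[asg$query == "q2"], "G2")
  expect_true(is.na(asg$group_id[asg$query == "decoy"]))
  expect_identical(asg$backend[1], "internal")
})
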