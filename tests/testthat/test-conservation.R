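# Group-set accounting, conservation matrix arithmetic, Venn regions,
# global alignment and site mapping/classification.

mini_membership <- function() {
  data.frame(
    group_id = c("G1", "G1", "G1", "G2", "G2", "G3", "G4", "G4"),
    species = c("ath", "osa", "gma", "ath", "osa", "ath", "osa", "gma"),
    accession = c("a1", "o1", "g1", "a2", "o2", "a3", "o4", "g4"),
    stringsAsFactors = FALSE)
}

test_that("responsive group sets use set semantics and tally orphans", {
  resp <- list(ath = c("a1", "a2", "a9"), osa = c("o1", "o1"), gma = character(0))
  sets <- responsive_group_sets(resp, mini_membership())
  expect_identical(sets$ath, c("G1", "G2"))
  expect_identical(sets$osa, "G1")
  expect_identical(sets$gma, character(0))
  expect_identical(attr(sets, "n_no_group")[["ath"]], 1L)  # a9 has no group
})

test_that("conservation matrix counts orthologs and responsive orthologs", {
  resp <- list(ath = c("a1", "a2", "a3"), osa = c("o1"), gma = c("g4"))
  cm <- conservation_matrix("ath", resp, mini_membership())
  osa_row <- cm[cm$target == "osa", ]
  # a1 (G1) and a2 (G2) have osa members, a3 (G3) does not
  expect_identical(osa_row$n_responsive, 3L)
  expect_identical(osa_row$n_with_ortholog, 2L)
  # only G1 is osa-responsive
  expect_identical(osa_row$n_ortholog_responsive, 1L)
  expect_equal(osa_row$pct_with_ortholog, percentage(2, 3))
  expect_equal(osa_row$pct_ortholog_responsive, percentage(1, 3))
  gma_row <- cm[cm$target == "gma", ]
  expect_identical(gma_row$n_with_ortholog, 1L)     # only G1 has a gma member
  expect_identical(gma_row$n_ortholog_responsive, 0L)

  # invariant chain on random sets
  set.seed(37)
  for (i in 1:10) {
    mem <- data.frame(
      group_id = sprintf("G%d", sample(1:20, 60, replace = TRUE)),
      species = sample(c("s1", "s2", "s3"), 60, replace = TRUE),
      accession = sprintf("x%02d", 1:60))
    mem <- mem[!duplicated(mem$accession), ]
    resp <- lapply(stats::setNames(c("s1", "s2", "s3"), c("s1", "s2", "s3")),
                   function(s) {
      acc <- mem$accession[mem$species == s]
      sample(acc, min(length(acc), 8))
    })
    cm <- conservation_matrix("s1", resp, mem)
    expect_true(all(cm$n_ortholog_responsive <= cm$n_with_ortholog))
    expect_true(all(cm$n_with_ortholog <= cm$n_responsive))
  }
})

test_that("venn regions sum correctly and are label-permutation invariant", {
  v <- venn_counts(list(x = c("1", "2"), y = c("2", "3"), z = "2"))
  expect_identical(unname(v$counts["A"]), 1L)        # {"2"}
  expect_identical(v$regions$A, "2")
  expect_identical(sum(v$counts), 3L)                # |union|

  v0 <- venn_counts(list(x = c("1", "2"), y = c("3", "4"), z = "5"))
  expect_true(all(v0$counts[c("A", "B", "C", "D")] == 0))

  # brute-force enumeration oracle on random sets
  set.seed(43)
  for (i in 1:10) {
    sets <- lapply(1:3, function(j) as.character(sample(1:30, sample(5:20, 1))))
    names(sets) <- c("s1", "s2", "s3")
    v <- venn_counts(sets)
    u <- unique(unlist(sets))
    key <- vapply(u, function(e) paste0(+(e %in% sets$s1), +(e %in% sets$s2),
                                        +(e %in% sets$s3)), "")
    brute <- c(A = sum(key == "111"), B = sum(key == "110"),
               C = sum(key == "101"), D = sum(key == "011"),
               E = sum(key == "100"), F = sum(key == "010"),
               G = sum(key == "001"))
    expect_identical(unname(v$counts), unname(as.integer(brute)))
    # permuting species labels permutes but preserves region content
    vp <- venn_counts(sets[c(2, 3, 1)])
    expect_identical(sort(unlist(vp$regions, use.names = FALSE)),
                     sort(unlist(v$regions, use.names = FALSE)))
    expect_identical(vp$counts[["A"]], v$counts[["A"]])
  }

  # overlap percentage relative to the reference species
  v2 <- venn_counts(list(s1 = as.character(1:624), s2 = as.character(1:480),
                         s3 = "999"))
  ov <- v2$pairwise_overlap
  expect_equal(ov$pct_of_reference[ov$reference == "s1" & ov$other == "s2"],
               percentage(480, 624))
})

test_that("global alignment matches the brute-force DP oracle", {
  p <- similarity_params()
  a <- needleman_wunsch_align("ACD", "ACD", p)
  expect_identical(a$aligned_a, a$aligned_b)
  expect_identical(a$score, oracle_nw_score("ACD", "ACD"))
  a2 <- needleman_wunsch_align("ACD", "AD", p)
  expect_identical(nchar(a2$aligned_a), 3L)
  expect_identical(a2$aligned_b, "A-D")
  set.seed(47)
  for (i in 1:60) {
    x <- random_aa_string(sample(5:30, 1))
    y <- random_aa_string(sample(5:30, 1))
    expect_identical(needleman_wunsch_align(x, y, p)$score,
                     oracle_nw_score(x, y))
  }
})

# build an alignment object directly from gapped strings
fake_alignment <- function(aligned_a, aligned_b, bit_score = 100) {
  structure(list(seq_a = gsub("-", "", aligned_a),
                 seq_b = gsub("-", "", aligned_b),
                 aligned_a = aligned_a, aligned_b = aligned_b,
                 score = NA_real_, bit_score = bit_score),
            class = "nw_alignment")
}

test_that("map_site transfers coordinates through gaps and is monotone", {
  id <- fake_alignment("MKSAPR", "MKSAPR")
  expect_identical(map_site(id, 3)$position, 3L)
  # insertion in b before the site shifts the coordinate
  ins <- fake_alignment("MK--SAPR", "MKQQSAPR")
  m <- map_site(ins, 3)
  expect_identical(m$position, 5L)
  expect_identical(m$residue, "S")
  # deletion in b maps the site onto a gap
  del <- fake_alignment("MKSAPR", "MK-APR")
  expect_identical(map_site(del, 3)$position, NA_integer_)
  expect_identical(map_site(del, 3)$residue, "-")
  expect_error(map_site(id, 99), "outside")

  # monotonicity + round trip on real alignments
  set.seed(53)
  p <- similarity_params()
  for (i in 1:10) {
    x <- random_aa_string(40)
    y <- paste0(substr(x, 1, 15), substr(x, 21, 40))  # 5-residue deletion
    al <- needleman_wunsch_align(x, y, p)
    mapped <- vapply(1:40, function(q) {
      mp <- map_site(al, q)$position
      if (is.null(mp) || is.na(mp)) NA_integer_ else mp
    }, 0L)
    expect_true(all(diff(mapped[!is.na(mapped)]) > 0))
    # round trip through the reversed alignment
    rev_al <- fake_alignment(al$aligned_b, al$aligned_a)
    for (q in which(!is.na(mapped))) {
      expect_identical(map_site(rev_al, mapped[q])$position, q)
    }
  }
})

test_that("classify_site distinguishes the four categories", {
  resp <- c(3L)
  al <- fake_alignment("MKSAPR", "MKSAPR")
  expect_identical(classify_site(al, 3, resp)$category, "conserved-responsive")
  expect_identical(classify_site(al, 3, integer(0))$category,
                   "conserved-residue-only")
  al2 <- fake_alignment("MKSAPR", "MKAAPR")
  expect_identical(classify_site(al2, 3, resp)$category,
                   "position-not-conserved")
  al3 <- fake_alignment("MKSAPR", "MK-APR")
  expect_identical(classify_site(al3, 3, resp)$category,
                   "position-not-conserved")
  al4 <- fake_alignment("MKSAPR", "MKSAPR", bit_score = 10)
  expect_identical(classify_site(al4, 3, resp)$category, "unalignable")
})
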