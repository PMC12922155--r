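# Cross-species conservation accounting: responsive ortholog-group sets,
# the per-reference conservation matrix, three-set Venn regions, and
# alignment-based phosphosite mapping/classification.

#' Combined group membership across catalogue and assignments
#'
#' Merges the members listed in the groups file with query-to-group
#' assignments from [assign_best_hit()] (e.g. a species absent from the
#' catalogue), yielding one membership table used by all conservation
#' accounting.
#'
#' @param groups an `"ortholog_groups"` object.
#' @param assignments optional data.frame from [assign_best_hit()]; rows
#'   with `NA` group are ignored.
#' @param assignment_species species tag of the assigned queries (required
#'   when `assignments` is given).
#' @return data.frame with columns `group_id`, `species`, `accession`.
#' @export
group_membership <- function(groups, assignments = NULL,
                             assignment_species = NULL) {
  tbl <- groups$table[, c("group_id", "species", "accession")]
  if (!is.null(assignments)) {
    if (is.null(assignment_species)) {
      stop("assignment_species is required when assignments are given")
    }
    ok <- !is.na(assignments$group_id)
    tbl <- rbind(tbl, data.frame(group_id = assignments$group_id[ok],
                                 species = assignment_species,
                                 accession = assignments$query[ok],
                                 stringsAsFactors = FALSE))
  }
  rownames(tbl) <- NULL
  tbl
}

#' Responsive ortholog-group sets per species
#'
#' A group id is included for a species iff at least one responsive protein
#' of that species belongs to it. Responsive proteins without any group are
#' tallied separately in the `"n_no_group"` attribute.
#'
#' @param responsive named list (by species) of responsive protein
#'   accessions.
#' @param membership data.frame from [group_membership()].
#' @return named list of group-id character vectors, with attribute
#'   `n_no_group` (named integer vector).
#' @export
responsive_group_sets <- function(responsive, membership) {
  sets <- list()
  n_no_group <- integer(0)
  for (sp in names(responsive)) {
    mem <- membership[membership$species == sp, ]
    gid <- mem$group_id[match(responsive[[sp]], mem$accession)]
    sets[[sp]] <- sort(unique(gid[!is.na(gid)]))
    n_no_group[[sp]] <- sum(is.na(gid))
  }
  attr(sets, "n_no_group") <- n_no_group
  sets
}

#' Cross-species conservation matrix for one reference species
#'
#' For every responsive protein of the reference species: it *has an
#' ortholog* in a target species iff its group contains at least one member
#' of that species, and its *ortholog is responsive* iff that group contains
#' a responsive protein of the target species. Both percentages use the
#' reference species' responsive-protein count as denominator, matching the
#' conventional presentation of such matrices.
#'
#' @param reference reference species tag.
#' @param responsive named list (by species) of responsive protein
#'   accessions.
#' @param membership data.frame from [group_membership()].
#' @return data.frame of class `"conservation_matrix"`, one row per target
#'   species: `reference`, `target`, `n_responsive`, `n_with_ortholog`,
#'   `pct_with_ortholog`, `n_ortholog_responsive`, `pct_ortholog_responsive`.
#' @export
conservation_matrix <- function(reference, responsive, membership) {
  stopifnot(reference %in% names(responsive))
  ref_acc <- responsive[[reference]]
  mem_ref <- membership[membership$species == reference, ]
  ref_groups <- mem_ref$group_id[match(ref_acc, mem_ref$accession)]
  targets <- setdiff(names(responsive), reference)
  rows <- lapply(targets, function(tg) {
    mem_tg <- membership[membership$species == tg, ]
    groups_with_tg <- unique(mem_tg$group_id)
    resp_groups_tg <- unique(mem_tg$group_id[mem_tg$accession %in% responsive[[tg]]])
    has_orth <- !is.na(ref_groups) & ref_groups %in% groups_with_tg
    orth_resp <- !is.na(ref_groups) & ref_groups %in% resp_groups_tg
    n_ref <- length(ref_acc)
    data.frame(reference = reference, target = tg,
               n_responsive = n_ref,
               n_with_ortholog = sum(has_orth),
               pct_with_ortholog = if (n_ref > 0) percentage(sum(has_orth), n_ref) else 0,
               n_ortholog_responsive = sum(orth_resp),
               pct_ortholog_responsive = if (n_ref > 0) percentage(sum(orth_resp), n_ref) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("conservation_matrix", class(out))
  out
}

#' Three-set Venn region accounting of responsive ortholog groups
#'
#' Computes the seven regions of the three-set Venn diagram, tagged A-G:
#' A = shared by all three species; B, C, D = exactly the pairs
#' (first+second, first+third, second+third); E, F, G = specific to the
#' first, second and third species. Pairwise overlap percentages are
#' reported relative to each reference species' total.
#'
#' @param sets named list of exactly three group-id character vectors, in
#'   species order.
#' @return list with `species`, `totals`, `counts` (named A-G), `regions`
#'   (group ids per region) and `pairwise_overlap` (data.frame with
#'   `reference`, `other`, `n_overlap`, `pct_of_reference`).
#' @export
venn_counts <- function(sets) {
  stopifnot(length(sets) == 3L, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  sp <- names(sets)
  s1 <- sets[[1L]]; s2 <- sets[[2L]]; s3 <- sets[[3L]]
  regions <- list(
    A = sort(intersect(intersect(s1, s2), s3)),
    B = sort(setdiff(intersect(s1, s2), s3)),
    C = sort(setdiff(intersect(s1, s3), s2)),
    D = sort(setdiff(intersect(s2, s3), s1)),
    E = sort(setdiff(setdiff(s1, s2), s3)),
    F = sort(setdiff(setdiff(s2, s1), s3)),
    G = sort(setdiff(setdiff(s3, s1), s2)))
  counts <- vapply(regions, length, 0L)
  pairs <- utils::combn(3L, 2L)
  overlap <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    ov <- length(intersect(sets[[i1]], sets[[i2]]))
    rbind(
      data.frame(reference = sp[i1], other = sp[i2], n_overlap = ov,
                 pct_of_reference = if (length(sets[[i1]])) percentage(ov, length(sets[[i1]])) else 0,
                 stringsAsFactors = FALSE),
      data.frame(reference = sp[i2], other = sp[i1], n_overlap = ov,
                 pct_of_reference = if (length(sets[[i2]])) percentage(ov, length(sets[[i2]])) else 0,
                 stringsAsFactors = FALSE))
  }))
  list(species = sp,
       totals = vapply(sets, length, 0L),
       counts = counts,
       regions = regions,
       pairwise_overlap = overlap)
}

#' Needleman-Wunsch global alignment
#'
#' Optimal global alignment under the same affine-gap scoring as
#' [smith_waterman_score()]; used to transfer phosphosite coordinates
#' between ortholog pairs.
#'
#' @param seq_a,seq_b amino-acid strings.
#' @param params a [similarity_params()].
#' @return object of class `"nw_alignment"`: list with the input sequences,
#'   `aligned_a`, `aligned_b` (gapped strings), `score` and `bit_score`.
#' @export
needleman_wunsch_align <- function(seq_a, seq_b, params = similarity_params()) {
  seq_a <- as.character(seq_a)
  seq_b <- as.character(seq_b)
  stopifnot(nzchar(seq_a), nzchar(seq_b))
  al <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global",
    substitutionMatrix = substitution_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  aligned_a <- as.character(Biostrings::alignedPattern(al))
  aligned_b <- as.character(Biostrings::alignedSubject(al))
  bits <- karlin_altschul_evalue(Biostrings::score(al), nchar(seq_a),
                                 nchar(seq_b), params)$bit_score
  structure(list(seq_a = seq_a, seq_b = seq_b,
                 aligned_a = unname(aligned_a), aligned_b = unname(aligned_b),
                 score = Biostrings::score(al), bit_score = bits),
            class = "nw_alignment")
}

#' Map a position through a pairwise alignment
#'
#' Transfers a 1-based coordinate in the first sequence to the aligned
#' coordinate in the second. If the site column is a gap in the second
#' sequence, the mapped position is `NA` and the residue is `"-"`.
#'
#' @param alignment an `"nw_alignment"`.
#' @param position 1-based position in `seq_a`.
#' @return list with `position` (integer or `NA`) and `residue` (single
#'   character, `"-"` for a gap).
#' @export
map_site <- function(alignment, position) {
  a_chars <- strsplit(alignment$aligned_a, "")[[1L]]
  b_chars <- strsplit(alignment$aligned_b, "")[[1L]]
  a_pos <- cumsum(a_chars != "-")
  if (position < 1L || position > max(a_pos)) {
    stop("position ", position, " outside sequence a (length ", max(a_pos), ")")
  }
  col <- which(a_chars != "-" & a_pos == position)
  if (b_chars[col] == "-") {
    list(position = NA_integer_, residue = "-")
  } else {
    list(position = sum(b_chars[seq_len(col)] != "-"), residue = b_chars[col])
  }
}

#' Classify the conservation of a phosphosite across an ortholog pair
#'
#' Categories: `"conserved-responsive"` when the site maps onto a responsive
#' phosphosite of the partner; `"conserved-residue-only"` when the mapped
#' residue is phosphorylatable (S/T/Y) but not responsive;
#' `"position-not-conserved"` when the site maps onto a gap or a
#' non-phosphorylatable residue; `"unalignable"` when the alignment bit
#' score is below `bit_floor`.
#'
#' @param alignment an `"nw_alignment"` between the reference protein
#'   (`seq_a`) and the partner (`seq_b`).
#' @param position 1-based phosphosite position in `seq_a`.
#' @param partner_responsive_positions integer vector of responsive
#'   phosphosite positions in `seq_b`.
#' @param bit_floor minimum alignment bit score for a trustworthy mapping
#'   (default 25 bits).
#' @return list with `category`, `mapped_position`, `mapped_residue`.
#' @export
classify_site <- function(alignment, position, partner_responsive_positions,
                          bit_floor = 25) {
  if (alignment$bit_score < bit_floor) {
    return(list(category = "unalignable", mapped_position = NA_integer_,
                mapped_residue = NA_character_))
  }
  m <- map_site(alignment, position)
  category <- if (is.na(m$position) || !(m$residue %in% c("S", "T", "Y"))) {
    "position-not-conserved"
  } else if (m$position %in% partner_responsive_positions) {
    "conserved-responsive"
  } else {
    "conserved-residue-only"
  }
  list(category = category, mapped_position = m$position,
       mapped_residue = m$residue)
}

#' Responsive phosphosites per protein
#'
#' Expands a phosphopeptide table restricted to responsive peptides into a
#' per-site table, used to build the partner-site lists for
#' [classify_site()].
#'
#' @param peptides phosphopeptide data.frame.
#' @param calls output of [call_responsive()] for the same table.
#' @return data.frame with columns `accession`, `position`, `residue`.
#' @export
responsive_sites <- function(peptides, calls) {
  resp_ids <- calls$peptide_id[calls$responsive]
  pep <- peptides[peptides$peptide_id %in% resp_ids, , drop = FALSE]
  if (nrow(pep) == 0L) {
    return(data.frame(accession = character(0), position = integer(0),
                      residue = character(0), stringsAsFactors = FALSE))
  }
  site_list <- parse_sites(pep$sites)
  n <- vapply(site_list, nrow, 0L)
  out <- data.frame(accession = rep(pep$protein_accession, n),
                    position = unlist(lapply(site_list, `[[`, "position")),
                    residue = unlist(lapply(site_list, `[[`, "residue")),
                    stringsAsFactors = FALSE)
  unique(out)
}
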