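# Ortholog-group parsing and best-hit group assignment. The similarity
# backend is either the internal Smith-Waterman aligner with Karlin-Altschul
# E-values (exact, used throughout the tests) or an externally produced
# 12-column BLAST tabular file; both feed the same lowest-E-value rule.

#' Scoring parameters for protein similarity
#'
#' @param matrix substitution matrix name (a matrix shipped with Biostrings;
#'   default BLOSUM62). Scores against `X` are forced to 0.
#' @param gap_open,gap_extend affine gap penalties (positive; the first gap
#'   residue costs `gap_open + gap_extend`).
#' @param lambda,K Karlin-Altschul parameters for converting raw scores to
#'   bit scores and E-values; defaults are the standard gapped BLOSUM62
#'   values.
#' @return a list of class `"similarity_params"`.
#' @export
similarity_params <- function(matrix = "BLOSUM62", gap_open = 11,
                              gap_extend = 1, lambda = 0.267, K = 0.041) {
  stopifnot(gap_open > 0, gap_extend > 0, lambda > 0, K > 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "similarity_params")
}

substitution_matrix <- function(params) {
  env <- new.env()
  utils::data(list = params$matrix, package = "Biostrings", envir = env)
  m <- env[[params$matrix]]
  if ("X" %in% rownames(m)) {
    m["X", ] <- 0L
    m[, "X"] <- 0L
  }
  m
}

#' Read an OrthoMCL-style groups file
#'
#' Each line is `GROUP_ID: taxon|accession taxon|accession ...`. Empty lines
#' are skipped; a malformed line is a hard error reporting its number; an
#' accession occurring in two groups is a hard error.
#'
#' @param path path to the groups file.
#' @return object of class `"ortholog_groups"`: a list with `table`
#'   (data.frame `group_id`, `species`, `accession`) and `index` (named
#'   character vector, accession to group id).
#' @export
read_groups <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  rows <- list()
  for (i in which(keep)) {
    m <- regmatches(lines[i], regexec("^(\\S+):\\s*(.+)$", lines[i]))[[1]]
    if (length(m) != 3L) stop("malformed groups line ", i, ": ", lines[i])
    members <- strsplit(trimws(m[3L]), "\\s+")[[1]]
    bad <- !grepl("^[^|]+\\|.+$", members)
    if (any(bad)) {
      stop("malformed member '", members[bad][1L], "' on groups line ", i)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      group_id = m[2L],
      species = sub("\\|.*$", "", members),
      accession = sub("^[^|]*\\|", "", members),
      stringsAsFactors = FALSE)
  }
  tbl <- do.call(rbind, rows)
  if (is.null(tbl) || nrow(tbl) == 0L) stop("no groups found in ", path)
  line_ids <- vapply(rows, function(r) r$group_id[1L], "")
  if (anyDuplicated(line_ids)) {
    stop("duplicate group id: ", line_ids[duplicated(line_ids)][1L])
  }
  dup <- tbl$accession[duplicated(tbl$accession)]
  if (length(dup)) {
    stop("accession in more than one group: ", paste(unique(dup), collapse = ", "))
  }
  index <- stats::setNames(tbl$group_id, tbl$accession)
  structure(list(table = tbl, index = index), class = "ortholog_groups")
}

#' Write an OrthoMCL-style groups file
#'
#' @param groups an `"ortholog_groups"` object or its `table` data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_groups <- function(groups, path) {
  tbl <- if (inherits(groups, "ortholog_groups")) groups$table else groups
  ids <- unique(tbl$group_id)
  lines <- vapply(ids, function(g) {
    rows <- tbl[tbl$group_id == g, ]
    paste0(g, ": ", paste0(rows$species, "|", rows$accession, collapse = " "))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment score under the affine-gap convention where the
#' first residue of a gap costs `gap_open + gap_extend`.
#'
#' @param seq_a,seq_b amino-acid strings.
#' @param params a [similarity_params()].
#' @return the raw alignment score.
#' @export
smith_waterman_score <- function(seq_a, seq_b, params = similarity_params()) {
  Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "local",
    substitutionMatrix = substitution_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = TRUE)
}

# Vectorized local scores of many patterns against one subject.
sw_scores_set <- function(patterns, subject, params, subm = NULL) {
  if (is.null(subm)) subm <- substitution_matrix(params)
  Biostrings::pairwiseAlignment(
    patterns, subject, type = "local", substitutionMatrix = subm,
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = TRUE)
}

#' Bit score and E-value from a raw alignment score
#'
#' Karlin-Altschul statistics: `bits = (lambda * S - ln K) / ln 2` and
#' `E = m * n * 2^(-bits)` with `m`, `n` the query and subject lengths.
#'
#' @param raw_score raw alignment score (vectorized).
#' @param len_query,len_subject sequence lengths (positive).
#' @param params a [similarity_params()].
#' @return data.frame with columns `bit_score` and `e_value`.
#' @export
karlin_altschul_evalue <- function(raw_score, len_query, len_subject,
                                   params = similarity_params()) {
  stopifnot(all(len_query > 0), all(len_subject > 0))
  bits <- (params$lambda * raw_score - log(params$K)) / log(2)
  data.frame(bit_score = bits,
             e_value = as.numeric(len_query) * as.numeric(len_subject) * 2^(-bits))
}

#' Read a 12-column BLAST tabular hit file (outfmt 6)
#'
#' @param path path to the tabular file.
#' @return data.frame with the standard column names (`qseqid`, `sseqid`,
#'   ..., `evalue`, `bitscore`).
#' @export
read_blast_tab <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tbl <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tbl) != 12L) stop("expected 12 tab-separated columns, got ", ncol(tbl))
  names(tbl) <- cols
  tbl
}

#' Assign query proteins to ortholog groups by lowest-E-value best hit
#'
#' Mirrors the classification rule used for a species absent from the group
#' catalogue: each query is searched against the reference proteins, hits
#' with `E < e_threshold` (strict) are kept, and the query inherits the
#' group of the subject with the lowest E-value (ties broken by higher bit
#' score, then lexicographically smallest subject accession). Queries with
#' no qualifying hit, or whose best subject carries no group, are unassigned.
#'
#' With `hits = NULL` the internal Smith-Waterman / Karlin-Altschul backend
#' aligns every query against every reference. Alternatively a precomputed
#' BLAST tabular data.frame (from [read_blast_tab()]) supplies E-values and
#' bit scores directly; rows whose query or subject accession is unknown are
#' dropped with a warning.
#'
#' @param queries named `AAStringSet` (or named character vector) of query
#'   proteins; with a tabular backend a bare character vector of accessions
#'   is accepted.
#' @param references named `AAStringSet` of reference proteins carrying
#'   group membership (ignored by the tabular backend).
#' @param groups an `"ortholog_groups"` object from [read_groups()].
#' @param params a [similarity_params()].
#' @param e_threshold strict E-value cutoff, default 1e-5.
#' @param hits optional BLAST tabular data.frame.
#' @return data.frame with one row per query: `query`, `group_id` (`NA` when
#'   unassigned), `subject`, `e_value`, `bit_score`, `backend`.
#' @export
assign_best_hit <- function(queries, references = NULL, groups,
                            params = similarity_params(), e_threshold = 1e-5,
                            hits = NULL) {
  if (is.null(hits)) {
    qnames <- names(queries)
    stopifnot(!is.null(qnames), !is.null(names(references)))
    subm <- substitution_matrix(params)
    rseqs <- as_named_seqs(references)
    refs <- Biostrings::AAStringSet(unname(rseqs))
    rlen <- nchar(rseqs)
    all_hits <- vector("list", length(queries))
    qseqs <- as_named_seqs(queries)
    for (i in seq_along(qseqs)) {
      sc <- sw_scores_set(refs, qseqs[[i]], params, subm)
      ka <- karlin_altschul_evalue(sc, nchar(qseqs[[i]]), rlen, params)
      all_hits[[i]] <- data.frame(qseqid = qnames[i], sseqid = names(rseqs),
                                  evalue = ka$e_value, bitscore = ka$bit_score,
                                  stringsAsFactors = FALSE)
    }
    hit_tbl <- do.call(rbind, all_hits)
    backend <- "internal"
  } else {
    qnames <- if (is.null(names(queries))) as.character(queries) else names(queries)
    known_subj <- unique(c(names(groups$index),
                           if (!is.null(references)) names(references)))
    bad <- !(hits$qseqid %in% qnames) | !(hits$sseqid %in% known_subj)
    if (any(bad)) {
      warning(sum(bad), " hit row(s) with unknown accession dropped")
    }
    hit_tbl <- hits[!bad, c("qseqid", "sseqid", "evalue", "bitscore")]
    backend <- "tabular"
  }
  out <- data.frame(query = qnames, group_id = NA_character_,
                    subject = NA_character_, e_value = NA_real_,
                    bit_score = NA_real_, backend = backend,
                    stringsAsFactors = FALSE)
  qual <- hit_tbl[hit_tbl$evalue < e_threshold, , drop = FALSE]
  if (nrow(qual)) {
    qual <- qual[order(qual$qseqid, qual$evalue, -qual$bitscore, qual$sseqid), ]
    best <- qual[!duplicated(qual$qseqid), ]
    idx <- match(best$qseqid, out$query)
    out$subject[idx] <- best$sseqid
    out$e_value[idx] <- best$evalue
    out$bit_score[idx] <- best$bitscore
    gid <- unname(groups$index[best$sseqid])
    out$group_id[idx] <- gid
  }
  rownames(out) <- NULL
  out
}
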