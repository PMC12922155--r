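# Readers/writers for proteome FASTA and phosphopeptide quantification
# tables, plus the dataset-level summary statistics (enrichment efficiency,
# phosphoresidue distribution, site multiplicity).

#' Read a proteome FASTA file
#'
#' Parses a protein FASTA into an [Biostrings::AAStringSet]. The accession is
#' the first whitespace-delimited token of the header; sequences are
#' uppercased and stop characters (`*`) are stripped.
#'
#' @param path path to a FASTA file.
#' @param species optional species tag stored in the `"species"` attribute.
#' @return an `AAStringSet` named by accession.
#' @export
read_proteome <- function(path, species = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  acc <- sub("\\s.*$", "", names(aa))
  dup <- acc[duplicated(acc)]
  if (length(dup)) {
    stop("duplicate accession(s) in proteome: ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(gsub("\\*", "", as.character(aa)))
  if (any(!nzchar(seqs))) stop("empty sequence in proteome: ", path)
  names(seqs) <- acc
  out <- Biostrings::AAStringSet(seqs)
  attr(out, "species") <- species
  out
}

#' Write a proteome FASTA file
#'
#' @param proteome named `AAStringSet` or named character vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_proteome <- function(proteome, path) {
  if (!methods::is(proteome, "XStringSet")) {
    proteome <- Biostrings::AAStringSet(proteome)
  }
  Biostrings::writeXStringSet(proteome, path, width = 60L)
  invisible(path)
}

#' Parse a semicolon-joined phosphosite string
#'
#' `"S173;S177"` becomes a data.frame with one row per site. Positions are
#' 1-based on the full protein sequence.
#'
#' @param sites character vector of site strings.
#' @return a list of data.frames with columns `residue` and `position`.
#' @export
parse_sites <- function(sites) {
  lapply(strsplit(as.character(sites), ";", fixed = TRUE), function(parts) {
    parts <- parts[nzchar(parts)]
    ok <- grepl("^[STY][0-9]+$", parts)
    if (length(parts) == 0L || !all(ok)) {
      stop("malformed phosphosite specification: '",
           paste(parts, collapse = ";"), "'")
    }
    data.frame(residue = substr(parts, 1L, 1L),
               position = as.integer(substring(parts, 2L)),
               stringsAsFactors = FALSE)
  })
}

format_sites <- function(site_list) {
  vapply(site_list, function(df) paste0(df$residue, df$position, collapse = ";"), "")
}

#' Read a phosphopeptide quantification table
#'
#' The table is a TSV with columns `peptide_id`, `bare_sequence`,
#' `protein_accession`, `sites` (semicolon-joined residue+position, e.g.
#' `"S173;S177"`), followed by the twelve abundance columns `t0_r1` ...
#' `t90_r3`. Blank abundance cells are read as missing (`NA`), never as zero.
#'
#' If a proteome is supplied, every site is cross-checked: a residue mismatch
#' or a position beyond the protein length quarantines the row (with a
#' warning) rather than aborting the run; quarantined rows are returned in
#' the `"rejects"` attribute and optionally written to a sidecar TSV with a
#' `reason` column. A malformed site string is a hard error.
#'
#' @param path path to the TSV.
#' @param species species tag recorded in the `species` column.
#' @param proteome optional `AAStringSet` from [read_proteome()] used to
#'   validate site residues and positions.
#' @param rejects_path optional path for the sidecar rejects TSV.
#' @return data.frame of validated peptides with a `species` column and an
#'   attribute `"rejects"` holding the quarantined rows.
#' @export
read_phosphopeptide_table <- function(path, species, proteome = NULL,
                                      rejects_path = NULL) {
  tbl <- read_tsv_plain(path)
  need <- c("peptide_id", "bare_sequence", "protein_accession", "sites",
            abundance_columns())
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols)) {
    stop("phosphopeptide table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tbl <- tbl[, need]
  for (cc in abundance_columns()) tbl[[cc]] <- as.numeric(tbl[[cc]])
  site_list <- parse_sites(tbl$sites)   # hard error on malformed rows

  reason <- rep(NA_character_, nrow(tbl))
  if (!is.null(proteome)) {
    seqs <- as_named_seqs(proteome)
    for (i in seq_len(nrow(tbl))) {
      seq <- seqs[[tbl$protein_accession[i]]]
      if (is.null(seq) || is.na(seq)) {
        reason[i] <- "unknown protein accession"
        next
      }
      st <- site_list[[i]]
      if (any(st$position > nchar(seq))) {
        reason[i] <- "site position beyond protein length"
        next
      }
      obs <- substring(seq, st$position, st$position)
      if (any(obs != st$residue)) {
        reason[i] <- sprintf("site residue mismatch (expected %s, protein has %s)",
                             paste0(st$residue, st$position, collapse = ";"),
                             paste0(obs, st$position, collapse = ";"))
      }
    }
  }
  bad <- !is.na(reason)
  if (any(bad)) {
    warning(sum(bad), " row(s) quarantined while reading ", path)
    rejects <- cbind(tbl[bad, , drop = FALSE], reason = reason[bad])
    if (!is.null(rejects_path)) write_tsv_plain(rejects, rejects_path)
  } else {
    rejects <- cbind(tbl[0, , drop = FALSE], reason = character(0))
  }
  out <- tbl[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out <- cbind(out[, 1:4, drop = FALSE],
               species = rep(species, nrow(out)),
               out[, abundance_columns(), drop = FALSE],
               stringsAsFactors = FALSE)
  attr(out, "rejects") <- rejects
  out
}

#' Write a phosphopeptide quantification table
#'
#' Inverse of [read_phosphopeptide_table()] on the documented TSV dialect;
#' missing abundances are written as empty cells.
#'
#' @param peptides data.frame of peptides.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_phosphopeptide_table <- function(peptides, path) {
  cols <- c("peptide_id", "bare_sequence", "protein_accession", "sites",
            abundance_columns())
  write_tsv_plain(peptides[, cols], path)
}

#' Phosphopeptide enrichment efficiency
#'
#' The fraction of identified peptides that carry at least one phosphosite,
#' reported as an integer percentage (half away from zero). This is the
#' standard figure of merit for a phosphopeptide enrichment step.
#'
#' @param n_phosphopeptides number of phosphopeptides.
#' @param n_peptides_total total identified peptides; must be positive.
#' @return integer percent.
#' @export
#' @examples
#' enrichment_efficiency(24604, 34767)  # 71
enrichment_efficiency <- function(n_phosphopeptides, n_peptides_total) {
  if (n_peptides_total <= 0) stop("n_peptides_total must be positive")
  stopifnot(n_phosphopeptides >= 0, n_phosphopeptides <= n_peptides_total)
  round_half_out(100 * n_phosphopeptides / n_peptides_total, 0)
}

#' Distribution of phosphorylated residues
#'
#' Counts every localized site once (a doubly phosphorylated peptide
#' contributes two sites) and reports pS/pT/pY percentages to one decimal.
#'
#' @param peptides phosphopeptide data.frame.
#' @return named numeric vector `c(pS=, pT=, pY=)`.
#' @export
residue_distribution <- function(peptides) {
  res <- unlist(lapply(parse_sites(peptides$sites), `[[`, "residue"))
  if (length(res) == 0L) stop("no phosphosites in table")
  counts <- vapply(c("S", "T", "Y"), function(r) sum(res == r), 0L)
  out <- round_half_out(100 * counts / length(res), 1)
  names(out) <- c("pS", "pT", "pY")
  out
}

#' Distribution of phosphosite multiplicity
#'
#' Bins peptides by number of localized sites (1, 2, >=3) and reports
#' percentages to one decimal.
#'
#' @param peptides phosphopeptide data.frame.
#' @return named numeric vector `c("1"=, "2"=, "3+"=)`.
#' @export
multiplicity_distribution <- function(peptides) {
  n_sites <- vapply(parse_sites(peptides$sites), nrow, 0L)
  if (length(n_sites) == 0L) stop("no peptides in table")
  counts <- c(sum(n_sites == 1L), sum(n_sites == 2L), sum(n_sites >= 3L))
  out <- round_half_out(100 * counts / length(n_sites), 1)
  names(out) <- c("1", "2", "3+")
  out
}

#' Dataset-level summary of a phosphoproteomics run
#'
#' @param peptides phosphopeptide data.frame.
#' @param n_peptides_total total identified peptides (phospho and not); when
#'   `NULL`, the enrichment efficiency is `NA`.
#' @return a list with counts, residue and multiplicity distributions, and
#'   the enrichment efficiency.
#' @export
dataset_summary <- function(peptides, n_peptides_total = NULL) {
  list(
    n_phosphopeptides = nrow(peptides),
    n_proteins = length(unique(peptides$protein_accession)),
    n_peptides_total = n_peptides_total,
    enrichment_efficiency = if (is.null(n_peptides_total)) NA_real_ else
      enrichment_efficiency(nrow(peptides), n_peptides_total),
    residue_fractions = residue_distribution(peptides),
    multiplicity_fractions = multiplicity_distribution(peptides)
  )
}
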