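# Orchestration: per-species analysis (summary, responsiveness calls,
# motifs, PCA QC) and the cross-species comparison (assignments,
# conservation matrices, Venn regions, site-conservation classes).

#' Run the per-species analysis stage
#'
#' Reads the proteome and phosphopeptide table of one species, computes the
#' dataset summary, responsiveness calls, responsive-protein list, motif
#' enrichment of responsive phosphosites against the whole-proteome
#' background, and PCA QC. When `outdir` is given, every artifact is written
#' as a plain-text file (TSV / one-accession-per-line / JSON summary).
#'
#' @param proteome_path path to the species proteome FASTA.
#' @param quant_path path to the phosphopeptide TSV.
#' @param species species tag.
#' @param outdir optional output directory for artifacts.
#' @param config a [stat_config()].
#' @param mconfig a [motif_config()].
#' @param n_peptides_total optional total identified-peptide count for the
#'   enrichment-efficiency summary.
#' @return list with `species`, `proteome`, `peptides`, `summary`, `calls`,
#'   `responsive_proteins`, `responsive_sites`, `motifs`, `pca`.
#' @export
run_species <- function(proteome_path, quant_path, species, outdir = NULL,
                        config = stat_config(), mconfig = motif_config(),
                        n_peptides_total = NULL) {
  proteome <- read_proteome(proteome_path, species)
  rejects_path <- if (is.null(outdir)) NULL else
    file.path(outdir, sprintf("rejects_%s.tsv", species))
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  peptides <- read_phosphopeptide_table(quant_path, species, proteome,
                                        rejects_path)
  summary <- dataset_summary(peptides, n_peptides_total)
  calls <- call_responsive(peptides, config)
  resp_proteins <- collapse_to_proteins(calls)
  sites <- responsive_sites(peptides, calls)
  fg <- extract_windows(proteome, sites, mconfig$half_width)
  bg <- background_windows(proteome, mconfig$half_width)
  motifs <- run_motifx(fg, bg, mconfig)
  pca <- pca_qc(log2_abundance_matrix(peptides))
  if (!is.null(outdir)) {
    write_tsv_plain(calls, file.path(outdir, sprintf("calls_%s.tsv", species)))
    writeLines(resp_proteins,
               file.path(outdir, sprintf("responsive_proteins_%s.txt", species)))
    write_tsv_plain(motifs, file.path(outdir, sprintf("motifs_%s.tsv", species)))
    if (!is.null(pca)) {
      sc <- data.frame(sample = rownames(pca$scores), pca$scores,
                       check.names = FALSE)
      write_tsv_plain(sc, file.path(outdir, sprintf("pca_%s.tsv", species)))
    }
    jsonlite::write_json(summary,
                         file.path(outdir, sprintf("summary_%s.json", species)),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  }
  list(species = species, proteome = proteome, peptides = peptides,
       summary = summary, calls = calls, responsive_proteins = resp_proteins,
       responsive_sites = sites, motifs = motifs, pca = pca)
}

#' Alignment-based site-conservation classification across species pairs
#'
#' For every responsive phosphosite of each reference species whose protein
#' belongs to a group with members in a partner species, aligns the protein
#' pair (the partner-group member with the highest alignment bit score, when
#' there are paralogs) and classifies the site with [classify_site()].
#'
#' @param proteomes named list (by species) of sequences (`AAStringSet` or
#'   named character vectors).
#' @param sites_list named list (by species) of responsive-site data.frames
#'   from [responsive_sites()].
#' @param membership data.frame from [group_membership()].
#' @param params a [similarity_params()].
#' @param bit_floor minimum alignment bit score, see [classify_site()].
#' @return data.frame with one row per (site, partner species).
#' @export
site_conservation <- function(proteomes, sites_list, membership,
                              params = similarity_params(), bit_floor = 25) {
  proteomes <- lapply(proteomes, as_named_seqs)
  species <- names(sites_list)
  aln_cache <- new.env(parent = emptyenv())
  get_aln <- function(seq_a, seq_b, key) {
    if (is.null(aln_cache[[key]])) {
      aln_cache[[key]] <- needleman_wunsch_align(seq_a, seq_b, params)
    }
    aln_cache[[key]]
  }
  rows <- list()
  for (a in species) {
    sites <- sites_list[[a]]
    if (nrow(sites) == 0L) next
    mem_a <- membership[membership$species == a, ]
    site_group <- mem_a$group_id[match(sites$accession, mem_a$accession)]
    for (b in setdiff(species, a)) {
      mem_b <- membership[membership$species == b, ]
      resp_b <- sites_list[[b]]
      for (i in seq_len(nrow(sites))) {
        gid <- site_group[i]
        if (is.na(gid)) next
        partners <- mem_b$accession[mem_b$group_id == gid]
        partners <- partners[partners %in% names(proteomes[[b]])]
        if (length(partners) == 0L) next
        seq_a <- proteomes[[a]][[sites$accession[i]]]
        alns <- lapply(partners, function(p) {
          get_aln(seq_a, proteomes[[b]][[p]],
                  paste(a, sites$accession[i], b, p, sep = "\r"))
        })
        j <- which.max(vapply(alns, `[[`, 0, "bit_score"))
        partner <- partners[j]
        aln <- alns[[j]]
        partner_pos <- resp_b$position[resp_b$accession == partner]
        cl <- classify_site(aln, sites$position[i], partner_pos, bit_floor)
        rows[[length(rows) + 1L]] <- data.frame(
          group_id = gid, ref_species = a, ref_accession = sites$accession[i],
          ref_position = sites$position[i], ref_residue = sites$residue[i],
          target_species = b, target_accession = partner,
          mapped_position = cl$mapped_position,
          mapped_residue = cl$mapped_residue,
          category = cl$category,
          bit_score = round(aln$bit_score, 1L), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(group_id = character(0), ref_species = character(0),
                      ref_accession = character(0), ref_position = integer(0),
                      ref_residue = character(0), target_species = character(0),
                      target_accession = character(0),
                      mapped_position = integer(0),
                      mapped_residue = character(0), category = character(0),
                      bit_score = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Run the cross-species comparison stage
#'
#' Assigns every species missing from the group catalogue by lowest-E-value
#' best hit, then computes responsive ortholog-group sets, the conservation
#' matrix for each reference species, three-set Venn regions, and
#' alignment-based site-conservation classes. All species must be present.
#'
#' @param species_runs named list of [run_species()] results (all three
#'   species).
#' @param groups an `"ortholog_groups"` object from [read_groups()].
#' @param outdir optional output directory for artifacts.
#' @param params a [similarity_params()].
#' @param e_threshold strict E-value cutoff for best-hit assignment.
#' @param bit_floor minimum alignment bit score for site classification.
#' @param hits optional named list (by query species) of BLAST tabular
#'   data.frames, bypassing the internal aligner.
#' @return list with `assignments`, `membership`, `responsive_groups`,
#'   `matrices`, `venn`, `sites`.
#' @export
run_comparison <- function(species_runs, groups, outdir = NULL,
                           params = similarity_params(), e_threshold = 1e-5,
                           bit_floor = 25, hits = NULL) {
  species <- names(species_runs)
  if (length(species) < 2L) stop("need at least two species")
  catalogue <- unique(groups$table$species)
  missing_sp <- setdiff(catalogue, species)
  if (length(missing_sp)) {
    stop("species in groups file but not supplied: ",
         paste(missing_sp, collapse = ", "))
  }
  proteomes <- lapply(species_runs, function(r) as_named_seqs(r$proteome))
  membership <- groups$table
  assignments <- list()
  for (qs in setdiff(species, catalogue)) {
    refs <- unlist(lapply(catalogue, function(s) proteomes[[s]]))
    refs <- refs[names(refs) %in% names(groups$index)]
    asg <- assign_best_hit(queries = proteomes[[qs]],
                           references = refs, groups = groups,
                           params = params, e_threshold = e_threshold,
                           hits = hits[[qs]])
    assignments[[qs]] <- asg
    membership <- group_membership(list(table = membership,
                                        index = groups$index),
                                   asg, qs)
  }
  responsive <- lapply(species_runs, `[[`, "responsive_proteins")
  resp_groups <- responsive_group_sets(responsive, membership)
  matrices <- do.call(rbind, lapply(species, function(s) {
    conservation_matrix(s, responsive, membership)
  }))
  venn <- if (length(species) == 3L) venn_counts(resp_groups) else NULL
  sites_list <- lapply(species_runs, `[[`, "responsive_sites")
  sites <- site_conservation(proteomes, sites_list, membership, params,
                             bit_floor)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (qs in names(assignments)) {
      write_tsv_plain(assignments[[qs]],
                      file.path(outdir, sprintf("assignments_%s.tsv", qs)))
    }
    write_tsv_plain(as.data.frame(matrices),
                    file.path(outdir, "conservation_matrix.tsv"))
    if (!is.null(venn)) {
      jsonlite::write_json(venn, file.path(outdir, "venn.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      for (rg in names(venn$regions)) {
        writeLines(venn$regions[[rg]],
                   file.path(outdir, sprintf("venn_region_%s.txt", rg)))
      }
    }
    write_tsv_plain(sites, file.path(outdir, "site_conservation.tsv"))
  }
  list(assignments = assignments, membership = membership,
       responsive_groups = resp_groups, matrices = matrices, venn = venn,
       sites = sites)
}

#' Run the full pipeline on a synthetic fixture bundle directory
#'
#' Convenience wrapper over [run_species()] and [run_comparison()] for the
#' directory layout written by [write_fixture_bundle()].
#'
#' @param bundle_dir directory containing `proteome_<sp>.fasta`,
#'   `phosphopeptides_<sp>.tsv` and `groups.txt`.
#' @param outdir optional artifact directory.
#' @param species species tags; defaults to those found in the bundle.
#' @param config,mconfig,params,e_threshold,bit_floor passed through.
#' @return list with `species` (per-species results) and `comparison`.
#' @export
run_bundle <- function(bundle_dir, outdir = NULL, species = NULL,
                       config = stat_config(), mconfig = motif_config(),
                       params = similarity_params(), e_threshold = 1e-5,
                       bit_floor = 25) {
  if (is.null(species)) {
    species <- sub("^proteome_(.*)\\.fasta$", "\\1",
                   basename(Sys.glob(file.path(bundle_dir, "proteome_*.fasta"))))
  }
  runs <- lapply(stats::setNames(species, species), function(s) {
    run_species(file.path(bundle_dir, sprintf("proteome_%s.fasta", s)),
                file.path(bundle_dir, sprintf("phosphopeptides_%s.tsv", s)),
                s, outdir = outdir, config = config, mconfig = mconfig)
  })
  groups <- read_groups(file.path(bundle_dir, "groups.txt"))
  comparison <- run_comparison(runs, groups, outdir = outdir, params = params,
                               e_threshold = e_threshold,
                               bit_floor = bit_floor)
  list(species = runs, comparison = comparison)
}
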