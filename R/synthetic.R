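# Seeded synthetic three-species fixture generator with planted ground
# truth: protein families evolved from a founder sequence, tryptic-like
# phosphopeptides with log-normal abundances and planted fold-change
# responders, planted sequence motifs around responsive sites, and planted
# cross-species site pairs of known conservation category.

# Rough proteome-wide amino-acid frequencies (percent-scale weights) used
# for founder sequences, insertions and decoys.
AA_FREQ <- c(A = 7.5, C = 1.5, D = 5.5, E = 6.5, F = 4.0, G = 6.5, H = 2.5,
             I = 5.0, K = 6.0, L = 9.5, M = 2.5, N = 4.5, P = 5.0, Q = 3.5,
             R = 5.5, S = 9.0, T = 5.0, V = 6.5, W = 1.5, Y = 3.0)

#' Configuration of the synthetic fixture generator
#'
#' The defaults define the reference study conditions used throughout the
#' test suite: three species (a founder species, a moderately diverged
#' partner and a more diverged held-out species absent from the group
#' catalogue), 200 ortholog families, 2000 phosphopeptides per species with
#' three replicates at 0/15/30/90 min, 4-fold planted responders with
#' log2-scale noise SD 0.1, a `(-3, R)` motif planted around 60% of
#' responsive sites, and planted cross-species site pairs covering the three
#' conservation categories.
#'
#' @param seed integer RNG seed; mandatory, every random draw derives from
#'   it.
#' @param n_families number of ortholog families.
#' @param n_decoys unrelated decoy proteins per species (never in a group).
#' @param species three species tags; the first is the founder, the third is
#'   held out of the groups file and assigned by best hit.
#' @param divergence named list per species of `p_sub` (per-site
#'   substitution probability relative to the founder sequence) and
#'   `indel_rate` (per-site indel initiation probability).
#' @param protein_length integer range (min, max) of founder lengths.
#' @param indel_geom,indel_max geometric length parameter and cap for indel
#'   lengths.
#' @param n_peptides phosphopeptides per species.
#' @param fraction_responsive fraction of peptides planted as responders.
#' @param effect_size linear fold change of planted responders.
#' @param noise_sigma log2-scale replicate noise SD.
#' @param residue_mix pS/pT/pY site-residue probabilities.
#' @param multiplicity_mix probabilities of 1, 2 and 3 sites per peptide.
#' @param motif_offset,motif_residue,motif_penetrance planted motif: the
#'   residue written at `motif_offset` relative to the first site of a
#'   responsive peptide, with the given penetrance.
#' @param n_site_families families that carry a planted cross-species site
#'   pair (categories cycle conserved-responsive / conserved-residue-only /
#'   position-not-conserved).
#' @param missing_rate per-cell missing-value probability.
#' @param baseline_log2_mean,baseline_log2_sd log2 abundance distribution of
#'   peptide baselines.
#' @return a list of class `"generator_config"`.
#' @export
generator_config <- function(seed,
                             n_families = 200L,
                             n_decoys = 40L,
                             species = c("ath", "osa", "gma"),
                             divergence = list(
                               ath = list(p_sub = 0.00, indel_rate = 0.000),
                               osa = list(p_sub = 0.10, indel_rate = 0.003),
                               gma = list(p_sub = 0.15, indel_rate = 0.003)),
                             protein_length = c(250L, 400L),
                             indel_geom = 0.5, indel_max = 5L,
                             n_peptides = 2000L,
                             fraction_responsive = 0.1,
                             effect_size = 4,
                             noise_sigma = 0.1,
                             residue_mix = c(S = 0.88, T = 0.117, Y = 0.003),
                             multiplicity_mix = c("1" = 0.787, "2" = 0.173,
                                                  "3" = 0.04),
                             motif_offset = -3L, motif_residue = "R",
                             motif_penetrance = 0.6,
                             n_site_families = 36L,
                             missing_rate = 0.05,
                             baseline_log2_mean = 20,
                             baseline_log2_sd = 2) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(length(species) == 3L, all(species %in% names(divergence)),
            fraction_responsive >= 0, fraction_responsive <= 1,
            effect_size > 0, noise_sigma >= 0, missing_rate >= 0,
            missing_rate < 1, motif_penetrance >= 0, motif_penetrance <= 1,
            n_site_families <= n_families)
  structure(list(seed = as.integer(seed), n_families = as.integer(n_families),
                 n_decoys = as.integer(n_decoys), species = species,
                 divergence = divergence,
                 protein_length = as.integer(protein_length),
                 indel_geom = indel_geom, indel_max = as.integer(indel_max),
                 n_peptides = as.integer(n_peptides),
                 fraction_responsive = fraction_responsive,
                 effect_size = effect_size, noise_sigma = noise_sigma,
                 residue_mix = residue_mix / sum(residue_mix),
                 multiplicity_mix = multiplicity_mix / sum(multiplicity_mix),
                 motif_offset = as.integer(motif_offset),
                 motif_residue = motif_residue,
                 motif_penetrance = motif_penetrance,
                 n_site_families = as.integer(n_site_families),
                 missing_rate = missing_rate,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd),
            class = "generator_config")
}

random_protein <- function(length) {
  sample(names(AA_FREQ), length, replace = TRUE, prob = AA_FREQ)
}

# Evolve a founder character vector: i.i.d. substitutions, then indels with
# geometric lengths. Returns the derived characters and the coordinate map
# founder position -> derived position (NA where deleted).
evolve_sequence <- function(founder, p_sub, indel_rate, indel_geom, indel_max) {
  L <- length(founder)
  chars <- founder
  sub_idx <- which(stats::runif(L) < p_sub)
  if (length(sub_idx)) {
    shift <- sample(19L, length(sub_idx), replace = TRUE)
    chars[sub_idx] <-
      AMINO_ACIDS[((match(chars[sub_idx], AMINO_ACIDS) - 1L + shift) %% 20L) + 1L]
  }
  if (indel_rate <= 0) {
    return(list(chars = chars, map = seq_len(L)))
  }
  keep <- rep(TRUE, L)
  ins_after <- vector("list", L)
  for (p in which(stats::runif(L) < indel_rate)) {
    len <- min(stats::rgeom(1L, indel_geom) + 1L, indel_max)
    if (stats::runif(1L) < 0.5) {
      span <- p:min(L, p + len - 1L)
      keep[span] <- FALSE
    } else {
      ins_after[[p]] <- random_protein(len)
    }
  }
  out <- character(L + sum(lengths(ins_after)))
  map <- rep(NA_integer_, L)
  k <- 0L
  for (p in seq_len(L)) {
    if (keep[p]) {
      k <- k + 1L
      out[k] <- chars[p]
      map[p] <- k
    }
    ins <- ins_after[[p]]
    if (!is.null(ins)) {
      out[k + seq_along(ins)] <- ins
      k <- k + length(ins)
    }
  }
  list(chars = out[seq_len(k)], map = map)
}

#' Generate evolved protein families, decoys and the groups file content
#'
#' Founder proteins are drawn per family and evolved per species by i.i.d.
#' substitutions and geometric indels. The first two species form the group
#' catalogue; the third is held out (assigned later by best hit). Unrelated
#' decoy proteins are added per species. Families designated as site
#' families carry a planted phosphosite whose partner-species fate encodes a
#' conservation category.
#'
#' Sets the RNG from `config$seed`.
#'
#' @param config a [generator_config()].
#' @return list with `proteomes` (per species, named character vectors),
#'   `families` (data.frame `group_id`, `species`, `accession` for all three
#'   species), `groups` (the same restricted to the first two species),
#'   `decoys` (per species accession vectors) and `site_pairs` (planted
#'   cross-species site truth).
#' @export
generate_families <- function(config) {
  set.seed(config$seed)
  sp <- config$species
  n <- config$n_families
  proteomes <- stats::setNames(vector("list", 3L), sp)
  fam_rows <- list()
  site_rows <- list()
  categories <- c("conserved-responsive", "conserved-residue-only",
                  "position-not-conserved")
  for (i in seq_len(n)) {
    L <- sample(config$protein_length[1L]:config$protein_length[2L], 1L)
    founder <- random_protein(L)
    group_id <- sprintf("OG7_%07d", i)
    derived <- list()
    for (s in sp) {
      d <- config$divergence[[s]]
      derived[[s]] <- evolve_sequence(founder, d$p_sub, d$indel_rate,
                                      config$indel_geom, config$indel_max)
    }
    if (i <= config$n_site_families) {
      category <- categories[((i - 1L) %% 3L) + 1L]
      map2 <- derived[[sp[2L]]]$map
      cand <- which(!(founder %in% c("K", "R", "P")) & !is.na(map2))
      cand <- cand[cand > 7L & cand < L - 7L]
      if (length(cand)) {
        a <- if (length(cand) == 1L) cand else sample(cand, 1L)
        derived[[sp[1L]]]$chars[a] <- "S"
        partner_res <- if (category == "position-not-conserved") "A" else "S"
        derived[[sp[2L]]]$chars[map2[a]] <- partner_res
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          group_id = group_id,
          ref_species = sp[1L],
          ref_accession = sprintf("%s_p%04d", sp[1L], i),
          ref_position = a,
          target_species = sp[2L],
          target_accession = sprintf("%s_p%04d", sp[2L], i),
          target_position = map2[a],
          category = category, stringsAsFactors = FALSE)
      }
    }
    for (s in sp) {
      acc <- sprintf("%s_p%04d", s, i)
      proteomes[[s]][[acc]] <- paste(derived[[s]]$chars, collapse = "")
      fam_rows[[length(fam_rows) + 1L]] <- data.frame(
        group_id = group_id, species = s, accession = acc,
        stringsAsFactors = FALSE)
    }
  }
  decoys <- stats::setNames(vector("list", 3L), sp)
  for (s in sp) {
    for (j in seq_len(config$n_decoys)) {
      L <- sample(config$protein_length[1L]:config$protein_length[2L], 1L)
      acc <- sprintf("%s_dec%03d", s, j)
      proteomes[[s]][[acc]] <- paste(random_protein(L), collapse = "")
      decoys[[s]] <- c(decoys[[s]], acc)
    }
    proteomes[[s]] <- unlist(proteomes[[s]])
  }
  families <- do.call(rbind, fam_rows)
  site_pairs <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(group_id = character(0), ref_species = character(0),
               ref_accession = character(0), ref_position = integer(0),
               target_species = character(0), target_accession = character(0),
               target_position = integer(0), category = character(0),
               stringsAsFactors = FALSE)
  list(proteomes = proteomes,
       families = families,
       groups = families[families$species %in% sp[1:2], ],
       decoys = decoys,
       site_pairs = site_pairs)
}

# Tryptic-like digestion: cut after K or R, never before P.
tryptic_peptides <- function(seq) {
  chars <- strsplit(seq, "")[[1L]]
  L <- length(chars)
  after <- which(chars %in% c("K", "R"))
  after <- after[after < L]
  after <- after[chars[after + 1L] != "P"]
  data.frame(start = c(1L, after + 1L), end = c(after, L))
}

#' Generate phosphopeptide quantification tables with planted truth
#'
#' Peptides are sampled from the tryptic-like digest of each species'
#' proteome. Phosphosite residues are written into the sequences per the
#' configured residue and multiplicity mixes; responders are planted with a
#' fold change of `effect_size` from a random onset timepoint onward; the
#' configured motif residue is written at `motif_offset` of responsive sites
#' with the configured penetrance; site-family peptides realize the planted
#' cross-species pairs. Abundances are log-normal with replicate noise
#' `noise_sigma`; cells go missing at `missing_rate`.
#'
#' Sets the RNG from `config$seed + 1`.
#'
#' @param config a [generator_config()].
#' @param fams output of [generate_families()].
#' @return list with `peptides` (per species data.frames), `proteomes` (per
#'   species, after site edits) and `truth`.
#' @export
generate_quant_tables <- function(config, fams) {
  set.seed(config$seed + 1L)
  sp <- config$species
  peptides <- list()
  proteomes <- fams$proteomes
  site_pairs <- fams$site_pairs
  all_pairs <- site_pairs   # incl. later-unrealized rows; used for blocking
  realized <- rep(TRUE, nrow(site_pairs))
  truth <- list(responsive_peptides = list(), responsive_proteins = list(),
                motif_sites = list(), onsets = list())

  # eligible digest fragments per species
  candidates <- lapply(sp, function(s) {
    prot <- proteomes[[s]]
    frags <- do.call(rbind, lapply(names(prot), function(acc) {
      d <- tryptic_peptides(prot[[acc]])
      d$accession <- acc
      d
    }))
    frags$len <- frags$end - frags$start + 1L
    frags[frags$len >= 9L & frags$len <= 35L, c("accession", "start", "end", "len")]
  })
  names(candidates) <- sp

  # locate the digest fragment containing a planted site
  find_fragment <- function(cand, acc, pos) {
    hit <- which(cand$accession == acc & cand$start <= pos & cand$end >= pos)
    if (length(hit)) hit[1L] else NA_integer_
  }
  forced <- stats::setNames(rep(list(NULL), 3L), sp)
  if (nrow(site_pairs)) {
    for (r in seq_len(nrow(site_pairs))) {
      i_ref <- find_fragment(candidates[[site_pairs$ref_species[r]]],
                             site_pairs$ref_accession[r],
                             site_pairs$ref_position[r])
      i_tgt <- if (site_pairs$category[r] == "conserved-responsive") {
        find_fragment(candidates[[site_pairs$target_species[r]]],
                      site_pairs$target_accession[r],
                      site_pairs$target_position[r])
      } else 0L   # no partner peptide needed
      if (is.na(i_ref) || is.na(i_tgt)) {
        realized[r] <- FALSE
        next
      }
      forced[[site_pairs$ref_species[r]]] <-
        rbind(forced[[site_pairs$ref_species[r]]],
              cbind(candidates[[site_pairs$ref_species[r]]][i_ref, ],
                    site = site_pairs$ref_position[r]))
      if (i_tgt > 0L) {
        forced[[site_pairs$target_species[r]]] <-
          rbind(forced[[site_pairs$target_species[r]]],
                cbind(candidates[[site_pairs$target_species[r]]][i_tgt, ],
                      site = site_pairs$target_position[r]))
      }
    }
    site_pairs <- site_pairs[realized, , drop = FALSE]
  }

  # planted pair positions are reserved: the general sampler must neither
  # phosphorylate nor motif-edit them, so fragments covering them are
  # excluded from the pool (forced fragments carry them instead)
  blocked <- function(s) {
    rbind(
      data.frame(accession = all_pairs$ref_accession[all_pairs$ref_species == s],
                 position = all_pairs$ref_position[all_pairs$ref_species == s]),
      data.frame(accession = all_pairs$target_accession[all_pairs$target_species == s],
                 position = all_pairs$target_position[all_pairs$target_species == s]))
  }

  for (s in sp) {
    cand <- candidates[[s]]
    blk <- blocked(s)
    for (r in seq_len(nrow(blk))) {
      cand <- cand[!(cand$accession == blk$accession[r] &
                     cand$start <= blk$position[r] &
                     cand$end >= blk$position[r]), ]
    }
    fr <- forced[[s]]
    n_forced <- if (is.null(fr)) 0L else nrow(fr)
    n_sample <- config$n_peptides - n_forced
    if (n_sample > nrow(cand)) {
      stop("not enough digest fragments for n_peptides in species ", s)
    }
    pick <- cand[sample(nrow(cand), n_sample), ]

    # phosphosites of sampled peptides: positions chosen at offsets that
    # keep the -3 motif slot inside the peptide; residues are written into
    # the protein sequence
    mult <- sample(c(1L, 2L, 3L), n_sample, replace = TRUE,
                   prob = config$multiplicity_mix)
    edits_acc <- character(0); edits_pos <- integer(0); edits_res <- character(0)
    site_pos <- vector("list", n_sample)
    site_res <- vector("list", n_sample)
    for (i in seq_len(n_sample)) {
      offs <- sort(sample(5:(pick$len[i] - 2L), mult[i]))
      pos <- pick$start[i] + offs - 1L
      res <- sample(c("S", "T", "Y"), mult[i], replace = TRUE,
                    prob = config$residue_mix)
      site_pos[[i]] <- pos
      site_res[[i]] <- res
      edits_acc <- c(edits_acc, rep(pick$accession[i], mult[i]))
      edits_pos <- c(edits_pos, pos)
      edits_res <- c(edits_res, res)
    }

    # responders among sampled peptides; forced site peptides are
    # responsive by construction except conserved-residue-only partners
    # (which are simply absent from the tables)
    n_resp <- round(config$fraction_responsive * n_sample)
    resp <- rep(FALSE, n_sample)
    if (n_resp > 0L) resp[sample(n_sample, n_resp)] <- TRUE

    # planted motif around the first site of responders
    motif_rows <- list()
    if (config$motif_penetrance > 0) {
      for (i in which(resp)) {
        if (stats::runif(1L) < config$motif_penetrance) {
          mpos <- site_pos[[i]][1L] + config$motif_offset
          if (mpos >= pick$start[i] && mpos <= pick$end[i] &&
              !(mpos %in% site_pos[[i]])) {
            edits_acc <- c(edits_acc, pick$accession[i])
            edits_pos <- c(edits_pos, mpos)
            edits_res <- c(edits_res, config$motif_residue)
            motif_rows[[length(motif_rows) + 1L]] <- data.frame(
              accession = pick$accession[i], site_position = site_pos[[i]][1L],
              motif_position = mpos, stringsAsFactors = FALSE)
          }
        }
      }
    }

    # apply edits to this species' proteome
    prot <- proteomes[[s]]
    for (j in seq_along(edits_pos)) {
      substr(prot[[edits_acc[j]]], edits_pos[j], edits_pos[j]) <- edits_res[j]
    }
    proteomes[[s]] <- prot

    # assemble the table: forced rows first, then sampled rows
    rows <- list()
    add_row <- function(acc, start, end, pos, res, responsive) {
      bare <- substring(prot[[acc]], start, end)
      ord <- order(pos)
      data.frame(peptide_id = NA_character_, bare_sequence = bare,
                 protein_accession = acc,
                 sites = paste0(res[ord], pos[ord], collapse = ";"),
                 responsive = responsive, stringsAsFactors = FALSE)
    }
    if (n_forced > 0L) {
      for (i in seq_len(n_forced)) {
        rows[[length(rows) + 1L]] <- add_row(fr$accession[i], fr$start[i],
                                             fr$end[i], fr$site[i], "S", TRUE)
      }
    }
    for (i in seq_len(n_sample)) {
      rows[[length(rows) + 1L]] <- add_row(pick$accession[i], pick$start[i],
                                           pick$end[i], site_pos[[i]],
                                           site_res[[i]], resp[i])
    }
    tbl <- do.call(rbind, rows)
    tbl$peptide_id <- sprintf("%s_pep%05d", s, seq_len(nrow(tbl)))
    tbl$species <- s

    # abundances: log-normal baseline, planted effect from a random onset
    n_all <- nrow(tbl)
    onset <- rep(NA_integer_, n_all)
    onset[tbl$responsive] <- sample(c(15L, 30L, 90L),
                                    sum(tbl$responsive), replace = TRUE)
    base <- stats::rnorm(n_all, config$baseline_log2_mean,
                         config$baseline_log2_sd)
    ab <- matrix(NA_real_, n_all, length(abundance_columns()),
                 dimnames = list(NULL, abundance_columns()))
    for (tp in quant_timepoints()) {
      for (r in quant_replicates()) {
        mu <- base + ifelse(tbl$responsive & !is.na(onset) & tp >= onset,
                            log2(config$effect_size), 0)
        val <- 2^(stats::rnorm(n_all, mu, config$noise_sigma))
        gone <- stats::runif(n_all) < config$missing_rate
        # planted pair peptides stay complete so their category is realized
        if (n_forced > 0L) gone[seq_len(n_forced)] <- FALSE
        val[gone] <- NA
        ab[, sprintf("t%d_r%d", tp, r)] <- round(val, 4L)
      }
    }
    out <- cbind(tbl[, c("peptide_id", "bare_sequence", "protein_accession",
                         "sites", "species")], as.data.frame(ab))
    peptides[[s]] <- out

    truth$responsive_peptides[[s]] <- tbl$peptide_id[tbl$responsive]
    truth$responsive_proteins[[s]] <-
      sort(unique(tbl$protein_accession[tbl$responsive]))
    truth$onsets[[s]] <- stats::setNames(onset[tbl$responsive],
                                         tbl$peptide_id[tbl$responsive])
    truth$motif_sites[[s]] <- if (length(motif_rows)) {
      do.call(rbind, motif_rows)
    } else {
      data.frame(accession = character(0), site_position = integer(0),
                 motif_position = integer(0), stringsAsFactors = FALSE)
    }
  }

  # responsive ortholog groups (truth-side, includes the held-out species)
  truth$responsive_groups <- lapply(stats::setNames(sp, sp), function(s) {
    mem <- fams$families[fams$families$species == s, ]
    sort(unique(mem$group_id[mem$accession %in% truth$responsive_proteins[[s]]]))
  })
  truth$site_pairs <- site_pairs

  list(peptides = peptides, proteomes = proteomes, truth = truth)
}

#' Generate the complete synthetic bundle in memory
#'
#' Runs [generate_families()] and [generate_quant_tables()] and packages
#' proteomes, quantification tables, groups and truth.
#'
#' @param config a [generator_config()].
#' @return list with `config`, `proteomes`, `peptides`, `groups`
#'   (data.frame for the first two species), `families`, `decoys`, `truth`.
#' @export
generate_bundle <- function(config) {
  fams <- generate_families(config)
  quant <- generate_quant_tables(config, fams)
  list(config = config,
       proteomes = quant$proteomes,
       peptides = quant$peptides,
       groups = fams$groups,
       families = fams$families,
       decoys = fams$decoys,
       truth = quant$truth)
}

#' Write a synthetic fixture bundle to disk
#'
#' Writes per-species proteome FASTA and phosphopeptide TSV files, the
#' groups file (first two species), `truth.json` and a `manifest.json`
#' echoing the configuration with MD5 checksums of every file. Identical
#' seeds produce byte-identical bundles. Optionally also writes a
#' BLAST-tabular hit file for the held-out species computed with the
#' internal aligner.
#'
#' @param config a [generator_config()].
#' @param outdir output directory.
#' @param overwrite allow writing into a directory that already contains a
#'   manifest.
#' @param write_hits also compute and write `hits_<heldout>.tsv`.
#' @param params [similarity_params()] for `write_hits`.
#' @return the manifest list, invisibly.
#' @export
write_fixture_bundle <- function(config, outdir, overwrite = FALSE,
                                 write_hits = FALSE,
                                 params = similarity_params()) {
  manifest_path <- file.path(outdir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite) {
    stop("bundle already exists in ", outdir, " (use overwrite = TRUE)")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  bundle <- generate_bundle(config)
  sp <- config$species
  files <- character(0)
  for (s in sp) {
    f <- file.path(outdir, sprintf("proteome_%s.fasta", s))
    write_proteome(bundle$proteomes[[s]], f)
    files <- c(files, f)
    f <- file.path(outdir, sprintf("phosphopeptides_%s.tsv", s))
    write_phosphopeptide_table(bundle$peptides[[s]], f)
    files <- c(files, f)
  }
  f <- file.path(outdir, "groups.txt")
  write_groups(bundle$groups, f)
  files <- c(files, f)
  if (write_hits) {
    groups <- read_groups(file.path(outdir, "groups.txt"))
    refs <- Biostrings::AAStringSet(c(bundle$proteomes[[sp[1L]]],
                                      bundle$proteomes[[sp[2L]]]))
    queries <- Biostrings::AAStringSet(bundle$proteomes[[sp[3L]]])
    subm <- substitution_matrix(params)
    rows <- lapply(seq_along(queries), function(i) {
      sc <- sw_scores_set(refs, as.character(queries[[i]]), params, subm)
      ka <- karlin_altschul_evalue(sc, Biostrings::width(queries)[i],
                                   Biostrings::width(refs), params)
      data.frame(qseqid = names(queries)[i], sseqid = names(refs),
                 pident = 0, length = 0, mismatch = 0, gapopen = 0,
                 qstart = 0, qend = 0, sstart = 0, send = 0,
                 evalue = signif(ka$e_value, 6L),
                 bitscore = round(ka$bit_score, 1L),
                 stringsAsFactors = FALSE)
    })
    f <- file.path(outdir, sprintf("hits_%s.tsv", sp[3L]))
    utils::write.table(do.call(rbind, rows), f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, eol = "\n")
    files <- c(files, f)
  }
  f <- file.path(outdir, "truth.json")
  truth <- bundle$truth
  truth$families <- bundle$families
  truth$decoys <- bundle$decoys
  jsonlite::write_json(truth, f, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  files <- c(files, f)
  manifest <- list(
    generator = "crossphos synthetic bundle",
    package_version = as.character(utils::packageVersion("crossphos")),
    config = unclass(config),
    files = lapply(stats::setNames(files, basename(files)), function(p) {
      list(md5 = unname(tools::md5sum(p)), bytes = file.size(p))
    }))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
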