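# Iterative motif enrichment (motif-x style): 13-residue windows centered on
# phosphosites are tested against a whole-proteome S/T/Y background; the
# most significant (offset, residue) pair is fixed, foreground and background
# are reduced to matching windows, and the search repeats until no pair
# passes the thresholds. Emitted motifs claim their foreground windows, so
# motifs are disjoint over the foreground.

#' Motif search configuration
#'
#' @param half_width residues on each side of the phosphosite (default 6,
#'   giving 13-residue windows).
#' @param min_occurrence strict lower bound on foreground matches: a pair is
#'   fixed only when its count `k > min_occurrence` (default 10, i.e. k >= 11).
#' @param p_threshold strict upper bound on the binomial upper-tail p-value
#'   (default 1e-6).
#' @param pool_st pool serine and threonine centers into one S/T class
#'   (default `TRUE`); tyrosine is always searched separately.
#' @return a list of class `"motif_config"`.
#' @export
motif_config <- function(half_width = 6L, min_occurrence = 10L,
                         p_threshold = 1e-6, pool_st = TRUE) {
  stopifnot(half_width >= 1, min_occurrence >= 0, p_threshold > 0)
  structure(list(half_width = as.integer(half_width),
                 min_occurrence = as.integer(min_occurrence),
                 p_threshold = p_threshold, pool_st = pool_st),
            class = "motif_config")
}

pad_window <- function(seq, position, half_width) {
  len <- nchar(seq)
  lo <- position - half_width
  hi <- position + half_width
  paste0(strrep("_", max(0L, 1L - lo)),
         substring(seq, max(1L, lo), min(len, hi)),
         strrep("_", max(0L, hi - len)))
}

#' Extract phosphosite-centered sequence windows
#'
#' One window per unique (protein, position) site; the phosphosite sits at
#' the center and termini are padded with `_` where the window overhangs the
#' protein. Sites whose residue is not S, T or Y are skipped with a warning.
#'
#' @param proteome `AAStringSet` or named character vector of protein
#'   sequences.
#' @param sites data.frame with columns `accession` and `position` (1-based).
#' @param half_width window half width, default 6.
#' @return data.frame with columns `accession`, `position`, `center`,
#'   `window`.
#' @export
extract_windows <- function(proteome, sites, half_width = 6L) {
  seqs <- as_named_seqs(proteome)
  sites <- unique(sites[, c("accession", "position")])
  if (nrow(sites) == 0L) {
    return(data.frame(accession = character(0), position = integer(0),
                      center = character(0), window = character(0),
                      stringsAsFactors = FALSE))
  }
  unknown <- setdiff(sites$accession, names(seqs))
  if (length(unknown)) {
    stop("site accession(s) not in proteome: ", paste(unknown, collapse = ", "))
  }
  seq <- seqs[sites$accession]
  if (any(sites$position < 1L | sites$position > nchar(seq))) {
    stop("site position outside protein")
  }
  center <- substring(seq, sites$position, sites$position)
  keep <- center %in% c("S", "T", "Y")
  if (any(!keep)) {
    warning(sum(!keep), " site(s) skipped: residue not S/T/Y")
  }
  sites <- sites[keep, , drop = FALSE]
  seq <- seq[keep]
  center <- center[keep]
  window <- mapply(pad_window, seq, sites$position,
                   MoreArgs = list(half_width = half_width), USE.NAMES = FALSE)
  data.frame(accession = sites$accession, position = sites$position,
             center = center, window = window, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Background windows: every S/T/Y occurrence in a proteome
#'
#' @inheritParams extract_windows
#' @return data.frame as in [extract_windows()].
#' @export
background_windows <- function(proteome, half_width = 6L) {
  seqs <- as_named_seqs(proteome)
  hits <- gregexpr("[STY]", seqs)
  acc <- rep(names(seqs), vapply(hits, function(h) sum(h > 0L), 0L))
  pos <- unlist(lapply(hits, function(h) h[h > 0L]), use.names = FALSE)
  extract_windows(proteome, data.frame(accession = acc, position = pos,
                                       stringsAsFactors = FALSE),
                  half_width = half_width)
}

#' Binomial upper-tail probability
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`; the enrichment test behind the
#' motif search. Computed through [stats::pbinom], which is stable for large
#' `n`.
#'
#' @param k observed count.
#' @param n number of trials.
#' @param p0 background success probability.
#' @return probability in `[0, 1]`.
#' @export
binomial_upper_tail <- function(k, n, p0) {
  stopifnot(k >= 0, k <= n, p0 >= 0, p0 <= 1)
  if (k == 0) return(1)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

parse_fixed <- function(fixed) {
  if (!nzchar(fixed)) {
    return(data.frame(offset = integer(0), residue = character(0)))
  }
  parts <- strsplit(fixed, "+", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(-?[0-9]+)([A-Z])$", parts))
  if (any(vapply(m, length, 0L) != 3L)) stop("malformed fixed-pair string: ", fixed)
  data.frame(offset = as.integer(vapply(m, `[`, "", 2L)),
             residue = vapply(m, `[`, "", 3L), stringsAsFactors = FALSE)
}

format_fixed <- function(pairs) {
  if (nrow(pairs) == 0L) return("")
  ord <- order(pairs$offset)
  paste(sprintf("%d%s", pairs$offset[ord], pairs$residue[ord]), collapse = "+")
}

motif_pattern <- function(center_class, pairs) {
  lo <- min(c(pairs$offset, 0L))
  hi <- max(c(pairs$offset, 0L))
  elems <- vapply(lo:hi, function(off) {
    if (off == 0L) {
      paste0("p", gsub("/", "/p", center_class))
    } else if (off %in% pairs$offset) {
      pairs$residue[match(off, pairs$offset)]
    } else "x"
  }, "")
  paste(elems, collapse = "-")
}

#' Does a window match a motif?
#'
#' A window matches when its center residue belongs to the motif's center
#' class and every fixed (offset, residue) pair agrees. The pad character
#' `_` never matches.
#'
#' @param windows character vector of odd-length windows (or the data.frame
#'   from [extract_windows()]).
#' @param center_class `"S/T"`, `"S"`, `"T"` or `"Y"`.
#' @param fixed fixed pairs serialized as e.g. `"-3R+2P"` (offset relative to
#'   the center, then residue), or a data.frame with `offset` and `residue`.
#' @return logical vector.
#' @export
motif_match <- function(windows, center_class, fixed = "") {
  if (is.data.frame(windows)) windows <- windows$window
  if (length(windows) == 0L) return(logical(0))
  hw <- (nchar(windows[1L]) - 1L) %/% 2L
  centers <- strsplit(center_class, "/", fixed = TRUE)[[1]]
  ok <- substring(windows, hw + 1L, hw + 1L) %in% centers
  pairs <- if (is.data.frame(fixed)) fixed else parse_fixed(fixed)
  for (i in seq_len(nrow(pairs))) {
    col <- hw + 1L + pairs$offset[i]
    ok <- ok & substring(windows, col, col) == pairs$residue[i]
  }
  ok
}

# Most significant unfixed (offset, residue) pair for the current
# foreground/background, or NULL if none passes the thresholds. Pads are
# excluded from both the trial count and the background frequency.
best_pair <- function(fg_mat, bg_mat, fixed_cols, config) {
  hw <- (ncol(fg_mat) - 1L) %/% 2L
  cand <- NULL
  for (col in seq_len(ncol(fg_mat))) {
    off <- col - hw - 1L
    if (off == 0L || col %in% fixed_cols) next
    fg_col <- fg_mat[, col]
    bg_col <- bg_mat[, col]
    n <- sum(fg_col != "_")
    bg_n <- sum(bg_col != "_")
    if (n == 0L || bg_n == 0L) next
    for (res in unique(fg_col[fg_col != "_"])) {
      k <- sum(fg_col == res)
      if (k <= config$min_occurrence) next
      p0 <- sum(bg_col == res) / bg_n
      p <- binomial_upper_tail(k, n, p0)
      if (p < config$p_threshold) {
        cand <- rbind(cand, data.frame(offset = off, residue = res, k = k,
                                       n = n, p0 = p0, p = p,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(cand)) return(NULL)
  cand[order(cand$p, -cand$k, abs(cand$offset), cand$residue)[1L], ]
}

#' Iterative motif enrichment over phosphosite windows
#'
#' For each center class (pooled S/T, then Y), repeatedly: (1) score every
#' unfixed (offset, residue) pair by the binomial upper tail of its
#' foreground count against the current background frequency; (2) fix the
#' most significant pair passing `k > min_occurrence` and `p < p_threshold`
#' (ties broken by larger k, smaller |offset|, then alphabetical residue);
#' (3) reduce foreground and background to matching windows and repeat.
#' When no pair qualifies, the accumulated pairs are emitted as a motif, its
#' foreground windows are removed from the pool, the background is restored,
#' and the search restarts; the class terminates when a round fixes nothing.
#'
#' @param foreground windows around phosphosites of interest
#'   ([extract_windows()] output or character vector).
#' @param background whole-proteome S/T/Y windows ([background_windows()]).
#' @param config a [motif_config()].
#' @return data.frame with one row per motif: `center_class`, `fixed`,
#'   `pattern`, `k` (foreground windows matching the full motif), `n`
#'   (foreground pool size when the motif search started), `p_value` (largest
#'   fixing-step p-value), `fold_enrichment` (foreground vs full-background
#'   match rate), `n_fixed`.
#' @export
run_motifx <- function(foreground, background, config = motif_config()) {
  if (is.data.frame(foreground)) foreground <- foreground$window
  if (is.data.frame(background)) background <- background$window
  empty <- data.frame(center_class = character(0), fixed = character(0),
                      pattern = character(0), k = integer(0), n = integer(0),
                      p_value = numeric(0), fold_enrichment = numeric(0),
                      n_fixed = integer(0), stringsAsFactors = FALSE)
  if (length(foreground) == 0L) return(empty)
  hw <- config$half_width
  stopifnot(all(nchar(foreground) == 2L * hw + 1L),
            all(nchar(background) == 2L * hw + 1L))
  classes <- if (config$pool_st) list("S/T" = c("S", "T"), "Y" = "Y")
             else list(S = "S", T = "T", Y = "Y")
  motifs <- empty
  for (cls in names(classes)) {
    centers <- classes[[cls]]
    pool <- foreground[substring(foreground, hw + 1L, hw + 1L) %in% centers]
    bg_all <- background[substring(background, hw + 1L, hw + 1L) %in% centers]
    if (length(pool) == 0L || length(bg_all) == 0L) next
    bg_mat_all <- do.call(rbind, strsplit(bg_all, ""))
    repeat {
      fg_cur <- pool
      fg_mat <- do.call(rbind, strsplit(fg_cur, ""))
      bg_mat <- bg_mat_all
      pairs <- data.frame(offset = integer(0), residue = character(0),
                          p = numeric(0), stringsAsFactors = FALSE)
      repeat {
        best <- best_pair(fg_mat, bg_mat, hw + 1L + pairs$offset, config)
        if (is.null(best)) break
        pairs <- rbind(pairs, best[, c("offset", "residue", "p")])
        col <- hw + 1L + best$offset
        fg_mat <- fg_mat[fg_mat[, col] == best$residue, , drop = FALSE]
        bg_mat <- bg_mat[bg_mat[, col] == best$residue, , drop = FALSE]
      }
      if (nrow(pairs) == 0L) break
      match_pool <- motif_match(pool, cls, pairs)
      bg_hits <- sum(motif_match(bg_all, cls, pairs))
      fg_rate <- sum(match_pool) / length(pool)
      bg_rate <- bg_hits / length(bg_all)
      motifs <- rbind(motifs, data.frame(
        center_class = cls,
        fixed = format_fixed(pairs),
        pattern = motif_pattern(cls, pairs),
        k = sum(match_pool),
        n = length(pool),
        p_value = max(pairs$p),
        fold_enrichment = if (bg_rate > 0) fg_rate / bg_rate else Inf,
        n_fixed = nrow(pairs), stringsAsFactors = FALSE))
      pool <- pool[!match_pool]
      if (length(pool) == 0L) break
    }
  }
  rownames(motifs) <- NULL
  motifs
}
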