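# Novel miRNA hairpin discovery: excise candidate precursors around
# unannotated tags, fold them, and apply miRNA:miRNA* duplex criteria
# (Dicer-like 2-nt 3' overhang, bounded duplex mismatches and
# asymmetric bulges, mostly-paired mature arm on one side of the loop).

#' Criteria for novel miRNA hairpin acceptance
#'
#' Numeric instantiation of the community criteria for plant miRNA
#' annotation: a 20-24 nt mature read on one arm of a stem-loop, at
#' most 4 unpaired mature bases in the miRNA:miRNA* duplex, at most a
#' 2-nt asymmetric bulge, a 2-nt 3' overhang for the star, and (when a
#' thermodynamic folding backend is active) a precursor MFE of at
#' least 18 kcal/mol in magnitude.
#'
#' @param mature_len_min,mature_len_max mature length window (nt)
#' @param flank_up,flank_down nt excised on each side of the mapped
#'   tag; both orientations are tried (tag near the 5' end and near
#'   the 3' end of the window)
#' @param flank_short compact fallback flank: two further windows are
#'   excised with `flank_short` in place of `flank_down`, large enough
#'   for any plausible hairpin but with less distal sequence to
#'   compete during folding
#' @param max_duplex_mismatch maximum unpaired mature bases
#' @param max_asym_bulge maximum asymmetric bulge (nt)
#' @param star_overhang 3' overhang of the star (nt)
#' @param min_mfe_magnitude |MFE| floor, kcal/mol (thermodynamic
#'   backend only)
#' @param min_paired_frac_mature minimum fraction of mature bases paired
#' @param max_multimap_loci tags mapping to more loci are skipped
#' @param min_reads minimum tag count (summed over libraries) before a
#'   tag is considered for discovery
#' @return a `novel_criteria` list
#' @export
novel_criteria <- function(mature_len_min = 20L, mature_len_max = 24L,
                           flank_up = 20L, flank_down = 160L,
                           flank_short = 60L,
                           max_duplex_mismatch = 4L, max_asym_bulge = 2L,
                           star_overhang = 2L, min_mfe_magnitude = 18,
                           min_paired_frac_mature = 0.6,
                           max_multimap_loci = 15L, min_reads = 5L) {
  stopifnot(mature_len_min > 0L, mature_len_min <= mature_len_max,
            flank_up > 0L, flank_down > 0L, flank_short > 0L,
            max_duplex_mismatch >= 0L,
            max_asym_bulge >= 0L, star_overhang > 0L,
            min_mfe_magnitude > 0, min_paired_frac_mature > 0,
            max_multimap_loci > 0L, min_reads >= 1L)
  structure(list(mature_len_min = as.integer(mature_len_min),
                 mature_len_max = as.integer(mature_len_max),
                 flank_up = as.integer(flank_up),
                 flank_down = as.integer(flank_down),
                 flank_short = as.integer(flank_short),
                 max_duplex_mismatch = as.integer(max_duplex_mismatch),
                 max_asym_bulge = as.integer(max_asym_bulge),
                 star_overhang = as.integer(star_overhang),
                 min_mfe_magnitude = min_mfe_magnitude,
                 min_paired_frac_mature = min_paired_frac_mature,
                 max_multimap_loci = as.integer(max_multimap_loci),
                 min_reads = as.integer(min_reads)),
            class = "novel_criteria")
}

#' Excise candidate precursor windows around a mapped tag
#'
#' Maps the tag to the genome exactly (0 mismatches) and, for each of
#' at most `max_multimap_loci` loci, excises a ladder of windows: the
#' tag near the window's 5' end (`flank_up` upstream / `flank_down`
#' downstream), the mirror, and the same pair with the compact
#' `flank_short` in place of `flank_down`. Windows are clipped to the
#' reference; minus-strand loci are reverse-complemented so the mature
#' sequence always lies on the returned precursor strand.
#'
#' @param tag_seq tag sequence (assumed unannotated)
#' @param genome a [reference_set()] of kind "genome"
#' @param crit a [novel_criteria()]
#' @return data.frame of windows: `ref`, `start`, `end`, `strand`,
#'   `seq` (precursor-strand sequence), `tag_start`, `tag_end`
#'   (1-based tag position within `seq`); zero rows if unmappable or
#'   multimapping beyond the bound
#' @export
excise_candidates <- function(tag_seq, genome, crit = novel_criteria()) {
  stopifnot(inherits(genome, "reference_set"), genome$kind == "genome")
  tag_seq <- .norm_seq(tag_seq)
  hits <- match_with_mismatches(tag_seq, genome, k = 0L, all_hits = TRUE)
  empty <- data.frame(ref = character(), start = integer(), end = integer(),
                      strand = character(), seq = character(),
                      tag_start = integer(), tag_end = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) > crit$max_multimap_loci) return(empty)
  ref_seq <- setNames(genome$records$seq, genome$records$id)
  out <- empty
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    rlen <- nchar(ref_seq[[h$hit_id]])
    # on the precursor strand, "upstream" is 5' of the mature tag;
    # wide windows first, then the compact fallback pair
    flank_pairs <- unique(list(
      c(crit$flank_up, crit$flank_down), c(crit$flank_down, crit$flank_up),
      c(crit$flank_up, crit$flank_short), c(crit$flank_short, crit$flank_up)))
    for (fp in flank_pairs) {
      up <- fp[1]; down <- fp[2]
      if (h$strand == "+") {
        s <- max(1L, h$start - up); e <- min(rlen, h$end + down)
        win <- substr(ref_seq[[h$hit_id]], s, e)
        ts <- h$start - s + 1L
      } else {
        s <- max(1L, h$start - down); e <- min(rlen, h$end + up)
        win <- .revcomp(substr(ref_seq[[h$hit_id]], s, e))
        ts <- e - h$end + 1L
      }
      out <- rbind(out, data.frame(
        ref = h$hit_id, start = s, end = e, strand = h$strand, seq = win,
        tag_start = ts, tag_end = ts + nchar(tag_seq) - 1L,
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

# Duplex geometry of the mature region read off a pair table. The
# miRNA:miRNA* duplex is taken as the largest consistent helix run:
# among the mature's pairing partners on the majority arm, the
# longest stretch of consecutive pairs whose partners stay monotone
# (nested) and whose bulge asymmetry never exceeds `max_asym`.
# Long-window folds occasionally pair stray mature bases with distant
# sequence or fold the mature tail back into the loop; such pairs lie
# outside the run and count as duplex mismatches, not bulges.
.duplex_geometry <- function(pt, m_start, m_end, max_asym = 2L) {
  idx <- m_start:m_end
  m_len <- length(idx)
  partners <- pt[idx]
  paired <- which(partners > 0L & (partners < m_start | partners > m_end))
  res <- list(n_unpaired = m_len, paired_frac = 0, asym = 0L,
              partner_min = NA_integer_, partner_max = NA_integer_,
              arm = NA_character_)
  if (length(paired) == 0L) return(res)
  pp <- partners[paired]
  is5 <- pp > m_end
  if (sum(is5) >= sum(!is5)) { sel <- is5; arm <- "5p" }
  else { sel <- !is5; arm <- "3p" }
  paired <- paired[sel]; pp <- pp[sel]
  # split into helix runs; nested pairs facing an ascending mature
  # have strictly descending partners
  run_id <- integer(length(paired))
  run_id[1] <- 1L
  if (length(paired) > 1L) {
    for (i in 2:length(paired)) {
      gap_m <- paired[i] - paired[i - 1L] - 1L
      gap_p <- pp[i - 1L] - pp[i] - 1L
      # a duplex is compact: break on crossing partners, asymmetric
      # bulges beyond the bound, or internal loops beyond small size
      broken <- gap_p < 0L || abs(gap_p - gap_m) > max_asym ||
        max(gap_m, gap_p) > max_asym + 2L
      run_id[i] <- run_id[i - 1L] + as.integer(broken)
    }
  }
  best_run <- as.integer(names(which.max(table(run_id))))
  keep <- run_id == best_run
  paired <- paired[keep]; pp <- pp[keep]
  res$arm <- arm
  res$n_unpaired <- m_len - length(paired)
  res$paired_frac <- length(paired) / m_len
  res$partner_min <- min(pp); res$partner_max <- max(pp)
  if (length(paired) > 1L) {
    gaps_m <- diff(paired) - 1L
    gaps_p <- abs(diff(pp)) - 1L
    res$asym <- max(abs(gaps_m - gaps_p))
  }
  res
}

#' Evaluate one excised window as a miRNA hairpin
#'
#' Folds the window and accepts it when (a) the mature region lies
#' entirely on one arm of the hairpin (all its pairing partners on one
#' side), (b) at most `max_duplex_mismatch` mature bases are unpaired
#' and the maximal asymmetric bulge is at most `max_asym_bulge` nt,
#' (c) at least `min_paired_frac_mature` of mature bases pair, and
#' (d) when the folding backend is thermodynamic, |MFE| >=
#' `min_mfe_magnitude`. The star sequence is the duplex partner with a
#' `star_overhang`-nt 3' overhang, flagged "observed" when present in
#' `all_tags`.
#'
#' @param window one row of [excise_candidates()] output (list or
#'   single-row data.frame with `seq`, `tag_start`, `tag_end`, and
#'   locus columns)
#' @param tag_counts named numeric vector of per-library counts of the
#'   mature tag
#' @param all_tags tag data.frame used to look up star counts (may be
#'   `NULL`)
#' @param crit a [novel_criteria()]
#' @param backend folding backend, see [fold()]
#' @return a `hairpin_candidate` list, or `NULL` with attribute
#'   dropped; rejections return a list of class `hairpin_rejection`
#'   with a `reason` string
#' @export
evaluate_hairpin <- function(window, tag_counts, all_tags = NULL,
                             crit = novel_criteria(),
                             backend = c("builtin", "vienna")) {
  backend <- match.arg(backend)
  if (is.data.frame(window)) window <- as.list(window[1L, ])
  res <- .evaluate_window(window, tag_counts, all_tags, crit, backend)
  if (inherits(res, "hairpin_candidate")) return(res)
  # focused re-fold: when the fold located the star arm but the duplex
  # failed the bounds, distal sequence in the wide window may have
  # competed for arm partners; re-fold the duplex neighborhood alone
  geo <- attr(res, "geometry")
  if (!is.null(geo) && !is.na(geo$arm)) {
    pad <- 12L
    n <- nchar(window$seq)
    a <- max(1L, min(window$tag_start, geo$partner_min) - pad)
    b <- min(n, max(window$tag_end, geo$partner_max) + pad)
    if (a > 1L || b < n) {
      sub <- list(ref = window$ref, strand = window$strand,
                  seq = substr(window$seq, a, b),
                  tag_start = window$tag_start - a + 1L,
                  tag_end = window$tag_end - a + 1L)
      if (window$strand == "+") {
        sub$start <- window$start + a - 1L
        sub$end <- window$start + b - 1L
      } else {
        sub$start <- window$end - b + 1L
        sub$end <- window$end - a + 1L
      }
      res2 <- .evaluate_window(sub, tag_counts, all_tags, crit, backend)
      if (inherits(res2, "hairpin_candidate")) return(res2)
    }
  }
  res
}

.evaluate_window <- function(window, tag_counts, all_tags, crit, backend) {
  reject <- function(reason, geo = NULL) {
    structure(list(reason = reason), geometry = geo,
              class = "hairpin_rejection")
  }
  m_len <- window$tag_end - window$tag_start + 1L
  if (m_len < crit$mature_len_min || m_len > crit$mature_len_max) {
    return(reject(sprintf("mature length %d outside [%d,%d]", m_len,
                          crit$mature_len_min, crit$mature_len_max)))
  }
  fr <- fold(window$seq, backend = backend)
  pt <- pair_table(fr$structure)
  geo <- .duplex_geometry(pt, window$tag_start, window$tag_end,
                          crit$max_asym_bulge)
  if (is.na(geo$arm)) {
    return(reject("mature region straddles the hairpin loop or is unpaired"))
  }
  if (geo$paired_frac < crit$min_paired_frac_mature) {
    return(reject(sprintf("only %.0f%% of mature bases paired",
                          100 * geo$paired_frac), geo))
  }
  if (geo$n_unpaired > crit$max_duplex_mismatch) {
    return(reject(sprintf("%d duplex mismatches exceed %d", geo$n_unpaired,
                          crit$max_duplex_mismatch), geo))
  }
  if (geo$asym > crit$max_asym_bulge) {
    return(reject(sprintf("asymmetric bulge of %d nt exceeds %d", geo$asym,
                          crit$max_asym_bulge), geo))
  }
  if (fr$energy_model == "thermodynamic" &&
      abs(fr$mfe) < crit$min_mfe_magnitude) {
    return(reject(sprintf("|MFE| %.2f below %.2f kcal/mol", abs(fr$mfe),
                          crit$min_mfe_magnitude)))
  }

  # star: duplex partner span shifted for the 2-nt 3' overhang
  ov <- crit$star_overhang
  n <- nchar(window$seq)
  if (geo$arm == "5p") {
    s_start <- max(1L, geo$partner_min + ov)
    s_end <- min(n, geo$partner_max + ov)
  } else {
    s_start <- max(1L, geo$partner_min - ov)
    s_end <- min(n, geo$partner_max - ov)
  }
  star_seq <- substr(window$seq, s_start, s_end)
  star_counts <- NULL
  star_observed <- FALSE
  if (!is.null(all_tags) && nrow(all_tags)) {
    # a sequenced star may sit a couple of nt off the computed duplex
    # partner; accept any tag contained in the star region +/- 2 nt
    region <- substr(window$seq, max(1L, s_start - 2L),
                     min(n, s_end + 2L))
    rl <- nchar(region)
    # stars run ~2 nt shorter than their matures (the 3' overhangs),
    # so scan a window of lengths around the mature range
    cand_len <- max(16L, crit$mature_len_min - 4L):
      min(crit$mature_len_max + 2L, rl)
    subs <- unlist(lapply(cand_len, function(l) {
      st <- seq_len(rl - l + 1L)
      substring(region, st, st + l - 1L)
    }))
    j <- match(subs, all_tags$seq)
    j <- j[!is.na(j)]
    if (length(j)) {
      libs <- setdiff(names(all_tags),
                      c("id", "seq", "category", "hit_id", "mismatches"))
      cnt <- rowSums(as.matrix(all_tags[j, libs, drop = FALSE]))
      best <- j[which.max(cnt)]
      star_seq <- all_tags$seq[best]
      star_counts <- unlist(all_tags[best, libs, drop = FALSE])
      star_observed <- TRUE
    }
  }

  mature_seq <- substr(window$seq, window$tag_start, window$tag_end)
  structure(list(
    name = NA_character_,
    locus = list(ref = window$ref, start = window$start, end = window$end,
                 strand = window$strand),
    precursor = window$seq, lp = nchar(window$seq), fold = fr,
    mature = mature_seq, mature_start = window$tag_start,
    mature_end = window$tag_end, arm = sub("p$", "'", geo$arm),
    mature_counts = tag_counts,
    star = star_seq, star_start = s_start, star_end = s_end,
    star_observed = star_observed, star_counts = star_counts,
    duplex_mismatches = geo$n_unpaired, asymmetry = geo$asym),
    class = "hairpin_candidate")
}

#' @export
print.hairpin_candidate <- function(x, ...) {
  cat(sprintf("<hairpin_candidate %s: %s arm, mature %d nt, LP %d nt, MFE %.2f, %d duplex mismatches%s>\n",
              if (is.na(x$name)) "(unnamed)" else x$name, x$arm,
              nchar(x$mature), x$lp, x$fold$mfe, x$duplex_mismatches,
              if (x$star_observed) ", star observed" else ""))
  invisible(x)
}

# genome-coordinate span of window-relative positions [a, b]
.to_genome_span <- function(w, a, b) {
  if (w$strand == "+") c(w$start + a - 1L, w$start + b - 1L)
  else c(w$end - b + 1L, w$end - a + 1L)
}

#' Discover novel miRNA hairpins from unannotated tags
#'
#' Runs [excise_candidates()] and [evaluate_hairpin()] over every
#' unannotated tag with at least `min_reads` reads and a length inside
#' the mature window, deduplicates by locus (a hairpin found from
#' either excision orientation is counted once; overlapping mature
#' loci keep the higher-count tag), and names accepted candidates
#' `miRn1, miRn2, ...` in discovery order (stars as `miRn<k>*`).
#'
#' @param ann annotated tag data.frame from [annotate_tags()]
#' @param genome a [reference_set()] of kind "genome"
#' @param crit a [novel_criteria()]
#' @param backend folding backend, see [fold()]
#' @param name_prefix prefix for candidate names
#' @return list of `hairpin_candidate` objects, named
#' @export
discover_novel <- function(ann, genome, crit = novel_criteria(),
                           backend = c("builtin", "vienna"),
                           name_prefix = "miRn") {
  backend <- match.arg(backend)
  libs <- setdiff(names(ann), c("id", "seq", "category", "hit_id",
                                "mismatches"))
  cand_tags <- ann[ann$category == "unannotated", , drop = FALSE]
  lens <- nchar(cand_tags$seq)
  totals <- rowSums(as.matrix(cand_tags[, libs, drop = FALSE]))
  cand_tags <- cand_tags[lens >= crit$mature_len_min &
                           lens <= crit$mature_len_max &
                           totals >= crit$min_reads, , drop = FALSE]
  # most-abundant tags first: overlapping loci keep the dominant mature
  ord <- order(-rowSums(as.matrix(cand_tags[, libs, drop = FALSE])),
               cand_tags$seq)
  cand_tags <- cand_tags[ord, , drop = FALSE]

  accepted <- list()
  seen_loci <- data.frame(ref = character(), start = integer(),
                          end = integer(), strand = character(),
                          stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cand_tags))) {
    tag <- cand_tags[i, ]
    wins <- excise_candidates(tag$seq, genome, crit)
    if (nrow(wins) == 0L) next
    counts <- unlist(tag[, libs, drop = FALSE])
    for (j in seq_len(nrow(wins))) {
      w <- as.list(wins[j, ])
      # dedupe: skip tags whose mature locus falls inside an accepted
      # candidate's duplex span (catches the star strand of an
      # already-accepted hairpin, and re-finds via the second window)
      # strand-agnostic: the star arm of a near-palindromic hairpin
      # also maps antisense to the mature arm, but it is the same locus
      g <- .to_genome_span(w, w$tag_start, w$tag_end)
      if (nrow(seen_loci)) {
        ov <- seen_loci$ref == w$ref &
          seen_loci$start <= g[2] & seen_loci$end >= g[1]
        if (any(ov)) next
      }
      res <- evaluate_hairpin(w, counts, all_tags = ann, crit = crit,
                              backend = backend)
      if (inherits(res, "hairpin_candidate")) {
        res$name <- paste0(name_prefix, length(accepted) + 1L)
        accepted[[res$name]] <- res
        d <- .to_genome_span(w, min(res$mature_start, res$star_start),
                             max(res$mature_end, res$star_end))
        seen_loci <- rbind(seen_loci, data.frame(
          ref = w$ref, start = d[1], end = d[2], strand = w$strand,
          stringsAsFactors = FALSE))
        break   # one accepted hairpin per tag
      }
    }
  }
  accepted
}

#' Tabulate accepted hairpin candidates
#'
#' One row per candidate (and one per observed star) with per-library
#' reads, mature sequence 5'-3', arm, size, precursor length, MFE and
#' locus, mirroring the usual novel-miRNA report layout.
#'
#' @param candidates list from [discover_novel()]
#' @param libraries library names for the read columns
#' @return data.frame
#' @export
novel_table <- function(candidates, libraries) {
  rows <- list()
  for (cand in candidates) {
    loc <- sprintf("%s:%d-%d(%s)", cand$locus$ref, cand$locus$start,
                   cand$locus$end, cand$locus$strand)
    cnt <- setNames(rep(0, length(libraries)), libraries)
    cnt[names(cand$mature_counts)] <- cand$mature_counts
    row <- data.frame(name = cand$name, t(cnt),
                      mature_seq = dna_to_rna(cand$mature), arm = cand$arm,
                      size = nchar(cand$mature), lp = cand$lp,
                      mfe = cand$fold$mfe, location = loc,
                      stringsAsFactors = FALSE, check.names = FALSE)
    rows[[length(rows) + 1L]] <- row
    if (cand$star_observed) {
      scnt <- setNames(rep(0, length(libraries)), libraries)
      scnt[names(cand$star_counts)] <- cand$star_counts
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0(cand$name, "*"), t(scnt),
        mature_seq = dna_to_rna(cand$star),
        arm = if (cand$arm == "5'") "3'" else "5'",
        size = nchar(cand$star), lp = cand$lp, mfe = cand$fold$mfe,
        location = loc, stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(name = character(), stringsAsFactors = FALSE)
    for (lib in libraries) out[[lib]] <- numeric()
    out$mature_seq <- character(); out$arm <- character()
    out$size <- integer(); out$lp <- integer(); out$mfe <- numeric()
    out$location <- character()
    return(out)
  }
  do.call(rbind, rows)
}
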