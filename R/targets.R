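# Plant miRNA target prediction by complementarity scoring, and the
# miRNA-target network. The expectation score is a penalty sum over
# the antiparallel miRNA:site duplex -- mismatch 1, G:U wobble 0.5,
# indel 2 -- with penalties doubled in the seed region (miRNA
# positions 2-13 from the 5' end); lower is better, 0 is a perfect
# complement.

#' Target-scoring configuration
#'
#' @param max_expectation report sites with expectation at or below
#'   this cutoff (default 3.0)
#' @param seed_start,seed_end seed region, miRNA positions from 5'
#' @param mismatch_penalty,wobble_penalty,indel_penalty per-position
#'   penalties
#' @param seed_multiplier penalty multiplier inside the seed
#' @param max_indels maximum indels in the duplex (0 or 1)
#' @param min_complementary_len minimum miRNA length scanned
#' @return a `target_scoring_config` list
#' @export
target_scoring_config <- function(max_expectation = 3.0, seed_start = 2L,
                                  seed_end = 13L, mismatch_penalty = 1.0,
                                  wobble_penalty = 0.5, indel_penalty = 2.0,
                                  seed_multiplier = 2.0, max_indels = 1L,
                                  min_complementary_len = 19L) {
  stopifnot(max_expectation >= 0, seed_start >= 1L, seed_end >= seed_start,
            mismatch_penalty >= 0, wobble_penalty >= 0, indel_penalty >= 0,
            seed_multiplier >= 0, max_indels %in% c(0L, 1L),
            min_complementary_len > 0L)
  structure(list(max_expectation = max_expectation,
                 seed_start = as.integer(seed_start),
                 seed_end = as.integer(seed_end),
                 mismatch_penalty = mismatch_penalty,
                 wobble_penalty = wobble_penalty,
                 indel_penalty = indel_penalty,
                 seed_multiplier = seed_multiplier,
                 max_indels = as.integer(max_indels),
                 min_complementary_len = as.integer(min_complementary_len)),
            class = "target_scoring_config")
}

# Penalty of pairing miRNA base m against site base s (both on the
# internal DNA alphabet, already antiparallel-aligned): 0 for a
# Watson-Crick pair, wobble for G:U, mismatch otherwise.
.pair_penalty <- function(m, s, cfg) {
  wc <- (m == "A" & s == "T") | (m == "T" & s == "A") |
        (m == "C" & s == "G") | (m == "G" & s == "C")
  wo <- (m == "G" & s == "T") | (m == "T" & s == "G")
  ifelse(wc, 0, ifelse(wo, cfg$wobble_penalty, cfg$mismatch_penalty))
}

.seed_weight <- function(pos, cfg) {
  ifelse(pos >= cfg$seed_start & pos <= cfg$seed_end, cfg$seed_multiplier, 1)
}

#' Score one miRNA:site duplex
#'
#' The site is the transcript subsequence 5'-3'; the miRNA binds it
#' antiparallel, so miRNA position i faces site position
#' len(site)-i+1. Lengths may differ by at most `max_indels`; with one
#' indel every gap placement is tried and the minimum expectation
#' kept. Positions are counted from the miRNA 5' end for seed
#' weighting.
#'
#' @param mirna_seq miRNA sequence 5'-3'
#' @param site_seq target site 5'-3'
#' @param cfg a [target_scoring_config()]
#' @return list: `expectation`, `alignment` (three-row character
#'   marking `|` match, `o` wobble, `.` mismatch/indel), and
#'   `mismatch_positions` (miRNA positions with penalty >= mismatch)
#' @export
score_duplex <- function(mirna_seq, site_seq, cfg = target_scoring_config()) {
  m <- strsplit(.norm_seq(mirna_seq), "")[[1]]
  s_fwd <- .norm_seq(site_seq)
  s <- rev(strsplit(s_fwd, "")[[1]])   # antiparallel: site 3'->5' vs miRNA 5'->3'
  lm <- length(m); ls <- length(s)
  if (abs(lm - ls) > cfg$max_indels) {
    stop(sprintf("length difference %d exceeds max_indels = %d",
                 abs(lm - ls), cfg$max_indels), call. = FALSE)
  }

  score_aligned <- function(mm, ss, pos) {
    # mm, ss aligned vectors with NA marking a gap; pos = miRNA position
    gap <- is.na(mm) | is.na(ss)
    pen <- numeric(length(mm))
    pen[gap] <- cfg$indel_penalty
    pen[!gap] <- .pair_penalty(mm[!gap], ss[!gap], cfg)
    total <- sum(pen * .seed_weight(pos, cfg))
    list(total = total, pen = pen, pos = pos)
  }

  best <- NULL
  if (lm == ls) {
    best <- score_aligned(m, s, seq_len(lm))
    best$m_aln <- m; best$s_aln <- s
  } else if (lm > ls) {
    # one miRNA base bulges out (gap in the site)
    for (g in seq_len(lm)) {
      ss <- append(s, NA_character_, after = g - 1L)
      cand <- score_aligned(m, ss, seq_len(lm))
      if (is.null(best) || cand$total < best$total) {
        best <- cand; best$m_aln <- m; best$s_aln <- ss
      }
    }
  } else {
    # one site base bulges out (gap in the miRNA); the gap inherits
    # the position of the following miRNA base for seed weighting
    for (g in seq_len(ls)) {
      mm <- append(m, NA_character_, after = g - 1L)
      pos <- cumsum(!is.na(mm))
      pos[is.na(mm)] <- pmin(pos[is.na(mm)] + 1L, lm)
      cand <- score_aligned(mm, s, pos)
      if (is.null(best) || cand$total < best$total) {
        best <- cand; best$m_aln <- mm; best$s_aln <- s
      }
    }
  }

  marks <- character(length(best$pen))
  gap <- is.na(best$m_aln) | is.na(best$s_aln)
  marks[gap] <- "."
  marks[!gap] <- ifelse(best$pen[!gap] == 0, "|",
                        ifelse(best$pen[!gap] == cfg$wobble_penalty, "o", "."))
  m_disp <- best$m_aln; m_disp[is.na(m_disp)] <- "-"
  s_disp <- best$s_aln; s_disp[is.na(s_disp)] <- "-"
  alignment <- c(mirna = paste0("5' ", dna_to_rna(paste(m_disp, collapse = "")), " 3'"),
                 marks = paste0("   ", paste(marks, collapse = ""), "   "),
                 site = paste0("3' ", dna_to_rna(paste(s_disp, collapse = "")), " 5'"))
  mismatch_pos <- unique(best$pos[best$pen >= cfg$mismatch_penalty])
  list(expectation = best$total, alignment = alignment,
       mismatch_positions = mismatch_pos)
}

# Vectorized expectation scores for every window of width w in one
# transcript, equivalent to calling score_duplex() per window. Gapped
# widths (one indel) are handled with prefix sums over the two
# possible row alignments so all gap placements cost O(w * nwin).
.scan_windows <- function(mchars, txc, w, cfg) {
  lm <- length(mchars)
  n <- length(txc)
  if (w > n) return(numeric(0))
  starts <- seq_len(n - w + 1L)
  nwin <- length(starts)
  # revS[r, j]: site base facing alignment row r of window j
  # (site read 3'->5', i.e. window reversed)
  revS <- vapply(seq_len(w), function(r) txc[starts + (w - r)],
                 character(nwin))
  revS <- matrix(revS, nrow = nwin)   # nwin x w
  weight <- .seed_weight(seq_len(lm), cfg)
  pen_row <- function(mbase, sbases) .pair_penalty(mbase, sbases, cfg)

  if (w == lm) {
    tot <- numeric(nwin)
    for (r in seq_len(lm)) tot <- tot + weight[r] * pen_row(mchars[r], revS[, r])
    return(tot)
  }

  if (w == lm - 1L) {
    # gap in the site at alignment row g (faces miRNA base g)
    P0 <- matrix(0, nwin, w)   # row r faces m[r]
    P1 <- matrix(0, nwin, w)   # row r faces m[r+1]
    for (r in seq_len(w)) {
      P0[, r] <- weight[r] * pen_row(mchars[r], revS[, r])
      P1[, r] <- weight[r + 1L] * pen_row(mchars[r + 1L], revS[, r])
    }
    c0 <- cbind(0, t(apply(P0, 1L, cumsum)))       # prefix sums
    s1 <- t(apply(P1[, w:1, drop = FALSE], 1L, cumsum))[, w:1, drop = FALSE]
    s1 <- cbind(s1, 0)                             # suffix sums
    best <- rep(Inf, nwin)
    for (g in seq_len(lm)) {
      tot <- c0[, g] + weight[g] * cfg$indel_penalty + s1[, g]
      best <- pmin(best, tot)
    }
    return(best)
  }

  if (w == lm + 1L) {
    # gap in the miRNA at alignment row g (a site base bulges out);
    # the gap inherits the position of the following miRNA base
    P0 <- matrix(0, nwin, lm)  # row r faces m[r]   (rows before the gap)
    P1 <- matrix(0, nwin, lm)  # row r+1 faces m[r] (rows after the gap)
    for (r in seq_len(lm)) {
      P0[, r] <- weight[r] * pen_row(mchars[r], revS[, r])
      P1[, r] <- weight[r] * pen_row(mchars[r], revS[, r + 1L])
    }
    c0 <- cbind(0, t(apply(P0, 1L, cumsum)))
    s1 <- t(apply(P1[, lm:1, drop = FALSE], 1L, cumsum))[, lm:1, drop = FALSE]
    s1 <- cbind(s1, 0)
    best <- rep(Inf, nwin)
    for (g in seq_len(w)) {
      gpos <- min(g, lm)
      tot <- c0[, min(g, lm + 1L)] + weight[gpos] * cfg$indel_penalty + s1[, g]
      best <- pmin(best, tot)
    }
    return(best)
  }
  stop("unsupported window width")
}

#' Scan transcripts for target sites of one miRNA
#'
#' Slides windows of the miRNA length (and length +/- 1 when one
#' indel is allowed) over each transcript, scores every window as
#' [score_duplex()] would, keeps sites with expectation at or below
#' the cutoff, and deduplicates overlapping sites keeping the lowest
#' expectation (then the earliest position). The inhibition mode is
#' "translation" when a mismatch falls in miRNA positions 9-11, else
#' "cleavage".
#'
#' @param mirna single-row data.frame or list with `id` and `seq`
#' @param transcripts a [reference_set()] of kind "transcript"
#' @param cfg a [target_scoring_config()]
#' @return data.frame: mirna, transcript, site_start, site_end
#'   (1-based inclusive), expectation, inhibition; ordered by
#'   (expectation, transcript, position)
#' @export
scan_transcripts <- function(mirna, transcripts,
                             cfg = target_scoring_config()) {
  stopifnot(inherits(transcripts, "reference_set"))
  empty <- data.frame(mirna = character(), transcript = character(),
                      site_start = integer(), site_end = integer(),
                      expectation = numeric(), inhibition = character(),
                      stringsAsFactors = FALSE)
  mseq <- .norm_seq(mirna$seq)
  lm <- nchar(mseq)
  if (lm < cfg$min_complementary_len) return(empty)
  mchars <- strsplit(mseq, "")[[1]]
  widths <- unique(pmax(1L, lm + (-cfg$max_indels):cfg$max_indels))
  hits <- list()
  for (i in seq_len(nrow(transcripts$records))) {
    tx <- transcripts$records$seq[i]
    txid <- transcripts$records$id[i]
    txc <- strsplit(tx, "")[[1]]
    for (w in widths) {
      e <- .scan_windows(mchars, txc, w, cfg)
      sel <- which(e <= cfg$max_expectation)
      for (j in sel) {
        site <- substr(tx, j, j + w - 1L)
        sc <- score_duplex(mseq, site, cfg)   # exact rescoring + alignment
        hits[[length(hits) + 1L]] <- data.frame(
          mirna = mirna$id, transcript = txid, site_start = j,
          site_end = j + w - 1L, expectation = sc$expectation,
          inhibition = if (any(sc$mismatch_positions >= 9L &
                                 sc$mismatch_positions <= 11L))
            "translation" else "cleavage",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) return(empty)
  h <- do.call(rbind, hits)
  h <- h[order(h$expectation, h$transcript, h$site_start), , drop = FALSE]
  # dedupe overlapping sites per transcript, keeping the best
  keep <- logical(nrow(h))
  for (tx in unique(h$transcript)) {
    idx <- which(h$transcript == tx)
    taken_s <- integer(0); taken_e <- integer(0)
    for (r in idx) {
      if (!any(taken_s <= h$site_end[r] & taken_e >= h$site_start[r])) {
        keep[r] <- TRUE
        taken_s <- c(taken_s, h$site_start[r])
        taken_e <- c(taken_e, h$site_end[r])
      }
    }
  }
  h <- h[keep, , drop = FALSE]
  h <- h[order(h$expectation, h$transcript, h$site_start), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Build the miRNA-target regulatory network
#'
#' Restricts target hits to differentially expressed miRNAs and emits
#' one edge per (miRNA, transcript) pair. When per-target expression
#' direction is supplied, an edge is labelled `negative` if the target
#' moves opposite to the miRNA call, else `unknown`. Hits whose miRNA
#' is absent from the DE table are skipped with a warning and counted
#' in the `n_dangling` attribute.
#'
#' @param de DE table from [de_table()]
#' @param hits target hits from [scan_transcripts()] (row-bound over
#'   miRNAs)
#' @param target_expr optional named vector transcript -> "up"/"down"
#' @return data.frame of edges: mirna, target_gene, direction,
#'   correlation; attribute `n_dangling`
#' @export
build_network <- function(de, hits, target_expr = NULL) {
  empty <- data.frame(mirna = character(), target_gene = character(),
                      direction = character(), correlation = character(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) {
    attr(empty, "n_dangling") <- 0L
    return(empty)
  }
  known <- hits$mirna %in% de$mirna
  n_dangling <- sum(!known)
  if (n_dangling > 0L) {
    warning(sprintf("%d target hits reference miRNAs absent from the DE table; skipped",
                    n_dangling))
  }
  h <- hits[known, , drop = FALSE]
  call <- setNames(de$call, de$mirna)[h$mirna]
  h <- h[call != "ns", , drop = FALSE]
  if (nrow(h) == 0L) {
    attr(empty, "n_dangling") <- n_dangling
    return(empty)
  }
  edges <- unique(data.frame(mirna = h$mirna, target_gene = h$transcript,
                             stringsAsFactors = FALSE))
  edges$direction <- setNames(de$call, de$mirna)[edges$mirna]
  if (!is.null(target_expr)) {
    tdir <- unname(target_expr[edges$target_gene])
    edges$correlation <- ifelse(!is.na(tdir) &
                                  ((edges$direction == "up" & tdir == "down") |
                                     (edges$direction == "down" & tdir == "up")),
                                "negative", "unknown")
  } else {
    edges$correlation <- "unknown"
  }
  edges <- edges[order(edges$mirna, edges$target_gene), , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "n_dangling") <- n_dangling
  edges
}

#' Write a network as SIF
#'
#' One `source interaction target` line per edge; the interaction type
#' is `represses`.
#'
#' @param edges edge data.frame from [build_network()]
#' @param path output path
#' @export
write_sif <- function(edges, path) {
  lines <- if (nrow(edges)) paste(edges$mirna, "represses",
                                  edges$target_gene) else character(0)
  writeLines(lines, path)
  invisible(path)
}
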