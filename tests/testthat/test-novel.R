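# build a canonical hairpin precursor around `mature`, with
# `n_mm` planted non-pairing substitutions in the opposite arm
make_precursor <- function(mature, loop_len = 10, n_mm = 0, on5p = TRUE,
                           mm_pos = NULL) {
  arm <- revcomp_chr(mature)
  m_len <- nchar(mature)
  if (n_mm > 0) {
    pos <- mm_pos %||% sample(3:(m_len - 2), n_mm)
    pairs_of <- list(A = "T", C = "G", G = c("C", "T"), T = c("A", "G"))
    for (p in pos) {
      m_base <- substr(mature, m_len - p + 1, m_len - p + 1)
      bad <- c(pairs_of[[m_base]], substr(arm, p, p))
      substr(arm, p, p) <- sample(setdiff(c("A", "C", "G", "T"), bad), 1)
    }
  }
  if (on5p) paste0(mature, random_dna(loop_len), arm)
  else paste0(arm, random_dna(loop_len), mature)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

genome_of <- function(seq) {
  reference_set(data.frame(id = "chr1", seq = seq, stringsAsFactors = FALSE),
                "genome", "genome")
}

test_that("excision windows follow the flank ladder and clip to bounds", {
  set.seed(51)
  g <- random_dna(1000)
  tag <- substr(g, 101, 121)
  wins <- excise_candidates(tag, genome_of(g))
  expect_equal(nrow(wins), 4L)
  # wide pair first: 20/160 and its mirror (101-160 clips to 1)
  expect_equal(wins$start, c(81L, 1L, 81L, 41L))
  expect_equal(wins$end, c(281L, 141L, 181L, 141L))
  expect_equal(wins$tag_start, c(21L, 101L, 21L, 61L))
  expect_equal(substr(wins$seq[1], wins$tag_start[1], wins$tag_end[1]), tag)
})

test_that("minus-strand excisions return the reverse-complement window", {
  set.seed(52)
  g <- random_dna(1000)
  tag <- revcomp_chr(substr(g, 501, 521))
  wins <- excise_candidates(tag, genome_of(g))
  expect_equal(unique(wins$strand), "-")
  expect_equal(wins$seq[1], revcomp_chr(substr(g, wins$start[1], wins$end[1])))
  expect_equal(substr(wins$seq[1], wins$tag_start[1], wins$tag_end[1]), tag)
})

test_that("tags multimapping beyond the locus bound yield no windows", {
  set.seed(53)
  tag <- random_dna(21)
  g <- paste(replicate(20, paste0(tag, random_dna(30))), collapse = "")
  expect_equal(nrow(excise_candidates(tag, genome_of(g))), 0L)
  expect_equal(nrow(excise_candidates(random_dna(25), genome_of(g))), 0L)
})

test_that("a perfect constructed hairpin is accepted with a shifted star", {
  set.seed(54)
  mature <- random_dna(21)
  prec <- make_precursor(mature, loop_len = 8)
  win <- list(ref = "chr1", start = 1L, end = nchar(prec), strand = "+",
              seq = prec, tag_start = 1L, tag_end = 21L)
  cand <- evaluate_hairpin(win, c(WA = 10))
  expect_s3_class(cand, "hairpin_candidate")
  expect_equal(cand$duplex_mismatches, 0L)
  expect_equal(cand$arm, "5'")
  # star = duplex partner with the 2-nt 3' overhang: here the
  # reverse complement of the mature, minus its first two bases
  expect_equal(cand$star, substr(revcomp_chr(mature), 3, 21))
  expect_false(cand$star_observed)
})

test_that("a heavily mismatched opposite arm is rejected", {
  set.seed(55)
  # designed so the five orphaned mature bases (all C) cannot re-pair
  # anywhere near the duplex: their only partner base, G, is replaced
  # by A at the five facing arm positions
  mature <- random_dna(21)
  for (p in c(6, 9, 12, 15, 18)) substr(mature, p, p) <- "C"
  arm <- revcomp_chr(mature)
  for (p in c(4, 7, 10, 13, 16)) substr(arm, p, p) <- "A"  # faces the Cs
  prec <- paste0(mature, "AATAATAA", arm)
  win <- list(ref = "chr1", start = 1L, end = nchar(prec), strand = "+",
              seq = prec, tag_start = 1L, tag_end = 21L)
  r <- evaluate_hairpin(win, c(WA = 10))
  expect_s3_class(r, "hairpin_rejection")
  expect_match(r$reason, "mismatch|paired")
})

test_that("an observed star strand is detected with its counts", {
  set.seed(56)
  mature <- random_dna(22)
  prec <- make_precursor(mature, loop_len = 9)
  win <- list(ref = "chr1", start = 1L, end = nchar(prec), strand = "+",
              seq = prec, tag_start = 1L, tag_end = 22L)
  star <- substr(revcomp_chr(mature), 3, 22)
  all_tags <- data.frame(id = c("t1", "t2"), seq = c(mature, star),
                         WA = c(443L, 8L), WB = c(0L, 0L),
                         stringsAsFactors = FALSE)
  cand <- evaluate_hairpin(win, c(WA = 443, WB = 0), all_tags = all_tags)
  expect_true(cand$star_observed)
  expect_equal(unname(cand$star_counts[["WA"]]), 443L * 0L + 8L)
  expect_equal(cand$star, star)
})

test_that("planted duplex mismatches are what the evaluator reports", {
  set.seed(57)
  for (i in 1:10) {
    mature <- random_dna(sample(20:24, 1))
    n_mm <- sample(0:2, 1)
    prec <- make_precursor(mature, loop_len = sample(8:15, 1), n_mm = n_mm,
                           on5p = i %% 2 == 0)
    tag_start <- if (i %% 2 == 0) 1L else nchar(prec) - nchar(mature) + 1L
    win <- list(ref = "chr1", start = 1L, end = nchar(prec), strand = "+",
                seq = prec, tag_start = tag_start,
                tag_end = tag_start + nchar(mature) - 1L)
    cand <- evaluate_hairpin(win, c(WA = 10))
    expect_s3_class(cand, "hairpin_candidate")
    expect_equal(cand$duplex_mismatches, n_mm, info = paste(i, mature))
  }
})

test_that("noise-free planted hairpins are all recovered and nothing else", {
  cfg <- simulation_config(seed = 58L, genome_len = 50000L, n_known = 5L,
                           n_novel = 20L, n_ncrna = 3L, depth = 0L)
  sim <- make_genome(cfg)
  tn <- sim$truth[sim$truth$kind == "novel", ]
  ann <- data.frame(id = paste0("t", seq_len(nrow(tn))), seq = tn$mature,
                    WA = 50L, WB = 50L, category = "unannotated",
                    hit_id = NA_character_, mismatches = NA_integer_,
                    stringsAsFactors = FALSE)
  cands <- discover_novel(ann, sim$genome)
  found <- vapply(cands, function(x) x$mature, character(1))
  expect_equal(sort(unname(found)), sort(tn$mature))   # recall 100%
  # every accepted locus is a planted locus (window slack allowed)
  for (cc in cands) {
    hit <- any(tn$start - 25 <= cc$locus$end & tn$end + 25 >= cc$locus$start)
    expect_true(hit, info = cc$name)
  }
  # acceptance is locus-deduplicated: one candidate per planted hairpin
  expect_equal(length(cands), nrow(tn))
})

test_that("candidate tables carry star rows and per-library reads", {
  set.seed(59)
  mature <- random_dna(21)
  prec <- make_precursor(mature, loop_len = 8)
  win <- list(ref = "chr1", start = 11L, end = 10L + nchar(prec),
              strand = "+", seq = prec, tag_start = 1L, tag_end = 21L)
  star <- substr(revcomp_chr(mature), 3, 21)
  all_tags <- data.frame(id = "t2", seq = star, WA = 8L, WB = 0L,
                         stringsAsFactors = FALSE)
  cand <- evaluate_hairpin(win, c(WA = 443, WB = 0), all_tags = all_tags)
  cand$name <- "miRn1"
  tab <- novel_table(list(miRn1 = cand), c("WA", "WB"))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$name, c("miRn1", "miRn1*"))
  expect_equal(tab$WA, c(443, 8))
  expect_equal(tab$arm, c("5'", "3'"))
  expect_equal(tab$lp, rep(nchar(prec), 2))
})
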