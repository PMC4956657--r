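tx_set <- function(seqs, ids = NULL) {
  reference_set(data.frame(id = ids %||% sprintf("TX%02d", seq_along(seqs)),
                           seq = seqs, stringsAsFactors = FALSE),
                "transcripts", "transcript")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# force a non-pairing base at the site position facing miRNA position `pos`
mismatch_at_gen <- function(mirna, site, pos) {
  sp <- nchar(mirna) - pos + 1
  m_base <- substr(mirna, pos, pos)
  pairs_of <- list(A = "T", C = "G", G = c("C", "T"), T = c("A", "G"))
  substr(site, sp, sp) <- setdiff(c("A", "C", "G", "T"),
                                  c(pairs_of[[m_base]],
                                    substr(site, sp, sp)))[1]
  site
}

test_that("duplex scoring: perfect complements, seed doubling, wobbles", {
  set.seed(71)
  mirna <- random_dna(21)
  expect_equal(score_duplex(mirna, revcomp_chr(mirna))$expectation, 0)

  # single mismatch at miRNA position 15 -> 1.0; at position 5 -> 2.0
  mismatch_at <- function(pos) {
    site <- revcomp_chr(mirna)        # site position pairing miRNA pos p
    sp <- nchar(mirna) - pos + 1      # is len - p + 1
    m_base <- substr(mirna, pos, pos)
    pairs_of <- list(A = "T", C = "G", G = c("C", "T"), T = c("A", "G"))
    substr(site, sp, sp) <- setdiff(c("A", "C", "G", "T"),
                                    c(pairs_of[[m_base]],
                                      substr(site, sp, sp)))[1]
    site
  }
  expect_equal(score_duplex(mirna, mismatch_at(15))$expectation, 1.0)
  expect_equal(score_duplex(mirna, mismatch_at(5))$expectation, 2.0)

  # G:U at position 3 (in seed, 0.5 x 2) plus a mismatch at 20 -> 2.0
  mirna2 <- paste0("AC", "G", substr(random_dna(21), 4, 21))
  site2 <- revcomp_chr(mirna2)
  sp3 <- nchar(mirna2) - 3 + 1
  substr(site2, sp3, sp3) <- "T"     # G:U wobble against miRNA G
  site2 <- substr(mismatch_at_gen(mirna2, site2, 20), 1, nchar(site2))
  expect_equal(score_duplex(mirna2, site2)$expectation, 2.0)

  expect_error(score_duplex(mirna, substr(mirna, 1, 18)), "length")
})

test_that("duplex scoring equals the literal hand-scoring oracle", {
  set.seed(72)
  for (i in 1:40) {
    lm <- sample(19:25, 1)
    mirna <- random_dna(lm)
    site <- revcomp_chr(mirna)
    # random damage: substitutions and maybe a 1-nt indel
    nsub <- sample(0:4, 1)
    for (p in sample(nchar(site), nsub)) {
      substr(site, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    indel <- sample(c("none", "del", "ins"), 1)
    if (indel == "del") {
      p <- sample(nchar(site), 1)
      site <- paste0(substr(site, 1, p - 1), substr(site, p + 1, nchar(site)))
    } else if (indel == "ins") {
      p <- sample(nchar(site), 1)
      site <- paste0(substr(site, 1, p), sample(c("A", "C", "G", "T"), 1),
                     substr(site, p + 1, nchar(site)))
    }
    expect_equal(score_duplex(mirna, site)$expectation,
                 naive_duplex_expectation(mirna, site),
                 info = paste(mirna, site))
  }
})

test_that("an embedded perfect complement is found at the right site", {
  set.seed(73)
  mirna <- list(id = "miR-x", seq = random_dna(21))
  site <- revcomp_chr(mirna$seq)
  tx <- paste0(random_dna(100), site, random_dna(100))
  hits <- scan_transcripts(mirna, tx_set(tx))
  expect_gte(nrow(hits), 1L)
  expect_equal(hits$expectation[1], 0)
  expect_equal(hits$site_start[1], 101L)
  expect_equal(hits$site_end[1], 121L)
  expect_equal(hits$inhibition[1], "cleavage")
})

test_that("an unmatchable transcript yields no hits", {
  mirna <- list(id = "miR-x", seq = paste(rep("ACG", 7), collapse = ""))
  hits <- scan_transcripts(mirna, tx_set(strrep("A", 300)))
  expect_equal(nrow(hits), 0L)
})

test_that("planted sites are tracked across positions and seeds", {
  for (seed in 1:10) {
    set.seed(73 + seed)
    mirna <- list(id = "m", seq = random_dna(21))
    pos <- sample(1:(500 - 21), 1)
    tx <- random_dna(500)
    substr(tx, pos, pos + 20) <- revcomp_chr(mirna$seq)
    hits <- scan_transcripts(mirna, tx_set(tx))
    best <- hits[which.min(hits$expectation), ]
    expect_equal(best$site_start, pos)
  }
})

test_that("vectorized scanning equals per-window rescoring", {
  set.seed(74)
  cfg <- target_scoring_config(max_expectation = 6)
  mirna <- random_dna(20)
  tx <- paste0(random_dna(40), revcomp_chr(mirna), random_dna(40))
  # mutate the planted site a little
  substr(tx, 45, 45) <- "A"; substr(tx, 52, 52) <- "G"
  txc <- strsplit(tx, "")[[1]]
  mchars <- strsplit(mirna, "")[[1]]
  for (w in 19:21) {
    vec <- mircms:::.scan_windows(mchars, txc, w, cfg)
    naive <- vapply(seq_len(nchar(tx) - w + 1), function(s)
      score_duplex(mirna, substr(tx, s, s + w - 1), cfg)$expectation,
      numeric(1))
    expect_equal(vec, naive, info = paste("width", w))
  }
})

test_that("lowering the expectation cutoff never adds hits", {
  set.seed(75)
  mirna <- list(id = "m", seq = random_dna(21))
  tx <- paste0(random_dna(30), revcomp_chr(mirna$seq), random_dna(30))
  substr(tx, 35, 35) <- "C"
  h3 <- scan_transcripts(mirna, tx_set(tx), target_scoring_config(max_expectation = 3))
  h1 <- scan_transcripts(mirna, tx_set(tx), target_scoring_config(max_expectation = 1))
  key <- function(h) paste(h$transcript, h$site_start, h$site_end)
  expect_true(all(key(h1) %in% key(h3)))
  expect_lte(nrow(h1), nrow(h3))
})

test_that("mismatches at miRNA positions 9-11 flag translational inhibition", {
  set.seed(76)
  mirna <- list(id = "m", seq = random_dna(21))
  site <- revcomp_chr(mirna$seq)
  sp <- 21 - 10 + 1                       # pairs miRNA position 10
  m10 <- substr(mirna$seq, 10, 10)
  pairs_of <- list(A = "T", C = "G", G = c("C", "T"), T = c("A", "G"))
  substr(site, sp, sp) <- setdiff(c("A", "C", "G", "T"),
                                  c(pairs_of[[m10]], substr(site, sp, sp)))[1]
  tx <- paste0(random_dna(50), site, random_dna(50))
  hits <- scan_transcripts(mirna, tx_set(tx))
  best <- hits[which.min(hits$expectation), ]
  expect_equal(best$inhibition, "translation")
})

test_that("networks restrict to DE miRNAs and label negative correlation", {
  de <- data.frame(mirna = c("m1", "m2"), call = c("up", "ns"),
                   stringsAsFactors = FALSE)
  hits <- data.frame(
    mirna = c("m1", "m1", "m1", "m2", "m3"),
    transcript = c("TX01", "TX02", "TX03", "TX01", "TX04"),
    site_start = 1L, site_end = 21L, expectation = 0,
    inhibition = "cleavage", stringsAsFactors = FALSE)
  expect_warning(net <- build_network(de, hits,
                                      target_expr = c(TX01 = "down")),
                 "absent")
  expect_equal(nrow(net), 3L)              # m2 is ns, m3 dangling
  expect_true(all(net$mirna == "m1"))
  expect_equal(net$correlation[net$target_gene == "TX01"], "negative")
  expect_equal(net$correlation[net$target_gene == "TX02"], "unknown")
  expect_equal(attr(net, "n_dangling"), 1L)

  f <- withr::local_tempfile(fileext = ".sif")
  write_sif(net, f)
  expect_equal(length(readLines(f)), 3L)
  expect_match(readLines(f)[1], "^m1 represses TX0")
})
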