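make_ref <- function(seqs, ids = NULL, name = "ref", kind = "mature") {
  reference_set(data.frame(id = ids %||% paste0("s", seq_along(seqs)),
                           seq = seqs, stringsAsFactors = FALSE),
                name, kind)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("exact hits report zero mismatches; over-budget tags miss", {
  ref <- make_ref(c("TATTCCGACGACAATTCCGACG", "ACGTACGTACGTACGTACGTA"),
                  c("m1", "m2"))
  h <- match_with_mismatches("TATTCCGACGACAATTCCGACG", ref, 2L)
  expect_equal(h$hit_id, "m1")
  expect_equal(h$mismatches, 0L)

  tag3 <- "TATTCCGACGACAATTCCGACG"
  substr(tag3, 1, 1) <- "G"; substr(tag3, 5, 5) <- "A"; substr(tag3, 9, 9) <- "T"
  expect_null(match_with_mismatches(tag3, make_ref("TATTCCGACGACAATTCCGACG"), 2L))
  expect_false(is.null(match_with_mismatches(tag3, make_ref("TATTCCGACGACAATTCCGACG"), 3L)))
})

test_that("window matching agrees with an exhaustive Hamming scan", {
  set.seed(31)
  refs <- data.frame(id = sprintf("ref%02d", 1:50),
                     seq = vapply(1:50, function(i) random_dna(60),
                                  character(1)),
                     stringsAsFactors = FALSE)
  ref <- reference_set(refs, "bank", "mature")
  for (i in 1:40) {
    tag <- if (i %% 2 == 0) random_dna(21) else {
      # plant a mutated copy of a reference window so hits exist
      r <- sample(50, 1); s <- sample(1:40, 1)
      t <- substr(refs$seq[r], s, s + 20)
      p <- sample(21, sample(0:3, 1))
      for (q in p) substr(t, q, q) <- sample(setdiff(c("A","C","G","T"),
                                                     substr(t, q, q)), 1)
      t
    }
    got <- match_with_mismatches(tag, ref, 2L)
    want <- brute_hamming_scan(tag, refs, 2L)
    if (is.null(want)) expect_null(got)
    else {
      expect_equal(got$hit_id, want$hit_id)
      expect_equal(got$mismatches, want$mismatches)
    }
  }
})

test_that("genome matching finds reverse-complement hits with equal mismatches", {
  set.seed(32)
  g <- random_dna(300)
  tag <- substr(g, 101, 121)
  genome_fwd <- make_ref(g, "chr1", "genome", kind = "genome")
  genome_rev <- make_ref(revcomp_chr(g), "chr1", "genome", kind = "genome")
  h1 <- match_with_mismatches(tag, genome_fwd, 1L)
  h2 <- match_with_mismatches(tag, genome_rev, 1L)
  expect_equal(h1$mismatches, h2$mismatches)
  expect_equal(h1$strand, "+")
  expect_equal(h2$strand, "-")
})

test_that("batch matching equals the per-tag route", {
  set.seed(33)
  refs <- data.frame(id = sprintf("nc%02d", 1:8),
                     seq = vapply(1:8, function(i) random_dna(120),
                                  character(1)),
                     stringsAsFactors = FALSE)
  ref <- reference_set(refs, "ncRNA", "ncRNA")
  tags <- c(
    vapply(1:60, function(i) random_dna(sample(18:24, 1)), character(1)),
    vapply(1:60, function(i) {
      r <- sample(8, 1); s <- sample(1:90, 1); L <- sample(18:24, 1)
      t <- substr(refs$seq[r], s, s + L - 1)
      p <- sample(L, sample(0:2, 1))
      for (q in p) substr(t, q, q) <- sample(setdiff(c("A","C","G","T"),
                                                     substr(t, q, q)), 1)
      t
    }, character(1)))
  batch <- mircms:::.batch_hits(tags, ref, 2L)
  for (i in seq_along(tags)) {
    per_tag <- match_with_mismatches(tags[i], ref, 2L)
    expect_equal(is.na(batch[i]), is.null(per_tag), info = tags[i])
  }
})

test_that("category priority resolves multi-hits and partitions tags", {
  seqA <- random_dna(21)   # in both rRNA and mature sets
  seqB <- random_dna(21)   # mature only
  seqC <- random_dna(21)   # nothing
  tags <- data.frame(id = c("t1", "t2", "t3"), seq = c(seqA, seqB, seqC),
                     WA = c(5L, 3L, 2L), WB = c(1L, 0L, 4L),
                     stringsAsFactors = FALSE)
  refs <- list(make_ref(c(seqA, seqB), c("matA", "matB"), "mature_mirna",
                        "mature"),
               make_ref(paste0(random_dna(30), seqA, random_dna(30)),
                        "rRNA_big", name = "rRNA", kind = "ncRNA"))
  ann <- annotate_tags(tags, refs, annotation_config())
  expect_equal(ann$category, c("rRNA", "miRNA", "unannotated"))
  expect_equal(ann$hit_id[2], "matB")
  expect_true(is.na(ann$hit_id[3]))
  # partition: unique and total counts per category sum to library totals
  expect_equal(sum(table(ann$category)), nrow(tags))
  expect_equal(sum(ann$WA), 10L)
  ct <- category_table(ann, c("WA", "WB"))
  expect_equal(ct$WA_total[ct$category == "total"], 10)
  expect_equal(sum(ct$WA_total[ct$category != "total"]), 10)
})

test_that("annotation requires mature and ncRNA reference sets", {
  tags <- data.frame(id = "t1", seq = random_dna(21), WA = 1L,
                     stringsAsFactors = FALSE)
  expect_error(annotate_tags(tags, list(make_ref(random_dna(21)))),
               "ncRNA")
})

test_that("family table reproduces the published two-library arithmetic", {
  # per-member records that sum to the printed family-level reads
  mk <- function(ids, wa, wb) {
    data.frame(id = paste0("t", seq_along(ids)), seq = NA, WA = wa, WB = wb,
               category = "miRNA", hit_id = ids, mismatches = 0L,
               stringsAsFactors = FALSE)
  }
  ann <- rbind(
    mk(c("rsa-miR156a", "rsa-miR157a"), c(400000, 10237), c(300000, 4695)),
    mk(c("rsa-miR158a", "rsa-miR158b"), c(15000, 565), c(7000, 641)),
    mk(c("rsa-miR395a", "rsa-miR395d"), c(45000, 236), c(40, 4)),
    mk("rsa-miR161", 152, 0))
  fam <- family_table(ann, c("WA", "WB"), alias = family_alias_map())
  row <- function(f) fam[fam$family == f, ]
  expect_equal(row("miR156/157")$total, 714932)
  expect_equal(row("miR156/157")$ratio, 1.35)
  expect_equal(row("miR156/157")$members, 2L)
  expect_equal(row("miR158")$total, 23206)
  expect_equal(row("miR158")$ratio, 2.04)
  expect_equal(row("miR395")$ratio, 1028.09)
  expect_true(is.na(row("miR161")$ratio))   # printed as "-"
})

test_that("family grouping never creates or loses reads", {
  set.seed(34)
  ids <- sprintf("rsa-miR%d%s", sample(150:170, 30, replace = TRUE),
                 sample(letters[1:3], 30, replace = TRUE))
  ann <- data.frame(id = paste0("t", 1:30), seq = NA,
                    WA = sample(0:1000, 30), WB = sample(0:1000, 30),
                    category = "miRNA", hit_id = ids, mismatches = 0L,
                    stringsAsFactors = FALSE)
  fam <- family_table(ann, c("WA", "WB"))
  expect_equal(sum(fam$WA), sum(ann$WA))
  expect_equal(sum(fam$WB), sum(ann$WB))
  expect_equal(sum(fam$total), sum(ann$WA) + sum(ann$WB))
})

test_that("summed family tables get the same ratio arithmetic", {
  df <- data.frame(family = c("a", "b"), WA = c(10, 5), WB = c(4, 0))
  out <- family_summary(df)
  expect_equal(out$total, c(14, 5))
  expect_equal(out$ratio[1], 2.5)
  expect_true(is.na(out$ratio[2]))
})
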