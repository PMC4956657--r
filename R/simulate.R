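# Fully-specified synthetic inputs: a genome with planted canonical
# hairpins, reference sets, and two-condition read libraries with
# known per-miRNA fold changes, so every pipeline stage is testable
# against a truth table.

#' Simulation configuration
#'
#' The generator emulates the structure of a two-library small-RNA
#' experiment: a sterile-line library ("WA") and a fertile maintainer
#' library ("WB") of 18-30 nt tags containing planted known miRNAs,
#' planted novel hairpin loci with mature and star reads, structural
#' ncRNA contamination, unannotated background, and planted per-miRNA
#' log2 fold changes (WA over WB).
#'
#' @param seed RNG seed driving every random choice
#' @param genome_len genome length in nt
#' @param n_known planted known mature miRNAs (present in the
#'   mature reference)
#' @param n_novel planted novel hairpin loci (absent from the
#'   reference; discoverable from the genome)
#' @param n_ncrna structural ncRNA decoy sequences
#' @param depth reads per library
#' @param fc_table optional named numeric vector miRNA -> true log2 FC
#'   (WA/WB); `Inf`/`-Inf` mean absent from WB/WA. By default 20
#'   percent of miRNAs receive a fold change drawn from {-3,-2,2,3}
#'   and the rest 0.
#' @param star_fraction expected star/mature count ratio for novel
#'   hairpins
#' @param noise per-base substitution rate applied to reads
#' @param mean_count mean mature read count per miRNA in WA (library
#'   means are drawn log-normally around this)
#' @param ncrna_fraction fraction of non-miRNA reads drawn from ncRNA
#'   decoys (the rest is genomic background)
#' @param n_transcripts transcripts in the synthetic target set
#' @param transcript_len transcript length in nt
#' @return a `simulation_config` list
#' @export
simulation_config <- function(seed = 1L, genome_len = 100000L,
                              n_known = 30L, n_novel = 20L, n_ncrna = 10L,
                              depth = 200000L, fc_table = NULL,
                              star_fraction = 0.05, noise = 0.001,
                              mean_count = 200, ncrna_fraction = 0.4,
                              n_transcripts = 20L, transcript_len = 500L) {
  stopifnot(genome_len > 0L, n_known >= 0L, n_novel >= 0L, n_ncrna >= 0L,
            depth >= 0L, star_fraction >= 0, star_fraction < 1,
            noise >= 0, noise < 1, mean_count > 0,
            ncrna_fraction >= 0, ncrna_fraction <= 1)
  structure(list(seed = as.integer(seed), genome_len = as.integer(genome_len),
                 n_known = as.integer(n_known), n_novel = as.integer(n_novel),
                 n_ncrna = as.integer(n_ncrna), depth = as.integer(depth),
                 fc_table = fc_table, star_fraction = star_fraction,
                 noise = noise, mean_count = mean_count,
                 ncrna_fraction = ncrna_fraction,
                 n_transcripts = as.integer(n_transcripts),
                 transcript_len = as.integer(transcript_len)),
            class = "simulation_config")
}

.rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1]]
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# substitute arm positions with bases that cannot pair (Watson-Crick
# or wobble) with the mature base they face, so a planted "mismatch"
# is a true duplex mismatch
.mutate_arm <- function(arm, positions, mature) {
  pairs_of <- list(A = "T", C = "G", G = c("C", "T"), T = c("A", "G"))
  m_len <- nchar(mature)
  chars <- strsplit(arm, "")[[1]]
  for (p in positions) {
    m_base <- substr(mature, m_len - p + 1L, m_len - p + 1L)
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"),
                               c(pairs_of[[m_base]], chars[p])), 1L)
  }
  paste(chars, collapse = "")
}

#' Build the synthetic genome, references and truth table
#'
#' Plants `n_novel` canonical hairpins (20-24 nt mature, 8-15 nt loop,
#' opposite arm a near-reverse-complement with at most 2 planted
#' mismatches) at non-overlapping loci on both strands of a random
#' background, generates `n_known` known mature miRNAs, `n_ncrna`
#' structural ncRNA decoys, and a transcript set in which every miRNA
#' with a planted fold change owns one perfectly complementary target
#' site.
#'
#' @param cfg a [simulation_config()]
#' @return list: `genome`, `mature_known`, `ncrna`, `transcripts`
#'   (reference_set objects) and `truth` (data.frame: name, kind,
#'   mature, star, ref, start, end, strand, planted_mm, true_fc,
#'   mean_wa, mean_wb)
#' @export
make_genome <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  genome_chars <- sample(c("A", "C", "G", "T"), cfg$genome_len, replace = TRUE)

  # --- known mature miRNAs (reference members, not genome-planted)
  known <- character(cfg$n_known)
  for (i in seq_len(cfg$n_known)) known[i] <- .rand_seq(sample(20:22, 1L))
  known_ids <- sprintf("miR%04d", seq_len(cfg$n_known))

  # --- planted novel hairpins
  truth_rows <- list()
  occupied_s <- integer(0); occupied_e <- integer(0)
  place <- function(len) {
    for (try in 1:200) {
      s <- sample.int(cfg$genome_len - len + 1L, 1L)
      e <- s + len - 1L
      if (!any(occupied_s <= e + 50L & occupied_e >= s - 50L)) return(c(s, e))
    }
    stop("cannot place non-overlapping hairpin loci; increase genome_len",
         call. = FALSE)
  }
  for (i in seq_len(cfg$n_novel)) {
    m_len <- sample(20:24, 1L)
    loop_len <- sample(8:15, 1L)
    n_mm <- sample(0:2, 1L)
    on5p <- runif(1) < 0.5
    # canonical by construction: resample until the folded precursor's
    # optimal structure is the intended one (the hairpin evaluator
    # confirms the planted arm and exactly the planted mismatches)
    for (try in 1:100) {
      mature <- .rand_seq(m_len)
      arm3 <- .revcomp(mature)
      if (n_mm > 0L) {
        # keep planted mismatches off the duplex ends so the stem closes
        pos <- sample(3:(m_len - 2L), n_mm)
        arm3 <- .mutate_arm(arm3, pos, mature)
      }
      prec <- if (on5p) paste0(mature, .rand_seq(loop_len), arm3)
              else paste0(arm3, .rand_seq(loop_len), mature)
      ts <- if (on5p) 1L else nchar(prec) - m_len + 1L
      chk <- evaluate_hairpin(
        list(ref = "chk", start = 1L, end = nchar(prec), strand = "+",
             seq = prec, tag_start = ts, tag_end = ts + m_len - 1L),
        c(sim = 1))
      if (inherits(chk, "hairpin_candidate") &&
          chk$duplex_mismatches == n_mm &&
          chk$arm == (if (on5p) "5'" else "3'")) break
      if (try == 100L) stop("could not construct a canonical hairpin")
    }
    strand <- if (runif(1) < 0.5) "+" else "-"
    loc <- place(nchar(prec))
    ins <- if (strand == "+") prec else .revcomp(prec)
    genome_chars[loc[1]:loc[2]] <- strsplit(ins, "")[[1]]
    occupied_s <- c(occupied_s, loc[1]); occupied_e <- c(occupied_e, loc[2])
    # star = duplex partner of the mature with the canonical overhang
    star <- if (on5p) substr(prec, m_len + loop_len + 3L, nchar(prec)) else
      substr(prec, 1L, nchar(arm3) - 2L)
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      name = sprintf("novel%02d", i), kind = "novel", mature = mature,
      star = star, ref = "chr1", start = loc[1], end = loc[2],
      strand = strand, arm = if (on5p) "5'" else "3'", planted_mm = n_mm,
      stringsAsFactors = FALSE)
  }

  genome_seq <- paste(genome_chars, collapse = "")
  # known matures must not collide with the genome or each other
  stopifnot(!anyDuplicated(c(known, vapply(truth_rows, function(r) r$mature,
                                           character(1)))))

  truth_known <- if (cfg$n_known > 0L) data.frame(
    name = known_ids, kind = "known", mature = known, star = NA_character_,
    ref = NA_character_, start = NA_integer_, end = NA_integer_,
    strand = NA_character_, arm = NA_character_, planted_mm = NA_integer_,
    stringsAsFactors = FALSE) else NULL
  truth <- rbind(truth_known, if (length(truth_rows))
    do.call(rbind, truth_rows))
  if (is.null(truth)) truth <- data.frame(name = character(),
                                          mature = character())

  # --- fold changes
  if (is.null(cfg$fc_table)) {
    fc <- setNames(rep(0, nrow(truth)), truth$name)
    n_de <- max(0L, round(0.2 * nrow(truth)))
    if (n_de > 0L) {
      de_idx <- sample(nrow(truth), n_de)
      fc[de_idx] <- sample(c(-3, -2, 2, 3), n_de, replace = TRUE)
    }
  } else {
    fc <- setNames(rep(0, nrow(truth)), truth$name)
    keep <- intersect(names(cfg$fc_table), names(fc))
    fc[keep] <- cfg$fc_table[keep]
  }
  truth$true_fc <- unname(fc[truth$name])
  mean_wa <- cfg$mean_count * exp(stats::rnorm(nrow(truth), 0, 0.8))
  mean_wa[!is.finite(truth$true_fc) & truth$true_fc < 0] <- 0
  mean_wb <- ifelse(is.finite(truth$true_fc),
                    mean_wa * 2^(-truth$true_fc), 0)
  mean_wb[!is.finite(truth$true_fc) & truth$true_fc < 0] <-
    cfg$mean_count * exp(stats::rnorm(sum(!is.finite(truth$true_fc) &
                                            truth$true_fc < 0), 0, 0.8))
  truth$mean_wa <- mean_wa
  truth$mean_wb <- mean_wb

  # --- structural ncRNA decoys
  cats <- rep(c("rRNA", "tRNA", "snRNA", "snoRNA"),
              length.out = cfg$n_ncrna)
  nc <- data.frame(id = sprintf("%s_%02d", cats, seq_len(cfg$n_ncrna)),
                   seq = vapply(seq_len(cfg$n_ncrna),
                                function(i) .rand_seq(sample(80:200, 1L)),
                                character(1)),
                   stringsAsFactors = FALSE)

  # --- transcripts with planted target sites for fold-changed miRNAs
  tx <- data.frame(id = sprintf("TX%03d", seq_len(cfg$n_transcripts)),
                   seq = vapply(seq_len(cfg$n_transcripts),
                                function(i) .rand_seq(cfg$transcript_len),
                                character(1)),
                   stringsAsFactors = FALSE)
  de_mirnas <- truth$name[truth$true_fc != 0]
  for (i in seq_along(de_mirnas)) {
    if (cfg$n_transcripts == 0L) break
    txi <- ((i - 1L) %% cfg$n_transcripts) + 1L
    site <- .revcomp(truth$mature[truth$name == de_mirnas[i]])
    pos <- 50L + 40L * ((i - 1L) %/% cfg$n_transcripts)
    if (pos + nchar(site) > cfg$transcript_len) next
    s <- tx$seq[txi]
    tx$seq[txi] <- paste0(substr(s, 1L, pos - 1L), site,
                          substr(s, pos + nchar(site), cfg$transcript_len))
  }

  list(genome = reference_set(data.frame(id = "chr1", seq = genome_seq,
                                         stringsAsFactors = FALSE),
                              "genome", "genome"),
       mature_known = reference_set(data.frame(id = known_ids, seq = known,
                                               stringsAsFactors = FALSE),
                                    "mature_mirna", "mature"),
       ncrna = reference_set(nc, "ncRNA", "ncRNA"),
       transcripts = reference_set(tx, "transcripts", "transcript"),
       truth = truth)
}

# sample n reads (sequences) from a set of source sequences as random
# 18-30 nt fragments
.sample_fragments <- function(sources, n) {
  if (n <= 0L || length(sources) == 0L) return(character(0))
  src <- sample(sources, n, replace = TRUE)
  len <- sample(18:30, n, replace = TRUE)
  slen <- nchar(src)
  len <- pmin(len, slen)
  start <- floor(runif(n) * (slen - len + 1)) + 1L
  substr(src, start, start + len - 1L)
}

# per-base substitution noise at rate `rate`, vectorized over reads
.apply_noise <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  hit <- runif(length(seqs)) < 1 - (1 - rate)^lens   # >=1 substitution
  idx <- which(hit)
  for (i in idx) {
    p <- sample.int(lens[i], 1L)
    old <- substr(seqs[i], p, p)
    substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  }
  seqs
}

#' Simulate the two read libraries
#'
#' Mature counts in WA are Poisson around each miRNA's mean; WB counts
#' are Poisson around mean * 2^(-true log2 FC). Star reads accompany
#' novel matures at `star_fraction` of the mature mean. Structural
#' ncRNA fragments and genomic background fill each library to
#' `depth`, and per-base substitution noise is applied at rate
#' `noise`.
#'
#' @param cfg a [simulation_config()]
#' @param sim output of [make_genome()]
#' @return list: `reads` (named list WA/WB of read data.frames),
#'   `expected_counts` (data.frame: name, kind, seq, WA, WB -- realized
#'   mature counts before noise)
#' @export
simulate_libraries <- function(cfg, sim) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 1L)
  truth <- sim$truth
  out_reads <- list()
  counts <- data.frame(name = truth$name, kind = truth$kind,
                       seq = truth$mature, stringsAsFactors = FALSE)
  for (lib in c("WA", "WB")) {
    mean_col <- if (lib == "WA") truth$mean_wa else truth$mean_wb
    n_mat <- rpois(nrow(truth), mean_col)
    counts[[lib]] <- n_mat
    reads <- rep(truth$mature, n_mat)
    is_novel <- truth$kind == "novel"
    n_star <- rpois(sum(is_novel), cfg$star_fraction * mean_col[is_novel])
    reads <- c(reads, rep(truth$star[is_novel], n_star))
    n_fill <- max(0L, cfg$depth - length(reads))
    n_nc <- round(cfg$ncrna_fraction * n_fill)
    reads <- c(reads,
               .sample_fragments(sim$ncrna$records$seq, n_nc),
               .sample_fragments(sim$genome$records$seq, n_fill - n_nc))
    reads <- .apply_noise(reads, cfg$noise)
    if (length(reads) > 0L) reads <- sample(reads)   # shuffle read order
    out_reads[[lib]] <- data.frame(
      id = if (length(reads)) sprintf("%s_r%d", lib, seq_along(reads))
           else character(0),
      seq = reads, qual = if (length(reads)) strrep("I", nchar(reads))
                          else character(0),
      stringsAsFactors = FALSE)
  }
  list(reads = out_reads, expected_counts = counts)
}

#' Generate and write a complete synthetic dataset
#'
#' Convenience wrapper: [make_genome()] + [simulate_libraries()], with
#' every artifact written to `out_dir` (genome.fa, ncrna.fa,
#' mature_known.fa, transcripts.fa, reads_WA.fastq, reads_WB.fastq,
#' truth.tsv).
#'
#' @param cfg a [simulation_config()]
#' @param out_dir output directory (created if missing)
#' @return invisibly, the in-memory list (`genome`, `mature_known`,
#'   `ncrna`, `transcripts`, `truth`, `reads`, `expected_counts`)
#' @export
simulate_dataset <- function(cfg = simulation_config(), out_dir = NULL) {
  sim <- make_genome(cfg)
  libs <- simulate_libraries(cfg, sim)
  sim$reads <- libs$reads
  sim$expected_counts <- libs$expected_counts
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(sim$genome$records, file.path(out_dir, "genome.fa"))
    write_fasta(sim$ncrna$records, file.path(out_dir, "ncrna.fa"))
    write_fasta(sim$mature_known$records,
                file.path(out_dir, "mature_known.fa"))
    write_fasta(sim$transcripts$records,
                file.path(out_dir, "transcripts.fa"))
    write_fastq(sim$reads$WA, file.path(out_dir, "reads_WA.fastq"))
    write_fastq(sim$reads$WB, file.path(out_dir, "reads_WB.fastq"))
    write.table(sim$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(sim)
}
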