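# Readers and writers for the formats the pipeline touches.
#
# Sequence records travel as plain data.frames:
#   reads:  id, seq, qual (qual may be NA)
#   tags:   id, seq, plus one integer count column per library
# Coordinates are 1-based inclusive in every written file.

#' Read a FASTQ file
#'
#' Parses plain (uncompressed) 4-line-per-record FASTQ. `U` bases are
#' normalized to `T` internally; `N` is allowed. Malformed records --
#' a quality string whose length differs from the sequence, or a
#' truncated record -- raise an error naming the offending line.
#'
#' @param path path to a FASTQ file
#' @return data.frame with columns `id`, `seq`, `qual`
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  }
  if (n %% 4L != 0L) {
    stop(sprintf("truncated FASTQ record starting at line %d in '%s'",
                 4L * (n %/% 4L) + 1L, path), call. = FALSE)
  }
  hdr <- lines[seq(1L, n, by = 4L)]
  seq <- lines[seq(2L, n, by = 4L)]
  qual <- lines[seq(4L, n, by = 4L)]
  bad_hdr <- !startsWith(hdr, "@")
  if (any(bad_hdr)) {
    stop(sprintf("expected '@' header at line %d in '%s'",
                 4L * (which(bad_hdr)[1L] - 1L) + 1L, path), call. = FALSE)
  }
  bad_len <- nchar(qual) != nchar(seq)
  if (any(bad_len)) {
    stop(sprintf("quality length differs from sequence length at line %d in '%s'",
                 4L * (which(bad_len)[1L] - 1L) + 4L, path), call. = FALSE)
  }
  .check_alphabet(seq, sprintf("FASTQ '%s'", basename(path)))
  data.frame(id = sub("^@", "", sub("\\s.*$", "", hdr)),
             seq = .norm_seq(seq), qual = qual, stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with `id`, `seq`, `qual`; missing qualities
#'   are written as `I` runs
#' @param path output path
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual
  fill <- is.na(qual) | !nzchar(qual)
  qual[fill] <- vapply(nchar(reads$seq[fill]),
                       function(n) strrep("I", n), character(1))
  out <- rbind(paste0("@", reads$id), reads$seq, "+", qual)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Read a FASTA file of reference sequences
#'
#' @param path FASTA path
#' @return data.frame with columns `id`, `seq` (U normalized to T)
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  .check_alphabet(seqs, sprintf("FASTA '%s'", basename(path)))
  data.frame(id = sub("\\s.*$", "", names(ss)), seq = .norm_seq(unname(seqs)),
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#' @param x data.frame with `id` and `seq`
#' @param path output path
#' @export
write_fasta <- function(x, path) {
  ss <- Biostrings::DNAStringSet(setNames(x$seq, x$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Bundle sequences into a named reference set
#'
#' @param records data.frame with `id`, `seq`
#' @param name label, e.g. "mature_mirna"
#' @param kind one of mature, precursor, ncRNA, genome, transcript
#' @return a `reference_set` list
#' @export
reference_set <- function(records, name,
                          kind = c("mature", "precursor", "ncRNA",
                                   "genome", "transcript")) {
  kind <- match.arg(kind)
  if (anyDuplicated(records$id)) {
    stop("duplicate ids in reference set '", name, "'", call. = FALSE)
  }
  structure(list(name = name, kind = kind, records = records),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set '%s' (%s): %d sequences, %d-%d nt>\n",
              x$name, x$kind, nrow(x$records),
              if (nrow(x$records)) min(nchar(x$records$seq)) else 0L,
              if (nrow(x$records)) max(nchar(x$records$seq)) else 0L))
  invisible(x)
}

#' Read a collapsed-tag FASTA into a tag table
#'
#' Accepts both common header dialects, `<name>-<count>` and
#' `<name> count=<n>`. Counts must be positive integers.
#'
#' @param path collapsed FASTA path
#' @param library library name the counts belong to
#' @return tag data.frame with columns `id`, `seq`, `<library>`
#' @export
read_collapsed_fasta <- function(path, library) {
  stopifnot(file.exists(path), is.character(library), nzchar(library))
  ss <- Biostrings::readBStringSet(path)
  hdr <- names(ss)
  count <- rep(NA_real_, length(hdr))
  m <- regmatches(hdr, regexec("count=([0-9]+)$", hdr))
  has_kv <- lengths(m) == 2L
  count[has_kv] <- as.numeric(vapply(m[has_kv], `[`, character(1), 2L))
  m2 <- regmatches(hdr, regexec("-([0-9]+)$", hdr))
  has_dash <- !has_kv & lengths(m2) == 2L
  count[has_dash] <- as.numeric(vapply(m2[has_dash], `[`, character(1), 2L))
  if (anyNA(count)) {
    stop(sprintf("cannot parse tag count from header '%s' in '%s'",
                 hdr[which(is.na(count))[1L]], path), call. = FALSE)
  }
  if (any(count <= 0)) {
    stop(sprintf("non-positive tag count in header '%s' in '%s'",
                 hdr[which(count <= 0)[1L]], path), call. = FALSE)
  }
  seqs <- as.character(ss)
  .check_alphabet(seqs, sprintf("collapsed FASTA '%s'", basename(path)))
  out <- data.frame(id = sub("([ -]count=[0-9]+|-[0-9]+)$", "",
                             sub("\\s.*$", "", hdr)),
                    seq = .norm_seq(unname(seqs)), stringsAsFactors = FALSE)
  out[[library]] <- as.integer(count)
  out
}

#' Write a tag table for one library as collapsed FASTA
#'
#' Headers use the canonical `<name>-<count>` dialect. Tags with zero
#' count in `library` are skipped.
#'
#' @param tags tag data.frame
#' @param library which count column to emit
#' @param path output path
#' @export
write_collapsed_fasta <- function(tags, library, path) {
  stopifnot(library %in% names(tags))
  keep <- tags[[library]] > 0L
  x <- tags[keep, , drop = FALSE]
  ss <- Biostrings::DNAStringSet(setNames(x$seq,
                                          paste0(x$id, "-", x[[library]])))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Merge per-library tag tables on sequence
#'
#' @param tag_list list of tag data.frames, each with one count column
#' @return tag data.frame with the union of sequences and one count
#'   column per library (absent counts are 0)
#' @export
merge_tag_tables <- function(tag_list) {
  libs <- unlist(lapply(tag_list, function(t) setdiff(names(t), c("id", "seq"))))
  if (anyDuplicated(libs)) stop("duplicate library names across tag tables")
  all_seq <- unique(unlist(lapply(tag_list, `[[`, "seq")))
  out <- data.frame(id = paste0("t", seq_along(all_seq)), seq = all_seq,
                    stringsAsFactors = FALSE)
  for (t in tag_list) {
    lib <- setdiff(names(t), c("id", "seq"))
    v <- integer(length(all_seq))
    v[match(t$seq, all_seq)] <- t[[lib]]
    out[[lib]] <- v
  }
  out
}

#' Write hairpin candidate loci as a GFF3-style table
#'
#' One tab-separated row per candidate: seqid, source, type, start,
#' end, score, strand, phase, attributes. Coordinates are 1-based
#' inclusive; strand is `+` or `-`.
#'
#' @param candidates list of `hairpin_candidate` objects (or an empty
#'   list, which yields a header-only file)
#' @param path output path
#' @export
write_gff_like_loci <- function(candidates, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (cand in candidates) {
    loc <- cand$locus
    if (loc$end < loc$start) {
      stop(sprintf("locus end (%d) < start (%d) for '%s'",
                   loc$end, loc$start, cand$name), call. = FALSE)
    }
    if (!loc$strand %in% c("+", "-")) stop("strand must be '+' or '-'")
    writeLines(paste(loc$ref, "mircms", "miRNA_primary_transcript",
                     loc$start, loc$end,
                     format(cand$fold$mfe, trim = TRUE), loc$strand, ".",
                     paste0("ID=", cand$name, ";arm=", cand$arm),
                     sep = "\t"), con)
  }
  invisible(path)
}
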