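# Raw reads -> clean, collapsed tags and per-library summary statistics.

#' Preprocessing configuration
#'
#' Filter order is: quality, 5' contaminant, 3' adapter trim, poly-A,
#' N-containing, length window. "Low quality" means mean Phred below
#' `min_qual` (applied only when qualities are present); the poly-A rule
#' removes reads that are >= 80 percent A after trimming.
#'
#' @param min_len minimum kept length in nt
#' @param max_len maximum kept length in nt
#' @param adapter3 optional 3' adapter to trim (prefix search, one
#'   mismatch allowed per 10 nt of adapter)
#' @param min_qual optional mean-Phred threshold (default 20)
#' @param drop_polyA drop poly-A reads?
#' @param drop_5p_contaminant optional 5' primer sequence; reads
#'   starting with it are removed
#' @return a `preprocess_config` list
#' @export
preprocess_config <- function(min_len = 18L, max_len = 30L, adapter3 = NULL,
                              min_qual = 20, drop_polyA = TRUE,
                              drop_5p_contaminant = NULL) {
  stopifnot(min_len > 0L, min_len <= max_len)
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 adapter3 = if (is.null(adapter3)) NULL else .norm_seq(adapter3),
                 min_qual = min_qual, drop_polyA = isTRUE(drop_polyA),
                 drop_5p_contaminant = if (is.null(drop_5p_contaminant)) NULL
                                       else .norm_seq(drop_5p_contaminant)),
            class = "preprocess_config")
}

# Locate the 3' adapter in each read (first position where the adapter,
# or its prefix at the read end, matches with <= 1 mismatch per 10 nt),
# returning the match start or NA.
.find_adapter <- function(seqs, adapter) {
  alen <- nchar(adapter)
  achars <- strsplit(adapter, "")[[1]]
  vapply(seqs, function(s) {
    n <- nchar(s)
    sc <- strsplit(s, "")[[1]]
    for (start in seq_len(n)) {
      span <- min(alen, n - start + 1L)
      if (span < min(6L, alen)) break   # too short to call an adapter hit
      mm <- sum(sc[start:(start + span - 1L)] != achars[seq_len(span)])
      if (mm <= span %/% 10L) return(start)
    }
    NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}

#' Clean raw reads
#'
#' Applies, in order: mean-quality filter, 5' contaminant removal,
#' 3' adapter trimming, poly-A removal (>= 80 percent A), N removal,
#' and the 18-30 nt length window. Filters never fail; every removal
#' is itemized in the attached accounting so that
#' reads_in == reads_kept + sum(reads_removed).
#'
#' @param reads data.frame from [read_fastq()]
#' @param cfg a [preprocess_config()]
#' @return cleaned reads data.frame, with an `accounting` attribute
#'   (named integer vector of removals per filter)
#' @export
clean_reads <- function(reads, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  acc <- c(low_quality = 0L, contaminant_5p = 0L, poly_a = 0L,
           has_n = 0L, length = 0L)
  if (nrow(reads) == 0L) {
    attr(reads, "accounting") <- acc
    return(reads)
  }
  n_in <- nrow(reads)

  if (!is.null(cfg$min_qual) && "qual" %in% names(reads) &&
      !all(is.na(reads$qual))) {
    meanq <- vapply(reads$qual, function(q) {
      if (is.na(q) || !nzchar(q)) return(Inf)
      mean(utf8ToInt(q) - 33L)
    }, numeric(1), USE.NAMES = FALSE)
    drop <- meanq < cfg$min_qual
    acc["low_quality"] <- sum(drop)
    reads <- reads[!drop, , drop = FALSE]
  }

  if (!is.null(cfg$drop_5p_contaminant) && nrow(reads)) {
    drop <- startsWith(reads$seq, cfg$drop_5p_contaminant)
    acc["contaminant_5p"] <- sum(drop)
    reads <- reads[!drop, , drop = FALSE]
  }

  if (!is.null(cfg$adapter3) && nrow(reads)) {
    at <- .find_adapter(reads$seq, cfg$adapter3)
    trim <- !is.na(at)
    reads$seq[trim] <- substr(reads$seq[trim], 1L, at[trim] - 1L)
    if ("qual" %in% names(reads)) {
      reads$qual[trim] <- substr(reads$qual[trim], 1L, at[trim] - 1L)
    }
  }

  if (cfg$drop_polyA && nrow(reads)) {
    na_ <- nchar(reads$seq) - nchar(gsub("A", "", reads$seq, fixed = TRUE))
    drop <- nchar(reads$seq) > 0L & na_ / pmax(nchar(reads$seq), 1L) >= 0.8
    acc["poly_a"] <- sum(drop)
    reads <- reads[!drop, , drop = FALSE]
  }

  if (nrow(reads)) {
    drop <- grepl("N", reads$seq, fixed = TRUE)
    acc["has_n"] <- sum(drop)
    reads <- reads[!drop, , drop = FALSE]
  }

  if (nrow(reads)) {
    len <- nchar(reads$seq)
    drop <- len < cfg$min_len | len > cfg$max_len
    acc["length"] <- sum(drop)
    reads <- reads[!drop, , drop = FALSE]
  }

  stopifnot(n_in == nrow(reads) + sum(acc))
  attr(reads, "accounting") <- acc
  reads
}

#' Collapse cleaned reads into unique tags
#'
#' @param reads cleaned reads data.frame
#' @param library library name for the count column
#' @return tag data.frame (`id`, `seq`, `<library>`); sum of counts
#'   equals the number of input reads
#' @export
collapse_reads <- function(reads, library) {
  stopifnot(is.character(library), nzchar(library))
  if (nrow(reads) == 0L) {
    out <- data.frame(id = character(), seq = character(),
                      stringsAsFactors = FALSE)
    out[[library]] <- integer()
    return(out)
  }
  tab <- table(reads$seq)
  # order by decreasing abundance, then sequence, for stable ids
  ord <- order(-as.integer(tab), names(tab))
  out <- data.frame(id = paste0("t", seq_along(tab)),
                    seq = names(tab)[ord], stringsAsFactors = FALSE)
  out[[library]] <- as.integer(tab)[ord]
  out
}

#' Per-library summary statistics
#'
#' Length histogram (reads and unique tags per nt) and totals, the
#' per-library half of a category-distribution table. Percentages are
#' computed as 100 * count / total and reported to 2 decimals.
#'
#' @param tags tag data.frame containing a count column for `library`
#' @param library library name
#' @return a `library_stats` list with `library`, `total_clean`,
#'   `unique_clean`, and `length_hist` (data.frame: length, reads,
#'   tags, pct_reads)
#' @export
library_stats <- function(tags, library) {
  stopifnot(library %in% c(names(tags), character(0)) || nrow(tags) == 0L)
  counts <- if (library %in% names(tags)) tags[[library]] else integer()
  keep <- counts > 0L
  seqs <- tags$seq[keep]
  counts <- counts[keep]
  total <- sum(counts)
  lens <- nchar(seqs)
  ulen <- sort(unique(lens))
  hist <- data.frame(
    length = ulen,
    reads = vapply(ulen, function(l) sum(counts[lens == l]), numeric(1)),
    tags = vapply(ulen, function(l) sum(lens == l), numeric(1)))
  hist$pct_reads <- if (total > 0) round(100 * hist$reads / total, 2) else
    numeric(nrow(hist))
  structure(list(library = library, total_clean = total,
                 unique_clean = length(seqs), length_hist = hist),
            class = "library_stats")
}

#' @export
print.library_stats <- function(x, ...) {
  cat(sprintf("<library_stats '%s': %s clean reads, %s unique tags>\n",
              x$library, format(x$total_clean, big.mark = ","),
              format(x$unique_clean, big.mark = ",")))
  invisible(x)
}

#' Category distribution table
#'
#' Aggregates annotation records into the familiar small-RNA category
#' table: unique-tag and total-read counts per category with
#' percentages of the library total, one block per library.
#'
#' @param ann annotation data.frame from [annotate_tags()] (tag columns
#'   plus `category`), or any data.frame with `category` and per-library
#'   count columns
#' @param libraries character vector of count column names
#' @return data.frame: category, then `<lib>_unique`, `<lib>_unique_pct`,
#'   `<lib>_total`, `<lib>_total_pct` per library, with a leading
#'   "total" row
#' @export
category_table <- function(ann, libraries) {
  cats <- c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "unannotated")
  cats <- c(cats, setdiff(unique(ann$category), cats))
  out <- data.frame(category = c("total", cats), stringsAsFactors = FALSE)
  for (lib in libraries) {
    cnt <- ann[[lib]]
    present <- cnt > 0L
    uniq <- vapply(cats, function(cc) sum(present & ann$category == cc),
                   numeric(1))
    tot <- vapply(cats, function(cc) sum(cnt[ann$category == cc]), numeric(1))
    out[[paste0(lib, "_unique")]] <- c(sum(uniq), uniq)
    out[[paste0(lib, "_unique_pct")]] <-
      round(100 * c(sum(uniq), uniq) / max(sum(uniq), 1), 2)
    out[[paste0(lib, "_total")]] <- c(sum(tot), tot)
    out[[paste0(lib, "_total_pct")]] <-
      round(100 * c(sum(tot), tot) / max(sum(tot), 1), 2)
  }
  out
}

#' Percentages for an already-summarized category table
#'
#' For workflows where only per-category tallies are at hand (unique
#' tags and total reads per category), computes the percentage columns
#' the category table reports: 100 * count / library total, to 2
#' decimals.
#'
#' @param counts data.frame with columns `category`, `unique`, `total`
#' @return the same data.frame with `unique_pct` and `total_pct` added
#' @export
category_percentages <- function(counts) {
  stopifnot(all(c("category", "unique", "total") %in% names(counts)))
  counts$unique_pct <- round(100 * counts$unique / sum(counts$unique), 2)
  counts$total_pct <- round(100 * counts$total / sum(counts$total), 2)
  counts
}
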