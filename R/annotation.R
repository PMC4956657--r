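# Tag classification against reference sets and miRNA family summaries.

#' Annotation configuration
#'
#' @param max_mismatch_ref mismatches allowed against structural ncRNA /
#'   genome references (default 2)
#' @param max_mismatch_mirbase mismatches allowed against mature miRNAs
#'   (default 2)
#' @param category_priority order in which multi-hits are resolved
#' @return an `annotation_config` list
#' @export
annotation_config <- function(max_mismatch_ref = 2L,
                              max_mismatch_mirbase = 2L,
                              category_priority = c("rRNA", "tRNA", "snRNA",
                                                    "snoRNA", "miRNA")) {
  stopifnot(max_mismatch_ref >= 0L, max_mismatch_mirbase >= 0L)
  structure(list(max_mismatch_ref = as.integer(max_mismatch_ref),
                 max_mismatch_mirbase = as.integer(max_mismatch_mirbase),
                 category_priority = category_priority),
            class = "annotation_config")
}

#' Ungapped mismatch-tolerant search of one tag against a reference set
#'
#' Slides an equal-length window over every reference sequence and
#' reports the best Hamming hit with at most `k` mismatches, or `NULL`.
#' Genome-kind sets are searched on both strands; mature/precursor/
#' ncRNA/transcript sets forward-only. Ties are broken by fewest
#' mismatches, then lexicographically smallest reference id, then
#' smallest start.
#'
#' @param tag_seq nucleotide string
#' @param ref a [reference_set()]
#' @param k maximum mismatches (>= 0)
#' @param all_hits return every hit location instead of the best one?
#' @return `NULL`, or a data.frame with `hit_id`, `start`, `end`,
#'   `strand`, `mismatches` (one row unless `all_hits`)
#' @export
match_with_mismatches <- function(tag_seq, ref, k, all_hits = FALSE) {
  stopifnot(inherits(ref, "reference_set"), k >= 0L)
  tag_seq <- .norm_seq(tag_seq)
  strands <- if (ref$kind == "genome") c("+", "-") else "+"
  pat <- Biostrings::DNAString(tag_seq)
  rc <- if ("-" %in% strands) Biostrings::reverseComplement(pat) else NULL
  hits <- list()
  for (i in seq_len(nrow(ref$records))) {
    subject <- Biostrings::DNAString(ref$records$seq[i])
    for (strand in strands) {
      p <- if (strand == "+") pat else rc
      if (length(p) > length(subject)) next
      m <- Biostrings::matchPattern(p, subject, max.mismatch = k,
                                    with.indels = FALSE)
      if (length(m) == 0L) next
      mm <- vapply(seq_along(m), function(j)
        Biostrings::neditAt(p, subject, at = IRanges::start(m)[j]),
        integer(1))
      hits[[length(hits) + 1L]] <- data.frame(
        hit_id = ref$records$id[i], start = IRanges::start(m),
        end = IRanges::end(m), strand = strand, mismatches = mm,
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) return(NULL)
  h <- do.call(rbind, hits)
  h <- h[order(h$mismatches, h$hit_id, h$start), , drop = FALSE]
  rownames(h) <- NULL
  if (all_hits) h else h[1L, , drop = FALSE]
}

# Batch mismatch-tolerant matching of many tags against one reference
# set. Exact ≤k-mismatch detection via the pigeonhole principle: tags
# are grouped by length and indexed in k+1 PDicts, each trusting a
# different contiguous band (a hit with ≤k mismatches leaves at least
# one band clean). Returns the id of the first reference sequence (in
# set order) hit by each tag, or NA.
.batch_hits <- function(seqs, ref, k) {
  n <- length(seqs)
  res <- rep(NA_character_, n)
  if (n == 0L || nrow(ref$records) == 0L) return(res)
  strands <- if (ref$kind == "genome") c("+", "-") else "+"
  lens <- nchar(seqs)
  for (L in sort(unique(lens))) {
    idx <- which(lens == L)
    x <- Biostrings::DNAStringSet(seqs[idx])
    nb <- k + 1L
    bands <- floor(seq(0L, L, length.out = nb + 1L))
    pdicts <- lapply(seq_len(nb), function(b) {
      if (k == 0L) Biostrings::PDict(x)
      else Biostrings::PDict(x, tb.start = bands[b] + 1L,
                             tb.end = bands[b + 1L])
    })
    for (ri in seq_len(nrow(ref$records))) {
      if (all(!is.na(res[idx]))) break
      if (L > nchar(ref$records$seq[ri])) next
      subj <- Biostrings::DNAString(ref$records$seq[ri])
      hit_local <- integer(0)
      for (strand in strands) {
        s <- if (strand == "+") subj else Biostrings::reverseComplement(subj)
        for (pd in pdicts) {
          hit_local <- union(hit_local,
                             Biostrings::whichPDict(pd, s, max.mismatch = k))
        }
      }
      if (length(hit_local)) {
        new <- idx[hit_local]
        new <- new[is.na(res[new])]
        res[new] <- ref$records$id[ri]
      }
    }
  }
  res
}

#' Classify tags into small-RNA categories
#'
#' Each tag is assigned exactly one category following the configured
#' priority (structural ncRNAs first, then known miRNAs); tags hitting
#' nothing are `unannotated`. Reference sets are matched by `name`:
#' sets named after a category ("rRNA", "tRNA", "snRNA", "snoRNA") are
#' used for that category, and a set of kind `mature` supplies the
#' miRNA category. A single combined set named "ncRNA" is also
#' accepted and feeds every structural category it contains (by id
#' prefix rRNA/tRNA/snRNA/snoRNA, else "rRNA").
#'
#' @param tags tag data.frame (possibly multi-library)
#' @param refs list of [reference_set()]s; must include a mature set
#'   and at least one ncRNA-kind set
#' @param cfg an [annotation_config()]
#' @return the tag data.frame with `category`, `hit_id`, `mismatches`
#'   columns appended
#' @export
annotate_tags <- function(tags, refs, cfg = annotation_config()) {
  stopifnot(inherits(cfg, "annotation_config"))
  kinds <- vapply(refs, `[[`, character(1), "kind")
  names(refs) <- vapply(refs, `[[`, character(1), "name")
  if (!any(kinds == "mature")) {
    stop("annotate_tags needs a reference set of kind 'mature'",
         call. = FALSE)
  }
  if (!any(kinds == "ncRNA")) {
    stop("annotate_tags needs at least one ncRNA reference set",
         call. = FALSE)
  }
  mature <- refs[[which(kinds == "mature")[1L]]]

  # expand a combined ncRNA set into per-category sets by id prefix
  cat_sets <- list()
  for (r in refs[kinds == "ncRNA"]) {
    if (r$name %in% c("rRNA", "tRNA", "snRNA", "snoRNA")) {
      cat_sets[[r$name]] <- r
    } else {
      pre <- sub("^((sno|sn|r|t)RNA).*", "\\1", r$records$id)
      pre[!pre %in% c("rRNA", "tRNA", "snRNA", "snoRNA")] <- "rRNA"
      for (cc in unique(pre)) {
        rec <- r$records[pre == cc, , drop = FALSE]
        cat_sets[[cc]] <- reference_set(
          if (is.null(cat_sets[[cc]])) rec else
            rbind(cat_sets[[cc]]$records, rec), cc, "ncRNA")
      }
    }
  }

  n <- nrow(tags)
  category <- rep("unannotated", n)
  hit_id <- rep(NA_character_, n)
  mism <- rep(NA_integer_, n)
  unassigned <- rep(TRUE, n)
  for (cc in cfg$category_priority) {
    if (!any(unassigned)) break
    if (cc == "miRNA") {
      set <- mature; k <- cfg$max_mismatch_mirbase
    } else if (!is.null(cat_sets[[cc]])) {
      set <- cat_sets[[cc]]; k <- cfg$max_mismatch_ref
    } else next
    ids <- .batch_hits(tags$seq[unassigned], set, k)
    hit <- !is.na(ids)
    w <- which(unassigned)[hit]
    category[w] <- cc
    hit_id[w] <- ids[hit]
    unassigned[w] <- FALSE
    # refine to the best hit (fewest mismatches, deterministic ties)
    # where the per-tag detail is affordable or feeds downstream
    # tables (known-miRNA family attribution)
    if (cc == "miRNA" || length(w) <= 2000L) {
      for (i in w) {
        h <- match_with_mismatches(tags$seq[i], set, k)
        hit_id[i] <- h$hit_id
        mism[i] <- h$mismatches
      }
    }
  }
  tags$category <- category
  tags$hit_id <- hit_id
  tags$mismatches <- mism
  tags
}

#' Summarize known-miRNA abundance by family
#'
#' Groups annotated miRNA tags by family and sums reads per library.
#' The family of a mature id comes from the `alias` map when given;
#' otherwise the id is stripped of species prefix, letter and arm
#' suffixes (e.g. `ath-miR156a-5p` -> `miR156`). The WA/WB-style
#' abundance ratio uses raw read counts and is rounded to 2 decimals;
#' it is `NA` (printed "-") when the denominator library has no reads.
#'
#' @param ann annotated tag data.frame from [annotate_tags()]
#' @param libraries two library names, c(numerator, denominator)
#' @param alias optional named character vector mature-id -> family
#' @return data.frame: family, members, `<lib>` read sums, total, ratio
#' @export
family_table <- function(ann, libraries, alias = NULL) {
  stopifnot(length(libraries) == 2L, all(libraries %in% names(ann)))
  mir <- ann[ann$category == "miRNA", , drop = FALSE]
  if (nrow(mir) == 0L) {
    out <- data.frame(family = character(), members = integer(),
                      stringsAsFactors = FALSE)
    out[[libraries[1]]] <- numeric(); out[[libraries[2]]] <- numeric()
    out$total <- numeric(); out$ratio <- numeric()
    return(out)
  }
  fam0 <- .strip_family(mir$hit_id)
  fam <- fam0
  if (!is.null(alias)) {
    # full-id aliases take precedence, then family-prefix aliases
    f1 <- unname(alias[mir$hit_id])
    f2 <- unname(alias[fam0])
    fam <- ifelse(!is.na(f1), f1, ifelse(!is.na(f2), f2, fam0))
  }
  fams <- sort(unique(fam))
  a <- vapply(fams, function(f) sum(mir[[libraries[1]]][fam == f]), numeric(1))
  b <- vapply(fams, function(f) sum(mir[[libraries[2]]][fam == f]), numeric(1))
  members <- vapply(fams, function(f) length(unique(mir$hit_id[fam == f])),
                    integer(1))
  out <- data.frame(family = fams, members = members, stringsAsFactors = FALSE)
  out[[libraries[1]]] <- a
  out[[libraries[2]]] <- b
  out$total <- a + b
  out$ratio <- ifelse(b == 0, NA_real_, round(a / b, 2))
  rownames(out) <- NULL
  out
}

#' Totals and abundance ratios for an already-summed family table
#'
#' The same arithmetic [family_table()] applies, for workflows where
#' per-family read sums are the starting point: total = sum over the
#' two libraries, ratio = first/second library raw reads rounded to 2
#' decimals, `NA` (printed "-") when the second library has none.
#'
#' @param family_reads data.frame with a `family` column and one
#'   read-count column per library
#' @param libraries two library names, c(numerator, denominator)
#' @return the input with `total` and `ratio` columns added
#' @export
family_summary <- function(family_reads, libraries = c("WA", "WB")) {
  stopifnot(all(libraries %in% names(family_reads)))
  a <- family_reads[[libraries[1]]]
  b <- family_reads[[libraries[2]]]
  family_reads$total <- a + b
  family_reads$ratio <- ifelse(b == 0, NA_real_, round(a / b, 2))
  family_reads
}

# "ath-miR156a-5p" -> "miR156"; merged families stay as given in alias maps
.strip_family <- function(ids) {
  x <- sub("^[a-z]{2,4}-", "", ids)
  x <- sub("-(3p|5p)$", "", x)
  sub("^((miR|miRn)[0-9]+).*", "\\1", x)
}
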