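# End-to-end orchestration: preprocess -> annotate -> {novel
# discovery, differential expression} -> targets -> network, with a
# report bundle shaped like the usual two-library small-RNA study
# tables and a JSON run log carrying seeds and filter accounting.

#' Run the full two-library small-RNA pipeline
#'
#' @param reads named list of two read data.frames (from
#'   [read_fastq()] or the simulator); names are the library names,
#'   first = numerator of fold changes
#' @param refs named list of [reference_set()]s: `mature` (known
#'   mature miRNAs), `ncrna`, and optionally `genome` (enables novel
#'   discovery) and `transcripts` (enables target prediction)
#' @param out_dir optional directory; when given, all report files are
#'   written there
#' @param preprocess_cfg,annotation_cfg,novel_crit,de_cfg,target_cfg
#'   stage configurations (defaults apply)
#' @param alias optional mature-id -> family map for the family table
#' @param backend folding backend for novel discovery, see [fold()]
#' @return a `pipeline_result` list: `stats` (per-library
#'   [library_stats()]), `annotated` (tag table with categories),
#'   `category_table`, `family_table`, `novel` (candidate list),
#'   `novel_table`, `de` (DE table over known + novel miRNAs),
#'   `target_hits`, `network`, `log`
#' @export
run_pipeline <- function(reads, refs, out_dir = NULL,
                         preprocess_cfg = preprocess_config(),
                         annotation_cfg = annotation_config(),
                         novel_crit = novel_criteria(),
                         de_cfg = de_config(),
                         target_cfg = target_scoring_config(),
                         alias = NULL,
                         backend = c("builtin", "vienna")) {
  backend <- match.arg(backend)
  stopifnot(is.list(reads), length(reads) == 2L, !is.null(names(reads)),
            all(c("mature", "ncrna") %in% names(refs)))
  libs <- names(reads)
  log <- list(libraries = libs, stages = list())

  # --- preprocess
  tag_tables <- list()
  stats <- list()
  for (lib in libs) {
    cleaned <- clean_reads(reads[[lib]], preprocess_cfg)
    acc <- attr(cleaned, "accounting")
    tags <- collapse_reads(cleaned, lib)
    stats[[lib]] <- library_stats(tags, lib)
    tag_tables[[lib]] <- tags
    log$stages$preprocess[[lib]] <- list(
      reads_in = nrow(reads[[lib]]), reads_clean = nrow(cleaned),
      removed = as.list(acc), unique_tags = nrow(tags))
  }
  tags <- merge_tag_tables(tag_tables)
  totals <- vapply(stats, `[[`, numeric(1), "total_clean")

  # --- annotate
  ref_list <- list(refs$mature, refs$ncrna)
  ann <- annotate_tags(tags, ref_list, annotation_cfg)
  cat_tab <- category_table(ann, libs)
  fam_tab <- family_table(ann, libs, alias = alias)
  log$stages$annotate <- list(
    categories = setNames(as.list(table(ann$category)), NULL))
  log$stages$annotate$categories <- as.list(table(ann$category))

  # --- novel discovery
  novel <- list()
  if (!is.null(refs$genome)) {
    novel <- discover_novel(ann, refs$genome, novel_crit, backend = backend)
  }
  nov_tab <- novel_table(novel, libs)
  log$stages$novel <- list(candidates = length(novel))

  # --- differential expression over known + novel miRNAs
  known_counts <- .aggregate_known(ann, libs)
  novel_counts <- .novel_counts(novel, libs)
  de_counts <- rbind(known_counts, novel_counts)
  de <- if (nrow(de_counts)) de_table(de_counts, libs, totals, de_cfg) else
    de_table(data.frame(mirna = character(),
                        setNames(list(integer(), integer()), libs),
                        check.names = FALSE),
             libs, totals, de_cfg)
  log$stages$differential <- list(
    tested = nrow(de), up = sum(de$call == "up"),
    down = sum(de$call == "down"))

  # --- targets + network
  hits <- data.frame(mirna = character(), transcript = character(),
                     site_start = integer(), site_end = integer(),
                     expectation = numeric(), inhibition = character(),
                     stringsAsFactors = FALSE)
  if (!is.null(refs$transcripts) && nrow(de)) {
    seqs <- .mirna_sequences(ann, novel, refs$mature)
    de_ids <- de$mirna[de$call != "ns"]
    for (id in intersect(de_ids, names(seqs))) {
      hits <- rbind(hits, scan_transcripts(list(id = id, seq = seqs[[id]]),
                                           refs$transcripts, target_cfg))
    }
  }
  net <- build_network(de, hits)
  log$stages$targets <- list(hits = nrow(hits), edges = nrow(net))

  result <- structure(list(stats = stats, annotated = ann,
                           category_table = cat_tab, family_table = fam_tab,
                           novel = novel, novel_table = nov_tab, de = de,
                           target_hits = hits, network = net,
                           totals = totals, log = log),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_report_bundle(result, out_dir)
  result
}

# per-mature-id known miRNA counts, summed over matching tags
.aggregate_known <- function(ann, libs) {
  mir <- ann[ann$category == "miRNA", , drop = FALSE]
  if (nrow(mir) == 0L) {
    out <- data.frame(mirna = character(), stringsAsFactors = FALSE)
    for (lib in libs) out[[lib]] <- integer()
    return(out)
  }
  ids <- sort(unique(mir$hit_id))
  out <- data.frame(mirna = ids, stringsAsFactors = FALSE)
  for (lib in libs) {
    out[[lib]] <- vapply(ids, function(i) sum(mir[[lib]][mir$hit_id == i]),
                         numeric(1))
  }
  rownames(out) <- NULL
  out
}

.novel_counts <- function(novel, libs) {
  out <- data.frame(mirna = character(), stringsAsFactors = FALSE)
  for (lib in libs) out[[lib]] <- numeric()
  for (cand in novel) {
    row <- data.frame(mirna = cand$name, stringsAsFactors = FALSE)
    for (lib in libs) {
      row[[lib]] <- if (lib %in% names(cand$mature_counts))
        unname(cand$mature_counts[[lib]]) else 0
    }
    out <- rbind(out, row)
  }
  out
}

# id -> sequence map for DE miRNAs (known matures + novel candidates)
.mirna_sequences <- function(ann, novel, mature_ref) {
  seqs <- as.list(setNames(mature_ref$records$seq, mature_ref$records$id))
  for (cand in novel) seqs[[cand$name]] <- cand$mature
  seqs
}

#' Write the report bundle of a pipeline run
#'
#' Emits category_table.tsv, family_table.tsv, novel_candidates.tsv,
#' novel_loci.gff, de_table.tsv, target_hits.tsv, network.sif,
#' network_edges.tsv and run_log.json into `out_dir`.
#'
#' @param result a `pipeline_result` from [run_pipeline()]
#' @param out_dir output directory (created if missing)
#' @export
write_report_bundle <- function(result, out_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) {
    write.table(x, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  tsv(result$category_table, "category_table.tsv")
  tsv(result$family_table, "family_table.tsv")
  tsv(result$novel_table, "novel_candidates.tsv")
  write_gff_like_loci(result$novel, file.path(out_dir, "novel_loci.gff"))
  tsv(result$de, "de_table.tsv")
  tsv(result$target_hits, "target_hits.tsv")
  write_sif(result$network, file.path(out_dir, "network.sif"))
  tsv(result$network, "network_edges.tsv")
  jsonlite::write_json(result$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  libs <- names(x$stats)
  cat("<pipeline_result>\n")
  for (lib in libs) {
    cat(sprintf("  %s: %s clean reads, %s unique tags\n", lib,
                format(x$stats[[lib]]$total_clean, big.mark = ","),
                format(x$stats[[lib]]$unique_clean, big.mark = ",")))
  }
  cat(sprintf("  known miRNA ids: %d; novel candidates: %d\n",
              nrow(x$de) - length(x$novel), length(x$novel)))
  cat(sprintf("  DE calls: %d up, %d down of %d tested\n",
              sum(x$de$call == "up"), sum(x$de$call == "down"), nrow(x$de)))
  cat(sprintf("  target hits: %d; network edges: %d\n",
              nrow(x$target_hits), nrow(x$network)))
  invisible(x)
}
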