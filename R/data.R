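# Bundled summary data from a published two-library radish floral-bud
# small-RNA experiment (sterile 'WA' line vs fertile maintainer 'WB'):
# per-family known-miRNA read counts, the novel miRNA/star summary
# rows, per-category tag/read tallies, and the per-library clean-read
# totals. These printed summaries are the worked-example inputs for
# the arithmetic stages (family ratios, category percentages,
# normalization and fold changes); the underlying raw libraries are
# not distributed.

#' Bundled two-library small-RNA summary dataset
#'
#' @return a list:
#' \describe{
#'   \item{family_reads}{data.frame of known miRNA families with
#'     member counts and WA/WB read sums}
#'   \item{novel_summary}{data.frame of novel miRNA and star rows
#'     (reads, mature sequence, arm, size, precursor length, MFE,
#'     locus)}
#'   \item{category_counts}{list of data.frames (WA, WB): per-category
#'     unique-tag and total-read counts}
#'   \item{totals}{named vector of clean reads per library}
#'   \item{unique_totals}{named vector of unique tags per library}
#' }
#' @export
cms_summary_data <- function() {
  ext <- function(f) system.file("extdata", f, package = "mircms",
                                 mustWork = TRUE)
  family_reads <- read.table(ext("known_family_reads.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  novel_summary <- read.table(ext("novel_mirna_summary.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE,
                              comment.char = "")
  category_counts <- list(
    WA = data.frame(
      category = c("miRNA", "rRNA", "snRNA", "snoRNA", "tRNA",
                   "unannotated"),
      unique = c(27092, 92089, 6099, 3383, 11010, 5388388),
      total = c(1453994, 2685339, 22072, 10011, 1157890, 14957919),
      stringsAsFactors = FALSE),
    WB = data.frame(
      category = c("miRNA", "rRNA", "snRNA", "snoRNA", "tRNA",
                   "unannotated"),
      unique = c(27764, 117885, 6602, 4120, 14008, 5511728),
      total = c(1521955, 3446274, 27969, 11837, 514526, 16466675),
      stringsAsFactors = FALSE))
  list(family_reads = family_reads, novel_summary = novel_summary,
       category_counts = category_counts,
       totals = c(WA = 20287225, WB = 21989236),
       unique_totals = c(WA = 5528061, WB = 5682107))
}

#' Family alias map shipped with the package
#'
#' Mature-id-prefix to family aliases for the merged families (e.g.
#' miR156/157). Family merging is a curation fact; the map is an
#' editable TSV under `inst/extdata/family_alias.tsv`.
#'
#' @return named character vector prefix -> family label
#' @export
family_alias_map <- function() {
  x <- read.table(system.file("extdata", "family_alias.tsv",
                              package = "mircms", mustWork = TRUE),
                  sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  setNames(x$family, x$mature_prefix)
}
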