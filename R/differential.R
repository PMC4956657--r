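# Two-library digital differential expression: per-million
# normalization with a 0.01 zero substitute, log2 fold change, and the
# Audic-Claverie exact test (Fisher's exact test as an alternative).

#' Differential-expression configuration
#'
#' @param alpha significance threshold on the (raw) p-value
#' @param fc_threshold absolute log2 fold-change threshold
#' @param pseudo value substituted for a normalized expression of zero
#' @param test "audic_claverie" (default) or "fisher"
#' @param adjust multiple-testing adjustment reported alongside raw
#'   p-values ("BH" default); calls always use the raw p-value
#' @return a `de_config` list
#' @export
de_config <- function(alpha = 0.05, fc_threshold = 1.0, pseudo = 0.01,
                      test = c("audic_claverie", "fisher"),
                      adjust = c("BH", "none")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  stopifnot(alpha > 0, alpha < 1, fc_threshold > 0, pseudo > 0)
  structure(list(alpha = alpha, fc_threshold = fc_threshold, pseudo = pseudo,
                 test = test, adjust = adjust), class = "de_config")
}

#' Normalize a raw count to reads per million
#'
#' `raw / total * 1e6`; a zero count yields the pseudo-expression
#' (default 0.01) so fold changes stay finite.
#'
#' @param raw_count non-negative integer count(s)
#' @param total_clean positive library total
#' @param pseudo zero substitute on the normalized scale
#' @return RPM value(s)
#' @export
normalize_rpm <- function(raw_count, total_clean, pseudo = 0.01) {
  if (any(total_clean <= 0)) stop("total_clean must be positive",
                                  call. = FALSE)
  if (any(raw_count < 0)) stop("raw_count must be non-negative",
                               call. = FALSE)
  ifelse(raw_count == 0, pseudo, raw_count / total_clean * 1e6)
}

#' Log2 fold change of two normalized expressions
#'
#' @param expr_a,expr_b positive RPM values (pseudo already applied);
#'   the result is log2(expr_a / expr_b)
#' @return log2 fold change(s)
#' @export
log2_fold_change <- function(expr_a, expr_b) {
  if (any(expr_a <= 0) || any(expr_b <= 0)) {
    stop("expressions must be positive (apply the pseudo first)",
         call. = FALSE)
  }
  log2(expr_a / expr_b)
}

#' Audic-Claverie two-library count test
#'
#' Exact two-sided test that a tag's counts x (library 1, total n1)
#' and y (library 2, total n2) are drawn from the same underlying
#' rate. With t = n2/n1, the conditional law of Y given x is
#' P(Y = y | x) = t^y (x+y)! / (x! y! (1+t)^(x+y+1)), the negative
#' binomial with size x+1 and success probability n1/(n1+n2), so tail
#' sums are evaluated with `pnbinom`. The two-sided p-value doubles
#' the smaller tail (capped at 1) and is symmetrized over the
#' conditioning direction (the more conservative of conditioning on x
#' or on y), so exchanging library labels cannot change the result.
#'
#' @param x,y non-negative counts (vectorized)
#' @param n1,n2 positive library totals
#' @return two-sided p-value(s)
#' @export
count_test_p <- function(x, y, n1, n2) {
  stopifnot(all(x >= 0), all(y >= 0), all(n1 > 0), all(n2 > 0))
  pmax(.ac_directed_p(x, y, n1, n2), .ac_directed_p(y, x, n2, n1))
}

.ac_directed_p <- function(x, y, n1, n2) {
  prob <- n1 / (n1 + n2)
  lower <- pnbinom(y, size = x + 1, prob = prob)
  # upper tail P(Y >= y) taken directly to avoid cancellation at 1
  upper <- pnbinom(y - 1, size = x + 1, prob = prob, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

# Fisher's exact test on (x, n1-x; y, n2-y), the usual 2x2 alternative
.fisher_p <- function(x, y, n1, n2) {
  vapply(seq_along(x), function(i) {
    stats::fisher.test(matrix(c(x[i], n1 - x[i], y[i], n2 - y[i]), 2L))$p.value
  }, numeric(1))
}

#' Differential-expression table for two libraries
#'
#' Normalizes counts, computes log2 fold changes (library A over B),
#' tests each miRNA, and calls up/down/ns at the configured
#' thresholds. A miRNA with a zero raw count in exactly one library is
#' flagged library-specific.
#'
#' @param counts data.frame with an id column (`mirna` or `id`) and
#'   one raw-count column per library
#' @param libraries two library names, c(A, B); fold changes are
#'   log2(A/B)
#' @param totals named vector of total clean reads per library
#'   (normalization denominators)
#' @param cfg a [de_config()]
#' @return data.frame: mirna, raw counts, rpm_A, rpm_B, log2_fc,
#'   p_value, q_value, call, library_specific
#' @export
de_table <- function(counts, libraries, totals, cfg = de_config()) {
  stopifnot(inherits(cfg, "de_config"), length(libraries) == 2L,
            all(libraries %in% names(counts)),
            all(libraries %in% names(totals)))
  idcol <- intersect(c("mirna", "id", "name"), names(counts))[1]
  if (is.na(idcol)) stop("counts needs an id column ('mirna', 'id' or 'name')")
  a <- counts[[libraries[1]]]
  b <- counts[[libraries[2]]]
  n1 <- totals[[libraries[1]]]
  n2 <- totals[[libraries[2]]]
  rpm_a <- normalize_rpm(a, n1, cfg$pseudo)
  rpm_b <- normalize_rpm(b, n2, cfg$pseudo)
  lfc <- log2_fold_change(rpm_a, rpm_b)
  p <- if (cfg$test == "audic_claverie") count_test_p(a, b, n1, n2)
       else .fisher_p(a, b, n1, n2)
  q <- if (cfg$adjust == "BH") p.adjust(p, "BH") else p
  call <- rep("ns", length(p))
  call[p <= cfg$alpha & lfc >= cfg$fc_threshold] <- "up"
  call[p <= cfg$alpha & lfc <= -cfg$fc_threshold] <- "down"
  spec <- rep(NA_character_, length(p))
  spec[a > 0 & b == 0] <- paste0(libraries[1], "-only")
  spec[a == 0 & b > 0] <- paste0(libraries[2], "-only")
  out <- data.frame(mirna = counts[[idcol]], stringsAsFactors = FALSE)
  out[[libraries[1]]] <- a
  out[[libraries[2]]] <- b
  out[[paste0("rpm_", libraries[1])]] <- rpm_a
  out[[paste0("rpm_", libraries[2])]] <- rpm_b
  out$log2_fc <- round(lfc, 4)
  out$p_value <- p
  out$q_value <- q
  out$call <- call
  out$library_specific <- spec
  out
}
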