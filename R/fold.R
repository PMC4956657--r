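# RNA secondary-structure folding with a pluggable backend.
#
# The built-in folder is a weighted Nussinov dynamic program (pair
# scores G:C = 3, A:U = 2, G:U = 1, hairpin loops of at least 3
# unpaired bases) with a deterministic traceback. It maximizes total
# pair score, which is what the hairpin evaluator needs: the duplex
# geometry is read off the pair table, not off an energy. Its "mfe"
# slot is the negated pair score, a pseudo-energy flagged by
# `energy_model = "pseudo"`. For publication-grade minimum free
# energies a thermodynamic backend ("vienna", shelling out to RNAfold
# when available) can be selected; its energies are kcal/mol and
# `energy_model = "thermodynamic"`.

#' Fold an RNA sequence
#'
#' @param seq nucleotide string (>= 15 nt for hairpin work; shorter is
#'   allowed and simply folded)
#' @param backend `"builtin"` (default, deterministic DP) or
#'   `"vienna"` (RNAfold, if installed)
#' @return a `fold_result` list: `seq` (RNA alphabet), `structure`
#'   (dot-bracket), `mfe` (<= 0), `score` (pair score, builtin),
#'   `energy_model` ("pseudo" or "thermodynamic")
#' @export
#' @examples
#' fold("GGGAAACCC")$structure   # "(((...)))"
fold <- function(seq, backend = c("builtin", "vienna")) {
  backend <- match.arg(backend)
  .check_alphabet(seq, "fold() input")
  dna <- .norm_seq(seq)
  if (grepl("N", dna, fixed = TRUE)) {
    stop("fold() cannot fold sequences containing N", call. = FALSE)
  }
  if (backend == "vienna") {
    res <- .vienna_fold(dna)
    if (!is.null(res)) return(res)
    warning("RNAfold not available; falling back to the builtin folder")
  }
  r <- .nussinov_fold(dna)
  structure(list(seq = dna_to_rna(dna), structure = r$structure,
                 mfe = -as.numeric(r$score), score = as.numeric(r$score),
                 energy_model = "pseudo"),
            class = "fold_result")
}

.vienna_fold <- function(dna) {
  rnafold <- Sys.which("RNAfold")
  if (!nzchar(rnafold)) return(NULL)
  out <- tryCatch(
    system2(rnafold, c("--noPS"), input = dna_to_rna(dna), stdout = TRUE),
    error = function(e) NULL)
  if (is.null(out) || length(out) < 2L) return(NULL)
  m <- regmatches(out[2], regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", out[2]))[[1]]
  if (length(m) != 3L) return(NULL)
  structure(list(seq = dna_to_rna(dna), structure = m[2],
                 mfe = as.numeric(m[3]), score = NA_real_,
                 energy_model = "thermodynamic"),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$seq, "\n", x$structure, sprintf(" (%.2f, %s)\n", x$mfe,
                                        x$energy_model), sep = "")
  invisible(x)
}

#' Pair table of a dot-bracket structure
#'
#' @param structure dot-bracket string
#' @return integer vector p with p[i] = partner of base i, or 0
#' @export
pair_table <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  n <- length(chars)
  p <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[i] <- j
      p[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket", call. = FALSE)
  p
}
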