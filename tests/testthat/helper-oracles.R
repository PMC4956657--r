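# Independent brute-force oracles used across the suite. These
# deliberately share no code with the package internals.

# all-window Hamming scan of a tag against a reference table
# (data.frame id, seq); forward-only or both strands
brute_hamming_scan <- function(tag, refs, k, both_strands = FALSE) {
  revcomp_chr <- function(x) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }
  tags <- if (both_strands) c(`+` = tag, `-` = revcomp_chr(tag)) else
    c(`+` = tag)
  best <- NULL
  for (i in seq_len(nrow(refs))) {
    ref <- refs$seq[i]
    for (strand in names(tags)) {
      t <- tags[[strand]]
      lt <- nchar(t)
      if (lt > nchar(ref)) next
      for (s in 1:(nchar(ref) - lt + 1)) {
        win <- substr(ref, s, s + lt - 1)
        mm <- sum(strsplit(t, "")[[1]] != strsplit(win, "")[[1]])
        if (mm <= k) {
          cand <- list(hit_id = refs$id[i], start = s, mismatches = mm,
                       strand = strand)
          if (is.null(best) ||
              mm < best$mismatches ||
              (mm == best$mismatches && cand$hit_id < best$hit_id) ||
              (mm == best$mismatches && cand$hit_id == best$hit_id &&
               s < best$start)) {
            best <- cand
          }
        }
      }
    }
  }
  best
}

# exhaustive enumeration of nested secondary structures (min hairpin
# loop 3) and the maximum total score under the package's scheme:
# pair scores G:C=3, A:U=2, G:U=1, +2 for each stacked pair
enum_fold_optimum <- function(seq) {
  chars <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  n <- length(chars)
  ps <- function(a, b) {
    x <- paste0(chars[a], chars[b])
    switch(x, GC = 3, CG = 3, AT = 2, TA = 2, GT = 1, TG = 1, 0)
  }
  # enumerate pair sets for interval [i, j]
  memo <- new.env()
  structs <- function(i, j) {
    if (j - i <= 3) return(list(list()))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- structs(i, j - 1)              # j unpaired
    for (k in i:(j - 4)) {
      if (ps(k, j) == 0) next
      left <- if (k > i) structs(i, k - 1) else list(list())
      inner <- structs(k + 1, j - 1)
      for (L in left) for (In in inner) {
        out[[length(out) + 1]] <- c(L, In, list(c(k, j)))
      }
    }
    memo[[key]] <- out
    out
  }
  score_of <- function(pairs) {
    if (length(pairs) == 0) return(0)
    tot <- sum(vapply(pairs, function(p) ps(p[1], p[2]), numeric(1)))
    key <- vapply(pairs, function(p) paste(p[1], p[2]), character(1))
    stacked <- sum(vapply(pairs, function(p)
      paste(p[1] + 1, p[2] - 1) %in% key, logical(1)))
    tot + 2 * stacked
  }
  if (n == 0) return(0)
  max(vapply(structs(1, n), score_of, numeric(1)))
}

# score of a dot-bracket structure under the same scheme (to verify
# the reported structure attains the reported score)
score_dot_bracket <- function(seq, db) {
  chars <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  ps <- function(a, b) {
    x <- paste0(chars[a], chars[b])
    switch(x, GC = 3, CG = 3, AT = 2, TA = 2, GT = 1, TG = 1, 0)
  }
  d <- strsplit(db, "")[[1]]
  stack <- integer(0)
  pairs <- list()
  for (i in seq_along(d)) {
    if (d[i] == "(") stack <- c(stack, i)
    else if (d[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[[length(pairs) + 1]] <- c(j, i)
    }
  }
  if (length(pairs) == 0) return(0)
  key <- vapply(pairs, function(p) paste(p[1], p[2]), character(1))
  tot <- sum(vapply(pairs, function(p) ps(p[1], p[2]), numeric(1)))
  stacked <- sum(vapply(pairs, function(p)
    paste(p[1] + 1, p[2] - 1) %in% key, logical(1)))
  tot + 2 * stacked
}

# brute-force Audic-Claverie two-sided p-value by direct log-space
# summation of P(k | x) = t^k (x+k)! / (x! k! (1+t)^(x+k+1)),
# symmetrized over the conditioning direction like the package's test
ac_brute_p <- function(x, y, n1, n2, kmax = 20000) {
  directed <- function(x, y, n1, n2) {
    t <- n2 / n1
    logp <- function(k) {
      k * log(t) + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
        (x + k + 1) * log(1 + t)
    }
    ks <- 0:kmax
    lp <- logp(ks)
    lower <- sum(exp(lp[ks <= y]))
    upper <- sum(exp(lp[ks >= y]))
    min(1, 2 * min(lower, upper))
  }
  max(directed(x, y, n1, n2), directed(y, x, n2, n1))
}

# literal hand-scoring oracle for miRNA:site duplexes: builds every
# explicit gapped alignment as strings and scores character by
# character (mismatch 1, G:U 0.5, indel 2, doubled at miRNA positions
# 2-13 counted 5'->3')
naive_duplex_expectation <- function(mirna, site) {
  m <- strsplit(toupper(chartr("U", "T", mirna)), "")[[1]]
  s <- rev(strsplit(toupper(chartr("U", "T", site)), "")[[1]])
  pen1 <- function(a, b) {
    if (paste0(a, b) %in% c("AT", "TA", "CG", "GC")) 0
    else if (paste0(a, b) %in% c("GT", "TG")) 0.5
    else 1
  }
  weight <- function(p) if (p >= 2 && p <= 13) 2 else 1
  score_alignment <- function(ma, sa) {
    # ma, sa equal-length vectors, "-" marks a gap
    tot <- 0
    mpos <- 0
    for (r in seq_along(ma)) {
      if (ma[r] != "-") mpos <- mpos + 1
      p <- if (ma[r] == "-" || sa[r] == "-") 2 else pen1(ma[r], sa[r])
      wpos <- if (ma[r] == "-") min(mpos + 1, sum(ma != "-")) else mpos
      tot <- tot + p * weight(wpos)
    }
    tot
  }
  lm <- length(m); ls <- length(s)
  if (lm == ls) return(score_alignment(m, s))
  if (lm == ls + 1) {
    return(min(vapply(1:lm, function(g)
      score_alignment(m, append(s, "-", after = g - 1)), numeric(1))))
  }
  if (ls == lm + 1) {
    return(min(vapply(1:ls, function(g)
      score_alignment(append(m, "-", after = g - 1), s), numeric(1))))
  }
  stop("length difference > 1")
}

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(chartr("U", "T", toupper(s)), "")[[1]]),
                 collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
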