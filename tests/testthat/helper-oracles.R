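# Independent oracles used to cross-check the package implementations.
# These are deliberately plain re-implementations (matrix DP, explicit loops,
# closed-form sums) kept separate from the package code paths.

# Brute-force seed-weighted local duplex scan: full Gotoh DP in base R with
# the same conventions as the package scanner (reversed query, seed weights
# scaling substitutions and gap penalties, greedy non-overlap masking,
# leftmost tie-break).
oracle_scan <- function(sncrna, utr, params = trfnet::scan_params()) {
  code <- c(A = 0L, C = 1L, G = 2L, T = 3L, U = 3L)
  q0 <- unname(code[strsplit(toupper(sncrna), "")[[1]]])
  s <- unname(code[strsplit(toupper(utr), "")[[1]]])
  L <- length(q0)
  w0 <- ifelse(
    seq_len(L) >= params$seed_from & seq_len(L) <= params$seed_to,
    params$seed_weight, 1
  )
  q <- rev(q0)
  w <- rev(w0)
  n <- L
  m <- length(s)
  masked <- rep(FALSE, m)
  subsc <- function(i, j) {
    a <- q[i]
    b <- s[j]
    base <- if (a + b == 3) {
      params$match
    } else if ((a == 2 && b == 3) || (a == 3 && b == 2)) {
      params$wobble
    } else {
      params$mismatch
    }
    w[i] * base
  }
  out <- NULL
  repeat {
    H <- matrix(0, n + 1, m + 1)
    E <- matrix(-1e18, n + 1, m + 1)
    FF <- matrix(-1e18, n + 1, m + 1)
    best <- 0
    bi <- -1L
    bj <- -1L
    for (i in 1:n) {
      for (j in 1:m) {
        if (masked[j]) next
        e <- max(H[i + 1, j] + params$gap_open * w[i],
                 E[i + 1, j] + params$gap_extend * w[i])
        f <- max(H[i, j + 1] + params$gap_open * w[i],
                 FF[i, j + 1] + params$gap_extend * w[i])
        h <- max(0, H[i, j] + subsc(i, j), e, f)
        E[i + 1, j + 1] <- e
        FF[i + 1, j + 1] <- f
        H[i + 1, j + 1] <- h
        if (h > best + 1e-9) {
          best <- h
          bi <- i
          bj <- j
        } else if (bi > 0 && h > 0 && abs(h - best) <= 1e-9 &&
                   (j < bj || (j == bj && i < bi))) {
          bi <- i
          bj <- j
        }
      }
    }
    if (best <= params$threshold + 1e-9) break
    i <- bi
    j <- bj
    minj <- bj
    while (i > 0 && j > 0 && H[i + 1, j + 1] > 1e-9) {
      h <- H[i + 1, j + 1]
      if (abs(h - (H[i, j] + subsc(i, j))) <= 1e-9) {
        minj <- j
        i <- i - 1
        j <- j - 1
      } else if (abs(h - E[i + 1, j + 1]) <= 1e-9) {
        repeat {
          minj <- j
          if (abs(E[i + 1, j + 1] -
                  (H[i + 1, j] + params$gap_open * w[i])) <= 1e-9) {
            j <- j - 1
            break
          }
          j <- j - 1
        }
      } else {
        repeat {
          if (abs(FF[i + 1, j + 1] -
                  (H[i, j + 1] + params$gap_open * w[i])) <= 1e-9) {
            i <- i - 1
            break
          }
          i <- i - 1
        }
      }
    }
    out <- rbind(out, data.frame(
      utr_start = minj - 1L, utr_end = bj, score = best
    ))
    masked[minj:bj] <- TRUE
  }
  if (is.null(out)) {
    data.frame(utr_start = integer(), utr_end = integer(), score = numeric())
  } else {
    out
  }
}

# Brute-force cross-join anti-correlation filter.
oracle_pair_filter <- function(de_snc, de_mrna, pairs) {
  keep <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    rd <- de_snc$direction[de_snc$feature_id == pairs$sncrna_id[r]]
    td <- de_mrna$direction[de_mrna$feature_id == pairs$utr_id[r]]
    keep[r] <- length(rd) == 1 && length(td) == 1 &&
      ((rd == "up" && td == "down") || (rd == "down" && td == "up"))
  }
  pairs[keep, c("sncrna_id", "utr_id")]
}

# Exact hypergeometric upper tail P(X >= k) by combinatorial sum.
oracle_hyper_tail <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# One-way ANOVA F from between/within sums of squares.
oracle_anova_f <- function(values, groups) {
  groups <- as.factor(groups)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  k <- nlevels(groups)
  (ssb / (k - 1)) / (ssw / (length(values) - k))
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(gsub("U", "T", x))
  ))
}
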