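# Independent brute-force oracles used to validate the implementations.
# These deliberately re-derive each quantity from first principles and
# share no code with the package internals.

# Plain-R Smith-Waterman: full DP matrix, linear gap penalty, traceback
# preferring diagonal, then up, then left; reported cell is the maximum
# with smallest query end, then smallest subject end.
sw_oracle <- function(query, subject, match = 1, mismatch = -1, gap = -2) {
  q <- strsplit(query, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  n <- length(q); m <- length(s)
  H <- matrix(0, n + 1, m + 1)
  TB <- matrix(0L, n + 1, m + 1)  # 1 diag, 2 up, 3 left
  best <- 0; bi <- 0; bj <- 0
  for (i in 1:n) {
    qi <- q[i]
    for (j in 1:m) {
      diag <- H[i, j] + if (qi == s[j]) match else mismatch
      up <- H[i, j + 1] + gap
      left <- H[i + 1, j] + gap
      h <- 0; code <- 0L
      if (diag >= up && diag >= left && diag > 0) { h <- diag; code <- 1L }
      else if (up >= left && up > 0) { h <- up; code <- 2L }
      else if (left > 0) { h <- left; code <- 3L }
      H[i + 1, j + 1] <- h
      TB[i + 1, j + 1] <- code
      if (h > best) { best <- h; bi <- i; bj <- j }
    }
  }
  if (best <= 0) return(NULL)
  i <- bi; j <- bj; matches <- 0; columns <- 0
  while (i > 0 && j > 0 && TB[i + 1, j + 1] != 0L) {
    code <- TB[i + 1, j + 1]
    columns <- columns + 1
    if (code == 1L) {
      if (q[i] == s[j]) matches <- matches + 1
      i <- i - 1; j <- j - 1
    } else if (code == 2L) i <- i - 1
    else j <- j - 1
  }
  list(score = best, identity = 100 * matches / columns,
       query_coverage = 100 * (bi - i) / n,
       qstart = i, qend = bi, sstart = j, send = bj)
}

# Textbook BH step-up: sort ascending, q_(i) = p_(i) * m / i, running
# minimum from the largest rank down, cap at 1, restore input order.
bh_oracle <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric())
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# Exhaustive tryptic digestion: every substring bounded by cleavage
# boundaries whose internal boundary count is <= max_missed.
digest_oracle <- function(protein, max_missed = 2, min_length = 4) {
  r <- strsplit(protein, "")[[1]]
  n <- length(r)
  cuts <- integer()
  for (i in seq_len(max(n - 1, 0))) {
    if (r[i] %in% c("K", "R") && r[i + 1] != "P") cuts <- c(cuts, i)
  }
  bounds <- c(0L, cuts, n)
  peps <- character()
  nb <- length(bounds)
  for (a in 1:(nb - 1)) {
    for (b in (a + 1):nb) {
      if (b - a - 1 > max_missed) next
      pep <- substr(protein, bounds[a] + 1, bounds[b])
      if (nchar(pep) >= min_length) peps <- c(peps, pep)
    }
  }
  peps
}

# Closed-form simple linear regression via the normal equations.
ols_oracle <- function(x, y) {
  sx <- sum(x); sy <- sum(y); n <- length(x)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                    collapse = "")

random_protein_str <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE),
        collapse = "")
}
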