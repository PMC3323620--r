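# Independent oracles used to cross-check the package implementations.
# These deliberately share no code with the package paths they verify.

# --- alignment -------------------------------------------------------------

# quadratic Gotoh re-implementation in plain R (score only): read aligned
# end-to-end, reference ends free, gap cost open + (L-1)*extend
oracle_semiglobal_score <- function(read, ref, match = 2, mismatch = -3,
                                    open = -6, extend = -1) {
  rd <- strsplit(read, "")[[1]]
  rf <- strsplit(ref, "")[[1]]
  m <- length(rd); n <- length(rf)
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1)  # gap in reference
  Y <- matrix(NEG, m + 1, n + 1)  # gap in read
  H <- matrix(NEG, m + 1, n + 1)
  H[1, ] <- 0
  for (i in 2:(m + 1)) {
    X[i, 1] <- open + (i - 2) * extend
    H[i, 1] <- X[i, 1]
  }
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      s <- if (rd[i - 1] == rf[j - 1]) match else mismatch
      M[i, j] <- H[i - 1, j - 1] + s
      X[i, j] <- max(H[i - 1, j] + open, X[i - 1, j] + extend)
      Y[i, j] <- max(H[i, j - 1] + open, Y[i, j - 1] + extend)
      H[i, j] <- max(M[i, j], X[i, j], Y[i, j])
    }
  }
  max(H[m + 1, ])
}

# exhaustive enumeration of every alignment path (tiny inputs only):
# recursion without memoization explores the complete path space
oracle_enumerate_score <- function(read, ref, match = 2, mismatch = -3,
                                   open = -6, extend = -1) {
  rd <- strsplit(read, "")[[1]]
  rf <- strsplit(ref, "")[[1]]
  m <- length(rd); n <- length(rf)
  rec <- function(i, j, prev) {
    if (i > m) return(0)                 # trailing reference free
    best <- -Inf
    if (j <= n) {
      s <- if (rd[i] == rf[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "M"))
      best <- max(best,
                  (if (prev == "D") extend else open) + rec(i, j + 1, "D"))
    }
    best <- max(best,
                (if (prev == "I") extend else open) + rec(i + 1, j, "I"))
    best
  }
  max(vapply(0:n, function(j0) rec(1, j0 + 1, "S"), numeric(1)))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# --- annotation ------------------------------------------------------------

# protein diff oracle: splice the variant into the reference CDS segment,
# translate both with Biostrings, and diff by maximal common prefix/suffix
oracle_protein_diff <- function(amp, v) {
  refNt <- ampliconSeq(amp)
  mutNt <- spliceVariant(amp, v)
  lead <- (3 - (cdsStart(amp) - 1) %% 3) %% 3
  trim <- function(s) {
    s <- substr(s, 1 + lead, nchar(s))
    substr(s, 1, nchar(s) - nchar(s) %% 3)
  }
  tr <- function(s)
    as.character(Biostrings::translate(Biostrings::DNAString(trim(s))))
  rp <- strsplit(tr(refNt), "")[[1]]
  mp <- strsplit(tr(mutNt), "")[[1]]
  firstCodon <- (cdsStart(amp) + lead - 1) %/% 3 + 1
  p <- 0
  while (p < length(rp) && p < length(mp) && rp[p + 1] == mp[p + 1])
    p <- p + 1
  if (length(rp) == length(mp)) {        # substitution
    if (p == length(rp)) return(list(kind = "synonymous"))
    list(kind = "substitution", codon = firstCodon + p,
         refAA = rp[p + 1], altAA = mp[p + 1])
  } else {                               # insertion
    s <- 0
    while (s < length(rp) - p && rp[length(rp) - s] == mp[length(mp) - s])
      s <- s + 1
    list(kind = "insertion", codon = firstCodon + p,
         peptide = paste(mp[(p + 1):(length(mp) - s)], collapse = ""))
  }
}

# --- statistics ------------------------------------------------------------

# two-sided Fisher exact by full hypergeometric enumeration
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + cc; N <- a + b + cc + d
  if (r1 == 0 || c1 == 0 || r1 == N || c1 == N) return(1)
  ks <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- vapply(ks, function(k)
    exp(lchoose(c1, k) + lchoose(N - c1, r1 - k) - lchoose(N, r1)),
    numeric(1))
  pObs <- probs[ks == a]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# permutation Kruskal-Wallis p-value
oracle_kw_perm <- function(groups, B = 10000, seed = 42) {
  set.seed(seed)
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  hstat <- function(x, g) {
    r <- rank(x)
    n <- length(x)
    h <- 12 / (n * (n + 1)) *
      sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
    ties <- table(x)
    h / (1 - sum(ties^3 - ties) / (n^3 - n))
  }
  h0 <- hstat(x, g)
  perm <- vapply(seq_len(B), function(b) hstat(x, sample(g)), numeric(1))
  mean(perm >= h0 - 1e-12)
}

# --- geometry --------------------------------------------------------------

random_rotation <- function() {
  # QR of a random Gaussian matrix gives a uniform orthogonal matrix
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

transform_atoms <- function(atoms, rot, shift = c(0, 0, 0)) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot)
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  atoms
}
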