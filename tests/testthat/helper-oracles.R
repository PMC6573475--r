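# Independent brute-force oracles and small fixture builders. Everything
# here deliberately avoids the package's own computational paths: explicit
# loops, direct formulas, or a second library's implementation.

# Build a haplotype_alignment from a character vector of sequences like
# c(P1 = "AATG", P1 = "AATG", P2 = "GGTA"): names are population codes.
toy_alignment <- function(seqs, locus_length_bp = NULL) {
  m <- do.call(rbind, strsplit(seqs, ""))
  ids <- paste0("s", seq_along(seqs))
  rownames(m) <- ids
  haplotype_alignment(m, stats::setNames(names(seqs), ids),
                      locus_length_bp %||% ncol(m))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force pairwise difference count with pairwise deletion.
oracle_diff <- function(a, b) {
  ok <- a != "N" & b != "N"
  sum(a[ok] != b[ok])
}

# Tajima's D, coded directly from the textbook constants (independent of
# the package's tajima_constants()).
oracle_tajimas_d <- function(S, pi, n) {
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Brute-force nested AMOVA from explicit sums of squares over a plain
# distance matrix d (NOT the package's delta^2 helper); delta2 = d^2 when
# squared = TRUE. pop/grp are per-individual labels.
oracle_amova <- function(d, pop, grp = NULL, squared = TRUE) {
  delta2 <- if (squared) d^2 else d
  N <- length(pop)
  ss_pairs <- function(idx) {
    s <- 0
    if (length(idx) >= 2)
      for (i in seq_along(idx)) for (j in seq_along(idx))
        if (i < j) s <- s + delta2[idx[i], idx[j]]
    s
  }
  SSD_T <- ss_pairs(seq_len(N)) / N
  pops <- unique(pop)
  SSD_WP <- 0
  for (p in pops) SSD_WP <- SSD_WP + ss_pairs(which(pop == p)) / sum(pop == p)
  np <- sapply(pops, function(p) sum(pop == p))
  P <- length(pops)
  if (is.null(grp)) {
    SSD_AP <- SSD_T - SSD_WP
    n_prime <- (N - sum(np^2) / N) / (P - 1)
    s2c <- SSD_WP / (N - P)
    s2b <- (SSD_AP / (P - 1) - s2c) / n_prime
    list(components = c(s2b, s2c),
         percentages = 100 * c(s2b, s2c) / (s2b + s2c),
         phi_st = s2b / (s2b + s2c))
  } else {
    grps <- unique(grp)
    G <- length(grps)
    SSD_WG <- 0
    for (g in grps) SSD_WG <- SSD_WG + ss_pairs(which(grp == g)) / sum(grp == g)
    SSD_APWG <- SSD_WG - SSD_WP
    SSD_AG <- SSD_T - SSD_WG
    gsum <- 0; ngsq <- 0
    for (g in grps) {
      idx <- which(grp == g)
      for (p in unique(pop[idx]))
        gsum <- gsum + sum(pop[idx] == p)^2 / length(idx)
      ngsq <- ngsq + length(idx)^2
    }
    nc <- (N - gsum) / (P - G)
    n2 <- (gsum - sum(np^2) / N) / (G - 1)
    n3 <- (N - ngsq / N) / (G - 1)
    s2c <- SSD_WP / (N - P)
    s2b <- (SSD_APWG / (P - G) - s2c) / nc
    s2a <- (SSD_AG / (G - 1) - s2c - n2 * s2b) / n3
    tot <- s2a + s2b + s2c
    list(components = c(s2a, s2b, s2c),
         percentages = 100 * c(s2a, s2b, s2c) / tot,
         phi = c(ct = s2a / tot, sc = s2b / (s2b + s2c),
                 st = (s2a + s2b) / tot))
  }
}

# Brute-force Mann-Whitney U of group 1 by enumerating pairwise wins.
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y)
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# Brute-force dA from the three mean-difference terms.
oracle_da <- function(seq_x, seq_y) {
  mean_between <- mean(outer(seq_along(seq_x), seq_along(seq_y),
                             Vectorize(function(i, j)
                               oracle_diff(strsplit(seq_x[i], "")[[1]],
                                           strsplit(seq_y[j], "")[[1]]))))
  within <- function(s) {
    n <- length(s); tot <- 0; k <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      tot <- tot + oracle_diff(strsplit(s[i], "")[[1]],
                               strsplit(s[j], "")[[1]]); k <- k + 1
    }
    tot / k
  }
  mean_between - (within(seq_x) + within(seq_y)) / 2
}
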