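#' Haplotype (gene) diversity, Nei's unbiased estimator
#'
#' \eqn{h = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)} where \eqn{p_i} are
#' haplotype relative frequencies. The same estimator applied to haplogroup
#' frequencies gives haplogroup diversity.
#'
#' @param counts non-negative integer counts per haplotype (or haplogroup).
#' @param n sample size; defaults to `sum(counts)`.
#' @return diversity in \[0, 1\].
#' @export
haplotype_diversity <- function(counts, n = sum(counts)) {
  counts <- counts[counts > 0]
  if (n < 2) stop_degenerate("need n >= 2 for haplotype diversity")
  if (sum(counts) != n) stop("counts must sum to n")
  h <- n / (n - 1) * (1 - sum((counts / n)^2))
  min(max(h, 0), 1)
}

#' @rdname haplotype_diversity
#' @param haplogroup_counts counts per haplogroup label.
#' @export
haplogroup_diversity <- function(haplogroup_counts, n = sum(haplogroup_counts)) {
  haplotype_diversity(haplogroup_counts, n)
}

#' Mean number of pairwise differences (MPD) within a population
#'
#' Mean of all \eqn{\binom{n}{2}} pairwise sequence difference counts.
#'
#' @param alignment a [haplotype_alignment()] (typically restricted to one
#'   population via [subset_alignment()]).
#' @param missing_policy passed to [pairwise_difference_matrix()].
#' @return non-negative real, in units of sites.
#' @export
mpd <- function(alignment, missing_policy = c("pairwise_deletion",
                                              "complete_deletion")) {
  n <- n_samples(alignment)
  if (n < 2) stop_degenerate("need n >= 2 for MPD")
  d <- pairwise_difference_matrix(alignment, missing_policy)$values
  sum(d[upper.tri(d)]) / choose(n, 2)
}

# Tajima (1989) normalizing constants for sample size n.
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' \eqn{D = (\pi - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}} with the standard
#' constants of the neutral-test literature; \eqn{\pi} is the mean number of
#' pairwise differences and S the number of segregating sites, both counted
#' on the same site set. `S = 0` gives an undefined (NA) result, flagged,
#' not an error.
#'
#' @param S segregating sites (>= 0).
#' @param pi mean pairwise differences.
#' @param n sample size (>= 4).
#' @return list with `D`, `defined`, and the `constants` record.
#' @export
tajimas_d <- function(S, pi, n) {
  if (n < 4) stop_degenerate("Tajima's D requires n >= 4")
  if (S < 0) stop("S must be >= 0")
  k <- tajima_constants(n)
  if (S == 0)
    return(list(D = NA_real_, defined = FALSE, constants = k))
  D <- (pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  list(D = D, defined = TRUE, constants = k)
}

# Branch lengths and subtree leaf counts of one neutral constant-size
# coalescent genealogy (time units arbitrary: only relative lengths are
# used by the fixed-S null). Returns list(len, ndesc) over the 2n-2 branches.
kingman_branches <- function(n) {
  k <- n:2
  times <- stats::rexp(n - 1, rate = k * (k - 1) / 2)
  ndesc <- c(rep(1L, n), integer(n - 1))
  len <- numeric(2 * n - 1)
  active <- seq_len(n)
  birth <- numeric(2 * n - 1)
  t <- 0
  for (j in seq_len(n - 1)) {
    t <- t + times[j]
    pick <- sample(length(active), 2L)
    a <- active[pick]
    node <- n + j
    len[a] <- t - birth[a]
    birth[node] <- t
    ndesc[node] <- ndesc[a[1]] + ndesc[a[2]]
    active <- c(active[-pick], node)
  }
  keep <- seq_len(2 * n - 2)           # root branch excluded
  list(len = len[keep], ndesc = ndesc[keep])
}

#' Simulation p-value for Tajima's D under a fixed-S coalescent null
#'
#' Two-sided p-value from neutral constant-size coalescent replicates
#' conditioned on the observed number of segregating sites: each replicate
#' draws a genealogy, places exactly S mutations on branches with
#' probability proportional to branch length, and computes D. The add-one
#' corrected p is \eqn{(b + 1)/(n_{sims} + 1)} with b the count of
#' replicates with \eqn{|D| \ge |D_{obs}|}.
#'
#' @param D_obs observed D.
#' @param n sample size.
#' @param S segregating sites (> 0).
#' @param n_sims number of replicates (>= 100).
#' @param seed RNG seed.
#' @return p-value in (0, 1\].
#' @export
tajima_significance <- function(D_obs, n, S, n_sims = 10000, seed = NULL) {
  if (S <= 0) stop("fixed-S null requires S > 0")
  if (n_sims < 100) stop("n_sims must be >= 100")
  k <- tajima_constants(n)
  denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  pair_w <- 2 / (n * (n - 1))
  with_seed(seed, {
    Dnull <- vapply(seq_len(n_sims), function(i) {
      br <- kingman_branches(n)
      mut <- as.vector(stats::rmultinom(1L, S, br$len))
      pi <- sum(mut * br$ndesc * (n - br$ndesc)) * pair_w
      (pi - S / k$a1) / denom
    }, 0)
    b <- sum(abs(Dnull) >= abs(D_obs))
    (b + 1) / (n_sims + 1)
  })
}

#' Per-population diversity summaries
#'
#' One row per population: sample size, number of distinct haplotypes,
#' haplotype diversity h, optional haplogroup diversity, MPD, segregating
#' sites S, Tajima's D and its fixed-S simulation p-value. Populations with
#' n < 2 are reported with undefined statistics.
#'
#' @param alignment a [haplotype_alignment()].
#' @param metadata optional metadata data.frame (from [read_metadata()]);
#'   used only to order/annotate rows.
#' @param haplogroups optional named character vector sample -> haplogroup.
#' @param missing_policy site-handling policy for MPD/S (complete deletion
#'   keeps D internally consistent; see [tajimas_d()]).
#' @param n_sims,seed control of the Tajima null; `n_sims = 0` skips
#'   p-values.
#' @return data.frame of class `diversity_summary`.
#' @export
population_summaries <- function(alignment, metadata = NULL,
                                 haplogroups = NULL,
                                 missing_policy = "complete_deletion",
                                 n_sims = 1000, seed = NULL) {
  pops <- unique(alignment$populations)
  if (!is.null(metadata)) pops <- c(intersect(metadata$code, pops),
                                    setdiff(pops, metadata$code))
  rows <- lapply(seq_along(pops), function(pi) {
    p <- pops[pi]
    ids <- names(alignment$populations)[alignment$populations == p]
    n <- length(ids)
    out <- data.frame(population = p, n = n, n_haplotypes = NA_integer_,
                      h = NA_real_, hg_div = NA_real_, mpd = NA_real_,
                      S = NA_integer_, tajimas_d = NA_real_,
                      p_tajima = NA_real_)
    if (n < 2) return(out)
    sub <- subset_alignment(alignment, samples = ids)
    ht <- collapse_haplotypes(sub)
    out$n_haplotypes <- nrow(ht$haplotypes)
    out$h <- haplotype_diversity(colSums(ht$counts), n)
    if (!is.null(haplogroups)) {
      hg <- haplogroups[ids]
      out$hg_div <- haplogroup_diversity(table(hg), n)
    }
    m <- sub$seqs
    if (missing_policy == "complete_deletion")
      m <- m[, !apply(m == "N", 2, any), drop = FALSE]
    out$mpd <- mpd(sub, missing_policy = missing_policy)
    out$S <- sum(apply(m, 2, function(col) length(unique(col[col != "N"])) > 1))
    if (n >= 4) {
      td <- tajimas_d(out$S, out$mpd, n)
      out$tajimas_d <- td$D
      if (td$defined && n_sims > 0)
        out$p_tajima <- tajima_significance(td$D, n, out$S, n_sims,
                                            seed = derive_seed(seed %||% 0, pi))
    }
    out
  })
  res <- do.call(rbind, rows)
  class(res) <- c("diversity_summary", class(res))
  res
}
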