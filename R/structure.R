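# Between-population structure: AMOVA variance components and Phi-statistics
# on molecular distances, permutation tests, Mantel, NMDS, shared-haplotype
# similarity, great-circle distances and rank-based group contrasts.

# delta^2 matrix for AMOVA: pairwise site-difference counts, squared by
# default (distance = "plain" uses the raw counts as delta^2, Arlequin-style).
amova_delta2 <- function(alignment, distance = c("squared", "plain"),
                         missing_policy = "complete_deletion") {
  distance <- match.arg(distance)
  d <- pairwise_difference_matrix(alignment, missing_policy)$values
  if (distance == "squared") d^2 else d
}

# Sums of squared deviations from the delta^2 matrix for a grouping factor:
# SSD(stratum) = sum over strata of (sum_{i<j in s} delta2_ij) / n_s.
ssd_within <- function(delta2, f) {
  f <- as.factor(f)
  sum(vapply(levels(f), function(l) {
    idx <- which(f == l)
    if (length(idx) < 2) return(0)
    sum(delta2[idx, idx]) / (2 * length(idx))
  }, 0))
}

# Variance components of the nested (group/population/individual) AMOVA.
# pop, grp: per-individual factors; grp = NULL gives the 2-level design.
amova_components <- function(delta2, pop, grp = NULL) {
  N <- length(pop)
  pop <- as.factor(pop)
  SSD_T <- sum(delta2) / (2 * N)
  SSD_WP <- ssd_within(delta2, pop)
  np <- table(pop)
  P <- nlevels(pop)
  if (is.null(grp)) {
    df_ap <- P - 1; df_wp <- N - P
    SSD_AP <- SSD_T - SSD_WP
    n_prime <- (N - sum(np^2) / N) / df_ap
    s2c <- SSD_WP / df_wp
    s2b <- (SSD_AP / df_ap - s2c) / n_prime
    tot <- s2b + s2c
    list(levels = 2L,
         variance_components = c(among_populations = s2b,
                                 within_populations = s2c),
         percentages = 100 * c(s2b, s2c) / tot,
         phi_stats = c(phi_st = s2b / tot),
         ss = c(among = SSD_AP, within = SSD_WP, total = SSD_T),
         df = c(among = df_ap, within = df_wp))
  } else {
    grp <- as.factor(grp)
    G <- nlevels(grp)
    SSD_WG <- ssd_within(delta2, grp)
    SSD_APWG <- SSD_WG - SSD_WP
    SSD_AG <- SSD_T - SSD_WG
    df_ag <- G - 1; df_ap <- P - G; df_wp <- N - P
    # per-group sums of squared population sizes
    gsum <- vapply(levels(grp), function(g) {
      p_in_g <- pop[grp == g]
      sum(table(droplevels(p_in_g))^2) / length(p_in_g)
    }, 0)
    ng <- table(grp)
    n2_coef <- (sum(gsum) - sum(np^2) / N) / df_ag
    n3_coef <- (N - sum(ng^2) / N) / df_ag
    s2c <- SSD_WP / df_wp
    # each population its own group: the among-population stratum is empty
    s2b <- if (df_ap == 0) 0 else {
      n_coef <- (N - sum(gsum)) / df_ap
      (SSD_APWG / df_ap - s2c) / n_coef
    }
    s2a <- (SSD_AG / df_ag - s2c - n2_coef * s2b) / n3_coef
    tot <- s2a + s2b + s2c
    list(levels = 3L,
         variance_components = c(among_groups = s2a,
                                 among_populations_within_groups = s2b,
                                 within_populations = s2c),
         percentages = 100 * c(s2a, s2b, s2c) / tot,
         phi_stats = c(phi_ct = s2a / tot,
                       phi_sc = s2b / (s2b + s2c),
                       phi_st = (s2a + s2b) / tot),
         ss = c(among_groups = SSD_AG, among_pops = SSD_APWG,
                within = SSD_WP, total = SSD_T),
         df = c(among_groups = df_ag, among_pops = df_ap, within = df_wp))
  }
}

#' Analysis of molecular variance (AMOVA) with permutation tests
#'
#' Nested decomposition of (squared) molecular distances into among-group,
#' among-population-within-group and within-population variance components,
#' with the moment estimators of the classical molecular-variance framework.
#' Negative components are reported as-is and percentages are computed on
#' the signed sum. Permutation schemes per component: within-population
#' variance — individuals permuted among populations across all groups;
#' among-population — individuals permuted among populations within their
#' group; among-group — whole populations permuted among groups.
#'
#' @param alignment a [haplotype_alignment()].
#' @param grouping optional named vector population -> group for the
#'   3-level design; `NULL` gives the 2-level (populations only) design.
#' @param n_perm permutations per component (0 skips p-values).
#' @param seed RNG seed for permutations.
#' @param distance `"squared"` (default) or `"plain"` delta^2 convention.
#' @return An `amova_result` list: `levels`, `variance_components`,
#'   `percentages`, `phi_stats`, `p_values`, `n_permutations`.
#' @export
amova <- function(alignment, grouping = NULL, n_perm = 10000, seed = NULL,
                  distance = c("squared", "plain")) {
  pop <- alignment$populations
  if (length(unique(pop)) < 2) stop("need >= 2 populations")
  grp <- NULL
  if (!is.null(grouping)) {
    miss <- setdiff(unique(pop), names(grouping))
    if (length(miss)) stop("grouping missing populations: ",
                           paste(miss, collapse = ", "))
    if (length(unique(grouping[unique(pop)])) < 2)
      stop("3-level design needs >= 2 groups")
    single <- names(table(grouping[unique(pop)]))[
      table(grouping[unique(pop)]) == 1]
    if (length(single))
      warning("group(s) with a single population: ",
              paste(single, collapse = ", "))
    grp <- as.character(grouping[pop])
  }
  delta2 <- amova_delta2(alignment, distance)
  obs <- amova_components(delta2, pop, grp)
  p <- rep(NA_real_, length(obs$variance_components))
  names(p) <- names(obs$variance_components)
  if (n_perm > 0) {
    p[] <- with_seed(seed, amova_permutation_p(delta2, pop, grp, obs, n_perm))
  }
  structure(c(obs, list(p_values = p, n_permutations = n_perm,
                        distance = match.arg(distance))),
            class = "amova_result")
}

# Permutation p-values (add-one corrected) for each variance component.
amova_permutation_p <- function(delta2, pop, grp, obs, n_perm) {
  N <- length(pop)
  if (is.null(grp)) {
    b <- 0L
    for (r in seq_len(n_perm)) {
      perm <- sample(N)
      comp <- amova_components(delta2, pop[perm], NULL)
      if (comp$variance_components[1] >= obs$variance_components[1])
        b <- b + 1L
    }
    p_b <- (b + 1) / (n_perm + 1)
    c(p_b, p_b)  # 2-level: a single among/within decomposition
  } else {
    hits <- c(a = 0L, b = 0L, c = 0L)
    pops <- unique(pop)
    pop_group <- vapply(pops, function(pp) grp[match(pp, pop)], "")
    for (r in seq_len(n_perm)) {
      # sigma2_c: permute individuals among populations across all groups
      perm <- sample(N)
      comp <- amova_components(delta2, pop[perm], grp[perm])
      if (comp$variance_components[3] <= obs$variance_components[3])
        hits["c"] <- hits["c"] + 1L
      # sigma2_b: permute individuals among populations within groups
      perm2 <- seq_len(N)
      for (g in unique(grp)) {
        idx <- which(grp == g)
        perm2[idx] <- idx[sample(length(idx))]
      }
      comp2 <- amova_components(delta2, pop[perm2], grp)
      if (comp2$variance_components[2] >= obs$variance_components[2])
        hits["b"] <- hits["b"] + 1L
      # sigma2_a: permute whole populations among groups
      gperm <- sample(pop_group)
      names(gperm) <- pops
      comp3 <- amova_components(delta2, pop, as.character(gperm[pop]))
      if (comp3$variance_components[1] >= obs$variance_components[1])
        hits["a"] <- hits["a"] + 1L
    }
    (hits + 1) / (n_perm + 1)
  }
}

#' @export
print.amova_result <- function(x, ...) {
  cat(x$levels, "-level AMOVA (", x$distance, " distances)\n", sep = "")
  df <- data.frame(component = names(x$variance_components),
                   sigma2 = x$variance_components,
                   percent = x$percentages, p = x$p_values)
  print(df, row.names = FALSE)
  cat("Phi:", paste(names(x$phi_stats),
                    formatC(x$phi_stats, digits = 4, format = "f"),
                    sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Pairwise Phi-st matrix with permutation p-values
#'
#' For each population pair, Phi-st from the two-population AMOVA on
#' (squared) pairwise sequence differences; significance by permuting
#' individuals between the two populations.
#'
#' @inheritParams amova
#' @param populations optional subset of population codes.
#' @return list with `phist` (a [distance_matrix()] of kind `phist`) and
#'   `p` matrix. Populations with n < 2 are skipped with a warning (rows NA).
#' @export
phist_pairwise <- function(alignment, populations = NULL, n_perm = 10000,
                           seed = NULL, distance = c("squared", "plain")) {
  distance <- match.arg(distance)
  pop <- alignment$populations
  pops <- populations %||% unique(pop)
  sizes <- table(pop)[pops]
  small <- pops[is.na(sizes) | sizes < 2]
  if (length(small)) {
    warning("population(s) with n < 2 skipped: ", paste(small, collapse = ", "))
  }
  k <- length(pops)
  phist <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  pmat <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  diag(phist) <- 0; diag(pmat) <- NA
  delta2_all <- NULL
  usable <- setdiff(pops, small)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- pops[i]; b <- pops[j]
    if (!(a %in% usable && b %in% usable)) next
    sub <- subset_alignment(alignment, populations = c(a, b))
    delta2 <- amova_delta2(sub, distance)
    f <- sub$populations
    obs <- amova_components(delta2, f, NULL)
    phist[i, j] <- phist[j, i] <- obs$phi_stats["phi_st"]
    if (n_perm > 0) {
      pv <- with_seed(derive_seed(seed %||% 0, i * 10000L + j), {
        b_ <- 0L
        for (r in seq_len(n_perm)) {
          comp <- amova_components(delta2, f[sample(length(f))], NULL)
          if (comp$phi_stats["phi_st"] >= obs$phi_stats["phi_st"])
            b_ <- b_ + 1L
        }
        (b_ + 1) / (n_perm + 1)
      })
      pmat[i, j] <- pmat[j, i] <- pv
    }
  }
  diag(phist) <- ifelse(pops %in% small, NA_real_, 0)
  list(phist = structure(list(labels = pops, values = phist, kind = "phist"),
                         class = "distance_matrix"),
       p = pmat)
}

#' Corrected pairwise difference (net divergence, dA) between populations
#'
#' \eqn{d_A = \pi_{XY} - (\pi_X + \pi_Y)/2}: the mean between-population
#' pairwise difference minus the average of the two within-population means.
#' Can be slightly negative for very similar populations.
#'
#' @param alignment a [haplotype_alignment()].
#' @param pop_i,pop_j population codes (each with n >= 2).
#' @param missing_policy passed to [pairwise_difference_matrix()].
#' @export
corrected_pairwise_difference <- function(alignment, pop_i, pop_j,
                                          missing_policy = "complete_deletion") {
  sub <- subset_alignment(alignment, populations = c(pop_i, pop_j))
  f <- sub$populations
  if (sum(f == pop_i) < 2 || sum(f == pop_j) < 2)
    stop_degenerate("both populations need n >= 2 for dA")
  d <- pairwise_difference_matrix(sub, missing_policy)$values
  ii <- which(f == pop_i); jj <- which(f == pop_j)
  pi_x <- mean(d[ii, ii][upper.tri(d[ii, ii])])
  pi_y <- mean(d[jj, jj][upper.tri(d[jj, jj])])
  pi_xy <- mean(d[ii, jj])
  pi_xy - (pi_x + pi_y) / 2
}

#' Shared-haplotype similarity matrix
#'
#' Entry (i, j) counts distinct haplotypes present (nonzero count) in both
#' populations i and j; `per_pair` divides by the number of distinct
#' haplotypes present in i or j (Jaccard-style normalization).
#'
#' @param haplotype_table from [collapse_haplotypes()].
#' @param normalize `"none"` or `"per_pair"`.
#' @return square numeric matrix, populations x populations.
#' @export
shared_haplotype_matrix <- function(haplotype_table,
                                    normalize = c("none", "per_pair")) {
  normalize <- match.arg(normalize)
  pres <- haplotype_table$counts > 0
  shared <- tcrossprod(pres * 1L)
  if (normalize == "per_pair") {
    tot <- rowSums(pres)
    union <- outer(tot, tot, "+") - shared
    shared <- ifelse(union > 0, shared / union, 0)
  }
  diag(shared) <- if (normalize == "none") rowSums(pres) else 1
  shared
}

#' Great-circle (haversine) distance in km
#'
#' Haversine distance on a sphere of radius 6371.0088 km.
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees (vectorized).
#' @export
great_circle_distance <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371.0088) # km
}

#' Geographic distance matrix from metadata coordinates
#' @param metadata data.frame with `code`, `latitude`, `longitude`.
#' @return a [distance_matrix()] of kind `geographic` (km).
#' @export
geographic_distance_matrix <- function(metadata) {
  k <- nrow(metadata)
  m <- matrix(0, k, k)
  for (i in seq_len(k)) {
    m[i, ] <- great_circle_distance(metadata$latitude[i], metadata$longitude[i],
                                    metadata$latitude, metadata$longitude)
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  distance_matrix(m, labels = metadata$code, kind = "geographic")
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the off-diagonal upper triangles; significance
#' by jointly permuting the row/column order of one matrix, with add-one
#' correction.
#'
#' @param matrix_a,matrix_b [distance_matrix()] objects or plain symmetric
#'   matrices with identical labels/order (n >= 4).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param tail `"one_sided_positive"` or `"two_sided"`.
#' @return list `r`, `p`, `n_permutations`.
#' @export
mantel <- function(matrix_a, matrix_b, n_perm = 9999, seed = NULL,
                   tail = c("one_sided_positive", "two_sided")) {
  tail <- match.arg(tail)
  a <- if (inherits(matrix_a, "distance_matrix")) matrix_a$values else matrix_a
  b <- if (inherits(matrix_b, "distance_matrix")) matrix_b$values else matrix_b
  if (!identical(dim(a), dim(b))) stop("matrices must have identical dimension")
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b)))
    stop("matrices must share labels in the same order")
  n <- nrow(a)
  if (n < 4) stop("Mantel test needs n >= 4")
  ut <- upper.tri(a)
  va <- a[ut]
  if (stats::sd(va) == 0 || stats::sd(b[ut]) == 0)
    stop("undefined Mantel r for a constant matrix")
  r_obs <- stats::cor(va, b[ut])
  p <- with_seed(seed, {
    hits <- 0L
    for (k in seq_len(n_perm)) {
      o <- sample(n)
      r_p <- stats::cor(va, b[o, o][ut])
      ok <- if (tail == "one_sided_positive") r_p >= r_obs
            else abs(r_p) >= abs(r_obs)
      if (ok) hits <- hits + 1L
    }
    (hits + 1) / (n_perm + 1)
  })
  list(r = r_obs, p = p, n_permutations = n_perm)
}

#' Nonmetric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 NMDS (monotone regression with iterative majorization,
#' via the global-model engine of \pkg{vegan}), best configuration over
#' `n_restarts` random starts plus one metric (classical-scaling) start.
#' Negative input distances (possible for Phi-st) are clamped to zero with
#' a warning. Coordinates are centered at the origin.
#'
#' @param distance_matrix a [distance_matrix()] or symmetric matrix.
#' @param k embedding dimension.
#' @param n_restarts random restarts.
#' @param max_iter,tol convergence controls.
#' @param seed RNG seed (configuration is deterministic given seed).
#' @return list `coordinates`, `stress` (Kruskal stress-1, proportion),
#'   `converged`, `seed`.
#' @export
nmds <- function(distance_matrix, k = 2, n_restarts = 20, max_iter = 500,
                 tol = 1e-7, seed = NULL) {
  v <- if (inherits(distance_matrix, "distance_matrix")) distance_matrix$values
       else as.matrix(distance_matrix)
  if (any(v < 0)) {
    warning("negative distances clamped to 0")
    v[v < 0] <- 0
  }
  d <- stats::as.dist(v)
  with_seed(seed %||% 1L, {
    best <- NULL
    for (r in seq_len(max(1L, n_restarts))) {
      init <- if (r == 1L) {
        co <- suppressWarnings(stats::cmdscale(d, k = k))
        if (ncol(co) < k) cbind(co, matrix(0, nrow(co), k - ncol(co))) else co
      } else matrix(stats::rnorm(nrow(v) * k), ncol = k)
      fit <- vegan::monoMDS(d, y = init, k = k, model = "global",
                            maxit = max_iter, smin = 1e-8, sratmax = 1 - tol)
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
    co <- scale(best$points, center = TRUE, scale = FALSE)
    attr(co, "scaled:center") <- NULL
    dimnames(co) <- list(rownames(v), paste0("MDS", seq_len(k)))
    list(coordinates = co, stress = best$stress,
         converged = best$iters < max_iter, seed = seed)
  })
}

#' Mann-Whitney U contrast between two groups of values
#'
#' U statistic (wins of group 1, ties counted 1/2), tie-corrected normal Z,
#' and two-sided p. When `n1 * n2 <= 400` and there are no ties, the exact
#' null distribution of U is used for p; the Z value is always reported
#' from the tie-corrected normal approximation.
#'
#' @param values_group1,values_group2 numeric vectors (nonempty).
#' @return list `U`, `Z`, `p`, `method`.
#' @export
rank_contrast <- function(values_group1, values_group2) {
  x <- values_group1[!is.na(values_group1)]
  y <- values_group2[!is.na(values_group2)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be nonempty")
  all_v <- c(x, y)
  r <- rank(all_v)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- table(all_v)
  if (all(all_v == all_v[1]))
    return(list(U = U, Z = 0, p = 1, method = "degenerate"))
  tie_corr <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_corr)
  Z <- (U - n1 * n2 / 2) / sqrt(sigma2)
  has_ties <- any(ties > 1)
  if (n1 * n2 <= 400 && !has_ties) {
    p <- 2 * min(stats::pwilcox(U, n1, n2),
                 1 - stats::pwilcox(U - 1, n1, n2))
    p <- min(p, 1)
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(Z))
    method <- "normal_tie_corrected"
  }
  list(U = U, Z = Z, p = p, method = method)
}

#' Residence-pattern contrast report
#'
#' Rank contrasts (patrilocal vs matrilocal) of within-population diversity
#' (h, MPD, haplogroup diversity) and of between-population differentiation
#' (off-diagonal Phi-st entries within each residence class), with
#' direction-of-effect flags. Under patrilocality, lower within-population
#' diversity and higher among-population differentiation are expected for a
#' paternally inherited locus.
#'
#' @param summaries output of [population_summaries()].
#' @param phist a [distance_matrix()] of Phi-st values (labels =
#'   population codes).
#' @param metadata metadata data.frame with `code` and `residence`.
#' @return data.frame: statistic, n per class, U, Z, p, direction.
#' @export
residence_contrast_report <- function(summaries, phist, metadata) {
  res <- stats::setNames(metadata$residence, metadata$code)
  pops <- summaries$population
  known <- pops[res[pops] %in% c("patrilocal", "matrilocal")]
  dropped <- setdiff(pops, known)
  if (length(dropped))
    warning("populations without patrilocal/matrilocal label excluded: ",
            paste(dropped, collapse = ", "))
  pat <- known[res[known] == "patrilocal"]
  mat <- known[res[known] == "matrilocal"]
  if (!length(pat) || !length(mat))
    stop("need at least one patrilocal and one matrilocal population")
  row_for <- function(stat, v_pat, v_mat) {
    rc <- rank_contrast(v_pat, v_mat)
    data.frame(statistic = stat, n_patrilocal = sum(!is.na(v_pat)),
               n_matrilocal = sum(!is.na(v_mat)), U = rc$U, Z = rc$Z,
               p = rc$p,
               direction = ifelse(mean(v_pat, na.rm = TRUE) <
                                  mean(v_mat, na.rm = TRUE),
                                  "patrilocal_lower", "patrilocal_higher"))
  }
  pick <- function(col, who) summaries[[col]][match(who, summaries$population)]
  out <- rbind(row_for("h", pick("h", pat), pick("h", mat)),
               row_for("mpd", pick("mpd", pat), pick("mpd", mat)))
  if (any(!is.na(summaries$hg_div)))
    out <- rbind(out, row_for("hg_div", pick("hg_div", pat),
                              pick("hg_div", mat)))
  pv <- if (inherits(phist, "distance_matrix")) phist$values else phist
  offdiag <- function(who) {
    who <- intersect(who, rownames(pv))
    if (length(who) < 2) return(NA_real_)
    m <- pv[who, who]
    m[upper.tri(m)]
  }
  fp <- offdiag(pat); fm <- offdiag(mat)
  if (!all(is.na(fp)) && !all(is.na(fm)))
    out <- rbind(out, row_for("phist_within_class", fp, fm))
  out
}
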