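test_that("Phi-st is 1 for fixed differences and ~0 for a random split", {
  al <- toy_alignment(c(A = "AAAA", A = "AAAA", A = "AAAA",
                        B = "TTTT", B = "TTTT", B = "TTTT"))
  ph <- phist_pairwise(al, n_perm = 99, seed = 1)
  expect_equal(ph$phist$values["A", "B"], 1.0)
  expect_lt(ph$p["A", "B"], 0.2)  # best attainable with 6 samples
  # one panmictic pool split arbitrarily in two
  set.seed(5)
  seqs <- replicate(16, paste(sample(c("A", "T"), 20, TRUE), collapse = ""))
  names(seqs) <- rep(c("X", "Y"), 8)
  ph2 <- phist_pairwise(toy_alignment(seqs), n_perm = 199, seed = 2)
  expect_lt(abs(ph2$phist$values["X", "Y"]), 0.15)
  expect_gt(ph2$p["X", "Y"], 0.05)
})

test_that("pairwise Phi-st equals the brute-force variance-component oracle", {
  set.seed(9)
  seqs <- replicate(8, paste(sample(c("A", "C", "G", "T"), 15, TRUE),
                             collapse = ""))
  names(seqs) <- rep(c("P1", "P2"), each = 4)
  al <- toy_alignment(seqs)
  ph <- phist_pairwise(al, n_perm = 0)
  d <- pairwise_difference_matrix(al)$values
  orc <- oracle_amova(d, names(seqs), squared = TRUE)
  expect_equal(ph$phist$values["P1", "P2"], unname(orc$phi_st),
               tolerance = 1e-10)
  # 2-level amova on the same two populations reproduces the entry
  am <- amova(al, n_perm = 0)
  expect_equal(unname(am$phi_stats["phi_st"]),
               ph$phist$values["P1", "P2"], tolerance = 1e-12)
})

test_that("populations with n < 2 are skipped with a warning", {
  al <- toy_alignment(c(A = "AAAA", A = "AATA", B = "TTTT", B = "TTAT",
                        C = "ACGT"))
  expect_warning(ph <- phist_pairwise(al, n_perm = 0), "skipped")
  expect_true(is.na(ph$phist$values["A", "C"]))
  expect_false(is.na(ph$phist$values["A", "B"]))
})

test_that("corrected pairwise difference dA matches brute-force means", {
  # identical (monomorphic) populations -> 0 exactly
  al <- toy_alignment(c(X = "AATT", X = "AATT", Y = "AATT", Y = "AATT"))
  expect_lt(abs(corrected_pairwise_difference(al, "X", "Y")), 1e-12)
  # two fixed haplotypes k = 3 sites apart -> dA = 3
  al2 <- toy_alignment(c(X = "AAAA", X = "AAAA", Y = "TTTA", Y = "TTTA"))
  expect_equal(corrected_pairwise_difference(al2, "X", "Y"), 3)
  # toy 3+3 alignment vs direct computation of the three mean terms
  sx <- c("AAAAAA", "AATAAA", "AATTCA")
  sy <- c("GGAAAA", "GGTAAA", "GGAATA")
  al3 <- toy_alignment(stats::setNames(c(sx, sy), rep(c("X", "Y"), each = 3)))
  expect_equal(corrected_pairwise_difference(al3, "X", "Y"),
               oracle_da(sx, sy), tolerance = 1e-10)
  expect_error(corrected_pairwise_difference(
    toy_alignment(c(X = "AA", Y = "AT", Y = "AT")), "X", "Y"), "n >= 2")
})

test_that("3-level AMOVA matches the explicit sums-of-squares oracle", {
  set.seed(21)
  seqs <- replicate(16, paste(sample(c("A", "G"), 25, TRUE), collapse = ""))
  pops <- rep(c("P1", "P2", "P3", "P4"), each = 4)
  names(seqs) <- pops
  al <- toy_alignment(seqs)
  grouping <- c(P1 = "G1", P2 = "G1", P3 = "G2", P4 = "G2")
  am <- amova(al, grouping = grouping, n_perm = 0)
  d <- pairwise_difference_matrix(al)$values
  orc <- oracle_amova(d, pops, grp = c("G1", "G2")[(as.integer(
    factor(pops)) + 1) %/% 2], squared = TRUE)
  expect_equal(unname(am$variance_components), orc$components,
               tolerance = 1e-10)
  expect_equal(unname(am$percentages), orc$percentages, tolerance = 1e-10)
  expect_equal(unname(am$phi_stats), unname(orc$phi), tolerance = 1e-10)
  expect_equal(sum(am$percentages), 100, tolerance = 1e-9)
  # Phi-st algebra: (s2a + s2b) / total
  v <- am$variance_components
  expect_equal(unname(am$phi_stats["phi_st"]),
               unname((v[1] + v[2]) / sum(v)), tolerance = 1e-12)
})

test_that("AMOVA SS decomposition agrees with an independent partitioning", {
  set.seed(33)
  seqs <- replicate(12, paste(sample(c("A", "G", "T"), 30, TRUE),
                              collapse = ""))
  pops <- rep(c("P1", "P2", "P3"), each = 4)
  names(seqs) <- pops
  al <- toy_alignment(seqs)
  am <- amova(al, n_perm = 0)
  d <- pairwise_difference_matrix(al)$values
  ad <- vegan::adonis2(as.dist(d) ~ pop, data = data.frame(pop = pops),
                       permutations = 0)
  expect_equal(unname(am$ss["among"]), ad$SumOfSqs[1], tolerance = 1e-8)
  expect_equal(unname(am$ss["within"]), ad$SumOfSqs[2], tolerance = 1e-8)
})

test_that("negative variance components are retained, not truncated", {
  # nearly identical populations inside one group produce a negative
  # among-population component; percentages still sum to 100
  set.seed(4)
  base <- sample(c("A", "G"), 30, TRUE)
  mk <- function() paste(ifelse(runif(30) < 0.1,
                                sample(c("A", "G"), 30, TRUE), base),
                         collapse = "")
  seqs <- replicate(16, mk())
  names(seqs) <- rep(c("P1", "P2", "P3", "P4"), each = 4)
  al <- toy_alignment(seqs)
  grouping <- c(P1 = "G1", P2 = "G1", P3 = "G2", P4 = "G2")
  am <- amova(al, grouping = grouping, n_perm = 0)
  expect_equal(sum(am$percentages), 100, tolerance = 1e-9)
  # at least verify the machinery can emit negatives on some seed
  found_negative <- FALSE
  for (s in 1:10) {
    set.seed(s)
    seqs2 <- replicate(12, mk())
    names(seqs2) <- rep(c("P1", "P2", "P3"), each = 4)
    am2 <- amova(toy_alignment(seqs2),
                 grouping = c(P1 = "G1", P2 = "G2", P3 = "G2"), n_perm = 0)
    if (any(am2$variance_components < 0)) { found_negative <- TRUE; break }
  }
  expect_true(found_negative)
})

test_that("panmixia gives ~100% within-population variance", {
  set.seed(8)
  seqs <- replicate(40, paste(sample(c("A", "T"), 80, TRUE), collapse = ""))
  names(seqs) <- rep(paste0("P", 1:4), each = 10)
  am <- amova(toy_alignment(seqs), n_perm = 0)
  expect_gt(am$percentages[2], 92)
  expect_lt(abs(am$percentages[1]), 8)
})

test_that("groups == populations zeroes the within-group stratum", {
  set.seed(13)
  seqs <- replicate(12, paste(sample(c("A", "C"), 20, TRUE), collapse = ""))
  names(seqs) <- rep(c("P1", "P2", "P3"), each = 4)
  al <- toy_alignment(seqs)
  am <- amova(al, grouping = c(P1 = "P1", P2 = "P2", P3 = "P3"), n_perm = 0)
  expect_equal(unname(am$variance_components[2]), 0, tolerance = 1e-10)
})

test_that("shared haplotype matrices count and normalize correctly", {
  al <- toy_alignment(c(P1 = "AAT", P1 = "GGG", P2 = "CCC", P2 = "CCA"))
  ht <- collapse_haplotypes(al)
  sh <- shared_haplotype_matrix(ht)
  expect_equal(sh["P1", "P2"], 0)
  al2 <- toy_alignment(c(P1 = "AAT", P1 = "AAT", P2 = "AAT"))
  sh2 <- shared_haplotype_matrix(collapse_haplotypes(al2))
  expect_equal(sh2["P1", "P2"], 1)
  expect_equal(shared_haplotype_matrix(collapse_haplotypes(al2),
                                       "per_pair")["P1", "P2"], 1.0)
  # three-way shared haplotype plus private ones: hand count
  al3 <- toy_alignment(c(P1 = "AAA", P1 = "TTT", P2 = "AAA", P2 = "GGG",
                         P3 = "AAA", P3 = "CCC"))
  sh3 <- shared_haplotype_matrix(collapse_haplotypes(al3))
  expect_true(all(sh3[upper.tri(sh3)] == 1))
  pp <- shared_haplotype_matrix(collapse_haplotypes(al3), "per_pair")
  expect_equal(pp["P1", "P2"], 1 / 3)   # union {AAA,TTT,GGG}
})

test_that("great-circle distances match spherical geometry", {
  expect_equal(great_circle_distance(10, 20, 10, 20), 0)
  expect_equal(great_circle_distance(0, 0, 0, 180), pi * 6371.0088,
               tolerance = 1e-6)
  expect_equal(great_circle_distance(0, 0, 0, 1), pi * 6371.0088 / 180,
               tolerance = 1e-6)
  md <- data.frame(code = c("a", "b"), latitude = c(0, 0),
                   longitude = c(0, 1))
  g <- geographic_distance_matrix(md)
  expect_equal(g$values["a", "b"], pi * 6371.0088 / 180, tolerance = 1e-6)
})

test_that("Mantel r matches direct correlation and is affine-invariant", {
  set.seed(17)
  a <- as.matrix(dist(matrix(rnorm(10), 5)))
  b <- 2 * a + 3; diag(b) <- 0
  expect_equal(mantel(a, b, n_perm = 99, seed = 1)$r, 1.0, tolerance = 1e-12)
  bneg <- max(a) - a; diag(bneg) <- 0
  expect_equal(mantel(a, bneg, n_perm = 99, seed = 1)$r, -1.0,
               tolerance = 1e-12)
  # agreement with an independent implementation on a random pair
  b2 <- as.matrix(dist(matrix(rnorm(10), 5)))
  r_pkg <- mantel(a, b2, n_perm = 99, seed = 1)$r
  r_vegan <- vegan::mantel(as.dist(a), as.dist(b2), permutations = 0)$statistic
  expect_equal(r_pkg, r_vegan, tolerance = 1e-10)
  expect_error(mantel(a * 0, b2, n_perm = 9), "constant")
})

test_that("Mantel p is stable across seeds at high permutation counts", {
  set.seed(23)
  x <- matrix(rnorm(14), 7)
  a <- as.matrix(dist(x))
  b <- as.matrix(dist(x + rnorm(14, sd = 0.8)))
  p1 <- mantel(a, b, n_perm = 9999, seed = 1)$p
  p2 <- mantel(a, b, n_perm = 9999, seed = 2)$p
  expect_lt(abs(p1 - p2), 0.01)
})

test_that("NMDS embeds exact configurations at ~zero stress", {
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  fit <- nmds(d3, k = 2, n_restarts = 5, seed = 1)
  expect_lt(fit$stress, 1e-6)
  expect_equal(colMeans(fit$coordinates), c(MDS1 = 0, MDS2 = 0),
               tolerance = 1e-9)
  set.seed(2)
  pts <- matrix(rnorm(16), 8, 2)
  fit2 <- nmds(as.matrix(dist(pts)), k = 2, n_restarts = 10, seed = 3)
  expect_lt(fit2$stress, 1e-4)
  # stress is nonincreasing in k (best of restarts)
  set.seed(3)
  dr <- as.matrix(dist(matrix(rnorm(30), 10, 3)))
  s2 <- nmds(dr, k = 2, n_restarts = 10, seed = 4)$stress
  s3 <- nmds(dr, k = 3, n_restarts = 10, seed = 4)$stress
  expect_lte(s3, s2 + 1e-8)
  # negative entries are clamped with a warning
  dneg <- dr; dneg[1, 2] <- dneg[2, 1] <- -0.01
  expect_warning(nmds(dneg, k = 2, n_restarts = 2, seed = 5), "clamped")
  # deterministic given seed
  f1 <- nmds(dr, k = 2, n_restarts = 5, seed = 6)
  f2 <- nmds(dr, k = 2, n_restarts = 5, seed = 6)
  expect_identical(f1$coordinates, f2$coordinates)
})

test_that("rank contrasts match enumeration and wilcox.test", {
  same <- rank_contrast(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$p, 1, tolerance = 1e-12)
  sep <- rank_contrast(c(1, 2, 3, 4), c(10, 11, 12, 13))
  expect_true(sep$U %in% c(0, 16))
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  rc <- rank_contrast(x, y)
  expect_equal(rc$U, oracle_u(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  expect_equal(rc$U, unname(wt$statistic))
  # tie-corrected Z and invariants on random data
  set.seed(31)
  for (i in 1:10) {
    x <- sample(1:8, 6, TRUE); y <- sample(1:8, 5, TRUE)
    rc <- rank_contrast(x, y)
    expect_equal(rc$U, oracle_u(x, y))
    expect_gte(rc$U, 0); expect_lte(rc$U, length(x) * length(y))
    # U_A + U_B = n1 n2
    expect_equal(rc$U + rank_contrast(y, x)$U, length(x) * length(y))
  }
  # exact p agrees with wilcox.test exact path when there are no ties
  x <- c(1.1, 2.2, 3.3, 4.4); y <- c(0.5, 2.8, 5.1)
  expect_equal(rank_contrast(x, y)$p,
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)
  deg <- rank_contrast(c(2, 2), c(2, 2, 2))
  expect_equal(deg$Z, 0); expect_equal(deg$p, 1)
})

test_that("residence contrast report flags construction direction", {
  sm <- data.frame(population = paste0("P", 1:6),
                   n = 10, n_haplotypes = 5,
                   h = c(0.2, 0.3, 0.25, 0.8, 0.9, 0.85),
                   hg_div = NA_real_,
                   mpd = c(1, 2, 1.5, 8, 9, 8.5),
                   S = 5, tajimas_d = 0, p_tajima = 0.5)
  md <- data.frame(code = paste0("P", 1:6),
                   residence = rep(c("patrilocal", "matrilocal"), each = 3))
  ph <- matrix(0.1, 6, 6, dimnames = list(md$code, md$code)); diag(ph) <- 0
  ph[1:3, 1:3] <- 0.5; diag(ph) <- 0
  rep_ <- residence_contrast_report(sm, ph, md)
  expect_equal(rep_$direction[rep_$statistic == "h"], "patrilocal_lower")
  expect_equal(rep_$direction[rep_$statistic == "phist_within_class"],
               "patrilocal_higher")
  # identical classes -> p = 1
  sm2 <- sm; sm2$h <- 0.5; sm2$mpd <- 2
  ph2 <- matrix(0.2, 6, 6, dimnames = list(md$code, md$code)); diag(ph2) <- 0
  rep2 <- residence_contrast_report(sm2, ph2, md)
  expect_true(all(rep2$p == 1))
  # one class only -> error
  md3 <- md; md3$residence <- "patrilocal"
  expect_error(residence_contrast_report(sm, ph, md3), "at least one")
  md4 <- md; md4$residence[4] <- "unknown"
  expect_warning(residence_contrast_report(sm, ph, md4), "excluded")
})
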