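test_that("prior sampling respects bounds and is reproducible", {
  mod <- demographic_model("demic",
                           size_priors = list(AA = c(1000, 1000),
                                              DAI = c(1e3, 1e5),
                                              TARGET = c(1e3, 1e5)))
  d <- sample_prior(mod, seed = 1)
  expect_equal(unname(d$Ne["AA"]), 1000)   # degenerate prior
  draws <- replicate(500, sample_prior(mod)$Ne["DAI"])
  expect_gte(min(draws), 1e3)
  expect_lte(max(draws), 1e5)
  expect_identical(sample_prior(mod, seed = 7), sample_prior(mod, seed = 7))
  cm <- demographic_model("continuous_migration")
  expect_true(!is.na(sample_prior(cm, seed = 1)$m))
  expect_true(is.na(sample_prior(mod, seed = 1)$m))
})

test_that("model construction validates times, priors and sample sizes", {
  expect_error(demographic_model("demic", t_target_years = 5000,
                                 t_root_years = 4500))
  expect_error(demographic_model("demic",
                                 size_priors = list(AA = c(-1, 10),
                                                    DAI = c(1, 2),
                                                    TARGET = c(1, 2))),
               "size prior")
  expect_error(demographic_model("continuous_migration",
                                 migration_prior = c(0.5, 1.5)),
               "migration prior")
})

test_that("single-deme genealogies match analytic coalescent expectations", {
  Ne <- 500
  tm2 <- vapply(1:800, function(i) {
    set.seed(i)
    msyabc:::sim_genealogy_engine(c(D = 2L), Ne)$tmrca
  }, 0)
  se <- sd(tm2) / sqrt(length(tm2))
  expect_lt(abs(mean(tm2) - Ne), 3 * se)   # E[T2] = N generations (haploid)
  tm20 <- vapply(1:800, function(i) {
    set.seed(1000 + i)
    msyabc:::sim_genealogy_engine(c(D = 20L), Ne)$tmrca
  }, 0)
  se20 <- sd(tm20) / sqrt(length(tm20))
  expect_lt(abs(mean(tm20) - 2 * Ne * (1 - 1 / 20)), 3 * se20)
})

test_that("scenario structure controls where and when lineages move", {
  mod <- demographic_model("demic", sample_sizes = c(AA = 5, DAI = 5,
                                                     TARGET = 5))
  for (i in 1:20) {
    gen <- simulate_genealogy(mod, sample_prior(mod, seed = i), seed = 100 + i)
    expect_equal(gen$n_migrations, 0L)   # no migration without the cm scenario
  }
  cm <- demographic_model("continuous_migration",
                          migration_prior = c(5e-3, 1e-2),
                          sample_sizes = c(AA = 5, DAI = 5, TARGET = 5))
  t_target_gen <- cm$t_target_years / cm$generation_time_years
  any_mig <- FALSE
  for (i in 1:30) {
    gen <- simulate_genealogy(cm, sample_prior(cm, seed = i), seed = 200 + i)
    if (gen$n_migrations > 0) {
      any_mig <- TRUE
      expect_true(all(gen$migration_times <= t_target_gen + 1e-9))
    }
  }
  expect_true(any_mig)
})

test_that("mutation dropping matches Watterson and SFS expectations", {
  # theta = 2 * Ne * mu_locus_per_gen = 10 with Ne = 500
  Ne <- 500; n <- 10; theta <- 10
  rate <- theta / (2 * Ne)
  S <- numeric(600); xi <- matrix(0, 600, n - 1)
  for (i in 1:600) {
    set.seed(i)
    gen <- msyabc:::sim_genealogy_engine(c(D = n), Ne)
    bs <- msyabc:::branch_stats(gen)
    s <- rpois(1, sum(bs$len) * rate)
    S[i] <- s
    if (s > 0) {
      br <- sample.int(length(bs$len), s, TRUE, bs$len)
      xi[i, ] <- tabulate(bs$desc[br, 1], n - 1)
    }
  }
  expect_lt(abs(mean(S) - theta * sum(1 / (1:(n - 1)))),
            3 * sd(S) / sqrt(length(S)))
  for (k in 1:3)
    expect_lt(abs(mean(xi[, k]) - theta / k),
              3 * sd(xi[, k]) / sqrt(nrow(xi)))
})

test_that("zero mutation rate yields an empty alignment and zero SFS", {
  mod <- demographic_model("demic", sample_sizes = c(AA = 3, DAI = 3,
                                                     TARGET = 3))
  gen <- simulate_genealogy(mod, sample_prior(mod, seed = 1), seed = 2)
  dm <- drop_mutations(gen, mu = 0, L = 1000, g = 30, seed = 3)
  expect_equal(ncol(dm$alignment$seqs), 0)
  expect_equal(dm$sfs$total_S, 0L)
  expect_true(all(unlist(dm$sfs$xi) == 0))
})

test_that("alignment and SFS from one genealogy are mutually consistent", {
  mod <- demographic_model("demic", locus_length_bp = 50000,
                           sample_sizes = c(AA = 6, DAI = 5, TARGET = 4))
  gen <- simulate_genealogy(mod, sample_prior(mod, seed = 3), seed = 4)
  dm <- drop_mutations(gen, mod$mutation_rate_per_bp_year,
                       mod$locus_length_bp, 30, seed = 5)
  expect_equal(dm$sfs$total_S, ncol(dm$alignment$seqs))
  o <- observed_sfs(dm$alignment, n_per_deme = c(AA = 6, DAI = 5, TARGET = 4))
  expect_equal(as_summary_vector(o), as_summary_vector(dm$sfs))
})

test_that("observed SFS excludes fixed classes and tallies by hand", {
  # 6 samples in two demes of 3; sites listed explicitly
  m <- matrix(c("1", "1", "1", "0", "0", "0",   # fixed derived in deme A
                "1", "0", "0", "0", "0", "0",   # xi_1 in A
                "1", "1", "0", "1", "0", "0",   # xi_2 in A, xi_1 in B
                "1", "1", "1", "1", "1", "1"),  # fixed overall: dropped
              nrow = 6,
              dimnames = list(paste0("s", 1:6), NULL))
  al <- haplotype_alignment(m, stats::setNames(rep(c("A", "B"), each = 3),
                                               paste0("s", 1:6)),
                            10, ancestral = rep("0", 4))
  sfs <- observed_sfs(al, n_per_deme = c(A = 3, B = 3))
  expect_equal(unname(sfs$xi$A), c(1, 1))       # xi_1 = 1, xi_2 = 1
  expect_equal(unname(sfs$xi$B), c(1, 0))
  expect_equal(sfs$total_S, 3L)                 # overall-fixed site dropped
  expect_error(observed_sfs(al, n_per_deme = c(A = 4, B = 3)), "smaller")
  # unpolarized alignments are rejected
  al2 <- haplotype_alignment(m, stats::setNames(rep(c("A", "B"), each = 3),
                                                paste0("s", 1:6)), 10)
  expect_error(observed_sfs(al2, n_per_deme = c(A = 3, B = 3)), "polarized")
})

test_that("batch simulation is reproducible row-wise and in full", {
  mod <- demographic_model("demic", locus_length_bp = 20000,
                           sample_sizes = c(AA = 5, DAI = 5, TARGET = 5))
  b1 <- simulate_sfs_batch(mod, 10, base_seed = 42)
  b2 <- simulate_sfs_batch(mod, 10, base_seed = 42)
  expect_identical(b1$summaries, b2$summaries)
  expect_identical(b1$params, b2$params)
  # row i depends only on base_seed + i - 1
  b3 <- simulate_sfs_batch(mod, 3, base_seed = 47)
  expect_identical(b3$summaries[1, ], b1$summaries[6, ])
  # degenerate priors share parameters but differ in SFS
  modd <- demographic_model("demic",
                            size_priors = list(AA = c(5000, 5000),
                                               DAI = c(5000, 5000),
                                               TARGET = c(5000, 5000)),
                            locus_length_bp = 20000,
                            sample_sizes = c(AA = 5, DAI = 5, TARGET = 5))
  bd <- simulate_sfs_batch(modd, 5, base_seed = 1)
  expect_equal(nrow(unique(bd$params)), 1)
  expect_gt(nrow(unique(bd$summaries)), 1)
})

test_that("exchangeability: per-deme SFS ignores sample ordering", {
  mod <- demographic_model("demic", locus_length_bp = 50000,
                           sample_sizes = c(AA = 6, DAI = 4, TARGET = 4))
  gen <- simulate_genealogy(mod, sample_prior(mod, seed = 9), seed = 10)
  dm <- drop_mutations(gen, mod$mutation_rate_per_bp_year,
                       mod$locus_length_bp, 30, seed = 11)
  al <- dm$alignment
  perm <- sample(rownames(al$seqs))
  al2 <- haplotype_alignment(al$seqs[perm, ], al$populations[perm],
                             al$locus_length_bp, ancestral = al$ancestral)
  expect_equal(as_summary_vector(observed_sfs(
    al2, n_per_deme = c(AA = 6, DAI = 4, TARGET = 4))),
    as_summary_vector(dm$sfs))
})

test_that("total branch length scales linearly with Ne", {
  grid <- c(200, 400, 800, 1600)
  means <- vapply(grid, function(Ne) {
    mean(vapply(1:400, function(i) {
      set.seed(Ne + i)
      sum(msyabc:::branch_stats(
        msyabc:::sim_genealogy_engine(c(D = 10L), Ne))$len)
    }, 0))
  }, 0)
  fit <- stats::lm(means ~ grid)
  slope <- unname(stats::coef(fit)[2])
  expect_lt(abs(slope - 2 * sum(1 / (1:9))) / (2 * sum(1 / (1:9))), 0.05)
})
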