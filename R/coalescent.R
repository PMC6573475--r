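# Structured Hudson coalescent on a single non-recombining haploid locus.
#
# The engine runs backwards in time in units of generations over a set of
# demes with haploid sizes Ne_d. Competing exponential events:
#   coalescence within deme d at rate k_d (k_d - 1) / (2 Ne_d),
#   migration of one lineage from d to e at rate k_d * m[d, e].
# Fixed demographic events (deme mergers, migration-matrix changes) occur
# at predetermined times; mergers relocate all lineages of one deme into
# another. The process is absorbing: after the last merger a single deme
# with positive coalescence rate remains.

#' Demographic model for the three-deme scenario comparison
#'
#' Three demes (AA, DAI, TARGET). All scenarios share an initial AA-DAI
#' split at `t_root_years`; the TARGET deme originates at `t_target_years`
#' from DAI (`demic`, `continuous_migration`) or from AA (`cultural`).
#' `continuous_migration` additionally allows symmetric TARGET-AA migration
#' at per-lineage, per-generation rate m, active only more recently than
#' the TARGET origin. Sizes are uniform through time within each branch;
#' the ancestral deme carries AA's size, and the DAI-parent branch DAI's
#' size. Priors are uniform.
#'
#' @param scenario `"demic"`, `"cultural"` or `"continuous_migration"`.
#' @param t_target_years,t_root_years fixed split times in years
#'   (0 < t_target < t_root).
#' @param generation_time_years generation time g.
#' @param size_priors named list AA/DAI/TARGET of c(lower, upper) bounds on
#'   haploid effective size.
#' @param migration_prior c(lower, upper) bounds on m
#'   (continuous_migration only).
#' @param mutation_rate_per_bp_year mutation rate mu.
#' @param locus_length_bp surveyed length L in bp.
#' @param sample_sizes named integer vector AA/DAI/TARGET.
#' @return object of class `demographic_model`.
#' @export
demographic_model <- function(scenario = c("demic", "cultural",
                                           "continuous_migration"),
                              t_target_years = 2000, t_root_years = 4500,
                              generation_time_years = 30,
                              size_priors = list(AA = c(1e3, 1e5),
                                                 DAI = c(1e3, 1e5),
                                                 TARGET = c(1e3, 1e5)),
                              migration_prior = c(1e-5, 1e-2),
                              mutation_rate_per_bp_year = 8.71e-10,
                              locus_length_bp = 2364048,
                              sample_sizes = c(AA = 10, DAI = 10, TARGET = 10)) {
  scenario <- match.arg(scenario)
  stopifnot(t_target_years > 0, t_root_years > t_target_years,
            generation_time_years > 0, mutation_rate_per_bp_year >= 0,
            locus_length_bp > 0)
  demes <- c("AA", "DAI", "TARGET")
  if (!all(demes %in% names(size_priors)))
    stop("size_priors must name AA, DAI, TARGET")
  for (d in demes) {
    b <- size_priors[[d]]
    if (length(b) != 2 || any(b <= 0) || b[1] > b[2])
      stop("invalid size prior for ", d)
  }
  if (scenario == "continuous_migration") {
    if (any(migration_prior < 0) || any(migration_prior >= 1) ||
        migration_prior[1] > migration_prior[2])
      stop("migration prior must satisfy 0 <= lower <= upper < 1")
  }
  sample_sizes <- sample_sizes[demes]
  if (any(is.na(sample_sizes)) || sum(sample_sizes) < 2)
    stop("sample_sizes must name AA, DAI, TARGET with total >= 2")
  structure(list(scenario = scenario, demes = demes,
                 t_target_years = t_target_years,
                 t_root_years = t_root_years,
                 generation_time_years = generation_time_years,
                 size_priors = size_priors,
                 migration_prior = migration_prior,
                 mutation_rate_per_bp_year = mutation_rate_per_bp_year,
                 locus_length_bp = locus_length_bp,
                 sample_sizes = sample_sizes),
            class = "demographic_model")
}

#' Draw model parameters from their priors
#'
#' Independent uniform draws of the per-deme effective sizes and (for the
#' continuous-migration scenario) the migration rate.
#'
#' @param model a [demographic_model()].
#' @param seed RNG seed (NULL uses the current stream).
#' @return list `Ne` (named), `m` (or NA), `seed`.
#' @export
sample_prior <- function(model, seed = NULL) {
  with_seed(seed, {
    Ne <- vapply(model$demes, function(d) {
      b <- model$size_priors[[d]]
      stats::runif(1, b[1], b[2])
    }, 0)
    m <- if (model$scenario == "continuous_migration")
      stats::runif(1, model$migration_prior[1], model$migration_prior[2])
    else NA_real_
    list(Ne = Ne, m = m, seed = seed)
  })
}

# Core event-driven structured coalescent.
# n_per_deme: named/unnamed integer vector; Ne: vector per deme;
# mig: ndeme x ndeme per-lineage rate matrix (row = source, backwards in
# time); events: list of list(time, type = "merge" (from,to) |
# "set_migration" (mig)). Returns a genealogy: parent/time arrays over
# 2n-1 nodes (leaves first), leaf_deme, n_per_deme.
sim_genealogy_engine <- function(n_per_deme, Ne, mig = NULL, events = list()) {
  nd <- length(n_per_deme)
  ntot <- sum(n_per_deme)
  if (ntot < 2) stop("need at least 2 sampled lineages")
  if (is.null(mig)) mig <- matrix(0, nd, nd)
  diag(mig) <- 0
  nnode <- 2L * ntot - 1L
  parent <- integer(nnode); time <- numeric(nnode)
  leaf_deme <- rep(seq_len(nd), n_per_deme)
  lin_node <- seq_len(ntot)        # active lineage -> node id
  lin_deme <- leaf_deme            # active lineage -> current deme
  nxt <- ntot + 1L
  t <- 0
  n_migrations <- 0L
  migration_times <- numeric(0)
  ev_times <- vapply(events, `[[`, 0, "time")
  ev_order <- order(ev_times)
  events <- events[ev_order]; ev_times <- ev_times[ev_order]
  ei <- 1L
  while (length(lin_node) > 1L) {
    k_d <- tabulate(lin_deme, nd)
    coal_rate <- k_d * (k_d - 1) / (2 * Ne)
    mig_rate <- k_d * mig          # row d: rates to each destination
    total <- sum(coal_rate) + sum(mig_rate)
    t_next_ev <- if (ei <= length(events)) ev_times[ei] else Inf
    dt <- if (total > 0) stats::rexp(1, total) else Inf
    if (t + dt >= t_next_ev) {
      t <- t_next_ev
      ev <- events[[ei]]; ei <- ei + 1L
      if (ev$type == "merge") {
        lin_deme[lin_deme == ev$from] <- ev$to
        mig[ev$from, ] <- 0; mig[, ev$from] <- 0
      } else if (ev$type == "set_migration") {
        mig <- ev$mig
        diag(mig) <- 0
      }
      next
    }
    if (!is.finite(dt))
      stop("no possible events left with >1 lineage (model misconfigured)")
    t <- t + dt
    u <- stats::runif(1, 0, total)
    if (u <= sum(coal_rate)) {
      d <- sample.int(nd, 1L, prob = coal_rate)
      in_d <- which(lin_deme == d)
      pick <- in_d[sample.int(length(in_d), 2L)]
      node <- nxt; nxt <- nxt + 1L
      time[node] <- t
      parent[lin_node[pick]] <- node
      lin_node <- c(lin_node[-pick], node)
      lin_deme <- c(lin_deme[-pick], d)
    } else {
      rates <- as.vector(mig_rate)
      idx <- sample.int(length(rates), 1L, prob = rates)
      d <- (idx - 1L) %% nd + 1L
      e <- (idx - 1L) %/% nd + 1L
      in_d <- which(lin_deme == d)
      mv <- in_d[sample.int(length(in_d), 1L)]
      lin_deme[mv] <- e
      n_migrations <- n_migrations + 1L
      migration_times <- c(migration_times, t)
    }
  }
  structure(list(parent = parent, time = time, leaf_deme = leaf_deme,
                 n_per_deme = n_per_deme, n_leaves = ntot,
                 root = lin_node[1L], tmrca = t,
                 n_migrations = n_migrations,
                 migration_times = migration_times),
            class = "genealogy")
}

# Scenario -> engine configuration (times in generations).
scenario_events <- function(model, draw) {
  g <- model$generation_time_years
  t_target <- model$t_target_years / g
  t_root <- model$t_root_years / g
  nd <- 3L
  mig <- matrix(0, nd, nd)
  parent_of_target <- if (model$scenario == "cultural") 1L else 2L # AA else DAI
  if (model$scenario == "continuous_migration") {
    mig[1, 3] <- mig[3, 1] <- draw$m   # TARGET <-> AA, active in [0, t_target]
  }
  events <- list(list(time = t_target, type = "merge",
                      from = 3L, to = parent_of_target),
                 list(time = t_root, type = "merge", from = 2L, to = 1L))
  list(mig = mig, events = events,
       Ne = as.numeric(draw$Ne[c("AA", "DAI", "TARGET")]))
}

#' Simulate one genealogy under a demographic scenario
#'
#' Event-driven structured coalescent with the scenario's deme mergers at
#' the fixed split times (converted to generations) and, for the
#' continuous-migration scenario, symmetric TARGET-AA migration active
#' only more recently than the TARGET origin.
#'
#' @param model a [demographic_model()].
#' @param draw a parameter draw from [sample_prior()].
#' @param seed RNG seed.
#' @return a `genealogy`: node `parent`/`time` arrays (generations), leaf
#'   deme labels, `tmrca`.
#' @export
simulate_genealogy <- function(model, draw, seed = NULL) {
  cfg <- scenario_events(model, draw)
  with_seed(seed, sim_genealogy_engine(model$sample_sizes, cfg$Ne,
                                       cfg$mig, cfg$events))
}

#' Simulate a genealogy under a symmetric island model
#'
#' One or more demes of constant haploid size with symmetric per-lineage
#' migration; the single-deme case is the standard neutral constant-size
#' coalescent. With several demes the migration rate must be positive,
#' otherwise lineages can never meet.
#'
#' @param n_per_deme named integer vector of sample sizes per deme.
#' @param Ne haploid effective size, recycled across demes.
#' @param migration per-lineage per-generation migration rate to each
#'   other deme.
#' @param seed RNG seed.
#' @return a `genealogy` (times in generations).
#' @export
simulate_island_model <- function(n_per_deme, Ne, migration = 0,
                                  seed = NULL) {
  nd <- length(n_per_deme)
  if (nd > 1 && migration <= 0)
    stop("multi-deme island model needs migration > 0")
  mig <- matrix(migration, nd, nd); diag(mig) <- 0
  with_seed(seed, sim_genealogy_engine(n_per_deme, rep(Ne, length.out = nd),
                                       mig))
}

# Per-branch lengths and per-deme descendant-leaf counts.
# Returns list(len[nnode], desc[nnode x ndeme]); the root row has length 0.
branch_stats <- function(gen) {
  nnode <- length(gen$parent)
  nd <- length(gen$n_per_deme)
  desc <- matrix(0L, nnode, nd)
  desc[cbind(seq_len(gen$n_leaves), gen$leaf_deme)] <- 1L
  ord <- order(gen$time)           # children always precede parents in time
  for (v in ord) {
    p <- gen$parent[v]
    if (p > 0L) desc[p, ] <- desc[p, ] + desc[v, ]
  }
  pidx <- pmax(gen$parent, 1L)
  len <- ifelse(gen$parent > 0L, gen$time[pidx] - gen$time, 0)
  list(len = len, desc = desc)
}

#' Drop infinite-sites mutations on a genealogy
#'
#' The number of mutations is Poisson with mean (total branch length in
#' generations) x (mu * g * L); each mutation hits a new site and is placed
#' on a branch with probability proportional to its length. Returns a 0/1
#' polarized alignment (ancestral state 0) and the per-deme unfolded SFS.
#'
#' @param genealogy from [simulate_genealogy()].
#' @param mu mutation rate per bp per year.
#' @param L locus length in bp.
#' @param g generation time in years.
#' @param seed RNG seed.
#' @param sample_ids,populations optional labels for the emitted alignment;
#'   defaults are deme-derived.
#' @return list `alignment` (a [haplotype_alignment()], 0 columns if no
#'   mutations), `sfs` (see [sfs_vector()]).
#' @export
drop_mutations <- function(genealogy, mu, L, g, seed = NULL,
                           sample_ids = NULL, populations = NULL) {
  stopifnot(mu >= 0, L > 0, g > 0)
  bs <- branch_stats(genealogy)
  rate <- mu * g * L
  with_seed(seed, {
    S <- stats::rpois(1L, sum(bs$len) * rate)
    n <- genealogy$n_leaves
    nd <- length(genealogy$n_per_deme)
    deme_names <- names(genealogy$n_per_deme) %||% paste0("D", seq_len(nd))
    if (is.null(populations))
      populations <- deme_names[genealogy$leaf_deme]
    if (is.null(sample_ids))
      sample_ids <- paste0(populations, "_", stats::ave(seq_len(n),
                                                        populations,
                                                        FUN = seq_along))
    if (S == 0L) {
      aln <- haplotype_alignment(
        matrix(character(0), nrow = n, ncol = 0,
               dimnames = list(sample_ids, NULL)),
        stats::setNames(populations, sample_ids), locus_length_bp = L,
        ancestral = character(0))
      return(list(alignment = aln,
                  sfs = empty_sfs(genealogy$n_per_deme, deme_names)))
    }
    br <- sample.int(length(bs$len), S, replace = TRUE, prob = bs$len)
    # leaf membership of each branch's subtree
    carrier <- matrix(0L, n, S)
    below <- subtree_leaves(genealogy)
    for (s in seq_len(S)) carrier[below[[br[s]]], s] <- 1L
    m <- matrix(as.character(carrier), n, S,
                dimnames = list(sample_ids, paste0("s", seq_len(S))))
    aln <- haplotype_alignment(m, stats::setNames(populations, sample_ids),
                               locus_length_bp = L,
                               ancestral = rep("0", S))
    sfs <- sfs_from_counts(bs$desc[br, , drop = FALSE],
                           genealogy$n_per_deme, deme_names)
    list(alignment = aln, sfs = sfs)
  })
}

# List of leaf index vectors below each node.
subtree_leaves <- function(gen) {
  nnode <- length(gen$parent)
  below <- vector("list", nnode)
  for (v in seq_len(gen$n_leaves)) below[[v]] <- v
  ord <- order(gen$time)
  for (v in ord) {
    p <- gen$parent[v]
    if (p > 0L) below[[p]] <- c(below[[p]], below[[v]])
  }
  below
}

empty_sfs <- function(n_per_deme, deme_names) {
  xi <- lapply(seq_along(n_per_deme), function(d)
    stats::setNames(integer(max(n_per_deme[d] - 1L, 0L)), NULL))
  names(xi) <- deme_names
  structure(list(xi = xi, total_S = 0L, n_per_deme = n_per_deme),
            class = "sfs_vector")
}

# desc_rows: one row per mutation, per-deme derived counts.
sfs_from_counts <- function(desc_rows, n_per_deme, deme_names) {
  xi <- lapply(seq_along(n_per_deme), function(d) {
    nd <- n_per_deme[d]
    if (nd < 2) return(integer(max(nd - 1L, 0L)))
    cnt <- desc_rows[, d]
    tabulate(cnt[cnt > 0L & cnt < nd], nd - 1L)
  })
  names(xi) <- deme_names
  structure(list(xi = xi, total_S = nrow(desc_rows), n_per_deme = n_per_deme),
            class = "sfs_vector")
}

#' Unfolded site-frequency spectrum container
#'
#' Per-deme derived-allele frequency class counts \eqn{\xi_1..\xi_{n_d-1}}
#' (classes fixed within a deme contribute nothing to that deme's vector)
#' plus the total number of segregating sites in the whole sample.
#'
#' @param x an `sfs_vector`.
#' @return `as_summary_vector()` flattens to the ABC summary layout:
#'   concatenated per-deme spectra followed by `total_S`.
#' @export
as_summary_vector <- function(x) {
  stopifnot(inherits(x, "sfs_vector"))
  v <- unlist(lapply(names(x$xi), function(d) {
    xi <- x$xi[[d]]
    if (length(xi)) stats::setNames(xi, paste0(d, "_xi", seq_along(xi)))
    else NULL
  }))
  c(v, total_S = x$total_S)
}

#' @export
print.sfs_vector <- function(x, ...) {
  cat("unfolded SFS: total_S =", x$total_S, "\n")
  for (d in names(x$xi)) cat(" ", d, ":", paste(x$xi[[d]], collapse = " "), "\n")
  invisible(x)
}

#' Simulate a batch of (parameter draw, SFS) rows for one model
#'
#' Row i is reproducible in isolation: its RNG stream is seeded from
#' `base_seed + i - 1`. Emits the flattened summary vector used by the ABC
#' reference table (concatenated per-deme unfolded SFS + total_S).
#'
#' @param model a [demographic_model()].
#' @param n_sims number of replicates.
#' @param base_seed integer base seed.
#' @return list `params` (data.frame), `summaries` (matrix), `model`,
#'   `seeds`.
#' @export
simulate_sfs_batch <- function(model, n_sims, base_seed = 1) {
  stopifnot(n_sims >= 1)
  seeds <- as.integer(base_seed) + seq_len(n_sims) - 1L
  rate_ok <- model$mutation_rate_per_bp_year
  rows <- vector("list", n_sims)
  params <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    with_seed(seeds[i], {
      draw <- sample_prior(model, seed = NULL)
      cfg <- scenario_events(model, draw)
      gen <- sim_genealogy_engine(model$sample_sizes, cfg$Ne, cfg$mig,
                                  cfg$events)
      bs <- branch_stats(gen)
      rate <- rate_ok * model$generation_time_years * model$locus_length_bp
      S <- stats::rpois(1L, sum(bs$len) * rate)
      if (S > 0L) {
        br <- sample.int(length(bs$len), S, replace = TRUE, prob = bs$len)
        sfs <- sfs_from_counts(bs$desc[br, , drop = FALSE],
                               model$sample_sizes, model$demes)
      } else sfs <- empty_sfs(model$sample_sizes, model$demes)
      rows[[i]] <- as_summary_vector(sfs)
      params[[i]] <- c(draw$Ne, m = draw$m)
    })
  }
  list(params = as.data.frame(do.call(rbind, params)),
       summaries = do.call(rbind, rows), model = model$scenario,
       seeds = seeds)
}

#' Observed unfolded SFS from a polarized alignment
#'
#' Requires per-site ancestral states; sites whose ancestral state is
#' missing are dropped (count reported via attribute `n_unpolarized`).
#' Each deme is subsampled without replacement to the model's sample size
#' so observed and simulated spectra are comparable (mirrors matching the
#' lowest sample size among populations in the model).
#'
#' @param alignment a polarized [haplotype_alignment()] (`ancestral` set).
#' @param demes named vector population code -> deme name, or NULL to use
#'   population codes as demes.
#' @param n_per_deme named target sample size per deme.
#' @param seed RNG seed for subsampling.
#' @return an `sfs_vector`.
#' @export
observed_sfs <- function(alignment, demes = NULL, n_per_deme, seed = NULL) {
  if (is.null(alignment$ancestral))
    stop("observed_sfs needs a polarized alignment (ancestral states)")
  pops <- alignment$populations
  deme_of <- if (is.null(demes)) stats::setNames(unique(pops), unique(pops))
             else demes
  samp_deme <- deme_of[pops]
  if (any(is.na(samp_deme))) stop("samples mapped to unknown deme")
  deme_names <- names(n_per_deme)
  keep <- with_seed(seed, {
    unlist(lapply(deme_names, function(d) {
      ids <- which(samp_deme == d)
      if (length(ids) < n_per_deme[d])
        stop("deme ", d, " smaller than required sample size ", n_per_deme[d])
      if (length(ids) == n_per_deme[d]) ids
      else sort(sample(ids, n_per_deme[d]))
    }))
  })
  m <- alignment$seqs[keep, , drop = FALSE]
  sd_ <- samp_deme[keep]
  anc <- alignment$ancestral
  polarizable <- !is.na(anc) & anc != "N"
  n_unpolarized <- sum(!polarizable)
  m <- m[, polarizable, drop = FALSE]; anc <- anc[polarizable]
  if (ncol(m)) {
    derived <- m != matrix(anc, nrow(m), ncol(m), byrow = TRUE)
    derived[m == "N"] <- NA
    total <- colSums(derived, na.rm = TRUE)
    poly <- total > 0 & total < nrow(m)
    derived <- derived[, poly, drop = FALSE]
    counts <- sapply(deme_names, function(d)
      colSums(derived[sd_ == d, , drop = FALSE], na.rm = TRUE))
    if (!is.matrix(counts)) counts <- matrix(counts, ncol = length(deme_names),
                                             dimnames = list(NULL, deme_names))
    sfs <- sfs_from_counts(counts, stats::setNames(n_per_deme, deme_names),
                           deme_names)
  } else {
    sfs <- empty_sfs(stats::setNames(n_per_deme, deme_names), deme_names)
  }
  attr(sfs, "n_unpolarized") <- n_unpolarized
  sfs
}
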