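# Synthetic study generator: haplotype alignments plus population metadata
# with the statistical structure the downstream analyses assume (lower
# within-population diversity and higher among-population heterogeneity in
# the AA-like block, residence labels correlated with that structure).
# Each language-family block is an independent island model; this is test
# scaffolding shaped like the field's data, not a historical claim.

#' Study design for the synthetic generator
#'
#' Defaults are desk-scale: 12 populations (5 AA-like with small deme sizes
#' and little migration, 5 TK-like with large sizes and much migration,
#' 2 ST-like intermediate), n = 15 samples per population, a 50 kb locus.
#' AA-like populations are labelled patrilocal, TK-like matrilocal,
#' ST-like neutral, so residence contrasts have a known construction
#' direction for a paternally inherited locus.
#'
#' @param blocks named list per block (`AA`, `TK`, `ST`) with fields
#'   `n_populations`, `Ne` (haploid, per deme), `migration` (per-lineage
#'   per-generation island-model rate), `residence`, `center`
#'   (lat, lon of the regional cluster).
#' @param n_per_population samples per population (>= 2).
#' @param locus_length_bp,mu,generation_time_years mutation process.
#' @param coord_jitter_deg uniform jitter applied to cluster centers.
#' @param haplogroup_age_years clade-age threshold for haplogroup labels.
#' @param seed design seed; all randomness derives from it.
#' @export
study_design <- function(blocks = list(
                           AA = list(n_populations = 5, Ne = 2000,
                                     migration = 5e-4,
                                     residence = "patrilocal",
                                     center = c(18.5, 98.0)),
                           TK = list(n_populations = 5, Ne = 20000,
                                     migration = 5e-3,
                                     residence = "matrilocal",
                                     center = c(15.5, 101.5)),
                           ST = list(n_populations = 2, Ne = 8000,
                                     migration = 2e-3,
                                     residence = "neutral",
                                     center = c(19.5, 99.5))),
                         n_per_population = 15,
                         locus_length_bp = 50000,
                         mu = 8.71e-10,
                         generation_time_years = 30,
                         coord_jitter_deg = 1.0,
                         haplogroup_age_years = 50000,
                         seed = 1) {
  stopifnot(n_per_population >= 2)
  for (b in blocks) stopifnot(b$n_populations >= 1, b$Ne > 0, b$migration > 0)
  structure(list(blocks = blocks, n_per_population = n_per_population,
                 locus_length_bp = locus_length_bp, mu = mu,
                 generation_time_years = generation_time_years,
                 coord_jitter_deg = coord_jitter_deg,
                 haplogroup_age_years = haplogroup_age_years, seed = seed),
            class = "study_design")
}

#' Haplogroup labels from a genealogy by clade age
#'
#' Labels are the maximal clades whose subtending branch crosses the age
#' threshold: every lineage alive at `age_threshold_years` (converted to
#' generations) founds one haplogroup containing all its descendant
#' samples. Threshold 0 gives one label per sample; a threshold at or above
#' the root age gives a single label with a warning.
#'
#' @param genealogy a `genealogy` (times in generations).
#' @param age_threshold_years clade age threshold.
#' @param generation_time_years conversion factor g.
#' @return character vector of labels, one per leaf (`HG1`, `HG2`, ...).
#' @export
assign_haplogroups <- function(genealogy, age_threshold_years,
                               generation_time_years = 30) {
  thr <- age_threshold_years / generation_time_years
  tm <- genealogy$time
  par <- genealogy$parent
  root_age <- tm[genealogy$root]
  labels <- rep(NA_character_, genealogy$n_leaves)
  if (thr >= root_age) {
    warning("threshold at or above root age: single haplogroup")
    return(rep("HG1", genealogy$n_leaves))
  }
  below <- subtree_leaves(genealogy)
  founders <- which(par > 0L & tm <= thr & tm[pmax(par, 1L)] > thr)
  founders <- founders[order(-vapply(below[founders], length, 0L))]
  for (i in seq_along(founders))
    labels[below[[founders[i]]]] <- paste0("HG", i)
  labels
}

#' Generate a study-shaped synthetic dataset
#'
#' Simulates each block as an island model (symmetric migration among the
#' block's populations) with the block's deme size, drops infinite-sites
#' mutations, recodes sites to nucleotides (random ancestral base, one
#' derived base per site), assigns clade-based haplogroup labels, and
#' builds metadata with jittered regional coordinates and residence labels.
#'
#' @param design a [study_design()].
#' @return list: `alignment` (a [haplotype_alignment()], ACGT states,
#'   ancestral states recorded), `metadata` (data.frame in
#'   [read_metadata()] layout plus `n_samples`), `haplogroups` (named
#'   vector), `manifest` (true parameters and the per-block seed scheme).
#' @export
generate_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  g <- design$generation_time_years
  all_seqs <- list(); all_pops <- c(); all_anc <- list()
  haplogroups <- c(); meta_rows <- list(); manifest_blocks <- list()
  for (bi in seq_along(design$blocks)) {
    bname <- names(design$blocks)[bi]
    blk <- design$blocks[[bi]]
    block_seed <- derive_seed(design$seed, bi)
    np <- blk$n_populations
    pops <- paste0(bname, seq_len(np))
    mig <- matrix(blk$migration, np, np); diag(mig) <- 0
    sim <- with_seed(block_seed, {
      gen <- sim_genealogy_engine(stats::setNames(rep(design$n_per_population,
                                                      np), pops),
                                  rep(blk$Ne, np), mig)
      dm <- drop_mutations(gen, design$mu, design$locus_length_bp, g,
                           populations = pops[gen$leaf_deme])
      hg <- assign_haplogroups(gen, design$haplogroup_age_years, g)
      coords <- cbind(blk$center[1] + stats::runif(np, -1, 1) *
                        design$coord_jitter_deg,
                      blk$center[2] + stats::runif(np, -1, 1) *
                        design$coord_jitter_deg)
      list(gen = gen, dm = dm, hg = hg, coords = coords)
    })
    aln <- sim$dm$alignment
    ids <- paste0(bname, "_", rownames(aln$seqs))
    seqs <- aln$seqs; rownames(seqs) <- ids
    all_seqs[[bi]] <- seqs
    all_pops <- c(all_pops, stats::setNames(as.character(aln$populations), ids))
    all_anc[[bi]] <- aln$ancestral
    haplogroups <- c(haplogroups, stats::setNames(sim$hg, ids))
    meta_rows[[bi]] <- data.frame(code = pops, ethnicity = pops,
                                  language_family = bname,
                                  region = paste0("region_", bname),
                                  latitude = sim$coords[, 1],
                                  longitude = sim$coords[, 2],
                                  residence = blk$residence,
                                  n_samples = design$n_per_population)
    manifest_blocks[[bname]] <- list(Ne = blk$Ne, migration = blk$migration,
                                     n_populations = np,
                                     residence = blk$residence,
                                     seed = block_seed)
  }
  # pad blocks to a common site count by concatenating columns block-wise:
  # sites are block-private (independent genealogies), so other blocks are
  # ancestral (0) at a block's sites.
  n_tot <- sum(vapply(all_seqs, nrow, 0L))
  s_per <- vapply(all_seqs, ncol, 0L)
  seqs <- matrix("0", n_tot, sum(s_per))
  rn <- unlist(lapply(all_seqs, rownames))
  rownames(seqs) <- rn
  col0 <- 0L; row0 <- 0L
  for (bi in seq_along(all_seqs)) {
    sb <- all_seqs[[bi]]
    if (ncol(sb))
      seqs[row0 + seq_len(nrow(sb)), col0 + seq_len(ncol(sb))] <- sb
    row0 <- row0 + nrow(sb); col0 <- col0 + ncol(sb)
  }
  anc <- unlist(all_anc) %||% character(0)
  # recode 0/1 to nucleotides: random ancestral base per site, one derived
  nuc <- with_seed(derive_seed(design$seed, 999L), {
    bases <- c("A", "C", "G", "T")
    a <- sample(bases, ncol(seqs), replace = TRUE)
    d <- vapply(a, function(x) sample(setdiff(bases, x), 1L), "")
    out <- seqs
    for (j in seq_len(ncol(seqs)))
      out[, j] <- ifelse(seqs[, j] == "0", a[j], d[j])
    list(m = out, anc = a)
  })
  alignment <- haplotype_alignment(nuc$m, all_pops,
                                   locus_length_bp =
                                     max(design$locus_length_bp, ncol(seqs)),
                                   ancestral = nuc$anc)
  metadata <- do.call(rbind, meta_rows)
  manifest <- list(design_seed = design$seed,
                   seed_scheme = "derive_seed(design_seed, block_index)",
                   n_per_population = design$n_per_population,
                   locus_length_bp = design$locus_length_bp,
                   mu = design$mu,
                   generation_time_years = design$generation_time_years,
                   blocks = manifest_blocks)
  list(alignment = alignment, metadata = metadata,
       haplogroups = haplogroups, manifest = manifest)
}

#' Pseudo-observed data for ABC experiments
#'
#' One draw from a scenario at fixed (true) parameters: polarized 0/1
#' alignment, its unfolded SFS, and a truth manifest sufficient to rerun
#' any downstream recovery test.
#'
#' @param model a [demographic_model()].
#' @param true_params list with `Ne` (named AA/DAI/TARGET) and optionally
#'   `m`.
#' @param seed RNG seed.
#' @return list `alignment`, `sfs`, `manifest`.
#' @export
generate_observed_for_abc <- function(model, true_params, seed = 1) {
  draw <- list(Ne = true_params$Ne, m = true_params$m %||% NA_real_)
  cfg <- scenario_events(model, draw)
  with_seed(seed, {
    gen <- sim_genealogy_engine(model$sample_sizes, cfg$Ne, cfg$mig,
                                cfg$events)
    dm <- drop_mutations(gen, model$mutation_rate_per_bp_year,
                         model$locus_length_bp,
                         model$generation_time_years)
    list(alignment = dm$alignment, sfs = dm$sfs,
         manifest = list(scenario = model$scenario, true_params = draw,
                         seed = seed,
                         sample_sizes = as.list(model$sample_sizes)))
  })
}
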