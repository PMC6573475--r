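# ABC model choice and parameter estimation with random forests.
#
# Model choice follows the random-forest ABC procedure: a classification
# forest is trained on the reference table of simulated summary statistics;
# the scenario receiving most tree votes at the observed summary is
# selected; the posterior probability of that selection is estimated by a
# regression forest trained on the out-of-bag success indicator of the
# classifier, evaluated at the observed summary. Parameter posteriors for
# the selected scenario come from quantile regression forests.

#' Build an ABC reference table from scenario simulations
#'
#' `n_sims_per_model` rows per model, simulated with
#' [simulate_sfs_batch()]; per-model seed blocks are spaced so every row is
#' independently reproducible. All models must share deme structure and
#' sample sizes so summary dimensions are comparable.
#'
#' @param models named list of [demographic_model()] objects (names are the
#'   model labels; keep the canonical order demic, cultural,
#'   continuous_migration for documented tie-breaking).
#' @param n_sims_per_model rows per model.
#' @param base_seed integer; model b gets seed block
#'   `base_seed + (b-1) * n_sims_per_model`.
#' @return object of class `reference_table`: `model_labels`, `params`,
#'   `summaries`, `provenance`.
#' @export
build_reference_table <- function(models, n_sims_per_model, base_seed = 1) {
  stopifnot(length(models) >= 1, !is.null(names(models)))
  batches <- vector("list", length(models))
  for (b in seq_along(models)) {
    batches[[b]] <- simulate_sfs_batch(models[[b]], n_sims_per_model,
                                       base_seed = base_seed +
                                         (b - 1L) * n_sims_per_model)
  }
  dims <- vapply(batches, function(x) ncol(x$summaries), 0L)
  if (length(unique(dims)) != 1L)
    stop("summary dimensions differ across models: ",
         paste(dims, collapse = ","))
  params <- lapply(batches, `[[`, "params")
  allnames <- unique(unlist(lapply(params, names)))
  params <- do.call(rbind, lapply(params, function(p) {
    for (nm in setdiff(allnames, names(p))) p[[nm]] <- NA_real_
    p[allnames]
  }))
  structure(list(
    model_labels = factor(rep(names(models),
                              each = n_sims_per_model),
                          levels = names(models)),
    params = params,
    summaries = do.call(rbind, lapply(batches, `[[`, "summaries")),
    provenance = list(base_seed = base_seed,
                      n_per_model = n_sims_per_model,
                      models = names(models))),
    class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  cat("ABC reference table:", nrow(x$summaries), "rows,",
      ncol(x$summaries), "summaries,",
      nlevels(x$model_labels), "models (",
      paste(levels(x$model_labels), collapse = ", "), ")\n")
  invisible(x)
}

rf_data <- function(table) {
  df <- as.data.frame(table$summaries)
  names(df) <- make.names(colnames(table$summaries), unique = TRUE)
  df
}

#' Separated-prior test regime for recovery experiments
#'
#' Three scenario models whose effective-size priors are pairwise disjoint
#' (demic low, continuous-migration intermediate, cultural high), so the
#' scenarios are separable by construction and classifier recovery can be
#' measured against a known answer. At the fixed split times of these
#' models (a few thousand years on a Bronze-Age scale), scenario topology
#' alone leaves the single-genealogy SFS nearly indistinguishable - which
#' is a property of the inference problem, not of the classifier - so
#' recovery experiments are run in this regime.
#'
#' @param n_per_deme sample size per deme.
#' @param locus_length_bp locus length (defaults to the full 2,364,048 bp
#'   target).
#' @return named list of three [demographic_model()] objects in canonical
#'   order demic, cultural, continuous_migration.
#' @export
abc_test_regime <- function(n_per_deme = 10, locus_length_bp = 2364048) {
  ss <- c(AA = n_per_deme, DAI = n_per_deme, TARGET = n_per_deme)
  band <- function(lo, hi) list(AA = c(lo, hi), DAI = c(lo, hi),
                                TARGET = c(lo, hi))
  list(
    demic = demographic_model("demic", size_priors = band(1e3, 5e3),
                              locus_length_bp = locus_length_bp,
                              sample_sizes = ss),
    cultural = demographic_model("cultural", size_priors = band(5e4, 1e5),
                                 locus_length_bp = locus_length_bp,
                                 sample_sizes = ss),
    continuous_migration = demographic_model(
      "continuous_migration", size_priors = band(1e4, 3e4),
      migration_prior = c(2e-3, 1e-2), locus_length_bp = locus_length_bp,
      sample_sizes = ss))
}

#' Random-forest ABC model choice
#'
#' @param table a [build_reference_table()] result with >= 2 model labels.
#' @param observed_summary numeric vector matching the table's summary
#'   dimension (e.g. from [as_summary_vector()]), or a matrix with one
#'   observed summary per row (the forests are trained once and evaluated
#'   at every row).
#' @param n_trees number of trees (warning below 50).
#' @param seed RNG seed; forests are deterministic given (table, seed,
#'   n_trees).
#' @return For a vector, an object of class `model_choice_result`:
#'   `selected_model`, `vote_fractions` (sums to 1),
#'   `posterior_probability`, `oob_prior_error`, `n_trees`, `seed`. Vote
#'   ties break by model-label order in the table (documented canonical
#'   order). For a matrix, a data.frame with one row per observed point
#'   (selected model, per-model vote fractions, posterior probability)
#'   plus attribute `oob_prior_error`.
#' @export
rf_model_choice <- function(table, observed_summary, n_trees = 500,
                            seed = 1) {
  if (nlevels(table$model_labels) < 2)
    stop("model choice needs >= 2 distinct model labels")
  obs_mat <- if (is.matrix(observed_summary)) observed_summary
             else matrix(observed_summary, nrow = 1)
  if (ncol(obs_mat) != ncol(table$summaries))
    stop("observed summary dimension (", ncol(obs_mat),
         ") does not match table (", ncol(table$summaries), ")")
  if (n_trees < 50) warning("n_trees < 50: vote fractions will be noisy")
  df <- rf_data(table)
  df$.model <- table$model_labels
  obs <- as.data.frame(obs_mat)
  names(obs) <- setdiff(names(df), ".model")
  lev <- levels(table$model_labels)
  res <- with_seed(seed, {
    rf <- ranger::ranger(dependent.variable.name = ".model", data = df,
                         num.trees = n_trees, seed = seed, num.threads = 1L,
                         classification = TRUE)
    pred <- stats::predict(rf, data = obs, predict.all = TRUE,
                           num.threads = 1L)
    votes <- t(apply(pred$predictions, 1, function(v)
      tabulate(v, length(lev)) / n_trees))
    colnames(votes) <- lev
    # posterior probability: regression forest on OOB classification success
    success <- as.numeric(rf$predictions == table$model_labels)
    df2 <- rf_data(table)
    df2$.success <- success
    rf2 <- ranger::ranger(dependent.variable.name = ".success", data = df2,
                          num.trees = n_trees, seed = seed + 1L,
                          num.threads = 1L)
    post <- stats::predict(rf2, data = obs, num.threads = 1L)$predictions
    list(votes = votes, post = pmin(pmax(post, 0), 1),
         oob = rf$prediction.error)
  })
  selected <- lev[apply(res$votes, 1, which.max)]  # first max: label order
  if (!is.matrix(observed_summary)) {
    return(structure(list(selected_model = selected[1],
                          vote_fractions = res$votes[1, ],
                          posterior_probability = res$post[1],
                          oob_prior_error = res$oob,
                          n_trees = n_trees, seed = seed),
                     class = "model_choice_result"))
  }
  out <- data.frame(selected_model = selected, res$votes,
                    posterior_probability = res$post,
                    check.names = FALSE)
  attr(out, "oob_prior_error") <- res$oob
  out
}

#' @export
print.model_choice_result <- function(x, ...) {
  cat("ABC-RF model choice: selected", x$selected_model, "\n")
  cat(" votes:", paste(names(x$vote_fractions),
                       formatC(x$vote_fractions, digits = 3, format = "f"),
                       sep = "=", collapse = "  "), "\n")
  cat(" posterior probability:",
      formatC(x$posterior_probability, digits = 3, format = "f"),
      " OOB prior error:",
      formatC(x$oob_prior_error, digits = 3, format = "f"), "\n")
  invisible(x)
}

#' Out-of-bag prior error rate and confusion matrix
#'
#' @inheritParams rf_model_choice
#' @return list `oob_prior_error`, `confusion` (rows = true model,
#'   columns = OOB-predicted model; rows sum to per-model counts).
#' @export
prior_error_rate <- function(table, n_trees = 500, seed = 1) {
  counts <- table(table$model_labels)
  if (any(counts < 2)) stop("need >= 2 rows per model")
  df <- rf_data(table)
  df$.model <- table$model_labels
  rf <- with_seed(seed,
    ranger::ranger(dependent.variable.name = ".model", data = df,
                   num.trees = n_trees, seed = seed, num.threads = 1L,
                   classification = TRUE))
  pred <- factor(levels(table$model_labels)[rf$predictions],
                 levels = levels(table$model_labels))
  conf <- table(true = table$model_labels, predicted = pred)
  list(oob_prior_error = rf$prediction.error, confusion = conf)
}

#' Random-forest parameter estimation for one scenario
#'
#' Per-parameter quantile regression forest trained on the reference-table
#' rows of the selected model; point estimate is the forest mean prediction
#' at the observed summary, quantiles come from the weighted out-of-bag
#' response distribution of co-occupied leaves. A flatness diagnostic
#' (posterior 5-95% width over prior 5-95% width) is reported because flat
#' posteriors are common when summaries carry little parameter information.
#'
#' @param table a [build_reference_table()] result restricted to (or built
#'   from) a single model; if several labels are present, use `model` to
#'   select one.
#' @param observed_summary numeric summary vector, or a matrix of observed
#'   summaries (one per row; forests are trained once).
#' @param model optional model label to subset on.
#' @param n_trees trees per forest.
#' @param seed RNG seed.
#' @return data.frame: parameter, estimate, q05, q50, q95, flatness.
#' @export
estimate_parameters <- function(table, observed_summary, model = NULL,
                                n_trees = 500, seed = 1) {
  rows <- if (is.null(model)) rep(TRUE, nrow(table$summaries))
          else table$model_labels == model
  if (sum(rows) < 500)
    warning("fewer than 500 reference rows for parameter estimation")
  summ <- table$summaries[rows, , drop = FALSE]
  params <- table$params[rows, , drop = FALSE]
  params <- params[, colSums(!is.na(params)) > 0, drop = FALSE]
  df0 <- as.data.frame(summ)
  names(df0) <- make.names(colnames(summ), unique = TRUE)
  obs_mat <- if (is.matrix(observed_summary)) observed_summary
             else matrix(observed_summary, nrow = 1)
  obs <- as.data.frame(obs_mat)
  names(obs) <- names(df0)
  n_obs <- nrow(obs)
  out <- lapply(seq_along(params), function(j) {
    y <- params[[j]]
    nm <- names(params)[j]
    if (stats::sd(y) == 0) {
      warning("constant parameter column '", nm, "': degenerate quantiles")
      return(data.frame(parameter = nm, obs_row = seq_len(n_obs),
                        estimate = y[1], q05 = y[1], q50 = y[1],
                        q95 = y[1], flatness = NA_real_))
    }
    df <- df0
    df$.y <- y
    # quantile forests draw node values through R's RNG: isolate the stream
    pq <- with_seed(seed + j, {
      rf <- ranger::ranger(dependent.variable.name = ".y", data = df,
                           num.trees = n_trees, seed = seed + j,
                           num.threads = 1L, quantreg = TRUE)
      list(est = stats::predict(rf, data = obs, type = "response",
                                num.threads = 1L)$predictions,
           q = stats::predict(rf, data = obs, type = "quantiles",
                              quantiles = c(0.05, 0.5, 0.95),
                              num.threads = 1L)$predictions)
    })
    q <- t(apply(pq$q, 1, sort))  # guard against inversions in tied leaves
    prior_w <- diff(stats::quantile(y, c(0.05, 0.95)))
    data.frame(parameter = nm, obs_row = seq_len(n_obs),
               estimate = as.numeric(pq$est), q05 = q[, 1], q50 = q[, 2],
               q95 = q[, 3],
               flatness = if (prior_w > 0) (q[, 3] - q[, 1]) / prior_w
                          else NA_real_)
  })
  res <- do.call(rbind, out)
  if (!is.matrix(observed_summary)) res$obs_row <- NULL
  res
}

#' End-to-end scenario comparison
#'
#' Builds (or reuses) the reference table, runs model choice on the
#' observed summary, and estimates parameters under the selected scenario.
#'
#' @param models named list of [demographic_model()] objects.
#' @param observed_summary observed summary vector (e.g. from
#'   [observed_sfs()] + [as_summary_vector()]).
#' @param n_sims_per_model reference-table rows per model.
#' @param n_trees trees per forest.
#' @param seed base seed (table and forests derive from it).
#' @param reference_table optional prebuilt table (skips simulation).
#' @return list `choice` (a `model_choice_result`), `estimates`
#'   (parameter table for the selected model), `manifest` (seeds, sizes,
#'   priors).
#' @export
run_model_comparison <- function(models, observed_summary,
                                 n_sims_per_model = 2000, n_trees = 500,
                                 seed = 1, reference_table = NULL) {
  tab <- reference_table %||%
    build_reference_table(models, n_sims_per_model, base_seed = seed)
  choice <- rf_model_choice(tab, observed_summary, n_trees = n_trees,
                            seed = derive_seed(seed, 1))
  est <- estimate_parameters(tab, observed_summary,
                             model = choice$selected_model,
                             n_trees = n_trees,
                             seed = derive_seed(seed, 2))
  manifest <- list(seed = seed, n_sims_per_model = tab$provenance$n_per_model,
                   n_trees = n_trees, models = tab$provenance$models,
                   priors = lapply(models, function(m)
                     list(size_priors = m$size_priors,
                          migration_prior = m$migration_prior,
                          t_target_years = m$t_target_years,
                          t_root_years = m$t_root_years,
                          generation_time_years = m$generation_time_years,
                          mu = m$mutation_rate_per_bp_year,
                          L = m$locus_length_bp)))
  list(choice = choice, estimates = est, manifest = manifest)
}
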