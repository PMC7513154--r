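# High-level learning entry point and the simulation-study driver:
# repeated (dataset, simulated-expert) replicates on a known ground-truth
# network, evaluated by structural difference and BIC.

#' Learn a Bayesian network structure from data and expert knowledge
#'
#' The full two-stage hybrid algorithm.  Stage 1 builds the initial
#' structure (MIC skeleton, CI pruning, v-structure orientation) and, when
#' knowledge placement includes stage 1, modifies it with the fused expert
#' knowledge through the probabilistic edge rules.  Stage 2 runs binary
#' particle swarm search seeded by the initial structure, maximizing
#' EVBIC when placement includes stage 2 and plain BIC otherwise.
#'
#' @param data a `discrete_dataset`.
#' @param items optional `knowledge_items` (raw, per expert).
#' @param accuracies accuracy table keyed by `expert` (required with
#'   `items`).
#' @param placement where knowledge acts: `"both"`, `"stage1"`,
#'   `"stage2"`, or `"none"`.
#' @param k vague-knowledge weight of the EVBIC score.
#' @param tau,alpha,max_cond,prune stage-1 parameters, see
#'   [build_skeleton()].
#' @param params [swarm_params()] for the search.
#' @param score_type `"evbic"` or `"explicit"` (the BDeu-based
#'   explicit-accuracy baseline score).
#' @param seed integer seed covering stage-1 rule draws and the swarm.
#' @return list with `structure` (a `bn_dag`), `score`, `trace`,
#'   `initial` (the stage-1 `bn_pdag`).
#' @export
learn_structure <- function(data, items = NULL, accuracies = NULL,
                            placement = c("both", "stage1", "stage2", "none"),
                            k = 0.5, tau = 0.1, alpha = 0.05, max_cond = 3L,
                            prune = TRUE, params = swarm_params(),
                            score_type = c("evbic", "explicit"),
                            seed = NULL) {
  placement <- match.arg(placement)
  score_type <- match.arg(score_type)
  if (!is.null(seed)) set.seed(seed)
  if (NROW(items) == 0L) placement <- "none"
  fused <- NULL
  if (placement %in% c("both", "stage1"))
    fused <- fuse_all(items, accuracies, nodes = data$nodes)
  init <- initial_structure(data, fused, tau = tau, alpha = alpha,
                            max_cond = max_cond, prune = prune)
  stage2_items <- if (placement %in% c("both", "stage2")) items else NULL
  score_fn <- make_score_fn(data, stage2_items, accuracies, k = k,
                            type = score_type)
  fit <- bpso_search(score_fn, init, params)
  list(structure = fit$best, score = fit$best_score, trace = fit$trace,
       initial = init)
}

#' Experiment configuration
#'
#' Bundles everything one simulation study needs; see [run_experiment()].
#'
#' @param truth a `discrete_bn` ground truth (structure + CPTs).
#' @param n_samples dataset size per replicate.
#' @param n_replicates independent replicates per condition (default 10).
#' @param cases knowledge cases to run, subset of
#'   `c("none", "explicit", "vague", "ev")`.
#' @param v_values coverage fractions to run.
#' @param placement knowledge placement, see [learn_structure()].
#' @param accuracies expert accuracy table (default: the bundled
#'   ten-expert panel).
#' @param params [swarm_params()].
#' @param k,tau,alpha,max_cond,prune,score_type passed through.
#' @param seed master seed; every replicate derives its own seeds from it.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(truth, n_samples = 500L, n_replicates = 10L,
                              cases = c("none", "explicit", "vague", "ev"),
                              v_values = 0.5, placement = "both",
                              accuracies = default_expert_accuracies(),
                              params = swarm_params(), k = 0.5, tau = 0.1,
                              alpha = 0.05, max_cond = 3L, prune = TRUE,
                              score_type = "evbic", seed = 1L) {
  stopifnot(inherits(truth, "discrete_bn"))
  cases <- match.arg(cases, several.ok = TRUE)
  structure(list(truth = truth, n_samples = as.integer(n_samples),
                 n_replicates = as.integer(n_replicates), cases = cases,
                 v_values = v_values, placement = placement,
                 accuracies = accuracies, params = params, k = k,
                 tau = tau, alpha = alpha, max_cond = max_cond,
                 prune = prune, score_type = score_type,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run a simulation study
#'
#' For every (case, v) condition, runs `n_replicates` independent
#' replicates: sample a dataset from the truth by forward sampling,
#' simulate one expert-knowledge set (skipped for case `"none"`), learn a
#' structure with [learn_structure()], and evaluate it against the true
#' structure.  Replicate r of every condition uses dataset r and
#' knowledge set r (paired by index).  A failed replicate is recorded
#' with `NA` metrics and the run continues.
#'
#' @param config an [experiment_config()].
#' @return list with `results` (one data frame row per replicate:
#'   condition, seeds, A/D/I/C/SHD, learned-structure BIC) and `summary`
#'   (per condition: MR means and BR best values).
#' @export
run_experiment <- function(config) {
  truth <- config$truth
  tg <- truth$structure
  set.seed(config$seed)
  # replicate r shares its dataset, knowledge stream and search seed
  # across every (case, v) condition: paired (common-random-numbers)
  # comparisons between conditions
  data_seeds <- sample.int(.Machine$integer.max, config$n_replicates)
  know_seeds <- sample.int(.Machine$integer.max, config$n_replicates)
  learn_seeds <- sample.int(.Machine$integer.max, config$n_replicates)
  rows <- list()
  conds <- list()
  if ("none" %in% config$cases) conds[[1L]] <- list(case = "none", v = 0)
  for (v in config$v_values)
    for (case in setdiff(config$cases, "none"))
      conds[[length(conds) + 1L]] <- list(case = case, v = v)
  for (cond in conds) {
    case <- cond$case; v <- cond$v
    for (r in seq_len(config$n_replicates)) {
      row <- tryCatch({
        dat <- forward_sample(truth, config$n_samples, seed = data_seeds[r])
        items <- NULL
        if (case != "none")
          items <- simulate_experts(tg, config$accuracies, v, case,
                                    seed = know_seeds[r])
        fit <- learn_structure(dat, items, config$accuracies,
                               placement = config$placement, k = config$k,
                               tau = config$tau, alpha = config$alpha,
                               max_cond = config$max_cond,
                               prune = config$prune, params = config$params,
                               score_type = config$score_type,
                               seed = learn_seeds[r])
        d <- structural_diff(fit$structure, tg)
        data.frame(case = case, v = if (case == "none") 0 else v,
                   replicate = r, added = d$added, deleted = d$deleted,
                   inverted = d$inverted, correct = d$correct, shd = d$shd,
                   bic = bic_score(dat, fit$structure))
      }, error = function(e) {
        warning("replicate failed (", case, ", v=", v, ", r=", r, "): ",
                conditionMessage(e))
        data.frame(case = case, v = if (case == "none") 0 else v,
                   replicate = r, added = NA, deleted = NA, inverted = NA,
                   correct = NA, shd = NA, bic = NA)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  results <- do.call(rbind, rows)
  agg <- lapply(split(results, list(results$case, results$v), drop = TRUE),
                function(d) {
    d <- d[!is.na(d$shd), , drop = FALSE]
    if (nrow(d) == 0L) return(NULL)
    data.frame(case = d$case[1L], v = d$v[1L], n_ok = nrow(d),
               mr_shd = mean(d$shd), mr_deleted = mean(d$deleted),
               mr_added = mean(d$added), mr_inverted = mean(d$inverted),
               mr_correct = mean(d$correct), mr_bic = mean(d$bic),
               br_shd = min(d$shd), br_bic = max(d$bic))
  })
  summary <- do.call(rbind, agg)
  rownames(summary) <- NULL
  list(results = results, summary = summary)
}

#' Write a run summary as TSV
#' @param summary the `summary` element of [run_experiment()] output.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
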