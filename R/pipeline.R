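#' Run the full two-wave analysis pipeline
#'
#' Orchestrates ingest (or simulation), circle statistics, community
#' detection, reciprocity and balance over a two-wave network pair, writing
#' one CSV/JSON report per stage plus a run manifest. Every stage draws its
#' RNG stream from a sub-seed derived from the global seed and the stage
#' name, so the whole bundle is deterministic given the configuration and
#' toggling one stage never changes another's output.
#'
#' @param config either a path to a YAML file or a list with entries:
#'   * `seed`: global integer seed (required);
#'   * exactly one of `generator` (arguments for [generator_config()]) or
#'     `inputs` (list with `roster` and `nominations` file paths);
#'   * `stages`: character subset of `c("circles", "communities",
#'     "reciprocity", "balance")` (default all);
#'   * optional per-stage parameter lists `circles` (`scope`, `direction`,
#'     `sign`), `communities` (`n_restarts`), `reciprocity` (`n_samples`,
#'     `mode`), `balance` (`criterion`, `n_realizations`).
#' @param outdir output directory, created if needed.
#' @return invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) stop_validation("config must set a seed")
  has_gen <- !is.null(config$generator)
  has_inp <- !is.null(config$inputs)
  if (has_gen == has_inp) {
    stop_validation("config must provide exactly one of 'generator' or 'inputs'")
  }
  stages <- config$stages %||% c("circles", "communities", "reciprocity",
                                 "balance")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  manifest <- list(package_version = as.character(utils::packageVersion("signedcircles")),
                   seed = seed, stages = stages, config = config,
                   sub_seeds = list(), skipped = list())
  results <- list()
  write_json <- function(x, name) {
    jsonlite::write_json(x, file.path(outdir, name), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  # ---- ingest / simulate ----
  if (has_gen) {
    gen_args <- config$generator
    gen_args$seed <- gen_args$seed %||% stage_seed(seed, "simulate")
    cfg <- do.call(generator_config, gen_args)
    manifest$sub_seeds$simulate <- cfg$seed
    sim <- generate_pair(cfg)
    pair <- sim$pair
    utils::write.csv(pair$roster, file.path(outdir, "roster.csv"),
                     row.names = FALSE)
    utils::write.csv(sim$records, file.path(outdir, "nominations.csv"),
                     row.names = FALSE)
    write_json(list(wave1 = list(community = as.list(sim$truth$wave1$community),
                                 reciprocity = sim$truth$wave1$reciprocity),
                    wave2 = list(community = as.list(sim$truth$wave2$community),
                                 reciprocity = sim$truth$wave2$reciprocity)),
               "truth.json")
  } else {
    roster <- load_roster(config$inputs$roster)
    noms <- load_nominations(config$inputs$nominations, roster)
    pair <- network_pair(resolve_weights(noms, 1, roster),
                         resolve_weights(noms, 2, roster), roster)
  }
  results$pair <- pair

  # ---- circles ----
  if ("circles" %in% stages) {
    p <- config$circles %||% list()
    scope <- p$scope %||% "all"; direction <- p$direction %||% "out"
    sign <- p$sign %||% "positive"
    prof1 <- circle_profiles(pair$wave1, pair$roster, 1, sign, scope, direction)
    prof2 <- circle_profiles(pair$wave2, pair$roster, 2, sign, scope, direction)
    inc <- mu_increment(pair, scope, sign, direction)
    tab <- group_mu_table(prof1, prof2, inc)
    tests <- increment_tests(inc)
    utils::write.csv(rbind(prof1, prof2),
                     file.path(outdir, "circle_profiles.csv"), row.names = FALSE)
    utils::write.csv(tab, file.path(outdir, "mu_group_table.csv"),
                     row.names = FALSE)
    write_json(list(per_group = tests$per_group, anova = tests$anova,
                    tukey = tests$tukey, skipped = tests$skipped),
               "increment_tests.json")
    results$circles <- list(profiles = list(prof1, prof2), increments = inc,
                            table = tab, tests = tests)
  }

  # ---- communities ----
  if ("communities" %in% stages) {
    p <- config$communities %||% list()
    nr <- p$n_restarts %||% 10
    sseed <- stage_seed(seed, "communities")
    manifest$sub_seeds$communities <- sseed
    fit1 <- optimize_partition(pair$wave1, n_restarts = nr, seed = sseed)
    fit2 <- optimize_partition(pair$wave2, n_restarts = nr, seed = sseed + 1L)
    flows <- community_flows(pair, fit1$partition, fit2$partition)
    mem <- data.frame(id = names(fit1$partition$membership),
                      wave1 = unname(fit1$partition$membership),
                      wave2 = unname(fit2$partition$membership[
                        names(fit1$partition$membership)]))
    utils::write.csv(mem, file.path(outdir, "memberships.csv"),
                     row.names = FALSE)
    write_json(list(
      wave1 = unclass(fit1$modularity), wave2 = unclass(fit2$modularity),
      flow = as.data.frame.matrix(flows$flow)), "communities.json")
    results$communities <- list(wave1 = fit1, wave2 = fit2, flows = flows)
  }

  # ---- reciprocity ----
  if ("reciprocity" %in% stages) {
    p <- config$reciprocity %||% list()
    ns <- p$n_samples %||% 500
    mode <- p$mode %||% "outdegree_preserving"
    sseed <- stage_seed(seed, "reciprocity")
    manifest$sub_seeds$reciprocity <- sseed
    rep_wave <- function(net, s) {
      nd <- rewiring_null(net, n_samples = ns, seed = s, mode = mode)
      list(observed = nd$observed, null_mean = nd$mean,
           ci_low = nd$ci_low, ci_high = nd$ci_high, n_samples = nd$n_samples)
    }
    rr <- list(wave1 = rep_wave(pair$wave1, sseed),
               wave2 = rep_wave(pair$wave2, sseed + 1L))
    write_json(rr, "reciprocity.json")
    results$reciprocity <- rr
  }

  # ---- balance ----
  if ("balance" %in% stages) {
    p <- config$balance %||% list()
    criterion <- p$criterion %||% "b"
    nreal <- p$n_realizations %||% 1e4
    sseed <- stage_seed(seed, "balance")
    manifest$sub_seeds$balance <- sseed
    bal <- list()
    for (w in 1:2) {
      net <- pair[[paste0("wave", w)]]
      if (!any(net$edges$weight < 0)) {
        manifest$skipped[[paste0("balance_wave", w)]] <-
          "no negative edges; balance test skipped"
        next
      }
      g <- project_signed(net, criterion)
      bt <- permutation_balance_test(g, n_realizations = nreal,
                                     seed = sseed + w)
      bal[[paste0("wave", w)]] <- list(
        criterion = criterion, census = as.list(bt$observed$counts),
        balanced = bt$observed$balanced, unbalanced = bt$observed$unbalanced,
        null_mean = bt$null$mean, ci_low = bt$null$ci_low,
        ci_high = bt$null$ci_high, fraction_below = bt$fraction_below,
        degenerate = bt$degenerate)
    }
    if (length(bal)) write_json(bal, "balance.json")
    results$balance <- bal
  }

  write_json(manifest, "manifest.json")
  results$manifest <- manifest
  invisible(results)
}
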