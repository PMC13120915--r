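#' Assemble a pipeline run configuration
#'
#' Merges user settings over the documented defaults. Either supply paths
#' to the six input tables (`pp`, `cp`, `flavonoids`, `drugs`, `atc`,
#' `composition`, optionally `evidence` and `bioassay`) or leave them
#' `NULL` to run on synthetic data generated from `sim_config`.
#'
#' @param out_dir output directory (created if missing).
#' @param inputs named list of input table paths (see Details), or `NULL`
#'   to simulate.
#' @param sim_config a `synthetic_config` used when simulating (default:
#'   `synthetic_config(seed = seed)`).
#' @param min_score combined-score threshold (default 700).
#' @param alpha enrichment significance level (default 0.05).
#' @param quantile high-confidence correlation quantile (default 0.05).
#' @param sweep quantile ladder for the sensitivity sweep.
#' @param transform potency transform for the concordance stage.
#' @param seed integer seed for every stochastic stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       inputs = NULL,
                       sim_config = NULL,
                       min_score = 700L,
                       alpha = 0.05,
                       quantile = 0.05,
                       sweep = c(0.01, 0.05, 0.10),
                       transform = "neg_log10_lc50",
                       seed = 1L) {
  if (!(min_score >= 0 && min_score <= 1000)) {
    fa_stop("min_score must lie in [0, 1000]")
  }
  if (!(alpha > 0 && alpha < 1)) fa_stop("alpha must lie in (0, 1)")
  if (!(quantile > 0 && quantile < 1)) fa_stop("quantile must lie in (0, 1)")
  if (is.null(sim_config)) sim_config <- synthetic_config(seed = seed)
  structure(list(out_dir = out_dir, inputs = inputs,
                 sim_config = sim_config, min_score = min_score,
                 alpha = alpha, quantile = quantile, sweep = sweep,
                 transform = transform, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [run_config()]; unknown keys
#' are an error. Synthetic-generator settings go under `sim_config` and
#' are passed to [synthetic_config()].
#'
#' @param path YAML file.
#' @param out_dir overrides the file's `out_dir` when non-`NULL`.
#' @return a `run_config`.
#' @export
load_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  known <- c("out_dir", "inputs", "sim_config", "min_score", "alpha",
             "quantile", "sweep", "transform", "seed")
  bad <- setdiff(names(y), known)
  if (length(bad)) fa_stop("unknown config key(s): ",
                           paste(bad, collapse = ", "))
  if (!is.null(out_dir)) y$out_dir <- out_dir
  if (!is.null(y$sim_config)) {
    y$sim_config <- do.call(synthetic_config, y$sim_config)
  }
  do.call(run_config, y)
}

# internal: run one stage, aborting with the stage name on failure
fa_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    fa_stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the complete analysis pipeline
#'
#' Executes build -> enrich -> food-map -> evidence in order, writing every
#' intermediate table under `config$out_dir` together with a
#' `topology.json` summary and a `manifest.json` recording the effective
#' configuration, seed, package version and the row count of every
#' artifact. Rerunning with an identical configuration reproduces
#' identical outputs.
#'
#' @param config a `run_config` (or a path to a YAML file for
#'   [load_run_config()]).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config[setdiff(names(config), "sim_config")],
                   seed = config$seed,
                   package_version = as.character(packageVersion("flavatlas")),
                   inputs = list(), outputs = list())
  p <- function(f) file.path(config$out_dir, f)
  count <- function(x) if (is.matrix(x)) nrow(x) else NROW(x)

  # ---- stage: inputs (read or simulate) -------------------------------
  sim <- is.null(config$inputs)
  dat <- fa_stage(if (sim) "simulate" else "read-inputs", {
    if (sim) {
      gen <- generate_interactome(config$sim_config, seed = config$seed)
      foods <- generate_foods(config$sim_config, gen$truth,
                              seed = config$seed + 1L)
      flavonoids <- gen$truth$flavonoids
      drugs <- gen$truth$drugs
      write_results_table(gen$pp, p("pp_links.tsv"))
      write_results_table(gen$cp, p("cp_links.tsv"))
      write_results_table(gen$atc, p("atc.tsv"))
      write_results_table(composition_table(foods), p("composition.tsv"))
      writeLines(flavonoids, p("flavonoids.txt"))
      writeLines(drugs, p("drugs.txt"))
      list(pp = gen$pp, cp = gen$cp,
           atc = fa_expand_atc(gen$atc),
           foods = foods, flavonoids = flavonoids, drugs = drugs,
           evidence = NULL, bioassay = NULL, truth = gen$truth)
    } else {
      inp <- config$inputs
      for (req in c("pp", "cp", "flavonoids", "drugs", "atc",
                    "composition")) {
        if (is.null(inp[[req]]) || !file.exists(inp[[req]])) {
          fa_stop("missing input table: ", req)
        }
      }
      flavonoids <- readLines(inp$flavonoids)
      atc <- read_atc_table(inp$atc)
      list(pp = read_interaction_table(inp$pp, "string_links"),
           cp = read_interaction_table(inp$cp, "stitch_links"),
           atc = atc,
           foods = NULL,  # needs the flavonoid universe, read below
           flavonoids = flavonoids,
           drugs = readLines(inp$drugs),
           evidence = if (!is.null(inp$evidence))
             read_evidence_table(inp$evidence) else NULL,
           bioassay = if (!is.null(inp$bioassay))
             read_bioassay_table(inp$bioassay) else NULL,
           truth = NULL,
           composition_path = inp$composition)
    }
  })
  manifest$inputs <- list(pp = count(dat$pp), cp = count(dat$cp),
                          atc = count(dat$atc),
                          flavonoids = length(dat$flavonoids),
                          drugs = length(dat$drugs))

  # ---- stage: build-network -------------------------------------------
  net <- fa_stage("build-network", {
    pp <- filter_by_score(dat$pp, config$min_score)
    cp <- filter_by_score(dat$cp, config$min_score)
    build_master_network(pp, cp, dat$flavonoids, dat$drugs)
  })
  topo <- topology_summary(net)
  write_network(net, p("network_edges.tsv"), p("network_nodes.tsv"))
  jsonlite::write_json(unclass(topo), p("topology.json"),
                       auto_unbox = TRUE, digits = NA)

  # ---- stage: enrich ---------------------------------------------------
  fit <- fa_stage("enrich", {
    if (is.null(dat$atc)) fa_stop("missing ATC table")
    enrich_all(net, dat$atc, alpha = config$alpha)
  })
  write_results_table(fit$tests, p("enrichment.tsv"))

  # ---- stage: food-map -------------------------------------------------
  if (is.null(dat$foods)) {
    dat$foods <- fa_stage("food-map", read_food_composition(
      dat$composition_path, flavonoid_universe = dat$flavonoids))
  }
  scores <- fa_stage("food-map",
                     predict(fit, dat$foods, quantile = config$quantile))
  write_results_table(as.data.frame(scores), p("food_atc.tsv"))
  sweep_tab <- fa_stage("food-map",
                        threshold_sweep(scores, config$sweep,
                                        reference = config$quantile))
  write_results_table(sweep_tab, p("sweep.tsv"))
  rho_mat <- score_matrix(scores)
  for (axis in c("foods", "categories")) {
    hc <- tryCatch(suppressWarnings(cluster_profiles(rho_mat, axis)),
                   error = function(e) NULL)
    if (!is.null(hc)) {
      write_cluster_newick(hc, p(paste0("clusters_", axis, ".nwk")))
    }
  }

  # ---- stage: evidence -------------------------------------------------
  ev <- fa_stage("evidence", {
    if (!is.null(dat$evidence)) dat$evidence
    else generate_evidence(scores, config$sim_config,
                           seed = config$seed + 2L)
  })
  write_results_table(ev, p("evidence.tsv"))
  supp <- fa_stage("evidence",
                   support_rates(scores, ev, group_by = "atc_code"))
  write_results_table(supp, p("support.tsv"))

  conc <- fa_stage("evidence", {
    top_cat <- fit$tests$atc_code[fit$tests$level == 2L][
      which.min(fit$tests$p[fit$tests$level == 2L])]
    strengths <- setNames(fit$strength[, top_cat], rownames(fit$strength))
    assays <- if (!is.null(dat$bioassay)) dat$bioassay
              else generate_bioassay(strengths, seed = config$seed + 3L)
    res <- prediction_potency_concordance(strengths, assays,
                                          transform = config$transform)
    jsonlite::write_json(
      list(atc_code = top_cat, pearson_r = res$pearson_r,
           r_squared = res$r_squared, p_value = res$p_value,
           n_pairs = nrow(res$pairs), n_censored = res$n_censored,
           transform = res$transform),
      p("concordance.json"), auto_unbox = TRUE, digits = NA)
    res
  })

  outputs <- c("network_edges.tsv", "network_nodes.tsv", "enrichment.tsv",
               "food_atc.tsv", "sweep.tsv", "evidence.tsv", "support.tsv")
  manifest$outputs <- lapply(setNames(outputs, outputs), function(f) {
    nrow(read_results_table(p(f)))
  })
  manifest$topology <- unclass(topo)
  manifest$concordance <- list(r = conc$pearson_r,
                               r_squared = conc$r_squared)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
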