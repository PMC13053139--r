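#' Pipeline configuration
#'
#' One config drives the full analysis: simulate (or load) the paired
#' matrices, group samples into conditions, screen sample correlations,
#' ordinate and test community structure, rank taxa by network degree, fit
#' the chain graphs and run the keystone robustness ensembles. Exactly one
#' of `synthetic` / `input` must be active. Defaults mirror the
#' conventional constants of the workflow: top-15 by degree, top-10
#' prevalence, r > 0.8 correlation screen, 999 PERMANOVA permutations, 100
#' robustness permutations with 14 companions and a 0.90 threshold
#' quantile.
#'
#' @param synthetic a [synthetic_config()], or `NULL` when reading files.
#' @param input `NULL`, or a list with paths `abundance_dna`,
#'   `abundance_rna`, `metadata`, and optional `taxonomy` and
#'   `orientation`.
#' @param out_dir output directory for all stage artifacts.
#' @param seed master seed; every stochastic stage derives its own stream.
#' @param correlation_threshold screen cut-off.
#' @param permanova_terms model terms in fitting order.
#' @param permanova_n_perm PERMANOVA permutations.
#' @param prevalence_k taxa per condition in the prevalence report.
#' @param top_k taxa selected by degree for the chain graph.
#' @param stars_subsamples,stars_beta StARS settings.
#' @param predictors chain-graph predictors (default: the nine sonde
#'   variables).
#' @param chain_lambda_b,chain_lambda_omega fixed chain-graph penalties, or
#'   `NULL` for BIC selection.
#' @param robustness_n_perm,robustness_companions,robustness_quantile,robustness_cutoff
#'   robustness-ensemble settings.
#' @param focal_taxa taxa to evaluate; `NULL` picks the most- and
#'   least-connected of the top-k as contrasting foci.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(), input = NULL,
                            out_dir = tempfile("keystonet_run_"), seed = 1,
                            correlation_threshold = 0.8,
                            permanova_terms = c("depth_m", "month", "oxygen"),
                            permanova_n_perm = 999,
                            prevalence_k = 10, top_k = 15,
                            stars_subsamples = 50, stars_beta = 0.05,
                            predictors = NULL,
                            chain_lambda_b = NULL, chain_lambda_omega = NULL,
                            robustness_n_perm = 100,
                            robustness_companions = 14,
                            robustness_quantile = 0.90,
                            robustness_cutoff = 30,
                            focal_taxa = NULL) {
  if (!is.null(synthetic) && !is.null(input))
    stop("exactly one of `synthetic` and `input` must be set")
  if (is.null(synthetic) && is.null(input))
    stop("one of `synthetic` and `input` must be set")
  if (!is.null(input)) {
    need <- c("abundance_dna", "abundance_rna", "metadata")
    miss <- setdiff(need, names(input))
    if (length(miss)) stop("input missing path(s): ", paste(miss, collapse = ", "))
    for (f in intersect(c(need, "taxonomy"), names(input)))
      if (!file.exists(input[[f]])) stop("input path does not exist: ", input[[f]])
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline config from YAML or JSON
#'
#' Top-level keys match the arguments of [pipeline_config()]; a `synthetic`
#' mapping is passed to [synthetic_config()].
#'
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$synthetic))
    raw$synthetic <- do.call(synthetic_config, raw$synthetic)
  do.call(pipeline_config, raw)
}

config_hash <- function(cfg) {
  flat <- utils::capture.output(utils::str(cfg[setdiff(names(cfg), "out_dir")]))
  h <- 2166136261
  for (ch in utf8ToInt(paste(flat, collapse = "\n")))
    h <- (h * 16777619 + ch) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: load/simulate -> condition grouping -> correlation
#' screen -> Bray-Curtis / PCoA / PERMANOVA (with pairwise contrasts) ->
#' top-k prevalence -> co-occurrence network with StARS -> degree top-k ->
#' chain graphs on the DNA and RNA layers -> robustness ensembles for the
#' focal taxa -> layer-comparison report. All artifacts are written under
#' `cfg$out_dir`; identical config + seed reproduces identical numeric
#' outputs. Any stage failure aborts with the stage name.
#'
#' @param cfg a [pipeline_config()].
#' @return A run manifest (invisible list): config hash, per-stage outputs
#'   and wall-clock seconds, and the seed ledger.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                   stages = list(), files = character(0),
                   versions = list(keystonet = as.character(utils::packageVersion("keystonet")),
                                   R = paste(R.version$major, R.version$minor, sep = ".")))
  seed_ledger <- list()
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }
  out <- function(name) {
    p <- file.path(cfg$out_dir, name)
    manifest$files <<- union(manifest$files, name)
    p
  }
  wtsv <- function(df, name) utils::write.table(df, out(name), sep = "\t",
                                                quote = FALSE, row.names = FALSE)

  dat <- stage("load", function() {
    if (!is.null(cfg$synthetic)) {
      sim <- simulate_dataset(cfg$synthetic)
      write_synthetic_dataset(sim, cfg$out_dir)
      manifest$files <<- union(manifest$files,
                               c("abundance_dna.tsv", "abundance_rna.tsv",
                                 "metadata.tsv", "taxonomy.tsv", "truth.json"))
      sim
    } else {
      ori <- if (is.null(cfg$input$orientation)) "sample_major" else cfg$input$orientation
      list(dna = read_abundance_table(cfg$input$abundance_dna, ori, "dna"),
           rna = read_abundance_table(cfg$input$abundance_rna, ori, "rna"),
           meta = read_sample_metadata(cfg$input$metadata),
           taxonomy = if (!is.null(cfg$input$taxonomy))
             read_taxonomy(cfg$input$taxonomy) else NULL,
           network = NULL)
    }
  })

  groups <- stage("grouping", function() {
    g <- assign_condition_groups(dat$meta)
    wtsv(condition_sizes(g), "condition_sizes.tsv")
    g
  })

  tss <- tss_normalise(dat$dna)
  stage("correlation_screen", function() {
    wtsv(sample_correlation_screen(tss, threshold = cfg$correlation_threshold),
         "correlation_pairs.tsv")
  })

  community <- stage("community", function() {
    hel <- hellinger_transform(dat$dna)
    d <- bray_curtis(hel)
    utils::write.table(data.frame(sample_id = d$sample_ids, d$values,
                                  check.names = FALSE),
                       out("bray_curtis.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    ord <- pcoa(d)
    wtsv(data.frame(sample_id = rownames(ord$coordinates), ord$coordinates,
                    check.names = FALSE), "pcoa_coordinates.tsv")
    wtsv(data.frame(axis = seq_along(ord$variance_explained),
                    variance_explained = ord$variance_explained),
         "pcoa_variance.tsv")
    fit <- permanova(d, dat$meta, cfg$permanova_terms,
                     n_perm = cfg$permanova_n_perm,
                     seed = derive_seed(cfg$seed, "permanova"))
    wtsv(fit$table, "permanova.tsv")
    pw <- do.call(rbind, lapply(c("depth_m", "month", "oxygen"), function(f) {
      lv <- unique(dat$meta[[f]])
      if (length(lv) < 2) return(NULL)
      suppressWarnings(cbind(factor_name = f,
            pairwise_permanova(d, dat$meta, f, n_perm = cfg$permanova_n_perm,
                               seed = derive_seed(cfg$seed, paste0("pairwise_", f)))))
    }))
    wtsv(pw, "pairwise_permanova.tsv")
    list(dist = d, ordination = ord, permanova = fit)
  })

  stage("prevalence", function() {
    rep <- top_taxa_prevalence(tss, groups, k = cfg$prevalence_k)
    wtsv(rep$top_taxa, "top_taxa.tsv")
    wtsv(rep$prevalence, "prevalence.tsv")
  })

  net <- stage("network", function() {
    nw <- spiec_easi_network(dat$dna, stars_subsamples = cfg$stars_subsamples,
                             stars_beta = cfg$stars_beta,
                             seed = derive_seed(cfg$seed, "stars"))
    export_network(nw, out("cooccurrence_edges.tsv"), "edge_tsv")
    export_network(nw, out("cooccurrence.graphml"), "graphml",
                   taxonomy = dat$taxonomy)
    nw
  })

  ranking <- degree_rank(net)
  wtsv(ranking, "degree_ranking.tsv")
  top <- select_top_k(ranking, cfg$top_k)
  writeLines(top, out("top_taxa_by_degree.txt"))

  chains <- stage("chain_graph", function() {
    lapply(list(dna = dat$dna, rna = dat$rna), function(mm) {
      sub <- abundance_matrix(mm$values[, top, drop = FALSE], layer = mm$layer,
                              normalisation = "raw")
      g <- fit_chain_graph(sub, dat$meta, predictor_names = cfg$predictors,
                           lambda_b = cfg$chain_lambda_b,
                           lambda_omega = cfg$chain_lambda_omega,
                           seed = derive_seed(cfg$seed, paste0("chain_", mm$layer)))
      export_network(g, out(paste0("chain_graph_", mm$layer, ".tsv")), "edge_tsv")
      export_network(g, out(paste0("chain_graph_", mm$layer, ".graphml")),
                     "graphml", taxonomy = dat$taxonomy)
      g
    })
  })

  focal <- cfg$focal_taxa
  if (is.null(focal)) focal <- unique(c(top[1], top[length(top)]))

  results <- stage("robustness", function() {
    lapply(focal, function(f) {
      ens <- lapply(c("dna", "rna"), function(layer) {
        mm <- dat[[layer]]
        sd_l <- derive_seed(cfg$seed, paste0("robustness_", layer, "_", f))
        seed_ledger[[paste0("robustness_", layer, "_", f)]] <<- sd_l
        e <- run_permutation_ensemble(
          f, setdiff(taxon_ids(mm), f), mm, dat$meta,
          n_perm = cfg$robustness_n_perm,
          n_companions = cfg$robustness_companions,
          quantile = cfg$robustness_quantile,
          chain_cfg = list(predictor_names = cfg$predictors,
                           lambda_b = cfg$chain_lambda_b,
                           lambda_omega = cfg$chain_lambda_omega),
          seed = sd_l)
        wtsv(ensemble_summary(e), paste0("ensemble_", layer, "_", f, ".tsv"))
        e
      })
      compare_layers(ens[[1]], ens[[2]], cutoff = cfg$robustness_cutoff)
    })
  })

  stage("report", function() {
    rep <- list(top_taxa_by_degree = top,
                focal = lapply(results, function(r)
                  list(focal_id = r$focal_id, index_dna = r$index_dna,
                       index_rna = r$index_rna,
                       classification = r$classification,
                       cutoff = r$cutoff)))
    jsonlite::write_json(rep, out("robustness_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  manifest$seed_ledger <- seed_ledger
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
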