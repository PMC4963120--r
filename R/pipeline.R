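#' Assemble a full pipeline configuration
#'
#' Bundles every stage's parameters: input paths, discretization technique,
#' GA settings, bicluster filters, detector choice and the evaluation
#' threshold. A single top-level `seed` drives all randomness.
#'
#' @param expression Path to the expression TSV (see
#'   [read_expression_matrix()]).
#' @param ppi Path to the PPI edge-list/SIF file.
#' @param outdir Output directory (created if needed).
#' @param benchmark Optional path to a gold-standard complex file.
#' @param discretization Named list: `technique` plus its parameters
#'   (default mean/sd bands with `alpha_disc = 1`, three-letter alphabet).
#' @param ga A [ga_config()]; its seed is overridden by `seed`.
#' @param detector Named list with `name` (registered detector) and
#'   `params`.
#' @param delta Jaccard match threshold for evaluation (default 0.25).
#' @param filters Named list: `min_genes`, `min_conditions`,
#'   `min_dcm_fraction`, `overlap_threshold`, `min_complex_size`.
#' @param seed Integer master seed.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(expression, ppi, outdir, benchmark = NULL,
                            discretization = list(technique = "mean_sd",
                                                  alpha_disc = 1),
                            ga = ga_config(), detector = list(
                              name = "greedy_density", params = list()),
                            delta = 0.25,
                            filters = list(min_genes = 3, min_conditions = 2,
                                           min_dcm_fraction = 0.5,
                                           overlap_threshold = 0.75,
                                           min_complex_size = 3),
                            seed = 1) {
  defaults <- list(min_genes = 3, min_conditions = 2, min_dcm_fraction = 0.5,
                   overlap_threshold = 0.75, min_complex_size = 3)
  filters <- utils::modifyList(defaults, filters)
  ga$seed <- as.integer(seed)
  structure(list(expression = expression, ppi = ppi, benchmark = benchmark,
                 outdir = outdir, discretization = discretization, ga = ga,
                 detector = detector, delta = delta, filters = filters,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat YAML mirroring the [pipeline_config()] arguments; unspecified
#' fields keep their defaults.
#'
#' @param path YAML file path.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (req in c("expression", "ppi", "outdir")) {
    if (is.null(y[[req]])) abort(sprintf("config '%s': missing '%s'", path, req))
  }
  ga <- do.call(ga_config, y$ga %||% list())
  args <- list(expression = y$expression, ppi = y$ppi, outdir = y$outdir,
               benchmark = y$benchmark, ga = ga, seed = y$seed %||% 1)
  if (!is.null(y$discretization)) args$discretization <- y$discretization
  if (!is.null(y$detector)) args$detector <- y$detector
  if (!is.null(y$delta)) args$delta <- y$delta
  if (!is.null(y$filters)) args$filters <- y$filters
  do.call(pipeline_config, args)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[stage %s] %s", stage, conditionMessage(e)))
  })
}

# The provenance hash covers the analysis configuration only, not the
# filesystem locations, so equal analyses hash equally wherever they run.
config_hash <- function(cfg) {
  rlang::hash(cfg[c("discretization", "ga", "detector", "delta", "filters",
                    "seed")])
}

file_header <- function(cfg) {
  sprintf("dynbic %s config=%s seed=%d",
          as.character(utils::packageVersion("dynbic")),
          config_hash(cfg), cfg$seed)
}

#' Run the full dynamic complex-detection pipeline
#'
#' Executes every stage in order: read expression and PPI inputs,
#' discretize, evolve biclusters, filter and deduplicate them, prune the
#' network to the expression genes, extract one dynamic subnetwork per
#' bicluster, classify stable/transient interactions, run the configured
#' detector on every subnetwork, aggregate and size-filter the predicted
#' complexes, and — when a benchmark is configured — prune it to the network
#' and score precision/recall/F1. All intermediates are written under
#' `outdir` with a provenance header (package version, config hash, seed);
#' the run is fully determined by the configuration.
#'
#' @param cfg A `"pipeline_config"`.
#' @return A list with `biclusters`, `subnetworks`, `interactions`,
#'   `complexes`, `evaluation` (`NULL` without a benchmark) and `files`
#'   (named paths of everything written).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t0 <- Sys.time()
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf("[%6.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                   sprintf(fmt, ...))
    inform(msg)
    log_lines <<- c(log_lines, msg)
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- file_header(cfg)

  M <- with_stage("read_expression", read_expression_matrix(cfg$expression))
  net <- with_stage("read_ppi", read_ppi(cfg$ppi))
  say("inputs: %d genes x %d time-points; network %d proteins / %d edges",
      nrow(M), ncol(M), length(net$proteins), nrow(net$edges))

  disc_args <- cfg$discretization
  technique <- disc_args$technique %||% "mean_sd"
  disc_args$technique <- NULL
  Md <- with_stage("discretize",
                   do.call(discretize, c(list(M, technique = technique),
                                         disc_args)))
  files <- list(discretized = file.path(cfg$outdir, "discretized.tsv"))
  write_discretized(Md, files$discretized)

  fit <- with_stage("biclustering", run_ga(Md, cfg$ga))
  say("GA harvested %d bicluster(s); best DCM %.3f", nrow(fit$biclusters),
      if (nrow(fit$biclusters)) fit$biclusters$dcm[1] else NA_real_)
  bics <- with_stage("bicluster_filtering", remove_redundant(
    filter_biclusters(fit, cfg$filters$min_genes, cfg$filters$min_conditions,
                      cfg$filters$min_dcm_fraction),
    cfg$filters$overlap_threshold))
  bics$bicluster_id <- seq_len(nrow(bics))
  say("%d bicluster(s) after filtering and redundancy removal", nrow(bics))
  files$biclusters <- file.path(cfg$outdir, "biclusters.txt")
  write_biclusters(bics, files$biclusters, comments = hdr)

  pruned <- with_stage("prune_network",
                       suppressMessages(prune_to_genes(net, rownames(M))))
  subs <- with_stage("extract_subnetworks", extract_subnetworks(pruned, bics))
  subdir <- file.path(cfg$outdir, "subnetworks")
  dir.create(subdir, showWarnings = FALSE)
  index <- tibble(bicluster_id = vapply(subs, `[[`, integer(1), "bicluster_id"),
                  file = sprintf("subnetwork_%d.tsv",
                                 vapply(subs, `[[`, integer(1), "bicluster_id")))
  for (i in seq_along(subs)) {
    write_ppi(subs[[i]], file.path(subdir, index$file[i]), comments = hdr)
  }
  files$subnetwork_index <- file.path(subdir, "index.tsv")
  writeLines(c(paste0("# ", hdr), "bicluster_id\tfile",
               sprintf("%d\t%s", index$bicluster_id, index$file)),
             files$subnetwork_index, useBytes = TRUE)

  interactions <- if (length(subs)) classify_interactions(subs) else
    tibble(protein_a = character(0), protein_b = character(0),
           support = integer(0), label = character(0))
  files$interactions <- file.path(cfg$outdir, "interactions.tsv")
  writeLines(c(paste0("# ", hdr), "protein_a\tprotein_b\tsupport\tlabel",
               sprintf("%s\t%s\t%d\t%s", interactions$protein_a,
                       interactions$protein_b, interactions$support,
                       interactions$label)),
             files$interactions, useBytes = TRUE)

  detected <- with_stage("detection",
                         detect_on_all(subs, cfg$detector$name %||% "greedy_density",
                                       cfg$detector$params %||% list()))
  complexes <- with_stage("aggregation",
                          filter_min_size(aggregate_complexes(detected),
                                          cfg$filters$min_complex_size))
  say("%d complex(es) after aggregation and size filtering", nrow(complexes))
  files$complexes <- file.path(cfg$outdir, "complexes.txt")
  write_complexes(complexes, files$complexes, comments = hdr)

  evaluation <- NULL
  if (!is.null(cfg$benchmark)) {
    gold <- with_stage("read_benchmark", read_complexes(cfg$benchmark))
    gold <- with_stage("prune_benchmark",
                       prune_benchmark(gold, pruned$proteins,
                                       cfg$filters$min_complex_size))
    evaluation <- with_stage("evaluation",
                             evaluate_complexes(complexes, gold, cfg$delta))
    say("evaluation: precision %.3f recall %.3f f1 %.3f",
        evaluation$precision, evaluation$recall, evaluation$f1)
    files$evaluation <- file.path(cfg$outdir, "evaluation.tsv")
    write_evaluation(evaluation, files$evaluation, comments = hdr)
  }

  files$summary <- file.path(cfg$outdir, "summary.yaml")
  yaml::write_yaml(list(
    tool = "dynbic", version = as.character(utils::packageVersion("dynbic")),
    config_hash = config_hash(cfg), seed = cfg$seed,
    n_biclusters = nrow(bics), n_subnetworks = length(subs),
    n_complexes = nrow(complexes),
    evaluation = if (!is.null(evaluation)) as.list(as.data.frame(evaluation))
  ), files$summary)
  files$log <- file.path(cfg$outdir, "pipeline.log")
  writeLines(log_lines, files$log)

  list(biclusters = bics, subnetworks = subs, interactions = interactions,
       complexes = complexes, evaluation = evaluation, files = files)
}

#' Write a synthetic study (expression, PPI, truth files) to disk
#'
#' Generates a planted-truth data set with [gen_expression()] and
#' [gen_ppi()] and writes the four files the pipeline and external tools
#' consume: `expression.tsv`, `ppi.tsv`, `truth_biclusters.txt` (bicluster
#' format) and `truth_complexes.txt` (complex format).
#'
#' @param outdir Output directory.
#' @param seed Integer seed.
#' @param ... Passed to [gen_expression()] (`m`, `n`, `truth_spec`,
#'   `noise_sd`, ...).
#' @param ppi_args Named list passed to [gen_ppi()].
#' @return Named list of written paths plus the generated objects,
#'   invisibly.
#' @export
write_synthetic_study <- function(outdir, seed = 1, ..., ppi_args = list()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- gen_expression(..., seed = seed)
  ppi <- do.call(gen_ppi, c(list(truth = sim$truth, seed = seed), ppi_args))
  paths <- list(expression = file.path(outdir, "expression.tsv"),
                ppi = file.path(outdir, "ppi.tsv"),
                truth_biclusters = file.path(outdir, "truth_biclusters.txt"),
                truth_complexes = file.path(outdir, "truth_complexes.txt"))
  write_expression_matrix(sim$expression, paths$expression)
  write_ppi(ppi$network, paths$ppi, comments = sprintf("synthetic seed=%d", seed))
  tb <- ppi$truth$biclusters
  write_biclusters(tibble(bicluster_id = tb$bicluster, genes = tb$genes,
                          conditions = tb$conditions,
                          dcm = rep(NA_real_, nrow(tb))),
                   paths$truth_biclusters,
                   comments = sprintf("synthetic planted biclusters seed=%d", seed))
  write_complexes(ppi$truth$complexes$proteins, paths$truth_complexes,
                  comments = sprintf("synthetic planted complexes seed=%d", seed))
  invisible(c(paths, list(expression_matrix = sim$expression,
                          network = ppi$network, truth = ppi$truth)))
}
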