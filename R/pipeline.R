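#' Configure the two-group analysis pipeline
#'
#' Collects every tunable of the end-to-end analysis.  Input is either a
#' named list of two single-group `measure_table`s (`tables`) or, when
#' `tables` is `NULL`, two group specs to simulate from (`specs`, default
#' [asd_td_specs()]).  All randomness (simulation, bootstrap resampling,
#' community-detection restarts) is derived from the single root `seed`.
#'
#' @param tables Named list of two `measure_table`s, or `NULL` to simulate.
#' @param specs Named list of two [group_spec()]s used when `tables` is
#'   `NULL`.
#' @param filter_alpha Significance level of the correlation filter.
#' @param alpha Family-wise level for the group comparisons.
#' @param grid_size Graphical-lasso penalty-grid size.
#' @param B Bootstrap replicates per group.
#' @param bootstrap Run the bootstrap comparison at all?
#' @param restarts Louvain restarts.
#' @param closeness_variant `"average"` or `"inverse_total"`.
#' @param z_denominator `"sd"` (calibrated) or `"se"` (see
#'   [centrality_z_test()]).
#' @param seed Root seed.
#' @param output_dir If non-`NULL`, artifacts are written there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tables = NULL, specs = asd_td_specs(),
                            filter_alpha = 0.05, alpha = 0.05,
                            grid_size = 100, B = 1000, bootstrap = TRUE,
                            restarts = 20, closeness_variant = "average",
                            z_denominator = "sd",
                            seed = 1, output_dir = NULL) {
  if (filter_alpha <= 0 || filter_alpha >= 1 || alpha <= 0 || alpha >= 1)
    stop("alpha levels must lie in (0, 1)")
  if (!is.null(tables)) {
    stopifnot(length(tables) == 2)
    ok <- vapply(tables, inherits, logical(1), "measure_table")
    if (!all(ok)) stop("`tables` must contain two measure_table objects")
  }
  structure(list(tables = tables, specs = specs,
                 filter_alpha = filter_alpha, alpha = alpha,
                 grid_size = grid_size, B = B, bootstrap = bootstrap,
                 restarts = restarts,
                 closeness_variant = closeness_variant,
                 z_denominator = z_denominator,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  keep <- config[setdiff(names(config), "output_dir")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(keep), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full two-group network analysis
#'
#' For each group: estimate the regularized partial-correlation network,
#' compute node centralities, detect communities; then bootstrap both
#' groups, compare centralities with Bonferroni-adjusted z tests, and run
#' the descriptive score comparisons.  With `output_dir` set, every
#' artifact (tables, edge lists, GraphML, centrality and partition CSVs,
#' the JSON report) is written to disk.  Reruns with the same config are
#' deterministic.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report`: list with `groups` (per group: `table`,
#'   `network`, `centrality`, `communities`), `comparison`, `descriptives`
#'   and `provenance`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(B = 20, grid_size = 40, seed = 42)
#' rep <- run_pipeline(cfg)
#' rep$groups$ASD$communities
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", what, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.null(config$tables)) {
    tabs <- stage("simulate", lapply(seq_along(config$specs), function(i)
      generate_group_sample(config$specs[[i]],
                            seed = derive_seed(config$seed, 1L, i))))
    names(tabs) <- vapply(config$specs, `[[`, character(1), "label")
  } else {
    tabs <- config$tables
    if (is.null(names(tabs)))
      names(tabs) <- vapply(tabs, function(t) unique(t$group)[1], character(1))
  }

  groups <- list()
  for (i in seq_along(tabs)) {
    g <- names(tabs)[i]
    net <- stage(paste0("estimate[", g, "]"),
                 estimate_network(tabs[[i]], alpha = config$filter_alpha,
                                  grid_size = config$grid_size))
    prof <- stage(paste0("centrality[", g, "]"),
                  centrality_profile(net,
                                     closeness_variant = config$closeness_variant))
    comm <- stage(paste0("communities[", g, "]"), {
      if (sum(abs(net$weights)) == 0) NULL
      else louvain(net, seed = derive_seed(config$seed, 2L, i),
                   restarts = config$restarts)
    })
    groups[[g]] <- list(table = tabs[[i]], network = net, centrality = prof,
                        communities = comm)
  }

  comparison <- NULL
  boots <- NULL
  if (config$bootstrap) {
    boots <- stage("bootstrap", lapply(seq_along(tabs), function(i)
      bootstrap_networks(tabs[[i]], B = config$B,
                         seed = derive_seed(config$seed, 3L, i),
                         alpha = config$filter_alpha,
                         grid_size = config$grid_size,
                         closeness_variant = config$closeness_variant)))
    comparison <- stage("z-test",
                        centrality_z_test(boots[[1]], boots[[2]],
                                          alpha = config$alpha,
                                          denominator = config$z_denominator))
  }
  descriptives <- stage("descriptive-tests",
                        descriptive_tests(tabs[[1]], tabs[[2]],
                                          alpha = config$alpha))

  report <- structure(
    list(groups = groups, bootstraps = boots, comparison = comparison,
         descriptives = descriptives,
         provenance = list(package = "mixedggm",
                           version = as.character(utils::packageVersion("mixedggm")),
                           seed = config$seed,
                           config_hash = config_hash(config),
                           B = config$B, restarts = config$restarts,
                           alpha = config$alpha,
                           filter_alpha = config$filter_alpha)),
    class = "pipeline_report")
  if (!is.null(config$output_dir))
    write_report(report, config$output_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report (seed ", x$provenance$seed, ", config ",
      substr(x$provenance$config_hash, 1, 8), ")\n", sep = "")
  for (g in names(x$groups)) {
    net <- x$groups[[g]]$network
    e <- sum(net$weights[upper.tri(net$weights)] != 0)
    q <- if (is.null(x$groups[[g]]$communities)) NA
         else x$groups[[g]]$communities$Q
    cat("  ", g, ": n = ", net$n, ", ", e, " edges, lambda = ",
        signif(net$lambda, 3), ", Q = ",
        if (is.na(q)) "NA (edgeless)" else signif(q, 3), "\n", sep = "")
  }
  if (!is.null(x$comparison))
    cat("  significant centrality differences: ",
        sum(x$comparison$significant, na.rm = TRUE), " of ",
        attr(x$comparison, "m"), "\n", sep = "")
  invisible(x)
}

#' Write every pipeline artifact to a directory
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in names(report$groups)) {
    gg <- report$groups[[g]]
    base <- file.path(dir, g)
    write_measure_table(gg$table, paste0(base, "_data.csv"))
    write_edge_list(gg$network, paste0(base, "_edges.csv"))
    write_network_graphml(gg$network, paste0(base, "_network.graphml"))
    write_network_json(gg$network, paste0(base, "_network.json"))
    write_centrality(gg$centrality, paste0(base, "_centrality.csv"))
    if (!is.null(gg$communities))
      write_partition(gg$communities, paste0(base, "_communities.csv"))
  }
  if (!is.null(report$comparison))
    write.csv(as.data.frame(report$comparison),
              file.path(dir, "comparison.csv"), row.names = FALSE)
  write.csv(report$descriptives, file.path(dir, "descriptives.csv"),
            row.names = FALSE)
  summary <- list(
    provenance = report$provenance,
    groups = lapply(report$groups, function(gg) list(
      n = gg$network$n,
      lambda = gg$network$lambda,
      n_edges = sum(gg$network$weights[upper.tri(gg$network$weights)] != 0),
      Q = if (is.null(gg$communities)) NULL else gg$communities$Q,
      n_communities = if (is.null(gg$communities)) NULL
                      else gg$communities$n_communities)))
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
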