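#' Read a subjects-by-measures CSV
#'
#' Expects a header row with a `group` column followed by one column per
#' declared variable.  Values are validated against the variable specs:
#' ordinal columns must be integers inside their declared range.
#'
#' @param path CSV file path.
#' @param variables List of [variable_spec()]s declaring column types.
#' @return A `measure_table`.
#' @export
read_measure_table <- function(path, variables) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"group" %in% names(df))
    stop("no 'group' column in ", path)
  nms <- vapply(variables, `[[`, character(1), "name")
  missing <- setdiff(nms, names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  measure_table(df[, c("group", nms)], variables)
}

#' Write a measure table as CSV
#' @param table A `measure_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measure_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Export a network as a weighted edge list CSV
#'
#' One row per nonzero edge: `node_i, node_j, weight`.
#'
#' @param network A `network_model`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  w <- network$weights
  idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  df <- data.frame(node_i = network$nodes[idx[, 1]],
                   node_j = network$nodes[idx[, 2]],
                   weight = w[idx])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# igraph representation; isolated nodes kept, signed weights preserved
as_igraph <- function(network) {
  igraph::graph_from_adjacency_matrix(network$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Export a network as GraphML
#'
#' Writes an undirected weighted graph (signed partial correlations in the
#' `weight` edge attribute) readable by any GraphML consumer.
#'
#' @inheritParams write_edge_list
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Export a network as JSON
#'
#' Serializes nodes, the full weight matrix, the selected penalty and the
#' fit score.
#'
#' @inheritParams write_edge_list
#' @return `path`, invisibly.
#' @export
write_network_json <- function(network, path) {
  jsonlite::write_json(
    list(nodes = network$nodes, weights = unname(network$weights),
         lambda = network$lambda, bic = network$bic, n = network$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export an association matrix
#'
#' Writes `<base>_r.csv` (correlations), `<base>_p.csv` (p-values) and
#' `<base>_meta.json` (method tags and sample size).
#'
#' @param assoc An `association_matrix`.
#' @param base Output path prefix.
#' @return The three paths, invisibly.
#' @export
write_association <- function(assoc, base) {
  paths <- paste0(base, c("_r.csv", "_p.csv", "_meta.json"))
  write.csv(assoc$r, paths[1])
  write.csv(assoc$p_value, paths[2])
  jsonlite::write_json(list(method = apply(assoc$method, 1, as.list),
                            n = assoc$n),
                       paths[3], auto_unbox = TRUE)
  invisible(paths)
}

#' Export a centrality profile as tidy CSV
#'
#' Long format: one row per node-metric pair (`node, metric, value`).
#'
#' @param profile A `centrality_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_centrality <- function(profile, path) {
  wide <- as.data.frame(profile)
  df <- data.frame(
    node = rep(wide$node, 3),
    metric = rep(c("strength", "betweenness", "closeness"),
                 each = nrow(wide)),
    value = c(wide$strength, wide$betweenness, wide$closeness))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a community partition as CSV
#' @param partition A `community_partition`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(node = names(partition$assignment),
                   community = unname(partition$assignment))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize / read a group spec as JSON
#'
#' The generating model (variables, precision, thresholds, continuous
#' scalings) round-trips through JSON so simulation configurations can be
#' stored alongside results.
#'
#' @param spec A `group_spec`.
#' @param path JSON file path.
#' @return `path` (write) or a `group_spec` (read).
#' @export
write_group_spec <- function(spec, path) {
  jsonlite::write_json(
    list(label = spec$label, n = spec$n,
         variables = lapply(spec$variables, function(v)
           list(name = v$name, kind = v$kind, levels = v$levels,
                range = v$range)),
         precision = unname(spec$precision),
         thresholds = spec$thresholds,
         continuous_scale = spec$continuous_scale),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_group_spec
#' @export
read_group_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  vars <- lapply(seq_len(nrow(x$variables)), function(i) {
    v <- x$variables[i, ]
    variable_spec(v$name, v$kind,
                  levels = if (v$kind == "ordinal") v$levels else NULL,
                  range = unlist(v$range))
  })
  group_spec(x$label, x$n, vars, as.matrix(x$precision),
             thresholds = x$thresholds,
             continuous_scale = x$continuous_scale)
}
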