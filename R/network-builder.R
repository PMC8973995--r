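#' Anti-correlation pair filter
#'
#' A predicted (sncRNA, mRNA) pair becomes a regulatory edge only when the
#' two differential-expression calls are anti-correlated: regulator up with
#' target down, or regulator down with target up. Features called `ns` never
#' contribute. Pairs whose regulator or target is missing from the DE tables
#' are dropped with a warning.
#'
#' @param de_sncrna,de_mrna [de_test()] tibbles.
#' @param predicted_pairs [predict_targets()] tibble
#'   (`sncrna_id`, `utr_id`, `best_score`).
#' @return RegulatoryEdge tibble (`regulator`, `target`,
#'   `regulator_direction`, `target_direction`, `score`).
#' @export
pair_filter <- function(de_sncrna, de_mrna, predicted_pairs) {
  snc <- dplyr::select(de_sncrna,
    regulator = "feature_id", regulator_direction = "direction"
  )
  mr <- dplyr::select(de_mrna,
    target = "feature_id", target_direction = "direction"
  )
  pairs <- dplyr::select(predicted_pairs,
    regulator = "sncrna_id", target = "utr_id", score = "best_score"
  )
  joined <- pairs |>
    dplyr::left_join(snc, by = "regulator") |>
    dplyr::left_join(mr, by = "target")
  orphan <- is.na(joined$regulator_direction) | is.na(joined$target_direction)
  if (any(orphan)) {
    warning(
      sum(orphan), " predicted pair(s) reference ids absent from the DE",
      " tables and were dropped",
      call. = FALSE
    )
    joined <- joined[!orphan, ]
  }
  joined |>
    dplyr::filter(
      (.data$regulator_direction == "up" & .data$target_direction == "down") |
        (.data$regulator_direction == "down" & .data$target_direction == "up")
    ) |>
    dplyr::select(
      "regulator", "target", "regulator_direction", "target_direction",
      "score"
    )
}

#' Build a bipartite sncRNA-mRNA regulatory network
#'
#' Nodes are regulators (miRNAs or tRF/tiRNAs) and mRNA targets; node
#' attributes carry the feature type, DE p-value and fold change,
#' transcription-factor status (mRNA nodes found in `tf_list`) and degree
#' recomputed from the edge set. Any edge joining two mRNA nodes, two
#' regulators, or a node to itself violates the bipartite contract and is an
#' error.
#'
#' @param edges RegulatoryEdge tibble from [pair_filter()].
#' @param de_sncrna,de_mrna optional [de_test()] tibbles supplying `p_value`
#'   and `fold_change` node attributes.
#' @param tf_list character vector of transcription-factor symbols.
#' @param regulator_type label for regulator nodes (e.g. `"miRNA"`,
#'   `"tRF/tiRNA"`).
#' @return an igraph object of class `trf_network` (undirected, with a
#'   `direction` edge attribute recording regulator -> target).
#' @export
build_network <- function(edges, de_sncrna = NULL, de_mrna = NULL,
                          tf_list = character(), regulator_type = "sncRNA") {
  regulators <- unique(edges$regulator)
  targets <- unique(edges$target)
  if (length(intersect(regulators, targets)) > 0 ||
    any(edges$regulator == edges$target)) {
    stop(
      "bipartite contract violated: ",
      paste(
        union(
          intersect(regulators, targets),
          edges$regulator[edges$regulator == edges$target]
        ),
        collapse = ", "
      ),
      call. = FALSE
    )
  }
  de_attr <- function(ids, de) {
    if (is.null(de)) {
      return(tibble::tibble(
        id = ids, p_value = NA_real_, fold_change = NA_real_
      ))
    }
    tibble::tibble(id = ids) |>
      dplyr::left_join(
        dplyr::select(de,
          id = "feature_id", p_value = "p_value", fold_change = "fold_change"
        ),
        by = "id"
      )
  }
  nodes <- dplyr::bind_rows(
    de_attr(regulators, de_sncrna) |>
      dplyr::mutate(node_type = regulator_type, is_tf = FALSE),
    de_attr(targets, de_mrna) |>
      dplyr::mutate(node_type = "mRNA", is_tf = .data$id %in% tf_list)
  )
  g <- igraph::graph_from_data_frame(
    d = dplyr::select(edges, "regulator", "target", "score"),
    directed = FALSE, vertices = nodes
  )
  igraph::E(g)$direction <- "regulator_to_target"
  igraph::V(g)$degree <- igraph::degree(g)
  class(g) <- c("trf_network", class(g))
  g
}

network_nodes <- function(graph) {
  tibble::tibble(
    id = igraph::V(graph)$name,
    node_type = igraph::V(graph)$node_type,
    is_tf = igraph::V(graph)$is_tf,
    p_value = igraph::V(graph)$p_value,
    fold_change = igraph::V(graph)$fold_change,
    degree = igraph::V(graph)$degree
  )
}

network_edges <- function(graph) {
  ends <- igraph::as_edgelist(graph)
  types <- stats::setNames(igraph::V(graph)$node_type, igraph::V(graph)$name)
  is_reg <- types[ends[, 1]] != "mRNA"
  tibble::tibble(
    regulator = ifelse(is_reg, ends[, 1], ends[, 2]),
    target = ifelse(is_reg, ends[, 2], ends[, 1]),
    score = igraph::E(graph)$score
  )
}

#' @export
tidy.trf_network <- function(x, ...) network_nodes(x)

#' @export
glance.trf_network <- function(x, ...) {
  nodes <- network_nodes(x)
  tibble::tibble(
    n_nodes = nrow(nodes),
    n_edges = igraph::ecount(x),
    n_regulators = sum(nodes$node_type != "mRNA"),
    n_targets = sum(nodes$node_type == "mRNA"),
    n_tfs = sum(nodes$is_tf)
  )
}

#' Rank regulator hubs
#'
#' Regulator nodes sorted by degree (descending), then DE p-value
#' (ascending), then id; the paper-style hub definition "highest degree and
#' lowest P value".
#'
#' @param graph a `trf_network`.
#' @param k number of hubs to return (all regulators if larger).
#' @return tibble of the top-k regulator nodes.
#' @export
hub_ranking <- function(graph, k = 10L) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (igraph::vcount(graph) == 0) stop("empty graph", call. = FALSE)
  network_nodes(graph) |>
    dplyr::filter(.data$node_type != "mRNA") |>
    dplyr::arrange(
      dplyr::desc(.data$degree), .data$p_value, .data$id
    ) |>
    head(k)
}

#' Overlapping transcription factors between two networks
#'
#' @param graph_a,graph_b `trf_network` objects with TF-annotated nodes.
#' @return sorted character vector of shared TF ids.
#' @export
tf_overlap <- function(graph_a, graph_b) {
  tf <- function(g) {
    nodes <- network_nodes(g)
    nodes$id[nodes$is_tf]
  }
  sort(intersect(tf(graph_a), tf(graph_b)))
}

#' Merge two regulatory networks
#'
#' Union of nodes and edges; mRNA (or any) nodes shared by id are merged and
#' degrees recomputed from the combined edge set. Shared nodes must agree on
#' their attributes, otherwise the conflict is reported as an error.
#'
#' @param graph_a,graph_b `trf_network` objects.
#' @return merged `trf_network`.
#' @export
merge_networks <- function(graph_a, graph_b) {
  nodes <- dplyr::bind_rows(network_nodes(graph_a), network_nodes(graph_b)) |>
    dplyr::select(-"degree") |>
    dplyr::distinct()
  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup)) {
    stop(
      "conflicting attributes for shared node(s): ",
      paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  edges <- dplyr::bind_rows(network_edges(graph_a), network_edges(graph_b)) |>
    dplyr::distinct()
  g <- igraph::graph_from_data_frame(
    d = edges, directed = FALSE, vertices = nodes
  )
  igraph::E(g)$direction <- "regulator_to_target"
  igraph::V(g)$degree <- igraph::degree(g)
  class(g) <- c("trf_network", class(g))
  g
}

#' Export a network as SIF
#'
#' One line per edge: `regulator<TAB>targets<TAB>mRNA`, Cytoscape-style.
#'
#' @param graph a `trf_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(graph, path) {
  e <- network_edges(graph)
  writeLines(paste(e$regulator, "targets", e$target, sep = "\t"), path)
  invisible(path)
}

#' Export a network as GraphML (with node and edge attributes)
#'
#' @param graph a `trf_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(graph, path) {
  g <- graph
  # igraph's GraphML writer rejects NA reals coming from absent DE info
  for (a in c("p_value", "fold_change")) {
    v <- igraph::vertex_attr(g, a)
    if (!is.null(v)) {
      v[is.na(v)] <- -1
      g <- igraph::set_vertex_attr(g, a, value = v)
    }
  }
  class(g) <- "igraph"
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Plot a regulatory network
#'
#' Bipartite ggplot rendering: node size maps to degree, colour to DE
#' p-value, shape to node type; TF nodes get a black outline label.
#'
#' @param object a `trf_network`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.trf_network <- function(object, ...) {
  set.seed(1L)
  xy <- igraph::layout_with_fr(object)
  nodes <- network_nodes(object) |>
    dplyr::mutate(x = xy[, 1], y = xy[, 2])
  e <- network_edges(object)
  idx <- stats::setNames(seq_len(nrow(nodes)), nodes$id)
  seg <- tibble::tibble(
    x = nodes$x[idx[e$regulator]], y = nodes$y[idx[e$regulator]],
    xend = nodes$x[idx[e$target]], yend = nodes$y[idx[e$target]]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      colour = "grey80", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(
        .data$x, .data$y,
        size = .data$degree, colour = .data$p_value, shape = .data$node_type
      )
    ) +
    ggplot2::geom_point(
      data = dplyr::filter(nodes, .data$is_tf),
      ggplot2::aes(.data$x, .data$y),
      shape = 21, colour = "black", size = 4, stroke = 0.8, fill = NA
    ) +
    ggplot2::scale_colour_gradient(low = "#27ae60", high = "#c0392b") +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
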