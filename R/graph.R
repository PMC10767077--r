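#' Build the cylinder topology graph
#'
#' Turns a validated QSM cylinder table into a directed graph: one node per
#' cylinder (keyed by `cylinder_id`, carrying all record attributes) and one
#' edge `parent -> child` for every cylinder whose `parent_cyl_id` matches an
#' existing cylinder id.  Cylinders whose parent id matches no cylinder
#' (conventionally 0, since the source QSM tool indexes from 1) are roots.
#' `child_cyl_id` is stored as a node attribute but never used for edges: a
#' single scalar cannot encode several children.
#'
#' The result must be a forest: a cycle raises a topology error listing the
#' cylinder ids involved, and in-degree > 1 is impossible by construction
#' (each cylinder has one parent pointer).
#'
#' @param cylinders Cylinder table (validated or coercible via
#'   [as_cylinders()]).
#' @return An object of class `tree_graph`:
#' \describe{
#'   \item{graph}{the underlying [igraph::graph] with node attributes}
#'   \item{nodes}{the cylinder tibble}
#'   \item{edges}{tibble of `from`, `to` cylinder ids}
#'   \item{roots}{integer vector of root cylinder ids}
#' }
#' @examples
#' cyl <- generate_tree(synthetic_tree_spec(seed = 1))$cylinders
#' g <- build_graph(cyl)
#' g$roots
#' @export
build_graph <- function(cylinders) {
  nodes <- as_cylinders(cylinders)
  ids <- nodes$cylinder_id
  has_parent <- nodes$parent_cyl_id %in% ids
  edges <- tibble(from = nodes$parent_cyl_id[has_parent],
                  to = nodes$cylinder_id[has_parent])
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges$from),
                   to = as.character(edges$to)),
    directed = TRUE,
    vertices = data.frame(name = as.character(ids), nodes,
                          check.names = FALSE)
  )
  if (nrow(edges) > 0 && !igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    in_cycle <- ids[comp$membership %in% which(comp$csize > 1)]
    cm_abort(sprintf("cylinder topology contains a cycle involving ids: %s",
                     paste(sort(in_cycle), collapse = ", ")),
             "cm_error_topology")
  }
  structure(
    list(graph = g,
         nodes = nodes,
         edges = edges,
         roots = sort(ids[!has_parent])),
    class = "tree_graph"
  )
}

#' @export
print.tree_graph <- function(x, ...) {
  cat(sprintf("<tree_graph> %d cylinders, %d edges, %d root(s): %s\n",
              nrow(x$nodes), nrow(x$edges), length(x$roots),
              paste(x$roots, collapse = ", ")))
  invisible(x)
}

#' @describeIn build_graph Node table (one row per cylinder).
#' @param x A `tree_graph`.
#' @param ... Unused.
#' @export
tidy.tree_graph <- function(x, ...) {
  x$nodes
}

#' @describeIn build_graph One-row structural summary (counts, roots, max
#'   branch order, total volume in litres).
#' @export
glance.tree_graph <- function(x, ...) {
  tibble(
    n_cylinders = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_roots = length(x$roots),
    max_branch_order = if (nrow(x$nodes)) max(x$nodes$branch_order) else NA_integer_,
    total_volume_l = if (nrow(x$nodes)) total_volume(x$nodes) else 0
  )
}

#' Serialize a tree graph to node-link JSON
#'
#' Writes a portable, diffable text serialization: a JSON object with a
#' `nodes` array (all cylinder attributes) and an `edges` array (`from`,
#' `to` cylinder ids).  Numeric attributes are written at full precision, so
#' the round trip through [read_graph()] is lossless.
#'
#' @param graph A [build_graph()] result.
#' @param path Output file path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path) {
  stopifnot(inherits(graph, "tree_graph"))
  payload <- list(
    format = "canopymetrics-tree-graph",
    version = 1L,
    nodes = graph$nodes,
    edges = graph$edges
  )
  jsonlite::write_json(payload, path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read a tree graph from node-link JSON
#'
#' @param path Path written by [write_graph()].
#' @return A `tree_graph`, equal to the serialized one (nodes, edges and all
#'   attributes).
#' @export
read_graph <- function(path) {
  if (!file.exists(path)) {
    cm_abort(sprintf("graph file not found: %s", path), "cm_error_io")
  }
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
                        cm_abort(sprintf("cannot parse graph file %s: %s",
                                         path, conditionMessage(e)),
                                 "cm_error_parse")
                      })
  if (!identical(payload$format, "canopymetrics-tree-graph")) {
    cm_abort(sprintf("%s is not a canopymetrics tree-graph file", path),
             "cm_error_parse")
  }
  nodes <- as_tibble(payload$nodes)
  if (nrow(nodes) == 0) {
    nodes <- as_cylinders(tibble(
      date = character(), project_id = character(), tree_id = character(),
      branch_id = integer(), branch_order = integer(), cylinder_id = integer(),
      pos_in_branch = integer(), parent_cyl_id = integer(),
      child_cyl_id = integer(), start_x = double(), start_y = double(),
      start_z = double(), axis_x = double(), axis_y = double(),
      axis_z = double(), length = double(), radius = double(),
      added_virtual = integer()))
  }
  build_graph(nodes)
}

#' @describeIn build_graph Tree layout of the cylinder graph, nodes coloured
#'   by branch order.
#' @param object A `tree_graph`.
#' @export
autoplot.tree_graph <- function(object, ...) {
  if (nrow(object$nodes) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void())
  }
  lay <- igraph::layout_as_tree(object$graph,
                                root = match(as.character(object$roots),
                                             igraph::V(object$graph)$name))
  dat <- tibble(
    x = lay[, 1], y = lay[, 2],
    cylinder_id = object$nodes$cylinder_id,
    branch_order = factor(object$nodes$branch_order)
  )
  seg <- dplyr::left_join(
    dplyr::left_join(object$edges,
                     dplyr::rename(dat, xend = "x", yend = "y"),
                     by = c("to" = "cylinder_id")),
    dat, by = c("from" = "cylinder_id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_point(data = dat,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$branch_order),
                        size = 1) +
    ggplot2::labs(colour = "branch order", x = NULL, y = NULL,
                  title = "Cylinder topology graph") +
    ggplot2::theme_void()
}
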