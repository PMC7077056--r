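#' Construct a biological network
#'
#' A `bio_network` is a simple, undirected, optionally weighted network over
#' typed molecular nodes (lncRNA, mRNA, miRNA, protein, TF). It is the common
#' currency of the package: all network builders return one and the random
#' walk, topology and fusion steps consume them.
#'
#' Edges are stored canonically: endpoints of each edge are sorted
#' lexicographically, duplicate edges are collapsed (first weight wins) and
#' self-loops are dropped with an informative message. Directed input is
#' thereby symmetrized.
#'
#' @param edges A data frame whose first two columns are node identifiers and
#'   whose optional `weight` column holds finite, non-negative edge weights.
#'   `NULL` or a zero-row frame gives an empty network.
#' @param nodes Optional node declaration: a data frame with columns
#'   `node_id`, `node_type`, or a named character vector mapping node id to
#'   type. Nodes seen in `edges` but not declared get `default_type`.
#'   Declared nodes absent from `edges` are kept as isolated nodes.
#' @param name Short network identifier (e.g. `"LCN"`, `"LMI"`).
#' @param default_type Node type assumed for undeclared nodes.
#'
#' @return An object of class `bio_network`: a list with fields `name`,
#'   `nodes` (tibble `node_id`, `node_type`) and `edges` (tibble `from`,
#'   `to`, `weight`).
#' @examples
#' net <- bio_network(data.frame(a = c("A", "B"), b = c("B", "C")), name = "toy")
#' n_edges(net)
#' @export
bio_network <- function(edges = NULL, nodes = NULL, name = "network",
                        default_type = "lncRNA") {
  default_type <- match.arg(default_type, NODE_TYPES)
  seen_ids <- character()
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    ed <- tibble(from = character(), to = character(), weight = numeric())
  } else {
    edges <- as_tibble(edges)
    if (ncol(edges) < 2L) abort("`edges` needs at least two columns.")
    ed <- tibble(
      from = as.character(edges[[1L]]),
      to = as.character(edges[[2L]]),
      weight = if ("weight" %in% names(edges)) as.numeric(edges[["weight"]]) else NA_real_
    )
    if (anyNA(ed$from) || anyNA(ed$to)) abort("Edge endpoints must be non-missing strings.")
    seen_ids <- unique(c(ed$from, ed$to))  # before self-loops drop out
    has_w <- !is.na(ed$weight)
    if (any(has_w & (!is.finite(ed$weight) | ed$weight < 0))) {
      abort("Edge weights must be finite and non-negative.")
    }
    loops <- ed$from == ed$to
    if (any(loops)) {
      inform(sprintf("Dropped %d self-loop(s).", sum(loops)))
      ed <- ed[!loops, , drop = FALSE]
    }
    swap <- ed$from > ed$to
    tmp <- ed$from[swap]
    ed$from[swap] <- ed$to[swap]
    ed$to[swap] <- tmp
    ed <- ed[!duplicated(ed[c("from", "to")]), , drop = FALSE]
    ed <- dplyr::arrange(ed, .data$from, .data$to)
  }

  node_tbl <- normalize_nodes(nodes, default_type)
  missing <- setdiff(seen_ids, node_tbl$node_id)
  if (length(missing)) {
    node_tbl <- dplyr::bind_rows(
      node_tbl, tibble(node_id = missing, node_type = default_type)
    )
  }
  node_tbl <- dplyr::arrange(node_tbl, .data$node_id)

  structure(list(name = name, nodes = node_tbl, edges = ed),
            class = "bio_network")
}

normalize_nodes <- function(nodes, default_type) {
  if (is.null(nodes)) {
    return(tibble(node_id = character(), node_type = character()))
  }
  if (is.data.frame(nodes)) {
    out <- tibble(node_id = as.character(nodes[[1L]]),
                  node_type = if (ncol(nodes) >= 2L) as.character(nodes[[2L]]) else default_type)
  } else if (is.character(nodes) && !is.null(names(nodes))) {
    out <- tibble(node_id = names(nodes), node_type = unname(nodes))
  } else if (is.character(nodes)) {
    out <- tibble(node_id = nodes, node_type = default_type)
  } else {
    abort("`nodes` must be NULL, a data frame, or a character vector.")
  }
  bad <- setdiff(unique(out$node_type), NODE_TYPES)
  if (length(bad)) {
    abort(sprintf("Unknown node type(s): %s", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(out$node_id)) {
    out <- out[!duplicated(out$node_id), , drop = FALSE]
  }
  out
}

#' @export
print.bio_network <- function(x, ...) {
  cat(sprintf("<bio_network> %s: %d nodes, %d edges\n",
              x$name, nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$nodes)) {
    tab <- table(x$nodes$node_type)
    cat("  nodes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Network sizes and node accessors
#'
#' @param net A [bio_network()].
#' @return `n_nodes()`/`n_edges()` return counts; `node_ids()` the sorted
#'   node identifiers, optionally restricted to one node type.
#' @export
n_nodes <- function(net) nrow(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname n_nodes
#' @param node_type Optional node type filter.
#' @export
node_ids <- function(net, node_type = NULL) {
  ids <- net$nodes
  if (!is.null(node_type)) ids <- ids[ids$node_type %in% node_type, , drop = FALSE]
  ids$node_id
}

has_weights <- function(net) any(!is.na(net$edges$weight))

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[c("from", "to")], directed = FALSE,
    vertices = net$nodes["node_id"]
  )
}

#' Read an edge-list TSV into a network
#'
#' Expects `node_a<TAB>node_b[<TAB>weight]`; lines starting with `#` are
#' skipped. Duplicate edges are collapsed and self-loops dropped as in
#' [bio_network()].
#'
#' @param path File path.
#' @param node_types Optional node typing, as the `nodes` argument of
#'   [bio_network()].
#' @param weighted `NA` (default) uses a third column when present; `TRUE`
#'   requires one; `FALSE` ignores it.
#' @param header Whether the first non-comment line is a header.
#' @param name,default_type Passed to [bio_network()].
#' @return A [bio_network()].
#' @export
read_edge_list <- function(path, node_types = NULL, weighted = NA,
                           header = TRUE, name = NULL,
                           default_type = "lncRNA") {
  name <- name %||% sub("\\.[^.]+$", "", basename(path))
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (isTRUE(header) && length(lines)) {
    lines <- lines[-1L]
    line_no <- line_no[-1L]
  }
  if (!length(lines)) {
    return(bio_network(NULL, nodes = node_types, name = name,
                       default_type = default_type))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  len <- lengths(parts)
  bad <- which(len < 2L)
  if (length(bad)) {
    abort(sprintf("Malformed row at line %d of %s: need at least 2 tab-separated fields.",
                  line_no[bad[1L]], path))
  }
  from <- vapply(parts, `[[`, "", 1L)
  to <- vapply(parts, `[[`, "", 2L)
  want_w <- if (is.na(weighted)) any(len >= 3L) else isTRUE(weighted)
  weight <- NA_real_
  if (want_w) {
    wchr <- vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else NA_character_, "")
    if (anyNA(wchr)) {
      abort(sprintf("Missing weight at line %d of %s.", line_no[which(is.na(wchr))[1L]], path))
    }
    weight <- suppressWarnings(as.numeric(wchr))
    bad_w <- which(is.na(weight) | weight < 0)
    if (length(bad_w)) {
      abort(sprintf("Weight at line %d of %s is not a non-negative number.",
                    line_no[bad_w[1L]], path))
    }
  }
  bio_network(tibble(from = from, to = to, weight = weight),
              nodes = node_types, name = name, default_type = default_type)
}

#' Write a network as an edge-list TSV
#'
#' Inverse of [read_edge_list()]: `read_edge_list(write_edge_list(net, f))`
#' reproduces the edge set and weights exactly. Weights are written with
#' full precision when present. An empty network yields a header-only file.
#'
#' @param net A [bio_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  w <- has_weights(net)
  hdr <- if (w) "node_a\tnode_b\tweight" else "node_a\tnode_b"
  body <- if (nrow(net$edges) == 0L) {
    character()
  } else if (w) {
    sprintf("%s\t%s\t%.17g", net$edges$from, net$edges$to, net$edges$weight)
  } else {
    sprintf("%s\t%s", net$edges$from, net$edges$to)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Column-normalized adjacency matrix
#'
#' Returns the sparse column-stochastic matrix `W` used by the random walk:
#' entry `(i, j)` is `A[i, j] / degree(j)`, so every column of a node with at
#' least one edge sums to 1. Columns of isolated (zero-degree) nodes are all
#' zero; walker mass at such nodes is replenished only through the restart
#' term.
#'
#' @param net A non-empty [bio_network()].
#' @param weighted Use edge weights instead of the binary adjacency
#'   (unweighted is the default: thresholded biological networks are
#'   effectively binary).
#' @return A `dgCMatrix` with node ids as dimnames, columns in
#'   [node_ids()] order.
#' @export
column_normalized_adjacency <- function(net, weighted = FALSE) {
  ids <- net$nodes$node_id
  n <- length(ids)
  if (n == 0L) abort("Network has no nodes.")
  ed <- net$edges
  if (nrow(ed) == 0L) {
    W <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(n, n), dimnames = list(ids, ids))
    return(W)
  }
  i <- match(ed$from, ids)
  j <- match(ed$to, ids)
  x <- if (weighted) {
    if (!has_weights(net)) abort("Network has no edge weights.")
    ifelse(is.na(ed$weight), 1, ed$weight)
  } else {
    rep(1, nrow(ed))
  }
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(x, x),
                            dims = c(n, n), dimnames = list(ids, ids))
  cs <- Matrix::colSums(A)
  scale <- ifelse(cs > 0, 1 / cs, 0)
  W <- A %*% Matrix::Diagonal(n, scale)
  dimnames(W) <- list(ids, ids)
  W
}

#' Node degree and betweenness centrality
#'
#' `node_degree()` counts incident edges. `node_betweenness()` is the
#' unnormalized shortest-path betweenness (Brandes accounting: each unordered
#' source-target pair counted once, fractional credit for tied shortest
#' paths). The fusion step min-max rescales these per network, so only the
#' relative values matter.
#'
#' @param net A [bio_network()].
#' @param ids Node identifiers; default all nodes. Unknown ids are an error.
#' @return A named numeric vector over `ids`.
#' @export
node_degree <- function(net, ids = NULL) {
  ids <- ids %||% net$nodes$node_id
  unknown <- setdiff(ids, net$nodes$node_id)
  if (length(unknown)) {
    abort(sprintf("Unknown node(s): %s", paste(utils::head(unknown, 5L), collapse = ", ")))
  }
  cnt <- table(factor(c(net$edges$from, net$edges$to), levels = net$nodes$node_id))
  out <- as.numeric(cnt)[match(ids, net$nodes$node_id)]
  names(out) <- ids
  out
}

#' @rdname node_degree
#' @export
node_betweenness <- function(net, ids = NULL) {
  ids <- ids %||% net$nodes$node_id
  unknown <- setdiff(ids, net$nodes$node_id)
  if (length(unknown)) {
    abort(sprintf("Unknown node(s): %s", paste(utils::head(unknown, 5L), collapse = ", ")))
  }
  if (nrow(net$nodes) == 0L) return(stats::setNames(numeric(), character()))
  b <- igraph::betweenness(as_igraph(net), directed = FALSE, normalized = FALSE)
  out <- as.numeric(b[ids])
  names(out) <- ids
  out
}

#' Degree-distribution summary with a log-log power-law fit
#'
#' Descriptive check that a network is scale-free-ish: tabulates the degree
#' histogram (positive degrees) and fits a least-squares line to
#' `log10(count) ~ log10(degree)`. No hypothesis test is performed. When the
#' positive-degree histogram has fewer than two distinct degrees the slope is
#' undefined and flagged.
#'
#' @param net A [bio_network()] with at least 10 nodes.
#' @return A list of class `power_law_summary` with `histogram` (tibble
#'   `degree`, `count`), `slope`, `intercept`, `r_squared`, and `undefined`.
#' @export
fit_power_law_summary <- function(net) {
  if (n_nodes(net) < 10L) abort("Need at least 10 nodes for a degree-distribution summary.")
  deg <- node_degree(net)
  pos <- deg[deg > 0]
  hist <- tibble(degree = as.integer(names(table(pos))),
                 count = as.integer(table(pos)))
  if (nrow(hist) < 2L) {
    out <- list(histogram = hist, slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, undefined = TRUE)
  } else {
    fit <- stats::lm(log10(count) ~ log10(degree), data = hist)
    out <- list(histogram = hist,
                slope = unname(stats::coef(fit)[2L]),
                intercept = unname(stats::coef(fit)[1L]),
                r_squared = summary(fit)$r.squared,
                undefined = FALSE)
  }
  structure(out, class = "power_law_summary")
}

#' @export
print.power_law_summary <- function(x, ...) {
  if (x$undefined) {
    cat("<power_law_summary> slope undefined (fewer than 2 distinct degrees)\n")
  } else {
    cat(sprintf("<power_law_summary> slope = %.3f (R^2 = %.3f) over %d degree bins\n",
                x$slope, x$r_squared, nrow(x$histogram)))
  }
  invisible(x)
}

#' Bundle networks into a collection
#'
#' A `network_collection` holds the N networks used to prioritize candidates
#' for one cancer type, plus the node-membership index from which per-node
#' network coverage is computed.
#'
#' @param networks A (preferably named) list of [bio_network()] objects;
#'   unnamed entries take their `$name` field.
#' @return An object of class `network_collection` with fields `networks`
#'   and `membership` (tibble `node_id`, `node_type`, `coverage`).
#' @export
network_collection <- function(networks) {
  if (inherits(networks, "bio_network")) networks <- list(networks)
  if (!length(networks)) abort("A collection needs at least one network.")
  stopifnot(all(vapply(networks, inherits, TRUE, "bio_network")))
  nm <- names(networks) %||% rep(NA_character_, length(networks))
  nm[is.na(nm) | !nzchar(nm)] <- vapply(networks, `[[`, "", "name")[is.na(nm) | !nzchar(nm)]
  if (anyDuplicated(nm)) abort("Network names must be unique.")
  names(networks) <- nm
  membership <- purrr::map_dfr(networks, function(net) net$nodes) |>
    dplyr::group_by(.data$node_id) |>
    dplyr::summarise(node_type = dplyr::first(.data$node_type),
                     coverage = dplyr::n(), .groups = "drop")
  structure(list(networks = networks, membership = membership),
            class = "network_collection")
}

#' @export
print.network_collection <- function(x, ...) {
  cat(sprintf("<network_collection> %d networks, %d distinct nodes\n",
              length(x$networks), nrow(x$membership)))
  for (nm in names(x$networks)) {
    net <- x$networks[[nm]]
    cat(sprintf("  %-6s %5d nodes %7d edges\n", nm, n_nodes(net), n_edges(net)))
  }
  invisible(x)
}

#' Per-node network coverage
#'
#' @param collection A [network_collection()].
#' @param node_type Optional node-type filter.
#' @return Tibble `node_id`, `node_type`, `coverage` (number of networks
#'   containing the node).
#' @export
node_coverage <- function(collection, node_type = NULL) {
  m <- collection$membership
  if (!is.null(node_type)) m <- m[m$node_type %in% node_type, , drop = FALSE]
  m
}
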