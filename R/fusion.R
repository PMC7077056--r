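#' Rank ratio of a candidate in one network
#'
#' A candidate ranked `R` among the `n` candidates of a network gets rank
#' ratio `R / n`; a candidate absent from the network gets 1, the worst
#' possible value, so missing evidence is neutral-to-unfavourable rather
#' than disqualifying.
#'
#' @param rank Rank(s) within the network, `1 <= rank <= n` where `member`.
#' @param n Number of candidates ranked in the network.
#' @param member Logical: is the candidate a node of the network?
#' @return Numeric in (0, 1].
#' @export
rank_ratio <- function(rank, n, member = TRUE) {
  k <- max(length(rank), length(member))
  member <- rep_len(member, k)
  rank <- rep_len(rank, k)
  n <- rep_len(n, k)
  if (any(member & (is.na(rank) | rank < 1 | rank > n))) {
    abort("Ranks of member candidates must satisfy 1 <= rank <= n.")
  }
  out <- rep(1, k)
  out[member] <- rank[member] / n[member]
  out
}

#' Min-max normalization of a topology statistic
#'
#' Rescales a node's betweenness or degree to `[0, 1]` relative to the
#' minimum and maximum over the network's nodes. Non-members get 0, as does
#' every node of a degenerate network where the statistic is constant
#' (no topological evidence either way).
#'
#' @param value Statistic value(s).
#' @param vmin,vmax Network-wide minimum and maximum of the statistic.
#' @param member Logical membership flag(s).
#' @return Numeric in `[0, 1]`.
#' @export
minmax_normalize <- function(value, vmin, vmax, member = TRUE) {
  k <- max(length(value), length(member))
  value <- rep_len(value, k)
  vmin <- rep_len(vmin, k)
  vmax <- rep_len(vmax, k)
  member <- rep_len(member, k)
  if (any(member & (value < vmin | value > vmax))) {
    abort("`value` must lie in [vmin, vmax] for member nodes.")
  }
  out <- numeric(k)
  ok <- member & vmax > vmin
  out[ok] <- (value[ok] - vmin[ok]) / (vmax[ok] - vmin[ok])
  out
}

minmax_vector <- function(x) {
  if (!length(x)) return(x)
  minmax_normalize(x, min(x), max(x), member = TRUE)
}

# Per-network min-max normalized betweenness and degree over ALL nodes of
# each network (the normalization reference set), plus the node id sets.
collection_topology <- function(collection) {
  purrr::map(collection$networks, function(net) {
    ids <- net$nodes$node_id
    list(
      nodes = ids,
      b = stats::setNames(minmax_vector(node_betweenness(net)), ids),
      d = stats::setNames(minmax_vector(node_degree(net)), ids)
    )
  })
}

# Stationary RWR probabilities per network for one seed set. Networks
# containing no seed get NULL (interpreted downstream as all-zero
# probabilities, i.e. a fully tied ranking).
network_probabilities <- function(collection, seeds, params, weighted = FALSE) {
  seeds <- as_seed_set(seeds)
  sd_all <- all_seeds(seeds)
  purrr::map(collection$networks, function(net) {
    retained <- intersect(sd_all, net$nodes$node_id)
    if (!length(retained)) return(NULL)
    W <- column_normalized_adjacency(net, weighted = weighted)
    p0 <- numeric(n_nodes(net))
    p0[match(retained, net$nodes$node_id)] <- 1 / length(retained)
    res <- rwr_iterate(W, matrix(p0, ncol = 1L), params$alpha, params$tol, params$max_iter)
    stats::setNames(res$P[, 1L], net$nodes$node_id)
  })
}

# Ranking of the candidates present in one network given its probability
# vector (NULL = no seed reached the network: everyone ties).
ranks_in_network <- function(net_nodes, probs, candidates) {
  members <- intersect(candidates, net_nodes)
  if (!length(members)) return(NULL)
  p <- if (is.null(probs)) numeric(length(members)) else unname(probs[members])
  out <- tibble(node_id = members, rank = rank_desc(p))
  attr(out, "n_candidates") <- length(members)
  out
}

# Core profile assembly over precomputed topology; used by the exported
# build_topology_profiles() and by the evaluation engine (quiet there).
profiles_from <- function(topo, net_names, per_network_ranks, candidates,
                          quiet = FALSE) {
  N <- length(net_names)
  k <- length(candidates)
  if (!k) abort("Empty candidate set.")

  member <- matrix(FALSE, k, N, dimnames = list(candidates, net_names))
  r_mat <- matrix(1, k, N)
  b_mat <- matrix(0, k, N)
  d_mat <- matrix(0, k, N)

  for (j in seq_len(N)) {
    nm <- net_names[j]
    in_net <- candidates %in% topo[[j]]$nodes
    member[, j] <- in_net
    if (!any(in_net)) next
    ranks <- per_network_ranks[[nm]]
    if (is.null(ranks)) {
      abort(sprintf("Ranks missing for network %s, which contains candidates.", nm))
    }
    n_j <- attr(ranks, "n_candidates") %||% nrow(ranks)
    idx <- match(candidates[in_net], ranks$node_id)
    if (anyNA(idx)) {
      abort(sprintf("Network %s lacks ranks for some member candidates.", nm))
    }
    r_mat[in_net, j] <- rank_ratio(ranks$rank[idx], n_j, member = TRUE)
    b_mat[in_net, j] <- topo[[j]]$b[candidates[in_net]]
    d_mat[in_net, j] <- topo[[j]]$d[candidates[in_net]]
  }

  T_i <- rowSums(member)
  orphaned <- T_i == 0
  if (any(orphaned)) {
    if (!quiet) {
      inform(sprintf("Dropped %d candidate(s) present in no network.", sum(orphaned)))
    }
    keep <- !orphaned
    member <- member[keep, , drop = FALSE]
    r_mat <- r_mat[keep, , drop = FALSE]
    b_mat <- b_mat[keep, , drop = FALSE]
    d_mat <- d_mat[keep, , drop = FALSE]
    candidates <- candidates[keep]
    T_i <- T_i[keep]
  }

  out <- tibble(
    node_id = candidates,
    coverage = as.integer(unname(T_i)),
    coverage_frac = unname(T_i) / N,
    avg_betweenness = unname(rowSums(b_mat) / T_i),
    avg_degree = unname(rowSums(d_mat) / T_i)
  )
  colnames(r_mat) <- paste0("r_", net_names)
  colnames(b_mat) <- paste0("b_", net_names)
  colnames(d_mat) <- paste0("d_", net_names)
  dplyr::bind_cols(out, as_tibble(r_mat), as_tibble(b_mat), as_tibble(d_mat))
}

#' Assemble per-candidate topology profiles across a network collection
#'
#' For every candidate and network this computes the rank ratio `r` (1 when
#' absent), the min-max normalized betweenness `b` and degree `d` (0 when
#' absent), then aggregates: coverage `T` (number of member networks),
#' coverage fraction `t = T / N`, and the averages `bs = sum_j b / T` and
#' `ds = sum_j d / T`, where the sums run over all N networks with absent
#' networks contributing 0. Candidates that are a member of no network
#' cannot be profiled and are dropped with a message.
#'
#' @param collection A [network_collection()] of N networks.
#' @param per_network_ranks Named list (one entry per network; `NULL`
#'   allowed for networks without candidates) of tibbles `node_id`, `rank`
#'   covering at least the candidates present in that network, with
#'   attribute `n_candidates` (defaults to the row count).
#' @param candidates Character vector of candidate node ids.
#' @return A tibble with columns `node_id`, `coverage`, `coverage_frac`,
#'   `avg_betweenness`, `avg_degree` and per-network columns `r_<net>`,
#'   `b_<net>`, `d_<net>`.
#' @export
build_topology_profiles <- function(collection, per_network_ranks, candidates) {
  stopifnot(inherits(collection, "network_collection"))
  profiles_from(collection_topology(collection), names(collection$networks),
                per_network_ranks, candidates, quiet = FALSE)
}

#' Overall prioritization score
#'
#' Fuses a candidate's per-network rank ratios with its topology summary:
#'
#' \deqn{S_i = \frac{\prod_{j=1}^{N} \ln(r_{ij} + 1)}{t_i \, e^{bs_i + ds_i}}}
#'
#' with natural logarithms. Every factor `ln(r + 1)` lies in `(0, ln 2]`, so
#' good (small) rank ratios shrink `S`, while high coverage, betweenness and
#' degree shrink it through the denominator: smaller `S` means a stronger
#' predicted cancer association. A network the candidate is absent from
#' contributes the neutral factor `ln 2` via `r = 1`.
#'
#' The alternative reading of the topology term (multiplying rather than
#' dividing by `e^{bs + ds}`) is available via `orientation = "multiply"`;
#' the default matches the observation that known cancer lncRNAs are
#' network hubs, so hub-like topology should strengthen (shrink) the score.
#'
#' @param r Rank ratios in (0, 1]: a vector (one profile) or a matrix with
#'   one row per profile and one column per network.
#' @param t Coverage fraction(s) in (0, 1].
#' @param bs,ds Average normalized betweenness and degree in `[0, 1]`.
#' @param orientation `"divide"` (default) places `e^{bs + ds}` in the
#'   denominator; `"multiply"` in the numerator.
#' @return Numeric score(s) `S > 0`; smaller is stronger.
#' @examples
#' overall_score(rep(1, 3), t = 1, bs = 0, ds = 0)  # log(2)^3
#' overall_score(exp(1) - 1, t = 1, bs = 0, ds = 0) # exactly 1
#' @export
overall_score <- function(r, t, bs, ds, orientation = c("divide", "multiply")) {
  orientation <- match.arg(orientation)
  if (is.null(dim(r))) r <- matrix(r, nrow = 1L)
  # rank ratios are <= 1 by construction, but the score itself is defined
  # for any positive argument
  if (any(r <= 0 | !is.finite(r))) abort("Rank ratios must be positive.")
  if (any(t <= 0 | t > 1)) abort("Coverage fractions must lie in (0, 1].")
  if (any(bs < 0 | bs > 1) || any(ds < 0 | ds > 1)) {
    abort("Normalized topology averages must lie in [0, 1].")
  }
  num <- unname(apply(log1p(r), 1L, prod))
  topo <- exp(bs + ds)
  unname(if (orientation == "divide") num / (t * topo) else num * topo / t)
}

# Rank + topology fusion over precomputed pieces; plain tibble out, ordered
# by final rank. Shared by prioritize() and the evaluation engine.
fuse_pipeline <- function(collection, topo, probs, candidates, min_coverage,
                          orientation, quiet = TRUE) {
  net_names <- names(collection$networks)
  per_network_ranks <- purrr::imap(collection$networks, function(net, nm) {
    ranks_in_network(topo[[nm]]$nodes, probs[[nm]], candidates)
  })
  profiles <- profiles_from(topo, net_names, per_network_ranks, candidates,
                            quiet = quiet)
  low <- profiles$coverage < min_coverage
  if (any(low)) {
    if (!quiet) {
      inform(sprintf("Filtered %d candidate(s) with coverage < %d.",
                     sum(low), min_coverage))
    }
    profiles <- profiles[!low, , drop = FALSE]
  }
  r_cols <- paste0("r_", net_names)
  score <- if (nrow(profiles)) {
    overall_score(as.matrix(profiles[r_cols]), profiles$coverage_frac,
                  profiles$avg_betweenness, profiles$avg_degree,
                  orientation = orientation)
  } else {
    numeric()
  }
  dplyr::mutate(profiles,
                overall_score = score,
                final_rank = if (nrow(profiles)) rank(score, ties.method = "average") else numeric()) |>
    dplyr::relocate("node_id", "overall_score", "final_rank") |>
    dplyr::arrange(.data$final_rank, .data$node_id)
}

#' Prioritize candidate lncRNAs across a network collection
#'
#' The full pipeline for one cancer type: runs a random walk with restart
#' from the seeds on each network, ranks the candidates present in each
#' network by stationary probability (total ties where a network contains no
#' seed), assembles topology profiles ([build_topology_profiles()]), filters
#' out candidates covered by fewer than `min_coverage` networks, and fuses
#' everything into the overall score ([overall_score()]). Candidates default
#' to every lncRNA node of the collection that is not a seed.
#'
#' @param collection A [network_collection()].
#' @param seeds A [seed_set()] or character vector of known cancer lncRNAs.
#' @param params [rwr_params()].
#' @param min_coverage Minimum number of networks a candidate must appear in
#'   to be scored (default 4, the best-performing setting).
#' @param orientation Passed to [overall_score()].
#' @param candidates Optional explicit candidate set (must not overlap the
#'   seeds).
#' @param weighted Use weighted adjacency in the walks.
#' @return A tibble of class `lnc_prioritization`, one row per scored
#'   candidate, ordered by `final_rank`: `node_id`, `overall_score`,
#'   `final_rank`, then the profile columns of [build_topology_profiles()].
#'   Run configuration is carried in attributes and surfaced by `glance()`.
#' @examples
#' sim <- simulate_collection(sim_params(n_lnc = 60, n_mrna = 30, n_mirna = 20,
#'                                       module_size = 6, rng_seed = 1))
#' res <- prioritize(sim$collection, sim$gold, min_coverage = 4)
#' head(tidy(res), 3)
#' glance(res)
#' @export
prioritize <- function(collection, seeds, params = rwr_params(),
                       min_coverage = 4L,
                       orientation = c("divide", "multiply"),
                       candidates = NULL, weighted = FALSE) {
  orientation <- match.arg(orientation)
  seeds <- as_seed_set(seeds)
  stopifnot(inherits(collection, "network_collection"))

  all_lnc <- collection$membership$node_id[collection$membership$node_type == "lncRNA"]
  sd_all <- all_seeds(seeds)
  if (!any(sd_all %in% collection$membership$node_id)) {
    abort("No network contains any seed.")
  }
  candidates <- candidates %||% setdiff(all_lnc, sd_all)
  if (length(intersect(candidates, sd_all))) {
    abort("Candidates must not overlap the seed set.")
  }
  if (!length(candidates)) abort("Empty candidate set.")

  topo <- collection_topology(collection)
  probs <- network_probabilities(collection, seeds, params, weighted = weighted)
  out <- fuse_pipeline(collection, topo, probs, candidates, min_coverage,
                       orientation, quiet = FALSE)
  if (!nrow(out)) {
    warn("No candidate passes the coverage filter; returning an empty result.")
  }

  tibble::new_tibble(out,
                     class = "lnc_prioritization",
                     cancer = seeds$cancer,
                     n_networks = length(collection$networks),
                     network_names = names(collection$networks),
                     n_seeds = length(sd_all),
                     min_coverage = as.integer(min_coverage),
                     orientation = orientation,
                     alpha = params$alpha)
}

#' @export
tidy.lnc_prioritization <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' @export
glance.lnc_prioritization <- function(x, ...) {
  tibble(
    cancer = attr(x, "cancer"),
    n_candidates = nrow(x),
    n_networks = attr(x, "n_networks"),
    n_seeds = attr(x, "n_seeds"),
    min_coverage = attr(x, "min_coverage"),
    alpha = attr(x, "alpha"),
    top_candidate = if (nrow(x)) x$node_id[[1L]] else NA_character_
  )
}

unclass_result <- function(x) {
  attrs <- c("cancer", "n_networks", "network_names", "n_seeds",
             "min_coverage", "orientation", "alpha")
  for (a in attrs) attr(x, a) <- NULL
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

#' Write a prioritization result as TSV
#'
#' @param result An `lnc_prioritization`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prioritization <- function(result, path) {
  readr::write_tsv(tidy(result), path)
  invisible(path)
}
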