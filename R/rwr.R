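#' Seed sets of known disease molecules
#'
#' The walk restarts at seed nodes: experimentally verified cancer lncRNAs,
#' optionally supplemented with cancer genes/miRNAs/proteins (`aux_seeds`)
#' that exist as nodes in some networks.
#'
#' @param lnc_seeds Character vector of known cancer lncRNA ids.
#' @param aux_seeds Optional character vector of auxiliary seed ids
#'   (genes, miRNAs, proteins, TFs).
#' @param cancer Label for the cancer type.
#' @return An object of class `seed_set`.
#' @export
seed_set <- function(lnc_seeds, aux_seeds = character(), cancer = "cancer") {
  lnc_seeds <- unique(as.character(lnc_seeds))
  aux_seeds <- setdiff(unique(as.character(aux_seeds)), lnc_seeds)
  if (!length(lnc_seeds) && !length(aux_seeds)) abort("Seed set is empty.")
  structure(list(cancer = cancer, lnc_seeds = lnc_seeds, aux_seeds = aux_seeds),
            class = "seed_set")
}

as_seed_set <- function(x) {
  if (inherits(x, "seed_set")) return(x)
  if (is.character(x)) return(seed_set(x))
  abort("Seeds must be a `seed_set` or a character vector of lncRNA ids.")
}

all_seeds <- function(seeds) c(seeds$lnc_seeds, seeds$aux_seeds)

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set> %s: %d lncRNA seed(s), %d auxiliary seed(s)\n",
              x$cancer, length(x$lnc_seeds), length(x$aux_seeds)))
  invisible(x)
}

#' Random-walk-with-restart parameters
#'
#' @param alpha Restart probability in (0, 1). At every step the walker
#'   returns to the seed distribution with probability `alpha`; larger values
#'   keep the walk local to the seeds. 0.7 is the canonical choice in
#'   network-propagation prioritization.
#' @param tol L1 convergence tolerance on successive probability vectors.
#' @param max_iter Iteration cap; convergence is geometric with rate at most
#'   `1 - alpha`, so the default is generous.
#' @return A list of class `rwr_params`.
#' @export
rwr_params <- function(alpha = 0.7, tol = 1e-10, max_iter = 1000L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number in (0, 1).")
  }
  if (!is.numeric(tol) || tol <= 0) abort("`tol` must be > 0.")
  if (!is.numeric(max_iter) || max_iter < 1) abort("`max_iter` must be a positive integer.")
  structure(list(alpha = alpha, tol = tol, max_iter = as.integer(max_iter)),
            class = "rwr_params")
}

# Iterate p_{q+1} = (1 - alpha) W p_q + alpha p0 for every column of P0 at
# once, starting from P0. No per-step renormalization: mass lost through
# zero-degree columns is deliberately not replaced, so the iterate converges
# to the same fixed point as the direct linear solve.
rwr_iterate <- function(W, P0, alpha, tol, max_iter) {
  P <- P0
  iter <- 0L
  converged <- FALSE
  for (q in seq_len(max_iter)) {
    Pn <- (1 - alpha) * (W %*% P) + alpha * P0
    delta <- max(Matrix::colSums(abs(Pn - P)))
    P <- Pn
    iter <- q
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(P = as.matrix(P), iterations = iter, converged = converged)
}

seed_p0 <- function(net, seeds, warn_missing = TRUE) {
  seeds <- as_seed_set(seeds)
  ids <- net$nodes$node_id
  retained <- intersect(all_seeds(seeds), ids)
  dropped <- setdiff(all_seeds(seeds), ids)
  if (length(dropped) && warn_missing) {
    warn(sprintf("%d seed(s) absent from network %s were dropped.",
                 length(dropped), net$name))
  }
  if (!length(retained)) {
    abort(sprintf("No seed is a node of network %s.", net$name))
  }
  p0 <- stats::setNames(numeric(length(ids)), ids)
  p0[retained] <- 1 / length(retained)
  p0
}

#' Random walk with restart on one network
#'
#' Iterates `p[q+1] = (1 - alpha) W p[q] + alpha p0` from the seed
#' distribution `p0` (total mass 1 split uniformly over the seeds present in
#' the network) until the L1 change drops below `tol`. `W` is the
#' column-normalized adjacency from [column_normalized_adjacency()]. The
#' stationary probabilities measure each node's proximity to the seed set.
#'
#' Seeds absent from the network are dropped with a warning; if none remain
#' this is an error (the network carries no information for this cancer).
#'
#' @param net A [bio_network()].
#' @param seeds A [seed_set()] or character vector of seed node ids.
#' @param params [rwr_params()].
#' @param weighted Use weighted adjacency normalization.
#' @return An object of class `rwr_result`: `probabilities` (tibble
#'   `node_id`, `probability`), `iterations`, `converged`, `residual`
#'   (the L1 fixed-point residual), and `alpha`.
#' @seealso [solve_rwr_direct()] for the exact dense solve used as an
#'   independent cross-check.
#' @export
run_rwr <- function(net, seeds, params = rwr_params(), weighted = FALSE) {
  stopifnot(inherits(params, "rwr_params"))
  p0 <- seed_p0(net, seeds)
  W <- column_normalized_adjacency(net, weighted = weighted)
  res <- rwr_iterate(W, matrix(p0, ncol = 1L), params$alpha, params$tol, params$max_iter)
  p <- res$P[, 1L]
  residual <- sum(abs(p - (1 - params$alpha) * as.numeric(W %*% p) - params$alpha * p0))
  structure(list(
    probabilities = tibble(node_id = net$nodes$node_id, probability = unname(p)),
    iterations = res$iterations,
    converged = res$converged,
    residual = residual,
    alpha = params$alpha
  ), class = "rwr_result")
}

#' @export
print.rwr_result <- function(x, ...) {
  cat(sprintf("<rwr_result> %d nodes, %d iteration(s), %s (residual %.2e)\n",
              nrow(x$probabilities), x$iterations,
              if (x$converged) "converged" else "NOT converged", x$residual))
  invisible(x)
}

#' @export
tidy.rwr_result <- function(x, ...) x$probabilities

#' Exact stationary distribution of the restarting walk
#'
#' Solves the fixed-point system `p = alpha (I - (1 - alpha) W)^{-1} p0`
#' directly with a dense linear solve. For `0 < alpha < 1` and substochastic
#' `W` the system matrix is strictly diagonally dominant, hence nonsingular.
#' Intended as the independent oracle for [run_rwr()] on small networks.
#'
#' @inheritParams run_rwr
#' @param alpha Restart probability in (0, 1).
#' @param max_nodes Guard against accidental dense solves on large networks.
#' @return An `rwr_result` with `iterations = 0`.
#' @export
solve_rwr_direct <- function(net, seeds, alpha = 0.7, weighted = FALSE,
                             max_nodes = 2000L) {
  if (n_nodes(net) > max_nodes) {
    abort(sprintf("Direct solve guarded to <= %d nodes.", max_nodes))
  }
  p0 <- seed_p0(net, seeds)
  W <- as.matrix(column_normalized_adjacency(net, weighted = weighted))
  A <- diag(length(p0)) - (1 - alpha) * W
  p <- alpha * solve(A, p0)
  structure(list(
    probabilities = tibble(node_id = net$nodes$node_id, probability = unname(p)),
    iterations = 0L,
    converged = TRUE,
    residual = 0,
    alpha = alpha
  ), class = "rwr_result")
}

#' Rank candidates by visiting probability
#'
#' Candidates are ranked by descending stationary probability; tied
#' probabilities share the average of the tied positions, so a network in
#' which no candidate is reachable ranks everyone `(n + 1) / 2`.
#'
#' @param res An `rwr_result` from [run_rwr()] or [solve_rwr_direct()].
#' @param seeds Seeds used for the walk (must be disjoint from `candidates`).
#' @param candidates Character vector of candidate node ids, a subset of the
#'   network's nodes.
#' @return Tibble `node_id`, `probability`, `rank` with `n_candidates` as an
#'   attribute.
#' @export
rank_candidates <- function(res, seeds, candidates) {
  seeds <- as_seed_set(seeds)
  if (!length(candidates)) abort("Empty candidate set.")
  overlap <- intersect(candidates, all_seeds(seeds))
  if (length(overlap)) {
    abort(sprintf("Candidates overlap seeds: %s", paste(utils::head(overlap, 5L), collapse = ", ")))
  }
  probs <- stats::setNames(res$probabilities$probability, res$probabilities$node_id)
  unknown <- setdiff(candidates, names(probs))
  if (length(unknown)) {
    abort(sprintf("Candidate(s) not in network: %s", paste(utils::head(unknown, 5L), collapse = ", ")))
  }
  p <- probs[candidates]
  out <- tibble(node_id = candidates, probability = unname(p),
                rank = rank_desc(unname(p)))
  attr(out, "n_candidates") <- length(candidates)
  out
}
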