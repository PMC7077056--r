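# Independent oracles, kept deliberately naive so they share no code path
# with the package internals.

# Brute-force betweenness: BFS distances and shortest-path counts per source,
# then pair-dependency accumulation over all unordered pairs.
oracle_betweenness <- function(net) {
  ids <- node_ids(net)
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (k in seq_len(nrow(net$edges))) {
    A[net$edges$from[k], net$edges$to[k]] <- TRUE
    A[net$edges$to[k], net$edges$from[k]] <- TRUE
  }
  dist <- matrix(Inf, n, n)
  npath <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0
    npath[s, s] <- 1
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer()
      for (u in frontier) {
        for (v in which(A[u, ])) {
          if (is.infinite(dist[s, v])) {
            dist[s, v] <- d
            nxt <- c(nxt, v)
          }
          if (dist[s, v] == d) npath[s, v] <- npath[s, v] + npath[s, u]
        }
      }
      frontier <- unique(nxt)
    }
  }
  b <- stats::setNames(numeric(n), ids)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (is.infinite(dist[s, t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(dist[s, v]) && is.finite(dist[v, t]) &&
            dist[s, v] + dist[v, t] == dist[s, t]) {
          b[v] <- b[v] + npath[s, v] * npath[v, t] / npath[s, t]
        }
      }
    }
  }
  b
}

# Exact hypergeometric upper tail by direct summation of binomial
# coefficients (exact in double precision for M <= 25).
oracle_hyper_tail <- function(M, K, n, k) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  i <- i[n - i <= M - K]
  if (!length(i)) return(0)
  sum(choose(K, i) * choose(M - K, n - i)) / choose(M, n)
}

# Log-domain evaluation of the overall score, an independent route to the
# same closed form.
oracle_score <- function(r, t, bs, ds) {
  exp(sum(log(log1p(r))) - log(t) - (bs + ds))
}

# Pairwise Mann-Whitney AUC with 0.5 tie credit, smaller score = better.
oracle_auc <- function(pos, neg) {
  total <- 0
  for (p in pos) total <- total + sum(p < neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Erdos-Renyi bio_network over lncRNA nodes.
random_graph <- function(n, p, seed, prefix = "N") {
  set.seed(seed)
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(idx)) < p
  bio_network(data.frame(from = ids[idx[keep, 1]], to = ids[idx[keep, 2]]),
              nodes = ids, name = sprintf("er%d", seed))
}

path_graph <- function(ids) {
  bio_network(data.frame(from = ids[-length(ids)], to = ids[-1]), nodes = ids,
              name = "path")
}

star_graph <- function(centre, leaves, name = "star") {
  bio_network(data.frame(from = centre, to = leaves),
              nodes = c(centre, leaves), name = name)
}
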