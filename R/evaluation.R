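# ---- internal evaluation engine -------------------------------------------
#
# LOOCV repeatedly reruns the fused prioritization with one known lncRNA
# held out. Because the stationary RWR distribution is linear in the restart
# vector, the walk for any seed subset is the average of per-seed walks, so
# the engine solves each network once per individual seed and reuses the
# columns across all hold-out rounds (and the full-seed run that provides
# the decoy scores). Topology (betweenness/degree min-max) is seed-free and
# computed once.

evaluation_engine <- function(collection, seeds, params, min_coverage,
                              orientation) {
  seeds <- as_seed_set(seeds)
  sd_all <- all_seeds(seeds)
  topo <- collection_topology(collection)

  P_list <- purrr::map(collection$networks, function(net) {
    retained <- intersect(sd_all, net$nodes$node_id)
    if (!length(retained)) return(NULL)
    W <- column_normalized_adjacency(net)
    P0 <- Matrix::sparseMatrix(i = match(retained, net$nodes$node_id),
                               j = seq_along(retained), x = 1,
                               dims = c(n_nodes(net), length(retained)))
    res <- rwr_iterate(W, P0, params$alpha, params$tol, params$max_iter)
    m <- res$P
    dimnames(m) <- list(net$nodes$node_id, retained)
    m
  })

  probs_for <- function(seed_subset) {
    purrr::map(P_list, function(m) {
      if (is.null(m)) return(NULL)
      cols <- intersect(seed_subset, colnames(m))
      if (!length(cols)) return(NULL)
      rowMeans(m[, cols, drop = FALSE])
    })
  }

  fuse <- function(seed_subset, candidates) {
    fuse_pipeline(collection, topo, probs_for(seed_subset), candidates,
                  min_coverage, orientation, quiet = TRUE)
  }

  list(seeds = seeds, sd_all = sd_all, fuse = fuse,
       base_candidates = setdiff(
         collection$membership$node_id[collection$membership$node_type == "lncRNA"],
         sd_all
       ))
}

#' Leave-one-out cross-validation of the fused prioritization
#'
#' Each known cancer lncRNA is held out in turn, the remaining knowns (plus
#' any auxiliary seeds) drive the full prioritization, and the held-out
#' lncRNA is scored as an ordinary candidate alongside all non-seed
#' lncRNAs. Held-out knowns that fail the coverage filter (or sit in no
#' network) cannot be ranked; they are recorded with `unrankable = TRUE`
#' and reported via a message.
#'
#' @inheritParams prioritize
#' @return A tibble of class `lnc_loocv`: `held_out`, `score`, `rank`,
#'   `rank_among` (number of candidates ranked in that round) and
#'   `unrankable`.
#' @export
loocv <- function(collection, seeds, params = rwr_params(), min_coverage = 4L,
                  orientation = c("divide", "multiply")) {
  orientation <- match.arg(orientation)
  seeds <- as_seed_set(seeds)
  if (length(seeds$lnc_seeds) < 2L) {
    abort("LOOCV needs at least 2 known lncRNA seeds.")
  }
  eng <- evaluation_engine(collection, seeds, params, min_coverage, orientation)
  records <- purrr::map_dfr(sort(seeds$lnc_seeds), function(g) {
    res <- eng$fuse(setdiff(eng$sd_all, g), c(g, eng$base_candidates))
    i <- match(g, res$node_id)
    if (is.na(i)) {
      tibble(held_out = g, score = NA_real_, rank = NA_real_,
             rank_among = nrow(res), unrankable = TRUE)
    } else {
      tibble(held_out = g, score = res$overall_score[i], rank = res$final_rank[i],
             rank_among = nrow(res), unrankable = FALSE)
    }
  })
  if (any(records$unrankable)) {
    inform(sprintf("%d held-out known(s) failed the coverage filter and are excluded from ROC.",
                   sum(records$unrankable)))
  }
  tibble::new_tibble(records, class = "lnc_loocv",
                     min_coverage = as.integer(min_coverage),
                     cancer = seeds$cancer)
}

#' ROC and precision-recall curves from cross-validation records
#'
#' Sweeps the overall-score threshold (smaller score = stronger prediction):
#' positives are the held-out knowns at their cross-validation score,
#' negatives the supplied decoy scores (all candidate lncRNAs outside the
#' gold standard, typically from the full-seed prioritization). The AUC is
#' the trapezoidal area, which for this step construction equals the
#' Mann-Whitney pair statistic with ties credited 0.5
#' (see [mann_whitney_auc()]).
#'
#' @param records An `lnc_loocv` tibble (unrankable rows are skipped).
#' @param decoy_scores Numeric scores of the non-gold candidates.
#' @return A list of class `lnc_roc`: `points` (tibble `fpr`, `tpr`),
#'   `pr_points` (tibble `recall`, `precision`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_from_cv <- function(records, decoy_scores) {
  pos <- records$score[!records$unrankable]
  pos <- pos[!is.na(pos)]
  if (!length(pos)) abort("No rankable positive records.")
  if (!length(decoy_scores)) abort("No decoy scores.")
  thr <- sort(unique(c(pos, decoy_scores)))
  tpr <- vapply(thr, function(t) mean(pos <= t), 0)
  fpr <- vapply(thr, function(t) mean(decoy_scores <= t), 0)
  tp <- vapply(thr, function(t) sum(pos <= t), 0)
  fp <- vapply(thr, function(t) sum(decoy_scores <= t), 0)
  points <- tibble(fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) + utils::tail(points$tpr, -1)) / 2)
  pr_points <- tibble(recall = tpr, precision = tp / (tp + fp))
  structure(list(points = points, pr_points = pr_points, auc = auc,
                 n_pos = length(pos), n_neg = length(decoy_scores)),
            class = "lnc_roc")
}

#' @export
print.lnc_roc <- function(x, ...) {
  cat(sprintf("<lnc_roc> AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
glance.lnc_roc <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Mann-Whitney AUC from raw score sets
#'
#' The probability that a random positive outscores a random negative, with
#' ties credited 0.5. With `smaller_is_better = TRUE` (the overall-score
#' convention) "outscores" means a strictly smaller score. Computed via the
#' rank-sum identity, so it is an independent route to the same quantity as
#' the trapezoidal area of [roc_from_cv()].
#'
#' @param pos,neg Numeric score vectors.
#' @param smaller_is_better Score orientation.
#' @return AUC in `[0, 1]`.
#' @export
mann_whitney_auc <- function(pos, neg, smaller_is_better = TRUE) {
  if (!length(pos) || !length(neg)) abort("Both score sets must be non-empty.")
  r <- rank(c(pos, neg), ties.method = "average")
  np <- length(pos)
  u_gt <- sum(r[seq_len(np)]) - np * (np + 1) / 2  # pairs where pos > neg (+ 0.5 ties)
  frac <- u_gt / (np * length(neg))
  if (smaller_is_better) 1 - frac else frac
}

#' Fused LOOCV AUC in one call
#'
#' Convenience wrapper: runs [loocv()], takes the decoy scores from the
#' full-seed prioritization of the non-gold candidates, and builds the ROC.
#'
#' @inheritParams prioritize
#' @return A list of class `lnc_evaluation`: `auc`, `cv` (the `lnc_loocv`
#'   records), `roc`, `decoy_scores`, `n_excluded`.
#' @export
loocv_auc <- function(collection, seeds, params = rwr_params(),
                      min_coverage = 4L,
                      orientation = c("divide", "multiply")) {
  orientation <- match.arg(orientation)
  seeds <- as_seed_set(seeds)
  if (length(seeds$lnc_seeds) < 2L) {
    abort("LOOCV needs at least 2 known lncRNA seeds.")
  }
  eng <- evaluation_engine(collection, seeds, params, min_coverage, orientation)
  full <- eng$fuse(eng$sd_all, eng$base_candidates)
  records <- purrr::map_dfr(sort(seeds$lnc_seeds), function(g) {
    res <- eng$fuse(setdiff(eng$sd_all, g), c(g, eng$base_candidates))
    i <- match(g, res$node_id)
    if (is.na(i)) {
      tibble(held_out = g, score = NA_real_, rank = NA_real_,
             rank_among = nrow(res), unrankable = TRUE)
    } else {
      tibble(held_out = g, score = res$overall_score[i], rank = res$final_rank[i],
             rank_among = nrow(res), unrankable = FALSE)
    }
  })
  records <- tibble::new_tibble(records, class = "lnc_loocv",
                                min_coverage = as.integer(min_coverage),
                                cancer = seeds$cancer)
  decoys <- full$overall_score
  roc <- roc_from_cv(records, decoys)
  structure(list(auc = roc$auc, cv = records, roc = roc,
                 decoy_scores = decoys,
                 n_excluded = sum(records$unrankable)),
            class = "lnc_evaluation")
}

#' @export
print.lnc_evaluation <- function(x, ...) {
  cat(sprintf("<lnc_evaluation> LOOCV AUC = %.4f (%d positives, %d excluded, %d decoys)\n",
              x$auc, sum(!x$cv$unrankable), x$n_excluded, length(x$decoy_scores)))
  invisible(x)
}

#' AUC as a function of the network-coverage filter
#'
#' Repeats the LOOCV/ROC evaluation at each minimum-coverage setting.
#' Settings under which no candidate (or no held-out known) survives give
#' `NA` with a warning.
#'
#' @inheritParams prioritize
#' @param coverage_values Integer vector of `min_coverage` settings.
#' @return Tibble `min_coverage`, `auc`, `n_pos`, `n_excluded`.
#' @export
coverage_sweep <- function(collection, seeds, params = rwr_params(),
                           coverage_values = seq_len(length(collection$networks)),
                           orientation = c("divide", "multiply")) {
  orientation <- match.arg(orientation)
  purrr::map_dfr(coverage_values, function(cv) {
    ev <- tryCatch(
      loocv_auc(collection, seeds, params, min_coverage = cv,
                orientation = orientation),
      error = function(e) NULL
    )
    if (is.null(ev)) {
      warn(sprintf("Coverage %d leaves nothing to evaluate; AUC undefined.", cv))
      tibble(min_coverage = as.integer(cv), auc = NA_real_,
             n_pos = 0L, n_excluded = NA_integer_)
    } else {
      tibble(min_coverage = as.integer(cv), auc = ev$auc,
             n_pos = sum(!ev$cv$unrankable), n_excluded = ev$n_excluded)
    }
  })
}

drop_network_nodes <- function(net, ids) {
  keep_nodes <- net$nodes[!net$nodes$node_id %in% ids, , drop = FALSE]
  keep_edges <- net$edges[!(net$edges$from %in% ids | net$edges$to %in% ids), , drop = FALSE]
  structure(list(name = net$name, nodes = keep_nodes, edges = keep_edges),
            class = "bio_network")
}

#' Robustness to random node removal
#'
#' Emulates network incompleteness: per repetition and per network,
#' `floor(fraction * n)` of that network's lncRNA nodes (n) are removed
#' uniformly at random together with their incident edges, and both the
#' fused LOOCV AUC (with only that network depleted) and the depleted
#' network's single-network AUC are recomputed. The removal pool is all
#' lncRNA nodes of the network, seeds included -- losing known lncRNAs from
#' one evidence layer is exactly the failure mode a multi-network method
#' should absorb. Removed knowns simply stop contributing in the depleted
#' network; rounds whose single network retains no seed are flagged `NA`.
#'
#' @inheritParams prioritize
#' @param fraction Fraction of lncRNA nodes removed per network, in `[0, 1)`.
#'   `fraction = 0` is a guard-rail no-op reproducing the baseline exactly.
#' @param reps Number of independent repetitions (resampled each time).
#' @param rng_seed Integer seed making the removals reproducible.
#' @return A tibble of class `lnc_robustness` with one row per
#'   (rep, network): `rep`, `network`, `fused_auc`, `single_auc`,
#'   `fused_drop`, `single_drop`, `flagged`. Baselines are stored in
#'   attributes `baseline_fused` and `baseline_single`.
#' @export
robustness_experiment <- function(collection, seeds, params = rwr_params(),
                                  fraction = 0.2, reps = 10L, rng_seed = 1L,
                                  min_coverage = 4L,
                                  orientation = c("divide", "multiply")) {
  orientation <- match.arg(orientation)
  if (fraction < 0 || fraction >= 1) abort("`fraction` must lie in [0, 1).")
  seeds <- as_seed_set(seeds)
  net_names <- names(collection$networks)

  baseline_fused <- loocv_auc(collection, seeds, params, min_coverage,
                              orientation)$auc
  single_auc_of <- function(net) {
    tryCatch(
      loocv_auc(network_collection(stats::setNames(list(net), net$name)),
                seeds, params, min_coverage = 1L, orientation)$auc,
      error = function(e) NA_real_
    )
  }
  baseline_single <- vapply(collection$networks, single_auc_of, 0)

  set.seed(rng_seed)
  rows <- list()
  for (rep_i in seq_len(reps)) {
    for (nm in net_names) {
      net <- collection$networks[[nm]]
      lnc <- node_ids(net, "lncRNA")
      n_rm <- floor(fraction * length(lnc))
      removed <- if (n_rm > 0) sample(lnc, n_rm) else character()
      depleted <- drop_network_nodes(net, removed)
      flagged <- n_edges(depleted) == 0L
      nets <- collection$networks
      nets[[nm]] <- depleted
      fused <- if (flagged) NA_real_ else {
        tryCatch(loocv_auc(network_collection(nets), seeds, params,
                           min_coverage, orientation)$auc,
                 error = function(e) NA_real_)
      }
      single <- if (flagged) NA_real_ else single_auc_of(depleted)
      rows[[length(rows) + 1L]] <- tibble(
        rep = rep_i, network = nm, fused_auc = fused, single_auc = single,
        fused_drop = baseline_fused - fused,
        single_drop = baseline_single[[nm]] - single,
        flagged = flagged | is.na(fused) | is.na(single)
      )
    }
  }
  tibble::new_tibble(dplyr::bind_rows(rows), class = "lnc_robustness",
                     baseline_fused = baseline_fused,
                     baseline_single = baseline_single,
                     fraction = fraction)
}

#' @export
glance.lnc_robustness <- function(x, ...) {
  ok <- !x$flagged
  tibble(
    baseline_fused_auc = attr(x, "baseline_fused"),
    mean_fused_drop = mean(x$fused_drop[ok]),
    mean_single_drop = mean(x$single_drop[ok]),
    best_single_network = names(which.max(attr(x, "baseline_single"))),
    n_flagged = sum(x$flagged)
  )
}

#' Single-network prioritization baseline
#'
#' Runs the walk-and-rank pipeline on one network alone (coverage filter 1,
#' no cross-network fusion beyond the degenerate N = 1 case) and evaluates
#' it with the same LOOCV/ROC protocol. Used as the baseline that the fused
#' multi-network prioritization is compared against.
#'
#' @param net A [bio_network()].
#' @inheritParams prioritize
#' @return A list of class `lnc_single_network`: `prioritization`, `cv`,
#'   `roc`, `auc`.
#' @export
single_network_prioritize <- function(net, seeds, params = rwr_params(),
                                      orientation = c("divide", "multiply")) {
  orientation <- match.arg(orientation)
  collection <- network_collection(stats::setNames(list(net), net$name))
  res <- prioritize(collection, seeds, params, min_coverage = 1L,
                    orientation = orientation)
  ev <- loocv_auc(collection, seeds, params, min_coverage = 1L,
                  orientation = orientation)
  structure(list(prioritization = res, cv = ev$cv, roc = ev$roc, auc = ev$auc),
            class = "lnc_single_network")
}

#' @export
print.lnc_single_network <- function(x, ...) {
  cat(sprintf("<lnc_single_network> %d candidate(s), LOOCV AUC = %.4f\n",
              nrow(x$prioritization), x$auc))
  invisible(x)
}

#' Write cross-validation records or ROC points as TSV
#'
#' @param x An `lnc_loocv` tibble or `lnc_roc` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(x, path) {
  if (inherits(x, "lnc_roc")) {
    readr::write_tsv(x$points, path)
  } else {
    readr::write_tsv(as_tibble(x), path)
  }
  invisible(path)
}
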