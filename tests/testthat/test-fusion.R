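test_that("rank ratio and min-max normalization follow the membership branches", {
  expect_equal(rank_ratio(1, 100), 0.01)
  expect_equal(rank_ratio(50, 50), 1)
  expect_equal(rank_ratio(NA, 10, member = FALSE), 1)
  expect_error(rank_ratio(101, 100), "<=")

  expect_equal(minmax_normalize(5, 0, 10), 0.5)
  expect_equal(minmax_normalize(7, 7, 7), 0)
  expect_equal(minmax_normalize(99, 0, 10, member = FALSE), 0)
  expect_error(minmax_normalize(11, 0, 10), "vmin")
})

test_that("overall score reproduces its closed forms", {
  expect_equal(overall_score(rep(1, 3), t = 1, bs = 0, ds = 0), log(2)^3)
  expect_equal(overall_score(exp(1) - 1, t = 1, bs = 0, ds = 0), 1)
  expect_equal(overall_score(c(0.1, 1), t = 0.5, bs = 0.4, ds = 0.6),
               oracle_score(c(0.1, 1), 0.5, 0.4, 0.6))
  expect_equal(overall_score(c(0.1, 1), t = 0.5, bs = 0.4, ds = 0.6),
               log(1.1) * log(2) / (0.5 * exp(1)), tolerance = 1e-12)
  # the alternative orientation moves the topology factor to the numerator
  expect_equal(overall_score(0.5, t = 0.5, bs = 0.3, ds = 0.2,
                             orientation = "multiply"),
               log(1.5) * exp(0.5) / 0.5)
  expect_error(overall_score(0, t = 1, bs = 0, ds = 0), "positive")
})

test_that("overall score matches the log-domain oracle on random profiles", {
  prof <- random_profiles(500, 9, seed = 31)
  s <- overall_score(prof$r, prof$t, prof$bs, prof$ds)
  for (i in seq_len(50)) {
    expect_equal(s[i], oracle_score(prof$r[i, ], prof$t[i], prof$bs[i], prof$ds[i]),
                 tolerance = 1e-12)
  }
  expect_true(all(s > 0))
  expect_true(all(s <= 9 * log(2)^9 / pmin(prof$t, 1) + 1e-9))
})

test_that("the score is monotone in each fusion component", {
  prof <- random_profiles(200, 5, seed = 32)
  s <- overall_score(prof$r, prof$t, prof$bs, prof$ds)
  set.seed(33)
  for (i in sample(200, 50)) {
    j <- sample(5, 1)
    r2 <- prof$r[i, ]
    r2[j] <- min(1, r2[j] + runif(1, 0.01, 0.3) * (1 - r2[j]) + 1e-6)
    if (r2[j] > prof$r[i, j]) {
      expect_gt(overall_score(r2, prof$t[i], prof$bs[i], prof$ds[i]), s[i])
    }
    if (prof$t[i] < 1) {
      expect_lt(overall_score(prof$r[i, ], prof$t[i] + 1 / 5,
                              prof$bs[i], prof$ds[i]), s[i])
    }
    expect_lt(overall_score(prof$r[i, ], prof$t[i],
                            min(1, prof$bs[i] + 0.1), prof$ds[i]), s[i])
    expect_lt(overall_score(prof$r[i, ], prof$t[i], prof$bs[i],
                            min(1, prof$ds[i] + 0.1)), s[i])
  }
})

test_that("topology profiles aggregate membership, ranks and normalized topology", {
  # three small networks over partially overlapping node sets
  n1 <- star_graph("hub", c("x", "y", "z"), name = "A")
  n2 <- path_graph(c("x", "hub", "y"))
  n2$name <- "B"
  n3 <- bio_network(data.frame(from = "x", to = "w"), name = "C")
  coll <- network_collection(list(A = n1, B = n2, C = n3))
  ranks <- list(
    A = structure(tibble::tibble(node_id = c("x", "y", "z"), rank = c(1, 2, 3)),
                  n_candidates = 3L),
    B = structure(tibble::tibble(node_id = c("x", "y"), rank = c(1, 2)),
                  n_candidates = 2L),
    C = structure(tibble::tibble(node_id = c("x", "w"), rank = c(1, 2)),
                  n_candidates = 2L)
  )
  prof <- build_topology_profiles(coll, ranks, c("x", "y", "w"))
  x <- prof[prof$node_id == "x", ]
  expect_equal(x$coverage, 3L)
  expect_equal(x$coverage_frac, 1)
  expect_equal(x$r_A, 1 / 3)
  expect_equal(x$r_B, 1 / 2)
  w <- prof[prof$node_id == "w", ]
  expect_equal(w$coverage, 1L)
  expect_equal(w$coverage_frac, 1 / 3)
  expect_equal(w$r_A, 1)  # absent -> worst ratio
  expect_equal(w$b_A, 0)  # absent -> no topology credit

  # the max-degree, max-betweenness node of its single network gets bs = ds = 1
  coll1 <- network_collection(list(A = n1))
  ranksA <- list(A = structure(tibble::tibble(node_id = "hub", rank = 1),
                               n_candidates = 1L))
  ph <- build_topology_profiles(coll1, ranksA, "hub")
  expect_equal(ph$avg_betweenness, 1)
  expect_equal(ph$avg_degree, 1)

  expect_message(
    prof2 <- build_topology_profiles(coll, ranks, c("x", "nowhere")),
    "present in no network"
  )
  expect_false("nowhere" %in% prof2$node_id)
})

test_that("coverage growth never increases the score at fixed topology averages", {
  prof <- random_profiles(300, 9, seed = 34)
  set.seed(35)
  for (i in sample(300, 60)) {
    T0 <- round(prof$t[i] * 9)
    if (T0 >= 9) next
    absent <- sample(9, 1)
    r0 <- prof$r[i, ]
    r0[absent] <- 1                       # candidate absent from this network
    s0 <- overall_score(r0, T0 / 9, prof$bs[i], prof$ds[i])
    r1 <- r0
    r1[absent] <- runif(1, 0.01, 1)       # now a member at any rank
    s1 <- overall_score(r1, (T0 + 1) / 9, prof$bs[i], prof$ds[i])
    expect_lte(s1, s0 + 1e-15)
  }
})

test_that("prioritization is deterministic and invariant to network order", {
  sim <- tiny_sim()
  res1 <- suppressMessages(prioritize(sim$collection, sim$gold))
  res2 <- suppressMessages(prioritize(sim$collection, sim$gold))
  expect_identical(tidy(res1), tidy(res2))

  perm <- rev(seq_along(sim$collection$networks))
  shuffled <- network_collection(sim$collection$networks[perm])
  res3 <- suppressMessages(prioritize(shuffled, sim$gold))
  m <- match(res1$node_id, res3$node_id)
  expect_equal(res1$overall_score, res3$overall_score[m], tolerance = 1e-12)
  expect_equal(res1$final_rank, res3$final_rank[m])
})

test_that("symmetric candidates tie and uniformly better candidates score lower", {
  # three identical stars seeded at the centre: all leaves are exchangeable
  leaves <- paste0("l", 1:4)
  stars <- lapply(1:3, function(i) star_graph("hub", leaves, name = paste0("S", i)))
  names(stars) <- paste0("S", 1:3)
  coll <- network_collection(stars)
  res <- suppressMessages(prioritize(coll, "hub", min_coverage = 1))
  expect_equal(length(unique(res$overall_score)), 1L)
  expect_equal(res$final_rank, rep(mean(seq_len(4)), 4))

  # A always ranked first, B always last, identical topology otherwise
  ranks <- list(N = structure(tibble::tibble(node_id = c("A", "B"), rank = c(1, 2)),
                              n_candidates = 2L))
  sA <- overall_score(rank_ratio(1, 10), 1, 0.2, 0.2)
  sB <- overall_score(rank_ratio(10, 10), 1, 0.2, 0.2)
  expect_lt(sA, sB)
})

test_that("coverage filtering and seed exclusion shape the candidate list", {
  sim <- tiny_sim()
  res <- suppressMessages(prioritize(sim$collection, sim$gold, min_coverage = 4))
  expect_true(all(res$coverage >= 4))
  expect_false(any(sim$gold$lnc_seeds %in% res$node_id))
  res1 <- suppressMessages(prioritize(sim$collection, sim$gold, min_coverage = 1))
  expect_gte(nrow(res1), nrow(res))
  expect_error(prioritize(sim$collection, c("ghost1", "ghost2")), "No network")
})

test_that("tidy and glance expose the result as plain tabular data", {
  sim <- tiny_sim()
  res <- suppressMessages(prioritize(sim$collection, sim$gold))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "lnc_prioritization"))
  g <- glance(res)
  expect_equal(g$n_candidates, nrow(res))
  expect_equal(g$n_networks, 9L)
  expect_equal(g$top_candidate, res$node_id[1])
})
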