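test_that("simulation is a deterministic function of its seed", {
  a <- simulate_collection(sim_params(n_lnc = 50, n_mrna = 20, n_mirna = 15,
                                      module_size = 5, rng_seed = 9))
  b <- simulate_collection(sim_params(n_lnc = 50, n_mrna = 20, n_mirna = 15,
                                      module_size = 5, rng_seed = 9))
  for (nm in names(a$collection$networks)) {
    expect_identical(a$collection$networks[[nm]]$edges,
                     b$collection$networks[[nm]]$edges)
  }
  expect_identical(a$module, b$module)
  c_ <- simulate_collection(sim_params(n_lnc = 50, n_mrna = 20, n_mirna = 15,
                                       module_size = 5, rng_seed = 10))
  expect_false(identical(a$collection$networks[[1]]$edges,
                         c_$collection$networks[[1]]$edges))
})

test_that("extreme wiring parameters force a module clique on clean layers", {
  sim <- simulate_collection(sim_params(
    n_lnc = 40, n_mrna = 10, n_mirna = 10, module_size = 6,
    p_in = 1, p_out = 0, topology_boost = 1, missing_frac = 0,
    informative_frac = 1, rng_seed = 2
  ))
  for (nm in c("LCN", "LCE", "LFS", "LSS")) {
    net <- sim$collection$networks[[nm]]
    deg <- node_degree(net, intersect(sim$module, node_ids(net)))
    expect_true(all(deg == length(sim$module) - 1))
    expect_equal(n_edges(net), choose(length(sim$module), 2))
  }
})

test_that("parameter validation rejects impossible settings", {
  expect_error(sim_params(module_size = 400), "< `n_lnc`")
  expect_error(sim_params(p_in = 0.1, p_out = 0.2), "p_out < p_in")
  expect_error(sim_params(missing_frac = 1), "missing_frac")
  expect_error(sim_params(n_networks = 10), "1..9")
})

test_that("the committed fixture plants hub-like knowns covered by >= 4 networks", {
  sim <- default_sim()
  cov <- node_coverage(sim$collection)
  expect_true(all(cov$coverage[cov$node_id %in% sim$module] >= 4))

  n_sig <- 0
  for (net in sim$collection$networks) {
    mod <- intersect(sim$module, node_ids(net))
    bg <- setdiff(node_ids(net, "lncRNA"), sim$module)
    if (length(mod) < 3) next
    w <- stats::wilcox.test(node_degree(net, mod), node_degree(net, bg),
                            alternative = "greater", exact = FALSE)
    if (w$p.value < 0.01) n_sig <- n_sig + 1
  }
  expect_gte(n_sig, 6)
})

test_that("expression simulation reproduces planted correlations", {
  ids <- sprintf("L%04d", 1:60)
  template <- bio_network(
    data.frame(from = ids[seq(1, 40, 2)], to = ids[seq(2, 40, 2)]),
    nodes = ids, name = "planted"
  )
  noiseless <- simulate_expression(template, n_samples = 20, noise_sd = 0,
                                   rng_seed = 4)
  m <- as_expression_matrix(noiseless$expr_a)
  for (k in 1:5) {
    expect_equal(stats::cor(m[template$edges$from[k], ], m[template$edges$to[k], ]),
                 1, tolerance = 1e-12)
  }

  noisy <- simulate_expression(template, n_samples = 50, noise_sd = 0.3,
                               rng_seed = 4)
  recovered <- coexpression_network(noisy$expr_a)
  planted <- paste(template$edges$from, template$edges$to)
  got <- paste(recovered$edges$from, recovered$edges$to)
  jaccard <- length(intersect(planted, got)) / length(union(planted, got))
  expect_gte(jaccard, 0.8)

  none <- bio_network(NULL, nodes = ids, name = "null")
  flat <- simulate_expression(none, n_samples = 30, noise_sd = 0.3, rng_seed = 5)
  expect_lte(n_edges(coexpression_network(flat$expr_a)), 2)
})

test_that("interval simulation bookkeeping matches the CLIP filter exactly", {
  all_in <- simulate_intervals(n_sites = 50, contained_frac = 1, rng_seed = 1)
  kept <- attr(clip_filter(all_in$sites, all_in$clusters), "retained_sites")
  expect_equal(nrow(kept), 50L)

  none <- simulate_intervals(n_sites = 50, contained_frac = 0, rng_seed = 1)
  kept0 <- attr(clip_filter(none$sites, none$clusters), "retained_sites")
  expect_equal(nrow(kept0), 0L)

  half <- simulate_intervals(n_sites = 200, contained_frac = 0.5, rng_seed = 7)
  expect_equal(sum(half$contained), 100L)
  kept_half <- attr(clip_filter(half$sites, half$clusters), "retained_sites")
  key <- function(df) paste(df$sequence_id, df$start, df$end, df$label)
  expect_setequal(key(kept_half), key(half$sites[half$contained, ]))
})

test_that("simulated BLAST hits filter back to exactly the planted pairs", {
  pairs <- data.frame(from = sprintf("L%04d", 1:10),
                      to = sprintf("L%04d", 11:20))
  hits <- simulate_blast_hits(pairs, rng_seed = 6)
  net <- sequence_similarity_filter(hits)
  expect_setequal(paste(net$edges$from, net$edges$to),
                  paste(pairs$from, pairs$to))
})

test_that("a written study directory reads back to the same collection", {
  dir <- withr::local_tempdir()
  sim <- write_simulated_inputs(dir, sim_params(
    n_lnc = 40, n_mrna = 20, n_mirna = 15, module_size = 5, rng_seed = 3
  ))
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(file.exists(file.path(dir, "blast_hits.tsv")))
  study <- read_study_dir(dir)
  expect_identical(names(study$collection$networks),
                   names(sim$collection$networks))
  for (nm in names(sim$collection$networks)) {
    expect_identical(study$collection$networks[[nm]]$edges[c("from", "to")],
                     sim$collection$networks[[nm]]$edges[c("from", "to")])
    expect_identical(study$collection$networks[[nm]]$nodes,
                     sim$collection$networks[[nm]]$nodes)
  }
  expect_identical(study$seeds$lnc_seeds, sim$gold$lnc_seeds)
})
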