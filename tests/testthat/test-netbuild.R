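expr_tbl <- function(m) {
  dplyr::bind_cols(tibble::tibble(feature_id = rownames(m)),
                   tibble::as_tibble(m))
}

test_that("co-expression edges require both the correlation and FDR thresholds", {
  set.seed(5)
  m <- rbind(x = c(1, 2, 3, 4), y = c(2, 4, 6, 8),
             neg = c(4, 3, 2, 1),
             matrix(rnorm(50 * 4), 50, 4,
                    dimnames = list(paste0("z", 1:50), NULL)))
  colnames(m) <- paste0("s", 1:4)
  net <- coexpression_network(expr_tbl(m))
  has_edge <- function(net, a, b) {
    any((net$edges$from == min(a, b)) & (net$edges$to == max(a, b)))
  }
  expect_true(has_edge(net, "x", "y"))       # PCC = 1, p = 0
  expect_false(has_edge(net, "x", "neg"))    # PCC = -1 fails PCC > 0.8

  # under the null nothing should survive
  set.seed(99)
  null_m <- matrix(rnorm(100 * 20), 100, 20,
                   dimnames = list(paste0("f", 1:100), paste0("s", 1:20)))
  null_net <- coexpression_network(expr_tbl(null_m))
  expect_lte(n_edges(null_net), 2)

  expect_error(coexpression_network(expr_tbl(m[, 1:2])), "3 samples")
  flat <- rbind(m, flatline = rep(1, 4))
  expect_message(coexpression_network(expr_tbl(flat)), "zero-variance")
})

test_that("cross-matrix co-expression is invariant under joint sample permutation", {
  set.seed(6)
  a <- matrix(rnorm(10 * 12), 10, 12,
              dimnames = list(paste0("l", 1:10), paste0("s", 1:12)))
  b <- rbind(a[1:3, ] + matrix(rnorm(36, sd = 0.1), 3),
             matrix(rnorm(5 * 12), 5, 12))
  rownames(b) <- paste0("g", 1:8)
  colnames(b) <- colnames(a)
  net1 <- coexpression_network(expr_tbl(a), expr_tbl(b))
  perm <- sample(12)
  net2 <- coexpression_network(expr_tbl(a[, perm]), expr_tbl(b[, perm]))
  expect_identical(net1$edges[c("from", "to")], net2$edges[c("from", "to")])
  expect_gt(n_edges(net1), 0)
})

test_that("BP annotation transfers only over-represented terms", {
  # lnc1 co-expressed with 5 genes that all carry term T, which only those
  # 5 of the 100 universe genes carry: p = 1 / choose(100, 5)
  genes <- sprintf("g%03d", 1:100)
  ann_tbl <- rbind(
    data.frame(gene_id = genes, term = "GO:common"),  # background term on all
    data.frame(gene_id = genes[1:5], term = "GO:rare")
  )
  lmcn <- bio_network(
    data.frame(from = "lnc1", to = genes[1:5]),
    nodes = c(stats::setNames("lncRNA", "lnc1"),
              stats::setNames(rep("mRNA", 100), genes)),
    name = "LMCN"
  )
  # declare all universe genes as nodes so the default universe sees them
  lmcn$nodes <- dplyr::bind_rows(
    lmcn$nodes,
    tibble::tibble(node_id = setdiff(genes, lmcn$nodes$node_id), node_type = "mRNA")
  )
  ann <- annotate_lncrna_bp(lmcn, ann_tbl)
  expect_true("GO:rare" %in% ann$lnc_terms$lnc1)
  expect_equal(oracle_hyper_tail(100, 5, 5, 5), 1 / choose(100, 5))
  # the term carried by every gene matches background frequency: p = 1
  expect_false("GO:common" %in% ann$lnc_terms$lnc1)
  expect_equal(ann$M, 2L)

  lonely <- bio_network(NULL, nodes = c(lonely = "lncRNA"), name = "LMCN")
  ann2 <- annotate_lncrna_bp(lonely, ann_tbl)
  expect_identical(ann2$lnc_terms$lonely, character())
})

test_that("functional similarity p-value matches its closed forms", {
  expect_equal(functional_similarity_pvalue(3, 4, 0, 10), 1)
  expect_equal(functional_similarity_pvalue(10, 10, 10, 10), 1)
  expect_equal(functional_similarity_pvalue(4, 5, 4, 10),
               choose(5, 4) * choose(5, 0) / choose(10, 4))
  expect_error(functional_similarity_pvalue(4, 5, 6, 10), "<=")
})

test_that("hypergeometric tails are monotone in the overlap and match enumeration", {
  set.seed(12)
  for (i in 1:50) {
    M <- sample(5:25, 1)
    La <- sample(1:M, 1)
    Lb <- sample(1:M, 1)
    ks <- max(0, La + Lb - M):min(La, Lb)
    p <- functional_similarity_pvalue(La, Lb, ks, M)
    expect_true(all(diff(p) <= 1e-14))
    for (k in ks) {
      expect_equal(functional_similarity_pvalue(La, Lb, k, M),
                   oracle_hyper_tail(M, Lb, La, k), tolerance = 1e-12)
      expect_equal(cerna_pvalue(La, Lb, k, M),
                   oracle_hyper_tail(M, Lb, La, k), tolerance = 1e-12)
    }
  }
})

test_that("functional similarity network links significantly overlapping term sets", {
  terms20 <- sprintf("GO:%04d", 1:20)
  ann <- structure(list(
    M = 5000L,
    lnc_terms = list(a = terms20, b = terms20, c = sprintf("GO:x%02d", 1:10)),
    gene_terms = list()
  ), class = "bp_annotation")
  net <- functional_similarity_network(ann)
  expect_equal(net$edges$from, "a")
  expect_equal(net$edges$to, "b")

  solo <- structure(list(M = 100L, lnc_terms = list(a = terms20),
                         gene_terms = list()), class = "bp_annotation")
  expect_equal(n_edges(functional_similarity_network(solo)), 0L)
})

test_that("ceRNA network requires significantly shared miRNA partner sets", {
  mk_bipartite <- function(pairs) {
    rna <- unique(pairs$from)
    mir <- unique(pairs$to)
    bio_network(pairs,
                nodes = c(stats::setNames(rep("lncRNA", length(rna)), rna),
                          stats::setNames(rep("miRNA", length(mir)), mir)))
  }
  mirs <- sprintf("mir%03d", 1:10)
  shared <- mk_bipartite(data.frame(from = rep(c("A", "B"), each = 10),
                                    to = rep(mirs, 2)))
  net <- cerna_network(shared, universe_size = 500)
  expect_equal(n_edges(net), 1L)

  disjoint <- mk_bipartite(data.frame(from = rep(c("A", "B"), each = 3),
                                      to = paste0("mir", 1:6)))
  expect_equal(n_edges(cerna_network(disjoint)), 0L)

  # full overlap of the full universe carries no signal: p = 1
  expect_equal(cerna_pvalue(10, 10, 10, 10), 1)
  expect_equal(n_edges(cerna_network(shared)), 0L)  # U defaults to 10 here

  nonbi <- bio_network(data.frame(from = "A", to = "B"),
                       nodes = c(A = "lncRNA", B = "lncRNA"))
  expect_error(cerna_network(nonbi), "bipartite")
})

test_that("sequence similarity filter applies strict thresholds and drops self-hits", {
  hits <- tibble::tibble(
    qseqid = c("A", "A", "A", "B", "A"),
    sseqid = c("B", "B", "C", "A", "A"),
    evalue = c(1e-6, 1e-6, 1e-5, 1e-6, 1e-20),
    bitscore = c(85, 80.0, 85, 90, 500)
  )
  net <- sequence_similarity_filter(hits)
  # A-B kept (first hit passes; the bitscore-80 hit alone would not; the
  # e-value boundary hit for A-C fails; the self-hit is discarded)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$from, "A")
  expect_equal(net$edges$to, "B")

  boundary <- tibble::tibble(qseqid = "A", sseqid = "B",
                             evalue = 1e-6, bitscore = 80.0)
  expect_equal(n_edges(sequence_similarity_filter(boundary)), 0L)
})

test_that("BLAST outfmt-6 parsing validates structure per line", {
  f <- withr::local_tempfile()
  writeLines(c("q1\ts1\t98.0\t100\t1\t0\t1\t100\t1\t100\t1e-30\t180",
               "q1\ts2\tnot_a_number\t100\t1\t0\t1\t100\t1\t100\t1e-30\t180"), f)
  expect_error(read_blast_table(f), "line 2")
  writeLines("q1\ts1\t98.0\t100", f)
  expect_error(read_blast_table(f), "12 fields")
  writeLines("q1\ts1\t98.0\t100\t1\t0\t1\t100\t1\t100\t1e-30\t180", f)
  tab <- read_blast_table(f)
  expect_equal(tab$evalue, 1e-30)
  expect_equal(tab$bitscore, 180)
})

test_that("CLIP support requires full containment, with closed boundaries", {
  site <- function(s, e) tibble::tibble(sequence_id = "lnc1", start = s, end = e,
                                        label = "mir1")
  clus <- function(s, e) tibble::tibble(sequence_id = "lnc1", start = s, end = e,
                                        label = "c1")
  expect_equal(n_edges(clip_filter(site(10, 20), clus(5, 30))), 1L)
  expect_equal(n_edges(clip_filter(site(10, 20), clus(12, 30))), 0L)
  expect_equal(n_edges(clip_filter(site(10, 20), clus(10, 20))), 1L)
  expect_equal(n_edges(clip_filter(site(10, 20), clus(5, 30)[0, ])), 0L)
})

test_that("widening CLIP clusters never removes support (monotonicity)", {
  iv <- simulate_intervals(n_sites = 80, contained_frac = 0.4, rng_seed = 3)
  before <- clip_filter(iv$sites, iv$clusters)
  wider <- dplyr::mutate(iv$clusters,
                         start = pmax(0, start - 15), end = end + 15)
  after <- clip_filter(iv$sites, wider)
  key <- function(net) paste(net$edges$from, net$edges$to)
  expect_true(all(key(before) %in% key(after)))
  # and the output is always a subset of the input site pairs
  in_pairs <- unique(paste(pmin(iv$sites$sequence_id, iv$sites$label),
                           pmax(iv$sites$sequence_id, iv$sites$label)))
  expect_true(all(key(after) %in% in_pairs))
})

test_that("pair tables become deduplicated typed networks", {
  pairs <- data.frame(a = c("l1", "l2", "l3", "l1", "l4"),
                      b = c("p1", "p2", "p3", "p1", "p1"))
  net <- pairs_to_network(pairs, name = "LPI", type_a = "lncRNA",
                          type_b = "protein")
  expect_equal(n_edges(net), 4L)  # exact duplicate collapses
  expect_equal(sort(node_ids(net, "protein")), c("p1", "p2", "p3"))
  expect_equal(n_edges(pairs_to_network(pairs[0, ], name = "LPI")), 0L)

  both_orders <- data.frame(a = c("l1", "l2"), b = c("l2", "l1"))
  expect_equal(n_edges(pairs_to_network(both_orders, name = "LCN",
                                        type_b = "lncRNA")), 1L)
})
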