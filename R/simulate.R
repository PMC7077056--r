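#' Parameters of the synthetic multi-network generator
#'
#' The generator plants a module of "known cancer" lncRNAs whose members are
#' densely interconnected (directly, or through shared partner molecules in
#' bipartite networks) and mildly hub-like, against a sparse background --
#' the structure that known cancer lncRNAs show in real lncRNA-centric
#' networks (higher degree and betweenness than other candidates, and
#' recoverable from the remaining knowns by network propagation).
#'
#' @param n_lnc,n_mrna,n_mirna,n_protein,n_tf Node counts per class.
#' @param n_networks Number of networks (up to 9, drawn in order from the
#'   templates LCN, LCE, LFS, LSS, LMCN, LMCE, LMI, LPI, LTFI: four
#'   lncRNA-lncRNA layers, then lncRNA-mRNA/miRNA/protein/TF layers).
#' @param module_size Number of planted known cancer lncRNAs.
#' @param p_in Edge probability between informative module members (or
#'   between an informative member and a module-associated partner node).
#' @param p_out Background edge probability.
#' @param topology_boost Multiplier on `p_out` for edges incident to module
#'   nodes, giving the knowns their hub-like excess degree.
#' @param missing_frac Per-network node dropout: each node is absent from a
#'   given network with this probability, emulating incomplete data.
#'   Module lncRNAs are exempt in the four lncRNA-lncRNA layers, so every
#'   planted known is covered by at least 4 networks by construction.
#' @param informative_frac Fraction of the module each network actually
#'   "sees": every layer captures a random subset of the module's
#'   connectivity, as real heterogeneous evidence types do. This is what
#'   makes the fused prioritization beat any single layer.
#' @param rng_seed Integer seed; the whole collection is a deterministic
#'   function of the parameters.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_lnc = 300L, n_mrna = 200L, n_mirna = 100L,
                       n_protein = 60L, n_tf = 30L, n_networks = 9L,
                       module_size = 15L, p_in = 0.5, p_out = 0.02,
                       topology_boost = 1.5, missing_frac = 0.15,
                       informative_frac = 0.7, rng_seed = 42L) {
  p <- list(n_lnc = as.integer(n_lnc), n_mrna = as.integer(n_mrna),
            n_mirna = as.integer(n_mirna), n_protein = as.integer(n_protein),
            n_tf = as.integer(n_tf), n_networks = as.integer(n_networks),
            module_size = as.integer(module_size), p_in = p_in, p_out = p_out,
            topology_boost = topology_boost, missing_frac = missing_frac,
            informative_frac = informative_frac, rng_seed = as.integer(rng_seed))
  if (p$module_size >= p$n_lnc) abort("`module_size` must be < `n_lnc`.")
  if (p$module_size < 1L) abort("`module_size` must be >= 1.")
  if (!(p$p_out >= 0 && p$p_out < p$p_in && p$p_in <= 1)) {
    abort("Need 0 <= p_out < p_in <= 1.")
  }
  if (p$missing_frac < 0 || p$missing_frac >= 1) abort("`missing_frac` must lie in [0, 1).")
  if (p$informative_frac <= 0 || p$informative_frac > 1) {
    abort("`informative_frac` must lie in (0, 1].")
  }
  if (p$n_networks < 1L || p$n_networks > 9L) abort("`n_networks` must be in 1..9.")
  structure(p, class = "sim_params")
}

net_templates <- function() {
  tibble(
    name = c("LCN", "LCE", "LFS", "LSS", "LMCN", "LMCE", "LMI", "LPI", "LTFI"),
    partner = c(NA, NA, NA, NA, "mRNA", "mRNA", "miRNA", "protein", "TF")
  )
}

bernoulli_pairs <- function(a, b, prob) {
  keep <- stats::runif(length(prob)) < prob
  tibble(from = a[keep], to = b[keep])
}

#' Simulate a network collection with a planted cancer-lncRNA module
#'
#' Generates `n_networks` networks over shared node pools following the
#' layer templates (lncRNA-lncRNA co-expression/ceRNA/functional/sequence
#' similarity, then bipartite lncRNA-mRNA/miRNA/protein/TF layers). See
#' [sim_params()] for the planted structure. The planted module doubles as
#' the gold-standard seed set for cross-validation.
#'
#' @param params A [sim_params()] object.
#' @return A list with `collection` (a [network_collection()]), `gold`
#'   (a [seed_set()] of the module members), `module` (their ids) and
#'   `params`.
#' @export
simulate_collection <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$rng_seed)

  pools <- list(
    lncRNA = new_ids("L", params$n_lnc),
    mRNA = new_ids("M", params$n_mrna),
    miRNA = new_ids("R", params$n_mirna),
    protein = new_ids("P", params$n_protein),
    TF = new_ids("F", params$n_tf)
  )
  module <- sort(sample(pools$lncRNA, params$module_size))
  templates <- net_templates()[seq_len(params$n_networks), ]

  nets <- purrr::pmap(templates, function(name, partner) {
    unipartite <- is.na(partner)
    core_layer <- unipartite  # module exempt from dropout in lnc-lnc layers
    lnc_keep <- stats::runif(params$n_lnc) >= params$missing_frac
    if (core_layer) lnc_keep[pools$lncRNA %in% module] <- TRUE
    lnc <- pools$lncRNA[lnc_keep]
    mod_here <- intersect(module, lnc)
    informative <- mod_here[stats::runif(length(mod_here)) < params$informative_frac]

    if (unipartite) {
      n <- length(lnc)
      idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      a <- lnc[idx[, 1L]]
      b <- lnc[idx[, 2L]]
      inf_a <- a %in% informative
      inf_b <- b %in% informative
      mod_a <- a %in% mod_here
      mod_b <- b %in% mod_here
      prob <- rep(params$p_out, length(a))
      prob[mod_a | mod_b] <- pmin(1, params$p_out * params$topology_boost)
      prob[inf_a & inf_b] <- params$p_in
      ed <- bernoulli_pairs(a, b, prob)
      # keep every module node attached in the core layers so that the
      # planted knowns are guaranteed members of >= 4 networks
      isolated <- setdiff(mod_here, unique(c(ed$from, ed$to)))
      if (length(isolated)) {
        anchor <- vapply(isolated, function(x) sample(setdiff(mod_here, x), 1L), "")
        ed <- dplyr::bind_rows(ed, tibble(from = isolated, to = anchor))
      }
      bio_network(ed, name = name, default_type = "lncRNA")
    } else {
      pool_b <- pools[[partner]]
      pb_keep <- stats::runif(length(pool_b)) >= params$missing_frac
      pb <- pool_b[pb_keep]
      mod_partners <- sample(pb, max(3L, ceiling(0.15 * length(pb))))
      grid <- expand.grid(i = seq_along(lnc), k = seq_along(pb))
      a <- lnc[grid$i]
      b <- pb[grid$k]
      prob <- rep(params$p_out, length(a))
      boost <- a %in% mod_here
      prob[boost] <- pmin(1, params$p_out * params$topology_boost)
      hit <- a %in% informative & b %in% mod_partners
      prob[hit] <- params$p_in
      ed <- bernoulli_pairs(a, b, prob)
      types <- c(stats::setNames(rep("lncRNA", length(lnc)), lnc),
                 stats::setNames(rep(partner, length(pb)), pb))
      used <- unique(c(ed$from, ed$to))
      bio_network(ed, nodes = types[used], name = name, default_type = "lncRNA")
    }
  })
  names(nets) <- templates$name
  collection <- network_collection(nets)
  if (!any(module %in% collection$membership$node_id)) {
    abort("Simulation produced a module present in no network; increase p_in or module_size.")
  }
  list(collection = collection,
       gold = seed_set(module, cancer = "synthetic"),
       module = module,
       params = params)
}

#' Simulate expression profiles for a planted co-expression network
#'
#' Every edge of the template network gets its own latent factor shared by
#' its two endpoint features; a feature's profile is the sum of the latents
#' of its incident edges (its own private factor if it has none) plus
#' Gaussian noise. For a degree-1 pair the population correlation is
#' `1 / (1 + noise_sd^2)`, so the default recovers the planted edges at
#' `PCC > 0.8` while unrelated features stay uncorrelated.
#'
#' @param net_template A [bio_network()] whose edges are the planted
#'   co-expressed pairs. A bipartite lncRNA-mRNA template yields two
#'   expression tables; a unipartite one yields a single table.
#' @param n_samples Number of samples (>= 4).
#' @param noise_sd Standard deviation of the per-feature noise.
#' @param rng_seed Integer seed.
#' @return A list with `expr_a` (tibble, `feature_id` + sample columns),
#'   `expr_b` (tibble or `NULL`), and `pairs` (the planted edges).
#' @export
simulate_expression <- function(net_template, n_samples = 50L, noise_sd = 0.3,
                                rng_seed = 1L) {
  if (n_samples < 4L) abort("`n_samples` must be >= 4.")
  set.seed(rng_seed)
  nodes <- net_template$nodes
  ed <- net_template$edges
  samples <- sprintf("S%03d", seq_len(n_samples))

  Z <- matrix(stats::rnorm(nrow(ed) * n_samples), nrow = max(1L, nrow(ed)))
  expr <- matrix(0, nrow(nodes), n_samples,
                 dimnames = list(nodes$node_id, samples))
  for (i in seq_len(nrow(nodes))) {
    id <- nodes$node_id[i]
    inc <- which(ed$from == id | ed$to == id)
    signal <- if (length(inc)) colSums(Z[inc, , drop = FALSE]) else stats::rnorm(n_samples)
    expr[i, ] <- signal + noise_sd * stats::rnorm(n_samples)
  }

  to_tbl <- function(m) {
    dplyr::bind_cols(tibble(feature_id = rownames(m)), as_tibble(m))
  }
  lnc <- nodes$node_id[nodes$node_type == "lncRNA"]
  other <- setdiff(nodes$node_id, lnc)
  if (length(other)) {
    list(expr_a = to_tbl(expr[lnc, , drop = FALSE]),
         expr_b = to_tbl(expr[other, , drop = FALSE]),
         pairs = ed[c("from", "to")])
  } else {
    list(expr_a = to_tbl(expr), expr_b = NULL, pairs = ed[c("from", "to")])
  }
}

#' Simulate miRNA binding sites and AGO-CLIP clusters
#'
#' Lays each predicted site in its own 100-bp window of an lncRNA sequence
#' and constructs, for a chosen fraction of sites, a cluster that fully
#' contains the site; the remaining sites get either a strictly partial
#' overlap or no cluster at all. [clip_filter()] therefore retains exactly
#' the constructed-contained sites.
#'
#' @param n_sites Number of predicted sites.
#' @param contained_frac Fraction of sites fully contained in a cluster.
#' @param n_lnc,n_mirna Sizes of the lncRNA and miRNA label pools.
#' @param rng_seed Integer seed.
#' @return A list with `sites`, `clusters` (interval tibbles) and
#'   `contained` (logical vector marking the constructed-contained sites).
#' @export
simulate_intervals <- function(n_sites = 200L, contained_frac = 0.5,
                               n_lnc = 50L, n_mirna = 30L, rng_seed = 7L) {
  if (contained_frac < 0 || contained_frac > 1) {
    abort("`contained_frac` must lie in [0, 1].")
  }
  set.seed(rng_seed)
  lnc <- new_ids("L", n_lnc)
  mir <- new_ids("R", n_mirna)
  seq_id <- sample(lnc, n_sites, replace = TRUE)
  slot <- stats::ave(seq_along(seq_id), seq_id, FUN = seq_along)
  base <- (slot - 1L) * 100L
  sites <- tibble(sequence_id = seq_id, start = base + 40L, end = base + 60L,
                  label = sample(mir, n_sites, replace = TRUE))
  contained <- rep(FALSE, n_sites)
  contained[sample.int(n_sites, round(contained_frac * n_sites))] <- TRUE

  idx_in <- which(contained)
  idx_part <- which(!contained)[c(TRUE, FALSE)][seq_len(ceiling(sum(!contained) / 2))]
  idx_part <- idx_part[!is.na(idx_part)]
  clusters <- dplyr::bind_rows(
    tibble(sequence_id = seq_id[idx_in], start = base[idx_in] + 30L,
           end = base[idx_in] + 70L,
           label = sprintf("cluster%04d", idx_in)),
    tibble(sequence_id = seq_id[idx_part], start = base[idx_part] + 50L,
           end = base[idx_part] + 90L,
           label = sprintf("cluster%04d", idx_part))
  )
  list(sites = sites, clusters = clusters, contained = contained)
}

#' Simulate a BLAST tabular result with planted similar pairs
#'
#' Planted pairs receive hits passing both retention thresholds
#' (`evalue < 1e-5`, `bitscore > 80`); an equal number of decoy hits fail
#' one threshold or the other, and a few self-hits are thrown in.
#'
#' @param similar_pairs Tibble `from`, `to` of lncRNA pairs to plant.
#' @param rng_seed Integer seed.
#' @return A tibble in the 12-column BLAST outfmt-6 layout.
#' @export
simulate_blast_hits <- function(similar_pairs, rng_seed = 1L) {
  set.seed(rng_seed)
  sp <- as_tibble(similar_pairs)
  n <- nrow(sp)
  ids <- unique(c(sp$from, sp$to))
  mk <- function(q, s, evalue, bits) {
    len <- sample(100:900, length(q), replace = TRUE)
    tibble(qseqid = q, sseqid = s,
           pident = round(stats::runif(length(q), 80, 100), 2),
           length = len, mismatch = sample(0:20, length(q), replace = TRUE),
           gapopen = sample(0:3, length(q), replace = TRUE),
           qstart = 1, qend = len, sstart = 1, send = len,
           evalue = evalue, bitscore = bits)
  }
  good <- mk(sp$from, sp$to,
             10^stats::runif(n, -30, -6), stats::runif(n, 90, 300))
  decoy_q <- sample(ids, n, replace = TRUE)
  decoy_s <- sample(ids, n, replace = TRUE)
  weak_e <- stats::runif(n) < 0.5
  decoys <- mk(decoy_q, decoy_s,
               ifelse(weak_e, 10^stats::runif(n, -4, 0), 10^stats::runif(n, -30, -6)),
               ifelse(weak_e, stats::runif(n, 90, 300), stats::runif(n, 20, 80)))
  selfs <- mk(ids[seq_len(min(3L, length(ids)))], ids[seq_len(min(3L, length(ids)))],
              1e-50, 500)
  dplyr::bind_rows(good, decoys, selfs)
}

#' Simulate a flat gene-to-GO-BP annotation table
#'
#' @param genes Character vector of gene ids.
#' @param n_terms Size of the BP term universe.
#' @param terms_per_gene Average annotations per gene.
#' @param rng_seed Integer seed.
#' @return Tibble `gene_id`, `term`.
#' @export
simulate_go_annotations <- function(genes, n_terms = 100L, terms_per_gene = 4L,
                                    rng_seed = 1L) {
  set.seed(rng_seed)
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  purrr::map_dfr(genes, function(g) {
    k <- max(1L, stats::rpois(1L, terms_per_gene))
    tibble(gene_id = g, term = sample(terms, min(k, n_terms)))
  })
}

#' Write a simulated study to disk in the package's external formats
#'
#' Materializes a simulated collection as edge-list TSVs plus a manifest,
#' the gold-standard seed list, and companion raw inputs (an expression
#' pair for the co-expression builder, binding sites/clusters in BED-like
#' TSV, a BLAST table, and a GO annotation table), so every file-based
#' entry point of the package can be exercised without downloads.
#'
#' @param dir Output directory (created if needed).
#' @param params A [sim_params()] object.
#' @return The simulation list of [simulate_collection()], invisibly, with
#'   an added `files` element.
#' @export
write_simulated_inputs <- function(dir, params = sim_params()) {
  sim <- simulate_collection(params)
  dir.create(file.path(dir, "networks"), recursive = TRUE, showWarnings = FALSE)
  files <- purrr::imap_chr(sim$collection$networks, function(net, nm) {
    f <- file.path(dir, "networks", paste0(nm, ".tsv"))
    write_edge_list(net, f)
    readr::write_tsv(net$nodes, file.path(dir, "networks", paste0(nm, ".nodes.tsv")))
    f
  })
  nms <- names(sim$collection$networks)
  manifest <- tibble(
    name = nms,
    file = file.path("networks", paste0(nms, ".tsv")),
    nodes_file = file.path("networks", paste0(nms, ".nodes.tsv"))
  )
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  writeLines(sim$gold$lnc_seeds, file.path(dir, "seeds.txt"))

  expr <- simulate_expression(sim$collection$networks[[1L]],
                              rng_seed = params$rng_seed)
  readr::write_tsv(expr$expr_a, file.path(dir, "expression_lncRNA.tsv"))
  iv <- simulate_intervals(rng_seed = params$rng_seed)
  readr::write_tsv(iv$sites, file.path(dir, "mirna_sites.bed"), col_names = FALSE)
  readr::write_tsv(iv$clusters, file.path(dir, "ago_clusters.bed"), col_names = FALSE)
  pairs <- utils::head(sim$collection$networks[[1L]]$edges[c("from", "to")], 50L)
  readr::write_tsv(simulate_blast_hits(pairs, rng_seed = params$rng_seed),
                   file.path(dir, "blast_hits.tsv"), col_names = FALSE)
  genes <- utils::head(sim$collection$membership$node_id[
    sim$collection$membership$node_type == "mRNA"], 100L)
  if (length(genes)) {
    readr::write_tsv(simulate_go_annotations(genes, rng_seed = params$rng_seed),
                     file.path(dir, "go_annotations.tsv"), col_names = FALSE)
  }
  sim$files <- c(files, manifest = file.path(dir, "manifest.tsv"))
  invisible(sim)
}

#' Read a simulated (or equivalently laid out) study directory
#'
#' Expects the `manifest.tsv` + `networks/` + `seeds.txt` layout of
#' [write_simulated_inputs()].
#'
#' @param dir Study directory.
#' @param cancer Label for the seed set.
#' @return A list with `collection` and `seeds`.
#' @export
read_study_dir <- function(dir, cancer = "study") {
  manifest <- readr::read_tsv(file.path(dir, "manifest.tsv"), show_col_types = FALSE)
  nets <- purrr::pmap(manifest, function(name, file, nodes_file) {
    types <- readr::read_tsv(file.path(dir, nodes_file), show_col_types = FALSE)
    read_edge_list(file.path(dir, file), node_types = types, header = TRUE,
                   name = name)
  })
  names(nets) <- manifest$name
  seeds <- readLines(file.path(dir, "seeds.txt"))
  list(collection = network_collection(nets),
       seeds = seed_set(seeds, cancer = cancer))
}
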