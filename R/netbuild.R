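#' Coerce an expression table to a feature-by-sample matrix
#'
#' Expression tables follow the TSV layout `feature_id` in the first column
#' and one column per sample. Values must be finite; duplicate feature or
#' sample ids are an error.
#'
#' @param x A data frame in that layout, or a numeric matrix with feature
#'   rownames (returned as-is after checks).
#' @return A numeric matrix, features in rows.
#' @export
as_expression_matrix <- function(x) {
  if (is.matrix(x)) {
    m <- x
    if (is.null(rownames(m))) abort("Expression matrix needs feature rownames.")
  } else {
    x <- as.data.frame(x)
    m <- as.matrix(x[, -1L, drop = FALSE])
    rownames(m) <- as.character(x[[1L]])
  }
  storage.mode(m) <- "double"
  if (anyDuplicated(rownames(m))) abort("Duplicate feature ids in expression data.")
  if (anyDuplicated(colnames(m))) abort("Duplicate sample ids in expression data.")
  if (!all(is.finite(m))) abort("Expression values must all be finite.")
  m
}

# two-sided p-value for a Pearson correlation via the t transform with
# n - 2 degrees of freedom; |r| = 1 maps to p = 0
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  p <- numeric(length(r))
  edge <- abs(r) >= 1
  p[edge] <- 0
  tt <- abs(r[!edge]) * sqrt((n - 2) / (1 - r[!edge]^2))
  p[!edge] <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  p
}

#' Build a co-expression network by correlation thresholding
#'
#' Computes the Pearson correlation of every feature pair (the upper
#' triangle when `expr_b` is `NULL`, i.e. the lncRNA-lncRNA case; all
#' cross pairs otherwise, the lncRNA-mRNA case), derives two-sided p-values
#' from the t transform with n - 2 degrees of freedom, adjusts them with
#' Benjamini-Hochberg over all pairs tested in the call, and keeps the
#' pairs with `PCC > pcc_min` and adjusted p `< fdr_max` as edges (weighted
#' by the correlation). Zero-variance features cannot be tested and are
#' skipped with a message.
#'
#' @param expr_a Expression table (see [as_expression_matrix()]).
#' @param expr_b Optional second expression table over the same samples in
#'   the same order; `NULL` correlates `expr_a` with itself.
#' @param pcc_min Correlation threshold (strict `>`).
#' @param fdr_max Adjusted p-value threshold (strict `<`).
#' @param type_a,type_b Node types for the two feature sets.
#' @param name Network name.
#' @return A [bio_network()] whose nodes are the features incident to at
#'   least one retained edge.
#' @export
coexpression_network <- function(expr_a, expr_b = NULL, pcc_min = 0.8,
                                 fdr_max = 0.01, type_a = "lncRNA",
                                 type_b = "mRNA", name = "coexpression") {
  a <- as_expression_matrix(expr_a)
  self <- is.null(expr_b)
  b <- if (self) a else as_expression_matrix(expr_b)
  if (ncol(a) < 3L) abort("Co-expression needs at least 3 samples.")
  if (!identical(colnames(a), colnames(b))) {
    abort("The two expression tables must share an identically ordered sample set.")
  }
  n <- ncol(a)

  sd_a <- apply(a, 1L, stats::sd)
  sd_b <- if (self) sd_a else apply(b, 1L, stats::sd)
  skip <- sum(sd_a == 0) + if (self) 0L else sum(sd_b == 0)
  if (skip > 0) {
    inform(sprintf("Skipped %d zero-variance feature(s).", skip))
  }
  a_ok <- a[sd_a > 0, , drop = FALSE]
  b_ok <- b[sd_b > 0, , drop = FALSE]
  if (nrow(a_ok) < 1L || nrow(b_ok) < (if (self) 2L else 1L)) {
    return(bio_network(NULL, name = name, default_type = type_a))
  }

  cc <- stats::cor(t(a_ok), t(b_ok))
  if (self) {
    idx <- which(upper.tri(cc), arr.ind = TRUE)
  } else {
    idx <- as.matrix(expand.grid(row = seq_len(nrow(a_ok)), col = seq_len(nrow(b_ok))))
  }
  r <- cc[idx]
  p_adj <- stats::p.adjust(cor_pvalue(r, n), method = "BH")
  keep <- r > pcc_min & p_adj < fdr_max
  ed <- tibble(from = rownames(a_ok)[idx[keep, 1L]],
               to = rownames(b_ok)[idx[keep, 2L]],
               weight = r[keep])
  types <- c(stats::setNames(rep(type_a, nrow(a_ok)), rownames(a_ok)),
             if (!self) stats::setNames(rep(type_b, nrow(b_ok)), rownames(b_ok)))
  used <- unique(c(ed$from, ed$to))
  bio_network(ed, nodes = types[used], name = name, default_type = type_a)
}

#' Annotate lncRNAs with enriched GO biological-process terms
#'
#' Transfers flat GO BP annotation from mRNAs to lncRNAs via guilt by
#' association: for every lncRNA in the lncRNA-mRNA co-expression network,
#' each BP term carried by its co-expressed mRNAs is tested for
#' over-representation among those partners against the annotated gene
#' universe (hypergeometric upper tail), and terms with a per-lncRNA
#' Benjamini-Hochberg adjusted p below `fdr_max` become the lncRNA's term
#' set. lncRNAs with no annotated partner simply get an empty set.
#'
#' @param lmcn An lncRNA-mRNA co-expression [bio_network()].
#' @param gene_terms Gene-to-term table: a data frame `gene_id`, `term`
#'   (one row per annotation) or a named list of term character vectors.
#' @param universe Gene universe for the enrichment test; defaults to all
#'   annotated mRNA nodes of `lmcn`.
#' @param fdr_max Per-lncRNA BH-adjusted threshold for assigning a term.
#' @return A list of class `bp_annotation` with `M` (number of distinct BP
#'   terms in the annotation universe), `lnc_terms` and `gene_terms`
#'   (named lists of term character vectors).
#' @export
annotate_lncrna_bp <- function(lmcn, gene_terms, universe = NULL,
                               fdr_max = 0.01) {
  gt <- as_term_list(gene_terms)
  mrna <- node_ids(lmcn, "mRNA")
  lnc <- node_ids(lmcn, "lncRNA")
  universe <- universe %||% intersect(mrna, names(gt))
  gt_u <- gt[intersect(universe, names(gt))]
  n_universe <- length(gt_u)
  term_count <- table(unlist(gt_u, use.names = FALSE))
  all_terms <- sort(unique(unlist(gt, use.names = FALSE)))

  neighbors <- dplyr::bind_rows(
    dplyr::select(lmcn$edges, lnc = "from", partner = "to"),
    dplyr::select(lmcn$edges, lnc = "to", partner = "from")
  ) |>
    dplyr::filter(.data$lnc %in% !!lnc, .data$partner %in% names(gt_u))

  lnc_terms <- stats::setNames(vector("list", length(lnc)), lnc)
  for (l in lnc) {
    partners <- neighbors$partner[neighbors$lnc == l]
    if (!length(partners)) {
      lnc_terms[[l]] <- character()
      next
    }
    hit <- table(unlist(gt_u[partners], use.names = FALSE))
    terms <- names(hit)
    K <- as.integer(term_count[terms])
    p <- stats::phyper(as.integer(hit) - 1L, K, n_universe - K,
                       length(partners), lower.tail = FALSE)
    lnc_terms[[l]] <- sort(terms[stats::p.adjust(p, "BH") < fdr_max])
  }

  structure(list(M = length(all_terms), lnc_terms = lnc_terms, gene_terms = gt),
            class = "bp_annotation")
}

as_term_list <- function(gene_terms) {
  if (is.list(gene_terms) && !is.data.frame(gene_terms)) {
    return(lapply(gene_terms, function(x) unique(as.character(x))))
  }
  df <- as.data.frame(gene_terms)
  split(as.character(df[[2L]]), as.character(df[[1L]])) |>
    lapply(unique)
}

#' @export
print.bp_annotation <- function(x, ...) {
  cat(sprintf("<bp_annotation> %d lncRNA(s), %d gene(s), %d BP term universe\n",
              length(x$lnc_terms), length(x$gene_terms), x$M))
  invisible(x)
}

#' Functional-similarity p-value for two annotated lncRNAs
#'
#' Upper-tail hypergeometric probability that two lncRNAs annotated with
#' `La` and `Lb` of the `M` BP terms share at least `k` terms by chance:
#' `P(X >= k)` for `X ~ Hypergeom(M, Lb, La)`.
#'
#' @param La,Lb Term-set sizes of the two lncRNAs.
#' @param k Number of shared terms.
#' @param M Size of the BP term universe.
#' @return p-value(s) in `[0, 1]`.
#' @examples
#' functional_similarity_pvalue(4, 5, 4, 10)  # choose(5,4)/choose(10,4)
#' @export
functional_similarity_pvalue <- function(La, Lb, k, M) {
  n <- max(length(La), length(Lb), length(k), length(M))
  La <- rep_len(La, n); Lb <- rep_len(Lb, n)
  k <- rep_len(k, n); M <- rep_len(M, n)
  if (any(k < 0 | k > pmin(La, Lb) | pmax(La, Lb) > M | La + Lb - k > M)) {
    abort("Need 0 <= k <= min(La, Lb) <= M and La + Lb - k <= M.")
  }
  stats::phyper(k - 1, Lb, M - Lb, La, lower.tail = FALSE)
}

#' Functional similarity network from BP annotation
#'
#' Connects lncRNA pairs whose assigned BP term sets overlap more than
#' expected by chance: for each pair the shared-term count feeds
#' [functional_similarity_pvalue()], p-values are Benjamini-Hochberg
#' adjusted over all tested pairs, and pairs below `fdr_max` become edges.
#'
#' @param ann A `bp_annotation` from [annotate_lncrna_bp()].
#' @param fdr_max Adjusted p-value threshold.
#' @param name Network name.
#' @return A [bio_network()] of lncRNA nodes.
#' @export
functional_similarity_network <- function(ann, fdr_max = 0.01, name = "LFS") {
  stopifnot(inherits(ann, "bp_annotation"))
  lnc <- names(ann$lnc_terms)
  if (length(lnc) < 2L) return(bio_network(NULL, name = name))
  pairs <- utils::combn(lnc, 2L)
  La <- lengths(ann$lnc_terms)[pairs[1L, ]]
  Lb <- lengths(ann$lnc_terms)[pairs[2L, ]]
  k <- mapply(function(a, b) length(intersect(ann$lnc_terms[[a]], ann$lnc_terms[[b]])),
              pairs[1L, ], pairs[2L, ])
  p <- functional_similarity_pvalue(La, Lb, k, ann$M)
  keep <- stats::p.adjust(p, "BH") < fdr_max
  bio_network(tibble(from = pairs[1L, keep], to = pairs[2L, keep]),
              name = name, default_type = "lncRNA")
}

#' ceRNA overlap p-value
#'
#' Upper-tail hypergeometric probability that two RNAs with `m` and `n`
#' miRNA partners out of a universe of `U` miRNAs share at least `s`
#' partners by chance: `P(X >= s)`, `X ~ Hypergeom(U, n, m)`.
#'
#' @param m,n Partner-set sizes of the two RNAs.
#' @param s Number of shared miRNA partners.
#' @param U miRNA universe size.
#' @return p-value(s) in `[0, 1]`.
#' @export
cerna_pvalue <- function(m, n, s, U) {
  k <- max(length(m), length(n), length(s), length(U))
  m <- rep_len(m, k); n <- rep_len(n, k); s <- rep_len(s, k); U <- rep_len(U, k)
  if (any(s < 0 | s > pmin(m, n) | pmax(m, n) > U | m + n - s > U)) {
    abort("Need 0 <= s <= min(m, n) <= U and m + n - s <= U.")
  }
  stats::phyper(s - 1, n, U - n, m, lower.tail = FALSE)
}

#' Competing-endogenous-RNA network from shared miRNA partners
#'
#' Two RNAs that bind many of the same miRNAs are candidate ceRNA partners:
#' they can de-repress each other by competing for the shared miRNA pool.
#' For every pair of non-miRNA nodes of the bipartite interaction network
#' with miRNA partner sets of sizes `m` and `n` out of a universe of `U`
#' miRNAs, the shared count `s` is scored with the hypergeometric upper
#' tail `P(X >= s)`, `X ~ Hypergeom(U, n, m)`; Benjamini-Hochberg adjusted
#' p-values below `fdr_max` become edges.
#'
#' @param interactions A bipartite [bio_network()] whose edges all connect a
#'   miRNA node to a non-miRNA RNA node (lncRNA or mRNA).
#' @param fdr_max Adjusted p-value threshold.
#' @param universe_size miRNA universe size `U`; defaults to the number of
#'   miRNA nodes in `interactions`.
#' @param name Network name.
#' @return A [bio_network()] over the RNA nodes.
#' @export
cerna_network <- function(interactions, fdr_max = 0.01, universe_size = NULL,
                          name = "ceRNA") {
  types <- stats::setNames(interactions$nodes$node_type, interactions$nodes$node_id)
  ed <- interactions$edges
  from_mir <- types[ed$from] == "miRNA"
  to_mir <- types[ed$to] == "miRNA"
  if (any(from_mir == to_mir)) {
    abort("Input must be bipartite: every edge must join a miRNA to a non-miRNA RNA.")
  }
  rna <- ifelse(from_mir, ed$to, ed$from)
  mir <- ifelse(from_mir, ed$from, ed$to)
  U <- universe_size %||% length(unique(mir))

  partners <- split(mir, rna)
  rnas <- names(partners)
  if (length(rnas) < 2L) return(bio_network(NULL, name = name))
  sizes <- lengths(partners)
  if (any(sizes > U)) abort("`universe_size` smaller than an observed partner set.")
  pairs <- utils::combn(rnas, 2L)
  m <- sizes[pairs[1L, ]]
  n_ <- sizes[pairs[2L, ]]
  s <- mapply(function(a, b) length(intersect(partners[[a]], partners[[b]])),
              pairs[1L, ], pairs[2L, ])
  p <- cerna_pvalue(m, n_, s, U)
  keep <- stats::p.adjust(p, "BH") < fdr_max
  node_types <- types[rnas]
  bio_network(tibble(from = pairs[1L, keep], to = pairs[2L, keep]),
              nodes = node_types[unique(c(pairs[1L, keep], pairs[2L, keep]))],
              name = name, default_type = "lncRNA")
}

#' Read BLAST tabular output (outfmt 6)
#'
#' Parses the standard 12-column tab-separated BLAST format; columns 11 and
#' 12 are the e-value and bit score. Extra columns are carried along
#' untouched; malformed lines are an error naming the line number.
#'
#' @param path File path.
#' @return A tibble with the 12 standard columns (`qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`).
#' @export
read_blast_table <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  line_no <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 12L)
  if (length(bad)) {
    abort(sprintf("Malformed outfmt-6 line %d of %s: fewer than 12 fields.",
                  line_no[bad[1L]], path))
  }
  df <- tibble(
    qseqid = vapply(parts, `[[`, "", 1L),
    sseqid = vapply(parts, `[[`, "", 2L)
  )
  for (i in 3:12) {
    v <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", i)))
    if (anyNA(v)) {
      abort(sprintf("Non-numeric %s at line %d of %s.",
                    cols[i], line_no[which(is.na(v))[1L]], path))
    }
    df[[cols[i]]] <- v
  }
  if (any(df$evalue < 0) || any(df$bitscore < 0)) {
    abort("e-values and bit scores must be non-negative.")
  }
  df
}

#' Sequence similarity network from BLAST hits
#'
#' Keeps the unordered query-subject pairs with at least one hit passing
#' both strict thresholds (`evalue < evalue_max` and
#' `bitscore > bitscore_min`); self-hits are discarded.
#'
#' @param hits A tibble of BLAST hits with at least `qseqid`, `sseqid`,
#'   `evalue`, `bitscore` (e.g. from [read_blast_table()]).
#' @param evalue_max E-value cutoff (strict `<`).
#' @param bitscore_min Bit-score cutoff (strict `>`).
#' @param name Network name.
#' @return A [bio_network()] of lncRNA nodes.
#' @export
sequence_similarity_filter <- function(hits, evalue_max = 1e-5,
                                       bitscore_min = 80.0, name = "LSS") {
  keep <- hits$evalue < evalue_max & hits$bitscore > bitscore_min &
    hits$qseqid != hits$sseqid
  bio_network(tibble(from = hits$qseqid[keep], to = hits$sseqid[keep]),
              name = name, default_type = "lncRNA")
}

validate_intervals <- function(x, what) {
  x <- as_tibble(x)
  need <- c("sequence_id", "start", "end", "label")
  if (!all(need %in% names(x))) {
    abort(sprintf("`%s` needs columns %s.", what, paste(need, collapse = ", ")))
  }
  if (any(x$start < 0 | x$start >= x$end)) {
    abort(sprintf("`%s` intervals must satisfy 0 <= start < end.", what))
  }
  x
}

#' Read a BED-like interval table
#'
#' `sequence_id<TAB>start<TAB>end<TAB>label` with 0-based half-open
#' coordinates; `#` comment lines skipped.
#'
#' @param path File path.
#' @param header Whether the first non-comment line is a header.
#' @return Tibble `sequence_id`, `start`, `end`, `label`.
#' @export
read_bed_intervals <- function(path, header = FALSE) {
  df <- readr::read_tsv(path, comment = "#",
                        col_names = if (header) TRUE else c("sequence_id", "start", "end", "label"),
                        show_col_types = FALSE)
  if (header) names(df)[1:4] <- c("sequence_id", "start", "end", "label")
  validate_intervals(df[1:4], basename(path))
}

#' Filter predicted miRNA binding sites by AGO-CLIP support
#'
#' A predicted miRNA binding site on an lncRNA is kept only when it is
#' fully contained in an Argonaute CLIP cluster on the same sequence
#' (`cluster_start <= site_start` and `site_end <= cluster_end`; 0-based
#' half-open, boundary containment counts). The surviving
#' (lncRNA, miRNA) pairs, deduplicated, form the CLIP-supported
#' interaction network.
#'
#' @param sites Predicted binding sites: tibble `sequence_id` (the lncRNA),
#'   `start`, `end`, `label` (the miRNA).
#' @param clusters AGO-CLIP clusters on the same coordinate system; the
#'   `label` column is a free-text cluster id.
#' @param name Network name.
#' @return A [bio_network()] of lncRNA-miRNA edges, with the retained sites
#'   in attribute `retained_sites`.
#' @export
clip_filter <- function(sites, clusters, name = "LMI") {
  sites <- validate_intervals(sites, "sites")
  clusters <- validate_intervals(clusters, "clusters")
  if (nrow(sites) == 0L) {
    net <- bio_network(NULL, name = name)
    attr(net, "retained_sites") <- sites
    return(net)
  }
  hit <- dplyr::inner_join(
    dplyr::mutate(sites, .site = dplyr::row_number()),
    dplyr::select(clusters, "sequence_id", cs = "start", ce = "end"),
    by = "sequence_id", relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$cs <= .data$start, .data$end <= .data$ce)
  retained <- sites[sort(unique(hit$.site)), , drop = FALSE]
  types <- c(stats::setNames(rep("lncRNA", length(unique(retained$sequence_id))),
                             unique(retained$sequence_id)),
             stats::setNames(rep("miRNA", length(unique(retained$label))),
                             unique(retained$label)))
  net <- bio_network(tibble(from = retained$sequence_id, to = retained$label),
                     nodes = types, name = name)
  attr(net, "retained_sites") <- retained
  net
}

#' Interaction network from a two-column pair table
#'
#' Turns curated interaction pairs (lncRNA-protein, lncRNA-TF,
#' lncRNA-miRNA, ...) into a deduplicated undirected network with node
#' types declared per column.
#'
#' @param pairs A two-column data frame or the path to a two-column TSV
#'   (read with [read_edge_list()] semantics, no header by default).
#' @param name Network name.
#' @param type_a,type_b Node types of the first and second column.
#' @param header Whether a file input has a header line.
#' @return A [bio_network()].
#' @export
pairs_to_network <- function(pairs, name, type_a = "lncRNA", type_b = "protein",
                             header = FALSE) {
  if (is.character(pairs) && length(pairs) == 1L) {
    pairs <- readr::read_tsv(pairs, comment = "#",
                             col_names = isTRUE(header),
                             col_types = readr::cols(.default = readr::col_character()),
                             show_col_types = FALSE)
  }
  df <- as.data.frame(pairs)
  if (ncol(df) < 2L) abort("`pairs` needs two columns.")
  types <- c(stats::setNames(rep(type_a, length(unique(as.character(df[[1L]])))),
                             unique(as.character(df[[1L]]))),
             stats::setNames(rep(type_b, length(unique(as.character(df[[2L]])))),
                             unique(as.character(df[[2L]]))))
  types <- types[!duplicated(names(types))]
  bio_network(df[1:2], nodes = types, name = name, default_type = type_a)
}
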