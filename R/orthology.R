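# Orthology from reciprocal best hits, protein distances, and
# cluster-based sequence diversity.

#' Gene-level aggregation of protein hits
#'
#' For every directed gene pair the best protein-variant pair (by summed
#' bitscore) represents the genes; that pair's alignment segments are
#' concatenated with query-overlaps resolved best-bitscore-first, giving a
#' length-weighted identity and a coverage relative to the query protein
#' length.
#' @noRd
.gene_level_hits <- function(hits, gene_of, protein_lengths) {
  unk <- setdiff(unique(c(hits$query_id, hits$subject_id)), names(gene_of))
  if (length(unk))
    stop("protein id not mappable to a gene: ", unk[1])
  hits$qgene <- unname(gene_of[hits$query_id])
  hits$sgene <- unname(gene_of[hits$subject_id])
  out <- list()
  for (key in unique(paste(hits$qgene, hits$sgene, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- hits[hits$qgene == parts[1] & hits$sgene == parts[2], , drop = FALSE]
    # best protein variant pair by summed bitscore
    vp <- paste(sub$query_id, sub$subject_id, sep = "\r")
    tot <- tapply(sub$bitscore, vp, sum)
    best_vp <- names(tot)[order(-tot, names(tot))][1]
    sub <- sub[vp == best_vp, , drop = FALSE]
    sub <- sub[order(-sub$bitscore), , drop = FALSE]
    # accept segments greedily, skipping query-overlapping ones
    acc <- logical(nrow(sub))
    ivs <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(nrow(sub))) {
      lo <- min(sub$q_start[i], sub$q_end[i]); hi <- max(sub$q_start[i], sub$q_end[i])
      if (!nrow(ivs) || all(hi < ivs[, 1] | lo > ivs[, 2])) {
        acc[i] <- TRUE
        ivs <- rbind(ivs, c(lo, hi))
      }
    }
    sub <- sub[acc, , drop = FALSE]
    alen <- sum(sub$alignment_length)
    qp <- strsplit(best_vp, "\r", fixed = TRUE)[[1]][1]
    qlen <- protein_lengths[[qp]]
    if (is.null(qlen))
      stop("protein length missing for ", qp)
    out[[key]] <- data.frame(
      qgene = parts[1], sgene = parts[2],
      identity = sum(sub$percent_identity * sub$alignment_length) / alen,
      coverage = 100 * sum(abs(sub$q_end - sub$q_start) + 1) / qlen,
      bitscore = sum(sub$bitscore), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Reciprocal-best-hit orthologs at the gene level
#'
#' A gene pair (a, b) is orthologous when b is a's best gene-level hit and
#' a is b's, where gene-level hits concatenate the alignment segments of
#' the best protein-variant pair, and both directions pass the identity
#' and coverage cutoffs.  Ties are broken by bitscore, then by
#' lexicographic subject gene id.
#'
#' @param hits_ab,hits_ba Hit tables (see [read_table()]) for the two
#'   search directions.
#' @param gene_of Named character vector mapping protein ids (both
#'   species) to gene ids.
#' @param protein_lengths Named numeric vector of protein lengths (aa).
#' @param min_identity,min_coverage Percent cutoffs applied to the
#'   concatenated gene-level alignment (defaults 60 and 40).
#' @return An `orthology_map`: list with `pairs` (data frame `gene_a,
#'   gene_b, identity, coverage`), `unpaired_a`, `unpaired_b`.
#' @export
rbh_orthologs <- function(hits_ab, hits_ba, gene_of, protein_lengths,
                          min_identity = 60, min_coverage = 40) {
  gl_ab <- .gene_level_hits(hits_ab, gene_of, protein_lengths)
  gl_ba <- .gene_level_hits(hits_ba, gene_of, protein_lengths)
  best_of <- function(gl) {
    if (is.null(gl)) return(NULL)
    out <- list()
    for (g in unique(gl$qgene)) {
      sub <- gl[gl$qgene == g, , drop = FALSE]
      sub <- sub[order(-sub$bitscore, sub$sgene), , drop = FALSE]
      out[[g]] <- sub[1, ]
    }
    do.call(rbind, out)
  }
  ba <- best_of(gl_ab); bb <- best_of(gl_ba)
  genes_a <- unique(unname(gene_of[unique(hits_ab$query_id)]))
  genes_b <- unique(unname(gene_of[unique(hits_ba$query_id)]))
  pairs <- list()
  for (g in rownames(ba %||% data.frame())) {
    cand <- ba[g, ]
    back <- if (!is.null(bb) && cand$sgene %in% rownames(bb))
      bb[cand$sgene, ] else NULL
    if (is.null(back) || back$sgene != g) next
    if (cand$identity < min_identity || back$identity < min_identity) next
    if (cand$coverage < min_coverage || back$coverage < min_coverage) next
    pairs[[g]] <- data.frame(gene_a = g, gene_b = cand$sgene,
                             identity = (cand$identity + back$identity) / 2,
                             coverage = (cand$coverage + back$coverage) / 2,
                             stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gene_a = character(0), gene_b = character(0),
               identity = numeric(0), coverage = numeric(0))
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 unpaired_a = setdiff(genes_a, pairs$gene_a),
                 unpaired_b = setdiff(genes_b, pairs$gene_b)),
            class = "orthology_map")
}

#' @export
print.orthology_map <- function(x, ...) {
  cat("<orthology_map> ", nrow(x$pairs), " 1:1 pairs; ",
      length(x$unpaired_a), " unpaired (A), ",
      length(x$unpaired_b), " unpaired (B)\n", sep = "")
  invisible(x)
}

#' Protein distance from an aligned sequence pair
#'
#' Columns containing a gap in either sequence are excluded (the
#' conserved-site convention); the observed proportion of differing sites
#' p is Poisson-corrected as -ln(1 - p).
#'
#' @param a,b Aligned sequences of equal length (strings or character
#'   vectors).
#' @param site_mask Optional logical vector selecting alignment columns
#'   (applied before gap filtering), so an external conserved-column mask
#'   can be honoured.
#' @return List of class `protein_distance` with `p_distance`,
#'   `poisson_distance`, `n_sites`.
#' @export
protein_distance <- function(a, b, site_mask = NULL) {
  av <- if (length(a) == 1L) strsplit(a, "")[[1]] else a
  bv <- if (length(b) == 1L) strsplit(b, "")[[1]] else b
  if (length(av) != length(bv))
    stop("aligned sequences must have equal length")
  if (!is.null(site_mask)) {
    av <- av[site_mask]; bv <- bv[site_mask]
  }
  keep <- av != "-" & bv != "-"
  n <- sum(keep)
  if (n == 0L) stop("no comparable (gap-free) columns")
  p <- sum(av[keep] != bv[keep]) / n
  if (p >= 1) stop("all sites differ; distance undefined")
  structure(list(p_distance = p, poisson_distance = -log(1 - p),
                 n_sites = n),
            class = "protein_distance")
}

#' Empirical cumulative distribution of pairwise ortholog distances
#'
#' @param orthology An `orthology_map`, or `NULL` when `distances` are
#'   supplied directly.
#' @param alignments List of aligned pairs (each a list/vector with the
#'   two aligned sequences), parallel to `orthology$pairs` rows.
#' @param distances Optional numeric vector of precomputed distances,
#'   bypassing `alignments`.
#' @param measure `"poisson"` (default) or `"p"`.
#' @return Data frame `distance, cum_fraction` (monotone, reaching 1 at
#'   the maximum distance), with the `stats::ecdf` as attribute `ecdf`.
#' @export
cumulative_distance_curve <- function(orthology = NULL, alignments = NULL,
                                      distances = NULL,
                                      measure = c("poisson", "p")) {
  measure <- match.arg(measure)
  if (is.null(distances)) {
    if (is.null(orthology) || nrow(orthology$pairs) < 1L)
      stop("at least one orthologous pair required")
    distances <- vapply(alignments, function(al) {
      pd <- protein_distance(al[[1]], al[[2]])
      if (measure == "poisson") pd$poisson_distance else pd$p_distance
    }, numeric(1))
  }
  if (!length(distances)) stop("no distances to summarize")
  d <- sort(distances)
  out <- data.frame(distance = d,
                    cum_fraction = seq_along(d) / length(d))
  attr(out, "ecdf") <- stats::ecdf(distances)
  out
}

#' Per-family divergence summary
#'
#' For each gene family: the number of 1:1 orthologous members, the mean
#' identity over those, and the count of species-specific genes (family
#' members with no 1:1 partner) on each side.
#'
#' @param family_of Named character vector gene id -> family id, covering
#'   genes of both species.
#' @param orthology An `orthology_map`.
#' @return Data frame per family: `family, n_pairs, mean_identity,
#'   specific_a, specific_b`.
#' @export
family_divergence_summary <- function(family_of, orthology) {
  prs <- orthology$pairs
  fams <- unique(unname(family_of))
  out <- list()
  for (f in fams) {
    members <- names(family_of)[family_of == f]
    if (!length(members)) {
      warning("family ", f, " has no members; skipped")
      next
    }
    sub <- prs[prs$gene_a %in% members & prs$gene_b %in% members, ,
               drop = FALSE]
    mem_a <- intersect(members, c(prs$gene_a, orthology$unpaired_a))
    mem_b <- intersect(members, c(prs$gene_b, orthology$unpaired_b))
    out[[f]] <- data.frame(
      family = f, n_pairs = nrow(sub),
      mean_identity = if (nrow(sub)) mean(sub$identity) else NA_real_,
      specific_a = length(setdiff(mem_a, sub$gene_a)),
      specific_b = length(setdiff(mem_b, sub$gene_b)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Single-linkage sequence diversity clustering
#'
#' Sequences are joined when a hit passes the identity and coverage
#' thresholds in both orientations; diversity is the number of connected
#' components (clusters), in the manner of Blastclust.
#'
#' @param ids Character vector of all sequence ids (singletons allowed).
#' @param hits Hit table of candidate pairs (directed rows).
#' @param seq_lengths Named numeric vector of sequence lengths, for
#'   coverage.
#' @param min_identity,min_coverage Percent thresholds.
#' @return List of class `diversity_clustering` with `clusters` (list of
#'   id vectors), `membership` (named integer), `n_clusters`,
#'   `thresholds`.
#' @export
cluster_diversity <- function(ids, hits, seq_lengths,
                              min_identity = 60, min_coverage = 50) {
  pass <- character(0)
  if (nrow(hits)) {
    cov <- 100 * (abs(hits$q_end - hits$q_start) + 1) /
      unname(seq_lengths[hits$query_id])
    ok <- hits$percent_identity >= min_identity & cov >= min_coverage
    pass <- paste(hits$query_id[ok], hits$subject_id[ok], sep = "\r")
  }
  both <- intersect(pass,
                    vapply(strsplit(pass, "\r", fixed = TRUE),
                           function(x) paste(x[2], x[1], sep = "\r"), ""))
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (length(both)) {
    ee <- unique(t(apply(do.call(rbind, strsplit(both, "\r", fixed = TRUE)),
                         1L, sort)))
    ee <- ee[ee[, 1] != ee[, 2], , drop = FALSE]
    if (nrow(ee)) g <- igraph::add_edges(g, t(ee))
  }
  comp <- igraph::components(g)
  membership <- stats::setNames(as.integer(comp$membership), ids)
  structure(list(clusters = split(ids, membership),
                 membership = membership,
                 n_clusters = comp$no,
                 thresholds = c(identity = min_identity,
                                coverage = min_coverage)),
            class = "diversity_clustering")
}
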