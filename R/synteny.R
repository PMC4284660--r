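# Bidirectional scaffold clustering for synteny dot plots.

#' Scaffold association and ordering from shared orthologs
#'
#' For every scaffold pair (one from each assembly) a 2x2 contingency
#' table of orthologous gene pairs (on both scaffolds vs elsewhere) is
#' tested with Fisher's exact test (two-sided); the score matrix holds
#' -log(P) (natural log).  Each side is then ordered by average-linkage
#' hierarchical clustering of its score profiles, giving the row/column
#' order for dot plots.  Scaffolds carrying no orthologs get infinite
#' dissimilarity entries and are placed last.
#'
#' @param orthology An `orthology_map`.
#' @param scaffold_a,scaffold_b Named character vectors mapping gene ids
#'   to scaffold names for each assembly.
#' @return List of class `synteny_clustering`: `score` (-log P matrix,
#'   rows = A scaffolds, cols = B scaffolds), `order_a`, `order_b` (leaf
#'   orders), `hclust_a`, `hclust_b`.
#' @export
synteny_clusters <- function(orthology, scaffold_a, scaffold_b) {
  prs <- orthology$pairs
  prs$sa <- unname(scaffold_a[prs$gene_a])
  prs$sb <- unname(scaffold_b[prs$gene_b])
  if (anyNA(prs$sa) || anyNA(prs$sb))
    stop("scaffold membership missing for some orthologous genes")
  sca <- sort(unique(scaffold_a))
  scb <- sort(unique(scaffold_b))
  if (length(sca) < 2L || length(scb) < 2L)
    stop("need at least 2 scaffolds per side")
  n <- nrow(prs)
  score <- matrix(0, length(sca), length(scb), dimnames = list(sca, scb))
  for (i in seq_along(sca)) for (j in seq_along(scb)) {
    n11 <- sum(prs$sa == sca[i] & prs$sb == scb[j])
    n12 <- sum(prs$sa == sca[i] & prs$sb != scb[j])
    n21 <- sum(prs$sa != sca[i] & prs$sb == scb[j])
    n22 <- n - n11 - n12 - n21
    p <- stats::fisher.test(matrix(c(n11, n21, n12, n22), 2L))$p.value
    score[i, j] <- -log(p)
  }
  empty_a <- sca[!sca %in% prs$sa]
  empty_b <- scb[!scb %in% prs$sb]
  score[empty_a, ] <- Inf
  score[, empty_b] <- Inf
  live_a <- setdiff(sca, empty_a); live_b <- setdiff(scb, empty_b)
  hc_a <- if (length(live_a) >= 3L)
    stats::hclust(stats::dist(score[live_a, live_b, drop = FALSE]),
                  method = "average") else NULL
  hc_b <- if (length(live_b) >= 3L)
    stats::hclust(stats::dist(t(score[live_a, live_b, drop = FALSE])),
                  method = "average") else NULL
  order_a <- c(if (is.null(hc_a)) live_a else live_a[hc_a$order], empty_a)
  order_b <- c(if (is.null(hc_b)) live_b else live_b[hc_b$order], empty_b)
  structure(list(score = score, order_a = order_a, order_b = order_b,
                 hclust_a = hc_a, hclust_b = hc_b),
            class = "synteny_clustering")
}

#' Export ortholog positions for a synteny dot plot
#'
#' One point per orthologous pair, with x/y given by the scaffold order
#' from [synteny_clusters()] and the gene rank within its scaffold.  A
#' TSV is always written; a PNG is drawn when `plot_path` is given.
#'
#' @param orthology An `orthology_map`.
#' @param clustering A `synteny_clustering`.
#' @param scaffold_a,scaffold_b Gene id -> scaffold maps.
#' @param pos_a,pos_b Named numeric vectors of gene start coordinates,
#'   used to rank genes within scaffolds.
#' @param path Output TSV path.
#' @param plot_path Optional PNG path.
#' @return The dot table (columns `gene_a, gene_b, x, y, scaffold_a,
#'   scaffold_b`), invisibly.
#' @export
dotplot_export <- function(orthology, clustering, scaffold_a, scaffold_b,
                           pos_a, pos_b, path, plot_path = NULL) {
  prs <- orthology$pairs
  prs$sa <- unname(scaffold_a[prs$gene_a])
  prs$sb <- unname(scaffold_b[prs$gene_b])
  global_rank <- function(genes, scaffold, pos, scaffold_order) {
    ord <- order(match(scaffold, scaffold_order), pos[genes])
    r <- integer(length(genes)); r[ord] <- seq_along(genes)
    r
  }
  prs$x <- global_rank(prs$gene_a, prs$sa, pos_a, clustering$order_a)
  prs$y <- global_rank(prs$gene_b, prs$sb, pos_b, clustering$order_b)
  out <- prs[, c("gene_a", "gene_b", "x", "y", "sa", "sb")]
  names(out)[5:6] <- c("scaffold_a", "scaffold_b")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(plot_path)) {
    grDevices::png(plot_path, width = 800, height = 800)
    plot(out$x, out$y, pch = 20, cex = 0.5,
         xlab = clustering$order_a[1], ylab = clustering$order_b[1],
         main = "ortholog dot plot")
    grDevices::dev.off()
  }
  invisible(out)
}
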