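# Reciprocal-best-hit orthology, protein distances and diversity
# clustering.

plens <- c(pa1 = 100, pa2 = 100, pb1 = 100, pb2 = 100)
gmap <- c(pa1 = "ga1", pa2 = "ga2", pb1 = "gb1", pb2 = "gb2")

test_that("symmetric unique best hits above cutoffs give one pair", {
  ab <- rbind(hit_row("pa1", "pb1", 90), hit_row("pa1", "pb2", 50))
  ba <- rbind(hit_row("pb1", "pa1", 90), hit_row("pb2", "pa1", 50))
  om <- rbh_orthologs(ab, ba, gmap, plens)
  expect_equal(nrow(om$pairs), 1L)
  expect_equal(om$pairs$gene_a, "ga1")
  expect_equal(om$pairs$gene_b, "gb1")
})

test_that("a best hit below the 60% identity cutoff is excluded", {
  ab <- hit_row("pa1", "pb1", 59)
  ba <- hit_row("pb1", "pa1", 59)
  om <- rbh_orthologs(ab, ba, gmap, plens)
  expect_equal(nrow(om$pairs), 0L)
  # exactly at the cutoff it is kept
  om2 <- rbh_orthologs(hit_row("pa1", "pb1", 60),
                       hit_row("pb1", "pa1", 60), gmap, plens)
  expect_equal(nrow(om2$pairs), 1L)
})

test_that("coverage is the concatenated segment length over the query", {
  # two non-overlapping 15 aa segments on a 100 aa protein: 30% < 40%
  ab <- rbind(hit_row("pa1", "pb1", 90, len = 15, qs = 1, qe = 15),
              hit_row("pa1", "pb1", 90, len = 15, qs = 50, qe = 64))
  ba <- rbind(hit_row("pb1", "pa1", 90, len = 15, qs = 1, qe = 15),
              hit_row("pb1", "pa1", 90, len = 15, qs = 50, qe = 64))
  om <- rbh_orthologs(ab, ba, gmap, plens)
  expect_equal(nrow(om$pairs), 0L)
  om2 <- rbh_orthologs(ab, ba, gmap, plens, min_coverage = 30)
  expect_equal(nrow(om2$pairs), 1L)
})

test_that("non-mappable protein ids are an error", {
  expect_error(rbh_orthologs(hit_row("nope", "pb1", 90),
                             hit_row("pb1", "nope", 90), gmap, plens),
               "not mappable")
})

test_that("raising min_identity never adds pairs", {
  set.seed(2)
  ids <- stats::setNames(paste0("g", 1:8),
                         paste0("p", 1:8))
  lens <- stats::setNames(rep(100, 8), paste0("p", 1:8))
  ab <- do.call(rbind, lapply(1:4, function(i)
    hit_row(paste0("p", i), paste0("p", i + 4), 50 + 12 * i)))
  ba <- do.call(rbind, lapply(1:4, function(i)
    hit_row(paste0("p", i + 4), paste0("p", i), 50 + 12 * i)))
  sizes <- vapply(c(50, 62, 74, 86, 99), function(cut)
    nrow(rbh_orthologs(ab, ba, ids, lens, min_identity = cut)$pairs),
    numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("simulated orthology is recovered exactly at low divergence", {
  px <- low_div_pair()
  hits <- derive_protein_hits(px$la$genome, px$lb$genome)
  om <- rbh_orthologs(hits$hits_ab, hits$hits_ba, hits$gene_of,
                      hits$protein_lengths)
  expect_setequal(paste(om$pairs$gene_a, om$pairs$gene_b),
                  paste(hits$truth$gene_a, hits$truth$gene_b))
})

test_that("protein distance follows the closed forms", {
  r <- protein_distance("AAAAAAAAAA", "AAAAAAAAAA")
  expect_equal(r$p_distance, 0)
  expect_equal(r$poisson_distance, 0)
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("C", 10), rep("A", 90)), collapse = "")
  r2 <- protein_distance(a, b)
  expect_equal(r2$p_distance, 0.10)
  expect_equal(r2$poisson_distance, -log(0.9), tolerance = 1e-9)
  # gap columns are excluded
  r3 <- protein_distance("AA-A", "AACA")
  expect_equal(r3$n_sites, 3)
  expect_error(protein_distance("--", "AA"), "no comparable")
})

test_that("simulated protein distance matches the planted value", {
  set.seed(7)
  n <- 4000
  p_true <- 0.19
  a <- sample(LETTERS[1:20], n, replace = TRUE)
  b <- a
  flip <- stats::runif(n) < p_true
  b[flip] <- vapply(a[flip], function(x)
    sample(setdiff(LETTERS[1:20], x), 1), character(1))
  est <- protein_distance(a, b)$p_distance
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(est - p_true), 3 * se)
})

test_that("cumulative distance curves are proper CDFs that order by
           divergence", {
  d1 <- c(0.1, 0.2, 0.15, 0.3)
  cc <- cumulative_distance_curve(distances = d1)
  expect_true(all(diff(cc$cum_fraction) >= 0))
  expect_equal(max(cc$cum_fraction), 1)
  cc0 <- cumulative_distance_curve(distances = rep(0, 5))
  expect_equal(unique(cc0$distance), 0)
  # stochastic dominance of the less diverged pair
  set.seed(4)
  lo <- stats::rbinom(300, 200, 0.1) / 200
  hi <- stats::rbinom(300, 200, 0.3) / 200
  f_lo <- attr(cumulative_distance_curve(distances = lo), "ecdf")
  f_hi <- attr(cumulative_distance_curve(distances = hi), "ecdf")
  grid <- seq(0, 0.5, by = 0.02)
  expect_true(all(f_lo(grid) >= f_hi(grid)))
})

test_that("family divergence separates paired and species-specific genes", {
  om <- structure(list(
    pairs = data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"),
                       identity = c(80, 90), coverage = c(90, 90)),
    unpaired_a = paste0("a", 3:10), unpaired_b = character(0)),
    class = "orthology_map")
  fam <- stats::setNames(rep("F1", 12), c(paste0("a", 1:10), "b1", "b2"))
  out <- family_divergence_summary(fam, om)
  expect_equal(out$n_pairs, 2L)
  expect_equal(out$specific_a, 8L)
  expect_equal(out$specific_b, 0L)
  expect_equal(out$mean_identity, 85)
})

test_that("diversity clustering is single-linkage over reciprocal edges", {
  ids <- c("a", "b", "c", "d")
  lens <- stats::setNames(rep(100, 4), ids)
  # chain a-b, b-c passing both ways; d isolated
  hits <- rbind(hit_row("a", "b", 90), hit_row("b", "a", 90),
                hit_row("b", "c", 90), hit_row("c", "b", 90),
                hit_row("a", "d", 90))  # one-directional: no edge
  cl <- cluster_diversity(ids, hits, lens)
  expect_equal(cl$n_clusters, 2L)
  expect_equal(cl$membership[["a"]], cl$membership[["c"]])
  expect_false(cl$membership[["a"]] == cl$membership[["d"]])
  # no edges at all: every sequence its own cluster
  cl0 <- cluster_diversity(ids, hits[0, ], lens)
  expect_equal(cl0$n_clusters, 4L)
})

test_that("planted domain families cluster into exactly k groups", {
  set.seed(9)
  k <- 5
  ids <- paste0("s", 1:20)
  fam <- rep(1:k, each = 4)
  lens <- stats::setNames(rep(100, 20), ids)
  rowsl <- list()
  for (i in 1:19) for (j in (i + 1):20) {
    ident <- if (fam[i] == fam[j]) 85 else 30
    rowsl[[length(rowsl) + 1L]] <- hit_row(ids[i], ids[j], ident)
    rowsl[[length(rowsl) + 1L]] <- hit_row(ids[j], ids[i], ident)
  }
  cl <- cluster_diversity(ids, do.call(rbind, rowsl), lens,
                          min_identity = 60)
  expect_equal(cl$n_clusters, k)
})
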