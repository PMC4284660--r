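# The genome-evolution simulator: determinism, event accounting, the
# replay property, and distributional checks.

test_that("identical seeds give byte-identical bundles", {
  p <- sim_params(seed = 77, n_genes = 25, n_cne_planted = 8)
  a1 <- build_ancestor(p)
  a2 <- build_ancestor(p)
  expect_identical(emit_layout(a1)$seqs, emit_layout(a2)$seqs)
  expect_identical(a1$domains, a2$domains)
  l1 <- evolve_lineage(a1, lineage_params(), seed = 5, name = "x")
  l2 <- evolve_lineage(a2, lineage_params(), seed = 5, name = "x")
  expect_identical(emit_layout(l1$genome)$seqs,
                   emit_layout(l2$genome)$seqs)
})

test_that("zero genes gives a purely intergenic genome and zero rates
           give an identical descendant with an empty log", {
  a <- build_ancestor(sim_params(seed = 1, n_genes = 0,
                                 n_cne_planted = 0))
  lay <- emit_layout(a)
  expect_equal(nrow(lay$genes), 0L)
  expect_gt(sum(nchar(lay$seqs)), 0)
  b <- build_ancestor(sim_params(seed = 2, n_genes = 10,
                                 n_cne_planted = 3))
  l <- evolve_lineage(b, lineage_params(subst_rate = 0, n_inversions = 0,
                                        n_translocations = 0),
                      seed = 3, name = "same")
  expect_equal(length(l$log), 0L)
  expect_identical(emit_layout(l$genome)$seqs, emit_layout(b)$seqs)
})

test_that("event counts in the log equal the requested counts", {
  a <- build_ancestor(sim_params(seed = 4, n_genes = 30,
                                 n_cne_planted = 5))
  l <- evolve_lineage(a, lineage_params(subst_rate = 0,
                                        n_inversions = 7,
                                        n_translocations = 4,
                                        n_exon_shuffles = 3),
                      seed = 6, name = "ev")
  kinds <- vapply(l$log, function(e) e$kind, character(1))
  expect_equal(sum(kinds == "inversion"), 7L)
  expect_equal(sum(kinds == "translocation"), 4L)
  expect_equal(sum(kinds == "exon_shuffle"), 3L)
})

test_that("replaying the event log reproduces the descendant exactly", {
  px <- std_pair()
  rep_a <- replay_events(px$anc, px$la$log)
  expect_identical(emit_layout(rep_a)$seqs,
                   emit_layout(px$la$genome)$seqs)
  expect_identical(rep_a$domains, px$la$genome$domains)
  rep_b <- replay_events(px$anc, px$lb$log)
  expect_identical(emit_layout(rep_b)$seqs,
                   emit_layout(px$lb$genome)$seqs)
})

test_that("exon counts follow the truncated geometric distribution", {
  a <- build_ancestor(sim_params(seed = 10, n_genes = 100,
                                 exons_per_gene = 5,
                                 n_cne_planted = 0))
  n_ex <- sum(emit_layout(a)$genes$n_exons)
  # geometric with mean 5: per-gene variance (1-p)/p^2 = 20
  expect_lt(abs(n_ex - 500), 3 * sqrt(100 * 20))
})

test_that("requesting shuffles without multi-exon genes is an error", {
  a <- build_ancestor(sim_params(seed = 11, n_genes = 4,
                                 exons_per_gene = 1, max_exons = 1,
                                 n_cne_planted = 0))
  expect_error(evolve_lineage(a, lineage_params(n_exon_shuffles = 1),
                              seed = 1), "internal exons")
})

test_that("an infeasible genome length is an error", {
  expect_error(build_ancestor(sim_params(seed = 12, n_genes = 50,
                                         genome_length = 1000)),
               "infeasible")
})

test_that("observed substitution fraction matches the planted rate", {
  a <- build_ancestor(sim_params(seed = 13, n_genes = 0,
                                 n_cne_planted = 0,
                                 intergenic_len_meanlog = log(5000)))
  l <- evolve_lineage(a, lineage_params(subst_rate = 0.05,
                                        n_inversions = 0,
                                        n_translocations = 0),
                      seed = 14, name = "sub")
  s0 <- paste(emit_layout(a)$seqs, collapse = "")
  s1 <- paste(emit_layout(l$genome)$seqs, collapse = "")
  n <- nchar(s0)
  expect_gt(n, 10000)
  mism <- sum(strsplit(s0, "")[[1]] != strsplit(s1, "")[[1]])
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(mism / n - 0.05), 3 * se)
})

test_that("with full phase preference every shuffled exon is 1-1", {
  a <- build_ancestor(sim_params(seed = 15, n_genes = 60,
                                 n_cne_planted = 0))
  l <- evolve_lineage(a, lineage_params(subst_rate = 0,
                                        n_inversions = 0,
                                        n_translocations = 0,
                                        n_exon_shuffles = 15,
                                        phase11_preference = 1),
                      seed = 16, name = "b1")
  sh <- Filter(function(e) e$kind == "exon_shuffle", l$log)
  expect_equal(length(sh), 15L)
  expect_true(all(vapply(sh, function(e)
    e$phase5 == 1 && e$phase3 == 1, logical(1))))
})

test_that("whole-genome duplication doubles gene content with 1:2
           orthology", {
  a <- build_ancestor(sim_params(seed = 17, n_genes = 20,
                                 n_cne_planted = 4))
  l <- evolve_lineage(a, lineage_params(subst_rate = 0,
                                        n_inversions = 0,
                                        n_translocations = 0,
                                        wgd = TRUE),
                      seed = 18, name = "wgd")
  lay <- emit_layout(l$genome)
  expect_equal(nrow(lay$genes), 40L)
  roots <- sub("(_2)+$", "", lay$genes$gene_id)
  expect_true(all(table(roots) == 2L))
})

test_that("a zero-rate diploid has no variants and planted indel truth
           has the requested rows", {
  seqs <- c(c1 = paste(sample(c("A", "C", "G", "T"), 5000, TRUE),
                       collapse = ""))
  d0 <- make_diploid(seqs, diploid_params(snp_rate = 0,
                                          small_indel_rate = 0,
                                          seed = 1))
  expect_equal(nrow(d0$truth), 0L)
  expect_identical(d0$hap_a, d0$hap_b)
  set.seed(2)
  d1 <- make_diploid(seqs, diploid_params(snp_rate = 0,
                                          small_indel_rate = 0.01,
                                          seed = 3))
  expect_equal(nrow(d1$truth), sum(d1$truth$type == "small_indel"))
  expect_gt(nrow(d1$truth), 10L)
})

test_that("CNE decay events are logged and decayed elements drop out
           of the alignment", {
  a <- build_ancestor(sim_params(seed = 19, n_genes = 10,
                                 n_cne_planted = 20))
  la <- evolve_lineage(a, lineage_params(cne_decay = 0.5),
                       seed = 20, name = "dk")
  lb <- evolve_lineage(a, lineage_params(), seed = 21, name = "keep")
  decayed <- vapply(Filter(function(e) e$kind == "cne_decay", la$log),
                    function(e) e$cne_id, character(1))
  expect_gt(length(decayed), 2L)
  blocks <- derive_alignment(la$genome, lb$genome)
  lay <- emit_layout(la$genome)
  for (cid in decayed) {
    tr <- lay$cnes[lay$cnes$id == cid, ]
    ov <- any(blocks$blocks$ref_seq == tr$seq &
                blocks$blocks$ref_start < tr$end &
                blocks$blocks$ref_end > tr$start)
    expect_false(ov)
  }
})
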