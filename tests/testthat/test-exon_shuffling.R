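# Intron phases, phase spectra, shuffled-exon detection, subgenic DCJ.

three_exon_gene <- function(strand = "+") {
  # CDS exon lengths 100, 200, 150 -> boundary phases 1 then 0
  starts <- c(0, 200, 500)
  lens <- c(100, 200, 150)
  if (strand == "-") {
    # mirror the structure so translation order is reversed
    starts <- c(0, 200, 600)
    lens <- rev(lens)
  }
  genome_annotation(
    c(chr1 = 2000),
    list(gene_model("g1", "chr1", strand,
                    cbind(starts, starts + lens))))
}

test_that("boundary phases are cumulative CDS length mod 3", {
  ph <- annotate_phases(three_exon_gene("+"))
  expect_equal(ph$phase3, c(1, 0, NA))
  expect_equal(ph$phase5, c(NA, 1, 0))
  expect_equal(ph$is_internal, c(FALSE, TRUE, FALSE))
})

test_that("minus-strand genes give the mirrored phases", {
  ph <- annotate_phases(three_exon_gene("-"))
  expect_equal(ph$phase5, c(NA, 1, 0))
  expect_equal(ph$phase3, c(1, 0, NA))
  expect_equal(ph$cds_len, c(100, 200, 150))
})

test_that("single-exon genes have no internal exons and incomplete
           frames are excluded with a warning", {
  ann <- genome_annotation(
    c(chr1 = 1000),
    list(gene_model("g1", "chr1", "+", cbind(0, 99)),
         gene_model("g2", "chr1", "+", cbind(200, 303),
                    complete = FALSE)))
  expect_warning(ph <- annotate_phases(ann), NA)
  expect_false(any(ph$is_internal))
  expect_false("g2" %in% ph$gene_id)   # 103 bp is out of frame
})

test_that("phase annotation reproduces simulator ground truth exactly", {
  px <- std_pair()
  lay <- emit_layout(px$anc)
  ph <- annotate_phases(lay$annotation)
  for (cn in names(px$anc$chroms)) for (f in px$anc$chroms[[cn]]) {
    if (f$kind != "gene") next
    lens <- nchar(f$gene$exons)
    got <- ph[ph$gene_id == f$gene$gene_id, ]
    expect_equal(got$cds_len, lens)
    expect_equal(got$phase3[-length(lens)],
                 (cumsum(lens) %% 3)[-length(lens)])
  }
})

test_that("phase spectrum proportions sum to one and respect filters", {
  px <- std_pair()
  ph <- annotate_phases(emit_layout(px$anc)$annotation)
  sp <- phase_spectrum(ph, min_len_bp = 100)
  expect_equal(sum(sp$proportions), 1, tolerance = 1e-9)
  sp0 <- phase_spectrum(ph, min_len_bp = 0)
  expect_gte(sp0$n, sp$n)
  expect_error(phase_spectrum(ph[0, ]), "no internal exons")
})

test_that("uniform random phases fill the nine classes evenly", {
  set.seed(11)
  n <- 9000
  ph <- data.frame(exon_id = as.character(1:n), gene_id = "g",
                   exon_index = 2L, cds_len = 150,
                   phase5 = sample(0:2, n, TRUE),
                   phase3 = sample(0:2, n, TRUE), is_internal = TRUE)
  sp <- phase_spectrum(ph)
  se <- sqrt((1 / 9) * (8 / 9) / n)
  expect_true(all(abs(sp$proportions - 1 / 9) < 3 * se + 1e-9))
})

test_that("planted shuffles are detected with no false positives", {
  anc <- build_ancestor(sim_params(seed = 5, n_genes = 60,
                                   n_cne_planted = 10))
  la <- evolve_lineage(anc, lineage_params(n_exon_shuffles = 20,
                                           n_inversions = 0,
                                           n_translocations = 0,
                                           subst_rate = 0.05,
                                           cds_subst_factor = 1),
                       seed = 51, name = "A")
  lb <- evolve_lineage(anc, lineage_params(n_inversions = 0,
                                           n_translocations = 0,
                                           subst_rate = 0.05,
                                           cds_subst_factor = 1),
                       seed = 52, name = "B")
  hits <- derive_protein_hits(la$genome, lb$genome)
  om <- rbh_orthologs(hits$hits_ab, hits$hits_ba, hits$gene_of,
                      hits$protein_lengths)
  eh <- derive_exon_hits(la$genome, lb$genome)
  sh <- detect_shuffled_exons(eh$hits_ab, eh$hits_ba, om,
                              eh$exon_gene_a, eh$exon_gene_b,
                              exon_lengths = eh$exon_lengths)
  planted <- vapply(Filter(function(e) e$kind == "exon_shuffle", la$log),
                    function(e) e$exon_id, character(1))
  expect_gte(sum(sh$exon_id %in% planted), 18)
  expect_lte(sum(!sh$exon_id %in% planted), 2)

  # with no shuffles at all there are no false positives
  lc <- evolve_lineage(anc, lineage_params(n_inversions = 3,
                                           n_translocations = 1,
                                           subst_rate = 0.05,
                                           cds_subst_factor = 1),
                       seed = 53, name = "C")
  hits2 <- derive_protein_hits(lc$genome, lb$genome)
  om2 <- rbh_orthologs(hits2$hits_ab, hits2$hits_ba, hits2$gene_of,
                       hits2$protein_lengths)
  eh2 <- derive_exon_hits(lc$genome, lb$genome)
  sh2 <- detect_shuffled_exons(eh2$hits_ab, eh2$hits_ba, om2,
                               eh2$exon_gene_a, eh2$exon_gene_b,
                               exon_lengths = eh2$exon_lengths)
  expect_equal(nrow(sh2), 0L)
})

test_that("chainnet mode reports at most as many calls as rbh mode", {
  anc <- build_ancestor(sim_params(seed = 6, n_genes = 50,
                                   n_cne_planted = 10))
  la <- evolve_lineage(anc, lineage_params(n_exon_shuffles = 10,
                                           n_inversions = 0,
                                           n_translocations = 0,
                                           subst_rate = 0.05,
                                           cds_subst_factor = 1),
                       seed = 61, name = "A")
  lb <- evolve_lineage(anc, lineage_params(n_inversions = 0,
                                           n_translocations = 0,
                                           subst_rate = 0.05,
                                           cds_subst_factor = 1),
                       seed = 62, name = "B")
  hits <- derive_protein_hits(la$genome, lb$genome)
  om <- rbh_orthologs(hits$hits_ab, hits$hits_ba, hits$gene_of,
                      hits$protein_lengths)
  eh <- derive_exon_hits(la$genome, lb$genome)
  sh_rbh <- detect_shuffled_exons(eh$hits_ab, eh$hits_ba, om,
                                  eh$exon_gene_a, eh$exon_gene_b,
                                  exon_lengths = eh$exon_lengths)
  lay_a <- emit_layout(la$genome); lay_b <- emit_layout(lb$genome)
  blocks <- derive_alignment(la$genome, lb$genome)
  spans_b <- data.frame(gene_id = lay_b$genes$gene_id,
                        seq = lay_b$genes$seq,
                        start = lay_b$genes$start, end = lay_b$genes$end)
  coords_a <- data.frame(exon_id = lay_a$exons$exon_id,
                         seq = lay_a$exons$seq,
                         start = lay_a$exons$start,
                         end = lay_a$exons$end)
  sh_cn <- detect_shuffled_exons(orthology = om,
                                 exon_gene_a = eh$exon_gene_a,
                                 exon_gene_b = eh$exon_gene_b,
                                 method = "chainnet", blocks = blocks,
                                 exon_coords_a = coords_a,
                                 gene_spans_b = spans_b)
  expect_lte(nrow(sh_cn), nrow(sh_rbh))
  expect_gte(nrow(sh_cn), 1L)
})

test_that("subgenic DCJ contribution is zero for gene-level-only
           rearrangement and bounded for pure shuffles", {
  # pure gene-level inversion: exon order tracks gene order
  gA <- gene_order(list(c(1, 2, 3, 4)))
  gB <- gene_order(list(c(1, -3, -2, 4)))
  # exons: two per gene, markers 11,12 for gene1 etc.
  exon_of <- function(go) gene_order(lapply(go$chromosomes, function(ch)
    as.integer(unlist(lapply(ch, function(m)
      sign(m) * (10 * abs(m) + if (m > 0) c(1, 2) else c(2, 1)))))))
  r <- subgenic_dcj(exon_of(gA), exon_of(gB), gA, gB)
  expect_equal(r$contribution, 0L)
  # k pure exon shuffles cost between k and 2k exon-level operations
  set.seed(13)
  k <- 4
  exA <- gene_order(list(1:20))
  ord <- 1:20
  for (i in seq_len(k)) {
    from <- sample(2:19, 1)
    rest <- ord[-from]
    at <- sample(seq_along(rest), 1)
    ord <- append(rest, ord[from], after = at)
  }
  exB <- gene_order(list(ord))
  geneA <- gene_order(list(1:2))
  r2 <- subgenic_dcj(exA, exB, geneA, geneA)
  expect_gte(r2$contribution, 1L)
  expect_lte(r2$contribution, 2L * k)
  # invariance under marker relabeling
  relabel <- sample(100:200, 20)
  exA2 <- gene_order(list(relabel[abs(exA$chromosomes[[1]])]))
  exB2 <- gene_order(list(sign(exB$chromosomes[[1]]) *
                            relabel[abs(exB$chromosomes[[1]])]))
  r3 <- subgenic_dcj(exA2, exB2, geneA, geneA)
  expect_equal(r3$contribution, r2$contribution)
})

test_that("shuffled phase bias matches a hand-computed chi-square", {
  ph <- data.frame(
    exon_id = as.character(1:200), gene_id = "g", exon_index = 2L,
    cds_len = 150,
    phase5 = c(rep(1, 40), rep(0, 60), rep(1, 28), rep(0, 72)),
    phase3 = c(rep(1, 40), rep(0, 60), rep(1, 28), rep(0, 72)),
    is_internal = TRUE)
  shuffled <- as.character(1:100)
  r <- shuffled_phase_bias(ph, shuffled)
  # 2x2 continuity-corrected chi-square, computed from first principles
  O <- matrix(c(40, 60, 28, 72), 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  stat <- sum((abs(O - E) - 0.5)^2 / E)
  expect_equal(r$statistic, stat, tolerance = 1e-9)
  expect_equal(r$prop_shuffled, 0.40)
  expect_equal(r$prop_background, 0.28)
  expect_equal(r$test, "chi-square")
})

test_that("equal proportions give a near-zero statistic and sparse
           tables fall back to Fisher", {
  ph <- data.frame(
    exon_id = as.character(1:80), gene_id = "g", exon_index = 2L,
    cds_len = 150,
    phase5 = rep(c(1, 0), 40), phase3 = rep(c(1, 0), 40),
    is_internal = TRUE)
  r <- shuffled_phase_bias(ph, as.character(1:40))
  expect_lt(r$statistic, 0.2)
  ph2 <- ph[1:12, ]
  r2 <- shuffled_phase_bias(ph2, as.character(1:6))
  expect_equal(r2$test, "fisher")
})
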