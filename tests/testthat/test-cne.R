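# CNE calling, the refinement filter chain, summaries, windows,
# intersections.

no_gene_ann <- function(len = 10000, name = "r1")
  genome_annotation(stats::setNames(len, name), list())

test_that("a clean intergenic block yields one candidate with gap
           columns counted as mismatches", {
  ref <- paste(rep("A", 200), collapse = "")
  qry <- paste(c(rep("A", 95), rep("C", 10), rep("A", 95)), collapse = "")
  bs <- alignment_block_set(simple_block(ref, qry))
  cand <- coarse_cnes(bs, no_gene_ann())
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$identity, 95)
  expect_equal(cand$length, 200)
})

test_that("blocks fully inside coding sequence yield no candidates", {
  ann <- genome_annotation(
    c(r1 = 10000),
    list(gene_model("g1", "r1", "+", cbind(0, 300))))
  ref <- paste(rep("A", 200), collapse = "")
  bs <- alignment_block_set(simple_block(ref, ref, ref_start = 50,
                                         query_start = 50))
  expect_equal(nrow(coarse_cnes(bs, ann)), 0L)
})

test_that("long gap runs split candidates; overlapping ref blocks are
           rejected", {
  ref <- paste(c(rep("A", 100), rep("-", 12), rep("G", 100)),
               collapse = "")
  qry <- paste(rep("A", 212), collapse = "")
  qry <- paste(c(rep("A", 100), rep("T", 12), rep("G", 100)), collapse = "")
  bs <- alignment_block_set(simple_block(ref, qry))
  cand <- coarse_cnes(bs, no_gene_ann())
  expect_equal(nrow(cand), 2L)
  over <- rbind(simple_block(paste(rep("A", 50), collapse = "")
                             , paste(rep("A", 50), collapse = "")),
                simple_block(paste(rep("A", 50), collapse = ""),
                             paste(rep("A", 50), collapse = ""),
                             ref_start = 20, query_start = 100))
  expect_error(coarse_cnes(alignment_block_set(over), no_gene_ann()),
               "reciprocal-best")
})

test_that("planted CNEs are recovered with high sensitivity and
           precision", {
  px <- std_pair()
  blocks <- derive_alignment(px$la$genome, px$lb$genome)
  lay <- emit_layout(px$la$genome)
  cand <- coarse_cnes(blocks, lay$annotation)
  ref <- refine_cnes(cand, lay$annotation)
  tr <- lay$cnes
  hit <- vapply(seq_len(nrow(tr)), function(i)
    any(ref$refined$ref_seq == tr$seq[i] &
          ref$refined$ref_start < tr$end[i] &
          ref$refined$ref_end > tr$start[i]), logical(1))
  sens <- mean(hit)
  prec <- mean(vapply(seq_len(nrow(ref$refined)), function(i)
    any(tr$seq == ref$refined$ref_seq[i] &
          tr$start < ref$refined$ref_end[i] &
          tr$end > ref$refined$ref_start[i]), logical(1)))
  expect_gte(sens, 0.95)
  expect_gte(prec, 0.95)
})

test_that("the engineered 10-candidate fixture refines to exactly 4
           with exact per-filter removal lengths", {
  fx <- engineered_candidates()
  r <- refine_cnes(fx$cand, fx$ann, hits = fx$hits)
  expect_equal(r$summary$refined_count, 4L)
  rl <- r$summary$removed_lengths
  expect_equal(unname(rl[["short"]]), 50 + 74)
  expect_equal(unname(rl[["cds_adjacent"]]), 90 + 100 + 80)
  expect_equal(unname(rl[["homology"]]), 120)
  # accounting identity: coarse = refined + removals
  expect_equal(r$summary$coarse_length,
               r$summary$refined_length + sum(rl))
})

test_that("74 bp candidates are removed as short; e <= 1e-5 hits are
           removed as homology", {
  fx <- engineered_candidates()
  r <- refine_cnes(fx$cand, fx$ann, hits = fx$hits)
  expect_true("cand02" %in% r$removed$id[r$removed$filter_flag == "short"])
  expect_true("cand06" %in%
                r$removed$id[r$removed$filter_flag == "homology"])
  # a weaker hit does not trigger the homology filter
  weak <- hit_row("cand06", "known_protein", 80, evalue = 1e-3)
  r2 <- refine_cnes(fx$cand, fx$ann, hits = weak)
  expect_false("cand06" %in% r2$removed$id)
})

test_that("raising thresholds never increases the refined length", {
  fx <- engineered_candidates()
  base <- refine_cnes(fx$cand, fx$ann)$summary$refined_length
  longer <- refine_cnes(fx$cand, fx$ann,
                        min_len = 150)$summary$refined_length
  stricter <- refine_cnes(fx$cand, fx$ann,
                          min_identity = 95)$summary$refined_length
  expect_lte(longer, base)
  expect_lte(stricter, base)
})

test_that("summary statistics reproduce the arithmetic of a published
           five-species comparison", {
  refined <- data.frame(length = 30003722)
  s <- cne_stats(refined, genome_size = 426108443)
  expect_equal(round(s$refined_pct, 2), 7.04)
  s2 <- cne_stats(data.frame(length = rep(30003722 / 135046, 135046)),
                  genome_size = 426108443)
  expect_equal(round(s2$mean_length, 1), 222.2)
  s0 <- cne_stats(data.frame(length = numeric(0)), genome_size = 100)
  expect_equal(s0$refined_pct, 0)
  expect_true(is.na(s0$mean_length))
})

test_that("enrichment windows rank a planted dense cluster first", {
  ann <- no_gene_ann(2e6)
  set.seed(31)
  scatter <- data.frame(ref_seq = "r1",
                        ref_start = seq(0, 1.9e6, by = 40000))
  scatter$ref_end <- scatter$ref_start + 100
  dense <- data.frame(ref_seq = "r1",
                      ref_start = seq(1.2e6, 1.25e6, by = 1000))
  dense$ref_end <- dense$ref_start + 400
  refined <- rbind(scatter, dense)
  refined$length <- refined$ref_end - refined$ref_start
  top <- enrichment_windows(refined, ann, window = 1e5, step = 5e4,
                            top_k = 5)
  expect_true(top$start[1] <= 1.2e6 && top$end[1] >= 1.25e6)
  expect_error(enrichment_windows(refined, ann, window = 1e4,
                                  step = 5e4), "at least step")
})

test_that("CNE set intersection keeps overlaps at or above min_len", {
  s1 <- data.frame(ref_seq = "r1", ref_start = c(100, 1000),
                   ref_end = c(300, 1100))
  expect_equal(nrow(intersect_cne_sets(s1, s1, min_len = 30)), 2L)
  s2 <- data.frame(ref_seq = "r1", ref_start = 150, ref_end = 250)
  out <- intersect_cne_sets(s1, s2, min_len = 30)
  expect_equal(out$ref_start, 150)
  expect_equal(out$ref_end, 250)
  s3 <- data.frame(ref_seq = "r1", ref_start = 5000, ref_end = 5100)
  expect_equal(nrow(intersect_cne_sets(s1, s3)), 0L)
  attr(s1, "reference") <- "human"
  attr(s3, "reference") <- "mouse"
  expect_error(intersect_cne_sets(s1, s3), "different references")
})
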