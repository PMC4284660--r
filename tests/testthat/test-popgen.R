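# Variant calling, polymorphism summaries, spacing fits, dN/dS, Ne.

test_that("single mismatches and gap runs are called as SNPs and
           indels", {
  bs <- alignment_block_set(simple_block("ACGT", "ACCT"))
  v <- call_variants(bs)
  expect_equal(sum(v$type == "snp"), 1L)
  expect_equal(v$ref_start[v$type == "snp"], 2)
  ref <- paste(c(rep("A", 20), rep("C", 10), rep("A", 20)), collapse = "")
  qry <- paste(c(rep("A", 20), rep("-", 10), rep("A", 20)), collapse = "")
  v2 <- call_variants(alignment_block_set(simple_block(ref, qry)))
  ind <- v2[v2$type == "small_indel", ]
  expect_equal(nrow(ind), 1L)
  expect_equal(ind$length, 10)
  expect_equal(ind$ref_start, 20)
})

test_that("adjacent SNPs stay separate calls and indels class by
           length", {
  bs <- alignment_block_set(simple_block("AAAA", "CCAA"))
  v <- call_variants(bs)
  expect_equal(sum(v$type == "snp"), 2L)
  ref <- paste(c(rep("A", 10), rep("G", 301), rep("A", 10)), collapse = "")
  qry <- paste(c(rep("A", 10), rep("-", 301), rep("A", 10)), collapse = "")
  v2 <- call_variants(alignment_block_set(simple_block(ref, qry)))
  expect_equal(sum(v2$type == "large_indel"), 1L)
})

test_that("minus-strand and off-chain blocks become inversion and
           translocation records", {
  b <- rbind(simple_block(strrep("A", 100), strrep("A", 100)),
             simple_block(strrep("C", 40), strrep("C", 40),
                          ref_start = 200, query_start = 200,
                          strand = "-"),
             simple_block(strrep("G", 30), strrep("G", 30),
                          ref_start = 300, query_seq = "q2",
                          query_start = 0))
  v <- call_variants(alignment_block_set(b))
  expect_equal(sum(v$type == "inversion"), 1L)
  expect_equal(sum(v$type == "translocation"), 1L)
})

test_that("planted diploid variants are recovered essentially
           perfectly", {
  anc <- build_ancestor(sim_params(seed = 8, n_genes = 30,
                                   n_cne_planted = 5))
  seqs <- emit_layout(anc)$seqs
  dip <- make_diploid(seqs, diploid_params(seed = 9))
  v <- call_variants(dip$blocks)
  key <- function(d) paste(d$type, d$ref_seq, d$ref_start, d$length)
  called <- key(v[v$type %in% c("snp", "small_indel", "large_indel"), ])
  truth <- key(dip$truth)
  expect_gte(mean(truth %in% called), 0.99)
  expect_gte(mean(called %in% truth), 0.99)
  expect_gte(nrow(dip$truth), 1000L)
})

test_that("polymorphism rates follow their definitions", {
  v <- data.frame(type = c(rep("snp", 439), "small_indel"),
                  ref_seq = "r1", ref_start = seq_len(440),
                  ref_end = seq_len(440) + 1, length = 1,
                  ref_allele = "A", alt_allele = "C")
  s <- summarize_polymorphism(v, aligned_length = 10000,
                              genome_length = 10000)
  expect_equal(s$snp_rate_pct, 4.39)
  v0 <- v[0, ]
  s0 <- summarize_polymorphism(v0, aligned_length = 100,
                               genome_length = 100)
  expect_equal(s0$snp_rate_pct, 0)
  expect_equal(s0$large_indel_count, 0L)
})

test_that("geometric spacing MLE recovers a planted rate and the GOF
           accepts", {
  set.seed(41)
  p <- 0.05
  n <- 10000
  gaps <- stats::rgeom(n, p)
  pos <- cumsum(gaps + 1L)
  sf <- spacing_fit(data.frame(ref_seq = "r1", ref_start = pos))
  se <- sqrt(p^2 * (1 - p) / n)
  expect_lt(abs(sf$p_hat - p), 3 * se)
  expect_gt(sf$p_value, 0.01)
  # every site variant: p_hat = 1
  sf1 <- spacing_fit(data.frame(ref_seq = "r1", ref_start = 1:200))
  expect_equal(sf1$p_hat, 1)
})

test_that("clustered variants are rejected by the goodness-of-fit
           test", {
  set.seed(42)
  rejections <- 0L
  for (rep in 1:20) {
    # clusters of nearby variants separated by long empty stretches
    centers <- cumsum(stats::rgeom(500, 0.002) + 200L)
    pos <- sort(unique(unlist(lapply(centers, function(cc)
      cc + sample(0:30, 8, replace = TRUE)))))
    sf <- spacing_fit(data.frame(ref_seq = "r1", ref_start = pos))
    if (sf$p_value < 0.01) rejections <- rejections + 1L
  }
  expect_gte(rejections / 20, 0.9)
})

test_that("spacing fit demands enough observations and bins", {
  expect_error(spacing_fit(data.frame(ref_seq = "r1", ref_start = 1:50)),
               "at least 100")
})

test_that("NG86 counts the worked synonymous-only example as dN = 0", {
  r <- dnds_ng86("ATGAAAGCTTTTGGG", "ATGAAGGCTTTCGGG")
  expect_equal(r$per_pair$Nd, 0)
  expect_equal(r$per_pair$Sd, 2)
  expect_equal(r$per_pair$dN, 0)
  ident <- dnds_ng86("ATGGCTAAA", "ATGGCTAAA")
  expect_equal(ident$per_pair$dN, 0)
  expect_equal(ident$per_pair$dS, 0)
})

test_that("internal stop codons skip the pair with a warning", {
  expect_warning(r <- dnds_ng86(c("ATGTAAAAAGCT", "ATGAAAGCTTTT"),
                                c("ATGTAAAAAGCT", "ATGAAAGCTTTC")),
                 "stop codon")
  expect_equal(nrow(r$per_pair), 1L)
})

test_that("synonymous-only simulation gives dN/dS near zero and
           neutral simulation near one", {
  set.seed(43)
  code <- chordevo:::.codon_table()
  codons <- names(code)[code != "*"]
  n <- 3000
  a <- sample(codons, n, replace = TRUE)
  # synonymous-only: swap codons within amino-acid classes
  syn_of <- split(codons, code[codons])
  b_syn <- vapply(a, function(cd) {
    if (stats::runif(1) > 0.15) return(cd)
    alts <- syn_of[[code[[cd]]]]
    sample(rep(alts, 2), 1)
  }, character(1))
  r_syn <- dnds_ng86(paste(a, collapse = ""), paste(b_syn, collapse = ""))
  expect_lt(r_syn$pooled$dN / max(r_syn$pooled$dS, 1e-9), 0.05)
  # neutral: random single-base changes accepted regardless of effect
  b_neu <- vapply(a, function(cd) {
    if (stats::runif(1) > 0.15) return(cd)
    for (tries in 1:10) {
      p <- sample(3, 1)
      alt <- cd
      substr(alt, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(cd, p, p)), 1)
      if (code[[alt]] != "*") return(alt)
    }
    cd
  }, character(1))
  r_neu <- dnds_ng86(paste(a, collapse = ""), paste(b_neu, collapse = ""))
  # at 3000 codons the sampling SE of the ratio is about 0.1
  expect_lt(abs(r_neu$pooled$dn_ds - 1), 0.3)
})

test_that("Ne is linear in heterozygosity and inverse in mutation
           rate", {
  expect_equal(effective_population_size(0.04, 1e-8), 1e6)
  expect_equal(effective_population_size(0.08, 1e-8),
               2 * effective_population_size(0.04, 1e-8))
  expect_equal(effective_population_size(0.04, 1e-9),
               10 * effective_population_size(0.04, 1e-8))
  expect_equal(effective_population_size(0.04, 1e-8, generation_years = 2),
               5e5)
  expect_error(effective_population_size(0, 1e-8), "positive")
})

test_that("TE attribution counts majority-overlap events", {
  v <- data.frame(type = "large_indel", ref_seq = "r1",
                  ref_start = c(100, 5000), ref_end = c(600, 5500),
                  length = 500, ref_allele = "x", alt_allele = "-")
  te <- data.frame(chrom = "r1", start = 50, end = 700)
  r <- te_attribution(v, te)
  expect_equal(r$n_te, 1L)
  expect_equal(r$fraction_events, 0.5)
  expect_equal(te_attribution(v, te[0, ])$fraction_events, 0)
})

test_that("planted TE-derived large indels are attributed at the
           planted fraction", {
  set.seed(44)
  n <- 300
  inside <- stats::runif(n) < 0.7
  starts <- seq(1000, by = 5000, length.out = n)
  te <- data.frame(chrom = "r1", start = starts[inside] - 50,
                   end = starts[inside] + 600)
  v <- data.frame(type = "large_indel", ref_seq = "r1",
                  ref_start = starts, ref_end = starts + 500,
                  length = 500, ref_allele = "x", alt_allele = "-")
  r <- te_attribution(v, te)
  se <- sqrt(0.7 * 0.3 / n)
  expect_lt(abs(r$fraction_events - 0.7), 3 * se)
})
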