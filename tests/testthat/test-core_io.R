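# Readers, writers and the shared coordinate conventions.

test_that("GFF3 coordinates convert to 0-based half-open", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr1 1 1000",
    "chr1\tsrc\tgene\t101\t400\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tID=gA.e1;Parent=gA.t1",
    "chr1\tsrc\texon\t301\t400\t.\t+\t.\tID=gA.e2;Parent=gA.t1",
    "chr1\tsrc\tCDS\t101\t200\t.\t+\t0\tID=gA.c1;Parent=gA.t1",
    "chr1\tsrc\tCDS\t301\t400\t.\t+\t2\tID=gA.c2;Parent=gA.t1"),
    path)
  ann <- read_gff3(path)
  expect_equal(length(ann$genes), 1L)
  expect_equal(unname(ann$genes$gA$exons),
               unname(cbind(c(100, 300), c(200, 400))))
  expect_equal(ann$sequences[["chr1"]], 1000)
})

test_that("empty GFF3 yields an annotation with zero genes", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "##sequence-region chr1 1 500"), path)
  ann <- read_gff3(path)
  expect_equal(length(ann$genes), 0L)
  expect_equal(ann$sequences[["chr1"]], 500)
})

test_that("GFF3 features outside the declared sequence are an error", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr1 1 300",
    "chr1\tsrc\tgene\t101\t400\t.\t+\t.\tID=gA",
    "chr1\tsrc\tCDS\t101\t400\t.\t+\t0\tID=gA.c1;Parent=gA"),
    path)
  expect_error(read_gff3(path), "outside sequence")
})

test_that("malformed parent links and unknown strands are errors", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t90\t.\t+\t.\tID=gA",
    "chr1\tsrc\texon\t1\t90\t.\t+\t.\tID=e1;Parent=nosuch"),
    path)
  expect_error(read_gff3(path), "nosuch")
  path2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t90\t.\t?\t.\tID=gA"), path2)
  expect_error(read_gff3(path2), "strand")
})

test_that("GFF3 round-trips through write_gff3", {
  ann <- genome_annotation(
    c(chr1 = 2000),
    list(gene_model("g1", "chr1", "+", cbind(c(100, 400), c(250, 550)))),
    assembly_name = "t")
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, path)
  back <- read_gff3(path)
  expect_equal(unname(back$genes$g1$exons), unname(ann$genes$g1$exons))
  expect_equal(back$genes$g1$strand, "+")
})

test_that("pairwise MAF parses and minus-strand axt converts to forward", {
  maf <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("##maf version=1", "a score=0",
               "s ref.chr1 10 5 + 100 ACGTA",
               "s qry.chr2 20 5 + 100 ACCTA", ""), maf)
  bs <- read_pairwise_alignment(maf, "maf")
  expect_equal(nrow(bs$blocks), 1L)
  expect_equal(bs$blocks$ref_start, 10)
  expect_equal(block_identity(bs), 80)

  axt <- withr::local_tempfile(fileext = ".axt")
  writeLines(c("#qlen chr2 100",
               "0 chr1 11 15 chr2 21 25 - 100",
               "ACGTA", "ACGTA"), axt)
  ba <- read_pairwise_alignment(axt, "axt")
  expect_equal(ba$blocks$query_strand, "-")
  # forward-strand query interval: reverse coords 21..25 on a 100 bp
  # sequence map to forward [75, 80)
  expect_equal(ba$blocks$query_start, 75)
  expect_equal(ba$blocks$query_end, 80)
})

test_that("MAF blocks with more than two rows or ragged texts error", {
  maf <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("a score=0",
               "s a.c 0 3 + 10 ACG",
               "s b.c 0 3 + 10 ACG",
               "s c.c 0 3 + 10 ACG", ""), maf)
  expect_error(read_pairwise_alignment(maf, "maf"), "exactly 2")
  expect_error(alignment_block_set(simple_block("ACGT", "ACG")),
               "unequal length|does not match")
})

test_that("MAF round-trips through write_maf", {
  blocks <- rbind(simple_block("ACGTACGT", "ACCTACGT"),
                  simple_block("GGGG", "GGCG", ref_start = 50,
                               query_start = 70))
  bs <- alignment_block_set(blocks, c("A", "B"))
  path <- withr::local_tempfile(fileext = ".maf")
  write_maf(bs, path)
  back <- read_pairwise_alignment(path, "maf")
  expect_equal(back$blocks$ref_text, bs$blocks$ref_text)
  expect_equal(back$blocks$ref_start, bs$blocks$ref_start)
  expect_equal(back$blocks$query_start, bs$blocks$query_start)
})

test_that("BED round-trips and rejects end < start", {
  iv <- data.frame(chrom = c("c1", "c1", "c2"),
                   start = c(0, 100, 5), end = c(50, 200, 9),
                   name = c("a", "b", "c"))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(iv, path)
  back <- read_bed(path)
  expect_equal(back$start, iv$start)
  expect_equal(back$end, iv$end)
  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines("c1\t100\t50", bad)
  expect_error(read_bed(bad), "end < start")
})

test_that("newick trees read rooted with unique leaves", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A,B),(C,D));", path)
  tr <- read_newick(path)
  expect_equal(sort(tr$tip.label), c("A", "B", "C", "D"))
  expect_true(ape::is.rooted(tr))
  dup <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A,A),B);", dup)
  expect_error(read_newick(dup), "duplicated")
})

test_that("schema'd tables validate columns and ranges", {
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(hit_row("p1", "p2", 90), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  hits <- read_table(path, "hits")
  expect_equal(hits$percent_identity, 90)
  short <- withr::local_tempfile(fileext = ".tsv")
  writeLines("p1\tp2\t90", short)
  expect_error(read_table(short, "hits"), "missing")
  dom <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tdomain_type", "p1\tPF1"), dom)
  expect_error(read_table(dom, "domains"), "missing columns")
})
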