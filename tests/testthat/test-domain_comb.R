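# Domain-pair extraction, Dollo gains, promiscuity, presence-absence
# trees.

test_that("pair extraction follows the adjacent/cooccur definitions", {
  arch <- list(p1 = c("Ig", "Ig", "TIR"))
  expect_equal(extract_pairs(arch, "adjacent"), "Ig|TIR")
  arch2 <- list(p1 = c("A", "B", "C"))
  expect_equal(extract_pairs(arch2, "adjacent"),
               sort(c("A|B", "B|C")))
  expect_equal(extract_pairs(arch2, "cooccur"),
               sort(c("A|B", "A|C", "B|C")))
})

test_that("adjacent pairs are always a subset of co-occurring pairs", {
  set.seed(21)
  for (rep in 1:10) {
    arch <- lapply(1:6, function(i)
      sample(LETTERS[1:8], sample(1:5, 1), replace = TRUE))
    expect_true(all(extract_pairs(arch, "adjacent") %in%
                      extract_pairs(arch, "cooccur")))
  }
})

test_that("overlapping domain hits resolve best e-value first", {
  dom <- data.frame(protein_id = "p1",
                    domain_type = c("A", "B", "C"),
                    env_start = c(0, 10, 50), env_end = c(30, 40, 80),
                    e_value = c(1e-20, 1e-5, 1e-10))
  arch <- resolve_architectures(dom)
  expect_equal(arch$p1, c("A", "C"))   # B overlaps the better-scoring A
})

test_that("Dollo places gains at the MRCA and forced losses below", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  m <- pair_matrix(list(A = "X|Y", B = "X|Y", C = character(0),
                        D = character(0)))
  bg <- dollo_gains(m, tree)
  expect_equal(bg$total_gains, 1L)
  expect_equal(sum(bg$per_branch$losses), 0L)
  # presence in A and C forces a root gain with two losses
  m2 <- pair_matrix(list(A = "X|Y", B = character(0), C = "X|Y",
                         D = character(0)))
  bg2 <- dollo_gains(m2, tree)
  root <- length(tree$tip.label) + 1L
  expect_equal(bg2$per_branch$gains[bg2$per_branch$node == root], 1L)
  expect_equal(sum(bg2$per_branch$losses), 2L)
})

test_that("Dollo reconstructions are minimal among single-gain
           scenarios on random matrices", {
  set.seed(23)
  tree <- ape::read.tree(text = "((A,B),((C,D),E));")
  for (rep in 1:25) {
    present <- sample(tree$tip.label, sample(1:5, 1))
    m <- pair_matrix(stats::setNames(
      lapply(tree$tip.label, function(s)
        if (s %in% present) "P|Q" else character(0)), tree$tip.label))
    bg <- dollo_gains(m, tree)
    total <- bg$total_gains + sum(bg$per_branch$losses)
    expect_equal(total, dollo_brute_min(present, tree))
  }
})

test_that("total Dollo gains equal the number of observed pairs", {
  set.seed(24)
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  sets <- stats::setNames(lapply(1:4, function(i)
    paste0("T", sample(1:6, sample(0:4, 1)), "|U")), tree$tip.label)
  m <- pair_matrix(sets)
  if (ncol(m)) {
    bg <- dollo_gains(m, tree)
    expect_equal(bg$total_gains, ncol(m))
  }
  expect_error(dollo_gains(pair_matrix(list(A = "X|Y", E = "X|Y")),
                           tree), "missing from tree")
})

test_that("gain rates scale inversely with branch duration", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  m <- pair_matrix(list(A = paste0("p", 1:10, "|q"), B = character(0),
                        C = character(0), D = character(0)))
  bg <- dollo_gains(m, tree)
  r1 <- gain_rate(bg, c(A = 10))
  expect_equal(r1$rate_per_myr[r1$label == "A"], 1)
  r2 <- gain_rate(bg, c(A = 20))
  expect_equal(r2$rate_per_myr[r2$label == "A"], 0.5)
})

test_that("promiscuity ranking finds hub domains", {
  pairs <- paste0("HUB|", paste0("p", 1:9))
  pr <- promiscuity_rank(list(sp = pairs))
  expect_equal(pr$domain[1], "HUB")
  expect_equal(pr$n_partners[1], 9L)
  # all-singleton pairs: uniform partner counts
  pr2 <- promiscuity_rank(list(sp = c("A|B", "C|D", "E|F")))
  expect_true(all(pr2$n_partners == 1L))
})

test_that("presence-absence NJ trees use Jaccard distances and recover
           a planted topology", {
  m <- rbind(s1 = c(1, 1, 0, 0), s2 = c(1, 1, 0, 0),
             s3 = c(0, 0, 1, 1), s4 = c(1, 0, 1, 0))
  colnames(m) <- paste0("p", 1:4)
  tr <- presence_absence_tree(m)
  expect_s3_class(tr, "phylo")
  expect_error(presence_absence_tree(m[1:3, ]), "at least 4")
  # planted gains/losses on a known 6-leaf tree
  set.seed(25)
  ref <- ape::read.tree(text = "(((A,B),(C,D)),(E,F));")
  wins <- 0L
  for (rep in 1:10) {
    # simulate pair content down the tree: shared core + clade-specific
    n_core <- 40
    clades <- list(c("A", "B"), c("C", "D"), c("E", "F"),
                   c("A", "B", "C", "D"))
    sets <- stats::setNames(vector("list", 6), ref$tip.label)
    for (s in ref$tip.label)
      sets[[s]] <- paste0("core", sample(n_core, 30), "|x")
    for (ci in seq_along(clades))
      for (s in clades[[ci]])
        sets[[s]] <- c(sets[[s]], paste0("clade", ci, "_", 1:15, "|y"))
    tr2 <- presence_absence_tree(pair_matrix(sets))
    rf <- ape::dist.topo(ape::unroot(ref), ape::unroot(tr2))
    if (rf == 0) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("pair vocabulary split is exhaustive", {
  pairs <- c("A|B", "B|V1", "V1|V2", "C|D")
  special <- pair_contains_type(pairs, c("V1", "V2"))
  expect_equal(sum(special) + sum(!special), length(pairs))
  expect_equal(sum(special), 2L)
})

test_that("planted novel pairs on one lineage are recovered by set
           difference", {
  px <- std_pair()
  pairs_anc <- extract_pairs(px$anc$domains)
  pairs_a <- extract_pairs(px$la$genome$domains)
  gained <- vapply(Filter(function(e) e$kind == "domain_gain", px$la$log),
                   function(e) e$pair, character(1))
  expect_setequal(setdiff(pairs_a, pairs_anc), gained)
})
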