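# Independent oracles and shared fixtures for the test suite.

# ---- enumeration of signed gene orders ------------------------------------

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L))
    for (i in 0:(n - 1L))
      out[[length(out) + 1L]] <- append(p, n, after = i)
  out
}

# every one-chromosome linear signed genome over markers 1..n
all_signed_orders <- function(n) {
  out <- list()
  for (p in all_permutations(n)) for (mask in 0:(2^n - 1L)) {
    signs <- ifelse(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0, -1L, 1L)
    out[[length(out) + 1L]] <- unlist(p) * signs
  }
  out
}

# ---- single-source BFS over the DCJ move space ----------------------------
# Distances from the identity genome to every reachable genome state
# (including circular intermediates), via the package's internal
# adjacency-set move generator.  Used to check dcj_distance exhaustively.

bfs_distance_map <- function(n) {
  identity_go <- gene_order(list(seq_len(n)))
  start <- chordevo:::.to_adjset(identity_go)
  dist <- new.env(hash = TRUE)
  assign(chordevo:::.adjset_key(start), 0L, envir = dist)
  frontier <- list(start)
  depth <- 0L
  while (length(frontier)) {
    depth <- depth + 1L
    nxt <- list()
    for (st in frontier) for (nb in chordevo:::.dcj_neighbours(st)) {
      k <- chordevo:::.adjset_key(nb)
      if (!exists(k, envir = dist, inherits = FALSE)) {
        assign(k, depth, envir = dist)
        nxt[[length(nxt) + 1L]] <- nb
      }
    }
    frontier <- nxt
  }
  dist
}

# ---- Dollo brute force ----------------------------------------------------
# Minimum (gains + losses) over all single-gain scenarios: the gain is
# placed on any node whose subtree covers the present species; losses
# are the maximal empty subtrees below it.

dollo_brute_min <- function(present, tree) {
  idx <- chordevo:::.tree_index(tree)
  nn <- idx$n_tips + tree$Nnode
  best <- Inf
  for (v in seq_len(nn)) {
    if (!all(present %in% idx$leaves[[v]])) next
    losses <- 0L
    count <- function(u) {
      if (!any(idx$leaves[[u]] %in% present)) {
        losses <<- losses + 1L
        return(invisible(NULL))
      }
      for (ch in idx$children[[u]]) count(ch)
    }
    for (ch in idx$children[[v]]) count(ch)
    best <- min(best, 1L + losses)
  }
  best
}

# ---- exact two-sided Fisher P by hypergeometric enumeration ---------------

fisher_two_sided_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(x, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# ---- memoized simulation fixtures -----------------------------------------

.fixture_env <- new.env()

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env, inherits = FALSE)
}

# a compact ancestor + default-condition descendant pair
std_pair <- function() fixture("std_pair", function() {
  anc <- build_ancestor(sim_params(seed = 1, n_genes = 80,
                                   n_cne_planted = 50))
  la <- evolve_lineage(anc, lineage_params(n_exon_shuffles = 5,
                                           domain_pair_gain = 4,
                                           domain_pair_loss = 2),
                       seed = 101, name = "spA")
  lb <- evolve_lineage(anc, lineage_params(n_exon_shuffles = 5,
                                           domain_pair_gain = 4,
                                           domain_pair_loss = 2),
                       seed = 102, name = "spB")
  list(anc = anc, la = la, lb = lb)
})

# low-divergence pair with no structural events, for orthology recovery
low_div_pair <- function() fixture("low_div_pair", function() {
  anc <- build_ancestor(sim_params(seed = 3, n_genes = 50,
                                   n_cne_planted = 20))
  la <- evolve_lineage(anc, lineage_params(subst_rate = 0.05,
                                           cds_subst_factor = 1,
                                           n_inversions = 0,
                                           n_translocations = 0),
                       seed = 31, name = "loA")
  lb <- evolve_lineage(anc, lineage_params(subst_rate = 0.05,
                                           cds_subst_factor = 1,
                                           n_inversions = 0,
                                           n_translocations = 0),
                       seed = 32, name = "loB")
  list(anc = anc, la = la, lb = lb)
})

# a small hit-table row in blast tabular layout
hit_row <- function(q, s, ident, len = 100, qs = 1, qe = len,
                    ss = 1, se = len, evalue = 1e-50,
                    bits = 2 * len * ident / 100) {
  data.frame(query_id = q, subject_id = s, percent_identity = ident,
             alignment_length = len, mismatches = round(len * (1 - ident / 100)),
             gap_opens = 0L, q_start = qs, q_end = qe, s_start = ss,
             s_end = se, e_value = evalue, bitscore = bits,
             stringsAsFactors = FALSE)
}

# engineered CNE candidate fixture: 10 candidates on a 100 kb reference
# with one gene at [50000, 50300); 2 are removed as short, 3 as
# CDS-adjacent, 1 by homology, 4 survive
engineered_candidates <- function() {
  ann <- genome_annotation(
    c(r1 = 100000),
    list(gene_model("g1", "r1", "+", cbind(50000, 50300))))
  mk <- function(id, start, len, ident = 90)
    data.frame(id = id, ref_seq = "r1", ref_start = start,
               ref_end = start + len, query_seq = "q1",
               query_start = start, query_end = start + len,
               length = len, identity = ident, stringsAsFactors = FALSE)
  cand <- rbind(
    mk("cand01", 1000, 50), mk("cand02", 2000, 74),      # short
    mk("cand03", 49900, 90),                             # 10 bp from CDS
    mk("cand04", 50310, 100),                            # right of CDS
    mk("cand05", 49920, 80),                             # overlaps flank
    mk("cand06", 10000, 120),                            # homology hit
    mk("cand07", 20000, 200), mk("cand08", 30000, 150),
    mk("cand09", 40000, 100), mk("cand10", 60000, 300))
  hits <- hit_row("cand06", "known_protein", 80, evalue = 1e-10)
  list(ann = ann, cand = cand, hits = hits)
}

# a gap-free pairwise alignment block
simple_block <- function(ref, qry, ref_seq = "r1", query_seq = "q1",
                         ref_start = 0, query_start = 0, strand = "+") {
  data.frame(ref_seq = ref_seq, ref_start = ref_start,
             ref_end = ref_start + nchar(gsub("-", "", ref)),
             query_seq = query_seq, query_start = query_start,
             query_end = query_start + nchar(gsub("-", "", qry)),
             query_strand = strand, ref_text = ref, query_text = qry,
             stringsAsFactors = FALSE)
}
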