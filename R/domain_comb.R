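# Protein domain-combination turnover: pair extraction, Dollo gains per
# tree branch, promiscuity, and presence-absence trees.

#' Resolve overlapping domain hits within each protein
#'
#' Hits are accepted greedily by ascending e-value; a hit overlapping an
#' already accepted interval on the same protein is dropped.  The result
#' is the ordered (N- to C-terminal) domain architecture per protein.
#'
#' @param domains Domain table (`"domains"` schema of [read_table()]).
#' @return Named list: protein id -> character vector of domain types in
#'   N->C order.
#' @export
resolve_architectures <- function(domains) {
  out <- list()
  for (p in unique(domains$protein_id)) {
    sub <- domains[domains$protein_id == p, , drop = FALSE]
    sub <- sub[order(sub$e_value, sub$env_start), , drop = FALSE]
    acc <- integer(0)
    for (i in seq_len(nrow(sub))) {
      if (!length(acc) ||
          all(sub$env_end[i] <= sub$env_start[acc] |
                sub$env_start[i] >= sub$env_end[acc]))
        acc <- c(acc, i)
    }
    sub <- sub[acc, , drop = FALSE]
    out[[p]] <- sub$domain_type[order(sub$env_start)]
  }
  out
}

#' Extract domain pairs from architectures
#'
#' `adjacent` mode takes unordered pairs of consecutive domain types;
#' `cooccur` mode takes all unordered type pairs within a protein.
#' Self-pairs (tandem repeats of one type) are excluded by default.
#' Adjacent pairs are always a subset of co-occurring pairs.
#'
#' @param architectures Output of [resolve_architectures()] (or a domain
#'   table, which is resolved first).
#' @param mode `"adjacent"` (default) or `"cooccur"`.
#' @param keep_self Keep same-type pairs (default FALSE).
#' @return Character vector of pair keys `"TYPE1|TYPE2"` (types sorted
#'   within the key), unique.
#' @export
extract_pairs <- function(architectures, mode = c("adjacent", "cooccur"),
                          keep_self = FALSE) {
  mode <- match.arg(mode)
  if (is.data.frame(architectures))
    architectures <- resolve_architectures(architectures)
  pairs <- character(0)
  for (arch in architectures) {
    if (length(arch) < 2L) next
    pp <- if (mode == "adjacent")
      cbind(arch[-length(arch)], arch[-1L])
    else t(utils::combn(arch, 2L))
    keys <- apply(pp, 1L, function(r) paste(sort(r), collapse = "|"))
    if (!keep_self)
      keys <- keys[pp[, 1L] != pp[, 2L]]
    pairs <- c(pairs, keys)
  }
  sort(unique(pairs))
}

#' Build a species-by-pair presence/absence matrix
#'
#' @param pair_sets Named list: species -> character vector of pair keys
#'   (from [extract_pairs()]).
#' @return Binary matrix, rows = species, columns = pairs.
#' @export
pair_matrix <- function(pair_sets) {
  all_pairs <- sort(unique(unlist(pair_sets)))
  m <- matrix(0L, length(pair_sets), length(all_pairs),
              dimnames = list(names(pair_sets), all_pairs))
  for (s in names(pair_sets))
    m[s, pair_sets[[s]]] <- 1L
  m
}

#' Classify pairs by domain vocabulary
#'
#' Splits pair keys into those containing at least one domain type from
#' `special_types` (e.g. vertebrate-specific domains) and the rest; the
#' two counts always sum to the total.
#'
#' @param pairs Character vector of pair keys.
#' @param special_types Character vector of domain types.
#' @return Logical vector: TRUE when the pair contains a special type.
#' @export
pair_contains_type <- function(pairs, special_types) {
  vapply(strsplit(pairs, "|", fixed = TRUE),
         function(x) any(x %in% special_types), logical(1))
}

# internal: per-node leaf sets of a rooted ape tree, and children lists
.tree_index <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  children <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge)))
    children[[tree$edge[i, 1]]] <- c(children[[tree$edge[i, 1]]],
                                     tree$edge[i, 2])
  leaves <- vector("list", nn)
  fill <- function(v) {
    if (v <= nt) leaves[[v]] <<- tree$tip.label[v]
    else {
      for (ch in children[[v]]) fill(ch)
      leaves[[v]] <<- unlist(leaves[children[[v]]])
    }
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  fill(root)
  list(root = root, children = children, leaves = leaves, n_tips = nt)
}

#' Dollo gains and losses of domain pairs on a species tree
#'
#' Each pair present in at least one leaf is gained exactly once, on the
#' branch above the most recent common ancestor of the species that have
#' it (for the root, the gain is assigned to the root itself); losses
#' are placed parsimoniously on the maximal pair-free subtrees below the
#' gain.  Pairs absent everywhere are ignored.
#'
#' @param matrix Binary species-by-pair matrix ([pair_matrix()]).
#' @param tree Rooted `ape::phylo`; leaves must cover the matrix species.
#' @return List of class `branch_gains`: `per_branch` (data frame `node,
#'   label, gains, losses`), `per_pair` (gain node per pair),
#'   `total_gains`.
#' @export
dollo_gains <- function(matrix, tree) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  miss <- setdiff(rownames(matrix), tree$tip.label)
  if (length(miss)) stop("species missing from tree: ",
                         paste(miss, collapse = ", "))
  idx <- .tree_index(tree)
  nn <- idx$n_tips + tree$Nnode
  gains <- integer(nn); losses <- integer(nn)
  per_pair <- character(0)
  for (j in seq_len(ncol(matrix))) {
    S <- rownames(matrix)[matrix[, j] > 0]
    if (!length(S)) next
    # MRCA of S
    has <- vapply(seq_len(nn), function(v) all(S %in% idx$leaves[[v]]) &&
                    any(idx$leaves[[v]] %in% S), logical(1))
    cand <- which(vapply(seq_len(nn), function(v)
      all(S %in% idx$leaves[[v]]), logical(1)))
    mrca <- cand[which.min(lengths(idx$leaves[cand]))]
    gains[mrca] <- gains[mrca] + 1L
    per_pair[colnames(matrix)[j]] <- mrca
    # losses: maximal subtrees under mrca with no presence
    count_losses <- function(v) {
      if (!any(idx$leaves[[v]] %in% S)) {
        losses[v] <<- losses[v] + 1L
        return(invisible(NULL))
      }
      for (ch in idx$children[[v]]) count_losses(ch)
      invisible(NULL)
    }
    for (ch in idx$children[[mrca]]) count_losses(ch)
  }
  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label)) tree$node.label
              else paste0("node", seq_len(tree$Nnode)))
  per_branch <- data.frame(node = seq_len(nn), label = labels,
                           gains = gains, losses = losses)
  structure(list(per_branch = per_branch, per_pair = per_pair,
                 total_gains = sum(gains), tree = tree),
            class = "branch_gains")
}

#' @export
print.branch_gains <- function(x, ...) {
  cat("<branch_gains>", x$total_gains, "pairs gained over",
      sum(x$per_branch$losses), "losses\n")
  print(x$per_branch[x$per_branch$gains + x$per_branch$losses > 0, ])
  invisible(x)
}

#' Domain-pair gain rate per branch
#'
#' @param gains A `branch_gains` object.
#' @param durations_myr Named numeric vector (names matching
#'   `per_branch$label`) of branch durations in Myr.
#' @return Data frame `label, gains, duration_myr, rate_per_myr`;
#'   branches without a duration are skipped with a warning.
#' @export
gain_rate <- function(gains, durations_myr) {
  pb <- gains$per_branch
  keep <- pb$label %in% names(durations_myr)
  if (any(!keep & pb$gains > 0))
    warning("no duration for branch(es): ",
            paste(pb$label[!keep & pb$gains > 0], collapse = ", "),
            "; skipped")
  pb <- pb[keep, , drop = FALSE]
  dur <- unname(durations_myr[pb$label])
  if (any(dur <= 0)) stop("branch durations must be positive")
  data.frame(label = pb$label, gains = pb$gains, duration_myr = dur,
             rate_per_myr = pb$gains / dur)
}

#' Rank domains by promiscuity
#'
#' Promiscuity is the number of distinct partner types a domain forms
#' pairs with; optionally the share of novel (per-branch) pairs using
#' each domain is reported to test whether hub domains recur across
#' branches.
#'
#' @param pair_sets Named list species -> pair keys, or a single
#'   character vector of pair keys.
#' @param novel_pairs Optional named list branch -> novel pair keys.
#' @return Data frame ordered by decreasing partner count: `domain,
#'   n_partners` and, when `novel_pairs` is given, one `share_<branch>`
#'   column per branch.
#' @export
promiscuity_rank <- function(pair_sets, novel_pairs = NULL) {
  pairs <- unique(unlist(pair_sets))
  parts <- strsplit(pairs, "|", fixed = TRUE)
  doms <- sort(unique(unlist(parts)))
  n_partners <- vapply(doms, function(d)
    length(unique(unlist(parts[vapply(parts, function(x) d %in% x,
                                      logical(1))], use.names = FALSE)
                  )) - 1L, integer(1))
  out <- data.frame(domain = doms, n_partners = n_partners)
  if (!is.null(novel_pairs)) {
    for (br in names(novel_pairs)) {
      np <- strsplit(novel_pairs[[br]], "|", fixed = TRUE)
      out[[paste0("share_", br)]] <- vapply(doms, function(d)
        if (length(np)) mean(vapply(np, function(x) d %in% x, logical(1)))
        else 0, numeric(1))
    }
  }
  out <- out[order(-out$n_partners, out$domain), ]
  rownames(out) <- NULL
  out
}

#' Neighbor-joining tree from domain-pair presence/absence
#'
#' Pairwise distances are Jaccard (1 - intersection/union of pair sets);
#' the tree is built with neighbor joining.  Identical species get
#' zero-length branches.
#'
#' @param matrix Binary species-by-pair matrix with >= 4 species.
#' @return Unrooted `ape::phylo`.
#' @export
presence_absence_tree <- function(matrix) {
  if (nrow(matrix) < 4L) stop("need at least 4 species")
  ns <- nrow(matrix)
  d <- matrix(0, ns, ns, dimnames = list(rownames(matrix), rownames(matrix)))
  for (i in seq_len(ns - 1L)) for (j in seq(i + 1L, ns)) {
    inter <- sum(matrix[i, ] & matrix[j, ])
    uni <- sum(matrix[i, ] | matrix[j, ])
    d[i, j] <- d[j, i] <- if (uni == 0) 0 else 1 - inter / uni
  }
  ape::nj(stats::as.dist(d))
}
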