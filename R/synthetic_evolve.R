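# Lineage evolution on the synthetic genome: whole-genome duplication,
# inversions, translocations, exon shuffles with a tunable 1-1 phase
# preference, domain-pair gain/loss, CNE decay, and per-site
# substitutions with class-specific rates.  Every event is recorded with
# enough detail that replaying the log on the ancestor reproduces the
# descendant exactly.

#' Lineage evolution parameters
#'
#' The substitution rate applies to neutral sequence (intergenic and
#' introns); coding exons and CNEs evolve at the rate scaled by their
#' respective factors, emulating purifying selection.  With the default
#' neutral rate, orthologous neutral sequence between two descendant
#' lineages falls below whole-genome-alignment detectability while
#' exons and CNEs remain alignable, which is the regime the CNE and
#' orthology estimators are built for.
#'
#' @param subst_rate Substitutions per neutral site along this lineage.
#' @param cds_subst_factor,cne_subst_factor Multipliers for exon and CNE
#'   sites (defaults 0.1).
#' @param n_inversions,n_translocations Structural event counts.
#' @param n_exon_shuffles Number of exon shuffle events.
#' @param phase11_preference Probability beta that a shuffle picks a
#'   donor exon with 1-1 flanking phases; with probability 1 - beta a
#'   phase class is drawn uniformly from the nine classes first.
#' @param domain_pair_gain,domain_pair_loss Domain-pair event counts.
#' @param wgd Whole-genome duplication before other events.
#' @param cne_decay Per-CNE probability of losing the element (sequence
#'   replaced by neutral DNA).
#' @return List of class `lineage_params`.
#' @export
lineage_params <- function(subst_rate = 0.35, cds_subst_factor = 0.1,
                           cne_subst_factor = 0.1,
                           n_inversions = 5, n_translocations = 3,
                           n_exon_shuffles = 0,
                           phase11_preference = 0.3,
                           domain_pair_gain = 0, domain_pair_loss = 0,
                           wgd = FALSE, cne_decay = 0) {
  stopifnot(phase11_preference >= 0, phase11_preference <= 1,
            subst_rate >= 0, cne_decay >= 0, cne_decay <= 1)
  p <- as.list(environment())
  class(p) <- "lineage_params"
  p
}

# internal-exon pool with phases, over the current state of a lineage
.internal_exon_pool <- function(sim) {
  rows <- list()
  for (cn in names(sim$chroms)) for (fi in seq_along(sim$chroms[[cn]])) {
    f <- sim$chroms[[cn]][[fi]]
    if (f$kind != "gene") next
    g <- f$gene
    k <- length(g$exons)
    if (k < 3L) next
    lens <- nchar(g$exons)
    bounds <- cumsum(lens) %% 3
    for (i in seq(2L, k - 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cn, feat = fi, gene_id = g$gene_id, idx = i,
        exon_id = g$exon_ids[i],
        phase5 = bounds[i - 1L], phase3 = bounds[i],
        stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

.find_gene_feat <- function(sim, gene_id) {
  for (cn in names(sim$chroms)) for (fi in seq_along(sim$chroms[[cn]])) {
    f <- sim$chroms[[cn]][[fi]]
    if (f$kind == "gene" && f$gene$gene_id == gene_id)
      return(c(chrom = cn, feat = fi))
  }
  stop("gene not found: ", gene_id)
}

.flip_feature <- function(f) {
  if (f$kind == "gene") {
    f$gene$strand <- if (f$gene$strand == "+") "-" else "+"
  } else {
    f$seq <- .revcomp(f$seq)
  }
  f
}

.apply_inversion <- function(sim, ev) {
  feats <- sim$chroms[[ev$chrom]]
  seg <- rev(lapply(feats[ev$from:ev$to], .flip_feature))
  sim$chroms[[ev$chrom]] <- c(feats[seq_len(ev$from - 1L)], seg,
                              if (ev$to < length(feats))
                                feats[seq(ev$to + 1L, length(feats))])
  sim
}

.apply_translocation <- function(sim, ev) {
  src <- sim$chroms[[ev$src]]
  seg <- src[ev$from:ev$to]
  rest <- src[-(ev$from:ev$to)]
  sim$chroms[[ev$src]] <- rest
  dst <- sim$chroms[[ev$dst]]
  # the landing site is inside an intergenic feature of the destination,
  # which is split at ev$split_at around the incoming segment
  at <- ev$at
  target <- dst[[at]]
  left <- target; right <- target
  left$seq <- substr(target$seq, 1L, ev$split_at)
  left$id <- paste0(target$id, "L")
  right$seq <- substr(target$seq, ev$split_at + 1L, nchar(target$seq))
  right$id <- paste0(target$id, "R")
  sim$chroms[[ev$dst]] <- c(dst[seq_len(at - 1L)], list(left), seg,
                            list(right),
                            if (at < length(dst))
                              dst[seq(at + 1L, length(dst))])
  sim
}

.apply_shuffle <- function(sim, ev) {
  dloc <- .find_gene_feat(sim, ev$donor_gene)
  rloc <- .find_gene_feat(sim, ev$recipient_gene)
  dg <- sim$chroms[[dloc["chrom"]]][[as.integer(dloc["feat"])]]$gene
  rg <- sim$chroms[[rloc["chrom"]]][[as.integer(rloc["feat"])]]$gene
  i <- ev$donor_idx
  exon <- dg$exons[i]; exon_id <- dg$exon_ids[i]
  upL <- substr(dg$introns[i - 1L], 1L, ev$cut_up)
  upR <- substr(dg$introns[i - 1L], ev$cut_up + 1L,
                nchar(dg$introns[i - 1L]))
  dnL <- substr(dg$introns[i], 1L, ev$cut_dn)
  dnR <- substr(dg$introns[i], ev$cut_dn + 1L, nchar(dg$introns[i]))
  # donor loses the exon; its flanking introns merge
  dg$exons <- dg$exons[-i]
  dg$exon_ids <- dg$exon_ids[-i]
  dg$introns <- c(dg$introns[seq_len(i - 2L)], paste0(upL, dnR),
                  if (i + 1L <= length(dg$introns))
                    dg$introns[seq(i + 1L, length(dg$introns))])
  # recipient intron r is split around the cassette
  r <- ev$recipient_intron
  rl <- substr(rg$introns[r], 1L, ev$cut_rec)
  rr <- substr(rg$introns[r], ev$cut_rec + 1L, nchar(rg$introns[r]))
  rg$exons <- append(rg$exons, exon, after = r)
  rg$exon_ids <- append(rg$exon_ids, exon_id, after = r)
  new_introns <- c(paste0(rl, upR), paste0(dnL, rr))
  rg$introns <- append(rg$introns[-r], new_introns, after = r - 1L)
  sim$chroms[[dloc["chrom"]]][[as.integer(dloc["feat"])]]$gene <- dg
  sim$chroms[[rloc["chrom"]]][[as.integer(rloc["feat"])]]$gene <- rg
  sim
}

.gene_location_index <- function(sim) {
  idx <- list()
  for (cn in names(sim$chroms)) for (fi in seq_along(sim$chroms[[cn]])) {
    f <- sim$chroms[[cn]][[fi]]
    if (f$kind == "gene") idx[[f$gene$gene_id]] <- c(cn, fi)
  }
  idx
}

.apply_substitutions <- function(sim, ev) {
  gene_idx <- .gene_location_index(sim)
  for (rec in ev$units) {
    mutate <- function(s) {
      v <- strsplit(s, "")[[1]]
      v[rec$pos] <- rec$base
      paste(v, collapse = "")
    }
    if (rec$unit == "feature") {
      loc <- rec$loc
      sim$chroms[[loc[1]]][[as.integer(loc[2])]]$seq <-
        mutate(sim$chroms[[loc[1]]][[as.integer(loc[2])]]$seq)
    } else {
      loc <- gene_idx[[rec$gene_id]]
      if (is.null(loc)) stop("gene not found: ", rec$gene_id)
      g <- sim$chroms[[loc[1]]][[as.integer(loc[2])]]$gene
      if (rec$unit == "exon") g$exons[rec$idx] <- mutate(g$exons[rec$idx])
      else g$introns[rec$idx] <- mutate(g$introns[rec$idx])
      sim$chroms[[loc[1]]][[as.integer(loc[2])]]$gene <- g
    }
  }
  sim
}

.apply_wgd <- function(sim) {
  new_chroms <- sim$chroms
  dup_domains <- sim$domains
  for (cn in names(sim$chroms)) {
    feats <- lapply(sim$chroms[[cn]], function(f) {
      f$id <- if (!is.null(f$id)) paste0(f$id, "_2") else f$id
      if (f$kind == "gene") {
        f$gene$gene_id <- paste0(f$gene$gene_id, "_2")
        f$gene$protein_id <- paste0(f$gene$protein_id, "_2")
        f$gene$exon_ids <- paste0(f$gene$exon_ids, "_2")
        f$id <- f$gene$gene_id
      }
      f
    })
    new_chroms[[paste0(cn, "_2")]] <- feats
  }
  dup_domains$protein_id <- paste0(dup_domains$protein_id, "_2")
  sim$chroms <- new_chroms
  sim$domains <- rbind(sim$domains, dup_domains)
  sim
}

#' Evolve a lineage from an ancestral genome
#'
#' Events are applied in the order WGD, inversions, translocations, exon
#' shuffles, domain-pair gains/losses, CNE decay, substitutions; each is
#' recorded in an event log whose replay on the ancestor reproduces the
#' descendant exactly (see [replay_events()]).
#'
#' @param ancestor A `sim_genome` from [build_ancestor()].
#' @param params A [lineage_params()].
#' @param seed Integer seed for this lineage.
#' @param name Assembly label of the descendant.
#' @return List: `genome` (descendant `sim_genome`), `log` (class
#'   `event_log`).
#' @export
evolve_lineage <- function(ancestor, params = lineage_params(), seed = 1,
                           name = "descendant") {
  set.seed(seed)
  sim <- ancestor
  sim$assembly_name <- name
  log <- list()
  push <- function(ev) log[[length(log) + 1L]] <<- ev

  if (isTRUE(params$wgd)) {
    sim <- .apply_wgd(sim)
    push(list(kind = "wgd"))
  }
  # structural breakpoints fall in neutral sequence: segments start and
  # end on item (gene/CNE) features, so no event ever strands a gene or
  # CNE against another feature without intergenic spacer
  item_idx <- function(cn)
    which(vapply(sim$chroms[[cn]], function(f) f$kind != "intergenic",
                 logical(1)))
  # inversions ----------------------------------------------------------
  for (i in seq_len(params$n_inversions)) {
    counts <- vapply(names(sim$chroms),
                     function(cn) length(item_idx(cn)), integer(1))
    if (all(counts == 0L)) break
    cn <- sample(names(sim$chroms), 1L, prob = counts)
    items <- item_idx(cn)
    from <- items[sample.int(length(items), 1L)]
    upto <- items[items >= from]
    to <- upto[min(length(upto), sample.int(3L, 1L))]
    ev <- list(kind = "inversion", chrom = cn, from = from, to = to)
    sim <- .apply_inversion(sim, ev)
    push(ev)
  }
  # translocations -------------------------------------------------------
  for (i in seq_len(params$n_translocations)) {
    counts <- vapply(names(sim$chroms),
                     function(cn) length(item_idx(cn)), integer(1))
    eligible <- names(counts)[counts >= 2L]
    if (!length(eligible)) break
    src <- sample(eligible, 1L)
    items <- item_idx(src)
    from <- items[sample.int(length(items), 1L)]
    upto <- items[items >= from]
    to <- upto[min(length(upto), sample.int(2L, 1L))]
    dst_pool <- if (length(sim$chroms) > 1L)
      setdiff(names(sim$chroms), src) else src
    dst <- sample(dst_pool, 1L)
    # landing intergenic feature, indexed in the post-removal layout
    post <- if (dst == src)
      sim$chroms[[src]][-(from:to)] else sim$chroms[[dst]]
    igs <- which(vapply(post, function(f)
      f$kind == "intergenic" && nchar(f$seq) >= 2L, logical(1)))
    if (!length(igs)) next
    at <- igs[sample.int(length(igs), 1L)]
    ev <- list(kind = "translocation", src = src, from = from, to = to,
               dst = dst, at = at,
               split_at = nchar(post[[at]]$seq) %/% 2L)
    sim <- .apply_translocation(sim, ev)
    push(ev)
  }
  # exon shuffles --------------------------------------------------------
  if (params$n_exon_shuffles > 0L) {
    for (i in seq_len(params$n_exon_shuffles)) {
      pool <- .internal_exon_pool(sim)
      if (is.null(pool))
        stop("exon shuffles requested but no gene has internal exons")
      use_pref <- stats::runif(1) < params$phase11_preference
      if (use_pref) {
        cand <- pool[pool$phase5 == 1 & pool$phase3 == 1, , drop = FALSE]
        if (!nrow(cand)) cand <- pool
      } else {
        cls <- c(sample(0:2, 1L), sample(0:2, 1L))
        cand <- pool[pool$phase5 == cls[1] & pool$phase3 == cls[2], ,
                     drop = FALSE]
        if (!nrow(cand)) cand <- pool
      }
      pick <- cand[sample.int(nrow(cand), 1L), ]
      # recipient: a different gene with at least one intron
      rec_pool <- list()
      for (cn in names(sim$chroms)) for (f in sim$chroms[[cn]]) {
        if (f$kind == "gene" && length(f$gene$exons) >= 2L &&
            f$gene$gene_id != pick$gene_id)
          rec_pool[[length(rec_pool) + 1L]] <- f$gene
      }
      if (!length(rec_pool))
        stop("no eligible recipient gene for exon shuffle")
      rg <- rec_pool[[sample.int(length(rec_pool), 1L)]]
      r <- sample.int(length(rg$introns), 1L)
      dloc <- .find_gene_feat(sim, pick$gene_id)
      dg <- sim$chroms[[dloc["chrom"]]][[as.integer(dloc["feat"])]]$gene
      ev <- list(kind = "exon_shuffle",
                 donor_gene = pick$gene_id, donor_idx = pick$idx,
                 exon_id = pick$exon_id,
                 phase5 = pick$phase5, phase3 = pick$phase3,
                 recipient_gene = rg$gene_id, recipient_intron = r,
                 cut_up = nchar(dg$introns[pick$idx - 1L]) %/% 2L,
                 cut_dn = nchar(dg$introns[pick$idx]) %/% 2L,
                 cut_rec = nchar(rg$introns[r]) %/% 2L,
                 phase_preferred = use_pref)
      sim <- .apply_shuffle(sim, ev)
      push(ev)
    }
  }
  # domain pair gains/losses ---------------------------------------------
  adjacent_pairs <- function(domains) {
    extract_pairs(domains, mode = "adjacent")
  }
  base_pairs <- adjacent_pairs(sim$domains)
  novel_vocab <- sprintf("N%02d", 1:30)
  gained_keys <- character(0)
  for (i in seq_len(params$domain_pair_gain)) {
    cur_pairs <- adjacent_pairs(sim$domains)
    prots <- unique(sim$domains$protein_id)
    ok <- FALSE
    for (tries in 1:50) {
      p <- sample(prots, 1L)
      sub <- sim$domains[sim$domains$protein_id == p, , drop = FALSE]
      last <- sub[which.max(sub$env_end), ]
      t_new <- sample(novel_vocab, 1L)
      key <- paste(sort(c(last$domain_type, t_new)), collapse = "|")
      if (!key %in% c(cur_pairs, base_pairs)) { ok <- TRUE; break }
    }
    if (!ok) break
    ev <- list(kind = "domain_gain", protein_id = p, domain_type = t_new,
               env_start = last$env_end + 5, env_end = last$env_end + 45,
               pair = key)
    sim$domains <- rbind(sim$domains, data.frame(
      protein_id = p, domain_type = t_new, env_start = ev$env_start,
      env_end = ev$env_end, e_value = 1e-8, stringsAsFactors = FALSE))
    gained_keys <- c(gained_keys, key)
    push(ev)
  }
  for (i in seq_len(params$domain_pair_loss)) {
    # remove a terminal domain whose adjacency occurs exactly once
    arch <- resolve_architectures(sim$domains)
    cand <- list()
    pair_count <- table(unlist(lapply(arch, function(a)
      if (length(a) >= 2L)
        apply(cbind(a[-length(a)], a[-1L]), 1L, function(r)
          paste(sort(r), collapse = "|")))))
    for (p in names(arch)) {
      a <- arch[[p]]
      if (length(a) < 2L) next
      key <- paste(sort(c(a[length(a) - 1L], a[length(a)])), collapse = "|")
      if (key %in% gained_keys) next   # losses target ancestral pairs
      if (pair_count[[key]] == 1L)
        cand[[length(cand) + 1L]] <- list(protein = p, pair = key)
    }
    if (!length(cand)) break
    pickc <- cand[[sample.int(length(cand), 1L)]]
    sub <- which(sim$domains$protein_id == pickc$protein)
    drop_row <- sub[which.max(sim$domains$env_end[sub])]
    ev <- list(kind = "domain_loss", protein_id = pickc$protein,
               domain_type = sim$domains$domain_type[drop_row],
               pair = pickc$pair)
    sim$domains <- sim$domains[-drop_row, , drop = FALSE]
    push(ev)
  }
  # CNE decay ------------------------------------------------------------
  if (params$cne_decay > 0) {
    for (cn in names(sim$chroms)) for (fi in seq_along(sim$chroms[[cn]])) {
      f <- sim$chroms[[cn]][[fi]]
      if (f$kind == "cne" && stats::runif(1) < params$cne_decay) {
        new_seq <- .random_dna(nchar(f$seq))
        sim$chroms[[cn]][[fi]]$seq <- new_seq
        push(list(kind = "cne_decay", cne_id = f$id, chrom = cn,
                  feat = fi, new_seq = new_seq))
      }
    }
  }
  # substitutions --------------------------------------------------------
  units <- list()
  draw_muts <- function(s, rate) {
    len <- nchar(s)
    n <- stats::rbinom(1L, len, min(1, rate))
    if (n == 0L) return(NULL)
    pos <- sort(sample.int(len, n))
    old <- strsplit(s, "")[[1]][pos]
    # uniform over the three alternative bases, vectorized
    shift <- sample.int(3L, n, replace = TRUE)
    base <- .BASES[((match(old, .BASES) - 1L + shift) %% 4L) + 1L]
    list(pos = pos, base = base)
  }
  for (cn in names(sim$chroms)) for (fi in seq_along(sim$chroms[[cn]])) {
    f <- sim$chroms[[cn]][[fi]]
    if (f$kind == "gene") {
      g <- f$gene
      for (j in seq_along(g$exons)) {
        m <- draw_muts(g$exons[j], params$subst_rate * params$cds_subst_factor)
        if (!is.null(m))
          units[[length(units) + 1L]] <- c(list(unit = "exon",
                                                gene_id = g$gene_id,
                                                idx = j), m)
      }
      for (j in seq_along(g$introns)) {
        m <- draw_muts(g$introns[j], params$subst_rate)
        if (!is.null(m))
          units[[length(units) + 1L]] <- c(list(unit = "intron",
                                                gene_id = g$gene_id,
                                                idx = j), m)
      }
    } else {
      rate <- if (f$kind == "cne")
        params$subst_rate * params$cne_subst_factor else params$subst_rate
      m <- draw_muts(f$seq, rate)
      if (!is.null(m))
        units[[length(units) + 1L]] <- c(list(unit = "feature",
                                              loc = c(cn, fi)), m)
    }
  }
  if (length(units)) {
    ev <- list(kind = "substitutions", units = units)
    sim <- .apply_substitutions(sim, ev)
    push(ev)
  }
  structure(list(genome = sim, log = structure(log, class = "event_log")),
            class = "sim_lineage")
}

#' @export
print.event_log <- function(x, ...) {
  kinds <- vapply(x, function(e) e$kind, character(1))
  cat("<event_log>", length(x), "events:\n")
  print(table(kinds))
  invisible(x)
}

#' Replay an event log on the ancestor
#'
#' Applies every recorded event deterministically; the result equals the
#' descendant the log came from, sequence for sequence.
#'
#' @param ancestor The `sim_genome` the log was generated from.
#' @param log An `event_log`.
#' @param name Assembly label for the reconstructed genome.
#' @return A `sim_genome`.
#' @export
replay_events <- function(ancestor, log, name = "replayed") {
  sim <- ancestor
  sim$assembly_name <- name
  for (ev in log) {
    sim <- switch(ev$kind,
      wgd = .apply_wgd(sim),
      inversion = .apply_inversion(sim, ev),
      translocation = .apply_translocation(sim, ev),
      exon_shuffle = .apply_shuffle(sim, ev),
      domain_gain = {
        sim$domains <- rbind(sim$domains, data.frame(
          protein_id = ev$protein_id, domain_type = ev$domain_type,
          env_start = ev$env_start, env_end = ev$env_end, e_value = 1e-8,
          stringsAsFactors = FALSE))
        sim
      },
      domain_loss = {
        sub <- which(sim$domains$protein_id == ev$protein_id &
                       sim$domains$domain_type == ev$domain_type)
        sub <- sub[which.max(sim$domains$env_end[sub])]
        sim$domains <- sim$domains[-sub, , drop = FALSE]
        sim
      },
      cne_decay = {
        sim$chroms[[ev$chrom]][[ev$feat]]$seq <- ev$new_seq
        sim
      },
      substitutions = .apply_substitutions(sim, ev),
      stop("unknown event kind: ", ev$kind))
  }
  sim
}
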