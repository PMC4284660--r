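# Conserved non-coding element (CNE) calling and refinement from
# reciprocal-best pairwise whole-genome alignments.

#' Coarse CNE candidates from alignment blocks
#'
#' Alignment columns overlapping annotated coding sequence on the
#' reference (or any exon, with `mask = "exon"`) are removed, gap runs
#' of `gap_break` bp or longer break candidates, and candidates closer
#' than `merge_dist` bp on both genomes are merged.  Identity counts gap
#' columns as mismatches.
#'
#' @param blocks An [alignment_block_set()]; reference intervals must
#'   not overlap (reciprocal-best property).
#' @param annotation Reference [genome_annotation()].
#' @param mask `"cds"` (default) or `"exon"`: which annotation intervals
#'   to subtract.
#' @param gap_break Gap-run length that splits candidates (default 10).
#' @param merge_dist Merge candidates separated by less than this on
#'   both genomes (default 10).
#' @return Data frame of class `cne_candidates`: `id, ref_seq,
#'   ref_start, ref_end, query_seq, query_start, query_end, length,
#'   identity`.
#' @export
coarse_cnes <- function(blocks, annotation, mask = c("cds", "exon"),
                        gap_break = 10L, merge_dist = 10L) {
  mask <- match.arg(mask)
  b <- blocks$blocks
  for (s in unique(b$ref_seq)) {
    iv <- b[b$ref_seq == s, , drop = FALSE]
    iv <- iv[order(iv$ref_start), , drop = FALSE]
    if (nrow(iv) > 1L && any(iv$ref_start[-1L] < iv$ref_end[-nrow(iv)]))
      stop("reference intervals overlap on ", s,
           "; blocks are not reciprocal-best")
  }
  mask_iv <- list()
  for (g in annotation$genes) {
    m <- if (mask == "cds") g$cds else g$exons
    mask_iv[[g$seq_name]] <- rbind(mask_iv[[g$seq_name]], m)
  }
  mask_ranges <- lapply(mask_iv, function(m)
    IRanges::reduce(IRanges::IRanges(start = m[, 1] + 1L, end = m[, 2])))

  cand <- list()
  for (bi in seq_len(nrow(b))) {
    r <- strsplit(b$ref_text[bi], "")[[1]]
    q <- strsplit(b$query_text[bi], "")[[1]]
    nc <- length(r)
    ref_pos <- b$ref_start[bi] + cumsum(r != "-") - 1L   # 0-based, NA-ish for gaps
    qry_off <- cumsum(q != "-")
    # columns to drop: inside coding mask
    drop <- logical(nc)
    mr <- mask_ranges[[b$ref_seq[bi]]]
    if (!is.null(mr) && length(mr)) {
      nongap <- r != "-"
      ov <- IRanges::overlapsAny(
        IRanges::IRanges(start = ref_pos[nongap] + 1L, width = 1L), mr)
      drop[which(nongap)[ov]] <- TRUE
    }
    # gap runs >= gap_break split candidates
    isgap <- r == "-" | q == "-"
    rl <- rle(isgap)
    ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
    long_gap <- which(rl$values & rl$lengths >= gap_break)
    for (k in long_gap) drop[starts[k]:ends[k]] <- TRUE
    # remaining runs of kept columns are candidates
    rl2 <- rle(!drop)
    e2 <- cumsum(rl2$lengths); s2 <- e2 - rl2$lengths + 1L
    for (k in which(rl2$values)) {
      cols <- s2[k]:e2[k]
      ref_cols <- cols[r[cols] != "-"]
      qry_cols <- cols[q[cols] != "-"]
      if (!length(ref_cols)) next
      ident <- 100 * sum(r[cols] == q[cols] & r[cols] != "-") /
        length(cols)
      qs <- if (length(qry_cols))
        b$query_start[bi] + qry_off[qry_cols[1L]] - 1L else NA_real_
      qe <- if (length(qry_cols))
        b$query_start[bi] + qry_off[qry_cols[length(qry_cols)]] else NA_real_
      cand[[length(cand) + 1L]] <- data.frame(
        ref_seq = b$ref_seq[bi],
        ref_start = ref_pos[ref_cols[1L]],
        ref_end = ref_pos[ref_cols[length(ref_cols)]] + 1L,
        query_seq = b$query_seq[bi],
        query_start = qs, query_end = qe,
        identity = ident, n_columns = length(cols),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(cand)) do.call(rbind, cand) else
    data.frame(ref_seq = character(0), ref_start = numeric(0),
               ref_end = numeric(0), query_seq = character(0),
               query_start = numeric(0), query_end = numeric(0),
               identity = numeric(0), n_columns = numeric(0))
  # merge candidates < merge_dist apart on both genomes
  if (nrow(out) > 1L) {
    out <- out[order(out$ref_seq, out$ref_start), , drop = FALSE]
    merged <- list(); cur <- out[1L, ]
    for (i in seq_len(nrow(out))[-1L]) {
      nx <- out[i, ]
      close_ref <- nx$ref_seq == cur$ref_seq &&
        nx$ref_start - cur$ref_end < merge_dist
      close_qry <- !is.na(nx$query_start) && !is.na(cur$query_end) &&
        nx$query_seq == cur$query_seq &&
        abs(nx$query_start - cur$query_end) < merge_dist
      if (close_ref && close_qry) {
        w1 <- cur$n_columns; w2 <- nx$n_columns
        cur$identity <- (cur$identity * w1 + nx$identity * w2) / (w1 + w2)
        cur$n_columns <- w1 + w2
        cur$ref_end <- nx$ref_end
        cur$query_end <- nx$query_end
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- nx
      }
    }
    merged[[length(merged) + 1L]] <- cur
    out <- do.call(rbind, merged)
  }
  out$length <- out$ref_end - out$ref_start
  out$id <- if (nrow(out)) paste0("cne_", seq_len(nrow(out))) else character(0)
  out <- out[, c("id", "ref_seq", "ref_start", "ref_end", "query_seq",
                 "query_start", "query_end", "length", "identity")]
  rownames(out) <- NULL
  class(out) <- c("cne_candidates", "data.frame")
  out
}

#' Refine CNE candidates
#'
#' Filters are applied in a fixed order so that per-class removed
#' lengths are comparable: (1) too short, (2) adjacent to CDS, (3)
#' homology to known proteins/structural RNAs (blast hit at or below
#' `homology_evalue`), (4) identity below `min_identity`.  Each
#' candidate is attributed to the first class that removes it; class
#' lengths plus the refined length always sum to the coarse length.
#'
#' @param candidates Output of [coarse_cnes()].
#' @param annotation Reference [genome_annotation()].
#' @param hits Optional hit table whose `query_id`s are candidate ids
#'   (homology filter); `NULL` disables that filter.
#' @param min_len Candidates shorter than this are removed (default 75).
#' @param min_identity Identity threshold in percent (default 70).
#' @param cds_flank_bp "Adjacent to CDS" distance (default 20).
#' @param homology_evalue E-value cutoff for the homology filter
#'   (default 1e-5).
#' @return List of class `cne_refinement`: `refined` (surviving
#'   candidates), `removed` (with a `filter_flag` column), `summary`
#'   (a `cne_summary`, see [cne_stats()]).
#' @export
refine_cnes <- function(candidates, annotation, hits = NULL,
                        min_len = 75, min_identity = 70,
                        cds_flank_bp = 20, homology_evalue = 1e-5) {
  if (min_len < 0 || min_identity < 0 || cds_flank_bp < 0)
    stop("thresholds must be non-negative")
  x <- as.data.frame(candidates)
  flag <- rep(NA_character_, nrow(x))
  flag[is.na(flag) & x$length < min_len] <- "short"
  cds_ranges <- list()
  for (g in annotation$genes)
    cds_ranges[[g$seq_name]] <- rbind(cds_ranges[[g$seq_name]], g$cds)
  near_cds <- vapply(seq_len(nrow(x)), function(i) {
    m <- cds_ranges[[x$ref_seq[i]]]
    if (is.null(m)) return(FALSE)
    any(x$ref_start[i] - cds_flank_bp < m[, 2] &
          x$ref_end[i] + cds_flank_bp > m[, 1])
  }, logical(1))
  flag[is.na(flag) & near_cds] <- "cds_adjacent"
  if (!is.null(hits) && nrow(hits)) {
    hom_ids <- unique(hits$query_id[hits$e_value <= homology_evalue])
    flag[is.na(flag) & x$id %in% hom_ids] <- "homology"
  }
  flag[is.na(flag) & x$identity < min_identity] <- "low_identity"
  refined <- x[is.na(flag), , drop = FALSE]
  removed <- x[!is.na(flag), , drop = FALSE]
  removed$filter_flag <- flag[!is.na(flag)]
  genome_size <- sum(annotation$sequences)
  summary <- cne_stats(refined, genome_size,
                       coarse_length = sum(x$length),
                       removed_lengths = tapply(removed$length,
                                                removed$filter_flag, sum))
  structure(list(refined = refined, removed = removed, summary = summary),
            class = "cne_refinement")
}

#' CNE summary statistics
#'
#' @param refined Data frame of refined CNEs (needs a `length` column).
#' @param genome_size Reference genome size in bp (> 0).
#' @param coarse_length,removed_lengths Optional accounting inputs
#'   carried into the summary.
#' @return List of class `cne_summary`: `genome_size, refined_length,
#'   refined_pct, refined_count, mean_length` (NA when empty) and the
#'   optional accounting fields.
#' @export
cne_stats <- function(refined, genome_size, coarse_length = NULL,
                      removed_lengths = NULL) {
  if (genome_size <= 0) stop("genome_size must be positive")
  total <- sum(refined$length)
  n <- nrow(refined)
  structure(list(genome_size = genome_size,
                 refined_length = total,
                 refined_pct = 100 * total / genome_size,
                 refined_count = n,
                 mean_length = if (n > 0) total / n else NA_real_,
                 coarse_length = coarse_length,
                 removed_lengths = removed_lengths),
            class = "cne_summary")
}

#' @export
print.cne_summary <- function(x, ...) {
  cat("<cne_summary> ", format(x$refined_length, big.mark = ","),
      " bp refined (", round(x$refined_pct, 2), "% of ",
      format(x$genome_size, big.mark = ","), " bp) in ",
      x$refined_count, " elements (mean ",
      round(x$mean_length, 1), " bp)\n", sep = "")
  invisible(x)
}

#' CNE-enriched genomic windows
#'
#' Sliding windows are ranked by CNE bp, the `top_k` windows are merged
#' where they overlap, and per merged region the CNE bp, CNE count and
#' overlapping gene count are reported.
#'
#' @param refined Refined CNE data frame.
#' @param annotation Reference [genome_annotation()].
#' @param window,step Window and step size in bp (window must be >=
#'   step).
#' @param top_k Number of top windows before merging (default 30).
#' @return Data frame `seq, start, end, cne_bp, cne_count, gene_count`,
#'   ordered by decreasing `cne_bp`.
#' @export
enrichment_windows <- function(refined, annotation, window = 5e5,
                               step = 1e5, top_k = 30) {
  if (window < step) stop("window must be at least step")
  wins <- list()
  for (s in names(annotation$sequences)) {
    len <- annotation$sequences[[s]]
    starts <- seq(0, max(0, len - 1), by = step)
    wins[[s]] <- data.frame(seq = s, start = starts,
                            end = pmin(starts + window, len))
  }
  wins <- do.call(rbind, wins)
  cne_ir <- split(IRanges::IRanges(start = refined$ref_start + 1L,
                                   end = refined$ref_end),
                  refined$ref_seq)
  score <- function(i) {
    ir <- cne_ir[[wins$seq[i]]]
    if (is.null(ir)) return(c(0, 0))
    w <- IRanges::IRanges(start = wins$start[i] + 1L, end = wins$end[i])
    inter <- IRanges::pintersect(
      IRanges::findOverlapPairs(ir, w))
    c(sum(IRanges::width(inter)), length(inter))
  }
  sc <- t(vapply(seq_len(nrow(wins)), score, numeric(2)))
  wins$cne_bp <- sc[, 1]; wins$cne_count <- sc[, 2]
  wins <- wins[order(-wins$cne_bp, wins$seq, wins$start), , drop = FALSE]
  top <- utils::head(wins, top_k)
  # merge overlapping top windows
  merged <- list()
  for (s in unique(top$seq)) {
    ir <- IRanges::reduce(IRanges::IRanges(start = top$start[top$seq == s] + 1L,
                                           end = top$end[top$seq == s]))
    merged[[s]] <- data.frame(seq = s, start = IRanges::start(ir) - 1L,
                              end = IRanges::end(ir))
  }
  merged <- do.call(rbind, merged)
  gene_spans <- lapply(split(annotation$genes,
                             vapply(annotation$genes,
                                    function(g) g$seq_name, character(1))),
                       function(gs) IRanges::IRanges(
                         start = vapply(gs, function(g)
                           min(g$exons[, 1]) + 1, numeric(1)),
                         end = vapply(gs, function(g)
                           max(g$exons[, 2]), numeric(1))))
  stats_of <- function(i) {
    w <- IRanges::IRanges(start = merged$start[i] + 1L, end = merged$end[i])
    ir <- cne_ir[[merged$seq[i]]]
    gs <- gene_spans[[merged$seq[i]]]
    c(if (is.null(ir)) 0 else
      sum(IRanges::width(IRanges::pintersect(
        IRanges::findOverlapPairs(ir, w)))),
      if (is.null(ir)) 0 else sum(IRanges::overlapsAny(ir, w)),
      if (is.null(gs)) 0 else sum(IRanges::overlapsAny(gs, w)))
  }
  sc2 <- t(vapply(seq_len(nrow(merged)), stats_of, numeric(3)))
  merged$cne_bp <- sc2[, 1]; merged$cne_count <- sc2[, 2]
  merged$gene_count <- sc2[, 3]
  merged <- merged[order(-merged$cne_bp, merged$seq, merged$start), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Intersect CNE sets on a shared reference
#'
#' @param set1,set2 CNE data frames (`ref_seq, ref_start, ref_end`) in
#'   the same reference coordinates; their `reference` attributes (when
#'   present) must match.
#' @param min_len Keep intersection intervals of at least this length
#'   (bp); the study's thresholds of interest are 30 and 45.
#' @return Data frame `ref_seq, ref_start, ref_end, length`.
#' @export
intersect_cne_sets <- function(set1, set2, min_len = 30) {
  r1 <- attr(set1, "reference"); r2 <- attr(set2, "reference")
  if (!is.null(r1) && !is.null(r2) && !identical(r1, r2))
    stop("CNE sets are on different references: ", r1, " vs ", r2)
  out <- list()
  for (s in intersect(unique(set1$ref_seq), unique(set2$ref_seq))) {
    a <- IRanges::reduce(IRanges::IRanges(
      start = set1$ref_start[set1$ref_seq == s] + 1L,
      end = set1$ref_end[set1$ref_seq == s]))
    b <- IRanges::reduce(IRanges::IRanges(
      start = set2$ref_start[set2$ref_seq == s] + 1L,
      end = set2$ref_end[set2$ref_seq == s]))
    iv <- IRanges::intersect(a, b)
    iv <- iv[IRanges::width(iv) >= min_len]
    if (length(iv))
      out[[s]] <- data.frame(ref_seq = s,
                             ref_start = IRanges::start(iv) - 1L,
                             ref_end = IRanges::end(iv),
                             length = IRanges::width(iv))
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(ref_seq = character(0), ref_start = numeric(0),
               ref_end = numeric(0), length = numeric(0))
  rownames(res) <- NULL
  res
}
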