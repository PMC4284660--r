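# Intron phase annotation, phase-combination spectra, shuffled-exon
# detection, and subgenic (exon-level) DCJ rates.

#' Annotate intron phases of every CDS exon
#'
#' Phases are computed in translation (5'->3') order: the phase at an
#' exon boundary is the cumulative CDS length modulo 3 at that boundary.
#' Minus-strand genes are handled by reversing genomic exon order, so a
#' gene yields identical phases regardless of strand.  Genes flagged
#' complete whose CDS length is not a multiple of 3 are excluded with a
#' warning; genes not flagged complete are skipped silently (their frame
#' is unknown).
#'
#' @param ann A [genome_annotation()].
#' @return Data frame of class `phased_exons`: one row per CDS exon with
#'   `exon_id, gene_id, exon_index` (translation order), `cds_len`,
#'   `phase5`, `phase3` (NA at gene ends), `is_internal`.
#' @export
annotate_phases <- function(ann) {
  rows <- list()
  for (g in ann$genes) {
    lens <- g$cds[, 2] - g$cds[, 1]
    if (sum(lens) %% 3 != 0) {
      if (g$complete)
        warning("gene ", g$gene_id,
                " flagged complete but CDS length is not a multiple of 3;",
                " excluded from phase annotation")
      next
    }
    if (g$strand == "-") lens <- rev(lens)
    k <- length(lens)
    bounds <- cumsum(lens) %% 3            # phase after exon i
    rows[[g$gene_id]] <- data.frame(
      exon_id = paste0(g$gene_id, ":", seq_len(k)),
      gene_id = g$gene_id,
      exon_index = seq_len(k),
      cds_len = lens,
      phase5 = c(NA, bounds[-k]),
      phase3 = c(bounds[-k], NA),
      is_internal = seq_len(k) > 1L & seq_len(k) < k,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(exon_id = character(0), gene_id = character(0),
               exon_index = integer(0), cds_len = numeric(0),
               phase5 = numeric(0), phase3 = numeric(0),
               is_internal = logical(0))
  rownames(out) <- NULL
  class(out) <- c("phased_exons", "data.frame")
  out
}

#' Flag exons that encode a protein domain
#'
#' A domain interval (amino acids, 0-based half-open) is projected onto
#' CDS nucleotide space codon-exactly; an exon encodes the domain when
#' the projected interval overlaps the exon's CDS-space interval by at
#' least 1 bp.
#'
#' @param phases Output of [annotate_phases()].
#' @param ann The [genome_annotation()] the phases came from.
#' @param domains Domain table (`"domains"` schema of [read_table()]).
#' @return `phases` with an added logical column `encodes_domain`.
#' @export
mark_domain_exons <- function(phases, ann, domains) {
  prot_of <- vapply(ann$genes, function(g) g$protein_id, character(1))
  gene_of_prot <- stats::setNames(names(prot_of), prot_of)
  phases$encodes_domain <- FALSE
  for (p in unique(domains$protein_id)) {
    gid <- gene_of_prot[[p]]
    if (is.null(gid) || is.na(gid)) next
    idx <- which(phases$gene_id == gid)
    if (!length(idx)) next
    lens <- phases$cds_len[idx]
    ends <- cumsum(lens); starts <- ends - lens   # CDS-space nt intervals
    dsub <- domains[domains$protein_id == p, , drop = FALSE]
    for (i in seq_len(nrow(dsub))) {
      d0 <- 3 * dsub$env_start[i]; d1 <- 3 * dsub$env_end[i]
      hit <- starts < d1 & ends > d0
      phases$encodes_domain[idx[hit]] <- TRUE
    }
  }
  phases
}

#' Phase-combination spectrum of internal exons
#'
#' Counts internal exons over the nine (phase5, phase3) combinations,
#' keeping exons longer than `min_len_bp`, and reports symmetric-class
#' proportions with 95% binomial confidence intervals.
#'
#' @param phases Output of [annotate_phases()] (optionally after
#'   [mark_domain_exons()]).
#' @param min_len_bp Keep exons with CDS length strictly greater than
#'   this (default 100).
#' @param subset Optional logical vector over `phases` rows (applied
#'   before the internal/length filters), e.g. domain exons or a
#'   shuffled set.
#' @return List of class `phase_spectrum`: `counts` (3x3 matrix),
#'   `proportions`, `n`, `symmetric` (data frame for 0-0, 1-1, 2-2 with
#'   CIs).
#' @export
phase_spectrum <- function(phases, min_len_bp = 100, subset = NULL) {
  x <- phases
  if (!is.null(subset)) x <- x[subset, , drop = FALSE]
  x <- x[x$is_internal & x$cds_len > min_len_bp, , drop = FALSE]
  if (!nrow(x)) stop("no internal exons in the selected subset")
  counts <- table(factor(x$phase5, levels = 0:2),
                  factor(x$phase3, levels = 0:2))
  n <- sum(counts)
  sym <- data.frame(class = c("0-0", "1-1", "2-2"),
                    count = diag(counts))
  sym$proportion <- sym$count / n
  ci <- t(vapply(sym$count, function(k)
    as.numeric(stats::binom.test(k, n)$conf.int), numeric(2)))
  sym$ci_lo <- ci[, 1]; sym$ci_hi <- ci[, 2]
  structure(list(counts = unclass(counts), proportions = counts / n,
                 n = n, symmetric = sym),
            class = "phase_spectrum")
}

#' @export
print.phase_spectrum <- function(x, ...) {
  cat("<phase_spectrum> n =", x$n, "internal exons\n")
  print(round(x$proportions, 3))
  invisible(x)
}

#' Detect shuffled exons
#'
#' In `rbh` mode an exon is shuffled when its reciprocal-best exon hit
#' lies in a gene that is not the 1:1 orthologue of the exon's own gene
#' (or lies in an unpaired gene).  In `chainnet` mode an exon is flagged
#' when its aligned counterpart (via whole-genome alignment blocks) falls
#' outside the span of its gene's orthologue; exons without alignment
#' coverage are not flagged, so chainnet reports fewer, higher-confidence
#' calls.
#'
#' @param exon_hits_ab,exon_hits_ba Exon-level reciprocal hit tables
#'   (queries/subjects are exon ids).
#' @param orthology Gene-level `orthology_map`.
#' @param exon_gene_a,exon_gene_b Named vectors exon id -> gene id.
#' @param method `"rbh"` or `"chainnet"`.
#' @param min_identity,min_coverage Exon-level cutoffs (percent; coverage
#'   is relative to the shorter exon).
#' @param exon_lengths Named numeric vector of exon lengths (both sides).
#' @param blocks,exon_coords_a,gene_spans_b chainnet mode inputs: an
#'   [alignment_block_set()] A->B, exon genomic intervals on A (data
#'   frame `exon_id, seq, start, end`), and gene spans on B (data frame
#'   `gene_id, seq, start, end`).
#' @return Data frame of class `shuffled_exon_set`: `exon_id, gene_id,
#'   counterpart, counterpart_gene, method`.
#' @export
detect_shuffled_exons <- function(exon_hits_ab = NULL, exon_hits_ba = NULL,
                                  orthology, exon_gene_a, exon_gene_b,
                                  method = c("rbh", "chainnet"),
                                  min_identity = 60, min_coverage = 50,
                                  exon_lengths = NULL,
                                  blocks = NULL, exon_coords_a = NULL,
                                  gene_spans_b = NULL) {
  method <- match.arg(method)
  if (is.null(orthology)) stop("gene orthology is required")
  partner_of <- stats::setNames(orthology$pairs$gene_b,
                                orthology$pairs$gene_a)
  rows <- list()
  if (method == "rbh") {
    best_hit <- function(hits) {
      if (!nrow(hits)) return(NULL)
      keep <- hits$percent_identity >= min_identity
      if (!is.null(exon_lengths)) {
        shorter <- pmin(unname(exon_lengths[hits$query_id]),
                        unname(exon_lengths[hits$subject_id]))
        keep <- keep & 100 * hits$alignment_length / shorter >=
          min_coverage  # exon hits are nucleotide-level on CDS exons
      }
      hits <- hits[keep, , drop = FALSE]
      if (!nrow(hits)) return(NULL)
      hits <- hits[order(hits$query_id, -hits$bitscore, hits$subject_id), ]
      hits[!duplicated(hits$query_id), c("query_id", "subject_id")]
    }
    ba <- best_hit(exon_hits_ab)
    bb <- best_hit(exon_hits_ba)
    if (is.null(ba) || is.null(bb))
      return(.empty_shuffled())
    back <- stats::setNames(bb$subject_id, bb$query_id)
    for (i in seq_len(nrow(ba))) {
      e <- ba$query_id[i]; f <- ba$subject_id[i]
      if (is.na(back[f]) || back[f] != e) next     # not reciprocal best
      g_a <- exon_gene_a[[e]]; g_b <- exon_gene_b[[f]]
      expected <- partner_of[g_a]
      if (is.na(expected) || expected != g_b)
        rows[[e]] <- data.frame(exon_id = e, gene_id = g_a,
                                counterpart = f, counterpart_gene = g_b,
                                method = "rbh", stringsAsFactors = FALSE)
    }
  } else {
    if (is.null(blocks) || is.null(exon_coords_a) || is.null(gene_spans_b))
      stop("chainnet mode needs blocks, exon_coords_a and gene_spans_b")
    b <- blocks$blocks
    for (i in seq_len(nrow(exon_coords_a))) {
      e <- exon_coords_a[i, ]
      g_a <- exon_gene_a[[e$exon_id]]
      expected <- partner_of[g_a]
      if (is.na(expected)) next                    # no orthologue to test
      hit <- which(b$ref_seq == e$seq & b$ref_start < e$end &
                     b$ref_end > e$start)
      if (!length(hit)) next                       # no alignment evidence
      j <- hit[1L]
      span <- gene_spans_b[gene_spans_b$gene_id == expected, , drop = FALSE]
      inside <- nrow(span) == 1L && b$query_seq[j] == span$seq &&
        b$query_start[j] < span$end && b$query_end[j] > span$start
      if (!inside)
        rows[[e$exon_id]] <- data.frame(
          exon_id = e$exon_id, gene_id = g_a,
          counterpart = paste0(b$query_seq[j], ":", b$query_start[j]),
          counterpart_gene = NA_character_, method = "chainnet",
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else .empty_shuffled()
  rownames(out) <- NULL
  class(out) <- c("shuffled_exon_set", "data.frame")
  out
}

.empty_shuffled <- function() {
  out <- data.frame(exon_id = character(0), gene_id = character(0),
                    counterpart = character(0),
                    counterpart_gene = character(0),
                    method = character(0), stringsAsFactors = FALSE)
  class(out) <- c("shuffled_exon_set", "data.frame")
  out
}

#' Subgenic (exon-level) DCJ contribution
#'
#' Computes DCJ distances on exon-marker orders and gene-marker orders
#' and reports the excess attributable to rearrangements below the gene
#' level.  Because the exon- and gene-level shared marker sets can
#' differ, the raw difference can be negative; the reported contribution
#' is floored at zero with the raw value kept alongside.
#'
#' @param exon_order_a,exon_order_b [gene_order()]s over matched exon
#'   markers.
#' @param gene_order_a,gene_order_b [gene_order()]s over matched gene
#'   markers.
#' @return List with `exon` and `gene` `dcj_result`s, `contribution`
#'   (floored) and `contribution_raw`.
#' @export
subgenic_dcj <- function(exon_order_a, exon_order_b,
                         gene_order_a, gene_order_b) {
  d_exon <- dcj_distance(exon_order_a, exon_order_b)
  d_gene <- dcj_distance(gene_order_a, gene_order_b)
  raw <- d_exon$d - d_gene$d
  list(exon = d_exon, gene = d_gene,
       contribution = max(0L, raw), contribution_raw = raw)
}

#' Phase bias of shuffled versus non-shuffled exons
#'
#' Compares the proportion of 1-1 phase combinations between a shuffled
#' exon set and the remaining internal exons with a 2x2 chi-square test
#' (continuity-corrected); when any expected cell is below 5 Fisher's
#' exact test is used instead (noted in the output).
#'
#' @param phases Output of [annotate_phases()].
#' @param shuffled_ids Exon ids flagged as shuffled.
#' @param min_len_bp Length filter as in [phase_spectrum()]; use 0 to
#'   keep all internal exons.
#' @return List: `prop_shuffled`, `prop_background`, `statistic`,
#'   `p_value`, `test` (`"chi-square"` or `"fisher"`), `table`.
#' @export
shuffled_phase_bias <- function(phases, shuffled_ids, min_len_bp = 0) {
  x <- phases[phases$is_internal & phases$cds_len > min_len_bp, ,
              drop = FALSE]
  is_sh <- x$exon_id %in% shuffled_ids
  if (!any(is_sh) || all(is_sh))
    stop("both shuffled and non-shuffled internal exons are required")
  one_one <- !is.na(x$phase5) & x$phase5 == 1 & x$phase3 == 1
  tab <- rbind(shuffled = c(sum(one_one & is_sh), sum(!one_one & is_sh)),
               background = c(sum(one_one & !is_sh), sum(!one_one & !is_sh)))
  colnames(tab) <- c("1-1", "other")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ft <- stats::fisher.test(tab)
    res <- list(statistic = NA_real_, p_value = ft$p.value, test = "fisher")
  } else {
    ct <- stats::chisq.test(tab, correct = TRUE)
    res <- list(statistic = unname(ct$statistic), p_value = ct$p.value,
                test = "chi-square")
  }
  c(list(prop_shuffled = tab[1, 1] / sum(tab[1, ]),
         prop_background = tab[2, 1] / sum(tab[2, ])),
    res, list(table = tab))
}
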