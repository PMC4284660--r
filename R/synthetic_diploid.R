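# Diploid individual simulation: a second haplotype with planted SNPs
# and indels, the exact alignment between haplotypes, and a ground-truth
# variant table.  Also small generators for transcription reads and
# methylation call tables used by the profiling module.

#' Diploid simulation parameters
#'
#' Defaults plant the polymorphism densities reported for a wild,
#' highly polymorphic marine invertebrate: a 4.39% SNP rate and a 0.98%
#' small-indel event rate per aligned site, geometric indel sizes (mean
#' 8 bp, truncated at 300 bp, which keeps well over 96% of events at or
#' under 50 bp), and large indels (301-10,000 bp) at a density matching
#' tens of thousands of events on a ~400 Mb genome.
#'
#' @param snp_rate Per-site SNP probability.
#' @param small_indel_rate Per-site small-indel event probability.
#' @param indel_mean_bp Mean of the geometric small-indel size (bp).
#' @param small_indel_max_bp Small-indel truncation (default 300).
#' @param large_indel_per_mb Large indels per Mb (default 0; set ~86
#'   for the full planted density).
#' @param large_indel_range Large indel size range in bp.
#' @param seed Integer seed.
#' @return List of class `diploid_params`.
#' @export
diploid_params <- function(snp_rate = 0.0439, small_indel_rate = 0.0098,
                           indel_mean_bp = 8, small_indel_max_bp = 300,
                           large_indel_per_mb = 0,
                           large_indel_range = c(301, 10000),
                           seed = 1) {
  stopifnot(snp_rate >= 0, snp_rate <= 1, small_indel_rate >= 0,
            small_indel_rate <= 1)
  p <- as.list(environment())
  class(p) <- "diploid_params"
  p
}

.rgeom_trunc <- function(n, mean, max) {
  p <- 1 / mean
  out <- integer(0)
  while (length(out) < n) {
    draw <- stats::rgeom(2L * n + 10L, p) + 1L
    out <- c(out, draw[draw <= max])
  }
  out[seq_len(n)]
}

#' Simulate a diploid individual
#'
#' Haplotype A is the input genome; haplotype B carries planted SNPs and
#' indels.  The alignment between haplotypes is exact by construction
#' and returned as alignment blocks (one per sequence), together with
#' the ground-truth variant table.  Overlapping indels are resolved by
#' rejection sampling; an impossible density is an error.
#'
#' @param seqs Named character vector of haplotype A sequences.
#' @param params A [diploid_params()].
#' @return List of class `sim_diploid`: `hap_a`, `hap_b`, `truth`
#'   (variant data frame in haplotype A coordinates), `blocks`
#'   ([alignment_block_set()]).
#' @export
make_diploid <- function(seqs, params = diploid_params()) {
  set.seed(params$seed)
  hap_b <- character(0)
  truth <- list()
  brow <- list()
  for (cn in names(seqs)) {
    ref <- strsplit(seqs[[cn]], "")[[1]]
    len <- length(ref)
    # ---- indel anchors (non-overlapping, >= 2 bp apart) ---------------
    n_small <- stats::rbinom(1L, len, params$small_indel_rate)
    n_large <- stats::rpois(1L, params$large_indel_per_mb * len / 1e6)
    sizes <- c(if (n_small) .rgeom_trunc(n_small, params$indel_mean_bp,
                                         params$small_indel_max_bp),
               if (n_large) sample(seq(params$large_indel_range[1],
                                       min(params$large_indel_range[2],
                                           max(302, len %/% 10))),
                                   n_large, replace = TRUE))
    is_del <- stats::runif(length(sizes)) < 0.5
    ev <- NULL
    if (length(sizes)) {
      if (sum(sizes[is_del]) + 3L * length(sizes) >= len)
        stop("impossible indel density: cannot place ", length(sizes),
             " events (", sum(sizes[is_del]), " deleted bp) on ", len,
             " bp")
      ev <- data.frame(pos = sample.int(max(1L, len - 1L), length(sizes),
                                        replace = TRUE),
                       size = sizes, del = is_del)
      for (round in 1:200) {
        ev <- ev[order(ev$pos), , drop = FALSE]
        span_end <- ev$pos + ifelse(ev$del, ev$size, 0L)
        bad <- c(FALSE, diff(ev$pos) <= utils::head(span_end - ev$pos, -1) + 2L) |
          span_end > len
        if (!any(bad)) break
        if (round == 200)
          stop("impossible indel density: cannot place ", nrow(ev),
               " events on ", len, " bp")
        ev$pos[bad] <- sample.int(max(1L, len - 1L), sum(bad),
                                  replace = TRUE)
      }
    }
    # ---- SNPs (outside deleted segments) ------------------------------
    n_snp <- stats::rbinom(1L, len, params$snp_rate)
    snp_pos <- sort(sample.int(len, min(n_snp, len)))
    if (!is.null(ev) && any(ev$del)) {
      del_iv <- ev[ev$del, , drop = FALSE]
      bad <- rep(FALSE, length(snp_pos))
      for (i in seq_len(nrow(del_iv)))
        bad <- bad | (snp_pos > del_iv$pos[i] &
                        snp_pos <= del_iv$pos[i] + del_iv$size[i])
      snp_pos <- snp_pos[!bad]
    }
    alt_vec <- ref
    if (length(snp_pos)) {
      alts <- vapply(ref[snp_pos], function(b)
        sample(setdiff(.BASES, b), 1L), character(1))
      alt_vec[snp_pos] <- alts
      truth[[length(truth) + 1L]] <- data.frame(
        type = "snp", ref_seq = cn, ref_start = snp_pos - 1L,
        ref_end = snp_pos, length = 1L,
        ref_allele = ref[snp_pos], alt_allele = unname(alts),
        stringsAsFactors = FALSE)
    }
    # ---- build aligned texts ------------------------------------------
    ref_parts <- list(); qry_parts <- list()
    cursor <- 1L
    if (!is.null(ev)) for (i in seq_len(nrow(ev))) {
      p <- ev$pos[i]; sz <- ev$size[i]
      ref_parts[[length(ref_parts) + 1L]] <-
        paste(ref[cursor:p], collapse = "")
      qry_parts[[length(qry_parts) + 1L]] <-
        paste(alt_vec[cursor:p], collapse = "")
      if (ev$del[i]) {
        ref_parts[[length(ref_parts) + 1L]] <-
          paste(ref[(p + 1L):(p + sz)], collapse = "")
        qry_parts[[length(qry_parts) + 1L]] <-
          paste(rep("-", sz), collapse = "")
        truth[[length(truth) + 1L]] <- data.frame(
          type = if (sz <= params$small_indel_max_bp) "small_indel"
                 else "large_indel",
          ref_seq = cn, ref_start = p, ref_end = p + sz, length = sz,
          ref_allele = paste(ref[(p + 1L):(p + sz)], collapse = ""),
          alt_allele = "-", stringsAsFactors = FALSE)
        cursor <- p + sz + 1L
      } else {
        ins <- .random_dna(sz)
        ref_parts[[length(ref_parts) + 1L]] <-
          paste(rep("-", sz), collapse = "")
        qry_parts[[length(qry_parts) + 1L]] <- ins
        truth[[length(truth) + 1L]] <- data.frame(
          type = if (sz <= params$small_indel_max_bp) "small_indel"
                 else "large_indel",
          ref_seq = cn, ref_start = p, ref_end = p, length = sz,
          ref_allele = "-", alt_allele = ins, stringsAsFactors = FALSE)
        cursor <- p + 1L
      }
    }
    if (cursor <= len) {
      ref_parts[[length(ref_parts) + 1L]] <-
        paste(ref[cursor:len], collapse = "")
      qry_parts[[length(qry_parts) + 1L]] <-
        paste(alt_vec[cursor:len], collapse = "")
    }
    ref_text <- paste(unlist(ref_parts), collapse = "")
    qry_text <- paste(unlist(qry_parts), collapse = "")
    hap_b[cn] <- gsub("-", "", qry_text, fixed = TRUE)
    brow[[cn]] <- data.frame(
      ref_seq = cn, ref_start = 0L, ref_end = len,
      query_seq = cn, query_start = 0L, query_end = nchar(hap_b[cn]),
      query_strand = "+", ref_text = ref_text, query_text = qry_text,
      stringsAsFactors = FALSE)
  }
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(type = character(0), ref_seq = character(0),
               ref_start = numeric(0), ref_end = numeric(0),
               length = numeric(0), ref_allele = character(0),
               alt_allele = character(0))
  rownames(truth_df) <- NULL
  structure(list(hap_a = seqs, hap_b = hap_b, truth = truth_df,
                 blocks = alignment_block_set(do.call(rbind, brow),
                                              c("hapA", "hapB"))),
            class = "sim_diploid")
}

#' Simulate mapped transcription reads with planted class fractions
#'
#' Reads are placed fully inside intervals of their drawn class, so the
#' planted per-class fractions are recoverable by majority-overlap
#' assignment.
#'
#' @param partition A `region_partition` (see [partition_regions()]).
#' @param fractions Named numeric over the five classes, summing to 1.
#' @param n_reads Number of reads.
#' @param read_len Read length in bp (default 100).
#' @return Data frame `chrom, start, end` of read intervals.
#' @export
simulate_transcription_reads <- function(partition, fractions, n_reads,
                                         read_len = 100) {
  fractions <- fractions / sum(fractions)
  cls_draw <- sample(names(fractions), n_reads, replace = TRUE,
                     prob = fractions)
  out <- vector("list", n_reads)
  pool <- split(partition, partition$class)
  for (cls in unique(cls_draw)) {
    p <- pool[[cls]]
    p <- p[p$end - p$start >= read_len, , drop = FALSE]
    if (is.null(p) || !nrow(p))
      stop("no ", cls, " interval can hold a ", read_len, " bp read")
    idx <- which(cls_draw == cls)
    rows <- sample.int(nrow(p), length(idx), replace = TRUE,
                       prob = p$end - p$start - read_len + 1)
    offs <- floor(stats::runif(length(idx)) *
                    (p$end[rows] - p$start[rows] - read_len + 1))
    for (k in seq_along(idx))
      out[[idx[k]]] <- data.frame(chrom = p$seq[rows[k]],
                                  start = p$start[rows[k]] + offs[k],
                                  end = p$start[rows[k]] + offs[k] + read_len,
                                  stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a CG methylation call table with planted class means
#'
#' Per-site methylation probabilities are drawn from a beta distribution
#' with the planted class mean and a precision that produces the
#' bimodal (mostly-on/mostly-off) pattern of real methylomes;
#' methylated read counts are binomial at the given coverage.
#'
#' @param partition A `region_partition`.
#' @param class_means Named numeric of per-class mean levels in percent.
#' @param n_sites Number of CG sites.
#' @param coverage Reads per site (default 30).
#' @param precision Beta precision parameter (default 0.6; smaller is
#'   more bimodal).
#' @return Data frame in the `"methylation"` schema of [read_table()].
#' @export
simulate_methylation_sites <- function(partition, class_means, n_sites,
                                       coverage = 30, precision = 0.6) {
  w <- partition$end - partition$start
  rows <- sample.int(nrow(partition), n_sites, replace = TRUE, prob = w)
  pos <- partition$start[rows] +
    floor(stats::runif(n_sites) * (partition$end[rows] -
                                     partition$start[rows]))
  cls <- partition$class[rows]
  mu <- class_means[cls] / 100
  a <- mu * precision; b <- (1 - mu) * precision
  p_site <- stats::rbeta(n_sites, pmax(a, 1e-3), pmax(b, 1e-3))
  meth <- stats::rbinom(n_sites, coverage, p_site)
  data.frame(seq = partition$seq[rows], pos0 = pos, strand = "+",
             context = "CG", methylated_reads = meth,
             total_reads = coverage, stringsAsFactors = FALSE)
}
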