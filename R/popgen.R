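# Polymorphism calling from haplotype alignments, spacing statistics,
# Nei-Gojobori dN/dS, and effective population size.

#' Call variants from pairwise haplotype alignment blocks
#'
#' SNPs are single-column mismatches (adjacent SNPs are not merged);
#' indels are maximal gap runs, classed small (<= 300 bp) or large
#' (> 300 bp); blocks on the minus strand are recorded as inversions and
#' blocks whose query sequence differs from the dominant counterpart of
#' their reference sequence as translocations.
#'
#' @param blocks An [alignment_block_set()] between two haplotypes;
#'   reference intervals must not overlap.
#' @return Data frame of class `variant_table`: `type, ref_seq,
#'   ref_start, ref_end, length, ref_allele, alt_allele`, with attribute
#'   `aligned_columns` (gap-free columns, the SNP-rate denominator).
#' @export
call_variants <- function(blocks) {
  b <- blocks$blocks
  for (s in unique(b$ref_seq)) {
    iv <- b[b$ref_seq == s, , drop = FALSE]
    iv <- iv[order(iv$ref_start), , drop = FALSE]
    if (nrow(iv) > 1L && any(iv$ref_start[-1L] < iv$ref_end[-nrow(iv)]))
      stop("overlapping reference blocks on ", s)
  }
  rows <- list()
  aligned_cols <- 0
  for (i in seq_len(nrow(b))) {
    r <- strsplit(b$ref_text[i], "")[[1]]
    q <- strsplit(b$query_text[i], "")[[1]]
    ref_pos <- b$ref_start[i] + cumsum(r != "-") - 1L
    both <- r != "-" & q != "-"
    aligned_cols <- aligned_cols + sum(both)
    snp <- which(both & r != q)
    if (length(snp))
      rows[[length(rows) + 1L]] <- data.frame(
        type = "snp", ref_seq = b$ref_seq[i], ref_start = ref_pos[snp],
        ref_end = ref_pos[snp] + 1L, length = 1L,
        ref_allele = r[snp], alt_allele = q[snp],
        stringsAsFactors = FALSE)
    gap_type <- ifelse(r == "-", 1L, ifelse(q == "-", 2L, 0L))
    rl <- rle(gap_type)
    ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
    ks <- which(rl$values != 0L)
    if (length(ks)) {
      len <- rl$lengths[ks]
      del <- rl$values[ks] == 2L
      pos <- ifelse(starts[ks] > 1L, ref_pos[pmax(starts[ks] - 1L, 1L)] + 1L,
                    b$ref_start[i])
      rows[[length(rows) + 1L]] <- data.frame(
        type = ifelse(len <= 300, "small_indel", "large_indel"),
        ref_seq = b$ref_seq[i], ref_start = pos,
        ref_end = ifelse(del, pos + len, pos), length = len,
        ref_allele = ifelse(del, substring(b$ref_text[i], starts[ks],
                                           ends[ks]), "-"),
        alt_allele = ifelse(del, "-", substring(b$query_text[i],
                                                starts[ks], ends[ks])),
        stringsAsFactors = FALSE)
    }
  }
  # block-level rearrangements
  if (nrow(b)) {
    bp <- b$ref_end - b$ref_start
    for (s in unique(b$ref_seq)) {
      sub <- which(b$ref_seq == s)
      dom <- names(sort(tapply(bp[sub], b$query_seq[sub], sum),
                        decreasing = TRUE))[1L]
      for (i in sub) {
        if (b$query_seq[i] != dom)
          rows[[length(rows) + 1L]] <- data.frame(
            type = "translocation", ref_seq = s, ref_start = b$ref_start[i],
            ref_end = b$ref_end[i], length = b$ref_end[i] - b$ref_start[i],
            ref_allele = NA_character_, alt_allele = b$query_seq[i],
            stringsAsFactors = FALSE)
        else if (b$query_strand[i] == "-")
          rows[[length(rows) + 1L]] <- data.frame(
            type = "inversion", ref_seq = s, ref_start = b$ref_start[i],
            ref_end = b$ref_end[i], length = b$ref_end[i] - b$ref_start[i],
            ref_allele = NA_character_, alt_allele = NA_character_,
            stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(0), ref_seq = character(0),
               ref_start = numeric(0), ref_end = numeric(0),
               length = numeric(0), ref_allele = character(0),
               alt_allele = character(0))
  rownames(out) <- NULL
  attr(out, "aligned_columns") <- aligned_cols
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Summarize polymorphism rates
#'
#' SNP and small-indel event rates use aligned (gap-free) columns as the
#' denominator; indel length fractions and rearranged fractions use the
#' genome length, matching how such rates are conventionally reported.
#'
#' @param variants A `variant_table`.
#' @param aligned_length Number of aligned gap-free columns (defaults to
#'   the table's `aligned_columns` attribute).
#' @param genome_length Reference genome length in bp.
#' @return List of class `polymorphism_summary`.
#' @export
summarize_polymorphism <- function(variants, aligned_length = NULL,
                                   genome_length) {
  if (is.null(aligned_length))
    aligned_length <- attr(variants, "aligned_columns")
  if (is.null(aligned_length) || aligned_length <= 0)
    stop("aligned_length must be positive")
  v <- variants
  n_snp <- sum(v$type == "snp")
  sm <- v[v$type == "small_indel", , drop = FALSE]
  lg <- v[v$type == "large_indel", , drop = FALSE]
  re <- v[v$type %in% c("inversion", "translocation"), , drop = FALSE]
  structure(list(
    snp_rate_pct = 100 * n_snp / aligned_length,
    small_indel_event_rate_pct = 100 * nrow(sm) / aligned_length,
    small_indel_length_pct = 100 * sum(sm$length) / genome_length,
    small_indel_le50_length_pct =
      100 * sum(sm$length[sm$length <= 50]) / genome_length,
    large_indel_count = nrow(lg),
    large_indel_length_pct = 100 * sum(lg$length) / genome_length,
    rearranged_count = nrow(re),
    rearranged_length_pct = 100 * sum(re$length) / genome_length,
    aligned_length = aligned_length,
    genome_length = genome_length),
    class = "polymorphism_summary")
}

#' @export
print.polymorphism_summary <- function(x, ...) {
  cat("<polymorphism_summary>\n",
      sprintf("  SNP rate:               %.2f%%\n", x$snp_rate_pct),
      sprintf("  small indel event rate: %.2f%%\n",
              x$small_indel_event_rate_pct),
      sprintf("  small indel length:     %.2f%% of genome\n",
              x$small_indel_length_pct),
      sprintf("  large indels:           %d (%.2f%% of genome)\n",
              x$large_indel_count, x$large_indel_length_pct), sep = "")
  invisible(x)
}

#' Fit a geometric distribution to inter-variant spacings
#'
#' Gaps are the non-variant run lengths between consecutive variant
#' positions within each reference sequence.  Under random (Poisson-like)
#' placement they follow a geometric law; clustering shows up as
#' goodness-of-fit rejection.
#'
#' @param variants A `variant_table` or data frame with `ref_seq` and
#'   `ref_start`.
#' @param support `"zero_based"` (gap of 0 allowed; MLE n/(n + sum g))
#'   or `"one_based"` (gaps >= 1; MLE 1/mean).
#' @param min_expected Minimum expected count per chi-square bin before
#'   tail pooling (default 5).
#' @return List of class `spacing_fit`: `p_hat, n, support, chisq, df,
#'   p_value, se` (asymptotic SE of `p_hat`).
#' @export
spacing_fit <- function(variants, support = c("zero_based", "one_based"),
                        min_expected = 5) {
  support <- match.arg(support)
  gaps <- unlist(lapply(split(variants$ref_start, variants$ref_seq),
                        function(p) diff(sort(p)) - 1L), use.names = FALSE)
  if (length(gaps) < 100L)
    stop("need at least 100 spacing observations, have ", length(gaps))
  n <- length(gaps)
  if (support == "zero_based") {
    p_hat <- n / (n + sum(gaps))
    pmf <- function(g) p_hat * (1 - p_hat)^g
    gg <- gaps
  } else {
    gg <- gaps + 1L
    p_hat <- 1 / mean(gg)
    pmf <- function(g) p_hat * (1 - p_hat)^(g - 1L)
  }
  # chi-square GOF with tail pooling
  gmax <- max(gg)
  lo <- if (support == "zero_based") 0L else 1L
  probs <- pmf(lo:gmax)
  probs <- c(probs, max(0, 1 - sum(probs)))   # tail beyond observed max
  obs <- c(tabulate(gg - lo + 1L, nbins = gmax - lo + 1L), 0)
  exp_ct <- n * probs
  # pool from the right until every bin has expected >= min_expected
  while (length(exp_ct) > 1L && exp_ct[length(exp_ct)] < min_expected) {
    k <- length(exp_ct)
    exp_ct[k - 1L] <- exp_ct[k - 1L] + exp_ct[k]
    obs[k - 1L] <- obs[k - 1L] + obs[k]
    exp_ct <- exp_ct[-k]; obs <- obs[-k]
  }
  # pool any interior sparse bins into their right neighbour
  i <- 1L
  while (i < length(exp_ct)) {
    if (exp_ct[i] < min_expected) {
      exp_ct[i + 1L] <- exp_ct[i + 1L] + exp_ct[i]
      obs[i + 1L] <- obs[i + 1L] + obs[i]
      exp_ct <- exp_ct[-i]; obs <- obs[-i]
    } else i <- i + 1L
  }
  if (length(exp_ct) < 3L) {
    if (p_hat >= 1 - 1e-12) {
      # degenerate case: every gap is zero; the fit is exact and there
      # is nothing left to test
      return(structure(list(p_hat = p_hat, n = n, support = support,
                            chisq = NA_real_, df = NA_integer_,
                            p_value = NA_real_, se = 0),
                       class = "spacing_fit"))
    }
    stop("fewer than 3 bins after pooling; cannot test fit")
  }
  chisq <- sum((obs - exp_ct)^2 / exp_ct)
  df <- length(exp_ct) - 2L               # one estimated parameter
  structure(list(p_hat = p_hat, n = n, support = support,
                 chisq = chisq, df = df,
                 p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
                 se = sqrt(p_hat^2 * (1 - p_hat) / n)),
            class = "spacing_fit")
}

# --- Nei-Gojobori (1986) dN/dS ---------------------------------------------

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

.syn_sites <- function(codon, code) {
  aa <- code[[codon]]
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) for (b in bases) {
    if (b == substr(codon, pos, pos)) next
    mut <- codon
    substr(mut, pos, pos) <- b
    if (code[[mut]] == aa && code[[mut]] != "*") s <- s + 1 / 3
    # changes to stop codons count as nonsynonymous
  }
  s
}

.path_diffs <- function(c1, c2, code) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(0, 0))
  perms <- if (k == 1L) list(pos) else
    if (k == 2L) list(pos, rev(pos)) else
      lapply(list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1)), function(o) pos[o])
  acc <- c(0, 0); n_valid <- 0L
  for (ord in perms) {
    cur <- c1; sd <- 0; nd <- 0; valid <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (code[[nxt]] == "*") { valid <- FALSE; break }
      if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (valid) { acc <- acc + c(sd, nd); n_valid <- n_valid + 1L }
  }
  if (n_valid == 0L) {
    # all pathways pass through stops; average over them anyway
    for (ord in perms) {
      cur <- c1; sd <- 0; nd <- 0
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (code[[nxt]] != "*" && code[[nxt]] == code[[cur]]) sd <- sd + 1
        else nd <- nd + 1
        cur <- nxt
      }
      acc <- acc + c(sd, nd)
    }
    n_valid <- length(perms)
  }
  acc / n_valid
}

#' Nei-Gojobori (1986) dN/dS for codon-aligned CDS pairs
#'
#' Synonymous and nonsynonymous sites are counted per codon (fractional,
#' averaged over the two sequences); differences are averaged over all
#' mutational pathways with equal weights, skipping pathways through
#' stop codons.  Proportions are Jukes-Cantor corrected,
#' d = -3/4 ln(1 - 4p/3); pairs with internal stop codons are skipped
#' with a warning.
#'
#' @param cds_a,cds_b Character vectors of in-frame, gap-free,
#'   equal-length CDS pairs (one element per gene pair).
#' @return List of class `dnds_result`: `per_pair` (data frame `dN, dS,
#'   dn_ds, S, N, Sd, Nd`) and `pooled` (counts summed over pairs before
#'   correction).
#' @export
dnds_ng86 <- function(cds_a, cds_b) {
  code <- .codon_table()
  # memoize per-codon site counts and per-codon-pair pathway averages;
  # the codon alphabet is tiny, the inputs are not
  syn_cache <- new.env(hash = TRUE)
  syn_sites_m <- function(codon) {
    v <- get0(codon, envir = syn_cache, ifnotfound = NULL)
    if (is.null(v)) {
      v <- .syn_sites(codon, code)
      assign(codon, v, envir = syn_cache)
    }
    v
  }
  diff_cache <- new.env(hash = TRUE)
  path_diffs_m <- function(c1, c2) {
    key <- paste0(c1, c2)
    v <- get0(key, envir = diff_cache, ifnotfound = NULL)
    if (is.null(v)) {
      v <- .path_diffs(c1, c2, code)
      assign(key, v, envir = diff_cache)
    }
    v
  }
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  per <- list()
  tot <- c(S = 0, N = 0, Sd = 0, Nd = 0)
  for (i in seq_along(cds_a)) {
    a <- toupper(cds_a[i]); b <- toupper(cds_b[i])
    if (nchar(a) != nchar(b) || nchar(a) %% 3 != 0)
      stop("pair ", i, ": sequences must be equal-length and in frame")
    nc <- nchar(a) %/% 3
    cods_a <- substring(a, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
    cods_b <- substring(b, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
    internal_a <- cods_a[-nc]; internal_b <- cods_b[-nc]
    if (any(code[internal_a] == "*") || any(code[internal_b] == "*")) {
      warning("pair ", i, " has an internal stop codon; skipped")
      next
    }
    S <- 0; Sd <- 0; Nd <- 0
    for (k in seq_len(nc)) {
      if (code[[cods_a[k]]] == "*" || code[[cods_b[k]]] == "*") next
      S <- S + (syn_sites_m(cods_a[k]) + syn_sites_m(cods_b[k])) / 2
      dd <- path_diffs_m(cods_a[k], cods_b[k])
      Sd <- Sd + dd[1]; Nd <- Nd + dd[2]
    }
    N <- 3 * nc - S
    pS <- if (S > 0) Sd / S else NA_real_
    pN <- if (N > 0) Nd / N else NA_real_
    dS <- jc(pS); dN <- jc(pN)
    per[[i]] <- data.frame(dN = dN, dS = dS,
                           dn_ds = if (!is.na(dS) && dS > 0) dN / dS
                                   else NA_real_,
                           S = S, N = N, Sd = Sd, Nd = Nd)
    tot <- tot + c(S = S, N = N, Sd = Sd, Nd = Nd)
  }
  per_pair <- do.call(rbind, per)
  pooled <- list(S = tot[["S"]], N = tot[["N"]],
                 Sd = tot[["Sd"]], Nd = tot[["Nd"]])
  pooled$dS <- jc(if (pooled$S > 0) pooled$Sd / pooled$S else NA_real_)
  pooled$dN <- jc(if (pooled$N > 0) pooled$Nd / pooled$N else NA_real_)
  pooled$dn_ds <- if (!is.na(pooled$dS) && pooled$dS > 0)
    pooled$dN / pooled$dS else NA_real_
  structure(list(per_pair = per_pair, pooled = pooled),
            class = "dnds_result")
}

#' Effective population size from heterozygosity
#'
#' Under the neutral expectation theta = 4 Ne mu, with per-site
#' heterozygosity pi and a per-year mutation rate, Ne = pi / (4 mu g)
#' where g is the generation time in years.
#'
#' @param pi Per-site heterozygosity (proportion, e.g. 0.0537).
#' @param mu_per_year Mutation rate per site per year.
#' @param generation_years Generation time in years (default 1).
#' @return Ne (numeric).
#' @export
effective_population_size <- function(pi, mu_per_year,
                                      generation_years = 1) {
  if (pi <= 0 || mu_per_year <= 0 || generation_years <= 0)
    stop("pi, mu_per_year and generation_years must be positive")
  pi / (4 * mu_per_year * generation_years)
}

#' Fraction of large indels attributable to transposable elements
#'
#' @param variants A `variant_table`.
#' @param te_bed Data frame `chrom, start, end` of TE intervals on the
#'   reference.
#' @param min_overlap_frac An indel counts as TE-derived when at least
#'   this fraction of its length overlaps TE intervals (default 0.5).
#' @return List: `n_large, n_te, fraction_events, fraction_bases`.
#' @export
te_attribution <- function(variants, te_bed, min_overlap_frac = 0.5) {
  lg <- variants[variants$type == "large_indel", , drop = FALSE]
  if (!nrow(lg) || is.null(te_bed) || !nrow(te_bed))
    return(list(n_large = nrow(lg), n_te = 0L,
                fraction_events = 0, fraction_bases = 0))
  te_ir <- split(IRanges::IRanges(start = te_bed$start + 1L,
                                  end = te_bed$end), te_bed$chrom)
  ov_len <- vapply(seq_len(nrow(lg)), function(i) {
    ir <- te_ir[[lg$ref_seq[i]]]
    if (is.null(ir)) return(0)
    # deletions occupy [ref_start, ref_end); insertions are points --
    # attribute insertions by their insertion-site context
    s <- lg$ref_start[i] + 1L
    e <- max(lg$ref_end[i], lg$ref_start[i] + 1L)
    sum(IRanges::width(IRanges::intersect(
      IRanges::reduce(ir), IRanges::IRanges(start = s, end = e))))
  }, numeric(1))
  span <- pmax(lg$ref_end - lg$ref_start, 1)
  te_hit <- ov_len / span >= min_overlap_frac
  list(n_large = nrow(lg), n_te = sum(te_hit),
       fraction_events = mean(te_hit),
       fraction_bases = sum(lg$length[te_hit]) / sum(lg$length))
}
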