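# Genome partition into region classes and transcription/methylation
# profiles by class.

.REGION_CLASSES <- c("cds", "intron", "upstream", "downstream", "intergenic")

#' Partition a genome into region classes
#'
#' Every base is assigned exactly one class with precedence
#' cds > intron > upstream/downstream > intergenic.  Flanks extend
#' `flank` bp from the gene span on the 5' (upstream) and 3'
#' (downstream) sides, strand-aware; where flanks of adjacent genes
#' overlap each other the overlap is split at its midpoint.
#'
#' @param ann A [genome_annotation()].
#' @param flank Flank length in bp (default 1000).
#' @return Data frame of class `region_partition`: `seq, start, end,
#'   class` (0-based half-open, disjoint, covering the genome exactly).
#' @export
partition_regions <- function(ann, flank = 1000) {
  ir <- function(m) if (is.null(m) || nrow(m) == 0L)
    IRanges::IRanges() else IRanges::IRanges(start = m[, 1] + 1L, end = m[, 2])
  out <- list()
  for (s in names(ann$sequences)) {
    len <- ann$sequences[[s]]
    genes <- Filter(function(g) g$seq_name == s, ann$genes)
    cds_m <- do.call(rbind, lapply(genes, function(g) g$cds))
    spans <- do.call(rbind, lapply(genes, function(g)
      c(min(g$exons[, 1]), max(g$exons[, 2]))))
    cds_r <- IRanges::reduce(ir(cds_m))
    span_r <- IRanges::reduce(ir(spans))
    intron_r <- IRanges::setdiff(span_r, cds_r)
    # strand-aware flank candidates, one row per gene and side
    fl <- list()
    for (g in genes) {
      sp <- c(min(g$exons[, 1]), max(g$exons[, 2]))
      up <- if (g$strand == "+") c(sp[1] - flank, sp[1]) else
        c(sp[2], sp[2] + flank)
      dn <- if (g$strand == "+") c(sp[2], sp[2] + flank) else
        c(sp[1] - flank, sp[1])
      fl[[length(fl) + 1L]] <- data.frame(start = max(0, up[1]),
                                          end = min(len, up[2]),
                                          class = "upstream")
      fl[[length(fl) + 1L]] <- data.frame(start = max(0, dn[1]),
                                          end = min(len, dn[2]),
                                          class = "downstream")
    }
    fl <- if (length(fl)) do.call(rbind, fl) else
      data.frame(start = numeric(0), end = numeric(0),
                 class = character(0))
    fl <- fl[fl$end > fl$start, , drop = FALSE]
    # split flank-flank overlaps at the midpoint
    if (nrow(fl) > 1L) {
      ord <- order(fl$start, fl$end)
      fl <- fl[ord, , drop = FALSE]
      for (i in seq_len(nrow(fl) - 1L)) for (j in seq(i + 1L, nrow(fl))) {
        if (fl$start[j] >= fl$end[i]) break
        mid <- floor((fl$start[j] + fl$end[i]) / 2)
        fl$end[i] <- mid
        fl$start[j] <- mid
      }
      fl <- fl[fl$end > fl$start, , drop = FALSE]
    }
    genic_r <- IRanges::union(cds_r, intron_r)
    add <- function(r, cls) {
      if (!length(r)) return(NULL)
      data.frame(seq = s, start = IRanges::start(r) - 1L,
                 end = IRanges::end(r), class = cls,
                 stringsAsFactors = FALSE)
    }
    res <- list(add(cds_r, "cds"), add(intron_r, "intron"))
    covered <- genic_r
    for (cls in c("upstream", "downstream")) {
      sub <- fl[fl$class == cls, , drop = FALSE]
      r <- IRanges::setdiff(IRanges::reduce(ir(as.matrix(sub[, 1:2]))),
                            covered)
      res[[length(res) + 1L]] <- add(r, cls)
      covered <- IRanges::union(covered, r)
    }
    inter_r <- IRanges::setdiff(IRanges::IRanges(start = 1L, end = len),
                                covered)
    res[[length(res) + 1L]] <- add(inter_r, "intergenic")
    out[[s]] <- do.call(rbind, res)
  }
  part <- do.call(rbind, out)
  part <- part[order(part$seq, part$start), ]
  rownames(part) <- NULL
  class(part) <- c("region_partition", "data.frame")
  part
}

.partition_ranges <- function(partition) {
  lapply(split(partition, partition$seq), function(p)
    lapply(split(p, p$class), function(q)
      IRanges::IRanges(start = q$start + 1L, end = q$end)))
}

#' Transcription fractions by region class
#'
#' Each read is assigned to the class containing the majority of its
#' bases (ties broken by class precedence); fractions are percentages of
#' reads per class and genome coverage is the fraction of genome bases
#' covered by at least one read.
#'
#' @param reads Data frame `chrom, start, end` of mapped read intervals
#'   (0-based half-open).
#' @param partition A `region_partition`.
#' @param genome_length Total genome length (defaults to the partition
#'   total).
#' @return List of class `transcription_profile`: `fractions_pct` (named
#'   over classes, summing to 100), `n_reads`, `coverage_pct`.
#' @export
transcription_fractions <- function(reads, partition,
                                    genome_length = NULL) {
  if (is.null(genome_length))
    genome_length <- sum(partition$end - partition$start)
  offc <- setdiff(unique(reads$chrom), unique(partition$seq))
  if (length(offc))
    stop("reads on sequences absent from the partition: ",
         paste(offc, collapse = ", "))
  pr <- .partition_ranges(partition)
  counts <- stats::setNames(numeric(length(.REGION_CLASSES)),
                            .REGION_CLASSES)
  cov_bp <- 0
  for (s in unique(reads$chrom)) {
    rr <- reads[reads$chrom == s, , drop = FALSE]
    read_ir <- IRanges::IRanges(start = rr$start + 1L, end = rr$end)
    ov <- matrix(0, nrow(rr), length(.REGION_CLASSES),
                 dimnames = list(NULL, .REGION_CLASSES))
    for (cls in .REGION_CLASSES) {
      cr <- pr[[s]][[cls]]
      if (is.null(cr) || !length(cr)) next
      cr <- IRanges::reduce(cr)
      fo <- IRanges::findOverlaps(read_ir, cr)
      if (!length(fo)) next
      w <- IRanges::width(IRanges::pintersect(
        read_ir[S4Vectors::queryHits(fo)],
        cr[S4Vectors::subjectHits(fo)]))
      agg <- tapply(w, S4Vectors::queryHits(fo), sum)
      ov[as.integer(names(agg)), cls] <- as.numeric(agg)
    }
    cls_idx <- apply(ov, 1L, which.max)   # first max: precedence order
    tab <- table(factor(.REGION_CLASSES[cls_idx],
                        levels = .REGION_CLASSES))
    counts <- counts + as.numeric(tab)
    cov_bp <- cov_bp + sum(IRanges::width(IRanges::reduce(read_ir)))
  }
  n <- sum(counts)
  structure(list(fractions_pct = 100 * counts / n,
                 n_reads = n,
                 coverage_pct = 100 * cov_bp / genome_length),
            class = "transcription_profile")
}

#' Methylation profile by region class
#'
#' Per-site methylation level is methylated/total reads; the class level
#' is the unweighted mean over sites (a coverage-weighted mean is also
#' reported), together with the fraction of highly methylated sites
#' (level >= `high_cut`) and Student's t-tests between all class pairs.
#'
#' @param methyl Methylation table (`"methylation"` schema of
#'   [read_table()]).
#' @param partition A `region_partition`.
#' @param te_bed Optional TE intervals (`chrom, start, end`), overlaid
#'   as an additional class `te`.
#' @param high_cut High-methylation threshold in percent (default 80).
#' @return List of class `methylation_profile`: `by_class` (data frame
#'   `class, n_sites, mean_level_pct, weighted_level_pct,
#'   high_fraction_pct`), `t_tests` (data frame of pairwise
#'   comparisons).
#' @export
methylation_by_region <- function(methyl, partition, te_bed = NULL,
                                  high_cut = 80) {
  lv <- 100 * methyl$methylated_reads / methyl$total_reads
  cls <- rep(NA_character_, nrow(methyl))
  pr <- .partition_ranges(partition)
  for (s in unique(methyl$seq)) {
    idx <- which(methyl$seq == s)
    site_ir <- IRanges::IRanges(start = methyl$pos0[idx] + 1L, width = 1L)
    for (cc in .REGION_CLASSES) {
      cr <- pr[[s]][[cc]]
      if (is.null(cr) || !length(cr)) next
      hit <- IRanges::overlapsAny(site_ir, cr)
      cls[idx[hit & is.na(cls[idx])]] <- cc
    }
  }
  classes <- .REGION_CLASSES
  levels_by <- split(lv, factor(cls, levels = classes))
  wts_by <- split(methyl$total_reads, factor(cls, levels = classes))
  if (!is.null(te_bed) && nrow(te_bed)) {
    te_ir <- split(IRanges::IRanges(start = te_bed$start + 1L,
                                    end = te_bed$end), te_bed$chrom)
    in_te <- vapply(seq_len(nrow(methyl)), function(i) {
      ir <- te_ir[[methyl$seq[i]]]
      !is.null(ir) && IRanges::overlapsAny(
        IRanges::IRanges(start = methyl$pos0[i] + 1L, width = 1L), ir)
    }, logical(1))
    levels_by$te <- lv[in_te]
    wts_by$te <- methyl$total_reads[in_te]
    classes <- c(classes, "te")
  }
  by_class <- do.call(rbind, lapply(classes, function(cc) {
    x <- levels_by[[cc]]; w <- wts_by[[cc]]
    data.frame(class = cc, n_sites = length(x),
               mean_level_pct = if (length(x)) mean(x) else NA_real_,
               weighted_level_pct = if (length(x))
                 sum(x * w) / sum(w) else NA_real_,
               high_fraction_pct = if (length(x))
                 100 * mean(x >= high_cut) else NA_real_)
  }))
  tt <- list()
  for (i in seq_len(length(classes) - 1L))
    for (j in seq(i + 1L, length(classes))) {
      a <- levels_by[[classes[i]]]; b <- levels_by[[classes[j]]]
      if (length(a) > 1L && length(b) > 1L) {
        t <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
        if (!is.null(t))
          tt[[length(tt) + 1L]] <- data.frame(
            class_a = classes[i], class_b = classes[j],
            t = unname(t$statistic), p_value = t$p.value)
      }
    }
  structure(list(by_class = by_class,
                 t_tests = if (length(tt)) do.call(rbind, tt) else NULL),
            class = "methylation_profile")
}
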