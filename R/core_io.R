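#' @keywords internal
"_PACKAGE"

## Internal coordinate convention: 0-based, half-open [start, end), forward
## strand.  GFF3 (1-based closed) and axt are converted at the I/O boundary
## only.  Amino-acid intervals in domain tables follow the same convention.

# ---------------------------------------------------------------------------
# Gene models and genome annotations
# ---------------------------------------------------------------------------

#' Construct a gene model
#'
#' A gene model holds the exon and CDS structure of a single gene on genomic
#' coordinates (0-based, half-open, forward strand).
#'
#' @param gene_id Unique gene identifier.
#' @param seq_name Name of the sequence (scaffold/chromosome) the gene is on.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix of exon `[start, end)` intervals, sorted in
#'   genomic order and non-overlapping.
#' @param cds Two-column matrix of CDS `[start, end)` intervals; defaults to
#'   `exons`.
#' @param protein_id Identifier of the encoded protein; defaults to `gene_id`.
#' @param complete Logical; `TRUE` when the CDS is expected to be a complete
#'   reading frame (total CDS length divisible by 3).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, seq_name, strand, exons, cds = exons,
                       protein_id = gene_id, complete = TRUE) {
  exons <- .as_interval_matrix(exons, "exons")
  cds <- .as_interval_matrix(cds, "cds")
  if (!strand %in% c("+", "-"))
    stop("gene ", gene_id, ": strand must be '+' or '-', got '", strand, "'")
  if (nrow(exons) == 0L)
    stop("gene ", gene_id, ": at least one exon required")
  if (is.unsorted(exons[, 1L]))
    stop("gene ", gene_id, ": exons must be sorted in genomic order")
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("gene ", gene_id, ": exons overlap")
  if (isTRUE(complete) && sum(cds[, 2L] - cds[, 1L]) %% 3L != 0L)
    stop("gene ", gene_id, ": complete CDS length not divisible by 3")
  structure(list(gene_id = gene_id, seq_name = seq_name, strand = strand,
                 exons = exons, cds = cds, protein_id = protein_id,
                 complete = isTRUE(complete)),
            class = "gene_model")
}

.as_interval_matrix <- function(x, what) {
  if (is.null(x) || length(x) == 0L)
    return(matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  x <- matrix(as.numeric(x), ncol = 2L)
  colnames(x) <- c("start", "end")
  if (any(x[, 2L] < x[, 1L]) || any(x[, 1L] < 0))
    stop("invalid ", what, " interval: end < start or negative start")
  x
}

#' Construct a genome annotation
#'
#' @param sequences Named numeric vector of sequence lengths in bp.
#' @param genes List of [gene_model()] objects.
#' @param assembly_name Label for the assembly.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(sequences, genes = list(),
                              assembly_name = "assembly") {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must be a uniquely named vector of lengths")
  ids <- vapply(genes, function(g) g$gene_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicated gene ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (g in genes) {
    if (!g$seq_name %in% names(sequences))
      stop("gene ", g$gene_id, ": unknown sequence '", g$seq_name, "'")
    len <- sequences[[g$seq_name]]
    iv <- rbind(g$exons, g$cds)
    if (nrow(iv) && (min(iv[, 1L]) < 0 || max(iv[, 2L]) > len))
      stop("gene ", g$gene_id, ": interval outside sequence '",
           g$seq_name, "' [0, ", len, ")")
  }
  names(genes) <- ids
  structure(list(sequences = sequences, genes = genes,
                 assembly_name = assembly_name),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> ", x$assembly_name, ": ",
      length(x$sequences), " sequences (",
      format(sum(x$sequences), big.mark = ","), " bp), ",
      length(x$genes), " genes\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Alignment blocks
# ---------------------------------------------------------------------------

#' Construct a pairwise alignment block set
#'
#' Blocks are gap-aware pairwise alignment fragments between a reference and
#' a query assembly.  Reference coordinates always ascend on the forward
#' strand; `query_strand` records the orientation of the query interval,
#' whose coordinates are given on the query's forward strand.
#'
#' @param blocks Data frame with columns `ref_seq, ref_start, ref_end,
#'   query_seq, query_start, query_end, query_strand, ref_text, query_text`.
#' @param source_pair Character vector of length 2: reference and query
#'   assembly labels.
#' @return Object of class `alignment_block_set`.
#' @export
alignment_block_set <- function(blocks, source_pair = c("A", "B")) {
  req <- c("ref_seq", "ref_start", "ref_end", "query_seq", "query_start",
           "query_end", "query_strand", "ref_text", "query_text")
  miss <- setdiff(req, names(blocks))
  if (length(miss))
    stop("alignment blocks missing columns: ", paste(miss, collapse = ", "))
  blocks <- as.data.frame(blocks)[req]
  for (i in seq_len(nrow(blocks))) {
    rt <- blocks$ref_text[i]; qt <- blocks$query_text[i]
    if (nchar(rt) != nchar(qt))
      stop("block ", i, ": aligned texts have unequal length")
    rlen <- nchar(gsub("-", "", rt, fixed = TRUE))
    qlen <- nchar(gsub("-", "", qt, fixed = TRUE))
    if (rlen != blocks$ref_end[i] - blocks$ref_start[i])
      stop("block ", i, ": ungapped ref length ", rlen,
           " does not match interval")
    if (qlen != blocks$query_end[i] - blocks$query_start[i])
      stop("block ", i, ": ungapped query length ", qlen,
           " does not match interval")
    if (!blocks$query_strand[i] %in% c("+", "-"))
      stop("block ", i, ": bad query strand")
  }
  structure(list(blocks = blocks, source_pair = source_pair),
            class = "alignment_block_set")
}

#' @export
print.alignment_block_set <- function(x, ...) {
  cat("<alignment_block_set> ", x$source_pair[1], " vs ", x$source_pair[2],
      ": ", nrow(x$blocks), " blocks, ",
      format(sum(x$blocks$ref_end - x$blocks$ref_start), big.mark = ","),
      " ref bp\n", sep = "")
  invisible(x)
}

#' Percent identity of each alignment block
#'
#' Gap columns count as mismatches.
#'
#' @param bs An [alignment_block_set()].
#' @return Numeric vector of identities in percent, one per block.
#' @export
block_identity <- function(bs) {
  vapply(seq_len(nrow(bs$blocks)), function(i) {
    r <- strsplit(bs$blocks$ref_text[i], "")[[1]]
    q <- strsplit(bs$blocks$query_text[i], "")[[1]]
    100 * sum(r == q & r != "-") / length(r)
  }, numeric(1))
}

# ---------------------------------------------------------------------------
# GFF3
# ---------------------------------------------------------------------------

.parse_gff_attrs <- function(s) {
  out <- list()
  for (kv in strsplit(s, ";", fixed = TRUE)[[1]]) {
    kv <- trimws(kv)
    if (!nzchar(kv)) next
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      out[[substr(kv, 1, eq - 1)]] <- utils::URLdecode(substr(kv, eq + 1, nchar(kv)))
  }
  out
}

#' Read a GFF3 genome annotation
#'
#' Parses `gene`/`mRNA`/`exon`/`CDS` features into [gene_model()] objects.
#' GFF3 1-based closed coordinates are converted to the package's 0-based
#' half-open convention.  Sequence lengths are taken from
#' `##sequence-region` pragmas when present, otherwise from the maximal
#' feature end per sequence.  The CDS phase column is read but recomputed by
#' downstream phase annotation.
#'
#' @param path Path to a GFF3 file.
#' @return A [genome_annotation()].
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  seqlens <- c()
  for (ln in grep("^##sequence-region", lines, value = TRUE)) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    seqlens[f[2]] <- as.numeric(f[4])
  }
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) {
    if (!length(seqlens)) seqlens <- c(empty = 0)[0]
    return(genome_annotation(seqlens, list(),
                             assembly_name = basename(path)))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 9L)
  if (length(bad))
    stop("malformed GFF3 line ", bad[1], ": expected 9 columns")
  tab <- data.frame(seq = vapply(f, `[`, "", 1L),
                    type = vapply(f, `[`, "", 3L),
                    start = as.numeric(vapply(f, `[`, "", 4L)) - 1,
                    end = as.numeric(vapply(f, `[`, "", 5L)),
                    strand = vapply(f, `[`, "", 7L),
                    attrs = vapply(f, `[`, "", 9L),
                    stringsAsFactors = FALSE)
  attrs <- lapply(tab$attrs, .parse_gff_attrs)
  tab$id <- vapply(attrs, function(a) a$ID %||% NA_character_, "")
  tab$parent <- vapply(attrs, function(a) a$Parent %||% NA_character_, "")

  genes_tab <- tab[tab$type == "gene", ]
  mrna_tab <- tab[tab$type == "mRNA", ]
  part_tab <- tab[tab$type %in% c("exon", "CDS"), ]
  if (any(is.na(genes_tab$id)))
    stop("gene feature without ID attribute")
  if (any(!genes_tab$strand %in% c("+", "-")))
    stop("unknown strand '", genes_tab$strand[!genes_tab$strand %in% c("+", "-")][1],
         "' on gene ", genes_tab$id[!genes_tab$strand %in% c("+", "-")][1])
  # map transcript id -> gene id (parts may point at either level)
  tx2gene <- stats::setNames(mrna_tab$parent, mrna_tab$id)
  bad_tx <- mrna_tab$id[!mrna_tab$parent %in% genes_tab$id]
  if (length(bad_tx))
    stop("malformed parent link: mRNA '", bad_tx[1],
         "' refers to unknown gene '", tx2gene[[bad_tx[1]]], "'")
  owner <- function(pid, fid) {
    if (pid %in% genes_tab$id) return(pid)
    if (pid %in% names(tx2gene)) return(tx2gene[[pid]])
    stop("malformed parent link: feature '", fid %||% "(no ID)",
         "' refers to unknown parent '", pid, "'")
  }
  kids_gene <- vapply(seq_len(nrow(part_tab)), function(j)
    owner(part_tab$parent[j], part_tab$id[j]), character(1))
  genes <- list()
  for (i in seq_len(nrow(genes_tab))) {
    gid <- genes_tab$id[i]
    mine <- part_tab[kids_gene == gid, , drop = FALSE]
    ex <- mine[mine$type == "exon", , drop = FALSE]
    cd <- mine[mine$type == "CDS", , drop = FALSE]
    if (!nrow(ex) && nrow(cd)) ex <- cd
    if (!nrow(ex))
      ex <- genes_tab[i, , drop = FALSE]
    if (!nrow(cd)) cd <- ex
    ex <- ex[order(ex$start), ]
    cd <- cd[order(cd$start), ]
    cds_m <- cbind(cd$start, cd$end)
    complete <- sum(cds_m[, 2] - cds_m[, 1]) %% 3 == 0
    genes[[gid]] <- gene_model(gid, genes_tab$seq[i], genes_tab$strand[i],
                               cbind(ex$start, ex$end), cds_m,
                               protein_id = paste0(gid, "_p1"),
                               complete = complete)
  }
  if (!length(seqlens)) {
    seqlens <- tapply(tab$end, tab$seq, max)
    seqlens <- stats::setNames(as.numeric(seqlens), names(seqlens))
  }
  genome_annotation(seqlens, genes, assembly_name = basename(path))
}

#' Write a genome annotation as GFF3
#'
#' @param ann A [genome_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (s in names(ann$sequences))
    writeLines(sprintf("##sequence-region %s 1 %d", s,
                       as.integer(ann$sequences[[s]])), con)
  for (g in ann$genes) {
    span <- c(min(g$exons[, 1]), max(g$exons[, 2]))
    tx <- paste0(g$gene_id, ".t1")
    writeLines(sprintf("%s\tchordevo\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$seq_name, span[1] + 1L, span[2], g$strand,
                       g$gene_id), con)
    writeLines(sprintf("%s\tchordevo\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       g$seq_name, span[1] + 1L, span[2], g$strand, tx,
                       g$gene_id), con)
    for (i in seq_len(nrow(g$exons)))
      writeLines(sprintf("%s\tchordevo\texon\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                         g$seq_name, g$exons[i, 1] + 1L, g$exons[i, 2],
                         g$strand, paste0(g$gene_id, ".e", i), tx), con)
    for (i in seq_len(nrow(g$cds)))
      writeLines(sprintf("%s\tchordevo\tCDS\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                         g$seq_name, g$cds[i, 1] + 1L, g$cds[i, 2],
                         g$strand, paste0(g$gene_id, ".c", i), tx), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Pairwise alignments: MAF and axt
# ---------------------------------------------------------------------------

#' Read a pairwise whole-genome alignment
#'
#' Supports pairwise MAF (exactly two `s` rows per block) and axt.  Query
#' coordinates of minus-strand blocks are converted to forward-strand
#' coordinates; reference coordinates always ascend.
#'
#' @param path Path to the alignment file.
#' @param format `"maf"` or `"axt"`.
#' @param source_pair Labels for the two assemblies.
#' @return An [alignment_block_set()].
#' @export
read_pairwise_alignment <- function(path, format = c("maf", "axt"),
                                    source_pair = c("ref", "query")) {
  format <- match.arg(format)
  lines <- readLines(path)
  rows <- list()
  if (format == "maf") {
    i <- 1L
    while (i <= length(lines)) {
      if (startsWith(lines[i], "a")) {
        srows <- list()
        j <- i + 1L
        while (j <= length(lines) && startsWith(lines[j], "s")) {
          srows[[length(srows) + 1L]] <- strsplit(trimws(lines[j]), "\\s+")[[1]]
          j <- j + 1L
        }
        if (length(srows) != 2L)
          stop("MAF block at line ", i, " has ", length(srows),
               " sequence rows; pairwise alignment requires exactly 2")
        r <- srows[[1]]; q <- srows[[2]]
        rstart <- as.numeric(r[3]); rsize <- as.numeric(r[4])
        qstart <- as.numeric(q[3]); qsize <- as.numeric(q[4])
        qsrc_size <- as.numeric(q[6])
        qstrand <- q[5]
        if (r[5] != "+")
          stop("MAF reference row must be on + strand (line ", i, ")")
        q_fwd_start <- if (qstrand == "+") qstart else qsrc_size - qstart - qsize
        rows[[length(rows) + 1L]] <- data.frame(
          ref_seq = r[2], ref_start = rstart, ref_end = rstart + rsize,
          query_seq = q[2], query_start = q_fwd_start,
          query_end = q_fwd_start + qsize, query_strand = qstrand,
          ref_text = r[7], query_text = q[7], stringsAsFactors = FALSE)
        i <- j
      } else i <- i + 1L
    }
  } else {
    i <- 1L
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (!nzchar(ln) || startsWith(ln, "#")) { i <- i + 1L; next }
      f <- strsplit(ln, "\\s+")[[1]]
      if (length(f) < 9L)
        stop("malformed axt header at line ", i)
      # axt: 1-based closed; minus-strand query coords are on the reverse
      # strand of the query sequence and need the query length to flip --
      # axt carries no length, so we require an attribute line '#qlen seq len'
      rstart <- as.numeric(f[3]) - 1; rend <- as.numeric(f[4])
      qstart <- as.numeric(f[6]) - 1; qend <- as.numeric(f[7])
      qstrand <- f[8]
      rtxt <- lines[i + 1L]; qtxt <- lines[i + 2L]
      if (qstrand == "-") {
        qlen_line <- grep(paste0("^#qlen\\s+", f[5], "\\s"), lines, value = TRUE)
        if (length(qlen_line)) {
          qlen <- as.numeric(strsplit(trimws(qlen_line[1]), "\\s+")[[1]][3])
          tmp <- qlen - qend
          qend <- qlen - qstart
          qstart <- tmp
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        ref_seq = f[2], ref_start = rstart, ref_end = rend,
        query_seq = f[5], query_start = qstart, query_end = qend,
        query_strand = qstrand, ref_text = rtxt, query_text = qtxt,
        stringsAsFactors = FALSE)
      i <- i + 3L
    }
  }
  blocks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ref_seq = character(0), ref_start = numeric(0),
               ref_end = numeric(0), query_seq = character(0),
               query_start = numeric(0), query_end = numeric(0),
               query_strand = character(0), ref_text = character(0),
               query_text = character(0))
  alignment_block_set(blocks, source_pair)
}

#' Write a pairwise alignment block set as MAF
#'
#' @param bs An [alignment_block_set()].
#' @param path Output path.
#' @param seq_lengths Optional named vector of query sequence lengths, used
#'   to express minus-strand query coordinates in MAF convention; defaults
#'   to the block end (sufficient for round-tripping plus-strand blocks).
#' @return `path`, invisibly.
#' @export
write_maf <- function(bs, path, seq_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  b <- bs$blocks
  for (i in seq_len(nrow(b))) {
    qlen <- if (!is.null(seq_lengths) && b$query_seq[i] %in% names(seq_lengths))
      seq_lengths[[b$query_seq[i]]] else b$query_end[i]
    qsize <- b$query_end[i] - b$query_start[i]
    qstart_maf <- if (b$query_strand[i] == "+") b$query_start[i] else
      qlen - b$query_end[i]
    writeLines("a score=0", con)
    writeLines(sprintf("s %s %d %d + %d %s", b$ref_seq[i], b$ref_start[i],
                       b$ref_end[i] - b$ref_start[i],
                       max(b$ref_end[i], qlen), b$ref_text[i]), con)
    writeLines(sprintf("s %s %d %d %s %d %s", b$query_seq[i], qstart_maf,
                       qsize, b$query_strand[i], qlen, b$query_text[i]), con)
    writeLines("", con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# BED, newick, FASTA, schema'd TSV
# ---------------------------------------------------------------------------

#' Read a BED file
#'
#' @param path Path to a BED3+ file.
#' @return Data frame with columns `chrom, start, end` and, when present,
#'   `name, score, strand` (0-based half-open, as BED).
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand")[1:max(3,
                             length(strsplit(readLines(path, n = 1),
                                             "\t")[[1]]))],
                           fill = FALSE)
  if (any(tab$end < tab$start))
    stop("BED interval with end < start at row ",
         which(tab$end < tab$start)[1])
  tab
}

#' Write intervals as BED
#'
#' @param intervals Data frame with at least `chrom, start, end`; optional
#'   `name, score, strand` columns are written in BED order.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  if (any(intervals$end < intervals$start))
    stop("refusing to write BED interval with end < start")
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  utils::write.table(intervals[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a rooted species tree from newick
#'
#' @param path Path to a newick file.
#' @return An `ape::phylo` tree; errors when leaf labels are duplicated.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (anyDuplicated(tr$tip.label))
    stop("duplicated leaf labels in tree")
  tr
}

#' Read sequences from FASTA
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

.table_schemas <- list(
  hits = c("query_id", "subject_id", "percent_identity", "alignment_length",
           "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
           "e_value", "bitscore"),
  domains = c("protein_id", "domain_type", "env_start", "env_end", "e_value"),
  methylation = c("seq", "pos0", "strand", "context", "methylated_reads",
                  "total_reads"))

#' Read a schema-checked TSV table
#'
#' Three schemas are supported: `"hits"` (12-column blast tabular, no
#' header), `"domains"` (per-protein domain architecture, with header) and
#' `"methylation"` (per-site methylation calls, with header).
#'
#' @param path Path to a TSV file.
#' @param schema One of `"hits"`, `"domains"`, `"methylation"`.
#' @return Data frame with the schema's canonical column names.
#' @export
read_table <- function(path, schema = c("hits", "domains", "methylation")) {
  schema <- match.arg(schema)
  cols <- .table_schemas[[schema]]
  if (schema == "hits") {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) != length(cols))
      stop("hits table must have ", length(cols), " columns, found ",
           ncol(tab), "; missing: ",
           paste(cols[seq(ncol(tab) + 1, length(cols))], collapse = ", "))
    names(tab) <- cols
  } else {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    miss <- setdiff(cols, names(tab))
    if (length(miss))
      stop(schema, " table missing columns: ", paste(miss, collapse = ", "))
    tab <- tab[cols]
  }
  if (schema == "hits") {
    if (any(tab$percent_identity < 0 | tab$percent_identity > 100))
      stop("percent_identity outside [0, 100]")
    if (any(tab$e_value < 0)) stop("negative e-value")
  }
  if (schema == "methylation" &&
      any(tab$methylated_reads > tab$total_reads))
    stop("methylated_reads exceeds total_reads")
  tab
}

#' Write a hit table in 12-column blast tabular format
#'
#' @param hits Data frame in the `"hits"` schema of [read_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits[.table_schemas$hits], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
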