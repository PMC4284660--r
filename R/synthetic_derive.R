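# Derived views of simulated descendant pairs: pairwise alignment
# blocks, protein- and exon-level hit tables, and signed marker orders.
# All are computed from shared ancestry recorded in the simulator, with
# an alignability threshold emulating what a reciprocal-best
# whole-genome aligner can detect.

.string_identity <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  100 * sum(va == vb) / length(va)
}

# unit tables: every atomic alignable unit with coordinates and sequence
.unit_table <- function(sim) {
  lay <- emit_layout(sim)
  units <- list()
  add <- function(id, kind, seq_name, start, end, strand, dna, gene_id = NA) {
    units[[id]] <<- list(id = id, kind = kind, seq_name = seq_name,
                         start = start, end = end, strand = strand,
                         dna = dna, gene_id = gene_id)
  }
  for (i in seq_len(nrow(lay$intergenic)))
    add(lay$intergenic$id[i], "intergenic", lay$intergenic$seq[i],
        lay$intergenic$start[i], lay$intergenic$end[i], "+",
        substr(lay$seqs[[lay$intergenic$seq[i]]],
               lay$intergenic$start[i] + 1L, lay$intergenic$end[i]))
  for (i in seq_len(nrow(lay$cnes)))
    add(lay$cnes$id[i], "cne", lay$cnes$seq[i], lay$cnes$start[i],
        lay$cnes$end[i], "+",
        substr(lay$seqs[[lay$cnes$seq[i]]], lay$cnes$start[i] + 1L,
               lay$cnes$end[i]))
  for (i in seq_len(nrow(lay$exons)))
    add(lay$exons$exon_id[i], "exon", lay$exons$seq[i],
        lay$exons$start[i], lay$exons$end[i], lay$exons$strand[i],
        substr(lay$seqs[[lay$exons$seq[i]]], lay$exons$start[i] + 1L,
               lay$exons$end[i]), lay$exons$gene_id[i])
  list(units = units, layout = lay)
}

# ancestral identity of a unit id: WGD copies share their ancestor unit
.root_id <- function(id) sub("(_2)+$", "", id)

#' Derive the pairwise whole-genome alignment of two descendants
#'
#' For every alignable unit (intergenic block, CNE, CDS exon) present in
#' both descendants, a gap-free alignment block is emitted when the
#' pairwise identity reaches `min_identity` percent -- unalignable
#' neutral sequence drops out, exactly as it does for a reciprocal-best
#' whole-genome aligner on diverged species.
#'
#' @param desc_a,desc_b Descendant `sim_genome`s of a common ancestor.
#' @param min_identity Alignability threshold (percent, default 60).
#' @return An [alignment_block_set()] (A as reference).
#' @export
derive_alignment <- function(desc_a, desc_b, min_identity = 60) {
  ua <- .unit_table(desc_a); ub <- .unit_table(desc_b)
  roots_b <- vapply(names(ub$units), .root_id, character(1))
  rows <- list()
  for (ida in names(ua$units)) {
    ra <- .root_id(ida)
    idb <- names(ub$units)[roots_b == ra]
    if (!length(idb)) next
    a <- ua$units[[ida]]
    for (idb1 in idb) {
      b <- ub$units[[idb1]]
      if (nchar(a$dna) != nchar(b$dna)) next  # unit changed length
      if (a$kind == "exon") {
        # exon orientation is known from the gene strand
        flip <- a$strand != b$strand
        btxt <- if (flip) .revcomp(b$dna) else b$dna
        ident <- .string_identity(a$dna, btxt)
      } else {
        # intergenic/CNE units may have been inverted; align in the
        # better orientation, as an aligner would
        id_f <- .string_identity(a$dna, b$dna)
        brc <- .revcomp(b$dna)
        id_r <- .string_identity(a$dna, brc)
        flip <- id_r > id_f
        btxt <- if (flip) brc else b$dna
        ident <- max(id_f, id_r)
      }
      if (ident < min_identity) next
      rows[[length(rows) + 1L]] <- data.frame(
        ref_seq = a$seq_name, ref_start = a$start, ref_end = a$end,
        query_seq = b$seq_name, query_start = b$start,
        query_end = b$end, query_strand = if (flip) "-" else "+",
        ref_text = a$dna, query_text = btxt, stringsAsFactors = FALSE)
    }
  }
  blocks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ref_seq = character(0), ref_start = numeric(0),
               ref_end = numeric(0), query_seq = character(0),
               query_start = numeric(0), query_end = numeric(0),
               query_strand = character(0), ref_text = character(0),
               query_text = character(0))
  blocks <- blocks[order(blocks$ref_seq, blocks$ref_start), , drop = FALSE]
  rownames(blocks) <- NULL
  alignment_block_set(blocks, c(desc_a$assembly_name, desc_b$assembly_name))
}

#' Protein sequences of a simulated genome
#'
#' @param sim A `sim_genome`.
#' @return Named character vector (protein id -> amino-acid sequence).
#' @export
protein_sequences <- function(sim) {
  out <- character(0)
  for (cn in names(sim$chroms)) for (f in sim$chroms[[cn]]) {
    if (f$kind != "gene") next
    cds <- paste(f$gene$exons, collapse = "")
    cds <- substr(cds, 1L, 3L * (nchar(cds) %/% 3L))
    out[f$gene$protein_id] <- as.character(Biostrings::translate(
      Biostrings::DNAString(cds), if.fuzzy.codon = "X"))
  }
  out
}

# per-gene exon id/sequence listing in translation order
.gene_exon_seqs <- function(sim) {
  out <- list()
  for (cn in names(sim$chroms)) for (f in sim$chroms[[cn]]) {
    if (f$kind != "gene") next
    out[[f$gene$gene_id]] <- list(ids = f$gene$exon_ids,
                                  seqs = f$gene$exons,
                                  protein_id = f$gene$protein_id)
  }
  out
}

#' Derive protein-level hit tables for a descendant pair
#'
#' For every gene pair sharing an ancestral gene, alignment segments are
#' emitted per maximal run of shared exons (in both genes' translation
#' order), with nucleotide-level identities and approximate amino-acid
#' coordinates; weak noise hits between random non-orthologous proteins
#' are added below the orthology cutoffs.
#'
#' @param desc_a,desc_b Descendant `sim_genome`s.
#' @param n_noise Number of random noise hits per direction (default
#'   2 per gene).
#' @param noise_identity_range Identity range of noise hits (default
#'   20-45 percent).
#' @return List: `hits_ab`, `hits_ba` (hit tables), `gene_of` (protein
#'   -> gene map), `protein_lengths` (aa), `truth` (data frame of true
#'   orthologous gene pairs).
#' @export
derive_protein_hits <- function(desc_a, desc_b, n_noise = NULL,
                                noise_identity_range = c(20, 45)) {
  ga <- .gene_exon_seqs(desc_a); gb <- .gene_exon_seqs(desc_b)
  roots_b <- vapply(names(gb), .root_id, character(1))
  gene_of <- c(
    stats::setNames(names(ga), vapply(ga, `[[`, "", "protein_id")),
    stats::setNames(names(gb), vapply(gb, `[[`, "", "protein_id")))
  plen <- c(
    vapply(ga, function(g) sum(nchar(g$seqs)) %/% 3, numeric(1)) |>
      stats::setNames(vapply(ga, `[[`, "", "protein_id")),
    vapply(gb, function(g) sum(nchar(g$seqs)) %/% 3, numeric(1)) |>
      stats::setNames(vapply(gb, `[[`, "", "protein_id")))
  mk_rows <- function(qg, sg, qname, sname) {
    shared <- intersect(qg$ids, sg$ids)
    if (!length(shared)) return(NULL)
    qi <- match(shared, qg$ids); si <- match(shared, sg$ids)
    ord <- order(qi)
    qi <- qi[ord]; si <- si[ord]
    # maximal runs consecutive in both
    run_id <- cumsum(c(1, diff(qi) != 1 | diff(si) != 1))
    q_off <- c(0, cumsum(nchar(qg$seqs)))
    s_off <- c(0, cumsum(nchar(sg$seqs)))
    rows <- list()
    for (r in unique(run_id)) {
      sel <- which(run_id == r)
      ident <- mean(vapply(sel, function(k)
        .string_identity(qg$seqs[qi[k]], sg$seqs[si[k]]), numeric(1)))
      nt <- sum(nchar(qg$seqs[qi[sel]]))
      aa <- max(1L, nt %/% 3L)
      qs <- q_off[qi[sel][1]] %/% 3L + 1L
      ss <- s_off[si[sel][1]] %/% 3L + 1L
      rows[[r]] <- data.frame(
        query_id = qg$protein_id, subject_id = sg$protein_id,
        percent_identity = ident, alignment_length = aa,
        mismatches = round(aa * (1 - ident / 100)), gap_opens = 0L,
        q_start = qs, q_end = qs + aa - 1L,
        s_start = ss, s_end = ss + aa - 1L,
        e_value = 1e-50, bitscore = round(2 * aa * ident / 100, 1),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  rows_ab <- list(); rows_ba <- list(); truth <- list()
  for (gna in names(ga)) {
    partners <- names(gb)[roots_b == .root_id(gna)]
    for (gnb in partners) {
      ab <- mk_rows(ga[[gna]], gb[[gnb]], gna, gnb)
      ba <- mk_rows(gb[[gnb]], ga[[gna]], gnb, gna)
      if (!is.null(ab)) rows_ab[[length(rows_ab) + 1L]] <- ab
      if (!is.null(ba)) rows_ba[[length(rows_ba) + 1L]] <- ba
      truth[[length(truth) + 1L]] <- data.frame(
        gene_a = gna, gene_b = gnb, stringsAsFactors = FALSE)
    }
  }
  # noise hits between non-orthologous proteins
  if (is.null(n_noise)) n_noise <- 2L * length(ga)
  if (n_noise > 0 && length(ga) > 1 && length(gb) > 1) {
    mk_noise <- function(src, dst, n) {
      qs <- sample(names(src), n, replace = TRUE)
      ss <- sample(names(dst), n, replace = TRUE)
      keep <- .root_id(qs) != .root_id(ss)
      qs <- qs[keep]; ss <- ss[keep]
      if (!length(qs)) return(NULL)
      qp <- vapply(src[qs], `[[`, "", "protein_id")
      sp <- vapply(dst[ss], `[[`, "", "protein_id")
      aa <- pmax(10L, round(pmin(plen[qp], plen[sp]) * 0.3))
      ident <- stats::runif(length(qs), noise_identity_range[1],
                            noise_identity_range[2])
      data.frame(query_id = qp, subject_id = sp,
                 percent_identity = ident, alignment_length = aa,
                 mismatches = round(aa * (1 - ident / 100)),
                 gap_opens = 0L, q_start = 1L, q_end = aa,
                 s_start = 1L, s_end = aa, e_value = 1e-3,
                 bitscore = round(0.5 * aa * ident / 100, 1),
                 stringsAsFactors = FALSE)
    }
    rows_ab[[length(rows_ab) + 1L]] <- mk_noise(ga, gb, n_noise)
    rows_ba[[length(rows_ba) + 1L]] <- mk_noise(gb, ga, n_noise)
  }
  bind_hits <- function(rows) {
    rows <- Filter(Negate(is.null), rows)
    if (length(rows)) do.call(rbind, rows) else
      stats::setNames(data.frame(matrix(ncol = 12, nrow = 0)),
                      .table_schemas$hits)
  }
  list(hits_ab = bind_hits(rows_ab), hits_ba = bind_hits(rows_ba),
       gene_of = gene_of, protein_lengths = plen,
       truth = do.call(rbind, truth))
}

#' Derive exon-level hit tables for a descendant pair
#'
#' One reciprocal hit per exon sharing an ancestral exon id, with
#' nucleotide identity; used by the shuffled-exon detectors.
#'
#' @param desc_a,desc_b Descendant `sim_genome`s.
#' @param min_identity Emit hits only at or above this identity
#'   (aligner detectability; default 40).
#' @return List: `hits_ab`, `hits_ba`, `exon_gene_a`, `exon_gene_b`
#'   (exon id -> gene id maps), `exon_lengths` (nt).
#' @export
derive_exon_hits <- function(desc_a, desc_b, min_identity = 40) {
  ga <- .gene_exon_seqs(desc_a); gb <- .gene_exon_seqs(desc_b)
  flat <- function(gg) {
    ids <- unlist(lapply(gg, `[[`, "ids"), use.names = FALSE)
    seqs <- unlist(lapply(gg, `[[`, "seqs"), use.names = FALSE)
    genes <- rep(names(gg), vapply(gg, function(g) length(g$ids),
                                   integer(1)))
    list(ids = ids, seqs = stats::setNames(seqs, ids),
         gene = stats::setNames(genes, ids))
  }
  fa <- flat(ga); fb <- flat(gb)
  roots_b <- stats::setNames(vapply(fb$ids, .root_id, character(1)),
                             fb$ids)
  rows_ab <- list(); rows_ba <- list()
  for (ida in fa$ids) {
    idb <- fb$ids[roots_b == .root_id(ida)]
    for (idb1 in idb) {
      if (nchar(fa$seqs[[ida]]) != nchar(fb$seqs[[idb1]])) next
      ident <- .string_identity(fa$seqs[[ida]], fb$seqs[[idb1]])
      if (ident < min_identity) next
      len <- nchar(fa$seqs[[ida]])
      row <- data.frame(query_id = ida, subject_id = idb1,
                        percent_identity = ident, alignment_length = len,
                        mismatches = round(len * (1 - ident / 100)),
                        gap_opens = 0L, q_start = 1L, q_end = len,
                        s_start = 1L, s_end = len, e_value = 1e-30,
                        bitscore = round(2 * len * ident / 100, 1),
                        stringsAsFactors = FALSE)
      rows_ab[[length(rows_ab) + 1L]] <- row
      row2 <- row
      row2$query_id <- idb1; row2$subject_id <- ida
      rows_ba[[length(rows_ba) + 1L]] <- row2
    }
  }
  bind_hits <- function(rows) {
    if (length(rows)) do.call(rbind, rows) else
      stats::setNames(data.frame(matrix(ncol = 12, nrow = 0)),
                      .table_schemas$hits)
  }
  list(hits_ab = bind_hits(rows_ab), hits_ba = bind_hits(rows_ba),
       exon_gene_a = fa$gene, exon_gene_b = fb$gene,
       exon_lengths = c(nchar(fa$seqs), nchar(fb$seqs)))
}

#' Signed gene orders of a descendant pair over shared genes
#'
#' @param desc_a,desc_b Descendant `sim_genome`s.
#' @return List: `order_a`, `order_b` ([gene_order()]s over integer
#'   markers), `marker_of_a`, `marker_of_b` (gene id -> marker).
#' @export
derive_gene_orders <- function(desc_a, desc_b) {
  la <- emit_layout(desc_a); lb <- emit_layout(desc_b)
  shared <- intersect(vapply(la$genes$gene_id, .root_id, character(1)),
                      vapply(lb$genes$gene_id, .root_id, character(1)))
  markers <- stats::setNames(seq_along(shared), shared)
  map_side <- function(lay) {
    ids <- lay$genes$gene_id
    roots <- vapply(ids, .root_id, character(1))
    keep <- roots %in% shared
    stats::setNames(markers[roots[keep]], ids[keep])
  }
  ma <- map_side(la); mb <- map_side(lb)
  list(order_a = gene_order_from_annotation(la$annotation, ma),
       order_b = gene_order_from_annotation(lb$annotation, mb),
       marker_of_a = ma, marker_of_b = mb)
}

#' Signed exon orders of a descendant pair over shared exons
#'
#' @param desc_a,desc_b Descendant `sim_genome`s.
#' @return List: `order_a`, `order_b` over matched exon markers.
#' @export
derive_exon_orders <- function(desc_a, desc_b) {
  la <- emit_layout(desc_a); lb <- emit_layout(desc_b)
  roots_a <- vapply(la$exons$exon_id, .root_id, character(1))
  roots_b <- vapply(lb$exons$exon_id, .root_id, character(1))
  shared <- intersect(roots_a[!duplicated(roots_a)],
                      roots_b[!duplicated(roots_b)])
  # exons duplicated by WGD are restricted to one copy per side
  shared <- setdiff(shared, c(roots_a[duplicated(roots_a)],
                              roots_b[duplicated(roots_b)]))
  markers <- stats::setNames(seq_along(shared), shared)
  order_side <- function(lay, roots) {
    ex <- lay$exons[roots %in% shared, , drop = FALSE]
    ex$marker <- markers[roots[roots %in% shared]]
    chroms <- list()
    for (s in unique(ex$seq)) {
      sub <- ex[ex$seq == s, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      chroms[[s]] <- ifelse(sub$strand == "+", 1L, -1L) * sub$marker
    }
    gene_order(unname(chroms))
  }
  list(order_a = order_side(la, roots_a), order_b = order_side(lb, roots_b))
}
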