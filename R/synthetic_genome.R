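# Synthetic ancestral genome: multi-exon genes with domain architectures
# and planted conserved non-coding elements (CNEs) embedded in neutral
# intergenic sequence.  The internal representation keeps every feature
# (intergenic block, CNE, gene) as a unit so that structural events move
# sequence and annotation together and every estimator can be checked
# against the generator's ground truth.

.BASES <- c("A", "C", "G", "T")

.random_dna <- function(n) paste(sample(.BASES, n, replace = TRUE),
                                 collapse = "")

.revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Simulation parameters for the ancestral genome
#'
#' Defaults describe a desk-scale genome in the image of a compact
#' invertebrate chordate assembly: a few hundred multi-exon genes over a
#' handful of scaffolds, lognormal exon/intron/intergenic lengths, and
#' planted CNEs in intergenic space.
#'
#' @param n_genes Number of genes.
#' @param n_chromosomes Number of chromosomes/scaffolds.
#' @param exons_per_gene Mean of the truncated geometric distribution of
#'   exon counts (support 1..`max_exons`).
#' @param max_exons Truncation point of the exon-count distribution.
#' @param exon_len_meanlog,exon_len_sdlog Lognormal parameters of exon
#'   (CDS) lengths in bp (minimum 30).
#' @param intron_len_meanlog,intron_len_sdlog Lognormal intron lengths
#'   (minimum 60).
#' @param intergenic_len_meanlog,intergenic_len_sdlog Lognormal
#'   intergenic block lengths (minimum 150).
#' @param n_cne_planted Number of planted CNEs (placed in intergenic
#'   space, never inside genes).
#' @param cne_len_range Planted CNE length range in bp.
#' @param domain_vocab_size Number of domain types in the ancestral
#'   vocabulary.
#' @param max_domains_per_protein Maximum domains per protein.
#' @param genome_length Optional total genome length; intergenic blocks
#'   are scaled to fill it, and an error is raised when genes + CNEs
#'   alone exceed it.
#' @param seed Integer seed; identical seeds give byte-identical
#'   bundles.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(n_genes = 150, n_chromosomes = 4,
                       exons_per_gene = 5, max_exons = 15,
                       exon_len_meanlog = log(150), exon_len_sdlog = 0.4,
                       intron_len_meanlog = log(250),
                       intron_len_sdlog = 0.5,
                       intergenic_len_meanlog = log(700),
                       intergenic_len_sdlog = 0.7,
                       n_cne_planted = 60, cne_len_range = c(80, 300),
                       domain_vocab_size = 40,
                       max_domains_per_protein = 4,
                       genome_length = NULL, seed = 1) {
  p <- as.list(environment())
  stopifnot(n_genes >= 0, n_chromosomes >= 1, n_cne_planted >= 0,
            exons_per_gene >= 1, domain_vocab_size >= 2)
  class(p) <- "sim_params"
  p
}

# truncated geometric on 1..max with mean target `mean` (untruncated)
.rtgeom <- function(n, mean, max) {
  p <- 1 / mean
  out <- integer(0)
  while (length(out) < n) {
    draw <- stats::rgeom(n, p) + 1L
    out <- c(out, draw[draw <= max])
  }
  out[seq_len(n)]
}

.rlen <- function(n, meanlog, sdlog, min_len) {
  pmax(min_len, round(stats::rlnorm(n, meanlog, sdlog)))
}

#' Build a synthetic ancestral genome
#'
#' Generates chromosomes of alternating intergenic blocks, planted CNEs
#' and multi-exon genes; every gene's CDS length is a multiple of 3 (the
#' last exon is padded), so intron phases are realized by construction.
#' Each protein gets a domain architecture drawn from the ancestral
#' vocabulary.  Deterministic under the seed in `params`.
#'
#' @param params A [sim_params()].
#' @return List of class `sim_genome`: `chroms` (features), `domains`
#'   (domain table), `params`, `assembly_name`.  Use [emit_layout()] for
#'   FASTA/GFF3-level views.
#' @export
build_ancestor <- function(params = sim_params()) {
  set.seed(params$seed)
  ng <- params$n_genes
  nc <- params$n_chromosomes
  # genes --------------------------------------------------------------
  genes <- list()
  if (ng > 0) {
    n_ex <- .rtgeom(ng, params$exons_per_gene, params$max_exons)
    for (i in seq_len(ng)) {
      gid <- sprintf("g%04d", i)
      k <- n_ex[i]
      lens <- .rlen(k, params$exon_len_meanlog, params$exon_len_sdlog, 30)
      pad <- (3 - sum(lens) %% 3) %% 3
      lens[k] <- lens[k] + pad
      exons <- vapply(lens, .random_dna, character(1))
      introns <- if (k > 1)
        vapply(.rlen(k - 1, params$intron_len_meanlog,
                     params$intron_len_sdlog, 60),
               .random_dna, character(1)) else character(0)
      genes[[gid]] <- list(
        gene_id = gid, protein_id = paste0(gid, "_p"),
        strand = sample(c("+", "-"), 1L),
        exons = exons, introns = introns,
        exon_ids = paste0(gid, ".x", seq_len(k)))
    }
  }
  # planted CNEs --------------------------------------------------------
  cnes <- list()
  for (i in seq_len(params$n_cne_planted)) {
    cid <- sprintf("cne%04d", i)
    len <- sample(seq(params$cne_len_range[1], params$cne_len_range[2]), 1L)
    cnes[[cid]] <- list(kind = "cne", id = cid, seq = .random_dna(len))
  }
  # layout: round-robin genes and CNEs over chromosomes, with
  # intergenic blocks between all features
  items <- c(lapply(genes, function(g) list(kind = "gene", id = g$gene_id,
                                            gene = g)),
             cnes)
  if (length(items)) items <- items[sample(length(items))]
  chrom_of <- if (length(items))
    rep_len(seq_len(nc), length(items)) else integer(0)
  content_len <- sum(vapply(items, function(f)
    if (f$kind == "gene")
      sum(nchar(f$gene$exons)) + sum(nchar(f$gene$introns))
    else nchar(f$seq), numeric(1)))
  n_intergenic <- length(items) + nc
  ig_lens <- .rlen(n_intergenic, params$intergenic_len_meanlog,
                   params$intergenic_len_sdlog, 150)
  if (!is.null(params$genome_length)) {
    if (content_len >= params$genome_length)
      stop("infeasible length demands: genic + CNE content (",
           content_len, " bp) exceeds genome_length (",
           params$genome_length, " bp)")
    ig_lens <- pmax(20, round(ig_lens * (params$genome_length - content_len) /
                                sum(ig_lens)))
  }
  ig_i <- 0L
  next_ig <- function() {
    ig_i <<- ig_i + 1L
    list(kind = "intergenic", id = sprintf("ig%04d", ig_i),
         seq = .random_dna(ig_lens[ig_i]))
  }
  chroms <- stats::setNames(vector("list", nc),
                            sprintf("chr%02d", seq_len(nc)))
  for (ci in seq_len(nc)) {
    feats <- list(next_ig())
    for (k in which(chrom_of == ci)) {
      feats[[length(feats) + 1L]] <- items[[k]]
      feats[[length(feats) + 1L]] <- next_ig()
    }
    chroms[[ci]] <- feats
  }
  # domain architectures -------------------------------------------------
  vocab <- sprintf("D%02d", seq_len(params$domain_vocab_size))
  dom_rows <- list()
  for (g in genes) {
    plen <- sum(nchar(g$exons)) %/% 3
    nd <- sample.int(params$max_domains_per_protein, 1L)
    pos <- 5L
    for (d in seq_len(nd)) {
      dl <- sample(25:60, 1L)
      if (pos + dl > plen - 3L) break
      dom_rows[[length(dom_rows) + 1L]] <- data.frame(
        protein_id = g$protein_id,
        domain_type = sample(vocab, 1L),
        env_start = pos, env_end = pos + dl, e_value = 1e-10,
        stringsAsFactors = FALSE)
      pos <- pos + dl + sample(3:15, 1L)
    }
  }
  domains <- if (length(dom_rows)) do.call(rbind, dom_rows) else
    data.frame(protein_id = character(0), domain_type = character(0),
               env_start = numeric(0), env_end = numeric(0),
               e_value = numeric(0))
  structure(list(chroms = chroms, domains = domains, params = params,
                 assembly_name = "ancestor"),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  lay <- emit_layout(x)
  cat("<sim_genome> ", x$assembly_name, ": ", length(x$chroms),
      " chromosomes, ", nrow(lay$genes), " genes, ",
      nrow(lay$cnes), " CNEs, ",
      format(sum(nchar(lay$seqs)), big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

# sense-strand sequence of a gene (exons interleaved with introns)
.gene_sense <- function(g) {
  k <- length(g$exons)
  parts <- character(2L * k - 1L)
  parts[seq(1L, 2L * k - 1L, by = 2L)] <- g$exons
  if (k > 1L) parts[seq(2L, 2L * k - 2L, by = 2L)] <- g$introns
  paste(parts, collapse = "")
}

#' Emit the sequence/annotation layout of a simulated genome
#'
#' @param sim A `sim_genome`.
#' @return List: `seqs` (named character), `annotation`
#'   ([genome_annotation()]), `genes` (data frame of gene spans),
#'   `exons` (per-exon genomic intervals with stable exon ids), `cnes`
#'   and `intergenic` (feature intervals), all 0-based half-open.
#' @export
emit_layout <- function(sim) {
  seqs <- character(0)
  gene_models <- list()
  gene_rows <- list(); exon_rows <- list(); cne_rows <- list()
  ig_rows <- list()
  for (cn in names(sim$chroms)) {
    pos <- 0L
    parts <- character(0)
    for (f in sim$chroms[[cn]]) {
      if (f$kind == "gene") {
        g <- f$gene
        sense <- .gene_sense(g)
        L <- nchar(sense)
        emitted <- if (g$strand == "+") sense else .revcomp(sense)
        # exon intervals: cumulative over sense parts, then mapped to
        # genomic coordinates for minus-strand genes
        k <- length(g$exons)
        lens <- nchar(g$exons)
        ilens <- if (k > 1L) nchar(g$introns) else numeric(0)
        sense_starts <- cumsum(c(0, as.numeric(rbind(
          lens, c(ilens, 0)))))[seq(1L, 2L * k - 1L, by = 2L)]
        sense_ends <- sense_starts + lens
        if (g$strand == "+") {
          e_start <- pos + sense_starts
          e_end <- pos + sense_ends
        } else {
          e_start <- pos + L - sense_ends
          e_end <- pos + L - sense_starts
        }
        ord <- order(e_start)
        gene_models[[g$gene_id]] <- gene_model(
          g$gene_id, cn, g$strand,
          exons = cbind(e_start, e_end)[ord, , drop = FALSE],
          protein_id = g$protein_id,
          complete = sum(lens) %% 3 == 0)
        gene_rows[[g$gene_id]] <- data.frame(
          gene_id = g$gene_id, seq = cn, start = pos, end = pos + L,
          strand = g$strand, n_exons = k, stringsAsFactors = FALSE)
        exon_rows[[length(exon_rows) + 1L]] <- data.frame(
          exon_id = g$exon_ids, gene_id = g$gene_id, seq = cn,
          start = e_start, end = e_end, strand = g$strand,
          translation_index = seq_len(k), stringsAsFactors = FALSE)
        parts <- c(parts, emitted)
        pos <- pos + L
      } else {
        L <- nchar(f$seq)
        row <- data.frame(id = f$id, seq = cn, start = pos, end = pos + L,
                          stringsAsFactors = FALSE)
        if (f$kind == "cne") cne_rows[[f$id]] <- row
        else ig_rows[[f$id]] <- row
        parts <- c(parts, f$seq)
        pos <- pos + L
      }
    }
    seqs[cn] <- paste(parts, collapse = "")
  }
  bind <- function(rows, proto) if (length(rows)) do.call(rbind, rows)
    else proto
  genes_df <- bind(gene_rows, data.frame(gene_id = character(0),
                                         seq = character(0),
                                         start = numeric(0),
                                         end = numeric(0),
                                         strand = character(0),
                                         n_exons = integer(0)))
  rownames(genes_df) <- NULL
  exons_df <- bind(exon_rows, data.frame(exon_id = character(0),
                                         gene_id = character(0),
                                         seq = character(0),
                                         start = numeric(0),
                                         end = numeric(0),
                                         strand = character(0),
                                         translation_index = integer(0)))
  rownames(exons_df) <- NULL
  cnes_df <- bind(cne_rows, data.frame(id = character(0), seq = character(0),
                                       start = numeric(0), end = numeric(0)))
  rownames(cnes_df) <- NULL
  igs_df <- bind(ig_rows, data.frame(id = character(0), seq = character(0),
                                     start = numeric(0), end = numeric(0)))
  rownames(igs_df) <- NULL
  ann <- genome_annotation(stats::setNames(nchar(seqs), names(seqs)),
                           gene_models, assembly_name = sim$assembly_name)
  list(seqs = seqs, annotation = ann, genes = genes_df, exons = exons_df,
       cnes = cnes_df, intergenic = igs_df)
}

#' Write a simulated genome bundle to files
#'
#' Emits FASTA, GFF3, a planted-CNE BED, and the domain table.
#'
#' @param sim A `sim_genome`.
#' @param dir Output directory (created if needed).
#' @return Named list of paths, invisibly.
#' @export
write_sim_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lay <- emit_layout(sim)
  paths <- list(
    fasta = file.path(dir, paste0(sim$assembly_name, ".fa")),
    gff3 = file.path(dir, paste0(sim$assembly_name, ".gff3")),
    cne_bed = file.path(dir, paste0(sim$assembly_name, ".cne.bed")),
    domains = file.path(dir, paste0(sim$assembly_name, ".domains.tsv")))
  write_fasta(lay$seqs, paths$fasta)
  write_gff3(lay$annotation, paths$gff3)
  write_bed(data.frame(chrom = lay$cnes$seq, start = lay$cnes$start,
                       end = lay$cnes$end, name = lay$cnes$id),
            paths$cne_bed)
  utils::write.table(sim$domains, paths$domains, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
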