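# End-to-end synthetic study driver: simulate an ancestor and two
# descendant lineages, then run orthology, rearrangement rates, exon
# phase statistics, domain-pair turnover, CNE refinement and diploid
# polymorphism, and write a versioned machine-readable report.

REPORT_SCHEMA_VERSION <- "1.0"

#' Default pipeline configuration
#'
#' @return Nested list understood by [run_pipeline()]: `sim` holds
#'   [sim_params()] arguments, `lineage_a`/`lineage_b` hold
#'   [lineage_params()] arguments, `diploid` holds [diploid_params()]
#'   arguments, `orthology` the RBH cutoffs.
#' @export
default_pipeline_config <- function() {
  list(
    sim = list(n_genes = 80, n_chromosomes = 4, n_cne_planted = 40),
    lineage_a = list(subst_rate = 0.35, n_inversions = 4,
                     n_translocations = 2, n_exon_shuffles = 5,
                     phase11_preference = 0.3, domain_pair_gain = 4,
                     domain_pair_loss = 2),
    lineage_b = list(subst_rate = 0.35, n_inversions = 4,
                     n_translocations = 2, n_exon_shuffles = 5,
                     phase11_preference = 0.3, domain_pair_gain = 4,
                     domain_pair_loss = 2),
    diploid = list(snp_rate = 0.0439, small_indel_rate = 0.0098),
    orthology = list(min_identity = 60, min_coverage = 40),
    divergence_time_myr = 120)
}

.log_stage <- function(...) {
  message(format(Sys.time(), "%H:%M:%S"), " [chordevo] ", ...)
}

#' Run the full synthetic study pipeline
#'
#' Stages: simulate (ancestor + two lineages + diploid), orthology,
#' DCJ rearrangement rates, exon phases and shuffled-exon detection,
#' domain-pair turnover, CNE calling/refinement, polymorphism summary.
#' The run is a pure function of the configuration and seed; the report
#' JSON is byte-identical across repeats.
#'
#' @param config Configuration list (see [default_pipeline_config()]) or
#'   path to a YAML file with the same structure.
#' @param seed Integer master seed.
#' @param out_dir Output directory for the report bundle; `NULL` writes
#'   nothing.
#' @return The report (list), invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(config = default_pipeline_config(), seed = 1,
                         out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_pipeline_config()
  for (nm in names(base))
    if (!is.null(config[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- utils::modifyList(base[[nm]], config[[nm]])
    else if (!is.null(config[[nm]])) base[[nm]] <- config[[nm]]
  config <- base

  .log_stage("simulate: building ancestor")
  anc <- build_ancestor(do.call(sim_params,
                                c(config$sim, list(seed = seed))))
  .log_stage("simulate: evolving lineages")
  lin_a <- evolve_lineage(anc, do.call(lineage_params, config$lineage_a),
                          seed = seed + 1L, name = "lineage_A")
  lin_b <- evolve_lineage(anc, do.call(lineage_params, config$lineage_b),
                          seed = seed + 2L, name = "lineage_B")
  A <- lin_a$genome; B <- lin_b$genome

  .log_stage("orthology: deriving hits and running RBH")
  hits <- derive_protein_hits(A, B)
  orth <- rbh_orthologs(hits$hits_ab, hits$hits_ba, hits$gene_of,
                        hits$protein_lengths,
                        min_identity = config$orthology$min_identity,
                        min_coverage = config$orthology$min_coverage)

  .log_stage("rearrangement: DCJ distance and rates")
  orders <- derive_gene_orders(A, B)
  dcj <- dcj_distance(orders$order_a, orders$order_b)
  mean_ident <- if (nrow(orth$pairs)) mean(orth$pairs$identity) else NA
  pdist <- if (!is.na(mean_ident) && mean_ident < 100)
    -log(mean_ident / 100) else NA
  rates <- if (!is.na(pdist) && pdist > 0)
    relative_rates(dcj, pdist, config$divergence_time_myr) else NULL

  .log_stage("exons: phases, spectrum, shuffled exons, subgenic DCJ")
  lay_a <- emit_layout(A)
  phases_a <- annotate_phases(lay_a$annotation)
  spectrum <- phase_spectrum(phases_a, min_len_bp = 100)
  ex_hits <- derive_exon_hits(A, B)
  shuffled <- detect_shuffled_exons(ex_hits$hits_ab, ex_hits$hits_ba,
                                    orth, ex_hits$exon_gene_a,
                                    ex_hits$exon_gene_b,
                                    exon_lengths = ex_hits$exon_lengths)
  ex_orders <- derive_exon_orders(A, B)
  sub_dcj <- subgenic_dcj(ex_orders$order_a, ex_orders$order_b,
                          orders$order_a, orders$order_b)

  .log_stage("domains: pair turnover")
  pairs_a <- extract_pairs(A$domains)
  pairs_b <- extract_pairs(B$domains)
  pairs_anc <- extract_pairs(anc$domains)
  novel_a <- setdiff(pairs_a, pairs_anc)
  novel_b <- setdiff(pairs_b, pairs_anc)

  .log_stage("cne: coarse call and refinement")
  blocks <- derive_alignment(A, B)
  cand <- coarse_cnes(blocks, lay_a$annotation)
  refinement <- refine_cnes(cand, lay_a$annotation)

  .log_stage("popgen: diploid polymorphism")
  dip <- make_diploid(emit_layout(A)$seqs,
                      do.call(diploid_params,
                              c(config$diploid, list(seed = seed + 3L))))
  called <- call_variants(dip$blocks)
  poly <- summarize_polymorphism(called,
                                 genome_length = sum(nchar(dip$hap_a)))
  spc <- tryCatch(spacing_fit(called[called$type == "snp", , drop = FALSE]),
                  error = function(e) NULL)

  report <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    seed = seed,
    orthology = list(n_pairs = nrow(orth$pairs),
                     mean_identity = mean_ident,
                     n_unpaired_a = length(orth$unpaired_a),
                     n_unpaired_b = length(orth$unpaired_b)),
    rearrangement = list(d = dcj$d, n_markers = dcj$N,
                         rho = dcj$per_marker_rate,
                         relative_rate = if (!is.null(rates))
                           rates$relative else NA,
                         per_time_myr = if (!is.null(rates))
                           rates$per_time_myr else NA),
    exons = list(
      n_internal = spectrum$n,
      prop_symmetric = as.list(stats::setNames(
        spectrum$symmetric$proportion, spectrum$symmetric$class)),
      n_shuffled_detected = nrow(shuffled),
      n_shuffles_planted =
        sum(vapply(lin_a$log, function(e)
          e$kind == "exon_shuffle", logical(1))) +
        sum(vapply(lin_b$log, function(e)
          e$kind == "exon_shuffle", logical(1))),
      subgenic_contribution = sub_dcj$contribution),
    domains = list(n_pairs_a = length(pairs_a),
                   n_pairs_b = length(pairs_b),
                   novel_a = length(novel_a), novel_b = length(novel_b)),
    cne = list(coarse_count = nrow(cand),
               refined_count = refinement$summary$refined_count,
               refined_length = refinement$summary$refined_length,
               refined_pct = refinement$summary$refined_pct,
               mean_length = refinement$summary$mean_length),
    polymorphism = list(snp_rate_pct = poly$snp_rate_pct,
                        small_indel_event_rate_pct =
                          poly$small_indel_event_rate_pct,
                        small_indel_length_pct =
                          poly$small_indel_length_pct,
                        spacing_p_hat = if (!is.null(spc)) spc$p_hat
                          else NA,
                        spacing_gof_p = if (!is.null(spc)) spc$p_value
                          else NA))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(orth$pairs, file.path(out_dir, "orthology.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame.table(spectrum$counts,
                                           responseName = "count"),
                       file.path(out_dir, "phase_spectrum.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_bed(data.frame(chrom = refinement$refined$ref_seq,
                         start = refinement$refined$ref_start,
                         end = refinement$refined$ref_end,
                         name = refinement$refined$id),
              file.path(out_dir, "cne_refined.bed"))
    .log_stage("report written to ", out_dir)
    return(invisible(report))
  }
  report
}
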