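#' Run the full synthetic-virome analysis pipeline
#'
#' Executes the stages in dependency order -- community synthesis, viral
#' screening, genus clustering, spacer-database construction, host
#' prediction, ecology, and Hi-C validation -- writing each stage's tables
#' under `out_dir` and returning a manifest. All randomness derives from
#' `cfg$seed`, so a rerun with the same configuration produces identical
#' files.
#'
#' @param cfg A [synth_config()] object.
#' @param out_dir Output directory.
#' @param criteria_mode Screening criteria mode, see [screen_vpf()].
#' @param score_threshold Genus-clustering edge threshold, see
#'   [assign_genera()].
#' @param thresholds Spacer-match thresholds, see [match_thresholds()].
#' @param crt CRISPR detector parameters, see [crt_params()].
#' @param hic_min_count,hic_dominance_ratio Hi-C deconvolution settings,
#'   see [hic_deconvolve()].
#' @return A list with `manifest` (data frame: stage, outputs, md5) and
#'   the in-memory stage results.
#' @export
run_pipeline <- function(cfg = synth_config(), out_dir,
                         criteria_mode = "any", score_threshold = 1,
                         thresholds = match_thresholds(),
                         crt = crt_params(),
                         hic_min_count = 5L, hic_dominance_ratio = 2) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_files <- list()
  p <- function(f) file.path(out_dir, f)

  ## 1. synth
  comm <- gen_community(cfg)
  stage_files$synth <- unname(write_community(comm, p("synth")))

  ## 2. screen
  all_contigs <- c(comm$viruses, comm$hosts)
  counts <- contig_annotation_counts(comm$annotation, nchar(all_contigs))
  counts$vpf_viral <- screen_vpf(counts, criteria_mode)
  lca <- lca_assign_all(comm$taxhits)
  lca_viral <- lca$contig_id[startsWith(lca$lineage, "Viruses")]
  viral_ids <- merge_viral_sets(counts$contig_id[counts$vpf_viral],
                                lca_viral)
  decision <- merge(counts, lca, by = "contig_id", all.x = TRUE)
  decision$lca_viral <- decision$contig_id %in% lca_viral
  decision$viral <- decision$contig_id %in% viral_ids
  stage_files$screen <- c(
    write_tsv(decision, p("screen_decisions.tsv")),
    write_tsv(data.frame(contig_id = viral_ids), p("viral_contigs.tsv")))
  viral_contigs <- comm$viruses[intersect(names(comm$viruses), viral_ids)]

  ## 3. cluster
  vir_genes <- comm$gene_map[comm$gene_map$contig_id %in% names(viral_contigs), ]
  pcs <- cluster_proteins(comm$proteins[vir_genes$gene_id])
  pc_map <- merge(pcs, comm$gene_map, by.x = "protein_id", by.y = "gene_id")
  gen <- assign_genera(pc_map, score_threshold,
                       contigs = names(viral_contigs))
  stage_files$cluster <- c(
    write_tsv(gen$assignment, p("genus_assignment.tsv")),
    write_tsv(gen$edges, p("genus_network_edges.tsv")))

  ## 4. spacers
  spacer_db <- build_spacer_db(comm$hosts, comm$host_lineage, crt)
  stage_files$spacers <- write_tsv(spacer_db, p("spacer_db.tsv"))

  ## 5. hosts
  links <- predict_hosts(viral_contigs, spacer_db, thresholds)
  host_range <- classify_host_range(links)
  functions <- map_functions(links, comm$function_table)
  stage_files$hosts <- c(
    write_tsv(links, p("virus_host_links.tsv")),
    write_tsv(host_range, p("host_range.tsv")),
    write_tsv(functions, p("host_functions.tsv")))

  ## 6. ecology
  genus_map <- stats::setNames(gen$assignment$genus,
                               gen$assignment$contig_id)
  cov <- comm$coverage[comm$coverage$contig_id %in% names(viral_contigs), ]
  ab <- relative_abundance(cov, nchar(comm$viruses), genus_map)
  div <- data.frame(
    sample_id = colnames(ab$abundance),
    shannon = apply(ab$abundance, 2, shannon),
    pielou = apply(ab$abundance, 2, pielou),
    n_genera = colSums(ab$presence), row.names = NULL)
  D <- bray_curtis_matrix(ab$abundance)
  ord <- pcoa_ord(D, k = min(2, max(1, ncol(ab$abundance) - 1)))
  core <- core_shared_genera(ab$presence)
  stage_files$ecology <- c(
    write_tsv(data.frame(genus = rownames(ab$abundance), ab$abundance,
                         check.names = FALSE), p("abundance_matrix.tsv")),
    write_tsv(div, p("diversity.tsv")),
    write_tsv(data.frame(sample_id = rownames(ord$points), ord$points,
                         check.names = FALSE), p("pcoa_coordinates.tsv")),
    write_tsv(core$counts, p("upset_counts.tsv")))

  ## 7. hic
  hic_links <- hic_deconvolve(comm$hic, hic_min_count, hic_dominance_ratio)
  crispr_bins <- links[, c("contig_id", "genome_id")]
  names(crispr_bins) <- c("virus_id", "genome_id")
  crispr_bins$bin_id <- comm$bin_membership$bin_id[
    match(crispr_bins$genome_id, comm$bin_membership$genome_id)]
  cmpres <- compare_with_crispr(
    crispr_bins[, c("virus_id", "bin_id")], hic_links)
  hic_summary <- data.frame(
    n_crispr = cmpres$n_crispr, n_detected = cmpres$n_detected,
    n_same = cmpres$n_same, n_different = cmpres$n_different,
    precision = cmpres$precision)
  stage_files$hic <- c(
    write_tsv(hic_links, p("hic_links.tsv")),
    write_tsv(hic_summary, p("hic_summary.tsv")))

  manifest <- data.frame(
    stage = names(stage_files),
    outputs = vapply(stage_files, paste, character(1), collapse = ";"),
    md5 = vapply(stage_files, function(fs)
      paste(unname(tools::md5sum(fs)), collapse = ";"), character(1)),
    row.names = NULL)
  manifest$seed <- cfg$seed
  write_tsv(manifest, p("manifest.tsv"))

  list(manifest = manifest, community = comm, screened = viral_ids,
       genus = gen, spacer_db = spacer_db, links = links,
       host_range = host_range, abundance = ab, diversity = div,
       ordination = ord, core = core, hic_links = hic_links,
       hic_summary = cmpres)
}
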