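#' Generate and write a complete synthetic study
#'
#' Convenience driver over [generate_counts()], [generate_genotypes()] and
#' [generate_annotations()]: simulates every input the pipeline consumes
#' and writes them in their standard on-disk formats (profile TSVs,
#' minimal VCF, GFF3, FASTA, headered TSVs for QTL/GO/pathway tables),
#' plus the ground truth as JSON.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory.
#' @param causal_maf_min passed to [generate_genotypes()].
#' @return list with the in-memory objects (profile, genotypes, traits,
#'   annotations, truth) and \code{paths} to everything written.
#' @export
write_synthetic_study <- function(cfg, dir, causal_maf_min = 0.2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_counts(cfg)
  hubs <- sim$truth$hub_genus_ids
  traits <- if (length(hubs)) hub_abundances(sim$profile, hubs) else
    matrix(stats::rnorm(cfg$n_samples), ncol = 1,
           dimnames = list(rownames(sim$profile$counts), "trait1"))
  gg <- generate_genotypes(cfg, traits, causal_maf_min = causal_maf_min)
  ann <- generate_annotations(cfg, gg$genotypes,
                              causal_snps = gg$truth$causal_snp_ids)

  paths <- list(
    profile_dir = file.path(dir, "profile"),
    vcf = file.path(dir, "genotypes.vcf"),
    gff = file.path(dir, "genes.gff3"),
    ref_fasta = file.path(dir, "reference.fa"),
    qtl_tsv = file.path(dir, "qtls.tsv"),
    go_tsv = file.path(dir, "go_annotation.tsv"),
    weights_tsv = file.path(dir, "pathway_weights.tsv"),
    hierarchy_tsv = file.path(dir, "pathway_hierarchy.tsv"),
    traits_tsv = file.path(dir, "hub_traits.tsv"),
    truth_json = file.path(dir, "truth.json"))

  write_profile(sim$profile, paths$profile_dir)
  write_vcf(ann$genotypes, paths$vcf)
  write_gff3(ann$gene_models, paths$gff)
  write_fasta(ann$reference, paths$ref_fasta)
  write_tsv(ann$qtls, paths$qtl_tsv)
  write_tsv(ann$go_annotation, paths$go_tsv)
  write_tsv(data.frame(genus = rownames(ann$pathway_weights$weights),
                       ann$pathway_weights$weights, check.names = FALSE),
            paths$weights_tsv)
  write_tsv(ann$pathway_weights$hierarchy, paths$hierarchy_tsv)
  write_tsv(data.frame(sample = rownames(gg$traits), gg$traits,
                       check.names = FALSE), paths$traits_tsv)

  truth <- list(hub_genus_ids = sim$truth$hub_genus_ids,
                causal_snp_ids = gg$truth$causal_snp_ids,
                causal_trait_map = as.list(gg$truth$causal_trait_map))
  jsonlite::write_json(truth, paths$truth_json, auto_unbox = TRUE,
                       pretty = TRUE)

  list(profile = sim$profile, genotypes = ann$genotypes,
       traits = gg$traits, annotations = ann,
       truth = c(sim$truth, gg$truth), paths = paths)
}
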