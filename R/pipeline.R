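#' Pipeline configuration
#'
#' Paths to the six stage inputs plus every stage parameter, with the
#' defaults used throughout the package. Any field can be overridden.
#'
#' @param profile_dir directory holding counts.tsv / lineage.tsv /
#'   metadata.tsv (see [write_profile()]).
#' @param vcf,gff,ref_fasta,qtl_tsv,go_tsv,weights_tsv,hierarchy_tsv
#'   input paths for the association / follow-up stages (any may be NULL
#'   to stop the pipeline after the stages that need them).
#' @param out_dir output directory.
#' @param min_prevalence,min_abundance,min_abs_r,n_permutations,fdr_alpha,
#'   hubs_k,min_maf,sig_threshold,use_fdr,block_window,seed stage
#'   parameters (documented on the stage functions).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(profile_dir, out_dir,
                            vcf = NULL, gff = NULL, ref_fasta = NULL,
                            qtl_tsv = NULL, go_tsv = NULL,
                            weights_tsv = NULL, hierarchy_tsv = NULL,
                            traits_tsv = NULL,
                            min_prevalence = 0.5, min_abundance = 0.01,
                            min_abs_r = 0.3, n_permutations = 50L,
                            fdr_alpha = 0.05, hubs_k = 12L, min_maf = 0.05,
                            sig_threshold = 0.05, use_fdr = TRUE,
                            block_window = 1e5, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

stage_hash <- function(params, input_files) {
  files <- input_files[!vapply(input_files, is.null, logical(1))]
  sums <- if (length(files)) unname(tools::md5sum(unlist(files))) else
    character(0)
  key <- paste(c(vapply(params, function(p) paste(format(p), collapse = ","),
                        character(1)), sums), collapse = "|")
  ## cheap stable hash of the key string
  sprintf("%08x", sum(utf8ToInt(key) * (seq_along(utf8ToInt(key)) %% 97 + 1)))
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes the stages profile -> diversity -> network/hubs -> functions
#' -> gwas -> blocks from one configuration, writing each stage's tables
#' under \code{out_dir} and a manifest (parameter snapshot plus md5
#' checksum of every produced file). A stage whose parameter+input hash
#' matches the existing manifest and whose outputs are still present is
#' skipped, so re-runs with an unchanged configuration recompute nothing
#' and changing one stage's parameters invalidates only that stage and
#' the ones downstream of it.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (invisibly), also written to
#'   \code{out_dir/manifest.json}.
#' @export
run_all <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  old_manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else NULL
  manifest <- list(version = as.character(utils::packageVersion("phyllonet")),
                   parameters = cfg[!(names(cfg) %in% c("out_dir"))],
                   stages = list())

  cached <- function(stage, hash) {
    st <- old_manifest$stages[[stage]]
    !is.null(st) && identical(st$hash, hash) &&
      all(file.exists(file.path(cfg$out_dir, names(st$outputs))))
  }
  record <- function(stage, hash, outputs, elapsed) {
    sums <- as.list(tools::md5sum(file.path(cfg$out_dir, outputs)))
    names(sums) <- outputs
    manifest$stages[[stage]] <<- list(hash = hash, outputs = sums,
                                      elapsed_s = round(elapsed, 3))
  }
  run_stage <- function(stage, params, inputs, outputs, fn) {
    hash <- stage_hash(params, inputs)
    if (cached(stage, hash)) {
      manifest$stages[[stage]] <<- old_manifest$stages[[stage]]
      message(sprintf("[%s] cached", stage))
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    fn()
    record(stage, hash, outputs, proc.time()[["elapsed"]] - t0)
    message(sprintf("[%s] done", stage))
  }
  op <- function(...) file.path(cfg$out_dir, ...)

  ## -- stage 1: profile ----------------------------------------------
  profile <- read_profile(cfg$profile_dir)
  run_stage("profile", cfg["min_abundance"],
            list(file.path(cfg$profile_dir, "counts.tsv")),
            c("relative_abundance_genus.tsv", "relative_abundance_phylum.tsv",
              "abundant_taxa.tsv"), function() {
    rel_g <- relative_abundance(profile, "genus")
    rel_p <- relative_abundance(profile, "phylum")
    write_tsv(data.frame(sample = rownames(rel_g), rel_g,
                         check.names = FALSE), op("relative_abundance_genus.tsv"))
    write_tsv(data.frame(sample = rownames(rel_p), rel_p,
                         check.names = FALSE), op("relative_abundance_phylum.tsv"))
    write_tsv(data.frame(
      taxon = c(abundance_filter(rel_g, cfg$min_abundance),
                abundance_filter(rel_p, cfg$min_abundance)),
      rank = c(rep("genus", length(abundance_filter(rel_g, cfg$min_abundance))),
               rep("phylum", length(abundance_filter(rel_p, cfg$min_abundance))))),
      op("abundant_taxa.tsv"))
  })

  ## -- stage 2: diversity --------------------------------------------
  run_stage("diversity", cfg["seed"],
            list(file.path(cfg$profile_dir, "counts.tsv")),
            c("diversity_per_sample.tsv", "diversity_by_group.tsv",
              "accumulation_curve.tsv", "diversity_tests.tsv",
              "simper.tsv"), function() {
    ds <- diversity_summary(profile)
    write_tsv(ds$per_sample, op("diversity_per_sample.tsv"))
    write_tsv(ds$by_group, op("diversity_by_group.tsv"))
    write_tsv(accumulation_curve(profile, n_permutations = 50,
                                 seed = cfg$seed), op("accumulation_curve.tsv"))
    kw_r <- kruskal_wallis(ds$per_sample$richness, ds$per_sample$group)
    kw_s <- kruskal_wallis(ds$per_sample$shannon, ds$per_sample$group)
    write_tsv(data.frame(metric = c("richness", "shannon"),
                         H = c(kw_r$H, kw_s$H),
                         p = c(kw_r$p.value, kw_s$p.value)),
              op("diversity_tests.tsv"))
    rel <- relative_abundance(profile, "genus")
    sp <- simper(rel, profile$metadata$location)
    write_tsv(sp$contributions, op("simper.tsv"))
  })

  ## -- stage 3: network / hubs ---------------------------------------
  net_params <- cfg[c("min_prevalence", "min_abs_r", "n_permutations",
                      "fdr_alpha", "hubs_k", "seed")]
  run_stage("network", net_params,
            list(file.path(cfg$profile_dir, "counts.tsv")),
            c("edges.tsv", "node_metrics.tsv", "hubs.tsv",
              "network_summary.tsv"), function() {
    pf <- prevalence_filter(profile, cfg$min_prevalence)
    clr <- clr_transform(pf$counts)
    net <- infer_edges(clr, min_abs_r = cfg$min_abs_r,
                       n_permutations = cfg$n_permutations,
                       fdr_alpha = cfg$fdr_alpha, seed = cfg$seed)
    met <- node_metrics(net)
    mod <- detect_modules(net, seed = cfg$seed)
    hub <- score_hubs(met, k = min(cfg$hubs_k, nrow(met)),
                      modules = mod$membership)
    write_tsv(net$edges, op("edges.tsv"))
    write_tsv(hub$scores, op("node_metrics.tsv"))
    write_tsv(hub$scores[hub$scores$is_hub, ], op("hubs.tsv"))
    s <- network_summary(net, mod)
    write_tsv(data.frame(metric = names(s), value = unname(s)),
              op("network_summary.tsv"))
  })
  hubs <- utils::read.delim(op("hubs.tsv"), stringsAsFactors = FALSE)$node

  ## -- stage 4: functions --------------------------------------------
  if (!is.null(cfg$weights_tsv)) {
    run_stage("functions", cfg["min_abundance"],
              list(cfg$weights_tsv, file.path(cfg$profile_dir, "counts.tsv")),
              c("function_profile.tsv", "abundant_pathways.tsv",
                "function_comparison.tsv"), function() {
      w <- read_pathway_weights(cfg$weights_tsv, cfg$hierarchy_tsv)
      rel <- relative_abundance(profile, "genus")
      fp <- project_functions(rel, w)
      write_tsv(data.frame(sample = rownames(fp), fp, check.names = FALSE),
                op("function_profile.tsv"))
      write_tsv(data.frame(pathway = abundance_filter(fp, cfg$min_abundance)),
                op("abundant_pathways.tsv"))
      grp <- split(rownames(fp), profile$metadata$location)
      cmp <- compare_function_profiles(fp[grp[[1]], , drop = FALSE],
                                       fp[grp[[2]], , drop = FALSE])
      write_tsv(data.frame(W = cmp$statistic, p = cmp$p.value,
                           n_pathways = cmp$n_pathways),
                op("function_comparison.tsv"))
    })
  }

  ## -- stage 5: gwas --------------------------------------------------
  if (!is.null(cfg$vcf)) {
    gwas_params <- cfg[c("min_maf", "sig_threshold", "use_fdr", "hubs_k",
                         "min_prevalence", "min_abs_r", "fdr_alpha", "seed")]
    run_stage("gwas", gwas_params,
              list(cfg$vcf, file.path(cfg$profile_dir, "counts.tsv"),
                   cfg$traits_tsv, op("hubs.tsv")),
              c("association_per_trait.tsv", "association_per_snp.tsv",
                "significant_snps.tsv", "haplotype_contrasts.tsv"),
              function() {
      geno <- read_vcf(cfg$vcf)
      common <- intersect(rownames(geno$dosage), rownames(profile$counts))
      geno <- genotype_matrix(geno$dosage[common, , drop = FALSE], geno$map)
      traits <- if (!is.null(cfg$traits_tsv)) {
        tt <- utils::read.delim(cfg$traits_tsv, check.names = FALSE,
                                stringsAsFactors = FALSE)
        tm <- as.matrix(tt[, -1, drop = FALSE])
        rownames(tm) <- tt[[1]]
        tm
      } else hub_abundances(profile, hubs)
      traits <- traits[common, , drop = FALSE]
      K <- kinship(geno)
      scan <- scan_hub_traits(geno, traits, K, min_maf = cfg$min_maf)
      gm <- if (!is.null(cfg$gff)) read_gene_models(cfg$gff) else NULL
      sig <- call_significant(scan, p_threshold = cfg$sig_threshold,
                              use_fdr = cfg$use_fdr, gene_models = gm)
      write_tsv(scan$per_trait, op("association_per_trait.tsv"))
      write_tsv(scan$per_snp, op("association_per_snp.tsv"))
      write_tsv(sig, op("significant_snps.tsv"))
      hap <- if (nrow(sig) > 0) {
        haplotype_abundance_test(geno, sig$snp, rowMeans(traits))
      } else data.frame()
      write_tsv(hap, op("haplotype_contrasts.tsv"))
    })
  }

  ## -- stage 6: haplotype blocks / follow-up --------------------------
  if (!is.null(cfg$vcf) && !is.null(cfg$gff)) {
    run_stage("blocks", cfg[c("block_window", "sig_threshold", "use_fdr")],
              list(cfg$vcf, cfg$gff, cfg$qtl_tsv, cfg$go_tsv,
                   op("significant_snps.tsv")),
              c("haploblocks.tsv", "candidate_genes.tsv", "qtl_overlap.tsv",
                "go_enrichment.tsv"), function() {
      sig <- utils::read.delim(op("significant_snps.tsv"),
                               stringsAsFactors = FALSE)
      gm <- read_gene_models(cfg$gff)
      if (nrow(sig) == 0) {
        for (f in c("haploblocks.tsv", "candidate_genes.tsv",
                    "qtl_overlap.tsv", "go_enrichment.tsv")) {
          write_tsv(data.frame(), op(f))
        }
        return(invisible(NULL))
      }
      geno <- read_vcf(cfg$vcf)
      blocks <- blocks_around(geno, sig$snp, window = cfg$block_window)
      write_tsv(blocks, op("haploblocks.tsv"))
      cand <- genes_in_blocks(blocks, gm)
      write_tsv(cand, op("candidate_genes.tsv"))
      if (!is.null(cfg$qtl_tsv) && nrow(cand) > 0) {
        qtls <- utils::read.delim(cfg$qtl_tsv, stringsAsFactors = FALSE)
        gr <- gm$genes[match(unique(cand$gene), gm$genes$ID)]
        iv <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                         start = GenomicRanges::start(gr),
                         end = GenomicRanges::end(gr), id = gr$ID,
                         stringsAsFactors = FALSE)
        qo <- qtl_overlap(iv, qtls)
        write_tsv(data.frame(category = names(qo$counts),
                             n_qtls = unname(qo$counts)), op("qtl_overlap.tsv"))
      } else write_tsv(data.frame(), op("qtl_overlap.tsv"))
      if (!is.null(cfg$go_tsv) && nrow(cand) > 0) {
        go <- utils::read.delim(cfg$go_tsv, stringsAsFactors = FALSE)
        enr <- hypergeometric_enrichment(unique(cand$gene), go,
                                         unique(gm$genes$ID))
        write_tsv(enr, op("go_enrichment.tsv"))
      } else write_tsv(data.frame(), op("go_enrichment.tsv"))
    })
  }

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
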