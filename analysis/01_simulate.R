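#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study all later stages analyse.
#
# The generator emulates the structure of a two-location rice
# leaf-microbiome survey built from host WGS unmapped reads: heavy-tailed
# genus abundances, five planted co-occurrence hubs, sporadic
# location-private genera, inbred genotypes in LD blocks and three SNPs
# that causally shift hub abundances on the CLR scale. Everything is
# written in plain interchange formats (TSV/VCF/GFF3/FASTA) under
# results/synthetic_study/, with the planted truth in truth.json.

suppressPackageStartupMessages(library(phyllonet))

seed <- as.integer(Sys.getenv("PHYLLONET_SEED", "1"))
out <- "results/synthetic_study"

cfg <- synth_config(n_samples = 300, n_genera = 200, n_hubs = 5,
                    hub_loading = 1.0, n_snps = 2000, n_blocks = 100,
                    n_causal = 3, causal_effect = 1.0,
                    maf_range = c(0.2, 0.5), seed = seed)
print(cfg)

st <- write_synthetic_study(cfg, out)

cat(sprintf("\nwrote study to %s\n", out))
cat(sprintf("  %d samples x %d genera, depth %d-%d\n",
            nrow(st$profile$counts), ncol(st$profile$counts),
            min(st$profile$metadata$total_reads),
            max(st$profile$metadata$total_reads)))
cat(sprintf("  planted hubs: %s\n",
            paste(st$truth$hub_genus_ids, collapse = ", ")))
cat(sprintf("  causal SNPs: %s\n",
            paste(st$truth$causal_snp_ids, collapse = ", ")))
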