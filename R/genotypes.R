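#' Genotype matrix container
#'
#' Samples x SNPs allele-dosage matrix (0/1/2, NA allowed) plus a SNP map
#' (chromosome, 1-based position, ref/alt alleles, minor-allele frequency).
#'
#' @param dosage samples x SNPs numeric matrix with dimnames.
#' @param map data.frame: snp, chrom, pos, ref, alt.
#' @return object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(dosage, map) {
  stop_if_not(is.matrix(dosage), "dosage must be a matrix")
  stop_if_not(all(dosage %in% c(0, 1, 2) | is.na(dosage)),
              "dosages must be 0/1/2 or NA")
  stop_if_not(ncol(dosage) == nrow(map), "map must have one row per SNP")
  stop_if_not(all(colnames(dosage) == map$snp), "map order must match columns")
  ord_ok <- all(tapply(map$pos, map$chrom, function(p) !is.unsorted(p)))
  stop_if_not(ord_ok, "positions must be sorted within chromosome")
  map$maf <- apply(dosage, 2, dosage_maf)
  structure(list(dosage = dosage, map = map), class = "genotype_matrix")
}

dosage_maf <- function(d) {
  p <- mean(d, na.rm = TRUE) / 2
  min(p, 1 - p)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype matrix: %d samples x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom))))
  invisible(x)
}

#' Write genotypes as a minimal VCF
#'
#' VCFv4.2, GT-only FORMAT, unphased diploid calls derived from dosages
#' (0 -> 0/0, 1 -> 0/1, 2 -> 1/1, NA -> ./.).
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output .vcf path.
#' @export
write_vcf <- function(genotypes, path) {
  d <- genotypes$dosage; map <- genotypes$map
  gt <- matrix("./.", nrow = ncol(d), ncol = nrow(d))
  gt[t(d) == 0] <- "0/0"; gt[t(d) == 1] <- "0/1"; gt[t(d) == 2] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(d)), collapse = "\t"))
  body <- vapply(seq_len(ncol(d)), function(j) {
    paste(c(map$chrom[j], map$pos[j], map$snp[j], map$ref[j], map$alt[j],
            ".", "PASS", ".", "GT", gt[j, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a GT-only VCF into a genotype matrix
#'
#' Uses vcfR for parsing; any ploidy-2 GT call is converted to an alt
#' dosage, missing calls to NA.
#'
#' @param path .vcf file.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")   # variants x samples
  to_dosage <- function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_real_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
  }
  dosage <- t(matrix(vapply(gt, to_dosage, numeric(1)),
                     nrow = nrow(gt), dimnames = dimnames(gt)))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  map <- data.frame(snp = fix$ID, chrom = fix$CHROM,
                    pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                    stringsAsFactors = FALSE)
  colnames(dosage) <- map$snp
  genotype_matrix(dosage, map)
}
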