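# Writers and readers for the standard formats the pipeline consumes:
# VCF 4.2 for rare genotypes, TSV for annotations/phenotypes/weights/dosages,
# CSV for the phecode map, YAML + TSV for the simulation truth record.

#' Write rare-variant genotypes as VCF 4.2
#'
#' Emits GT:GQ:DP per call. Hemizygous male X genotypes are written
#' haploid-as-homozygous (`1/1`), the convention the reader reverses through
#' sample sex.
#'
#' @param rare rare-genotype list (`gt`, `gq`, `dp`, `variants`)
#' @param path output path
#' @export
write_rare_vcf <- function(rare, path) {
  v <- rare$variants
  samples <- colnames(rare$gt)
  gt_str <- matrix("0/0", nrow(rare$gt), ncol(rare$gt))
  gt_str[rare$gt == 1L] <- "0/1"
  gt_str[rare$gt == 2L] <- "1/1"
  gt_str[is.na(rare$gt)] <- "./."
  calls <- matrix(paste(gt_str, rare$gq, rare$dp, sep = ":"),
                  nrow(rare$gt), ncol(rare$gt))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(v$chrom[i], v$pos[i], v$variant_id[i], v$ref[i], v$alt[i], ".",
            "PASS", paste0("GENE=", v$gene[i]), "GT:GQ:DP", calls[i, ]),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
}

#' Read a rare-variant VCF into the genotype-list representation
#'
#' Uses vcfR; requires GT, GQ, and DP in FORMAT. Multi-allelic records must
#' be split upstream (one ALT per record).
#'
#' @param path VCF path
#' @return rare-genotype list (`gt` alt-allele counts, `gq`, `dp`,
#'   `variants`)
#' @export
read_rare_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (any(grepl(",", fx$ALT, fixed = TRUE)))
    stop("multi-allelic records must be split into biallelic records",
         call. = FALSE)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  gq <- vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE)
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  alt_count <- function(g) {
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0", "0|0", "0")] <- 0L
    out[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    out[g %in% c("1/1", "1|1", "1")] <- 2L
    out
  }
  gt <- matrix(alt_count(gt_raw), nrow(gt_raw), ncol(gt_raw),
               dimnames = dimnames(gt_raw))
  gene <- sub(".*GENE=([^;]+).*", "\\1", vcfR::getINFO(vcf))
  variants <- data.frame(variant_id = fx$ID, gene = gene, chrom = fx$CHROM,
                         pos = as.numeric(fx$POS), ref = fx$REF, alt = fx$ALT,
                         stringsAsFactors = FALSE)
  rownames(gt) <- rownames(gq) <- rownames(dp) <- variants$variant_id
  list(gt = gt, gq = matrix(as.integer(gq), nrow(gq), ncol(gq),
                            dimnames = dimnames(gt)),
       dp = matrix(as.integer(dp), nrow(dp), ncol(dp),
                   dimnames = dimnames(gt)),
       variants = variants)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write every pipeline input of a synthetic cohort to a directory
#'
#' rare-variant VCF, annotation TSV, dosage TSV (samples x variants),
#' weights TSV, phenotype TSV, reference-panel TSVs, phecode map CSV, and
#' the truth record (YAML scalars + TSV tables). Intended for desk-scale
#' cohorts; large simulations are normally consumed in memory.
#'
#' @param cohort a `penetrax_cohort`
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_rare_vcf(cohort$rare, p("rare_variants.vcf"))
  write_tsv(cohort$annotations, p("annotations.tsv"))
  write_tsv(cohort$phenotypes, p("phenotypes.tsv"))
  write_tsv(cohort$weights, p("weights.tsv"))
  write_tsv(data.frame(participant_id = rownames(cohort$dosages),
                       cohort$dosages, check.names = FALSE),
            p("dosages.tsv"))
  write_tsv(data.frame(sample_id = rownames(cohort$reference_panel$dosages),
                       ancestry = cohort$reference_panel$labels,
                       cohort$reference_panel$dosages, check.names = FALSE),
            p("reference_panel.tsv"))
  write_tsv(cohort$apol1, p("apol1.tsv"))
  utils::write.csv(cohort$phecode_map, p("phecode_map.csv"),
                   row.names = FALSE)
  write_tsv(cohort$truth$participants, p("truth_participants.tsv"))
  write_tsv(cohort$truth$variants, p("truth_variants.tsv"))
  yaml::write_yaml(list(config = unclass(cohort$config),
                        plants = cohort$truth$plants),
                   p("truth_config.yaml"))
  invisible(dir)
}

#' Read a written cohort truth record back
#'
#' @param dir directory written by [write_cohort()]
#' @return list: participants, variants, config, plants
#' @export
read_truth <- function(dir) {
  y <- yaml::read_yaml(file.path(dir, "truth_config.yaml"))
  list(participants = read_tsv(file.path(dir, "truth_participants.tsv")),
       variants = read_tsv(file.path(dir, "truth_variants.tsv")),
       config = y$config, plants = y$plants)
}
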