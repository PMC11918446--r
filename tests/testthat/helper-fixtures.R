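# Fixtures are built in code at test time; nothing is stored on disk.

# A small phased VCF with two duos and hand-picked sites. VCF GT codes count
# ALT alleles (0 = REF); the duo matrices count REF alleles. Sites:
#   rs1: mother1 REF-dosage 2, child1 transmits REF        -> m1=1 m2=1 p1=0
#        mother2 REF-dosage 0, child2 transmits ALT        -> m1=0 m2=0 p1=1
#   rs2: duo1 Mendelian-inconsistent (child maternal allele REF, mother 0/0)
#   rs3: multi-allelic, must be skipped
write_toy_vcf <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  vcf <- file.path(dir, "toy.vcf")
  ped <- file.path(dir, "toy.ped")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "MO1", "MO2", "CH1", "CH2", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0|0", "1|1", "0|1", "1|0", sep = "\t"),
    paste("1", "200", "rs2", "A", "G", ".", "PASS", ".", "GT",
          "1|1", "0|1", "0|1", "0|0", sep = "\t"),
    paste("1", "300", "rs3", "A", "G,T", ".", "PASS", ".", "GT",
          "0|0", "0|1", "0|0", "0|1", sep = "\t")
  ), vcf)
  writeLines(c("CH1\tMO1", "CH2\tMO2"), ped)
  list(vcf = vcf, ped = ped)
}

# Tiny hand-constructed panel: 2 duos x 3 SNPs, no missingness.
toy_panel <- function() {
  duo_haplotypes(
    m1 = rbind(c(1L, 0L, 1L), c(0L, 0L, 1L)),
    m2 = rbind(c(0L, 1L, 1L), c(0L, 1L, 0L)),
    p1 = rbind(c(1L, 0L, 0L), c(1L, 1L, 1L)),
    mother_ids = c("M1", "M2"), child_ids = c("C1", "C2"),
    snps = data.frame(snp_id = c("s1", "s2", "s3"), chrom = "1",
                      pos = c(100L, 200L, 300L), ref_allele = "A",
                      freq = NA_real_)
  )
}

# Brute-force haplotype GRM: per-pair average over SNPs of products of
# standardized allele indicators, written as an explicit double loop.
brute_grm_haploid <- function(h, p) {
  n <- nrow(h); S <- ncol(h)
  A <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    s <- 0
    for (i in seq_len(S)) {
      s <- s + (h[j, i] - p[i]) * (h[k, i] - p[i]) / (p[i] * (1 - p[i]))
    }
    A[j, k] <- s / S
  }
  A
}
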