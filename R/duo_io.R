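#' Duo haplotype panels
#'
#' A `duo_haplotypes` object holds, for `n` mother-child duos and `S`
#' biallelic SNPs, the three haplotype allele matrices of the duo design:
#' `m1` (maternal transmitted), `m2` (maternal non-transmitted) and `p1`
#' (paternal transmitted), each an `n x S` 0/1 matrix counting reference
#' alleles. A logical `missing` mask marks entries that are unobserved or
#' Mendelian-inconsistent; masked entries are mean-imputed downstream when
#' columns are standardized.
#'
#' @param m1,m2,p1 Integer `n x S` matrices with entries in `{0, 1}`.
#' @param mother_ids,child_ids Character vectors of length `n`.
#' @param snps Data frame with columns `snp_id`, `chrom`, `pos`,
#'   `ref_allele` and `freq` (reference-allele frequency, possibly `NA`
#'   until [allele_frequencies()] is run).
#' @param missing Logical `n x S` mask (`TRUE` = treat entry as missing in
#'   all three matrices).
#'
#' @return An object of class `duo_haplotypes`.
#' @seealso [read_phased_duos()], [simulate_duo_genotypes()]
#' @export
duo_haplotypes <- function(m1, m2, p1, mother_ids, child_ids, snps,
                           missing = NULL) {
  stopifnot(is.matrix(m1), is.matrix(m2), is.matrix(p1))
  n <- nrow(m1); S <- ncol(m1)
  stopifnot(
    nrow(m2) == n, ncol(m2) == S,
    nrow(p1) == n, ncol(p1) == S,
    length(mother_ids) == n, length(child_ids) == n,
    is.data.frame(snps), nrow(snps) == S
  )
  req <- c("snp_id", "chrom", "pos", "ref_allele", "freq")
  miss_col <- setdiff(req, names(snps))
  if (length(miss_col)) {
    stop("snps is missing columns: ", paste(miss_col, collapse = ", "))
  }
  if (anyDuplicated(snps$snp_id)) stop("snp_id must be unique within a panel")
  if (is.null(missing)) missing <- matrix(FALSE, n, S)
  ok <- !missing
  for (h in list(m1, m2, p1)) {
    if (!all(h[ok] %in% c(0L, 1L))) {
      stop("haplotype entries must be 0 or 1 where not missing")
    }
  }
  structure(
    list(m1 = m1, m2 = m2, p1 = p1,
         mother_ids = as.character(mother_ids),
         child_ids = as.character(child_ids),
         snps = snps, missing = missing),
    class = "duo_haplotypes"
  )
}

#' @export
print.duo_haplotypes <- function(x, ...) {
  cat(sprintf("<duo_haplotypes> %d duos x %d SNPs (%d masked entries)\n",
              n_duos(x), n_snps(x), sum(x$missing)))
  invisible(x)
}

#' Number of duos / SNPs in a panel
#' @param x A `duo_haplotypes` object.
#' @return Integer count.
#' @export
n_duos <- function(x) nrow(x$m1)

#' @rdname n_duos
#' @export
n_snps <- function(x) ncol(x$m1)

#' Resolve mother-child duos from a phased VCF
#'
#' Reads a phased VCF and a two-column pedigree (child, mother) and resolves
#' each duo into the m1/m2/p1 haplotype matrices. The phase convention is the
#' one produced by duo-aware phasing: the child's first allele is the one
#' transmitted from the mother, the second the one transmitted from the
#' father. Hence `m1` is the child's first phased allele, `p1` the child's
#' second, and `m2 = mother genotype - m1`.
#'
#' Sites where the implied `m2` falls outside `{0, 1}` are Mendelian
#' inconsistencies (for example a 1|0 child with a 0/0 mother); they are
#' flagged in the missing mask for that duo rather than raising an error, and
#' are mean-imputed when matrices are standardized. Multi-allelic records are
#' skipped with a warning; the model is biallelic. An unphased child genotype
#' at a used site is an error, since transmission cannot be resolved.
#'
#' @param vcf_path Path to a VCF (plain text or gzipped) with GT fields.
#' @param pedigree Either a data frame with columns `child_id` and
#'   `mother_id` (first two columns used), or the path to a whitespace/TSV
#'   file with those two columns (header optional).
#' @return A [duo_haplotypes()] object; reference alleles count as in the
#'   VCF REF column, positions are 1-based.
#' @export
read_phased_duos <- function(vcf_path, pedigree) {
  ped <- if (is.character(pedigree) && length(pedigree) == 1) {
    read_pedigree(pedigree)
  } else {
    stopifnot(is.data.frame(pedigree), ncol(pedigree) >= 2)
    data.frame(child_id = as.character(pedigree[[1]]),
               mother_id = as.character(pedigree[[2]]))
  }
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)

  absent <- setdiff(unique(c(ped$child_id, ped$mother_id)), samples)
  if (length(absent)) {
    stop("pedigree members absent from VCF: ", paste(absent, collapse = ", "))
  }

  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"])
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
    fix <- fix[!multi, , drop = FALSE]
    gt <- gt[!multi, , drop = FALSE]
  }
  S <- nrow(fix)
  if (S == 0) stop("no biallelic records in ", vcf_path)
  n <- nrow(ped)

  child_gt <- gt[, ped$child_id, drop = FALSE]
  mother_gt <- gt[, ped$mother_id, drop = FALSE]

  unphased <- matrix(grepl("/", child_gt), nrow = S)
  if (any(unphased, na.rm = TRUE)) {
    w <- which(unphased, arr.ind = TRUE)[1, ]
    stop(sprintf("unphased child genotype for sample %s at %s:%s",
                 ped$child_id[w[2]], fix[w[1], "CHROM"], fix[w[1], "POS"]))
  }

  # child: "a|b" -> m1 = a, p1 = b (allele code 0 = reference? VCF codes
  # 0 = REF; we count REFERENCE alleles, so m1 = 1 - code).
  a1 <- suppressWarnings(as.integer(substr(child_gt, 1, 1)))
  a2 <- suppressWarnings(as.integer(substr(child_gt, 3, 3)))
  m1 <- matrix(1L - a1, nrow = S)   # S x n for now
  p1 <- matrix(1L - a2, nrow = S)

  mg1 <- suppressWarnings(as.integer(substr(mother_gt, 1, 1)))
  mg2 <- suppressWarnings(as.integer(substr(mother_gt, 3, 3)))
  mdos <- matrix((1L - mg1) + (1L - mg2), nrow = S)  # mother reference dosage

  m2 <- mdos - m1
  miss <- is.na(m1) | is.na(p1) | is.na(m2) | m2 < 0L | m2 > 1L
  m1[miss] <- 0L; p1[miss] <- 0L; m2[miss] <- 0L

  snps <- data.frame(
    snp_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                    paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"]),
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref_allele = fix[, "REF"],
    freq = NA_real_,
    stringsAsFactors = FALSE
  )
  duo_haplotypes(t(m1), t(m2), t(p1),
                 mother_ids = ped$mother_id, child_ids = ped$child_id,
                 snps = snps, missing = t(miss))
}

read_pedigree <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (identical(tolower(tab[1, 1]), "child_id")) tab <- tab[-1, , drop = FALSE]
  data.frame(child_id = as.character(tab[[1]]),
             mother_id = as.character(tab[[2]]))
}

#' Reference-allele frequencies of a duo panel
#'
#' Computes per-SNP reference-allele frequencies, either treating the mothers
#' as the founder population (frequency of `(m1 + m2) / 2` over unmasked
#' duos, the default and the convention used for duo GRMs) or pooling all
#' three resolved haplotypes.
#'
#' @param duos A [duo_haplotypes()] object.
#' @param founder_mode `"mothers"` or `"all_haplotypes"`.
#' @return The `duo_haplotypes` object with `snps$freq` filled in.
#' @export
allele_frequencies <- function(duos, founder_mode = c("mothers", "all_haplotypes")) {
  founder_mode <- match.arg(founder_mode)
  ok <- !duos$missing
  n_ok <- colSums(ok)
  if (any(n_ok == 0)) {
    stop("SNP(s) with all entries masked: ",
         paste(duos$snps$snp_id[n_ok == 0], collapse = ", "))
  }
  freq <- if (founder_mode == "mothers") {
    colSums((duos$m1 + duos$m2) * ok) / (2 * n_ok)
  } else {
    colSums((duos$m1 + duos$m2 + duos$p1) * ok) / (3 * n_ok)
  }
  duos$snps$freq <- freq
  duos
}

#' Collapse a duo panel to genotype dosages
#'
#' Reconstitutes diploid genotype matrices from the haplotype panel:
#' mothers' dosage is `m1 + m2`, children's `m1 + p1`. The missing mask is
#' propagated.
#'
#' @param duos A [duo_haplotypes()] object.
#' @param who `"mothers"` or `"children"`.
#' @return A list of class `genotype_matrix` with elements `dosage`
#'   (`n x S`, entries 0/1/2), `ids`, `snps` and `missing`.
#' @export
genotypes_from_duos <- function(duos, who = c("mothers", "children")) {
  who <- match.arg(who)
  dosage <- if (who == "mothers") duos$m1 + duos$m2 else duos$m1 + duos$p1
  ids <- if (who == "mothers") duos$mother_ids else duos$child_ids
  structure(
    list(dosage = dosage, ids = ids, snps = duos$snps, missing = duos$missing),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d SNPs\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

#' Write a duo panel as a phased VCF plus pedigree
#'
#' Exports the panel in the duo-phasing convention read back by
#' [read_phased_duos()]: the child's GT is `m1|p1` (first allele maternal
#' transmitted), the mother's is `m1|m2`. Alleles are written as REF/ALT
#' codes (`0` = reference); masked entries become `./.`. A matching
#' two-column pedigree file (`child_id`, `mother_id`) is written alongside.
#'
#' @param duos A [duo_haplotypes()] object.
#' @param vcf_path Output VCF path.
#' @param pedigree_path Output pedigree path (default `vcf_path` with a
#'   `.ped` suffix).
#' @return Invisibly, `c(vcf_path, pedigree_path)`.
#' @export
write_duo_vcf <- function(duos, vcf_path,
                          pedigree_path = paste0(vcf_path, ".ped")) {
  n <- n_duos(duos); S <- n_snps(duos)
  # VCF codes count ALT alleles; our matrices count REF, so code = 1 - count
  gt_str <- function(a, b) {
    out <- paste0(1L - a, "|", 1L - b)
    out[duos$missing] <- "./."
    matrix(out, n, S)
  }
  mom <- gt_str(duos$m1, duos$m2)
  kid <- gt_str(duos$m1, duos$p1)
  samples <- c(duos$mother_ids, duos$child_ids)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  alt <- ifelse(duos$snps$ref_allele == "A", "G", "A")
  body <- vapply(seq_len(S), function(i) {
    paste(c(duos$snps$chrom[i], duos$snps$pos[i], duos$snps$snp_id[i],
            duos$snps$ref_allele[i], alt[i], ".", "PASS", ".", "GT",
            mom[, i], kid[, i]), collapse = "\t")
  }, "")
  writeLines(c(header, body), vcf_path)
  utils::write.table(
    data.frame(duos$child_ids, duos$mother_ids),
    pedigree_path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(c(vcf_path, pedigree_path))
}

#' Dump a duo panel to TSV files (debugging aid)
#'
#' Writes `m1`, `m2`, `p1` and the SNP table as plain TSV files under
#' `prefix.m1.tsv` etc.
#'
#' @param duos A [duo_haplotypes()] object.
#' @param prefix Output path prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_duo_tsv <- function(duos, prefix) {
  files <- character(0)
  for (h in c("m1", "m2", "p1")) {
    f <- paste0(prefix, ".", h, ".tsv")
    utils::write.table(duos[[h]], f, sep = "\t", quote = FALSE,
                       row.names = duos$child_ids, col.names = duos$snps$snp_id)
    files <- c(files, f)
  }
  f <- paste0(prefix, ".snps.tsv")
  utils::write.table(duos$snps, f, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(files, f))
}
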