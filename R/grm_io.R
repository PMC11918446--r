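#' Read and write GRMs in GCTA binary format
#'
#' The GCTA convention stores a GRM as three files sharing a prefix:
#' `.grm.bin` holds the lower triangle (diagonal included) row by row as
#' little-endian 4-byte floats, `n(n+1)/2` values; `.grm.N.bin` holds the
#' per-pair counts of SNPs used, in the same layout; `.grm.id` is a
#' two-column text file of family and individual ids.
#'
#' @param grm A `grm` object to write.
#' @param prefix File path prefix (files `prefix.grm.bin`,
#'   `prefix.grm.N.bin`, `prefix.grm.id` are written/read).
#' @return `write_grm` invisibly returns the prefix; `read_grm` returns a
#'   `grm` object (its `kind` is taken from `kind`, since the binary format
#'   does not record it). Round-tripping reproduces `A` to float32
#'   precision.
#' @export
write_grm <- function(grm, prefix) {
  A <- grm$A
  if (!all(is.finite(A))) stop("GRM contains non-finite values")
  n <- nrow(A)
  idx <- lower_tri_index(n)
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(A[idx]), con, size = 4, endian = "little")
  close(con)
  N <- grm$N %||% matrix(grm$n_snps_used, n, n)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(N[idx]), con, size = 4, endian = "little")
  close(con)
  utils::write.table(
    data.frame(fid = grm$ids, iid = grm$ids),
    paste0(prefix, ".grm.id"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(prefix)
}

#' @rdname write_grm
#' @param kind Label to attach to the GRM read back (see [compute_grm()]).
#' @export
read_grm <- function(prefix, kind = "M") {
  id <- utils::read.table(paste0(prefix, ".grm.id"),
                          stringsAsFactors = FALSE)
  n <- nrow(id)
  m <- n * (n + 1) / 2
  read_f32 <- function(path) {
    sz <- file.info(path)$size
    if (is.na(sz) || sz != 4 * m) {
      stop(sprintf("%s: expected %d float32 values (%d bytes), found %s bytes",
                   path, m, 4 * m, ifelse(is.na(sz), "no", sz)))
    }
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "numeric", n = m, size = 4, endian = "little")
  }
  vals <- read_f32(paste0(prefix, ".grm.bin"))
  nvals <- read_f32(paste0(prefix, ".grm.N.bin"))
  idx <- lower_tri_index(n)
  A <- matrix(0, n, n); A[idx] <- vals; A <- A + t(A) - diag(diag(A))
  N <- matrix(0, n, n); N[idx] <- nvals; N <- N + t(N) - diag(diag(N))
  structure(
    list(A = A, ids = as.character(id[[2]]), n_snps_used = round(max(N)),
         kind = kind, weight_spec = NULL, N = N),
    class = "grm"
  )
}

# row-major lower-triangle linear indices of an n x n matrix:
# pairs (1,1), (2,1), (2,2), (3,1), ...
lower_tri_index <- function(n) {
  i <- rep(seq_len(n), seq_len(n))
  j <- unlist(lapply(seq_len(n), seq_len))
  cbind(i, j)
}
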