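#' Read and write PLINK bed/bim/fam filesets
#'
#' `write_plink()` emits the standard PLINK 1 binary triplet (variant-major
#' bed with the `6c 1b 01` magic, tab-separated bim and fam); `read_plink()`
#' reads one back into a [genotype_matrix()]. Dosages count copies of the bim
#' `allele1` (the A1/coded allele), with the usual 2-bit encoding
#' (00 = hom A1, 10 = het, 11 = hom A2, 01 = missing). Files written here are
#' bit-compatible with plink itself.
#'
#' @param gm a [genotype_matrix()].
#' @param prefix path prefix; `.bed`, `.bim`, `.fam` are appended.
#' @return `write_plink()` returns `prefix` invisibly; `read_plink()` returns
#'   a [genotype_matrix()].
#' @examples
#' gm <- genotype_matrix(matrix(c(0L, 1L, 2L, NA, 1L, 0L), nrow = 3))
#' pre <- file.path(tempdir(), "toy")
#' write_plink(gm, pre)
#' gm2 <- read_plink(pre)
#' identical(gm$dosages, gm2$dosages)
#' @export
write_plink <- function(gm, prefix) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (n_samples(gm) == 0 || n_variants(gm) == 0) {
    abort("cannot write an empty cohort (0 samples or 0 variants).")
  }
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  d <- gm$dosages
  n <- nrow(d)
  m <- ncol(d)
  # dosage -> 2-bit code: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  code <- matrix(3L, n, m)
  code[is.na(d)] <- 1L
  code[!is.na(d) & d == 1L] <- 2L
  code[!is.na(d) & d == 2L] <- 0L
  npad <- 4L * ceiling(n / 4L)
  if (npad > n) code <- rbind(code, matrix(0L, npad - n, m))
  i4 <- seq(1L, npad, by = 4L)
  bytes <- code[i4, , drop = FALSE] +
    4L * code[i4 + 1L, , drop = FALSE] +
    16L * code[i4 + 2L, , drop = FALSE] +
    64L * code[i4 + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  bim <- data.frame(
    chrom = gm$variants$chrom, id = gm$variants$variant_id, cm = 0,
    pos = gm$variants$pos, a1 = gm$variants$allele1, a2 = gm$variants$allele2
  )
  write.table(bim, paste0(prefix, ".bim"),
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  fam <- data.frame(
    fid = gm$samples$sample_id, iid = gm$samples$sample_id,
    pat = 0, mat = 0, sex = 0, pheno = -9
  )
  write.table(fam, paste0(prefix, ".fam"),
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(prefix)
}

#' @rdname write_plink
#' @export
read_plink <- function(prefix) {
  bim <- read.table(paste0(prefix, ".bim"),
    col.names = c("chrom", "variant_id", "cm", "pos", "allele1", "allele2"),
    colClasses = c("integer", "character", "numeric", "integer", "character", "character")
  )
  fam <- read.table(paste0(prefix, ".fam"),
    col.names = c("fid", "sample_id", "pat", "mat", "sex", "pheno"),
    colClasses = c("character", "character", "character", "character", "integer", "numeric")
  )
  n <- nrow(fam)
  m <- nrow(bim)
  bpv <- ceiling(n / 4)
  raw <- readBin(paste0(prefix, ".bed"), "raw", n = 3 + bpv * m)
  if (length(raw) < 3 || !identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L))) {
    abort("not a variant-major PLINK bed file (bad magic bytes).")
  }
  if (length(raw) != 3 + bpv * m) abort("bed file length inconsistent with bim/fam.")
  body <- as.integer(raw[-(1:3)])
  # 256 x 4 lookup: byte value -> 4 dosages (code 00->2, 01->NA, 10->1, 11->0)
  code2dose <- c(2L, NA_integer_, 1L, 0L)
  b <- 0:255
  lut <- cbind(
    code2dose[b %% 4 + 1], code2dose[(b %/% 4) %% 4 + 1],
    code2dose[(b %/% 16) %% 4 + 1], code2dose[(b %/% 64) %% 4 + 1]
  )
  dose <- matrix(t(lut[body + 1L, , drop = FALSE]), nrow = 4 * bpv)
  d <- dose[seq_len(n), , drop = FALSE]
  genotype_matrix(d,
    variants = tibble(
      variant_id = bim$variant_id, chrom = bim$chrom, pos = bim$pos,
      allele1 = bim$allele1, allele2 = bim$allele2
    ),
    samples = tibble(sample_id = fam$sample_id)
  )
}

#' Read / write the phenotype-label table
#'
#' Tab-separated with header
#' `sample_id  true_status  <one column per channel>  billing_count`.
#' Labels are 0/1; `true_status` may be `NA` for real cohorts where truth is
#' unknown.
#'
#' @param pheno a data frame of per-sample labels.
#' @param path file path.
#' @return `read_pheno()` returns a tibble; `write_pheno()` returns `path`
#'   invisibly.
#' @export
write_pheno <- function(pheno, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pheno
#' @export
read_pheno <- function(path) {
  as_tibble(read.table(path, header = TRUE, sep = "\t", colClasses = NA,
                       stringsAsFactors = FALSE))
}
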