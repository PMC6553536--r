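# File interfaces: minimal biallelic VCF writer (GT, optional AD), VCF
# reader via vcfR, delimited dosage-matrix and kernel readers/writers.

#' Write a genotype matrix as VCF
#'
#' Minimal VCFv4.2 with biallelic SNP records and a GT field (0/0, 0/1,
#' 1/1, ./.), plus an AD field when an allelic-depth table is supplied.
#' Fractional (imputed) dosages cannot be represented and are an error.
#'
#' @param G a [geno_matrix()] with integer dosages (NA allowed).
#' @param file output path (plain text).
#' @param ad optional data.frame (`sample`, `marker`, `ref_depth`,
#'   `total_depth`) as from [simulate_allelic_depths()].
#' @return `file`, invisibly.
#' @export
write_vcf <- function(G, file, ad = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  X <- G$dosage
  vals <- X[!is.na(X)]
  if (any(vals != round(vals))) stop("VCF output requires integer dosages")
  n <- nrow(X); m <- ncol(X)
  gt <- matrix("./.", m, n)
  gt[t(X) == 0] <- "0/0"; gt[t(X) == 1] <- "0/1"; gt[t(X) == 2] <- "1/1"
  fmt <- "GT"
  if (!is.null(ad)) {
    fmt <- "GT:AD"
    adm <- matrix(".", m, n, dimnames = list(G$map$marker, rownames(X)))
    adm[cbind(match(ad$marker, G$map$marker), match(ad$sample, rownames(X)))] <-
      paste0(ad$ref_depth, ",", ad$total_depth - ad$ref_depth)
    gt <- matrix(paste0(gt, ":", adm), m, n)
  }
  header <- c("##fileformat=VCFv4.2",
              "##source=wintergp",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              if (!is.null(ad))
                '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(X)), collapse = "\t"))
  body <- paste(G$map$chrom, G$map$pos, G$map$marker, "A", "T", ".", "PASS",
                ".", fmt, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), file)
  invisible(file)
}

#' Read a biallelic-SNP VCF
#'
#' Parses GT into a dosage matrix (count of alternate alleles; `./.` as
#' NA) and, when present, AD into an allelic-depth table with
#' heterozygous-call flags taken from the GT field.
#'
#' @param file VCF path.
#' @return list with `geno` (a [geno_matrix()]) and `ad` (data.frame or
#'   NULL).
#' @export
read_vcf <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[code == "0/0"] <- 0
  dos[code %in% c("0/1", "1/0")] <- 1
  dos[code == "1/1"] <- 2
  fix <- vcfR::getFIX(v)
  map <- data.frame(marker = fix[, "ID"], chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]), stringsAsFactors = FALSE)
  geno <- geno_matrix(t(dos), map)
  ad <- NULL
  if ("AD" %in% strsplit(v@gt[1, "FORMAT"], ":")[[1]]) {
    adm <- vcfR::extract.gt(v, element = "AD")
    keep <- which(!is.na(adm) & adm != ".", arr.ind = TRUE)
    if (nrow(keep)) {
      parts <- strsplit(adm[keep], ",", fixed = TRUE)
      ref <- as.integer(vapply(parts, `[`, character(1), 1))
      alt <- as.integer(vapply(parts, `[`, character(1), 2))
      ad <- data.frame(sample = colnames(adm)[keep[, 2]],
                       marker = rownames(adm)[keep[, 1]],
                       ref_depth = ref, total_depth = ref + alt,
                       het = code[keep] %in% c("0/1", "1/0"),
                       stringsAsFactors = FALSE)
    }
  }
  list(geno = geno, ad = ad)
}

#' Write / read a delimited dosage matrix
#'
#' Tab-separated matrix with individual ids in the first column and marker
#' ids as the header; missing calls as NA.
#'
#' @param G a [geno_matrix()] or dosage matrix.
#' @param file path.
#' @return `file` invisibly (writer); a [geno_matrix()] (reader).
#' @export
write_dosage <- function(G, file) {
  X <- as_dosage(G)
  write.table(data.frame(id = rownames(X), X, check.names = FALSE),
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_dosage
#' @export
read_dosage <- function(file) {
  d <- read.table(file, header = TRUE, sep = "\t", check.names = FALSE)
  X <- as.matrix(d[, -1, drop = FALSE])
  rownames(X) <- d[[1]]
  geno_matrix(X)
}

#' Write / read a kernel matrix as square CSV
#'
#' Square CSV with individual ids as header and first column.
#'
#' @param K a `kernel_matrix` (or square matrix).
#' @param file path.
#' @param kind kind tag restored on read (default `"GRM"`).
#' @return `file` invisibly (writer); a `kernel_matrix` (reader).
#' @export
write_kernel <- function(K, file) {
  K <- unclass(K)
  write.table(data.frame(id = rownames(K), K, check.names = FALSE),
              file, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(file, kind = "GRM") {
  d <- read.table(file, header = TRUE, sep = ",", check.names = FALSE)
  K <- as.matrix(d[, -1, drop = FALSE])
  new_kernel(K, d[[1]], kind)
}
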