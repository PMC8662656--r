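#' Read a VCF file into a variant set
#'
#' Parsing is delegated to \pkg{vcfR}; diploid GT plus optional DP and GQ
#' FORMAT fields are extracted. Positions are 1-based as in the file.
#'
#' @param path VCF file (plain or gzipped)
#' @return a [variant_set()]
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  alleles <- substr(gsub("\\|", "/", gt_raw), 1, 3)
  ok <- is.na(alleles) | alleles %in% c("0/0", "0/1", "1/0", "1/1", "./.")
  if (!all(ok)) {
    bad <- unique(alleles[!ok])
    if (any(nchar(gsub("[^/|]", "", gt_raw[!ok])) != 1)) {
      stop("non-diploid GT entries found: ", paste(head(bad), collapse = " "))
    }
    # multi-allelic diploid calls (e.g. 1/2) are kept as NA genotype copies;
    # the sites themselves are removed by the biallelic filter
  }
  gt <- matrix(NA_integer_, nrow(gt_raw), ncol(gt_raw))
  gt[alleles == "0/0"] <- 0L
  gt[alleles %in% c("0/1", "1/0")] <- 1L
  gt[alleles == "1/1"] <- 2L
  fmt <- strsplit(unname(v@gt[, "FORMAT"]), ":")
  has <- function(f) all(vapply(fmt, function(x) f %in% x, logical(1)))
  dp <- if (has("DP")) {
    suppressWarnings(matrix(as.integer(vcfR::extract.gt(v, "DP")),
                            nrow(gt_raw), ncol(gt_raw)))
  }
  gq <- if (has("GQ")) {
    suppressWarnings(matrix(as.integer(vcfR::extract.gt(v, "GQ")),
                            nrow(gt_raw), ncol(gt_raw)))
  }
  fix <- vcfR::getFIX(v)
  variant_set(fix[, "CHROM"], as.integer(fix[, "POS"]), fix[, "REF"],
              fix[, "ALT"], gt, dp, gq, samples = colnames(gt_raw))
}

#' Write a variant set as a plain-text VCF v4.2
#'
#' Genotypes are emitted as unphased GT with DP and GQ subfields when
#' present; missing genotypes are `./.`. The writer is the inverse of
#' [read_vcf()]: write then read preserves genotypes, DP, GQ and site order.
#'
#' @param records a [variant_set()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_vcf <- function(records, path) {
  stopifnot(inherits(records, "variant_set"))
  has_dp <- !is.null(records$dp)
  has_gq <- !is.null(records$gq)
  fmt <- paste(c("GT", if (has_dp) "DP", if (has_gq) "GQ"), collapse = ":")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bathypop",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_dp) "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    if (has_gq) "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", records$samples), collapse = "\t")
  )
  gt_str <- matrix("./.", nrow(records$gt), ncol(records$gt))
  gt_str[!is.na(records$gt) & records$gt == 0L] <- "0/0"
  gt_str[!is.na(records$gt) & records$gt == 1L] <- "0/1"
  gt_str[!is.na(records$gt) & records$gt == 2L] <- "1/1"
  dot <- function(m) {
    m <- as.character(m)
    m[is.na(m)] <- "."
    m
  }
  cell <- gt_str
  if (has_dp) cell <- matrix(paste(cell, dot(records$dp), sep = ":"),
                             nrow(cell), ncol(cell))
  if (has_gq) cell <- matrix(paste(cell, dot(records$gq), sep = ":"),
                             nrow(cell), ncol(cell))
  body <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                ".", "PASS", ".", fmt,
                apply(cell, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
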