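#' Read and write single-sample VCF variant sites
#'
#' `read_vcf()` parses a single-sample VCF into a variant tibble, classifying
#' each record's genotype as heterozygous (two distinct alleles) or homozygous
#' alternate (two identical non-reference alleles). Records with a missing
#' genotype are skipped with a warning giving the count. 1-based `POS` is
#' converted to the internal 0-based convention.
#'
#' @param path Path to a VCF file (uncompressed or bgzipped).
#' @return A tibble with columns `seq_name`, `pos` (0-based), `ref_allele`,
#'   `alt_allele`, `zygosity` (`"het"`/`"hom"`), `is_snp`.
#' @export
read_vcf <- function(path) {
  v <- suppressMessages(vcfR::read.vcfR(path, verbose = FALSE))
  if (nrow(v@fix) == 0) return(empty_variants())
  if (ncol(v@gt) < 2) abort("VCF has no sample column")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[, 1]
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  alleles <- str_split(ifelse(is.na(gt), "./.", gt), "[/|]")
  missing <- map_lgl(alleles, ~ any(.x %in% c(".", "")) || length(.x) != 2)
  if (any(missing)) {
    warn(paste0(sum(missing), " record(s) skipped for missing genotype"))
  }
  keep <- !missing
  out <- tibble(
    seq_name = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]) - 1L,
    ref = fix$REF[keep],
    alt_field = fix$ALT[keep],
    a1 = map_chr(alleles[keep], 1),
    a2 = map_chr(alleles[keep], 2)
  )
  # drop hom-ref genotypes: not variant in this sample
  out <- out[!(out$a1 == "0" & out$a2 == "0"), , drop = FALSE]
  alts <- str_split(out$alt_field, ",")
  pick <- ifelse(out$a1 != "0", out$a1, out$a2)
  out$alt_allele <- map2_chr_safe(alts, as.integer(pick), function(a, i) a[i])
  out$zygosity <- ifelse(out$a1 == out$a2, "hom", "het")
  out$ref_allele <- out$ref
  out$is_snp <- nchar(out$ref_allele) == 1L & nchar(out$alt_allele) == 1L
  select(out, "seq_name", "pos", "ref_allele", "alt_allele", "zygosity", "is_snp")
}

map2_chr_safe <- function(x, i, f) {
  vapply(seq_along(x), function(k) f(x[[k]], i[k]), "")
}

empty_variants <- function() {
  tibble(
    seq_name = character(), pos = integer(),
    ref_allele = character(), alt_allele = character(),
    zygosity = character(), is_snp = logical()
  )
}

#' @param variants A variant tibble (`seq_name`, `pos`, `ref_allele`,
#'   `alt_allele`, `zygosity`); `pos` 0-based.
#' @param sample Sample name for the header.
#' @rdname read_vcf
#' @export
write_vcf <- function(variants, path, sample = "SAMPLE") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  v <- arrange(variants, .data$seq_name, .data$pos)
  body <- if (nrow(v) == 0) character(0) else paste(
    v$seq_name, v$pos + 1L, ".", v$ref_allele, v$alt_allele, ".", "PASS", ".",
    "GT", ifelse(v$zygosity == "hom", "1/1", "0/1"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}
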