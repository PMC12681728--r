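# X-linked zygosity coding, allele-frequency estimation, Hardy-Weinberg
# expectations, and single-variant genotype input (CSV and VCF).

ZYGOSITY_LEVELS <- c(
  "ref_hemizygote", "var_hemizygote",
  "ref_homozygote", "heterozygote", "var_homozygote"
)

#' Zygosity label from sex and X-linked variant allele count
#'
#' Codes zygosity for an X-chromosome variant. Males are hemizygous and may
#' carry 0 or 1 variant allele; females carry 0, 1, or 2. The mapping is
#' deterministic: males map to `ref_hemizygote`/`var_hemizygote`, females to
#' `ref_homozygote`/`heterozygote`/`var_homozygote`. Counts that violate
#' X-linkage (male count 2, negative counts, counts above 2) raise an
#' invalid-genotype error rather than being coerced.
#'
#' @param sex Character vector, `"male"` or `"female"`, recycled against
#'   `allele_count` if scalar.
#' @param allele_count Integer vector of variant allele counts.
#' @return Factor of zygosity labels with the five X-linked levels.
#' @examples
#' zygosity_from_allele_count("male", 1)
#' zygosity_from_allele_count(c("female", "female"), c(1, 2))
#' @export
zygosity_from_allele_count <- function(sex, allele_count) {
  if (length(sex) == 1L) sex <- rep(sex, length(allele_count))
  if (length(allele_count) == 1L) allele_count <- rep(allele_count, length(sex))
  if (length(sex) != length(allele_count)) {
    abort_invalid("`sex` and `allele_count` must have matching lengths.")
  }
  if (!all(sex %in% c("male", "female"))) {
    abort_invalid("`sex` must be \"male\" or \"female\".")
  }
  if (!is.numeric(allele_count) || anyNA(allele_count) ||
      any(allele_count != as.integer(allele_count))) {
    abort_genotype("`allele_count` must be whole numbers without missing values.")
  }
  allele_count <- as.integer(allele_count)
  bad_male <- sex == "male" & !allele_count %in% 0:1
  bad_female <- sex == "female" & !allele_count %in% 0:2
  if (any(bad_male) || any(bad_female)) {
    i <- which(bad_male | bad_female)[1L]
    abort_genotype(sprintf(
      "allele count %d is invalid for a %s at an X-linked locus (entry %d).",
      allele_count[i], sex[i], i
    ))
  }
  label <- character(length(sex))
  label[sex == "male"] <- c("ref_hemizygote", "var_hemizygote")[allele_count[sex == "male"] + 1L]
  label[sex == "female"] <- c("ref_homozygote", "heterozygote", "var_homozygote")[allele_count[sex == "female"] + 1L]
  factor(label, levels = ZYGOSITY_LEVELS)
}

#' Estimate the variant allele frequency from an X-linked sample
#'
#' Counts alleles directly: each male contributes one X allele, each female
#' two, so `q` is the total number of variant alleles over the total number
#' of X alleles sampled.
#'
#' @inheritParams zygosity_from_allele_count
#' @return Allele frequency `q` in \[0, 1\].
#' @examples
#' estimate_allele_frequency(c("male", "male", "female"), c(1, 0, 1)) # 0.5
#' @export
estimate_allele_frequency <- function(sex, allele_count) {
  if (length(sex) == 0L || length(allele_count) == 0L) {
    abort_invalid("cannot estimate an allele frequency from an empty sample.")
  }
  zygosity_from_allele_count(sex, allele_count) # validates the pairs
  sum(allele_count) / sum(ifelse(sex == "male", 1L, 2L))
}

#' Expected zygosity frequencies under X-linked Hardy-Weinberg equilibrium
#'
#' At allele frequency `q`, X-linked Hardy-Weinberg equilibrium implies a
#' male hemizygote frequency of `q`, a female heterozygote frequency of
#' `2q(1 - q)`, and a female homozygote frequency of `q^2`. These identities
#' give a consistency check between the male and female zygosity frequencies
#' observed in a cohort: the squared hemizygote frequency should reproduce
#' the homozygote frequency.
#'
#' @param q Allele frequency in \[0, 1\].
#' @return A list with elements `q`, `male_hemizygote`, `female_heterozygote`,
#'   and `female_homozygote` (proportions).
#' @examples
#' hwe_expected_frequencies(0.154)$female_homozygote # about 0.0237
#' @export
hwe_expected_frequencies <- function(q) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || !is.finite(q) ||
      q < 0 || q > 1) {
    abort_invalid("`q` must be a single allele frequency in [0, 1].")
  }
  list(
    q = q,
    male_hemizygote = q,
    female_heterozygote = 2 * q * (1 - q),
    female_homozygote = q^2
  )
}

#' Read variant allele counts for one variant from a VCF
#'
#' Extracts the genotype (GT) field for a single variant — by default matched
#' on its ID column (e.g. `rs1050828`) — and decodes X-chromosome calls into
#' variant allele counts. Both common X dialects are accepted for males:
#' haploid calls (`"0"`, `"1"`) and homozygous-coded diploid calls (`"0/0"`,
#' `"1/1"`). A heterozygous diploid male call is an X-linkage violation and
#' raises an invalid-genotype error naming the sample, rather than being
#' silently dropped or coerced. Female calls must be diploid. Missing calls
#' (`"."`, `"./."`) are omitted from the result.
#'
#' @param vcf_file Path to a VCF (v4.x) file containing the variant.
#' @param sample_sex Named character vector mapping sample id to `"male"` or
#'   `"female"`; every called sample must be present.
#' @param variant_id Variant ID to match (default `"rs1050828"`).
#' @param chrom,pos Optional chromosome/position override used instead of
#'   ID matching when both are supplied.
#' @return Named integer vector of variant allele counts for called samples.
#' @export
read_variant_genotypes <- function(vcf_file, sample_sex,
                                   variant_id = "rs1050828",
                                   chrom = NULL, pos = NULL) {
  vcf <- vcfR::read.vcfR(vcf_file, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (!is.null(chrom) && !is.null(pos)) {
    idx <- which(fix[, "CHROM"] == chrom & as.numeric(fix[, "POS"]) == pos)
  } else {
    idx <- which(fix[, "ID"] == variant_id)
  }
  if (length(idx) == 0L) {
    abort_lookup(sprintf("variant %s not found in %s.",
                         if (is.null(chrom)) variant_id else paste0(chrom, ":", pos),
                         vcf_file))
  }
  idx <- idx[1L]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  calls <- gt[idx, , drop = TRUE]
  samples <- colnames(gt)
  counts <- integer(0)
  for (i in seq_along(calls)) {
    count <- decode_x_call(calls[[i]], samples[i], sample_sex)
    if (!is.na(count)) {
      counts[samples[i]] <- count
    }
  }
  counts
}

# Decode one GT string for sample `sample_id`; NA means a missing call.
decode_x_call <- function(call, sample_id, sample_sex) {
  if (is.na(call) || call %in% c(".", "./.", ".|.")) {
    return(NA_integer_)
  }
  alleles <- strsplit(call, "[/|]")[[1L]]
  if (any(alleles == ".")) {
    return(NA_integer_)
  }
  if (!all(alleles %in% c("0", "1"))) {
    abort_genotype(sprintf(
      "sample %s: unsupported allele in GT \"%s\" (biallelic 0/1 expected).",
      sample_id, call
    ))
  }
  if (!sample_id %in% names(sample_sex)) {
    abort_integrity(sprintf("sample %s has a genotype call but no sex in `sample_sex`.",
                            sample_id))
  }
  sex <- sample_sex[[sample_id]]
  n_alt <- sum(alleles == "1")
  if (sex == "male") {
    if (length(alleles) == 1L) {
      return(n_alt)
    }
    if (length(alleles) == 2L && alleles[1L] == alleles[2L]) {
      return(as.integer(n_alt > 0))
    }
    abort_genotype(sprintf(
      "sample %s: male heterozygous diploid call \"%s\" violates X-linkage.",
      sample_id, call
    ))
  }
  if (length(alleles) != 2L) {
    abort_genotype(sprintf(
      "sample %s: female haploid call \"%s\" is not a valid X genotype.",
      sample_id, call
    ))
  }
  n_alt
}

#' Read a genotype table from CSV
#'
#' Reads a genotype table with columns `participant_id`, `sex`, and
#' `allele_count`, validates the counts against X-linkage, and appends the
#' zygosity label.
#'
#' @param file Path to a CSV file.
#' @return A tibble with `participant_id`, `sex`, `allele_count`, `zygosity`.
#' @export
read_genotype_table <- function(file) {
  df <- readr::read_csv(file, na = c("", ".", "NA"), show_col_types = FALSE)
  validate_columns(df, c("participant_id", "sex", "allele_count"), file)
  df$zygosity <- zygosity_from_allele_count(df$sex, df$allele_count)
  tibble::as_tibble(df)
}
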