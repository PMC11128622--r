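#' Assemble a genotyped cohort
#'
#' A cohort bundles a sample table, a variant table and a dosage matrix.
#' Dosages are additive alternate-allele counts (0, 1, 2) with `NA` for a
#' missing genotype; every variant is biallelic (multi-allelic sites are
#' split at parse time, see [read_vcf()]).
#'
#' @param samples data frame with columns `sample_id`, `family_id`
#'   (`"UNRELATED"` for unrelated individuals), `sex` (`"female"`/`"male"`)
#'   and `affected` (`"case"`/`"control"`). `sex`/`affected` may be `NA`
#'   until a pedigree is attached.
#' @param variants data frame with columns `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `gene`, the site-QC metrics `dp`, `mq`, `qd`, `fs`,
#'   `call_rate`, the functional annotation `impact` (one of HIGH,
#'   MODERATE, LOW, MODIFIER, NONE) and `cadd_phred`, plus zero or more
#'   reference-panel frequency columns prefixed `af_` (`NA` = absent from
#'   that panel).
#' @param dosage integer matrix, samples x variants, entries in
#'   \{0, 1, 2, `NA`\}.
#'
#' @return An object of class `"cohort"`.
#' @export
cohort <- function(samples, variants, dosage) {
  samples <- as.data.frame(samples)
  variants <- as.data.frame(variants)
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"

  req_s <- c("sample_id", "family_id", "sex", "affected")
  if (!all(req_s %in% names(samples)))
    stop("samples must contain columns: ", paste(req_s, collapse = ", "))
  req_v <- c("variant_id", "chrom", "pos", "ref", "alt", "gene")
  if (!all(req_v %in% names(variants)))
    stop("variants must contain columns: ", paste(req_v, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in cohort")
  if (anyDuplicated(variants$variant_id))
    stop("duplicate variant_id in cohort")
  if (nrow(dosage) != nrow(samples) || ncol(dosage) != nrow(variants))
    stop("dosage matrix dimensions do not match sample/variant tables")
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad))
    stop("dosage entries must be 0, 1, 2 or NA")
  if (any(!is.na(variants$pos) & variants$pos < 1))
    stop("variant pos must be >= 1")
  ok_sex <- is.na(samples$sex) | samples$sex %in% c("female", "male")
  if (!all(ok_sex)) stop("sex must be 'female', 'male' or NA")
  ok_aff <- is.na(samples$affected) | samples$affected %in% c("case", "control")
  if (!all(ok_aff)) stop("affected must be 'case', 'control' or NA")

  dimnames(dosage) <- list(samples$sample_id, variants$variant_id)
  structure(list(samples = samples, variants = variants, dosage = dosage),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n <- nrow(x$samples)
  v <- nrow(x$variants)
  ncase <- sum(x$samples$affected == "case", na.rm = TRUE)
  nctl <- sum(x$samples$affected == "control", na.rm = TRUE)
  nfam <- length(setdiff(unique(x$samples$family_id), c("UNRELATED", NA)))
  cat(sprintf("<cohort> %d samples (%d cases / %d controls; %d families) x %d variants\n",
              n, ncase, nctl, nfam, v))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  dosage missingness: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Subset a cohort
#'
#' `x[i, j]` subsets samples (`i`) and variants (`j`) by index, logical
#' vector or id.
#'
#' @param x a [cohort()].
#' @param i,j sample / variant selectors.
#' @param ... ignored.
#' @export
`[.cohort` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$samples))
  if (missing(j)) j <- seq_len(nrow(x$variants))
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  if (is.character(j)) j <- match(j, x$variants$variant_id)
  if (anyNA(i)) stop("unknown sample id in subset")
  if (anyNA(j)) stop("unknown variant id in subset")
  cohort(x$samples[i, , drop = FALSE],
         x$variants[j, , drop = FALSE],
         x$dosage[i, j, drop = FALSE])
}

#' Attach pedigree phenotypes to a cohort
#'
#' Joins a pedigree/phenotype table (see [read_pedigree()]) onto the cohort
#' samples by `sample_id`, filling `family_id`, `sex` and `affected`.
#'
#' @param x a [cohort()], typically fresh from [read_vcf()].
#' @param ped data frame as returned by [read_pedigree()].
#' @param require_all error when a cohort sample is absent from the
#'   pedigree (default `TRUE`).
#' @return the cohort with phenotype columns filled.
#' @export
attach_pedigree <- function(x, ped, require_all = TRUE) {
  m <- match(x$samples$sample_id, ped$sample_id)
  if (require_all && anyNA(m))
    stop("samples missing from pedigree: ",
         paste(x$samples$sample_id[is.na(m)], collapse = ", "))
  hit <- !is.na(m)
  x$samples$family_id[hit] <- ped$family_id[m[hit]]
  x$samples$sex[hit] <- ped$sex[m[hit]]
  x$samples$affected[hit] <- ped$affected[m[hit]]
  cohort(x$samples, x$variants, x$dosage)
}

# names of reference-panel frequency columns in a variant table
freq_cols <- function(variants) grep("^af_", names(variants), value = TRUE)

# affected as 0/1 integer; NA propagates
affected01 <- function(samples) {
  ifelse(is.na(samples$affected), NA_integer_,
         as.integer(samples$affected == "case"))
}

# sex as 0/1 integer (female = 1); NA propagates
sex01 <- function(samples) {
  ifelse(is.na(samples$sex), NA_integer_,
         as.integer(samples$sex == "female"))
}
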