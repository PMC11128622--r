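#' Co-segregation verdict for one variant in one family
#'
#' A family member is a carrier when its dosage is at least 1 (dominant
#' coding, the natural reading for rare, fully penetrant heterozygous
#' variants). The variant shows *complete penetrance* in the family when
#' no unaffected member is a carrier, and *no phenocopy* when every
#' affected member is a carrier. The verdict is `"qualifies"` when both
#' hold; otherwise it names the violated condition(s)
#' (`"incomplete_penetrance"`, `"phenocopy"`, `"both_violations"`). A
#' family with any missing dosage, or without at least one affected and
#' one unaffected genotyped member, is `"untyped"`: penetrance claims are
#' never asserted on incomplete data.
#'
#' @param dosage integer dosages (0/1/2, `NA` = missing) of the family
#'   members.
#' @param affected logical (or `"case"`/`"control"`) affection status,
#'   same length as `dosage`.
#' @return a single verdict string.
#' @export
family_verdict <- function(dosage, affected) {
  if (is.character(affected)) affected <- affected == "case"
  stopifnot(length(dosage) == length(affected))
  if (anyNA(dosage) || anyNA(affected)) return("untyped")
  if (!any(affected) || all(affected)) return("untyped")
  carrier <- dosage >= 1
  inc <- any(carrier & !affected)   # unaffected carrier
  phe <- any(affected & !carrier)   # affected non-carrier
  if (inc && phe) "both_violations"
  else if (inc) "incomplete_penetrance"
  else if (phe) "phenocopy"
  else "qualifies"
}

#' Select variants co-segregating with disease in at least one family
#'
#' Evaluates [family_verdict()] for every variant in every family
#' (samples with `family_id != "UNRELATED"`) and selects variants that
#' qualify — complete penetrance and no phenocopy — in at least
#' `min_families` families.
#'
#' @param x a [cohort()] with pedigree attached.
#' @param variants optional variant ids to restrict to (default: all).
#' @param min_families minimum number of qualifying families (default 1).
#' @return an object of class `"segregation_report"`: a list with
#'   `report` (long data frame `variant_id` x `family_id` -> `verdict`),
#'   `counts` (per-variant qualifying family count) and `selected`
#'   (character vector of qualifying variant ids).
#' @export
select_cosegregating <- function(x, variants = NULL, min_families = 1) {
  stopifnot(inherits(x, "cohort"))
  if (is.null(variants)) variants <- x$variants$variant_id
  fams <- setdiff(unique(x$samples$family_id), c("UNRELATED", NA))
  if (length(fams) == 0) stop("cohort contains no family members")
  fam_idx <- lapply(fams, function(f) which(x$samples$family_id == f))
  names(fam_idx) <- fams
  aff <- affected01(x$samples)

  rows <- vector("list", length(variants) * length(fams))
  k <- 0L
  counts <- integer(length(variants))
  for (vi in seq_along(variants)) {
    d <- x$dosage[, variants[vi]]
    for (f in fams) {
      idx <- fam_idx[[f]]
      a <- aff[idx]
      verdict <- if (anyNA(a)) "untyped" else family_verdict(d[idx], a == 1L)
      k <- k + 1L
      rows[[k]] <- c(variants[vi], f, verdict)
      if (verdict == "qualifies") counts[vi] <- counts[vi] + 1L
    }
  }
  rep_df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(rep_df) <- c("variant_id", "family_id", "verdict")
  gene <- x$variants$gene[match(variants, x$variants$variant_id)]
  counts_df <- data.frame(variant_id = variants, gene = gene,
                          qualifying_family_count = counts,
                          stringsAsFactors = FALSE)
  structure(list(report = rep_df, counts = counts_df,
                 selected = variants[counts >= min_families]),
            class = "segregation_report")
}

#' @export
print.segregation_report <- function(x, ...) {
  cat(sprintf("<segregation_report> %d variants x %d families; %d selected\n",
              nrow(x$counts), length(unique(x$report$family_id)),
              length(x$selected)))
  invisible(x)
}
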