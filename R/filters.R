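#' Variant filter thresholds
#'
#' Thresholds for site quality control, rarity and non-neutrality of
#' variants called from whole-exome data. Defaults follow common GATK
#' hard-filter practice for exome calls: depth DP >= 12, mapping quality
#' MQ >= 30, quality-by-depth QD >= 2, strand-bias FS <= 25 and call rate
#' >= 95% (all comparisons inclusive); a variant is rare when every
#' reference-panel frequency observed for it is strictly below 1%; it is
#' non-neutral when its predicted impact is HIGH, MODERATE or MODIFIER
#' or its Phred-scaled CADD score is at least 15.
#'
#' @param min_dp,min_mq,min_qd minimum DP, MQ and QD (inclusive).
#' @param max_fs maximum phred-scaled strand-bias FS (inclusive).
#' @param min_call_rate minimum fraction of non-missing genotypes
#'   (inclusive).
#' @param rare_maf_ceiling frequency below which a variant counts as rare
#'   (strict).
#' @param cadd_floor minimum Phred CADD score qualifying a variant as
#'   non-neutral (inclusive).
#' @param qualifying_impacts impact classes qualifying as non-neutral.
#' @return an object of class `"filter_thresholds"`.
#' @export
filter_thresholds <- function(min_dp = 12, min_mq = 30, min_qd = 2,
                              max_fs = 25, min_call_rate = 0.95,
                              rare_maf_ceiling = 0.01, cadd_floor = 15,
                              qualifying_impacts = c("HIGH", "MODERATE", "MODIFIER")) {
  stopifnot(min_dp > 0, min_mq > 0, min_qd > 0, max_fs > 0,
            min_call_rate > 0, cadd_floor > 0,
            rare_maf_ceiling > 0, rare_maf_ceiling < 1)
  structure(list(min_dp = min_dp, min_mq = min_mq, min_qd = min_qd,
                 max_fs = max_fs, min_call_rate = min_call_rate,
                 rare_maf_ceiling = rare_maf_ceiling,
                 cadd_floor = cadd_floor,
                 qualifying_impacts = qualifying_impacts),
            class = "filter_thresholds")
}

as_variant_table <- function(x) {
  if (inherits(x, "cohort")) x$variants else as.data.frame(x)
}

#' Site quality-control predicate
#'
#' A site passes when DP, MQ, QD, FS and call rate all meet their
#' thresholds (inclusive comparisons). A site with any metric missing is
#' unevaluable and fails.
#'
#' @param x a [cohort()] or a variant table with columns `dp`, `mq`, `qd`,
#'   `fs`, `call_rate`.
#' @param thresholds a [filter_thresholds()].
#' @return named logical vector, one entry per variant.
#' @export
site_qc_pass <- function(x, thresholds = filter_thresholds()) {
  v <- as_variant_table(x)
  t <- thresholds
  ok <- v$dp >= t$min_dp & v$mq >= t$min_mq & v$qd >= t$min_qd &
    v$fs <= t$max_fs & v$call_rate >= t$min_call_rate
  ok[is.na(ok)] <- FALSE
  setNames(ok, v$variant_id)
}

#' Rarity predicate over reference-panel frequencies
#'
#' A variant is rare when every panel frequency that is present is
#' strictly below `rare_maf_ceiling`. Panels without an observation do not
#' veto: a variant absent from all panels counts as rare, since
#' study-private familial variants are absent from public panels by
#' construction.
#'
#' @inheritParams site_qc_pass
#' @return named logical vector, one entry per variant.
#' @export
is_rare <- function(x, thresholds = filter_thresholds()) {
  v <- as_variant_table(x)
  fc <- freq_cols(v)
  if (length(fc) == 0) return(setNames(rep(TRUE, nrow(v)), v$variant_id))
  fm <- as.matrix(v[, fc, drop = FALSE])
  ok <- apply(fm, 1, function(f) all(f[!is.na(f)] < thresholds$rare_maf_ceiling))
  setNames(as.logical(ok), v$variant_id)
}

#' Non-neutrality predicate
#'
#' A variant is non-neutral when its predicted impact class is in
#' `qualifying_impacts` or its Phred CADD score is at least `cadd_floor`
#' (disjunction). A missing CADD score does not qualify.
#'
#' @inheritParams site_qc_pass
#' @return named logical vector, one entry per variant.
#' @export
is_non_neutral <- function(x, thresholds = filter_thresholds()) {
  v <- as_variant_table(x)
  imp <- ifelse(is.na(v$impact), "NONE", v$impact)
  ok <- imp %in% thresholds$qualifying_impacts |
    (!is.na(v$cadd_phred) & v$cadd_phred >= thresholds$cadd_floor)
  setNames(ok, v$variant_id)
}

#' Apply site QC to a cohort and produce an audit table
#'
#' Removes variants failing site QC and annotates every variant with its
#' rarity and non-neutrality status. The audit table lists, for each
#' record, each rule outcome and the first failing rule (or `"pass"`).
#'
#' @inheritParams site_qc_pass
#' @return list with elements `cohort` (site-QC-passing variants only) and
#'   `audit` (data frame: `variant_id`, `site_qc`, `rare`, `non_neutral`,
#'   `first_fail`).
#' @export
filter_variants <- function(x, thresholds = filter_thresholds()) {
  stopifnot(inherits(x, "cohort"))
  v <- x$variants
  t <- thresholds
  rule <- function(ok) { ok[is.na(ok)] <- FALSE; ok }
  r_dp <- rule(v$dp >= t$min_dp)
  r_mq <- rule(v$mq >= t$min_mq)
  r_qd <- rule(v$qd >= t$min_qd)
  r_fs <- rule(v$fs <= t$max_fs)
  r_cr <- rule(v$call_rate >= t$min_call_rate)
  rules <- cbind(dp = r_dp, mq = r_mq, qd = r_qd, fs = r_fs, call_rate = r_cr)
  qc <- apply(rules, 1, all)
  first_fail <- apply(rules, 1, function(z) {
    bad <- which(!z)
    if (length(bad)) colnames(rules)[bad[1]] else "pass"
  })
  audit <- data.frame(variant_id = v$variant_id,
                      site_qc = qc,
                      rare = unname(is_rare(v, t)),
                      non_neutral = unname(is_non_neutral(v, t)),
                      first_fail = first_fail,
                      stringsAsFactors = FALSE)
  list(cohort = x[, which(qc)], audit = audit)
}
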