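# Independent oracles used to cross-check the package's statistics.
# These deliberately avoid the code paths they verify.

# BH step-up adjustment via explicit sort / cumulative-minimum
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# upper-tail hypergeometric by enumerating every draw of size n from a
# universe of N items whose first m are "special"
hyper_oracle <- function(k, m, n, N) {
  draws <- combn(N, n)
  overlap <- colSums(draws <= m)
  mean(overlap >= k)
}

# exact HWE p by enumerating all assignments of the alt alleles to the
# 2n allele slots (slot pairs (1,2), (3,4), ... are individuals)
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_alt <- 2 * n_hom_alt + n_het
  if (n_alt == 0 || n_alt == 2 * n) return(1)
  sl <- combn(2 * n, n_alt)
  ind <- rep(seq_len(n), each = 2)
  het_of <- apply(sl, 2, function(s) {
    per <- tabulate(ind[s], nbins = n)
    sum(per == 1)
  })
  tot <- length(het_of)
  p_obs <- sum(het_of == n_het) / tot
  probs <- table(het_of) / tot
  sum(probs[probs <= p_obs + 1e-12])
}

# minimal in-memory cohort builder for unit tests
make_cohort <- function(dosage, affected, sex = NULL, family = NULL,
                        genes = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage); v <- ncol(dosage)
  if (is.null(sex)) sex <- rep(c("female", "male"), length.out = n)
  if (is.null(family)) family <- rep("UNRELATED", n)
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(v))
  samples <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)), family_id = family,
    sex = sex,
    affected = if (is.logical(affected))
      ifelse(affected, "case", "control") else affected,
    stringsAsFactors = FALSE)
  variants <- data.frame(
    variant_id = sprintf("v%02d", seq_len(v)), chrom = "1",
    pos = seq_len(v) * 100L, ref = "A", alt = "G", gene = genes,
    dp = 60, mq = 60, qd = 25, fs = 2, call_rate = 1,
    impact = "NONE", cadd_phred = NA_real_, af_kg1000_eur = NA_real_,
    stringsAsFactors = FALSE)
  cohort(samples, variants, dosage)
}

# a cohort realising a 2x2 exposure table in genotype cells (1,1) vs (0,0)
make_2x2_cohort <- function(exp_case, exp_ctrl, unexp_case, unexp_ctrl,
                            sex_constant = TRUE) {
  n <- exp_case + exp_ctrl + unexp_case + unexp_ctrl
  d1 <- c(rep(1L, exp_case + exp_ctrl), rep(0L, unexp_case + unexp_ctrl))
  aff <- c(rep(TRUE, exp_case), rep(FALSE, exp_ctrl),
           rep(TRUE, unexp_case), rep(FALSE, unexp_ctrl))
  sex <- if (sex_constant) rep("female", n) else
    rep(c("female", "male"), length.out = n)
  make_cohort(cbind(d1, d1), aff, sex = sex)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# tiny VCF text with default INFO keys; body rows are pre-formatted
tiny_vcf <- function(rows, samples = c("S1", "S2", "S3", "S4")) {
  write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Float,Description=\"d\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rows), ext = ".vcf")
}

vcf_row <- function(chrom = "1", pos = 100, id = "rs1", ref = "A",
                    alt = "G", info = "DP=50;MQ=60;QD=20;FS=1",
                    gts = c("0/0", "0/1", "1/1", "0/0")) {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", info, "GT", gts),
        collapse = "\t")
}
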