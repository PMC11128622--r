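#' Default INFO key mapping for annotated VCFs
#'
#' Names of the INFO fields carrying the gene symbol, predicted impact,
#' Phred-scaled CADD score and reference-panel allele frequencies. The
#' frequency entry is a named character vector mapping panel name to INFO
#' key; panels absent from a record are recorded as `NA` frequencies.
#'
#' @export
default_info_keys <- function() {
  list(gene = "GENE", impact = "IMPACT", cadd = "CADD_PHRED",
       freqs = c(KG1000_EUR = "AF_1KG_EUR", ExAC = "AF_EXAC",
                 ESP6500 = "AF_ESP", CG69 = "AF_CG69"))
}

#' Read an annotated VCF into a cohort
#'
#' Parses a VCF 4.x file with per-site QC annotations (DP, MQ, QD, FS),
#' functional annotations and reference-panel frequencies in INFO.
#' Multi-allelic sites are split into one biallelic record per alternate
#' allele, with the dosage of each record counting copies of that allele
#' only. Records where the length difference between reference and
#' alternate allele exceeds `max_indel_len` bases are dropped. A missing
#' genotype (any `.` allele) yields a missing dosage; the per-record call
#' rate is the fraction of non-missing genotypes.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param max_indel_len maximum indel length in bases (default 50; longer
#'   records are rejected at parse time).
#' @param info_keys INFO key mapping, see [default_info_keys()].
#' @return a [cohort()]; `sex`/`affected` are `NA` until
#'   [attach_pedigree()] is called.
#' @export
read_vcf <- function(path, max_indel_len = 50, info_keys = default_info_keys()) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  gt <- vcf@gt
  n_meta <- length(vcf@meta)
  sample_ids <- colnames(gt)[-1]
  n_samp <- length(sample_ids)

  samples <- data.frame(sample_id = sample_ids,
                        family_id = NA_character_,
                        sex = NA_character_,
                        affected = NA_character_,
                        stringsAsFactors = FALSE)

  out_var <- list()
  out_dos <- list()
  nr <- nrow(fix)
  if (is.null(nr)) nr <- 0L
  for (r in seq_len(nr)) {
    line_no <- n_meta + 1L + r
    ref <- fix[r, "REF"]
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    pos <- as.integer(fix[r, "POS"])
    if (is.na(pos) || pos < 1)
      stop(sprintf("parse error at line %d: invalid POS", line_no))

    # genotype alleles for this site
    fmt <- strsplit(gt[r, 1], ":", fixed = TRUE)[[1]]
    gti <- match("GT", fmt)
    if (is.na(gti))
      stop(sprintf("parse error at line %d: FORMAT lacks GT", line_no))
    raw <- vapply(gt[r, -1], function(s) {
      if (is.na(s)) return("./.")
      strsplit(s, ":", fixed = TRUE)[[1]][gti]
    }, character(1), USE.NAMES = FALSE)
    al <- strsplit(raw, "[/|]")
    ok_len <- lengths(al) == 2L
    if (!all(ok_len))
      stop(sprintf("parse error at line %d: ploidy != 2 in GT '%s'",
                   line_no, raw[which(!ok_len)[1]]))
    alm <- matrix(unlist(al), nrow = 2)
    ok_tok <- alm == "." | grepl("^[0-9]+$", alm)
    if (!all(ok_tok))
      stop(sprintf("parse error at line %d: malformed GT '%s'",
                   line_no, raw[which(colSums(!ok_tok) > 0)[1]]))
    missing_gt <- colSums(alm == ".") > 0
    alnum <- suppressWarnings(matrix(as.integer(alm), nrow = 2))
    if (any(!is.na(alnum) & alnum > length(alts)))
      stop(sprintf("parse error at line %d: allele index out of range", line_no))

    info <- parse_info(fix[r, "INFO"])
    id <- fix[r, "ID"]

    for (a in seq_along(alts)) {
      alt <- alts[a]
      if (identical(ref, alt))
        stop(sprintf("parse error at line %d: REF equals ALT", line_no))
      if (abs(nchar(alt) - nchar(ref)) > max_indel_len) next
      dos <- colSums(alnum == a)
      dos[missing_gt] <- NA_integer_
      vid <- if (is.na(id) || id == ".") {
        paste(fix[r, "CHROM"], pos, ref, alt, sep = ":")
      } else if (length(alts) > 1L) {
        paste(id, alt, sep = ":")
      } else id
      freqs <- vapply(info_keys$freqs, function(k) {
        v <- info[[k]]
        if (is.null(v)) NA_real_ else suppressWarnings(as.numeric(v))
      }, numeric(1))
      imp <- info[[info_keys$impact]]
      if (is.null(imp)) imp <- "NONE"
      if (!imp %in% c("HIGH", "MODERATE", "LOW", "MODIFIER", "NONE"))
        stop(sprintf("parse error at line %d: unknown impact '%s'", line_no, imp))
      rec <- data.frame(
        variant_id = vid, chrom = fix[r, "CHROM"], pos = pos,
        ref = ref, alt = alt,
        gene = if (is.null(info[[info_keys$gene]])) NA_character_ else info[[info_keys$gene]],
        dp = info_num(info, "DP"), mq = info_num(info, "MQ"),
        qd = info_num(info, "QD"), fs = info_num(info, "FS"),
        call_rate = mean(!missing_gt),
        impact = imp,
        cadd_phred = if (is.null(info[[info_keys$cadd]])) NA_real_ else
          suppressWarnings(as.numeric(info[[info_keys$cadd]])),
        stringsAsFactors = FALSE)
      for (pn in names(freqs)) rec[[paste0("af_", tolower(pn))]] <- freqs[[pn]]
      out_var[[length(out_var) + 1L]] <- rec
      out_dos[[length(out_dos) + 1L]] <- as.integer(dos)
    }
  }

  if (length(out_var) == 0L) {
    panels <- paste0("af_", tolower(names(info_keys$freqs)))
    variants <- data.frame(variant_id = character(0), chrom = character(0),
                           pos = integer(0), ref = character(0),
                           alt = character(0), gene = character(0),
                           dp = numeric(0), mq = numeric(0), qd = numeric(0),
                           fs = numeric(0), call_rate = numeric(0),
                           impact = character(0), cadd_phred = numeric(0),
                           stringsAsFactors = FALSE)
    for (pn in panels) variants[[pn]] <- numeric(0)
    return(cohort(samples, variants,
                  matrix(integer(0), nrow = n_samp, ncol = 0)))
  }
  variants <- do.call(rbind, out_var)
  dosage <- do.call(cbind, out_dos)
  cohort(samples, variants, dosage)
}

parse_info <- function(s) {
  if (is.na(s) || s == ".") return(list())
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- lapply(kv, function(x) if (length(x) >= 2) x[2] else TRUE)
  names(vals) <- vapply(kv, `[`, character(1), 1)
  vals
}

info_num <- function(info, key) {
  v <- info[[key]]
  if (is.null(v)) NA_real_ else suppressWarnings(as.numeric(v))
}

#' Write a cohort to a VCF 4.2 file
#'
#' Emits one biallelic record per variant with the QC metrics and
#' annotations in INFO and `GT` genotypes recoded from dosages
#' (0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`, `NA` -> `./.`). Re-reading the file
#' with [read_vcf()] reproduces the dosage matrix and sample order.
#'
#' @param x a [cohort()].
#' @param path output path.
#' @param info_keys INFO key mapping, see [default_info_keys()].
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, info_keys = default_info_keys()) {
  v <- x$variants
  panels <- info_keys$freqs
  meta <- c("##fileformat=VCFv4.2",
    "##source=epifam",
    "##INFO=<ID=DP,Number=1,Type=Float,Description=\"Total read depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled strand bias\">",
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Gene symbol\">", info_keys$gene),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Predicted impact\">", info_keys$impact),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Phred-scaled CADD score\">", info_keys$cadd),
    vapply(names(panels), function(pn) sprintf(
      "##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s allele frequency\">",
      panels[[pn]], pn), character(1)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", x$samples$sample_id), collapse = "\t")
  gt_code <- c("0/0", "0/1", "1/1")
  rows <- vapply(seq_len(nrow(v)), function(j) {
    kv <- character(0)
    add <- function(kv, key, val) {
      if (length(val) == 1 && !is.na(val)) c(kv, paste0(key, "=", as.character(val))) else kv
    }
    kv <- add(kv, "DP", v$dp[j]); kv <- add(kv, "MQ", v$mq[j])
    kv <- add(kv, "QD", v$qd[j]); kv <- add(kv, "FS", v$fs[j])
    kv <- add(kv, info_keys$gene, v$gene[j])
    if (!is.na(v$impact[j]) && v$impact[j] != "NONE")
      kv <- add(kv, info_keys$impact, v$impact[j])
    kv <- add(kv, info_keys$cadd, v$cadd_phred[j])
    for (pn in names(panels))
      kv <- add(kv, panels[[pn]], v[[paste0("af_", tolower(pn))]][j])
    info <- if (length(kv)) paste(kv, collapse = ";") else "."
    d <- x$dosage[, j]
    gts <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    paste(c(v$chrom[j], v$pos[j], v$variant_id[j], v$ref[j], v$alt[j],
            ".", "PASS", info, "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(meta, header, rows), path)
  invisible(path)
}

#' Read a 6-column PED/FAM pedigree file
#'
#' Columns: family id, sample id, father, mother, sex (1 = male,
#' 2 = female), phenotype (1 = unaffected, 2 = affected). Founders have
#' father/mother `"0"`. Family id `"0"` denotes an unrelated individual and
#' is mapped to `"UNRELATED"`.
#'
#' @param path path to a whitespace-delimited PED/FAM file.
#' @return data frame with columns `family_id`, `sample_id`, `father`,
#'   `mother`, `sex` (`"female"`/`"male"`) and `affected`
#'   (`"case"`/`"control"`).
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("cannot read pedigree: ", path)
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(tab) != 6)
    stop("pedigree file must have exactly 6 columns, found ", ncol(tab))
  names(tab) <- c("family_id", "sample_id", "father", "mother", "sex_code",
                  "pheno_code")
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id in pedigree: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", "))
  if (!all(tab$sex_code %in% c("1", "2")))
    stop("unknown sex code (expected 1=male, 2=female): ",
         paste(unique(setdiff(tab$sex_code, c("1", "2"))), collapse = ", "))
  if (!all(tab$pheno_code %in% c("1", "2")))
    stop("phenotype code outside {1,2}: ",
         paste(unique(setdiff(tab$pheno_code, c("1", "2"))), collapse = ", "))
  data.frame(
    family_id = ifelse(tab$family_id == "0", "UNRELATED", tab$family_id),
    sample_id = tab$sample_id,
    father = tab$father, mother = tab$mother,
    sex = c(`1` = "male", `2` = "female")[tab$sex_code],
    affected = c(`1` = "control", `2` = "case")[tab$pheno_code],
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a cohort's samples as a 6-column PED file
#'
#' @param samples sample table (or a [cohort()]); optional `father`/`mother`
#'   columns are used when present, otherwise founders (`"0 0"`) are
#'   written.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(samples, path) {
  if (inherits(samples, "cohort")) samples <- samples$samples
  fam <- ifelse(samples$family_id == "UNRELATED", "0", samples$family_id)
  father <- if ("father" %in% names(samples)) samples$father else "0"
  mother <- if ("mother" %in% names(samples)) samples$mother else "0"
  sexc <- ifelse(samples$sex == "male", "1", "2")
  phc <- ifelse(samples$affected == "case", "2", "1")
  writeLines(paste(fam, samples$sample_id, father, mother, sexc, phc,
                   sep = "\t"), path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: set id, description, then tab-separated gene symbols.
#' Duplicate genes within a line are de-duplicated.
#'
#' @param path path to a GMT file.
#' @return list of gene sets, each a list with `set_id`, `name` and
#'   `genes`; names of the list are the set ids.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("cannot read GMT: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    list(set_id = f[1], name = f[2], genes = unique(f[-(1:2)]))
  })
  names(sets) <- vapply(sets, `[[`, character(1), "set_id")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets list of gene sets as returned by [read_gene_sets()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  writeLines(vapply(sets, function(s)
    paste(c(s$set_id, s$name, s$genes), collapse = "\t"), character(1)), path)
  invisible(path)
}

# results-table writer: one header line, tab-separated, '.' for missing,
# numbers rendered with up to 6 significant digits for stable output
write_results_tsv <- function(df, path) {
  out <- df
  for (cn in names(out)) {
    col <- out[[cn]]
    if (is.double(col)) out[[cn]] <- ifelse(is.na(col), ".", sprintf("%.6g", col))
    else out[[cn]] <- ifelse(is.na(col), ".", as.character(col))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
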