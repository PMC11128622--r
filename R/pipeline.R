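stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
}

# Table-1-shaped listing: one row per cell of each significant category,
# with the pooled statistics and model-competition deltas alongside
interaction_summary <- function(scan, comp) {
  res <- scan$results
  rows <- list()
  for (i in which(res$significant)) {
    tab <- scan$tables[[res$pair[i]]]
    tot_ca <- sum(tab$n_cases); tot_co <- sum(tab$n_controls)
    cells <- strsplit(res$cells[i], ";", fixed = TRUE)[[1]]
    ci <- comp[comp$pair == res$pair[i] & comp$category == res$category[i], ]
    for (cl in cells) {
      g <- as.integer(strsplit(cl, "/", fixed = TRUE)[[1]])
      rows[[length(rows) + 1L]] <- data.frame(
        gene1 = res$gene1[i], gene2 = res$gene2[i],
        var1 = res$var1[i], var2 = res$var2[i],
        g1 = g[1], g2 = g[2], category = res$category[i],
        freq_cases = tab$n_cases[g[1] + 1, g[2] + 1] / tot_ca,
        freq_controls = tab$n_controls[g[1] + 1, g[2] + 1] / tot_co,
        or = res$or[i], ci_lo = res$ci_lo[i], ci_hi = res$ci_hi[i],
        fdr_q = res$fdr_q[i],
        permutation_p = if ("permutation_p" %in% names(res))
          res$permutation_p[i] else NA_real_,
        delta_var1 = if (nrow(ci)) ci$delta_var1[1] else NA_real_,
        delta_var2 = if (nrow(ci)) ci$delta_var2[1] else NA_real_,
        delta_var1_var2 = if (nrow(ci)) ci$delta_var1_var2[1] else NA_real_,
        retained = if (nrow(ci)) ci$retained[1] else NA,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(gene1 = character(0), gene2 = character(0),
               var1 = character(0), var2 = character(0),
               g1 = integer(0), g2 = integer(0), category = character(0),
               freq_cases = numeric(0), freq_controls = numeric(0),
               or = numeric(0), ci_lo = numeric(0), ci_hi = numeric(0),
               fdr_q = numeric(0), permutation_p = numeric(0),
               delta_var1 = numeric(0), delta_var2 = numeric(0),
               delta_var1_var2 = numeric(0), retained = logical(0))
}

#' Run the discovery workflow end-to-end
#'
#' Executes, in order: site-QC filtering, selection of rare variants
#' co-segregating with disease in at least one family, gene-set
#' over-representation of the non-neutral co-segregating genes, an
#' MB-MDR pairwise scan restricted to the genes of the chosen pathway
#' (QC-passing variants, rare and frequent), permutation confirmation of
#' the significant categories, and AICc model competition. Any stage
#' error halts the run with the stage name.
#'
#' @param vcf,ped,gmt input file paths (see [read_vcf()],
#'   [read_pedigree()], [read_gene_sets()]).
#' @param out_dir optional directory; when given, per-stage TSVs and a
#'   JSON manifest are written.
#' @param thresholds a [filter_thresholds()].
#' @param qc_thresholds a [pair_qc_thresholds()].
#' @param alpha_cell,min_cell,fdr_level MB-MDR parameters ([mbmdr()]).
#' @param perm_B permutations per significant category (default 999).
#' @param top_k cap on permuted categories (default 1000).
#' @param delta_threshold AICc retention threshold (default 10).
#' @param pathway set id to scan; default: the most significant enriched
#'   set.
#' @param seed integer seed controlling the permutation draws.
#' @return an object of class `"discovery_bundle"`: list with `cohort`,
#'   `filter` (audit), `segregation`, `enrichment`, `pathway`,
#'   `scan` (the [mbmdr()] fit with permutation p-values),
#'   `model_selection`, `summary` (Table-style listing of significant
#'   interactions with one row per category cell) and `manifest`.
#' @export
run_discovery <- function(vcf, ped, gmt, out_dir = NULL,
                          thresholds = filter_thresholds(),
                          qc_thresholds = pair_qc_thresholds(),
                          alpha_cell = 0.1, min_cell = 10,
                          fdr_level = 0.05, perm_B = 999, top_k = 1000,
                          delta_threshold = 10, pathway = NULL,
                          seed = 1) {
  co <- stage("read", {
    x <- read_vcf(vcf)
    x <- attach_pedigree(x, read_pedigree(ped))
    x
  })
  sets <- stage("read", read_gene_sets(gmt))
  filt <- stage("filter", filter_variants(co, thresholds))
  cq <- filt$cohort

  seg <- stage("segregate", {
    rare_ids <- names(which(is_rare(cq$variants, thresholds)))
    select_cosegregating(cq, variants = rare_ids)
  })
  ora <- stage("enrich", {
    nn <- is_non_neutral(cq$variants, thresholds)
    sel_var <- intersect(seg$selected, names(which(nn)))
    sel_genes <- unique(cq$variants$gene[cq$variants$variant_id %in% sel_var])
    universe <- unique(cq$variants$gene)
    run_ora(sel_genes[!is.na(sel_genes)], sets, universe[!is.na(universe)],
            fdr_level)
  })
  if (is.null(pathway)) {
    if (nrow(ora) == 0 || !any(ora$significant))
      stop("stage 'enrich': no significantly enriched gene set; pass `pathway` explicitly")
    pathway <- ora$set_id[which.min(ora$fdr_q)]
  }
  path_genes <- sets[[pathway]]$genes

  scan <- stage("epistasis", {
    vids <- cq$variants$variant_id[cq$variants$gene %in% path_genes]
    if (length(vids) < 2) {
      message("epistasis: fewer than two pathway variants; zero pairs tested")
      mbmdr(cq, pairs = matrix(character(0), ncol = 2),
            alpha_cell = alpha_cell, min_cell = min_cell,
            fdr_level = fdr_level, qc_thresholds = qc_thresholds)
    } else {
      fit <- mbmdr(cq, pairs = t(combn(vids, 2)), alpha_cell = alpha_cell,
                   min_cell = min_cell, fdr_level = fdr_level,
                   qc_thresholds = qc_thresholds)
      mbmdr_permute(fit, cq, B = perm_B, seed = seed, top_k = top_k)
    }
  })
  comp <- stage("select-models", mbmdr_compete(scan, cq,
                                               delta_threshold = delta_threshold))
  summ <- interaction_summary(scan, comp)
  manifest <- list(
    package = "epifam",
    version = as.character(utils::packageVersion("epifam")),
    seed = seed,
    inputs = list(vcf = basename(vcf), ped = basename(ped),
                  gmt = basename(gmt)),
    thresholds = unclass(thresholds),
    pair_qc = unclass(qc_thresholds),
    mbmdr = list(alpha_cell = alpha_cell, min_cell = min_cell,
                 fdr_level = fdr_level, perm_B = perm_B, top_k = top_k),
    delta_threshold = delta_threshold,
    pathway = pathway,
    note = paste("Family members are treated as independent in the",
                 "epistasis scan; relatedness is not modelled."))
  bundle <- structure(list(cohort = cq, filter = filt$audit,
                           segregation = seg, enrichment = ora,
                           pathway = pathway, scan = scan,
                           model_selection = comp, summary = summ,
                           manifest = manifest),
                      class = "discovery_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' @export
print.discovery_bundle <- function(x, ...) {
  cat("<discovery_bundle>\n")
  cat(sprintf("  cohort: %d samples x %d QC-passing variants\n",
              nrow(x$cohort$samples), nrow(x$cohort$variants)))
  cat(sprintf("  co-segregating variants selected: %d\n",
              length(x$segregation$selected)))
  cat(sprintf("  pathway scanned: %s\n", x$pathway))
  cat(sprintf("  significant categories: %d; retained interactions: %d\n",
              sum(x$scan$results$significant),
              sum(x$model_selection$retained, na.rm = TRUE)))
  invisible(x)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_results_tsv(bundle$filter, file.path(out_dir, "01_filter_audit.tsv"))
  write_results_tsv(bundle$segregation$counts,
                    file.path(out_dir, "02_segregation.tsv"))
  write_results_tsv(bundle$enrichment, file.path(out_dir, "03_enrichment.tsv"))
  if (!is.null(bundle$scan$qc))
    write_results_tsv(bundle$scan$qc, file.path(out_dir, "04_pair_qc.tsv"))
  write_results_tsv(bundle$scan$results,
                    file.path(out_dir, "05_epistasis.tsv"))
  write_results_tsv(bundle$model_selection,
                    file.path(out_dir, "06_model_selection.tsv"))
  write_results_tsv(bundle$summary, file.path(out_dir, "07_interactions.tsv"))
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the replication workflow on selected pairs
#'
#' Re-applies the MB-MDR scan and model competition to the pairs selected
#' in discovery, on an independent replication cohort. A discovery
#' category replicates when the replication scan finds the same
#' category label (H or L) significant — permutation p-values
#' Benjamini-Hochberg-adjusted across all replication tests — with at
#' least one genotype cell in common; a same-label significant category
#' with disjoint cells is flagged `"category_mismatch"`. Pairs whose
#' variants are absent from the replication data are `"untestable"`.
#'
#' @param vcf,ped replication cohort inputs.
#' @param discovery a `discovery_bundle` or a data frame with columns
#'   `var1`, `var2`, `category`, `cells` (the discovery categories to
#'   replicate).
#' @param out_dir optional output directory for TSVs.
#' @param fdr_level significance level on the adjusted replication
#'   p-values (default 0.05).
#' @param perm_B permutations per category (default 999).
#' @param delta_threshold AICc retention threshold (default 10).
#' @param qc_thresholds a [pair_qc_thresholds()].
#' @param alpha_cell,min_cell MB-MDR parameters.
#' @param seed integer seed.
#' @return an object of class `"replication_bundle"`: list with
#'   `cohort`, `scan`, `model_selection`, `replication` (per discovery
#'   category: status and replication statistics) and `manifest`.
#' @export
run_replication <- function(vcf, ped, discovery, out_dir = NULL,
                            fdr_level = 0.05, perm_B = 999,
                            delta_threshold = 10,
                            qc_thresholds = pair_qc_thresholds(),
                            alpha_cell = 0.1, min_cell = 10, seed = 1) {
  selected <- if (inherits(discovery, "discovery_bundle")) {
    res <- discovery$scan$results
    res[res$significant, c("var1", "var2", "category", "cells")]
  } else as.data.frame(discovery)
  stopifnot(all(c("var1", "var2", "category", "cells") %in% names(selected)))
  if (nrow(selected) == 0) stop("no discovery categories to replicate")

  co <- stage("read", attach_pedigree(read_vcf(vcf), read_pedigree(ped)))
  have <- selected$var1 %in% co$variants$variant_id &
          selected$var2 %in% co$variants$variant_id
  pairs <- unique(selected[have, c("var1", "var2"), drop = FALSE])

  scan <- stage("epistasis", {
    if (nrow(pairs) == 0) {
      mbmdr(co, pairs = matrix(character(0), ncol = 2),
            alpha_cell = alpha_cell, min_cell = min_cell,
            fdr_level = fdr_level, qc_thresholds = qc_thresholds)
    } else {
      fit <- mbmdr(co, pairs = as.matrix(pairs), alpha_cell = alpha_cell,
                   min_cell = min_cell, fdr_level = fdr_level,
                   qc_thresholds = qc_thresholds)
      mbmdr_permute(fit, co, B = perm_B, seed = seed,
                    only_significant = FALSE)
    }
  })
  rres <- scan$results
  rres$replication_q <- if (nrow(rres) && any(!is.na(rres$permutation_p)))
    bh_adjust(rres$permutation_p) else rep(NA_real_, nrow(rres))
  comp <- stage("select-models",
                mbmdr_compete(scan, co, which = "all",
                              delta_threshold = delta_threshold))

  status <- character(nrow(selected))
  rep_rows <- vector("list", nrow(selected))
  for (i in seq_len(nrow(selected))) {
    if (!have[i]) { status[i] <- "untestable"; next }
    pid <- paste(selected$var1[i], selected$var2[i], sep = "*")
    if (!pid %in% names(scan$tables)) { status[i] <- "qc_fail"; next }
    same <- rres[rres$pair == pid & rres$category == selected$category[i], ,
                 drop = FALSE]
    if (nrow(same) == 0 || all(is.na(same$replication_q)) ||
        !any(same$replication_q < fdr_level, na.rm = TRUE)) {
      status[i] <- "not_significant"
    } else {
      dcells <- strsplit(selected$cells[i], ";", fixed = TRUE)[[1]]
      rcells <- strsplit(same$cells[1], ";", fixed = TRUE)[[1]]
      status[i] <- if (length(intersect(dcells, rcells)))
        "replicated" else "category_mismatch"
    }
    rep_rows[[i]] <- same[1, c("statistic", "p", "permutation_p",
                               "replication_q", "or", "cells")]
  }
  replication <- data.frame(
    pair = paste(selected$var1, selected$var2, sep = "*"),
    category = selected$category,
    discovery_cells = selected$cells,
    replication_cells = vapply(rep_rows, function(r)
      if (is.null(r)) NA_character_ else r$cells, character(1)),
    replication_perm_p = vapply(rep_rows, function(r)
      if (is.null(r)) NA_real_ else r$permutation_p, numeric(1)),
    replication_q = vapply(rep_rows, function(r)
      if (is.null(r)) NA_real_ else r$replication_q, numeric(1)),
    replication_or = vapply(rep_rows, function(r)
      if (is.null(r)) NA_real_ else r$or, numeric(1)),
    status = status, stringsAsFactors = FALSE)

  manifest <- list(package = "epifam",
                   version = as.character(utils::packageVersion("epifam")),
                   seed = seed, fdr_level = fdr_level, perm_B = perm_B,
                   delta_threshold = delta_threshold)
  bundle <- structure(list(cohort = co, scan = scan,
                           model_selection = comp,
                           replication = replication, manifest = manifest),
                      class = "replication_bundle")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results_tsv(rres, file.path(out_dir, "01_epistasis.tsv"))
    write_results_tsv(comp, file.path(out_dir, "02_model_selection.tsv"))
    write_results_tsv(replication, file.path(out_dir, "03_replication.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  bundle
}

#' @export
print.replication_bundle <- function(x, ...) {
  cat("<replication_bundle>\n")
  tab <- table(x$replication$status)
  for (s in names(tab)) cat(sprintf("  %s: %d\n", s, tab[[s]]))
  invisible(x)
}
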