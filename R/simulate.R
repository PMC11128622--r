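#' Default multiplex-family layouts
#'
#' Nine nuclear families totalling 30 members: 19 designated affected and
#' 11 unaffected under the default planting (complete penetrance, no
#' phenocopy), mirroring a small multiplex-family discovery design. Seven
#' families are parent-pair + one child trios with two affected members,
#' one is a five-member family with three affected, and one a four-member
#' family with two affected. The `carrier` column designates the affected
#' branch through which planted variants are transmitted (one carrier
#' founder plus carrier offspring, always Mendelian-consistent).
#'
#' @return named list of pedigree data frames with columns `member_id`,
#'   `father`, `mother` (`"0"` for founders), `sex` and `carrier`.
#' @export
default_pedigrees <- function() {
  make_fam <- function(fid, n_children, carrier_children, child_sexes) {
    fa <- paste0(fid, "_FA"); mo <- paste0(fid, "_MO")
    kids <- paste0(fid, "_C", seq_len(n_children))
    data.frame(
      member_id = c(fa, mo, kids),
      father = c("0", "0", rep(fa, n_children)),
      mother = c("0", "0", rep(mo, n_children)),
      sex = c("male", "female", child_sexes),
      carrier = c(TRUE, FALSE, seq_len(n_children) %in% carrier_children),
      stringsAsFactors = FALSE)
  }
  fams <- c(
    lapply(1:7, function(i) make_fam(paste0("F", i), 1, 1,
                                     if (i %% 2) "female" else "male")),
    list(make_fam("F8", 3, c(1, 2), c("female", "male", "female")),
         make_fam("F9", 2, 1, c("male", "female"))))
  names(fams) <- paste0("F", 1:9)
  fams
}

#' Two-locus penetrance table
#'
#' Disease probabilities `f(g1, g2)` over the 3x3 dosage grid, marker
#' allele frequencies, and a multiplicative sex effect on the odds scale
#' (`sex_or_female` > 1 raises female risk, exercising the sex adjustment
#' in the analysis stages).
#'
#' @param f 3x3 matrix of disease probabilities, rows = dosage of locus
#'   1.
#' @param q1,q2 alternate-allele frequencies of the two loci.
#' @param sex_or_female odds multiplier applied to females (default 1.5).
#' @return an object of class `"penetrance_table"`.
#' @export
penetrance_table <- function(f, q1, q2, sex_or_female = 1.5) {
  f <- as.matrix(f)
  stopifnot(all(dim(f) == c(3, 3)), all(f >= 0 & f <= 1),
            q1 > 0, q1 < 1, q2 > 0, q2 < 1, sex_or_female > 0)
  dimnames(f) <- list(g1 = 0:2, g2 = 0:2)
  structure(list(f = f, q1 = q1, q2 = q2, sex_or_female = sex_or_female),
            class = "penetrance_table")
}

#' Default epistatic penetrance table
#'
#' Background disease probability 0.1 with two high-risk genotype cells,
#' (1,1) and (0,2), at probability 0.625: each high-risk cell carries a
#' genotype-cell odds ratio of exactly 15 against the background,
#' matching the magnitude of the strongest pairwise interactions this
#' kind of scan reports. Both marker frequencies are 0.5, so the
#' high-risk mass is concentrated off the dosage diagonal and is poorly
#' captured by additive single-locus models.
#'
#' @inheritParams penetrance_table
#' @export
default_penetrance_table <- function(sex_or_female = 1.5) {
  f <- matrix(0.1, 3, 3)
  f[2, 2] <- 0.625  # cell (1,1)
  f[1, 3] <- 0.625  # cell (0,2)
  penetrance_table(f, 0.5, 0.5, sex_or_female)
}

#' Penetrance table with additive marginal effects only
#'
#' Disease log-odds increase linearly with the total dosage
#' `g1 + g2`; there is no interaction structure. Used to verify that the
#' AICc competition does not retain interaction models for purely
#' marginal signals.
#'
#' @param or_per_allele per-allele odds ratio (default 2.5).
#' @param f0 baseline disease probability at dosage (0, 0).
#' @inheritParams penetrance_table
#' @export
additive_penetrance_table <- function(or_per_allele = 2.5, f0 = 0.1,
                                      q1 = 0.5, q2 = 0.5,
                                      sex_or_female = 1.5) {
  g <- outer(0:2, 0:2, `+`)
  f <- plogis(log(f0 / (1 - f0)) + log(or_per_allele) * g)
  penetrance_table(matrix(f, 3, 3), q1, q2, sex_or_female)
}

#' Flat (null) penetrance table
#'
#' Constant disease probability: genotypes carry no risk information.
#'
#' @param f0 disease probability (default 0.5).
#' @inheritParams penetrance_table
#' @export
flat_penetrance_table <- function(f0 = 0.5, q1 = 0.5, q2 = 0.5,
                                  sex_or_female = 1.5) {
  penetrance_table(matrix(f0, 3, 3), q1, q2, sex_or_female)
}

# disease probability for dosages g1, g2 (0..2) and sex ("female"/"male")
risk_prob <- function(pen, g1, g2, sex) {
  f <- pen$f[cbind(g1 + 1L, g2 + 1L)]
  mult <- ifelse(sex == "female", pen$sex_or_female, 1)
  odds <- f / (1 - f) * mult
  p <- odds / (1 + odds)
  p[f == 0] <- 0
  p[f == 1] <- 1
  p
}

#' Drop a biallelic marker through a pedigree
#'
#' Founder genotypes are drawn binomially from the allele frequency;
#' each offspring receives one allele per parent, transmitted with
#' probability `dosage/2`. Offspring are resolved iteratively; a pedigree
#' where some member can never be resolved (a cycle) is an error.
#'
#' @param ped pedigree data frame with columns `member_id`, `father`,
#'   `mother` (`"0"` for founders).
#' @param q alternate-allele frequency in founders (0 < q < 1).
#' @return named integer dosage vector over the pedigree members.
#' @export
gene_drop <- function(ped, q) {
  stopifnot(q > 0, q < 1)
  n <- nrow(ped)
  dos <- setNames(rep(NA_integer_, n), ped$member_id)
  founder <- ped$father == "0" & ped$mother == "0"
  dos[founder] <- rbinom(sum(founder), 2, q)
  while (anyNA(dos)) {
    todo <- which(is.na(dos))
    ready <- todo[!is.na(dos[ped$father[todo]]) & !is.na(dos[ped$mother[todo]])]
    if (length(ready) == 0) stop("cyclic or incomplete pedigree")
    for (i in ready) {
      a1 <- rbinom(1, 1, dos[ped$father[i]] / 2)
      a2 <- rbinom(1, 1, dos[ped$mother[i]] / 2)
      dos[i] <- a1 + a2
    }
  }
  dos
}

#' Plant a co-segregating variant in a family
#'
#' The designated carriers (the pedigree's `carrier` column) receive one
#' copy of the variant; everyone else none. Affection is then drawn from
#' carrier status: each carrier is affected with probability
#' `penetrance`, each non-carrier with probability `phenocopy_rate`. At
#' the defaults (complete penetrance, no phenocopy) the family verdict is
#' `"qualifies"` by construction.
#'
#' @param ped pedigree data frame with a logical `carrier` column.
#' @param penetrance probability a carrier is affected (default 1).
#' @param phenocopy_rate probability a non-carrier is affected
#'   (default 0).
#' @return list with `dosage` (named integer) and `affected` (named
#'   logical).
#' @export
plant_cosegregating_variant <- function(ped, penetrance = 1,
                                        phenocopy_rate = 0) {
  stopifnot(penetrance >= 0, penetrance <= 1,
            phenocopy_rate >= 0, phenocopy_rate <= 1)
  carrier <- ped$carrier
  dosage <- setNames(as.integer(carrier), ped$member_id)
  p <- ifelse(carrier, penetrance, phenocopy_rate)
  affected <- setNames(rbinom(nrow(ped), 1, p) == 1, ped$member_id)
  list(dosage = dosage, affected = affected)
}

#' Simulate an unrelated case-control cohort around one epistatic pair
#'
#' Individuals are drawn with genotypes from Hardy-Weinberg products of
#' the two allele frequencies and sex from Bernoulli(0.5); disease status
#' follows the penetrance table (with the sex odds multiplier). Sampling
#' continues until the case and control quotas are both met (rejection
#' sampling), so the returned cohort has exactly the requested
#' composition.
#'
#' @param pen a [penetrance_table()].
#' @param n_cases,n_controls quotas.
#' @param seed optional integer seed; the same seed yields an identical
#'   cohort.
#' @param variant_ids,genes ids and gene symbols of the two planted
#'   variants.
#' @return a [cohort()] of unrelated samples with two variants.
#' @export
simulate_epistatic_pair <- function(pen, n_cases, n_controls, seed = NULL,
                                    variant_ids = c("rsEPI1", "rsEPI2"),
                                    genes = c("GENE001", "GENE002")) {
  stopifnot(inherits(pen, "penetrance_table"))
  if (n_cases > 0 && all(pen$f == 0))
    stop("unreachable case quota: all penetrances are zero")
  if (n_controls > 0 && all(pen$f == 1))
    stop("unreachable control quota: all penetrances are one")
  if (!is.null(seed)) set.seed(seed)
  acc <- list(g1 = integer(0), g2 = integer(0), sex = character(0),
              y = integer(0))
  got_cases <- 0L; got_controls <- 0L; iter <- 0L
  while ((got_cases < n_cases || got_controls < n_controls)) {
    iter <- iter + 1L
    if (iter > 10000L) stop("rejection sampling did not reach the quotas")
    nb <- 512L
    g1 <- rbinom(nb, 2, pen$q1)
    g2 <- rbinom(nb, 2, pen$q2)
    sex <- ifelse(rbinom(nb, 1, 0.5) == 1, "female", "male")
    y <- rbinom(nb, 1, risk_prob(pen, g1, g2, sex))
    keep <- (y == 1 & got_cases + cumsum(y == 1) <= n_cases) |
            (y == 0 & got_controls + cumsum(y == 0) <= n_controls)
    acc$g1 <- c(acc$g1, g1[keep]); acc$g2 <- c(acc$g2, g2[keep])
    acc$sex <- c(acc$sex, sex[keep]); acc$y <- c(acc$y, y[keep])
    got_cases <- sum(acc$y == 1); got_controls <- sum(acc$y == 0)
  }
  n <- length(acc$y)
  samples <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    family_id = "UNRELATED", sex = acc$sex,
    affected = ifelse(acc$y == 1, "case", "control"),
    stringsAsFactors = FALSE)
  variants <- data.frame(
    variant_id = variant_ids, chrom = c("1", "2"), pos = c(1000L, 2000L),
    ref = "A", alt = "G", gene = genes,
    dp = 60, mq = 60, qd = 25, fs = 2, call_rate = 1,
    impact = "NONE", cadd_phred = NA_real_,
    af_kg1000_eur = c(pen$q1, pen$q2), af_exac = c(pen$q1, pen$q2),
    af_esp6500 = NA_real_, af_cg69 = NA_real_,
    stringsAsFactors = FALSE)
  cohort(samples, variants, cbind(acc$g1, acc$g2))
}

# conditional epistatic-pair genotypes for unrelated samples given
# affection and sex: exact retrospective draw over the nine HWE-weighted
# cells
retrospective_pair_draw <- function(pen, affected, sex) {
  hw <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)
  prior <- outer(hw(pen$q1), hw(pen$q2))
  grid <- expand.grid(g1 = 0:2, g2 = 0:2)
  n <- length(affected)
  g1 <- integer(n); g2 <- integer(n)
  for (i in seq_len(n)) {
    r <- risk_prob(pen, grid$g1, grid$g2, sex[i])
    w <- prior[cbind(grid$g1 + 1, grid$g2 + 1)] *
      (if (affected[i]) r else 1 - r)
    pick <- sample.int(9, 1, prob = w)
    g1[i] <- grid$g1[pick]; g2[i] <- grid$g2[pick]
  }
  list(g1 = g1, g2 = g2)
}

# conditional epistatic-pair genotypes inside one family: gene-drop with
# rejection on the affection pattern (exact conditional sampling that
# stays Mendelian-consistent)
family_pair_draw <- function(ped, pen, affected) {
  for (iter in seq_len(100000L)) {
    d1 <- gene_drop(ped, pen$q1)
    d2 <- gene_drop(ped, pen$q2)
    r <- risk_prob(pen, d1, d2, ped$sex)
    w <- prod(ifelse(affected, r, 1 - r))
    if (runif(1) < w) return(list(g1 = d1, g2 = d2))
  }
  stop("family conditional sampling did not converge")
}

#' Simulation configuration for a full study fixture
#'
#' Bundles the pedigree layouts, planted co-segregating variants,
#' planted epistatic pair, null variants, gene sets and nuisance rates
#' that [simulate_study()] and [emit_fixture()] consume. The defaults
#' emulate a familial discovery design: nine multiplex families (19
#' affected / 11 unaffected) plus 98 unrelated controls; 17 rare,
#' fully penetrant, no-phenocopy variants private to single families
#' (12 of them in the 25-gene focal-adhesion-like pathway, 5 elsewhere);
#' one common epistatic pair in pathway genes with cell odds ratio 15
#' ([default_penetrance_table()]); 60 common null variants spread over
#' 60 genes; and 1% uniform genotype missingness (planted
#' co-segregating genotypes within their own family are exempt so their
#' selection is deterministic).
#'
#' @param pedigrees named list of pedigree layouts
#'   ([default_pedigrees()]).
#' @param n_unrelated_controls,n_unrelated_cases unrelated sample counts
#'   (defaults 98 and 0; a replication design would use 91 and 200).
#' @param coseg data frame of planted co-segregating variants
#'   (`variant_id`, `gene`, `family`, `penetrance`, `phenocopy`).
#' @param epi `NULL`, or list with `pen` (a [penetrance_table()]),
#'   `variant_id` (length 2) and `gene` (length 2).
#' @param n_null_variants number of common null variants.
#' @param n_qc_fail number of null variants written with failing site-QC
#'   metrics (default 0).
#' @param missing_rate uniform genotype missingness rate (default 0.01).
#' @param gene_sets gene sets written to the fixture GMT
#'   ([default_gene_sets()]).
#' @param pathway set id of the planted pathway.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(pedigrees = default_pedigrees(),
                       n_unrelated_controls = 98,
                       n_unrelated_cases = 0,
                       coseg = default_coseg_spec(),
                       epi = list(pen = default_penetrance_table(),
                                  variant_id = c("rsEPI1", "rsEPI2"),
                                  gene = c("GENE001", "GENE002")),
                       n_null_variants = 60,
                       n_qc_fail = 0,
                       missing_rate = 0.01,
                       gene_sets = default_gene_sets(),
                       pathway = "FOCAL_ADHESION_SYN") {
  stopifnot(missing_rate >= 0, missing_rate < 1)
  structure(list(pedigrees = pedigrees,
                 n_unrelated_controls = n_unrelated_controls,
                 n_unrelated_cases = n_unrelated_cases,
                 coseg = coseg, epi = epi,
                 n_null_variants = n_null_variants,
                 n_qc_fail = n_qc_fail,
                 missing_rate = missing_rate,
                 gene_sets = gene_sets, pathway = pathway),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_coseg_spec <- function() {
  path_genes <- sprintf("GENE%03d", 3:14)
  other_genes <- sprintf("GENE%03d", c(30, 35, 40, 45, 50))
  fams <- paste0("F", c(1:9, 1:3))
  data.frame(
    variant_id = sprintf("rsCOSEG%02d", 1:17),
    gene = c(path_genes, other_genes),
    family = c(fams, paste0("F", 4:8)),
    penetrance = 1, phenocopy = 0,
    stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
default_gene_sets <- function() {
  gs <- list(
    list(set_id = "FOCAL_ADHESION_SYN",
         name = "synthetic focal-adhesion-like pathway",
         genes = sprintf("GENE%03d", 1:25)),
    list(set_id = "DECOY_1", name = "decoy set 1",
         genes = sprintf("GENE%03d", 26:50)),
    list(set_id = "DECOY_2", name = "decoy set 2",
         genes = sprintf("GENE%03d", 36:60)),
    list(set_id = "DECOY_3", name = "decoy set 3",
         genes = sprintf("GENE%03d", 46:70)),
    list(set_id = "DECOY_4", name = "decoy set 4",
         genes = sprintf("GENE%03d", 56:80)),
    list(set_id = "DECOY_5", name = "decoy set 5",
         genes = sprintf("GENE%03d", 20:44)))
  names(gs) <- vapply(gs, `[[`, character(1), "set_id")
  gs
}

#' Simulate a full study cohort from a configuration
#'
#' Builds the family samples (affection from the planted co-segregating
#' branches), unrelated cases/controls, and the full dosage matrix:
#' planted co-segregating variants (heterozygous in their designated
#' family branch, absent elsewhere, no reference-panel frequencies),
#' the planted epistatic pair (drawn conditionally on affection — exact
#' retrospective sampling for unrelated samples, rejection-sampled gene
#' drops inside families so transmissions stay Mendelian), and common
#' null variants (gene drops in families, Hardy-Weinberg draws in
#' unrelated samples). Uniform missingness is injected last, sparing
#' planted co-segregating genotypes within their own family.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (mandatory; the same seed yields an
#'   identical cohort).
#' @return a [cohort()]; the sample table carries `father`/`mother`
#'   columns for PED round-tripping.
#' @export
simulate_study <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  peds <- config$pedigrees

  # ---- samples ----
  fam_rows <- lapply(names(peds), function(f) {
    p <- peds[[f]]
    data.frame(sample_id = p$member_id, family_id = f,
               sex = p$sex, affected = NA_character_,
               father = p$father, mother = p$mother,
               stringsAsFactors = FALSE)
  })
  n_ca <- config$n_unrelated_cases
  n_co <- config$n_unrelated_controls
  unrel <- data.frame(
    sample_id = c(sprintf("CASE%03d", seq_len(n_ca)),
                  sprintf("CTRL%03d", seq_len(n_co))),
    family_id = "UNRELATED",
    sex = ifelse(rbinom(n_ca + n_co, 1, 0.5) == 1, "female", "male"),
    affected = rep(c("case", "control"), c(n_ca, n_co)),
    father = "0", mother = "0", stringsAsFactors = FALSE)
  samples <- rbind(do.call(rbind, c(fam_rows, list(NULL))), unrel)

  # ---- family affection from the designated carrier branches ----
  for (f in names(peds)) {
    p <- peds[[f]]
    cs <- config$coseg[config$coseg$family == f, , drop = FALSE]
    pen <- if (nrow(cs)) cs$penetrance[1] else 1
    phe <- if (nrow(cs)) cs$phenocopy[1] else 0
    plant <- plant_cosegregating_variant(p, pen, phe)
    idx <- match(p$member_id, samples$sample_id)
    samples$affected[idx] <- ifelse(plant$affected, "case", "control")
  }
  affected <- samples$affected == "case"

  # ---- variants ----
  passing_qc <- list(dp = 60, mq = 60, qd = 25, fs = 2)
  failing_qc <- list(dp = 5, mq = 60, qd = 25, fs = 2)
  mk_var <- function(id, gene, chrom, pos, impact, cadd, af, qc) {
    data.frame(variant_id = id, chrom = chrom, pos = pos, ref = "A",
               alt = "G", gene = gene, dp = qc$dp, mq = qc$mq, qd = qc$qd,
               fs = qc$fs, call_rate = 1, impact = impact,
               cadd_phred = cadd,
               af_kg1000_eur = af, af_exac = af, af_esp6500 = NA_real_,
               af_cg69 = NA_real_, stringsAsFactors = FALSE)
  }
  n <- nrow(samples)
  var_list <- list(); dos_list <- list()

  # planted co-segregating variants: private to one family branch
  cs <- config$coseg
  for (i in seq_len(nrow(cs))) {
    p <- peds[[cs$family[i]]]
    d <- rep(0L, n)
    d[match(p$member_id, samples$sample_id)] <- as.integer(p$carrier)
    var_list[[length(var_list) + 1L]] <-
      mk_var(cs$variant_id[i], cs$gene[i], "3",
             10000L + 100L * i, "MODERATE", 25, NA_real_, passing_qc)
    dos_list[[length(dos_list) + 1L]] <- d
  }

  # planted epistatic pair, conditional on affection
  if (!is.null(config$epi)) {
    pen <- config$epi$pen
    g1 <- integer(n); g2 <- integer(n)
    for (f in names(peds)) {
      p <- peds[[f]]
      idx <- match(p$member_id, samples$sample_id)
      fd <- family_pair_draw(p, pen, affected[idx])
      g1[idx] <- fd$g1; g2[idx] <- fd$g2
    }
    uidx <- which(samples$family_id == "UNRELATED")
    if (length(uidx)) {
      ud <- retrospective_pair_draw(pen, affected[uidx], samples$sex[uidx])
      g1[uidx] <- ud$g1; g2[uidx] <- ud$g2
    }
    for (j in 1:2) {
      var_list[[length(var_list) + 1L]] <-
        mk_var(config$epi$variant_id[j], config$epi$gene[j],
               as.character(j), 1000L * j, "NONE", NA_real_,
               c(pen$q1, pen$q2)[j], passing_qc)
      dos_list[[length(dos_list) + 1L]] <- if (j == 1) g1 else g2
    }
  }

  # common null variants, independent of affection
  fam_names <- samples$family_id
  for (j in seq_len(config$n_null_variants)) {
    q <- round(runif(1, 0.1, 0.45), 3)
    d <- integer(n)
    for (f in names(peds)) {
      p <- peds[[f]]
      d[match(p$member_id, samples$sample_id)] <- gene_drop(p, q)
    }
    uidx <- which(fam_names == "UNRELATED")
    d[uidx] <- rbinom(length(uidx), 2, q)
    qc <- if (j <= config$n_qc_fail) failing_qc else passing_qc
    var_list[[length(var_list) + 1L]] <-
      mk_var(sprintf("rsNULL%03d", j), sprintf("GENE%03d", (j - 1) %% 60 + 1),
             "4", 50000L + 100L * j, "NONE", NA_real_, q, qc)
    dos_list[[length(dos_list) + 1L]] <- as.integer(d)
  }

  variants <- do.call(rbind, var_list)
  dosage <- do.call(cbind, dos_list)
  colnames(dosage) <- variants$variant_id

  # ---- missingness (sparing planted family genotypes) ----
  if (config$missing_rate > 0) {
    mask <- matrix(runif(length(dosage)) < config$missing_rate,
                   nrow = nrow(dosage))
    for (i in seq_len(nrow(cs))) {
      p <- peds[[cs$family[i]]]
      mask[match(p$member_id, samples$sample_id), i] <- FALSE
    }
    dosage[mask] <- NA_integer_
  }
  variants$call_rate <- colMeans(!is.na(dosage))

  cohort(samples, variants, dosage)
}

#' Write a simulated study to VCF + PED + GMT files
#'
#' Emits the merged VCF (families and unrelated samples), the 6-column
#' PED, the GMT with the planted pathway and decoy sets, and a JSON
#' manifest recording the configuration summary and seed. Deterministic:
#' the same configuration and seed produce byte-identical files.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return named list of file paths (`vcf`, `ped`, `gmt`, `manifest`),
#'   invisibly; the simulated [cohort()] is attached as attribute
#'   `"cohort"`.
#' @export
emit_fixture <- function(config, dir, seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  x <- simulate_study(config, seed)
  paths <- list(vcf = file.path(dir, "study.vcf"),
                ped = file.path(dir, "study.ped"),
                gmt = file.path(dir, "study.gmt"),
                manifest = file.path(dir, "manifest.json"))
  write_vcf(x, paths$vcf)
  write_pedigree(x$samples, paths$ped)
  write_gene_sets(config$gene_sets, paths$gmt)
  manifest <- list(
    seed = seed,
    n_families = length(config$pedigrees),
    n_family_members = sum(vapply(config$pedigrees, nrow, integer(1))),
    n_unrelated_controls = config$n_unrelated_controls,
    n_unrelated_cases = config$n_unrelated_cases,
    n_coseg_variants = nrow(config$coseg),
    epi_pair = if (is.null(config$epi)) NULL else config$epi$variant_id,
    n_null_variants = config$n_null_variants,
    n_qc_fail = config$n_qc_fail,
    missing_rate = config$missing_rate,
    pathway = config$pathway)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  out <- paths
  attr(out, "cohort") <- x
  invisible(out)
}
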