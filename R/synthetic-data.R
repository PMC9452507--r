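# Synthetic cohort generators.
#
# Every pipeline stage is exercised on cohorts generated here with a known
# ground truth ("truth table"), so the whole resource can be tested without
# any restricted-access download. Generators are pure functions of
# (config, seed): identical inputs give identical outputs.

#' Simulation configuration
#'
#' Collects every knob of the synthetic cohort in one validated object.
#' Defaults describe the reference cohort emulated throughout the package:
#' 192 liver samples (about 35% female), hard-call genotype dosages in
#' Hardy-Weinberg proportions, a 1 Mb cis window, unit latent noise, and a
#' six-dataset TWAS panel with equicorrelation 0.5.
#'
#' @param n_samples number of samples (>= 2).
#' @param n_variants number of autosomal variants.
#' @param n_genes number of genes.
#' @param maf_range length-2 interval in (0, 0.5] from which per-variant
#'   minor allele frequencies are drawn uniformly.
#' @param cis_window cis window half-width in bp (closed interval around TSS).
#' @param effect_table data.frame with columns `gene`, `variant`,
#'   `beta_latent` (additive effect on the latent normal scale per dosage
#'   unit) and `afc` (allelic fold change on the TPM scale; 1 = none), or
#'   NULL for a null cohort.
#' @param noise_sd residual standard deviation on the latent log scale.
#' @param sex_fraction_female proportion of female samples.
#' @param n_datasets number of TWAS reference datasets (>= 2).
#' @param panel_rho equicorrelation among null TWAS z columns; must lie in
#'   (-1/(n_datasets-1), 1) for positive definiteness.
#' @param causal_genes character vector of gene ids planted as causal in the
#'   TWAS panel.
#' @param causal_shift mean z added to causal genes in every panel.
#' @param missing_rate proportion of TWAS panel entries masked missing.
#' @param n_x_variants number of X-chromosome variants (males hemizygous).
#' @param seed integer seed; all generators derive their randomness from it.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 192, n_variants = 200, n_genes = 50,
                       maf_range = c(0.05, 0.5), cis_window = 1e6,
                       effect_table = NULL, noise_sd = 1,
                       sex_fraction_female = 0.35, n_datasets = 6,
                       panel_rho = 0.5, causal_genes = character(),
                       causal_shift = 4, missing_rate = 0,
                       n_x_variants = 60, seed = 1L) {
  stopifnot(n_samples >= 1, n_variants >= 1, n_genes >= 1, n_datasets >= 1,
            length(maf_range) == 2, cis_window > 0, noise_sd >= 0)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must be an interval within (0, 0.5]")
  if (abs(panel_rho) >= 1) stop("|panel_rho| must be < 1")
  stopifnot_prob(sex_fraction_female, "sex_fraction_female")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0,1)")
  if (!is.null(effect_table)) {
    req <- c("gene", "variant", "beta_latent", "afc")
    if (!all(req %in% names(effect_table)))
      stop("effect_table needs columns: ", paste(req, collapse = ", "))
  }
  structure(list(
    n_samples = as.integer(n_samples), n_variants = as.integer(n_variants),
    n_genes = as.integer(n_genes), maf_range = maf_range,
    cis_window = cis_window, effect_table = effect_table,
    noise_sd = noise_sd, sex_fraction_female = sex_fraction_female,
    n_datasets = as.integer(n_datasets), panel_rho = panel_rho,
    causal_genes = as.character(causal_genes), causal_shift = causal_shift,
    missing_rate = missing_rate, n_x_variants = as.integer(n_x_variants),
    seed = as.integer(seed)), class = "sim_config")
}

#' Synthetic gene annotation
#'
#' Lays genes out deterministically on two autosomes with 2.5 Mb spacing (so
#' neighbouring cis windows barely overlap), and appends one XIST-like
#' (chrX) and one RPS4Y1-like (chrY) sex-marker gene.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `gene_id`, `symbol`, `chrom`, `tss`,
#'   `strand`, `biotype`.
#' @export
gen_annotation <- function(config) {
  n <- config$n_genes
  ids <- sprintf("gene_%04d", seq_len(n))
  chrom <- rep(c("1", "2"), length.out = n)
  idx_on_chrom <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  tss <- 2e6 + (idx_on_chrom - 1) * 2.5e6
  ann <- data.frame(gene_id = ids, symbol = toupper(ids), chrom = chrom,
                    tss = tss, strand = "+", biotype = "protein_coding",
                    stringsAsFactors = FALSE)
  rbind(ann, data.frame(
    gene_id = c("XISTL", "RPS4Y1L"), symbol = c("XISTL", "RPS4Y1L"),
    chrom = c("X", "Y"), tss = c(73e6, 2.7e6), strand = "+",
    biotype = c("lincRNA", "protein_coding"), stringsAsFactors = FALSE))
}

#' Genotype matrix container
#'
#' @param dosage numeric matrix, samples x variants, entries in [0,2] (NA =
#'   missing call).
#' @param variants data.frame with at least `variant_id`, `chrom`, `pos`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants) {
  dosage <- as.matrix(dosage)
  stopifnot(ncol(dosage) == nrow(variants),
            all(c("variant_id", "chrom", "pos") %in% names(variants)))
  colnames(dosage) <- variants$variant_id
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%d on X)\n",
              nrow(x$dosage), ncol(x$dosage), sum(x$variants$chrom == "X")))
  invisible(x)
}

#' Generate hard-call genotype dosages under Hardy-Weinberg equilibrium
#'
#' Autosomal dosages are drawn per variant as {0,1,2} with probabilities
#' ((1-p)^2, 2p(1-p), p^2) at a minor allele frequency p sampled uniformly
#' from `maf_range`. A block of X-chromosome variants is appended on which
#' males are hemizygous (coded 0/2, never 1) and females follow HWE.
#' Autosomal variants are placed round-robin inside the cis windows of the
#' annotation's genes so every gene has local variants.
#'
#' @param config a [sim_config()].
#' @param annotation gene annotation as from [gen_annotation()]; generated
#'   from `config` when NULL.
#' @return list with elements `genotypes` (a [genotype_matrix()]), `sex`
#'   (per-sample true sex) and `annotation`.
#' @export
gen_genotypes <- function(config, annotation = NULL) {
  if (config$n_samples < 2) stop("n_samples must be >= 2")
  annotation <- annotation %||% gen_annotation(config)
  auto <- annotation[!annotation$chrom %in% c("X", "Y"), ]
  n <- config$n_samples
  set.seed(sub_seed(config$seed, 11L))
  sex <- ifelse(stats::runif(n) < config$sex_fraction_female, "female", "male")
  sample_ids <- sprintf("S%03d", seq_len(n))
  names(sex) <- sample_ids

  m <- config$n_variants
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  gidx <- rep(seq_len(nrow(auto)), length.out = m)
  pos <- auto$tss[gidx] +
    round(stats::runif(m, -0.9, 0.9) * config$cis_window)
  dos <- vapply(seq_len(m), function(j) {
    p <- maf[j]
    sample(0:2, n, replace = TRUE, prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
  }, numeric(n))

  mx <- config$n_x_variants
  if (mx > 0) {
    maf_x <- stats::runif(mx, config$maf_range[1], config$maf_range[2])
    dx <- vapply(seq_len(mx), function(j) {
      p <- maf_x[j]
      d <- numeric(n)
      male <- sex == "male"
      d[male] <- sample(c(0, 2), sum(male), replace = TRUE, prob = c(1 - p, p))
      d[!male] <- sample(0:2, sum(!male), replace = TRUE,
                         prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
      d
    }, numeric(n))
    dos <- cbind(dos, dx)
  }
  variants <- data.frame(
    variant_id = sprintf("var_%05d", seq_len(m + mx)),
    chrom = c(auto$chrom[gidx], rep("X", mx)),
    pos = c(pos, if (mx > 0) round(seq(1e6, 150e6, length.out = mx))),
    maf = c(maf, if (mx > 0) maf_x), stringsAsFactors = FALSE)
  rownames(dos) <- sample_ids
  list(genotypes = genotype_matrix(dos, variants), sex = sex,
       annotation = annotation)
}

#' Expression matrix container
#'
#' @param tpm,counts numeric matrices, genes x samples, sharing dimnames.
#' @param annotation gene annotation data.frame.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(tpm, counts, annotation) {
  stopifnot(identical(dim(tpm), dim(counts)),
            identical(rownames(tpm), rownames(counts)))
  structure(list(tpm = tpm, counts = counts, annotation = annotation),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              nrow(x$tpm), ncol(x$tpm)))
  invisible(x)
}

#' Generate expression with planted cis effects
#'
#' TPM for gene g in sample s is
#' `baseline_g * (1 + (afc-1)/2 * d) * exp(beta_latent * d + N(0, noise_sd^2))`
#' where d is the dosage of the gene's planted variant (if any): the
#' `beta_latent` term plants an additive effect on the latent log scale
#' (detectable by the linear scan after inverse-normal transformation) and
#' the `afc` term plants a multiplicative allelic fold change on the TPM
#' scale, with aFC defined as mean TPM at dosage 2 over mean TPM at dosage
#' 0. Counts are TPM times a per-sample library-size factor, rounded. One
#' XIST-like gene (high in females) and one RPS4Y1-like gene (high in
#' males) carry the sex signal.
#'
#' @param geno result of [gen_genotypes()].
#' @param config a [sim_config()] (its `effect_table` drives the planting).
#' @param annotation optional override of `geno$annotation`.
#' @return list with `expr` (an [expression_matrix()]) and `truth` (planted
#'   effects, true sex, marker gene ids).
#' @export
gen_expression <- function(geno, config, annotation = NULL) {
  annotation <- annotation %||% geno$annotation
  dos <- geno$genotypes$dosage
  vinfo <- geno$genotypes$variants
  n <- nrow(dos)
  genes <- annotation$gene_id
  eff <- config$effect_table
  if (!is.null(eff)) {
    for (i in seq_len(nrow(eff))) {
      g <- match(eff$gene[i], annotation$gene_id)
      v <- match(eff$variant[i], vinfo$variant_id)
      if (is.na(g) || is.na(v)) stop("effect_table references unknown gene or variant")
      if (vinfo$chrom[v] != annotation$chrom[g] ||
          abs(vinfo$pos[v] - annotation$tss[g]) > config$cis_window)
        stop(sprintf("planted effect %s~%s lies outside the cis window",
                     eff$gene[i], eff$variant[i]))
    }
  }
  set.seed(sub_seed(config$seed, 23L))
  baseline <- stats::rlnorm(length(genes), meanlog = 3, sdlog = 1)
  names(baseline) <- genes
  tpm <- matrix(0, length(genes), n, dimnames = list(genes, rownames(dos)))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    lat <- stats::rnorm(n, 0, config$noise_sd)
    mult <- rep(1, n)
    if (!is.null(eff) && g %in% eff$gene) {
      rows <- which(eff$gene == g)
      for (i in rows) {
        d <- dos[, eff$variant[i]]
        lat <- lat + eff$beta_latent[i] * d
        mult <- mult * (1 + (eff$afc[i] - 1) / 2 * d)
      }
    }
    if (g == "XISTL") {
      base_sex <- ifelse(geno$sex == "female", 50, 0.05)
      tpm[gi, ] <- base_sex * exp(lat)
    } else if (g == "RPS4Y1L") {
      base_sex <- ifelse(geno$sex == "male", 50, 0.05)
      tpm[gi, ] <- base_sex * exp(lat)
    } else {
      tpm[gi, ] <- baseline[g] * mult * exp(lat)
    }
  }
  lib <- stats::rlnorm(n, meanlog = log(30), sdlog = 0.2)
  counts <- round(sweep(tpm, 2, lib, "*"))
  truth <- list(effects = eff, sex = geno$sex, swaps = list(),
                xist_id = "XISTL", rps4y1_id = "RPS4Y1L")
  list(expr = expression_matrix(tpm, counts, annotation), truth = truth)
}

#' Swap expression columns between sample pairs
#'
#' Exchanges the expression profiles (TPM and counts) of each listed sample
#' pair while leaving genotypes untouched -- the condition the sample-QC
#' swap scan is built to detect. Applying the same swap twice restores the
#' original matrix.
#'
#' @param expr an [expression_matrix()].
#' @param pairs list of length-2 character vectors of sample ids; pairs must
#'   be disjoint.
#' @return the expression matrix with columns exchanged.
#' @export
inject_swaps <- function(expr, pairs) {
  if (length(pairs) == 0) return(expr)
  ids <- unlist(pairs)
  if (anyDuplicated(ids)) stop("swap pairs must be disjoint")
  missing_ids <- setdiff(ids, colnames(expr$tpm))
  if (length(missing_ids)) stop("unknown sample id(s): ", paste(missing_ids, collapse = ", "))
  for (p in pairs) {
    i <- match(p[1], colnames(expr$tpm)); j <- match(p[2], colnames(expr$tpm))
    expr$tpm[, c(i, j)] <- expr$tpm[, c(j, i)]
    expr$counts[, c(i, j)] <- expr$counts[, c(j, i)]
  }
  expr
}

#' Generate exon counts with optional planted splicing QTLs
#'
#' Per gene and sample, exon counts are multinomial draws around baseline
#' usage proportions. For a planted sQTL gene the first exon's proportion is
#' shifted by `shift * dosage / 2` (so the dosage-2 and dosage-0 group means
#' differ by `shift`), with the complement redistributed over the remaining
#' exons.
#'
#' @param geno result of [gen_genotypes()].
#' @param config a [sim_config()].
#' @param n_exons exons per gene (>= 2).
#' @param sqtl_effects data.frame with columns `gene`, `variant`, `shift`,
#'   or NULL for a null cohort.
#' @param mean_reads mean per-sample gene read total (Poisson).
#' @return list with `exon_counts` (named list of samples x exons count
#'   matrices) and `truth`.
#' @export
gen_exon_usage <- function(geno, config, n_exons = 4, sqtl_effects = NULL,
                           mean_reads = 500) {
  stopifnot(n_exons >= 2)
  annotation <- geno$annotation
  genes <- annotation$gene_id[!annotation$chrom %in% c("X", "Y")]
  dos <- geno$genotypes$dosage
  n <- nrow(dos)
  set.seed(sub_seed(config$seed, 37L))
  out <- vector("list", length(genes)); names(out) <- genes
  for (g in genes) {
    planted <- !is.null(sqtl_effects) && g %in% sqtl_effects$gene
    a <- stats::rgamma(n_exons, shape = 2)
    base <- a / sum(a)
    if (planted) {
      # planted genes start from a mid-range first-exon usage so the full
      # dosage-2 shift stays inside [0,1]
      row <- sqtl_effects[sqtl_effects$gene == g, ][1, ]
      lo <- 0.05; hi <- 1 - 0.05 - max(row$shift, 0)
      if (hi <= lo || row$shift < -0.9)
        stop("planted shift produces proportions outside [0,1] for gene ", g)
      b1 <- stats::runif(1, lo, hi)
      base <- c(b1, (1 - b1) * base[-1] / sum(base[-1]))
    }
    pmat <- matrix(base, n, n_exons, byrow = TRUE)
    if (planted) {
      d <- dos[, row$variant]
      shift <- row$shift * d / 2
      p1 <- base[1] + shift
      if (any(p1 < 0) || any(p1 > 1))
        stop("planted shift produces proportions outside [0,1] for gene ", g)
      rest <- (1 - p1) / (1 - base[1])
      pmat <- cbind(p1, outer(rest, base[-1]))
    }
    tot <- stats::rpois(n, mean_reads)
    cnt <- t(vapply(seq_len(n), function(i) {
      if (tot[i] == 0) return(integer(n_exons))
      as.integer(stats::rmultinom(1, tot[i], pmat[i, ]))
    }, integer(n_exons)))
    dimnames(cnt) <- list(rownames(dos), paste0(g, "_exon", seq_len(n_exons)))
    out[[g]] <- cnt
  }
  list(exon_counts = out,
       truth = list(sqtl_effects = sqtl_effects, n_exons = n_exons))
}

#' Generate a multi-dataset TWAS z panel with planted causal genes
#'
#' Null genes' z rows are multivariate normal with unit variances and
#' equicorrelation `panel_rho` across the `n_datasets` columns, emulating
#' reference panels that share samples. Causal genes get `causal_shift`
#' added in every dataset. Entries are then masked missing completely at
#' random at `missing_rate`.
#'
#' @param config a [sim_config()]; `n_genes` sets the panel height.
#' @return list with `z` (genes x datasets matrix, NA = missing) and
#'   `truth` (causal gene ids).
#' @export
gen_reference_panels <- function(config) {
  k <- config$n_datasets
  if (k < 2) stop("n_datasets must be >= 2")
  rho <- config$panel_rho
  if (rho <= -1 / (k - 1) || rho >= 1)
    stop(sprintf("panel_rho must lie in (-1/(K-1), 1) = (%.4f, 1) for positive definiteness",
                 -1 / (k - 1)))
  g <- config$n_genes
  set.seed(sub_seed(config$seed, 41L))
  r <- matrix(rho, k, k); diag(r) <- 1
  z <- matrix(stats::rnorm(g * k), g, k) %*% chol(r)
  ids <- sprintf("gene_%04d", seq_len(g))
  dimnames(z) <- list(ids, sprintf("dataset_%d", seq_len(k)))
  causal <- intersect(config$causal_genes, ids)
  if (length(causal)) z[causal, ] <- z[causal, ] + config$causal_shift
  if (config$missing_rate > 0) {
    mask <- stats::runif(g * k) < config$missing_rate
    z[mask] <- NA_real_
  }
  list(z = z, truth = list(causal_genes = causal))
}

#' Generate a tissue x gene eQTL posterior-probability matrix
#'
#' Emulates per-tissue posterior probabilities that each gene has a
#' cis-eQTL, as produced by a multi-tissue empirical-Bayes model. A shared
#' latent gene quality drives all tissues; the liver columns additionally
#' share a liver-only latent factor, making them more correlated with each
#' other than with any non-liver column. Planted liver-specific genes get
#' posteriors near 1 in liver and near 0 elsewhere.
#'
#' @param config a [sim_config()].
#' @param tissues character vector of tissue names (>= 3).
#' @param liver_tissues subset of `tissues` treated as liver datasets.
#' @param liver_specific character vector of gene ids planted liver-specific.
#' @return list with `posteriors` (genes x tissues matrix in [0,1]) and
#'   `truth`.
#' @export
gen_posterior_matrix <- function(config, tissues, liver_tissues,
                                 liver_specific = character()) {
  if (length(liver_tissues) == 0) stop("liver_tissues must be non-empty")
  if (!all(liver_tissues %in% tissues)) stop("liver_tissues must be a subset of tissues")
  if (length(tissues) < 3) stop("need at least 3 tissues")
  g <- config$n_genes
  ids <- sprintf("gene_%04d", seq_len(g))
  set.seed(sub_seed(config$seed, 53L))
  quality <- stats::rnorm(g)              # shared gene-level signal
  liver_factor <- stats::rnorm(g)         # shared only by liver columns
  post <- sapply(tissues, function(tis) {
    lv <- tis %in% liver_tissues
    eta <- 1.5 * quality + if (lv) 1.0 * liver_factor else 0
    stats::plogis(eta + stats::rnorm(g, 0, if (lv) 0.5 else 1.0))
  })
  rownames(post) <- ids
  liver_specific <- intersect(liver_specific, ids)
  if (length(liver_specific)) {
    post[liver_specific, liver_tissues] <-
      stats::runif(length(liver_specific) * length(liver_tissues), 0.95, 1)
    non_liver <- setdiff(tissues, liver_tissues)
    post[liver_specific, non_liver] <-
      stats::runif(length(liver_specific) * length(non_liver), 0, 0.05)
  }
  list(posteriors = post,
       truth = list(liver_specific = liver_specific,
                    liver_tissues = liver_tissues))
}

#' Generate a gene-set catalog with one planted enriched set
#'
#' Builds a catalog in GMT structure: one set in which genes carrying a
#' planted eQTL enter with elevated odds (log odds ratio `target_lnor`
#' against a baseline membership probability), plus random control sets
#' with no enrichment.
#'
#' @param annotation gene annotation data.frame.
#' @param config a [sim_config()].
#' @param eqtl_genes character vector of gene ids that carry planted eQTLs.
#' @param target_lnor natural-log odds ratio planted into the enriched set.
#' @param base_prob baseline membership probability for non-eQTL genes.
#' @param n_control number of random control sets.
#' @return list with `sets` (named list of gene-id vectors; first element is
#'   the enriched set) and `truth`.
#' @export
gen_gene_sets <- function(annotation, config, eqtl_genes,
                          target_lnor = 1.5, base_prob = 0.3, n_control = 3) {
  genes <- annotation$gene_id[!annotation$chrom %in% c("X", "Y")]
  p1 <- stats::plogis(stats::qlogis(base_prob) + target_lnor)
  has_eqtl <- genes %in% eqtl_genes
  if (sum(has_eqtl) * p1 < 1 || sum(!has_eqtl) * base_prob < 1)
    stop("requested lnOR unreachable: expected cell counts below 1")
  set.seed(sub_seed(config$seed, 67L))
  memb <- ifelse(has_eqtl, stats::runif(length(genes)) < p1,
                 stats::runif(length(genes)) < base_prob)
  sets <- list(enriched_set = genes[memb])
  if (n_control > 0) {
    for (i in seq_len(n_control)) {
      sets[[sprintf("control_set_%d", i)]] <-
        genes[stats::runif(length(genes)) < base_prob]
    }
  }
  list(sets = sets,
       truth = list(target_lnor = target_lnor, enriched_set = sets[[1]]))
}
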