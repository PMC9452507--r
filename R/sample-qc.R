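# Sample-level quality control: call-rate exclusion, sex concordance from
# genotypes and expression, duplicate screen, and swap detection via
# expression prediction from genotypes.

#' Exclude samples with low genotype call rate
#'
#' @param genotypes a [genotype_matrix()] (NA entries = missing calls).
#' @param threshold call-rate threshold in (0,1]; samples strictly below it
#'   are flagged `low_call_rate` and removed.
#' @return list with `genotypes` (filtered), `call_rate` (per-sample) and
#'   `excluded` (sample ids removed).
#' @export
sample_call_rate_filter <- function(genotypes, threshold = 0.98) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0,1]")
  dos <- genotypes$dosage
  cr <- rowMeans(!is.na(dos))
  excluded <- rownames(dos)[cr < threshold]
  list(genotypes = genotype_matrix(dos[cr >= threshold, , drop = FALSE],
                                   genotypes$variants),
       call_rate = cr, excluded = excluded)
}

#' Sex call from X-chromosome heterozygosity
#'
#' Heterozygosity rate = fraction of dosage-1 calls among non-missing
#' X-chromosome calls (hemizygous males coded 0/2 never reach 1). A rate
#' below `het_threshold` calls male, otherwise female. Fewer than 50 X
#' variants gives `unknown` for every sample.
#'
#' @param genotypes a [genotype_matrix()]; X variants identified by
#'   `chrom == "X"`.
#' @param het_threshold heterozygosity cutoff (default 0.1; the source
#'   procedure states no value).
#' @return named character vector of calls in {male, female, unknown}.
#' @export
genotype_sex <- function(genotypes, het_threshold = 0.1) {
  x_idx <- genotypes$variants$chrom == "X"
  ids <- rownames(genotypes$dosage)
  if (!any(x_idx)) {
    warning("no X-chromosome variants present: sex call unknown for all samples")
    return(stats::setNames(rep("unknown", length(ids)), ids))
  }
  if (sum(x_idx) < 50)
    return(stats::setNames(rep("unknown", length(ids)), ids))
  xd <- genotypes$dosage[, x_idx, drop = FALSE]
  het <- apply(xd, 1, function(v) {
    ok <- !is.na(v)
    if (!any(ok)) return(NA_real_)
    mean(round(v[ok]) == 1)
  })
  call <- ifelse(is.na(het), "unknown", ifelse(het < het_threshold, "male", "female"))
  stats::setNames(call, ids)
}

#' Sex call from XIST-like and RPS4Y1-like expression
#'
#' 2-means clustering on the log-TPM of the two sex-marker genes; the
#' cluster with the higher XIST-like centroid is labelled female. Degenerate
#' configurations (a single sample, or no expression spread) give `unknown`.
#'
#' @param expr an [expression_matrix()] or a genes x samples TPM matrix.
#' @param xist_id,rps4y1_id row ids of the marker genes.
#' @return named character vector of calls in {male, female, unknown}.
#' @export
expression_sex <- function(expr, xist_id = "XISTL", rps4y1_id = "RPS4Y1L") {
  tpm <- if (inherits(expr, "expression_matrix")) expr$tpm else as.matrix(expr)
  if (!all(c(xist_id, rps4y1_id) %in% rownames(tpm)))
    stop("marker gene absent from the expression matrix")
  m <- t(log10(tpm[c(xist_id, rps4y1_id), , drop = FALSE] + 1))
  ids <- rownames(m)
  unknown <- stats::setNames(rep("unknown", nrow(m)), ids)
  if (nrow(m) < 2 || nrow(unique(m)) < 2) return(unknown)
  km <- tryCatch(stats::kmeans(m, centers = 2, nstart = 5),
                 error = function(e) NULL)
  if (is.null(km) || length(unique(km$cluster)) < 2) return(unknown)
  female_cluster <- which.max(km$centers[, 1])
  stats::setNames(ifelse(km$cluster == female_cluster, "female", "male"), ids)
}

#' Sex-concordance exclusion rule
#'
#' A sample is excluded iff its reported sex differs from BOTH the
#' genotype-based and the expression-based call; an `unknown` call never
#' triggers exclusion.
#'
#' @param reported,genotype_call,expression_call named character vectors
#'   over the same samples, values in {male, female, unknown}.
#' @return character vector of excluded sample ids.
#' @export
sex_concordance <- function(reported, genotype_call, expression_call) {
  ids <- names(reported)
  stopifnot(!is.null(ids), all(ids %in% names(genotype_call)),
            all(ids %in% names(expression_call)))
  g <- genotype_call[ids]; e <- expression_call[ids]
  bad <- reported != "unknown" &
    g != "unknown" & e != "unknown" &
    reported != g & reported != e
  ids[bad]
}

#' Pairwise genotype-concordance screen for duplicated samples
#'
#' Concordance = fraction of shared non-missing variants with identical
#' hard calls. Pairs above `dup_threshold` are flagged as duplicates; pairs
#' sharing fewer than 100 non-missing variants are reported as
#' not-assessable (NA).
#'
#' @param genotypes a [genotype_matrix()] with >= 2 samples and >= 100
#'   variants.
#' @param dup_threshold concordance above which a pair is flagged.
#' @return list with `concordance` (samples x samples matrix, NA diagonal)
#'   and `duplicates` (data.frame of flagged pairs).
#' @export
relatedness_screen <- function(genotypes, dup_threshold = 0.95) {
  dos <- genotypes$dosage
  if (nrow(dos) < 2) stop("need at least 2 samples")
  if (ncol(dos) < 100) stop("need at least 100 variants")
  hard <- round(dos)
  obs <- !is.na(hard)
  shared <- tcrossprod(obs * 1)
  matches <- matrix(0, nrow(dos), nrow(dos))
  for (g in 0:2) {
    ind <- (hard == g) & obs
    matches <- matches + tcrossprod(ind * 1)
  }
  conc <- matches / shared
  conc[shared < 100] <- NA      # not assessable
  diag(conc) <- NA              # self-pairs excluded from the report
  dimnames(conc) <- list(rownames(dos), rownames(dos))
  idx <- which(upper.tri(conc) & !is.na(conc) & conc > dup_threshold,
               arr.ind = TRUE)
  dup <- data.frame(sample1 = rownames(dos)[idx[, 1]],
                    sample2 = rownames(dos)[idx[, 2]],
                    concordance = conc[idx], stringsAsFactors = FALSE)
  list(concordance = conc, duplicates = dup)
}

#' Swap detection via expression prediction from genotypes
#'
#' Finds mislabeled/swapped samples: (1) rank genes by the |Pearson r|
#' between their best cis variant's dosage and their (inverse-normal
#' transformed) expression; (2) keep the top `k` genes with |r| at or above
#' `r_floor`; (3) fit one simple linear model expression ~ dosage per gene;
#' (4) predict each sample's k-gene expression vector from its genotypes;
#' (5) correlate predicted against every sample's observed expression. A
#' correctly handled sample's maximal correlation is with itself; when the
#' argmax is another sample, both are flagged for exclusion.
#'
#' @param genotypes a [genotype_matrix()].
#' @param expr an [expression_matrix()] or genes x samples TPM matrix.
#' @param annotation gene annotation with `gene_id`, `chrom`, `tss`.
#' @param covariates optional covariate matrix residualized out of the
#'   expression before matching.
#' @param k number of predictive genes to use (default 100).
#' @param r_floor minimum |r| for a gene to be eligible (default 0.3;
#'   prevents noise-driven matching on null cohorts).
#' @param window_bp cis window half-width.
#' @param leave_one_out if TRUE, each sample's predictive models are fitted
#'   with that sample held out (default FALSE: models are fitted on all
#'   samples, as in the described procedure).
#' @return list with `match` (predicted x observed correlation matrix),
#'   `best_match` (argmax sample per sample) and `flagged` (sample ids).
#' @export
swap_scan <- function(genotypes, expr, annotation, covariates = NULL,
                      k = 100, r_floor = 0.3, window_bp = 1e6,
                      leave_one_out = FALSE) {
  tpm <- if (inherits(expr, "expression_matrix")) expr$tpm else as.matrix(expr)
  dos <- genotypes$dosage
  ids <- rownames(dos)
  stopifnot(identical(colnames(tpm), ids))
  genes <- intersect(rownames(tpm), annotation$gene_id)
  pairs <- cis_pairs(annotation[annotation$gene_id %in% genes, ],
                     genotypes$variants, window_bp = window_bp)
  if (nrow(pairs) == 0) stop("no predictive genes: no cis pairs available")
  eint <- t(apply(tpm[unique(pairs$gene_id), , drop = FALSE], 1,
                  inverse_normal_transform))
  colnames(eint) <- ids
  if (!is.null(covariates)) eint <- t(residualize(t(eint), covariates))
  # best cis |r| per gene
  rr <- abs(vapply(seq_len(nrow(pairs)), function(i) {
    stats::cor(eint[pairs$gene_id[i], ], dos[, pairs$variant_id[i]])
  }, numeric(1)))
  best <- tapply(seq_len(nrow(pairs)), pairs$gene_id, function(ix) ix[which.max(rr[ix])])
  best <- unlist(best)
  eligible <- best[rr[best] >= r_floor & !is.na(rr[best])]
  if (length(eligible) < 2)   # correlation matching needs >= 2 genes
    stop("no predictive genes: |r| floor unmet for every gene")
  if (length(eligible) < k) {
    warning(sprintf("only %d eligible genes (< k = %d); using all", length(eligible), k))
    k <- length(eligible)
  }
  top <- eligible[order(rr[eligible], decreasing = TRUE)[seq_len(k)]]
  gsel <- pairs$gene_id[top]; vsel <- pairs$variant_id[top]
  obs <- eint[gsel, , drop = FALSE]
  dmat <- dos[, vsel, drop = FALSE]                  # samples x k
  n <- length(ids)
  if (!leave_one_out) {
    fits <- vapply(seq_len(k), function(j) {
      stats::coef(stats::lm.fit(cbind(1, dmat[, j]), obs[j, ]))
    }, numeric(2))
    pred <- sweep(t(dmat), 1, fits[2, ], "*") + fits[1, ]     # k x n
  } else {
    pred <- matrix(0, k, n)
    for (i in seq_len(n)) {
      for (j in seq_len(k)) {
        cf <- stats::coef(stats::lm.fit(cbind(1, dmat[-i, j]), obs[j, -i]))
        pred[j, i] <- cf[1] + cf[2] * dmat[i, j]
      }
    }
  }
  dimnames(pred) <- list(gsel, ids)
  cmat <- stats::cor(pred, obs)                      # predicted(i) vs observed(j)
  dimnames(cmat) <- list(ids, ids)
  best_match <- ids[apply(cmat, 1, which.max)]
  names(best_match) <- ids
  off <- best_match != ids
  flagged <- sort(unique(c(ids[off], best_match[off])))
  list(match = cmat, best_match = best_match, flagged = flagged)
}

#' Full sample-QC report
#'
#' Runs call-rate filtering, both sex calls, the concordance rule, the
#' duplicate screen and the swap scan, and returns one row per sample with
#' exclusion flags (the exclusion list is the union of all flags).
#'
#' @param genotypes a [genotype_matrix()].
#' @param expr an [expression_matrix()].
#' @param annotation gene annotation.
#' @param reported_sex named character vector of reported sex.
#' @param callrate_threshold,het_threshold,k,r_floor stage parameters.
#' @return data.frame, one row per sample, with per-stage calls and a
#'   semicolon-separated `flags` column.
#' @export
sample_qc_report <- function(genotypes, expr, annotation, reported_sex,
                             callrate_threshold = 0.98, het_threshold = 0.1,
                             k = 100, r_floor = 0.3) {
  ids <- rownames(genotypes$dosage)
  crf <- sample_call_rate_filter(genotypes, callrate_threshold)
  gsex <- genotype_sex(genotypes, het_threshold)
  esex <- expression_sex(expr)
  sex_excl <- sex_concordance(reported_sex[ids], gsex, esex)
  dup <- relatedness_screen(genotypes)
  swap <- swap_scan(genotypes, expr, annotation, k = k, r_floor = r_floor)
  flags <- stats::setNames(vector("list", length(ids)), ids)
  for (s in crf$excluded) flags[[s]] <- c(flags[[s]], "low_call_rate")
  for (s in sex_excl) flags[[s]] <- c(flags[[s]], "sex_mismatch")
  for (s in unique(c(dup$duplicates$sample1, dup$duplicates$sample2)))
    flags[[s]] <- c(flags[[s]], "duplicate")
  for (s in swap$flagged) flags[[s]] <- c(flags[[s]], "swap")
  data.frame(
    sample_id = ids,
    call_rate = crf$call_rate[ids],
    reported_sex = unname(reported_sex[ids]),
    genotype_sex = unname(gsex[ids]),
    expression_sex = unname(esex[ids]),
    swap_match = unname(swap$best_match[ids]),
    flags = vapply(flags, function(f) paste(f, collapse = ";"), character(1)),
    excluded = vapply(flags, length, integer(1)) > 0,
    stringsAsFactors = FALSE, row.names = NULL)
}
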