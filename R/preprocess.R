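# Variant/gene filtering, normalization, transforms, covariate assembly.

#' Minor allele frequency of a dosage vector
#'
#' Allele frequency is mean(dosage)/2 over non-missing entries; MAF folds it
#' to min(f, 1-f).
#'
#' @param dosages numeric vector with entries in [0,2]; NA = missing.
#' @return MAF in [0, 0.5].
#' @export
maf <- function(dosages) {
  ok <- !is.na(dosages)
  if (!any(ok)) stop("all dosages missing")
  f <- mean(dosages[ok]) / 2
  min(f, 1 - f)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test: enumerates every heterozygote count consistent with
#' the observed allele counts and sums the probabilities of configurations
#' no more probable than the observed one (Wigginton-style).
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return two-sided exact p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("all genotype counts are zero")
  n_a <- 2 * n_aa + n_Aa
  n_minor <- min(n_a, 2 * n - n_a)
  # heterozygote counts share the parity of the minor allele count
  h <- seq(n_minor %% 2, n_minor, by = 2)
  logp <- h * log(2) + lfactorial(n) -
    lfactorial((n_minor - h) / 2) - lfactorial(h) -
    lfactorial(n - (n_minor + h) / 2) +
    lfactorial(n_minor) + lfactorial(2 * n - n_minor) - lfactorial(2 * n)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, h)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Variant-level quality filters
#'
#' Drops a variant iff its call rate is below `callrate_min`, its MAF is
#' below `maf_min` (strict inequalities, so a variant at exactly MAF 0.01
#' is kept), or its exact HWE p-value is below `hwe_alpha`. HWE is computed
#' on hard calls (dosages rounded to {0,1,2}).
#'
#' @param genotypes a [genotype_matrix()].
#' @param callrate_min,maf_min,hwe_alpha thresholds.
#' @return list with `genotypes` (filtered) and `report` (per-variant
#'   data.frame of call rate, MAF, HWE p and all applicable drop reasons).
#' @export
filter_variants <- function(genotypes, callrate_min = 0.95, maf_min = 0.01,
                            hwe_alpha = 1e-6) {
  dos <- genotypes$dosage
  call_rate <- colMeans(!is.na(dos))
  mafs <- apply(dos, 2, function(v) if (all(is.na(v))) NA_real_ else maf(v))
  hwe_p <- apply(dos, 2, function(v) {
    h <- round(v[!is.na(v)])
    if (!length(h)) return(NA_real_)
    hwe_exact_test(sum(h == 0), sum(h == 1), sum(h == 2))
  })
  low_cr <- call_rate < callrate_min
  low_maf <- !is.na(mafs) & mafs < maf_min
  hwe_fail <- !is.na(hwe_p) & hwe_p < hwe_alpha
  drop <- low_cr | low_maf | hwe_fail
  reasons <- mapply(function(a, b, c) {
    paste(c(if (a) "low_call_rate", if (b) "low_maf", if (c) "hwe_fail"),
          collapse = ";")
  }, low_cr, low_maf, hwe_fail)
  report <- data.frame(variant_id = genotypes$variants$variant_id,
                       call_rate = call_rate, maf = mafs, hwe_p = hwe_p,
                       dropped = drop, reasons = reasons,
                       stringsAsFactors = FALSE, row.names = NULL)
  keep <- !drop
  list(genotypes = genotype_matrix(dos[, keep, drop = FALSE],
                                   genotypes$variants[keep, , drop = FALSE]),
       report = report)
}

#' Gene expression-level filter
#'
#' A gene is kept iff at least `n_thr` samples have TPM strictly above
#' `tpm_thr` AND read count at least `read_thr`.
#'
#' @param tpm,counts genes x samples matrices sharing dimnames.
#' @param tpm_thr,read_thr,n_thr thresholds.
#' @return character vector of kept gene ids.
#' @export
filter_genes <- function(tpm, counts, tpm_thr = 0.1, read_thr = 6, n_thr = 10) {
  if (!identical(dim(tpm), dim(counts)) ||
      !identical(rownames(tpm), rownames(counts)))
    stop("tpm and counts must share gene/sample indices")
  n_pass <- rowSums(tpm > tpm_thr & counts >= read_thr)
  rownames(tpm)[n_pass >= n_thr]
}

#' Quantile-normalize samples to the average empirical distribution
#'
#' Each sample's values are replaced by the mean of the cross-sample order
#' statistics at the matching rank (average ranks for ties, linear
#' interpolation at fractional ranks), so every sample shares one reference
#' distribution while within-sample ranks are preserved.
#'
#' @param tpm genes x samples matrix.
#' @return normalized matrix, same dimensions.
#' @export
quantile_normalize_to_average <- function(tpm) {
  tpm <- as.matrix(tpm)
  if (ncol(tpm) < 2) stop("need at least 2 samples")
  target <- rowMeans(apply(tpm, 2, sort))
  out <- apply(tpm, 2, function(x) {
    r <- rank(x, ties.method = "average")
    stats::approx(seq_along(target), target, xout = r)$y
  })
  dimnames(out) <- dimnames(tpm)
  out
}

#' Rank-based inverse normal transform
#'
#' Maps the value at rank r (average ranks for ties) to
#' `qnorm((r - 0.5) / n)`.
#'
#' @param values numeric vector, length >= 3, not constant.
#' @return transformed vector.
#' @export
inverse_normal_transform <- function(values) {
  if (length(values) < 3) stop("need at least 3 values")
  if (length(unique(values)) == 1) stop("constant vector: all values tied")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 0.5) / length(values))
}

# sign convention shared by the PC extractors: flip each component so its
# largest-|loading| entry is positive
fix_signs <- function(scores, loadings) {
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      scores[, j] <- -scores[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  scores
}

#' Genotype principal components
#'
#' PCs of the column-standardized dosage matrix via SVD (monomorphic
#' variants dropped). Deterministic up to sign; sign is fixed by making
#' each component's largest-|loading| variant positive.
#'
#' @param genotypes a [genotype_matrix()] or a samples x variants matrix.
#' @param k number of components (default 3).
#' @return samples x k matrix of PC scores (columns `genoPC1..k`); an empty
#'   0-column matrix when `k = 0`.
#' @export
genotype_pcs <- function(genotypes, k = 3) {
  dos <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage else as.matrix(genotypes)
  if (k == 0) return(matrix(0, nrow(dos), 0, dimnames = list(rownames(dos), NULL)))
  z <- standardize_cols(dos)
  if (k >= min(dim(z))) stop("k must be < min(n_samples, n_variants)")
  sv <- svd(z, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  scores <- fix_signs(scores, sv$v)
  dimnames(scores) <- list(rownames(dos), paste0("genoPC", seq_len(k)))
  scores
}

#' Latent expression factors (PCA substitute for PEER)
#'
#' Top principal components of the normalized expression matrix, treated as
#' opaque hidden covariates of expression.
#'
#' @param expr_normalized genes x samples matrix (already normalized).
#' @param n_factors number of factors; must be < number of samples.
#' @return samples x n_factors matrix (columns `exprPC1..F`).
#' @export
expression_factors <- function(expr_normalized, n_factors) {
  m <- t(as.matrix(expr_normalized))       # samples x genes
  if (n_factors == 0) return(matrix(0, nrow(m), 0, dimnames = list(rownames(m), NULL)))
  if (n_factors >= nrow(m)) stop("n_factors must be < number of samples")
  z <- scale(m, center = TRUE, scale = FALSE)
  keep <- apply(z, 2, function(x) any(x != 0))
  z <- z[, keep, drop = FALSE]
  sv <- svd(z, nu = n_factors, nv = n_factors)
  scores <- sv$u %*% diag(sv$d[seq_len(n_factors)], n_factors)
  scores <- fix_signs(scores, sv$v)
  dimnames(scores) <- list(rownames(m), paste0("exprPC", seq_len(n_factors)))
  scores
}

#' Assemble the covariate matrix for the association scans
#'
#' Binds sex, optional age/batch, genotype PCs and expression factors into
#' one samples x covariates matrix; columns are standardized and the result
#' is checked for full column rank.
#'
#' @param sex character vector ("male"/"female") or numeric; coded 0/1.
#' @param genotype_pcs,expression_factors matrices as returned by
#'   [genotype_pcs()] and [expression_factors()]; NULL to omit.
#' @param age,batch optional per-sample vectors (batch is factor-coded).
#' @return samples x covariates numeric matrix with no missing entries.
#' @export
build_covariates <- function(sex = NULL, genotype_pcs = NULL,
                             expression_factors = NULL, age = NULL,
                             batch = NULL) {
  blocks <- list()
  if (!is.null(sex)) {
    s <- if (is.character(sex) || is.factor(sex)) as.numeric(as.character(sex) == "female") else as.numeric(sex)
    blocks$sex <- matrix(s, dimnames = list(names(sex), "sex"))
  }
  if (!is.null(age)) blocks$age <- matrix(as.numeric(age), dimnames = list(names(age), "age"))
  if (!is.null(batch)) {
    mm <- stats::model.matrix(~ factor(batch))[, -1, drop = FALSE]
    colnames(mm) <- paste0("batch", seq_len(ncol(mm)))
    blocks$batch <- mm
  }
  if (!is.null(genotype_pcs)) blocks$gpc <- genotype_pcs
  if (!is.null(expression_factors)) blocks$epc <- expression_factors
  if (!length(blocks)) return(NULL)
  cov <- do.call(cbind, unname(blocks))
  cn <- unlist(lapply(blocks, colnames))
  colnames(cov) <- cn
  if (anyNA(cov)) stop("covariates contain missing entries")
  cov <- standardize_cols(cov, drop_constant = TRUE)
  if (qr(cov)$rank < ncol(cov)) stop("covariate matrix is rank-deficient")
  cov
}
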