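# cis and trans eQTL mapping: covariate-adjusted linear scan, eGene
# adaptive-permutation p-values with beta extrapolation, allelic
# fold-change fits, BH FDR, and trans quality flags.

#' Enumerate cis gene-variant pairs
#'
#' A pair is included iff the variant lies on the gene's chromosome with
#' position inside the closed interval [TSS - window, TSS + window].
#'
#' @param annotation data.frame with `gene_id`, `chrom`, `tss`.
#' @param variants data.frame with `variant_id`, `chrom`, `pos`.
#' @param window_bp window half-width (default 1 Mb).
#' @return data.frame with columns `gene_id`, `variant_id`.
#' @export
cis_pairs <- function(annotation, variants, window_bp = 1e6) {
  if (anyNA(annotation$tss)) stop("gene(s) missing TSS")
  out <- lapply(seq_len(nrow(annotation)), function(i) {
    hit <- variants$chrom == annotation$chrom[i] &
      abs(variants$pos - annotation$tss[i]) <= window_bp
    if (!any(hit)) return(NULL)
    data.frame(gene_id = annotation$gene_id[i],
               variant_id = variants$variant_id[hit],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(gene_id = character(), variant_id = character()) else out
}

#' Covariate-adjusted linear cis scan
#'
#' For every pair, the t-statistic and p-value of the dosage coefficient in
#' an ordinary least-squares fit of expression on dosage plus covariates
#' (with intercept). Implemented by residualizing both expression and
#' dosage on the covariates once and using the correlation-to-t identity
#' `t = r * sqrt(df / (1 - r^2))` with `df = n - n_covariates - 2`, which
#' is numerically identical to the per-pair OLS refit.
#'
#' @param expr_int genes x samples matrix of inverse-normal transformed
#'   expression.
#' @param genotypes a [genotype_matrix()] (samples x variants dosages).
#' @param covariates samples x covariates matrix or NULL.
#' @param pairs data.frame from [cis_pairs()].
#' @return data.frame with `gene_id`, `variant_id`, `beta` (effect on the
#'   INT scale per dosage unit), `t`, `p`, `q` (BH within this family) and
#'   an `underflow` marker where p hit the representable floor.
#' @export
cis_scan <- function(expr_int, genotypes, covariates = NULL, pairs) {
  dos <- genotypes$dosage
  n <- nrow(dos)
  kcov <- n_covariates(covariates)
  df <- n - kcov - 2
  if (df < 1) stop("not enough samples for the covariate count")
  er <- residualize(t(expr_int), covariates)      # samples x genes
  dr <- residualize(dos, covariates)              # samples x variants
  ge <- er[, pairs$gene_id, drop = FALSE]
  dv <- dr[, pairs$variant_id, drop = FALSE]
  sxy <- colSums(ge * dv)
  sxx <- colSums(dv^2)
  syy <- colSums(ge^2)
  r <- sxy / sqrt(sxx * syy)
  r[!is.finite(r)] <- 0
  r <- pmin(1, pmax(-1, r))
  tt <- r * sqrt(df / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tt), df)
  underflow <- p == 0 | !is.finite(tt)
  data.frame(gene_id = pairs$gene_id, variant_id = pairs$variant_id,
             beta = sxy / sxx, t = tt, p = p_floor(p), q = bh_fdr(p_floor(p)),
             underflow = underflow, stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg FDR q-values
#'
#' Standard step-up BH with monotonicity enforcement. Families (cis, trans,
#' sQTL, TWAS) are kept separate by the caller.
#'
#' @param pvals numeric vector of p-values in [0,1].
#' @return q-values, same length.
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values outside [0,1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Gene-level eGene p-value by adaptive permutation with beta extrapolation
#'
#' Permutes the expression vector across samples (covariates residualized
#' out once; genotypes fixed), records the minimum nominal p across the
#' gene's cis variants per permutation, stops early once `adaptive_stop`
#' permutation minima beat the observed minimum, fits a Beta(a,b) to the
#' permutation minima by maximum likelihood (method-of-moments start, with
#' fallback to moments), and extrapolates the gene-level p as the Beta CDF
#' at the observed minimum. The direct empirical permutation p
#' `(1 + #hits) / (1 + #perms)` is reported alongside.
#'
#' @param expr_vec expression vector (INT scale) for the gene.
#' @param dosage_cis samples x cis-variants dosage matrix.
#' @param covariates covariate matrix or NULL.
#' @param max_perm maximum permutations (>= 10).
#' @param adaptive_stop early-stopping hit count.
#' @param seed integer seed for the permutation stream.
#' @return list with `p_nominal_min`, `best_variant`, `p_beta`,
#'   `p_empirical`, `n_perm`, `beta_shape1`, `beta_shape2`.
#' @export
egene_pvalue <- function(expr_vec, dosage_cis, covariates = NULL,
                         max_perm = 1000, adaptive_stop = 100, seed = 1L) {
  if (max_perm < 10) stop("max_perm must be >= 10")
  dosage_cis <- as.matrix(dosage_cis)
  n <- length(expr_vec)
  kcov <- n_covariates(covariates)
  df <- n - kcov - 2
  er <- drop(residualize(matrix(expr_vec), covariates))
  dr <- residualize(dosage_cis, covariates)
  dss <- colSums(dr^2)
  minp_of <- function(e) {
    r <- crossprod(dr, e) / sqrt(dss * sum(e^2))
    r <- pmin(1, pmax(-1, r))
    tt <- abs(r) * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
    2 * stats::pt(-max(tt), df)
  }
  r_obs <- crossprod(dr, er) / sqrt(dss * sum(er^2))
  best <- which.max(abs(r_obs))
  p_obs <- minp_of(er)
  set.seed(seed)
  minima <- numeric(max_perm)
  hits <- 0L; nperm <- 0L
  for (b in seq_len(max_perm)) {
    pm <- minp_of(sample(er))
    nperm <- b
    minima[b] <- pm
    if (pm <= p_obs) hits <- hits + 1L
    if (hits >= adaptive_stop) break
  }
  minima <- minima[seq_len(nperm)]
  ab <- fit_beta(minima)
  list(p_nominal_min = max(p_obs, 5e-324),
       best_variant = colnames(dosage_cis)[best] %||% best,
       p_beta = stats::pbeta(p_obs, ab[1], ab[2]),
       p_empirical = (1 + hits) / (1 + nperm),
       n_perm = nperm, beta_shape1 = ab[1], beta_shape2 = ab[2])
}

# Beta(a,b) fit: MLE with method-of-moments start; moments fallback.
fit_beta <- function(x) {
  x <- pmin(pmax(x, 1e-12), 1 - 1e-12)
  m <- mean(x); v <- stats::var(x)
  if (is.na(v) || v <= 0) return(c(1, 1))
  common <- m * (1 - m) / v - 1
  start <- pmax(c(m * common, (1 - m) * common), 1e-3)
  nll <- function(lp) {
    a <- exp(lp[1]); b <- exp(lp[2])
    -sum(stats::dbeta(x, a, b, log = TRUE))
  }
  fit <- tryCatch(stats::optim(log(start), nll, method = "Nelder-Mead"),
                  error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0) start else exp(fit$par)
}

#' eGene scan over all genes
#'
#' Applies [egene_pvalue()] to every gene with at least one cis variant and
#' adds BH q-values over the beta-extrapolated gene-level p's.
#'
#' @param expr_int genes x samples INT expression matrix.
#' @param genotypes a [genotype_matrix()].
#' @param annotation gene annotation.
#' @param covariates covariate matrix or NULL.
#' @param window_bp cis window half-width.
#' @param max_perm,adaptive_stop see [egene_pvalue()].
#' @param seed integer seed.
#' @return data.frame, one row per gene.
#' @export
egene_scan <- function(expr_int, genotypes, annotation, covariates = NULL,
                       window_bp = 1e6, max_perm = 1000, adaptive_stop = 100,
                       seed = 1L) {
  pairs <- cis_pairs(annotation[annotation$gene_id %in% rownames(expr_int), ],
                     genotypes$variants, window_bp)
  genes <- unique(pairs$gene_id)
  res <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    vs <- pairs$variant_id[pairs$gene_id == g]
    eg <- egene_pvalue(expr_int[g, ], genotypes$dosage[, vs, drop = FALSE],
                       covariates, max_perm, adaptive_stop,
                       seed = sub_seed(seed, i))
    data.frame(gene_id = g, best_variant = eg$best_variant,
               p_nominal_min = eg$p_nominal_min, p_beta = eg$p_beta,
               p_empirical = eg$p_empirical, n_perm = eg$n_perm,
               beta_shape1 = eg$beta_shape1, beta_shape2 = eg$beta_shape2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p_beta)
  out
}

#' Allelic fold-change fit (log-of-linear model)
#'
#' Fits `log(TPM + 1) = log(1 + c0 + c1 * dosage) + gamma' covariates +
#' eps` by Gauss-Newton nonlinear least squares with a damped step and
#' backtracking (start c1 = 0, c0 = exp(mean log(TPM+1)) - 1; the
#' positivity constraint c0 + c1*d > 0 is enforced over the observed
#' dosage range), so noiseless `TPM = c0 * (1 + (c1/c0) d)` is recovered
#' exactly. The allelic fold change is aFC = (c0 + 2 c1) / c0, reported as
#' log2 and clipped to +/- log2(100). The p-value is a likelihood-ratio
#' test against c1 = 0.
#'
#' @param tpm non-negative TPM vector.
#' @param dosage dosage vector in [0,2]; at least 2 distinct groups.
#' @param covariates covariate matrix or NULL.
#' @param max_iter Gauss-Newton iteration cap.
#' @return list with `c0`, `c1`, `log2_afc`, `p`, `converged`, `n_iter`.
#' @export
afc_fit <- function(tpm, dosage, covariates = NULL, max_iter = 100) {
  if (any(tpm < 0)) stop("TPM must be non-negative")
  if (length(unique(round(dosage))) < 2) stop("need >= 2 dosage groups")
  y <- log(tpm + 1)
  n <- length(y)
  # the model's own log(1 + c0 + c1 d) carries the level, so covariates
  # enter centered and WITHOUT an intercept -- a free intercept would leave
  # (c0, c1) identified only through c1/(1 + c0)
  qx <- if (is.null(covariates)) NULL else qr(scale(as.matrix(covariates), scale = FALSE))
  proj <- function(v) if (is.null(qx)) v - mean(v) * 0 else qr.resid(qx, v)
  proj_m <- function(m) if (is.null(qx)) m else qr.resid(qx, m)
  rss0 <- sum(qr.resid(qr(cbind(rep(1, n), covariates)), y)^2)  # null: c1 = 0
  c0 <- max(exp(mean(y)) - 1, 1e-6); c1 <- 0
  feasible <- function(c0, c1) c0 > 0 && min(c0 + c1 * range(dosage)) > 0
  obj <- function(c0, c1) sum(proj(y - log(1 + c0 + c1 * dosage))^2)
  f <- obj(c0, c1)
  converged <- FALSE; it <- 0
  while (it < max_iter) {
    it <- it + 1
    mu <- 1 + c0 + c1 * dosage
    resid <- proj(y - log(mu))
    J <- proj_m(cbind(1 / mu, dosage / mu))
    jtj <- crossprod(J)
    damp <- 1e-10 * max(diag(jtj), 1e-12)
    step <- tryCatch(solve(jtj + damp * diag(2), crossprod(J, resid)),
                     error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1; improved <- FALSE; fn <- f
    for (half in 1:40) {
      c0n <- c0 + lambda * step[1]; c1n <- c1 + lambda * step[2]
      if (feasible(c0n, c1n)) {
        fn <- obj(c0n, c1n)
        if (fn < f) { improved <- TRUE; break }
      }
      lambda <- lambda / 2
    }
    if (!improved) { converged <- TRUE; break }
    rel <- (f - fn) / max(f, .Machine$double.eps)
    c0 <- c0n; c1 <- c1n; f <- fn
    if (rel < 1e-12) { converged <- TRUE; break }
  }
  rss1 <- f
  lrt <- n * log(max(rss0, .Machine$double.xmin) / max(rss1, .Machine$double.xmin))
  p <- stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
  afc <- (c0 + 2 * c1) / c0
  l2 <- log2(max(afc, .Machine$double.eps))
  l2 <- max(min(l2, log2(100)), -log2(100))
  list(c0 = c0, c1 = c1, log2_afc = l2, p = p,
       converged = converged, n_iter = it)
}

#' Trans eQTL scan
#'
#' Same linear model as [cis_scan()], restricted to gene-variant pairs on
#' different chromosomes, with BH correction within the trans family only.
#'
#' @param expr_int genes x samples INT expression matrix.
#' @param genotypes a [genotype_matrix()].
#' @param covariates covariate matrix or NULL.
#' @param annotation gene annotation (`gene_id`, `chrom`).
#' @return data.frame of trans associations with positions attached.
#' @export
trans_scan <- function(expr_int, genotypes, covariates = NULL, annotation) {
  genes <- intersect(rownames(expr_int), annotation$gene_id)
  ann <- annotation[match(genes, annotation$gene_id), ]
  v <- genotypes$variants
  pairs <- do.call(rbind, lapply(seq_along(genes), function(i) {
    hit <- v$chrom != ann$chrom[i]
    if (!any(hit)) return(NULL)
    data.frame(gene_id = genes[i], variant_id = v$variant_id[hit],
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs)) stop("no cross-chromosome pairs")
  res <- cis_scan(expr_int, genotypes, covariates, pairs)
  res$q <- bh_fdr(res$p)        # trans family corrected on its own
  res$chrom <- v$chrom[match(res$variant_id, v$variant_id)]
  res$pos <- v$pos[match(res$variant_id, v$variant_id)]
  res
}

#' Greedy regional clumping of significant trans associations
#'
#' For each gene, significant variants (q < `q_max`) are sorted by p
#' ascending and grouped greedily: a variant joins an existing region if it
#' lies within `region_bp` of that region's representative on the same
#' chromosome, else it seeds a new region. The regionally most significant
#' variant represents each region.
#'
#' @param assocs data.frame from [trans_scan()] (needs `chrom`, `pos`, `q`).
#' @param q_max FDR threshold for inclusion.
#' @param region_bp region radius in bp.
#' @return data.frame of representatives with `region_id` and per-gene
#'   `n_regions`.
#' @export
trans_clump <- function(assocs, q_max = 0.1, region_bp = 1e6) {
  sig <- assocs[assocs$q < q_max, , drop = FALSE]
  if (nrow(sig) == 0) return(cbind(sig, region_id = character(0), n_regions = integer(0)))
  out <- lapply(split(sig, sig$gene_id), function(d) {
    d <- d[order(d$p), , drop = FALSE]
    reps <- integer(0)
    region_of <- integer(nrow(d))
    for (i in seq_len(nrow(d))) {
      joined <- FALSE
      for (ri in seq_along(reps)) {
        r <- reps[ri]
        if (d$chrom[i] == d$chrom[r] && abs(d$pos[i] - d$pos[r]) <= region_bp) {
          region_of[i] <- ri; joined <- TRUE; break
        }
      }
      if (!joined) { reps <- c(reps, i); region_of[i] <- length(reps) }
    }
    rep_rows <- d[reps, , drop = FALSE]
    rep_rows$region_id <- sprintf("%s_region%d", rep_rows$gene_id, seq_along(reps))
    rep_rows$n_regions <- length(reps)
    rep_rows
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Quality flags for clumped trans associations
#'
#' Applies the four flags: `crossmap` (target gene appears in the
#' cross-mappability pair list), `multi_region` (more than 2 significant
#' regions for the gene), `no_symbol` (missing/empty gene symbol),
#' `pseudogene` (biotype contains "pseudogene"). An association is
#' high-quality iff it has no flags.
#'
#' @param clumped data.frame from [trans_clump()].
#' @param crossmap_pairs data.frame with columns `gene1`, `gene2` listing
#'   cross-mappable gene pairs; NULL for none.
#' @param annotation gene annotation with `symbol` and `biotype`.
#' @return `clumped` with added `flags` (semicolon string) and
#'   `high_quality` columns.
#' @export
trans_flags <- function(clumped, crossmap_pairs = NULL, annotation) {
  cm_genes <- if (is.null(crossmap_pairs)) character(0) else
    unique(c(crossmap_pairs$gene1, crossmap_pairs$gene2))
  ann <- annotation[match(clumped$gene_id, annotation$gene_id), ]
  flags <- vapply(seq_len(nrow(clumped)), function(i) {
    f <- character(0)
    if (clumped$gene_id[i] %in% cm_genes) f <- c(f, "crossmap")
    if (clumped$n_regions[i] > 2) f <- c(f, "multi_region")
    sym <- ann$symbol[i]
    if (is.na(sym) || !nzchar(sym)) f <- c(f, "no_symbol")
    bt <- ann$biotype[i]
    if (!is.na(bt) && grepl("pseudogene", bt, fixed = TRUE)) f <- c(f, "pseudogene")
    paste(f, collapse = ";")
  }, character(1))
  clumped$flags <- flags
  clumped$high_quality <- !nzchar(flags)
  clumped
}
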