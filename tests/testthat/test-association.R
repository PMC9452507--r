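# Association: cis pairing, linear scan vs OLS oracle, eGene permutation
# machinery, aFC fit, BH, trans scan/clump/flags.

test_that("cis_pairs uses a closed window on the same chromosome", {
  ann <- data.frame(gene_id = "g1", chrom = "1", tss = 5e6)
  v <- data.frame(variant_id = c("at_edge", "past_edge", "other_chr"),
                  chrom = c("1", "1", "2"),
                  pos = c(5e6 + 1e6, 5e6 + 1e6 + 1, 5e6))
  pr <- cis_pairs(ann, v)
  expect_identical(pr$variant_id, "at_edge")

  # recount oracle on a toy layout
  set.seed(4)
  ann2 <- data.frame(gene_id = paste0("g", 1:3), chrom = c("1", "1", "2"),
                     tss = c(2e6, 9e6, 4e6))
  v2 <- data.frame(variant_id = paste0("v", 1:10),
                   chrom = sample(c("1", "2"), 10, TRUE),
                   pos = round(runif(10, 0, 12e6)))
  pr2 <- cis_pairs(ann2, v2)
  manual <- expand.grid(g = 1:3, v = 1:10)
  manual <- manual[mapply(function(g, v)
    ann2$chrom[g] == v2$chrom[v] && abs(v2$pos[v] - ann2$tss[g]) <= 1e6,
    manual$g, manual$v), ]
  expect_identical(nrow(pr2), nrow(manual))
  expect_error(cis_pairs(data.frame(gene_id = "g", chrom = "1", tss = NA), v2),
               "TSS")
})

test_that("cis_scan equals the per-pair OLS oracle and handles degeneracies", {
  co <- make_cohort(seed = 3, n = 100, n_variants = 100, n_genes = 30,
                    n_effects = 10, beta = 0.8)
  eint <- int_rows(co$expr$tpm)
  cov <- cbind(genotype_pcs(co$geno$genotypes, 2),
               expression_factors(eint, 2))
  pr <- co$pairs[sample(nrow(co$pairs), 50), ]
  res <- cis_scan(eint, co$geno$genotypes, cov, pr)
  for (i in seq_len(nrow(pr))) {
    y <- eint[pr$gene_id[i], ]
    d <- co$geno$genotypes$dosage[, pr$variant_id[i]]
    sm <- summary(lm(y ~ d + cov))$coefficients
    expect_lt(abs(sm["d", "t value"] - res$t[i]), 1e-8)
    expect_lt(abs(sm["d", "Pr(>|t|)"] - res$p[i]), 1e-8)
    expect_lt(abs(sm["d", "Estimate"] - res$beta[i]), 1e-8)
  }
  # orthogonal expression -> t = 0, p = 1
  d <- co$geno$genotypes$dosage[, 1]
  y0 <- matrix(residuals(lm(rnorm(100) ~ d)), 1,
               dimnames = list("g", rownames(co$geno$genotypes$dosage)))
  g1 <- genotype_matrix(matrix(d, 100, dimnames = list(NULL, "v")),
                        data.frame(variant_id = "v", chrom = "1", pos = 1))
  r0 <- cis_scan(y0, g1, NULL, data.frame(gene_id = "g", variant_id = "v"))
  expect_lt(abs(r0$t), 1e-10)
  expect_equal(r0$p, 1)
  # expression identical to dosage -> underflow marked, p floored not zero
  y1 <- matrix(d, 1, dimnames = list("g", rownames(co$geno$genotypes$dosage)))
  r1 <- cis_scan(y1, g1, NULL, data.frame(gene_id = "g", variant_id = "v"))
  expect_true(r1$underflow)
  expect_gt(r1$p, 0)
})

test_that("bh_fdr reproduces the step-up rule", {
  expect_equal(bh_fdr(c(0.005, 0.02, 0.04)), c(0.015, 0.03, 0.04))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(11)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bh_fdr(c(0.1, 1.2)), "outside")
})

test_that("egene_pvalue: empirical formula, median placement, determinism", {
  co <- make_cohort(seed = 13, n = 100, n_variants = 50, n_genes = 20,
                    n_effects = 5, beta = 1.5)
  eint <- int_rows(co$expr$tpm)
  g <- co$effects$gene[1]
  vs <- co$pairs$variant_id[co$pairs$gene_id == g]
  dc <- co$geno$genotypes$dosage[, vs, drop = FALSE]
  e1 <- egene_pvalue(eint[g, ], dc, max_perm = 500, seed = 7)
  # strong planted effect beats every permutation
  expect_equal(e1$p_empirical, 1 / (e1$n_perm + 1))
  expect_lt(e1$p_beta, 0.01)
  expect_identical(e1, egene_pvalue(eint[g, ], dc, max_perm = 500, seed = 7))
  expect_error(egene_pvalue(eint[g, ], dc, max_perm = 5), "max_perm")

  # observed at the permutation median -> beta p near 0.5
  set.seed(21)
  y <- rnorm(100)
  d1 <- dc[, 1, drop = FALSE]
  mids <- replicate(20, {
    yy <- sample(y)
    e <- egene_pvalue(yy, d1, max_perm = 400, adaptive_stop = 400, seed = 3)
    e$p_beta - e$p_empirical
  })
  expect_lt(abs(mean(mids)), 0.1)   # extrapolation tracks the empirical p
})

test_that("afc_fit recovers the noiseless model exactly and flags issues", {
  set.seed(22)
  d <- sample(0:2, 192, TRUE, c(0.49, 0.42, 0.09))
  f <- afc_fit(10 * (1 + 0.5 * d), d)
  expect_equal(f$c0, 10, tolerance = 1e-8)
  expect_equal(f$c1, 5, tolerance = 1e-8)
  expect_equal(f$log2_afc, 1, tolerance = 1e-10)
  expect_true(f$converged)
  # covariates leave the noiseless solution untouched
  fc <- afc_fit(10 * (1 + 0.5 * d), d, covariates = matrix(rnorm(192)))
  expect_equal(fc$log2_afc, 1, tolerance = 1e-8)
  # clipping at 100-fold
  fx <- afc_fit(c(0.01, 1e4)[1 + (d > 0)], d)
  expect_lte(abs(fx$log2_afc), log2(100))
  expect_error(afc_fit(rep(5, 10), rep(1, 10)), "dosage groups")
  expect_error(afc_fit(c(-1, 2, 3), c(0, 1, 2)), "non-negative")
})

test_that("trans_scan tests only cross-chromosome pairs and finds planted effects", {
  cfg0 <- sim_config(n_samples = 150, n_variants = 60, n_genes = 20,
                     maf_range = c(0.2, 0.5), seed = 17)
  g <- gen_genotypes(cfg0)
  ge <- gen_expression(g, cfg0)
  eint <- int_rows(ge$expr$tpm)
  # plant a trans effect by hand: chr-1 variant -> chr-2 gene
  v1 <- which(g$genotypes$variants$chrom == "1")[1]
  gene2 <- g$annotation$gene_id[g$annotation$chrom == "2"][1]
  eint[gene2, ] <- eint[gene2, ] + 0.8 * g$genotypes$dosage[, v1]
  eint[gene2, ] <- inverse_normal_transform(eint[gene2, ])
  res <- trans_scan(eint[g$annotation$gene_id[1:20], ], g$genotypes, NULL,
                    g$annotation)
  same_chr <- g$annotation$chrom[match(res$gene_id, g$annotation$gene_id)] ==
    g$genotypes$variants$chrom[match(res$variant_id, g$genotypes$variants$variant_id)]
  expect_false(any(same_chr))
  top <- res[which.min(res$q), ]
  expect_identical(top$gene_id, gene2)
  expect_identical(top$variant_id, g$genotypes$variants$variant_id[v1])
})

test_that("trans_clump groups greedily by p within the region radius", {
  base <- data.frame(gene_id = "g1", chrom = "5",
                     variant_id = paste0("v", 1:2), q = 0.01,
                     stringsAsFactors = FALSE)
  close_pair <- transform(base, pos = c(1e6, 1e6 + 1e4), p = c(1e-8, 1e-6))
  r1 <- trans_clump(close_pair)
  expect_identical(nrow(r1), 1L)
  expect_identical(r1$variant_id, "v1")
  far_pair <- transform(base, pos = c(1e6, 6e6), p = c(1e-8, 1e-6))
  expect_identical(nrow(trans_clump(far_pair)), 2L)

  # random layout: greedy rule re-applied independently gives the same regions
  set.seed(23)
  lay <- data.frame(gene_id = "g", chrom = "1", variant_id = paste0("v", 1:30),
                    pos = sort(round(runif(30, 0, 2e7))),
                    p = runif(30, 1e-10, 1e-4), q = 0.01)
  got <- trans_clump(lay)
  d <- lay[order(lay$p), ]
  reps <- list()
  for (i in seq_len(nrow(d))) {
    hit <- FALSE
    for (r in reps) if (abs(d$pos[i] - r$pos) <= 1e6) { hit <- TRUE; break }
    if (!hit) reps[[length(reps) + 1]] <- d[i, ]
  }
  expect_identical(nrow(got), length(reps))
})

test_that("trans_flags applies the four criteria and high_quality means no flags", {
  ann <- data.frame(gene_id = c("gA", "gB", "gC"),
                    symbol = c("", "SYMB", "SYMC"), chrom = "1", tss = 1,
                    biotype = c("protein_coding", "processed_pseudogene",
                                "protein_coding"))
  clumped <- data.frame(gene_id = c("gA", "gB", "gC"),
                        variant_id = paste0("v", 1:3),
                        n_regions = c(1, 3, 1), stringsAsFactors = FALSE)
  out <- trans_flags(clumped, crossmap_pairs = NULL, annotation = ann)
  expect_identical(out$flags, c("no_symbol", "multi_region;pseudogene", ""))
  expect_identical(out$high_quality, c(FALSE, FALSE, TRUE))
  out2 <- trans_flags(clumped, data.frame(gene1 = "gC", gene2 = "gX"), ann)
  expect_false(out2$high_quality[3])
  expect_match(out2$flags[3], "crossmap")
})
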