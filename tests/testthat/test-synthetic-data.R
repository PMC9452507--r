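# Generators: construction identities, determinism, and null behaviour.

test_that("gen_genotypes draws HWE dosages with the right mean and is deterministic", {
  cfg <- sim_config(n_samples = 2000, n_variants = 50, n_genes = 10,
                    maf_range = c(0.3, 0.3), n_x_variants = 0, seed = 5)
  g <- gen_genotypes(cfg)
  means <- colMeans(g$genotypes$dosage)
  se <- sqrt(2 * 0.3 * 0.7 / 2000)   # var of dosage = 2pq under HWE
  expect_true(all(abs(means - 0.6) < 3 * se))
  expect_true(all(g$genotypes$dosage %in% 0:2))
  g2 <- gen_genotypes(cfg)
  expect_identical(g$genotypes$dosage, g2$genotypes$dosage)
  expect_error(gen_genotypes(sim_config(n_samples = 1)), "n_samples")
})

test_that("generated genotypes pass the HWE exact test at the null rate", {
  cfg <- sim_config(n_samples = 5000, n_variants = 200, n_genes = 10,
                    maf_range = c(0.2, 0.2), n_x_variants = 0, seed = 2)
  g <- gen_genotypes(cfg)
  p <- apply(g$genotypes$dosage, 2, function(v)
    hwe_exact_test(sum(v == 0), sum(v == 1), sum(v == 2)))
  expect_gte(mean(p >= 0.01), 0.99)
})

test_that("males are hemizygous on X and females are not", {
  cfg <- sim_config(n_samples = 300, n_variants = 20, n_genes = 10, seed = 3)
  g <- gen_genotypes(cfg)
  xd <- g$genotypes$dosage[, g$genotypes$variants$chrom == "X"]
  male <- g$sex == "male"
  expect_false(any(xd[male, ] == 1))
  expect_true(any(xd[!male, ] == 1))
})

test_that("gen_expression plants null, multiplicative and latent effects as stated", {
  # null: correlations scatter around zero
  co <- make_cohort(seed = 11, n = 200, n_effects = 0)
  eint <- int_rows(co$expr$tpm[1:20, ])
  r <- vapply(1:20, function(i)
    cor(eint[i, ], co$geno$genotypes$dosage[, i]), numeric(1))
  expect_lt(abs(mean(r)), 3 * (1 / sqrt(200)) / sqrt(20))

  # planted aFC = 2, no noise: exact 2x ratio between dosage groups
  cfg0 <- sim_config(n_samples = 150, n_variants = 50, n_genes = 10,
                     noise_sd = 0, seed = 4)
  g <- gen_genotypes(cfg0)
  pr <- cis_pairs(g$annotation, g$genotypes$variants)
  eff <- data.frame(gene = pr$gene_id[1], variant = pr$variant_id[1],
                    beta_latent = 0, afc = 2)
  cfg <- sim_config(n_samples = 150, n_variants = 50, n_genes = 10,
                    noise_sd = 0, effect_table = eff, seed = 4)
  ge <- gen_expression(g, cfg)
  d <- g$genotypes$dosage[, pr$variant_id[1]]
  tpm <- ge$expr$tpm[pr$gene_id[1], ]
  expect_equal(mean(tpm[d == 2]) / mean(tpm[d == 0]), 2, tolerance = 1e-12)

  # effect outside the window is rejected
  far <- g$genotypes$variants$variant_id[
    g$genotypes$variants$chrom != g$annotation$chrom[1]][1]
  bad <- data.frame(gene = g$annotation$gene_id[1], variant = far,
                    beta_latent = 1, afc = 1)
  cfgb <- sim_config(n_samples = 150, n_variants = 50, n_genes = 10,
                     effect_table = bad, seed = 4)
  expect_error(gen_expression(g, cfgb), "cis window")
})

test_that("planted beta_latent = 0.8 is detected by cis_scan with high power", {
  hits <- vapply(1:100, function(s) {
    co <- make_cohort(seed = 1000 + s, n = 192, n_variants = 10, n_genes = 5,
                      n_effects = 1, beta = 0.8, maf = c(0.3, 0.3))
    eint <- int_rows(co$expr$tpm[co$effects$gene, , drop = FALSE])
    res <- cis_scan(eint, co$geno$genotypes, NULL,
                    data.frame(gene_id = co$effects$gene,
                               variant_id = co$effects$variant))
    res$p < 1e-5
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("inject_swaps is the identity for no pairs and an involution", {
  co <- make_cohort(seed = 7, n = 30, n_variants = 20, n_genes = 10, n_effects = 0)
  expect_identical(inject_swaps(co$expr, list()), co$expr)
  once <- inject_swaps(co$expr, list(c("S001", "S002")))
  expect_false(identical(once$tpm, co$expr$tpm))
  twice <- inject_swaps(once, list(c("S001", "S002")))
  expect_identical(twice$tpm, co$expr$tpm)
  expect_error(inject_swaps(co$expr, list(c("S001", "S002"), c("S002", "S003"))),
               "disjoint")
  expect_error(inject_swaps(co$expr, list(c("S001", "nope"))), "unknown sample")
})

test_that("gen_exon_usage: null groups match; planted shift is recovered", {
  cfg <- sim_config(n_samples = 400, n_variants = 20, n_genes = 6,
                    maf_range = c(0.3, 0.5), seed = 9)
  g <- gen_genotypes(cfg)
  pr <- cis_pairs(g$annotation, g$genotypes$variants)
  eu0 <- gen_exon_usage(g, cfg, n_exons = 2)
  u <- exon_usage(eu0$exon_counts[[1]])
  d <- round(g$genotypes$dosage[, pr$variant_id[pr$gene_id == names(eu0$exon_counts)[1]][1]])
  gm <- tapply(u$proportions[, 1], d, mean)
  expect_true(max(gm) - min(gm) < 0.05)   # sampling error only

  sq <- data.frame(gene = pr$gene_id[1], variant = pr$variant_id[1], shift = 0.3)
  eu <- gen_exon_usage(g, cfg, n_exons = 2, sqtl_effects = sq)
  u1 <- exon_usage(eu$exon_counts[[pr$gene_id[1]]])
  d1 <- round(g$genotypes$dosage[, pr$variant_id[1]])
  gm1 <- tapply(u1$proportions[, 1], d1, mean)
  expect_lt(abs((gm1[["2"]] - gm1[["0"]]) - 0.3), 3 * 0.03)
  expect_error(gen_exon_usage(g, cfg, n_exons = 2,
                              sqtl_effects = transform(sq, shift = 2)),
               "proportions")
})

test_that("gen_reference_panels matches its equicorrelation and missingness", {
  z0 <- gen_reference_panels(sim_config(n_genes = 10000, n_datasets = 4,
                                        panel_rho = 0, seed = 6))$z
  expect_true(all(abs(cor(z0)[upper.tri(diag(4))]) < 0.03))
  z5 <- gen_reference_panels(sim_config(n_genes = 10000, n_datasets = 4,
                                        panel_rho = 0.5, seed = 6))$z
  expect_true(all(abs(cor(z5)[upper.tri(diag(4))] - 0.5) < 0.03))
  zm <- gen_reference_panels(sim_config(n_genes = 10000, n_datasets = 4,
                                        panel_rho = 0.5, missing_rate = 0.2,
                                        seed = 8))$z
  expect_equal(mean(is.na(zm)), 0.2, tolerance = 0.01 / 0.2)
  expect_error(gen_reference_panels(sim_config(n_datasets = 3, panel_rho = -0.6)),
               "positive definite")
  # causal shift lands in every column
  cz <- gen_reference_panels(sim_config(n_genes = 100, n_datasets = 3,
                                        panel_rho = 0.3,
                                        causal_genes = "gene_0001",
                                        causal_shift = 10, seed = 2))$z
  expect_true(all(cz["gene_0001", ] > 4))
})

test_that("gen_posterior_matrix plants liver structure", {
  tis <- c("UNC_Liver", "GTEx_Liver", paste0("tissue_", 1:8))
  planted <- sprintf("gene_%04d", 1:10)
  sib <- vapply(1:20, function(s) {
    pm <- gen_posterior_matrix(sim_config(n_genes = 300, seed = s),
                               tis, tis[1:2], liver_specific = planted)
    rs <- cor(pm$posteriors, method = "spearman")["UNC_Liver", ]
    rs["GTEx_Liver"] > max(rs[setdiff(tis, tis[1:2])])
  }, logical(1))
  expect_gte(mean(sib), 0.95)
  pm <- gen_posterior_matrix(sim_config(n_genes = 300, seed = 1),
                             tis, tis[1:2], liver_specific = planted)
  expect_true(all(pm$posteriors >= 0 & pm$posteriors <= 1))
  sp <- specificity_score(pm$posteriors, tis[1:2])
  expect_setequal(sp$gene_id[1:10], planted)
  expect_error(gen_posterior_matrix(sim_config(), tis, character()), "non-empty")
})

test_that("gen_gene_sets builds the catalog and validates reachability", {
  cfg <- sim_config(n_genes = 200, seed = 3)
  ann <- gen_annotation(cfg)
  gs <- gen_gene_sets(ann, cfg, eqtl_genes = ann$gene_id[1:60], n_control = 0)
  expect_named(gs$sets, "enriched_set")
  gs2 <- gen_gene_sets(ann, cfg, eqtl_genes = ann$gene_id[1:60], n_control = 2)
  expect_length(gs2$sets, 3)
  expect_error(gen_gene_sets(ann, sim_config(n_genes = 5, seed = 1),
                             eqtl_genes = character(), target_lnor = 1.5),
               "unreachable")
})
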