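# Shared fixture builders. Everything is generated in code at test time;
# seeds are fixed so every test is deterministic.

# A cohort with planted strong cis effects: the regime the swap scan and
# the association power examples assume (common variants, per-gene
# R^2 ~ 0.6 on the latent scale).
make_cohort <- function(seed = 1, n = 120, n_variants = 200, n_genes = 60,
                        n_effects = 40, beta = 2, afc = 1,
                        maf = c(0.2, 0.5), noise_sd = 1) {
  cfg0 <- sim_config(n_samples = n, n_variants = n_variants,
                     n_genes = n_genes, maf_range = maf,
                     noise_sd = noise_sd, seed = seed)
  geno <- gen_genotypes(cfg0)
  pairs <- cis_pairs(geno$annotation, geno$genotypes$variants)
  eff <- NULL
  if (n_effects > 0) {
    genes <- unique(pairs$gene_id)[seq_len(n_effects)]
    eff <- data.frame(
      gene = genes,
      variant = vapply(genes, function(g) pairs$variant_id[pairs$gene_id == g][1],
                       character(1)),
      beta_latent = beta, afc = afc, stringsAsFactors = FALSE)
  }
  cfg <- sim_config(n_samples = n, n_variants = n_variants,
                    n_genes = n_genes, maf_range = maf,
                    effect_table = eff, noise_sd = noise_sd, seed = seed)
  ge <- gen_expression(geno, cfg)
  list(config = cfg, geno = geno, annotation = geno$annotation,
       pairs = pairs, effects = eff, expr = ge$expr, truth = ge$truth)
}

# INT-transform a TPM matrix row-wise
int_rows <- function(tpm) {
  out <- t(apply(tpm, 1, inverse_normal_transform))
  colnames(out) <- colnames(tpm)
  out
}

# independent Monte-Carlo HWE oracle: randomly pair the observed alleles
# into genotypes and tabulate the heterozygote-count distribution, then
# apply the same "sum of probabilities <= observed" rule on the empirical
# distribution. Shares no formula with the implementation.
hwe_mc_oracle <- function(n_AA, n_Aa, n_aa, n_sim = 20000, seed = 99) {
  set.seed(seed)
  n <- n_AA + n_Aa + n_aa
  alleles <- rep(c(0L, 1L), c(2 * n_AA + n_Aa, n_Aa + 2 * n_aa))
  hets <- replicate(n_sim, {
    a <- sample(alleles)
    sum(a[seq(1, 2 * n, 2)] != a[seq(2, 2 * n, 2)])
  })
  tab <- table(hets) / n_sim
  obs <- tab[as.character(n_Aa)]
  if (is.na(obs)) obs <- 0
  sum(tab[tab <= obs + 1e-12])
}
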