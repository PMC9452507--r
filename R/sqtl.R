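# Splicing QTLs on exon-usage proportions: distance-based pseudo-F with
# permutation p-values.

#' Exon-usage proportions for one gene
#'
#' Converts a samples x exons count matrix to per-sample usage proportions
#' (counts over the row total). Samples with zero total reads are marked
#' missing and excluded downstream.
#'
#' @param exon_counts samples x exons count matrix (>= 2 exons).
#' @return object of class `exon_usage`: list with `proportions` (rows sum
#'   to 1; missing rows NA), `total_reads`, `missing` (logical).
#' @export
exon_usage <- function(exon_counts) {
  exon_counts <- as.matrix(exon_counts)
  if (ncol(exon_counts) < 2) stop("single-exon gene: usage undefined")
  tot <- rowSums(exon_counts)
  prop <- sweep(exon_counts, 1, tot, "/")
  prop[tot == 0, ] <- NA_real_
  structure(list(proportions = prop, total_reads = tot, missing = tot == 0),
            class = "exon_usage")
}

# round dosages to {0,1,2} and merge groups below the size floor toward the
# nearest dosage group
dosage_groups <- function(dosage, floor_n = 5) {
  g <- round(dosage)
  g <- pmin(pmax(g, 0), 2)
  repeat {
    tab <- table(g)
    small <- names(tab)[tab < floor_n & tab > 0]
    if (!length(small) || length(tab) <= 1) break
    s <- as.numeric(small[1])
    others <- as.numeric(setdiff(names(tab), small[1]))
    nearest <- others[which.min(abs(others - s))]
    g[g == s] <- nearest
  }
  g
}

# distance-based pseudo-F (Euclidean distances between usage vectors):
# between-group over within-group mean squares
pseudo_f <- function(u, g) {
  n <- nrow(u)
  levs <- unique(g)
  k <- length(levs)
  grand <- colMeans(u)
  sst <- sum(sweep(u, 2, grand)^2)
  ssw <- 0
  for (l in levs) {
    ul <- u[g == l, , drop = FALSE]
    ssw <- ssw + sum(sweep(ul, 2, colMeans(ul))^2)
  }
  ((sst - ssw) / (k - 1)) / (ssw / (n - k))
}

#' Splicing-QTL permutation test for one gene-variant pair
#'
#' Compares exon-usage composition across genotype groups with an
#' Anderson-style distance-based pseudo-F (Euclidean distance between usage
#' vectors; between-group over within-group mean squared distance). The
#' p-value is `(1 + #{permuted F >= observed F}) / (1 + n_perm)` with
#' genotype labels permuted; it is never exactly 0.
#'
#' @param usage an [exon_usage()] object.
#' @param dosage dosage vector aligned to the usage rows.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @param floor_n minimum genotype-group size; smaller groups are merged
#'   toward the nearest group.
#' @return list with `statistic`, `p`, `n_perm`, `groups`; or a `skipped`
#'   reason when fewer than 2 groups meet the floor.
#' @export
sqtl_test <- function(usage, dosage, n_perm = 1000, seed = 1L, floor_n = 5) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  ok <- !usage$missing
  u <- usage$proportions[ok, , drop = FALSE]
  d <- dosage[ok]
  g <- dosage_groups(d, floor_n)
  tab <- table(g)
  if (length(tab) < 2 || any(tab < floor_n))
    return(list(skipped = "fewer than 2 genotype groups with enough samples"))
  f_obs <- pseudo_f(u, g)
  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    if (pseudo_f(u, sample(g)) >= f_obs) count <- count + 1L
  }
  list(statistic = f_obs, p = (1 + count) / (1 + n_perm), n_perm = n_perm,
       groups = tab)
}

#' Gene-level splicing-QTL scan
#'
#' For each gene: observed statistic = maximum pseudo-F over the gene's cis
#' variants; the gene-level permutation p is obtained by recomputing that
#' maximum under permuted sample labels (one permutation stream per gene),
#' which corrects for the number of cis variants tested. BH q-values are
#' computed across genes.
#'
#' @param exon_counts named list of samples x exons count matrices (one per
#'   gene), as from [gen_exon_usage()].
#' @param genotypes a [genotype_matrix()].
#' @param annotation gene annotation.
#' @param window_bp cis window half-width.
#' @param n_perm permutations per gene.
#' @param seed integer seed.
#' @param floor_n genotype-group size floor.
#' @return data.frame: per gene best variant, statistic, permutation p, q;
#'   skipped genes carry the reason and NA results.
#' @export
sqtl_scan <- function(exon_counts, genotypes, annotation, window_bp = 1e6,
                      n_perm = 1000, seed = 1L, floor_n = 5) {
  genes <- intersect(names(exon_counts), annotation$gene_id)
  if (!length(genes))
    return(data.frame(gene_id = character(), best_variant = character(),
                      statistic = numeric(), p = numeric(), q = numeric(),
                      reason = character()))
  pairs <- cis_pairs(annotation[annotation$gene_id %in% genes, ],
                     genotypes$variants, window_bp)
  rows <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    vs <- pairs$variant_id[pairs$gene_id == g]
    if (!length(vs))
      return(data.frame(gene_id = g, best_variant = NA, statistic = NA,
                        p = NA, reason = "no cis variants", stringsAsFactors = FALSE))
    usage <- exon_usage(exon_counts[[g]])
    ok <- !usage$missing
    u <- usage$proportions[ok, , drop = FALSE]
    dmat <- genotypes$dosage[ok, vs, drop = FALSE]
    glist <- lapply(seq_along(vs), function(j) dosage_groups(dmat[, j], floor_n))
    usable <- vapply(glist, function(gg) {
      tab <- table(gg); length(tab) >= 2 && all(tab >= floor_n)
    }, logical(1))
    if (!any(usable))
      return(data.frame(gene_id = g, best_variant = NA, statistic = NA,
                        p = NA, reason = "no variant with 2 usable genotype groups",
                        stringsAsFactors = FALSE))
    glist <- glist[usable]; vs <- vs[usable]
    f_all <- vapply(glist, function(gg) pseudo_f(u, gg), numeric(1))
    f_obs <- max(f_all)
    set.seed(sub_seed(seed, i))
    count <- 0L
    nsamp <- nrow(u)
    for (b in seq_len(n_perm)) {
      perm <- sample.int(nsamp)
      fmax <- max(vapply(glist, function(gg) pseudo_f(u, gg[perm]), numeric(1)))
      if (fmax >= f_obs) count <- count + 1L
    }
    data.frame(gene_id = g, best_variant = vs[which.max(f_all)],
               statistic = f_obs, p = (1 + count) / (1 + n_perm),
               reason = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  tested <- !is.na(out$p)
  out$q[tested] <- bh_fdr(out$p[tested])
  out
}
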