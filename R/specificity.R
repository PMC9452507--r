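# Tissue clustering of eQTL posterior profiles and the rank-based
# liver-specificity score, with a rank-sum set-enrichment test.

#' Hierarchical clustering of tissues by eQTL posterior profiles
#'
#' Distance between two tissues = 1 - Spearman correlation of their
#' gene-wise posterior columns; tree built by average linkage.
#'
#' @param posteriors genes x tissues matrix of cis-eQTL posterior
#'   probabilities (>= 3 tissues, no constant column).
#' @return an [stats::hclust] tree.
#' @export
tissue_clustering <- function(posteriors) {
  posteriors <- as.matrix(posteriors)
  if (ncol(posteriors) < 3) stop("need at least 3 tissues")
  const <- apply(posteriors, 2, function(x) length(unique(x)) == 1)
  if (any(const))
    stop("constant tissue column(s): ", paste(colnames(posteriors)[const], collapse = ", "))
  d <- 1 - stats::cor(posteriors, method = "spearman")
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Rank-based liver-specificity score
#'
#' Within each tissue column, genes are ranked by posterior probability
#' (ascending: larger posterior, larger rank; ties get average ranks).
#' Then, per gene: `score1` = sum of its ranks in the two liver columns,
#' `score2` = mean rank across non-liver columns, and
#' `specificity = score1 / score2`. A gene ranked identically everywhere
#' scores exactly 2 (the baseline).
#'
#' @param posteriors genes x tissues matrix.
#' @param liver_columns exactly 2 column names (the two liver datasets).
#' @param nonliver_columns remaining columns; defaults to all others.
#' @return data.frame (`gene_id`, `score1`, `score2`, `specificity`),
#'   sorted by specificity descending.
#' @export
specificity_score <- function(posteriors, liver_columns,
                              nonliver_columns = NULL) {
  posteriors <- as.matrix(posteriors)
  if (length(liver_columns) != 2) stop("liver_columns must name exactly 2 columns")
  if (!all(liver_columns %in% colnames(posteriors)))
    stop("liver column(s) not found")
  nonliver_columns <- nonliver_columns %||%
    setdiff(colnames(posteriors), liver_columns)
  if (!length(nonliver_columns)) stop("no non-liver columns")
  ranks <- apply(posteriors, 2, rank, ties.method = "average")
  score1 <- rowSums(ranks[, liver_columns, drop = FALSE])
  score2 <- rowMeans(ranks[, nonliver_columns, drop = FALSE])
  out <- data.frame(gene_id = rownames(posteriors), score1 = score1,
                    score2 = score2, specificity = score1 / score2,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$specificity, decreasing = TRUE), , drop = FALSE]
}

#' Rank-sum enrichment of a gene set in the specificity ordering
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation with continuity
#' correction) of the specificity values of set members against the
#' complement; reports whether the set ranks higher or lower.
#'
#' @param spec_table data.frame from [specificity_score()].
#' @param gene_set character vector of gene ids.
#' @return list with `statistic` (rank-sum W), `p`, `direction`
#'   ("higher"/"lower"), `n_set`.
#' @export
rank_set_enrichment <- function(spec_table, gene_set) {
  in_set <- spec_table$gene_id %in% gene_set
  n_in <- sum(in_set); n_out <- sum(!in_set)
  if (n_in == 0) stop("empty intersection of gene set and universe")
  if (n_out < 2) stop("degenerate test: complement has fewer than 2 genes")
  wt <- stats::wilcox.test(spec_table$specificity[in_set],
                           spec_table$specificity[!in_set],
                           exact = FALSE, correct = TRUE)
  dir <- if (mean(rank(spec_table$specificity)[in_set]) >
             mean(rank(spec_table$specificity)[!in_set])) "higher" else "lower"
  list(statistic = unname(wt$statistic), p = wt$p.value, direction = dir,
       n_set = n_in)
}

#' Top-N liver-specific genes
#'
#' @param spec_table data.frame from [specificity_score()].
#' @param n number of top genes (default 200, the conventional export for
#'   downstream pathway tools).
#' @return character vector of gene ids.
#' @export
top_specific_genes <- function(spec_table, n = 200) {
  utils::head(spec_table$gene_id, n)
}
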