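# Plain-text readers/writers for the pipeline's interchange formats:
# genotype/expression/annotation/posterior TSVs, GMT gene-set catalogs,
# TWAS z panels (blank cell = missing), and the truth-table JSON.

#' Write / read a genotype dosage TSV (variants x samples)
#'
#' First column `variant_id`, then `chrom`, `pos`, then one column per
#' sample. Missing calls are written as empty cells.
#'
#' @param genotypes a [genotype_matrix()].
#' @param path file path.
#' @export
write_genotype_tsv <- function(genotypes, path) {
  d <- t(genotypes$dosage)
  out <- cbind(genotypes$variants[, c("variant_id", "chrom", "pos")],
               as.data.frame(d, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

#' @rdname write_genotype_tsv
#' @return `read_genotype_tsv` returns a [genotype_matrix()].
#' @export
read_genotype_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = c(chrom = "character"))
  meta <- df[, c("variant_id", "chrom", "pos")]
  dos <- t(as.matrix(df[, setdiff(names(df), c("variant_id", "chrom", "pos"))]))
  colnames(dos) <- meta$variant_id
  genotype_matrix(dos, meta)
}

#' Write / read a genes x samples matrix TSV
#'
#' @param m numeric matrix with gene row names.
#' @param path file path.
#' @param id_col name of the id column (default "gene_id").
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  out <- data.frame(rownames(m), as.data.frame(m, check.names = FALSE),
                    check.names = FALSE)
  names(out)[1] <- id_col
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, id_col = "gene_id") {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, setdiff(names(df), id_col), drop = FALSE])
  rownames(m) <- df[[id_col]]
  m
}

#' Write / read a GMT gene-set catalog
#'
#' One set per line: name, description, then member gene ids,
#' tab-separated.
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1],
                        character(1), USE.NAMES = FALSE)
  sets
}

#' Write / read a TWAS z panel TSV (genes x datasets; blank = missing)
#'
#' @param z genes x datasets matrix.
#' @param path file path.
#' @export
write_zpanel_tsv <- function(z, path) write_matrix_tsv(z, path)

#' @rdname write_zpanel_tsv
#' @export
read_zpanel_tsv <- function(path) read_matrix_tsv(path)

#' Write / read the simulation truth table as JSON
#'
#' @param truth truth list as returned by the generators.
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Write a full synthetic cohort to a directory
#'
#' Materializes genotypes, TPM/count expression, annotation, the gene-set
#' catalog, TWAS z panel, posterior matrix and the truth JSON as plain-text
#' files, so the command-line stages can be exercised end to end.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the list of generated objects.
#' @export
simulate_cohort_files <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  geno <- gen_genotypes(config)
  ge <- gen_expression(geno, config)
  write_genotype_tsv(geno$genotypes, file.path(outdir, "genotypes.tsv"))
  write_matrix_tsv(ge$expr$tpm, file.path(outdir, "tpm.tsv"))
  write_matrix_tsv(ge$expr$counts, file.path(outdir, "counts.tsv"))
  utils::write.table(geno$annotation, file.path(outdir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  panel <- gen_reference_panels(config)
  write_zpanel_tsv(panel$z, file.path(outdir, "zpanel.tsv"))
  truth <- c(ge$truth, panel$truth)
  truth$effects <- ge$truth$effects
  write_truth_json(truth, file.path(outdir, "truth.json"))
  invisible(list(genotypes = geno, expression = ge, panel = panel))
}
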