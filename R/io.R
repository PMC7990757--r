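#' Read a genetic map from CSV
#'
#' Expects a header with columns `marker,group,pos_cM` (UTF-8).
#'
#' @param path file path.
#' @return A [genetic_map()].
#' @export
read_map_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("marker", "group", "pos_cM")
  if (!all(need %in% names(df)))
    stop("map CSV must have columns: ", paste(need, collapse = ", "))
  genetic_map(df$marker, df$group, df$pos_cM)
}

#' @rdname read_map_csv
#' @param map a [genetic_map()] to write.
#' @export
write_map_csv <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genotype matrix from CSV
#'
#' First column `line`, one column per marker, cells in `A`/`B`/`H` or empty
#' for missing.
#'
#' @param path file path.
#' @param dh validate as doubled-haploid (no `H` calls).
#' @return A [genotype_matrix()].
#' @export
read_genotypes_csv <- function(path, dh = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  if (names(df)[1] != "line") stop("genotype CSV must start with a 'line' column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$line
  genotype_matrix(m, dh = dh)
}

#' @rdname read_genotypes_csv
#' @param genotypes a [genotype_matrix()] to write.
#' @param numeric write the numeric export variant: +1 for A, -1 for B, empty
#'   for missing (H not representable).
#' @export
write_genotypes_csv <- function(genotypes, path, numeric = FALSE) {
  if (numeric) {
    num <- matrix(NA_real_, nrow(genotypes), ncol(genotypes),
                  dimnames = dimnames(genotypes))
    num[genotypes == "A"] <- 1
    num[genotypes == "B"] <- -1
    if (any(genotypes == "H", na.rm = TRUE))
      stop("numeric export is defined for homozygous calls only")
    df <- data.frame(line = rownames(genotypes), num, check.names = FALSE)
  } else {
    df <- data.frame(line = rownames(genotypes),
                     unclass(genotypes)[, , drop = FALSE], check.names = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a plot-level multi-environment phenotype table from CSV
#'
#' Long format: one row per plot with columns `env`, `line`, `rep`, `row`,
#' `col` and one column per trait.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_phenotypes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  need <- c("env", "line", "rep", "row", "col")
  if (!all(need %in% names(df)))
    stop("phenotype CSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname read_phenotypes_csv
#' @param phenotypes data.frame to write.
#' @export
write_phenotypes_csv <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
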