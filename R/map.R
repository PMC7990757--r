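#' Genetic map object
#'
#' An ordered table of markers with their linkage group and position in
#' centimorgans. Within each group positions must be non-decreasing and marker
#' names must be unique across the whole map.
#'
#' @param marker character vector of marker names.
#' @param group character vector of linkage-group labels.
#' @param pos_cM numeric vector of map positions (cM, >= 0).
#' @return A `genetic_map` object: a data.frame with columns `marker`, `group`,
#'   `pos_cM`.
#' @examples
#' gm <- genetic_map(c("m1", "m2", "m3"), c("1B", "1B", "1B"), c(0, 10, 25))
#' @export
genetic_map <- function(marker, group, pos_cM) {
  marker <- as.character(marker)
  group <- as.character(group)
  pos_cM <- as.numeric(pos_cM)
  if (length(marker) != length(group) || length(marker) != length(pos_cM))
    stop("marker, group and pos_cM must have equal length")
  if (anyDuplicated(marker))
    stop("duplicated marker names: ",
         paste(unique(marker[duplicated(marker)]), collapse = ", "))
  if (any(is.na(pos_cM)) || any(pos_cM < 0))
    stop("positions must be non-negative and non-missing")
  gm <- data.frame(marker = marker, group = group, pos_cM = pos_cM,
                   stringsAsFactors = FALSE)
  # stable sort: group blocks keep input order, positions sorted within group
  gm <- gm[order(match(gm$group, unique(gm$group)), gm$pos_cM), , drop = FALSE]
  rownames(gm) <- NULL
  class(gm) <- c("genetic_map", "data.frame")
  gm
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("Genetic map: %d markers on %d linkage group(s), %.1f cM total\n",
              nrow(x), length(unique(x$group)),
              sum(tapply(x$pos_cM, x$group, function(p) diff(range(p))))))
  NextMethod()
}

#' Genotype matrix for a biparental population
#'
#' Lines-by-markers categorical calls. `A` denotes the parent-1 allele
#' (Excalibur role, coded +1), `B` the parent-2 allele (Kukri role, coded -1),
#' `H` heterozygous, `NA` missing. A doubled-haploid (DH) matrix must contain
#' no `H` calls.
#'
#' @param calls character matrix (lines x markers) with values in
#'   `c("A", "B", "H", NA)`; rownames are line ids, colnames marker names.
#' @param dh logical; if `TRUE` (default) the matrix is validated to be free of
#'   heterozygous calls.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(calls, dh = TRUE) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls))) rownames(calls) <- paste0("L", seq_len(nrow(calls)))
  if (is.null(colnames(calls))) stop("calls must have marker column names")
  ok <- is.na(calls) | calls %in% c("A", "B", "H")
  if (!all(ok)) stop("invalid genotype codes: ",
                     paste(unique(calls[!ok]), collapse = ", "))
  if (dh && any(calls == "H", na.rm = TRUE))
    stop("doubled-haploid genotype matrix contains H calls")
  structure(calls, dh = dh, class = c("genotype_matrix", class(calls)))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d lines x %d markers (%s), %.1f%% missing\n",
              nrow(x), ncol(x), if (isTRUE(attr(x, "dh"))) "DH" else "non-DH",
              100 * mean(is.na(x))))
  invisible(x)
}

#' Kosambi map function
#'
#' Converts a recombination fraction to map distance in centimorgans using the
#' Kosambi map function d = 25 * ln((1 + 2r) / (1 - 2r)), which allows for
#' crossover interference.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @return Map distance(s) in cM.
#' @seealso [r_from_kosambi_cm()] for the inverse.
#' @examples
#' kosambi_cm_from_r(0.25) # 25 * log(3) = 27.465 cM
#' @export
kosambi_cm_from_r <- function(r) {
  if (any(is.na(r)) || any(r < 0) || any(r >= 0.5))
    stop("recombination fraction must lie in [0, 0.5)")
  100 * 0.25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi map function
#'
#' Converts a Kosambi map distance in centimorgans back to a recombination
#' fraction: r = 0.5 * tanh(2 d / 100).
#'
#' @param d map distance(s) in cM, >= 0.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @export
r_from_kosambi_cm <- function(d) {
  if (any(is.na(d)) || any(d < 0)) stop("map distance must be non-negative")
  0.5 * tanh(2 * d / 100)
}

#' Estimate the recombination fraction between two DH marker columns
#'
#' For a doubled-haploid population the recombination fraction between two
#' loci is the proportion of lines with discordant non-missing calls. The
#' estimate is capped just below 0.5 so that downstream map conversion stays
#' finite; unlinked markers carry no interval information anyway.
#'
#' @param calls_a,calls_b character vectors of DH calls (`A`/`B`/`NA`), equal
#'   length.
#' @param cap upper cap applied to the estimate before map conversion.
#' @return list with `r_hat` (estimate, `NA` if no informative lines),
#'   `n_informative` (lines non-missing in both columns) and `no_information`
#'   flag.
#' @export
estimate_recomb_fraction <- function(calls_a, calls_b, cap = 0.4999) {
  if (length(calls_a) != length(calls_b))
    stop("marker columns must have equal length")
  bad <- function(x) !all(is.na(x) | x %in% c("A", "B"))
  if (bad(calls_a) || bad(calls_b))
    stop("DH columns may contain only A, B or NA")
  use <- !is.na(calls_a) & !is.na(calls_b)
  n <- sum(use)
  if (n == 0L)
    return(list(r_hat = NA_real_, n_informative = 0L, no_information = TRUE))
  r <- sum(calls_a[use] != calls_b[use]) / n
  list(r_hat = min(r, cap), n_informative = n, no_information = FALSE)
}

#' Chi-square test for segregation distortion at a DH marker
#'
#' Tests the observed A:B allele counts against the 1:1 segregation expected
#' in a doubled-haploid population (goodness of fit, 1 df).
#'
#' @param calls character vector of DH calls (`A`/`B`/`NA`).
#' @return list with `chi2`, `p`, `n_A`, `n_B`.
#' @export
segregation_distortion_test <- function(calls) {
  n_A <- sum(calls == "A", na.rm = TRUE)
  n_B <- sum(calls == "B", na.rm = TRUE)
  n <- n_A + n_B
  if (n == 0L) stop("no non-missing calls")
  chi2 <- (n_A - n / 2)^2 / (n / 2) + (n_B - n / 2)^2 / (n / 2)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       n_A = n_A, n_B = n_B)
}

#' Filter markers on missingness and segregation distortion
#'
#' Drops markers whose missing-call rate exceeds `max_missing` or whose
#' 1:1 segregation chi-square p-value falls below `distortion_alpha`
#' (Bonferroni-adjusted over the tested markers by default). Surviving marker
#' order is preserved and the operation is idempotent.
#'
#' @param map a [genetic_map()].
#' @param genotypes a [genotype_matrix()] containing the map's markers.
#' @param max_missing maximum tolerated missing fraction, in (0, 1).
#' @param distortion_alpha familywise significance level for the distortion
#'   test, in (0, 1).
#' @param bonferroni divide `distortion_alpha` by the number of markers tested.
#' @return list with filtered `map`, `genotypes` and a `report` data.frame of
#'   removals (`marker`, `reason`, `value`).
#' @export
filter_markers <- function(map, genotypes, max_missing = 0.20,
                           distortion_alpha = 1e-3, bonferroni = TRUE) {
  stopifnot(max_missing > 0, max_missing < 1,
            distortion_alpha > 0, distortion_alpha < 1)
  mk <- intersect(map$marker, colnames(genotypes))
  if (length(mk) == 0L) stop("map and genotypes share no markers")
  alpha <- if (bonferroni) distortion_alpha / length(mk) else distortion_alpha
  miss <- colMeans(is.na(genotypes[, mk, drop = FALSE]))
  pdist <- vapply(mk, function(m) {
    col <- genotypes[, m]
    if (all(is.na(col))) return(0) # fully missing: caught by missing rule too
    segregation_distortion_test(col)$p
  }, numeric(1))
  drop_miss <- miss > max_missing
  drop_dist <- !drop_miss & pdist < alpha
  report <- rbind(
    data.frame(marker = mk[drop_miss],
               reason = rep("missing", sum(drop_miss)),
               value = unname(miss[drop_miss]), row.names = NULL),
    data.frame(marker = mk[drop_dist],
               reason = rep("distortion", sum(drop_dist)),
               value = unname(pdist[drop_dist]), row.names = NULL))
  keep <- mk[!(drop_miss | drop_dist)]
  if (length(keep) == 0L)
    stop(sprintf(paste0("all markers removed (max_missing = %g, ",
                        "distortion_alpha = %g)"), max_missing,
                 distortion_alpha))
  map2 <- map[map$marker %in% keep, , drop = FALSE]
  rownames(map2) <- NULL
  class(map2) <- c("genetic_map", "data.frame")
  geno2 <- genotypes[, keep, drop = FALSE]
  geno2 <- structure(geno2, dh = attr(genotypes, "dh"),
                     class = class(genotypes))
  list(map = map2, genotypes = geno2, report = report)
}
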