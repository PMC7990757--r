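# Near-isogenic line (NIL) development bookkeeping and fine-mapping:
# select residually heterozygous lines, derive homozygous sib pairs, check
# background homogeneity, compare traits within pairs by t-test, and delimit
# the QTL interval from segment/phenotype concordance.

#' Select lines heterozygous at all target markers
#'
#' Residual heterozygosity at the QTL region is the entry point for NIL
#' development: heterozygous plants are selfed and homozygous progeny of both
#' classes recovered.
#'
#' @param genotypes a (non-DH) [genotype_matrix()] that may contain `H` calls.
#' @param target_markers marker names that must all be `H`.
#' @return character vector of line ids (possibly empty, with a warning).
#' @export
select_heterozygous <- function(genotypes, target_markers) {
  miss <- setdiff(target_markers, colnames(genotypes))
  if (length(miss)) stop("target markers absent: ", paste(miss, collapse = ", "))
  calls <- unclass(genotypes)[, target_markers, drop = FALSE]
  hit <- rownames(genotypes)[rowSums(calls == "H", na.rm = TRUE) ==
                               length(target_markers) &
                               rowSums(is.na(calls)) == 0L]
  if (length(hit) == 0L) warning("no line heterozygous at all target markers")
  hit
}

#' Derive homozygous NIL pairs within families
#'
#' Within each family, pairs one line homozygous parent-1 (A) across the
#' interval markers with one homozygous parent-2 (B) line. The differing
#' segment is the maximal contiguous block of interval markers at which the
#' pair actually differs (recombinants shrink it).
#'
#' @param genotypes progeny [genotype_matrix()].
#' @param interval_markers ordered marker names spanning the QTL interval.
#' @param families named character vector or list mapping each line id to a
#'   family id; defaults to one family containing all lines.
#' @return list of `nil_pair` objects: `pair_id`, `line_AA`, `line_BB`,
#'   `segment_markers`. Families lacking a homozygous class are skipped with
#'   a reason in attribute `skipped`.
#' @export
derive_pairs <- function(genotypes, interval_markers, families = NULL) {
  miss <- setdiff(interval_markers, colnames(genotypes))
  if (length(miss)) stop("interval markers absent: ", paste(miss, collapse = ", "))
  if (is.null(families))
    families <- stats::setNames(rep("F1", nrow(genotypes)), rownames(genotypes))
  calls <- unclass(genotypes)[, interval_markers, drop = FALSE]
  pairs <- list(); skipped <- character(0)
  for (fam in unique(unlist(families))) {
    ln <- names(families)[unlist(families) == fam]
    sub <- calls[ln, , drop = FALSE]
    # fully homozygous (no H, no missing) candidates only; members may carry
    # recombination points, so pick the most-A and most-B lines
    hom <- ln[rowSums(is.na(sub) | sub == "H") == 0L]
    if (length(hom) < 2L) {
      skipped <- c(skipped, paste0(fam, ": fewer than two homozygous lines"))
      next
    }
    nA <- rowSums(calls[hom, , drop = FALSE] == "A")
    a <- hom[which.max(nA)]
    b <- hom[which.max(length(interval_markers) - nA)]
    if (!any(calls[a, ] == "A") || a == b) {
      skipped <- c(skipped, paste0(fam, ": missing homozygous A class"))
      next
    }
    if (!any(calls[b, ] == "B")) {
      skipped <- c(skipped, paste0(fam, ": missing homozygous B class"))
      next
    }
    # maximal contiguous block where the pair is A vs B
    diffm <- seq_along(interval_markers) %in%
      which(calls[a, ] == "A" & calls[b, ] == "B")
    if (any(diffm)) {
      runs <- rle(diffm)
      ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
      big <- which(runs$values)[which.max(runs$lengths[runs$values])]
      seg <- interval_markers[starts[big]:ends[big]]
    } else {
      skipped <- c(skipped, paste0(fam, ": no differing segment"))
      next
    }
    pairs[[length(pairs) + 1L]] <- structure(
      list(pair_id = fam, line_AA = a, line_BB = b, segment_markers = seg),
      class = "nil_pair")
  }
  attr(pairs, "skipped") <- skipped
  pairs
}

#' Background homogeneity of a NIL pair
#'
#' Fraction of genome-wide background markers (disjoint from the segment) at
#' which both members carry identical non-missing calls; the check that the
#' genetic background is fixed apart from the target segment.
#'
#' @param pair a `nil_pair`.
#' @param genotypes the [genotype_matrix()] containing both members.
#' @param background_markers marker names to compare.
#' @return Fraction in `[0, 1]`, or `NA` (flagged undefined) when no marker
#'   is non-missing in both members.
#' @export
background_homogeneity <- function(pair, genotypes, background_markers) {
  if (length(intersect(background_markers, pair$segment_markers)))
    stop("background markers must be disjoint from the segment")
  a <- unclass(genotypes)[pair$line_AA, background_markers]
  b <- unclass(genotypes)[pair$line_BB, background_markers]
  use <- !is.na(a) & !is.na(b)
  if (!any(use)) {
    warning("background homogeneity undefined: no shared non-missing calls")
    return(NA_real_)
  }
  mean(a[use] == b[use])
}

#' Compare a trait between the two members of a NIL pair
#'
#' Two-sided two-sample t-test; pooled-variance (Student) by default, Welch
#' via `welch = TRUE`. Stars follow the usual tiers: `*` p < 0.05, `**`
#' p < 0.01, `***` p < 0.001, `ns` otherwise (strict inequalities). The
#' percentage difference is relative to the BB (parent-2 allele) member.
#'
#' @param values_AA,values_BB replicate trait measurements (>= 2 each).
#' @param welch use the Welch unequal-variance test.
#' @return A `pair_comparison` list: `mean_AA`, `mean_BB`, `t`, `df`, `p`,
#'   `stars`, `pct_diff`.
#' @export
compare_traits <- function(values_AA, values_BB, welch = FALSE) {
  if (length(values_AA) < 2L || length(values_BB) < 2L)
    stop("need at least 2 values per side")
  mA <- mean(values_AA); mB <- mean(values_BB)
  if (stats::var(values_AA) == 0 && stats::var(values_BB) == 0) {
    if (mA == mB)
      return(structure(list(mean_AA = mA, mean_BB = mB, t = 0,
                            df = length(values_AA) + length(values_BB) - 2L,
                            p = 1, stars = "ns",
                            pct_diff = 0), class = "pair_comparison"))
    stop("zero variance on both sides with unequal means: t undefined")
  }
  tt <- stats::t.test(values_AA, values_BB, var.equal = !welch)
  p <- tt$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
  structure(list(mean_AA = mA, mean_BB = mB,
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = p, stars = stars,
                 pct_diff = 100 * (mA - mB) / mB),
            class = "pair_comparison")
}

#' @export
print.pair_comparison <- function(x, ...) {
  cat(sprintf("AA %.3f vs BB %.3f: t = %.3f (df %.1f), p = %.4g %s (%+.1f%%)\n",
              x$mean_AA, x$mean_BB, x$t, x$df, x$p, x$stars, x$pct_diff))
  invisible(x)
}

#' Delimit the QTL interval from NIL segment/phenotype concordance
#'
#' The candidate region is the intersection of the differing segments of all
#' pairs with a significant focal-trait difference, minus the union of the
#' segments of the non-significant pairs; the region must lie inside every
#' significant segment, and a non-significant pair covering the whole
#' intersection makes the pairs discordant. Returns the flanking markers
#' immediately outside the surviving block and its cM span.
#'
#' @param pairs list of `nil_pair` objects (segments on one linkage group).
#' @param comparisons list of `pair_comparison` objects, same order.
#' @param map the [genetic_map()] of the group.
#' @param alpha significance level splitting the pairs (default 0.05, the
#'   lowest star tier).
#' @return list: `markers` (the delimited block), `left_marker`,
#'   `right_marker` (flanks just outside, `NA` at map ends), `span_cM`.
#' @export
delimit_interval <- function(pairs, comparisons, map, alpha = 0.05) {
  stopifnot(length(pairs) == length(comparisons))
  sig <- vapply(comparisons, function(cmp) cmp$p < alpha, logical(1))
  if (!any(sig)) stop("no significant pair: nothing to delimit")
  grp <- unique(map$group[match(unlist(lapply(pairs, `[[`, "segment_markers")),
                                map$marker)])
  grp <- grp[!is.na(grp)]
  if (length(grp) != 1L) stop("segments must lie on a single linkage group")
  gmap <- map[map$group == grp, , drop = FALSE]
  ord <- gmap$marker
  as_idx <- function(mk) sort(match(mk, ord))
  region <- as_idx(pairs[[which(sig)[1]]]$segment_markers)
  for (i in which(sig)[-1])
    region <- intersect(region, as_idx(pairs[[i]]$segment_markers))
  if (length(region) == 0L)
    stop("discordant pairs: significant segments do not overlap")
  for (i in which(!sig))
    region <- setdiff(region, as_idx(pairs[[i]]$segment_markers))
  if (length(region) == 0L)
    stop("discordant pairs: a non-significant segment covers the candidate region")
  region <- sort(region)
  left <- if (min(region) > 1L) ord[min(region) - 1L] else NA_character_
  right <- if (max(region) < length(ord)) ord[max(region) + 1L]
  else NA_character_
  list(markers = ord[region], left_marker = left, right_marker = right,
       span_cM = diff(range(gmap$pos_cM[region])))
}

#' Add derived NIL traits
#'
#' Screenings Scr = 100 * screened grain weight / total grain weight (% small
#' grains); harvest index HI = Yld / BM; grain-filling duration GFD =
#' DTM - DTA (days from anthesis to physiological maturity). Each is computed
#' only when its components are present.
#'
#' @param records data.frame of plot records; recognised component columns:
#'   `screened_weight`, `total_weight`, `Yld`, `BM`, `DTA`, `DTM`.
#' @return The records with `Scr`, `HI`, `GFD` columns appended as available.
#' @export
derived_traits <- function(records) {
  if (all(c("screened_weight", "total_weight") %in% names(records)))
    records$Scr <- 100 * records$screened_weight / records$total_weight
  if (all(c("Yld", "BM") %in% names(records)))
    records$HI <- records$Yld / records$BM
  if (all(c("DTA", "DTM") %in% names(records)))
    records$GFD <- records$DTM - records$DTA
  records
}

#' Per-pair NIL report
#'
#' One row per pair and trait: segment bounds, background identity and the
#' t-test summary.
#'
#' @param pairs list of `nil_pair` objects.
#' @param trait_values function(line_id, trait) returning replicate values,
#'   or a long data.frame with columns `line`, `trait`, `value`.
#' @param traits trait names to compare.
#' @param genotypes,background_markers optional; when both given the report
#'   includes background identity.
#' @return data.frame.
#' @export
nil_pair_report <- function(pairs, trait_values, traits, genotypes = NULL,
                            background_markers = NULL) {
  getv <- if (is.function(trait_values)) trait_values
  else function(id, tr) trait_values$value[trait_values$line == id &
                                             trait_values$trait == tr]
  rows <- list()
  for (pr in pairs) {
    bg <- if (!is.null(genotypes) && !is.null(background_markers))
      background_homogeneity(pr, genotypes, background_markers) else NA_real_
    for (tr in traits) {
      cmp <- compare_traits(getv(pr$line_AA, tr), getv(pr$line_BB, tr))
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = pr$pair_id, trait = tr,
        segment_start = pr$segment_markers[1],
        segment_end = pr$segment_markers[length(pr$segment_markers)],
        background_identity = bg, mean_AA = cmp$mean_AA,
        mean_BB = cmp$mean_BB, t = cmp$t, df = cmp$df, p = cmp$p,
        stars = cmp$stars, pct_diff = cmp$pct_diff, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
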