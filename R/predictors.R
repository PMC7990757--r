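#' Conditional probability of the parent-1 allele given flanking markers
#'
#' For a doubled-haploid line, the probability that a query locus carries the
#' parent-1 (A) allele given the nearest non-missing flanking marker calls
#' (Martinez-Curnow flanking-marker conditioning). Recombination fractions on
#' either side combine without interference:
#' r_LR = r_left + r_right - 2 r_left r_right.
#'
#' @param left_state,right_state flanking calls: `"A"`, `"B"` or `"none"` when
#'   no informative marker exists on that side.
#' @param r_left,r_right recombination fractions between the query locus and
#'   the respective flank, in `[0, 0.5)`. Ignored for a `"none"` flank.
#' @return P(query = A | flanks), a probability.
#' @examples
#' interval_probability("A", "A", 0.1, 0.1)
#' @export
interval_probability <- function(left_state, right_state, r_left = NA,
                                 r_right = NA) {
  chk <- function(s) if (!s %in% c("A", "B", "none"))
    stop("flank state must be A, B or none")
  chk(left_state); chk(right_state)
  chk_r <- function(r) if (is.na(r) || r < 0 || r >= 0.5)
    stop("recombination fraction must lie in [0, 0.5)")
  # single- and no-flank cases
  if (left_state == "none" && right_state == "none") return(0.5)
  if (right_state == "none") {
    chk_r(r_left)
    return(if (left_state == "A") 1 - r_left else r_left)
  }
  if (left_state == "none") {
    chk_r(r_right)
    return(if (right_state == "A") 1 - r_right else r_right)
  }
  chk_r(r_left); chk_r(r_right)
  r_lr <- r_left + r_right - 2 * r_left * r_right
  same <- left_state == right_state
  if (same) {
    p_a <- (1 - r_left) * (1 - r_right) / (1 - r_lr)
    if (left_state == "A") p_a else 1 - p_a
  } else {
    if (r_lr == 0)
      stop("inconsistent flanks: apparent double crossover at zero distance")
    if (left_state == "A") (1 - r_left) * r_right / r_lr
    else r_left * (1 - r_right) / r_lr
  }
}

# Locate, for each line, the nearest non-missing flanking markers around a
# query position on one linkage group and return the conditional +/-1
# expectation. calls: lines x group-markers; pos: group marker positions.
.predict_at_position <- function(calls, pos, query) {
  n <- nrow(calls)
  out <- numeric(n)
  for (i in seq_len(n)) {
    obs <- which(!is.na(calls[i, ]))
    if (length(obs) == 0L) { out[i] <- 0; next }
    po <- pos[obs]
    # marker exactly at the query position wins outright
    at <- obs[abs(po - query) < 1e-9]
    if (length(at) > 0L) {
      out[i] <- if (calls[i, at[1]] == "A") 1 else -1
      next
    }
    li <- obs[po < query]
    ri <- obs[po > query]
    left_state <- if (length(li)) calls[i, li[length(li)]] else "none"
    right_state <- if (length(ri)) calls[i, ri[1]] else "none"
    r_l <- if (length(li)) r_from_kosambi_cm(query - pos[li[length(li)]]) else NA
    r_r <- if (length(ri)) r_from_kosambi_cm(pos[ri[1]] - query) else NA
    p <- interval_probability(left_state, right_state, r_l, r_r)
    out[i] <- 2 * p - 1
  }
  out
}

#' Genetic predictor for one line at one map position
#'
#' The conditional expectation of the +/-1-coded genotype at a query position
#' given the line's nearest non-missing flanking markers on that linkage
#' group. Coding: +1 homozygous parent-1 (Excalibur role), -1 homozygous
#' parent-2 (Kukri role). Imputation of missing calls is implicit: the search
#' simply walks outward to the nearest informative markers.
#'
#' @param calls named character vector of the line's calls (names = markers).
#' @param map a [genetic_map()].
#' @param group linkage-group label.
#' @param position query position in cM.
#' @return Value in `[-1, 1]`; 0 (with a warning) for a line with no
#'   informative marker on the group.
#' @export
line_predictor <- function(calls, map, group, position) {
  gmap <- map[map$group == group, , drop = FALSE]
  if (nrow(gmap) == 0L) stop("unknown linkage group: ", group)
  if (position < min(gmap$pos_cM) - 1e-9 || position > max(gmap$pos_cM) + 1e-9)
    stop("query position outside the group's map span")
  row <- matrix(calls[gmap$marker], nrow = 1,
                dimnames = list(NULL, gmap$marker))
  v <- .predict_at_position(row, gmap$pos_cM, position)
  if (all(is.na(row))) warning("line has no non-missing marker on group ", group)
  v
}

#' Marker-interval genetic predictor matrix
#'
#' Builds the lines x query-positions matrix of conditional +/-1 genotype
#' expectations used as genetic predictors in the genome scan. The default
#' scheme places one query at the midpoint of every adjacent-marker interval
#' per linkage group, labelled by its flanking markers; the `markers` scheme
#' queries the marker positions themselves (diagnostics; equals the +/-1
#' numeric coding wherever calls are observed).
#'
#' @param genotypes a [genotype_matrix()].
#' @param map a [genetic_map()] covering the genotyped markers.
#' @param scheme `"interval_midpoints"` (default), `"markers"` or `"both"`.
#' @return A `predictor_matrix`: list with `values` (lines x queries matrix)
#'   and `positions` (data.frame: `group`, `pos_cM`, `label`, `left_marker`,
#'   `right_marker`).
#' @export
predictor_matrix <- function(genotypes, map,
                             scheme = c("interval_midpoints", "markers",
                                        "both")) {
  scheme <- match.arg(scheme)
  groups <- unique(map$group)
  vals <- list(); qpos <- list()
  for (g in groups) {
    gmap <- map[map$group == g, , drop = FALSE]
    mk <- intersect(gmap$marker, colnames(genotypes))
    gmap <- gmap[gmap$marker %in% mk, , drop = FALSE]
    if (nrow(gmap) == 0L) next
    calls <- unclass(genotypes)[, gmap$marker, drop = FALSE]
    pos <- gmap$pos_cM
    want_mid <- scheme %in% c("interval_midpoints", "both")
    want_mrk <- scheme %in% c("markers", "both")
    if (want_mid && nrow(gmap) < 2L) {
      warning("group ", g, " has < 2 markers; interval scheme skipped")
      want_mid <- FALSE
    }
    q <- data.frame(group = character(), pos_cM = numeric(),
                    label = character(), left_marker = character(),
                    right_marker = character(), stringsAsFactors = FALSE)
    if (want_mid) {
      k <- nrow(gmap) - 1L
      q <- rbind(q, data.frame(
        group = g, pos_cM = (pos[-1] + pos[-(k + 1)]) / 2,
        label = paste0(g, ":", gmap$marker[-(k + 1)], "-", gmap$marker[-1]),
        left_marker = gmap$marker[-(k + 1)], right_marker = gmap$marker[-1],
        stringsAsFactors = FALSE))
    }
    if (want_mrk) {
      q <- rbind(q, data.frame(
        group = g, pos_cM = pos, label = paste0(g, ":", gmap$marker),
        left_marker = gmap$marker, right_marker = gmap$marker,
        stringsAsFactors = FALSE))
    }
    if (nrow(q) == 0L) next
    q <- q[order(q$pos_cM), , drop = FALSE]
    m <- vapply(q$pos_cM, function(p) .predict_at_position(calls, pos, p),
                numeric(nrow(calls)))
    m <- matrix(m, nrow = nrow(calls),
                dimnames = list(rownames(genotypes), q$label))
    vals[[g]] <- m; qpos[[g]] <- q
  }
  if (length(vals) == 0L) stop("no usable linkage groups")
  structure(list(values = do.call(cbind, vals),
                 positions = do.call(rbind, c(qpos, make.row.names = FALSE))),
            class = "predictor_matrix")
}

#' @export
print.predictor_matrix <- function(x, ...) {
  cat(sprintf("Predictor matrix: %d lines x %d query positions on %d group(s)\n",
              nrow(x$values), ncol(x$values), length(unique(x$positions$group))))
  invisible(x)
}

#' Export a predictor matrix to CSV
#'
#' One `line` column plus one column per query position labelled
#' `group:leftMarker-rightMarker`.
#'
#' @param pm a [predictor_matrix()].
#' @param path file path.
#' @export
write_predictors_csv <- function(pm, path) {
  df <- data.frame(line = rownames(pm$values), pm$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
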