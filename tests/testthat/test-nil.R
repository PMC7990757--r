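nil_map <- function(k = 9) {
  genetic_map(paste0("m", 1:k), rep("1B", k), seq(0, by = 1.5, length.out = k))
}

test_that("heterozygous line selection requires H at every target marker", {
  calls <- rbind(L1 = c("H", "H", "A"),
                 L2 = c("A", "H", "B"),
                 L3 = c("H", "H", "A"),
                 L4 = c("H", NA, "B"))
  colnames(calls) <- c("t1", "t2", "x")
  gen <- genotype_matrix(calls, dh = FALSE)
  expect_setequal(select_heterozygous(gen, c("t1", "t2")), c("L1", "L3"))
  expect_warning(out <- select_heterozygous(gen, c("t1", "x")), "no line")
  expect_length(out, 0L)
  expect_error(select_heterozygous(gen, "absent"))
})

test_that("pair derivation finds homozygous sibs and their differing segment", {
  mk <- paste0("m", 1:4)
  calls <- rbind(F1_a = c("A", "A", "A", "A"), F1_b = c("B", "B", "B", "B"),
                 F2_a = c("A", "A", "A", "A"), F2_c = c("A", "A", "A", "A"),
                 F3_a = c("A", "A", "B", "B"), F3_b = c("B", "B", "B", "B"))
  colnames(calls) <- mk
  gen <- genotype_matrix(calls, dh = FALSE)
  fam <- setNames(sub("_.*", "", rownames(calls)), rownames(calls))
  pairs <- derive_pairs(gen, mk, fam)
  ids <- vapply(pairs, `[[`, "", "pair_id")
  expect_setequal(ids, c("F1", "F3")) # F2 lacks an all-B line
  expect_match(attr(pairs, "skipped"), "F2")
  p1 <- pairs[[which(ids == "F1")]]
  expect_equal(p1$segment_markers, mk) # full 4-marker segment
  p3 <- pairs[[which(ids == "F3")]]
  expect_equal(p3$segment_markers, mk[1:2]) # recombinant shrinks the block
})

test_that("background homogeneity counts identical non-missing calls", {
  calls <- rbind(AA = c(rep("A", 4), rep("A", 20), NA, NA),
                 BB = c(rep("B", 4), rep("A", 18), "B", "B", NA, "A"))
  colnames(calls) <- c(paste0("seg", 1:4), paste0("bg", 1:22))
  gen <- genotype_matrix(calls, dh = FALSE)
  pair <- structure(list(pair_id = "P", line_AA = "AA", line_BB = "BB",
                         segment_markers = paste0("seg", 1:4)),
                    class = "nil_pair")
  # 20 comparable markers, 18 identical
  expect_equal(background_homogeneity(pair, gen, paste0("bg", 1:22)),
               18 / 20)
  expect_error(background_homogeneity(pair, gen, c("seg1", "bg1")),
               "disjoint")
})

test_that("pair t-test reproduces the pooled-variance closed form", {
  cmp <- compare_traits(c(10, 12, 14), c(20, 22, 24))
  expect_equal(cmp$t, -6.123724, tolerance = 1e-6)
  expect_equal(cmp$df, 4)
  expect_equal(cmp$p, 2 * pt(cmp$t, 4), tolerance = 1e-10)
  expect_equal(cmp$p, 0.0036, tolerance = 0.02)
  expect_equal(cmp$stars, "**")
  expect_equal(cmp$pct_diff, -45.4545, tolerance = 1e-4)
  # identical samples
  same <- compare_traits(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$stars, "ns")
  # percentage arithmetic
  expect_equal(compare_traits(c(2, 2.0001), c(1, 0.9999))$pct_diff, 100,
               tolerance = 0.1)
  # degenerate variance cases
  expect_equal(compare_traits(c(5, 5), c(5, 5))$t, 0)
  expect_error(compare_traits(c(5, 5), c(7, 7)), "zero variance")
  expect_error(compare_traits(5, c(1, 2)))
})

test_that("pair comparison is antisymmetric and stars are strict step functions", {
  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(5, 10, 2); b <- rnorm(6, 11, 2)
    f <- compare_traits(a, b); r <- compare_traits(b, a)
    expect_equal(f$t, -r$t, tolerance = 1e-12)
    expect_equal(f$p, r$p, tolerance = 1e-12)
    expect_equal(f$pct_diff, -100 * r$pct_diff / (100 + r$pct_diff),
                 tolerance = 1e-8)
  }
  # boundary p exactly at a tier stays in the lower tier (strict <)
  star_of <- function(p) if (p < 0.001) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
  expect_equal(star_of(0.05), "ns")
  expect_equal(star_of(0.01), "*")
  expect_equal(star_of(0.049999), "*")
})

test_that("interval delimitation is intersection minus union with flanks", {
  map <- nil_map(9)
  mk <- map$marker
  pair <- function(id, seg) structure(
    list(pair_id = id, line_AA = paste0(id, "a"), line_BB = paste0(id, "b"),
         segment_markers = seg), class = "nil_pair")
  cmp <- function(p) structure(list(p = p), class = "pair_comparison")
  # significant {m1..m5} and {m3..m7}; non-significant {m6..m9}
  pairs <- list(pair("P1", mk[1:5]), pair("P2", mk[3:7]), pair("P3", mk[6:9]))
  cmps <- list(cmp(0.001), cmp(0.01), cmp(0.6))
  out <- delimit_interval(pairs, cmps, map)
  expect_equal(out$markers, mk[3:5])
  expect_equal(out$left_marker, "m2")
  expect_equal(out$right_marker, "m6")
  expect_equal(out$span_cM, 1.5 * 2)
  # region always inside every significant segment
  expect_true(all(out$markers %in% mk[1:5]))
  expect_true(all(out$markers %in% mk[3:7]))
  # single significant pair keeps its whole segment, NA flank at the map end
  out1 <- delimit_interval(list(pair("P1", mk[1:5])), list(cmp(0.01)), map)
  expect_equal(out1$markers, mk[1:5])
  expect_true(is.na(out1$left_marker))
  # a non-significant pair covering the intersection is discordant
  expect_error(delimit_interval(
    list(pair("P1", mk[1:5]), pair("P2", mk[1:9])),
    list(cmp(0.01), cmp(0.9)), map), "discordant")
  # disjoint significant segments are discordant too
  expect_error(delimit_interval(
    list(pair("P1", mk[1:2]), pair("P2", mk[5:6])),
    list(cmp(0.01), cmp(0.01)), map), "discordant")
  expect_error(delimit_interval(list(pair("P1", mk[1:2])), list(cmp(0.5)),
                                map), "no significant")
})

test_that("derived traits follow their defining ratios", {
  rec <- data.frame(screened_weight = 5, total_weight = 100,
                    Yld = 40, BM = 100, DTA = 70, DTM = 110)
  out <- derived_traits(rec)
  expect_equal(out$Scr, 5)
  expect_equal(out$HI, 0.4)
  expect_equal(out$GFD, 40)
})

test_that("simulated NIL experiment supports the fine-mapping workflow", {
  pe <- data.frame(pair_id = c("P1", "P2", "P3"), effect = c(15, 15, 0))
  tab <- simulate_nil_experiment(pe, n_plants = 24, noise_sd = 5, seed = 5)
  # determinism
  expect_identical(tab, simulate_nil_experiment(pe, n_plants = 24,
                                                noise_sd = 5, seed = 5))
  getv <- function(pair, mem) tab$value[tab$pair_id == pair &
                                          tab$member == mem]
  c1 <- compare_traits(getv("P1", "AA"), getv("P1", "BB"))
  expect_lt(c1$p, 0.001) # 3-sd effect at n = 48 per side
  expect_gt(c1$mean_AA, c1$mean_BB)
  c3 <- compare_traits(getv("P3", "AA"), getv("P3", "BB"))
  expect_gt(c3$p, 0.001) # null pair rarely extreme
})
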