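make_map_n <- function(n_mut, n_wt = 0) {
  set.seed(99)
  n <- n_mut + n_wt
  barcode_map(random_dna(n, 20),
              sprintf("s%03d", seq_len(n)),
              c(sprintf("G%03d", seq_len(n_mut)), rep("WT", n_wt)),
              c(rep("mutant", n_mut), rep("wildtype", n_wt)))
}

test_that("absence filter excludes strictly below 0.0025% of input reads", {
  map <- make_map_n(3)
  cfg <- screen_config()  # absence_fraction 2.5e-5
  b <- map$barcode
  ## total 1e6 reads -> cutoff 25
  counts <- make_counts(setNames(c(24L, 25L, 999951L), b), map,
                        total = 1e6)
  kept <- filter_absent(counts, cfg)
  expect_false(b[1] %in% kept)  # 24 < 25: excluded
  expect_true(b[2] %in% kept)   # exactly at the cutoff: retained
  expect_true(b[3] %in% kept)

  ## degenerate: single non-zero barcode
  counts <- make_counts(setNames(c(0L, 0L, 100L), b), map, total = 100L)
  expect_equal(filter_absent(counts, cfg), b[3])

  counts$total_reads <- 0L
  expect_error(filter_absent(counts, cfg), "empty input sample")

  ip <- make_counts(setNames(c(1L, 1L, 1L), b), map, role = "IP")
  expect_error(filter_absent(ip, cfg), "input sample")
})

test_that("median normalization centres the retained median at 1", {
  map <- make_map_n(4)
  b <- map$barcode
  counts <- make_counts(setNames(c(10L, 20L, 30L, 0L), b), map)
  sc <- median_normalize(counts, b[1:3])
  expect_equal(unname(sc), c(0.5, 1.0, 1.5))

  counts <- make_counts(setNames(c(4L, 8L, 0L, 0L), b), map)
  sc <- median_normalize(counts, b[1:2])  # even-size midpoint median = 6
  expect_equal(unname(sc), c(4 / 6, 8 / 6))
  expect_equal(median(sc), 1)

  ## scale invariance
  counts7 <- make_counts(setNames(7L * c(10L, 20L, 30L, 0L), b), map)
  expect_equal(median_normalize(counts7, b[1:3]),
               median_normalize(make_counts(setNames(c(10L, 20L, 30L, 0L), b),
                                            map), b[1:3]))

  zero <- make_counts(setNames(c(0L, 0L, 0L, 0L), b), map, total = 10L)
  expect_error(median_normalize(zero, b[1:2]), "degenerate")
  expect_error(median_normalize(counts, character(0)), "empty")
})

test_that("IP/input ratios divide matched scores and zero IP gives ratio 0", {
  ip <- c(a = 2.0, b = 1.0, c = 0.0)
  input <- c(a = 1.0, b = 1.0, c = 0.5)
  r <- ip_over_input(ip, input)
  expect_equal(unname(r[c("a", "b", "c")]), c(2.0, 1.0, 0.0))
  expect_equal(unname(ip_over_input(input, input)), rep(1, 3))
  expect_error(ip_over_input(ip[1:2], input), "same retained set")
})

test_that("replicate merging intersects retained sets and averages raw ratios", {
  ratios <- list(
    t40 = list(rep1 = c(g1 = 0.5, g2 = 1.0, g3 = 2.0),
               rep2 = c(g1 = 0.7, g2 = 1.0)),
    t80 = list(rep1 = c(g1 = 1.0, g2 = 1.0, g3 = 1.0),
               rep2 = c(g1 = 1.0, g2 = 3.0)))
  m <- merge_replicates(ratios)
  expect_setequal(m$barcodes, c("g1", "g2"))  # g3 missing from rep2
  expect_equal(m$mean_ratio$t40[["g1"]], 0.6)
  expect_equal(m$mean_ratio$t80[["g2"]], 2.0)

  one <- list(t40 = list(rep1 = c(g1 = 1), rep2 = c(g1 = 2)),
              t80 = list(rep1 = c(g1 = 1), rep2 = c(g1 = 1)))
  expect_equal(merge_replicates(one)$barcodes, "g1")

  none <- list(t40 = list(rep1 = c(g1 = 1), rep2 = c(g2 = 1)),
               t80 = list(rep1 = c(g1 = 1), rep2 = c(g2 = 1)))
  expect_error(merge_replicates(none), "no overlapping")
})

test_that("log2 fold change centres on the chosen baseline and floors zeros", {
  ## 5-entry toy table recomputed by hand: wildtype barcodes w1, w2
  mean_ratio <- c(g1 = 2.0, g2 = 0.5, g3 = 0.0, w1 = 0.9, w2 = 1.1)
  wt <- c("w1", "w2")
  cfg <- screen_config(baseline_policy = "wildtype_median")
  fc <- log2_fold_change(mean_ratio, wt, cfg)
  B <- (0.9 + 1.1) / 2  # = 1.0
  expect_equal(fc$baseline, B)
  expect_equal(fc$log2fc[["g1"]], log2(2.0 / B))
  expect_equal(fc$log2fc[["g2"]], -1)
  ## zero ratio floored to the smallest positive ratio in the table (0.5)
  expect_equal(fc$log2fc[["g3"]], log2(0.5 / B))
  expect_true(fc$floored[["g3"]])
  expect_false(any(fc$floored[c("g1", "g2")]))

  fc_all <- log2_fold_change(mean_ratio, wt,
                             screen_config(baseline_policy = "all_median"))
  expect_equal(fc_all$baseline, median(mean_ratio))
  fc_none <- log2_fold_change(mean_ratio, wt,
                              screen_config(baseline_policy = "none"))
  expect_equal(fc_none$log2fc[["g1"]], 1)

  expect_error(log2_fold_change(mean_ratio, character(0), cfg),
               "no wild-type")
})

test_that("classification matches the rule table on a grid spanning the boundaries", {
  tau <- 1.25
  grid <- seq(-2.5, 2.5, length.out = 41)  # includes -1.25, 0, 1.25
  expect_true(all(c(-tau, tau) %in% grid))
  g <- expand.grid(fc40 = grid, fc80 = grid)
  got <- classify_mutants(g$fc40, g$fc80, tau)
  ## independent scalar re-derivation of the rule
  want <- mapply(function(a, b) {
    if (a < -tau && b < -tau) "down_both"
    else if (a > tau && b > tau) "up_both"
    else if (a < -tau) "down_40_only"          # and b >= -tau by the above
    else if (abs(a) <= tau && b < -tau) "down_80_only"
    else "other"
  }, g$fc40, g$fc80)
  expect_identical(as.character(got), unname(want))

  ## boundary cases: strict inequalities at tau
  expect_identical(as.character(classify_mutants(-1.5, -1.4)), "down_both")
  expect_identical(as.character(classify_mutants(-1.25, -1.30)),
                   "down_80_only")
  expect_identical(as.character(classify_mutants(0, 0)), "other")
  expect_identical(as.character(classify_mutants(1.5, -1.5)), "other")
})

test_that("the five classes partition the fold-change plane", {
  set.seed(1)
  fc40 <- runif(2000, -4, 4)
  fc80 <- runif(2000, -4, 4)
  cls <- classify_mutants(fc40, fc80)
  expect_false(anyNA(cls))  # exhaustive
  expect_setequal(levels(cls), c("down_both", "up_both", "down_40_only",
                                 "down_80_only", "other"))
  ## exclusivity: rebuild each condition and check exactly one fires
  tau <- 1.25
  cond <- cbind(down_both = fc40 < -tau & fc80 < -tau,
                up_both = fc40 > tau & fc80 > tau,
                down_40_only = fc40 < -tau & fc80 >= -tau,
                down_80_only = abs(fc40) <= tau & fc80 < -tau)
  expect_true(all(rowSums(cond) <= 1))
  expect_identical(rowSums(cond) == 0, as.character(cls) == "other")
})

test_that("replicate correlation matches the definitional Pearson formula", {
  r1 <- c(a = 1.0, b = 2.0, c = 4.0, d = 0.5, e = 1.5)
  r2 <- c(a = 1.2, b = 1.8, c = 3.1, d = 0.6, e = 2.2)
  x <- log2(r1); y <- log2(r2)
  n <- 5
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  expect_equal(replicate_correlation(r1, r2), num / den)

  expect_equal(replicate_correlation(r1, r1), 1.0)
  expect_equal(replicate_correlation(r1, 1 / r1), -1.0)  # rep2 = -rep1 in log space
  expect_true(is.na(replicate_correlation(r1[1:2], r2[1:2])))
  expect_true(is.na(replicate_correlation(r1, c(a = 2, b = 2, c = 2,
                                                d = 2, e = 2))))
})

## -- integrated score_screen behaviour on constructed counts ------------

build_screen_counts <- function(map, ip_mult = NULL, depth = 1e5,
                                seed = 3, scale = list()) {
  ## deterministic expected counts with optional per-barcode IP multiplier
  set.seed(seed)
  n <- nrow(map)
  if (is.null(ip_mult)) ip_mult <- rep(1, n)
  base <- rep(round(depth / n), n)
  out <- list()
  i <- 1L
  for (r in 1:2) for (t in c(40L, 80L)) for (role in c("input", "IP")) {
    mult <- if (role == "IP") ip_mult else rep(1, n)
    cnt <- round(base * mult)
    s <- scale[[paste(role, t, r)]]
    if (is.null(s)) s <- 1
    cnt <- as.integer(round(cnt * s))
    out[[i]] <- make_counts(setNames(cnt, map$barcode), map, role = role,
                            timepoint = t, replicate = r,
                            id = sprintf("%s_t%d_rep%d", role, t, r))
    i <- i + 1L
  }
  out
}

test_that("score_screen is invariant to rescaling any single sample", {
  map <- make_map_n(30, 10)
  ip_mult <- c(rep(c(0.25, 1), length.out = 30), rep(1, 10))
  counts_a <- build_screen_counts(map, ip_mult)
  counts_b <- build_screen_counts(map, ip_mult,
                                  scale = list("IP 40 1" = 3,
                                               "input 80 2" = 5))
  st_a <- score_screen(counts_a, map)
  st_b <- score_screen(counts_b, map)
  expect_equal(st_a$log2fc_t40, st_b$log2fc_t40)
  expect_equal(st_a$log2fc_t80, st_b$log2fc_t80)
  expect_identical(as.character(st_a$hit_class),
                   as.character(st_b$hit_class))
})

test_that("wildtype-median baseline centres wild-type log2fc at 0", {
  map <- make_map_n(40, 20)
  ip_mult <- c(runif(40, 0.2, 5), rep(1, 20))
  counts <- build_screen_counts(map, ip_mult)
  st <- score_screen(counts, map)
  wt_ratio <- attr(st, "wildtype_ratio")
  B <- attr(st, "baseline")
  for (t in names(wt_ratio)) {
    expect_equal(median(log2(wt_ratio[[t]] / B[[t]])), 0)
  }
})

test_that("increasing a gene's IP count never decreases its log2fc", {
  map <- make_map_n(20, 10)
  base_mult <- rep(1, 30)
  last <- -Inf
  for (m in c(0.5, 1, 2, 4)) {
    mult <- base_mult; mult[5] <- m
    st <- score_screen(build_screen_counts(map, mult), map)
    fc <- st$log2fc_t40[st$gene == map$gene[5]]
    expect_gte(fc, last)
    last <- fc
  }
})
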