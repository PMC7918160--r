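## small structure-set fixture: k jittered spheres on one grid
make_structures <- function(k, seed, pid = "P1", grid = ImageGrid(c(24, 24, 24), c(2, 2, 2))) {
  set.seed(seed)
  ctr <- c(23, 23, 23)
  masks <- lapply(seq_len(k), function(o)
    voxelizeSphere(grid, ctr + rnorm(3, 0, 2), 10 + rnorm(1, 0, 1)))
  names(masks) <- paste0("RO", seq_len(k))
  StructureSet(pid, manual = masks)
}

test_that("pairwise design yields k-1 ordered records per observer per patient", {
  s6 <- make_structures(6, 1)
  rec <- pairwiseMetrics(s6)
  expect_equal(nrow(rec), 6 * 5)
  expect_true(all(table(rec$test_observer) == 5))
  expect_true(all(rec$test_observer != rec$reference_observer))

  s2 <- make_structures(2, 2)
  rec2 <- pairwiseMetrics(s2)
  expect_equal(nrow(rec2), 2)
  expect_equal(rec2$dsc[1], rec2$dsc[2])           # dsc symmetric
  expect_equal(rec2$precision[1], rec2$sensitivity[2])

  expect_error(pairwiseMetrics(make_structures(1, 3)), class = "designError")
})

test_that("a 7-patient 6-observer cohort gives 210 ordered records", {
  recs <- do.call(rbind, lapply(1:7, function(p)
    pairwiseMetrics(make_structures(6, 100 + p, pid = sprintf("P%d", p),
                                    grid = ImageGrid(c(18, 18, 18), c(2, 2, 2))))))
  expect_equal(nrow(recs), 7 * 6 * 5)
  ## swap duality: pooled over ordered pairs, grand mean precision equals
  ## grand mean sensitivity
  expect_equal(mean(recs$precision), mean(recs$sensitivity), tolerance = 1e-12)
})

test_that("observer summaries use sample sd over defined values only", {
  rec <- data.frame(patient_id = "P1",
                    test_observer = c("A", "A", "B", "B"),
                    reference_observer = c("B", "C", "A", "C"),
                    dsc = c(0.5, 0.7, 0.8, 0.6),
                    precision = c(0.5, 0.7, 0.8, 0.6),
                    sensitivity = c(0.5, 0.7, 0.8, 0.6),
                    specificity = c(0.9, NA, 0.8, 0.7),
                    mean_dta_cm = c(0.1, 0.2, 0.3, 0.4),
                    max_dta_cm = c(1, 2, 3, 4))
  sm <- observerSummary(rec)
  a_dsc <- sm[sm$observer == "A" & sm$metric == "dsc", ]
  expect_equal(a_dsc$mean, 0.6)
  expect_equal(a_dsc$sd, sd(c(0.5, 0.7)))
  expect_equal(a_dsc$n, 2)
  a_spec <- sm[sm$observer == "A" & sm$metric == "specificity", ]
  expect_equal(a_spec$n, 1)          # undefined value dropped for this metric
  expect_equal(a_spec$mean, 0.9)
})

test_that("identical masks give DSC mean 1 with sd 0 everywhere", {
  g <- ImageGrid(c(16, 16, 16), c(2, 2, 2))
  m <- voxelizeSphere(g, c(15, 15, 15), 9)
  s <- StructureSet("P1", manual = list(RO1 = m, RO2 = m, RO3 = m))
  sm <- observerSummary(pairwiseMetrics(s))
  dsc_rows <- sm[sm$metric == "dsc", ]
  expect_true(all(dsc_rows$mean == 1))
  expect_true(all(dsc_rows$sd == 0))
})

test_that("one-way ANOVA matches hand computation and stats::oneway.test", {
  groups <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  res <- oneWayAnova(groups)
  expect_equal(res$statistic, 3.0)
  expect_equal(res$df, c(2, 6))
  ## independent route: stats::oneway.test on the same data
  df <- data.frame(y = unlist(groups), g = rep(letters[1:3], each = 3))
  ref <- stats::oneway.test(y ~ g, df, var.equal = TRUE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, unname(ref$p.value))

  ## F = 0 when group means coincide
  res0 <- oneWayAnova(list(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(res0$statistic, 0)

  expect_error(oneWayAnova(list(c(1, 1), c(1, 1))), class = "degenerateVarianceError")
  expect_error(oneWayAnova(list(c(1, 1), c(2, 2))), class = "degenerateVarianceError")
  expect_error(oneWayAnova(list(c(1, 2), c(3))), class = "designError")
})

test_that("ANOVA F is invariant to shift and scale of the data", {
  set.seed(8)
  groups <- lapply(1:4, function(i) rnorm(6, i * 0.3))
  f0 <- oneWayAnova(groups)$statistic
  expect_equal(oneWayAnova(lapply(groups, function(g) g + 100))$statistic, f0)
  expect_equal(oneWayAnova(lapply(groups, function(g) g * 17))$statistic, f0,
               tolerance = 1e-12)
})

test_that("Wilcoxon rank sum: exact enumeration, ties, and identical samples", {
  res <- wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 6)      # rank sum of x
  expect_equal(res$p_value, 0.1)
  expect_true(res$exact)
  orc <- oracle_wilcoxon_exact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, orc$w)
  expect_equal(res$p_value, orc$p)

  ## a lower exact-test size limit forces the approximation path
  res_lim <- wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6), exact_limit = 4)
  expect_false(res_lim$exact)

  ## identical multisets force the approximation path with p = 1
  res2 <- wilcoxonRankSum(c(1, 1, 2), c(1, 1, 2))
  expect_false(res2$exact)
  expect_equal(res2$p_value, 1)

  ## mid-ranks with ties: statistic uses mid-ranks, p stays large
  res3 <- wilcoxonRankSum(c(1, 1, 2), c(1, 2, 2))
  expect_equal(res3$statistic, sum(rank(c(1, 1, 2, 1, 2, 2))[1:3]))
  expect_gt(res3$p_value, 0.5)
})

test_that("exact and approximate Wilcoxon p agree for moderate samples", {
  set.seed(21)
  for (i in 1:20) {
    x <- round(rnorm(6, 0, 10), 4)   # continuous, no ties
    y <- round(rnorm(6, 1, 10), 4)
    exact_p <- oracle_wilcoxon_exact(x, y)$p
    approx_p <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                    correct = TRUE)$p.value)
    got <- wilcoxonRankSum(x, y)     # n = 12: enumeration path
    expect_equal(got$p_value, exact_p)
    expect_lt(abs(exact_p - approx_p), 0.02)
  }
})

test_that("size comparison produces one test per observer-multiplier pair", {
  vols <- list(RO1 = c(10, 20, 30, 25, 18, 22, 28))
  manual <- setNames(rep(vols, 6), paste0("RO", 1:6))
  auto <- list("1.5" = vols$RO1 * 2, "2" = vols$RO1, "2.5" = vols$RO1 / 2)
  res <- sizeComparison(manual, auto)
  expect_equal(nrow(res$tests), 18)
  same <- res$tests[res$tests$multiplier == "2", ]
  expect_true(all(same$p_value == 1))
  ## fully separated samples at n = 7 vs 7: exact enumeration p = 2/choose(14,7)
  auto10 <- list("2" = vols$RO1 * 10)
  res10 <- sizeComparison(vols, auto10)
  expect_equal(res10$tests$p_value, 2 / choose(14, 7))
  expect_error(sizeComparison(vols, list("2" = c(1, 2))), class = "designError")
})

test_that("cohort ANOVA under a common observer-error level is not anticonservative", {
  ## all observers share one error level, so the across-observer ANOVA should
  ## reject near (not far above) the nominal 0.05 rate despite the pooled
  ## pairwise design's shared-record correlation
  ct <- ImageGrid(c(64, 64, 24), c(1.5, 1.5, 4))
  err <- observerErrorSpec("parametric-sphere", center_jitter_sd = 3,
                           radius_jitter_sd = 1.5)
  rep_p <- vapply(1:20, function(rep) {
    dsc_by_obs <- vector("list", 6)
    for (p in 1:7) {
      t_p <- list(center = c(47, 47, 46), radius = 13 + p)
      masks <- lapply(1:6, function(o)
        simulateObserver(t_p, err, 500000 + 10000 * rep + 100 * p + o, grid = ct))
      for (i in 1:5) for (j in (i + 1):6) {
        d <- maskAgreement(masks[[i]], masks[[j]])$dsc
        dsc_by_obs[[i]] <- c(dsc_by_obs[[i]], d)
        dsc_by_obs[[j]] <- c(dsc_by_obs[[j]], d)
      }
    }
    oneWayAnova(dsc_by_obs)$p_value
  }, numeric(1))
  expect_lte(sum(rep_p < 0.05), 5)  # <= 25% over 20 null cohorts
})

test_that("metricAnova runs per metric and honours p adjustment", {
  recs <- do.call(rbind, lapply(1:3, function(p)
    pairwiseMetrics(make_structures(4, 200 + p, pid = sprintf("P%d", p),
                                    grid = ImageGrid(c(18, 18, 18), c(2, 2, 2))))))
  a <- metricAnova(recs)
  expect_equal(nrow(a), 6)
  expect_true(all(a$df1 == 3))
  expect_true(all(a$p_value >= 0 & a$p_value <= 1))
  ah <- metricAnova(recs, p_adjust = "holm")
  expect_true(all(ah$p_value >= a$p_value))
})
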