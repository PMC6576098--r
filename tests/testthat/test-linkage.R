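# Segregation classification, distortion tests, two-point estimates,
# Kosambi conversions, co-segregation bins and map summaries.

test_that("segregation types follow the parental call patterns", {
  f1 <- "F1_pseudo_testcross"
  expect_equal(classify_segregation(0, 0, f1), "non_segregating")
  expect_equal(classify_segregation(1, 0, f1), "hetxhom")
  expect_equal(classify_segregation(0, 1, f1), "homxhet")
  expect_equal(classify_segregation(1, 1, f1), "hetxhet")
  expect_equal(classify_segregation(0, 2, f1), "non_segregating")
  expect_equal(classify_segregation(NA, 1, f1), "unusable")
  expect_equal(classify_segregation(0, 2, "F2_self"), "f2_codominant")
  expect_equal(classify_segregation(2, 0, "F2_self"), "f2_codominant")
  expect_equal(classify_segregation(0, 0, "F2_self"), "non_segregating")
  expect_equal(classify_segregation(1, 2, "F2_self"), "non_segregating")
})

test_that("chi-squared distortion statistics match closed forms", {
  d0 <- distortion_test(c(35, 70, 35), "f2_codominant")
  expect_equal(d0$chisq, 0)
  expect_equal(d0$p, 1)
  expect_false(d0$distorted_0.01)
  d1 <- distortion_test(c(60, 60, 20), "f2_codominant")
  expect_equal(d1$chisq, 625 / 35 + 100 / 70 + 225 / 35, tolerance = 1e-6)
  expect_equal(d1$chisq, 25.714, tolerance = 1e-3)
  expect_true(d1$distorted_0.001)
  d2 <- distortion_test(c(50, 43), "hetxhom")
  expect_equal(d2$chisq, (50 - 46.5)^2 / 46.5 * 2, tolerance = 1e-6)
  expect_equal(d2$p, stats::pchisq(d2$chisq, 1, lower.tail = FALSE))
  expect_false(d2$distorted_0.01)
  expect_error(distortion_test(c(0, 0), "hetxhom"), "zero total")
  expect_error(distortion_test(c(10, 10), "f2_codominant"), "length")
})

test_that("null distortion p-values are uniform", {
  withr::with_seed(91, {
    counts <- stats::rmultinom(10000, 400, c(0.25, 0.5, 0.25))
    p <- apply(counts, 2, function(cn)
      distortion_test(cn, "f2_codominant")$p)
    frac <- mean(p < 0.01)
    expect_gte(frac, 0.007)
    expect_lte(frac, 0.013)
  })
})

test_that("Kosambi conversions match their closed forms and invert", {
  expect_equal(kosambi_cm(0), 0)
  expect_equal(kosambi_cm(0.25), 25 * log(3), tolerance = 1e-9)
  expect_equal(kosambi_cm(0.25), 27.465, tolerance = 1e-3)
  expect_equal(kosambi_cm(0.1), 25 * log(1.2 / 0.8), tolerance = 1e-9)
  expect_equal(kosambi_cm(0.1), 10.137, tolerance = 1e-3)
  r <- seq(0, 0.49, by = 0.01)
  expect_equal(kosambi_r(kosambi_cm(r)), r, tolerance = 1e-10)
  # strictly increasing and convex
  d <- kosambi_cm(r)
  expect_true(all(diff(d) > 0))
  expect_true(all(diff(diff(d)) > 0))
  expect_error(kosambi_cm(0.5), "< 0.5")
  expect_warning(kosambi_cm(0.5, cap = TRUE), "capped")
  expect_error(kosambi_r(-1), ">= 0")
})

test_that("two-point estimates behave at the boundaries", {
  withr::with_seed(92, {
    a <- rbinom(200, 1, 0.5)
    tp0 <- two_point(a, a, "F1_pseudo_testcross")
    expect_equal(tp0$r, 0)
    expect_gt(tp0$lod, 3)
    b <- rbinom(200, 1, 0.5)  # independent locus
    tp5 <- two_point(a, b, "F1_pseudo_testcross")
    se <- sqrt(0.25 / 200)
    expect_lt(abs(tp5$r - 0.5), 3 * se)
    expect_lt(tp5$lod, 3)
  })
  expect_error(two_point(c(0, 1), c(0, 1), "F1_pseudo_testcross"),
               "at least 10")
})

test_that("the F2 EM recovers a planted recombination fraction", {
  map <- data.frame(chrom = "1", cM = c(0, kosambi_cm(0.1)),
                    row.names = c("La", "Lb"))
  p1 <- list(h1 = c(0, 0), h2 = c(0, 0))
  p2 <- list(h1 = c(1, 1), h2 = c(1, 1))
  off <- simulate_mapping_progeny(p1, p2, "F2_self", 2000, map, seed = 93)
  tp <- two_point(off["La", ], off["Lb", ], "F2_self")
  expect_gte(tp$r, 0.08)
  expect_lte(tp$r, 0.12)
  expect_gt(tp$lod, 50)
  # repulsion phase: flipping one locus must give the same estimate
  tp_flip <- two_point(off["La", ], 2 - off["Lb", ], "F2_self")
  expect_equal(tp_flip$r, tp$r, tolerance = 1e-9)
  expect_equal(tp_flip$phase, "repulsion")
})

test_that("two-point r is consistent as progeny size grows", {
  map <- data.frame(chrom = "1", cM = c(0, kosambi_cm(0.2)),
                    row.names = c("La", "Lb"))
  p1 <- list(h1 = c(0, 0), h2 = c(0, 0))
  p2 <- list(h1 = c(1, 1), h2 = c(1, 1))
  err <- vapply(c(100, 1000, 10000), function(n) {
    off <- simulate_mapping_progeny(p1, p2, "F2_self", n, map, seed = 94)
    abs(two_point(off["La", ], off["Lb", ], "F2_self")$r - 0.2)
  }, numeric(1))
  expect_lt(err[3], 0.02)
  expect_lt(err[3], err[1] + 0.02)
})

test_that("co-segregation bins match a transitive-closure oracle", {
  withr::with_seed(95, {
    base <- matrix(rbinom(8 * 30, 2, 0.5), nrow = 8)
    g <- base[rep(1:8, length.out = 50), ]
    # phase flips and one recombinant column
    g[3, ] <- 2 - g[3, ]
    g[50, 1] <- (g[50, 1] + 1) %% 3
    rownames(g) <- sprintf("m%02d", 1:50)
    colnames(g) <- sprintf("o%02d", 1:30)
    bins <- cluster_cosegregating(g)
    # oracle: pairwise zero-recombination graph, connected components
    adj <- matrix(FALSE, 50, 50)
    for (i in 1:50) for (j in 1:50) {
      x <- g[i, ]; y <- g[j, ]
      adj[i, j] <- all(x == y) || all(x == 2 - y)
    }
    gr <- adj
    for (k in 1:50) gr <- gr | (gr[, k] %o% gr[k, ])  # transitive closure
    comp <- match(apply(gr, 1, paste, collapse = ""),
                  unique(apply(gr, 1, paste, collapse = "")))
    expect_equal(unname(bins), comp)
  })
})

test_that("duplicated and near-duplicated columns bin as expected", {
  g <- rbind(a = c(0, 1, 2, 1), b = c(0, 1, 2, 1), c = c(0, 1, 2, 2),
             d = c(2, 1, 0, 1))
  colnames(g) <- sprintf("o%d", 1:4)
  bins <- cluster_cosegregating(g)
  expect_equal(bins[["a"]], bins[["b"]])    # identical
  expect_equal(bins[["a"]], bins[["d"]])    # phase flip
  expect_false(bins[["a"]] == bins[["c"]])  # one recombinant
})

test_that("map summaries reproduce coverage, means and ratios", {
  mt <- data.frame(marker = sprintf("m%d", 1:3), lg = "A",
                   cM = c(0, 50, 100), array_snp = c(TRUE, FALSE, FALSE))
  ms <- map_summary(mt)
  expect_equal(ms$per_lg$coverage_cM, 100)
  expect_equal(ms$per_lg$mean_dist_unique_cM, 50)
  # the array-SNP ratio as printed: 1307 of 3039 markers -> 43%
  mt2 <- data.frame(marker = sprintf("m%d", 1:3039), lg = "A",
                    cM = seq(0, 1370, length.out = 3039),
                    array_snp = c(rep(TRUE, 1307), rep(FALSE, 1732)))
  expect_equal(map_summary(mt2)$total$array_ratio_pct, 43)
  # gap statistics equal a diff-and-sort oracle
  withr::with_seed(96, {
    mt3 <- data.frame(marker = sprintf("m%d", 1:40),
                      lg = rep(c("A", "B"), each = 20),
                      cM = c(sort(runif(20, 0, 80)),
                             sort(runif(20, 0, 120))))
    ms3 <- map_summary(mt3)
    for (lg in c("A", "B")) {
      pos <- sort(unique(mt3$cM[mt3$lg == lg]))
      expect_equal(ms3$gaps[[lg]], diff(pos))
      expect_equal(ms3$per_lg$coverage_cM[ms3$per_lg$lg == lg],
                   max(pos) - min(pos))
    }
  })
})
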