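# Call thresholds, call rates, panel classification, species summaries,
# replicate concordance.

test_that("score thresholds convert failing calls to missing", {
  g <- make_dosage(10, 4, seed = 51)
  calls <- matrix(1, 10, 4)
  calls[1, 1] <- 0.19   # below the call threshold
  calls[2, 2] <- 0.2    # exactly at the threshold: passes
  locus <- rep(1, 10)
  locus[3] <- 0.59      # whole locus fails
  out <- apply_call_thresholds(g, locus, calls)
  expect_true(is.na(out[1, 1]))
  expect_equal(out[2, 2], g[2, 2])
  expect_true(all(is.na(out[3, ])))
  # all scores perfect: identity
  expect_identical(apply_call_thresholds(g, rep(1, 10), matrix(1, 10, 4)),
                   g)
  expect_error(apply_call_thresholds(g, rep(1, 9)), "aligned")
})

test_that("call rate reproduces the reported one-decimal percentage", {
  g <- matrix(0, nrow = 8580, ncol = 1,
              dimnames = list(NULL, "acc1"))
  g[seq_len(8580 - 7065), 1] <- NA
  expect_equal(unname(call_rate(g, "acc1")), 82.3)
  g2 <- matrix(NA_real_, 10, 1, dimnames = list(NULL, "s"))
  expect_equal(unname(call_rate(g2, "s")), 0)
  g2[] <- 1
  expect_equal(unname(call_rate(g2, "s")), 100)
  expect_error(call_rate(g2, "nope"), "unknown")
})

test_that("panel locus classification matches a counting oracle", {
  g <- make_dosage(200, 20, missing_rate = 0.3, seed = 52)
  panel <- data.frame(sample = colnames(g), species = "sp")
  cls <- classify_panel_loci(g, panel, "sp", scorable_min_fraction = 0.75)
  for (i in seq_len(nrow(g))) {
    x <- g[i, ]
    expect_equal(cls$scorable[i], mean(!is.na(x)) >= 0.75)
    expect_equal(cls$polymorphic[i],
                 cls$scorable[i] && length(unique(x[!is.na(x)])) >= 2)
  }
})

test_that("monomorphic and all-missing loci classify as expected", {
  g <- rbind(mono = rep(0, 6), gone = rep(NA_real_, 6))
  colnames(g) <- sprintf("s%d", 1:6)
  panel <- data.frame(sample = colnames(g), species = "sp")
  cls <- classify_panel_loci(g, panel, "sp")
  expect_true(cls$scorable[1] && !cls$polymorphic[1])
  expect_false(cls$scorable[2])
  expect_error(classify_panel_loci(g, panel, "other"), "no samples")
})

test_that("dihaploid calls partition loci into three classes", {
  g <- cbind(di = c(1, NA, 0, 2), s1 = c(0, 0, 0, 0))
  rownames(g) <- c("a", "b", "c", "d")
  cls <- classify_homeologous(g, "di")
  expect_equal(unname(cls), c("homeologous", "unusable",
                              "allelic_candidate", "allelic_candidate"))
  expect_setequal(unique(cls),
                  c("homeologous", "unusable", "allelic_candidate"))
  expect_error(classify_homeologous(g, "zz"), "not in matrix")
})

test_that("raising the scorable threshold never increases scorable counts", {
  g <- make_dosage(300, 10, missing_rate = 0.25, seed = 53)
  panel <- data.frame(sample = colnames(g), species = "sp")
  n_prev <- Inf
  for (f in c(0.5, 0.75, 0.9, 1)) {
    n <- sum(classify_panel_loci(g, panel, "sp", f)$scorable)
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("species summary percentages recompute from their counts", {
  cfg <- sim_config(seed = 54, n_loci = 400, n_per_group_a = 2,
                    n_tetraploid = 5, n_f1 = 5, n_f2 = 5)
  st <- simulate_study(cfg, withr::local_tempdir())
  g <- st$masked_genotypes
  catalog <- st$catalog
  catalog$source <- rep(c("speciesA", "tetraploid"),
                        length.out = nrow(catalog))
  catalog$genic_class <- rep(c("coding", "non-coding"),
                             length.out = nrow(catalog))
  for (sp in c("speciesA", "speciesB")) {
    s <- summarize_species(g, st$panel, catalog, sp)
    expect_true(all(s$scorable <= s$synthesized))
    expect_true(all(s$polymorphic <= s$scorable))
    ok <- !is.na(s$scorable_pct)
    expect_equal(s$scorable_pct[ok],
                 pct(s$scorable, s$synthesized)[ok])
  }
  s_tet <- summarize_species(g, st$panel, catalog, "tetraploid",
                             dihaploid_id = "dihaploid")
  expect_true(all(s_tet$dihaploid_het <= s_tet$scorable))
})

test_that("a monomorphic panel reports zero polymorphism everywhere", {
  g <- matrix(0, 20, 4,
              dimnames = list(sprintf("L%02d", 1:20), sprintf("s%d", 1:4)))
  panel <- data.frame(sample = colnames(g), species = "sp")
  catalog <- data.frame(locus_id = rownames(g),
                        source = "x",
                        genic_class = rep(c("coding", "non-coding"), 10))
  s <- summarize_species(g, panel, catalog, "sp")
  expect_true(all(s$polymorphic == 0))
  expect_true(all(s$polymorphic_pct == 0, na.rm = TRUE))
})

test_that("replicate concordance excludes loci missing in either member", {
  g <- cbind(a = c(0, 1, 2, NA, 1, 0, 2, 1, 0, 1),
             b = c(0, 1, 2, 1, NA, 0, 2, 2, NA, 1))
  rownames(g) <- sprintf("L%02d", 1:10)
  panel <- data.frame(sample = c("a", "b"),
                      replicate_of = c(NA, "a"),
                      stringsAsFactors = FALSE)
  out <- replicate_concordance(g, panel)
  # 7 jointly called loci, one discordant (L08)
  expect_equal(out$n_joint, 7)
  expect_equal(out$concordance_pct, pct(6, 7))
  # identical columns give 100
  g2 <- cbind(a = c(0, 1, 2), b = c(0, 1, 2))
  expect_equal(replicate_concordance(g2, panel)$concordance_pct, 100)
  # no declared pairs -> empty report
  expect_equal(nrow(replicate_concordance(g, data.frame(sample = "a"))), 0)
})
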