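# Array-design filters against brute-force oracles, plus the filter
# algebra (idempotence, monotonicity, order invariance).

test_that("quality filter drops multiallelic, indel and low-QUAL records", {
  rec <- data.frame(
    chrom = "1", pos = c(1000L, 2000L, 3000L, 4000L, 5000L),
    ref = c("A", "C", "G", "AT", "T"),
    alt = c("G", "T,A", "A", "A", "C"),
    qual = c(60, 60, 39, 60, 40),
    stringsAsFactors = FALSE)
  out <- basic_quality_filter(rec)
  # multiallelic (2000), QUAL 39 (3000), indel (4000), QUAL == 40 (5000)
  expect_equal(out$pos, 1000L)
})

test_that("QUAL comparison is strict at the boundary", {
  rec <- data.frame(chrom = "1", pos = c(1000L, 2000L), ref = "A",
                    alt = "G", qual = c(40, 40.01))
  expect_equal(basic_quality_filter(rec)$pos, 2000L)
})

test_that("two close SNPs knock each other out by the flanking rule", {
  rec <- data.frame(chrom = "1", pos = c(1000L, 1050L), ref = "A",
                    alt = "G", qual = 60)
  expect_equal(nrow(basic_quality_filter(rec)), 0)
  rec$pos <- c(1000L, 1061L)  # 61 bp apart: flank of 60 is clean
  expect_equal(nrow(basic_quality_filter(rec)), 2)
})

test_that("quality filter matches a brute-force oracle on random input", {
  cat <- make_catalog(1000, n_chrom = 3, chrom_len = 2e5,
                      qual = c(20, 100), seed = 41)
  out <- basic_quality_filter(cat, qual_min = 40, flank_bp = 60)
  oracle <- vapply(seq_len(nrow(cat)), function(i) {
    same <- cat$chrom == cat$chrom[i]
    d <- abs(cat$pos - cat$pos[i])
    clear <- sum(same & d <= 60) == 1  # only itself within the flank
    cat$qual[i] > 40 && clear
  }, logical(1))
  expect_identical(out$locus_id, cat$locus_id[oracle])
})

test_that("unsorted or duplicated records are rejected", {
  rec <- data.frame(chrom = "1", pos = c(2000L, 1000L), ref = "A",
                    alt = "G", qual = 60)
  expect_error(basic_quality_filter(rec), "sorted")
  rec$pos <- c(1000L, 1000L)
  expect_error(basic_quality_filter(rec), "duplicated")
})

test_that("dihaploid allelic filter matches exhaustive enumeration", {
  # every genotype configuration of a dihaploid and four accessions
  states <- c(0, 1, 2, NA)
  grid <- expand.grid(di = states, a1 = states, a2 = states, a3 = states,
                      a4 = states)
  g <- as.matrix(grid)  # loci x samples: one locus per configuration
  colnames(g) <- c("di", "a1", "a2", "a3", "a4")
  rownames(g) <- sprintf("cfg%04d", seq_len(nrow(g)))
  cat <- data.frame(locus_id = rownames(g), stringsAsFactors = FALSE)
  rownames(cat) <- cat$locus_id
  out <- subgenome_allelic_filter(cat, g, "di")
  oracle <- apply(g, 1, function(x) {
    di <- x[["di"]]; acc <- x[-1]
    !is.na(di) && di != 1 &&
      sum(acc == 0, na.rm = TRUE) >= 1 && sum(acc == 2, na.rm = TRUE) >= 1
  })
  expect_identical(out$locus_id, cat$locus_id[oracle])
  # spot checks from the rule: heterozygous dihaploid is homeologous
  expect_false("cfg0002" %in% out$locus_id)  # di = 1
})

test_that("recurrence filter keeps loci with >= 2 minor-allele carriers", {
  g <- rbind(
    singleton_het = c(1, rep(0, 11)),
    two_hets      = c(1, 1, rep(0, 10)),
    one_hom_alt   = c(2, rep(0, 11)),
    common        = c(rep(2, 6), rep(0, 6)))
  colnames(g) <- sprintf("S%02d", 1:12)
  cat <- data.frame(locus_id = rownames(g), stringsAsFactors = FALSE)
  rownames(cat) <- cat$locus_id
  out <- recurrence_filter(cat, g)
  expect_identical(out$locus_id, c("two_hets", "common"))
})

test_that("recurrence filter matches a carrier-count oracle", {
  g <- make_dosage(50, 12, missing_rate = 0.05, seed = 42)
  cat <- data.frame(locus_id = rownames(g), stringsAsFactors = FALSE)
  rownames(cat) <- cat$locus_id
  out <- recurrence_filter(cat, g)
  oracle <- apply(g, 1, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(FALSE)
    alt <- sum(x); ref <- 2 * length(x) - alt
    minor <- if (alt <= ref) "alt" else "ref"
    carriers <- if (minor == "alt") sum(x > 0) else sum(x < 2)
    carriers >= 2
  })
  expect_identical(out$locus_id, rownames(g)[oracle])
})

test_that("genic annotation is 1-based inclusive at both interval ends", {
  genes <- data.frame(chrom = "1", start = 100L, end = 200L,
                      gene_id = "g1", stringsAsFactors = FALSE)
  cat <- data.frame(locus_id = c("a", "b", "c", "d", "e"), chrom = "1",
                    pos = c(99L, 100L, 150L, 200L, 201L),
                    stringsAsFactors = FALSE)
  out <- annotate_genic(cat, genes, candidate_genes = "g1")
  expect_equal(out$genic_class, c("non-coding", "coding", "coding",
                                  "coding", "non-coding"))
  expect_equal(out$candidate_gene_id,
               c(NA, "g1", "g1", "g1", NA))
})

test_that("genic annotation matches a linear-scan oracle", {
  m <- simulate_genome_model(sim_config(seed = 43, genic_fraction = 0.3))
  cat <- withr::with_seed(43, {
    ch <- sample(m$chromosomes$chrom, 1000, replace = TRUE)
    data.frame(locus_id = sprintf("L%04d", 1:1000), chrom = ch,
               pos = vapply(ch, function(c0) {
                 sample.int(m$chromosomes$length[
                   m$chromosomes$chrom == c0], 1)
               }, integer(1)), stringsAsFactors = FALSE)
  })
  out <- annotate_genic(cat, m$genes)
  oracle <- vapply(seq_len(nrow(cat)), function(i) {
    any(m$genes$chrom == cat$chrom[i] & m$genes$start <= cat$pos[i] &
          m$genes$end >= cat$pos[i])
  }, logical(1))
  expect_identical(out$genic_class == "coding", oracle)
})

test_that("spacing selection is maximal greedy on a simple instance", {
  cat <- data.frame(locus_id = c("a", "b", "c"), chrom = "1",
                    pos = c(100L, 30000L, 50000L),
                    stringsAsFactors = FALSE)
  out <- spacing_selection(cat, balance_genic = FALSE)
  expect_equal(out$locus_id, c("a", "c"))
  expect_equal(nrow(spacing_selection(cat[1, , drop = FALSE])), 1)
})

test_that("candidate-gene loci are exempt from the spacing rule", {
  cat <- data.frame(locus_id = c("a", "b"), chrom = "1",
                    pos = c(100L, 10100L),
                    genic_class = c("non-coding", "coding"),
                    candidate_gene_id = c(NA, "g9"),
                    stringsAsFactors = FALSE)
  out <- spacing_selection(cat)
  expect_setequal(out$locus_id, c("a", "b"))
  expect_equal(out$priority_class[out$locus_id == "b"], "candidate")
})

test_that("spacing invariant holds on random catalogs", {
  for (s in 1:100) {
    cat <- make_catalog(60, n_chrom = 2, chrom_len = 5e5, seed = 500 + s)
    cat$genic_class <- withr::with_seed(s, sample(c("coding", "non-coding"),
                                                  60, replace = TRUE))
    out <- spacing_selection(cat)
    for (ch in unique(out$chrom)) {
      pos <- sort(out$pos[out$chrom == ch &
                            out$priority_class != "candidate"])
      if (length(pos) > 1) expect_true(all(diff(pos) >= 40000))
    }
  }
})

test_that("filters are idempotent and order-invariant", {
  cat <- make_catalog(500, n_chrom = 2, qual = c(20, 100), seed = 44)
  f1 <- basic_quality_filter(cat)
  expect_identical(basic_quality_filter(f1[names(cat)])$locus_id,
                   f1$locus_id)
  sel1 <- spacing_selection(f1)
  sel2 <- spacing_selection(sel1[names(f1)])
  expect_identical(sel1$locus_id, sel2$locus_id)
  # shuffling rows then resorting yields the same manifest
  shuf <- withr::with_seed(9, cat[sample.int(nrow(cat)), ])
  shuf <- shuf[order(shuf$chrom, shuf$pos), ]
  expect_identical(spacing_selection(basic_quality_filter(shuf))$locus_id,
                   sel1$locus_id)
})

test_that("raising the QUAL threshold never increases the retained count", {
  cat <- make_catalog(500, qual = c(20, 100), seed = 45)
  n_prev <- Inf
  for (q in c(20, 40, 60, 80)) {
    n <- nrow(basic_quality_filter(cat, qual_min = q))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("design summary reports density and adjacent distances", {
  man <- data.frame(locus_id = sprintf("m%d", 1:10), chrom = "1",
                    pos = seq(50000L, 950000L, length.out = 10),
                    stringsAsFactors = FALSE)
  chroms <- data.frame(chrom = "1", length = 1e6)
  ds <- design_summary(man, chroms, unanchored_label = "0")
  expect_equal(ds$per_chrom$density_per_mb, 10)
  man3 <- data.frame(locus_id = c("a", "b", "c"), chrom = "1",
                     pos = c(0L, 100000L, 300000L))
  ds3 <- design_summary(man3, chroms)
  expect_equal(ds3$per_chrom$mean_dist_bp, 150000)
  # the unanchored pseudo-chromosome is excluded from genome-wide means
  man0 <- rbind(man3, data.frame(locus_id = "z", chrom = "0", pos = 1L))
  chroms0 <- rbind(chroms, data.frame(chrom = "0", length = 1e5))
  ds0 <- design_summary(man0, chroms0)
  expect_equal(ds0$genome$n_snp, 3)
  expect_equal(ds0$genome$mean_dist_bp, 150000)
})
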