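# Fixture builders shared across test files.  Everything is generated in
# code under fixed seeds; nothing is read from disk.

# Random variant catalog: sorted biallelic SNP records on `n_chrom`
# chromosomes, with optional QUAL range.
make_catalog <- function(n, n_chrom = 2, chrom_len = 1e6,
                         qual = c(41, 100), seed = 1) {
  withr::with_seed(seed, {
    chrom <- sort(sample(as.character(seq_len(n_chrom)), n, replace = TRUE))
    pos <- unlist(lapply(split(seq_len(n), chrom), function(i) {
      sort(sample.int(chrom_len, length(i)))
    }))
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                          1), "", USE.NAMES = FALSE)
    d <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                    alt = alt,
                    qual = round(stats::runif(n, qual[1], qual[2]), 1),
                    stringsAsFactors = FALSE)
    d <- d[order(d$chrom, d$pos), ]
    d$locus_id <- sprintf("L%04d", seq_len(n))
    rownames(d) <- d$locus_id
    d
  })
}

# Random dosage matrix (loci x samples) with controlled missingness.
make_dosage <- function(n_loci, n_samples, missing_rate = 0, seed = 1,
                        p = NULL) {
  withr::with_seed(seed, {
    if (is.null(p)) p <- stats::runif(n_loci, 0.1, 0.9)
    g <- matrix(stats::rbinom(n_loci * n_samples, 2, p),
                nrow = n_loci, ncol = n_samples)
    if (missing_rate > 0) {
      g[stats::runif(length(g)) < missing_rate] <- NA
    }
    dimnames(g) <- list(sprintf("L%04d", seq_len(n_loci)),
                        sprintf("S%03d", seq_len(n_samples)))
    g
  })
}

# A dosage matrix realizing exact scorable / polymorphic / dihaploid-het
# counts within one catalog cell, for accounting arithmetic checks.
# Panel: two ordinary samples (+ optional dihaploid).  Scorable loci are
# fully called; non-scorable loci fully missing.  Polymorphic loci get
# dosages 0 and 2; the dihaploid is heterozygous at `n_homeo` scorable
# monomorphic loci.
make_accounting_cell <- function(n_synth, n_scorable, n_poly,
                                 n_homeo = NULL, prefix = "X") {
  stopifnot(n_scorable <= n_synth, n_poly <= n_scorable,
            is.null(n_homeo) || n_poly + n_homeo <= n_scorable)
  with_dihaploid <- !is.null(n_homeo)
  n_samp <- if (with_dihaploid) 3 else 2
  g <- matrix(NA_real_, nrow = n_synth, ncol = n_samp)
  if (n_scorable > 0) g[seq_len(n_scorable), ] <- 0
  if (n_poly > 0) g[seq_len(n_poly), 1] <- 0 * g[seq_len(n_poly), 1]
  if (n_poly > 0) g[seq_len(n_poly), 2] <- 2
  if (with_dihaploid && n_homeo > 0) {
    g[n_poly + seq_len(n_homeo), 3] <- 1
  }
  rownames(g) <- sprintf("%s%05d", prefix, seq_len(n_synth))
  colnames(g) <- paste0(prefix, c("_s1", "_s2", "_di")[seq_len(n_samp)])
  g
}
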