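# Linkage statistics: segregation classification, distortion tests,
# two-point recombination estimates, Kosambi distances, map summaries.

#' Kosambi mapping function
#'
#' Converts a recombination fraction into a map distance allowing for
#' crossover interference: `d = 25 * ln((1 + 2r) / (1 - 2r))` cM.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @param cap if `TRUE`, values `>= 0.5` are capped at 0.499 with a
#'   warning instead of erroring (batch mode).
#' @return map distance(s) in cM.
#' @export
kosambi_cm <- function(r, cap = FALSE) {
  if (any(r < 0, na.rm = TRUE)) stop("r must be >= 0", call. = FALSE)
  if (any(r >= 0.5, na.rm = TRUE)) {
    if (!cap) stop("r must be < 0.5", call. = FALSE)
    warning("recombination fractions >= 0.5 capped at 0.499")
    r <- pmin(r, 0.499)
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi function
#'
#' @param d map distance(s) in cM.
#' @return recombination fraction(s), `0.5 * tanh(d / 50)`.
#' @export
kosambi_r <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("distance must be >= 0", call. = FALSE)
  0.5 * tanh(d / 50)
}

#' Classify the segregation type of a locus from its parental calls
#'
#' In an F1 pseudo-testcross, loci heterozygous in one parent and
#' homozygous in the other segregate 1:1; loci heterozygous in both
#' segregate 1:2:1 (codominant scoring); homozygous x homozygous loci do
#' not segregate.  In a selfed F2 only founder-divergent loci (parents
#' homozygous for different alleles, so the F1 is heterozygous) are
#' informative and segregate 1:2:1.
#'
#' @param parent1_call,parent2_call dosages in `{0, 1, 2}` or `NA`.
#' @param design `"F1_pseudo_testcross"` or `"F2_self"`.
#' @return one of `"hetxhom"`, `"homxhet"`, `"hetxhet"`, `"f2_codominant"`,
#'   `"non_segregating"`, `"unusable"` (missing parental call).
#' @export
classify_segregation <- function(parent1_call, parent2_call,
                                 design = c("F1_pseudo_testcross",
                                            "F2_self")) {
  design <- match.arg(design)
  cls1 <- function(p1, p2) {
    if (is.na(p1) || is.na(p2)) return("unusable")
    if (design == "F1_pseudo_testcross") {
      if (p1 == 1 && p2 == 1) return("hetxhet")
      if (p1 == 1) return("hetxhom")
      if (p2 == 1) return("homxhet")
      return("non_segregating")
    }
    # F2: informative loci are founder-divergent (both founders
    # homozygous for different alleles, so the selfed F1 is heterozygous);
    # a heterozygous founder call in an allotetraploid is ambiguous
    # (possibly homeologous) and is not scored
    if (p1 != 1 && p2 != 1 && p1 != p2) return("f2_codominant")
    "non_segregating"
  }
  mapply(cls1, parent1_call, parent2_call, USE.NAMES = FALSE)
}

# Mendelian expectation per segregation type (codominant scoring).
segregation_expectation <- function(type) {
  switch(type,
         hetxhom = , homxhet = c(0.5, 0.5),
         hetxhet = , f2_codominant = c(0.25, 0.5, 0.25),
         stop(sprintf("no Mendelian expectation for type '%s'", type),
              call. = FALSE))
}

#' Segregation distortion test
#'
#' Pearson chi-squared goodness-of-fit of observed progeny genotype
#' counts against the Mendelian expectation of the segregation type, with
#' `df = categories - 1` and no continuity correction.  Flags are set at
#' the conventional 0.01 and 0.001 levels.
#'
#' @param counts observed genotype counts, in dosage order (two classes
#'   for 1:1 types, three for 1:2:1).
#' @param type segregation type (see [classify_segregation()]).
#' @return list: `chisq`, `df`, `p`, `distorted_0.01`, `distorted_0.001`.
#' @export
distortion_test <- function(counts, type = "f2_codominant") {
  expected <- segregation_expectation(type)
  if (length(counts) != length(expected)) {
    stop("counts length does not match the segregation type", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) stop("zero total count", call. = FALSE)
  e <- n * expected
  chisq <- sum((counts - e)^2 / e)
  df <- length(counts) - 1L
  p <- stats::pchisq(chisq, df, lower.tail = FALSE)
  list(chisq = chisq, df = df, p = p,
       distorted_0.01 = p < 0.01, distorted_0.001 = p < 0.001)
}

# F2 codominant two-locus class probabilities for recombination fraction
# r under coupling phase.  Classes indexed [dosage A + 1, dosage B + 1].
f2_class_probs <- function(r) {
  g <- c(AB = (1 - r) / 2, Ab = r / 2, aB = r / 2, ab = (1 - r) / 2)
  dosA <- c(AB = 1, Ab = 1, aB = 0, ab = 0)
  dosB <- c(AB = 1, Ab = 0, aB = 1, ab = 0)
  p <- matrix(0, 3, 3)
  for (i in 1:4) for (j in 1:4) {
    p[dosA[i] + dosA[j] + 1, dosB[i] + dosB[j] + 1] <-
      p[dosA[i] + dosA[j] + 1, dosB[i] + dosB[j] + 1] + g[i] * g[j]
  }
  p
}

# Recombinant-gamete counts contributed by each F2 two-locus class
# (coupling phase); the double heterozygote [2,2] is ambiguous.
f2_rec_counts <- matrix(c(0, 1, 2,
                          1, NA, 1,
                          2, 1, 0), 3, 3, byrow = TRUE)

#' Two-point linkage estimate
#'
#' Estimates the recombination fraction between two loci and the LOD
#' score against independence (r = 0.5).
#'
#' For the F1 pseudo-testcross design both loci must segregate 1:1
#' (dosages 0/1); `r` is the mismatch fraction of the progeny patterns,
#' with the phase (coupling vs repulsion) chosen to give `r <= 0.5`.
#' For the F2 codominant design the maximum-likelihood estimate is
#' obtained by EM over the ambiguous double-heterozygote class, run for
#' both phases with the higher-likelihood solution returned.
#'
#' @param a,b progeny dosage vectors for the two loci (NA = missing).
#' @param design `"F1_pseudo_testcross"` or `"F2_self"`.
#' @param tol,max_iter EM convergence settings.
#' @return list: `r`, `lod`, `n` (jointly scored progeny), `phase`.
#' @export
two_point <- function(a, b, design = c("F1_pseudo_testcross", "F2_self"),
                      tol = 1e-8, max_iter = 500L) {
  design <- match.arg(design)
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 10) stop("need at least 10 jointly scored progeny", call. = FALSE)
  if (design == "F1_pseudo_testcross") {
    ua <- sort(unique(a)); ub <- sort(unique(b))
    if (length(ua) > 2 || length(ub) > 2) {
      stop("1:1 loci must show two genotype classes", call. = FALSE)
    }
    m <- mean((a == max(a)) != (b == max(b)))
    phase <- if (m <= 0.5) "coupling" else "repulsion"
    r <- min(m, 1 - m)
    nR <- round(r * n); nN <- n - nR
    lod <- nR * log10(2 * max(r, 1e-12)) + nN * log10(2 * (1 - r))
    return(list(r = r, lod = lod, n = n, phase = phase))
  }
  counts <- table(factor(a, 0:2), factor(b, 0:2))
  fit1 <- f2_em(counts, tol, max_iter)
  fit2 <- f2_em(counts[, 3:1], tol, max_iter)  # repulsion: flip locus b
  fit <- if (fit1$loglik >= fit2$loglik) c(fit1, phase = "coupling") else
    c(fit2, phase = "repulsion")
  p0 <- f2_class_probs(0.5)
  ll0 <- sum(counts[counts > 0] * log(p0[counts > 0]))
  list(r = fit$r, lod = (fit$loglik - ll0) / log(10), n = n,
       phase = fit$phase)
}

# EM for the F2 codominant recombination fraction (coupling phase
# assumed for the given count orientation).
f2_em <- function(counts, tol = 1e-8, max_iter = 500L) {
  n <- sum(counts)
  known <- sum(counts * f2_rec_counts, na.rm = TRUE)
  n11 <- counts[2, 2]
  r <- 0.25
  for (it in seq_len(max_iter)) {
    w <- r^2 / (r^2 + (1 - r)^2)       # P(double recombinant | double het)
    r_new <- (known + n11 * 2 * w) / (2 * n)
    r_new <- min(max(r_new, 1e-9), 0.5)
    if (abs(r_new - r) < tol) { r <- r_new; break }
    r <- r_new
  }
  p <- f2_class_probs(r)
  list(r = r, loglik = sum(counts[counts > 0] * log(p[counts > 0])))
}

#' Group co-segregating markers into unique map positions
#'
#' Markers whose informative progeny patterns show zero observed
#' recombinants (identical over jointly scored progeny, up to a phase
#' flip `dosage -> 2 - dosage`) are merged into one position bin by
#' transitive closure.
#'
#' @param geno progeny dosage matrix (loci x progeny).
#' @return integer vector of bin ids, named by locus.
#' @export
cluster_cosegregating <- function(geno) {
  check_dosage(geno)
  n <- nrow(geno)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      x <- geno[i, ]; y <- geno[j, ]
      keep <- !is.na(x) & !is.na(y)
      if (!any(keep)) next
      same <- all(x[keep] == y[keep]) || all(x[keep] == 2 - y[keep])
      if (same) parent[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  bins <- match(roots, unique(roots))
  names(bins) <- rownames(geno)
  bins
}

#' Summarize a genetic map
#'
#' Per linkage group: marker count, array-SNP count and ratio, coverage
#' (max - min position), number of unique positions, mean adjacent
#' distance over all markers and over unique positions, and the list of
#' gaps between adjacent unique positions.  The ratio and mean distances
#' are also reported over all groups.
#'
#' @param map_table data frame: `marker`, `lg`, `cM`, and optional logical
#'   `array_snp` flagging markers that come from the designed array.
#' @return list of class `map_summary` with a per-LG data frame
#'   (`per_lg`), per-LG gap lists (`gaps`), and `total`.
#' @export
map_summary <- function(map_table) {
  stopifnot(all(c("marker", "lg", "cM") %in% names(map_table)))
  if (is.null(map_table$array_snp)) map_table$array_snp <- FALSE
  lgs <- unique(map_table$lg)
  gaps <- list()
  rows <- lapply(lgs, function(lg) {
    d <- map_table[map_table$lg == lg, ]
    d <- d[order(d$cM), ]
    upos <- unique(d$cM)
    g <- diff(upos)
    gaps[[as.character(lg)]] <<- g
    data.frame(
      lg = lg, n_markers = nrow(d), n_array_snp = sum(d$array_snp),
      array_ratio_pct = pct(sum(d$array_snp), nrow(d), 0),
      coverage_cM = max(d$cM) - min(d$cM),
      n_unique_pos = length(upos),
      mean_dist_all_cM = if (nrow(d) > 1)
        (max(d$cM) - min(d$cM)) / (nrow(d) - 1) else NA_real_,
      mean_dist_unique_cM = if (length(upos) > 1) mean(g) else NA_real_,
      max_gap_cM = if (length(g)) max(g) else NA_real_,
      stringsAsFactors = FALSE)
  })
  per_lg <- do.call(rbind, rows)
  all_gaps <- unlist(gaps)
  total <- data.frame(
    n_markers = sum(per_lg$n_markers),
    n_array_snp = sum(per_lg$n_array_snp),
    array_ratio_pct = pct(sum(per_lg$n_array_snp), sum(per_lg$n_markers), 0),
    coverage_cM = sum(per_lg$coverage_cM),
    n_unique_pos = sum(per_lg$n_unique_pos),
    mean_dist_all_cM = sum(per_lg$coverage_cM) /
      (sum(per_lg$n_markers) - length(lgs)),
    mean_dist_unique_cM = mean(all_gaps),
    pct_gaps_below_2cM = pct(sum(all_gaps < 2), length(all_gaps), 0),
    max_gap_cM = max(all_gaps))
  structure(list(per_lg = per_lg, gaps = gaps, total = total),
            class = "map_summary")
}

#' @export
print.map_summary <- function(x, ...) {
  print(x$per_lg, row.names = FALSE)
  cat(sprintf("TOTAL: %d markers (%d array SNPs, %s%%), %.0f cM, mean unique-position gap %.2f cM\n",
              x$total$n_markers, x$total$n_array_snp,
              x$total$array_ratio_pct, x$total$coverage_cM,
              x$total$mean_dist_unique_cM))
  invisible(x)
}
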