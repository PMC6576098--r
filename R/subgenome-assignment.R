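# Subgenome assignment: haploid downscaling + identity-by-state distances
# between an allotetraploid's accessions and candidate progenitor
# individuals.

#' Loci called in every sample of two sets
#'
#' @param genotypes dosage matrix (loci x samples).
#' @param query_set,reference_set sample id vectors.
#' @return character vector of locus ids with no missing call in either
#'   set.
#' @export
shared_complete_loci <- function(genotypes, query_set, reference_set) {
  ids <- c(query_set, reference_set)
  if (!length(query_set) || !length(reference_set)) {
    stop("both sample sets must be non-empty", call. = FALSE)
  }
  missing_ids <- setdiff(ids, colnames(genotypes))
  if (length(missing_ids)) {
    stop(sprintf("samples not in matrix: %s",
                 paste(missing_ids, collapse = ", ")), call. = FALSE)
  }
  g <- genotypes[, ids, drop = FALSE]
  keep <- rowSums(is.na(g)) == 0
  if (!any(keep)) stop("no shared loci without missing data", call. = FALSE)
  rownames(genotypes)[keep]
}

#' Draw one haploid genotype from a diploid (or collapsed tetraploid) call
#'
#' Dosage 0 gives allele 0, dosage 2 gives allele 1, and a heterozygous
#' call contributes a fair Bernoulli draw.  The random stream is keyed by
#' `(seed, run, sample_id)`, so a draw is reproducible in isolation and
#' unaffected by which other samples are drawn.
#'
#' @param genotype_vector dosages in `{0, 1, 2}` (no missing).
#' @param seed integer seed.
#' @param run run index.
#' @param sample_id sample identifier used in the stream key.
#' @return 0/1 haploid vector.
#' @export
draw_haploid <- function(genotype_vector, seed = 1L, run = 1L,
                         sample_id = "sample") {
  if (anyNA(genotype_vector)) {
    stop("missing dosage in the complete-locus set", call. = FALSE)
  }
  if (!all(genotype_vector %in% c(0, 1, 2))) {
    stop("dosages must be 0, 1 or 2", call. = FALSE)
  }
  out <- genotype_vector / 2
  het <- genotype_vector == 1
  if (any(het)) {
    out[het] <- with_seed(substream_seed(seed, run, sample_id),
                          stats::rbinom(sum(het), 1, 0.5))
  }
  out
}

#' Identity-by-state distance between two haploid vectors
#'
#' @param haploid_a,haploid_b 0/1 vectors of equal length, no missing.
#' @return the fraction of loci at which the alleles differ.
#' @export
ibs_distance <- function(haploid_a, haploid_b) {
  if (length(haploid_a) != length(haploid_b)) {
    stop("haploid vectors must have equal length", call. = FALSE)
  }
  if (!length(haploid_a)) stop("zero loci", call. = FALSE)
  if (anyNA(haploid_a) || anyNA(haploid_b)) {
    stop("haploid vectors must have no missing values", call. = FALSE)
  }
  mean(haploid_a != haploid_b)
}

#' Assign an allotetraploid subgenome to progenitor populations
#'
#' Implements the haploid-downscaling IBS procedure: over `n_runs` runs,
#' a haploid genotype is drawn for every query and reference accession
#' (heterozygous calls resolved by a fair coin keyed per run and sample),
#' pairwise IBS distances are computed on the shared complete-locus set,
#' distances are averaged over runs for each query, and finally the mean
#' and standard deviation over all queries are reported per reference
#' individual, together with group-level aggregates (unweighted mean over
#' the group's individuals).  References are ranked by ascending mean
#' IBS: the top-ranked individual/group is the closest present-day
#' relative of the subgenome the queries carry.
#'
#' @param genotypes dosage matrix (loci x samples).
#' @param queries query (allotetraploid) sample ids.
#' @param references_by_group named list: group label -> reference sample
#'   ids.
#' @param admixed reference sample ids to exclude (individuals with mixed
#'   ancestry are not meaningful single-population references).
#' @param n_runs number of haploid-downscaling runs (default 200).
#' @param seed integer seed.
#' @param downscale_references also downscale heterozygous reference
#'   genotypes (default); if `FALSE` only queries are downscaled and
#'   reference heterozygotes contribute half a mismatch in expectation.
#' @return list of class `assignment_report`: `pair` (query x reference
#'   mean IBS), `by_reference` (mean, sd over queries, rank), `by_group`,
#'   `loci_used`.
#' @export
assign_subgenome <- function(genotypes, queries, references_by_group,
                             admixed = character(), n_runs = 200L,
                             seed = 1L, downscale_references = TRUE) {
  if (n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  references_by_group <- lapply(references_by_group, setdiff, y = admixed)
  references_by_group <-
    references_by_group[lengths(references_by_group) > 0]
  refs <- unlist(references_by_group, use.names = FALSE)
  group_of <- rep(names(references_by_group),
                  lengths(references_by_group))
  loci <- shared_complete_loci(genotypes, queries, refs)
  gq <- genotypes[loci, queries, drop = FALSE]
  gr <- genotypes[loci, refs, drop = FALSE]
  L <- length(loci)
  acc <- matrix(0, nrow = length(queries), ncol = length(refs),
                dimnames = list(queries, refs))
  for (run in seq_len(n_runs)) {
    hq <- vapply(queries, function(s)
      draw_haploid(gq[, s], seed, run, s), numeric(L))
    hr <- if (downscale_references) {
      vapply(refs, function(s)
        draw_haploid(gr[, s], seed, run, s), numeric(L))
    } else {
      gr / 2  # expectation: heterozygote contributes allele frequency 1/2
    }
    # mismatch fraction for all query x reference pairs at once
    acc <- acc + (crossprod(hq, 1 - hr) + crossprod(1 - hq, hr)) / L
  }
  pair <- acc / n_runs
  by_ref <- data.frame(
    reference = refs, group = group_of,
    mean_ibs = colMeans(pair),
    sd_ibs = apply(pair, 2, stats::sd),
    row.names = NULL, stringsAsFactors = FALSE)
  by_ref$rank <- rank(by_ref$mean_ibs, ties.method = "first")
  by_ref <- by_ref[order(by_ref$rank), ]
  grp_mean <- tapply(by_ref$mean_ibs, by_ref$group, mean)
  by_group <- data.frame(group = names(grp_mean),
                         mean_ibs = as.numeric(grp_mean),
                         row.names = NULL, stringsAsFactors = FALSE)
  by_group <- by_group[order(by_group$mean_ibs), ]
  by_group$rank <- seq_len(nrow(by_group))
  structure(list(pair = pair, by_reference = by_ref, by_group = by_group,
                 loci_used = loci, n_runs = n_runs),
            class = "assignment_report")
}

#' @export
print.assignment_report <- function(x, ...) {
  cat(sprintf("Subgenome assignment over %d loci, %d runs, %d queries\n",
              length(x$loci_used), x$n_runs, nrow(x$pair)))
  cat("Closest reference individuals (mean +/- SD IBS over queries):\n")
  top <- utils::head(x$by_reference, 5)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %d. %s [%s]  %.4f +/- %.4f\n", top$rank[i],
                top$reference[i], top$group[i], top$mean_ibs[i],
                top$sd_ibs[i]))
  }
  cat("Group ranking:",
      paste(x$by_group$group, collapse = " < "), "\n")
  invisible(x)
}
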