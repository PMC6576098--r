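# Diversity analytics: LD decay and neighbour-joining trees with
# block-bootstrap support.

#' Filter loci for LD estimation
#'
#' Retains biallelic loci with minor allele frequency strictly above
#' `maf_min`, missing fraction strictly below `max_missing`, and not on
#' the virtual unanchored pseudo-chromosome.
#'
#' @param genotypes dosage matrix (loci x samples).
#' @param catalog catalog supplying `locus_id` and `chrom`.
#' @param maf_min MAF threshold (strict).
#' @param max_missing missing-fraction threshold (strict).
#' @param unanchored_label chromosome label to exclude.
#' @return the filtered dosage matrix.
#' @export
ld_filter <- function(genotypes, catalog, maf_min = 0.10,
                      max_missing = 0.10, unanchored_label = "0") {
  check_dosage(genotypes)
  idx <- match(rownames(genotypes), catalog$locus_id)
  chrom <- catalog$chrom[idx]
  called <- rowSums(!is.na(genotypes))
  alt <- rowSums(genotypes, na.rm = TRUE)
  af <- ifelse(called > 0, alt / (2 * called), NA)
  maf <- pmin(af, 1 - af)
  miss <- (ncol(genotypes) - called) / ncol(genotypes)
  keep <- !is.na(maf) & maf > maf_min & miss < max_missing &
    !is.na(chrom) & chrom != unanchored_label
  genotypes[keep, , drop = FALSE]
}

#' Pairwise r-squared within a distance window
#'
#' For every same-chromosome locus pair within `max_dist_bp`, the squared
#' Pearson correlation of the dosage vectors over jointly non-missing
#' samples (composite LD on unphased genotypes).  Pairs where either
#' locus has zero variance over the joint samples are skipped.
#'
#' @param genotypes filtered dosage matrix (loci x samples).
#' @param catalog catalog supplying `locus_id`, `chrom`, `pos`.
#' @param max_dist_bp maximum pair distance.
#' @return data frame: `locus_a`, `locus_b`, `dist_bp`, `r2`.
#' @export
pairwise_r2 <- function(genotypes, catalog, max_dist_bp = 100000) {
  if (nrow(genotypes) < 2) {
    return(data.frame(locus_a = character(), locus_b = character(),
                      dist_bp = numeric(), r2 = numeric()))
  }
  idx <- match(rownames(genotypes), catalog$locus_id)
  chrom <- catalog$chrom[idx]; pos <- catalog$pos[idx]
  ord <- order(chrom, pos)
  genotypes <- genotypes[ord, , drop = FALSE]
  chrom <- chrom[ord]; pos <- pos[ord]
  out <- list()
  for (ch in unique(chrom)) {
    ii <- which(chrom == ch)
    if (length(ii) < 2) next
    for (k in seq_len(length(ii) - 1)) {
      i <- ii[k]
      for (j in ii[(k + 1):length(ii)]) {
        d <- pos[j] - pos[i]
        if (d > max_dist_bp) break
        x <- genotypes[i, ]; y <- genotypes[j, ]
        joint <- !is.na(x) & !is.na(y)
        if (sum(joint) < 2) next
        x <- x[joint]; y <- y[joint]
        if (stats::var(x) == 0 || stats::var(y) == 0) next
        out[[length(out) + 1L]] <- data.frame(
          locus_a = rownames(genotypes)[i],
          locus_b = rownames(genotypes)[j],
          dist_bp = d, r2 = stats::cor(x, y)^2,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(locus_a = character(), locus_b = character(),
                      dist_bp = numeric(), r2 = numeric()))
  }
  do.call(rbind, out)
}

#' LD decay curve and half-decay distance
#'
#' Bins pair records by distance, averages r-squared per bin, and finds
#' the half-decay distance: the smallest distance at which the binned
#' mean falls to half the maximum binned mean, linearly interpolated
#' between the straddling bin midpoints.  When the curve never crosses
#' half-maximum the distance is `NA` and flagged.
#'
#' @param records output of [pairwise_r2()].
#' @param bin_width_bp distance bin width (default 1 kb).
#' @return list of class `ld_decay`: `curve` (data frame `mid_bp`,
#'   `mean_r2`, `n_pairs`), `max_r2`, `half_decay_bp`, `crossed` flag.
#' @export
decay_curve <- function(records, bin_width_bp = 1000) {
  if (!nrow(records)) stop("no LD records", call. = FALSE)
  bin <- floor(records$dist_bp / bin_width_bp)
  mids <- (sort(unique(bin)) + 0.5) * bin_width_bp
  agg <- tapply(records$r2, bin, mean)
  npairs <- tapply(records$r2, bin, length)
  curve <- data.frame(mid_bp = mids, mean_r2 = as.numeric(agg),
                      n_pairs = as.integer(npairs))
  maxr <- max(curve$mean_r2)
  half <- maxr / 2
  below <- which(curve$mean_r2 <= half)
  if (!length(below) || maxr == 0) {
    return(structure(list(curve = curve, max_r2 = maxr,
                          half_decay_bp = NA_real_, crossed = FALSE),
                     class = "ld_decay"))
  }
  j <- below[1]
  if (j == 1) {
    hd <- curve$mid_bp[1]
  } else {
    x0 <- curve$mid_bp[j - 1]; x1 <- curve$mid_bp[j]
    y0 <- curve$mean_r2[j - 1]; y1 <- curve$mean_r2[j]
    hd <- x0 + (y0 - half) / (y0 - y1) * (x1 - x0)
  }
  structure(list(curve = curve, max_r2 = maxr, half_decay_bp = hd,
                 crossed = TRUE), class = "ld_decay")
}

#' @export
print.ld_decay <- function(x, ...) {
  cat(sprintf("LD decay over %d bins; max mean r2 = %.3f; half-decay = %s\n",
              nrow(x$curve), x$max_r2,
              if (x$crossed) sprintf("%.0f bp", x$half_decay_bp)
              else "not reached"))
  invisible(x)
}

#' Euclidean distance matrix between genotypes
#'
#' Distances over loci with no missing data across the sample set (the
#' default), or over all loci with pairwise-complete observations.
#'
#' @param genotypes dosage matrix (loci x samples).
#' @param complete_loci_only drop loci with any missing call first.
#' @return a symmetric `matrix` of Euclidean distances.
#' @export
euclidean_distance_matrix <- function(genotypes, complete_loci_only = TRUE) {
  check_dosage(genotypes)
  if (ncol(genotypes) < 2) stop("need at least two samples", call. = FALSE)
  if (complete_loci_only) {
    genotypes <- genotypes[stats::complete.cases(genotypes), , drop = FALSE]
    if (!nrow(genotypes)) {
      stop("no loci without missing data", call. = FALSE)
    }
  }
  as.matrix(stats::dist(t(genotypes)))
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou--Nei agglomeration; negative branch lengths, which NJ
#' can produce on noisy distances, are clamped to zero with the deficit
#' transferred to the adjacent edge.
#'
#' @param distances symmetric distance matrix with sample names.
#' @return an [ape::nj()] `phylo` tree.
#' @export
nj_tree <- function(distances) {
  distances <- as.matrix(distances)
  if (!isSymmetric(unname(distances), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (nrow(distances) < 3) stop("need at least three samples", call. = FALSE)
  tree <- ape::nj(as.dist(distances))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    # standard post-hoc fix: move the negative length to the sibling edge
    for (e in which(neg)) {
      parent <- tree$edge[e, 1]
      sib <- which(tree$edge[, 1] == parent & seq_along(neg) != e)
      if (length(sib)) {
        tree$edge.length[sib[1]] <- tree$edge.length[sib[1]] +
          tree$edge.length[e]
      }
      tree$edge.length[e] <- 0
    }
  }
  tree
}

#' Block-bootstrap support for a neighbour-joining tree
#'
#' Loci are partitioned in genome order into consecutive blocks of
#' `block_snps` (the trailing partial block is kept); each bootstrap
#' replicate resamples blocks with replacement up to the original block
#' count, rebuilds the distance matrix and NJ tree, and support is the
#' percentage of replicates containing each internal bipartition of the
#' reference tree.
#'
#' @param genotypes dosage matrix (loci x samples) in genome order.
#' @param n_boot number of bootstrap replicates (0 = reference tree only).
#' @param block_snps block size in SNPs.
#' @param seed integer seed.
#' @param complete_loci_only passed to [euclidean_distance_matrix()].
#' @return the reference `phylo` tree with `node.label` support values
#'   (0--100; root label empty).
#' @export
block_bootstrap_support <- function(genotypes, n_boot = 100,
                                    block_snps = 100, seed = 1L,
                                    complete_loci_only = TRUE) {
  check_dosage(genotypes)
  if (nrow(genotypes) < block_snps) {
    stop("fewer loci than one block", call. = FALSE)
  }
  ref <- nj_tree(euclidean_distance_matrix(genotypes, complete_loci_only))
  if (n_boot == 0) return(ref)
  blocks <- split(seq_len(nrow(genotypes)),
                  (seq_len(nrow(genotypes)) - 1) %/% block_snps)
  counts <- with_seed(substream_seed(seed, 6L, "bootstrap"), {
    trees <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
      take <- sample.int(length(blocks), length(blocks), replace = TRUE)
      g <- genotypes[unlist(blocks[take]), , drop = FALSE]
      trees[[b]] <- nj_tree(euclidean_distance_matrix(g,
                                                      complete_loci_only))
    }
    ape::prop.clades(ref, trees, rooted = FALSE)
  })
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_boot)
  support[1] <- NA  # root "bipartition" is not meaningful for unrooted NJ
  ref$node.label <- ifelse(is.na(support), "", as.character(support))
  ref
}
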