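# Array design: the SNP selection workflow from raw variant calls to the
# array manifest.

#' Basic quality filter for candidate array SNPs
#'
#' Retains biallelic SNPs (single-base ref and alt) with QUAL strictly
#' above `qual_min` and no other variant call within `flank_bp` on either
#' side (so the probe flanking sequence carries no variation).  The
#' flanking test is made against *all* input variant positions, including
#' records that themselves fail the quality or biallelic criteria.
#'
#' @param records data frame of variant records sorted by chromosome and
#'   position: `chrom`, `pos`, `ref`, `alt` (comma-separated if
#'   multiallelic), `qual`, and optionally `locus_id`.
#' @param qual_min QUAL threshold (strict; the boundary value fails).
#' @param flank_bp required variant-free flank on each side.
#' @return the retained records, with a `filters_passed` provenance column.
#' @export
basic_quality_filter <- function(records, qual_min = 40, flank_bp = 60) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "qual") %in% names(records)))
  # chromosomes must form contiguous blocks with increasing positions
  blocks <- rle(records$chrom)$values
  same <- c(FALSE, records$chrom[-1] == records$chrom[-nrow(records)])
  if (anyDuplicated(blocks) ||
      any(diff(records$pos)[same[-1]] < 0)) {
    stop("records must be sorted by chromosome and position", call. = FALSE)
  }
  if (anyDuplicated(records[, c("chrom", "pos")])) {
    stop("duplicated (chrom, pos) in input records", call. = FALSE)
  }
  is_snp <- !grepl(",", records$alt) & nchar(records$ref) == 1 &
    nchar(records$alt) == 1 & records$ref %in% c("A", "C", "G", "T") &
    records$alt %in% c("A", "C", "G", "T")
  hi_qual <- !is.na(records$qual) & records$qual > qual_min
  # neighbour distances within chromosome (against every variant record)
  prev_ok <- rep(TRUE, nrow(records)); next_ok <- rep(TRUE, nrow(records))
  same_prev <- c(FALSE, records$chrom[-1] == records$chrom[-nrow(records)])
  d_prev <- c(NA, diff(records$pos))
  prev_ok[same_prev & d_prev <= flank_bp] <- FALSE
  same_next <- c(same_prev[-1], FALSE)
  d_next <- c(diff(records$pos), NA)
  next_ok[same_next & d_next <= flank_bp] <- FALSE
  keep <- is_snp & hi_qual & prev_ok & next_ok
  out <- records[keep, , drop = FALSE]
  if (nrow(out)) out$filters_passed <- "qual+biallelic+flank"
  out
}

#' Dihaploid-based allelic filter for tetraploid-derived SNPs
#'
#' In an allotetraploid, a SNP heterozygous in the dihaploid reflects a
#' fixed difference between the two subgenomes (homeologous
#' polymorphism), not allelic variation.  This filter keeps loci where
#' (i) the dihaploid call is homozygous (heterozygous-or-missing calls
#' are removed) and (ii) at least two panel accessions are homozygous for
#' different alleles, so the locus is a true within-subgenome codominant
#' marker.
#'
#' @param catalog variant catalog (rows must be named by `locus_id`).
#' @param genotypes dosage matrix (loci x samples) covering the catalog.
#' @param dihaploid_id column name of the dihaploid sample.
#' @param accession_ids columns to scan for condition (ii); defaults to
#'   all samples except the dihaploid.
#' @return the retained catalog rows.
#' @export
subgenome_allelic_filter <- function(catalog, genotypes, dihaploid_id,
                                     accession_ids = NULL) {
  if (!dihaploid_id %in% colnames(genotypes)) {
    stop(sprintf("dihaploid sample '%s' not in genotype matrix",
                 dihaploid_id), call. = FALSE)
  }
  check_dosage(genotypes)
  if (is.null(accession_ids)) {
    accession_ids <- setdiff(colnames(genotypes), dihaploid_id)
  }
  g <- genotypes[catalog$locus_id, , drop = FALSE]
  di <- g[, dihaploid_id]
  acc <- g[, accession_ids, drop = FALSE]
  hom_ref <- rowSums(acc == 0, na.rm = TRUE)
  hom_alt <- rowSums(acc == 2, na.rm = TRUE)
  keep <- !is.na(di) & di != 1 & hom_ref >= 1 & hom_alt >= 1
  out <- catalog[keep, , drop = FALSE]
  if (nrow(out)) {
    out$filters_passed <- paste0(out$filters_passed, "+dihaploid_allelic")
  }
  out
}

#' Minor-allele recurrence filter
#'
#' Keeps loci whose minor allele is carried by at least `min_recurrence`
#' distinct genotypes in the panel (a carrier counts once whether
#' heterozygous or homozygous), screening out rare and
#' individual-specific alleles.
#'
#' @param catalog variant catalog.
#' @param genotypes dosage matrix (loci x samples).
#' @param min_recurrence minimum number of distinct carriers (default 2).
#' @return the retained catalog rows.
#' @export
recurrence_filter <- function(catalog, genotypes, min_recurrence = 2L) {
  check_dosage(genotypes)
  if (ncol(genotypes) < min_recurrence) {
    stop("panel smaller than the recurrence threshold", call. = FALSE)
  }
  g <- genotypes[catalog$locus_id, , drop = FALSE]
  alt_cnt <- rowSums(g, na.rm = TRUE)
  called <- rowSums(!is.na(g))
  minor_is_alt <- alt_cnt <= 2 * called - alt_cnt
  carriers_alt <- rowSums(g > 0, na.rm = TRUE)
  carriers_ref <- rowSums(g < 2, na.rm = TRUE)
  carriers <- ifelse(minor_is_alt, carriers_alt, carriers_ref)
  keep <- called > 0 & carriers >= min_recurrence
  out <- catalog[keep, , drop = FALSE]
  if (nrow(out)) {
    out$filters_passed <- paste0(out$filters_passed, "+recurrence")
  }
  out
}

#' Annotate catalog loci as coding or non-coding
#'
#' Labels a locus `coding` when its position falls inside a gene interval
#' (1-based, inclusive at both ends) and `non-coding` otherwise, and tags
#' loci inside candidate genes.
#'
#' @param catalog variant catalog (`chrom`, `pos`).
#' @param genes gene intervals: data frame `chrom`, `start`, `end`,
#'   `gene_id` (e.g. from [read_gff_genes()] or a genome model).
#' @param candidate_genes character vector of candidate gene ids.
#' @return the catalog with `genic_class`, `gene_id` and
#'   `candidate_gene_id` columns.
#' @export
annotate_genic <- function(catalog, genes, candidate_genes = character()) {
  bad <- setdiff(unique(genes$chrom), unique(catalog$chrom))
  # genes on chromosomes absent from the catalog are legitimate; the
  # reverse check guards against chromosome naming mismatches
  if (nrow(genes) && !any(genes$chrom %in% catalog$chrom) &&
      nrow(catalog) > 0) {
    stop("GFF and catalog share no chromosome names", call. = FALSE)
  }
  snp_gr <- GenomicRanges::GRanges(catalog$chrom,
                                   IRanges::IRanges(catalog$pos,
                                                    catalog$pos))
  catalog$genic_class <- "non-coding"
  catalog$gene_id <- NA_character_
  catalog$candidate_gene_id <- NA_character_
  if (nrow(genes)) {
    gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                      IRanges::IRanges(genes$start,
                                                       genes$end))
    hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr, select = "first")
    inside <- !is.na(hits)
    catalog$genic_class[inside] <- "coding"
    catalog$gene_id[inside] <- genes$gene_id[hits[inside]]
    is_cand <- catalog$gene_id %in% candidate_genes
    catalog$candidate_gene_id[is_cand] <- catalog$gene_id[is_cand]
  }
  catalog
}

#' Spacing-constrained marker selection
#'
#' Greedy left-to-right selection per chromosome: every pair of retained
#' non-candidate loci is at least `min_spacing_bp` apart.  Candidate-gene
#' loci are force-included and exempt from the spacing rule.  To approach
#' the target genic/non-genic parity, the scan keeps, among the loci
#' eligible after the spacing constraint within a one-window lookahead,
#' the first locus of whichever genic class is currently
#' under-represented; when none exists the first eligible locus is taken.
#' The procedure is deterministic, ties broken toward the lower
#' coordinate.
#'
#' @param catalog annotated variant catalog (`chrom`, `pos`,
#'   `genic_class`, `candidate_gene_id`).
#' @param min_spacing_bp minimum distance between retained non-candidate
#'   loci (default 40 kb).
#' @param balance_genic balance coding/non-coding counts while scanning.
#' @return an `array_manifest`: the selected catalog rows, position
#'   sorted, with a `priority_class` column (`candidate`, `spacing`).
#' @export
spacing_selection <- function(catalog, min_spacing_bp = 40000,
                              balance_genic = TRUE) {
  if (nrow(catalog) == 0) {
    return(structure(cbind(catalog, priority_class = character(0)),
                     class = c("array_manifest", "data.frame")))
  }
  if (is.null(catalog$genic_class)) catalog$genic_class <- "non-coding"
  if (is.null(catalog$candidate_gene_id)) {
    catalog$candidate_gene_id <- NA_character_
  }
  catalog <- catalog[order(catalog$chrom, catalog$pos), , drop = FALSE]
  is_cand <- !is.na(catalog$candidate_gene_id)
  n_coding <- sum(is_cand & catalog$genic_class == "coding")
  n_noncod <- sum(is_cand & catalog$genic_class != "coding")
  picked <- is_cand
  for (ch in unique(catalog$chrom)) {
    idx <- which(catalog$chrom == ch & !is_cand)
    last <- -Inf
    while (length(idx)) {
      eligible <- idx[catalog$pos[idx] >= last + min_spacing_bp]
      if (!length(eligible)) break
      chosen <- eligible[1]
      if (balance_genic && n_coding != n_noncod) {
        want <- if (n_coding < n_noncod) "coding" else "non-coding"
        window <- eligible[catalog$pos[eligible] <
                             catalog$pos[eligible[1]] + min_spacing_bp]
        pref <- window[catalog$genic_class[window] == want]
        if (length(pref)) chosen <- pref[1]
      }
      picked[chosen] <- TRUE
      if (catalog$genic_class[chosen] == "coding") {
        n_coding <- n_coding + 1
      } else {
        n_noncod <- n_noncod + 1
      }
      last <- catalog$pos[chosen]
      idx <- idx[catalog$pos[idx] >= last + min_spacing_bp]
    }
  }
  out <- catalog[picked, , drop = FALSE]
  out$priority_class <- ifelse(!is.na(out$candidate_gene_id),
                               "candidate", "spacing")
  structure(out, class = c("array_manifest", "data.frame"))
}

#' Per-chromosome design report
#'
#' Marker count, density (SNPs/Mb) and mean adjacent inter-marker
#' distance per chromosome; the genome-wide means exclude the virtual
#' unanchored pseudo-chromosome (label `"0"`).
#'
#' @param manifest an [spacing_selection()] manifest.
#' @param model a genome model supplying chromosome lengths, or a data
#'   frame `chrom`, `length`.
#' @param unanchored_label chromosome label excluded from genome-wide
#'   summaries.
#' @return list with `per_chrom` (data frame) and `genome` (density,
#'   mean distance over anchored chromosomes).
#' @export
design_summary <- function(manifest, model, unanchored_label = "0") {
  if (nrow(manifest) == 0) stop("empty manifest", call. = FALSE)
  chroms <- if (inherits(model, "genome_model")) model$chromosomes else model
  rows <- lapply(seq_len(nrow(chroms)), function(i) {
    ch <- chroms$chrom[i]
    pos <- sort(manifest$pos[manifest$chrom == ch])
    data.frame(chrom = ch, length_bp = chroms$length[i], n_snp = length(pos),
               density_per_mb = length(pos) / (chroms$length[i] / 1e6),
               mean_dist_bp = if (length(pos) > 1) mean(diff(pos))
               else NA_real_,
               stringsAsFactors = FALSE)
  })
  per_chrom <- do.call(rbind, rows)
  anchored <- per_chrom$chrom != unanchored_label
  keep <- manifest$chrom != unanchored_label
  dists <- unlist(lapply(unique(manifest$chrom[keep]), function(ch) {
    diff(sort(manifest$pos[manifest$chrom == ch]))
  }))
  genome <- data.frame(
    n_snp = sum(per_chrom$n_snp[anchored]),
    density_per_mb = sum(per_chrom$n_snp[anchored]) /
      (sum(per_chrom$length_bp[anchored]) / 1e6),
    mean_dist_bp = if (length(dists)) mean(dists) else NA_real_)
  list(per_chrom = per_chrom, genome = genome)
}
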