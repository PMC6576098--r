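# Genotyping QC: call thresholds, call rates, scorable/polymorphic and
# homeologous classification, species summaries, replicate concordance.

#' Apply locus/call score thresholds
#'
#' Calls whose locus-level clustering score falls below `locus_min` or
#' whose per-call score falls below `call_min` are set to missing before
#' any downstream accounting (GenTrain-/GenCall-style screening).
#'
#' @param genotypes dosage matrix (loci x samples).
#' @param locus_scores numeric vector of per-locus scores (aligned to the
#'   rows) or `NULL` to skip.
#' @param call_scores matrix of per-call scores, same dimensions as
#'   `genotypes`, or `NULL` to skip.
#' @param locus_min,call_min thresholds (strict: a score equal to the
#'   threshold passes).
#' @return the masked genotype matrix.
#' @export
apply_call_thresholds <- function(genotypes, locus_scores = NULL,
                                  call_scores = NULL,
                                  locus_min = 0.6, call_min = 0.2) {
  check_dosage(genotypes)
  if (!is.null(locus_scores)) {
    if (length(locus_scores) != nrow(genotypes)) {
      stop("locus score table not aligned to the matrix", call. = FALSE)
    }
    genotypes[locus_scores < locus_min, ] <- NA
  }
  if (!is.null(call_scores)) {
    if (!identical(dim(call_scores), dim(genotypes))) {
      stop("call score table not aligned to the matrix", call. = FALSE)
    }
    genotypes[call_scores < call_min] <- NA
  }
  genotypes
}

#' Per-sample call rate
#'
#' The percentage of scorable (non-missing) calls for a sample, reported
#' to one decimal.
#'
#' @param genotypes dosage matrix (loci x samples).
#' @param sample sample id(s); default all.
#' @return named numeric vector of percentages.
#' @export
call_rate <- function(genotypes, sample = colnames(genotypes)) {
  check_dosage(genotypes)
  missing_ids <- setdiff(sample, colnames(genotypes))
  if (length(missing_ids)) {
    stop(sprintf("unknown sample(s): %s",
                 paste(missing_ids, collapse = ", ")), call. = FALSE)
  }
  g <- genotypes[, sample, drop = FALSE]
  pct(colSums(!is.na(g)), nrow(g), 1)
}

#' Classify loci as scorable / polymorphic within a species panel
#'
#' A locus is scorable in a panel when its non-missing call fraction is
#' at least `scorable_min_fraction`; a scorable locus is polymorphic when
#' at least two dosage states are observed among the called samples.
#'
#' @param genotypes dosage matrix (loci x samples).
#' @param panel panel data frame (`sample`, `species`).
#' @param species species label to subset.
#' @param scorable_min_fraction minimum called fraction (default 0.75).
#' @return data frame: `locus_id`, `scorable`, `polymorphic`.
#' @export
classify_panel_loci <- function(genotypes, panel, species,
                                scorable_min_fraction = 0.75) {
  ids <- intersect(panel$sample[panel$species == species],
                   colnames(genotypes))
  if (!length(ids)) {
    stop(sprintf("no samples of species '%s' in the matrix", species),
         call. = FALSE)
  }
  g <- genotypes[, ids, drop = FALSE]
  called <- rowSums(!is.na(g))
  scorable <- called / length(ids) >= scorable_min_fraction
  n_states <- apply(g, 1, function(x) length(unique(x[!is.na(x)])))
  data.frame(locus_id = rownames(g), scorable = scorable,
             polymorphic = scorable & n_states >= 2,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify loci by the dihaploid call
#'
#' In the tetraploid species, a locus heterozygous in the dihaploid marks
#' a fixed inter-subgenome (homeologous) difference; a missing dihaploid
#' call leaves the locus unusable for the allelic-polymorphism
#' denominator; a homozygous call makes it a candidate allelic marker.
#'
#' @param genotypes dosage matrix (loci x samples).
#' @param dihaploid_id dihaploid sample id.
#' @return character vector (`homeologous`, `allelic_candidate`,
#'   `unusable`) named by locus.
#' @export
classify_homeologous <- function(genotypes, dihaploid_id) {
  if (!dihaploid_id %in% colnames(genotypes)) {
    stop(sprintf("dihaploid '%s' not in matrix", dihaploid_id),
         call. = FALSE)
  }
  di <- genotypes[, dihaploid_id]
  out <- ifelse(is.na(di), "unusable",
                ifelse(di == 1, "homeologous", "allelic_candidate"))
  names(out) <- rownames(genotypes)
  out
}

#' Species-level array utilization summary
#'
#' Produces the per-species accounting of an array evaluation: for each
#' SNP source and genic class, the number of synthesized loci, the
#' scorable count with its percentage of synthesized loci, and the
#' polymorphic count with its percentage of scorable loci.  For a
#' tetraploid species (when `dihaploid_id` is given) the summary
#' additionally reports loci heterozygous in the dihaploid (homeologous,
#' as a percentage of scorable loci) and restricts the polymorphic count
#' to allelic-candidate loci: markers heterozygous or missing in the
#' dihaploid cannot count as allelic polymorphism.
#'
#' @param genotypes dosage matrix (loci x samples).
#' @param panel panel data frame (`sample`, `species`).
#' @param catalog catalog with `locus_id`, `source`, `genic_class`
#'   covering the matrix loci.
#' @param species species label to summarize.
#' @param dihaploid_id dihaploid sample id (tetraploid species only).
#' @param scorable_min_fraction passed to [classify_panel_loci()].
#' @return data frame of class `species_summary`, one row per SNP source
#'   x genic class plus `total` rows.
#' @export
summarize_species <- function(genotypes, panel, catalog, species,
                              dihaploid_id = NULL,
                              scorable_min_fraction = 0.75) {
  cls <- classify_panel_loci(genotypes, panel, species,
                             scorable_min_fraction)
  idx <- match(cls$locus_id, catalog$locus_id)
  if (anyNA(idx)) stop("catalog does not cover the matrix loci",
                       call. = FALSE)
  src <- catalog$source[idx]
  gen <- catalog$genic_class[idx]
  homeo <- rep(FALSE, nrow(cls)); usable <- rep(TRUE, nrow(cls))
  if (!is.null(dihaploid_id)) {
    hcls <- classify_homeologous(genotypes, dihaploid_id)[cls$locus_id]
    homeo <- hcls == "homeologous"
    usable <- hcls == "allelic_candidate"
    cls$polymorphic <- cls$polymorphic & usable
  }
  cell <- function(pick) {
    data.frame(
      synthesized = sum(pick),
      scorable = sum(cls$scorable[pick]),
      scorable_pct = pct(sum(cls$scorable[pick]), sum(pick)),
      polymorphic = sum(cls$polymorphic[pick]),
      polymorphic_pct = pct(sum(cls$polymorphic[pick]),
                            sum(cls$scorable[pick])),
      dihaploid_het = if (is.null(dihaploid_id)) NA_integer_ else
        sum(homeo[pick] & cls$scorable[pick]),
      dihaploid_het_pct = if (is.null(dihaploid_id)) NA_real_ else
        pct(sum(homeo[pick] & cls$scorable[pick]),
            sum(cls$scorable[pick])))
  }
  rows <- list()
  for (s in sort(unique(src))) {
    for (g in c("coding", "non-coding")) {
      rows[[paste(s, g)]] <- cbind(source = s, genic_class = g,
                                   cell(src == s & gen == g))
    }
    rows[[paste(s, "all")]] <- cbind(source = s, genic_class = "all",
                                     cell(src == s))
  }
  rows[["total"]] <- cbind(source = "total", genic_class = "all",
                           cell(rep(TRUE, nrow(cls))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  audit_species_summary(out)
  structure(out, species = species,
            scorable_min_fraction = scorable_min_fraction,
            class = c("species_summary", "data.frame"))
}

# Self-consistency audit: every percentage recomputes from its counts and
# counts nest (polymorphic <= scorable <= synthesized).
audit_species_summary <- function(x) {
  stopifnot(all(x$scorable <= x$synthesized),
            all(x$polymorphic <= x$scorable))
  ok_sc <- is.na(x$scorable_pct) |
    x$scorable_pct == pct(x$scorable, x$synthesized)
  ok_po <- is.na(x$polymorphic_pct) |
    x$polymorphic_pct == pct(x$polymorphic, x$scorable)
  if (!all(ok_sc, ok_po)) {
    stop("internal error: summary percentages do not recompute from counts",
         call. = FALSE)
  }
  invisible(x)
}

#' Replicate concordance
#'
#' For each declared replicate pair, the percentage of identical calls
#' over the loci scored in both samples (loci missing in either member
#' are excluded from the denominator).
#'
#' @param genotypes dosage matrix (loci x samples).
#' @param panel panel data frame with `sample` and `replicate_of`
#'   columns (`NA` for non-replicates).
#' @return data frame: `sample`, `replicate_of`, `n_joint`,
#'   `concordance_pct` (empty when no pairs are declared).
#' @export
replicate_concordance <- function(genotypes, panel) {
  if (is.null(panel$replicate_of)) panel$replicate_of <- NA_character_
  pairs <- panel[!is.na(panel$replicate_of) & panel$replicate_of != "", ]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- genotypes[, pairs$sample[i]]
    b <- genotypes[, pairs$replicate_of[i]]
    joint <- !is.na(a) & !is.na(b)
    data.frame(sample = pairs$sample[i],
               replicate_of = pairs$replicate_of[i],
               n_joint = sum(joint),
               concordance_pct = pct(sum(a[joint] == b[joint]), sum(joint)),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(sample = character(), replicate_of = character(),
                      n_joint = integer(), concordance_pct = numeric()))
  }
  do.call(rbind, rows)
}
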