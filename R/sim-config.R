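# Simulation configuration for the synthetic study generator.

#' Configuration for the synthetic array study
#'
#' Bundles every tunable of the synthetic-data generator.  The defaults
#' emulate the design of a coffee-type array study: a structured
#' outcrossing diploid species A partitioned into eight differentiated
#' genetic groups, a second low-diversity diploid species B, an
#' allotetraploid formed from one haplotype pool of each (so that sites
#' divergently fixed between the species show fixed heterozygosity), a
#' dihaploid carrying a single haplotype per subgenome, and two mapping
#' progenies: an F1 pseudo-testcross of 93 individuals in species A and a
#' selfed F2 of 138 individuals in the tetraploid.
#'
#' @param seed integer seed; the same config yields byte-identical outputs.
#' @param n_loci number of candidate SNP loci to simulate.
#' @param n_chromosomes number of anchored pseudo-chromosomes.
#' @param chrom_length_bp length of each anchored pseudo-chromosome.
#' @param include_unanchored add a virtual pseudo-chromosome "0" of
#'   unanchored sequence (excluded from density and LD summaries).
#' @param unanchored_length_bp length of pseudo-chromosome 0.
#' @param genic_fraction fraction of each chromosome covered by genes.
#' @param mean_gene_length_bp mean simulated gene length.
#' @param n_groups_a number of genetic groups in species A (default 8).
#' @param fst_a differentiation of species-A groups, in (0,1); the
#'   Balding--Nichols dispersion of group allele frequencies around the
#'   ancestral frequency.
#' @param n_per_group_a diploid diversity individuals per species-A group
#'   (recycled to `n_groups_a`); defaults sum to 27.
#' @param n_discovery_a species-A discovery (resequencing) individuals.
#' @param diversity_b probability that a locus is polymorphic within
#'   species B; controls its (low) expected heterozygosity.
#' @param ld_corr_bp physical correlation scale of the latent AR(1)
#'   process that links alleles along a haplotype; nearby loci are in
#'   linkage disequilibrium that decays with distance while per-locus
#'   allele frequencies keep their exact hierarchical-model marginals.
#'   The default puts the realized half-decay of a multi-group
#'   discovery panel on the order of 10 kb, as seen in outcrossing
#'   perennial crops.  `0` switches the correlation off.
#' @param n_diversity_b species-B diversity individuals.
#' @param n_tetraploid allotetraploid diversity individuals (a dihaploid
#'   is always added, giving `n_tetraploid + 1` tetraploid-species
#'   samples).
#' @param donor_group_a species-A group donating the tetraploid's A-like
#'   subgenome haplotypes; `NULL` picks one at random.
#' @param n_f1,n_f2 mapping progeny sizes (F1 pseudo-testcross in species
#'   A; selfed F2 in the tetraploid species).
#' @param map_length_cM genetic length of each chromosome.
#' @param specific_a_fraction fraction of loci whose assay reads only the
#'   A-like subgenome in tetraploid-species samples (emulating
#'   subgenome-specific read mapping / probe hybridization, the mechanism
#'   that yields codominant within-subgenome markers in an
#'   allotetraploid); the remaining loci report fully collapsed calls.
#' @param missing_rate per-call probability of a missing genotype.
#' @param qual_range range of simulated variant QUAL scores.
#' @param candidate_gene_n number of genes tagged as trait candidates.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_loci = 2000L,
                       n_chromosomes = 11L,
                       chrom_length_bp = 5e5,
                       include_unanchored = TRUE,
                       unanchored_length_bp = 2e5,
                       genic_fraction = 0.4,
                       mean_gene_length_bp = 3000,
                       n_groups_a = 8L,
                       fst_a = 0.2,
                       n_per_group_a = c(4L, 4L, 4L, 3L, 3L, 3L, 3L, 3L),
                       n_discovery_a = 12L,
                       diversity_b = 0.05,
                       ld_corr_bp = 6000,
                       n_diversity_b = 6L,
                       n_tetraploid = 16L,
                       donor_group_a = NULL,
                       n_f1 = 93L,
                       n_f2 = 138L,
                       map_length_cM = 100,
                       specific_a_fraction = 0.25,
                       missing_rate = 0.03,
                       qual_range = c(20, 100),
                       candidate_gene_n = 25L) {
  cfg <- list(
    seed = as.integer(seed), n_loci = as.integer(n_loci),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = chrom_length_bp,
    include_unanchored = isTRUE(include_unanchored),
    unanchored_length_bp = unanchored_length_bp,
    genic_fraction = genic_fraction,
    mean_gene_length_bp = mean_gene_length_bp,
    n_groups_a = as.integer(n_groups_a), fst_a = fst_a,
    n_per_group_a = rep_len(as.integer(n_per_group_a), n_groups_a),
    n_discovery_a = as.integer(n_discovery_a),
    diversity_b = diversity_b, ld_corr_bp = ld_corr_bp,
    n_diversity_b = as.integer(n_diversity_b),
    n_tetraploid = as.integer(n_tetraploid),
    donor_group_a = donor_group_a,
    n_f1 = as.integer(n_f1), n_f2 = as.integer(n_f2),
    map_length_cM = map_length_cM,
    specific_a_fraction = specific_a_fraction,
    missing_rate = missing_rate,
    qual_range = qual_range,
    candidate_gene_n = as.integer(candidate_gene_n)
  )
  probs <- c(missing = cfg$missing_rate, genic = cfg$genic_fraction,
             diversity_b = cfg$diversity_b,
             specific_a = cfg$specific_a_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$missing_rate >= 1) stop("missing_rate must be < 1", call. = FALSE)
  if (cfg$fst_a <= 0 || cfg$fst_a >= 1) {
    stop("fst_a must lie in (0, 1)", call. = FALSE)
  }
  counts <- c(cfg$n_loci, cfg$n_chromosomes, cfg$n_groups_a,
              cfg$n_diversity_b, cfg$n_tetraploid, cfg$n_f1, cfg$n_f2)
  if (any(counts < 1)) stop("counts must be positive", call. = FALSE)
  if (cfg$chrom_length_bp < 1) {
    stop("chromosome length must be positive", call. = FALSE)
  }
  if (any(cfg$map_length_cM <= 0)) {
    stop("map lengths must be positive", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  seed %d | %d loci on %d chromosome(s)%s\n", x$seed, x$n_loci,
              x$n_chromosomes,
              if (x$include_unanchored) " + unanchored chr0" else ""))
  cat(sprintf("  species A: %d groups (Fst %.2f), %d diversity + %d discovery samples\n",
              x$n_groups_a, x$fst_a, sum(x$n_per_group_a), x$n_discovery_a))
  cat(sprintf("  species B: diversity %.3f, %d samples\n", x$diversity_b,
              x$n_diversity_b))
  cat(sprintf("  tetraploids: %d (+1 dihaploid); progenies F1 n=%d, F2 n=%d\n",
              x$n_tetraploid, x$n_f1, x$n_f2))
  invisible(x)
}

#' Simulate a genome model: chromosomes and gene annotation
#'
#' Lays out `n_chromosomes` anchored pseudo-chromosomes (plus, optionally,
#' a virtual pseudo-chromosome "0" of unanchored sequence) and places
#' non-overlapping gene intervals so that the genic fraction of every
#' chromosome equals `genic_fraction` up to rounding.  Gene lengths are
#' gamma-distributed around `mean_gene_length_bp` and rescaled so their
#' total matches the target fraction; the gaps between genes are drawn
#' uniformly, which spreads genes over the whole chromosome.
#'
#' @param config a [sim_config()].
#' @return an object of class `genome_model`: a list with `chromosomes`
#'   (data frame: `chrom`, `length`) and `genes` (data frame: `chrom`,
#'   `start`, `end`, `gene_id`, 1-based inclusive).
#' @export
simulate_genome_model <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  chroms <- data.frame(
    chrom = as.character(seq_len(config$n_chromosomes)),
    length = rep(config$chrom_length_bp, config$n_chromosomes),
    stringsAsFactors = FALSE
  )
  if (config$include_unanchored) {
    chroms <- rbind(data.frame(chrom = "0",
                               length = config$unanchored_length_bp),
                    chroms)
  }
  genes <- with_seed(substream_seed(config$seed, 1L, "genome"), {
    do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
      place_genes(chroms$chrom[i], chroms$length[i], config$genic_fraction,
                  config$mean_gene_length_bp)
    }))
  })
  if (!is.null(genes) && nrow(genes)) {
    genes$gene_id <- sprintf("gene_%04d", seq_len(nrow(genes)))
  } else {
    genes <- data.frame(chrom = character(), start = integer(),
                        end = integer(), gene_id = character(),
                        stringsAsFactors = FALSE)
  }
  structure(list(chromosomes = chroms, genes = genes),
            class = "genome_model")
}

place_genes <- function(chrom, len, frac, mean_len) {
  target <- round(frac * len)
  if (target <= 0) return(NULL)
  k <- max(1L, round(target / mean_len))
  lens <- stats::rgamma(k, shape = 2, scale = mean_len / 2)
  lens <- pmax(1L, round(lens * target / sum(lens)))
  # rescaling can overshoot by rounding; trim the last genes if needed
  while (sum(lens) > len) lens[which.max(lens)] <- lens[which.max(lens)] - 1L
  slack <- len - sum(lens)
  gaps <- stats::runif(k + 1)
  gaps <- floor(gaps / sum(gaps) * slack)
  starts <- cumsum(gaps[seq_len(k)] + c(1L, lens[-k]))
  data.frame(chrom = chrom, start = as.integer(starts),
             end = as.integer(starts + lens - 1L),
             stringsAsFactors = FALSE)
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("Genome model: %d chromosome(s), %.2f Mb, %d genes (%.1f%% genic)\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6,
              nrow(x$genes),
              100 * sum(x$genes$end - x$genes$start + 1) /
                sum(x$chromosomes$length)))
  invisible(x)
}
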