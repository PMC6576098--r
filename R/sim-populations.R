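# Population simulators: locus catalog, structured progenitor species,
# allotetraploid + dihaploid, and mapping progenies.

#' Simulate the candidate-locus catalog
#'
#' Draws `n_loci` distinct SNP positions across the chromosomes of a
#' genome model (proportionally to chromosome length), sorted by
#' chromosome and position, with simulated QUAL scores.  Ref/alt alleles
#' are filled in when the reference FASTA is generated.
#'
#' @param model a [simulate_genome_model()] result.
#' @param config a [sim_config()].
#' @return data frame: `locus_id`, `chrom`, `pos`, `qual`.
#' @export
simulate_locus_catalog <- function(model, config) {
  stopifnot(inherits(model, "genome_model"), inherits(config, "sim_config"))
  chroms <- model$chromosomes
  with_seed(substream_seed(config$seed, 2L, "loci"), {
    n_per <- as.vector(stats::rmultinom(1, config$n_loci,
                                        chroms$length / sum(chroms$length)))
    cat_list <- lapply(seq_len(nrow(chroms)), function(i) {
      if (n_per[i] == 0) return(NULL)
      pos <- sort(sample.int(chroms$length[i], n_per[i]))
      data.frame(chrom = chroms$chrom[i], pos = pos,
                 stringsAsFactors = FALSE)
    })
    cat <- do.call(rbind, cat_list)
    # chromosome "0" (if any) first, then 1..n, matching a sorted VCF
    ord <- order(suppressWarnings(as.integer(cat$chrom)), cat$pos)
    cat <- cat[ord, , drop = FALSE]
    cat$qual <- round(stats::runif(nrow(cat), config$qual_range[1],
                                   config$qual_range[2]), 1)
    cat$locus_id <- sprintf("snp_%05d", seq_len(nrow(cat)))
    rownames(cat) <- cat$locus_id
    cat[, c("locus_id", "chrom", "pos", "qual")]
  })
}

#' Simulate structured progenitor panels
#'
#' Species A follows a hierarchical (Balding--Nichols) allele-frequency
#' model: each locus has an ancestral frequency `p ~ U(0.05, 0.95)` and
#' every genetic group draws its own frequency from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F = fst_a`, which produces
#' discrete, well-differentiated groups with one interpretable parameter.
#' Species B drifts to fixation at most loci (the fixed allele is drawn
#' with the ancestral frequency, creating inter-species divergent sites)
#' and stays polymorphic with probability `diversity_b`.
#'
#' @param model a [simulate_genome_model()] result.
#' @param config a [sim_config()].
#' @return list with elements `pools` (named list of haplotype pools, one
#'   per species-A group plus `"B"`; each pool is a list with `species`,
#'   `group`, `freqs` and a loci x haplotypes 0/1 matrix `haplotypes`),
#'   `genotypes` (dosage matrix, loci x samples, for the species-A
#'   diversity + discovery panels and the species-B diversity panel) and
#'   `panel` (data frame: `sample`, `species`, `group`, `role`).
#' @export
simulate_progenitor_panels <- function(model, config) {
  stopifnot(inherits(model, "genome_model"), inherits(config, "sim_config"))
  if (config$n_groups_a < 1) stop("need at least one group", call. = FALSE)
  catalog <- simulate_locus_catalog(model, config)
  L <- nrow(catalog)
  with_seed(substream_seed(config$seed, 3L, "panels"), {
    p_anc <- stats::runif(L, 0.05, 0.95)
    f <- config$fst_a
    groups <- paste0("G", seq_len(config$n_groups_a))
    group_freqs <- vapply(groups, function(g) {
      stats::rbeta(L, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
    }, numeric(L))
    # species B: fixed allele by drift, occasionally still polymorphic
    b_fixed <- stats::rbinom(L, 1, p_anc)
    b_poly <- stats::runif(L) < config$diversity_b
    freq_b <- ifelse(b_poly, stats::runif(L, 0.1, 0.9), b_fixed)

    n_hap_a <- 2L * (max(config$n_per_group_a) + config$n_discovery_a +
                       config$n_tetraploid + 4L) + 8L
    pools <- lapply(seq_along(groups), function(i) {
      hap <- draw_correlated_haplotypes(group_freqs[, i], catalog,
                                        n_hap_a, config$ld_corr_bp)
      rownames(hap) <- catalog$locus_id
      list(species = "speciesA", group = groups[i],
           freqs = group_freqs[, i], haplotypes = hap)
    })
    names(pools) <- groups
    n_hap_b <- 2L * (config$n_diversity_b + config$n_tetraploid + 4L) + 8L
    hap_b <- draw_correlated_haplotypes(freq_b, catalog, n_hap_b,
                                        config$ld_corr_bp)
    rownames(hap_b) <- catalog$locus_id
    pools$B <- list(species = "speciesB", group = "B", freqs = freq_b,
                    haplotypes = hap_b)

    # diploid individuals: consecutive haplotype pairs from their pool
    samples <- list(); panel <- list(); used <- integer(length(pools))
    names(used) <- names(pools)
    take <- function(pool_name, n_ind) {
      idx <- used[[pool_name]] + seq_len(2L * n_ind)
      used[[pool_name]] <<- used[[pool_name]] + 2L * n_ind
      h <- pools[[pool_name]]$haplotypes[, idx, drop = FALSE]
      h[, seq(1, 2 * n_ind, 2), drop = FALSE] +
        h[, seq(2, 2 * n_ind, 2), drop = FALSE]
    }
    for (i in seq_along(groups)) {
      n_ind <- config$n_per_group_a[i]
      g <- take(groups[i], n_ind)
      colnames(g) <- sprintf("A_%s_%02d", groups[i], seq_len(n_ind))
      samples[[length(samples) + 1L]] <- g
      panel[[length(panel) + 1L]] <- data.frame(
        sample = colnames(g), species = "speciesA", group = groups[i],
        role = "diversity", stringsAsFactors = FALSE)
    }
    # discovery panel of species A: spread round-robin over the groups
    disc_groups <- rep_len(groups, config$n_discovery_a)
    for (j in seq_len(config$n_discovery_a)) {
      g <- take(disc_groups[j], 1L)
      colnames(g) <- sprintf("A_disc_%02d", j)
      samples[[length(samples) + 1L]] <- g
      panel[[length(panel) + 1L]] <- data.frame(
        sample = colnames(g), species = "speciesA", group = disc_groups[j],
        role = "discovery", stringsAsFactors = FALSE)
    }
    gb <- take("B", config$n_diversity_b)
    colnames(gb) <- sprintf("B_%02d", seq_len(config$n_diversity_b))
    samples[[length(samples) + 1L]] <- gb
    panel[[length(panel) + 1L]] <- data.frame(
      sample = colnames(gb), species = "speciesB", group = "B",
      role = "diversity", stringsAsFactors = FALSE)

    genotypes <- do.call(cbind, samples)
    rownames(genotypes) <- catalog$locus_id
    list(catalog = catalog, pools = pools, genotypes = genotypes,
         panel = do.call(rbind, panel), hap_used = used)
  })
}

#' Simulate an allotetraploid panel and its dihaploid
#'
#' Each tetraploid individual carries two haplotypes from the species-A
#' donor pool (its A-like subgenome) and two from the species-B pool; the
#' reported genotype is the merged tetraploid call collapsed to dosage
#' `{0, 1, 2}`: 0 if all four alleles are ref, 2 if all four are alt,
#' otherwise heterozygous.  At loci divergently fixed between the two
#' pools every tetraploid is therefore heterozygous (fixed
#' heterozygosity).  The dihaploid carries exactly one haplotype per
#' subgenome, so its heterozygous calls mark exactly the
#' inter-subgenome (homeologous) positions of its two haplotypes.
#'
#' @param pool_a species-A haplotype pool (the subgenome donor group).
#' @param pool_b species-B haplotype pool.
#' @param n_individuals number of tetraploids (the dihaploid is added).
#' @param seed integer seed.
#' @param hap_offset_a,hap_offset_b first pool column to use (so samples
#'   do not reuse the haplotypes already consumed by the diploid panels).
#' @return list with `genotypes` (loci x (n_individuals + 1) collapsed
#'   dosage matrix, last column the dihaploid), `genotypes_a` (the
#'   A-subgenome dosages the same samples would show on a
#'   subgenome-specific assay; the dihaploid's single A haplotype reads
#'   as homozygous), `dihaploid_id`, and `truth` (donor group label,
#'   haplotype indices used).
#' @export
simulate_allotetraploid <- function(pool_a, pool_b, n_individuals,
                                    seed = 1L, hap_offset_a = 0L,
                                    hap_offset_b = 0L) {
  if (!length(pool_a$haplotypes) || !length(pool_b$haplotypes)) {
    stop("empty haplotype pool", call. = FALSE)
  }
  if (!identical(rownames(pool_a$haplotypes), rownames(pool_b$haplotypes))) {
    stop("pools must share the same locus list", call. = FALSE)
  }
  L <- nrow(pool_a$haplotypes)
  with_seed(substream_seed(seed, 4L, "tetraploid"), {
    n_a <- ncol(pool_a$haplotypes); n_b <- ncol(pool_b$haplotypes)
    avail_a <- setdiff(seq_len(n_a), seq_len(hap_offset_a))
    avail_b <- setdiff(seq_len(n_b), seq_len(hap_offset_b))
    need_a <- 2L * n_individuals + 1L; need_b <- 2L * n_individuals + 1L
    idx_a <- if (length(avail_a) >= need_a) avail_a[seq_len(need_a)] else
      sample(avail_a, need_a, replace = TRUE)
    idx_b <- if (length(avail_b) >= need_b) avail_b[seq_len(need_b)] else
      sample(avail_b, need_b, replace = TRUE)
    geno <- matrix(NA_real_, nrow = L, ncol = n_individuals + 1L)
    geno_a <- matrix(NA_real_, nrow = L, ncol = n_individuals + 1L)
    for (i in seq_len(n_individuals)) {
      ha <- pool_a$haplotypes[, idx_a[2 * i - 1]] +
        pool_a$haplotypes[, idx_a[2 * i]]
      hb <- pool_b$haplotypes[, idx_b[2 * i - 1]] +
        pool_b$haplotypes[, idx_b[2 * i]]
      s <- ha + hb  # 0..4 alt alleles over the four homoeologous copies
      geno[, i] <- ifelse(s == 0, 0, ifelse(s == 4, 2, 1))
      geno_a[, i] <- ha
    }
    di_a <- pool_a$haplotypes[, idx_a[need_a]]
    di_b <- pool_b$haplotypes[, idx_b[need_b]]
    geno[, n_individuals + 1L] <- di_a + di_b
    geno_a[, n_individuals + 1L] <- 2 * di_a  # one A haplotype, read as hom
    ids <- c(sprintf("T_%02d", seq_len(n_individuals)), "dihaploid")
    dimnames(geno) <- list(rownames(pool_a$haplotypes), ids)
    dimnames(geno_a) <- dimnames(geno)
    list(genotypes = geno, genotypes_a = geno_a,
         dihaploid_id = "dihaploid",
         truth = list(donor_group = pool_a$group,
                      hap_a = idx_a, hap_b = idx_b,
                      dihaploid_hap = cbind(A = di_a, B = di_b)))
  })
}

#' Simulate a mapping progeny
#'
#' Gametes are generated by a Markov walk along each chromosome: between
#' adjacent loci at genetic distance `d` cM the gamete switches parental
#' haplotype with probability given by the inverse Kosambi function
#' [kosambi_r()], so two-point recombination fractions between adjacent
#' loci match the Kosambi map by construction.
#'
#' @param parent1,parent2 phased parents: lists with 0/1 haplotype
#'   vectors `h1`, `h2` (named by locus).
#' @param design `"F1_pseudo_testcross"` (offspring unite one gamete from
#'   each parent) or `"F2_self"` (an F1 is formed from one gamete of each
#'   parent, then selfed).
#' @param n_offspring progeny size.
#' @param map data frame with `chrom` and `cM` per locus, in locus order.
#' @param seed integer seed.
#' @return dosage matrix (loci x offspring); attribute `f1` holds the F1
#'   haplotypes for the selfing design.
#' @export
simulate_mapping_progeny <- function(parent1, parent2,
                                     design = c("F1_pseudo_testcross",
                                                "F2_self"),
                                     n_offspring, map, seed = 1L) {
  design <- match.arg(design)
  for (p in list(parent1, parent2)) {
    if (is.null(p$h1) || is.null(p$h2) ||
        length(p$h1) != nrow(map) || length(p$h2) != nrow(map)) {
      stop("parents must be phased: haplotypes h1/h2 over the map loci",
           call. = FALSE)
    }
  }
  with_seed(substream_seed(seed, 5L, design), {
    if (design == "F1_pseudo_testcross") {
      off <- vapply(seq_len(n_offspring), function(i) {
        gamete(parent1, map) + gamete(parent2, map)
      }, numeric(nrow(map)))
    } else {
      f1 <- list(h1 = gamete(parent1, map), h2 = gamete(parent2, map))
      off <- vapply(seq_len(n_offspring), function(i) {
        gamete(f1, map) + gamete(f1, map)
      }, numeric(nrow(map)))
    }
    colnames(off) <- sprintf("off_%03d", seq_len(n_offspring))
    rownames(off) <- rownames(map)
    if (design == "F2_self") attr(off, "f1") <- f1
    off
  })
}

# Haplotypes with distance-decaying linkage disequilibrium: a latent
# standard-normal AR(1) process runs along each chromosome (lag-1
# correlation exp(-d_bp / ld_corr_bp)); allele_i = 1 when
# pnorm(z_i) < freq_i.  The uniform marginal of pnorm(z) keeps each
# locus exactly Bernoulli(freq_i) while neighbouring loci stay
# correlated, so pairwise r2 decays smoothly with physical distance.
draw_correlated_haplotypes <- function(freqs, catalog, n_hap, ld_corr_bp) {
  L <- length(freqs)
  z <- matrix(stats::rnorm(L * n_hap), nrow = L, ncol = n_hap)
  if (ld_corr_bp > 0) {
    for (ch in unique(catalog$chrom)) {
      idx <- which(catalog$chrom == ch)
      if (length(idx) < 2) next
      phi <- exp(-diff(catalog$pos[idx]) / ld_corr_bp)
      for (k in seq_along(phi)) {
        i <- idx[k + 1]
        z[i, ] <- phi[k] * z[idx[k], ] + sqrt(1 - phi[k]^2) * z[i, ]
      }
    }
  }
  (stats::pnorm(z) < freqs) + 0L
}

# One recombinant gamete from a phased parent: per-chromosome Markov walk
# with switch probability kosambi_r(adjacent distance).
gamete <- function(parent, map) {
  out <- numeric(nrow(map))
  for (ch in unique(map$chrom)) {
    i <- which(map$chrom == ch)
    d <- diff(map$cM[i])
    r <- kosambi_r(pmin(d, 49.9 * 2))  # r < 0.5 always
    phase <- cumsum(c(stats::rbinom(1, 1, 0.5),
                      stats::rbinom(length(r), 1, r))) %% 2
    out[i] <- ifelse(phase == 0, parent$h1[i], parent$h2[i])
  }
  out
}
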