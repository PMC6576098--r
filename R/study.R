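# Orchestration: simulate a full synthetic array study and run the whole
# analysis pipeline on its files.

#' Simulate a complete synthetic array study
#'
#' Generates, from one configuration and seed, every input the analysis
#' pipeline consumes: the genome model, the structured species-A panels
#' (diversity + discovery), the low-diversity species-B panel, the
#' allotetraploid diversity panel with its dihaploid, replicated mapping
#' parents, an F1 pseudo-testcross progeny in species A and a selfed F2
#' progeny in the tetraploid species.
#'
#' Tetraploid diversity samples carry collapsed `{0, het, 2}` calls.  The
#' F2 family is scored codominantly: at loci where the B-subgenome pair
#' of the founders is homozygous, the reported call is the segregating
#' A-subgenome dosage (emulating family-calibrated cluster calling);
#' where that pair is heterozygous the call is constant heterozygous
#' (homeologous, non-segregating).
#'
#' @param config a [sim_config()].
#' @param out_dir if non-`NULL`, files are written there via
#'   [inject_missingness_and_write()].
#' @return list of class `sim_study`: `model`, `catalog`, `genotypes`
#'   (complete, before masking), `panel`, `map`, `truth`, `pools`, and
#'   (when written) `paths` plus `masked_genotypes`.
#' @export
simulate_study <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  model <- simulate_genome_model(config)
  pan <- simulate_progenitor_panels(model, config)
  catalog <- pan$catalog
  groups <- paste0("G", seq_len(config$n_groups_a))
  donor <- config$donor_group_a
  if (is.null(donor)) {
    donor <- with_seed(substream_seed(config$seed, 9L, "donor"),
                       sample(groups, 1))
  }
  used <- pan$hap_used
  tet <- simulate_allotetraploid(pan$pools[[donor]], pan$pools$B,
                                 config$n_tetraploid, config$seed,
                                 hap_offset_a = used[[donor]],
                                 hap_offset_b = used[["B"]])
  used[[donor]] <- used[[donor]] + 2L * config$n_tetraploid + 1L
  used[["B"]] <- used[["B"]] + 2L * config$n_tetraploid + 1L

  # loci whose assay reads only the A-like subgenome in the tetraploid
  # species (subgenome-specific mapping/hybridization); elsewhere calls
  # collapse over the four homoeologous copies
  a_specific <- with_seed(substream_seed(config$seed, 11L, "specific"),
                          stats::runif(nrow(catalog)) <
                            config$specific_a_fraction)
  tet_geno <- tet$genotypes
  tet_geno[a_specific, ] <- tet$genotypes_a[a_specific, ]

  # genetic map: uniform recombination along each chromosome
  chrom_len <- stats::setNames(model$chromosomes$length,
                               model$chromosomes$chrom)
  map <- data.frame(chrom = catalog$chrom,
                    cM = catalog$pos / chrom_len[catalog$chrom] *
                      config$map_length_cM,
                    row.names = catalog$locus_id)

  take_pair <- function(pool, off) {
    list(h1 = pool$haplotypes[, off + 1L], h2 = pool$haplotypes[, off + 2L])
  }
  # F1 pseudo-testcross in species A: parents from two different groups
  g1 <- groups[1]; g2 <- groups[min(2L, length(groups))]
  p1 <- take_pair(pan$pools[[g1]], used[[g1]]); used[[g1]] <- used[[g1]] + 2L
  p2 <- take_pair(pan$pools[[g2]], used[[g2]]); used[[g2]] <- used[[g2]] + 2L
  f1_prog <- simulate_mapping_progeny(p1, p2, "F1_pseudo_testcross",
                                      config$n_f1, map, config$seed)
  colnames(f1_prog) <- sprintf("F1_%03d", seq_len(config$n_f1))

  # selfed F2 in the tetraploid species: founders differ in their
  # A-subgenome; both share one B-subgenome haplotype pair
  q1 <- take_pair(pan$pools[[donor]], used[[donor]])
  used[[donor]] <- used[[donor]] + 2L
  q2 <- take_pair(pan$pools[[donor]], used[[donor]])
  used[[donor]] <- used[[donor]] + 2L
  bpair <- take_pair(pan$pools$B, used[["B"]]); used[["B"]] <- used[["B"]] + 2L
  b_het <- bpair$h1 != bpair$h2
  b_dos <- bpair$h1 + bpair$h2
  f2_a <- simulate_mapping_progeny(q1, q2, "F2_self", config$n_f2, map,
                                   config$seed + 1L)
  # family-calibrated codominant scoring: the A-subgenome dosage is read
  # wherever the shared B-subgenome pair is homozygous or the assay is
  # A-specific; a heterozygous B pair on a collapsed assay gives a
  # constant (homeologous) heterozygous call
  codominant <- function(dos_a) ifelse(b_het & !a_specific, 1, dos_a)
  f2_prog <- apply(f2_a, 2, codominant)
  dimnames(f2_prog) <- list(rownames(f2_a),
                            sprintf("F2_%03d", seq_len(config$n_f2)))

  founder_call <- function(pair) codominant(pair$h1 + pair$h2)
  parents <- cbind(F1_parent1 = p1$h1 + p1$h2, F1_parent2 = p2$h1 + p2$h2,
                   F2_parent1 = founder_call(q1),
                   F2_parent2 = founder_call(q2))
  replicates <- parents[, c("F1_parent1", "F1_parent2")]
  colnames(replicates) <- c("F1_parent1_rep", "F1_parent2_rep")

  genotypes <- cbind(pan$genotypes, tet_geno, parents, replicates,
                     f1_prog, f2_prog)
  rownames(genotypes) <- catalog$locus_id

  panel <- rbind(
    pan$panel,
    data.frame(sample = setdiff(colnames(tet$genotypes), "dihaploid"),
               species = "tetraploid", group = "tetraploid",
               role = "diversity", stringsAsFactors = FALSE),
    data.frame(sample = "dihaploid", species = "tetraploid",
               group = "tetraploid", role = "dihaploid",
               stringsAsFactors = FALSE),
    data.frame(sample = colnames(parents), species =
                 c("speciesA", "speciesA", "tetraploid", "tetraploid"),
               group = c(g1, g2, "tetraploid", "tetraploid"),
               role = "mapping_parent", stringsAsFactors = FALSE),
    data.frame(sample = colnames(replicates), species = "speciesA",
               group = c(g1, g2), role = "replicate",
               stringsAsFactors = FALSE),
    data.frame(sample = colnames(f1_prog), species = "speciesA",
               group = "F1", role = "progeny", stringsAsFactors = FALSE),
    data.frame(sample = colnames(f2_prog), species = "tetraploid",
               group = "F2", role = "progeny", stringsAsFactors = FALSE))
  panel$replicate_of <- NA_character_
  panel$replicate_of[panel$sample == "F1_parent1_rep"] <- "F1_parent1"
  panel$replicate_of[panel$sample == "F1_parent2_rep"] <- "F1_parent2"
  panel$admixed <- FALSE

  truth <- list(seed = config$seed, donor_group = donor,
                f1_parents = c("F1_parent1", "F1_parent2"),
                f2_parents = c("F2_parent1", "F2_parent2"),
                map = data.frame(locus_id = catalog$locus_id,
                                 chrom = map$chrom, cM = map$cM),
                b_homeologous = catalog$locus_id[b_het],
                a_specific = catalog$locus_id[a_specific])
  study <- list(model = model, catalog = catalog, genotypes = genotypes,
                panel = panel, map = map, truth = truth, pools = pan$pools,
                config = config)
  if (!is.null(out_dir)) {
    paths <- inject_missingness_and_write(
      genotypes, catalog, model, out_dir,
      missing_rate = config$missing_rate, seed = config$seed,
      panel = panel, truth = truth)
    study$paths <- paths
    study$masked_genotypes <- attr(paths, "genotypes")
    study$catalog <- attr(paths, "catalog")
  }
  structure(study, class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("Synthetic array study: %d loci x %d samples (donor group %s)\n",
              nrow(x$genotypes), ncol(x$genotypes), x$truth$donor_group))
  invisible(x)
}

#' Run the full analysis pipeline on a simulated study
#'
#' Chains every stage on the files written by [simulate_study()]:
#' variant filtering and array design, genotyping QC accounting, LD
#' decay, neighbour-joining tree with block-bootstrap support, subgenome
#' assignment and linkage statistics.  All outputs are written as
#' plain-text TSV/JSON/Newick files under `out_dir`; with a fixed config
#' the run is byte-reproducible.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param n_boot bootstrap replicates for tree support.
#' @param n_runs haploid-downscaling runs for subgenome assignment.
#' @param ld_max_dist_bp distance window for pairwise r-squared.
#' @return (invisibly) a list with every stage's in-memory result.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         n_boot = 25, n_runs = 50,
                         ld_max_dist_bp = 50000) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim_dir <- file.path(out_dir, "sim")
  study <- simulate_study(config, sim_dir)

  vcf <- read_genotype_vcf(study$paths[["vcf"]])
  panel <- read_panel(study$paths[["panel"]])
  panel$admixed <- panel$admixed == "TRUE"
  genes <- read_gff_genes(study$paths[["gff"]])
  geno <- vcf$genotypes
  catalog <- vcf$catalog

  # --- array design from the discovery panels -------------------------
  qc_cat <- basic_quality_filter(catalog)
  disc_a <- panel$sample[panel$species == "speciesA" &
                           panel$role == "discovery"]
  tet_disc <- c(panel$sample[panel$species == "tetraploid" &
                               panel$role == "diversity"][1:4], "dihaploid")
  cat_tet <- subgenome_allelic_filter(qc_cat, geno[, tet_disc],
                                      "dihaploid")
  cat_a <- recurrence_filter(qc_cat, geno[, disc_a, drop = FALSE])
  sel <- rbind(cbind(cat_tet, source = "tetraploid"),
               cbind(cat_a[!cat_a$locus_id %in% cat_tet$locus_id, ],
                     source = "speciesA"))
  sel <- sel[order(match(sel$locus_id, catalog$locus_id)), ]
  candidates <- with_seed(substream_seed(config$seed, 10L, "candidates"), {
    genic <- unique(study$model$genes$gene_id)
    sample(genic, min(config$candidate_gene_n, length(genic)))
  })
  sel <- annotate_genic(sel, study$model$genes, candidates)
  manifest <- spacing_selection(sel)
  dsum <- design_summary(manifest, study$model)

  # --- genotyping QC over the array loci ------------------------------
  gm <- geno[manifest$locus_id, , drop = FALSE]
  cat_m <- manifest
  summaries <- list(
    speciesA = summarize_species(gm, panel, cat_m, "speciesA"),
    speciesB = summarize_species(gm, panel, cat_m, "speciesB"),
    tetraploid = summarize_species(gm, panel, cat_m, "tetraploid",
                                   dihaploid_id = "dihaploid"))
  rates <- call_rate(gm)
  concordance <- replicate_concordance(gm, panel)

  # --- LD decay on the species-A discovery panel ----------------------
  ld_g <- ld_filter(geno[, disc_a, drop = FALSE], catalog)
  ld_rec <- pairwise_r2(ld_g, catalog, max_dist_bp = ld_max_dist_bp)
  ld <- if (nrow(ld_rec)) decay_curve(ld_rec) else NULL

  # --- NJ tree of the diversity panels --------------------------------
  div <- panel$sample[panel$role %in% c("diversity", "dihaploid")]
  tree <- block_bootstrap_support(geno[, div, drop = FALSE],
                                  n_boot = n_boot, block_snps = 100,
                                  seed = config$seed)

  # --- subgenome assignment -------------------------------------------
  queries <- panel$sample[panel$species == "tetraploid" &
                            panel$role %in% c("diversity", "dihaploid")]
  refs <- split(panel$sample[panel$species == "speciesA" &
                               panel$role == "diversity"],
                panel$group[panel$species == "speciesA" &
                              panel$role == "diversity"])
  assignment <- assign_subgenome(geno, queries, refs,
                                 admixed = panel$sample[panel$admixed],
                                 n_runs = n_runs, seed = config$seed)

  # --- linkage statistics on the F2 family ----------------------------
  f2 <- panel$sample[panel$group == "F2"]
  seg_type <- classify_segregation(geno[, "F2_parent1"],
                                   geno[, "F2_parent2"], "F2_self")
  informative <- which(seg_type == "f2_codominant")
  linkage <- do.call(rbind, lapply(informative, function(i) {
    counts <- table(factor(geno[i, f2], 0:2))
    dt <- distortion_test(as.integer(counts), "f2_codominant")
    data.frame(locus_id = rownames(geno)[i], chisq = dt$chisq, p = dt$p,
               distorted_0.01 = dt$distorted_0.01,
               stringsAsFactors = FALSE)
  }))
  # map summary over the informative loci at their simulator-truth
  # positions, with zero-recombination markers merged into position bins
  linkage_map <- NULL
  if (length(informative) > 1) {
    inf_ids <- rownames(geno)[informative]
    bins <- cluster_cosegregating(geno[inf_ids, f2, drop = FALSE])
    map_tab <- data.frame(
      marker = inf_ids,
      lg = study$map[inf_ids, "chrom"],
      cM = study$map[inf_ids, "cM"],
      array_snp = inf_ids %in% manifest$locus_id,
      coseg_bin = unname(bins),
      stringsAsFactors = FALSE)
    multi <- map_tab$lg %in% names(which(table(map_tab$lg) > 1))
    if (any(multi)) {
      linkage_map <- map_summary(map_tab[multi, , drop = FALSE])
      linkage_map$markers <- map_tab
    }
  }

  # --- write outputs --------------------------------------------------
  w <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(as.data.frame(manifest), "manifest.tsv")
  w(dsum$per_chrom, "design_per_chrom.tsv")
  for (s in names(summaries)) {
    w(as.data.frame(summaries[[s]]), sprintf("qc_%s.tsv", s))
  }
  w(data.frame(sample = names(rates), call_rate_pct = rates),
    "call_rates.tsv")
  w(concordance, "replicate_concordance.tsv")
  if (!is.null(ld)) w(ld$curve, "ld_curve.tsv")
  ape::write.tree(tree, file.path(out_dir, "nj_tree.nwk"))
  w(assignment$by_reference, "assignment_by_reference.tsv")
  w(assignment$by_group, "assignment_by_group.tsv")
  if (!is.null(linkage)) w(linkage, "f2_distortion.tsv")
  if (!is.null(linkage_map)) {
    w(linkage_map$per_lg, "f2_map_per_lg.tsv")
    w(linkage_map$markers, "f2_map_markers.tsv")
  }
  report <- list(
    n_candidate_loci = nrow(catalog),
    n_after_quality = nrow(qc_cat),
    n_selected = nrow(manifest),
    genome_density_per_mb = dsum$genome$density_per_mb,
    mean_marker_dist_bp = dsum$genome$mean_dist_bp,
    ld_half_decay_bp = if (!is.null(ld)) ld$half_decay_bp else NA,
    top_group = assignment$by_group$group[1],
    donor_group = study$truth$donor_group,
    f2_distortion_rate_0.01 = if (!is.null(linkage))
      mean(linkage$distorted_0.01) else NA)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(study = study, manifest = manifest, design = dsum,
                 qc = summaries, call_rates = rates,
                 concordance = concordance, ld = ld, tree = tree,
                 assignment = assignment, linkage = linkage,
                 linkage_map = linkage_map, report = report))
}
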