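# Serialization of the simulated study (FASTA, GFF3, VCF, panel TSV,
# truth JSON) and the matching readers.

#' Inject missing calls and write the study files
#'
#' Masks calls uniformly at random at `missing_rate`, then writes the
#' reference FASTA, the GFF3 gene annotation, a VCF v4.2 with QUAL
#' scores, the panel definition TSV and a `truth.json` carrying the
#' simulation ground truth for test oracles.  Output is deterministic:
#' the same inputs and seed give byte-identical files.
#'
#' @param genotypes dosage matrix (loci x samples).
#' @param catalog locus catalog (`locus_id`, `chrom`, `pos`, `qual`,
#'   `ref`, `alt`).
#' @param model genome model (chromosome lengths, genes).
#' @param out_dir output directory (created if needed).
#' @param missing_rate per-call missing probability in `[0, 1)`.
#' @param seed integer seed for the masking and reference sequence.
#' @param panel panel data frame, written as `panel.tsv` when given.
#' @param truth list serialized to `truth.json` when given.
#' @return named character vector of file paths (invisibly the masked
#'   matrix as attribute `genotypes`).
#' @export
inject_missingness_and_write <- function(genotypes, catalog, model,
                                         out_dir, missing_rate = 0.03,
                                         seed = 1L, panel = NULL,
                                         truth = NULL) {
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  check_dosage(genotypes)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (missing_rate > 0) {
    genotypes <- with_seed(substream_seed(seed, 7L, "missing"), {
      mask <- stats::runif(length(genotypes)) < missing_rate
      genotypes[mask] <- NA
      genotypes
    })
  }
  seqs <- simulate_reference_sequence(model, catalog, seed)
  paths <- c(
    fasta = file.path(out_dir, "genome.fa"),
    gff = file.path(out_dir, "annotation.gff3"),
    vcf = file.path(out_dir, "genotypes.vcf"),
    panel = file.path(out_dir, "panel.tsv"),
    truth = file.path(out_dir, "truth.json"))
  Biostrings::writeXStringSet(seqs$sequences, paths[["fasta"]], width = 80)
  write_gff3_genes(model$genes, paths[["gff"]])
  write_genotype_vcf(genotypes, seqs$catalog, model, paths[["vcf"]])
  if (!is.null(panel)) {
    utils::write.table(panel, paths[["panel"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    paths <- paths[names(paths) != "panel"]
  }
  if (!is.null(truth)) {
    jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    paths <- paths[names(paths) != "truth"]
  }
  out <- paths
  attr(out, "genotypes") <- genotypes
  attr(out, "catalog") <- seqs$catalog
  invisible(out)
}

# Random reference sequence per chromosome; the catalog gains ref/alt
# alleles consistent with the sequence.
simulate_reference_sequence <- function(model, catalog, seed) {
  bases <- c("A", "C", "G", "T")
  with_seed(substream_seed(seed, 8L, "reference"), {
    seq_list <- lapply(seq_len(nrow(model$chromosomes)), function(i) {
      paste(sample(bases, model$chromosomes$length[i], replace = TRUE),
            collapse = "")
    })
    seqs <- Biostrings::DNAStringSet(unlist(seq_list))
    names(seqs) <- model$chromosomes$chrom
    if (is.null(catalog$ref)) {
      ref <- substring(as.character(seqs[catalog$chrom]),
                       catalog$pos, catalog$pos)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1),
                    character(1), USE.NAMES = FALSE)
      catalog$ref <- ref
      catalog$alt <- alt
    }
    list(sequences = seqs, catalog = catalog)
  })
}

write_gff3_genes <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    writeLines(sprintf("%s\tallosnp_sim\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                       genes$chrom, genes$start, genes$end, genes$gene_id),
               con)
  }
}

write_genotype_vcf <- function(genotypes, catalog, model, path) {
  stopifnot(identical(rownames(genotypes), catalog$locus_id))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=allosnp_sim",
               sprintf("##contig=<ID=%s,length=%d>",
                       model$chromosomes$chrom,
                       as.integer(model$chromosomes$length)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(genotypes)),
                   collapse = "\t"), con)
  gt <- matrix("./.", nrow = nrow(genotypes), ncol = ncol(genotypes))
  gt[!is.na(genotypes) & genotypes == 0] <- "0/0"
  gt[!is.na(genotypes) & genotypes == 1] <- "0/1"
  gt[!is.na(genotypes) & genotypes == 2] <- "1/1"
  lines <- paste(catalog$chrom, catalog$pos, catalog$locus_id, catalog$ref,
                 catalog$alt, catalog$qual, "PASS", ".", "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
}

#' Read a genotype VCF into a catalog and dosage matrix
#'
#' @param path VCF file path.
#' @return list: `catalog` (`locus_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `qual`) and `genotypes` (dosage matrix, loci x samples).
#' @export
read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  catalog <- data.frame(
    locus_id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, qual = as.numeric(fix$QUAL),
    stringsAsFactors = FALSE)
  if (anyNA(catalog$locus_id)) {
    catalog$locus_id <- sprintf("%s_%d", catalog$chrom, catalog$pos)
  }
  rownames(catalog) <- catalog$locus_id
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt %in% c("0/0", "0|0")] <- 0
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  dos[gt %in% c("1/1", "1|1")] <- 2
  rownames(dos) <- catalog$locus_id
  list(catalog = catalog, genotypes = dos)
}

#' Read gene intervals from a GFF3 file
#'
#' @param path GFF3 file path.
#' @param feature feature type to keep (default `"gene"`).
#' @return data frame: `chrom`, `start`, `end`, `gene_id`.
#' @export
read_gff_genes <- function(path, feature = "gene") {
  cols <- c("chrom", "source", "type", "start", "end", "score", "strand",
            "phase", "attributes")
  gff <- utils::read.table(path, sep = "\t", comment.char = "#",
                           quote = "", col.names = cols,
                           colClasses = c("character", "character",
                                          "character", "integer", "integer",
                                          "character", "character",
                                          "character", "character"))
  gff <- gff[gff$type == feature, , drop = FALSE]
  ids <- sub("^.*ID=([^;]+).*$", "\\1", gff$attributes)
  data.frame(chrom = gff$chrom, start = gff$start, end = gff$end,
             gene_id = ids, stringsAsFactors = FALSE)
}

#' Read a panel definition TSV
#'
#' @param path TSV with at least `sample` and `species` columns.
#' @return data frame.
#' @export
read_panel <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = "character")
}
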