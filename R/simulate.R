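## Synthetic footprint generator.  Emulates the structure of a plastid
## ribosome-profiling experiment: several genotypes x replicates, footprint
## lengths with a mode at 31-33 nt, 3-nt periodicity set by a frame-fidelity
## parameter, and gene-specific codon-level pause sites whose height is
## genotype-dependent.  Everything is driven by one integer seed.

#' Build a toy plastid annotation (genome + ORFs)
#'
#' Genes are laid out left to right on alternating strands, separated by
#' `spacer_nt` of intergenic sequence (with a leading and trailing
#' spacer).  Each gene starts with ATG and ends with TAA in its own
#' orientation; intervening codons are random.  The first gene of length
#' 508 codons is named `"psbB"` (the scale of CP47), so stall-injection
#' tests have a realistic target; other genes are named `g01`, `g02`, ...
#'
#' @param n_genes number of genes
#' @param lengths_codons integer vector (recycled to `n_genes`) of gene
#'   lengths in codons; all must be >= 50 so peak calling has room
#' @param spacer_nt intergenic spacer length (>= 0)
#' @param seed integer seed for the random sequence
#' @return list with elements `genome` ([Biostrings::DNAStringSet], one
#'   sequence named `"plastome"`) and `orfs` (an [orf_table()])
#' @export
make_toy_annotation <- function(n_genes = 3L,
                                lengths_codons = c(100L, 508L, 80L),
                                spacer_nt = 50L, seed = 1L) {
  lengths_codons <- rep_len(as.integer(lengths_codons), n_genes)
  if (any(lengths_codons < 50L))
    stop("all gene lengths must be >= 50 codons")
  if (spacer_nt < 0L) stop("spacer_nt must be >= 0")
  lens_nt <- 3L * lengths_codons
  total <- (n_genes + 1L) * spacer_nt + sum(lens_nt)
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  seq_chr <- sample(bases, total, replace = TRUE)
  starts <- spacer_nt + cumsum(c(0L, lens_nt[-n_genes] + spacer_nt))
  ends <- starts + lens_nt
  strands <- rep(c("+", "-"), length.out = n_genes)
  for (i in seq_len(n_genes)) {
    if (strands[i] == "+") {
      seq_chr[starts[i] + 1:3] <- c("A", "T", "G")
      seq_chr[ends[i] - 2:0] <- c("T", "A", "A")
    } else {
      seq_chr[ends[i] - 2:0] <- c("C", "A", "T")  # revcomp of ATG
      seq_chr[starts[i] + 1:3] <- c("T", "T", "A")  # revcomp of TAA
    }
  }
  ids <- sprintf("g%02d", seq_len(n_genes))
  psbb_like <- which(lengths_codons == 508L)
  if (length(psbb_like)) ids[psbb_like[1]] <- "psbB"
  genome <- Biostrings::DNAStringSet(paste(seq_chr, collapse = ""))
  names(genome) <- "plastome"
  list(genome = genome,
       orfs = orf_table(gene_id = ids, seq_id = "plastome",
                        start = starts, end = ends, strand = strands))
}

#' Write a toy annotation to FASTA + GFF3
#'
#' @param annotation list from [make_toy_annotation()]
#' @param fasta_path,gff_path output paths
#' @return invisibly, a character vector of the two paths
#' @export
write_annotation <- function(annotation, fasta_path, gff_path) {
  Biostrings::writeXStringSet(annotation$genome, fasta_path)
  orfs <- annotation$orfs
  gr <- GenomicRanges::GRanges(
    seqnames = orfs$seq_id,
    ranges = IRanges::IRanges(start = orfs$start + 1L, end = orfs$end),
    strand = orfs$strand)
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- orfs$gene_id
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(c(fasta_path, gff_path))
}

#' Default footprint length distribution (mode 32 nt, support 28--36)
#'
#' Mirrors the typical plant chloroplast footprint profile with the bulk
#' of reads at 31--33 nt.
#' @return named numeric vector summing to 1
#' @export
default_length_dist <- function() {
  setNames(c(0.02, 0.05, 0.10, 0.18, 0.25, 0.18, 0.12, 0.07, 0.03),
           28:36)
}

#' Simulation configuration
#'
#' Full generative description of a synthetic dataset.  Multiplicative
#' pause and genotype effects act on codon sampling weights *before*
#' per-gene normalization, so a stall at one codon slightly depresses
#' normalized density elsewhere -- the same artifact that per-gene
#' normalization of real profiles produces.
#'
#' @param orfs an [orf_table()] (must have triplet lengths)
#' @param depth_per_gene expected footprint count per gene per sample
#'   (Poisson mean)
#' @param baseline_weights optional list `gene_id -> numeric vector`
#'   of per-codon relative occupancies (default uniform)
#' @param pause_map list `gene_id -> named numeric`, names = 1-based codon
#'   indices, values = stall multipliers (>= 1, or in (0,1] for depletion)
#' @param genotype_effects list `genotype -> list(gene_id -> named
#'   numeric)` of extra multipliers applied on top of `pause_map`;
#'   genotypes not listed (e.g. `"WT"`) have all effects equal to 1
#' @param replicate_noise_cv coefficient of variation of the lognormal
#'   noise applied per replicate to each pause/effect multiplier
#' @param length_dist named numeric distribution over footprint lengths
#' @param frame_fidelity probability a 5' end falls at the canonical
#'   offset from its codon; otherwise it is shifted +-1 nt equiprobably
#' @param psite_offset distance in nt from the 5' end to the P-site codon
#' @param genotypes genotype labels; defaults to `"WT"` plus the names of
#'   `genotype_effects`
#' @param n_replicates biological replicates per genotype
#' @param seed master integer seed
#' @return list of class `sim_config`
#' @export
sim_config <- function(orfs, depth_per_gene = 50000,
                       baseline_weights = NULL,
                       pause_map = list(),
                       genotype_effects = list(),
                       replicate_noise_cv = 0.05,
                       length_dist = default_length_dist(),
                       frame_fidelity = 0.9,
                       psite_offset = 12L,
                       genotypes = NULL,
                       n_replicates = 3L,
                       seed = 1L) {
  stopifnot(inherits(orfs, "orf_table"), depth_per_gene >= 0,
            frame_fidelity >= 0, frame_fidelity <= 1,
            psite_offset >= 0L, replicate_noise_cv >= 0)
  if (abs(sum(length_dist) - 1) > 1e-8)
    stop("length_dist must sum to 1")
  bad <- setdiff(names(pause_map), orfs$gene_id)
  if (length(bad))
    stop("pause_map gene(s) absent from annotation: ",
         paste(bad, collapse = ", "))
  for (g in names(genotype_effects)) {
    bad <- setdiff(names(genotype_effects[[g]]), orfs$gene_id)
    if (length(bad))
      stop("genotype_effects gene(s) absent from annotation: ",
           paste(bad, collapse = ", "))
  }
  mults <- c(unlist(pause_map), unlist(genotype_effects))
  if (length(mults) && any(mults <= 0))
    stop("all multipliers must be > 0")
  structure(list(orfs = orfs, depth_per_gene = depth_per_gene,
                 baseline_weights = baseline_weights,
                 pause_map = pause_map,
                 genotype_effects = genotype_effects,
                 replicate_noise_cv = replicate_noise_cv,
                 length_dist = length_dist,
                 frame_fidelity = frame_fidelity,
                 psite_offset = as.integer(psite_offset),
                 genotypes = genotypes %||%
                   union("WT", names(genotype_effects)),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default simulated experiment: psbB-like stalling in two mutants
#'
#' Three genotypes (WT, fpb1, pam68) x three replicates over the default
#' toy annotation.  The psbB-like gene carries five 3-codon pause regions
#' (centres at codons 8, 120, 210, 265 and 480; multipliers 6, 4, 4, 4
#' and 5), mimicking the initiation pause and pauses where transmembrane
#' segments emerge from the ribosomal exit tunnel.  The two mutants add
#' an extra multiplier (1.31 for fpb1, 1.42 for pam68) over the fifth
#' pause region, the signature of impaired co-translational insertion of
#' the last transmembrane segment.  The other genes carry mild pauses and
#' no genotype effect, so the genome-wide scan has true negatives.
#'
#' @param seed master seed
#' @param depth_per_gene expected footprints per gene per sample
#' @return a [sim_config()]
#' @export
default_experiment_config <- function(seed = 1L, depth_per_gene = 50000) {
  ann <- make_toy_annotation(seed = seed)
  region <- function(centre, m) setNames(rep(m, 3), centre + (-1:1))
  pause_map <- list(
    psbB = c(region(8, 6), region(120, 4), region(210, 4),
             region(265, 4), region(480, 5)),
    g01 = c(region(30, 3), region(70, 3)),
    g03 = region(40, 3))
  genotype_effects <- list(
    fpb1 = list(psbB = region(480, 1.31)),
    pam68 = list(psbB = region(480, 1.42)))
  cfg <- sim_config(ann$orfs, depth_per_gene = depth_per_gene,
                    pause_map = pause_map,
                    genotype_effects = genotype_effects,
                    seed = seed)
  cfg$genome <- ann$genome
  cfg
}

## Combined per-codon sampling weights for one gene in one sample,
## with per-replicate lognormal noise on each multiplier.
codon_weights <- function(config, gene_id, n_codons, genotype) {
  w <- config$baseline_weights[[gene_id]] %||% rep(1, n_codons)
  if (length(w) != n_codons)
    stop("baseline_weights for ", gene_id, " has wrong length")
  apply_mult <- function(w, mult) {
    idx <- as.integer(names(mult))
    if (any(idx < 1L | idx > n_codons))
      stop("pause codon index out of range for ", gene_id)
    cv <- config$replicate_noise_cv
    if (cv > 0) {
      s <- sqrt(log(1 + cv^2))
      mult <- mult * rlnorm(length(mult), meanlog = -s^2 / 2, sdlog = s)
    }
    w[idx] <- w[idx] * mult
    w
  }
  pm <- config$pause_map[[gene_id]]
  if (!is.null(pm)) w <- apply_mult(w, pm)
  ge <- config$genotype_effects[[genotype]][[gene_id]]
  if (!is.null(ge)) w <- apply_mult(w, ge)
  w
}

#' Simulate ribosome footprints for one (genotype, replicate) sample
#'
#' For each gene the footprint count is Poisson(`depth_per_gene`); each
#' footprint's codon is drawn from baseline x pause x genotype weights
#' (each multiplier perturbed once per replicate by lognormal noise with
#' the configured CV); the 5' end sits `psite_offset` nt upstream of the
#' codon start, shifted +-1 nt with probability `1 - frame_fidelity`;
#' the length is drawn from `length_dist`; the strand matches the gene.
#' The random stream is a deterministic function of
#' (`config$seed`, `genotype`, `replicate`).
#'
#' @param config a [sim_config()]
#' @param genotype genotype label (must be in `config$genotypes`)
#' @param replicate replicate index (>= 1)
#' @param sample_id label for the sample (default `genotype_replicate`)
#' @return a [footprint_table()]
#' @export
simulate_footprints <- function(config, genotype, replicate,
                                sample_id = paste0(genotype, "_", replicate)) {
  stopifnot(inherits(config, "sim_config"))
  if (!genotype %in% config$genotypes)
    stop("unknown genotype: ", genotype)
  if (replicate < 1L) stop("replicate index must be >= 1")
  set.seed(derive_seed(config$seed, genotype, replicate))
  orfs <- config$orfs
  lens <- as.numeric(names(config$length_dist))
  out <- vector("list", nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    orf <- orfs[i, ]
    if (!orf$triplet)
      stop("gene ", orf$gene_id, " has non-triplet length; the simulator ",
           "works at codon resolution")
    n_codons <- orf$length_nt %/% 3L
    w <- codon_weights(config, orf$gene_id, n_codons, genotype)
    n <- rpois(1L, config$depth_per_gene)
    if (n == 0L) next
    codon <- sample.int(n_codons, n, replace = TRUE, prob = w)
    rel5 <- 3L * (codon - 1L) - config$psite_offset
    off_frame <- runif(n) >= config$frame_fidelity
    n_off <- sum(off_frame)
    if (n_off)
      rel5[off_frame] <- rel5[off_frame] +
        sample(c(-1L, 1L), n_off, replace = TRUE)
    len <- sample(lens, n, replace = TRUE, prob = config$length_dist)
    if (orf$strand == "+") {
      fp5 <- orf$start + rel5
      start <- fp5
      end <- fp5 + len
    } else {
      fp5 <- orf$end - 1L - rel5
      end <- fp5 + 1L
      start <- end - len
    }
    keep <- start >= 0L
    out[[i]] <- data.frame(seq_id = orf$seq_id, start = start[keep],
                           end = end[keep], strand = orf$strand,
                           stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, out)
  if (is.null(all))
    return(footprint_table(character(0), integer(0), integer(0),
                           character(0), character(0)))
  footprint_table(all$seq_id, all$start, all$end, all$strand, sample_id)
}

#' Simulate a full multi-genotype experiment
#'
#' Runs [simulate_footprints()] for every genotype x replicate in the
#' configuration.  With `dir` set, writes the dataset to disk in the
#' pipeline's input formats: `genome.fasta`, `orfs.gff3`, one
#' `<genotype>_<rep>.bed` per sample, and `samples.tsv`.
#'
#' @param config a [sim_config()] (needs a `genome` element to write FASTA,
#'   e.g. from [default_experiment_config()])
#' @param dir optional output directory (created if missing)
#' @return list with `footprints` (one combined [footprint_table()]),
#'   `sample_sheet` (data.frame), and `dir` (or `NULL`)
#' @export
simulate_experiment <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  samples <- expand.grid(replicate = seq_len(config$n_replicates),
                         genotype = config$genotypes,
                         stringsAsFactors = FALSE)[, 2:1]
  samples$sample_id <- paste0(samples$genotype, "_", samples$replicate)
  fps <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples)))
    fps[[i]] <- simulate_footprints(config, samples$genotype[i],
                                    samples$replicate[i],
                                    samples$sample_id[i])
  footprints <- do.call(rbind, fps)
  class(footprints) <- c("footprint_table", "data.frame")
  sheet <- data.frame(sample_id = samples$sample_id,
                      genotype = samples$genotype,
                      replicate = samples$replicate,
                      path = paste0(samples$sample_id, ".bed"),
                      stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (is.null(config$genome))
      stop("config carries no genome sequence; cannot write FASTA")
    write_annotation(list(genome = config$genome, orfs = config$orfs),
                     file.path(dir, "genome.fasta"),
                     file.path(dir, "orfs.gff3"))
    for (i in seq_len(nrow(sheet)))
      write_footprints(fps[[i]], file.path(dir, sheet$path[i]))
    write.table(sheet, file.path(dir, "samples.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(footprints = footprints, sample_sheet = sheet, dir = dir)
}
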