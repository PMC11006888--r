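## Quantification: 5'-end assignment of footprints to ORFs, cpRPKM, and
## mutant/WT log2 ratios with replicate mean +- SD.

#' Assign footprints to ORFs by their 5' ends
#'
#' A footprint is assigned to the ORF that contains its 5' end on the
#' same strand (half-open containment: `start <= five_prime < end`).
#' When overlapping ORFs both contain the 5' end, the ORF whose start
#' codon is nearest upstream on the matching strand wins; remaining ties
#' go to the lexicographically smallest `gene_id`.  Every ambiguous
#' assignment is counted and reported via a message.
#'
#' @param footprints a [footprint_table()]
#' @param orfs an [orf_table()]
#' @return `footprints` with an added `gene_id` column (`NA` =
#'   unassigned) and attributes `n_unassigned` and `n_ambiguous`
#' @export
assign_to_orfs <- function(footprints, orfs) {
  gene <- rep(NA_character_, nrow(footprints))
  if (nrow(footprints) > 0L && nrow(orfs) > 0L) {
    lv <- union(unique(footprints$seq_id), unique(orfs$seq_id))
    q <- GenomicRanges::GRanges(
      factor(footprints$seq_id, levels = lv),
      IRanges::IRanges(start = footprints$five_prime + 1L, width = 1L),
      strand = footprints$strand)
    s <- GenomicRanges::GRanges(
      factor(orfs$seq_id, levels = lv),
      IRanges::IRanges(start = orfs$start + 1L, end = orfs$end),
      strand = orfs$strand)
    ov <- GenomicRanges::findOverlaps(q, s)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    ## distance from the 5' end to the containing ORF's start codon
    rel5 <- ifelse(orfs$strand[sh] == "+",
                   footprints$five_prime[qh] - orfs$start[sh],
                   orfs$end[sh] - 1L - footprints$five_prime[qh])
    ord <- order(qh, rel5, orfs$gene_id[sh])
    first <- !duplicated(qh[ord])
    gene[qh[ord][first]] <- orfs$gene_id[sh[ord]][first]
    n_ambiguous <- length(unique(qh[duplicated(qh)]))
    if (n_ambiguous > 0L)
      message(n_ambiguous, " footprint 5' end(s) inside multiple ORFs; ",
              "assigned to the nearest upstream start codon")
  } else {
    n_ambiguous <- 0L
  }
  out <- footprints
  out$gene_id <- gene
  attr(out, "n_unassigned") <- sum(is.na(gene))
  attr(out, "n_ambiguous") <- n_ambiguous
  class(out) <- c("footprint_table", "data.frame")
  out
}

#' Per-gene, per-sample footprint counts
#'
#' @param assigned output of [assign_to_orfs()]
#' @param orfs an [orf_table()]; every gene appears in the output, with
#'   zero counts where no footprint was assigned
#' @param sample_ids samples to tabulate (default: those present)
#' @return data.frame with columns `gene_id`, `sample_id`, `n`
#' @export
count_by_gene <- function(assigned, orfs,
                          sample_ids = unique(assigned$sample_id)) {
  grid <- expand.grid(gene_id = orfs$gene_id, sample_id = sample_ids,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  hit <- assigned[!is.na(assigned$gene_id), c("gene_id", "sample_id")]
  if (nrow(hit)) {
    tab <- aggregate(list(n = rep(1L, nrow(hit))), hit, FUN = sum)
    grid$n <- tab$n[match(paste(grid$gene_id, grid$sample_id),
                          paste(tab$gene_id, tab$sample_id))]
    grid$n[is.na(grid$n)] <- 0L
  } else {
    grid$n <- 0L
  }
  grid <- grid[order(grid$sample_id, grid$gene_id), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' cpRPKM: reads per kb of ORF per million reads in all chloroplast ORFs
#'
#' For gene g in one sample, `cpRPKM_g = n_g / ((L_g/1000) * (N/10^6))`
#' where `N` is the total count assigned to ORFs in that sample (reads
#' not assigned to any ORF do not contribute to `N`).  The formula
#' telescopes: `sum_g cpRPKM_g * L_g/1000 = 10^6` for every sample.
#'
#' @param gene_counts data.frame from [count_by_gene()]
#' @param orfs an [orf_table()] supplying ORF lengths
#' @return data.frame with columns `gene_id`, `sample_id`, `n`,
#'   `cp_rpkm`
#' @export
compute_cp_rpkm <- function(gene_counts, orfs) {
  len <- orfs$length_nt[match(gene_counts$gene_id, orfs$gene_id)]
  if (anyNA(len))
    stop("gene(s) in counts absent from ORF table: ",
         paste(unique(gene_counts$gene_id[is.na(len)]), collapse = ", "))
  totals <- tapply(gene_counts$n, gene_counts$sample_id, sum)
  if (any(totals == 0))
    stop("no ORF-assigned reads in sample(s): ",
         paste(names(totals)[totals == 0], collapse = ", "))
  n_total <- as.numeric(totals[gene_counts$sample_id])
  out <- gene_counts
  out$cp_rpkm <- out$n / ((len / 1000) * (n_total / 1e6))
  out
}

#' Mutant/WT log2 cpRPKM ratios with replicate mean and SD
#'
#' The wild-type reference for each gene is the mean cpRPKM over WT
#' replicates (`ratio_mode = "mean_ref"`); with `"paired"`, mutant
#' replicate r is divided by WT replicate r instead.  Genes where any
#' involved sample (WT or that genotype) has fewer than `min_reads` raw
#' assigned reads are flagged excluded -- computed but never silently
#' dropped -- as are genes whose WT reference is zero.
#'
#' @param quants data.frame from [compute_cp_rpkm()] (all samples)
#' @param sample_sheet data.frame with `sample_id`, `genotype`,
#'   `replicate`; genotype `"WT"` is the reference
#' @param min_reads exclusion threshold on raw per-sample counts
#'   (default 200)
#' @param ratio_mode `"mean_ref"` or `"paired"`
#' @return data.frame of class `ratio_table`: `gene_id`, `genotype`,
#'   `mean_log2`, `sd_log2`, `n_replicates`, `excluded`, `reason`, plus
#'   a list column `log2_ratios` with the per-replicate values
#' @export
genotype_log2_ratios <- function(quants, sample_sheet, min_reads = 200,
                                 ratio_mode = c("mean_ref", "paired")) {
  ratio_mode <- match.arg(ratio_mode)
  stopifnot(min_reads >= 0)
  wt <- sample_sheet[sample_sheet$genotype == "WT", , drop = FALSE]
  if (nrow(wt) == 0L) stop("sample sheet contains no WT sample")
  muts <- setdiff(unique(sample_sheet$genotype), "WT")
  genes <- unique(quants$gene_id)
  get <- function(gene, ids, col)
    quants[[col]][match(paste(gene, ids), paste(quants$gene_id,
                                                quants$sample_id))]
  rows <- list()
  for (g in genes) {
    wt_cp <- get(g, wt$sample_id, "cp_rpkm")
    wt_ref <- mean(wt_cp)
    for (m in muts) {
      ms <- sample_sheet[sample_sheet$genotype == m, , drop = FALSE]
      ms <- ms[order(ms$replicate), , drop = FALSE]
      mut_cp <- get(g, ms$sample_id, "cp_rpkm")
      counts <- c(get(g, wt$sample_id, "n"), get(g, ms$sample_id, "n"))
      excluded <- FALSE; reason <- ""
      if (ratio_mode == "paired") {
        wt_ord <- wt[order(wt$replicate), , drop = FALSE]
        if (!identical(wt_ord$replicate, ms$replicate))
          stop("paired ratio_mode needs matching WT/mutant replicate ",
               "indices")
        ref <- get(g, wt_ord$sample_id, "cp_rpkm")
      } else {
        ref <- rep(wt_ref, length(mut_cp))
      }
      if (any(counts < min_reads)) {
        excluded <- TRUE
        reason <- paste0("raw count below ", min_reads)
      }
      if (all(ref == 0)) {
        excluded <- TRUE; reason <- "WT zero"
        lr <- rep(NA_real_, length(mut_cp))
      } else {
        lr <- log2(mut_cp / ref)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, genotype = m,
        mean_log2 = mean(lr),
        sd_log2 = if (length(lr) >= 2L) sd(lr) else NA_real_,
        n_replicates = length(lr),
        excluded = excluded, reason = reason,
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$log2_ratios <- I(list(lr))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ratio_table", "data.frame")
  out
}
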