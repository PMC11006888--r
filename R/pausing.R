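## Pause-site detection: per-ORF coverage profiles normalized by total
## gene reads, codon-level major-peak calling, replicate-based relative
## peak-height ratios between genotypes, a plastid genome-wide scan, and
## mapping of pause positions to ribosome exit-tunnel emergence.

#' Per-nucleotide footprint coverage along one ORF
#'
#' Positions are ORF-relative, 0-based, 5'->3' in the gene's own
#' orientation; each footprint contributes one count at its (optionally
#' P-site-shifted) 5' end.  Footprints landing outside `[0, L)` after
#' the offset are dropped and counted.
#'
#' @param footprints a [footprint_table()], typically pre-filtered to one
#'   gene via [assign_to_orfs()]; reads on the wrong strand or whose 5'
#'   end lies outside the ORF are dropped
#' @param orf single-row subset of an [orf_table()]
#' @param offset_nt shift applied to the ORF-relative 5' end (default 0 =
#'   raw 5' end; set to the P-site offset for codon-aligned profiles)
#' @return object of class `coverage_profile`: list with `gene_id`,
#'   `sample_id`, `values` (integer vector of length `L`), `total`, and
#'   `n_dropped`
#' @export
build_profile <- function(footprints, orf, offset_nt = 0L) {
  stopifnot(nrow(orf) == 1L, offset_nt >= 0L)
  L <- orf$length_nt
  fp <- footprints[footprints$strand == orf$strand &
                     footprints$seq_id == orf$seq_id, , drop = FALSE]
  rel5 <- if (orf$strand == "+") fp$five_prime - orf$start
          else orf$end - 1L - fp$five_prime
  pos <- rel5 + offset_nt
  inside <- rel5 >= 0L & rel5 < L
  pos <- pos[inside]
  usable <- pos >= 0L & pos < L
  values <- tabulate(pos[usable] + 1L, nbins = L)
  structure(list(gene_id = orf$gene_id,
                 sample_id = paste(unique(footprints$sample_id),
                                   collapse = "+"),
                 values = values, total = sum(values),
                 n_dropped = sum(!usable)),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("Coverage profile for", x$gene_id, "(", x$sample_id, "):",
      x$total, "reads over", length(x$values), "nt\n")
  invisible(x)
}

#' Normalize a coverage profile by its total reads
#'
#' @param profile a [build_profile()] result with `total > 0`
#' @return object of class `normalized_profile`: list with `gene_id`,
#'   `sample_id` and `density` summing to 1
#' @export
normalize_profile <- function(profile) {
  if (profile$total <= 0L)
    stop("no coverage on ", profile$gene_id, ": cannot normalize")
  structure(list(gene_id = profile$gene_id, sample_id = profile$sample_id,
                 density = profile$values / profile$total),
            class = "normalized_profile")
}

#' Aggregate a per-nucleotide density to codon resolution
#' @param density numeric vector of length divisible by 3
#' @return numeric vector of per-codon density (sum of the 3 nt)
#' @export
codon_density <- function(density) {
  if (length(density) %% 3L != 0L)
    stop("density length not divisible by 3 (non-triplet ORF)")
  colSums(matrix(density, nrow = 3L))
}

#' Centered moving average with truncated edges
#' @param x numeric vector
#' @param k odd window width in codons (`k = 1` is the identity)
#' @return smoothed vector of the same length
#' @export
smooth_density <- function(x, k = 3L) {
  stopifnot(k >= 1L, k %% 2L == 1L)
  if (k == 1L) return(x)
  n <- length(x)
  half <- k %/% 2L
  ## direct window sums (not cumsum differences): exact ties in the
  ## input stay exact ties in the output, which peak plateaus rely on
  vapply(seq_len(n), function(i) {
    w <- max(1L, i - half):min(n, i + half)
    sum(x[w]) / length(w)
  }, numeric(1))
}

## Plateau-aware local maxima: 5'-most codon of every run of equal values
## that is strictly higher than both flanking values (signal boundaries
## count as -Inf).
local_maxima <- function(s) {
  n <- length(s)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  left <- c(-Inf, r$values[-k])
  right <- c(r$values[-1L], -Inf)
  starts[r$values > left & r$values > right]
}

## Topographic prominence of a candidate peak at index i: on each side,
## walk to the nearest strictly higher point (or the signal edge); the
## base on that side is the minimum in between; prominence is the height
## above the higher of the two bases.
peak_prominence <- function(s, i) {
  n <- length(s)
  h <- s[i]
  left_hi <- which(s[seq_len(i - 1L)] > h)
  lo <- if (length(left_hi)) max(left_hi) + 1L else 1L
  left_base <- min(s[lo:i])
  right_hi <- which(s[seq(i, n)] > h) + i - 1L
  hi <- if (length(right_hi)) min(right_hi) - 1L else n
  right_base <- min(s[i:hi])
  h - max(left_base, right_base)
}

#' Call major pause peaks on a normalized profile
#'
#' The density is aggregated to codon resolution, smoothed by a centered
#' moving average, and candidate peaks (plateau-aware local maxima) are
#' kept when their topographic prominence reaches
#' `min_prominence_frac x global maximum`.  Candidates closer than
#' `min_sep_codons` are merged keeping the higher (ties: 5'-most), the
#' `top_k` highest survive, and survivors are labelled with roman
#' numerals in 5'->3' order (`psbB-I`, `psbB-II`, ...).  A flat profile
#' yields zero peaks.
#'
#' @param profile a [normalize_profile()] result (triplet-length gene)
#' @param smooth_codons moving-average window in codons (odd, default 3)
#' @param min_prominence_frac prominence threshold as a fraction of the
#'   smoothed global maximum (default 0.25)
#' @param min_sep_codons minimum separation between called peaks
#'   (default 9)
#' @param top_k maximum number of peaks returned (default 6)
#' @return data.frame of class `peak_table`: `gene_id`, `label`,
#'   `codon_index` (1-based), `position_nt` (0-based), `height` (smoothed
#'   codon density), `prominence`, `rank` (1 = highest)
#' @export
call_major_peaks <- function(profile, smooth_codons = 3L,
                             min_prominence_frac = 0.25,
                             min_sep_codons = 9L, top_k = 6L) {
  stopifnot(min_prominence_frac > 0, min_prominence_frac <= 1,
            min_sep_codons >= 1L, top_k >= 1L)
  s <- smooth_density(codon_density(profile$density), smooth_codons)
  empty <- data.frame(gene_id = character(0), label = character(0),
                      codon_index = integer(0), position_nt = integer(0),
                      height = numeric(0), prominence = numeric(0),
                      rank = integer(0), stringsAsFactors = FALSE)
  class(empty) <- c("peak_table", "data.frame")
  if (max(s) == min(s)) return(empty)
  cand <- local_maxima(s)
  prom <- vapply(cand, function(i) peak_prominence(s, i), numeric(1))
  keep <- prom >= min_prominence_frac * max(s)
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) == 0L) return(empty)
  ## merge close candidates: greedily keep from the highest down
  ord <- order(-s[cand], cand)
  kept <- integer(0); kept_prom <- numeric(0)
  for (j in ord) {
    if (all(abs(cand[j] - kept) >= min_sep_codons)) {
      kept <- c(kept, cand[j]); kept_prom <- c(kept_prom, prom[j])
    }
  }
  if (length(kept) > top_k) {
    sel <- order(-s[kept], kept)[seq_len(top_k)]
    kept <- kept[sel]; kept_prom <- kept_prom[sel]
  }
  pos_ord <- order(kept)
  kept <- kept[pos_ord]; kept_prom <- kept_prom[pos_ord]
  out <- data.frame(gene_id = profile$gene_id,
                    label = roman_labels(profile$gene_id, length(kept)),
                    codon_index = kept,
                    position_nt = 3L * (kept - 1L),
                    height = s[kept],
                    prominence = kept_prom,
                    rank = rank(-s[kept], ties.method = "first"),
                    stringsAsFactors = FALSE)
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Peak height of one sample's profile near a given codon
#'
#' @param profile a [normalize_profile()] result
#' @param codon_index 1-based codon position of the peak
#' @param match_window_codons half-width of the matching window; the
#'   height is the maximum smoothed codon density within
#'   `codon_index +- match_window_codons` (0 = exactly at the codon)
#' @param smooth_codons smoothing window, as in [call_major_peaks()]
#' @return numeric height
#' @export
peak_height <- function(profile, codon_index, match_window_codons = 1L,
                        smooth_codons = 3L) {
  s <- smooth_density(codon_density(profile$density), smooth_codons)
  lo <- max(1L, codon_index - match_window_codons)
  hi <- min(length(s), codon_index + match_window_codons)
  max(s[lo:hi])
}

#' Relative peak-height ratio between mutant and WT replicates
#'
#' Each profile is individually normalized, so the statistic compares
#' the *share* of a gene's ribosomes sitting at the peak, not raw
#' abundance.  The WT reference is the mean height over WT replicates;
#' each mutant replicate contributes one ratio, summarized as mean +-
#' sample SD (n - 1 denominator).
#'
#' @param wt_profiles list of [normalize_profile()] results (>= 1)
#' @param mut_profiles list of [normalize_profile()] results (>= 1)
#' @param codon_index peak codon (1-based), typically from
#'   [call_major_peaks()] on the pooled-WT profile
#' @param match_window_codons,smooth_codons see [peak_height()]
#' @param label,genotype optional metadata carried into the result
#' @return object of class `peak_ratio`: list with `label`, `genotype`,
#'   `codon_index`, `ratios` (per mutant replicate), `mean`, `sd`, `n`
#' @export
peak_ratio <- function(wt_profiles, mut_profiles, codon_index,
                       match_window_codons = 1L, smooth_codons = 3L,
                       label = NA_character_, genotype = NA_character_) {
  stopifnot(length(wt_profiles) >= 1L, length(mut_profiles) >= 1L)
  h <- function(p) peak_height(p, codon_index, match_window_codons,
                               smooth_codons)
  wt_ref <- mean(vapply(wt_profiles, h, numeric(1)))
  if (wt_ref == 0)
    stop("peak absent in WT (zero reference height) at codon ",
         codon_index)
  ratios <- vapply(mut_profiles, h, numeric(1)) / wt_ref
  structure(list(label = label, genotype = genotype,
                 codon_index = codon_index, ratios = ratios,
                 mean = mean(ratios),
                 sd = if (length(ratios) >= 2L) sd(ratios) else NA_real_,
                 n = length(ratios)),
            class = "peak_ratio")
}

#' @export
print.peak_ratio <- function(x, ...) {
  cat(sprintf("Peak %s (%s), codon %d: ratio %.3f +- %.3f (n = %d)\n",
              x$label, x$genotype, x$codon_index, x$mean,
              if (is.na(x$sd)) 0 else x$sd, x$n))
  invisible(x)
}

## Normalized profiles per sample for one gene; NULL when a sample has
## no coverage on the gene.
sample_profiles <- function(assigned, orf, sample_ids, offset_nt = 0L) {
  lapply(sample_ids, function(sid) {
    fp <- assigned[!is.na(assigned$gene_id) &
                     assigned$gene_id == orf$gene_id &
                     assigned$sample_id == sid, , drop = FALSE]
    p <- build_profile(fp, orf, offset_nt)
    if (p$total == 0L) return(NULL)
    p$sample_id <- sid
    normalize_profile(p)
  })
}

#' Plastid genome-wide stall scan
#'
#' For every triplet-length gene passing `min_reads` raw assigned reads
#' in all samples, peaks are called on the pooled wild-type profile and
#' the relative height ratio of every peak is computed for each mutant
#' genotype.  Rows are sorted by mean ratio, descending, within
#' genotype; genes that could not be scanned are recorded with reasons
#' in the `excluded` attribute, never silently dropped.
#'
#' @param footprints a [footprint_table()] covering all samples
#' @param orfs an [orf_table()]
#' @param sample_sheet data.frame with `sample_id`, `genotype`,
#'   `replicate` (genotype `"WT"` is the reference)
#' @param min_reads per-sample raw-count threshold (default 200)
#' @param offset_nt profile offset, see [build_profile()]
#' @param smooth_codons,min_prominence_frac,min_sep_codons,top_k peak
#'   parameters, see [call_major_peaks()]
#' @param match_window_codons height-matching window, see [peak_ratio()]
#' @return data.frame of class `stall_scan`: `gene_id`, `label`,
#'   `codon_index`, `genotype`, `mean_ratio`, `sd_ratio`,
#'   `n_replicates`, `wt_height`, plus per-replicate ratios in the list
#'   column `ratios`; attribute `excluded` is a data.frame
#'   (`gene_id`, `reason`)
#' @export
genome_wide_scan <- function(footprints, orfs, sample_sheet,
                             min_reads = 200, offset_nt = 0L,
                             smooth_codons = 3L,
                             min_prominence_frac = 0.25,
                             min_sep_codons = 9L, top_k = 6L,
                             match_window_codons = 1L) {
  wt_ids <- sample_sheet$sample_id[sample_sheet$genotype == "WT"]
  if (length(wt_ids) == 0L) stop("sample sheet contains no WT sample")
  mut_types <- setdiff(unique(sample_sheet$genotype), "WT")
  if (length(mut_types) == 0L)
    warning("no mutant samples: scan table is empty")
  assigned <- assign_to_orfs(footprints, orfs)
  counts <- count_by_gene(assigned, orfs, sample_sheet$sample_id)
  rows <- list(); excl <- list()
  for (gi in seq_len(nrow(orfs))) {
    orf <- orfs[gi, ]
    g <- orf$gene_id
    if (!orf$triplet) {
      excl[[g]] <- "non-triplet ORF length"
      next
    }
    if (any(counts$n[counts$gene_id == g] < min_reads)) {
      excl[[g]] <- paste0("raw count below ", min_reads,
                          " in at least one sample")
      next
    }
    wt_fp <- assigned[!is.na(assigned$gene_id) & assigned$gene_id == g &
                        assigned$sample_id %in% wt_ids, , drop = FALSE]
    pooled <- normalize_profile(build_profile(wt_fp, orf, offset_nt))
    peaks <- call_major_peaks(pooled, smooth_codons, min_prominence_frac,
                              min_sep_codons, top_k)
    if (nrow(peaks) == 0L) {
      excl[[g]] <- "no major peak in pooled WT"
      next
    }
    wt_profiles <- sample_profiles(assigned, orf, wt_ids, offset_nt)
    for (m in mut_types) {
      m_ids <- sample_sheet$sample_id[sample_sheet$genotype == m]
      mut_profiles <- sample_profiles(assigned, orf, m_ids, offset_nt)
      for (pi in seq_len(nrow(peaks))) {
        pr <- peak_ratio(wt_profiles, mut_profiles,
                         peaks$codon_index[pi], match_window_codons,
                         smooth_codons, label = peaks$label[pi],
                         genotype = m)
        row <- data.frame(gene_id = g, label = pr$label,
                          codon_index = pr$codon_index, genotype = m,
                          mean_ratio = pr$mean, sd_ratio = pr$sd,
                          n_replicates = pr$n,
                          wt_height = peaks$height[pi],
                          stringsAsFactors = FALSE)
        row$ratios <- I(list(pr$ratios))
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), label = character(0),
               codon_index = integer(0), genotype = character(0),
               mean_ratio = numeric(0), sd_ratio = numeric(0),
               n_replicates = integer(0), wt_height = numeric(0),
               stringsAsFactors = FALSE)
  ord <- order(out$genotype, -out$mean_ratio)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- data.frame(
    gene_id = if (length(excl)) names(excl) else character(0),
    reason = unlist(excl, use.names = FALSE) %||% character(0),
    stringsAsFactors = FALSE)
  class(out) <- c("stall_scan", "data.frame")
  out
}

#' @export
print.stall_scan <- function(x, n = 10L, ...) {
  cat("Genome-wide stall scan:", nrow(x), "(gene, peak, genotype) rows\n")
  excl <- attr(x, "excluded")
  if (!is.null(excl) && nrow(excl))
    cat("Excluded genes:", paste(excl$gene_id, collapse = ", "), "\n")
  if (nrow(x)) {
    cat("Top ratios:\n")
    print.data.frame(head(x[, c("gene_id", "label", "codon_index",
                                "genotype", "mean_ratio", "sd_ratio")],
                          n), digits = 4)
  }
  invisible(x)
}

#' Map a pause peak to the residue emerging from the ribosome exit tunnel
#'
#' The nascent chain occupies roughly `tunnel_len_codons` residues
#' between the P-site and the tunnel exit, so a ribosome paused with its
#' P-site at codon c has residue `c - tunnel_len_codons` just emerging.
#' With a transmembrane-domain table, the emerging residue is mapped to
#' the TMD (or inter-TMD loop) that contains it.
#'
#' @param codon_index peak codon (1-based, P-site position)
#' @param tunnel_len_codons exit-tunnel length in codons (default 33;
#'   structural estimates span roughly 30--40)
#' @param tmd_table optional data.frame with columns `tmd_label`,
#'   `start_residue`, `end_residue` (1-based, inclusive, non-overlapping)
#' @return list of class `tunnel_mapping`: `codon_index`,
#'   `emerging_residue` (`NA` when the chain is still inside the tunnel)
#'   and `emerging_feature` (TMD label, `"loop"`, or `NA`)
#' @export
map_peak_to_tunnel <- function(codon_index, tunnel_len_codons = 33L,
                               tmd_table = NULL) {
  stopifnot(tunnel_len_codons >= 0L, codon_index >= 1L)
  res <- codon_index - tunnel_len_codons
  if (res < 1L) res <- NA_integer_
  feature <- NA_character_
  if (!is.null(tmd_table)) {
    validate_tmd_table(tmd_table)
    if (!is.na(res)) {
      hit <- which(tmd_table$start_residue <= res &
                     res <= tmd_table$end_residue)
      feature <- if (length(hit)) tmd_table$tmd_label[hit] else "loop"
    }
  }
  structure(list(codon_index = codon_index,
                 emerging_residue = as.integer(res),
                 emerging_feature = feature),
            class = "tunnel_mapping")
}

validate_tmd_table <- function(tmd_table, protein_len = NULL) {
  need <- c("tmd_label", "start_residue", "end_residue")
  if (!all(need %in% names(tmd_table)))
    stop("TMD table needs columns: ", paste(need, collapse = ", "))
  if (any(tmd_table$start_residue < 1L) ||
      any(tmd_table$start_residue > tmd_table$end_residue))
    stop("invalid TMD interval(s)")
  if (!is.null(protein_len) && any(tmd_table$end_residue > protein_len))
    stop("TMD interval(s) beyond protein length ", protein_len)
  o <- order(tmd_table$start_residue)
  s <- tmd_table$start_residue[o]; e <- tmd_table$end_residue[o]
  if (any(s[-1] <= e[-length(e)]))
    stop("overlapping TMD intervals")
  invisible(TRUE)
}

#' Read a TMD table (TSV: tmd_label, start_residue, end_residue)
#' @param path TSV file path
#' @return validated data.frame
#' @export
read_tmd_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_tmd_table(tab)
  tab
}
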