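## Library QC: footprint length distribution and 3-nt periodicity.

#' Footprint length distribution
#'
#' A healthy chloroplast ribosome-profiling library shows a length mode
#' in the low thirties (peak at 31--33 nt).
#'
#' @param footprints a [footprint_table()]
#' @return object of class `length_hist`: list with `counts` (named
#'   integer vector, one entry per observed length), `mode_length`
#'   (`NA` for empty input; ties resolved to the smallest length) and
#'   `total`
#' @export
length_distribution <- function(footprints) {
  counts <- table(footprints$length_nt)
  counts <- setNames(as.integer(counts), names(counts))
  mode_length <- if (length(counts) == 0L) NA_integer_ else
    as.integer(names(counts)[which.max(counts)])
  structure(list(counts = counts, mode_length = mode_length,
                 total = sum(counts)),
            class = "length_hist")
}

#' @export
print.length_hist <- function(x, ...) {
  cat("Footprint length histogram:", x$total, "footprints\n")
  if (is.na(x$mode_length)) cat("  (empty: no mode)\n")
  else cat("  mode:", x$mode_length, "nt\n")
  invisible(x)
}

#' @export
as.data.frame.length_hist <- function(x, ...) {
  data.frame(length_nt = as.integer(names(x$counts)),
             count = unname(x$counts))
}

## ORF-relative 5' position of each footprint, NA when the 5' end is not
## inside a same-strand ORF.  Minus-strand positions are measured from the
## gene's own start codon (biological frame is gene-relative).
orf_relative_five_prime <- function(footprints, orfs) {
  gene <- assign_to_orfs(footprints, orfs)$gene_id
  idx <- match(gene, orfs$gene_id)
  ifelse(orfs$strand[idx] == "+",
         footprints$five_prime - orfs$start[idx],
         orfs$end[idx] - 1L - footprints$five_prime)
}

#' 3-nt periodicity of footprint 5' ends
#'
#' Reads whose 5' end lies inside a same-strand ORF of triplet length are
#' classified by `(orf_relative_5' + psite_offset) mod 3`; frame 0 is the
#' canonical frame.  Minus-strand positions are measured from the gene's
#' own start codon.  Ribosomes translocate three nucleotides at a time,
#' so a dominant frame-0 fraction is the expected signature.
#'
#' @param footprints a [footprint_table()]
#' @param orfs an [orf_table()]; non-triplet ORFs are ignored
#' @param psite_offset offset in nt making the canonical frame explicit
#'   (default 12, the conventional P-site distance for ~31-nt footprints)
#' @return object of class `frame_fractions`: list with `f0`, `f1`, `f2`
#'   (summing to 1) and `n_used`
#' @export
frame_periodicity <- function(footprints, orfs, psite_offset = 12L) {
  stopifnot(psite_offset >= 0L)
  use_orfs <- orfs[orfs$triplet, , drop = FALSE]
  rel5 <- orf_relative_five_prime(footprints, use_orfs)
  rel5 <- rel5[!is.na(rel5)]
  if (length(rel5) == 0L)
    stop("no footprint 5' ends inside triplet-length ORFs; ",
         "periodicity QC impossible")
  fr <- (rel5 + psite_offset) %% 3L
  f <- tabulate(fr + 1L, nbins = 3L) / length(fr)
  structure(list(f0 = f[1], f1 = f[2], f2 = f[3], n_used = length(fr)),
            class = "frame_fractions")
}

#' @export
print.frame_fractions <- function(x, ...) {
  cat(sprintf("Frame fractions (n = %d): f0 = %.3f, f1 = %.3f, f2 = %.3f\n",
              x$n_used, x$f0, x$f1, x$f2))
  invisible(x)
}

#' @export
as.data.frame.frame_fractions <- function(x, ...) {
  data.frame(frame = 0:2, fraction = c(x$f0, x$f1, x$f2),
             n_used = x$n_used)
}
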