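## I/O layer: genome (FASTA), ORF annotation (GFF3), footprints (BED6),
## sample sheet (TSV).  Everything downstream works on plain data.frames
## in 0-based half-open coordinates; conversion happens only here.

#' Read a genome sequence from FASTA
#'
#' @param path path to a FASTA file
#' @return a [Biostrings::DNAStringSet]; names are truncated at the first
#'   whitespace so they match GFF3/BED `seqid` fields
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (length(seqs) == 0L || any(Biostrings::width(seqs) == 0L))
    stop("empty genome sequence in ", path)
  seqs
}

#' Construct / validate an ORF table
#'
#' Internal coordinates are 0-based half-open, so `length_nt = end - start`.
#' ORFs whose length is not a multiple of 3 are kept but flagged
#' (`triplet = FALSE`); codon-level operations refuse them.
#'
#' @param gene_id,seq_id,start,end,strand vectors of equal length
#' @return data.frame of class `orf_table`, sorted by (seq_id, start)
#' @export
orf_table <- function(gene_id, seq_id, start, end, strand) {
  df <- data.frame(gene_id = as.character(gene_id),
                   seq_id = as.character(seq_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  if (any(df$start < 0L) || any(df$start >= df$end))
    stop("invalid ORF coordinates: need 0 <= start < end")
  if (!all(df$strand %in% c("+", "-")))
    stop("ORF strand must be '+' or '-'")
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in ORF table: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  df$length_nt <- df$end - df$start
  df$triplet <- df$length_nt %% 3L == 0L
  df <- df[order(df$seq_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("orf_table", "data.frame")
  df
}

#' Load plastid ORF annotation from GFF3 (with optional genome check)
#'
#' GFF3 coordinates are 1-based inclusive and are converted to the
#' internal 0-based half-open convention.  The plastid genome is treated
#' as linear: ORFs extending past the sequence end (e.g. wrapping the
#' origin of a circular genome) are rejected.
#'
#' @param gff_path path to a GFF3 file
#' @param genome optional [Biostrings::DNAStringSet] from [read_genome()];
#'   if supplied, seqids must match and ORFs must fit inside the sequence
#' @param feature_type GFF3 feature type to select (default `"CDS"`)
#' @param id_attr attribute holding the gene identifier (default `"ID"`)
#' @return an [orf_table()]
#' @export
load_annotation <- function(gff_path, genome = NULL, feature_type = "CDS",
                            id_attr = "ID") {
  if (!file.exists(gff_path)) stop("GFF3 file not found: ", gff_path)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_type]
  if (length(gr) == 0L)
    stop("no '", feature_type, "' features in ", gff_path)
  ids <- as.character(S4Vectors::mcols(gr)[[id_attr]])
  if (length(ids) != length(gr))
    stop("GFF3 features lack the '", id_attr, "' attribute entirely")
  if (anyNA(ids) || any(!nzchar(ids))) {
    bad <- which(is.na(ids) | !nzchar(ids))
    stop("GFF3 record(s) ", paste(bad, collapse = ", "),
         " (in feature order) lack the '", id_attr, "' attribute")
  }
  orfs <- orf_table(gene_id = ids,
                    seq_id = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)))
  if (!is.null(genome)) {
    unknown <- setdiff(orfs$seq_id, names(genome))
    if (length(unknown))
      stop("GFF3 seqid(s) absent from the genome FASTA: ",
           paste(unknown, collapse = ", "))
    lim <- Biostrings::width(genome)[match(orfs$seq_id, names(genome))]
    over <- orfs$end > lim
    if (any(over))
      stop("ORF(s) extend past the sequence end (circular wrap is not ",
           "supported): ", paste(orfs$gene_id[over], collapse = ", "))
  }
  orfs
}

#' Construct / validate a footprint table
#'
#' One row per ribosome-protected fragment.  The 5' end is derived from
#' the strand: `start` for `+`, `end - 1` for `-` (0-based).
#'
#' @param seq_id,start,end,strand,sample_id vectors of equal length
#' @return data.frame of class `footprint_table` with columns `seq_id`,
#'   `start`, `end`, `strand`, `length_nt`, `five_prime`, `sample_id`
#' @export
footprint_table <- function(seq_id, start, end, strand, sample_id) {
  df <- data.frame(seq_id = as.character(seq_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   sample_id = as.character(sample_id),
                   stringsAsFactors = FALSE)
  if (nrow(df) && any(df$start >= df$end))
    stop("footprint with start >= end")
  if (nrow(df) && !all(df$strand %in% c("+", "-")))
    stop("footprint strand must be '+' or '-'")
  df$length_nt <- df$end - df$start
  df$five_prime <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df <- df[, c("seq_id", "start", "end", "strand", "length_nt",
               "five_prime", "sample_id")]
  class(df) <- c("footprint_table", "data.frame")
  df
}

#' Load ribosome footprints from BED6 with a length filter
#'
#' The default filter 20--40 nt corresponds to the insert-size range of
#' typical ribosome-profiling libraries; records outside the bounds are
#' dropped and the dropped count is reported (message + attribute
#' `n_filtered`).
#'
#' @param bed_path path to a BED6 file (score column ignored)
#' @param sample_id sample label attached to every footprint
#' @param length_min,length_max inclusive length bounds in nt
#' @return a [footprint_table()]; attribute `n_filtered` holds the number
#'   of records removed by the length filter
#' @export
load_footprints <- function(bed_path, sample_id, length_min = 20L,
                            length_max = 40L) {
  if (!file.exists(bed_path)) stop("BED file not found: ", bed_path)
  stopifnot(length_min >= 1L, length_min <= length_max)
  if (file.size(bed_path) == 0L) {
    warning("empty BED file: ", bed_path)
    fp <- footprint_table(character(0), integer(0), integer(0),
                          character(0), character(0))
    attr(fp, "n_filtered") <- 0L
    return(fp)
  }
  gr <- tryCatch(rtracklayer::import(bed_path, format = "bed"),
                 error = function(e)
                   stop("malformed BED file ", bed_path, ": ",
                        conditionMessage(e), call. = FALSE))
  if (any(as.character(GenomicRanges::strand(gr)) == "*"))
    stop("BED6 strand column required (found records without strand) in ",
         bed_path)
  fp <- footprint_table(seq_id = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr) - 1L,
                        end = GenomicRanges::end(gr),
                        strand = as.character(GenomicRanges::strand(gr)),
                        sample_id = sample_id)
  keep <- fp$length_nt >= length_min & fp$length_nt <= length_max
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    message(n_drop, " footprint(s) outside [", length_min, ", ",
            length_max, "] nt dropped from ", bed_path)
  fp <- fp[keep, , drop = FALSE]
  rownames(fp) <- NULL
  class(fp) <- c("footprint_table", "data.frame")
  attr(fp, "n_filtered") <- n_drop
  fp
}

#' Write footprints to BED6
#'
#' @param footprints a [footprint_table()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_footprints <- function(footprints, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = footprints$seq_id,
    ranges = IRanges::IRanges(start = footprints$start + 1L,
                              end = footprints$end),
    strand = footprints$strand)
  gr$name <- rep(".", length(gr))
  gr$score <- rep(0L, length(gr))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a sample sheet (TSV: sample_id, genotype, replicate, path)
#'
#' @param path TSV file with a header line
#'   `sample_id genotype replicate path`; `path` entries are resolved
#'   relative to the sheet's directory when not absolute
#' @return data.frame with those four columns
#' @export
read_sample_sheet <- function(path) {
  sheet <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "genotype", "replicate", "path")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  sheet$replicate <- as.integer(sheet$replicate)
  if (any(sheet$replicate < 1L)) stop("replicate indices must be >= 1")
  key <- paste(sheet$genotype, sheet$replicate)
  if (anyDuplicated(key))
    stop("duplicate (genotype, replicate) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample_id")
  rel <- !grepl("^(/|[A-Za-z]:)", sheet$path)
  sheet$path[rel] <- file.path(dirname(path), sheet$path[rel])
  sheet
}
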