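## Internal helpers shared across modules.

#' Derive a reproducible sub-seed for one (genotype, replicate) stream
#'
#' Integer-state only: no time, hash-order or platform dependence, so a
#' fixed (seed, genotype, replicate) triple always yields the same stream.
#'
#' @param seed base integer seed
#' @param genotype genotype label
#' @param replicate replicate index (>= 1)
#' @return an integer in [0, 2^31 - 2]
#' @keywords internal
derive_seed <- function(seed, genotype, replicate) {
  codes <- utf8ToInt(as.character(genotype))
  h <- sum(codes * seq_along(codes)) %% 1e6
  as.integer(((abs(as.numeric(seed)) %% 1e6) * 10007 +
                h * 131 + as.numeric(replicate) * 7) %% 2147483647)
}

#' Roman-numeral peak labels in 5'->3' order
#' @param gene_id gene identifier
#' @param n number of peaks
#' @return character vector like "psbB-I", "psbB-II", ...
#' @keywords internal
roman_labels <- function(gene_id, n) {
  if (n == 0L) return(character(0))
  paste0(gene_id, "-", as.character(as.roman(seq_len(n))))
}

#' Write a TSV result table with '#'-prefixed metadata lines
#'
#' Metadata lines carry the package version plus any parameters given, so
#' every output is self-describing and diff-able.  No timestamps are
#' written: identical inputs and parameters give byte-identical files.
#'
#' @param df data.frame to write
#' @param path output path
#' @param metadata named list of parameter values recorded as `# key: value`
#' @return `path`, invisibly
#' @export
write_result_tsv <- function(df, path, metadata = list()) {
  meta <- c(list(tool = paste0("ribostall ", packageVersion("ribostall"))),
            metadata)
  lines <- sprintf("# %s: %s", names(meta),
                   vapply(meta, function(x) paste(format(x), collapse = ","),
                          character(1)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_result_tsv()]
#' @param path file path
#' @return data.frame (metadata lines skipped)
#' @export
read_result_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
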