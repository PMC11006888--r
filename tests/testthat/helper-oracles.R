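## Independent brute-force oracles and small fixture builders.
## These deliberately re-derive results with plain loops so they share
## no code with the implementation they check.

## All-pairs 5'-end containment assignment with the same tie-break rule
## (nearest upstream start codon, then lexicographic gene_id).
brute_assign <- function(footprints, orfs) {
  out <- rep(NA_character_, nrow(footprints))
  for (i in seq_len(nrow(footprints))) {
    p <- footprints$five_prime[i]
    best <- NULL; best_rel <- Inf
    for (j in seq_len(nrow(orfs))) {
      if (footprints$strand[i] != orfs$strand[j]) next
      if (footprints$seq_id[i] != orfs$seq_id[j]) next
      if (p < orfs$start[j] || p >= orfs$end[j]) next
      rel <- if (orfs$strand[j] == "+") p - orfs$start[j]
             else orfs$end[j] - 1 - p
      if (rel < best_rel ||
          (rel == best_rel && orfs$gene_id[j] < best)) {
        best <- orfs$gene_id[j]; best_rel <- rel
      }
    }
    if (!is.null(best)) out[i] <- best
  }
  out
}

## O(n^2) peak caller on a per-nt density vector: codon aggregation,
## truncated moving average, plateau local maxima, prominence by direct
## scan, distance merge, top-k.  Returns sorted codon indices.
brute_peaks <- function(density, smooth_codons = 3, frac = 0.25,
                        min_sep = 9, top_k = 6) {
  nc <- length(density) / 3
  cd <- numeric(nc)
  for (c in seq_len(nc)) cd[c] <- sum(density[(3 * c - 2):(3 * c)])
  s <- numeric(nc)
  half <- smooth_codons %/% 2
  for (c in seq_len(nc)) {
    w <- max(1, c - half):min(nc, c + half)
    s[c] <- mean(cd[w])
  }
  if (max(s) == min(s)) return(integer(0))
  ## plateau-aware local maxima: 5'-most index of each maximal run
  cand <- integer(0)
  c <- 1
  while (c <= nc) {
    e <- c
    while (e < nc && s[e + 1] == s[c]) e <- e + 1
    left <- if (c == 1) -Inf else s[c - 1]
    right <- if (e == nc) -Inf else s[e + 1]
    if (s[c] > left && s[c] > right) cand <- c(cand, c)
    c <- e + 1
  }
  ## prominence by direct scan
  prom <- numeric(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    lmin <- s[i]
    if (i > 1) for (j in (i - 1):1) {
      if (s[j] > s[i]) break
      lmin <- min(lmin, s[j])
      if (j == 1) lmin <- min(lmin, s[1])
    }
    rmin <- s[i]
    if (i < nc) for (j in (i + 1):nc) {
      if (s[j] > s[i]) break
      rmin <- min(rmin, s[j])
    }
    prom[k] <- s[i] - max(lmin, rmin)
  }
  keep <- prom >= frac * max(s)
  cand <- cand[keep]
  if (!length(cand)) return(integer(0))
  ord <- order(-s[cand], cand)
  kept <- integer(0)
  for (j in ord) {
    ok <- TRUE
    for (m in kept) if (abs(cand[j] - m) < min_sep) ok <- FALSE
    if (ok) kept <- c(kept, cand[j])
  }
  if (length(kept) > top_k)
    kept <- kept[order(-s[kept], kept)][1:top_k]
  sort(kept)
}

## Random assignment instance: a handful of (possibly overlapping) ORFs
## and uniform random footprints on one sequence.
random_instance <- function(n_fp = 500, n_orfs = 5, genome_len = 5000) {
  starts <- sample.int(genome_len - 400L, n_orfs)
  lens <- 3L * sample(20:100, n_orfs, replace = TRUE)
  ends <- pmin(starts + lens, genome_len)
  orfs <- suppressWarnings(orf_table(
    gene_id = sprintf("orf%02d", seq_len(n_orfs)),
    seq_id = "chr", start = starts, end = ends,
    strand = sample(c("+", "-"), n_orfs, replace = TRUE)))
  fstart <- sample.int(genome_len - 40L, n_fp, replace = TRUE)
  flen <- sample(20:40, n_fp, replace = TRUE)
  fp <- footprint_table(seq_id = "chr", start = fstart,
                        end = fstart + flen,
                        strand = sample(c("+", "-"), n_fp, replace = TRUE),
                        sample_id = "s1")
  list(footprints = fp, orfs = orfs)
}

## Tiny 3-gene GFF3 + FASTA fixture written as plain text.
write_tiny_annotation <- function(
    dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fasta <- file.path(dir, "toy.fasta")
  gff <- file.path(dir, "toy.gff3")
  set.seed(42)
  writeLines(c(">ptg",
               paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                     collapse = "")), fasta)
  writeLines(c("##gff-version 3",
               "ptg\ttoy\tCDS\t101\t400\t.\t+\t0\tID=geneA",
               "ptg\ttoy\tCDS\t501\t801\t.\t-\t0\tID=geneB",
               "ptg\ttoy\tCDS\t901\t1200\t.\t+\t0\tID=geneC"), gff)
  list(fasta = fasta, gff = gff)
}
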