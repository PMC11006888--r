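prof <- function(density, gene_id = "g") {
  structure(list(gene_id = gene_id, sample_id = "s",
                 density = density / sum(density)),
            class = "normalized_profile")
}
prof_raw <- function(density, gene_id = "g") {
  structure(list(gene_id = gene_id, sample_id = "s", density = density),
            class = "normalized_profile")
}

test_that("profiles place 5' ends in ORF-relative orientation", {
  orf_p <- orf_table("g", "chr", 100, 400, "+")
  fp <- footprint_table("chr", 150, 182, "+", "s1")
  p <- build_profile(fp, orf_p[1, ])
  expect_equal(p$values[51], 1L)  # 0-based position 50
  expect_equal(p$total, 1L)
  orf_m <- orf_table("g", "chr", 100, 400, "-")
  fpm <- footprint_table("chr", 318, 350, "-", "s1")  # 5' end at 349
  pm <- build_profile(fpm, orf_m[1, ])
  expect_equal(which(pm$values == 1L) - 1L, 50L)  # 400 - 1 - 349
})

test_that("profile totals agree with assignment counts", {
  set.seed(14)
  ann <- make_toy_annotation(2, c(60, 80), seed = 2)
  cfg <- sim_config(ann$orfs, depth_per_gene = 1000, seed = 5)
  fp <- simulate_footprints(cfg, "WT", 1)
  a <- assign_to_orfs(fp, ann$orfs)
  counts <- count_by_gene(a, ann$orfs)
  for (g in ann$orfs$gene_id) {
    p <- build_profile(a[!is.na(a$gene_id) & a$gene_id == g, ],
                       ann$orfs[ann$orfs$gene_id == g, ])
    expect_equal(p$total, counts$n[counts$gene_id == g])
  }
})

test_that("normalization produces a unit-mass density and rejects empties", {
  p <- structure(list(gene_id = "g", sample_id = "s",
                      values = c(2L, 0L, 2L), total = 4L),
                 class = "coverage_profile")
  np <- normalize_profile(p)
  expect_equal(np$density, c(0.5, 0, 0.5))
  ## doubling counts leaves the density unchanged
  p2 <- p; p2$values <- p$values * 2L; p2$total <- 8L
  expect_equal(normalize_profile(p2)$density, np$density)
  p0 <- p; p0$values <- rep(0L, 3); p0$total <- 0L
  expect_error(normalize_profile(p0), "no coverage")
})

test_that("flat and single-spike densities call 0 and 1 peaks", {
  flat <- prof(rep(1, 300))
  expect_equal(nrow(call_major_peaks(flat)), 0L)
  spike <- rep(0, 300); spike[3 * 50 - 2] <- 1
  pk <- call_major_peaks(prof(spike), smooth_codons = 1)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$codon_index, 50L)
  expect_equal(pk$height, 1.0)
  expect_equal(pk$label, "g-I")
})

test_that("peak calling matches the O(n^2) brute-force oracle", {
  set.seed(33)
  for (i in 1:40) {
    nc <- sample(100:600, 1)
    d <- rexp(3 * nc)^2  # spiky random density
    got <- call_major_peaks(prof(d))
    expect_equal(got$codon_index, brute_peaks(d), info = paste("trial", i))
  }
})

test_that("peak labels are consecutive roman numerals in 5'->3' order", {
  d <- rep(1, 3 * 200)
  for (c in c(20, 60, 100, 140, 180)) d[(3 * c - 2):(3 * c)] <- 8
  pk <- call_major_peaks(prof(d), min_sep_codons = 9)
  expect_equal(pk$label, paste0("g-", c("I", "II", "III", "IV", "V")))
  expect_true(all(diff(pk$codon_index) > 0))
})

test_that("peak ratio: identical profiles give 1 +- 0; arithmetic checks", {
  d <- rep(1, 300); d[150] <- 20
  wt <- list(prof(d), prof(d), prof(d))
  pr <- peak_ratio(wt, wt, codon_index = 50L)
  expect_equal(pr$mean, 1)
  expect_equal(pr$sd, 0)
  ## WT height 0.10 vs single mutant height 0.13 -> ratio 1.3
  den_wt <- rep(0.9 / 27, 30); den_wt[13:15] <- 0.10 / 3
  den_mut <- rep(0.87 / 27, 30); den_mut[13:15] <- 0.13 / 3
  pr2 <- peak_ratio(list(prof_raw(den_wt)), list(prof_raw(den_mut)),
                    codon_index = 5L, match_window_codons = 0L,
                    smooth_codons = 1L)
  expect_equal(pr2$mean, 1.3, tolerance = 1e-12)
  expect_true(is.na(pr2$sd))
  ## absent WT peak is an error
  z <- prof_raw(c(rep(1 / 27, 27), 0, 0, 0))
  expect_error(peak_ratio(list(z), list(z), codon_index = 10L,
                          match_window_codons = 0L, smooth_codons = 1L),
               "absent in WT")
})

test_that("peak ratio ignores sequencing depth", {
  set.seed(40)
  counts <- rpois(300, 20) + 1L
  p1 <- structure(list(gene_id = "g", sample_id = "a",
                       values = counts, total = sum(counts)),
                  class = "coverage_profile")
  p10 <- p1; p10$values <- counts * 10L; p10$total <- sum(counts) * 10L
  r <- peak_ratio(list(normalize_profile(p1)),
                  list(normalize_profile(p10)), codon_index = 50L)
  expect_equal(r$mean, 1, tolerance = 1e-9)
})

test_that("stall recovery approaches the renormalization-corrected truth", {
  ann <- make_toy_annotation(1, 508, seed = 2)
  m <- 2
  d0 <- 1 / 508
  truth <- m / (1 + (m - 1) * d0)
  means <- vapply(1:3, function(s) {
    cfg <- sim_config(ann$orfs, depth_per_gene = 5e4,
                      genotype_effects = list(mut = list(
                        psbB = setNames(m, "80"))),
                      replicate_noise_cv = 0.05, seed = s)
    ex <- simulate_experiment(cfg)
    a <- suppressMessages(assign_to_orfs(ex$footprints, ann$orfs))
    orf <- ann$orfs[1, ]
    profs <- function(ids) lapply(ids, function(sid)
      normalize_profile(build_profile(
        a[!is.na(a$gene_id) & a$sample_id == sid, ], orf,
        offset_nt = cfg$psite_offset)))
    pr <- peak_ratio(profs(paste0("WT_", 1:3)),
                     profs(paste0("mut_", 1:3)),
                     codon_index = 80L, match_window_codons = 0L,
                     smooth_codons = 1L)
    pr$mean
  }, numeric(1))
  expect_lt(abs(mean(means) - truth) / truth, 0.15)
})

test_that("genome-wide scan ranks an injected stall first", {
  ann <- make_toy_annotation(3, c(100, 508, 80), seed = 1)
  region <- function(centre, mlt) setNames(rep(mlt, 3), centre + (-1:1))
  cfg <- sim_config(ann$orfs, depth_per_gene = 2e4,
                    pause_map = list(psbB = c(region(120, 4),
                                              region(480, 5)),
                                     g01 = region(30, 3),
                                     g03 = region(40, 3)),
                    genotype_effects = list(
                      mut = list(psbB = region(480, 2))),
                    seed = 17)
  ex <- simulate_experiment(cfg)
  scan <- suppressMessages(genome_wide_scan(ex$footprints, ann$orfs,
                                            ex$sample_sheet,
                                            min_reads = 200))
  top <- scan[scan$genotype == "mut", ][1, ]
  expect_equal(top$gene_id, "psbB")
  expect_gt(top$mean_ratio, 1.5)
  ## the injected peak is the 5'-shifted image of codon 480
  expect_lte(abs(top$codon_index - 476L), 2L)
})

test_that("scan without mutants warns and returns an empty table", {
  ann <- make_toy_annotation(1, 100, seed = 2)
  cfg <- sim_config(ann$orfs, depth_per_gene = 2000,
                    pause_map = list(g01 = setNames(4, "50")), seed = 3)
  fp <- simulate_footprints(cfg, "WT", 1)
  sheet <- data.frame(sample_id = "WT_1", genotype = "WT", replicate = 1)
  expect_warning(scan <- genome_wide_scan(fp, ann$orfs, sheet,
                                          min_reads = 0), "no mutant")
  expect_equal(nrow(scan), 0L)
})

test_that("excluded genes are listed with reasons", {
  ann <- make_toy_annotation(2, c(100, 80), seed = 2)
  cfg <- sim_config(ann$orfs, depth_per_gene = 100,
                    genotypes = c("WT", "mut"), seed = 3)
  ex <- simulate_experiment(cfg)
  scan <- suppressMessages(genome_wide_scan(ex$footprints, ann$orfs,
                                            ex$sample_sheet,
                                            min_reads = 1e6))
  excl <- attr(scan, "excluded")
  expect_equal(sort(excl$gene_id), c("g01", "g02"))
  expect_match(excl$reason[1], "below")
})

test_that("tunnel mapping subtracts the tunnel length in codons", {
  expect_equal(map_peak_to_tunnel(40, 33)$emerging_residue, 7L)
  expect_true(is.na(map_peak_to_tunnel(20, 33)$emerging_residue))
  tmd <- read_tmd_table(system.file("extdata", "cp47_tmd_synthetic.tsv",
                                    package = "ribostall"))
  hit <- map_peak_to_tunnel(433 + 33, 33, tmd)
  expect_equal(hit$emerging_feature, "TMD VI")
  expect_equal(map_peak_to_tunnel(300, 33, tmd)$emerging_feature, "loop")
  bad <- data.frame(tmd_label = c("a", "b"), start_residue = c(10, 15),
                    end_residue = c(20, 25))
  expect_error(map_peak_to_tunnel(100, 33, bad), "overlapping")
})
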