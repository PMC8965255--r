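test_that("RI genotype chains honor the map-expansion switch probability", {
  ## r = 0: no recombination anywhere
  cfg0 <- sim_config(seed = 1, meiotic_recomb_fraction_per_interval = 0,
                     n_chromosomes = 2, markers_per_chromosome = 30)
  g0 <- simulate_ri_genotypes(cfg0)
  per_chrom <- split(seq_len(nrow(g0$markers)), g0$markers$chrom)
  for (idx in per_chrom)
    expect_true(all(apply(g0$alleles[, idx], 1,
                          function(v) length(unique(v)) == 1)))

  ## r = 0.5 is the fixed point of the expansion: switch prob 0.5
  expect_equal(4 * 0.5 / (1 + 6 * 0.5), 0.5)

  ## r = 0.01: empirical switch frequency matches 4r/(1+6r) = 0.0377
  cfg <- sim_config(seed = 2, meiotic_recomb_fraction_per_interval = 0.01,
                    n_strains = 60, n_chromosomes = 4,
                    markers_per_chromosome = 80)
  g <- simulate_ri_genotypes(cfg)
  switches <- 0; intervals <- 0
  for (idx in split(seq_len(nrow(g$markers)), g$markers$chrom)) {
    a <- g$alleles[, idx]
    switches <- switches + sum(a[, -1] != a[, -ncol(a)])
    intervals <- intervals + nrow(a) * (ncol(a) - 1)
  }
  expect_gte(intervals, 1e4)
  R <- 4 * 0.01 / (1 + 6 * 0.01)
  se <- sqrt(R * (1 - R) / intervals)
  expect_lt(abs(switches / intervals - R), 4 * se)

  ## identity expansion uses r unchanged
  cfgi <- sim_config(seed = 3, meiotic_recomb_fraction_per_interval = 0.2,
                     map_expansion = "identity", n_strains = 60,
                     n_chromosomes = 4, markers_per_chromosome = 60)
  gi <- simulate_ri_genotypes(cfgi)
  switches <- 0; intervals <- 0
  for (idx in split(seq_len(nrow(gi$markers)), gi$markers$chrom)) {
    a <- gi$alleles[, idx]
    switches <- switches + sum(a[, -1] != a[, -ncol(a)])
    intervals <- intervals + nrow(a) * (ncol(a) - 1)
  }
  expect_lt(abs(switches / intervals - 0.2),
            4 * sqrt(0.2 * 0.8 / intervals))

  expect_error(sim_config(meiotic_recomb_fraction_per_interval = 0.6),
               "0, 0.5")
})

test_that("marginal allele frequency is one half", {
  ## free recombination: strain-marker draws are independent fair coins
  cfg <- sim_config(seed = 4, n_strains = 50, n_chromosomes = 5,
                    markers_per_chromosome = 50,
                    meiotic_recomb_fraction_per_interval = 0.5)
  g <- simulate_ri_genotypes(cfg)
  n <- length(g$alleles)
  expect_gte(n, 1e4)
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(g$alleles) - 0.5), 3 * se)
  ## a linked map keeps the same marginal; with tight linkage the
  ## effective sample size is roughly one draw per strain-chromosome
  cfg2 <- sim_config(seed = 5, n_strains = 50, n_chromosomes = 5,
                     markers_per_chromosome = 50)
  g2 <- simulate_ri_genotypes(cfg2)
  n_eff <- cfg2$n_strains * cfg2$n_chromosomes
  expect_lt(abs(mean(g2$alleles) - 0.5), 3 * sqrt(0.25 / n_eff))
})

test_that("fixed seeds reproduce every simulated artifact exactly", {
  cfg <- sim_config(seed = 123, n_transcripts = 40, n_chromosomes = 2,
                    markers_per_chromosome = 10,
                    planted_pqtl = list(list(marker = 5, varfrac = 0.4)))
  run <- function() {
    g <- simulate_ri_genotypes(cfg)
    ann <- simulate_annotation(cfg)
    meta <- simulate_library_meta(cfg)
    list(g = g, ann = ann, meta = meta,
         ex = simulate_expression(g, ann, meta, cfg),
         ph = simulate_phenotype(g, cfg))
  }
  expect_identical(run(), run())
})

test_that("SDP collapsing merges identical and complemented patterns", {
  a <- cbind(c(0, 0, 1, 1), c(0, 0, 1, 1), c(1, 1, 0, 0),
             c(0, 1, 0, 1), c(1, 1, 1, 1))
  g <- fixture_geno(a)
  sdp <- collapse_to_sdp(g)
  expect_equal(sdp$mapping$sdp[1:3], rep(g$markers$id[1], 3))
  expect_true(sdp$mapping$monomorphic[5])
  expect_equal(nrow(sdp$genotype$markers), 2)   # patterns {0011}, {0101}
  ## complement merging can be disabled
  sdp2 <- collapse_to_sdp(g, merge_complements = FALSE)
  expect_equal(nrow(sdp2$genotype$markers), 3)
  ## distinct random vectors stay distinct (brute-force comparison)
  set.seed(6)
  b <- matrix(rbinom(30 * 40, 1, 0.5), 30, 40)
  key <- apply(b, 2, function(v) paste(if (v[1] == 1) 1 - v else v,
                                       collapse = ""))
  expected <- length(unique(key))
  got <- nrow(collapse_to_sdp(fixture_geno(b))$genotype$markers)
  expect_equal(got, expected)
})

test_that("phenotype simulation plants the configured variance fraction", {
  ## no planted effect: phenotype independent of genotype
  cfg0 <- sim_config(seed = 7, n_chromosomes = 2,
                     markers_per_chromosome = 10)
  g <- simulate_ri_genotypes(cfg0)
  ph0 <- simulate_phenotype(g, cfg0)
  expect_length(ph0$strain_means, 21)
  sc <- genome_scan(ph0$strain_means, collapse_to_sdp(g)$genotype)
  expect_lt(max(sc$lod, na.rm = TRUE), 6)

  ## noise-free planting: group difference equals the scaled effect
  cfg1 <- sim_config(seed = 8, n_chromosomes = 2,
                     markers_per_chromosome = 10, pheno_within_sd = 0,
                     planted_pqtl = list(list(marker = 3, varfrac = 1)))
  ph1 <- simulate_phenotype(g, cfg1)
  allele <- g$alleles[names(ph1$strain_means), 3]
  gap <- mean(ph1$strain_means[allele == 1]) -
    mean(ph1$strain_means[allele == 0])
  expect_equal(unname(gap), unname(ph1$effects[1]), tolerance = 1e-10)

  ## realized variance fraction across replicates is centered on target
  fracs <- vapply(1:40, function(i) {
    cfg <- sim_config(seed = 100 + i, n_chromosomes = 2,
                      markers_per_chromosome = 10, pheno_within_sd = 0,
                      planted_pqtl = list(list(marker = 3, varfrac = 0.5)))
    gg <- simulate_ri_genotypes(cfg)
    pp <- tryCatch(simulate_phenotype(gg, cfg), error = function(e) NULL)
    if (is.null(pp)) return(NA_real_)
    summary(lm(pp$strain_means ~
                 gg$alleles[names(pp$strain_means), 3]))$r.squared
  }, numeric(1))
  expect_lt(abs(mean(fracs, na.rm = TRUE) - 0.5), 0.07)

  expect_error(sim_config(planted_pqtl = list(
    list(marker = 1, varfrac = 0.7), list(marker = 2, varfrac = 0.5))),
    "sum")
})

test_that("near-Poisson, batch-free expression gives near-identical replicates", {
  cfg <- sim_config(seed = 9, n_transcripts = 50, n_chromosomes = 2,
                    markers_per_chromosome = 10, nb_dispersion = 1e-10,
                    within_log_var = 0, batch_sd = 0, batch_tx_sd = 0,
                    heritability_range = c(0, 0))
  g <- simulate_ri_genotypes(cfg)
  ann <- simulate_annotation(cfg)
  meta <- simulate_library_meta(cfg)
  meta$raw_read_pairs <- 7e7                  # equal depth
  ex <- simulate_expression(g, ann, meta, cfg)
  ri <- meta$library_id[meta$strain == "S01"]
  reps <- ex$counts[, ri]
  rel_range <- apply(reps, 1, function(v) diff(range(v)) / max(mean(v), 1))
  ## replicate counts differ only by counting noise (CV ~ 1/sqrt(mu))
  expect_lt(median(rel_range), 0.5)
  expect_gt(min(cor(log1p(reps))), 0.95)
})

test_that("equivalence-class structure mirrors exon sharing", {
  ## two non-overlapping transcripts: only singleton classes
  ann2 <- txome(data.frame(
    transcript_id = c("A", "B"), gene_id = c("GA", "GB"), chrom = "chr1",
    strand = "+", start = c(100, 5000), end = c(1099, 5999),
    source = "ensembl"))
  ec <- simulate_equivalence_classes(ann2, c(A = 5, B = 5), 1000, seed = 1)
  expect_true(all(lengths(ec$members) == 1))

  ## identical twins: every read lands in the shared class
  ec2 <- simulate_equivalence_classes(twin_txome(), c(T1 = 2, T2 = 1),
                                      1000, seed = 2)
  expect_length(ec2$members, 1)
  expect_equal(sort(ec2$members[[1]]), c("T1", "T2"))
  expect_equal(sum(ec2$counts), 1000)

  ## twins with unique equal-length 3' exons at abundance (2, 1): the
  ## unique-class read ratio approaches 2:1
  ann3 <- twin_unique3p_txome()
  ec3 <- simulate_equivalence_classes(ann3, c(T1 = 2, T2 = 1), 20000,
                                      seed = 3)
  key <- vapply(ec3$members, paste, character(1), collapse = ",")
  u1 <- ec3$counts[key == "T1", 1]
  u2 <- ec3$counts[key == "T2", 1]
  ratio <- u1 / u2
  expect_lt(abs(ratio - 2), 0.3)
  expect_error(simulate_equivalence_classes(ann3, c(T1 = 0, T2 = 0), 10),
               "zero total abundance")
})
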