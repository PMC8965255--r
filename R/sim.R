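#' Simulation configuration for a synthetic RI panel
#'
#' Defaults emulate the study design the pipeline targets: ~30 inbred
#' strains with 3 RNA-Seq libraries each across 8 batches, a loading-
#' control strain with technical replicates, biallelic homozygous
#' genotypes, heritable transcript expression with median panel
#' heritability near 0.5, and a phenotype measured in a subset of strains.
#'
#' @param n_strains RI strains (default 30)
#' @param n_chromosomes chromosomes (default 5)
#' @param markers_per_chromosome markers per chromosome (default 40)
#' @param chromosome_length chromosome length in bp (default 1e8)
#' @param meiotic_recomb_fraction_per_interval per-interval meiotic
#'   recombination fraction r in [0, 0.5] (default 0.01)
#' @param map_expansion `"sib"` applies the sib-mating RI map expansion
#'   R = 4r/(1+6r); `"identity"` uses r unchanged (for unit tests)
#' @param n_replicates_per_strain libraries per strain (default 3)
#' @param n_batches sequencing batches (default 8)
#' @param n_transcripts transcripts in the synthetic annotation
#' @param n_control_libraries loading-control libraries (default 10)
#' @param n_low_depth_controls control libraries given sub-threshold raw
#'   depth so the library filter has work to do (default 1)
#' @param planted_pqtl list of `list(marker=, varfrac=)`: marker (index or
#'   id) and fraction of strain-level phenotype variance explained
#' @param planted_eqtl list of `list(transcript=, marker=, beta=)`: log-
#'   scale allele effect on a transcript
#' @param planted_module optional `list(n=, marker=, beta=)`: plant a
#'   shared eQTL of effect `beta` at `marker` into the first `n`
#'   multi-exon reference transcripts from distinct genes, creating a
#'   coexpression module driven by that locus
#' @param heritability_range target interval for realized one-way-ANOVA
#'   heritability (default c(0.34, 0.66): median near 0.5 at a 30x3
#'   design, whose null R-squared floor is about 0.33)
#' @param nb_dispersion negative-binomial dispersion (default 0.05;
#'   values near 0 recover Poisson counts)
#' @param within_log_var within-strain log-scale variance budget for
#'   expression (default 0.3; counting noise is folded into it, so the
#'   heritability calibration stays unbiased)
#' @param n_phenotyped_strains strains with phenotype data (default 21)
#' @param n_pheno_replicates animals per strain for the phenotype
#'   (default 6; a free parameter of the design)
#' @param pheno_within_sd within-strain animal SD of the phenotype
#' @param batch_sd SD of global per-batch log-scale shifts (default 0.3)
#' @param batch_tx_sd SD of per-transcript batch wobble (default 0.1)
#' @param seed integer seed; fixed seed implies bit-reproducible output
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_strains = 30, n_chromosomes = 5,
                       markers_per_chromosome = 40,
                       chromosome_length = 1e8,
                       meiotic_recomb_fraction_per_interval = 0.01,
                       map_expansion = c("sib", "identity"),
                       n_replicates_per_strain = 3, n_batches = 8,
                       n_transcripts = 300,
                       n_control_libraries = 10,
                       n_low_depth_controls = 1,
                       planted_pqtl = list(), planted_eqtl = list(),
                       planted_module = NULL,
                       heritability_range = c(0.34, 0.66),
                       nb_dispersion = 0.05,
                       within_log_var = 0.3,
                       n_phenotyped_strains = 21,
                       n_pheno_replicates = 6,
                       pheno_within_sd = 0.5,
                       batch_sd = 0.3, batch_tx_sd = 0.1,
                       seed = 1L) {
  map_expansion <- match.arg(map_expansion)
  r <- meiotic_recomb_fraction_per_interval
  if (r < 0 || r > 0.5) stop("recombination fraction must be in [0, 0.5]")
  stopifnot(n_strains >= 2, n_chromosomes >= 1,
            markers_per_chromosome >= 1, chromosome_length > 0,
            n_replicates_per_strain >= 1, n_batches >= 1,
            length(heritability_range) == 2,
            all(heritability_range >= 0), all(heritability_range <= 1),
            heritability_range[1] <= heritability_range[2],
            nb_dispersion >= 0, n_phenotyped_strains <= n_strains,
            pheno_within_sd >= 0, batch_sd >= 0)
  if (length(planted_pqtl)) {
    fr <- vapply(planted_pqtl, function(p) p$varfrac, numeric(1))
    if (any(fr < 0) || sum(fr) > 1)
      stop("planted phenotype variance fractions must be in [0,1] and sum to <= 1")
  }
  structure(list(
    n_strains = n_strains, n_chromosomes = n_chromosomes,
    markers_per_chromosome = markers_per_chromosome,
    chromosome_length = chromosome_length,
    meiotic_recomb_fraction_per_interval = r,
    map_expansion = map_expansion,
    n_replicates_per_strain = n_replicates_per_strain,
    n_batches = n_batches, n_transcripts = n_transcripts,
    n_control_libraries = n_control_libraries,
    n_low_depth_controls = n_low_depth_controls,
    planted_pqtl = planted_pqtl, planted_eqtl = planted_eqtl,
    planted_module = planted_module,
    heritability_range = heritability_range,
    nb_dispersion = nb_dispersion,
    within_log_var = within_log_var,
    n_phenotyped_strains = n_phenotyped_strains,
    n_pheno_replicates = n_pheno_replicates,
    pheno_within_sd = pheno_within_sd,
    batch_sd = batch_sd, batch_tx_sd = batch_tx_sd,
    seed = seed), class = "sim_config")
}

## deterministic child seeds so stages can be rerun in isolation
seeds_for <- function(seed, n, salt = 0L) {
  if (is.null(seed) || is.na(seed)) return(rep(NA_integer_, n))
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed + salt)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

#' Simulate RI-panel genotypes
#'
#' Each strain's chromosome is a two-state Markov chain over ordered
#' markers. The inter-marker switch probability is the RI map expansion
#' of the configured meiotic recombination fraction: R = 4r/(1+6r) under
#' sib mating (or r itself with `map_expansion = "identity"`). Chromosome
#' starts are fair coin flips per strain; strains are fully homozygous,
#' so alleles are coded 0/1.
#'
#' @param config a [sim_config()]
#' @return object of class `genotype_matrix`: list with `strain_ids`,
#'   `markers` (data.frame chrom, pos, id), `alleles` (strains x markers
#'   0/1 matrix)
#' @export
simulate_ri_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seeds_for(config$seed, 1L, salt = 101L))
  r <- config$meiotic_recomb_fraction_per_interval
  R <- if (config$map_expansion == "sib") 4 * r / (1 + 6 * r) else r
  n_s <- config$n_strains
  m <- config$markers_per_chromosome
  strains <- sprintf("S%02d", seq_len(n_s))
  markers <- do.call(rbind, lapply(seq_len(config$n_chromosomes), function(c) {
    pos <- round(seq(config$chromosome_length / (m + 1),
                     by = config$chromosome_length / (m + 1), length.out = m))
    data.frame(chrom = paste0("chr", c), pos = pos,
               id = sprintf("chr%d_mk%03d", c, seq_len(m)),
               stringsAsFactors = FALSE)
  }))
  alleles <- matrix(0L, n_s, nrow(markers),
                    dimnames = list(strains, markers$id))
  col0 <- 0L
  for (c in seq_len(config$n_chromosomes)) {
    start <- rbinom(n_s, 1L, 0.5)
    switches <- matrix(rbinom(n_s * (m - 1L), 1L, R), n_s, max(m - 1L, 0L))
    chain <- matrix(0L, n_s, m)
    chain[, 1L] <- start
    if (m > 1L) for (j in 2L:m)
      chain[, j] <- (chain[, j - 1L] + switches[, j - 1L]) %% 2L
    alleles[, col0 + seq_len(m)] <- chain
    col0 <- col0 + m
  }
  structure(list(strain_ids = strains, markers = markers,
                 alleles = alleles), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$strain_ids), "strains x",
      nrow(x$markers), "markers on",
      length(unique(x$markers$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Collapse markers to strain distribution patterns
#'
#' Markers with identical allele vectors across strains (or, by default,
#' complemented vectors: single-marker regression is invariant to allele
#' relabeling) are statistically indistinguishable and merged. The
#' representative is the left-most member in map order; the mapping is
#' retained so peaks can be reported in genomic coordinates. Monomorphic
#' markers are flagged and excluded from the representative set.
#'
#' @param g a `genotype_matrix`
#' @param merge_complements merge 0/1-complemented patterns (default TRUE)
#' @return list: `genotype` (collapsed `genotype_matrix`), `mapping`
#'   (data.frame marker id, sdp representative id, monomorphic flag)
#' @export
collapse_to_sdp <- function(g, merge_complements = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  A <- g$alleles
  mono <- colSums(A) %in% c(0L, nrow(A))
  key <- apply(A, 2L, function(v) {
    if (merge_complements && v[1L] == 1L) v <- 1L - v
    paste(v, collapse = "")
  })
  key[mono] <- NA_character_
  first_idx <- match(key, key)            # left-most member per pattern
  rep_id <- ifelse(mono, NA_character_, g$markers$id[first_idx])
  keep <- which(!mono & seq_along(key) == first_idx)
  collapsed <- structure(
    list(strain_ids = g$strain_ids,
         markers = g$markers[keep, , drop = FALSE],
         alleles = A[, keep, drop = FALSE]),
    class = "genotype_matrix")
  rownames(collapsed$markers) <- NULL
  list(genotype = collapsed,
       mapping = data.frame(marker = g$markers$id, sdp = rep_id,
                            monomorphic = mono,
                            stringsAsFactors = FALSE))
}

#' Simulate a strain-level phenotype with planted QTL
#'
#' Strain means are a sum of planted marker effects and strain-level
#' noise; each planted effect is scaled against the realized allele
#' variance among the phenotyped strains so that the marker explains the
#' configured fraction of strain-level variance. Replicate animals add
#' within-strain noise; the reported strain mean is the mean over
#' animals, and only strain means feed QTL mapping.
#'
#' @param g a `genotype_matrix`
#' @param config a [sim_config()] (uses `planted_pqtl`,
#'   `n_phenotyped_strains`, `n_pheno_replicates`, `pheno_within_sd`)
#' @return list: `strain_means` (named vector over phenotyped strains),
#'   `animals` (data.frame strain, value), `genetic_values`, `effects`
#' @export
simulate_phenotype <- function(g, config) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(config, "sim_config"))
  set.seed(seeds_for(config$seed, 1L, salt = 202L))
  strains <- sort(g$strain_ids)[seq_len(config$n_phenotyped_strains)]
  A <- g$alleles[strains, , drop = FALSE]
  n <- length(strains)
  frac <- if (length(config$planted_pqtl))
    vapply(config$planted_pqtl, function(p) p$varfrac, numeric(1)) else numeric(0)
  if (sum(frac) > 1) stop("variance fractions sum to > 1")
  genetic <- setNames(rep(0, n), strains)
  effects <- numeric(0)
  for (p in config$planted_pqtl) {
    j <- if (is.character(p$marker)) match(p$marker, g$markers$id) else p$marker
    if (is.na(j) || j < 1 || j > ncol(A)) stop("unknown planted marker")
    v <- var(A[, j])
    if (p$varfrac > 0 && v == 0)
      stop("planted marker is monomorphic among phenotyped strains")
    beta <- if (p$varfrac > 0) sqrt(p$varfrac / v) else 0
    genetic <- genetic + beta * A[, j]
    effects <- c(effects, setNames(beta, g$markers$id[j]))
  }
  noise_sd <- sqrt(max(0, 1 - sum(frac)))
  strain_level <- genetic + rnorm(n, 0, noise_sd)
  reps <- config$n_pheno_replicates
  animals <- data.frame(
    strain = rep(strains, each = reps),
    value = rep(strain_level, each = reps) +
      rnorm(n * reps, 0, config$pheno_within_sd),
    stringsAsFactors = FALSE)
  means <- tapply(animals$value, animals$strain, mean)[strains]
  list(strain_means = setNames(as.numeric(means), strains),
       animals = animals, genetic_values = genetic, effects = effects)
}

#' Simulate library metadata
#'
#' RI-panel libraries (`n_replicates_per_strain` per strain) plus loading-
#' control libraries from a separate control strain, spread over batches;
#' one control library per batch where possible (technical replicates).
#' Raw read-pair depths are log-normal around 7e7; a configurable number
#' of control libraries is given sub-threshold depth.
#'
#' @param config a [sim_config()]
#' @return data.frame: library_id, strain, batch, raw_read_pairs,
#'   loading_control, technical_replicate
#' @export
simulate_library_meta <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seeds_for(config$seed, 1L, salt = 303L))
  strains <- sprintf("S%02d", seq_len(config$n_strains))
  ri <- data.frame(
    library_id = sprintf("L_%s_r%d",
                         rep(strains, each = config$n_replicates_per_strain),
                         rep(seq_len(config$n_replicates_per_strain),
                             times = config$n_strains)),
    strain = rep(strains, each = config$n_replicates_per_strain),
    loading_control = FALSE, technical_replicate = FALSE,
    stringsAsFactors = FALSE)
  meta <- ri
  if (config$n_control_libraries > 0) {
    ctl <- data.frame(
      library_id = sprintf("L_CTRL_t%02d",
                           seq_len(config$n_control_libraries)),
      strain = "CTRL", loading_control = TRUE,
      technical_replicate = TRUE, stringsAsFactors = FALSE)
    meta <- rbind(ri, ctl)
  }
  n <- nrow(meta)
  meta$batch <- paste0("B", rep_len(seq_len(config$n_batches), n))
  meta$raw_read_pairs <- round(exp(rnorm(n, log(7e7), 0.4)))
  if (config$n_low_depth_controls > 0 && config$n_control_libraries > 0) {
    low <- which(meta$loading_control)[seq_len(
      min(config$n_low_depth_controls, config$n_control_libraries))]
    meta$raw_read_pairs[low] <- 8e6
  }
  meta[, c("library_id", "strain", "batch", "raw_read_pairs",
           "loading_control", "technical_replicate")]
}

#' Simulate a multi-source transcript annotation
#'
#' Emulates the merged three-source annotation the pipeline consumes:
#' reference transcripts, splice-reconstruction isoforms (one internal
#' exon skipped, so all remaining junctions are shared), and 3'-terminus
#' extension isoforms (a copy of an existing transcript whose final base
#' moves, occasionally landing near another transcript's terminus). A
#' small fraction of transcripts are short (<= 200 nt) or placed on an
#' unplaced contig so the background filters have true positives.
#'
#' @param config a [sim_config()]
#' @param p_splice probability a gene gains a splice isoform (default .4)
#' @param p_apa probability a gene gains a 3'-extension isoform (.4)
#' @param p_apa_match fraction of 3'-extension termini placed within the
#'   matching tolerance of an existing terminus (default 0.2)
#' @param fraction_short fraction of genes whose reference transcript is
#'   at most 200 nt (default 0.03)
#' @param fraction_contig fraction of genes on an unplaced contig (0.03)
#' @return a `txome`
#' @export
simulate_annotation <- function(config, p_splice = 0.4, p_apa = 0.4,
                                p_apa_match = 0.2, fraction_short = 0.03,
                                fraction_contig = 0.03) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seeds_for(config$seed, 1L, salt = 404L))
  rows <- list()
  n_tx <- 0L
  gi <- 0L
  cursor <- setNames(rep(1e5, config$n_chromosomes + 1L),
                     c(paste0("chr", seq_len(config$n_chromosomes)),
                       "chrUn_1"))
  while (n_tx < config$n_transcripts) {
    gi <- gi + 1L
    gene <- sprintf("G%04d", gi)
    chrom <- if (runif(1) < fraction_contig) "chrUn_1" else
      paste0("chr", sample.int(config$n_chromosomes, 1L))
    strand <- sample(c("+", "-"), 1L)
    short <- runif(1) < fraction_short
    n_ex <- if (short) 1L else sample(2:7, 1L)
    ex_len <- if (short) sample(60:200, 1L) else sample(100:800, n_ex,
                                                        replace = TRUE)
    intron <- if (n_ex > 1L) sample(500:5000, n_ex - 1L, replace = TRUE)
              else integer(0)
    start0 <- cursor[chrom]
    starts <- start0 + cumsum(c(0, head(ex_len, -1L) + intron))
    ends <- starts + ex_len - 1L
    cursor[chrom] <- max(ends) + sample(2e4:5e4, 1L)
    base_id <- sprintf("ENSSYNT%08d", gi)
    add <- function(id, src, s, e) {
      data.frame(transcript_id = id, gene_id = gene, chrom = chrom,
                 strand = strand, start = s, end = e, source = src,
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- add(base_id, "ensembl", starts, ends)
    n_tx <- n_tx + 1L
    iso_ids <- base_id
    if (n_ex >= 3L && runif(1) < p_splice && n_tx < config$n_transcripts) {
      skip <- sample(2:(n_ex - 1L), 1L)
      sid <- sprintf("MSTRG.%d.1", gi)
      rows[[length(rows) + 1L]] <- add(sid, "stringtie",
                                       starts[-skip], ends[-skip])
      n_tx <- n_tx + 1L
      iso_ids <- c(iso_ids, sid)
    }
    if (runif(1) < p_apa && n_tx < config$n_transcripts) {
      src_id <- sample(iso_ids, 1L)
      src_rows <- rows[[which(vapply(rows, function(r)
        r$transcript_id[1L], character(1)) == src_id)]]
      s <- src_rows$start; e <- src_rows$end
      shift <- if (runif(1) < p_apa_match) sample(0:100, 1L) else
        sample(300:1500, 1L)
      if (strand == "+") e[length(e)] <- e[length(e)] + shift
      else s[1L] <- max(1, s[1L] - shift)
      cursor[chrom] <- max(cursor[chrom], max(e) + 2e4)
      rows[[length(rows) + 1L]] <- add(paste0(src_id, ".1"), "aptardi", s, e)
      n_tx <- n_tx + 1L
    }
  }
  txome(do.call(rbind, rows))
}

## calibration: strain/within variance ratio that makes the expected
## one-way-ANOVA R^2 equal the target at a balanced k x n design
herit_to_ratio <- function(target, k, n) {
  a <- k - 1
  b <- k * (n - 1)
  floor_t <- a / (a + b)
  pmax(0, (target * b / (a * (1 - pmin(target, 0.999))) - 1) / n)
}

#' Simulate per-library transcript counts
#'
#' Counts are negative binomial with a log-link mean combining a
#' transcript baseline, a strain effect, planted eQTL allele effects,
#' batch effects (a global per-batch shift plus per-transcript wobble),
#' and a library depth offset. The per-transcript strain-effect variance
#' is calibrated against the design (strains x replicates) and the
#' counting-noise floor so that realized one-way-ANOVA heritability
#' spans `heritability_range`.
#'
#' @param g a `genotype_matrix`
#' @param ann a `txome`
#' @param meta library metadata from [simulate_library_meta()]
#' @param config a [sim_config()]
#' @return list: `counts` (transcripts x libraries), `truth` (data.frame
#'   transcript_id, h_target, baseline), `meta`
#' @export
simulate_expression <- function(g, ann, meta, config) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(ann, "txome"),
            inherits(config, "sim_config"))
  if (!all(c("strain", "batch") %in% names(meta)))
    stop("every library needs strain and batch labels")
  set.seed(seeds_for(config$seed, 1L, salt = 505L))
  tx <- ann$transcripts$transcript_id
  n_t <- length(tx)
  strains <- g$strain_ids
  n_lib <- nrow(meta)
  phi <- config$nb_dispersion

  h_target <- runif(n_t, config$heritability_range[1],
                    config$heritability_range[2])
  b0 <- runif(n_t, log(20), log(2000))
  k <- length(strains)
  nrep <- config$n_replicates_per_strain
  ratio <- herit_to_ratio(h_target, k, nrep)
  sw2 <- config$within_log_var            # within-strain log-scale budget
  nb_noise <- 1 / exp(b0) + phi           # delta-method counting noise
  eps_var <- pmax(0, sw2 - nb_noise)
  sb2 <- ratio * sw2

  u <- matrix(rnorm(n_t * k, 0, sqrt(sb2)), n_t, k,
              dimnames = list(tx, strains))
  batches <- sort(unique(meta$batch))
  delta_b <- setNames(rnorm(length(batches), 0, config$batch_sd), batches)
  gamma <- matrix(rnorm(n_t * length(batches), rep(delta_b, each = n_t),
                        config$batch_tx_sd),
                  n_t, length(batches), dimnames = list(tx, batches))

  for (e in config$planted_eqtl) {
    t_id <- if (is.numeric(e$transcript)) tx[e$transcript] else e$transcript
    j <- if (is.character(e$marker)) match(e$marker, g$markers$id) else e$marker
    if (is.na(match(t_id, tx)) || is.na(j)) stop("unknown planted eQTL")
    u[t_id, ] <- u[t_id, ] + e$beta * g$alleles[, j]
  }

  module_ids <- character(0)
  if (!is.null(config$planted_module)) {
    pm <- config$planted_module
    tt <- ann$transcripts
    eligible <- tt$transcript_id[tt$source == "ensembl" & tt$n_exons >= 2L]
    eligible <- eligible[!duplicated(tt[eligible, "gene_id"])]
    if (length(eligible) < pm$n)
      stop("not enough multi-exon reference transcripts for the planted module")
    module_ids <- sort(eligible)[seq_len(pm$n)]
    j <- if (is.character(pm$marker)) match(pm$marker, g$markers$id)
         else pm$marker
    if (is.na(j)) stop("unknown planted-module marker")
    for (t_id in module_ids)
      u[t_id, ] <- u[t_id, ] + pm$beta * g$alleles[, j]
  }

  depth_factor <- meta$raw_read_pairs / median(meta$raw_read_pairs)
  lib_strain <- match(meta$strain, strains)      # NA for control strain
  lib_batch <- match(meta$batch, batches)

  counts <- matrix(0, n_t, n_lib, dimnames = list(tx, meta$library_id))
  eps <- matrix(rnorm(n_t * n_lib, 0, sqrt(eps_var)), n_t, n_lib)
  for (l in seq_len(n_lib)) {
    su <- if (is.na(lib_strain[l])) 0 else u[, lib_strain[l]]
    mu <- exp(b0 + su + gamma[, lib_batch[l]] + eps[, l]) * depth_factor[l]
    counts[, l] <- if (phi < 1e-8) stats::rpois(n_t, mu) else
      rnbinom(n_t, mu = mu, size = 1 / phi)
  }
  list(counts = counts,
       truth = data.frame(transcript_id = tx, h_target = h_target,
                          baseline = exp(b0), stringsAsFactors = FALSE),
       planted_module_transcripts = module_ids,
       meta = meta)
}

#' Simulate equivalence-class counts from true abundances
#'
#' Reads are drawn multinomially over (transcript, exon) cells with
#' weight abundance x exon length. A read's equivalence class is the set
#' of same-gene transcripts containing its exon (exact coordinates), so
#' identical twin transcripts produce fully shared classes and transcripts
#' with unique 3' exons produce unique classes.
#'
#' @param ann a `txome`
#' @param abundances named vector, or transcripts x libraries matrix, of
#'   true abundances (must not be all zero)
#' @param n_reads reads per library (recycled)
#' @param seed optional seed
#' @return an `ec_set`
#' @export
simulate_equivalence_classes <- function(ann, abundances, n_reads,
                                         seed = NULL) {
  stopifnot(inherits(ann, "txome"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dim(abundances)))
    abundances <- matrix(abundances, ncol = 1L,
                         dimnames = list(names(abundances), "lib1"))
  if (any(colSums(abundances) == 0)) stop("zero total abundance")
  n_reads <- rep_len(n_reads, ncol(abundances))

  ex <- ann$exons
  ex <- ex[ex$transcript_id %in% rownames(abundances), , drop = FALSE]
  gene_of <- setNames(ann$transcripts$gene_id, ann$transcripts$transcript_id)
  exon_key <- paste(gene_of[ex$transcript_id], ex$chrom, ex$start, ex$end)
  ## class of a cell: all same-gene transcripts containing the exact exon
  class_of_exon <- vapply(split(ex$transcript_id, exon_key),
                          function(t) paste(sort(unique(t)), collapse = ","),
                          character(1))
  cell_class <- class_of_exon[exon_key]
  cell_len <- ex$end - ex$start + 1

  classes <- sort(unique(cell_class))
  counts <- matrix(0, length(classes), ncol(abundances),
                   dimnames = list(classes, colnames(abundances)))
  for (l in seq_len(ncol(abundances))) {
    w <- abundances[ex$transcript_id, l] * cell_len
    if (sum(w) == 0) next
    draws <- rmultinom(1L, n_reads[l], w)[, 1L]
    cc <- rowsum(draws, cell_class)
    counts[rownames(cc), l] <- cc[, 1L]
  }
  ec_set(strsplit(classes, ","), counts)
}
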