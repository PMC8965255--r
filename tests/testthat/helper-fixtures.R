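## Fixtures are built in code; nothing binary ships with the package.

## Two-gene annotation: gene A multi-exon on "+" with a splice isoform and
## a 3'-extension isoform; gene B single transcript on "-".
fixture_txome <- function() {
  ex <- rbind(
    data.frame(transcript_id = "ENSA1", gene_id = "GA", chrom = "chr1",
               strand = "+", start = c(100, 500, 900),
               end = c(200, 600, 1000), source = "ensembl"),
    data.frame(transcript_id = "MSTRG.1.1", gene_id = "GA", chrom = "chr1",
               strand = "+", start = c(100, 900), end = c(200, 1000),
               source = "stringtie"),
    data.frame(transcript_id = "ENSA1.1", gene_id = "GA", chrom = "chr1",
               strand = "+", start = c(100, 500, 900),
               end = c(200, 600, 1400), source = "aptardi"),
    data.frame(transcript_id = "ENSB1", gene_id = "GB", chrom = "chr2",
               strand = "-", start = 5000, end = 6000, source = "ensembl")
  )
  txome(ex)
}

## Identical twin transcripts (same exons) in one gene.
twin_txome <- function() {
  ex <- rbind(
    data.frame(transcript_id = "T1", gene_id = "G1", chrom = "chr1",
               strand = "+", start = c(100, 500), end = c(299, 699),
               source = "ensembl"),
    data.frame(transcript_id = "T2", gene_id = "G1", chrom = "chr1",
               strand = "+", start = c(100, 500), end = c(299, 699),
               source = "stringtie")
  )
  txome(ex)
}

## Twins sharing one exon but with unique 3' exons of equal length.
twin_unique3p_txome <- function() {
  ex <- rbind(
    data.frame(transcript_id = "T1", gene_id = "G1", chrom = "chr1",
               strand = "+", start = c(100, 500), end = c(299, 699),
               source = "ensembl"),
    data.frame(transcript_id = "T2", gene_id = "G1", chrom = "chr1",
               strand = "+", start = c(100, 900), end = c(299, 1099),
               source = "stringtie")
  )
  txome(ex)
}

## Planted two-block expression matrix (rows = transcripts).
block_expr <- function(n_per = 10, n_strains = 30, wcor = 0.95,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  one_block <- function(prefix) {
    z <- rnorm(n_strains)
    x <- t(vapply(seq_len(n_per), function(i)
      sqrt(wcor) * z + sqrt(1 - wcor) * rnorm(n_strains),
      numeric(n_strains)))
    rownames(x) <- sprintf("%s%02d", prefix, seq_len(n_per))
    x
  }
  rbind(one_block("a"), one_block("b"))
}

## Small genotype_matrix built directly from an allele matrix.
fixture_geno <- function(alleles, chrom = "chr1",
                         pos = seq_len(ncol(alleles)) * 1e6) {
  if (is.null(rownames(alleles)))
    rownames(alleles) <- sprintf("S%02d", seq_len(nrow(alleles)))
  ids <- sprintf("%s_mk%03d", chrom, seq_len(ncol(alleles)))
  colnames(alleles) <- ids
  structure(list(strain_ids = rownames(alleles),
                 markers = data.frame(chrom = chrom, pos = pos, id = ids,
                                      stringsAsFactors = FALSE),
                 alleles = alleles),
            class = "genotype_matrix")
}

## Independent-marker genotypes for n strains x m markers.
random_geno <- function(n_strains, n_markers, seed = 1) {
  set.seed(seed)
  a <- matrix(rbinom(n_strains * n_markers, 1L, 0.5), n_strains, n_markers)
  fixture_geno(a)
}

## Library metadata for hand-built count fixtures.
fixture_meta <- function(library_ids, strains = NULL,
                         raw = 2e7, control = FALSE) {
  n <- length(library_ids)
  data.frame(library_id = library_ids,
             strain = if (is.null(strains))
               sprintf("S%02d", seq_len(n)) else strains,
             batch = rep_len(c("B1", "B2"), n),
             raw_read_pairs = rep_len(raw, n),
             loading_control = rep_len(control, n),
             technical_replicate = FALSE,
             stringsAsFactors = FALSE)
}

## 12-transcript annotation with engineered filter violations: 3 on an
## unplaced contig, one at each side of the length boundary (200 nt and
## 201 nt), the rest long enough; the count fixture below decides the
## zero-count violations.
dabg_fixture <- function() {
  mk <- function(id, gene, chrom, len, src, start = 1000) {
    data.frame(transcript_id = id, gene_id = gene, chrom = chrom,
               strand = "+", start = start, end = start + len - 1,
               source = src, stringsAsFactors = FALSE)
  }
  ex <- rbind(
    mk("K01", "g01", "chr1", 1000, "ensembl"),
    mk("K02", "g02", "chr1", 1000, "stringtie"),
    mk("K03", "g03", "chr2", 1000, "aptardi"),
    mk("K04", "g04", "chr2", 1000, "ensembl"),
    mk("LEN200", "g05", "chr1", 200, "stringtie"),   # boundary: removed
    mk("LEN201", "g06", "chr1", 201, "aptardi"),     # boundary: kept
    mk("CTG1", "g07", "chrUn_1", 1000, "ensembl"),
    mk("CTG2", "g08", "chrUn_1", 1000, "stringtie"),
    mk("CTG3", "g09", "chrUn_1", 1000, "aptardi"),
    mk("ZEXACT", "g10", "chr1", 1000, "ensembl"),
    mk("ZUNDER", "g11", "chr1", 1000, "stringtie"),
    mk("ZOVER", "g12", "chr1", 1000, "aptardi")
  )
  txome(ex)
}

## Reference scalar EM used as an independent oracle on tiny instances:
## tracks the data log-likelihood at every iteration.
reference_em <- function(members, counts, lengths, iters = 500) {
  tx <- names(lengths)
  alpha <- setNames(rep(1 / length(tx), length(tx)), tx)
  loglik <- function(a) {
    sum(vapply(seq_along(members), function(c) {
      rate <- sum(a[members[[c]]] / lengths[members[[c]]])
      if (counts[c] == 0) 0 else counts[c] * log(rate)
    }, numeric(1)))
  }
  lls <- numeric(iters)
  for (it in seq_len(iters)) {
    expected <- setNames(rep(0, length(tx)), tx)
    for (c in seq_along(members)) {
      m <- members[[c]]
      w <- alpha[m] / lengths[m]
      expected[m] <- expected[m] + counts[c] * w / sum(w)
    }
    alpha <- expected / sum(expected)
    lls[it] <- loglik(alpha)
  }
  list(alpha = alpha, expected = expected, loglik = lls)
}

## Engineered 12-transcript cascade fixture:
##  - libraries: 7, one below the 10M read-pair threshold (removed)
##  - CTG1-3 on an unplaced contig (removed at the chromosome step)
##  - LEN200 exactly 200 nt (removed), LEN201 at 201 nt (kept)
##  - ZEXACT zero in exactly ceiling(6/3) = 2 of 6 libraries (removed),
##    ZUNDER zero in 1 of 6 (kept), ZOVER zero in 4 of 6 (removed)
dabg_cascade_fixture <- function() {
  ann <- dabg_fixture()
  libs <- sprintf("L%d", 1:7)
  meta <- fixture_meta(libs, strains = sprintf("S%02d", 1:7))
  meta$raw_read_pairs[7] <- 9e6                 # dropped by depth filter
  tx <- ann$transcripts$transcript_id
  counts <- matrix(50, length(tx), 7, dimnames = list(tx, libs))
  counts["ZEXACT", c("L1", "L2")] <- 0
  counts["ZUNDER", "L1"] <- 0
  counts["ZOVER", c("L1", "L2", "L3", "L4")] <- 0
  ec <- ec_set(as.list(tx), counts)
  list(ann = ann, ec = ec, meta = meta)
}

## independent re-implementation of the accumulation rule used as oracle
brute_ci <- function(pos, lod, coverage = 0.95) {
  mass <- 10^(lod - max(lod)); mass <- mass / sum(mass)
  ord <- order(-mass)
  best <- NULL
  for (k in seq_along(ord)) {
    if (sum(mass[ord[seq_len(k)]]) >= coverage) { best <- ord[seq_len(k)]; break }
  }
  lo <- max(1, min(best) - 1); hi <- min(length(pos), max(best) + 1)
  c(pos[lo], pos[hi])
}
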