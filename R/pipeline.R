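#' Pipeline configuration
#'
#' Bundles the per-stage parameter sets and the single seed from which
#' deterministic child seeds fan out to each stage, so stages can be
#' rerun in isolation reproducibly.
#'
#' @param sim a [sim_config()] describing the synthetic panel
#' @param dabg a [dabg_params()] list
#' @param net a [network_params()] list
#' @param criteria a [candidate_criteria()] list
#' @param n_perm permutations for every genome-wide empirical p-value
#' @param reads_per_library equivalence-class reads at median depth; each
#'   library scales with its raw depth (default 5e4)
#' @param k_isoforms dominant isoforms kept per gene (default 3)
#' @param local_window local-QTL window in bases (default 1e7)
#' @export
pipeline_config <- function(sim = sim_config(),
                            dabg = dabg_params(),
                            net = network_params(),
                            criteria = candidate_criteria(),
                            n_perm = 1000L,
                            reads_per_library = 5e4,
                            k_isoforms = 3L,
                            local_window = 1e7) {
  stopifnot(inherits(sim, "sim_config"))
  list(sim = sim, dabg = dabg, net = net, criteria = criteria,
       n_perm = as.integer(n_perm),
       reads_per_library = reads_per_library,
       k_isoforms = as.integer(k_isoforms),
       local_window = local_window)
}

#' Run the full synthetic pipeline
#'
#' Simulation, equivalence-class quantitation, the detected-above-
#' background cascade, normalization, heritability prefiltering, module
#' detection, QTL mapping, and candidate selection, in order. With
#' `out_dir` set, every stage output is written (TSV/GTF/BED) together
#' with a JSON manifest of parameters, seeds and file digests; a rerun
#' with the same configuration reproduces byte-identical outputs.
#'
#' @param config a [pipeline_config()]
#' @param out_dir optional output directory (created if missing)
#' @return results bundle (invisibly a list): genotypes, annotation,
#'   dabg, expression, heritability, prefilter, network, pqtl,
#'   candidates, report lines
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  sim <- config$sim
  seeds <- seeds_for(sim$seed, 6L, salt = 909L)

  res <- list(config = config)
  on.exit({
    if (!is.null(out_dir) && !is.null(res$failed_stage))
      writeLines(res$failed_stage, file.path(out_dir, "FAILED"))
  })
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  fail_wrap <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      res$failed_stage <<- name
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ## -- simulate ------------------------------------------------------
  fail_wrap("simulate", {
    res$genotypes <- simulate_ri_genotypes(sim)
    sdp <- collapse_to_sdp(res$genotypes)
    res$sdp <- sdp$genotype
    res$sdp_mapping <- sdp$mapping
    res$annotation <- simulate_annotation(sim)
    res$meta <- simulate_library_meta(sim)
    ex <- simulate_expression(res$genotypes, res$annotation, res$meta, sim)
    res$sim_counts <- ex$counts
    res$sim_truth <- ex$truth
    res$planted_module <- ex$planted_module_transcripts
    res$phenotype <- simulate_phenotype(res$genotypes, sim)
  })

  ## -- quantify ------------------------------------------------------
  fail_wrap("quantify", {
    depth <- res$meta$raw_read_pairs / median(res$meta$raw_read_pairs)
    n_reads <- pmax(1L, round(config$reads_per_library * depth))
    res$ec <- simulate_equivalence_classes(
      res$annotation, res$sim_counts, n_reads, seed = seeds[1L])
    res$dabg <- build_dabg(res$annotation, res$ec, res$meta, config$dabg)
  })

  ## -- normalize -----------------------------------------------------
  fail_wrap("normalize", {
    meta_kept <- res$dabg$meta
    uq <- upper_quartile_normalize(res$dabg$counts)
    rl <- regularized_log(uq)
    res$norm_expr <- batch_adjust(rl, meta_kept$batch, meta_kept$strain)
    res$strain_expr <- strain_means(res$norm_expr, meta_kept)
  })

  ## -- prefilter -----------------------------------------------------
  fail_wrap("prefilter", {
    meta_kept <- res$dabg$meta
    ri <- meta_kept$library_id[!meta_kept$loading_control]
    res$heritability <- heritability(
      res$norm_expr[, ri, drop = FALSE],
      meta_kept$strain[match(ri, meta_kept$library_id)])
    reference <- subset_txome(res$annotation,
      res$annotation$transcripts$transcript_id[
        res$annotation$transcripts$source == "ensembl"])
    res$prefilter <- apply_prefilter(
      res$dabg$counts[, ri, drop = FALSE], res$heritability,
      res$dabg$annotation, reference, k = config$k_isoforms)
  })

  ## -- network -------------------------------------------------------
  fail_wrap("network", {
    kept <- res$prefilter$retained
    expr <- res$strain_expr[kept, , drop = FALSE]
    if (length(kept) >= config$net$min_module_size) {
      adj <- adjacency(expr, config$net)
      tomd <- 1 - tom_similarity(adj)
      mods <- detect_modules(tomd, config$net)
      egs <- lapply(mods$modules, function(m)
        module_eigengene(expr, m))
      eg_mat <- do.call(rbind, lapply(egs, `[[`, "eigengene"))
      conn <- lapply(mods$modules, function(m)
        intramodular_connectivity(adj, m))
      res$network <- list(
        adjacency = adj, modules = mods, eigengenes = eg_mat,
        variance_explained = vapply(egs, `[[`, numeric(1),
                                    "variance_explained"),
        connectivity = conn,
        scale_free_r2 = if (nrow(expr) >= 20)
          scale_free_fit(adj) else NA_real_)
    } else {
      res$network <- list(adjacency = NULL,
                          modules = list(modules = list(),
                                         labels = character(0),
                                         unassigned = kept),
                          eigengenes = NULL, variance_explained = numeric(0),
                          connectivity = list(), scale_free_r2 = NA_real_)
    }
  })

  ## -- qtl -----------------------------------------------------------
  fail_wrap("qtl", {
    ph <- res$phenotype$strain_means
    res$pqtl_scan <- genome_scan(ph, res$sdp)
    res$pqtl_thresholds <- permutation_thresholds(
      ph, res$sdp, n_perm = config$n_perm, seed = seeds[2L])
    res$pqtl_peaks <- qtl_peaks(res$pqtl_scan, res$pqtl_thresholds)
  })

  ## -- candidates ----------------------------------------------------
  fail_wrap("candidates", {
    kept <- res$prefilter$retained
    res$candidate_transcripts <- candidate_transcripts(
      res$strain_expr[kept, , drop = FALSE], res$phenotype$strain_means,
      res$sdp, res$dabg$annotation, res$pqtl_peaks,
      criteria = config$criteria, n_perm = config$n_perm,
      seed = seeds[3L], local_window = config$local_window)
    res$candidate_modules <- if (!is.null(res$network$eigengenes) &&
                                 nrow(res$network$eigengenes))
      candidate_modules(res$network$eigengenes, res$phenotype$strain_means,
                        res$sdp, res$pqtl_peaks,
                        criteria = config$criteria,
                        n_perm = config$n_perm, seed = seeds[4L])
    else candidate_modules_empty()
  })

  res$report <- report(res)

  if (!is.null(out_dir)) fail_wrap("write", write_results(res, out_dir))
  invisible(res)
}

candidate_modules_empty <- function() {
  data.frame(feature_id = character(), kind = character(),
             rho = numeric(), cor_p = numeric(), n_strains = integer(),
             lod = numeric(), qtl_p = numeric(), qtl_chrom = character(),
             qtl_pos = numeric(), ci_lo = numeric(), ci_hi = numeric(),
             pqtl_overlap = character(), locality = character(),
             stringsAsFactors = FALSE)
}

ledger_with_percent <- function(ledger) {
  out <- ledger
  for (src in c("ensembl", "stringtie", "aptardi")) {
    n <- out[[paste0("n_", src)]]
    out[[paste0("pct_", src)]] <-
      round(100 * n / pmax(out$n_transcripts, 1L), 1)
  }
  out
}

md_table <- function(df) {
  df <- as.data.frame(df)
  cells <- vapply(df, function(col) format(col, trim = TRUE),
                  character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "),
                                        " |")))
}

#' Human-readable run summary
#'
#' Renders the filter ledgers, phenotype QTL peak table, module summary,
#' and candidate tables as Markdown lines.
#'
#' @param res results bundle from [run_pipeline()]
#' @return character vector of Markdown lines
#' @export
report <- function(res) {
  lines <- c("# Pipeline report", "")
  lines <- c(lines, "## Detected-above-background filter ledger", "",
             md_table(ledger_with_percent(res$dabg$ledger)), "")
  lines <- c(lines, "## Prefilter ledger", "",
             md_table(ledger_with_percent(res$prefilter$ledger)), "")
  lines <- c(lines, "## Phenotype QTL peaks", "")
  if (nrow(res$pqtl_peaks)) {
    lines <- c(lines, md_table(res$pqtl_peaks), "")
  } else lines <- c(lines, "No suggestive or significant phenotype QTL.", "")
  nm <- length(res$network$modules$modules)
  lines <- c(lines, "## Coexpression modules", "",
             sprintf("%d module(s); %d unassigned transcript(s).", nm,
                     length(res$network$modules$unassigned)), "")
  for (tab in c("candidate_transcripts", "candidate_modules")) {
    title <- if (tab == "candidate_transcripts") "## Candidate transcripts"
             else "## Candidate modules"
    lines <- c(lines, title, "")
    if (!is.null(res[[tab]]) && nrow(res[[tab]])) {
      lines <- c(lines, md_table(res[[tab]]), "")
    } else lines <- c(lines, "No candidates.", "")
  }
  lines
}

write_results <- function(res, out_dir) {
  p <- function(...) file.path(out_dir, ...)
  write_genotypes_tsv(res$genotypes, p("genotypes.tsv"))
  write_markers_bed(res$genotypes, p("markers.bed"))
  write_gtf(res$annotation, p("annotation.gtf"))
  write_gtf(res$dabg$annotation, p("dabg.gtf"))
  write_meta_tsv(res$meta, p("library_meta.tsv"))
  write_ec_tsv(res$ec, p("equivalence_classes.tsv"))
  write_matrix_tsv(res$dabg$counts, p("dabg_counts.tsv"))
  write_matrix_tsv(res$strain_expr, p("strain_expression.tsv"))
  write.table(ledger_with_percent(res$dabg$ledger), p("dabg_ledger.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ledger_with_percent(res$prefilter$ledger),
              p("prefilter_ledger.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(res$heritability, p("heritability.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  labels <- res$network$modules$labels
  write.table(data.frame(transcript_id = names(labels), module = labels),
              p("modules.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(res$network$eigengenes))
    write_matrix_tsv(res$network$eigengenes, p("eigengenes.tsv"))
  write.table(as.data.frame(res$pqtl_scan), p("pqtl_scan.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(res$pqtl_peaks, p("pqtl_peaks.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(res$candidate_transcripts, p("candidate_transcripts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(res$candidate_modules, p("candidate_modules.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(res$report, p("report.md"))

  files <- setdiff(list.files(out_dir), "manifest.json")
  digests <- tools::md5sum(file.path(out_dir, files))
  names(digests) <- files
  manifest <- list(
    package = "isoqtl",
    version = as.character(utils::packageVersion("isoqtl")),
    seed = res$config$sim$seed,
    n_perm = res$config$n_perm,
    parameters = res$config$sim[setdiff(names(res$config$sim),
                                        c("planted_pqtl", "planted_eqtl"))],
    files = as.list(digests))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
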