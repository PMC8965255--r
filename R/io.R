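## Plain-text interchange: every writer here round-trips through the
## matching reader.

#' Write / read a genotype matrix as TSV (strains x markers)
#' @param g a `genotype_matrix`
#' @param path output TSV
#' @export
write_genotypes_tsv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  df <- data.frame(strain = g$strain_ids, g$alleles, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @param marker_bed BED file of marker positions (as written by
#'   [write_markers_bed()])
#' @export
read_genotypes_tsv <- function(path, marker_bed) {
  df <- read.delim(path, check.names = FALSE)
  alleles <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(alleles) <- "integer"
  rownames(alleles) <- df$strain
  bed <- read.delim(marker_bed, header = FALSE,
                    col.names = c("chrom", "start", "end", "id"))
  markers <- data.frame(chrom = bed$chrom, pos = bed$end, id = bed$id,
                        stringsAsFactors = FALSE)
  markers <- markers[match(colnames(alleles), markers$id), ]
  rownames(markers) <- NULL
  structure(list(strain_ids = df$strain, markers = markers,
                 alleles = alleles), class = "genotype_matrix")
}

#' Write marker positions as BED4 (0-based half-open)
#' @param g a `genotype_matrix`
#' @param path output BED
#' @export
write_markers_bed <- function(g, path) {
  m <- g$markers
  write.table(data.frame(m$chrom, m$pos - 1L, m$pos, m$id),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a numeric matrix as TSV with row names in `id`
#' @param x matrix
#' @param path output TSV
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(id = rownames(x), as.matrix(x), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$id
  m
}

#' Write / read library metadata as TSV
#' @param meta metadata data.frame
#' @param path output TSV
#' @export
write_meta_tsv <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_meta_tsv
#' @export
read_meta_tsv <- function(path) read.delim(path)

#' Write / read equivalence-class counts as TSV
#'
#' One row per class: comma-separated member ids, then one count column
#' per library.
#' @param ec an `ec_set`
#' @param path output TSV
#' @export
write_ec_tsv <- function(ec, path) {
  stopifnot(inherits(ec, "ec_set"))
  members <- vapply(ec$members, paste, character(1), collapse = ",")
  df <- data.frame(members = members, ec$counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ec_tsv
#' @export
read_ec_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  ec_set(strsplit(df$members, ","),
         as.matrix(df[, -1L, drop = FALSE]))
}
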