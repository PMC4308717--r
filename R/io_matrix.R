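# Tabular data model shared by every stage: expression matrices, orthology
# maps, junction/boundary count tables. All TSV, header row = sample ids,
# first column = feature id.

#' Construct an expression matrix
#'
#' Genes x samples matrix of non-negative abundances (RPKM) carrying a species
#' tag and an optional replicate-to-biosample pairing. Missing values are `NA`
#' (not quantified), distinct from 0 (reproducibly undetected).
#'
#' @param values numeric matrix, rows = genes, columns = samples, with
#'   dimnames set.
#' @param species single label for the species of the panel.
#' @param replicate_of optional named character vector mapping each sample id
#'   to its biosample, used by [filter_reproducible()].
#' @return the matrix with class `expr_matrix` and attributes `species`,
#'   `replicate_of`.
#' @export
expression_matrix <- function(values, species = NA_character_, replicate_of = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicated gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicated sample ids")
  if (any(values < 0, na.rm = TRUE)) stop("negative abundance values")
  if (!is.null(replicate_of)) {
    if (is.null(names(replicate_of)) || !all(colnames(values) %in% names(replicate_of))) {
      stop("'replicate_of' must name every sample")
    }
    replicate_of <- replicate_of[colnames(values)]
  }
  structure(values,
            species = as.character(species)[1L],
            replicate_of = replicate_of,
            class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d samples (species: %s)\n",
              nrow(x), ncol(x), attr(x, "species")))
  if (!is.null(attr(x, "replicate_of"))) {
    cat(sprintf("  replicate pairing over %d biosamples\n",
                length(unique(attr(x, "replicate_of")))))
  }
  print(head(unclass(x)[, seq_len(min(ncol(x), 5L)), drop = FALSE], 5L), ...)
  invisible(x)
}

#' Write a feature-by-sample matrix as TSV
#'
#' Values are printed with `%.6g`; [read_matrix()] on the result round-trips
#' bit-identically when re-written.
#'
#' @param m numeric matrix with dimnames.
#' @param path output file.
#' @param id_col header for the feature-id column.
#' @export
write_matrix <- function(m, path, id_col = "feature_id") {
  fmt <- apply(m, 2L, function(v) {
    out <- sprintf("%.6g", v)
    out[is.na(v)] <- "NA"
    out
  })
  if (nrow(m) == 1L) fmt <- matrix(fmt, nrow = 1L)
  df <- data.frame(rownames(m), fmt, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature-by-sample TSV matrix
#'
#' @param path TSV with header row of sample ids and feature ids in the first
#'   column.
#' @param species,replicate_of passed to [expression_matrix()]; use
#'   `species = NULL` to get a bare matrix.
#' @return an `expr_matrix` (or bare matrix if `species` is `NULL`).
#' @export
read_matrix <- function(path, species = NA_character_, replicate_of = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix file needs an id column and at least one sample")
  if (anyDuplicated(df[[1L]])) stop("duplicated feature id in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  if (is.null(species)) return(m)
  expression_matrix(m, species = species, replicate_of = replicate_of)
}

#' Read a one-to-one orthology table
#'
#' @param path two-column TSV (id in species 1, id in species 2).
#' @param header whether the file carries a header line (default `FALSE`).
#' @return data.frame with columns `id1`, `id2`; rejected unless one-to-one.
#' @export
read_orthology <- function(path, header = FALSE) {
  df <- read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("orthology file needs two columns")
  orthology_map(df[[1L]], df[[2L]])
}

#' Construct a one-to-one orthology map
#'
#' @param id1,id2 equal-length id vectors for the two species.
#' @return data.frame with columns `id1`, `id2`.
#' @export
orthology_map <- function(id1, id2) {
  id1 <- as.character(id1); id2 <- as.character(id2)
  if (length(id1) != length(id2)) stop("orthology columns differ in length")
  if (anyDuplicated(id1)) stop("orthology not one-to-one: duplicated id in column 1")
  if (anyDuplicated(id2)) stop("orthology not one-to-one: duplicated id in column 2")
  data.frame(id1 = id1, id2 = id2, stringsAsFactors = FALSE)
}

#' Read a splice-junction split-read count table
#'
#' Native 6-column format: chrom, donor position, acceptor position (0-based),
#' strand, sample, split-read count. Donor/acceptor are splice-site
#' coordinates; on the minus strand the donor position exceeds the acceptor
#' position in genomic coordinates.
#'
#' @param path TSV file.
#' @param header whether the file carries a header line (default `TRUE`).
#' @return data.frame `chrom, donor, acceptor, strand, sample, n` plus a
#'   `junction_id` key `chrom:donor:acceptor:strand`.
#' @export
read_junctions <- function(path, header = TRUE) {
  df <- read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("junction file needs 6 columns")
  df <- df[, 1:6]
  colnames(df) <- c("chrom", "donor", "acceptor", "strand", "sample", "n")
  junction_table(df)
}

#' Assemble a junction count table
#'
#' @param df data.frame with columns `chrom, donor, acceptor, strand, sample, n`.
#' @return validated data.frame with a `junction_id` column, class
#'   `junction_table`.
#' @export
junction_table <- function(df) {
  need <- c("chrom", "donor", "acceptor", "strand", "sample", "n")
  if (!all(need %in% colnames(df))) {
    stop("junction table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$n < 0)) stop("negative split-read count")
  if (any(df$donor == df$acceptor)) stop("junction with donor == acceptor")
  bad <- df$strand == "-" & df$donor <= df$acceptor
  if (any(bad)) stop("minus-strand junction with donor <= acceptor")
  df$junction_id <- paste(df$chrom, df$donor, df$acceptor, df$strand, sep = ":")
  if (anyDuplicated(df[, c("junction_id", "sample")])) {
    stop("duplicated (junction, sample) record")
  }
  class(df) <- c("junction_table", "data.frame")
  df
}

#' Read splice-site boundary (exon-intron) read counts
#'
#' @param path TSV with columns chrom, position, side (`donor`/`acceptor`),
#'   sample, continuous-read count.
#' @param header whether the file carries a header line (default `TRUE`).
#' @return data.frame `chrom, pos, side, sample, e`.
#' @export
read_boundaries <- function(path, header = TRUE) {
  df <- read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(df) < 5L) stop("boundary file needs 5 columns")
  df <- df[, 1:5]
  colnames(df) <- c("chrom", "pos", "side", "sample", "e")
  if (any(df$e < 0)) stop("negative boundary-read count")
  if (!all(df$side %in% c("donor", "acceptor"))) {
    stop("boundary side must be 'donor' or 'acceptor'")
  }
  if (anyDuplicated(df[, c("chrom", "pos", "side", "sample")])) {
    stop("duplicated (splice site, sample) boundary record")
  }
  df
}
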