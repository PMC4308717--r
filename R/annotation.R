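# Gene models, genome partition and distances. Internal coordinates are
# 0-based half-open everywhere; GTF (1-based closed) is converted on read and
# write. Interval algebra is delegated to IRanges/GenomicRanges.

#' Construct gene models
#'
#' @param genes data.frame with columns `gene_id, chrom, start, end, strand`
#'   (0-based half-open) and optionally `transcript_ids` (comma-separated).
#' @param exons data.frame with columns `gene_id, chrom, start, end`
#'   (0-based half-open); overlapping exons of a gene are merged.
#' @return object of class `gene_models`: list with elements `genes`
#'   (including `exonic_length`, the merged-exon union length) and `exons`
#'   (merged, sorted).
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% colnames(genes)),
            all(c("gene_id", "chrom", "start", "end") %in% colnames(exons)))
  if (any(genes$start >= genes$end)) stop("gene with start >= end")
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene_id")
  if (!all(exons$gene_id %in% genes$gene_id)) stop("exon for unknown gene")

  # merge overlapping exons per gene
  exons <- as.data.frame(exons)
  empty_exons <- data.frame(gene_id = character(), chrom = character(),
                            start = integer(), end = integer(),
                            stringsAsFactors = FALSE)
  merged <- if (nrow(exons) == 0L) empty_exons else
    do.call(rbind, lapply(split(exons, exons$gene_id), function(e) {
    ir <- IRanges::reduce(IRanges::IRanges(start = e$start + 1L, end = e$end))
    data.frame(gene_id = e$gene_id[1L], chrom = e$chrom[1L],
               start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
               stringsAsFactors = FALSE)
    }))
  rownames(merged) <- NULL

  exlen <- vapply(split(merged$end - merged$start, merged$gene_id), sum, numeric(1))
  genes$exonic_length <- unname(exlen[genes$gene_id])
  genes$exonic_length[is.na(genes$exonic_length)] <- 0

  # extend gene span to cover stray exons (warned about by the reader)
  sp <- split(merged, merged$gene_id)
  for (g in names(sp)) {
    i <- match(g, genes$gene_id)
    genes$start[i] <- min(genes$start[i], sp[[g]]$start)
    genes$end[i] <- max(genes$end[i], sp[[g]]$end)
  }
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  merged <- merged[order(merged$chrom, merged$start, merged$gene_id), , drop = FALSE]
  structure(list(genes = genes, exons = merged), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene models: %d genes, %d merged exons on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons), length(unique(x$genes$chrom))))
  invisible(x)
}

#' Read gene models from GTF
#'
#' Parses exon features (Ensembl dialect, `gene_id`/`transcript_id`
#' attributes), converts to 0-based half-open coordinates and merges
#' overlapping exons per gene. Gene spans come from `gene` features when
#' present, otherwise from the exon union; an exon outside a declared gene
#' span extends the span with a warning.
#'
#' @param path GTF file (1-based closed coordinates).
#' @return `gene_models`, ordered by (chrom, start, gene_id).
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  if (!any(keep)) {
    warning("empty annotation file: ", path)
    return(gene_models(
      data.frame(gene_id = character(), chrom = character(), start = integer(),
                 end = integer(), strand = character(), stringsAsFactors = FALSE),
      data.frame(gene_id = character(), chrom = character(), start = integer(),
                 end = integer(), stringsAsFactors = FALSE)))
  }
  nf <- lengths(strsplit(lines[keep], "\t", fixed = TRUE))
  if (any(nf < 9L)) {
    stop(sprintf("malformed GTF line %d: expected 9 tab-separated fields",
                 which(keep)[which(nf < 9L)[1L]]))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  if (!"type" %in% colnames(S4Vectors::mcols(gr))) stop("GTF without feature type column")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) stop("GTF contains no exon features")
  if (is.null(ex$gene_id) || anyNA(ex$gene_id)) stop("exon feature without gene_id")

  exons <- data.frame(gene_id = as.character(ex$gene_id),
                      chrom = as.character(GenomicRanges::seqnames(ex)),
                      start = GenomicRanges::start(ex) - 1L,
                      end = GenomicRanges::end(ex),
                      stringsAsFactors = FALSE)
  tx <- if (!is.null(ex$transcript_id)) {
    vapply(split(as.character(ex$transcript_id), exons$gene_id),
           function(t) paste(sort(unique(t)), collapse = ","), character(1))
  }

  gfeat <- gr[gr$type == "gene"]
  span_from_exons <- do.call(rbind, lapply(split(exons, exons$gene_id), function(e) {
    data.frame(gene_id = e$gene_id[1L], chrom = e$chrom[1L],
               start = min(e$start), end = max(e$end), stringsAsFactors = FALSE)
  }))
  strands <- vapply(split(as.character(GenomicRanges::strand(ex)), exons$gene_id),
                    `[`, character(1), 1L)
  genes <- span_from_exons
  genes$strand <- unname(strands[genes$gene_id])
  if (length(gfeat) > 0L) {
    i <- match(genes$gene_id, as.character(gfeat$gene_id))
    has <- !is.na(i)
    gs <- GenomicRanges::start(gfeat)[i[has]] - 1L
    ge <- GenomicRanges::end(gfeat)[i[has]]
    stray <- genes$start[has] < gs | genes$end[has] > ge
    if (any(stray)) {
      warning(sprintf("%d gene(s) with exons outside the declared span; span extended",
                      sum(stray)))
    }
    genes$start[has] <- pmin(genes$start[has], gs)
    genes$end[has] <- pmax(genes$end[has], ge)
  }
  if (!is.null(tx)) genes$transcript_ids <- unname(tx[genes$gene_id])
  gene_models(genes, exons)
}

#' Write gene models as GTF
#'
#' Inverse of [read_annotation()]: emits one `gene` feature per gene and one
#' `exon` feature per merged exon, converting back to 1-based closed
#' coordinates.
#'
#' @param gm `gene_models`.
#' @param path output GTF file.
#' @export
write_annotation <- function(gm, path) {
  g <- gm$genes
  e <- gm$exons
  strand_of <- setNames(g$strand, g$gene_id)
  lines <- c(
    sprintf("%s\txconstraint\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
            g$chrom, g$start + 1L, g$end, g$strand, g$gene_id),
    sprintf("%s\txconstraint\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\";",
            e$chrom, e$start + 1L, e$end, strand_of[e$gene_id], e$gene_id, e$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Partition a genome into exonic, intronic and intergenic regions
#'
#' A position is exonic if inside any gene's exon (either strand), else
#' intronic if inside any gene span, else intergenic; the three labels give a
#' disjoint cover of every chromosome. Precedence exonic > intronic >
#' intergenic resolves overlaps between genes.
#'
#' @param gm `gene_models`.
#' @param chrom_sizes named vector of chromosome lengths covering every
#'   chromosome in `gm`.
#' @return object of class `region_partition`: data.frame
#'   `chrom, start, end, label` (0-based half-open) plus a `chrom_sizes`
#'   attribute.
#' @export
partition_genome <- function(gm, chrom_sizes) {
  g <- gm$genes
  missing_chr <- setdiff(g$chrom, names(chrom_sizes))
  if (length(missing_chr)) stop("chrom_sizes missing: ", paste(missing_chr, collapse = ", "))
  if (any(g$end > chrom_sizes[g$chrom])) {
    bad <- g$gene_id[g$end > chrom_sizes[g$chrom]][1L]
    stop("gene beyond chromosome end: ", bad)
  }
  si <- GenomeInfoDb_seqinfo(chrom_sizes)
  genome <- GenomicRanges::GRanges(names(chrom_sizes),
                                   IRanges::IRanges(1L, unname(chrom_sizes)),
                                   seqinfo = si)
  exonic <- if (nrow(gm$exons)) {
    GenomicRanges::reduce(GenomicRanges::GRanges(
      gm$exons$chrom, IRanges::IRanges(gm$exons$start + 1L, gm$exons$end), seqinfo = si))
  } else GenomicRanges::GRanges(seqinfo = si)
  genic <- if (nrow(g)) {
    GenomicRanges::reduce(GenomicRanges::GRanges(
      g$chrom, IRanges::IRanges(g$start + 1L, g$end), seqinfo = si))
  } else GenomicRanges::GRanges(seqinfo = si)
  intronic <- GenomicRanges::setdiff(genic, exonic)
  intergenic <- GenomicRanges::setdiff(genome, genic)

  as_df <- function(gr, label) {
    if (length(gr) == 0L) {
      return(data.frame(chrom = character(), start = integer(), end = integer(),
                        label = character(), stringsAsFactors = FALSE))
    }
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               label = label, stringsAsFactors = FALSE)
  }
  out <- rbind(as_df(exonic, "exonic"), as_df(intronic, "intronic"),
               as_df(intergenic, "intergenic"))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, chrom_sizes = chrom_sizes, class = c("region_partition", "data.frame"))
}

# seqinfo constructor kept local so GenomeInfoDb is not a direct dependency
# (it ships with GenomicRanges).
GenomeInfoDb_seqinfo <- function(chrom_sizes) {
  GenomeInfoDb::Seqinfo(seqnames = names(chrom_sizes),
                        seqlengths = unname(as.integer(chrom_sizes)))
}

#' Summarise a region partition
#'
#' @param object `region_partition`.
#' @param ... unused.
#' @return named vector of total nucleotides per label.
#' @export
summary.region_partition <- function(object, ...) {
  vapply(split(object$end - object$start, object$label), sum, numeric(1))
}

#' Distance from intervals to the nearest gene
#'
#' 0 for intervals overlapping any gene span (either strand); otherwise the
#' gap in nucleotides to the closest gene start/end. Intervals on chromosomes
#' absent from the annotation get `NA` with a warning.
#'
#' @param bins data.frame with columns `chrom, start, end` (0-based half-open).
#' @param gm `gene_models`.
#' @return integer vector of distances, one per row of `bins`.
#' @export
distance_to_nearest_gene <- function(bins, gm) {
  g <- gm$genes
  if (nrow(g) == 0L) {
    warning("no genes in annotation; all distances undefined")
    return(rep(NA_integer_, nrow(bins)))
  }
  bgr <- GenomicRanges::GRanges(bins$chrom, IRanges::IRanges(bins$start + 1L, bins$end))
  ggr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start + 1L, g$end))
  # GRanges warns when a bin's chromosome has no genes; we report that case
  # ourselves below
  hits <- suppressWarnings(
    GenomicRanges::distanceToNearest(bgr, ggr, ignore.strand = TRUE))
  d <- rep(NA_integer_, nrow(bins))
  d[S4Vectors::queryHits(hits)] <- as.integer(S4Vectors::mcols(hits)$distance)
  if (anyNA(d)) {
    warning(sum(is.na(d)), " bin(s) on chromosomes without genes; distance undefined")
  }
  d
}

#' Read a bedGraph coverage track
#'
#' Intervals are 0-based half-open; strand-specific coverage is conventionally
#' supplied as separate plus/minus files. Overlapping intervals are rejected.
#'
#' @param path bedGraph file.
#' @return `GRanges` with a numeric `score` column.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(ov) > 0L) {
    stop(sprintf("bedGraph with overlapping intervals (records %d and %d)",
                 S4Vectors::queryHits(ov)[1L], S4Vectors::subjectHits(ov)[1L]))
  }
  if (any(gr$score < 0)) stop("negative coverage value")
  gr
}

#' Write a coverage track as bedGraph
#'
#' @param gr `GRanges` with a `score` column (or data.frame
#'   `chrom, start, end, value`, 0-based half-open).
#' @param path output file.
#' @export
write_bedgraph <- function(gr, path) {
  if (is.data.frame(gr)) {
    df <- gr
    lines <- sprintf("%s\t%d\t%d\t%s", df$chrom, df$start, df$end,
                     sprintf("%.6g", df$value))
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s", as.character(GenomicRanges::seqnames(gr)),
                     GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                     sprintf("%.6g", gr$score))
  }
  writeLines(lines, path)
  invisible(path)
}
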