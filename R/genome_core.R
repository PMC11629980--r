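# Core coordinate conventions:
#   * all intervals are 0-based, half-open [start, end), as in BED
#   * an interval is a data.frame with columns chrom, start, end and
#     optionally label and score
#   * a gene table additionally carries gene_id, strand, tss, tes

#' The ten-state chromatin vocabulary
#'
#' Returns the chromatin-state labels used throughout the package, in their
#' conventional order: two promoter states (TssA, TssAFlnk), four enhancer
#' states (EnhG, Str.Enh, MidEnh, EnhPois), an accessible CpG state
#' (ATAC-CpG), bivalent enhancers (BivEnh), polycomb-repressed (ReprPC) and
#' quiescent (Quies).
#'
#' @return Character vector of length 10.
#' @export
chromatin_states <- function() {
  c("TssA", "TssAFlnk", "EnhG", "Str.Enh", "MidEnh",
    "EnhPois", "ATAC-CpG", "BivEnh", "ReprPC", "Quies")
}

#' Active chromatin states (states 1-5)
#' @return Character vector of the five active states.
#' @export
active_states <- function() chromatin_states()[1:5]

#' Enhancer states used for QTL intersection
#' @return The genic, strong and intermediate enhancer labels.
#' @export
qtl_enhancer_states <- function() c("EnhG", "Str.Enh", "MidEnh")

#' Construct a genome model from chromosome sizes
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @return A `genome_model` object (named list with `chrom_sizes` and the
#'   total genome size `D`).
#' @export
genome_model <- function(chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be > 0")
  structure(list(chrom_sizes = chrom_sizes, D = sum(as.numeric(chrom_sizes))),
            class = "genome_model")
}

#' Read a UCSC-style chrom.sizes file
#'
#' @param path Two-column TSV: chromosome name, length in bp.
#' @return A [genome_model()].
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "numeric"))
  genome_model(stats::setNames(df$size, df$chrom))
}

#' Write a chrom.sizes file
#' @param genome A [genome_model()].
#' @param path Output path.
#' @export
write_chrom_sizes <- function(genome, path) {
  utils::write.table(
    data.frame(chrom = names(genome$chrom_sizes),
               size = format(genome$chrom_sizes, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Validate an interval data.frame
#'
#' Checks the interval invariants: required columns present, numeric
#' coordinates, `0 <= start < end`.
#'
#' @param x data.frame with chrom, start, end.
#' @param what Name used in error messages.
#' @return `x` invisibly; stops on violation.
#' @export
validate_intervals <- function(x, what = "intervals") {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(x$start) || !is.numeric(x$end))
    stop(what, ": start/end must be numeric")
  bad <- which(x$start < 0 | x$start >= x$end)
  if (length(bad))
    stop(what, ": invalid interval (need 0 <= start < end) at row ", bad[1])
  invisible(x)
}

#' Read intervals from a BED or TSV file
#'
#' BED columns are chrom, start, end and optionally name (-> `label`) and
#' score; coordinates are taken verbatim as 0-based half-open. A TSV with a
#' header row containing at least chrom, start, end is also accepted.
#'
#' @param path File path.
#' @param format `"bed"` (headerless) or `"tsv"` (header row).
#' @return data.frame of intervals, input order preserved.
#' @export
read_intervals <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    x <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
    return(validate_intervals(as.data.frame(x), path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], " in ", path,
         ": fewer than 3 fields")
  start <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  end   <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1], " in ",
         path, ": non-numeric coordinate")
  out <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                    start = start, end = end,
                    stringsAsFactors = FALSE)
  if (all(nf >= 4)) out$label <- vapply(parts, `[`, "", 4L)
  if (all(nf >= 5))
    out$score <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 5L)))
  validate_intervals(out, path)
}

#' Write intervals as BED
#'
#' Writes BED3/4/5 depending on which of `label`/`score` are present.
#'
#' @param x Interval data.frame.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- data.frame(chrom = x$chrom,
                     start = format(x$start, scientific = FALSE, trim = TRUE),
                     end = format(x$end, scientific = FALSE, trim = TRUE))
  if (!is.null(x$label)) cols$label <- x$label
  if (!is.null(x$score)) {
    if (is.null(cols$label)) cols$label <- "."
    cols$score <- x$score
  }
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# interval data.frame -> GRanges (internal; shifts to 1-based closed)
.as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end))
}

# GRanges -> interval data.frame (back to 0-based half-open)
.from_granges <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Overlap length of two intervals
#'
#' Vectorized over rows; intervals on different chromosomes have overlap 0,
#' as do half-open abutting intervals.
#'
#' @param a,b Interval data.frames (single rows or equal-length).
#' @return Numeric vector of overlap lengths in bp.
#' @export
overlap_length <- function(a, b) {
  validate_intervals(a, "a"); validate_intervals(b, "b")
  same <- a$chrom == b$chrom
  pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start)) * as.numeric(same)
}

#' All overlapping query/subject interval pairs
#'
#' Equivalent to the all-pairs brute force: returns exactly the pairs whose
#' overlap length is positive.
#'
#' @param query,subject Interval data.frames.
#' @return data.frame with `query_idx`, `subject_idx` (row indices) and
#'   `overlap_bp`.
#' @export
find_overlaps <- function(query, subject) {
  validate_intervals(query, "query"); validate_intervals(subject, "subject")
  if (!nrow(query) || !nrow(subject))
    return(data.frame(query_idx = integer(), subject_idx = integer(),
                      overlap_bp = numeric()))
  qg <- .as_granges(query); sg <- .as_granges(subject)
  # disjoint chromosome sets are a valid query (zero overlaps), not worth
  # the seqlevel warning GenomicRanges emits
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(qg, sg, minoverlap = 1L))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(qg)[qi],
                                           IRanges::ranges(sg)[si]))
  data.frame(query_idx = qi, subject_idx = si, overlap_bp = as.numeric(ov))
}

#' Merge overlapping or book-ended intervals
#'
#' @param x Interval data.frame.
#' @return Merged intervals sorted by (chrom, start, end).
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  if (!nrow(x)) return(x[, c("chrom", "start", "end")])
  .from_granges(GenomicRanges::reduce(.as_granges(x)))
}

#' Total bases covered by an interval set
#'
#' Overlapping input intervals are merged first, so each base counts once.
#'
#' @param x Interval data.frame.
#' @return Number of covered bases.
#' @export
interval_bases <- function(x) {
  m <- merge_intervals(x)
  sum(m$end - m$start)
}

#' Read a gene table
#'
#' TSV with header `gene_id, chrom, start, end, strand` plus one TPM column
#' per tissue. TSS/TES are derived from the strand (TSS = start on `+`,
#' end on `-`).
#'
#' @param path File path.
#' @return data.frame with derived `tss`/`tes` columns; TPM columns keep
#'   their tissue names.
#' @export
read_gene_table <- function(path) {
  g <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(g))
  if (length(miss)) stop("gene table missing column(s): ",
                         paste(miss, collapse = ", "))
  validate_intervals(g, "gene table")
  if (!all(g$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  g$tss <- ifelse(g$strand == "+", g$start, g$end)
  g$tes <- ifelse(g$strand == "+", g$end, g$start)
  g
}

#' Write a gene table
#' @param genes Gene data.frame (from [read_gene_table()] or the simulator).
#' @param path Output path.
#' @param tpm Optional TPM matrix (rownames = gene_id) appended as columns.
#' @export
write_gene_table <- function(genes, path, tpm = NULL) {
  out <- genes[, c("gene_id", "chrom", "start", "end", "strand")]
  if (!is.null(tpm)) {
    stopifnot(all(genes$gene_id %in% rownames(tpm)))
    out <- cbind(out, as.data.frame(tpm[genes$gene_id, , drop = FALSE]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the TPM matrix from a gene table
#' @param genes Gene table with TPM columns.
#' @param tissues Tissue column names.
#' @return Numeric matrix genes x tissues with gene_id rownames.
#' @export
gene_tpm_matrix <- function(genes, tissues) {
  miss <- setdiff(tissues, names(genes))
  if (length(miss)) stop("missing TPM column(s): ", paste(miss, collapse = ", "))
  m <- as.matrix(genes[, tissues, drop = FALSE])
  rownames(m) <- genes$gene_id
  m
}

# 0-based coordinate of the actual TSS base (start on +, end-1 on -)
.tss_base <- function(genes) {
  ifelse(genes$strand == "+", genes$tss, genes$tss - 1)
}

#' Strand-aware window around gene TSSs
#'
#' On the `+` strand the window is `[tss - upstream, tss + downstream)`; on
#' the `-` strand "upstream" extends toward larger coordinates, giving
#' `[tss - downstream, tss + upstream)`. Windows are clipped to
#' `[0, chromosome length)` when a genome model is supplied.
#'
#' @param genes Gene data.frame (one or more rows).
#' @param upstream,downstream Extents in bp (>= 0).
#' @param genome Optional [genome_model()] used for clipping; chromosomes
#'   absent from it raise an error.
#' @return Interval data.frame with a `gene_id` column.
#' @export
flank_tss <- function(genes, upstream, downstream, genome = NULL) {
  stopifnot(upstream >= 0, downstream >= 0)
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  if (!is.null(genome)) {
    unknown <- setdiff(unique(genes$chrom), names(genome$chrom_sizes))
    if (length(unknown)) stop("unknown chromosome: ", unknown[1])
    lim <- genome$chrom_sizes[genes$chrom]
    start <- pmax(0, start)
    end <- pmin(lim, end)
  } else {
    start <- pmax(0, start)
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = start, end = end, stringsAsFactors = FALSE)
}

#' Read a per-tissue chromatin-state track
#'
#' A BED4 file whose name field is the state label; labels are checked
#' against the 10-state vocabulary.
#'
#' @param path BED4 path.
#' @param tissue Tissue name attached as attribute.
#' @return Interval data.frame with a `state` column and `tissue` attribute.
#' @export
read_state_track <- function(path, tissue = NA_character_) {
  x <- read_intervals(path, "bed")
  if (is.null(x$label)) stop("state track must be BED4 (state label in col 4)")
  bad <- setdiff(unique(x$label), chromatin_states())
  if (length(bad)) stop("unknown chromatin state label: ", bad[1])
  names(x)[names(x) == "label"] <- "state"
  attr(x, "tissue") <- tissue
  x
}

#' Write a chromatin-state track as BED4
#' @param track State track data.frame (chrom, start, end, state).
#' @param path Output path.
#' @export
write_state_track <- function(track, path) {
  x <- track
  names(x)[names(x) == "state"] <- "label"
  write_bed(x[, c("chrom", "start", "end", "label")], path)
}
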