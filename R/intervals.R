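#' Genomic intervals
#'
#' Throughout the package intervals follow the BED convention: 0-based,
#' half-open `[start, end)`. Intervals are plain data.frames with columns
#' `chrom`, `start`, `end` and optionally `name` and `score`. These helpers
#' read/write BED and provide the overlap machinery the higher-level
#' modules share (backed by GenomicRanges).
#'
#' @name intervals
NULL

validate_intervals <- function(df, what = "interval") {
  if (any(df$start < 0)) {
    stop(what, " with negative start coordinate")
  }
  if (any(df$start >= df$end)) {
    i <- which(df$start >= df$end)[1]
    stop("empty or inverted ", what, ": ",
         df$chrom[i], ":", df$start[i], "-", df$end[i])
  }
  invisible(df)
}

sort_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

#' Read intervals from a BED file
#'
#' Accepts BED3 and upward; `name` and `score` columns are preserved when
#' present. Records are returned sorted per chromosome. Overlapping records
#' are kept as-is (no merging).
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand` columns; 0-based half-open coordinates.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   stringsAsFactors = FALSE)
  md <- as.data.frame(S4Vectors::mcols(gr))
  for (col in c("name", "score", "strand")) {
    if (col %in% names(md) && !all(is.na(md[[col]]))) df[[col]] <- md[[col]]
  }
  validate_intervals(df)
  sort_intervals(df)
}

#' Write intervals to a BED file
#'
#' Emits BED3/4/5/6 depending on which of `name`, `score`, `strand` are
#' present; tab-separated, newline-terminated.
#'
#' @param df interval data.frame (see [read_intervals()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(df, path) {
  cols <- c("chrom", "start", "end")
  if (!is.null(df$name)) cols <- c(cols, "name")
  if (!is.null(df$score)) {
    if (is.null(df$name)) df$name <- "."
    cols <- union(c(cols, "name"), "score")
  }
  if (!is.null(df$strand)) {
    if (is.null(df$name)) df$name <- "."
    if (is.null(df$score)) df$score <- 0
    cols <- union(c(cols, "name", "score"), "strand")
  }
  out <- as.data.frame(df)[, cols, drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chromosome sizes table
#'
#' Two tab-separated columns: chromosome name and length in bp.
#'
#' @param path file path.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          stringsAsFactors = FALSE)
  if (any(df$size <= 0)) stop("non-positive chromosome length in ", path)
  stats::setNames(as.numeric(df$size), df$chrom)
}

#' @rdname read_chrom_sizes
#' @param sizes named numeric vector of chromosome lengths.
#' @export
write_chrom_sizes <- function(sizes, path) {
  utils::write.table(data.frame(names(sizes), as.integer(sizes)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- internal overlap machinery ------------------------------------------

# data.frame (0-based half-open) -> GRanges (1-based closed)
as_granges <- function(df) {
  if (nrow(df) == 0L) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(df$chrom, IRanges(df$start + 1L, df$end))
}

granges_to_df <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             stringsAsFactors = FALSE)
}

# pairs (query, subject) of >= 1 bp overlaps between two interval frames
overlap_pairs <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(query = integer(), subject = integer()))
  }
  hits <- suppressWarnings(findOverlaps(as_granges(a), as_granges(b)))
  data.frame(query = queryHits(hits), subject = subjectHits(hits))
}

# union of possibly-overlapping intervals, as a sorted disjoint frame
merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  sort_intervals(granges_to_df(reduce(as_granges(df))))
}

total_bp <- function(df) {
  if (nrow(df) == 0L) return(0)
  sum(as.numeric(df$end) - as.numeric(df$start))
}

# bp of the intersection of two interval sets
intersect_bp <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  total_bp(granges_to_df(GenomicRanges::intersect(
    reduce(as_granges(a)), reduce(as_granges(b)))))
}

#' Base-level Jaccard index of two interval sets
#'
#' `|A intersect B| / |A union B|` in bp, after merging overlaps within
#' each set. Used to score recovery of planted hypomethylated segments.
#'
#' @param a,b interval data.frames.
#' @return numeric scalar in \[0, 1\] (`NA` if both sets are empty).
#' @export
interval_jaccard <- function(a, b) {
  ib <- intersect_bp(a, b)
  ub <- total_bp(merge_intervals(rbind(a[, c("chrom", "start", "end")],
                                       b[, c("chrom", "start", "end")])))
  if (ub == 0) return(NA_real_)
  ib / ub
}

# which sites (chrom, pos vectors) fall inside any interval of df
sites_in_intervals <- function(chroms, positions, df) {
  if (length(positions) == 0L || nrow(df) == 0L) {
    return(rep(FALSE, length(positions)))
  }
  q <- GenomicRanges::GRanges(chroms, IRanges(positions + 1L, positions + 1L))
  suppressWarnings(IRanges::overlapsAny(q, as_granges(df)))
}
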