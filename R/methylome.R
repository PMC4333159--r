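#' Methylome objects
#'
#' A methylome is a per-CpG table of methylated and total read counts, one
#' row per cytosine record, sorted by chromosome and position. Coordinates
#' are 0-based: `pos` is the offset of the plus-strand C of the CG dyad
#' (minus-strand records, when present, sit at `pos + 1`; see
#' [merge_symmetric()]).
#'
#' @param sites data.frame with columns `chrom`, `pos`, `strand`, `context`,
#'   `meth`, `cov`.
#' @param sample_id sample identifier attached to the object.
#' @return An object of class `methylome` (a `data.table` underneath).
#' @export
methylome <- function(sites, sample_id = "sample") {
  dt <- data.table::as.data.table(sites)
  required <- c("chrom", "pos", "strand", "context", "meth", "cov")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols) > 0L) {
    stop("methylome is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  dt <- dt[, required, with = FALSE]
  dt[, pos := as.integer(pos)]
  dt[, meth := as.integer(meth)]
  dt[, cov := as.integer(cov)]
  if (any(dt$meth < 0L) || any(dt$cov < 0L)) {
    stop("negative counts in methylome")
  }
  if (any(dt$meth > dt$cov)) {
    stop("methylated count exceeds coverage at ",
         sum(dt$meth > dt$cov), " site(s)")
  }
  o <- order(dt$chrom, dt$pos)
  if (!identical(o, seq_len(nrow(dt)))) {
    dt <- dt[o]
  }
  if (anyDuplicated(dt[, c("chrom", "pos")])) {
    stop("duplicate (chrom, pos) records in methylome")
  }
  data.table::setattr(dt, "sample_id", sample_id)
  data.table::setattr(dt, "class", c("methylome", class(data.table::data.table())))
  dt
}

#' @export
print.methylome <- function(x, ...) {
  cat(sprintf("methylome '%s': %d sites on %d chromosome(s), mean coverage %.1f\n",
              sample_id(x), nrow(x), length(unique(x$chrom)),
              mean(x$cov)))
  print(data.table::as.data.table(utils::head(as.data.frame(x), 6)))
  invisible(x)
}

#' @rdname methylome
#' @param m a `methylome`.
#' @export
sample_id <- function(m) attr(m, "sample_id") %||% "sample"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-site methylation level
#'
#' `meth / cov`, `NA` where coverage is zero.
#'
#' @param m a `methylome`.
#' @return numeric vector, one value per site.
#' @export
meth_level <- function(m) {
  lv <- m$meth / m$cov
  lv[m$cov == 0L] <- NA_real_
  lv
}

#' Read a per-CpG methylation count table
#'
#' The native format is tab-separated with six columns: chrom, pos (0-based),
#' strand, context, methylated count, total count. Lines starting with `#`
#' are treated as headers. A level-based dialect (column 5 a methylation
#' fraction in \[0, 1\] with a decimal point instead of a count) is detected
#' automatically; counts are then reconstructed as `round(level * cov)`.
#'
#' @param path file path.
#' @param context_filter character vector of contexts to keep
#'   (default `"CG"`; use `c("CG", "CHG", "CHH")` to keep everything).
#' @param min_cov minimum total read count for a site to be returned.
#' @param sample_id sample identifier (defaults to the file name).
#' @return a [methylome].
#' @export
read_methylome <- function(path, context_filter = "CG", min_cov = 0L,
                           sample_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (length(lines) == 0L) {
    return(methylome(data.frame(chrom = character(), pos = integer(),
                                strand = character(), context = character(),
                                meth = integer(), cov = integer()),
                     sample_id = sample_id))
  }
  fields <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(fields) < 6L) {
    stop("expected >= 6 tab-separated fields in ", path)
  }
  bad <- is.na(fields[[6]])
  if (any(bad)) {
    stop("malformed line(s) ", paste(lineno[bad][seq_len(min(5, sum(bad)))],
                                     collapse = ", "),
         " in ", path, ": fewer than 6 fields")
  }
  pos <- suppressWarnings(as.integer(fields[[2]]))
  covv <- suppressWarnings(as.numeric(fields[[6]]))
  f5 <- fields[[5]]
  f5num <- suppressWarnings(as.numeric(f5))
  bad <- is.na(pos) | is.na(f5num) | is.na(covv)
  if (any(bad)) {
    stop("non-numeric field on line ", lineno[which(bad)[1]], " in ", path)
  }
  # level dialect: every value in column 5 carries a decimal point and
  # lies in [0, 1]
  level_dialect <- all(grepl(".", f5, fixed = TRUE)) &&
    all(f5num >= 0 & f5num <= 1)
  if (level_dialect) {
    methv <- as.integer(round(f5num * covv))
  } else {
    if (any(f5num != floor(f5num)) || any(covv != floor(covv))) {
      i <- which(f5num != floor(f5num) | covv != floor(covv))[1]
      stop("non-integer count on line ", lineno[i], " in ", path)
    }
    methv <- as.integer(f5num)
  }
  covv <- as.integer(covv)
  over <- methv > covv
  if (any(over)) {
    stop("meth > cov on line ", lineno[which(over)[1]], " in ", path)
  }
  dt <- data.table::data.table(
    chrom = fields[[1]], pos = pos, strand = fields[[3]],
    context = fields[[4]], meth = methv, cov = covv)
  o <- order(dt$chrom, dt$pos)
  if (!identical(o, seq_len(nrow(dt)))) {
    warning("input methylome ", path, " was not sorted; sorting")
    dt <- dt[o]
  }
  dt <- dt[dt$context %in% context_filter & dt$cov >= min_cov]
  methylome(dt, sample_id = sample_id)
}

#' Write a methylome to a tab-separated count table
#'
#' Output round-trips exactly through [read_methylome()] (same records,
#' same order). A single `#`-prefixed header line is written first.
#'
#' @param m a [methylome].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_methylome <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tpos\tstrand\tcontext\tmeth\tcov", con)
  if (nrow(m) > 0L) {
    writeLines(paste(m$chrom, m$pos, m$strand, m$context, m$meth, m$cov,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Merge strand-symmetric CpG records into dyad records
#'
#' CG methylation is palindromic: a plus-strand record at position `p` and a
#' minus-strand record at `p + 1` measure the same CG dyad. This collapses
#' such pairs into a single record at the plus-strand position with summed
#' counts. Lone minus-strand records are shifted to `p - 1` and kept. Total
#' methylated and total read counts are conserved.
#'
#' @param m a [methylome] with per-strand records.
#' @return a [methylome] with one record per dyad, all on the plus strand.
#' @export
merge_symmetric <- function(m) {
  if (nrow(m) == 0L) return(m)
  dt <- data.table::as.data.table(m)
  dt[, pos := ifelse(strand == "-", pos - 1L, pos)]
  merged <- dt[, list(strand = "+", context = context[1L],
                      meth = sum(meth), cov = sum(cov)),
               by = c("chrom", "pos")]
  data.table::setcolorder(merged,
                          c("chrom", "pos", "strand", "context", "meth", "cov"))
  methylome(merged, sample_id = sample_id(m))
}
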