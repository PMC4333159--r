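#' Read gene models from a BED12 file
#'
#' @param path BED12 file path.
#' @return data.frame with one row per transcript: `chrom`, `strand`,
#'   `txStart`, `txEnd`, `cdsStart`, `cdsEnd`, `name`, and a list-column
#'   `exons` of per-gene exon data.frames (`start`, `end`, 0-based
#'   half-open, sorted, within the transcript span). Non-coding models have
#'   `cdsStart == cdsEnd`.
#' @export
read_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  txStart <- start(gr) - 1L
  txEnd <- end(gr)
  thick <- mcols(gr)$thick
  if (is.null(thick)) {
    cdsStart <- txStart
    cdsEnd <- txStart
  } else {
    cdsStart <- start(thick) - 1L
    cdsEnd <- end(thick)
    zero <- IRanges::width(thick) == 0L
    cdsEnd[zero] <- cdsStart[zero]
  }
  blocks <- mcols(gr)$blocks
  exons <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    if (is.null(blocks) || length(blocks[[i]]) == 0L) {
      exons[[i]] <- data.frame(start = txStart[i], end = txEnd[i])
    } else {
      b <- blocks[[i]]  # relative 1-based within the transcript
      ex <- data.frame(start = txStart[i] + start(b) - 1L,
                       end = txStart[i] + end(b))
      exons[[i]] <- ex[order(ex$start), , drop = FALSE]
    }
  }
  nm <- mcols(gr)$name
  if (is.null(nm)) nm <- paste0("gene_", seq_along(gr))
  out <- data.frame(chrom = as.character(seqnames(gr)),
                    strand = as.character(BiocGenerics::strand(gr)),
                    txStart = txStart, txEnd = txEnd,
                    cdsStart = cdsStart, cdsEnd = cdsEnd,
                    name = nm, stringsAsFactors = FALSE)
  out$exons <- exons
  out
}

#' Write gene models as BED12
#'
#' @param genes gene model data.frame as returned by [read_genes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    ex <- ex[order(ex$start), , drop = FALSE]
    paste(genes$chrom[i], genes$txStart[i], genes$txEnd[i], genes$name[i],
          0, genes$strand[i], genes$cdsStart[i], genes$cdsEnd[i], "0,0,0",
          nrow(ex),
          paste0(paste(ex$end - ex$start, collapse = ","), ","),
          paste0(paste(ex$start - genes$txStart[i], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Feature label levels, in display order
#' @export
feature_labels <- function() {
  c("Upstream", "Promoter", "5'UTR", "Exon", "Intron", "3'UTR", "Intergenic")
}

# per-label interval frames for a gene model table
feature_windows <- function(genes, promoter_bp = 2000L, upstream_bp = 12000L) {
  n <- nrow(genes)
  plus <- genes$strand != "-"
  clip <- function(df) {
    df$start <- pmax(df$start, 0L)
    df[df$start < df$end, , drop = FALSE]
  }
  win <- function(start, end) {
    data.frame(chrom = genes$chrom, start = start, end = end,
               stringsAsFactors = FALSE)
  }
  promoter <- clip(win(ifelse(plus, genes$txStart - promoter_bp, genes$txEnd),
                       ifelse(plus, genes$txStart, genes$txEnd + promoter_bp)))
  upstream <- clip(win(
    ifelse(plus, genes$txStart - upstream_bp, genes$txEnd + promoter_bp),
    ifelse(plus, genes$txStart - promoter_bp, genes$txEnd + upstream_bp)))

  per_gene <- function(i) {
    ex <- genes$exons[[i]]
    ex_gr <- IRanges(ex$start + 1L, ex$end)
    tx <- IRanges(genes$txStart[i] + 1L, genes$txEnd[i])
    coding <- genes$cdsStart[i] < genes$cdsEnd[i]
    if (coding) {
      cds <- IRanges(genes$cdsStart[i] + 1L, genes$cdsEnd[i])
      left <- IRanges(genes$txStart[i] + 1L,
                      max(genes$txStart[i], genes$cdsStart[i]))
      right <- IRanges(min(genes$cdsEnd[i] + 1L, genes$txEnd[i] + 1L),
                       genes$txEnd[i])
      utr5_span <- if (plus[i]) left else right
      utr3_span <- if (plus[i]) right else left
      utr5 <- IRanges::intersect(ex_gr, utr5_span)
      utr3 <- IRanges::intersect(ex_gr, utr3_span)
      exon <- IRanges::intersect(ex_gr, cds)
    } else {
      utr5 <- utr3 <- IRanges()
      exon <- ex_gr
    }
    intron <- IRanges::setdiff(tx, ex_gr)
    to_df <- function(ir) {
      if (length(ir) == 0L) return(NULL)
      data.frame(chrom = genes$chrom[i], start = start(ir) - 1L,
                 end = end(ir), stringsAsFactors = FALSE)
    }
    list(utr5 = to_df(utr5), utr3 = to_df(utr3),
         exon = to_df(exon), intron = to_df(intron))
  }
  parts <- lapply(seq_len(n), per_gene)
  bind <- function(key) {
    dfs <- Filter(Negate(is.null), lapply(parts, `[[`, key))
    if (length(dfs) == 0L) {
      data.frame(chrom = character(), start = integer(), end = integer())
    } else {
      do.call(rbind, dfs)
    }
  }
  list(Promoter = promoter, `5'UTR` = bind("utr5"), `3'UTR` = bind("utr3"),
       Exon = bind("exon"), Intron = bind("intron"), Upstream = upstream)
}

#' Assign genomic positions to gene-centred feature categories
#'
#' Each position receives exactly one of the labels Upstream, Promoter,
#' 5'UTR, Exon, Intron, 3'UTR or Intergenic. Windows are strand-aware:
#' the promoter is the 2 kb immediately upstream of the TSS and the
#' upstream region the -12..-2 kb window, following the gene's strand.
#' 5'/3' UTRs are the exonic bp between the transcript boundary and the
#' CDS; `Exon` means coding exon. When windows of several genes overlap,
#' the precedence Promoter > 5'UTR > 3'UTR > Exon > Intron > Upstream
#' decides; positions in no window are Intergenic.
#'
#' @param chroms,positions parallel vectors of chromosome names and 0-based
#'   positions.
#' @param genes gene model data.frame (see [read_genes()]).
#' @param promoter_bp promoter window size upstream of the TSS (bp).
#' @param upstream_bp outer edge of the upstream window (bp from TSS).
#' @return factor of feature labels, one per position.
#' @export
assign_feature <- function(chroms, positions, genes,
                           promoter_bp = 2000L, upstream_bp = 12000L) {
  labels <- factor(rep("Intergenic", length(positions)),
                   levels = feature_labels())
  if (is.null(genes) || nrow(genes) == 0L) return(labels)
  wins <- feature_windows(genes, promoter_bp, upstream_bp)
  precedence <- c("Promoter", "5'UTR", "3'UTR", "Exon", "Intron", "Upstream")
  unassigned <- rep(TRUE, length(positions))
  for (lab in precedence) {
    if (!any(unassigned)) break
    hit <- sites_in_intervals(chroms, positions, wins[[lab]])
    take <- unassigned & hit
    labels[take] <- lab
    unassigned <- unassigned & !hit
  }
  labels
}
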