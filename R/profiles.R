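#' Methylation level classes
#'
#' CpGs are binned into three classes by methylation fraction: sparsely
#' methylated (`SPARSE`, below 10%), low-methylated (`LOW`, 10% to 50%
#' inclusive) and highly methylated (`HIGH`, above 50%). The three classes
#' partition \[0, 1\].
#'
#' @param level numeric vector of methylation fractions in \[0, 1\].
#' @return factor with levels `SPARSE`, `LOW`, `HIGH`.
#' @export
classify_cpg_level <- function(level) {
  ok <- !is.na(level)
  if (any(level[ok] < 0 | level[ok] > 1)) {
    stop("methylation level outside [0, 1]")
  }
  cls <- rep(NA_character_, length(level))
  cls[ok & level < 0.1] <- "SPARSE"
  cls[ok & level >= 0.1 & level <= 0.5] <- "LOW"
  cls[ok & level > 0.5] <- "HIGH"
  factor(cls, levels = c("SPARSE", "LOW", "HIGH"))
}

#' Level-class composition of a methylome
#'
#' Counts and fractions of SPARSE/LOW/HIGH CpGs, optionally restricted to
#' CpGs falling inside a set of regions. Only sites with coverage at
#' least `min_cov` are counted.
#'
#' @param m a [methylome].
#' @param regions optional interval frame; `NULL` means genome-wide. An
#'   empty frame selects nothing (all-zero counts).
#' @param min_cov minimum coverage.
#' @return data.frame with `class`, `n`, `fraction` (fractions sum to 1
#'   over counted sites; all NA when nothing is counted).
#' @export
composition <- function(m, regions = NULL, min_cov = 1L) {
  keep <- m$cov >= min_cov & m$cov > 0L
  if (!is.null(regions)) {
    keep <- keep & sites_in_intervals(m$chrom, m$pos, regions)
  }
  cls <- classify_cpg_level(meth_level(m)[keep])
  counts <- table(cls)
  n <- sum(counts)
  data.frame(class = names(counts), n = as.integer(counts),
             fraction = if (n > 0) as.numeric(counts) / n else NA_real_,
             stringsAsFactors = FALSE)
}

#' Mean methylation of CpGs inside one region
#'
#' Unweighted mean of per-site levels with coverage at least `min_cov`.
#'
#' @param m a [methylome].
#' @param interval a one-row interval frame (or list with `chrom`,
#'   `start`, `end`).
#' @param min_cov minimum coverage.
#' @return list with `mean_level` (`NA` if no qualifying site) and
#'   `n_cpg`.
#' @export
region_mean_level <- function(m, interval, min_cov = 1L) {
  sel <- m$chrom == interval$chrom[1] & m$pos >= interval$start[1] &
    m$pos < interval$end[1] & m$cov >= min_cov & m$cov > 0L
  lv <- meth_level(m)[sel]
  list(mean_level = if (length(lv) > 0L) mean(lv) else NA_real_,
       n_cpg = length(lv))
}

#' Mean methylation per gene-centred feature
#'
#' Assigns every covered CpG a feature label with [assign_feature()] and
#' averages levels per label (unweighted over CpGs).
#'
#' @param m a [methylome].
#' @param genes gene models (see [read_genes()]).
#' @param min_cov minimum coverage.
#' @inheritParams assign_feature
#' @return data.frame with `feature`, `mean_level`, `n`.
#' @export
feature_summary <- function(m, genes, min_cov = 1L,
                            promoter_bp = 2000L, upstream_bp = 12000L) {
  keep <- m$cov >= min_cov & m$cov > 0L
  lab <- assign_feature(m$chrom[keep], m$pos[keep], genes,
                        promoter_bp = promoter_bp,
                        upstream_bp = upstream_bp)
  lv <- meth_level(m)[keep]
  means <- tapply(lv, lab, mean)
  ns <- tapply(lv, lab, length)
  data.frame(feature = feature_labels(),
             mean_level = as.numeric(means[feature_labels()]),
             n = ifelse(is.na(ns[feature_labels()]), 0L,
                        as.integer(ns[feature_labels()])),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Four-level methylation summary of a two-tissue comparison
#'
#' The characteristic four levels of CG methylation seen when two
#' tissues' HMR sets are compared: (1) near-total unmethylation inside
#' shared (common) HMRs, (2) low methylation inside a tissue's own
#' tissue-specific HMRs, (3) intermediate methylation over the other
#' tissue's specific HMRs (the footprint), and (4) high background
#' methylation outside all HMRs. Computed per tissue as unweighted CpG
#' means over: the bp-intersection of the two HMR sets, the tissue's own
#' S1 components, the other tissue's S1 components, and the complement of
#' the HMR union.
#'
#' @param comparison an `hmr_comparison` from [compare_sets()].
#' @param methylome_a,methylome_b the two tissues' [methylome]s.
#' @param min_cov minimum coverage.
#' @return data.frame with one row per tissue x class
#'   (`common`, `ts_own`, `ts_other`, `background`), columns `tissue`,
#'   `class`, `mean_level`, `n_cpg`. Classes with no qualifying CpG (e.g.
#'   S1 classes when the HMR sets are identical) report `NA`.
#' @export
four_level_summary <- function(comparison, methylome_a, methylome_b,
                               min_cov = 1L) {
  setA <- comparison$setA
  setB <- comparison$setB
  mergedA <- merge_intervals(setA)
  mergedB <- merge_intervals(setB)
  common <- granges_to_df(GenomicRanges::intersect(as_granges(mergedA),
                                                   as_granges(mergedB)))
  s1a_rows <- unlist(lapply(which(comparison$labels == "S1_A"),
                            function(i) comparison$component_members[[i]]$a))
  s1b_rows <- unlist(lapply(which(comparison$labels == "S1_B"),
                            function(i) comparison$component_members[[i]]$b))
  s1a <- setA[s1a_rows, , drop = FALSE]
  s1b <- setB[s1b_rows, , drop = FALSE]
  union_hmr <- merge_intervals(rbind(mergedA, mergedB))

  mean_over <- function(m, regions, complement = FALSE) {
    keep <- m$cov >= min_cov & m$cov > 0L
    inside <- sites_in_intervals(m$chrom, m$pos, regions)
    sel <- keep & (if (complement) !inside else inside)
    lv <- meth_level(m)[sel]
    c(mean_level = if (length(lv) > 0L) mean(lv) else NA_real_,
      n_cpg = length(lv))
  }
  rows <- list(
    c(tissue = "A", class = "common"), c(tissue = "B", class = "common"),
    c(tissue = "A", class = "ts_own"), c(tissue = "B", class = "ts_own"),
    c(tissue = "A", class = "ts_other"), c(tissue = "B", class = "ts_other"),
    c(tissue = "A", class = "background"),
    c(tissue = "B", class = "background"))
  vals <- rbind(
    mean_over(methylome_a, common), mean_over(methylome_b, common),
    mean_over(methylome_a, s1a), mean_over(methylome_b, s1b),
    mean_over(methylome_a, s1b), mean_over(methylome_b, s1a),
    mean_over(methylome_a, union_hmr, complement = TRUE),
    mean_over(methylome_b, union_hmr, complement = TRUE))
  out <- data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  out$mean_level <- as.numeric(vals[, "mean_level"])
  out$n_cpg <- as.integer(vals[, "n_cpg"])
  out
}

#' Region-scaled methylation matrix
#'
#' The matrix behind HMR-centred heat maps: each region contributes one
#' row; its body is linearly rescaled into `body_bins` columns and flanked
#' on both sides by `flank_bins` fixed-width bins covering `flank_bp` bp.
#' Cells hold the mean CpG level in the bin, `NA` where the bin contains
#' no covered CpG.
#'
#' @param regions interval frame (non-empty).
#' @param m a [methylome].
#' @param body_bins,flank_bp,flank_bins matrix geometry.
#' @param min_cov minimum coverage.
#' @return numeric matrix (rows = regions, columns = left flank, body,
#'   right flank) with attributes `counts` (CpGs per cell) and `regions`.
#' @export
scaled_matrix <- function(regions, m, body_bins = 30L, flank_bp = 2000L,
                          flank_bins = 20L, min_cov = 1L) {
  if (nrow(regions) == 0L) stop("no regions")
  ncol_total <- body_bins + 2L * flank_bins
  mat <- matrix(NA_real_, nrow(regions), ncol_total)
  cnt <- matrix(0L, nrow(regions), ncol_total)
  colnames(mat) <- colnames(cnt) <- c(
    paste0("L", seq_len(flank_bins)), paste0("B", seq_len(body_bins)),
    paste0("R", seq_len(flank_bins)))
  keep <- m$cov >= min_cov & m$cov > 0L
  lv <- meth_level(m)
  for (i in seq_len(nrow(regions))) {
    ch <- regions$chrom[i]
    s <- regions$start[i]
    e <- regions$end[i]
    sel <- which(keep & m$chrom == ch & m$pos >= s - flank_bp &
                   m$pos < e + flank_bp)
    if (length(sel) == 0L) next
    pos <- m$pos[sel]
    col <- integer(length(pos))
    left <- pos < s
    right <- pos >= e
    body <- !left & !right
    col[left] <- pmax(1L, pmin(flank_bins, 1L + as.integer(
      floor((pos[left] - (s - flank_bp)) / flank_bp * flank_bins))))
    col[body] <- flank_bins + pmax(1L, pmin(body_bins, 1L + as.integer(
      floor((pos[body] - s) / (e - s) * body_bins))))
    col[right] <- flank_bins + body_bins + pmax(1L, pmin(flank_bins,
      1L + as.integer(floor((pos[right] - e) / flank_bp * flank_bins))))
    sums <- rowsum(lv[sel], col)
    ns <- rowsum(rep(1L, length(sel)), col)
    idx <- as.integer(rownames(sums))
    mat[i, idx] <- sums[, 1] / ns[, 1]
    cnt[i, idx] <- ns[, 1]
  }
  attr(mat, "counts") <- cnt
  attr(mat, "regions") <- regions
  attr(mat, "body_bins") <- body_bins
  attr(mat, "flank_bins") <- flank_bins
  mat
}

#' Neighbour-CpG methylation correlation by distance
#'
#' For every ordered pair of covered CpGs on the same chromosome
#' separated by at most `max_dist` bp (consecutive and non-consecutive
#' pairs alike), the pair's two levels enter the Pearson correlation of
#' the pair's distance bin. Bins with fewer than 3 pairs, or with zero
#' variance in either margin, are reported `NA`.
#'
#' @param m a [methylome].
#' @param max_dist maximum pair distance in bp.
#' @param bin_width distance bin width in bp.
#' @param min_cov minimum coverage.
#' @return data.frame with `bin_start`, `bin_end` (half-open distance
#'   bins), `r`, `n_pairs`.
#' @export
neighbor_correlation <- function(m, max_dist = 1000L, bin_width = 10L,
                                 min_cov = 1L) {
  stopifnot(bin_width > 0, max_dist >= bin_width)
  keep <- m$cov >= min_cov & m$cov > 0L
  d_all <- integer(0)
  l1_all <- numeric(0)
  l2_all <- numeric(0)
  lv <- meth_level(m)
  for (ch in unique(m$chrom)) {
    idx <- which(keep & m$chrom == ch)
    if (length(idx) < 2L) next
    pos <- m$pos[idx]
    l <- lv[idx]
    k <- 1L
    repeat {
      if (k >= length(idx)) break
      i1 <- seq_len(length(idx) - k)
      d <- pos[i1 + k] - pos[i1]
      ok <- d <= max_dist
      if (!any(ok)) break
      d_all <- c(d_all, d[ok])
      l1_all <- c(l1_all, l[i1][ok])
      l2_all <- c(l2_all, l[i1 + k][ok])
      k <- k + 1L
    }
  }
  n_bins <- as.integer(ceiling(max_dist / bin_width))
  bin <- pmin(n_bins, 1L + (d_all - 1L) %/% bin_width)
  out <- data.frame(bin_start = (seq_len(n_bins) - 1L) * bin_width,
                    bin_end = seq_len(n_bins) * bin_width,
                    r = NA_real_, n_pairs = 0L)
  for (b in unique(bin)) {
    sel <- bin == b
    n <- sum(sel)
    out$n_pairs[b] <- n
    if (n >= 3L) {
      x <- l1_all[sel]
      y <- l2_all[sel]
      if (stats::sd(x) > 0 && stats::sd(y) > 0) {
        out$r[b] <- cor(x, y)
      }
    }
  }
  out
}
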