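#' Observed motif occurrences in a region set
#'
#' Counts motif occurrence intervals that intersect the (internally
#' merged) region set by at least one bp; each occurrence is counted at
#' most once however many regions it touches.
#'
#' @param hits motif occurrence interval frame.
#' @param regions region interval frame.
#' @return integer count.
#' @export
occ_obs <- function(hits, regions) {
  if (nrow(hits) == 0L || nrow(regions) == 0L) return(0L)
  merged <- merge_intervals(regions)
  sum(suppressWarnings(overlapsAny(as_granges(hits), as_granges(merged))))
}

#' Expected motif occurrences under uniform placement
#'
#' `N * L_r / L_g`: the genome-wide occurrence count scaled by the
#' fraction of the genome the regions cover.
#'
#' @param n_total total occurrences N in the genome.
#' @param region_bp total region length L_r in bp.
#' @param genome_bp total genome length L_g in bp.
#' @return numeric expected count.
#' @export
occ_exp <- function(n_total, region_bp, genome_bp) {
  if (genome_bp <= 0) stop("genome length must be positive")
  if (region_bp < 0 || region_bp > genome_bp) {
    stop("region length must be within [0, genome length]")
  }
  n_total * region_bp / genome_bp
}

#' Motif enrichment score over a region set
#'
#' The ratio E = OCC_obs / OCC_exp of observed to expected motif
#' occurrences in the regions, the expectation taken under uniform
#' placement across the genome. Regions are merged before their total
#' length enters the expectation. E is `NA` when the expectation is zero.
#' Optionally a one-sided binomial tail p-value (OCC_obs or more
#' successes in N trials at rate L_r/L_g) can be attached; the score
#' itself carries no significance statement.
#'
#' @param hits motif occurrence interval frame (one motif).
#' @param regions region interval frame.
#' @param sizes named vector of chromosome lengths.
#' @param p_value attach the binomial tail p-value.
#' @return one-row data.frame: `n_total`, `occ_obs`, `occ_exp`,
#'   `enrichment`, `region_bp`, `genome_bp` (and `p_value` on request).
#' @export
enrichment <- function(hits, regions, sizes, p_value = FALSE) {
  bad <- setdiff(unique(hits$chrom), names(sizes))
  if (length(bad) > 0L) {
    stop("hits on chromosome(s) absent from sizes: ",
         paste(bad, collapse = ", "))
  }
  merged <- merge_intervals(regions)
  L_r <- total_bp(merged)
  L_g <- sum(as.numeric(sizes))
  N <- nrow(hits)
  obs <- occ_obs(hits, merged)
  ex <- occ_exp(N, L_r, L_g)
  out <- data.frame(n_total = N, occ_obs = obs, occ_exp = ex,
                    enrichment = if (ex > 0) obs / ex else NA_real_,
                    region_bp = L_r, genome_bp = L_g)
  if (p_value) {
    out$p_value <- stats::pbinom(obs - 1L, N, L_r / L_g,
                                 lower.tail = FALSE)
  }
  out
}

#' Enrichment table over motifs and region classes
#'
#' One enrichment score per (motif, region class) pair, sorted by
#' decreasing score within each class. Motifs with no genome-wide
#' occurrence report `NA`.
#'
#' @param hit_sets named list of motif occurrence frames.
#' @param region_sets named list of region frames (e.g. the HMR taxonomy
#'   classes).
#' @param sizes named vector of chromosome lengths.
#' @inheritParams enrichment
#' @return data.frame with `motif`, `region_class` and the [enrichment()]
#'   columns.
#' @export
enrich_table <- function(hit_sets, region_sets, sizes, p_value = FALSE) {
  rows <- list()
  for (cls in names(region_sets)) {
    for (motif in names(hit_sets)) {
      r <- enrichment(hit_sets[[motif]], region_sets[[cls]], sizes,
                      p_value = p_value)
      r <- cbind(data.frame(motif = motif, region_class = cls,
                            stringsAsFactors = FALSE), r)
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$region_class, -ifelse(is.na(out$enrichment), -Inf,
                                             out$enrichment)), ]
  rownames(out) <- NULL
  out
}
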