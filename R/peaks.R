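# total bp of each query interval covered by a (merged) interval set
covered_bp <- function(query, set) {
  if (nrow(query) == 0L) return(numeric(0))
  out <- numeric(nrow(query))
  if (nrow(set) == 0L) return(out)
  qgr <- as_granges(query)
  sgr <- as_granges(merge_intervals(set))
  hits <- findOverlaps(qgr, sgr)
  if (length(hits) == 0L) return(out)
  w <- IRanges::width(IRanges::pintersect(qgr[queryHits(hits)],
                                          sgr[subjectHits(hits)]))
  agg <- rowsum(w, queryHits(hits))
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Methylation state of ChIP peaks from HMR overlap
#'
#' A peak is called hypomethylated in a tissue when at least a fraction
#' `phi` of its length lies inside that tissue's HMRs (inclusive, so a
#' peak straddling a boundary at exactly half its length counts at
#' `phi = 0.5`). The two per-tissue calls combine into four states:
#' hypo in both (`UNMETHYLATED_BOTH`), in neither (`METHYLATED_BOTH`), or
#' in one only (`DIFFERENTIAL_A_HYPO` / `DIFFERENTIAL_B_HYPO`).
#' Alternatively (`rule = "mean_level"`) a peak is hypo in a tissue when
#' its mean CpG methylation there is below `level_cutoff`.
#'
#' @param peaks peak interval frame.
#' @param hmr_a,hmr_b the two tissues' HMR frames.
#' @param phi minimum overlapped length fraction (overlap rule).
#' @param rule `"overlap"` (default) or `"mean_level"`.
#' @param methylome_a,methylome_b required for the mean-level rule.
#' @param level_cutoff hypomethylation cutoff for the mean-level rule.
#' @param min_cov minimum coverage for the mean-level rule.
#' @return character vector of states, one per peak.
#' @export
classify_peaks <- function(peaks, hmr_a, hmr_b, phi = 0.5,
                           rule = c("overlap", "mean_level"),
                           methylome_a = NULL, methylome_b = NULL,
                           level_cutoff = 0.25, min_cov = 1L) {
  rule <- match.arg(rule)
  if (nrow(peaks) == 0L) return(character(0))
  if (rule == "overlap") {
    w <- peaks$end - peaks$start
    hypo_a <- covered_bp(peaks, hmr_a) >= phi * w
    hypo_b <- covered_bp(peaks, hmr_b) >= phi * w
  } else {
    if (is.null(methylome_a) || is.null(methylome_b)) {
      stop("mean_level rule needs both methylomes")
    }
    mean_in <- function(m) {
      vapply(seq_len(nrow(peaks)), function(i)
        region_mean_level(m, peaks[i, ], min_cov = min_cov)$mean_level,
        numeric(1))
    }
    hypo_a <- mean_in(methylome_a) < level_cutoff
    hypo_b <- mean_in(methylome_b) < level_cutoff
    hypo_a[is.na(hypo_a)] <- FALSE
    hypo_b[is.na(hypo_b)] <- FALSE
  }
  ifelse(hypo_a & hypo_b, "UNMETHYLATED_BOTH",
         ifelse(!hypo_a & !hypo_b, "METHYLATED_BOTH",
                ifelse(hypo_a, "DIFFERENTIAL_A_HYPO",
                       "DIFFERENTIAL_B_HYPO")))
}

#' Annotate ChIP peaks with methylation state and genomic context
#'
#' Combines the HMR-overlap methylation state ([classify_peaks()]), the
#' mean methylation of each peak in both tissues, the gene-centred
#' feature at the peak midpoint, and CpG-island overlap, and cross-
#' tabulates state against feature and CGI context.
#'
#' @param peaks peak interval frame.
#' @param hmr_a,hmr_b the two tissues' HMR frames.
#' @param methylome_a,methylome_b the two [methylome]s.
#' @param genes optional gene models for feature labels.
#' @param cgis optional CpG-island interval frame.
#' @inheritParams classify_peaks
#' @return list of class `peak_annotation` with `peaks` (the annotated
#'   table), `state_feature` and `state_cgi` cross-tabulations.
#' @export
annotate_peaks <- function(peaks, hmr_a, hmr_b, methylome_a, methylome_b,
                           genes = NULL, cgis = NULL, phi = 0.5,
                           rule = "overlap", min_cov = 1L) {
  known <- unique(c(methylome_a$chrom, methylome_b$chrom,
                    hmr_a$chrom, hmr_b$chrom))
  bad <- setdiff(unique(peaks$chrom), known)
  if (length(bad) > 0L) {
    stop("peaks on unknown chromosome(s): ", paste(bad, collapse = ", "))
  }
  n <- nrow(peaks)
  if (n == 0L) {
    empty <- data.frame(chrom = character(), start = integer(),
                        end = integer(), state = character(),
                        mean_a = numeric(), mean_b = numeric(),
                        feature = character(), cgi = logical())
    return(structure(list(peaks = empty,
                          state_feature = table(character(), character()),
                          state_cgi = table(character(), logical())),
                     class = "peak_annotation"))
  }
  state <- classify_peaks(peaks, hmr_a, hmr_b, phi = phi, rule = rule,
                          methylome_a = methylome_a,
                          methylome_b = methylome_b, min_cov = min_cov)
  mean_in <- function(m) {
    vapply(seq_len(n), function(i)
      region_mean_level(m, peaks[i, ], min_cov = min_cov)$mean_level,
      numeric(1))
  }
  mid <- (peaks$start + peaks$end) %/% 2L
  feature <- if (is.null(genes)) {
    factor(rep("Intergenic", n), levels = feature_labels())
  } else {
    assign_feature(peaks$chrom, mid, genes)
  }
  cgi <- if (is.null(cgis)) {
    rep(FALSE, n)
  } else {
    nrow(cgis) > 0L & sites_in_intervals_any(peaks, cgis)
  }
  ann <- data.frame(chrom = peaks$chrom, start = peaks$start,
                    end = peaks$end, state = state,
                    mean_a = mean_in(methylome_a),
                    mean_b = mean_in(methylome_b),
                    feature = as.character(feature), cgi = cgi,
                    stringsAsFactors = FALSE)
  if (!is.null(peaks$name)) ann$name <- peaks$name
  structure(list(peaks = ann,
                 state_feature = table(ann$state, ann$feature),
                 state_cgi = table(ann$state, ann$cgi)),
            class = "peak_annotation")
}

# >= 1 bp interval-vs-set overlap indicator
sites_in_intervals_any <- function(query, set) {
  if (nrow(query) == 0L) return(logical(0))
  if (nrow(set) == 0L) return(rep(FALSE, nrow(query)))
  suppressWarnings(overlapsAny(as_granges(query), as_granges(set)))
}

#' @export
print.peak_annotation <- function(x, ...) {
  cat(sprintf("peak annotation: %d peaks\n", nrow(x$peaks)))
  print(table(x$peaks$state))
  invisible(x)
}
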