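#' Connected overlap components of two HMR sets
#'
#' Builds the bipartite overlap graph between the HMRs of tissue A and
#' tissue B (an edge wherever two HMRs share at least one bp; overlaps
#' within a tissue are not edges — HMR sets are disjoint within a tissue)
#' and returns its connected components. HMRs overlapping nothing in the
#' other tissue form singleton components, the tissue-specific (S1)
#' candidates.
#'
#' @param setA,setB HMR interval frames (sorted, disjoint within each
#'   set), e.g. from [call_hmrs()].
#' @return list of components, each a list with integer row indices `a`
#'   and `b` into `setA`/`setB`.
#' @export
overlap_components <- function(setA, setB) {
  nA <- nrow(setA)
  nB <- nrow(setB)
  parent <- seq_len(nA + nB)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  ov <- overlap_pairs(setA, setB)
  for (i in seq_len(nrow(ov))) {
    ra <- find(ov$query[i])
    rb <- find(nA + ov$subject[i])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(nA + nB), find, integer(1))
  comps <- split(seq_len(nA + nB), roots)
  lapply(unname(comps), function(nodes) {
    list(a = nodes[nodes <= nA],
         b = nodes[nodes > nA] - nA)
  })
}

#' Classify one overlap component into the S1/C1-C5 taxonomy
#'
#' Tissue-specific HMRs (no overlap partner) are S1. For one-to-one
#' overlaps: C1 when both boundaries agree within `tau` bp, C2 when
#' exactly one boundary agrees (sub-labelled by the tissue with the longer
#' HMR; the non-shared span is returned as the extension segment), C3 when
#' neither agrees (containment or stagger). One HMR overlapping several in
#' the other tissue is C4; several against several is C5.
#'
#' @param a,b interval frames holding the component's HMRs from each
#'   tissue.
#' @param tau boundary tolerance in bp (0 = exact).
#' @return list with `label` and `extension` (interval frame, possibly
#'   empty).
#' @export
classify_component <- function(a, b, tau = 20L) {
  nA <- nrow(a)
  nB <- nrow(b)
  no_ext <- data.frame(chrom = character(), start = integer(),
                       end = integer(), tissue = character())
  if (nA + nB == 0L) stop("empty component")
  if (nB == 0L) return(list(label = "S1_A", extension = no_ext))
  if (nA == 0L) return(list(label = "S1_B", extension = no_ext))
  if (nA > 1L && nB > 1L) return(list(label = "C5", extension = no_ext))
  if (nA > 1L || nB > 1L) return(list(label = "C4", extension = no_ext))
  sa <- a$start[1]; ea <- a$end[1]
  sb <- b$start[1]; eb <- b$end[1]
  start_match <- abs(sa - sb) <= tau
  end_match <- abs(ea - eb) <= tau
  if (start_match && end_match) {
    return(list(label = "C1", extension = no_ext))
  }
  if (!start_match && !end_match) {
    return(list(label = "C3", extension = no_ext))
  }
  a_longer <- (ea - sa) > (eb - sb)
  ext <- if (start_match) {
    data.frame(chrom = a$chrom[1], start = min(ea, eb), end = max(ea, eb),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = a$chrom[1], start = min(sa, sb), end = max(sa, sb),
               stringsAsFactors = FALSE)
  }
  ext$tissue <- if (a_longer) "A" else "B"
  list(label = if (a_longer) "C2_A_LONGER" else "C2_B_LONGER",
       extension = ext)
}

taxonomy_labels <- function() {
  c("S1_A", "S1_B", "C1", "C2_A_LONGER", "C2_B_LONGER", "C3", "C4", "C5")
}

#' Compare two tissues' HMR sets
#'
#' Runs [overlap_components()] and [classify_component()] over two HMR
#' sets and tabulates, per taxonomy class and tissue: component count, HMR
#' count, total bp, genome fraction (bp divided by the summed chromosome
#' sizes), mean HMR length and mean CpG count. Every input HMR lands in
#' exactly one component, so per-tissue bp totals are conserved across the
#' classification.
#'
#' @param setA,setB HMR frames (need `chrom`, `start`, `end`; `n_cpg` used
#'   when present).
#' @param sizes named vector of chromosome lengths.
#' @param tau boundary tolerance in bp.
#' @return list of class `hmr_comparison` with `class_table`,
#'   `components` (per-component class and membership), `extensions`
#'   (all C2 extension segments) and the inputs' totals.
#' @export
compare_sets <- function(setA, setB, sizes, tau = 20L) {
  for (s in list(setA, setB)) {
    missing_chr <- setdiff(unique(s$chrom), names(sizes))
    if (length(missing_chr) > 0L) {
      stop("HMRs on chromosome(s) absent from sizes: ",
           paste(missing_chr, collapse = ", "))
    }
  }
  comps <- overlap_components(setA, setB)
  labels <- character(length(comps))
  ext_list <- list()
  comp_rows <- list()
  for (i in seq_along(comps)) {
    cl <- classify_component(setA[comps[[i]]$a, , drop = FALSE],
                             setB[comps[[i]]$b, , drop = FALSE], tau = tau)
    labels[i] <- cl$label
    if (nrow(cl$extension) > 0L) {
      cl$extension$component <- i
      cl$extension$label <- cl$label
      ext_list[[length(ext_list) + 1L]] <- cl$extension
    }
    comp_rows[[i]] <- data.frame(
      component = i, class = cl$label,
      n_a = length(comps[[i]]$a), n_b = length(comps[[i]]$b),
      bp_a = total_bp(setA[comps[[i]]$a, , drop = FALSE]),
      bp_b = total_bp(setB[comps[[i]]$b, , drop = FALSE]),
      stringsAsFactors = FALSE)
  }
  comp_df <- do.call(rbind, comp_rows)
  extensions <- if (length(ext_list) > 0L) {
    do.call(rbind, ext_list)
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               tissue = character(), component = integer(),
               label = character())
  }
  L_g <- sum(as.numeric(sizes))

  ncpg <- function(set, rows) {
    if (is.null(set$n_cpg) || length(rows) == 0L) return(NA_real_)
    mean(set$n_cpg[rows])
  }
  tab <- lapply(taxonomy_labels(), function(lab) {
    sel <- which(labels == lab)
    ra <- unlist(lapply(comps[sel], `[[`, "a"))
    rb <- unlist(lapply(comps[sel], `[[`, "b"))
    a <- setA[ra, , drop = FALSE]
    b <- setB[rb, , drop = FALSE]
    data.frame(class = lab, n_components = length(sel),
               n_hmrs_a = nrow(a), n_hmrs_b = nrow(b),
               bp_a = total_bp(a), bp_b = total_bp(b),
               frac_a = total_bp(a) / L_g, frac_b = total_bp(b) / L_g,
               mean_len_a = if (nrow(a)) mean(a$end - a$start) else NA_real_,
               mean_len_b = if (nrow(b)) mean(b$end - b$start) else NA_real_,
               mean_ncpg_a = ncpg(setA, ra), mean_ncpg_b = ncpg(setB, rb),
               stringsAsFactors = FALSE)
  })
  class_table <- do.call(rbind, tab)
  structure(list(class_table = class_table, components = comp_df,
                 component_members = comps, labels = labels,
                 extensions = extensions, setA = setA, setB = setB,
                 genome_size = L_g, tau = tau),
            class = "hmr_comparison")
}

#' @export
print.hmr_comparison <- function(x, ...) {
  cat(sprintf("HMR comparison (tau = %d bp, genome %.3g bp)\n",
              x$tau, x$genome_size))
  tt <- x$class_table
  tt$frac_a <- sprintf("%.3f%%", 100 * tt$frac_a)
  tt$frac_b <- sprintf("%.3f%%", 100 * tt$frac_b)
  print(tt[, c("class", "n_components", "n_hmrs_a", "n_hmrs_b",
               "bp_a", "bp_b", "frac_a", "frac_b")], row.names = FALSE)
  invisible(x)
}

#' C2 extension segments with per-tissue methylation
#'
#' The non-shared spans of C2 components — the parts by which one
#' tissue's HMR extends past the common core — annotated with their
#' length, CpG count and mean methylation level in each tissue.
#'
#' @param comparison an `hmr_comparison` from [compare_sets()].
#' @param methylome_a,methylome_b the two tissues' [methylome]s.
#' @param min_cov minimum coverage for a CpG to enter the means.
#' @return data.frame, one row per extension segment.
#' @export
extension_segments <- function(comparison, methylome_a, methylome_b,
                               min_cov = 1L) {
  ext <- comparison$extensions
  if (nrow(ext) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), tissue = character(),
                      length = integer(), n_cpg_a = integer(),
                      mean_a = numeric(), n_cpg_b = integer(),
                      mean_b = numeric()))
  }
  stats_a <- lapply(seq_len(nrow(ext)), function(i)
    region_mean_level(methylome_a, ext[i, ], min_cov = min_cov))
  stats_b <- lapply(seq_len(nrow(ext)), function(i)
    region_mean_level(methylome_b, ext[i, ], min_cov = min_cov))
  data.frame(chrom = ext$chrom, start = ext$start, end = ext$end,
             tissue = ext$tissue, length = ext$end - ext$start,
             n_cpg_a = vapply(stats_a, `[[`, numeric(1), "n_cpg"),
             mean_a = vapply(stats_a, `[[`, numeric(1), "mean_level"),
             n_cpg_b = vapply(stats_b, `[[`, numeric(1), "n_cpg"),
             mean_b = vapply(stats_b, `[[`, numeric(1), "mean_level"),
             stringsAsFactors = FALSE)
}
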