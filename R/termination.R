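# Allelic termination windows, mRNA primary-structure change flags,
# stability indices and the associated group comparisons.

#' Call allelic termination (AT) windows
#'
#' An AT window is the intersection of a transcription unit with a
#' same-strand allelic block that (1) starts (5' edge, strand-aware)
#' inside the unit, (2) ends in the final `final_frac` of the unit or
#' beyond its 3' end, and (3) yields a window no longer than
#' `length_cap` of the unit. Multiple qualifying blocks contribute the
#' union of their intersections (one window per unit); the long allele is
#' the biased allele of the block with the largest intersection.
#'
#' @param units data.frame `gene, contig, start, end, strand`
#'   (0-based half-open).
#' @param blocks Allelic blocks from [hmm_call_blocks()].
#' @param final_frac End-rule fraction (default 0.10).
#' @param length_cap Maximum window/unit length ratio (default 0.50).
#' @return data.frame of AT windows (`gene, contig, strand, start, end,
#'   long_allele, unit_length, window_length`).
#' @export
call_at_windows <- function(units, blocks, final_frac = 0.10,
                            length_cap = 0.50) {
  out <- list()
  for (i in seq_len(nrow(units))) {
    u <- units[i, ]
    len <- u$end - u$start
    b <- blocks[blocks$contig == u$contig & blocks$strand == u$strand &
                  blocks$end > u$start & blocks$start < u$end, , drop = FALSE]
    if (!nrow(b)) next
    b5 <- if (u$strand == "+") b$start else b$end - 1L   # block 5' edge
    starts_inside <- b5 >= u$start & b5 < u$end
    if (u$strand == "+") {
      end_ok <- b$end >= u$end - final_frac * len
    } else {
      end_ok <- b$start <= u$start + final_frac * len
    }
    q <- which(starts_inside & end_ok)
    if (!length(q)) next
    ws <- pmax(b$start[q], u$start)
    we <- pmin(b$end[q], u$end)
    win_start <- min(ws); win_end <- max(we)
    wl <- win_end - win_start
    if (wl > length_cap * len) next
    main <- q[which.max(we - ws)]
    out[[length(out) + 1L]] <- data.frame(
      gene = u$gene, contig = u$contig, strand = u$strand,
      start = win_start, end = win_end,
      long_allele = b$direction[main], unit_length = len,
      window_length = wl, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene = character(), contig = character(),
                      strand = character(), start = integer(),
                      end = integer(), long_allele = character(),
                      unit_length = integer(), window_length = integer())
  }
  rownames(res) <- NULL
  res
}

#' Flag allelic changes in mature-mRNA structure
#'
#' A unit's AT window is flagged when any same-strand mRNA-level allelic
#' block intersects the region from `upstream` bp (strand-aware) upstream
#' of the window to the window's end.
#'
#' @param at_windows Output of [call_at_windows()].
#' @param mrna_blocks Blocks from [hmm_call_blocks()] on mRNA counts.
#' @param upstream Upstream extension (default 10 kb).
#' @return Logical vector, one flag per AT window.
#' @export
flag_mrna_structure_change <- function(at_windows, mrna_blocks,
                                       upstream = 10000L) {
  vapply(seq_len(nrow(at_windows)), function(i) {
    w <- at_windows[i, ]
    if (w$strand == "+") {
      lo <- w$start - upstream; hi <- w$end
    } else {
      lo <- w$start; hi <- w$end + upstream
    }
    b <- mrna_blocks[mrna_blocks$contig == w$contig &
                       mrna_blocks$strand == w$strand, , drop = FALSE]
    any(b$end > lo & b$start < hi)
  }, logical(1))
}

#' Per-gene allelic mRNA stability indices
#'
#' Stability = allele-specific mRNA exon reads / allele-specific nascent
#' gene-body reads; computed only for genes with at least `min_reads`
#' nascent reads on both alleles. Zero mRNA with nonzero nascent records
#' stability 0 and an `NA` log-ratio (flagged).
#'
#' @param mrna_gene data.frame `gene, a1, a2` of summed mRNA exon counts.
#' @param nascent_gene data.frame `gene, a1, a2` of nascent gene-body
#'   counts.
#' @param min_reads Nascent read floor per allele (default 10).
#' @return data.frame with per-allele stabilities and
#'   `stability_diff = |log2(stab_a1/stab_a2)|`.
#' @export
stability_index <- function(mrna_gene, nascent_gene, min_reads = 10L) {
  genes <- intersect(mrna_gene$gene, nascent_gene$gene)
  m <- mrna_gene[match(genes, mrna_gene$gene), ]
  n <- nascent_gene[match(genes, nascent_gene$gene), ]
  keep <- n$a1 >= min_reads & n$a2 >= min_reads
  m <- m[keep, ]; n <- n[keep, ]
  s1 <- m$a1 / n$a1
  s2 <- m$a2 / n$a2
  diff <- ifelse(s1 > 0 & s2 > 0, abs(log2(s1 / s2)), NA_real_)
  data.frame(gene = m$gene, mrna_a1 = m$a1, mrna_a2 = m$a2,
             nascent_a1 = n$a1, nascent_a2 = n$a2,
             stab_a1 = s1, stab_a2 = s2, stability_diff = diff,
             zero_mrna = s1 == 0 | s2 == 0)
}

# one-sided two-sample KS: tests whether x is stochastically larger than y
# (D+ = max ECDF_y - ECDF_x), asymptotic tail exp(-2 ne D+^2)
ks_one_sided <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) return(list(D = NA_real_, p = NA_real_))
  pts <- sort(unique(c(x, y)))
  dplus <- max(stats::ecdf(y)(pts) - stats::ecdf(x)(pts))
  ne <- length(x) * length(y) / (length(x) + length(y))
  list(D = dplus, p = min(1, exp(-2 * ne * max(dplus, 0)^2)))
}

#' Group comparisons around allelic termination
#'
#' (a) Fisher's exact test for enrichment of mRNA structure changes in
#' units with an AT window versus units without; (b) one-sided KS testing
#' whether allelic stability differences are larger in structure-changed
#' units; (c) Fisher's exact test asking whether the adjacent transcript's
#' high-expression allele is the early-terminating allele, overall and
#' restricted to opposite-strand neighbours.
#'
#' @param flag_at Logical structure-change flags for AT-window units.
#' @param flag_noat Same flags for units without an AT window.
#' @param stab_flagged,stab_unflagged Stability differences
#'   (`stability_diff`) for structure-changed vs other units.
#' @param adjacency Optional data.frame `early_allele, adj_high_allele,
#'   opposite_strand`.
#' @return List `(structure_fisher, stability_ks, adjacency_fisher,
#'   adjacency_fisher_opposite)`.
#' @export
group_comparisons <- function(flag_at, flag_noat, stab_flagged,
                              stab_unflagged, adjacency = NULL) {
  structure_fisher <- if (length(flag_at) && length(flag_noat)) {
    fisher_exact_2x2(sum(flag_at), sum(!flag_at),
                     sum(flag_noat), sum(!flag_noat))
  } else list(odds_ratio = NA_real_, p = NA_real_)
  stability_ks <- ks_one_sided(stab_flagged, stab_unflagged)
  adj_test <- function(d) {
    if (is.null(d) || nrow(d) < 4L ||
        length(unique(d$early_allele)) < 2L ||
        length(unique(d$adj_high_allele)) < 2L) {
      return(list(odds_ratio = NA_real_, p = NA_real_))
    }
    tab <- table(factor(d$early_allele, c("A1", "A2")),
                 factor(d$adj_high_allele, c("A1", "A2")))
    fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  }
  list(structure_fisher = structure_fisher,
       stability_ks = stability_ks,
       adjacency_fisher = adj_test(adjacency),
       adjacency_fisher_opposite =
         adj_test(if (!is.null(adjacency))
           adjacency[adjacency$opposite_strand, , drop = FALSE] else NULL))
}
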