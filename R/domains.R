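# Merging HMM blocks into strain-effect and imprinted domains across
# reciprocal crosses and organs, gene-level allelic state, the neighbour
# sharing test, and gene-per-domain counting.
#
# Cross labels: "A1xA2" means strain A1 is the mother, "A2xA1" the reverse.
# A block biased to the same *strain* allele in both crosses is a strain
# effect; biased to the same *parent* (so the strain allele flips with the
# cross) is imprinted.

# per-replicate binomial p-values for one block, requiring consistent
# direction ("same direction" rule)
block_replicate_stats <- function(block, reads5, organ, cross) {
  r <- reads5[reads5$organ == organ & reads5$cross == cross &
                reads5$strand == block$strand &
                reads5$contig == block$contig &
                reads5$allele %in% c("A1", "A2") &
                reads5$five_prime >= block$start &
                reads5$five_prime < block$end, , drop = FALSE]
  reps <- sort(unique(r$replicate))
  if (!length(reps)) return(NULL)
  a1 <- vapply(reps, function(k) sum(r$replicate == k & r$allele == "A1"),
               integer(1))
  a2 <- vapply(reps, function(k) sum(r$replicate == k & r$allele == "A2"),
               integer(1))
  dir_ok <- if (block$direction == "A1") all(a1 >= a2) else all(a2 >= a1)
  list(p = binomial_allelic_test(a1, a2), same_direction = dir_ok)
}

#' Merge allelic blocks into strain-effect and imprinted domains
#'
#' Implements the four-step procedure: (1) candidate blocks are called per
#' organ x cross from pooled replicates; (2) blocks are kept when all
#' replicates are biased in the same direction and the Fisher-combined
#' replicate p-values are <= `alpha`; (3) blocks overlapping between the
#' reciprocal crosses of an organ are classified strain-effect (same strain
#' biased in both) or imprinted (same parent biased, i.e. the strain flips
#' with the cross); (4) overlapping same-class regions are merged across
#' organs into domains, recording the supporting organs.
#'
#' @param reads Read-end table (all samples; 5' ends are used as the
#'   informative positions).
#' @param tau,rho HMM parameters.
#' @param alpha Step-2 Fisher significance cutoff (default 0.05, no further
#'   multiplicity correction at this step).
#' @return List with `blocks` (kept per organ x cross), `classified`
#'   (per-organ reciprocal-cross intersections with class) and `domains`.
#' @export
merge_blocks_to_domains <- function(reads, tau = 1e-4, rho = 0.9,
                                    alpha = 0.05) {
  crosses <- unique(reads$cross)
  if (!all(c("A1xA2", "A2xA1") %in% crosses)) {
    stop("both reciprocal crosses are required to classify domains")
  }
  organs <- unique(reads$organ)
  kept <- list()
  for (org in organs) {
    for (cr in c("A1xA2", "A2xA1")) {
      counts <- make_base_counts(reads, "five_prime", organ = org, cross = cr)
      pos <- counts[counts$a1 + counts$a2 > 0L,
                    c("contig", "strand", "pos", "a1", "a2")]
      blocks <- hmm_call_blocks(pos, tau = tau, rho = rho)
      if (!nrow(blocks)) next
      keep <- logical(nrow(blocks))
      pfis <- numeric(nrow(blocks))
      for (i in seq_len(nrow(blocks))) {
        st <- block_replicate_stats(blocks[i, ], reads, org, cr)
        if (is.null(st)) next
        pfis[i] <- fisher_combine(st$p)
        keep[i] <- st$same_direction && !is.na(pfis[i]) && pfis[i] <= alpha
      }
      blocks$fisher_p <- pfis
      blocks$organ <- org
      blocks$cross <- cr
      kept[[paste(org, cr)]] <- blocks[keep, , drop = FALSE]
    }
  }
  kept_df <- do.call(rbind, kept)
  empty <- data.frame(contig = character(), strand = character(),
                      start = integer(), end = integer(), class = character(),
                      direction = character(), organs = character())
  if (is.null(kept_df) || nrow(kept_df) == 0L) {
    return(list(blocks = kept_df, classified = empty, domains = empty))
  }

  # step 3: reciprocal-cross intersection and classification per organ
  cls <- list()
  for (org in organs) {
    b1 <- kept_df[kept_df$organ == org & kept_df$cross == "A1xA2", , drop = FALSE]
    b2 <- kept_df[kept_df$organ == org & kept_df$cross == "A2xA1", , drop = FALSE]
    if (!nrow(b1) || !nrow(b2)) next
    for (i in seq_len(nrow(b1))) {
      j <- which(b2$contig == b1$contig[i] & b2$strand == b1$strand[i] &
                   b2$start < b1$end[i] & b2$end > b1$start[i])
      for (k in j) {
        klass <- if (b2$direction[k] == b1$direction[i]) "strain_effect"
                 else "imprinted"
        # direction label: strain allele for strain effects, parent for
        # imprinted ones (mother = A1 in cross A1xA2)
        dir <- if (klass == "strain_effect") b1$direction[i]
               else if (b1$direction[i] == "A1") "maternal" else "paternal"
        cls[[length(cls) + 1L]] <- data.frame(
          contig = b1$contig[i], strand = b1$strand[i],
          start = max(b1$start[i], b2$start[k]),
          end = min(b1$end[i], b2$end[k]),
          class = klass, direction = dir, organ = org,
          stringsAsFactors = FALSE)
      }
    }
  }
  classified <- do.call(rbind, cls)
  if (is.null(classified) || nrow(classified) == 0L) {
    return(list(blocks = kept_df, classified = empty, domains = empty))
  }

  # step 4: merge overlapping same-class (and same-direction) regions
  # across organs
  dom <- list()
  sp <- split(seq_len(nrow(classified)),
              paste(classified$contig, classified$strand,
                    classified$class, classified$direction))
  for (i in sp) {
    d <- classified[i, ]
    ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    hits <- IRanges::findOverlaps(IRanges::IRanges(d$start + 1L, d$end), ir)
    orgs <- tapply(d$organ[S4Vectors::queryHits(hits)],
                   S4Vectors::subjectHits(hits),
                   function(x) paste(sort(unique(x)), collapse = ","))
    dom[[length(dom) + 1L]] <- data.frame(
      contig = d$contig[1], strand = d$strand[1],
      start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
      class = d$class[1], direction = d$direction[1],
      organs = as.character(orgs), stringsAsFactors = FALSE)
  }
  domains <- do.call(rbind, dom)
  rownames(domains) <- NULL
  list(blocks = kept_df, classified = classified, domains = domains)
}

#' Gene-level allelic state across reciprocal crosses
#'
#' Per cross, exact binomial test on pooled gene counts with BH at `fdr`;
#' genes significant in both crosses are classified `strain` when the same
#' strain allele is high in both, `imprinted` when the same parent is high
#' (the strain allele flips between reciprocal crosses), else `none`.
#'
#' @param gene_counts data.frame `gene, cross, a1, a2` (pooled replicates,
#'   one organ).
#' @param fdr FDR cutoff (default 0.10).
#' @return data.frame `gene, q_cross1, q_cross2, state`.
#' @export
classify_gene_allelic_state <- function(gene_counts, fdr = 0.10) {
  stopifnot(all(c("A1xA2", "A2xA1") %in% gene_counts$cross))
  one <- function(cr) {
    d <- gene_counts[gene_counts$cross == cr, ]
    d <- d[order(d$gene), ]
    d$p <- binomial_allelic_test(d$a1, d$a2)
    d$q <- bh_fdr(d$p)
    d$dir <- ifelse(d$a1 >= d$a2, "A1", "A2")
    d
  }
  d1 <- one("A1xA2"); d2 <- one("A2xA1")
  genes <- intersect(d1$gene, d2$gene)
  d1 <- d1[match(genes, d1$gene), ]; d2 <- d2[match(genes, d2$gene), ]
  sig <- !is.na(d1$q) & !is.na(d2$q) & d1$q <= fdr & d2$q <= fdr
  state <- ifelse(!sig, "none",
                  ifelse(d1$dir == d2$dir, "strain", "imprinted"))
  data.frame(gene = genes, q_cross1 = d1$q, q_cross2 = d2$q,
             a1_cross1 = d1$a1, a2_cross1 = d1$a2,
             a1_cross2 = d2$a1, a2_cross2 = d2$a2,
             state = state, stringsAsFactors = FALSE)
}

#' Do neighbouring genes share allelic specificity?
#'
#' Focal genes are allele-specific (q < `fdr`) or confidently non-specific
#' (q > `fdr_background`); the nearest other transcript on the contig is
#' the neighbour. Fisher's exact test on the 2x2 of focal class x
#' neighbour allele-specificity.
#'
#' @param genes data.frame `gene, contig, start, end, q`.
#' @param fdr,fdr_background Cutoffs (defaults 0.10 / 0.90).
#' @return List `(odds_ratio, p, table)`; the no-test sentinel (`NA`s) when
#'   a stratum is empty.
#' @export
adjacency_sharing_test <- function(genes, fdr = 0.10, fdr_background = 0.90) {
  g <- genes[!is.na(genes$q), ]
  g <- g[order(g$contig, g$start), ]
  mid <- (g$start + g$end) / 2
  nb <- rep(NA_integer_, nrow(g))
  for (i in seq_len(nrow(g))) {
    j <- which(g$contig == g$contig[i])
    j <- j[j != i]
    if (length(j)) nb[i] <- j[which.min(abs(mid[j] - mid[i]))]
  }
  focal_as <- g$q < fdr
  focal_non <- g$q > fdr_background
  ok <- (focal_as | focal_non) & !is.na(nb)
  if (!any(ok & focal_as) || !any(ok & focal_non)) {
    return(list(odds_ratio = NA_real_, p = NA_real_, table = NULL))
  }
  nb_as <- g$q[nb[ok]] < fdr
  tab <- table(factor(focal_as[ok], levels = c(TRUE, FALSE)),
               factor(nb_as, levels = c(TRUE, FALSE)))
  ft <- fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  list(odds_ratio = ft$odds_ratio, p = ft$p, table = tab)
}

#' Count genes per domain after same-strand overlap/bookend merging
#'
#' Same-strand annotations that overlap or are directly adjacent
#' (bookended) are merged so that one transcriptional unit is counted once;
#' merged units overlapping a domain are counted for it.
#'
#' @param domains data.frame `contig, strand, start, end` (a `.` strand
#'   matches both).
#' @param annotations data.frame `contig, start, end, strand`.
#' @return Integer vector of gene counts, one per domain row.
#' @export
count_genes_per_domain <- function(domains, annotations) {
  counts <- integer(nrow(domains))
  for (i in seq_len(nrow(domains))) {
    strands <- if (identical(domains$strand[i], ".")) c("+", "-")
               else domains$strand[i]
    tot <- 0L
    for (st in strands) {
      a <- annotations[annotations$contig == domains$contig[i] &
                         annotations$strand == st, , drop = FALSE]
      if (!nrow(a)) next
      merged <- IRanges::reduce(IRanges::IRanges(a$start + 1L, a$end))
      tot <- tot + sum(IRanges::start(merged) - 1L < domains$end[i] &
                         IRanges::end(merged) > domains$start[i])
    }
    counts[i] <- tot
  }
  counts
}
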