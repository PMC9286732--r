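# Gene-body quantification, normalisation and allelic ratio matrices.

#' Gene-body read counts and RPKM
#'
#' Counts reads whose 5' end falls in the gene body -- the annotation with
#' its first `skip` bp (strand-aware) removed -- per gene and sample, and
#' normalises to reads per kilobase per million sample reads. Genes
#' shorter than `min_length` or with fewer than `min_reads` in any sample
#' are flagged (not dropped).
#'
#' @param reads Read-end table.
#' @param annotations data.frame `gene, contig, start, end, strand`.
#' @param skip Bases skipped at the 5' end (default 500).
#' @param min_length Minimum annotation length (default 10000).
#' @param min_reads Per-sample read floor (default 5).
#' @return List `(counts, rpkm, samples, genes)`; matrices are gene x
#'   sample, `genes` holds length and `pass` flags.
#' @export
gene_body_counts <- function(reads, annotations, skip = 500L,
                             min_length = 10000L, min_reads = 5L) {
  ann <- annotations
  len <- ann$end - ann$start
  too_short <- len <= skip
  if (any(too_short)) {
    warning(sum(too_short), " annotation(s) shorter than the skip; excluded")
    ann <- ann[!too_short, ]; len <- len[!too_short]
  }
  body_start <- ifelse(ann$strand == "+", ann$start + skip, ann$start)
  body_end <- ifelse(ann$strand == "+", ann$end, ann$end - skip)
  sm <- unique(reads[, c("organ", "cross", "replicate")])
  sm <- sm[order(sm$organ, sm$cross, sm$replicate), ]
  sample_id <- paste(sm$organ, sm$cross, sm$replicate, sep = "_")
  counts <- matrix(0L, nrow(ann), nrow(sm),
                   dimnames = list(ann$gene, sample_id))
  read_sample <- match(paste(reads$organ, reads$cross, reads$replicate,
                             sep = "_"), sample_id)
  for (i in seq_len(nrow(ann))) {
    hit <- reads$contig == ann$contig[i] & reads$strand == ann$strand[i] &
      reads$five_prime >= body_start[i] & reads$five_prime < body_end[i]
    if (any(hit)) {
      tab <- table(factor(read_sample[hit], levels = seq_len(nrow(sm))))
      counts[i, ] <- as.integer(tab)
    }
  }
  depth <- colSums(counts)
  rpkm <- sweep(counts, 2, pmax(depth, 1) / 1e6, "/") / (len / 1000)
  genes <- data.frame(gene = ann$gene, length = len,
                      pass = len >= min_length &
                        apply(counts >= min_reads, 1, all))
  list(counts = counts, rpkm = rpkm, samples = sm, genes = genes)
}

#' Pairwise Spearman correlation between samples
#'
#' @param mat Gene x sample matrix (e.g. RPKM of passing genes).
#' @return Symmetric sample x sample correlation matrix; pairs involving a
#'   constant column are `NA`.
#' @export
spearman_matrix <- function(mat) {
  suppressWarnings(stats::cor(mat, method = "spearman"))
}

#' Allelic log-ratio matrix across samples
#'
#' log2((a1 + 0.5) / (a2 + 0.5)) per gene and sample, with a per-sample
#' exact binomial allele-specificity call (BH within sample, q <= `fdr`).
#' Genes allele-specific in at least `min_specific` samples of every organ
#' are marked `kept`.
#'
#' @param gene_allele_counts data.frame `gene, organ, cross, replicate,
#'   a1, a2`.
#' @param fdr Per-sample FDR (default 0.10).
#' @param min_specific Minimum allele-specific samples per organ
#'   (default 3).
#' @return List `(ratio, specific, kept, samples)`.
#' @export
allelic_ratio_matrix <- function(gene_allele_counts, fdr = 0.10,
                                 min_specific = 3L) {
  d <- gene_allele_counts
  d$sample <- paste(d$organ, d$cross, d$replicate, sep = "_")
  genes <- sort(unique(d$gene))
  samples <- unique(d[, c("organ", "cross", "replicate", "sample")])
  ratio <- matrix(NA_real_, length(genes), nrow(samples),
                  dimnames = list(genes, samples$sample))
  specific <- matrix(FALSE, length(genes), nrow(samples),
                     dimnames = list(genes, samples$sample))
  for (j in seq_len(nrow(samples))) {
    x <- d[d$sample == samples$sample[j], ]
    i <- match(x$gene, genes)
    ratio[i, j] <- log2((x$a1 + 0.5) / (x$a2 + 0.5))
    p <- binomial_allelic_test(x$a1, x$a2)
    q <- bh_fdr(p)
    specific[i, j] <- !is.na(q) & q <= fdr
  }
  per_organ <- vapply(unique(samples$organ), function(org) {
    cols <- which(samples$organ == org)
    rowSums(specific[, cols, drop = FALSE]) >= min_specific
  }, logical(length(genes)))
  kept <- apply(matrix(per_organ, nrow = length(genes)), 1, all)
  list(ratio = ratio, specific = specific, kept = kept, samples = samples)
}
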