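# Allelic pause-shape testing and the dissection of pause-position
# determinants: test/control set construction, indel offsets, SNP profiles
# around the short pause, base-composition blocks, and explanation
# accounting. "Short allele" = smaller projected TSS-to-pause distance.

#' Test candidate regions for allelic pause-shape differences
#'
#' Weighted two-sample KS between the allele1 and allele2 3'-end
#' distributions within each candidate region (per strand), for regions
#' with at least `min_obs` tagged reads on both alleles; BH-adjusted.
#'
#' @param counts3 Three-prime `site_counts`.
#' @param regions Candidate-region table.
#' @param min_obs Minimum allelic reads per allele (default 5).
#' @param fdr,fdr_background Significance / control cutoffs (0.10 / 0.90).
#' @return data.frame per (region, strand): `D, p, q, eligible,
#'   significant, control`.
#' @export
pause_shape_test <- function(counts3, regions, min_obs = 5L, fdr = 0.10,
                             fdr_background = 0.90, method = "mc", B = 499L) {
  stopifnot(attr(counts3, "end_type") == "three_prime")
  d <- as.data.frame(counts3)
  d$region_id <- assign_regions(d, regions)
  d <- d[!is.na(d$region_id) & d$a1 + d$a2 > 0L, ]
  sp <- split(seq_len(nrow(d)), paste(d$region_id, d$strand))
  res <- do.call(rbind, lapply(sp, function(i) {
    x <- d[i, ]
    ks <- ks_two_sample(x$pos, x$pos, x$a1, x$a2, min_obs = min_obs,
                        method = method, B = B)
    data.frame(region_id = x$region_id[1], strand = x$strand[1],
               D = ks$D, p = ks$p, n1 = ks$n1, n2 = ks$n2,
               eligible = ks$ok, stringsAsFactors = FALSE)
  }))
  res$q <- NA_real_
  res$q[res$eligible] <- bh_fdr(res$p[res$eligible])
  res$significant <- res$eligible & !is.na(res$q) & res$q <= fdr
  res$control <- res$eligible & !is.na(res$q) & res$q > fdr_background
  rownames(res) <- NULL
  res
}

#' Same-TSS, different-pause test and control sets
#'
#' From valid TSS-pause pairs sharing the same maxTSS on both alleles:
#' the test set has a shape-test q <= `fdr` and distinct allelic maxPause
#' positions; the control set has q > `fdr_background` and identical
#' maxPause. Both must pass the allelic read filters (at least `min_reads`
#' per allele and an allelic read ratio within `ratio_bounds`).
#'
#' @param pairs Output of [pair_tss_pause()].
#' @param shape_results Output of [pause_shape_test()].
#' @param min_reads Minimum allelic 3' reads per allele (default 5).
#' @param ratio_bounds Allelic read-ratio bounds (default `c(0.5, 2)`).
#' @param fdr,fdr_background Cutoffs (0.10 / 0.90).
#' @return List `(test, control)` of pause-determinant records with
#'   short/long labels and projected distance.
#' @export
same_tss_diff_pause_sets <- function(pairs, shape_results, min_reads = 5L,
                                     ratio_bounds = c(0.5, 2), fdr = 0.10,
                                     fdr_background = 0.90) {
  key <- paste(pairs$region_id, pairs$strand)
  skey <- paste(shape_results$region_id, shape_results$strand)
  q <- shape_results$q[match(key, skey)]
  ratio <- pairs$pause_n_a1 / pairs$pause_n_a2
  base_ok <- pairs$valid & !is.na(pairs$tss_a1) & pairs$tss_a1 == pairs$tss_a2 &
    pairs$pause_n_a1 >= min_reads & pairs$pause_n_a2 >= min_reads &
    ratio >= ratio_bounds[1] & ratio <= ratio_bounds[2] & !is.na(q)
  mk_records <- function(d) {
    if (!nrow(d)) return(d)
    short <- ifelse(d$dist_a1 <= d$dist_a2, "A1", "A2")
    data.frame(region_id = d$region_id, strand = d$strand, tss = d$tss_a1,
               short_allele = short,
               long_allele = ifelse(short == "A1", "A2", "A1"),
               short_pause = ifelse(short == "A1", d$pause_a1, d$pause_a2),
               long_pause = ifelse(short == "A1", d$pause_a2, d$pause_a1),
               dist = abs(d$dist_a1 - d$dist_a2), stringsAsFactors = FALSE)
  }
  test <- mk_records(pairs[base_ok & q <= fdr &
                             pairs$pause_a1 != pairs$pause_a2, , drop = FALSE])
  control <- mk_records(pairs[base_ok & q > fdr_background &
                                pairs$pause_a1 == pairs$pause_a2, , drop = FALSE])
  list(test = test, control = control)
}

# net bases missing from allele2 (deletions positive) within a projected
# allele1 interval [lo, hi]
net_deleted_a2 <- function(genome, lo, hi) {
  v <- genome$variants
  v <- v[v$kind != "snp", , drop = FALSE]
  if (!nrow(v)) return(0L)
  hit <- v$pos1 + nchar(v$ref) - 1L >= lo & v$pos1 <= hi
  sum(nchar(v$ref[hit]) - nchar(v$alt[hit]))
}

#' Indels between initiation and pause vs pause-position offsets
#'
#' For each test record, sums the signed indel length between the shared
#' maxTSS and the long-allele pause (positive = bases deleted on the
#' projected-long allele) and pairs it with the projected allelic pause
#' difference. Reports the regression of pause difference on indel length
#' and a Fisher test of indel presence, test vs control.
#'
#' @param test,control Record sets from [same_tss_diff_pause_sets()].
#' @param genome A `genome_pair`.
#' @return List `(records, slope, fisher)`.
#' @export
indel_offset_analysis <- function(test, control, genome) {
  annotate <- function(d) {
    if (!nrow(d)) { d$indel_net <- numeric(0); d$has_indel <- logical(0); return(d) }
    net <- vapply(seq_len(nrow(d)), function(i) {
      lo <- min(d$tss[i], d$long_pause[i])
      hi <- max(d$tss[i], d$long_pause[i])
      net_deleted_a2(genome, lo, hi)
    }, numeric(1))
    # orient: positive = deletion on the long allele
    d$indel_net <- ifelse(d$long_allele == "A2", net, -net)
    d$has_indel <- d$indel_net != 0
    d
  }
  test <- annotate(test)
  control <- annotate(control)
  slope <- NA_real_
  with_indel <- test[test$has_indel, , drop = FALSE]
  if (nrow(with_indel) >= 3L && stats::sd(with_indel$indel_net) > 0) {
    slope <- unname(stats::coef(stats::lm(dist ~ indel_net,
                                          data = with_indel))[2])
  }
  ft <- if (nrow(test) && nrow(control)) {
    fisher_exact_2x2(sum(test$has_indel), sum(!test$has_indel),
                     sum(control$has_indel), sum(!control$has_indel))
  } else list(odds_ratio = NA_real_, p = NA_real_)
  list(records = test, control = control, slope = slope, fisher = ft)
}

#' SNP profile around the short-pause position
#'
#' [snp_positional_profile()] anchored at each test/control record's
#' short-allele pause position.
#'
#' @param test,control Record sets from [same_tss_diff_pause_sets()].
#' @param genome A `genome_pair`.
#' @param window Half-window (default 20 bp).
#' @param ... Passed to [snp_positional_profile()].
#' @return As [snp_positional_profile()].
#' @export
pause_snp_profile <- function(test, control, genome, window = 20L, ...) {
  if (!nrow(test) || !nrow(control)) stop("empty test or control set")
  snp_positional_profile(
    data.frame(pos = test$short_pause, strand = test$strand),
    data.frame(pos = control$short_pause, strand = control$strand),
    genome, window = window, ...)
}

#' Base composition around pause positions
#'
#' Per-position base frequencies around unique maxPause sites and G/C/GC
#' content in three blocks (block 1: 11-20 bp upstream; block 2: 1-10 bp
#' upstream, the transcription bubble; block 3: 1-10 bp downstream),
#' compared with paired signed-rank tests (block 2 vs 1, block 2 vs 3).
#'
#' @param pauses data.frame `pos, strand` of unique pause sites
#'   (duplicates removed).
#' @param genome A `genome_pair`.
#' @param flank Offsets for the frequency table (default -20..10).
#' @return List `(freq, blocks, tests)`.
#' @export
pause_sequence_context <- function(pauses, genome, flank = c(-20L, 10L)) {
  pauses <- unique(pauses[, c("pos", "strand")])
  seqs <- vapply(seq_len(nrow(pauses)), function(i)
    oriented_window(genome$seq1, pauses$pos[i], pauses$strand[i],
                    flank[1], flank[2]) %||% NA_character_, character(1))
  ok <- !is.na(seqs)
  m <- do.call(rbind, strsplit(seqs[ok], ""))
  offs <- seq(flank[1], flank[2])
  freq <- do.call(rbind, lapply(seq_along(offs), function(j) {
    data.frame(offset = offs[j],
               A = mean(m[, j] == "A"), C = mean(m[, j] == "C"),
               G = mean(m[, j] == "G"), T = mean(m[, j] == "T"))
  }))
  content <- function(lo, hi, base) {
    j <- which(offs >= lo & offs <= hi)
    rowMeans(matrix(m[, j] %in% base, nrow = nrow(m)))
  }
  blocks <- data.frame(
    g1 = content(-20L, -11L, "G"), g2 = content(-10L, -1L, "G"),
    g3 = content(1L, 10L, "G"),
    c1 = content(-20L, -11L, "C"), c2 = content(-10L, -1L, "C"),
    c3 = content(1L, 10L, "C"),
    gc1 = content(-20L, -11L, c("G", "C")), gc2 = content(-10L, -1L, c("G", "C")),
    gc3 = content(1L, 10L, c("G", "C")))
  pw <- function(x, y) {
    if (all(x == y)) return(NA_real_)
    stats::wilcox.test(x, y, paired = TRUE, exact = FALSE)$p.value
  }
  tests <- data.frame(
    comparison = c("G_block2_vs_block1", "G_block2_vs_block3",
                   "C_block2_vs_block1", "C_block2_vs_block3"),
    p = c(pw(blocks$g2, blocks$g1), pw(blocks$g2, blocks$g3),
          pw(blocks$c2, blocks$c1), pw(blocks$c2, blocks$c3)))
  list(freq = freq, blocks = blocks, tests = tests, n = nrow(m))
}

#' Classify what explains each allelic pause difference
#'
#' Tags each test record by the variant classes found around the
#' short-allele pause: a SNP at the active site (offset 0), in the
#' transcription bubble (-10..-1), just downstream (+1..+10), or an indel
#' between the maxTSS and the long pause. Records with more than one class
#' are `multiple`; with none, `unexplained`.
#'
#' @param test Record set from [same_tss_diff_pause_sets()].
#' @param genome A `genome_pair`.
#' @return List `(records, fractions, fraction_explained)`.
#' @export
classify_pause_explanations <- function(test, genome) {
  v <- genome$variants
  snp_pos <- v$pos1[v$kind == "snp"]
  cats <- c("active_site_snp", "bubble_snp", "downstream_snp",
            "indel_tss_to_pause")
  recs <- test
  recs$explanation <- "unexplained"
  tag_mat <- matrix(FALSE, nrow(test), length(cats),
                    dimnames = list(NULL, cats))
  for (i in seq_len(nrow(test))) {
    off <- downstream_dist(test$short_pause[i], snp_pos, test$strand[i])
    lo <- min(test$tss[i], test$long_pause[i])
    hi <- max(test$tss[i], test$long_pause[i])
    tag_mat[i, ] <- c(any(off == 0L), any(off >= -10L & off <= -1L),
                      any(off >= 1L & off <= 10L),
                      net_deleted_a2(genome, lo, hi) != 0L ||
                        has_any_indel(genome, lo, hi))
    k <- sum(tag_mat[i, ])
    recs$explanation[i] <- if (k == 0L) "unexplained"
                           else if (k > 1L) "multiple"
                           else cats[which(tag_mat[i, ])]
  }
  recs <- cbind(recs, tag_mat)
  lev <- c(cats, "multiple", "unexplained")
  fr <- table(factor(recs$explanation, levels = lev)) / max(nrow(recs), 1L)
  list(records = recs, fractions = as.data.frame(fr),
       fraction_explained = unname(1 - fr[["unexplained"]]))
}

has_any_indel <- function(genome, lo, hi) {
  v <- genome$variants
  v <- v[v$kind != "snp", , drop = FALSE]
  if (!nrow(v)) return(FALSE)
  any(v$pos1 + nchar(v$ref) - 1L >= lo & v$pos1 <= hi)
}

#' Compare pause-distance distributions between record subsets
#'
#' Two-sample KS (asymptotic) of projected pause-position distances for a
#' subset against its complement, and optionally one subset against
#' another (one-sided direction reported via the subset medians).
#'
#' @param records Record set with a `dist` column.
#' @param subsets Named list of logical vectors over `records` rows.
#' @return data.frame of comparisons (`subset`, `n`, medians, KS `p`).
#' @export
pause_distance_comparisons <- function(records, subsets) {
  do.call(rbind, lapply(names(subsets), function(nm) {
    s <- subsets[[nm]]
    x <- records$dist[s]
    y <- records$dist[!s]
    if (!length(x) || !length(y)) {
      return(data.frame(subset = nm, n_subset = length(x),
                        n_rest = length(y), median_subset = NA_real_,
                        median_rest = NA_real_, p = NA_real_))
    }
    ks <- ks_two_sample(x, y, min_obs = 1L)
    data.frame(subset = nm, n_subset = length(x), n_rest = length(y),
               median_subset = stats::median(x), median_rest = stats::median(y),
               p = ks$p, stringsAsFactors = FALSE)
  }))
}
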