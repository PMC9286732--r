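# DNA-sequence determinants of transcription initiation: initiator
# dinucleotide hierarchy, positional SNP profiles with ascertainment-matched
# controls, base composition / AT content, TATA scoring against a
# first-order Markov background, and the local redistribution
# ("shooting-gallery") analysis.

DINUC_ORDER <- c("CA", "TA", "TG", "CG")  # strong to weak initiator

counts_lookup <- function(counts) {
  k <- paste(counts$contig, counts$strand, counts$pos)
  list(key = k, a1 = counts$a1, a2 = counts$a2)
}

lookup_allelic <- function(idx, contig, strand, pos) {
  i <- match(paste(contig, strand, pos), idx$key)
  cbind(a1 = ifelse(is.na(i), 0L, idx$a1[i]),
        a2 = ifelse(is.na(i), 0L, idx$a2[i]))
}

#' Initiator dinucleotide hierarchy from allelic maxTSS changes
#'
#' For every cluster whose maxTSS initiator (bases -1,0) differs between
#' alleles and lies in the pyrimidine-purine set {CA, TA, TG, CG}, assigns
#' the site to a category `strong_weak` (ordered CA > TA > TG > CG) and
#' computes the allelic bias ratio log2(reads on the stronger-initiator
#' allele / reads on the other allele) at the maxTSS. Categories are
#' compared pairwise with the two-sided rank-sum test, BH-adjusted.
#'
#' @param tsc_set A `tsc_set`.
#' @param counts5 Five-prime `site_counts` (for allelic reads at the maxTSS).
#' @param genome A `genome_pair`.
#' @return List `(sites, tests)`: per-site categories/ratios and pairwise
#'   category comparisons.
#' @export
dinucleotide_hierarchy <- function(tsc_set, counts5, genome) {
  tsc <- tsc_set$tsc
  idx <- counts_lookup(counts5)
  pos2 <- map_coords(genome, tsc$maxtss_pos, from = "a1")
  d1 <- vapply(seq_len(nrow(tsc)), function(i)
    initiator_dinuc(genome, "A1", tsc$maxtss_pos[i], tsc$strand[i]) %||% NA_character_,
    character(1))
  d2 <- vapply(seq_len(nrow(tsc)), function(i)
    initiator_dinuc(genome, "A2", pos2[i], tsc$strand[i]) %||% NA_character_,
    character(1))
  cnt <- lookup_allelic(idx, tsc$contig, tsc$strand, tsc$maxtss_pos)
  keep <- !is.na(d1) & !is.na(d2) & d1 != d2 &
    d1 %in% DINUC_ORDER & d2 %in% DINUC_ORDER &
    cnt[, "a1"] > 0L & cnt[, "a2"] > 0L
  r1 <- match(d1, DINUC_ORDER)
  r2 <- match(d2, DINUC_ORDER)
  strong_first <- r1 < r2
  category <- ifelse(strong_first, paste0(d1, "_", d2), paste0(d2, "_", d1))
  ratio <- ifelse(strong_first, log2(cnt[, "a1"] / cnt[, "a2"]),
                  log2(cnt[, "a2"] / cnt[, "a1"]))
  sites <- data.frame(tsc_id = tsc$tsc_id, maxtss = tsc$maxtss_pos,
                      strand = tsc$strand, dinuc_a1 = d1, dinuc_a2 = d2,
                      a1 = cnt[, "a1"], a2 = cnt[, "a2"],
                      category = category, ratio = ratio,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  cats <- unique(sites$category)
  tests <- NULL
  if (length(cats) > 1L) {
    pairs <- utils::combn(sort(cats), 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      x <- sites$ratio[sites$category == pairs[1, j]]
      y <- sites$ratio[sites$category == pairs[2, j]]
      w <- wilcoxon_rank_sum(x, y, method = "normal")
      data.frame(cat1 = pairs[1, j], cat2 = pairs[2, j],
                 median1 = stats::median(x), median2 = stats::median(y),
                 n1 = length(x), n2 = length(y), p = w$p,
                 stringsAsFactors = FALSE)
    }))
    tests$q <- bh_fdr(tests$p)
  }
  rownames(sites) <- NULL
  list(sites = sites, tests = tests)
}

# strand-aware offsets of SNPs around each anchor, one list element per site
site_snp_offsets <- function(genome, anchors, window) {
  v <- genome$variants
  snp_pos <- v$pos1[v$kind == "snp"]
  lapply(seq_len(nrow(anchors)), function(i) {
    off <- downstream_dist(anchors$pos[i], snp_pos, anchors$strand[i])
    off[abs(off) <= window]
  })
}

#' Positional SNP profile around anchors, test vs control
#'
#' Computes the mean SNP count per strand-aware profile bin around test and
#' control anchors, then tests per merged bin whether test sites are
#' enriched for carrying a SNP (Fisher's exact test, BH at `fdr`). The
#' control set must be the ascertainment-matched no-change background.
#'
#' @param test,control data.frames `pos, strand` of anchor sites.
#' @param genome A `genome_pair`.
#' @param window Half-window in bp (default 100).
#' @param profile_bin Display bin (default 5 bp).
#' @param test_bin Merged test bin (default 10 bp).
#' @param fdr Enrichment FDR (default 0.05).
#' @return List `(profile, tests)`.
#' @export
snp_positional_profile <- function(test, control, genome, window = 100L,
                                   profile_bin = 5L, test_bin = 10L,
                                   fdr = 0.05) {
  if (is.null(control) || nrow(control) == 0L) stop("empty control set")
  offs_t <- site_snp_offsets(genome, test, window)
  offs_c <- site_snp_offsets(genome, control, window)
  bins <- seq(-window, window - profile_bin, by = profile_bin)
  mean_in_bin <- function(offs, lo, hi) {
    mean(vapply(offs, function(o) sum(o >= lo & o < hi), numeric(1)))
  }
  profile <- data.frame(
    bin_start = bins, bin_end = bins + profile_bin,
    mean_test = vapply(bins, function(b) mean_in_bin(offs_t, b, b + profile_bin),
                       numeric(1)),
    mean_control = vapply(bins, function(b) mean_in_bin(offs_c, b, b + profile_bin),
                          numeric(1)))
  tbins <- seq(-window, window - test_bin, by = test_bin)
  tests <- do.call(rbind, lapply(tbins, function(b) {
    ht <- vapply(offs_t, function(o) any(o >= b & o < b + test_bin), logical(1))
    hc <- vapply(offs_c, function(o) any(o >= b & o < b + test_bin), logical(1))
    ft <- fisher_exact_2x2(sum(ht), sum(!ht), sum(hc), sum(!hc))
    data.frame(bin_start = b, bin_end = b + test_bin,
               test_with_snp = sum(ht), control_with_snp = sum(hc),
               odds_ratio = ft$odds_ratio, p = ft$p)
  }))
  tests$q <- bh_fdr(tests$p)
  tests$significant <- tests$q <= fdr
  list(profile = profile, tests = tests)
}

#' Base composition and AT content, high vs low allele
#'
#' Per strand-aware position around the anchor, the difference in base
#' frequencies between the high- and low-usage alleles; per 5 bp window
#' (with initiator positions -1 and 0 masked) the AT-fraction difference;
#' and per window a Fisher test for enrichment of AT-(high) to GC-(low)
#' SNPs in test vs control sites, BH-adjusted.
#'
#' @param test data.frame `pos, strand, high` (high allele `"A1"`/`"A2"`,
#'   anchored at the high-allele maxTSS, allele1 coordinates).
#' @param control Background sites, same columns.
#' @param genome A `genome_pair`.
#' @param window Half-window (default 30 bp).
#' @param at_bin AT window size (default 5 bp).
#' @param fdr Enrichment FDR (default 0.05).
#' @return List `(freq_diff, at_windows)`.
#' @export
base_composition_and_at <- function(test, control, genome, window = 30L,
                                    at_bin = 5L, fdr = 0.05) {
  offs <- seq(-window, window)
  site_seqs <- function(sites) {
    lapply(seq_len(nrow(sites)), function(i) {
      hi <- sites$high[i]
      lo <- setdiff(c("A1", "A2"), hi)
      p_hi <- local_pos(genome, sites$pos[i], hi)
      p_lo <- local_pos(genome, sites$pos[i], lo)
      list(high = oriented_window(allele_seq(genome, hi), p_hi,
                                  sites$strand[i], -window, window),
           low = oriented_window(allele_seq(genome, lo), p_lo,
                                 sites$strand[i], -window, window))
    })
  }
  st <- site_seqs(test)
  ok <- vapply(st, function(x) !is.na(x$high) && !is.na(x$low), logical(1))
  st <- st[ok]
  mat_of <- function(which) {
    do.call(rbind, lapply(st, function(x) strsplit(x[[which]], "")[[1]]))
  }
  mh <- mat_of("high"); ml <- mat_of("low")
  freq_diff <- do.call(rbind, lapply(seq_along(offs), function(j) {
    data.frame(offset = offs[j],
               dA = mean(mh[, j] == "A") - mean(ml[, j] == "A"),
               dC = mean(mh[, j] == "C") - mean(ml[, j] == "C"),
               dG = mean(mh[, j] == "G") - mean(ml[, j] == "G"),
               dT = mean(mh[, j] == "T") - mean(ml[, j] == "T"))
  }))
  # AT windows with the initiator masked
  wins <- seq(-window, window - at_bin, by = at_bin)
  masked <- function(o) o %in% c(-1L, 0L)
  at_diff <- vapply(wins, function(b) {
    j <- which(offs >= b & offs < b + at_bin & !masked(offs))
    if (!length(j)) return(NA_real_)
    mean(mh[, j, drop = FALSE] %in% c("A", "T")) -
      mean(ml[, j, drop = FALSE] %in% c("A", "T"))
  }, numeric(1))
  # AT(high) -> GC(low) SNP enrichment per window, test vs control
  at_gc_hits <- function(sites) {
    ss <- site_seqs(sites)
    vapply(seq_along(ss), function(i) {
      x <- ss[[i]]
      if (is.na(x$high) || is.na(x$low)) return(rep(FALSE, length(wins)))
      h <- strsplit(x$high, "")[[1]]; l <- strsplit(x$low, "")[[1]]
      snp <- h != l & h %in% c("A", "T") & l %in% c("G", "C") & !masked(offs)
      vapply(wins, function(b) any(snp & offs >= b & offs < b + at_bin),
             logical(1))
    }, logical(length(wins)))
  }
  ht <- at_gc_hits(test)
  hc <- at_gc_hits(control)
  at_windows <- do.call(rbind, lapply(seq_along(wins), function(j) {
    ft <- fisher_exact_2x2(sum(ht[j, ]), sum(!ht[j, ]),
                           sum(hc[j, ]), sum(!hc[j, ]))
    data.frame(win_start = wins[j], win_end = wins[j] + at_bin,
               at_diff = at_diff[j], test_with_snp = sum(ht[j, ]),
               control_with_snp = sum(hc[j, ]), p = ft$p)
  }))
  at_windows$q <- bh_fdr(at_windows$p)
  at_windows$significant <- at_windows$q <= fdr
  list(freq_diff = freq_diff, at_windows = at_windows)
}

#' Read a position weight matrix from plain text
#'
#' Format: a `>name` header line followed by one line per motif position
#' with four probabilities (A C G T order).
#'
#' @param path File path.
#' @return List `(id, mat)` with a w x 4 probability matrix.
#' @export
read_pwm <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  stopifnot(startsWith(lines[1], ">"))
  mat <- do.call(rbind, lapply(lines[-1], function(l)
    as.numeric(strsplit(l, "\\s+")[[1]])))
  colnames(mat) <- BASES
  if (any(abs(rowSums(mat) - 1) > 1e-6)) stop("PWM rows must sum to 1")
  list(id = sub("^>", "", lines[1]), mat = mat)
}

#' Load a bundled TATA position weight matrix
#'
#' Two matrices ship with the package: `"degenerate"` (AT-rich, low
#' information) and `"strict"` (TATAAA-like, high information). Both are
#' user-replaceable via [read_pwm()].
#'
#' @param which `"degenerate"` or `"strict"`.
#' @return A PWM list as from [read_pwm()].
#' @export
load_bundled_pwm <- function(which = c("degenerate", "strict")) {
  which <- match.arg(which)
  read_pwm(system.file("extdata", paste0("pwm_tata_", which, ".txt"),
                       package = "allelicTx", mustWork = TRUE))
}

# first-order Markov background estimated from a sequence
markov_background <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  p0 <- table(factor(b, levels = BASES)) / length(b)
  trans <- table(factor(b[-length(b)], levels = BASES),
                 factor(b[-1], levels = BASES))
  trans <- sweep(trans + 1, 1, rowSums(trans + 1), "/")  # add-one smoothing
  list(p0 = as.numeric(p0) + 1e-9, trans = as.matrix(trans))
}

# maximal log-likelihood-ratio PWM score over all placements in a window
pwm_max_score <- function(window_seq, pwm, bg) {
  if (is.na(window_seq)) return(NA_real_)
  x <- strsplit(window_seq, "")[[1]]
  w <- nrow(pwm$mat)
  n <- length(x)
  if (n < w) return(NA_real_)
  xi <- match(x, BASES)
  best <- -Inf
  for (s in 0:(n - w)) {
    i <- xi[(s + 1):(s + w)]
    if (anyNA(i)) next
    lm <- sum(log(pwm$mat[cbind(seq_len(w), i)]))
    lb <- log(bg$p0[i[1]])
    if (w > 1) lb <- lb + sum(log(bg$trans[cbind(i[-w], i[-1])]))
    best <- max(best, lm - lb)
  }
  best
}

#' Associate TATA motif changes with allelic maxTSS usage
#'
#' Scores the -35..-20 window upstream of each maxTSS on both alleles with
#' a PWM against a first-order Markov background (log likelihood ratio,
#' maximal placement). Conditioning on a clear motif (max score >
#' `threshold` on at least one allele), correlates the allelic score
#' difference with the allelic usage difference (Pearson).
#'
#' @param sites data.frame `pos, strand, dusage` (anchor = maxTSS on
#'   allele1 coordinates; `dusage` = log2 allelic usage difference,
#'   allele1 over allele2).
#' @param genome A `genome_pair`.
#' @param pwm A PWM from [read_pwm()]/[load_bundled_pwm()].
#' @param window Upstream window, strand-aware offsets (default -35..-20).
#' @param threshold Motif-presence score threshold (default 3).
#' @return List `(sites, r, p, n)`; `r = NA` when degenerate.
#' @export
tata_association <- function(sites, genome, pwm, window = c(-35L, -20L),
                             threshold = 3) {
  bg <- markov_background(genome$seq1)
  s1 <- vapply(seq_len(nrow(sites)), function(i) {
    pwm_max_score(oriented_window(genome$seq1, sites$pos[i], sites$strand[i],
                                  window[1], window[2]), pwm, bg)
  }, numeric(1))
  p2 <- map_coords(genome, sites$pos, from = "a1")
  s2 <- vapply(seq_len(nrow(sites)), function(i) {
    pwm_max_score(oriented_window(genome$seq2, p2[i], sites$strand[i],
                                  window[1], window[2]), pwm, bg)
  }, numeric(1))
  keep <- !is.na(s1) & !is.na(s2) & pmax(s1, s2) > threshold
  out <- data.frame(pos = sites$pos, strand = sites$strand,
                    score_a1 = s1, score_a2 = s2,
                    dscore = s1 - s2, dusage = sites$dusage)[keep, ]
  if (nrow(out) < 3L || stats::sd(out$dscore) == 0 ||
      stats::sd(out$dusage) == 0) {
    return(list(sites = out, r = NA_real_, p = NA_real_, n = nrow(out)))
  }
  ct <- stats::cor.test(out$dscore, out$dusage)
  list(sites = out, r = unname(ct$estimate), p = ct$p.value, n = nrow(out))
}

#' Redistribution of initiation around initiator-disrupted maxTSSs
#'
#' Tests the local-search model of start-site selection: among clusters not
#' overlapping allelic-imbalance blocks, test sites have a CA initiator on
#' the high allele and a non-CA initiator on the low allele; control sites
#' have identical initiators on both alleles. At every other candidate
#' initiator (YR dinucleotide on both alleles) the allelic signal ratio
#' low/high is collected as a function of strand-aware distance from the
#' maxTSS, compared test vs control per distance bin (rank-sum test, BH).
#'
#' @param tsc_set A `tsc_set`.
#' @param counts5 Five-prime `site_counts`.
#' @param blocks Allelic blocks to exclude (may be empty).
#' @param genome A `genome_pair`.
#' @param window Half-window for the near analysis (default 20 bp).
#' @param wide_window TSR-wide half-window (default 150 bp).
#' @param bin Distance bin (default 5 bp).
#' @param fdr BH cutoff (default 0.05).
#' @return List `(candidates, bin_tests, near_test, wide_test)`.
#' @export
shooting_gallery <- function(tsc_set, counts5, blocks, genome,
                             window = 20L, wide_window = 150L, bin = 5L,
                             fdr = 0.05) {
  tsc <- tsc_set$tsc
  idx <- counts_lookup(counts5)
  # exclude clusters overlapping blocks
  if (!is.null(blocks) && nrow(blocks)) {
    ov <- vapply(seq_len(nrow(tsc)), function(i) {
      b <- blocks[blocks$contig == tsc$contig[i] &
                    blocks$strand == tsc$strand[i], , drop = FALSE]
      any(b$start < tsc$end[i] & b$end > tsc$start[i])
    }, logical(1))
    tsc <- tsc[!ov, , drop = FALSE]
  }
  cnt <- lookup_allelic(idx, tsc$contig, tsc$strand, tsc$maxtss_pos)
  pos2 <- map_coords(genome, tsc$maxtss_pos, from = "a1")
  d1 <- vapply(seq_len(nrow(tsc)), function(i)
    initiator_dinuc(genome, "A1", tsc$maxtss_pos[i], tsc$strand[i]) %||% NA_character_,
    character(1))
  d2 <- vapply(seq_len(nrow(tsc)), function(i)
    initiator_dinuc(genome, "A2", pos2[i], tsc$strand[i]) %||% NA_character_,
    character(1))
  usable <- cnt[, "a1"] + cnt[, "a2"] > 0L & cnt[, "a1"] != cnt[, "a2"] &
    !is.na(d1) & !is.na(d2)
  high <- ifelse(cnt[, "a1"] > cnt[, "a2"], "A1", "A2")
  d_high <- ifelse(high == "A1", d1, d2)
  d_low <- ifelse(high == "A1", d2, d1)
  group <- ifelse(d_high == "CA" & d_low != "CA", "test",
                  ifelse(d1 == d2, "control", NA_character_))
  rows <- which(usable & !is.na(group))
  cand <- list()
  for (i in rows) {
    offs <- setdiff(seq(-wide_window, wide_window), 0L)
    p1 <- offset_pos(tsc$maxtss_pos[i], offs, tsc$strand[i])
    dn1 <- vapply(p1, function(p)
      initiator_dinuc(genome, "A1", p, tsc$strand[i]) %||% NA_character_,
      character(1))
    yr1 <- !is.na(dn1) & dn1 %in% DINUC_ORDER
    if (!any(yr1)) next
    p2i <- map_coords(genome, p1[yr1], from = "a1")
    dn2 <- vapply(seq_along(p2i), function(k)
      initiator_dinuc(genome, "A2", p2i[k], tsc$strand[i]) %||% NA_character_,
      character(1))
    yr <- which(yr1)[!is.na(dn2) & dn2 %in% DINUC_ORDER]
    if (!length(yr)) next
    cc <- lookup_allelic(idx, rep(tsc$contig[i], length(yr)),
                         rep(tsc$strand[i], length(yr)), p1[yr])
    hi_col <- if (high[i] == "A1") "a1" else "a2"
    lo_col <- if (high[i] == "A1") "a2" else "a1"
    keep <- cc[, hi_col] > 0L
    if (!any(keep)) next
    cand[[length(cand) + 1L]] <- data.frame(
      tsc_id = tsc$tsc_id[i], offset = offs[yr][keep],
      ratio = cc[keep, lo_col] / cc[keep, hi_col],
      group = group[i], stringsAsFactors = FALSE)
  }
  cand <- do.call(rbind, cand)
  empty <- list(candidates = cand, bin_tests = NULL, near_test = NULL,
                wide_test = NULL)
  if (is.null(cand) || !all(c("test", "control") %in% cand$group)) return(empty)
  near <- cand[abs(cand$offset) <= window, ]
  bins <- seq(-window, window - bin, by = bin)
  bin_tests <- do.call(rbind, lapply(bins, function(b) {
    x <- near$ratio[near$group == "test" & near$offset >= b & near$offset < b + bin]
    y <- near$ratio[near$group == "control" & near$offset >= b & near$offset < b + bin]
    if (length(x) < 3L || length(y) < 3L) {
      return(data.frame(bin_start = b, bin_end = b + bin, n_test = length(x),
                        n_control = length(y), median_test = NA, median_control = NA,
                        p = NA_real_))
    }
    w <- wilcoxon_rank_sum(x, y, method = "normal")
    data.frame(bin_start = b, bin_end = b + bin, n_test = length(x),
               n_control = length(y), median_test = stats::median(x),
               median_control = stats::median(y), p = w$p)
  }))
  bin_tests$q <- bh_fdr(bin_tests$p)
  bin_tests$significant <- !is.na(bin_tests$q) & bin_tests$q <= fdr
  one_test <- function(d) {
    x <- d$ratio[d$group == "test"]; y <- d$ratio[d$group == "control"]
    if (length(x) < 3L || length(y) < 3L) return(NULL)
    w <- wilcoxon_rank_sum(x, y, method = "normal")
    data.frame(n_test = length(x), n_control = length(y),
               median_test = stats::median(x), median_control = stats::median(y),
               p = w$p)
  }
  list(candidates = cand, bin_tests = bin_tests,
       near_test = one_test(near),
       wide_test = one_test(cand[abs(cand$offset) > window, ]))
}
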