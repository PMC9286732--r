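# Statistical core: exact allelic tests, FDR, weighted two-sample KS,
# p-value combination. Standard tests delegate to stats::; the weighted KS
# and the rank-sum test are implemented here because the base versions
# reject or approximate ties, which dominate discrete positional data.

#' Two-sided exact binomial test of allelic balance
#'
#' Tests `count_a1` successes out of `count_a1 + count_a2` trials against an
#' expected allelic ratio of 0.5. Vectorised.
#'
#' @param count_a1,count_a2 Non-negative integer vectors.
#' @return Numeric vector of two-sided p-values; `NA` where the total is 0.
#' @export
binomial_allelic_test <- function(count_a1, count_a2) {
  n <- count_a1 + count_a2
  if (!length(n)) return(numeric(0))
  mapply(function(x, tot) {
    if (tot == 0L) return(NA_real_)
    stats::binom.test(x, tot, p = 0.5)$p.value
  }, count_a1, n)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (delegates to [stats::p.adjust()]); `NA` inputs
#' other than missing-by-design raise an error.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed, NaN not).
#' @return Vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (any(is.nan(p))) stop("NaN p-value")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0,1]")
  stats::p.adjust(p, method = "BH")
}

# expand weighted positions to an observation vector
expand_obs <- function(pos, w) {
  stopifnot(length(pos) == length(w), all(w >= 0))
  rep(pos, w)
}

# D statistic of two observation vectors (max absolute ECDF difference)
ks_d_stat <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  fx <- stats::ecdf(x)(pts)
  fy <- stats::ecdf(y)(pts)
  max(abs(fx - fy))
}

# asymptotic two-sample KS tail probability (Kolmogorov distribution with
# the standard finite-sample correction)
ks_p_asymptotic <- function(d, n1, n2) {
  ne <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * d
  if (lambda < 1e-3) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Weighted two-sample Kolmogorov-Smirnov test
#'
#' Compares two discrete positional distributions given as positions with
#' counts. Counts are expanded to observations; D is the maximum absolute
#' ECDF difference. P-values are asymptotic by default, or exact by full
#' enumeration of all splits of the pooled observations (feasible for small
#' totals; heavy ties make the asymptotic formula conservative).
#'
#' @param pos_a1,pos_a2 Integer positions per allele.
#' @param w_a1,w_a2 Non-negative counts per position (default 1 each).
#' @param min_obs Minimum observations per side (default 5); below it the
#'   no-test sentinel (`NA` statistics, `ok = FALSE`) is returned.
#' @param method `"asymptotic"`, `"exact"` (full enumeration; requires
#'   `choose(n, n1) <= max_splits`) or `"mc"` (Monte-Carlo permutation,
#'   better calibrated than the asymptotic formula under heavy ties; uses
#'   the R RNG, so seed for reproducibility).
#' @param max_splits Enumeration cap for the exact method.
#' @param B Number of Monte-Carlo permutations (default 499).
#' @return List `(D, p, n1, n2, ok, method)`.
#' @export
ks_two_sample <- function(pos_a1, pos_a2, w_a1 = NULL, w_a2 = NULL,
                          min_obs = 5L,
                          method = c("asymptotic", "exact", "mc"),
                          max_splits = 2e5, B = 499L) {
  method <- match.arg(method)
  x <- expand_obs(pos_a1, w_a1 %||% rep(1L, length(pos_a1)))
  y <- expand_obs(pos_a2, w_a2 %||% rep(1L, length(pos_a2)))
  n1 <- length(x); n2 <- length(y)
  if (n1 < min_obs || n2 < min_obs) {
    return(list(D = NA_real_, p = NA_real_, n1 = n1, n2 = n2, ok = FALSE,
                method = "none"))
  }
  d <- ks_d_stat(x, y)
  if (method == "exact") {
    if (choose(n1 + n2, n1) > max_splits) {
      stop("exact KS enumeration too large; use method = 'asymptotic'")
    }
    pooled <- c(x, y)
    splits <- utils::combn(n1 + n2, n1)
    ds <- apply(splits, 2, function(i) ks_d_stat(pooled[i], pooled[-i]))
    p <- mean(ds >= d - 1e-12)
  } else if (method == "mc") {
    pooled <- c(x, y)
    pts <- sort(unique(pooled))
    code <- match(pooled, pts)
    tot <- tabulate(code, length(pts))
    n <- n1 + n2
    ds <- vapply(seq_len(B), function(b) {
      g1 <- tabulate(code[sample.int(n, n1)], length(pts))
      max(abs(cumsum(g1) / n1 - cumsum(tot - g1) / n2))
    }, numeric(1))
    p <- (1 + sum(ds >= d - 1e-12)) / (B + 1)
  } else {
    p <- ks_p_asymptotic(d, n1, n2)
  }
  list(D = d, p = p, n1 = n1, n2 = n2, ok = TRUE, method = method)
}

#' Combine p-values with Fisher's method
#'
#' `X2 = -2 sum(log p)` against a chi-square with `2k` df. Zero p-values
#' are clipped to the smallest positive double with a warning.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return Combined p-value.
#' @export
fisher_combine <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  if (any(p <= 0)) {
    warning("p-value <= 0 clipped for Fisher combination")
    p <- pmax(p, .Machine$double.xmin)
  }
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by hypergeometric enumeration of tables at most as probable
#' as the observed one (via [stats::fisher.test()]); the reported odds
#' ratio is the conditional maximum-likelihood estimate.
#'
#' @param a,b,c,d Non-negative integer cell counts (row-wise).
#' @return List `(odds_ratio, p)`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  ft <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact mode enumerates all assignments of the pooled observations to the
#' two groups (ties handled with midranks), with the two-sided p defined as
#' the probability of a rank-sum at least as far from its null mean as
#' observed. The normal mode applies the tie-corrected normal approximation
#' with continuity correction.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param method `"auto"` (exact when `choose(n, nx) <= max_splits`),
#'   `"exact"` or `"normal"`.
#' @param max_splits Enumeration cap.
#' @return List `(W, p, method)` where `W` is the rank-sum of `x`.
#' @export
wilcoxon_rank_sum <- function(x, y, method = c("auto", "exact", "normal"),
                              max_splits = 1e4) {
  method <- match.arg(method)
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) return(list(W = NA_real_, p = NA_real_,
                                        method = "none"))
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(nx)])
  mu <- nx * (nx + ny + 1) / 2
  if (method == "auto") {
    method <- if (choose(nx + ny, nx) <= max_splits) "exact" else "normal"
  }
  if (method == "exact") {
    splits <- utils::combn(nx + ny, nx)
    ws <- colSums(matrix(r[splits], nrow = nx))
    p <- mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
  } else {
    n <- nx + ny
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(W = w, p = p, method = method)
}

#' Test TSCs for allelic abundance differences
#'
#' Exact binomial test of summed allele-specific counts per cluster against
#' 0.5, BH-adjusted. Clusters with `q <= fdr` are the allele-specific set;
#' clusters with `q > fdr_background` form the no-change control set.
#'
#' @param tsc_set A `tsc_set` from [cluster_tsc()].
#' @param fdr Significance FDR (default 0.10).
#' @param fdr_background Control-set cutoff (default 0.90).
#' @return data.frame with counts, `p`, `q`, `significant`, `control`.
#' @export
tsc_abundance_test <- function(tsc_set, fdr = 0.10, fdr_background = 0.90) {
  tsc <- tsc_set$tsc
  tested <- tsc$a1 + tsc$a2 > 0L
  p <- rep(NA_real_, nrow(tsc))
  p[tested] <- binomial_allelic_test(tsc$a1[tested], tsc$a2[tested])
  q <- rep(NA_real_, nrow(tsc))
  q[tested] <- bh_fdr(p[tested])
  data.frame(tsc_id = tsc$tsc_id, a1 = tsc$a1, a2 = tsc$a2, p = p, q = q,
             significant = !is.na(q) & q <= fdr,
             control = !is.na(q) & q > fdr_background,
             high_allele = ifelse(tsc$a1 >= tsc$a2, "A1", "A2"))
}

#' Test TSCs for allelic shape differences
#'
#' Weighted two-sample KS between the allele1 and allele2 5'-end
#' distributions over member TSSs, for clusters with at least `min_obs`
#' tagged reads per allele; BH-adjusted.
#'
#' @param tsc_set A `tsc_set`.
#' @param min_obs Minimum tagged reads per allele (default 5).
#' @param fdr,fdr_background Significance / control cutoffs.
#' @return data.frame with `D, p, q, eligible, significant, control`.
#' @export
tsc_shape_test <- function(tsc_set, min_obs = 5L, fdr = 0.10,
                           fdr_background = 0.90, method = "mc", B = 499L) {
  m <- tsc_set$members
  sp <- split(seq_len(nrow(m)), m$tsc_id)
  res <- do.call(rbind, lapply(sp, function(i) {
    d <- m[i, ]
    ks <- ks_two_sample(d$pos, d$pos, d$a1, d$a2, min_obs = min_obs,
                        method = method, B = B)
    data.frame(tsc_id = d$tsc_id[1], D = ks$D, p = ks$p,
               n1 = ks$n1, n2 = ks$n2, eligible = ks$ok)
  }))
  res$q <- NA_real_
  res$q[res$eligible] <- bh_fdr(res$p[res$eligible])
  res$significant <- res$eligible & !is.na(res$q) & res$q <= fdr
  res$control <- res$eligible & !is.na(res$q) & res$q > fdr_background
  rownames(res) <- NULL
  res
}

#' Classify shape changes as single- or multi-TSS driven
#'
#' For each shape-significant cluster, masks the member TSS with the
#' largest absolute allelic count difference (5'-most on ties) and re-runs
#' the KS test. If the masked p exceeds the nominal threshold (the highest
#' nominal p that achieved the first-pass FDR) the change was driven by a
#' single TSS, otherwise by multiple TSSs. If masking leaves fewer than
#' `min_obs` observations on either allele the effect was carried by the
#' masked TSS and the cluster is classified single (flagged low-power).
#'
#' @param tsc_set A `tsc_set`.
#' @param shape_results Output of [tsc_shape_test()].
#' @param fdr First-pass FDR (default 0.10).
#' @param min_obs Minimum post-masking observations per allele.
#' @return `shape_results` with `class` (`single`/`multi`/`none`),
#'   `masked_pos` and `low_power` columns.
#' @export
classify_shape_change <- function(tsc_set, shape_results, fdr = 0.10,
                                  min_obs = 5L, method = "mc", B = 499L) {
  res <- shape_results
  sig <- res$eligible & !is.na(res$q) & res$q <= fdr
  nominal <- if (any(sig)) max(res$p[sig]) else NA_real_
  res$class <- "none"
  res$masked_pos <- NA_integer_
  res$low_power <- FALSE
  m <- tsc_set$members
  for (i in which(sig)) {
    d <- m[m$tsc_id == res$tsc_id[i], ]
    dd <- abs(d$a1 - d$a2)
    cand <- d$pos[dd == max(dd)]
    mask <- five_prime_most(cand, d$strand[1])
    keep <- d[d$pos != mask, , drop = FALSE]
    res$masked_pos[i] <- mask
    if (sum(keep$a1) < min_obs || sum(keep$a2) < min_obs) {
      res$class[i] <- "single"
      res$low_power[i] <- TRUE
      next
    }
    ks <- ks_two_sample(keep$pos, keep$pos, keep$a1, keep$a2,
                        min_obs = min_obs, method = method, B = B)
    res$class[i] <- if (ks$p > nominal) "single" else "multi"
  }
  res
}
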