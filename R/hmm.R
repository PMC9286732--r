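# Three-state HMM segmentation of allelic imbalance along informative
# positions: balanced (allele1 probability 0.5), allele1-biased (rho) and
# allele2-biased (1 - rho), binomial emissions per position and a symmetric
# switch probability tau. Decoding is Viterbi; the chain starts balanced.

hmm_viterbi <- function(a1, a2, tau, rho) {
  n <- length(a1)
  ps <- c(0.5, rho, 1 - rho)
  # log transition matrix: stay 1 - 2*tau, switch tau to each other state
  lt <- matrix(log(tau), 3, 3)
  diag(lt) <- log(1 - 2 * tau)
  emis <- vapply(ps, function(p) stats::dbinom(a1, a1 + a2, p, log = TRUE),
                 numeric(n))
  if (n == 1L) emis <- matrix(emis, nrow = 1L)
  v <- matrix(-Inf, n, 3)
  back <- matrix(0L, n, 3)
  init <- c(0, -Inf, -Inf)           # starts in the balanced state
  v[1, ] <- init + emis[1, ]
  if (n > 1) for (t in 2:n) {
    for (s in 1:3) {
      cand <- v[t - 1, ] + lt[, s]
      back[t, s] <- which.max(cand)
      v[t, s] <- cand[back[t, s]] + emis[t, s]
    }
  }
  path <- integer(n)
  path[n] <- which.max(v[n, ])
  if (n > 1) for (t in (n - 1):1) path[t] <- back[t + 1, path[t + 1]]
  list(path = path, loglik = max(v[n, ]))
}

#' Call allelically imbalanced blocks with a three-state HMM
#'
#' Informative positions (>= 1 tagged read) ordered along each contig and
#' strand are decoded with Viterbi; maximal runs of a biased state become
#' blocks. Each block's p-value is the exact binomial test on its summed
#' allelic counts.
#'
#' @param positions data.frame with `contig, strand, pos, a1, a2`
#'   (informative positions; rows with `a1 + a2 == 0` are dropped).
#' @param tau State-switch probability (`tau = 0` forbids leaving the
#'   balanced start state, hence no blocks).
#' @param rho Emission probability of the biased states (default 0.9).
#' @return data.frame of blocks: `contig, strand, start, end, direction,
#'   a1, a2, n_pos, p`.
#' @export
hmm_call_blocks <- function(positions, tau = 1e-4, rho = 0.9) {
  stopifnot(tau >= 0, tau < 1 / 3, rho > 0.5, rho < 1)
  d <- positions[positions$a1 + positions$a2 > 0L, , drop = FALSE]
  out <- list()
  for (key in unique(paste(d$contig, d$strand))) {
    x <- d[paste(d$contig, d$strand) == key, , drop = FALSE]
    x <- x[order(x$pos), ]
    if (nrow(x) < 2L) next
    if (tau == 0) next                       # switching forbidden
    path <- hmm_viterbi(x$a1, x$a2, tau, rho)$path
    run <- rle(path)
    ends <- cumsum(run$lengths)
    starts <- ends - run$lengths + 1L
    for (j in which(run$values != 1L)) {
      i <- starts[j]:ends[j]
      out[[length(out) + 1L]] <- data.frame(
        contig = x$contig[1], strand = x$strand[1],
        start = x$pos[starts[j]], end = x$pos[ends[j]] + 1L,
        direction = c("A1", "A2")[run$values[j] - 1L],
        a1 = sum(x$a1[i]), a2 = sum(x$a2[i]), n_pos = length(i),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(), strand = character(),
                      start = integer(), end = integer(),
                      direction = character(), a1 = integer(),
                      a2 = integer(), n_pos = integer(), p = numeric()))
  }
  blocks <- do.call(rbind, out)
  blocks$p <- binomial_allelic_test(blocks$a1, blocks$a2)
  rownames(blocks) <- NULL
  blocks
}

#' Select the HMM switch probability on a labelled reference
#'
#' Evaluates each grid value by calling blocks and classifying reference
#' units (labelled allelic or not) as positive when any same-strand block
#' overlaps them; picks the tau maximising sensitivity + specificity,
#' breaking ties toward the smaller tau.
#'
#' @param positions Informative-position table as for [hmm_call_blocks()].
#' @param reference data.frame of units `contig, start, end, strand,
#'   allelic` (logical truth labels).
#' @param tau_grid Candidate switch probabilities.
#' @param rho Biased emission probability.
#' @return List `(tau, scores)` where `scores` has one row per grid value.
#' @export
select_tau <- function(positions, reference, tau_grid = c(1e-5, 1e-4),
                       rho = 0.9) {
  if (is.null(reference) || nrow(reference) == 0L) {
    stop("empty reference set for tau selection")
  }
  scores <- do.call(rbind, lapply(tau_grid, function(tau) {
    blocks <- hmm_call_blocks(positions, tau = tau, rho = rho)
    pred <- vapply(seq_len(nrow(reference)), function(i) {
      b <- blocks[blocks$contig == reference$contig[i] &
                    blocks$strand == reference$strand[i], , drop = FALSE]
      any(b$start < reference$end[i] & b$end > reference$start[i])
    }, logical(1))
    sens <- if (any(reference$allelic)) mean(pred[reference$allelic]) else NA_real_
    spec <- if (any(!reference$allelic)) mean(!pred[!reference$allelic]) else NA_real_
    data.frame(tau = tau, sensitivity = sens, specificity = spec,
               score = sum(c(sens, spec), na.rm = TRUE))
  }))
  best <- scores$tau[scores$score == max(scores$score)]
  list(tau = min(best), scores = scores)
}
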