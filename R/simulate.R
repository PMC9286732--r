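# Read-end and mRNA-count simulation from a planted truth set.

# symmetric geometric jitter truncated to +/-4 bp
draw_jitter <- function(n, p) {
  j <- -4:4
  w <- (1 - p)^abs(j)
  sample(j, n, replace = TRUE, prob = w / sum(w))
}

rcount <- function(n, mu, overdispersion) {
  if (overdispersion > 0) rnbinom(n, size = 1 / overdispersion, mu = mu)
  else rpois(n, mu)
}

# strain-axis rate multiplied by the parent-of-origin multiplier for a cross.
# cross "A1xA2" means the A1 strain is the mother.
imprint_mult <- function(loci, cross, allele, ratio) {
  maternal <- if (cross == "A1xA2") "A1" else "A2"
  high <- ifelse(loci$imprint_high_parent == "mother", maternal,
                 setdiff(c("A1", "A2"), maternal))
  ifelse(loci$class == "imprinted",
         ifelse(high == allele, ratio, 1), 1)
}

#' Simulate allele-tagged nascent-RNA read ends
#'
#' For every sample (organ x cross x replicate) draws per-TSS promoter read
#' counts (Poisson, or negative binomial when overdispersion is configured),
#' places each read's 3' end at that allele's pause position plus symmetric
#' geometric jitter, and adds gene-body reads uniform over each allele's own
#' transcription-unit extent (the long allele transcribes through the
#' allelic termination window). Reads are allele-tagged with the configured
#' tagging probability, otherwise reported as `"untagged"`. Coordinates are
#' projected onto allele1; allele-local coordinates are retained in
#' `five_local`/`three_local`. Columns `source_allele`, `locus` and `source`
#' are simulation truth kept for evaluation only and are not used by any
#' analysis function.
#'
#' @param truth A `truth_set` from [plant_truth()].
#' @param config The matching [sim_config()].
#' @return A data.frame of read ends (see Details).
#' @export
simulate_read_ends <- function(truth, config) {
  stopifnot(inherits(truth, "truth_set"))
  cfg <- config
  set.seed(cfg$seed + 2L)
  gp <- truth$genome
  loci <- truth$loci
  tss <- truth$tss

  # global depth scalar so that the mean tagged promoter reads per TSC per
  # sample hits the configured target
  locus_tot <- tapply((tss$rate_a1 + tss$rate_a2) * loci$expr[tss$locus],
                      tss$locus, sum)
  # with tagging disabled the target is read as mean total reads per TSC
  eff_p <- if (cfg$tagging_p > 0) cfg$tagging_p else 1
  depth <- cfg$mean_tagged_per_tsc / (eff_p * mean(locus_tot))

  samples <- expand.grid(organ = cfg$organs, cross = c("A1xA2", "A2xA1"),
                         replicate = seq_len(cfg$n_reps),
                         stringsAsFactors = FALSE)
  out <- vector("list", nrow(samples) * 2L)
  k <- 0L
  for (s in seq_len(nrow(samples))) {
    cross <- samples$cross[s]
    im1 <- imprint_mult(loci, cross, "A1", cfg$imprint_ratio)
    im2 <- imprint_mult(loci, cross, "A2", cfg$imprint_ratio)

    # promoter reads per TSS x allele
    mu1 <- tss$rate_a1 * loci$expr[tss$locus] * im1[tss$locus] * depth
    mu2 <- tss$rate_a2 * loci$expr[tss$locus] * im2[tss$locus] * depth
    n1 <- rcount(length(mu1), mu1, cfg$overdispersion)
    n2 <- rcount(length(mu2), mu2, cfg$overdispersion)
    for (al in 1:2) {
      nn <- if (al == 1L) n1 else n2
      idx <- rep.int(seq_len(nrow(tss)), nn)
      if (!length(idx)) next
      li <- tss$locus[idx]
      strand <- tss$strand[idx]
      five_local <- if (al == 1L) tss$pos1[idx] else tss$pos2[idx]
      pl <- if (al == 1L) loci$pause1[li] else loci$pause2_local[li]
      three_local <- pl + draw_jitter(length(idx), cfg$pause_jitter_p)
      five_proj <- tss$pos1[idx]
      three_proj <- if (al == 1L) three_local
                    else map_coords(gp, three_local, from = "a2")
      k <- k + 1L
      out[[k]] <- data.frame(
        contig = gp$contig, five_prime = five_proj, three_prime = three_proj,
        strand = strand, source_allele = c("A1", "A2")[al],
        organ = samples$organ[s], cross = cross,
        replicate = samples$replicate[s],
        five_local = five_local, three_local = three_local,
        locus = li, source = "promoter", stringsAsFactors = FALSE)
    }

    # gene-body reads uniform over each allele's own unit extent
    for (al in 1:2) {
      len <- abs(ifelse(!is.na(loci$long_allele) &
                          loci$long_allele == c("A1", "A2")[al],
                        loci$end3_long, loci$end3_short) - loci$anchor)
      im <- if (al == 1L) im1 else im2
      strain <- ifelse(loci$class == "abundance" &
                         loci$biased_allele == c("A1", "A2")[al],
                       cfg$abundance_ratio, 1)
      mu <- cfg$gb_read_density * loci$expr * im * strain * len / 1000
      ng <- rcount(length(mu), mu, cfg$overdispersion)
      idx <- rep.int(seq_len(nrow(loci)), ng)
      if (!length(idx)) next
      li <- idx
      strand <- loci$strand[li]
      rl <- sample(20:80, length(idx), replace = TRUE)
      t0 <- as.integer(floor(runif(length(idx)) * pmax(len[li] - rl, 1L)))
      anc_local <- if (al == 1L) loci$anchor[li] else loci$anchor2[li]
      five_local <- offset_pos(anc_local, t0, strand)
      three_local <- offset_pos(anc_local, t0 + rl, strand)
      if (al == 1L) {
        five_proj <- five_local; three_proj <- three_local
      } else {
        five_proj <- map_coords(gp, five_local, from = "a2")
        three_proj <- map_coords(gp, three_local, from = "a2")
      }
      k <- k + 1L
      out[[k]] <- data.frame(
        contig = gp$contig, five_prime = five_proj, three_prime = three_proj,
        strand = strand, source_allele = c("A1", "A2")[al],
        organ = samples$organ[s], cross = cross,
        replicate = samples$replicate[s],
        five_local = five_local, three_local = three_local,
        locus = li, source = "genebody", stringsAsFactors = FALSE)
    }
  }
  reads <- do.call(rbind, out[seq_len(k)])
  if (is.null(reads)) {
    reads <- data.frame(contig = character(), five_prime = integer(),
                        three_prime = integer(), strand = character(),
                        source_allele = character(), organ = character(),
                        cross = character(), replicate = integer(),
                        five_local = integer(), three_local = integer(),
                        locus = integer(), source = character())
  }
  tagged <- runif(nrow(reads)) < cfg$tagging_p
  reads$allele <- ifelse(tagged, reads$source_allele, "untagged")
  rownames(reads) <- NULL
  reads[, c("contig", "five_prime", "three_prime", "strand", "allele",
            "organ", "cross", "replicate", "five_local", "three_local",
            "source_allele", "locus", "source")]
}

#' Simulate allele-assigned mRNA exon counts
#'
#' Per organ x cross, draws exon-level allele-specific mRNA counts as
#' Poisson with mean transcription rate x allelic stability multiplier x
#' exon length. Novel 3' exons planted on structure-changed termination loci
#' emit counts only on the long allele.
#'
#' @param truth A `truth_set`.
#' @param config The matching [sim_config()].
#' @return A data.frame with columns `gene, exon_id, start, end, strand,
#'   novel, organ, cross, allele, count`.
#' @export
simulate_mrna_counts <- function(truth, config) {
  stopifnot(inherits(truth, "truth_set"))
  cfg <- config
  set.seed(cfg$seed + 3L)
  loci <- truth$loci
  ex <- truth$exons
  samples <- expand.grid(organ = cfg$organs, cross = c("A1xA2", "A2xA1"),
                         stringsAsFactors = FALSE)
  out <- list()
  for (s in seq_len(nrow(samples))) {
    cross <- samples$cross[s]
    for (al in 1:2) {
      a <- c("A1", "A2")[al]
      im <- imprint_mult(loci, cross, a, cfg$imprint_ratio)
      strain <- ifelse(loci$class == "abundance" & loci$biased_allele == a,
                       cfg$abundance_ratio, 1)
      stab <- if (al == 1L) loci$stab_a1 else loci$stab_a2
      li <- ex$locus
      mu <- cfg$mrna_depth * loci$expr[li] * im[li] * strain[li] * stab[li] *
        ex$len / 1000
      # novel exon transcribed only on the long allele
      off_allele <- ex$novel & (is.na(loci$long_allele[li]) |
                                  loci$long_allele[li] != a)
      mu[off_allele] <- 0
      out[[length(out) + 1L]] <- data.frame(
        gene = li, exon_id = ex$exon_id, start = ex$start, end = ex$end,
        strand = loci$strand[li], novel = ex$novel,
        organ = samples$organ[s], cross = cross, allele = a,
        count = rpois(length(mu), mu), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a complete study
#'
#' Convenience wrapper chaining [generate_genome_pair()], [plant_truth()],
#' [simulate_read_ends()] and [simulate_mrna_counts()].
#'
#' @param config A [sim_config()].
#' @return List with `genome`, `truth`, `reads`, `mrna`, `config`.
#' @export
simulate_dataset <- function(config) {
  gp <- generate_genome_pair(config)
  truth <- plant_truth(gp, config)
  reads <- simulate_read_ends(truth, config)
  mrna <- simulate_mrna_counts(truth, config)
  list(genome = truth$genome, truth = truth, reads = reads, mrna = mrna,
       config = config)
}
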