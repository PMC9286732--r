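# Self-contained validation experiments: each simulates a study at fixed
# conditions, runs the analysis pipeline on the simulated reads only, and
# scores recovery against the planted truth. These back the acceptance
# checks and the reported summary numbers; the vignette documents the
# conditions.

#' Abundance-recovery experiment
#'
#' 500 clusters, 20% planted at a 3:1 allelic ratio, ~40 tagged reads per
#' cluster (organ-pooled); exact binomial + BH at q <= 0.1.
#'
#' @param seed Integer seed.
#' @param n_loci,planted_frac,ratio,mean_tagged Study conditions.
#' @return List `(sensitivity, empirical_fdr, n_tested)`.
#' @export
experiment_abundance <- function(seed, n_loci = 500L, planted_frac = 0.2,
                                 ratio = 3, mean_tagged = 10) {
  cfg <- sim_config(seed = seed, n_loci = n_loci, promoter_only = TRUE,
                    snp_density = 0, indel_density = 0,
                    init_snp_prob = 0, pause_csnp_prob = 0,
                    pause_indel_prob = 0,
                    mean_tagged_per_tsc = mean_tagged, n_reps = 2L,
                    abundance_ratio = ratio,
                    class_props = c(none = 1 - planted_frac,
                                    abundance = planted_frac,
                                    shape_single = 0, shape_multi = 0,
                                    termination = 0, imprinted = 0))
  ds <- simulate_dataset(cfg)
  c5 <- make_base_counts(ds$reads, "five_prime")
  tsc <- cluster_tsc(call_tss(c5, truth_regions_(ds$truth), 5L), 60L)
  ab <- tsc_abundance_test(tsc)
  truth_ab <- ds$truth$loci$class[tsc$tsc$region_id] == "abundance"
  list(sensitivity = mean(ab$significant[truth_ab]),
       empirical_fdr = sum(ab$significant & !truth_ab) /
         max(sum(ab$significant), 1L),
       n_tested = nrow(ab))
}

#' Null-calibration experiment
#'
#' 500 clusters with no planted effects and a variant-free genome: the
#' fraction of abundance calls at q <= 0.1 measures type-I control. Also
#' splits the no-change control anchors in half and runs the positional
#' SNP profile test on a genome with background SNPs, reporting the
#' fraction of significant bins.
#'
#' @param seed Integer seed.
#' @param n_loci Number of clusters.
#' @return List `(false_call_fraction, profile_sig_bin_fraction)`.
#' @export
experiment_null <- function(seed, n_loci = 500L) {
  cfg <- sim_config(seed = seed, n_loci = n_loci, promoter_only = TRUE,
                    snp_density = 0, indel_density = 0,
                    init_snp_prob = 0, pause_csnp_prob = 0,
                    pause_indel_prob = 0,
                    mean_tagged_per_tsc = 10, n_reps = 2L,
                    class_props = c(none = 1, abundance = 0, shape_single = 0,
                                    shape_multi = 0, termination = 0,
                                    imprinted = 0))
  ds <- simulate_dataset(cfg)
  c5 <- make_base_counts(ds$reads, "five_prime")
  tsc <- cluster_tsc(call_tss(c5, truth_regions_(ds$truth), 5L), 60L)
  ab <- tsc_abundance_test(tsc)
  frac <- mean(ab$significant, na.rm = TRUE)
  # profile on a null split: same genome with background SNPs, anchors
  # randomly halved into pseudo test/control sets
  cfg2 <- sim_config(seed = seed + 1000L, n_loci = 120L, promoter_only = TRUE,
                     init_snp_prob = 0, pause_csnp_prob = 0,
                     pause_indel_prob = 0,
                     class_props = c(none = 1, abundance = 0, shape_single = 0,
                                     shape_multi = 0, termination = 0,
                                     imprinted = 0))
  truth <- plant_truth(generate_genome_pair(cfg2), cfg2)
  tl <- truth$loci
  set.seed(seed + 2000L)
  half <- sample(c(TRUE, FALSE), nrow(tl), replace = TRUE)
  anchors <- data.frame(pos = tl$anchor, strand = tl$strand)
  pr <- snp_positional_profile(anchors[half, ], anchors[!half, ],
                               truth$genome, window = 50L)
  list(false_call_fraction = frac,
       profile_sig_bin_fraction = mean(pr$tests$significant, na.rm = TRUE))
}

#' Shape-classification experiment
#'
#' 150 clusters, 20% single-TSS (one TSS shifted 4-fold) and 20% multi-TSS
#' (three TSSs shifted 2-fold) planted changes; shape KS + masking
#' classifier; reports label accuracy among detected planted events.
#'
#' @param seed Integer seed.
#' @param n_loci Number of clusters.
#' @return List `(accuracy, n_detected, n_single, n_multi)`.
#' @export
experiment_shape <- function(seed, n_loci = 150L) {
  cfg <- sim_config(seed = seed, n_loci = n_loci, promoter_only = TRUE,
                    snp_density = 0, indel_density = 0,
                    init_snp_prob = 0, pause_csnp_prob = 0,
                    pause_indel_prob = 0,
                    mean_tagged_per_tsc = 30, n_reps = 2L,
                    class_props = c(none = 0.6, abundance = 0,
                                    shape_single = 0.2, shape_multi = 0.2,
                                    termination = 0, imprinted = 0))
  ds <- simulate_dataset(cfg)
  set.seed(seed + 500L)
  c5 <- make_base_counts(ds$reads, "five_prime")
  tsc <- cluster_tsc(call_tss(c5, truth_regions_(ds$truth), 5L), 60L)
  cl <- classify_shape_change(tsc, tsc_shape_test(tsc))
  truth <- ds$truth$loci$class[tsc$tsc$region_id[match(cl$tsc_id, tsc$tsc$tsc_id)]]
  det <- cl$class != "none" & truth %in% c("shape_single", "shape_multi")
  acc <- mean((cl$class[det] == "single") == (truth[det] == "shape_single"))
  list(accuracy = acc, n_detected = sum(det),
       n_single = sum(det & truth == "shape_single"),
       n_multi = sum(det & truth == "shape_multi"))
}

#' Initiator-hierarchy experiment
#'
#' Single-TSS promoters with planted initiator SNPs at weights
#' CA=1, TA=0.5, TG=0.25, CG=0.1; reports the recovered median log2
#' allelic-bias ratios per dinucleotide category.
#'
#' @param seed Integer seed.
#' @param n_loci Number of loci.
#' @return List `(medians, n_sites)`; medians named by category.
#' @export
experiment_hierarchy <- function(seed, n_loci = 250L) {
  cfg <- sim_config(seed = seed, n_loci = n_loci, promoter_only = TRUE,
                    mean_tagged_per_tsc = 40, n_reps = 2L,
                    init_snp_prob = 0.6, init_snp_n_tss = c(1L, 1L),
                    pause_csnp_prob = 0, pause_indel_prob = 0,
                    class_props = c(none = 1, abundance = 0, shape_single = 0,
                                    shape_multi = 0, termination = 0,
                                    imprinted = 0))
  ds <- simulate_dataset(cfg)
  c5 <- make_base_counts(ds$reads, "five_prime")
  tsc <- cluster_tsc(call_tss(c5, truth_regions_(ds$truth), 5L), 60L)
  h <- dinucleotide_hierarchy(tsc, c5, ds$genome)
  med <- tapply(h$sites$ratio, h$sites$category, stats::median)
  list(medians = med, n_sites = nrow(h$sites))
}

#' Block-recovery experiment at the HMM level
#'
#' Informative positions with binomial(5, 0.9) counts inside planted
#' blocks (>= 10 positions) and binomial(5, 0.5) outside; reports the
#' median Jaccard overlap between called and planted blocks.
#'
#' @param seed Integer seed.
#' @param n_rep Number of replicate instances.
#' @return List `(median_jaccard)`.
#' @export
experiment_hmm_recovery <- function(seed, n_rep = 20L) {
  set.seed(seed)
  jac <- replicate(n_rep, {
    n <- 300L
    p <- sort(sample.int(30000L, n))
    a1 <- rbinom(n, 5L, 0.5)
    lo <- sample(5000:15000, 1L); hi <- lo + 4000L
    inb <- p >= lo & p < hi
    a1[inb] <- rbinom(sum(inb), 5L, 0.9)
    pos <- data.frame(contig = "c", strand = "+", pos = p, a1 = a1,
                      a2 = 5L - a1)
    b <- hmm_call_blocks(pos, tau = 1e-4, rho = 0.9)
    b <- b[b$direction == "A1", , drop = FALSE]
    if (!nrow(b)) return(0)
    inter <- sum(pmax(0, pmin(b$end, hi) - pmax(b$start, lo)))
    inter / (max(b$end, hi) - min(b$start, lo))
  })
  list(median_jaccard = stats::median(jac))
}

#' Reciprocal-cross domain-classification experiment
#'
#' Full simulation with strain (4:1) and imprinted (4:1) loci; blocks are
#' called per organ x cross, intersected across reciprocal crosses, and
#' classified; reports per-locus recall and classification accuracy.
#'
#' @param seed Integer seed.
#' @param n_loci Number of loci.
#' @return List `(recall, accuracy)`.
#' @export
experiment_domains <- function(seed, n_loci = 40L) {
  cfg <- sim_config(seed = seed, n_loci = n_loci, gb_read_density = 25,
                    snp_density = 0, indel_density = 0,
                    init_snp_prob = 0, pause_csnp_prob = 0,
                    pause_indel_prob = 0,
                    mean_tagged_per_tsc = 15, abundance_ratio = 4,
                    imprint_ratio = 4,
                    unit_length_range = c(6000L, 10000L),
                    class_props = c(none = 0.4, abundance = 0.3,
                                    shape_single = 0, shape_multi = 0,
                                    termination = 0, imprinted = 0.3))
  ds <- simulate_dataset(cfg)
  dom <- merge_blocks_to_domains(ds$reads, tau = 1e-4, rho = 0.9)
  tl <- ds$truth$loci
  cl <- dom$classified
  biased <- tl[tl$class %in% c("abundance", "imprinted"), ]
  got <- vapply(seq_len(nrow(biased)), function(i) {
    lo <- pmin(biased$anchor[i], biased$end3_long[i])
    hi <- pmax(biased$anchor[i], biased$end3_long[i])
    ov <- cl[cl$strand == biased$strand[i] & cl$start < hi & cl$end > lo, ,
             drop = FALSE]
    if (!nrow(ov)) return(NA_character_)
    w <- pmin(ov$end, hi) - pmax(ov$start, lo)
    ov$class[which.max(w)]
  }, character(1))
  expect_cls <- ifelse(biased$class == "abundance", "strain_effect", "imprinted")
  list(recall = mean(!is.na(got)),
       accuracy = mean(got == expect_cls, na.rm = TRUE))
}

#' Pause-determinant experiment
#'
#' Promoters with planted active-site C SNPs and TSS-pause deletions at
#' deep single-base 3'-end coverage; runs the full maxTSS/maxPause
#' pipeline and reports: the fraction of combined maxPause sites whose
#' active-site base is C, the bubble G-content contrasts, the regression
#' slope of projected pause difference on indel length, and the C-SNP vs
#' indel distance comparison.
#'
#' @param seed Integer seed.
#' @param n_loci Number of loci.
#' @return List of summary statistics (see Details).
#' @export
experiment_pause <- function(seed, n_loci = 500L) {
  cfg <- sim_config(seed = seed, n_loci = n_loci, promoter_only = TRUE,
                    mean_tagged_per_tsc = 20, n_reps = 2L,
                    init_snp_prob = 0, pause_csnp_prob = 0.2,
                    pause_indel_prob = 0.2,
                    class_props = c(none = 1, abundance = 0, shape_single = 0,
                                    shape_multi = 0, termination = 0,
                                    imprinted = 0))
  ds <- simulate_dataset(cfg)
  regions <- truth_regions_(ds$truth)
  set.seed(seed + 700L)
  c5 <- make_base_counts(ds$reads, "five_prime")
  c3 <- make_base_counts(ds$reads, "three_prime")
  pairs <- pair_tss_pause(call_max_site(c5, regions, "A1"),
                          call_max_site(c5, regions, "A2"),
                          call_max_pause(c3, regions, "A1"),
                          call_max_pause(c3, regions, "A2"))
  sh <- pause_shape_test(c3, regions)
  sets <- same_tss_diff_pause_sets(pairs, sh)
  io <- indel_offset_analysis(sets$test, sets$control, ds$genome)
  mpa <- call_max_pause(c3, regions, "all")
  ctx <- pause_sequence_context(
    data.frame(pos = mpa$pos[mpa$ok], strand = mpa$strand[mpa$ok]), ds$genome)
  f0 <- ctx$freq[ctx$freq$offset == 0, ]
  ex <- classify_pause_explanations(sets$test, ds$genome)
  rec <- ex$records
  csnp <- rec$active_site_snp & !rec$indel_tss_to_pause
  indel <- rec$indel_tss_to_pause
  dist_p <- if (sum(csnp) >= 3 && sum(indel) >= 3) {
    stats::wilcox.test(rec$dist[csnp], rec$dist[indel],
                       alternative = "less", exact = FALSE)$p.value
  } else NA_real_
  list(n_test = nrow(sets$test), n_control = nrow(sets$control),
       modal_c_fraction = f0$C,
       modal_base_is_c = f0$C == max(f0$A, f0$C, f0$G, f0$T),
       g2_minus_g1 = mean(ctx$blocks$g2) - mean(ctx$blocks$g1),
       g2_minus_g3 = mean(ctx$blocks$g2) - mean(ctx$blocks$g3),
       g_block_p = max(ctx$tests$p[1:2]),
       n_context = ctx$n,
       indel_slope = io$slope,
       indel_fisher_p = io$fisher$p,
       fraction_explained = ex$fraction_explained,
       median_dist_csnp = stats::median(rec$dist[csnp]),
       median_dist_indel = stats::median(rec$dist[indel]),
       csnp_less_indel_p = dist_p)
}

#' Allelic-termination experiment
#'
#' Dense gene-body coverage over units with planted termination
#' extensions; calls blocks and AT windows and scores them against truth.
#'
#' @param seed Integer seed.
#' @param n_loci Number of loci.
#' @return List `(median_jaccard, long_allele_accuracy, rule_violations)`.
#' @export
experiment_termination <- function(seed, n_loci = 16L) {
  cfg <- sim_config(seed = seed, n_loci = n_loci, gb_read_density = 1000,
                    snp_density = 1 / 300, indel_density = 0,
                    init_snp_prob = 0, pause_csnp_prob = 0,
                    pause_indel_prob = 0,
                    mean_tagged_per_tsc = 20,
                    unit_length_range = c(6000L, 10000L),
                    class_props = c(none = 0.25, abundance = 0,
                                    shape_single = 0, shape_multi = 0,
                                    termination = 0.75, imprinted = 0))
  ds <- simulate_dataset(cfg)
  tl <- ds$truth$loci
  units <- truth_units_(ds$truth)
  c5 <- make_base_counts(ds$reads, "five_prime", cross = "A1xA2")
  pos <- c5[c5$a1 + c5$a2 > 0L, c("contig", "strand", "pos", "a1", "a2")]
  blocks <- hmm_call_blocks(pos, tau = 1e-4, rho = 0.9)
  aw <- call_at_windows(units, blocks)
  term <- tl[tl$class == "termination", ]
  jac <- vapply(seq_len(nrow(term)), function(i) {
    w <- aw[aw$gene == term$locus[i], , drop = FALSE]
    if (!nrow(w)) return(0)
    ts <- min(term$end3_short[i], term$end3_long[i])
    te <- max(term$end3_short[i], term$end3_long[i])
    inter <- max(0, min(w$end, te) - max(w$start, ts))
    inter / (max(w$end, te) - min(w$start, ts))
  }, numeric(1))
  la <- aw$long_allele == term$long_allele[match(aw$gene, term$locus)]
  viol <- sum(aw$window_length > 0.5 * aw$unit_length)
  list(median_jaccard = stats::median(jac),
       long_allele_accuracy = mean(la, na.rm = TRUE),
       rule_violations = viol, n_windows = nrow(aw),
       n_planted = nrow(term))
}

#' mRNA structure-flag and stability experiment
#'
#' Units with planted termination and primary-structure changes; mRNA
#' blocks are called from exon-level allelic counts and the structure flag
#' and stability coupling are scored.
#'
#' @param seed Integer seed.
#' @param n_loci Number of loci.
#' @return List `(flag_accuracy, stability_ks_p, n_records)`.
#' @export
experiment_stability <- function(seed, n_loci = 200L) {
  cfg <- sim_config(seed = seed, n_loci = n_loci, gb_read_density = 12,
                    snp_density = 0, indel_density = 0,
                    init_snp_prob = 0, pause_csnp_prob = 0,
                    pause_indel_prob = 0,
                    mean_tagged_per_tsc = 5, n_reps = 1L,
                    unit_length_range = c(6000L, 8000L),
                    class_props = c(none = 0.5, abundance = 0,
                                    shape_single = 0, shape_multi = 0,
                                    termination = 0.5, imprinted = 0))
  ds <- simulate_dataset(cfg)
  tl <- ds$truth$loci
  units <- truth_units_(ds$truth)
  # mRNA blocks from exon-level allelic counts (crosses pooled)
  mr <- ds$mrna
  mpos <- stats::aggregate(count ~ gene + exon_id + start + end + strand + allele,
                           mr, sum)
  wdf <- stats::reshape(mpos, idvar = c("gene", "exon_id", "start", "end",
                                        "strand"),
                        timevar = "allele", direction = "wide")
  pos <- data.frame(contig = tl$contig[1], strand = wdf$strand,
                    pos = as.integer((wdf$start + wdf$end) / 2),
                    a1 = wdf$count.A1, a2 = wdf$count.A2)
  mb <- hmm_call_blocks(pos, tau = 1e-4, rho = 0.9)
  term <- tl[tl$class == "termination", ]
  awt <- data.frame(gene = term$locus, contig = term$contig,
                    strand = term$strand,
                    start = pmin(term$end3_short, term$end3_long),
                    end = pmax(term$end3_short, term$end3_long) + 1L)
  fl <- flag_mrna_structure_change(awt, mb)
  flag_acc <- mean(fl == term$structure_change)
  # stability indices from nascent gene-body vs mRNA exon counts
  gb <- ds$reads[ds$reads$allele %in% c("A1", "A2"), ]
  nas <- do.call(rbind, lapply(seq_len(nrow(units)), function(i) {
    r <- gb[gb$strand == units$strand[i] &
              gb$five_prime >= units$start[i] &
              gb$five_prime < units$end[i], ]
    data.frame(gene = units$gene[i], a1 = sum(r$allele == "A1"),
               a2 = sum(r$allele == "A2"))
  }))
  mrg <- stats::aggregate(count ~ gene + allele, mr, sum)
  mg <- data.frame(gene = sort(unique(mrg$gene)))
  mg$a1 <- mrg$count[mrg$allele == "A1"][match(mg$gene, mrg$gene[mrg$allele == "A1"])]
  mg$a2 <- mrg$count[mrg$allele == "A2"][match(mg$gene, mrg$gene[mrg$allele == "A2"])]
  st <- stability_index(mg, nas, 10L)
  flagged <- tl$structure_change[match(st$gene, tl$locus)]
  ks <- ks_one_sided(st$stability_diff[flagged], st$stability_diff[!flagged])
  list(flag_accuracy = flag_acc, stability_ks_p = ks$p,
       n_records = nrow(st), n_flagged = sum(flagged))
}

# internal mirrors of the test helpers (regions/units from a truth set)
truth_regions_ <- function(truth) {
  tl <- truth$loci
  data.frame(contig = tl$contig, start = tl$tsr_start, end = tl$tsr_end,
             region_id = tl$locus)
}

truth_units_ <- function(truth) {
  tl <- truth$loci
  data.frame(gene = tl$locus, contig = tl$contig,
             start = pmin(tl$anchor, tl$end3_long),
             end = pmax(tl$anchor, tl$end3_long) + 1L,
             strand = tl$strand)
}
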