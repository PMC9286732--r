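# Initiation determinants: hierarchy categories, SNP profiles, AT content,
# PWM scoring, redistribution.

test_that("hierarchy sites are categorised and oriented by initiator strength", {
  # CA on allele1 (20 reads), TA on allele2 (10 reads): category CA_TA,
  # ratio log2(2) = 1
  s <- strsplit(paste(rep("G", 300), collapse = ""), "")[[1]]
  s[150:151] <- c("C", "A")
  gp <- toy_genome(paste(s, collapse = ""),
                   data.frame(pos1 = 149L, ref = "C", alt = "T", kind = "snp"))
  tsc_set <- structure(list(
    tsc = data.frame(tsc_id = 1L, contig = "chrT", strand = "+",
                     region_id = 1L, start = 150L, end = 151L, n_tss = 1L,
                     a1 = 20L, a2 = 10L, untagged = 0L, all = 30L,
                     max_count = 30L, maxtss_pos = 150L, n_maxtss = 1L),
    members = NULL), class = "tsc_set")
  counts <- data.frame(contig = "chrT", strand = "+", pos = 150L,
                       a1 = 20L, a2 = 10L, untagged = 0L, all = 30L)
  class(counts) <- c("site_counts", "data.frame")
  attr(counts, "end_type") <- "five_prime"
  h <- dinucleotide_hierarchy(tsc_set, counts, gp)
  expect_equal(nrow(h$sites), 1L)
  expect_equal(h$sites$category, "CA_TA")
  expect_equal(h$sites$ratio, 1)
  # identical initiators are excluded
  gp2 <- toy_genome(paste(s, collapse = ""))
  h2 <- dinucleotide_hierarchy(tsc_set, counts, gp2)
  expect_equal(nrow(h2$sites), 0L)
})

test_that("SNP profiles count planted offsets and control the null", {
  set.seed(18)
  s <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE), collapse = "")
  anchors <- data.frame(pos = seq(300, 3700, by = 200))
  anchors$strand <- rep(c("+", "-"), length.out = nrow(anchors))
  # one SNP exactly at every test anchor
  ref <- substring(s, anchors$pos + 1, anchors$pos + 1)
  alt <- ifelse(ref == "A", "C", "A")
  gp <- toy_genome(s, data.frame(pos1 = anchors$pos, ref = ref, alt = alt,
                                 kind = "snp"))
  test <- anchors[1:9, ]
  ctl <- anchors[10:18, ]
  ctl$pos <- ctl$pos + 57L              # controls have no SNP at offset 0
  r <- snp_positional_profile(test, ctl, gp, window = 50)
  b0 <- r$profile[r$profile$bin_start == 0, ]
  expect_gte(b0$mean_test, 1)
  t0 <- r$tests[r$tests$bin_start == 0, ]
  expect_true(t0$significant)
  # strand flip: a SNP 3 bp 5'-ward of a minus-strand anchor lands in [-5, 0)
  gpm <- toy_genome(s, data.frame(pos1 = 1003L, ref = substring(s, 1004, 1004),
                                  alt = "N", kind = "snp"))
  rm_ <- snp_positional_profile(data.frame(pos = 1000L, strand = "-"),
                                data.frame(pos = 2000L, strand = "-"),
                                gpm, window = 10, profile_bin = 5)
  bm <- rm_$profile[rm_$profile$bin_start == -5, ]
  expect_equal(bm$mean_test, 1)
  expect_error(snp_positional_profile(test, ctl[0, ], gp), "empty control")
})

test_that("base composition differences respect the initiator mask", {
  s <- paste(rep("G", 500), collapse = "")
  gp <- toy_genome(s, data.frame(pos1 = 250L, ref = "G", alt = "A", kind = "snp"))
  sites <- data.frame(pos = 250L, strand = "+", high = "A1")
  ctl <- data.frame(pos = 400L, strand = "+", high = "A1")
  r <- base_composition_and_at(sites, ctl, gp, window = 20)
  # the only difference sits at offset 0, which the AT mask removes
  expect_true(all(abs(r$at_windows$at_diff) < 1e-12, na.rm = TRUE))
  expect_equal(r$freq_diff$dG[r$freq_diff$offset == 0], 1)  # high G, low A
  # identical alleles: all differences zero
  gp0 <- toy_genome(s)
  r0 <- base_composition_and_at(sites, ctl, gp0, window = 20)
  expect_true(all(abs(unlist(r0$freq_diff[, -1])) < 1e-12))
})

test_that("PWM scoring matches a hand-computed log-likelihood ratio", {
  pwm <- list(id = "toy", mat = matrix(c(0.97, 0.01, 0.01, 0.01,
                                         0.01, 0.01, 0.01, 0.97), nrow = 2,
                                       byrow = TRUE,
                                       dimnames = list(NULL, c("A", "C", "G", "T"))))
  # near-uniform background estimated from a balanced sequence
  set.seed(30)
  bgseq <- paste(sample(rep(c("A", "C", "G", "T"), 2500)), collapse = "")
  bg <- allelicTx:::markov_background(bgseq)
  sc <- allelicTx:::pwm_max_score("GGATGG", pwm, bg)
  exp_sc <- log(0.97 / bg$p0[1]) + log(0.97 / bg$trans[1, 4])
  expect_equal(sc, unname(exp_sc), tolerance = 1e-9)
  # uniform PWM columns equal to background: scores hover at zero
  pwm0 <- list(id = "flat", mat = matrix(0.25, 4, 4,
                                         dimnames = list(NULL, c("A", "C", "G", "T"))))
  sc0 <- allelicTx:::pwm_max_score("ACGTACGT", pwm0, bg)
  expect_lt(abs(sc0), 0.2)
  # bundled PWMs load and have unit rows
  for (w in c("degenerate", "strict")) {
    p <- load_bundled_pwm(w)
    expect_true(all(abs(rowSums(p$mat) - 1) < 1e-6))
  }
})

test_that("TATA association returns the sentinel on degenerate inputs", {
  cfg <- sim_config(seed = 40, n_loci = 6, promoter_only = TRUE,
                    snp_density = 0, indel_density = 0)
  truth <- plant_truth(generate_genome_pair(cfg), cfg)
  tl <- truth$loci
  sites <- data.frame(pos = tl$anchor, strand = tl$strand, dusage = rnorm(nrow(tl)))
  r <- tata_association(sites, truth$genome, load_bundled_pwm("strict"))
  # identical alleles: dscore constant zero -> correlation undefined
  expect_true(is.na(r$r))
})

test_that("redistribution is confined to +/-20 bp of the disrupted initiator", {
  cfg <- sim_config(seed = 52, n_loci = 120, promoter_only = TRUE,
                    mean_tagged_per_tsc = 30, n_reps = 2,
                    init_snp_prob = 0.5, pause_csnp_prob = 0, pause_indel_prob = 0,
                    redistribute_initiation = TRUE,
                    class_props = c(none = 1, abundance = 0, shape_single = 0,
                                    shape_multi = 0, termination = 0, imprinted = 0))
  ds <- simulate_dataset(cfg)
  set.seed(7)
  c5 <- make_base_counts(ds$reads, "five_prime")
  tsc <- cluster_tsc(call_tss(c5, truth_regions(ds$truth), 5), 60)
  sg <- shooting_gallery(tsc, c5, NULL, ds$genome)
  expect_false(is.null(sg$near_test))
  # low allele gains signal at nearby initiators in the test set only
  expect_gt(sg$near_test$median_test, sg$near_test$median_control)
  expect_lt(sg$near_test$p, 0.01)
  # beyond +/-20 bp the two sets look alike
  if (!is.null(sg$wide_test)) expect_gt(sg$wide_test$p, 0.05)
})
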