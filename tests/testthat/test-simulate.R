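# Read-end and mRNA simulation.

test_that("allele tags conserve totals and zero tagging yields only untagged reads", {
  ds <- quick_dataset(seed = 2, n_loci = 10)
  expect_true(all(ds$reads$allele %in% c("A1", "A2", "untagged")))
  li <- factor(ds$reads$locus, levels = ds$truth$loci$locus)
  total <- table(li)
  tagged <- table(li[ds$reads$allele %in% c("A1", "A2")])
  untagged <- table(li[ds$reads$allele == "untagged"])
  expect_equal(as.integer(total), as.integer(tagged) + as.integer(untagged))

  cfg0 <- sim_config(seed = 2, n_loci = 5, promoter_only = TRUE, tagging_p = 0)
  ds0 <- simulate_dataset(cfg0)
  expect_true(all(ds0$reads$allele == "untagged"))
  # downstream allelic tests report the no-test sentinel
  c5 <- make_base_counts(ds0$reads, "five_prime")
  tsc <- cluster_tsc(call_tss(c5, truth_regions(ds0$truth), 5), 60)
  ab <- tsc_abundance_test(tsc)
  expect_true(all(is.na(ab$p)))
})

test_that("per-TSS read counts are Poisson with the planted mean", {
  # single TSS, known rate; many replicates via n_reps
  cfg <- sim_config(seed = 13, n_loci = 4, promoter_only = TRUE,
                    snp_density = 0, indel_density = 0, tagging_p = 1,
                    init_snp_prob = 0, pause_csnp_prob = 0, pause_indel_prob = 0,
                    n_reps = 250L,
                    class_props = c(none = 1, abundance = 0, shape_single = 0,
                                    shape_multi = 0, termination = 0, imprinted = 0))
  ds <- simulate_dataset(cfg)
  ts <- ds$truth$tss
  depth_mu <- with(ds$truth, {
    locus_tot <- tapply((tss$rate_a1 + tss$rate_a2) * loci$expr[tss$locus],
                        tss$locus, sum)
    cfg$mean_tagged_per_tsc / (cfg$tagging_p * mean(locus_tot))
  })
  k <- which(ts$is_max)[1]
  mu <- ts$rate_a1[k] * ds$truth$loci$expr[ts$locus[k]] * depth_mu
  obs <- ds$reads[ds$reads$five_prime == ts$pos1[k] &
                    ds$reads$source_allele == "A1" &
                    ds$reads$cross == "A1xA2" &
                    ds$reads$source == "promoter", ]
  counts <- tabulate(obs$replicate, nbins = 250L)
  se <- sqrt(mu / 250)
  expect_lt(abs(mean(counts) - mu), 3 * se)
  # Poisson variance of the same magnitude as the mean
  expect_lt(abs(var(counts) - mu), 5 * mu / sqrt(250))
})

test_that("read tables are deterministic and strand-consistent", {
  d1 <- quick_dataset(seed = 3, n_loci = 6)
  d2 <- quick_dataset(seed = 3, n_loci = 6)
  expect_identical(d1$reads, d2$reads)
  plus <- d1$reads$strand == "+"
  expect_true(all(d1$reads$five_prime[plus] <= d1$reads$three_prime[plus]))
  expect_true(all(d1$reads$five_prime[!plus] >= d1$reads$three_prime[!plus]))
})

test_that("mRNA counts follow transcription, stability and structure truth", {
  cfg <- sim_config(seed = 17, n_loci = 60, gb_read_density = 0,
                    snp_density = 0, indel_density = 0,
                    init_snp_prob = 0, pause_csnp_prob = 0, pause_indel_prob = 0,
                    structure_change_prob = 1, stability_base_sd = 0,
                    stability_coupling_sd = 0,
                    class_props = c(none = 0.5, abundance = 0.25, shape_single = 0,
                                    shape_multi = 0, termination = 0.25, imprinted = 0))
  truth <- plant_truth(generate_genome_pair(cfg), cfg)
  mr <- simulate_mrna_counts(truth, cfg)
  tl <- truth$loci
  # equal stability: expected mRNA allelic ratio equals the transcription ratio
  ab <- tl$locus[tl$class == "abundance"]
  agg <- aggregate(count ~ gene + allele, mr[mr$gene %in% ab & !mr$novel, ], sum)
  hi <- ifelse(tl$biased_allele[ab] == "A1", "A1", "A2")
  r <- vapply(seq_along(ab), function(i) {
    a <- agg$count[agg$gene == ab[i] & agg$allele == hi[i]]
    b <- agg$count[agg$gene == ab[i] & agg$allele != hi[i]]
    a / b
  }, numeric(1))
  expect_lt(abs(mean(r) - cfg$abundance_ratio), 0.4)
  # novel exons emit zero counts on the short allele
  nov <- mr[mr$novel, ]
  expect_gt(nrow(nov), 0)
  short <- ifelse(tl$long_allele[nov$gene] == "A1", "A2", "A1")
  expect_true(all(nov$count[nov$allele == short] == 0))
  expect_gt(sum(nov$count[nov$allele != short]), 0)
})

test_that("a doubled stability multiplier doubles the expected mRNA ratio", {
  cfg <- sim_config(seed = 19, n_loci = 40, promoter_only = TRUE,
                    snp_density = 0, indel_density = 0,
                    init_snp_prob = 0, pause_csnp_prob = 0, pause_indel_prob = 0,
                    class_props = c(none = 1, abundance = 0, shape_single = 0,
                                    shape_multi = 0, termination = 0, imprinted = 0))
  truth <- plant_truth(generate_genome_pair(cfg), cfg)
  truth$loci$stab_a1 <- 2
  truth$loci$stab_a2 <- 1
  mr <- simulate_mrna_counts(truth, cfg)
  agg <- aggregate(count ~ allele, mr, sum)
  ratio <- agg$count[agg$allele == "A1"] / agg$count[agg$allele == "A2"]
  expect_lt(abs(ratio - 2), 0.15)
})
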