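# Planted truth: geometry invariants, rate law, pause energy rule.

test_that("planted loci respect the geometric invariants", {
  cfg <- sim_config(seed = 5, n_loci = 30, promoter_only = FALSE)
  truth <- plant_truth(generate_genome_pair(cfg), cfg)
  tl <- truth$loci
  ts <- truth$tss
  # every planted TSS inside its locus TSR
  expect_true(all(ts$pos1 >= tl$tsr_start[ts$locus] &
                    ts$pos1 < tl$tsr_end[ts$locus]))
  # pause offsets within the search window on both alleles
  expect_true(all(tl$pause_off1 >= 20 & tl$pause_off1 <= 60))
  expect_true(all(tl$pause_off2 >= 20 & tl$pause_off2 <= 60))
  # termination extension at most 50% of unit length
  term <- tl[tl$class == "termination", ]
  expect_true(all(term$ext <= 0.5 * term$unit_len))
  expect_true(all(abs(tl$end3_long - tl$end3_short) == tl$ext))
})

test_that("equal initiator weights and zero AT coefficient give allele-equal rates", {
  cfg <- sim_config(seed = 6, n_loci = 10, promoter_only = TRUE,
                    snp_density = 0, indel_density = 0,
                    init_snp_prob = 0, pause_csnp_prob = 0, pause_indel_prob = 0,
                    init_weights = c(CA = 1, TA = 1, TG = 1, CG = 1),
                    at_alpha = 0,
                    class_props = c(none = 1, abundance = 0, shape_single = 0,
                                    shape_multi = 0, termination = 0, imprinted = 0))
  truth <- plant_truth(generate_genome_pair(cfg), cfg)
  expect_equal(truth$tss$rate_a1, truth$tss$rate_a2)
  # all TSSs share the same weight so rates reduce to the base rate
  expect_equal(truth$tss$rate_a1, truth$tss$base_rate)
})

test_that("an initiator CA->CG SNP scales the allelic rate by w_CA/w_CG", {
  seq1 <- paste(rep("T", 400), collapse = "")
  s <- strsplit(seq1, "")[[1]]
  s[200:201] <- c("C", "A")                    # CA initiator at 0-based TSS 200
  gp <- toy_genome(paste(s, collapse = ""),
                   data.frame(pos1 = 200L, ref = "A", alt = "G", kind = "snp"))
  cfg <- sim_config(seed = 1, n_loci = 1, promoter_only = TRUE, at_alpha = 0)
  r1 <- allelicTx:::tss_rate_on_allele(gp, "A1", 200L, "+", cfg)
  r2 <- allelicTx:::tss_rate_on_allele(gp, "A2", 200L, "+", cfg)
  expect_equal(r1 / r2, cfg$init_weights[["CA"]] / cfg$init_weights[["CG"]])
})

test_that("pause positions match a brute-force energy argmax, including with an indel", {
  cfg <- sim_config(seed = 23, n_loci = 20, promoter_only = TRUE,
                    pause_csnp_prob = 0.3, pause_indel_prob = 0.3,
                    init_snp_prob = 0,
                    class_props = c(none = 1, abundance = 0, shape_single = 0,
                                    shape_multi = 0, termination = 0, imprinted = 0))
  truth <- plant_truth(generate_genome_pair(cfg), cfg)
  gp <- truth$genome
  tl <- truth$loci
  # independent per-offset oracle (loops, no cumsums)
  oracle <- function(seq, tss, strand, d0) {
    best_e <- -Inf; best_o <- NA
    for (o in 20:60) {
      b <- allelicTx:::oriented_window(seq, allelicTx:::offset_pos(tss, o, strand),
                                       strand, 0L, 0L)
      up <- allelicTx:::oriented_window(seq, tss, strand, o - 10L, o - 1L)
      ng <- sum(strsplit(up, "")[[1]] == "G")
      e <- cfg$pause_w_c * (b == "C") + cfg$pause_w_g * ng -
        cfg$pause_w_d * abs(o - d0)
      if (e > best_e) { best_e <- e; best_o <- o }
    }
    best_o
  }
  for (i in seq_len(nrow(tl))) {
    expect_identical(tl$pause_off1[i],
                     oracle(gp$seq1, tl$anchor[i], tl$strand[i], tl$d0[i]))
    expect_identical(tl$pause_off2[i],
                     oracle(gp$seq2, tl$anchor2[i], tl$strand[i], tl$d0[i]))
  }
  # planted deletions reproduce as projected pause differences of equal size
  ind <- tl[tl$pause_variant == "indel", ]
  expect_gt(nrow(ind), 0)
  expect_true(all(abs(ind$pause2_proj - ind$pause1) == ind$indel_len))
  # truth records both allele-local pause coordinates
  expect_true(all(!is.na(ind$pause2_local)))
})

test_that("planting is deterministic given (seed, config)", {
  cfg <- sim_config(seed = 8, n_loci = 8, promoter_only = TRUE)
  t1 <- plant_truth(generate_genome_pair(cfg), cfg)
  t2 <- plant_truth(generate_genome_pair(cfg), cfg)
  expect_identical(t1, t2)
})
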