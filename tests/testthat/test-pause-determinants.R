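# Pause determinants: set construction, explanations, context, distances.

test_that("pause test/control sets apply read and q filters", {
  pairs <- data.frame(region_id = 1:5, strand = "+",
                      tss_a1 = 100L, tss_a2 = 100L,
                      pause_a1 = c(140L, 140L, 140L, 140L, 140L),
                      pause_a2 = c(143L, 143L, 140L, 143L, 140L),
                      tss_n_a1 = 20L, tss_n_a2 = 20L,
                      pause_n_a1 = c(10L, 30L, 10L, 10L, 10L),
                      pause_n_a2 = c(10L, 10L, 10L, 10L, 12L),
                      dist_a1 = 40L, dist_a2 = c(43L, 43L, 40L, 43L, 40L),
                      valid = TRUE)
  shape <- data.frame(region_id = 1:5, strand = "+",
                      q = c(0.05, 0.05, 0.05, 0.5, 0.95))
  s <- same_tss_diff_pause_sets(pairs, shape)
  expect_equal(s$test$region_id, 1L)     # 2 fails ratio 3; 3 same pause; 4 mid-q
  expect_equal(s$control$region_id, 5L)  # q > 0.9 and identical maxPause
  expect_equal(s$test$short_allele, "A1")
  expect_equal(s$test$dist, 3L)
})

test_that("explanation tagging is a deterministic partition", {
  s <- paste(rep("A", 1000), collapse = "")
  gp <- toy_genome(s, data.frame(
    pos1 = c(140L, 200L, 310L),
    ref = c("A", "AAAA", "A"), alt = c("G", "A", "C"),
    kind = c("snp", "deletion", "snp")))
  recs <- data.frame(region_id = 1:3, strand = "+", tss = c(100L, 180L, 500L),
                     short_allele = "A1", long_allele = "A2",
                     short_pause = c(140L, 215L, 540L),
                     long_pause = c(145L, 220L, 545L), dist = 5L)
  ex <- classify_pause_explanations(recs, gp)
  expect_equal(ex$records$explanation,
               c("active_site_snp", "indel_tss_to_pause", "unexplained"))
  expect_equal(sum(ex$fractions$Freq), 1)
  ex2 <- classify_pause_explanations(recs, gp)
  expect_identical(ex$records, ex2$records)
  expect_equal(ex$fraction_explained, 2 / 3)
})

test_that("pause sequence context recovers a planted G-run / C-site", {
  s <- strsplit(paste(rep("T", 600), collapse = ""), "")[[1]]
  s[291:300] <- "G"   # 10 bp G-run at offsets -10..-1 of pause at 300
  s[301] <- "C"
  gp <- toy_genome(paste(s, collapse = ""))
  ctx <- pause_sequence_context(data.frame(pos = 300L, strand = "+"), gp)
  expect_equal(ctx$freq$C[ctx$freq$offset == 0], 1)
  expect_equal(ctx$blocks$g2, 1)
  expect_equal(ctx$blocks$g1, 0)
  expect_equal(ctx$blocks$g3, 0)
})

test_that("distance comparisons return the KS contrast and sentinels", {
  recs <- data.frame(dist = c(3, 5, 20, 30, 40))
  r <- pause_distance_comparisons(recs, list(full = rep(TRUE, 5),
                                             small = c(TRUE, TRUE, FALSE, FALSE, FALSE)))
  expect_true(is.na(r$p[r$subset == "full"]))   # empty complement -> sentinel
  sm <- r[r$subset == "small", ]
  expect_equal(sm$median_subset, 4)
  expect_equal(sm$median_rest, 30)
  # small-n KS agrees with direct enumeration over splits
  x <- c(3, 5); y <- c(20, 30, 40)
  pooled <- c(x, y)
  sp <- combn(5, 2)
  d0 <- oracle_ks_d(x, y)
  ds <- apply(sp, 2, function(i) oracle_ks_d(pooled[i], pooled[-i]))
  p_oracle <- mean(ds >= d0 - 1e-12)
  kk <- ks_two_sample(x, y, min_obs = 1L, method = "exact")
  expect_equal(kk$p, p_oracle, tolerance = 1e-12)
})

test_that("under-covered regions are skipped by the pause shape test", {
  reads <- data.frame(contig = "c", five_prime = 100L,
                      three_prime = rep(c(140L, 141L), c(8L, 4L)),
                      strand = "+", allele = rep(c("A1", "A2"), c(8L, 4L)),
                      organ = "o", cross = "A1xA2", replicate = 1L)
  c3 <- make_base_counts(reads, "three_prime")
  regions <- data.frame(contig = "c", start = 0L, end = 400L, region_id = 1L)
  set.seed(2)
  r <- pause_shape_test(c3, regions)
  expect_false(r$eligible)   # 4 reads on allele2 is below the floor
})
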