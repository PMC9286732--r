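# Base counts, TSS calling, clustering, TSR grouping, maxPause, pairing.

mk_reads <- function(five, three, strand, allele, contig = "c") {
  data.frame(contig = contig, five_prime = five, three_prime = three,
             strand = strand, allele = allele, organ = "o", cross = "A1xA2",
             replicate = 1L, stringsAsFactors = FALSE)
}

test_that("base counts are strand-aware and partition by allele class", {
  reads <- mk_reads(c(100L, 100L, 100L, 200L), c(140L, 140L, 140L, 160L),
                    c("+", "+", "-", "+"), c("A1", "untagged", "A1", "A2"))
  c5 <- make_base_counts(reads, "five_prime")
  plus100 <- c5[c5$strand == "+" & c5$pos == 100L, ]
  expect_equal(plus100$all, 2L)        # mixed strands not pooled
  expect_equal(plus100$a1, 1L)
  expect_equal(plus100$untagged, 1L)
  expect_true(all(c5$all == c5$a1 + c5$a2 + c5$untagged))
  c3 <- make_base_counts(reads, "three_prime")
  expect_equal(sum(c3$all), 4L)
  expect_equal(attr(c3, "end_type"), "three_prime")
})

test_that("TSS calling applies the 5-read floor within candidate regions", {
  reads <- mk_reads(rep(c(50L, 60L, 300L), c(5L, 4L, 5L)), rep(90L, 14L),
                    "+", "untagged")
  c5 <- make_base_counts(reads, "five_prime")
  regions <- data.frame(contig = "c", start = 0L, end = 200L, region_id = 1L)
  tss <- call_tss(c5, regions, min_reads = 5L)
  expect_equal(tss$pos, 50L)           # 60 has 4 reads; 300 outside the region
  tss1 <- call_tss(c5, regions, min_reads = 1L)
  expect_setequal(tss1$pos, c(50L, 60L))
  expect_warning(out <- call_tss(c5, regions[0, ], 5L), "no candidate regions")
  expect_equal(nrow(out), 0L)
})

test_that("clustering chains TSSs within the merge gap and keeps maxTSS ties", {
  tss <- data.frame(contig = "c", strand = "+", pos = c(100L, 130L, 200L),
                    a1 = 0L, a2 = 0L, untagged = c(7L, 7L, 3L),
                    all = c(7L, 7L, 3L), region_id = 1L)
  ts <- cluster_tsc(tss, merge_gap = 60L)
  expect_equal(nrow(ts$tsc), 2L)       # 30 <= 60 < 70
  first <- ts$tsc[ts$tsc$start == 100L, ]
  expect_equal(first$n_maxtss, 2L)     # both at count 7 retained
  expect_equal(first$maxtss_pos, 100L) # 5'-most deterministic representative
  single <- ts$tsc[ts$tsc$start == 200L, ]
  expect_equal(single$n_tss, 1L)
  expect_equal(single$maxtss_pos, 200L)
})

test_that("clustering is permutation-invariant and idempotent", {
  set.seed(3)
  tss <- data.frame(contig = "c", strand = "+",
                    pos = sort(sample(1:2000, 40)), a1 = 1L, a2 = 1L,
                    untagged = 3L, all = 5L, region_id = 1L)
  t1 <- cluster_tsc(tss, 60L)
  t2 <- cluster_tsc(tss[sample(nrow(tss)), ], 60L)
  expect_equal(t1$tsc[, c("start", "end", "n_tss")],
               t2$tsc[, c("start", "end", "n_tss")])
  # re-clustering the member table reproduces the same clusters
  t3 <- cluster_tsc(t1$members[, names(tss)], 60L)
  expect_equal(t1$tsc$start, t3$tsc$start)
})

test_that("TSR grouping keeps strands separate and demands a region", {
  tss <- data.frame(contig = "c", strand = c("+", "+", "-"),
                    pos = c(100L, 300L, 150L), a1 = 0L, a2 = 0L,
                    untagged = 5L, all = 5L, region_id = 1L)
  ts <- cluster_tsc(tss, 60L)
  regions <- data.frame(contig = "c", start = 0L, end = 400L, region_id = 1L)
  tsr <- assign_tsr(ts, regions)
  expect_equal(nrow(tsr), 2L)          # one per strand
  expect_equal(tsr$n_tsc[tsr$strand == "+"], 2L)
})

test_that("maxPause is the allelic mode with 5'-most tie-break and a read floor", {
  reads <- mk_reads(rep(100L, 11L), rep(c(140L, 141L), c(9L, 2L)), "+", "A1")
  c3 <- make_base_counts(reads, "three_prime")
  regions <- data.frame(contig = "c", start = 0L, end = 400L, region_id = 1L)
  mp <- call_max_pause(c3, regions, "A1")
  expect_equal(mp$pos, 140L)
  # tie -> 5'-most (strand-aware)
  tie <- mk_reads(rep(100L, 10L), rep(c(140L, 145L), each = 5L), "+", "A1")
  mp <- call_max_pause(make_base_counts(tie, "three_prime"), regions, "A1")
  expect_equal(mp$pos, 140L)
  tie_m <- mk_reads(rep(300L, 10L), rep(c(240L, 245L), each = 5L), "-", "A1")
  mp <- call_max_pause(make_base_counts(tie_m, "three_prime"), regions, "A1")
  expect_equal(mp$pos, 245L)           # 5'-most on the minus strand
  # 4 reads -> insufficient
  few <- mk_reads(rep(100L, 4L), rep(140L, 4L), "+", "A1")
  mp <- call_max_pause(make_base_counts(few, "three_prime"), regions, "A1")
  expect_false(mp$ok)
  expect_true(is.na(mp$pos))
})

test_that("TSS-pause pairing applies the 10-50 bp window strand-aware", {
  mk <- function(pos, strand = "+") data.frame(region_id = 1L, strand = strand,
                                               pos = pos, n = 10L, ok = TRUE)
  p <- pair_tss_pause(mk(100L), mk(100L), mk(140L), mk(140L))
  expect_true(p$valid)
  expect_equal(p$dist_a1, 40L)
  p <- pair_tss_pause(mk(100L), mk(100L), mk(160L), mk(140L))
  expect_false(p$valid)                # 60 bp on allele1
  p <- pair_tss_pause(mk(200L, "-"), mk(200L, "-"), mk(170L, "-"), mk(170L, "-"))
  expect_true(p$valid)
  expect_equal(p$dist_a1, 30L)
})
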