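# Allelic termination windows, structure flags, stability, group tests.

test_that("AT windows apply the start, end and length rules", {
  units <- data.frame(gene = "g1", contig = "c", start = 0L, end = 10000L,
                      strand = "+")
  # qualifying block: starts inside, ends past the unit, window 4000 <= 5000
  b <- data.frame(contig = "c", strand = "+", start = 6000L, end = 12000L,
                  direction = "A1", a1 = 50L, a2 = 5L, n_pos = 20L, p = 1e-9)
  w <- call_at_windows(units, b)
  expect_equal(nrow(w), 1L)
  expect_equal(c(w$start, w$end), c(6000L, 10000L))
  expect_equal(w$long_allele, "A1")
  expect_equal(w$window_length, 4000L)
  # end rule: block ending at 40% of the unit is rejected
  b2 <- transform(b, start = 2000L, end = 4000L)
  expect_equal(nrow(call_at_windows(units, b2)), 0L)
  # length cap: window longer than half the unit is rejected
  b3 <- transform(b, start = 3000L, end = 12000L)
  expect_equal(nrow(call_at_windows(units, b3)), 0L)
  # minus strand: the same geometry mirrored
  units_m <- data.frame(gene = "g2", contig = "c", start = 0L, end = 10000L,
                        strand = "-")
  b_m <- data.frame(contig = "c", strand = "-", start = -2000L, end = 4000L,
                    direction = "A2", a1 = 5L, a2 = 50L, n_pos = 20L, p = 1e-9)
  w_m <- call_at_windows(units_m, b_m)
  expect_equal(nrow(w_m), 1L)
  expect_equal(c(w_m$start, w_m$end), c(0L, 4000L))
  # every emitted window satisfies the rules by construction
  expect_true(all(w_m$window_length <= 0.5 * w_m$unit_length))
})

test_that("structure-change flags use the strand-aware 10 kb upstream window", {
  aw <- data.frame(gene = "g1", contig = "c", strand = "+",
                   start = 50000L, end = 54000L)
  near <- data.frame(contig = "c", strand = "+", start = 47000L, end = 48500L)
  far <- data.frame(contig = "c", strand = "+", start = 30000L, end = 35000L)
  expect_true(flag_mrna_structure_change(aw, near))
  expect_false(flag_mrna_structure_change(aw, far))
  expect_false(flag_mrna_structure_change(aw, near[0, ]))
  # on the minus strand, upstream means higher coordinates
  aw_m <- transform(aw, strand = "-")
  near_m <- data.frame(contig = "c", strand = "-", start = 56000L, end = 57000L)
  expect_true(flag_mrna_structure_change(aw_m, near_m))
  expect_false(flag_mrna_structure_change(aw_m, transform(near_m, start = 70000L,
                                                          end = 71000L)))
})

test_that("stability indices apply the 10-read floor and flag zero mRNA", {
  mr <- data.frame(gene = c("g1", "g2", "g3"), a1 = c(100L, 50L, 0L),
                   a2 = c(100L, 50L, 40L))
  na <- data.frame(gene = c("g1", "g2", "g3"), a1 = c(50L, 9L, 20L),
                   a2 = c(50L, 50L, 20L))
  st <- stability_index(mr, na, min_reads = 10L)
  expect_setequal(st$gene, c("g1", "g3"))   # g2 filtered (9 < 10)
  g1 <- st[st$gene == "g1", ]
  expect_equal(g1$stab_a1, 2)
  expect_equal(g1$stability_diff, 0)
  g3 <- st[st$gene == "g3", ]
  expect_true(g3$zero_mrna)
  expect_true(is.na(g3$stability_diff))
})

test_that("group comparisons detect planted coupling and stay null on identical groups", {
  set.seed(12)
  same <- abs(rnorm(80, 0, 0.2))
  gc <- group_comparisons(flag_at = rep(c(TRUE, FALSE), 20),
                          flag_noat = rep(c(TRUE, FALSE), 20),
                          stab_flagged = same, stab_unflagged = same)
  expect_gt(gc$stability_ks$p, 0.5)
  expect_gt(gc$structure_fisher$p, 0.9)
  # planted coupling: flagged differences stochastically larger
  gc2 <- group_comparisons(flag_at = rep(TRUE, 30), flag_noat = rep(FALSE, 30),
                           stab_flagged = abs(rnorm(60, 0, 0.8)),
                           stab_unflagged = abs(rnorm(140, 0, 0.15)))
  expect_lt(gc2$stability_ks$p, 0.01)
  expect_lt(gc2$structure_fisher$p, 1e-6)
  # adjacency: early-terminating allele carries the neighbour's high expression
  adj <- data.frame(early_allele = rep(c("A1", "A2"), each = 20),
                    adj_high_allele = c(rep("A1", 18), rep("A2", 2),
                                        rep("A2", 17), rep("A1", 3)),
                    opposite_strand = rep(c(TRUE, FALSE), 20))
  gc3 <- group_comparisons(logical(0), logical(0), numeric(0), numeric(0),
                           adjacency = adj)
  expect_gt(gc3$adjacency_fisher$odds_ratio, 1)
  expect_lt(gc3$adjacency_fisher$p, 1e-4)
  expect_false(is.na(gc3$adjacency_fisher_opposite$p))
})
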