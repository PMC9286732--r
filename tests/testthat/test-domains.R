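# Domain merging across reciprocal crosses, gene states, adjacency, counting.

# build a read table with an allelic block; direction can flip with cross
block_reads <- function(cross, rep, bias_allele, n_pos = 30, depth = 6,
                        organ = "o1") {
  pos <- seq(1000, by = 50, length.out = n_pos)
  a1 <- if (bias_allele == "A1") rbinom(n_pos, depth, 0.9)
        else rbinom(n_pos, depth, 0.1)
  reads <- do.call(rbind, lapply(seq_len(n_pos), function(i) {
    k1 <- a1[i]; k2 <- depth - a1[i]
    data.frame(contig = "c", five_prime = pos[i], three_prime = pos[i] + 40L,
               strand = "+", allele = rep(c("A1", "A2"), c(k1, k2)),
               organ = organ, cross = cross, replicate = rep)
  }))
  # balanced flanks so the chain starts and ends balanced
  flank <- do.call(rbind, lapply(c(seq(100, 900, 100), seq(2600, 3400, 100)), function(p) {
    data.frame(contig = "c", five_prime = p, three_prime = p + 40L,
               strand = "+", allele = rep(c("A1", "A2"), each = 3),
               organ = organ, cross = cross, replicate = rep)
  }))
  rbind(reads, flank)
}

test_that("strain-effect and imprinted domains are classified by cross logic", {
  set.seed(4)
  strain <- rbind(block_reads("A1xA2", 1L, "A1"), block_reads("A1xA2", 2L, "A1"),
                  block_reads("A2xA1", 1L, "A1"), block_reads("A2xA1", 2L, "A1"))
  res <- merge_blocks_to_domains(strain, tau = 1e-4)
  expect_true(nrow(res$domains) >= 1L)
  expect_true(all(res$domains$class == "strain_effect"))
  expect_true(all(res$domains$direction == "A1"))

  imprint <- rbind(block_reads("A1xA2", 1L, "A1"), block_reads("A1xA2", 2L, "A1"),
                   block_reads("A2xA1", 1L, "A2"), block_reads("A2xA1", 2L, "A2"))
  res <- merge_blocks_to_domains(imprint, tau = 1e-4)
  expect_true(all(res$domains$class == "imprinted"))
  expect_true(all(res$domains$direction == "maternal"))
})

test_that("blocks with opposite directions between replicates are dropped", {
  set.seed(5)
  reads <- rbind(block_reads("A1xA2", 1L, "A1"), block_reads("A1xA2", 2L, "A2"),
                 block_reads("A2xA1", 1L, "A1"), block_reads("A2xA1", 2L, "A2"))
  res <- merge_blocks_to_domains(reads, tau = 1e-4)
  expect_equal(nrow(res$domains), 0L)
})

test_that("a single cross direction is an error", {
  set.seed(6)
  expect_error(merge_blocks_to_domains(block_reads("A1xA2", 1L, "A1")),
               "reciprocal")
})

test_that("gene allelic state follows the reciprocal-cross direction logic", {
  gc <- data.frame(gene = rep(c("g1", "g2", "g3"), each = 2),
                   cross = rep(c("A1xA2", "A2xA1"), 3),
                   a1 = c(80L, 80L, 80L, 20L, 55L, 45L),
                   a2 = c(20L, 20L, 20L, 80L, 45L, 55L))
  st <- classify_gene_allelic_state(gc, fdr = 0.10)
  expect_equal(st$state[st$gene == "g1"], "strain")
  expect_equal(st$state[st$gene == "g2"], "imprinted")
  expect_equal(st$state[st$gene == "g3"], "none")
})

test_that("adjacency sharing uses the 2x2 Fisher construction", {
  # two interleaved blocks of allele-specific genes -> neighbours share state
  set.seed(8)
  n <- 40
  g <- data.frame(gene = paste0("g", 1:n), contig = "c",
                  start = seq(0, by = 1000, length.out = n))
  g$end <- g$start + 500L
  g$q <- rep(c(0.01, 0.99), each = n / 2)
  r <- adjacency_sharing_test(g)
  expect_gt(r$odds_ratio, 1)
  expect_lt(r$p, 0.01)
  # under independence the odds ratio hovers around 1
  ors <- replicate(20, {
    g$q <- sample(rep(c(0.01, 0.99), each = n / 2))
    adjacency_sharing_test(g)$odds_ratio
  })
  expect_lt(abs(median(log(ors[is.finite(ors) & ors > 0]))), 1.5)
  # degenerate stratum -> sentinel
  g$q <- rep(0.01, n)
  expect_true(is.na(adjacency_sharing_test(g)$p))
})

test_that("genes per domain merge same-strand overlapping and bookended units", {
  domains <- data.frame(contig = "c", strand = "+", start = 0L, end = 1000L)
  ann <- data.frame(contig = "c", start = c(100L, 150L), end = c(200L, 300L),
                    strand = "+")
  expect_equal(count_genes_per_domain(domains, ann), 1L)   # overlap
  ann <- data.frame(contig = "c", start = c(100L, 200L), end = c(200L, 300L),
                    strand = "+")
  expect_equal(count_genes_per_domain(domains, ann), 1L)   # bookended
  ann$strand <- c("+", "-")
  domains$strand <- "."
  expect_equal(count_genes_per_domain(domains, ann), 2L)   # opposite strands
})
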