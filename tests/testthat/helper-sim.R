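# Shared fixtures: all synthetic, built in code at test time.

# candidate-region table from a truth set
truth_regions <- function(truth) {
  tl <- truth$loci
  data.frame(contig = tl$contig, start = tl$tsr_start, end = tl$tsr_end,
             region_id = tl$locus)
}

# transcription-unit annotation (long-allele extent) from a truth set
truth_units <- function(truth) {
  tl <- truth$loci
  data.frame(gene = tl$locus, contig = tl$contig,
             start = pmin(tl$anchor, tl$end3_long),
             end = pmax(tl$anchor, tl$end3_long) + 1L,
             strand = tl$strand)
}

# small promoter-focused dataset for pipeline tests
quick_dataset <- function(seed = 1, n_loci = 40, ...) {
  cfg <- sim_config(seed = seed, n_loci = n_loci, promoter_only = TRUE,
                    mean_tagged_per_tsc = 25, ...)
  simulate_dataset(cfg)
}

# independent weighted-ECDF D oracle (kept separate from the package code)
oracle_ks_d <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(fx - fy))
}

# a minimal hand-built genome pair
toy_genome <- function(seq1, variants = NULL) {
  if (is.null(variants)) {
    variants <- data.frame(pos1 = integer(), ref = character(),
                           alt = character(), kind = character())
  }
  allelicTx:::new_genome_pair("chrT", seq1, variants)
}
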