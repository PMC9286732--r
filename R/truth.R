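# Planting transcription-cycle truth on a diploid genome.
#
# Each locus gets: a candidate regulatory region (TSR), 1-5 TSSs within a
# 60 bp cluster whose initiator dinucleotides are written into allele1, a
# pause box (G-rich stretch followed by a C-run) 20-60 bp downstream of the
# maxTSS, a transcription unit with optional allelic termination extension,
# exons, and an effect class. Sequence-level effects (initiator SNPs,
# active-site C SNPs, TSS-pause deletions) are injected as variants on
# class-"none" loci. Per-TSS initiation rates and per-allele pause positions
# are then derived from each haplotype's own final sequence, so background
# variants that happen to hit functional positions behave exactly like
# planted ones.

YR_DINUCS <- c("CA", "TA", "TG", "CG")

# sample() guard: a length-1 x must be returned as-is, not treated as 1:x
safe_sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# energy of a candidate pause at strand-aware offset o downstream of a local
# TSS: reward for a C at the active site and for G content in the 10 bp
# upstream (the transcription bubble), minus a tether penalty that grows
# with deviation from the preferred PIC distance d0.
pause_energy <- function(seq, tss_local, strand, offsets, d0, cfg) {
  vapply(offsets, function(o) {
    b <- oriented_window(seq, offset_pos(tss_local, o, strand), strand, 0L, 0L)
    up <- oriented_window(seq, tss_local, strand, o - 10L, o - 1L)
    if (is.na(b) || is.na(up)) return(-Inf)
    ng <- sum(strsplit(up, "")[[1]] == "G")
    cfg$pause_w_c * (b == "C") + cfg$pause_w_g * ng - cfg$pause_w_d * abs(o - d0)
  }, numeric(1))
}

# argmax pause offset in the search window; ties -> smallest offset.
# Vectorised: extracts the oriented sequence once and scans with cumsums.
compute_pause_offset <- function(seq, tss_local, strand, d0, cfg) {
  lo <- cfg$pause_window[1]; hi <- cfg$pause_window[2]
  win <- oriented_window(seq, tss_local, strand, lo - 10L, hi)
  if (is.na(win)) {
    offs <- seq.int(lo, hi)
    return(offs[which.max(pause_energy(seq, tss_local, strand, offs, d0, cfg))])
  }
  b <- strsplit(win, "")[[1]]              # b[k] = base at offset lo - 11 + k
  offs <- seq.int(lo, hi)
  idx <- offs - (lo - 10L) + 1L
  gcum <- c(0, cumsum(b == "G"))
  ng <- gcum[idx] - gcum[idx - 10L]        # G count in [o-10, o-1]
  e <- cfg$pause_w_c * (b[idx] == "C") + cfg$pause_w_g * ng -
    cfg$pause_w_d * abs(offs - d0)
  offs[which.max(e)]
}

# per-TSS initiation rate on one haplotype: initiator weight at (-1,0) times
# AT-melting term over the +/-5 bp window with the initiator masked
tss_rate_on_allele <- function(gp, allele, pos_local, strand, cfg) {
  d <- initiator_dinuc(gp, allele, pos_local, strand)
  w <- if (!is.na(d) && d %in% names(cfg$init_weights)) cfg$init_weights[[d]] else 0.02
  win <- c(oriented_window(allele_seq(gp, allele), pos_local, strand, -5L, -2L),
           oriented_window(allele_seq(gp, allele), pos_local, strand, 1L, 5L))
  atf <- at_fraction(paste(win[!is.na(win)], collapse = ""))
  if (is.na(atf)) atf <- 0.5
  w * exp(cfg$at_alpha * atf)
}

# write oriented bases at strand-aware offsets around an anchor; returns a
# data.frame of (pos, base) edits on allele1
oriented_edits <- function(anchor, strand, offsets, bases) {
  if (strand == "+") {
    data.frame(pos = anchor + offsets, base = bases)
  } else {
    data.frame(pos = anchor - offsets,
               base = chartr("ACGT", "TGCA", bases))
  }
}

#' Plant transcription-cycle truth on a genome pair
#'
#' Lays out non-overlapping loci, writes initiator dinucleotides and pause
#' boxes into the sequence, injects planted variants (initiator SNPs,
#' active-site C SNPs, short TSS-pause deletions), assigns effect classes at
#' the configured proportions, and derives per-TSS per-allele initiation
#' rates and per-allele pause positions from the final haplotype sequences.
#'
#' @param genome A `genome_pair` from [generate_genome_pair()].
#' @param config The [sim_config()] used to generate it.
#' @return A `truth_set`: list with the updated `genome` (planted variants
#'   included), `loci`, `tss` and `exons` data.frames, and the `config`.
#' @export
plant_truth <- function(genome, config) {
  stopifnot(inherits(genome, "genome_pair"), inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed + 1L)
  n <- as.integer(cfg$n_loci)
  span <- as.integer(ceiling(1.5 * max(cfg$unit_length_range)) + 4000L)
  starts <- seq(5000L, by = span, length.out = n)
  if (starts[n] + span > nchar(genome$seq1)) {
    stop("infeasible placement: contig shorter than n_loci * locus span")
  }

  # deterministic class counts at the configured proportions, then shuffled
  cls_n <- floor(cfg$class_props * n)
  while (sum(cls_n) < n) {
    i <- which.max(cfg$class_props * n - cls_n)
    cls_n[i] <- cls_n[i] + 1L
  }
  classes <- sample(rep(names(cls_n), cls_n))

  strand <- sample(c("+", "-"), n, replace = TRUE)
  unit_len <- sample(seq(cfg$unit_length_range[1], cfg$unit_length_range[2]),
                     n, replace = TRUE)
  anchor <- ifelse(strand == "+", starts + 2000L, starts + 2000L + unit_len)
  d0 <- sample(30:45, n, replace = TRUE)
  expr <- exp(rnorm(n, 0, 0.5))

  # sequence-level plantings live on class-"none" loci
  is_none <- classes == "none"
  init_snp <- is_none & runif(n) < cfg$init_snp_prob
  rest <- is_none & !init_snp
  u <- runif(n)
  pause_csnp <- rest & u < cfg$pause_csnp_prob
  pause_indel <- rest & !pause_csnp & u < cfg$pause_csnp_prob + cfg$pause_indel_prob

  # ---- per-locus TSS architecture ------------------------------------------
  tss_list <- vector("list", n)
  edits <- vector("list", n)
  maxtss_dinuc <- character(n)
  for (i in seq_len(n)) {
    up_grid <- seq(-30L, -2L, by = 2L)
    dn_grid <- seq(2L, 12L, by = 2L)
    grid <- if (pause_csnp[i] || pause_indel[i]) up_grid else c(up_grid, dn_grid)
    n_tss <- if (classes[i] == "shape_multi") sample(4:5, 1L)
             else if (classes[i] == "shape_single") sample(2:4, 1L)
             else if (init_snp[i])
               safe_sample1(seq(cfg$init_snp_n_tss[1], cfg$init_snp_n_tss[2]))
             else sample(1:4, 1L, prob = c(0.3, 0.3, 0.25, 0.15))
    n_tss <- min(n_tss, length(grid) + 1L)
    offs <- c(0L, sort(sample(grid, n_tss - 1L)))
    # shape_multi loci are broad promoters: several TSSs of comparable
    # strength (the architecture in which multi-TSS changes arise); all
    # other loci are sharp-peaked around the maxTSS
    member_rate <- if (classes[i] == "shape_multi") runif(n_tss - 1L, 0.5, 0.9)
                   else runif(n_tss - 1L, 0.15, 0.5)
    dnuc <- c(sample(YR_DINUCS, 1L, prob = if (init_snp[i]) c(0.55, 0.25, 0.1, 0.1)
                                           else c(0.8, 0.1, 0.05, 0.05)),
              sample(YR_DINUCS, n_tss - 1L, replace = TRUE,
                     prob = c(0.5, 0.25, 0.15, 0.1)))
    base_rate <- c(1, member_rate)
    maxtss_dinuc[i] <- dnuc[1L]
    pos1 <- offset_pos(anchor[i], offs, strand[i])
    tss_list[[i]] <- data.frame(locus = i, offset = offs, pos1 = pos1,
                                strand = strand[i], base_rate = base_rate,
                                is_max = offs == 0L)
    # initiator edits ((-1,0) of every TSS) and the pause box
    ed <- lapply(seq_len(n_tss), function(k) {
      oriented_edits(pos1[k], strand[i], c(-1L, 0L),
                     strsplit(dnuc[k], "")[[1]])
    })
    run_off <- seq(d0[i] - 14L, d0[i] + 9L)
    run_base <- c(rep("G", 14L), "C",
                  if (pause_csnp[i]) sample(c("C", "A", "T"), 9L, replace = TRUE,
                                            prob = c(0.7, 0.15, 0.15))
                  else rep("C", 9L))
    ed <- c(ed, list(oriented_edits(anchor[i], strand[i], run_off, run_base)))
    edits[[i]] <- do.call(rbind, ed)
  }
  all_edits <- do.call(rbind, edits)
  gp <- edit_allele1(genome, all_edits$pos, all_edits$base)

  # drop background indels between TSS and pause box (keeps the indel-offset
  # analysis driven by planted indels only; background SNPs stay everywhere)
  v <- gp$variants
  if (nrow(v)) {
    lo <- ifelse(strand == "+", anchor - 5L, anchor - d0 - 15L)
    hi <- ifelse(strand == "+", anchor + d0 + 15L, anchor + 5L)
    bad <- rep(FALSE, nrow(v))
    for (i in seq_len(n)) {
      bad <- bad | (v$kind != "snp" & v$pos1 + nchar(v$ref) > lo[i] & v$pos1 <= hi[i])
    }
    if (any(bad)) gp <- new_genome_pair(gp$contig, gp$seq1,
                                        v[!bad, c("pos1", "ref", "alt", "kind")])
  }

  # ---- planted variants ----------------------------------------------------
  pv <- list()
  indel_len <- integer(n)
  for (i in seq_len(n)) {
    if (init_snp[i]) {
      d1 <- maxtss_dinuc[i]
      d2 <- sample(setdiff(YR_DINUCS, d1), 1L)
      b1 <- strsplit(d1, "")[[1]]; b2 <- strsplit(d2, "")[[1]]
      for (k in 1:2) {
        if (b1[k] != b2[k]) {
          off <- k - 2L  # offsets -1, 0
          p <- offset_pos(anchor[i], off, strand[i])
          alt <- if (strand[i] == "+") b2[k] else chartr("ACGT", "TGCA", b2[k])
          pv[[length(pv) + 1L]] <- data.frame(
            pos1 = p, ref = subseq0(gp$seq1, p, p + 1L), alt = alt,
            kind = "snp", stringsAsFactors = FALSE)
        }
      }
    } else if (pause_csnp[i]) {
      p <- offset_pos(anchor[i], d0[i], strand[i])
      ref <- subseq0(gp$seq1, p, p + 1L)    # "C" on +, "G" on -
      alt <- sample(setdiff(BASES, ref), 1L)
      pv[[length(pv) + 1L]] <- data.frame(pos1 = p, ref = ref, alt = alt,
                                          kind = "snp", stringsAsFactors = FALSE)
    } else if (pause_indel[i]) {
      len <- sample(2:6, 1L)
      u <- safe_sample1(3:(14L - len))
      p <- if (strand[i] == "+") anchor[i] + u - 1L else anchor[i] - u - len
      pv[[length(pv) + 1L]] <- data.frame(
        pos1 = p, ref = subseq0(gp$seq1, p, p + 1L + len),
        alt = subseq0(gp$seq1, p, p + 1L), kind = "deletion",
        stringsAsFactors = FALSE)
      indel_len[i] <- len
    }
  }
  if (length(pv)) gp <- add_variants(gp, do.call(rbind, pv))

  # ---- derive rates and pauses from the final sequences --------------------
  tss <- do.call(rbind, tss_list)
  tss$pos2 <- map_coords(gp, tss$pos1, from = "a1")
  tss$dinuc1 <- vapply(seq_len(nrow(tss)), function(k)
    initiator_dinuc(gp, "A1", tss$pos1[k], tss$strand[k]), character(1))
  tss$dinuc2 <- vapply(seq_len(nrow(tss)), function(k)
    initiator_dinuc(gp, "A2", tss$pos2[k], tss$strand[k]), character(1))
  tss$rate_a1 <- tss$base_rate * vapply(seq_len(nrow(tss)), function(k)
    tss_rate_on_allele(gp, "A1", tss$pos1[k], tss$strand[k], cfg), numeric(1))
  tss$rate_a2 <- tss$base_rate * vapply(seq_len(nrow(tss)), function(k)
    tss_rate_on_allele(gp, "A2", tss$pos2[k], tss$strand[k], cfg), numeric(1))

  # abundance / shape multipliers on the strain axis
  biased_allele <- ifelse(runif(n) < 0.5, "A1", "A2")
  imprint_high_parent <- ifelse(runif(n) < 0.5, "mother", "father")
  tss$shifted <- FALSE
  for (i in seq_len(n)) {
    rows <- which(tss$locus == i)
    if (classes[i] == "abundance") {
      col <- if (biased_allele[i] == "A1") "rate_a1" else "rate_a2"
      tss[rows, col] <- tss[rows, col] * cfg$abundance_ratio
    } else if (classes[i] == "shape_single") {
      k <- safe_sample1(rows[!tss$is_max[rows]])
      col <- if (biased_allele[i] == "A1") "rate_a1" else "rate_a2"
      tss[k, col] <- tss[k, col] * cfg$shape_single_fold
      tss$shifted[k] <- TRUE
    } else if (classes[i] == "shape_multi") {
      # three prominent TSSs shifted with directions straddling both alleles:
      # a multi-TSS shape change is carried by several substantial start
      # sites, and an alternating direction pattern (strongest and weakest
      # one way, middle the other) keeps the change in cluster shape rather
      # than abundance, however the cluster is truncated or masked
      ks <- rows[order(-tss$base_rate[rows])][1:3]
      ab <- sample(c("rate_a1", "rate_a2"))
      cols <- c(ab[1], ab[2], ab[1])
      for (j in 1:3) {
        tss[ks[j], cols[j]] <- tss[ks[j], cols[j]] * cfg$shape_multi_fold
      }
      tss$shifted[ks] <- TRUE
    }
  }
  # redistribution mode: conserve per-locus totals by boosting members within
  # +/-20 bp of the maxTSS on the weaker allele
  if (isTRUE(cfg$redistribute_initiation)) {
    for (i in which(init_snp)) {
      rows <- which(tss$locus == i)
      near <- rows[abs(tss$offset[rows]) <= 20L & !tss$is_max[rows]]
      if (!length(near)) next
      t1 <- sum(tss$rate_a1[rows]); t2 <- sum(tss$rate_a2[rows])
      if (t1 < t2 && sum(tss$rate_a1[near]) > 0) {
        tss$rate_a1[near] <- tss$rate_a1[near] *
          (1 + (t2 - t1) / sum(tss$rate_a1[near]))
      } else if (t2 < t1 && sum(tss$rate_a2[near]) > 0) {
        tss$rate_a2[near] <- tss$rate_a2[near] *
          (1 + (t1 - t2) / sum(tss$rate_a2[near]))
      }
    }
  }

  # per-allele pause positions anchored at the maxTSS
  anchor2 <- map_coords(gp, anchor, from = "a1")
  pause_off1 <- pause_off2 <- integer(n)
  for (i in seq_len(n)) {
    pause_off1[i] <- compute_pause_offset(gp$seq1, anchor[i], strand[i], d0[i], cfg)
    pause_off2[i] <- compute_pause_offset(gp$seq2, anchor2[i], strand[i], d0[i], cfg)
  }
  pause1 <- offset_pos(anchor, pause_off1, strand)
  pause2_local <- offset_pos(anchor2, pause_off2, strand)
  pause2_proj <- map_coords(gp, pause2_local, from = "a2")

  # termination truth
  long_allele <- ifelse(classes == "termination",
                        ifelse(runif(n) < 0.5, "A1", "A2"), NA_character_)
  ext <- ifelse(classes == "termination",
                round(runif(n, cfg$termination_frac_range[1],
                            cfg$termination_frac_range[2]) * unit_len), 0L)
  end3_short <- offset_pos(anchor, unit_len, strand)
  end3_long <- offset_pos(anchor, unit_len + as.integer(ext), strand)
  structure_change <- classes == "termination" & runif(n) < cfg$structure_change_prob

  # mRNA stability (log2 allelic ratio wider where structure changes)
  d_stab <- rnorm(n, 0, ifelse(structure_change, cfg$stability_coupling_sd,
                               cfg$stability_base_sd))
  stab_a1 <- 2^(d_stab / 2)
  stab_a2 <- 2^(-d_stab / 2)

  loci <- data.frame(
    locus = seq_len(n), contig = gp$contig, strand = strand,
    anchor = anchor, anchor2 = anchor2,
    tsr_start = pmin(offset_pos(anchor, -60L, strand),
                     offset_pos(anchor, 80L, strand)),
    tsr_end = pmax(offset_pos(anchor, -60L, strand),
                   offset_pos(anchor, 80L, strand)) + 1L,
    unit_len = unit_len, end3_short = end3_short, end3_long = end3_long,
    class = classes, expr = expr, biased_allele = biased_allele,
    imprint_high_parent = imprint_high_parent,
    init_snp = init_snp, maxtss_dinuc = maxtss_dinuc,
    pause_variant = ifelse(pause_csnp, "csnp",
                           ifelse(pause_indel, "indel", "none")),
    indel_len = indel_len, d0 = d0,
    pause1 = pause1, pause_off1 = pause_off1,
    pause2_local = pause2_local, pause_off2 = pause_off2,
    pause2_proj = pause2_proj,
    long_allele = long_allele, ext = as.integer(ext),
    structure_change = structure_change,
    stab_a1 = stab_a1, stab_a2 = stab_a2,
    stringsAsFactors = FALSE)

  # exon structure: 5' exon, 2-3 internal exons, plus a novel 3' exon inside
  # the extension on structure-changed loci
  ex_list <- vector("list", n)
  for (i in seq_len(n)) {
    n_int <- sample(2:3, 1L)
    starts5 <- sort(runif(n_int, 0.1, 0.85)) * unit_len[i]
    offs <- c(0, starts5)
    lens <- c(300L, sample(150:400, n_int, replace = TRUE))
    exs <- data.frame(locus = i,
                      exon_id = paste0("e", seq_len(n_int + 1L)),
                      off5 = as.integer(offs), len = as.integer(lens),
                      novel = FALSE)
    if (structure_change[i]) {
      exs <- rbind(exs, data.frame(locus = i, exon_id = "novel",
                                   off5 = as.integer(unit_len[i] + 100L),
                                   len = 300L, novel = TRUE))
    }
    a <- offset_pos(anchor[i], exs$off5, strand[i])
    b <- offset_pos(anchor[i], exs$off5 + exs$len, strand[i])
    exs$start <- pmin(a, b)
    exs$end <- pmax(a, b)
    ex_list[[i]] <- exs
  }
  exons <- do.call(rbind, ex_list)

  out <- list(genome = gp, loci = loci, tss = tss, exons = exons, config = cfg)
  class(out) <- "truth_set"
  out
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("<truth_set> %d loci (%s), %d TSSs, %d exons\n",
              nrow(x$loci),
              paste(names(table(x$loci$class)), table(x$loci$class),
                    sep = ":", collapse = " "),
              nrow(x$tss), nrow(x$exons)))
  invisible(x)
}
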