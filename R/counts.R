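# From read ends to per-base counts, TSSs, TSCs, TSRs and pause positions.

#' Per-base read-end counts
#'
#' Counts read 5' or 3' ends per (contig, strand, position), split by allele
#' class. Untagged reads contribute to `untagged` and `all` only.
#'
#' @param reads Read-end data.frame.
#' @param end_type `"five_prime"` or `"three_prime"`.
#' @param organ,cross,replicate Optional sample filters (vectors allowed).
#' @return A data.frame of class `site_counts` with columns
#'   `contig, strand, pos, a1, a2, untagged, all` and attribute `end_type`.
#' @export
make_base_counts <- function(reads, end_type = c("five_prime", "three_prime"),
                             organ = NULL, cross = NULL, replicate = NULL) {
  end_type <- match.arg(end_type)
  if (!is.null(organ)) reads <- reads[reads$organ %in% organ, ]
  if (!is.null(cross)) reads <- reads[reads$cross %in% cross, ]
  if (!is.null(replicate)) reads <- reads[reads$replicate %in% replicate, ]
  dt <- data.table::data.table(contig = reads$contig, strand = reads$strand,
                               pos = reads[[end_type]], allele = reads$allele)
  agg <- dt[, list(
    a1 = sum(allele == "A1"), a2 = sum(allele == "A2"),
    untagged = sum(allele == "untagged")),
    by = c("contig", "strand", "pos")]
  data.table::setorderv(agg, c("contig", "strand", "pos"))
  out <- as.data.frame(agg)
  out$all <- out$a1 + out$a2 + out$untagged
  attr(out, "end_type") <- end_type
  class(out) <- c("site_counts", "data.frame")
  out
}

# assign each row of a position table to at most one region; regions are
# 0-based half-open with a region_id column
assign_regions <- function(pos_df, regions) {
  if (is.null(regions$region_id)) regions$region_id <- seq_len(nrow(regions))
  out <- rep(NA_integer_, nrow(pos_df))
  for (ct in unique(pos_df$contig)) {
    r <- regions[regions$contig == ct, ]
    i <- which(pos_df$contig == ct)
    if (!nrow(r) || !length(i)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = pos_df$pos[i] + 1L, width = 1L),
      IRanges::IRanges(start = r$start + 1L, end = r$end))
    out[i[S4Vectors::queryHits(hits)]] <- r$region_id[S4Vectors::subjectHits(hits)]
  }
  out
}

#' Call single-base TSSs
#'
#' A TSS is any base whose combined (all-read) 5' count reaches `min_reads`
#' and which falls inside a candidate regulatory region; positions outside
#' every region are dropped.
#'
#' @param counts `site_counts` with `end_type == "five_prime"`.
#' @param regions data.frame of candidate regions (`contig, start, end`,
#'   0-based half-open; a `region_id` is added if absent).
#' @param min_reads Minimum supporting reads (default 5).
#' @return data.frame of TSSs with their allele-class counts and
#'   `region_id`.
#' @export
call_tss <- function(counts, regions, min_reads = 5L) {
  stopifnot(inherits(counts, "site_counts"),
            attr(counts, "end_type") == "five_prime")
  if (is.null(regions) || nrow(regions) == 0L) {
    warning("no candidate regions supplied; no TSSs called")
    return(counts[0, ])
  }
  tss <- counts[counts$all >= min_reads, , drop = FALSE]
  tss <- as.data.frame(tss)
  tss$region_id <- assign_regions(tss, regions)
  tss <- tss[!is.na(tss$region_id), , drop = FALSE]
  rownames(tss) <- NULL
  tss
}

#' Cluster TSSs into transcription start clusters
#'
#' Single-linkage chaining: consecutive TSSs on the same contig, strand and
#' region closer than or equal to `merge_gap` join one cluster. The maxTSS
#' set is every member sharing the maximal combined count; `maxtss_pos` is
#' the 5'-most of the set (deterministic representative).
#'
#' @param tss TSS table from [call_tss()].
#' @param merge_gap Maximum gap in bp (default 60).
#' @return List of class `tsc_set`: `tsc` (one row per cluster) and
#'   `members` (the TSS table with `tsc_id`).
#' @export
cluster_tsc <- function(tss, merge_gap = 60L) {
  if (nrow(tss) == 0L) {
    return(structure(list(tsc = data.frame(), members = tss), class = "tsc_set"))
  }
  tss <- tss[order(tss$contig, tss$strand, tss$region_id, tss$pos), ]
  new_cluster <- c(TRUE, tss$contig[-1] != tss$contig[-nrow(tss)] |
                     tss$strand[-1] != tss$strand[-nrow(tss)] |
                     tss$region_id[-1] != tss$region_id[-nrow(tss)] |
                     diff(tss$pos) > merge_gap)
  tss$tsc_id <- cumsum(new_cluster)
  sp <- split(seq_len(nrow(tss)), tss$tsc_id)
  tsc <- do.call(rbind, lapply(sp, function(i) {
    d <- tss[i, ]
    mx <- max(d$all)
    max_set <- d$pos[d$all == mx]
    data.frame(tsc_id = d$tsc_id[1], contig = d$contig[1], strand = d$strand[1],
               region_id = d$region_id[1],
               start = min(d$pos), end = max(d$pos) + 1L,
               n_tss = nrow(d), a1 = sum(d$a1), a2 = sum(d$a2),
               untagged = sum(d$untagged), all = sum(d$all),
               max_count = mx,
               maxtss_pos = five_prime_most(max_set, d$strand[1]),
               n_maxtss = length(max_set), stringsAsFactors = FALSE)
  }))
  rownames(tsc) <- NULL
  structure(list(tsc = tsc, members = tss), class = "tsc_set")
}

#' @export
print.tsc_set <- function(x, ...) {
  cat(sprintf("<tsc_set> %d clusters from %d TSSs in %d regions\n",
              nrow(x$tsc), nrow(x$members),
              length(unique(x$tsc$region_id))))
  invisible(x)
}

#' Group TSCs into transcription start regions
#'
#' A TSR is a candidate region together with all its TSCs on one strand.
#'
#' @param tsc_set A `tsc_set`.
#' @param regions The candidate-region table used for calling.
#' @return data.frame with one row per (region, strand) holding TSC counts.
#' @export
assign_tsr <- function(tsc_set, regions) {
  tsc <- tsc_set$tsc
  if (nrow(tsc) == 0L) return(data.frame())
  if (any(is.na(tsc$region_id))) stop("internal error: orphan TSC without region")
  if (is.null(regions$region_id)) regions$region_id <- seq_len(nrow(regions))
  sp <- split(seq_len(nrow(tsc)), paste(tsc$region_id, tsc$strand))
  out <- do.call(rbind, lapply(sp, function(i) {
    d <- tsc[i, ]
    r <- regions[regions$region_id == d$region_id[1], ]
    data.frame(tsr_id = paste0("tsr_", d$region_id[1], d$strand[1]),
               region_id = d$region_id[1], contig = d$contig[1],
               strand = d$strand[1], start = r$start[1], end = r$end[1],
               n_tsc = nrow(d), all = sum(d$all), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Modal read-end base for one allele per region
#'
#' Returns, per (region, strand), the allele-specific modal position (the
#' maxTSS for 5' counts, the maxPause for 3' counts). Regions where the
#' allele has fewer than `min_reads` tagged reads are flagged
#' insufficient. Ties are broken to the 5'-most position, strand-aware.
#'
#' @param counts A `site_counts` (either end type).
#' @param regions Candidate-region table.
#' @param allele `"A1"`, `"A2"` or `"all"`.
#' @param min_reads Minimum allele-specific reads in the region (default 5).
#' @return data.frame `region_id, strand, pos, n, ok`.
#' @export
call_max_site <- function(counts, regions, allele = c("A1", "A2", "all"),
                          min_reads = 5L) {
  allele <- match.arg(allele)
  col <- switch(allele, A1 = "a1", A2 = "a2", all = "all")
  d <- as.data.frame(counts)
  d <- d[d[[col]] > 0L, , drop = FALSE]
  d$region_id <- assign_regions(d, regions)
  d <- d[!is.na(d$region_id), , drop = FALSE]
  if (nrow(d) == 0L) {
    return(data.frame(region_id = integer(), strand = character(),
                      pos = integer(), n = integer(), ok = logical()))
  }
  sp <- split(seq_len(nrow(d)), paste(d$region_id, d$strand))
  out <- do.call(rbind, lapply(sp, function(i) {
    x <- d[i, ]
    tot <- sum(x[[col]])
    mx <- max(x[[col]])
    pos <- five_prime_most(x$pos[x[[col]] == mx], x$strand[1])
    data.frame(region_id = x$region_id[1], strand = x$strand[1],
               pos = if (tot >= min_reads) pos else NA_integer_,
               n = tot, ok = tot >= min_reads, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Call the allele-specific maxPause per region
#'
#' Convenience wrapper over [call_max_site()] for 3'-end counts.
#'
#' @inheritParams call_max_site
#' @return data.frame `region_id, strand, pos, n, ok`.
#' @export
call_max_pause <- function(counts, regions, allele = c("A1", "A2", "all"),
                           min_reads = 5L) {
  stopifnot(attr(counts, "end_type") == "three_prime")
  call_max_site(counts, regions, allele, min_reads)
}

#' Pair allelic maxTSS with allelic maxPause
#'
#' Joins per-allele maxTSS and maxPause calls per (region, strand) and
#' flags a pair valid when the strand-aware TSS-to-pause distance lies in
#' `window` on both alleles. Invalid pairs are retained with
#' `valid = FALSE` for accounting.
#'
#' @param maxtss_a1,maxtss_a2 Output of [call_max_site()] on 5' counts.
#' @param maxpause_a1,maxpause_a2 Output of [call_max_pause()].
#' @param window Inclusive distance window (default `c(10, 50)`).
#' @return data.frame of pause pairs with per-allele positions, distances
#'   and flags.
#' @export
pair_tss_pause <- function(maxtss_a1, maxtss_a2, maxpause_a1, maxpause_a2,
                           window = c(10L, 50L)) {
  key <- function(d) paste(d$region_id, d$strand)
  ids <- Reduce(intersect, list(key(maxtss_a1), key(maxtss_a2),
                                key(maxpause_a1), key(maxpause_a2)))
  pick <- function(d, f) d[match(ids, key(d)), f]
  out <- data.frame(
    region_id = pick(maxtss_a1, "region_id"),
    strand = pick(maxtss_a1, "strand"),
    tss_a1 = pick(maxtss_a1, "pos"), tss_a2 = pick(maxtss_a2, "pos"),
    pause_a1 = pick(maxpause_a1, "pos"), pause_a2 = pick(maxpause_a2, "pos"),
    tss_n_a1 = pick(maxtss_a1, "n"), tss_n_a2 = pick(maxtss_a2, "n"),
    pause_n_a1 = pick(maxpause_a1, "n"), pause_n_a2 = pick(maxpause_a2, "n"),
    stringsAsFactors = FALSE)
  out$dist_a1 <- downstream_dist(out$tss_a1, out$pause_a1, out$strand)
  out$dist_a2 <- downstream_dist(out$tss_a2, out$pause_a2, out$strand)
  complete <- !is.na(out$dist_a1) & !is.na(out$dist_a2)
  out$valid <- complete & out$dist_a1 >= window[1] & out$dist_a1 <= window[2] &
    out$dist_a2 >= window[1] & out$dist_a2 <= window[2]
  rownames(out) <- NULL
  out
}
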