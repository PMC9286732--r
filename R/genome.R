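# Diploid genome pair: allele1 is the reference-like haplotype, allele2 is
# derived from it by a sorted, non-overlapping variant list. Indels are
# anchored VCF-style (ref and alt share their first base), so a SNP has
# len1 == len2 == 1 and an indel has min(len1, len2) == 1.

new_genome_pair <- function(contig, seq1, variants) {
  variants <- normalize_variants(variants)
  av <- apply_variants(seq1, variants)
  variants$pos2 <- av$pos2
  gp <- list(contig = contig, seq1 = seq1, seq2 = av$seq2, variants = variants)
  class(gp) <- "genome_pair"
  gp
}

normalize_variants <- function(v) {
  if (is.null(v) || nrow(v) == 0L) {
    return(data.frame(pos1 = integer(), ref = character(), alt = character(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  v <- v[order(v$pos1), , drop = FALSE]
  v$ref <- toupper(v$ref); v$alt <- toupper(v$alt)
  v$kind <- ifelse(nchar(v$ref) == 1L & nchar(v$alt) == 1L, "snp",
                   ifelse(nchar(v$ref) > nchar(v$alt), "deletion", "insertion"))
  ends <- v$pos1 + nchar(v$ref)
  if (nrow(v) > 1L && any(v$pos1[-1L] < ends[-nrow(v)])) {
    stop("variants overlap on allele1")
  }
  rownames(v) <- NULL
  v
}

# apply variants left-to-right; returns allele2 sequence and each variant's
# 0-based start on allele2
apply_variants <- function(seq1, v) {
  if (nrow(v) == 0L) return(list(seq2 = seq1, pos2 = integer()))
  pieces <- character(2L * nrow(v) + 1L)
  pos2 <- integer(nrow(v))
  cur1 <- 0L   # next unconsumed allele1 position
  cur2 <- 0L   # length of allele2 built so far
  for (i in seq_len(nrow(v))) {
    stopifnot(subseq0(seq1, v$pos1[i], v$pos1[i] + nchar(v$ref[i])) == v$ref[i])
    pieces[2L * i - 1L] <- subseq0(seq1, cur1, v$pos1[i])
    cur2 <- cur2 + (v$pos1[i] - cur1)
    pos2[i] <- cur2
    pieces[2L * i] <- v$alt[i]
    cur2 <- cur2 + nchar(v$alt[i])
    cur1 <- v$pos1[i] + nchar(v$ref[i])
  }
  pieces[2L * nrow(v) + 1L] <- subseq0(seq1, cur1, nchar(seq1))
  list(seq2 = paste(pieces, collapse = ""), pos2 = pos2)
}

#' Generate a diploid genome pair
#'
#' Draws a random contig for allele1 and a background variant list (SNPs and
#' short anchored indels) at the configured densities, derives allele2 by
#' applying the variants, and records the monotone coordinate map between
#' the two haplotypes.
#'
#' @param config A [sim_config()].
#' @return An object of class `genome_pair` with fields `contig`, `seq1`,
#'   `seq2` and a `variants` data.frame (`pos1`, `ref`, `alt`, `kind`,
#'   `pos2`; all positions 0-based).
#' @export
generate_genome_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- as.integer(config$contig_length)
  seq1 <- paste(sample(BASES, L, replace = TRUE), collapse = "")
  n_snp <- rpois(1L, L * config$snp_density)
  n_indel <- rpois(1L, L * config$indel_density)
  v <- draw_background_variants(seq1, n_snp, n_indel, config$max_indel)
  new_genome_pair("chrS", seq1, v)
}

draw_background_variants <- function(seq1, n_snp, n_indel, max_indel) {
  L <- nchar(seq1)
  n <- n_snp + n_indel
  if (n == 0L) {
    return(data.frame(pos1 = integer(), ref = character(), alt = character(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  pos <- sort(sample.int(L - 2L * max_indel - 20L, n) + 10L)
  # enforce non-overlapping footprints
  keep <- c(TRUE, diff(pos) > max_indel + 1L)
  pos <- pos[keep]
  n <- length(pos)
  is_snp <- sample(rep(c(TRUE, FALSE), c(n_snp, n_indel))[seq_len(n)])
  ref <- alt <- character(n)
  for (i in seq_len(n)) {
    b <- subseq0(seq1, pos[i], pos[i] + 1L)
    if (is_snp[i]) {
      ref[i] <- b
      alt[i] <- sample(setdiff(BASES, b), 1L)
    } else {
      len <- 1L + rgeom(1L, 0.35)
      len <- min(max(len, 1L), max_indel)
      if (runif(1) < 0.5) {            # deletion on allele2
        ref[i] <- subseq0(seq1, pos[i], pos[i] + 1L + len)
        alt[i] <- b
      } else {                          # insertion on allele2
        ref[i] <- b
        alt[i] <- paste0(b, paste(sample(BASES, len, replace = TRUE),
                                  collapse = ""))
      }
    }
  }
  data.frame(pos1 = pos, ref = ref, alt = alt, kind = NA_character_,
             stringsAsFactors = FALSE)
}

# add planted variants to a genome pair and rebuild allele2; existing
# background variants whose footprints collide are dropped in favour of the
# planted ones
add_variants <- function(gp, newv) {
  if (is.null(newv) || nrow(newv) == 0L) return(gp)
  newv <- normalize_variants(newv)
  old <- gp$variants
  if (nrow(old)) {
    nstart <- newv$pos1; nend <- newv$pos1 + nchar(newv$ref)
    collide <- vapply(seq_len(nrow(old)), function(i) {
      s <- old$pos1[i]; e <- s + nchar(old$ref[i])
      any(nstart < e + 1L & nend + 1L > s)
    }, logical(1))
    old <- old[!collide, , drop = FALSE]
  }
  comb <- rbind(old[, c("pos1", "ref", "alt", "kind")],
                newv[, c("pos1", "ref", "alt", "kind")])
  new_genome_pair(gp$contig, gp$seq1, comb)
}

# edit allele1 bases in place (0-based positions). Background variants whose
# footprints are touched get their ref (and indel anchor base) refreshed from
# the edited sequence; SNPs that become no-ops are dropped.
edit_allele1 <- function(gp, pos, bases) {
  s <- strsplit(gp$seq1, "")[[1]]
  s[pos + 1L] <- bases
  seq1 <- paste(s, collapse = "")
  v <- gp$variants[, c("pos1", "ref", "alt", "kind")]
  if (nrow(v)) {
    for (i in seq_len(nrow(v))) {
      newref <- subseq0(seq1, v$pos1[i], v$pos1[i] + nchar(v$ref[i]))
      if (newref == v$ref[i]) next
      v$ref[i] <- newref
      if (nchar(v$ref[i]) > 1L || nchar(v$alt[i]) > 1L) {
        v$alt[i] <- paste0(substr(newref, 1, 1), substr(v$alt[i], 2, nchar(v$alt[i])))
      }
    }
    v <- v[v$ref != v$alt, , drop = FALSE]
  }
  new_genome_pair(gp$contig, seq1, v)
}

#' Map positions between the two haplotypes
#'
#' Projects 0-based positions through the variant list in either direction.
#' Positions strictly inside an indel footprint (which do not exist on the
#' other haplotype) are mapped to the indel's anchor base; use
#' `detail = TRUE` to recover that flag.
#'
#' @param gp A `genome_pair`.
#' @param pos Integer vector of 0-based positions.
#' @param from `"a1"` or `"a2"`: haplotype the input positions live on.
#' @param detail If `TRUE`, return a data.frame with an `inside_indel` flag.
#' @return Integer vector of projected positions (or a data.frame).
#' @export
map_coords <- function(gp, pos, from = c("a2", "a1"), detail = FALSE) {
  from <- match.arg(from)
  v <- gp$variants
  if (nrow(v) == 0L) {
    out <- as.integer(pos)
    if (detail) return(data.frame(pos = out, inside_indel = logical(length(pos))))
    return(out)
  }
  if (from == "a1") {
    src_start <- v$pos1; src_len <- nchar(v$ref)
    dst_start <- v$pos2; dst_len <- nchar(v$alt)
  } else {
    src_start <- v$pos2; src_len <- nchar(v$alt)
    dst_start <- v$pos1; dst_len <- nchar(v$ref)
  }
  shift <- cumsum(dst_len - src_len)
  breaks <- src_start + src_len             # first position after each variant
  k <- findInterval(pos, breaks)
  out <- as.integer(pos + c(0L, shift)[k + 1L])
  # positions inside the next variant's footprint (past its anchor base)
  j <- findInterval(pos, src_start)
  inside <- j >= 1L & pos > src_start[pmax(j, 1L)] &
    pos < src_start[pmax(j, 1L)] + src_len[pmax(j, 1L)]
  if (any(inside)) {
    out[inside] <- as.integer(dst_start[j[inside]])
  }
  if (detail) return(data.frame(pos = out, inside_indel = inside))
  out
}

# sequence of one haplotype
allele_seq <- function(gp, allele) {
  if (allele %in% c("A1", "a1", 1)) gp$seq1 else gp$seq2
}

# project an allele1 position onto a haplotype's local coordinates
local_pos <- function(gp, pos1, allele) {
  if (allele %in% c("A1", "a1", 1)) as.integer(pos1)
  else map_coords(gp, pos1, from = "a1")
}

# strand-aware dinucleotide at (-1, 0) relative to a local position
initiator_dinuc <- function(gp, allele, pos_local, strand) {
  oriented_window(allele_seq(gp, allele), pos_local, strand, -1L, 0L)
}

#' @export
print.genome_pair <- function(x, ...) {
  v <- x$variants
  cat(sprintf("<genome_pair> contig %s: allele1 %d bp, allele2 %d bp, %d variants (%d SNP, %d indel)\n",
              x$contig, nchar(x$seq1), nchar(x$seq2), nrow(v),
              sum(v$kind == "snp"), sum(v$kind != "snp")))
  invisible(x)
}
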