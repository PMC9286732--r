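# Readers and writers. All intervals are 0-based half-open internally;
# 1-based conversion is confined to this file (GTF-like input only).

#' Read allele-assigned read ends
#'
#' Reads the 8+ column TSV written by [write_read_ends()]:
#' `contig five_prime three_prime strand allele organ cross replicate`.
#' Malformed lines are rejected with their line numbers.
#'
#' @param path Path to a TSV with a header line.
#' @return A validated data.frame of read ends.
#' @export
read_read_ends <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "contig"))
  df <- as.data.frame(dt)
  if (nrow(df) == 0L) {
    warning("empty read-end file: ", path)
    return(df)
  }
  need <- c("contig", "five_prime", "three_prime", "strand", "allele",
            "organ", "cross", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad)) stop("unknown strand token at line(s): ",
                        paste(utils::head(bad + 1L, 5L), collapse = ", "))
  bad <- which(!df$allele %in% c("A1", "A2", "untagged"))
  if (length(bad)) stop("unknown allele token at line(s): ",
                        paste(utils::head(bad + 1L, 5L), collapse = ", "))
  bad <- which((df$strand == "+" & df$five_prime > df$three_prime) |
                 (df$strand == "-" & df$three_prime > df$five_prime))
  if (length(bad)) stop("5'/3' order violates strand at line(s): ",
                        paste(utils::head(bad + 1L, 5L), collapse = ", "))
  df
}

#' Write read ends as TSV
#'
#' @param reads Read-end data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_read_ends <- function(reads, path) {
  cols <- c("contig", "five_prime", "three_prime", "strand", "allele",
            "organ", "cross", "replicate")
  utils::write.table(reads[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export read ends as BED6
#'
#' One BED line per read spanning min to max of its two ends; the score
#' column is 0 and the name encodes the allele tag.
#'
#' @param reads Read-end data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  lo <- pmin(reads$five_prime, reads$three_prime)
  hi <- pmax(reads$five_prime, reads$three_prime) + 1L
  df <- data.frame(reads$contig, lo, hi, reads$allele, 0L, reads$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read genomic intervals (BED or GTF-like)
#'
#' BED input is taken as 0-based half-open; GTF-like input (1-based closed
#' `contig source feature start end score strand` or a minimal
#' `contig start end strand` 1-based table) is converted to 0-based
#' half-open on read.
#'
#' @param path File path.
#' @param format `"bed"` or `"gtf_like"`.
#' @return data.frame with `contig, start, end` (+ `name, score, strand`
#'   when present), 0-based half-open.
#' @export
read_intervals <- function(path, format = c("bed", "gtf_like")) {
  format <- match.arg(format)
  df <- as.data.frame(data.table::fread(path, header = FALSE, sep = "\t"))
  if (nrow(df) == 0L) return(data.frame(contig = character(),
                                        start = integer(), end = integer()))
  if (format == "bed") {
    names(df)[1:3] <- c("contig", "start", "end")
    if (ncol(df) >= 6L) names(df)[4:6] <- c("name", "score", "strand")
  } else {
    if (ncol(df) >= 9L) {
      df <- df[, c(1, 4, 5, 7)]
    } else if (ncol(df) >= 4L) {
      df <- df[, 1:4]
    } else stop("gtf_like input needs at least 4 columns")
    names(df) <- c("contig", "start", "end", "strand")
    df$start <- df$start - 1L
  }
  df$contig <- as.character(df$contig)
  if (any(df$start < 0L)) stop("negative interval start")
  if (any(df$start >= df$end)) stop("interval start >= end at line(s): ",
                                    paste(utils::head(which(df$start >= df$end), 5L),
                                          collapse = ", "))
  df
}

#' Write intervals as BED6
#'
#' @param x data.frame with `contig, start, end` and optionally
#'   `name, score, strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- data.frame(x$contig, x$start, x$end,
                   x$name %||% ".", x$score %||% 0L, x$strand %||% ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write per-base signal as bedGraph
#'
#' Writes one sorted bedGraph per strand for one allele class, with
#' adjacent equal-value runs merged. Values are non-negative counts on both
#' strands (no negated minus strand).
#'
#' @param counts A `site_counts` object from [make_base_counts()].
#' @param prefix Output path prefix; files are
#'   `<prefix>_<allele>_plus.bedGraph` / `..._minus.bedGraph`.
#' @param allele One of `"all", "A1", "A2", "untagged"`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_signal_track <- function(counts, prefix, allele = "all") {
  stopifnot(inherits(counts, "site_counts"))
  col <- switch(allele, all = "all", A1 = "a1", A2 = "a2",
                untagged = "untagged", stop("unknown allele class"))
  paths <- character(2)
  for (i in 1:2) {
    st <- c("+", "-")[i]
    lab <- c("plus", "minus")[i]
    paths[i] <- paste0(prefix, "_", allele, "_", lab, ".bedGraph")
    d <- counts[counts$strand == st & counts[[col]] > 0L, ]
    if (nrow(d) == 0L) { file.create(paths[i]); next }
    d <- d[order(d$contig, d$pos), ]
    if (any(diff(d$pos[d$contig == d$contig[1]]) < 0)) {
      stop("internal error: unsorted site counts")
    }
    # merge adjacent equal-value runs
    brk <- c(TRUE, d$contig[-1] != d$contig[-nrow(d)] |
               d$pos[-1] != d$pos[-nrow(d)] + 1L |
               d[[col]][-1] != d[[col]][-nrow(d)])
    run <- cumsum(brk)
    out <- data.frame(contig = tapply(d$contig, run, `[`, 1L),
                      start = as.integer(tapply(d$pos, run, min)),
                      end = as.integer(tapply(d$pos, run, max)) + 1L,
                      value = as.integer(tapply(d[[col]], run, `[`, 1L)))
    utils::write.table(out, paths[i], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}

#' Write the two haplotype sequences as FASTA
#'
#' @param gp A `genome_pair`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(gp, path) {
  x <- Biostrings::DNAStringSet(c(gp$seq1, gp$seq2))
  names(x) <- paste0(gp$contig, c("_allele1", "_allele2"))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a haplotype pair FASTA written by [write_genome_fasta()]
#'
#' @param path FASTA path with two records (allele1, allele2).
#' @return Named character vector of the two sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write variants as a minimal VCF
#'
#' Emits a sites-only VCF (CHROM POS ID REF ALT) with POS 1-based per the
#' format; QUAL/FILTER/INFO are placeholders.
#'
#' @param gp A `genome_pair`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(gp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", gp$contig, nchar(gp$seq1)),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  v <- gp$variants
  if (nrow(v)) {
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.", gp$contig, v$pos1 + 1L,
                       paste0("v", seq_len(nrow(v))), v$ref, v$alt), con)
  }
  invisible(path)
}

#' Read a minimal VCF back into a variant table
#'
#' @param path VCF path.
#' @return data.frame with `pos1` (0-based), `ref`, `alt`, `kind`.
#' @export
read_variants_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) {
    return(data.frame(pos1 = integer(), ref = character(), alt = character(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t")
  v <- data.frame(pos1 = vapply(f, function(x) as.integer(x[2]), integer(1)) - 1L,
                  ref = vapply(f, `[`, character(1), 4L),
                  alt = vapply(f, `[`, character(1), 5L),
                  stringsAsFactors = FALSE)
  v$kind <- ifelse(nchar(v$ref) == 1L & nchar(v$alt) == 1L, "snp",
                   ifelse(nchar(v$ref) > nchar(v$alt), "deletion", "insertion"))
  v
}

#' Write a truth set as documented TSV files
#'
#' @param truth A `truth_set`.
#' @param prefix Output path prefix (`<prefix>_loci.tsv`, `_tss.tsv`,
#'   `_exons.tsv`).
#' @return Paths, invisibly.
#' @export
write_truth_tsv <- function(truth, prefix) {
  paths <- paste0(prefix, c("_loci.tsv", "_tss.tsv", "_exons.tsv"))
  utils::write.table(truth$loci, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$tss, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$exons, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
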