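# Internal helpers shared across modules. All genomic coordinates in this
# package are 0-based half-open; conversion to/from 1-based happens only in
# readers/writers and when indexing R strings.

BASES <- c("A", "C", "G", "T")

# let data.table know this non-depending package uses its [ semantics
.datatable.aware <- TRUE

# reverse complement of a plain character scalar
revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# substring by 0-based half-open coordinates
subseq0 <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

# oriented sequence covering strand-aware offsets [from, to] relative to an
# anchor base at 0-based position `pos`. On "+" offset o is pos + o; on "-"
# it is pos - o, read on the reverse complement. Returns NA if out of range.
oriented_window <- function(seq, pos, strand, from, to) {
  stopifnot(to >= from)
  n <- nchar(seq, type = "bytes")   # sequences are ASCII; avoid re-scanning
  if (strand == "+") {
    lo <- pos + from
    hi <- pos + to
    if (lo < 0 || hi >= n) return(NA_character_)
    subseq0(seq, lo, hi + 1L)
  } else {
    lo <- pos - to
    hi <- pos - from
    if (lo < 0 || hi >= n) return(NA_character_)
    revcomp(subseq0(seq, lo, hi + 1L))
  }
}

# strand-aware distance from a to b (positive when b is downstream of a);
# strand recycles against vector positions
downstream_dist <- function(a, b, strand) {
  (b - a) * ifelse(strand == "+", 1L, -1L)
}

# strand-aware position at offset o downstream of pos
offset_pos <- function(pos, o, strand) {
  pos + o * ifelse(strand == "+", 1L, -1L)
}

# pick the 5'-most element of positions (strand-aware deterministic tie-break)
five_prime_most <- function(pos, strand) {
  if (strand == "+") min(pos) else max(pos)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fraction of A/T bases in a character scalar (NA-safe)
at_fraction <- function(s) {
  if (is.na(s) || nchar(s) == 0L) return(NA_real_)
  b <- strsplit(s, "")[[1]]
  mean(b %in% c("A", "T"))
}

stop_if_not_df <- function(x, cols, what) {
  if (!is.data.frame(x) || !all(cols %in% names(x))) {
    stop(sprintf("%s must be a data.frame with columns: %s",
                 what, paste(cols, collapse = ", ")), call. = FALSE)
  }
}
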