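#' Read a small-RNA FASTQ library
#'
#' Reads a 4-line-record FASTQ file (plain or gz) into a read table tagged
#' with its pool of origin. Qualities are checked for length consistency and
#' then dropped: the downstream pipeline is exact-match only.
#'
#' @param path FASTQ path (`.gz` accepted).
#' @param pool `"total"` (total small RNAs, <=200 nt) or `"IP"`
#'   (Ago-immunoprecipitated, RISC-associated RNAs).
#' @return A data.frame with columns `id`, `seq` (uppercase), `pool`.
#' @export
read_small_rna_fastq <- function(path, pool = c("total", "IP")) {
  pool <- match.arg(pool)
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) {
    warning("empty FASTQ: ", path)
    return(empty_reads(pool))
  }
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ '", path, "': record ",
         length(lines) %/% 4L + 1L, " is incomplete")
  }
  idx <- seq(1L, length(lines), by = 4L)
  heads <- lines[idx]
  seqs <- toupper(lines[idx + 1L])
  quals <- lines[idx + 3L]
  badh <- !startsWith(heads, "@")
  if (any(badh)) {
    stop("malformed FASTQ '", path, "': record ", which(badh)[1L],
         " does not start with '@'")
  }
  badq <- nchar(seqs) != nchar(quals)
  if (any(badq)) {
    stop("FASTQ '", path, "': sequence/quality length mismatch in record ",
         which(badq)[1L])
  }
  badc <- grepl("[^ACGTN]", seqs)
  if (any(badc)) {
    stop("FASTQ '", path, "': non-ACGTN base in record ", which(badc)[1L])
  }
  data.frame(id = sub("^@", "", sub("\\s.*$", "", heads)),
             seq = seqs, pool = pool, stringsAsFactors = FALSE)
}

empty_reads <- function(pool) {
  data.frame(id = character(0), seq = character(0),
             pool = character(0), stringsAsFactors = FALSE)
}

#' Trim the 3' sequencing adapter from read sequences
#'
#' The insert is everything 5' of the left-most exact occurrence of the full
#' adapter. When the full adapter is absent (insert longer than
#' read-length minus adapter), the longest read suffix equal to an adapter
#' prefix of at least `min_overlap` nt is removed instead. Reads showing
#' neither are returned `NA` (dropped) unless `keep_untrimmed = TRUE`, in
#' which case they pass through untouched: a genuine <=200-nt small-RNA
#' insert shorter than the read must exhibit the adapter.
#'
#' @param seq Character vector of read sequences.
#' @param adapter 3' adapter sequence (DNA, non-empty).
#' @param min_overlap Minimum suffix/prefix overlap for partial matches
#'   (default 5).
#' @param keep_untrimmed Keep reads with no adapter evidence as-is?
#' @return Character vector of inserts; `NA` marks dropped reads.
#' @export
trim_adapter <- function(seq, adapter, min_overlap = 5L,
                         keep_untrimmed = FALSE) {
  stopifnot(nzchar(adapter), min_overlap >= 1L)
  adapter <- toupper(adapter)
  pos <- unname(stringi::stri_locate_first_fixed(seq, adapter)[, 1L])
  out <- ifelse(is.na(pos), seq, substr(seq, 1L, pos - 1L))
  partial <- which(is.na(pos))
  for (i in partial) {
    r <- seq[i]
    n <- nchar(r)
    maxov <- min(n, nchar(adapter) - 1L)
    hit <- NA_integer_
    if (maxov >= min_overlap) {
      for (ov in maxov:min_overlap) {
        if (substr(r, n - ov + 1L, n) == substr(adapter, 1L, ov)) {
          hit <- ov
          break
        }
      }
    }
    if (!is.na(hit)) {
      out[i] <- substr(r, 1L, n - hit)
    } else if (!keep_untrimmed) {
      out[i] <- NA_character_
    }
  }
  out
}

#' Trim and length-filter a read table
#'
#' Applies [trim_adapter()] then [length_filter()]; drop counts are reported
#' via `message()`.
#'
#' @param reads Read table from [read_small_rna_fastq()].
#' @inheritParams trim_adapter
#' @param min_len Minimum retained insert length (default 15 nt).
#' @return The read table with trimmed `seq`, adapterless and short reads
#'   removed.
#' @export
prepare_reads <- function(reads, adapter, min_overlap = 5L,
                          keep_untrimmed = FALSE, min_len = 15L) {
  ins <- trim_adapter(reads$seq, adapter, min_overlap, keep_untrimmed)
  drop <- is.na(ins)
  if (any(drop)) {
    message("readprep\tinfo\tdropped ", sum(drop), " read(s) with no adapter")
  }
  reads <- reads[!drop, , drop = FALSE]
  reads$seq <- ins[!drop]
  length_filter(reads, min_len)
}

#' Retain reads of at least a minimum length
#'
#' @param reads Read table (column `seq`).
#' @param min_len Minimum length in nt (default 15).
#' @return Filtered read table.
#' @export
length_filter <- function(reads, min_len = 15L) {
  keep <- nchar(reads$seq) >= min_len
  if (any(!keep)) {
    message("readprep\tinfo\tdropped ", sum(!keep),
            " read(s) shorter than ", min_len, " nt")
  }
  reads[keep, , drop = FALSE]
}
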