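#' Build an exact-substring lookup index over mature miRNAs
#'
#' Enumerates every substring of length >= `min_len` of every mature
#' sequence into a hash, so each read resolves in one lookup. This is the
#' 0-mismatch, end-to-end analogue of Bowtie `-v 0` against the mature
#' library: no indels, no soft clipping. Results are required (and tested)
#' to equal a naive all-pairs substring scan.
#'
#' @param matures A `mature_ref` table.
#' @param min_len Shortest indexable read (default 15 nt).
#' @return A `mature_index` object.
#' @export
build_mature_index <- function(matures, min_len = 15L) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(matures))) {
    s <- matures$seq[i]
    L <- nchar(s)
    if (L < min_len) next
    for (l in min_len:L) {
      for (st in 1L:(L - l + 1L)) {
        key <- substr(s, st, st + l - 1L)
        cur <- env[[key]]
        if (is.null(cur)) {
          env[[key]] <- cbind(i, st - 1L)
        } else if (!any(cur[, 1L] == i)) {
          # st ascending per length: the first stored offset is left-most
          env[[key]] <- rbind(cur, c(i, st - 1L))
        }
      }
    }
  }
  structure(list(env = env, min_len = min_len, ids = matures$id),
            class = "mature_index")
}

#' Match one read against the mature miRNA library (0 mismatches)
#'
#' A read hits every mature that contains it as an exact contiguous
#' substring (left-most offset per mature). A read matching k matures gets
#' weight 1/k per hit so counts are conserved; reads containing `N` match
#' nothing.
#'
#' @param read A single read sequence (>= `min_len` nt).
#' @param matures A `mature_ref` table (ignored if `index` is given).
#' @param index Optional prebuilt [build_mature_index()] result.
#' @return A data.frame with columns `mirna_id`, `offset` (0-based start of
#'   the read within the mature), `weight`; zero rows if unmatched.
#' @export
match_mature <- function(read, matures = NULL, index = NULL) {
  if (is.null(index)) index <- build_mature_index(matures)
  stopifnot(length(read) == 1L, nchar(read) >= index$min_len)
  hit <- index$env[[read]]
  if (is.null(hit)) {
    return(data.frame(mirna_id = character(0), offset = integer(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  }
  k <- nrow(hit)
  data.frame(mirna_id = index$ids[hit[, 1L]], offset = as.integer(hit[, 2L]),
             weight = rep(1 / k, k), stringsAsFactors = FALSE)
}

#' Does a read align exactly to any hairpin?
#'
#' @param read Character vector of read sequences.
#' @param hairpins A `hairpin_ref` table.
#' @return Logical vector: `TRUE` iff the read is an exact contiguous
#'   substring of at least one hairpin.
#' @export
match_hairpin <- function(read, hairpins) {
  if (length(read) == 0L) return(logical(0))
  # '#' separator cannot occur in ACGT(N) reads, so no cross-boundary hits
  hay <- paste(hairpins$seq, collapse = "#")
  stringi::stri_detect_fixed(hay, read)
}

#' Count miRNA-aligned reads for one library
#'
#' Assigns every read by exact substring match to the mature library and
#' accumulates (fractionally weighted) counts per miRNA. Unmatched reads are
#' excluded from `total_aligned` but kept in the `unaligned` tally, so
#' `total_aligned + unaligned` equals the number of input reads.
#'
#' @param reads Read table (column `seq`; trimmed and length-filtered).
#' @param matures A `mature_ref` table (ignored if `index` is given).
#' @param pool `"total"` or `"IP"`.
#' @param index Optional prebuilt [build_mature_index()].
#' @return A `pool_counts` object: list with `pool`, `counts` (named numeric
#'   over all mature ids), `total_aligned`, `unaligned`.
#' @export
count_pool <- function(reads, matures = NULL, pool = c("total", "IP"),
                       index = NULL) {
  pool <- match.arg(pool)
  if (is.null(index)) index <- build_mature_index(matures)
  counts <- stats::setNames(numeric(length(index$ids)), index$ids)
  unaligned <- 0
  tab <- table(reads$seq)
  for (j in seq_along(tab)) {
    s <- names(tab)[j]
    n <- as.numeric(tab[j])
    hit <- if (nchar(s) >= index$min_len) index$env[[s]] else NULL
    if (is.null(hit)) {
      unaligned <- unaligned + n
    } else {
      k <- nrow(hit)
      ids <- index$ids[hit[, 1L]]
      counts[ids] <- counts[ids] + n / k
    }
  }
  structure(list(pool = pool, counts = counts,
                 total_aligned = sum(counts), unaligned = unaligned),
            class = "pool_counts")
}

#' @export
print.pool_counts <- function(x, ...) {
  cat("pool_counts (", x$pool, "): ", sum(x$counts > 0), " of ",
      length(x$counts), " miRNAs detected; ", format(x$total_aligned),
      " aligned, ", format(x$unaligned), " unaligned\n", sep = "")
  invisible(x)
}
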