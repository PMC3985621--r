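#' Classify reads as 3'-tailed isomiRs
#'
#' Implements the hairpin-exclusion tail classifier. Per read:
#' \enumerate{
#'   \item A read that aligns exactly (0 mismatches) anywhere within a
#'     hairpin is templated: it is assigned by the prefix rule below but can
#'     never be tailed.
#'   \item Otherwise, among matures whose full sequence is an exact prefix
#'     of the read (enforcing a discrete, shared 5' start site), the read is
#'     assigned to the mature of length closest to the read length, i.e. the
#'     shortest 3' extension; length ties break lexicographically by id.
#'     No candidate: the read is left uncalled.
#'   \item The 3' extension is checked against every hairpin capable of
#'     generating the assigned mature, at the position immediately 3' of the
#'     mature's occurrence(s) (or anywhere in those hairpins with
#'     `extension_check = "anywhere"`). Only if no generating hairpin
#'     explains the extension is the read called tailed.
#' }
#' Extensions containing `N` are returned with `tailed = NA`
#' (undetermined) and excluded from tail-percentage denominators.
#'
#' @param reads Read table (columns `seq`, `pool`, optionally `id`), trimmed
#'   and length-filtered.
#' @param matures A linked `mature_ref` table ([link_matures()]); matures
#'   without generating hairpins are skipped as assignment targets.
#' @param hairpins A `hairpin_ref` table.
#' @param extension_check `"positional"` (default) or `"anywhere"`.
#' @return A data.frame of calls: `read_id`, `pool`, `mirna_id`, `tail_seq`,
#'   `tailed`, `templated`. Uncalled reads are omitted.
#' @export
call_tails <- function(reads, matures, hairpins,
                       extension_check = c("positional", "anywhere")) {
  extension_check <- match.arg(extension_check)
  stopifnot(inherits(matures, "mature_ref"), inherits(hairpins, "hairpin_ref"))
  if (is.null(matures$hairpin_ids)) {
    stop("matures are not linked to hairpins; run link_matures() first")
  }
  usable <- lengths(matures$hairpin_ids) > 0L
  if (any(!usable)) {
    message("tailcall\tinfo\tskipping ", sum(!usable),
            " mature(s) with no generating hairpin")
  }
  mat <- matures[usable, , drop = FALSE]
  # seq -> sorted ids (identical sequences at different loci tie-break by id)
  seq2ids <- split(mat$id, mat$seq)
  seq2ids <- lapply(seq2ids, sort)
  mat_lens <- sort(unique(nchar(names(seq2ids))), decreasing = TRUE)
  id2row <- match(mat$id, mat$id)
  names(id2row) <- mat$id
  hp_seq <- stats::setNames(hairpins$seq, hairpins$id)

  if (is.null(reads$id)) reads$id <- paste0("read", seq_len(nrow(reads)))
  useq <- unique(reads$seq)
  in_hairpin <- match_hairpin(useq, hairpins)
  names(in_hairpin) <- useq

  call_one <- function(s) {
    n <- nchar(s)
    assigned <- NULL
    for (L in mat_lens) {
      if (L > n) next
      ids <- seq2ids[[substr(s, 1L, L)]]
      if (!is.null(ids)) {
        assigned <- ids[1L]
        break
      }
    }
    if (is.null(assigned)) return(NULL)
    ext <- substr(s, nchar(mat$seq[id2row[assigned]]) + 1L, n)
    if (in_hairpin[[s]]) {
      return(list(mirna_id = assigned, tail_seq = ext, tailed = FALSE,
                  templated = nzchar(ext)))
    }
    if (!nzchar(ext)) {
      return(list(mirna_id = assigned, tail_seq = "", tailed = FALSE,
                  templated = FALSE))
    }
    if (grepl("N", ext, fixed = TRUE)) {
      return(list(mirna_id = assigned, tail_seq = ext, tailed = NA,
                  templated = FALSE))
    }
    mseq <- mat$seq[id2row[assigned]]
    hps <- mat$hairpin_ids[[id2row[assigned]]]
    templ <- FALSE
    for (h in hps) {
      hs <- hp_seq[[h]]
      if (extension_check == "anywhere") {
        if (stringi::stri_detect_fixed(hs, ext)) {
          templ <- TRUE
          break
        }
      } else {
        occ <- stringi::stri_locate_all_fixed(hs, mseq)[[1L]]
        for (k in seq_len(nrow(occ))) {
          after <- occ[k, 2L] + 1L
          if (substr(hs, after, after + nchar(ext) - 1L) == ext) {
            templ <- TRUE
            break
          }
        }
        if (templ) break
      }
    }
    list(mirna_id = assigned, tail_seq = ext, tailed = !templ,
         templated = templ)
  }

  ucall <- lapply(useq, call_one)
  names(ucall) <- useq
  keep <- !vapply(ucall[reads$seq], is.null, logical(1))
  got <- ucall[reads$seq[keep]]
  data.frame(
    read_id = reads$id[keep],
    pool = reads$pool[keep],
    mirna_id = vapply(got, `[[`, character(1), "mirna_id"),
    tail_seq = vapply(got, `[[`, character(1), "tail_seq"),
    tailed = vapply(got, `[[`, logical(1), "tailed"),
    templated = vapply(got, `[[`, logical(1), "templated"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Per-miRNA tailing summary for one pool
#'
#' @param calls Tail calls from [call_tails()] (a single pool). Calls with
#'   `tailed = NA` (undetermined extensions) are excluded from denominators.
#' @return A data.frame `mirna_id`, `pool`, `n_reads`, `n_tailed`,
#'   `pct_tailed`.
#' @export
summarize_tails <- function(calls) {
  ok <- !is.na(calls$tailed)
  calls <- calls[ok, , drop = FALSE]
  if (nrow(calls) == 0L) {
    return(data.frame(mirna_id = character(0), pool = character(0),
                      n_reads = integer(0), n_tailed = integer(0),
                      pct_tailed = numeric(0), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(cbind(n_reads = rep(1L, nrow(calls)),
                                n_tailed = as.integer(calls$tailed)) ~
                            mirna_id + pool, data = calls, FUN = sum)
  agg$pct_tailed <- 100 * agg$n_tailed / agg$n_reads
  agg[order(agg$pool, agg$mirna_id), , drop = FALSE]
}

#' Tail sequence composition table
#'
#' Counts of each distinct tail sequence among tailed reads, per miRNA and
#' pool, with tail length binned at 1, 2, 3, >=4 nt for reporting.
#'
#' @param calls Tail calls from [call_tails()].
#' @return A data.frame `mirna_id`, `pool`, `tail_seq`, `tail_len_bin`,
#'   `count`.
#' @export
tail_composition <- function(calls) {
  t <- calls[!is.na(calls$tailed) & calls$tailed, , drop = FALSE]
  if (nrow(t) == 0L) {
    return(data.frame(mirna_id = character(0), pool = character(0),
                      tail_seq = character(0), tail_len_bin = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(list(count = rep(1L, nrow(t))),
                          by = list(mirna_id = t$mirna_id, pool = t$pool,
                                    tail_seq = t$tail_seq), FUN = sum)
  len <- nchar(agg$tail_seq)
  agg$tail_len_bin <- ifelse(len >= 4L, ">=4", as.character(len))
  agg[order(agg$pool, agg$mirna_id, -agg$count), , drop = FALSE]
}

#' Ratio of tailing in the total versus RISC-associated pool
#'
#' Values > 1 mean tailing is enriched in the total pool; if the free miRNA
#' pool were enriched for degradation-bound (tailed) species, ratios should
#' systematically exceed 1.
#'
#' @param pct_total,pct_ip Percent tailed per miRNA in each pool.
#' @return `pct_total / pct_ip`; `NA` (undefined, excluded from summaries)
#'   where `pct_ip == 0` while `pct_total > 0`.
#' @export
tail_ratio <- function(pct_total, pct_ip) {
  ifelse(pct_ip > 0, pct_total / pct_ip,
         ifelse(pct_total > 0, NA_real_, 0))
}

#' Fold prevalence of each tail sequence, total versus IP pool
#'
#' For each distinct tail sequence, the fraction of tailed reads carrying it
#' in the total pool divided by the same fraction in the IP pool.
#'
#' @param calls_total,calls_ip Tail calls for the two pools.
#' @return A data.frame `tail_seq`, `frac_total`, `frac_ip`, `fold`.
#' @export
tail_enrichment_by_sequence <- function(calls_total, calls_ip) {
  frac <- function(calls) {
    t <- calls[!is.na(calls$tailed) & calls$tailed, , drop = FALSE]
    if (nrow(t) == 0L) return(numeric(0))
    tab <- table(t$tail_seq)
    stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  }
  ft <- frac(calls_total)
  fi <- frac(calls_ip)
  seqs <- sort(union(names(ft), names(fi)))
  ftv <- ifelse(seqs %in% names(ft), ft[seqs], 0)
  fiv <- ifelse(seqs %in% names(fi), fi[seqs], 0)
  data.frame(tail_seq = seqs, frac_total = unname(ftv), frac_ip = unname(fiv),
             fold = unname(ifelse(fiv > 0, ftv / fiv,
                                  ifelse(ftv > 0, Inf, NA_real_))),
             stringsAsFactors = FALSE)
}
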