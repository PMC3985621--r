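#' Per-miRNA percent shares of a library
#'
#' Normalizes counts to total miRNA-aligned reads, as percentages summing
#' to 100.
#'
#' @param counts A `pool_counts` object or named numeric vector.
#' @return Named numeric vector of percent shares.
#' @export
mirna_shares <- function(counts) {
  if (inherits(counts, "pool_counts")) counts <- counts$counts
  tot <- sum(counts)
  if (tot <= 0) stop("no miRNA-aligned reads: cannot compute shares")
  100 * counts / tot
}

#' RISC-association ratio from paired shares
#'
#' The ratio of a miRNA's percent share in the IP (RISC-associated) pool to
#' its share in the total pool. Because both share vectors sum to 100%, a
#' ratio of 1 is the "average miRNA" line; >1 means preferentially RISC
#' associated. One-sided detections give `Inf` (IP only) or `0`
#' (total only); both-zero gives `NA`.
#'
#' @param share_ip,share_total Percent shares (same length).
#' @return A data.frame with columns `ratio` and `log2_ratio`.
#' @export
risc_ratio <- function(share_ip, share_total) {
  ratio <- ifelse(share_total > 0, share_ip / share_total,
                  ifelse(share_ip > 0, Inf, NA_real_))
  data.frame(ratio = ratio, log2_ratio = log2(ratio))
}

#' Quantify differential RISC association from paired pool counts
#'
#' The core quantification: per-miRNA shares in both pools, fold-over-average
#' RISC-association ratio, expression gating and 2-fold classification.
#' miRNAs detected in only one pool receive `pseudocount` reads in the empty
#' pool before shares are computed (keeping log2 ratios finite) and are
#' flagged `one_pool_only`; miRNAs absent from both pools are dropped.
#'
#' @param counts_total,counts_ip `pool_counts` objects (or named numeric
#'   count vectors) for the total and IP libraries.
#' @param pseudocount Reads added to the empty pool of one-sided detections
#'   (default 0.5).
#' @param threshold_percent Expression gate, percent (default 0.1).
#' @param gate_mode `"either_pool"` (share >= threshold in total and/or IP,
#'   default) or `"total"`.
#' @param fold_threshold Fold line for over/under classification (default 2).
#' @return A `mirna_quant` data.frame: `mirna_id`, `count_total`, `count_ip`,
#'   `share_total`, `share_ip`, `ratio`, `log2_ratio`, `assoc_class`,
#'   `expressed`, `one_pool_only`.
#' @export
risc_quant <- function(counts_total, counts_ip, pseudocount = 0.5,
                       threshold_percent = 0.1,
                       gate_mode = c("either_pool", "total"),
                       fold_threshold = 2) {
  gate_mode <- match.arg(gate_mode)
  if (inherits(counts_total, "pool_counts")) counts_total <- counts_total$counts
  if (inherits(counts_ip, "pool_counts")) counts_ip <- counts_ip$counts
  ids <- union(names(counts_total), names(counts_ip))
  ct <- stats::setNames(numeric(length(ids)), ids)
  cip <- ct
  ct[names(counts_total)] <- counts_total
  cip[names(counts_ip)] <- counts_ip
  keep <- ct > 0 | cip > 0
  ids <- ids[keep]
  ct <- ct[keep]
  cip <- cip[keep]
  one_pool <- (ct == 0) != (cip == 0)
  ct[ct == 0] <- pseudocount
  cip[cip == 0] <- pseudocount
  share_total <- mirna_shares(ct)
  share_ip <- mirna_shares(cip)
  rr <- risc_ratio(share_ip, share_total)
  quants <- data.frame(mirna_id = ids, count_total = unname(ct),
                       count_ip = unname(cip),
                       share_total = unname(share_total),
                       share_ip = unname(share_ip),
                       ratio = rr$ratio, log2_ratio = rr$log2_ratio,
                       one_pool_only = unname(one_pool),
                       stringsAsFactors = FALSE)
  quants <- expression_gate(quants, threshold_percent, gate_mode)
  quants <- classify_association(quants, fold_threshold)
  class(quants) <- c("mirna_quant", "data.frame")
  quants
}

#' Flag miRNAs passing the expression gate
#'
#' A miRNA is "expressed" if its share is at or above `threshold_percent`
#' in the total pool (`mode = "total"`) or in the total and/or IP pool
#' (`mode = "either_pool"`, the default). The gate is inclusive.
#'
#' @param quants A `mirna_quant` data.frame (columns `share_total`,
#'   `share_ip`).
#' @param threshold_percent Gate in percent (default 0.1).
#' @param mode `"either_pool"` or `"total"`.
#' @return `quants` with a logical `expressed` column.
#' @export
expression_gate <- function(quants, threshold_percent = 0.1,
                            mode = c("either_pool", "total")) {
  mode <- match.arg(mode)
  quants$expressed <- if (mode == "total") {
    quants$share_total >= threshold_percent
  } else {
    quants$share_total >= threshold_percent |
      quants$share_ip >= threshold_percent
  }
  quants
}

#' Classify miRNAs by fold difference from the average
#'
#' `over` iff ratio > `fold_threshold`, `under` iff ratio <
#' 1/`fold_threshold`, otherwise `average`. Inequalities are strict: a miRNA
#' sitting exactly on a 2-fold line is `average`.
#'
#' @param quants A `mirna_quant` data.frame (column `ratio`).
#' @param fold_threshold Fold line (default 2).
#' @return `quants` with an `assoc_class` column.
#' @export
classify_association <- function(quants, fold_threshold = 2) {
  r <- quants$ratio
  quants$assoc_class <- ifelse(is.na(r), NA_character_,
                        ifelse(r > fold_threshold, "over",
                        ifelse(r < 1 / fold_threshold, "under", "average")))
  quants
}

#' Pool miRNAs sharing a seed into families
#'
#' Reads specific to same-seed miRNAs (which repress the same targets) are
#' summed per pool; the family ratio is recomputed from the pooled shares,
#' not averaged over member ratios.
#'
#' @param quants A `mirna_quant` data.frame.
#' @param families Named list: family id -> character vector of member
#'   `mirna_id`s. Default [default_seed_families()].
#' @return A data.frame with `family_id`, `members`, `n_members`,
#'   `share_total`, `share_ip`, `ratio`, `log2_ratio`.
#' @export
pool_families <- function(quants, families = default_seed_families()) {
  stopifnot(is.list(families), length(families) > 0)
  rows <- lapply(names(families), function(fam) {
    members <- families[[fam]]
    miss <- setdiff(members, quants$mirna_id)
    if (length(miss) > 0) {
      stop("family '", fam, "' has unknown member(s): ",
           paste(miss, collapse = ", "))
    }
    sel <- quants[match(members, quants$mirna_id), ]
    st <- sum(sel$share_total)
    si <- sum(sel$share_ip)
    rr <- risc_ratio(si, st)
    data.frame(family_id = fam, members = paste(members, collapse = ","),
               n_members = length(members), share_total = st, share_ip = si,
               ratio = rr$ratio, log2_ratio = rr$log2_ratio,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Seed families pooled for the sensor analyses
#'
#' Three same-seed groups whose members a single bulged sensor cannot
#' distinguish: miR-92a-3p/miR-92b-3p/miR-25-3p, miR-30a-3p/miR-30e-3p, and
#' miR-125a-5p/miR-125b-5p.
#'
#' @return Named list of member-id character vectors.
#' @export
default_seed_families <- function() {
  list(
    "miR-92-3p"  = c("hsa-miR-92a-3p", "hsa-miR-92b-3p", "hsa-miR-25-3p"),
    "miR-30-3p"  = c("hsa-miR-30a-3p", "hsa-miR-30e-3p"),
    "miR-125-5p" = c("hsa-miR-125a-5p", "hsa-miR-125b-5p")
  )
}

#' Spread between the most and least RISC-associated miRNAs
#'
#' Maximum over minimum RISC-association ratio among expressed miRNAs with
#' finite, two-sided (not pseudocounted) ratios.
#'
#' @param quants A `mirna_quant` data.frame, or any data.frame with columns
#'   `ratio` and `expressed` (and optionally `one_pool_only`, `mirna_id`).
#' @return List with `spread`, `ratio_max`, `ratio_min`, `max_id`, `min_id`.
#' @export
extreme_spread <- function(quants) {
  ok <- quants$expressed & is.finite(quants$ratio) & quants$ratio > 0
  if (!is.null(quants$one_pool_only)) ok <- ok & !quants$one_pool_only
  if (sum(ok) < 2L) stop("need >= 2 expressed miRNAs with finite ratios")
  r <- quants$ratio[ok]
  ids <- if (is.null(quants$mirna_id)) rep(NA_character_, sum(ok))
         else quants$mirna_id[ok]
  list(spread = max(r) / min(r), ratio_max = max(r), ratio_min = min(r),
       max_id = ids[which.max(r)], min_id = ids[which.min(r)])
}

#' RISC-bound percentage implied by fold-over-average ratios
#'
#' Under the assumption that the most RISC-associated miRNA is 100% bound in
#' RISC, a miRNA with association ratio `ratio_i` is
#' `100 * ratio_i / ratio_max` percent RISC-bound.
#'
#' @param ratio_i Association ratio of the miRNA of interest (> 0).
#' @param ratio_max Largest association ratio observed (>= `ratio_i`).
#' @return Implied percentage in RISC.
#' @export
implied_risc_fraction <- function(ratio_i, ratio_max) {
  if (any(ratio_i <= 0) || any(ratio_max <= 0)) stop("ratios must be > 0")
  if (any(ratio_i > ratio_max)) stop("ratio_i exceeds ratio_max")
  100 * ratio_i / ratio_max
}
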