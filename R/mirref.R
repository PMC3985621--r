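#' Construct a mature miRNA reference table
#'
#' Builds the canonical mature-miRNA container used throughout the package:
#' one row per mature species with its identifier, sequence (uppercase DNA;
#' `U` is converted to `T` so reads from DNA sequencers compare directly),
#' length, and seed (nucleotides 2-8, the main determinant of target
#' recognition). Generating hairpins are attached later by [link_matures()].
#'
#' @param id Character vector of unique identifiers (e.g. `"hsa-miR-22-3p"`).
#' @param seq Character vector of sequences, RNA or DNA alphabet, any case.
#' @return A data.frame of class `mature_ref` with columns `id`, `seq`,
#'   `length`, `seed` and a list-column `hairpin_ids` (initially empty sets).
#' @export
mature_ref <- function(id, seq) {
  seq <- canonicalize_seq(seq, id)
  if (anyDuplicated(id)) {
    stop("duplicate mature identifiers: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  len <- nchar(seq)
  short <- len < 15L
  if (any(short)) {
    stop("mature sequences shorter than 15 nt: ",
         paste(id[short], collapse = ", "))
  }
  out <- data.frame(id = as.character(id), seq = seq, length = len,
                    seed = seed_sequence(seq), stringsAsFactors = FALSE)
  out$hairpin_ids <- replicate(nrow(out), character(0), simplify = FALSE)
  class(out) <- c("mature_ref", "data.frame")
  out
}

#' Construct a pre-miRNA hairpin reference table
#'
#' @param id Character vector of unique hairpin identifiers.
#' @param seq Character vector of hairpin sequences (canonicalized as in
#'   [mature_ref()]).
#' @return A data.frame of class `hairpin_ref` with columns `id`, `seq`.
#' @export
hairpin_ref <- function(id, seq) {
  seq <- canonicalize_seq(seq, id)
  if (anyDuplicated(id)) {
    stop("duplicate hairpin identifiers: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  out <- data.frame(id = as.character(id), seq = seq, stringsAsFactors = FALSE)
  class(out) <- c("hairpin_ref", "data.frame")
  out
}

# U -> T, uppercase, strict ACGT alphabet; names failing records in errors.
canonicalize_seq <- function(seq, id) {
  seq <- chartr("U", "T", toupper(as.character(seq)))
  bad <- grepl("[^ACGT]", seq) | !nzchar(seq)
  if (any(bad)) {
    stop("sequence with characters outside {A,C,G,T,U} in record(s): ",
         paste(id[bad], collapse = ", "))
  }
  seq
}

#' Seed sequence of a mature miRNA
#'
#' The seed is nucleotides 2 through 8 (1-based, inclusive; 7 nt). miRNAs
#' sharing a seed form a family and are pooled for sensor analyses.
#'
#' @param seq Character vector of mature sequences (>= 8 nt).
#' @return Character vector of 7-nt seeds.
#' @export
seed_sequence <- function(seq) {
  if (any(nchar(seq) < 8L)) stop("sequence shorter than 8 nt has no seed")
  substring(seq, 2L, 8L)
}

#' Read a miRBase-style FASTA reference
#'
#' Loads mature or hairpin sequences from FASTA (wrapped or unwrapped lines;
#' the header token before the first whitespace is the identifier).
#' Sequences are canonicalized to uppercase DNA (`U` -> `T`); any other
#' non-ACGT character is an error naming the record, as exact matching
#' cannot adjudicate ambiguity codes.
#'
#' @param path Path to a FASTA file.
#' @param kind `"mature"` or `"hairpin"`.
#' @return A `mature_ref` or `hairpin_ref` data.frame.
#' @export
read_mirna_fasta <- function(path, kind = c("mature", "hairpin")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  if (kind == "mature") mature_ref(ids, seqs) else hairpin_ref(ids, seqs)
}

#' Link mature miRNAs to their generating hairpins
#'
#' A hairpin can generate a mature iff the mature sequence occurs as a
#' contiguous substring of the hairpin. A mature may be generated by zero,
#' one, or several hairpins (paralogous loci); matures with no generating
#' hairpin are kept for quantification but warned about, since tail calling
#' requires hairpin context.
#'
#' @param matures A `mature_ref` table.
#' @param hairpins A `hairpin_ref` table.
#' @return `matures` with the `hairpin_ids` list-column filled.
#' @export
link_matures <- function(matures, hairpins) {
  stopifnot(inherits(matures, "mature_ref"), inherits(hairpins, "hairpin_ref"))
  matures$hairpin_ids <- lapply(matures$seq, function(s) {
    hairpins$id[stringi::stri_detect_fixed(hairpins$seq, s)]
  })
  n0 <- sum(lengths(matures$hairpin_ids) == 0L)
  if (n0 > 0L) {
    warning(n0, " mature miRNA(s) have no generating hairpin; ",
            "they are quantifiable but excluded from tail calling")
  }
  matures
}

#' G+C content of a sequence
#'
#' @param seq Character vector over {A,C,G,T}, non-empty.
#' @return Numeric vector of G+C fractions in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  if (any(!nzchar(seq)) || any(is.na(seq))) stop("empty sequence")
  if (any(grepl("[^ACGT]", seq))) stop("sequence outside {A,C,G,T}")
  (nchar(seq) - nchar(gsub("[GC]", "", seq))) / nchar(seq)
}

#' A+T content of a sequence
#'
#' Complement of [gc_content()]; `gc_content(s) + at_content(s) == 1`.
#'
#' @inheritParams gc_content
#' @return Numeric vector of A+T fractions.
#' @export
at_content <- function(seq) 1 - gc_content(seq)
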