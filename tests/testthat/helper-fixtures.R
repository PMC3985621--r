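# Shared hand-built fixtures and independent naive oracles.

# Two matures where M2 extends M1 by 2 nt, each with a hairpin giving known
# templated 3' context:
#   hp1 continues M1 with "GG...", hp2 continues M2 with "GG..."
toy_ref <- function() {
  m1 <- "ACGTACGTACGTACGTACGT"          # 20 nt
  m2 <- paste0(m1, "CA")                 # 22 nt, M1 is a prefix
  matures <- mature_ref(c("miR-a", "miR-b"), c(m1, m2))
  hairpins <- hairpin_ref(
    c("hp-a", "hp-b"),
    c(paste0("TTGG", m1, "GGCCAT"), paste0("AATT", m2, "GGGTTT"))
  )
  list(matures = link_matures(matures, hairpins), hairpins = hairpins,
       m1 = m1, m2 = m2)
}

make_reads <- function(seqs, pool = "total", ids = NULL) {
  if (is.null(ids)) {
    ids <- if (length(seqs)) paste0("r", seq_along(seqs)) else character(0)
  }
  data.frame(id = ids, seq = seqs, pool = rep(pool, length.out = length(seqs)),
             stringsAsFactors = FALSE)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Naive all-pairs substring oracle for read-vs-mature matching.
naive_match_mature <- function(read, matures) {
  hits <- lapply(seq_len(nrow(matures)), function(i) {
    p <- regexpr(read, matures$seq[i], fixed = TRUE)
    if (p > 0) data.frame(mirna_id = matures$id[i], offset = as.integer(p) - 1L)
    else NULL
  })
  do.call(rbind, hits)
}

# Naive all-windows substring oracle for read-vs-hairpin matching.
naive_match_hairpin <- function(read, hairpins) {
  any(vapply(hairpins$seq, function(h) {
    n <- nchar(read)
    H <- nchar(h)
    if (n > H) return(FALSE)
    any(vapply(1:(H - n + 1L), function(s) substr(h, s, s + n - 1L) == read,
               logical(1)))
  }, logical(1)))
}

# Naive recount oracle for count_pool.
naive_count <- function(seqs, matures) {
  counts <- setNames(numeric(nrow(matures)), matures$id)
  unaligned <- 0
  for (s in seqs) {
    hit <- naive_match_mature(s, matures)
    if (is.null(hit)) unaligned <- unaligned + 1
    else counts[hit$mirna_id] <- counts[hit$mirna_id] + 1 / nrow(hit)
  }
  list(counts = counts, unaligned = unaligned)
}

write_fastq_text <- function(path, ids, seqs, quals = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
}
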