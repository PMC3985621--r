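#' Simulate a mature + hairpin miRNA reference with known structure
#'
#' Generates random mature sequences, each embedded in at least one hairpin
#' with at least `context_min` nt of templated 3' context, and embeds a
#' configurable fraction of matures in a second hairpin (exercising the
#' "all hairpins capable of generating it" rule). Rejection sampling
#' guarantees that no mature occurs in an unrelated hairpin, occurs more
#' than once in its own hairpin, or is a substring of another mature — so
#' read-level ground truth stays unambiguous.
#'
#' @param n_mirnas Number of mature miRNAs.
#' @param mature_len_range Inclusive length range of matures (min >= 15).
#' @param hairpin_len_range Inclusive length range of hairpins
#'   (min >= max mature length + 10).
#' @param shared_fraction Fraction of matures embedded in two hairpins
#'   (default 0.2).
#' @param context_min Minimum templated 3' context, nt (default 4).
#' @param seed Optional RNG seed; a fixed seed gives identical references.
#' @return List with linked `matures` and `hairpins` tables.
#' @export
simulate_reference <- function(n_mirnas, mature_len_range = c(20L, 24L),
                               hairpin_len_range = c(70L, 100L),
                               shared_fraction = 0.2, context_min = 4L,
                               seed = NULL) {
  if (mature_len_range[1] < 15L) stop("mature length must be >= 15 nt")
  if (hairpin_len_range[1] < mature_len_range[2] + 10L) {
    stop("hairpins must be at least 10 nt longer than the longest mature")
  }
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rand_seq <- function(n) {
    paste(sample(bases, n, replace = TRUE), collapse = "")
  }

  mseqs <- character(0)
  while (length(mseqs) < n_mirnas) {
    cand <- rand_seq(sample(mature_len_range[1]:mature_len_range[2], 1L))
    clash <- any(stringi::stri_detect_fixed(mseqs, cand)) ||
      (length(mseqs) > 0 && any(stringi::stri_detect_fixed(cand, mseqs)))
    if (!clash) mseqs <- c(mseqs, cand)
  }
  mids <- sprintf("syn-miR-%03d", seq_len(n_mirnas))

  n_shared <- round(shared_fraction * n_mirnas)
  hp_ids <- character(0)
  hp_seqs <- character(0)
  make_hairpin <- function(mseq, hid) {
    L <- nchar(mseq)
    repeat {
      H <- sample(hairpin_len_range[1]:hairpin_len_range[2], 1L)
      left <- sample(0L:(H - L - context_min), 1L)
      hp <- paste0(if (left > 0) rand_seq(left) else "", mseq,
                   rand_seq(H - L - left))
      others <- mseqs[mseqs != mseq]
      ok <- stringi::stri_count_fixed(hp, mseq) == 1L &&
        !any(stringi::stri_detect_fixed(hp, others))
      if (ok) return(hp)
    }
  }
  for (i in seq_len(n_mirnas)) {
    hid <- sprintf("syn-mir-%03d", i)
    hp_ids <- c(hp_ids, hid)
    hp_seqs <- c(hp_seqs, make_hairpin(mseqs[i], hid))
    if (i <= n_shared) {
      hp_ids <- c(hp_ids, paste0(hid, "-2"))
      hp_seqs <- c(hp_seqs, make_hairpin(mseqs[i], hid))
    }
  }
  matures <- mature_ref(mids, mseqs)
  hairpins <- hairpin_ref(hp_ids, hp_seqs)
  matures <- link_matures(matures, hairpins)
  list(matures = matures, hairpins = hairpins)
}

#' Ground-truth manifest for a simulated experiment
#'
#' Draws the per-miRNA truth parameters that define a simulated pair of
#' libraries: cellular abundance `a_i` (log-normal, so a handful of miRNAs
#' dominate the library as in real small-RNA data), RISC loading fraction
#' `L_i` (log-uniform across three orders of magnitude), and tailing rate
#' `t_i` (log-uniform, spanning the <0.3% to >20% range seen across
#' miRNAs). The total pool samples miRNAs proportional to `a_i`, the IP
#' pool proportional to `a_i * L_i`, so the expected association ratio is
#' `L_i * sum(a) / sum(a * L)` (see [expected_association_ratios()]).
#'
#' @param matures A `mature_ref` table (typically from
#'   [simulate_reference()]).
#' @param depth Reads per pool (default 1e5).
#' @param adapter 3' adapter appended to every read (default: Illumina
#'   TruSeq small-RNA 3' adapter).
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance parameters
#'   (default 0 and 2.9; with ~1000 miRNAs the default sdlog puts roughly
#'   7-8% of species above a 0.1% share gate).
#' @param loading_log10_range Range of log10 loading fractions (default
#'   c(-3, 0): 0.1% to 100% in RISC).
#' @param tail_rate_range Range of per-miRNA tailing probabilities, sampled
#'   log-uniformly (default c(0.002, 0.2)).
#' @param tail_base_weights Sampling weights of tail bases (default A/T-rich:
#'   A 0.4, T 0.4, C 0.15, G 0.05).
#' @param templated_ext_rate Probability of a templated 3'-extension isomiR
#'   (default 0.05).
#' @param fiveprime_jitter_rate Probability of +/- 1 nt 5'-end heterogeneity
#'   (default 0.02).
#' @param seed Integer seed; fixed seed gives byte-identical libraries.
#' @param abundance,loading_fraction,tail_rate Optional explicit per-miRNA
#'   vectors overriding the random draws.
#' @return A `truth_manifest` object.
#' @export
truth_manifest <- function(matures, depth = 1e5,
                           adapter = "TGGAATTCTCGGGTGCCAAGG",
                           abundance_meanlog = 0, abundance_sdlog = 2.9,
                           loading_log10_range = c(-3, 0),
                           tail_rate_range = c(0.002, 0.2),
                           tail_base_weights = c(A = 0.4, T = 0.4,
                                                 C = 0.15, G = 0.05),
                           templated_ext_rate = 0.05,
                           fiveprime_jitter_rate = 0.02, seed = 1L,
                           abundance = NULL, loading_fraction = NULL,
                           tail_rate = NULL) {
  n <- nrow(matures)
  set.seed(seed)
  if (is.null(abundance)) {
    abundance <- stats::rlnorm(n, abundance_meanlog, abundance_sdlog)
  }
  if (is.null(loading_fraction)) {
    loading_fraction <- 10^stats::runif(n, loading_log10_range[1],
                                        loading_log10_range[2])
  }
  if (is.null(tail_rate)) {
    tail_rate <- exp(stats::runif(n, log(tail_rate_range[1]),
                                  log(tail_rate_range[2])))
  }
  stopifnot(length(abundance) == n, length(loading_fraction) == n,
            length(tail_rate) == n, all(abundance > 0),
            all(loading_fraction > 0), all(loading_fraction <= 1),
            all(tail_rate >= 0), all(tail_rate < 1))
  structure(list(
    mirna = data.frame(mirna_id = matures$id, abundance = abundance,
                       loading_fraction = loading_fraction,
                       tail_rate = tail_rate, stringsAsFactors = FALSE),
    depth = depth, adapter = toupper(adapter),
    tail_base_weights = tail_base_weights,
    templated_ext_rate = templated_ext_rate,
    fiveprime_jitter_rate = fiveprime_jitter_rate, seed = as.integer(seed)
  ), class = "truth_manifest")
}

#' Expected RISC-association ratios under a truth manifest
#'
#' @param manifest A `truth_manifest`.
#' @return Named vector of expected `share_ip / share_total` ratios,
#'   `L_i * sum(a) / sum(a * L)`.
#' @export
expected_association_ratios <- function(manifest) {
  a <- manifest$mirna$abundance
  L <- manifest$mirna$loading_fraction
  stats::setNames(L * sum(a) / sum(a * L), manifest$mirna$mirna_id)
}

#' Simulate paired total and IP small-RNA libraries
#'
#' Samples `depth` reads per pool (total pool proportional to abundance, IP
#' pool proportional to abundance x loading fraction). Each read is the
#' mature sequence, optionally extended by a templated 3' isomiR extension
#' copied from one generating hairpin, optionally tailed with 1-3
#' non-templated bases drawn from the A/T-rich tail law, then given
#' optional 5'-end jitter and the 3' adapter. The first tail base is
#' resampled whenever it would coincide with the templated continuation of
#' any generating hairpin, so a truth-tailed read is never explainable by a
#' hairpin and ground-truth labels stay exact; the number of such avoided
#' collisions is returned.
#'
#' @param reference A list with linked `matures` and `hairpins` (from
#'   [simulate_reference()] or loaded references).
#' @param manifest A [truth_manifest()].
#' @return List with `reads_total`, `reads_ip` (read tables with raw,
#'   adapter-bearing sequences), `truth` (per-read ground truth),
#'   `collisions_avoided`, and the `manifest`.
#' @export
simulate_libraries <- function(reference, manifest) {
  matures <- reference$matures
  hairpins <- reference$hairpins
  stopifnot(inherits(manifest, "truth_manifest"),
            identical(manifest$mirna$mirna_id, matures$id))
  hp_seq <- stats::setNames(hairpins$seq, hairpins$id)
  # per mature: templated continuation (6 nt) in each generating hairpin
  contexts <- lapply(seq_len(nrow(matures)), function(i) {
    vapply(matures$hairpin_ids[[i]], function(h) {
      hs <- hp_seq[[h]]
      p <- stringi::stri_locate_first_fixed(hs, matures$seq[i])[, 2L]
      substr(hs, p + 1L, p + 6L)
    }, character(1))
  })
  w <- manifest$tail_base_weights
  bases <- names(w)
  a <- manifest$mirna$abundance
  L <- manifest$mirna$loading_fraction
  t_rate <- manifest$mirna$tail_rate
  depth <- manifest$depth
  collisions <- 0L

  sample_pool <- function(pool, prob, stream) {
    if (sum(prob) <= 0) stop("zero-probability pool: ", pool)
    set.seed(manifest$seed + stream)
    idx <- sample.int(nrow(matures), depth, replace = TRUE, prob = prob)
    insert <- matures$seq[idx]
    ext_flag <- stats::runif(depth) < manifest$templated_ext_rate
    tail_flag <- stats::runif(depth) < t_rate[idx]
    jit_flag <- stats::runif(depth) < manifest$fiveprime_jitter_rate
    ext <- character(depth)
    for (r in which(ext_flag)) {
      conts <- contexts[[idx[r]]]
      cont <- conts[[sample.int(length(conts), 1L)]]
      ext[r] <- substr(cont, 1L, sample.int(3L, 1L))
    }
    tails <- character(depth)
    for (r in which(tail_flag)) {
      conts <- contexts[[idx[r]]]
      elen <- nchar(ext[r])
      # bases that would make the extension templated in some hairpin
      forbidden <- unique(vapply(conts, function(cont) {
        if (nchar(cont) >= elen + 1L &&
            substr(cont, 1L, elen) == ext[r]) {
          substr(cont, elen + 1L, elen + 1L)
        } else ""
      }, character(1)))
      forbidden <- forbidden[nzchar(forbidden)]
      tl <- sample.int(3L, 1L)
      tb <- sample(bases, tl, replace = TRUE, prob = w)
      if (tb[1L] %in% forbidden) {
        collisions <<- collisions + 1L
        ok <- setdiff(bases, forbidden)
        tb[1L] <- sample(ok, 1L, prob = w[ok])
      }
      tails[r] <- paste(tb, collapse = "")
    }
    insert <- paste0(insert, ext, tails)
    jitter <- character(depth)
    for (r in which(jit_flag)) {
      if (stats::runif(1) < 0.5) {
        insert[r] <- substr(insert[r], 2L, nchar(insert[r]))
        jitter[r] <- "trim5"
      } else {
        insert[r] <- paste0(sample(bases, 1L), insert[r])
        jitter[r] <- "ext5"
      }
    }
    ids <- sprintf("%s_%06d", pool, seq_len(depth))
    list(
      reads = data.frame(id = ids, seq = paste0(insert, manifest$adapter),
                         pool = pool, stringsAsFactors = FALSE),
      truth = data.frame(read_id = ids, pool = pool,
                         mirna_id = matures$id[idx],
                         tailed = tail_flag, tail_seq = tails,
                         templated_ext = ext, jitter = jitter,
                         stringsAsFactors = FALSE)
    )
  }

  tot <- sample_pool("total", a, 1L)
  ip <- sample_pool("IP", a * L, 2L)
  list(reads_total = tot$reads, reads_ip = ip$reads,
       truth = rbind(tot$truth, ip$truth),
       collisions_avoided = collisions, manifest = manifest)
}

#' Write a read table as FASTQ
#'
#' @param reads Read table (columns `id`, `seq`).
#' @param path Output path; `.gz` suffix writes gzip.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  qual <- strrep("I", nchar(reads$seq))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", qual), con)
  invisible(path)
}

#' Write a reference as FASTA
#'
#' @param ref A `mature_ref` or `hairpin_ref` table.
#' @param path Output FASTA path.
#' @export
write_reference_fasta <- function(ref, path) {
  writeLines(paste0(">", ref$id, "\n", ref$seq), path)
  invisible(path)
}

#' Write a full simulation bundle to a directory
#'
#' Emits `mature.fa`, `hairpin.fa`, `total.fastq.gz`, `ip.fastq.gz`,
#' `truth.tsv` and `manifest.yaml`.
#'
#' @param sim Result of [simulate_libraries()].
#' @param reference The reference used to simulate.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_reference_fasta(reference$matures, file.path(dir, "mature.fa"))
  write_reference_fasta(reference$hairpins, file.path(dir, "hairpin.fa"))
  write_fastq(sim$reads_total, file.path(dir, "total.fastq.gz"))
  write_fastq(sim$reads_ip, file.path(dir, "ip.fastq.gz"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  m <- sim$manifest
  yaml::write_yaml(list(
    depth = m$depth, adapter = m$adapter,
    tail_base_weights = as.list(m$tail_base_weights),
    templated_ext_rate = m$templated_ext_rate,
    fiveprime_jitter_rate = m$fiveprime_jitter_rate, seed = m$seed,
    mirna = m$mirna
  ), file.path(dir, "manifest.yaml"))
  invisible(dir)
}
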