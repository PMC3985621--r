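#' Default pipeline configuration
#'
#' Every tunable parameter of the pipeline with its default, suitable for
#' merging with user overrides; the resolved configuration is embedded in
#' the report bundle for provenance.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    adapter = "TGGAATTCTCGGGTGCCAAGG", min_overlap = 5L,
    keep_untrimmed = FALSE, min_len = 15L,
    pseudocount = 0.5, threshold_percent = 0.1,
    gate_mode = "either_pool", fold_threshold = 2,
    extension_check = "positional", families = NULL
  )
}

#' Run the full differential RISC-association pipeline
#'
#' Wires the stages end to end: load and link references, read and trim
#' both FASTQ libraries, count each pool by exact matching, quantify
#' RISC association (shares, ratios, gate, 2-fold classes, families), call
#' and summarize 3' tails, and compute the downstream statistics
#' (discrepancy count, extreme spread). Writes a report bundle of TSVs, a
#' stats JSON and a log file to `outdir`.
#'
#' @param config Named list (or path to a YAML file) with at least
#'   `mature_fa`, `hairpin_fa`, `fastq_total`, `fastq_ip`, `outdir`;
#'   optional keys override [default_config()]. `families` may be a named
#'   list or a YAML path mapping family id -> member ids; `NULL` pools the
#'   default seed families present in the data.
#' @return Invisibly, a list with `quant`, `families`, `tail_summary`,
#'   `tail_composition`, `stats`, `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  required <- c("mature_fa", "hairpin_fa", "fastq_total", "fastq_ip",
                "outdir")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0) {
    stop("config is missing: ", paste(missing, collapse = ", "))
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(cfg$outdir, "pipeline.log")
  logit <- function(stage, level, msg) {
    cat(sprintf("%s\t%s\t%s\n", stage, level, msg), file = logfile,
        append = TRUE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      logit(stage, "error", conditionMessage(e))
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ref <- run_stage("mirref", {
    matures <- read_mirna_fasta(cfg$mature_fa, "mature")
    hairpins <- read_mirna_fasta(cfg$hairpin_fa, "hairpin")
    suppressWarnings(list(matures = link_matures(matures, hairpins),
                          hairpins = hairpins))
  })
  logit("mirref", "info", sprintf("%d matures, %d hairpins",
                                  nrow(ref$matures), nrow(ref$hairpins)))

  reads <- run_stage("readprep", {
    rt <- read_small_rna_fastq(cfg$fastq_total, "total")
    ri <- read_small_rna_fastq(cfg$fastq_ip, "IP")
    suppressMessages(list(
      total = prepare_reads(rt, cfg$adapter, cfg$min_overlap,
                            cfg$keep_untrimmed, cfg$min_len),
      ip = prepare_reads(ri, cfg$adapter, cfg$min_overlap,
                         cfg$keep_untrimmed, cfg$min_len)
    ))
  })
  logit("readprep", "info", sprintf("retained %d total / %d IP reads",
                                    nrow(reads$total), nrow(reads$ip)))

  counts <- run_stage("matcher", {
    index <- build_mature_index(ref$matures, cfg$min_len)
    list(total = count_pool(reads$total, pool = "total", index = index),
         ip = count_pool(reads$ip, pool = "IP", index = index))
  })
  logit("matcher", "info",
        sprintf("aligned %.1f total / %.1f IP reads (%.1f / %.1f unaligned)",
                counts$total$total_aligned, counts$ip$total_aligned,
                counts$total$unaligned, counts$ip$unaligned))

  quant <- run_stage("riscquant", {
    risc_quant(counts$total, counts$ip, cfg$pseudocount,
               cfg$threshold_percent, cfg$gate_mode, cfg$fold_threshold)
  })

  fams <- run_stage("riscquant", {
    fl <- cfg$families
    if (is.character(fl) && length(fl) == 1L) fl <- yaml::read_yaml(fl)
    if (is.null(fl)) {
      fl <- Filter(function(m) all(m %in% quant$mirna_id),
                   default_seed_families())
    }
    if (length(fl) > 0) pool_families(quant, fl) else NULL
  })

  tails <- run_stage("tailcall", {
    ct <- suppressMessages(call_tails(reads$total, ref$matures,
                                      ref$hairpins, cfg$extension_check))
    ci <- suppressMessages(call_tails(reads$ip, ref$matures, ref$hairpins,
                                      cfg$extension_check))
    list(total = ct, ip = ci,
         summary = rbind(summarize_tails(ct), summarize_tails(ci)),
         composition = rbind(tail_composition(ct), tail_composition(ci)))
  })

  stats <- run_stage("assoc_stats", {
    disc <- discrepancy_count(quant, cfg$fold_threshold)
    spread <- tryCatch(extreme_spread(quant), error = function(e) NULL)
    list(
      n_mirnas_detected = nrow(quant),
      n_expressed = sum(quant$expressed),
      n_over = sum(quant$expressed & quant$assoc_class == "over"),
      n_under = sum(quant$expressed & quant$assoc_class == "under"),
      n_discrepant = disc$n_discrepant,
      extreme_spread = if (is.null(spread)) NULL else spread
    )
  })
  logit("assoc_stats", "info",
        sprintf("%d expressed; %d over / %d under; %d discrepant",
                stats$n_expressed, stats$n_over, stats$n_under,
                stats$n_discrepant))

  wt <- function(x, f) {
    utils::write.table(x, file.path(cfg$outdir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(quant[, setdiff(names(quant), "hairpin_ids")], "quant.tsv")
  if (!is.null(fams)) wt(fams, "families.tsv")
  wt(tails$summary, "tails_summary.tsv")
  wt(tails$composition, "tail_composition.tsv")
  scatter <- data.frame(mirna_id = quant$mirna_id,
                        log2_share_total = log2(quant$share_total),
                        log2_share_ip = log2(quant$share_ip))
  wt(scatter[quant$expressed, ], "scatter.tsv")
  report <- list(package_version = as.character(utils::packageVersion("riscload")),
                 config = cfg, stats = stats)
  jsonlite::write_json(report, file.path(cfg$outdir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  logit("pipeline", "info", "done")

  invisible(list(quant = quant, families = fams,
                 tail_summary = tails$summary,
                 tail_composition = tails$composition,
                 stats = stats, config = cfg))
}
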