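test_that("simulated references are deterministic and structurally sound", {
  r1 <- simulate_reference(10, shared_fraction = 0.2, seed = 71)
  r2 <- simulate_reference(10, shared_fraction = 0.2, seed = 71)
  expect_identical(r1$matures$seq, r2$matures$seq)
  expect_identical(r1$hairpins$seq, r2$hairpins$seq)
  # every mature links to its constructed hairpin(s)
  expect_true(all(lengths(r1$matures$hairpin_ids) >= 1))
  # duplicate-embedding fraction 0.2 of 10 -> exactly 2 doubly-linked matures
  expect_equal(sum(lengths(r1$matures$hairpin_ids) == 2), 2)
  # independent re-derivation of the links
  relinked <- link_matures(mature_ref(r1$matures$id, r1$matures$seq),
                           r1$hairpins)
  expect_identical(relinked$hairpin_ids, r1$matures$hairpin_ids)
  # >= 4 nt of templated 3' context everywhere
  for (i in seq_len(nrow(r1$matures))) {
    for (h in r1$matures$hairpin_ids[[i]]) {
      hs <- r1$hairpins$seq[r1$hairpins$id == h]
      p <- regexpr(r1$matures$seq[i], hs, fixed = TRUE)
      expect_gte(nchar(hs) - (p + nchar(r1$matures$seq[i]) - 1), 4)
    }
  }
  expect_error(simulate_reference(5, mature_len_range = c(12, 14)), ">= 15")
  expect_error(simulate_reference(5, hairpin_len_range = c(20, 30)),
               "10 nt longer")
})

test_that("simulated libraries are byte-identical under a fixed seed", {
  ref <- simulate_reference(12, seed = 73)
  man <- truth_manifest(ref$matures, depth = 500, seed = 74)
  s1 <- simulate_libraries(ref, man)
  s2 <- simulate_libraries(ref, man)
  expect_identical(s1$reads_total, s2$reads_total)
  expect_identical(s1$reads_ip, s2$reads_ip)
  expect_identical(s1$truth, s2$truth)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(s1, ref, d1)
  write_simulation(s2, ref, d2)
  for (f in c("mature.fa", "hairpin.fa", "total.fastq.gz", "ip.fastq.gz",
              "truth.tsv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("zero tailing rates give zero tailed truth and 0% called tails", {
  ref <- simulate_reference(10, seed = 79)
  man <- truth_manifest(ref$matures, depth = 2000, seed = 80,
                        tail_rate = rep(0, 10))
  sim <- simulate_libraries(ref, man)
  expect_equal(sum(sim$truth$tailed), 0)
  reads <- suppressMessages(prepare_reads(sim$reads_total, man$adapter))
  calls <- call_tails(reads, ref$matures, ref$hairpins)
  s <- summarize_tails(calls)
  expect_true(all(s$pct_tailed == 0))
})

test_that("equal loading fractions give association ratios near 1", {
  ref <- simulate_reference(10, seed = 83)
  man <- truth_manifest(ref$matures, depth = 2e4, seed = 84,
                        loading_fraction = rep(0.3, 10),
                        tail_rate = rep(0, 10), templated_ext_rate = 0,
                        fiveprime_jitter_rate = 0)
  expect_equal(unname(expected_association_ratios(man)), rep(1, 10))
  sim <- simulate_libraries(ref, man)
  rt <- suppressMessages(prepare_reads(sim$reads_total, man$adapter))
  ri <- suppressMessages(prepare_reads(sim$reads_ip, man$adapter))
  idx <- build_mature_index(ref$matures)
  q <- risc_quant(count_pool(rt, pool = "total", index = idx),
                  count_pool(ri, pool = "IP", index = idx))
  ok <- q$count_total >= 30 & q$count_ip >= 30
  expect_true(all(abs(log(q$ratio[ok])) <
                    3 * sqrt(1 / q$count_ip[ok] + 1 / q$count_total[ok])))
})

test_that("generated tails never equal the templated continuation", {
  ref <- simulate_reference(15, shared_fraction = 0.4, seed = 89)
  man <- truth_manifest(ref$matures, depth = 4000, seed = 90,
                        tail_rate = rep(0.3, 15))
  sim <- simulate_libraries(ref, man)
  tailed <- sim$truth[sim$truth$tailed, ]
  expect_gt(nrow(tailed), 0)
  hp <- setNames(ref$hairpins$seq, ref$hairpins$id)
  for (i in sample(nrow(tailed), min(200, nrow(tailed)))) {
    row <- tailed[i, ]
    m <- ref$matures[ref$matures$id == row$mirna_id, ]
    ext <- paste0(row$templated_ext, row$tail_seq)
    for (h in m$hairpin_ids[[1]]) {
      p <- regexpr(m$seq, hp[[h]], fixed = TRUE)
      cont <- substr(hp[[h]], p + nchar(m$seq),
                     p + nchar(m$seq) + nchar(ext) - 1)
      expect_false(cont == ext)
    }
  }
})

test_that("truth manifests expose the documented abundance law", {
  # draws only depend on the id table, so a large catalogue is cheap
  fake <- data.frame(id = sprintf("m%04d", 1:1000))
  man <- truth_manifest(fake, seed = 98)
  L <- man$mirna$loading_fraction
  expect_true(all(L > 0 & L <= 1))
  expect_gt(max(L) / min(L), 100)   # spans orders of magnitude
  share <- 100 * man$mirna$abundance / sum(man$mirna$abundance)
  # heavy-tailed: of ~1000 species only a small minority clears the 0.1%
  # gate, yet that minority carries most of the library
  expect_gt(mean(share >= 0.1), 0.03)
  expect_lt(mean(share >= 0.1), 0.15)
  expect_gt(sum(share[share >= 0.1]), 50)
})
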