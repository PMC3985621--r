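quant_from_shares <- function(share_total, share_ip, ids = NULL) {
  if (is.null(ids)) ids <- paste0("m", seq_along(share_total))
  rr <- risc_ratio(share_ip, share_total)
  q <- data.frame(mirna_id = ids, share_total = share_total,
                  share_ip = share_ip, ratio = rr$ratio,
                  log2_ratio = rr$log2_ratio, one_pool_only = FALSE,
                  stringsAsFactors = FALSE)
  classify_association(expression_gate(q))
}

test_that("shares normalize to percent and sum to 100", {
  expect_equal(mirna_shares(c(a = 50, b = 30, c = 20)),
               c(a = 50, b = 30, c = 20))
  expect_equal(mirna_shares(c(a = 1)), c(a = 100))
  expect_error(mirna_shares(c(a = 0, b = 0)), "no miRNA-aligned")
  set.seed(41)
  x <- setNames(runif(50, 0, 1000), paste0("m", 1:50))
  s <- mirna_shares(x)
  expect_equal(sum(s), 100, tolerance = 1e-12)
  expect_equal(s, 100 * x / sum(x))
})

test_that("association ratios match hand arithmetic", {
  expect_equal(risc_ratio(10, 2)$ratio, 5)
  expect_equal(risc_ratio(10, 2)$log2_ratio, log2(5), tolerance = 1e-12)
  expect_equal(risc_ratio(2, 2)$log2_ratio, 0)
  expect_equal(risc_ratio(1, 4)$ratio, 0.25)
  expect_equal(risc_ratio(1, 4)$log2_ratio, -2)
  expect_equal(risc_ratio(1, 0)$ratio, Inf)
  expect_equal(risc_ratio(0, 1)$ratio, 0)
  expect_true(is.na(risc_ratio(0, 0)$ratio))
})

test_that("the 0.1% expression gate is inclusive and pool-mode aware", {
  q <- quant_from_shares(c(0.09, 0.05, 0.1, 50, 49.76),
                         c(0.09, 0.2, 1e-6, 50, 49.71))
  expect_equal(q$expressed, c(FALSE, TRUE, TRUE, TRUE, TRUE))
  q_tot <- expression_gate(q, mode = "total")
  expect_equal(q_tot$expressed, c(FALSE, FALSE, TRUE, TRUE, TRUE))
})

test_that("2-fold classification uses strict boundaries", {
  q <- quant_from_shares(c(10, 10, 10, 10, 10, 50),
                         c(50, 4, 20, 5, 10.5, 10.5))
  expect_equal(q$ratio[1:5], c(5, 0.4, 2, 0.5, 1.05))
  expect_equal(q$assoc_class[1:5],
               c("over", "under", "average", "average", "average"))
})

test_that("risc_quant pseudocounts one-sided detections and keeps sums at 100", {
  ct <- c(a = 80, b = 19, c = 1, d = 0)
  ci <- c(a = 40, b = 58, c = 0, d = 2)
  q <- risc_quant(ct, ci, pseudocount = 0.5)
  expect_equal(sum(q$share_total), 100, tolerance = 1e-9)
  expect_equal(sum(q$share_ip), 100, tolerance = 1e-9)
  expect_equal(q$one_pool_only, c(FALSE, FALSE, TRUE, TRUE))
  expect_true(all(is.finite(q$log2_ratio)))
  # ratio for two-sided species matches direct arithmetic on shares
  expect_equal(q$ratio[q$mirna_id == "a"],
               (40 / 100.5 * 100) / (80 / 100.5 * 100))
})

test_that("shares and classes are invariant to per-pool count rescaling", {
  set.seed(43)
  ct <- setNames(rpois(30, 200) + 1, paste0("m", 1:30))
  ci <- setNames(rpois(30, 200) + 1, paste0("m", 1:30))
  q1 <- risc_quant(ct, ci)
  q2 <- risc_quant(ct * 17, ci * 0.03)
  expect_equal(q1$share_total, q2$share_total, tolerance = 1e-12)
  expect_equal(q1$share_ip, q2$share_ip, tolerance = 1e-12)
  expect_equal(q1$ratio, q2$ratio, tolerance = 1e-12)
  expect_identical(q1$assoc_class, q2$assoc_class)
  expect_identical(q1$expressed, q2$expressed)
})

test_that("classification is monotone in the ratio", {
  r <- sort(c(10^runif(50, -2, 2), 2, 0.5))
  q <- quant_from_shares(rep(10, length(r)), 10 * r)
  cls <- factor(q$assoc_class[order(q$ratio)],
                levels = c("under", "average", "over"))
  expect_true(all(diff(as.integer(cls)) >= 0))
})

test_that("family pooling sums shares and recomputes the ratio", {
  q <- quant_from_shares(c(3, 1, 0.5, 95.5), c(9, 1, 0.5, 89.5),
                         ids = c("hsa-miR-92a-3p", "hsa-miR-92b-3p",
                                 "hsa-miR-25-3p", "other"))
  fam <- pool_families(q, default_seed_families()["miR-92-3p"])
  expect_equal(fam$share_total, 4.5)
  expect_equal(fam$share_ip, 10.5)
  # pooled ratio is sum(ip)/sum(total), not the mean of member ratios
  expect_equal(fam$ratio, 10.5 / 4.5)
  expect_false(isTRUE(all.equal(fam$ratio, mean(q$ratio[1:3]))))
  # single-member family is the member itself
  f1 <- pool_families(q, list(solo = "other"))
  expect_equal(f1$ratio, q$ratio[4])
  expect_error(pool_families(q, list(bad = "absent-miR")), "unknown")
  # pooling never alters the underlying share sums
  expect_equal(sum(q$share_total), 100)
})

test_that("extreme spread and implied RISC fraction match brute force", {
  q <- quant_from_shares(rep(10, 3), 10 * c(59, 1, 1 / 31))
  es <- extreme_spread(q)
  expect_equal(es$spread, 59 * 31)
  expect_equal(es$max_id, "m1")
  expect_equal(es$min_id, "m3")
  # all equal ratios -> spread 1
  expect_equal(extreme_spread(quant_from_shares(c(30, 70), c(30, 70)))$spread, 1)
  set.seed(47)
  r <- 10^runif(40, -2, 2)
  q2 <- quant_from_shares(rep(2.5, 40), 2.5 * r)
  expect_equal(extreme_spread(q2)$spread, max(r) / min(r))

  expect_equal(implied_risc_fraction(1 / 31, 59), 100 / (59 * 31))
  expect_equal(implied_risc_fraction(5, 5), 100)
  expect_equal(implied_risc_fraction(2.5, 5), 50)
  expect_error(implied_risc_fraction(6, 5), "exceeds")
})
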