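eval_vcf <- function(pos, ref, alt, gt = "0/1") {
  n <- length(pos)
  recs <- data.frame(
    chrom = "chrT", pos = as.integer(pos), id = ".", ref = ref, alt = alt,
    qual = "100", filter = "PASS", info = ".", format = "GT:GQ:DP",
    S1 = paste(rep_len(gt, n), "99", "50", sep = ":"),
    stringsAsFactors = FALSE)
  vcf_object(recs, samples = "S1", contig_lengths = c(chrT = 100000L))
}

test_that("normalization trims to minimal left-anchored form", {
  v <- eval_vcf(100, "ATT", "AT")
  norm <- normalize_variants(v)
  expect_equal(norm[, c("pos", "ref", "alt")],
               data.frame(pos = 100L, ref = "AT", alt = "A"))
  # oracle: both spellings describe deleting one T from the TT run
  v2 <- eval_vcf(101, "TT", "T")
  norm2 <- normalize_variants(v2)
  expect_equal(norm2$ref, "TT")  # no shared trailing/leading beyond anchor
  # leading-base trim advances pos
  v3 <- eval_vcf(100, "CAT", "CGT")
  norm3 <- normalize_variants(v3)
  expect_equal(norm3[, c("pos", "ref", "alt")],
               data.frame(pos = 101L, ref = "A", alt = "G"))
  # idempotence
  v4 <- eval_vcf(norm$pos, norm$ref, norm$alt)
  expect_equal(normalize_variants(v4)[, c("pos", "ref", "alt")],
               norm[, c("pos", "ref", "alt")])
})

test_that("multiallelic records split and symbolic alts are tallied out", {
  v <- eval_vcf(100, "A", "G,T")
  norm <- normalize_variants(v)
  expect_equal(nrow(norm), 2L)
  expect_equal(norm$alt, c("G", "T"))
  # genotype 1/2 projects onto each split alt
  v2 <- eval_vcf(100, "A", "G,T", gt = "1/2")
  norm2 <- normalize_variants(v2)
  expect_equal(norm2$gt, c("0/1", "0/1"))
  v3 <- eval_vcf(c(100, 200), c("A", "A"), c("<DEL>", "G"))
  norm3 <- normalize_variants(v3)
  expect_equal(nrow(norm3), 1L)
  expect_equal(attr(norm3, "n_symbolic"), 1L)
})

test_that("exact matching yields the planted TP/FP/FN structure", {
  truth <- eval_vcf(100, "A", "G")
  expect_equal(unlist(match_calls(truth, eval_vcf(100, "A", "G"))$counts["total", ]),
               c(tp = 1, fp = 0, fn = 0))
  expect_equal(unlist(match_calls(truth, eval_vcf(100, "A", "T"))$counts["total", ]),
               c(tp = 0, fp = 1, fn = 1))
  sim <- simulate_vcf_pair(list(n_shared = 80, n_call_only = 20,
                                n_truth_only = 20), 31)
  res <- match_calls(sim$truth, sim$calls, genotype_match = TRUE)
  expect_equal(unlist(res$counts["total", ]), c(tp = 80, fp = 20, fn = 20))
})

test_that("genotype matching separates same-allele genotype discordance", {
  truth <- eval_vcf(100, "A", "G", gt = "1/1")
  calls <- eval_vcf(100, "A", "G", gt = "0/1")
  gt_on <- match_calls(truth, calls, genotype_match = TRUE)
  expect_equal(unlist(gt_on$counts["total", ]), c(tp = 0, fp = 1, fn = 1))
  gt_off <- match_calls(truth, calls, genotype_match = FALSE)
  expect_equal(unlist(gt_off$counts["total", ]), c(tp = 1, fp = 0, fn = 0))
  # phased and unphased genotypes compare equal after normalization
  truth2 <- eval_vcf(100, "A", "G", gt = "1|0")
  expect_equal(unlist(match_calls(truth2, calls)$counts["total", ]),
               c(tp = 1, fp = 0, fn = 0))
})

test_that("FP class comes from the call, FN class from the truth record", {
  truth <- eval_vcf(100, "AT", "A")            # indel in truth only
  calls <- eval_vcf(200, "A", "G")             # snv in calls only
  res <- match_calls(truth, calls)
  expect_equal(unlist(res$counts["snv", ]), c(tp = 0, fp = 1, fn = 0))
  expect_equal(unlist(res$counts["small_indel", ]), c(tp = 0, fp = 0, fn = 1))
})

test_that("metrics match the printed formulas and handle degeneracy", {
  expect_equal(unlist(compute_metrics(8, 2, 2)),
               c(precision = 0.8, sensitivity = 0.8, f_measure = 0.8))
  m <- compute_metrics(9, 1, 3)
  expect_equal(m$precision, 0.9)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$f_measure, 2 * 0.9 * 0.75 / (0.9 + 0.75), tolerance = 1e-12)
  m0 <- compute_metrics(0, 0, 5)
  expect_true(is.na(m0$precision))
  expect_equal(m0$sensitivity, 0)
  expect_true(is.na(m0$f_measure))
  expect_true(is.na(compute_metrics(0, 0, 0)$precision))
})

test_that("metrics agree with brute-force formula evaluation at random", {
  set.seed(99)
  for (i in 1:500) {
    tp <- sample(0:200, 1); fp <- sample(0:200, 1); fn <- sample(0:200, 1)
    got <- unlist(compute_metrics(tp, fp, fn))
    want <- oracle_metrics(tp, fp, fn)
    expect_equal(got, want, tolerance = 1e-12)
    # harmonic-mean identity and bounds when defined
    if (!anyNA(got)) {
      expect_equal(got[["f_measure"]] * (got[["precision"]] + got[["sensitivity"]]),
                   2 * got[["precision"]] * got[["sensitivity"]],
                   tolerance = 1e-12)
      expect_lte(got[["f_measure"]], max(got[["precision"]], got[["sensitivity"]]))
      expect_lte(got[["f_measure"]], 2 * min(got[["precision"]], got[["sensitivity"]]))
      expect_gte(got[["f_measure"]], 0)
    }
  }
})

test_that("swapping truth and calls exchanges FP and FN with TP fixed", {
  sim <- simulate_vcf_pair(list(n_shared = 30, n_call_only = 12,
                                n_truth_only = 7), 13)
  ab <- match_calls(sim$truth, sim$calls)
  ba <- match_calls(sim$calls, sim$truth)
  expect_equal(ab$counts["total", "tp"], ba$counts["total", "tp"])
  expect_equal(ab$counts["total", "fp"], ba$counts["total", "fn"])
  expect_equal(ab$counts["total", "fn"], ba$counts["total", "fp"])
})

test_that("region restriction commutes with matching on point variants", {
  sim <- simulate_vcf_pair(list(n_shared = 40, n_call_only = 10,
                                n_truth_only = 10, p_indel = 0), 41)
  all_pos <- sort(unique(c(sim$truth$records$pos, sim$calls$records$pos)))
  cut <- all_pos[length(all_pos) %/% 2]
  regions <- merge_regions(region_set("chrT", 0, cut))
  a <- match_calls(sim$truth, sim$calls, regions = regions)
  t2 <- sim$truth; t2$records <- t2$records[t2$records$pos - 1L < cut, ]
  c2 <- sim$calls; c2$records <- c2$records[c2$records$pos - 1L < cut, ]
  b <- match_calls(t2, c2)
  expect_equal(a$counts, b$counts)
})
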