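mk_counts <- function(pos, ref, alt, sample_id = "T1", chrom = "chr1") {
  data.frame(sample_id = sample_id, chrom = chrom, pos = pos,
             ref_count = ref, alt_count = alt, stringsAsFactors = FALSE)
}

whole_chr1_seg <- function(sample_id = "T1", direction = "loss") {
  data.frame(sample_id = sample_id, chrom = "chr1", start = 0, end = 1e7,
             median_logr = if (direction == "loss") -0.4 else 0.4,
             direction = direction, stringsAsFactors = FALSE)
}

test_that("het-SNP selection enforces depth and inclusive VAF bounds", {
  counts <- mk_counts(pos = c(100, 200, 300, 400, 500),
                      ref = c(5, 12, 14, 6, 0),
                      alt = c(5, 8, 6, 6, 0), sample_id = "N")
  het <- select_het_snps(counts)
  # depth 10 excluded (need > 10); VAF 0.40 included; VAF 0.30 excluded;
  # depth-0 rows skipped silently
  expect_equal(het$pos, c(200, 400))
})

test_that("exact binomial p matches closed forms and enumeration", {
  expect_equal(binomial_two_sided_p(10, 10), 1.0)
  expect_equal(binomial_two_sided_p(20, 0), 2 * 0.5^20, tolerance = 1e-12)
  # sum over all 21 outcomes of Binomial(20, 1/2) with P(k) <= P(5)
  expect_equal(binomial_two_sided_p(15, 5), 43400 / 2^20, tolerance = 1e-12)
  expect_equal(binomial_two_sided_p(15, 5), 0.0413894653, tolerance = 1e-8)

  for (n in c(1:15, 20, 27, 30)) {
    for (a in 0:n) {
      expect_equal(binomial_two_sided_p(n - a, a), oracle_binom_p(n - a, a),
                   tolerance = 1e-12)
    }
  }
  # independent cross-check against the standard exact test
  set.seed(31)
  for (i in 1:50) {
    a <- sample(0:80, 1); b <- sample(0:80, 1)
    if (a + b == 0) a <- 1
    expect_equal(binomial_two_sided_p(a, b),
                 binom.test(a, a + b, 0.5)$p.value, tolerance = 1e-9)
  }
  expect_error(binomial_two_sided_p(0, 0), "both counts")
})

test_that("exact binomial p is symmetric in its arguments", {
  for (n in 1:50) {
    a <- 0:n
    expect_equal(binomial_two_sided_p(a, n - a),
                 binomial_two_sided_p(n - a, a))
  }
})

test_that("BH adjustment matches the sort-based reference", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_bh(numeric(0)), numeric(0))

  set.seed(32)
  for (len in 1:20) {
    p <- runif(len)
    expect_equal(adjust_bh(p), oracle_bh(p), tolerance = 1e-12)
  }
  for (i in 1:50) {
    p <- runif(sample.int(1e3, 1))
    adj <- adjust_bh(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))  # adjusted never below raw
  }
})

test_that("informative-SNP calling gates on depth and adjusts within the family", {
  het <- mk_counts(pos = (1:100) * 1000, ref = 0, alt = 0, sample_id = "N")
  # 90 skewed SNPs (40, 8), 10 balanced (25, 25)
  tum <- mk_counts(pos = (1:100) * 1000,
                   ref = c(rep(40, 90), rep(25, 10)),
                   alt = c(rep(8, 90), rep(25, 10)))
  seg <- whole_chr1_seg()
  calls <- call_informative_snps(tum, het, seg, "p")
  expect_equal(sum(calls$informative), 90)
  expect_true(all(calls$major_allele[calls$informative] == "REF"))
  expect_true(all(calls$p_adj >= calls$p_raw))

  # tumor depth exactly 10 is not a candidate; (30,30) is but never informative
  tum2 <- mk_counts(pos = c(1000, 2000), ref = c(5, 30), alt = c(5, 30))
  calls2 <- call_informative_snps(tum2, het, seg, "p")
  expect_equal(nrow(calls2), 1)
  expect_equal(calls2$p_raw, 1)
  expect_false(calls2$informative)

  # zero candidates is an empty frame, not an error
  expect_equal(nrow(call_informative_snps(tum2[0, ], het, seg, "p")), 0)

  # rejection monotonicity: informative at 0.05 subset of 0.1
  c05 <- call_informative_snps(tum, het, seg, "p", alpha = 0.05)
  c10 <- call_informative_snps(tum, het, seg, "p", alpha = 0.1)
  expect_true(all(c05$pos[c05$informative] %in% c10$pos[c10$informative]))
})

fake_calls <- function(pos, p_adj, major) {
  data.frame(chrom = "chr1", pos = pos, ref_count = 40, alt_count = 8,
             p_raw = p_adj, p_adj = p_adj, major_allele = major,
             informative = TRUE, stringsAsFactors = FALSE)
}

test_that("pairwise comparison computes concordance and verdicts", {
  a <- fake_calls(1:1200 * 10, 0.01, "REF")
  b <- fake_calls(1:1200 * 10, 0.01, "REF")
  r <- compare_parental_alleles(a, b)
  expect_equal(r$concordance, 1.0)
  expect_equal(r$verdict, "same_allele")
  expect_equal(r$alpha_used, 0.05)  # >= 1000 shared: no relaxation

  b$major_allele <- "ALT"
  r <- compare_parental_alleles(a, b)
  expect_equal(r$concordance, 0.0)
  expect_equal(r$verdict, "different_allele")

  r <- compare_parental_alleles(a[0, ], b[0, ])
  expect_equal(r$verdict, "no_call")
  expect_equal(r$n_shared_informative, 0)
})

test_that("the < 1000 shared-SNP relaxation re-calls both tumors at 0.1", {
  # 800 SNPs significant at 0.05 in both tumors; another 300 only at 0.1
  pos <- 1:1100 * 10
  p_a <- c(rep(0.01, 800), rep(0.07, 300))
  a <- fake_calls(pos, p_a, "REF")
  b <- fake_calls(pos, p_a, "REF")
  r <- compare_parental_alleles(a, b)
  expect_equal(r$alpha_used, 0.1)
  expect_equal(r$n_shared_informative, 1100)

  # exactly 1000 shared at 0.05: stays at the primary level
  a2 <- fake_calls(1:1000 * 10, 0.01, "REF")
  r2 <- compare_parental_alleles(a2, a2)
  expect_equal(r2$alpha_used, 0.05)
  expect_equal(r2$n_shared_informative, 1000)
})

test_that("pairwise comparison is symmetric", {
  set.seed(33)
  phase <- toy_phase(400)
  a <- counts_for_event(phase, "T1", "loss", "A", 0.6, 60)
  b <- counts_for_event(phase, "T2", "loss", "B", 0.6, 60)
  het <- mk_counts(phase$pos, 15, 15, sample_id = "N")
  seg <- whole_chr1_seg()
  ca <- call_informative_snps(a, het, seg, "q")
  cb <- call_informative_snps(b, het, seg, "q")
  r_ab <- compare_parental_alleles(ca, cb, tumor_a = "T1", tumor_b = "T2")
  r_ba <- compare_parental_alleles(cb, ca, tumor_a = "T2", tumor_b = "T1")
  expect_equal(r_ab$n_shared_informative, r_ba$n_shared_informative)
  expect_equal(r_ab$alpha_used, r_ba$alpha_used)
  expect_equal(r_ab$concordance, r_ba$concordance)
  expect_equal(r_ab$verdict, r_ba$verdict)
})

test_that("informative SNPs recover the ground-truth haplotype", {
  set.seed(34)
  for (rep in 1:5) {
    phase <- toy_phase(600)
    tum <- counts_for_event(phase, "T1", "loss", "B", 0.6, 60)
    het <- mk_counts(phase$pos, 15, 15, sample_id = "N")
    for (arm in c("p", "q")) {
      calls <- call_informative_snps(tum, het, whole_chr1_seg(), arm)
      inf <- calls[calls$informative, ]
      expect_gt(nrow(inf), 50)
      truth <- truth_major(phase, "loss", "B")[match(inf$pos, phase$pos)]
      expect_gte(mean(inf$major_allele == truth), 0.99)
    }
  }
})

test_that("segment mapping splits arms and handles degenerate input", {
  set.seed(35)
  phase <- toy_phase(800)
  # two events on one tumor: p arm loses A, q arm loses B
  p_iv <- c(0, 4e6); q_iv <- c(4.5e6, 1e7)
  cp <- counts_for_event(phase, "T1", "loss", "A", 0.6, 60, interval = p_iv)
  cq <- counts_for_event(phase, "T1", "loss", "B", 0.6, 60, interval = q_iv)
  inq <- phase$pos > q_iv[1] & phase$pos <= q_iv[2]
  counts <- cp
  counts[inq, ] <- cq[inq, ]
  het <- mk_counts(phase$pos, 15, 15, sample_id = "N")
  rep_tab <- map_segment(counts, het, whole_chr1_seg())
  expect_equal(rep_tab$arm, c("p", "q"))
  expect_equal(rep_tab$call, c("mapped", "mapped"))
  # opposite retained haplotypes: REF-major fractions are complementary,
  # matching the per-SNP truth on each arm
  for (i in 1:2) {
    arm_iv <- if (rep_tab$arm[i] == "p") p_iv else q_iv
    hap <- if (rep_tab$arm[i] == "p") "A" else "B"
    inside <- phase$pos > arm_iv[1] & phase$pos <= arm_iv[2]
    expect_equal(rep_tab$fraction_major_ref[i],
                 mean(truth_major(phase, "loss", hap)[inside] == "REF"),
                 tolerance = 0.05)
  }

  # purity 0: no allelic skew, zero informative SNPs
  c0 <- counts_for_event(phase, "T1", "loss", "A", 0.0, 60)
  r0 <- map_segment(c0, het, whole_chr1_seg())
  expect_true(all(r0$call == "no_call"))
  expect_true(all(r0$n_informative == 0))

  # segment entirely inside the centromere: single no_call row
  cen_seg <- data.frame(sample_id = "T1", chrom = "chr1", start = 4.1e6,
                        end = 4.4e6, median_logr = -0.4, direction = "loss",
                        stringsAsFactors = FALSE)
  rc <- map_segment(counts, het, cen_seg)
  expect_equal(nrow(rc), 1)
  expect_equal(rc$call, "no_call")
  expect_true(is.na(rc$arm))
})
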