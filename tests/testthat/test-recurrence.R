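mk_cohort_meta <- function(n_tumors_per_patient, n_patients) {
  rows <- list()
  for (p in seq_len(n_patients)) {
    pid <- paste0("PT", p)
    ids <- paste0(pid, "_T", seq_len(n_tumors_per_patient))
    rows[[p]] <- data.frame(
      sample_id = c(ids, paste0(pid, "_N")), patient_id = pid,
      sample_type = c(rep("primary", n_tumors_per_patient), "normal"),
      purity = c(rep(0.5, n_tumors_per_patient), 0), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

mk_gvar <- function(sample_id, gene, effect = "missense",
                    region = "coding", pos = 1000) {
  data.frame(sample_id = sample_id, chrom = "chr1", pos = pos, ref = "A",
             alt = "T", total_depth = 30, population_af = 0,
             variant_class = "SNV", region = region, gene = gene,
             effect = effect, stringsAsFactors = FALSE)
}

test_that("mutation burden is count over genome megabases", {
  expect_equal(mutation_burden(empty_variants <- mk_gvar("S", "G")[0, ], 300), 0)
  v <- do.call(rbind, lapply(1:90, function(i) mk_gvar("S", "G", pos = i)))
  expect_equal(mutation_burden(v, 300), 0.30)

  # simulated burden matches the configured rate
  set.seed(51)
  burdens <- replicate(100, {
    cfg <- sim_config(het_snps_per_chrom = 0, seed = 51)
    p <- simulate_patient(cfg, "PT", n_primaries = 1, n_mets = 0)
    mutation_burden(p$variants, genome_mb(toy_genome()))
  })
  se <- sqrt(0.41 / 30 / 100)
  expect_lt(abs(mean(burdens) - 0.41), 3 * se)
})

test_that("recurrent genes count patients once and drop silent-only genes", {
  meta <- mk_cohort_meta(5, 3)
  v <- rbind(
    # gene A: 5 tumors, all one patient
    do.call(rbind, lapply(1:5, function(i)
      mk_gvar(paste0("PT1_T", i), "GENE_A", pos = i))),
    # gene B: silent only, two patients
    mk_gvar("PT1_T1", "GENE_B", effect = "silent", pos = 100),
    mk_gvar("PT2_T1", "GENE_B", effect = "silent", pos = 101),
    # gene C: nonsynonymous in 3 patients
    mk_gvar("PT1_T1", "GENE_C", pos = 200),
    mk_gvar("PT2_T1", "GENE_C", effect = "nonsense", pos = 201),
    mk_gvar("PT3_T2", "GENE_C", effect = "frameshift", pos = 202))
  tab <- recurrent_genes(v, meta)
  expect_false("GENE_B" %in% tab$gene)
  a <- tab[tab$gene == "GENE_A", ]
  expect_equal(a$n_patients, 1)
  expect_equal(a$n_tumors, 5)
  expect_false(a$recurrent)
  expect_equal(tab$n_patients[tab$gene == "GENE_C"], 3)
  expect_true(tab$recurrent[tab$gene == "GENE_C"])

  # duplicating a tumor's variants never changes patient counts
  dup <- v; dup$sample_id <- sub("_T1", "_T4", dup$sample_id)
  tab2 <- recurrent_genes(rbind(v, dup), meta)
  expect_equal(tab2$n_patients[tab2$gene == "GENE_C"], 3)

  # unannotated variants are skipped with an audit note
  v$gene[1] <- NA
  tab3 <- recurrent_genes(v, meta)
  expect_equal(attr(tab3, "n_skipped"), 1)
})

test_that("recurrent noncoding positions use the exact variant key", {
  meta <- mk_cohort_meta(2, 2)
  v <- rbind(mk_gvar("PT1_T1", NA, NA, "noncoding", pos = 500),
             mk_gvar("PT2_T1", NA, NA, "noncoding", pos = 500),
             mk_gvar("PT1_T2", NA, NA, "noncoding", pos = 900))
  v$alt[3] <- "T"
  v2 <- mk_gvar("PT2_T2", NA, NA, "noncoding", pos = 900)
  v2$alt <- "G"  # same position, different substitution
  tab <- recurrent_noncoding(rbind(v, v2), meta)
  expect_equal(tab$n_patients[tab$pos == 500], 2)
  expect_true(tab$recurrent[tab$pos == 500])
  expect_equal(sum(tab$pos == 900), 2)
  expect_true(all(!tab$recurrent[tab$pos == 900]))
})

test_that("CNA events classify by fractional coverage and tally correctly", {
  g <- toy_genome()
  meta <- mk_cohort_meta(2, 2)
  seg <- function(sid, start, end, dir = "loss") {
    data.frame(sample_id = sid, chrom = "chr1", start = start, end = end,
               median_logr = ifelse(dir == "loss", -0.4, 0.4), direction = dir,
               stringsAsFactors = FALSE)
  }
  segs <- rbind(seg("PT1_T1", 0.2e6, 9.7e6),        # 95%: whole-chromosome
                seg("PT2_T1", 0, 1e7),               # whole
                seg("PT1_T2", 4.5e6, 9.9e6, "gain"), # q arm
                seg("PT2_T2", 6e6, 8e6, "gain"))     # 2 Mb mid-arm: focal
  tab <- recurrent_cnas(segs, meta, g)
  whole <- tab[tab$scope == "whole" & tab$direction == "loss", ]
  expect_equal(whole$n_tumors, 2)
  expect_equal(whole$n_patients, 2)
  expect_true(whole$recurrent)
  expect_equal(whole$tumor_fraction, 2 / 4)
  expect_setequal(tab$scope[tab$direction == "gain"], c("arm", "focal"))

  # planted prevalence is recovered exactly: chr1 loss in 57% of tumors
  set.seed(52)
  cfg <- sim_config(n_patients = 4, primaries_per_patient = c(10, 10),
                    mets_per_patient = c(0, 0), het_snps_per_chrom = 0,
                    purity_range = c(0.5, 0.9), seed = 52,
                    cna_event_table = data.frame(
                      chrom = "chr1", scope = "whole", start = NA, end = NA,
                      direction = "loss", prob = 0.57))
  co <- simulate_cohort(cfg)
  kept <- filter_cna_segments(co$segments, filter_config(), co$genome)$kept
  tab2 <- recurrent_cnas(kept, co$samples, co$genome)
  n_true <- length(unique(co$truth$cna_events$sample_id))
  expect_equal(tab2$n_tumors, n_true)
  expect_equal(tab2$tumor_fraction, n_true / 40)
})

test_that("minimal regions are intersections, disjoint, and size-limited", {
  meta <- mk_cohort_meta(1, 3)
  seg <- function(sid, start, end) {
    data.frame(sample_id = sid, chrom = "chrT", start = start, end = end,
               median_logr = -0.4, direction = "loss",
               stringsAsFactors = FALSE)
  }
  two <- rbind(seg("PT1_T1", 2e6, 9e6), seg("PT2_T1", 5.5e6, 8e6))
  out <- minimal_regions(two, meta)
  expect_equal(out$start, 5.5e6)
  expect_equal(out$end, 8e6)
  expect_equal(out$length, 2.5e6)
  expect_equal(out$n_patients, 2)

  # 6 Mb intersection: not reported (>= 5 Mb)
  wide <- rbind(seg("PT1_T1", 2e6, 9e6), seg("PT2_T1", 3e6, 9e6))
  expect_equal(nrow(minimal_regions(wide, meta)), 0)

  # both segments from one patient: not reported
  one <- rbind(seg("PT1_T1", 2e6, 9e6), seg("PT1_T1", 5.5e6, 8e6))
  expect_equal(nrow(suppressWarnings(minimal_regions(one, meta))), 0)

  # random property: outputs disjoint and contained in every supporting segment
  set.seed(53)
  for (rep in 1:10) {
    starts <- sample.int(8e6, 12)
    segs <- data.frame(sample_id = sample(meta$sample_id[meta$sample_type
                                                         != "normal"], 12, TRUE),
                       chrom = "chrT", start = starts,
                       end = pmin(starts + sample.int(4e6, 12), 1e7),
                       median_logr = -0.4, direction = "loss",
                       stringsAsFactors = FALSE)
    out <- minimal_regions(segs, meta)
    if (nrow(out) >= 2) {
      o <- out[order(out$start), ]
      expect_true(all(o$start[-1] >= o$end[-nrow(o)]))
    }
    for (i in seq_len(nrow(out))) {
      sup <- segs$start <= out$start[i] & segs$end >= out$end[i]
      expect_gte(length(unique(segs$sample_id[sup])), 1)
      expect_equal(sum(sup), out$n_segments[i])
    }
  }
})

test_that("hypergeometric enrichment matches enumeration", {
  universe <- paste0("G", 1:10)
  pw <- list(P1 = paste0("G", 1:5))
  mutated <- paste0("G", c(1:4))
  tab <- hypergeom_enrichment(mutated, pw, universe)
  expect_equal(tab$p_raw, 5 / 210, tolerance = 1e-12)
  expect_equal(tab$k, 4)

  # overlap 0 with mutated 0; pathway == universe
  expect_equal(hypergeom_enrichment(character(0), pw, universe)$p_raw, 1)
  expect_equal(hypergeom_enrichment(mutated, list(U = universe),
                                    universe)$p_raw, 1)

  # enumeration oracle across many parameter tuples
  set.seed(54)
  for (rep in 1:100) {
    N <- sample(2:25, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    uni <- paste0("g", 1:N)
    mut <- sample(uni, n)
    sets <- list(S = sample(uni, K))
    k <- length(intersect(sets$S, mut))
    got <- hypergeom_enrichment(mut, sets, uni)
    expect_equal(got$p_raw, oracle_hyper_p(k, K, N, n), tolerance = 1e-12)
  }
  expect_error(hypergeom_enrichment("g", list(S = "g"), character(0)),
               "empty gene universe")
})
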