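test_that("genome config derives arm boundaries and enforces invariants", {
  g <- genome_config(data.frame(name = "chrT", length = 1e7,
                                centromere_start = 4e6, centromere_end = 4.5e6))
  ab <- arm_bounds(g, "chrT")
  expect_equal(ab$start, c(0, 4.5e6))
  expect_equal(ab$end, c(4e6, 1e7))
  expect_equal(genome_mb(g), 10)

  expect_error(genome_config(data.frame(name = "c", length = 1e6,
                                        centromere_start = 4e5,
                                        centromere_end = 2e6)),
               "strictly inside")
  expect_error(genome_config(data.frame(name = c("c", "c"), length = 1e6,
                                        centromere_start = 4e5,
                                        centromere_end = 5e5)),
               "duplicate")
  expect_error(genome_config(data.frame(name = "c", length = 1e6,
                                        centromere_start = NA,
                                        centromere_end = NA)),
               "centromere")
})

test_that("genome config round-trips through YAML", {
  g <- toy_genome()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_genome_config(g, path)
  g2 <- load_genome_config(path)
  expect_equal(g2$chromosomes$name, g$chromosomes$name)
  expect_equal(g2$chromosomes$length, g$chromosomes$length)
  expect_equal(g2$chromosomes$centromere_start, g$chromosomes$centromere_start)
})

test_that("VCF reader maps fields, decomposes multi-allelics, and validates", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="d">',
    '##INFO=<ID=PAF,Number=1,Type=Float,Description="p">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"),
    "chr1\t100\t.\tA\tT\t.\t.\tDP=30;PAF=0.0",
    "chr1\t200\t.\tA\tT,C\t.\t.\tDP=12"
  ), path)
  v <- read_small_variants(path, "S1", genome = toy_genome())
  expect_equal(nrow(v), 3)
  expect_equal(v$pos[1], 100)
  expect_equal(v$total_depth[1], 30)
  expect_equal(v$population_af[1], 0)
  # multi-allelic decomposition: two rows sharing (chrom, pos, ref)
  ma <- v[v$pos == 200, ]
  expect_equal(ma$alt, c("T", "C"))
  expect_equal(unique(ma$ref), "A")
  # missing annotations are NA, not defaults
  expect_true(is.na(v$population_af[2]))
  expect_true(all(is.na(v$gene)))

  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO"), collapse = "\t"),
               "chrZZ\t100\t.\tA\tT\t.\t.\tDP=5"), path)
  expect_error(read_small_variants(path, "S1", genome = toy_genome()),
               "absent from genome")
})

test_that("small variants round-trip through VCF", {
  set.seed(11)
  cfg <- sim_config(n_patients = 1, primaries_per_patient = c(2, 2),
                    mets_per_patient = c(0, 0), het_snps_per_chrom = 0,
                    seed = 11)
  co <- simulate_cohort(cfg)
  v <- co$variants[co$variants$sample_id == co$samples$sample_id[1], ]
  path <- withr::local_tempfile(fileext = ".vcf")
  write_small_variants(v, path)
  v2 <- read_small_variants(path, v$sample_id[1])
  v <- v[order(v$chrom, v$pos), ]; rownames(v) <- NULL
  v2 <- v2[order(v2$chrom, v2$pos), ]; rownames(v2) <- NULL
  expect_equal(v2[, c("chrom", "pos", "ref", "alt", "total_depth", "gene",
                      "effect", "region")],
               v[, c("chrom", "pos", "ref", "alt", "total_depth", "gene",
                     "effect", "region")])
})

test_that("allelic-count reader follows the CollectAllelicCounts dialect", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("@HD\tVN:1.6",
               "CONTIG\tPOSITION\tREF_COUNT\tALT_COUNT",
               "chrT\t500\t12\t9",
               "chrT\t100\t3\t4"), path)
  ac <- read_allelic_counts(path, "S1")
  expect_equal(ac$pos, c(100, 500))        # sorted on return
  expect_equal(ac$ref_count[2], 12)
  expect_equal(ac$alt_count[2], 9)

  writeLines(c("CONTIG\tPOSITION\tREF_COUNT\tALT_COUNT"), path)
  expect_equal(nrow(read_allelic_counts(path, "S1")), 0)

  writeLines(c("CONTIG\tPOSITION\tREF_COUNT\tALT_COUNT",
               "chrT\t500\t12\t9", "chrT\t500\t1\t1"), path)
  expect_error(read_allelic_counts(path, "S1"), "duplicate")

  writeLines(c("CONTIG\tPOSITION\tREF_COUNT\tALT_COUNT",
               "chrT\t500\t-1\t9"), path)
  expect_error(read_allelic_counts(path, "S1"), "negative")
})

test_that("SEG files round-trip with the 1-based inclusive disk convention", {
  path <- withr::local_tempfile(fileext = ".seg")
  seg <- data.frame(sample_id = "S1", chrom = "chr1", start = 0, end = 1000,
                    median_logr = -0.4, direction = "loss",
                    stringsAsFactors = FALSE)
  write_seg(seg, path)
  disk <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(disk$START, 1)
  expect_equal(disk$END, 1000)
  # on-disk inclusive length equals in-memory half-open length
  expect_equal(disk$END - disk$START + 1, seg$end - seg$start)
  back <- read_seg(path)
  expect_equal(back, seg)

  # random round-trip property
  set.seed(42)
  for (i in 1:20) {
    n <- sample(1:8, 1)
    start <- sort(sample.int(1e6, n)) * 10
    seg <- data.frame(sample_id = "S1",
                      chrom = paste0("chr", seq_len(n)),  # avoid overlap warning
                      start = start, end = start + sample.int(1e5, n),
                      median_logr = round(rnorm(n), 4),
                      direction = sample(c("loss", "gain", "cn_loh"), n, TRUE),
                      stringsAsFactors = FALSE)
    write_seg(seg, path)
    expect_equal(read_seg(path), seg)
  }

  writeLines(c("SAMPLE\tCHROM\tSTART\tEND\tMEDIAN_LOGR\tDIRECTION",
               "S1\tchr1\t1000\t1000\t0.4\tgain"), path)
  expect_error(read_seg(path), "END <= START")

  # empty collection -> header-only file -> empty collection
  write_seg(seg[0, ], path)
  expect_equal(nrow(read_seg(path)), 0)
})

test_that("overlapping segments within a sample warn but are kept", {
  path <- withr::local_tempfile(fileext = ".seg")
  seg <- data.frame(sample_id = "S1", chrom = "chr1",
                    start = c(0, 500), end = c(1000, 1500),
                    median_logr = 0.4, direction = "gain",
                    stringsAsFactors = FALSE)
  write_seg(seg, path)
  expect_warning(out <- read_seg(path), "overlapping")
  expect_equal(nrow(out), 2)
})

test_that("SV tables and sample metadata round-trip; metadata validates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  svs <- data.frame(sample_id = "S1", chrom1 = c("chr1", "chr1"),
                    pos1 = c(100, 5000), chrom2 = c("chr1", "chr2"),
                    pos2 = c(20000, 7000),
                    sv_type = c("deletion", "interchromosomal"),
                    stringsAsFactors = FALSE)
  write_svs(svs, path)
  expect_equal(read_svs(path), svs)

  meta <- data.frame(sample_id = c("P1", "M1", "N1"), patient_id = "PT1",
                     sample_type = c("primary", "metastasis", "normal"),
                     purity = c(0.6, 0.5, 0), stringsAsFactors = FALSE)
  write_sample_meta(meta, path)
  expect_equal(read_sample_meta(path), meta)

  bad <- meta[meta$sample_type != "normal", ]
  write_sample_meta(bad, path)
  expect_error(read_sample_meta(path), "exactly one normal")
})

test_that("GMT gene sets are read as a named list", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SET_A\tdesc\tGENE1\tGENE2\tGENE3",
               "SET_B\tdesc\tGENE2\tGENE4"), path)
  sets <- read_gmt(path)
  expect_named(sets, c("SET_A", "SET_B"))
  expect_equal(sets$SET_B, c("GENE2", "GENE4"))
})
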