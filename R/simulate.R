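#' Simulation settings for a synthetic multifocal tumor cohort
#'
#' The generator emulates the structure of a multifocal ileal NET cohort:
#' each patient carries several independently arising synchronous primary
#' tumors (by construction they share no designed somatic variants) and
#' zero or more metastases, each seeded from one primary and inheriting a
#' fixed fraction of its parent's variants. Copy-number events are
#' whole-chromosome, arm-level or focal, each affecting one recorded
#' parental haplotype; heterozygous germline SNPs with a per-SNP coin-flip
#' phase provide the allelic-imbalance signal that chromosome mapping
#' recovers. Tumor reads are drawn at Poisson depth with beta-binomial
#' allele counts.
#'
#' Defaults mirror the study conditions: 2--18 primaries and 0--4
#' metastases per patient, 0.41 somatic mutations/Mb, purity >= 20%,
#' 60x tumor and 30x normal mean depth, and a whole-chromosome loss as the
#' most common CNA (57% of tumors), with gains and copy-neutral LOH at
#' lower rates.
#'
#' @param n_patients Number of patients.
#' @param primaries_per_patient Integer range `c(min, max)`.
#' @param mets_per_patient Integer range `c(min, max)`.
#' @param mutation_rate Somatic mutations per Mb per primary tumor.
#' @param coding_fraction Fraction of variants in coding regions.
#' @param purity_range Tumor purity interval within `[0.2, 1]`.
#' @param mean_tumor_depth,mean_normal_depth Mean sequencing depth (reads).
#' @param het_snps_per_chrom Heterozygous germline SNPs per chromosome.
#' @param cna_event_table data.frame `(chrom, scope, start, end, direction,
#'   prob)`; `scope` is `"whole"`, `"p"`, `"q"` or `"focal"` (`start`/`end`
#'   used only for focal events). Events are drawn independently per tumor;
#'   at most one event per chromosome per tumor.
#' @param met_inherited_fraction Probability a parent-primary variant is
#'   present in a metastasis seeded from it.
#' @param met_time_factor Multiplier on the mutation rate for
#'   metastasis-private variants (the study reports a higher burden in
#'   metastases but no generative model; exposed, not hard-coded).
#' @param sv_rate_per_tumor Mean number of structural variants per tumor.
#' @param overdispersion Beta-binomial overdispersion rho in `[0, 1)`;
#'   0 degenerates to binomial sampling.
#' @param seed Integer seed; mandatory, every draw flows from it.
#' @param genome A [genome_config()]; default [toy_genome()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 13,
                       primaries_per_patient = c(2, 18),
                       mets_per_patient = c(0, 4),
                       mutation_rate = 0.41,
                       coding_fraction = 0.012,
                       purity_range = c(0.2, 0.9),
                       mean_tumor_depth = 60,
                       mean_normal_depth = 30,
                       het_snps_per_chrom = 2000,
                       cna_event_table = default_cna_events(),
                       met_inherited_fraction = 0.9,
                       met_time_factor = 1.0,
                       sv_rate_per_tumor = 1.0,
                       overdispersion = 0.01,
                       seed = NULL,
                       genome = toy_genome()) {
  if (is.null(seed)) stop("sim_config: a seed is mandatory")
  stopifnot(n_patients >= 1,
            length(primaries_per_patient) == 2,
            primaries_per_patient[1] >= 1,
            primaries_per_patient[1] <= primaries_per_patient[2],
            length(mets_per_patient) == 2,
            mets_per_patient[1] >= 0,
            mets_per_patient[1] <= mets_per_patient[2],
            mutation_rate >= 0, coding_fraction >= 0, coding_fraction <= 1,
            purity_range[1] >= 0, purity_range[2] <= 1,
            purity_range[1] <= purity_range[2],
            mean_tumor_depth > 0, mean_normal_depth > 0,
            het_snps_per_chrom >= 0,
            met_inherited_fraction >= 0, met_inherited_fraction <= 1,
            met_time_factor >= 0, sv_rate_per_tumor >= 0,
            overdispersion >= 0, overdispersion < 1,
            all(cna_event_table$prob >= 0 & cna_event_table$prob <= 1),
            inherits(genome, "genome_config"))
  structure(list(n_patients = n_patients,
                 primaries_per_patient = primaries_per_patient,
                 mets_per_patient = mets_per_patient,
                 mutation_rate = mutation_rate,
                 coding_fraction = coding_fraction,
                 purity_range = purity_range,
                 mean_tumor_depth = mean_tumor_depth,
                 mean_normal_depth = mean_normal_depth,
                 het_snps_per_chrom = het_snps_per_chrom,
                 cna_event_table = cna_event_table,
                 met_inherited_fraction = met_inherited_fraction,
                 met_time_factor = met_time_factor,
                 sv_rate_per_tumor = sv_rate_per_tumor,
                 overdispersion = overdispersion,
                 seed = as.integer(seed),
                 genome = genome),
            class = "sim_config")
}

#' Default copy-number event table for the toy genome
#'
#' chr1 whole-chromosome loss at 57% of tumors plays the role of the
#' dominant chr18 loss; lower-rate whole-chromosome and arm-level gains,
#' a focal loss, and occasional copy-neutral LOH exercise every mapping
#' path.
#'
#' @return data.frame `(chrom, scope, start, end, direction, prob)`.
#' @export
default_cna_events <- function() {
  data.frame(
    chrom = c("chr1", "chr2", "chr3", "chr3", "chr1"),
    scope = c("whole", "whole", "q", "focal", "whole"),
    start = c(NA, NA, NA, 6.0e6, NA),
    end = c(NA, NA, NA, 8.5e6, NA),
    direction = c("loss", "gain", "gain", "loss", "cn_loh"),
    prob = c(0.57, 0.13, 0.10, 0.08, 0.05),
    stringsAsFactors = FALSE
  )
}

#' Expected ALT read fraction under a purity mixture
#'
#' At a heterozygous germline SNP, tumor cells carry `n_alt_hap` copies of
#' the ALT-bearing haplotype and `n_ref_hap` of the REF-bearing one, while
#' admixed normal cells carry one of each:
#' `f = (purity * n_alt_hap + (1 - purity)) /
#'      (purity * (n_alt_hap + n_ref_hap) + 2 * (1 - purity))`.
#'
#' @param n_alt_hap,n_ref_hap Non-negative haplotype copy numbers.
#' @param purity Tumor purity in `[0, 1]`.
#' @return Expected ALT fraction in `[0, 1]`. Vectorized.
#' @export
expected_alt_fraction <- function(n_alt_hap, n_ref_hap, purity) {
  stopifnot(all(n_alt_hap >= 0), all(n_ref_hap >= 0),
            all(purity >= 0 & purity <= 1))
  den <- purity * (n_alt_hap + n_ref_hap) + 2 * (1 - purity)
  if (any(den == 0)) {
    stop("expected_alt_fraction: total copy number 0 in a fully pure tumor")
  }
  (purity * n_alt_hap + (1 - purity)) / den
}

#' Draw sequencing read counts at one or more SNPs
#'
#' Depth is Poisson with the given mean; the ALT count is beta-binomial
#' with mean `expected_fraction` and overdispersion `rho`
#' (`rho = 1 / (alpha + beta + 1)`), degenerating to binomial at
#' `rho = 0`. Depth 0 yields `(0, 0)`.
#'
#' @param expected_fraction Expected ALT fraction(s) in `[0, 1]`.
#' @param mean_depth Mean depth (> 0).
#' @param overdispersion rho in `[0, 1)`.
#' @return data.frame `(ref_count, alt_count)`, one row per input fraction.
#' @export
sample_allelic_depth <- function(expected_fraction, mean_depth,
                                 overdispersion = 0) {
  stopifnot(all(expected_fraction >= 0 & expected_fraction <= 1),
            mean_depth > 0, overdispersion >= 0, overdispersion < 1)
  n <- length(expected_fraction)
  depth <- stats::rpois(n, mean_depth)
  p <- expected_fraction
  if (overdispersion > 0) {
    s <- (1 - overdispersion) / overdispersion  # alpha + beta
    interior <- p > 0 & p < 1
    if (any(interior)) {
      p[interior] <- stats::rbeta(sum(interior),
                                  expected_fraction[interior] * s,
                                  (1 - expected_fraction[interior]) * s)
    }
  }
  alt <- stats::rbinom(n, depth, p)
  data.frame(ref_count = depth - alt, alt_count = alt)
}

rand_range <- function(range) {
  if (range[1] == range[2]) range[1] else sample(range[1]:range[2], 1)
}

BASES <- c("A", "C", "G", "T")

# Draw unique genome positions (chrom + 1-based pos), length-weighted.
draw_positions <- function(genome, n) {
  chs <- genome$chromosomes
  if (n == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      stringsAsFactors = FALSE))
  }
  repeat {
    ci <- sample.int(nrow(chs), n, replace = TRUE, prob = chs$length)
    pos <- floor(stats::runif(n, 0, chs$length[ci])) + 1
    key <- paste(chs$name[ci], pos)
    if (!anyDuplicated(key)) break
  }
  data.frame(chrom = chs$name[ci], pos = as.integer(pos),
             stringsAsFactors = FALSE)
}

# Gene catalog: coding variants map deterministically to a 100-kb gene tile,
# so planted recurrences across patients land in the same gene.
gene_at <- function(chrom, pos) {
  sprintf("G_%s_%03d", chrom, floor((pos - 1) / 1e5))
}

draw_variants <- function(genome, n, sample_id, coding_fraction, mean_depth) {
  if (n == 0) return(empty_variants())
  loc <- draw_positions(genome, n)
  ref <- sample(BASES, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), character(1))
  coding <- stats::runif(n) < coding_fraction
  effect <- rep(NA_character_, n)
  if (any(coding)) {
    effect[coding] <- sample(
      c("missense", "silent", "nonsense", "frameshift", "splice"),
      sum(coding), replace = TRUE, prob = c(0.65, 0.27, 0.03, 0.03, 0.02))
  }
  data.frame(sample_id = sample_id, chrom = loc$chrom, pos = loc$pos,
             ref = ref, alt = unname(alt),
             total_depth = stats::rpois(n, mean_depth),
             population_af = 0,
             variant_class = ifelse(effect %in% "frameshift", "indel", "SNV"),
             region = ifelse(coding, "coding", "noncoding"),
             gene = ifelse(coding, gene_at(loc$chrom, loc$pos), NA_character_),
             effect = effect, stringsAsFactors = FALSE)
}

event_interval <- function(genome, chrom, scope, start, end) {
  r <- chrom_row(genome, chrom)
  switch(scope,
         whole = c(0, r$length),
         p = c(0, r$centromere_start),
         q = c(r$centromere_end, r$length),
         focal = c(start, end),
         stop("unknown CNA scope: ", scope))
}

# Draw CNA events for one tumor: at most one event per chromosome.
draw_cna_events <- function(config, sample_id) {
  tab <- config$cna_event_table
  hit <- stats::runif(nrow(tab)) < tab$prob
  ev <- tab[hit, , drop = FALSE]
  ev <- ev[!duplicated(ev$chrom), , drop = FALSE]
  if (nrow(ev) == 0) {
    return(data.frame(sample_id = character(), chrom = character(),
                      scope = character(), start = numeric(), end = numeric(),
                      direction = character(), affected_hap = character(),
                      stringsAsFactors = FALSE))
  }
  iv <- t(vapply(seq_len(nrow(ev)), function(i) {
    event_interval(config$genome, ev$chrom[i], ev$scope[i],
                   ev$start[i], ev$end[i])
  }, numeric(2)))
  data.frame(sample_id = sample_id, chrom = ev$chrom, scope = ev$scope,
             start = iv[, 1], end = iv[, 2], direction = ev$direction,
             affected_hap = sample(c("A", "B"), nrow(ev), replace = TRUE),
             stringsAsFactors = FALSE)
}

# Copy numbers of the ALT- and REF-bearing haplotypes at phased het SNPs,
# given one tumor's CNA events. `affected_hap` semantics: loss = the lost
# haplotype, gain = the gained one, cn_loh = the duplicated one.
snp_copy_state <- function(phase, events) {
  n_alt <- rep(1, nrow(phase))
  n_ref <- rep(1, nrow(phase))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    inside <- phase$chrom == ev$chrom &
      phase$pos > ev$start & phase$pos <= ev$end
    if (!any(inside)) next
    alt_affected <- phase$alt_hap[inside] == ev$affected_hap
    cs <- switch(ev$direction,
                 loss = list(alt = ifelse(alt_affected, 0, 1),
                             ref = ifelse(alt_affected, 1, 0)),
                 gain = list(alt = ifelse(alt_affected, 2, 1),
                             ref = ifelse(alt_affected, 1, 2)),
                 cn_loh = list(alt = ifelse(alt_affected, 2, 0),
                               ref = ifelse(alt_affected, 0, 2)),
                 stop("unknown direction: ", ev$direction))
    n_alt[inside] <- cs$alt
    n_ref[inside] <- cs$ref
  }
  data.frame(n_alt_hap = n_alt, n_ref_hap = n_ref)
}

# Median logR implied by purity and total copy number, with segment noise.
event_logr <- function(direction, purity) {
  total <- c(loss = 1, gain = 3, cn_loh = 2)[direction]
  log2((purity * total + (1 - purity) * 2) / 2) + stats::rnorm(1, 0, 0.02)
}

draw_svs <- function(config, sample_id) {
  n <- stats::rpois(1, config$sv_rate_per_tumor)
  if (n == 0) return(empty_svs())
  bp1 <- draw_positions(config$genome, n)
  types <- sample(c("deletion", "duplication", "inversion", "translocation"),
                  n, replace = TRUE, prob = c(0.33, 0.31, 0.13, 0.23))
  bp2 <- bp1
  for (i in seq_len(n)) {
    if (types[i] == "translocation") {
      other <- draw_positions(config$genome, 1)
      bp2$chrom[i] <- other$chrom
      bp2$pos[i] <- other$pos
      if (bp2$chrom[i] != bp1$chrom[i]) types[i] <- "interchromosomal"
    } else {
      len <- chrom_length(config$genome, bp1$chrom[i])
      span <- round(stats::runif(1, 2e4, 2e6))
      bp2$pos[i] <- min(bp1$pos[i] + span, len)
    }
  }
  data.frame(sample_id = sample_id, chrom1 = bp1$chrom, pos1 = bp1$pos,
             chrom2 = bp2$chrom, pos2 = bp2$pos, sv_type = types,
             stringsAsFactors = FALSE)
}

tumor_allelic_counts <- function(config, sample_id, phase, events, purity) {
  if (nrow(phase) == 0) return(empty_counts())
  cs <- snp_copy_state(phase, events)
  f <- expected_alt_fraction(cs$n_alt_hap, cs$n_ref_hap, purity)
  rc <- sample_allelic_depth(f, config$mean_tumor_depth, config$overdispersion)
  data.frame(sample_id = sample_id, chrom = phase$chrom, pos = phase$pos,
             ref_count = rc$ref_count, alt_count = rc$alt_count,
             stringsAsFactors = FALSE)
}

#' Simulate one patient
#'
#' Draws the patient's phased germline het SNPs, then each tumor's somatic
#' variants, CNA events (with the affected parental haplotype recorded in
#' the ground truth), structural variants, and allelic read counts, plus a
#' purity-0 normal sample. Primaries are designed independent: they share
#' no variants except chance positional collisions. Each metastasis
#' inherits `met_inherited_fraction` of its parent primary's variants and
#' the parent's CNA events, plus private variants of its own.
#'
#' @param config A [sim_config()]. The caller owns the RNG state; use
#'   [simulate_cohort()] for seeded end-to-end generation.
#' @param patient_id Patient label.
#' @param n_primaries,n_mets Optional overrides of the configured ranges.
#' @param met_parents Optional integer vector (length `n_mets`) forcing the
#'   parent primary index of each metastasis.
#' @return A list with `samples`, `variants`, `segments`, `svs`, `counts`,
#'   `evidence` (per-tumor allelic support at every patient variant), and
#'   `truth` (`phase`, `cna_events`, `met_parent`).
#' @export
simulate_patient <- function(config, patient_id,
                             n_primaries = NULL, n_mets = NULL,
                             met_parents = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genome <- config$genome
  if (is.null(n_primaries)) n_primaries <- rand_range(config$primaries_per_patient)
  if (is.null(n_mets)) n_mets <- rand_range(config$mets_per_patient)
  if (n_mets > 0 && n_primaries == 0) {
    stop("metastases requested but no primaries to seed them")
  }
  if (!is.null(met_parents)) {
    stopifnot(length(met_parents) == n_mets,
              all(met_parents >= 1 & met_parents <= n_primaries))
  } else {
    met_parents <- if (n_mets > 0) sample.int(n_primaries, n_mets, replace = TRUE)
                   else integer(0)
  }

  # phased germline het SNPs
  phase <- do.call(rbind, lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    r <- genome$chromosomes[i, ]
    k <- config$het_snps_per_chrom
    pos <- sort(sample.int(r$length, k))
    data.frame(chrom = rep(r$name, k), pos = as.integer(pos),
               alt_hap = sample(c("A", "B"), k, replace = TRUE),
               stringsAsFactors = FALSE)
  }))

  mb <- genome_mb(genome)
  normal_id <- paste0(patient_id, "_N")
  prim_ids <- sprintf("%s_P%d", patient_id, seq_len(n_primaries))
  met_ids <- sprintf("%s_M%d", patient_id, seq_len(n_mets))

  samples <- data.frame(
    sample_id = c(prim_ids, met_ids, normal_id),
    patient_id = patient_id,
    sample_type = c(rep("primary", n_primaries),
                    rep("metastasis", n_mets), "normal"),
    purity = c(stats::runif(n_primaries + n_mets,
                            config$purity_range[1], config$purity_range[2]), 0),
    stringsAsFactors = FALSE)

  variants <- list(); segments <- list(); svs <- list(); counts <- list()
  events_all <- list(); prim_variants <- list()

  # normal sample: balanced het SNPs at normal depth
  if (nrow(phase) > 0) {
    rc <- sample_allelic_depth(rep(0.5, nrow(phase)),
                               config$mean_normal_depth, config$overdispersion)
    counts[[normal_id]] <- data.frame(
      sample_id = normal_id, chrom = phase$chrom, pos = phase$pos,
      ref_count = rc$ref_count, alt_count = rc$alt_count,
      stringsAsFactors = FALSE)
  } else counts[[normal_id]] <- empty_counts()

  simulate_tumor <- function(sid, purity, inherited = NULL, rate_factor = 1) {
    n_private <- stats::rpois(1, config$mutation_rate * mb * rate_factor)
    v <- draw_variants(genome, n_private, sid, config$coding_fraction,
                       config$mean_tumor_depth)
    if (!is.null(inherited) && nrow(inherited) > 0) {
      keep <- stats::runif(nrow(inherited)) < config$met_inherited_fraction
      inh <- inherited[keep, , drop = FALSE]
      if (nrow(inh) > 0) {
        inh$sample_id <- sid
        inh$total_depth <- stats::rpois(nrow(inh), config$mean_tumor_depth)
        v <- rbind(inh, v)
        v <- v[!duplicated(variant_key(v)), , drop = FALSE]
      }
    }
    v
  }

  for (i in seq_len(n_primaries)) {
    sid <- prim_ids[i]
    purity <- samples$purity[samples$sample_id == sid]
    ev <- draw_cna_events(config, sid)
    events_all[[sid]] <- ev
    v <- simulate_tumor(sid, purity)
    prim_variants[[i]] <- v
    variants[[sid]] <- v
    segments[[sid]] <- if (nrow(ev) == 0) empty_segments() else data.frame(
      sample_id = sid, chrom = ev$chrom, start = ev$start, end = ev$end,
      median_logr = vapply(ev$direction, event_logr, numeric(1), purity = purity),
      direction = ev$direction, stringsAsFactors = FALSE)
    svs[[sid]] <- draw_svs(config, sid)
    counts[[sid]] <- tumor_allelic_counts(config, sid, phase, ev, purity)
  }

  for (j in seq_len(n_mets)) {
    sid <- met_ids[j]
    purity <- samples$purity[samples$sample_id == sid]
    parent <- met_parents[j]
    ev <- events_all[[prim_ids[parent]]]
    if (nrow(ev) > 0) ev$sample_id <- sid
    events_all[[sid]] <- ev
    variants[[sid]] <- simulate_tumor(sid, purity,
                                      inherited = prim_variants[[parent]],
                                      rate_factor = config$met_time_factor)
    segments[[sid]] <- if (nrow(ev) == 0) empty_segments() else data.frame(
      sample_id = sid, chrom = ev$chrom, start = ev$start, end = ev$end,
      median_logr = vapply(ev$direction, event_logr, numeric(1), purity = purity),
      direction = ev$direction, stringsAsFactors = FALSE)
    svs[[sid]] <- draw_svs(config, sid)
    counts[[sid]] <- tumor_allelic_counts(config, sid, phase, ev, purity)
  }

  variants <- do.call(rbind, c(variants, list(empty_variants())))
  rownames(variants) <- NULL

  # allelic evidence for every tumor at every designed patient variant
  tumor_ids <- c(prim_ids, met_ids)
  uniq <- variants[!duplicated(variant_key(variants)),
                   c("chrom", "pos", "ref", "alt"), drop = FALSE]
  evidence <- do.call(rbind, c(lapply(tumor_ids, function(sid) {
    if (nrow(uniq) == 0) {
      return(data.frame(sample_id = character(), chrom = character(),
                        pos = integer(), ref = character(), alt = character(),
                        ref_count = integer(), alt_count = integer(),
                        stringsAsFactors = FALSE))
    }
    purity <- samples$purity[samples$sample_id == sid]
    carried <- variant_key(uniq) %in%
      variant_key(variants[variants$sample_id == sid, , drop = FALSE])
    depth <- stats::rpois(nrow(uniq), config$mean_tumor_depth)
    alt <- ifelse(carried, stats::rbinom(nrow(uniq), depth, purity / 2), 0L)
    data.frame(sample_id = sid, uniq, ref_count = depth - alt,
               alt_count = as.integer(alt), stringsAsFactors = FALSE)
  }), list()))
  rownames(evidence) <- NULL

  cna_truth <- do.call(rbind, c(unname(events_all),
                                list(data.frame(sample_id = character(),
                                                chrom = character(),
                                                scope = character(),
                                                start = numeric(), end = numeric(),
                                                direction = character(),
                                                affected_hap = character(),
                                                stringsAsFactors = FALSE))))
  rownames(cna_truth) <- NULL

  list(
    patient_id = patient_id,
    samples = samples,
    variants = variants,
    segments = do.call(rbind, c(unname(segments), list(empty_segments()))),
    svs = do.call(rbind, c(unname(svs), list(empty_svs()))),
    counts = do.call(rbind, c(unname(counts), list(empty_counts()))),
    evidence = evidence,
    truth = list(
      phase = cbind(patient_id = rep(patient_id, nrow(phase)), phase),
      cna_events = cbind(patient_id = rep(patient_id, nrow(cna_truth)),
                         cna_truth),
      met_parent = data.frame(patient_id = rep(patient_id, n_mets),
                              metastasis_id = met_ids,
                              parent_id = prim_ids[met_parents],
                              stringsAsFactors = FALSE)
    )
  )
}

#' Simulate a full cohort
#'
#' Seeds the RNG from `config$seed` and simulates `config$n_patients`
#' patients; identical configs produce byte-identical outputs.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, the cohort is written in
#'   the package's file formats via [write_cohort()].
#' @return A `sim_cohort` list: `genome`, `config`, per-cohort data.frames
#'   (`samples`, `variants`, `segments`, `svs`, `counts`, `evidence`) and
#'   `truth` (`phase`, `cna_events`, `met_parent`).
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ids <- sprintf("PT%03d", seq_len(config$n_patients))
  pats <- lapply(ids, function(pid) simulate_patient(config, pid))
  bind <- function(name) {
    out <- do.call(rbind, lapply(pats, `[[`, name))
    rownames(out) <- NULL
    out
  }
  truth <- list(
    phase = do.call(rbind, lapply(pats, function(p) p$truth$phase)),
    cna_events = do.call(rbind, lapply(pats, function(p) p$truth$cna_events)),
    met_parent = do.call(rbind, lapply(pats, function(p) p$truth$met_parent))
  )
  rownames(truth$phase) <- rownames(truth$cna_events) <-
    rownames(truth$met_parent) <- NULL
  cohort <- structure(list(genome = config$genome, config = config,
                           samples = bind("samples"),
                           variants = bind("variants"),
                           segments = bind("segments"),
                           svs = bind("svs"),
                           counts = bind("counts"),
                           evidence = bind("evidence"),
                           truth = truth),
                      class = "sim_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort:", length(unique(x$samples$patient_id)), "patient(s),",
      sum(x$samples$sample_type == "primary"), "primaries,",
      sum(x$samples$sample_type == "metastasis"), "metastases\n")
  cat("  ", nrow(x$variants), "somatic variant records,",
      nrow(x$segments), "CNA segments,", nrow(x$svs), "SVs\n")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits `genome.yaml`, `samples.tsv`, a `manifest.json` ground-truth
#' file, and one directory per patient with per-sample VCF, SEG, SV,
#' allelic-count and variant-evidence files.
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  write_genome_config(cohort$genome, file.path(dir, "genome.yaml"))
  write_sample_meta(cohort$samples, file.path(dir, "samples.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "manifest.json"),
                       dataframe = "columns", digits = NA, pretty = TRUE)
  for (pid in unique(cohort$samples$patient_id)) {
    pdir <- file.path(dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    meta <- cohort$samples[cohort$samples$patient_id == pid, , drop = FALSE]
    for (sid in meta$sample_id) {
      if (meta$sample_type[meta$sample_id == sid] != "normal") {
        write_small_variants(
          cohort$variants[cohort$variants$sample_id == sid, , drop = FALSE],
          file.path(pdir, paste0(sid, ".vcf")))
        seg <- cohort$segments[cohort$segments$sample_id == sid, , drop = FALSE]
        write_seg(seg, file.path(pdir, paste0(sid, ".seg")))
        write_svs(cohort$svs[cohort$svs$sample_id == sid, , drop = FALSE],
                  file.path(pdir, paste0(sid, ".sv.tsv")))
        ev <- cohort$evidence[cohort$evidence$sample_id == sid, , drop = FALSE]
        utils::write.table(ev, file.path(pdir, paste0(sid, ".evidence.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      write_allelic_counts(
        cohort$counts[cohort$counts$sample_id == sid, , drop = FALSE],
        file.path(pdir, paste0(sid, ".counts.tsv")))
    }
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A `sim_cohort`-shaped list (without the generating config).
#' @export
read_cohort <- function(dir) {
  genome <- load_genome_config(file.path(dir, "genome.yaml"))
  samples <- read_sample_meta(file.path(dir, "samples.tsv"))
  truth_raw <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                   simplifyVector = TRUE)
  truth <- lapply(truth_raw, function(x) as.data.frame(x, stringsAsFactors = FALSE))
  variants <- list(); segments <- list(); svs <- list()
  counts <- list(); evidence <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    pdir <- file.path(dir, samples$patient_id[i])
    if (samples$sample_type[i] != "normal") {
      variants[[sid]] <- read_small_variants(
        file.path(pdir, paste0(sid, ".vcf")), sid, genome = genome)
      segments[[sid]] <- read_seg(file.path(pdir, paste0(sid, ".seg")))
      svs[[sid]] <- read_svs(file.path(pdir, paste0(sid, ".sv.tsv")))
      evidence[[sid]] <- utils::read.table(
        file.path(pdir, paste0(sid, ".evidence.tsv")), header = TRUE,
        sep = "\t", stringsAsFactors = FALSE)
    }
    counts[[sid]] <- read_allelic_counts(
      file.path(pdir, paste0(sid, ".counts.tsv")), sid)
  }
  structure(list(genome = genome, config = NULL, samples = samples,
                 variants = do.call(rbind, c(unname(variants),
                                             list(empty_variants()))),
                 segments = do.call(rbind, c(unname(segments),
                                             list(empty_segments()))),
                 svs = do.call(rbind, c(unname(svs), list(empty_svs()))),
                 counts = do.call(rbind, c(unname(counts),
                                           list(empty_counts()))),
                 evidence = do.call(rbind, evidence),
                 truth = truth),
            class = "sim_cohort")
}
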