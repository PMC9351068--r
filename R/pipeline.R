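#' Pairwise parental-allele concordance across a patient's tumors
#'
#' For every chromosome where at least two tumors of the patient carry a
#' filtered CNA segment, compares each tumor pair on each arm using the
#' tumors' own segments (the longest kept segment per tumor and
#' chromosome).
#'
#' @param counts Cohort allelic-count data.frame.
#' @param het_snps Het-SNP data.frame for the patient (from
#'   [select_het_snps()] on the normal sample).
#' @param segments Filtered segment data.frame for the patient's tumors.
#' @param samples Patient sample metadata.
#' @param genome A [genome_config()].
#' @param config A [mapping_config()].
#' @return data.frame of [compare_parental_alleles()] rows (plus the
#'   tumors' directions); zero rows when no chromosome is shared.
#' @export
concordance_table <- function(counts, het_snps, segments, samples,
                              genome = toy_genome(),
                              config = mapping_config()) {
  tumors <- samples$sample_id[samples$sample_type != "normal"]
  rows <- list()
  longest_segment <- function(sid, ch) {
    s <- segments[segments$sample_id == sid & segments$chrom == ch, ,
                  drop = FALSE]
    s[which.max(s$end - s$start), , drop = FALSE]
  }
  for (ch in unique(segments$chrom)) {
    with_seg <- intersect(tumors, segments$sample_id[segments$chrom == ch])
    if (length(with_seg) < 2) next
    for (i in seq_along(with_seg)) for (j in seq_along(with_seg)) {
      if (j <= i) next
      a <- with_seg[i]; b <- with_seg[j]
      seg_a <- longest_segment(a, ch)
      seg_b <- longest_segment(b, ch)
      for (arm in c("p", "q")) {
        if (is.null(arm_restrict(as.list(seg_a), genome, arm)) ||
            is.null(arm_restrict(as.list(seg_b), genome, arm))) next
        calls_a <- call_informative_snps(
          counts[counts$sample_id == a, , drop = FALSE], het_snps,
          seg_a, arm, genome, config)
        calls_b <- call_informative_snps(
          counts[counts$sample_id == b, , drop = FALSE], het_snps,
          seg_b, arm, genome, config)
        cr <- compare_parental_alleles(calls_a, calls_b, config,
                                       tumor_a = a, tumor_b = b,
                                       chrom = ch, arm = arm)
        cr$direction_a <- seg_a$direction
        cr$direction_b <- seg_b$direction
        rows[[length(rows) + 1]] <- cr
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(tumor_a = character(), tumor_b = character(),
                      chrom = character(), arm = character(),
                      n_shared_informative = integer(),
                      alpha_used = numeric(), concordance = numeric(),
                      verdict = character(), direction_a = character(),
                      direction_b = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  class(out) <- "data.frame"
  rownames(out) <- NULL
  out
}

#' Run the full downstream analysis on a cohort
#'
#' `simulate -> filter -> map alleles -> clonality -> summarize` in one
#' call: applies the post-calling filters, maps every kept CNA segment to
#' its affected parental allele, compares tumor pairs per arm, infers
#' clonality per patient, and produces the cohort recurrence tables.
#' Given `out_dir`, every table is written as TSV with deterministic
#' formatting, so a fixed-seed cohort yields byte-identical outputs on
#' repeated runs.
#'
#' @param cohort A `sim_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param out_dir Optional output directory for TSV reports.
#' @param filter_cfg,mapping_cfg,clonality_cfg,recurrence_cfg Module
#'   configs.
#' @param pathways Optional named list of gene sets for enrichment.
#' @return Invisibly, a list of result tables: `filtered` (kept variants /
#'   segments / svs + audits), `mapping`, `concordance`, `shared_counts`,
#'   `primary_pairs`, `origins`, `dissemination`, `burden`, `genes`,
#'   `noncoding`, `cnas`, `minimal_regions`, `pathways`.
#' @export
run_pipeline <- function(cohort, out_dir = NULL,
                         filter_cfg = filter_config(),
                         mapping_cfg = mapping_config(),
                         clonality_cfg = clonality_config(),
                         recurrence_cfg = recurrence_config(),
                         pathways = NULL) {
  genome <- cohort$genome
  samples <- cohort$samples

  fv <- filter_small_variants(cohort$variants, filter_cfg)
  fs <- filter_cna_segments(cohort$segments, filter_cfg, genome)
  fx <- filter_svs(cohort$svs, filter_cfg, genome)

  mapping <- list(); concord <- list()
  pairs <- list(); origins <- list(); dissem <- list(); shared <- list()

  for (pid in unique(samples$patient_id)) {
    meta <- samples[samples$patient_id == pid, , drop = FALSE]
    normal_id <- meta$sample_id[meta$sample_type == "normal"]
    hets <- select_het_snps(
      cohort$counts[cohort$counts$sample_id == normal_id, , drop = FALSE],
      mapping_cfg)
    seg_p <- fs$kept[fs$kept$sample_id %in% meta$sample_id, , drop = FALSE]
    for (i in seq_len(nrow(seg_p))) {
      sid <- seg_p$sample_id[i]
      mapping[[length(mapping) + 1]] <- map_segment(
        cohort$counts[cohort$counts$sample_id == sid, , drop = FALSE],
        hets, seg_p[i, , drop = FALSE], genome, mapping_cfg)
    }
    concord[[pid]] <- concordance_table(cohort$counts, hets, seg_p, meta,
                                        genome, mapping_cfg)

    n_tumors <- sum(meta$sample_type != "normal")
    if (n_tumors >= 2) {
      m <- shared_variant_matrix(
        fv$kept[fv$kept$sample_id %in% meta$sample_id, , drop = FALSE],
        meta, clonality_cfg)
      shared[[pid]] <- data.frame(patient_id = pid,
                                  tumor_a = rep(rownames(m$counts),
                                                each = ncol(m$counts)),
                                  tumor_b = rep(colnames(m$counts),
                                                nrow(m$counts)),
                                  shared_count = as.vector(t(m$counts)),
                                  shared_fraction = as.vector(t(m$fractions)),
                                  stringsAsFactors = FALSE)
      if (sum(meta$sample_type == "primary") >= 2) {
        pp <- classify_primary_pairs(m, clonality_cfg)
        pairs[[pid]] <- cbind(patient_id = pid, pp)
      }
      mets <- meta$sample_id[meta$sample_type == "metastasis"]
      if (length(mets) > 0 && sum(meta$sample_type == "primary") >= 1) {
        oc <- do.call(rbind, lapply(mets, function(mid) {
          assign_metastasis_origin(m, mid, clonality_cfg)
        }))
        origins[[pid]] <- cbind(patient_id = pid, oc)
        dissem[[pid]] <- data.frame(patient_id = pid,
                                    pattern = classify_dissemination(oc),
                                    stringsAsFactors = FALSE)
      }
    }
  }

  bind0 <- function(lst) if (length(lst) == 0) NULL else {
    out <- do.call(rbind, lst)
    rownames(out) <- NULL
    out
  }

  results <- list(
    filtered = list(variants = fv$kept, variant_audit = fv$audit,
                    segments = fs$kept, segment_audit = fs$audit,
                    svs = fx$kept, sv_audit = fx$audit),
    mapping = bind0(mapping),
    concordance = bind0(unname(concord)),
    shared_counts = bind0(unname(shared)),
    primary_pairs = bind0(unname(pairs)),
    origins = bind0(unname(origins)),
    dissemination = bind0(unname(dissem)),
    burden = burden_table(fv$kept, samples, genome),
    genes = recurrent_genes(fv$kept, samples, recurrence_cfg),
    noncoding = recurrent_noncoding(fv$kept, samples, recurrence_cfg),
    cnas = recurrent_cnas(fs$kept, samples, genome, recurrence_cfg),
    minimal_regions = minimal_regions(fs$kept, samples, recurrence_cfg),
    pathways = if (is.null(pathways)) NULL else {
      universe <- sort(unique(stats::na.omit(cohort$variants$gene)))
      mutated <- unique(fv$kept$gene[!is.na(fv$kept$gene) &
                                       fv$kept$effect != "silent"])
      hypergeom_enrichment(mutated, pathways, universe, recurrence_cfg)
    }
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, name) {
      if (is.null(df)) return(invisible(NULL))
      utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    wt(results$filtered$variants, "kept_variants")
    wt(results$filtered$segments, "kept_segments")
    wt(results$filtered$svs, "kept_svs")
    wt(cbind(results$filtered$variant_audit), "variant_audit")
    wt(results$mapping, "mapping_report")
    wt(results$concordance, "concordance")
    wt(results$shared_counts, "shared_variant_counts")
    wt(results$primary_pairs, "primary_pairs")
    wt(results$origins, "origin_calls")
    wt(results$dissemination, "dissemination")
    wt(results$burden, "burden")
    wt(results$genes, "recurrent_genes")
    wt(results$noncoding, "recurrent_noncoding")
    wt(results$cnas, "recurrent_cnas")
    wt(results$minimal_regions, "minimal_regions")
    wt(results$pathways, "pathway_enrichment")
  }
  invisible(results)
}
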