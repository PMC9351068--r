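#' Cohort recurrence settings
#'
#' @param min_patients Minimum distinct patients for a gene, position, or
#'   CNA event to count as recurrent across patients.
#' @param minimal_region_max_len Report minimally targeted regions shorter
#'   than this (bp).
#' @param arm_coverage_threshold Fraction of an arm (or chromosome) a
#'   segment must cover to be classified as an arm-level (whole-chromosome)
#'   event rather than focal.
#' @param pathway_alpha FDR level for pathway enrichment.
#' @return A `recurrence_config` list.
#' @export
recurrence_config <- function(min_patients = 2,
                              minimal_region_max_len = 5e6,
                              arm_coverage_threshold = 0.8,
                              pathway_alpha = 0.1) {
  stopifnot(min_patients >= 2, minimal_region_max_len > 0,
            arm_coverage_threshold > 0, arm_coverage_threshold <= 1,
            pathway_alpha > 0, pathway_alpha < 1)
  structure(list(min_patients = min_patients,
                 minimal_region_max_len = minimal_region_max_len,
                 arm_coverage_threshold = arm_coverage_threshold,
                 pathway_alpha = pathway_alpha),
            class = "recurrence_config")
}

#' Somatic mutation burden
#'
#' @param variants Small-variant data.frame for one sample.
#' @param genome_mb Genome size in Mb (> 0).
#' @return Mutations per Mb.
#' @export
mutation_burden <- function(variants, genome_mb) {
  stopifnot(genome_mb > 0)
  nrow(variants) / genome_mb
}

#' Per-sample mutation burden table for a cohort
#'
#' @param variants Cohort variant data.frame.
#' @param samples Sample-metadata data.frame.
#' @param genome A [genome_config()].
#' @return data.frame `(sample_id, patient_id, sample_type, n_variants,
#'   burden_per_mb)`, one row per tumor sample.
#' @export
burden_table <- function(variants, samples, genome) {
  mb <- genome_mb(genome)
  tumors <- samples[samples$sample_type != "normal", , drop = FALSE]
  n <- vapply(tumors$sample_id, function(sid) {
    sum(variants$sample_id == sid)
  }, numeric(1))
  data.frame(sample_id = tumors$sample_id, patient_id = tumors$patient_id,
             sample_type = tumors$sample_type, n_variants = n,
             burden_per_mb = n / mb, row.names = NULL,
             stringsAsFactors = FALSE)
}

patient_of <- function(sample_id, samples) {
  samples$patient_id[match(sample_id, samples$sample_id)]
}

#' Recurrently mutated genes
#'
#' Counts, per gene, the patients and tumors carrying at least one
#' nonsynonymous variant (any effect other than silent). A gene counts
#' once per patient regardless of how many of that patient's tumors carry
#' it. Variants without gene or effect annotation are skipped and tallied
#' in the `n_skipped` attribute.
#'
#' @param variants Cohort variant data.frame.
#' @param samples Sample-metadata data.frame.
#' @param config A [recurrence_config()].
#' @return data.frame `(gene, n_patients, n_tumors, recurrent)` sorted by
#'   descending patient count.
#' @export
recurrent_genes <- function(variants, samples, config = recurrence_config()) {
  skip <- is.na(variants$gene) | is.na(variants$effect)
  v <- variants[!skip & variants$effect != "silent", , drop = FALSE]
  v$patient <- patient_of(v$sample_id, samples)
  out <- if (nrow(v) == 0) {
    data.frame(gene = character(), n_patients = integer(),
               n_tumors = integer(), recurrent = logical(),
               stringsAsFactors = FALSE)
  } else {
    agg <- lapply(split(v, v$gene), function(g) {
      data.frame(gene = g$gene[1],
                 n_patients = length(unique(g$patient)),
                 n_tumors = length(unique(g$sample_id)),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, agg)
    out$recurrent <- out$n_patients >= config$min_patients
    out <- out[order(-out$n_patients, -out$n_tumors, out$gene), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  attr(out, "n_skipped") <- sum(skip)
  out
}

#' Recurrent noncoding positions
#'
#' Noncoding variants keyed by exact `(chrom, pos, ref, alt)`; a key is
#' recurrent across patients at `min_patients` distinct patients. Two
#' different ALT alleles at one position are two keys.
#'
#' @inheritParams recurrent_genes
#' @return data.frame `(chrom, pos, ref, alt, n_patients, n_tumors,
#'   recurrent)`.
#' @export
recurrent_noncoding <- function(variants, samples,
                                config = recurrence_config()) {
  v <- variants[!is.na(variants$region) & variants$region == "noncoding", ,
                drop = FALSE]
  if (nrow(v) == 0) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), n_patients = integer(),
                      n_tumors = integer(), recurrent = logical(),
                      stringsAsFactors = FALSE))
  }
  v$patient <- patient_of(v$sample_id, samples)
  v$key <- variant_key(v)
  agg <- lapply(split(v, v$key), function(g) {
    data.frame(chrom = g$chrom[1], pos = g$pos[1], ref = g$ref[1],
               alt = g$alt[1], n_patients = length(unique(g$patient)),
               n_tumors = length(unique(g$sample_id)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out$recurrent <- out$n_patients >= config$min_patients
  out <- out[order(-out$n_patients, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Classify one segment as whole-chromosome, arm-level, or focal by
# fractional coverage of the chromosome / arm.
classify_segment_scope <- function(segment, genome, threshold) {
  len <- segment$end - segment$start
  chrom_len <- chrom_length(genome, segment$chrom)
  if (len / chrom_len >= threshold) return(list(scope = "whole", arm = "whole"))
  ab <- arm_bounds(genome, segment$chrom)
  for (i in seq_len(nrow(ab))) {
    ov <- max(0, min(segment$end, ab$end[i]) - max(segment$start, ab$start[i]))
    if (ov / (ab$end[i] - ab$start[i]) >= threshold) {
      return(list(scope = "arm", arm = ab$arm[i]))
    }
  }
  list(scope = "focal", arm = NA_character_)
}

#' Recurrent copy-number events
#'
#' Each filtered segment is classified as whole-chromosome, arm-level or
#' focal by fractional coverage; events are keyed by
#' `(chromosome-or-arm, direction, scope)` and tallied over tumors and
#' patients. Focal events are keyed by chromosome and marked `"F"`-style
#' via `scope = "focal"`.
#'
#' @param segments Filtered cohort segment data.frame.
#' @param samples Sample-metadata data.frame.
#' @param genome A [genome_config()].
#' @param config A [recurrence_config()].
#' @return data.frame `(chrom, arm, scope, direction, n_tumors,
#'   tumor_fraction, n_patients, recurrent)`; `tumor_fraction` is over all
#'   tumor samples in `samples`.
#' @export
recurrent_cnas <- function(segments, samples, genome = toy_genome(),
                           config = recurrence_config()) {
  n_tumors_total <- sum(samples$sample_type != "normal")
  if (nrow(segments) == 0) {
    return(data.frame(chrom = character(), arm = character(),
                      scope = character(), direction = character(),
                      n_tumors = integer(), tumor_fraction = numeric(),
                      n_patients = integer(), recurrent = logical(),
                      stringsAsFactors = FALSE))
  }
  cls <- lapply(seq_len(nrow(segments)), function(i) {
    classify_segment_scope(segments[i, ], genome, config$arm_coverage_threshold)
  })
  segments$scope <- vapply(cls, `[[`, character(1), "scope")
  segments$arm <- vapply(cls, `[[`, character(1), "arm")
  segments$patient <- patient_of(segments$sample_id, samples)
  key <- paste(segments$chrom, segments$arm, segments$scope, segments$direction)
  agg <- lapply(split(segments, key), function(g) {
    data.frame(chrom = g$chrom[1], arm = g$arm[1], scope = g$scope[1],
               direction = g$direction[1],
               n_tumors = length(unique(g$sample_id)),
               tumor_fraction = length(unique(g$sample_id)) / n_tumors_total,
               n_patients = length(unique(g$patient)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out$recurrent <- out$n_patients >= config$min_patients
  out <- out[order(-out$n_tumors, out$chrom, out$direction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Minimally targeted regions
#'
#' Direction-stratified interval intersection: within each direction and
#' chromosome, the genome is cut at all segment breakpoints; maximal runs
#' of atomic intervals supported by the identical set of segments and
#' covering at least `min_patients` distinct patients form candidate
#' regions (the intersection of their supporting segments). Regions
#' shorter than `minimal_region_max_len` are reported. By construction the
#' output regions are pairwise disjoint and each lies inside every
#' contributing segment.
#'
#' @param segments Filtered cohort segment data.frame.
#' @param samples Sample-metadata data.frame.
#' @param config A [recurrence_config()].
#' @return data.frame `(chrom, start, end, length, direction, n_patients,
#'   n_segments)`.
#' @export
minimal_regions <- function(segments, samples, config = recurrence_config()) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      length = numeric(), direction = character(),
                      n_patients = integer(), n_segments = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(segments) == 0) return(empty)
  segments$patient <- patient_of(segments$sample_id, samples)
  out <- list()
  for (dir in unique(segments$direction)) {
    sd <- segments[segments$direction == dir, , drop = FALSE]
    for (ch in unique(sd$chrom)) {
      sc <- sd[sd$chrom == ch, , drop = FALSE]
      cuts <- sort(unique(c(sc$start, sc$end)))
      if (length(cuts) < 2) next
      atoms <- data.frame(start = cuts[-length(cuts)], end = cuts[-1])
      support <- lapply(seq_len(nrow(atoms)), function(i) {
        which(sc$start <= atoms$start[i] & sc$end >= atoms$end[i])
      })
      npat <- vapply(support, function(s) {
        length(unique(sc$patient[s]))
      }, integer(1))
      keep <- npat >= config$min_patients
      if (!any(keep)) next
      # merge consecutive atoms with identical support
      sig <- vapply(support, paste, character(1), collapse = ",")
      run_id <- cumsum(c(TRUE, sig[-1] != sig[-length(sig)] |
                           atoms$start[-1] != atoms$end[-length(sig)]))
      for (r in unique(run_id[keep])) {
        idx <- which(run_id == r & keep)
        if (length(idx) == 0) next
        s <- support[[idx[1]]]
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = atoms$start[idx[1]], end = atoms$end[max(idx)],
          length = atoms$end[max(idx)] - atoms$start[idx[1]],
          direction = dir, n_patients = length(unique(sc$patient[s])),
          n_segments = length(s), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(empty)
  out <- do.call(rbind, out)
  out <- out[out$length < config$minimal_region_max_len, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$direction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric pathway enrichment
#'
#' Upper-tail hypergeometric test of overlap between the mutated gene set
#' and each pathway, both restricted to the gene universe, with BH
#' correction across pathways. For a pathway of size `K` in a universe of
#' `N` genes of which `n` are mutated and `k` fall in the pathway,
#' `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)`.
#'
#' @param mutated Character vector of mutated genes (intersected with the
#'   universe).
#' @param pathways Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Character vector of all testable genes; must be
#'   non-empty.
#' @param config A [recurrence_config()].
#' @return data.frame `(pathway, k, K, n, N, p_raw, p_adj, significant)`.
#' @export
hypergeom_enrichment <- function(mutated, pathways, universe,
                                 config = recurrence_config()) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty gene universe")
  mutated <- intersect(unique(mutated), universe)
  N <- length(universe)
  n <- length(mutated)
  rows <- lapply(names(pathways), function(pw) {
    genes <- intersect(unique(pathways[[pw]]), universe)
    K <- length(genes)
    k <- length(intersect(genes, mutated))
    p <- if (k == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, k = k, K = K, n = n, N = N, p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_bh(out$p_raw)
  out$significant <- out$p_adj < config$pathway_alpha
  out <- out[order(out$p_raw, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}
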