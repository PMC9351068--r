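#' Post-calling filter thresholds
#'
#' Defaults follow the study rules: small variants with total depth
#' <= 6 reads or population allele frequency > 0.001 are removed; CNA
#' segments are kept when |median logR| clears 0.15 (copy-neutral LOH
#' segments bypass the logR rule — they are logR-neutral by definition),
#' are >= 10 kb long, and have no breakpoint inside a centromere or
#' strictly within 1 Mb of a chromosome end; intrachromosomal SVs
#' spanning < 10 kb and SVs with a centromeric breakpoint are removed.
#' All comparisons sit on the quoted side of each boundary: depth 7 is
#' kept, AF exactly 0.001 is kept, logR exactly 0.15 is removed, a
#' 10,000 bp segment is kept.
#'
#' Breakpoints exactly at position 0 or at the chromosome length are
#' telomeric termini of whole-chromosome/terminal events and are exempt
#' from the end-margin rule; otherwise every whole-chromosome event would
#' be discarded by its own telomeric breakpoints.
#'
#' @param min_depth_exclusive Remove variants with depth <= this (reads).
#' @param max_population_af Remove variants with population AF > this.
#' @param logr_gain_threshold Keep gains with median logR > this.
#' @param logr_loss_threshold Keep losses with median logR < this.
#' @param min_cna_length Remove CNA segments shorter than this (bp).
#' @param chrom_end_margin Remove segments with an internal breakpoint
#'   strictly within this distance of a chromosome end (bp).
#' @param min_sv_span Remove intrachromosomal SVs spanning less than this (bp).
#' @param manual_exclusions Optional data.frame `(sample_id, chrom, pos,
#'   ref, alt)` of records to drop, emulating manual artifact review.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_depth_exclusive = 6,
                          max_population_af = 0.001,
                          logr_gain_threshold = 0.15,
                          logr_loss_threshold = -0.15,
                          min_cna_length = 10000,
                          chrom_end_margin = 1e6,
                          min_sv_span = 10000,
                          manual_exclusions = NULL) {
  stopifnot(is.finite(min_depth_exclusive), is.finite(max_population_af),
            is.finite(logr_gain_threshold), is.finite(logr_loss_threshold),
            min_cna_length >= 0, chrom_end_margin >= 0, min_sv_span >= 0)
  structure(list(min_depth_exclusive = min_depth_exclusive,
                 max_population_af = max_population_af,
                 logr_gain_threshold = logr_gain_threshold,
                 logr_loss_threshold = logr_loss_threshold,
                 min_cna_length = min_cna_length,
                 chrom_end_margin = chrom_end_margin,
                 min_sv_span = min_sv_span,
                 manual_exclusions = manual_exclusions),
            class = "filter_config")
}

filter_result <- function(records, kept, rule) {
  stopifnot(length(kept) == nrow(records), length(rule) == nrow(records))
  stopifnot(all(kept == is.na(rule)))  # kept xor named failing rule
  audit <- data.frame(kept = kept, rule = rule, stringsAsFactors = FALSE)
  list(kept = records[kept, , drop = FALSE], audit = audit)
}

#' Filter somatic small variants
#'
#' A variant is kept iff its total depth exceeds the depth cutoff and its
#' population allele frequency is missing or at most the AF cutoff.
#' A missing population AF never removes a variant: absence of evidence
#' that a variant is a population polymorphism is not evidence.
#'
#' @param variants Small-variant data.frame.
#' @param config A [filter_config()].
#' @return `list(kept =, audit =)`; the audit has one row per input record
#'   with `kept` and the first failing `rule` (`NA` when kept). Input order
#'   is preserved.
#' @export
filter_small_variants <- function(variants, config = filter_config()) {
  n <- nrow(variants)
  rule <- rep(NA_character_, n)
  if (n > 0) {
    fail_depth <- variants$total_depth <= config$min_depth_exclusive
    fail_af <- !is.na(variants$population_af) &
      variants$population_af > config$max_population_af
    rule[fail_af] <- "population_af"
    rule[fail_depth] <- "depth"
    if (!is.null(config$manual_exclusions) && nrow(config$manual_exclusions) > 0) {
      ex <- paste(config$manual_exclusions$sample_id,
                  variant_key(config$manual_exclusions))
      hit <- paste(variants$sample_id, variant_key(variants)) %in% ex
      rule[hit & is.na(rule)] <- "manual_exclusion"
    }
  }
  filter_result(variants, is.na(rule), rule)
}

breakpoint_in_centromere <- function(genome, chrom, bp) {
  r <- chrom_row(genome, chrom)
  bp > r$centromere_start & bp < r$centromere_end
}

breakpoint_near_end <- function(genome, chrom, bp, margin) {
  len <- chrom_length(genome, chrom)
  (bp > 0 & bp < margin) | (bp < len & bp > len - margin)
}

#' Filter copy-number segments
#'
#' @param segments Segment data.frame (0-based half-open coordinates).
#' @param config A [filter_config()].
#' @param genome A [genome_config()]; unknown chromosomes are an error.
#' @return `list(kept =, audit =)` as in [filter_small_variants()].
#' @export
filter_cna_segments <- function(segments, config = filter_config(),
                                genome = toy_genome()) {
  n <- nrow(segments)
  rule <- rep(NA_character_, n)
  if (n > 0) {
    chrom_row(genome, unique(segments$chrom))  # errors on unknown chromosome
    pass_logr <- segments$direction == "cn_loh" |
      segments$median_logr > config$logr_gain_threshold |
      segments$median_logr < config$logr_loss_threshold
    fail_len <- (segments$end - segments$start) < config$min_cna_length
    fail_cen <- breakpoint_in_centromere(genome, segments$chrom, segments$start) |
      breakpoint_in_centromere(genome, segments$chrom, segments$end)
    fail_end <- breakpoint_near_end(genome, segments$chrom, segments$start,
                                    config$chrom_end_margin) |
      breakpoint_near_end(genome, segments$chrom, segments$end,
                          config$chrom_end_margin)
    rule[fail_end] <- "chrom_end_margin"
    rule[fail_cen] <- "centromere_breakpoint"
    rule[fail_len] <- "min_length"
    rule[!pass_logr] <- "logr"
  }
  filter_result(segments, is.na(rule), rule)
}

#' Filter structural variants
#'
#' Intrachromosomal SVs must span at least the minimum size (distance
#' between the two breakpoints); interchromosomal SVs have no span rule.
#' Any SV with a breakpoint inside a centromere is removed.
#'
#' @param svs SV data.frame.
#' @param config A [filter_config()].
#' @param genome A [genome_config()].
#' @return `list(kept =, audit =)` as in [filter_small_variants()].
#' @export
filter_svs <- function(svs, config = filter_config(), genome = toy_genome()) {
  n <- nrow(svs)
  rule <- rep(NA_character_, n)
  if (n > 0) {
    chrom_row(genome, unique(c(svs$chrom1, svs$chrom2)))
    intra <- svs$chrom1 == svs$chrom2
    fail_span <- intra & abs(svs$pos2 - svs$pos1) < config$min_sv_span
    fail_cen <- breakpoint_in_centromere(genome, svs$chrom1, svs$pos1) |
      breakpoint_in_centromere(genome, svs$chrom2, svs$pos2)
    rule[fail_cen] <- "centromere_breakpoint"
    rule[fail_span] <- "min_span"
  }
  filter_result(svs, is.na(rule), rule)
}

#' Consensus of two call sets
#'
#' Utility mirroring a two-caller intersection: keeps records of `a`
#' whose `(chrom, pos, ref, alt)` key also occurs in `b`.
#'
#' @param a,b Small-variant data.frames for the same sample.
#' @return Subset of `a`.
#' @export
consensus_variants <- function(a, b) {
  a[variant_key(a) %in% variant_key(b), , drop = FALSE]
}
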