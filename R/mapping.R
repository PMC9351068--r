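#' Chromosome-mapping settings
#'
#' Thresholds for selecting heterozygous germline SNPs, calling
#' informative SNPs in tumors, and comparing the affected parental allele
#' between tumors. Defaults follow the study procedure: het SNPs require
#' normal read depth > 10 and VAF in `[0.4, 0.6]` (inclusive); tumor SNPs
#' enter the test only at depth > 10; informative SNPs have FDR-adjusted
#' P < 0.05, relaxed to P < 0.1 for tumor pairs sharing fewer than 1000
#' informative SNPs. The concordance cutoffs that turn a fraction of
#' allele-agreeing SNPs into a same/different verdict are this package's
#' own (the study reports qualitative calls only) and are config-exposed.
#'
#' @param normal_min_depth_exclusive Het-SNP normal depth cutoff (strict >).
#' @param normal_vaf_low,normal_vaf_high Inclusive het-SNP VAF bounds.
#' @param tumor_min_depth_exclusive Tumor depth cutoff (strict >).
#' @param alpha_primary,alpha_relaxed FDR levels.
#' @param relaxation_snp_count Shared-informative-SNP count below which the
#'   relaxed level is applied to both tumors.
#' @param concordance_same_min Concordance at or above which the verdict is
#'   `same_allele`.
#' @param concordance_diff_max Concordance at or below which the verdict is
#'   `different_allele`.
#' @return A `mapping_config` list.
#' @export
mapping_config <- function(normal_min_depth_exclusive = 10,
                           normal_vaf_low = 0.4, normal_vaf_high = 0.6,
                           tumor_min_depth_exclusive = 10,
                           alpha_primary = 0.05, alpha_relaxed = 0.1,
                           relaxation_snp_count = 1000,
                           concordance_same_min = 0.9,
                           concordance_diff_max = 0.1) {
  stopifnot(alpha_primary > 0, alpha_primary <= alpha_relaxed,
            alpha_relaxed < 1,
            normal_vaf_low >= 0, normal_vaf_low < normal_vaf_high,
            normal_vaf_high <= 1,
            concordance_diff_max < concordance_same_min)
  structure(list(normal_min_depth_exclusive = normal_min_depth_exclusive,
                 normal_vaf_low = normal_vaf_low,
                 normal_vaf_high = normal_vaf_high,
                 tumor_min_depth_exclusive = tumor_min_depth_exclusive,
                 alpha_primary = alpha_primary,
                 alpha_relaxed = alpha_relaxed,
                 relaxation_snp_count = relaxation_snp_count,
                 concordance_same_min = concordance_same_min,
                 concordance_diff_max = concordance_diff_max),
            class = "mapping_config")
}

#' Select heterozygous germline SNPs from the matched normal
#'
#' @param normal_counts Allelic-count data.frame from the patient's normal
#'   sample. Depth-0 rows are skipped (VAF undefined).
#' @param config A [mapping_config()].
#' @return Subset of `normal_counts` passing depth > cutoff and
#'   VAF within the inclusive bounds.
#' @export
select_het_snps <- function(normal_counts, config = mapping_config()) {
  depth <- normal_counts$ref_count + normal_counts$alt_count
  ok <- depth > config$normal_min_depth_exclusive
  vaf <- ifelse(depth > 0, normal_counts$alt_count / depth, NA)
  ok <- ok & !is.na(vaf) &
    vaf >= config$normal_vaf_low & vaf <= config$normal_vaf_high
  out <- normal_counts[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact two-sided binomial test against a fair null
#'
#' Minimum-likelihood two-sided p-value under Binomial(n = ref + alt, 1/2):
#' the sum of P(k) over all outcomes k whose probability does not exceed
#' that of the observed count. Symmetric in its two arguments; equal
#' counts give p = 1 (the observed value is the mode of a symmetric null).
#'
#' @param ref_count,alt_count Non-negative read counts (vectorized);
#'   `ref_count + alt_count >= 1`.
#' @return p-values in `(0, 1]`.
#' @export
binomial_two_sided_p <- function(ref_count, alt_count) {
  stopifnot(length(ref_count) == length(alt_count),
            all(ref_count >= 0), all(alt_count >= 0))
  n <- ref_count + alt_count
  if (any(n < 1)) stop("binomial_two_sided_p: both counts are 0")
  # relative tolerance guards against ties broken by floating-point noise
  rel <- 1 + 1e-7
  vapply(seq_along(n), function(i) {
    d <- stats::dbinom(0:n[i], n[i], 0.5)
    min(1, sum(d[d <= d[alt_count[i] + 1] * rel]))
  }, numeric(1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-adjusted p-values, clipped to 1, returned in the input
#' order.
#'
#' @param p p-values in `(0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stopifnot(all(p > 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

# Restrict a segment to one chromosome arm; NULL when they do not overlap.
arm_restrict <- function(segment, genome, arm) {
  ab <- arm_bounds(genome, segment$chrom)
  ab <- ab[ab$arm == arm, , drop = FALSE]
  if (nrow(ab) == 0) return(NULL)
  lo <- max(segment$start, ab$start)
  hi <- min(segment$end, ab$end)
  if (hi <= lo) return(NULL)
  list(chrom = segment$chrom, start = lo, end = hi)
}

#' Call informative SNPs for one tumor on one arm-restricted segment
#'
#' Candidates are the het-SNP positions inside the segment restricted to
#' the given arm whose tumor depth exceeds the cutoff. The exact binomial
#' p-values of the candidates form one BH family; candidates with adjusted
#' P below `alpha` are informative. The major allele (larger read count)
#' of an informative SNP is always defined: tied counts give p = 1 and can
#' never be informative.
#'
#' @param tumor_counts Allelic-count data.frame for the tumor.
#' @param het_snps Het-SNP data.frame from [select_het_snps()] (or any
#'   data.frame with `chrom` and `pos`).
#' @param segment One-row segment data.frame (or list) with `chrom`,
#'   `start`, `end` (0-based half-open).
#' @param arm `"p"` or `"q"`.
#' @param genome A [genome_config()].
#' @param config A [mapping_config()].
#' @param alpha FDR level; default `config$alpha_primary`.
#' @return data.frame of candidates: `chrom`, `pos`, `ref_count`,
#'   `alt_count`, `p_raw`, `p_adj`, `major_allele` (`"REF"`/`"ALT"`/NA for
#'   ties), `informative`. Zero candidates give a zero-row frame.
#' @export
call_informative_snps <- function(tumor_counts, het_snps, segment, arm,
                                  genome = toy_genome(),
                                  config = mapping_config(),
                                  alpha = config$alpha_primary) {
  seg <- arm_restrict(as.list(segment[1, , drop = FALSE]), genome, arm)
  empty <- data.frame(chrom = character(), pos = integer(),
                      ref_count = integer(), alt_count = integer(),
                      p_raw = numeric(), p_adj = numeric(),
                      major_allele = character(), informative = logical(),
                      stringsAsFactors = FALSE)
  if (is.null(seg)) return(empty)
  het_key <- paste(het_snps$chrom, het_snps$pos)
  tc <- tumor_counts
  inside <- tc$chrom == seg$chrom & tc$pos > seg$start & tc$pos <= seg$end
  cand <- tc[inside & paste(tc$chrom, tc$pos) %in% het_key, , drop = FALSE]
  depth <- cand$ref_count + cand$alt_count
  cand <- cand[depth > config$tumor_min_depth_exclusive, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  p_raw <- binomial_two_sided_p(cand$ref_count, cand$alt_count)
  p_adj <- adjust_bh(p_raw)
  out <- data.frame(
    chrom = cand$chrom, pos = cand$pos,
    ref_count = cand$ref_count, alt_count = cand$alt_count,
    p_raw = p_raw, p_adj = p_adj,
    major_allele = ifelse(cand$ref_count > cand$alt_count, "REF",
                          ifelse(cand$alt_count > cand$ref_count, "ALT",
                                 NA_character_)),
    informative = p_adj < alpha,
    stringsAsFactors = FALSE)
  stopifnot(!any(out$informative & is.na(out$major_allele)))
  rownames(out) <- NULL
  out
}

#' Compare the affected parental allele between two tumors on one arm
#'
#' Takes the candidate tables of two tumors from the same patient on the
#' same chromosome arm (outputs of [call_informative_snps()]; the adjusted
#' p-values of each tumor's own family are reused at both FDR levels).
#' The shared set is the positions informative in both tumors at the
#' primary level; if it holds fewer than `relaxation_snp_count` SNPs, both
#' tumors are re-called at the relaxed level and the shared set is
#' recomputed, with the level recorded in `alpha_used`. Concordance is the
#' fraction of shared SNPs whose major allele agrees; verdicts:
#' `same_allele` (>= `concordance_same_min`), `different_allele`
#' (<= `concordance_diff_max`), otherwise `ambiguous`; `no_call` when the
#' shared set is empty even after relaxation.
#'
#' @param calls_a,calls_b Candidate tables from [call_informative_snps()].
#' @param config A [mapping_config()].
#' @param tumor_a,tumor_b Sample labels for the report.
#' @param chrom,arm Location labels for the report.
#' @return One-row data.frame of class `concordance_result`: `tumor_a`,
#'   `tumor_b`, `chrom`, `arm`, `n_shared_informative`, `alpha_used`,
#'   `concordance`, `verdict`.
#' @export
compare_parental_alleles <- function(calls_a, calls_b,
                                     config = mapping_config(),
                                     tumor_a = "tumor_a", tumor_b = "tumor_b",
                                     chrom = NA_character_,
                                     arm = NA_character_) {
  shared_at <- function(alpha) {
    ia <- calls_a[calls_a$p_adj < alpha, , drop = FALSE]
    ib <- calls_b[calls_b$p_adj < alpha, , drop = FALSE]
    key_a <- paste(ia$chrom, ia$pos)
    key_b <- paste(ib$chrom, ib$pos)
    shared <- intersect(key_a, key_b)
    list(n = length(shared),
         agree = sum(ia$major_allele[match(shared, key_a)] ==
                       ib$major_allele[match(shared, key_b)]))
  }
  alpha_used <- config$alpha_primary
  s <- shared_at(alpha_used)
  if (s$n < config$relaxation_snp_count) {
    alpha_used <- config$alpha_relaxed
    s <- shared_at(alpha_used)
  }
  if (s$n == 0) {
    concordance <- NA_real_
    verdict <- "no_call"
  } else {
    concordance <- s$agree / s$n
    verdict <- if (concordance >= config$concordance_same_min) "same_allele"
               else if (concordance <= config$concordance_diff_max) "different_allele"
               else "ambiguous"
  }
  out <- data.frame(tumor_a = tumor_a, tumor_b = tumor_b,
                    chrom = chrom, arm = arm,
                    n_shared_informative = s$n, alpha_used = alpha_used,
                    concordance = concordance, verdict = verdict,
                    stringsAsFactors = FALSE)
  class(out) <- c("concordance_result", class(out))
  out
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("%s vs %s (%s %s-arm): %s [%d shared informative SNPs, alpha %.2g%s]\n",
              x$tumor_a, x$tumor_b, x$chrom, x$arm, x$verdict,
              x$n_shared_informative, x$alpha_used,
              if (is.na(x$concordance)) ""
              else sprintf(", concordance %.3f", x$concordance)))
  invisible(x)
}

#' Map one copy-number segment to its affected parental allele
#'
#' Splits the segment at the centromere and calls informative SNPs on
#' each arm independently (each arm is its own BH family, because p and q
#' arms can carry different parental-allele events). For each arm the
#' report gives the candidate and informative counts and the fraction of
#' informative SNPs whose major allele is REF; under a loss the major
#' allele marks the retained haplotype, under a gain the amplified one,
#' and under copy-neutral LOH the duplicated one.
#'
#' @param tumor_counts Allelic-count data.frame for the tumor.
#' @param het_snps Het-SNP data.frame from [select_het_snps()].
#' @param segment One-row segment data.frame (must have survived
#'   [filter_cna_segments()]).
#' @param genome A [genome_config()].
#' @param config A [mapping_config()].
#' @param alpha FDR level; default `config$alpha_primary`.
#' @return data.frame with one row per overlapped arm: `sample_id`,
#'   `chrom`, `arm`, `direction`, `n_candidates`, `n_informative`,
#'   `alpha_used`, `fraction_major_ref`, `call`
#'   (`"mapped"`/`"no_call"`). A segment entirely inside the centromere
#'   yields a single `no_call` row with `arm = NA`.
#' @export
map_segment <- function(tumor_counts, het_snps, segment,
                        genome = toy_genome(), config = mapping_config(),
                        alpha = config$alpha_primary) {
  seg <- segment[1, , drop = FALSE]
  rows <- list()
  for (arm in c("p", "q")) {
    if (is.null(arm_restrict(as.list(seg), genome, arm))) next
    calls <- call_informative_snps(tumor_counts, het_snps, seg, arm,
                                   genome, config, alpha)
    inf <- calls[calls$informative, , drop = FALSE]
    rows[[arm]] <- data.frame(
      sample_id = seg$sample_id, chrom = seg$chrom, arm = arm,
      direction = seg$direction,
      n_candidates = nrow(calls), n_informative = nrow(inf),
      alpha_used = alpha,
      fraction_major_ref = if (nrow(inf) == 0) NA_real_
                           else mean(inf$major_allele == "REF"),
      call = if (nrow(inf) == 0) "no_call" else "mapped",
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(sample_id = seg$sample_id, chrom = seg$chrom,
                      arm = NA_character_, direction = seg$direction,
                      n_candidates = 0L, n_informative = 0L,
                      alpha_used = alpha, fraction_major_ref = NA_real_,
                      call = "no_call", stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
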