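#' Clonality-inference settings
#'
#' Tumor pairs are compared on full variant identity
#' `(chrom, pos, ref, alt)`: two different substitutions at the same
#' position are different variants. Synchronous primaries are called
#' independent when they share essentially nothing (the study observed a
#' mean of 1.9 shared SNVs/indels, 0.08%, range 0--14 / 0--0.7%, and
#' called all primary pairs independent). The metastasis-origin thresholds
#' (minimum shared count and dominance over the runner-up) are this
#' package's explicit restatement of the study's by-inspection assignment.
#'
#' @param independence_max_shared_fraction Pairs with shared fraction below
#'   this (and count below `origin_min_shared`) are independent.
#' @param origin_min_shared Minimum shared variants to assign an origin.
#' @param origin_dominance_ratio Best primary must share at least this
#'   multiple of the runner-up's count.
#' @param subclonal_check_min_reads ALT reads that flag a shared variant as
#'   subclonally present in a tumor where it was not called.
#' @param fraction_denominator `"min"` (smaller tumor set; conservative,
#'   symmetric) or `"union"`.
#' @return A `clonality_config` list.
#' @export
clonality_config <- function(independence_max_shared_fraction = 0.01,
                             origin_min_shared = 5,
                             origin_dominance_ratio = 2.0,
                             subclonal_check_min_reads = 2,
                             fraction_denominator = c("min", "union")) {
  fraction_denominator <- match.arg(fraction_denominator)
  stopifnot(independence_max_shared_fraction > 0, origin_min_shared > 0,
            origin_dominance_ratio > 1, subclonal_check_min_reads > 0)
  structure(list(independence_max_shared_fraction = independence_max_shared_fraction,
                 origin_min_shared = origin_min_shared,
                 origin_dominance_ratio = origin_dominance_ratio,
                 subclonal_check_min_reads = subclonal_check_min_reads,
                 fraction_denominator = fraction_denominator),
            class = "clonality_config")
}

#' Pairwise shared-variant matrix for one patient
#'
#' @param variants Small-variant data.frame covering the patient's tumor
#'   samples (post-filtering).
#' @param samples Sample-metadata data.frame; all tumors must belong to one
#'   patient (mixing patients is an error: variant sharing is undefined
#'   across germlines).
#' @param config A [clonality_config()].
#' @return A `shared_variant_matrix`: list with `counts` (symmetric matrix;
#'   diagonal = each tumor's own set size), `fractions`, `shared_keys`
#'   (per-pair audit list), `samples`.
#' @export
shared_variant_matrix <- function(variants, samples,
                                  config = clonality_config()) {
  tumors <- samples[samples$sample_type != "normal", , drop = FALSE]
  if (nrow(tumors) < 2) stop("need at least 2 tumor samples")
  if (length(unique(tumors$patient_id)) != 1) {
    stop("tumor samples from more than one patient")
  }
  ids <- tumors$sample_id
  sets <- lapply(ids, function(sid) {
    unique(variant_key(variants[variants$sample_id == sid, , drop = FALSE]))
  })
  names(sets) <- ids
  k <- length(ids)
  counts <- matrix(0, k, k, dimnames = list(ids, ids))
  fractions <- matrix(0, k, k, dimnames = list(ids, ids))
  shared_keys <- list()
  for (i in seq_len(k)) {
    counts[i, i] <- length(sets[[i]])
    fractions[i, i] <- 1
    for (j in seq_len(k)) {
      if (j <= i) next
      sh <- intersect(sets[[i]], sets[[j]])
      counts[i, j] <- counts[j, i] <- length(sh)
      den <- switch(config$fraction_denominator,
                    min = min(length(sets[[i]]), length(sets[[j]])),
                    union = length(union(sets[[i]], sets[[j]])))
      fractions[i, j] <- fractions[j, i] <-
        if (den == 0) 0 else length(sh) / den
      shared_keys[[paste(ids[i], ids[j], sep = "|")]] <- sh
    }
  }
  structure(list(counts = counts, fractions = fractions,
                 shared_keys = shared_keys, samples = tumors),
            class = "shared_variant_matrix")
}

#' @export
print.shared_variant_matrix <- function(x, ...) {
  cat("shared_variant_matrix:", nrow(x$counts), "tumors, patient",
      x$samples$patient_id[1], "\n")
  print(x$counts)
  invisible(x)
}

#' Classify primary-tumor pairs as independent or clonally related
#'
#' A pair is independent iff its shared fraction is below
#' `independence_max_shared_fraction` and its shared count below
#' `origin_min_shared`; otherwise clonally related.
#'
#' @param matrix A [shared_variant_matrix()].
#' @param config A [clonality_config()].
#' @return data.frame with one row per unordered primary pair:
#'   `tumor_a`, `tumor_b`, `shared_count`, `shared_fraction`, `relation`.
#' @export
classify_primary_pairs <- function(matrix, config = clonality_config()) {
  prim <- matrix$samples$sample_id[matrix$samples$sample_type == "primary"]
  out <- list()
  for (i in seq_along(prim)) for (j in seq_along(prim)) {
    if (j <= i) next
    a <- prim[i]; b <- prim[j]
    cnt <- matrix$counts[a, b]
    frac <- matrix$fractions[a, b]
    out[[length(out) + 1]] <- data.frame(
      tumor_a = a, tumor_b = b, shared_count = cnt, shared_fraction = frac,
      relation = if (frac < config$independence_max_shared_fraction &&
                     cnt < config$origin_min_shared) "independent"
                 else "clonally_related",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Assign a metastasis its primary tumor of origin
#'
#' The origin is the primary sharing the most variants with the
#' metastasis, provided that count reaches `origin_min_shared` and
#' dominates the runner-up by `origin_dominance_ratio`. Zero sharing with
#' every primary is reported as `unassigned_no_sharing` (interpretable as
#' an unsequenced-primary origin); ties or sub-threshold sharing as
#' `unassigned_ambiguous`.
#'
#' @param matrix A [shared_variant_matrix()] including the metastasis.
#' @param metastasis_id Metastasis sample id.
#' @param config A [clonality_config()].
#' @return One-row data.frame: `metastasis_id`, `origin_primary_id`,
#'   `shared_with_origin`, `runner_up`, `evidence`.
#' @export
assign_metastasis_origin <- function(matrix, metastasis_id,
                                     config = clonality_config()) {
  prim <- matrix$samples$sample_id[matrix$samples$sample_type == "primary"]
  if (length(prim) == 0) stop("no primary tumors in matrix")
  stopifnot(metastasis_id %in% rownames(matrix$counts))
  shared <- matrix$counts[metastasis_id, prim]
  best <- max(shared)
  runner <- if (length(shared) > 1) max(shared[-which.max(shared)]) else 0
  if (best == 0) {
    origin <- NA_character_; evidence <- "unassigned_no_sharing"
  } else if (best >= config$origin_min_shared &&
             best >= config$origin_dominance_ratio * runner &&
             sum(shared == best) == 1) {
    origin <- prim[which.max(shared)]; evidence <- "assigned"
  } else {
    origin <- NA_character_; evidence <- "unassigned_ambiguous"
  }
  data.frame(metastasis_id = metastasis_id, origin_primary_id = origin,
             shared_with_origin = best, runner_up = runner,
             evidence = evidence, stringsAsFactors = FALSE)
}

#' Classify a patient's dissemination pattern
#'
#' With at least two origin-assigned metastases, the pattern is `clonal`
#' when all assigned metastases trace to a single primary and
#' `independent` when they trace to two or more; otherwise
#' `mixed_unassigned` (single or unassigned metastases leave the pattern
#' undefined).
#'
#' @param origin_calls data.frame of [assign_metastasis_origin()] rows for
#'   one patient.
#' @return `"clonal"`, `"independent"` or `"mixed_unassigned"`.
#' @export
classify_dissemination <- function(origin_calls) {
  assigned <- origin_calls[origin_calls$evidence == "assigned", , drop = FALSE]
  if (nrow(assigned) < 2) return("mixed_unassigned")
  origins <- unique(assigned$origin_primary_id)
  if (length(origins) == 1) "clonal" else "independent"
}

#' Check shared variants for subclonal presence in other tumors
#'
#' For each shared variant key and each tumor of the patient, reports the
#' ALT-supporting read count from the evidence table and flags the variant
#' as supported when it reaches `subclonal_check_min_reads`, even where
#' the variant was not called. This is an audit table; with
#' `promote = TRUE` supported variants are added to the tumors' call sets
#' and the matrix recomputed (shared counts can only grow).
#'
#' @param matrix A [shared_variant_matrix()].
#' @param evidence data.frame `(sample_id, chrom, pos, ref, alt,
#'   ref_count, alt_count)` of allelic support at variant positions.
#' @param variants The patient's variant data.frame (used when promoting).
#' @param config A [clonality_config()].
#' @param promote Recompute the matrix with supported variants promoted?
#' @return list with `audit` (per variant x tumor: `key`, `sample_id`,
#'   `alt_reads`, `status` in supported/not_supported/no_data) and, when
#'   promoting, `matrix` (the recomputed [shared_variant_matrix()]).
#' @export
check_subclonal_presence <- function(matrix, evidence, variants = NULL,
                                     config = clonality_config(),
                                     promote = FALSE) {
  keys <- unique(unlist(matrix$shared_keys, use.names = FALSE))
  ids <- matrix$samples$sample_id
  if (length(keys) == 0) {
    audit <- data.frame(key = character(), sample_id = character(),
                        alt_reads = integer(), status = character(),
                        stringsAsFactors = FALSE)
    return(list(audit = audit,
                matrix = if (promote) matrix else NULL))
  }
  ev_key <- paste(evidence$sample_id, variant_key(evidence))
  grid <- expand.grid(key = keys, sample_id = ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  hit <- match(paste(grid$sample_id, grid$key), ev_key)
  grid$alt_reads <- evidence$alt_count[hit]
  grid$status <- ifelse(is.na(hit), "no_data",
                        ifelse(grid$alt_reads >= config$subclonal_check_min_reads,
                               "supported", "not_supported"))
  out <- list(audit = grid)
  if (promote) {
    stopifnot(!is.null(variants))
    promoted <- grid[grid$status == "supported", , drop = FALSE]
    add <- list()
    for (i in seq_len(nrow(promoted))) {
      sid <- promoted$sample_id[i]
      already <- promoted$key[i] %in%
        variant_key(variants[variants$sample_id == sid, , drop = FALSE])
      if (already) next
      parts <- strsplit(promoted$key[i], ":", fixed = TRUE)[[1]]
      row <- variants[variant_key(variants) == promoted$key[i], , drop = FALSE][1, ]
      row$sample_id <- sid
      add[[length(add) + 1]] <- row
    }
    newv <- rbind(variants, do.call(rbind, add))
    out$matrix <- shared_variant_matrix(newv, matrix$samples, config)
  }
  out
}
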