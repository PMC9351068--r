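#' Column conventions
#'
#' All tabular objects in the package are plain data.frames:
#'
#' * small variants: `sample_id`, `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `total_depth`, `population_af` (NA = missing), `variant_class`
#'   (`"SNV"`/`"indel"`), `region` (`"coding"`/`"noncoding"`/NA), `gene`,
#'   `effect` (`"missense"`, `"silent"`, `"nonsense"`, `"frameshift"`,
#'   `"splice"`, `"other"`, or NA)
#' * CNA segments: `sample_id`, `chrom`, `start`, `end` (0-based half-open
#'   in memory; 1-based inclusive on disk, SEG convention), `median_logr`,
#'   `direction` (`"loss"`/`"gain"`/`"cn_loh"`)
#' * SVs: `sample_id`, `chrom1`, `pos1`, `chrom2`, `pos2`, `sv_type`
#' * allelic counts: `sample_id`, `chrom`, `pos` (1-based), `ref_count`,
#'   `alt_count`
#' * sample metadata: `sample_id`, `patient_id`, `sample_type`
#'   (`"primary"`/`"metastasis"`/`"normal"`), `purity`
#'
#' @name clonemap-columns
#' @keywords internal
NULL

empty_variants <- function() {
  data.frame(sample_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), total_depth = integer(),
             population_af = numeric(), variant_class = character(),
             region = character(), gene = character(), effect = character(),
             stringsAsFactors = FALSE)
}

empty_segments <- function() {
  data.frame(sample_id = character(), chrom = character(), start = numeric(),
             end = numeric(), median_logr = numeric(), direction = character(),
             stringsAsFactors = FALSE)
}

empty_svs <- function() {
  data.frame(sample_id = character(), chrom1 = character(), pos1 = numeric(),
             chrom2 = character(), pos2 = numeric(), sv_type = character(),
             stringsAsFactors = FALSE)
}

empty_counts <- function() {
  data.frame(sample_id = character(), chrom = character(), pos = integer(),
             ref_count = integer(), alt_count = integer(),
             stringsAsFactors = FALSE)
}

#' Variant identity key
#'
#' Somatic variants are matched on the full key `(chrom, pos, ref, alt)`,
#' so two different substitutions at the same position never count as the
#' same variant.
#'
#' @param df data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @return Character vector of keys.
#' @export
variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' INFO-field names used in variant VCFs
#'
#' The population-allele-frequency and annotation INFO keys are
#' configurable because upstream annotators differ (and the choice of
#' gnomAD field — global vs population-max AF — is a pipeline decision,
#' not hard-coded here).
#'
#' @param depth,population_af,gene,effect,region INFO key names.
#' @return Named list of key names.
#' @export
vcf_info_keys <- function(depth = "DP", population_af = "PAF",
                          gene = "GENE", effect = "EFFECT", region = "REGION") {
  list(depth = depth, population_af = population_af,
       gene = gene, effect = effect, region = region)
}

#' Read somatic small variants from a VCF
#'
#' One row per ALT allele: multi-allelic records are decomposed into rows
#' sharing `(chrom, pos, ref)`. Missing annotations become `NA`, never a
#' default value.
#'
#' @param path VCF 4.x file.
#' @param sample_id Sample label to attach to every record.
#' @param genome Optional [genome_config()]; if given, records on unknown
#'   contigs are an error.
#' @param info_keys [vcf_info_keys()].
#' @return A small-variant data.frame (see [clonemap-columns]).
#' @export
read_small_variants <- function(path, sample_id, genome = NULL,
                                info_keys = vcf_info_keys()) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0) return(empty_variants())
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (any(is.na(pos))) {
    stop("malformed VCF record (non-numeric POS) at data line ",
         which(is.na(pos))[1], " in ", path)
  }
  getinfo <- function(key, as = "character") {
    x <- vcfR::extract.info(v, element = key, as.numeric = (as == "numeric"))
    if (is.null(x)) x <- rep(NA, nrow(fix))
    x
  }
  dp <- suppressWarnings(as.integer(getinfo(info_keys$depth)))
  paf <- suppressWarnings(as.numeric(getinfo(info_keys$population_af)))
  gene <- getinfo(info_keys$gene)
  effect <- getinfo(info_keys$effect)
  region <- getinfo(info_keys$region)

  alt_list <- strsplit(as.character(fix[, "ALT"]), ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  out <- data.frame(
    sample_id = sample_id,
    chrom = as.character(fix[idx, "CHROM"]),
    pos = pos[idx],
    ref = as.character(fix[idx, "REF"]),
    alt = unlist(alt_list),
    total_depth = dp[idx],
    population_af = paf[idx],
    stringsAsFactors = FALSE
  )
  out$variant_class <- ifelse(nchar(out$ref) == 1 & nchar(out$alt) == 1,
                              "SNV", "indel")
  out$region <- as.character(region[idx])
  out$gene <- as.character(gene[idx])
  out$effect <- as.character(effect[idx])
  if (!is.null(genome)) {
    unknown <- setdiff(unique(out$chrom), genome$chromosomes$name)
    if (length(unknown) > 0) {
      stop("VCF contig(s) absent from genome config: ",
           paste(unknown, collapse = ", "))
    }
    len <- chrom_length(genome, out$chrom)
    if (any(out$pos < 1 | out$pos > len)) {
      stop("VCF position outside chromosome bounds in ", path)
    }
  }
  if (any(out$ref == out$alt)) stop("VCF record with REF == ALT in ", path)
  if (anyDuplicated(variant_key(out))) {
    stop("duplicate (chrom,pos,ref,alt) records in ", path)
  }
  rownames(out) <- NULL
  out
}

#' Write somatic small variants to a VCF
#'
#' @param variants Small-variant data.frame for one sample.
#' @param path Output path.
#' @param info_keys [vcf_info_keys()].
#' @return `path`, invisibly.
#' @export
write_small_variants <- function(variants, path, info_keys = vcf_info_keys()) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf('##INFO=<ID=%s,Number=1,Type=Integer,Description="Total read depth">',
            info_keys$depth),
    sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="Population allele frequency">',
            info_keys$population_af),
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="Gene symbol">',
            info_keys$gene),
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="Functional effect">',
            info_keys$effect),
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="coding or noncoding">',
            info_keys$region),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t")
  )
  fmt_info <- function(i) {
    parts <- c(
      sprintf("%s=%d", info_keys$depth, as.integer(variants$total_depth[i])),
      if (!is.na(variants$population_af[i]))
        sprintf("%s=%.6g", info_keys$population_af, variants$population_af[i]),
      if (!is.na(variants$gene[i]))
        sprintf("%s=%s", info_keys$gene, variants$gene[i]),
      if (!is.na(variants$effect[i]))
        sprintf("%s=%s", info_keys$effect, variants$effect[i]),
      if (!is.na(variants$region[i]))
        sprintf("%s=%s", info_keys$region, variants$region[i])
    )
    paste(parts, collapse = ";")
  }
  body <- if (nrow(variants) == 0) character(0) else {
    vapply(seq_len(nrow(variants)), function(i) {
      paste(variants$chrom[i], variants$pos[i], ".", variants$ref[i],
            variants$alt[i], ".", ".", fmt_info(i), sep = "\t")
    }, character(1))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read allelic read counts (GATK CollectAllelicCounts dialect)
#'
#' Header lines beginning `@` are skipped; the column header row names
#' `CONTIG`, `POSITION`, `REF_COUNT`, `ALT_COUNT`. Rows are returned sorted
#' by `(chrom, pos)`.
#'
#' @param path TSV file.
#' @param sample_id Sample label.
#' @return Allelic-count data.frame (see [clonemap-columns]).
#' @export
read_allelic_counts <- function(path, sample_id) {
  if (!file.exists(path)) stop("allelic-count file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) <= 1) return(empty_counts())
  tab <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  req <- c("CONTIG", "POSITION", "REF_COUNT", "ALT_COUNT")
  if (!all(req %in% names(tab))) {
    stop("allelic-count file missing required columns in ", path)
  }
  if (any(tab$REF_COUNT < 0 | tab$ALT_COUNT < 0)) {
    stop("negative read count in ", path)
  }
  out <- data.frame(sample_id = sample_id,
                    chrom = as.character(tab$CONTIG),
                    pos = as.integer(tab$POSITION),
                    ref_count = as.integer(tab$REF_COUNT),
                    alt_count = as.integer(tab$ALT_COUNT),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(paste(out$chrom, out$pos))) {
    stop("duplicate (chrom, pos) rows in ", path)
  }
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write allelic read counts
#'
#' @param counts Allelic-count data.frame for one sample.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allelic_counts <- function(counts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6", "@CO\tallelic counts"), con)
  df <- data.frame(CONTIG = counts$chrom, POSITION = counts$pos,
                   REF_COUNT = counts$ref_count, ALT_COUNT = counts$alt_count)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write copy-number segments (SEG-like TSV)
#'
#' On disk coordinates are 1-based inclusive (SEG convention); in memory
#' they are 0-based half-open, so `read_seg(write_seg(x))` is the identity
#' and lengths agree between both conventions.
#'
#' @param path TSV with columns `SAMPLE`, `CHROM`, `START`, `END`,
#'   `MEDIAN_LOGR`, `DIRECTION`.
#' @return Segment data.frame (see [clonemap-columns]).
#' @export
read_seg <- function(path) {
  if (!file.exists(path)) stop("SEG file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0) return(empty_segments())
  if (any(tab$END <= tab$START)) {
    stop("SEG segment with END <= START in ", path)
  }
  out <- data.frame(sample_id = as.character(tab$SAMPLE),
                    chrom = as.character(tab$CHROM),
                    start = as.numeric(tab$START) - 1,
                    end = as.numeric(tab$END),
                    median_logr = as.numeric(tab$MEDIAN_LOGR),
                    direction = as.character(tab$DIRECTION),
                    stringsAsFactors = FALSE)
  warn_overlaps(out)
  out
}

warn_overlaps <- function(segments) {
  by_sc <- split(segments, paste(segments$sample_id, segments$chrom))
  for (grp in by_sc) {
    if (nrow(grp) < 2) next
    grp <- grp[order(grp$start), ]
    if (any(grp$start[-1] < grp$end[-nrow(grp)])) {
      warning("overlapping segments within sample ", grp$sample_id[1],
              " on ", grp$chrom[1], " (kept; callers may emit subclonal overlaps)")
      break
    }
  }
  invisible(NULL)
}

#' @rdname read_seg
#' @param segments Segment data.frame.
#' @export
write_seg <- function(segments, path) {
  stopifnot(all(segments$end > segments$start))
  df <- data.frame(SAMPLE = segments$sample_id, CHROM = segments$chrom,
                   START = format(segments$start + 1, scientific = FALSE, trim = TRUE),
                   END = format(segments$end, scientific = FALSE, trim = TRUE),
                   MEDIAN_LOGR = segments$median_logr,
                   DIRECTION = segments$direction)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write structural-variant breakpoint tables
#'
#' @param path TSV with columns `SAMPLE`, `CHROM1`, `POS1`, `CHROM2`,
#'   `POS2`, `TYPE` (positions 1-based).
#' @return SV data.frame (see [clonemap-columns]).
#' @export
read_svs <- function(path) {
  if (!file.exists(path)) stop("SV file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0) return(empty_svs())
  data.frame(sample_id = as.character(tab$SAMPLE),
             chrom1 = as.character(tab$CHROM1), pos1 = as.numeric(tab$POS1),
             chrom2 = as.character(tab$CHROM2), pos2 = as.numeric(tab$POS2),
             sv_type = as.character(tab$TYPE), stringsAsFactors = FALSE)
}

#' @rdname read_svs
#' @param svs SV data.frame.
#' @export
write_svs <- function(svs, path) {
  df <- data.frame(SAMPLE = svs$sample_id, CHROM1 = svs$chrom1,
                   POS1 = format(svs$pos1, scientific = FALSE, trim = TRUE),
                   CHROM2 = svs$chrom2,
                   POS2 = format(svs$pos2, scientific = FALSE, trim = TRUE),
                   TYPE = svs$sv_type)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata
#'
#' @param path TSV with columns `SAMPLE`, `PATIENT`, `TYPE`, `PURITY`.
#' @return Sample-metadata data.frame (see [clonemap-columns]).
#' @export
read_sample_meta <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  out <- data.frame(sample_id = as.character(tab$SAMPLE),
                    patient_id = as.character(tab$PATIENT),
                    sample_type = as.character(tab$TYPE),
                    purity = as.numeric(tab$PURITY),
                    stringsAsFactors = FALSE)
  validate_sample_meta(out)
  out
}

#' @rdname read_sample_meta
#' @param meta Sample-metadata data.frame.
#' @export
write_sample_meta <- function(meta, path) {
  df <- data.frame(SAMPLE = meta$sample_id, PATIENT = meta$patient_id,
                   TYPE = meta$sample_type, PURITY = meta$purity)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_sample_meta <- function(meta) {
  stopifnot(all(meta$sample_type %in% c("primary", "metastasis", "normal")))
  tumors <- meta[meta$sample_type != "normal", , drop = FALSE]
  normals <- meta[meta$sample_type == "normal", , drop = FALSE]
  n_norm <- table(factor(normals$patient_id, levels = unique(tumors$patient_id)))
  if (any(n_norm != 1)) {
    stop("every tumor sample's patient must have exactly one normal sample; ",
         "offending patient(s): ",
         paste(names(n_norm)[n_norm != 1], collapse = ", "))
  }
  invisible(meta)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (one set per line: id, description, genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  fgsea::gmtPathways(path)
}
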