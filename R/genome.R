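#' Genome configuration
#'
#' A `genome_config` holds the coordinate frame every other object in the
#' package uses: ordered chromosome names with lengths, and a centromere
#' interval per chromosome. Chromosome arms are derived from the centromere:
#' the p arm is `[0, centromere_start)` and the q arm is
#' `[centromere_end, length)`, both 0-based half-open.
#'
#' @param chromosomes data.frame with columns `name`, `length`,
#'   `centromere_start`, `centromere_end`. Lengths and centromere bounds are
#'   in bp; the centromere interval must lie strictly inside the chromosome.
#'
#' @return An object of class `genome_config`.
#' @export
genome_config <- function(chromosomes) {
  stopifnot(is.data.frame(chromosomes))
  req <- c("name", "length", "centromere_start", "centromere_end")
  missing_cols <- setdiff(req, names(chromosomes))
  if (length(missing_cols) > 0) {
    stop("genome_config: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  chromosomes$name <- as.character(chromosomes$name)
  if (anyDuplicated(chromosomes$name)) {
    stop("genome_config: duplicate chromosome names: ",
         paste(unique(chromosomes$name[duplicated(chromosomes$name)]), collapse = ", "))
  }
  if (any(is.na(chromosomes$length)) || any(chromosomes$length <= 0)) {
    stop("genome_config: chromosome lengths must be positive")
  }
  bad <- is.na(chromosomes$centromere_start) | is.na(chromosomes$centromere_end)
  if (any(bad)) {
    stop("genome_config: missing centromere for chromosome(s): ",
         paste(chromosomes$name[bad], collapse = ", "))
  }
  inside <- chromosomes$centromere_start > 0 &
    chromosomes$centromere_end > chromosomes$centromere_start &
    chromosomes$centromere_end < chromosomes$length
  if (!all(inside)) {
    stop("genome_config: centromere interval must lie strictly inside chromosome: ",
         paste(chromosomes$name[!inside], collapse = ", "))
  }
  structure(list(chromosomes = chromosomes), class = "genome_config")
}

#' Read a genome configuration from YAML or JSON
#'
#' The schema is a top-level `chromosomes` list, each entry with fields
#' `name`, `length`, `centromere_start`, `centromere_end`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [genome_config()].
#' @export
load_genome_config <- function(path) {
  if (!file.exists(path)) stop("genome config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$chromosomes)) stop("genome config: no 'chromosomes' entry in ", path)
  rows <- lapply(raw$chromosomes, function(ch) {
    if (is.null(ch$name) || is.null(ch$length)) {
      stop("genome config: every chromosome needs 'name' and 'length'")
    }
    if (is.null(ch$centromere_start) || is.null(ch$centromere_end)) {
      stop("genome config: missing centromere for chromosome ", ch$name)
    }
    data.frame(name = as.character(ch$name),
               length = as.numeric(ch$length),
               centromere_start = as.numeric(ch$centromere_start),
               centromere_end = as.numeric(ch$centromere_end),
               stringsAsFactors = FALSE)
  })
  genome_config(do.call(rbind, rows))
}

#' Write a genome configuration to YAML
#'
#' @param genome A [genome_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_config <- function(genome, path) {
  stopifnot(inherits(genome, "genome_config"))
  chs <- lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    r <- genome$chromosomes[i, ]
    list(name = r$name, length = r$length,
         centromere_start = r$centromere_start,
         centromere_end = r$centromere_end)
  })
  yaml::write_yaml(list(chromosomes = chs), path)
  invisible(path)
}

#' @export
print.genome_config <- function(x, ...) {
  cat("genome_config:", nrow(x$chromosomes), "chromosome(s),",
      format(sum(x$chromosomes$length), big.mark = ","), "bp total\n")
  print(x$chromosomes, row.names = FALSE)
  invisible(x)
}

chrom_row <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$name)
  if (any(is.na(i))) {
    stop("unknown chromosome(s): ", paste(unique(chrom[is.na(i)]), collapse = ", "))
  }
  genome$chromosomes[i, , drop = FALSE]
}

chrom_length <- function(genome, chrom) chrom_row(genome, chrom)$length

#' Chromosome-arm boundaries
#'
#' @param genome A [genome_config()].
#' @param chrom Chromosome name.
#' @return data.frame with columns `arm` (`"p"`, `"q"`), `start`, `end`
#'   (0-based half-open). Arms of zero length (acrocentric-style configs)
#'   are dropped.
#' @export
arm_bounds <- function(genome, chrom) {
  r <- chrom_row(genome, chrom)
  out <- data.frame(arm = c("p", "q"),
                    start = c(0, r$centromere_end),
                    end = c(r$centromere_start, r$length),
                    stringsAsFactors = FALSE)
  out[out$end > out$start, , drop = FALSE]
}

#' Built-in toy genome
#'
#' Three 10-Mb chromosomes with centromeres at 40--45% of their length.
#' This desk-scale frame is the default coordinate system of the
#' synthetic-cohort simulator; every analysis function takes an arbitrary
#' [genome_config()] and scales to real assemblies unchanged.
#'
#' @return A [genome_config()].
#' @export
toy_genome <- function() {
  genome_config(data.frame(
    name = c("chr1", "chr2", "chr3"),
    length = rep(10e6, 3),
    centromere_start = rep(4.0e6, 3),
    centromere_end = rep(4.5e6, 3),
    stringsAsFactors = FALSE
  ))
}

#' Total genome size in megabases
#'
#' @param genome A [genome_config()].
#' @return Numeric scalar, sum of chromosome lengths / 1e6.
#' @export
genome_mb <- function(genome) {
  stopifnot(inherits(genome, "genome_config"))
  sum(genome$chromosomes$length) / 1e6
}
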