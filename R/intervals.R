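#' Genomic intervals and feature tables
#'
#' All coordinates inside the package are 0-based, half-open `[start, end)`.
#' External formats (GenBank, the regulatory TSV dialect, SNP tables) are
#' 1-based inclusive and are converted exactly once, at the I/O boundary.
#'
#' A *feature table* is a tibble with one row per annotated feature and
#' columns:
#' \describe{
#'   \item{id}{identifier (locus tag, site id, or generated)}
#'   \item{category}{feature class, e.g. `"cds"`, `"transcription_unit"`,
#'     `"promoter"`, `"tfbs"`, `"regulon"`}
#'   \item{subtype}{within-class label (codon string, amino-acid code,
#'     COG letter, regulator name); `NA` where not applicable}
#'   \item{strand}{`"+"`, `"-"` or `"."`}
#'   \item{intervals}{list-column of data frames with integer columns
#'     `start`, `end` (0-based half-open); multi-interval features hold the
#'     pieces in coding order}
#'   \item{links}{list-column of character vectors of linked locus tags /
#'     feature ids}
#'   \item{attributes}{list-column of named lists (e.g. `translation`,
#'     `tss`, `wraps`)}
#' }
#'
#' @param start,end 0-based half-open bounds.
#' @name feature-tables
NULL

#' Build a one-interval list-column entry
#' @noRd
iv <- function(start, end) {
  data.frame(start = as.integer(start), end = as.integer(end))
}

#' Construct a feature table row-wise
#'
#' Convenience constructor used by the parsers and the synthetic generator.
#' Vector arguments are recycled per tibble rules; `intervals`, `links` and
#' `attributes` must be lists (or NULL for empty defaults).
#'
#' @param id,category,subtype,strand character vectors.
#' @param intervals list of data frames with `start`,`end`.
#' @param links list of character vectors.
#' @param attributes list of named lists.
#' @return a feature table tibble.
#' @export
feature_tbl <- function(id = character(), category = character(),
                        subtype = NA_character_, strand = ".",
                        intervals = NULL, links = NULL, attributes = NULL) {
  n <- length(id)
  if (is.null(intervals)) intervals <- rep(list(iv(integer(), integer())), n)
  if (is.null(links)) links <- rep(list(character()), n)
  if (is.null(attributes)) attributes <- rep(list(list()), n)
  tibble(
    id = as.character(id),
    category = rep_len(as.character(category), n),
    subtype = rep_len(as.character(subtype), n),
    strand = rep_len(as.character(strand), n),
    intervals = intervals,
    links = links,
    attributes = attributes
  )
}

#' Validate a feature table against the coordinate invariants
#'
#' Checks category names, strand codes, interval sanity
#' (`0 <= start < end <= genome_length` for non-wrapping intervals) and that
#' CDS translations are consistent with their summed interval length.
#'
#' @param features feature table.
#' @param genome_length genome length in bp, or `NA` to skip bound checks.
#' @param circular whether origin-wrapping intervals (marked by the
#'   `wraps` attribute) are permitted.
#' @return `features`, invisibly; aborts with a message on violation.
#' @export
validate_features <- function(features, genome_length = NA, circular = FALSE) {
  stopifnot(is.data.frame(features))
  bad_cat <- setdiff(unique(features$category), ALL_CATEGORIES)
  if (length(bad_cat) > 0) {
    abort(paste0("unknown feature category: ", paste(bad_cat, collapse = ", ")))
  }
  if (!all(features$strand %in% c("+", "-", "."))) {
    abort("strand must be one of '+', '-', '.'")
  }
  for (k in seq_len(nrow(features))) {
    ivs <- features$intervals[[k]]
    wraps <- isTRUE(features$attributes[[k]]$wraps)
    if (nrow(ivs) == 0 &&
        !features$category[k] %in% SINGLE_ROW_CATEGORIES &&
        !features$category[k] %in% c("cog", "structural_track")) {
      abort(paste0("feature ", features$id[k], " has no intervals"))
    }
    if (any(ivs$start < 0)) abort(paste0("negative coordinate in ", features$id[k]))
    if (wraps) {
      if (!circular) abort(paste0("wrapping interval on linear genome: ", features$id[k]))
    } else if (any(ivs$start >= ivs$end)) {
      abort(paste0("empty or inverted interval in ", features$id[k]))
    }
    if (!is.na(genome_length) && !wraps && any(ivs$end > genome_length)) {
      abort(paste0("interval beyond genome end in ", features$id[k]))
    }
    tr <- features$attributes[[k]]$translation
    if (features$category[k] == "cds" && !is.null(tr)) {
      len <- feature_length(ivs, wraps = wraps, genome_length = genome_length)
      # translation excludes the stop codon under the usual convention
      if (len %% 3L != 0L || nchar(tr) != len %/% 3L - 1L) {
        abort(paste0("CDS ", features$id[k], ": translation length ", nchar(tr),
                     " inconsistent with interval length ", len))
      }
    }
  }
  invisible(features)
}

#' Total length of a feature's intervals
#' @noRd
feature_length <- function(ivs, wraps = FALSE, genome_length = NA) {
  if (wraps) {
    # single wrapping interval stored as (start, end) with end < start meaning
    # it runs off the origin; effective length (L - start) + end
    sum((genome_length - ivs$start) + ivs$end)
  } else {
    sum(ivs$end - ivs$start)
  }
}

#' 0-based genomic positions covered by a feature's intervals
#' @noRd
feature_positions <- function(ivs, wraps = FALSE, genome_length = NA) {
  if (nrow(ivs) == 0) return(integer())
  if (wraps) {
    unlist(lapply(seq_len(nrow(ivs)), function(k) {
      c(seq.int(ivs$start[k], genome_length - 1L),
        if (ivs$end[k] > 0) seq.int(0L, ivs$end[k] - 1L) else integer())
    }))
  } else {
    unlist(Map(function(s, e) seq.int(s, e - 1L), ivs$start, ivs$end))
  }
}

#' Leftmost / rightmost genomic coordinate of a feature (non-wrapping)
#' @noRd
span_of <- function(ivs) c(min(ivs$start), max(ivs$end))

#' Reverse-complement of a nucleotide string
#' @noRd
revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                     collapse = ""), ""))
}

#' IRanges view of a set of 0-based half-open intervals (1-based closed inside)
#' @noRd
as_iranges0 <- function(ivs) {
  IRanges::IRanges(start = ivs$start + 1L, end = ivs$end)
}

#' Convert an IRanges back to a 0-based half-open tibble
#' @noRd
from_iranges0 <- function(ir) {
  tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}
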