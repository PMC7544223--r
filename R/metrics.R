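#' Per-position bit counts
#'
#' Column-wise sum of the bitome: how many feature rows are set at each
#' genomic position.
#'
#' @param bitome a `bitome`.
#' @return numeric vector of length `genome_length`.
#' @export
column_bit_counts <- function(bitome) {
  Matrix::colSums(bitome$matrix)
}

#' Sequence coverage of a set of feature rows
#'
#' Fraction of genomic positions carrying at least one bit among the
#' selected rows (union over rows, so overlapping rows are not double
#' counted).
#'
#' @param bitome a `bitome`.
#' @param ... row-key filter expressions (see [bitome_select_rows()]); omit
#'   to use all rows.
#' @return scalar fraction in \[0, 1\].
#' @examples
#' \dontrun{sequence_coverage(b, category == "cds")}
#' @export
sequence_coverage <- function(bitome, ...) {
  sub <- if (...length() > 0) bitome_select_rows(bitome, ...) else bitome
  mean(Matrix::colSums(sub$matrix) > 0)
}

#' Bit density of a genomic range
#'
#' Total bits in the sub-matrix over `[start, end)` divided by the range
#' length, in bits per bp. Bits from all rows (both strands) count.
#'
#' @param bitome a `bitome`.
#' @param start,end 0-based half-open range.
#' @return scalar bits/bp.
#' @export
bit_density <- function(bitome, start, end) {
  sub <- bitome_extract(bitome, start, end)
  sum(bitome::column_bit_counts(sub)) / (end - start)
}

#' Moving-window bit-density profile
#'
#' Bit density in sliding windows across the genome (wrapping past the
#' origin when the bitome is circular). Windows are anchored by their
#' start; the reported center is `start + window/2` modulo the genome
#' length.
#'
#' @param bitome a `bitome`.
#' @param window window size in bp (default 100 kb).
#' @param step step between window starts in bp (default 1 kb).
#' @return tibble of class `bitome_density_profile` with columns `start`,
#'   `center`, `density`; attributes `window`, `step`, `mean`, `sd` (used
#'   for mean +/- 2 sd banding in plots).
#' @export
moving_density <- function(bitome, window = 100000L, step = 1000L) {
  L <- ncol(bitome$matrix)
  if (window <= 0) abort("window must be positive")
  if (window > L) abort("window exceeds genome length")
  if (step <= 0) abort("step must be positive")
  cc <- column_bit_counts(bitome)
  starts <- if (bitome$circular) {
    seq.int(0L, L - 1L, by = step)
  } else {
    seq.int(0L, L - window, by = step)
  }
  cum <- cumsum(c(0, cc, if (bitome$circular) cc[seq_len(min(window, L))] else NULL))
  vals <- (cum[starts + window + 1L] - cum[starts + 1L]) / window
  out <- tibble(start = starts, center = (starts + window %/% 2L) %% L,
                density = vals)
  class(out) <- c("bitome_density_profile", class(out))
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "mean") <- mean(vals)
  attr(out, "sd") <- stats::sd(vals)
  out
}

#' Bit density per feature, with the median
#'
#' Applies [bit_density()] to the genomic span of each feature, as used for
#' feature-class density histograms.
#'
#' @param bitome a `bitome`.
#' @param features feature table.
#' @return tibble `id`, `category`, `length`, `density`; attribute
#'   `median` holds the median density.
#' @export
feature_density_distribution <- function(bitome, features) {
  dens <- purrr::map_dbl(features$intervals, function(ivs) {
    sp <- span_of(ivs)
    bit_density(bitome, sp[1], sp[2])
  })
  out <- tibble(id = features$id, category = features$category,
                length = purrr::map_int(features$intervals, ~ sum(.x$end - .x$start)),
                density = dens)
  attr(out, "median") <- stats::median(dens)
  out
}

#' 5' and 3' UTR lengths of transcription units
#'
#' For each transcription unit linked to at least one gene, the 5' UTR is
#' the strand-aware distance from the TU 5' end to the start of its first
#' gene, and the 3' UTR the distance from the end of its last gene to the
#' TU 3' end. Zero-length UTRs (gene abutting the TU edge) are recorded
#' but flagged, since length histograms conventionally show only existing
#' UTRs.
#'
#' @param tus feature table of transcription units (links = locus tags).
#' @param genes feature table of genes.
#' @param drop_zero exclude zero-length UTRs from [utr_summary()] views.
#' @return tibble `tu_id`, `side` (`"five_prime"`/`"three_prime"`),
#'   `length`, `zero`; TUs with no locatable gene are skipped with a
#'   warning.
#' @export
utr_lengths <- function(tus, genes, drop_zero = TRUE) {
  rows <- list()
  skipped <- 0L
  for (k in seq_len(nrow(tus))) {
    members <- match(tus$links[[k]], genes$id)
    members <- members[!is.na(members)]
    if (length(members) == 0) { skipped <- skipped + 1L; next }
    tu_sp <- span_of(tus$intervals[[k]])
    g_left <- min(purrr::map_int(genes$intervals[members], ~ min(.x$start)))
    g_right <- max(purrr::map_int(genes$intervals[members], ~ max(.x$end)))
    if (tus$strand[k] == "-") {
      five <- tu_sp[2] - g_right
      three <- g_left - tu_sp[1]
    } else {
      five <- g_left - tu_sp[1]
      three <- tu_sp[2] - g_right
    }
    rows[[length(rows) + 1L]] <- tibble(
      tu_id = tus$id[k], side = c("five_prime", "three_prime"),
      length = c(five, three))
  }
  if (skipped > 0) warn(paste0(skipped, " TU(s) with no locatable gene skipped"))
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(tu_id = character(), side = character(),
                  length = integer(), zero = logical())
  } else {
    out$zero <- out$length == 0L
  }
  attr(out, "drop_zero") <- drop_zero
  out
}

#' Outlier-excluded UTR length summary
#'
#' Summarises [utr_lengths()] output per side after excluding zero-length
#' UTRs (if requested at computation time) and, optionally, 1.5 x IQR
#' outliers beyond Q1/Q3 — the conventional boxplot whisker rule. The raw
#' lengths are untouched; this is a view.
#'
#' @param utrs tibble from [utr_lengths()].
#' @param iqr_exclude apply the 1.5 x IQR rule.
#' @return tibble per `side`: `n`, `n_outliers`, `median`, `q1`, `q3`.
#' @export
utr_summary <- function(utrs, iqr_exclude = TRUE) {
  if (isTRUE(attr(utrs, "drop_zero"))) utrs <- utrs[!utrs$zero, , drop = FALSE]
  utrs %>%
    dplyr::group_by(.data$side) %>%
    dplyr::group_modify(function(d, g) {
      x <- d$length
      q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
      keep <- if (iqr_exclude) {
        x >= q[1] - 1.5 * (q[2] - q[1]) & x <= q[2] + 1.5 * (q[2] - q[1])
      } else rep(TRUE, length(x))
      tibble(n = sum(keep), n_outliers = sum(!keep),
             median = stats::median(x[keep]),
             q1 = stats::quantile(x[keep], 0.25, names = FALSE),
             q3 = stats::quantile(x[keep], 0.75, names = FALSE))
    }) %>% dplyr::ungroup()
}

#' Promoter element geometry
#'
#' For promoters carrying a TSS and -10/-35 boxes, computes the distance
#' from each box center to the TSS (box center = floor of the interval
#' midpoint) and the spacer between the two boxes, measured between the
#' TSS-proximal end of the -35 box and the TSS-distal end of the -10 box
#' (i.e. the gap in bp between the element ends). Distances are reported
#' unsigned with an `upstream` flag; a box on the downstream side of the
#' TSS is kept but flagged.
#'
#' @param promoters feature table rows with category `"promoter"` whose
#'   `attributes` carry `tss` and `minus10`/`minus35` (as stored by
#'   [read_regulatory_tables()]).
#' @return tibble `promoter_id`, `minus10_distance`, `minus35_distance`,
#'   `spacer`, `minus10_upstream`, `minus35_upstream`; rows only for
#'   promoters with a TSS and both boxes (class `bitome_promoter_geometry`).
#' @export
promoter_geometry <- function(promoters) {
  rows <- purrr::map(seq_len(nrow(promoters)), function(k) {
    a <- promoters$attributes[[k]]
    if (is.null(a$tss) || is.null(a$minus10) || is.null(a$minus35)) return(NULL)
    strand <- promoters$strand[k]
    center <- function(box) (box[1] + box[2]) %/% 2L # floor midpoint of [start, end)
    d10 <- center(a$minus10) - a$tss
    d35 <- center(a$minus35) - a$tss
    # upstream means 5' of the TSS on the promoter's strand
    up <- function(d) if (strand == "-") d > 0 else d < 0
    spacer <- if (strand == "-") a$minus35[1] - a$minus10[2] else a$minus10[1] - a$minus35[2]
    tibble(promoter_id = promoters$id[k],
           minus10_distance = abs(d10), minus35_distance = abs(d35),
           spacer = spacer,
           minus10_upstream = up(d10), minus35_upstream = up(d35))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(promoter_id = character(), minus10_distance = integer(),
                  minus35_distance = integer(), spacer = integer(),
                  minus10_upstream = logical(), minus35_upstream = logical())
  }
  class(out) <- c("bitome_promoter_geometry", class(out))
  out
}

#' Inter-TU regions
#'
#' Maximal genomic intervals covered by no transcription unit on either
#' strand. The returned regions and the TU coverage union tile the genome
#' exactly.
#'
#' @param tus feature table of transcription units.
#' @param genome_length genome length in bp.
#' @return tibble `start`, `end` (0-based half-open).
#' @export
inter_tu_regions <- function(tus, genome_length) {
  if (nrow(tus) == 0) return(tibble(start = 0L, end = as.integer(genome_length)))
  ir <- IRanges::reduce(as_iranges0(dplyr::bind_rows(tus$intervals)))
  gaps <- IRanges::gaps(ir, start = 1L, end = genome_length)
  from_iranges0(gaps)
}

#' Sliding-window folding energies
#'
#' Applies a folding engine to every window of `window` bp across the
#' sequence. The default engine is a base-pair-maximization scorer
#' (Nussinov dynamic program over Watson-Crick plus G.U wobble pairs,
#' minimum hairpin loop 3) returning the negated maximal pair count, a
#' structure-propensity stand-in for a thermodynamic minimum free energy;
#' any callable `function(subsequence) -> scalar` can be plugged in.
#'
#' @param sequence nucleotide string.
#' @param window window size in bp (default 100).
#' @param step step between window starts (default = `window`, i.e.
#'   non-overlapping; set 1 for fully sliding).
#' @param engine folding callable; `NULL` selects the built-in scorer.
#' @param circular wrap windows past the origin.
#' @return tibble `start`, `end`, `energy`, one row per window.
#' @export
window_fold_energies <- function(sequence, window = 100L, step = window,
                                 engine = NULL, circular = FALSE) {
  L <- nchar(sequence)
  if (window > L) abort("window exceeds sequence length")
  if (is.null(engine)) engine <- function(s) nussinov_energy(s)
  starts <- if (circular) seq.int(0L, L - 1L, by = step) else seq.int(0L, L - window, by = step)
  seq2 <- if (circular) paste0(sequence, substr(sequence, 1L, window)) else sequence
  vals <- vapply(starts, function(s)
    engine(substr(seq2, s + 1L, s + window)), numeric(1))
  tibble(start = starts, end = starts + window, energy = vals)
}

#' Base-pair-maximization folding score
#'
#' Negated maximal number of nested base pairs (Watson-Crick + G.U wobble,
#' hairpin loops of at least `min_loop` unpaired bases) attainable by the
#' sequence, computed with a Nussinov-style dynamic program.
#'
#' @param sequence nucleotide string.
#' @param min_loop minimum hairpin loop length (default 3).
#' @return scalar score (0 for sequences that cannot pair).
#' @export
nussinov_energy <- function(sequence, min_loop = 3L) {
  -nussinov_pairs_cpp(toupper(sequence), as.integer(min_loop))
}

#' Tight-structure regions from window energies
#'
#' Selects windows whose energy lies at or below the `fraction` quantile of
#' all window energies (ties at the threshold included) and merges
#' overlapping or adjacent selected windows into maximal intervals. Also
#' reports the genome-wide mean energy.
#'
#' @param energies tibble from [window_fold_energies()].
#' @param fraction lower quantile defining "tight" (default 0.10).
#' @return tibble `start`, `end`; attributes `threshold`, `mean_energy`,
#'   `n_selected`.
#' @export
tight_structure_regions <- function(energies, fraction = 0.10) {
  if (nrow(energies) == 0) abort("empty energy vector")
  thr <- stats::quantile(energies$energy, fraction, type = 1, names = FALSE)
  sel <- energies[energies$energy <= thr, , drop = FALSE]
  merged <- from_iranges0(IRanges::reduce(as_iranges0(sel)))
  attr(merged, "threshold") <- thr
  attr(merged, "mean_energy") <- mean(energies$energy)
  attr(merged, "n_selected") <- nrow(sel)
  merged
}
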