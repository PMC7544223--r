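#' Assemble a bitome: the sparse binary feature-by-position matrix
#'
#' Builds the matrix `b_ij` with one row per distinct feature row key and
#' one column per genomic position; `b_ij = 1` means feature row `i` is
#' present at position `j`. Overlapping features sharing a row key OR their
#' bits (the matrix stays binary). Derived tracks are added automatically:
#' the eight nucleobase rows always; codon, amino-acid and protein tracks
#' whenever CDS features are present (disable via `derive`).
#'
#' Features without their own coordinates (regulons, sigmulons, i-modulons)
#' are painted over the intervals of their linked genes.
#'
#' @param sequence genome nucleotide string.
#' @param features feature table (see [feature_tbl()]); may be empty.
#' @param circular treat the genome as circular (origin-wrapping intervals
#'   allowed, windows wrap in downstream metrics).
#' @param include optional character vector of categories to keep
#'   (nucleobase rows are always kept).
#' @param derive derive codon/amino-acid/protein tracks from CDS records.
#' @param frame_anchor see [assign_row_keys()].
#' @param genome_id identifier recorded in headers and BED output.
#' @return an object of class `bitome`.
#' @examples
#' b <- build_bitome("ACGTACGTAC", feature_tbl(
#'   id = "g1", category = "cds", strand = "+",
#'   intervals = list(data.frame(start = 2L, end = 8L))), derive = FALSE)
#' glance(b)
#' @export
build_bitome <- function(sequence, features = feature_tbl(), circular = TRUE,
                         include = NULL, derive = TRUE,
                         frame_anchor = c("leftmost", "coding_start"),
                         genome_id = "genome") {
  frame_anchor <- match.arg(frame_anchor)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (!is.null(include)) {
    features <- features[features$category %in% include, , drop = FALSE]
  }
  validate_features(features, L, circular)

  gene_cats <- c("cds", "pseudogene", "rna_gene")
  genes <- features[features$category %in% gene_cats, , drop = FALSE]

  derived <- list(derive_sequence_tracks(sequence))
  if (derive) {
    cds <- features[features$category == "cds", , drop = FALSE]
    if (nrow(cds) > 0) {
      derived <- c(derived, list(derive_codon_aa_tracks(cds, sequence),
                                 derive_protein_tracks(cds)))
    }
  }
  all_feats <- dplyr::bind_rows(c(derived, list(features)))

  # coordinate-less gene-set features inherit their members' intervals
  setlike <- which(all_feats$category %in% c("regulon", "sigmulon", "imodulon") &
                     purrr::map_int(all_feats$intervals, nrow) == 0)
  for (k in setlike) {
    members <- match(all_feats$links[[k]], genes$id)
    members <- members[!is.na(members)]
    if (length(members) == 0) next
    merged <- from_iranges0(IRanges::reduce(
      as_iranges0(dplyr::bind_rows(genes$intervals[members]))))
    all_feats$intervals[[k]] <- as.data.frame(merged)
  }

  keys <- assign_row_keys(all_feats, frame_anchor)
  row_keys <- keys %>%
    dplyr::distinct(.data$category, .data$subtype, .data$strand_class,
                    .data$frame, .data$row_label) %>%
    dplyr::arrange(.data$category, .data$subtype, .data$strand_class, .data$frame) %>%
    dplyr::mutate(row = dplyr::row_number(), .before = 1)
  key_of_feature <- match(keys$row_label, row_keys$row_label)

  # expand every interval of every feature into (row, run) pairs, then into
  # set-bit coordinates with a fully vectorized rep/sequence expansion
  n_iv <- purrr::map_int(all_feats$intervals, nrow)
  f_idx <- rep.int(seq_len(nrow(all_feats)), n_iv)
  if (length(f_idx) > 0) {
    ivs <- dplyr::bind_rows(all_feats$intervals)
    run_row <- key_of_feature[f_idx]
    wraps_flag <- purrr::map_lgl(all_feats$attributes, ~ isTRUE(.x$wraps))[f_idx]
    starts <- ivs$start
    ends <- ivs$end
    # a wrapping interval [s, e) with e < s splits into [s, L) and [0, e)
    wrap_k <- which(wraps_flag & ends <= starts)
    if (length(wrap_k)) {
      run_row <- c(run_row, run_row[wrap_k])
      starts <- c(starts, rep(0L, length(wrap_k)))
      ends <- c(ends, ends[wrap_k])
      ends[wrap_k] <- L
    }
    lens <- ends - starts
    j <- rep.int(starts, lens) + sequence(lens) - 1L
    i <- rep.int(run_row, lens)
    if (any(j >= L)) abort("interval exceeds genome length")
    M <- Matrix::sparseMatrix(i = i, j = j + 1L,
                              dims = c(nrow(row_keys), L), x = 1)
    M <- methods::as(M > 0, "CsparseMatrix") * 1
  } else {
    M <- Matrix::sparseMatrix(i = integer(), j = integer(),
                              dims = c(nrow(row_keys), L), x = numeric())
  }
  dimnames(M) <- list(row_keys$row_label, NULL)
  structure(list(matrix = M, row_keys = row_keys, sequence = sequence,
                 circular = circular, genome_id = genome_id,
                 frame_anchor = frame_anchor),
            class = "bitome")
}

#' @export
print.bitome <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<bitome> %s: %d feature rows x %s positions (%s), %s bits (%.3f%% dense)\n",
              x$genome_id, g$n_rows, format(g$n_cols, big.mark = ","),
              if (x$circular) "circular" else "linear",
              format(g$total_bits, big.mark = ","), 100 * g$sparsity))
  cat("categories:", paste(sort(unique(x$row_keys$category)), collapse = ", "), "\n")
  invisible(x)
}

#' Per-row summary of a bitome
#'
#' @param x a `bitome`.
#' @param ... unused.
#' @return tibble with one row per matrix row: the row key fields plus
#'   `n_bits` (row sum) and `coverage` (fraction of positions set).
#' @export
tidy.bitome <- function(x, ...) {
  x$row_keys %>%
    dplyr::mutate(n_bits = Matrix::rowSums(x$matrix),
                  coverage = .data$n_bits / ncol(x$matrix))
}

#' One-line summary statistics of a bitome
#' @param x a `bitome`.
#' @param ... unused.
#' @return one-row tibble: dimensions, total bits, sparsity, and the
#'   minimum / maximum per-position bit counts.
#' @export
glance.bitome <- function(x, ...) {
  cc <- column_bit_counts(x)
  tb <- sum(cc)
  tibble(n_rows = nrow(x$matrix), n_cols = ncol(x$matrix),
         total_bits = tb, sparsity = tb / (as.numeric(nrow(x$matrix)) * ncol(x$matrix)),
         min_column_bits = if (length(cc)) min(cc) else NA_real_,
         max_column_bits = if (length(cc)) max(cc) else NA_real_)
}

#' Extract the sub-bitome over a genomic range
#'
#' Keeps all rows and restricts the columns to `[start, end)`; bit columns
#' are shifted so the first retained position becomes local column 1. On a
#' circular genome the range may run past the origin (`end` up to
#' `start + genome_length`).
#'
#' @param bitome a `bitome`.
#' @param start,end 0-based half-open range.
#' @return a `bitome` over the extracted range (sequence restricted too).
#' @export
bitome_extract <- function(bitome, start, end) {
  L <- ncol(bitome$matrix)
  if (end <= start) abort("empty interval")
  if (end - start > L) abort("interval longer than the genome")
  if (end > L && !bitome$circular) abort("interval beyond the end of a linear genome")
  cols <- (seq.int(start, end - 1L) %% L) + 1L
  out <- bitome
  out$matrix <- bitome$matrix[, cols, drop = FALSE]
  chars <- strsplit(bitome$sequence, "", fixed = TRUE)[[1]]
  out$sequence <- paste(chars[cols], collapse = "")
  out$circular <- FALSE
  out
}

#' Row-filter a bitome by row-key predicate
#'
#' Filters the row-key table with dplyr-style expressions and keeps the
#' matching matrix rows; columns are unchanged.
#'
#' @param bitome a `bitome`.
#' @param ... filter expressions over `category`, `subtype`,
#'   `strand_class`, `frame`, `row_label`.
#' @return a `bitome` with the selected rows (possibly zero, with warning).
#' @examples
#' \dontrun{bitome_select_rows(b, category == "cds")}
#' @export
bitome_select_rows <- function(bitome, ...) {
  keep <- dplyr::filter(bitome$row_keys, ...)
  if (nrow(keep) == 0) warn("row predicate matched no rows")
  out <- bitome
  out$matrix <- bitome$matrix[keep$row, , drop = FALSE]
  out$row_keys <- keep %>% dplyr::mutate(row = dplyr::row_number())
  out
}

#' Serialize a bitome to plain-text files
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate format), `row_keys.tsv`
#' (`index`, `category`, `subtype`, `strand`, `frame`, `row_label`),
#' `header.json` (genome id, length, circularity, frame anchor) and
#' `sequence.txt` into `dir`.
#'
#' @param bitome a `bitome`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_bitome <- function(bitome, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(bitome$matrix, "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  rk <- bitome$row_keys %>%
    dplyr::transmute(index = .data$row, category = .data$category,
                     subtype = .data$subtype, strand = .data$strand_class,
                     frame = .data$frame, row_label = .data$row_label)
  readr::write_tsv(rk, file.path(dir, "row_keys.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(genome_id = bitome$genome_id, genome_length = ncol(bitome$matrix),
         circular = bitome$circular, frame_anchor = bitome$frame_anchor,
         n_rows = nrow(bitome$matrix)),
    file.path(dir, "header.json"), auto_unbox = TRUE)
  writeLines(bitome$sequence, file.path(dir, "sequence.txt"))
  invisible(dir)
}

#' Read a bitome serialized by [write_bitome()]
#' @param dir directory holding `matrix.mtx`, `row_keys.tsv`,
#'   `header.json`, `sequence.txt`.
#' @return a `bitome`.
#' @export
read_bitome <- function(dir) {
  hdr <- jsonlite::read_json(file.path(dir, "header.json"), simplifyVector = TRUE)
  M <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix") * 1
  rk <- readr::read_tsv(file.path(dir, "row_keys.tsv"), col_types = readr::cols(
    index = readr::col_integer(), frame = readr::col_integer(),
    .default = readr::col_character()), progress = FALSE) %>%
    dplyr::transmute(row = .data$index, category = .data$category,
                     subtype = .data$subtype, strand_class = .data$strand,
                     frame = .data$frame, row_label = .data$row_label)
  dimnames(M) <- list(rk$row_label, NULL)
  structure(list(matrix = M, row_keys = rk,
                 sequence = readLines(file.path(dir, "sequence.txt"))[1],
                 circular = isTRUE(hdr$circular), genome_id = hdr$genome_id,
                 frame_anchor = hdr$frame_anchor %||% "leftmost"),
            class = "bitome")
}

#' Export bitome rows as BED intervals
#'
#' One BED line (0-based half-open) per maximal run of set bits per row;
#' the `name` column is the row label. Suitable for genome-browser
#' inspection of any track.
#'
#' @param bitome a `bitome`.
#' @param path output BED path.
#' @param rows optional character vector of row labels to export.
#' @return tibble of the exported intervals, invisibly.
#' @export
bitome_to_bed <- function(bitome, path, rows = NULL) {
  rk <- bitome$row_keys
  if (!is.null(rows)) rk <- rk[rk$row_label %in% rows, , drop = FALSE]
  Mt <- methods::as(bitome$matrix, "TsparseMatrix")
  per_row <- split(Mt@j, factor(Mt@i + 1L, levels = rk$row))
  recs <- purrr::imap(per_row, function(cols, rr) {
    if (length(cols) == 0) return(NULL)
    cols <- sort(cols)
    grp <- cumsum(c(1L, diff(cols) != 1L))
    tibble(start = tapply(cols, grp, min), end = tapply(cols, grp, max) + 1L,
           name = rk$row_label[rk$row == as.integer(rr)])
  })
  bed <- dplyr::bind_rows(recs) %>%
    dplyr::transmute(chrom = bitome$genome_id, start = as.integer(.data$start),
                     end = as.integer(.data$end), name = .data$name)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(bed)
}

#' Accession-anchored sanity checks against a local reference genome
#'
#' Builds a bitome from a locally supplied GenBank file (plus optional
#' regulatory tables) and reports the quantities used for anchoring
#' against a published reference: the matrix column count (genome length),
#' the minimum per-position bit count, and the fraction of the sequence
#' coding for the hydrophobic amino acids Leu, Ala, Gly, Val and Ile. No
#' download is performed; the caller provides the file.
#'
#' @param genbank_path local GenBank flat file.
#' @param regulatory_paths optional named paths for [read_regulatory_tables()].
#' @return one-row tibble: `n_columns`, `min_column_bit_count`,
#'   `hydrophobic_aa_coverage`.
#' @export
verify_reference_bitome <- function(genbank_path, regulatory_paths = NULL) {
  gb <- read_genbank(genbank_path)
  feats <- gb$features
  if (!is.null(regulatory_paths)) {
    genes <- feats[feats$category %in% c("cds", "pseudogene", "rna_gene"), ]
    feats <- dplyr::bind_rows(feats, read_regulatory_tables(regulatory_paths, genes))
  }
  b <- build_bitome(gb$sequence, feats, circular = gb$circular,
                    genome_id = gb$accession)
  hydro <- c("Leu", "Ala", "Gly", "Val", "Ile")
  tibble(
    n_columns = ncol(b$matrix),
    min_column_bit_count = min(column_bit_counts(b)),
    hydrophobic_aa_coverage = sequence_coverage(
      b, category == "amino_acid" & subtype %in% hydro)
  )
}
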