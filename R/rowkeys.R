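#' Reading frame of a coding start position
#'
#' The frame is the mod-3 residue class of the 0-based genomic coordinate
#' anchoring the feature. Together with the strand this splits gene-like
#' tracks into six rows so that overlapping features in different frames
#' never collide in one row.
#'
#' @param position 0-based genomic coordinate(s).
#' @return integer frame(s) in `{0, 1, 2}`.
#' @examples
#' frame_of(c(0, 7, 99))
#' @export
frame_of <- function(position) as.integer(position %% 3L)

# standard genetic code, codon -> 3-letter amino acid ("*" = stop)
GENETIC_CODE3 <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(as.vector(t(outer(b, b, paste0))), b, paste0)))
  aa1 <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  setNames(aa1, codons)
})

AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
              U = "Sec")

#' Translate a codon string under the standard code
#' @param codon 3-letter nucleotide string(s), coding strand 5'-3'.
#' @return one-letter amino acid(s); `"*"` for stop codons.
#' @export
translate_codon <- function(codon) unname(GENETIC_CODE3[toupper(codon)])

#' Assign bitome row keys to features
#'
#' Applies the row-splitting rules that keep the matrix binary:
#' \itemize{
#'   \item gene-like and per-residue tracks (cds, pseudogene, rna_gene,
#'     codon, amino_acid, protein, secondary_structure, exposure, cog) are
#'     split into six rows: (forward, reverse) x (frame 0, 1, 2);
#'   \item positional regulatory tracks (operon, transcription unit,
#'     promoter and its elements, terminator, attenuator, Shine-Dalgarno,
#'     riboswitch, nucleobase, repeats/origin) are split by strand only;
#'   \item regulons, sigmulons, i-modulons and TF binding sites carry no
#'     strand information and stay single rows.
#' }
#' The frame anchor is the feature's leftmost genomic coordinate by
#' default; set `frame_anchor = "coding_start"` to anchor reverse-strand
#' features on their rightmost (first transcribed/translated) base.
#'
#' @param features feature table.
#' @param frame_anchor `"leftmost"` (default) or `"coding_start"`.
#' @return tibble with one row per feature: `category`, `subtype`,
#'   `strand_class`, `frame` (NA where not applicable) and a canonical
#'   `row_label`.
#' @export
assign_row_keys <- function(features, frame_anchor = c("leftmost", "coding_start")) {
  frame_anchor <- match.arg(frame_anchor)
  bad <- setdiff(unique(features$category), ALL_CATEGORIES)
  if (length(bad)) abort(paste0("unknown category: ", paste(bad, collapse = ", ")))
  n <- nrow(features)
  strand_class <- ifelse(features$category %in% SINGLE_ROW_CATEGORIES, ".",
                         features$strand)
  frame <- rep(NA_integer_, n)
  six <- which(features$category %in% SIX_ROW_CATEGORIES)
  if (length(six)) {
    anchor <- vapply(six, function(k) {
      ivs <- features$intervals[[k]]
      if (nrow(ivs) == 0) return(NA_integer_)
      if (frame_anchor == "coding_start" && features$strand[k] == "-") {
        max(ivs$end) - 1L
      } else {
        min(ivs$start)
      }
    }, integer(1))
    frame[six] <- frame_of(anchor)
  }
  tibble(
    category = features$category,
    subtype = features$subtype,
    strand_class = strand_class,
    frame = frame,
    row_label = row_key_label(features$category, features$subtype, strand_class, frame)
  )
}

#' @noRd
row_key_label <- function(category, subtype, strand_class, frame) {
  paste0(category,
         ifelse(is.na(subtype) | subtype == "", "", paste0(":", subtype)),
         ifelse(strand_class == ".", "", paste0("|", ifelse(strand_class == "+", "fwd", "rev"))),
         ifelse(is.na(frame), "", paste0("|f", frame)))
}

#' Derive the per-position nucleobase tracks
#'
#' Emits eight nucleobase records (4 bases x 2 strands; the reverse strand
#' holds the complement), so every genomic position receives exactly two
#' nucleobase bits — the bitome's column-count floor.
#'
#' @param sequence nucleotide string over `A`,`C`,`G`,`T` (other codes are
#'   skipped or abort per `ambiguous`).
#' @param ambiguous `"skip"` (default) leaves ambiguous positions without
#'   nucleobase bits; `"error"` aborts.
#' @return feature table of `nucleobase` records with run-length-encoded
#'   intervals.
#' @export
derive_sequence_tracks <- function(sequence, ambiguous = c("skip", "error")) {
  ambiguous <- match.arg(ambiguous)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (ambiguous == "error" && !all(chars %in% c("A", "C", "G", "T"))) {
    abort("ambiguous base codes in sequence")
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  recs <- list()
  for (base in c("A", "C", "G", "T")) {
    for (strand in c("+", "-")) {
      # reverse-strand base `base` sits opposite its complement on the
      # reference sequence
      target <- if (strand == "+") base else comp[[base]]
      hits <- chars == target
      r <- rle(hits)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values
      recs[[paste0(base, strand)]] <- feature_tbl(
        id = paste0("nt_", base, "_", if (strand == "+") "fwd" else "rev"),
        category = "nucleobase", subtype = base, strand = strand,
        intervals = list(iv(starts[keep], ends[keep]))
      )
    }
  }
  dplyr::bind_rows(recs)
}

#' Derive codon and amino-acid tracks from coding sequences
#'
#' Walks each CDS codon-by-codon on its coding strand and emits one 3-bp
#' `codon` record per codon (subtype = the codon string read 5'-3' on the
#' coding strand) and one matching `amino_acid` record per non-stop codon
#' (subtype = 3-letter code, including `Sec` for annotated selenocysteine).
#' Amino-acid identity is taken from the annotation's `translation`
#' attribute where present (it is trusted over the standard-code
#' translation, with a warning when the two disagree) and from the standard
#' genetic code otherwise.
#'
#' @param cds_features feature table rows with category `"cds"`.
#' @param sequence genome nucleotide string.
#' @return feature table of `codon` and `amino_acid` records; each carries
#'   the parent locus tag in `links`.
#' @export
derive_codon_aa_tracks <- function(cds_features, sequence) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out <- vector("list", nrow(cds_features))
  warned <- FALSE
  for (k in seq_len(nrow(cds_features))) {
    ivs <- cds_features$intervals[[k]]
    strand <- cds_features$strand[k]
    # genomic positions in coding order (5'-3' on the coding strand)
    pos <- feature_positions(ivs)
    if (strand == "-") pos <- rev(pos)
    n_cod <- length(pos) %/% 3L
    if (n_cod == 0L || length(pos) %% 3L != 0L) {
      warn(paste0("CDS ", cds_features$id[k], " length not divisible by 3; skipped"))
      next
    }
    bases <- substring(sequence, pos + 1L, pos + 1L)
    if (strand == "-") bases <- comp[bases]
    codons <- vapply(seq_len(n_cod) * 3L - 2L, function(s)
      paste0(bases[s], bases[s + 1L], bases[s + 2L]), "")
    aa <- translate_codon(codons)
    tr <- cds_features$attributes[[k]]$translation
    if (!is.null(tr)) {
      tr_aa <- strsplit(tr, "", fixed = TRUE)[[1]]
      code_aa <- aa[seq_along(tr_aa)]
      # an annotated Sec at a TGA is the standard convention, not a conflict
      real_conflict <- tr_aa != code_aa & !(tr_aa == "U" & code_aa == "*")
      if (!warned && any(real_conflict, na.rm = TRUE)) {
        warn(paste0("CDS ", cds_features$id[k],
                    ": annotated translation disagrees with the standard code; ",
                    "trusting the annotation"))
        warned <- TRUE
      }
      aa[seq_along(tr_aa)] <- tr_aa
    }
    # genomic intervals per codon: contiguous for single-interval CDSs
    starts_cod <- pos[seq_len(n_cod) * 3L - 2L]
    left <- if (strand == "+") starts_cod else starts_cod - 2L
    contiguous <- nrow(ivs) == 1L
    codon_iv <- if (contiguous) {
      purrr::map(left, function(s) iv(s, s + 3L))
    } else {
      purrr::map(seq_len(n_cod), function(j) {
        p <- sort(pos[(3L * j - 2L):(3L * j)])
        runs <- split(p, cumsum(c(1L, diff(p) != 1L)))
        iv(vapply(runs, min, integer(1)), vapply(runs, max, integer(1)) + 1L)
      })
    }
    is_stop <- aa == "*"
    aa3 <- AA_THREE[aa]
    tag <- cds_features$id[k]
    cod_tbl <- feature_tbl(
      id = paste0(tag, "_cod", seq_len(n_cod)),
      category = "codon", subtype = codons, strand = strand,
      intervals = codon_iv, links = rep(list(tag), n_cod))
    keep <- !is_stop & !is.na(aa3)
    aa_tbl <- feature_tbl(
      id = paste0(tag, "_aa", which(keep)),
      category = "amino_acid", subtype = aa3[keep], strand = strand,
      intervals = codon_iv[keep], links = rep(list(tag), sum(keep)))
    out[[k]] <- dplyr::bind_rows(cod_tbl, aa_tbl)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) feature_tbl() else res
}

#' Derive per-gene protein-presence tracks
#'
#' One `protein` record per CDS covering the full coding span, split into
#' the same six (strand, frame) rows as the genes themselves.
#'
#' @param cds_features feature table rows with category `"cds"`.
#' @return feature table of `protein` records.
#' @export
derive_protein_tracks <- function(cds_features) {
  if (nrow(cds_features) == 0) return(feature_tbl())
  feature_tbl(
    id = paste0(cds_features$id, "_prot"),
    category = "protein", subtype = NA_character_,
    strand = cds_features$strand,
    intervals = cds_features$intervals,
    links = as.list(cds_features$id)
  )
}
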