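#' Read a single-record GenBank flat file
#'
#' Parses the genome sequence and the core positional features (coding
#' sequences, pseudogenes, RNA genes, insertion elements, repeat regions and
#' the replication origin) from a GenBank flat file. GenBank's 1-based
#' inclusive coordinates are converted to the package's 0-based half-open
#' convention at this boundary; `complement(...)` becomes strand `"-"` and
#' `join(...)` becomes a multi-interval feature in coding order.
#'
#' @param path path to a GenBank flat file containing exactly one record
#'   with sequence.
#' @return a list with elements `sequence` (uppercase nucleotide string),
#'   `features` (feature table, see [feature_tbl()]), `genome_length`,
#'   `circular` and `accession`.
#' @examples
#' gb <- write_genbank_string("ACGTACGTAC", feature_tbl(
#'   id = "b0001", category = "cds", strand = "+",
#'   intervals = list(data.frame(start = 0L, end = 9L))), circular = FALSE)
#' tf <- tempfile(fileext = ".gb"); writeLines(gb, tf)
#' read_genbank(tf)$genome_length
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_idx <- grep("^LOCUS ", lines)
  if (length(locus_idx) == 0) abort("not a GenBank flat file: no LOCUS line")
  if (length(locus_idx) > 1) {
    abort(paste0("multi-record GenBank file (", length(locus_idx),
                 " LOCUS lines); expected a single record"))
  }
  locus <- strsplit(trimws(lines[locus_idx]), "\\s+")[[1]]
  accession <- locus[2]
  circular <- any(locus == "circular")

  origin_idx <- grep("^ORIGIN", lines)
  if (length(origin_idx) == 0) abort("GenBank record has no ORIGIN sequence block")
  end_idx <- grep("^//", lines)
  end_idx <- if (length(end_idx)) end_idx[1] else length(lines) + 1L
  seq_lines <- lines[(origin_idx[1] + 1L):(end_idx - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  genome_length <- nchar(sequence)

  feat_start <- grep("^FEATURES", lines)
  raw_feats <- list()
  if (length(feat_start)) {
    block <- lines[(feat_start[1] + 1L):(origin_idx[1] - 1L)]
    cur <- NULL
    for (ln in block) {
      if (grepl("^ {5}\\S", ln)) { # new feature key at column 6
        if (!is.null(cur)) raw_feats[[length(raw_feats) + 1L]] <- cur
        key <- trimws(substr(ln, 1, 21))
        cur <- list(key = key, loc = trimws(substr(ln, 22, nchar(ln))),
                    quals = character())
      } else if (!is.null(cur)) {
        body <- trimws(ln)
        if (startsWith(body, "/")) {
          cur$quals <- c(cur$quals, body)
        } else if (length(cur$quals) == 0) {
          cur$loc <- paste0(cur$loc, body) # continued location
        } else {
          cur$quals[length(cur$quals)] <- paste0(cur$quals[length(cur$quals)], body)
        }
      }
    }
    if (!is.null(cur)) raw_feats[[length(raw_feats) + 1L]] <- cur
  }

  recs <- purrr::map(raw_feats, parse_genbank_feature,
                     genome_length = genome_length, circular = circular)
  features <- dplyr::bind_rows(purrr::compact(recs))
  if (nrow(features) > 0) {
    # fill generated ids where no locus_tag was present
    noid <- is.na(features$id) | features$id == ""
    features$id[noid] <- paste0("feat_", which(noid))
    validate_features(features, genome_length, circular)
  } else {
    features <- feature_tbl()
  }
  list(sequence = sequence, features = features,
       genome_length = genome_length, circular = circular,
       accession = accession)
}

GENBANK_KEY_MAP <- c(
  CDS = "cds", tRNA = "rna_gene", rRNA = "rna_gene", ncRNA = "rna_gene",
  tmRNA = "rna_gene", misc_RNA = "rna_gene",
  mobile_element = "insertion_element", repeat_region = "repeat_region",
  rep_origin = "origin"
)

#' @noRd
parse_genbank_feature <- function(f, genome_length, circular) {
  quals <- parse_qualifiers(f$quals)
  category <- if (f$key == "gene" && !is.null(quals$pseudo)) {
    "pseudogene"
  } else if (f$key == "CDS" && !is.null(quals$pseudo)) {
    "pseudogene"
  } else {
    unname(GENBANK_KEY_MAP[f$key])
  }
  if (is.na(category) || is.null(category)) return(NULL)
  loc <- parse_genbank_location(f$loc)
  if (!isTRUE(attr(loc, "wraps")) && any(loc$end > genome_length)) {
    if (!circular) {
      abort(paste0("feature at '", f$loc, "' extends beyond the ",
                   genome_length, " bp sequence of a non-circular record"))
    }
  }
  attrs <- quals[setdiff(names(quals), c("locus_tag"))]
  if (isTRUE(attr(loc, "wraps"))) attrs$wraps <- TRUE
  attrs$genbank_key <- f$key
  feature_tbl(
    id = quals$locus_tag %||% NA_character_,
    category = category, subtype = NA_character_,
    strand = attr(loc, "strand"),
    intervals = list(data.frame(start = loc$start, end = loc$end)),
    attributes = list(attrs)
  )
}

#' @noRd
parse_qualifiers <- function(quals) {
  out <- list()
  for (q in quals) {
    m <- regmatches(q, regexec('^/([A-Za-z_0-9]+)(=(.*))?$', q))[[1]]
    if (length(m) == 0) next
    key <- m[2]
    val <- m[4]
    if (is.na(val) || val == "") val <- TRUE else val <- gsub('^"|"$', "", val)
    if (key == "translation" && is.character(val)) val <- gsub("\\s", "", val)
    out[[key]] <- val
  }
  out
}

#' Parse a GenBank location string into 0-based half-open intervals
#'
#' Supports `a..b`, single positions, `complement(...)`, `join(...)` and
#' `order(...)`; partial-end markers (`<`, `>`) are stripped. Pieces of a
#' `complement(join(...))` are returned in coding order (rightmost genomic
#' piece first when read 5' to 3' on the reverse strand is *not* re-sorted:
#' genomic order is preserved, coding order is derived downstream from the
#' strand).
#'
#' @param loc location string as it appears in the flat file.
#' @return data frame `start`,`end` with attributes `strand` and `wraps`.
#' @export
parse_genbank_location <- function(loc) {
  s <- gsub("[<>\\s]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", s)) {
    strand <- "-"
    s <- sub("^complement\\((.*)\\)$", "\\1", s)
  }
  if (grepl("^(join|order)\\(", s)) {
    s <- sub("^(join|order)\\((.*)\\)$", "\\2", s)
  }
  pieces <- strsplit(s, ",", fixed = TRUE)[[1]]
  if (length(pieces) == 0) abort(paste0("unparseable location: ", loc))
  parts <- lapply(pieces, function(p) {
    if (grepl("^\\d+\\.\\.\\d+$", p)) {
      ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else if (grepl("^\\d+$", p)) {
      ab <- rep(as.integer(p), 2L)
    } else {
      abort(paste0("unparseable location piece '", p, "' in: ", loc))
    }
    c(ab[1] - 1L, ab[2]) # to 0-based half-open
  })
  out <- data.frame(start = vapply(parts, `[`, integer(1), 1L),
                    end = vapply(parts, `[`, integer(1), 2L))
  wraps <- nrow(out) > 1 && out$start[1] > out$start[nrow(out)]
  attr(out, "strand") <- strand
  attr(out, "wraps") <- wraps
  out
}

#' Render a 0-based half-open feature location back to GenBank text
#' @param ivs data frame `start`,`end`.
#' @param strand `"+"`, `"-"` or `"."`.
#' @return GenBank location string (1-based inclusive).
#' @export
format_genbank_location <- function(ivs, strand = "+") {
  pieces <- paste0(ivs$start + 1L, "..", ivs$end)
  s <- if (length(pieces) > 1) paste0("join(", paste(pieces, collapse = ","), ")") else pieces
  if (strand == "-") s <- paste0("complement(", s, ")")
  s
}

#' Serialize a genome and its core features to GenBank flat-file lines
#'
#' Emits a minimal but standard-conformant single-record GenBank flat file
#' (LOCUS / FEATURES / ORIGIN) that third-party parsers read back. Only
#' categories with a GenBank feature key (cds, pseudogene, rna_gene,
#' insertion_element, repeat_region, origin) are written; regulatory
#' features travel in the TSV dialect instead.
#'
#' @param sequence nucleotide string.
#' @param features feature table.
#' @param accession record name.
#' @param circular mark the record circular.
#' @return character vector of file lines.
#' @export
write_genbank_string <- function(sequence, features, accession = "SYNTH01",
                                 circular = TRUE) {
  L <- nchar(sequence)
  topo <- if (circular) "circular" else "linear"
  lines <- c(
    # LOCUS column layout mirrors the reference flat-file format so strict
    # third-party parsers read it without complaint
    paste0("LOCUS       ", accession,
           formatC(as.integer(L),
                   width = max(28L - nchar(accession),
                               nchar(as.character(L)) + 1L)),
           " bp    DNA     ", formatC(topo, width = -8), " BCT 01-JAN-2026"),
    sprintf("DEFINITION  synthetic genome %s.", accession),
    sprintf("ACCESSION   %s", accession),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", L)
  )
  rev_key_map <- c(cds = "CDS", rna_gene = "ncRNA", pseudogene = "gene",
                   insertion_element = "mobile_element",
                   repeat_region = "repeat_region", origin = "rep_origin")
  for (k in seq_len(nrow(features))) {
    cat_k <- features$category[k]
    key <- rev_key_map[cat_k]
    if (is.na(key)) next
    attrs <- features$attributes[[k]]
    if (!is.null(attrs$genbank_key)) key <- attrs$genbank_key
    loc <- format_genbank_location(features$intervals[[k]], features$strand[k])
    lines <- c(lines, sprintf("     %-15s %s", key, loc),
               sprintf('                     /locus_tag="%s"', features$id[k]))
    if (cat_k == "pseudogene") lines <- c(lines, "                     /pseudo")
    tr <- attrs$translation
    if (!is.null(tr)) {
      body <- paste0('/translation="', tr, '"')
      wrapped <- substring(body, seq(1, nchar(body), 58),
                           pmin(seq(58, nchar(body) + 57, 58), nchar(body)))
      lines <- c(lines, paste0("                     ", wrapped))
    }
  }
  lines <- c(lines, "ORIGIN")
  starts <- seq(1, L, 60)
  for (s in starts) {
    chunk <- substr(sequence, s, min(s + 59, L))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", s, tolower(paste(groups, collapse = " "))))
  }
  c(lines, "//")
}
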