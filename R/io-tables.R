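#' Read regulatory annotation tables
#'
#' Reads the package's regulatory TSV dialect (one file per feature class)
#' into a feature table, applying the linking and exclusion filters used
#' when assembling a bitome:
#' \itemize{
#'   \item operons / transcription units with no link to a known gene are
#'     excluded, and genes with no operon or TU link are flagged;
#'   \item promoters with no link to a surviving transcription unit are
#'     excluded;
#'   \item link entries naming unknown locus tags are dropped with a
#'     warning.
#' }
#' Promoter rows expand into a `promoter` record plus child `minus10`,
#' `minus35` and `tss` records (whichever sub-elements the row carries),
#' each linked back to the promoter id.
#'
#' Columns: `id`, `left`, `right` (1-based inclusive), `strand` (`+`/`-`/`.`),
#' `linked_locus_tags` (comma-separated). Promoter files add `tss`,
#' `minus10_left`, `minus10_right`, `minus35_left`, `minus35_right`
#' (1-based; empty where absent). Regulon / sigmulon / imodulon files carry
#' only `id` and `linked_locus_tags`.
#'
#' @param paths named list/vector of file paths; names are feature classes
#'   (`operon`, `transcription_unit`, `promoter`, `terminator`,
#'   `attenuator`, `shine_dalgarno`, `riboswitch`, `tfbs`, `regulon`,
#'   `sigmulon`, `imodulon`).
#' @param genes feature table of reference-genome genes (for link checks).
#' @return feature table of surviving regulatory records; attribute
#'   `unlinked_genes` lists locus tags of genes with no operon/TU link.
#' @export
read_regulatory_tables <- function(paths, genes) {
  known <- genes$id
  classes <- names(paths)
  bad <- setdiff(classes, c(TWO_ROW_CATEGORIES, SINGLE_ROW_CATEGORIES))
  if (length(bad)) abort(paste0("unknown regulatory table class: ", paste(bad, collapse = ", ")))

  read_one <- function(cls, path) {
    tb <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    if (nrow(tb) == 0) return(feature_tbl())
    coordless <- cls %in% c("regulon", "sigmulon", "imodulon")
    if (!coordless) {
      left <- suppressWarnings(as.integer(tb$left))
      right <- suppressWarnings(as.integer(tb$right))
      bad_row <- which(is.na(left) | is.na(right) | left > right | left < 1)
      if (length(bad_row)) {
        abort(paste0("malformed coordinates in ", path, " at line ",
                     bad_row[1] + 1L, " (id ", tb$id[bad_row[1]], ")"))
      }
    }
    links <- strsplit(dplyr::coalesce(tb$linked_locus_tags, ""), ",", fixed = TRUE)
    links <- lapply(links, function(x) x[nzchar(x)])
    out <- feature_tbl(
      id = tb$id, category = cls,
      subtype = if (cls %in% c("tfbs", "regulon", "sigmulon", "imodulon")) tb$id else NA_character_,
      strand = if (coordless) "." else tb$strand,
      intervals = if (coordless) NULL else
        purrr::map2(left, right, function(l, r) iv(l - 1L, r)),
      links = links
    )
    if (cls == "promoter") {
      out$attributes <- purrr::pmap(tb, function(...) {
        row <- list(...)
        a <- list()
        if (!is.null(row$tss) && !is.na(row$tss) && nzchar(row$tss))
          a$tss <- as.integer(row$tss) - 1L
        for (el in c("minus10", "minus35")) {
          l <- row[[paste0(el, "_left")]]; r <- row[[paste0(el, "_right")]]
          if (!is.null(l) && !is.na(l) && nzchar(l))
            a[[el]] <- c(as.integer(l) - 1L, as.integer(r))
        }
        a
      })
    }
    out
  }

  feats <- purrr::imap(paths, function(p, cls) read_one(cls, p))
  feats <- dplyr::bind_rows(feats)
  if (nrow(feats) == 0) return(feature_tbl())

  # drop link entries that name unknown locus tags (links of promoters point
  # at TU ids and are checked below instead)
  tu_ids <- feats$id[feats$category %in% c("transcription_unit")]
  gene_linked <- c("operon", "transcription_unit", "terminator", "attenuator",
                   "shine_dalgarno", "riboswitch", "tfbs", "regulon",
                   "sigmulon", "imodulon")
  n_dropped <- 0L
  for (k in which(feats$category %in% gene_linked)) {
    keep <- feats$links[[k]] %in% known
    n_dropped <- n_dropped + sum(!keep)
    feats$links[[k]] <- feats$links[[k]][keep]
  }
  if (n_dropped > 0) {
    warn(paste0(n_dropped, " link entr", if (n_dropped == 1) "y" else "ies",
                " named unknown locus tags and were dropped"))
  }

  # operons / TUs must link to >= 1 reference gene
  drop_tu <- feats$category %in% c("operon", "transcription_unit") &
    lengths(feats$links) == 0
  surviving_tus <- feats$id[feats$category == "transcription_unit" & !drop_tu]
  # promoters must link to a surviving TU
  drop_prom <- feats$category == "promoter" &
    !purrr::map_lgl(feats$links, function(l) any(l %in% surviving_tus))
  feats <- feats[!(drop_tu | drop_prom), , drop = FALSE]

  # expand promoter sub-elements into their own records
  children <- list()
  for (k in which(feats$category == "promoter")) {
    a <- feats$attributes[[k]]
    pid <- feats$id[k]
    strand <- feats$strand[k]
    if (!is.null(a$tss)) {
      children[[length(children) + 1L]] <- feature_tbl(
        id = paste0(pid, "_tss"), category = "tss", strand = strand,
        intervals = list(iv(a$tss, a$tss + 1L)), links = list(pid))
    }
    for (el in c("minus10", "minus35")) {
      if (!is.null(a[[el]])) {
        children[[length(children) + 1L]] <- feature_tbl(
          id = paste0(pid, "_", sub("minus", "m", el)), category = el,
          strand = strand, intervals = list(iv(a[[el]][1], a[[el]][2])),
          links = list(pid))
      }
    }
  }
  out <- dplyr::bind_rows(c(list(feats), children))

  linked_genes <- unique(unlist(out$links[out$category %in% c("operon", "transcription_unit")]))
  unlinked <- setdiff(known, linked_genes)
  if (length(unlinked)) {
    inform(paste0(length(unlinked), " gene(s) have no operon/TU link"))
  }
  attr(out, "unlinked_genes") <- unlinked
  out
}

#' Write regulatory feature tables in the TSV dialect
#'
#' Inverse of [read_regulatory_tables()]: one file per feature class, named
#' `<class>.tsv`, in the column layout that reader expects. Promoter
#' sub-element records (`minus10`, `minus35`, `tss`) are folded back into
#' the promoter rows' columns rather than written as separate files.
#'
#' @param features feature table of regulatory records.
#' @param dir output directory (created if missing).
#' @return named vector of written paths, invisibly.
#' @export
write_regulatory_tables <- function(features, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character()
  top <- features[!features$category %in% c("minus10", "minus35", "tss"), , drop = FALSE]
  for (cls in unique(top$category)) {
    rows <- top[top$category == cls, , drop = FALSE]
    coordless <- cls %in% c("regulon", "sigmulon", "imodulon")
    tb <- tibble(id = rows$id)
    if (!coordless) {
      tb$left <- purrr::map_int(rows$intervals, ~ min(.x$start)) + 1L
      tb$right <- purrr::map_int(rows$intervals, ~ max(.x$end))
      tb$strand <- rows$strand
    }
    tb$linked_locus_tags <- purrr::map_chr(rows$links, paste, collapse = ",")
    if (cls == "promoter") {
      gx <- function(f) purrr::map_chr(rows$attributes, f)
      tb$tss <- gx(function(a) if (is.null(a$tss)) "" else as.character(a$tss + 1L))
      for (el in c("minus10", "minus35")) {
        tb[[paste0(el, "_left")]] <- gx(function(a) if (is.null(a[[el]])) "" else as.character(a[[el]][1] + 1L))
        tb[[paste0(el, "_right")]] <- gx(function(a) if (is.null(a[[el]])) "" else as.character(a[[el]][2]))
      }
    }
    p <- file.path(dir, paste0(cls, ".tsv"))
    readr::write_tsv(tb, p, progress = FALSE)
    written[cls] <- p
  }
  invisible(written)
}

#' Read a SNP table (TSV or minimal VCF)
#'
#' Accepts either a TSV with columns `position` (1-based), `ref`, `alt`,
#' `experiment`, or a minimal VCF 4.x (`#CHROM POS ID REF ALT ...`). Only
#' single-nucleotide substitutions are retained; rows describing indels or
#' multi-nucleotide variants are skipped with a count reported.
#'
#' @param path input file.
#' @param genome_length optional; positions at or beyond it abort.
#' @return tibble with `position` (0-based), `ref`, `alt`, `source_id`.
#' @export
read_snp_table <- function(path, genome_length = NA) {
  first <- readLines(path, n = 1L)
  is_vcf <- grepl("^##fileformat=VCF", first) || grepl("\\.vcf$", path)
  if (is_vcf) {
    lines <- readLines(path, warn = FALSE)
    body <- lines[!startsWith(lines, "##")]
    tb <- readr::read_tsv(I(paste(body, collapse = "\n")),
                          col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    names(tb) <- sub("^#", "", names(tb))
    tb <- tibble(position = as.integer(tb$POS), ref = tb$REF, alt = tb$ALT,
                 source_id = if ("ID" %in% names(tb)) tb$ID else NA_character_)
  } else {
    tb <- readr::read_tsv(path, col_types = readr::cols(
      position = readr::col_integer(), .default = readr::col_character()),
      progress = FALSE)
    tb <- tibble(position = tb$position, ref = tb$ref, alt = tb$alt,
                 source_id = if ("experiment" %in% names(tb)) tb$experiment else NA_character_)
  }
  is_snv <- nchar(tb$ref) == 1L & nchar(tb$alt) == 1L &
    toupper(tb$ref) %in% c("A", "C", "G", "T") &
    toupper(tb$alt) %in% c("A", "C", "G", "T") &
    toupper(tb$ref) != toupper(tb$alt)
  n_skip <- sum(!is_snv)
  if (n_skip > 0) inform(paste0("skipped ", n_skip, " non-SNV row(s)"))
  out <- tb[is_snv, , drop = FALSE]
  out$position <- out$position - 1L
  out$ref <- toupper(out$ref); out$alt <- toupper(out$alt)
  if (!is.na(genome_length) && nrow(out) > 0 &&
      (any(out$position < 0) || any(out$position >= genome_length))) {
    abort("SNP position outside the genome")
  }
  out
}

#' Read a binary gene-label table
#'
#' Reads a TSV with columns `locus_tag` and `label` and returns one label
#' per gene. Genes absent from the table receive `default` (essentiality
#' screens typically list only the positives). Duplicate locus tags with
#' conflicting labels abort.
#'
#' @param path label TSV.
#' @param genes feature table of genes to label.
#' @param default label for genes missing from the table (0 or 1).
#' @return tibble with `locus_tag`, `label` covering every gene.
#' @export
read_label_table <- function(path, genes, default = 0L) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    locus_tag = readr::col_character(), label = readr::col_integer()),
    progress = FALSE)
  if (nrow(tb) > 0) {
    conf <- tb %>% dplyr::group_by(.data$locus_tag) %>%
      dplyr::summarise(k = dplyr::n_distinct(.data$label), .groups = "drop") %>%
      dplyr::filter(.data$k > 1)
    if (nrow(conf) > 0) {
      abort(paste0("conflicting duplicate labels for: ",
                   paste(conf$locus_tag, collapse = ", ")))
    }
    tb <- dplyr::distinct(tb)
  }
  out <- tibble(locus_tag = genes$id) %>%
    dplyr::left_join(tb, by = "locus_tag") %>%
    dplyr::mutate(label = dplyr::coalesce(.data$label, as.integer(default)))
  stopifnot(all(out$label %in% c(0L, 1L)))
  out
}

#' Read a COG functional-annotation table into cog feature records
#'
#' TSV with columns `locus_tag`, `cog` (one functional-category letter).
#' Each row becomes a `cog` record carrying the letter as subtype and the
#' gene's own intervals and strand, so the bitome places COG bits over the
#' gene body in the gene's (strand, frame) row set.
#'
#' @param path COG TSV.
#' @param genes feature table of genes.
#' @return feature table of `cog` records.
#' @export
read_cog_table <- function(path, genes) {
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  idx <- match(tb$locus_tag, genes$id)
  if (anyNA(idx)) {
    warn(paste0(sum(is.na(idx)), " COG row(s) named unknown locus tags; dropped"))
    tb <- tb[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  if (nrow(tb) == 0) return(feature_tbl())
  feature_tbl(
    id = paste0(tb$locus_tag, "_cog_", tb$cog),
    category = "cog", subtype = tb$cog,
    strand = genes$strand[idx],
    intervals = genes$intervals[idx],
    links = as.list(tb$locus_tag)
  )
}
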