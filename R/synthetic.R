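#' Configuration for the synthetic annotation generator
#'
#' Bundles the geometry and statistical structure of a synthetic bacterial
#' genome: operon/gene layout, UTR length distributions, promoter element
#' offsets, TF binding site density, regulon membership, and the sizes of
#' the derived tables. Defaults emulate the feature geometry of a
#' well-annotated enterobacterial genome at desk scale: geometric UTR
#' lengths with median 50 bp, canonical -10/-35 boxes at -12..-7 and
#' -35..-30 relative to the TSS with +/- 1 bp jitter (spacer ~17 bp), and
#' protein-coding genes of 300-900 bp.
#'
#' @param genome_length genome size in bp.
#' @param n_operons number of operons (one transcription unit each).
#' @param genes_per_operon integer range `c(min, max)`.
#' @param gene_length_range ORF length range in bp (rounded to codons).
#' @param utr5_sampler,utr3_sampler functions `n -> n lengths` (bp);
#'   defaults draw geometric lengths with median ~50.
#' @param intergenic_range within-TU gap range between genes, bp.
#' @param promoter_jitter max +/- jitter on each box position, bp.
#' @param tfbs_density TF binding sites per inter-TU bp.
#' @param n_tfs,n_regulons,n_sigmulons,n_imodulons table sizes.
#' @param membership_p per-gene membership probability for regulons,
#'   sigmulons and i-modulons.
#' @param cog_letters COG category letters assigned (one per gene).
#' @param n_selenoproteins CDSs given one internal TGA read as Sec.
#' @param min_gap minimum inter-operon gap, bp.
#' @param seed integer seed; the entire generation is a deterministic
#'   function of the config including this seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(genome_length = 80000L, n_operons = 40L,
                             genes_per_operon = c(1L, 3L),
                             gene_length_range = c(300L, 900L),
                             utr5_sampler = NULL, utr3_sampler = NULL,
                             intergenic_range = c(20L, 80L),
                             promoter_jitter = 1L,
                             tfbs_density = 1 / 500,
                             n_tfs = 6L, n_regulons = 8L, n_sigmulons = 3L,
                             n_imodulons = 5L, membership_p = 0.15,
                             cog_letters = c("C", "E", "G", "J", "K", "L",
                                             "M", "O", "P", "T"),
                             n_selenoproteins = 1L,
                             min_gap = 60L, seed = 42L) {
  geom50 <- function(n) rgeom(n, 1 - 0.5^(1 / 50)) + 1L
  cfg <- list(genome_length = as.integer(genome_length),
              n_operons = as.integer(n_operons),
              genes_per_operon = as.integer(genes_per_operon),
              gene_length_range = as.integer(gene_length_range),
              utr5_sampler = utr5_sampler %||% geom50,
              utr3_sampler = utr3_sampler %||% geom50,
              intergenic_range = as.integer(intergenic_range),
              promoter_jitter = as.integer(promoter_jitter),
              tfbs_density = tfbs_density, n_tfs = as.integer(n_tfs),
              n_regulons = as.integer(n_regulons),
              n_sigmulons = as.integer(n_sigmulons),
              n_imodulons = as.integer(n_imodulons),
              membership_p = membership_p, cog_letters = cog_letters,
              n_selenoproteins = as.integer(n_selenoproteins),
              min_gap = as.integer(min_gap), seed = as.integer(seed))
  stopifnot(cfg$genome_length > 0, cfg$n_operons >= 0,
            cfg$membership_p >= 0, cfg$membership_p <= 1,
            cfg$tfbs_density >= 0)
  structure(cfg, class = "synthetic_config")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# sample() treats a scalar first argument as 1:n; guard degenerate ranges
sample_range <- function(lo, hi, n = 1L) {
  vals <- seq.int(lo, hi)
  if (length(vals) == 1L) rep(vals, n) else sample(vals, n, replace = TRUE)
}

#' @noRd
random_orf <- function(len_bp, sec = FALSE) {
  n_cod <- len_bp %/% 3L
  body_codons <- setdiff(names(GENETIC_CODE3), STOP_CODONS)
  cods <- c("ATG", sample(body_codons, n_cod - 2L, replace = TRUE),
            sample(STOP_CODONS, 1L))
  sec_at <- NA_integer_
  if (sec && n_cod > 4L) {
    sec_at <- sample(3:(n_cod - 2L), 1L)
    cods[sec_at] <- "TGA"
  }
  aa <- translate_codon(cods[-length(cods)])
  if (!is.na(sec_at)) aa[sec_at] <- "U"
  list(seq = paste(cods, collapse = ""), translation = paste(aa, collapse = ""))
}

#' Generate a synthetic annotated genome
#'
#' Lays out non-overlapping operons (one transcription unit each) with
#' valid ORFs (start codon, in-frame internal stops only where a
#' selenocysteine is planted, terminal stop), 5'/3' UTRs drawn from the
#' configured samplers, promoters with -10/-35 boxes at canonical offsets
#' upstream of each TSS, terminators, Shine-Dalgarno sites, TF binding
#' sites in inter-TU gaps, regulons / sigmulons / i-modulons as random
#' gene subsets and one COG letter per gene. Every planted quantity is
#' recorded in the returned `truth` list so tests can compare analysis
#' output against the generator's ground truth rather than constants.
#'
#' @param config a [synthetic_config()].
#' @return list with `sequence`, `features` (feature table), `truth`.
#' @export
generate_annotation <- function(config = synthetic_config()) {
  cfg <- config
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  L <- cfg$genome_length
  sequence <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  if (cfg$n_operons == 0L) {
    return(list(sequence = sequence, features = feature_tbl(),
                truth = list(config = cfg, n_genes = 0L)))
  }

  prom_pad <- 45L; term_pad <- 20L; term_len <- 15L
  plans <- purrr::map(seq_len(cfg$n_operons), function(o) {
    ng <- sample_range(cfg$genes_per_operon[1], cfg$genes_per_operon[2])
    glens <- 3L * sample_range(cfg$gene_length_range[1] %/% 3L,
                               cfg$gene_length_range[2] %/% 3L, ng)
    gaps <- if (ng > 1) sample_range(cfg$intergenic_range[1],
                                     cfg$intergenic_range[2], ng - 1L)
            else integer()
    utr5 <- cfg$utr5_sampler(1L); utr3 <- cfg$utr3_sampler(1L)
    tu_len <- utr5 + sum(glens) + sum(gaps) + utr3
    list(ng = ng, glens = glens, gaps = gaps, utr5 = utr5, utr3 = utr3,
         tu_len = tu_len, strand = sample(c("+", "-"), 1L),
         block = prom_pad + tu_len + term_pad)
  })
  blocks <- purrr::map_int(plans, "block")
  need <- sum(blocks) + (cfg$n_operons + 1L) * cfg$min_gap
  if (need > L) {
    abort(sprintf("config infeasible: %d bp of features + gaps exceed the %d bp genome",
                  need, L))
  }
  extra <- stats::rmultinom(1, L - need, rep(1, cfg$n_operons + 1L))[, 1]
  gap_lens <- cfg$min_gap + extra

  seq_chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  paint <- function(s, piece) {
    seq_chars[(s + 1L):(s + nchar(piece))] <<- strsplit(piece, "", fixed = TRUE)[[1]]
  }

  genes <- list(); tus <- list(); operons <- list(); promoters <- list()
  children <- list(); terminators <- list(); sds <- list()
  truth_utr5 <- integer(); truth_utr3 <- integer()
  truth_d10 <- integer(); truth_d35 <- integer(); truth_spacer <- integer()
  sec_pool <- sample(seq_len(cfg$n_operons), min(cfg$n_selenoproteins, cfg$n_operons))
  gene_ctr <- 0L
  cursor <- 0L
  for (o in seq_len(cfg$n_operons)) {
    cursor <- cursor + gap_lens[o]
    pl <- plans[[o]]
    s <- cursor
    fwd <- pl$strand == "+"
    tu_left <- if (fwd) s + prom_pad else s + term_pad
    tu_right <- tu_left + pl$tu_len
    tss <- if (fwd) tu_left else tu_right - 1L
    tu_id <- sprintf("tu%03d", o); op_id <- sprintf("op%03d", o)
    p_id <- sprintf("p%03d", o)

    # gene placement, 5' to 3' along the TU
    gene_ids <- character(pl$ng)
    g_edge <- if (fwd) tu_left + pl$utr5 else tu_right - pl$utr5
    for (g in seq_len(pl$ng)) {
      gene_ctr <- gene_ctr + 1L
      gid <- sprintf("b%04d", gene_ctr)
      gene_ids[g] <- gid
      glen <- pl$glens[g]
      gs <- if (fwd) g_edge else g_edge - glen
      ge <- gs + glen
      orf <- random_orf(glen, sec = o %in% sec_pool && g == 1L)
      paint(gs, if (fwd) orf$seq else revcomp(orf$seq))
      genes[[gid]] <- feature_tbl(
        id = gid, category = "cds", strand = pl$strand,
        intervals = list(iv(gs, ge)),
        attributes = list(list(translation = orf$translation)))
      # Shine-Dalgarno 6 bp, ending 6 bp upstream of the start codon
      sd_iv <- if (fwd) iv(gs - 12L, gs - 6L) else iv(ge + 6L, ge + 12L)
      if (sd_iv$start >= 0 && sd_iv$end <= L) {
        sds[[gid]] <- feature_tbl(id = paste0("sd_", gid),
                                  category = "shine_dalgarno",
                                  strand = pl$strand, intervals = list(sd_iv),
                                  links = list(gid))
      }
      step <- glen + if (g < pl$ng) pl$gaps[g] else 0L
      g_edge <- if (fwd) g_edge + step else g_edge - step
    }
    truth_utr5 <- c(truth_utr5, pl$utr5); truth_utr3 <- c(truth_utr3, pl$utr3)

    tus[[tu_id]] <- feature_tbl(id = tu_id, category = "transcription_unit",
                                strand = pl$strand,
                                intervals = list(iv(tu_left, tu_right)),
                                links = list(gene_ids))
    operons[[op_id]] <- feature_tbl(id = op_id, category = "operon",
                                    strand = pl$strand,
                                    intervals = list(iv(tu_left, tu_right)),
                                    links = list(gene_ids))
    # promoter boxes at canonical offsets with jitter
    j10 <- sample_range(-cfg$promoter_jitter, cfg$promoter_jitter)
    j35 <- sample_range(-cfg$promoter_jitter, cfg$promoter_jitter)
    if (fwd) {
      m10 <- c(tss - 12L + j10, tss - 6L + j10)
      m35 <- c(tss - 35L + j35, tss - 29L + j35)
      prom_iv <- iv(m35[1], tss + 1L)
      spacer <- m10[1] - m35[2]
    } else {
      m10 <- c(tss + 7L - j10, tss + 13L - j10)
      m35 <- c(tss + 30L - j35, tss + 36L - j35)
      prom_iv <- iv(tss, m35[2])
      spacer <- m35[1] - m10[2]
    }
    center <- function(b) (b[1] + b[2]) %/% 2L
    truth_d10 <- c(truth_d10, abs(center(m10) - tss))
    truth_d35 <- c(truth_d35, abs(center(m35) - tss))
    truth_spacer <- c(truth_spacer, spacer)
    promoters[[p_id]] <- feature_tbl(
      id = p_id, category = "promoter", strand = pl$strand,
      intervals = list(prom_iv), links = list(tu_id),
      attributes = list(list(tss = tss, minus10 = m10, minus35 = m35)))
    children[[paste0(p_id, "_tss")]] <- feature_tbl(
      id = paste0(p_id, "_tss"), category = "tss", strand = pl$strand,
      intervals = list(iv(tss, tss + 1L)), links = list(p_id))
    children[[paste0(p_id, "_m10")]] <- feature_tbl(
      id = paste0(p_id, "_m10"), category = "minus10", strand = pl$strand,
      intervals = list(iv(m10[1], m10[2])), links = list(p_id))
    children[[paste0(p_id, "_m35")]] <- feature_tbl(
      id = paste0(p_id, "_m35"), category = "minus35", strand = pl$strand,
      intervals = list(iv(m35[1], m35[2])), links = list(p_id))
    term_iv <- if (fwd) iv(tu_right, tu_right + term_len) else
      iv(tu_left - term_len, tu_left)
    terminators[[op_id]] <- feature_tbl(
      id = sprintf("term%03d", o), category = "terminator",
      strand = pl$strand, intervals = list(term_iv),
      links = list(gene_ids[pl$ng]))
    cursor <- cursor + pl$block
  }
  sequence <- paste(seq_chars, collapse = "")
  gene_tbl <- dplyr::bind_rows(genes)

  # TF binding sites in the inter-operon gaps
  tfbs <- list()
  gap_starts <- cumsum(c(0L, blocks)) + cumsum(c(0L, gap_lens[-length(gap_lens)]))
  gap_bounds <- purrr::map2(gap_starts, gap_lens, function(gs, gl) c(gs, gs + gl))
  tf_ctr <- 0L
  for (gb in gap_bounds) {
    glen <- gb[2] - gb[1]
    if (glen < 20L) next
    n_tf <- rbinom(1L, glen, cfg$tfbs_density)
    for (t in seq_len(n_tf)) {
      tf_ctr <- tf_ctr + 1L
      st <- gb[1] + sample.int(glen - 16L, 1L) - 1L
      tf_name <- sprintf("TF%02d", (tf_ctr %% cfg$n_tfs) + 1L)
      tfbs[[tf_ctr]] <- feature_tbl(
        id = sprintf("tfbs%03d", tf_ctr), category = "tfbs",
        subtype = tf_name, strand = ".",
        intervals = list(iv(st, st + 16L)),
        links = list(sample(gene_tbl$id, 1L)))
    }
  }

  gene_sets <- function(prefix, n) {
    purrr::map(seq_len(n), function(k) {
      members <- gene_tbl$id[runif(nrow(gene_tbl)) < cfg$membership_p]
      if (length(members) == 0) members <- sample(gene_tbl$id, 1L)
      feature_tbl(id = sprintf("%s%02d", prefix, k),
                  category = switch(prefix, Reg = "regulon", Sig = "sigmulon",
                                    iMod = "imodulon"),
                  subtype = sprintf("%s%02d", prefix, k), strand = ".",
                  links = list(members))
    })
  }
  regulons <- gene_sets("Reg", cfg$n_regulons)
  sigmulons <- gene_sets("Sig", cfg$n_sigmulons)
  imodulons <- gene_sets("iMod", cfg$n_imodulons)

  cog_letter <- sample(cfg$cog_letters, nrow(gene_tbl), replace = TRUE)
  cogs <- feature_tbl(
    id = paste0(gene_tbl$id, "_cog_", cog_letter),
    category = "cog", subtype = cog_letter, strand = gene_tbl$strand,
    intervals = gene_tbl$intervals, links = as.list(gene_tbl$id))

  features <- dplyr::bind_rows(c(
    list(gene_tbl), tus, operons, promoters, children, terminators, sds,
    tfbs, regulons, sigmulons, imodulons, list(cogs)))
  validate_features(features, L, circular = TRUE)

  truth <- list(
    config = cfg, n_genes = nrow(gene_tbl),
    gene_ids = gene_tbl$id,
    utr5 = truth_utr5, utr3 = truth_utr3,
    minus10_distances = truth_d10, minus35_distances = truth_d35,
    spacers = truth_spacer,
    cog = setNames(cog_letter, gene_tbl$id),
    regulon_members = setNames(purrr::map(regulons, ~ .x$links[[1]]),
                               purrr::map_chr(regulons, ~ .x$id)),
    sec_genes = gene_tbl$id[grepl("U", purrr::map_chr(gene_tbl$attributes,
                                                      "translation"))],
    tu_coverage_bp = sum(purrr::map_int(tus, ~ .x$intervals[[1]]$end -
                                          .x$intervals[[1]]$start))
  )
  list(sequence = sequence, features = features, truth = truth)
}

#' Generate SNPs with a configurable bit-count bias
#'
#' Draws `n_snps` distinct genomic positions with sampling weights
#' log-linear in the planted biases: positions whose bit count lies below
#' the median get odds multiplied by `odds_ratio_low`, and positions
#' covered by amino-acid tracks named in `aa_enrichment` get odds
#' multiplied by the named factor. `odds_ratio_low = 1` and empty
#' enrichment gives uniform placement.
#'
#' @param bitome a `bitome`.
#' @param n_snps number of SNPs (unique positions).
#' @param odds_ratio_low odds multiplier for below-median bit-count
#'   positions.
#' @param aa_enrichment named numeric, e.g. `c(Thr = 3)`.
#' @param restrict optional integer vector of candidate 0-based positions
#'   (e.g. coding positions only); default all positions.
#' @param seed integer seed.
#' @return list with `snps` (tibble as [read_snp_table()]) and `truth`
#'   (realized per-stratum counts).
#' @export
generate_snps <- function(bitome, n_snps, odds_ratio_low = 1,
                          aa_enrichment = NULL, restrict = NULL, seed = 1L) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  L <- ncol(bitome$matrix)
  cand <- if (is.null(restrict)) seq.int(0L, L - 1L) else as.integer(restrict)
  cc <- column_bit_counts(bitome)[cand + 1L]
  w <- rep(1, length(cand))
  low <- cc < stats::median(cc)
  w[low] <- w[low] * odds_ratio_low
  for (aa in names(aa_enrichment)) {
    sub <- bitome_select_rows(bitome, .data$category == "amino_acid",
                              .data$subtype == aa)
    covered <- Matrix::colSums(sub$matrix)[cand + 1L] > 0
    w[covered] <- w[covered] * aa_enrichment[[aa]]
  }
  if (n_snps == 0L) {
    return(list(snps = tibble(position = integer(), ref = character(),
                              alt = character(), source_id = character()),
                truth = list(n = 0L)))
  }
  pos <- sort(sample(cand, n_snps, prob = w))
  ref <- toupper(substring(bitome$sequence, pos + 1L, pos + 1L))
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
  list(snps = tibble(position = pos, ref = ref, alt = unname(alt),
                     source_id = "ale1"),
       truth = list(n = n_snps, n_low_bit = sum(pos %in% cand[low]),
                    odds_ratio_low = odds_ratio_low,
                    aa_enrichment = aa_enrichment, seed = seed))
}

#' Generate gene labels from planted linear effects
#'
#' Labels each gene 1 with probability
#' `sigmoid(intercept + sum_k effect_k * x_k)` computed on the min/max
#' normalized feature matrix, then flips labels at the configured noise
#' rate. The informative feature names are returned as truth.
#'
#' @param gfm a `gene_feature_matrix`.
#' @param effects named numeric vector of effects, names = feature
#'   (row-key) labels present in the matrix.
#' @param intercept scalar added to the linear predictor.
#' @param noise label flip probability.
#' @param seed integer seed.
#' @return list with `labels` (named integer vector) and `truth`.
#' @export
generate_labels <- function(gfm, effects = numeric(), intercept = 0,
                            noise = 0, seed = 1L) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  xn <- minmax_normalize(gfm$x)
  eta <- rep(intercept, nrow(xn))
  missing <- setdiff(names(effects), colnames(xn))
  if (length(missing)) abort(paste0("unknown feature(s): ", paste(missing, collapse = ", ")))
  for (f in names(effects)) eta <- eta + effects[[f]] * xn[, f]
  p <- plogis(eta)
  labels <- rbinom(length(p), 1L, p)
  flip <- runif(length(p)) < noise
  labels[flip] <- 1L - labels[flip]
  names(labels) <- rownames(gfm$x)
  list(labels = labels,
       truth = list(informative = names(effects), effects = effects,
                    intercept = intercept, noise = noise, seed = seed))
}

#' Write a complete synthetic fixture set to disk
#'
#' Emits `genome.gb` (GenBank flat file with the core features),
#' `regulatory/` (the TSV dialect tables), `cog.tsv`, optional `snps.tsv`
#' and `labels.tsv`, and `truth.json`, so that every parser in the package
#' (and third-party GenBank readers) can consume the fixture.
#'
#' @param ann result of [generate_annotation()].
#' @param dir output directory.
#' @param snps optional SNP tibble.
#' @param labels optional named label vector.
#' @return named vector of written paths, invisibly.
#' @export
write_fixtures <- function(ann, dir, snps = NULL, labels = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.gb"))
  core <- ann$features[ann$features$category %in%
                         c("cds", "pseudogene", "rna_gene", "insertion_element",
                           "repeat_region", "origin"), , drop = FALSE]
  writeLines(write_genbank_string(ann$sequence, core), paths["genome"])
  reg <- ann$features[ann$features$category %in%
                        c("operon", "transcription_unit", "promoter", "minus10",
                          "minus35", "tss", "terminator", "attenuator",
                          "shine_dalgarno", "riboswitch", "tfbs", "regulon",
                          "sigmulon", "imodulon"), , drop = FALSE]
  if (nrow(reg) > 0) {
    paths <- c(paths, write_regulatory_tables(reg, file.path(dir, "regulatory")))
  }
  cog <- ann$features[ann$features$category == "cog", , drop = FALSE]
  if (nrow(cog) > 0) {
    readr::write_tsv(tibble(locus_tag = purrr::map_chr(cog$links, 1),
                            cog = cog$subtype),
                     file.path(dir, "cog.tsv"), progress = FALSE)
    paths["cog"] <- file.path(dir, "cog.tsv")
  }
  if (!is.null(snps)) {
    readr::write_tsv(tibble(position = snps$position + 1L, ref = snps$ref,
                            alt = snps$alt,
                            experiment = snps$source_id %||% "ale1"),
                     file.path(dir, "snps.tsv"), progress = FALSE)
    paths["snps"] <- file.path(dir, "snps.tsv")
  }
  if (!is.null(labels)) {
    readr::write_tsv(tibble(locus_tag = names(labels),
                            label = as.integer(labels)),
                     file.path(dir, "labels.tsv"), progress = FALSE)
    paths["labels"] <- file.path(dir, "labels.tsv")
  }
  truth <- ann$truth
  truth$config <- unclass(truth$config)
  truth$config$utr5_sampler <- NULL # closures do not serialize
  truth$config$utr3_sampler <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  paths["truth"] <- file.path(dir, "truth.json")
  invisible(paths)
}
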