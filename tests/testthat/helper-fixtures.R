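# Shared fixtures, built once per session and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# medium synthetic genome: 12 operons in 30 kb, every feature class present
small_ann <- function() cached("small_ann", {
  generate_annotation(synthetic_config(genome_length = 30000L, n_operons = 12L,
                                       seed = 7L))
})

small_bitome <- function() cached("small_bitome", {
  ann <- small_ann()
  build_bitome(ann$sequence, ann$features, genome_id = "synth30k")
})

# independent position-painting oracle: given the full post-derivation
# feature list, paint a dense logical grid row-by-row with naive loops
# (regulon-like features painted over their linked genes' positions) and
# return the per-column bit counts.
paint_columns_oracle <- function(all_feats, genome_length) {
  genes <- all_feats[all_feats$category %in% c("cds", "pseudogene", "rna_gene"), ]
  keys <- assign_row_keys(all_feats)
  labels <- unique(keys$row_label)
  grid <- matrix(FALSE, nrow = length(labels), ncol = genome_length)
  for (k in seq_len(nrow(all_feats))) {
    r <- match(keys$row_label[k], labels)
    ivs <- all_feats$intervals[[k]]
    if (nrow(ivs) == 0 &&
        all_feats$category[k] %in% c("regulon", "sigmulon", "imodulon")) {
      for (tag in all_feats$links[[k]]) {
        g <- which(genes$id == tag)
        if (length(g) == 0) next
        givs <- genes$intervals[[g[1]]]
        for (q in seq_len(nrow(givs))) {
          for (p in seq(givs$start[q], givs$end[q] - 1L)) grid[r, p + 1L] <- TRUE
        }
      }
      next
    }
    for (q in seq_len(nrow(ivs))) {
      for (p in seq(ivs$start[q], ivs$end[q] - 1L)) grid[r, p + 1L] <- TRUE
    }
  }
  colSums(grid)
}

# every derived track build_bitome would add, for feeding the oracle
with_derived_tracks <- function(sequence, features) {
  cds <- features[features$category == "cds", , drop = FALSE]
  dplyr::bind_rows(
    derive_sequence_tracks(sequence),
    if (nrow(cds) > 0) derive_codon_aa_tracks(cds, sequence),
    if (nrow(cds) > 0) derive_protein_tracks(cds),
    features)
}

# make a plain random gene feature matrix with labeled features
random_gfm <- function(n, p, seed) {
  set.seed(seed)
  x <- matrix(runif(n * p), n, p,
              dimnames = list(sprintf("g%04d", seq_len(n)),
                              sprintf("feat%03d", seq_len(p))))
  as_gene_feature_matrix(x)
}
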