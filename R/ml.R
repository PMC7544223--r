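#' Collapse bitome regions into gene feature vectors
#'
#' For every gene, extracts the bitome sub-matrix over the gene's span and
#' collapses it column-wise into one vector per gene: `collapse = "sum"`
#' gives per-row bit totals, `"mean"` per-row bits per bp. Stacking the
#' vectors gives the genes x features matrix used by the classification
#' harness.
#'
#' @param bitome a `bitome`.
#' @param genes feature table of genes (non-empty intervals required).
#' @param collapse `"sum"` or `"mean"`.
#' @return object of class `gene_feature_matrix`: list with `x` (genes x
#'   features numeric matrix, dimnames = gene ids x row labels),
#'   `feature_keys` (row-key tibble), `labels` (NULL until set),
#'   `collapse`.
#' @export
gene_feature_vectors <- function(bitome, genes, collapse = c("sum", "mean")) {
  collapse <- match.arg(collapse)
  L <- ncol(bitome$matrix)
  lens <- purrr::map_int(genes$intervals, function(ivs) {
    if (nrow(ivs) == 0) abort("zero-length gene")
    sum(ivs$end - ivs$start)
  })
  if (any(lens == 0)) abort("zero-length gene")
  n_iv <- purrr::map_int(genes$intervals, nrow)
  g_idx <- rep.int(seq_len(nrow(genes)), n_iv)
  ivs <- dplyr::bind_rows(genes$intervals)
  runs <- ivs$end - ivs$start
  j <- rep.int(ivs$start, runs) + sequence(runs) - 1L
  gi <- rep.int(g_idx, runs)
  G <- Matrix::sparseMatrix(i = j + 1L, j = gi, dims = c(L, nrow(genes)), x = 1)
  X <- Matrix::t(bitome$matrix %*% G) # genes x features
  X <- as.matrix(X)
  if (collapse == "mean") X <- X / lens
  dimnames(X) <- list(genes$id, bitome$row_keys$row_label)
  structure(list(x = X, feature_keys = bitome$row_keys, labels = NULL,
                 collapse = collapse, normalized = FALSE),
            class = "gene_feature_matrix")
}

#' Wrap a plain matrix as a gene feature matrix
#'
#' For workflows starting from an externally assembled genes x features
#' matrix rather than a bitome: builds minimal row-key metadata from the
#' column names.
#'
#' @param x numeric matrix with gene ids as rownames and feature labels as
#'   colnames.
#' @param labels optional binary label vector.
#' @param collapse collapse mode recorded on the object.
#' @return a `gene_feature_matrix`.
#' @export
as_gene_feature_matrix <- function(x, labels = NULL, collapse = "sum") {
  stopifnot(is.matrix(x), !is.null(colnames(x)), !is.null(rownames(x)))
  out <- structure(list(
    x = x,
    feature_keys = tibble(row = seq_len(ncol(x)),
                          category = sub("[:|].*$", "", colnames(x)),
                          subtype = NA_character_, strand_class = ".",
                          frame = NA_integer_, row_label = colnames(x)),
    labels = NULL, collapse = collapse, normalized = FALSE),
    class = "gene_feature_matrix")
  if (!is.null(labels)) out <- set_labels(out, labels)
  out
}

#' @export
print.gene_feature_matrix <- function(x, ...) {
  cat(sprintf("<gene_feature_matrix> %d genes x %d features (collapse = %s%s%s)\n",
              nrow(x$x), ncol(x$x), x$collapse,
              if (x$normalized) ", min/max normalized" else "",
              if (!is.null(x$labels)) sprintf(", %d/%d labels 1/0",
                                              sum(x$labels == 1), sum(x$labels == 0)) else ""))
  invisible(x)
}

#' @export
tidy.gene_feature_matrix <- function(x, ...) {
  as_tibble(x$x, rownames = "gene_id")
}

#' Label genes by SNP presence
#'
#' Gene label 1 iff at least one SNP position falls within the gene's
#' genomic span.
#'
#' @param genes feature table of genes.
#' @param snps SNP tibble.
#' @return integer vector of labels, named by gene id.
#' @export
label_from_snps <- function(genes, snps) {
  pos <- unique(snps$position)
  setNames(purrr::map_int(genes$intervals, function(ivs) {
    sp <- span_of(ivs)
    as.integer(any(pos >= sp[1] & pos < sp[2]))
  }), genes$id)
}

#' Attach a label vector to a gene feature matrix
#' @param gfm `gene_feature_matrix`.
#' @param labels binary vector, recycled/matched by gene id when named.
#' @return the labelled `gene_feature_matrix`.
#' @export
set_labels <- function(gfm, labels) {
  if (!is.null(names(labels))) labels <- labels[rownames(gfm$x)]
  stopifnot(length(labels) == nrow(gfm$x), all(labels %in% c(0L, 1L)))
  gfm$labels <- as.integer(labels)
  gfm
}

#' Min/max normalize a feature matrix
#'
#' Per-feature (column) rescaling to `(x - min) / (max - min)`; constant
#' columns map to 0. Idempotent.
#'
#' @param x numeric matrix or `gene_feature_matrix`.
#' @return same type as the input.
#' @export
minmax_normalize <- function(x) {
  if (inherits(x, "gene_feature_matrix")) {
    x$x <- minmax_normalize(x$x)
    x$normalized <- TRUE
    return(x)
  }
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  rng <- hi - lo
  out <- sweep(x, 2, lo, "-")
  out <- sweep(out, 2, ifelse(rng == 0, 1, rng), "/")
  out[, rng == 0] <- 0
  out
}

#' @noRd
gfm_subset <- function(gfm, idx) {
  out <- gfm
  out$x <- gfm$x[idx, , drop = FALSE]
  if (!is.null(gfm$labels)) out$labels <- gfm$labels[idx]
  out
}

#' @noRd
derive_seeds <- function(seed, n) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n)
}

#' Stratified lockbox split
#'
#' Holds out `fraction` of the genes, stratified by class (lockbox size
#' per class = `round(fraction * n_class)`), as a final test set never
#' touched during training or model selection. Deterministic under `seed`.
#'
#' @param gfm labelled `gene_feature_matrix`.
#' @param fraction held-out fraction (default 0.20).
#' @param seed integer seed.
#' @return list of `gene_feature_matrix`es: `train`, `lockbox`.
#' @export
lockbox_split <- function(gfm, fraction = 0.20, seed = 1L) {
  y <- gfm$labels
  if (is.null(y)) abort("gene feature matrix has no labels")
  if (any(table(factor(y, levels = c(0, 1))) < 2)) {
    abort("each class needs at least 2 members to split")
  }
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  lock_idx <- unlist(lapply(c(0L, 1L), function(cl) {
    idx <- which(y == cl)
    sample(idx, round(fraction * length(idx)))
  }))
  list(train = gfm_subset(gfm, setdiff(seq_along(y), lock_idx)),
       lockbox = gfm_subset(gfm, sort(lock_idx)))
}

#' Downsample the majority class to balance a training set
#'
#' Randomly subsamples the majority class without replacement to the
#' minority class size; already-balanced inputs pass through unchanged.
#'
#' @param train labelled `gene_feature_matrix`.
#' @param seed integer seed.
#' @return balanced `gene_feature_matrix`.
#' @export
downsample_majority <- function(train, seed = 1L) {
  y <- train$labels
  tab <- table(factor(y, levels = c(0, 1)))
  if (tab[1] == tab[2]) return(train)
  maj <- as.integer(names(which.max(tab)))
  k <- min(tab)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  keep <- sort(c(which(y != maj), sample(which(y == maj), k)))
  gfm_subset(train, keep)
}

#' @noRd
stratified_folds <- function(y, k, seed) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' @noRd
confusion_normalized <- function(truth, pred) {
  cm <- table(factor(truth, levels = c(0, 1)), factor(pred, levels = c(0, 1)))
  sweep(unclass(cm), 1, pmax(rowSums(cm), 1), "/")
}

#' Repeated downsampled cross-validation
#'
#' For each of `n_downsamples` majority-downsampled versions of the
#' training set, runs stratified k-fold cross-validation of the model spec
#' and scores held-out accuracy per fold. Reports the mean and sd over all
#' folds x downsamples, plus the aggregated per-true-class normalized
#' confusion matrix.
#'
#' @param spec a `bitome_model_spec`.
#' @param train labelled `gene_feature_matrix`.
#' @param k folds (default 5).
#' @param n_downsamples downsampled resamples (default 5).
#' @param seed run seed; expanded into per-stage seeds recorded in the
#'   report.
#' @param downsample set `FALSE` to skip balancing (e.g. when the spec
#'   uses class-weighted losses); the resample loop then repeats CV with
#'   different fold seeds only.
#' @return object of class `bitome_eval`.
#' @export
cv_evaluate <- function(spec, train, k = 5L, n_downsamples = 5L, seed = 1L,
                        downsample = TRUE) {
  y <- train$labels
  if (is.null(y)) abort("training set has no labels")
  seeds <- derive_seeds(seed, 2L * n_downsamples)
  runs <- list()
  cm_sum <- matrix(0, 2, 2)
  for (d in seq_len(n_downsamples)) {
    ds <- if (downsample) downsample_majority(train, seeds[d]) else train
    fold <- stratified_folds(ds$labels, k, seeds[n_downsamples + d])
    for (f in seq_len(k)) {
      tr <- gfm_subset(ds, which(fold != f))
      te <- gfm_subset(ds, which(fold == f))
      if (length(unique(tr$labels)) < 2) abort("fold with a single class")
      fit <- spec$fit(tr$x, tr$labels)
      pred <- as.integer(spec$decision(fit, te$x) > 0)
      runs[[length(runs) + 1L]] <- tibble(
        downsample = d, fold = f, n = length(te$labels),
        accuracy = mean(pred == te$labels))
      cm_sum <- cm_sum + confusion_normalized(te$labels, pred)
    }
  }
  runs <- dplyr::bind_rows(runs)
  structure(list(
    runs = runs, mean_accuracy = mean(runs$accuracy),
    sd_accuracy = stats::sd(runs$accuracy),
    confusion = cm_sum / pmax(rowSums(cm_sum), 1e-12),
    spec = spec$name, seeds = seeds, k = k, n_downsamples = n_downsamples
  ), class = "bitome_eval")
}

#' @export
print.bitome_eval <- function(x, ...) {
  cat(sprintf("<bitome_eval> %s: accuracy %.3f +/- %.3f over %d folds\n",
              x$spec, x$mean_accuracy, x$sd_accuracy, nrow(x$runs)))
  invisible(x)
}

#' @export
tidy.bitome_eval <- function(x, ...) x$runs

#' @export
glance.bitome_eval <- function(x, ...) {
  tibble(spec = x$spec, mean_accuracy = x$mean_accuracy,
         sd_accuracy = x$sd_accuracy, n_runs = nrow(x$runs),
         auc = x$auc %||% NA_real_)
}

#' Shuffled-label negative control
#'
#' Permutes the training labels (preserving label counts) and re-runs
#' [cv_evaluate()]; on balanced data the expected accuracy is 0.5
#' (guessing), the floor against which real signal is judged.
#'
#' @inheritParams cv_evaluate
#' @return `bitome_eval` for the shuffled labels.
#' @export
shuffled_label_control <- function(spec, train, k = 5L, n_downsamples = 5L,
                                   seed = 1L, downsample = TRUE) {
  seeds <- derive_seeds(seed, 2L)
  old <- globalenv()$.Random.seed
  set.seed(seeds[1])
  train$labels <- sample(train$labels)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  cv_evaluate(spec, train, k = k, n_downsamples = n_downsamples,
              seed = seeds[2], downsample = downsample)
}

#' Sequence-only baseline
#'
#' Re-runs [cv_evaluate()] with the feature matrix restricted to the
#' nucleobase rows, quantifying how much of the signal is carried by raw
#' sequence composition alone.
#'
#' @inheritParams cv_evaluate
#' @return `bitome_eval` on the restricted features.
#' @export
sequence_only_baseline <- function(spec, train, k = 5L, n_downsamples = 5L,
                                   seed = 1L, downsample = TRUE) {
  keep <- train$feature_keys$category == "nucleobase"
  if (!any(keep)) abort("no nucleobase features present")
  train$x <- train$x[, keep, drop = FALSE]
  train$feature_keys <- train$feature_keys[keep, , drop = FALSE]
  cv_evaluate(spec, train, k = k, n_downsamples = n_downsamples, seed = seed,
              downsample = downsample)
}

#' Train the final linear model on a training set
#'
#' Fits the model spec on the (optionally downsampled) full training set
#' and packages the per-feature coefficients for importance ranking.
#'
#' @param train labelled `gene_feature_matrix`.
#' @param spec a `bitome_model_spec` (default L1 linear SVM, C = 0.1).
#' @param downsample balance the classes first.
#' @param seed seed for the downsampling.
#' @return object of class `bitome_model`: `coefficients` tibble
#'   (`feature`, `coefficient`), `intercept`, `spec`, `converged`.
#' @export
train_final_model <- function(train, spec = model_spec_svm_l1(C = 0.1),
                              downsample = TRUE, seed = 1L) {
  ds <- if (downsample) downsample_majority(train, seed) else train
  fit <- spec$fit(ds$x, ds$labels)
  structure(list(
    coefficients = tibble(feature = colnames(ds$x),
                          coefficient = unname(fit$w)),
    intercept = fit$b, spec = spec$name, converged = isTRUE(fit$converged),
    fit = fit, decision = spec$decision
  ), class = "bitome_model")
}

#' @export
print.bitome_model <- function(x, ...) {
  nz <- sum(x$coefficients$coefficient != 0)
  cat(sprintf("<bitome_model> %s: %d/%d nonzero coefficients, intercept %.4f%s\n",
              x$spec, nz, nrow(x$coefficients), x$intercept,
              if (!x$converged) " (solver did not converge)" else ""))
  invisible(x)
}

#' @export
tidy.bitome_model <- function(x, ...) x$coefficients

#' @export
glance.bitome_model <- function(x, ...) {
  tibble(spec = x$spec, n_features = nrow(x$coefficients),
         n_nonzero = sum(x$coefficients$coefficient != 0),
         intercept = x$intercept, converged = x$converged)
}

#' Evaluate a trained model on the lockbox set
#'
#' Reports overall accuracy, the per-true-class normalized confusion
#' matrix, and the rank-based AUC of the decision values.
#'
#' @param model a `bitome_model`.
#' @param lockbox labelled `gene_feature_matrix` held out by
#'   [lockbox_split()].
#' @return `bitome_eval` with a single run and an `auc` field.
#' @export
evaluate_lockbox <- function(model, lockbox) {
  scores <- model$decision(model$fit, lockbox$x)
  pred <- as.integer(scores > 0)
  y <- lockbox$labels
  auc <- if (length(unique(y)) == 2) {
    r <- rank(scores)
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else NA_real_
  runs <- tibble(downsample = NA_integer_, fold = NA_integer_,
                 n = length(y), accuracy = mean(pred == y))
  structure(list(runs = runs, mean_accuracy = runs$accuracy,
                 sd_accuracy = NA_real_,
                 confusion = confusion_normalized(y, pred),
                 auc = auc, spec = model$spec, seeds = integer(),
                 k = NA_integer_, n_downsamples = NA_integer_),
            class = "bitome_eval")
}

#' Coefficient-based feature importance
#'
#' Nonzero model coefficients ranked by absolute magnitude; the sign is
#' retained (positive coefficients push toward class 1).
#'
#' @param model a `bitome_model`.
#' @return tibble `rank`, `feature`, `coefficient`.
#' @export
feature_importance <- function(model) {
  model$coefficients %>%
    dplyr::filter(.data$coefficient != 0) %>%
    dplyr::arrange(dplyr::desc(abs(.data$coefficient))) %>%
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
}

#' Persist / restore a linear model as JSON
#'
#' Coefficients, intercept and feature names only — no opaque binary
#' formats.
#'
#' @param model a `bitome_model`.
#' @param path JSON file path.
#' @return `path` invisibly (write); a `bitome_model` (read).
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(list(
    spec = model$spec, intercept = model$intercept,
    features = model$coefficients$feature,
    coefficients = model$coefficients$coefficient,
    converged = model$converged), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- list(w = as.numeric(m$coefficients), b = as.numeric(m$intercept),
              converged = isTRUE(m$converged))
  structure(list(
    coefficients = tibble(feature = m$features, coefficient = fit$w),
    intercept = fit$b, spec = m$spec, converged = fit$converged,
    fit = fit, decision = function(fit, x) drop(x %*% fit$w + fit$b)
  ), class = "bitome_model")
}
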