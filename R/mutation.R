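#' SNP density over the positions of a feature-row set
#'
#' Number of SNPs falling at genomic positions where the selected rows
#' carry at least one bit, divided by the number of such positions (SNPs
#' per bp of feature sequence). SNP records at the same position are
#' deduplicated to unique positions by default, since recurrence across
#' experiments is a property of the experiment set, not the position.
#'
#' @param bitome a `bitome`.
#' @param snps SNP tibble from [read_snp_table()] or [generate_snps()].
#' @param ... row-key filter expressions; omit for all rows.
#' @param dedup count unique SNP positions (default) or raw records.
#' @return scalar SNPs/bp, or `NA` if the selected rows cover no position.
#' @export
snp_density <- function(bitome, snps, ..., dedup = TRUE) {
  sub <- if (...length() > 0) bitome_select_rows(bitome, ...) else bitome
  covered <- Matrix::colSums(sub$matrix) > 0
  n_pos <- sum(covered)
  if (n_pos == 0) return(NA_real_)
  pos <- snps$position
  if (dedup) pos <- unique(pos)
  sum(covered[pos + 1L]) / n_pos
}

#' Per-amino-acid SNP mutation frequencies
#'
#' For every amino-acid row subtype, the fraction of its covered genomic
#' positions (all three codon positions of residues of that type) that
#' carry a SNP, alongside the genome-wide baseline frequency
#' (total SNPs / genome length). Amino acids with zero coverage are
#' excluded.
#'
#' @param bitome a `bitome` with amino-acid tracks.
#' @param snps SNP tibble.
#' @param dedup deduplicate SNPs to unique positions first.
#' @return tibble `amino_acid`, `coverage_bp`, `snp_count`, `frequency`;
#'   attribute `baseline` carries the genome-wide frequency.
#' @export
aa_mutation_frequencies <- function(bitome, snps, dedup = TRUE) {
  pos <- snps$position
  if (dedup) pos <- unique(pos)
  L <- ncol(bitome$matrix)
  is_snp <- logical(L)
  is_snp[pos + 1L] <- TRUE
  aa_rows <- bitome$row_keys[bitome$row_keys$category == "amino_acid", , drop = FALSE]
  out <- aa_rows %>%
    dplyr::group_by(amino_acid = .data$subtype) %>%
    dplyr::group_modify(function(d, g) {
      covered <- Matrix::colSums(bitome$matrix[d$row, , drop = FALSE]) > 0
      tibble(coverage_bp = sum(covered), snp_count = sum(is_snp & covered))
    }) %>%
    dplyr::ungroup() %>%
    dplyr::filter(.data$coverage_bp > 0) %>%
    dplyr::mutate(frequency = .data$snp_count / .data$coverage_bp)
  attr(out, "baseline") <- length(pos) / L
  out
}

#' Mann-Whitney U comparison of bit counts at SNP vs all coding positions
#'
#' Tests whether SNPs fall at coding positions with systematically
#' different per-position bit counts than coding positions at large. The
#' population sample is the bit-count distribution over *all* coding
#' positions (size `n`); the second sample is the bit counts at the coding
#' positions carrying a SNP (size `m`). Two-sided; exact permutation
#' enumeration on small instances, tie-corrected normal approximation with
#' continuity correction otherwise (bit counts are small integers with
#' massive ties).
#'
#' @param bitome a `bitome`.
#' @param snps SNP tibble.
#' @param ... row-key filter expressions defining "coding" rows (default
#'   `category == "cds"`).
#' @param dedup deduplicate SNP positions.
#' @return object of class `bitome_rank_test`: list with `statistic_U`
#'   (for the population sample), `p_two_sided`, `n`, `m`, `method`.
#' @export
bitcount_snp_test <- function(bitome, snps, ..., dedup = TRUE) {
  sub <- if (...length() > 0) bitome_select_rows(bitome, ...) else
    bitome_select_rows(bitome, .data$category == "cds")
  coding <- Matrix::colSums(sub$matrix) > 0
  cc <- column_bit_counts(bitome)
  pos <- snps$position
  if (dedup) pos <- unique(pos)
  pos <- pos[coding[pos + 1L]]
  if (length(pos) == 0) abort("no SNPs at coding positions")
  mw_u_test(cc[coding], cc[pos + 1L])
}

#' Two-sided Mann-Whitney U test
#'
#' U is counted for sample `x` against sample `y`
#' (`U = #\{x_i > y_j\} + 0.5 #\{ties\}`). For small instances
#' (`choose(n + m, m) <= max_exact`) the permutation null distribution of U
#' is enumerated exactly over all group assignments of the pooled values,
#' which remains valid under ties; otherwise the tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param x,y numeric samples.
#' @param max_exact enumeration budget (number of assignments).
#' @return `bitome_rank_test` object.
#' @export
mw_u_test <- function(x, y, max_exact = 5e5) {
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) abort("both samples must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  n_assign <- choose(n + m, m)
  if (n_assign <= max_exact) {
    # exact permutation distribution of U over all assignments
    idx <- utils::combn(n + m, n)
    r_all <- r
    U_all <- Matrix::colSums(matrix(r_all[idx], nrow = n)) - n * (n + 1) / 2
    p <- min(1, 2 * min(mean(U_all <= U), mean(U_all >= U)))
    method <- "exact enumeration"
  } else {
    mu <- n * m / 2
    N <- n + m
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n * m / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal approximation, tie-corrected"
  }
  structure(list(statistic_U = U, p_two_sided = p, n = n, m = m,
                 method = method),
            class = "bitome_rank_test")
}

#' @export
print.bitome_rank_test <- function(x, ...) {
  cat(sprintf("Two-sided Mann-Whitney U test (%s)\nU = %.1f, p = %.4g, n = %d, m = %d\n",
              x$method, x$statistic_U, x$p_two_sided, x$n, x$m))
  invisible(x)
}

#' @export
tidy.bitome_rank_test <- function(x, ...) {
  tibble(statistic_U = x$statistic_U, p_value = x$p_two_sided,
         n = x$n, m = x$m, method = x$method)
}

#' @export
glance.bitome_rank_test <- function(x, ...) tidy(x)
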