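test_that("column bit counts match a transpose-then-row-sum oracle", {
  b <- small_bitome()
  cc <- column_bit_counts(b)
  expect_equal(unname(cc), unname(Matrix::rowSums(Matrix::t(b$matrix))))
  expect_equal(unname(column_bit_counts(build_bitome("ACGTAC"))), rep(2, 6))
})

test_that("sequence coverage is a union over rows, not a sum", {
  feats <- feature_tbl(id = c("t1", "t2"), category = "transcription_unit",
                       strand = c("+", "-"),
                       intervals = list(iv(0, 5), iv(3, 8)),
                       links = list("x", "y"))
  b <- build_bitome("ACGTACGTAC", feats, derive = FALSE)
  expect_equal(sequence_coverage(b, category == "transcription_unit",
                                 strand_class == "+"), 0.5)
  expect_equal(sequence_coverage(b, category == "transcription_unit"), 0.8)
  # union coverage <= sum of individual coverages
  both <- sequence_coverage(b, category == "transcription_unit")
  expect_lte(both, 0.5 + 0.5)
})

test_that("bit density obeys its exact identities", {
  b <- small_bitome()
  L <- ncol(b$matrix)
  expect_equal(bit_density(b, 0, L) * L, sum(b$matrix))
  nb <- bitome_select_rows(b, category == "nucleobase")
  expect_equal(bit_density(nb, 100, 900), 2)
  # per-position counting oracle on random intervals
  cc <- column_bit_counts(b)
  set.seed(31)
  for (k in 1:200) {
    s <- sample.int(L - 2L, 1L)
    e <- s + sample.int(min(2000L, L - s), 1L)
    expect_equal(bit_density(b, s, e), sum(cc[(s + 1):e]) / (e - s))
  }
  # length-weighted mean over a partition equals the genome-wide density
  cuts <- sort(c(0L, sample.int(L - 1L, 7L), L))
  dens <- purrr::map_dbl(1:8, ~ bit_density(b, cuts[.x], cuts[.x + 1]))
  lens <- diff(cuts)
  expect_equal(sum(dens * lens) / L, bit_density(b, 0, L))
})

test_that("moving density banding behaves on uniform and peaked matrices", {
  u <- build_bitome(paste(rep("A", 5000), collapse = ""))
  prof <- moving_density(u, window = 500, step = 100)
  expect_true(all(prof$density == 2))
  expect_equal(attr(prof, "sd"), 0)

  # single dense block: peak height at full overlap is block density
  feats <- feature_tbl(id = "t1", category = "transcription_unit", strand = "+",
                       intervals = list(iv(2000, 3000)), links = list("x"))
  p <- build_bitome(paste(rep("A", 10000), collapse = ""), feats, derive = FALSE)
  prof2 <- moving_density(p, window = 1000, step = 100)
  expect_equal(max(prof2$density), 3) # 2 nucleobase + 1 TU
  expect_equal(prof2$density[prof2$start == 2000], 3)
  expect_equal(prof2$density[prof2$start == 6000], 2)

  # window = genome length reduces to the genome-wide density
  whole <- moving_density(p, window = 10000, step = 10000)
  expect_equal(whole$density[1], bit_density(p, 0, 10000))

  # circular full-coverage average at any window equals genome density
  prof3 <- moving_density(p, window = 700, step = 1)
  expect_equal(mean(prof3$density), bit_density(p, 0, 10000))
})

test_that("per-feature densities and their median match a sort oracle", {
  b <- small_bitome()
  ann <- small_ann()
  tus <- ann$features[ann$features$category == "transcription_unit", ]
  fd <- feature_density_distribution(b, tus)
  expect_equal(nrow(fd), nrow(tus))
  ds <- sort(fd$density)
  n <- length(ds)
  med_oracle <- if (n %% 2 == 1) ds[(n + 1) / 2] else mean(ds[n / 2 + 0:1])
  expect_equal(attr(fd, "median"), med_oracle)
  nb <- bitome_select_rows(b, category == "nucleobase")
  expect_true(all(feature_density_distribution(nb, tus)$density == 2))
})

test_that("UTR lengths are strand-aware distances from TU edges", {
  genes <- feature_tbl(id = "g1", category = "cds", strand = "+",
                       intervals = list(iv(20, 80)))
  tu_f <- feature_tbl(id = "t1", category = "transcription_unit", strand = "+",
                      intervals = list(iv(0, 100)), links = list("g1"))
  u <- utr_lengths(tu_f, genes)
  expect_equal(u$length[u$side == "five_prime"], 20)
  expect_equal(u$length[u$side == "three_prime"], 20)

  tu_r <- tu_f; tu_r$strand <- "-"
  ur <- utr_lengths(tu_r, genes)
  expect_equal(ur$length[ur$side == "five_prime"], 20)
  expect_equal(ur$length[ur$side == "three_prime"], 20)

  # asymmetric case distinguishes the sides
  genes2 <- feature_tbl(id = "g1", category = "cds", strand = "-",
                        intervals = list(iv(30, 90)))
  ua <- utr_lengths(tu_r, genes2)
  expect_equal(ua$length[ua$side == "five_prime"], 10)
  expect_equal(ua$length[ua$side == "three_prime"], 30)
})

test_that("synthetic TU set UTRs match coordinate arithmetic and the truth", {
  ann <- small_ann()
  tus <- ann$features[ann$features$category == "transcription_unit", ]
  genes <- ann$features[ann$features$category == "cds", ]
  u <- utr_lengths(tus, genes)
  expect_equal(sort(u$length[u$side == "five_prime"]), sort(ann$truth$utr5))
  expect_equal(sort(u$length[u$side == "three_prime"]), sort(ann$truth$utr3))
})

test_that("promoter geometry uses floor midpoints and end-to-end spacers", {
  p <- feature_tbl(id = "p1", category = "promoter", strand = "+",
                   intervals = list(iv(63, 101)), links = list("t1"),
                   attributes = list(list(tss = 100L, minus10 = c(88L, 94L),
                                          minus35 = c(63L, 69L))))
  g <- promoter_geometry(p)
  expect_equal(g$minus10_distance, 9) # center (88+94)/2 = 91
  expect_equal(g$minus35_distance, 34)
  expect_equal(g$spacer, 19) # 88 - 69
  expect_true(g$minus10_upstream)

  # planted canonical offsets are recovered from the generator truth
  ann <- small_ann()
  proms <- ann$features[ann$features$category == "promoter", ]
  pg <- promoter_geometry(proms)
  expect_equal(sort(pg$minus10_distance), sort(ann$truth$minus10_distances))
  expect_equal(sort(pg$minus35_distance), sort(ann$truth$minus35_distances))
  expect_equal(sort(pg$spacer), sort(ann$truth$spacers))
})

test_that("inter-TU regions complement TU coverage exactly", {
  tus <- feature_tbl(id = c("t1", "t2"), category = "transcription_unit",
                     strand = "+", intervals = list(iv(0, 40), iv(60, 100)),
                     links = list("a", "b"))
  r <- inter_tu_regions(tus, 100)
  expect_equal(r, tibble::tibble(start = 40L, end = 60L))
  full <- feature_tbl(id = "t", category = "transcription_unit", strand = "+",
                      intervals = list(iv(0, 100)), links = list("a"))
  expect_equal(nrow(inter_tu_regions(full, 100)), 0)

  # conservation on random TU sets
  set.seed(9)
  for (k in 1:20) {
    n <- sample(1:6, 1)
    st <- sort(sample.int(180, n))
    ivs <- purrr::map(st, ~ iv(.x, min(200L, .x + sample.int(40, 1))))
    tus_k <- feature_tbl(id = paste0("t", seq_len(n)),
                         category = "transcription_unit", strand = "+",
                         intervals = ivs, links = as.list(rep("a", n)))
    gaps <- inter_tu_regions(tus_k, 200)
    cov <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = purrr::map_int(ivs, ~ .x$start) + 1L,
                       end = purrr::map_int(ivs, ~ .x$end)))))
    expect_equal(sum(gaps$end - gaps$start) + cov, 200)
  }
})
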