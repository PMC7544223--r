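test_that("a single forward CDS sets exactly its positions in its frame row", {
  b <- build_bitome("ACGTACGTAC",
                    feature_tbl(id = "g1", category = "cds", strand = "+",
                                intervals = list(iv(2, 8))),
                    derive = FALSE)
  cds_rows <- b$row_keys[b$row_keys$category == "cds", ]
  expect_equal(nrow(cds_rows), 1)
  expect_equal(cds_rows$frame, 2L) # 2 mod 3
  expect_equal(cds_rows$strand_class, "+")
  bits <- which(b$matrix[cds_rows$row, ] == 1) - 1L
  expect_equal(bits, 2:7)
})

test_that("an empty feature list yields nucleobase rows only, 2 bits per position", {
  b <- build_bitome("ACGTACGTAC")
  expect_equal(unique(b$row_keys$category), "nucleobase")
  expect_equal(nrow(b$row_keys), 8)
  expect_equal(sum(b$matrix), 2 * 10)
  expect_equal(unname(column_bit_counts(b)), rep(2, 10))
})

test_that("total and per-column bits equal the position-painting oracle", {
  # 5 genes / 2 TUs / 1 regulon on a 600 bp genome
  set.seed(5)
  seqn <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
  genes <- feature_tbl(id = sprintf("b%d", 1:5), category = "cds",
                       strand = c("+", "+", "-", "+", "-"),
                       intervals = list(iv(10, 70), iv(80, 140), iv(200, 260),
                                        iv(300, 360), iv(400, 460)))
  feats <- dplyr::bind_rows(
    genes,
    feature_tbl(id = c("tu1", "tu2"), category = "transcription_unit",
                strand = c("+", "-"),
                intervals = list(iv(5, 150), iv(195, 270)),
                links = list(c("b1", "b2"), "b3")),
    feature_tbl(id = "reg1", category = "regulon", subtype = "reg1",
                strand = ".", links = list(c("b1", "b3", "b5"))))
  b <- build_bitome(seqn, feats, derive = TRUE)
  oracle_cc <- paint_columns_oracle(with_derived_tracks(seqn, feats), 600)
  expect_equal(unname(column_bit_counts(b)), unname(oracle_cc))
  expect_equal(sum(b$matrix), sum(oracle_cc))
})

test_that("re-adding a feature leaves the bit count unchanged (binarity)", {
  ann <- small_ann()
  feats <- ann$features
  doubled <- dplyr::bind_rows(feats, feats[feats$category == "cds", ][1:3, ])
  b1 <- build_bitome(ann$sequence, feats, derive = FALSE)
  b2 <- build_bitome(ann$sequence, doubled, derive = FALSE)
  expect_equal(sum(b2$matrix), sum(b1$matrix))
})

test_that("frame rows of non-overlapping CDSs are column-disjoint", {
  b <- small_bitome()
  cds_rows <- b$row_keys[b$row_keys$category == "cds", ]
  cover <- lapply(cds_rows$row, function(r) which(b$matrix[r, ] != 0))
  for (i in seq_along(cover)) for (j in seq_len(i - 1L)) {
    expect_length(intersect(cover[[i]], cover[[j]]), 0)
  }
})

test_that("extract shifts columns and preserves bits", {
  b <- build_bitome("ACGTACGTAC",
                    feature_tbl(id = "g1", category = "cds", strand = "+",
                                intervals = list(iv(2, 8))),
                    derive = FALSE)
  whole <- bitome_extract(b, 0, 10)
  expect_equal(as.matrix(whole$matrix), as.matrix(b$matrix))
  sub <- bitome_extract(b, 2, 8)
  r <- sub$row_keys$row[sub$row_keys$category == "cds"]
  expect_equal(which(sub$matrix[r, ] == 1), 1:6)
  expect_error(bitome_extract(b, 4, 4), "empty")
})

test_that("extract-then-sum equals masked sums on 100 random intervals", {
  b <- small_bitome()
  cc <- column_bit_counts(b)
  set.seed(21)
  L <- ncol(b$matrix)
  for (k in 1:100) {
    s <- sample.int(L - 2L, 1L)
    e <- s + sample.int(min(5000L, L - s), 1L)
    expect_equal(sum(bitome_extract(b, s, e)$matrix), sum(cc[(s + 1):e]))
  }
})

test_that("row selection filters and complementary predicates partition bits", {
  b <- small_bitome()
  all_bits <- sum(b$matrix)
  a <- bitome_select_rows(b, category == "cds")
  z <- bitome_select_rows(b, category != "cds")
  expect_equal(sum(a$matrix) + sum(z$matrix), all_bits)
  ident <- bitome_select_rows(b, TRUE)
  expect_equal(sum(ident$matrix), all_bits)
  expect_warning(bitome_select_rows(build_bitome("ACGT"), category == "cds"),
                 "no rows")
})

test_that("building twice from identical inputs serializes identically", {
  ann <- small_ann()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_bitome(build_bitome(ann$sequence, ann$features), d1)
  write_bitome(build_bitome(ann$sequence, ann$features), d2)
  for (f in c("matrix.mtx", "row_keys.tsv", "header.json", "sequence.txt")) {
    expect_equal(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("serialization round-trips through MatrixMarket + sidecars", {
  b <- small_bitome()
  d <- withr::local_tempdir()
  write_bitome(b, d)
  back <- read_bitome(d)
  expect_equal(as.matrix(back$matrix), as.matrix(b$matrix), ignore_attr = TRUE)
  expect_equal(back$row_keys$row_label, b$row_keys$row_label)
  expect_equal(back$sequence, b$sequence)
  expect_equal(back$circular, b$circular)
})

test_that("BED export reproduces each row's set-bit runs", {
  b <- build_bitome("ACGTACGTAC",
                    feature_tbl(id = "g1", category = "cds", strand = "+",
                                intervals = list(iv(2, 8))),
                    derive = FALSE, genome_id = "mini")
  tf <- withr::local_tempfile(fileext = ".bed")
  bed <- bitome_to_bed(b, tf)
  cds_label <- b$row_keys$row_label[b$row_keys$category == "cds"]
  row <- bed[bed$name == cds_label, ]
  expect_equal(row$start, 2L)
  expect_equal(row$end, 8L)
  expect_true(file.exists(tf))
  # every row's total run length equals its bit count
  lens <- bed %>% dplyr::group_by(name) %>%
    dplyr::summarise(bp = sum(end - start), .groups = "drop")
  rs <- Matrix::rowSums(b$matrix)
  expect_equal(lens$bp[match(names(rs)[rs > 0], lens$name)], unname(rs[rs > 0]))
})

test_that("wrapping intervals on circular genomes paint across the origin", {
  f <- feature_tbl(id = "r1", category = "repeat_region", strand = "+",
                   intervals = list(iv(8, 3)),
                   attributes = list(list(wraps = TRUE)))
  b <- build_bitome("ACGTACGTAC", f, circular = TRUE, derive = FALSE)
  r <- b$row_keys$row[b$row_keys$category == "repeat_region"]
  expect_equal(which(b$matrix[r, ] != 0) - 1L, c(0L, 1L, 2L, 8L, 9L))
  expect_error(build_bitome("ACGTACGTAC", f, circular = FALSE, derive = FALSE),
               "wrapping")
})
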