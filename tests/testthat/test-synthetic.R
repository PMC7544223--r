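test_that("generation is deterministic: same config + seed, byte-identical files", {
  cfg <- synthetic_config(genome_length = 15000L, n_operons = 5L, seed = 19L)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1$sequence, a2$sequence)
  expect_identical(a1$features, a2$features)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixtures(a1, d1)
  write_fixtures(a2, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("zero operons yields a bare random sequence", {
  a <- generate_annotation(synthetic_config(genome_length = 5000L,
                                            n_operons = 0L, seed = 2L))
  expect_equal(nchar(a$sequence), 5000)
  expect_equal(nrow(a$features), 0)
})

test_that("infeasible configs abort before emission", {
  expect_error(generate_annotation(synthetic_config(genome_length = 3000L,
                                                    n_operons = 10L, seed = 1L)),
               "infeasible")
})

test_that("emitted fixtures re-parse through the annotation readers cleanly", {
  ann <- small_ann()
  d <- withr::local_tempdir()
  b <- small_bitome()
  sn <- generate_snps(b, 200, seed = 3)
  labs <- setNames(rep(c(1L, 0L), length.out = ann$truth$n_genes),
                   ann$truth$gene_ids)
  write_fixtures(ann, d, snps = sn$snps, labels = labs)

  expect_no_warning({
    gb <- read_genbank(file.path(d, "genome.gb"))
    genes <- gb$features[gb$features$category == "cds", ]
    files <- list.files(file.path(d, "regulatory"), full.names = TRUE)
    reg <- read_regulatory_tables(
      setNames(as.list(files), sub("\\.tsv$", "", basename(files))), genes)
    cog <- read_cog_table(file.path(d, "cog.tsv"), genes)
    snps <- read_snp_table(file.path(d, "snps.tsv"), gb$genome_length)
    lt <- read_label_table(file.path(d, "labels.tsv"), genes)
  })
  expect_equal(nrow(genes), ann$truth$n_genes)
  expect_equal(snps$position, sn$snps$position)
  expect_equal(sum(lt$label), sum(labs))
  # the regulatory records survive the filters untouched
  expect_setequal(reg$id[reg$category == "transcription_unit"],
                  ann$features$id[ann$features$category == "transcription_unit"])
  expect_equal(sort(cog$subtype), sort(unname(ann$truth$cog)))
})

test_that("every generated ORF is a valid coding sequence", {
  ann <- small_ann()
  cds <- ann$features[ann$features$category == "cds", ]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (k in seq_len(nrow(cds))) {
    ivs <- cds$intervals[[k]]
    chars <- strsplit(ann$sequence, "", fixed = TRUE)[[1]][(ivs$start + 1):ivs$end]
    if (cds$strand[k] == "-") chars <- rev(unname(comp[chars]))
    cods <- apply(matrix(chars, nrow = 3), 2, paste, collapse = "")
    expect_equal(cods[1], "ATG", label = cds$id[k])
    expect_true(cods[length(cods)] %in% c("TAA", "TAG", "TGA"))
    internal <- cods[-c(1, length(cods))]
    internal_stops <- internal %in% c("TAA", "TAG", "TGA")
    if (cds$id[k] %in% ann$truth$sec_genes) {
      expect_equal(sum(internal_stops), 1) # the planted Sec TGA
      expect_equal(internal[internal_stops], "TGA")
    } else {
      expect_false(any(internal_stops), label = cds$id[k])
    }
  }
})

test_that("planted constant UTRs and promoter offsets round-trip", {
  cfg <- synthetic_config(genome_length = 30000L, n_operons = 8L,
                          utr5_sampler = function(n) rep(30L, n),
                          utr3_sampler = function(n) rep(45L, n),
                          promoter_jitter = 0L, seed = 11L)
  ann <- generate_annotation(cfg)
  tus <- ann$features[ann$features$category == "transcription_unit", ]
  genes <- ann$features[ann$features$category == "cds", ]
  u <- utr_lengths(tus, genes)
  expect_true(all(u$length[u$side == "five_prime"] == 30))
  expect_true(all(u$length[u$side == "three_prime"] == 45))
  pg <- promoter_geometry(ann$features[ann$features$category == "promoter", ])
  # canonical boxes without jitter: fixed center distances per strand
  expect_true(all(pg$minus10_distance %in% c(9L, 10L)))
  expect_true(all(pg$minus35_distance %in% c(32L, 33L)))
  expect_true(all(pg$spacer == 17L))
})

test_that("SNP generation respects uniformity, bias strata and emptiness", {
  b <- small_bitome()
  z <- generate_snps(b, 0, seed = 1)
  expect_equal(nrow(z$snps), 0)
  u <- generate_snps(b, 800, odds_ratio_low = 1, seed = 2)
  expect_equal(nrow(u$snps), 800)
  expect_false(any(duplicated(u$snps$position)))
  # ref column matches the genome sequence
  expect_equal(u$snps$ref,
               toupper(substring(b$sequence, u$snps$position + 1,
                                 u$snps$position + 1)))
  expect_true(all(u$snps$alt != u$snps$ref))
  # biased draw puts visibly more SNPs in the low-bit stratum
  bi <- generate_snps(b, 800, odds_ratio_low = 3, seed = 2)
  expect_gt(bi$truth$n_low_bit, u$truth$n_low_bit)
})

test_that("planted label effects behave at the limits", {
  gfm <- random_gfm(400, 12, seed = 9)
  flat <- generate_labels(gfm, effects = numeric(), intercept = 0, seed = 1)
  expect_gt(mean(flat$labels), 0.4)
  expect_lt(mean(flat$labels), 0.6)
  hard <- generate_labels(gfm, effects = c(feat004 = 60), intercept = -30,
                          noise = 0, seed = 2)
  # near-threshold function of the feature
  thresh <- as.integer(gfm$x[, "feat004"] > 0.5)
  expect_gt(mean(hard$labels == thresh), 0.97)
  expect_equal(hard$truth$informative, "feat004")
})
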