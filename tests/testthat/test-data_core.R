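test_that("marker IDs parse, format and round-trip", {
  m <- parse_marker_id("chrXIV:466588_T/G")
  expect_equal(m$chrom, "chrXIV")
  expect_equal(m$pos, 466588L)
  expect_equal(m$allele_by, "T")
  expect_equal(m$allele_rm, "G")
  m2 <- parse_marker_id("chrI:1_A/C")
  expect_equal(m2$pos, 1L)
  ids <- c("chrI:100_A/C", "chrXVI:948010_G/A")
  expect_identical(format_marker_id(parse_marker_id(ids)), ids)
  expect_error(parse_marker_id("chrI;100_A/C"), "malformed")
  expect_error(parse_marker_id("chrI:100_AC"), "malformed")
})

test_that("interval overlap rule is boundary-inclusive, symmetric, reflexive", {
  set.seed(5)
  for (i in 1:200) {
    a <- sort(sample.int(50, 2)); b <- sort(sample.int(50, 2))
    got <- eqtlgrowth:::.int_overlaps(a[1], a[2], b[1], b[2])
    brute <- length(intersect(seq(a[1], a[2]), seq(b[1], b[2]))) > 0
    expect_identical(got, brute)
    expect_identical(got, eqtlgrowth:::.int_overlaps(b[1], b[2], a[1], a[2]))
    expect_true(eqtlgrowth:::.int_overlaps(a[1], a[2], a[1], a[2]))
  }
})

test_that("eQTLs classify as local within the strand-aware window", {
  layout <- genome_layout(c("chrI", "chrII"), c(100000, 100000))
  genes <- data.frame(gene = "g1", chrom = "chrI", cds_start = 5000,
                      cds_end = 6000, strand = "+")
  q <- function(chrom, lo, hi) data.frame(trait = "g1", chrom = chrom,
                                          peak_pos = lo, ci_lo = lo, ci_hi = hi)
  # + strand window is [4000, 6200]
  expect_equal(classify_eqtl(q("chrI", 1, 4200), genes, layout), "local")
  expect_equal(classify_eqtl(q("chrI", 1, 3999), genes, layout), "trans")
  expect_equal(classify_eqtl(q("chrI", 6200, 7000), genes, layout), "local")
  expect_equal(classify_eqtl(q("chrI", 6201, 7000), genes, layout), "trans")
  expect_equal(classify_eqtl(q("chrII", 4000, 6200), genes, layout), "trans")
  # mirroring to the - strand mirrors the asymmetric window to [4800, 7000]
  genes$strand <- "-"
  expect_equal(classify_eqtl(q("chrI", 1, 4800), genes, layout), "local")
  expect_equal(classify_eqtl(q("chrI", 1, 4799), genes, layout), "trans")
  expect_equal(classify_eqtl(q("chrI", 7000, 8000), genes, layout), "local")
  expect_equal(classify_eqtl(q("chrI", 7001, 8000), genes, layout), "trans")
  expect_error(classify_eqtl(q("chrX", 1, 10), genes, layout), "unknown")
})

test_that("trait matrices round-trip through TSV with NA preserved", {
  m <- matrix(c(1.25, NA, -0.5, 2, 3.75, 0.001), nrow = 3,
              dimnames = list(c("s1", "s2", "s3"), c("gA", "gB")))
  tm <- trait_matrix(m, "growth")
  f <- tempfile(fileext = ".tsv")
  write_trait_matrix(tm, f)
  back <- read_trait_matrix(f, "growth")
  expect_equal(unclass(back)[, ], m, tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(is.na(back["s2", "gA"]))
})

test_that("trait matrix reader rejects duplicate IDs and non-numeric cells", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("segregant\tg1", "s1\t1.0", "s1\t2.0"), f)
  expect_error(read_trait_matrix(f), "duplicate")
  writeLines(c("segregant\tg1", "s1\t1.0", "s2\tabc"), f)
  expect_error(read_trait_matrix(f), "non-numeric")
})

test_that("genotype matrices validate, recode and round-trip", {
  X <- random_genotypes(5, 4)
  g <- genotype_matrix(X)
  f <- tempfile(fileext = ".tsv")
  write_genotype_matrix(g, f)
  back <- read_genotype_matrix(f)
  expect_identical(back$geno, g$geno)
  expect_identical(back$markers$pos, g$markers$pos)
  # {0,1} recoding
  X01 <- (X + 1) / 2
  df <- data.frame(segregant = rownames(X01), X01, check.names = FALSE)
  f2 <- tempfile(fileext = ".tsv")
  data.table::fwrite(df, f2, sep = "\t")
  back2 <- read_genotype_matrix(f2, recode = c("0" = -1, "1" = 1))
  expect_identical(back2$geno, g$geno)
  # invalid codings rejected
  Xbad <- X; Xbad[1, 1] <- 0
  expect_error(genotype_matrix(Xbad), "-1")
  Xna <- X; Xna[2, 2] <- NA
  expect_error(genotype_matrix(Xna), "complete")
})

test_that("genotype markers are sorted by chromosome and position", {
  X <- random_genotypes(4, 3)
  colnames(X) <- c("chrI:300_A/C", "chrI:100_A/C", "chrI:200_A/C")
  g <- genotype_matrix(X)
  expect_identical(g$markers$pos, c(100L, 200L, 300L))
  expect_identical(colnames(g$geno), g$markers$id)
})

test_that("QTL tables validate invariants and round-trip", {
  qtl <- data.frame(trait = c("g1", "g2"), chrom = c("chrI", "chrII"),
                    peak_pos = c(500L, 800L), ci_lo = c(100L, 700L),
                    ci_hi = c(900L, 950L), lod = c(12.5, 3.1),
                    effect_r = c(0.3, -0.2))
  f <- tempfile(fileext = ".tsv")
  write_qtl_table(qtl, f)
  expect_equal(read_qtl_table(f), qtl, tolerance = 1e-9, ignore_attr = TRUE)
  bad <- qtl; bad$peak_pos[1] <- 50L
  expect_error(validate_qtl_table(bad), "peak outside")
  bad2 <- qtl; bad2$lod[2] <- -1
  expect_error(validate_qtl_table(bad2), "negative LOD")
})

test_that("hotspot tables require the peak inside the interval", {
  h <- data.frame(hotspot = "hs1", chrom = "chrI", ci_lo = 100, ci_hi = 200,
                  peak_marker = "chrI:150_A/C", n_target_genes = 10)
  f <- tempfile(fileext = ".tsv")
  data.table::fwrite(h, f, sep = "\t")
  expect_equal(read_hotspots(f)$peak_marker, "chrI:150_A/C")
  h$peak_marker <- "chrI:250_A/C"
  data.table::fwrite(h, f, sep = "\t")
  expect_error(read_hotspots(f), "outside")
})

test_that("GMT gene sets parse", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4"), f)
  sets <- read_gmt(f)
  expect_identical(sets$setA, c("g1", "g2", "g3"))
  expect_identical(sets$setB, "g4")
  writeLines("broken\tdesc", f)
  expect_error(read_gmt(f), "without genes")
})
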