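test_that("hard filter enforces strict GATK bounds on present metrics", {
  rec <- function(QD = 10, FS = 1, SOR = 1, MQRankSum = 0,
                  ReadPosRankSum = 0) {
    data.frame(chrom = "A01", pos = 100, ref = "A", alt = "T",
               QD = QD, FS = FS, SOR = SOR, MQRankSum = MQRankSum,
               ReadPosRankSum = ReadPosRankSum)
  }
  # QD below bound with everything else passing -> filtered out
  out <- apply_hard_filter(variant_set(rec(QD = 1.5)))
  expect_identical(nrow(out), 0L)
  expect_identical(attr(out, "n_filtered"), 1L)
  # exactly at every bound -> passes (all inequalities are strict)
  at_bounds <- variant_set(rec(QD = 2.0, FS = 200.0, SOR = 10.0,
                               MQRankSum = -12.5, ReadPosRankSum = -8.0))
  expect_identical(nrow(apply_hard_filter(at_bounds)), 1L)
  # each metric individually triggers
  for (args in list(list(FS = 200.01), list(SOR = 10.01),
                    list(MQRankSum = -12.51), list(ReadPosRankSum = -8.01))) {
    expect_identical(nrow(apply_hard_filter(variant_set(do.call(rec, args)))),
                     0L)
  }
  # absent metrics are not violations
  na_rec <- rec(); na_rec$QD <- NA_real_
  expect_identical(nrow(apply_hard_filter(variant_set(na_rec))), 1L)
  # non-numeric INFO is a parse failure naming the record
  bad <- rec(); bad$QD <- "oops"
  expect_error(variant_set(bad), "oops")
})

test_that("hard filter recovers a planted pass/fail truth exactly", {
  info <- simulate_info_fields(1000, fail_fraction = 0.1, seed = 21)
  df <- data.frame(chrom = "A01", pos = seq_len(1000) * 10, ref = "A",
                   alt = "G", info[, 1:5])
  out <- apply_hard_filter(variant_set(df))
  expect_identical(nrow(out), sum(info$passes))
  expect_setequal(out$pos, df$pos[info$passes])
  # idempotent and never grows
  expect_identical(nrow(apply_hard_filter(out)), nrow(out))
})

test_that("normalization trims, left-aligns, and splits MNPs", {
  # context ACGTAC CTTTT GCA starting at position 1
  genome <- Biostrings::DNAStringSet(c(T01 = "ACGTACCTTTTGCAACGTTTAGCA"))
  norm1 <- normalize_variants(vs_of("T01", 7, "CT", "CAT"), genome)
  expect_identical(norm1$pos, 7L)
  expect_identical(norm1$ref, "C")
  expect_identical(norm1$alt, "CA")
  # SNP already minimal
  snp <- normalize_variants(vs_of("T01", 8, "T", "C"), genome)
  expect_identical(snp$ref, "T")
  expect_identical(snp$alt, "C")
  # ref = alt is rejected outright (at construction)
  expect_error(vs_of("T01", 4, "TAC", "TAC"))
  # REF/genome mismatch is an explicit failure
  expect_error(normalize_variants(vs_of("T01", 7, "G", "A"), genome),
               "mismatch")
  # MNP decomposes into component SNPs
  mnp <- normalize_variants(vs_of("T01", 4, "TAC", "GAT"), genome)
  expect_identical(mnp$pos, c(4L, 6L))
  expect_identical(mnp$ref, c("T", "C"))
  expect_identical(mnp$alt, c("G", "T"))
})

test_that("equivalent indel spellings normalize to one left-aligned key", {
  genome <- Biostrings::DNAStringSet(c(T01 = "ACGTACCTTTTGCAACGTTTAGCA"))
  # one-T deletion in the homopolymer TTTT (positions 8-11)
  spellings <- list(c(7, "CT", "C"), c(8, "TT", "T"), c(9, "TT", "T"),
                    c(10, "TT", "T"), c(7, "CTT", "CT"), c(8, "TTT", "TT"))
  keys <- vapply(spellings, function(s) {
    variant_keys(normalize_variants(
      vs_of("T01", as.integer(s[1]), s[2], s[3]), genome))
  }, character(1))
  expect_identical(unique(keys), "T01:7:CT:C")
  # one-T insertion in the same run
  ins <- list(c(7, "C", "CT"), c(8, "T", "TT"), c(11, "T", "TT"))
  ikeys <- vapply(ins, function(s) {
    variant_keys(normalize_variants(
      vs_of("T01", as.integer(s[1]), s[2], s[3]), genome))
  }, character(1))
  expect_identical(unique(ikeys), "T01:7:C:CT")
  # idempotence on a batch of random planted records
  sim <- tiny_sim()
  pl <- plant_variants(sim$genome, sim$models, n_shared = 80,
                       n_private = c(hybs1 = 40, hybs2 = 0), seed = 13)
  once <- normalize_variants(pl$variants$hybs1, sim$genome)
  twice <- normalize_variants(once, sim$genome)
  expect_identical(variant_keys(once), variant_keys(twice))
})

test_that("private/shared subtraction forms an exact partition", {
  a <- vs_of("A01", c(10, 20, 30), c("A", "C", "G"), c("T", "T", "T"),
             sample = "mut")
  b <- vs_of("A01", 20, "C", "T", sample = "wt")
  priv <- private_variants(a, b)
  expect_identical(priv$pos, c(10L, 30L))
  inter <- shared_variants(a, b)
  expect_identical(inter$pos, 20L)
  # partition: private + intersection = mutant, disjoint
  expect_setequal(c(variant_keys(priv), variant_keys(inter)),
                  variant_keys(a))
  expect_length(intersect(variant_keys(priv), variant_keys(inter)), 0)
  # identity and disjoint cases
  expect_identical(nrow(private_variants(a, a)), 0L)
  expect_identical(nrow(shared_variants(a, vs_of("A01", 99, "A", "T"))), 0L)
  # refusing to mix genomes
  c1 <- vs_of("A01", 10, "A", "T", genome_id = "g1")
  c2 <- vs_of("A01", 10, "A", "T", genome_id = "g2")
  expect_error(private_variants(c1, c2), "different genomes")
})

test_that("variant sets survive a VCF write/read round trip", {
  sim <- tiny_sim()
  pl <- plant_variants(sim$genome, sim$models, n_shared = 40,
                       n_private = c(hybs1 = 20, hybs2 = 0), seed = 17,
                       fail_fraction = 0.2)
  vs <- pl$variants$hybs1
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vs, path, genome = sim$genome)
  back <- read_vcf_variants(path, sample = "hybs1", genome_id = "synthetic")
  expect_identical(variant_keys(back), variant_keys(vs))
  expect_equal(back$QD, vs$QD, tolerance = 1e-4)
  expect_equal(back$ReadPosRankSum, vs$ReadPosRankSum, tolerance = 1e-4)
  # filtering decisions identical after the round trip
  expect_identical(variant_keys(apply_hard_filter(back)),
                   variant_keys(apply_hard_filter(vs)))
})

test_that("multi-allelic VCF rows split into biallelic records", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "A01\t100\t.\tA\tT,G\t.\t.\tQD=10",
               "A01\t200\t.\tCTT\tC,CT\t.\t.\t."), path)
  vs <- read_vcf_variants(path)
  expect_identical(nrow(vs), 4L)
  expect_setequal(variant_keys(vs),
                  c("A01:100:A:T", "A01:100:A:G",
                    "A01:200:CTT:C", "A01:200:CTT:CT"))
  expect_identical(vs$QD[vs$pos == 100], c(10, 10))
})
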