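test_that("simulated genomes satisfy the gene-model construction invariants", {
  sim <- simulate_genome(1, 100e3, 10, seed = 1)
  expect_length(sim$models, 10)
  spans <- t(vapply(sim$models, function(m) c(m$tx_start, m$tx_end),
                    integer(2)))
  spans <- spans[order(spans[, 1]), ]
  expect_true(all(spans[-1, 1] > spans[-nrow(spans), 2]))  # non-overlapping
  for (m in sim$models) {
    expect_identical(mutcand:::iv_width(m$cds) %% 3L, 0L)
    s <- cds_sequence(m, sim$genome)
    expect_identical(substr(s, 1, 3), "ATG")
    expect_true(substr(s, nchar(s) - 2, nchar(s)) %in% c("TAA", "TAG", "TGA"))
    aa <- suppressWarnings(as.character(
      Biostrings::translate(Biostrings::DNAString(s))))
    expect_false(grepl("[*]", substr(aa, 1, nchar(aa) - 1)))
    # canonical GT..AG intron ends on the transcript strand
    intr <- mutcand:::model_introns(m)
    if (!is.null(intr)) {
      for (i in seq_len(nrow(intr))) {
        is <- mutcand:::get_seq(sim$genome, m$chrom, intr[i, "start"],
                                intr[i, "end"])
        if (m$strand == "-") is <- mutcand:::revcomp(is)
        expect_identical(substr(is, 1, 2), "GT")
        expect_identical(substr(is, nchar(is) - 1, nchar(is)), "AG")
      }
    }
  }
})

test_that("genome simulation is deterministic and uses both strands", {
  d1 <- withr::local_tempdir()
  s1 <- simulate_genome(2, 60e3, 12, seed = 1)
  s2 <- simulate_genome(2, 60e3, 12, seed = 1)
  write_genome_fasta(s1$genome, file.path(d1, "a.fa"))
  write_genome_fasta(s2$genome, file.path(d1, "b.fa"))
  expect_identical(readLines(file.path(d1, "a.fa")),
                   readLines(file.path(d1, "b.fa")))
  write_gff3(s1$models, file.path(d1, "a.gff3"))
  write_gff3(s2$models, file.path(d1, "b.gff3"))
  expect_identical(readLines(file.path(d1, "a.gff3")),
                   readLines(file.path(d1, "b.gff3")))
  big <- simulate_genome(2, 200e3, 40, seed = 7)
  strands <- vapply(big$models, `[[`, character(1), "strand")
  expect_true(all(c("+", "-") %in% strands))
  expect_error(simulate_genome(1, 50e3, 100, seed = 1), "pack")
})

test_that("GFF3 written by the generator round-trips to identical models", {
  sim <- tiny_sim()
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sim$models, path)
  back <- read_gff3_models(path)
  expect_setequal(names(back), names(sim$models))
  for (id in names(sim$models)) {
    a <- sim$models[[id]]; b <- back[[id]]
    expect_identical(a$strand, b$strand)
    expect_identical(unname(a$exons), unname(b$exons))
    expect_identical(unname(a$cds), unname(b$cds))
  }
})

test_that("planted variant trios match the genome and the declared truth", {
  sim <- tiny_sim()
  pl <- plant_variants(sim$genome, sim$models, n_shared = 60,
                       n_private = c(hybs1 = 25, hybs2 = 35),
                       planted_effects = data.frame(
                         sample = c("hybs1", "hybs2"),
                         gene = c("gene0003", "gene0005"),
                         category = c("frameshift", "stop_gained")),
                       seed = 3)
  # REF consistency: every emitted record matches the FASTA
  for (vs in pl$variants) {
    for (i in seq_len(nrow(vs))) {
      expect_identical(
        mutcand:::get_seq(sim$genome, vs$chrom[i], vs$pos[i],
                          vs$pos[i] + nchar(vs$ref[i]) - 1L),
        vs$ref[i])
    }
  }
  # shared variants appear in all three samples
  kw <- variant_keys(pl$variants$WT)
  expect_true(all(kw %in% variant_keys(pl$variants$hybs1)))
  expect_true(all(kw %in% variant_keys(pl$variants$hybs2)))
  # the planted frameshift is a 1-bp insertion inside the gene's CDS
  fs_key <- setdiff(variant_keys(pl$variants$hybs1),
                    c(kw, pl$truth$planted_private_variants$hybs1))
  expect_length(fs_key, 0)  # truth enumerates all private records
  g3 <- sim$models[[match("gene0003",
                          vapply(sim$models, `[[`, character(1), "gene_id"))]]
  vs1 <- pl$variants$hybs1
  in_cds <- vapply(seq_len(nrow(vs1)), function(i) {
    mutcand:::iv_contains(g3$cds, vs1$pos[i])
  }, logical(1))
  fs <- vs1[in_cds & vs1$vclass == "INDEL", ]
  expect_identical(nrow(fs), 1L)
  expect_identical(nchar(fs$ref), 1L)
  expect_identical(nchar(fs$alt), 2L)
  # the planted stop gain yields a premature stop on re-translation
  g5 <- sim$models[[match("gene0005",
                          vapply(sim$models, `[[`, character(1), "gene_id"))]]
  vs2 <- pl$variants$hybs2
  in_cds5 <- vapply(seq_len(nrow(vs2)), function(i) {
    mutcand:::iv_contains(g5$cds, vs2$pos[i])
  }, logical(1))
  sg <- vs2[in_cds5 & vs2$vclass == "SNP", ]
  expect_identical(nrow(sg), 1L)
  want <- oracle_consequence(as.character(sim$genome[[g5$chrom]]), sg$pos,
                             sg$ref, sg$alt, g5$cds, g5$strand)
  expect_identical(want, "stop_gained")
})

test_that("degenerate planting gives three identical variant sets", {
  sim <- tiny_sim()
  pl <- plant_variants(sim$genome, sim$models, n_shared = 30,
                       n_private = c(hybs1 = 0, hybs2 = 0), seed = 5)
  expect_identical(variant_keys(pl$variants$WT),
                   variant_keys(pl$variants$hybs1))
  expect_identical(variant_keys(pl$variants$WT),
                   variant_keys(pl$variants$hybs2))
  pl2 <- plant_variants(sim$genome, sim$models, n_shared = 30,
                        n_private = c(hybs1 = 0, hybs2 = 0), seed = 5)
  expect_identical(pl$variants$WT$pos, pl2$variants$WT$pos)
  expect_error(
    plant_variants(sim$genome, sim$models, n_shared = 5,
                   n_private = c(hybs1 = 0),
                   planted_effects = data.frame(sample = "hybs1",
                                                gene = "gene0001",
                                                category = "nonsense_x"),
                   seed = 1),
    "category")
})

test_that("depth simulation honours planted deletions and noise settings", {
  lens <- c(A01 = 1e6)
  t0 <- simulate_depth(lens, mean_depth = 30, window = 1e5, noise_cv = 0)
  expect_true(all(t0$depth == 30))
  del <- data.frame(chrom = "A01", start = 200001, end = 400000,
                    copy_ratio = 0.5)
  t1 <- simulate_depth(lens, 30, 1e5, deletions = del, noise_cv = 0)
  expect_equal(t1$depth[t1$start >= 200001 & t1$end <= 400000],
               c(15, 15))
  expect_true(all(t1$depth[t1$end < 200001 | t1$start > 400000] == 30))
  a <- simulate_depth(lens, 30, 1e5, noise_cv = 0.1, seed = 4)
  b <- simulate_depth(lens, 30, 1e5, noise_cv = 0.1, seed = 4)
  expect_identical(a$depth, b$depth)
  expect_error(simulate_depth(lens, 30, 2e6), "larger")
  expect_error(
    simulate_depth(lens, 30, 1e5,
                   deletions = data.frame(chrom = "A01", start = 9e5,
                                          end = 1.2e6, copy_ratio = 0)),
    "bounds")
})

test_that("count simulation plants fold changes and respects library sizes", {
  genes <- paste0("g", 1:1000)
  lens <- stats::setNames(rep(1000L, 1000), genes)
  # no DE: group mean ratios track library-size ratios
  cm <- simulate_counts(genes, de_spec = NULL, dispersion = 0.05,
                        lib_sizes = rep(c(1, 1.5, 0.7), each = 3),
                        conditions = c("WT", "m1", "m2"), seed = 2,
                        gene_lengths = lens)
  grp_mean <- vapply(c("WT", "m1", "m2"), function(cond) {
    mean(cm$counts[, cm$samples$condition == cond])
  }, numeric(1))
  expect_equal(unname(grp_mean / grp_mean[1]), c(1, 1.5, 0.7),
               tolerance = 0.05)
  # planted +2 recovers empirical fold change near 4 in both mutants
  fc1 <- fc2 <- numeric(200)
  for (r in 1:200) {
    cmr <- simulate_counts(paste0("g", 1:5),
                           de_spec = data.frame(gene = "g1",
                                                condition = c("m1", "m2"),
                                                log2fc = 2),
                           dispersion = 0.05, seed = 1000 + r,
                           conditions = c("WT", "m1", "m2"),
                           baseline = stats::setNames(rep(500, 5), paste0("g", 1:5)),
                           gene_lengths = stats::setNames(rep(1000L, 5), paste0("g", 1:5)))
    wt <- mean(cmr$counts["g1", cmr$samples$condition == "WT"])
    fc1[r] <- mean(cmr$counts["g1", cmr$samples$condition == "m1"]) / wt
    fc2[r] <- mean(cmr$counts["g1", cmr$samples$condition == "m2"]) / wt
  }
  expect_equal(mean(fc1), 4, tolerance = 0.1)
  expect_equal(mean(fc2), 4, tolerance = 0.1)
  # dispersion 0 reduces to Poisson: variance ~ mean across many draws
  cmp <- simulate_counts(paste0("g", 1:2000), dispersion = 0,
                         conditions = "c1", n_reps = 2, seed = 9,
                         baseline = stats::setNames(rep(100, 2000),
                                                    paste0("g", 1:2000)),
                         gene_lengths = stats::setNames(rep(1000L, 2000),
                                                        paste0("g", 1:2000)))
  expect_equal(stats::var(as.numeric(cmp$counts)), 100, tolerance = 0.1)
  # counts TSV round-trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(cm, path)
  back <- read_counts_tsv(path)
  expect_identical(back$counts, cm$counts)
  expect_identical(back$samples$condition, cm$samples$condition)
})
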