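test_that("element classification follows coordinates and precedence", {
  hm <- hand_model()
  lens <- mutcand:::chrom_lengths(hm$genome)
  lab <- function(pos) {
    classify_element(data.frame(chrom = "A01", pos = pos),
                     list(hm$model), lens)
  }
  expect_identical(lab(3150), "exon")       # CDS
  expect_identical(lab(3050), "utr5")
  expect_identical(lab(3650), "utr3")
  expect_identical(lab(3350), "intron")
  expect_identical(lab(2500), "promoter")   # 500 bp upstream of TSS, 2 kb span
  expect_identical(lab(4000), "terminator")
  expect_identical(lab(500), "intergenic")  # beyond the 2 kb flank
  expect_identical(lab(10000), "intergenic")
  expect_error(lab(60001), "beyond")
  # vectorized call gives exactly one label per site
  many <- lab(c(3150, 3050, 500, 3350))
  expect_identical(many, c("exon", "utr5", "intergenic", "intron"))
})

test_that("splice-site calls are definitional and strand-aware", {
  hm <- hand_model()
  cons <- function(pos, ref, alt) {
    classify_consequence(data.frame(chrom = "A01", pos = pos, ref = ref,
                                    alt = alt), hm$model, hm$genome)
  }
  g <- function(p) mutcand:::get_seq(hm$genome, "A01", p, p)
  # plus strand: intron 3251-3500, donor = first 2 bp, acceptor = last 2
  expect_identical(cons(3251, g(3251), "C")$consequence, "splice_donor")
  expect_identical(cons(3252, g(3252), "C")$consequence, "splice_donor")
  expect_identical(cons(3499, g(3499), "C")$consequence, "splice_acceptor")
  expect_identical(cons(3500, g(3500), "C")$consequence, "splice_acceptor")
  expect_identical(cons(3300, g(3300), ifelse(g(3300) == "A", "C", "A"))$consequence,
                   "none")
  # minus strand: donor sits at the genomic *end* of the intron
  sim <- tiny_sim()
  minus <- Filter(function(m) m$strand == "-" &&
                    !is.null(mutcand:::model_introns(m)), sim$models)[[1]]
  intr <- mutcand:::model_introns(minus)
  p_don <- intr[1, "end"]
  p_acc <- intr[1, "start"]
  gm <- function(p) mutcand:::get_seq(sim$genome, minus$chrom, p, p)
  res_don <- classify_consequence(
    data.frame(chrom = minus$chrom, pos = p_don, ref = gm(p_don),
               alt = setdiff(c("A", "C", "G", "T"), gm(p_don))[1]),
    minus, sim$genome)
  res_acc <- classify_consequence(
    data.frame(chrom = minus$chrom, pos = p_acc, ref = gm(p_acc),
               alt = setdiff(c("A", "C", "G", "T"), gm(p_acc))[1]),
    minus, sim$genome)
  expect_identical(res_don$consequence, "splice_donor")
  expect_identical(res_acc$consequence, "splice_acceptor")
})

test_that("CDS consequence calls match closed-form codon arithmetic", {
  hm <- hand_model()
  m <- hm$model
  cons <- function(pos, ref, alt) {
    classify_consequence(data.frame(chrom = "A01", pos = pos, ref = ref,
                                    alt = alt), m, hm$genome)$consequence
  }
  g <- function(p) mutcand:::get_seq(hm$genome, "A01", p, p)
  # start codon ATG at 3101-3103
  expect_identical(cons(3101, "A", "G"), "start_lost")
  expect_identical(cons(3103, "G", "T"), "start_lost")
  # terminal stop TAA at 3600-3602: destroying it loses the stop,
  # swapping it for another stop is silent
  expect_identical(mutcand:::get_seq(hm$genome, "A01", 3600, 3602), "TAA")
  expect_identical(cons(3601, "A", "C"), "stop_lost")   # TAA -> TCA
  expect_identical(cons(3602, "A", "G"), "synonymous")  # TAA -> TAG
  # frameshift and in-frame indels
  expect_identical(cons(3150, g(3150), paste0(g(3150), "A")), "frameshift")
  expect_identical(cons(3150, g(3150), paste0(g(3150), "ACG")), "none")
  # candidate-report calls: a C|CA insertion is a frameshift; a T>C SNP that
  # changes the amino acid is reported as the amino-acid-change class
  cds_pos <- mutcand:::cds_genomic_positions(m)
  chrom_seq <- as.character(hm$genome[["A01"]])
  t_pos <- cds_pos[vapply(cds_pos, function(p) g(p) == "T", logical(1))]
  t_missense <- Filter(function(p) {
    oracle_consequence(chrom_seq, p, "T", "C", m$cds, "+") == "missense"
  }, t_pos[t_pos > 3103 & t_pos < 3600])
  expect_true(length(t_missense) > 0)
  expect_identical(cons(t_missense[1], "T", "C"), "missense")
  c_pos <- cds_pos[vapply(cds_pos, function(p) g(p) == "C", logical(1))]
  c_in <- c_pos[c_pos > 3103 & c_pos < 3599 &
                  vapply(c_pos, function(p) mutcand:::iv_contains(m$cds, p + 1L),
                         logical(1))]
  expect_identical(cons(c_in[1], "C", "CA"), "frameshift")
})

test_that("consequence calls are invariant under genome reverse-complement", {
  sim <- tiny_sim()
  lens <- mutcand:::chrom_lengths(sim$genome)
  flipped_genome <- Biostrings::reverseComplement(sim$genome)
  names(flipped_genome) <- names(sim$genome)
  flip_model <- function(m) {
    L <- lens[[m$chrom]]
    fl <- function(iv) {
      if (is.null(iv)) return(NULL)
      cbind(start = L - iv[, "end"] + 1L, end = L - iv[, "start"] + 1L)
    }
    transcript_model(m$gene_id, m$tx_id, m$chrom,
                     strand = if (m$strand == "+") "-" else "+",
                     exons = fl(m$exons), cds = fl(m$cds),
                     utr5 = fl(m$utr5), utr3 = fl(m$utr3))
  }
  set.seed(31)
  for (rep in 1:60) {
    m <- sim$models[[sample(length(sim$models), 1)]]
    cds_pos <- mutcand:::cds_genomic_positions(m)
    p <- sample(cds_pos, 1)
    ref <- mutcand:::get_seq(sim$genome, m$chrom, p, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    orig <- classify_consequence(
      data.frame(chrom = m$chrom, pos = p, ref = ref, alt = alt),
      m, sim$genome)$consequence
    L <- lens[[m$chrom]]
    mirr <- classify_consequence(
      data.frame(chrom = m$chrom, pos = L - p + 1L,
                 ref = mutcand:::comp_base(ref),
                 alt = mutcand:::comp_base(alt)),
      flip_model(m), flipped_genome)$consequence
    expect_identical(mirr, orig)
  }
})

test_that("gene-level large-effect aggregation and Venn partition work", {
  eff <- data.frame(
    chrom = "A01", pos = c(10, 20, 30, 40), ref = "A",
    alt = c("T", "AT", "T", "T"),
    vclass = c("SNP", "INDEL", "SNP", "SNP"),
    gene_id = c("g1", "g2", "g3", NA),
    tx_id = c("g1.1", "g2.1", "g3.1", NA),
    element = c("exon", "exon", "exon", "intergenic"),
    consequence = c("stop_gained", "frameshift", "synonymous", "none"),
    is_large_effect = c(TRUE, TRUE, FALSE, FALSE))
  leg <- large_effect_genes(eff)
  expect_identical(leg$snp, "g1")
  expect_identical(leg$indel, "g2")
  expect_identical(leg$all, c("g1", "g2"))
  expect_length(large_effect_genes(
    eff[eff$consequence == "synonymous", ])$all, 0)
  v <- shared_gene_venn(c("a", "b", "c"), c("b", "c", "d"))
  expect_identical(unname(v$counts), c(1L, 1L, 2L))
  expect_identical(v$shared, c("b", "c"))
  v2 <- shared_gene_venn(c("a", "b"), c("a", "b"))
  expect_identical(unname(v2$counts), c(0L, 0L, 2L))
})

test_that("element labels tile the genome: one summary label per variant", {
  sim <- tiny_sim()
  pl <- plant_variants(sim$genome, sim$models, n_shared = 100,
                       n_private = c(hybs1 = 50, hybs2 = 0), seed = 19)
  vs <- pl$variants$hybs1
  labels <- classify_element(vs, sim$models,
                             mutcand:::chrom_lengths(sim$genome))
  expect_length(labels, nrow(vs))
  expect_true(all(labels %in% c("exon", "utr5", "utr3", "intron", "promoter",
                                "terminator", "intergenic")))
  tab <- effect_count_table(annotate_effects(vs, sim$models, sim$genome))
  expect_identical(sum(tab[1:7, ]), nrow(vs))
})
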