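test_that("depth filtering removes strictly-below-threshold sites, keeps boundaries", {
  s <- methyl_sites(chrom = c("chr1", "chr1", "chrX", "chrX"),
                    pos = c(10, 20, 30, 40), strand = c("+", "-", "+", "-"),
                    coverage = c(29, 30, 15, 14))
  th <- depth_thresholds(30, 15)
  out <- filter_by_depth(s, th, sex_chroms = "chrX")
  expect_equal(out$pos, c(20L, 30L))           # 29 < 30 goes, 15 boundary kept
  expect_equal(filter_by_depth(s, depth_thresholds(0, 0), "chrX")$pos,
               sort(s$pos))                    # (0,0) is the identity
  # idempotence across random fixtures
  for (seed in 1:5) {
    set.seed(seed)
    r <- methyl_sites("chr1", sample(1e5, 200), sample(c("+", "-"), 200, TRUE),
                      rpois(200, 30))
    once <- filter_by_depth(r, th, "chrX")
    expect_identical(filter_by_depth(once, th, "chrX"), once)
  }
})

test_that("genome density divides sites by strand-adenine count", {
  g <- Biostrings::DNAStringSet(c(chr1 = strrep("AT", 500)))  # 1000 adenines
  s <- methyl_sites(c("chr1", "chr1"), c(1, 3), c("+", "+"), c(40, 40))
  expect_equal(genome_density(s, g), 0.002)
  expect_equal(genome_density(s[0, ], g), 0)
  expect_error(genome_density(s, Biostrings::DNAStringSet(c(chr1 = "GGCC"))),
               "adenine")
  # brute-force per-base scan on a synthetic genome
  sim <- simulate_truth(tiny_params(3))
  st <- sim$samples$sample_a$sites
  sm <- methyl_sites(st$chrom, st$pos, st$strand, st$coverage)
  chars <- lapply(names(sim$genome), function(ch)
    strsplit(as.character(sim$genome[[ch]]), "")[[1]])
  nA <- sum(vapply(chars, function(x) sum(x %in% c("A", "T")), 0L))
  expect_equal(genome_density(sm, sim$genome), nrow(sm) / nA)
})

test_that("per-chromosome densities weight-average to the genome density", {
  sim <- simulate_truth(tiny_params(4))
  st <- sim$samples$sample_a$sites
  sm <- methyl_sites(st$chrom, st$pos, st$strand, st$coverage)
  dens <- per_chromosome_density(sm, sim$genome)
  lf <- Biostrings::letterFrequency(sim$genome, c("A", "T"))
  w <- rowSums(lf)
  expect_equal(sum(dens * w) / sum(w), genome_density(sm, sim$genome))
  only1 <- sm[sm$chrom == "chr1", ]
  d1 <- per_chromosome_density(only1, sim$genome)
  expect_true(all(d1[names(d1) != "chr1"] == 0))
})

test_that("gene methylation counts same-strand sites only", {
  gm <- toy_gm()
  genome <- toy_genome()
  s <- methyl_sites(c("chr1", "chr1"), c(50, 60), c("+", "-"), c(40, 40))
  res <- gene_methylation(gm, s, genome)
  expect_equal(res$n_6mA[res$gene_id == "gplus"], 1L)    # only the + site
  expect_equal(res$n_6mA[res$gene_id == "gminus"], 0L)
  expect_true(res$methylated[res$gene_id == "gplus"])
})

test_that("per-gene counts and adenine denominators match a per-base scan", {
  for (seed in c(5, 6)) {
    sim <- simulate_truth(tiny_params(seed))
    st <- sim$samples$sample_a$sites
    sm <- methyl_sites(st$chrom, st$pos, st$strand, st$coverage)
    res <- gene_methylation(sim$gene_models, sm, sim$genome)
    g <- sim$gene_models$genes
    expect_equal(res$n_6mA, oracle_sites_per_gene(g, sm))
    expect_equal(res$n_A, oracle_gene_nA(g, sim$genome))
    expect_equal(res$density, res$n_6mA / res$n_A)
    expect_equal(res$methylated, res$n_6mA > 0)
    expect_true(all(res$n_6mA <= res$n_A))
  }
})

test_that("a gene with zero coding-strand adenines gets density 0 and a flag", {
  gm <- gene_models(data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                               start = 1, end = 8))
  genome <- Biostrings::DNAStringSet(c(chr1 = "GGCCGGCCTT"))
  expect_warning(res <- gene_methylation(gm, methyl_sites(character(),
                                                          integer(),
                                                          character(),
                                                          integer()),
                                         genome),
                 "zero coding-strand adenines")
  expect_equal(res$density, 0)
  expect_true(res$zero_adenine)
})

test_that("on-gene methyloci summary counts sites once and requires sites", {
  gm <- toy_gm()
  s <- methyl_sites(rep("chr1", 3), c(50, 250, 390), c("+", "-", "+"),
                    rep(40, 3))
  sm <- methyloci_on_gene_summary(s, gm)
  expect_equal(sm$n_total, 3L)
  expect_equal(sm$n_on_gene, 2L)                 # 390 is intergenic
  expect_equal(sm$pct_on_gene, round(100 * 2 / 3, 2))
  expect_equal(sm$n_methylated_genes, 2L)
  expect_error(methyloci_on_gene_summary(s[0, ], gm), "no 6mA sites")
  # all-intergenic
  far <- methyl_sites("chr1", 399, "+", 40)
  expect_equal(methyloci_on_gene_summary(far, gm)$pct_on_gene, 0)
})

test_that("shared-gene summary handles identical and disjoint sets", {
  ident <- shared_gene_summary(list(a = c("g1", "g2"), b = c("g1", "g2")))
  expect_equal(unname(ident$pct_all), c(100, 100))
  expect_equal(ident$pairwise$n, 2L)
  disj <- shared_gene_summary(list(a = c("g1"), b = c("g2"), c = c("g3")))
  expect_equal(disj$n_all, 0L)
  expect_true(all(disj$pairwise$n == 0))
  empt <- shared_gene_summary(list(a = character(), b = c("g1", "g2")))
  expect_true(is.na(empt$pct_all[["a"]]))
})

test_that("consistent sites equal a brute-force keyed intersection", {
  a <- methyl_sites("chr1", c(1, 5, 9), c("+", "-", "+"), c(40, 50, 60))
  expect_equal(consistent_sites(a, a)[, c("chrom", "pos", "strand")],
               a[, c("chrom", "pos", "strand")])
  b <- methyl_sites("chr1", c(100, 200), c("+", "-"), c(1, 2))
  expect_equal(nrow(consistent_sites(a, b)), 0)
  for (seed in 1:5) {
    set.seed(seed)
    mk <- function() methyl_sites("chr1", sample(500, 200),
                                  sample(c("+", "-"), 200, TRUE),
                                  rpois(200, 40))
    x <- mk(); y <- mk()
    got <- consistent_sites(x, y)
    keep <- oracle_intersect_keys(paste(x$chrom, x$pos, x$strand),
                                  paste(y$chrom, y$pos, y$strand))
    expect_equal(nrow(got), sum(keep))
    expect_setequal(paste(got$chrom, got$pos, got$strand),
                    paste(x$chrom, x$pos, x$strand)[keep])
    # coverage is the pairwise minimum
    ky <- paste(y$chrom, y$pos, y$strand)
    for (i in seq_len(nrow(got)))
      expect_equal(got$coverage[i],
                   min(x$coverage[paste(x$chrom, x$pos, x$strand) ==
                                    paste(got$chrom, got$pos, got$strand)[i]],
                       y$coverage[ky == paste(got$chrom, got$pos,
                                              got$strand)[i]]))
  }
})

test_that("density correlation behaves like the textbook formula", {
  a <- c(chr1 = .1, chr2 = .3, chr3 = .2, chrX = .4)
  expect_equal(density_correlation(a, 2 * a), 1)
  expect_equal(density_correlation(a, -a), -1)
  expect_equal(density_correlation(a, a), 1)
  set.seed(11)
  b <- a + rnorm(4, 0, 0.05)
  expect_equal(density_correlation(a, b), oracle_pearson(a, b[names(a)]))
  expect_warning(r <- density_correlation(a, c(chr1 = 1, chr2 = 1, chr3 = 1,
                                               chrX = 1)),
                 "zero variance")
  expect_true(is.na(r))
  expect_error(density_correlation(a[1:2], a[1:2]), "3 shared")
})

test_that("motif contexts are strand-normalised with the adenine centred", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "GGAGGTATTCC"))
  plus <- methyl_sites("chr1", 3, "+", 40)         # A at pos 3
  ctx <- export_motif_contexts(plus, genome, flank = 2)
  expect_equal(as.character(ctx[[1]]), "GGAGG")   # centre base is the A
  minus <- methyl_sites("chr1", 8, "-", 40)        # T at pos 8 -> A on minus
  ctx2 <- export_motif_contexts(minus, genome, flank = 2)
  expect_equal(as.character(Biostrings::subseq(ctx2[[1]], 3, 3)), "A")
  expect_equal(as.character(ctx2[[1]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString("TATTC"))))
  edge <- methyl_sites("chr1", 1, "+", 40)
  expect_warning(e <- export_motif_contexts(edge, genome, flank = 2),
                 "contig end")
  expect_length(e, 0)
})

test_that("planted motif contexts are recovered around generator sites", {
  sim <- simulate_truth(tiny_params(8, p_motif = 0.8))
  st <- sim$samples$sample_a$sites
  planted <- st[!is.na(st$motif), ]
  len <- stats::setNames(Biostrings::width(sim$genome), names(sim$genome))
  planted <- planted[planted$pos - 6 >= 1 &
                       planted$pos + 6 <= len[planted$chrom], ]
  expect_gt(nrow(planted), 0)
  sm <- methyl_sites(planted$chrom, planted$pos, planted$strand,
                     planted$coverage)
  ctx <- export_motif_contexts(sm, sim$genome, flank = 6)
  centre <- as.character(Biostrings::subseq(ctx, 7, 7))
  expect_true(all(centre == "A"))
  downstream <- unname(as.character(Biostrings::subseq(ctx, 7, 11)))
  expect_equal(downstream, planted$motif)
})
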