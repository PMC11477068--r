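mk_vars <- function(chrom, pos, ref, alt, gt = "0/1", depth = 40,
                    source = "DNA") {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             genotype = rep_len(gt, length(pos)),
             depth = rep_len(as.integer(depth), length(pos)),
             source = source)
}

test_that("dbSNP screening keeps listed positions, passes through without a list", {
  v <- mk_vars("chr1", c(100, 200), c("A", "C"), c("G", "T"))
  db <- data.frame(chrom = "chr1", pos = 100L)
  expect_equal(filter_dna_variants(v, db)$pos, 100L)
  expect_message(out <- filter_dna_variants(v, NULL), "passed through")
  expect_equal(out, v)
  for (seed in 1:3) {          # brute-force membership check
    set.seed(seed)
    r <- mk_vars("chr1", sample(1e4, 300), "A", "G")
    db <- data.frame(chrom = "chr1", pos = sample(1e4, 500))
    expect_equal(filter_dna_variants(r, db)$pos,
                 r$pos[r$pos %in% db$pos])
  }
})

test_that("RNA depth screening is strict (>30X) and drops missing depth", {
  v <- mk_vars("chr1", c(1, 2, 3), "A", "G", depth = c(31, 30, 29))
  expect_equal(filter_rna_variants(v)$pos, 1L)
  v$depth[2] <- NA
  expect_warning(out <- filter_rna_variants(v), "without depth")
  expect_equal(out$pos, 1L)
  v2 <- mk_vars("chr1", c(1, 2), "A", "G", depth = c(1, 5))
  expect_equal(nrow(filter_rna_variants(v2, min_depth = 0)), 2)
})

test_that("region labels follow UTR > exon > intron precedence", {
  gm <- toy_gm()
  # pos 15: inside gplus UTR5 (11..20) which also lies in exon 11..40
  # pos 30: exon only; pos 50: intron; pos 399: intergenic
  x <- data.frame(chrom = "chr1", pos = c(15L, 30L, 50L, 399L))
  ann <- annotate_regions(x, gm)
  lab <- ann$region[match(1:4, ann$row)]
  expect_equal(lab, c("UTR", "exon", "intron", "intergenic"))
  expect_true(is.na(ann$gene_id[ann$row == 4]))
})

test_that("region labelling matches a brute-force per-base scan", {
  for (seed in c(9, 10)) {
    sim <- simulate_truth(tiny_params(seed))
    gm <- sim$gene_models
    dv <- sim$samples$sample_a$dna_variants
    ann <- annotate_regions(dv, gm)
    genic <- ann[!is.na(ann$gene_id), ]
    for (k in sample(nrow(genic), min(nrow(genic), 150)))
      expect_equal(genic$region[k],
                   oracle_region_label(gm, genic$gene_id[k], genic$pos[k]))
    # fractions over variants sum to one
    dist <- region_distribution(dv, gm)
    expect_equal(sum(dist$fraction), 1)
  }
})

test_that("gene variation ratios divide counts by gene length", {
  gm <- gene_models(data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                               start = 1, end = 3000))
  v <- mk_vars("chr1", c(10, 20, 30), c("A", "T", "C"), c("G", "C", "G"))
  gv <- gene_variation(gm, v)
  expect_equal(gv$n_var, 3L)
  expect_equal(gv$variation_ratio, 0.001)
  expect_equal(gv$n_AT, 2L)
  expect_equal(gv$n_CG, 1L)
  gv0 <- gene_variation(gm, v[0, ])
  expect_equal(gv0$n_var, 0L)                       # gene still emitted
  expect_equal(gv0$variation_ratio, 0)
})

test_that("A/T vs C/G partition is conserved on synthetic fixtures", {
  sim <- simulate_truth(tiny_params(11))
  st <- sim$samples$sample_a$sites
  sm <- methyl_sites(st$chrom, st$pos, st$strand, st$coverage)
  gv <- gene_variation(sim$gene_models, sim$samples$sample_a$dna_variants,
                       sites = sm)
  expect_true(all(gv$n_AT + gv$n_CG == gv$n_var))
  expect_true(all(gv$n_methylated_var <= gv$n_AT))
})

test_that("methylated variation requires positional and base concordance", {
  sites <- methyl_sites(c("chr1", "chr1", "chr1"), c(10, 20, 30),
                        c("+", "-", "+"), rep(40, 3))
  v <- mk_vars("chr1", c(10, 20, 30, 40), c("A", "T", "C", "A"),
               c("G", "C", "G", "G"))
  out <- suppressMessages(methylated_variation(v, sites))
  expect_equal(out$methylated, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(attr(out, "log")$n_inconsistent, 1L)
  # bare positional overlap by flag
  out2 <- suppressMessages(methylated_variation(v, sites, require_base = FALSE))
  expect_equal(out2$methylated, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("A-mutated ratios classify adenines by modification status", {
  # gene 1..40 on +, genome with known adenines
  seqstr <- paste(rep("ACGT", 10), collapse = "")   # 10 adenines at 1,5,9,...
  genome <- Biostrings::DNAStringSet(c(chr1 = seqstr))
  gm <- gene_models(data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                               start = 1, end = 40))
  sites <- methyl_sites("chr1", c(1, 5), c("+", "+"), c(40, 40))
  v <- mk_vars("chr1", c(1, 9, 13), c("A", "A", "A"), c("G", "G", "G"))
  r <- suppressMessages(a_mutated_ratio(gm, sites, v, genome))
  expect_equal(r$n_modified_A, 2L)
  expect_equal(r$n_modified_mut, 1L)                 # variant at pos 1
  expect_equal(r$n_unmodified_A, 8L)
  expect_equal(r$n_unmodified_mut, 2L)               # pos 9 and 13
  expect_equal(r$ratio_modified, 0.5)
  expect_equal(r$ratio_unmodified, 0.25)
  # no 6mA in gene: modified ratio undefined, unmodified computed
  r2 <- suppressMessages(
    a_mutated_ratio(gm, methyl_sites(character(), integer(), character(),
                                     integer()), v, genome))
  expect_true(is.na(r2$ratio_modified))
  expect_equal(r2$ratio_unmodified, 3 / 10)
})

test_that("group comparison matches the textbook Student formula", {
  expect_equal(group_ratio_comparison(c(1, 1, 1), c(1, 1, 1))$p_value, 1)
  set.seed(3)
  a <- rnorm(40); b <- rnorm(35, 0.2)
  got <- group_ratio_comparison(a, b)
  want <- oracle_student_t(a, b)
  expect_equal(got$statistic, want$t)
  expect_equal(got$df, want$df)
  expect_equal(got$p_value, want$p)
  big <- group_ratio_comparison(rnorm(2000), rnorm(2000) + 1)
  expect_lt(big$p_value, 1e-10)
})

test_that("unmethylated genes carry higher variation ratios at the study rates", {
  sim <- simulate_truth(sim_params(seed = 21, n_genes = 800))
  st <- sim$samples$sample_a$sites
  sm <- methyl_sites(st$chrom, st$pos, st$strand, st$coverage)
  sm <- filter_by_depth(sm, sim$params$thresholds, sim$params$sex_chroms)
  gmeth <- gene_methylation(sim$gene_models, sm, sim$genome)
  gv <- gene_variation(sim$gene_models, sim$samples$sample_a$dna_variants)
  cmp <- group_ratio_comparison(gv$variation_ratio[!gmeth$methylated],
                                gv$variation_ratio[gmeth$methylated],
                                names = c("unmethylated", "methylated"))
  expect_gt(cmp$means[1], cmp$means[2])
  expect_lt(cmp$p_value, 0.01)
})

test_that("region-level ratios use per-region lengths", {
  gm <- toy_gm()
  reg <- gene_regions(gm)
  v <- mk_vars("chr1", c(30, 50), c("A", "C"), c("G", "T"))  # exon, intron
  rv <- region_gene_variation(gm, v)
  exon_len <- sum(reg$end[reg$region == "exon" & reg$gene_id == "gplus"] -
                    reg$start[reg$region == "exon" & reg$gene_id == "gplus"] + 1)
  got <- rv[rv$gene_id == "gplus" & rv$region == "exon", ]
  expect_equal(got$n_var, 1L)
  expect_equal(got$variation_ratio, 1 / exon_len)
})
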