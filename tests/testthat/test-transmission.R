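test_that("the 2x3 genotype grid yields exactly the six transmit types", {
  grid <- expand.grid(dna = c("0/1", "1/1"), rna = c("0/0", "0/1", "1/1"),
                      stringsAsFactors = FALSE)
  got <- classify_transmit(grid$dna, grid$rna)
  expect_setequal(got, transmit_types())
  expect_length(unique(got), 6)
  expect_equal(classify_transmit("0/1", "0/1"), "0/1_0/1")
  expect_equal(classify_transmit("1/1", "1/1"), "1/1_1/1")
  expect_error(classify_transmit("0/0", "0/1"), "0/1 or 1/1")
  expect_error(classify_transmit("0/1", "2/2"))
})

mk_v <- function(pos, ref, alt, gt, depth = 40, source = "DNA")
  data.frame(chrom = "chr1", pos = as.integer(pos), ref = ref, alt = alt,
             genotype = gt, depth = as.integer(depth), source = source)

test_that("DNA/RNA join applies the three rules and the allele check", {
  dna <- mk_v(c(10, 20, 30, 40), "A", "G", c("0/1", "0/1", "0/1", "0/1"))
  rna <- rbind(mk_v(10, "A", "G", "1/1", source = "RNA"),
               mk_v(40, "A", "T", "0/1", source = "RNA"),     # discordant alt
               mk_v(99, "C", "T", "0/1", source = "RNA"))     # RNA-only
  cov <- data.frame(chrom = "chr1", start = c(20L, 30L), end = c(20L, 30L),
                    depth = c(40L, 10L))
  jr <- join_dna_rna(dna, rna, cov)
  expect_equal(jr$records$pos, c(10L, 20L))
  expect_equal(jr$records$transmit_type, c("0/1_1/1", "0/1_0/0"))
  expect_equal(jr$log$n_allele_discordant, 1L)     # pos 40
  expect_equal(jr$log$n_insufficient_rna, 1L)      # pos 30, depth 10
  expect_equal(jr$rna_only$pos, 99L)
  # accounting: nothing silently lost
  expect_equal(jr$log$n_classified + jr$log$n_allele_discordant +
                 jr$log$n_insufficient_rna, nrow(dna))
})

test_that("join accounting holds on synthetic fixtures", {
  for (seed in c(13, 14)) {
    sim <- simulate_truth(tiny_params(seed))
    s <- sim$samples$sample_a
    dna <- filter_dna_variants(
      s$dna_variants[, c("chrom", "pos", "ref", "alt", "genotype", "depth")],
      sim$dbsnp)
    jr <- join_dna_rna(dna, s$rna_variants, s$rna_coverage)
    expect_equal(jr$log$n_classified + jr$log$n_allele_discordant +
                   jr$log$n_insufficient_rna, nrow(dna))
    expect_equal(jr$log$n_rna_only, nrow(jr$rna_only))
    expect_true(all(jr$records$transmit_type %in% transmit_types()))
  }
})

test_that("consistent transmissions use the strict transmission-event key", {
  a <- data.frame(chrom = "chr1", pos = c(1L, 2L), ref = "A", alt = "G",
                  dna_gt = "0/1", rna_gt = c("0/1", "1/1"),
                  transmit_type = c("0/1_0/1", "0/1_1/1"))
  expect_equal(consistent_transmissions(a, a), a)
  b <- a
  b$rna_gt[2] <- "0/0"; b$transmit_type[2] <- "0/1_0/0"
  expect_equal(consistent_transmissions(a, b)$pos, 1L)   # type mismatch at 2
  expect_equal(consistent_transmissions(a, b, key = "position")$pos, c(1L, 2L))
  # brute-force keyed intersection on random fixtures
  for (seed in 1:5) {
    set.seed(seed)
    mk <- function() {
      d <- data.frame(chrom = "chr1", pos = sample(200, 80), ref = "A",
                      alt = "G", dna_gt = sample(c("0/1", "1/1"), 80, TRUE),
                      rna_gt = sample(c("0/0", "0/1", "1/1"), 80, TRUE))
      d$transmit_type <- classify_transmit(d$dna_gt, d$rna_gt)
      d
    }
    x <- mk(); y <- mk()
    got <- consistent_transmissions(x, y)
    keep <- oracle_intersect_keys(
      paste(x$chrom, x$pos, x$ref, x$alt, x$transmit_type),
      paste(y$chrom, y$pos, y$ref, y$alt, y$transmit_type))
    expect_setequal(paste(got$chrom, got$pos, got$transmit_type),
                    paste(x$chrom, x$pos, x$transmit_type)[keep])
  }
})

test_that("per-gene transmit counts match direct tallies and conserve totals", {
  gm <- gene_models(data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                               strand = c("+", "-"),
                               start = c(1L, 101L), end = c(100L, 200L)))
  recs <- data.frame(chrom = "chr1", pos = c(10L, 20L, 150L, 250L),
                     transmit_type = c("0/1_0/1", "0/1_0/1", "1/1_1/1",
                                       "0/1_0/0"))
  tc <- gene_transmit_counts(recs, gm)
  expect_equal(tc$x01_01[tc$gene_id == "g1"], 2L)
  expect_equal(tc$x11_11[tc$gene_id == "g2"], 1L)
  expect_equal(sum(as.matrix(tc[, -1])), 3L)       # pos 250 is intergenic
  # genes with no records still emit all-zero rows
  expect_equal(nrow(tc), 2)
  # brute-force oracle on a synthetic fixture
  sim <- simulate_truth(tiny_params(15))
  tv <- sim$samples$sample_a$transmissions
  tv <- tv[tv$assessable, ]
  got <- gene_transmit_counts(tv, sim$gene_models)
  want <- oracle_transmit_counts(tv, sim$gene_models$genes)
  expect_equal(unname(as.matrix(got[, -1])), unname(want))
})

test_that("empirical transmit frequencies recover the planted matrices", {
  p <- sim_params(seed = 77, n_genes = 1200,
                  dna_ratio_meth = 0.004, dna_ratio_unmeth = 0.004)
  sim <- simulate_truth(p)
  tv <- sim$samples$sample_a$transmissions
  cls <- sim$genes$methylated_sample_a[match(tv$gene_id, sim$genes$gene_id)]
  for (m in c(TRUE, FALSE)) for (gt in c("0/1", "1/1")) {
    sub <- tv[cls == m & tv$genotype == gt, ]
    n <- nrow(sub)
    expect_gt(n, 200)
    tm <- if (m) p$t_meth else p$t_unmeth
    for (r in c("0/0", "0/1", "1/1")) {
      phat <- mean(sub$rna_gt == r)
      p0 <- tm[gt, r]
      expect_lt(abs(phat - p0), 2.58 * sqrt(p0 * (1 - p0) / n) + 1e-9,
                label = sprintf("meth=%s %s->%s", m, gt, r))
    }
  }
})
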