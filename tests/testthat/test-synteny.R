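test_that("longest-isoform extraction sums CDS length and applies the tie rule", {
  gff <- write_toy_gff3(c(
    "chrI\tsrc\tgene\t100\t5000\t.\t+\t.\tID=g1",
    "chrI\tsrc\tmRNA\t100\t5000\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chrI\tsrc\tCDS\t100\t999\t.\t+\t0\tID=c1;Parent=g1.t1",
    "chrI\tsrc\tmRNA\t100\t5000\t.\t+\t.\tID=g1.t2;Parent=g1",
    "chrI\tsrc\tCDS\t100\t699\t.\t+\t0\tID=c2;Parent=g1.t2",
    "chrI\tsrc\tCDS\t900\t1499\t.\t+\t0\tID=c3;Parent=g1.t2",
    "chrI\tsrc\tgene\t8000\t9000\t.\t-\t.\tID=g2",
    "chrI\tsrc\tmRNA\t8000\t9000\t.\t-\t.\tID=g2.t2;Parent=g2",
    "chrI\tsrc\tCDS\t8000\t8499\t.\t-\t0\tID=c4;Parent=g2.t2",
    "chrI\tsrc\tmRNA\t8000\t9000\t.\t-\t.\tID=g2.t1;Parent=g2",
    "chrI\tsrc\tCDS\t8000\t8499\t.\t-\t0\tID=c5;Parent=g2.t1",
    "chrI\tsrc\tgene\t12000\t12500\t.\t+\t.\tID=g3",
    "chrI\tsrc\tmRNA\t12000\t12500\t.\t+\t.\tID=g3.t1;Parent=g3"))
  recs <- extract_longest_isoforms(gff)
  # g1: 900 vs 600+600 -> t2 wins; g2: exact tie -> lexicographic t1; g3: no CDS
  expect_identical(recs$representative_isoform_id[recs$gene_id == "g1"], "g1.t2")
  expect_identical(recs$cds_length[recs$gene_id == "g1"], 1200L)
  expect_identical(recs$representative_isoform_id[recs$gene_id == "g2"], "g2.t1")
  expect_false("g3" %in% recs$gene_id)

  # orphan mRNA becomes its own gene, with a warning
  gff2 <- write_toy_gff3(c(
    "chrI\tsrc\tmRNA\t100\t900\t.\t+\t.\tID=orphan.t1",
    "chrI\tsrc\tCDS\t100\t399\t.\t+\t0\tID=c1;Parent=orphan.t1"))
  expect_warning(recs2 <- extract_longest_isoforms(gff2), "own gene")
  expect_identical(recs2$gene_id, "orphan.t1")
})

test_that("single-copy ortholog ranking keeps 1:1 groups and orders by position", {
  genes_a <- data.frame(gene_id = c("a1", "a2", "a3"), chrom = "chrI",
                        start_bp = c(5e6, 1e6, 9e6), end_bp = c(5e6, 1e6, 9e6) + 100,
                        strand = "+")
  genes_a$gene_id <- c("a1", "a2", "a3")
  genes_b <- data.frame(gene_id = c("b1", "b2", "b3", "b4", "b5"), chrom = "chrI",
                        start_bp = c(1, 2, 3, 4, 5) * 1e6,
                        end_bp = c(1, 2, 3, 4, 5) * 1e6 + 100,
                        strand = "+")
  og <- data.frame(orthogroup_id = c("OG1", "OG2", "OG3", "OG4"),
                   A = c("a1", "a2", "a3", "a4"),
                   B = c("b1", "b2", "b3", "b4, b5"))
  genes_a <- rbind(genes_a, data.frame(gene_id = "a4", chrom = "chrI",
                                       start_bp = 99e6, end_bp = 99e6 + 100,
                                       strand = "+"))
  rk <- rank_single_copy_orthologs(og, list(A = genes_a, B = genes_b))
  expect_false("OG4" %in% rk$orthogroup_id)  # two B genes -> dropped
  a <- rk[rk$species == "A", ]
  # retained genes at 5 / 1 / 9 Mb get ranks 2 / 1 / 3
  expect_identical(a$rank[match(c("a1", "a2", "a3"), a$gene_id)], c(2, 1, 3))

  og_bad <- data.frame(orthogroup_id = "OGX", A = "a9", B = "b1")
  expect_error(rank_single_copy_orthologs(og_bad, list(A = genes_a, B = genes_b)),
               "a9")
})

test_that("collinearity scoring matches brute-force enumeration on the spec toys", {
  # 10-gene chromosome, target order 1 2 3 6 5 4 7 8 9 10
  mk_genes <- function(sp, order_ids) {
    data.frame(gene_id = paste0(sp, order_ids), chrom = "chrI",
               start_bp = seq_along(order_ids) * 1e4,
               end_bp = seq_along(order_ids) * 1e4 + 100, strand = "+")
  }
  og <- data.frame(orthogroup_id = sprintf("OG%02d", 1:10),
                   A = paste0("A", 1:10), B = paste0("B", 1:10))
  genes_a <- mk_genes("A", 1:10)
  genes_b <- mk_genes("B", c(1, 2, 3, 6, 5, 4, 7, 8, 9, 10))
  rk <- rank_single_copy_orthologs(og, list(A = genes_a, B = genes_b))
  prof <- score_collinearity(rk, "A", "B")
  bad <- prof$pairs[!prof$pairs$collinear, ]
  expect_identical(sort(bad$left_gene), c("A3", "A6"))  # pairs (3,4) and (6,7)
  expect_equal(prof$genome_pct_collinear, 100 * 7 / 9)
  expect_identical(sort(prof$blocks$gene_count), c(3L, 3L, 4L))
  # independent enumeration agrees
  oracle <- enumerate_noncollinear(list(chrI = paste0("OG", sprintf("%02d", 1:10))),
                                   list(chrI = sprintf("OG%02d", c(1, 2, 3, 6, 5, 4, 7, 8, 9, 10))))
  expect_identical(sum(!prof$pairs$collinear), oracle$noncollinear)

  # identity -> 100% collinear, one block spanning all genes
  rk_id <- rank_single_copy_orthologs(og, list(A = genes_a, B = mk_genes("B", 1:10)))
  p_id <- score_collinearity(rk_id, "A", "B")
  expect_equal(p_id$genome_pct_collinear, 100)
  expect_identical(p_id$blocks$gene_count, 10L)

  # whole-chromosome reversal stays 100% collinear (orientation-agnostic)
  rk_rev <- rank_single_copy_orthologs(og, list(A = genes_a, B = mk_genes("B", 10:1)))
  expect_equal(score_collinearity(rk_rev, "A", "B")$genome_pct_collinear, 100)
})

test_that("m disjoint internal inversions give exactly 2m noncollinear pairs", {
  for (seed in c(2, 9, 17)) {
    m <- sample(3:8, 1)
    sim <- simulate_rearranged_genomes(3, 50, n_inversions = m,
                                       n_translocations = 0, seed = seed)
    rk <- rank_single_copy_orthologs(sim$orthogroups, sim$genes)
    prof <- score_collinearity(rk, "A", "B")
    expect_identical(sum(!prof$pairs$collinear), 2L * m)
    # brute-force enumeration agrees
    oracle <- enumerate_noncollinear(
      gene_orders(sim$genes$A, sim$orthogroups, "A"),
      gene_orders(sim$genes$B, sim$orthogroups, "B"))
    expect_identical(oracle$noncollinear, 2L * m)
  }
})

test_that("a single-gene translocation breaks between 1 and 3 neighbor pairs", {
  for (seed in c(3, 8, 21, 30)) {
    sim <- simulate_rearranged_genomes(3, 30, n_inversions = 0,
                                       n_translocations = 1, seed = seed)
    rk <- rank_single_copy_orthologs(sim$orthogroups, sim$genes)
    for (ref in c("A", "B")) {
      prof <- score_collinearity(rk, ref, setdiff(c("A", "B"), ref))
      nbad <- sum(!prof$pairs$collinear)
      expect_gte(nbad, 1L)
      expect_lte(nbad, 3L)
    }
  }
})

test_that("block gene counts and window proportions recompose the pair totals", {
  sim <- simulate_rearranged_genomes(4, 60, n_inversions = 6,
                                     n_translocations = 2, seed = 12)
  rk <- rank_single_copy_orthologs(sim$orthogroups, sim$genes)
  prof <- score_collinearity(rk, "A", "B", window_bp = 100000)
  for (ch in unique(prof$pairs$chrom)) {
    n_coll <- sum(prof$pairs$collinear[prof$pairs$chrom == ch])
    blk <- prof$blocks[prof$blocks$chrom == ch, ]
    expect_identical(sum(blk$gene_count - 1L), n_coll)
    w <- prof$windows[prof$windows$chrom == ch, ]
    expect_equal(sum(w$prop_collinear * w$n_pairs), n_coll)
    chr_pct <- prof$chromosomes$pct_collinear[prof$chromosomes$chrom == ch]
    expect_equal(100 * sum(w$prop_collinear * w$n_pairs) / sum(w$n_pairs), chr_pct)
  }
  expect_true(all(prof$windows$prop_collinear >= 0 & prof$windows$prop_collinear <= 1))
})

test_that("species-set comparison contrasts rearrangement loads", {
  # selfer pair carries twice the inversions of the outcrosser pair
  selfer <- simulate_rearranged_genomes(3, 60, n_inversions = 10, seed = 5,
                                        species = c("sA", "sB"))
  outcr <- simulate_rearranged_genomes(3, 60, n_inversions = 5, seed = 6,
                                       species = c("oA", "oB"))
  p_self <- score_collinearity(
    rank_single_copy_orthologs(selfer$orthogroups, selfer$genes), "sA", "sB")
  p_out <- score_collinearity(
    rank_single_copy_orthologs(outcr$orthogroups, outcr$genes), "oA", "oB")
  cmp <- compare_species_sets(list(p_self, p_out), c("selfer", "outcrosser"))
  n_pairs <- nrow(p_self$pairs)
  bad_self <- (100 - cmp$table[cmp$table$chrom == "genome", 2]) / 100 * n_pairs
  bad_out <- (100 - cmp$table[cmp$table$chrom == "genome", 3]) / 100 * n_pairs
  expect_equal(bad_self, 20)
  expect_equal(bad_out, 10)
  expect_equal(cmp$difference$difference[cmp$difference$chrom == "genome"],
               (10 - 20) / n_pairs * 100, tolerance = 1e-9)
  # identical profiles -> zero differences
  cmp0 <- compare_species_sets(list(p_self, p_self), c("x", "y"))
  expect_true(all(cmp0$difference$difference == 0))
  # single profile degenerates to its own summary
  cmp1 <- compare_species_sets(list(p_self), "only")
  expect_identical(ncol(cmp1$table), 2L)
  expect_null(cmp1$difference)
})

test_that("patristic distances are path sums over the tree", {
  tr <- "((A:0.05,B:0.06):0.01,C:0.10);"
  expect_equal(patristic_distance(tr, "A", "A"), 0)
  expect_equal(patristic_distance(tr, "A", "B"), 0.11)
  expect_equal(patristic_distance(tr, "A", "C"), 0.16)
  expect_error(patristic_distance(tr, "A", "Z"), "Z")
})
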