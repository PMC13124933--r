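toy_ranges <- data.frame(
  gene = c("GA", "GB", "GC"),
  chrom = c("chr1", "chr1", "chr2"),
  start = c(50000L, 55000L, 10000L),
  end = c(60000L, 70000L, 20000L),
  stringsAsFactors = FALSE
)

toy_arc_map <- data.frame(
  ard_id = c("stroke", "hypertension", "arthritis", "diabetes"),
  arc_id = c("Cardiovascular", "Cardiovascular", "Musculoskeletal", "Endocrine"),
  stringsAsFactors = FALSE
)

snp_row <- function(snp, chrom, pos, ard) {
  data.frame(snp = snp, chrom = chrom, pos = pos, ard_id = ard,
             stringsAsFactors = FALSE)
}

test_that("a SNP inside the gene body associates the gene with its disease", {
  assoc <- map_snps_to_genes(snp_row("s1", "chr2", 15000, "diabetes"),
                             toy_ranges, arc_map = toy_arc_map)
  expect_equal(assoc$ard, data.frame(gene = "GC", ard_id = "diabetes",
                                     stringsAsFactors = FALSE))
})

test_that("the 10 kb flank boundary is inclusive on both sides", {
  # GA spans 50000-60000; positions checked against a direct interval oracle
  for (pos in c(40000, 40001, 60000 + 10000)) {
    hit <- pos >= 50000 - 10000 && pos <= 60000 + 10000
    assoc <- map_snps_to_genes(snp_row("s", "chr1", pos, "stroke"), toy_ranges)
    expect_identical("GA" %in% assoc$ard$gene, hit, label = paste("pos", pos))
  }
  miss <- map_snps_to_genes(snp_row("s", "chr1", 39999, "stroke"), toy_ranges)
  expect_false("GA" %in% miss$ard$gene)
  miss2 <- map_snps_to_genes(snp_row("s", "chr1", 70001 + 10000, "stroke"),
                             toy_ranges)
  expect_equal(nrow(miss2$ard), 0)
})

test_that("a SNP overlapping two genes is assigned to both", {
  assoc <- map_snps_to_genes(snp_row("s1", "chr1", 57000, "stroke"), toy_ranges)
  expect_setequal(assoc$ard$gene, c("GA", "GB"))
})

test_that("SNPs on unknown chromosomes are skipped with a warning", {
  snps <- rbind(snp_row("s1", "chrX", 100, "stroke"),
                snp_row("s2", "chr2", 15000, "diabetes"))
  expect_warning(assoc <- map_snps_to_genes(snps, toy_ranges), "chrX")
  expect_equal(assoc$ard$gene, "GC")
})

test_that("malformed coordinates are an input error", {
  bad <- toy_ranges
  bad$start[1] <- bad$end[1] + 5
  expect_error(map_snps_to_genes(snp_row("s", "chr1", 1, "stroke"), bad),
               "malformed")
  expect_error(map_snps_to_genes(snp_row("s", "chr1", NA, "stroke"), toy_ranges),
               "malformed")
  expect_error(map_snps_to_genes(snp_row("s", "chr1", 1, "stroke"), toy_ranges,
                                 flank = -1), "flank")
})

test_that("duplicate gene-disease pairs collapse to one association", {
  snps <- rbind(snp_row("s1", "chr2", 15000, "diabetes"),
                snp_row("s2", "chr2", 16000, "diabetes"))
  assoc <- map_snps_to_genes(snps, toy_ranges)
  expect_equal(nrow(assoc$ard), 1)
})

test_that("pleiotropy counts distinct diseases and distinct clusters", {
  # gene X with stroke + hypertension: ARD-Pleiotropy 2, both cardiovascular
  ard <- data.frame(gene = "X", ard_id = c("stroke", "hypertension"))
  p <- compute_pleiotropy(associations_from_pairs(ard, toy_arc_map))
  expect_equal(p$ard_pleiotropy, 2)
  expect_equal(p$arc_pleiotropy, 1)

  # adding arthritis (musculoskeletal) gives ARC-Pleiotropy 2
  ard2 <- data.frame(gene = "X", ard_id = c("stroke", "hypertension", "arthritis"))
  p2 <- compute_pleiotropy(associations_from_pairs(ard2, toy_arc_map))
  expect_equal(p2$ard_pleiotropy, 3)
  expect_equal(p2$arc_pleiotropy, 2)
  expect_equal(p2$pleiotropy_class, "low")
})

test_that("genes spanning four or more clusters are classified high", {
  map4 <- data.frame(ard_id = paste0("d", 1:4), arc_id = paste0("c", 1:4))
  p <- compute_pleiotropy(associations_from_pairs(
    data.frame(gene = "X", ard_id = paste0("d", 1:4)), map4))
  expect_equal(p$arc_pleiotropy, 4)
  expect_equal(p$pleiotropy_class, "high")
})

test_that("increasing the flank never removes an association", {
  set.seed(20)
  ranges <- data.frame(
    gene = paste0("g", 1:30),
    chrom = sample(paste0("chr", 1:3), 30, replace = TRUE),
    start = sample.int(5e5, 30)
  )
  ranges$end <- ranges$start + sample.int(5e4, 30)
  snps <- data.frame(
    snp = paste0("s", 1:100),
    chrom = sample(paste0("chr", 1:3), 100, replace = TRUE),
    pos = sample.int(6e5, 100),
    ard_id = sample(c("d1", "d2", "d3"), 100, replace = TRUE)
  )
  prev <- character(0)
  for (flank in c(0, 2000, 10000, 50000)) {
    a <- map_snps_to_genes(snps, ranges, flank = flank)
    keys <- paste(a$ard$gene, a$ard$ard_id)
    expect_true(all(prev %in% keys), label = paste("flank", flank))
    prev <- keys
  }
})

test_that("cluster pleiotropy never exceeds disease pleiotropy on synthetic data", {
  study <- small_study()
  assoc <- study_assoc(study)
  p <- compute_pleiotropy(assoc)
  expect_true(all(p$arc_pleiotropy <= p$ard_pleiotropy))
})

test_that("planted associations are recovered exactly from SNPs in gene bodies", {
  study <- small_study()
  assoc <- study_assoc(study)
  expect_setequal(paste(assoc$ard$gene, assoc$ard$ard_id),
                  paste(study$truth$gene, study$truth$ard_id))
})
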