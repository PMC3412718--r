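test_that("GFF3 CDS rows keep their 1-based closed coordinates", {
  fa <- tempfile(fileext = ".fasta"); gff <- tempfile(fileext = ".gff3")
  writeLines(c(">ctg", randomContig(60, seed = 1)), fa)
  writeLines(c("##gff-version 3",
               "ctg\t.\tCDS\t11\t40\t.\t+\t0\tID=gA;locus_tag=LT_A"), gff)
  g <- readGenome(fa, gff, genomeId = "t")
  ft <- geneFeatures(g)
  expect_equal(GenomicRanges::start(ft), 11)   # 0-based half-open [10, 40)
  expect_equal(GenomicRanges::end(ft), 40)
  expect_equal(as.character(GenomicRanges::strand(ft)), "+")
  expect_equal(ft$gene_id, "gA")
})

test_that("annotation referencing an absent contig is a format error", {
  fa <- tempfile(fileext = ".fasta"); gff <- tempfile(fileext = ".gff3")
  writeLines(c(">ctg", randomContig(60, seed = 2)), fa)
  writeLines(c("##gff-version 3",
               "other\t.\tCDS\t11\t40\t.\t+\t0\tID=gA"), gff)
  expect_error(readGenome(fa, gff), "absent from the FASTA")
  writeLines("##gff-version 3", gff)
  expect_error(readGenome(fa, gff), "no CDS")
})

test_that("synthetic genomes round-trip through FASTA + GFF3 unchanged", {
  for (seed in 1:40) {
    spec <- simulationSpec(seed = seed, genesPerGenome = 5,
                           geneLength = c(60, 120),
                           intergenicLength = c(40, 80), anchor = FALSE,
                           geneStrands = "random")
    sim <- simulateGenome(spec, genomeId = paste0("rt", seed))
    fa <- tempfile(fileext = ".fasta"); gff <- tempfile(fileext = ".gff3")
    writeGenome(sim$genome, fa, gff)
    back <- readGenome(fa, gff, genomeId = genomeId(sim$genome))
    expect_equal(as.character(contigs(back)), as.character(contigs(sim$genome)))
    f1 <- geneFeatures(sim$genome); f2 <- geneFeatures(back)
    expect_equal(GenomicRanges::start(f2), GenomicRanges::start(f1))
    expect_equal(GenomicRanges::end(f2), GenomicRanges::end(f1))
    expect_equal(as.character(GenomicRanges::strand(f2)),
                 as.character(GenomicRanges::strand(f1)))
    expect_equal(f2$gene_id, f1$gene_id)
    expect_equal(f2$locus_tag, f1$locus_tag)
    unlink(c(fa, gff))
  }
})

test_that("operon inference merges by strand and intergenic gap", {
  ctg <- randomContig(3000, seed = 3)
  ## gap 30: one operon, leader = upstream gene
  g <- handGenome(ctg, list(list(gene_id = "a", start = 101, end = 400, strand = "+"),
                            list(gene_id = "b", start = 431, end = 700, strand = "+")))
  ops <- inferOperons(g, maxGap = 150)
  expect_equal(nrow(ops), 1)
  expect_equal(ops$leader_gene, "a")
  expect_equal(ops$members, "a,b")
  ## gap 300: two singletons
  g2 <- handGenome(ctg, list(list(gene_id = "a", start = 101, end = 400, strand = "+"),
                             list(gene_id = "b", start = 701, end = 1000, strand = "+")))
  expect_equal(nrow(inferOperons(g2, maxGap = 150)), 2)
  ## opposite strands never merge even when adjacent
  g3 <- handGenome(ctg, list(list(gene_id = "a", start = 101, end = 400, strand = "+"),
                             list(gene_id = "b", start = 431, end = 700, strand = "-")))
  expect_equal(nrow(inferOperons(g3, maxGap = 150)), 2)
  ## minus-strand operon: leader is the 5'-most member on the coding strand
  g4 <- handGenome(ctg, list(list(gene_id = "a", start = 101, end = 400, strand = "-"),
                             list(gene_id = "b", start = 431, end = 700, strand = "-")))
  ops4 <- inferOperons(g4, maxGap = 150)
  expect_equal(ops4$leader_gene, "b")
  expect_equal(ops4$members, "b,a")
})

test_that("operons partition the gene set", {
  for (seed in 1:10) {
    spec <- simulationSpec(seed = 100 + seed, genesPerGenome = 12,
                           geneLength = c(80, 200),
                           intergenicLength = c(20, 300), anchor = FALSE,
                           geneStrands = "random")
    sim <- simulateGenome(spec)
    ops <- inferOperons(sim$genome)
    members <- unlist(operonMembers(ops), use.names = FALSE)
    expect_equal(sort(members), sort(geneFeatures(sim$genome)$gene_id))
  }
})

test_that("upstream extraction follows the fixed-window arithmetic", {
  ctg <- randomContig(3000, seed = 4)
  g <- handGenome(ctg, list(list(gene_id = "p", start = 1001, end = 2000, strand = "+"),
                            list(gene_id = "m", start = 1001, end = 2000, strand = "-")))
  rp <- extractUpstream(g, "p", window = 250)
  expect_equal(c(rp@gstart, rp@gend), c(751, 1000))
  expect_equal(regionSequence(rp), substr(ctg, 751, 1000))
  expect_false(rp@truncated)
  rm <- extractUpstream(g, "m", window = 250)
  expect_equal(c(rm@gstart, rm@gend), c(2001, 2250))
  expect_equal(regionSequence(rm), as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(substr(ctg, 2001, 2250)))))
  ## the last region base abuts the translation start on both strands
  expect_equal(substr(regionSequence(rp), 250, 250), substr(ctg, 1000, 1000))
})

test_that("windows clip at contig edges and flag truncation", {
  ctg <- randomContig(500, seed = 5)
  g <- handGenome(ctg, list(list(gene_id = "p", start = 101, end = 400, strand = "+")))
  r <- extractUpstream(g, "p", window = 250)
  expect_true(r@truncated)
  expect_equal(c(r@gstart, r@gend), c(1, 100))
  expect_equal(nchar(regionSequence(r)), 100)
  ## leader abutting the edge: empty region, not an error
  g2 <- handGenome(ctg, list(list(gene_id = "p", start = 1, end = 300, strand = "+")))
  r2 <- extractUpstream(g2, "p", window = 250)
  expect_true(r2@truncated)
  expect_equal(nchar(regionSequence(r2)), 0)
})

test_that("extraction is symmetric under genome reverse complement", {
  for (seed in 1:5) {
    n <- 2000
    ctg <- randomContig(n, seed = 200 + seed)
    g <- handGenome(ctg, list(list(gene_id = "x", start = 801, end = 1400, strand = "+")))
    rcCtg <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ctg)))
    gRC <- handGenome(rcCtg, list(list(gene_id = "x", start = n - 1400 + 1,
                                       end = n - 801 + 1, strand = "-")))
    r1 <- extractUpstream(g, "x", window = 150)
    r2 <- extractUpstream(gRC, "x", window = 150)
    expect_equal(regionSequence(r2), regionSequence(r1))
  }
})

test_that("divergons are head-to-head leader pairs only", {
  ctg <- randomContig(2000, seed = 6)
  ## <-A [1,500], B [701,1200]-> : mutual partners across [501,700]
  g <- handGenome(ctg, list(list(gene_id = "A", start = 1, end = 500, strand = "-"),
                            list(gene_id = "B", start = 701, end = 1200, strand = "+")))
  ops <- inferOperons(g)
  dv <- classifyDivergons(g, ops)
  expect_equal(unname(dv["A"]), "B")
  expect_equal(unname(dv["B"]), "A")
  ## tandem
  gT <- handGenome(ctg, list(list(gene_id = "A", start = 1, end = 500, strand = "+"),
                             list(gene_id = "B", start = 701, end = 1200, strand = "+")))
  expect_length(classifyDivergons(gT, inferOperons(gT)), 0)
  ## convergent (-> <-)
  gC <- handGenome(ctg, list(list(gene_id = "A", start = 1, end = 500, strand = "+"),
                             list(gene_id = "B", start = 701, end = 1200, strand = "-")))
  expect_length(classifyDivergons(gC, inferOperons(gC)), 0)
})

test_that("upstream FASTA writer records provenance headers", {
  ctg <- randomContig(2000, seed = 7)
  g <- handGenome(ctg, list(list(gene_id = "x", start = 801, end = 1400, strand = "+")))
  r <- extractUpstream(g, "x", window = 100)
  path <- tempfile(fileext = ".fasta")
  writeUpstreamFasta(list(r), path)
  back <- Biostrings::readDNAStringSet(path)
  expect_equal(names(back), "hand|x|701-800|+")
  expect_equal(as.character(back[[1]]), regionSequence(r))
})
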