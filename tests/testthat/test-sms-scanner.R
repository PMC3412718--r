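toyPFM <- buildPFM(c("ACGT", "ACGA", "ACTT", "GCGT"))

test_that("SMS scores match the hand-worked toy example", {
  s <- smsScore(toyPFM, "ACGT")
  expect_equal(s$raw, 3.25)
  expect_equal(s$similarity, 0.8125)
  expect_equal(s$relative, 1.0)
  s2 <- smsScore(toyPFM, "GCTA")
  expect_equal(s2$raw, 1.75)
  expect_equal(s2$relative, 1.75 / 3.25)
  expect_error(smsScore(toyPFM, "ACGTA"), "length")
})

test_that("any window scores relative 1 against the uniform matrix", {
  uniform <- buildPFM(c("AAAA", "CCCC", "GGGG", "TTTT"))
  set.seed(1)
  for (k in 1:5) {
    s <- smsScore(uniform, randomWindow(4))
    expect_equal(s$relative, 1.0)
    expect_equal(s$similarity, 0.25)
  }
})

test_that("non-ACGT characters contribute zero", {
  s <- smsScore(toyPFM, "NCGT")
  expect_equal(s$raw, 3.25 - 0.75)
})

test_that("SMS agrees with an independent re-implementation", {
  set.seed(101)
  for (k in 1:50) {
    i <- sample(3:8, 1)
    pfm <- buildPFM(randomSites(sample(2:10, 1), i))
    win <- randomWindow(i)
    expect_equal(smsScore(pfm, win)$raw, bruteSMS(pfm, win),
                 tolerance = 1e-12)
  }
})

test_that("maxAttainable equals the enumerated maximum over all windows", {
  set.seed(102)
  for (k in 1:10) {
    i <- sample(3:6, 1)
    pfm <- buildPFM(randomSites(sample(2:8, 1), i))
    expect_equal(maxAttainable(pfm), enumMaxScore(pfm), tolerance = 1e-12)
  }
  expect_equal(maxAttainable(buildPFM("ACGTAC")), 6)
})

test_that("relative similarity is 1 exactly at column-maximal windows", {
  set.seed(103)
  for (k in 1:10) {
    pfm <- buildPFM(randomSites(5, 6))
    p <- profileMatrix(pfm)
    argmaxWin <- paste(rownames(p)[apply(p, 2, which.max)], collapse = "")
    expect_equal(smsScore(pfm, argmaxWin)$relative, 1.0)
    ## mutating one position away from the column maximum lowers the score
    for (j in 1:6) {
      ch <- strsplit(argmaxWin, "")[[1]]
      worst <- rownames(p)[which.min(p[, j])]
      if (worst == ch[j]) next   # tied column
      ch[j] <- worst
      mut <- smsScore(pfm, paste(ch, collapse = ""))
      expect_true(mut$relative <= 1.0 - 1e-12 ||
                  p[worst, j] == max(p[, j]))
    }
  }
})

test_that("region scanning matches the naive per-window loop", {
  set.seed(104)
  for (k in 1:50) {
    i <- sample(3:6, 1)
    pfm <- buildPFM(randomSites(4, i))
    seq <- randomContig(sample(20:60, 1))
    thr <- runif(1, 0.6, 0.95)
    got <- scanRegion(pfm, seq, bothStrands = TRUE, threshold = thr)
    want <- naiveScan(pfm, seq, bothStrands = TRUE, threshold = thr)
    expect_equal(nrow(got), if (is.null(want)) 0L else nrow(want))
    if (nrow(got)) {
      expect_equal(sort(got$raw), sort(want$raw), tolerance = 1e-12)
      ## minus-strand offsets are reported in forward coordinates
      expect_equal(sort(paste(got$offset, got$strand)),
                   sort(paste(want$offset, want$strand)))
    }
  }
})

test_that("scan examples behave as specified", {
  h <- scanRegion(toyPFM, "AAACGTAA", bothStrands = FALSE, threshold = 0.9)
  expect_equal(nrow(h), 1)
  expect_equal(h$window_sequence, "ACGT")
  expect_equal(h$offset, 3)          # 0-based offset 2
  expect_equal(h$relative, 1.0)
  ## a threshold above 1 can never be met
  expect_equal(nrow(scanRegion(toyPFM, "AAACGTAA", threshold = 1.01)), 0)
  ## regions shorter than the motif yield an empty result
  expect_equal(nrow(scanRegion(toyPFM, "ACG")), 0)
})

test_that("both-strand scans of a region and its reverse complement agree", {
  set.seed(105)
  for (k in 1:10) {
    pfm <- buildPFM(randomSites(5, 5))
    seq <- randomContig(50)
    rcSeq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    a <- scanRegion(pfm, seq, bothStrands = TRUE, threshold = 0)
    b <- scanRegion(pfm, rcSeq, bothStrands = TRUE, threshold = 0)
    expect_equal(sort(a$raw), sort(b$raw), tolerance = 1e-12)
  }
})

test_that("hits are ranked by score, proximity, strand, offset", {
  set.seed(106)
  pfm <- buildPFM(randomSites(4, 4))
  h <- scanRegion(pfm, randomContig(80), bothStrands = TRUE, threshold = 0)
  expect_true(all(diff(h$relative) <= 1e-12))
  ties <- which(abs(diff(h$relative)) < 1e-12)
  for (t in ties)
    expect_true(h$distance_to_start[t] <= h$distance_to_start[t + 1] ||
                h$relative[t] > h$relative[t + 1])
})

test_that("genome-wide scans find planted sites at their planted distance", {
  spec <- simulationSpec(seed = 31, genesPerGenome = 8, geneStrands = "plus",
                         plantingPFM = sitePFM(sharpness = 1),
                         targetGenes = "g05", anchor = FALSE)
  sim <- simulateGenome(spec, genomeId = "scan1")
  ops <- inferOperons(sim$genome)
  hits <- scanGenomeUpstreams(sitePFM(), sim$genome, ops, threshold = 0.87)
  expect_true("g05" %in% hits$gene_id)
  best <- hits[hits$gene_id == "g05", ][1, ]
  expect_equal(best$distance_to_start, sim$truth$distance_to_start[1])
  expect_equal(best$window_sequence, sim$truth$site[1])
  ## site genomic span re-extracts to the reported window sequence
  ctg <- as.character(contigs(sim$genome)[[best$contig]])
  gseq <- substr(ctg, best$site_gstart, best$site_gend)
  if (best$leader_strand != best$strand)
    gseq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(gseq)))
  expect_equal(gseq, best$window_sequence)
})

test_that("sites outside the upstream window never qualify", {
  ## plant at distance 300 with window 250: criterion (ii) excludes it
  spec <- simulationSpec(seed = 32, genesPerGenome = 6, geneStrands = "plus",
                         plantingPFM = sitePFM(sharpness = 1),
                         intergenicLength = c(400, 500),
                         positionRange = c(300, 300), targetGenes = "g04",
                         anchor = FALSE)
  sim <- simulateGenome(spec, genomeId = "far1")
  ops <- inferOperons(sim$genome)
  hits <- scanGenomeUpstreams(sitePFM(), sim$genome, ops,
                              window = 250, threshold = 0.87)
  expect_false("g04" %in% hits$gene_id)
  ## the same site qualifies once the window covers it
  hits2 <- scanGenomeUpstreams(sitePFM(), sim$genome, ops,
                               window = 350, threshold = 0.87)
  expect_true("g04" %in% hits2$gene_id)
})

test_that("background-only genomes rarely produce qualifying operons", {
  fp <- vapply(1:20, function(r) {
    spec <- simulationSpec(seed = 9000 + r, genesPerGenome = 200,
                           geneLength = c(100, 200),
                           intergenicLength = c(260, 300),
                           anchor = FALSE, geneStrands = "plus")
    sim <- simulateGenome(spec, genomeId = paste0("bg", r))
    ops <- inferOperons(sim$genome)
    hits <- scanGenomeUpstreams(sitePFM(), sim$genome, ops, threshold = 0.87)
    length(unique(hits$operon_id)) / nrow(ops)
  }, 0)
  expect_true(all(fp < 0.05))
})

test_that("hit tables export as TSV and BED6", {
  spec <- simulationSpec(seed = 33, genesPerGenome = 6, geneStrands = "plus",
                         targetGenes = c("g03", "g05"), anchor = FALSE)
  sim <- simulateGenome(spec, genomeId = "exp1")
  ops <- inferOperons(sim$genome)
  hits <- scanGenomeUpstreams(sitePFM(), sim$genome, ops, threshold = 0.87)
  tsv <- tempfile(fileext = ".tsv"); bed <- tempfile(fileext = ".bed")
  writeHitsTSV(hits, tsv)
  expect_equal(nrow(read.delim(tsv)), nrow(hits))
  writeHitsBED(hits, bed)
  b <- read.delim(bed, header = FALSE)
  expect_equal(nrow(b), nrow(hits))
  expect_true(all(b$V5 >= 870 & b$V5 <= 1000))
  expect_equal(b$V3 - b$V2, rep(17, nrow(b)))   # half-open BED spans
})
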