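## Independent oracles and fixture builders, kept deliberately naive.

## brute-force SMS: per-position lookup by rowname, summed back to front
## (different access path and summation order from the implementation)
bruteSMS <- function(pfm, window) {
  p <- profileMatrix(pfm)
  ch <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  raw <- 0
  for (j in rev(seq_along(ch))) {
    if (ch[j] %in% rownames(p)) raw <- raw + p[ch[j], j]
  }
  unname(raw)
}

## exact maximum raw score by enumerating all 4^i windows
enumMaxScore <- function(pfm) {
  p <- profileMatrix(pfm)
  v <- 0
  for (j in seq_len(ncol(p))) v <- as.vector(outer(v, p[, j], "+"))
  max(v)
}

## fraction of all 4^i windows with relative score >= threshold, and the
## probability-weighted fraction under an i.i.d. background model
enumQualifying <- function(pfm, threshold, baseProb = rep(0.25, 4)) {
  p <- profileMatrix(pfm)
  v <- 0; w <- 1
  for (j in seq_len(ncol(p))) {
    v <- as.vector(outer(v, p[, j], "+"))
    w <- as.vector(outer(w, baseProb, "*"))
  }
  rel <- v / maxAttainable(pfm)
  list(fraction = mean(rel >= threshold),
       probMass = sum(w[rel >= threshold]))
}

## naive window-by-window scanner built on bruteSMS
naiveScan <- function(pfm, seq, bothStrands = TRUE, threshold = 0.87) {
  i <- motifLength(pfm)
  L <- nchar(seq)
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  out <- NULL
  for (o in seq_len(max(L - i + 1L, 0L))) {
    win <- substr(seq, o, o + i - 1L)
    strands <- if (bothStrands) c("+", "-") else "+"
    for (st in strands) {
      raw <- bruteSMS(pfm, if (st == "+") win else rc(win))
      rel <- raw / maxAttainable(pfm)
      if (rel >= threshold)
        out <- rbind(out, data.frame(offset = o, strand = st, raw = raw,
                                     relative = rel))
    }
  }
  out
}

randomSites <- function(n, i) {
  vapply(seq_len(n), function(k)
    paste(sample(c("A", "C", "G", "T"), i, replace = TRUE), collapse = ""), "")
}

randomWindow <- function(i) randomSites(1, i)

## small hand-built genome: contig string + features given as
## list(gene_id, start, end, strand), 1-based closed
handGenome <- function(contigSeq, genes, genomeId = "hand") {
  gr <- GenomicRanges::GRanges(
    "ctg", IRanges::IRanges(vapply(genes, `[[`, 0, "start"),
                            vapply(genes, `[[`, 0, "end")),
    strand = vapply(genes, `[[`, "", "strand"))
  gr$gene_id <- vapply(genes, `[[`, "", "gene_id")
  gr$locus_tag <- paste0("LT_", gr$gene_id)
  GenomeRecord(genomeId, c(ctg = contigSeq), gr)
}

randomContig <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
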