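## Internal sequence helpers shared across modules.

.BASES <- c("A", "C", "G", "T")

## IUPAC code -> allowed base set
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

## sorted base set (pasted) -> IUPAC code
.IUPAC_FROM_SET <- local({
  v <- vapply(.IUPAC_SETS, function(b) paste(sort(b), collapse = ""), "")
  setNames(names(v), v)
})

.rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## A/C/G/T -> 1..4, anything else (N etc.) -> 5; vectorised over characters
.encode5 <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  code <- match(ch, .BASES)
  code[is.na(code)] <- 5L
  code
}

## raw SMS scores of every window of length i, vectorised.
## profile5 = rbind(profile, 0): row 5 catches non-ACGT characters.
.windowScores <- function(profile5, code5, i) {
  L <- length(code5)
  n <- L - i + 1L
  if (n < 1L) return(numeric(0))
  idx <- outer(seq_len(n), 0:(i - 1L), "+")
  b <- matrix(code5[idx], n, i)
  rowSums(matrix(profile5[cbind(as.vector(b), rep(seq_len(i), each = n))], n, i))
}

## deterministic hit ordering: relative desc, nearer the start codon first,
## plus strand before minus, then smaller offset
.orderHits <- function(df) {
  order(-df$relative, df$distance_to_start, df$strand != "+", df$offset)
}

.sampleBases <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(.BASES, n, replace = TRUE, prob = p)
}

## sample one sequence column-wise from a frequency profile
.samplePFM <- function(profile) {
  paste(apply(profile, 2L, function(p) sample(.BASES, 1L, prob = p)),
        collapse = "")
}

.fmt2 <- function(x) sprintf("%.2f", x)
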