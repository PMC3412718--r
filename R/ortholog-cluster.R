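#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Read a tabular homology-hit file (BLAST outfmt 6 dialect)
#'
#' Twelve tab-separated columns; columns 1 (query), 2 (subject) and 11
#' (e-value) are used, extras are ignored. Subjects encoded as
#' \code{"genome_id|gene_id"} are split into the two fields. Hits with
#' e-value above \code{includeCutoff} are dropped with a message; an
#' e-value of exactly 0 is stored as the sentinel 1e-200 so that log10
#' arithmetic stays finite.
#'
#' @param path TSV path.
#' @param includeCutoff inclusion e-value cut-off (default 1e-5).
#' @return data.frame of hit records: \code{query_id}, \code{subject_id},
#'   \code{subject_genome_id}, \code{subject_gene_id}, \code{evalue},
#'   \code{bitscore}.
#' @export
readHitTable <- function(path, includeCutoff = 1e-5) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 12L))
    stop("malformed hit-table row at line ", which(nf < 12L)[1L],
         ": expected >= 12 tab-separated columns, found ", nf[nf < 12L][1L])
  ev <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 11L)))
  if (anyNA(ev))
    stop("malformed e-value at line ", which(is.na(ev))[1L])
  bs <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 12L)))
  subj <- vapply(parts, `[`, "", 2L)
  sp <- strsplit(subj, "|", fixed = TRUE)
  df <- data.frame(
    query_id = vapply(parts, `[`, "", 1L),
    subject_id = subj,
    subject_genome_id = vapply(sp, function(x)
      if (length(x) >= 2L) x[1L] else NA_character_, ""),
    subject_gene_id = vapply(sp, function(x)
      if (length(x) >= 2L) x[2L] else x[1L], ""),
    evalue = pmax(ev, 1e-200),
    bitscore = bs,
    stringsAsFactors = FALSE)
  drop <- df$evalue > includeCutoff
  if (any(drop))
    message(sum(drop), " hit(s) above the e-value cut-off ",
            format(includeCutoff), " dropped")
  df <- df[!drop, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Cluster homology hits into an ortholog group by e-value gap
#'
#' Implements the comparable-low-e-value rule: the in-group consists of
#' hits with e-value below \code{coreCutoff} (default 1e-30); the group
#' counts as cleanly separated when no hit is excluded or when the first
#' excluded e-value lies at least \code{gapOrders} orders of magnitude
#' (default 15) above the last included one. A group that fails the gap
#' test is returned all the same, flagged for manual review rather than
#' rejected. For short proteins (e.g. the regulators themselves) where the
#' whole distribution shifts to higher e-values, raise \code{coreCutoff}
#' per family.
#'
#' @param hits data.frame from \code{\link{readHitTable}} (or with at least
#'   an \code{evalue} column plus subject identifiers).
#' @param coreCutoff in-group e-value cut-off (default 1e-30).
#' @param gapOrders required log10 separation (default 15).
#' @param familyName label stored on the group.
#' @return list of class \code{"orthologGroup"}: \code{familyName},
#'   \code{members} (data.frame sorted by ascending e-value),
#'   \code{separationLog10} (NA when one side is empty) and
#'   \code{cleanSeparation}.
#' @examples
#' h <- data.frame(subject_genome_id = paste0("g", 1:6),
#'                 subject_gene_id = paste0("x", 1:6),
#'                 evalue = c(1e-80, 1e-75, 1e-72, 1e-40, 1e-10, 1e-6))
#' evalueGapCluster(h)   # 4 members, gap 30 orders, clean
#' @export
evalueGapCluster <- function(hits, coreCutoff = 1e-30, gapOrders = 15,
                             familyName = "") {
  if (is.null(hits) || nrow(hits) == 0L) {
    out <- list(familyName = familyName,
                members = data.frame(subject_genome_id = character(0),
                                     subject_gene_id = character(0),
                                     evalue = numeric(0)),
                separationLog10 = NA_real_, cleanSeparation = TRUE)
    class(out) <- "orthologGroup"
    return(out)
  }
  hits <- hits[order(hits$evalue), , drop = FALSE]
  ev <- pmax(hits$evalue, 1e-200)
  inGrp <- ev < coreCutoff
  sep <- if (any(inGrp) && any(!inGrp))
    log10(min(ev[!inGrp])) - log10(max(ev[inGrp])) else NA_real_
  clean <- !any(!inGrp) || (!is.na(sep) && sep >= gapOrders)
  if (!any(inGrp)) clean <- TRUE   # nothing included: vacuously clean
  members <- hits[inGrp, , drop = FALSE]
  members <- members[!duplicated(members$subject_id %||% paste(
    members$subject_genome_id, members$subject_gene_id)), , drop = FALSE]
  rownames(members) <- NULL
  out <- list(familyName = familyName, members = members,
              separationLog10 = sep, cleanSeparation = clean)
  class(out) <- "orthologGroup"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.orthologGroup <- function(x, ...) {
  cat("orthologGroup", x$familyName, "-", nrow(x$members), "member(s);",
      if (x$cleanSeparation) "clean separation" else "separation FLAGGED",
      if (!is.na(x$separationLog10))
        paste0("(gap ", round(x$separationLog10, 1), " orders)") else "",
      "\n")
  invisible(x)
}

#' Build a presence/absence matrix across genomes
#'
#' Rows are ortholog families, columns genomes; each cell is the copy count
#' of the family in that genome, with the number of copies whose operon
#' carries a qualifying predicted binding site tracked in parallel
#' ("regulated" copies).
#'
#' @param groups named list of \code{orthologGroup}s (family -> group).
#' @param genomes character vector of genome ids (column order).
#' @param regulons optional named list (genome id -> prediction data.frame
#'   from \code{\link{predictRegulon}}); a member counts as regulated when
#'   its gene id appears among a prediction entry's target genes.
#' @return a \linkS4class{PresenceAbsenceMatrix}.
#' @export
buildPresenceAbsence <- function(groups, genomes, regulons = NULL) {
  fam <- names(groups)
  counts <- matrix(0L, length(fam), length(genomes),
                   dimnames = list(fam, genomes))
  regulated <- counts
  for (f in fam) {
    m <- groups[[f]]$members
    if (nrow(m) == 0L) next
    tab <- table(factor(m$subject_genome_id, levels = genomes))
    counts[f, ] <- as.integer(tab)
    if (!is.null(regulons)) {
      for (g in intersect(unique(m$subject_genome_id), genomes)) {
        pred <- regulons[[g]]
        if (is.null(pred) || nrow(pred) == 0L) next
        targets <- unlist(strsplit(pred$target_genes, ",", fixed = TRUE))
        regulated[f, g] <- sum(m$subject_gene_id[m$subject_genome_id == g]
                               %in% targets)
      }
    }
  }
  new("PresenceAbsenceMatrix", counts = counts, regulated = regulated)
}

#' Render a presence/absence matrix in "total(regulated)" cell syntax
#'
#' A genome lacking the family renders as an empty cell; a copy count with
#' no regulated copy renders as the bare count; otherwise
#' \code{"total(regulated)"} (e.g. \code{"2(1)"}).
#'
#' @param pam a \linkS4class{PresenceAbsenceMatrix}.
#' @return character matrix of rendered cells.
#' @export
renderPresenceAbsence <- function(pam) {
  cnt <- pam@counts; reg <- pam@regulated
  out <- matrix("", nrow(cnt), ncol(cnt), dimnames = dimnames(cnt))
  nz <- cnt > 0L
  out[nz] <- ifelse(reg[nz] > 0L,
                    paste0(cnt[nz], "(", reg[nz], ")"),
                    as.character(cnt[nz]))
  out
}

#' Write a presence/absence matrix as TSV
#'
#' @param pam a \linkS4class{PresenceAbsenceMatrix}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writePresenceAbsence <- function(pam, path) {
  m <- renderPresenceAbsence(pam)
  df <- data.frame(family = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

setMethod("show", "PresenceAbsenceMatrix", function(object) {
  cat("PresenceAbsenceMatrix:", nrow(object@counts), "family(ies) x",
      ncol(object@counts), "genome(s);",
      sum(object@regulated), "regulated copy(ies) of",
      sum(object@counts), "total\n")
})
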