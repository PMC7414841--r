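# Single-sample gene-set enrichment (ssGSEA) and paired treatment deltas.

#' Read a gene-by-sample expression matrix
#'
#' TSV with genes in rows (first column = gene symbol) and a header of
#' sample ids.  Duplicate gene symbols are collapsed by the per-sample
#' maximum, with a message.
#'
#' @param path path to the TSV file.
#' @return numeric matrix, rownames = gene symbols.
#' @export
readExpression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyDuplicated(genes) > 0) {
    nDup <- sum(duplicated(genes))
    logMsg("collapsing ", nDup, " duplicate gene row(s) by per-sample max")
    m <- do.call(rbind, lapply(split(seq_along(genes), genes), function(ix)
      apply(m[ix, , drop = FALSE], 2, max)))
  } else {
    rownames(m) <- genes
  }
  m
}

#' Read a sample-pairing table
#'
#' TSV with columns \code{sample}, \code{subject}, \code{timepoint}
#' (\code{before}/\code{after}) and optionally \code{group} (e.g. an
#' improver flag, passed through untouched).
#'
#' @param path path to the TSV file.
#' @return \code{data.frame}.
#' @export
readPairing <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "subject", "timepoint")
  if (!all(need %in% names(df)))
    stop("pairing table needs columns: ", paste(need, collapse = ", "))
  df
}

# ES of one sample for one gene set.  rnk: within-sample ranks (highest
# expression = N); ord: walk order (descending expression, gene-name
# tie-break); inSet: logical along ord.
ssgseaOneSample <- function(rnk, ord, inSet, tau) {
  N <- length(ord)
  w <- rnk[ord]^tau
  w[!inSet] <- 0
  stepIn <- w / sum(w)
  stepOut <- as.numeric(!inSet) / (N - sum(inSet))
  sum(cumsum(stepIn) - cumsum(stepOut))
}

#' Single-sample gene-set enrichment scores
#'
#' For each sample independently, genes are ranked by expression
#' (average ranks on ties) and the ranked list is walked from the
#' highest-expressed gene down, accumulating the weighted empirical
#' cumulative distribution of the in-set genes (weights = rank^tau,
#' normalized) minus the uniform ECDF of the out-of-set genes; the
#' enrichment score is the sum of the running difference (integrated
#' deviation).  Scores depend only on within-sample ranks, so any
#' strictly increasing transform of a sample leaves its ES unchanged,
#' and editing one sample never changes another's score.
#'
#' @param expr numeric gene-by-sample matrix with gene symbols as
#'   rownames (duplicates collapsed by max, with a message).
#' @param geneSets one character vector, or a named list of them.
#' @param tau rank weight exponent (default 0.25, the single-sample
#'   convention; 0 gives the unweighted ECDF difference).
#' @return numeric matrix, gene sets in rows and samples in columns (a
#'   single gene set still yields a 1-row matrix).
#' @export
ssgseaScore <- function(expr, geneSets, tau = 0.25) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (nrow(expr) < 2) stop("need at least 2 genes")
  if (anyDuplicated(rownames(expr)) > 0) {
    genes <- rownames(expr)
    logMsg("collapsing ", sum(duplicated(genes)),
           " duplicate gene row(s) by per-sample max")
    expr <- do.call(rbind, lapply(split(seq_len(nrow(expr)), genes),
                                  function(ix)
      apply(expr[ix, , drop = FALSE], 2, max)))
  }
  if (!is.list(geneSets)) geneSets <- list(gene_set = geneSets)
  stopifnot(!is.null(names(geneSets)))
  genes <- rownames(expr)
  N <- length(genes)
  setIdx <- lapply(geneSets, function(s) which(genes %in% s))
  for (nm in names(setIdx)) {
    if (length(setIdx[[nm]]) == 0)
      stop("gene set ", nm, " shares no gene with the matrix")
    if (length(setIdx[[nm]]) == N)
      stop("gene set ", nm, " covers every gene; out-of-set ECDF undefined")
  }
  out <- matrix(NA_real_, length(geneSets), ncol(expr),
                dimnames = list(names(geneSets), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    x <- expr[, j]
    rnk <- rank(x, ties.method = "average")
    ord <- order(-x, genes)
    for (nm in names(setIdx)) {
      inSet <- ord %in% setIdx[[nm]]
      out[nm, j] <- ssgseaOneSample(rnk, ord, inSet, tau)
    }
  }
  out
}

#' Per-subject enrichment-score change under treatment
#'
#' Joins a gene-set-by-sample ES table with a before/after pairing and
#' returns \eqn{\Delta ES = ES_{after} - ES_{before}} per subject and
#' gene set; any \code{group} labels (e.g. improver flags) are passed
#' through untouched.
#'
#' @param scores matrix from \code{\link{ssgseaScore}}.
#' @param pairing \code{data.frame} with columns \code{sample},
#'   \code{subject}, \code{timepoint} and optionally \code{group}.
#' @return \code{data.frame} with columns \code{gene_set},
#'   \code{subject}, \code{es_before}, \code{es_after}, \code{delta}
#'   (and \code{group} if supplied).
#' @export
pairedDelta <- function(scores, pairing) {
  stopifnot(is.matrix(scores))
  need <- c("sample", "subject", "timepoint")
  if (!all(need %in% names(pairing)))
    stop("pairing needs columns: ", paste(need, collapse = ", "))
  missing <- setdiff(pairing$sample, colnames(scores))
  if (length(missing) > 0)
    stop("samples in pairing but not scored: ",
         paste(missing, collapse = ", "))
  bad <- character(0)
  for (subj in unique(pairing$subject)) {
    tp <- pairing$timepoint[pairing$subject == subj]
    if (sum(tp == "before") != 1 || sum(tp == "after") != 1)
      bad <- c(bad, subj)
  }
  if (length(bad) > 0)
    stop("subjects without exactly one before and one after sample: ",
         paste(bad, collapse = ", "))
  subjects <- unique(pairing$subject)
  rows <- lapply(subjects, function(subj) {
    sb <- pairing$sample[pairing$subject == subj &
                           pairing$timepoint == "before"]
    sa <- pairing$sample[pairing$subject == subj &
                           pairing$timepoint == "after"]
    df <- data.frame(
      gene_set = rownames(scores), subject = subj,
      es_before = scores[, sb], es_after = scores[, sa],
      delta = scores[, sa] - scores[, sb],
      stringsAsFactors = FALSE, row.names = NULL)
    if ("group" %in% names(pairing))
      df$group <- pairing$group[pairing$subject == subj][1]
    df
  })
  do.call(rbind, rows)
}
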