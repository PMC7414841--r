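# Validation of a DIAMOnD ranking against orthogonal gene sets: per-gene
# hit scoring, sliding-window significance, and the stopping rule that
# fixes the module boundary.

#' Score ranked genes against validation gene sets
#'
#' A ranked gene counts as a hit when it belongs to at least one of the
#' validation sources (expression-derived gene lists, pathway or GO sets
#' judged relevant on independent grounds) — i.e. to the union of the
#' sources.
#'
#' @param ranking \code{data.frame} from \code{\link{runDiamond}} or a
#'   character vector of ranked genes.
#' @param validationSets named list of character vectors (>= 1 source).
#' @return \code{data.frame} with columns \code{iteration}, \code{gene},
#'   \code{hit} (0/1) and \code{cumulative_hits}.
#' @export
scoreHits <- function(ranking, validationSets) {
  genes <- if (is.data.frame(ranking)) ranking$gene else as.character(ranking)
  if (length(genes) == 0) stop("empty ranking")
  stopifnot(is.list(validationSets), length(validationSets) >= 1)
  members <- unique(unlist(validationSets, use.names = FALSE))
  hit <- as.integer(genes %in% members)
  data.frame(iteration = seq_along(genes), gene = genes, hit = hit,
             cumulative_hits = cumsum(hit), stringsAsFactors = FALSE)
}

#' Sliding-window significance of the hit sequence
#'
#' At each iteration i, the window covers ranked genes in
#' [i - floor(w/2), i + floor(w/2)], truncated (never padded) at the ends
#' of the ranking; a window of the seed-set size makes consecutive
#' windows comparable.  Significance of the window hit count is, by
#' default, the one-sided binomial tail against the expected background
#' hit rate (the fraction of all interactome genes belonging to the
#' validation union); \code{mode = "fisher"} instead tests the window
#' against the rest of the ranking with a one-sided hypergeometric
#' (Fisher 2x2) test.
#'
#' @param hits 0/1 vector, or the \code{data.frame} from
#'   \code{\link{scoreHits}}.
#' @param windowSize window width w >= 1 (the published protocol uses the
#'   seed-set size).
#' @param backgroundRate expected hit probability in (0, 1); required for
#'   \code{mode = "binomial"}.
#' @param mode \code{"binomial"} (default) or \code{"fisher"}.
#' @return \code{data.frame} with columns \code{iteration},
#'   \code{window_lo}, \code{window_hi}, \code{hits_in_window},
#'   \code{window_size}, \code{p_window}.
#' @export
slidingWindowStats <- function(hits, windowSize, backgroundRate = NULL,
                               mode = c("binomial", "fisher")) {
  mode <- match.arg(mode)
  if (is.data.frame(hits)) hits <- hits$hit
  hits <- as.integer(hits)
  L <- length(hits)
  windowSize <- as.integer(windowSize)
  if (windowSize < 1) stop("windowSize must be >= 1")
  if (mode == "binomial") {
    if (is.null(backgroundRate) || backgroundRate <= 0 ||
        backgroundRate >= 1)
      stop("binomial mode needs backgroundRate in (0, 1)")
  }
  half <- windowSize %/% 2L
  lo <- pmax(1L, seq_len(L) - half)
  hi <- pmin(L, seq_len(L) + half)
  cs <- c(0L, cumsum(hits))
  h <- cs[hi + 1L] - cs[lo]
  n <- hi - lo + 1L
  p <- if (mode == "binomial") {
    stats::pbinom(h - 1L, n, backgroundRate, lower.tail = FALSE)
  } else {
    totalHits <- sum(hits)
    stats::phyper(h - 1L, totalHits, L - totalHits, n,
                  lower.tail = FALSE)
  }
  data.frame(iteration = seq_len(L), window_lo = lo, window_hi = hi,
             hits_in_window = h, window_size = n, p_window = p)
}

#' Stopping iteration from the window p-value sequence
#'
#' Operationalizes "no further significant gain": scanning the window
#' p-values in ranking order, the module boundary is the last significant
#' window before the first run of \code{patience} consecutive
#' non-significant windows.  If no such run occurs, the last significant
#' window is returned (the full ranking length when every window is
#' significant); if no window is ever significant, 0 with a warning.
#'
#' @param windowStats \code{data.frame} from
#'   \code{\link{slidingWindowStats}} (or a numeric p-value vector).
#' @param pThreshold significance level (default 0.05).
#' @param patience run length of non-significant windows that closes the
#'   module (default: the window size).
#' @return integer stopping iteration.
#' @export
stoppingIteration <- function(windowStats, pThreshold = 0.05,
                              patience = NULL) {
  p <- if (is.data.frame(windowStats)) windowStats$p_window
       else as.numeric(windowStats)
  if (length(p) == 0) stop("empty window statistics")
  if (is.null(patience)) {
    patience <- if (is.data.frame(windowStats))
      max(windowStats$window_size) else length(p)
  }
  patience <- max(1L, as.integer(patience))
  sig <- p <= pThreshold
  if (!any(sig)) {
    warning("no window ever significant at ", pThreshold,
            "; returning 0")
    return(0L)
  }
  runStart <- NA_integer_
  run <- 0L
  for (i in seq_along(sig)) {
    if (!sig[i]) {
      run <- run + 1L
      if (run == patience) {
        runStart <- i - patience + 1L
        break
      }
    } else {
      run <- 0L
    }
  }
  if (is.na(runStart)) return(max(which(sig)))
  before <- which(sig[seq_len(runStart - 1L)])
  if (length(before) == 0) {
    warning("non-significant from the start; returning 0")
    return(0L)
  }
  max(before)
}
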