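# Gene-set I/O.  Collections are plain named lists of character vectors
# (the fgsea convention); GMT descriptions are kept in a "description"
# attribute per element.

#' Read gene sets from a GMT file
#'
#' GMT: one set per line, tab-separated, fields set-name, description,
#' then members.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors; each element carries its GMT
#'   description as attribute \code{"description"}.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) stop("no gene sets in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0)
    stop("malformed GMT line ", bad[1], " in ", path,
         ": need name, description and at least one member")
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids) > 0)
    stop("duplicate gene-set ids in ", path, ": ",
         ids[duplicated(ids)][1])
  sets <- lapply(parts, function(p) {
    members <- unique(p[-(1:2)])
    members <- members[nzchar(members)]
    attr(members, "description") <- p[2]
    members
  })
  names(sets) <- ids
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors (optional
#'   \code{"description"} attributes are honoured).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(id) {
    desc <- attr(sets[[id]], "description") %||% id
    paste(c(id, desc, as.character(sets[[id]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a single-column gene list
#'
#' One symbol per line; \code{#} comments and blank lines ignored.
#'
#' @param path path to the file.
#' @return character vector of unique gene symbols.
#' @export
readGeneList <- function(path) {
  if (!file.exists(path)) stop("gene-list file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  genes <- lines[!grepl("^(#|$)", lines)]
  unique(genes)
}

#' Read a drug-to-target map
#'
#' TSV with columns \code{drug_id} and \code{target_symbol}, one pair per
#' row (header optional, detected by name).
#'
#' @param path path to the TSV file.
#' @return named list: drug id to character vector of target symbols.
#' @export
readDrugTargets <- function(path) {
  if (!file.exists(path)) stop("drug-target file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("drug-target file needs two columns (drug_id, target_symbol)")
  if (identical(tolower(df[1, 1]), "drug_id")) df <- df[-1, , drop = FALSE]
  split(as.character(df[[2]]), as.character(df[[1]]))
}

#' Write a drug-to-target map
#'
#' @param drugs named list of character target vectors.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDrugTargets <- function(drugs, path) {
  df <- data.frame(
    drug_id = rep(names(drugs), lengths(drugs)),
    target_symbol = unlist(drugs, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
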