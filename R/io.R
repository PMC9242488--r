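#' Read a response matrix from a wide CSV/TSV file
#'
#' Expected layout: header row of item ids, first column holding the
#' respondent id, one row per respondent.  Entries must be 0/1 (or 0/1/2 if
#' `dichotomize = TRUE`) or the declared missing token.
#'
#' @param path file path.
#' @param informant informant tag, see [response_matrix()].
#' @param sep field separator (`","` or `"\t"`).
#' @param na_token token that marks a missing response (default `"NA"`).
#' @param dichotomize collapse 0/1/2 responses to 0/1 via [dichotomize()]?
#' @return A [response_matrix()].
#' @export
read_response_matrix <- function(path, informant = "other", sep = ",",
                                 na_token = "NA", dichotomize = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          na.strings = character(0))
  if (ncol(df) < 3L)
    stop("expected a respondent-id column plus at least 2 item columns in ",
         path, call. = FALSE)
  ids <- df[[1]]
  raw <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(ifelse(raw == na_token, NA, as.numeric(raw)))
  unparsed <- is.na(vals) & raw != na_token
  if (any(unparsed)) {
    w <- which(unparsed, arr.ind = TRUE)[1, ]
    stop(sprintf("unrecognized token '%s' at row %d, column '%s' of %s (missing token is '%s')",
                 raw[unparsed][1], w[1], colnames(raw)[w[2]], path, na_token),
         call. = FALSE)
  }
  rownames(vals) <- ids
  if (dichotomize) dichotomize(vals, informant = informant)
  else response_matrix(vals, respondent_ids = ids, colnames(vals),
                       informant = informant)
}

#' Write a response matrix to a wide CSV/TSV file
#'
#' Inverse of [read_response_matrix()]; a read of the written file restores
#' values, missingness mask and ids exactly.
#'
#' @param m a [response_matrix()].
#' @param path file path.
#' @param sep field separator.
#' @param na_token token written for missing responses.
#' @return `path`, invisibly.
#' @export
write_response_matrix <- function(m, path, sep = ",", na_token = "NA") {
  stopifnot(inherits(m, "response_matrix"))
  df <- data.frame(respondent_id = m$respondent_ids, m$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, na = na_token, row.names = FALSE,
                     quote = TRUE)
  invisible(path)
}

#' Read an item-to-syndrome map from a two-column CSV
#'
#' @param path CSV with columns `item_id`, `syndrome`; syndrome `"none"` (or
#'   empty) marks unassigned items.
#' @param sep field separator.
#' @return A [syndrome_map()].
#' @export
read_syndrome_map <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          na.strings = character(0))
  if (ncol(df) < 2L)
    stop("expected columns item_id, syndrome in ", path, call. = FALSE)
  syn <- df[[2]]
  syn[syn == "" | is.na(syn)] <- "none"
  syndrome_map(data.frame(item_id = df[[1]], syndrome = syn))
}

#' Write an item-to-syndrome map
#'
#' @param syndromes a [syndrome_map()].
#' @param path file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_syndrome_map <- function(syndromes, path, sep = ",") {
  df <- data.frame(item_id = names(syndromes$assignments),
                   syndrome = unname(syndromes$assignments))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read and align a paired-informant dataset
#'
#' Reads two response-matrix files and a syndrome-map file and harmonizes
#' them by id: columns are matched on item id and rows on respondent id
#' (file order is irrelevant), so both instruments end up with the same
#' item and respondent order.
#'
#' @param path_a,path_b response-matrix files (see [read_response_matrix()]).
#' @param path_syndromes syndrome-map file (see [read_syndrome_map()]).
#' @param informant_a,informant_b informant tags for the two files.
#' @param sep,na_token file dialect, shared by the two response files.
#' @param dichotomize collapse 0/1/2 responses to 0/1?
#' @return A [paired_dataset()].
#' @export
read_paired_dataset <- function(path_a, path_b, path_syndromes,
                                informant_a = "parent", informant_b = "self",
                                sep = ",", na_token = "NA",
                                dichotomize = FALSE) {
  a <- read_response_matrix(path_a, informant_a, sep, na_token, dichotomize)
  b <- read_response_matrix(path_b, informant_b, sep, na_token, dichotomize)
  if (!setequal(a$item_ids, b$item_ids)) {
    off <- c(setdiff(a$item_ids, b$item_ids), setdiff(b$item_ids, a$item_ids))
    stop("item ids do not match between the two files: ",
         paste(utils::head(off, 10), collapse = ", "), call. = FALSE)
  }
  if (!setequal(a$respondent_ids, b$respondent_ids)) {
    off <- c(setdiff(a$respondent_ids, b$respondent_ids),
             setdiff(b$respondent_ids, a$respondent_ids))
    stop("respondent ids do not match between the two files: ",
         paste(utils::head(off, 10), collapse = ", "), call. = FALSE)
  }
  b <- response_matrix(b$values[a$respondent_ids, a$item_ids, drop = FALSE],
                       a$respondent_ids, a$item_ids, informant = b$informant)
  paired_dataset(a, b, read_syndrome_map(path_syndromes, sep = sep))
}
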