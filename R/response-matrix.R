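#' Binary respondent-by-item response matrix
#'
#' Container for a dichotomous questionnaire response matrix: respondents in
#' rows, items in columns, entries 0/1 or `NA` for missing, with unique
#' respondent and item labels and an informant tag (who filled the form in:
#' the parent, the child themselves, or another reporter).
#'
#' @param values numeric or integer matrix with entries in \{0, 1\} or `NA`.
#' @param respondent_ids character vector of unique respondent labels;
#'   defaults to existing rownames or `"R1"..."RN"`.
#' @param item_ids character vector of unique item labels; defaults to
#'   existing colnames or `"Item 1"..."Item P"`.
#' @param informant one of `"parent"`, `"self"`, `"other"`.
#' @return An object of class `"response_matrix"`: a list with elements
#'   `values` (matrix with dimnames), `respondent_ids`, `item_ids`,
#'   `informant`.
#' @seealso [dichotomize()], [positive_rate()], [read_response_matrix()]
#' @export
response_matrix <- function(values, respondent_ids = NULL, item_ids = NULL,
                            informant = c("parent", "self", "other")) {
  informant <- match.arg(informant)
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(respondent_ids)) {
    respondent_ids <- rownames(values)
    if (is.null(respondent_ids)) respondent_ids <- paste0("R", seq_len(nrow(values)))
  }
  if (is.null(item_ids)) {
    item_ids <- colnames(values)
    if (is.null(item_ids)) item_ids <- paste("Item", seq_len(ncol(values)))
  }
  respondent_ids <- as.character(respondent_ids)
  item_ids <- as.character(item_ids)
  if (length(respondent_ids) != nrow(values))
    stop("'respondent_ids' must have one entry per row", call. = FALSE)
  if (length(item_ids) != ncol(values))
    stop("'item_ids' must have one entry per column", call. = FALSE)
  if (anyDuplicated(respondent_ids))
    stop("respondent ids must be unique", call. = FALSE)
  if (anyDuplicated(item_ids))
    stop("item ids must be unique", call. = FALSE)
  bad <- !is.na(values) & !(values %in% c(0L, 1L))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-binary entry %s at row '%s', column '%s'",
                 values[bad][1], respondent_ids[w[1]], item_ids[w[2]]),
         call. = FALSE)
  }
  dimnames(values) <- list(respondent_ids, item_ids)
  structure(list(values = values, respondent_ids = respondent_ids,
                 item_ids = item_ids, informant = informant),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("Binary response matrix (%s report): %d respondents x %d items\n",
              x$informant, nrow(v), ncol(v)))
  nm <- sum(is.na(v))
  cat(sprintf("  positive rate %.3f, %d missing cells (%.3f%%)\n",
              mean(v, na.rm = TRUE), nm, 100 * nm / length(v)))
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$values)

#' Dichotomize trichotomous questionnaire responses
#'
#' Collapses the three ordered response categories 0 ("not true"),
#' 1 ("somewhat or sometimes true") and 2 ("very true or often true") to
#' binary by merging the two positive categories: 0 stays 0, 1 and 2 become
#' 1, and missing entries stay missing.
#'
#' @param raw matrix (or `response_matrix`) with entries in \{0, 1, 2\} or `NA`.
#' @param ... passed to [response_matrix()] (`respondent_ids`, `item_ids`,
#'   `informant`).
#' @return A [response_matrix()].
#' @export
dichotomize <- function(raw, ...) {
  args <- list(...)
  if (inherits(raw, "response_matrix")) {
    if (is.null(args$respondent_ids)) args$respondent_ids <- raw$respondent_ids
    if (is.null(args$item_ids)) args$item_ids <- raw$item_ids
    if (is.null(args$informant)) args$informant <- raw$informant
    raw <- raw$values
  }
  raw <- as.matrix(raw)
  bad <- !is.na(raw) & !(raw %in% c(0, 1, 2))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid response category %s at row %d, column %d: expected 0, 1, 2 or NA",
                 format(raw[bad][1]), w[1], w[2]), call. = FALSE)
  }
  do.call(response_matrix, c(list(values = ifelse(is.na(raw), NA, as.integer(raw >= 1))),
                             args))
}

#' Proportion of positive responses
#'
#' Mean of the non-missing entries of a binary response matrix; missing cells
#' are excluded from both numerator and denominator.  Optionally returns
#' per-item and per-respondent rates as well.
#'
#' @param m a [response_matrix()] or plain 0/1 matrix.
#' @param by one of `"overall"`, `"item"`, `"respondent"`.
#' @return A proportion in \[0, 1\], or a named vector of proportions.
#' @export
positive_rate <- function(m, by = c("overall", "item", "respondent")) {
  by <- match.arg(by)
  v <- if (inherits(m, "response_matrix")) m$values else as.matrix(m)
  if (all(is.na(v)))
    stop("all entries are missing; positive rate is undefined", call. = FALSE)
  switch(by,
         overall = mean(v, na.rm = TRUE),
         item = colMeans(v, na.rm = TRUE),
         respondent = rowMeans(v, na.rm = TRUE))
}

#' Item-to-syndrome membership table
#'
#' Records which syndrome scale (subscale) each item belongs to.  The eight
#' standard syndromes of the CBCL/YSR family are Aggressive Behavior (AB),
#' Anxious/Depressed (AD), Attention Problems (AP), Rule-Breaking Behavior
#' (RBB), Somatic Complaints (SC), Social Problems (SP), Thought Problems
#' (TP) and Withdrawn/Depressed (WD); AD, WD and SC form the internalizing
#' (INT) pole and RBB and AB the externalizing (EXT) pole.  Items may
#' legitimately belong to no syndrome (`"none"`).
#'
#' @param assignments named character vector or two-column data frame
#'   (`item_id`, `syndrome`) mapping item ids to syndrome labels; `"none"`
#'   (or `NA`) marks unassigned items.
#' @param syndrome_order canonical ordering of the syndrome labels used in
#'   all reports.
#' @return An object of class `"syndrome_map"` with elements `assignments`
#'   (named character vector), `syndrome_order`, and the derived higher-order
#'   groups `internalizing` and `externalizing`.
#' @export
syndrome_map <- function(assignments,
                         syndrome_order = c("AB", "AD", "AP", "RBB",
                                            "SC", "SP", "TP", "WD")) {
  if (is.data.frame(assignments)) {
    a <- as.character(assignments[[2]])
    names(a) <- as.character(assignments[[1]])
    assignments <- a
  }
  if (is.null(names(assignments)))
    stop("'assignments' must be named by item id", call. = FALSE)
  if (anyDuplicated(names(assignments)))
    stop("each item may appear at most once in a syndrome map", call. = FALSE)
  assignments <- as.character2(assignments)
  assignments[is.na(assignments)] <- "none"
  unknown <- setdiff(unique(assignments), c(syndrome_order, "none"))
  if (length(unknown))
    stop("unknown syndrome label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  structure(list(assignments = assignments,
                 syndrome_order = syndrome_order,
                 internalizing = intersect(c("AD", "WD", "SC"), syndrome_order),
                 externalizing = intersect(c("RBB", "AB"), syndrome_order)),
            class = "syndrome_map")
}

# as.character that keeps names (base as.character drops them)
as.character2 <- function(x) {
  y <- as.character(x)
  names(y) <- names(x)
  y
}

#' @export
print.syndrome_map <- function(x, ...) {
  tab <- table(factor(x$assignments, levels = c(x$syndrome_order, "none")))
  cat("Syndrome map:", length(x$assignments), "items\n")
  print(tab)
  invisible(x)
}

#' Member items of one syndrome
#'
#' @param syndromes a [syndrome_map()].
#' @param label a syndrome label.
#' @return Character vector of item ids.
#' @export
syndrome_items <- function(syndromes, label) {
  names(syndromes$assignments)[syndromes$assignments == label]
}

#' Paired-informant dataset
#'
#' Binds two response matrices collected with the same items on the same
#' children from two informants (e.g. parent-report and self-report), plus
#' the item-to-syndrome map.  Respondent and item indices must agree: row k
#' of both matrices concerns the same child, column i the same item.
#'
#' @param a,b [response_matrix()] objects with identical `item_ids` and
#'   `respondent_ids` (order included).
#' @param syndromes a [syndrome_map()] covering (at least) the shared items.
#' @return An object of class `"paired_dataset"`.
#' @export
paired_dataset <- function(a, b, syndromes) {
  stopifnot(inherits(a, "response_matrix"), inherits(b, "response_matrix"),
            inherits(syndromes, "syndrome_map"))
  if (!identical(a$item_ids, b$item_ids))
    stop("the two instruments must share identical item ids in identical order",
         call. = FALSE)
  if (!identical(a$respondent_ids, b$respondent_ids))
    stop("the two instruments must cover identical respondents in identical order",
         call. = FALSE)
  missing_items <- setdiff(a$item_ids, names(syndromes$assignments))
  if (length(missing_items))
    stop("items absent from the syndrome map: ",
         paste(utils::head(missing_items, 5), collapse = ", "), call. = FALSE)
  structure(list(a = a, b = b, syndromes = syndromes),
            class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf("Paired informant dataset: %d respondents x %d items\n",
              nrow(x$a$values), ncol(x$a$values)))
  cat(sprintf("  a: %s report, positive rate %.3f\n", x$a$informant,
              positive_rate(x$a)))
  cat(sprintf("  b: %s report, positive rate %.3f\n", x$b$informant,
              positive_rate(x$b)))
  invisible(x)
}
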