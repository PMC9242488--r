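#' Syndrome-level sum scores
#'
#' Per-respondent sum of the binary responses to each syndrome's member
#' items; missing items are dropped from the sum and the per-cell count of
#' items actually available is recorded.  Unassigned items (`"none"`)
#' contribute to no syndrome.
#'
#' @param m a [response_matrix()] (dichotomized).
#' @param syndromes a [syndrome_map()].
#' @return A list of class `"syndrome_scores"`: `scores` (N x K matrix),
#'   `n_available` (N x K count of non-missing member items), `n_items`
#'   (member-item count per syndrome).
#' @export
syndrome_sum_scores <- function(m, syndromes) {
  stopifnot(inherits(m, "response_matrix"), inherits(syndromes, "syndrome_map"))
  labs <- syndromes$syndrome_order
  keep <- labs[vapply(labs, function(s)
    length(intersect(syndrome_items(syndromes, s), m$item_ids)) > 0, NA)]
  scores <- avail <- matrix(0L, nrow(m$values), length(keep),
                            dimnames = list(m$respondent_ids, keep))
  n_items <- integer(length(keep)); names(n_items) <- keep
  for (s in keep) {
    members <- intersect(syndrome_items(syndromes, s), m$item_ids)
    n_items[s] <- length(members)
    sub <- m$values[, members, drop = FALSE]
    scores[, s] <- as.integer(rowSums(sub, na.rm = TRUE))
    avail[, s] <- as.integer(rowSums(!is.na(sub)))
  }
  structure(list(scores = scores, n_available = avail, n_items = n_items),
            class = "syndrome_scores")
}

#' Between-informant syndrome score correlations
#'
#' Pearson correlation, per syndrome, of the syndrome sum scores of the two
#' instruments over the paired respondents.  A zero-variance score column
#' yields `NA` with a warning rather than a silent value.
#'
#' @param scores_a,scores_b [syndrome_sum_scores()] results on the paired
#'   instruments.
#' @return Named numeric vector of correlations, one per shared syndrome.
#' @export
syndrome_correlations <- function(scores_a, scores_b) {
  stopifnot(inherits(scores_a, "syndrome_scores"),
            inherits(scores_b, "syndrome_scores"))
  shared <- intersect(colnames(scores_a$scores), colnames(scores_b$scores))
  out <- stats::setNames(rep(NA_real_, length(shared)), shared)
  for (s in shared) {
    x <- scores_a$scores[, s]; y <- scores_b$scores[, s]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("zero-variance sum score for syndrome '", s,
              "'; correlation undefined")
    } else {
      out[s] <- stats::cor(x, y)
    }
  }
  out
}

# Unweighted Cohen's kappa from paired binary vectors (pairwise-complete)
kappa_binary <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n == 0) return(NA_real_)
  po <- mean(x == y)
  pe <- mean(x) * mean(y) + mean(1 - x) * mean(1 - y)
  if (abs(1 - pe) < .Machine$double.eps^0.5) return(NA_real_)  # degenerate marginals
  (po - pe) / (1 - pe)
}

#' Item-level Cohen's kappa between informants
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` per item
#' between the two instruments, computed over respondents with both
#' responses observed (pairwise-complete deletion), plus the mean kappa per
#' syndrome.  Items with degenerate marginals (`p_e = 1`) get `NA`.
#'
#' @param a,b paired [response_matrix()] objects (same respondents/items).
#' @param syndromes optional [syndrome_map()] for the per-syndrome means.
#' @return A list with `kappa` (named per-item vector) and, when
#'   `syndromes` is given, `syndrome_mean` (named per-syndrome mean of the
#'   item-level coefficients).
#' @export
item_kappa <- function(a, b, syndromes = NULL) {
  stopifnot(inherits(a, "response_matrix"), inherits(b, "response_matrix"))
  if (!identical(a$item_ids, b$item_ids) ||
      !identical(a$respondent_ids, b$respondent_ids))
    stop("instruments must be paired on identical respondents and items",
         call. = FALSE)
  kap <- vapply(seq_along(a$item_ids), function(i)
    kappa_binary(a$values[, i], b$values[, i]), 0)
  names(kap) <- a$item_ids
  out <- list(kappa = kap)
  if (!is.null(syndromes)) {
    labs <- syndromes$syndrome_order
    out$syndrome_mean <- stats::setNames(vapply(labs, function(s) {
      members <- intersect(syndrome_items(syndromes, s), a$item_ids)
      if (!length(members)) NA_real_ else mean(kap[members], na.rm = TRUE)
    }, 0), labs)
  }
  out
}

#' Jaccard similarity matrix of item response vectors
#'
#' `J(A, B) = |A intersect B| / |A union B|` over the positive-response
#' sets of two item columns.  Missing responses are treated as negative
#' (absent), with the affected-cell count recorded; pairs whose union is
#' empty (two all-zero columns) are undefined and returned as `NA`.
#'
#' @param m a [response_matrix()].
#' @return A list with `J` (P x P symmetric matrix, unit diagonal for
#'   nonempty columns) and `n_missing_as_zero`.
#' @export
jaccard_similarity <- function(m) {
  stopifnot(inherits(m, "response_matrix"))
  v <- m$values
  n_miss <- sum(is.na(v))
  v[is.na(v)] <- 0L
  inter <- crossprod(v)                      # |A & B|
  ones <- colSums(v)
  uni <- outer(ones, ones, "+") - inter      # |A | B|
  J <- ifelse(uni > 0, inter / uni, NA_real_)
  dimnames(J) <- list(m$item_ids, m$item_ids)
  list(J = J, n_missing_as_zero = n_miss)
}

#' Jaccard similarity difference between informants
#'
#' Within-instrument item-pair Jaccard similarity for each instrument and
#' their difference (`J_b - J_a`), with the pairs ranked by absolute
#' difference — the conventional direct dyadic comparison.  Pairs undefined
#' in either instrument are flagged and excluded from the ranking.
#'
#' @param a,b paired [response_matrix()] objects.
#' @param top_k number of top-ranked pairs returned (default 12).
#' @return A list with `difference` (P x P matrix `J_b - J_a`), `J_a`,
#'   `J_b`, `top_pairs` (data frame of the `top_k` largest absolute
#'   differences), `undefined_pairs` (count excluded).
#' @export
jaccard_difference <- function(a, b, top_k = 12) {
  stopifnot(inherits(a, "response_matrix"), inherits(b, "response_matrix"))
  if (!identical(a$item_ids, b$item_ids))
    stop("instruments must share identical item ids", call. = FALSE)
  ja <- jaccard_similarity(a)$J
  jb <- jaccard_similarity(b)$J
  dif <- jb - ja
  ut <- which(upper.tri(dif), arr.ind = TRUE)
  vals <- dif[ut]
  ok <- !is.na(vals)
  ord <- order(-abs(vals[ok]))
  idx <- ut[ok, , drop = FALSE][ord, , drop = FALSE]
  top <- data.frame(item_i = a$item_ids[idx[, 1]],
                    item_j = a$item_ids[idx[, 2]],
                    J_a = ja[idx], J_b = jb[idx],
                    difference = dif[idx])
  list(difference = dif, J_a = ja, J_b = jb,
       top_pairs = utils::head(top, top_k),
       undefined_pairs = sum(!ok))
}
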