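#' Orthogonal Procrustes fit of one configuration onto another
#'
#' Finds the rigid motion (rotation and/or reflection plus translation, no
#' scaling) minimizing the squared Frobenius residual between a transformed
#' configuration `X` and a fixed target `X0`: the classical orthogonal
#' Procrustes solution via the singular value decomposition of the centered
#' cross-product.  Both matrices are M x d with rows in correspondence.
#'
#' @param X configuration to transform.
#' @param X0 target configuration.
#' @return A list of class `"rigid_transform"`: `rotation` (d x d orthogonal
#'   matrix `T`, determinant +1 or -1), `translation` (length-d vector `t`),
#'   `residual` (minimized squared residual), such that the aligned
#'   configuration is `X %*% T + t` (rowwise).
#' @export
procrustes_fit <- function(X, X0) {
  X <- as.matrix(X); X0 <- as.matrix(X0)
  if (!identical(dim(X), dim(X0)))
    stop("configurations must have identical dimensions", call. = FALSE)
  cX <- colMeans(X); c0 <- colMeans(X0)
  Xc <- sweep(X, 2, cX); X0c <- sweep(X0, 2, c0)
  M <- crossprod(Xc, X0c)
  sv <- svd(M)
  if (min(sv$d) < 1e-12 * max(sv$d, 1))
    warning("rank-deficient cross-product; Procrustes rotation may be non-unique")
  rot <- sv$u %*% t(sv$v)
  transl <- as.numeric(c0 - cX %*% rot)
  aligned <- X %*% rot + rep(transl, each = nrow(X))
  structure(list(rotation = rot, translation = transl,
                 residual = sum((X0 - aligned)^2)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("Rigid transform (det %+.0f), residual %.4g\n",
              det(x$rotation), x$residual))
  invisible(x)
}

#' Apply a rigid transform to a configuration
#'
#' @param transform a `"rigid_transform"` from [procrustes_fit()].
#' @param X M x d configuration.
#' @return The transformed M x d configuration `X T + t`.
#' @export
apply_transform <- function(transform, X) {
  X <- as.matrix(X)
  X %*% transform$rotation + rep(transform$translation, each = nrow(X))
}

#' Procrustes-align the retained draws of a chain
#'
#' Latent positions are identified only up to rotation, reflection and
#' translation, so raw draws from different sweeps live in arbitrary
#' frames.  This post-processing fixes the frame: the stacked item and
#' respondent positions of the maximum-a-posteriori retained draw serve as
#' the target, and every other draw's stacked positions are mapped onto it
#' by their fitted rigid transform.  Intercepts, traits and the trait
#' variance are untouched, and all within-draw distances are preserved
#' exactly (rigid motions are isometries).
#'
#' @param fit an unaligned [lsirm()] fit.
#' @return The fit with aligned `W` and `Z` draws and `aligned = TRUE`.
#' @export
procrustes_align <- function(fit) {
  stopifnot(inherits(fit, "lsirm"))
  S <- n_draws(fit)
  if (S < 1) stop("empty chain", call. = FALSE)
  m <- fit$map_index
  P <- dim(fit$W)[1]
  target <- rbind(fit$W[, , m], fit$Z[, , m])
  for (s in seq_len(S)) {
    if (s == m) next
    stacked <- rbind(fit$W[, , s], fit$Z[, , s])
    tr <- procrustes_fit(stacked, target)
    aligned <- apply_transform(tr, stacked)
    fit$W[, , s] <- aligned[seq_len(P), , drop = FALSE]
    fit$Z[, , s] <- aligned[-seq_len(P), , drop = FALSE]
  }
  fit$aligned <- TRUE
  fit
}

#' Match two fitted interaction maps into a common frame
#'
#' Estimates the rigid motion carrying the second model's posterior-mean
#' item positions onto the reference model's (items are the anchors: they
#' are the objects shared verbatim across the two instruments, while
#' respondent positions may genuinely differ by informant), then applies
#' that single transform to all of the second model's positions — item and
#' respondent posterior means and every retained draw — yielding an
#' integrated frame in which the two maps can be overlaid and compared.
#' Within-instrument distances are unchanged.
#'
#' @param reference an aligned [lsirm()] fit that defines the frame.
#' @param other an aligned [lsirm()] fit on the same items.
#' @return `other` with transformed positions; the fitted transform is
#'   attached as attribute `"match_transform"`.
#' @export
match_maps <- function(reference, other) {
  stopifnot(inherits(reference, "lsirm"), inherits(other, "lsirm"))
  if (!identical(reference$data$item_ids, other$data$item_ids))
    stop("the two fits must share identical item ids", call. = FALSE)
  if (!reference$aligned || !other$aligned)
    stop("both fits must be Procrustes-aligned before matching", call. = FALSE)
  tr <- procrustes_fit(other$W_mean, reference$W_mean)
  other$W_mean <- apply_transform(tr, other$W_mean)
  other$Z_mean <- apply_transform(tr, other$Z_mean)
  for (s in seq_len(n_draws(other))) {
    other$W[, , s] <- apply_transform(tr, other$W[, , s])
    other$Z[, , s] <- apply_transform(tr, other$Z[, , s])
  }
  attr(other, "match_transform") <- tr
  other
}
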