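## Fuzzy comprehensive evaluation of salt tolerance: min-max membership
## functions per indicator, correlation-matrix PCA of the memberships,
## contribution-rate weights, and the integrated D score with ranking.

#' Min-max membership values
#'
#' Maps each indicator column linearly onto [0,1]: positive-direction
#' indicators send the column minimum to 0 and maximum to 1; negative
#' indicators are reversed (min to 1, max to 0).
#'
#' @param matrix numeric matrix or data.frame, evaluation units in rows,
#'   indicators in columns.
#' @param directions character vector (\code{"positive"} or
#'   \code{"negative"}) per indicator; default all positive.
#' @return membership matrix of the same shape, entries in [0,1].
#' @examples
#' membershipValues(cbind(a = c(10, 20, 30)))            # 0, 0.5, 1
#' membershipValues(cbind(a = c(10, 20, 30)), "negative") # 1, 0.5, 0
#' @export
membershipValues <- function(matrix,
                             directions = rep("positive", ncol(matrix))) {
  X <- as.matrix(matrix)
  if (nrow(X) < 2) stop("need >= 2 evaluation units")
  if (length(directions) != ncol(X))
    stop("one direction per indicator required")
  if (!all(directions %in% c("positive", "negative")))
    stop("directions must be 'positive' or 'negative'")
  if (anyNA(X)) stop("missing cells not allowed")
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("ind", seq_len(ncol(X)))
  mu <- X
  for (j in seq_len(ncol(X))) {
    rng <- range(X[, j])
    if (rng[1] == rng[2])
      stop("degenerate input: indicator '", cn[j], "' is constant")
    mu[, j] <- (X[, j] - rng[1]) / (rng[2] - rng[1])
    if (directions[j] == "negative") mu[, j] <- 1 - mu[, j]
  }
  mu
}

#' Mean membership per evaluation unit
#'
#' Per-unit average of the membership values across indicators.
#'
#' @param memberships membership matrix from
#'   \code{\link{membershipValues}}.
#' @return numeric vector of per-unit means, in [0,1].
#' @export
aggregateMembership <- function(memberships) {
  M <- as.matrix(memberships)
  if (anyNA(M)) stop("missing cells not allowed")
  rowMeans(M)
}

#' Comprehensive indices by correlation-matrix PCA
#'
#' Principal component analysis of the (standardized) membership matrix.
#' Components with eigenvalue >= 1 are retained (Kaiser rule; at least
#' one).  Each retained component's sign is oriented so that the sum of
#' its loadings is nonnegative (in membership space every indicator points
#' in the positive direction), making scores reproducible.
#'
#' @param memberships membership matrix (units x indicators, >= 2 of each).
#' @return list: \code{scores} (units x retained components),
#'   \code{contributions} (percent variance of the retained components),
#'   \code{allContributions} (percent for every component; sums to 100),
#'   \code{loadings}.
#' @export
extractComprehensiveIndices <- function(memberships) {
  M <- as.matrix(memberships)
  if (nrow(M) < 2 || ncol(M) < 2)
    stop("need >= 2 units and >= 2 indicators")
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0))
    stop("degenerate input: constant indicator column(s): ",
         paste(colnames(M)[sds == 0], collapse = ", "))
  pc <- prcomp(M, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  contrib_all <- ev / sum(ev) * 100
  keep <- which(ev >= 1)
  if (!length(keep)) keep <- 1L
  rot <- pc$rotation[, keep, drop = FALSE]
  scores <- pc$x[, keep, drop = FALSE]
  for (j in seq_along(keep)) {           # deterministic sign convention
    if (sum(rot[, j]) < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- paste0("X", seq_along(keep))
  rownames(scores) <- rownames(M)
  list(scores = scores, contributions = contrib_all[keep],
       allContributions = contrib_all, loadings = rot)
}

#' Contribution-rate weights
#'
#' Normalizes the retained components' variance contributions to weights
#' summing to one: W_i = P_i / sum(P).
#'
#' @param contributions positive contribution rates (percent or fractions).
#' @return numeric weights summing to 1.
#' @examples
#' componentWeights(c(60, 20))  # 0.75 0.25
#' @export
componentWeights <- function(contributions) {
  if (!length(contributions)) stop("empty contribution list")
  if (any(contributions <= 0)) stop("contributions must be positive")
  contributions / sum(contributions)
}

#' Integrated salt-tolerance score D
#'
#' Maps each retained component's scores to [0,1] with the positive
#' min-max membership function, then combines them with the
#' contribution-rate weights: D = sum_i mu(X_i) W_i.  Ranks are assigned
#' by descending D with ties broken stably by unit order.
#'
#' @param scores units x components score matrix (e.g. from
#'   \code{\link{extractComprehensiveIndices}}).
#' @param weights weights from \code{\link{componentWeights}} (same number
#'   of components).
#' @param contributions optional raw contribution rates stored in the
#'   result (defaults to the weights as percentages).
#' @return A \linkS4class{ToleranceEvaluation}.
#' @examples
#' ts <- toleranceScore(cbind(X1 = c(-1, 0, 1)), weights = 1)
#' toleranceD(ts)  # 0, 0.5, 1
#' @export
toleranceScore <- function(scores, weights,
                           contributions = weights * 100) {
  S <- as.matrix(scores)
  if (nrow(S) < 2) stop("need >= 2 units")
  if (length(weights) != ncol(S))
    stop("one weight per component required")
  if (abs(sum(weights) - 1) > 1e-8)
    stop("weights must sum to 1 (use componentWeights)")
  units <- rownames(S)
  if (is.null(units)) units <- paste0("unit", seq_len(nrow(S)))
  mu <- S
  for (j in seq_len(ncol(S))) {
    rng <- range(S[, j])
    if (rng[1] == rng[2])
      stop("degenerate component ", j, ": constant scores")
    mu[, j] <- (S[, j] - rng[1]) / (rng[2] - rng[1])
  }
  D <- as.numeric(mu %*% weights)
  names(D) <- units
  ord <- order(-D, seq_along(D))
  rk <- integer(length(D))
  rk[ord] <- seq_along(D)
  new("ToleranceEvaluation", indices = S,
      contributions = as.numeric(contributions),
      weights = as.numeric(weights), memberships = mu, D = D,
      rank = rk)
}

#' Full fuzzy comprehensive evaluation
#'
#' Convenience chain: raw indicators -> min-max memberships -> PCA
#' comprehensive indices (Kaiser retention) -> contribution-rate weights
#' -> integrated D with ranking.
#'
#' @param indicators units x indicators matrix or data.frame of raw trait
#'   values (rownames = unit labels).
#' @param directions per-indicator direction flags (default all
#'   positive).
#' @return A \linkS4class{ToleranceEvaluation}.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(8 * 7), 8, 7,
#'             dimnames = list(LETTERS[1:8], paste0("t", 1:7)))
#' fuzzyToleranceEvaluation(X)
#' @export
fuzzyToleranceEvaluation <- function(indicators,
                                     directions =
                                       rep("positive", ncol(indicators))) {
  mu <- membershipValues(indicators, directions)
  pca <- extractComprehensiveIndices(mu)
  w <- componentWeights(pca$contributions)
  toleranceScore(pca$scores, w, contributions = pca$contributions)
}
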