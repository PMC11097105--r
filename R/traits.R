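## Shoot functional-trait metrics: derived leaf traits, coefficients of
## variation, one-way ANOVA reconstructed from group summaries, and
## pairwise Pearson trait correlations.

#' Derive per-shoot leaf metrics
#'
#' Adds specific leaf area (\code{sla = leaf_area / leaf_dry_weight},
#' cm^2/g) and leaf dry matter content (\code{ldmc}) columns.  The default
#' LDMC is the dimensionless dry-to-fresh mass ratio DW/FW; mode
#' \code{"paper-literal"} instead applies the expression
#' \code{1 - (FW - DW)/DW} verbatim for audit purposes (it is not a
#' fraction and can leave the unit interval).
#'
#' @param raw data.frame with positive columns \code{leaf_area},
#'   \code{leaf_dry_weight}, \code{fresh_weight}, \code{dry_weight}.
#' @param ldmcMode \code{"ratio"} (default, DW/FW) or
#'   \code{"paper-literal"}.
#' @return the input with \code{sla} and \code{ldmc} columns populated.
#' @examples
#' df <- data.frame(shoot = "s1", leaf_area = 30, leaf_dry_weight = 0.25,
#'                  fresh_weight = 2, dry_weight = 1)
#' deriveShootMetrics(df)[, c("sla", "ldmc")]  # 120, 0.5
#' @export
deriveShootMetrics <- function(raw, ldmcMode = c("ratio", "paper-literal")) {
  ldmcMode <- match.arg(ldmcMode)
  need <- c("leaf_area", "leaf_dry_weight", "fresh_weight", "dry_weight")
  missing_cols <- setdiff(need, colnames(raw))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  id <- if ("shoot" %in% colnames(raw)) raw$shoot else
    as.character(seq_len(nrow(raw)))
  for (cn in need) {
    bad <- which(!is.finite(raw[[cn]]) | raw[[cn]] <= 0)
    if (length(bad))
      stop("non-positive ", cn, " for shoot(s): ",
           paste(head(id[bad], 5), collapse = ", "))
  }
  bad <- which(raw$dry_weight > raw$fresh_weight)
  if (length(bad))
    stop("dry weight exceeds fresh weight for shoot(s): ",
         paste(head(id[bad], 5), collapse = ", "))
  raw$sla <- raw$leaf_area / raw$leaf_dry_weight
  raw$ldmc <- if (ldmcMode == "ratio")
    raw$dry_weight / raw$fresh_weight
  else
    1 - (raw$fresh_weight - raw$dry_weight) / raw$dry_weight
  raw
}

#' Coefficient of variation (percent)
#'
#' CV = sd/mean x 100.  Give either a numeric vector (sample SD, n-1
#' denominator) or a mean and SD directly.
#'
#' @param x numeric vector of raw values (ignored if \code{mean} given).
#' @param mean,sd summary statistics, used instead of \code{x} when
#'   supplied.
#' @return CV in percent.
#' @examples
#' coefficientOfVariation(mean = 199.56, sd = 54.33)  # 27.22
#' @export
coefficientOfVariation <- function(x = NULL, mean = NULL, sd = NULL) {
  if (is.null(mean)) {
    if (length(x) < 2) stop("need n >= 2 raw values")
    mean <- base::mean(x)
    sd <- stats::sd(x)
  }
  if (!is.finite(mean) || mean <= 0) stop("mean must be positive")
  if (sd < 0) stop("sd must be nonnegative")
  sd / mean * 100
}

#' Per-group trait summary
#'
#' Group-wise n, mean, sample SD and CV (percent) for one trait column.
#'
#' @param table data.frame of shoot records.
#' @param trait name of the numeric trait column.
#' @param group name of the grouping column (default \code{"site"}).
#' @return data.frame with columns group, n, mean, sd, cv.
#' @export
groupSummary <- function(table, trait, group = "site") {
  stopifnot(trait %in% colnames(table), group %in% colnames(table))
  sp <- split(table[[trait]], table[[group]])
  sp <- sp[unique(table[[group]])]      # preserve first-appearance order
  out <- data.frame(group = names(sp),
                    n = vapply(sp, length, 1L),
                    mean = vapply(sp, mean, 1),
                    sd = vapply(sp, stats::sd, 1),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$cv <- out$sd / out$mean * 100
  out
}

#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the omnibus F test from per-group means, sample SDs and
#' sizes: MS_between from the group means weighted by n, MS_within pooled
#' from the SDs; p from the F distribution with (k-1, sum(n_i - 1)) df.
#' Algebraically identical to a one-way ANOVA on the raw data.
#'
#' @param means,sds,ns numeric vectors of equal length (>= 2 groups,
#'   each n >= 2).
#' @return list with elements F, df_between, df_within, p.
#' @examples
#' anovaFromSummary(c(108.93, 115.20, 145.32, 199.56),
#'                  c(40.16, 17.27, 34.51, 54.33),
#'                  c(75, 25, 50, 50))$F  # about 52.77
#' @export
anovaFromSummary <- function(means, sds, ns) {
  k <- length(means)
  if (k < 2 || length(sds) != k || length(ns) != k)
    stop("need >= 2 groups with matching means, sds, ns")
  if (any(ns < 2)) stop("every group needs n >= 2")
  if (any(sds < 0)) stop("negative SD")
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((ns - 1) * sds^2)
  df_b <- k - 1L
  df_w <- as.integer(N - k)
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  if (ms_w == 0) {
    F <- if (ms_b == 0) 0 else Inf
    p <- if (ms_b == 0) 1 else 0
  } else {
    F <- ms_b / ms_w
    p <- pf(F, df_b, df_w, lower.tail = FALSE)
  }
  list(F = F, df_between = df_b, df_within = df_w, p = p)
}

#' Pairwise Pearson trait correlations
#'
#' Symmetric correlation matrix with two-sided p-values for each trait
#' pair.  A constant trait yields NA entries and a warning naming the
#' trait rather than a silent zero.
#'
#' @param table data.frame of shoot records.
#' @param traits character vector of numeric columns (>= 2).
#' @return list with matrices \code{r} (unit diagonal) and \code{p}.
#' @export
pairwiseTraitCorrelation <- function(table, traits) {
  stopifnot(length(traits) >= 2, all(traits %in% colnames(table)))
  X <- as.matrix(table[, traits, drop = FALSE])
  X <- X[complete.cases(X), , drop = FALSE]
  if (nrow(X) < 3) stop("need >= 3 complete rows")
  const <- apply(X, 2, function(v) stats::sd(v) == 0)
  if (any(const))
    warning("constant trait(s): ",
            paste(traits[const], collapse = ", "),
            "; correlations set to NA")
  r <- suppressWarnings(cor(X))
  r[const, ] <- NA; r[, const] <- NA
  diag(r) <- ifelse(const, NA, 1)
  p <- .corP(r, nrow(X))
  diag(p) <- NA
  list(r = r, p = p, n = nrow(X))
}
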