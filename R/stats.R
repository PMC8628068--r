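#' One-way ANOVA across groups
#'
#' Classical fixed-effects one-way analysis of variance (no Welch
#' correction): between/within mean-square F with k - 1 and N - k degrees of
#' freedom and a p value from the F distribution.
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 values).
#' @return list with `statistic` (F), `df` (c(between, within)) and `p`.
#' @examples
#' oneWayAnova(list(c(1, 2, 3), c(4, 5, 6)))  # F = 13.5
#' @export
oneWayAnova <- function(groups) {
  stopIfNot(length(groups) >= 2, "need at least two groups")
  stopIfNot(all(lengths(groups) >= 2), "each group needs >= 2 values")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(statistic = unname(fit$statistic),
       df = unname(c(fit$parameter[["num df"]],
                     fit$parameter[["denom df"]])),
       p = unname(fit$p.value))
}

#' Tukey HSD pairwise contrasts
#'
#' All pairwise group contrasts with p values adjusted over the family via
#' the studentized range distribution (family-wise error controlled at the
#' nominal level).
#'
#' @param groups named or unnamed list of numeric vectors.
#' @return data.frame with columns `group1`, `group2`, `diff`, `lwr`, `upr`,
#'   `adjustedP`.
#' @export
tukeyPairwise <- function(groups) {
  stopIfNot(length(groups) >= 2, "need at least two groups")
  stopIfNot(all(lengths(groups) >= 2), "each group needs >= 2 values")
  labs <- names(groups)
  if (is.null(labs)) labs <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(labs, lengths(groups)), levels = labs)
  tk <- TukeyHSD(aov(values ~ g))$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(group1 = vapply(pairs, `[`, character(1), 1),
             group2 = vapply(pairs, `[`, character(1), 2),
             diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
             adjustedP = tk[, "p adj"], row.names = NULL)
}

#' Spearman rank correlation with small-sample exact permutation p
#'
#' Pearson correlation of the (average-tie) ranks. The two-sided p value
#' uses the t approximation with n - 2 degrees of freedom for n >= 10, and
#' the exact permutation distribution of rho (all n! orderings of one
#' variable's ranks) for n < 10, which handles ties exactly — the relevant
#' regime for feature-cost screens over a handful of plasmids.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return list with `rho`, `p`, `n` and `method` (`"t"` or `"exact"`).
#' @examples
#' spearmanRho(1:5, c(5, 6, 7, 8, 7))
#' @export
spearmanRho <- function(x, y) {
  stopIfNot(length(x) == length(y), "x and y must have equal length")
  n <- length(x)
  stopIfNot(n >= 3, "need at least 3 observations")
  stopIfNot(!anyNA(x) && !anyNA(y), "missing values are not supported")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n >= 10) {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    if (abs(rho) == 1) p <- 0
    return(list(rho = rho, p = min(p, 1), n = n, method = "t"))
  }
  ## exact two-sided permutation distribution of rho
  perms <- pracma::perms(seq_len(n))
  rxC <- rx - mean(rx)
  ryC <- ry - mean(ry)
  denom <- sqrt(sum(rxC^2) * sum(ryC^2))
  rhoPerm <- as.numeric(matrix(ryC[perms], nrow = nrow(perms)) %*% rxC) / denom
  tol <- 1e-12
  p <- mean(abs(rhoPerm) >= abs(rho) - tol)
  list(rho = rho, p = p, n = n, method = "exact")
}
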