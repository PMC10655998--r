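#' Assemble a group table
#'
#' @param x either a named list of numeric vectors, or a data frame with
#'   columns `group` and `value`.
#' @return A named list of numeric vectors (class `group_table`).
#' @export
group_table <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("group", "value") %in% names(x)))
    x <- split(x$value, x$group)
  }
  if (is.null(names(x)) || any(names(x) == ""))
    stop("groups must be named")
  if (any(lengths(x) == 0)) stop("every group must be non-empty")
  x <- lapply(x, as.numeric)
  structure(x, class = "group_table")
}

# midranks of the pooled data plus the tie-correction sum
pooled_ranks <- function(groups) {
  pooled <- unlist(groups, use.names = FALSE)
  r <- rank(pooled)
  tie_sizes <- table(pooled)
  list(ranks = split(r, rep(seq_along(groups), lengths(groups))),
       n = length(pooled),
       tie_sum = sum(tie_sizes^3 - tie_sizes))
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis omnibus test on midranks (chi-square
#' reference with k - 1 degrees of freedom), followed by Dunn's pairwise
#' z tests on mean ranks with the tie-corrected variance, adjusted by
#' Bonferroni over the requested comparison set. When all pooled values are
#' tied the statistic is defined as H = 0 with p = 1.
#'
#' @param table a [group_table()] (or something coercible to one).
#' @param comparisons `"all"` for every pair, or a list of length-2
#'   character vectors / a two-column matrix of group names. The study
#'   design motivates explicit lists: typically each transgenic line versus
#'   its control, not all pairs.
#' @return An object of class `kw_dunn`: `H`, `df`, `p_omnibus` and a
#'   `pairwise` data frame (`group_i`, `group_j`, `z`, `p_unadjusted`,
#'   `p_adjusted`).
#' @export
kruskal_dunn <- function(table, comparisons = "all") {
  g <- group_table(table)
  k <- length(g)
  if (k < 2) stop("need at least 2 groups")
  pr <- pooled_ranks(g)
  n <- pr$n
  ni <- lengths(g)
  rbar <- setNames(vapply(pr$ranks, mean, 0), names(g))

  corr <- 1 - pr$tie_sum / (n^3 - n)
  if (corr <= 0) {
    h <- 0; p <- 1  # all observations tied
  } else {
    h <- (12 / (n * (n + 1)) * sum(ni * (rbar - (n + 1) / 2)^2)) / corr
    p <- pchisq(h, df = k - 1, lower.tail = FALSE)
  }

  if (identical(comparisons, "all")) {
    cmp <- combn(names(g), 2)
  } else {
    cmp <- if (is.matrix(comparisons)) t(comparisons)
      else vapply(comparisons, function(p) as.character(p[1:2]), character(2))
    bad <- setdiff(as.vector(cmp), names(g))
    if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "))
  }
  m <- ncol(cmp)
  sigma2 <- n * (n + 1) / 12 - pr$tie_sum / (12 * (n - 1))
  pw <- do.call(rbind, lapply(seq_len(m), function(j) {
    gi <- cmp[1, j]; gj <- cmp[2, j]
    se <- sqrt(sigma2 * (1 / ni[[gi]] + 1 / ni[[gj]]))
    z <- if (se > 0) (rbar[[gi]] - rbar[[gj]]) / se else 0
    pu <- 2 * pnorm(-abs(z))
    data.frame(group_i = gi, group_j = gj, z = z,
               p_unadjusted = pu, p_adjusted = min(1, pu * m),
               stringsAsFactors = FALSE)
  }))
  structure(list(H = h, df = k - 1, p_omnibus = p, pairwise = pw,
                 n_comparisons = m),
            class = "kw_dunn")
}

#' @export
print.kw_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g\n",
              x$H, x$df, x$p_omnibus))
  cat(sprintf("Dunn's comparisons (Bonferroni over %d):\n", x$n_comparisons))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Spearman correlation with an exact permutation p-value
#'
#' For untied data with n at most 10, the one-sided p-value is computed by
#' full enumeration: the fraction of the n! rank permutations whose
#' correlation is at least as extreme as observed, in the direction of the
#' observed sign (so a perfectly concordant n = 5 sample gives p = 1/120).
#' Ties or larger n fall back to the t approximation with a warning.
#'
#' @param x,y numeric vectors of equal length (n >= 3), neither constant.
#' @param two_sided report the two-sided p-value instead (both tails of the
#'   permutation distribution of |rho|).
#' @return An object of class `spearman_result`: `rho`, `p`, `method`
#'   ("exact" or "asymptotic"), `n`, `two_sided`.
#' @export
spearman_exact <- function(x, y, two_sided = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("constant input vector")
  rx <- rank(x); ry <- rank(y)
  s <- sum((rx - ry)^2)
  m <- n^3 - n
  rho <- 1 - 6 * s / m
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0

  if (!ties && n <= 10) {
    nf <- factorial(n)
    if (two_sided) {
      s_hi <- m * (1 - abs(rho)) / 6   # S at +|rho|
      s_lo <- m / 3 - s_hi             # S at -|rho|
      count <- cpp_spearman_tail_count(n, s_hi, 1L) +
        cpp_spearman_tail_count(n, s_lo, -1L)
      p <- min(1, count / nf)
    } else {
      dir <- if (rho >= 0) 1L else -1L
      p <- cpp_spearman_tail_count(n, s, dir) / nf
    }
    method <- "exact"
  } else {
    if (ties)
      warning("ties present; falling back to the t approximation")
    # correct rho for ties via the product-moment correlation of midranks
    rho <- stats::cor(rx, ry)
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p1 <- stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    p <- if (two_sided) min(1, 2 * p1) else p1
    method <- "asymptotic"
  }
  structure(list(rho = rho, p = p, method = method, n = n,
                 two_sided = two_sided),
            class = "spearman_result")
}

#' @export
print.spearman_result <- function(x, ...) {
  cat(sprintf("Spearman r = %.4g, %s%s p = %.4g (%s, n = %d)\n",
              x$rho, if (x$two_sided) "two-sided" else "one-sided", "",
              x$p, x$method, x$n))
  invisible(x)
}

#' Per-group summary: n, median and interquartile range
#'
#' Medians use the midpoint convention for even n (R's default); quartiles
#' use linear interpolation (quantile type 7).
#'
#' @param table a [group_table()] (or coercible).
#' @return A data frame with columns `group`, `n`, `median`, `q1`, `q3`,
#'   `iqr`.
#' @export
summarize_groups <- function(table) {
  g <- group_table(table)
  do.call(rbind, lapply(names(g), function(nm) {
    v <- g[[nm]]
    q <- unname(quantile(v, c(0.25, 0.75), type = 7))
    data.frame(group = nm, n = length(v), median = median(v),
               q1 = q[1], q3 = q[2], iqr = q[2] - q[1],
               stringsAsFactors = FALSE)
  }))
}
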