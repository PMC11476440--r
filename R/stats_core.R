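#' Exact null distribution of the Mann-Whitney U statistic
#'
#' Probability of each value of U = #{(x_i, y_j): x_i < y_j} under the null
#' that all C(n1+n2, n1) orderings of the pooled sample are equally likely,
#' computed by the standard count recursion
#' N(u; m, n) = N(u - n; m - 1, n) + N(u; m, n - 1).
#'
#' @param n1,n2 group sizes with `n1 + n2 <= 20` (exact mode).
#' @return numeric vector of probabilities named by U value, over
#'   `0:(n1*n2)`; symmetric about `n1*n2/2` and summing to 1.
#' @export
mw_null_distribution <- function(n1, n2) {
  stopifnot(n1 >= 1, n2 >= 1)
  if (n1 + n2 > 20)
    stop("exact null distribution limited to n1 + n2 <= 20")
  # arrangement counts per U value, tabulated over (m, n) subproblems
  tab <- vector("list", (n1 + 1) * (n2 + 1))
  idx <- function(m, n) m * (n2 + 1) + n + 1
  for (m in 0:n1) tab[[idx(m, 0)]] <- 1
  for (n in 0:n2) tab[[idx(0, n)]] <- 1
  for (m in seq_len(n1)) {
    for (n in seq_len(n2)) {
      a <- c(numeric(n), tab[[idx(m - 1, n)]])        # N(u - n; m-1, n)
      b <- tab[[idx(m, n - 1)]]                        # N(u; m, n-1)
      len <- m * n + 1
      length(a) <- len; length(b) <- len
      a[is.na(a)] <- 0; b[is.na(b)] <- 0
      tab[[idx(m, n)]] <- a + b
    }
  }
  cnt <- tab[[idx(n1, n2)]]
  stats::setNames(cnt / sum(cnt), 0:(n1 * n2))
}

#' Exact two-sided Mann-Whitney rank test
#'
#' U is the number of (x, y) pairs with x < y; the smaller of the two
#' orientations (U, n1*n2 - U) is reported and the two-sided p-value is
#' twice the lower-tail mass at it under the exact null distribution,
#' capped at 1. With no ties and `n1 + n2 <= 20` the null distribution
#' comes from the count recursion of [mw_null_distribution]; with ties each
#' tied pair contributes 1/2 to U and the null distribution is enumerated
#' over all C(n1+n2, n1) group-label assignments of the observed values
#' (the result is flagged `tied`). For `n1 + n2 > 20` a normal
#' approximation with continuity correction is used and flagged
#' `approximate`.
#'
#' @param x,y numeric measurement vectors (both non-empty).
#' @return list with `u_statistic`, `p_two_sided`, `n1`, `n2`, `tied`,
#'   `approximate`.
#' @export
mann_whitney_exact <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty group")
  n1 <- length(x); n2 <- length(y)
  less <- sum(outer(x, y, `<`))
  ties <- sum(outer(x, y, `==`))
  u_raw <- less + ties / 2
  u <- min(u_raw, n1 * n2 - u_raw)
  if (n1 + n2 > 20) {
    mu <- n1 * n2 / 2
    sigma <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    p <- min(1, 2 * stats::pnorm((u + 0.5 - mu) / sigma))
    return(list(u_statistic = u, p_two_sided = p, n1 = n1, n2 = n2,
                tied = ties > 0, approximate = TRUE))
  }
  if (ties == 0) {
    dist <- mw_null_distribution(n1, n2)
    p <- min(1, 2 * sum(dist[as.numeric(names(dist)) <= u]))
  } else {
    pooled <- c(x, y)
    combos <- utils::combn(n1 + n2, n1)
    us <- apply(combos, 2, function(ix) {
      xx <- pooled[ix]; yy <- pooled[-ix]
      sum(outer(xx, yy, `<`)) + sum(outer(xx, yy, `==`)) / 2
    })
    us <- pmin(us, n1 * n2 - us)
    p <- min(1, 2 * mean(us <= u))
  }
  list(u_statistic = u, p_two_sided = p, n1 = n1, n2 = n2,
       tied = ties > 0, approximate = FALSE)
}
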