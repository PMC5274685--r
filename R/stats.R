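# cache of combn(n, n1) index matrices, keyed "n:n1"
.mw_cache <- new.env(parent = emptyenv())

mw_assignments <- function(n, n1) {
  key <- paste(n, n1, sep = ":")
  if (is.null(.mw_cache[[key]])) .mw_cache[[key]] <- combn(n, n1)
  .mw_cache[[key]]
}

#' Exact Mann-Whitney U test
#'
#' Rank-sum U statistic with midranks for ties. For pooled sample sizes up
#' to `exact_max_n` the two-sided p-value is obtained by full enumeration
#' of all `choose(n1 + n2, n1)` assignments of the observed pooled values
#' to the groups (a permutation test on ranks, exact also under ties);
#' larger samples fall back to the normal approximation with tie
#' correction and continuity correction. The two-sided p-value is
#' `2 * min(P(U <= u), P(U >= u))` capped at 1.
#'
#' @param x,y numeric samples of the two groups, each with >= 2 non-missing
#'   values.
#' @param exact_max_n largest pooled size enumerated exactly (default 16,
#'   i.e. up to 12870 assignments).
#' @return a list of class `"mw_test"`: `U` (for `x`), `p_value`, `method`
#'   (`"exact"`, `"normal"` or `"degenerate"`), `n1`, `n2`.
#' @examples
#' mann_whitney_exact(1:3, 4:6)$p_value  # 0.1
#' @export
mann_whitney_exact <- function(x, y, exact_max_n = 16) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("both groups need >= 2 values", call. = FALSE)
  n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (diff(range(pooled)) == 0) {
    return(structure(list(U = U, p_value = 1, method = "degenerate",
                          n1 = n1, n2 = n2), class = "mw_test"))
  }

  if (n <= exact_max_n) {
    idx <- mw_assignments(n, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p_le <- mean(u_all <= U + 1e-9)
    p_ge <- mean(u_all >= U - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  structure(list(U = U, p_value = p, method = method, n1 = n1, n2 = n2),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), p = %.4g [%s]\n",
              x$U, x$n1, x$n2, x$p_value, x$method))
  invisible(x)
}

#' Per-parameter two-group comparison table
#'
#' For every numeric parameter column, compares the two groups with
#' [mann_whitney_exact()] and reports group means +/- SD, U, the p-value
#' and a significance flag at `p <= alpha`. No multiplicity correction is
#' applied. Parameters with missing specimen values are skipped with a
#' warning.
#'
#' @param data data frame with one row per specimen: a group column plus
#'   numeric parameter columns.
#' @param group_col name of the group column (two levels; default
#'   `"group"`).
#' @param value_cols parameter columns to compare; default: all numeric
#'   columns except `group_col`.
#' @param alpha significance level (default 0.05; significance is
#'   `p <= alpha`).
#' @return a data frame of class `"group_comparison"`, one row per
#'   parameter; attribute `"groups"` records the level order (U is for the
#'   first level).
#' @export
summarize_groups <- function(data, group_col = "group", value_cols = NULL,
                             alpha = 0.05) {
  stopifnot(is.data.frame(data), group_col %in% names(data))
  g <- data[[group_col]]
  lev <- if (is.factor(g)) levels(g) else sort(unique(as.character(g)))
  if (length(lev) != 2) stop("exactly two groups are required",
                             call. = FALSE)
  g <- as.character(g)
  if (is.null(value_cols)) {
    value_cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          group_col)
  }
  rows <- lapply(value_cols, function(col) {
    v <- data[[col]]
    if (anyNA(v)) {
      warning(sprintf("parameter `%s` has missing values; skipped", col),
              call. = FALSE)
      return(NULL)
    }
    x <- v[g == lev[1]]
    y <- v[g == lev[2]]
    tst <- mann_whitney_exact(x, y)
    out <- data.frame(parameter = col,
                      mean_1 = mean(x), sd_1 = sd(x),
                      mean_2 = mean(y), sd_2 = sd(y),
                      U = tst$U, p_value = tst$p_value,
                      method = tst$method,
                      significant = tst$p_value <= alpha)
    names(out)[2:5] <- c(paste0("mean_", lev[1]), paste0("sd_", lev[1]),
                         paste0("mean_", lev[2]), paste0("sd_", lev[2]))
    out
  })
  res <- do.call(rbind, rows)
  attr(res, "groups") <- lev
  attr(res, "alpha") <- alpha
  class(res) <- c("group_comparison", "data.frame")
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  lev <- attr(x, "groups")
  cat(sprintf("Two-group comparison (%s vs %s), alpha = %g\n",
              lev[1], lev[2], attr(x, "alpha")))
  NextMethod()
}
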