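# Spearman rank correlation between proxies and PM2.5, per stratum and
# pooled, with two-sided p-values.

# All permutations of 1..n (n <= 9 keeps this tractable: 9! = 362,880).
#' @keywords internal
.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(rep(i, nrow(sub)), matrix(rest[sub], nrow(sub)))
  }))
}

#' Spearman rank correlation with two-sided p-value
#'
#' rho is the Pearson correlation of mid-ranks (ties receive their mean
#' rank). The two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom for
#' n >= 10, and the exact permutation distribution of rho (all n!
#' permutations) for n < 10. If either variable is constant the rank
#' correlation is undefined; rho = 0 and p = 1 are returned with the
#' `"constant-input"` flag. Pairs with a missing value are dropped
#' (complete-case).
#'
#' @param x,y Numeric vectors of equal length (n >= 3 after dropping
#'   missing pairs).
#' @return list with `n`, `rho`, `p_value`, `flags`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(n = n, rho = 0, p_value = 1, flags = "constant-input"))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n >= 10) {
    if (1 - rho^2 < 1e-15) {
      p <- 0
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
    }
  } else {
    perms <- .all_permutations(n)
    s <- matrix(ry[perms], nrow(perms)) %*% rx
    mrx <- mean(rx); mry <- mean(ry)
    denom <- sqrt(sum((rx - mrx)^2) * sum((ry - mry)^2))
    rho_perm <- (as.numeric(s) - n * mrx * mry) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  }
  list(n = n, rho = rho, p_value = min(1, p), flags = character(0))
}

#' @keywords internal
.stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", ""))))
}

#' Proxy-PM2.5 correlation matrix by stratum
#'
#' Spearman correlation of each proxy against PM2.5 within each stratum
#' (e.g. country) and pooled over all observations (`"global"`). Strata
#' with fewer than 3 complete pairs are reported with the `"undefined"`
#' flag rather than raising an error. Significance stars: * p < 0.05,
#' ** p < 0.01, *** p < 0.001.
#'
#' @param village_table data.frame keyed by village with a PM2.5 column and
#'   proxy columns.
#' @param proxy_cols Named character vector mapping display names to
#'   columns, default `c(WRND = "wrnd", EM = "em", EH = "eh")`.
#' @param pm_col Name of the PM2.5 column.
#' @param stratum_col Optional stratum column; `NULL` gives global only.
#' @return data.frame: `proxy`, `stratum`, `n`, `rho`, `p_value`, `stars`,
#'   `flags`.
#' @export
correlation_matrix <- function(village_table,
                               proxy_cols = c(WRND = "wrnd", EM = "em", EH = "eh"),
                               pm_col = "pm25", stratum_col = NULL) {
  strata <- if (is.null(stratum_col)) character(0)
            else sort(unique(village_table[[stratum_col]]))
  rows <- list()
  for (pn in names(proxy_cols)) {
    for (s in c(strata, "global")) {
      tab <- if (s == "global") village_table
             else village_table[village_table[[stratum_col]] == s, , drop = FALSE]
      x <- tab[[proxy_cols[[pn]]]]
      y <- tab[[pm_col]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3) {
        rows[[length(rows) + 1L]] <- data.frame(
          proxy = pn, stratum = s, n = sum(ok), rho = NA_real_,
          p_value = NA_real_, stars = "", flags = "undefined")
        next
      }
      r <- spearman_cor(x[ok], y[ok])
      rows[[length(rows) + 1L]] <- data.frame(
        proxy = pn, stratum = s, n = r$n, rho = r$rho, p_value = r$p_value,
        stars = .stars(r$p_value),
        flags = paste(r$flags, collapse = ","))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
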