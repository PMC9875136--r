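# Nonparametric cohort statistics. Statistic values lean on base R where the
# contract matches (kruskal.test); the small-sample exact-p branches are
# enumerated here.

resolve_xy <- function(data, xq, yq) {
  if (is.data.frame(data)) {
    xv <- rlang::eval_tidy(xq, data)
    yv <- rlang::eval_tidy(yq, data)
  } else {
    xv <- data
    yv <- rlang::eval_tidy(xq)
  }
  stop_if(length(xv) != length(yv), "x and y must be paired")
  ok <- is.finite(xv) & is.finite(yv)
  list(x = xv[ok], y = yv[ok])
}

#' Spearman rank correlation
#'
#' Tie-corrected rho on mid-ranks. The two-sided p-value is computed by full
#' permutation enumeration for `n <= exact_n` and by the t approximation
#' otherwise.
#'
#' @param data Data frame (with columns `x`, `y` given unquoted), or the
#'   first numeric vector.
#' @param x,y Column names (data-frame form) or the second vector.
#' @param exact_n Largest n for exact enumeration (capped at 10).
#'
#' @return One-row tibble: `statistic` (rho), `p`, `n`, `method`, `exact`.
#' @export
#' @examples
#' spearman_test(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
spearman_test <- function(data, x, y, exact_n = 10) {
  v <- resolve_xy(data, rlang::enquo(x), rlang::enquo(y))
  n <- length(v$x)
  stop_if(n < 3, "need >= 3 pairs")
  stop_if(var(v$x) == 0 || var(v$y) == 0,
          "Spearman correlation undefined for a constant vector")
  xr <- rank(v$x); yr <- rank(v$y)
  rho <- stats::cor(xr, yr)
  exact <- n <= min(exact_n, 10)
  if (exact) {
    p <- spearman_exact_p(xr, yr, rho)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
    p <- min(1, 2 * pt(-abs(tstat), df = n - 2))
  }
  tibble::tibble(statistic = rho, p = p, n = n,
                 method = "Spearman rank correlation", exact = exact)
}

# index matrix of all permutations of 1..n (rows)
perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- perm_matrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, ifelse(p >= i, p + 1L, p)) # first element i, rest shifted
  }))
}

# P(|rho_perm| >= |rho_obs|) over all n! permutations, chunked by the first
# rank to bound memory at n = 10
spearman_exact_p <- function(xr, yr, rho_obs) {
  n <- length(xr)
  mx <- mean(xr); my <- mean(yr)
  sx <- sd(xr); sy <- sd(yr)
  sub <- perm_matrix(n - 1L)
  count <- 0
  total <- 0
  for (first in seq_len(n)) {
    rest <- seq_len(n)[-first]
    M <- matrix(yr[rest][sub], nrow(sub), n - 1L)
    s <- yr[first] * xr[1] + drop(M %*% xr[-1])
    rho_perm <- (s - n * mx * my) / ((n - 1) * sx * sy)
    count <- count + sum(abs(rho_perm) >= abs(rho_obs) - 1e-12)
    total <- total + nrow(sub)
  }
  count / total
}

resolve_two_groups <- function(data, vq, gq) {
  if (is.data.frame(data)) {
    vv <- rlang::eval_tidy(vq, data)
    gv <- rlang::eval_tidy(gq, data)
    sp <- split(vv, gv)
    stop_if(length(sp) != 2, "group must have exactly 2 levels")
    list(a = sp[[1]], b = sp[[2]])
  } else {
    list(a = data, b = rlang::eval_tidy(vq))
  }
}

#' Mann-Whitney U test
#'
#' U for the first sample (number of (a, b) pairs with a ahead, ties counted
#' half). Two-sided p by exact enumeration of all group splits when
#' `n_a * n_b <= 64`, otherwise by the tie-corrected normal approximation
#' with continuity correction.
#'
#' @param data Data frame (then give `value` and a 2-level `group`), or the
#'   first sample vector.
#' @param value Column name, or the second sample vector.
#' @param group Grouping column (data-frame form).
#'
#' @return One-row tibble: `statistic` (U), `p`, `n` (list of both sizes),
#'   `method`, `exact`.
#' @export
#' @examples
#' mann_whitney_test(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
mann_whitney_test <- function(data, value, group = NULL) {
  g <- resolve_two_groups(data, rlang::enquo(value), rlang::enquo(group))
  a <- g$a[is.finite(g$a)]; b <- g$b[is.finite(g$b)]
  na <- length(a); nb <- length(b)
  stop_if(na == 0 || nb == 0, "both samples must be nonempty")
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  exact <- na * nb <= 64
  if (exact) {
    splits <- combn(na + nb, na)
    us <- colSums(matrix(r[splits], na)) - na * (na + 1) / 2
    p <- min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
  } else {
    mu <- na * nb / 2
    ties <- table(r)
    sigma <- sqrt((na * nb / 12) *
                    ((na + nb + 1) - sum(ties^3 - ties) /
                       ((na + nb) * (na + nb - 1))))
    z <- (abs(u_obs - mu) - 0.5) / sigma
    p <- min(1, 2 * pnorm(-max(0, z)))
  }
  tibble::tibble(statistic = u_obs, p = p, n = list(c(na, nb)),
                 method = "Mann-Whitney U", exact = exact)
}

#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected H with a chi-squared p on k - 1 degrees of freedom
#' (delegates to [stats::kruskal.test()]); the all-tied degenerate case is
#' reported as H = 0, p = 1.
#'
#' @param data Data frame, or a list of sample vectors.
#' @param value,group Column names (data-frame form).
#'
#' @return One-row tibble: `statistic` (H), `df`, `p`, `n`, `method`.
#' @export
kruskal_test <- function(data, value, group = NULL) {
  if (is.data.frame(data)) {
    vv <- rlang::eval_tidy(rlang::enquo(value), data)
    gv <- rlang::eval_tidy(rlang::enquo(group), data)
    groups <- split(vv, gv)
  } else {
    groups <- data
  }
  k <- length(groups)
  nn <- sum(lengths(groups))
  if (var(unlist(groups)) == 0) {
    return(tibble::tibble(statistic = 0, df = k - 1, p = 1, n = nn,
                          method = "Kruskal-Wallis"))
  }
  kt <- stats::kruskal.test(groups)
  tibble::tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
                 p = kt$p.value, n = nn, method = "Kruskal-Wallis")
}

#' Dunn-Sidak correction
#'
#' Familywise adjustment `p_adj = 1 - (1 - p)^m`, clipped to `[0, 1]`.
#'
#' @param p Vector of raw p-values.
#' @param m Number of comparisons (default `length(p)`).
#'
#' @return Adjusted p-values.
#' @export
#' @examples
#' dunn_sidak(0.05, m = 3)  # 0.142625
dunn_sidak <- function(p, m = length(p)) {
  stop_if(m < 1, "m must be >= 1")
  stop_if(any(p < 0 | p > 1, na.rm = TRUE), "p must be in [0, 1]")
  pmin(1, pmax(0, 1 - (1 - p)^m))
}

#' Dunn's pairwise rank comparisons after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks with tie correction, Dunn-Sidak
#' adjusted over all pairs; intended as the follow-up to a significant
#' omnibus [kruskal_test()].
#'
#' @param data Data frame, or a named list of sample vectors.
#' @param value,group Column names (data-frame form).
#'
#' @return Tibble, one row per pair: `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_posthoc <- function(data, value, group = NULL) {
  if (is.data.frame(data)) {
    vv <- rlang::eval_tidy(rlang::enquo(value), data)
    gv <- rlang::eval_tidy(rlang::enquo(group), data)
    groups <- split(vv, gv)
  } else {
    groups <- data
    if (is.null(names(groups))) names(groups) <- seq_along(groups)
  }
  k <- length(groups)
  stop_if(k < 2, "need >= 2 groups")
  nn <- lengths(groups)
  N <- sum(nn)
  r <- rank(unlist(groups))
  gidx <- rep(seq_len(k), nn)
  rbar <- tapply(r, gidx, mean)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- combn(k, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / nn[i1] + 1 / nn[i2]))
    z <- (rbar[i1] - rbar[i2]) / se
    tibble::tibble(group1 = names(groups)[i1], group2 = names(groups)[i2],
                   z = unname(z), p = 2 * pnorm(-abs(z)))
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- dunn_sidak(out$p, m)
  out
}

#' Fleiss' kappa for multi-rater categorical agreement
#'
#' Chance-corrected agreement `(P - Pe) / (1 - Pe)` for a fixed number of
#' raters per subject. When every rating falls in a single category the
#' expected agreement is 1 and kappa is undefined; the result is flagged
#' degenerate.
#'
#' @param ratings Subjects-by-categories count matrix (each row sums to the
#'   rater count), or a long data frame with columns `subject` and `rating`.
#'
#' @return One-row tibble: `kappa`, `raters`, `subjects`, `degenerate`.
#' @export
fleiss_kappa <- function(ratings) {
  if (is.data.frame(ratings)) {
    ratings <- as.matrix(table(ratings$subject, ratings$rating))
  }
  n_rat <- unique(rowSums(ratings))
  stop_if(length(n_rat) != 1, "every subject needs the same rater count")
  n <- n_rat[1]
  N <- nrow(ratings)
  p_j <- colSums(ratings) / (N * n)
  p_i <- (rowSums(ratings^2) - n) / (n * (n - 1))
  pbar <- mean(p_i)
  pe <- sum(p_j^2)
  if (abs(1 - pe) < 1e-12) {
    return(tibble::tibble(kappa = NA_real_, raters = n, subjects = N,
                          degenerate = TRUE))
  }
  tibble::tibble(kappa = (pbar - pe) / (1 - pe), raters = n, subjects = N,
                 degenerate = FALSE)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measure: the
#' conventional interobserver reliability coefficient for continuous lesion
#' measurements. Computed from the two-way mean squares
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param measurements Subjects-by-raters numeric matrix, or a long data
#'   frame with columns `subject`, `rater`, `value`.
#' @param min_subjects Minimum subject count.
#'
#' @return One-row tibble: `icc`, `raters`, `subjects`, `degenerate` (zero
#'   between-subject variance).
#' @export
icc21 <- function(measurements, min_subjects = 5) {
  if (is.data.frame(measurements)) {
    measurements <- stats::xtabs(value ~ subject + rater, data = measurements)
    measurements <- matrix(measurements, nrow(measurements))
  }
  M <- as.matrix(measurements)
  n <- nrow(M); k <- ncol(M)
  stop_if(n < min_subjects, sprintf("need >= %d subjects", min_subjects))
  stop_if(k < 2, "need >= 2 raters")
  stop_if(any(!is.finite(M)), "measurements must be complete and finite")
  grand <- mean(M)
  row_m <- rowMeans(M); col_m <- colMeans(M)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((M - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  degenerate <- msr <= mse
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  tibble::tibble(icc = icc, raters = k, subjects = n, degenerate = degenerate)
}

#' Two-group comparison with selectable branch
#'
#' Defaults to the nonparametric branch ([mann_whitney_test()]); the
#' parametric branch (two-tailed Welch t test) is available for data that
#' pass a normality check.
#'
#' @param data Data frame or first sample vector.
#' @param value,group See [mann_whitney_test()].
#' @param parametric Use the t test instead.
#'
#' @return One-row tibble: `statistic`, `p`, `n`, `method`, `exact`.
#' @export
compare_groups <- function(data, value, group = NULL, parametric = FALSE) {
  g <- resolve_two_groups(data, rlang::enquo(value), rlang::enquo(group))
  if (!parametric) return(mann_whitney_test(g$a, g$b))
  tt <- stats::t.test(g$a, g$b)
  tibble::tibble(statistic = unname(tt$statistic), p = tt$p.value,
                 n = list(c(length(g$a), length(g$b))),
                 method = "Welch two-sample t", exact = FALSE)
}
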