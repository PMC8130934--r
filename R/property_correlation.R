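#' @title Pairwise property-correlation analysis
#' @description Categorization rules for in vivo variables (phase
#'   peak/trough dichotomy, ratio >= 1, tercile extremes), Barnard's exact
#'   unconditional test for 2x2 contingency tables, Spearman rank
#'   correlation, Mann-Whitney U and Student t comparisons, and a
#'   pairwise scan over a typed property matrix. Raw p-values are
#'   reported without multiple-comparison correction by default.
#' @name property_correlation
NULL

test_result <- function(test, statistic, p_value, n, table = NULL,
                        undefined = FALSE, reason = NA_character_) {
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 n = n, table = table, undefined = undefined,
                 reason = reason),
            class = "hp_test")
}

#' @export
print.hp_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g, n = %d%s\n", x$test,
              x$statistic, x$p_value, x$n,
              if (isTRUE(x$undefined)) paste0(" [undefined: ", x$reason, "]")
              else ""))
  invisible(x)
}

#' Categorize a continuous or circular column
#'
#' * `phase_peak_trough`: phases within 90 degrees of the CA1-SP theta
#'   peak (wrapped into `[-90, 90)`) are "peak", the rest "trough".
#' * `ratio_ge1`: values split at 1 into "lt1" / "ge1" (boundary included
#'   in "ge1").
#' * `tercile_extremes`: top third "high", bottom third "low", middle
#'   third set to missing.
#'
#' @param x numeric vector.
#' @param kind one of `"phase_peak_trough"`, `"ratio_ge1"`,
#'   `"tercile_extremes"`.
#' @param peak_halfwidth_deg half-width of the peak-aligned sector.
#' @return character vector (NA for missing / middle-tercile cells).
#' @export
categorize_property <- function(x, kind = c("phase_peak_trough", "ratio_ge1",
                                            "tercile_extremes"),
                                peak_halfwidth_deg = 90) {
  kind <- match.arg(kind)
  if (kind == "phase_peak_trough") {
    w <- wrap180(x)
    out <- ifelse(w >= -peak_halfwidth_deg & w < peak_halfwidth_deg,
                  "peak", "trough")
  } else if (kind == "ratio_ge1") {
    out <- ifelse(x >= 1, "ge1", "lt1")
  } else {
    ok <- !is.na(x)
    if (sum(ok) < 3) stopf("tercile categorization needs at least 3 values")
    r <- rank(x[ok], ties.method = "average")
    n <- sum(ok)
    cat_ok <- rep(NA_character_, n)
    cat_ok[r <= n / 3] <- "low"
    cat_ok[r > 2 * n / 3] <- "high"
    out <- rep(NA_character_, length(x))
    out[ok] <- cat_ok
  }
  out[is.na(x)] <- NA_character_
  out
}

# Pooled Wald score for a 2x2 table with columns as groups; zero when the
# pooled proportion is degenerate.
wald_score <- function(a, b, n1, n2) {
  p1 <- a / n1; p2 <- b / n2
  pp <- (a + b) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  z[!is.finite(z)] <- 0
  z
}

# P(|Z| >= |z_obs|) under independent binomials at nuisance pi, evaluated
# on a vector of pi values; E is the extremeness indicator over outcomes.
barnard_p_at <- function(pi_grid, n1, n2, extreme) {
  A <- outer(0:n1, pi_grid, function(a, p) stats::dbinom(a, n1, p))
  B <- outer(0:n2, pi_grid, function(b, p) stats::dbinom(b, n2, p))
  colSums(A * (extreme %*% B))
}

#' Barnard's exact unconditional test for a 2x2 table
#'
#' Treats the two columns as independent binomial samples of fixed size;
#' the two-sided p-value is the supremum over the nuisance success
#' probability of the probability of outcomes at least as extreme (in
#' absolute pooled Wald score) as the observed table. The supremum is
#' taken over 1001 equally spaced nuisance values on (0, 1) with local
#' refinement around the grid maximizer.
#'
#' @param tab 2x2 matrix of non-negative integer counts; columns are the
#'   two groups, rows the two outcome categories.
#' @return an `hp_test` result (statistic is the observed Wald score).
#' @export
barnard_test <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stopf("tab must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) stopf("counts must be non-negative integers")
  n <- sum(tab)
  if (n == 0) stopf("all-zero table")
  n1 <- sum(tab[, 1]); n2 <- sum(tab[, 2])
  a_obs <- tab[1, 1]; b_obs <- tab[1, 2]
  z_obs <- wald_score(a_obs, b_obs, n1, n2)
  if (n1 == 0 || n2 == 0)
    return(test_result("barnard", 0, 1, n, tab))
  z_all <- outer(0:n1, 0:n2, function(a, b) wald_score(a, b, n1, n2))
  extreme <- (abs(z_all) >= abs(z_obs) - 1e-12) * 1
  grid <- seq_len(1001) / 1002
  p_grid <- barnard_p_at(grid, n1, n2, extreme)
  i_max <- which.max(p_grid)
  lo <- grid[max(1L, i_max - 1L)]; hi <- grid[min(length(grid), i_max + 1L)]
  opt <- stats::optimize(function(p) barnard_p_at(p, n1, n2, extreme),
                         c(lo, hi), maximum = TRUE, tol = 1e-9)
  p <- min(1, max(p_grid[i_max], opt$objective))
  test_result("barnard", z_obs, p, n, tab)
}

# All n! permutations of seq_len(n), one per row (n <= 8).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                           drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Spearman rank correlation test
#'
#' Average-rank tie handling. For n up to `exact_max` the p-value is the
#' exact two-sided permutation probability over all n! orderings of one
#' variable; beyond that the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom is
#' used.
#'
#' @param x,y paired numeric vectors (pairwise-complete cases used).
#' @param exact_max largest n for which the exact permutation null is
#'   enumerated.
#' @return an `hp_test` result (statistic is rho).
#' @export
spearman_test <- function(x, y, exact_max = 7) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stopf("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(test_result("spearman", NA_real_, NA_real_, n,
                       undefined = TRUE, reason = "zero variance in ranks"))
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- all_permutations(n)
    rho_null <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  test_result("spearman", rho, min(1, p), n)
}

#' Two-sample comparisons: Mann-Whitney U and Student t
#'
#' The Mann-Whitney statistic is reported in the smaller-U convention
#' (U = min(U1, U2), where U1 counts pairwise wins of the first group,
#' ties half); the p-value comes from the usual rank-sum procedure.
#' The Student t test uses pooled variance.
#'
#' @param a,b numeric samples.
#' @param test `"mann_whitney"` or `"student_t"`.
#' @return an `hp_test` result.
#' @export
compare_groups <- function(a, b, test = c("mann_whitney", "student_t")) {
  test <- match.arg(test)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stopf("empty group")
  n1 <- length(a); n2 <- length(b)
  if (test == "mann_whitney") {
    r <- rank(c(a, b))
    u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    u2 <- n1 * n2 - u1
    p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
    test_result("mann_whitney", min(u1, u2), p, n1 + n2)
  } else {
    if (n1 < 2 || n2 < 2) stopf("student_t needs n >= 2 per group")
    ht <- stats::t.test(a, b, var.equal = TRUE)
    test_result("student_t", unname(ht$statistic), ht$p.value, n1 + n2)
  }
}

#' Pairwise association scan over a typed property matrix
#'
#' Categorical x categorical pairs go to [barnard_test()] on the 2x2
#' table of their two most frequent levels; pairs involving an ordinal or
#' continuous column go to [spearman_test()] (categorical columns coerced
#' to their integer codes). Missing cells are excluded pairwise;
#' incomputable pairs are kept in the output with the skip reason. No
#' multiple-comparison correction is applied unless `p_adjust` names a
#' method for [stats::p.adjust()].
#'
#' @param mat data.frame of properties (rows = neuron types).
#' @param kinds named character vector mapping each column to
#'   `"categorical"`, `"ordinal"` or `"continuous"`.
#' @param p_adjust optional p-adjustment method.
#' @return data.frame with one row per property pair.
#' @export
pairwise_scan <- function(mat, kinds, p_adjust = NULL) {
  props <- names(mat)
  missing_kinds <- setdiff(props, names(kinds))
  if (length(missing_kinds))
    stopf("no kind declared for column(s): %s",
          paste(missing_kinds, collapse = ", "))
  pairs <- utils::combn(props, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    pa <- pairs[1, i]; pb <- pairs[2, i]
    xa <- mat[[pa]]; xb <- mat[[pb]]
    ok <- !is.na(xa) & !is.na(xb)
    base <- data.frame(prop_a = pa, prop_b = pb, test = NA_character_,
                       statistic = NA_real_, p_value = NA_real_,
                       n = sum(ok), reason = NA_character_)
    if (sum(ok) < 3) {
      base$reason <- "fewer than 3 complete pairs"
      return(base)
    }
    both_cat <- kinds[[pa]] == "categorical" && kinds[[pb]] == "categorical"
    res <- tryCatch({
      if (both_cat) {
        fa <- factor(xa[ok]); fb <- factor(xb[ok])
        if (nlevels(fa) < 2 || nlevels(fb) < 2)
          stop("a categorical column is constant on complete pairs")
        top2 <- function(f) names(sort(table(f), decreasing = TRUE))[1:2]
        la <- top2(fa); lb <- top2(fb)
        keep <- fa %in% la & fb %in% lb
        tab <- table(factor(fa[keep], la), factor(fb[keep], lb))
        barnard_test(tab)
      } else {
        num <- function(v, kind) if (kind == "categorical")
          as.numeric(factor(v)) else as.numeric(v)
        spearman_test(num(xa[ok], kinds[[pa]]), num(xb[ok], kinds[[pb]]))
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      base$reason <- conditionMessage(res)
    } else if (isTRUE(res$undefined)) {
      base$test <- res$test; base$reason <- res$reason
    } else {
      base$test <- res$test; base$statistic <- res$statistic
      base$p_value <- res$p_value; base$n <- res$n
    }
    base
  })
  out <- do.call(rbind, rows)
  if (!is.null(p_adjust))
    out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  out
}
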