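# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (loops, direct enumeration) so they share no code path
# with the package implementations they check.

# Barnard p by direct outcome enumeration over the nuisance grid, with a
# one-dimensional refinement around the grid maximizer.
oracle_barnard <- function(tab) {
  n1 <- sum(tab[, 1]); n2 <- sum(tab[, 2])
  if (n1 == 0 || n2 == 0) return(1)
  z_of <- function(a, b) {
    p1 <- a / n1; p2 <- b / n2; pp <- (a + b) / (n1 + n2)
    se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    if (!is.finite(se) || se == 0) 0 else (p1 - p2) / se
  }
  zobs <- abs(z_of(tab[1, 1], tab[1, 2]))
  extreme <- list()
  for (a in 0:n1) for (b in 0:n2)
    if (abs(z_of(a, b)) >= zobs - 1e-12)
      extreme[[length(extreme) + 1L]] <- c(a, b)
  p_at <- function(p) {
    s <- 0
    for (ab in extreme)
      s <- s + stats::dbinom(ab[1], n1, p) * stats::dbinom(ab[2], n2, p)
    s
  }
  grid <- seq_len(1001) / 1002
  acc <- numeric(length(grid))
  for (ab in extreme)
    acc <- acc + stats::dbinom(ab[1], n1, grid) * stats::dbinom(ab[2], n2, grid)
  i <- which.max(acc)
  opt <- stats::optimize(p_at, c(grid[max(1, i - 1)], grid[min(1001, i + 1)]),
                         maximum = TRUE, tol = 1e-9)
  min(1, max(acc[i], opt$objective))
}

# Mann-Whitney U as a literal count of pairwise wins (ties half).
oracle_u_count <- function(a, b) {
  u1 <- 0
  for (x in a) for (y in b) u1 <- u1 + (x > y) + 0.5 * (x == y)
  min(u1, length(a) * length(b) - u1)
}

# Closed-form mean vector length of a von Mises distribution.
vonmises_mvl <- function(kappa) {
  if (kappa == 0) return(0)
  besselI(kappa, 1) / besselI(kappa, 0)
}

# Phase-locked, event-modulated reference spike counts from ground truth.
oracle_event_rate_ratio <- function(times, peaks, half_window, span) {
  in_win <- vapply(times, function(s) any(abs(s - peaks) <= half_window),
                   logical(1))
  t_win <- 2 * half_window * length(peaks)
  rate_in <- sum(in_win) / t_win
  rate_out <- sum(!in_win) / (diff(span) - t_win)
  rate_in / rate_out
}

# Benchmark scoring: match detected peaks to truth within a tolerance.
score_detection <- function(detected_peaks, true_peaks, tol_s = 0.025) {
  if (!length(true_peaks))
    return(list(recall = NA_real_, precision = NA_real_))
  hit <- vapply(true_peaks, function(t)
    any(abs(detected_peaks - t) <= tol_s), logical(1))
  fp <- if (!length(detected_peaks)) 0 else
    sum(vapply(detected_peaks, function(d)
      !any(abs(true_peaks - d) <= tol_s), logical(1)))
  list(recall = mean(hit),
       precision = if (length(detected_peaks))
         1 - fp / length(detected_peaks) else NA_real_)
}

# Small helper: reference cells for a 3-type, 28-cell labeled set with the
# composition of a PV-interneuron map (12 + 9 + 7).
make_reference_cells <- function(sep_kappa = 8) {
  data.frame(
    phase_deg = c(hippophen:::rvonmises_deg(12, 270, sep_kappa),
                  hippophen:::rvonmises_deg(9, 10, sep_kappa),
                  hippophen:::rvonmises_deg(7, 180, sep_kappa)),
    swr_ratio = pmax(0, c(stats::rnorm(12, 4.3, 1), stats::rnorm(9, 0.4, 0.2),
                          stats::rnorm(7, 3.0, 0.8))),
    label = rep(c("PV-BC", "AAC", "Bistratified"), c(12, 9, 7)),
    stringsAsFactors = FALSE)
}

ang_diff <- function(a, b) abs(((a - b + 180) %% 360) - 180)
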