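# Cross-site and cross-organism statistics: relative site position within
# genes with a location-shift test, and a rank-based comparison of
# methylation levels between site sets. Both tests are computed from first
# principles; base R equivalents serve as independent cross-checks in the
# test suite.

#' Relative position of a site within its gene
#'
#' Maps a genomic site to [0, 1] along the gene's sense strand: 0 is the 5'
#' end, 1 the 3' end. The denominator is (gene length - 1) so both ends are
#' attainable.
#'
#' @param pos genomic position(s) of the site(s).
#' @param gene one-row data.frame/list with start, end, strand.
#' @return numeric in [0, 1]; vectorised over \code{pos}.
#' @export
relative_position <- function(pos, gene) {
  if (any(pos < gene$start | pos > gene$end))
    stop("site outside the gene interval")
  L <- gene$end - gene$start + 1L
  if (L == 1L) return(rep(0, length(pos)))
  if (gene$strand == "+") (pos - gene$start) / (L - 1L)
  else (gene$end - pos) / (L - 1L)
}

#' Welch two-sample location-shift test
#'
#' Compares the distributions of two sets of relative positions (or any
#' numeric measurements) with the Welch t statistic: unpooled variances and
#' Welch-Satterthwaite degrees of freedom, two-sided p.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @return list with \code{statistic}, \code{df}, \code{p.value},
#'   \code{mean_a}, \code{mean_b}.
#' @export
position_shift_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("both sets need size >= 2")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) stop("degenerate (zero) variance in both sets")
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  list(statistic = t, df = df, p.value = 2 * stats::pt(-abs(t), df),
       mean_a = mean(a), mean_b = mean(b))
}

# exact Mann-Whitney by enumeration of rank assignments (midranks for ties)
.mw_exact <- function(a, b, u_obs, alternative) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a); n2 <- length(b)
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2L, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  eps <- 1e-9
  p_le <- mean(us <= u_obs + eps)
  p_ge <- mean(us >= u_obs - eps)
  switch(alternative,
         less = p_le,
         greater = p_ge,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

#' Mann-Whitney comparison of methylation levels
#'
#' Rank-sum test between two sets of site methylation levels. The U
#' statistic counts, over all cross pairs, wins of the first set (ties count
#' one half). For small samples (both n <= 8) the p-value is computed by
#' exact enumeration of all rank assignments; otherwise by the normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b numeric vectors of levels.
#' @param alternative "two.sided" (default), "less" or "greater";
#'   "less" tests whether \code{a} is stochastically smaller than \code{b}.
#' @param exact_max largest per-group size for the exact path (default 8).
#' @return list with \code{U}, \code{p.value} and \code{method}.
#' @export
level_shift_test <- function(a, b, alternative = c("two.sided", "less", "greater"),
                             exact_max = 8L) {
  alternative <- match.arg(alternative)
  if (length(a) < 1L || length(b) < 1L) stop("both sets must be nonempty")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    p <- .mw_exact(a, b, u, alternative)
    return(list(U = u, p.value = p, method = "exact"))
  }
  n <- n1 + n2
  mu <- n1 * n2 / 2
  ties <- table(c(a, b))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(U = u, p.value = 1, method = "normal"))
  sigma <- sqrt(sigma2)
  z <- switch(alternative,
              two.sided = (u - mu - sign(u - mu) * 0.5) / sigma,
              less = (u - mu + 0.5) / sigma,
              greater = (u - mu - 0.5) / sigma)
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              less = stats::pnorm(z),
              greater = stats::pnorm(z, lower.tail = FALSE))
  list(U = u, p.value = min(1, p), method = "normal")
}
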