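#' Approximate randomization test for paired classifier predictions
#'
#' Starting from the labels assigned by two classifiers to the same held-out
#' items, each prediction pair is swapped with probability 1/2 and the
#' accuracy difference `d'` recomputed; over `R` replicates, with `r` the
#' number of times `d'` meets or exceeds the observed difference `d`, the
#' significance level is approximated by `p = (r + 1) / (R + 1)`. The default
#' is two-sided: `d` and `d'` are absolute accuracy differences. Swapping a
#' pair flips the sign of that item's accuracy-difference contribution, so
#' replicates are computed directly on the per-item difference vector.
#'
#' @param gold Integer vector of gold labels.
#' @param preds_a,preds_b Predicted-label vectors, paired with `gold`.
#' @param R Number of replicates (the study default is 1e5).
#' @param seed Integer seed; results are reproducible given the seed.
#' @param sided `"two"` (default) or `"one"` (tests `acc_a - acc_b` against
#'   its sign-flipped replicates).
#' @return An `art_result` list: `d` (observed difference `acc_a - acc_b`),
#'   `r`, `R`, `p`, `sided`, `seed`.
#' @export
art_test <- function(gold, preds_a, preds_b, R = 1e5, seed = 0L,
                     sided = c("two", "one")) {
  sided <- match.arg(sided)
  n <- length(gold)
  if (length(preds_a) != n || length(preds_b) != n) {
    stop("gold, preds_a, and preds_b must have equal length")
  }
  stopifnot(n >= 1, R >= 1)
  R <- as.integer(R)
  delta <- (preds_a == gold) - (preds_b == gold)   # per-item contribution
  d_signed <- mean(delta)
  d <- if (sided == "two") abs(d_signed) else d_signed
  nz <- which(delta != 0)
  m <- length(nz)
  r <- 0L
  withr::with_seed(as.integer(seed), {
    if (m == 0L) {
      r <- R                                       # all replicates give d' = 0
    } else {
      dnz <- delta[nz]
      chunk <- max(1L, min(R, 200000L %/% m))
      done <- 0L
      while (done < R) {
        nb <- min(chunk, R - done)
        swap <- matrix(stats::runif(nb * m) < 0.5, nrow = nb)
        signs <- 1 - 2 * swap
        dprime <- as.vector(signs %*% dnz) / n
        if (sided == "two") dprime <- abs(dprime)
        r <- r + sum(dprime >= d - 1e-12)
        done <- done + nb
      }
    }
  })
  structure(list(d = d_signed, r = as.integer(r), R = R,
                 p = (r + 1) / (R + 1), sided = sided,
                 seed = as.integer(seed)),
            class = "art_result")
}

#' @export
print.art_result <- function(x, ...) {
  cat(sprintf("ART: d = %+.4f, p = %.4g (r = %d of R = %d, %s-sided)\n",
              x$d, x$p, x$r, x$R, x$sided))
  invisible(x)
}

#' Exact randomization test by full enumeration
#'
#' Enumerates all `2^n` swap patterns (feasible for `n <= 20`) and reports
#' the exact p-value under the same add-one convention as [art_test()]
#' (`p = (#\{d' >= d\} + 1) / (2^n + 1)`) together with the raw proportion
#' `#\{d' >= d\} / 2^n`. Items on which both classifiers agree in correctness
#' contribute nothing to `d'`, so only the sign patterns of the non-zero
#' contributions are enumerated.
#'
#' @inheritParams art_test
#' @return List with `d`, `p` (add-one convention), `p_raw` (plain
#'   proportion), and `n_patterns`.
#' @export
exact_art <- function(gold, preds_a, preds_b, sided = c("two", "one")) {
  sided <- match.arg(sided)
  n <- length(gold)
  if (length(preds_a) != n || length(preds_b) != n) {
    stop("gold, preds_a, and preds_b must have equal length")
  }
  if (n > 20) stop("exact enumeration requires n <= 20")
  delta <- (preds_a == gold) - (preds_b == gold)
  d_signed <- mean(delta)
  d <- if (sided == "two") abs(d_signed) else d_signed
  nz <- delta[delta != 0]
  m <- length(nz)
  if (m == 0L) {
    count <- 2^n
  } else {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), m)))
    dprime <- as.vector(signs %*% nz) / n
    if (sided == "two") dprime <- abs(dprime)
    count <- sum(dprime >= d - 1e-12) * 2^(n - m)
  }
  list(d = d_signed, p = (count + 1) / (2^n + 1), p_raw = count / 2^n,
       n_patterns = 2^n)
}

#' Bonferroni correction for a pre-registered comparison family
#'
#' @param p_values Numeric vector of p-values.
#' @param family_size Number of comparisons in the family (defaults to the
#'   number of p-values; the study uses 18 per corpus).
#' @param alpha Family-wise significance level in (0, 1).
#' @return List with `reject` (logical vector, `p <= alpha / family_size`),
#'   `threshold`, `family_size`, `alpha`.
#' @export
bonferroni <- function(p_values, family_size = length(p_values),
                       alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  stopifnot(family_size >= length(p_values), family_size >= 1)
  threshold <- alpha / family_size
  list(reject = p_values <= threshold, threshold = threshold,
       family_size = as.integer(family_size), alpha = alpha)
}

#' Significance stars at Bonferroni-corrected thresholds
#'
#' `"*"`, `"**"`, `"***"` for p at or below the corrected 0.05, 0.01, and
#' 0.001 levels (each level divided by the family size); `""` otherwise.
#'
#' @param p P-value(s).
#' @param family_size Comparison-family size (default 18 per corpus).
#' @return Character vector of star codes.
#' @export
star_code <- function(p, family_size = 18L) {
  vapply(p, function(pp) {
    if (pp <= 0.001 / family_size) "***"
    else if (pp <= 0.01 / family_size) "**"
    else if (pp <= 0.05 / family_size) "*"
    else ""
  }, character(1))
}
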