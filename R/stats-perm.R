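# Inferential machinery: two-sample permutation test of mean equality
# (H0: mu1 - mu2 = 0, two-sided, 1600 permutations by default) and
# Benjamini-Hochberg FDR adjustment.

#' Two-sample permutation test for equality of means
#'
#' Statistic `T = mean(x) - mean(y)`. Group labels are permuted uniformly at
#' random `n_perm` times; when the number of distinct splits `choose(n, nx)`
#' does not exceed `n_perm` every split is enumerated instead and the exact
#' proportion is returned (`exhaustive = TRUE`). The sampled two-sided p-value
#' uses the add-one correction `p = (1 + #{|T*| >= |T|}) / (1 + n_perm)` so it
#' can never be zero. Deterministic under a fixed seed.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @param n_perm number of random permutations (default 1600).
#' @param seed RNG seed.
#' @return object of class `permutation_result`: list with `observed`, `p`,
#'   `n_permutations`, `seed`, `exhaustive`, `note`.
#' @export
permutation_test <- function(x, y, n_perm = 1600L, seed = 1L) {
  stopifnot(is.numeric(x), is.numeric(y), all(is.finite(x)), all(is.finite(y)))
  if (length(x) < 2L || length(y) < 2L) {
    stop("permutation_test: each sample needs >= 2 values")
  }
  obs <- mean(x) - mean(y)
  pooled <- c(x, y)
  nx <- length(x); n <- length(pooled)
  note <- NULL
  tol <- 1e-12 * max(1, abs(obs), max(abs(pooled)))
  if (max(pooled) - min(pooled) <= 0) {
    return(structure(list(observed = obs, p = 1, n_permutations = 0L,
                          seed = seed, exhaustive = TRUE,
                          note = "degenerate: all values identical"),
                     class = "permutation_result"))
  }
  n_splits <- choose(n, nx)
  if (n_splits <= n_perm) {
    idx <- utils::combn(n, nx)
    tstar <- apply(idx, 2L, function(i) {
      mean(pooled[i]) - mean(pooled[-i])
    })
    p <- sum(abs(tstar) >= abs(obs) - tol) / n_splits
    return(structure(list(observed = obs, p = p,
                          n_permutations = as.integer(n_splits), seed = seed,
                          exhaustive = TRUE, note = note),
                     class = "permutation_result"))
  }
  tstar <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      g <- sample.int(n, nx)
      mean(pooled[g]) - mean(pooled[-g])
    }, numeric(1))
  })
  p <- (1 + sum(abs(tstar) >= abs(obs) - tol)) / (1 + n_perm)
  structure(list(observed = obs, p = p, n_permutations = as.integer(n_perm),
                 seed = seed, exhaustive = FALSE, note = note),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test: T = %.4g, p = %.4g (%s, %d permutations)\n",
              x$observed, x$p,
              if (x$exhaustive) "exhaustive" else "sampled",
              x$n_permutations))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment: sort ascending, `q_i = p_i * m / i`, enforce
#' monotonicity from the largest rank down, cap at 1, return in input order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  stopifnot(all(p > 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Pairwise period comparisons of a feature table
#'
#' For each feature and period pair runs the unpaired permutation test on the
#' per-recording period values (the default exchangeable unit). The reported
#' descriptives are paired: mean and SD of the per-recording differences,
#' first-listed period minus second (so a positive MTI-PRE change is an
#' increase during MTI). Features whose name appears in `fdr_groups` are
#' additionally routed through [bh_fdr()] within their group.
#'
#' @param tab data.frame with columns `recording`, `period`, `feature`,
#'   `value` (one row per recording x period x feature).
#' @param pairs list of `c(a, b)` period pairs, compared as a - b.
#' @param n_perm,seed,alpha permutation-test configuration.
#' @param fdr_groups optional named list: group label -> character vector of
#'   feature names adjusted together.
#' @return data.frame with `feature`, `pair`, `mean_change`, `sd_change`, `p`,
#'   `p_adjusted` (NA outside FDR groups), `significant`.
#' @export
compare_periods <- function(tab,
                            pairs = list(c("mti", "pre"), c("post", "pre"),
                                         c("mti", "post")),
                            n_perm = 1600L, seed = 1L, alpha = 0.05,
                            fdr_groups = NULL) {
  stopifnot(all(c("recording", "period", "feature", "value") %in% names(tab)))
  res <- list()
  for (feat in unique(tab$feature)) {
    sub <- tab[tab$feature == feat, ]
    for (pr in pairs) {
      a <- sub[sub$period == pr[1L], ]
      b <- sub[sub$period == pr[2L], ]
      common <- intersect(a$recording, b$recording)
      if (length(common) < 2L) {
        stop("compare_periods: need >= 2 recordings per period for ", feat)
      }
      av <- a$value[match(common, a$recording)]
      bv <- b$value[match(common, b$recording)]
      pt <- permutation_test(av, bv, n_perm = n_perm,
                             seed = derive_seed(seed, feat, pr[1L], pr[2L]))
      res[[length(res) + 1L]] <- data.frame(
        feature = feat, pair = paste(pr[1L], pr[2L], sep = "-"),
        mean_change = mean(av - bv), sd_change = stats::sd(av - bv),
        p = pt$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$p_adjusted <- NA_real_
  if (!is.null(fdr_groups)) {
    for (g in fdr_groups) {
      for (pr_lab in unique(out$pair)) {
        sel <- out$feature %in% g & out$pair == pr_lab
        if (any(sel)) out$p_adjusted[sel] <- bh_fdr(out$p[sel])
      }
    }
  }
  out$significant <- ifelse(is.na(out$p_adjusted), out$p, out$p_adjusted) < alpha
  out
}
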