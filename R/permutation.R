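# Permutation-based significance: FDR tables for transcriptome-wide scans
# and genome-wide empirical p-values for individual (behavioral) traits.

#' Permutation FDR table for a transcriptome-wide scan
#'
#' Computes the observed per-trait per-chromosome maximum LRS values, then
#' repeats the scan under `n_perm` permutations of the strain labels. By
#' default each permutation applies ONE shared shuffle to all traits, which
#' preserves the trait-trait correlation structure of the matrix
#' (`shared_permutation = FALSE` shuffles each trait independently). For each
#' threshold theta on the grid,
#' \deqn{FDR(\theta) = \frac{mean_{perm}\,\#\{permuted\ maxima > \theta\}}{\#\{observed\ maxima > \theta\}}}
#' with the estimate reported as missing where no observed maximum exceeds
#' theta. The reported curve is made non-increasing in theta by a running
#' minimum over the ascending grid, and the smallest grid theta with
#' FDR <= `target` is returned (NA when none attains it, e.g. under a global
#' null where the estimator is ~1 everywhere).
#'
#' @param traits_mat Numeric trait x strain matrix (one condition).
#' @param geno A [geno_matrix()].
#' @param n_perm Number of permutations (>= 1; the study design uses 1000).
#' @param theta_grid Ascending LRS thresholds to tabulate.
#' @param target FDR target for threshold selection (default 0.05).
#' @param shared_permutation One shuffle shared across traits per iteration?
#' @param seed Optional RNG seed.
#' @param cap Perfect-fit LRS cap.
#' @return An object of class `fdr_table`: list with `table` (`data.frame`
#'   with columns `theta`, `n_observed`, `mean_permuted`, `fdr`),
#'   `theta_at_target`, `target`, `n_perm`, `observed_maxima` (numeric vector,
#'   all trait-chromosome maxima), and `perm_maxima` (pooled permuted maxima,
#'   used by [significance_threshold()]).
#' @export
permutation_fdr <- function(traits_mat, geno, n_perm = 1000,
                            theta_grid = seq(5, 50, by = 0.5), target = 0.05,
                            shared_permutation = TRUE, seed = NULL, cap = 300) {
  stopifnot(n_perm >= 1, !is.unsorted(theta_grid))
  maybe_seed(seed)
  al <- align_condition(traits_mat, geno)
  map <- geno$markers[match(al$markers, geno$markers$marker), ]
  blocks <- split(seq_along(al$markers), chrom_factor(map$chr), drop = TRUE)
  chrom_maxima <- function(lrs) {
    unlist(lapply(blocks, function(idx) {
      sub <- lrs[, idx, drop = FALSE]
      sub[cbind(seq_len(nrow(sub)), max.col(sub, ties.method = "first"))]
    }), use.names = FALSE)
  }
  obs <- chrom_maxima(lrs_matrix(al$X, al$G, cap = cap)$lrs)
  n_strain <- nrow(al$X)
  perm_max <- matrix(NA_real_, n_perm, length(obs))
  for (k in seq_len(n_perm)) {
    Xp <- if (shared_permutation) {
      al$X[sample.int(n_strain), , drop = FALSE]
    } else {
      apply(al$X, 2, sample)
    }
    perm_max[k, ] <- chrom_maxima(lrs_matrix(Xp, al$G, cap = cap)$lrs)
  }
  n_obs <- vapply(theta_grid, function(th) sum(obs > th), numeric(1))
  mean_perm <- vapply(theta_grid, function(th) mean(rowSums(perm_max > th)),
                      numeric(1))
  fdr_raw <- ifelse(n_obs > 0, mean_perm / n_obs, NA_real_)
  fdr <- cummin_na(fdr_raw)
  ok <- which(!is.na(fdr) & fdr <= target)
  structure(
    list(table = data.frame(theta = theta_grid, n_observed = n_obs,
                            mean_permuted = mean_perm, fdr = fdr),
         theta_at_target = if (length(ok)) theta_grid[min(ok)] else NA_real_,
         target = target, n_perm = n_perm,
         observed_maxima = obs,
         perm_maxima = as.vector(perm_max)),
    class = "fdr_table"
  )
}

# Running minimum that passes NA through untouched.
cummin_na <- function(x) {
  cur <- Inf
  for (i in seq_along(x)) {
    if (!is.na(x[i])) {
      cur <- min(cur, x[i])
      x[i] <- cur
    }
  }
  x
}

#' @export
print.fdr_table <- function(x, ...) {
  cat(sprintf("fdr_table: %d permutations, %d observed trait-chromosome maxima\n",
              x$n_perm, length(x$observed_maxima)))
  cat(sprintf("  smallest theta with FDR <= %.2f: %s\n", x$target,
              ifelse(is.na(x$theta_at_target), "none on grid",
                     format(x$theta_at_target))))
  invisible(x)
}

#' Significance threshold from a permutation FDR object
#'
#' Two constructions are available. `"fdr"` returns the smallest grid
#' threshold whose estimated FDR is at or below `rate` (appropriate when the
#' scan contains signal; missing under a global null, where the FDR estimator
#' is ~1 everywhere). `"null-quantile"` returns the `(1 - rate)` quantile of
#' the pooled permuted trait-chromosome maxima: the per-comparison threshold
#' at which a null trait-chromosome maximum exceeds it with probability
#' `rate`.
#'
#' @param fdr An `fdr_table` from [permutation_fdr()].
#' @param rate Target rate (default 0.05).
#' @param method `"fdr"` or `"null-quantile"`.
#' @return A scalar LRS threshold (NA if the FDR curve never reaches `rate`).
#' @export
significance_threshold <- function(fdr, rate = 0.05,
                                   method = c("fdr", "null-quantile")) {
  method <- match.arg(method)
  stopifnot(inherits(fdr, "fdr_table"))
  if (method == "fdr") {
    if (!identical(rate, fdr$target)) {
      ok <- which(!is.na(fdr$table$fdr) & fdr$table$fdr <= rate)
      return(if (length(ok)) fdr$table$theta[min(ok)] else NA_real_)
    }
    return(fdr$theta_at_target)
  }
  unname(stats::quantile(fdr$perm_maxima, 1 - rate, names = FALSE))
}

#' Genome-wide empirical p-value for one trait
#'
#' The observed genome-wide maximum LRS is compared with the maxima obtained
#' under `n_perm` permutations of the strain labels:
#' `p = (1 + #permuted maxima >= observed) / (n_perm + 1)`.
#'
#' @param trait Named numeric vector of strain-mean values.
#' @param geno A [geno_matrix()].
#' @param n_perm Number of permutations (the study design uses 1000).
#' @param seed Optional RNG seed.
#' @param cap Perfect-fit LRS cap.
#' @return List: `p_value`, `max_lrs`, `best_marker`, `n_perm`.
#' @export
genomewide_pvalue <- function(trait, geno, n_perm = 1000, seed = NULL,
                              cap = 300) {
  stopifnot(n_perm >= 1)
  maybe_seed(seed)
  tm <- matrix(trait, nrow = 1, dimnames = list("trait", names(trait)))
  al <- align_condition(tm, geno)
  lrs <- lrs_matrix(al$X, al$G, cap = cap)$lrs[1, ]
  obs <- max(lrs)
  best <- al$markers[which.max(lrs)]
  n_strain <- nrow(al$X)
  exceed <- 0L
  for (k in seq_len(n_perm)) {
    Xp <- al$X[sample.int(n_strain), , drop = FALSE]
    if (max(lrs_matrix(Xp, al$G, cap = cap)$lrs) >= obs) exceed <- exceed + 1L
  }
  list(p_value = (1 + exceed) / (n_perm + 1), max_lrs = obs,
       best_marker = best, n_perm = n_perm)
}
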