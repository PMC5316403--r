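# Independent oracles and small fixtures, built in code.

# Exhaustive grid-search oracle for the constrained sigmoid fit:
# log10 EC50 in [log10(min dose/100), log10(max dose*100)] step `e_step`,
# Top in [1, 150] step `top_step`. Independent of the package's profiled
# optimizer.
grid_fit_oracle <- function(conc, viab, e_step = 0.01, top_step = 0.5) {
  e_grid <- seq(log10(min(conc) / 100), log10(max(conc) * 100), by = e_step)
  top_grid <- seq(1, 150, by = top_step)
  w <- 1 / (1 + outer(conc, 10^e_grid, "/"))        # n x E
  a <- colSums(w * w)                               # E
  b <- colSums(viab * w)                            # E
  sv2 <- sum(viab^2)
  # rss(e, top) = sv2 - 2 top b[e] + top^2 a[e]
  rss <- outer(b, top_grid, function(bb, tt) -2 * tt * bb) +
    outer(a, top_grid, function(aa, tt) tt^2 * aa) + sv2
  idx <- arrayInd(which.min(rss), dim(rss))
  list(rss = rss[idx], log10_ec50 = e_grid[idx[1]], top = top_grid[idx[2]])
}

# Naive hand-executable complete-linkage agglomeration on a distance
# matrix; returns the column label sets merged at each step and the merge
# heights, independent of stats::hclust.
naive_complete_linkage <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(colnames(d))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1]] <- merged
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  list(merges = merges, heights = heights)
}

# Cluster membership sets implied by an hclust object, step by step.
hclust_merge_sets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    members <- function(x) {
      if (x < 0) hc$labels[-x] else sets[[x]]
    }
    sets[[k]] <- sort(c(members(hc$merge[k, 1]), members(hc$merge[k, 2])))
  }
  sets
}

# Simulate one noisy dilution series from the constrained sigmoid.
make_series <- function(ec50, top = 100, grid = c(3, 5, 10, 30, 50, 100, 300),
                        reps = 3, noise = 5) {
  conc <- rep(grid, each = reps)
  viab <- pmax(top / (1 + conc / ec50) + rnorm(length(conc), 0, noise), 0)
  tibble::tibble(concentration_um = conc, viability_pct = viab)
}

# Residual-permutation reference p-value for the curve-comparison F-test:
# residuals of the shared (pooled) fit are permuted between the two series,
# the F statistic recomputed each time, and the upper-tail proportion
# returned.
permutation_p <- function(a, b, n_perm = 400) {
  pooled_conc <- c(a$concentration_um, b$concentration_um)
  pooled_viab <- c(a$viability_pct, b$viability_pct)
  pooled <- fit_series(pooled_conc, pooled_viab)
  fitted_vals <- pooled$top / (1 + pooled_conc / pooled$ec50_um)
  resid <- pooled_viab - fitted_vals
  n_a <- nrow(a)
  f_obs <- compare_series(a, b)$f_stat
  f_perm <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    r <- sample(resid)
    viab <- fitted_vals + r
    ap <- tibble::tibble(concentration_um = pooled_conc[seq_len(n_a)],
                         viability_pct = viab[seq_len(n_a)])
    bp <- tibble::tibble(concentration_um = pooled_conc[-seq_len(n_a)],
                         viability_pct = viab[-seq_len(n_a)])
    f_perm[k] <- compare_series(ap, bp)$f_stat
  }
  mean(f_perm >= f_obs)
}
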