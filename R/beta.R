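#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = 1 - 2 sum_i min(x_i, y_i) / sum_i (x_i + y_i)`, computed for
#' every sample pair. Uses the identity
#' `2 sum min(x, y) = sum(x) + sum(y) - sum |x - y|`, so the pairwise work is
#' a single Manhattan distance.
#'
#' @param x A `rel_abund_table`, [count_table()], or numeric OTU x sample
#'   matrix with no all-zero column.
#' @return A `distance_matrix`: symmetric numeric matrix with zero diagonal
#'   and sample ids as dimnames.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "rel_abund_table")) x$values
       else if (inherits(x, "count_table")) x$counts
       else as.matrix(x)
  if (ncol(m) < 2) stopf("need at least 2 samples")
  tot <- colSums(m)
  if (any(tot <= 0)) {
    stopf("all-zero sample profile(s): %s",
          paste(utils::head(colnames(m)[tot <= 0], 5), collapse = ", "))
  }
  man <- as.matrix(stats::dist(t(m), method = "manhattan"))
  denom <- outer(tot, tot, "+")
  d <- man / denom
  diag(d) <- 0
  dimnames(d) <- list(colnames(m), colnames(m))
  class(d) <- c("distance_matrix", "matrix")
  d
}

as_distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stopf("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-8) stopf("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stopf("distance matrix must have a zero diagonal")
  if (is.null(rownames(d))) {
    dimnames(d) <- list(paste0("s", seq_len(nrow(d))), paste0("s", seq_len(nrow(d))))
  }
  class(d) <- c("distance_matrix", "matrix")
  d
}

#' @rdname bray_curtis
#' @param d A `distance_matrix`.
#' @param path TSV path (square, with header row and id column).
#' @export
write_distance_matrix <- function(d, path) {
  d <- as_distance_matrix(d)
  df <- data.frame(sample_id = rownames(d), unclass(d), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname bray_curtis
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  as_distance_matrix(m)
}

# pooled-adjacent-violators: weighted least-squares monotone fit to y
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n == 0) return(numeric(0))
  val <- y; wt <- w; idx <- rep(1L, n)   # block values, weights, sizes
  nb <- 0L
  for (i in seq_len(n)) {
    nb <- nb + 1L
    val[nb] <- y[i]; wt[nb] <- w[i]; idx[nb] <- 1L
    while (nb > 1L && val[nb - 1L] > val[nb]) {
      tw <- wt[nb - 1L] + wt[nb]
      val[nb - 1L] <- (wt[nb - 1L] * val[nb - 1L] + wt[nb] * val[nb]) / tw
      wt[nb - 1L] <- tw
      idx[nb - 1L] <- idx[nb - 1L] + idx[nb]
      nb <- nb - 1L
    }
  }
  rep(val[seq_len(nb)], idx[seq_len(nb)])
}

lower_tri_pairs <- function(n) {
  ij <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  ij[order(ij[, 2], ij[, 1]), , drop = FALSE]
}

config_dist <- function(X, pairs) {
  dx <- X[pairs[, 1], , drop = FALSE] - X[pairs[, 2], , drop = FALSE]
  sqrt(rowSums(dx * dx))
}

# Kruskal stress-1 of configuration distances D against dissimilarity order
# `ord` (primary/weak ties: within tied dissimilarities, D is pre-sorted so
# ties impose no constraint)
stress1 <- function(D, ord_key) {
  ord <- order(ord_key, D)
  dhat <- numeric(length(D))
  dhat[ord] <- pava(D[ord])
  T2 <- sum(D^2)
  if (T2 <= 0) return(list(stress = 0, dhat = dhat))
  list(stress = sqrt(sum((D - dhat)^2) / T2), dhat = dhat)
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Embeds a dissimilarity matrix in `k` dimensions by minimizing Kruskal's
#' stress-1, `sqrt(sum((D - Dhat)^2) / sum(D^2))`, where `Dhat` are
#' monotone-regressed disparities (pooled-adjacent-violators isotonic fit of
#' configuration distances against the dissimilarity ranks; tied
#' dissimilarities are unconstrained, i.e. the primary/weak approach).
#' Optimization is steepest descent with a backtracking line search, so the
#' stress of accepted iterations never increases. The first start is the
#' classical (metric) MDS solution; the remaining `n_restarts - 1` starts
#' are random, and the lowest-stress configuration wins.
#'
#' @param d A `distance_matrix` (or square symmetric matrix).
#' @param k Embedding dimension (>= 1).
#' @param n_restarts Number of starts (default 20).
#' @param max_iter Iteration cap per restart (default 300).
#' @param tol Relative stress-improvement convergence tolerance.
#' @param seed Integer seed for the random starts.
#' @return An `ordination_result`: `points` (sample x k coordinates),
#'   `stress`, `n_restarts`, `best_restart`, `converged` (FALSE when the
#'   best restart hit `max_iter` without meeting `tol`), `iterations`.
#' @export
nmds <- function(d, k = 2, n_restarts = 20, max_iter = 300, tol = 1e-6,
                 seed = NULL) {
  d <- as_distance_matrix(d)
  n <- nrow(d)
  if (!is_count_scalar(k, 1)) stopf("`k` must be a positive integer")
  if (n < 3) stopf("need at least 3 samples to ordinate")
  pairs <- lower_tri_pairs(n)
  diss <- d[pairs]
  rk <- rank(diss, ties.method = "min")

  run_start <- function(X0) {
    X <- X0
    D <- config_dist(X, pairs)
    st <- stress1(D, rk)
    conv <- FALSE
    it <- 0L
    step <- 0.2
    while (it < max_iter) {
      it <- it + 1L
      S <- st$stress
      if (S <= 1e-12) { conv <- TRUE; break }
      Sstar <- sum((D - st$dhat)^2)
      T2 <- sum(D^2)
      Dsafe <- pmax(D, 1e-12)
      # dS/dD with disparities held fixed
      gD <- S * ((D - st$dhat) / max(Sstar, 1e-300) - D / T2)
      G <- matrix(0, n, k)
      coef <- gD / Dsafe
      dx <- X[pairs[, 1], , drop = FALSE] - X[pairs[, 2], , drop = FALSE]
      contrib <- dx * coef
      for (col in seq_len(k)) {
        G[, col] <- rowsum(c(contrib[, col], -contrib[, col]),
                           c(pairs[, 1], pairs[, 2]), reorder = TRUE)
      }
      gn <- sqrt(sum(G^2))
      if (gn < 1e-14) { conv <- TRUE; break }
      scale_len <- sqrt(sum(X^2)) / gn
      accepted <- FALSE
      s_try <- step
      for (half in 1:20) {
        Xn <- X - s_try * scale_len * G
        Dn <- config_dist(Xn, pairs)
        stn <- stress1(Dn, rk)
        if (stn$stress < S) { accepted <- TRUE; break }
        s_try <- s_try / 2
      }
      if (!accepted) { conv <- TRUE; break }
      improved <- (S - stn$stress) / max(S, 1e-300)
      X <- Xn; D <- Dn; st <- stn
      step <- min(0.5, s_try * 2)
      if (improved < tol) { conv <- TRUE; break }
    }
    list(X = X, stress = st$stress, converged = conv, iterations = it)
  }

  with_seed(seed, {
    starts <- vector("list", n_restarts)
    cm <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = k))
    if (ncol(cm) < k) {
      cm <- cbind(cm, matrix(stats::rnorm(n * (k - ncol(cm)), sd = 1e-4), n))
    }
    starts[[1]] <- cm
    if (n_restarts > 1) {
      rng <- max(d)
      for (r in 2:n_restarts) {
        starts[[r]] <- matrix(stats::runif(n * k, -rng, rng), n, k)
      }
    }
    fits <- lapply(starts, run_start)
    best <- which.min(vapply(fits, `[[`, 0, "stress"))
    fit <- fits[[best]]
    pts <- fit$X
    dimnames(pts) <- list(rownames(d), paste0("NMDS", seq_len(k)))
    structure(list(points = pts, stress = fit$stress,
                   n_restarts = n_restarts, best_restart = best,
                   converged = fit$converged, iterations = fit$iterations,
                   seed = seed),
              class = "ordination_result")
  })
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("nMDS ordination: %d points in %d dims, stress-1 = %.4f (%s, best of %d starts)\n",
              nrow(x$points), ncol(x$points), x$stress,
              if (x$converged) "converged" else "not converged", x$n_restarts))
  invisible(x)
}

permanova_ss <- function(d2, idx_list, ng, N) {
  sst <- sum(d2) / (2 * N)
  ssw <- 0
  for (g in seq_along(idx_list)) {
    ii <- idx_list[[g]]
    ssw <- ssw + sum(d2[ii, ii]) / (2 * ng[[g]])
  }
  c(sst = sst, ssw = ssw)
}

#' Permutational multivariate analysis of variance (one-way)
#'
#' Partitions the squared dissimilarities into between- and within-group
#' sums of squares: `SS_total = sum_{i<j} d_ij^2 / N`,
#' `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`,
#' `SS_between = SS_total - SS_within`, and tests
#' `pseudo-F = (SS_between / (a - 1)) / (SS_within / (N - a))` by permuting
#' the group labels. The permutation p-value uses the add-one convention
#' `p = (#{F_perm >= F_obs} + 1) / (n_permutations + 1)`, so `p > 0` always.
#' With `permutations = "exhaustive"` (N <= 8) every relabeling is
#' enumerated and `p` is the exact proportion with `F_perm >= F_obs`.
#'
#' @param d A `distance_matrix`.
#' @param groups Group labels, one per sample (>= 2 groups).
#' @param n_permutations Number of random permutations (default 999).
#' @param seed Integer seed.
#' @param permutations `"sampled"` (default) or `"exhaustive"`.
#' @return A `permanova_result` list: `pseudo_F`, `R2`, `p_value`,
#'   `n_permutations`, `df_between`, `df_within`, `n`, `seed`, `method`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = NULL,
                      permutations = c("sampled", "exhaustive")) {
  d <- as_distance_matrix(d)
  permutations <- match.arg(permutations)
  N <- nrow(d)
  if (length(groups) != N) stopf("`groups` must have one label per sample")
  if (N < 3) stopf("need at least 3 samples")
  g <- factor(groups)
  a <- nlevels(g)
  if (a < 2) stopf("need at least 2 groups")
  if (any(table(g) == N)) stopf("a group equals the whole sample set")
  if (permutations == "sampled" && !is_count_scalar(n_permutations, 1)) {
    stopf("`n_permutations` must be >= 1")
  }
  d2 <- unclass(d)^2
  f_of <- function(gi) {
    idx <- split(seq_len(N), gi)
    ng <- lengths(idx)
    ss <- permanova_ss(d2, idx, ng, N)
    ssb <- ss[["sst"]] - ss[["ssw"]]
    list(F = (ssb / (a - 1)) / (ss[["ssw"]] / (N - a)),
         R2 = ssb / ss[["sst"]])
  }
  obs <- f_of(g)
  if (permutations == "exhaustive") {
    if (N > 8) stopf("exhaustive enumeration supported for N <= 8 (got %d)", N)
    perms <- all_permutations(N)
    fp <- vapply(seq_len(nrow(perms)), function(i) f_of(g[perms[i, ]])$F, 0)
    p <- mean(fp >= obs$F - 1e-12)
    nperm <- nrow(perms)
  } else {
    fp <- with_seed(seed, {
      vapply(seq_len(n_permutations),
             function(i) f_of(g[sample.int(N)])$F, 0)
    })
    p <- (sum(fp >= obs$F - 1e-12) + 1) / (n_permutations + 1)
    nperm <- n_permutations
  }
  structure(list(pseudo_F = obs$F, R2 = obs$R2, p_value = p,
                 n_permutations = nperm, df_between = a - 1,
                 df_within = N - a, n = N, seed = seed,
                 method = permutations),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.3f, p = %.4g (df = %d, %d; n = %d; %d permutations)\n",
              x$pseudo_F, x$R2, x$p_value, x$df_between, x$df_within, x$n,
              x$n_permutations))
  invisible(x)
}

# all N! row permutations of 1..N (N small)
all_permutations <- function(N) {
  if (N == 1) return(matrix(1L))
  sub <- all_permutations(N - 1L)
  out <- matrix(0L, nrow = N * nrow(sub), ncol = N)
  r <- 0L
  for (pos in seq_len(N)) {
    blk <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], N,
                 sub[, seq(pos, N - 1L)[seq_len(N - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

#' Two-way fixed-effects ANOVA (Type II) with Tukey HSD on factor A
#'
#' Fits the cell-means model with interaction and reports Type II sums of
#' squares -- appropriate for the unbalanced sampling designs of field
#' surveys -- with F tests against the full-model mean squared error.
#' Pairwise comparisons of factor-A marginal means use the Tukey-Kramer
#' studentized-range adjustment.
#'
#' @param values Numeric response (e.g. per-sample Shannon index).
#' @param factor_a,factor_b Grouping labels (>= 2 levels each).
#' @return An `anova_tukey_result`: `anova` (data frame with SS, df, F, p
#'   for A, B, A:B and residuals) and `tukey` (pairwise factor-A table with
#'   difference, SE and adjusted p).
#' @export
anova_tukey <- function(values, factor_a, factor_b) {
  fa <- factor(factor_a)
  fb <- factor(factor_b)
  if (nlevels(fa) < 2 || nlevels(fb) < 2) {
    stopf("both factors need at least 2 levels")
  }
  stopifnot(length(values) == length(fa), length(values) == length(fb))
  y <- as.numeric(values)
  rss <- function(form) {
    fit <- stats::lm(form, data = data.frame(y = y, fa = fa, fb = fb))
    sum(stats::residuals(fit)^2)
  }
  rss_a <- rss(y ~ fa)
  rss_b <- rss(y ~ fb)
  rss_ab <- rss(y ~ fa + fb)
  full <- stats::lm(y ~ fa + fb + fa:fb)
  rss_full <- sum(stats::residuals(full)^2)
  df_res <- stats::df.residual(full)
  if (df_res <= 0) stopf("zero residual degrees of freedom")
  mse <- rss_full / df_res
  df_a <- nlevels(fa) - 1
  df_b <- nlevels(fb) - 1
  # interaction df from the fitted rank (empty cells reduce it)
  df_int <- (length(y) - df_res) - (1 + df_a + df_b)
  ss_a <- rss_b - rss_ab          # SS(A | B)
  ss_b <- rss_a - rss_ab          # SS(B | A)
  ss_int <- rss_ab - rss_full
  frow <- function(ss, df) {
    if (df <= 0) return(c(F = NA_real_, p = NA_real_))
    f <- (ss / df) / mse
    c(F = f, p = stats::pf(f, df, df_res, lower.tail = FALSE))
  }
  tab <- data.frame(
    term = c("factor_a", "factor_b", "interaction", "residuals"),
    df = c(df_a, df_b, df_int, df_res),
    sum_sq = c(ss_a, ss_b, ss_int, rss_full),
    F = c(frow(ss_a, df_a)[1], frow(ss_b, df_b)[1], frow(ss_int, df_int)[1], NA),
    p = c(frow(ss_a, df_a)[2], frow(ss_b, df_b)[2], frow(ss_int, df_int)[2], NA),
    stringsAsFactors = FALSE
  )
  lev <- levels(fa)
  means <- tapply(y, fa, mean)
  nn <- tapply(y, fa, length)
  cmb <- utils::combn(length(lev), 2)
  tk <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
    i1 <- cmb[1, j]; i2 <- cmb[2, j]
    diff <- means[i2] - means[i1]
    se <- sqrt(mse / 2 * (1 / nn[i1] + 1 / nn[i2]))
    q <- abs(diff) / se
    p_adj <- if (se == 0) {
      if (abs(diff) < 1e-12) 1 else 0
    } else {
      stats::ptukey(q, nmeans = length(lev), df = df_res, lower.tail = FALSE)
    }
    data.frame(level_1 = lev[i1], level_2 = lev[i2],
               difference = unname(diff), se = unname(se),
               p_adj = min(1, p_adj), stringsAsFactors = FALSE)
  }))
  structure(list(anova = tab, tukey = tk, mse = mse, df_residual = df_res),
            class = "anova_tukey_result")
}

#' @export
print.anova_tukey_result <- function(x, ...) {
  cat("Two-way ANOVA (Type II SS):\n")
  print(x$anova, row.names = FALSE)
  cat("Tukey HSD on factor A:\n")
  print(x$tukey, row.names = FALSE)
  invisible(x)
}
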