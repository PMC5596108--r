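# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (loops, direct formula transcription) so they cannot
# share a defect with the vectorized implementations they check.

shannon_oracle <- function(x, base = exp(1)) {
  tot <- sum(x)
  h <- 0
  for (xi in x) {
    if (xi > 0) {
      p <- xi / tot
      h <- h - p * log(p, base = base)
    }
  }
  h
}

chao1_oracle <- function(x) {
  s <- 0; f1 <- 0; f2 <- 0
  for (xi in x) {
    if (xi > 0) s <- s + 1
    if (xi == 1) f1 <- f1 + 1
    if (xi == 2) f2 <- f2 + 1
  }
  s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

bray_oracle <- function(x, y) {
  smin <- 0; stot <- 0
  for (i in seq_along(x)) {
    smin <- smin + min(x[i], y[i])
    stot <- stot + x[i] + y[i]
  }
  unname(1 - 2 * smin / stot)
}

ols_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r2 = r2)
}

# direct transcription of the pseudo-F partition for a given grouping
permanova_F_oracle <- function(dmat, groups) {
  N <- nrow(dmat)
  a <- length(unique(groups))
  sst <- 0
  for (i in seq_len(N - 1)) for (j in seq(i + 1, N)) sst <- sst + dmat[i, j]^2
  sst <- sst / N
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    s <- 0
    if (length(idx) > 1) {
      for (ii in seq_len(length(idx) - 1)) for (jj in seq(ii + 1, length(idx))) {
        s <- s + dmat[idx[ii], idx[jj]]^2
      }
    }
    ssw <- ssw + s / length(idx)
  }
  ssb <- sst - ssw
  (ssb / (a - 1)) / (ssw / (N - a))
}

presence_oracle <- function(counts, sample_stratum, strata, min_count, min_samples) {
  out <- matrix(FALSE, nrow(counts), length(strata),
                dimnames = list(rownames(counts), strata))
  for (o in rownames(counts)) {
    for (z in strata) {
      n_det <- 0
      for (s in colnames(counts)) {
        if (sample_stratum[[s]] == z && counts[o, s] >= min_count) n_det <- n_det + 1
      }
      out[o, z] <- n_det >= min_samples
    }
  }
  out
}

venn_oracle <- function(hab_sets) {
  # hab_sets: list per OTU of habitat character vectors
  reg <- c(water_only = 0, sediment_only = 0, nodule_only = 0,
           water_sediment = 0, water_nodule = 0, sediment_nodule = 0,
           all_three = 0)
  for (hs in hab_sets) {
    key <- paste(sort(hs), collapse = "+")
    nm <- switch(key,
                 "water" = "water_only", "sediment" = "sediment_only",
                 "nodule" = "nodule_only",
                 "sediment+water" = "water_sediment",
                 "nodule+water" = "water_nodule",
                 "nodule+sediment" = "sediment_nodule",
                 "nodule+sediment+water" = "all_three",
                 NA_character_)
    if (!is.na(nm)) reg[nm] <- reg[nm] + 1
  }
  reg
}

# small random count table with ids, used across oracle tests
random_count_table <- function(n_otu, n_sample, lambda = 5, seed = NULL,
                               taxonomy = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rpois(n_otu * n_sample, lambda), n_otu, n_sample,
              dimnames = list(sprintf("OTU_%d", seq_len(n_otu)),
                              sprintf("s%d", seq_len(n_sample))))
  count_table(m, taxonomy)
}

# three-habitat mini scheme used where the full ten-stratum default is
# unnecessarily heavy
mini_scheme <- function() {
  stratum_scheme(label = c("epipelagic", "sed_0_5cm", "nodule"),
                 habitat = c("water", "sediment", "nodule"),
                 lower = c(0, 0, NA), upper = c(200, 5, NA))
}

as_distance_matrix_test <- function(m) nodulecomm:::as_distance_matrix(m)

as_dist_sub <- function(d, ord) {
  nodulecomm:::as_distance_matrix(unclass(d)[ord, ord])
}

mini_frame <- function(n_per = 2) {
  sc <- mini_scheme()
  ids <- as.vector(outer(seq_len(n_per), sc$label,
                         function(r, z) sprintf("%s.r%d", z, r)))
  strat <- rep(sc$label, each = n_per)
  hab <- structure(sc$habitat, names = sc$label)[strat]
  sample_frame(ids, unname(hab), strat, area = "UK1-A", scheme = sc)
}
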