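#' Shannon diversity index
#'
#' `H = -sum(p_i log p_i)` over taxa with positive counts, with
#' `p_i = count_i / total`. Natural log (nats) by default; the printed
#' indices of surveys at this OTU richness are consistent with nats, and a
#' `base` argument covers the alternatives.
#'
#' @param counts Non-negative numeric vector with positive sum.
#' @param base Logarithm base (default `exp(1)`).
#' @return Shannon index (scalar).
#' @examples
#' shannon(c(1, 1))        # log(2)
#' shannon(c(5, 0, 0))     # 0
#' @export
shannon <- function(counts, base = exp(1)) {
  if (anyNA(counts) || any(counts < 0)) stopf("counts must be non-negative")
  tot <- sum(counts)
  if (tot <= 0) stopf("cannot compute Shannon index of an all-zero vector")
  p <- counts[counts > 0] / tot
  -sum(p * log(p)) / log(base)
}

#' Chao-1 richness estimator
#'
#' Bias-corrected form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, where `F1` and
#' `F2` are the singleton and doubleton counts; finite even when no
#' doubletons exist. `bias_corrected = FALSE` gives the classical
#' `S_obs + F1^2 / (2 F2)` (falling back to the corrected form when
#' `F2 = 0`, where the classical estimator is undefined).
#'
#' @param counts Non-negative integer vector.
#' @param bias_corrected Use the bias-corrected form (default `TRUE`).
#' @return Estimated richness (scalar, >= observed richness).
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  if (anyNA(counts) || any(counts < 0)) stopf("counts must be non-negative")
  if (any(counts != round(counts))) {
    stopf("Chao-1 needs integer counts (singletons/doubletons)")
  }
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected || f2 == 0) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    s_obs + f1^2 / (2 * f2)
  }
}

#' Per-sample alpha diversity on a rarefied table, with group summaries
#'
#' Rarefies the (already filtered) table once at `depth` with `seed`, then
#' computes observed OTU richness, Shannon and Chao-1 per sample, and
#' aggregates means and standard errors by (habitat, stratum, area) group.
#' Samples below the rarefaction depth are dropped and reported; groups left
#' with no surviving samples are reported with `n = 0` rather than silently
#' omitted.
#'
#' @param table A filtered [count_table()].
#' @param frame A [sample_frame()] covering the table's samples.
#' @param depth Rarefaction depth (reads per sample).
#' @param seed Integer seed for the rarefaction draw.
#' @param base Shannon log base.
#' @return An `alpha_result` list: `samples` (per-sample data frame),
#'   `groups` (per-group means/SEs), `dropped` (sample ids below depth),
#'   `depth`, `seed`.
#' @export
alpha_summary <- function(table, frame, depth, seed, base = exp(1)) {
  stopifnot(inherits(table, "count_table"))
  validate_frame(frame, table = table)
  rt <- rarefy(table, depth, seed)
  dropped <- attr(rt, "rarefaction")$dropped_samples
  ids <- colnames(rt$counts)
  meta <- frame[match(ids, frame$sample_id), , drop = FALSE]
  samples <- if (length(ids) == 0) {
    data.frame(sample_id = character(0), habitat = character(0),
               stratum = character(0), area = character(0),
               observed_otus = numeric(0), shannon = numeric(0),
               chao1 = numeric(0), stringsAsFactors = FALSE)
  } else data.frame(
    sample_id = ids,
    habitat = meta$habitat,
    stratum = meta$stratum,
    area = meta$area,
    observed_otus = apply(rt$counts, 2, function(x) sum(x > 0)),
    shannon = apply(rt$counts, 2, shannon, base = base),
    chao1 = apply(rt$counts, 2, chao1),
    row.names = NULL, stringsAsFactors = FALSE
  )
  # groups come from the full frame (non-control), so emptied groups show up
  meta_all <- frame[frame$habitat != "control" &
                      frame$sample_id %in% colnames(table$counts), , drop = FALSE]
  key_all <- unique(meta_all[, c("habitat", "stratum", "area")])
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  groups <- do.call(rbind, lapply(seq_len(nrow(key_all)), function(i) {
    k <- key_all[i, ]
    sub <- samples[samples$habitat == k$habitat & samples$stratum == k$stratum &
                     samples$area == k$area, , drop = FALSE]
    data.frame(habitat = k$habitat, stratum = k$stratum, area = k$area,
               n = nrow(sub),
               mean_observed = if (nrow(sub)) mean(sub$observed_otus) else NA_real_,
               se_observed = if (nrow(sub)) se(sub$observed_otus) else NA_real_,
               mean_shannon = if (nrow(sub)) mean(sub$shannon) else NA_real_,
               se_shannon = if (nrow(sub)) se(sub$shannon) else NA_real_,
               mean_chao1 = if (nrow(sub)) mean(sub$chao1) else NA_real_,
               se_chao1 = if (nrow(sub)) se(sub$chao1) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  structure(list(samples = samples, groups = groups, dropped = dropped,
                 depth = depth, seed = seed),
            class = "alpha_result")
}

#' @export
print.alpha_result <- function(x, ...) {
  cat(sprintf("alpha_result: %d samples at depth %d (%d dropped), %d groups\n",
              nrow(x$samples), x$depth, length(x$dropped), nrow(x$groups)))
  invisible(x)
}
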