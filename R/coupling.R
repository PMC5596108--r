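# mean relative abundance of every OTU in every stratum (mean over the
# stratum's samples, matching the per-sample normalization applied first)
stratum_mean_abund <- function(rel, frame, scheme) {
  rel <- as_rel_abund(rel)
  validate_scheme(scheme)
  validate_frame(frame, scheme = scheme)
  ids <- intersect(colnames(rel$values), noncontrol_samples(frame))
  strat <- stratum_of(frame)[ids]
  out <- matrix(NA_real_, nrow = nrow(rel$values), ncol = nrow(scheme),
                dimnames = list(rownames(rel$values), scheme$label))
  for (z in scheme$label) {
    cols <- ids[strat == z]
    if (length(cols)) out[, z] <- rowMeans(rel$values[, cols, drop = FALSE])
  }
  out
}

#' Cross-stratum abundance coupling by log-log regression
#'
#' For each requested stratum pair `"A:B"`, regresses
#' `log10(mean relative abundance in B)` on `log10(mean relative abundance
#' in A)` by ordinary least squares over the OTUs detected (mean abundance
#' > 0) in both strata -- so no pseudocount is needed. Reports slope,
#' intercept, R-squared and the two-sided p-value on the slope. Pairs with
#' fewer than `min_shared` jointly detected OTUs are flagged not estimable.
#'
#' @param rel A `rel_abund_table` (or [count_table()], normalized
#'   internally).
#' @param frame A [sample_frame()].
#' @param scheme A [stratum_scheme()].
#' @param pairs Character vector of `"source:destination"` stratum labels,
#'   e.g. `c("epipelagic:nodule", "epipelagic:sed_0_5cm")`.
#' @param min_shared Minimum jointly detected OTUs (default 3).
#' @return A `coupling_result` list: `pairs` (one row per pair: `n_shared`,
#'   `slope`, `intercept`, `r2`, `p`, `estimable`) and `otu_means` (OTU x
#'   stratum mean relative abundances).
#' @export
habitat_abundance_regression <- function(rel, frame, scheme, pairs,
                                         min_shared = 3) {
  mu <- stratum_mean_abund(rel, frame, scheme)
  parse_pair <- function(p) {
    ab <- strsplit(p, ":", fixed = TRUE)[[1]]
    if (length(ab) != 2) stopf("pair must be 'stratumA:stratumB' (got '%s')", p)
    miss <- setdiff(ab, colnames(mu))
    if (length(miss)) stopf("unknown stratum in pair '%s': %s", p,
                            paste(miss, collapse = ", "))
    if (any(is.na(mu[, ab[1]])) || any(is.na(mu[, ab[2]]))) {
      stopf("stratum without samples in pair '%s'", p)
    }
    ab
  }
  res <- do.call(rbind, lapply(pairs, function(p) {
    ab <- parse_pair(p)
    x <- mu[, ab[1]]; y <- mu[, ab[2]]
    joint <- x > 0 & y > 0
    n <- sum(joint)
    if (n < min_shared) {
      return(data.frame(pair = p, n_shared = n, slope = NA_real_,
                        intercept = NA_real_, r2 = NA_real_, p = NA_real_,
                        estimable = FALSE, stringsAsFactors = FALSE))
    }
    lx <- log10(x[joint]); ly <- log10(y[joint])
    fit <- stats::lm(ly ~ lx)
    sm <- suppressWarnings(summary(fit))  # perfect fits warn harmlessly
    pval <- if (nrow(sm$coefficients) < 2 || sm$sigma == 0) NA_real_
            else sm$coefficients["lx", "Pr(>|t|)"]
    data.frame(pair = p, n_shared = n,
               slope = unname(stats::coef(fit)[["lx"]]),
               intercept = unname(stats::coef(fit)[["(Intercept)"]]),
               r2 = sm$r.squared, p = pval,
               estimable = TRUE, stringsAsFactors = FALSE)
  }))
  structure(list(pairs = res, otu_means = mu), class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Habitat/stratum share of a taxon group's sequences
#'
#' Pools the sequence counts of all OTUs whose lineage matches
#' `lineage_pattern` (case-insensitive substring) and reports what fraction
#' of the group's total falls in each stratum and each habitat; both
#' breakdowns sum to one over the full partition.
#'
#' @param table A [count_table()] (filtered; counts, not fractions, so the
#'   shares are sequence shares).
#' @param frame A [sample_frame()].
#' @param lineage_pattern Case-insensitive substring, e.g.
#'   `"Cyanobacteria"`.
#' @param habitats Habitats to report in `by_habitat` (fractions are always
#'   computed over the full partition).
#' @return A `taxon_fractions` list: `by_habitat`, `by_stratum` (named
#'   fraction vectors), `n_otus`, `n_sequences`.
#' @export
taxon_habitat_fractions <- function(table, frame, lineage_pattern,
                                    habitats = c("water", "sediment", "nodule")) {
  stopifnot(inherits(table, "count_table"))
  validate_frame(frame, table = table)
  hit <- lineage_matches(table$taxonomy, lineage_pattern)
  if (!any(hit)) stopf("lineage pattern '%s' matches no OTU", lineage_pattern)
  ids <- intersect(colnames(table$counts), noncontrol_samples(frame))
  cnt <- table$counts[hit, ids, drop = FALSE]
  per_sample <- colSums(cnt)
  total <- sum(per_sample)
  if (total == 0) stopf("matched OTUs have zero reads outside controls")
  hab <- habitat_of(frame)[ids]
  strat <- stratum_of(frame)[ids]
  by_habitat <- tapply(per_sample, hab, sum) / total
  by_stratum <- tapply(per_sample, strat, sum) / total
  structure(list(
    by_habitat = by_habitat[intersect(habitats, names(by_habitat))],
    by_habitat_full = by_habitat,
    by_stratum = by_stratum,
    n_otus = sum(hit), n_sequences = total,
    pattern = lineage_pattern
  ), class = "taxon_fractions")
}

#' @export
print.taxon_fractions <- function(x, ...) {
  cat(sprintf("taxon group '%s': %d OTUs, %s sequences\n", x$pattern,
              x$n_otus, format(x$n_sequences, big.mark = ",")))
  print(round(x$by_habitat_full, 4))
  invisible(x)
}

#' Distribution of abundant source-stratum OTUs across all strata
#'
#' Selects OTUs whose mean relative abundance in `source_stratum` exceeds
#' `threshold` (default 1%, the conventional "abundant" cut) and tabulates
#' their mean relative abundance and detection in every other stratum --
#' the table behind alluvial "flow" plots of abundant photic-zone OTUs into
#' benthic habitats.
#'
#' @param rel A `rel_abund_table` (or [count_table()]).
#' @param frame A [sample_frame()].
#' @param scheme A [stratum_scheme()].
#' @param source_stratum Stratum label to select abundant OTUs from.
#' @param threshold Mean relative-abundance cut (strict `>`; default 0.01).
#' @return A `flow_table` data frame: `otu_id`, `destination`,
#'   `mean_rel_abund`, `detected`; attributes `source_stratum`, `threshold`,
#'   `source_abundance`.
#' @export
abundant_flow <- function(rel, frame, scheme, source_stratum,
                          threshold = 0.01) {
  mu <- stratum_mean_abund(rel, frame, scheme)
  if (!source_stratum %in% colnames(mu)) {
    stopf("unknown source stratum '%s'", source_stratum)
  }
  if (any(is.na(mu[, source_stratum]))) {
    stopf("source stratum '%s' has no samples", source_stratum)
  }
  sel <- mu[, source_stratum] > threshold
  dest <- setdiff(colnames(mu), source_stratum)
  otus <- rownames(mu)[sel]
  out <- expand.grid(otu_id = otus, destination = dest,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$mean_rel_abund <- mu[cbind(out$otu_id, out$destination)]
  out$detected <- !is.na(out$mean_rel_abund) & out$mean_rel_abund > 0
  structure(out, source_stratum = source_stratum, threshold = threshold,
            source_abundance = mu[sel, source_stratum],
            class = c("flow_table", "data.frame"))
}

# average ranks per row, then center/scale so that tcrossprod gives
# Spearman's rho; rows with zero variance come back as NA
rank_scale_rows <- function(m) {
  r <- t(apply(m, 1, rank))
  mu <- rowMeans(r)
  r <- r - mu
  ss <- sqrt(rowSums(r^2))
  bad <- ss <= 1e-12
  r <- r / ifelse(bad, NA_real_, ss)
  list(scaled = r, constant = bad)
}

#' Cross-domain co-occurrence network with permutation p and FDR control
#'
#' Computes Spearman's rho between every (table A OTU, table B OTU) pair
#' over their shared samples (typically 16S vs 18S tables). Significance
#' comes from sample-label permutations of table B -- one shared set of
#' `n_permutations` permutations applied to every pair, which is the
#' exchangeable null for each pair -- with the add-one convention
#' `p = (#{|rho_perm| >= |rho_obs|} + 1) / (n_permutations + 1)`.
#' Benjamini-Hochberg q-values are computed over all tested pairs; retained
#' edges satisfy `q <= fdr_alpha` and `|rho| >= min_abs_rho`.
#'
#' OTUs detected in fewer than `min_prevalence` of the shared samples are
#' excluded before testing (double-zero pairs are a notorious source of
#' spurious correlation in compositional data), as are constant-rank OTUs
#' (rho undefined).
#'
#' @param table_a,table_b `rel_abund_table`s (or [count_table()]s) sharing
#'   at least 8 sample ids.
#' @param method Correlation method; only `"spearman"` is implemented.
#' @param n_permutations Permutations for the null (default 999).
#' @param fdr_alpha BH false-discovery-rate cut (default 0.05).
#' @param min_prevalence Minimum detection fraction across shared samples
#'   (default 0.2).
#' @param min_abs_rho Minimum absolute correlation for a retained edge.
#' @param seed Integer seed for the permutations.
#' @return An `edge_list`: data frame of retained edges (`otu_a`, `otu_b`,
#'   `rho`, `p`, `q`, `sign`) with attributes `params`, `n_tested`,
#'   `skipped` (constant OTUs), `shared_samples`, and `all_pairs` (the full
#'   tested table, for diagnostics).
#' @export
cooccurrence_network <- function(table_a, table_b, method = "spearman",
                                 n_permutations = 999, fdr_alpha = 0.05,
                                 min_prevalence = 0.2, min_abs_rho = 0,
                                 seed = NULL) {
  method <- match.arg(method, "spearman")
  a <- as_rel_abund(table_a); b <- as_rel_abund(table_b)
  shared <- intersect(colnames(a$values), colnames(b$values))
  if (length(shared) < 8) {
    stopf("tables share only %d samples (need >= 8)", length(shared))
  }
  n <- length(shared)
  va <- a$values[, shared, drop = FALSE]
  vb <- b$values[, shared, drop = FALSE]
  prev_ok <- function(m) rowMeans(m > 0) >= min_prevalence
  va <- va[prev_ok(va), , drop = FALSE]
  vb <- vb[prev_ok(vb), , drop = FALSE]
  if (!nrow(va) || !nrow(vb)) stopf("no OTU passes the prevalence filter")
  ra <- rank_scale_rows(va)
  rb <- rank_scale_rows(vb)
  skipped <- c(rownames(va)[ra$constant], rownames(vb)[rb$constant])
  A <- ra$scaled[!ra$constant, , drop = FALSE]
  B <- rb$scaled[!rb$constant, , drop = FALSE]
  if (!nrow(A) || !nrow(B)) stopf("no non-constant OTU left to correlate")
  rho <- tcrossprod(A, B)
  rho[rho > 1] <- 1; rho[rho < -1] <- -1
  abs_obs <- abs(rho) - 1e-12
  exceed <- matrix(0L, nrow(rho), ncol(rho))
  with_seed(seed, {
    for (i in seq_len(n_permutations)) {
      perm <- sample.int(n)
      rp <- tcrossprod(A, B[, perm, drop = FALSE])
      exceed <- exceed + (abs(rp) >= abs_obs)
    }
  })
  p <- (exceed + 1) / (n_permutations + 1)
  q <- matrix(stats::p.adjust(p, method = "BH"), nrow(p), ncol(p))
  keep <- q <= fdr_alpha & abs(rho) >= min_abs_rho
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(
    otu_a = rownames(A)[idx[, 1]],
    otu_b = rownames(B)[idx[, 2]],
    rho = rho[idx],
    p = p[idx],
    q = q[idx],
    sign = ifelse(rho[idx] >= 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$q, edges$p, -abs(edges$rho)), , drop = FALSE]
  rownames(edges) <- NULL
  all_pairs <- data.frame(
    otu_a = rownames(A)[row(rho)], otu_b = rownames(B)[col(rho)],
    rho = as.vector(rho), p = as.vector(p), q = as.vector(q),
    stringsAsFactors = FALSE
  )
  structure(edges,
            params = list(method = method, n_permutations = n_permutations,
                          fdr_alpha = fdr_alpha, min_prevalence = min_prevalence,
                          min_abs_rho = min_abs_rho, seed = seed),
            n_tested = length(rho), skipped = skipped,
            shared_samples = shared, all_pairs = all_pairs,
            class = c("edge_list", "data.frame"))
}

#' Write a co-occurrence edge list as TSV or GraphML
#'
#' @param edges An `edge_list` from [cooccurrence_network()].
#' @param path Output path.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(as.data.frame(edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(edges, path) {
  stopifnot(inherits(edges, "edge_list"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  nodes <- unique(c(edges$otu_a, edges$otu_b))
  head_xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="rho" for="edge" attr.name="rho" attr.type="double"/>',
    '  <key id="q" for="edge" attr.name="q" attr.type="double"/>',
    '  <key id="sign" for="edge" attr.name="sign" attr.type="string"/>',
    '  <graph id="cooccurrence" edgedefault="undirected">'
  )
  node_xml <- sprintf('    <node id="%s"/>', esc(nodes))
  edge_xml <- if (nrow(edges)) sprintf(
    '    <edge source="%s" target="%s"><data key="rho">%.6g</data><data key="q">%.6g</data><data key="sign">%s</data></edge>',
    esc(edges$otu_a), esc(edges$otu_b), edges$rho, edges$q, edges$sign
  ) else character(0)
  writeLines(c(head_xml, node_xml, edge_xml, "  </graph>", "</graphml>"), path)
  invisible(path)
}
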