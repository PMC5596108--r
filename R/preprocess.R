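#' Filter an OTU table by lineage patterns and blank-control hits
#'
#' Applies the two standard amplicon cleanup rules for this survey design,
#' in a fixed order. First, every OTU whose taxonomy lineage matches any of
#' `exclude_lineage_patterns` (case-insensitive substring) is removed --
#' by default chloroplast/plastid and archaeal lineages, which the
#' bacteria-targeted primers amplify as off-target decoys. Second, every OTU
#' with at least one read in any `habitat == "control"` (extraction blank)
#' sample is removed outright, wherever it occurs: a contaminant seen in the
#' blank is not trusted anywhere. Control samples are dropped from the
#' output.
#'
#' `blank_mode = "subtract_counts"` is an alternative sensitivity mode that
#' subtracts each OTU's total blank count from every sample (flooring at
#' zero) instead of removing the row.
#'
#' @param table A [count_table()].
#' @param frame A [sample_frame()] covering every table sample (may be
#'   `NULL` when only lineage filtering is wanted).
#' @param exclude_lineage_patterns Character vector of case-insensitive
#'   substrings; `character(0)` disables lineage filtering.
#' @param blank_mode `"remove_otu"` (default) or `"subtract_counts"`.
#' @return A filtered [count_table()] with a `filter_report` attribute
#'   listing removed OTUs and dropped control samples.
#' @export
filter_table <- function(table, frame = NULL,
                         exclude_lineage_patterns = c("Chloroplast", "Archaea"),
                         blank_mode = c("remove_otu", "subtract_counts")) {
  stopifnot(inherits(table, "count_table"))
  blank_mode <- match.arg(blank_mode)
  if (!is.null(frame)) validate_frame(frame, table = table)

  lineage_removed <- character(0)
  if (length(exclude_lineage_patterns)) {
    hit <- lineage_matches(table$taxonomy, exclude_lineage_patterns)
    lineage_removed <- rownames(table$counts)[hit]
  }
  keep <- setdiff(rownames(table$counts), lineage_removed)
  cnt <- table$counts[keep, , drop = FALSE]

  blank_removed <- character(0)
  control_samples <- character(0)
  if (!is.null(frame)) {
    control_samples <- intersect(colnames(cnt),
                                 frame$sample_id[frame$habitat == "control"])
    if (length(control_samples)) {
      blank_cnt <- cnt[, control_samples, drop = FALSE]
      in_blank <- rowSums(blank_cnt) > 0
      if (blank_mode == "remove_otu") {
        blank_removed <- rownames(cnt)[in_blank]
        cnt <- cnt[!in_blank, , drop = FALSE]
      } else {
        cnt <- pmax(cnt - rowSums(blank_cnt), 0)
      }
      cnt <- cnt[, setdiff(colnames(cnt), control_samples), drop = FALSE]
    }
  }

  out <- count_table(cnt, table$taxonomy[rownames(cnt)])
  attr(out, "filter_report") <- list(
    lineage_removed = lineage_removed,
    blank_removed = blank_removed,
    control_samples_dropped = control_samples,
    blank_mode = blank_mode,
    patterns = exclude_lineage_patterns
  )
  out
}

#' Normalize counts to relative abundances
#'
#' Divides each OTU's count by its sample's total, so every sample column
#' sums to one. Empty samples are an error: drop them (or rarefy first)
#' before normalizing.
#'
#' @param table A [count_table()].
#' @return A `rel_abund_table` with a `values` fraction matrix and the
#'   taxonomy carried over.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "count_table"))
  tot <- colSums(table$counts)
  if (any(tot <= 0)) {
    stopf("sample(s) with zero total reads: %s",
          paste(utils::head(colnames(table$counts)[tot <= 0], 5), collapse = ", "))
  }
  structure(list(values = sweep(table$counts, 2, tot, "/"),
                 taxonomy = table$taxonomy),
            class = "rel_abund_table")
}

#' @export
print.rel_abund_table <- function(x, ...) {
  cat(sprintf("rel_abund_table: %d OTUs x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# accept either relative-abundance or count input where fractions are needed
as_rel_abund <- function(x) {
  if (inherits(x, "rel_abund_table")) return(x)
  if (inherits(x, "count_table")) return(to_relative(x))
  stopf("expected a rel_abund_table or count_table")
}

#' Rarefy (subsample) each sample to a fixed depth
#'
#' Draws exactly `depth` reads per sample without replacement (multivariate
#' hypergeometric), one draw per sample. Samples whose total falls below
#' `depth` are dropped and listed in the `rarefaction` attribute -- they are
#' never padded. The seed is mandatory so the draw is reproducible and can
#' be logged.
#'
#' @param table A [count_table()].
#' @param depth Target reads per sample (>= 1).
#' @param seed Integer seed.
#' @return A [count_table()] whose retained columns each sum to `depth`,
#'   with attribute `rarefaction = list(depth, seed, dropped_samples)`.
#' @export
rarefy <- function(table, depth, seed) {
  stopifnot(inherits(table, "count_table"))
  if (!is_count_scalar(depth, min = 1)) stopf("`depth` must be a positive integer")
  totals <- colSums(table$counts)
  keep <- names(totals)[totals >= depth]
  dropped <- setdiff(colnames(table$counts), keep)
  sub <- matrix(0, nrow = nrow(table$counts), ncol = length(keep),
                dimnames = list(rownames(table$counts), keep))
  with_seed(seed, {
    for (s in keep) {
      x <- table$counts[, s]
      if (totals[s] == depth) {
        sub[, s] <- x
      } else {
        pool <- rep.int(seq_along(x), x)
        draw <- sample(pool, depth, replace = FALSE)
        sub[, s] <- tabulate(draw, nbins = length(x))
      }
    }
  })
  out <- count_table(sub, table$taxonomy)
  attr(out, "rarefaction") <- list(depth = depth, seed = seed,
                                   dropped_samples = dropped)
  out
}
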