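#' Construct an OTU count table
#'
#' The central container: a non-negative integer matrix of read counts with
#' OTUs as rows and samples as columns, plus an optional semicolon-ranked
#' taxonomy lineage per OTU (SILVA-style, e.g.
#' `"d__Bacteria;p__Cyanobacteria;...;g__Prochlorococcus"`).
#'
#' @param counts Integer matrix (OTU x sample) with unique row and column
#'   names.
#' @param taxonomy Named character vector of lineage strings keyed by OTU id,
#'   or `NULL`. Missing OTUs get an empty lineage.
#' @return A `count_table` object.
#' @export
count_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    stopf("`counts` needs OTU row names and sample column names")
  }
  storage.mode(counts) <- "double"
  validate_ids(rownames(counts) %||% character(0), "OTU")
  validate_ids(colnames(counts) %||% character(0), "sample")
  if (anyNA(counts) || any(counts < 0)) {
    stopf("counts must be non-negative and non-missing")
  }
  if (any(counts != round(counts))) {
    stopf("counts must be integers (found non-integer values)")
  }
  tax <- rep("", nrow(counts))
  names(tax) <- rownames(counts)
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[!is.na(taxonomy)]
    unknown <- setdiff(names(taxonomy), rownames(counts))
    if (length(unknown)) {
      stopf("taxonomy given for unknown OTU id(s): %s",
            paste(utils::head(unknown, 3), collapse = ", "))
    }
    tax[names(taxonomy)] <- unname(taxonomy)
  }
  structure(list(counts = counts, taxonomy = tax), class = "count_table")
}

validate_ids <- function(ids, what) {
  if (anyNA(ids) || any(ids == "")) stopf("%s ids must be non-empty", what)
  if (anyDuplicated(ids)) {
    stopf("duplicate %s id(s): %s", what,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  invisible(ids)
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d OTUs x %d samples, %s total reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  n_tax <- sum(nzchar(x$taxonomy))
  cat(sprintf("  taxonomy for %d/%d OTUs\n", n_tax, nrow(x$counts)))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

otu_ids <- function(x) rownames(x$counts %||% x$values)
sample_ids <- function(x) colnames(x$counts %||% x$values)

#' Subset a count table by OTU and/or sample ids
#'
#' @param x A `count_table`.
#' @param otus,samples Character vectors of ids to keep (default all).
#' @return A `count_table`.
#' @export
subset_table <- function(x, otus = NULL, samples = NULL) {
  stopifnot(inherits(x, "count_table"))
  otus <- otus %||% rownames(x$counts)
  samples <- samples %||% colnames(x$counts)
  missing_o <- setdiff(otus, rownames(x$counts))
  missing_s <- setdiff(samples, colnames(x$counts))
  if (length(missing_o)) stopf("unknown OTU id(s): %s", paste(utils::head(missing_o, 3), collapse = ", "))
  if (length(missing_s)) stopf("unknown sample id(s): %s", paste(utils::head(missing_s, 3), collapse = ", "))
  count_table(x$counts[otus, samples, drop = FALSE], x$taxonomy[otus])
}

#' Read an OTU count table from TSV
#'
#' Two dialects are supported. `"wide-tsv"`: a header row of sample ids with
#' the first column holding OTU ids and an optional trailing `taxonomy`
#' column. `"biom-tsv"`: the classic BIOM text export, where comment lines
#' precede a header line starting with `#OTU ID`.
#'
#' @param path Path to the TSV file.
#' @param dialect `"wide-tsv"` (default) or `"biom-tsv"`.
#' @return A [count_table()].
#' @export
read_count_table <- function(path, dialect = c("wide-tsv", "biom-tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  if (dialect == "biom-tsv") {
    hdr <- grep("^#OTU ID", lines)
    if (!length(hdr)) stopf("biom-tsv file lacks a '#OTU ID' header line: %s", path)
    lines <- lines[hdr[1]:length(lines)]
    lines[1] <- sub("^#OTU ID", "otu_id", lines[1])
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  len <- length(fields[[1]])
  # strsplit drops a trailing empty field (an empty taxonomy cell)
  fields <- lapply(fields, function(f) if (length(f) == len - 1L) c(f, "") else f)
  nf <- lengths(fields)
  if (any(nf != len)) {
    stopf("ragged TSV: rows have %s fields", paste(sort(unique(nf)), collapse = "/"))
  }
  header <- fields[[1]]
  validate_ids(header[-1], "sample/column")
  has_tax <- tolower(header[length(header)]) %in% c("taxonomy", "lineage")
  samp_idx <- if (has_tax) 2:(length(header) - 1L) else seq_along(header)[-1]
  if (!length(samp_idx)) stopf("no sample columns in %s", path)
  body <- fields[-1]
  otus <- vapply(body, `[[`, "", 1L)
  validate_ids(otus, "OTU")
  cnt <- matrix(NA_real_, nrow = length(body), ncol = length(samp_idx),
                dimnames = list(otus, header[samp_idx]))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][samp_idx]))
    if (anyNA(v)) stopf("non-numeric count in row for OTU %s", otus[i])
    cnt[i, ] <- v
  }
  tax <- NULL
  if (has_tax) {
    tax <- vapply(body, function(f) f[[length(header)]], "")
    names(tax) <- otus
  }
  count_table(cnt, tax)
}

#' Write an OTU count table as TSV
#'
#' @param x A [count_table()].
#' @param path Output path.
#' @param dialect `"wide-tsv"` or `"biom-tsv"`.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path, dialect = c("wide-tsv", "biom-tsv")) {
  stopifnot(inherits(x, "count_table"))
  dialect <- match.arg(dialect)
  first <- if (dialect == "biom-tsv") "#OTU ID" else "otu_id"
  header <- paste(c(first, colnames(x$counts), "taxonomy"), collapse = "\t")
  rows <- vapply(seq_len(nrow(x$counts)), function(i) {
    paste(c(rownames(x$counts)[i],
            format(x$counts[i, ], scientific = FALSE, trim = TRUE),
            x$taxonomy[i]),
          collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Build and validate a sample metadata frame
#'
#' Maps each sample to its habitat (`water`, `sediment`, `nodule` or
#' `control`), stratum, study area and depth. Control (blank) samples carry
#' habitat `"control"` and are exempt from the stratum check.
#'
#' @param sample_id,habitat,stratum,area Character vectors of equal length.
#' @param depth_m Numeric depth (m) or `NA`.
#' @param scheme Optional [stratum_scheme()] used to check strata.
#' @return A `sample_frame` data frame.
#' @export
sample_frame <- function(sample_id, habitat, stratum, area,
                         depth_m = NA_real_, scheme = NULL) {
  validate_ids(sample_id, "sample")
  bad <- setdiff(unique(habitat), c("water", "sediment", "nodule", "control"))
  if (length(bad)) stopf("unknown habitat(s): %s", paste(bad, collapse = ", "))
  out <- data.frame(sample_id = as.character(sample_id),
                    habitat = as.character(habitat),
                    stratum = as.character(stratum),
                    area = as.character(area),
                    depth_m = rep_len(as.numeric(depth_m), length(sample_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_frame", "data.frame")
  if (!is.null(scheme)) validate_frame(out, scheme = scheme)
  out
}

validate_frame <- function(frame, table = NULL, scheme = NULL) {
  if (!is.data.frame(frame)) stopf("`frame` must be a sample_frame data frame")
  need <- c("sample_id", "habitat", "stratum", "area")
  miss <- setdiff(need, names(frame))
  if (length(miss)) stopf("sample frame lacks column(s): %s", paste(miss, collapse = ", "))
  if (!is.null(scheme)) {
    noncontrol <- frame$habitat != "control"
    bad <- setdiff(unique(frame$stratum[noncontrol]), scheme$label)
    if (length(bad)) {
      stopf("sample strata not in scheme: %s", paste(bad, collapse = ", "))
    }
  }
  if (!is.null(table)) {
    miss <- setdiff(colnames(table$counts), frame$sample_id)
    if (length(miss)) {
      stopf("sample frame missing table sample(s): %s",
            paste(utils::head(miss, 5), collapse = ", "))
    }
  }
  invisible(frame)
}

#' @rdname sample_frame
#' @param path Path to a TSV with columns `sample_id`, `habitat`, `stratum`,
#'   `area` and optionally `depth_m`.
#' @export
read_sample_frame <- function(path, scheme = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "habitat", "stratum", "area")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("%s lacks column(s): %s", path, paste(miss, collapse = ", "))
  sample_frame(df$sample_id, df$habitat, df$stratum, df$area,
               depth_m = if ("depth_m" %in% names(df)) df$depth_m else NA_real_,
               scheme = scheme)
}

#' @rdname sample_frame
#' @param frame A `sample_frame`.
#' @export
write_sample_frame <- function(frame, path) {
  utils::write.table(as.data.frame(frame), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# samples of `frame` that are not blanks/controls
noncontrol_samples <- function(frame) frame$sample_id[frame$habitat != "control"]

# named stratum lookup restricted to samples present in a table
stratum_of <- function(frame) {
  structure(frame$stratum, names = frame$sample_id)
}

habitat_of <- function(frame) {
  structure(frame$habitat, names = frame$sample_id)
}
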