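#' Presence/absence of each OTU per stratum
#'
#' An OTU is "detected" in a stratum when it has at least `min_count` reads
#' in at least `min_samples` samples of that stratum (defaults 1 and 1: a
#' single read anywhere counts, the loosest defensible rule). OTUs detected
#' nowhere are dropped and reported; strata with no samples are reported and
#' kept as all-false columns. Control samples are ignored.
#'
#' @param table A filtered [count_table()].
#' @param frame A [sample_frame()] covering the table's samples.
#' @param scheme A [stratum_scheme()].
#' @param min_count Minimum reads per sample to count as a detection.
#' @param min_samples Minimum detecting samples per stratum.
#' @return A `presence_matrix`: logical OTU x stratum matrix with attributes
#'   `occupancy` (per-OTU fraction of non-control samples with a detection),
#'   `dropped_otus`, `empty_strata`, `min_count`, `min_samples`,
#'   `n_samples`.
#' @export
presence_matrix <- function(table, frame, scheme, min_count = 1,
                            min_samples = 1) {
  stopifnot(inherits(table, "count_table"))
  validate_scheme(scheme)
  validate_frame(frame, table = table, scheme = scheme)
  if (!is_count_scalar(min_count, 1) || !is_count_scalar(min_samples, 1)) {
    stopf("`min_count` and `min_samples` must be positive integers")
  }
  ids <- intersect(colnames(table$counts), noncontrol_samples(frame))
  strat <- stratum_of(frame)[ids]
  det_sample <- table$counts[, ids, drop = FALSE] >= min_count
  pres <- matrix(FALSE, nrow = nrow(table$counts), ncol = nrow(scheme),
                 dimnames = list(rownames(table$counts), scheme$label))
  empty <- character(0)
  for (z in scheme$label) {
    cols <- ids[strat == z]
    if (!length(cols)) { empty <- c(empty, z); next }
    pres[, z] <- rowSums(det_sample[, cols, drop = FALSE]) >= min_samples
  }
  occupancy <- rowSums(det_sample) / max(1L, length(ids))
  dropped <- rownames(pres)[rowSums(pres) == 0]
  keep <- rowSums(pres) > 0
  out <- pres[keep, , drop = FALSE]
  structure(out,
            occupancy = occupancy[keep],
            dropped_otus = dropped,
            empty_strata = empty,
            min_count = min_count, min_samples = min_samples,
            n_samples = length(ids),
            class = c("presence_matrix", "matrix"))
}

habitat_presence <- function(presence, scheme) {
  validate_scheme(scheme)
  habs <- c("water", "sediment", "nodule")
  cols <- lapply(habs, function(h) {
    st <- intersect(scheme$label[scheme$habitat == h], colnames(presence))
    if (!length(st)) return(rep(FALSE, nrow(presence)))
    rowSums(presence[, st, drop = FALSE]) > 0
  })
  matrix(unlist(cols), nrow = nrow(presence),
         dimnames = list(rownames(presence), habs))
}

#' Three-habitat Venn partition of OTU occurrences
#'
#' Collapses stratum-level presence to habitat level (an OTU is in a habitat
#' if detected in any of its strata) and counts OTUs in each of the seven
#' regions of the water/sediment/nodule Venn diagram, plus habitat totals
#' and pairwise shared counts.
#'
#' @param presence A [presence_matrix()].
#' @param scheme The matching [stratum_scheme()].
#' @return A `venn_partition` list: `regions` (7 named counts), `totals`
#'   (per-habitat), `pairwise` (shared counts), `n_otus`.
#' @export
venn_partition <- function(presence, scheme) {
  hp <- habitat_presence(presence, scheme)
  w <- hp[, "water"]; s <- hp[, "sediment"]; n <- hp[, "nodule"]
  regions <- c(
    water_only = sum(w & !s & !n),
    sediment_only = sum(!w & s & !n),
    nodule_only = sum(!w & !s & n),
    water_sediment = sum(w & s & !n),
    water_nodule = sum(w & !s & n),
    sediment_nodule = sum(!w & s & n),
    all_three = sum(w & s & n)
  )
  structure(list(
    regions = regions,
    totals = c(water = sum(w), sediment = sum(s), nodule = sum(n)),
    pairwise = c(water_sediment = sum(w & s), water_nodule = sum(w & n),
                 sediment_nodule = sum(s & n)),
    n_otus = nrow(presence)
  ), class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("Venn partition of %d OTUs over water/sediment/nodule:\n", x$n_otus))
  print(x$regions)
  cat("pairwise shared:\n")
  print(x$pairwise)
  invisible(x)
}

#' Count OTUs detected in every one of a set of strata
#'
#' @param presence A [presence_matrix()].
#' @param strata Character vector of stratum labels.
#' @return Number of OTUs detected in all listed strata.
#' @export
shared_otus <- function(presence, strata) {
  miss <- setdiff(strata, colnames(presence))
  if (length(miss)) stopf("unknown strata: %s", paste(miss, collapse = ", "))
  sum(rowSums(presence[, strata, drop = FALSE]) == length(strata))
}

#' Classify OTUs as specialists, moderate generalists or generalists
#'
#' Habitat-breadth classification from presence/absence patterns:
#' * **specialist** -- detected in exactly one stratum (hence one habitat);
#' * **generalist** -- detected in every stratum of the core set (all strata
#'   under `rule_set = "strict"`; under the default `"operative"` rule, all
#'   water zones, the nodules, and sediment layers above 6 cm -- the strict
#'   rule returns nothing on real surveys of this design because the deep
#'   sediment layers share no OTUs with the water column);
#' * **moderate_generalist** -- detected in at least two habitats and not a
#'   generalist;
#' * **unclassified** -- multi-stratum but single-habitat OTUs, which none
#'   of the three rules covers; they are kept visible rather than forced
#'   into a class.
#'
#' @param presence A [presence_matrix()].
#' @param scheme The matching [stratum_scheme()].
#' @param rule_set `"operative"` (default) or `"strict"`.
#' @param core_set Optional explicit core stratum set overriding `rule_set`.
#' @return A `habitat_classification` data frame: `otu_id`, `label`,
#'   `habitat` and `stratum` (specialists only), `n_strata`, `n_habitats`,
#'   `occupancy`; attributes `rule_set` and `core_set`.
#' @export
classify_otus <- function(presence, scheme,
                          rule_set = c("operative", "strict"),
                          core_set = NULL) {
  if (!nrow(presence)) stopf("empty presence matrix")
  validate_scheme(scheme)
  rule_set <- match.arg(rule_set)
  core <- core_set %||% core_stratum_set(scheme, rule_set)
  miss <- setdiff(core, colnames(presence))
  if (length(miss)) stopf("core set references unknown strata: %s",
                          paste(miss, collapse = ", "))
  hp <- habitat_presence(presence, scheme)
  n_strata <- rowSums(presence)
  n_hab <- rowSums(hp)
  is_gen <- rowSums(presence[, core, drop = FALSE]) == length(core)
  label <- ifelse(n_strata == 1, "specialist",
           ifelse(is_gen, "generalist",
           ifelse(n_hab >= 2, "moderate_generalist", "unclassified")))
  hab_lookup <- structure(scheme$habitat, names = scheme$label)
  spec_stratum <- rep(NA_character_, nrow(presence))
  one <- which(n_strata == 1)
  if (length(one)) {
    spec_stratum[one] <- colnames(presence)[apply(presence[one, , drop = FALSE], 1, which)]
  }
  out <- data.frame(
    otu_id = rownames(presence),
    label = label,
    habitat = ifelse(label == "specialist", unname(hab_lookup[spec_stratum]), NA_character_),
    stratum = ifelse(label == "specialist", spec_stratum, NA_character_),
    n_strata = as.integer(n_strata),
    n_habitats = as.integer(n_hab),
    occupancy = unname(attr(presence, "occupancy")),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(out, rule_set = rule_set, core_set = core,
            class = c("habitat_classification", "data.frame"))
}

#' Sequence-contribution and occupancy summaries per habitat class
#'
#' For each class: the number of OTUs and its share of the total sequence
#' count (totals over non-control samples, restricted to classified OTUs so
#' the shares sum to 100%). Specialists are additionally broken down by
#' their home stratum. The `top_otus` table ranks each class's OTUs by
#' occupancy (ties broken by total count, then id) -- the "widest
#' distribution" ranking.
#'
#' @param classification A [classify_otus()] result.
#' @param table The [count_table()] the classification came from.
#' @param frame The matching [sample_frame()].
#' @param n_top Rows per class in `top_otus` (default 20).
#' @return A `class_summary` list: `per_class`, `specialists_by_stratum`,
#'   `top_otus`.
#' @export
class_summary <- function(classification, table, frame, n_top = 20) {
  stopifnot(inherits(classification, "habitat_classification"),
            inherits(table, "count_table"))
  validate_frame(frame, table = table)
  ids <- intersect(colnames(table$counts), noncontrol_samples(frame))
  cnt <- table$counts[classification$otu_id, ids, drop = FALSE]
  otu_tot <- rowSums(cnt)
  grand <- sum(otu_tot)
  cls <- c("specialist", "moderate_generalist", "generalist", "unclassified")
  per_class <- do.call(rbind, lapply(cls, function(cl) {
    sel <- classification$label == cl
    data.frame(label = cl, n_otus = sum(sel),
               n_sequences = sum(otu_tot[sel]),
               pct_sequences = if (grand > 0) 100 * sum(otu_tot[sel]) / grand else NA_real_,
               stringsAsFactors = FALSE)
  }))
  spec <- classification[classification$label == "specialist", , drop = FALSE]
  specialists_by_stratum <- if (nrow(spec)) {
    agg <- split(seq_len(nrow(spec)), spec$stratum)
    do.call(rbind, lapply(names(agg), function(z) {
      rows <- agg[[z]]
      data.frame(stratum = z,
                 habitat = spec$habitat[rows[1]],
                 n_otus = length(rows),
                 pct_sequences = if (grand > 0)
                   100 * sum(otu_tot[spec$otu_id[rows]]) / grand else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(stratum = character(0), habitat = character(0),
               n_otus = integer(0), pct_sequences = numeric(0))
  }
  top_otus <- do.call(rbind, lapply(cls, function(cl) {
    sub <- classification[classification$label == cl, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    tot <- otu_tot[sub$otu_id]
    ord <- order(-sub$occupancy, -tot, sub$otu_id)
    sub <- sub[utils::head(ord, n_top), , drop = FALSE]
    data.frame(label = cl, otu_id = sub$otu_id, occupancy = sub$occupancy,
               total_count = unname(otu_tot[sub$otu_id]),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_class = per_class,
                 specialists_by_stratum = specialists_by_stratum,
                 top_otus = top_otus),
            class = "class_summary")
}

#' @export
print.class_summary <- function(x, ...) {
  print(x$per_class, row.names = FALSE)
  invisible(x)
}
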