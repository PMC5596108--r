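#' Define an ordered stratum scheme
#'
#' A stratum scheme lists the vertical strata of a nodule-field survey in
#' order: water-column depth zones, sediment layers, and the nodule habitat.
#' Each stratum belongs to exactly one habitat (`water`, `sediment` or
#' `nodule`). Depth bounds are metres below the surface for water strata and
#' centimetres below the seafloor for sediment strata; the nodule stratum has
#' no depth bounds.
#'
#' @param label Character vector of unique stratum labels, in vertical order.
#' @param habitat Character vector, one of `"water"`, `"sediment"`,
#'   `"nodule"` per stratum.
#' @param lower,upper Numeric depth bounds (m for water, cm for sediment);
#'   `NA` allowed (e.g. for nodules).
#' @return A `stratum_scheme` data frame with columns `label`, `habitat`,
#'   `lower`, `upper`.
#' @seealso [default_stratum_scheme()]
#' @export
stratum_scheme <- function(label, habitat, lower = NA_real_, upper = NA_real_) {
  if (anyDuplicated(label)) {
    stopf("stratum labels must be unique (duplicated: %s)",
          paste(unique(label[duplicated(label)]), collapse = ", "))
  }
  bad <- setdiff(unique(habitat), c("water", "sediment", "nodule"))
  if (length(bad)) {
    stopf("unknown habitat(s): %s", paste(bad, collapse = ", "))
  }
  out <- data.frame(label = as.character(label),
                    habitat = as.character(habitat),
                    lower = rep_len(as.numeric(lower), length(label)),
                    upper = rep_len(as.numeric(upper), length(label)),
                    stringsAsFactors = FALSE)
  class(out) <- c("stratum_scheme", "data.frame")
  out
}

#' Default stratum scheme for an abyssal nodule-field survey
#'
#' Four water-column zones (epipelagic 0--200 m, mesopelagic 200--1,000 m,
#' bathypelagic 1,000--3,000 m, abyssopelagic 3,000 m to the seafloor), five
#' sediment layers (0--5, 5--6, 6--8, 8--10 and 15--18 cm) and the nodule
#' habitat. Water-zone boundaries are configurable; the 200 m epipelagic
#' bound is the conventional photic-zone limit.
#'
#' @param epi_max,meso_max,bathy_max Water-zone upper depth bounds in metres.
#' @return A [stratum_scheme()].
#' @export
default_stratum_scheme <- function(epi_max = 200, meso_max = 1000,
                                   bathy_max = 3000) {
  stratum_scheme(
    label = c("epipelagic", "mesopelagic", "bathypelagic", "abyssopelagic",
              "sed_0_5cm", "sed_5_6cm", "sed_6_8cm", "sed_8_10cm",
              "sed_15_18cm", "nodule"),
    habitat = c(rep("water", 4), rep("sediment", 5), "nodule"),
    lower = c(0, epi_max, meso_max, bathy_max, 0, 5, 6, 8, 15, NA),
    upper = c(epi_max, meso_max, bathy_max, NA, 5, 6, 8, 10, 18, NA)
  )
}

validate_scheme <- function(scheme) {
  if (!inherits(scheme, "stratum_scheme")) {
    stopf("`scheme` must be a stratum_scheme (see stratum_scheme())")
  }
  invisible(scheme)
}

water_strata <- function(scheme) scheme$label[scheme$habitat == "water"]
sediment_strata <- function(scheme) scheme$label[scheme$habitat == "sediment"]
nodule_strata <- function(scheme) scheme$label[scheme$habitat == "nodule"]

#' Core stratum set used by the operative generalist rule
#'
#' The strict generalist rule (detected in every stratum) returns no OTUs on
#' real surveys of this design because deep sediment layers share essentially
#' nothing with the water column. The operative rule instead requires
#' detection across all water zones, the nodules, and the sediment layers
#' shallower than 6 cm.
#'
#' @param scheme A [stratum_scheme()].
#' @param rule_set `"operative"` (default) or `"strict"`.
#' @return Character vector of core stratum labels.
#' @export
core_stratum_set <- function(scheme, rule_set = c("operative", "strict")) {
  validate_scheme(scheme)
  rule_set <- match.arg(rule_set)
  if (rule_set == "strict") return(scheme$label)
  shallow_sed <- scheme$habitat == "sediment" &
    !is.na(scheme$upper) & scheme$upper <= 6
  scheme$label[scheme$habitat %in% c("water", "nodule") | shallow_sed]
}
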