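#' Parameters for the synthetic nodule-field community generator
#'
#' Returns a validated parameter list describing the simulated survey. The
#' defaults emulate the post-clustering artifacts of a real abyssal
#' nodule-field 16S survey at desk scale: four study areas sampled over four
#' water-column zones, five sediment layers and nodules (11 replicates per
#' stratum per area gives 440 samples plus one extraction blank, close to
#' the 447-sample survey the design mirrors), with sequencing depth drawn
#' from Normal(9694.7, 892.7) reads per sample -- the survey's reported
#' mean +/- sd.
#'
#' Each OTU gets a lognormal base abundance. Habitat preference is a
#' multiplicative boost (`preference_multiplier`) in an OTU's preferred
#' strata and a leakage factor (`off_habitat_epsilon`) elsewhere. A fraction
#' of epipelagic specialists (`export_fraction`) is additionally seeded onto
#' nodules at `export_scale` times their preferred-stratum abundance --
#' never into sediments -- emulating vertical export of photic-zone cells
#' that end up associated with nodules but are not retrieved from the
#' sediment.
#'
#' @param n_areas Number of study areas (named UK1-A, UK1-B, OMS-A, APEI-6,
#'   then AREA-5, ...).
#' @param strata A [stratum_scheme()].
#' @param samples_per_stratum_per_area Replicates per (area, stratum) cell.
#' @param n_specialist_otus_per_stratum,n_moderate_otus,n_generalist_otus
#'   Planted class sizes.
#' @param n_contaminant_otus OTUs seeded into the blank (and, at leakage
#'   level, into real samples).
#' @param n_decoy_otus OTUs carrying chloroplast or archaeal lineages, to be
#'   removed by [filter_table()].
#' @param abund_mu,abund_sigma Lognormal parameters of base OTU abundance.
#' @param preference_multiplier Boost (>= 1) in preferred strata.
#' @param off_habitat_epsilon Leakage factor (>= 0) outside preferred strata.
#' @param export_fraction Fraction of epipelagic specialists co-seeded onto
#'   nodules.
#' @param export_scale Attenuation of exported abundance relative to the
#'   preferred-stratum level.
#' @param export_to_bottom_water Also seed exported OTUs into the deepest
#'   water zone (off by default).
#' @param depth_mean,depth_sd Per-sample sequencing depth distribution
#'   (Normal, rounded, truncated at 1).
#' @param overdispersion Dirichlet-multinomial overdispersion; 0 (default)
#'   gives plain multinomial sampling, theta > 0 multiplies each latent cell
#'   by an independent Gamma(1/theta, 1/theta) factor (mean 1, variance
#'   theta).
#' @param n_euk_otus,n_planted_pairs,pair_noise_sigma Eukaryote-table
#'   parameters for [generate_paired_euk_table()].
#' @param seed Integer RNG seed.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_areas = 4,
                       strata = default_stratum_scheme(),
                       samples_per_stratum_per_area = 11,
                       n_specialist_otus_per_stratum = 30,
                       n_moderate_otus = 120,
                       n_generalist_otus = 30,
                       n_contaminant_otus = 5,
                       n_decoy_otus = 10,
                       abund_mu = 0,
                       abund_sigma = 1.5,
                       preference_multiplier = 50,
                       off_habitat_epsilon = 0.01,
                       export_fraction = 0.3,
                       export_scale = 0.1,
                       export_to_bottom_water = FALSE,
                       depth_mean = 9694.7,
                       depth_sd = 892.7,
                       overdispersion = 0,
                       n_euk_otus = 100,
                       n_planted_pairs = 20,
                       pair_noise_sigma = 0.3,
                       seed = 1) {
  p <- as.list(environment())
  validate_scheme(p$strata)
  counts <- c("n_areas", "samples_per_stratum_per_area",
              "n_specialist_otus_per_stratum", "n_moderate_otus",
              "n_generalist_otus", "n_contaminant_otus", "n_decoy_otus",
              "n_euk_otus", "n_planted_pairs")
  for (nm in counts) {
    if (!is_count_scalar(p[[nm]])) stopf("`%s` must be a non-negative integer", nm)
  }
  if (p$n_areas < 1 || p$samples_per_stratum_per_area < 1) {
    stopf("need at least one area and one sample per stratum")
  }
  if (!is_number(p$abund_sigma) || p$abund_sigma <= 0) stopf("`abund_sigma` must be > 0")
  if (!is_number(p$pair_noise_sigma) || p$pair_noise_sigma <= 0) {
    stopf("`pair_noise_sigma` must be > 0")
  }
  if (!is_number(p$preference_multiplier, min = 1)) {
    stopf("`preference_multiplier` must be >= 1")
  }
  if (!is_number(p$off_habitat_epsilon, min = 0)) stopf("`off_habitat_epsilon` must be >= 0")
  if (!is_number(p$export_fraction, min = 0) || p$export_fraction > 1) {
    stopf("`export_fraction` must be in [0, 1]")
  }
  if (!is_number(p$export_scale) || p$export_scale <= 0) stopf("`export_scale` must be > 0")
  if (!is_number(p$depth_mean) || p$depth_mean <= 0) stopf("`depth_mean` must be > 0")
  if (!is_number(p$depth_sd, min = 0)) stopf("`depth_sd` must be >= 0")
  if (!is_number(p$overdispersion, min = 0)) stopf("`overdispersion` must be >= 0")
  if (!is_count_scalar(p$seed %||% 0, min = 0) && !is.numeric(p$seed)) {
    stopf("`seed` must be an integer")
  }
  if (p$export_fraction > 0) {
    habs <- unique(p$strata$habitat)
    if (!all(c("water", "sediment", "nodule") %in% habs)) {
      stopf("export coupling needs water, sediment and nodule strata in the scheme")
    }
  }
  class(p) <- "sim_params"
  p
}

area_names <- function(n) {
  base <- c("UK1-A", "UK1-B", "OMS-A", "APEI-6")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, sprintf("AREA-%d", seq(length(base) + 1L, n)))
}

# plausible SILVA-flavoured lineages per ecological role
sim_lineage <- function(role) {
  pick <- function(tab) tab[[sample.int(length(tab), 1L)]]
  # epipelagic specialists are always cyanobacterial so the photic-zone
  # group can be pulled out by lineage; no other planted class (decoys
  # aside, which the lineage filter removes) carries a cyanobacterial
  # lineage
  epi_tax <- list(
    c("Cyanobacteria", "Cyanobacteriia", "Synechococcales", "Cyanobiaceae", "Prochlorococcus"),
    c("Cyanobacteria", "Cyanobacteriia", "Synechococcales", "Cyanobiaceae", "Synechococcus")
  )
  deep_water_tax <- list(
    c("Proteobacteria", "Alphaproteobacteria", "SAR11 clade", "Clade I", "Clade Ia"),
    c("Actinobacteriota", "Acidimicrobiia", "Actinomarinales", "Actinomarinaceae", "Candidatus Actinomarina"),
    c("Proteobacteria", "Deltaproteobacteria", "SAR324 clade", "SAR324 clade", "SAR324"),
    c("Chloroflexi", "Dehalococcoidia", "SAR202 clade", "SAR202 clade", "SAR202"),
    c("Proteobacteria", "Gammaproteobacteria", "Oceanospirillales", "Nitrincolaceae", "Amphritea")
  )
  sediment_tax <- list(
    c("Planctomycetota", "Planctomycetes", "Pirellulales", "Pirellulaceae", "Blastopirellula"),
    c("Chloroflexi", "Anaerolineae", "Anaerolineales", "Anaerolineaceae", "Anaerolinea"),
    c("Acidobacteriota", "Subgroup 21", "Subgroup 21", "Subgroup 21", "Subgroup 21"),
    c("Nitrospirota", "Nitrospiria", "Nitrospirales", "Nitrospiraceae", "Nitrospira")
  )
  nodule_tax <- list(
    c("Proteobacteria", "Gammaproteobacteria", "Steroidobacterales", "Woeseiaceae", "JTB255 marine benthic group"),
    c("Proteobacteria", "Alphaproteobacteria", "Rhizobiales", "Rhodobiaceae", "Rhodobium"),
    c("Proteobacteria", "Gammaproteobacteria", "Vibrionales", "Vibrionaceae", "Vibrio"),
    c("Proteobacteria", "Alphaproteobacteria", "Rhodospirillales", "Rhodospirillaceae", "Magnetospira")
  )
  tx <- switch(role,
    epipelagic = pick(epi_tax),
    water = pick(deep_water_tax),
    sediment = pick(sediment_tax),
    nodule = pick(nodule_tax),
    generalist = pick(c(deep_water_tax, nodule_tax)),
    moderate = pick(c(deep_water_tax, sediment_tax, nodule_tax)),
    contaminant = c("Proteobacteria", "Gammaproteobacteria", "Pseudomonadales",
                    "Pseudomonadaceae", "Pseudomonas"),
    decoy_plastid = c("Cyanobacteria", "Chloroplast", "Chloroplast", "Chloroplast", "Chloroplast"),
    decoy_archaea = NULL
  )
  if (identical(role, "decoy_archaea")) {
    return("d__Archaea;p__Crenarchaeota;c__Nitrososphaeria;o__Nitrosopumilales;f__Nitrosopumilaceae;g__Nitrosopumilus")
  }
  sprintf("d__Bacteria;p__%s;c__%s;o__%s;f__%s;g__%s",
          tx[1], tx[2], tx[3], tx[4], tx[5])
}

#' Generate a synthetic nodule-field OTU survey with planted truth
#'
#' Simulates the OTU count table, sample metadata and a truth record for a
#' survey laid out as one sample per (area, stratum, replicate) plus one
#' extraction blank. Latent expected abundances follow the preference model
#' described in [sim_params()]; realized counts are a single multinomial
#' draw per sample at a Normal(depth_mean, depth_sd) depth rounded and
#' truncated at 1 (Dirichlet-multinomial when `overdispersion > 0`). The
#' blank contains only contaminant OTUs. Identical parameters (including
#' the seed) give bit-identical output.
#'
#' @param params A [sim_params()] list.
#' @return A list with elements `table` ([count_table()]), `frame`
#'   ([sample_frame()]) and `truth` (a `synthetic_truth` record of planted
#'   classes, preferred strata, export flags and the latent matrix used for
#'   eukaryote pairing).
#' @export
generate_community <- function(params) {
  if (!inherits(params, "sim_params")) stopf("`params` must come from sim_params()")
  p <- params
  scheme <- p$strata
  areas <- area_names(p$n_areas)

  ## ---- sample frame -------------------------------------------------
  grid <- expand.grid(rep = seq_len(p$samples_per_stratum_per_area),
                      stratum = scheme$label, area = areas,
                      stringsAsFactors = FALSE)
  hab <- structure(scheme$habitat, names = scheme$label)
  mid_depth <- function(lab) {
    i <- match(lab, scheme$label)
    lo <- scheme$lower[i]; up <- scheme$upper[i]
    if (hab[[lab]] != "water") return(4100)          # seafloor habitats
    if (is.na(up)) return(lo + 500)
    (lo + up) / 2
  }
  ids <- sprintf("%s.%s.r%02d", grid$area, grid$stratum, grid$rep)
  frame <- sample_frame(
    sample_id = ids,
    habitat = unname(hab[grid$stratum]),
    stratum = grid$stratum,
    area = grid$area,
    depth_m = vapply(grid$stratum, mid_depth, 0),
    scheme = scheme
  )
  has_blank <- p$n_contaminant_otus > 0
  if (has_blank) {
    frame <- rbind(frame,
                   data.frame(sample_id = "blank.1", habitat = "control",
                              stratum = "control", area = areas[1],
                              depth_m = NA_real_, stringsAsFactors = FALSE))
    class(frame) <- c("sample_frame", "data.frame")
  }

  out <- with_seed(p$seed, {
    ## ---- OTU roster -------------------------------------------------
    n_strata <- nrow(scheme)
    n_spec <- p$n_specialist_otus_per_stratum * n_strata
    n_total <- n_spec + p$n_moderate_otus + p$n_generalist_otus +
      p$n_contaminant_otus + p$n_decoy_otus
    if (n_total == 0) stopf("no OTUs requested")
    otu_id <- sprintf("OTU_%d", seq_len(n_total))
    planted_class <- character(n_total)
    preferred <- vector("list", n_total)
    role <- character(n_total)

    i <- 0L
    for (z in scheme$label) {
      for (k in seq_len(p$n_specialist_otus_per_stratum)) {
        i <- i + 1L
        planted_class[i] <- "specialist"
        preferred[[i]] <- z
        role[i] <- if (z == "epipelagic") "epipelagic" else hab[[z]]
      }
    }
    core <- core_stratum_set(scheme, "operative")
    habitats <- unique(scheme$habitat)
    for (k in seq_len(p$n_moderate_otus)) {
      i <- i + 1L
      planted_class[i] <- "moderate_generalist"
      two <- sample(habitats, 2L)
      pref <- unlist(lapply(two, function(h) {
        st <- scheme$label[scheme$habitat == h]
        st[sample.int(length(st), sample.int(length(st), 1L))]
      }))
      preferred[[i]] <- sort(unique(pref))
      role[i] <- "moderate"
    }
    for (k in seq_len(p$n_generalist_otus)) {
      i <- i + 1L
      planted_class[i] <- "generalist"
      preferred[[i]] <- core
      role[i] <- "generalist"
    }
    for (k in seq_len(p$n_contaminant_otus)) {
      i <- i + 1L
      planted_class[i] <- "contaminant"
      preferred[[i]] <- character(0)
      role[i] <- "contaminant"
    }
    for (k in seq_len(p$n_decoy_otus)) {
      i <- i + 1L
      planted_class[i] <- "decoy"
      preferred[[i]] <- scheme$label
      role[i] <- if (k %% 2L == 1L) "decoy_plastid" else "decoy_archaea"
    }
    names(planted_class) <- names(preferred) <- otu_id
    taxonomy <- vapply(role, sim_lineage, "")
    names(taxonomy) <- otu_id

    ## ---- export flags ----------------------------------------------
    epi_spec <- otu_id[planted_class == "specialist" &
                         vapply(preferred, function(s) identical(s, "epipelagic"), TRUE)]
    n_export <- round(p$export_fraction * length(epi_spec))
    exported <- structure(rep(FALSE, n_total), names = otu_id)
    if (n_export > 0) exported[sample(epi_spec, n_export)] <- TRUE

    ## ---- latent expected abundances --------------------------------
    base <- stats::rlnorm(n_total, p$abund_mu, p$abund_sigma)
    names(base) <- otu_id
    real_ids <- noncontrol_samples(frame)
    strat <- stratum_of(frame)[real_ids]
    L <- matrix(0, nrow = n_total, ncol = length(real_ids),
                dimnames = list(otu_id, real_ids))
    pref_mat <- matrix(FALSE, n_total, n_strata,
                       dimnames = list(otu_id, scheme$label))
    for (j in seq_len(n_total)) pref_mat[j, preferred[[j]]] <- TRUE
    nod <- nodule_strata(scheme)
    deepest_water <- utils::tail(water_strata(scheme), 1L)
    for (s in seq_along(real_ids)) {
      z <- strat[[s]]
      mult <- ifelse(pref_mat[, z], p$preference_multiplier, p$off_habitat_epsilon)
      mult[planted_class == "contaminant"] <- p$off_habitat_epsilon
      lat <- base * mult
      seed_here <- z %in% nod ||
        (p$export_to_bottom_water && z %in% deepest_water)
      if (seed_here && any(exported)) {
        lat[exported] <- lat[exported] +
          base[exported] * p$preference_multiplier * p$export_scale
      }
      L[, s] <- lat
    }
    if (p$overdispersion > 0) {
      sh <- 1 / p$overdispersion
      L <- L * matrix(stats::rgamma(length(L), shape = sh, rate = sh),
                      nrow = nrow(L))
    }

    ## ---- realized counts -------------------------------------------
    all_ids <- frame$sample_id
    depth <- pmax(1, round(stats::rnorm(length(all_ids), p$depth_mean, p$depth_sd)))
    names(depth) <- all_ids
    counts <- matrix(0, nrow = n_total, ncol = length(all_ids),
                     dimnames = list(otu_id, all_ids))
    for (s in real_ids) {
      lat <- L[, s]
      if (sum(lat) <= 0) {
        stopf("sample %s has zero expected abundance; increase off_habitat_epsilon or plant OTUs in its stratum", s)
      }
      counts[, s] <- stats::rmultinom(1, depth[[s]], lat)
    }
    if (has_blank) {
      blat <- numeric(n_total)
      blat[planted_class == "contaminant"] <- base[planted_class == "contaminant"]
      counts[, "blank.1"] <- stats::rmultinom(1, depth[["blank.1"]], blat)
    }

    truth <- structure(list(
      planted_class = planted_class,
      preferred = preferred,
      exported = exported,
      planted_pairs = data.frame(bacterial = character(0), eukaryote = character(0),
                                 stringsAsFactors = FALSE),
      latent = L,
      seed = p$seed
    ), class = "synthetic_truth")

    list(table = count_table(counts, taxonomy), frame = frame, truth = truth)
  })
  out
}

#' Generate a eukaryote (18S) table latently coupled to a bacterial survey
#'
#' Builds a eukaryote OTU table over the same (non-control) samples as a
#' community from [generate_community()]. `n_planted_pairs` eukaryote OTUs
#' copy the per-sample latent log-abundance of a randomly chosen bacterial
#' partner plus Normal(0, pair_noise_sigma) noise, so each pair co-occurs
#' across samples; the remaining eukaryote OTUs are independent. Counts are
#' drawn like the bacterial table (multinomial at a fresh Normal depth).
#'
#' @param params The same [sim_params()] used for the community.
#' @param truth,frame Outputs of [generate_community()].
#' @return A list with `table` (eukaryote [count_table()]) and `truth` (the
#'   input truth with `planted_pairs` filled in).
#' @export
generate_paired_euk_table <- function(params, truth, frame) {
  if (!inherits(params, "sim_params")) stopf("`params` must come from sim_params()")
  if (!inherits(truth, "synthetic_truth")) stopf("`truth` must come from generate_community()")
  p <- params
  eligible <- names(truth$planted_class)[
    !truth$planted_class %in% c("contaminant", "decoy")]
  if (p$n_planted_pairs > length(eligible)) {
    stopf("n_planted_pairs (%d) exceeds available bacterial OTUs (%d)",
          p$n_planted_pairs, length(eligible))
  }
  if (p$n_euk_otus < p$n_planted_pairs) {
    stopf("n_euk_otus must be >= n_planted_pairs")
  }
  real_ids <- noncontrol_samples(frame)
  real_ids <- real_ids[real_ids %in% colnames(truth$latent)]

  euk_tax_pool <- c(
    "d__Eukaryota;p__Retaria;c__Foraminifera;o__Rotaliida;f__Calcarinidae;g__Calcarina",
    "d__Eukaryota;p__Retaria;c__Foraminifera;o__Rotaliida;f__Amphisteginidae;g__Amphistegina",
    "d__Eukaryota;p__Retaria;c__Foraminifera;o__Lituolida;f__Trochamminidae;g__Trochammina",
    "d__Eukaryota;p__Ciliophora;c__Spirotrichea;o__Choreotrichida;f__Strombidinopsidae;g__Strombidinopsis",
    "d__Eukaryota;p__Cryptophyta;c__Cryptophyceae;o__Pyrenomonadales;f__Geminigeraceae;g__Teleaulax"
  )

  # one derived seed keeps the eukaryote draw reproducible but distinct from
  # the bacterial draw of the same params
  with_seed(as.integer(p$seed) + 1L, {
    n_euk <- p$n_euk_otus
    euk_id <- sprintf("EUK_%d", seq_len(n_euk))
    partners <- if (p$n_planted_pairs > 0) sample(eligible, p$n_planted_pairs) else character(0)
    Lk <- matrix(0, nrow = n_euk, ncol = length(real_ids),
                 dimnames = list(euk_id, real_ids))
    base <- stats::rlnorm(n_euk, p$abund_mu, p$abund_sigma)
    for (j in seq_len(n_euk)) {
      if (j <= p$n_planted_pairs) {
        Lk[j, ] <- truth$latent[partners[j], real_ids] *
          exp(stats::rnorm(length(real_ids), 0, p$pair_noise_sigma))
      } else {
        Lk[j, ] <- base[j]
      }
    }
    if (p$overdispersion > 0 && n_euk > p$n_planted_pairs) {
      idx <- seq(p$n_planted_pairs + 1L, n_euk)
      sh <- 1 / p$overdispersion
      Lk[idx, ] <- Lk[idx, ] *
        matrix(stats::rgamma(length(idx) * length(real_ids), shape = sh, rate = sh),
               nrow = length(idx))
    }
    depth <- pmax(1, round(stats::rnorm(length(real_ids), p$depth_mean, p$depth_sd)))
    counts <- matrix(0, nrow = n_euk, ncol = length(real_ids),
                     dimnames = list(euk_id, real_ids))
    for (s in seq_along(real_ids)) {
      counts[, s] <- stats::rmultinom(1, depth[s], Lk[, s])
    }
    taxonomy <- sample(euk_tax_pool, n_euk, replace = TRUE)
    names(taxonomy) <- euk_id
    truth$planted_pairs <- data.frame(
      bacterial = partners,
      eukaryote = euk_id[seq_len(p$n_planted_pairs)],
      stringsAsFactors = FALSE)
    list(table = count_table(counts, taxonomy), truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d OTUs (%s), %d exported, %d planted pairs, seed %s\n",
              length(x$planted_class),
              paste(sprintf("%d %s", table(x$planted_class),
                            names(table(x$planted_class))), collapse = ", "),
              sum(x$exported), nrow(x$planted_pairs), format(x$seed)))
  invisible(x)
}

#' Write a synthetic truth record as JSON
#'
#' The latent abundance matrix (internal plumbing for eukaryote pairing) is
#' omitted from the file.
#'
#' @param truth A `synthetic_truth`.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  out <- list(
    planted_class = as.list(truth$planted_class),
    preferred = truth$preferred,
    exported = names(truth$exported)[truth$exported],
    planted_pairs = truth$planted_pairs,
    seed = truth$seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
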