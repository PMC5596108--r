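make_presence_fixture <- function(counts_list, n_per = 2) {
  # counts_list: named list otu -> named vector sample -> count
  fr <- mini_frame(n_per)
  m <- matrix(0, length(counts_list), nrow(fr),
              dimnames = list(names(counts_list), fr$sample_id))
  for (o in names(counts_list)) {
    m[o, names(counts_list[[o]])] <- counts_list[[o]]
  }
  list(table = count_table(m), frame = fr, scheme = mini_scheme())
}

test_that("detection thresholds behave as specified", {
  fx <- make_presence_fixture(list(
    solo = c(epipelagic.r1 = 1),
    everywhere = c(epipelagic.r1 = 5, epipelagic.r2 = 5, sed_0_5cm.r1 = 5,
                   sed_0_5cm.r2 = 5, nodule.r1 = 5, nodule.r2 = 5)
  ))
  p1 <- presence_matrix(fx$table, fx$frame, fx$scheme)
  expect_true(p1["solo", "epipelagic"])
  expect_false(any(p1["solo", c("sed_0_5cm", "nodule")]))

  # min_count = 2 drops the single-read OTU entirely, with a report
  p2 <- presence_matrix(fx$table, fx$frame, fx$scheme, min_count = 2)
  expect_false("solo" %in% rownames(p2))
  expect_equal(attr(p2, "dropped_otus"), "solo")

  # min_samples = 2 needs two detecting samples per stratum
  p3 <- presence_matrix(fx$table, fx$frame, fx$scheme, min_samples = 2)
  expect_false("solo" %in% rownames(p3))
  expect_true(all(p3["everywhere", ]))
})

test_that("presence matches a brute-force recomputation on random tables", {
  for (s in 1:10) {
    fx_tab <- random_count_table(25, 6, lambda = 0.7, seed = s)
    fr <- mini_frame(2)
    colnames(fx_tab$counts) <- fr$sample_id
    tab <- count_table(fx_tab$counts)
    for (mc in c(1, 2)) for (ms in c(1, 2)) {
      p <- presence_matrix(tab, fr, mini_scheme(), min_count = mc, min_samples = ms)
      oracle <- presence_oracle(tab$counts, setNames(fr$stratum, fr$sample_id),
                                mini_scheme()$label, mc, ms)
      oracle <- oracle[rowSums(oracle) > 0, , drop = FALSE]
      ro <- rownames(oracle); if (is.null(ro)) ro <- character(0)
      rn <- rownames(p); if (is.null(rn)) rn <- character(0)
      got <- unclass(p)[order(rn), , drop = FALSE]
      attributes(got)[setdiff(names(attributes(got)), c("dim", "dimnames"))] <- NULL
      expect_equal(got, oracle[order(ro), , drop = FALSE], ignore_attr = TRUE)
      expect_identical(dim(got), dim(oracle))
      expect_identical(sort(rn), sort(ro))
    }
  }
})

test_that("raising min_count never increases detections", {
  tab <- random_count_table(40, 6, lambda = 2, seed = 4)
  fr <- mini_frame(2)
  colnames(tab$counts) <- fr$sample_id
  tab <- count_table(tab$counts)
  prev <- NULL
  for (mc in 1:4) {
    p <- presence_matrix(tab, fr, mini_scheme(), min_count = mc)
    det <- colSums(p)
    if (!is.null(prev)) expect_true(all(det <= prev))
    prev <- det
  }
})

test_that("venn partition handles confined and ubiquitous OTUs", {
  fx <- make_presence_fixture(list(
    w = c(epipelagic.r1 = 3),
    s = c(sed_0_5cm.r1 = 3),
    n = c(nodule.r1 = 3),
    all = c(epipelagic.r1 = 1, sed_0_5cm.r1 = 1, nodule.r1 = 1)
  ))
  p <- presence_matrix(fx$table, fx$frame, fx$scheme)
  v <- venn_partition(p, fx$scheme)
  expect_equal(unname(v$regions[c("water_only", "sediment_only", "nodule_only")]),
               c(1, 1, 1))
  expect_equal(unname(v$regions["all_three"]), 1)
  expect_equal(sum(v$regions), v$n_otus)
  expect_equal(unname(v$pairwise["water_sediment"]),
               unname(v$regions["water_sediment"] + v$regions["all_three"]))
})

test_that("venn counts match exhaustive set enumeration on random input", {
  set.seed(90)
  for (rep in 1:5) {
    tab <- random_count_table(100, 6, lambda = 0.5, seed = rep + 50)
    fr <- mini_frame(2)
    colnames(tab$counts) <- fr$sample_id
    tab <- count_table(tab$counts)
    p <- presence_matrix(tab, fr, mini_scheme())
    v <- venn_partition(p, mini_scheme())
    hab_sets <- lapply(seq_len(nrow(p)), function(i) {
      c("water", "sediment", "nodule")[c(p[i, "epipelagic"],
                                         p[i, "sed_0_5cm"],
                                         p[i, "nodule"])]
    })
    expect_equal(v$regions, venn_oracle(hab_sets))
    expect_equal(sum(v$regions), nrow(p))
  }
})

test_that("shared_otus counts joint detections over stratum subsets", {
  fx <- make_presence_fixture(list(
    a = c(epipelagic.r1 = 1, nodule.r1 = 1),
    b = c(epipelagic.r1 = 1, sed_0_5cm.r1 = 1, nodule.r1 = 1),
    c = c(sed_0_5cm.r2 = 4)
  ))
  p <- presence_matrix(fx$table, fx$frame, fx$scheme)
  expect_equal(shared_otus(p, c("epipelagic", "nodule")), 2)
  expect_equal(shared_otus(p, c("epipelagic", "sed_0_5cm", "nodule")), 1)
  expect_error(shared_otus(p, "abyssal_plain"), "unknown")
})

test_that("classification applies the three published-style rules", {
  sc <- default_stratum_scheme()
  n_st <- nrow(sc)
  otus <- c("deep_sed", "ubiquitous", "epi_nodule", "two_layers")
  pres <- matrix(FALSE, 4, n_st, dimnames = list(otus, sc$label))
  pres["deep_sed", "sed_8_10cm"] <- TRUE
  pres["ubiquitous", ] <- TRUE
  pres["epi_nodule", c("epipelagic", "nodule")] <- TRUE
  pres["two_layers", c("sed_0_5cm", "sed_5_6cm")] <- TRUE
  pres <- structure(pres, occupancy = setNames(rep(0.5, 4), otus),
                    class = c("presence_matrix", "matrix"))

  cls <- classify_otus(pres, sc, rule_set = "operative")
  lab <- setNames(cls$label, cls$otu_id)
  expect_equal(unname(lab["deep_sed"]), "specialist")
  expect_equal(cls$stratum[cls$otu_id == "deep_sed"], "sed_8_10cm")
  expect_equal(cls$habitat[cls$otu_id == "deep_sed"], "sediment")
  expect_equal(unname(lab["ubiquitous"]), "generalist")
  expect_equal(unname(lab["epi_nodule"]), "moderate_generalist")
  expect_equal(unname(lab["two_layers"]), "unclassified")

  # under the strict rule the ubiquitous OTU is still a generalist
  cls_strict <- classify_otus(pres, sc, rule_set = "strict")
  lab_s <- setNames(cls_strict$label, cls_strict$otu_id)
  expect_equal(unname(lab_s["ubiquitous"]), "generalist")

  # an OTU spanning the operative core but missing a deep layer is a
  # generalist operatively but not strictly
  pres2 <- pres
  pres2["ubiquitous", c("sed_6_8cm", "sed_8_10cm", "sed_15_18cm")] <- FALSE
  cls_op <- classify_otus(pres2, sc, rule_set = "operative")
  cls_st <- classify_otus(pres2, sc, rule_set = "strict")
  expect_equal(cls_op$label[cls_op$otu_id == "ubiquitous"], "generalist")
  expect_equal(cls_st$label[cls_st$otu_id == "ubiquitous"], "moderate_generalist")
})

test_that("every OTU gets exactly one label and shares sum to 100%", {
  p <- sim_params(n_areas = 2, samples_per_stratum_per_area = 2,
                  n_specialist_otus_per_stratum = 3, n_moderate_otus = 15,
                  n_generalist_otus = 5, n_contaminant_otus = 2,
                  n_decoy_otus = 2, seed = 31)
  sim <- generate_community(p)
  filt <- filter_table(sim$table, sim$frame)
  fnc <- sim$frame[sim$frame$habitat != "control", ]
  pres <- presence_matrix(filt, fnc, p$strata)
  cls <- classify_otus(pres, p$strata)
  expect_equal(anyDuplicated(cls$otu_id), 0)
  expect_true(all(cls$label %in% c("specialist", "moderate_generalist",
                                   "generalist", "unclassified")))
  summ <- class_summary(cls, filt, fnc)
  expect_equal(sum(summ$per_class$pct_sequences), 100, tolerance = 1e-9)
  expect_true(all(cls$occupancy >= 0 & cls$occupancy <= 1))
})

test_that("occupancy counts detecting samples out of all non-control samples", {
  fr <- mini_frame(5)   # 15 samples
  m <- matrix(0, 1, 15, dimnames = list("o1", fr$sample_id))
  m[1, 1:9] <- 2
  tab <- count_table(m)
  p <- presence_matrix(tab, fr, mini_scheme())
  expect_equal(unname(attr(p, "occupancy")["o1"]), 9 / 15)
})

test_that("class_summary ranks widest-distribution OTUs by occupancy", {
  p <- sim_params(n_areas = 1, samples_per_stratum_per_area = 4,
                  n_specialist_otus_per_stratum = 2, n_moderate_otus = 10,
                  n_generalist_otus = 6, n_contaminant_otus = 0,
                  n_decoy_otus = 0, seed = 77)
  sim <- generate_community(p)
  fnc <- sim$frame[sim$frame$habitat != "control", ]
  pres <- presence_matrix(sim$table, fnc, p$strata)
  cls <- classify_otus(pres, p$strata)
  summ <- class_summary(cls, sim$table, fnc, n_top = 5)
  top_gen <- summ$top_otus[summ$top_otus$label == "generalist", ]
  expect_lte(nrow(top_gen), 5)
  expect_true(!is.unsorted(rev(top_gen$occupancy)))
  # per-class OTU counts agree with the classification itself
  for (cl in unique(cls$label)) {
    expect_equal(summ$per_class$n_otus[summ$per_class$label == cl],
                 sum(cls$label == cl))
  }
})

test_that("noise-free synthetic truth is recovered exactly", {
  p <- sim_params(n_areas = 1, samples_per_stratum_per_area = 3,
                  n_specialist_otus_per_stratum = 5, n_moderate_otus = 20,
                  n_generalist_otus = 8, n_contaminant_otus = 3,
                  n_decoy_otus = 4, preference_multiplier = 100,
                  off_habitat_epsilon = 0, export_fraction = 0,
                  depth_mean = 20000, depth_sd = 1, seed = 55)
  sim <- generate_community(p)
  filt <- filter_table(sim$table, sim$frame)
  fnc <- sim$frame[sim$frame$habitat != "control", ]
  pres <- presence_matrix(filt, fnc, p$strata)
  cls <- classify_otus(pres, p$strata)
  planted <- sim$truth$planted_class
  planted <- planted[planted %in% c("specialist", "moderate_generalist", "generalist")]
  called <- setNames(cls$label, cls$otu_id)[names(planted)]
  expect_equal(unname(called), unname(planted))
})
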