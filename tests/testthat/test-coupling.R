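rel_fixture <- function(m, frame) {
  colnames(m) <- frame$sample_id[seq_len(ncol(m))]
  to_relative(count_table(m))
}

test_that("identical stratum profiles regress with slope 1 and R2 1", {
  fr <- mini_frame(2)
  set.seed(1)
  prof <- rpois(12, 30) + 1
  m <- matrix(rep(prof, 6), 12, 6, dimnames = list(paste0("o", 1:12), fr$sample_id))
  rel <- to_relative(count_table(m))
  res <- habitat_abundance_regression(rel, fr, mini_scheme(),
                                      pairs = "epipelagic:nodule")
  row <- res$pairs[1, ]
  expect_true(row$estimable)
  expect_equal(row$slope, 1, tolerance = 1e-9)
  expect_equal(row$r2, 1, tolerance = 1e-9)
})

test_that("regression matches closed-form least squares on fixed points", {
  # 4 OTUs whose log10 mean abundances are (1,2),(2,3),(3,5),(4,6)
  fr <- mini_frame(1)
  x <- 10^c(1, 2, 3, 4); y <- 10^c(2, 3, 5, 6)
  m <- matrix(0, 4, 3, dimnames = list(paste0("o", 1:4), fr$sample_id))
  m[, "epipelagic.r1"] <- x
  m[, "nodule.r1"] <- y
  m[, "sed_0_5cm.r1"] <- 1
  tab <- count_table(m)
  rel <- structure(list(values = sweep(m, 2, colSums(m), "/"),
                        taxonomy = tab$taxonomy), class = "rel_abund_table")
  res <- habitat_abundance_regression(rel, fr, mini_scheme(),
                                      pairs = "epipelagic:nodule")
  # relative abundance normalization shifts both axes by a constant, which
  # leaves the slope and R2 of the log-log fit unchanged
  oracle <- ols_oracle(c(1, 2, 3, 4), c(2, 3, 5, 6))
  expect_equal(res$pairs$slope[1], oracle$slope, tolerance = 1e-9)
  expect_equal(res$pairs$r2[1], oracle$r2, tolerance = 1e-9)
})

test_that("R2 equals the squared correlation of the log-mean vectors", {
  fr <- mini_frame(3)
  tab <- random_count_table(30, 9, lambda = 8, seed = 6)
  colnames(tab$counts) <- fr$sample_id
  rel <- to_relative(count_table(tab$counts))
  res <- habitat_abundance_regression(rel, fr, mini_scheme(),
                                      pairs = "epipelagic:sed_0_5cm")
  mu <- res$otu_means
  joint <- mu[, "epipelagic"] > 0 & mu[, "sed_0_5cm"] > 0
  r <- cor(log10(mu[joint, "epipelagic"]), log10(mu[joint, "sed_0_5cm"]))
  expect_equal(res$pairs$r2[1], r^2, tolerance = 1e-12)
})

test_that("pairs with too few shared OTUs are flagged not estimable", {
  fr <- mini_frame(1)
  m <- matrix(0, 3, 3, dimnames = list(paste0("o", 1:3), fr$sample_id))
  m[1, ] <- c(5, 0, 2)   # only o1 shared between epipelagic and nodule
  m[2, 1] <- 3
  m[2, 2] <- 3
  m[3, 3] <- 4
  rel <- to_relative(count_table(m + ifelse(m == 0, 0, 0)))
  res <- habitat_abundance_regression(rel, fr, mini_scheme(),
                                      pairs = "epipelagic:nodule")
  expect_false(res$pairs$estimable[1])
  expect_true(is.na(res$pairs$slope[1]))
  expect_error(habitat_abundance_regression(rel, fr, mini_scheme(),
                                            pairs = "epipelagic~nodule"),
               "stratumA:stratumB")
})

test_that("taxon fractions partition the group's sequences", {
  fr <- mini_frame(2)
  m <- matrix(0, 3, 6, dimnames = list(c("cy1", "cy2", "other"), fr$sample_id))
  m["cy1", c("nodule.r1", "nodule.r2")] <- c(30, 30)
  m["cy2", c("epipelagic.r1", "nodule.r1")] <- c(60, 0)
  m["other", ] <- 10
  tab <- count_table(m, c(cy1 = "d__Bacteria;p__Cyanobacteria;g__Synechococcus",
                          cy2 = "d__Bacteria;p__Cyanobacteria;g__Prochlorococcus",
                          other = "d__Bacteria;p__Chloroflexi"))
  fx <- taxon_habitat_fractions(tab, fr, "cyanobacteria")
  expect_equal(sum(fx$by_habitat_full), 1, tolerance = 1e-12)
  expect_equal(sum(fx$by_stratum), 1, tolerance = 1e-12)
  expect_equal(unname(fx$by_habitat_full["nodule"]), 0.5)
  expect_equal(unname(fx$by_habitat_full["water"]), 0.5)
  expect_equal(unname(fx$by_habitat_full["sediment"]), 0)
  expect_error(taxon_habitat_fractions(tab, fr, "Euryarchaeota"), "matches no OTU")
})

test_that("a group confined to one habitat gets fraction one there", {
  fr <- mini_frame(1)
  m <- matrix(c(0, 0, 9), 1, 3, dimnames = list("nod", fr$sample_id))
  tab <- count_table(m, c(nod = "d__Bacteria;p__Proteobacteria;f__Rhodobiaceae"))
  fx <- taxon_habitat_fractions(tab, fr, "Rhodobiaceae")
  expect_equal(unname(fx$by_habitat_full["nodule"]), 1)
})

test_that("abundant_flow applies the >1% source threshold exactly", {
  fr <- mini_frame(2)
  m <- matrix(1, 3, 6, dimnames = list(c("big", "border", "small"), fr$sample_id))
  # epipelagic mean rel abundances: big 2%, border exactly 1%, small 0.9%
  epi <- c("epipelagic.r1", "epipelagic.r2")
  m["big", epi] <- 2; m["border", epi] <- 1; m["small", epi] <- 0.9
  m["big", "nodule.r1"] <- 0; m["big", "nodule.r2"] <- 0
  base <- matrix(96.1 / 97, 97, 6,
                 dimnames = list(paste0("f", 1:97), fr$sample_id))
  cnt <- rbind(m, base) * 1000
  cnt <- round(cnt)
  rel0 <- sweep(cnt, 2, colSums(cnt), "/")
  rel <- structure(list(values = rel0, taxonomy = NULL), class = "rel_abund_table")
  mu_src <- rowMeans(rel0[c("big", "border", "small"), epi])
  fl <- abundant_flow(rel, fr, mini_scheme(), "epipelagic", threshold = 0.01)
  otus <- unique(fl$otu_id)
  expect_true("big" %in% otus)
  expect_equal(sort(intersect(otus, c("big", "border", "small"))),
               sort(names(mu_src)[mu_src > 0.01]))
  # destinations exclude the source and carry detection flags
  expect_setequal(unique(fl$destination), c("sed_0_5cm", "nodule"))
  big_nod <- fl[fl$otu_id == "big" & fl$destination == "nodule", ]
  expect_false(big_nod$detected)
})

test_that("abundant_flow matches a brute-force filter on random tables", {
  for (s in 1:5) {
    fr <- mini_frame(3)
    tab <- random_count_table(40, 9, lambda = 5, seed = s + 20)
    colnames(tab$counts) <- fr$sample_id
    rel <- to_relative(count_table(tab$counts))
    fl <- abundant_flow(rel, fr, mini_scheme(), "nodule", threshold = 0.02)
    strat <- setNames(fr$stratum, fr$sample_id)
    nod_cols <- names(strat)[strat == "nodule"]
    mu <- rowMeans(rel$values[, nod_cols, drop = FALSE])
    expect_setequal(unique(fl$otu_id), names(mu)[mu > 0.02])
    for (i in seq_len(nrow(fl))) {
      cols <- names(strat)[strat == fl$destination[i]]
      expect_equal(fl$mean_rel_abund[i],
                   mean(rel$values[fl$otu_id[i], cols]), tolerance = 1e-12)
    }
  }
})

net_fixture <- function(seed, n_pairs = 3, noise = 0.15) {
  p <- sim_params(n_areas = 1, samples_per_stratum_per_area = 2,
                  n_specialist_otus_per_stratum = 0, n_moderate_otus = 0,
                  n_generalist_otus = 30, n_contaminant_otus = 0,
                  n_decoy_otus = 0, preference_multiplier = 1,
                  off_habitat_epsilon = 1, overdispersion = 1,
                  export_fraction = 0, depth_mean = 20000, depth_sd = 100,
                  n_euk_otus = 30, n_planted_pairs = n_pairs,
                  pair_noise_sigma = noise, seed = seed)
  sim <- generate_community(p)
  euk <- generate_paired_euk_table(p, sim$truth, sim$frame)
  list(bact = to_relative(sim$table), euk = to_relative(euk$table),
       pairs = euk$truth$planted_pairs)
}

test_that("planted pairs are retained with strong positive correlation", {
  fx <- net_fixture(5)
  # p-value granularity must be fine enough for BH at 900 tested pairs:
  # the smallest attainable p is 1/(B+1)
  net <- cooccurrence_network(fx$bact, fx$euk, n_permutations = 9999,
                              fdr_alpha = 0.05, min_prevalence = 0.2, seed = 11)
  found <- paste(net$otu_a, net$otu_b)
  planted <- paste(fx$pairs$bacterial, fx$pairs$eukaryote)
  expect_true(all(planted %in% found))
  planted_rows <- net[found %in% planted, ]
  expect_true(all(planted_rows$sign == "positive"))
  expect_true(all(planted_rows$p == 1 / 10000))
  expect_true(all(abs(net$rho) <= 1))
})

test_that("an exactly anti-coupled pair gives rho -1 with negative sign", {
  n <- 10
  # hand-built relative-abundance tables: one rising OTU, one constant
  a2 <- rbind(up = seq_len(n) / sum(1:n), flat = rep(0.1, n))
  b2 <- rbind(down = rev(seq_len(n)) / sum(1:n), flat2 = rep(0.2, n))
  colnames(a2) <- colnames(b2) <- paste0("s", 1:n)
  as_rel <- function(m) structure(list(values = m, taxonomy = NULL),
                                  class = "rel_abund_table")
  net <- cooccurrence_network(as_rel(a2), as_rel(b2),
                              n_permutations = 499, fdr_alpha = 1,
                              min_prevalence = 0, seed = 3)
  row <- net[net$otu_a == "up" & net$otu_b == "down", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$rho, -1, tolerance = 1e-12)
  expect_equal(row$sign, "negative")
  # constant-rank OTUs are skipped with a report, not an error
  expect_true(all(c("flat", "flat2") %in% attr(net, "skipped")))
})

test_that("edges obey BH monotonicity and shrink as alpha tightens", {
  fx <- net_fixture(9)
  net1 <- cooccurrence_network(fx$bact, fx$euk, n_permutations = 499,
                               fdr_alpha = 0.10, seed = 2)
  net2 <- cooccurrence_network(fx$bact, fx$euk, n_permutations = 499,
                               fdr_alpha = 0.01, seed = 2)
  expect_true(all(net1$q >= net1$p))
  e1 <- paste(net1$otu_a, net1$otu_b)
  e2 <- paste(net2$otu_a, net2$otu_b)
  expect_true(all(e2 %in% e1))
  ap <- attr(net1, "all_pairs")
  ord <- order(ap$p)
  expect_true(!is.unsorted(ap$q[ord]))
})

test_that("the network run is seed-deterministic and validates inputs", {
  fx <- net_fixture(13)
  n1 <- cooccurrence_network(fx$bact, fx$euk, n_permutations = 199, seed = 7)
  n2 <- cooccurrence_network(fx$bact, fx$euk, n_permutations = 199, seed = 7)
  expect_identical(as.data.frame(n1), as.data.frame(n2))
  few <- to_relative(count_table(fx$bact$values[, 1:5] * 0 +
                                   matrix(rpois(5 * nrow(fx$bact$values), 5) + 1,
                                          ncol = 5,
                                          dimnames = list(rownames(fx$bact$values),
                                                          colnames(fx$bact$values)[1:5]))))
  expect_error(cooccurrence_network(few, fx$euk), "8")
})

test_that("a table against itself recovers its own OTUs as perfect edges", {
  fx <- net_fixture(17, n_pairs = 0)
  net <- cooccurrence_network(fx$bact, fx$bact, n_permutations = 1999,
                              fdr_alpha = 0.05, min_prevalence = 0.2, seed = 1)
  self <- net[net$otu_a == net$otu_b, ]
  expect_true(all(abs(self$rho - 1) < 1e-12))
  expect_gt(nrow(self), 0)
})

test_that("edge lists export as TSV and GraphML", {
  fx <- net_fixture(21)
  net <- cooccurrence_network(fx$bact, fx$euk, n_permutations = 199, seed = 4)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_edge_list(net, tsv)
  back <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(net))
  write_graphml(net, gml)
  doc <- readLines(gml)
  expect_true(any(grepl("<graphml", doc)))
  expect_equal(sum(grepl("<edge ", doc)), nrow(net))
})
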