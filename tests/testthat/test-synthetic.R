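test_that("species trees are binary, ultrametric, unit height and seeded", {
  tr <- simulate_species_tree(8, 1, seed = 42)
  expect_equal(length(tr$tip.label), 8)
  expect_true(ape::is.binary(tr))
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_equal(max(ape::node.depth.edgelength(tr)), 1, tolerance = 1e-12)
  expect_identical(ape::write.tree(tr),
                   ape::write.tree(simulate_species_tree(8, 1, seed = 42)))
  expect_false(identical(ape::write.tree(tr),
                         ape::write.tree(simulate_species_tree(8, 1, 43))))
  two <- simulate_species_tree(2, 1, seed = 1)
  d <- ape::node.depth.edgelength(two)[1:2]
  expect_equal(d[1], d[2])
  expect_error(simulate_species_tree(1, 1, seed = 1))
})

test_that("Yule trees show the expected cherry count", {
  # E[cherries] = n/3 for Yule trees; simulation against the closed form
  n <- 50
  ch <- vapply(1:300, function(s) {
    tr <- simulate_species_tree(n, 1, seed = 5000 + s)
    sum(tabulate(tr$edge[tr$edge[, 2] <= n, 1]) == 2)
  }, numeric(1))
  se <- stats::sd(ch) / sqrt(length(ch))
  expect_lt(abs(mean(ch) - n / 3), 3 * se)
})

test_that("gene trees without events mirror the species tree", {
  sp <- simulate_species_tree(7, 1, seed = 3)
  gt <- simulate_gene_tree(sp, 0, 0, seed = 9)
  expect_equal(sort(gt$tip.label), sort(paste0(sp$tip.label, "|1")))
  gt2 <- gt
  gt2$tip.label <- taxon_from_id(gt$tip.label)
  expect_equal(phangorn::RF.dist(ape::unroot(gt2), ape::unroot(sp)), 0)
  expect_true(all(attr(gt, "leaf_truth")$original))
  expect_equal(attr(gt, "n_duplications"), 0L)
})

test_that("loss-only processes only remove taxa", {
  sp <- simulate_species_tree(10, 1, seed = 3)
  seen_absent <- FALSE
  for (s in 1:20) {
    gt <- simulate_gene_tree(sp, 0, 1.2, seed = s)
    if (is.null(gt)) { seen_absent <- TRUE; next }
    taxa <- taxon_from_id(gt$tip.label)
    expect_lte(max(table(taxa)), 1)
    if (length(taxa) < 10) seen_absent <- TRUE
  }
  expect_true(seen_absent)
})

test_that("copy numbers match a Monte-Carlo birth-death oracle", {
  # linear birth-death from one copy along each unit root-to-tip path;
  # loci whose total copy count falls below 2 yield no gene tree, so the
  # oracle applies the same conditioning
  sp <- simulate_species_tree(2, 1, seed = 1)  # two tips, both at depth 1
  for (rates in list(c(0.3, 0.3), c(0.6, 0.2))) {
    totals <- vapply(1:600, function(s) {
      gt <- simulate_gene_tree(sp, rates[1], rates[2], seed = 7000 + s)
      if (is.null(gt)) return(NA_real_)
      length(gt$tip.label)
    }, numeric(1))
    totals <- totals[!is.na(totals)]
    set.seed(99)
    o1 <- oracle_bd_counts(rates[1], rates[2], 1, n = 4000)
    o2 <- oracle_bd_counts(rates[1], rates[2], 1, n = 4000)
    otot <- (o1 + o2)[o1 + o2 >= 2]
    se <- sqrt(stats::var(totals) / length(totals) +
                 stats::var(otot) / length(otot))
    expect_lt(abs(mean(totals) - mean(otot)), 3 * se)
    # unconditional sanity: e^(d - l) expected copies per tip
    expect_lt(abs(mean(c(o1, o2)) - exp(rates[1] - rates[2])),
              3 * stats::sd(c(o1, o2)) / sqrt(8000))
  }
})

test_that("gene trees are deterministic per seed and carry truth", {
  sp <- simulate_species_tree(6, 1, seed = 2)
  g1 <- simulate_gene_tree(sp, 0.4, 0.3, seed = 77)
  g2 <- simulate_gene_tree(sp, 0.4, 0.3, seed = 77)
  expect_identical(ape::write.tree(g1), ape::write.tree(g2))
  truth <- attr(g1, "leaf_truth")
  expect_setequal(truth$seq_id, g1$tip.label)
  # at most one original copy per taxon
  orig <- truth[truth$original, ]
  expect_lte(max(table(orig$taxon)), 1)
})

test_that("NNI noise assigns sub-unit supports only to disturbed edges", {
  sp <- simulate_species_tree(8, 1, seed = 4)
  gt <- simulate_gene_tree(sp, 0, 0, seed = 5, nni_moves = 2)
  sup <- suppressWarnings(as.numeric(gt$node.label))
  expect_true(any(!is.na(sup) & sup < 1))
  gt0 <- simulate_gene_tree(sp, 0, 0, seed = 5)
  expect_true(all(as.numeric(gt0$node.label[-1]) == 1))
})

test_that("compositional bias raises RCFV", {
  sp <- simulate_species_tree(8, 1, seed = 6)
  model <- aa_model("Poisson")
  gt <- simulate_gene_tree(sp, 0, 0, seed = 1)
  wins <- 0
  for (s in 1:30) {
    og0 <- simulate_biased_alignment(gt, model, 200, seed = 100 + s)
    og1 <- simulate_biased_alignment(gt, model, 200, seed = 100 + s,
                                     biased_taxa = c("t01", "t02", "t03"),
                                     bias_intensity = 0.5)
    if (rcfv(og1) > rcfv(og0)) wins <- wins + 1
  }
  expect_gte(wins, 28)
})

test_that("rate multipliers make long branches", {
  sp <- simulate_species_tree(6, 1, seed = 8)
  gt <- simulate_gene_tree(sp, 0, 0, seed = 2)
  m <- aa_model("Poisson")
  og <- simulate_biased_alignment(gt, m, 400, seed = 9,
                                  rate_multipliers = c(t01 = 6))
  d <- estimate_distances(og, m)
  mean_d <- rowMeans(d)
  expect_equal(taxon_from_id(names(which.max(mean_d))), "t01")
})

test_that("occupancy masks are seeded and calibrated", {
  ogs <- lapply(1:400, function(i) {
    taxa <- sprintf("t%02d", 1:20)
    orthogroup(sprintf("L%03d", i), taxa, paste0(taxa, "|1"),
               rep("MKLV", 20))
  })
  m1 <- apply_occupancy_mask(ogs, 1, 1, seed = 13)
  m2 <- apply_occupancy_mask(ogs, 1, 1, seed = 13)
  expect_identical(m1$mask, m2$mask)
  # alpha = beta = 1: mean per-taxon occupancy 0.5 within 3 se (mixture of
  # Bernoulli(p), p uniform, has variance 1/4)
  occ <- mean(m1$mask$retained)
  se <- sqrt(0.25 / nrow(m1$mask))
  expect_lt(abs(occ - 0.5), 3 * se)
  # alpha >> beta retains everything
  m3 <- apply_occupancy_mask(ogs[1:50], 1e6, 1, seed = 5)
  expect_true(all(m3$mask$retained))
  expect_length(m3$orthogroups, 50)
})

test_that("generated datasets are conserved and reproducible", {
  cfg <- synthetic_config(n_taxa = 10, n_loci = 25,
                          locus_length_range = c(30, 60),
                          duplication_rate = 0.3, loss_rate = 0.3,
                          long_branch_taxa = "t01",
                          biased_taxa = c("t02", "t03"),
                          biased_loci_fraction = 0.2, seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- generate_dataset(cfg, dir = d1)
  r2 <- generate_dataset(cfg, dir = d2)
  # byte-identical outputs across runs
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  # locus accounting: kept + dropped = configured count
  expect_equal(nrow(r1$truth$loci), 25)
  expect_equal(sum(r1$truth$loci$status == "kept"),
               length(r1$orthogroups))
  # every emitted sequence maps to exactly one gene-tree leaf
  for (i in seq_along(r1$orthogroups)) {
    og <- r1$orthogroups[[i]]
    leaves <- r1$truth$leaves
    lt <- leaves[leaves$locus_id == og$locus_id, ]
    expect_true(all(og$seq_id %in% lt$seq_id))
    expect_equal(anyDuplicated(lt$seq_id), 0)
    expect_setequal(og$seq_id, r1$gene_trees[[i]]$tip.label)
  }
  # flags cover all loci
  expect_false(any(is.na(r1$truth$loci$biased)))
})

test_that("the long-branch taxon has the largest mean LB score", {
  cfg <- synthetic_config(n_taxa = 8, n_loci = 12,
                          locus_length_range = c(150, 200),
                          duplication_rate = 0, loss_rate = 0,
                          long_branch_taxa = "t05",
                          long_branch_multiplier = 6,
                          biased_loci_fraction = 0,
                          occupancy_alpha = 1e6, occupancy_beta = 1,
                          seed = 11)
  ds <- generate_dataset(cfg)
  m <- aa_model(cfg$model)
  lb_by_taxon <- list()
  for (i in seq_along(ds$orthogroups)) {
    og <- ds$orthogroups[[i]]
    fit <- ml_search(og, m)
    tr <- fit$tree
    tr$tip.label <- taxon_from_id(tr$tip.label)
    lb <- lb_scores(tr)
    lb_by_taxon[[i]] <- lb
  }
  mean_lb <- tapply(unlist(lb_by_taxon),
                    names(unlist(lb_by_taxon)), mean)
  expect_equal(names(which.max(mean_lb)), "t05")
})
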