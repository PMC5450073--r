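test_that("patristic distances follow the branch-length paths", {
  two <- ape::read.tree(text = "(A:0.1,B:0.2);")
  expect_equal(patristic_distances(two)["A", "B"], 0.3)
  star <- star_tree(LETTERS[1:5], b = 0.4)
  pd <- patristic_distances(star)
  expect_true(all(abs(pd[upper.tri(pd)] - 0.8) < 1e-12))
  set.seed(77)
  for (rep in 1:15) {
    tr <- ape::rtree(10)
    expect_equal(patristic_distances(tr),
                 oracle_patristic(tr)[tr$tip.label, tr$tip.label],
                 tolerance = 1e-12)
  }
})

test_that("LB scores are centred on zero and flag long branches", {
  star <- star_tree(LETTERS[1:6], b = 1)
  expect_true(all(abs(lb_scores(star)) < 1e-12))
  set.seed(5)
  for (rep in 1:20) {
    tr <- ape::rtree(sample(4:12, 1))
    expect_lt(abs(mean(lb_scores(tr))), 1e-9)
  }
  # one terminal branch 10x longer: that taxon maximises LB, and the value
  # matches direct arithmetic on the distance matrix
  tr <- ape::read.tree(text = "((A:1,B:1):0.5,(C:1,D:10):0.5);")
  lb <- lb_scores(tr)
  expect_equal(names(which.max(lb)), "D")
  pd <- patristic_distances(tr)
  mean_i <- rowSums(pd) / (nrow(pd) - 1)
  expect_equal(unname(lb["D"]),
               100 * (mean_i[["D"]] / mean(mean_i) - 1), tolerance = 1e-12)
  expect_error(lb_scores(star_tree(LETTERS[1:4], b = 0)), "undefined")
})

test_that("tip-to-root spread is zero for clocklike trees, sqrt(2) for the
           worked two-leaf case", {
  ultra <- ape::rcoal(8)
  expect_lt(tip_to_root_sd(ultra), 1e-10)
  two <- ape::read.tree(text = "(A:1,B:3);")  # rooted, depths 1 and 3
  expect_equal(tip_to_root_sd(two), sqrt(2), tolerance = 1e-12)
  # midpoint rooting applies to unrooted input; path-enumeration oracle
  set.seed(12)
  for (rep in 1:10) {
    tr <- ape::unroot(ape::rtree(7))
    rooted <- phangorn::midpoint(tr)
    depths <- oracle_patristic_depths(rooted)
    expect_equal(tip_to_root_sd(tr), stats::sd(depths), tolerance = 1e-9)
  }
})

test_that("branch indices scale as they should", {
  tr <- ape::rtree(8)
  b <- locus_branch_indices(tr)
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 3
  b2 <- locus_branch_indices(tr2)
  expect_equal(b2$avg_pd, 3 * b$avg_pd, tolerance = 1e-9)
  expect_equal(b2$tip_root_sd, 3 * b$tip_root_sd, tolerance = 1e-9)
  expect_equal(b2$lb_index, b$lb_index, tolerance = 1e-9)
  star <- star_tree(LETTERS[1:5], b = 0.7)
  bs <- locus_branch_indices(star)
  expect_equal(bs$avg_pd, 1.4, tolerance = 1e-12)
  expect_equal(bs$lb_index, 0, tolerance = 1e-12)
  expect_equal(bs$tip_root_sd, 0, tolerance = 1e-12)
})

test_that("the compositional chi-square reproduces the textbook example", {
  # 2 taxa x 2 states with counts [[30,10],[10,30]] -> X2 = 20, df 1
  og <- orthogroup("L", c("A", "B"), c("A|1", "B|1"),
                   c(paste(c(rep("K", 30), rep("L", 10)), collapse = ""),
                     paste(c(rep("K", 10), rep("L", 30)), collapse = "")))
  cs <- composition_chisq(og)
  expect_equal(cs$statistic, 20, tolerance = 1e-12)
  expect_equal(cs$df, 1L)
  expect_equal(cs$p_value, 7.7e-6, tolerance = 0.01)
  # cross-check against stats::chisq.test on the same table
  ref <- suppressWarnings(stats::chisq.test(
    rbind(c(30, 10), c(10, 30)), correct = FALSE))
  expect_equal(cs$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(cs$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("identical compositions give statistic 0 and p 1, and gapped
           taxa are dropped with a warning", {
  og <- orthogroup("L", c("A", "B", "C"), c("A|1", "B|1", "C|1"),
                   c("KKLL", "KLKL", "LLKK"))
  cs <- composition_chisq(og)
  expect_equal(cs$statistic, 0, tolerance = 1e-12)
  expect_equal(cs$p_value, 1)
  og2 <- orthogroup("L", c("A", "B", "C"), c("A|1", "B|1", "C|1"),
                    c("KKLL", "KLKL", "----"))
  expect_warning(composition_chisq(og2), "no countable")
})

test_that("RCFV matches hand computation and frequency invariances", {
  og0 <- orthogroup("L", c("A", "B"), c("A|1", "B|1"), c("KLKL", "LKKL"))
  expect_equal(rcfv(og0), 0, tolerance = 1e-12)  # identical compositions
  # two-state split (1,0) vs (0,1) -> RCFV = 1
  og1 <- orthogroup("L", c("A", "B"), c("A|1", "B|1"), c("KKKK", "LLLL"))
  expect_equal(rcfv(og1), 1, tolerance = 1e-12)
  # frequency-based: doubling sequence length changes nothing
  og2 <- orthogroup("L", c("A", "B"), c("A|1", "B|1"),
                    c("KKKKKKKK", "LLLLLLLL"))
  expect_equal(rcfv(og2), rcfv(og1), tolerance = 1e-12)
})

test_that("IQR flags follow the worked example and are translation
           equivariant", {
  v <- c(1, 2, 3, 4, 100)
  expect_equal(iqr_flags(v), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(iqr_flags(v + 57.3), iqr_flags(v))
  expect_true(all(iqr_flags(rep(2, 6))))  # degenerate all-equal case
  expect_error(iqr_flags(1:3), "at least 4")
  # boundary: a value exactly at median + 1.5 IQR is flagged ("equal to or
  # greater than")
  v3 <- c(1, 2, 3, 4, 6)    # median 3, IQR 2, cutoff 6
  expect_true(iqr_flags(v3)[5])
})

test_that("locus filtering is two-stage with survivor-based quantiles", {
  d <- tibble::tibble(
    locus_id = sprintf("L%02d", 1:12),
    avg_pd = c(1.0, 1.2, 0.8, 1.1, 0.9, 1.05, 0.95, 1.15, 0.85, 1.12,
               0.88, 8),               # L12 flagged at stage 1
    tip_root_sd = rep(0.2, 12),        # zero IQR: degenerate, no flags
    lb_index = rep(10, 12),
    rcfv = c(0.10, 0.12, 0.08, 0.11, 0.09, 0.105, 0.095, 0.115, 0.085,
             0.10, 2.0, 5.0),
    chisq_p = c(0.5, 0.9, 0.01, rep(0.6, 9)))
  class(d) <- c("locus_diagnostics", class(d))
  fl <- filter_loci(d, alpha = 0.05, multiplier = 1.5)
  rep_ <- fl$report
  expect_true(grepl("PD", rep_$eliminated_by[12]))
  expect_true(grepl("CHI2", rep_$eliminated_by[3]))
  expect_true(grepl("RCFV", rep_$eliminated_by[11]))
  # L12 is already gone at stage 1, so RCFV is not evaluated for it
  expect_false(grepl("RCFV", rep_$eliminated_by[12]))
  expect_setequal(fl$retained, sprintf("L%02d", c(1, 2, 4:10)))
  # stage-2 quantiles are computed on stage-1 survivors only: L11 clears
  # the cutoff that the survivor pool implies
  pool <- d$rcfv[!grepl("PD|TIPROOT|LB", rep_$eliminated_by)]
  q <- stats::quantile(pool, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  expect_true(d$rcfv[11] >= q[2] + 1.5 * (q[3] - q[1]))
  # with the whole-pool quantiles instead, the cutoff would be inflated by
  # L12's extreme value
  q_all <- stats::quantile(d$rcfv, c(0.25, 0.5, 0.75), type = 7,
                           names = FALSE)
  expect_gt(q_all[2] + 1.5 * (q_all[3] - q_all[1]),
            q[2] + 1.5 * (q[3] - q[1]))
})

test_that("vacuous thresholds retain everything", {
  set.seed(3)
  d <- tibble::tibble(
    locus_id = sprintf("L%d", 1:20),
    avg_pd = stats::runif(20), tip_root_sd = stats::runif(20),
    lb_index = stats::runif(20), rcfv = stats::runif(20),
    chisq_p = stats::runif(20))
  fl <- filter_loci(d, alpha = 0, multiplier = 1e9)
  expect_setequal(fl$retained, d$locus_id)
})

test_that("locus_diagnostics assembles one row per locus", {
  set.seed(8)
  ogs <- list(); trees <- list()
  for (i in 1:4) {
    tr <- ape::rtree(5)
    tr$tip.label <- paste0(LETTERS[1:5], "|1")
    og <- supermatrix::simulate_along_tree(tr, aa_model("Poisson"), 40,
                                           seed = i, locus_id = paste0("L", i))
    ogs[[i]] <- og; trees[[i]] <- tr
  }
  d <- locus_diagnostics(ogs, trees)
  expect_equal(nrow(d), 4)
  expect_true(all(d$chisq_p >= 0 & d$chisq_p <= 1))
  expect_true(all(d$rcfv >= 0))
  expect_s3_class(d, "locus_diagnostics")
})
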