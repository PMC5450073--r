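poisson_pair_lnl <- function(t, match) {
  # closed form for one site on a two-leaf tree of total length t under the
  # 20-state equal-rates model
  p_same <- 1 / 20 + (19 / 20) * exp(-20 * t / 19)
  if (match) log(p_same / 20) else log((1 - p_same) / 19 / 20)
}

test_that("two-taxon Poisson likelihood matches the closed form", {
  m <- aa_model("Poisson")
  og_same <- orthogroup("x", c("A", "B"), c("A", "B"), c("M", "M"))
  og_diff <- orthogroup("x", c("A", "B"), c("A", "B"), c("M", "K"))
  for (t in c(0.01, 0.05, 0.2, 0.5, 1, 2, 5)) {
    tr <- ape::read.tree(text = sprintf("(A:%f,B:%f);", t / 2, t / 2))
    expect_equal(log_likelihood(tr, og_same, m), poisson_pair_lnl(t, TRUE),
                 tolerance = 1e-8)
    expect_equal(log_likelihood(tr, og_diff, m), poisson_pair_lnl(t, FALSE),
                 tolerance = 1e-8)
  }
  # zero branch lengths, identical one-site sequences: ln(1/20)
  tr0 <- ape::read.tree(text = "(A:0,B:0);")
  expect_equal(log_likelihood(tr0, og_same, m), log(1 / 20),
               tolerance = 1e-10)
})

test_that("pattern compression is a pure refactoring", {
  set.seed(4)
  tr <- ape::rtree(6)
  og <- simulate_along_tree(tr, aa_model("WAG"), 120, seed = 9, delim = "@")
  for (nm in c("Poisson", "LG")) {
    m <- aa_model(nm, alpha = if (nm == "LG") 0.8 else NULL)
    expect_equal(log_likelihood(tr, og, m, compress = TRUE),
                 log_likelihood(tr, og, m, compress = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("likelihoods agree with an independent implementation", {
  set.seed(21)
  for (rep in 1:5) {
    tr <- ape::rtree(sample(4:8, 1))
    og <- simulate_along_tree(tr, aa_model("LG"), 60, seed = rep,
                              delim = "@")
    x <- og$mat
    rownames(x) <- og$taxon
    pd <- phangorn::phyDat(x, type = "AA")
    expect_equal(log_likelihood(tr, og, aa_model("WAG")),
                 phangorn::pml(tr, pd, model = "WAG")$logLik,
                 tolerance = 1e-6)
    expect_equal(log_likelihood(tr, og, aa_model("JTT", alpha = 0.5)),
                 phangorn::pml(tr, pd, model = "JTT", k = 4,
                               shape = 0.5)$logLik,
                 tolerance = 1e-6)
  }
})

test_that("gaps and ambiguity codes are fully ambiguous", {
  m <- aa_model("Poisson")
  tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
  og_gap <- orthogroup("x", c("A", "B"), c("A", "B"), c("-", "X"))
  # all-ambiguous site contributes sum(pi) = 1 -> lnL 0
  expect_equal(log_likelihood(tr, og_gap, m), 0, tolerance = 1e-10)
})

test_that("ML distances invert the Poisson mismatch fraction", {
  m <- aa_model("Poisson")
  set.seed(2)
  aa <- sample(supermatrix:::AA_STATES, 400, replace = TRUE)
  for (n_mis in c(0, 40, 120, 240)) {
    bb <- aa
    if (n_mis > 0) {
      idx <- seq_len(n_mis)
      bb[idx] <- vapply(aa[idx], function(s)
        sample(setdiff(supermatrix:::AA_STATES, s), 1), character(1))
    }
    og <- orthogroup("x", c("A", "B"), c("A", "B"),
                     c(paste(aa, collapse = ""), paste(bb, collapse = "")))
    d <- estimate_distances(og, m)
    p <- n_mis / 400
    want <- if (p == 0) 0 else -(19 / 20) * log(1 - 20 * p / 19)
    expect_equal(d["A", "B"], want, tolerance = 1e-6)
    expect_equal(d["B", "A"], d["A", "B"])
    expect_equal(diag(d), c(A = 0, B = 0))
  }
})

test_that("pairs with no shared sites are capped with a warning", {
  og <- orthogroup("x", c("A", "B"), c("A", "B"), c("MK--", "--KL"))
  expect_warning(d <- estimate_distances(og, aa_model("Poisson"),
                                         max_dist = 7), "capped")
  expect_equal(d["A", "B"], 7)
})

test_that("neighbour joining recovers additive trees exactly", {
  set.seed(6)
  for (rep in 1:10) {
    tr <- ape::unroot(ape::rtree(5))
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
    d <- patristic_distances(tr)
    nj <- nj_tree(d)
    expect_equal(phangorn::RF.dist(nj, tr), 0)
    expect_equal(patristic_distances(nj)[rownames(d), colnames(d)], d,
                 tolerance = 1e-9)
    # order invariance
    perm <- sample(nrow(d))
    nj2 <- nj_tree(d[perm, perm])
    expect_equal(phangorn::RF.dist(nj2, nj), 0)
  }
  expect_equal(length(nj_tree(patristic_distances(
    star_tree(c("A", "B", "C"))))$tip.label), 3)
})

test_that("branch-length optimisation is monotone and consistent", {
  m <- aa_model("Poisson")
  tru <- ape::read.tree(
    text = "((A:0.15,B:0.3):0.1,(C:0.2,D:0.45):0.12,(E:0.25,F:0.1):0.3);")
  og <- simulate_along_tree(tru, m, 10000, seed = 31, delim = "@")
  start <- tru
  start$edge.length <- rep(0.5, nrow(tru$edge))
  fit <- optimize_branch_lengths(start, og, m)
  expect_true(all(diff(attr(fit, "trace")) >= 0))
  # recovered lengths within 10% of truth (long simulation)
  ref <- patristic_distances(tru)
  est <- patristic_distances(fit)[rownames(ref), colnames(ref)]
  expect_true(all(abs(est - ref)[upper.tri(ref)] / ref[upper.tri(ref)]
                  < 0.1))
  # restarting at the optimum changes nothing measurable
  fit2 <- optimize_branch_lengths(fit, og, m)
  expect_equal(attr(fit2, "loglik"), attr(fit, "loglik"), tolerance = 1e-6)
})

test_that("NNI neighbours match phangorn's move set", {
  set.seed(14)
  for (n in c(4, 5, 7)) {
    tr <- ape::unroot(ape::rtree(n))
    mine <- nni_neighbors(tr)
    ref <- phangorn::nni(tr)
    expect_length(mine, length(ref))
    # identical sets of unrooted topologies
    key <- function(t) paste(sort(ape::write.tree(
      ape::ladderize(ape::root(t, 1, resolve.root = TRUE)))), collapse = "")
    d <- outer(seq_along(mine), seq_along(ref), Vectorize(function(i, j)
      phangorn::RF.dist(mine[[i]], ref[[j]])))
    expect_true(all(apply(d == 0, 1, any)))
    # branch lengths carried over: same multiset
    for (nb in mine)
      expect_equal(sort(nb$edge.length), sort(tr$edge.length))
  }
})

test_that("tree search recovers the generating topology and respects
           constraints", {
  m <- aa_model("Poisson")
  tru <- ape::read.tree(
    text = "((A:0.2,B:0.2):0.15,(C:0.2,D:0.2):0.15,(E:0.2,F:0.2):0.15);")
  og <- simulate_along_tree(tru, m, 2000, seed = 41, delim = "@")
  fit <- ml_search(og, m)
  expect_equal(phangorn::RF.dist(fit$tree, tru), 0)
  con <- ml_search(og, m, constraint = c("A", "C"))
  expect_true(is_monophyletic(con$tree, c("A", "C")))
  expect_gte(fit$loglik, con$loglik - 1e-6)  # nested hypotheses
  # a constraint satisfied by the truth costs nothing
  con2 <- ml_search(og, m, constraint = c("A", "B"))
  expect_lt(abs(con2$loglik - fit$loglik), 1e-3)
  expect_error(ml_search(og, m, constraint = c("A", "NOPE")), "missing")
})

test_that("model selection scores candidates in order", {
  set.seed(51)
  tr <- ape::rtree(8)
  og <- simulate_along_tree(tr, aa_model("WAG"), 800, seed = 3, delim = "@")
  sel <- select_model(og)
  expect_equal(sel$model, "WAG")
  expect_equal(nrow(sel$scores), 4)
  # single candidate; and ties broken by order (duplicate candidate)
  expect_equal(select_model(og, "LG")$model, "LG")
  expect_equal(select_model(og, c("JTT", "JTT"))$model, "JTT")
  expect_error(select_model(og, character(0)), "empty")
})

test_that("sequence simulation hits its analytic limits", {
  m <- aa_model("Poisson")
  # zero branch lengths: everyone equals the root draw
  tr0 <- star_tree(paste0(LETTERS[1:6], "|1"), b = 0)
  og0 <- simulate_along_tree(tr0, m, 50, seed = 8)
  expect_true(all(apply(og0$mat, 2, function(col)
    length(unique(col)) == 1)))
  # seeded determinism
  og0b <- simulate_along_tree(tr0, m, 50, seed = 8)
  expect_identical(og0$mat, og0b$mat)
  # saturation on a long-branch star: mean pairwise identity -> 1/20
  trs <- star_tree(paste0(LETTERS[1:8], "|1"), b = 30)
  ogs <- simulate_along_tree(trs, m, 3000, seed = 10)
  ids <- utils::combn(8, 2)
  pid <- mean(apply(ids, 2, function(ij)
    mean(ogs$mat[ij[1], ] == ogs$mat[ij[2], ])))
  se <- sqrt(0.05 * 0.95 / (3000 * ncol(ids)))
  expect_lt(abs(pid - 0.05), 4 * se)
  # equilibrium frequencies at saturation
  expect_lt(max(abs(table(factor(ogs$mat,
                                 levels = supermatrix:::AA_STATES)) /
                      length(ogs$mat) - 0.05)), 0.01)
})
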