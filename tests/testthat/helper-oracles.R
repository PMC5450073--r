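# Independent brute-force oracles and random-fixture builders used across
# the suite.  These deliberately avoid the package's own code paths:
# adjacency BFS instead of recursive descendant sets, per-cell censuses
# instead of vectorised column operations.

# adjacency list of a phylo
oracle_adjacency <- function(tree) {
  n <- max(tree$edge)
  adj <- vector("list", n)
  for (r in seq_len(nrow(tree$edge))) {
    a <- tree$edge[r, 1]; b <- tree$edge[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# nodes reachable from `start` without stepping onto `banned` (0 = none)
oracle_component <- function(adj, start, banned) {
  seen <- start
  queue <- start
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (u in adj[[v]]) {
      if (u != banned && !(u %in% seen)) {
        seen <- c(seen, u); queue <- c(queue, u)
      }
    }
  }
  seen
}

# patristic distance by explicit path enumeration (BFS parents)
oracle_patristic <- function(tree) {
  n <- length(tree$tip.label)
  adj <- oracle_adjacency(tree)
  elen <- matrix(NA_real_, max(tree$edge), max(tree$edge))
  for (r in seq_len(nrow(tree$edge))) {
    a <- tree$edge[r, 1]; b <- tree$edge[r, 2]
    elen[a, b] <- elen[b, a] <- tree$edge.length[r]
  }
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    # BFS distances from tip i
    dist <- rep(NA_real_, max(tree$edge))
    dist[i] <- 0
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) {
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + elen[v, u]
          queue <- c(queue, u)
        }
      }
    }
    d[i, ] <- dist[seq_len(n)]
  }
  d
}

# exhaustive search for the maximally inclusive one-per-taxon subtree,
# sharing only the *definition* with the implementation
oracle_max_subtree <- function(tree, taxon_map, residues = NULL) {
  nt <- length(tree$tip.label)
  adj <- oracle_adjacency(tree)
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
  if (is.null(residues))
    residues <- stats::setNames(rep(0, nt), tree$tip.label)

  leaves_of <- function(nodes) nodes[nodes <= nt]

  taxon_ok <- function(comp_nodes, cand_leaves, t, lt) {
    # polytomy: all of t's leaves share one neighbouring node
    pars <- vapply(lt, function(l) adj[[l]][1], numeric(1))
    if (length(unique(pars)) == 1) return(TRUE)
    # monophyly within the component: some edge separates exactly lt from
    # the rest of the component (the component's entry point outside it)
    for (r in seq_len(nrow(tree$edge))) {
      for (dir in 1:2) {
        a <- tree$edge[r, dir]; b <- tree$edge[r, 3 - dir]
        if (!(a %in% comp_nodes) || !(b %in% comp_nodes)) next
        side <- oracle_component(adj, b, a)
        if (setequal(leaves_of(side), lt)) return(TRUE)
      }
    }
    FALSE
  }

  valid <- function(start, banned) {
    comp <- oracle_component(adj, start, banned)
    lv <- leaves_of(comp)
    taxa <- unname(taxon_map[tree$tip.label[lv]])
    for (t in unique(taxa[duplicated(taxa)])) {
      lt <- lv[taxa == t]
      # restrict the component for the monophyly scan: nodes of comp only
      if (!taxon_ok(comp, lv, t, lt)) return(FALSE)
    }
    lv
  }

  cand <- list(c(root, 0L))
  for (r in seq_len(nrow(tree$edge))) {
    cand[[length(cand) + 1L]] <- c(tree$edge[r, 2], tree$edge[r, 1])
    cand[[length(cand) + 1L]] <- c(tree$edge[r, 1], tree$edge[r, 2])
  }
  best <- NULL
  best_key <- NULL
  for (cd in cand) {
    lv <- valid(cd[1], cd[2])
    if (isFALSE(lv)) next
    labs <- sort(tree$tip.label[lv])
    key <- list(length(lv),
                length(unique(unname(taxon_map[tree$tip.label[lv]]))),
                sum(residues[tree$tip.label[lv]]),
                paste(labs, collapse = "\r"))
    better <- FALSE
    if (is.null(best_key)) better <- TRUE
    else {
      for (i in 1:3) {
        if (key[[i]] != best_key[[i]]) {
          better <- key[[i]] > best_key[[i]]
          break
        }
      }
      if (!better && key[[1]] == best_key[[1]] &&
          key[[2]] == best_key[[2]] && key[[3]] == best_key[[3]])
        better <- key[[4]] < best_key[[4]]
    }
    if (better) { best <- labs; best_key <- key }
  }
  best
}

# Gillespie simulation of a linear birth-death process from one copy
oracle_bd_counts <- function(birth, death, t, n = 2000) {
  vapply(seq_len(n), function(i) {
    cnt <- 1L
    time <- 0
    repeat {
      if (cnt == 0L) return(0L)
      rate <- cnt * (birth + death)
      if (rate == 0) return(cnt)
      time <- time + stats::rexp(1, rate)
      if (time > t) return(cnt)
      if (stats::runif(1) < birth / (birth + death)) cnt <- cnt + 1L
      else cnt <- cnt - 1L
    }
  }, integer(1))
}

# root-to-tip distances by walking parent chains
oracle_patristic_depths <- function(rooted) {
  parent <- integer(max(rooted$edge))
  plen <- numeric(max(rooted$edge))
  for (r in seq_len(nrow(rooted$edge))) {
    parent[rooted$edge[r, 2]] <- rooted$edge[r, 1]
    plen[rooted$edge[r, 2]] <- rooted$edge.length[r]
  }
  root <- setdiff(unique(rooted$edge[, 1]), rooted$edge[, 2])
  vapply(seq_along(rooted$tip.label), function(i) {
    d <- 0
    while (i != root) {
      d <- d + plen[i]
      i <- parent[i]
    }
    d
  }, numeric(1))
}

# random gene tree with multiple copies per taxon and random supports
random_gene_tree <- function(n_taxa, max_copies = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  taxa <- LETTERS[seq_len(n_taxa)]
  copies <- sample.int(max_copies, n_taxa, replace = TRUE)
  labels <- unlist(lapply(seq_len(n_taxa), function(i)
    sprintf("%s|%d", taxa[i], seq_len(copies[i]))))
  if (length(labels) < 3) labels <- c(labels, "Z|1")
  tr <- ape::rtree(length(labels))
  tr$tip.label <- sample(labels)
  tr <- ape::unroot(tr)
  tr$node.label <- as.character(round(stats::runif(tr$Nnode), 3))
  tr$node.label[1] <- ""  # root has no support
  tr
}

# random orthogroup (aligned, possibly gappy)
random_orthogroup <- function(n_records = 6, len = 30, locus = "L",
                              gap_prob = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  taxa <- sample(LETTERS[1:max(2, ceiling(n_records / 2))], n_records,
                 replace = TRUE)
  ids <- sprintf("%s|%d", taxa, stats::ave(seq_len(n_records), taxa,
                                           FUN = seq_along))
  chars <- c(supermatrix:::AA_STATES, "-")
  probs <- c(rep((1 - gap_prob) / 20, 20), gap_prob)
  mat <- matrix(sample(chars, n_records * len, replace = TRUE, prob = probs),
                nrow = n_records)
  orthogroup(locus, taxa, ids, mat)
}

# star tree over given labels with equal branch lengths
star_tree <- function(labels, b = 1) {
  ape::read.tree(text = paste0(
    "(", paste(sprintf("%s:%f", labels, b), collapse = ","), ");"))
}
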