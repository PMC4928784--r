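test_that("W is the chi-squared style discrepancy", {
  p <- c(a = 0.5, b = 0.5)
  expect_equal(w_statistic(p, p), 0)
  expect_equal(w_statistic(c(a = 0.5, b = 0.5), c(a = 0.25, b = 0.75)),
               0.25 / 0.25 * 0.25 + 0.0625 / 0.75, tolerance = 1e-12)
  expect_error(w_statistic(c(a = 1, b = 0), c(a = 1, b = 0)), "zero")
})

test_that("reconstruction error is 0 for identical trees, 100 when disjoint", {
  tree <- chain_tree()
  expect_equal(reconstruction_error(tree, tree), 0)
  pan <- toy_panel()
  # generated tree shares no non-root pattern: all Jaccard overlaps vanish
  other <- progression_tree(rbind(c(2, 2, 2), c(3, 2, 2), c(4, 2, 2)),
                            c(NA, 1L, 2L), panel = pan)
  r <- reconstruction_error(tree, other)
  expect_gt(r, 85)
  expect_lte(r, 100)
})

test_that("reconstruction error matches a brute-force matching oracle", {
  set.seed(55)
  pan <- toy_panel()
  brute_match <- function(w) {
    # maximum-weight matching by enumeration over column subsets/permutations
    n <- nrow(w); m <- ncol(w)
    if (n > m) return(brute_match(t(w)))
    perms <- function(v) if (length(v) <= 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(r) c(v[i], r))))
    best <- 0
    for (cols in utils::combn(m, n, simplify = FALSE)) {
      for (pp in perms(cols)) best <- max(best, sum(w[cbind(1:n, pp)]))
    }
    best
  }
  for (rep in 1:10) {
    ta <- simulate_tree(uniform_frequencies(2L), sample(3:6, 1), pan)
    tb <- simulate_tree(uniform_frequencies(2L), sample(3:6, 1), pan)
    shared <- intersect(rownames(ta$states), rownames(tb$states))
    ps <- ploidytree:::bipartition_sets(ta, shared)
    pg <- ploidytree:::bipartition_sets(tb, shared)
    w <- matrix(0, length(ps), length(pg))
    for (i in seq_along(ps)) for (j in seq_along(pg)) {
      u <- length(union(ps[[i]], pg[[j]]))
      w[i, j] <- if (u == 0) 0 else length(intersect(ps[[i]], pg[[j]])) / u
    }
    m_opt <- brute_match(w)
    r_expected <- (1 - m_opt / (length(ps) + length(pg) - m_opt)) * 100
    expect_equal(reconstruction_error(ta, tb), r_expected, tolerance = 1e-9)
  }
})

test_that("a chain with swapped tails has the expected bipartition error", {
  pan <- toy_panel()
  chain <- progression_tree(
    rbind(c(2, 2, 2), c(2, 3, 2), c(2, 3, 3), c(2, 4, 3)),
    c(NA, 1L, 2L, 3L), panel = pan)
  swapped <- progression_tree(
    rbind(c(2, 2, 2), c(2, 3, 2), c(2, 3, 3), c(2, 4, 3)),
    c(NA, 1L, 2L, 2L), panel = pan)
  # splits: chain {234}|{34}|{4} vs swapped {234}|{3}|{4}; middle pair
  # overlaps at Jaccard 1/2; M = 1 + 1 + 1/2
  r <- reconstruction_error(chain, swapped)
  m <- 2.5
  expect_equal(r, (1 - m / (6 - m)) * 100, tolerance = 1e-9)
})

test_that("tree weight sums -log p over decomposed edge events", {
  pan <- toy_panel()
  tree <- chain_tree()
  f1 <- ploidytree:::normalize_tally(c("0,0,1" = 1), 2L, floor = 0)
  expect_equal(tree_weight(tree, f1), 0)
  fe <- stats::setNames(rep(0, 8), rownames(event_types(2L)))
  fe["0,0,1"] <- exp(-1); fe["0,1,0"] <- 1 - exp(-1)
  expect_equal(tree_weight(tree, fe), 2)
  expect_equal(avg_edge_weight(tree, fe), 1)
  expect_equal(tree_weight(tree), avg_edge_weight(tree) * 2, tolerance = 1e-12)
  bad <- fe; bad["0,0,1"] <- 0
  expect_error(tree_weight(tree, bad), "zero-probability")
  expect_error(avg_edge_weight(root_only_tree(pan)), "no edges")
})

test_that("expected depth weights node depth by cell fraction", {
  pan <- toy_panel()
  tree <- chain_tree(ncells = c(60, 0, 0))
  expect_equal(expected_depth(tree), 0)
  tree2 <- chain_tree(ncells = c(30, 30, 0))
  expect_equal(expected_depth(tree2), 0.5)
  tree3 <- chain_tree(ncells = c(10, 20, 30))
  expect_equal(expected_depth(tree3), 4 / 3)
  ds <- fish_data(rbind(c(2, 2, 2), c(2, 2, 4)), c(1, 1), pan)
  expect_equal(expected_depth(chain_tree(), ds), 1)
  ds_bad <- fish_data(matrix(c(2, 9, 9), 1), 1, pan)
  expect_error(expected_depth(chain_tree(), ds_bad), "missing from the tree")
})

test_that("entropy and Simpson index take their closed-form values", {
  u8 <- rep(1 / 8, 8)
  expect_equal(shannon_entropy(u8), log(8))
  expect_equal(simpson_index(u8), 0.125)
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(simpson_index(c(1, 0, 0)), 1)
  p <- c(0.5, 0.25, 0.25)
  expect_equal(shannon_entropy(p), -sum(p * log(p)))
  expect_equal(simpson_index(p), 0.375)
  # opposite movement under concentration
  spread <- rep(1 / 4, 4); conc <- c(0.7, 0.1, 0.1, 0.1)
  expect_gt(shannon_entropy(spread), shannon_entropy(conc))
  expect_lt(simpson_index(spread), simpson_index(conc))
})

test_that("coverage and Steiner fraction count nodes as defined", {
  pan <- toy_panel()
  tree <- chain_tree()
  ds <- fish_data(rbind(c(2, 2, 2), c(2, 2, 3)), c(5, 5), pan)
  expect_equal(coverage(tree, ds), 1)
  ds4 <- fish_data(rbind(c(2, 2, 2), c(3, 3, 3), c(4, 4, 4), c(5, 5, 5)),
                   c(1, 1, 1, 1), pan)
  expect_equal(coverage(root_only_tree(pan), ds4), 0.25)
  tr <- simulate_tree(uniform_frequencies(2L), 10L, pan)
  tr$steiner[c(3, 7)] <- TRUE
  expect_equal(steiner_fraction(tr), 0.2)
})

test_that("bootstrap state retention matches its closed-form expectation", {
  pan <- toy_panel()
  one <- fish_data(matrix(c(2, 2, 2), 1), 50, pan)
  expect_equal(state_retention_bootstrap(one, 10L), 1)

  set.seed(88)
  n_pat <- 10L
  pats <- cbind(2L, seq_len(n_pat) - 1L, 2L)
  ds <- fish_data(pats, rep(1L, n_pat), pan)
  got <- state_retention_bootstrap(ds, 400L)
  expected <- 1 - (1 - 1 / n_pat)^n_pat
  expect_equal(got, expected, tolerance = 0.03)

  set.seed(5); a <- state_retention_bootstrap(ds, 50L)
  set.seed(5); b <- state_retention_bootstrap(ds, 50L)
  expect_identical(a, b)
})
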