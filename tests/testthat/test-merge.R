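test_that("merge problems carry normalized joint frequencies and weights", {
  pan <- toy_panel()
  panA <- probe_panel("cep", "gA"); panB <- probe_panel("cep", "gB")
  rootA <- root_only_tree(panA, freqs = uniform_frequencies(1L))
  rootB <- root_only_tree(panB, freqs = uniform_frequencies(1L))

  ds <- fish_data(matrix(c(2, 2, 2), 1), 10, pan)
  pr <- build_merge_problem(rootA, rootB, ds)
  expect_equal(pr$p, matrix(1, 1, 1))
  expect_equal(pr$wA, 0)

  ds2 <- fish_data(rbind(c(2, 2, 2), c(2, 3, 2)), c(60, 40), pan)
  ta <- progression_tree(rbind(c(2, 2), c(2, 3)), c(NA, 1L), panel = panA,
                         ncells = c(60, 40), freqs = uniform_frequencies(1L))
  pr2 <- build_merge_problem(ta, rootB, ds2)
  expect_setequal(as.vector(pr2$p), c(0.6, 0.4))
  expect_equal(pr2$wA[2], log(6), tolerance = 1e-12)

  # a joint pattern whose marginal is missing from a tree is a contract error
  ds3 <- fish_data(rbind(c(2, 2, 2), c(2, 4, 2)), c(1, 1), pan)
  expect_error(build_merge_problem(ta, rootB, ds3), "absent")
})

test_that("p row and column marginals equal the trees' observed frequencies", {
  set.seed(71)
  for (rep in 1:8) {
    pan <- toy_panel()
    tr <- simulate_tree(uniform_frequencies(2L), 8L, pan)
    ds <- simulate_cells(tr, 100L)
    ta <- fit_gene_tree(ds, "gA", ploidytree_control(restarts = 1))
    tb <- fit_gene_tree(ds, "gB", ploidytree_control(restarts = 1))
    pr <- build_merge_problem(ta, tb, ds)
    dsa <- marginalize(ds, c("cep", "gA"))
    fa <- stats::setNames(rep(0, pr$m), rownames(ta$states))
    fa[rownames(dsa$patterns)] <- dsa$counts / sum(dsa$counts)
    expect_equal(unname(rowSums(pr$p)), unname(fa), tolerance = 1e-9)
    dsb <- marginalize(ds, c("cep", "gB"))
    fb <- stats::setNames(rep(0, pr$n), rownames(tb$states))
    fb[rownames(dsb$patterns)] <- dsb$counts / sum(dsb$counts)
    expect_equal(unname(colSums(pr$p)), unname(fb), tolerance = 1e-9)
  }
})

test_that("merging two root-only trees yields the root-only joint tree", {
  pan <- toy_panel()
  rootA <- root_only_tree(probe_panel("cep", "gA"), freqs = uniform_frequencies(1L))
  rootB <- root_only_tree(probe_panel("cep", "gB"), freqs = uniform_frequencies(1L))
  ds <- fish_data(matrix(c(2, 2, 2), 1), 10, pan)
  res <- solve_merge(build_merge_problem(rootA, rootB, ds))
  expect_equal(nrow(res$tree$states), 1L)
  expect_equal(res$solution$objective, 0, tolerance = 1e-9)
  expect_equal(res$solution$c[1, 1], 1)
})

test_that("a concerted-gain pair merges through a single c edge", {
  pan <- toy_panel()
  panA <- probe_panel("cep", "gA"); panB <- probe_panel("cep", "gB")
  fa <- ploidytree:::normalize_tally(c("1,1" = 1), 1L)
  ta <- progression_tree(rbind(c(2, 2), c(3, 3)), c(NA, 1L), panel = panA,
                         ncells = c(5, 5), freqs = fa)
  tb <- progression_tree(rbind(c(2, 2), c(3, 3)), c(NA, 1L), panel = panB,
                         ncells = c(5, 5), freqs = fa)
  ds <- fish_data(rbind(c(2, 2, 2), c(3, 3, 3)), c(5, 5), pan)
  pr <- build_merge_problem(ta, tb, ds)
  res <- solve_merge(pr)
  expect_equal(nrow(res$tree$states), 2L)
  expect_equal(rownames(res$tree$states), c("2,2,2", "3,3,3"))
  expect_equal(res$solution$c[2, 2], 1)
  expect_equal(sum(res$solution$a) + sum(res$solution$b), 0)
  expect_equal(merge_oracle(pr), res$solution$objective, tolerance = 1e-6)
})

test_that("a single-gene change merges through an a edge at cost wA", {
  pan <- toy_panel()
  panA <- probe_panel("cep", "gA"); panB <- probe_panel("cep", "gB")
  fa <- ploidytree:::normalize_tally(c("0,1" = 1), 1L)
  ta <- progression_tree(rbind(c(2, 2), c(2, 3)), c(NA, 1L), panel = panA,
                         ncells = c(5, 5), freqs = fa)
  tb <- root_only_tree(panB, ncells = 10, freqs = uniform_frequencies(1L))
  ds <- fish_data(rbind(c(2, 2, 2), c(2, 3, 2)), c(5, 5), pan)
  pr <- build_merge_problem(ta, tb, ds)
  res <- solve_merge(pr)
  expect_equal(res$solution$a[2, 1], 1)
  expect_equal(res$solution$objective, pr$wA[2], tolerance = 1e-6)
  expect_equal(merge_oracle(pr), res$solution$objective, tolerance = 1e-6)
})

test_that("the solver attains the exhaustive-enumeration optimum", {
  set.seed(501)
  problems <- replicate(25, random_merge_problem(3L), simplify = FALSE)
  results <- solve_merge_batch(problems)
  for (k in seq_along(problems)) {
    expect_equal(results[[k]]$solution$objective, merge_oracle(problems[[k]]),
                 tolerance = 1e-5)
  }
})

test_that("solutions satisfy every program constraint and the tree property", {
  set.seed(502)
  problems <- replicate(10, random_merge_problem(3L), simplify = FALSE)
  results <- solve_merge_batch(problems)
  for (k in seq_along(problems)) {
    sol <- results[[k]]$solution
    pr <- problems[[k]]
    # check_merge_solution already ran inside solve_merge; assert key
    # invariants independently here
    expect_true(all(sol$a + sol$b + sol$c <= 1))
    expect_equal(sol$c[1, 1], 1)
    expect_equal(unname(rowSums(sol$q)), unname(rowSums(pr$p)), tolerance = 1e-6)
    expect_equal(unname(colSums(sol$q)), unname(colSums(pr$p)), tolerance = 1e-6)
    expect_silent(ploidytree:::validate_tree(results[[k]]$tree))
    # recomputed objective agrees with the solver's
    expect_equal(ploidytree:::merge_objective(sol, pr), sol$objective,
                 tolerance = 1e-5)
  }
})

test_that("merged trees cover the observed joint patterns of their input", {
  set.seed(61)
  pan <- toy_panel()
  for (rep in 1:5) {
    tr <- simulate_tree(validation_rates()$profile1, 12L, pan)
    ds <- simulate_cells(tr, 150L)
    fit <- ploidytree(ds)
    expect_equal(coverage(fit$tree, ds), 1.0)
  }
})

test_that("merge_all folds left and preserves validity across orders", {
  set.seed(62)
  pan3 <- probe_panel("cep", c("g1", "g2", "g3"))
  rates3 <- ploidytree:::normalize_tally(
    c("0,0,0,1" = 0.4, "0,1,0,0" = 0.2, "0,0,1,0" = 0.2, "1,1,1,1" = 0.2), 3L)
  tr <- simulate_tree(rates3, 10L, pan3)
  ds <- simulate_cells(tr, 200L)
  gts <- lapply(pan3$genes, function(g) fit_gene_tree(ds, g))
  m12 <- merge_all(gts[1:2], ds)
  direct <- solve_merge(build_merge_problem(gts[[1]], gts[[2]], ds))$tree
  expect_equal(m12$states, direct$states)

  for (ord in list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))) {
    m <- merge_all(gts[ord], ds)
    expect_silent(ploidytree:::validate_tree(m))
    # every observed joint pattern appears (in the fold's probe order)
    remapped <- apply(ds$patterns[, c("cep", pan3$genes[ord])], 1,
                      paste, collapse = ",")
    expect_true(all(remapped %in% rownames(m$states)))
  }

  expect_error(merge_all(list(gts[[1]], gts[[1]]), ds), "disjoint")
})
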