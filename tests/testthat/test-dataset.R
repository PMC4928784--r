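test_that("per-cell rows are aggregated into patterns", {
  path <- write_tsv_fixture(rep("2\t2\t2", 3), "cep\tgA\tgB")
  ds <- read_fish_data(path)
  expect_equal(nrow(ds$patterns), 1L)
  expect_equal(ds$counts, 3L)
  expect_equal(unname(ds$patterns[1, ]), c(2L, 2L, 2L))

  path2 <- write_tsv_fixture(c("2\t2\t2", "2\t2\t2", "2\t3\t2"), "cep\tgA\tgB")
  ds2 <- read_fish_data(path2)
  expect_equal(nrow(ds2$patterns), 2L)
  expect_equal(sum(ds2$counts), 3L)
})

test_that("pattern+count dialect is detected from the trailing count column", {
  path <- write_tsv_fixture("2\t3\t4\t2\t2\t17",
                            "cep\tLAMP3\tPROX1\tPRKAA1\tCCND1\tcount")
  ds <- read_fish_data(path)
  expect_equal(nrow(ds$patterns), 1L)
  expect_equal(ds$counts, 17L)
  expect_equal(unname(ds$patterns[1, ]), c(2L, 3L, 4L, 2L, 2L))
})

test_that("malformed input is rejected with informative errors", {
  p1 <- write_tsv_fixture(c("2\t2\t2", "2\tx\t2"), "cep\tgA\tgB")
  expect_error(read_fish_data(p1), "line 3")
  p2 <- write_tsv_fixture("2\t12\t2", "cep\tgA\tgB")
  expect_error(read_fish_data(p2), "range error")
  p3 <- write_tsv_fixture(character(0), "cep\tgA\tgB")
  expect_error(read_fish_data(p3), "empty dataset")
  # ploidy zero is an input error unless explicitly permitted
  p4 <- write_tsv_fixture("0\t2\t2", "cep\tgA\tgB")
  expect_error(read_fish_data(p4))
  expect_silent(ds <- read_fish_data(p4, allow_zero_ploidy = TRUE))
  # clamping caps counts at max_copy instead of rejecting
  p5 <- write_tsv_fixture("2\t12\t2", "cep\tgA\tgB")
  ds5 <- read_fish_data(p5, clamp = TRUE)
  expect_equal(unname(ds5$patterns[1, ]), c(2L, 9L, 2L))
})

test_that("marginalize sums counts over dropped probes and conserves cells", {
  pan <- probe_panel("cep", c("LAMP3", "PROX1", "PRKAA1", "CCND1"))
  ds <- fish_data(matrix(c(2, 3, 4, 2, 2), 1), 10, pan)
  m <- marginalize(ds, c("cep", "PROX1"))
  expect_equal(unname(m$patterns[1, ]), c(2L, 4L))
  expect_equal(m$counts, 10L)

  pan2 <- toy_panel()
  ds2 <- fish_data(rbind(c(2, 2, 3), c(2, 4, 3)), c(5, 7), pan2)
  m2 <- marginalize(ds2, c("cep", "gB"))
  expect_equal(nrow(m2$patterns), 1L)
  expect_equal(m2$counts, 12L)

  full <- marginalize(ds2, probe_names(pan2))
  expect_equal(full$patterns, ds2$patterns)
  expect_equal(full$counts, ds2$counts)

  expect_error(marginalize(ds2, "gA"), "ploidy")
})

test_that("cell totals are conserved by marginalization of random data", {
  set.seed(101)
  pan <- probe_panel("cep", c("g1", "g2", "g3"))
  for (rep in 1:10) {
    pats <- unique(matrix(sample(0:9, 40, TRUE), 10, 4))
    pats[, 1] <- pmax(pats[, 1], 1L)
    pats <- unique(pats)
    ds <- fish_data(pats, sample(1:20, nrow(pats), TRUE), pan)
    for (genes in list("g1", c("g1", "g3"), c("g2", "g3"))) {
      m <- marginalize(ds, c("cep", genes))
      expect_equal(sum(m$counts), sum(ds$counts))
    }
  }
})

test_that("write/read round trip is the identity for both dialects", {
  set.seed(7)
  ds <- random_single_gene_data()
  path <- tempfile(fileext = ".tsv")
  write_fish_data(ds, path)
  back <- read_fish_data(path, panel = ds$panel)
  expect_equal(back$patterns, ds$patterns)
  expect_equal(back$counts, ds$counts)
  # per-cell dialect of the same data
  rows <- rep(apply(ds$patterns, 1, paste, collapse = "\t"), ds$counts)
  p2 <- write_tsv_fixture(rows, paste(colnames(ds$patterns), collapse = "\t"))
  back2 <- read_fish_data(p2, panel = ds$panel)
  expect_equal(back2$patterns, ds$patterns)
  expect_equal(back2$counts, ds$counts)
})

test_that("DOT output has one node per state, dashed Steiner, parseable edges", {
  pan <- toy_panel()
  root <- root_only_tree(pan)
  dot <- write_dot(root)
  expect_match(dot, "\"2,2,2\"")
  expect_false(grepl("->", dot))

  tree <- progression_tree(rbind(c(2, 2, 2), c(2, 2, 3), c(2, 2, 4)),
                           c(NA, 1L, 2L), steiner = c(FALSE, TRUE, FALSE),
                           ncells = c(5, 0, 5), panel = pan,
                           freqs = uniform_frequencies(2L))
  dot2 <- write_dot(tree)
  expect_equal(length(gregexpr("style=dashed", dot2)[[1]]), 1L)
  # node and edge sets can be parsed back from the DOT text
  lines <- strsplit(dot2, "\n")[[1]]
  nodes <- lines[grepl("\\[label", lines) & !grepl("->", lines)]
  expect_equal(length(nodes), 3L)
  edges <- lines[grepl("->", lines)]
  expect_equal(length(edges), 2L)
  expect_match(edges[1], '"2,2,2" -> "2,2,3"', fixed = TRUE)
})

test_that("JSON serialization round-trips trees losslessly and validates", {
  pan <- toy_panel()
  root <- root_only_tree(pan)
  expect_equal(deserialize_tree(serialize_tree(root))$states, root$states)

  set.seed(42)
  for (rep in 1:5) {
    tr <- simulate_tree(uniform_frequencies(2L), 10L, pan)
    back <- deserialize_tree(serialize_tree(tr))
    expect_equal(back$states, tr$states)
    expect_equal(back$parent, tr$parent)
    expect_equal(back$steiner, tr$steiner)
    expect_equal(back$ncells, tr$ncells)
    expect_equal(back$freqs, tr$freqs)
  }

  txt <- serialize_tree(chain_tree())
  tampered <- sub('"parent":"2,2,3"', '"parent":"9,9,9"', txt, fixed = TRUE)
  expect_error(deserialize_tree(tampered), "missing node")
  expect_error(deserialize_tree(sub("ploidytree/1", "ploidytree/99", txt)),
               "schema")
})
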