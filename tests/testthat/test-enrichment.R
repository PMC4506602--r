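test_that("fisher_enrichment matches exhaustive enumeration on a toy universe", {
  universe <- paste0("u", 1:4)
  ann <- annotation_collection(list(s = universe[1:2]), universe)
  row <- fisher_enrichment(universe[1:2], ann)   # overlap 2 of set size 2
  # all C(4,2)=6 equally likely draws; exactly one covers the whole set
  expect_equal(row$p_value, 1 / 6)
  expect_equal(row$p_value, enum_upper_tail(4, 2, 2, 2))

  full <- annotation_collection(list(all = universe), universe)
  r2 <- fisher_enrichment(universe[c(1, 3)], full)
  expect_equal(r2$overlap, 2)
  expect_equal(r2$p_value, 1)
})

test_that("fisher p equals the enumeration oracle across small universes", {
  set.seed(3)
  for (N in c(5, 8, 12)) {
    universe <- paste0("u", seq_len(N))
    for (K in c(2, floor(N / 2))) {
      for (n in c(2, min(5, N - 1))) {
        ann <- annotation_collection(list(s = universe[seq_len(K)]), universe)
        targets <- sample(universe, n)
        got <- fisher_enrichment(targets, ann)
        expect_equal(got$p_value, enum_upper_tail(N, K, n, got$overlap),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("targets outside the universe are dropped; empty targets give p = 1", {
  universe <- paste0("u", 1:10)
  ann <- annotation_collection(list(s = universe[1:3]), universe)
  expect_message(r <- fisher_enrichment(c("u1", "alien"), ann), "dropped")
  expect_equal(r$overlap, 1)
  r0 <- suppressMessages(fisher_enrichment(c("alien1", "alien2"), ann))
  expect_equal(r0$p_value, 1)
})

test_that("bh_adjust matches the hand-computed step-up", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  # hand step-up: sorted (.005,.03,.04,.8) * 4/rank = (.02,.06,.0533,.8),
  # cumulative min from the right = (.02,.0533,.0533,.8), back to input order
  p <- c(0.005, 0.04, 0.03, 0.8)
  expect_equal(bh_adjust(p), c(0.02, 0.04 * 4 / 3, 0.04 * 4 / 3, 0.8))
  expect_error(bh_adjust(c(0.5, 1.1)), "\\[0, 1\\]")
})

test_that("propagate handles degenerate and symmetric graphs", {
  g1 <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(g1)$name <- "a"
  expect_equal(unname(propagate(g1, "a", 0.3)), 1)

  g2 <- igraph::make_graph(~ a - b)
  s <- propagate(g2, c("a", "b"), 0.3)
  expect_equal(unname(s), c(0.5, 0.5))

  expect_error(propagate(g2, "zz", 0.3), "seed")
  expect_error(propagate(g2, "a", 1.5), "restart")
})

test_that("propagate matches a dense linear-system solve on a path graph", {
  g <- igraph::make_graph(~ n1 - n2, n2 - n3, n3 - n4, n4 - n5)
  for (r in c(0.15, 0.3, 0.7)) {
    got <- propagate(g, "n1", r)
    want <- rwr_dense_solve(g, "n1", r)
    expect_equal(got[names(want)], want, tolerance = 1e-8)
  }
})

test_that("propagation conserves unit score mass, including dangling nodes", {
  set.seed(9)
  g <- igraph::sample_pa(80, m = 2, directed = FALSE)
  igraph::V(g)$name <- paste0("P", 1:80)
  g <- igraph::add_vertices(g, 2, name = c("iso1", "iso2"))  # degree-0 nodes
  s <- propagate(g, c("P1", "P5", "iso1"), 0.3)
  expect_equal(sum(s), 1, tolerance = 1e-8)
  expect_true(all(s >= 0))
  s2 <- propagate(g, c("P1", "P5", "iso1"), 0.3)
  expect_identical(s, s2)  # deterministic
})

test_that("xd_scores are deviations from the across-set mean", {
  scores <- c(a = 0.3, b = 0.3, c = 0.1, d = 0.1)
  ann <- annotation_collection(list(s1 = c("a", "b"), s2 = c("c", "d")),
                               names(scores))
  xd <- xd_scores(scores, ann)
  expect_equal(xd$raw_score, c(0.3, 0.1))
  expect_equal(xd$xd_score, c(0.1, -0.1))
  expect_equal(mean(xd$xd_score), 0, tolerance = 1e-12)

  same <- annotation_collection(list(s1 = c("a", "c"), s2 = c("a", "c")),
                                names(scores))
  expect_true(all(xd_scores(scores, same)$xd_score == 0))
})

test_that("sets absent from the network get NA and are excluded from the mean", {
  scores <- c(a = 0.6, b = 0.4)
  ann <- annotation_collection(list(on = c("a", "b"), off = "zz"),
                               c("a", "b", "zz"))
  xd <- xd_scores(scores, ann)
  expect_true(is.na(xd$xd_score[xd$set_name == "off"]))
  expect_equal(xd$xd_score[xd$set_name == "on"], 0)  # only scored set
  expect_equal(mean(xd$xd_score, na.rm = TRUE), 0, tolerance = 1e-12)
})

test_that("threshold_filter reproduces the printed pathway and disease tables", {
  t3 <- utils::read.table(fixture("table3_pathways.tsv"), header = TRUE,
                          sep = "\t", quote = "\"")
  expect_equal(nrow(threshold_filter(t3, xd_min = 0.67)), 34)
  expect_equal(nrow(threshold_filter(t3, xd_min = 3.2)), 0)

  t5 <- utils::read.table(fixture("table5_diseases.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(threshold_filter(t5, p_max = 0.01)), 12)

  expect_error(threshold_filter(t3), "at least one")
})

test_that("threshold_filter is monotone in each criterion", {
  t3 <- utils::read.table(fixture("table3_pathways.tsv"), header = TRUE,
                          sep = "\t", quote = "\"")
  t3$p_value <- t3$q_value
  n_at <- function(x) nrow(threshold_filter(t3, xd_min = x))
  xs <- c(0, 0.5, 0.67, 1, 2, 4)
  expect_true(all(diff(vapply(xs, n_at, numeric(1))) <= 0))
  n_p <- function(p) nrow(threshold_filter(t3, p_max = p))
  ps <- c(0, 0.001, 0.01, 0.05, 1)
  expect_true(all(diff(vapply(ps, n_p, numeric(1))) >= 0))
})

test_that("GMT files round-trip and respect the universe", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg4"), path)
  ann <- read_gmt(path)
  expect_equal(lengths(ann$sets), c(setA = 3L, setB = 2L))
  expect_setequal(ann$universe, paste0("g", 1:4))

  ann2 <- read_gmt(path, universe = paste0("g", 1:3))
  expect_equal(ann2$sets$setB, "g2")  # members outside the universe trimmed

  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(ann, out)
  back <- read_gmt(out)
  expect_equal(back$sets, ann$sets)

  writeLines("lonely\tdesc", path)
  expect_error(read_gmt(path), "malformed")
})
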