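test_that("read_compound_table reads well-formed tables and flags bad ones", {
  cat3 <- make_catalog(data.frame(
    name = c("Alpha", "Beta", "Gamma"), herb = c("H1", "H1", "H2"),
    mw = c(100, 200, 300), alogp = c(1, 2, 3), hbd = 0:2, hba = 1:3,
    ob = c(40, 50, 60), dl = c(0.2, 0.3, 0.4)))
  expect_s3_class(cat3, "compound_catalog")
  expect_equal(nrow(cat3), 3)
  expect_equal(cat3$name, c("Alpha", "Beta", "Gamma"))  # row order preserved

  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(name = "x", mw = 1), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_compound_table(path), "herb")

  utils::write.table(data.frame(name = "x", herb = "H1", mw = "heavy"), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_compound_table(path), "non-numeric.*mw|mw.*row 1")
})

test_that("missing descriptor cells become explicit NA, never zero", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\therb\tmw\tob", "x\tH1\t\t40", "y\tH1\t120\t"), path)
  cat <- read_compound_table(path)
  expect_true(is.na(cat$mw[1]))
  expect_true(is.na(cat$ob[2]))
  expect_true(all(is.na(cat$dl)))
})

test_that("the printed bioactive-compound table loads as 63 records", {
  cat63 <- read_table2()
  expect_equal(nrow(cat63), 63)
  expect_equal(anyDuplicated(cat63$compound_id), 0)
  expect_equal(nrow(expand_herbs(cat63)), 66)  # three dual-herb compounds
})

test_that("merge_sources keeps every record and unions provenance on dedup", {
  sizes <- c(29, 44, 38, 56, 7, 29)  # one catalog per herb, single source
  cats <- lapply(seq_along(sizes), function(i)
    make_catalog(data.frame(name = sprintf("h%d_c%03d", i, seq_len(sizes[i])),
                            herb = paste0("H", i)),
                 source_tag = "dbA"))
  merged <- merge_sources(cats)
  expect_equal(nrow(merged), 203)

  dup <- make_catalog(data.frame(name = "Shared One", herb = "H1"), "dbA")
  dup2 <- make_catalog(data.frame(name = "shared-one", herb = "H2"), "dbB")
  both <- merge_sources(list(dup, dup2))
  expect_equal(nrow(both), 2)
  dd <- deduplicate(both)
  expect_equal(nrow(dd), 1)
  expect_setequal(strsplit(dd$sources, ";")[[1]], c("dbA", "dbB"))
  expect_setequal(strsplit(dd$herbs, ";")[[1]], c("H1", "H2"))

  expect_equal(nrow(merge_sources(list())), 0)
})

test_that("merge warns on conflicting descriptors and keeps first source", {
  a <- make_catalog(data.frame(name = "x", herb = "H1", mw = 100), "dbA")
  b <- make_catalog(data.frame(name = "x", herb = "H1", mw = 150), "dbB")
  expect_warning(m <- merge_sources(list(a, b)), "conflict")
  expect_equal(deduplicate(m)$mw, 100)  # input order is priority
  expect_silent(merge_sources(list(a, a)))
})

test_that("deduplicate is idempotent and collapses exact-name duplicates", {
  cat63 <- read_table2()
  hl <- expand_herbs(cat63)
  dd <- deduplicate(hl)
  expect_equal(nrow(dd), 63)
  expect_identical(as.data.frame(deduplicate(dd)), as.data.frame(dd))

  names10 <- c("a", "b", "c", "a", "d", "b", "e", "f", "c", "g")
  cat10 <- make_catalog(data.frame(name = names10, herb = "H1"))
  expect_equal(nrow(deduplicate(cat10)), length(unique(names10)))  # brute-force set
  expect_equal(nrow(deduplicate(cat10)), 7)
})

test_that("merge then deduplicate is order-independent", {
  set.seed(11)
  cats <- lapply(1:4, function(i)
    make_catalog(data.frame(
      name = sample(sprintf("cmp%02d", 1:25), 12),
      herb = sample(c("H1", "H2"), 12, replace = TRUE)),
      source_tag = paste0("db", i)))
  ref <- deduplicate(merge_sources(cats))
  key <- function(x) {
    df <- as.data.frame(x)[order(x$compound_id), c("compound_id", "herbs")]
    df$herbs <- vapply(strsplit(df$herbs, ";"),
                       function(h) paste(sort(h), collapse = ";"), character(1))
    rownames(df) <- NULL
    df
  }
  for (perm in list(c(2, 1, 3, 4), c(4, 3, 2, 1), c(3, 1, 4, 2))) {
    out <- deduplicate(merge_sources(cats[perm]))
    expect_equal(key(out), key(ref))
  }
})

test_that("count_by counts herb memberships and per-source totals conserve", {
  cat63 <- read_table2()
  by_herb <- count_by(cat63, "herb")
  expect_equal(sum(by_herb$n), 66)  # dual-herb compounds count once per herb
  expect_equal(by_herb$n[by_herb$group == "HE"], 17)

  empty <- deduplicate(merge_sources(list()))
  expect_equal(nrow(count_by(empty, "herb")), 0)

  a <- make_catalog(data.frame(name = c("x", "y"), herb = "H1"), "dbA")
  b <- make_catalog(data.frame(name = "z", herb = "H2"), "dbB")
  m <- merge_sources(list(a, b))
  by_src <- count_by(m, "source")
  expect_equal(sum(by_src$n), nrow(m))  # pre-dedup conservation

  expect_error(count_by(cat63, "colour"))
})

test_that("catalogs round-trip through the canonical TSV writer", {
  cat63 <- read_table2()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_compound_table(cat63, path)
  back <- read_compound_table(path)
  expect_equal(back$compound_id, cat63$compound_id)
  expect_equal(back$mw, cat63$mw)
  expect_equal(back$herbs, cat63$herbs)
})

test_that("catalog invariants are enforced", {
  expect_error(make_catalog(data.frame(name = "x", herb = "H1", mw = -5)), "mw")
  expect_error(make_catalog(data.frame(name = "x", herb = "H1", hbd = 1.5)), "hbd")
  expect_error(make_catalog(data.frame(name = "x", herb = "H1", dl = 1.2)), "dl")
})
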