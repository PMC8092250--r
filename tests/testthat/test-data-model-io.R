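test_that("asv_table validates counts and applies canonical child order", {
  t <- toy_table()
  expect_equal(t$depth, c(c1 = 10, c2 = 7, c3 = 3))
  expect_error(asv_table(matrix(c(1.5, 2, 3, 4), 2)), "integral")
  expect_error(asv_table(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  m <- toy_counts()
  rownames(m) <- c("b", "a", "c")
  t2 <- asv_table(m)
  expect_equal(t2$child_ids, c("a", "b", "c"))
  expect_equal(t2$counts["a", ], m["a", ])
  expect_error(asv_table(rbind(m, m)), "duplicate child_id")
})

test_that("explicit depths survive ASV subsetting, defaults are row sums", {
  t <- toy_table(depth = c(100, 200, 300))
  kept <- subset_asvs(t, c("A1", "A3"))
  expect_equal(unname(kept$depth), c(100, 200, 300))
  expect_equal(unname(toy_table()$depth), unname(rowSums(toy_counts())))
})

test_that("asv table marginals are conserved under column reordering", {
  t <- toy_table()
  perm <- c(3, 1, 4, 2)
  t2 <- subset_asvs(t, perm)
  expect_equal(rowSums(t2$counts), rowSums(t$counts))
  expect_equal(sort(colSums(t2$counts)), sort(colSums(t$counts)))
})

test_that("count tables round-trip through disk with covariates", {
  t <- toy_table(depth = c(50, 60, 70))
  md <- toy_metadata()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_asv_table(t, f, metadata = md)
  back <- read_asv_table(f)
  expect_equal(back$table$counts, t$counts)
  expect_equal(back$table$depth, t$depth)
  expect_equal(back$metadata$home_id, md$home_id)
  expect_equal(back$metadata$age_years, md$age_years)
})

test_that("reader recomputes depth when the column is absent", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("child_id\tA1\tA2", "c1\t3\t4", "c2\t0\t2"), f)
  got <- read_asv_table(f)
  expect_equal(unname(got$table$depth), c(7, 2))
  expect_null(got$metadata)
})

test_that("reader rejects malformed count tables", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("child_id\tA1", "c1\t2.5"), f)
  expect_error(read_asv_table(f), "non-integer")
  writeLines(c("child_id\tA1", "c1\t2", "c1\t3"), f)
  expect_error(read_asv_table(f), "duplicate child_id")
  writeLines(c("child_id\tA1", "c1\t2", "c2\t3"), f)
  md <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("child_id\thome_id\tsex\tage_years\tbmi_z",
               "c1\t\t1\t5\t0", "c2\th2\t2\t6\t0"), md)
  expect_error(read_asv_table(f, metadata_path = md), "home_id")
})

test_that("metadata validation enforces coding and completeness", {
  base <- data.frame(child_id = "c1", home_id = "h1", sex = 1,
                     age_years = 5, bmi_z = 0.2)
  expect_s3_class(sample_metadata(base), "sample_metadata")
  bad <- base; bad$sex <- 3
  expect_error(sample_metadata(bad), "sex")
  bad <- base; bad$age_years <- -1
  expect_error(sample_metadata(bad), "age_years")
  bad <- base; bad$bmi_z <- NA
  expect_error(sample_metadata(bad), "bmi_z")
})

test_that("square matrices read back across delimiters and layouts", {
  # labelled, tab
  f <- withr::local_tempfile()
  writeLines(c("id\tc1\tc2", "c1\t0\t0.4", "c2\t0.4\t0"), f)
  m <- read_square_matrix(f, "bray_curtis")
  expect_equal(m$child_ids, c("c1", "c2"))
  expect_equal(m$values["c1", "c2"], 0.4)
  # unlabelled, comma
  writeLines(c("0,0.4", "0.4,0"), f)
  m2 <- read_square_matrix(f, "bray_curtis")
  expect_equal(unname(m2$values[1, 2]), 0.4)
  expect_equal(diag(m2$values), c(child1 = 0, child2 = 0))
  # header only, space-delimited
  writeLines(c("c1 c2", "0 0.4", "0.4 0"), f)
  m3 <- read_square_matrix(f, "jaccard")
  expect_equal(m3$child_ids, c("c1", "c2"))
})

test_that("asymmetry and shape errors are informative", {
  f <- withr::local_tempfile()
  writeLines(c("id\tc1\tc2", "c1\t0\t0.4", "c2\t0.5\t0"), f)
  expect_error(read_square_matrix(f, "bray_curtis"), "worst cell")
  writeLines(c("0\t0.4\t0.1", "0.4\t0\t0.2"), f)
  expect_error(read_square_matrix(f, "bray_curtis"), "not square")
  expect_error(pairwise_matrix(matrix(c(0, 0.4, 0.4 + 2e-8, 0), 2),
                               "bray_curtis"),
               "asymmetric")
})

test_that("write/read is an identity at 1e-12 for every matrix kind", {
  set.seed(41)
  f <- withr::local_tempfile()
  for (kind in c("bray_curtis", "jaccard", "genetic_dissimilarity")) {
    m <- random_sym(10)
    pm <- pairwise_matrix(m, kind)
    write_square_matrix(pm, f)
    back <- read_square_matrix(f, kind)
    expect_equal(back$values, pm$values, tolerance = 1e-12)
    expect_identical(back$child_ids, pm$child_ids)
  }
  env <- (random_sym(6) > 0.5) * 1
  pm <- pairwise_matrix(env, "environment_dissimilarity")
  write_square_matrix(pm, f)
  expect_equal(read_square_matrix(f, "environment_dissimilarity")$values,
               pm$values)
  # degenerate single child
  one <- pairwise_matrix(matrix(0, 1, 1, dimnames = list("c1", "c1")),
                         "bray_curtis")
  write_square_matrix(one, f)
  expect_equal(read_square_matrix(f, "bray_curtis")$values, one$values)
})

test_that("environment matrices must be binary, relatedness unit-diagonal", {
  expect_error(pairwise_matrix(matrix(c(0, 0.5, 0.5, 0), 2),
                               "environment_dissimilarity"),
               "binary")
  expect_error(pairwise_matrix(matrix(c(0.9, 0.2, 0.2, 1), 2), "relatedness"),
               "unit diagonal")
})

test_that("pair records classify relationship bands and co-residence", {
  ids <- c("c1", "c2", "c3", "c4")
  K <- diag(1, 4)
  K[1, 2] <- K[2, 1] <- 0.5
  K[3, 4] <- K[4, 3] <- 0.25
  dimnames(K) <- list(ids, ids)
  md <- toy_metadata(ids, homes = c("h1", "h2", "h1", "h3"))
  pr <- pair_records(md, pairwise_matrix(K, "relatedness"))
  expect_equal(nrow(pr), 6)
  census <- pair_census(pr)
  expect_equal(unname(census["full_apart"]), 1L)
  expect_equal(unname(census["half_apart"]), 1L)
  expect_equal(unname(census["unrelated_together"]), 1L)
  lnd <- pr$age_diff_ln[pr$child_a == "c1" & pr$child_b == "c2"]
  expect_equal(lnd, abs(log(5) - log(7)))
})
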