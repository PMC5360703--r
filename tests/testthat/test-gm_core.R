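test_that("variable construction rejects degenerate cardinalities", {
  expect_error(gm_variable("X", "feature", 1), "cardinality")
  expect_error(gm_variable("X", "feature", 0), "cardinality")
  expect_s3_class(gm_variable("X", "feature", 2), "gm_variable")
  expect_error(gm_variable("X", "nonsense", 2))
})

test_that("validate_model flags constructed defects and passes a clean chain", {
  chain <- gen_model(
    list(gm_variable("X", "feature", 2), gm_variable("Y", "observation", 2)),
    list(gm_block("X", table = c(0.5, 0.5)),
         gm_block("Y", "X", matrix(c(0.9, 0.1, 0.2, 0.8), 2))))
  expect_identical(validate_model(chain), character(0))

  bad_norm <- gen_model(
    list(gm_variable("X", "feature", 2), gm_variable("Y", "observation", 2)),
    list(gm_block("X", table = c(0.5, 0.5)),
         gm_block("Y", "X", matrix(c(0.8, 0.1, 0.2, 0.8), 2))))
  v <- validate_model(bad_norm)
  expect_length(v, 1)
  expect_match(v, "sums to 0.9")
  expect_match(v, "Y\\|X")

  cyc <- gen_model(
    list(gm_variable("A", "feature", 2), gm_variable("B", "feature", 2)),
    list(gm_block("A", "B", matrix(0.5, 2, 2)),
         gm_block("B", "A", matrix(0.5, 2, 2))))
  expect_match(validate_model(cyc), "cycle", all = FALSE)

  uncovered <- gen_model(
    list(gm_variable("A", "feature", 2), gm_variable("B", "feature", 2)),
    list(gm_block("A", table = c(0.5, 0.5))))
  expect_match(validate_model(uncovered), "not a child", all = FALSE)
})

test_that("joint_probability matches naive per-cell products and normalizes", {
  single <- gen_model(list(gm_variable("X", "feature", 2)),
                      list(gm_block("X", table = c(0.5, 0.5))))
  expect_equal(joint_probability(single, c(X = 0L)), 0.5)
  expect_error(joint_probability(single, c(Y = 0L)), "incomplete")

  chain <- load_fixture("chain3")$payload
  expect_equal(joint_probability(chain, c(X = 1L, Y = 1L, Z = 0L)), 0.0675)
  expect_error(joint_probability(chain, c(X = 1L, Y = 1L)), "incomplete")

  set.seed(11)
  for (i in 1:20) {
    m <- random_model(4, joint_block = i %% 2 == 0)
    g <- oracle_joint_grid(m)
    expect_equal(sum(g$p), 1, tolerance = 1e-10)
    j <- sample(nrow(g), 1)
    expect_equal(joint_probability(m, unlist(g[j, names(m$cards)])),
                 g$p[j], tolerance = 1e-12)
  }
})

test_that("count_block_cells equals the product closed form on random shapes", {
  b <- gen_model(
    list(gm_variable("C1", "feature", 2), gm_variable("C2", "feature", 2),
         gm_variable("P", "feature", 2)),
    list(gm_block("P", table = c(0.5, 0.5)),
         gm_block(c("C1", "C2"), "P", matrix(0.25, 4, 2))))
  expect_equal(count_block_cells(b, 2), 8)
  expect_equal(count_block_cells(b, integer(0)), 0L)
  expect_error(count_block_cells(b, 5), "selector")

  set.seed(42)
  for (i in 1:100) {
    m <- random_model(sample(3:5, 1), joint_block = TRUE)
    expected <- sum(vapply(m$blocks, function(bl)
      prod(m$cards[bl$children]) * prod(c(1, m$cards[bl$parents])),
      numeric(1)))
    expect_equal(count_block_cells(m), expected)
  }
})

test_that("model serialization round-trips variables, tables and metadata", {
  set.seed(7)
  m <- random_model(4, joint_block = TRUE)
  m$metadata <- list(id = "roundtrip", note = "x")
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(names(m2$cards), names(m$cards))
  expect_identical(m2$cards, m$cards)
  for (i in seq_along(m$blocks)) {
    expect_identical(m2$blocks[[i]]$children, m$blocks[[i]]$children)
    expect_identical(m2$blocks[[i]]$parents, m$blocks[[i]]$parents)
    expect_equal(m2$blocks[[i]]$table, m$blocks[[i]]$table,
                 tolerance = 1e-12)
  }
  expect_identical(m2$metadata$id, "roundtrip")
})
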