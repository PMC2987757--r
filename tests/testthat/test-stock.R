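test_that("stock constructor builds a labelled, zero-filled array", {
  st <- specialty_stock(specialties = c("a", "b"))
  expect_s3_class(st, "specialty_stock")
  expect_equal(dim(st), c(2L, 2L, 36L))
  expect_equal(stock_ages(st), 30:65)
  expect_equal(stock_specialties(st), c("a", "b"))
  expect_equal(stock_total(st), 0)
  expect_error(specialty_stock(matrix(1, 2, 2), specialties = c("a", "b")),
               "array")
})

test_that("stock totals agree with plain margin sums", {
  set.seed(7)
  st <- random_stock(S = 4)
  expect_equal(stock_total(st), sum(unclass(st)))
  expect_equal(unname(stock_total(st, by = "specialty")),
               sapply(1:4, function(s) sum(st[s, , ])))
  expect_equal(unname(stock_total(st, by = "sex")),
               c(sum(st[, 1, ]), sum(st[, 2, ])))
  df <- as.data.frame(st)
  expect_equal(sum(df$count), stock_total(st))
  expect_equal(nrow(df), 4 * 2 * 36)
})

test_that("negative cells are rejected with the offending cell named", {
  st <- specialty_stock(specialties = "onc")
  st["onc", "male", "40"] <- -1
  expect_error(workforcesim:::validate_stock(st), "onc.*male.*40")
})

test_that("stock CSV round trip preserves counts exactly", {
  set.seed(11)
  st <- random_stock(S = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_stock_csv(st, f)
  back <- read_stock_csv(f)
  expect_equal(unclass(back), unclass(st), tolerance = 0)
})
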