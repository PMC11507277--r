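test_that("CSV reading preserves rows and parses labels case-insensitively", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("p1,p2,p3,p4,label",
               "3.32,2.6,3.61,2.0,Supine",
               "2.2,2.8,3.0,2.3,SIDE",
               "2.7,3.22,2.5,2.1,prone"), path)
  d <- read_posture_csv(path)
  expect_equal(nrow(d), 3)
  expect_equal(as.character(d$label), c("supine", "side", "prone"))
  expect_equal(posture_code(d$label), c(0L, 1L, 3L))
})

test_that("schema remapping reads nonstandard column names", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("back,waist,butt,legs,pose",
               "1,1,1,1,fetus"), path)
  d <- read_posture_csv(path, schema = c(p1 = "back", p2 = "waist",
                                         p3 = "butt", p4 = "legs",
                                         label = "pose"))
  expect_equal(d$p2, 1)
  expect_equal(as.character(d$label), "fetus")
})

test_that("reader errors name the offending column, row, or label", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("p1,p2,p3,label", "1,1,1,supine"), path)
  expect_error(read_posture_csv(path), "p4")

  writeLines(c("p1,p2,p3,p4,label",
               "1,1,1,1,supine",
               "1,abc,1,1,side"), path)
  expect_error(read_posture_csv(path), "abc.*row 2")

  writeLines(c("p1,p2,p3,p4,label",
               "1,1,1,1,supine",
               "1,1,1,1,sitting"), path)
  expect_error(read_posture_csv(path), "sitting.*row 2")
})

test_that("write/read round trip preserves pressures and labels", {
  d <- generate_postures(10, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_posture_csv(d, path)
  d2 <- read_posture_csv(path)
  expect_equal(as.matrix(d2[1:4]), as.matrix(d[1:4]), tolerance = 1e-6)
  expect_equal(as.character(d2$label), as.character(d$label))
})

test_that("pressure validation rejects negatives and non-finite values", {
  expect_error(posture_dataset(data.frame(p1 = -1, p2 = 1, p3 = 1, p4 = 1)),
               "negative")
  expect_error(posture_dataset(data.frame(p1 = NaN, p2 = 1, p3 = 1, p4 = 1)),
               "non-finite")
})

test_that("splitting gives an exact 8:2 partition, deterministic per seed", {
  d <- generate_postures(25, seed = 3) # 100 rows
  sp <- split_dataset(d, test_fraction = 0.2, seed = 11)
  expect_equal(nrow(sp$train), 80)
  expect_equal(nrow(sp$test), 20)
  # exact partition: multiset of rows is preserved
  all_rows <- rbind(as.data.frame(sp$train), as.data.frame(sp$test))
  key <- function(x) sort(do.call(paste, c(x[1:4], x["label"])))
  expect_equal(key(all_rows), key(as.data.frame(d)))
  sp2 <- split_dataset(d, test_fraction = 0.2, seed = 11)
  expect_identical(as.data.frame(sp$test), as.data.frame(sp2$test))
  sp3 <- split_dataset(d, test_fraction = 0.2, seed = 12)
  expect_false(identical(as.data.frame(sp$test), as.data.frame(sp3$test)))
})

test_that("stratified split of 40 balanced samples puts 2 of each class in test", {
  d <- generate_postures(10, seed = 5) # 40 rows, 10 per class
  sp <- split_dataset(d, test_fraction = 0.2, stratified = TRUE, seed = 1)
  expect_equal(unname(table(sp$test$label)), rep(2L, 4), ignore_attr = TRUE)
  expect_equal(unname(table(sp$train$label)), rep(8L, 4), ignore_attr = TRUE)
})

test_that("the seed controls the RNG, not the data order", {
  d <- generate_postures(25, seed = 3)
  shuffled <- with_seed_order <- as.data.frame(d)[rev(seq_len(nrow(d))), ]
  d2 <- posture_dataset(shuffled[1:4], label = shuffled$label)
  sp_a <- split_dataset(d, seed = 9, stratified = FALSE)
  sp_b <- split_dataset(d2, seed = 9, stratified = FALSE)
  expect_false(identical(as.data.frame(sp_a$test), as.data.frame(sp_b$test)))
})

test_that("stratification refuses classes with fewer than 2 members", {
  d <- posture_dataset(data.frame(p1 = rep(1, 9), p2 = 1, p3 = 1, p4 = 1),
                       label = c(rep("supine", 4), rep("side", 2),
                                 rep("fetus", 2), "prone"))
  expect_error(split_dataset(d, stratified = TRUE, seed = 0),
               "stratification error.*prone")
})
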