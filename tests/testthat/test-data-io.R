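# Readers/writers and container invariants.

make_matrix_file <- function(m, path, labels = NULL, sep = "\t") {
  chr <- matrix(as.character(m), nrow(m), dimnames = dimnames(m))
  if (!is.null(labels)) chr <- rbind(chr, class = labels)
  out <- cbind(id = rownames(chr), chr)
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

test_that("expression parsing preserves shape, labels, and orientation symmetry", {
  m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12), 3, 4,
              dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
  labs <- c("tumor", "Tumor", "normal", "NORMAL")
  f <- make_matrix_file(m, tempfile(fileext = ".tsv"), labels = labs)
  ds <- read_expression(f, scale = "linear")
  expect_identical(dim(ds$values), c(3L, 4L))
  expect_identical(unname(ds$labels), c("tumor", "tumor", "normal", "normal"))
  expect_equal(ds$values, m)

  ft <- make_matrix_file(t(m), tempfile(fileext = ".tsv"))
  lf <- tempfile()
  write.table(data.frame(paste0("S", 1:4), labs), lf, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  ds2 <- read_expression(ft, lf, orientation = "samples_in_rows", scale = "linear")
  expect_equal(ds$values, ds2$values)
  expect_identical(ds$labels, ds2$labels)
})

test_that("duplicate gene rows collapse to the max-mean row", {
  m <- matrix(c(5, 5, 2, 2, 1, 1), 3, 2, byrow = TRUE,
              dimnames = list(c("G1", "G1", "G2"), c("S1", "S2")))
  f <- make_matrix_file(m, tempfile(), labels = c("tumor", "normal"))
  expect_message(ds <- read_expression(f, scale = "linear"), "collapsed")
  expect_identical(rownames(ds$values), c("G1", "G2"))
  expect_equal(unname(ds$values["G1", ]), c(5, 5))
})

test_that("expression reader rejects bad input with informative errors", {
  m <- matrix(c("1", "oops", "3", "4"), 2, 2,
              dimnames = list(c("G1", "G2"), c("S1", "S2")))
  f <- tempfile()
  write.table(cbind(id = rownames(m), m), f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  lf <- tempfile()
  write.table(data.frame(c("S1", "S2"), c("tumor", "normal")), lf, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  expect_error(read_expression(f, lf, scale = "linear"), "non-numeric.*G2.*S1")

  m2 <- matrix(c(1, -2, 3, 4), 2, 2, dimnames = list(c("G1", "G2"), c("S1", "S2")))
  f2 <- make_matrix_file(m2, tempfile())
  expect_error(read_expression(f2, lf, scale = "linear"), "negative")
  expect_silent(read_expression(f2, lf, scale = "log2"))
  expect_error(read_expression(f2, scale = "log2"), "label")
  lf3 <- tempfile()
  write.table(data.frame("S1", "tumor"), lf3, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  expect_error(read_expression(f2, lf3, scale = "log2"), "missing class label.*S2")
})

test_that("expression write/read round-trips to full precision", {
  set.seed(42)
  m <- matrix(2^rnorm(20, 5), 5, 4,
              dimnames = list(paste0("G", 1:5), paste0("S", 1:4)))
  ds <- expression_dataset(m, rep(c("tumor", "normal"), each = 2), "linear")
  f <- tempfile(); lf <- tempfile()
  write_expression(ds, f, lf)
  ds2 <- read_expression(f, lf, scale = "linear")
  expect_identical(ds$values, ds2$values)
  expect_identical(ds$labels, ds2$labels)
})

test_that("GMT parsing de-duplicates genes and round-trips term sets", {
  f <- tempfile()
  writeLines(c("DOID:1\tlabel one\tG1\tG2\tG2",
               "DOID:2\tlabel two\tG2\tG3"), f)
  map <- read_gmt(f)
  expect_identical(map$term_to_genes$`DOID:1`, c("G1", "G2"))
  expect_true("G2" %in% map$term_to_genes$`DOID:2`)
  f2 <- tempfile()
  write_gmt(map, f2)
  map2 <- read_gmt(f2)
  expect_identical(lapply(map$term_to_genes, sort), lapply(map2$term_to_genes, sort))

  f3 <- tempfile()
  writeLines(c("DOID:1\tonly-description"), f3)
  expect_error(read_gmt(f3), "line 1")
})

test_that("OBO is_a parsing handles chains, obsolete terms, and cycles", {
  f <- tempfile()
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: DOID:A", "name: a", "is_a: DOID:B ! b", "",
               "[Term]", "id: DOID:B", "name: b", "is_a: DOID:C", "",
               "[Term]", "id: DOID:C", "name: c", "",
               "[Term]", "id: DOID:D", "is_a: DOID:A", "is_obsolete: true", "",
               "[Typedef]", "id: part_of"), f)
  edges <- read_obo_isa(f)
  expect_identical(nrow(edges), 2L)
  expect_setequal(paste(edges$child, edges$parent),
                  c("DOID:A DOID:B", "DOID:B DOID:C"))

  f2 <- tempfile()
  writeLines(c("[Term]", "id: A", "is_a: B", "",
               "[Term]", "id: B", "is_a: A"), f2)
  expect_error(read_obo_isa(f2), "cycle")

  f3 <- tempfile()
  writeLines(c("[Term]", "id: A", "name: alone"), f3)
  expect_identical(nrow(read_obo_isa(f3)), 0L)
})

test_that("survival reader drops incomplete rows and rejects invalid values", {
  f <- tempfile()
  writeLines(c("sample\ttime\tevent", "S1\t10\t1", "S2\t20\t0",
               "S3\t\t1", "S4\t5\t1"), f)
  expect_message(sv <- read_survival(f), "1 survival row")
  expect_identical(nrow(sv), 3L)

  f2 <- tempfile()
  writeLines(c("sample\ttime\tevent", "S1\t-1\t1"), f2)
  expect_error(read_survival(f2), "> 0")
  f3 <- tempfile()
  writeLines(c("sample\ttime\tevent", "S1\t3\t2"), f3)
  expect_error(read_survival(f3), "event")
})
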