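test_that("expression round-trips through TSV and CSV in canonical orientation", {
  m <- matrix(c(1.5, 2, 3, 4.25, 5, 6), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene = rownames(m), m, check.names = FALSE), tsv,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_expression(tsv), m)

  csv <- withr::local_tempfile(fileext = ".csv")
  write.table(data.frame(gene = rownames(m), m, check.names = FALSE), csv,
              sep = ",", quote = FALSE, row.names = FALSE)
  expect_equal(read_expression(csv), m)
})

test_that("a transposed file with the orientation flag gives the same matrix", {
  set.seed(11)
  m <- matrix(round(rnorm(20), 3), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene = rownames(m), m, check.names = FALSE), f1,
              sep = "\t", quote = FALSE, row.names = FALSE)
  tm <- t(m)
  write.table(data.frame(sample = rownames(tm), tm, check.names = FALSE), f2,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_expression(f2, orientation = "samples_in_rows"),
               read_expression(f1))
})

test_that("malformed cells and duplicate headers are rejected with locations", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "A\t1\t2", "B\tNA\t4"), f)
  expect_error(read_expression(f), "row 'B', column 's1'")

  writeLines(c("gene\ts1\ts1", "A\t1\t2"), f)
  expect_error(read_expression(f), "duplicate column.*s1")

  writeLines(c("gene\ts1\ts2", "A\t1\t2", "A\t3\t4"), f)
  expect_error(read_expression(f), "duplicate row.*A")
})

test_that("collapse_duplicates averages probes and patient records", {
  m <- matrix(c(4, 6, 10, 2, 8, 1), nrow = 3,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  out <- collapse_duplicates(m, gene_map = c(p1 = "G1", p2 = "G1", p3 = "G2"))
  expect_equal(out["G1", "s1"], 5)     # probes 4 and 6 -> 5
  expect_equal(out["G1", "s2"], 5)
  expect_equal(out["G2", ], c(s1 = 10, s2 = 1))

  m2 <- matrix(c(1, 3, 2, 4), nrow = 2,
               dimnames = list(c("gA", "gB"), c("r1", "r2")))
  out2 <- collapse_duplicates(m2, sample_map = c(r1 = "pat1", r2 = "pat1"))
  expect_equal(unname(out2[, "pat1"]), c(1.5, 3.5))  # (1,3) and (2,4) averaged

  # identity maps are a no-op, and collapsing is idempotent
  id_g <- setNames(rownames(m), rownames(m))
  id_s <- setNames(colnames(m), colnames(m))
  expect_equal(collapse_duplicates(m, id_g, id_s), m)
  once <- collapse_duplicates(m, gene_map = c(p1 = "G1", p2 = "G1", p3 = "G2"))
  idg2 <- setNames(rownames(once), rownames(once))
  expect_equal(collapse_duplicates(once, idg2), once)

  expect_error(collapse_duplicates(m, gene_map = c(p1 = "G1")), "absent from gene_map")
})

test_that("restrict_to_gene_list keeps matrix order and errors on no overlap", {
  m <- matrix(1:10, nrow = 5, dimnames = list(c("E", "A", "C", "B", "D"), c("s1", "s2")))
  out <- restrict_to_gene_list(m, c("B", "A", "C"))
  expect_equal(rownames(out), c("A", "C", "B"))  # input order preserved
  expect_equal(restrict_to_gene_list(m, rownames(m)), m)
  expect_error(restrict_to_gene_list(m, c("X", "Y")), "no genes")
})

test_that("align_cohort intersects and orders samples identically", {
  m <- matrix(1:10, nrow = 2, dimnames = list(c("A", "B"), paste0("s", 1:5)))
  clin <- make_clin(time = c(3, 1, 2, 5), event = c(1, 0, 1, 1))
  clin$sample_id <- c("s4", "s1", "s3", "s9")
  out <- align_cohort(m, clin)
  expect_equal(colnames(out$expression), c("s1", "s3", "s4"))
  expect_equal(out$clinical$sample_id, c("s1", "s3", "s4"))
  expect_equal(out$clinical$time, c(1, 2, 3))

  # row order of the clinical table must not matter
  out2 <- align_cohort(m, clin[c(3, 1, 4, 2), ])
  expect_equal(out2, out)

  clin_far <- clin
  clin_far$sample_id <- paste0("x", 1:4)
  expect_error(align_cohort(m, clin_far), "no samples")
})

test_that("clinical reading validates fields and converts time units to years", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ttime\tevent\tage", "P1\t24\t1\t61", "P2\t6\t0\t55"), f)
  clin <- read_clinical(f, time_unit = "months")
  expect_equal(clin$time, c(2, 0.5))
  expect_equal(clin$event, c(1L, 0L))

  writeLines(c("sample_id\ttime\tevent", "P1\t0\t1"), f)
  expect_error(read_clinical(f), "> 0")
  writeLines(c("sample_id\ttime\tevent", "P1\t2\t3"), f)
  expect_error(read_clinical(f), "event")
  writeLines(c("sample_id\ttime\tevent", "P1\t2\t1", "P1\t3\t0"), f)
  expect_error(read_clinical(f), "duplicate sample_id")
})

test_that("gene lists drop comments and blanks and must be non-empty", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# immune genes", "CD1C", "", "ERAP2  ", "CD1C", "SSTR1 # receptor"), f)
  expect_equal(read_gene_list(f), c("CD1C", "ERAP2", "SSTR1"))
  writeLines(c("# nothing", ""), f)
  expect_error(read_gene_list(f), "empty")
})
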