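make_study_files <- function(vals, labels, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  mp <- file.path(dir, "expr.tsv")
  lp <- file.path(dir, "labels.tsv")
  tab <- data.frame(gene = rownames(vals), vals, check.names = FALSE)
  write.table(tab, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(names(labels), labels), lp, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  list(matrix = mp, labels = lp)
}

test_that("expression TSV and labels are read with validation", {
  vals <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 2,
                 dimnames = list(c("g1", "g2"), c("s1", "s2", "s3", "s4")))
  labels <- setNames(c("case", "case", "control", "control"),
                     colnames(vals))
  f <- make_study_files(vals, labels)
  st <- read_expression(f$matrix, f$labels)
  expect_s3_class(st, "expression_study")
  expect_equal(dim(st$values), c(2L, 4L))
  expect_equal(st$values["g2", "s3"], 6)
  expect_equal(sum(st$labels == "case"), 2)
})

test_that("label and matrix defects are rejected", {
  vals <- matrix(1:8, 2, dimnames = list(c("g1", "g2"),
                                         c("s1", "s2", "s3", "s4")))
  labels <- setNames(c("case", "case", "control", "control"), colnames(vals))
  f <- make_study_files(vals * 1.0, labels[1:3])     # one sample unlabeled
  expect_error(read_expression(f$matrix, f$labels), "missing from labels")

  # duplicate gene rows need an explicit probe-level declaration
  vals2 <- matrix(as.numeric(1:8), 2,
                  dimnames = list(c("g1", "g1"), c("s1", "s2", "s3", "s4")))
  f2 <- make_study_files(vals2, labels)
  expect_error(read_expression(f2$matrix, f2$labels), "duplicate")
  expect_s3_class(read_expression(f2$matrix, f2$labels, probe_level = TRUE),
                  "expression_study")

  # non-numeric cell named with coordinates
  d <- withr::local_tempdir()
  writeLines(c("gene\ts1\ts2\ts3", "g1\t1\toops\t3", "g2\t1\t2\t3"),
             file.path(d, "bad.tsv"))
  writeLines(c("s1\tcase", "s2\tcontrol", "s3\tcontrol"),
             file.path(d, "lab.tsv"))
  expect_error(read_expression(file.path(d, "bad.tsv"),
                               file.path(d, "lab.tsv")),
               "gene 'g1', sample 's2'")
})

test_that("probe averaging is the arithmetic mean on the stored scale", {
  vals <- rbind(p1 = c(1, 3, 0), p2 = c(2, 4, 0), p3 = c(9, 9, 9),
                p4 = c(5, 5, 5))
  colnames(vals) <- c("s1", "s2", "s3")
  labels <- setNames(c("case", "control", "control"), colnames(vals))
  st <- expression_study(vals, labels, probe_level = TRUE)
  pm <- data.frame(probe = c("p1", "p2", "p3"),
                   gene = c("geneX", "geneX", "geneY"))
  expect_warning(out <- collapse_probes(st, pm), "dropped 1 probe")
  expect_equal(out$values["geneX", c("s1", "s2")],
               c(s1 = 1.5, s2 = 3.5))
  expect_equal(out$values["geneY", ], c(s1 = 9, s2 = 9, s3 = 9))
  # single probe per gene leaves values unchanged
  expect_equal(unname(out$values["geneY", "s3"]), 9)
  # empty mapping result errors
  expect_error(suppressWarnings(
    collapse_probes(st, data.frame(probe = "zz", gene = "g"))),
    "no probes left")
})

test_that("probe collapsing commutes with sample reordering", {
  withr::local_seed(5)
  vals <- matrix(rnorm(30), 5, 6,
                 dimnames = list(paste0("p", 1:5), paste0("s", 1:6)))
  labels <- setNames(rep(c("case", "control"), 3), colnames(vals))
  pm <- data.frame(probe = paste0("p", 1:5),
                   gene = c("a", "a", "b", "b", "b"))
  st <- expression_study(vals, labels, probe_level = TRUE)
  perm <- sample(colnames(vals))
  st_perm <- expression_study(vals[, perm], labels[perm], probe_level = TRUE)
  a <- collapse_probes(st, pm)
  b <- collapse_probes(st_perm, pm)
  expect_equal(a$values[, perm], b$values)
})

test_that("study construction enforces cohort minima", {
  vals <- matrix(1.0 * 1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(expression_study(vals, c(s1 = "case", s2 = "control")),
               "at least 2 control")
  expect_error(expression_study(vals, c(s1 = "control", s2 = "control")),
               "at least 1 case")
  expect_error(expression_study(vals, c(s1 = "case", s2 = "sick")),
               "'case' or 'control'")
})

test_that("expression round-trips through TSV", {
  withr::local_seed(9)
  vals <- matrix(round(rnorm(12), 6), 3, 4,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  labels <- setNames(rep(c("case", "control"), each = 2), colnames(vals))
  st <- expression_study(vals, labels)
  d <- withr::local_tempdir()
  write_expression(st, file.path(d, "m.tsv"), file.path(d, "l.tsv"))
  st2 <- read_expression(file.path(d, "m.tsv"), file.path(d, "l.tsv"))
  expect_equal(st2$values, st$values)
  expect_identical(st2$labels, st$labels)
})
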