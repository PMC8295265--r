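writeTempFasta <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fasta",
    .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("FASTA records parse in order with ids and sequences", {
  f <- writeTempFasta(c(">p1", "MKV"))
  aa <- readProteinFasta(f)
  expect_equal(names(aa), "p1")
  expect_equal(as.character(aa[["p1"]]), "MKV")

  f2 <- writeTempFasta(c(">a desc", "MKV", ">b", "MKVLI"))
  aa2 <- readProteinFasta(f2)
  expect_equal(names(aa2), c("a", "b"))
  expect_equal(unname(Biostrings::width(aa2)), c(3L, 5L))
})

test_that("sequences are upper-cased and unknown letters map to X", {
  f <- writeTempFasta(c(">p1", "mkz"))
  expect_equal(as.character(readProteinFasta(f)[["p1"]]), "MKX")
  # B, J, O, U, Z and * are all non-standard
  f2 <- writeTempFasta(c(">p1", "MBJOUZ"))
  expect_equal(as.character(readProteinFasta(f2)[["p1"]]), "MXXXXX")
})

test_that("malformed FASTA inputs are rejected with informative errors", {
  f <- writeTempFasta(character(0))
  expect_error(readProteinFasta(f), "empty")
  f2 <- writeTempFasta(c("MKV", ">p1", "MKV"))
  expect_error(readProteinFasta(f2), "before any header")
  f3 <- writeTempFasta(c(">p1", "MKV", ">p1", "AAA"))
  expect_error(readProteinFasta(f3), "p1")
})

test_that("regionsToTrack fills, unions and defaults to structured", {
  r0 <- data.frame(protein_id = character(0), start = integer(0),
    end = integer(0), label = character(0))
  expect_equal(regionsToTrack(r0, "disorder", "p", 4L), rep(0L, 4))

  r1 <- data.frame(protein_id = "p", start = 1L, end = 3L,
    label = "disorder")
  expect_equal(regionsToTrack(r1, "disorder", "p", 5L),
    c(1L, 1L, 1L, 0L, 0L))

  r2 <- data.frame(protein_id = "p", start = c(1L, 2L), end = c(3L, 4L),
    label = "disorder")
  expect_equal(regionsToTrack(r2, "disorder", "p", 5L),
    c(1L, 1L, 1L, 1L, 0L))

  # idempotent under duplication
  r3 <- rbind(r2, r2[1L, ])
  expect_equal(regionsToTrack(r3, "disorder", "p", 5L),
    regionsToTrack(r2, "disorder", "p", 5L))

  rBad <- data.frame(protein_id = "p", start = 4L, end = 9L,
    label = "disorder")
  expect_error(regionsToTrack(rBad, "disorder", "p", 5L), "p")
})

test_that("track coverage matches a position-set oracle", {
  set.seed(5)
  for (rep in 1:20) {
    L <- sample(5:40, 1)
    k <- sample(1:5, 1)
    s <- sample(L, k, replace = TRUE)
    e <- pmin(L, s + sample(0:10, k, replace = TRUE))
    r <- data.frame(protein_id = "p", start = s, end = e,
      label = "disorder")
    covered <- unique(unlist(Map(seq, s, e)))
    tr <- regionsToTrack(r, "disorder", "p", L)
    expect_equal(sum(tr), length(covered))
    expect_equal(which(tr == 1L), sort(covered))
  }
})

test_that("profile tables read with validation and column reordering", {
  sc <- defaultSchema()
  pr <- randomProfile(3L, "p1", sc)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeProfileTable(pr, f)
  back <- readProfileTable(f, sc, "p1", seqLength = 3L)
  expect_equal(dim(profileValues(back)), c(3L, 45L))
  expect_equal(profileValues(back), profileValues(pr), tolerance = 1e-12)

  # shuffled columns give the same profile
  df <- utils::read.delim(f, check.names = FALSE)
  set.seed(1)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df[, sample(ncol(df))], f2, sep = "\t",
    quote = FALSE, row.names = FALSE)
  expect_equal(profileValues(readProfileTable(f2, sc, "p1")),
    profileValues(back))

  # missing channel is named in the error
  f3 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df[, setdiff(names(df), "iupred_long")], f3,
    sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readProfileTable(f3, sc), "iupred_long")

  # non-numeric cell is located
  df4 <- df
  df4$conservation <- as.character(df4$conservation)
  df4$conservation[2] <- "oops"
  f4 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df4, f4, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readProfileTable(f4, sc), "conservation")

  expect_error(readProfileTable(f, sc, "p1", seqLength = 5L), "5 residues")
})

test_that("prediction CSV round-trips at 3-decimal precision", {
  set.seed(3)
  L <- 7L
  prop <- runif(L)
  bin <- as.integer(prop > 0.5)
  fl <- functionLabels()
  fp <- matrix(runif(L * 4), L, 4, dimnames = list(NULL, fl))
  fb <- matrix(0L, L, 4, dimnames = list(NULL, fl))
  fb[bin == 1L, 2] <- 1L
  fp[bin == 0L, ] <- 0
  res <- new("PredictionResult",
    proteinId = "p1", sequence = paste(sample(LETTERS[c(1, 3, 4)], L,
      replace = TRUE), collapse = ""),
    disorderPropensity = prop, disorderBinary = bin,
    functionPropensity = fp, functionBinary = fb
  )
  f <- withr::local_tempfile(fileext = ".csv")
  writePredictionCsv(res, f)
  lines <- readLines(f)
  expect_length(lines, L + 1L)

  back <- readPredictionCsv(f, "p1")
  expect_equal(back@disorderPropensity, round(prop, 3))
  expect_equal(back@disorderBinary, bin)
  expect_equal(unname(back@functionPropensity), unname(round(fp, 3)))

  # structured residues carry all-zero function binaries in the file
  rows <- utils::read.csv(f)
  structured <- rows$disorder_binary == 0
  expect_true(all(rows[structured, paste0(fl, "_binary")] == 0))
})

test_that("annotation files round-trip and validate against proteins", {
  ann <- data.frame(
    protein_id = c("a", "a", "b"), start = c(1L, 5L, 2L),
    end = c(3L, 6L, 4L),
    label = c("disorder", "protein_binding", "disorder")
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  writeRegionAnnotations(ann, f)
  prot <- Biostrings::AAStringSet(c(a = "MKVLIA", b = "MKVL"))
  back <- readRegionAnnotations(f, prot)
  expect_equal(back, ann)

  annBad <- ann
  annBad$end[3] <- 10L
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeRegionAnnotations(annBad, f2)
  expect_error(readRegionAnnotations(f2, prot), "exceeds length")

  annBad2 <- ann
  annBad2$label[1] <- "kinase"
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeRegionAnnotations(annBad2, f3)
  expect_error(readRegionAnnotations(f3), "kinase")
})
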