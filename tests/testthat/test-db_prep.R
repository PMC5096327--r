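write_tmp_fasta <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fasta",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("read_fasta parses records and normalizes residues", {
  f <- write_tmp_fasta(c(">s1", "MKV"))
  db <- read_fasta(f)
  expect_equal(db$meta$accession, "s1")
  expect_equal(db$meta$length, 3L)
  expect_identical(decode_residues(db$seqs[[1]]), "MKV")

  f2 <- write_tmp_fasta(c(">s1 some description", "mkv"))
  db2 <- read_fasta(f2)
  expect_identical(decode_residues(db2$seqs[[1]]), "MKV")
  expect_equal(db2$meta$description, "some description")

  # multi-line sequences concatenate
  f3 <- write_tmp_fasta(c(">a", "MKVL", "ITGA", ">b", "ARND"))
  db3 <- read_fasta(f3)
  expect_equal(db3$meta$length, c(8L, 4L))
})

test_that("read_fasta masks out-of-alphabet characters with a warning", {
  f <- write_tmp_fasta(c(">s1", "MK#V"))
  expect_warning(db <- read_fasta(f), "masked")
  expect_identical(decode_residues(db$seqs[[1]]), "MKXV")
  # masked count equals count of non-alphabet input characters
  f2 <- write_tmp_fasta(c(">s1", "M#K1V"))
  expect_warning(db2 <- read_fasta(f2), "2 residue")
})

test_that("read_fasta rejects empty and malformed files", {
  f <- write_tmp_fasta(character())
  expect_error(read_fasta(f), "empty")
  f2 <- write_tmp_fasta(c("", "MKVL", ">s1", "MKV"))
  expect_error(read_fasta(f2), "line 2")
  expect_error(read_fasta(tempfile()), "no such file")
})

test_that("sort_database orders by length, stably, and is invertible", {
  db <- protein_db(c(a = random_protein(5), b = random_protein(3),
                     c = random_protein(9)))
  s <- sort_database(db)
  expect_equal(s$meta$length, c(3L, 5L, 9L))
  expect_equal(s$meta$accession, c("b", "a", "c"))

  # stability on ties
  db2 <- protein_db(c(a = "MKVL", b = "ARND"))
  s2 <- sort_database(db2)
  expect_equal(s2$meta$accession, c("a", "b"))

  # round trip through the id map reproduces the input exactly
  set.seed(31)
  strs <- random_db_strings(1000, 3, 60)
  db3 <- protein_db(strs)
  s3 <- sort_database(db3)
  inv <- order(s3$sorted_to_orig)
  expect_identical(s3$meta$accession[inv], db3$meta$accession)
  expect_identical(s3$seqs[inv], db3$seqs)
  expect_true(!is.unsorted(s3$meta$length))
})

test_that("partition_blocks fills greedily and conserves the database", {
  db <- sort_database(protein_db(stats::setNames(
    vapply(c(50, 50, 50), random_protein, ""), c("a", "b", "c"))))
  bl <- partition_blocks(db, 100)
  expect_length(bl, 2)
  expect_equal(vapply(bl, function(b) length(b$seqs), 0L), c(2L, 1L))

  # an oversized sequence occupies its own block
  db2 <- sort_database(protein_db(c(big = random_protein(200))))
  bl2 <- partition_blocks(db2, 100)
  expect_length(bl2, 1)
  expect_equal(bl2[[1]]$letters, 200L)

  # conservation: blocks concatenate back to the sorted database
  set.seed(17)
  db3 <- sort_database(protein_db(random_db_strings(120, 10, 80)))
  for (cap in c(1, 64, 300, 1e6)) {
    bl3 <- partition_blocks(db3, cap)
    expect_equal(sum(vapply(bl3, `[[`, 0L, "letters")), sum(db3$meta$length))
    glob <- unlist(lapply(bl3, `[[`, "local_to_global"))
    expect_identical(glob, seq_len(nrow(db3$meta)))
    expect_identical(do.call(c, lapply(bl3, `[[`, "seqs")), db3$seqs)
    # cap respected except for single oversized sequences
    for (b in bl3)
      expect_true(b$letters <= cap || length(b$seqs) == 1L)
    # blocking never widens the id field
    for (b in bl3)
      expect_lte(seqid_bit_width(length(b$seqs)),
                 seqid_bit_width(nrow(db3$meta)))
  }
})

test_that("formatted database files round-trip byte-identically", {
  set.seed(23)
  db <- sort_database(protein_db(random_db_strings(40, 5, 50)))
  f <- withr::local_tempfile()
  write_formatted_db(db, f)
  db2 <- read_formatted_db(f)
  expect_identical(db2$meta, db$meta)
  expect_identical(db2$seqs, db$seqs)
  expect_identical(db2$sorted_to_orig, db$sorted_to_orig)
  f2 <- withr::local_tempfile()
  write_formatted_db(db2, f2)
  expect_identical(readBin(f, "raw", file.size(f) + 10),
                   readBin(f2, "raw", file.size(f2) + 10))
})

test_that("formatted database reader rejects corrupt files", {
  db <- protein_db(c(a = "MKVLITGA"))
  f <- withr::local_tempfile()
  write_formatted_db(db, f)
  raw <- readBin(f, "raw", file.size(f))
  f2 <- withr::local_tempfile()
  writeBin(raw[1:10], f2)
  expect_error(read_formatted_db(f2), "truncated")
  raw2 <- raw; raw2[1] <- as.raw(0)
  writeBin(raw2, f2)
  expect_error(read_formatted_db(f2), "magic")
})
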