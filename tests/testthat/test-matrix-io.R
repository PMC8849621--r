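test_that("TNT parsing handles minimal blocks, polymorphism and specials", {
  m <- parse_tnt("xread\n3 1\nonly 010\n;")
  expect_equal(length(m$taxa), 1L)
  expect_equal(m$n_char, 3L)
  expect_equal(unname(m$cells[1, ]), c(1L, 2L, 1L)) # bitmasks for 0,1,0

  m2 <- parse_tnt("xread\n4 2\na 0?[01]-\nb 1101\n;")
  expect_true(is.na(m2$cells[1, 2]))
  expect_equal(unname(m2$cells[1, 3]), 3L)      # {0,1}
  expect_equal(unname(m2$cells[1, 4]), -1L)     # inapplicable
  # defaults when no ccode present
  expect_true(all(m2$char_meta$active))
  expect_false(any(m2$char_meta$ordered))
  expect_true(all(m2$char_meta$weight == 1))
})

test_that("TNT parsing honours ccode ordering/activation/weight commands", {
  txt <- "xread\n5 2\na 01210\nb 10012\n;\nccode + 1 3;\nccode ] 0;\nccode /2 4;\nproc /;"
  m <- parse_tnt(txt)
  expect_equal(which(m$char_meta$ordered), c(2L, 4L)) # 0-based in file
  expect_equal(which(!m$char_meta$active), 1L)
  expect_equal(m$char_meta$weight, c(1, 1, 1, 1, 2))
})

test_that("TNT parser reports structural errors with context", {
  expect_error(parse_tnt("xread\n3 2\na 010\n;"), "declared 2 taxa")
  expect_error(parse_tnt("xread\n3 1\na 01\n;"), "declared 3 characters")
  expect_error(parse_tnt("xread\n3 1\na 0x0\n;"), "unknown state token")
  # a repeated taxon whose combined row overshoots the declared length
  expect_error(parse_tnt("xread\n2 2\na 01\na 01\n;"), "declared")
})

test_that("NEXUS parsing reads FORMAT symbols and reports errors", {
  txt <- paste(
    "#NEXUS",
    "BEGIN DATA;",
    "  DIMENSIONS NTAX=2 NCHAR=2;",
    '  FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS="0 1";',
    "  MATRIX", "  t1 00", "  t2 0?", "  ;", "END;", sep = "\n")
  m <- parse_nexus(txt)
  expect_equal(length(m$taxa), 2L)
  expect_equal(m$n_char, 2L)
  expect_true(is.na(m$cells[2, 2]))

  expect_error(parse_nexus(sub("DIMENSIONS NTAX=2 NCHAR=2;", "", txt)),
               "DIMENSIONS")
  expect_error(parse_nexus(sub("t2 0\\?", "t2 02", txt)),
               "outside declared SYMBOLS")
  expect_error(parse_nexus("no nexus here"), "#NEXUS")
})

test_that("TNT and NEXUS writers round-trip random matrices (property)", {
  set.seed(11)
  for (r in 1:100) {
    m <- random_matrix(sample(2:8, 1), sample(1:15, 1),
                       n_states = sample(2:4, 1), random_meta = r %% 2 == 0)
    expect_true(m == parse_tnt(write_tnt(m)), label = paste("tnt rep", r))
    expect_true(m == parse_nexus(write_nexus(m)), label = paste("nexus rep", r))
  }
})

test_that("writers force the documented notation", {
  m <- character_matrix("t", list(list(0L)))
  expect_match(write_tnt(m), "1 1")
  m2 <- character_matrix("t", list(list(c(0L, 1L))))
  expect_match(write_tnt(m2), "\\[01\\]", all = FALSE)
  expect_match(write_nexus(m2), "\\(01\\)", all = FALSE)
})

test_that("drop_characters keeps order, drops metadata in parallel", {
  set.seed(3)
  m <- random_matrix(4, 10, random_meta = TRUE)
  expect_true(drop_characters(m, integer(0)) == m)
  d <- drop_characters(m, c(3L, 7L))
  expect_equal(d$n_char, 8L)
  keep <- setdiff(1:10, c(3, 7))
  expect_identical(unname(d$cells), unname(m$cells[, keep]))
  expect_equal(d$char_meta$weight, m$char_meta$weight[keep])
  # two sequential drops commute with one combined drop (index remapping)
  a <- drop_characters(drop_characters(m, 3L), 6L) # 6 post-drop == original 7
  expect_true(a == d)
  expect_error(drop_characters(m, c(2L, 2L)), "duplicate")
  expect_error(drop_characters(m, 11L), "out of range")

  m3 <- drop_characters(parse_tnt("xread\n3 1\na 012\n;"), 2L)
  expect_equal(unname(m3$cells[1, ]), c(1L, 4L)) # states 0 and 2 remain
})

test_that("drop_taxa removes rows only and validates names", {
  set.seed(4)
  m <- random_matrix(5, 6)
  expect_true(drop_taxa(m, character(0)) == m)
  d <- drop_taxa(m, c("tax2", "tax4"))
  expect_equal(d$taxa, c("tax1", "tax3", "tax5"))
  expect_equal(d$n_char, m$n_char)
  expect_error(drop_taxa(m, "nope"), "unknown taxa")
})

test_that("merge_matrices concatenates blocks over identical taxon sets", {
  set.seed(5)
  a <- random_matrix(3, 4)
  b <- random_matrix(3, 3)
  ab <- merge_matrices(a, b)
  expect_equal(ab$n_char, 7L)
  expect_identical(unname(ab$cells[, 1:4]), unname(a$cells))
  expect_identical(unname(ab$cells[, 5:7]), unname(b$cells))
  # merging with a 0-character matrix is the identity
  empty <- character_matrix(a$taxa, matrix(integer(0), 3, 0),
                            cladomorph:::default_char_meta(0))
  expect_true(merge_matrices(a, empty) == a)
  # associative in block order
  c3 <- random_matrix(3, 2)
  expect_true(merge_matrices(merge_matrices(a, b), c3) ==
                merge_matrices(a, merge_matrices(b, c3)))
  # taxon mismatch names the asymmetric difference
  bad <- drop_taxa(b, "tax3")
  expect_error(merge_matrices(a, bad), "tax3")
  # taxon order of b irrelevant
  b2 <- character_matrix(rev(b$taxa), b$cells[3:1, , drop = FALSE], b$char_meta)
  expect_true(merge_matrices(a, b2) == ab)
})
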