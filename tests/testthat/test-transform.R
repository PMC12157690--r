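test_that("barcode validation uppercases, accepts IUPAC codes, rejects others", {
  expect_equal(validate_barcode("catatac"), "CATATAC")
  expect_equal(validate_barcode("CATATAC"), "CATATAC")
  expect_equal(validate_barcode("nryswkmbdhvu"), "NRYSWKMBDHVU")
  expect_equal(validate_barcode(""), "")
  err <- tryCatch(validate_barcode("CAT-1"), barcodify_data_error = function(e) e)
  expect_match(conditionMessage(err), "'-'")
  expect_match(conditionMessage(err), "'1'")
})

test_that("spec construction enforces its invariants", {
  expect_error(read_structure_spec(umi_first = TRUE, umi_length = 0),
               "umi_first", class = "barcodify_usage_error")
  expect_error(read_structure_spec(umi_length = -1),
               class = "barcodify_usage_error")
  expect_error(read_structure_spec(fill_quality = "II"),
               class = "barcodify_usage_error")
  expect_error(read_structure_spec(fill_quality = " "),
               class = "barcodify_usage_error")
  expect_silent(read_structure_spec(fill_quality = "!"))
  expect_silent(read_structure_spec(fill_quality = "~"))
})

test_that("default mode prepends the barcode with fill qualities", {
  rec <- fastq_records("r1", "TTTTTTTTAAAAGGGG", "FFFFFFFFFFFFFFFF")
  out <- transform_record(rec, read_structure_spec())
  expect_equal(out$sequence, "CATATACTTTTTTTTAAAAGGGG")
  expect_equal(out$quality, "IIIIIIIFFFFFFFFFFFFFFFF")
  expect_equal(out$id, "r1")
  # geometry: barcode occupies positions 1-7, original 5' base lands at 8
  expect_equal(substr(out$sequence, 1, 7), "CATATAC")
  expect_equal(substr(out$sequence, 8, 15), "TTTTTTTT")
})

test_that("umi-first mode keeps the UMI's original qualities at the 5' end", {
  rec <- fastq_records("r1", "NNNNNNNNGGGG", "AAAAAAAABBBB")
  spec <- read_structure_spec("CAT", umi_length = 8, umi_first = TRUE)
  out <- transform_record(rec, spec)
  expect_equal(out$sequence, "NNNNNNNNCATGGGG")
  expect_equal(out$quality, "AAAAAAAAIIIBBBB")
})

test_that("linker bases and their qualities are discarded", {
  # positional classes: 8 x U (umi), 6 x L (linker), 4 x X (insert)
  rec <- fastq_records("r1", "UUUUUUUULLLLLLXXXX", "uuuuuuuullllllxxxx")
  spec <- read_structure_spec("CAT", umi_length = 8, linker_length = 6,
                              umi_first = TRUE)
  out <- transform_record(rec, spec)
  expect_equal(out$sequence, "UUUUUUUUCATXXXX")
  expect_equal(out$quality, "uuuuuuuuIIIxxxx")
  expect_equal(nchar(out$sequence), 18 + 3 - 6)
})

test_that("empty barcode with no UMI/linker is the identity transform", {
  fix <- generate_fixture(100, seed = 5)
  spec <- read_structure_spec("", 0, 0)
  out <- transform_records(fix$records, spec)
  expect_identical(out$records, fix$records)
  expect_equal(out$result$records_skipped, 0L)
})

test_that("engine output matches the naive oracle on 1000+ reads per mode", {
  fix <- generate_fixture(1000, umi_length = 8, linker_length = 6,
                          insert_length_range = c(20, 80), seed = 77)
  for (spec in mode_specs()) {
    got <- transform_records(fix$records, spec)$records
    expect_identical(got, oracle_transform(fix$records, spec))
  }
})

test_that("length arithmetic and provenance hold across random parameterizations", {
  set.seed(2024)
  for (i in 1:25) {
    u <- sample(0:10, 1)
    l <- sample(0:8, 1)
    bc <- paste0(sample(c("A", "C", "G", "T", "N"), sample(0:12, 1),
                        replace = TRUE), collapse = "")
    umi_first <- u > 0 && runif(1) < 0.5
    spec <- read_structure_spec(bc, u, l, umi_first, short_read_policy = "skip")
    fix <- generate_fixture(40, umi_length = u, linker_length = l,
                            insert_length_range = c(0, 30),
                            n_short = if (u + l > 0) 4 else 0, seed = i)
    res <- transform_records(fix$records, spec)
    out <- res$records
    kept <- fix$records[fix$records$id %in% out$id, ]
    rownames(kept) <- NULL
    expect_equal(nchar(out$sequence),
                 nchar(kept$sequence) + nchar(bc) - l)
    expect_equal(nchar(out$quality), nchar(out$sequence))
    # provenance: every non-barcode output base is an input base in order
    expect_identical(out, oracle_transform(kept, spec))
    # headers and order untouched
    expect_identical(out$id, kept$id)
    expect_identical(out$comment, kept$comment)
  }
})

test_that("umi-first and linker code paths degenerate to the simple modes", {
  fix <- generate_fixture(200, umi_length = 8, linker_length = 0,
                          insert_length_range = c(10, 40), seed = 11)
  # with no linker and barcode-first, declaring the UMI is a no-op
  a <- transform_records(fix$records, read_structure_spec("CATATAC", 0, 0))
  b <- transform_records(fix$records, read_structure_spec("CATATAC", 8, 0, FALSE))
  expect_identical(a$records, b$records)
  # u = 0 reduces linker removal to plain 5' trimming regardless of order flag
  fix2 <- generate_fixture(200, umi_length = 0, linker_length = 6,
                           insert_length_range = c(10, 40), seed = 12)
  c1 <- transform_records(fix2$records, read_structure_spec("CATATAC", 0, 6, FALSE))
  expect_identical(c1$records, oracle_transform(fix2$records,
                                                read_structure_spec("CATATAC", 0, 6, FALSE)))
})

test_that("short reads are fatal under the fail policy, counted under skip", {
  fix <- generate_fixture(100, umi_length = 8, linker_length = 6,
                          insert_length_range = c(20, 60), n_short = 7,
                          seed = 42)
  spec_fail <- read_structure_spec("CAT", 8, 6, short_read_policy = "fail")
  short_ids <- fix$truth$read_id[fix$truth$is_short]
  err <- tryCatch(transform_records(fix$records, spec_fail),
                  barcodify_data_error = function(e) e)
  expect_s3_class(err, "barcodify_data_error")
  expect_match(conditionMessage(err), short_ids[1], fixed = TRUE)

  spec_skip <- read_structure_spec("CAT", 8, 6, short_read_policy = "skip")
  res <- transform_records(fix$records, spec_skip)
  expect_equal(res$result$records_in, 100L)
  expect_equal(res$result$records_out, 93L)
  expect_equal(res$result$records_skipped, 7L)
  expect_false(any(res$records$id %in% short_ids))
})

test_that("streaming transform reports absolute record ordinals on failure", {
  fix <- generate_fixture(60, umi_length = 8, linker_length = 6,
                          insert_length_range = c(20, 30), seed = 8)
  recs <- fix$records
  recs$sequence[47] <- "ACGT"
  recs$quality[47] <- "FFFF"
  f <- tempfile(fileext = ".fq")
  write_fastq(recs, f)
  err <- tryCatch(
    transform_fastq(f, tempfile(fileext = ".fq"),
                    spec = read_structure_spec("CAT", 8, 6),
                    chunk_size = 20),
    barcodify_data_error = function(e) e)
  expect_match(conditionMessage(err), "record 47")
  expect_match(conditionMessage(err), recs$id[47], fixed = TRUE)
})

test_that("empty input yields empty output and zero counts", {
  f <- tempfile(fileext = ".fq")
  file.create(f)
  out <- tempfile(fileext = ".fq")
  res <- transform_fastq(f, out)
  expect_equal(unclass(res)[c("records_in", "records_out", "records_skipped")],
               list(records_in = 0L, records_out = 0L, records_skipped = 0L))
  expect_equal(file.size(out), 0)
})

test_that("transform_result enforces conservation", {
  expect_error(transform_result(10, 5, 4), class = "barcodify_usage_error")
  r <- transform_result(10, 5, 5)
  expect_output(print(r), "in: 10, out: 5, skipped: 5")
})
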