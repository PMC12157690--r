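#' Generate synthetic reads with a known UMI/linker/insert decomposition
#'
#' Emits a seeded batch of synthetic reads emulating the 5'-technical
#' structure of a UMI-bearing, barcode-free plate-based library: each
#' well-formed read is `UMI (u random bases) + LINKER (a fixed l-base
#' spacer drawn once per batch) + INSERT (random bases, length uniform in
#' `insert_length_range`)`. A companion truth table records the exact
#' decomposition of every read, so transform output can be checked
#' against ground truth base by base. Optionally, `n_short` reads are
#' generated deliberately shorter than `u + l` (and flagged in the truth
#' table) to exercise the short-read policies.
#'
#' The defaults mirror the read-2 geometry of a STORM-seq-style library:
#' an 8-base UMI followed by a 6-base spacer (so that a 7-base synthetic
#' cell barcode plus UMI plus spacer spans 21 bases, the 5' region an
#' aligner would be told to clip on that mate), with 20-80 base inserts.
#'
#' Identical parameters and seed reproduce byte-identical output; the
#' caller's random-number state is left untouched.
#'
#' @param n_reads Total number of reads to generate.
#' @param umi_length UMI length `u` (default 8).
#' @param linker_length Linker/spacer length `l` (default 6).
#' @param insert_length_range Integer pair: inclusive range of insert
#'   lengths (default `c(20, 80)`).
#' @param n_short Number of reads generated with total length `< u + l`
#'   (default 0; requires `u + l > 0` when positive).
#' @param seed Integer seed; required, so every fixture is reproducible.
#' @return A list with `records` (a record `data.frame`, see
#'   [fastq_records()]) and `truth` (a `data.frame` with columns
#'   `read_id`, `umi`, `linker`, `insert`, `is_short`; for non-short
#'   reads `paste0(umi, linker, insert)` equals the read sequence, for
#'   short reads the decomposition columns are empty).
#' @examples
#' fix <- generate_fixture(5, seed = 1)
#' fix$truth
#' @export
generate_fixture <- function(n_reads,
                             umi_length = 8L,
                             linker_length = 6L,
                             insert_length_range = c(20L, 80L),
                             n_short = 0L,
                             seed) {
  n_reads <- as.integer(n_reads)
  u <- as.integer(umi_length)
  l <- as.integer(linker_length)
  n_short <- as.integer(n_short)
  if (missing(seed)) stop_usage("generate_fixture requires an explicit seed")
  if (n_reads < 0L || u < 0L || l < 0L)
    stop_usage("n_reads, umi_length and linker_length must be >= 0")
  if (n_short < 0L || n_short > n_reads)
    stop_usage("n_short must be between 0 and n_reads")
  if (n_short > 0L && u + l == 0L)
    stop_usage("cannot generate short reads when umi_length + linker_length == 0")
  ins_rng <- as.integer(insert_length_range)
  if (length(ins_rng) != 2L || any(is.na(ins_rng)) || any(ins_rng < 0L) ||
      ins_rng[1] > ins_rng[2])
    stop_usage("insert_length_range must be an increasing pair of integers >= 0")

  bases <- c("A", "C", "G", "T")
  qual_alphabet <- strsplit(rawToChar(as.raw(utf8ToInt("#"):utf8ToInt("I"))),
                            "", fixed = TRUE)[[1]]
  rand_str <- function(lens, alphabet) {
    vapply(lens, function(k)
      paste0(sample(alphabet, k, replace = TRUE), collapse = ""), character(1))
  }

  withr::with_seed(seed, {
    linker_seq <- paste0(sample(bases, l, replace = TRUE), collapse = "")
    is_short <- rep(FALSE, n_reads)
    if (n_short > 0L)
      is_short[sample.int(n_reads, n_short)] <- TRUE

    n_ok <- n_reads - n_short
    ins_len <- ins_rng[1] +
      sample.int(ins_rng[2] - ins_rng[1] + 1L, n_ok, replace = TRUE) - 1L
    umi <- rand_str(rep.int(u, n_ok), bases)
    insert <- rand_str(ins_len, bases)
    ok_seq <- paste0(umi, linker_seq, insert)
    # short reads: any total length in 0 .. u+l-1 (0 = empty sequence line)
    short_len <- sample.int(u + l, n_short, replace = TRUE) - 1L
    short_seq <- rand_str(short_len, bases)

    sequence <- character(n_reads)
    sequence[!is_short] <- ok_seq
    sequence[is_short] <- short_seq
    quality <- rand_str(nchar(sequence), qual_alphabet)
    id <- sprintf("synth%0*d", nchar(n_reads) + 1L, seq_len(max(n_reads, 1L)))[seq_len(n_reads)]

    truth <- data.frame(read_id = id,
                        umi = "", linker = "", insert = "",
                        is_short = is_short,
                        stringsAsFactors = FALSE)
    truth$umi[!is_short] <- umi
    truth$linker[!is_short] <- linker_seq
    truth$insert[!is_short] <- insert

    list(records = fastq_records(id, sequence, quality),
         truth = truth)
  })
}

#' Write a fixture to disk
#'
#' Serializes a [generate_fixture()] result as a FASTQ file (optionally
#' gzip-compressed) plus a tab-separated truth table with columns
#' `read_id`, `umi`, `linker`, `insert`, `is_short`.
#'
#' @param fixture A list from [generate_fixture()].
#' @param fastq_path Output FASTQ path (a `.gz` suffix compresses).
#' @param truth_path Output TSV path for the truth table.
#' @param compress Override FASTQ compression (see [open_fastq_sink()]).
#' @return Invisibly, a character vector of the two paths.
#' @export
write_fixture <- function(fixture, fastq_path, truth_path, compress = NULL) {
  write_fastq(fixture$records, fastq_path, compress = compress)
  utils::write.table(fixture$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fastq = fastq_path, truth = truth_path))
}
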