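IUPAC_CODES <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Validate and normalize a barcode sequence
#'
#' The inserted barcode may be any length and composition over the IUPAC
#' nucleotide alphabet (including ambiguity codes), case-insensitive. The
#' empty string is accepted and makes insertion a no-op, which is useful
#' when the tool is used purely to strip a linker.
#'
#' @param barcode Character scalar.
#' @return The barcode, uppercased.
#' @examples
#' validate_barcode("catatac")
#' @export
validate_barcode <- function(barcode) {
  if (length(barcode) != 1L || !is.character(barcode) || is.na(barcode))
    stop_data("barcode must be a single character string")
  bc <- toupper(barcode)
  chars <- strsplit(bc, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), IUPAC_CODES)
  if (length(bad))
    stop_data(sprintf(
      "invalid barcode '%s': character%s %s outside the IUPAC nucleotide alphabet",
      barcode, if (length(bad) == 1L) "" else "s",
      paste0("'", bad, "'", collapse = ", ")))
  bc
}

#' Describe a read-structure rewrite
#'
#' Bundles the parameters of the rewrite applied to every read. Each input
#' sequence is decomposed positionally as
#' `UMI (first umi_length bases) + LINKER (next linker_length bases) +
#' REST (remainder)`; qualities partition identically. The output is
#'
#' * `umi_first = FALSE`: `barcode + UMI + REST` — the barcode goes to the
#'   5' end (the default mode, used to satisfy aligners that expect a cell
#'   barcode at position 1);
#' * `umi_first = TRUE`: `UMI + barcode + REST` — the UMI is kept at the
#'   5' end and the barcode is inserted directly after it.
#'
#' Linker bases (and their qualities) are always discarded when
#' `linker_length > 0`. Inserted barcode bases receive `fill_quality`;
#' all retained bases keep their original qualities, because they were
#' really sequenced. The linker is located by length and position, not by
#' sequence matching: library-construction spacers sit at a fixed offset
#' after the UMI, and positional removal is deterministic and O(n).
#'
#' With the defaults (`barcode = "CATATAC"`, no UMI reordering, no
#' linker), a library whose reads begin with an 8-base UMI gains a 7-base
#' cell-barcode field at positions 1-7 and keeps its UMI at positions
#' 8-15 — i.e. cell-barcode start 1 / length 7, UMI start 8 / length 8 in
#' the geometry flags of a solo-style aligner.
#'
#' @param barcode Barcode to insert (IUPAC, any length, may be `""`).
#'   Default `"CATATAC"`.
#' @param umi_length Number of 5' bases treated as the UMI (`>= 0`;
#'   0 means the read has no in-read UMI).
#' @param linker_length Number of bases immediately after the UMI to
#'   remove (`>= 0`; 0 means no linker).
#' @param umi_first If `TRUE`, keep the UMI at the 5' end and insert the
#'   barcode after it; requires `umi_length > 0`.
#' @param fill_quality Single ASCII character in the printable Phred+33
#'   range (`!` .. `~`) assigned to every inserted barcode base. Default
#'   `"I"` (Phred 40), so synthetic bases are never removed by downstream
#'   quality filters.
#' @param short_read_policy What to do with reads shorter than
#'   `umi_length + linker_length`: `"fail"` (default) aborts naming the
#'   read — silent truncation would corrupt the barcode/UMI geometry the
#'   aligner is told to expect — while `"skip"` drops and counts them.
#' @return An object of class `read_structure_spec`.
#' @examples
#' read_structure_spec()                     # prepend CATATAC
#' read_structure_spec("CAT", umi_length = 8, umi_first = TRUE)
#' @export
read_structure_spec <- function(barcode = "CATATAC",
                                umi_length = 0L,
                                linker_length = 0L,
                                umi_first = FALSE,
                                fill_quality = "I",
                                short_read_policy = c("fail", "skip")) {
  barcode <- validate_barcode(barcode)
  umi_length <- as.integer(umi_length)
  linker_length <- as.integer(linker_length)
  if (is.na(umi_length) || umi_length < 0L)
    stop_usage("umi_length must be an integer >= 0")
  if (is.na(linker_length) || linker_length < 0L)
    stop_usage("linker_length must be an integer >= 0")
  if (!is.character(fill_quality) || length(fill_quality) != 1L ||
      nchar(fill_quality) != 1L)
    stop_usage("fill_quality must be a single character")
  code <- utf8ToInt(fill_quality)
  if (code < utf8ToInt("!") || code > utf8ToInt("~"))
    stop_usage("fill_quality must be a printable ASCII character in '!'..'~'")
  if (isTRUE(umi_first) && umi_length == 0L)
    stop_usage("umi_first requires umi_length > 0")
  short_read_policy <- match.arg(short_read_policy)
  structure(list(barcode = barcode,
                 umi_length = umi_length,
                 linker_length = linker_length,
                 umi_first = isTRUE(umi_first),
                 fill_quality = fill_quality,
                 short_read_policy = short_read_policy),
            class = "read_structure_spec")
}

#' @export
print.read_structure_spec <- function(x, ...) {
  cat(sprintf(
    "read_structure_spec: barcode='%s' (len %d), umi_length=%d, linker_length=%d,\n  order=%s, fill_quality='%s', short reads: %s\n",
    x$barcode, nchar(x$barcode), x$umi_length, x$linker_length,
    if (x$umi_first) "UMI+barcode+rest" else "barcode+UMI+rest",
    x$fill_quality, x$short_read_policy))
  invisible(x)
}

#' Per-run record accounting
#'
#' @param records_in Records read.
#' @param records_out Records written.
#' @param records_skipped Records dropped under the `skip` short-read
#'   policy. Always `records_in == records_out + records_skipped`.
#' @return An object of class `transform_result`.
#' @export
transform_result <- function(records_in, records_out, records_skipped = 0L) {
  records_in <- as.integer(records_in)
  records_out <- as.integer(records_out)
  records_skipped <- as.integer(records_skipped)
  if (records_in != records_out + records_skipped)
    stop_usage("record accounting violated: in != out + skipped")
  structure(list(records_in = records_in, records_out = records_out,
                 records_skipped = records_skipped),
            class = "transform_result")
}

#' @export
print.transform_result <- function(x, ...) {
  cat(sprintf("records in: %d, out: %d, skipped: %d\n",
              x$records_in, x$records_out, x$records_skipped))
  invisible(x)
}

#' Rewrite the structure of a batch of reads
#'
#' Applies the rewrite described by a [read_structure_spec()] to every
#' record in a table, preserving order, ids, and comments. Reads shorter
#' than `umi_length + linker_length` are either fatal or dropped
#' according to the spec's short-read policy.
#'
#' For every emitted read,
#' `nchar(out sequence) == nchar(in sequence) + nchar(barcode) - linker_length`
#' and the quality string has exactly the same length as the sequence.
#'
#' @param records A record `data.frame` (see [fastq_records()]).
#' @param spec A `read_structure_spec`.
#' @return A list with elements `records` (the transformed table) and
#'   `result` (a [transform_result()]).
#' @examples
#' r <- fastq_records("r1", "TTTTTTTTAAAAGGGG", "FFFFFFFFFFFFFFFF")
#' transform_records(r, read_structure_spec())$records$sequence
#' @export
transform_records <- function(records, spec) {
  stopifnot(inherits(spec, "read_structure_spec"))
  u <- spec$umi_length
  l <- spec$linker_length
  n_in <- nrow(records)
  short <- nchar(records$sequence) < u + l
  if (any(short)) {
    if (spec$short_read_policy == "fail") {
      i <- which(short)[1]
      stop_data(sprintf(
        "read '%s' (record %d) has length %d, shorter than umi_length + linker_length = %d",
        records$id[i], i, nchar(records$sequence[i]), u + l),
        record_index = i, read_id = records$id[i])
    }
    records <- records[!short, , drop = FALSE]
  }
  n_out <- nrow(records)

  seqs <- records$sequence
  quals <- records$quality
  fill <- strrep(spec$fill_quality, nchar(spec$barcode))
  umi_s <- substr(seqs, 1L, u)
  umi_q <- substr(quals, 1L, u)
  rest_s <- substring(seqs, u + l + 1L)
  rest_q <- substring(quals, u + l + 1L)
  if (spec$umi_first) {
    out_s <- paste0(umi_s, spec$barcode, rest_s)
    out_q <- paste0(umi_q, fill, rest_q)
  } else {
    out_s <- paste0(spec$barcode, umi_s, rest_s)
    out_q <- paste0(fill, umi_q, rest_q)
  }
  out <- records
  out$sequence <- out_s
  out$quality <- out_q
  rownames(out) <- NULL
  list(records = out,
       result = transform_result(n_in, n_out, n_in - n_out))
}

#' Rewrite a single read
#'
#' Single-record convenience over [transform_records()].
#'
#' @param record A one-row record `data.frame`.
#' @param spec A `read_structure_spec`.
#' @return The transformed one-row record table, or `NULL` when the read
#'   is shorter than `umi_length + linker_length` and the policy is
#'   `"skip"`.
#' @export
transform_record <- function(record, spec) {
  stopifnot(nrow(record) == 1L)
  res <- transform_records(record, spec)
  if (res$result$records_out == 0L) NULL else res$records
}

#' Transform a FASTQ file end to end
#'
#' Streams records from `input` through [transform_records()] into
#' `output` in a single pass with bounded memory: records are processed
#' in fixed-size chunks and never accumulated. Input compression is
#' detected from content; output compression follows
#' [open_fastq_sink()]'s rules unless overridden.
#'
#' @param input FASTQ path or `"-"` for standard input.
#' @param output FASTQ path or `"-"` for standard output (default).
#' @param spec A [read_structure_spec()] (default: prepend `CATATAC`).
#' @param gzip_output `TRUE`/`FALSE` to force output compression, or
#'   `NULL` to decide from the output filename.
#' @param chunk_size Records per chunk; affects memory and speed only,
#'   never output bytes.
#' @return A [transform_result()] with the run's record counts.
#' @examples
#' fq <- tempfile(fileext = ".fq")
#' writeLines(c("@r1", "ACGT", "+", "FFFF"), fq)
#' out <- tempfile(fileext = ".fq")
#' transform_fastq(fq, out)
#' readLines(out)
#' @export
transform_fastq <- function(input, output = "-",
                            spec = read_structure_spec(),
                            gzip_output = NULL,
                            chunk_size = 10000L) {
  src <- open_fastq_source(input)
  on.exit(close(src), add = TRUE)
  snk <- open_fastq_sink(output, compress = gzip_output)
  on.exit(close(snk), add = TRUE)
  n_in <- 0L; n_out <- 0L
  repeat {
    ch <- read_records(src, n = chunk_size)
    if (nrow(ch) == 0L) break
    res <- tryCatch(transform_records(ch, spec),
                    barcodify_data_error = function(e) {
                      # re-signal with the absolute (whole-file) record ordinal
                      if (!is.null(e$record_index))
                        e$message <- sub(sprintf("record %d", e$record_index),
                                         sprintf("record %d", n_in + e$record_index),
                                         e$message, fixed = TRUE)
                      stop(e)
                    })
    n_in <- n_in + res$result$records_in
    n_out <- n_out + res$result$records_out
    write_records(snk, res$records)
  }
  transform_result(n_in, n_out, n_in - n_out)
}
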