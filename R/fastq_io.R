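#' Construct a table of FASTQ records
#'
#' Records are carried as a plain `data.frame` with one row per read and
#' character columns `id`, `comment`, `sequence`, `quality`. `comment` is
#' `NA` when the header line had no text after the first whitespace. The
#' constructor enforces the record invariants shared by the reader, the
#' writer, and the transform engine.
#'
#' @param id Character vector of read identifiers (must be non-empty,
#'   no whitespace).
#' @param sequence Character vector of nucleotide strings. Any
#'   non-whitespace characters are accepted; the alphabet is not policed
#'   so that IUPAC ambiguity codes, lowercase masking, and unusual calls
#'   pass through untouched.
#' @param quality Character vector of ASCII-encoded per-base qualities,
#'   same length per read as `sequence`. Phred+33 is assumed downstream
#'   but scores are never decoded.
#' @param comment Optional character vector of header comments
#'   (`NA_character_` for none).
#' @return A `data.frame` with columns `id`, `comment`, `sequence`,
#'   `quality`.
#' @examples
#' fastq_records("r1", "ACGT", "FFFF")
#' @export
fastq_records <- function(id, sequence, quality, comment = NA_character_) {
  n <- length(id)
  comment <- rep_len(as.character(comment), n)
  id <- as.character(id); sequence <- as.character(sequence)
  quality <- as.character(quality)
  if (length(sequence) != n || length(quality) != n)
    stop_usage("id, sequence and quality must have equal lengths")
  bad <- which(!nzchar(id) | grepl("[[:space:]]", id))
  if (length(bad))
    stop_parse(sprintf("record %d: read id must be non-empty and contain no whitespace", bad[1]))
  bad <- which(grepl("[[:space:]]", sequence) | grepl("[[:space:]]", quality))
  if (length(bad))
    stop_parse(sprintf("read '%s': sequence/quality must not contain whitespace", id[bad[1]]))
  bad <- which(nchar(sequence) != nchar(quality))
  if (length(bad))
    stop_parse(sprintf("read '%s': sequence length (%d) != quality length (%d)",
                       id[bad[1]], nchar(sequence[bad[1]]), nchar(quality[bad[1]])))
  data.frame(id = id, comment = comment, sequence = sequence,
             quality = quality, stringsAsFactors = FALSE)
}

#' Open a streaming FASTQ source
#'
#' Opens a strict 4-line FASTQ reader over a file or standard input.
#' Compression is detected from the stream content (the gzip magic bytes),
#' never from the filename, so gzip-compressed data arriving on standard
#' input decompresses transparently. Records are pulled in bounded-size
#' chunks with [read_records()], so memory use does not grow with file
#' size.
#'
#' Malformed input is fatal: a header line not starting with `@` or a
#' separator line not starting with `+` raises a parse error with the
#' offending line number; a sequence/quality length mismatch names the
#' read; a trailing partial record (fewer than 4 lines at end of file)
#' reports the ordinal of the last complete record. Multi-line (wrapped)
#' FASTQ is rejected: modern sequencer output is strictly 4-line, and
#' wrapped records indicate either ancient or corrupt input.
#'
#' @param path Path to a FASTQ file (plain or gzip), or `"-"` for
#'   standard input.
#' @return An object of class `fastq_source`; pass to [read_records()]
#'   and [close()] when done.
#' @seealso [read_fastq()] to slurp a whole file, [open_fastq_sink()] for
#'   writing.
#' @export
open_fastq_source <- function(path) {
  gzip_magic <- as.raw(c(0x1f, 0x8b))
  src <- new.env(parent = emptyenv())
  src$lines_read <- 0L   # absolute line counter, for error reporting
  src$records_read <- 0L
  src$eof <- FALSE
  src$prefix <- ""       # bytes consumed while sniffing stdin, not yet parsed
  src$carry <- character()  # complete lines of a record split across chunks
  src$tmpfile <- NULL

  if (identical(path, "-")) {
    src$label <- "<stdin>"
    raw_con <- file("stdin", open = "rb")
    peek <- readBin(raw_con, "raw", n = 2L)
    if (length(peek) == 2L && identical(peek, gzip_magic)) {
      # Compressed data on stdin: R has no incremental inflater over an
      # already-started pipe, so spool the stream to a temporary file
      # (fixed-size chunks, bounded memory) and decompress from there.
      tmp <- tempfile(fileext = ".gz")
      out <- file(tmp, open = "wb")
      writeBin(peek, out)
      repeat {
        chunk <- readBin(raw_con, "raw", n = 1048576L)
        if (length(chunk) == 0L) break
        writeBin(chunk, out)
      }
      close(out)
      close(raw_con)
      src$tmpfile <- tmp
      src$con <- gzfile(tmp)
      open(src$con, "rt")
    } else {
      # Plain text on stdin: keep streaming; the sniffed bytes are
      # re-attached to the first chunk. Fewer than 2 bytes means the
      # stream is empty or cannot hold a record.
      src$con <- raw_con
      src$prefix <- rawToChar(peek)
      if (length(peek) == 0L) src$eof <- TRUE
    }
  } else {
    if (!file.exists(path))
      stop_io(sprintf("cannot open FASTQ input '%s': no such file", path))
    src$label <- path
    peek <- tryCatch({
      h <- file(path, open = "rb")
      on.exit(close(h))
      readBin(h, "raw", n = 2L)
    }, error = function(e) stop_io(sprintf(
      "cannot open FASTQ input '%s': %s", path, conditionMessage(e))))
    if (length(peek) == 2L && identical(peek, gzip_magic)) {
      src$con <- gzfile(path)
      open(src$con, "rt")
    } else {
      src$con <- file(path, open = "rt")
    }
  }
  class(src) <- "fastq_source"
  src
}

# Re-attach bytes consumed during compression sniffing to the line stream.
stitch_prefix <- function(prefix, lines) {
  if (prefix == "") return(lines)
  parts <- strsplit(prefix, "\n", fixed = TRUE)[[1]]
  if (length(parts) == 0L) parts <- ""   # prefix was pure newlines
  if (endsWith(prefix, "\n")) return(c(parts, lines))
  if (length(lines) == 0L) return(parts) # partial final line at EOF
  lines[1] <- paste0(parts[length(parts)], lines[1])
  c(parts[-length(parts)], lines)
}

#' Read records from a FASTQ source
#'
#' Pulls up to `n` records from an open source in file order. Returns a
#' zero-row record table once the stream is exhausted.
#'
#' @param src A `fastq_source` from [open_fastq_source()].
#' @param n Maximum number of records to read in this call.
#' @return A record `data.frame` (see [fastq_records()]); zero rows at
#'   end of input.
#' @export
read_records <- function(src, n = 10000L) {
  stopifnot(inherits(src, "fastq_source"))
  empty <- fastq_records(character(), character(), character())
  if (src$eof && length(src$carry) == 0L) return(empty)
  if (n <= 0) return(empty)
  lines <- if (src$eof) character() else
    suppressWarnings(readLines(src$con, n = 4L * as.integer(n)))
  if (length(lines) < 4L * n) src$eof <- TRUE
  lines <- c(src$carry, stitch_prefix(src$prefix, lines))
  src$carry <- character()
  src$prefix <- ""
  nl <- length(lines)
  if (nl == 0L) return(empty)
  nrec <- nl %/% 4L
  rem <- nl %% 4L
  if (rem != 0L) {
    if (src$eof) {
      stop_parse(sprintf(
        "%s: truncated FASTQ record at end of input after record %d (%d trailing line%s)",
        src$label, src$records_read + nrec, rem, if (rem == 1L) "" else "s"),
        line = src$lines_read + nl)
    }
    # stitching can leave a partial record mid-stream; carry it forward
    src$carry <- lines[(nl - rem + 1L):nl]
    lines <- lines[seq_len(nl - rem)]
    nl <- nl - rem
    if (nl == 0L) return(read_records(src, n))
  }

  idx <- seq_len(nrec)
  hdr <- lines[4L * idx - 3L]
  seqs <- lines[4L * idx - 2L]
  sep <- lines[4L * idx - 1L]
  qual <- lines[4L * idx]

  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop_parse(sprintf("%s, line %d: expected header starting with '@', got '%s'",
                       src$label, src$lines_read + 4L * bad[1] - 3L,
                       substr(hdr[bad[1]], 1, 40)),
               line = src$lines_read + 4L * bad[1] - 3L)
  bad <- which(!startsWith(sep, "+"))
  if (length(bad))
    stop_parse(sprintf("%s, line %d: expected separator starting with '+', got '%s'",
                       src$label, src$lines_read + 4L * bad[1] - 1L,
                       substr(sep[bad[1]], 1, 40)),
               line = src$lines_read + 4L * bad[1] - 1L)

  body <- substring(hdr, 2L)
  ws <- regexpr("[[:space:]]", body)
  has_comment <- ws > 0L
  id <- ifelse(has_comment, substr(body, 1L, ws - 1L), body)
  comment <- ifelse(has_comment, substring(body, ws + 1L), NA_character_)

  out <- fastq_records(id, seqs, qual, comment)
  src$lines_read <- src$lines_read + nl
  src$records_read <- src$records_read + nrec
  out
}

#' @export
close.fastq_source <- function(con, ...) {
  close(con$con)
  if (!is.null(con$tmpfile)) unlink(con$tmpfile)
  invisible(NULL)
}

#' Read an entire FASTQ file
#'
#' Convenience wrapper around [open_fastq_source()]/[read_records()] that
#' loads all records at once. Intended for small files; use the streaming
#' interface (or [transform_fastq()]) for large ones.
#'
#' @inheritParams open_fastq_source
#' @return A record `data.frame`.
#' @examples
#' fq <- tempfile(fileext = ".fq")
#' writeLines(c("@r1", "ACGT", "+", "FFFF"), fq)
#' read_fastq(fq)
#' @export
read_fastq <- function(path) {
  src <- open_fastq_source(path)
  on.exit(close(src))
  chunks <- list()
  repeat {
    ch <- read_records(src)
    if (nrow(ch) == 0L) break
    chunks[[length(chunks) + 1L]] <- ch
  }
  if (length(chunks) == 0L) return(fastq_records(character(), character(), character()))
  do.call(rbind, chunks)
}

#' Open a FASTQ sink
#'
#' Opens a writer that serializes records as strict 4-line FASTQ:
#' `@id[ comment]`, sequence, bare `+`, quality. Output to a path ending
#' in `.gz` is gzip-compressed by default; standard output (`"-"`) is
#' uncompressed by default. Both defaults can be overridden with
#' `compress`.
#'
#' @param path Output file path, or `"-"` for standard output.
#' @param compress `TRUE` to gzip the output, `FALSE` for plain text, or
#'   `NULL` (default) to decide from the filename suffix.
#' @return An object of class `fastq_sink`; pass to [write_records()] and
#'   [close()] (closing flushes compressed streams).
#' @export
open_fastq_sink <- function(path, compress = NULL) {
  to_stdout <- identical(path, "-")
  if (is.null(compress))
    compress <- !to_stdout && grepl("\\.gz$", path)
  con <- tryCatch({
    if (to_stdout) {
      # R has no binary-mode handle on C-level stdout; on POSIX systems
      # /dev/stdout provides one for the compressed case
      if (compress) gzcon(file("/dev/stdout", open = "wb")) else stdout()
    } else if (compress) {
      gzfile(path, open = "wb")
    } else {
      file(path, open = "wb")
    }
  }, error = function(e) stop_io(sprintf(
    "cannot open output '%s': %s", if (to_stdout) "<stdout>" else path,
    conditionMessage(e))))
  snk <- new.env(parent = emptyenv())
  snk$con <- con
  snk$owns_con <- !(to_stdout && !compress)  # never close R's shared stdout()
  snk$records_written <- 0L
  class(snk) <- "fastq_sink"
  snk
}

#' Write records to a FASTQ sink
#'
#' @param snk A `fastq_sink` from [open_fastq_sink()].
#' @param records A record `data.frame` (see [fastq_records()]).
#' @return The sink, invisibly.
#' @export
write_records <- function(snk, records) {
  stopifnot(inherits(snk, "fastq_sink"))
  if (nrow(records) == 0L) return(invisible(snk))
  hdr <- paste0("@", records$id,
                ifelse(is.na(records$comment), "", paste0(" ", records$comment)))
  lines <- as.vector(rbind(hdr, records$sequence, "+", records$quality))
  writeLines(lines, snk$con)
  snk$records_written <- snk$records_written + nrow(records)
  invisible(snk)
}

#' @export
close.fastq_sink <- function(con, ...) {
  if (isTRUE(con$owns_con)) close(con$con) else flush(con$con)
  invisible(NULL)
}

#' Write a record table to a FASTQ file
#'
#' @inheritParams open_fastq_sink
#' @param records A record `data.frame`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path, compress = NULL) {
  snk <- open_fastq_sink(path, compress = compress)
  on.exit(close(snk))
  write_records(snk, records)
  invisible(path)
}
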