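# Naive slice-and-concatenate oracle for the read-structure rewrite.
# Works character by character on exploded vectors, deliberately sharing
# no code with the substr/paste0 implementation it checks.
oracle_transform_one <- function(sequence, quality, barcode, umi_length,
                                 linker_length, umi_first, fill_quality) {
  sc <- strsplit(sequence, "", fixed = TRUE)[[1]]
  qc <- strsplit(quality, "", fixed = TRUE)[[1]]
  stopifnot(length(sc) >= umi_length + linker_length)
  umi_idx <- seq_len(umi_length)
  drop_idx <- seq_len(umi_length + linker_length)
  bc <- strsplit(toupper(barcode), "", fixed = TRUE)[[1]]
  fill <- rep(fill_quality, length(bc))
  umi_s <- sc[umi_idx]; umi_q <- qc[umi_idx]
  rest_s <- sc[setdiff(seq_along(sc), drop_idx)]
  rest_q <- qc[setdiff(seq_along(qc), drop_idx)]
  if (umi_first) {
    list(sequence = paste(c(umi_s, bc, rest_s), collapse = ""),
         quality = paste(c(umi_q, fill, rest_q), collapse = ""))
  } else {
    list(sequence = paste(c(bc, umi_s, rest_s), collapse = ""),
         quality = paste(c(fill, umi_q, rest_q), collapse = ""))
  }
}

oracle_transform <- function(records, spec) {
  out <- records
  for (i in seq_len(nrow(records))) {
    o <- oracle_transform_one(records$sequence[i], records$quality[i],
                              spec$barcode, spec$umi_length,
                              spec$linker_length, spec$umi_first,
                              spec$fill_quality)
    out$sequence[i] <- o$sequence
    out$quality[i] <- o$quality
  }
  out
}

# The four canonical mode parameterizations: barcode to 5' end (A),
# umi-first (B), linker removal (C), umi-first plus linker removal (D).
mode_specs <- function(policy = "fail") {
  list(
    prepend    = read_structure_spec("CATATAC", 0, 0, FALSE, short_read_policy = policy),
    umi_first  = read_structure_spec("CATATAC", 8, 0, TRUE,  short_read_policy = policy),
    linker     = read_structure_spec("CATATAC", 8, 6, FALSE, short_read_policy = policy),
    umi_linker = read_structure_spec("CATATAC", 8, 6, TRUE,  short_read_policy = policy)
  )
}

write_tmp_fastq <- function(lines, ext = ".fq") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

write_tmp_fastq_gz <- function(lines) {
  f <- tempfile(fileext = ".fq.gz")
  con <- gzfile(f, "w")
  writeLines(lines, con)
  close(con)
  f
}

# Run main() in a child R process so stdin/stdout/exit-status behave as
# they would in a shell pipeline.
run_cli_subprocess <- function(args, stdin_file = "") {
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- tempfile(); err <- tempfile()
  code <- "status <- barcodify::main(); quit(save='no', status=as.integer(status))"
  status <- suppressWarnings(system2(
    rscript, c("-e", shQuote(code), vapply(args, shQuote, character(1))),
    stdout = out, stderr = err, stdin = stdin_file,
    env = paste0("R_LIBS=", shQuote(paste(.libPaths(), collapse = ":")))))
  list(status = status,
       stdout_raw = readBin(out, "raw", n = file.size(out)),
       stdout = readLines(out, warn = FALSE),
       stderr = readLines(err, warn = FALSE))
}
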