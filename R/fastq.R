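# FASTQ streaming. Validation requirements (record-indexed truncation and
# sequence/quality length errors, transparent gzip, multi-file iteration)
# drive a small line-based reader; 4-line FASTQ records only.

#' Stream reads from one or more FASTQ files
#'
#' Returns a chunked iterator over reads. Files may be plain or
#' gzip-compressed; paired-end mates are treated as independent reads and
#' every read is yielded exactly once across all files. Sequences are
#' uppercased, quality strings validated for length then discarded.
#'
#' @param paths character vector of FASTQ(.gz) paths, read in order.
#' @param chunk_size number of records per chunk.
#' @return an object of class `fastq_stream` with a `$next_chunk()` function
#'   returning a list with `id` and `seq` character vectors (zero-length when
#'   exhausted).
#' @export
fastq_stream <- function(paths, chunk_size = 50000L) {
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("FASTQ file(s) not found: ", paste(missing, collapse = ", "))
  env <- new.env(parent = emptyenv())
  env$paths <- paths
  env$file_i <- 0L
  env$con <- NULL
  env$rec_i <- 0L   # record index within current file (1-based)
  env$carry <- character(0)

  open_next <- function() {
    if (!is.null(env$con)) { close(env$con); env$con <- NULL }
    env$file_i <- env$file_i + 1L
    if (env$file_i > length(env$paths)) return(FALSE)
    p <- env$paths[env$file_i]
    env$con <- if (grepl("\\.gz$", p)) gzfile(p, "rt") else file(p, "rt")
    env$rec_i <- 0L
    env$carry <- character(0)
    TRUE
  }

  parse_records <- function(lines, path) {
    n_rec <- length(lines) %/% 4L
    use <- lines[seq_len(n_rec * 4L)]
    hdr <- use[seq(1L, by = 4L, length.out = n_rec)]
    seqs <- use[seq(2L, by = 4L, length.out = n_rec)]
    plus <- use[seq(3L, by = 4L, length.out = n_rec)]
    qual <- use[seq(4L, by = 4L, length.out = n_rec)]
    bad_hdr <- which(!startsWith(hdr, "@"))
    if (length(bad_hdr))
      stop("malformed FASTQ record ", env$rec_i + bad_hdr[1], " in ", path,
           ": header does not start with '@'")
    bad_plus <- which(!startsWith(plus, "+"))
    if (length(bad_plus))
      stop("malformed FASTQ record ", env$rec_i + bad_plus[1], " in ", path,
           ": separator line does not start with '+'")
    bad_len <- which(nchar(seqs) != nchar(qual))
    if (length(bad_len))
      stop("FASTQ record ", env$rec_i + bad_len[1], " in ", path,
           ": sequence and quality lengths differ")
    env$rec_i <- env$rec_i + n_rec
    list(id = sub("^@", "", sub("\\s.*$", "", hdr)), seq = toupper(seqs))
  }

  env$next_chunk <- function() {
    tryCatch(next_chunk_impl(), error = function(e) {
      if (!is.null(env$con)) { close(env$con); env$con <- NULL }
      stop(e)
    })
  }

  next_chunk_impl <- function() {
    ids <- character(0); seqs <- character(0)
    while (length(seqs) < chunk_size) {
      if (is.null(env$con)) {
        if (!open_next()) break
      }
      want <- (chunk_size - length(seqs)) * 4L - length(env$carry)
      lines <- c(env$carry, readLines(env$con, n = max(want, 4L)))
      env$carry <- character(0)
      if (length(lines) == 0) {          # current file exhausted
        close(env$con); env$con <- NULL
        next
      }
      leftover <- length(lines) %% 4L
      if (leftover) {
        # either mid-record (more lines coming) or truncated file
        more <- readLines(env$con, n = 4L - leftover)
        lines <- c(lines, more)
        if (length(lines) %% 4L != 0L)
          stop("truncated FASTQ record ", env$rec_i + length(lines) %/% 4L + 1L,
               " in ", env$paths[env$file_i])
      }
      rec <- parse_records(lines, env$paths[env$file_i])
      ids <- c(ids, rec$id); seqs <- c(seqs, rec$seq)
    }
    list(id = ids, seq = seqs)
  }
  env$close <- function() {
    if (!is.null(env$con)) { close(env$con); env$con <- NULL }
    env$file_i <- length(env$paths)
  }
  class(env) <- "fastq_stream"
  env
}

#' Read all reads from FASTQ files into memory
#'
#' Convenience wrapper around [fastq_stream()] for small files.
#'
#' @inheritParams fastq_stream
#' @return named character vector of sequences (names are read ids).
#' @export
read_fastq <- function(paths) {
  st <- fastq_stream(paths)
  ids <- character(0); seqs <- character(0)
  repeat {
    ch <- st$next_chunk()
    if (length(ch$seq) == 0) break
    ids <- c(ids, ch$id); seqs <- c(seqs, ch$seq)
  }
  stats::setNames(seqs, ids)
}

# Minimal deterministic FASTQ writer used by the simulator (constant 'I'
# qualities; gz when the path ends in .gz).
write_fastq <- function(ids, seqs, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(seqs)) {
    rec <- paste0("@", ids, "\n", seqs, "\n+\n",
                  strrep("I", nchar(seqs)), "\n")
    writeChar(paste(rec, collapse = ""), con, eos = NULL)
  }
  invisible(path)
}
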